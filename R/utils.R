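#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor p.adjust phyper pt sd wilcox.test ks.test rnorm
#'   rlnorm rpois runif rbinom
#' @importFrom utils read.table write.table combn
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Deterministic TSV writer: fixed column order, full double precision,
# no quoting, no row names. Numeric columns are rendered with %.17g so a
# write/read cycle reproduces doubles exactly.
write_tsv_ <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv_ <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "", ...)
}

# Write a genes x samples expression matrix as TSV (gene id first column).
write_matrix_tsv_ <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_(df, path)
}

read_matrix_tsv_ <- function(path) {
  df <- read_tsv_(path, colClasses = NA)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df$gene
  mat
}

stopf_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
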