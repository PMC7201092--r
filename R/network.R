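#' Filter genes by expression level
#'
#' Keeps genes expressed at or above \code{min_value} in strictly more
#' than \code{min_fraction} of the samples (the FPM >= 1 in > 80 percent
#' convention for RNA-seq matrices).
#'
#' @param matrix genes x samples non-negative expression matrix.
#' @param min_value expression level counted as expressed.
#' @param min_fraction strict lower bound on the expressed-sample fraction.
#' @return the row-subset matrix.
#' @export
filter_expressed <- function(matrix, min_value = 1, min_fraction = 0.8) {
  if (min_fraction < 0 || min_fraction > 1)
    stopf_("min_fraction must lie in [0, 1]")
  stopifnot(is.matrix(matrix), ncol(matrix) >= 1)
  frac <- rowMeans(matrix >= min_value)
  matrix[frac > min_fraction, , drop = FALSE]
}

# Vectorized two-tailed p for Pearson r at sample size n via Student's t
# with df = n - 2 and t = r * sqrt(df / (1 - r^2)). r with |r| >= 1 maps
# to p = 0 (the t statistic diverges).
r_to_p_ <- function(r, n) {
  df <- n - 2
  p <- numeric(length(r))
  extreme <- abs(r) >= 1
  p[extreme] <- 0
  t <- r[!extreme] * sqrt(df / (1 - r[!extreme]^2))
  p[!extreme] <- 2 * pt(-abs(t), df)
  p
}

#' Pearson correlation with a t-based two-tailed p-value
#'
#' The significance of a sample Pearson correlation under the
#' no-correlation null: \code{t = r * sqrt(df / (1 - r^2))} follows a
#' Student's t-distribution with \code{df = N - 2}, where N is the sample
#' size; the p-value is the two-tailed tail probability.
#'
#' @param x,y numeric vectors of equal length N >= 3; neither constant.
#' @return list with elements \code{r} and \code{p}.
#' @export
pearson_with_pvalue <- function(x, y) {
  if (length(x) != length(y)) stopf_("x and y must have equal length")
  n <- length(x)
  if (n < 3) stopf_("need at least 3 samples")
  if (sd(x) == 0 || sd(y) == 0)
    stopf_("correlation undefined for a constant vector")
  r <- cor(x, y)
  list(r = r, p = r_to_p_(r, n))
}

#' Correlation cutoff of equal statistical significance at another sample size
#'
#' A fixed correlation cutoff corresponds to different significance levels
#' at different sample sizes, which is what biases networks built from
#' unequal groups. This scans a grid of cutoffs at the target sample size
#' and returns the smallest one whose two-tailed p-value is at least as
#' extreme as that of \code{r_ref} at \code{n_ref}.
#'
#' @param r_ref reference correlation cutoff, in (0, 1).
#' @param n_ref,n_target sample sizes (>= 3).
#' @param step grid step over \code{[0, 1]}.
#' @return the smallest qualifying grid cutoff (1, with a warning, if only
#'   the degenerate endpoint qualifies).
#' @export
equivalent_cutoff <- function(r_ref, n_ref, n_target, step = 0.01) {
  if (r_ref <= 0 || r_ref >= 1) stopf_("r_ref must lie in (0, 1)")
  if (n_ref < 3 || n_target < 3) stopf_("sample sizes must be >= 3")
  p_ref <- r_to_p_(r_ref, n_ref)
  grid <- seq(0, 1, by = step)
  p_grid <- r_to_p_(grid, n_target)
  ok <- which(p_grid <= p_ref)
  if (!length(ok)) {
    warning("no grid cutoff reaches the reference significance; returning 1")
    return(1)
  }
  c_sel <- grid[ok[1]]
  if (c_sel >= 1)
    warning("only the degenerate cutoff 1 reaches the reference significance")
  c_sel
}

# Pearson correlations for a set of gene pairs in one pass: rows of `mat`
# are z-scored so each pair's r is an inner product.
edge_correlations_ <- function(mat, gene_a, gene_b) {
  n <- ncol(mat)
  mu <- rowMeans(mat)
  cmat <- mat - mu
  ss <- sqrt(rowSums(cmat^2))
  const <- ss == 0
  z <- cmat / ifelse(ss == 0, 1, ss)
  r <- rowSums(z[gene_a, , drop = FALSE] * z[gene_b, , drop = FALSE])
  r[const[gene_a] | const[gene_b]] <- NA_real_
  r
}

#' Build a condition-specific ceRNA network
#'
#' Keeps a backbone edge when the two genes' expression profiles have a
#' Pearson correlation of at least \code{cutoff} (positive co-expression
#' only; ceRNA co-regulation is positive). Nodes without any retained
#' edge are dropped. Genes with constant expression cannot be correlated
#' and are excluded with a warning.
#'
#' @param matrix genes x samples expression matrix covering all backbone
#'   genes (at least 3 samples).
#' @param backbone a \code{\link{build_backbone}} network.
#' @param cutoff correlation cutoff in \code{[0, 1]}.
#' @param log_transform correlate \code{log2(x + 1)} (default) rather than
#'   raw values; the log stabilizes variance on FPM-scale data.
#' @param condition optional label stored on the network.
#' @return an igraph network with edge attributes \code{r} and \code{q}
#'   (backbone FDR) and graph attributes \code{condition}, \code{cutoff},
#'   \code{n_samples}.
#' @export
build_cerna_network <- function(matrix, backbone, cutoff,
                                log_transform = TRUE, condition = NA) {
  if (cutoff < 0 || cutoff > 1) stopf_("cutoff must lie in [0, 1]")
  genes <- igraph::V(backbone)$name
  if (!all(genes %in% rownames(matrix)))
    stopf_("expression matrix does not cover all backbone genes")
  if (ncol(matrix) < 3) stopf_("need at least 3 samples")
  mat <- matrix[genes, , drop = FALSE]
  if (log_transform) mat <- log2(mat + 1)
  ed <- igraph::as_data_frame(backbone, what = "edges")
  if (nrow(ed)) {
    r <- edge_correlations_(mat, ed$from, ed$to)
    if (anyNA(r))
      warning("edges involving constant-expression genes were dropped")
    keep <- !is.na(r) & r >= cutoff
  } else {
    r <- numeric(0); keep <- logical(0)
  }
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  igraph::V(g)$name <- genes
  if (any(keep)) {
    idx <- match(c(rbind(ed$from[keep], ed$to[keep])), genes)
    g <- igraph::add_edges(g, idx)
    igraph::E(g)$r <- r[keep]
    if (!is.null(ed$q)) igraph::E(g)$q <- ed$q[keep]
  }
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  g <- igraph::set_graph_attr(g, "kind", "cerna")
  g <- igraph::set_graph_attr(g, "condition", condition)
  g <- igraph::set_graph_attr(g, "cutoff", cutoff)
  g <- igraph::set_graph_attr(g, "n_samples", ncol(matrix))
  g
}
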