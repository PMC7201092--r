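#' Gene x miRNA target-site table
#'
#' Container for non-negative integer site counts with an explicit miRNA
#' universe (the hypergeometric population for overlap tests). Duplicate
#' gene or miRNA identifiers are rejected rather than merged.
#'
#' @param site_count gene x miRNA matrix of non-negative integers with
#'   gene row names and miRNA column names, or a long data frame with
#'   columns \code{gene}, \code{mirna}, \code{site_count}.
#' @param universe optional ordered character vector of miRNA ids; must
#'   contain every miRNA referenced. Defaults to the matrix columns.
#' @return a list of class \code{target_table} with elements
#'   \code{site_count} (matrix over the full universe) and \code{universe}.
#' @export
target_site_table <- function(site_count, universe = NULL) {
  if (is.data.frame(site_count)) {
    df <- site_count
    stopifnot(all(c("gene", "mirna", "site_count") %in% names(df)))
    genes <- sort(unique(df$gene))
    mirs <- if (is.null(universe)) sort(unique(df$mirna)) else universe
    m <- matrix(0L, length(genes), length(mirs), dimnames = list(genes, mirs))
    if (!all(df$mirna %in% mirs))
      stopf_("target table references miRNAs outside the universe")
    if (anyDuplicated(df[c("gene", "mirna")]))
      stopf_("duplicate gene/miRNA entries in target table")
    if (nrow(df)) m[cbind(df$gene, df$mirna)] <- as.integer(df$site_count)
    site_count <- m
  } else {
    site_count <- as.matrix(site_count)
    storage.mode(site_count) <- "integer"
    if (is.null(rownames(site_count)) || is.null(colnames(site_count)))
      stopf_("site_count matrix needs gene row names and miRNA column names")
    if (!is.null(universe)) {
      if (!all(colnames(site_count) %in% universe))
        stopf_("target table references miRNAs outside the universe")
      m <- matrix(0L, nrow(site_count), length(universe),
                  dimnames = list(rownames(site_count), universe))
      m[, colnames(site_count)] <- site_count
      site_count <- m
    }
  }
  if (anyDuplicated(rownames(site_count)))
    stopf_("duplicate gene identifiers in target table")
  if (anyDuplicated(colnames(site_count)))
    stopf_("duplicate miRNA identifiers in target table")
  if (any(site_count < 0)) stopf_("negative site counts")
  structure(list(site_count = site_count, universe = colnames(site_count)),
            class = "target_table")
}

#' @export
print.target_table <- function(x, ...) {
  cat(sprintf("target-site table: %d genes x %d miRNAs, %d positive entries\n",
              nrow(x$site_count), length(x$universe), sum(x$site_count > 0)))
  invisible(x)
}

#' miRNAs targeting a gene
#'
#' @param table a \code{\link{target_site_table}}.
#' @param gene gene identifier present in the table.
#' @return character vector of miRNAs with at least one site on the gene.
#' @export
mirna_set <- function(table, gene) {
  stopifnot(inherits(table, "target_table"))
  if (!gene %in% rownames(table$site_count))
    stopf_("unknown gene: %s", gene)
  colnames(table$site_count)[table$site_count[gene, ] >= 1L]
}

# Upper-tail hypergeometric kernel: P(X >= q) drawing k from a population
# of size n_pop containing m successes. Vectorized over q, m, k.
hyper_tail_ <- function(q, m, k, n_pop) {
  phyper(q - 1, m, n_pop - m, k, lower.tail = FALSE)
}

#' Significance of miRNA-set overlap between two genes
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between two miRNA sets drawn from a common universe.
#'
#' @param set_a,set_b character vectors of miRNA ids (duplicates ignored).
#' @param universe_size size of the miRNA universe.
#' @return \code{P(X >= |A intersect B|)} in \code{[0, 1]}.
#' @export
overlap_pvalue <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (universe_size < max(length(set_a), length(set_b)))
    stopf_("universe_size smaller than a set")
  ov <- length(intersect(set_a, set_b))
  hyper_tail_(ov, length(set_a), length(set_b), universe_size)
}

#' Build the miRNA target-site-share backbone network
#'
#' Restricts to genes with a total site count of at least \code{min_sites}
#' (sponge candidates: more than 5 sites by default), tests every
#' unordered gene pair for miRNA-set overlap with the upper-tail
#' hypergeometric test, adjusts all pair p-values with Benjamini-Hochberg
#' in one family, and keeps pairs with \code{q < q_threshold}.
#'
#' @param table a \code{\link{target_site_table}}.
#' @param min_sites minimum total site count for a gene to enter.
#' @param q_threshold BH-adjusted significance threshold.
#' @param universe_size hypergeometric population size; defaults to the
#'   number of miRNAs in the table's universe.
#' @return an \pkg{igraph} undirected simple graph whose vertices are the
#'   qualifying genes and whose edges carry attributes \code{p} and
#'   \code{q}; graph attributes record the parameters.
#' @export
build_backbone <- function(table, min_sites = 6L, q_threshold = 0.05,
                           universe_size = NULL) {
  stopifnot(inherits(table, "target_table"))
  if (min_sites < 0) stopf_("min_sites must be >= 0")
  if (q_threshold <= 0 || q_threshold > 1)
    stopf_("q_threshold must lie in (0, 1]")
  if (is.null(universe_size)) universe_size <- length(table$universe)
  m <- table$site_count
  keep <- rowSums(m) >= min_sites
  m <- m[keep, , drop = FALSE]
  genes <- rownames(m)
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  igraph::V(g)$name <- genes
  g <- igraph::set_graph_attr(g, "kind", "backbone")
  g <- igraph::set_graph_attr(g, "min_sites", min_sites)
  g <- igraph::set_graph_attr(g, "q_threshold", q_threshold)
  g <- igraph::set_graph_attr(g, "universe_size", universe_size)
  if (length(genes) < 2L) return(g)
  bin <- (m > 0) * 1L
  sizes <- rowSums(bin)
  if (universe_size < max(sizes)) stopf_("universe_size smaller than a gene's miRNA set")
  ov <- tcrossprod(bin)
  iu <- which(upper.tri(ov), arr.ind = TRUE)
  p <- hyper_tail_(ov[iu], sizes[iu[, 1]], sizes[iu[, 2]], universe_size)
  q <- p.adjust(p, method = "BH")
  sel <- which(q < q_threshold)
  if (length(sel)) {
    ends <- rbind(iu[sel, 1], iu[sel, 2])
    g <- igraph::add_edges(g, as.vector(ends))
    igraph::E(g)$p <- p[sel]
    igraph::E(g)$q <- q[sel]
  }
  g
}

#' Backbone or ceRNA network edges as a data frame
#'
#' @param network an igraph network produced by this package.
#' @return data frame with columns \code{gene_a}, \code{gene_b} plus any
#'   edge attributes, rows ordered lexicographically.
#' @export
network_edges <- function(network) {
  df <- igraph::as_data_frame(network, what = "edges")
  if (!nrow(df)) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE)
    extra <- setdiff(names(df), c("from", "to"))
    for (nm in extra) out[[nm]] <- numeric(0)
    return(out)
  }
  a <- pmin(df$from, df$to); b <- pmax(df$from, df$to)
  out <- data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
  for (nm in setdiff(names(df), c("from", "to"))) out[[nm]] <- df[[nm]]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
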