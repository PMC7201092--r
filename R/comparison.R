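#' Recurrently alternatively-polyadenylated genes
#'
#' Genes whose APA call of the requested kind occurs in strictly more than
#' a fraction of the samples (the recurrence convention for 3'US calls).
#'
#' @param calls data frame with columns \code{gene}, \code{sample},
#'   \code{kind} (one row per per-sample call).
#' @param kind \code{"3US"} or \code{"3UL"}.
#' @param fraction strict recurrence threshold in \code{[0, 1)}.
#' @param samples character vector of all samples considered (the
#'   denominator); defaults to the samples appearing in \code{calls}.
#' @return sorted character vector of recurrent genes.
#' @export
recurrent_apa <- function(calls, kind = c("3US", "3UL"), fraction = 0.2,
                          samples = NULL) {
  kind <- match.arg(kind)
  if (fraction < 0 || fraction >= 1) stopf_("fraction must lie in [0, 1)")
  if (is.null(samples)) samples <- unique(calls$sample)
  if (length(samples) < 1) stopf_("need at least one sample")
  sub <- calls[calls$kind == kind & calls$sample %in% samples, , drop = FALSE]
  if (!nrow(sub)) return(character(0))
  freq <- tapply(sub$sample, sub$gene, function(s) length(unique(s)))
  sort(names(freq)[freq / length(samples) > fraction])
}

#' ceRNA partners of a gene set
#'
#' Union of the network neighbors of the seed genes, minus the seed genes
#' themselves. Seeds absent from the network contribute nothing.
#'
#' @param network an igraph network.
#' @param seed_genes character vector of seed gene ids.
#' @return sorted character vector of partner genes.
#' @export
cerna_partners <- function(network, seed_genes) {
  present <- intersect(seed_genes, igraph::V(network)$name)
  if (!length(present)) return(character(0))
  nb <- unique(unlist(lapply(
    igraph::adjacent_vertices(network, present), names)))
  sort(setdiff(nb, seed_genes))
}

#' Subnetwork of edges involving a gene set
#'
#' Keeps every edge with at least one endpoint in \code{genes} (the
#' incidence reading of "edges involving" a sponge gene set), dropping
#' vertices left without edges.
#'
#' @param network an igraph network.
#' @param genes character vector of focal genes.
#' @return an igraph subnetwork.
#' @export
edge_subnetwork <- function(network, genes) {
  el <- igraph::as_data_frame(network, what = "edges")
  sel <- el$from %in% genes | el$to %in% genes
  igraph::subgraph_from_edges(network, igraph::E(network)[sel],
                              delete.vertices = TRUE)
}

#' Focal-subnetwork similarity against matched random subnetworks
#'
#' Tests whether the subnetworks of edges involving a focal gene set
#' (e.g., sponge housekeeping genes) are more similar between two
#' conditions than expected: the focal edge-subnetworks of the two
#' networks are compared spectrally, and for each of \code{reps}
#' replicates the same numbers of edges are drawn (without replacement)
#' from each network's edges not touching any focal gene and compared the
#' same way. The empirical p-value uses the add-one permutation estimator
#' so it is never zero.
#'
#' @param net_a,net_b igraph networks (the two conditions).
#' @param focal_genes non-empty character vector of focal genes.
#' @param reps number of matched random subnetwork pairs.
#' @param seed RNG seed for the subsampling.
#' @return a list of class \code{subnetwork_comparison}: \code{focal_p},
#'   \code{null_ps}, \code{empirical_p}, \code{n_focal_edges}.
#' @export
matched_null_similarity <- function(net_a, net_b, focal_genes, reps = 200L,
                                    seed = 1L) {
  if (!length(focal_genes)) stopf_("focal_genes must be non-empty")
  fa <- edge_subnetwork(net_a, focal_genes)
  fb <- edge_subnetwork(net_b, focal_genes)
  if (igraph::ecount(fa) == 0 || igraph::ecount(fb) == 0)
    stopf_("a focal subnetwork has no edges")
  focal_p <- ks_similarity(fa, fb)$p_value
  pool <- function(net) {
    el <- igraph::as_data_frame(net, what = "edges")
    which(!(el$from %in% focal_genes | el$to %in% focal_genes))
  }
  pa <- pool(net_a); pb <- pool(net_b)
  na <- igraph::ecount(fa); nb <- igraph::ecount(fb)
  if (length(pa) < na || length(pb) < nb)
    stopf_("not enough non-focal edges to match the focal edge counts")
  null_ps <- with_seed_(seed, {
    vapply(seq_len(reps), function(i) {
      ga <- igraph::subgraph_from_edges(net_a,
              igraph::E(net_a)[sample(pa, na)], delete.vertices = TRUE)
      gb <- igraph::subgraph_from_edges(net_b,
              igraph::E(net_b)[sample(pb, nb)], delete.vertices = TRUE)
      ks_similarity(ga, gb)$p_value
    }, numeric(1))
  })
  structure(list(focal_p = focal_p, null_ps = null_ps,
                 empirical_p = (1 + sum(null_ps >= focal_p)) / (reps + 1),
                 n_focal_edges = c(a = na, b = nb)),
            class = "subnetwork_comparison")
}

#' @export
print.subnetwork_comparison <- function(x, ...) {
  cat(sprintf(
    "focal subnetworks: KS p = %.4g; empirical p vs %d matched nulls = %.4g\n",
    x$focal_p, length(x$null_ps), x$empirical_p))
  invisible(x)
}

#' Fraction of normal-network neighbors retained in the tumor network
#'
#' @param normal_net,tumor_net igraph networks for the two conditions.
#' @param gene gene with at least one neighbor in the normal network.
#' @return ratio in \code{[0, 1]}; tumor-only neighbor gains are ignored.
#' @export
degree_ratio <- function(normal_net, tumor_net, gene) {
  if (!gene %in% igraph::V(normal_net)$name)
    stopf_("gene %s absent from the normal network", gene)
  nn <- names(igraph::neighbors(normal_net, gene))
  if (!length(nn)) stopf_("gene %s has no neighbors in the normal network", gene)
  if (!gene %in% igraph::V(tumor_net)$name) return(0)
  nt <- names(igraph::neighbors(tumor_net, gene))
  length(intersect(nn, nt)) / length(nn)
}

#' Log2 fold change of mean expression (tumor vs. normal)
#'
#' @param tumor_vals,normal_vals non-negative expression values.
#' @param pseudocount added to both means before the ratio.
#' @return \code{log2((mean(tumor) + pc) / (mean(normal) + pc))}.
#' @export
log2_fold_change <- function(tumor_vals, normal_vals, pseudocount = 1) {
  if (!length(tumor_vals) || !length(normal_vals))
    stopf_("both vectors must be non-empty")
  if (any(tumor_vals < 0) || any(normal_vals < 0))
    stopf_("expression values must be non-negative")
  log2((mean(tumor_vals) + pseudocount) / (mean(normal_vals) + pseudocount))
}

#' Two-sided rank-sum test between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) p-value; the
#' distribution-free default for comparing skewed expression summaries.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return p-value in \code{[0, 1]}.
#' @export
group_difference_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stopf_("need at least 2 values per group")
  if (length(unique(c(a, b))) == 1L)
    stopf_("all values tied; rank-sum test is degenerate")
  suppressWarnings(wilcox.test(a, b, alternative = "two.sided")$p.value)
}

#' Significance of overlap between two gene sets
#'
#' Upper-tail hypergeometric probability of drawing at least the observed
#' overlap, with the supplied gene universe as the population.
#'
#' @param set_a,set_b gene sets (subsets of \code{universe}).
#' @param universe the gene universe.
#' @return p-value.
#' @export
set_overlap_significance <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stopf_("sets must be contained in the universe")
  ov <- length(intersect(set_a, set_b))
  hyper_tail_(ov, length(set_a), length(set_b), length(universe))
}

#' Gene-set over-representation test
#'
#' Hypergeometric over-representation of a query gene set in each set of
#' a collection, BH-adjusted across the collection.
#'
#' @param genes query gene set.
#' @param collection named list of gene sets (e.g., from a GMT file).
#' @param universe the gene universe; sets and query are intersected with it.
#' @return data frame (set, n_set, n_overlap, p, q) sorted by ascending p.
#' @export
overrepresentation <- function(genes, collection, universe) {
  if (!length(universe)) stopf_("universe must be non-empty")
  if (!length(collection)) stopf_("collection must be non-empty")
  universe <- unique(universe)
  genes <- intersect(unique(genes), universe)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(collection[[nm]]), universe)
    ov <- length(intersect(genes, s))
    data.frame(set = nm, n_set = length(s), n_overlap = ov,
               p = hyper_tail_(ov, length(s), length(genes), length(universe)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify network genes by their relationship to 3'US genes
#'
#' In backbone-only ceRNA mode (target-site overlap significance alone,
#' no co-expression filter) each network gene is labelled a 3'US gene, a
#' 3'US ceRNA partner (neighbor of a 3'US gene), or unconnected to 3'US;
#' the labels are cross-tabulated with the gene-class annotation.
#'
#' @param backbone the backbone network.
#' @param apa_genes character vector of 3'US genes.
#' @param annotation data frame with columns \code{gene} and \code{class}
#'   (\code{HK}, \code{TA}, \code{TF} or \code{none}).
#' @return a list with \code{table} (gene, role, class) and
#'   \code{counts} (role x class cross-tabulation).
#' @export
classify_network_genes <- function(backbone, apa_genes, annotation) {
  genes <- igraph::V(backbone)$name
  partners <- cerna_partners(backbone, apa_genes)
  role <- ifelse(genes %in% apa_genes, "3US",
                 ifelse(genes %in% partners, "partner", "unconnected"))
  cls <- annotation$class[match(genes, annotation$gene)]
  cls[is.na(cls)] <- "none"
  tab <- data.frame(gene = genes, role = role, class = cls,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       counts = table(role = factor(tab$role,
                                    c("3US", "partner", "unconnected")),
                      class = factor(tab$class, c("HK", "TA", "TF", "none"))))
}

#' Edge-count behaviour under expression subsampling
#'
#' Builds the ceRNA network repeatedly from random sample subsets of
#' several sizes at a fixed correlation cutoff, recording the edge count
#' of every replicate and, per edge, how often it occurs across the
#' replicates of each size. Demonstrates the small-sample inflation of
#' correlation-thresholded networks.
#'
#' @param matrix expression matrix covering the backbone genes.
#' @param backbone the backbone network.
#' @param sizes integer vector of subsample sizes (each >= 3, at most the
#'   sample count).
#' @param reps replicates per size.
#' @param cutoff fixed correlation cutoff.
#' @param seed RNG seed.
#' @param log_transform passed to \code{\link{build_cerna_network}}.
#' @return list with \code{edge_counts} (size, rep, n_edges) and
#'   \code{occurrence} (per size, a named count vector over edges
#'   "geneA|geneB").
#' @export
subsample_experiment <- function(matrix, backbone, sizes, reps = 100L,
                                 cutoff, seed = 1L, log_transform = TRUE) {
  if (any(sizes < 3)) stopf_("subsample sizes must be >= 3")
  if (max(sizes) > ncol(matrix))
    stopf_("a subsample size exceeds the sample count")
  with_seed_(seed, {
    counts <- list(); occ <- list()
    for (s in sizes) {
      occ_s <- new.env(parent = emptyenv())
      n_edges <- integer(reps)
      for (r in seq_len(reps)) {
        cols <- sample(ncol(matrix), s)
        g <- build_cerna_network(matrix[, cols, drop = FALSE], backbone,
                                 cutoff, log_transform = log_transform)
        ed <- network_edges(g)
        n_edges[r] <- nrow(ed)
        if (nrow(ed)) {
          keys <- paste(ed$gene_a, ed$gene_b, sep = "|")
          for (k in keys)
            assign(k, (if (exists(k, occ_s)) get(k, occ_s) else 0L) + 1L, occ_s)
        }
      }
      counts[[as.character(s)]] <- data.frame(size = s, rep = seq_len(reps),
                                              n_edges = n_edges)
      keys <- sort(ls(occ_s))
      occ[[as.character(s)]] <- vapply(keys, get, integer(1), envir = occ_s)
    }
    list(edge_counts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
         occurrence = occ)
  })
}

#' Per-gene expression variability of two gene groups
#'
#' Per-gene standard deviation across the samples of the matrix for each
#' group, compared with the two-sided rank-sum test (the
#' housekeeping-vs-rest variance comparison).
#'
#' @param matrix expression matrix.
#' @param group_a,group_b non-empty gene sets present in the matrix.
#' @return list with \code{sd_a}, \code{sd_b} (named vectors) and \code{p}.
#' @export
expression_variability <- function(matrix, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stopf_("groups must be non-empty")
  missing <- setdiff(c(group_a, group_b), rownames(matrix))
  if (length(missing))
    stopf_("genes absent from the matrix: %s",
           paste(utils::head(missing, 3), collapse = ", "))
  sd_a <- apply(matrix[group_a, , drop = FALSE], 1, sd)
  sd_b <- apply(matrix[group_b, , drop = FALSE], 1, sd)
  list(sd_a = sd_a, sd_b = sd_b, p = group_difference_test(sd_a, sd_b))
}
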