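#' Normalized Laplacian of a network
#'
#' The normalized Laplacian \code{N = D^{-1/2} L D^{-1/2}} with
#' \code{L = D - A}: entries are 1 on the diagonal for vertices of
#' positive degree, \code{-1 / sqrt(deg_i * deg_j)} for adjacent pairs,
#' and 0 otherwise. Isolated (degree-0) vertices are dropped first: their
#' all-zero rows would pad the spectrum with zeros that depend only on
#' node-universe bookkeeping, not topology. Rows follow lexicographic
#' vertex order.
#'
#' @param network an igraph network with at least one edge.
#' @return a symmetric numeric matrix with vertex names as dimnames.
#' @export
normalized_laplacian <- function(network) {
  if (igraph::ecount(network) == 0) stopf_("network has no edges")
  g <- igraph::delete_vertices(network, igraph::degree(network) == 0)
  ord <- order(igraph::V(g)$name)
  g <- igraph::permute(g, order(ord))
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  a[a > 1] <- 1
  deg <- rowSums(a)
  dis <- 1 / sqrt(deg)
  n <- -a * outer(dis, dis)
  diag(n) <- 1
  dimnames(n) <- list(igraph::V(g)$name, igraph::V(g)$name)
  n
}

#' Eigenvalue distribution of a symmetric matrix
#'
#' All eigenvalues, ascending. Values straying outside \code{[0, 2]} by no
#' more than the tolerance (numerical jitter of the symmetric solver) are
#' clipped to the boundary.
#'
#' @param matrix symmetric numeric matrix.
#' @param tol symmetry / clipping tolerance.
#' @return sorted numeric vector of eigenvalues.
#' @export
eigenvalue_distribution <- function(matrix, tol = 1e-8) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stopf_("input must be a square matrix")
  if (max(abs(matrix - t(matrix))) > tol)
    stopf_("input matrix is not symmetric within tolerance")
  ev <- sort(eigen(matrix, symmetric = TRUE, only.values = TRUE)$values)
  ev[ev < 0 & ev > -tol] <- 0
  ev[ev > 2 & ev < 2 + tol] <- 2
  ev
}

#' Spectral similarity of two networks (Kolmogorov-Smirnov on spectra)
#'
#' Compares the eigenvalue distributions of the two networks' normalized
#' Laplacians with a two-sample, two-sided KS test (asymptotic p-value).
#' The statistic is the sup-distance between the two empirical CDFs; a
#' high p-value means the two topologies are indistinguishable at the
#' spectral level.
#'
#' @param net_a,net_b igraph networks, each with at least one edge.
#' @return a list of class \code{spectral_similarity} with
#'   \code{ks_statistic}, \code{p_value}, \code{eigenvalues_a},
#'   \code{eigenvalues_b}.
#' @export
ks_similarity <- function(net_a, net_b) {
  ea <- eigenvalue_distribution(normalized_laplacian(net_a))
  eb <- eigenvalue_distribution(normalized_laplacian(net_b))
  ks_similarity_values_(ea, eb)
}

ks_similarity_values_ <- function(ea, eb) {
  kt <- suppressWarnings(ks.test(ea, eb, exact = FALSE))
  structure(list(ks_statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 eigenvalues_a = ea, eigenvalues_b = eb),
            class = "spectral_similarity")
}

#' @export
print.spectral_similarity <- function(x, ...) {
  cat(sprintf("spectral similarity: KS = %.4f, p = %.4g (|E_a| = %d, |E_b| = %d)\n",
              x$ks_statistic, x$p_value,
              length(x$eigenvalues_a), length(x$eigenvalues_b)))
  invisible(x)
}

#' Average clustering coefficient
#'
#' Mean over all vertices of the local clustering coefficient (triangles
#' through a vertex over possible triangles); vertices of degree below 2
#' contribute 0.
#'
#' @param network an igraph network with at least one vertex.
#' @return a value in \code{[0, 1]}.
#' @export
average_clustering <- function(network) {
  if (igraph::vcount(network) == 0) stopf_("network has no vertices")
  cc <- igraph::transitivity(network, type = "local", isolates = "zero")
  mean(cc)
}

#' Calibrate the correlation cutoff of one group against a reference network
#'
#' Networks built from fewer samples are inflated at any fixed correlation
#' cutoff. This scans cutoffs over \code{[0, 1]}, builds the target
#' group's network on the shared backbone at each cutoff, and selects the
#' cutoff whose network is spectrally most similar (maximal KS p-value) to
#' the reference network. Ties are broken by the average clustering
#' coefficient closest to the reference's, then by the smaller cutoff.
#'
#' @param reference the reference ceRNA network (from the larger group).
#' @param target_expr expression matrix of the group being calibrated;
#'   must cover the backbone genes.
#' @param backbone the shared target-share backbone.
#' @param step cutoff grid step.
#' @param log_transform passed to \code{\link{build_cerna_network}}; use
#'   the same setting as for the reference.
#' @param min_nodes smallest target network eligible for selection. The
#'   asymptotic two-sample KS p-value is vacuously high when one spectrum
#'   has only a handful of eigenvalues, so near-empty networks at extreme
#'   cutoffs would otherwise win the scan; such grid entries are still
#'   reported but not selectable.
#' @return a list of class \code{calibration_result}: \code{grid} (data
#'   frame with cutoff, ks_statistic, p_value, n_edges, n_nodes,
#'   avg_clustering, eligible), \code{selected_cutoff},
#'   \code{reference_clustering}.
#' @export
calibrate_cutoff <- function(reference, target_expr, backbone, step = 0.01,
                             log_transform = TRUE, min_nodes = 10L) {
  ref_ev <- eigenvalue_distribution(normalized_laplacian(reference))
  ref_cc <- average_clustering(reference)
  grid <- seq(0, 1, by = step)
  res <- data.frame(cutoff = grid, ks_statistic = NA_real_,
                    p_value = NA_real_, n_edges = NA_integer_,
                    n_nodes = NA_integer_, avg_clustering = NA_real_)
  # edge correlations are cutoff-independent: compute once at cutoff 0,
  # then threshold the stored r per grid point
  g0 <- build_cerna_network(target_expr, backbone, 0,
                            log_transform = log_transform)
  r0 <- igraph::E(g0)$r
  for (i in seq_along(grid)) {
    g <- igraph::subgraph_from_edges(g0, igraph::E(g0)[r0 >= grid[i]],
                                     delete.vertices = TRUE)
    res$n_edges[i] <- igraph::ecount(g)
    res$n_nodes[i] <- igraph::vcount(g)
    if (igraph::ecount(g) == 0) next
    sim <- ks_similarity_values_(ref_ev,
                                 eigenvalue_distribution(normalized_laplacian(g)))
    res$ks_statistic[i] <- sim$ks_statistic
    res$p_value[i] <- sim$p_value
    res$avg_clustering[i] <- average_clustering(g)
  }
  res$eligible <- !is.na(res$p_value) & res$n_nodes >= min_nodes
  if (!any(res$eligible)) {
    if (all(is.na(res$p_value))) stopf_("all grid networks are empty")
    res$eligible <- !is.na(res$p_value)
  }
  best_p <- max(res$p_value[res$eligible])
  cand <- which(res$eligible & res$p_value == best_p)
  if (length(cand) > 1) {
    dcc <- abs(res$avg_clustering[cand] - ref_cc)
    cand <- cand[dcc == min(dcc)]
  }
  selected <- grid[min(cand)]
  structure(list(grid = res, selected_cutoff = selected,
                 reference_clustering = ref_cc), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  i <- match(x$selected_cutoff, x$grid$cutoff)
  cat(sprintf("calibration: selected cutoff %.2f (KS p = %.4g, %d edges)\n",
              x$selected_cutoff, x$grid$p_value[i], x$grid$n_edges[i]))
  invisible(x)
}
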