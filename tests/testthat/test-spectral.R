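test_that("normalized Laplacians of canonical graphs have their known spectra", {
  # single edge: [[1, -1], [-1, 1]], eigenvalues {0, 2}
  k2 <- graph_from_pairs("a", "b")
  n2 <- normalized_laplacian(k2)
  expect_equal(unname(n2), matrix(c(1, -1, -1, 1), 2))
  expect_equal(eigenvalue_distribution(n2), c(0, 2))
  # path on three vertices: off-diagonals -1/sqrt(2), spectrum {0, 1, 2}
  p3 <- graph_from_pairs("a", "b", "b", "c")
  n3 <- normalized_laplacian(p3)
  expect_equal(n3["a", "b"], -1 / sqrt(2))
  expect_equal(eigenvalue_distribution(n3), c(0, 1, 2))
  # complete graph K5: {0} plus n/(n-1) with multiplicity n-1
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(eigenvalue_distribution(normalized_laplacian(k5)),
               c(0, rep(5 / 4, 4)))
})

test_that("the matrix agrees with igraph's normalized Laplacian", {
  set.seed(5)
  g <- igraph::sample_gnp(15, 0.3)
  igraph::V(g)$name <- sprintf("v%02d", 1:15)
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  ours <- normalized_laplacian(g)
  ref <- as.matrix(igraph::laplacian_matrix(g, normalization = "symmetric"))
  ref <- ref[rownames(ours), colnames(ours)]
  expect_equal(ours, ref, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("spectra lie in [0, 2] with trace and component-count identities", {
  set.seed(7)
  for (i in 1:5) {
    g <- igraph::sample_gnp(30, 0.08)
    igraph::V(g)$name <- sprintf("v%02d", 1:30)
    if (igraph::ecount(g) == 0) next
    nl <- normalized_laplacian(g)
    ev <- eigenvalue_distribution(nl)
    expect_true(all(ev >= 0 & ev <= 2))
    expect_equal(sum(ev), nrow(nl))  # trace = number of non-isolated nodes
    g2 <- igraph::delete_vertices(g, igraph::degree(g) == 0)
    expect_equal(sum(ev < 1e-8), igraph::count_components(g2))
  }
})

test_that("eigenvalue_distribution validates and clips its input", {
  expect_equal(eigenvalue_distribution(diag(4)), rep(1, 4))
  asym <- matrix(c(1, 2, 3, 1), 2)
  expect_error(eigenvalue_distribution(asym), "symmetric")
  near <- matrix(c(0, -1e-12, -1e-12, 0), 2)
  expect_true(all(eigenvalue_distribution(near + diag(2)) >= 0))
})

test_that("spectral similarity is reflexive, maximal on disjoint supports, and exact", {
  g <- graph_from_pairs("a", "b", "b", "c", "c", "a", "c", "d")
  self <- ks_similarity(g, g)
  expect_equal(self$ks_statistic, 0)
  expect_equal(self$p_value, 1)
  # complete graphs of different orders: eigenvalue supports {0, 4/3} vs
  # {0, 10/9 x 9}; statistic driven to its sup by the mass split
  k4 <- igraph::make_full_graph(4); igraph::V(k4)$name <- letters[1:4]
  star <- igraph::make_star(8, mode = "undirected")
  igraph::V(star)$name <- letters[1:8]
  # star spectrum: {0, 1 x (n-2), 2}; triangle: {0, 1.5, 1.5}
  tri <- graph_from_pairs("a", "b", "b", "c", "c", "a")
  sim <- ks_similarity(tri, star)
  ea <- eigenvalue_distribution(normalized_laplacian(tri))
  eb <- eigenvalue_distribution(normalized_laplacian(star))
  expect_equal(sim$ks_statistic, brute_ks_stat(ea, eb))
  # two random graphs: statistic equals brute-force sup over breakpoints
  set.seed(11)
  g1 <- igraph::sample_gnp(12, 0.35); igraph::V(g1)$name <- letters[1:12]
  g2 <- igraph::sample_gnp(12, 0.6); igraph::V(g2)$name <- letters[1:12]
  s <- ks_similarity(g1, g2)
  expect_equal(s$ks_statistic,
               brute_ks_stat(eigenvalue_distribution(normalized_laplacian(g1)),
                             eigenvalue_distribution(normalized_laplacian(g2))))
})

test_that("similarity is symmetric and invariant to vertex relabelling", {
  set.seed(13)
  g1 <- igraph::sample_gnp(14, 0.3); igraph::V(g1)$name <- letters[1:14]
  g2 <- igraph::sample_gnp(14, 0.3); igraph::V(g2)$name <- letters[1:14]
  ab <- ks_similarity(g1, g2); ba <- ks_similarity(g2, g1)
  expect_equal(ab$ks_statistic, ba$ks_statistic)
  expect_equal(ab$p_value, ba$p_value)
  # relabel g1's vertices: spectrum and similarity unchanged
  perm <- sample(14)
  g1p <- igraph::permute(g1, perm)
  igraph::V(g1p)$name <- sprintf("x%02d", 1:14)
  expect_equal(ks_similarity(g1p, g2)$ks_statistic, ab$ks_statistic)
})

test_that("average clustering matches hand counts", {
  tri <- graph_from_pairs("a", "b", "b", "c", "c", "a")
  expect_equal(average_clustering(tri), 1)
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- letters[1:5]
  expect_equal(average_clustering(star), 0)
  # 4-cycle plus one chord: local ccs 2/3, 1, 2/3, 1
  chord <- graph_from_pairs("a", "b", "b", "c", "c", "d", "d", "a", "a", "c")
  expect_equal(average_clustering(chord), (2 / 3 + 1 + 2 / 3 + 1) / 4)
})

test_that("self-calibration recovers the reference cutoff", {
  ds <- generate_dataset(tiny_config(seed = 31L))
  bb <- build_backbone(ds$targets)
  ref <- build_cerna_network(ds$expression$A_normal, bb, 0.6)
  cal <- calibrate_cutoff(ref, ds$expression$A_normal, bb, step = 0.01)
  expect_lte(abs(cal$selected_cutoff - 0.6), 0.01)
  expect_true(cal$selected_cutoff %in% cal$grid$cutoff)
})

test_that("a coarse grid is evaluated in full and returns one optimum", {
  ds <- generate_dataset(tiny_config(seed = 32L))
  bb <- build_backbone(ds$targets)
  ref <- build_cerna_network(ds$expression$A_normal, bb, 0.6)
  cal <- suppressWarnings(
    calibrate_cutoff(ref, ds$expression$B_normal, bb, step = 0.5))
  expect_equal(cal$grid$cutoff, c(0, 0.5, 1))
  expect_length(cal$selected_cutoff, 1)
  expect_true(cal$selected_cutoff %in% c(0, 0.5, 1))
})

test_that("calibrating the smaller group against the larger selects a higher cutoff", {
  hits <- 0L
  for (s in 1:5) {
    ds <- generate_dataset(generator_config(seed = 300L + s))
    bb <- build_backbone(ds$targets)
    ref <- suppressWarnings(build_cerna_network(ds$expression$A_normal, bb, 0.6))
    cal <- suppressWarnings(calibrate_cutoff(ref, ds$expression$B_normal, bb))
    if (cal$selected_cutoff > 0.6) hits <- hits + 1L
    # the calibrated network is at least as similar as the shared-cutoff one
    i_cal <- match(cal$selected_cutoff, cal$grid$cutoff)
    i_ref <- match(0.6, cal$grid$cutoff)
    expect_gte(cal$grid$p_value[i_cal], cal$grid$p_value[i_ref])
  }
  expect_gte(hits, 4L)
})
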