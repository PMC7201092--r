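make_calls <- function(gene, samples) {
  data.frame(gene = gene, sample = samples, kind = "3US",
             stringsAsFactors = FALSE)
}

test_that("APA recurrence applies a strict fraction over the sample universe", {
  smp <- sprintf("s%02d", 1:10)
  calls <- rbind(make_calls("gIn", smp[1:3]), make_calls("gEdge", smp[1:2]))
  expect_identical(recurrent_apa(calls, "3US", 0.2, samples = smp), "gIn")
  none <- calls[0, ]
  expect_identical(recurrent_apa(none, "3US", 0.2, samples = smp), character(0))
  calls$kind <- "3UL"
  expect_identical(recurrent_apa(calls, "3US", 0.2, samples = smp), character(0))
  expect_error(recurrent_apa(calls, "3US", 1), "fraction")
})

test_that("ceRNA partners are the neighbor union minus the seeds", {
  star <- graph_from_pairs("hub", "l1", "hub", "l2", "hub", "l3")
  expect_setequal(cerna_partners(star, "hub"), c("l1", "l2", "l3"))
  expect_identical(cerna_partners(star, "absent"), character(0))
  path <- graph_from_pairs("a", "b", "b", "c", "c", "d")
  # two seeds sharing neighbor c: counted once, seeds excluded
  expect_identical(cerna_partners(path, c("b", "d")), c("a", "c"))
})

test_that("edge subnetworks keep edges incident to the focal set", {
  path <- graph_from_pairs("a", "b", "b", "c")
  sub <- edge_subnetwork(path, "b")
  expect_equal(igraph::ecount(sub), 2)
  whole <- edge_subnetwork(path, c("a", "b", "c"))
  expect_equal(igraph::ecount(whole), igraph::ecount(path))
  empty <- edge_subnetwork(path, character(0))
  expect_equal(igraph::ecount(empty), 0)
})

test_that("degree ratio counts retained normal neighbors only", {
  normal <- graph_from_pairs("g", "a", "g", "b", "g", "c", "g", "d", "a", "b")
  tumor_same <- normal
  expect_equal(degree_ratio(normal, tumor_same, "g"), 1)
  tumor_gone <- graph_from_pairs("a", "b")
  expect_equal(degree_ratio(normal, tumor_gone, "g"), 0)
  # 4 normal neighbors, 2 retained, plus new tumor-only neighbors ignored
  tumor_mix <- graph_from_pairs("g", "a", "g", "b", "g", "x", "g", "y", "g", "z")
  expect_equal(degree_ratio(normal, tumor_mix, "g"), 0.5)
  expect_error(degree_ratio(normal, tumor_same, "nope"), "absent")
})

test_that("log2 fold change uses pseudocounted means", {
  expect_equal(log2_fold_change(c(1, 1), c(1, 1)), 0)
  expect_equal(log2_fold_change(3, 1), 1)          # log2(4 / 2)
  expect_equal(log2_fold_change(3, 1, pseudocount = 0), log2(3))
  expect_error(log2_fold_change(-1, 2), "non-negative")
  expect_error(log2_fold_change(numeric(0), 1), "non-empty")
})

test_that("rank-sum test matches exact enumeration and detects planted shifts", {
  expect_gt(group_difference_test(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0.95)
  # complete separation at n = 20 per group: p = 2 / choose(40, 20)
  expect_equal(group_difference_test(1:20, 21:40), 2 / choose(40, 20))
  expect_error(group_difference_test(rep(1, 5), rep(1, 5)), "tied")
  set.seed(77)
  hits <- mean(replicate(40, {
    group_difference_test(rnorm(200), rnorm(200, mean = 1)) < 0.01
  }))
  expect_gte(hits, 0.95)
})

test_that("set overlap significance shares the hypergeometric kernel", {
  u <- letters[1:12]
  a <- u[1:6]; b <- u[1:6]
  expect_equal(set_overlap_significance(a, b, u), pmf_sum_tail(6, 6, 6, 12))
  expect_equal(set_overlap_significance(a, b, u),
               set_overlap_significance(b, a, u))
  expect_gt(set_overlap_significance(u[1:2], u[3:4], u), 0.5)
  expect_error(set_overlap_significance(c("zz"), a, u), "universe")
})

test_that("over-representation ranks a fully recovered set first", {
  u <- sprintf("g%02d", 1:40)
  coll <- list(hit = u[1:8], half = u[5:14], off = u[30:39])
  res <- overrepresentation(u[1:8], coll, u)
  expect_equal(res$set[1], "hit")
  expect_true(all(diff(res$p) >= 0))
  expect_true(all(res$q >= res$p - 1e-15))
  res0 <- overrepresentation(character(0), coll, u)
  expect_true(all(res0$p == 1))
  expect_error(overrepresentation(u[1:3], list(), u), "collection")
})

test_that("over-representation p-values are uniform under the null", {
  set.seed(19)
  u <- sprintf("g%03d", 1:200)
  ps <- replicate(400, {
    genes <- sample(u, 20)
    s <- sample(u, 25)
    overrepresentation(genes, list(s = s), u)$p
  })
  # hypergeometric p-values are discrete, hence super-uniform: the
  # rejection rate never exceeds the nominal level (within MC error),
  # and the mean stays near 1/2
  for (a in c(0.05, 0.2, 0.5))
    expect_lte(mean(ps <= a), a + 2 * sqrt(a * (1 - a) / length(ps)))
  expect_gt(mean(ps), 0.45)
})

test_that("network genes are classified by their 3'US relationship", {
  star <- graph_from_pairs("us1", "p1", "us1", "p2", "p2", "p3")
  ann <- data.frame(gene = c("us1", "p1", "p2", "p3"),
                    class = c("none", "HK", "TA", "none"))
  cls <- classify_network_genes(star, "us1", ann)
  roles <- setNames(cls$table$role, cls$table$gene)
  expect_equal(roles[["us1"]], "3US")
  expect_equal(roles[["p1"]], "partner")
  expect_equal(roles[["p2"]], "partner")
  expect_equal(roles[["p3"]], "unconnected")
  none <- classify_network_genes(star, character(0), ann)
  expect_true(all(none$table$role == "unconnected"))
})

test_that("classification agrees with set operations on the edge table", {
  ds <- generate_dataset(tiny_config(seed = 41L))
  bb <- build_backbone(ds$targets)
  us_in <- intersect(ds$us_genes, igraph::V(bb)$name)
  cls <- classify_network_genes(bb, ds$us_genes, ds$annotations)
  ed <- network_edges(bb)
  touching <- unique(c(ed$gene_b[ed$gene_a %in% us_in],
                       ed$gene_a[ed$gene_b %in% us_in]))
  expected_partners <- sort(setdiff(touching, ds$us_genes))
  expect_identical(sort(cls$table$gene[cls$table$role == "partner"]),
                   expected_partners)
  expect_identical(sort(cls$table$gene[cls$table$role == "3US"]), sort(us_in))
})

test_that("matched-null comparison is seeded, bounded and error-checked", {
  ds <- generate_dataset(tiny_config(seed = 42L))
  bb <- build_backbone(ds$targets)
  netA <- build_cerna_network(ds$expression$A_normal, bb, 0.5)
  netB <- build_cerna_network(ds$expression$B_normal, bb, 0.5)
  hk <- ds$annotations$gene[ds$annotations$class == "HK"]
  r1 <- matched_null_similarity(netA, netB, hk, reps = 25, seed = 7)
  r2 <- matched_null_similarity(netA, netB, hk, reps = 25, seed = 7)
  expect_identical(r1$null_ps, r2$null_ps)
  expect_gt(r1$empirical_p, 0)           # add-one rule: never zero
  expect_lte(r1$empirical_p, 1)
  expect_length(r1$null_ps, 25)
  expect_error(matched_null_similarity(netA, netB, character(0)), "non-empty")
})

test_that("expression variability flags the low-variance gene class", {
  m <- rbind(flat1 = rep(3, 8), flat2 = rep(5, 8),
             wig1 = c(1, 9, 2, 8, 1, 9, 2, 8), wig2 = c(0, 10, 0, 10, 0, 10, 0, 10))
  colnames(m) <- paste0("s", 1:8)
  v <- expression_variability(m, c("flat1", "flat2"), c("wig1", "wig2"))
  expect_equal(unname(v$sd_a), c(0, 0))
  expect_true(all(v$sd_b > 3))
  expect_error(expression_variability(m, "missing", "wig1"), "absent")
})

test_that("full-size subsamples reproduce the full network every time", {
  ds <- generate_dataset(tiny_config(seed = 43L))
  bb <- build_backbone(ds$targets)
  n <- ncol(ds$expression$B_normal)
  full <- igraph::ecount(build_cerna_network(ds$expression$B_normal, bb, 0.5))
  sub <- subsample_experiment(ds$expression$B_normal, bb, sizes = n,
                              reps = 4, cutoff = 0.5, seed = 9)
  expect_true(all(sub$edge_counts$n_edges == full))
  expect_true(all(sub$occurrence[[as.character(n)]] == 4))
  s2 <- subsample_experiment(ds$expression$B_normal, bb, sizes = n,
                             reps = 4, cutoff = 0.5, seed = 9)
  expect_identical(sub$edge_counts, s2$edge_counts)
  expect_error(subsample_experiment(ds$expression$B_normal, bb, sizes = 2,
                                    reps = 2, cutoff = 0.5, seed = 1), ">= 3")
  expect_error(subsample_experiment(ds$expression$B_normal, bb,
                                    sizes = n + 1, reps = 2, cutoff = 0.5,
                                    seed = 1), "exceeds")
})
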