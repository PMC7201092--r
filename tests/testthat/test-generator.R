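test_that("generation is deterministic under a fixed seed and varies across seeds", {
  d1 <- generate_dataset(tiny_config(seed = 42L))
  d2 <- generate_dataset(tiny_config(seed = 42L))
  d3 <- generate_dataset(tiny_config(seed = 43L))
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$targets$site_count, d2$targets$site_count)
  expect_identical(d1$apa_calls, d2$apa_calls)
  expect_false(identical(d1$expression$A_normal, d3$expression$A_normal))
})

test_that("generator leaves the caller's RNG stream untouched", {
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_dataset(tiny_config())); after <- runif(1)
  expect_identical(before, after)
})

test_that("config validation rejects out-of-domain parameters", {
  expect_error(generator_config(hk_fraction = 1.5), "hk_fraction")
  expect_error(generator_config(sponge_site_range = c(4L, 8L)), "sponge")
  expect_error(generator_config(hk_noise_sd = 10, noise_sd = 5), "hk_noise_sd")
  expect_error(generator_config(n_3us_genes = 1000, n_genes = 100), "n_3us")
})

test_that("genes with identical site rows correlate perfectly as noise vanishes", {
  # all genes in the coherent class over a small miRNA pool, so identical
  # site rows occur; near-zero noise leaves only the shared miRNA signal;
  # a gentle activity scale keeps expression off the zero floor
  ds <- generate_dataset(generator_config(
    n_genes = 150L, n_mirnas = 10L, n_modules = 2L, hk_fraction = 0,
    coherent_fraction = 1, samples_per_group = c(40L, 5L, 5L, 5L),
    n_3us_genes = 0L, n_3ul_genes = 0L, activity_scale = 0.1,
    noise_sd = 1e-6, hk_noise_sd = 1e-7, seed = 3L))
  m <- ds$targets$site_count
  # coherent genes of one module share the full common pool; find a pair
  # with identical rows
  key <- apply(m, 1, paste, collapse = ",")
  dup <- names(key)[duplicated(key) | duplicated(key, fromLast = TRUE)]
  dup <- dup[rowSums(m[dup, , drop = FALSE]) > 0]
  expect_gte(length(dup), 2)
  pair <- dup[key[dup] == key[dup][1]][1:2]
  r <- cor(ds$expression$A_normal[pair[1], ], ds$expression$A_normal[pair[2], ])
  expect_gt(r, 0.999)
})

test_that("planted partners are repressed in tumor relative to other genes", {
  ds <- generate_dataset(generator_config(seed = 5L))
  expect_gte(length(ds$partner_truth), 40)
  dmean <- rowMeans(ds$expression$B_tumor) - rowMeans(ds$expression$B_normal)
  other <- setdiff(rownames(ds$expression$B_tumor),
                   c(ds$partner_truth, ds$us_genes))
  expect_lt(mean(dmean[ds$partner_truth]), 0)
  expect_lt(mean(dmean[ds$partner_truth]), mean(dmean[other]))
})

test_that("structural invariants of the planted ground truth hold", {
  for (seed in c(2L, 9L)) {
    ds <- generate_dataset(tiny_config(seed = seed))
    m <- ds$targets$site_count
    # every planted pair shares at least one miRNA
    sh <- rowSums((m[ds$cerna_truth$gene_a, , drop = FALSE] > 0) &
                    (m[ds$cerna_truth$gene_b, , drop = FALSE] > 0))
    expect_true(all(sh >= 1))
    # 3'US genes lose sites in tumor; other genes keep theirs
    mt <- ds$targets_tumor$site_count
    expect_true(all(rowSums(mt[ds$us_genes, , drop = FALSE]) <
                      rowSums(m[ds$us_genes, , drop = FALSE])))
    keep <- setdiff(rownames(m), ds$us_genes)
    expect_identical(mt[keep, ], m[keep, ])
    # expression non-negative, HK genes qualify as sponges
    expect_true(all(vapply(ds$expression, function(x) all(x >= 0), logical(1))))
    hk <- ds$annotations$gene[ds$annotations$class == "HK"]
    expect_true(all(rowSums(m[hk, , drop = FALSE]) > 5))
  }
})

test_that("housekeeping genes vary less across normal samples than other genes", {
  ds <- generate_dataset(generator_config(n_genes = 500L, hk_fraction = 0.3,
                                          seed = 11L))
  hk <- ds$annotations$gene[ds$annotations$class == "HK"]
  other <- setdiff(rownames(ds$expression$A_normal), hk)
  v <- expression_variability(ds$expression$A_normal, hk, other)
  expect_lt(median(v$sd_a), median(v$sd_b))
  expect_lt(v$p, 0.01)
})

test_that("target-sharing pairs are more correlated than non-sharing pairs", {
  ds <- generate_dataset(tiny_config(seed = 4L))
  mat <- log2(ds$expression$A_normal + 1)
  ct <- ds$cerna_truth
  key <- paste(ct$gene_a, ct$gene_b)
  r_planted <- mapply(function(a, b) cor(mat[a, ], mat[b, ]),
                      ct$gene_a, ct$gene_b)
  genes <- rownames(mat)
  r_rand <- with_seed <- local({
    set.seed(8)
    replicate(500, {
      g <- sort(sample(genes, 2))
      if (paste(g[1], g[2]) %in% key) NA_real_ else cor(mat[g[1], ], mat[g[2], ])
    })
  })
  expect_gt(mean(r_planted), mean(r_rand, na.rm = TRUE) + 0.2)
})

test_that("datasets round-trip through the plain-text on-disk format", {
  ds <- generate_dataset(tiny_config(seed = 6L))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$expression, ds$expression)
  expect_identical(back$targets$site_count, ds$targets$site_count)
  expect_identical(back$targets_tumor$site_count, ds$targets_tumor$site_count)
  expect_identical(back$apa_calls, ds$apa_calls)
  expect_identical(back$us_genes, ds$us_genes)
  expect_identical(back$cerna_truth, ds$cerna_truth)
  expect_identical(back$partner_truth, ds$partner_truth)
  expect_equal(back$annotations, ds$annotations)
})

test_that("row counts of written files match gene counts; no-APA datasets write headers only", {
  ds <- generate_dataset(tiny_config(seed = 7L, n_3us_genes = 0L,
                                     n_3ul_genes = 0L))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expr <- read.table(file.path(dir, "expression_A_normal.tsv"), header = TRUE,
                     sep = "\t")
  expect_equal(nrow(expr), nrow(ds$expression$A_normal))
  apa <- readLines(file.path(dir, "apa_calls.tsv"))
  expect_equal(length(apa), 1L)  # header only
  back <- read_dataset(dir)
  expect_equal(nrow(back$apa_calls), 0L)
  expect_length(back$us_genes, 0L)
})
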