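#' Configuration for the synthetic ceRNA dataset generator
#'
#' The generator emulates the data structure the downstream analysis
#' assumes: two sample groups of unequal size, each with normal and tumor
#' conditions; gene expression driven by shared latent miRNA activities so
#' that genes sharing target sites are positively co-expressed;
#' housekeeping (HK) genes acting as stable miRNA sponges (many sites, low
#' expression variance); and planted 3'-UTR-shortening (3'US) genes whose
#' tumor-state site loss represses their ceRNA partners.
#'
#' @param n_genes number of genes.
#' @param n_mirnas number of miRNAs in the target universe.
#' @param samples_per_group integer vector of length 4: samples in group A
#'   normal, A tumor, B normal, B tumor. Defaults to 77/77/20/20, the
#'   asymmetry the calibration machinery exists to handle.
#' @param hk_fraction fraction of genes labelled housekeeping.
#' @param coherent_fraction fraction of non-HK genes in the coherent
#'   (low-noise, full module coverage) class whose mutual correlations
#'   stay above typical cutoffs at any sample size; the remaining non-HK
#'   genes carry most of the small-sample edge inflation.
#' @param sponge_site_range integer interval (min, max) for the total
#'   target-site count of HK genes; the minimum must be at least 6 so HK
#'   genes qualify as sponges (more than 5 sites).
#' @param n_3us_genes number of planted 3'US genes (drawn from non-HK genes).
#' @param n_3ul_genes number of decoy 3'UL genes (no expression effect;
#'   exercise the APA-kind filter only).
#' @param repression_effect mean expression shift (FPM units) subtracted
#'   from each ceRNA partner of a 3'US gene in tumor samples.
#' @param noise_sd Gaussian noise SD for non-HK genes (FPM units).
#' @param hk_noise_sd Gaussian noise SD for HK genes; must be smaller than
#'   \code{noise_sd} (HK genes are the low-variance class).
#' @param hk_signal_scale multiplier (< 1) on the miRNA-driven signal for
#'   HK genes: sponges buffer miRNA fluctuations, so their expression
#'   responds less to miRNA activity while remaining strongly correlated
#'   with one another.
#' @param activity_scale expression change per target site per unit of
#'   miRNA activity.
#' @param n_modules number of miRNA modules; the miRNA universe is
#'   partitioned into modules and each gene draws its sites from one
#'   module, producing block-correlated expression.
#' @param us_modules number of modules the planted 3'US genes are drawn
#'   from; confining them leaves the remaining modules' genes unconnected
#'   to any 3'US gene.
#' @param apa_call_rate per-tumor-sample probability that a planted 3'US
#'   gene is called 3'US in that sample.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline expression (FPM scale).
#' @param ta_fraction,tf_fraction fractions of non-HK genes labelled
#'   tumor-associated and transcription-factor, respectively.
#' @param seed integer RNG seed; identical configs with identical seeds
#'   produce bit-identical datasets.
#' @return a list of class \code{generator_config}.
#' @export
generator_config <- function(n_genes = 400L,
                             n_mirnas = 60L,
                             samples_per_group = c(77L, 77L, 20L, 20L),
                             hk_fraction = 0.2,
                             coherent_fraction = 0.3,
                             sponge_site_range = c(10L, 16L),
                             n_3us_genes = 20L,
                             n_3ul_genes = 10L,
                             repression_effect = 3,
                             noise_sd = 7,
                             hk_noise_sd = 0.5,
                             hk_signal_scale = 0.4,
                             activity_scale = 1,
                             n_modules = 10L,
                             us_modules = 3L,
                             apa_call_rate = 0.5,
                             baseline_meanlog = log(50),
                             baseline_sdlog = 0.3,
                             ta_fraction = 0.1,
                             tf_fraction = 0.1,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              samples_per_group = as.integer(samples_per_group),
              hk_fraction = hk_fraction,
              coherent_fraction = coherent_fraction,
              sponge_site_range = as.integer(sponge_site_range),
              n_3us_genes = as.integer(n_3us_genes),
              n_3ul_genes = as.integer(n_3ul_genes),
              repression_effect = repression_effect,
              noise_sd = noise_sd, hk_noise_sd = hk_noise_sd,
              hk_signal_scale = hk_signal_scale,
              activity_scale = activity_scale,
              n_modules = as.integer(n_modules),
              us_modules = as.integer(us_modules),
              apa_call_rate = apa_call_rate,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              ta_fraction = ta_fraction, tf_fraction = tf_fraction,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_genes < 1L || cfg$n_mirnas < 1L)
    stopf_("n_genes and n_mirnas must be positive")
  if (length(cfg$samples_per_group) != 4L || any(cfg$samples_per_group < 1L))
    stopf_("samples_per_group must be four positive integers")
  if (cfg$hk_fraction < 0 || cfg$hk_fraction > 1)
    stopf_("hk_fraction must lie in [0, 1]")
  if (cfg$sponge_site_range[1] < 6L)
    stopf_("sponge_site_range minimum must be >= 6 (sponge definition: >5 sites)")
  if (cfg$sponge_site_range[2] < cfg$sponge_site_range[1])
    stopf_("sponge_site_range must be a valid interval")
  if (cfg$n_3us_genes < 0L || cfg$n_3us_genes > cfg$n_genes)
    stopf_("n_3us_genes must lie in [0, n_genes]")
  if (cfg$repression_effect < 0) stopf_("repression_effect must be >= 0")
  if (cfg$noise_sd <= 0) stopf_("noise_sd must be positive")
  if (cfg$hk_noise_sd <= 0 || cfg$hk_noise_sd >= cfg$noise_sd)
    stopf_("hk_noise_sd must be positive and smaller than noise_sd")
  invisible(cfg)
}

#' Generate a synthetic ceRNA dataset with planted ground truth
#'
#' Generative model: each sample draws latent activities for every miRNA,
#' \code{a ~ N(1, 1)}; gene expression is
#' \code{baseline - scale * sum_m(sites[g, m] * a[m]) + noise}, floored at
#' zero. Genes drawing sites from the same miRNA module are thereby
#' positively correlated. In tumor samples the planted 3'US genes have
#' their site counts zeroed (complete 3'-UTR site loss, so they decouple
#' from the miRNA field) and each of their target-sharing partners
#' receives an additional \code{-repression_effect} mean shift.
#'
#' @param config a \code{\link{generator_config}}.
#' @return a list of class \code{cerna_dataset} with elements
#'   \code{expression} (named list of four genes x samples matrices:
#'   \code{A_normal}, \code{A_tumor}, \code{B_normal}, \code{B_tumor}),
#'   \code{targets} (a \code{\link{target_site_table}}, normal state),
#'   \code{targets_tumor} (effective tumor-state table),
#'   \code{annotations} (gene/class data frame), \code{apa_calls}
#'   (per-sample calls), \code{us_genes}, \code{ul_genes},
#'   \code{cerna_truth} (all target-sharing gene pairs),
#'   \code{partner_truth} (planted 3'US ceRNA partners), \code{modules}
#'   (gene module assignment) and \code{config}.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  with_seed_(config$seed, generate_dataset_(config))
}

generate_dataset_ <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  mirnas <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
  n_hk <- round(cfg$hk_fraction * cfg$n_genes)
  is_hk <- rep(FALSE, cfg$n_genes)
  if (n_hk > 0) is_hk[sample.int(cfg$n_genes, n_hk)] <- TRUE
  # a coherent class of non-HK genes (full common-pool coverage, low
  # noise) whose mutual correlations sit stably above the usual cutoff
  # scale; the remaining non-HK bulk stays below it
  is_coherent <- !is_hk & runif(cfg$n_genes) < cfg$coherent_fraction

  # miRNA modules: contiguous partition of the universe. Within each
  # module's pool the first two miRNAs form a sponge sub-pool targeted
  # heavily by the module's HK genes only (their near-identical profiles
  # make HK-HK correlations high and stable); the remainder is the common
  # sub-pool that non-HK genes draw from with per-gene site intensity
  # (wide correlation spread: most pairs below the usual cutoff scale,
  # a tail of strongly coupled pairs above it). HK genes add a light
  # footprint on the common sub-pool so they still share targets with
  # the module's other genes.
  module_of_mirna <- rep(seq_len(cfg$n_modules), length.out = cfg$n_mirnas)
  module_of_gene <- sample.int(cfg$n_modules, cfg$n_genes, replace = TRUE)
  n_sponge_mirnas <- 2L

  sites <- matrix(0L, cfg$n_genes, cfg$n_mirnas,
                  dimnames = list(genes, mirnas))
  for (g in seq_len(cfg$n_genes)) {
    pool <- which(module_of_mirna == module_of_gene[g])
    if (length(pool) <= n_sponge_mirnas)
      stopf_("module miRNA pools too small; need n_mirnas/n_modules > %d",
             n_sponge_mirnas)
    sponge_pool <- pool[seq_len(n_sponge_mirnas)]
    common_pool <- pool[-seq_len(n_sponge_mirnas)]
    if (is_hk[g]) {
      total <- sample(seq(cfg$sponge_site_range[1],
                          cfg$sponge_site_range[2]), 1L)
      n_common <- min(2L, total - n_sponge_mirnas)
      chosen_common <- sample(common_pool, n_common)
      heavy <- total - n_common
      counts_sponge <- rep(heavy %/% n_sponge_mirnas, n_sponge_mirnas)
      extra <- heavy - sum(counts_sponge)
      if (extra > 0)
        counts_sponge[seq_len(extra)] <- counts_sponge[seq_len(extra)] + 1L
      chosen <- c(sponge_pool, chosen_common)
      counts <- c(counts_sponge, rep(1L, n_common))
    } else if (is_coherent[g]) {
      chosen <- common_pool
      counts <- 1L + rpois(length(common_pool), 3)
    } else {
      # bulk non-HK: full common-pool support at moderate intensity
      # concentrates pairwise correlations in a band just below the
      # usual cutoff scale, the mass that drives small-sample edge
      # inflation
      chosen <- common_pool
      counts <- 1L + rpois(length(common_pool), 2)
    }
    sites[g, chosen] <- as.integer(counts)
  }

  # annotations: HK from above; TA/TF sampled among non-HK genes
  cls <- rep("none", cfg$n_genes)
  cls[is_hk] <- "HK"
  non_hk <- which(!is_hk)
  n_ta <- round(cfg$ta_fraction * cfg$n_genes)
  n_tf <- round(cfg$tf_fraction * cfg$n_genes)
  pool <- sample(non_hk)
  if (n_ta > 0) cls[pool[seq_len(min(n_ta, length(pool)))]] <- "TA"
  rest <- pool[cls[pool] == "none"]
  if (n_tf > 0) cls[rest[seq_len(min(n_tf, length(rest)))]] <- "TF"

  # planted 3'US genes: non-HK genes confined to a few modules, so the
  # other modules' genes (HK in particular) stay unconnected to 3'US
  if (cfg$n_3us_genes > length(non_hk))
    stopf_("n_3us_genes exceeds the number of non-HK genes")
  us_idx <- integer(0)
  if (cfg$n_3us_genes > 0) {
    us_mods <- sample.int(cfg$n_modules, min(cfg$us_modules, cfg$n_modules))
    cand <- non_hk[module_of_gene[non_hk] %in% us_mods]
    if (length(cand) < cfg$n_3us_genes)
      cand <- union(cand, non_hk)
    us_idx <- sample(cand, cfg$n_3us_genes)
  }
  us_genes <- genes[us_idx]
  remaining <- setdiff(seq_len(cfg$n_genes), us_idx)
  ul_idx <- if (cfg$n_3ul_genes > 0)
    sample(remaining, min(cfg$n_3ul_genes, length(remaining))) else integer(0)
  ul_genes <- genes[ul_idx]

  sites_tumor <- sites
  sites_tumor[us_idx, ] <- 0L

  # partner truth: genes sharing >= 1 miRNA with a planted 3'US gene
  bin <- sites > 0
  share <- tcrossprod(bin * 1)          # n_genes x n_genes shared-miRNA counts
  diag(share) <- 0
  partner_idx <- if (length(us_idx))
    setdiff(which(rowSums(share[, us_idx, drop = FALSE] > 0) > 0), us_idx)
  else integer(0)
  partner_truth <- genes[partner_idx]

  # all sharing pairs (the planted co-regulation ledger)
  sh <- which(share > 0 & upper.tri(share), arr.ind = TRUE)
  cerna_truth <- data.frame(gene_a = genes[sh[, 1]], gene_b = genes[sh[, 2]],
                            stringsAsFactors = FALSE)
  ord <- order(cerna_truth$gene_a, cerna_truth$gene_b)
  cerna_truth <- cerna_truth[ord, , drop = FALSE]
  rownames(cerna_truth) <- NULL

  baseline <- rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  # per-gene noise heterogeneity for non-HK genes: real transcripts differ
  # widely in expression noise, and the resulting continuum of pair
  # correlations puts most backbone pairs below the usual cutoff scale
  # with a solid tail of strongly coupled pairs above it
  noise_sd_g <- ifelse(is_hk, cfg$hk_noise_sd,
                       ifelse(is_coherent,
                              cfg$noise_sd * runif(cfg$n_genes, 0.2, 0.35),
                              cfg$noise_sd * runif(cfg$n_genes, 0.95, 1.15)))
  signal_scale_g <- cfg$activity_scale * ifelse(is_hk, cfg$hk_signal_scale, 1)

  sim_cond <- function(n_samples, prefix, site_mat, repress_partners) {
    act <- matrix(rnorm(cfg$n_mirnas * n_samples, mean = 1, sd = 1),
                  cfg$n_mirnas, n_samples)
    expr <- matrix(baseline, cfg$n_genes, n_samples) -
      (signal_scale_g * site_mat) %*% act +
      matrix(rnorm(cfg$n_genes * n_samples), cfg$n_genes, n_samples) * noise_sd_g
    if (repress_partners && length(partner_idx))
      expr[partner_idx, ] <- expr[partner_idx, ] - cfg$repression_effect
    expr[expr < 0] <- 0
    dimnames(expr) <- list(genes, sprintf("%s_%02d", prefix, seq_len(n_samples)))
    expr
  }

  nsg <- cfg$samples_per_group
  expression <- list(
    A_normal = sim_cond(nsg[1], "A_normal", sites, FALSE),
    A_tumor  = sim_cond(nsg[2], "A_tumor", sites_tumor, TRUE),
    B_normal = sim_cond(nsg[3], "B_normal", sites, FALSE),
    B_tumor  = sim_cond(nsg[4], "B_tumor", sites_tumor, TRUE))

  # per-sample APA calls in tumor samples of both groups
  apa_calls <- list()
  for (cond in c("A_tumor", "B_tumor")) {
    smp <- colnames(expression[[cond]])
    for (g in us_genes) {
      hit <- smp[runif(length(smp)) < cfg$apa_call_rate]
      if (length(hit))
        apa_calls[[length(apa_calls) + 1L]] <-
          data.frame(gene = g, sample = hit, kind = "3US",
                     stringsAsFactors = FALSE)
    }
    for (g in ul_genes) {
      hit <- smp[runif(length(smp)) < cfg$apa_call_rate]
      if (length(hit))
        apa_calls[[length(apa_calls) + 1L]] <-
          data.frame(gene = g, sample = hit, kind = "3UL",
                     stringsAsFactors = FALSE)
    }
  }
  apa_calls <- if (length(apa_calls)) do.call(rbind, apa_calls)
  else data.frame(gene = character(0), sample = character(0),
                  kind = character(0), stringsAsFactors = FALSE)
  apa_calls <- apa_calls[order(apa_calls$gene, apa_calls$sample), , drop = FALSE]
  rownames(apa_calls) <- NULL

  annotations <- data.frame(gene = genes, class = cls,
                            module = module_of_gene,
                            stringsAsFactors = FALSE)

  structure(list(
    expression = expression,
    targets = target_site_table(sites),
    targets_tumor = target_site_table(sites_tumor),
    annotations = annotations,
    apa_calls = apa_calls,
    us_genes = sort(us_genes),
    ul_genes = sort(ul_genes),
    cerna_truth = cerna_truth,
    partner_truth = sort(partner_truth),
    config = cfg), class = "cerna_dataset")
}

#' @export
print.cerna_dataset <- function(x, ...) {
  ns <- vapply(x$expression, ncol, 0L)
  cat(sprintf("synthetic ceRNA dataset: %d genes, %d miRNAs\n",
              nrow(x$expression$A_normal), length(x$targets$universe)))
  cat(sprintf("  samples: %s\n",
              paste(sprintf("%s=%d", names(ns), ns), collapse = ", ")))
  cat(sprintf("  planted: %d 3'US genes, %d partners, %d sharing pairs\n",
              length(x$us_genes), length(x$partner_truth),
              nrow(x$cerna_truth)))
  invisible(x)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits one expression TSV per condition, a long-format target-site TSV
#' (positive entries only) with a sidecar miRNA-universe list, annotation
#' and APA-call TSVs, ground-truth files, and the generator configuration
#' as JSON. \code{\link{read_dataset}} round-trips the result.
#'
#' @param dataset a \code{cerna_dataset}.
#' @param directory output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "cerna_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (cond in names(dataset$expression))
    write_matrix_tsv_(dataset$expression[[cond]],
                      file.path(directory, sprintf("expression_%s.tsv", cond)))
  write_target_table_ <- function(tab, path) {
    m <- tab$site_count
    idx <- which(m > 0, arr.ind = TRUE)
    df <- data.frame(gene = rownames(m)[idx[, 1]],
                     mirna = colnames(m)[idx[, 2]],
                     site_count = m[idx], stringsAsFactors = FALSE)
    df <- df[order(df$gene, df$mirna), , drop = FALSE]
    write_tsv_(df, path)
  }
  write_target_table_(dataset$targets, file.path(directory, "targets.tsv"))
  write_target_table_(dataset$targets_tumor,
                      file.path(directory, "targets_tumor.tsv"))
  writeLines(dataset$targets$universe,
             file.path(directory, "mirna_universe.txt"))
  write_tsv_(dataset$annotations, file.path(directory, "annotations.tsv"))
  write_tsv_(dataset$apa_calls, file.path(directory, "apa_calls.tsv"))
  writeLines(dataset$us_genes, file.path(directory, "us_genes.txt"))
  writeLines(dataset$ul_genes, file.path(directory, "ul_genes.txt"))
  writeLines(dataset$partner_truth, file.path(directory, "partner_truth.txt"))
  write_tsv_(dataset$cerna_truth, file.path(directory, "cerna_truth.tsv"))
  jsonlite::write_json(unclass(dataset$config),
                       file.path(directory, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Read a dataset written by \code{\link{write_dataset}}
#'
#' @param directory directory produced by \code{\link{write_dataset}}.
#' @return a \code{cerna_dataset}.
#' @export
read_dataset <- function(directory) {
  cfg <- jsonlite::read_json(file.path(directory, "config.json"),
                             simplifyVector = TRUE)
  cfg <- do.call(generator_config, cfg[setdiff(names(cfg), character(0))])
  conds <- c("A_normal", "A_tumor", "B_normal", "B_tumor")
  expression <- lapply(conds, function(cond)
    read_matrix_tsv_(file.path(directory, sprintf("expression_%s.tsv", cond))))
  names(expression) <- conds
  genes <- rownames(expression$A_normal)
  universe <- readLines(file.path(directory, "mirna_universe.txt"))
  read_target_table_ <- function(path) {
    df <- read_tsv_(path)
    m <- matrix(0L, length(genes), length(universe),
                dimnames = list(genes, universe))
    if (nrow(df)) m[cbind(df$gene, df$mirna)] <- as.integer(df$site_count)
    target_site_table(m)
  }
  annotations <- read_tsv_(file.path(directory, "annotations.tsv"))
  apa_calls <- read_tsv_(file.path(directory, "apa_calls.tsv"),
                         colClasses = "character")
  if (!nrow(apa_calls))
    apa_calls <- data.frame(gene = character(0), sample = character(0),
                            kind = character(0), stringsAsFactors = FALSE)
  structure(list(
    expression = expression,
    targets = read_target_table_(file.path(directory, "targets.tsv")),
    targets_tumor = read_target_table_(file.path(directory, "targets_tumor.tsv")),
    annotations = annotations,
    apa_calls = apa_calls,
    us_genes = readLines(file.path(directory, "us_genes.txt")),
    ul_genes = readLines(file.path(directory, "ul_genes.txt")),
    cerna_truth = read_tsv_(file.path(directory, "cerna_truth.tsv")),
    partner_truth = readLines(file.path(directory, "partner_truth.txt")),
    config = cfg), class = "cerna_dataset")
}
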