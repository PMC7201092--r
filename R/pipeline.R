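#' Pipeline run configuration
#'
#' Assembles and validates every threshold the end-to-end analysis uses,
#' so each appears exactly once. Unknown arguments are errors.
#'
#' @param generator a \code{\link{generator_config}} describing the
#'   synthetic dataset (datasets on disk can be loaded with
#'   \code{\link{read_dataset}} and passed to \code{\link{run_pipeline}}
#'   directly).
#' @param reference_group group used to build the reference network
#'   (\code{"A"} or \code{"B"}); the other group's cutoff is calibrated.
#' @param reference_cutoff correlation cutoff of the reference network.
#' @param calibration_step cutoff grid step for the calibration scan.
#' @param backbone_q BH FDR threshold for backbone edges.
#' @param min_sites minimum total site count (sponge candidates).
#' @param recurrence_fraction strict APA recurrence threshold.
#' @param expr_min_value,expr_min_fraction expression filter parameters.
#' @param null_reps matched random subnetworks for the focal comparison.
#' @param subsample_sizes sizes for the subsampling experiment
#'   (\code{NULL} skips it).
#' @param subsample_reps replicates per subsample size.
#' @param log_transform correlate log2(x + 1) values.
#' @param seed global seed, fanned out to per-stage child seeds.
#' @param output_dir directory for result files.
#' @return a validated list of class \code{run_config}.
#' @export
run_config <- function(generator = generator_config(),
                       reference_group = "A",
                       reference_cutoff = 0.6,
                       calibration_step = 0.01,
                       backbone_q = 0.05,
                       min_sites = 6L,
                       recurrence_fraction = 0.2,
                       expr_min_value = 1,
                       expr_min_fraction = 0.8,
                       null_reps = 200L,
                       subsample_sizes = NULL,
                       subsample_reps = 100L,
                       log_transform = TRUE,
                       seed = 1L,
                       output_dir = tempfile("cerna_run_")) {
  cfg <- as.list(environment())
  stopifnot(inherits(cfg$generator, "generator_config"))
  if (!cfg$reference_group %in% c("A", "B"))
    stopf_("reference_group must be 'A' or 'B'")
  if (cfg$reference_cutoff < 0 || cfg$reference_cutoff > 1)
    stopf_("reference_cutoff must lie in [0, 1]")
  if (cfg$backbone_q <= 0 || cfg$backbone_q > 1)
    stopf_("backbone_q must lie in (0, 1]")
  if (cfg$recurrence_fraction < 0 || cfg$recurrence_fraction >= 1)
    stopf_("recurrence_fraction must lie in [0, 1)")
  if (cfg$null_reps < 1) stopf_("null_reps must be positive")
  class(cfg) <- "run_config"
  cfg
}

stage_seed_ <- function(seed, stage) (as.integer(seed) * 131L + stage) %% 2147483647L

#' Run the end-to-end subtype-comparable ceRNA analysis
#'
#' Stages: generate (or accept) the dataset; filter expressed genes; build
#' the target-share backbone; build the reference group's normal network
#' at the reference cutoff; calibrate the other group's cutoff against it;
#' build all four condition networks; run the downstream comparisons
#' (focal HK subnetworks vs matched nulls, gene classification, degree
#' ratios, fold changes, APA recurrence, variability, set overlap) and
#' write every table plus a JSON manifest. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @param dataset optional pre-built \code{cerna_dataset}; by default one
#'   is generated from \code{config$generator} with the run seed.
#' @param quiet suppress stage messages.
#' @return the manifest (also written to \code{manifest.json}), invisibly.
#' @export
run_pipeline <- function(config, dataset = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  say <- function(fmt, ...) if (!quiet)
    message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0)),
            sprintf(fmt, ...))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  # stage 1: data
  if (is.null(dataset)) {
    gen_cfg <- config$generator
    gen_cfg$seed <- stage_seed_(config$seed, 1L)
    dataset <- generate_dataset(gen_cfg)
  }
  say("dataset: %d genes, groups %s", nrow(dataset$expression$A_normal),
      paste(vapply(dataset$expression, ncol, 0L), collapse = "/"))

  # stage 2: expression filter over all samples jointly
  all_expr <- do.call(cbind, dataset$expression)
  expressed <- rownames(filter_expressed(all_expr, config$expr_min_value,
                                         config$expr_min_fraction))
  say("expression filter: %d of %d genes kept", length(expressed),
      nrow(all_expr))

  # stage 3: backbone on expressed genes
  tt <- dataset$targets
  tt <- target_site_table(tt$site_count[intersect(rownames(tt$site_count),
                                                  expressed), , drop = FALSE])
  backbone <- build_backbone(tt, min_sites = config$min_sites,
                             q_threshold = config$backbone_q)
  say("backbone: %d genes, %d edges", igraph::vcount(backbone),
      igraph::ecount(backbone))
  write_tsv_(network_edges(backbone), file.path(out, "backbone_edges.tsv"))

  ref <- config$reference_group
  tgt <- setdiff(c("A", "B"), ref)

  # stage 4: reference normal network
  ref_net <- build_cerna_network(dataset$expression[[paste0(ref, "_normal")]],
                                 backbone, config$reference_cutoff,
                                 log_transform = config$log_transform,
                                 condition = paste0(ref, "_normal"))
  say("reference network (%s normal, cutoff %.2f): %d nodes, %d edges",
      ref, config$reference_cutoff, igraph::vcount(ref_net),
      igraph::ecount(ref_net))

  # stage 5: calibrate the other group's cutoff
  calib <- calibrate_cutoff(ref_net,
                            dataset$expression[[paste0(tgt, "_normal")]],
                            backbone, step = config$calibration_step,
                            log_transform = config$log_transform)
  say("calibration: selected cutoff %.2f for group %s",
      calib$selected_cutoff, tgt)
  write_tsv_(calib$grid, file.path(out, "calibration_grid.tsv"))

  # stage 6: four condition networks (per-group cutoffs shared by
  # normal and tumor: equal sample sizes within a group)
  cutoffs <- c(config$reference_cutoff, calib$selected_cutoff)
  names(cutoffs) <- c(ref, tgt)
  nets <- list()
  for (grp in c("A", "B")) for (cond in c("normal", "tumor")) {
    key <- paste0(grp, "_", cond)
    nets[[key]] <- build_cerna_network(dataset$expression[[key]], backbone,
                                       cutoffs[[grp]],
                                       log_transform = config$log_transform,
                                       condition = key)
    write_tsv_(network_edges(nets[[key]]),
               file.path(out, sprintf("network_%s.tsv", key)))
  }
  say("networks: %s", paste(vapply(nets, igraph::ecount, 0), collapse = "/"))

  # stage 7: downstream comparisons
  hk_genes <- dataset$annotations$gene[dataset$annotations$class == "HK"]
  net_ref_n <- nets[[paste0(ref, "_normal")]]
  net_tgt_n <- nets[[paste0(tgt, "_normal")]]
  hk_in_both <- intersect(hk_genes, union(igraph::V(net_ref_n)$name,
                                          igraph::V(net_tgt_n)$name))
  hk_null <- tryCatch(
    matched_null_similarity(net_ref_n, net_tgt_n, hk_in_both,
                            reps = config$null_reps,
                            seed = stage_seed_(config$seed, 7L)),
    error = function(e) e)
  if (inherits(hk_null, "error")) {
    say("HK focal comparison skipped: %s", conditionMessage(hk_null))
    hk_null <- NULL
  } else {
    write_tsv_(data.frame(rep = seq_along(hk_null$null_ps),
                          null_p = hk_null$null_ps),
               file.path(out, "hk_null_ps.tsv"))
  }

  tumor_samples <- colnames(dataset$expression[[paste0(tgt, "_tumor")]])
  us_rec <- recurrent_apa(dataset$apa_calls, "3US",
                          config$recurrence_fraction, samples = tumor_samples)
  writeLines(us_rec, file.path(out, "recurrent_3us_genes.txt"))

  cls <- classify_network_genes(backbone, us_rec, dataset$annotations)
  write_tsv_(cls$table, file.path(out, "gene_classification.tsv"))

  # per-gene table on the calibrated target group: degree ratio + log2FC
  norm_net <- net_tgt_n
  tum_net <- nets[[paste0(tgt, "_tumor")]]
  genes_n <- igraph::V(norm_net)$name
  en <- dataset$expression[[paste0(tgt, "_normal")]]
  et <- dataset$expression[[paste0(tgt, "_tumor")]]
  partners <- cerna_partners(norm_net, us_rec)
  gene_stats <- data.frame(
    gene = genes_n,
    degree_normal = as.integer(igraph::degree(norm_net, genes_n)),
    degree_ratio = vapply(genes_n, function(g)
      degree_ratio(norm_net, tum_net, g), numeric(1)),
    log2fc = vapply(genes_n, function(g)
      log2_fold_change(et[g, ], en[g, ]), numeric(1)),
    is_3us = genes_n %in% us_rec,
    is_partner = genes_n %in% partners,
    class = dataset$annotations$class[match(genes_n,
                                            dataset$annotations$gene)],
    stringsAsFactors = FALSE)
  gene_stats <- gene_stats[order(gene_stats$gene), , drop = FALSE]
  write_tsv_(gene_stats, file.path(out, "gene_stats.tsv"))

  # the planted contrast: ceRNA partners of recurrent 3'US genes vs
  # housekeeping genes unconnected to any 3'US gene
  is_part <- gene_stats$is_partner & !gene_stats$is_3us
  hk_uncon <- gene_stats$class == "HK" & !gene_stats$is_partner &
    !gene_stats$is_3us
  fc_p <- if (sum(is_part) >= 2 && sum(hk_uncon) >= 2)
    group_difference_test(gene_stats$log2fc[is_part],
                          gene_stats$log2fc[hk_uncon]) else NA_real_
  dr_p <- if (sum(is_part) >= 2 && sum(hk_uncon) >= 2)
    group_difference_test(gene_stats$degree_ratio[is_part],
                          gene_stats$degree_ratio[hk_uncon]) else NA_real_

  hk_in_net <- intersect(hk_genes, rownames(en))
  non_hk_in_net <- intersect(setdiff(igraph::V(norm_net)$name, hk_genes),
                             rownames(en))
  vari <- if (length(hk_in_net) >= 2 && length(non_hk_in_net) >= 2)
    expression_variability(en, hk_in_net, non_hk_in_net) else NULL

  hk_overlap_p <- {
    u <- igraph::V(backbone)$name
    a <- intersect(hk_genes, igraph::V(net_ref_n)$name)
    b <- intersect(hk_genes, igraph::V(net_tgt_n)$name)
    if (length(a) && length(b))
      set_overlap_significance(a, b, u) else NA_real_
  }

  subs <- NULL
  if (!is.null(config$subsample_sizes)) {
    subs <- subsample_experiment(
      dataset$expression[[paste0(ref, "_normal")]], backbone,
      sizes = config$subsample_sizes, reps = config$subsample_reps,
      cutoff = config$reference_cutoff,
      seed = stage_seed_(config$seed, 8L),
      log_transform = config$log_transform)
    write_tsv_(subs$edge_counts, file.path(out, "subsample_edge_counts.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cernacomp")),
    seed = config$seed,
    config = serialize_config_(config),
    n_genes_expressed = length(expressed),
    backbone = list(n_nodes = igraph::vcount(backbone),
                    n_edges = igraph::ecount(backbone)),
    cutoffs = as.list(cutoffs),
    selected_cutoff = calib$selected_cutoff,
    networks = lapply(nets, function(g)
      list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g))),
    hk_focal = if (!is.null(hk_null))
      list(focal_p = hk_null$focal_p, empirical_p = hk_null$empirical_p,
           n_focal_edges = as.list(hk_null$n_focal_edges)),
    n_recurrent_3us = length(us_rec),
    gene_class_counts = as.list(as.data.frame(cls$counts)),
    partner_vs_unconnected_hk = list(
      n_partner = sum(is_part), n_unconnected_hk = sum(hk_uncon),
      median_log2fc_partner = median_or_na_(gene_stats$log2fc[is_part]),
      median_log2fc_unconnected = median_or_na_(gene_stats$log2fc[hk_uncon]),
      median_degree_ratio_partner =
        median_or_na_(gene_stats$degree_ratio[is_part]),
      median_degree_ratio_unconnected =
        median_or_na_(gene_stats$degree_ratio[hk_uncon]),
      log2fc_p = fc_p, degree_ratio_p = dr_p),
    hk_variability_p = if (!is.null(vari)) vari$p,
    hk_overlap_p = hk_overlap_p,
    subsampling = if (!is.null(subs))
      lapply(split(subs$edge_counts$n_edges, subs$edge_counts$size), mean),
    files = sort(unique(c(list.files(out), "manifest.json"))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  say("done; outputs in %s", out)
  invisible(manifest)
}

median_or_na_ <- function(x) if (length(x)) stats::median(x) else NA_real_

serialize_config_ <- function(config) {
  cfg <- unclass(config)
  cfg$generator <- unclass(cfg$generator)
  cfg
}

#' Summarize a completed pipeline run
#'
#' @param run_dir directory containing \code{manifest.json}.
#' @param path optional file to write the summary to
#'   (\code{report.txt} in the run directory by default).
#' @return the summary lines, invisibly.
#' @export
report <- function(run_dir, path = file.path(run_dir, "report.txt")) {
  mf <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf)) stopf_("no manifest.json in %s", run_dir)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  fnum <- function(x, fmt = "%.3f") {
    x <- suppressWarnings(as.numeric(x))
    if (length(x) == 0 || is.na(x)) "NA" else sprintf(fmt, x)
  }
  fmt_net <- function(nm) sprintf("  %-9s %6d nodes %7d edges", nm,
                                  m$networks[[nm]]$n_nodes,
                                  m$networks[[nm]]$n_edges)
  lines <- c(
    "Subtype-comparable ceRNA network analysis - run summary",
    sprintf("seed: %d", m$seed),
    sprintf("expressed genes: %d", m$n_genes_expressed),
    sprintf("backbone: %d genes, %d edges", m$backbone$n_nodes,
            m$backbone$n_edges),
    sprintf("cutoffs: %s", paste(sprintf("%s=%.2f", names(m$cutoffs),
                                         unlist(m$cutoffs)), collapse = ", ")),
    sprintf("calibrated cutoff: %.2f", m$selected_cutoff),
    "networks:", vapply(names(m$networks), fmt_net, ""),
    if (!is.null(m$hk_focal)) sprintf(
      "HK focal similarity p = %.4g, empirical p vs matched nulls = %.4g",
      m$hk_focal$focal_p, m$hk_focal$empirical_p)
    else "HK focal comparison: not run (degenerate networks)",
    sprintf("recurrent 3'US genes: %d", m$n_recurrent_3us),
    sprintf("3'US partners vs unconnected HK: median log2FC %s vs %s (p = %s)",
            fnum(m$partner_vs_unconnected_hk$median_log2fc_partner),
            fnum(m$partner_vs_unconnected_hk$median_log2fc_unconnected),
            fnum(m$partner_vs_unconnected_hk$log2fc_p, "%.3g")),
    sprintf("  median degree ratio %s vs %s (p = %s)",
            fnum(m$partner_vs_unconnected_hk$median_degree_ratio_partner),
            fnum(m$partner_vs_unconnected_hk$median_degree_ratio_unconnected),
            fnum(m$partner_vs_unconnected_hk$degree_ratio_p, "%.3g")),
    if (!is.null(m$hk_variability_p))
      sprintf("HK vs non-HK expression variability p = %s",
              fnum(m$hk_variability_p, "%.3g")),
    if (!is.null(m$hk_overlap_p) && !is.na(m$hk_overlap_p))
      sprintf("HK network-gene overlap between groups p = %s",
              fnum(m$hk_overlap_p, "%.3g")),
    if (!is.null(m$subsampling))
      sprintf("mean subsampled edge counts: %s",
              paste(sprintf("n=%s: %.1f", names(m$subsampling),
                            unlist(m$subsampling)), collapse = ", ")),
    "result files:",
    sprintf("  %s", m$files))
  lines <- unlist(lines)
  writeLines(lines, path)
  invisible(lines)
}
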