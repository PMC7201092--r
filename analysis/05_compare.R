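#!/usr/bin/env Rscript
# Downstream comparisons: (1) are the sponge-HK edge subnetworks more
# similar between the groups' normal networks than matched random
# non-HK subnetworks; (2) how do recurrent 3'US genes rewire the small
# group's network from normal to tumor (fold change, degree ratio of
# their ceRNA partners vs housekeeping genes unconnected to 3'US);
# (3) HK variability and cross-group HK overlap.

library(cernacomp)

ds <- read_dataset("results/data")
all_expr <- do.call(cbind, ds$expression)
expressed <- rownames(filter_expressed(all_expr, 1, 0.8))
tt <- target_site_table(
  ds$targets$site_count[intersect(rownames(ds$targets$site_count), expressed), ,
                        drop = FALSE])
bb <- build_backbone(tt)
hk <- ds$annotations$gene[ds$annotations$class == "HK"]

cal <- read.table("results/calibration_grid.tsv", header = TRUE, sep = "\t")
eligible <- !is.na(cal$p_value) & cal$n_nodes >= 10
sel <- cal$cutoff[eligible][which.max(cal$p_value[eligible])]

netA <- suppressWarnings(build_cerna_network(ds$expression$A_normal, bb, 0.6))
netBn <- suppressWarnings(build_cerna_network(ds$expression$B_normal, bb, sel))
netBt <- suppressWarnings(build_cerna_network(ds$expression$B_tumor, bb, sel))

# (1) sponge-HK subnetworks vs 200 matched random non-HK subnetworks
mn <- matched_null_similarity(netA, netBn, hk, reps = 200L, seed = 202L)
print(mn)
write.table(data.frame(rep = seq_along(mn$null_ps), null_p = mn$null_ps),
            "results/hk_null_ps.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# (2) recurrent 3'US genes and their partners in the small group
us <- recurrent_apa(ds$apa_calls, "3US", 0.2,
                    samples = colnames(ds$expression$B_tumor))
partners <- cerna_partners(netBn, us)
genes <- igraph::V(netBn)$name
stats <- data.frame(
  gene = genes,
  degree_normal = as.integer(igraph::degree(netBn, genes)),
  degree_ratio = vapply(genes, function(g) degree_ratio(netBn, netBt, g),
                        numeric(1)),
  log2fc = vapply(genes, function(g)
    log2_fold_change(ds$expression$B_tumor[g, ], ds$expression$B_normal[g, ]),
    numeric(1)),
  is_3us = genes %in% us,
  is_partner = genes %in% partners,
  class = ds$annotations$class[match(genes, ds$annotations$gene)])
write.table(stats, "results/gene_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

is_p <- stats$is_partner
hk_unc <- stats$class == "HK" & !stats$is_partner & !stats$is_3us
cat(sprintf("recurrent 3'US genes (> 20%% of tumor samples): %d\n", length(us)))
cat(sprintf("3'US ceRNA partners in the network: %d; unconnected HK: %d\n",
            sum(is_p), sum(hk_unc)))
cat(sprintf("median log2FC: partners %.3f vs unconnected HK %.3f (rank-sum p = %.3g)\n",
            median(stats$log2fc[is_p]), median(stats$log2fc[hk_unc]),
            group_difference_test(stats$log2fc[is_p], stats$log2fc[hk_unc])))
cat(sprintf("median degree ratio: partners %.3f vs unconnected HK %.3f (p = %.3g)\n",
            median(stats$degree_ratio[is_p]), median(stats$degree_ratio[hk_unc]),
            group_difference_test(stats$degree_ratio[is_p],
                                  stats$degree_ratio[hk_unc])))

# (3) HK variability and cross-group overlap of network HK genes
v <- expression_variability(ds$expression$B_normal,
                            intersect(hk, rownames(ds$expression$B_normal)),
                            setdiff(genes, hk))
cat(sprintf("HK vs non-HK expression SD (normal): medians %.2f vs %.2f, p = %.3g\n",
            median(v$sd_a), median(v$sd_b), v$p))
hkA <- intersect(hk, igraph::V(netA)$name)
hkB <- intersect(hk, igraph::V(netBn)$name)
cat(sprintf("HK genes in both normal networks: %d / %d; overlap p = %.3g\n",
            length(intersect(hkA, hkB)), length(union(hkA, hkB)),
            set_overlap_significance(hkA, hkB, igraph::V(bb)$name)))

# backbone-only classification against the planted truth
cls <- classify_network_genes(bb, us, ds$annotations)
write.table(cls$table, "results/gene_classification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(cls$counts)
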