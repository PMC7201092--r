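#!/usr/bin/env Rscript
# Build the four condition networks on the shared backbone: the reference
# group at the traditional cutoff 0.6, the small group at its calibrated
# cutoff; within each group the normal-derived cutoff is reused for the
# tumor network (equal sample sizes within a group).

library(cernacomp)

ds <- read_dataset("results/data")
all_expr <- do.call(cbind, ds$expression)
expressed <- rownames(filter_expressed(all_expr, 1, 0.8))
tt <- target_site_table(
  ds$targets$site_count[intersect(rownames(ds$targets$site_count), expressed), ,
                        drop = FALSE])
bb <- build_backbone(tt)

cal <- read.table("results/calibration_grid.tsv", header = TRUE, sep = "\t")
eligible <- !is.na(cal$p_value) & cal$n_nodes >= 10
sel <- cal$cutoff[eligible][which.max(cal$p_value[eligible])]
cutoffs <- c(A = 0.6, B = sel)
cat(sprintf("cutoffs: A = %.2f, B = %.2f\n", cutoffs["A"], cutoffs["B"]))

for (grp in c("A", "B")) for (cond in c("normal", "tumor")) {
  key <- paste0(grp, "_", cond)
  net <- suppressWarnings(
    build_cerna_network(ds$expression[[key]], bb, cutoffs[[grp]],
                        condition = key))
  write.table(network_edges(net), sprintf("results/network_%s.tsv", key),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("  %s: %d nodes, %d edges\n", key, igraph::vcount(net),
              igraph::ecount(net)))
}
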