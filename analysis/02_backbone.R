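#!/usr/bin/env Rscript
# Build the miRNA target-site-share backbone: restrict to sponge
# candidates (at least 6 total sites), test every gene pair's miRNA-set
# overlap with the upper-tail hypergeometric test, and keep pairs with
# BH FDR below 0.05. The backbone is condition-independent; expression
# only enters later.

library(cernacomp)

ds <- read_dataset("results/data")

all_expr <- do.call(cbind, ds$expression)
expressed <- rownames(filter_expressed(all_expr, 1, 0.8))
cat(sprintf("expression filter (>= 1 in > 80%% of samples): %d of %d genes\n",
            length(expressed), nrow(all_expr)))

tt <- target_site_table(
  ds$targets$site_count[intersect(rownames(ds$targets$site_count), expressed), ,
                        drop = FALSE])
bb <- build_backbone(tt, min_sites = 6L, q_threshold = 0.05)
write_tsv <- function(df, path) write.table(df, path, sep = "\t",
                                            quote = FALSE, row.names = FALSE)
write_tsv(network_edges(bb), "results/backbone_edges.tsv")
cat(sprintf("backbone: %d genes, %d significant target-sharing pairs\n",
            igraph::vcount(bb), igraph::ecount(bb)))
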