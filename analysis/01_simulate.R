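#!/usr/bin/env Rscript
# Generate the synthetic study dataset: two groups of tumor/normal pairs
# with unequal sample sizes (77 vs 20), miRNA-module-structured target
# sharing, sponge housekeeping genes, and planted 3'US genes whose site
# loss represses their ceRNA partners. Writes plain-text inputs for the
# later stages under results/data/.

library(cernacomp)

cfg <- generator_config(seed = 1L)
ds <- generate_dataset(cfg)
print(ds)

dir.create("results", showWarnings = FALSE)
write_dataset(ds, "results/data")

hk <- sum(ds$annotations$class == "HK")
cat(sprintf("wrote results/data: %d genes (%d HK), %d planted 3'US genes, %d partners\n",
            nrow(ds$expression$A_normal), hk, length(ds$us_genes),
            length(ds$partner_truth)))
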