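#!/usr/bin/env Rscript
# Single-command alternative to the numbered stages: run the packaged
# end-to-end pipeline with one config and produce the run summary.

library(cernacomp)

cfg <- run_config(seed = 0L, output_dir = "results/run",
                  subsample_sizes = c(20L, 40L, 60L, 75L))
mf <- run_pipeline(cfg)
lines <- report("results/run")
cat(lines, sep = "\n")
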