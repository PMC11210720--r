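#!/usr/bin/env Rscript
# Full-size Gaussian-sphere benchmark: 5 frames at 50^3, published parameter
# set, 4 independent loops, ground-truth MSE curve. Expect 30-60 min on one
# CPU. Equivalent to `romt all --size 50 --mode independent --out <dir>`.

suppressMessages(library(romt))

out_dir <- commandArgs(trailingOnly = TRUE)
if (length(out_dir) == 0L) out_dir <- "results/phantom50"

cfg <- romt_config(mode = "independent")
t0 <- proc.time()
pip <- romt_pipeline(cfg = cfg, spec = sphere_spec(scale = 1),
                     out_dir = out_dir, verbose = TRUE)
acc <- pip$accuracy
cat(sprintf("elapsed: %.1f min\n", (proc.time() - t0)[3] / 60))
cat(sprintf("MSE over %d steps: %.4f +/- %.4f\n",
            nrow(acc$curve), acc$mean, acc$sd))
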