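#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study region — covariate fields, the
# nested two-level census hierarchy, the true population surface and the
# geolocated point events — and write everything under results/synthetic/.

suppressPackageStartupMessages(library(dasypop))

cfg <- landscape_config(seed = 1)
truth <- generate_truth(cfg)
write_truth(truth, "results/synthetic")

ncoarse <- nrow(truth$admin_coarse$units)
nfine <- nrow(truth$admin_fine$units)
area_km2 <- sum(truth$admin_coarse$units$area_km2)
cat(sprintf("study region: %d x %d cells of %g deg (%.0f km2)\n",
            cfg$grid_shape[1], cfg$grid_shape[2], cfg$cell_size, area_km2))
cat(sprintf("census: %d coarse units (ASR %.2f km), %d fine units (ASR %.2f km)\n",
            ncoarse, asr(area_km2, ncoarse), nfine, asr(area_km2, nfine)))
cat(sprintf("population: %d persons; built fraction %.2f\n",
            sum(truth$true_population$values),
            mean(truth$covariates$blt_cls$values)))
cat(sprintf("events: %d points (%.3f per person)\n",
            nrow(truth$events), nrow(truth$events) / cfg$pop_total))
stopifnot(sum(truth$admin_fine$units$pop_count) ==
            sum(truth$admin_coarse$units$pop_count))
cat("fine counts nest exactly into coarse counts: OK\n")
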