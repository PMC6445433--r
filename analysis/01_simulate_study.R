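#!/usr/bin/env Rscript
# Step 1 — simulate the imaging study.
#
# Writes a complete synthetic case-control study (8 impaired + 8 matched
# controls, macular SCP + disc RPC/SVC scans per participant) with the
# OCTA metric columns produced by quantifying the images, plus one
# full-resolution angiogram pair with its binarization/skeleton masks
# for inspection.

suppressMessages(library(octaq))
seed <- 20260918L
out <- "results/study"

fx <- end_to_end_fixture(seed = seed, dir = out, n_per_group = 8L,
                         size_px = 160L)
cat(sprintf("wrote %d participants (%d scans) under %s\n",
            nrow(fx$cohort), 3L * nrow(fx$cohort), out))

# full-size exemplars: macular SCP and disc RPC
dir.create("results/exemplar", showWarnings = FALSE, recursive = TRUE)
mac <- generate_angiogram(304L, scan_type = "macula", seed = seed)
dsc <- generate_angiogram(304L, scan_type = "disc", seed = seed + 1L)
write_angiogram(mac$image, "results/exemplar/macula_scp.png")
write_angiogram(dsc$image, "results/exemplar/disc_rpc.png")

fz <- faz_background_binarize(mac$image)
write_mask_png(fz$map$mask, "results/exemplar/macula_binary.png")
write_mask_png(skeletonize(fz$map)$mask, "results/exemplar/macula_skeleton.png")
write_mask_png(fz$faz$mask, "results/exemplar/macula_faz.png")
pb <- phansalkar_binarize(dsc$image)
write_mask_png(pb$mask, "results/exemplar/disc_binary.png")
write_mask_png(large_vessel_mask(dsc$image)$mask,
               "results/exemplar/disc_large_vessels.png")

cat(sprintf("exemplar macula: true VD %.1f%%, FAZ area %.3f mm^2 (measured %.3f)\n",
            mac$truth$true_vd_percent, mac$truth$faz_area_mm2,
            fz$faz$area_mm2))
cat("exemplar images and masks under results/exemplar\n")
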