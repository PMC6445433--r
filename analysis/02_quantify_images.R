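#!/usr/bin/env Rscript
# Step 2 — quantify vascular metrics from the stored scans.
#
# Re-reads one participant's images from disk (as a user would with real
# exported angiograms), runs the full per-eye quantification, and logs
# the thresholds chosen for each scan.

suppressMessages(library(octaq))
study <- "results/study"
if (!dir.exists(file.path(study, "images"))) {
  stop("run analysis/01_simulate_study.R first")
}

cohort <- read_cohort_table(file.path(study, "cohort.csv"))
id <- cohort$id[1]
img <- function(scan, type, layer) {
  read_angiogram(file.path(study, "images", paste0(id, "_", scan, ".png")),
                 field_width_mm = if (type == "macula") 3.0 else 4.5,
                 scan_type = type, layer = layer,
                 quality = c(SQ = 8, SSI = 60))
}
scans <- list(macula_scp = img("macula_scp", "macula", "SCP"),
              disc_rpc = img("disc_rpc", "disc", "RPC"),
              disc_svc = img("disc_svc", "disc", "SVC"))

metrics <- quantify_eye(scans)
print(metrics, digits = 4)
dir.create("results", showWarnings = FALSE)
utils::write.csv(metrics, sprintf("results/metrics_%s.csv", id),
                 row.names = FALSE)

fz <- faz_background_binarize(scans$macula_scp)
log <- list(
  participant = id,
  faz_threshold = fz$faz$threshold,
  faz_area_mm2 = fz$faz$area_mm2,
  shanbhag_bin =
    large_vessel_mask(scans$disc_rpc)$min_component_area_um2,
  phansalkar = phansalkar_binarize(scans$disc_rpc)$threshold_params)
jsonlite::write_json(log, sprintf("results/thresholds_%s.json", id),
                     auto_unbox = TRUE, digits = 8)
cat(sprintf("metrics and threshold log for %s written under results/\n", id))
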