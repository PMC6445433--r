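# octaq

Vessel density, flow and case-control statistics for en face OCT
angiography.

`octaq` is for researchers quantifying retinal perfusion from en face
OCTA exports — typically small case-control studies asking whether
capillary dropout in the macula or around the optic disc tracks a
disease state (the motivating setting is amnestic MCI / early
Alzheimer's disease vs matched controls). It implements the full chain
from exported angiogram to result tables:

* **ROIs**: physically calibrated annuli — the parafovea (1.0–3.0 mm
  ring diameters, fovea-centred) and the peripapillary "donut"
  (2.0–4.0 mm, disc-centred) — with exact quadrant partitions.
* **Binarization**: Phansalkar local thresholding (15×15 px window) for
  disc scans; Shanbhag entropy thresholding inside the large-vessel
  pipeline; the foveal-avascular-zone (FAZ) background threshold for
  macular scans.
* **Metrics**, over an ROI mask `R` with vessel map `V`, skeleton `S`,
  large-vessel mask `L`, decorrelation image `I`:
  - vessel density `VD = 100·|V∩R|/|R|`
  - vessel length density `VLD = 100·|S∩R|/|R|` (1-px skeleton,
    calibre-independent)
  - microcapillary VD `= 100·|V∩R∖L| / |R∖L|`
  - adjusted flow index `AFI = mean(I over V∩R)` (flow-velocity
    surrogate on the [0,1] decorrelation scale)
  - FAZ area in mm²
* **Statistics**: right-eye-first selection with quality gates (SQ ≥ 6,
  SSI ≥ 50 macula / ≥ 45 disc); Shapiro-Wilk-gated Student t vs
  Mann-Whitney comparisons with Hedges g
  (`J·(m_c − m_i)/s_pooled`, `J = 1 − 3/(4N−9)`); gated
  Pearson/Spearman correlations against MoCA; two-way single-measure
  ICC (absolute agreement and consistency); assembly of the full
  demographic, metric, correlation and supplementary tables.
* **Synthetic data**: seeded angiogram generation with known truth
  masks (branching trees + capillary mesh + FAZ with its terminal
  ring), a latent-severity cohort generator calibrated to the published
  group summaries, and a deterministic reference cohort whose sample
  moments and MoCA correlations match the published values exactly.

## Worked example

```r
library(octaq)

# a 304-px macular SCP angiogram with known ground truth
g   <- generate_angiogram(size_px = 304, scan_type = "macula", seed = 7)
fz  <- faz_background_binarize(g$image)       # FAZ noise threshold
roi <- make_annulus(g$image, 1.0, 3.0)        # parafovea

vessel_density(fz$map, roi)                   # 42.35  (truth 41.72)
vessel_length_density(skeletonize(fz$map), roi)  # 15.66
adjusted_flow_index(g$image, fz$map, roi)     # 0.498  (truth 0.504)
fz$faz$area_mm2                               # 0.194  (analytic 0.196)
```

Measured VD recovers the constructed truth within the noise admitted by
the threshold; the FAZ area approaches the analytic π·0.25² mm² disc up
to pixelation.

At the cohort level, the reference stand-in reproduces the published
group contrast by computation:

```r
ref <- synthetic_reference_cohort()
tb  <- reproduce_tables(ref, force_test = "student", force_corr = "pearson")
tb$table2[1, c("mean_impaired", "mean_control", "p", "hedges_g", "cohen_d")]
#   mean_impaired mean_control       p  hedges_g   cohen_d
#           40.67         44.5 0.02838   0.79377    0.8143
tb$table3[c(1, 5), c("variable", "r", "p", "n")]
#                variable     r       p  n
#       Parafoveal SCP VD 0.361 0.04237 32
#   Peripapillary RPC VLD 0.463 0.00998 30
```

A parafoveal vessel-density deficit of ~3.8 percentage points at these
sample sizes is significant at p ≈ 0.028 with a large effect
(d ≈ 0.81), and MoCA correlates with both parafoveal VD and
peripapillary VLD — the central findings this pipeline regenerates.

The numbered scripts under `analysis/` run the same machinery as a
narrative workflow (simulate a study, quantify its images, build the
tables, validate the methods), writing their outputs under `results/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Recomputes the pipeline end to end from scratch: builds the reference
cohort and its result tables, simulates a miniature imaging study
(angiograms → per-eye metrics → group tables), and measures
ground-truth recovery on a full-size synthetic angiogram, writing the
JSON report to `--out`.
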