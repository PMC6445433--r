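# Binarization, morphology and the four vascular metrics.

test_that("Phansalkar thresholding matches its closed form on flat images", {
  zero <- matrix(0, 40, 40)
  expect_false(any(phansalkar_binarize(zero)$mask))

  half <- matrix(0.5, 40, 40)
  # t = 0.5 (1 + 2 e^-5 - 0.25) ~ 0.3817 < 0.5 -> everything foreground
  expect_true(all(phansalkar_binarize(half)$mask))

  expect_error(phansalkar_binarize(half, window_px = 14L), "odd")
})

test_that("Phansalkar equals the brute-force windowed oracle", {
  for (s in 1:20) {
    set.seed(s)
    px <- matrix(runif(32 * 32), 32, 32)
    fast <- phansalkar_binarize(px)$mask
    expect_identical(fast, phansalkar_oracle(px), info = paste("seed", s))
  }
  # non-default window
  set.seed(99)
  px <- matrix(runif(32 * 32), 32, 32)
  expect_identical(phansalkar_binarize(px, window_px = 7L)$mask,
                   phansalkar_oracle(px, window = 7L))
})

test_that("Shanbhag separates a two-delta histogram and flags constants", {
  px <- matrix(rep(c(0.2, 0.8), each = 512), 32, 32)
  bin <- shanbhag_binarize(px)
  expect_identical(bin$mask, px == 0.8)
  expect_gte(bin$threshold_params$threshold_value, 0.2)
  expect_lt(bin$threshold_params$threshold_value, 0.8)

  expect_warning(flat <- shanbhag_binarize(matrix(0.4, 16, 16)), "constant")
  expect_false(any(flat$mask))
})

test_that("Shanbhag threshold equals the exhaustive criterion scan", {
  set.seed(7)
  px <- matrix(pmin(pmax(c(rnorm(2048, 0.25, 0.06),
                           rnorm(2048, 0.7, 0.08)), 0), 1), 64, 64)
  bin <- shanbhag_binarize(px)
  counts <- tabulate(pmin(pmax(round(px * 255), 0), 255) + 1L, nbins = 256L)
  expect_identical(bin$threshold_params$threshold_bin,
                   shanbhag_oracle_bin(counts))
  # and on several random histograms
  for (s in 1:5) {
    set.seed(s)
    counts <- rpois(256, lambda = runif(256, 0, 30))
    expect_identical(shanbhag_threshold_bin(counts),
                     shanbhag_oracle_bin(counts), info = paste("seed", s))
  }
})

test_that("contrast stretch expands the range and preserves ordering", {
  set.seed(2)
  px <- matrix(runif(64 * 64, 0.4, 0.6), 64, 64)
  st <- contrast_stretch(px)
  expect_lt(min(st), 0.01)
  expect_gt(max(st), 0.99)
  ord_in <- order(px)
  expect_true(all(diff(st[ord_in]) >= 0))

  expect_warning(same <- contrast_stretch(matrix(0.3, 8, 8)), "degenerate")
  expect_identical(same, matrix(0.3, 8, 8))
})

test_that("FAZ background threshold recovers constructed vessels", {
  cm <- constructed_macula(seed = 11)
  fz <- faz_background_binarize(cm$image)
  # all true vessel pixels above threshold
  expect_true(all(fz$map$mask[cm$vessel]))
  # >= 97% of the background suppressed
  bg <- !cm$vessel
  expect_gte(mean(!fz$map$mask[bg]), 0.97)
  # FAZ area within 2% of the analytic disc area
  expect_equal(fz$faz$area_mm2, cm$faz_analytic_mm2, tolerance = 0.02)
})

test_that("a zero-valued FAZ gives threshold 0 and nonzero foreground", {
  n <- 120L
  px <- matrix(0, n, n)
  px[, seq(5L, n, by = 9L)] <- 0.5   # vessels well outside the centre
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  px[d < 25] <- 0
  img <- en_face_angiogram(px, 1.5, "macula")
  fz <- faz_background_binarize(img)
  expect_identical(fz$faz$threshold, 0)
  expect_identical(fz$map$mask, px > 0)
})

test_that("a high-signal FAZ seed is rejected with guidance", {
  cm <- constructed_macula(seed = 3)
  vessel_px <- which(cm$vessel, arr.ind = TRUE)[1, ]
  expect_error(faz_background_binarize(cm$image, faz_seed_px = vessel_px),
               "seed")
})

test_that("vessel density counts pixels exactly", {
  roi <- matrix(FALSE, 50, 50)
  roi[11:40, 11:40] <- TRUE               # 900 px ROI
  full <- matrix(TRUE, 50, 50)
  empty <- matrix(FALSE, 50, 50)
  expect_identical(vessel_density(full, roi), 100)
  expect_identical(vessel_density(empty, roi), 0)
  fg <- matrix(FALSE, 50, 50)
  fg[11:40, 11:22] <- TRUE                # 30 x 12 = 360 px -> 40%
  expect_identical(vessel_density(fg, roi), 40)
  expect_error(vessel_density(full, empty), "empty ROI")
})

test_that("large-vessel mask removes components below the area cutoff", {
  n <- 304L
  px <- matrix(0.05, n, n)
  px[100:124, 100:119] <- 0.9      # 500 px component
  px[200, 200:201] <- 0.9          # 2 px component
  img <- en_face_angiogram(px, 4.5, "disc")
  # 14.8 um/px -> 2 px = 438 um^2: removed at a 500 um^2 cutoff
  lvm <- large_vessel_mask(img, min_component_area_um2 = 500)
  expect_true(all(lvm$mask[100:124, 100:119]))
  expect_false(any(lvm$mask[200, 200:201]))
  # the conventional 25 um^2 criterion is sub-pixel here: floor of one
  # pixel keeps both components
  lvm25 <- large_vessel_mask(img, min_component_area_um2 = 25)
  expect_true(all(lvm25$mask[200, 200:201]))
  # never introduces pixels beyond the thresholded foreground
  expect_false(any(lvm$mask & !lvm25$mask))
})

test_that("an empty disc image yields an empty large-vessel mask", {
  img <- en_face_angiogram(matrix(0, 64, 64), 4.5, "disc")
  # degenerate on two counts: flat contrast range and a single-bin histogram
  lvm <- suppressWarnings(large_vessel_mask(img))
  expect_false(any(lvm$mask))
})

test_that("microcapillary density removes large vessels from both sides", {
  roi <- matrix(TRUE, 60, 60)
  fg <- matrix(FALSE, 60, 60)
  fg[seq(1L, 60L, by = 2L), ] <- TRUE      # 50% coverage
  none <- matrix(FALSE, 60, 60)
  expect_identical(microcapillary_density(fg, none, roi),
                   vessel_density(fg, roi))
  expect_identical(microcapillary_density(fg, fg, roi), 0)
  # constructed: outside the large block, 30% of remaining ROI is vessel
  large <- matrix(FALSE, 60, 60)
  large[1:60, 1:20] <- TRUE                # 1200 px large region
  fg2 <- large                             # all large pixels are vessels
  fg2[1:18, 21:60] <- TRUE                 # 720 of 2400 remaining px = 30%
  expect_identical(microcapillary_density(fg2, large, roi), 30)
  expect_error(microcapillary_density(fg, matrix(TRUE, 60, 60), roi),
               "large vessels")
})

test_that("skeletonization thins a bar to a single centreline", {
  bar <- matrix(FALSE, 20, 120)
  bar[8:12, 11:110] <- TRUE               # 5 px wide, 100 px long
  sk <- skeletonize(bar)$mask
  expect_identical(max(label_components(sk)), 1L)
  cols <- range(which(apply(sk, 2, any)))
  len <- diff(cols) + 1L
  # flat bar caps erode by at most ceil(width/2) px per end under
  # iterative thinning (scikit-image's reference variant measures 97 on
  # the same bar)
  expect_gte(len, 94L)
  expect_lte(len, 104L)
  # 1-px wide: no skeleton pixel with a fully-foreground 3x3 block
  expect_false(any(window_full3(sk)))
  expect_true(all(sk[!bar] == FALSE))     # subset of the source
})

test_that("skeletonization is idempotent and preserves components", {
  single <- matrix(FALSE, 9, 9)
  single[5, 5] <- TRUE
  expect_identical(skeletonize(single)$mask, single)

  block <- matrix(FALSE, 8, 8)
  block[3:4, 3:4] <- TRUE                  # plain Zhang-Suen erases this
  skb <- skeletonize(block)$mask
  expect_identical(sum(skb), 1L)

  for (s in 1:5) {
    set.seed(s)
    m <- matrix(runif(48 * 48) < 0.4, 48, 48)
    m <- binary_dilate(m, 1)
    sk1 <- skeletonize(m)$mask
    sk2 <- skeletonize(sk1)$mask
    expect_identical(sk2, sk1, info = paste("seed", s))
    expect_true(all(sk1[!m] == FALSE))
    big <- max(label_components(m))
    expect_identical(max(label_components(sk1)), big)
  }
})

test_that("vessel length density counts skeleton pixels over the ROI", {
  roi <- matrix(FALSE, 80, 80)
  roi[11:60, 11:60] <- TRUE                # 2500 px ROI
  sk <- matrix(FALSE, 80, 80)
  sk[30, 21:45] <- TRUE                    # 25 px line -> 1% of 2500
  expect_identical(vessel_length_density(sk, roi), 1)
  expect_identical(vessel_length_density(matrix(FALSE, 80, 80), roi), 0)
})

test_that("AFI averages decorrelation over vessel pixels only", {
  px <- matrix(0.05, 64, 64)
  fg <- matrix(FALSE, 64, 64)
  fg[10:50, 10:50] <- TRUE
  px[fg] <- 0.42
  roi <- matrix(TRUE, 64, 64)
  expect_identical(adjusted_flow_index(px, fg, roi), 0.42)
  # invariant to sub-threshold background pixels
  px2 <- px
  px2[!fg] <- 0.11
  expect_identical(adjusted_flow_index(px2, fg, roi),
                   adjusted_flow_index(px, fg, roi))
  expect_warning(
    val <- adjusted_flow_index(px, matrix(FALSE, 64, 64), roi), "AFI")
  expect_true(is.na(val))
})

test_that("AFI recovers the mean of noisy vessel decorrelation", {
  set.seed(21)
  n <- 160L
  fg <- matrix(runif(n * n) < 0.45, n, n)   # ~11500 vessel px
  px <- matrix(0.05, n, n)
  px[fg] <- pmin(pmax(rnorm(sum(fg), 0.40, 0.05), 0), 1)
  expect_gte(sum(fg), 1e4)
  expect_equal(adjusted_flow_index(px, fg, matrix(TRUE, n, n)), 0.40,
               tolerance = 0.002 / 0.40)
})

test_that("VD, VLD and AFI are invariant under 90-degree rotation", {
  g <- generate_angiogram(size_px = 151L, seed = 5L,
                          truth_skeleton = FALSE)
  img <- g$image
  roi <- make_annulus(img, 1, 3)
  fz <- faz_background_binarize(img)
  sk <- skeletonize(fz$map)
  vd <- vessel_density(fz$map, roi)
  vld <- vessel_length_density(sk, roi)
  afi <- adjusted_flow_index(img, fz$map, roi)

  img_r <- en_face_angiogram(rot_ccw(img$pixels), img$field_width_mm,
                             "macula")
  roi_r <- make_annulus(img_r, 1, 3)
  fz_r <- faz_background_binarize(img_r)
  expect_identical(vessel_density(fz_r$map, roi_r), vd)
  # thinning breaks directional ties in a fixed scan order, so the
  # skeleton is equivariant only up to a fraction of a percent
  expect_equal(vessel_length_density(skeletonize(fz_r$map), roi_r), vld,
               tolerance = 0.005)
  expect_identical(adjusted_flow_index(img_r, fz_r$map, roi_r), afi)
})

test_that("quantify_eye fills one row per layer/ROI/metric and is deterministic", {
  mk <- function(seed, type, layer, q = c(SQ = 8, SSI = 60)) {
    generate_angiogram(128L, scan_type = type, layer = layer, seed = seed,
                       quality = q, truth_skeleton = FALSE)$image
  }
  scans <- list(macula_scp = mk(1, "macula", "SCP"),
                disc_rpc = mk(2, "disc", "RPC"),
                disc_svc = mk(3, "disc", "SVC"))
  res1 <- quantify_eye(scans)
  res2 <- quantify_eye(scans)
  expect_identical(res1, res2)
  expect_identical(nrow(res1), 12L)
  expect_identical(sum(!is.na(res1$value)), 9L)   # DCP + whole retina absent
  expect_identical(length(attr(res1, "skipped")), 0L)
  # vascular sanity: VLD below VD for each binarized layer
  v <- function(l, r, m) res1$value[res1$layer == l & res1$region == r &
                                      res1$metric == m]
  expect_lt(v("SCP", "parafovea", "vld_percent"),
            v("SCP", "parafovea", "vd_percent"))
  expect_lt(v("RPC", "peripapillary", "vld_percent"),
            v("RPC", "peripapillary", "vd_percent"))

  # quality gate: SQ = 5 macula scan is skipped with a log entry
  scans$macula_scp <- mk(1, "macula", "SCP", q = c(SQ = 5, SSI = 60))
  expect_message(res3 <- quantify_eye(scans), "quality below gate")
  expect_true(all(is.na(res3$value[res3$layer == "SCP"])))
  expect_match(attr(res3, "skipped"), "macula_scp")
})
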