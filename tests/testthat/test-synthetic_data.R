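# Synthetic angiogram and cohort generators.

test_that("angiogram generation is deterministic under a fixed seed", {
  a <- generate_angiogram(size_px = 128L, seed = 13L)
  b <- generate_angiogram(size_px = 128L, seed = 13L)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$vessel_mask, b$truth$vessel_mask)
  expect_identical(a$truth$true_afi, b$truth$true_afi)
  c <- generate_angiogram(size_px = 128L, seed = 14L)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("truth fields are consistent with the truth masks", {
  g <- generate_angiogram(size_px = 160L, seed = 2L)
  tr <- g$truth
  expect_true(all(tr$vessel_mask[tr$large_vessel_mask]))  # large subset
  expect_identical(vessel_density(tr$vessel_mask, tr$roi),
                   tr$true_vd_percent)
  expect_identical(mean(g$image$pixels[tr$vessel_mask & tr$roi$mask]),
                   tr$true_afi)
  expect_false(any(tr$vessel_mask & tr$faz_mask))
  expect_gt(tr$skeleton_length_px, 0)
})

test_that("true vessel density rises strictly with capillary density", {
  vd <- vapply(c(0.5, 0.75, 1, 1.5, 2), function(dens) {
    generate_angiogram(size_px = 152L, seed = 40L,
                       vessel_params = list(capillary_density = dens),
                       truth_skeleton = FALSE)$truth$true_vd_percent
  }, numeric(1))
  expect_true(all(diff(vd) > 0))
})

test_that("the noiseless limit recovers AFI and VD exactly", {
  g <- generate_angiogram(
    size_px = 152L, seed = 8L,
    vessel_params = list(vessel_mean = 0.5, vessel_sd = 0,
                         large_vessel_mean = 0.5, large_vessel_sd = 0),
    noise_params = list(floor = 0.03, sigma = 0),
    truth_skeleton = FALSE)
  fz <- faz_background_binarize(g$image)
  expect_identical(fz$map$mask, g$truth$vessel_mask)
  expect_identical(vessel_density(fz$map, g$truth$roi),
                   g$truth$true_vd_percent)
  expect_identical(adjusted_flow_index(g$image, fz$map, g$truth$roi), 0.5)
})

test_that("degenerate vessel parameters are rejected", {
  expect_error(
    generate_angiogram(size_px = 64L, seed = 1L,
                       vessel_params = list(n_major_trees = 0L,
                                            capillary_density = 1e-6,
                                            faz_radius_mm = 10)),
    "zero vessel pixels")
})

test_that("cohort generation is seeded, matched, and range-safe", {
  spec <- cohort_spec(16L)
  a <- generate_cohort(spec, seed = 4L)
  b <- generate_cohort(spec, seed = 4L)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # 1:1 matching: age within 3 years, same gender and race per pair
  pair <- attr(a, "pair_id")
  imp <- is_impaired(a)
  for (k in unique(pair)) {
    i <- which(imp & pair == k)
    j <- which(!imp & pair == k)
    expect_lte(abs(a$age[i] - a$age[j]), 3)
    expect_identical(a$gender[i], a$gender[j])
    expect_identical(a$race[i], a$race[j])
  }
  expect_true(all(a$moca >= 0 & a$moca <= 30))
  expect_true(all(a$ravlt_del >= 0 & a$ravlt_del <= 15))
})

test_that("zero loadings give uncorrelated scores within groups", {
  spec <- cohort_spec(2000L)
  for (nm in names(spec$variables)) spec$variables[[nm]]$loading <- 0
  big <- generate_cohort(spec, seed = 10L)
  ctl <- !is_impaired(big)
  expect_lt(abs(cor(big$moca[ctl], big$scp_vd[ctl])), 0.1)
  expect_lt(abs(cor(big$moca[ctl], big$rpc_vld[ctl])), 0.1)
  # with equalized group moments the whole-cohort correlation vanishes too
  spec$variables$moca$impaired <- spec$variables$moca$control
  spec$variables$scp_vd$impaired <- spec$variables$scp_vd$control
  big2 <- generate_cohort(spec, seed = 11L)
  expect_lt(abs(cor(big2$moca, big2$scp_vd)), 0.1)
})

test_that("infeasible loadings are rejected with a diagnostic", {
  spec <- cohort_spec(8L)
  spec$variables$scp_vd$loading <- -1.2
  expect_error(generate_cohort(spec, seed = 1L), "infeasible loading")
})

test_that("group mean differences are recovered over repeated cohorts", {
  spec <- cohort_spec(16L)
  diffs <- vapply(1:500, function(s) {
    co <- generate_cohort(spec, seed = s)
    imp <- is_impaired(co)
    mean(co$scp_vd[!imp]) - mean(co$scp_vd[imp])
  }, numeric(1))
  expect_equal(mean(diffs), 44.50 - 40.67, tolerance = 0.5 / 3.83)
})

test_that("generator calibration holds across 200 cohorts", {
  spec <- cohort_spec(16L)
  octa_vars <- c("scp_vd", "scp_vld", "scp_afi", "rpc_vd_global",
                 "rpc_vd_superior", "rpc_vd_capillary", "rpc_vld",
                 "svc_vd", "svc_vld")
  n_rep <- 200L
  sums <- matrix(0, length(octa_vars), 2L,
                 dimnames = list(octa_vars, c("impaired", "control")))
  for (s in seq_len(n_rep)) {
    co <- generate_cohort(spec, seed = 1000L + s)
    imp <- is_impaired(co)
    for (v in octa_vars) {
      sums[v, "impaired"] <- sums[v, "impaired"] + mean(co[[v]][imp])
      sums[v, "control"] <- sums[v, "control"] + mean(co[[v]][!imp])
    }
  }
  means <- sums / n_rep
  # z-score of the empirical mean against the spec mean, with
  # SE = sd / sqrt(n_rep * n_per_group)
  zs <- unlist(lapply(octa_vars, function(v) {
    vapply(c("impaired", "control"), function(gr) {
      mu <- spec$variables[[v]][[gr]][["mean"]]
      sd_ <- spec$variables[[v]][[gr]][["sd"]]
      abs(means[v, gr] - mu) / (sd_ / sqrt(n_rep * 16))
    }, numeric(1))
  }))
  # simultaneous check over 18 comparisons: every variable within 4 SE,
  # and at least 90% within the 2 SE band a single comparison would use
  expect_true(all(zs < 4))
  expect_gte(mean(zs < 2), 0.9)
})

test_that("the end-to-end fixture regenerates bit for bit", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- end_to_end_fixture(seed = 5L, dir = d1, n_per_group = 3L,
                           size_px = 128L)
  f2 <- end_to_end_fixture(seed = 5L, dir = d2, n_per_group = 3L,
                           size_px = 128L)
  expect_identical(as.data.frame(f1$cohort), as.data.frame(f2$cohort))
  rel <- function(d) {
    fs <- sort(list.files(d, recursive = TRUE))
    vapply(file.path(d, fs), function(f) unname(tools::md5sum(f)),
           character(1))
  }
  h1 <- rel(d1); h2 <- rel(d2)
  expect_identical(unname(h1), unname(h2))
  expect_identical(basename(names(h1)), basename(names(h2)))

  # pipeline outputs written to disk equal a fresh re-run on the stored
  # cohort table (the golden-file property)
  back <- read_cohort_table(file.path(d1, "cohort.csv"))
  tb <- reproduce_tables(back)
  stored <- utils::read.csv(file.path(d1, "tables", "table2.csv"))
  expect_equal(tb$table2$mean_impaired, stored$mean_impaired,
               tolerance = 1e-9)
  expect_equal(tb$table2$p, stored$p, tolerance = 1e-9)

  # metrics quantified from the images populate every macular/disc row
  expect_true(all(!is.na(f1$cohort$scp_vd)))
  expect_true(all(!is.na(f1$cohort$rpc_vld)))
})
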