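# Eye selection, group comparisons, correlations, ICC, table assembly.

test_that("eye selection follows the OD-first rule with quality gates", {
  # clean OD -> OD selected
  c1 <- as_cohort_table(rbind(make_eye_row("p1", "OD", sq_mac = 7,
                                           ssi_mac = 55),
                              make_eye_row("p1", "OS")))
  sel <- select_eye(c1)
  expect_identical(sel$cohort$eye, "OD")

  # OD fails the macular SSI gate (48 < 50), OS passes (52) -> OS
  c2 <- as_cohort_table(rbind(make_eye_row("p2", "OD", ssi_mac = 48),
                              make_eye_row("p2", "OS", ssi_mac = 52)))
  sel2 <- select_eye(c2)
  expect_identical(sel2$cohort$eye, "OS")

  # both eyes below the SQ gate -> excluded and logged
  c3 <- as_cohort_table(rbind(make_eye_row("p3", "OD", sq_mac = 5),
                              make_eye_row("p3", "OS", sq_mac = 5)))
  sel3 <- select_eye(c3)
  expect_identical(nrow(sel3$cohort), 0L)
  expect_identical(sel3$excluded$id, "p3")

  # pathology flag on OD pushes selection to OS
  r_od <- make_eye_row("p4", "OD")
  r_od$pathology <- TRUE
  r_os <- make_eye_row("p4", "OS")
  r_os$pathology <- FALSE
  sel4 <- select_eye(as_cohort_table(rbind(r_od, r_os)))
  expect_identical(sel4$cohort$eye, "OS")
})

test_that("Hedges g reproduces the hand-computed example", {
  # {1,2,3} vs {2,3,4}: pooled SD 1, uncorrected d 1, J = 1 - 3/15 = 0.8
  es <- hedges_g(c(2, 3, 4), c(1, 2, 3))
  expect_equal(es$d, 1.0)
  expect_equal(es$J, 0.8)
  expect_equal(es$g, 0.8)

  cmp <- compare_groups(c(1, 2, 3), c(2, 3, 4), force_test = "student")
  expect_equal(cmp$hedges_g, 0.8)
  expect_equal(cmp$cohen_d, 1.0)
})

test_that("identical groups give null effects and degenerate flags", {
  cmp <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4),
                        force_test = "student")
  expect_equal(cmp$p_value, 1.0)
  expect_equal(cmp$hedges_g, 0.0)

  mwu <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4),
                        force_test = "mann_whitney")
  expect_gte(mwu$p_value, 0.99)

  const <- compare_groups(rep(2, 5), rep(2, 5), force_test = "student")
  expect_true(const$degenerate)
  expect_true(is.na(const$hedges_g))
})

test_that("compare_groups is antisymmetric in group order", {
  set.seed(31)
  for (rep in 1:5) {
    a <- rnorm(12, 1)
    b <- rnorm(14)
    f <- compare_groups(a, b)
    r <- compare_groups(b, a)
    expect_equal(r$hedges_g, -f$hedges_g)
    expect_equal(r$p_value, f$p_value)
    expect_identical(r$test_used, f$test_used)
  }
})

test_that("the gated test recovers a known standardized effect", {
  set.seed(77)
  n_rep <- 1000L
  g_hat <- vapply(seq_len(n_rep), function(i) {
    compare_groups(rnorm(16, 0, 1), rnorm(16, 0.8, 1))$hedges_g
  }, numeric(1))
  J <- 1 - 3 / (4 * 32 - 9)
  expect_equal(mean(abs(g_hat)), 0.8 * J, tolerance = 0.1 / (0.8 * J))
})

test_that("missing values are dropped pairwise with n reported", {
  cmp <- compare_groups(c(1, 2, NA, 4), c(5, NA, 7, 8, 9),
                        force_test = "student")
  expect_identical(unname(cmp$n), c(3L, 4L))
})

test_that("correlate picks up perfect linear and monotone association", {
  set.seed(8)
  x <- rnorm(20)
  lin <- correlate(x, 2 * x + 1, force_method = "pearson")
  expect_equal(lin$r, 1.0)

  y_mono <- exp(x)  # rank-preserving transform
  sp <- correlate(x, y_mono, force_method = "spearman")
  expect_equal(sp$r, 1.0)

  expect_warning(cc <- correlate(x, rep(1, 20), force_method = "pearson"),
                 "constant")
  expect_true(is.na(cc$r))
})

test_that("Pearson r matches the closed-form covariance formula", {
  set.seed(14)
  for (rep in 1:5) {
    x <- rnorm(25)
    y <- rnorm(25)
    r_closed <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(correlate(x, y, force_method = "pearson")$r, r_closed,
                 tolerance = 1e-12)
  }
  # Spearman equals Pearson on (mid)ranks
  x <- c(1, 2, 2, 3, 5, 5, 5, 9)
  y <- c(2, 1, 4, 4, 6, 8, 7, 9)
  expect_equal(correlate(x, y, force_method = "spearman")$r,
               cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("Spearman p equals the exhaustive permutation distribution", {
  set.seed(12)
  for (n in c(6L, 7L)) {
    x <- sample(100, n)
    y <- sample(100, n)
    got <- correlate(x, y, force_method = "spearman")$p
    expect_equal(got, spearman_perm_p(x, y), tolerance = 1e-10,
                 info = paste("n =", n))
  }
})

test_that("ICC separates absolute agreement from consistency", {
  set.seed(9)
  r1 <- rnorm(10, 50, 5)
  dup <- cbind(r1, r1)
  expect_equal(icc(dup, "absolute_agreement")$icc, 1.0)
  shifted <- cbind(r1, r1 + 3)
  expect_equal(icc(shifted, "consistency")$icc, 1.0)
  expect_lt(icc(shifted, "absolute_agreement")$icc, 1.0)
  expect_error(icc(cbind(r1, c(r1[-1], NA))), "complete")
})

test_that("ICC equals the ANOVA mean-squares oracle", {
  toy <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  for (mode in c("absolute_agreement", "consistency")) {
    expect_equal(icc(toy, mode)$icc, icc_aov_oracle(toy, mode),
                 tolerance = 1e-10, info = mode)
  }
  for (s in 1:8) {
    set.seed(s)
    m <- matrix(rnorm(6 * sample(2:4, 1), 20, 4), nrow = 6)
    for (mode in c("absolute_agreement", "consistency")) {
      expect_equal(icc(m, mode)$icc, icc_aov_oracle(m, mode),
                   tolerance = 1e-10, info = paste(mode, "seed", s))
    }
  }
})

test_that("reproduce_tables assembles all rows from a synthetic cohort", {
  cohort <- generate_cohort(cohort_spec(16L), seed = 6L)
  tb <- reproduce_tables(cohort)
  expect_identical(nrow(tb$table2), 9L)
  expect_true(all(!is.na(tb$table2$p)))
  expect_true(all(tb$table2$p >= 0 & tb$table2$p <= 1))
  expect_identical(nrow(tb$table3), 7L)
  expect_true(all(tb$table3$n == 32L))
  expect_true(all(abs(tb$table3$r) <= 1))
  expect_identical(nrow(tb$table1), 9L)
  expect_identical(nrow(tb$tableS1), 4L)
  # diagnostics record the chosen test per variable
  expect_true(all(tb$diagnostics$table2$test %in%
                    c("student_t", "mann_whitney")))

  # a cohort of identical participants: every effect null or degenerate
  flat <- cohort
  for (v in names(octaq:::TABLE2_VARS)) flat[[v]] <- 42
  tb_flat <- suppressWarnings(reproduce_tables(flat))  # constant metrics warn
  expect_true(all(is.na(tb_flat$table2$hedges_g)))
})

test_that("variables missing wholesale still yield table rows", {
  cohort <- generate_cohort(cohort_spec(8L), seed = 2L)
  cohort$rnfl_um <- NA_real_
  tb <- reproduce_tables(cohort)
  rnfl_row <- tb$tableS1[grep("RNFL", tb$tableS1$variable), ]
  expect_true(is.na(rnfl_row$p))
  expect_identical(rnfl_row$n_impaired, 0L)
})

test_that("a 2-pooled-SD vessel-density shift is detected", {
  cohort <- generate_cohort(cohort_spec(8L), seed = 19L)
  imp <- is_impaired(cohort)
  sp <- sqrt((var(cohort$scp_vd[imp]) + var(cohort$scp_vd[!imp])) / 2)
  cohort$scp_vd[imp] <- cohort$scp_vd[imp] - 2 * sp +
    (mean(cohort$scp_vd[!imp]) - mean(cohort$scp_vd[imp]))
  tb <- reproduce_tables(cohort)
  row <- tb$table2[tb$table2$variable == octaq:::TABLE2_VARS[["scp_vd"]], ]
  expect_lt(row$p, 0.05)
  expect_gt(row$hedges_g, 1)
})
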