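# Case-control statistics: eye selection, normality-gated two-sample
# comparisons with Hedges g, normality-gated correlations, and two-way
# single-measure intraclass correlations.

#' Select the analysis eye per participant
#'
#' The right eye (OD) is selected when it passes all quality gates
#' (SQ >= `sq_min` for both scans, SSI >= `ssi_macula_min` macular and
#' `ssi_disc_min` disc) and carries no pathology flag; otherwise the left
#' eye is used if it passes; otherwise the participant is excluded. An
#' optional logical `pathology` column marks eyes with confounding
#' retinal findings.
#'
#' @param cohort A `cohort_table` with 1-2 rows (eyes) per participant.
#' @param sq_min,ssi_macula_min,ssi_disc_min Quality gates.
#' @return List with `cohort` (one row per retained participant, plus a
#'   logical `eye_used` bookkeeping column) and `excluded` (data frame of
#'   `id`, `reason`).
#' @export
select_eye <- function(cohort, sq_min = 6, ssi_macula_min = 50,
                       ssi_disc_min = 45) {
  stopifnot(is.data.frame(cohort))
  passes <- function(row) {
    gates <- c(row$sq_macula >= sq_min, row$ssi_macula >= ssi_macula_min,
               row$sq_disc >= sq_min, row$ssi_disc >= ssi_disc_min)
    path_ok <- is.null(row$pathology) || is.na(row$pathology) ||
      !isTRUE(row$pathology)
    all(gates, na.rm = FALSE) && path_ok
  }
  kept <- list()
  excluded <- list()
  for (pid in unique(cohort$id)) {
    rows <- cohort[cohort$id == pid, , drop = FALSE]
    od <- rows[rows$eye == "OD", , drop = FALSE]
    os <- rows[rows$eye == "OS", , drop = FALSE]
    if (nrow(od) == 1L && isTRUE(passes(od))) {
      kept[[pid]] <- od
    } else if (nrow(os) == 1L && isTRUE(passes(os))) {
      kept[[pid]] <- os
    } else {
      excluded[[pid]] <- data.frame(
        id = pid, reason = "no eye passed quality/pathology gates",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(kept)) do.call(rbind, kept) else cohort[0, ]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  list(cohort = out,
       excluded = if (length(excluded)) do.call(rbind, excluded)
                  else data.frame(id = character(0), reason = character(0)))
}

#' Hedges g with small-sample correction
#'
#' Pooled-SD standardized mean difference `(mean(x) - mean(y)) /
#' s_pooled`, multiplied by the small-sample correction
#' `J = 1 - 3 / (4 * (n1 + n2) - 9)`.
#'
#' @param x,y Numeric vectors (NAs dropped).
#' @return List with `g` (corrected), `d` (uncorrected), `J`,
#'   `s_pooled`. `g`/`d` are `NA` when the pooled variance is zero.
#' @export
hedges_g <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  if (sp == 0) {
    return(list(g = NA_real_, d = NA_real_, J = J, s_pooled = 0))
  }
  d <- (mean(x) - mean(y)) / sp
  list(g = J * d, d = d, J = J, s_pooled = sp)
}

#' Compare a variable between the impaired and control groups
#'
#' Two-sample comparison with the test chosen by Shapiro-Wilk normality
#' in both groups at `alpha_normality`: Student's t (pooled variance,
#' two-sided) when both groups look normal, Mann-Whitney U otherwise
#' (exact when feasible, normal approximation with continuity/tie
#' correction otherwise — the base-R `wilcox.test` conventions). The
#' effect size is Hedges g oriented as `(control - impaired) / s_pooled`
#' so that a positive g means the control group is higher.
#'
#' @param values_impaired,values_control Numeric vectors (NAs dropped;
#'   at least 2 non-missing values per group).
#' @param force_test `NULL` (gate on normality), `"student"`, or
#'   `"mann_whitney"`.
#' @param alpha_normality Shapiro-Wilk significance gate.
#' @param variable Label carried into the result.
#' @return An object of class `group_comparison`: variable, per-group n,
#'   mean, sd, min, max, `test_used`, `p_value`, `hedges_g`, `cohen_d`,
#'   and the per-group Shapiro p-values.
#' @export
compare_groups <- function(values_impaired, values_control,
                           force_test = NULL, alpha_normality = 0.05,
                           variable = "") {
  xi <- values_impaired[!is.na(values_impaired)]
  xc <- values_control[!is.na(values_control)]
  if (length(xi) < 2L || length(xc) < 2L) {
    stop("need at least 2 non-missing values per group")
  }
  sw <- vapply(list(impaired = xi, control = xc), shapiro_p, numeric(1))
  if (is.null(force_test)) {
    normal <- all(sw > alpha_normality, na.rm = TRUE)
    test_used <- if (normal) "student_t" else "mann_whitney"
  } else {
    test_used <- switch(match.arg(force_test, c("student", "mann_whitney")),
                        student = "student_t",
                        mann_whitney = "mann_whitney")
  }
  es <- hedges_g(xc, xi)  # positive when controls higher
  p <- if (es$s_pooled == 0) {
    NA_real_  # degenerate: both groups constant
  } else if (test_used == "student_t") {
    stats::t.test(xi, xc, var.equal = TRUE)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(xi, xc, exact = NULL,
                                        correct = TRUE)$p.value)
  }
  structure(
    list(variable = variable,
         n = c(impaired = length(xi), control = length(xc)),
         mean = c(impaired = mean(xi), control = mean(xc)),
         sd = c(impaired = stats::sd(xi), control = stats::sd(xc)),
         min = c(impaired = min(xi), control = min(xc)),
         max = c(impaired = max(xi), control = max(xc)),
         test_used = test_used, p_value = p,
         hedges_g = es$g, cohen_d = es$d,
         shapiro_p = sw,
         degenerate = is.na(es$g)),
    class = "group_comparison")
}

shapiro_p <- function(v) {
  if (length(v) < 3L || length(unique(v)) < 3L) return(0)  # treat as non-normal
  if (length(v) > 5000L) v <- v[seq_len(5000L)]
  stats::shapiro.test(v)$p.value
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: impaired %.3g +/- %.3g (n=%d) vs control %.3g +/- %.3g (n=%d)\n  %s p = %.4g, Hedges g = %.3g\n",
    x$variable, x$mean[["impaired"]], x$sd[["impaired"]],
    x$n[["impaired"]], x$mean[["control"]], x$sd[["control"]],
    x$n[["control"]], x$test_used, x$p_value, x$hedges_g))
  invisible(x)
}

#' Correlate two variables with a normality-gated method
#'
#' Pearson when both variables pass Shapiro-Wilk at `alpha_normality`,
#' Spearman otherwise (unless forced). Two-sided p; pairwise-complete
#' observations.
#'
#' @param x,y Numeric vectors of equal length.
#' @param force_method `NULL`, `"pearson"`, or `"spearman"`.
#' @param alpha_normality Shapiro-Wilk significance gate.
#' @param x_name,y_name Labels carried into the result.
#' @return An object of class `correlation_result`: `method`, `r`, `p`,
#'   `n`, labels, and the per-variable Shapiro p-values. Constant input
#'   gives `r = NA` with a warning.
#' @export
correlate <- function(x, y, force_method = NULL, alpha_normality = 0.05,
                      x_name = deparse(substitute(x)),
                      y_name = deparse(substitute(y))) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  sw <- c(x = shapiro_p(x), y = shapiro_p(y))
  method <- if (!is.null(force_method)) {
    match.arg(force_method, c("pearson", "spearman"))
  } else if (all(sw > alpha_normality)) "pearson" else "spearman"
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant variable; correlation undefined")
    res <- list(r = NA_real_, p = NA_real_)
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                           alternative = "two.sided"))
    res <- list(r = unname(ct$estimate), p = ct$p.value)
  }
  structure(
    list(x_name = x_name, y_name = y_name, method = method,
         r = res$r, p = res$p, n = length(x), shapiro_p = sw),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s ~ %s: %s r = %.3f, p = %.4g (n=%d)\n",
              x$y_name, x$x_name, x$method, x$r, x$p, x$n))
  invisible(x)
}

#' Two-way single-measure intraclass correlation
#'
#' ICC from the two-way mean squares of a complete subjects-by-raters
#' layout (McGraw-Wong conventions):
#' * `consistency` — ICC(C,1) `= (MSR - MSE) / (MSR + (k - 1) MSE)`;
#'   insensitive to systematic rater offsets;
#' * `absolute_agreement` — ICC(A,1) `= (MSR - MSE) / (MSR + (k - 1) MSE
#'   + (k / n) (MSC - MSE))`; penalizes them.
#'
#' @param ratings Numeric matrix, subjects in rows, raters (k >= 2) in
#'   columns; no missing cells.
#' @param mode `"absolute_agreement"` or `"consistency"`.
#' @return An object of class `icc_result`: `mode`, `icc`, `n`, `k`, and
#'   the mean squares.
#' @export
icc <- function(ratings, mode = c("absolute_agreement", "consistency")) {
  mode <- match.arg(mode)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ICC requires a complete layout (no missing cells)")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  grand <- mean(ratings)
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  value <- if (mode == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  structure(list(mode = mode, icc = value, n = n, k = k,
                 ms = c(MSR = msr, MSC = msc, MSE = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s single-measure ICC = %.4f (n=%d, k=%d)\n",
              x$mode, x$icc, x$n, x$k))
  invisible(x)
}
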