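# Assembly of the cohort result tables: demographics (table 1), OCTA
# metric comparisons (table 2), MoCA correlations (table 3), and the
# supplementary structural/secondary comparisons (table S1).

TABLE1_VARS <- c(age = "Age (years)",
                 education_years = "Education (years)",
                 iop = "IOP (mmHg)",
                 test_imaging_interval_years =
                   "Time lapse between cognitive and imaging visits (years)",
                 moca = "MoCA (total = 30)",
                 cdr = "CDR",
                 craft_imm = "Craft Story immediate (total = 25)",
                 craft_del = "Craft Story delayed (total = 25)",
                 ravlt_del = "RAVLT delayed (total = 15)")

TABLE2_VARS <- c(scp_vd = "Parafoveal SCP VD (%)",
                 scp_vld = "Parafoveal SCP VLD (%)",
                 scp_afi = "Parafoveal SCP AFI",
                 rpc_vd_global = "Peripapillary RPC VD global (%)",
                 rpc_vd_superior = "Peripapillary RPC VD superior (%)",
                 rpc_vd_capillary = "Peripapillary RPC VD capillary (%)",
                 rpc_vld = "Peripapillary RPC VLD (%)",
                 svc_vd = "Peripapillary SVC VD (%)",
                 svc_vld = "Peripapillary SVC VLD (%)")

TABLE3_VARS <- c(scp_vd = "Parafoveal SCP VD",
                 scp_vld = "Parafoveal SCP VLD",
                 scp_afi = "Parafoveal SCP AFI",
                 rpc_vd_global = "Peripapillary RPC VD",
                 rpc_vld = "Peripapillary RPC VLD",
                 svc_vd = "Peripapillary SVC VD",
                 svc_vld = "Peripapillary SVC VLD")

TABLES1_VARS <- c(wr_vd = "Parafoveal whole-retina VD (%)",
                  dcp_vd = "Parafoveal DCP VD (%)",
                  faz_area_mm2 = "FAZ area (mm^2)",
                  rnfl_um = "Peripapillary RNFL thickness (um)")

#' Reproduce the cohort analysis tables
#'
#' Runs the full statistical battery over a cohort table: pooled
#' impaired (aMCI + eAD) vs control comparisons of the demographic and
#' cognitive variables (table 1), of the nine OCTA metrics (table 2), and
#' of the supplementary variables (table S1), plus Pearson/Spearman
#' correlations between MoCA and the seven OCTA parameters over the
#' entire cohort (table 3). Missing values are dropped listwise per
#' variable with n reported per row; no multiple-testing correction is
#' applied.
#'
#' @param cohort A `cohort_table` with one row per participant (apply
#'   [select_eye()] first if both eyes are present) and at least 2
#'   participants per group.
#' @param force_test `NULL`, `"student"`, or `"mann_whitney"`; either a
#'   single value for all rows or a named vector keyed by variable.
#' @param force_corr `NULL`, `"pearson"`, or `"spearman"`, same keying.
#' @param alpha_normality Shapiro-Wilk gate for test/method choice.
#' @return List of data frames `table1`, `table1_counts`, `table2`,
#'   `table3`, `tableS1`, and `diagnostics` (per-variable normality
#'   p-values and the test actually chosen).
#' @export
reproduce_tables <- function(cohort, force_test = NULL, force_corr = NULL,
                             alpha_normality = 0.05) {
  stopifnot(inherits(cohort, "data.frame"))
  if (anyDuplicated(cohort$id)) {
    stop("cohort has multiple rows per participant; run select_eye() first")
  }
  imp <- is_impaired(cohort)
  if (sum(imp) < 2L || sum(!imp) < 2L) {
    stop("need at least 2 participants per group")
  }
  pick_force <- function(force, var) {
    if (is.null(force)) return(NULL)
    if (length(force) == 1L && is.null(names(force))) return(force[[1L]])
    if (var %in% names(force)) return(force[[var]])
    NULL
  }

  comparison_table <- function(vars) {
    rows <- list()
    diags <- list()
    for (var in names(vars)) {
      vi <- cohort[[var]][imp]
      vc <- cohort[[var]][!imp]
      if (sum(!is.na(vi)) < 2L || sum(!is.na(vc)) < 2L) {
        rows[[var]] <- data.frame(
          variable = vars[[var]], n_impaired = sum(!is.na(vi)),
          n_control = sum(!is.na(vc)), mean_impaired = NA_real_,
          sd_impaired = NA_real_, min_impaired = NA_real_,
          max_impaired = NA_real_, mean_control = NA_real_,
          sd_control = NA_real_, min_control = NA_real_,
          max_control = NA_real_, test = NA_character_, p = NA_real_,
          hedges_g = NA_real_, cohen_d = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      cmp <- compare_groups(vi, vc, force_test = pick_force(force_test, var),
                            alpha_normality = alpha_normality,
                            variable = vars[[var]])
      rows[[var]] <- data.frame(
        variable = vars[[var]],
        n_impaired = cmp$n[["impaired"]], n_control = cmp$n[["control"]],
        mean_impaired = cmp$mean[["impaired"]],
        sd_impaired = cmp$sd[["impaired"]],
        min_impaired = cmp$min[["impaired"]],
        max_impaired = cmp$max[["impaired"]],
        mean_control = cmp$mean[["control"]],
        sd_control = cmp$sd[["control"]],
        min_control = cmp$min[["control"]],
        max_control = cmp$max[["control"]],
        test = cmp$test_used, p = cmp$p_value,
        hedges_g = cmp$hedges_g, cohen_d = cmp$cohen_d,
        stringsAsFactors = FALSE)
      diags[[var]] <- data.frame(
        variable = var, shapiro_p_impaired = cmp$shapiro_p[["impaired"]],
        shapiro_p_control = cmp$shapiro_p[["control"]],
        test = cmp$test_used, stringsAsFactors = FALSE)
    }
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         diag = if (length(diags))
           do.call(rbind, c(diags, list(make.row.names = FALSE)))
         else NULL)
  }

  t1 <- comparison_table(TABLE1_VARS)
  t2 <- comparison_table(TABLE2_VARS)
  ts1 <- comparison_table(TABLES1_VARS)

  counts <- do.call(rbind, lapply(c("gender", "race"), function(var) {
    tab <- table(factor(cohort[[var]]), ifelse(imp, "impaired", "control"))
    data.frame(variable = var, level = rownames(tab),
               n_impaired = as.integer(tab[, "impaired"]),
               n_control = as.integer(tab[, "control"]),
               stringsAsFactors = FALSE)
  }))

  t3_rows <- list()
  t3_diag <- list()
  for (var in names(TABLE3_VARS)) {
    res <- tryCatch(
      correlate(cohort$moca, cohort[[var]],
                force_method = pick_force(force_corr, var),
                alpha_normality = alpha_normality,
                x_name = "moca", y_name = var),
      error = function(e) NULL)
    t3_rows[[var]] <- data.frame(
      variable = TABLE3_VARS[[var]],
      method = if (is.null(res)) NA_character_ else res$method,
      r = if (is.null(res)) NA_real_ else res$r,
      p = if (is.null(res)) NA_real_ else res$p,
      n = if (is.null(res)) sum(!is.na(cohort$moca) & !is.na(cohort[[var]]))
          else res$n,
      stringsAsFactors = FALSE)
    if (!is.null(res)) {
      t3_diag[[var]] <- data.frame(
        variable = var, shapiro_p_moca = res$shapiro_p[["x"]],
        shapiro_p_metric = res$shapiro_p[["y"]], method = res$method,
        stringsAsFactors = FALSE)
    }
  }

  list(table1 = t1$table,
       table1_counts = counts,
       table2 = t2$table,
       table3 = do.call(rbind, c(t3_rows, list(make.row.names = FALSE))),
       tableS1 = ts1$table,
       diagnostics = list(
         table1 = t1$diag, table2 = t2$diag, tableS1 = ts1$diag,
         table3 = if (length(t3_diag))
           do.call(rbind, c(t3_diag, list(make.row.names = FALSE)))
         else NULL))
}

#' Write the result tables to CSV files
#'
#' @param tables The list returned by [reproduce_tables()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("table1", "table1_counts", "table2", "table3", "tableS1")) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  diag <- tables$diagnostics
  diag_flat <- do.call(rbind, lapply(names(diag), function(nm) {
    d <- diag[[nm]]
    if (is.null(d)) return(NULL)
    sw <- grep("shapiro", names(d), value = TRUE)
    choice_col <- intersect(c("test", "method"), names(d))[1]
    data.frame(table = nm, variable = d$variable,
               test_or_method = d[[choice_col]],
               shapiro_p_1 = d[[sw[1]]], shapiro_p_2 = d[[sw[2]]],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(diag_flat, file.path(dir, "diagnostics.csv"),
                   row.names = FALSE)
  invisible(dir)
}
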