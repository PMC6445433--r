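# Cohort table I/O.
#
# One row per participant-eye; columns cover demographics, cognitive
# scores, per-scan quality indices, and the per-eye OCTA metrics. CSV
# (UTF-8, header row) is the native format; XLSX (first sheet) is read
# via readxl when available.

#' Canonical cohort columns
#'
#' @return Character vectors naming the required identifier/clinical
#'   columns and the metric columns of a cohort table.
#' @export
cohort_columns <- function() {
  list(
    required = c("id", "group", "age", "gender", "race", "eye",
                 "sq_macula", "ssi_macula", "sq_disc", "ssi_disc",
                 "moca", "cdr", "craft_imm", "craft_del", "ravlt_del",
                 "iop", "education_years", "test_imaging_interval_years"),
    metrics = c("scp_vd", "scp_vld", "scp_afi",
                "rpc_vd_global", "rpc_vd_superior", "rpc_vd_capillary",
                "rpc_vld", "svc_vd", "svc_vld",
                "wr_vd", "dcp_vd", "faz_area_mm2", "rnfl_um")
  )
}

#' Read a cohort table
#'
#' Reads a per-participant-eye cohort table from CSV or XLSX, validates
#' the schema, and types the columns. Missing metric cells are preserved
#' as `NA`, never zero-filled.
#'
#' @param path `.csv` or `.xlsx` file.
#' @param column_map Optional named character vector mapping canonical
#'   column names to the file's column names, for tables using different
#'   headers (e.g. `c(moca = "MoCA_total")`).
#' @return A data frame of class `cohort_table`, one row per
#'   participant-eye.
#' @export
read_cohort_table <- function(path, column_map = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "")),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading XLSX requires the readxl package")
      }
      as.data.frame(readxl::read_excel(path, sheet = 1L),
                    stringsAsFactors = FALSE)
    },
    stop("unsupported cohort table format '", ext, "' for ", path)
  )
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      hit <- match(column_map[[canonical]], names(raw))
      if (!is.na(hit)) names(raw)[hit] <- canonical
    }
  }
  as_cohort_table(raw)
}

#' Validate and type a data frame as a cohort table
#'
#' @param df Data frame with the canonical columns (see
#'   [cohort_columns()]). Metric columns are optional but recommended;
#'   missing ones are added as all-`NA`.
#' @return A `cohort_table`.
#' @export
as_cohort_table <- function(df) {
  cols <- cohort_columns()
  missing_req <- setdiff(cols$required, names(df))
  if (length(missing_req)) {
    stop("cohort table missing required column(s): ",
         paste(missing_req, collapse = ", "))
  }
  if (anyDuplicated(df[, c("id", "eye")])) {
    dup <- df[duplicated(df[, c("id", "eye")]), c("id", "eye")]
    stop("duplicate (id, eye) rows: ",
         paste(paste(dup$id, dup$eye), collapse = "; "))
  }
  bad_group <- setdiff(unique(df$group), c("aMCI", "eAD", "control"))
  if (length(bad_group)) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         " (expected aMCI, eAD, control)")
  }
  bad_eye <- setdiff(unique(df$eye), c("OD", "OS"))
  if (length(bad_eye)) {
    stop("unknown eye label(s): ", paste(bad_eye, collapse = ", "),
         " (expected OD, OS)")
  }
  numeric_cols <- setdiff(c(cols$required, cols$metrics),
                          c("id", "group", "gender", "race", "eye"))
  for (cc in cols$metrics) {
    if (!cc %in% names(df)) df[[cc]] <- NA_real_
  }
  for (cc in numeric_cols) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  df$id <- as.character(df$id)
  range_check <- list(moca = c(0, 30), craft_imm = c(0, 25),
                      craft_del = c(0, 25), ravlt_del = c(0, 15))
  for (cc in names(range_check)) {
    v <- df[[cc]]
    out <- !is.na(v) & (v < range_check[[cc]][1] | v > range_check[[cc]][2])
    if (any(out)) {
      stop(cc, " outside valid range [", range_check[[cc]][1], ", ",
           range_check[[cc]][2], "] for id(s): ",
           paste(df$id[out], collapse = ", "))
    }
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table to CSV
#'
#' Round-trips with [read_cohort_table()]: read -> write -> read is the
#' identity on records.
#'
#' @param cohort A `cohort_table` (or compatible data frame).
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Pooled impairment indicator
#'
#' aMCI and eAD participants form one "impaired" group for all
#' comparisons.
#'
#' @param cohort A `cohort_table`.
#' @return Logical vector, `TRUE` for aMCI/eAD rows.
#' @export
is_impaired <- function(cohort) {
  cohort$group %in% c("aMCI", "eAD")
}
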