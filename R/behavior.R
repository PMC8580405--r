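# Behavioral cohort table: loading, summary statistics, percentage change,
# and responder classification.

cohort_schema <- function() {
  c("id", "group", "lesion_age_mo",
    "hrp_black_pre", "hrp_gray_pre", "hrp_white_pre",
    "hrp_black_post", "hrp_gray_post", "hrp_white_post",
    "hrp_black_fu", "hrp_gray_fu", "hrp_white_fu",
    "rt_gray_pre", "rt_white_pre", "rt_gray_post", "rt_white_post",
    "rt_gray_fu", "rt_white_fu",
    "fov_pre", "fov_post", "fov_fu", "gender", "age")
}

group_codes <- function() c("0" = "Sham", "1" = "AC", "2" = "ACDC")

#' Path to the packaged 24-patient behavioral table
#'
#' The per-patient visual-field table of the hemianopia cohort: high-resolution
#' perimetry (HRP) black/gray/white stimulus counts, gray/white reaction times
#' (s), and perimetric visual-field sensitivity (FOV, dB) at the three time
#' points (Pre, Post, FU), plus group, lesion age, gender, and age.
#'
#' @return File path of the packaged CSV.
#' @export
patient_table_path <- function() {
  system.file("extdata", "table1_patients.csv", package = "fcnet",
              mustWork = TRUE)
}

#' Load a behavioral cohort table
#'
#' Reads and validates a CSV in the patient-table schema. Group codes 0/1/2
#' are decoded to Sham/AC/ACDC (kept alongside the numeric code). Rows with a
#' missing time point or a malformed group code are rejected with the row
#' identified.
#'
#' @param path CSV path; defaults to the packaged 24-patient table.
#' @return Data frame of class `cohort_table` with all schema columns plus
#'   `group_label` (factor Sham/AC/ACDC).
#' @examples
#' tab <- load_cohort()
#' table(tab$group_label)
#' @export
load_cohort <- function(path = patient_table_path()) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_schema(), names(tab))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  tab <- tab[, cohort_schema()]
  bad_group <- !as.character(tab$group) %in% names(group_codes())
  if (any(bad_group))
    stop("malformed group code in row(s) id = ",
         paste(tab$id[bad_group], collapse = ", "))
  num_cols <- setdiff(cohort_schema(), c("id", "gender"))
  for (cl in num_cols) {
    if (anyNA(tab[[cl]]))
      stop(sprintf("missing value in column '%s' for row(s) id = %s", cl,
                   paste(tab$id[is.na(tab[[cl]])], collapse = ", ")))
  }
  if (any(tab[, grep("^hrp_", names(tab))] < 0)) stop("HRP counts must be >= 0")
  if (any(tab[, grep("^rt_", names(tab))] <= 0)) stop("reaction times must be > 0")
  tab$group_label <- factor(group_codes()[as.character(tab$group)],
                            levels = c("Sham", "AC", "ACDC"))
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

# Truncation (not rounding) to two decimals, the display convention of the
# printed cohort table: 25.4166 -> 25.41, 57.375 -> 57.37.
truncate2 <- function(x) trunc(x * 100) / 100

#' Per-column mean and SD of a cohort table
#'
#' Arithmetic mean and sample SD of every numeric column, with display values
#' truncated to two decimals (the printed table's convention).
#'
#' @param records A `cohort_table` (or compatible data frame) with >= 2 rows.
#' @return Data frame with columns `column`, `mean`, `sd`, `mean_display`,
#'   `sd_display`.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) < 2) stop("need at least 2 records to summarize")
  num_cols <- setdiff(cohort_schema(), c("id", "group", "gender"))
  data.frame(
    column = num_cols,
    mean = vapply(num_cols, function(cl) mean(records[[cl]]), numeric(1)),
    sd = vapply(num_cols, function(cl) sd(records[[cl]]), numeric(1)),
    mean_display = vapply(num_cols, function(cl) truncate2(mean(records[[cl]])), numeric(1)),
    sd_display = vapply(num_cols, function(cl) truncate2(sd(records[[cl]])), numeric(1)),
    row.names = NULL)
}

measure_column <- function(records, measure, timepoint) {
  tp <- tolower(timepoint)
  if (!tp %in% c("pre", "post", "fu")) stop("timepoint must be pre, post, or fu")
  col <- paste0(tolower(measure), "_", tp)
  if (!col %in% names(records)) stop("no such measure column: ", col)
  records[[col]]
}

#' Per-patient percentage change of a measure
#'
#' `100 * (later - baseline) / baseline`. A zero baseline is an error naming
#' the patient (never silently dropped).
#'
#' @param records A `cohort_table`.
#' @param measure Measure stem, e.g. `"fov"`, `"rt_gray"`, `"hrp_black"`.
#' @param later,baseline Time points (`"post"`/`"fu"` vs `"pre"`).
#' @return Data frame with columns `id`, `baseline`, `later`, `pct_change`.
#' @export
percentage_change <- function(records, measure = "fov", later = "post",
                              baseline = "pre") {
  b <- measure_column(records, measure, baseline)
  l <- measure_column(records, measure, later)
  if (any(b == 0))
    stop("zero baseline for patient id = ",
         paste(records$id[b == 0], collapse = ", "),
         ": percentage change undefined")
  data.frame(id = records$id, baseline = b, later = l,
             pct_change = 100 * (l - b) / b)
}

#' Classify responders from visual-field change
#'
#' A patient is a responder when the percentage change of FOV from baseline is
#' strictly above zero. The comparison time point defaults to Post (the
#' alternative FU criterion is one parameter away).
#'
#' @param records A `cohort_table`.
#' @param timepoint Later time point of the FOV change. Default `"post"`.
#' @return Data frame of class `responder_labels` with columns `id`,
#'   `pct_change`, `label` (factor responder/non-responder); attributes
#'   `n_responders` and `n_nonresponders`.
#' @examples
#' labs <- classify_responders(load_cohort())
#' attr(labs, "n_responders")      # 10
#' attr(labs, "n_nonresponders")   # 14
#' @export
classify_responders <- function(records, timepoint = "post") {
  pc <- percentage_change(records, "fov", later = timepoint, baseline = "pre")
  label <- factor(ifelse(pc$pct_change > 0, "responder", "non-responder"),
                  levels = c("responder", "non-responder"))
  out <- data.frame(id = pc$id, pct_change = pc$pct_change, label = label)
  structure(out, n_responders = sum(label == "responder"),
            n_nonresponders = sum(label == "non-responder"),
            class = c("responder_labels", "data.frame"))
}
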