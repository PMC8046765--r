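#' Collapse ICD-9 codes to their three-digit category
#'
#' Numeric codes keep the (zero-padded) digits before the decimal
#' (`"401.9"` to `"401"`), V codes keep `"V"` plus two digits
#' (`"V65.4"` to `"V65"`), E codes keep `"E"` plus three digits
#' (`"E849.0"` to `"E849"`). Input is case-normalised and trimmed.
#' Unparseable codes map to `NA`.
#'
#' @param codes character vector of raw ICD-9 code strings.
#' @return character vector of the same length; `NA` where unparseable.
#' @export
collapse_icd9 <- function(codes) {
  x <- toupper(trimws(as.character(codes)))
  out <- rep(NA_character_, length(x))
  num <- grepl("^[0-9]{1,3}(\\.[0-9]*)?$", x)
  if (any(num))
    out[num] <- sprintf("%03d", as.integer(sub("\\..*$", "", x[num])))
  v <- grepl("^V[0-9]{2}(\\.[0-9]*)?$", x)
  out[v] <- substr(x[v], 1L, 3L)
  e <- grepl("^E[0-9]{3}(\\.[0-9]*)?$", x)
  out[e] <- substr(x[e], 1L, 4L)
  out
}

#' Collapse an event table to three-digit codes, dropping unparseable rows
#'
#' Adds a `code3` column via [collapse_icd9()]. Rows whose code cannot be
#' parsed are dropped with a warning and counted.
#'
#' @param events data frame with at least `icd9_code`.
#' @return list with `events` (with `code3` column) and `n_rejected`.
#' @export
collapse_events <- function(events) {
  stopifnot(is.data.frame(events), "icd9_code" %in% names(events))
  code3 <- collapse_icd9(events$icd9_code)
  bad <- is.na(code3)
  if (any(bad))
    warning(sprintf("%d event(s) with unparseable ICD-9 codes dropped", sum(bad)))
  events <- events[!bad, , drop = FALSE]
  events$code3 <- code3[!bad]
  rownames(events) <- NULL
  list(events = events, n_rejected = sum(bad))
}

#' Restrict a cohort to patients with sufficient follow-up
#'
#' Retains exactly the patients whose span between earliest and latest
#' encounter of any kind (diagnostic or V code) is at least `min_years`,
#' with years computed as days / 365.25.
#'
#' @param events event data frame with `patient_id` and `event_date`.
#' @param min_years minimum follow-up in years (default 5).
#' @return list with `events` (retained patients' rows, all of them) and
#'   `patients` (retained patient ids, sorted).
#' @export
filter_followup <- function(events, min_years = 5) {
  stopifnot(is.data.frame(events))
  if (!nrow(events))
    return(list(events = events, patients = character()))
  dt <- as.data.table(events)
  span <- dt[, .(yrs = as.numeric(max(event_date) - min(event_date)) / 365.25),
             by = patient_id]
  keep <- sort(span[yrs >= min_years, patient_id])
  list(events = events[events$patient_id %in% keep, , drop = FALSE],
       patients = keep)
}

#' Extract each patient's first occurrence of each three-digit code
#'
#' Per `(patient_id, code3)` the minimum `event_date`; repeat encounters are
#' ignored. Same-day first occurrences of different codes are preserved as
#' equal dates (they are handled by the relative-risk classification).
#' The result is independent of the input row order.
#'
#' @param events event data frame with `patient_id`, `event_date` and a
#'   `code3` column (see [collapse_events()]).
#' @return data frame `(patient_id, code3, first_date)`, sorted.
#' @export
first_occurrences <- function(events) {
  stopifnot(is.data.frame(events))
  if (!"code3" %in% names(events))
    stop("events must carry a code3 column; run collapse_events() first")
  if (!nrow(events))
    return(data.frame(patient_id = character(), code3 = character(),
                      first_date = as.Date(character())))
  dt <- as.data.table(events)
  fo <- dt[, .(first_date = min(event_date)), by = .(patient_id, code3)]
  setorder(fo, patient_id, code3)
  as.data.frame(fo)
}

#' Network exclusions for three-digit codes
#'
#' Removes the code groups excluded from the comorbidity network:
#' all V codes (non-diagnostic supplementary classification), complications
#' of pregnancy/childbirth/puerperium (630-679), symptoms/signs/ill-defined
#' conditions (780-799), and unclassified complications of surgical and
#' medical care (996-999). E codes are retained (they are not on the
#' exclusion list; in practice they virtually never survive the prevalence
#' filter).
#'
#' @param codes3 character vector of three-digit codes.
#' @return the retained codes, in input order.
#' @export
network_exclusions <- function(codes3) {
  codes3 <- as.character(codes3)
  isv <- startsWith(codes3, "V")
  num <- suppressWarnings(as.integer(codes3))
  excl <- !is.na(num) & ((num >= 630L & num <= 679L) |
                           (num >= 780L & num <= 799L) |
                           (num >= 996L & num <= 999L))
  codes3[!isv & !excl]
}

#' Prevalence filter for network codes
#'
#' Retains code `c` iff the number of patients with a first occurrence of `c`
#' divided by `cohort_size` is at least `threshold`.
#'
#' @param first_occ first-occurrence table from [first_occurrences()].
#' @param cohort_size number of patients in the analysis cohort.
#' @param threshold prevalence fraction in `(0, 1]` (default 0.10).
#' @return character vector of retained codes, sorted.
#' @export
prevalence_filter <- function(first_occ, cohort_size, threshold = 0.10) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (cohort_size <= 0) stop("cohort_size must be positive")
  counts <- table(first_occ$code3)
  sort(names(counts)[as.vector(counts) / cohort_size >= threshold])
}

#' Descriptive summary of a retained cohort
#'
#' Median/IQR of age at first and last diagnosis (when birth dates are
#' present), follow-up years (median/IQR/range), diagnosis rows per patient,
#' distinct full-code diagnoses and distinct three-digit diagnoses per
#' patient. Ages and follow-up use days / 365.25.
#'
#' @param events event data frame with `patient_id`, `event_date`,
#'   `icd9_code`, optionally `birth_date` and `code3`.
#' @return list of class `"cohort_summary"`.
#' @export
cohort_summary <- function(events) {
  stopifnot(is.data.frame(events), nrow(events) > 0)
  dt <- as.data.table(events)
  if (!"code3" %in% names(dt)) dt[, code3 := collapse_icd9(icd9_code)]
  per <- dt[, .(
    first = min(event_date), last = max(event_date),
    n_dx = .N,
    n_full = length(unique(icd9_code)),
    n_code3 = length(unique(code3))
  ), by = patient_id]
  med_iqr <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    c(median = q[2], q1 = q[1], q3 = q[3])
  }
  fy <- as.numeric(per$last - per$first) / 365.25
  out <- list(
    n_patients = nrow(per),
    followup_years = c(med_iqr(fy), min = min(fy), max = max(fy)),
    dx_per_patient = med_iqr(per$n_dx),
    distinct_full_codes = med_iqr(per$n_full),
    distinct_code3 = med_iqr(per$n_code3)
  )
  if ("birth_date" %in% names(dt) && !all(is.na(dt$birth_date))) {
    bd <- dt[, .(birth = birth_date[1]), by = patient_id]
    per <- merge(per, bd, by = "patient_id")
    ok <- !is.na(per$birth)
    out$age_first <- med_iqr(as.numeric(per$first[ok] - per$birth[ok]) / 365.25)
    out$age_last <- med_iqr(as.numeric(per$last[ok] - per$birth[ok]) / 365.25)
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$n_patients))
  fmt <- function(v) sprintf("%.1f (%.1f-%.1f)", v[["median"]], v[["q1"]], v[["q3"]])
  if (!is.null(x$age_first))
    cat("  Age at first diagnosis (years):", fmt(x$age_first), "\n",
        " Age at last diagnosis (years): ", fmt(x$age_last), "\n", sep = "")
  cat(sprintf("  Years of follow-up: %s [range %.1f-%.1f]\n",
              fmt(x$followup_years),
              x$followup_years[["min"]], x$followup_years[["max"]]))
  cat("  Diagnoses per patient:", fmt(x$dx_per_patient), "\n")
  cat("  Distinct full-code diagnoses:", fmt(x$distinct_full_codes), "\n")
  cat("  Distinct 3-digit diagnoses:", fmt(x$distinct_code3), "\n")
  invisible(x)
}

#' Percentage of cohort, one decimal
#'
#' The rounding convention used by the prevalence table:
#' `round(100 * n / cohort_size, 1)`.
#'
#' @param n patient count(s).
#' @param cohort_size cohort size.
#' @return numeric percentage(s) with one decimal.
#' @export
pct_of_cohort <- function(n, cohort_size) {
  stopifnot(cohort_size > 0)
  round(100 * n / cohort_size, 1)
}

#' Prevalence table of three-digit codes
#'
#' Per three-digit code (V codes included; network exclusions apply only to
#' the network itself): total encounter rows, distinct patients, and percent
#' of the cohort to one decimal. Sorted by patient count descending, ties
#' broken by code.
#'
#' @param events event data frame with a `code3` column.
#' @param cohort_size denominator for the percentage; defaults to the number
#'   of distinct patients in `events`.
#' @param labels optional named character vector of code descriptions.
#' @return data frame `(code3, label, n_encounters, n_patients, pct_patients)`.
#' @export
prevalence_table <- function(events, cohort_size = NULL, labels = NULL) {
  stopifnot(is.data.frame(events))
  if (!"code3" %in% names(events))
    stop("events must carry a code3 column; run collapse_events() first")
  if (is.null(cohort_size)) cohort_size <- length(unique(events$patient_id))
  dt <- as.data.table(events)
  tab <- dt[, .(n_encounters = .N,
                n_patients = length(unique(patient_id))), by = code3]
  setorder(tab, -n_patients, code3)
  tab[, pct_patients := pct_of_cohort(n_patients, cohort_size)]
  out <- as.data.frame(tab)
  out$label <- if (is.null(labels)) out$code3 else {
    lab <- unname(labels[out$code3]); ifelse(is.na(lab), out$code3, lab)
  }
  out[, c("code3", "label", "n_encounters", "n_patients", "pct_patients")]
}

#' Read an optional code-label map
#'
#' Two-column tab-separated file (`code3`, `label`), no header required
#' (a header line starting with "code" is skipped).
#'
#' @param path file path.
#' @return named character vector mapping code to label.
#' @export
read_code_labels <- function(path) {
  x <- read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                  col.names = c("code3", "label"),
                  colClasses = "character", quote = "")
  if (nrow(x) && grepl("^code", x$code3[1], ignore.case = TRUE)) x <- x[-1, ]
  setNames(x$label, x$code3)
}
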