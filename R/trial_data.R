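# Ingestion, validation, normalisation and summary of arm-level aggregate
# trial data. The canonical interchange format is a CSV with one row per
# trial x arm x visit and wide covariate columns.

.csv_columns <- c(
  "trial_id", "arm_id", "drug", "dose_amount", "dose_unit", "regimen_tag",
  "endpoint", "time_weeks", "n_total", "n_response",
  "age", "weight", "male_pct", "duration", "prior_tnf_pct", "steroid_pct",
  "baseline_activity"
)

#' Load an arm-level aggregate trial dataset
#'
#' Reads the canonical CSV schema (one row per trial x arm x visit; see
#' Details), validates it, and splits it into an observation table and an
#' arm-descriptor table. Only rows for the requested endpoint are kept;
#' arms left without observations are dropped with a warning.
#'
#' Required columns: `trial_id, arm_id, drug, dose_amount, dose_unit
#' (mg | mg_per_kg), regimen_tag, endpoint, time_weeks, n_total,
#' n_response, age, weight, male_pct, duration, prior_tnf_pct,
#' steroid_pct, baseline_activity`. Empty covariate cells are missing
#' values.
#'
#' @param path CSV file path.
#' @param endpoint one of [uc_endpoints].
#' @return a list with elements `records` (data.frame: `trial_id`, `arm_id`,
#'   `endpoint`, `time`, `n_total`, `n_response`) and `arms` (one row per
#'   arm: identifiers, drug, dose, regimen and covariate columns).
#' @export
load_dataset <- function(path, endpoint = uc_endpoints) {
  endpoint <- match.arg(endpoint)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.csv_columns, names(raw))
  if (length(missing_cols))
    stop("malformed dataset: missing columns ",
         paste(missing_cols, collapse = ", "))
  for (j in c("dose_amount", "time_weeks", "n_total", "n_response",
              .uc_covariates)) {
    if (!is.numeric(raw[[j]])) {
      conv <- suppressWarnings(as.numeric(raw[[j]]))
      bad <- which(!is.na(raw[[j]]) & raw[[j]] != "" & is.na(conv))
      if (length(bad))
        stop("malformed dataset: non-numeric '", j, "' in row ", bad[1])
      raw[[j]] <- conv
    }
  }
  .validate_rows(raw)
  raw <- raw[raw$endpoint == endpoint, , drop = FALSE]
  if (!nrow(raw)) stop("no rows for endpoint '", endpoint, "'")

  records <- data.frame(
    trial_id = raw$trial_id, arm_id = raw$arm_id, endpoint = raw$endpoint,
    time = raw$time_weeks, n_total = raw$n_total,
    n_response = raw$n_response, stringsAsFactors = FALSE
  )
  key <- paste(records$trial_id, records$arm_id, records$endpoint,
               records$time)
  if (anyDuplicated(key))
    stop("duplicate observation for (trial, arm, endpoint, time): ",
         key[duplicated(key)][1])

  first <- !duplicated(paste(raw$trial_id, raw$arm_id))
  arms <- raw[first, c("trial_id", "arm_id", "drug", "dose_amount",
                       "dose_unit", "regimen_tag", .uc_covariates)]
  rownames(arms) <- NULL

  has_obs <- paste(arms$trial_id, arms$arm_id) %in%
    paste(records$trial_id, records$arm_id)
  if (any(!has_obs)) {
    warning("dropping ", sum(!has_obs), " arm(s) without observations")
    arms <- arms[has_obs, , drop = FALSE]
  }
  list(records = records, arms = arms)
}

.validate_rows <- function(raw) {
  chk <- function(cond, msg) {
    bad <- which(cond)
    if (length(bad)) stop("invalid dataset row ", bad[1], ": ", msg)
  }
  chk(is.na(raw$n_total) | raw$n_total < 1, "n_total must be >= 1")
  chk(is.na(raw$n_response) | raw$n_response < 0, "n_response must be >= 0")
  chk(raw$n_response > raw$n_total, "n_response exceeds n_total")
  chk(is.na(raw$time_weeks) | raw$time_weeks < 0, "time_weeks must be >= 0")
  chk(is.na(raw$dose_amount) | raw$dose_amount < 0, "dose_amount must be >= 0")
  chk(!(raw$endpoint %in% uc_endpoints), "unknown endpoint")
  chk(!(raw$drug %in% uc_drugs), "unknown drug")
  chk(raw$drug == "placebo" & raw$dose_amount != 0,
      "placebo arms must have dose_amount = 0")
  for (cv in c("male_pct", "prior_tnf_pct", "steroid_pct"))
    chk(!is.na(raw[[cv]]) & (raw[[cv]] < 0 | raw[[cv]] > 100),
        paste(cv, "must be within [0, 100]"))
  for (cv in c("age", "weight", "duration"))
    chk(!is.na(raw[[cv]]) & raw[[cv]] <= 0, paste(cv, "must be positive"))
  invisible(TRUE)
}

#' Write a dataset back to the canonical CSV schema
#'
#' Inverse of [load_dataset()]: joins the observation and arm tables and
#' writes one row per trial x arm x visit.
#'
#' @param records,arms as returned by [load_dataset()] or
#'   [generate_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, arms, path) {
  merged <- merge(records, arms, by = c("trial_id", "arm_id"), sort = FALSE)
  out <- data.frame(
    trial_id = merged$trial_id, arm_id = merged$arm_id, drug = merged$drug,
    dose_amount = merged$dose_amount, dose_unit = merged$dose_unit,
    regimen_tag = merged$regimen_tag, endpoint = merged$endpoint,
    time_weeks = merged$time, n_total = merged$n_total,
    n_response = merged$n_response, stringsAsFactors = FALSE
  )
  for (cv in .uc_covariates) out[[cv]] <- merged[[cv]]
  ord <- order(out$trial_id, out$arm_id, out$time_weeks)
  utils::write.csv(out[ord, ], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Normalise weight-based doses to a fixed milligram amount
#'
#' Doses recorded in mg/kg are converted to mg for a reference body weight
#' (70 kg by default, the typical-patient assumption used to pool dose
#' regimens); fixed-mg doses are unchanged.
#'
#' @param arms arm table (one or more rows) with `dose_amount` and
#'   `dose_unit` columns.
#' @param reference_weight reference body weight in kg.
#' @return the arm table with all doses in mg (`dose_unit` set to `"mg"`).
#' @export
#' @examples
#' arm <- data.frame(trial_id = "t", arm_id = "a", drug = "ustekinumab",
#'                   dose_amount = 6, dose_unit = "mg_per_kg",
#'                   regimen_tag = "6mgkg")
#' normalize_dose(arm)$dose_amount  # 420
normalize_dose <- function(arms, reference_weight = 70) {
  if (any(is.na(arms$dose_amount) | arms$dose_amount < 0))
    stop("dose_amount must be non-negative")
  if (!all(arms$dose_unit %in% c("mg", "mg_per_kg")))
    stop("dose_unit must be 'mg' or 'mg_per_kg'")
  idx <- arms$dose_unit == "mg_per_kg"
  if (any(idx)) {
    arms$dose_amount[idx] <- arms$dose_amount[idx] * reference_weight
    arms$dose_unit[idx] <- "mg"
    message("normalised ", sum(idx), " mg/kg dose(s) at ",
            reference_weight, " kg reference weight")
  }
  arms
}

#' Mean-impute missing arm-level covariates
#'
#' Missing covariate values are replaced by the mean of the available
#' values across arms (unweighted by default, matching the source
#' procedure; optionally weighted by arm size). Imputed fields are flagged
#' in `imputed_<covariate>` columns. Idempotent.
#'
#' @param arms arm table.
#' @param records optional observation table; required when
#'   `patient_weighted = TRUE` to derive arm sizes.
#' @param patient_weighted use an arm-size-weighted mean instead of the
#'   unweighted mean.
#' @return the arm table with missing covariates filled and flag columns
#'   added.
#' @export
impute_covariates <- function(arms, records = NULL, patient_weighted = FALSE) {
  w <- NULL
  if (patient_weighted) {
    if (is.null(records))
      stop("patient_weighted imputation requires the records table")
    sizes <- records[!duplicated(paste(records$trial_id, records$arm_id)), ]
    w <- sizes$n_total[match(paste(arms$trial_id, arms$arm_id),
                             paste(sizes$trial_id, sizes$arm_id))]
  }
  for (cv in intersect(.uc_covariates, names(arms))) {
    flag_col <- paste0("imputed_", cv)
    if (!flag_col %in% names(arms)) arms[[flag_col]] <- FALSE
    miss <- is.na(arms[[cv]])
    if (!any(miss)) next
    avail <- !miss
    if (!any(avail))
      stop("covariate '", cv, "' is missing in all arms")
    m <- if (patient_weighted) {
      sum(arms[[cv]][avail] * w[avail]) / sum(w[avail])
    } else mean(arms[[cv]][avail])
    arms[[cv]][miss] <- m
    arms[[flag_col]][miss] <- TRUE
  }
  arms
}

#' Summarise a dataset by drug
#'
#' One row per drug with trial, patient and arm counts and the median
#' (min, max) of each covariate across arms, plus a `total` row; the
#' layout mirrors the usual baseline-characteristics table of an
#' aggregate-data meta-analysis.
#'
#' @param arms,records as returned by [load_dataset()].
#' @return a data.frame summary, one row per drug plus `total`.
#' @export
summarize_dataset <- function(arms, records) {
  if (!nrow(arms)) stop("empty dataset")
  sizes <- records[!duplicated(paste(records$trial_id, records$arm_id)), ]
  arm_n <- sizes$n_total[match(paste(arms$trial_id, arms$arm_id),
                               paste(sizes$trial_id, sizes$arm_id))]
  fmt_cov <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_character_)
    sprintf("%.1f (%.1f, %.1f)", stats::median(x), min(x), max(x))
  }
  one <- function(idx, label) {
    row <- data.frame(
      drug = label,
      trials = length(unique(arms$trial_id[idx])),
      patients = sum(arm_n[idx]),
      arms = sum(idx), stringsAsFactors = FALSE
    )
    for (cv in intersect(.uc_covariates, names(arms)))
      row[[cv]] <- fmt_cov(arms[[cv]][idx])
    row
  }
  drugs <- unique(arms$drug)
  drugs <- c(setdiff(sort(drugs), "placebo"),
             intersect("placebo", drugs))
  out <- do.call(rbind, lapply(drugs, function(d) one(arms$drug == d, d)))
  rbind(out, one(rep(TRUE, nrow(arms)), "total"))
}
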