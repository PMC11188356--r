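# Synthetic trial-database generator. The packaged design reproduces the
# marginal structure of the source meta-analytic database: 35 trials, 95
# arms (32 placebo), 15,585 patients, per-drug arm/patient counts and
# baseline-covariate medians and ranges.

# Per-drug margins: trial, patient and arm counts plus covariate
# median (lo, hi) triplets. Weight is unreported for golimumab,
# filgotinib and etrasimod. Baseline disease activity (full Mayo score)
# is not tabulated per drug in the source; a common 8.5 (6.5-10.5) is used.
.design_margins <- function() {
  tri <- function(m, lo, hi) c(m, lo, hi)
  rows <- list(
    infliximab   = list(7, 996,  10, tri(61.4, 42.0, 66.7), tri(39.8, 34.1, 42.4),
                        tri(70.0, 57.6, 80.0), tri(5.9, 3.7, 8.4),
                        tri(0.0, 0.0, 0.0),    tri(54.4, 43.5, 80.0)),
    adalimumab   = list(7, 2237, 10, tri(57.8, 56.0, 67.8), tri(40.5, 39.6, 44.4),
                        tri(75.4, 73.4, 76.8), tri(7.8, 6.4, 8.3),
                        tri(0.0, 0.0, 39.1),   tri(55.8, 36.3, 72.4)),
    golimumab    = list(1, 690,  3,  tri(55.6, 54.4, 60.7), tri(40.7, 40.0, 40.9),
                        NULL,                  tri(6.4, 6.4, 6.6),
                        tri(0.0, 0.0, 0.0),    tri(43.8, 42.9, 48.6)),
    vedolizumab  = list(3, 772,  3,  tri(60.8, 58.7, 67.1), tri(40.8, 40.1, 44.0),
                        tri(72.4, 58.6, 72.7), tri(7.3, 6.1, 8.6),
                        tri(42.2, 20.8, 50.0), tri(36.1, 30.8, 56.0)),
    etrolizumab  = list(5, 948,  6,  tri(59.0, 51.0, 68.0), tri(40.5, 40.0, 44.4),
                        tri(81.8, 74.8, 88.8), tri(8.6, 8.0, 9.2),
                        tri(30.5, 0.0, 100.0), tri(43.6, 41.0, 47.0)),
    ustekinumab  = list(1, 642,  2,  tri(60.0, 59.4, 60.6), tri(42.0, 41.7, 42.2),
                        tri(73.4, 73.0, 73.7), tri(8.2, 8.1, 8.2),
                        tri(68.4, 67.8, 68.9), tri(53.2, 52.2, 54.1)),
    mirikizumab  = list(2, 1054, 4,  tri(61.0, 59.7, 62.8), tri(42.6, 41.8, 43.4),
                        tri(75.6, 73.0, 77.0), tri(8.2, 6.0, 9.0),
                        tri(37.4, 37.4, 37.4), tri(46.0, 40.3, 55.7)),
    tofacitinib  = list(3, 1073, 8,  tri(57.2, 50.0, 64.0), tri(41.4, 41.0, 43.8),
                        tri(74.2, 72.9, 75.9), tri(8.9, 7.6, 10.9),
                        tri(42.2, 29.0, 55.2), tri(45.3, 27.0, 58.0)),
    upadacitinib = list(3, 864,  6,  tri(61.6, 48.9, 66.1), tri(42.1, 37.0, 47.0),
                        tri(70.3, 69.3, 71.2), tri(7.1, 6.6, 7.6),
                        tri(77.2, 69.6, 100.0), tri(49.1, 38.9, 55.4)),
    filgotinib   = list(2, 1069, 4,  tri(56.6, 50.2, 65.3), tri(42.5, 42.0, 43.0),
                        NULL,                  tri(8.5, 6.7, 9.8),
                        tri(46.6, 0.0, 93.3),  tri(30.1, 22.0, 36.1)),
    ozanimod     = list(2, 561,  3,  tri(57.1, 49.2, 71.6), tri(41.4, 38.8, 41.8),
                        tri(74.9, 72.3, 77.4), tri(6.7, 5.9, 6.9),
                        tri(22.4, 18.5, 30.3), tri(34.0, 27.7, 40.0)),
    etrasimod    = list(3, 598,  4,  tri(55.4, 52.6, 57.7), tri(40.8, 40.3, 43.2),
                        NULL,                  tri(6.6, 6.2, 7.0),
                        tri(31.4, 28.8, 34.0), tri(30.5, 25.0, 36.0)),
    placebo      = list(NA, 4081, 32, tri(60.0, 42.0, 72.9), tri(41.2, 34.5, 44.8),
                        tri(72.8, 57.2, 78.7), tri(7.1, 3.7, 10.2),
                        tri(30.6, 0.0, 100.0), tri(47.0, 8.0, 67.6))
  )
  lapply(rows, function(r) {
    names(r) <- c("trials", "patients", "arms", "male_pct", "age", "weight",
                  "duration", "prior_tnf_pct", "steroid_pct")
    r$baseline_activity <- c(8.5, 6.5, 10.5)
    r
  })
}

# dose regimens cycled over a drug's arms: amount, unit, tag
.design_regimens <- list(
  infliximab   = list(c("5",   "mg_per_kg", "5mgkg"),
                      c("10",  "mg_per_kg", "10mgkg")),
  adalimumab   = list(c("40",  "mg", "40mg")),
  golimumab    = list(c("200", "mg", "200mg"), c("100", "mg", "100mg")),
  vedolizumab  = list(c("300", "mg", "300mg")),
  etrolizumab  = list(c("105", "mg", "105mg")),
  ustekinumab  = list(c("6",   "mg_per_kg", "6mgkg"),
                      c("130", "mg", "130mg")),
  mirikizumab  = list(c("300", "mg", "300mg")),
  tofacitinib  = list(c("10",  "mg", "10mg"), c("5", "mg", "5mg")),
  upadacitinib = list(c("45",  "mg", "45mg"), c("30", "mg", "30mg"),
                      c("15",  "mg", "15mg"), c("7.5", "mg", "7.5mg")),
  filgotinib   = list(c("200", "mg", "200mg"), c("100", "mg", "100mg")),
  ozanimod     = list(c("1",   "mg", "1mg")),
  etrasimod    = list(c("2",   "mg", "2mg"), c("1", "mg", "1mg"))
)

.split_even <- function(total, k) {
  base <- total %/% k
  out <- rep(base, k)
  rem <- total - base * k
  if (rem > 0) out[seq_len(rem)] <- out[seq_len(rem)] + 1
  out
}

#' The packaged study design
#'
#' Builds the synthetic analogue of the source database design: 35 trials,
#' 95 arms, 15,585 patients, 32 placebo arms, and per-drug trial, arm and
#' patient counts matching the published summary, with per-drug covariate
#' distributions (median and range). The per-drug trial counts sum to 39,
#' so four trials host two drugs each: a vedolizumab/adalimumab
#' head-to-head without placebo, two etrolizumab trials with an
#' adalimumab comparator arm, and an etrolizumab/infliximab comparison
#' without placebo -- mirroring the head-to-head designs in the source
#' database. Every trial except three (the two head-to-heads and one
#' upadacitinib extension study) carries one placebo arm. The last
#' single-drug trial of every multi-trial drug, and the
#' vedolizumab/adalimumab head-to-head, are flagged as maintenance
#' studies with visits at weeks 24, 44, 52 and 60; all other trials use
#' induction visits at weeks 2, 4, 6, 8 and 12.
#'
#' @param induction_visits,maintenance_visits visit schedules in weeks.
#' @return an object of class `uc_study_design`: a list with `trials`
#'   (each with `trial_id`, `maintenance`, `visit_weeks`, and a list of
#'   arms) and `covariates` (per-drug distribution triplets).
#' @export
#' @examples
#' d <- paper_design()
#' design_summary(d)
paper_design <- function(induction_visits = c(2, 4, 6, 8, 12),
                         maintenance_visits = c(24, 44, 52, 60)) {
  margins <- .design_margins()
  active <- setdiff(names(margins), "placebo")
  # shared (two-drug) trials: drug memberships, placebo presence,
  # maintenance flag; one arm per member drug
  shared <- list(
    `h2h-vedo-adal` = list(drugs = c("vedolizumab", "adalimumab"),
                           placebo = FALSE, maintenance = TRUE),
    `h2h-etro-adal-1` = list(drugs = c("etrolizumab", "adalimumab"),
                             placebo = TRUE, maintenance = FALSE),
    `h2h-etro-adal-2` = list(drugs = c("etrolizumab", "adalimumab"),
                             placebo = TRUE, maintenance = FALSE),
    `h2h-etro-infl` = list(drugs = c("etrolizumab", "infliximab"),
                           placebo = FALSE, maintenance = FALSE)
  )
  shared_count <- table(unlist(lapply(shared, `[[`, "drugs")))
  no_placebo_own <- "upadacitinib-3"

  # per-drug arm bookkeeping: sizes split evenly over all of a drug's arms,
  # regimens cycled in order
  state <- list()
  for (dr in active) {
    m <- margins[[dr]]
    state[[dr]] <- list(sizes = .split_even(m$patients, m$arms), i = 0L)
  }
  next_arm <- function(dr, tid) {
    st <- state[[dr]]
    st$i <- st$i + 1L
    state[[dr]] <<- st
    regs <- .design_regimens[[dr]]
    rg <- regs[[(st$i - 1L) %% length(regs) + 1L]]
    list(arm_id = paste0(tid, "-", dr, st$i), drug = dr,
         dose_amount = as.numeric(rg[1]), dose_unit = rg[2],
         regimen_tag = rg[3], n_total = st$sizes[st$i])
  }

  trials <- list()
  for (dr in active) {
    m <- margins[[dr]]
    n_own <- m$trials - (if (dr %in% names(shared_count))
      shared_count[[dr]] else 0L)
    arms_own <- m$arms - (if (dr %in% names(shared_count))
      shared_count[[dr]] else 0L)
    arms_per_trial <- .split_even(arms_own, n_own)
    for (tr in seq_len(n_own)) {
      tid <- paste0(dr, "-", tr)
      maint <- n_own > 1 && tr == n_own
      trials[[tid]] <- list(
        trial_id = tid, maintenance = maint,
        visit_weeks = if (maint) maintenance_visits else induction_visits,
        arms = lapply(seq_len(arms_per_trial[tr]),
                      function(a) next_arm(dr, tid))
      )
    }
  }
  for (tid in names(shared)) {
    sh <- shared[[tid]]
    trials[[tid]] <- list(
      trial_id = tid, maintenance = sh$maintenance,
      visit_weeks = if (sh$maintenance) maintenance_visits
                    else induction_visits,
      arms = lapply(sh$drugs, function(dr) next_arm(dr, tid))
    )
  }
  pbo_trials <- setdiff(
    names(trials),
    c(no_placebo_own, names(shared)[!vapply(shared, `[[`, TRUE, "placebo")])
  )
  stopifnot(length(pbo_trials) == margins$placebo$arms)
  pbo_sizes <- .split_even(margins$placebo$patients, length(pbo_trials))
  for (i in seq_along(pbo_trials)) {
    tid <- pbo_trials[i]
    trials[[tid]]$arms <- c(trials[[tid]]$arms, list(list(
      arm_id = paste0(tid, "-pbo"), drug = "placebo",
      dose_amount = 0, dose_unit = "mg", regimen_tag = "placebo",
      n_total = pbo_sizes[i]
    )))
  }
  structure(list(trials = trials, covariates = margins),
            class = "uc_study_design")
}

#' Summarise a study design
#' @param design a `uc_study_design`.
#' @return a list with `n_trials`, `n_arms`, `n_patients`,
#'   `n_placebo_arms`.
#' @export
design_summary <- function(design) {
  arms <- unlist(lapply(design$trials, `[[`, "arms"), recursive = FALSE)
  list(
    n_trials = length(design$trials),
    n_arms = length(arms),
    n_patients = sum(vapply(arms, `[[`, 0, "n_total")),
    n_placebo_arms = sum(vapply(arms, `[[`, "", "drug") == "placebo")
  )
}

#' @export
print.uc_study_design <- function(x, ...) {
  s <- design_summary(x)
  cat("<uc_study_design>", s$n_trials, "trials,", s$n_arms, "arms (",
      s$n_placebo_arms, "placebo ),", s$n_patients, "patients\n")
  invisible(x)
}

#' Scale down a study design for fast testing
#'
#' Multiplies every arm size by `scale` (rounded, floor of 10 patients per
#' arm); the trial/arm structure is untouched.
#'
#' @param design a `uc_study_design`.
#' @param scale fraction in (0, 1].
#' @return the scaled design.
#' @export
perturb_design <- function(design, scale) {
  if (!is.numeric(scale) || scale <= 0 || scale > 1)
    stop("scale must be in (0, 1]")
  if (scale == 1) return(design)
  for (tid in names(design$trials)) {
    design$trials[[tid]]$arms <- lapply(
      design$trials[[tid]]$arms, function(a) {
        a$n_total <- max(10L, as.integer(round(a$n_total * scale)))
        a
      })
  }
  design
}

#' Generate a synthetic dataset from a design and a generating model
#'
#' Draws arm-level covariates from the design's per-drug truncated-normal
#' distributions (mean = published median, sd = range/4, clipped to the
#' range), one between-arm random effect per arm from `N(0, omega2)`,
#' computes the response probability at every visit via
#' [response_probability()], and samples responder counts binomially.
#' Arms of drugs absent from the generating model (e.g. etrasimod in the
#' remission model) are dropped, together with trials left without an
#' active arm. Fully reproducible given `seed`.
#'
#' @param design a `uc_study_design`.
#' @param truth a `uc_model_spec` used as the generating model.
#' @param seed integer RNG seed.
#' @param missingness fraction of covariate cells blanked at random (to
#'   exercise imputation); default 0.
#' @return a list with `records`, `arms` (the [load_dataset()] layout,
#'   doses already normalised to mg at 70 kg) and `eta` (the simulated
#'   arm effects, for reference).
#' @export
generate_dataset <- function(design, truth, seed, missingness = 0) {
  validate_model_spec(truth)
  stopifnot(missingness >= 0, missingness < 1)
  set.seed(seed)

  keep_drug <- c("placebo", names(truth$drugs))
  arm_rows <- list(); rec_rows <- list(); etas <- numeric(); clipped <- 0
  for (tr in design$trials) {
    drugs_here <- vapply(tr$arms, `[[`, "", "drug")
    if (!any(drugs_here %in% setdiff(keep_drug, "placebo"))) next
    for (a in tr$arms) {
      if (!a$drug %in% keep_drug) next
      cv <- design$covariates[[a$drug]]
      draw <- list()
      for (nm in .uc_covariates) {
        trip <- cv[[nm]]
        if (is.null(trip)) { draw[[nm]] <- NA_real_; next }
        m <- trip[1]; lo <- trip[2]; hi <- trip[3]
        if (hi <= lo) { draw[[nm]] <- m; next }
        x <- stats::rnorm(1, m, (hi - lo) / 4)
        if (x < lo || x > hi) clipped <- clipped + 1
        draw[[nm]] <- min(max(x, lo), hi)
      }
      dose_mg <- if (a$dose_unit == "mg_per_kg") a$dose_amount * 70
                 else a$dose_amount
      arm <- c(list(trial_id = tr$trial_id, arm_id = a$arm_id,
                    drug = a$drug, dose_amount = dose_mg, dose_unit = "mg",
                    regimen_tag = a$regimen_tag), draw)
      eta <- stats::rnorm(1, 0, sqrt(truth$omega2))
      p <- response_probability(arm, tr$visit_weeks, truth, eta = eta)
      if (any(p <= 0 | p >= 1))
        stop("degenerate response probability for arm ", a$arm_id)
      n_resp <- stats::rbinom(length(p), a$n_total, p)
      arm_rows[[length(arm_rows) + 1]] <- as.data.frame(
        arm, stringsAsFactors = FALSE)
      rec_rows[[length(rec_rows) + 1]] <- data.frame(
        trial_id = tr$trial_id, arm_id = a$arm_id,
        endpoint = truth$endpoint, time = tr$visit_weeks,
        n_total = a$n_total, n_response = n_resp,
        stringsAsFactors = FALSE
      )
      etas[a$arm_id] <- eta
    }
  }
  if (!length(arm_rows)) stop("design contains no arms covered by the model")
  arms <- do.call(rbind, arm_rows)
  records <- do.call(rbind, rec_rows)
  rownames(arms) <- rownames(records) <- NULL
  if (clipped > 0)
    message(clipped, " covariate draw(s) clipped to the design range")
  if (missingness > 0) {
    for (nm in .uc_covariates) {
      blank <- stats::runif(nrow(arms)) < missingness
      arms[[nm]][blank] <- NA_real_
    }
  }
  list(records = records, arms = arms, eta = etas)
}

#' Write / read a study design as YAML
#' @param design a `uc_study_design`.
#' @param path file path.
#' @return `path` (write) or the design (read).
#' @export
write_design <- function(design, path) {
  yaml::write_yaml(unclass(design), path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  y$covariates <- lapply(y$covariates, function(cv) {
    lapply(cv, function(el)
      if (is.list(el)) as.numeric(unlist(el)) else el)
  })
  y$trials <- lapply(y$trials, function(tr) {
    tr$visit_weeks <- as.numeric(unlist(tr$visit_weeks))
    tr$arms <- lapply(tr$arms, function(a) {
      a$dose_amount <- as.numeric(a$dose_amount)
      a$n_total <- as.integer(a$n_total)
      a
    })
    tr
  })
  structure(y, class = "uc_study_design")
}
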