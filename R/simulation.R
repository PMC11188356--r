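# Monte-Carlo simulation of treatment efficacy in a hypothetical
# population, ET90 onset times, and treatment ranking.

#' Hypothetical population profile
#'
#' The covariate values at which efficacy is simulated. Defaults match the
#' reference scenario: 7 years disease duration, age 40, 50% prior
#' anti-TNF exposure, 50% concomitant corticosteroid use, 70 kg weight.
#'
#' @param duration,age,prior_tnf_pct,steroid_pct,weight covariate values.
#' @return an object of class `uc_population`.
#' @export
population_profile <- function(duration = 7, age = 40, prior_tnf_pct = 50,
                               steroid_pct = 50, weight = 70) {
  stopifnot(duration > 0, age > 0, weight > 0,
            prior_tnf_pct >= 0, prior_tnf_pct <= 100,
            steroid_pct >= 0, steroid_pct <= 100)
  structure(list(duration = duration, age = age,
                 prior_tnf_pct = prior_tnf_pct, steroid_pct = steroid_pct,
                 weight = weight),
            class = "uc_population")
}

#' Default dose regimens for simulation
#'
#' Enumerates the treatment entries to simulate: one entry per drug for
#' flat-Emax drugs (dose regimens are equivalent by construction), one per
#' distinct dose for linear dose-response drugs, and separate entries for
#' regimen-specific Emax overrides.
#'
#' @param model a `uc_model_spec`.
#' @param design a `uc_study_design` supplying the observed dose regimens.
#' @return data.frame with `treatment`, `drug`, `dose`, `regimen_tag`.
#' @export
default_regimens <- function(model, design = paper_design()) {
  arms <- unlist(lapply(design$trials, `[[`, "arms"), recursive = FALSE)
  tab <- unique(data.frame(
    drug = vapply(arms, `[[`, "", "drug"),
    dose = vapply(arms, function(a)
      if (a$dose_unit == "mg_per_kg") a$dose_amount * 70 else a$dose_amount,
      0),
    regimen_tag = vapply(arms, `[[`, "", "regimen_tag"),
    stringsAsFactors = FALSE
  ))
  out <- list()
  for (dr in names(model$drugs)) {
    ds <- model$drugs[[dr]]
    rows <- tab[tab$drug == dr, , drop = FALSE]
    if (!nrow(rows))
      rows <- data.frame(drug = dr, dose = 1, regimen_tag = dr)
    if (ds$dose_model == "linear") {
      sel <- rows
      sel$treatment <- paste0(dr, " ", sel$dose, "mg")
    } else {
      ov <- names(ds$regimen_overrides)
      sel_ov <- rows[rows$regimen_tag %in% ov, , drop = FALSE]
      sel_ov <- sel_ov[!duplicated(sel_ov$regimen_tag), , drop = FALSE]
      rest <- rows[!rows$regimen_tag %in% ov, , drop = FALSE]
      rest <- rest[which.max(rest$dose), , drop = FALSE]
      if (nrow(rest)) rest$treatment <- dr
      if (nrow(sel_ov)) sel_ov$treatment <- paste(dr, sel_ov$regimen_tag)
      sel <- rbind(rest, sel_ov)
    }
    out[[dr]] <- sel
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("treatment", "drug", "dose", "regimen_tag")]
}

#' Monte-Carlo simulation of treatment efficacy
#'
#' Draws parameter vectors (multivariate normal from the fit covariance,
#' or resampled bootstrap rows), optionally one between-arm effect per
#' draw, evaluates the response probability for every treatment and week
#' in the hypothetical population, and summarises medians and 95% bands.
#' Placebo is simulated from the same parameter draws, and the
#' placebo-corrected response is computed per draw before taking the
#' median.
#'
#' @param fitted a `uc_fit` (preferred; supplies the covariance) or a
#'   `uc_model_spec`.
#' @param uncertainty `NULL` (use the fit covariance; for a bare spec this
#'   means no parameter uncertainty), a covariance matrix, a
#'   `uc_bootstrap` / bootstrap estimates data.frame, or `"none"`.
#' @param pop a [population_profile()].
#' @param weeks weeks at which to simulate.
#' @param n_draws number of Monte-Carlo draws.
#' @param seed integer seed.
#' @param include_eta include a between-arm random effect per draw so the
#'   bands reflect between-arm heterogeneity (disable for typical-value
#'   prediction).
#' @param regimens regimen table (see [default_regimens()]).
#' @return an object of class `uc_simulation` with a `results` data.frame:
#'   `treatment`, `week`, `median`, `lo`, `hi`, `placebo_median`,
#'   `placebo_corrected` (plus its `pc_lo`, `pc_hi` band).
#' @export
simulate_efficacy <- function(fitted, uncertainty = NULL,
                              pop = population_profile(), weeks = 1:60,
                              n_draws = 10000, seed = 1L,
                              include_eta = TRUE, regimens = NULL) {
  if (inherits(fitted, "uc_fit")) {
    spec <- fitted$model
    if (is.null(uncertainty)) uncertainty <- fitted$vcov %||% "none"
  } else {
    spec <- fitted
    if (is.null(uncertainty)) uncertainty <- "none"
  }
  validate_model_spec(spec)
  stopifnot(n_draws >= 1)
  if (inherits(uncertainty, "uc_bootstrap"))
    uncertainty <- uncertainty$estimates
  regimens <- regimens %||% default_regimens(spec)

  slots <- .free_params(spec, objective_config())
  par0 <- .slot_values(spec, slots)
  set.seed(seed)
  par_draws <- if (is.matrix(uncertainty)) {
    vc <- uncertainty[names(par0), names(par0), drop = FALSE]
    ok <- tryCatch({ chol(vc); TRUE }, error = function(e) FALSE)
    if (!ok) {
      # ridge the covariance just enough to draw from it
      warning("covariance not positive definite; adding a small ridge")
      vc <- vc + diag(1e-8 + abs(min(eigen(vc, symmetric = TRUE,
                                           only.values = TRUE)$values)),
                      nrow(vc))
    }
    MASS::mvrnorm(n_draws, par0, vc)
  } else if (is.data.frame(uncertainty)) {
    m <- as.matrix(uncertainty[, names(par0), drop = FALSE])
    m[sample(nrow(m), n_draws, replace = TRUE), , drop = FALSE]
  } else if (identical(uncertainty, "none")) {
    matrix(rep(par0, each = n_draws), n_draws,
           dimnames = list(NULL, names(par0)))
  } else stop("unusable uncertainty source")

  # evaluation grid: placebo + each treatment regimen at every week
  grid <- rbind(
    data.frame(treatment = ".placebo", drug = "placebo", dose = 0,
               regimen_tag = "placebo", stringsAsFactors = FALSE),
    regimens
  )
  evald <- grid[rep(seq_len(nrow(grid)), each = length(weeks)), ]
  evald$time <- rep(weeks, nrow(grid))
  evald$dose_amount <- evald$dose
  for (nm in names(pop)) evald[[nm]] <- pop[[nm]]
  rownames(evald) <- NULL

  eta <- if (include_eta) stats::rnorm(n_draws, 0, sqrt(max(spec$omega2, 0)))
         else numeric(n_draws)
  P <- matrix(0, nrow(evald), n_draws)
  for (s in seq_len(n_draws)) {
    spec_s <- .apply_params(spec, slots, par_draws[s, ])
    if (spec_s$omega2 < 0) spec_s$omega2 <- 0
    P[, s] <- stats::plogis(.linear_predictor(evald, spec_s) + eta[s])
  }
  pbo_rows <- which(evald$treatment == ".placebo")
  pbo_P <- P[pbo_rows, , drop = FALSE]   # weeks x draws
  wk_of <- match(evald$time, weeks)

  res <- lapply(which(evald$treatment != ".placebo"), function(i) {
    q <- stats::quantile(P[i, ], c(0.025, 0.5, 0.975))
    diff_draws <- P[i, ] - pbo_P[wk_of[i], ]
    qd <- stats::quantile(diff_draws, c(0.025, 0.5, 0.975))
    data.frame(
      treatment = evald$treatment[i], drug = evald$drug[i],
      regimen_tag = evald$regimen_tag[i], dose = evald$dose[i],
      week = evald$time[i],
      median = q[2], lo = q[1], hi = q[3],
      placebo_median = stats::median(pbo_P[wk_of[i], ]),
      placebo_corrected = qd[2], pc_lo = qd[1], pc_hi = qd[3],
      stringsAsFactors = FALSE
    )
  })
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  structure(list(results = results, n_draws = n_draws, seed = seed,
                 include_eta = include_eta, pop = pop),
            class = "uc_simulation")
}

#' @export
print.uc_simulation <- function(x, ...) {
  cat("<uc_simulation>", length(unique(x$results$treatment)),
      "treatments x", length(unique(x$results$week)), "weeks,",
      x$n_draws, "draws (eta",
      if (x$include_eta) "included" else "excluded", ")\n")
  invisible(x)
}

#' Time to 90% of maximal effect (ET90)
#'
#' Two definitions are provided because onset can be read on two scales:
#' `onset_factor` solves `1 - exp(-k t) = 0.9`, i.e. `ln(10) / k`;
#' `probability` finds the time at which the predicted response
#' probability reaches 90% of its asymptotic value (bracketed root find,
#' tolerance 1e-6 weeks; exponential placebo only, since the spline forms
#' have no asymptote).
#'
#' @param component a [placebo_spec()] (exponential form) or a
#'   [drug_spec()] with an onset rate.
#' @param scale `"onset_factor"` or `"probability"`.
#' @param covs optional covariates for the probability-scale placebo
#'   computation.
#' @param effects covariate effects accompanying `covs`.
#' @param onset_rates named onset rates resolving a drug's shared `onset`.
#' @param dose dose used for the probability scale of a drug component.
#' @return time in weeks.
#' @export
#' @examples
#' ds <- drug_spec("tofacitinib", "emax_flat", Emax = 1.88, k_onset = 0.103)
#' et90(ds)  # ln(10) / 0.103 ~ 22.4 weeks
et90 <- function(component, scale = c("onset_factor", "probability"),
                 covs = NULL, effects = list(), onset_rates = numeric(),
                 dose = NULL) {
  scale <- match.arg(scale)
  is_placebo <- inherits(component, "uc_placebo_spec")
  k <- if (is_placebo) {
    if (component$form != "exponential")
      stop("no onset defined: ET90 requires the exponential placebo form")
    component$k_pbo
  } else {
    if (!is.na(component$onset)) onset_rates[[component$onset]]
    else component$k_onset
  }
  if (is.null(k) || is.na(k)) stop("no onset defined for this component")
  if (scale == "onset_factor") return(log(10) / k)

  f <- if (is_placebo) {
    function(t) stats::plogis(placebo_effect(t, component, covs, effects))
  } else {
    dose <- dose %||% 1
    function(t) stats::plogis(drug_effect(
      component$drug, dose, t, component, covs, effects, onset_rates))
  }
  p_inf <- f(1e9)
  target <- 0.9 * p_inf
  stats::uniroot(function(t) f(t) - target, interval = c(0, 1e4),
                 tol = 1e-6)$root
}

#' Rank treatments at a given week
#'
#' Orders treatments by the placebo-corrected median response
#' (descending). Ties are broken by the narrower 95% band, then by
#' treatment name; tied entries are flagged.
#'
#' @param sim a `uc_simulation`.
#' @param week week to rank at (must be in the simulation grid).
#' @return data.frame of ranked treatments with a `tied` flag.
#' @export
rank_treatments <- function(sim, week) {
  r <- sim$results
  if (!week %in% r$week)
    stop("week ", week, " not simulated; available: ",
         paste(sort(unique(r$week)), collapse = ", "))
  r <- r[r$week == week, , drop = FALSE]
  band <- r$hi - r$lo
  ord <- order(-r$placebo_corrected, band, r$treatment)
  r <- r[ord, , drop = FALSE]
  r$rank <- seq_len(nrow(r))
  r$tied <- duplicated(r$placebo_corrected) |
    duplicated(r$placebo_corrected, fromLast = TRUE)
  rownames(r) <- NULL
  r
}
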