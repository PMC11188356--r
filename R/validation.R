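# Model validation: non-parametric bootstrap, visual predictive check,
# and weighted-residual diagnostics.

#' Bootstrap a fitted model
#'
#' Resamples arms with replacement, stratified by placebo vs active status
#' (the arm is the model's exchangeability unit: one random effect per
#' arm), refits each replicate starting from the supplied spec, and
#' summarises the converged replicates by per-parameter medians and
#' 2.5/97.5 percentile intervals. Replicates that fail to converge are
#' dropped and counted, not retried. Fully reproducible given `seed`.
#'
#' @param records,arms dataset tables.
#' @param spec fitted `uc_model_spec` used as starting values (a `uc_fit`
#'   is also accepted).
#' @param cfg an [objective_config()]; `compute_vcov` is forced off for
#'   the replicate fits.
#' @param n number of bootstrap replicates.
#' @param seed integer seed.
#' @return an object of class `uc_bootstrap`: `n_requested`,
#'   `n_converged`, `estimates` (one row per converged replicate),
#'   `medians`, `percentile_cis`, and `seed`.
#' @export
bootstrap_model <- function(records, arms, spec, cfg = objective_config(),
                            n = 1000, seed = 1L) {
  if (inherits(spec, "uc_fit")) spec <- spec$model
  validate_model_spec(spec)
  cfg$compute_vcov <- FALSE
  is_pbo <- arms$drug == "placebo"
  idx_pbo <- which(is_pbo); idx_act <- which(!is_pbo)
  set.seed(seed)
  rows <- list(); n_conv <- 0L; fail_msgs <- character()
  for (b in seq_len(n)) {
    take <- c(
      if (length(idx_pbo)) sample(idx_pbo, length(idx_pbo), replace = TRUE),
      if (length(idx_act)) sample(idx_act, length(idx_act), replace = TRUE)
    )
    arms_b <- arms[take, , drop = FALSE]
    # resampled copies of the same arm become distinct arms
    new_id <- paste0(arms_b$arm_id, "#", seq_along(take))
    rec_list <- lapply(seq_along(take), function(i) {
      sel <- records$trial_id == arms_b$trial_id[i] &
        records$arm_id == arms_b$arm_id[i]
      r <- records[sel, , drop = FALSE]
      r$arm_id <- new_id[i]
      r
    })
    arms_b$arm_id <- new_id
    recs_b <- do.call(rbind, rec_list)
    cfg_b <- cfg
    cfg_b$seed <- cfg$seed + b
    fit_b <- tryCatch(fit_model(recs_b, arms_b, spec, cfg_b),
                      error = function(e) e)
    if (inherits(fit_b, "error")) {
      fail_msgs <- c(fail_msgs, conditionMessage(fit_b))
    } else if (fit_b$converged) {
      n_conv <- n_conv + 1L
      rows[[n_conv]] <- fit_b$par
    } else {
      fail_msgs <- c(fail_msgs, "optimizer did not converge")
    }
  }
  if (!n_conv)
    stop("all bootstrap replicates failed: ",
         paste(utils::head(unique(fail_msgs), 3), collapse = "; "))
  est <- do.call(rbind, rows)
  structure(
    list(
      n_requested = n, n_converged = n_conv,
      estimates = as.data.frame(est),
      medians = apply(est, 2, stats::median),
      percentile_cis = t(apply(est, 2, stats::quantile,
                               probs = c(0.025, 0.975))),
      seed = seed, resampling_unit = "arm (stratified placebo/active)"
    ),
    class = "uc_bootstrap"
  )
}

#' @export
print.uc_bootstrap <- function(x, ...) {
  cat("<uc_bootstrap>", x$n_converged, "/", x$n_requested,
      "replicates converged\n")
  tab <- data.frame(median = signif(x$medians, 4),
                    lo2.5 = signif(x$percentile_cis[, 1], 4),
                    hi97.5 = signif(x$percentile_cis[, 2], 4))
  print(tab)
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates responder counts for every (arm, visit) design point from the
#' fitted model -- drawing a fresh between-arm effect and binomial counts
#' per replicate -- and summarises the simulated response proportions by
#' 2.5/50/97.5 percentile bands at each design point. Coverage is the
#' fraction of observed proportions inside the 95% band.
#'
#' @param records,arms dataset tables.
#' @param fitted a fitted `uc_model_spec` (or `uc_fit`).
#' @param n_sim number of simulation replicates (>= 100).
#' @param seed integer seed.
#' @return an object of class `uc_vpc` with a `bands` data.frame
#'   (trial, arm, time, observed proportion, p2.5/p50/p97.5), `n_sim`,
#'   `coverage`, and `seed`.
#' @export
vpc <- function(records, arms, fitted, n_sim = 1000, seed = 1L) {
  if (inherits(fitted, "uc_fit")) fitted <- fitted$model
  validate_model_spec(fitted)
  if (n_sim < 100) stop("n_sim must be >= 100")
  d <- .prepare_data(records, arms)
  lp <- .linear_predictor(d, fitted)
  nA <- max(d$arm_idx)
  set.seed(seed)
  sims <- matrix(0, nrow(d), n_sim)
  for (s in seq_len(n_sim)) {
    eta <- stats::rnorm(nA, 0, sqrt(fitted$omega2))
    p <- stats::plogis(lp + eta[d$arm_idx])
    sims[, s] <- stats::rbinom(nrow(d), d$n_total, p) / d$n_total
  }
  qs <- t(apply(sims, 1, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  obs <- d$n_response / d$n_total
  bands <- data.frame(
    trial_id = d$trial_id, arm_id = d$arm_id, drug = d$drug,
    time = d$time, n_total = d$n_total, observed = obs,
    p2.5 = qs[, 1], p50 = qs[, 2], p97.5 = qs[, 3],
    stringsAsFactors = FALSE
  )
  structure(
    list(bands = bands, n_sim = n_sim, seed = seed,
         coverage = mean(obs >= qs[, 1] & obs <= qs[, 3])),
    class = "uc_vpc"
  )
}

#' @export
print.uc_vpc <- function(x, ...) {
  cat("<uc_vpc>", x$n_sim, "simulations,",
      nrow(x$bands), "design points, coverage",
      sprintf("%.3f", x$coverage), "\n")
  invisible(x)
}

#' Plot a visual predictive check
#'
#' Time-course overlay of observed response proportions on the simulated
#' 2.5/50/97.5 percentile bands, one panel per trial.
#'
#' @param x a `uc_vpc`.
#' @param trials optional subset of trial ids to plot.
#' @param max_panels cap on the number of panels.
#' @param ... unused.
#' @export
plot.uc_vpc <- function(x, trials = NULL, max_panels = 12, ...) {
  b <- x$bands
  trials <- trials %||% utils::head(unique(b$trial_id), max_panels)
  n <- length(trials)
  mf <- grDevices::n2mfrow(n)
  op <- graphics::par(mfrow = mf, mar = c(3.5, 3.5, 2, 0.5),
                      mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op))
  for (tr in trials) {
    bi <- b[b$trial_id == tr, ]
    plot(NA, xlim = range(bi$time), ylim = c(0, max(bi$p97.5, bi$observed)),
         xlab = "week", ylab = "response proportion", main = tr)
    for (a in unique(bi$arm_id)) {
      ba <- bi[bi$arm_id == a, ]
      ba <- ba[order(ba$time), ]
      graphics::polygon(c(ba$time, rev(ba$time)),
                        c(ba$p2.5, rev(ba$p97.5)),
                        col = grDevices::adjustcolor("steelblue", 0.2),
                        border = NA)
      graphics::lines(ba$time, ba$p50, col = "steelblue")
      graphics::points(ba$time, ba$observed, pch = 19,
                       cex = 0.4 + ba$n_total / max(b$n_total))
    }
  }
  invisible(x)
}

#' Weighted residual diagnostics
#'
#' Per-observation weighted residual
#' `(observed - predicted) / sqrt(P (1 - P) / N)` evaluated at the typical
#' prediction (`eta = 0`), tabulated against time and predicted value.
#' For data simulated from the model the residuals have mean ~0 and
#' variance ~1.
#'
#' @param records,arms dataset tables.
#' @param fitted a fitted `uc_model_spec` (or `uc_fit`).
#' @return a data.frame with one row per observation (`time`, `predicted`,
#'   `observed`, `wres`) and attributes `mean` and `variance`.
#' @export
residual_diagnostics <- function(records, arms, fitted) {
  if (inherits(fitted, "uc_fit")) fitted <- fitted$model
  d <- .prepare_data(records, arms)
  p <- stats::plogis(.linear_predictor(d, fitted))
  obs <- d$n_response / d$n_total
  wres <- (obs - p) / sqrt(p * (1 - p) / d$n_total)
  out <- data.frame(
    trial_id = d$trial_id, arm_id = d$arm_id, drug = d$drug,
    time = d$time, n_total = d$n_total,
    observed = obs, predicted = p, wres = wres,
    stringsAsFactors = FALSE
  )
  attr(out, "mean") <- mean(wres)
  attr(out, "variance") <- stats::var(wres)
  out
}
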