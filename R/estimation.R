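# Maximum-likelihood estimation of endpoint models: exact binomial
# likelihood with a logit-scale between-arm random effect integrated by
# adaptive Gauss-Hermite quadrature (default), or a weighted-normal
# approximation with optional within-arm autocorrelation. Plus model
# comparison and stepwise covariate selection.

#' Estimation configuration
#'
#' @param likelihood `"binomial"` (exact arm-level binomial likelihood,
#'   self-weighting and well defined at extreme proportions; the default) or
#'   `"weighted_normal"` (Gaussian likelihood of observed proportions with
#'   binomial-standard-error weights and optional AR1 / compound-symmetry
#'   autocorrelation).
#' @param integration random-effect integration rule; `"aghq"` (adaptive
#'   Gauss-Hermite) or `"laplace"` (equivalent to 1 quadrature point).
#' @param quad_points number of quadrature nodes (>= 1); 9 by default.
#' @param fixed_params names of parameters to hold at their `init` values
#'   (e.g. `"omega2"`).
#' @param seed integer seed controlling optimizer restarts.
#' @param tol relative convergence tolerance passed to the optimizer.
#' @param maxit maximum optimizer iterations per start.
#' @param n_restarts number of optimizer starts (first at `init`, the rest
#'   jittered); onset-rate likelihoods can be multimodal in `k`.
#' @param jitter_sd relative jitter of restart values.
#' @param prob_floor floor applied to probabilities inside log terms (the
#'   exponential placebo intercept drives predictions into underflow at
#'   week 0).
#' @param compute_vcov compute the inverse-Hessian covariance and Wald 95%
#'   intervals after fitting (disable for speed in replicate studies).
#' @return an object of class `uc_objective_config`.
#' @export
objective_config <- function(likelihood = c("binomial", "weighted_normal"),
                             integration = c("aghq", "laplace"),
                             quad_points = 9, fixed_params = character(),
                             seed = 1L, tol = 2e-8, maxit = 1000,
                             n_restarts = 5, jitter_sd = 0.1,
                             prob_floor = 1e-8, compute_vcov = TRUE) {
  likelihood <- match.arg(likelihood)
  integration <- match.arg(integration)
  stopifnot(quad_points >= 1, tol > 0, maxit >= 1, n_restarts >= 1)
  if (integration == "laplace") quad_points <- 1
  structure(
    list(likelihood = likelihood, integration = integration,
         quad_points = as.integer(quad_points), fixed_params = fixed_params,
         seed = as.integer(seed), tol = tol, maxit = maxit,
         n_restarts = n_restarts, jitter_sd = jitter_sd,
         prob_floor = prob_floor, compute_vcov = compute_vcov),
    class = "uc_objective_config"
  )
}

# merge records and arms into one observation table sorted by arm and time
.prepare_data <- function(records, arms) {
  d <- merge(records, arms, by = c("trial_id", "arm_id"), sort = FALSE)
  if (nrow(d) != nrow(records))
    stop("records reference arms absent from the arm table")
  d <- d[order(d$trial_id, d$arm_id, d$time), , drop = FALSE]
  key <- paste(d$trial_id, d$arm_id)
  d$arm_idx <- as.integer(factor(key, levels = unique(key)))
  attr(d, "arm_ids") <- unique(key)
  attr(d, "lchoose_sum") <- sum(lchoose(d$n_total, d$n_response))
  d
}

#' Conditional binomial log-likelihood given arm effects
#'
#' Sum over observations of `log C(N, n) + n log P + (N - n) log(1 - P)`,
#' with `P` from [response_probability()] evaluated at each arm's `eta`.
#'
#' @param records,arms dataset tables (see [load_dataset()]).
#' @param model a `uc_model_spec`.
#' @param eta_by_arm named numeric of logit offsets, one entry per arm
#'   (names `"<trial_id> <arm_id>"` or a vector in arm order).
#' @param prob_floor probability floor for the log terms.
#' @param warn warn when probabilities are clipped at the floor.
#' @return scalar log-likelihood.
#' @export
binomial_loglik <- function(records, arms, model, eta_by_arm,
                            prob_floor = 1e-8, warn = TRUE) {
  d <- .prepare_data(records, arms)
  ids <- attr(d, "arm_ids")
  if (!is.null(names(eta_by_arm))) {
    if (!all(ids %in% names(eta_by_arm)))
      stop("eta_by_arm is missing entries for some arms")
    eta <- eta_by_arm[ids]
  } else {
    if (length(eta_by_arm) == 1) eta_by_arm <- rep(eta_by_arm, length(ids))
    if (length(eta_by_arm) != length(ids))
      stop("eta_by_arm must have one entry per arm")
    eta <- eta_by_arm
  }
  lp <- .linear_predictor(d, model) + eta[d$arm_idx]
  p <- stats::plogis(lp)
  clipped <- p < prob_floor | p > 1 - prob_floor
  if (warn && any(clipped))
    warning(sum(clipped), " probability value(s) clipped at floor ",
            prob_floor)
  p <- .floor_prob(p, prob_floor)
  attr(d, "lchoose_sum") +
    sum(d$n_response * log(p) + (d$n_total - d$n_response) * log1p(-p))
}

# vectorised adaptive Gauss-Hermite marginal log-likelihood over the
# prepared table d. lp may be supplied (fast compiled path); eta0 warm-starts
# the per-arm mode search. The returned value carries the modes as an
# attribute so optimizer calls can reuse them.
.marginal_ll <- function(d, model, quad_points = 9, prob_floor = 1e-8,
                         lp = NULL, eta0 = NULL) {
  if (is.null(lp)) lp <- .linear_predictor(d, model)
  n <- d$n_response; N <- d$n_total; ai <- d$arm_idx
  nA <- max(ai)
  lch <- attr(d, "lchoose_sum")
  w2 <- model$omega2
  if (w2 < 1e-12) {
    p <- .floor_prob(stats::plogis(lp), prob_floor)
    return(lch + sum(n * log(p) + (N - n) * log1p(-p)))
  }
  # d is sorted by arm, so per-arm sums reduce to cumsum differences
  ends <- c(which(diff(ai) != 0), length(ai))
  rs <- function(x) {
    cs <- cumsum(x)
    cs[ends] - c(0, cs[ends[-nA]])
  }
  # per-arm posterior mode of eta by Newton iteration (vectorised over arms)
  eta <- if (is.null(eta0)) numeric(nA) else eta0
  for (it in 1:30) {
    p <- stats::plogis(lp + eta[ai])
    g <- rs(n - N * p) - eta / w2
    h <- -rs(N * p * (1 - p)) - 1 / w2
    step <- pmax(pmin(g / h, 2), -2)
    eta <- eta - step
    if (max(abs(step)) < 1e-9) break
  }
  p <- stats::plogis(lp + eta[ai])
  h <- -rs(N * p * (1 - p)) - 1 / w2
  sig <- sqrt(-1 / h)
  gh <- gauss_hermite(quad_points)
  logm <- matrix(0, nA, quad_points)
  sqrt_w2 <- sqrt(w2)
  for (k in seq_len(quad_points)) {
    ek <- eta + sqrt(2) * sig * gh$nodes[k]
    pk <- .floor_prob(stats::plogis(lp + ek[ai]), prob_floor)
    condk <- rs(n * log(pk) + (N - n) * log1p(-pk))
    logm[, k] <- log(gh$weights[k]) + gh$nodes[k]^2 + condk +
      stats::dnorm(ek, 0, sqrt_w2, log = TRUE)
  }
  ll_arm <- log(sqrt(2) * sig) + .row_logsumexp(logm)
  if (any(!is.finite(ll_arm)))
    stop("non-finite marginal likelihood for arm ",
         attr(d, "arm_ids")[which(!is.finite(ll_arm))[1]])
  structure(lch + sum(ll_arm), eta = eta)
}

# Compile the linear predictor for a fixed data layout and spec structure
# into a closure of pure vector operations (index vectors and covariate
# deltas precomputed). Falls back to the generic evaluator when the spec
# uses a full Emax (estimated ED50) dose model.
.compile_lp <- function(d, spec) {
  if (any(vapply(spec$drugs, function(s) s$dose_model == "emax", TRUE)))
    return(function(model) .linear_predictor(d, model))
  nrec <- nrow(d)
  t <- d$time
  covs <- d[intersect(names(d), .uc_covariates)]

  # covariate-effect terms: per effect, the applicable rows and either the
  # additive delta or the log covariate ratio
  eff_terms <- function(target, rows_of) {
    idx <- which(vapply(spec$covariate_effects,
                        function(e) e$target == target, TRUE))
    lapply(idx, function(i) {
      e <- spec$covariate_effects[[i]]
      rows <- rows_of(e)
      v <- covs[[e$covariate]][rows]
      if (any(is.na(v)))
        stop("covariate '", e$covariate, "' has missing values; ",
             "impute before model evaluation")
      if (e$form == "power" && any(v <= 0))
        stop("power-form covariate effect requires positive '",
             e$covariate, "'")
      list(i = i, form = e$form, rows = rows,
           delta = if (e$form == "additive") v - e$cov_mean,
           lr = if (e$form == "power") log(v / e$cov_mean))
    })
  }
  pbo_terms <- eff_terms("placebo", function(e) seq_len(nrec))
  drug_rows_of <- function(e) {
    which(d$drug != "placebo" &
            (if (is.null(e$dose_models)) TRUE
             else vapply(d$drug, function(dr)
               dr != "placebo" &&
                 spec$drugs[[dr]]$dose_model %in% e$dose_models, TRUE)))
  }
  drug_terms <- eff_terms("drug", drug_rows_of)

  apply_terms <- function(val, terms, model, pass_rows = NULL) {
    for (pass in c("power", "additive")) {
      for (tm in terms) {
        if (tm$form != pass) next
        th <- model$covariate_effects[[tm$i]]$theta
        if (pass == "power") {
          val[tm$rows] <- val[tm$rows] * exp(th * tm$lr)
        } else {
          val[tm$rows] <- val[tm$rows] + th * tm$delta
        }
      }
    }
    val
  }

  # placebo structure
  pl_form <- spec$placebo$form
  X <- if (pl_form == "rcs") cbind(1, rcs_basis(t, spec$placebo$knots))
       else if (pl_form == "polynomial")
         outer(t, seq_along(spec$placebo$coeffs) - 1, `^`)

  # drug structure: slot id per record (which Emax/slope parameter), dose
  # multiplier, onset grouping
  slot_of <- rep(NA_integer_, nrec)
  slot_defs <- list()   # list(drug, tag or NA, kind)
  dose_mult <- rep(1, nrec)
  onset_grp <- rep(NA_character_, nrec)
  static_onset <- rep(1, nrec)
  for (dr in setdiff(unique(d$drug), "placebo")) {
    sp <- spec$drugs[[dr]]
    if (is.null(sp)) stop("no drug specification for '", dr, "'")
    rows <- which(d$drug == dr)
    base_rows <- rows
    for (tag in names(sp$regimen_overrides)) {
      trows <- rows[d$regimen_tag[rows] == tag]
      if (!length(trows)) next
      slot_defs[[length(slot_defs) + 1]] <-
        list(drug = dr, tag = tag, kind = "override")
      slot_of[trows] <- length(slot_defs)
      base_rows <- setdiff(base_rows, trows)
    }
    slot_defs[[length(slot_defs) + 1]] <-
      list(drug = dr, tag = NA_character_,
           kind = if (sp$dose_model == "linear") "slope" else "emax")
    slot_of[base_rows] <- length(slot_defs)
    if (sp$dose_model == "linear") {
      dose_mult[rows] <- d$dose_amount[rows]
    } else {
      dose_mult[rows] <- as.numeric(d$dose_amount[rows] > 0)
    }
    if (!is.na(sp$onset)) {
      onset_grp[rows] <- sp$onset
    } else if (!is.na(sp$k_onset)) {
      static_onset[rows] <- 1 - exp(-sp$k_onset * t[rows])
    }
  }
  onset_names <- unique(onset_grp[!is.na(onset_grp)])
  onset_rows <- lapply(onset_names, function(nm) which(onset_grp == nm))
  names(onset_rows) <- onset_names
  drug_row_any <- which(!is.na(slot_of))

  function(model) {
    # placebo part
    if (pl_form == "exponential") {
      A_adj <- apply_terms(rep(model$placebo$A, nrec), pbo_terms, model)
      e0 <- model$placebo$B + A_adj * (1 - exp(-model$placebo$k_pbo * t))
    } else {
      e0 <- drop(X %*% model$placebo$coeffs)
      e0 <- apply_terms(e0, pbo_terms, model)
    }
    if (!length(drug_row_any)) return(e0)
    # drug part
    slot_val <- vapply(slot_defs, function(s) {
      sp <- model$drugs[[s$drug]]
      switch(s$kind,
             override = sp$regimen_overrides[[s$tag]],
             slope = sp$slope,
             emax = sp$Emax)
    }, 0)
    val <- rep(0, nrec)
    val[drug_row_any] <- slot_val[slot_of[drug_row_any]]
    val <- apply_terms(val, drug_terms, model)
    ofac <- static_onset
    for (nm in onset_names) {
      rows <- onset_rows[[nm]]
      ofac[rows] <- 1 - exp(-model$onset_rates[[nm]] * t[rows])
    }
    e0 + ofac * val * dose_mult
  }
}

#' Marginal log-likelihood over the between-arm random effect
#'
#' Integrates the conditional binomial likelihood over the arm-level
#' Gaussian random effect `eta ~ N(0, omega2)` by adaptive Gauss-Hermite
#' quadrature (per-arm mode and curvature re-centre the nodes). With
#' `omega2 = 0` this reduces exactly to [binomial_loglik()] at `eta = 0`.
#'
#' @inheritParams binomial_loglik
#' @param cfg an [objective_config()].
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(records, arms, model,
                            cfg = objective_config()) {
  if (model$omega2 < 0) stop("omega2 must be >= 0")
  d <- .prepare_data(records, arms)
  .marginal_ll(d, model, cfg$quad_points, cfg$prob_floor)
}

#' Weighted-normal objective for observed proportions
#'
#' Gaussian log-likelihood of the observed response proportions with
#' standard deviation `sigma * sqrt(P (1 - P) / N)` (the binomial standard
#' error scaled by a free residual parameter), an approximation that
#' weights arms by size and shrinks the residual at extreme predicted
#' probabilities. When the model's `autocorr` is `"ar1"` or `"cs"`, visits
#' within an arm are correlated (`rho^|i-j|` by visit order, or constant
#' `rho`).
#'
#' @inheritParams binomial_loglik
#' @return scalar log-likelihood.
#' @export
weighted_normal_objective <- function(records, arms, model) {
  d <- .prepare_data(records, arms)
  lp <- .linear_predictor(d, model)
  P <- stats::plogis(lp)
  y <- d$n_response / d$n_total
  sdv <- model$sigma * sqrt(P * (1 - P) / d$n_total)
  if (any(sdv <= 0)) stop("degenerate residual standard deviation")
  r <- y - P
  if (model$autocorr == "none" || abs(model$rho) < 1e-12) {
    return(sum(stats::dnorm(r, 0, sdv, log = TRUE)))
  }
  ll <- 0
  for (a in split(seq_len(nrow(d)), d$arm_idx)) {
    Tn <- length(a)
    R <- if (model$autocorr == "ar1") {
      model$rho^abs(outer(seq_len(Tn), seq_len(Tn), `-`))
    } else {
      matrix(model$rho, Tn, Tn) + diag(1 - model$rho, Tn)
    }
    S <- R * tcrossprod(sdv[a])
    ch <- tryCatch(chol(S), error = function(e)
      stop("singular residual covariance for arm ", attr(d, "arm_ids")[
        d$arm_idx[a[1]]]))
    z <- backsolve(ch, r[a], transpose = TRUE)
    ll <- ll - 0.5 * (Tn * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  ll
}

# ---- free-parameter packing ------------------------------------------------

.get_path <- function(x, path) Reduce(function(a, k) a[[k]], path, x)

.set_path <- function(x, path, value) {
  if (length(path) == 1) {
    x[[path[[1]]]] <- value
  } else {
    x[[path[[1]]]] <- .set_path(x[[path[[1]]]], path[-1], value)
  }
  x
}

# enumerate the free parameters of a spec under a config: name, path into
# the spec list, and box bounds. k-type rates are bounded in (1e-4, 10).
.free_params <- function(spec, cfg = objective_config()) {
  slots <- list()
  add <- function(name, path, lower, upper)
    slots[[length(slots) + 1]] <<- list(name = name, path = path,
                                        lower = lower, upper = upper)
  pl <- spec$placebo
  if (pl$form == "exponential") {
    add("B", list("placebo", "B"), -300, 100)
    add("A", list("placebo", "A"), -100, 400)
    add("k_pbo", list("placebo", "k_pbo"), 1e-4, 10)
  } else {
    for (i in seq_along(pl$coeffs))
      add(paste0("pbo_c", i), list("placebo", "coeffs", i), -100, 100)
  }
  for (dr in names(spec$drugs)) {
    ds <- spec$drugs[[dr]]
    if (ds$dose_model == "linear") {
      add(paste0("slope_", dr), list("drugs", dr, "slope"), -5, 5)
    } else {
      add(paste0("emax_", dr), list("drugs", dr, "Emax"), -20, 20)
      if (ds$dose_model == "emax")
        add(paste0("ed50_", dr), list("drugs", dr, "ED50"), 1e-6, 1e4)
    }
    for (tag in names(ds$regimen_overrides))
      add(paste0("emax_", dr, "_", tag),
          list("drugs", dr, "regimen_overrides", tag), -20, 20)
  }
  for (nm in names(spec$onset_rates))
    add(paste0("k_onset_", nm), list("onset_rates", nm), 1e-4, 10)
  for (i in seq_along(spec$covariate_effects)) {
    e <- spec$covariate_effects[[i]]
    add(paste0("theta_", e$covariate, "_", e$target, i),
        list("covariate_effects", i, "theta"), -100, 100)
  }
  if (cfg$likelihood == "binomial") {
    add("omega2", list("omega2"), 0, 5)
  } else {
    add("sigma", list("sigma"), 1e-3, 100)
    if (spec$autocorr != "none") add("rho", list("rho"), -0.99, 0.99)
  }
  keep <- !vapply(slots, function(s) s$name %in% cfg$fixed_params, TRUE)
  slots[keep]
}

.slot_values <- function(spec, slots)
  setNames(vapply(slots, function(s) .get_path(spec, s$path), 0),
           vapply(slots, `[[`, "", "name"))

.apply_params <- function(spec, slots, par) {
  for (i in seq_along(slots)) spec <- .set_path(spec, slots[[i]]$path, par[i])
  spec
}

# ---- fitting ---------------------------------------------------------------

#' Fit an endpoint model by maximum likelihood
#'
#' Maximises the marginal binomial likelihood (or the weighted-normal
#' objective) with a bounded quasi-Newton optimizer and jittered restarts.
#' Wald 95% intervals are derived from the inverse Hessian when it is
#' positive semi-definite. Deterministic given `cfg$seed` and `init`.
#'
#' @param records,arms dataset tables.
#' @param init a `uc_model_spec` providing the structure and starting
#'   values.
#' @param cfg an [objective_config()].
#' @return an object of class `uc_fit`: the updated spec (`$model`),
#'   `$par` (named estimates), `$loglik`, `$n_params`, `$aic`, `$vcov`,
#'   `$cis`, `$converged`, `$n_obs`, and the per-restart `$trace`.
#' @export
fit_model <- function(records, arms, init, cfg = objective_config()) {
  validate_model_spec(init)
  d <- .prepare_data(records, arms)
  slots <- .free_params(init, cfg)
  if (!length(slots)) stop("no free parameters to estimate")
  if (nrow(d) < length(slots))
    warning("fewer observations (", nrow(d), ") than free parameters (",
            length(slots), "); the model is likely unidentifiable")
  lower <- vapply(slots, `[[`, 0, "lower")
  upper <- vapply(slots, `[[`, 0, "upper")
  start <- pmin(pmax(.slot_values(init, slots), lower), upper)

  lp_fun <- .compile_lp(d, init)
  negll <- function(par) {
    spec <- .apply_params(init, slots, par)
    ll <- tryCatch({
      if (cfg$likelihood == "binomial") {
        as.numeric(.marginal_ll(d, spec, cfg$quad_points, cfg$prob_floor,
                                lp = lp_fun(spec)))
      } else weighted_normal_objective(records, arms, spec)
    }, error = function(e) NA_real_)
    if (!is.finite(ll)) 1e10 else -ll
  }

  set.seed(cfg$seed)
  starts <- list(start)
  if (cfg$n_restarts > 1) {
    for (r in seq_len(cfg$n_restarts - 1)) {
      jit <- start + stats::rnorm(length(start)) * cfg$jitter_sd *
        pmax(abs(start), 0.1)
      starts[[r + 1]] <- pmin(pmax(jit, lower), upper)
    }
  }
  factr <- max(cfg$tol / .Machine$double.eps, 10)
  # forward-difference gradient: n + 1 objective calls per gradient instead
  # of the optimizer's central differences (2n)
  grad <- function(par) {
    f0 <- negll(par)
    vapply(seq_along(par), function(j) {
      hj <- 1e-6 * max(abs(par[j]), 1e-2)
      pj <- par
      pj[j] <- min(par[j] + hj, upper[j])
      if (pj[j] == par[j]) {
        pj[j] <- max(par[j] - hj, lower[j])
        if (pj[j] == par[j]) return(0)
      }
      (negll(pj) - f0) / (pj[j] - par[j])
    }, 0)
  }
  fits <- lapply(starts, function(s0) {
    tryCatch(
      stats::optim(s0, negll, gr = grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = cfg$maxit, factr = factr,
                                  parscale = pmax(abs(s0), 0.05))),
      error = function(e) list(par = s0, value = Inf, convergence = 99,
                               message = conditionMessage(e))
    )
  })
  vals <- vapply(fits, `[[`, 0, "value")
  best <- fits[[which.min(vals)]]
  converged <- best$convergence == 0 && is.finite(best$value) &&
    best$value < 1e9
  par <- setNames(best$par, names(start))
  model <- .apply_params(init, slots, par)
  loglik <- -best$value
  n_par <- length(par)

  vcov <- NULL; cis <- NULL
  if (cfg$compute_vcov && converged) {
    H <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc) && all(eigen(vc, symmetric = TRUE,
                                    only.values = TRUE)$values > -1e-8)) {
        dimnames(vc) <- list(names(par), names(par))
        vcov <- vc
        se <- sqrt(pmax(diag(vc), 0))
        cis <- data.frame(
          parameter = names(par), estimate = unname(par), se = se,
          lower = unname(par) - 1.96 * se, upper = unname(par) + 1.96 * se,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  trace <- data.frame(
    restart = seq_along(fits),
    value = vals,
    convergence = vapply(fits, `[[`, 0, "convergence"),
    stringsAsFactors = FALSE
  )
  structure(
    list(model = model, par = par, loglik = loglik, n_params = n_par,
         aic = -2 * loglik + 2 * n_par, vcov = vcov, cis = cis,
         converged = converged, n_obs = nrow(d), trace = trace,
         cfg = cfg, slots = slots),
    class = "uc_fit"
  )
}

#' @export
coef.uc_fit <- function(object, ...) object$par

#' @export
logLik.uc_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' @export
print.uc_fit <- function(x, ...) {
  cat("<uc_fit>", x$model$endpoint, "endpoint |",
      x$n_obs, "observations |", x$n_params, "parameters\n")
  cat(sprintf("  logLik = %.3f  AIC = %.3f  converged = %s\n",
              x$loglik, x$aic, x$converged))
  if (!is.null(x$cis)) {
    tab <- x$cis
    tab$estimate <- signif(tab$estimate, 4)
    tab$lower <- signif(tab$lower, 4); tab$upper <- signif(tab$upper, 4)
    print(tab[, c("parameter", "estimate", "lower", "upper")],
          row.names = FALSE)
  } else {
    print(signif(x$par, 4))
  }
  invisible(x)
}

#' Likelihood-ratio and AIC comparison of two fits
#'
#' `fit_b` must nest `fit_a` (checked by parameter-name subset); the LRT
#' statistic is `2 * (logLik_b - logLik_a)` on `df = n_params_b -
#' n_params_a` degrees of freedom. Non-nested pairs are compared by AIC
#' only.
#'
#' @param fit_a,fit_b `uc_fit` objects (`fit_a` the smaller model).
#' @return a list with `lrt`, `df`, `p_value` (NA when non-nested),
#'   `delta_aic` (`aic_b - aic_a`) and `nested`.
#' @export
compare_models <- function(fit_a, fit_b) {
  nested <- all(names(fit_a$par) %in% names(fit_b$par))
  out <- list(nested = nested,
              delta_aic = fit_b$aic - fit_a$aic,
              lrt = NA_real_, df = NA_integer_, p_value = NA_real_)
  if (nested) {
    out$lrt <- 2 * (fit_b$loglik - fit_a$loglik)
    out$df <- fit_b$n_params - fit_a$n_params
    out$p_value <- if (out$df == 0) {
      if (abs(out$lrt) <= 1e-8) 1 else NA_real_
    } else {
      stats::pchisq(out$lrt, out$df, lower.tail = FALSE)
    }
  } else {
    warning("models are not nested; AIC comparison only")
  }
  class(out) <- "uc_model_comparison"
  out
}

#' @export
print.uc_model_comparison <- function(x, ...) {
  cat("<model comparison>\n")
  if (x$nested)
    cat(sprintf("  LRT = %.4f on %d df, p = %.4g\n", x$lrt, x$df, x$p_value))
  cat(sprintf("  delta AIC (b - a) = %.3f\n", x$delta_aic))
  invisible(x)
}

#' Forward stepwise covariate selection
#'
#' At each round every remaining candidate effect is added to the current
#' model (starting at `theta = 0`) and refitted; the candidate with the
#' smallest likelihood-ratio p-value is accepted if `p < alpha` and the
#' AIC improves, otherwise selection stops. Candidate fits that fail to
#' converge are skipped with a warning.
#'
#' @param records,arms dataset tables.
#' @param base a `uc_model_spec` without the candidate effects.
#' @param candidates list of [covariate_effect()] objects.
#' @param cfg an [objective_config()].
#' @param alpha acceptance p-value threshold.
#' @return a list with `fit` (the final `uc_fit`) and `selection` (a log
#'   with one row per candidate fit).
#' @export
stepwise_covariates <- function(records, arms, base, candidates,
                                cfg = objective_config(), alpha = 0.05) {
  lab <- function(e) paste(e$covariate, e$target, e$form, sep = ":")
  current <- fit_model(records, arms, base, cfg)
  remaining <- candidates
  log_rows <- list()
  round_i <- 0
  while (length(remaining)) {
    round_i <- round_i + 1
    trial_fits <- vector("list", length(remaining))
    stats_df <- data.frame(p = rep(NA_real_, length(remaining)),
                           aic = NA_real_)
    for (i in seq_along(remaining)) {
      cand <- remaining[[i]]
      cand$theta <- 0
      spec_i <- current$model
      spec_i$covariate_effects <- c(spec_i$covariate_effects, list(cand))
      fit_i <- tryCatch(fit_model(records, arms, spec_i, cfg),
                        error = function(e) NULL)
      ok <- !is.null(fit_i) && fit_i$converged
      if (!ok) {
        warning("candidate ", lab(remaining[[i]]),
                " failed to converge; skipped")
      } else {
        cmp <- compare_models(current, fit_i)
        stats_df$p[i] <- cmp$p_value
        stats_df$aic[i] <- fit_i$aic
        trial_fits[[i]] <- fit_i
      }
      log_rows[[length(log_rows) + 1]] <- data.frame(
        round = round_i, candidate = lab(remaining[[i]]),
        converged = ok,
        loglik = if (ok) fit_i$loglik else NA_real_,
        aic = if (ok) fit_i$aic else NA_real_,
        p_value = stats_df$p[i], accepted = FALSE,
        stringsAsFactors = FALSE
      )
    }
    usable <- which(is.finite(stats_df$p))
    if (!length(usable)) break
    ibest <- usable[which.min(stats_df$p[usable])]
    if (stats_df$p[ibest] < alpha && stats_df$aic[ibest] < current$aic) {
      current <- trial_fits[[ibest]]
      n <- length(log_rows)
      log_rows[[n - length(remaining) + ibest]]$accepted <- TRUE
      remaining <- remaining[-ibest]
    } else break
  }
  list(fit = current,
       selection = do.call(rbind, log_rows) %||%
         data.frame(round = integer(), candidate = character(),
                    converged = logical(), loglik = numeric(),
                    aic = numeric(), p_value = numeric(),
                    accepted = logical()))
}
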