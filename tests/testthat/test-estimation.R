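# a model whose linear predictor is a constant logit, for closed-form checks
const_spec <- function(p, omega2 = 0, sigma = 1) {
  model_spec(
    endpoint = "remission",
    placebo = placebo_spec("exponential", B = logit(p), A = 0, k_pbo = 1),
    omega2 = omega2, sigma = sigma
  )
}

const_data <- function(n_total, n_response, times = 8, trial = "t1",
                       arm = "pbo") {
  list(
    records = data.frame(trial_id = trial, arm_id = arm,
                         endpoint = "remission", time = times,
                         n_total = n_total, n_response = n_response),
    arms = data.frame(trial_id = trial, arm_id = arm, drug = "placebo",
                      dose_amount = 0, dose_unit = "mg",
                      regimen_tag = "placebo")
  )
}

test_that("binomial log-likelihood matches direct and enumerated values", {
  dd <- const_data(10, 5)
  ll <- binomial_loglik(dd$records, dd$arms, const_spec(0.5), eta_by_arm = 0)
  expect_equal(ll, log(choose(10, 5)) - 10 * log(2))
  expect_equal(ll, -1.402, tolerance = 1e-3)

  # n = 0 with P -> 0: contribution vanishes
  dd0 <- const_data(50, 0)
  ll0 <- suppressWarnings(
    binomial_loglik(dd0$records, dd0$arms, const_spec(1e-12),
                    eta_by_arm = 0))
  expect_lt(abs(ll0), 1e-4)

  # exhaustive enumeration oracle over all binary outcome sequences, N <= 5
  enum_pmf <- function(n, N, p) {
    seqs <- expand.grid(rep(list(0:1), N))
    sum(apply(seqs, 1, function(s)
      if (sum(s) == n) prod(ifelse(s == 1, p, 1 - p)) else 0))
  }
  set.seed(7)
  recs <- data.frame(
    trial_id = "t1", arm_id = rep(c("a", "b", "c"), each = 2),
    endpoint = "remission", time = rep(c(4, 8), 3),
    n_total = c(5, 5, 4, 4, 3, 3), n_response = c(1, 3, 0, 2, 3, 1)
  )
  arms <- data.frame(trial_id = "t1", arm_id = c("a", "b", "c"),
                     drug = "placebo", dose_amount = 0, dose_unit = "mg",
                     regimen_tag = "placebo")
  spec <- const_spec(0.35)
  p <- 0.35
  oracle <- sum(mapply(function(n, N) log(enum_pmf(n, N, p)),
                       recs$n_response, recs$n_total))
  expect_equal(binomial_loglik(recs, arms, spec, eta_by_arm = 0), oracle)
  # and the omega2 = 0 marginal likelihood is that same conditional value
  expect_equal(marginal_loglik(recs, arms, spec), oracle)
})

test_that("Gauss-Hermite rule integrates polynomials exactly", {
  gh <- ucmbma:::gauss_hermite(9)
  exact <- function(k) if (k %% 2 == 1) 0 else gamma((k + 1) / 2)
  for (k in 0:16)
    expect_equal(sum(gh$weights * gh$nodes^k), exact(k), tolerance = 1e-8)
})

test_that("marginal likelihood matches numeric integration and converges", {
  spec <- const_spec(0.3, omega2 = 0.5)
  dd <- const_data(1, 1)
  oracle <- log(stats::integrate(function(e)
    stats::plogis(logit(0.3) + e) * stats::dnorm(e, 0, sqrt(0.5)),
    -Inf, Inf, rel.tol = 1e-10)$value)
  got <- marginal_loglik(dd$records, dd$arms, spec)
  expect_equal(as.numeric(got), oracle, tolerance = 1e-6)

  # a harder arm: several visits, moderate counts
  dd2 <- const_data(30, c(4, 9, 12), times = c(2, 6, 10))
  ll_arm <- function(e, spec) {
    p <- stats::plogis(logit(0.3) + e)
    exp(sum(dbinom(c(4, 9, 12), 30, p, log = TRUE))) *
      stats::dnorm(e, 0, sqrt(0.5))
  }
  oracle2 <- log(stats::integrate(function(e)
    vapply(e, ll_arm, 0, spec = spec), -Inf, Inf, rel.tol = 1e-12)$value)
  got2 <- marginal_loglik(dd2$records, dd2$arms, spec)
  expect_equal(as.numeric(got2), oracle2, tolerance = 1e-6)

  # quadrature convergence: 7 vs 15 points nearly identical
  g <- mini_dataset(seed = 11)
  l7 <- marginal_loglik(g$records, g$arms, mini_spec(),
                        objective_config(quad_points = 7))
  l15 <- marginal_loglik(g$records, g$arms, mini_spec(),
                         objective_config(quad_points = 15))
  expect_lt(abs(as.numeric(l7) - as.numeric(l15)), 1e-4)
})

test_that("weighted-normal objective uses binomial-standard-error weights", {
  dd <- const_data(100, 53)
  spec <- const_spec(0.5, sigma = 2)
  # residual sd = sigma * sqrt(0.25 / 100) = sigma * 0.05
  expect_equal(weighted_normal_objective(dd$records, dd$arms, spec),
               dnorm(0.53 - 0.5, 0, 2 * 0.05, log = TRUE))
  dd2 <- const_data(64, 13)
  spec2 <- const_spec(0.2, sigma = 1)
  expect_equal(weighted_normal_objective(dd2$records, dd2$arms, spec2),
               dnorm(13 / 64 - 0.2, 0, sqrt(0.2 * 0.8 / 64), log = TRUE))
  # rho = 0 reproduces the independent-residual objective exactly
  dd3 <- const_data(40, c(6, 9, 11), times = c(2, 6, 10))
  s_ind <- const_spec(0.25)
  s_ar1 <- const_spec(0.25); s_ar1$autocorr <- "ar1"; s_ar1$rho <- 0
  expect_equal(weighted_normal_objective(dd3$records, dd3$arms, s_ar1),
               weighted_normal_objective(dd3$records, dd3$arms, s_ind))
  # and a nonzero correlation changes it
  s_ar1$rho <- 0.5
  expect_false(isTRUE(all.equal(
    weighted_normal_objective(dd3$records, dd3$arms, s_ar1),
    weighted_normal_objective(dd3$records, dd3$arms, s_ind))))
})

test_that("additive covariate likelihood is shift-invariant", {
  eff <- covariate_effect("duration", "drug", "additive",
                          theta = 0.25, cov_mean = 7)
  spec <- mini_spec(covariate_effects = list(eff))
  g <- mini_dataset(seed = 21)
  l1 <- marginal_loglik(g$records, g$arms, spec)
  g2 <- g
  g2$arms$duration <- g2$arms$duration + 3
  spec2 <- spec
  spec2$covariate_effects[[1]]$cov_mean <- 10
  l2 <- marginal_loglik(g2$records, g2$arms, spec2)
  expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-10)
})

test_that("fitting is deterministic and scales errors like sqrt(n)", {
  g <- mini_dataset(seed = 31)
  cfg <- objective_config(n_restarts = 2, compute_vcov = TRUE, seed = 5)
  f1 <- fit_model(g$records, g$arms, mini_spec(), cfg)
  f2 <- fit_model(g$records, g$arms, mini_spec(), cfg)
  expect_identical(f1$par, f2$par)
  expect_true(f1$converged)
  expect_equal(f1$aic, -2 * f1$loglik + 2 * f1$n_params)
  expect_false(is.null(f1$cis))

  # doubling all arm sizes shrinks standard errors by about sqrt(2); the
  # information scaling is exact in the no-heterogeneity limit, so fit
  # with the between-arm variance held at zero
  spec0 <- mini_spec(omega2 = 0)
  cfg0 <- objective_config(n_restarts = 1, compute_vcov = TRUE,
                           fixed_params = "omega2")
  g0 <- suppressMessages(generate_dataset(mini_design(), spec0, seed = 32))
  g2 <- g0
  g2$records$n_total <- g2$records$n_total * 2L
  g2$records$n_response <- g2$records$n_response * 2L
  fa <- fit_model(g0$records, g0$arms, spec0, cfg0)
  fb <- fit_model(g2$records, g2$arms, spec0, cfg0)
  se1 <- fa$cis$se[fa$cis$parameter == "emax_infliximab"]
  se2 <- fb$cis$se[fb$cis$parameter == "emax_infliximab"]
  expect_equal(se1 / se2, sqrt(2), tolerance = 0.12)
})

test_that("the weighted-normal objective also recovers the drug effect", {
  g <- mini_dataset(seed = 41)
  cfg <- objective_config(likelihood = "weighted_normal", n_restarts = 1,
                          compute_vcov = FALSE)
  fit <- fit_model(g$records, g$arms, mini_spec(), cfg)
  expect_true(fit$converged)
  expect_lt(abs(fit$par[["emax_infliximab"]] - 1.2), 0.4)
  expect_true("sigma" %in% names(fit$par))
  expect_false("omega2" %in% names(fit$par))
  # with AR1 autocorrelation the correlation parameter is estimated too
  s2 <- mini_spec(); s2$autocorr <- "ar1"; s2$rho <- 0.2
  fit2 <- fit_model(g$records, g$arms, s2, cfg)
  expect_true(fit2$converged)
  expect_true("rho" %in% names(fit2$par))
  expect_lt(abs(fit2$par[["rho"]]), 0.99)
})

test_that("Wald intervals cover a null drug effect at the nominal rate", {
  spec0 <- mini_spec()
  spec0$drugs$infliximab$Emax <- 0
  cfg <- objective_config(n_restarts = 1, compute_vcov = TRUE)
  covered <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    g <- suppressMessages(generate_dataset(mini_design(n_trials = 4),
                                           spec0, seed = 400 + r))
    fit <- fit_model(g$records, g$arms, spec0, cfg)
    ci <- fit$cis[fit$cis$parameter == "emax_infliximab", ]
    if (!is.null(fit$cis) && ci$lower <= 0 && ci$upper >= 0)
      covered <- covered + 1L
  }
  # P(X >= 16 | n = 20, p = 0.95) > 0.997
  expect_gte(covered, 16L)
})

test_that("model comparison reports LRT, df, p and AIC differences", {
  f_small <- list(par = c(a = 1), loglik = -100, n_params = 1, aic = 202)
  f_big <- list(par = c(a = 1, b = 2), loglik = -97, n_params = 2,
                aic = 198)
  class(f_small) <- class(f_big) <- "uc_fit"
  cmp <- compare_models(f_small, f_big)
  expect_equal(cmp$lrt, 6)
  expect_equal(cmp$df, 1)
  expect_equal(cmp$p_value, pchisq(6, 1, lower.tail = FALSE))
  expect_equal(cmp$p_value, 0.0143, tolerance = 1e-3)
  # AIC difference = -2 dloglik + 2 dparams by construction
  expect_equal(cmp$delta_aic, -cmp$lrt + 2 * cmp$df)
  # identical fits
  cmp2 <- compare_models(f_small, f_small)
  expect_equal(cmp2$lrt, 0)
  expect_equal(cmp2$p_value, 1)
  # non-nested pair: AIC only
  f_other <- f_small; f_other$par <- c(z = 1)
  expect_warning(cmp3 <- compare_models(f_big, f_other), "not nested")
  expect_true(is.na(cmp3$p_value))
})

test_that("stepwise selection keeps the base model when no signal exists", {
  g <- mini_dataset(seed = 51)
  cands <- list(
    covariate_effect("age", "drug", "additive", theta = 0, cov_mean = 40)
  )
  out <- stepwise_covariates(g$records, g$arms, mini_spec(), cands,
                             fast_cfg(), alpha = 1e-6)
  expect_equal(length(out$fit$par), length(mini_spec_par <- fit_model(
    g$records, g$arms, mini_spec(), fast_cfg())$par))
  expect_equal(nrow(out$selection), 1)  # one candidate fit logged
  expect_false(any(out$selection$accepted))
})

test_that("stepwise selection finds a strong simulated covariate effect", {
  eff <- covariate_effect("duration", "drug", "additive",
                          theta = 0.5, cov_mean = 7)
  truth <- mini_spec(covariate_effects = list(eff))
  cands <- list(
    covariate_effect("duration", "drug", "additive", theta = 0,
                     cov_mean = 7),
    covariate_effect("age", "drug", "additive", theta = 0, cov_mean = 40)
  )
  hits <- 0L
  n_rep <- 6L
  for (r in seq_len(n_rep)) {
    g <- suppressMessages(generate_dataset(mini_design(), truth,
                                           seed = 600 + r))
    out <- stepwise_covariates(g$records, g$arms, mini_spec(), cands,
                               fast_cfg())
    first <- out$selection[out$selection$round == 1 &
                             out$selection$accepted, ]
    if (nrow(first) == 1 && grepl("duration", first$candidate))
      hits <- hits + 1L
    # likelihood never decreases along the accepted path
    expect_gte(out$fit$loglik,
               fit_model(g$records, g$arms, mini_spec(),
                         fast_cfg())$loglik - 1e-6)
  }
  expect_gte(hits, 5L)
})
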