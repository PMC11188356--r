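test_that("inverse_logit matches hand-computed values and inverts logit", {
  expect_equal(inverse_logit(0), 0.5)
  expect_equal(inverse_logit(-2.22), 1 / (1 + exp(2.22)))
  expect_equal(inverse_logit(-2.22), 0.0980, tolerance = 1e-3)
  p <- c(0.01, 0.3, 0.5, 0.97)
  expect_equal(inverse_logit(logit(p)), p)
  expect_error(inverse_logit(Inf), "finite")
})

test_that("exponential placebo follows B + A(1 - exp(-k t))", {
  ps <- placebo_spec("exponential", B = -39.26, A = 37.04, k_pbo = 0.66)
  expect_equal(placebo_effect(0, ps), -39.26)
  e8 <- placebo_effect(8, ps)
  expect_equal(e8, -39.26 + 37.04 * (1 - exp(-0.66 * 8)))
  expect_equal(e8, -2.41, tolerance = 1e-2)
  expect_equal(inverse_logit(e8), 0.082, tolerance = 1e-2)
  expect_equal(placebo_effect(1e6, ps), -39.26 + 37.04)  # asymptote B + A
  expect_error(placebo_effect(-1, ps), "t >= 0")
  # strictly increasing towards the asymptote for A, k > 0
  tt <- seq(0, 15, by = 0.5)
  expect_true(all(diff(placebo_effect(tt, ps)) > 0))
})

test_that("rcs basis has linear tails and curvature at interior knots", {
  knots <- c(2, 6, 14)
  B <- rcs_basis(c(0, 1, 20, 30), knots)
  expect_equal(dim(B), c(4, 2))
  # second differences vanish in the tails but not at an interior knot
  d2 <- function(t, j, h = 0.25) {
    b <- rcs_basis(c(t - h, t, t + h), knots)[, j]
    (b[1] - 2 * b[2] + b[3]) / h^2
  }
  expect_equal(d2(20, 2), 0, tolerance = 1e-8)
  expect_equal(d2(1, 2), 0, tolerance = 1e-8)
  expect_gt(abs(d2(6, 2)), 1e-3)
  expect_error(rcs_basis(1, knots = c(1, 2)), "3 knots")
  expect_error(rcs_basis(1, knots = c(2, 2, 5)), "increasing")
})

test_that("drug effects honour dose model, onset, and overrides", {
  flat <- drug_spec("infliximab", "emax_flat", Emax = 1.48)
  expect_equal(drug_effect("infliximab", 350, 8, flat), 1.48)
  expect_equal(drug_effect("infliximab", 700, 30, flat), 1.48)

  lin <- drug_spec("filgotinib", "linear", slope = 6.87e-3)
  expect_equal(drug_effect("filgotinib", 200, 8, lin), 1.374)
  expect_equal(drug_effect("filgotinib", 0, 8, lin), 0)
  # logit effect exactly proportional to dose
  doses <- c(50, 100, 200)
  eff <- drug_effect("filgotinib", doses, 8, lin)
  expect_equal(eff / doses, rep(6.87e-3, 3))

  onset <- drug_spec("tofacitinib", "emax_flat", Emax = 1, k_onset = 0.103)
  t90 <- log(10) / 0.103
  expect_equal(t90, 22.36, tolerance = 1e-2)
  expect_equal(drug_effect("tofacitinib", 10, t90, onset), 0.9)

  ov <- drug_spec("upadacitinib", "emax_flat", Emax = 0.234,
                  regimen_overrides = list(`45mg` = 2.90))
  expect_equal(drug_effect("upadacitinib", 45, 8, ov,
                           regimen_tag = "45mg"), 2.90)
  expect_equal(drug_effect("upadacitinib", 30, 8, ov,
                           regimen_tag = "30mg"), 0.234)

  expect_equal(drug_effect("placebo", 0, 8, NULL), 0)
  expect_error(drug_effect("aspirin", 100, 8, flat), "unknown drug")
})

test_that("covariate adjustment follows the additive and power formulas", {
  add <- covariate_effect("duration", "placebo", "additive",
                          theta = 0.695, cov_mean = 7.53)
  expect_equal(apply_covariate(37.04, 8.53, add), 37.735)
  expect_equal(apply_covariate(37.04, 7.53, add), 37.04)  # reference point
  pow <- covariate_effect("duration", "drug", "power",
                          theta = 0, cov_mean = 7.53)
  expect_equal(apply_covariate(5, 2.2, pow), 5)
  pow2 <- covariate_effect("duration", "drug", "power",
                           theta = -0.8, cov_mean = 7.53)
  expect_equal(apply_covariate(2, 15.06, pow2), 2 * 2^-0.8)
  expect_error(apply_covariate(2, -1, pow2), "cov_value > 0")
})

test_that("response_probability composes placebo, drug and eta", {
  spec <- uc_model_spec("remission")
  arm <- list(drug = "infliximab", dose_amount = 350,
              regimen_tag = "5mgkg", duration = 7.53)
  p <- response_probability(arm, 8, spec)
  expect_equal(p, 0.283, tolerance = 1e-3)
  pbo <- list(drug = "placebo", dose_amount = 0, duration = 7.53)
  expect_equal(response_probability(pbo, 8, spec),
               inverse_logit(placebo_effect(8, spec$placebo)),
               tolerance = 1e-12)
  # monotone in eta
  expect_gt(response_probability(arm, 8, spec, eta = 1), p)
  expect_true(all(response_probability(arm, c(0, 2, 8, 40), spec) > 0 &
                    response_probability(arm, c(0, 2, 8, 40), spec) < 1))
})

test_that("reference covariates reproduce the unadjusted model exactly", {
  for (ep in uc_endpoints) {
    spec <- uc_model_spec(ep)
    ref <- list(drug = "infliximab", dose_amount = 350,
                regimen_tag = "5mgkg", duration = 7.53, age = 41.2,
                prior_tnf_pct = 22.4, steroid_pct = 46.0)
    bare <- spec
    bare$covariate_effects <- list()
    arm0 <- list(drug = "infliximab", dose_amount = 350,
                 regimen_tag = "5mgkg")
    expect_equal(response_probability(ref, c(4, 12, 40), spec),
                 response_probability(arm0, c(4, 12, 40), bare),
                 tolerance = 1e-12)
  }
})

test_that("flat-Emax predictions are dose-independent for positive dose", {
  spec <- uc_model_spec("remission")
  arm1 <- list(drug = "vedolizumab", dose_amount = 300, duration = 7.53)
  arm2 <- list(drug = "vedolizumab", dose_amount = 108, duration = 7.53)
  expect_equal(response_probability(arm1, 10, spec),
               response_probability(arm2, 10, spec))
})

test_that("compiled linear predictor matches the generic evaluator", {
  for (ep in uc_endpoints) {
    spec <- uc_model_spec(ep)
    g <- suppressMessages(generate_dataset(
      perturb_design(paper_design(), 0.1), spec, seed = 5))
    d <- ucmbma:::.prepare_data(g$records, g$arms)
    lp_fast <- ucmbma:::.compile_lp(d, spec)(spec)
    lp_gen <- ucmbma:::.linear_predictor(d, spec)
    expect_equal(lp_fast, lp_gen, tolerance = 1e-12)
  }
})

test_that("model specs survive a YAML round trip", {
  spec <- uc_model_spec("response")
  f <- tempfile(fileext = ".yaml")
  write_model_spec(spec, f)
  spec2 <- read_model_spec(f)
  expect_equal(spec2$drugs$upadacitinib$regimen_overrides$`45mg`, 2.90)
  arm <- list(drug = "upadacitinib", dose_amount = 45, regimen_tag = "45mg",
              duration = 7, age = 40, prior_tnf_pct = 50, steroid_pct = 50)
  expect_equal(response_probability(arm, c(4, 12), spec2),
               response_probability(arm, c(4, 12), spec))
})
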