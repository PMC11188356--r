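test_that("ET90 has the closed form ln(10)/k on the onset-factor scale", {
  ds <- drug_spec("tofacitinib", "emax_flat", Emax = 1, k_onset = log(10))
  expect_equal(et90(ds), 1)
  jak <- drug_spec("tofacitinib", "emax_flat", Emax = 1.88, onset = "jak")
  expect_equal(et90(jak, onset_rates = c(jak = 0.103)), log(10) / 0.103)
  flat <- drug_spec("infliximab", "emax_flat", Emax = 1.48)
  expect_error(et90(flat), "no onset")
  rcs <- placebo_spec("rcs", knots = c(2, 6, 16), coeffs = c(-2, 0.3, -0.4))
  expect_error(et90(rcs), "no onset")
})

test_that("probability-scale ET90 solves P(t) = 0.9 P(inf)", {
  ps <- placebo_spec("exponential", B = -39.26, A = 37.04, k_pbo = 0.66)
  t90 <- et90(ps, scale = "probability")
  p_inf <- inverse_logit(-39.26 + 37.04)
  expect_equal(inverse_logit(placebo_effect(t90, ps)), 0.9 * p_inf,
               tolerance = 1e-6)
  expect_equal(t90, 8.733, tolerance = 1e-3)
  # onset-factor scale answers a different question for the same component
  expect_equal(et90(ps), log(10) / 0.66)
})

test_that("degenerate simulation reproduces deterministic predictions", {
  spec <- uc_model_spec("remission")
  pop <- population_profile()
  sim <- simulate_efficacy(spec, uncertainty = "none", pop = pop,
                           weeks = c(4, 12), n_draws = 50, seed = 1,
                           include_eta = FALSE)
  r <- sim$results
  arm <- list(drug = "infliximab", dose_amount = 700, regimen_tag = "10mgkg",
              duration = pop$duration, age = pop$age,
              prior_tnf_pct = pop$prior_tnf_pct,
              steroid_pct = pop$steroid_pct)
  expect_equal(r$median[r$treatment == "infliximab" & r$week == 12],
               response_probability(arm, 12, spec), tolerance = 1e-12)
  expect_equal(r$lo, r$hi, tolerance = 1e-12)  # no uncertainty, no bands
  pbo_arm <- list(drug = "placebo", dose_amount = 0,
                  duration = pop$duration, age = pop$age,
                  prior_tnf_pct = pop$prior_tnf_pct,
                  steroid_pct = pop$steroid_pct)
  expect_equal(unique(r$placebo_median[r$week == 4]),
               response_probability(pbo_arm, 4, spec), tolerance = 1e-12)
})

test_that("simulation bands contract as parameter uncertainty is removed", {
  spec <- mini_spec()
  vc <- diag(c(0.4, 0.4, 0.01, 0.05, 1e-4))
  slots <- ucmbma:::.free_params(spec, objective_config())
  dimnames(vc) <- list(vapply(slots, `[[`, "", "name"),
                       vapply(slots, `[[`, "", "name"))
  reg <- data.frame(treatment = "infliximab", drug = "infliximab",
                    dose = 350, regimen_tag = "5mgkg")
  sim_u <- simulate_efficacy(spec, uncertainty = vc, weeks = 12,
                             n_draws = 800, seed = 2, include_eta = FALSE,
                             regimens = reg)
  sim_0 <- simulate_efficacy(spec, uncertainty = "none", weeks = 12,
                             n_draws = 800, seed = 2, include_eta = FALSE,
                             regimens = reg)
  expect_gt(sim_u$results$hi - sim_u$results$lo, 0.02)
  expect_equal(sim_0$results$hi - sim_0$results$lo, 0)
  expect_equal(sim_u$results$median, sim_0$results$median,
               tolerance = 0.05)
})

test_that("ranking orders by placebo-corrected median with stable ties", {
  spec <- mini_spec()
  spec$drugs$adalimumab <- drug_spec("adalimumab", "emax_flat", Emax = 1.2)
  spec$drugs$vedolizumab <- drug_spec("vedolizumab", "emax_flat",
                                      Emax = 1.8)
  reg <- data.frame(
    treatment = c("infliximab", "adalimumab", "vedolizumab"),
    drug = c("infliximab", "adalimumab", "vedolizumab"),
    dose = c(350, 40, 300), regimen_tag = c("a", "b", "c"))
  sim <- simulate_efficacy(spec, uncertainty = "none", weeks = 12,
                           n_draws = 10, seed = 3, include_eta = FALSE,
                           regimens = reg)
  rk <- rank_treatments(sim, 12)
  expect_equal(rk$treatment[1], "vedolizumab")  # larger Emax ranks higher
  expect_true(all(rk$tied[rk$treatment != "vedolizumab"]))  # equal Emax tie
  expect_false(rk$tied[1])
  # tie broken lexically between the equal pair
  tied <- rk$treatment[rk$tied]
  expect_equal(tied, sort(tied))
  # permutation invariance
  sim2 <- simulate_efficacy(spec, uncertainty = "none", weeks = 12,
                            n_draws = 10, seed = 3, include_eta = FALSE,
                            regimens = reg[c(3, 1, 2), ])
  expect_equal(rank_treatments(sim2, 12)$treatment, rk$treatment)
  expect_error(rank_treatments(sim, 40), "not simulated")
})

test_that("single-treatment ranking and rank monotonicity in Emax", {
  spec <- mini_spec()
  reg <- data.frame(treatment = "infliximab", drug = "infliximab",
                    dose = 350, regimen_tag = "a")
  sim <- simulate_efficacy(spec, uncertainty = "none", weeks = 8,
                           n_draws = 5, seed = 1, include_eta = FALSE,
                           regimens = reg)
  expect_equal(nrow(rank_treatments(sim, 8)), 1)

  # increasing one drug's Emax never lowers its rank
  spec$drugs$adalimumab <- drug_spec("adalimumab", "emax_flat", Emax = 0.8)
  reg2 <- rbind(reg, data.frame(treatment = "adalimumab",
                                drug = "adalimumab", dose = 40,
                                regimen_tag = "b"))
  rank_of <- function(emax) {
    s <- spec
    s$drugs$adalimumab$Emax <- emax
    sim <- simulate_efficacy(s, uncertainty = "none", weeks = 8,
                             n_draws = 5, seed = 1, include_eta = FALSE,
                             regimens = reg2)
    rk <- rank_treatments(sim, 8)
    which(rk$treatment == "adalimumab")
  }
  expect_lte(rank_of(1.6), rank_of(0.8))
})
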