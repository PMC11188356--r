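# Shared fixtures: small specs, designs and datasets built in code.

# a compact remission-like spec with one drug, used for fast estimation tests
mini_spec <- function(omega2 = 0.04, covariate_effects = list()) {
  model_spec(
    endpoint = "remission",
    placebo = placebo_spec("exponential", B = -8, A = 6, k_pbo = 0.6),
    drugs = list(infliximab = drug_spec("infliximab", "emax_flat",
                                        Emax = 1.2)),
    covariate_effects = covariate_effects,
    omega2 = omega2
  )
}

# a small design: n_trials trials, each one infliximab arm + one placebo arm
mini_design <- function(n_trials = 6, n_per_arm = 150,
                        visits = c(2, 4, 8, 12)) {
  margins <- ucmbma:::.design_margins()
  trials <- list()
  for (i in seq_len(n_trials)) {
    tid <- paste0("mini-", i)
    trials[[tid]] <- list(
      trial_id = tid, maintenance = FALSE, visit_weeks = visits,
      arms = list(
        list(arm_id = paste0(tid, "-a1"), drug = "infliximab",
             dose_amount = 5, dose_unit = "mg_per_kg",
             regimen_tag = "5mgkg", n_total = n_per_arm),
        list(arm_id = paste0(tid, "-pbo"), drug = "placebo",
             dose_amount = 0, dose_unit = "mg", regimen_tag = "placebo",
             n_total = n_per_arm)
      )
    )
  }
  structure(list(trials = trials, covariates = margins),
            class = "uc_study_design")
}

mini_dataset <- function(seed = 1, ...) {
  suppressMessages(generate_dataset(mini_design(...), mini_spec(),
                                    seed = seed))
}

fast_cfg <- function(...) {
  objective_config(n_restarts = 1, compute_vcov = FALSE, ...)
}

# write a tiny valid CSV dataset and return its path
write_tiny_csv <- function(path = tempfile(fileext = ".csv")) {
  df <- data.frame(
    trial_id = c("t1", "t1", "t1"), arm_id = c("a1", "a1", "pbo"),
    drug = c("infliximab", "infliximab", "placebo"),
    dose_amount = c(5, 5, 0), dose_unit = c("mg_per_kg", "mg_per_kg", "mg"),
    regimen_tag = c("5mgkg", "5mgkg", "placebo"),
    endpoint = "remission", time_weeks = c(2, 8, 8),
    n_total = c(120, 120, 118), n_response = c(3, 30, 9),
    age = 40, weight = c(72, 72, NA), male_pct = 60, duration = 7,
    prior_tnf_pct = 0, steroid_pct = 50, baseline_activity = 8.5
  )
  write.csv(df, path, row.names = FALSE, na = "")
  path
}
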