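# End-to-end pipeline: generate/load -> impute -> fit -> covariate
# selection -> bootstrap -> VPC -> simulate -> rank, with a manifest tying
# every artifact to its seed.

#' Pipeline run configuration
#'
#' Either `data_path` (a CSV in the canonical schema) or synthetic mode
#' (`design` + `truth`) must be supplied, not both. One global seed fans
#' out to fixed per-stage child seeds so stages are individually
#' reproducible.
#'
#' @param endpoint one of [uc_endpoints], or `"all"`.
#' @param data_path CSV path (observed-data mode).
#' @param design,truth a `uc_study_design` and generating `uc_model_spec`
#'   (synthetic mode). In `"all"` mode `truth` may be `NULL`, in which
#'   case the packaged spec of each endpoint is used.
#' @param scale design scale fraction passed to [perturb_design()].
#' @param objective an [objective_config()].
#' @param candidates list of candidate [covariate_effect()]s for stepwise
#'   selection (empty to skip).
#' @param bootstrap_n,vpc_n,sim_draws stage sizes (the reference analysis
#'   used 1000 / 1000 / 10000).
#' @param population a [population_profile()].
#' @param weeks simulation grid; ranking is reported at `rank_week`.
#' @param rank_week headline comparison week (12 by default).
#' @param output_dir artifact directory (created if needed).
#' @param seed global integer seed.
#' @return an object of class `uc_run_config`.
#' @export
run_config <- function(endpoint, data_path = NULL, design = NULL,
                       truth = NULL, scale = 1,
                       objective = objective_config(),
                       candidates = list(),
                       bootstrap_n = 1000, vpc_n = 1000, sim_draws = 10000,
                       population = population_profile(), weeks = 1:60,
                       rank_week = 12, output_dir, seed = 1L) {
  endpoint <- match.arg(endpoint, c(uc_endpoints, "all"))
  synthetic <- !is.null(design)
  if (synthetic == !is.null(data_path))
    stop("specify exactly one of data_path or design (+ truth)")
  if (synthetic && is.null(truth) && endpoint != "all")
    stop("synthetic mode requires a generating truth spec")
  stopifnot(bootstrap_n >= 1, vpc_n >= 100, sim_draws >= 1)
  structure(
    list(endpoint = endpoint, data_path = data_path, design = design,
         truth = truth, scale = scale, objective = objective,
         candidates = candidates, bootstrap_n = bootstrap_n,
         vpc_n = vpc_n, sim_draws = sim_draws, population = population,
         weeks = weeks, rank_week = rank_week, output_dir = output_dir,
         seed = as.integer(seed)),
    class = "uc_run_config"
  )
}

.stage_seeds <- function(seed)
  c(generate = seed + 101L, fit = seed + 202L, bootstrap = seed + 303L,
    vpc = seed + 404L, simulate = seed + 505L)

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

.fit_artifact <- function(fit) {
  list(
    endpoint = fit$model$endpoint,
    estimates = as.list(fit$par),
    cis = fit$cis,
    loglik = fit$loglik, n_params = fit$n_params, aic = fit$aic,
    converged = fit$converged, n_obs = fit$n_obs
  )
}

#' Run the full analysis pipeline
#'
#' Executes generate/load, imputation, fitting, optional stepwise
#' covariate selection, bootstrap, VPC, Monte-Carlo simulation and
#' ranking, writing every intermediate artifact plus a `manifest.json`
#' recording seeds, file list and modelling assumptions. A stage failure
#' aborts with the stage name; artifacts of completed stages remain on
#' disk.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (class `uc_run_report`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "uc_run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- .stage_seeds(config$seed)
  endpoints <- if (config$endpoint == "all") uc_endpoints else config$endpoint
  manifest <- list(
    package_version = as.character(utils::packageVersion("ucmbma")),
    seed = config$seed, stage_seeds = as.list(seeds),
    endpoints = endpoints, files = character(),
    assumptions = list(
      covariate_forms = "as encoded per effect in the model spec",
      bootstrap_unit = "arm, stratified placebo/active",
      eta_in_simulation = TRUE,
      dose_reference_weight_kg = 70
    )
  )
  add_file <- function(f) manifest$files <<- c(manifest$files, basename(f))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  for (ep in endpoints) {
    pfx <- file.path(config$output_dir, ep)
    truth <- config$truth
    if (!is.null(config$design) && is.null(truth))
      truth <- uc_model_spec(ep)

    data <- stage("data", {
      if (!is.null(config$design)) {
        des <- perturb_design(config$design, config$scale)
        g <- generate_dataset(des, truth, seed = seeds[["generate"]])
        write_dataset(g$records, g$arms, paste0(pfx, "_dataset.csv"))
        add_file(paste0(pfx, "_dataset.csv"))
        g
      } else {
        load_dataset(config$data_path, ep)
      }
    })
    arms <- stage("impute", impute_covariates(data$arms, data$records))
    stage("summary", {
      utils::write.csv(summarize_dataset(arms, data$records),
                       paste0(pfx, "_summary.csv"), row.names = FALSE)
      add_file(paste0(pfx, "_summary.csv"))
    })

    init <- truth %||% uc_model_spec(ep)
    cfg <- config$objective
    cfg$seed <- seeds[["fit"]]
    fit <- stage("fit", fit_model(data$records, arms, init, cfg))
    if (length(config$candidates)) {
      sel <- stage("stepwise", stepwise_covariates(
        data$records, arms, fit$model, config$candidates, cfg))
      fit <- sel$fit
      utils::write.csv(sel$selection, paste0(pfx, "_stepwise.csv"),
                       row.names = FALSE)
      add_file(paste0(pfx, "_stepwise.csv"))
    }
    .write_json(.fit_artifact(fit), paste0(pfx, "_fit.json"))
    add_file(paste0(pfx, "_fit.json"))

    boot <- stage("bootstrap", bootstrap_model(
      data$records, arms, fit$model, cfg, n = config$bootstrap_n,
      seed = seeds[["bootstrap"]]))
    .write_json(list(
      n_requested = boot$n_requested, n_converged = boot$n_converged,
      medians = as.list(boot$medians),
      percentile_cis = as.data.frame(boot$percentile_cis),
      resampling_unit = boot$resampling_unit
    ), paste0(pfx, "_bootstrap.json"))
    add_file(paste0(pfx, "_bootstrap.json"))

    v <- stage("vpc", vpc(data$records, arms, fit$model,
                          n_sim = config$vpc_n, seed = seeds[["vpc"]]))
    .write_json(list(n_sim = v$n_sim, coverage = v$coverage,
                     bands = v$bands), paste0(pfx, "_vpc.json"))
    add_file(paste0(pfx, "_vpc.json"))

    resid <- stage("residuals",
                   residual_diagnostics(data$records, arms, fit$model))
    utils::write.csv(resid, paste0(pfx, "_residuals.csv"),
                     row.names = FALSE)
    add_file(paste0(pfx, "_residuals.csv"))

    sim <- stage("simulate", simulate_efficacy(
      fit, pop = config$population, weeks = config$weeks,
      n_draws = config$sim_draws, seed = seeds[["simulate"]]))
    utils::write.csv(sim$results, paste0(pfx, "_simulation.csv"),
                     row.names = FALSE)
    add_file(paste0(pfx, "_simulation.csv"))

    rk <- stage("rank", rank_treatments(sim, config$rank_week))
    utils::write.csv(rk, paste0(pfx, "_ranking.csv"), row.names = FALSE)
    add_file(paste0(pfx, "_ranking.csv"))
  }

  manifest$files <- c(manifest$files, "manifest.json")
  .write_json(manifest, file.path(config$output_dir, "manifest.json"))
  invisible(structure(manifest, class = "uc_run_report"))
}
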