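# Model specification objects: structural + stochastic parameterisation of
# one endpoint model. A spec is an ordinary named list of class
# "uc_model_spec" so that fitted values can be filled in by the estimator.

#' Drugs covered by the packaged models
#'
#' The twelve targeted agents of the source database plus placebo.
#' @export
uc_drugs <- c(
  "placebo", "infliximab", "adalimumab", "golimumab", "vedolizumab",
  "etrolizumab", "ustekinumab", "mirikizumab", "tofacitinib",
  "upadacitinib", "filgotinib", "ozanimod", "etrasimod"
)

#' Endpoints covered by the packaged models
#' @export
uc_endpoints <- c("remission", "response", "endoscopic")

# arm-level covariate columns understood by the covariate model
.uc_covariates <- c(
  "age", "weight", "male_pct", "duration",
  "prior_tnf_pct", "steroid_pct", "baseline_activity"
)

#' Placebo time-course specification
#'
#' The placebo effect `E0(t)` on the logit scale. Three functional forms are
#' supported: `exponential` `E0 = B + A * (1 - exp(-k_pbo * t))` (intercept
#' `B`, asymptote `A`, first-order rate `k_pbo` per week), `rcs` (restricted
#' cubic spline in time: intercept plus `length(knots) - 1` basis
#' coefficients), and `polynomial` (degree at most 3).
#'
#' @param form one of `"exponential"`, `"rcs"`, `"polynomial"`.
#' @param B,A,k_pbo exponential-form parameters; `k_pbo` must be positive.
#' @param coeffs numeric coefficients for `rcs` (intercept + basis) or
#'   `polynomial` (ascending powers of `t`, intercept first).
#' @param knots strictly increasing spline knots in weeks (`rcs` only,
#'   at least 3).
#' @return an object of class `uc_placebo_spec`.
#' @export
placebo_spec <- function(form = c("exponential", "rcs", "polynomial"),
                         B = NA_real_, A = NA_real_, k_pbo = NA_real_,
                         coeffs = NULL, knots = NULL) {
  form <- match.arg(form)
  out <- structure(
    list(form = form, B = B, A = A, k_pbo = k_pbo,
         coeffs = coeffs, knots = knots),
    class = "uc_placebo_spec"
  )
  validate_placebo_spec(out)
  out
}

validate_placebo_spec <- function(x) {
  if (x$form == "exponential") {
    if (any(is.na(c(x$B, x$A, x$k_pbo))))
      stop("exponential placebo requires B, A and k_pbo")
    if (x$k_pbo <= 0) stop("k_pbo must be > 0")
  } else if (x$form == "rcs") {
    if (is.null(x$knots) || length(x$knots) < 3)
      stop("rcs placebo requires >= 3 knots")
    if (any(diff(x$knots) <= 0)) stop("rcs knots must be strictly increasing")
    if (length(x$coeffs) != length(x$knots))
      stop("rcs placebo requires length(coeffs) == length(knots) ",
           "(intercept + ", length(x$knots) - 1, " basis terms)")
  } else {
    if (is.null(x$coeffs) || length(x$coeffs) < 2 || length(x$coeffs) > 4)
      stop("polynomial placebo requires 2-4 coefficients (degree <= 3)")
  }
  invisible(x)
}

#' Drug-effect specification
#'
#' The drug effect on the logit scale is `onset(t) * f(dose)` where
#' `onset(t) = 1 - exp(-k * t)` when an onset rate is attached (else 1, a
#' time-constant effect) and `f(dose)` is one of:
#' * `emax_flat`: `Emax` for any positive dose (ED50 fixed to 0; consistent
#'   efficacy across dose regimens),
#' * `emax`: `Emax * dose^gamma / (dose^gamma + ED50^gamma)` with the Hill
#'   coefficient `gamma` fixed to 1 unless overridden,
#' * `linear`: `slope * dose` (zero effect at dose 0).
#'
#' @param drug drug name (one of [uc_drugs], not `"placebo"`).
#' @param dose_model `"emax_flat"`, `"emax"`, or `"linear"`.
#' @param Emax maximum effect, logit scale.
#' @param ED50 dose (mg) achieving half the maximum effect (`emax` only).
#' @param gamma Hill coefficient; fixed to 1 by convention.
#' @param slope logit units per mg (`linear` only).
#' @param onset name of a shared onset rate in the model's `onset_rates`
#'   (e.g. `"jak"`), or `NA` for a time-constant effect.
#' @param k_onset drug-specific onset rate per week, used when `onset` is
#'   `NA`; `NA` means no onset term.
#' @param regimen_overrides named list mapping a `regimen_tag` to a separate
#'   `Emax` (e.g. the 45 mg upadacitinib regimen in the response model).
#' @return an object of class `uc_drug_spec`.
#' @export
drug_spec <- function(drug, dose_model = c("emax_flat", "emax", "linear"),
                      Emax = NA_real_, ED50 = 0, gamma = 1,
                      slope = NA_real_, onset = NA_character_,
                      k_onset = NA_real_, regimen_overrides = list()) {
  dose_model <- match.arg(dose_model)
  drug <- match.arg(drug, setdiff(uc_drugs, "placebo"))
  if (dose_model == "emax_flat" && ED50 != 0)
    stop("emax_flat requires ED50 = 0")
  if (dose_model == "linear" && is.na(slope))
    stop("linear dose model requires a slope")
  if (dose_model %in% c("emax_flat", "emax") && is.na(Emax))
    stop(dose_model, " requires Emax")
  structure(
    list(drug = drug, dose_model = dose_model, Emax = Emax, ED50 = ED50,
         gamma = gamma, slope = slope, onset = onset, k_onset = k_onset,
         regimen_overrides = regimen_overrides),
    class = "uc_drug_spec"
  )
}

#' Covariate-effect specification
#'
#' Adjusts a structural parameter for an arm-level covariate relative to a
#' reference mean, either additively
#' (`adjusted = base + (cov - cov_mean) * theta`) or as a power function
#' (`adjusted = base * (cov / cov_mean)^theta`, requiring `cov > 0`).
#'
#' @param covariate arm-level covariate column name (e.g. `"duration"`,
#'   `"prior_tnf_pct"`).
#' @param target `"placebo"` (the placebo asymptote `A` for the exponential
#'   form, or the whole `E0(t)` level for spline/polynomial forms) or
#'   `"drug"` (the `Emax`, or the slope of a linear dose model).
#' @param form `"additive"` or `"power"`.
#' @param theta effect coefficient.
#' @param cov_mean reference covariate mean; must be positive for the power
#'   form.
#' @param dose_models optional character vector restricting a drug-targeted
#'   effect to drugs with these dose models (e.g. `c("emax_flat", "emax")`);
#'   `NULL` applies to all drugs.
#' @return an object of class `uc_covariate_effect`.
#' @export
covariate_effect <- function(covariate, target = c("placebo", "drug"),
                             form = c("additive", "power"),
                             theta, cov_mean, dose_models = NULL) {
  target <- match.arg(target)
  form <- match.arg(form)
  covariate <- match.arg(covariate, .uc_covariates)
  if (form == "power" && cov_mean <= 0)
    stop("power-form covariate effect requires cov_mean > 0")
  structure(
    list(covariate = covariate, target = target, form = form,
         theta = theta, cov_mean = cov_mean, dose_models = dose_models),
    class = "uc_covariate_effect"
  )
}

#' Full endpoint model specification
#'
#' Bundles the placebo time-course, the per-drug effects, shared onset
#' rates, covariate adjustments and the stochastic components (between-arm
#' variance `omega2` of the logit-scale random effect, residual scale
#' `sigma` for the weighted-normal objective, optional within-arm
#' autocorrelation).
#'
#' @param endpoint one of [uc_endpoints].
#' @param placebo a [placebo_spec()].
#' @param drugs list of [drug_spec()] objects (named by drug, or names are
#'   derived).
#' @param onset_rates named numeric vector of shared onset rates per week
#'   (referenced by `drug_spec$onset`).
#' @param covariate_effects list of [covariate_effect()] objects.
#' @param omega2 between-arm variance of the additive logit random effect
#'   `eta` (>= 0).
#' @param sigma residual scale of the weighted-normal objective (> 0).
#' @param autocorr within-arm residual correlation structure for the
#'   weighted-normal objective: `"none"`, `"ar1"`, or `"cs"`.
#' @param rho correlation parameter (|rho| < 1) when `autocorr != "none"`.
#' @return an object of class `uc_model_spec`.
#' @export
model_spec <- function(endpoint, placebo, drugs = list(),
                       onset_rates = numeric(), covariate_effects = list(),
                       omega2 = 0, sigma = 1,
                       autocorr = c("none", "ar1", "cs"), rho = 0) {
  endpoint <- match.arg(endpoint, uc_endpoints)
  autocorr <- match.arg(autocorr)
  if (length(drugs) && is.null(names(drugs)))
    names(drugs) <- vapply(drugs, `[[`, "", "drug")
  out <- structure(
    list(endpoint = endpoint, placebo = placebo, drugs = drugs,
         onset_rates = onset_rates, covariate_effects = covariate_effects,
         omega2 = omega2, sigma = sigma, autocorr = autocorr, rho = rho),
    class = "uc_model_spec"
  )
  validate_model_spec(out)
  out
}

#' Validate a model specification
#' @param x a `uc_model_spec`.
#' @return the spec, invisibly; errors on violation.
#' @export
validate_model_spec <- function(x) {
  stopifnot(inherits(x, "uc_model_spec"))
  validate_placebo_spec(x$placebo)
  if (x$omega2 < 0) stop("omega2 must be >= 0")
  if (x$sigma <= 0) stop("sigma must be > 0")
  if (x$autocorr != "none" && abs(x$rho) >= 1)
    stop("|rho| must be < 1 when autocorrelation is used")
  for (d in x$drugs) {
    if (!is.na(d$onset) && !(d$onset %in% names(x$onset_rates)))
      stop("drug ", d$drug, " references unknown onset rate '", d$onset, "'")
  }
  invisible(x)
}

#' @export
print.uc_model_spec <- function(x, ...) {
  cat("<uc_model_spec>", x$endpoint, "endpoint\n")
  cat("  placebo:", x$placebo$form)
  if (x$placebo$form == "exponential")
    cat(sprintf(" (B=%.3g, A=%.3g, k_pbo=%.3g)",
                x$placebo$B, x$placebo$A, x$placebo$k_pbo))
  cat("\n  drugs:", length(x$drugs),
      " | onset rates:", length(x$onset_rates),
      " | covariate effects:", length(x$covariate_effects), "\n")
  cat(sprintf("  omega2=%.3g sigma=%.3g autocorr=%s\n",
              x$omega2, x$sigma, x$autocorr))
  invisible(x)
}

# ---- serialisation ---------------------------------------------------------

.spec_to_list <- function(spec) {
  spec$onset_rates <- as.list(spec$onset_rates)  # keep names in YAML maps
  lapply(unclass(spec), function(el) {
    if (inherits(el, "uc_placebo_spec")) unclass(el)
    else if (is.list(el)) lapply(el, function(e)
      if (inherits(e, c("uc_drug_spec", "uc_covariate_effect"))) unclass(e)
      else e)
    else el
  })
}

#' Write a model specification to YAML
#' @param spec a `uc_model_spec`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  validate_model_spec(spec)
  yaml::write_yaml(.spec_to_list(spec), path)
  invisible(path)
}

#' Read a model specification from YAML
#' @param path YAML file written by [write_model_spec()] (or hand-edited with
#'   the same keys).
#' @return a `uc_model_spec`.
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  pl <- y$placebo
  placebo <- placebo_spec(
    form = pl$form,
    B = pl$B %||% NA_real_, A = pl$A %||% NA_real_,
    k_pbo = pl$k_pbo %||% NA_real_,
    coeffs = if (!is.null(pl$coeffs)) as.numeric(pl$coeffs),
    knots = if (!is.null(pl$knots)) as.numeric(pl$knots)
  )
  num <- function(x, default = NA_real_)
    if (is.null(x)) default else as.numeric(x)
  drugs <- lapply(y$drugs, function(d) {
    drug_spec(
      drug = d$drug, dose_model = d$dose_model,
      Emax = num(d$Emax), ED50 = num(d$ED50, 0),
      gamma = num(d$gamma, 1), slope = num(d$slope),
      onset = d$onset %||% NA_character_,
      k_onset = num(d$k_onset),
      regimen_overrides = lapply(d$regimen_overrides %||% list(), as.numeric)
    )
  })
  effects <- lapply(y$covariate_effects, function(e) {
    covariate_effect(
      covariate = e$covariate, target = e$target, form = e$form,
      theta = num(e$theta), cov_mean = num(e$cov_mean),
      dose_models = if (!is.null(e$dose_models)) unlist(e$dose_models)
    )
  })
  onset <- vapply(y$onset_rates %||% list(), as.numeric, numeric(1))
  model_spec(
    endpoint = y$endpoint, placebo = placebo, drugs = drugs,
    onset_rates = onset,
    covariate_effects = effects,
    omega2 = num(y$omega2, 0), sigma = num(y$sigma, 1),
    autocorr = y$autocorr %||% "none", rho = num(y$rho, 0)
  )
}

#' Packaged endpoint models
#'
#' Returns the packaged parameter set for one endpoint: the final published
#' point estimates for the drug effects, onset rates, and covariate
#' coefficients, together with the packaged placebo time-course and
#' stochastic components. Quantities that the source tables do not print
#' (the spline placebo coefficients of the response and endoscopic models,
#' `omega2`, `sigma`) are calibrated package choices documented in the
#' methods vignette.
#'
#' @param endpoint one of [uc_endpoints].
#' @return a `uc_model_spec`.
#' @export
#' @examples
#' spec <- uc_model_spec("remission")
#' response_probability(
#'   list(drug = "infliximab", dose_amount = 350, regimen_tag = "5mgkg"),
#'   t = 8, model = spec)
uc_model_spec <- function(endpoint = uc_endpoints) {
  endpoint <- match.arg(endpoint)
  path <- system.file("extdata", paste0("parameters_", endpoint, ".yaml"),
                      package = "ucmbma", mustWork = TRUE)
  read_model_spec(path)
}
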