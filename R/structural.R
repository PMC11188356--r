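# Structural model: logit-scale placebo time-course, drug effect, covariate
# adjustment, and the probability-scale prediction that ties them together.

#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline basis (Harrell parameterisation):
#' linear in `t` beyond the boundary knots, continuous second derivative at
#' the interior knots. With `k` knots the basis has `k - 1` columns
#' (excluding the intercept): the linear term plus `k - 2` non-linear terms.
#'
#' @param t numeric vector of times (weeks).
#' @param knots strictly increasing knot locations (at least 3).
#' @return a `length(t) x (length(knots) - 1)` matrix.
#' @export
#' @examples
#' rcs_basis(c(0, 5, 30), knots = c(2, 6, 14))
rcs_basis <- function(t, knots) {
  if (length(knots) < 3) stop("rcs_basis() requires at least 3 knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  pp <- function(x) pmax(x, 0)^3
  B <- matrix(0, length(t), k - 1)
  B[, 1] <- t
  for (j in seq_len(k - 2)) {
    B[, j + 1] <- (pp(t - knots[j]) -
                     pp(t - tk1) * (tk - knots[j]) / (tk - tk1) +
                     pp(t - tk) * (tk1 - knots[j]) / (tk - tk1)) / (tk - t1)^2
  }
  colnames(B) <- c("t", if (k > 2) paste0("rcs", seq_len(k - 2)))
  B
}

#' Apply a covariate effect to a structural parameter
#'
#' Additive form: `base + (cov_value - cov_mean) * theta`. Power form:
#' `base * (cov_value / cov_mean)^theta` (requires `cov_value > 0`). At
#' `cov_value == cov_mean` both forms return `base` unchanged.
#'
#' @param base numeric parameter value(s).
#' @param cov_value covariate value(s), recycled against `base`.
#' @param effect a [covariate_effect()].
#' @return adjusted value(s).
#' @export
#' @examples
#' eff <- covariate_effect("duration", "placebo", "additive",
#'                         theta = 0.695, cov_mean = 7.53)
#' apply_covariate(37.04, 8.53, eff)  # 37.735
apply_covariate <- function(base, cov_value, effect) {
  if (effect$form == "additive") {
    base + (cov_value - effect$cov_mean) * effect$theta
  } else {
    if (any(cov_value <= 0))
      stop("power-form covariate effect requires cov_value > 0 (",
           effect$covariate, ")")
    base * (cov_value / effect$cov_mean)^effect$theta
  }
}

# Select the effects relevant for a target (and, for drug effects, a dose
# model), then apply them: power (multiplicative) effects first, additive
# shifts second. covs is a data.frame whose rows align with base.
.adjust_parameter <- function(base, covs, effects, target, dose_model = NULL) {
  if (!length(effects)) return(base)
  for (pass in c("power", "additive")) {
    for (e in effects) {
      if (e$target != target || e$form != pass) next
      if (target == "drug" && !is.null(e$dose_models) &&
          !(dose_model %in% e$dose_models)) next
      if (is.null(covs) || !(e$covariate %in% names(covs)))
        stop("covariate '", e$covariate, "' not available for adjustment")
      v <- covs[[e$covariate]]
      if (any(is.na(v)))
        stop("covariate '", e$covariate, "' has missing values; ",
             "impute before model evaluation")
      base <- apply_covariate(base, v, e)
    }
  }
  base
}

#' Placebo effect on the logit scale
#'
#' Evaluates `E0(t)`. For the exponential form,
#' `E0 = B + A_adj * (1 - exp(-k_pbo * t))` where the asymptote `A` carries
#' any placebo-targeted covariate adjustment. For the spline and polynomial
#' forms the basis is evaluated at `t` and covariate adjustments act on the
#' resulting `E0` level (additive shift or power scaling of the logit).
#'
#' @param t weeks since randomisation (vector, `>= 0`).
#' @param spec a [placebo_spec()].
#' @param covs optional data.frame (or list) of arm covariates; either one
#'   row (shared) or one row per element of `t`.
#' @param effects list of [covariate_effect()] objects (only
#'   `target == "placebo"` entries are used).
#' @return numeric vector of logit-scale placebo effects.
#' @export
#' @examples
#' ps <- placebo_spec("exponential", B = -39.26, A = 37.04, k_pbo = 0.66)
#' placebo_effect(8, ps)   # about -2.41
placebo_effect <- function(t, spec, covs = NULL, effects = list()) {
  if (any(t < 0)) stop("placebo_effect() requires t >= 0")
  validate_placebo_spec(spec)
  covs <- .as_cov_df(covs, length(t))
  if (spec$form == "exponential") {
    A_adj <- .adjust_parameter(rep(spec$A, length(t)), covs, effects, "placebo")
    spec$B + A_adj * (1 - exp(-spec$k_pbo * t))
  } else {
    X <- if (spec$form == "rcs") cbind(1, rcs_basis(t, spec$knots))
         else outer(t, seq_along(spec$coeffs) - 1, `^`)
    e0 <- drop(X %*% spec$coeffs)
    .adjust_parameter(e0, covs, effects, "placebo")
  }
}

.as_cov_df <- function(covs, n) {
  if (is.null(covs)) return(NULL)
  covs <- as.data.frame(covs, stringsAsFactors = FALSE)
  if (nrow(covs) == 1 && n > 1) covs <- covs[rep(1, n), , drop = FALSE]
  if (nrow(covs) != n)
    stop("covariate rows must be 1 or match length(t)")
  covs
}

#' Drug effect on the logit scale
#'
#' `E_drug(t, dose) = onset(t) * f(dose)` with `onset(t) = 1 - exp(-k * t)`
#' when an onset rate is present (else 1) and `f(dose)` given by the drug's
#' dose model (see [drug_spec()]). Regimen-specific `Emax` overrides are
#' consulted before the default. Drug-targeted covariate effects adjust the
#' `Emax` (or the slope of a linear model) before the onset multiplication.
#' A zero dose under the `emax` or `linear` model, or `drug == "placebo"`,
#' yields 0.
#'
#' @param drug drug name.
#' @param dose per-administration dose in mg (`>= 0`), vector or scalar.
#' @param t weeks (`>= 0`), vector or scalar.
#' @param spec a [drug_spec()] for this drug.
#' @param covs optional covariate data.frame (see [placebo_effect()]).
#' @param effects list of [covariate_effect()] objects.
#' @param onset_rates named numeric of shared onset rates (from the model
#'   spec) used to resolve `spec$onset`.
#' @param regimen_tag optional regimen label matched against
#'   `spec$regimen_overrides`.
#' @return numeric vector of logit-scale drug effects.
#' @export
#' @examples
#' ds <- drug_spec("infliximab", "emax_flat", Emax = 1.48)
#' drug_effect("infliximab", 350, t = 8, spec = ds)  # 1.48
drug_effect <- function(drug, dose, t, spec, covs = NULL, effects = list(),
                        onset_rates = numeric(), regimen_tag = NULL) {
  if (drug == "placebo") return(rep(0, max(length(t), length(dose))))
  if (!drug %in% uc_drugs) stop("unknown drug: ", drug)
  if (is.null(spec)) stop("no drug specification supplied for ", drug)
  if (any(dose < 0)) stop("dose must be >= 0")
  if (any(t < 0)) stop("t must be >= 0")
  n <- max(length(t), length(dose))
  t <- rep_len(t, n); dose <- rep_len(dose, n)
  covs <- .as_cov_df(covs, n)

  emax <- rep(spec$Emax, n)
  if (!is.null(regimen_tag) && length(spec$regimen_overrides)) {
    tag <- rep_len(as.character(regimen_tag), n)
    hit <- tag %in% names(spec$regimen_overrides)
    if (any(hit))
      emax[hit] <- unlist(spec$regimen_overrides[tag[hit]])
  }

  if (spec$dose_model == "linear") {
    slope <- .adjust_parameter(rep(spec$slope, n), covs, effects,
                               "drug", "linear")
    base <- slope * dose
  } else {
    emax <- .adjust_parameter(emax, covs, effects, "drug", spec$dose_model)
    base <- if (spec$dose_model == "emax_flat") {
      ifelse(dose > 0, emax, 0)
    } else {
      emax * dose^spec$gamma / (dose^spec$gamma + spec$ED50^spec$gamma)
    }
  }

  k <- if (!is.na(spec$onset)) {
    onset_rates[[spec$onset]]
  } else if (!is.na(spec$k_onset)) {
    spec$k_onset
  } else NA_real_
  onset <- if (is.na(k)) 1 else 1 - exp(-k * t)
  onset * base
}

#' Response probability for one arm
#'
#' `P(response) = inverse_logit(E0 + E_drug + eta)`: the complete structural
#' prediction for an arm at time `t`, with `eta` the arm-level logit offset
#' (0 for a typical-arm prediction).
#'
#' @param arm a one-row data.frame or list with at least `drug`,
#'   `dose_amount`, and (optionally) `regimen_tag` plus covariate columns.
#' @param t weeks (vector allowed).
#' @param model a `uc_model_spec`.
#' @param eta arm-level logit-scale random effect (finite scalar).
#' @return numeric vector of probabilities in (0, 1).
#' @export
#' @examples
#' spec <- uc_model_spec("remission")
#' response_probability(
#'   list(drug = "placebo", dose_amount = 0), t = 8, model = spec)
response_probability <- function(arm, t, model, eta = 0) {
  stopifnot(is.finite(eta))
  validate_model_spec(model)
  arm <- as.list(arm)
  covs <- arm[intersect(names(arm), .uc_covariates)]
  covs <- if (length(covs)) as.data.frame(covs) else NULL
  e0 <- placebo_effect(t, model$placebo, covs, model$covariate_effects)
  ed <- if (identical(arm$drug, "placebo")) 0 else {
    drug_effect(arm$drug, arm$dose_amount %||% 0, t,
                model$drugs[[arm$drug]], covs, model$covariate_effects,
                model$onset_rates, arm$regimen_tag %||% NULL)
  }
  inverse_logit(e0 + ed + eta)
}

# ---- vectorised evaluation over a prepared record table --------------------

# d: data.frame with one row per observation, columns time, drug,
# dose_amount, regimen_tag and the covariate columns. Returns the logit
# linear predictor (eta excluded).
.linear_predictor <- function(d, model) {
  covs <- d[intersect(names(d), .uc_covariates)]
  lp <- placebo_effect(d$time, model$placebo, covs, model$covariate_effects)
  for (dr in setdiff(unique(d$drug), "placebo")) {
    idx <- which(d$drug == dr)
    sp <- model$drugs[[dr]]
    if (is.null(sp))
      stop("no drug specification for '", dr, "' in the model")
    lp[idx] <- lp[idx] + drug_effect(
      dr, d$dose_amount[idx], d$time[idx], sp,
      covs[idx, , drop = FALSE], model$covariate_effects,
      model$onset_rates, d$regimen_tag[idx]
    )
  }
  lp
}
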