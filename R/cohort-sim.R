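#' Default imaging-parameter distributions for synthetic cohorts
#'
#' One entry per imaging parameter: sampling distribution (log-normal for
#' volume-like quantities such as MTV and TLG, normal for the rest), a
#' dichotomization cutoff and the high-risk side. Scales are illustrative
#' magnitudes for FDG-avid head-and-neck tumors; low transfer constant
#' (poorly perfused, hypoxic tumors) and low ADC are coded as the adverse
#' side, high metabolic burden and entropy as adverse.
#'
#' @return Named list of distribution specs (`dist`, location/scale,
#'   `cutoff`, `high_risk`).
#' @export
default_parameter_distributions <- function() {
  norm <- function(mean, sd, cutoff, high_risk = "high", lower = -Inf)
    list(dist = "normal", mean = mean, sd = sd, cutoff = cutoff,
         high_risk = high_risk, lower = lower)
  lnorm <- function(mlog, slog, cutoff, high_risk = "high")
    list(dist = "lognormal", meanlog = mlog, sdlog = slog, cutoff = cutoff,
         high_risk = high_risk)
  list(
    suvmax = norm(12, 4, 12, lower = 2.6),
    mtv_ml = lnorm(log(15), 0.7, 15),
    tlg = lnorm(log(120), 0.9, 120),
    uniformity = norm(0.035, 0.01, 0.035, high_risk = "low", lower = 1e-4),
    entropy = norm(7.0, 0.15, 7.0),
    dissimilarity = norm(8, 2, 8, lower = 0.1),
    homogeneity = norm(0.35, 0.08, 0.35, high_risk = "low", lower = 0.01),
    inverse_difference_moment = norm(0.3, 0.08, 0.3, high_risk = "low", lower = 0.01),
    coarseness = lnorm(log(0.01), 0.5, 0.01, high_risk = "low"),
    contrast = lnorm(log(0.05), 0.6, 0.05),
    busyness = lnorm(log(0.5), 0.5, 0.5),
    complexity = lnorm(log(2000), 0.6, 2000),
    ktrans = lnorm(log(0.45), 0.5, 0.45, high_risk = "low"),
    ve = norm(0.35, 0.1, 0.35, high_risk = "low", lower = 0.02),
    vp = lnorm(log(0.05), 0.5, 0.05),
    adc = norm(1.0e-3, 0.2e-3, 1.0e-3, high_risk = "low", lower = 1e-4)
  )
}

#' Specification of a synthetic patient cohort
#'
#' Defines how imaging parameters, treatment response and survival outcomes
#' are generated. Response (non-complete vs complete) follows a logistic
#' model on the high-risk indicators of the named parameters; overall and
#' recurrence-free survival follow exponential proportional-hazards models
#' with independent exponential censoring calibrated to the requested
#' marginal censoring fraction.
#'
#' @param n_patients cohort size.
#' @param parameter_distributions per-parameter sampling specs; see
#'   [default_parameter_distributions()].
#' @param response_model list with `intercept` (log-odds of non-complete
#'   response when no risk factor is present) and `coefficients` (named
#'   log-odds applied to the high-risk indicators).
#' @param survival_models list with elements `os` and `rfs`, each a list
#'   with `baseline_rate_per_month` and named `coefficients` (log hazard
#'   ratios on high-risk indicators). OS is measured from diagnosis, RFS
#'   from end of treatment (the generator offsets RFS onset by
#'   `rfs_offset_months`).
#' @param censoring_rate target marginal censoring fraction in \[0, 1).
#' @param rfs_offset_months gap between diagnosis and end of treatment.
#' @param rng_seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200L,
                        parameter_distributions = default_parameter_distributions(),
                        response_model = list(
                          intercept = -1.75,
                          coefficients = c(tlg = log(9.746), entropy = log(7.319))),
                        survival_models = list(
                          os = list(baseline_rate_per_month = 0.004,
                                    coefficients = c(ktrans = 0.7, vp = 0.7,
                                                     suvmax = 0.7, entropy = 0.7)),
                          rfs = list(baseline_rate_per_month = 0.008,
                                     coefficients = c(ktrans = 0.7, tlg = 0.7,
                                                      entropy = 0.7))),
                        censoring_rate = 0.3,
                        rfs_offset_months = 2,
                        rng_seed = 1L) {
  stop_if(!is_count(n_patients) || n_patients < 1, "n_patients must be a positive integer")
  stop_if(censoring_rate < 0 || censoring_rate >= 1, "censoring_rate must lie in [0, 1)")
  all_coef <- c(response_model$intercept, response_model$coefficients,
                unlist(lapply(survival_models, function(m)
                  c(m$baseline_rate_per_month, m$coefficients))))
  stop_if(any(!is.finite(all_coef)), "model coefficients must be finite")
  known <- names(parameter_distributions)
  used <- c(names(response_model$coefficients),
            unlist(lapply(survival_models, function(m) names(m$coefficients))))
  bad <- setdiff(used, known)
  stop_if(length(bad) > 0, "model coefficients refer to unknown parameters: ",
          paste(bad, collapse = ", "))
  structure(list(n_patients = as.integer(n_patients),
                 parameter_distributions = parameter_distributions,
                 response_model = response_model,
                 survival_models = survival_models,
                 censoring_rate = censoring_rate,
                 rfs_offset_months = rfs_offset_months,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

draw_parameter <- function(dspec, n) {
  x <- switch(dspec$dist,
    normal = stats::rnorm(n, dspec$mean, dspec$sd),
    lognormal = stats::rlnorm(n, dspec$meanlog, dspec$sdlog),
    stop("unknown distribution: ", dspec$dist))
  if (!is.null(dspec$lower)) x <- pmax(x, dspec$lower)
  x
}

risk_indicator <- function(values, cutoff, high_risk) {
  if (identical(high_risk, "high")) as.integer(values > cutoff)
  else as.integer(values < cutoff)
}

# Censoring rate mu of an independent exponential censor such that the
# marginal censoring fraction matches the target, given per-patient event
# rates.
solve_censoring_rate <- function(event_rates, target) {
  if (target <= 0) return(0)
  f <- function(mu) mean(mu / (event_rates + mu)) - target
  stats::uniroot(f, c(1e-10, 1e6), tol = 1e-12)$root
}

#' Generate a synthetic patient cohort with planted outcome effects
#'
#' Draws per-patient imaging parameters, dichotomizes them at the cutoffs of
#' the spec, and generates treatment response from the logistic model and
#' OS/RFS from exponential proportional-hazards models with independent
#' censoring. The planted coefficients, per-patient indicators and linear
#' predictors are attached so recovery tests can compare estimates against
#' truth.
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` (one row per patient) with imaging parameters,
#'   clinical covariates (`age`, `sex`, `t_stage`, `n_stage`), `response`
#'   (`"complete"`/`"non_complete"`), `os_months`/`death` and
#'   `rfs_months`/`recurrence`. The ground truth is attached as attribute
#'   `"ground_truth"` (list with `spec`, `indicators`, linear predictors).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$rng_seed)
  n <- spec$n_patients

  params <- lapply(spec$parameter_distributions, draw_parameter, n = n)
  params <- as.data.frame(params)
  params$kep <- params$ktrans / params$ve

  ind <- vapply(names(spec$parameter_distributions), function(nm) {
    d <- spec$parameter_distributions[[nm]]
    risk_indicator(params[[nm]], d$cutoff, d$high_risk)
  }, integer(n))
  ind <- matrix(ind, nrow = n,
                dimnames = list(NULL, names(spec$parameter_distributions)))

  # response: logistic model for P(non-complete)
  rm <- spec$response_model
  lp_resp <- rep(rm$intercept, n)
  for (nm in names(rm$coefficients)) lp_resp <- lp_resp + rm$coefficients[[nm]] * ind[, nm]
  p_ncr <- stats::plogis(lp_resp)
  non_complete <- stats::rbinom(n, 1L, p_ncr)

  surv_one <- function(model) {
    lp <- rep(0, n)
    for (nm in names(model$coefficients)) lp <- lp + model$coefficients[[nm]] * ind[, nm]
    rate <- model$baseline_rate_per_month * exp(lp)
    t_event <- stats::rexp(n, rate)
    if (spec$censoring_rate > 0) {
      mu <- solve_censoring_rate(rate, spec$censoring_rate)
      t_cens <- stats::rexp(n, mu)
      list(time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens), lp = lp)
    } else {
      list(time = t_event, event = rep(1L, n), lp = lp)
    }
  }
  os <- surv_one(spec$survival_models$os)
  rfs <- surv_one(spec$survival_models$rfs)

  cohort <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    params,
    age = round(pmax(stats::rnorm(n, 58, 9), 25)),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.93, 0.07)),
    t_stage = sample(paste0("T", 1:4), n, replace = TRUE, prob = c(0.08, 0.22, 0.3, 0.4)),
    n_stage = sample(paste0("N", 0:3), n, replace = TRUE, prob = c(0.15, 0.2, 0.55, 0.1)),
    response = ifelse(non_complete == 1L, "non_complete", "complete"),
    os_months = os$time,
    death = os$event,
    rfs_months = rfs$time,
    recurrence = rfs$event,
    stringsAsFactors = FALSE
  )
  attr(cohort, "ground_truth") <- list(
    spec = spec, indicators = ind,
    p_non_complete = p_ncr, lp_os = os$lp, lp_rfs = rfs$lp
  )
  cohort
}
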