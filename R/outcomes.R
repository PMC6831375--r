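#' Dichotomization rule for an imaging parameter
#'
#' @param parameter name of the cohort column.
#' @param cutoff cutoff value.
#' @param direction which side is high-risk: `"high"` (value > cutoff) or
#'   `"low"` (value < cutoff).
#' @param sensitivity,specificity,youden_j optional criterion record from
#'   the ROC analysis that produced the rule.
#' @return An object of class `cutoff_rule`.
#' @export
cutoff_rule <- function(parameter, cutoff, direction = c("high", "low"),
                        sensitivity = NA_real_, specificity = NA_real_,
                        youden_j = NA_real_) {
  direction <- match.arg(direction)
  structure(list(parameter = parameter, cutoff = cutoff, direction = direction,
                 sensitivity = sensitivity, specificity = specificity,
                 youden_j = youden_j),
            class = "cutoff_rule")
}

#' @export
print.cutoff_rule <- function(x, ...) {
  cat(sprintf("%s %s %.4g (J = %.3f, sens %.3f, spec %.3f)\n", x$parameter,
              if (x$direction == "high") ">" else "<", x$cutoff,
              x$youden_j, x$sensitivity, x$specificity))
  invisible(x)
}

apply_rule <- function(rule, values) {
  if (rule$direction == "high") as.integer(values > rule$cutoff)
  else as.integer(values < rule$cutoff)
}

#' ROC-derived dichotomization cutoff (Youden's J)
#'
#' Scans the midpoints between consecutive observed values (both
#' directions) and returns the cutoff maximizing Youden's J = sensitivity +
#' specificity - 1 for predicting the positive outcome class. Ties are
#' broken toward higher sensitivity, then the smaller cutoff value.
#'
#' @param values numeric predictor.
#' @param outcome binary outcome (0/1, logical, or a factor whose second
#'   level is the positive class).
#' @param parameter name recorded in the resulting rule.
#' @return A [cutoff_rule()] with the criterion record filled in.
#' @export
roc_cutoff <- function(values, outcome, parameter = deparse(substitute(values))) {
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  outcome <- as.integer(outcome)
  keep <- is.finite(values) & !is.na(outcome)
  values <- values[keep]; outcome <- outcome[keep]
  stop_if(length(unique(outcome)) < 2, "both outcome classes must be present")
  sv <- sort(unique(values))
  stop_if(length(sv) < 2, "at least two distinct values are required")
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  n_pos <- sum(outcome == 1L); n_neg <- sum(outcome == 0L)
  best <- NULL
  for (dir in c("high", "low")) {
    for (cut in cand) {
      pred <- if (dir == "high") values > cut else values < cut
      sens <- sum(pred & outcome == 1L) / n_pos
      spec <- sum(!pred & outcome == 0L) / n_neg
      j <- sens + spec - 1
      if (is.null(best) || j > best$j + 1e-12 ||
          (abs(j - best$j) <= 1e-12 &&
           (sens > best$sens + 1e-12 ||
            (abs(sens - best$sens) <= 1e-12 && cut < best$cut)))) {
        best <- list(cut = cut, dir = dir, sens = sens, spec = spec, j = j)
      }
    }
  }
  cutoff_rule(parameter, best$cut, best$dir,
              sensitivity = best$sens, specificity = best$spec, youden_j = best$j)
}

#' Pearson chi-square association test for a dichotomized parameter
#'
#' 2 x 2 Pearson chi-square (no continuity correction) between a high-risk
#' indicator and a binary response, with the expected counts reported.
#'
#' @param indicator binary (0/1) high-risk indicator.
#' @param response binary outcome (0/1, logical or 2-level factor).
#' @return List with `statistic`, `p_value`, `df`, `observed`, `expected`.
#' @export
association_test <- function(indicator, response) {
  if (is.factor(response)) response <- as.integer(response) - 1L
  tab <- table(factor(indicator, levels = 0:1), factor(as.integer(response), levels = 0:1))
  stop_if(any(rowSums(tab) == 0) || any(colSums(tab) == 0),
          "2 x 2 table has a zero margin")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter), observed = ct$observed, expected = ct$expected)
}

#' Multivariable logistic model of treatment response
#'
#' Fits non-complete response against the high-risk indicators defined by a
#' set of cutoff rules and reports exponentiated coefficients with Wald
#' confidence intervals. The exponentiated logistic coefficients are odds
#' ratios (they are sometimes loosely labeled hazard ratios in the clinical
#' literature; the correct term is used here). Quasi-complete separation is
#' detected and refit with a weak ridge penalty (iteratively reweighted
#' least squares with an L2 term), flagged in the output.
#'
#' @param cohort cohort `data.frame` with a `response` column
#'   (`"complete"`/`"non_complete"` or 0/1 where 1 = non-complete).
#' @param rules list of [cutoff_rule()]s naming cohort columns.
#' @param min_events_per_param guard: warn when events or non-events per
#'   fitted parameter fall below this (default 5).
#' @return An object of class `response_model_fit`: a data.frame `table`
#'   with per-predictor `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`,
#'   plus `separation` flag and the underlying `fit`.
#' @export
response_model <- function(cohort, rules, min_events_per_param = 5) {
  y <- cohort$response
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "non_complete")
  X <- vapply(rules, function(r) apply_rule(r, cohort[[r$parameter]]), integer(nrow(cohort)))
  X <- matrix(X, nrow = nrow(cohort),
              dimnames = list(NULL, vapply(rules, `[[`, "", "parameter")))
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  k <- ncol(X)
  if (min(sum(y), sum(1 - y)) < min_events_per_param * k) {
    warning("fewer than ", min_events_per_param,
            " events or non-events per fitted parameter; estimates may be unstable")
  }
  dat <- data.frame(y = y, X)
  fit <- stats::glm(y ~ ., data = dat, family = stats::binomial())
  separation <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
  if (separation) {
    fit <- ridge_logistic(X, y, lambda = 0.5)
  }
  sm <- summary_coefs(fit, exp = TRUE)
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  tab <- data.frame(parameter = rownames(sm), odds_ratio = sm[, "est"],
                    ci_lower = sm[, "lo"], ci_upper = sm[, "hi"],
                    p_value = sm[, "p"], row.names = NULL)
  structure(list(table = tab, separation = separation, fit = fit,
                 n = length(y)),
            class = "response_model_fit")
}

# Wald summaries on the exponentiated scale for glm/ridge fits.
summary_coefs <- function(fit, exp = TRUE) {
  if (inherits(fit, "ridge_logistic")) {
    est <- fit$coef; se <- fit$se
  } else {
    cf <- summary(fit)$coefficients
    est <- cf[, 1]; se <- cf[, 2]
  }
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  lo <- est - 1.96 * se; hi <- est + 1.96 * se
  if (exp) { est <- exp(est); lo <- exp(lo); hi <- exp(hi) }
  out <- cbind(est = est, lo = lo, hi = hi, p = p)
  rownames(out) <- names(fit$coef %||% stats::coef(fit))
  out
}

# Weak-ridge logistic regression via penalized IRLS; fallback for separated
# data (keeps estimates finite with honest, slightly conservative SEs).
ridge_logistic <- function(X, y, lambda = 0.5, maxit = 100, tol = 1e-10) {
  Xd <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(Xd))
  pen <- diag(c(0, rep(lambda, ncol(X))))
  for (it in seq_len(maxit)) {
    eta <- as.vector(Xd %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    H <- crossprod(Xd, Xd * W) + pen
    g <- crossprod(Xd, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  structure(list(coef = stats::setNames(as.vector(beta), colnames(Xd)),
                 se = stats::setNames(se, colnames(Xd)), lambda = lambda),
            class = "ridge_logistic")
}

#' Survival modeling: univariate screen, multivariable Cox, Kaplan-Meier
#'
#' For a chosen endpoint each rule's high-risk indicator is screened with a
#' univariate Cox model; indicators passing the entry threshold (default
#' p < 0.05) enter a multivariable Cox model (Efron ties). Kaplan-Meier
#' curves (Greenwood variance) and the log-rank test are computed per
#' retained indicator.
#'
#' @param cohort cohort data.frame with `os_months`/`death` and
#'   `rfs_months`/`recurrence` columns.
#' @param rules list of [cutoff_rule()]s.
#' @param endpoint `"os"` or `"rfs"`.
#' @param entry_p univariate entry threshold for the multivariable model.
#' @param ties tie handling for Cox models (default `"efron"`).
#' @return An object of class `survival_model_fit`: `univariate`
#'   (data.frame of HR, CI, p per rule), `selected` (parameter names),
#'   `multivariable` (data.frame, `NULL` when nothing passes the screen),
#'   `km` (list of `survfit` objects per selected rule), `logrank_p`
#'   (named vector) and the endpoint metadata.
#' @export
survival_models <- function(cohort, rules, endpoint = c("os", "rfs"),
                            entry_p = 0.05, ties = "efron") {
  endpoint <- match.arg(endpoint)
  time <- if (endpoint == "os") cohort$os_months else cohort$rfs_months
  event <- if (endpoint == "os") cohort$death else cohort$recurrence
  stop_if(sum(event) == 0, "no events for endpoint ", endpoint)
  nm <- vapply(rules, `[[`, "", "parameter")
  X <- vapply(rules, function(r) apply_rule(r, cohort[[r$parameter]]), integer(nrow(cohort)))
  X <- matrix(X, nrow = nrow(cohort), dimnames = list(NULL, nm))

  uni <- do.call(rbind, lapply(seq_along(rules), function(i) {
    f <- survival::coxph(survival::Surv(time, event) ~ x,
                         data = data.frame(x = X[, i]), ties = ties)
    s <- summary(f)
    data.frame(parameter = nm[i],
               hazard_ratio = unname(s$conf.int[1, "exp(coef)"]),
               ci_lower = unname(s$conf.int[1, "lower .95"]),
               ci_upper = unname(s$conf.int[1, "upper .95"]),
               p_value = unname(s$coefficients[1, "Pr(>|z|)"]))
  }))
  selected <- uni$parameter[!is.na(uni$p_value) & uni$p_value < entry_p]

  multi <- NULL
  if (length(selected) > 0) {
    dat <- data.frame(time = time, event = event, X[, selected, drop = FALSE])
    f <- survival::coxph(survival::Surv(time, event) ~ ., data = dat, ties = ties)
    s <- summary(f)
    multi <- data.frame(parameter = rownames(s$conf.int),
                        hazard_ratio = unname(s$conf.int[, "exp(coef)"]),
                        ci_lower = unname(s$conf.int[, "lower .95"]),
                        ci_upper = unname(s$conf.int[, "upper .95"]),
                        p_value = unname(s$coefficients[, "Pr(>|z|)"]),
                        row.names = NULL)
  }

  km <- list(); logrank_p <- stats::setNames(numeric(0), character(0))
  for (p in selected) {
    grp <- factor(X[, p], levels = 0:1, labels = c("low_risk", "high_risk"))
    km[[p]] <- survival::survfit(survival::Surv(time, event) ~ grp,
                                 conf.type = "log")  # Greenwood variance
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
    logrank_p[p] <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  }
  structure(list(endpoint = endpoint, univariate = uni,
                 selected = as.character(selected), multivariable = multi,
                 km = km, logrank_p = logrank_p,
                 entry_p = entry_p, ties = ties, n_events = sum(event)),
            class = "survival_model_fit")
}

#' Additive risk-factor score and outcome stratification
#'
#' The score of a patient is the count of satisfied high-risk rules (each
#' independent adverse factor contributes 1), so it ranges from 0 to the
#' number of rules. For the response endpoint the complete-response rate is
#' reported per score level with a chi-square test across levels and a
#' Cochran-Armitage trend test; for survival endpoints Kaplan-Meier strata
#' per score level with the log-rank test.
#'
#' @param cohort cohort data.frame.
#' @param rules nonempty list of [cutoff_rule()]s, the independent risk
#'   factors of the score.
#' @param endpoint `"response"`, `"os"` or `"rfs"`.
#' @return An object of class `risk_score`: `score` (integer per included
#'   patient), `max_score`, `excluded` (ids of patients dropped for missing
#'   values), plus for response: `response_table` (per-level n, complete
#'   responders, rate), `chisq_p`, `trend_p`; for survival: `km` (survfit
#'   by score), `logrank_p`.
#' @export
build_score <- function(cohort, rules, endpoint = c("response", "os", "rfs")) {
  endpoint <- match.arg(endpoint)
  stop_if(length(rules) == 0, "at least one rule is required")
  for (r in rules) stop_if(is.null(cohort[[r$parameter]]),
                           "cohort lacks parameter: ", r$parameter)
  X <- vapply(rules, function(r) apply_rule(r, cohort[[r$parameter]]),
              integer(nrow(cohort)))
  X <- matrix(X, nrow = nrow(cohort))
  ok <- stats::complete.cases(X)
  excluded <- cohort$id[!ok] %||% which(!ok)
  score <- as.integer(rowSums(X[ok, , drop = FALSE]))
  res <- list(score = score, max_score = length(rules), excluded = excluded,
              endpoint = endpoint, rules = rules)
  lev <- factor(score, levels = 0:length(rules))
  if (endpoint == "response") {
    y <- cohort$response[ok]
    if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "complete")
    tab <- data.frame(score = 0:length(rules),
                      n = as.integer(table(lev)),
                      complete = as.integer(tapply(y, lev, sum, default = 0L)))
    tab$complete[is.na(tab$complete)] <- 0L
    tab$complete_response_rate <- ifelse(tab$n > 0, tab$complete / tab$n, NA_real_)
    present <- tab$n > 0
    res$response_table <- tab
    # small strata trip the asymptotic-approximation warning; expected here
    res$chisq_p <- if (sum(present) > 1)
      suppressWarnings(stats::chisq.test(
        rbind(tab$complete[present], tab$n[present] - tab$complete[present]))$p.value)
    else NA_real_
    res$trend_p <- if (sum(present) > 1)
      suppressWarnings(stats::prop.trend.test(tab$complete[present], tab$n[present])$p.value)
    else NA_real_
  } else {
    time <- if (endpoint == "os") cohort$os_months[ok] else cohort$rfs_months[ok]
    event <- if (endpoint == "os") cohort$death[ok] else cohort$recurrence[ok]
    grp <- droplevels(lev)
    res$km <- survival::survfit(survival::Surv(time, event) ~ grp)
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
    res$logrank_p <- stats::pchisq(sd_$chisq, df = length(unique(grp)) - 1,
                                   lower.tail = FALSE)
    res$median_by_score <- tapply(time, grp, stats::median)
  }
  structure(res, class = "risk_score")
}

#' @export
print.risk_score <- function(x, ...) {
  cat("Risk score (", x$endpoint, "), ", length(x$rules), " rules, max score ",
      x$max_score, "\n", sep = "")
  if (!is.null(x$response_table)) {
    print(x$response_table, row.names = FALSE)
    cat(sprintf("chi-square p = %.4g, trend p = %.4g\n", x$chisq_p, x$trend_p))
  } else if (!is.null(x$logrank_p)) {
    cat(sprintf("log-rank p = %.4g across score strata\n", x$logrank_p))
  }
  invisible(x)
}
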