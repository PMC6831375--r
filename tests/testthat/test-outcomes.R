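test_that("Youden cutoff separates perfectly separable classes", {
  values <- c(1, 2, 3, 4)
  outcome <- c(0, 0, 1, 1)
  rule <- roc_cutoff(values, outcome, parameter = "x")
  expect_equal(rule$youden_j, 1)
  expect_equal(rule$cutoff, 2.5)
  expect_equal(rule$direction, "high")
  expect_equal(rule$sensitivity, 1)
  expect_equal(rule$specificity, 1)
  # reversed direction detected
  rule2 <- roc_cutoff(values, 1 - outcome, parameter = "x")
  expect_equal(rule2$direction, "low")
  expect_equal(rule2$youden_j, 1)
})

test_that("Youden cutoff equals the exhaustive-search oracle (pROC cross-check)", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (rep in 1:5) {
    x <- rnorm(60)
    y <- rbinom(60, 1, plogis(1.2 * x))
    rule <- roc_cutoff(x, y, parameter = "x")
    r <- pROC::roc(y, x, quiet = TRUE, direction = "<")
    best_j <- max(r$sensitivities + r$specificities - 1)
    expect_equal(rule$youden_j, best_j, tolerance = 1e-12)
  }
})

test_that("label-permuted data gives near-zero expected Youden J", {
  set.seed(5)
  x <- rnorm(100)
  y <- rbinom(100, 1, 0.4)
  js <- replicate(200, roc_cutoff(x, sample(y), parameter = "x")$youden_j)
  # optimized-over-thresholds J is positively biased under the null, but small
  expect_lt(mean(js), 0.35)
  expect_gt(mean(js), 0)
})

test_that("chi-square association matches closed forms and the brute-force oracle", {
  t0 <- association_test(rep(c(0, 1), each = 20), rep(c(0, 1, 0, 1), each = 10))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # perfectly associated 2x2 [[20,0],[0,20]]
  t1 <- association_test(rep(c(0, 1), each = 20), rep(c(0, 1), each = 20))
  expect_equal(t1$statistic, 40)
  # random tables against sum (O-E)^2/E
  set.seed(2)
  for (r in 1:5) {
    ind <- rbinom(80, 1, 0.5); resp <- rbinom(80, 1, 0.4)
    res <- tryCatch(association_test(ind, resp), error = function(e) NULL)
    if (is.null(res)) next
    o <- res$observed; e <- res$expected
    expect_equal(res$statistic, sum((o - e)^2 / e), tolerance = 1e-12)
  }
  expect_error(association_test(rep(0, 10), rbinom(10, 1, 0.5)), "zero margin")
})

test_that("single-predictor logistic fit equals the 2x2-table odds ratio", {
  set.seed(7)
  x <- rbinom(200, 1, 0.5)
  y <- rbinom(200, 1, plogis(-1 + 1.2 * x))
  cohort <- data.frame(id = seq_along(x), marker = x,
                       response = ifelse(y == 1, "non_complete", "complete"))
  rule <- cutoff_rule("marker", 0.5, "high")
  fit <- response_model(cohort, list(rule))
  tab <- table(x, y)
  or_tab <- (tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1])
  expect_equal(fit$table$odds_ratio, or_tab, tolerance = 1e-6)
  expect_false(fit$separation)
})

test_that("perfect separation is flagged and refit with finite estimates", {
  cohort <- data.frame(id = 1:40, marker = rep(c(0, 10), each = 20),
                       response = rep(c("complete", "non_complete"), each = 20))
  rule <- cutoff_rule("marker", 5, "high")
  fit <- response_model(cohort, list(rule))
  expect_true(fit$separation)
  expect_true(is.finite(fit$table$odds_ratio))
  expect_gt(fit$table$odds_ratio, 1)
})

test_that("Kaplan-Meier on uncensored data equals the empirical survivor function", {
  set.seed(9)
  tm <- rexp(60, 0.1)
  cohort <- data.frame(id = 1:60, marker = rbinom(60, 1, 0.5),
                       os_months = tm, death = 1L,
                       rfs_months = tm, recurrence = 1L)
  sf <- survival::survfit(survival::Surv(tm, rep(1, 60)) ~ 1)
  emp <- vapply(sf$time, function(t) mean(tm > t), numeric(1))
  expect_equal(sf$surv, emp, tolerance = 1e-12)
  expect_equal(max(sf$surv), (60 - 1) / 60)  # starts below 1 at first event
})

test_that("log-rank statistic is zero for identical strata", {
  tm <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  ev <- rep(1L, 10)
  grp <- rep(0:1, each = 5)
  sd_ <- survival::survdiff(survival::Surv(tm, ev) ~ grp)
  expect_lt(sd_$chisq, 1e-10)
})

test_that("survival screen retains the planted predictor and Cox recovers its effect", {
  set.seed(13)
  n <- 600
  x <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  tm <- rexp(n, 0.02 * exp(0.9 * x))
  cohort <- data.frame(id = 1:n, marker = x, noise = noise,
                       os_months = tm, death = 1L, rfs_months = tm, recurrence = 1L)
  rules <- list(cutoff_rule("marker", 0.5, "high"), cutoff_rule("noise", 0, "high"))
  fit <- survival_models(cohort, rules, endpoint = "os")
  expect_true("marker" %in% fit$selected)
  hr_row <- fit$multivariable[fit$multivariable$parameter == "marker", ]
  expect_gt(hr_row$ci_upper, exp(0.9) * 0.8)
  expect_lt(hr_row$ci_lower, exp(0.9) * 1.2)
  expect_true("marker" %in% names(fit$km))
  expect_lt(fit$logrank_p["marker"], 0.001)
})

test_that("risk score counts satisfied rules and is order-invariant", {
  cohort <- data.frame(id = 1:4,
                       tlg = c(200, 50, 200, 50),
                       entropy = c(7.5, 7.5, 6.5, 6.5),
                       response = c("non_complete", "complete", "complete", "complete"))
  r_tlg <- cutoff_rule("tlg", 100, "high")
  r_ent <- cutoff_rule("entropy", 7, "high")
  s1 <- build_score(cohort, list(r_tlg, r_ent), endpoint = "response")
  s2 <- build_score(cohort, list(r_ent, r_tlg), endpoint = "response")
  expect_equal(s1$score, c(2L, 1L, 1L, 0L))
  expect_identical(s1$score, s2$score)
  expect_equal(s1$max_score, 2L)
  # counting identity: score equals the sum of individual indicators
  expect_equal(s1$score, as.integer((cohort$tlg > 100) + (cohort$entropy > 7)))
})

test_that("four-rule survival score has max_score 4 and stratifies KM", {
  set.seed(21)
  n <- 400
  X <- matrix(rbinom(4 * n, 1, 0.5), n, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  lp <- X %*% rep(0.8, 4)
  tm <- rexp(n, 0.02 * exp(lp))
  cohort <- data.frame(id = 1:n, X, os_months = tm, death = 1L,
                       rfs_months = tm, recurrence = 1L)
  rules <- lapply(colnames(X), function(p) cutoff_rule(p, 0.5, "high"))
  sc <- build_score(cohort, rules, endpoint = "os")
  expect_equal(sc$max_score, 4L)
  expect_lt(sc$logrank_p, 1e-6)
  med <- sc$median_by_score
  expect_true(all(diff(med[!is.na(med)]) < 0))  # higher score, shorter survival
})

test_that("patients with missing rule parameters are excluded with a report", {
  cohort <- data.frame(id = c("A", "B", "C"), tlg = c(200, NA, 50),
                       response = c("non_complete", "complete", "complete"))
  sc <- build_score(cohort, list(cutoff_rule("tlg", 100, "high")), endpoint = "response")
  expect_equal(sc$excluded, "B")
  expect_equal(length(sc$score), 2L)
  expect_error(build_score(cohort, list(cutoff_rule("absent", 1, "high"))),
               "lacks parameter")
})
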