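#' Default configuration of the end-to-end synthetic pipeline
#'
#' Single structured configuration with one section per stage, so that
#' cross-stage parameters (seeds, thresholds, bin counts) are locked
#' together for reproducibility. Unknown keys are rejected by
#' [run_pipeline()].
#'
#' @param n_patients cohort size of the synthetic run.
#' @param seed master seed; per-patient and per-stage seeds derive from it.
#' @param out_dir optional output directory; when `NULL` the run is
#'   in-memory only.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(n_patients = 40L, seed = 1L, out_dir = NULL) {
  structure(list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    out_dir = out_dir,
    pet = list(
      threshold = 2.5, n_bins = 64L,
      grid_shape = c(28L, 28L, 20L), voxel_spacing_mm = c(2, 2, 2),
      mean_suv_meanlog = log(8), mean_suv_sdlog = 0.25,
      radii_range_mm = c(8, 13),
      heterogeneity_sigma_range = c(0.1, 0.4),
      correlation_range_mm = c(2, 6)
    ),
    dce = list(snr = 40, aif_mode = "population"),
    dwi = list(snr = 50, grid = c(4L, 4L, 4L)),
    truth = list(
      # distributions of the underlying kinetic/diffusion ground truth
      ktrans_meanlog = log(0.45), ktrans_sdlog = 0.5,
      ve_mean = 0.35, ve_sd = 0.1,
      vp_meanlog = log(0.05), vp_sdlog = 0.5,
      adc_mean = 1.0e-3, adc_sd = 0.2e-3,
      t10_ms = 1000, m0 = 1000
    ),
    planted = list(
      # outcome models act on indicators of the TRUE parameter values
      response = list(intercept = -1.5,
                      coefficients = c(tlg = 2.0, heterogeneity = 1.6)),
      os = list(baseline_rate_per_month = 0.006,
                coefficients = c(ktrans_low = 0.8, vp_high = 0.8,
                                 suv_high = 0.8, heterogeneity = 0.8)),
      rfs = list(baseline_rate_per_month = 0.010,
                 coefficients = c(ktrans_low = 0.8, tlg = 0.8,
                                  heterogeneity = 0.8)),
      censoring_rate = 0.3,
      # medians of the generating distributions, so each indicator splits
      # the cohort roughly in half
      cutoffs = list(tlg = 40, heterogeneity = 0.25,
                     ktrans = 0.45, vp = 0.05, suv = 8)
    ),
    outcomes = list(entry_p = 0.05,
                    response_parameters = c("tlg", "entropy"),
                    survival_parameters = c("ktrans", "vp", "suvmax", "entropy",
                                            "tlg", "ve", "mtv_ml", "adc")),
    corrupt_patients = integer(0)  # fault-injection hook for testing
  ), class = "run_config")
}

# Draw per-patient ground truth and simulate + measure all modalities.
measure_patient <- function(i, config) {
  seed <- derive_seed(config$seed, i)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  pet <- config$pet; tr <- config$truth
  mean_suv <- max(stats::rlnorm(1, pet$mean_suv_meanlog, pet$mean_suv_sdlog), 3)
  radii <- stats::runif(3, pet$radii_range_mm[1], pet$radii_range_mm[2])
  sigma <- stats::runif(1, pet$heterogeneity_sigma_range[1], pet$heterogeneity_sigma_range[2])
  corr <- stats::runif(1, pet$correlation_range_mm[1], pet$correlation_range_mm[2])
  ktrans <- stats::rlnorm(1, tr$ktrans_meanlog, tr$ktrans_sdlog)
  ve <- min(max(stats::rnorm(1, tr$ve_mean, tr$ve_sd), 0.05), 0.8)
  vp <- min(stats::rlnorm(1, tr$vp_meanlog, tr$vp_sdlog), 0.3)
  if (vp + ve > 1) vp <- 1 - ve - 0.01
  adc <- max(stats::rnorm(1, tr$adc_mean, tr$adc_sd), 2e-4)

  spec <- phantom_spec(
    grid_shape = pet$grid_shape, voxel_spacing_mm = pet$voxel_spacing_mm,
    tumor_radii_mm = radii, tumor_mean_suv = mean_suv,
    heterogeneity_sigma = sigma, heterogeneity_correlation_mm = corr,
    rng_seed = derive_seed(seed, 1L))
  ph <- generate_pet_phantom(spec)
  if (i %in% config$corrupt_patients) {
    ph$volume$values[1] <- NaN  # simulated corrupt image
  }
  stop_if(any(!is.finite(ph$volume$values)), "corrupt PET image for patient ", i)

  bb <- which(ph$tumor_mask, arr.ind = TRUE)
  lo <- pmax(apply(bb, 2, min) - 2L, 1L)
  hi <- pmin(apply(bb, 2, max) + 2L, dim(ph$volume$values))
  seg <- segment_fixed_threshold(ph$volume, list(lo = lo, hi = hi),
                                 threshold = pet$threshold)
  mi <- metabolic_indices(ph$volume, seg)
  tex <- texture_features(ph$volume, seg, n_bins = pet$n_bins)

  acq <- acquisition_spec()
  truth <- kinetic_truth(ktrans, ve, vp, t10_ms = tr$t10_ms, m0 = tr$m0,
                         adc_mm2_per_s = adc)
  sim <- generate_dce_series(truth, acq, snr = config$dce$snr,
                             rng_seed = derive_seed(seed, 2L))
  t1 <- fit_t1_vfa(sim$vfa$signals, sim$vfa$flips_deg, acq$tr_ms)
  conc <- signal_to_concentration(sim$series, t1)
  kfit <- fit_extended_kety(as.vector(conc$ct_mM), sim$aif, frame_times(acq))

  dwi <- generate_dwi_pair(array(adc, config$dwi$grid), b = acq$b_value_s_per_mm2,
                           snr = config$dwi$snr, rng_seed = derive_seed(seed, 3L))
  adc_res <- adc_map(dwi$s0, dwi$sb, b = dwi$b,
                     roi_mask = array(TRUE, config$dwi$grid))

  true_volume_ml <- 4 / 3 * pi * prod(radii) / 1000
  list(
    measured = data.frame(
      id = sprintf("P%04d", i),
      suvmax = mi$suvmax, mtv_ml = mi$mtv_ml, tlg = mi$tlg,
      uniformity = tex$uniformity, entropy = tex$entropy_bits,
      dissimilarity = tex$dissimilarity, homogeneity = tex$homogeneity,
      inverse_difference_moment = tex$inverse_difference_moment,
      coarseness = tex$coarseness, contrast = tex$contrast,
      busyness = tex$busyness, complexity = tex$complexity,
      ktrans = kfit$ktrans_per_min, ve = kfit$ve_fraction,
      vp = kfit$vp_fraction, kep = kfit$kep_per_min,
      adc = adc_res$roi_mean
    ),
    truth = c(mean_suv = mean_suv, tlg_true = mean_suv * true_volume_ml,
              heterogeneity = sigma, ktrans = ktrans, ve = ve, vp = vp, adc = adc)
  )
}

# Generate response and survival outcomes from the TRUE parameter values of
# the measured patients (planted effects).
plant_outcomes <- function(truths, config) {
  pl <- config$planted
  cuts <- pl$cutoffs
  n <- nrow(truths)
  ind <- cbind(
    tlg = as.integer(truths[, "tlg_true"] > cuts$tlg),
    heterogeneity = as.integer(truths[, "heterogeneity"] > cuts$heterogeneity),
    ktrans_low = as.integer(truths[, "ktrans"] < cuts$ktrans),
    vp_high = as.integer(truths[, "vp"] > cuts$vp),
    suv_high = as.integer(truths[, "mean_suv"] > cuts$suv)
  )
  lp_resp <- pl$response$intercept +
    as.vector(ind[, names(pl$response$coefficients), drop = FALSE] %*%
                pl$response$coefficients)
  non_complete <- stats::rbinom(n, 1L, stats::plogis(lp_resp))
  surv_one <- function(model) {
    lp <- as.vector(ind[, names(model$coefficients), drop = FALSE] %*% model$coefficients)
    rate <- model$baseline_rate_per_month * exp(lp)
    t_event <- stats::rexp(n, rate)
    if (pl$censoring_rate > 0) {
      mu <- solve_censoring_rate(rate, pl$censoring_rate)
      t_cens <- stats::rexp(n, mu)
      list(time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens))
    } else list(time = t_event, event = rep(1L, n))
  }
  os <- surv_one(pl$os); rfs <- surv_one(pl$rfs)
  data.frame(response = ifelse(non_complete == 1L, "non_complete", "complete"),
             os_months = os$time, death = os$event,
             rfs_months = rfs$time, recurrence = rfs$event)
}

#' Run the full synthetic imaging-to-outcome pipeline
#'
#' Generates a cohort of digital patients (PET phantom, DCE series, DWI
#' pair each), measures every imaging parameter with the package's
#' estimators, plants response and survival outcomes on the true parameter
#' values, and runs the statistical layer: ROC cutoffs, logistic response
#' model, Cox/Kaplan-Meier survival models and the additive risk scores.
#' A failure in one patient quarantines that patient without aborting the
#' run. When `config$out_dir` is set, all tables, a markdown report and a
#' JSON manifest (file checksums, parameter snapshot, warnings) are
#' written; repeated runs with the same config produce byte-identical
#' tables and report.
#'
#' @param config a [default_run_config()] (possibly modified). Unknown
#'   top-level keys are rejected.
#' @return A list of class `run_result`: `cohort`, `rules`,
#'   `response_fit`, `response_score`, `os_fit`, `rfs_fit`, `os_score`,
#'   `quarantined` (patient indices that failed), `manifest`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  known <- names(default_run_config())
  unknown <- setdiff(names(config), known)
  stop_if(length(unknown) > 0, "unknown config keys: ", paste(unknown, collapse = ", "))

  warnings_log <- character(0)
  rows <- list(); truths <- list(); quarantined <- integer(0)
  for (i in seq_len(config$n_patients)) {
    res <- tryCatch(
      withCallingHandlers(
        measure_patient(i, config),
        warning = function(w) {
          warnings_log <<- c(warnings_log, paste0("patient ", i, ": ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        warnings_log <<- c(warnings_log,
                           paste0("patient ", i, " quarantined: ", conditionMessage(e)))
        NULL
      })
    if (is.null(res)) { quarantined <- c(quarantined, i); next }
    rows[[length(rows) + 1L]] <- res$measured
    truths[[length(truths) + 1L]] <- res$truth
  }
  stop_if(length(rows) == 0, "imaging stage produced no usable patients")
  measured <- do.call(rbind, rows)
  truth_mat <- do.call(rbind, truths)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(derive_seed(config$seed, 999L))
  cohort <- cbind(measured, plant_outcomes(truth_mat, config))

  # statistical layer on the MEASURED parameters
  y_ncr <- as.integer(cohort$response == "non_complete")
  oc <- config$outcomes
  resp_rules <- lapply(oc$response_parameters, function(p)
    roc_cutoff(cohort[[p]], y_ncr, parameter = p))
  response_fit <- tryCatch(response_model(cohort, resp_rules),
                           warning = function(w) {
                             warnings_log <<- c(warnings_log, conditionMessage(w))
                             suppressWarnings(response_model(cohort, resp_rules))
                           })
  # response risk direction: cutoff_rule already encodes the high-risk side
  response_score <- build_score(cohort, resp_rules, endpoint = "response")

  surv_rules <- lapply(oc$survival_parameters, function(p)
    roc_cutoff(cohort[[p]], cohort$death, parameter = p))
  os_fit <- survival_models(cohort, surv_rules, endpoint = "os", entry_p = oc$entry_p)
  rfs_rules <- lapply(oc$survival_parameters, function(p)
    roc_cutoff(cohort[[p]], cohort$recurrence, parameter = p))
  rfs_fit <- survival_models(cohort, rfs_rules, endpoint = "rfs", entry_p = oc$entry_p)
  os_score_rules <- Filter(function(r) r$parameter %in% os_fit$selected, surv_rules)
  os_score <- if (length(os_score_rules) > 0)
    build_score(cohort, os_score_rules, endpoint = "os") else NULL

  result <- structure(list(
    cohort = cohort, truth = truth_mat,
    rules = list(response = resp_rules, os = surv_rules, rfs = rfs_rules),
    response_fit = response_fit, response_score = response_score,
    os_fit = os_fit, rfs_fit = rfs_fit, os_score = os_score,
    quarantined = quarantined, warnings = warnings_log,
    config = config
  ), class = "run_result")

  if (!is.null(config$out_dir)) {
    result$manifest <- write_run_outputs(result, config$out_dir)
  }
  result
}

rules_table <- function(rules) {
  do.call(rbind, lapply(rules, function(r)
    data.frame(parameter = r$parameter, cutoff = r$cutoff, direction = r$direction,
               sensitivity = r$sensitivity, specificity = r$specificity,
               youden_j = r$youden_j)))
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }
  write_cohort_csv(result$cohort, file.path(out_dir, "cohort.csv"))
  paths <- c(paths, file.path(out_dir, "cohort.csv"))
  wr(rules_table(result$rules$response), "cutoffs_response.csv")
  wr(rules_table(result$rules$os), "cutoffs_os.csv")
  wr(result$response_fit$table, "response_model.csv")
  wr(result$os_fit$univariate, "survival_os_univariate.csv")
  if (!is.null(result$os_fit$multivariable)) wr(result$os_fit$multivariable, "survival_os_multivariable.csv")
  wr(result$rfs_fit$univariate, "survival_rfs_univariate.csv")
  if (!is.null(result$rfs_fit$multivariable)) wr(result$rfs_fit$multivariable, "survival_rfs_multivariable.csv")
  wr(result$response_score$response_table, "score_response.csv")
  if (!is.null(result$os_score)) {
    km <- result$os_score$km
    wr(data.frame(time = km$time, n_risk = km$n.risk, n_event = km$n.event,
                  survival = km$surv, std_err = km$std.err,
                  stratum = rep(names(km$strata), km$strata)),
       "km_os_by_score.csv")
  }
  report <- c(
    "# Synthetic multimodal imaging pipeline report", "",
    sprintf("Patients simulated: %d (quarantined: %d)",
            result$config$n_patients, length(result$quarantined)),
    sprintf("Non-complete response rate: %.3f",
            mean(result$cohort$response == "non_complete")), "",
    "## Response cutoffs (Youden)", "",
    knit_table(rules_table(result$rules$response)), "",
    "## Logistic response model (odds ratios)", "",
    knit_table(result$response_fit$table), "",
    "## Response score strata", "",
    knit_table(result$response_score$response_table),
    sprintf("Trend p = %.4g", result$response_score$trend_p), "",
    "## OS: multivariable Cox", "",
    if (!is.null(result$os_fit$multivariable)) knit_table(result$os_fit$multivariable)
    else "(no predictor passed the univariate screen)", "",
    if (!is.null(result$os_score))
      sprintf("OS score strata log-rank p = %.4g", result$os_score$logrank_p) else NULL
  )
  report_path <- file.path(out_dir, "report.md")
  writeLines(report, report_path)
  paths <- c(paths, report_path)
  cfg_path <- file.path(out_dir, "config_resolved.yaml")
  cfg_dump <- unclass(result$config)
  cfg_dump$out_dir <- NULL  # the file already sits in that directory
  yaml::write_yaml(cfg_dump, cfg_path)
  paths <- c(paths, cfg_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("petmriprog")),
    seed = result$config$seed,
    n_patients = result$config$n_patients,
    quarantined = result$quarantined,
    warnings = result$warnings,
    wall_clock_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    files = lapply(stats::setNames(paths, basename(paths)), function(p)
      list(md5 = unname(tools::md5sum(p)), bytes = file.size(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

# minimal markdown table renderer
knit_table <- function(df) {
  fmt <- function(x) if (is.numeric(x)) formatC(x, digits = 5, format = "g") else as.character(x)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' @export
print.run_result <- function(x, ...) {
  cat("Pipeline run:", nrow(x$cohort), "patients",
      if (length(x$quarantined)) paste0("(", length(x$quarantined), " quarantined)") else "", "\n")
  cat("Non-complete response rate:", round(mean(x$cohort$response == "non_complete"), 3), "\n")
  cat("OS predictors selected:", paste(x$os_fit$selected, collapse = ", "), "\n")
  invisible(x)
}
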