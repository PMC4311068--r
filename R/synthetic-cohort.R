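#' Specification of a synthetic study cohort
#'
#' Bundles every parameter of the synthetic data generator: the population
#' distribution of RL parameters (a Gaussian in transformed space whose
#' natural-space medians sit at the cohort quartile-table medians:
#' learning rate 0.62, reward sensitivity 2.73, punishment sensitivity
#' 0.84), the stressful-life-events distribution (normal with mean 16.31,
#' SD 4.59, rounded and truncated to the 0–42 checklist range), the
#' linear model generating fluid IQ from the true BOLD PE scale and SLES,
#' and the BOLD forward-model settings.
#'
#' The SLES-to-BOLD-scale link `scale = scale0 + scale_sles * z(SLES) +
#' noise` has a positive default slope, mirroring the positive
#' SLES/ventral-striatal PE-signal association the analysis is built to
#' probe; set `scale_sles = 0` for null cohorts. The fluid-IQ model is
#' `iq = intercept + b_pe * scale + b_sles * z(SLES) +
#' b_interaction * scale * z(SLES) + noise`; `b_interaction = 0` gives
#' the no-moderation null. Effect-size defaults are one-time calibration
#' choices (see the package vignette), not estimates taken from any real
#' cohort.
#'
#' @param n_subjects cohort size.
#' @param prior [population_prior()] the true transformed parameters are
#'   drawn from.
#' @param sles_mean,sles_sd,sles_max SLES distribution settings.
#' @param age_range years; ages are drawn uniformly.
#' @param iq_intercept,b_pe,b_sles,b_interaction,iq_noise_sd fluid-IQ
#'   model coefficients and residual SD.
#' @param bold_scale0,bold_scale_sles,bold_scale_noise_sd SLES-to-scale
#'   link coefficients and noise.
#' @param bold_noise_sd,bold_ar1,bold_baseline voxel noise model.
#' @param cfg a [task_config()].
#' @param protocol a [scan_protocol()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 16L,
                        prior = population_prior(
                          mu = c(stats::qlogis(0.62), log(2.73), log(0.84)),
                          sigma = diag(c(1.44, 0.49, 0.19))),
                        sles_mean = 16.31, sles_sd = 4.59, sles_max = 42L,
                        age_range = c(20, 60),
                        iq_intercept = 0.60, b_pe = 0.5, b_sles = 0,
                        b_interaction = 0.8, iq_noise_sd = 0.25,
                        bold_scale0 = 1, bold_scale_sles = 0.4,
                        bold_scale_noise_sd = 0.2,
                        bold_noise_sd = 1, bold_ar1 = 0.3,
                        bold_baseline = 100,
                        cfg = task_config(),
                        protocol = scan_protocol()) {
  stopifnot(n_subjects >= 2, sles_sd > 0, iq_noise_sd > 0,
            bold_noise_sd >= 0, sles_max > 0)
  structure(list(
    n_subjects = as.integer(n_subjects), prior = prior,
    sles_mean = sles_mean, sles_sd = sles_sd, sles_max = as.integer(sles_max),
    age_range = age_range,
    iq_intercept = iq_intercept, b_pe = b_pe, b_sles = b_sles,
    b_interaction = b_interaction, iq_noise_sd = iq_noise_sd,
    bold_scale0 = bold_scale0, bold_scale_sles = bold_scale_sles,
    bold_scale_noise_sd = bold_scale_noise_sd,
    bold_noise_sd = bold_noise_sd, bold_ar1 = bold_ar1,
    bold_baseline = bold_baseline, cfg = cfg, protocol = protocol
  ), class = "cohort_spec")
}

draw_sles <- function(n, spec) {
  pmin(pmax(round(stats::rnorm(n, spec$sles_mean, spec$sles_sd)), 0L),
       spec$sles_max)
}

#' Generate the covariate level of a synthetic cohort
#'
#' Draws SLES counts, the true per-subject BOLD PE scale (linked to SLES)
#' and fluid IQ from the generative moderation model, without simulating
#' behavior or voxel series. This is the fast path used for the
#' statistical calibration of the group-level tests (type-I error, power);
#' `pe_beta` is set to the true scale, i.e. measurement noise from the
#' GLM stage is omitted.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `cohort` (tibble: `subject`, `sles`, `fluid_iq`,
#'   `age`, `pe_beta`) and `truth` (tibble of the generative components).
#' @export
simulate_cohort_table <- function(spec = cohort_spec()) {
  n <- spec$n_subjects
  sles <- draw_sles(n, spec)
  z <- (sles - spec$sles_mean) / spec$sles_sd
  scale <- spec$bold_scale0 + spec$bold_scale_sles * z +
    stats::rnorm(n, 0, spec$bold_scale_noise_sd)
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  iq <- spec$iq_intercept + spec$b_pe * scale + spec$b_sles * z +
    spec$b_interaction * scale * z + stats::rnorm(n, 0, spec$iq_noise_sd)
  cohort <- tibble::tibble(subject = seq_len(n), sles = sles,
                           fluid_iq = iq, age = age, pe_beta = scale)
  truth <- tibble::tibble(subject = seq_len(n), sles = sles, sles_z = z,
                          bold_scale = scale, fluid_iq = iq)
  list(cohort = cohort, truth = truth)
}

#' Generate a complete synthetic study dataset
#'
#' Per subject: transformed RL parameters are drawn from the population
#' prior, behavior on the reversal task is simulated from the
#' RW/softmax model, trial prediction errors are computed at the *true*
#' parameters, and a voxel time series is synthesized as the true scale
#' times the HRF-convolved PE regressor plus AR(1) noise. SLES, age and
#' fluid IQ come from the covariate model of [simulate_cohort_table()].
#'
#' @param spec a [cohort_spec()].
#' @param dir optional directory; when given, all artifacts are written in
#'   the package's interchange formats (events TSV, voxel TSV per
#'   session, `cohort.csv`, `ground_truth.json`).
#' @return A list with `events` (list of trial-record tibbles), `voxel`
#'   (list of per-subject session-series lists), `cohort` (tibble:
#'   `subject`, `sles`, `fluid_iq`, `age`; the `pe_beta` column is added
#'   by the analysis pipeline), and `truth` (tibble including the true
#'   RL parameters and BOLD scale).
#' @export
generate_cohort <- function(spec = cohort_spec(), dir = NULL) {
  n <- spec$n_subjects
  tab <- simulate_cohort_table(spec)
  thetas <- MASS::mvrnorm(n, spec$prior$mu, spec$prior$sigma)
  thetas <- matrix(thetas, ncol = 3)

  events <- vector("list", n)
  voxel <- vector("list", n)
  for (i in seq_len(n)) {
    pars <- from_theta(thetas[i, ])
    events[[i]] <- simulate_agent(pars, spec$cfg)
    pe <- sequence_loglik(events[[i]], pars)$trace$pe
    des <- build_design(events[[i]], pe, spec$protocol)
    voxel[[i]] <- simulate_bold(des, tab$truth$bold_scale[i],
                                noise_sd = spec$bold_noise_sd,
                                ar1_coef = spec$bold_ar1,
                                baseline = spec$bold_baseline)
  }

  truth <- tab$truth
  truth$epsilon <- stats::plogis(thetas[, 1])
  truth$beta_rew <- exp(thetas[, 2])
  truth$beta_pun <- exp(thetas[, 3])
  cohort <- tab$cohort[, c("subject", "sles", "fluid_iq", "age")]

  out <- list(events = events, voxel = voxel, cohort = cohort, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_events(events[[i]], file.path(dir, sprintf("sub%02d_events.tsv", i)))
      for (s in seq_along(voxel[[i]]))
        write_voxel_series(voxel[[i]][[s]],
                           file.path(dir, sprintf("sub%02d_ses%d_voxel.tsv", i, s)))
    }
    utils::write.csv(as.data.frame(cohort), file.path(dir, "cohort.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.data.frame(truth),
                         file.path(dir, "ground_truth.json"),
                         digits = NA)
  }
  out
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates a cohort, fits the hierarchical RL model by EM, computes
#' prediction errors at the MAP estimates, estimates each subject's BOLD
#' PE beta by GLM, and runs the two-step moderation regression of fluid
#' IQ on the PE beta and SLES — then scores every stage against the
#' generative ground truth.
#'
#' @param spec a [cohort_spec()].
#' @param sles_coding passed to [moderation_regression()].
#' @param em_max_iter,n_restarts fitting effort knobs.
#' @return A list with `moderation` (a `moderation_result`), `subgroups`
#'   (low/high SLES R-squared), `cohort` (with the estimated `pe_beta`
#'   column), `em` (the `em_fit`), and `recovery` (rank correlations of
#'   true vs recovered learning rate and reward sensitivity, correlation
#'   and RMSE of true vs estimated BOLD scale).
#' @export
end_to_end <- function(spec = cohort_spec(),
                       sles_coding = "median_split",
                       em_max_iter = 25, n_restarts = 3) {
  data <- generate_cohort(spec)
  em <- em_fit_population(data$events, max_iter = em_max_iter,
                          n_restarts = n_restarts)
  traces <- compute_pe_sequences(em$fits, data$events)
  pe_beta <- vapply(seq_along(data$events), function(i) {
    des <- build_design(data$events[[i]], traces[[i]]$pe, spec$protocol)
    fit_glm(data$voxel[[i]], des)$beta_pe
  }, 0)
  cohort <- data$cohort
  cohort$pe_beta <- pe_beta

  moderation <- moderation_regression(cohort, sles_coding = sles_coding)
  split <- median_split_code(cohort$sles)
  subgroups <- tryCatch(subgroup_r2(cohort, split), error = function(e) NULL)

  eps_hat <- vapply(em$fits, function(f) f$params$epsilon, 0)
  brew_hat <- vapply(em$fits, function(f) f$params$beta_rew, 0)
  recovery <- list(
    epsilon_rank_cor = stats::cor(data$truth$epsilon, eps_hat,
                                  method = "spearman"),
    beta_rew_rank_cor = stats::cor(data$truth$beta_rew, brew_hat,
                                   method = "spearman"),
    scale_cor = stats::cor(data$truth$bold_scale, pe_beta),
    scale_rmse = sqrt(mean((data$truth$bold_scale - pe_beta)^2)))

  list(moderation = moderation, subgroups = subgroups, cohort = cohort,
       em = em, recovery = recovery)
}
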