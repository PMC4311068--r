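#' Scan protocol parameters
#'
#' @param tr_s repetition time in seconds.
#' @param n_volumes_per_session EPI volumes acquired per session.
#' @param n_sessions number of sessions.
#' @param microtime_resolution temporal subdivisions per TR used when
#'   placing event sticks and convolving with the HRF.
#' @return A list of class `scan_protocol`.
#' @export
scan_protocol <- function(tr_s = 2.3, n_volumes_per_session = 310L,
                          n_sessions = 2L, microtime_resolution = 16L) {
  stopifnot(tr_s > 0, n_volumes_per_session > 0, n_sessions > 0,
            microtime_resolution > 0)
  structure(list(tr_s = tr_s,
                 n_volumes_per_session = as.integer(n_volumes_per_session),
                 n_sessions = as.integer(n_sessions),
                 microtime_resolution = as.integer(microtime_resolution)),
            class = "scan_protocol")
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard canonical HRF: a gamma density peaking at 6 s minus a
#' 1/6-weighted gamma undershoot peaking at 16 s, with 32 s of support,
#' sampled on the microtime grid (`tr_s / microtime_resolution` seconds
#' per bin) and normalized to unit peak, so a regression coefficient on a
#' convolved unit stick reads as the BOLD amplitude at the response peak.
#'
#' @param tr_s repetition time in seconds.
#' @param microtime_resolution subdivisions per TR.
#' @return A list with `kernel` (samples on the microtime grid), `dt`
#'   (grid step, seconds) and `t` (sample times).
#' @export
canonical_hrf <- function(tr_s = 2.3, microtime_resolution = 16L) {
  stopifnot(tr_s > 0, microtime_resolution > 0)
  dt <- tr_s / microtime_resolution
  t <- seq(0, 32, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  list(kernel = h / max(h), dt = dt, t = t)
}

# Build one session's design matrix on the microtime grid.
build_session_design <- function(onsets, pe, protocol, hrf, nuisance = NULL) {
  mt <- protocol$microtime_resolution
  n_vol <- protocol$n_volumes_per_session
  n_bins <- n_vol * mt
  scan_end <- n_vol * protocol$tr_s
  bad <- which(onsets >= scan_end | onsets < 0)
  if (length(bad))
    stop("feedback onset outside the scanned interval for trial(s) ",
         paste(bad, collapse = ", "))

  bins <- floor(onsets / hrf$dt) + 1L
  u_onset <- numeric(n_bins)
  u_mod <- numeric(n_bins)
  pe_c <- pe - mean(pe)  # mean-centered per session (parametric modulation)
  for (i in seq_along(bins)) {
    u_onset[bins[i]] <- u_onset[bins[i]] + 1
    u_mod[bins[i]] <- u_mod[bins[i]] + pe_c[i]
  }
  conv <- function(u) {
    y <- stats::convolve(u, rev(hrf$kernel), type = "open")
    y[seq_len(n_bins)]
  }
  keep <- (seq_len(n_vol) - 1L) * mt + 1L
  X <- cbind(intercept = 1, onset = conv(u_onset)[keep],
             pe_mod = conv(u_mod)[keep])
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_vol) stop("nuisance rows must match volumes")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  X
}

#' Build PE-modulated feedback-onset regressors
#'
#' For each session, places a stick (delta) function at every feedback
#' onset on the microtime grid, plus a parametrically modulated copy whose
#' stick heights are the session-mean-centered trial prediction errors.
#' Both are convolved with the canonical HRF and down-sampled to the TR
#' grid. Mean-centering the modulator keeps it orthogonal in expectation
#' to the unmodulated onset regressor.
#'
#' @param events a trial-record tibble (all sessions); `onset_s` is
#'   seconds from session start.
#' @param pe numeric vector of trial prediction errors aligned with
#'   `events` rows (e.g. the `pe` column of a [sequence_loglik()] trace).
#' @param protocol a [scan_protocol()].
#' @param nuisance optional list (one matrix per session) of nuisance
#'   regressor columns.
#' @return A list of class `pe_design` with `sessions` (one design matrix
#'   per session: columns `intercept`, `onset`, `pe_mod`, nuisance) and
#'   `protocol`.
#' @export
build_design <- function(events, pe, protocol = scan_protocol(),
                         nuisance = NULL) {
  if (length(pe) != nrow(events)) stop("pe must align with events rows")
  hrf <- canonical_hrf(protocol$tr_s, protocol$microtime_resolution)
  sessions <- sort(unique(events$session))
  mats <- lapply(seq_along(sessions), function(k) {
    sel <- events$session == sessions[k]
    build_session_design(events$onset_s[sel], pe[sel], protocol, hrf,
                         nuisance = if (is.null(nuisance)) NULL else nuisance[[k]])
  })
  structure(list(sessions = mats, protocol = protocol), class = "pe_design")
}

#' Simulate a voxel time series from a design
#'
#' Forward model for testing the GLM stage: the series is a baseline plus
#' `signal_scale` times the PE-modulated regressor plus stationary AR(1)
#' Gaussian noise with marginal standard deviation `noise_sd`.
#'
#' @param design a [build_design()] result.
#' @param signal_scale amplitude multiplying the PE regressor (the true
#'   per-subject "BOLD PE signal").
#' @param noise_sd marginal noise standard deviation (>= 0).
#' @param ar1_coef lag-1 autocorrelation of the noise.
#' @param baseline additive constant.
#' @return A list with one numeric vector per session.
#' @export
simulate_bold <- function(design, signal_scale, noise_sd = 1,
                          ar1_coef = 0.3, baseline = 100) {
  stopifnot(noise_sd >= 0, abs(ar1_coef) < 1)
  lapply(design$sessions, function(X) {
    n <- nrow(X)
    innov_sd <- noise_sd * sqrt(1 - ar1_coef^2)
    noise <- if (noise_sd == 0) numeric(n) else
      as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), ar1_coef,
                               method = "recursive"))
    baseline + signal_scale * X[, "pe_mod"] + noise
  })
}

#' Fit the per-subject GLM and extract the BOLD PE beta
#'
#' Ordinary least squares per session; sessions are combined by averaging
#' the betas (the standard error of the average pools the per-session
#' standard errors). The PE-modulator coefficient is the subject's "BOLD
#' PE signal" carried into the group-level analysis. Note the
#' t-statistic is naive with respect to temporal autocorrelation (OLS
#' betas stay unbiased under AR(1) noise).
#'
#' @param series list of per-session voxel time series (a bare numeric
#'   vector is treated as one session).
#' @param design a [build_design()] result.
#' @return A list of class `glm_result`: `beta_pe`, `beta_onset`,
#'   `residual_variance`, `t_beta_pe`, `df`, and `per_session` (tibble of
#'   session-level estimates).
#' @export
fit_glm <- function(series, design) {
  if (is.numeric(series)) series <- list(series)
  if (length(series) != length(design$sessions))
    stop("series/design session count mismatch")
  per <- lapply(seq_along(series), function(k) {
    X <- design$sessions[[k]]
    y <- series[[k]]
    if (length(y) != nrow(X)) stop("series length must match design rows")
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dropped <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
      stop("rank-deficient design; offending column(s): ",
           paste(dropped, collapse = ", "))
    }
    fit <- stats::lm.fit(X, y)
    df <- length(y) - ncol(X)
    s2 <- sum(fit$residuals^2) / df
    xtx_inv <- chol2inv(qr.R(qx))
    se <- sqrt(s2 * diag(xtx_inv))
    names(se) <- colnames(X)
    list(beta = fit$coefficients, se = se, s2 = s2, df = df)
  })
  k <- length(per)
  beta_pe <- mean(vapply(per, function(p) p$beta[["pe_mod"]], 0))
  beta_onset <- mean(vapply(per, function(p) p$beta[["onset"]], 0))
  se_mean <- sqrt(sum(vapply(per, function(p) p$se[["pe_mod"]]^2, 0))) / k
  df <- sum(vapply(per, function(p) p$df, 0))
  structure(list(
    beta_pe = beta_pe, beta_onset = beta_onset,
    residual_variance = mean(vapply(per, function(p) p$s2, 0)),
    t_beta_pe = beta_pe / se_mean, df = df,
    per_session = tibble::tibble(
      session = seq_len(k),
      beta_pe = vapply(per, function(p) p$beta[["pe_mod"]], 0),
      se_pe = vapply(per, function(p) p$se[["pe_mod"]], 0))
  ), class = "glm_result")
}

#' Write / read a voxel time series
#'
#' Tab-separated columns `volume`, `signal`; one file per session.
#'
#' @param series numeric vector for one session.
#' @param path file path.
#' @return `write_voxel_series` returns `path` invisibly;
#'   `read_voxel_series` the numeric vector.
#' @export
write_voxel_series <- function(series, path) {
  utils::write.table(
    data.frame(volume = seq_along(series), signal = series),
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_voxel_series
#' @export
read_voxel_series <- function(path) {
  utils::read.delim(path)$signal
}
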