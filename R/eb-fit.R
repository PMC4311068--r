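#' Gaussian population prior over transformed parameters
#'
#' The hierarchical model treats each subject's transformed parameter
#' vector `theta = (logit eps, log beta_rew, log beta_pun)` as a draw from
#' `N(mu, sigma)`. `mu` and `sigma` are estimated from the whole cohort by
#' expectation-maximization ([em_fit_population()]) and then act as the
#' prior for per-subject MAP estimates.
#'
#' @param mu numeric 3-vector.
#' @param sigma 3x3 symmetric positive-definite covariance matrix.
#' @return A list of class `population_prior`.
#' @export
population_prior <- function(mu = rep(0, 3), sigma = diag(6.25, 3)) {
  mu <- as.numeric(mu)
  sigma <- as.matrix(sigma)
  stopifnot(length(mu) == 3, all(dim(sigma) == c(3, 3)))
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("sigma must be symmetric")
  if (any(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("sigma must be positive definite")
  structure(list(mu = mu, sigma = (sigma + t(sigma)) / 2),
            class = "population_prior")
}

# log N(theta; mu, sigma) via the Cholesky factor
log_mvnorm <- function(theta, mu, chol_sigma) {
  z <- backsolve(chol_sigma, theta - mu, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(chol_sigma))) - 1.5 * log(2 * pi)
}

# negative log-posterior in transformed space
make_neg_log_post <- function(enc, prior, carry_over) {
  chol_sigma <- chol(prior$sigma)
  function(theta) {
    eps <- stats::plogis(theta[1])
    ll <- rw_loglik_cpp(enc$choice, enc$outcome, enc$session,
                        eps, exp(theta[2]), exp(theta[3]),
                        carry_over)$loglik
    -(ll + log_mvnorm(theta, prior$mu, chol_sigma))
  }
}

#' MAP fit of one subject's RW parameters under a Gaussian prior
#'
#' Maximizes `log p(A | theta) + log N(theta; mu, sigma)` over the
#' transformed parameter vector by quasi-Newton (BFGS) optimization from
#' multiple starting points: the prior mean plus `n_restarts - 1` draws
#' from the prior (RL likelihoods can be multimodal). The best optimum is
#' kept; its curvature (Hessian of the negative log-posterior) is returned
#' for the Laplace approximation used by the EM loop.
#'
#' @param events a trial-record tibble for one subject.
#' @param prior a [population_prior()].
#' @param n_restarts number of optimization starts (>= 1).
#' @param carry_over see [sequence_loglik()].
#' @param start optional list of extra starting vectors (used internally
#'   for warm starts).
#' @return A list of class `subject_fit`: `theta_map`, `params`
#'   (natural-space [agent_params()]), `loglik` (data log-likelihood term
#'   at the MAP), `log_posterior`, `hessian` (3x3), `n_trials`.
#' @export
map_fit_subject <- function(events, prior = population_prior(),
                            n_restarts = 5, carry_over = TRUE,
                            start = NULL) {
  enc <- encode_events(events)
  if (length(enc$choice) < 20)
    warning("fewer than 20 trials; parameter estimates will be prior-dominated")
  nlp <- make_neg_log_post(enc, prior, carry_over)

  starts <- c(list(prior$mu), start)
  if (n_restarts > length(starts)) {
    # restart draws come from the prior, but with the spread capped so a
    # deliberately flat prior still yields starts in the numerically
    # sensible region of the transformed space
    cap <- 6.25 / max(diag(prior$sigma))
    restart_sigma <- if (cap < 1) prior$sigma * cap else prior$sigma
    extra <- MASS::mvrnorm(n_restarts - length(starts), prior$mu, restart_sigma)
    extra <- matrix(extra, ncol = 3)
    starts <- c(starts, lapply(seq_len(nrow(extra)), function(i) extra[i, ]))
  }

  best <- NULL
  failures <- character(0)
  for (s0 in starts) {
    opt <- tryCatch(
      stats::optim(s0, nlp, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) e)
    if (inherits(opt, "error")) {
      failures <- c(failures, conditionMessage(opt))
      next
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("MAP optimization failed on all restarts: ",
         paste(unique(failures), collapse = "; "))

  theta <- best$par
  hess <- stats::optimHess(theta, nlp)
  hess <- (hess + t(hess)) / 2
  params <- from_theta(theta)
  ll <- sequence_loglik(events, params, carry_over)$loglik
  structure(list(theta_map = theta, params = params, loglik = ll,
                 log_posterior = -best$value, hessian = hess,
                 n_trials = length(enc$choice)),
            class = "subject_fit")
}

# Laplace covariance = inverse Hessian of the negative log-posterior,
# guarded against non-PD curvature at flat or ridge-shaped optima.
laplace_cov <- function(hessian) {
  ev <- eigen(hessian, symmetric = TRUE)
  vals <- pmax(ev$values, 1e-6)
  ev$vectors %*% diag(1 / vals) %*% t(ev$vectors)
}

#' Hierarchical empirical-Bayes fit of a cohort by expectation-maximization
#'
#' Alternates an E-step — per-subject MAP estimates and Laplace
#' covariances under the current prior — with an M-step that re-estimates
#' the population prior: `mu <-` mean of the MAP vectors and `sigma <-`
#' mean of `outer(theta_i - mu) + H_i^{-1}` (the Laplace covariance term
#' prevents the prior variance collapsing onto the point estimates).
#' Iteration stops when the largest absolute change in `mu` and `sigma`
#' falls below `tol` or after `max_iter` iterations. Subject fits keep the
#' previous iteration's optimum as a warm start alongside fresh restarts.
#'
#' @param events_list list of per-subject trial-record tibbles (>= 2).
#' @param init initial [population_prior()]; the default is broad
#'   (`mu = 0`, `sigma = 6.25 I`) to avoid early over-shrinkage.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the prior parameters.
#' @param n_restarts optimization restarts per subject and iteration (the
#'   previous iteration's optimum is always an extra starting point).
#' @param diagonal_sigma if `TRUE` (default), keep only the diagonal of
#'   the M-step covariance update. At typical cohort sizes the
#'   off-diagonal entries are dominated by Laplace-approximation noise,
#'   and carrying them into the prior couples the weakly identified
#'   punishment sensitivity to the other parameters, degrading their
#'   recovery; set `FALSE` for a full covariance.
#' @param carry_over see [sequence_loglik()].
#' @param verbose print per-iteration progress.
#' @return A list of class `em_fit`: `prior` (final
#'   [population_prior()]), `fits` (list of `subject_fit`), `summary`
#'   (cohort quartile table, see [fit_summary()]), `em_iterations`,
#'   `converged`, and `objective_trace` (summed per-subject log-posterior
#'   at each iteration's prior, a monotonicity diagnostic up to Laplace
#'   noise).
#' @export
em_fit_population <- function(events_list, init = population_prior(),
                              max_iter = 100, tol = 1e-3, n_restarts = 5,
                              diagonal_sigma = TRUE, carry_over = TRUE,
                              verbose = FALSE) {
  n <- length(events_list)
  if (n < 2) stop("need at least 2 subjects for a population fit")
  prior <- init
  fits <- vector("list", n)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0

  for (iter in seq_len(max_iter)) {
    warm <- if (iter == 1) vector("list", n) else lapply(fits, `[[`, "theta_map")
    for (i in seq_len(n)) {
      fits[[i]] <- map_fit_subject(
        events_list[[i]], prior, n_restarts = n_restarts,
        carry_over = carry_over,
        start = if (is.null(warm[[i]])) NULL else list(warm[[i]]))
    }
    objective <- c(objective, sum(vapply(fits, `[[`, 0, "log_posterior")))

    thetas <- t(vapply(fits, `[[`, numeric(3), "theta_map"))
    mu_new <- colMeans(thetas)
    covs <- lapply(fits, function(f) laplace_cov(f$hessian))
    sigma_new <- Reduce(`+`, lapply(seq_len(n), function(i) {
      d <- thetas[i, ] - mu_new
      outer(d, d) + covs[[i]]
    })) / n
    if (diagonal_sigma) sigma_new <- diag(diag(sigma_new))
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    ev <- eigen(sigma_new, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8) {
      warning("M-step covariance nearly singular; adding diagonal jitter")
      sigma_new <- sigma_new + diag(1e-6 - min(ev, 0), 3)
    }

    delta <- max(max(abs(mu_new - prior$mu)), max(abs(sigma_new - prior$sigma)))
    prior <- population_prior(mu_new, sigma_new)
    if (verbose)
      message(sprintf("EM iter %d: objective %.3f, delta %.5f",
                      iter, objective[iter], delta))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  structure(list(prior = prior, fits = fits, summary = fit_summary(fits),
                 em_iterations = iter, converged = converged,
                 objective_trace = objective),
            class = "em_fit")
}

#' Cohort summary of fitted parameters (quartile table)
#'
#' 25th/50th/75th percentiles across subjects of the natural-space reward
#' and punishment sensitivities, the negative data log-likelihood at the
#' optimum, and the learning rate — the conventional reporting format for
#' cohort RL fits.
#'
#' @param fits list of `subject_fit` objects.
#' @return A tibble with rows q25/median/q75 and columns `beta_rew`,
#'   `beta_pun`, `neg_loglik`, `epsilon`.
#' @export
fit_summary <- function(fits) {
  g <- function(f) c(f$params$beta_rew, f$params$beta_pun, -f$loglik,
                     f$params$epsilon)
  m <- t(vapply(fits, g, numeric(4)))
  q <- apply(m, 2, stats::quantile, probs = c(0.25, 0.5, 0.75))
  tibble::tibble(quantile = c("q25", "median", "q75"),
                 beta_rew = q[, 1], beta_pun = q[, 2],
                 neg_loglik = q[, 3], epsilon = q[, 4])
}

#' Prediction-error sequences at the fitted parameters
#'
#' Recomputes each subject's trial-wise value/prediction-error trace at
#' the MAP parameter estimates; identical to the side product of
#' [sequence_loglik()] at `theta_map`.
#'
#' @param fits list of `subject_fit` objects.
#' @param events_list matching list of trial-record tibbles.
#' @param carry_over see [sequence_loglik()].
#' @return List of trace tibbles.
#' @export
compute_pe_sequences <- function(fits, events_list, carry_over = TRUE) {
  if (length(fits) != length(events_list))
    stop("fits and events_list must have the same length")
  lapply(seq_along(fits), function(i) {
    sequence_loglik(events_list[[i]], fits[[i]]$params, carry_over)$trace
  })
}

#' Write per-subject fits as CSV and the population prior as JSON
#'
#' @param fits list of `subject_fit` objects.
#' @param path output file path.
#' @param subject_ids optional subject identifiers.
#' @return The path, invisibly.
#' @export
write_fits_csv <- function(fits, path, subject_ids = seq_along(fits)) {
  d <- data.frame(
    subject = subject_ids,
    epsilon = vapply(fits, function(f) f$params$epsilon, 0),
    beta_rew = vapply(fits, function(f) f$params$beta_rew, 0),
    beta_pun = vapply(fits, function(f) f$params$beta_pun, 0),
    neg_loglik = vapply(fits, function(f) -f$loglik, 0),
    n_trials = vapply(fits, function(f) f$n_trials, 0L)
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @param fit an `em_fit` object.
#' @rdname write_fits_csv
#' @export
write_prior_json <- function(fit, path) {
  jsonlite::write_json(
    list(mu = fit$prior$mu, sigma = fit$prior$sigma,
         em_iterations = fit$em_iterations, converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
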