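#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-constant.
#' @return A list with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Median-split coding of stressful life event counts
#'
#' Subjects reporting below-median SLES are coded 1, above-median 2.
#' Subjects exactly at the median join the low group (configurable).
#'
#' @param sles numeric vector of event counts (n >= 2).
#' @param ties_high if `TRUE`, ties at the median go to the high group
#'   instead.
#' @return Integer vector of 1/2 codes.
#' @export
median_split_code <- function(sles, ties_high = FALSE) {
  if (length(sles) < 2) stop("need at least 2 values")
  med <- stats::median(sles)
  code <- if (ties_high) ifelse(sles >= med, 2L, 1L) else
    ifelse(sles > med, 2L, 1L)
  if (length(unique(code)) == 1)
    warning("degenerate median split: all subjects in one group")
  code
}

# standardized coefficients: b * sd(x) / sd(y), intercept dropped
std_betas <- function(fit, y) {
  X <- stats::model.matrix(fit)
  b <- stats::coef(fit)
  keep <- setdiff(names(b), "(Intercept)")
  vapply(keep, function(nm) b[[nm]] * stats::sd(X[, nm]) / stats::sd(y), 0)
}

check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("collinear predictors; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
}

#' Two-step moderation regression of fluid IQ on the BOLD PE signal and SLES
#'
#' Hierarchical (two-step) entry: step 1 regresses fluid IQ on the
#' per-subject BOLD PE beta and the SLES term; step 2 adds their product
#' (the moderation term). The interaction's contribution is tested by the
#' F-change statistic
#' `((R2_full - R2_base) / q) / ((1 - R2_full) / (n - k - 1))`,
#' with `q` added terms and `k` predictors in the full model. SLES enters
#' either as the 1/2 median-split code or as a z-transformed continuous
#' score; in both codings the PE beta is left uncentered in the product
#' (a centered variant is available). Influence diagnostics (Cook's
#' distance, standardized residuals) are reported for the full model;
#' points are flagged, never dropped.
#'
#' @param cohort a data frame with columns `fluid_iq`, `pe_beta`, `sles`
#'   and (if `age_covariate`) `age`.
#' @param sles_coding `"median_split"` (1/2 code) or `"continuous_z"`
#'   (z-transformed count).
#' @param age_covariate include age as a covariate in both steps.
#' @param center_pe mean-center the PE beta before forming the product.
#' @param ties_high see [median_split_code()].
#' @return A list of class `moderation_result`: `coefficients` (tibble of
#'   standardized betas and t values per step), `r2_base`, `r2_full`,
#'   `f_change`, `p_f_change`, `cooks_distance`, `residual_z`,
#'   `flagged` (Cook's distance >= 1 or |z| >= 3), `n`, and the two `lm`
#'   fits (`fit_base`, `fit_full`).
#' @export
moderation_regression <- function(cohort,
                                  sles_coding = c("median_split", "continuous_z"),
                                  age_covariate = FALSE,
                                  center_pe = FALSE,
                                  ties_high = FALSE) {
  sles_coding <- match.arg(sles_coding)
  need <- c("fluid_iq", "pe_beta", "sles", if (age_covariate) "age")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  d <- as.data.frame(cohort)[, need]
  if (anyNA(d)) stop("missing values in cohort; complete cases required")
  n <- nrow(d)
  if (n < 4) stop("need at least 4 subjects")

  d$sles_code <- if (sles_coding == "median_split")
    as.numeric(median_split_code(d$sles, ties_high)) else
    as.numeric(scale(d$sles))
  pe <- if (center_pe) d$pe_beta - mean(d$pe_beta) else d$pe_beta
  d$interaction <- pe * d$sles_code

  base_terms <- c("pe_beta", "sles_code", if (age_covariate) "age")
  f_base <- stats::reformulate(base_terms, response = "fluid_iq")
  f_full <- stats::reformulate(c(base_terms, "interaction"),
                               response = "fluid_iq")
  check_full_rank(stats::model.matrix(f_full, d))
  fit_base <- stats::lm(f_base, data = d)
  fit_full <- stats::lm(f_full, data = d)

  r2_base <- summary(fit_base)$r.squared
  r2_full <- summary(fit_full)$r.squared
  q <- 1
  k <- length(stats::coef(fit_full)) - 1
  f_change <- ((r2_full - r2_base) / q) / ((1 - r2_full) / (n - k - 1))
  p_f_change <- stats::pf(f_change, q, n - k - 1, lower.tail = FALSE)

  coefs <- rbind(
    tibble::tibble(step = 1L,
                   term = names(std_betas(fit_base, d$fluid_iq)),
                   beta_std = std_betas(fit_base, d$fluid_iq),
                   b = stats::coef(fit_base)[-1],
                   t = summary(fit_base)$coefficients[-1, "t value"],
                   p = summary(fit_base)$coefficients[-1, "Pr(>|t|)"]),
    tibble::tibble(step = 2L,
                   term = names(std_betas(fit_full, d$fluid_iq)),
                   beta_std = std_betas(fit_full, d$fluid_iq),
                   b = stats::coef(fit_full)[-1],
                   t = summary(fit_full)$coefficients[-1, "t value"],
                   p = summary(fit_full)$coefficients[-1, "Pr(>|t|)"]))

  cooks <- stats::cooks.distance(fit_full)
  rz <- stats::rstandard(fit_full)
  structure(list(
    coefficients = coefs, r2_base = r2_base, r2_full = r2_full,
    f_change = f_change, p_f_change = p_f_change,
    cooks_distance = unname(cooks), residual_z = unname(rz),
    flagged = unname(cooks >= 1 | abs(rz) >= 3), n = n,
    sles_coding = sles_coding, fit_base = fit_base, fit_full = fit_full
  ), class = "moderation_result")
}

#' @export
print.moderation_result <- function(x, ...) {
  cat(sprintf("Moderation regression (SLES coding: %s, n = %d)\n",
              x$sles_coding, x$n))
  cat(sprintf("  R2 step 1 (main effects): %.3f\n", x$r2_base))
  cat(sprintf("  R2 step 2 (+ interaction): %.3f\n", x$r2_full))
  cat(sprintf("  F-change = %.3f, p = %.4f\n", x$f_change, x$p_f_change))
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  if (any(x$flagged))
    cat("  influence flags on subject(s):",
        paste(which(x$flagged), collapse = ", "), "\n")
  cat(sprintf("  max Cook's distance = %.3f\n", max(x$cooks_distance)))
  invisible(x)
}

#' Within-subgroup variance explained by the PE beta
#'
#' Simple-regression R-squared of fluid IQ on the PE beta computed
#' separately in the low- and high-SLES subgroups (the subgroup scatter
#' behind a median-split moderation plot).
#'
#' @param cohort data frame with `fluid_iq`, `pe_beta`.
#' @param split vector of 1/2 subgroup codes (e.g. from
#'   [median_split_code()]).
#' @return A list with `r2_low` and `r2_high`.
#' @export
subgroup_r2 <- function(cohort, split) {
  stopifnot(length(split) == nrow(cohort), all(split %in% c(1, 2)))
  one <- function(g) {
    d <- cohort[split == g, ]
    if (nrow(d) < 3) stop("subgroup ", g, " has fewer than 3 subjects")
    if (stats::sd(d$pe_beta) == 0)
      stop("pe_beta is constant within subgroup ", g)
    summary(stats::lm(fluid_iq ~ pe_beta, data = d))$r.squared
  }
  list(r2_low = one(1), r2_high = one(2))
}

#' Write a moderation result as JSON plus a tidy coefficients CSV
#'
#' @param result a `moderation_result`.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @return `result`, invisibly.
#' @export
write_moderation_result <- function(result, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(
      list(r2_base = result$r2_base, r2_full = result$r2_full,
           f_change = result$f_change, p_f_change = result$p_f_change,
           n = result$n, sles_coding = result$sles_coding,
           cooks_distance = result$cooks_distance,
           residual_z = result$residual_z, flagged = result$flagged),
      json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(result$coefficients), csv_path,
                     row.names = FALSE)
  invisible(result)
}
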