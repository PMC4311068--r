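test_that("pearson_r matches the textbook formula and handles edge cases", {
  x <- c(1, 3, 4, 6, 8)
  y <- c(2, 3, 7, 8, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  res <- pearson_r(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 3), tolerance = 1e-12)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x + 7)$r, -1)
  expect_error(pearson_r(x, rep(1, 5)))
  expect_error(pearson_r(1:2, 1:2))
})

test_that("median split codes below-median as 1, ties to the low group", {
  expect_equal(median_split_code(c(1, 2, 3, 4)), c(1L, 1L, 2L, 2L))
  expect_equal(median_split_code(c(10, 17, 17, 20, 30)),
               c(1L, 1L, 1L, 2L, 2L))  # ties at the median stay low
  expect_equal(median_split_code(c(10, 17, 17, 20, 30), ties_high = TRUE),
               c(1L, 2L, 2L, 2L, 2L))
  expect_warning(code <- median_split_code(rep(5, 4)))
  expect_true(all(code == 1L))
  # a synthetic SLES vector splitting at 17 reported events
  set.seed(50)
  sles <- pmin(pmax(round(rnorm(16, 16.31, 4.59)), 0), 42)
  med <- median(sles)
  code <- median_split_code(sles)
  expect_true(all(code[sles > med] == 2L))
  expect_true(all(code[sles <= med] == 1L))
})

test_that("two-step moderation regression reports coherent statistics", {
  set.seed(51)
  d <- simulate_cohort_table(cohort_spec())$cohort
  m <- moderation_regression(d)
  expect_gte(m$r2_full, m$r2_base)
  expect_lte(m$r2_full, 1)
  expect_gte(m$f_change, 0)

  # F-change from R-squared equals the partial F of the added term
  aov <- anova(m$fit_base, m$fit_full)
  expect_equal(m$f_change, aov$F[2], tolerance = 1e-10)
  expect_equal(m$p_f_change, aov$`Pr(>F)`[2], tolerance = 1e-10)

  # location invariance: shifting the outcome leaves slopes and fit alone
  d2 <- d; d2$fluid_iq <- d2$fluid_iq + 100
  m2 <- moderation_regression(d2)
  expect_equal(m2$coefficients$b, m$coefficients$b, tolerance = 1e-8)
  expect_equal(m2$r2_full, m$r2_full, tolerance = 1e-10)
  expect_equal(m2$f_change, m$f_change, tolerance = 1e-8)

  # standardized betas are invariant to rescaling a raw predictor
  d3 <- d; d3$pe_beta <- d3$pe_beta * 1000
  m3 <- moderation_regression(d3)
  expect_equal(m3$coefficients$beta_std[m3$coefficients$term == "pe_beta"],
               m$coefficients$beta_std[m$coefficients$term == "pe_beta"],
               tolerance = 1e-8)

  # continuous coding and optional age covariate run and keep invariants
  mc <- moderation_regression(d, sles_coding = "continuous_z",
                              age_covariate = TRUE)
  expect_gte(mc$r2_full, mc$r2_base)
  expect_true("age" %in% mc$coefficients$term)

  # degenerate input surfaces a named error
  d4 <- d; d4$pe_beta <- 2 * d4$sles
  expect_error(moderation_regression(d4, sles_coding = "continuous_z"))
  expect_error(moderation_regression(d[1:3, ]))
  expect_error(moderation_regression(d[, c("sles", "fluid_iq")]), "pe_beta")
})

test_that("influence diagnostics flag planted outliers and spare the centroid", {
  set.seed(52)
  d <- simulate_cohort_table(cohort_spec())$cohort
  # a point at the predictor centroid lying on the fitted plane has
  # negligible influence
  m0 <- moderation_regression(d)
  centroid <- d[1, ]
  centroid$pe_beta <- mean(d$pe_beta)
  centroid$sles <- median(d$sles)  # joins the low group; median unchanged
  code <- 1
  b <- coef(m0$fit_full)
  centroid$fluid_iq <- b[["(Intercept)"]] + b[["pe_beta"]] * centroid$pe_beta +
    b[["sles_code"]] * code + b[["interaction"]] * centroid$pe_beta * code
  m <- moderation_regression(rbind(d, centroid))
  expect_lt(m$cooks_distance[nrow(d) + 1], 0.02)

  # a manufactured high-leverage outlier gets the cohort's max distance
  outlier <- d[1, ]
  outlier$pe_beta <- max(d$pe_beta) + 6 * sd(d$pe_beta)
  outlier$fluid_iq <- min(d$fluid_iq) - 6 * sd(d$fluid_iq)
  m2 <- moderation_regression(rbind(d, outlier))
  expect_equal(which.max(m2$cooks_distance), nrow(d) + 1)
  # flags are reported, nothing is dropped
  expect_equal(m2$n, nrow(d) + 1)
  expect_length(m2$flagged, nrow(d) + 1)
})

test_that("subgroup R-squared separates planted moderation", {
  spec <- cohort_spec()
  set.seed(53)
  wins <- 0
  for (i in 1:20) {
    d <- simulate_cohort_table(spec)$cohort
    s <- subgroup_r2(d, median_split_code(d$sles))
    expect_gte(s$r2_low, 0); expect_lte(s$r2_high, 1)
    if (s$r2_high > s$r2_low) wins <- wins + 1
  }
  expect_gt(wins, 10)  # the majority of seeds

  # perfectly linear subgroup reaches R2 = 1; constant predictor errors
  d <- tibble::tibble(fluid_iq = c(1, 2, 3, 1, 2, 4),
                      pe_beta = c(1, 2, 3, 1, 1, 1))
  split <- c(1, 1, 1, 2, 2, 2)
  expect_error(suppressWarnings(subgroup_r2(d, split)), "constant")
  d$pe_beta[4:6] <- c(2, 4, 8)
  # lm warns about the deliberately perfect fit; the R2 value is the point
  expect_equal(suppressWarnings(subgroup_r2(d, split)$r2_low), 1)
  expect_error(suppressWarnings(subgroup_r2(d[1:4, ], split[1:4])))
})

test_that("moderation results serialize to JSON and CSV", {
  set.seed(54)
  m <- moderation_regression(simulate_cohort_table(cohort_spec())$cohort)
  js <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_moderation_result(m, js, csv)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$f_change, m$f_change)
  expect_equal(j$r2_full, m$r2_full)
  d <- utils::read.csv(csv)
  expect_equal(nrow(d), nrow(m$coefficients))
  expect_output(print(m), "F-change")
})
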