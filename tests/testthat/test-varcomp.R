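test_that("constant response gives all-zero variance components", {
  panel <- data.frame(WB = rep(c("A", "B"), 4), Year = rep(c("Y1", "Y2"), each = 4),
                      Surveyor = "S1", EQR = 0.7)
  fit <- fit_reml(panel, structure = c("wb", "year"))
  expect_equal(fit$var_wb, 0)
  expect_equal(fit$var_year, 0)
  expect_equal(fit$var_residual, 0)
  expect_equal(fit$grand_mean, 0.7)
  rf <- residuals_vs_fitted(fit)
  expect_equal(rf$residual, rep(0, 8))
})

test_that("REML equals the balanced one-way ANOVA moment estimator", {
  panel <- make_oneway_panel(g = 7, r = 4, seed = 11)
  oracle <- oneway_anova_oracle(panel)
  expect_gt(oracle$between, 0)  # fixture chosen with a positive estimator
  fit <- fit_reml(panel, structure = "wb")
  expect_equal(fit$var_wb, oracle$between, tolerance = 1e-6)
  expect_equal(fit$var_residual, oracle$within, tolerance = 1e-6)
  expect_equal(fit$grand_mean, oracle$grand, tolerance = 1e-8)
})

test_that("one-way BLUP residuals match the hand shrinkage formula", {
  panel <- make_oneway_panel(g = 6, r = 5, seed = 3)
  fit <- fit_reml(panel, structure = "wb")
  rf <- residuals_vs_fitted(fit)
  # balanced one-way BLUP: u_i = r*tau2 / (r*tau2 + s2) * (ybar_i - ybar)
  tau2 <- fit$var_wb; s2 <- fit$var_residual; r <- 5
  shrink <- r * tau2 / (r * tau2 + s2)
  means <- tapply(panel$EQR, panel$WB, mean)
  fitted_hand <- fit$grand_mean +
    shrink * (means[panel$WB] - fit$grand_mean)
  expect_equal(rf$fitted, as.numeric(fitted_hand), tolerance = 1e-6)
  expect_equal(rf$residual, panel$EQR - as.numeric(fitted_hand),
               tolerance = 1e-6)
  # residuals sum to ~0 on any fit
  expect_lt(abs(sum(rf$residual)), 1e-6)
})

test_that("crossed fits agree with lme4 on variances and REML criterion", {
  skip_if_not_installed("lme4")
  panel <- simulate_eqr_panel(n_wb = 10, n_year = 6, n_surveyor = 3,
                              var_wb = 0.02, var_year = 0.003,
                              var_surveyor = 0.001, var_residual = 0.004,
                              seed = 5)
  fit <- fit_reml(panel, structure = c("wb", "year", "surveyor"))
  m <- lme4::lmer(EQR ~ (1 | WB) + (1 | Year) + (1 | Surveyor), data = panel,
                  REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  get <- function(g) vc$vcov[vc$grp == g]
  expect_equal(fit$var_wb, get("WB"), tolerance = 1e-5)
  expect_equal(fit$var_year, get("Year"), tolerance = 1e-4)
  expect_equal(fit$var_surveyor, get("Surveyor"), tolerance = 1e-4)
  expect_equal(fit$var_residual, get("Residual"), tolerance = 1e-5)
  expect_equal(fit$criterion, lme4::REMLcrit(m), tolerance = 1e-6)
})

test_that("P_samp fractions reproduce the published decade decomposition", {
  vc <- liguria_varcomp()
  fr <- variance_fractions(vc, rounding = "integer")
  expect_equal(unname(fr[["wb"]]), 47)
  expect_equal(unname(fr[["wb_in_year:Genova-Camogli"]]), 20)
  expect_equal(unname(fr[["residual"]]), 7)
  expect_equal(unname(fr[["year"]]), 0)
  expect_equal(unname(fr[["surveyor"]]), 0)
  # unrounded fractions always sum to 100
  expect_equal(sum(variance_fractions(vc)), 100, tolerance = 1e-9)
  expect_lte(abs(sum(fr) - 100), 0.5 * length(fr))
})

test_that("fractions handle edge cases", {
  one <- variance_components(var_wb = 0.5)
  expect_equal(unname(variance_fractions(one)[["wb"]]), 100)
  zero <- variance_components()
  expect_error(variance_fractions(zero), "undefined")
  expect_error(variance_components(var_wb = -1), "non-negative")
})

test_that("response scaling scales variances by c^2, fractions unchanged", {
  panel <- simulate_eqr_panel(n_wb = 8, n_year = 5, var_wb = 0.02,
                              var_year = 0.002, var_residual = 0.004, seed = 9)
  f1 <- fit_reml(panel, structure = c("wb", "year"))
  panel2 <- panel; panel2$EQR <- 3 * panel2$EQR
  f2 <- fit_reml(panel2, structure = c("wb", "year"))
  expect_equal(f2$var_wb, 9 * f1$var_wb, tolerance = 1e-4)
  expect_equal(f2$var_residual, 9 * f1$var_residual, tolerance = 1e-4)
  expect_equal(variance_fractions(f2), variance_fractions(f1),
               tolerance = 1e-3)
})

test_that("single nonzero generating component is recovered, others near 0", {
  ests <- sapply(1:20, function(i) {
    p <- simulate_eqr_panel(n_wb = 30, n_year = 8, var_wb = 0.03,
                            var_year = 0, var_surveyor = 0,
                            var_residual = 0.004, seed = 500 + i)
    f <- fit_reml(p, structure = c("wb", "year", "surveyor"))
    c(f$var_wb, f$var_year, f$var_surveyor, f$var_residual)
  })
  m <- rowMeans(ests)
  expect_equal(m[1], 0.03, tolerance = 0.2)
  expect_equal(m[4], 0.004, tolerance = 0.2)
  expect_lt(m[2], 0.0008)
  expect_lt(m[3], 0.0008)
})

test_that("degenerate designs are diagnosed", {
  # surveyor is a relabelling of year -> completely confounded
  panel <- simulate_eqr_panel(n_wb = 6, n_year = 4, n_surveyor = 4,
                              var_wb = 0.02, var_residual = 0.004, seed = 2)
  expect_warning(fit_reml(panel, structure = c("wb", "year", "surveyor")),
                 "confounded")
  # single-level factor is rejected
  one <- data.frame(WB = "A", Year = c("Y1", "Y2"), Surveyor = "S1",
                    EQR = c(0.5, 0.6))
  expect_error(fit_reml(one, structure = "wb"), "at least 2 levels")
  # one observation per (WB, Year) cell: slope variances weakly identified
  p <- simulate_eqr_panel(n_wb = 7, n_year = 4, n_surveyor = 2,
                          var_wb = 0.03, var_residual = 0.004, seed = 4)
  expect_warning(fit_reml(p), "weakly identified")
})

test_that("AIC model comparison ranks structures sensibly", {
  # identical structures tie exactly
  panel <- simulate_eqr_panel(n_wb = 8, n_year = 5, var_wb = 0.02,
                              var_residual = 0.004, seed = 21)
  cmp <- compare_models(panel, list(c("wb", "year"), c("wb", "year")))
  expect_equal(cmp$aic[1], cmp$aic[2], tolerance = 1e-8)
  expect_identical(cmp$rank, c(1L, 1L))
  # when surveyor truly has zero variance, dropping it usually ranks no worse
  wins <- sapply(1:40, function(i) {
    p <- simulate_eqr_panel(n_wb = 8, n_year = 6, n_surveyor = 3,
                            var_wb = 0.02, var_surveyor = 0,
                            var_residual = 0.004, seed = 900 + i)
    cmp <- compare_models(p, list(c("wb", "year"),
                                  c("wb", "year", "surveyor")))
    cmp$structure[1] == "wb+year"
  })
  expect_gte(mean(wins), 0.8)
})

test_that("panel validation reports malformed input", {
  expect_error(read_panel(textConnection("WB,Year,EQR\nA,1,0.5")),
               "missing column")
  bad <- data.frame(WB = "A", Year = "Y1", Surveyor = "S1", EQR = NA)
  expect_error(fit_reml(bad), "finite")
})
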