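test_that("Tukey fences remove gross outliers and are idempotent", {
  v <- c(1, 2, 3, 4, 100)
  # oracle: type-7 quartiles of v are Q1 = 2, Q3 = 4; fences [-1, 7]
  q <- stats::quantile(v, c(0.25, 0.75), type = 7)
  expect_identical(unname(q), c(2, 4))
  res <- tukey_filter(v)
  expect_identical(res$removed, 100)
  expect_identical(res$kept, c(1, 2, 3, 4))
  # all-equal values: fences collapse, nothing removed
  same <- tukey_filter(rep(5, 6))
  expect_length(same$removed, 0L)
  # clean Normal sample: < 2% removed
  x <- withr::with_seed(3, stats::rnorm(1000))
  expect_lt(length(tukey_filter(x)$removed) / 1000, 0.02)
  # idempotence
  once <- tukey_filter(x)$kept
  expect_identical(tukey_filter(once)$kept, once)
  expect_warning(tukey_filter(c(1, 2, 3)), "fewer than 4")
})

test_that("well summaries report mean, sd, sem, cv per endpoint", {
  df <- data.frame(length_um = c(10, 10, 10), area_um2 = c(1, 2, 3),
                   volume_um3 = c(5, 5, 5))
  s <- summarize_well(df, filter = FALSE)
  expect_equal(s$endpoints$length_um$mean, 10)
  expect_equal(s$endpoints$length_um$sd, 0)
  expect_equal(s$endpoints$length_um$cv, 0)
  df2 <- data.frame(length_um = c(8, 12))
  s2 <- summarize_well(df2, filter = FALSE)
  expect_equal(s2$endpoints$length_um$mean, 10)
  expect_equal(s2$endpoints$length_um$sd, sqrt(8), tolerance = 1e-12)
  expect_equal(s2$endpoints$length_um$cv, sqrt(8) / 10, tolerance = 1e-12)
  expect_equal(s2$endpoints$length_um$sem, sqrt(8) / sqrt(2), tolerance = 1e-12)
})

test_that("the ECf transform and noiseless Hill recovery are exact", {
  expect_equal(ec_anything(2.5, 3, 50), 2.5)
  expect_equal(ec_anything(2.5, -1.2, 50), 2.5)
  doses <- exp(seq(log(0.2), log(20), length.out = 12))
  truth <- list(top = 1000, ec50 = 1.0, h = 2.2)
  mu <- truth$top / (1 + (doses / truth$ec50)^truth$h)
  fit <- hill_fit(doses, mu, "body")
  ec10_true <- (10 / 90)^(1 / truth$h) * truth$ec50
  expect_true(fit$converged)
  expect_equal(fit$ec10, ec10_true, tolerance = 1e-6)
  expect_equal(fit$ec50, truth$ec50, tolerance = 1e-6)
  # analytic inversion oracle: response at the fitted EC10 is 90% of Top
  y_at <- truth$top / (1 + (fit$ec10 / truth$ec50)^truth$h)
  expect_equal(y_at / truth$top, 0.9, tolerance = 1e-6)
})

test_that("hill_fit is scale-equivariant in dose", {
  doses <- c(0, exp(seq(log(0.2), log(20), length.out = 11)))
  mu <- 800 / (1 + (ifelse(doses == 0, 0, doses) / 1.5)^1.8)
  y <- withr::with_seed(5, mu + stats::rnorm(length(mu), 0, 10))
  f1 <- hill_fit(doses, y, "body")
  f2 <- hill_fit(doses * 7, y, "body")
  expect_equal(f2$ec50 / f1$ec50, 7, tolerance = 1e-4)
  expect_equal(f2$ec10 / f1$ec10, 7, tolerance = 1e-4)
})

test_that("unconstrained fits recover a nonzero bottom", {
  doses <- c(0, exp(seq(log(0.2), log(20), length.out = 11)))
  mu <- 0.3 + (1.2 - 0.3) / (1 + (ifelse(doses == 0, 0, doses) / 2)^-(-2.5))
  fit <- hill_fit(doses, mu, "af")
  expect_true(fit$converged)
  expect_equal(fit$bottom, 0.3, tolerance = 1e-4)
  expect_equal(fit$top, 1.2, tolerance = 1e-4)
})

test_that("Welch ANOVA matches its algebraic identities and oneway.test", {
  x <- withr::with_seed(2, stats::rnorm(8))
  y <- withr::with_seed(3, stats::rnorm(9, 0.5, 2))
  wa <- welch_anova(c(x, y), rep(c("a", "b"), c(8, 9)))
  tt <- stats::t.test(x, y)
  expect_equal(wa$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(wa$p_value, tt$p.value, tolerance = 1e-10)
  # independent route: stats::oneway.test
  v <- withr::with_seed(4, stats::rnorm(30, rep(c(0, 1, 3), each = 10),
                                        rep(c(1, 2, 0.5), each = 10)))
  g <- rep(c("a", "b", "c"), each = 10)
  ow <- stats::oneway.test(v ~ g)
  wa3 <- welch_anova(v, g)
  expect_equal(wa3$statistic, unname(ow$statistic), tolerance = 1e-10)
  expect_equal(wa3$df2, unname(ow$parameter[2]), tolerance = 1e-10)
  expect_equal(wa3$p_value, ow$p.value, tolerance = 1e-10)
})

test_that("Dunnett T3 SMM adjustment: closed form matches Monte Carlo", {
  vals <- withr::with_seed(6, stats::rnorm(40, rep(c(0, 0, 1.2, 2), each = 10)))
  grp <- rep(c("0", "1", "2", "4"), each = 10)
  cf <- dunnett_t3(vals, grp, control = "0")
  mc <- dunnett_t3(vals, grp, control = "0", mc = TRUE, seed = 2)
  expect_equal(cf$p_adj, mc$p_adj, tolerance = 0.02)
  expect_true(all(cf$p_adj >= 0 & cf$p_adj <= 1))
})

test_that("LOAEL flags overwhelming effects and respects monotonicity", {
  ctrl <- withr::with_seed(8, stats::rnorm(10, 100, 2))
  v1 <- withr::with_seed(9, stats::rnorm(10, 80, 2))   # 10 sigma shift
  v2 <- withr::with_seed(10, stats::rnorm(10, 60, 2))
  res <- loael(list(`0` = ctrl, `1` = v1, `2` = v2))
  expect_equal(res$loael_dose_um, 1)
  expect_identical(res$test, "welch_anova_dunnett_t3")
  expect_length(res$shapiro_p, 3L)
  # larger shifts never raise the LOAEL
  res2 <- loael(list(`0` = ctrl, `1` = v1 - 20, `2` = v2 - 20))
  expect_lte(res2$loael_dose_um, res$loael_dose_um)
  expect_error(loael(list(`0` = ctrl, `1` = v1[1:2])), "fewer than 3")
})

test_that("control CV across replicate wells follows its closed form", {
  expect_equal(unname(control_cv(data.frame(len = c(100, 100, 100)))["len"]), 0)
  expect_equal(unname(control_cv(data.frame(len = c(95, 100, 105)))[["len"]]),
               5 / 100, tolerance = 1e-12)
  expect_error(control_cv(data.frame(len = 100)), "at least 2")
})

test_that("the device-level report recovers the generating dose-response", {
  # full-decline curve so the Bottom = 0 constraint of the body fit matches
  # the generating model
  plan <- dose_plan(hill = list(top = 1100, bottom = 0, ec50 = 2,
                                slope = -2.5))
  set.seed(11)
  rows <- list()
  wells <- expand.grid(rep_well = 1:2, dose = plan$doses_um)
  for (i in seq_len(nrow(wells))) {
    mu <- hill_curve(wells$dose[i], plan$hill$top, plan$hill$bottom,
                     plan$hill$ec50, plan$hill$slope)
    lens <- stats::rnorm(12, mu, plan$biological_cv * max(mu, 1))
    rows[[i]] <- data.frame(well = sprintf("W%02d", i), dose_um = wells$dose[i],
                            length_um = lens, area_um2 = lens * 60,
                            volume_um3 = lens * 60 * 30)
  }
  phe <- do.call(rbind, rows)
  rep <- devtox_report(phe)
  expect_lt(rep$control_cv[["length_um"]], 0.08)
  fit <- rep$fits$length_um
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50 - plan$hill$ec50) / plan$hill$ec50, 0.15)
  ec10_true <- ec_anything(plan$hill$ec50, plan$hill$slope, 10)
  expect_lt(abs(fit$ec10 - ec10_true) / ec10_true, 0.25)
  expect_false(is.null(rep$loael$length_um))
})
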