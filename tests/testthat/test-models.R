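test_that("the conditional-logit fitter matches survival::clogit", {
  skip_if_not_installed("survival")
  set.seed(101)
  df <- sim_clogit_strata(120, K = 10,
                          beta = c(snow = -1, wind_support = 0.3,
                                   crosswind = -0.1))
  fit <- fit_clogit(case ~ snow + wind_support + crosswind, df)
  df$one <- 1
  ref <- survival::coxph(
    survival::Surv(one, case) ~ snow + wind_support + crosswind +
      survival::strata(stratum),
    data = df, method = "exact")
  expect_equal(coef(fit), coef(ref), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-5)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("the fitter equals a brute-force grid maximiser", {
  set.seed(55)
  df <- sim_clogit_strata(40, K = 10, beta = c(snow = -1))
  fit <- fit_clogit(case ~ snow, df)
  b_grid <- oracle_clogit_grid(df, "snow", lo = -4, hi = 2, by = 0.001)
  expect_lt(abs(coef(fit)[["snow"]] - b_grid), 1e-3)
})

test_that("stratum-constant predictors are dropped and give the null likelihood", {
  set.seed(7)
  df <- sim_clogit_strata(30, K = 5, beta = c(snow = -1))
  df$elev <- rep(rnorm(30), each = 6)   # constant within every stratum
  expect_warning(fit <- fit_clogit(case ~ elev, df), "elev")
  expect_length(coef(fit), 0)
  expect_equal(fit$logLik, -30 * log(6))   # null logLik = -sum log(K+1)
})

test_that("the conditional likelihood ignores stratum-constant offsets", {
  set.seed(8)
  df <- sim_clogit_strata(60, K = 8, beta = c(snow = -1.2))
  fit1 <- fit_clogit(case ~ snow, df)
  offs <- rnorm(length(unique(df$stratum)), 0, 10)
  df2 <- df
  df2$snow <- df$snow + offs[as.integer(factor(df$stratum))]
  fit2 <- fit_clogit(case ~ snow, df2)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-8)
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-8)
})

test_that("complete separation raises an error naming the predictor", {
  # chosen endpoint always uniquely snow-free
  df <- do.call(rbind, lapply(1:20, function(s)
    data.frame(stratum = s, individual = "a",
               case = as.integer(1:6 == 1), snow = c(0, 1, 1, 1, 1, 1))))
  expect_error(fit_clogit(case ~ snow, df), "separation.*snow")
})

test_that("cluster-robust standard errors are available by individual", {
  set.seed(9)
  df <- sim_clogit_strata(100, K = 5, beta = c(snow = -1), n_individuals = 8)
  fit <- fit_clogit(case ~ snow, df, cluster = "individual")
  expect_false(is.null(fit$robust))
  expect_gt(fit$robust$se[["snow"]], 0)
  s_rob <- summary(fit, robust = TRUE)
  expect_equal(unname(s_rob$coefficients[, "Std. Error"]),
               unname(fit$robust$se))
})

test_that("predict and simulate respect the stratum softmax", {
  set.seed(10)
  df <- sim_clogit_strata(40, K = 5, beta = c(snow = -1.5))
  fit <- fit_clogit(case ~ snow, df)
  p <- predict(fit, df)
  expect_equal(as.numeric(rowsum(p, df$stratum)), rep(1, 40))
  sim <- simulate(fit, nsim = 3, seed = 1, newdata = df)
  expect_equal(colSums(sim), rep(40, 3))   # one pick per stratum
})

test_that("Akaike machinery matches the closed form with a strict > 2 flag", {
  mk <- function(aic, n = 50) list(logLik = -aic / 2, AIC = aic, n = n)
  cmp <- compare_models(a = mk(100), b = mk(100))
  expect_equal(cmp$weight, c(0.5, 0.5))
  expect_equal(cmp$dAIC, c(0, 0))
  cmp2 <- compare_models(a = mk(100), b = mk(102))
  expect_false(any(cmp2$different))        # exactly 2 is "not different"
  cmp3 <- compare_models(a = mk(100), b = mk(102), c = mk(110))
  w <- exp(-c(0, 1, 5)); w <- w / sum(w)
  expect_equal(cmp3$weight, w)
  expect_equal(sum(cmp3$weight), 1)
  expect_equal(cmp3$different, c(FALSE, FALSE, TRUE))
  expect_error(compare_models(a = mk(100, n = 50), b = mk(100, n = 60)),
               "differing")
})

test_that("the collinearity screen flags duplicates and zero variance", {
  set.seed(11)
  d <- data.frame(a = rnorm(1e4))
  d$b <- d$a
  d$c <- rnorm(1e4)
  d$z <- 1
  scr <- screen_collinearity(d, c("a", "b", "c", "z"))
  expect_equal(scr$flagged$r, 1)
  expect_setequal(c(scr$flagged$var1, scr$flagged$var2), c("a", "b"))
  expect_lt(abs(scr$correlations["a", "c"]), 0.05)
  expect_equal(scr$zero_variance, "z")
  # matches the direct covariance/sd formula
  r_hand <- sum((d$a - mean(d$a)) * (d$c - mean(d$c))) /
    ((1e4 - 1) * sd(d$a) * sd(d$c))
  expect_equal(scr$correlations["a", "c"], r_hand, tolerance = 1e-12)
})

sim_lag_gauss <- function(n_ind = 12, slope = 0.3, sd = 1, seed = 20) {
  set.seed(seed)
  lags <- -10:10
  do.call(rbind, lapply(seq_len(n_ind), function(i) {
    u <- rnorm(1, 0, 0.5)
    data.frame(point_id = i, individual = sprintf("i%02d", i), year = 2016,
               lon = 20, lat = 60, date = as.Date("2016-04-15"), lag = lags,
               variable = "temp", value = u + slope * lags + rnorm(21, 0, sd),
               missing = FALSE)
  }))
}

test_that("the gaussian lag model recovers a known slope", {
  lt <- sim_lag_gauss(n_ind = 15, slope = 0.3)
  fit <- fit_lag_model(lt, "temp", family = "gaussian")
  expect_lt(abs(fit$slope - 0.3), 3 * fit$slope_se)
  expect_equal(fit$n, 15 * 21)
})

test_that("REML and ML give the same slope for a balanced design", {
  lt <- sim_lag_gauss(n_ind = 10)
  d <- data.frame(value = lt$value, day = lt$lag,
                  individual = factor(lt$individual))
  ml <- lme4::lmer(value ~ day + (1 | individual), d, REML = FALSE)
  reml <- lme4::lmer(value ~ day + (1 | individual), d, REML = TRUE)
  expect_lt(abs(lme4::fixef(ml)[["day"]] - lme4::fixef(reml)[["day"]]), 1e-6)
})

test_that("degenerate and single-individual lag data are handled", {
  lt <- sim_lag_gauss(n_ind = 3)
  lt$value <- 5
  expect_warning(fit <- fit_lag_model(lt, "temp", "gaussian"), "constant")
  expect_equal(fit$slope, 0)
  expect_true(fit$degenerate)
  lt2 <- sim_lag_gauss(n_ind = 1)
  expect_warning(fit2 <- fit_lag_model(lt2, "temp", "gaussian"),
                 "fewer than 2")
  expect_false(is.na(fit2$slope))
})

test_that("the binomial lag model detects melting at fixed locations", {
  # deterministic receding front: snow switches 1 -> 0 later at higher lat
  set.seed(23)
  lags <- -10:10
  lt <- do.call(rbind, lapply(1:12, function(i) {
    melt_lag <- sample(-6:6, 1)
    data.frame(point_id = i, individual = sprintf("i%02d", (i - 1) %/% 2 + 1),
               year = 2015 + i %% 2, lon = 20, lat = 60, date = as.Date("2016-04-15"),
               lag = lags, variable = "snow",
               value = as.numeric(lags < melt_lag), missing = FALSE)
  }))
  fit <- fit_lag_model(lt, "snow")
  expect_equal(fit$family, "binomial")
  expect_lt(fit$slope, 0)
})
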