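test_that("zero-intercept polynomial fit recovers exact linear data", {
  d <- data.frame(time_min = c(0, 5, 10, 20, 30), product_mM = 2 * c(0, 5, 10, 20, 30))
  fit <- fit_progress_polynomial(d, degree = 3)
  expect_equal(unname(fit$coefficients), c(2, 0, 0), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("polynomial fit matches the normal-equations oracle and improves with degree", {
  t <- c(5, 10, 20, 30, 60)
  p <- 6.5 * (1 - exp(-0.04 * t))
  d <- data.frame(time_min = t, product_mM = p)
  for (deg in 2:3) {
    fit <- fit_progress_polynomial(d, degree = deg)
    expect_equal(unname(fit$coefficients), unname(normal_eq_poly(t, p, deg)),
                 tolerance = 1e-8)
  }
  ssr <- function(deg) {
    fit <- fit_progress_polynomial(d, degree = deg)
    pred <- outer(t, seq_len(deg), `^`) %*% fit$coefficients
    sum((p - pred)^2)
  }
  expect_lt(ssr(3), ssr(2))
})

test_that("degenerate polynomial inputs are handled explicitly", {
  d0 <- data.frame(time_min = c(0, 10, 20, 30), product_mM = rep(0, 4))
  fit <- fit_progress_polynomial(d0, degree = 3)
  expect_equal(unname(fit$coefficients), c(0, 0, 0))
  expect_true(is.na(fit$r_squared))
  expect_error(
    fit_progress_polynomial(data.frame(time_min = c(0, 5, 10), product_mM = c(0, 1, 2)),
                            degree = 3),
    "at least 3 points with t > 0"
  )
  expect_error(fit_progress_polynomial(d0, degree = 1), "between 2 and 5")
})

test_that("instantaneous activity is the analytic derivative, no extrapolation", {
  d <- data.frame(time_min = c(0, 5, 10, 20, 30), product_mM = 2 * c(0, 5, 10, 20, 30))
  fit <- fit_progress_polynomial(d, degree = 3)
  expect_equal(instantaneous_activity(fit, c(0, 7, 30)), rep(2, 3),
               tolerance = 1e-9)
  expect_error(instantaneous_activity(fit, 31), "extrapolation")
  expect_error(instantaneous_activity(fit, -1), "extrapolation")
  zero <- fit_progress_polynomial(
    data.frame(time_min = c(0, 10, 20, 30), product_mM = rep(0, 4)), 3)
  expect_equal(instantaneous_activity(zero, 15), 0)
})

test_that("derivative at 0 of a polynomial fitted to A(1-exp(-bt)) approximates A*b", {
  t <- seq(0, 25, 2.5) # within ~1.5 decay half-lives of b = 0.04
  A <- 6.5; b <- 0.04
  d <- data.frame(time_min = t, product_mM = A * (1 - exp(-b * t)))
  fit <- fit_progress_polynomial(d, degree = 3)
  expect_equal(instantaneous_activity(fit, 0), A * b, tolerance = 0.05)
})

test_that("residual activity normalises to 100% and clips negatives", {
  lin <- fit_progress_polynomial(
    data.frame(time_min = c(0, 5, 10, 20, 30), product_mM = 2 * c(0, 5, 10, 20, 30)), 3)
  res <- residual_activity(lin, c(0, 10, 20, 30))
  expect_equal(res$residual_pct, rep(100, 4), tolerance = 1e-8)
  # a saturating curve fitted over a long window turns negative late
  t <- c(0, 10, 20, 30, 60)
  sat <- fit_progress_polynomial(
    data.frame(time_min = t, product_mM = 6.5 * (1 - exp(-0.08 * t))), 3)
  expect_warning(res2 <- residual_activity(sat, seq(0, 60, 5)), "clipped")
  expect_true(all(res2$residual_pct >= 0))
  zero <- fit_progress_polynomial(
    data.frame(time_min = c(0, 10, 20, 30), product_mM = rep(0, 4)), 3)
  expect_error(residual_activity(zero, c(0, 10)), "not positive")
})

test_that("residual activity is invariant to product unit rescaling", {
  t <- seq(0, 25, 5)
  p <- 6.5 * (1 - exp(-0.05 * t))
  r1 <- residual_activity(fit_progress_polynomial(
    data.frame(time_min = t, product_mM = p), 3), t)
  r2 <- residual_activity(fit_progress_polynomial(
    data.frame(time_min = t, product_mM = 1000 * p), 3), t)
  expect_equal(r1$residual_pct, r2$residual_pct, tolerance = 1e-9)
})

test_that("exponential decay fit recovers exact and degenerate series", {
  t <- c(0, 5, 10, 20, 30)
  exact <- fit_inactivation(data.frame(time_min = t,
                                       residual_pct = 100 * exp(-0.0387 * t)))
  expect_equal(exact$lambda_per_min, 0.0387, tolerance = 1e-6)
  expect_equal(exact$half_life_min, log(2) / 0.0387, tolerance = 1e-6)
  expect_equal(exact$kinact_per_s, 0.0387 / 60, tolerance = 1e-6)

  flat <- fit_inactivation(data.frame(time_min = t, residual_pct = rep(100, 5)))
  expect_equal(flat$lambda_per_min, 0)
  expect_equal(flat$half_life_min, Inf)

  expect_error(fit_inactivation(data.frame(time_min = c(0, 10),
                                           residual_pct = c(100, 50))),
               "at least 3")
  expect_error(fit_inactivation(data.frame(time_min = c(5, 10, 20),
                                           residual_pct = c(100, 80, 60))),
               "first point")
  expect_error(fit_inactivation(data.frame(time_min = c(0, 10, 20),
                                           residual_pct = c(100, 0, 0))),
               "degenerate")
})

test_that("decay fit is robust to measurement noise on residual activity", {
  lambda <- 0.0115
  t <- seq(0, 60, 5)
  truth <- 100 * exp(-lambda * t)
  est <- withr::with_seed(42, replicate(200, {
    r <- truth + c(0, rnorm(length(t) - 1, 0, 3))
    r[1] <- 100
    fit_inactivation(data.frame(time_min = t, residual_pct = pmax(r, 0)))$lambda_per_min
  }))
  expect_lt(abs(median(est) - lambda) / lambda, 0.05)
})

test_that("noiseless pipeline recovers the effective decay constant within 5%", {
  p <- wt_params(0.0011)
  cond <- wt_cond()
  lam_eff <- 0.0011 * 60 * cond$S0 / (p$Km + cond$S0) # per minute
  traj <- simulate_progress(p, cond, decay_grid(lam_eff))
  fit <- fit_stability(data.frame(time_min = traj$time_min, product_mM = traj$P_mM))
  expect_lt(abs(fit$lambda_per_min - lam_eff) / lam_eff, 0.05)
})

test_that("estimated half-life ratios track true ratios across degrees 3-5", {
  cond <- wt_cond(E0 = 0.2) # low load keeps substrate ~constant for both variants
  k1 <- 7e-4
  for (r in c(2, 3.37)) {
    k2 <- k1 / r
    for (deg in 3:5) {
      est <- vapply(c(k1, k2), function(k) {
        p <- wt_params(k)
        lam <- k * 60 * cond$S0 / (p$Km + cond$S0)
        traj <- simulate_progress(p, cond, decay_grid(lam))
        fit_stability(data.frame(time_min = traj$time_min, product_mM = traj$P_mM),
                      degree = deg)$lambda_per_min
      }, numeric(1))
      expect_lt(abs(est[1] / est[2] - r) / r, 0.03)
    }
  }
})

test_that("empirical TTN matches the model partition ratio on a plateaued curve", {
  p <- wt_params(0.0011)
  cond <- wt_cond()
  traj <- simulate_progress(p, cond, seq(0, 120, 5))
  ttn <- empirical_ttn(data.frame(time_min = traj$time_min, product_mM = traj$P_mM),
                       cond)
  expect_equal(ttn, partition_ratio(p), tolerance = 0.01)
})

test_that("empirical TTN matches direct mole division and guards its inputs", {
  # plateau 1.41 umol product in 1 mL (1.41 mM) with 1.7 nmol enzyme (1.7 uM)
  d <- data.frame(time_min = c(0, 30, 60, 90), product_mM = c(0, 1.3, 1.405, 1.41))
  expect_equal(empirical_ttn(d, wt_cond(E0 = 1.7)), 1.41 / 0.0017,
               tolerance = 1e-6)
  rising <- data.frame(time_min = c(0, 10, 20), product_mM = c(0, 1, 2))
  expect_error(empirical_ttn(rising, wt_cond()), "No plateau")
  expect_silent(empirical_ttn(rising, wt_cond(), force = TRUE))
  zero <- data.frame(time_min = c(0, 10, 20), product_mM = c(0, 0, 0))
  expect_error(empirical_ttn(zero, wt_cond()), "no product")
})
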