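test_that("sigmoid evaluation: plateaus, midpoint and the worked value", {
  cv <- fixed_calibration_curve()
  expect_equal(evaluate_sigmoid(cv, 0), cv$S_min)
  expect_equal(evaluate_sigmoid(cv, cv$EC50), (cv$S_min + cv$S_max) / 2)
  # fixed curve (-0.5, 4, 1030 pM, n=1) at X = 506 pM
  expect_equal(evaluate_sigmoid(cv, 506), -0.5 + 4.5 * 506 / 1536)
  expect_equal(evaluate_sigmoid(cv, 506), 0.9825, tolerance = 1e-4)
  # strictly increasing
  X <- seq(0, 5000, by = 50)
  expect_true(all(diff(evaluate_sigmoid(cv, X)) > 0))
  expect_error(evaluate_sigmoid(cv, -5), ">= 0")
  expect_error(calibration_curve(1, 0.5, 100), "S_max > S_min")
  expect_error(calibration_curve(0, 1, -3), "EC50")
})

test_that("scale covariance: with n = 1 the response depends on X/EC50", {
  c1 <- calibration_curve(0, 1, 100, 1)
  c2 <- calibration_curve(0, 1, 1000, 1)
  X <- c(10, 50, 200, 900)
  expect_equal(evaluate_sigmoid(c1, X), evaluate_sigmoid(c2, 10 * X))
})

test_that("sigmoid inversion is exact and flags out-of-range signals", {
  cv <- fixed_calibration_curve()
  expect_equal(as.numeric(invert_sigmoid(cv, (cv$S_min + cv$S_max) / 2)),
               cv$EC50)
  for (X in c(10, 1e3, 1e5)) {
    rt <- as.numeric(invert_sigmoid(cv, evaluate_sigmoid(cv, X)))
    expect_equal(rt, X, tolerance = 1e-9)
  }
  expect_equal(as.numeric(invert_sigmoid(cv, 0.9825)), 506, tolerance = 1e-3)
  lo <- invert_sigmoid(cv, cv$S_min - 0.1)
  expect_equal(as.numeric(lo), 0)
  expect_equal(attr(lo, "flag"), "below_range")
  hi <- invert_sigmoid(cv, cv$S_max + 0.1)
  expect_equal(as.numeric(hi), Inf)
  expect_equal(attr(hi, "flag"), "above_range")
  # non-unit slope round trip
  c2 <- calibration_curve(-0.2, 3, 400, 1.7)
  expect_equal(as.numeric(invert_sigmoid(c2, evaluate_sigmoid(c2, 123))), 123,
               tolerance = 1e-9)
})

test_that("normalization maps anchors to 0/1 and interpolates in time", {
  a <- normalization_anchors(c(0, 60), c(10, 8), c(20, 16),
                             zero_conc_pM = 125, unity_conc_pM = 506)
  expect_equal(normalize_signals(0, 10, a), 0)
  expect_equal(normalize_signals(60, 16, a), 1)
  # hand interpolation at t = 30: anchors (9, 18), A = 13 -> 4/9
  expect_equal(normalize_signals(30, 13, a), 4 / 9, tolerance = 1e-12)
  # constant extrapolation outside the anchored range
  expect_equal(normalize_signals(-30, 10, a), 0)
  expect_equal(normalize_signals(120, 8, a), 0)
  expect_error(normalization_anchors(c(0, 60), c(10, 8), c(20, 7)),
               "degenerate")
  expect_error(normalization_anchors(c(60, 0), c(1, 1), c(2, 2)),
               "increasing")
})

test_that("anchor self-normalization is exact-affine at machine precision", {
  set.seed(31)
  t <- sort(stats::runif(6, 0, 600))
  lo <- stats::runif(6, 5, 10)
  hi <- lo + stats::runif(6, 3, 8)
  a <- normalization_anchors(t, lo, hi)
  expect_equal(normalize_signals(t, lo, a), rep(0, 6), tolerance = 1e-12)
  expect_equal(normalize_signals(t, hi, a), rep(1, 6), tolerance = 1e-12)
})

test_that("fit recovers a noiseless curve to high accuracy", {
  cv <- calibration_curve(-0.3, 3.5, 800, 1.3)
  X <- rep(c(0, 31.3, 62.5, 125, 250, 500, 1000, 2000, 4000), each = 2)
  S <- evaluate_sigmoid(cv, X)
  fit <- fit_calibration(X, S)
  expect_equal(fit$S_min, cv$S_min, tolerance = 1e-6)
  expect_equal(fit$S_max, cv$S_max, tolerance = 1e-6)
  expect_equal(fit$EC50, cv$EC50, tolerance = 1e-6)
  expect_equal(fit$n, cv$n, tolerance = 1e-6)
  expect_true(attr(fit, "fit")$convergence)
})

test_that("fit input validation", {
  expect_error(fit_calibration(c(0, 10, 100), c(0, 0.5, 1)), ">= 4")
  expect_error(fit_calibration(rep(c(1, 10, 100, 1000), 2), rep(0.7, 8)),
               "identical")
  # fixed n needs only 3 distinct concentrations
  cv <- calibration_curve(0, 1, 50, 1)
  X <- rep(c(5, 50, 500), each = 3)
  fit <- fit_calibration(X, evaluate_sigmoid(cv, X), fix_n = 1)
  expect_equal(fit$EC50, 50, tolerance = 1e-5)
  expect_equal(fit$n, 1)
})

test_that("EC50 parameter recovery: median error < 10% over replicates", {
  cv <- fixed_calibration_curve()
  concs <- c(0, 31.3, 62.5, 125, 250, 500, 1000, 2000, 4000)
  X <- rep(concs, each = 8)
  mu <- evaluate_sigmoid(cv, X)
  set.seed(32)
  err <- replicate(200, {
    fit <- fit_calibration(X, mu + stats::rnorm(length(X), 0, 0.05))
    abs(fit$EC50 - cv$EC50) / cv$EC50
  })
  expect_lt(stats::median(err), 0.10)
})

test_that("strategies coincide on noiseless drift-free data", {
  p <- kinetic_params()
  sched <- preset_schedule("figure5_blind", drift_rate = 0)
  iv <- schedule_intervals(sched)
  # noiseless activity: exact stationary rates (no Poisson draw)
  act <- data.frame(t_min = iv$t_min, injection_index = iv$injection_index,
                    role = iv$role, true_conc_pM = iv$conc_pM,
                    counts = NA, n_particles = 4000,
                    activity = stationary_stats(p, iv$conc_pM)$utb_rate * 60)
  # the stationary activity is exactly a slope-1 4PL in concentration
  # (a Moebius function of C); derive the generating curve on the
  # normalized scale analytically
  a_lo <- stationary_stats(p, 125)$utb_rate * 60
  a_hi <- stationary_stats(p, 506)$utb_rate * 60
  a_0 <- stationary_stats(p, 0)$utb_rate * 60
  a_inf <- (p$lambda_bg + p$lambda_max) * p$k_off_sw /
    (p$lambda_bg + p$lambda_max + p$k_off_sw) * 60
  ec50_eff <- p$EC50_kin * (p$k_off_sw + p$lambda_bg) /
    (p$k_off_sw + p$lambda_bg + p$lambda_max)
  gen_curve <- calibration_curve(
    S_min = (a_0 - a_lo) / (a_hi - a_lo),
    S_max = (a_inf - a_lo) / (a_hi - a_lo),
    EC50 = ec50_eff, n = 1)
  # sanity: the derived curve reproduces the noiseless normalized signal
  S_chk <- normalize_signals(iv$t_min, act$activity,
                             extract_anchors(act))
  expect_equal(S_chk, evaluate_sigmoid(gen_curve, iv$conc_pM),
               tolerance = 1e-9)
  r1 <- apply_strategy(act, 1)
  r2 <- apply_strategy(act, 2)
  r3 <- apply_strategy(act, 3, fixed_curve = gen_curve)
  m1 <- vapply(r1$estimates, function(e) e$mean, numeric(1))
  m2 <- vapply(r2$estimates, function(e) e$mean, numeric(1))
  m3 <- vapply(r3$estimates, function(e) e$mean, numeric(1))
  tr <- vapply(r1$estimates, function(e) e$true_conc_pM, numeric(1))
  expect_equal(m1, m2, tolerance = 1e-6)
  expect_equal(m1, m3, tolerance = 1e-6)
  expect_equal(unname(m3), unname(tr), tolerance = 1e-6)
})

test_that("strategy 3 cancels common multiplicative drift exactly", {
  p <- kinetic_params()
  sched <- preset_schedule("figure5_blind", drift_rate = 0)
  iv <- schedule_intervals(sched)
  base <- stationary_stats(p, iv$conc_pM)$utb_rate * 60
  mk <- function(a) data.frame(t_min = iv$t_min,
                               injection_index = iv$injection_index,
                               role = iv$role, true_conc_pM = iv$conc_pM,
                               counts = NA, n_particles = 4000, activity = a)
  m1 <- vapply(apply_strategy(mk(base), 3)$estimates,
               function(e) e$mean, numeric(1))
  # a drift factor linear in time is reproduced exactly by the
  # piecewise-linear anchor interpolation: cancellation is exact
  f_lin <- 1 - 0.0005 * iv$t_min
  m_lin <- vapply(apply_strategy(mk(base * f_lin), 3)$estimates,
                  function(e) e$mean, numeric(1))
  expect_equal(m1, m_lin, tolerance = 1e-9)
  # geometric decay (8%/h) is cancelled up to the linear-interpolation
  # error between anchor repeats (~2 h apart): sub-percent signal error
  m_geo <- vapply(apply_strategy(mk(base * drift_factor(iv$t_min, 0.08)),
                                 3)$estimates,
                  function(e) e$mean, numeric(1))
  expect_equal(m1, m_geo, tolerance = 2e-2)
})

test_that("strategy errors are informative", {
  p <- kinetic_params()
  sched <- sample_schedule(c(125, 506, 300), c("norm_reference",
                                               "norm_reference", "blind"),
                           n_intervals = 4, drift_rate = 0)
  e <- generate_experiment(sched, p, 4000, "counts", seed = 33)
  expect_error(apply_strategy(e, 1), "calibrant")
  expect_error(apply_strategy(e, 3, fixed_curve = NULL), "fixed")
  expect_error(apply_strategy(e, 5), "strategy")
  r3 <- apply_strategy(e, 3)
  expect_length(r3$estimates, 1)
  expect_s3_class(r3$estimates[[1]], "concentration_estimate")
})
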