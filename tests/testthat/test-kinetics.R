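test_that("kinetic_params validates its invariants", {
  expect_s3_class(kinetic_params(), "kinetic_params")
  expect_error(kinetic_params(R_bound = 0.3, R_free = 0.28), "R_bound")
  expect_error(kinetic_params(D_bound = 0.5, D_free = 0.3), "D_bound")
  expect_error(kinetic_params(k_off_sw = -1), ">= 0")
  expect_error(kinetic_params(EC50_kin = 0), "EC50_kin")
})

test_that("lambda_on saturates with concentration", {
  p <- kinetic_params(lambda_bg = 0)
  expect_equal(lambda_on(p, 0), 0)
  expect_equal(lambda_on(p, p$EC50_kin), p$lambda_max / 2)
  expect_lt(lambda_on(p, 1e9), p$lambda_max * 1.001)
  expect_error(lambda_on(p, -1), ">= 0")
})

test_that("zero binding rate yields a single unbound interval", {
  p <- kinetic_params(lambda_bg = 0)
  s <- simulate_state_sequence(p, 0, 500, seed = 1)
  expect_equal(nrow(s), 1L)
  expect_equal(s$state, "unbound")
  expect_equal(c(s$t_start, s$t_end), c(0, 500))
})

test_that("bound dwells are Exp(k_off): mean and KS distribution", {
  p <- kinetic_params(k_off_sw = 0.1, lambda_max = 0.05, lambda_bg = 0,
                      EC50_kin = 1000)
  s <- simulate_state_sequence(p, 4000, 6e5, seed = 2)
  bd <- s$t_end[s$state == "bound"] - s$t_start[s$state == "bound"]
  bd <- head(bd, -1)  # last interval may be truncated by the horizon
  expect_gt(length(bd), 1e4)
  se <- 10 / sqrt(length(bd))          # SD of Exp(0.1) is 10
  expect_lt(abs(mean(bd) - 10), 3 * se)
  ks <- suppressWarnings(stats::ks.test(bd, "pexp", rate = 0.1))
  expect_gt(ks$p.value, 0.01)
  ud <- s$t_end[s$state == "unbound"] - s$t_start[s$state == "unbound"]
  ud <- head(ud, -1)
  lon <- lambda_on(p, 4000)
  ks2 <- suppressWarnings(stats::ks.test(ud, "pexp", rate = lon))
  expect_gt(ks2$p.value, 0.01)
})

test_that("long-run UTB rate and bound fraction match the analytic forms", {
  p <- kinetic_params(lambda_max = 0.05, EC50_kin = 1000, lambda_bg = 0,
                      k_off_sw = 0.1)
  C <- 1000; dur <- 1e5
  s <- simulate_state_sequence(p, C, dur, seed = 3)
  st <- stationary_stats(p, C)
  lon <- lambda_on(p, C)
  expect_equal(st$utb_rate, lon * p$k_off_sw / (lon + p$k_off_sw))
  n_ev <- length(utb_times(s))
  # events are ~Poisson(rate * dur): 3 SE band
  expect_lt(abs(n_ev - st$utb_rate * dur), 3 * sqrt(st$utb_rate * dur))
  bf <- sum(s$t_end[s$state == "bound"] - s$t_start[s$state == "bound"]) / dur
  # bound-fraction SE from the number of switching cycles
  expect_lt(abs(bf - st$p_bound), 3 * st$p_bound / sqrt(n_ev))
})

test_that("state sequences are contiguous, alternating and reproducible", {
  p <- kinetic_params()
  s1 <- simulate_state_sequence(p, 250, 2000, seed = 7)
  s2 <- simulate_state_sequence(p, 250, 2000, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(abs(s1$t_start[-1] - s1$t_end[-nrow(s1)]) < 1e-12))
  expect_true(all(s1$state[-1] != s1$state[-nrow(s1)]))
  expect_error(simulate_state_sequence(p, -1, 100), "concentration")
  expect_error(simulate_state_sequence(p, 100, 0), "duration")
})

test_that("bound trajectories respect the confinement radius", {
  p <- kinetic_params(sigma_loc = 0)
  s <- make_sequence("bound", 100)
  tr <- render_trajectory(s, p, seed = 4)
  expect_true(all(sqrt(tr$x_um^2 + tr$y_um^2) <= p$R_bound + 1e-12))
})

test_that("unconfined free diffusion reproduces MSD = 4 D dt", {
  p <- kinetic_params(sigma_loc = 0, R_free = 1e3, D_free = 0.3)
  s <- make_sequence("unbound", 4000)   # 1.2e5 steps at 30 Hz
  tr <- render_trajectory(s, p, seed = 5)
  sq <- diff(tr$x_um)^2 + diff(tr$y_um)^2
  D_hat <- mean(sq) / (4 / p$frame_rate)
  se <- stats::sd(sq / (4 / p$frame_rate)) / sqrt(length(sq))
  expect_lt(abs(D_hat - 0.3), 3 * se)
})

test_that("immobile particle with localization noise: var = 2 sigma^2", {
  p <- kinetic_params(D_free = 0, D_bound = 0, sigma_loc = 0.02)
  s <- make_sequence("bound", 2000)
  tr <- render_trajectory(s, p, seed = 6)
  v <- stats::var(diff(tr$x_um))
  se <- sqrt(2 / length(tr$x_um)) * 2 * p$sigma_loc^2  # var of a variance
  expect_lt(abs(v - 2 * p$sigma_loc^2), 4 * se)
  expect_error(render_trajectory(s[0, ], p), "at least one interval")
})

test_that("counts mode: blanks are silent and dispersion is Poisson", {
  p <- kinetic_params(lambda_bg = 0)
  blanks <- sample_schedule(rep(0, 3), "blank", n_intervals = 5,
                            drift_rate = 0)
  e <- generate_experiment(blanks, p, 1000, "counts", seed = 8)
  expect_true(all(e$activity$counts == 0))

  fixedC <- sample_schedule(500, "calibrant", n_intervals = 100,
                            drift_rate = 0)
  e2 <- generate_experiment(fixedC, kinetic_params(), 1000, "counts",
                            seed = 9)
  counts <- e2$activity$counts
  disp <- stats::var(counts) / mean(counts)
  # dispersion index null band: (n-1)*disp ~ chisq(n-1)
  n <- length(counts)
  band <- stats::qchisq(c(0.025, 0.975), n - 1) / (n - 1)
  expect_gt(disp, band[1])
  expect_lt(disp, band[2])
})

test_that("drift law: counts at 9 h are scaled by 0.95^9", {
  p <- kinetic_params()
  expect_equal(drift_factor(9 * 60, 0.05), 0.95^9)
  expect_equal(0.95^9, 0.6302, tolerance = 1e-4)
  # two injections far apart, huge particle number to beat Poisson noise
  sched <- sample_schedule(c(1000, 1000), "calibrant", n_intervals = 1,
                           flow_min = 0, gap_min = c(538, 0),
                           drift_rate = 0.05)
  iv <- schedule_intervals(sched)
  expect_equal(iv$t_min, c(0.5, 539.5))
  e <- generate_experiment(sched, p, 2e6, "counts", seed = 10)
  ratio <- e$activity$counts[2] / e$activity$counts[1]
  expect_equal(ratio, drift_factor(539, 0.05) / drift_factor(0, 0.05),
               tolerance = 0.01)
  expect_error(generate_experiment(sched, p, 0), "n_particles")
})

test_that("trajectories mode carries a consistent ground-truth event log", {
  p <- kinetic_params()
  e <- generate_experiment(tiny_schedule(), p, 25, "trajectories", seed = 11)
  expect_equal(sum(e$activity$counts), nrow(e$events))
  expect_equal(length(e$trajectories), 2 * 25)
  # reproducibility of the full output
  e2 <- generate_experiment(tiny_schedule(), p, 25, "trajectories", seed = 11)
  expect_identical(e$activity, e2$activity)
  expect_identical(e$events, e2$events)
})

test_that("counts and trajectories modes agree on mean activity (10%)", {
  p <- kinetic_params()
  sched <- tiny_schedule(conc = c(500, 500, 500), n_intervals = 4)
  et <- generate_experiment(sched, p, 80, "trajectories", seed = 12)
  analytic <- stationary_stats(p, 500)$utb_rate * 60
  expect_equal(mean(et$activity$activity), analytic, tolerance = 0.1)
  ec <- generate_experiment(sched, p, 4000, "counts", seed = 13)
  expect_equal(mean(et$activity$activity), mean(ec$activity$activity),
               tolerance = 0.1)
})

test_that("preset schedules satisfy their contracts", {
  s3 <- preset_schedule("figure3_series")
  expect_equal(sum(s3$role == "blank"), 5)
  concs <- unique(s3$conc_pM[s3$role == "calibrant"])
  expect_equal(sort(concs), c(31.3, 62.5, 125, 250, 500, 1000))
  expect_true(all(diff(s3$conc_pM[1:7]) > 0))      # ascending within a series
  expect_equal(nrow(s3), 35)
  total_h <- max(schedule_intervals(s3)$t_min) / 60
  expect_gt(total_h, 8); expect_lt(total_h, 10)    # ~9 h
  expect_true(all(s3$n_intervals == 10))
  expect_true(all(s3$flow_min == 1))

  s4 <- preset_schedule("figure4_milk")
  expect_true(all(c(125, 506) %in% s4$conc_pM[s4$role == "norm_reference"]))
  expect_true(all(s4$n_intervals == 8))
  expect_true(all(s4$flow_min == 3.5))

  s5 <- preset_schedule("figure5_blind")
  expect_true(any(s5$role == "blind"))
  expect_true(any(s5$role == "calibrant"))
  expect_equal(length(unique(s5$conc_pM[s5$role == "calibrant"])), 5)
  for (s in list(s3, s4, s5)) {
    expect_s3_class(s, "sample_schedule")
    expect_true(all(s$conc_pM >= 0))
    expect_true(all(s$n_intervals >= 1))
  }
  expect_error(preset_schedule("nope"))
})
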