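test_that("mean size curve honors initial and absorbing conditions", {
  d8 <- drift_params_from_composite(0.3, 8)
  expect_equal(mean_size_curve("orthodox", d8, 0, n_sim = 500, seed = 61),
               1 / 8)
  expect_equal(mean_size_curve("orthodox", d8, 100, n_sim = 500, seed = 62),
               1) # survivors are monoclonal in the long run
  # segment-capped asymptote: frozen barriers at {0, 4}
  bp0 <- barrier_params(birth_rate = 0, death_rate = 0)
  m <- mean_size_curve("pnd", d8, 50, n_sim = 2000, seed = 63,
                       barriers = bp0, init_barriers = c(0, 4))
  expect_equal(m, 0.5, tolerance = 1e-9)
  expect_warning(mean_size_curve("orthodox", d8, 1, n_sim = 50, seed = 64),
                 "noisy")
})

test_that("orthodox fit recovers the generative composite rate", {
  times <- c(0.25, 0.5, 1, 2, 3, 6, 9, 12)
  ests <- vapply(1:20, function(s) {
    tr <- simulate_orthodox(drift_params_from_composite(0.05, 8), times,
                            2000, seed = 100 + s)
    suppressWarnings(
      fit_orthodox(curve_from_trajectories(tr, times), n_sim = 2000,
                   seed = 200 + s)$estimates$lambda_over_n2)
  }, numeric(1))
  expect_true(all(ests >= 0.035 & ests <= 0.065))
  expect_lt(abs(mean(ests) - 0.05), 0.25 * 0.05) # unbiased within 25%
})

test_that("orthodox fit warns on degenerate observations and grid edges", {
  flat <- data.frame(time_months = c(1, 3), mean_size = c(0.4, 0.4))
  expect_warning(fit_orthodox(flat, n_sim = 300, seed = 65), "flat")
  expect_error(fit_orthodox(data.frame(time_months = 1, mean_size = 0.2)),
               "at least 2")
})

test_that("barrier ratio is recovered from count histograms", {
  # self-consistency: histogram exactly Poisson(2.5)
  counts <- rep(0:9, round(stats::dpois(0:9, 2.5) * 1e5))
  expect_equal(tune_barriers(counts)$beta_over_mu, 2.5, tolerance = 0.02)
  # concentrated near zero -> ratio near zero
  expect_lt(tune_barriers(c(rep(0L, 99), 1L))$beta_over_mu, 0.05)
  expect_error(tune_barriers(rep(0L, 50)), "zero")
  expect_error(tune_barriers(integer(0)), "empty")
  # recovery from simulated stationary censuses at the default rates
  ratios <- vapply(1:20, function(s) {
    sb <- stationary_barrier_distribution(default_barriers(), 8, 1000,
                                          burn_in = 20, seed = 300 + s)
    tune_barriers(sb$counts)$beta_over_mu
  }, numeric(1))
  expect_true(all(ratios >= 2.2 & ratios <= 2.8))
})

test_that("joint PND fit recovers (lambda/N2, mu) from two-arm data", {
  d <- pnd_drift(); bp <- default_barriers()
  times <- c(0.5, 3, 6, 12)
  hits <- vapply(1:20, function(s) {
    ctl <- simulate_pnd(d, bp, perturbation_arm("control"), times, 600,
                        seed = 400 + s)
    dmp <- simulate_pnd(d, bp, perturbation_arm("dmp777"), times, 600,
                        seed = 500 + s)
    f <- suppressWarnings(
      fit_pnd(curve_from_trajectories(ctl, times),
              curve_from_trajectories(dmp, times),
              beta_over_mu = 2.5, n_sim = 400, seed = 600 + s))
    (f$estimates$lambda_over_n2 >= 0.2 && f$estimates$lambda_over_n2 <= 0.45 &&
       f$estimates$mu >= 0.2 && f$estimates$mu <= 0.8)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("PND fit guards: under-determined input and missing DMP arm", {
  cp <- data.frame(time_months = c(1, 3, 6), mean_size = c(0.4, 0.6, 0.8))
  expect_error(fit_pnd(cp[1:2, ], NULL), "determined")
  expect_warning(
    fit_pnd(cp, NULL, beta_over_mu = 2.5, n_sim = 150, seed = 66,
            rate_grid = c(0.15, 0.3, 0.6), mu_grid = c(0.2, 0.4, 0.8)),
    "weakly identified")
})

test_that("model discrimination: PND fits PND data better than orthodox", {
  d <- pnd_drift(); bp <- default_barriers()
  times <- c(0.5, 3, 6, 12)
  ctl <- simulate_pnd(d, bp, perturbation_arm("control"), times, 1500,
                      seed = 67)
  dmp <- simulate_pnd(d, bp, perturbation_arm("dmp777"), times, 1500,
                      seed = 68)
  cp <- curve_from_trajectories(ctl, times)
  dp <- curve_from_trajectories(dmp, times)
  fp <- fit_pnd(cp, dp, beta_over_mu = 2.5, n_sim = 400, seed = 69)
  # best orthodox fit to the pooled two-arm points (no arm structure)
  fo <- suppressWarnings(
    fit_orthodox(rbind(cp, dp), n_sim = 2000, seed = 69))
  expect_lt(fp$objective, fo$objective)
})

test_that("parametric bootstrap intervals behave like intervals", {
  times <- c(0.25, 0.5, 1, 2, 3, 6, 9, 12)
  truth <- 0.05
  tr <- simulate_orthodox(drift_params_from_composite(truth, 8), times,
                          600, seed = 701)
  obs <- curve_from_trajectories(tr, times)
  f <- suppressWarnings(fit_orthodox(obs, n_sim = 1500, seed = 801))
  f <- bootstrap_ci(f, obs, n_boot = 60, boot_n_sim = 400, seed = 901)
  ci <- f$ci95$lambda_over_n2
  expect_true(ci[1] <= f$estimates$lambda_over_n2 &&
                ci[2] >= f$estimates$lambda_over_n2)
  expect_gt(ci[2], ci[1])

  # a much larger cohort shrinks the interval
  tr_big <- simulate_orthodox(drift_params_from_composite(truth, 8), times,
                              8000, seed = 750)
  obs_big <- curve_from_trajectories(tr_big, times)
  f_big <- suppressWarnings(fit_orthodox(obs_big, n_sim = 1500, seed = 850))
  f_big <- bootstrap_ci(f_big, obs_big, n_boot = 60, boot_n_sim = 400,
                        seed = 950)
  expect_lt(f_big$ci95$lambda_over_n2[2] - f_big$ci95$lambda_over_n2[1],
            ci[2] - ci[1])
  expect_warning(bootstrap_ci(f_big, obs_big, n_boot = 4, boot_n_sim = 200,
                              seed = 951), "unstable")
})

test_that("fits are bit-reproducible under a fixed master seed", {
  times <- c(0.5, 3, 6)
  tr <- simulate_orthodox(drift_params_from_composite(0.1, 8), times, 800,
                          seed = 70)
  obs <- curve_from_trajectories(tr, times)
  f1 <- fit_orthodox(obs, n_sim = 800, seed = 71)
  f2 <- fit_orthodox(obs, n_sim = 800, seed = 71)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$objective, f2$objective)
})
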