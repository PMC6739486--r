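test_that("barrier placement maximizes the minimum circular distance", {
  set.seed(21)
  expect_equal(place_barrier(8, 0), 4) # unique antipodal edge
  picks <- replicate(400, place_barrier(8, c(0, 4)))
  expect_setequal(unique(picks), c(2, 6)) # symmetric ties
  expect_equal(mean(picks == 2), 0.5, tolerance = 0.1)
  uni <- replicate(800, place_barrier(8))
  expect_setequal(unique(uni), 0:7) # uniform fallback, all edges reachable
  expect_gt(stats::chisq.test(table(uni))$p.value, 0.001)
  expect_error(place_barrier(4, 0:3), "occupied")
})

test_that("PND reduces to orthodox drift when barrier rates vanish", {
  d <- drift_params(19.2, 8)
  bp <- barrier_params(birth_rate = 0, death_rate = 0)
  po <- simulate_orthodox(d, 1, 3000, seed = 22)
  pp <- simulate_pnd(d, bp, perturbation_arm("control"), 1, 3000, seed = 23)
  ks <- ks_two_sample(po$labeled_fraction, pp$labeled_fraction)
  expect_gt(ks$p_value, 0.01)
  expect_true(all(pp$barrier_count == 0))
})

test_that("frozen barriers cap the clone at its segment, fixation 1/4", {
  d <- drift_params(19.2, 8)
  bp <- barrier_params(birth_rate = 0, death_rate = 0)
  n_rep <- 4000
  # barriers on edges 0 and 4 split the ring into two 4-site segments;
  # a uniformly placed labeled cell fixes its segment with probability
  # mean over segment positions = 1/4, and can never cross the barriers
  tr <- simulate_pnd(d, bp, perturbation_arm("control"), 6, n_rep,
                     seed = 24, init_barriers = c(0, 4))
  expect_true(all(tr$labeled_fraction <= 0.5))
  got <- mean(tr$labeled_fraction == 0.5)
  expect_lt(abs(got - 0.25), 3.5 * sqrt(0.25 * 0.75 / n_rep))
  # position-resolved cross-check against the exact 4-site chain oracle:
  # a cell adjacent to a barrier fixes its segment with probability 1/6
  oracle_end <- exact_small_markov(drift_params(1, 4), 0,
                                   topology = "chain")$fixation_prob
  tr_end <- simulate_pnd(d, bp, perturbation_arm("control"), 6, n_rep,
                         seed = 124, labeled_site = 1,
                         init_barriers = c(0, 4))
  got_end <- mean(tr_end$labeled_fraction == 0.5)
  expect_lt(abs(got_end - oracle_end),
            3.5 * sqrt(oracle_end * (1 - oracle_end) / n_rep))
})

test_that("martingale conservation holds under punctuated drift", {
  n_rep <- 4000
  tr <- simulate_pnd(pnd_drift(), default_barriers(),
                     perturbation_arm("control"), c(1, 6), n_rep, seed = 25)
  for (tt in c(1, 6)) {
    x <- tr$labeled_fraction[tr$time_months == tt]
    expect_lt(abs(mean(x) - 1 / 8), 3 * stats::sd(x) / sqrt(n_rep))
  }
})

test_that("stationary barrier census is Poisson(beta/mu)", {
  bp <- default_barriers() # beta 1.0, mu 0.4
  sb <- stationary_barrier_distribution(bp, 8, 3000, burn_in = 20, seed = 26)
  expect_equal(mean(sb$counts), 2.5, tolerance = 0.1)
  # chi-square goodness of fit against Poisson(2.5), tail lumped
  kmax <- 6
  obs <- tabulate(pmin(sb$counts, kmax) + 1L, nbins = kmax + 1L)
  p <- stats::dpois(0:kmax, 2.5)
  p[kmax + 1] <- p[kmax + 1] + stats::ppois(kmax, 2.5, lower.tail = FALSE)
  gof <- stats::chisq.test(obs, p = p)
  expect_gt(gof$p.value, 0.01)
  expect_error(
    stationary_barrier_distribution(barrier_params(death_rate = 0)),
    "stationary")
})

test_that("maximal spacing shifts minimum angular distances toward 180", {
  bp <- default_barriers()
  sb <- stationary_barrier_distribution(bp, 8, 3000, burn_in = 20, seed = 27)
  # uniform-placement null: two distinct edges chosen uniformly at random
  set.seed(28)
  null_d <- replicate(3000, {
    e <- sample(0:7, 2)
    min_angular_distance((e + 0.5) * 45)
  })
  expect_gt(mean(sb$min_distance_deg), mean(null_d))
  expect_lt(stats::t.test(sb$min_distance_deg, null_d,
                          alternative = "greater")$p.value, 0.01)
})

test_that("DMP-777 arm stochastically dominates control in clone size", {
  d <- pnd_drift(); bp <- default_barriers()
  times <- c(0.5, 1, 3)
  ctl <- simulate_pnd(d, bp, perturbation_arm("control"), times, 3000,
                      seed = 29)
  dmp <- simulate_pnd(d, bp, perturbation_arm("dmp777"), times, 3000,
                      seed = 30)
  for (tt in times) {
    sc <- surviving_stats(ctl, tt)$sizes
    sd_ <- surviving_stats(dmp, tt)$sizes
    expect_gt(mean(sd_), mean(sc))
    # ECDF of the DMP sizes lies at or below control (dominance, with a
    # small Monte-Carlo allowance)
    q <- (1:7) / 8
    expect_true(all(stats::ecdf(sd_)(q) <= stats::ecdf(sc)(q) + 0.05))
  }
})

test_that("perturbation discrimination separates lambda from barrier lifespan", {
  d <- pnd_drift(); bp <- default_barriers(); vp <- vertical_params()
  t_pre <- 1 # pre-saturation readout
  whole <- perturbation_arm("lambda_scale", scale = 2, onset = 0,
                            duration = t_pre)
  ctl_a <- surviving_stats(
    simulate_pnd(d, bp, perturbation_arm("control"), t_pre, 4000, seed = 31),
    t_pre)
  lam_a <- surviving_stats(
    simulate_pnd(d, bp, whole, t_pre, 4000, seed = 32), t_pre)
  mu_a <- surviving_stats(
    simulate_pnd(d, bp, perturbation_arm("lifespan_scale", scale = 2),
                 t_pre, 4000, seed = 33), t_pre)
  # doubling lambda leaves lateral expansion nearly unchanged (barrier-gated)
  expect_lt(abs(lam_a$mean_size - ctl_a$mean_size), 0.04)
  # halving barrier lifespan (mu x2) accelerates lateral expansion
  expect_gt(mu_a$mean_size, ctl_a$mean_size + 0.04)

  ctl_v <- simulate_vertical(d, vp, perturbation_arm("control"), t_pre,
                             4000, seed = 34)
  lam_v <- simulate_vertical(d, vp, whole, t_pre, 4000, seed = 34)
  # vertical expansion is division-driven: lambda x2 is strictly faster ...
  expect_gt(mean(lam_v$rel_length), mean(ctl_v$rel_length) + 0.02)
  # ... while barrier perturbations do not enter the vertical model at all:
  # same seed, identical trajectories
  mu_v <- simulate_vertical(d, vp, perturbation_arm("lifespan_scale",
                                                    scale = 2),
                            t_pre, 4000, seed = 34)
  expect_identical(mu_v$rel_length, ctl_v$rel_length)
})

test_that("C++ core agrees with an independent pure-R Gillespie reference", {
  d <- pnd_drift()
  set.seed(35)
  ref <- ref_pnd_final(8, d$lambda_rate, 1.0, 0.4, t_end = 2, n_rep = 400)
  cpp <- simulate_pnd(d, default_barriers(), perturbation_arm("control"),
                      2, 4000, seed = 36)$labeled_fraction
  rs <- ref[ref > 0]; cs <- cpp[cpp > 0]
  se <- sqrt(stats::var(rs) / length(rs) + stats::var(cs) / length(cs))
  expect_lt(abs(mean(rs) - mean(cs)), 3.5 * se)
  pf_r <- mean(rs == 1); pf_c <- mean(cs == 1)
  se_pf <- sqrt(pf_r * (1 - pf_r) / length(rs) +
                  pf_c * (1 - pf_c) / length(cs))
  expect_lt(abs(pf_r - pf_c), 3.5 * se_pf)
})

test_that("PND trajectories are reproducible and barrier snapshots align", {
  d <- pnd_drift(); bp <- default_barriers()
  a <- simulate_pnd(d, bp, perturbation_arm("control"), c(1, 3), 300,
                    seed = 37, record_edges = TRUE)
  b <- simulate_pnd(d, bp, perturbation_arm("control"), c(1, 3), 300,
                    seed = 37, record_edges = TRUE)
  expect_identical(a, b)
  snaps <- attr(a, "barrier_edges")
  expect_length(snaps, 2)
  expect_identical(unname(rowSums(snaps[[1]])),
                   as.numeric(a$barrier_count[a$time_months == 1]))
})
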