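test_that("3-point angular scoring follows the clockwise image convention", {
  expect_equal(angular_fraction(c(1, 0), c(0, 0), c(-1, 0)), 0.5)
  expect_equal(angular_fraction(c(0, 1), c(0, 0), c(1, 0)), 0.25)
  expect_equal(angular_fraction(c(1, 0), c(0, 0), c(0, 1)), 0.75)
  expect_error(angular_fraction(c(0, 0), c(0, 0), c(1, 0)), "is_full")
  expect_error(angular_fraction(c(1, 0), c(0, 0), c(1, 0)), "coincident")
})

test_that("angular fraction: complementarity and similarity invariance", {
  set.seed(41)
  for (i in 1:50) {
    p2 <- stats::rnorm(2)
    a1 <- stats::runif(1, 0, 2 * pi); a3 <- stats::runif(1, 0, 2 * pi)
    r1 <- stats::runif(1, 0.1, 5); r3 <- stats::runif(1, 0.1, 5)
    p1 <- p2 + r1 * c(cos(a1), sin(a1))
    p3 <- p2 + r3 * c(cos(a3), sin(a3))
    f <- angular_fraction(p1, p2, p3)
    expect_equal(f + angular_fraction(p3, p2, p1), 1, tolerance = 1e-9)
    # rotate and scale all points about p2: fraction unchanged
    th <- stats::runif(1, 0, 2 * pi); sc <- stats::runif(1, 0.2, 3)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tf <- function(p) as.numeric(p2 + sc * R %*% (p - p2))
    expect_equal(angular_fraction(tf(p1), p2, tf(p3)), f, tolerance = 1e-9)
  }
})

test_that("isthmus summary reduces section fractions", {
  expect_equal(isthmus_summary(c(0.2, 0.3, 0.4)), 0.3)
  expect_equal(isthmus_summary(0.5), 0.5)
  expect_equal(isthmus_summary(c(1, 1, 1)), 1)
  expect_equal(isthmus_summary(c(0.2, NA, 0.6)), 0.4)
  expect_equal(isthmus_summary(c(0.2, 0.3, 0.4), method = "max"), 0.4)
  expect_error(isthmus_summary(c(NA_real_, NA_real_)), "no isthmus")
})

test_that("full/partial classification is boundary-inclusive", {
  expect_equal(classify_gland(c(0.96, 0.5, 0.95)),
               c("full", "partial", "full"))
  expect_equal(classify_gland(1, full_threshold = 1), "full")
  expect_error(classify_gland(1.2), "0, 1")
})

test_that("vertical metrics map clone spans to gland-relative units", {
  expect_equal(vertical_metrics(0, 10, 0, 10),
               c(rel_length = 1, rel_midpoint = 0.5))
  expect_equal(vertical_metrics(0, 5, 0, 10),
               c(rel_length = 0.5, rel_midpoint = 0.25))
  # orientation-independent: axis may increase in either direction
  expect_equal(vertical_metrics(10, 5, 10, 0),
               c(rel_length = 0.5, rel_midpoint = 0.25))
  expect_error(vertical_metrics(3, 3, 0, 10), "zero-length")
  expect_error(vertical_metrics(0, 0, 0, 0), "zero extent")
  expect_error(vertical_metrics(-1, 5, 0, 10), "outside")
})

test_that("cohort summary multiplies size by survival frequency", {
  obs <- data.frame(time_months = rep(1, 5),
                    angular_fraction = c(0.6, 0.6, 0.6, 0.6, 0.6))
  tot <- data.frame(time_months = 1, n_glands = 10)
  s <- cohort_summary(obs, tot)
  expect_equal(s$mean_size_surviving, 0.6)
  expect_equal(s$survival_frequency, 0.5)
  expect_equal(s$labeled_fraction, 0.3)

  # all clones lost at a time point
  s2 <- cohort_summary(obs, data.frame(time_months = c(1, 3),
                                       n_glands = c(10, 8)))
  expect_equal(s2$survival_frequency[2], 0)
  expect_equal(s2$labeled_fraction[2], 0)
  expect_true(is.na(s2$mean_size_surviving[2]))

  # single surviving monoclonal gland of 10
  s3 <- cohort_summary(data.frame(time_months = 2, angular_fraction = 1),
                       data.frame(time_months = 2, n_glands = 10))
  expect_equal(unlist(s3[c("mean_size_surviving", "survival_frequency",
                           "labeled_fraction", "pct_full")]),
               c(mean_size_surviving = 1, survival_frequency = 0.1,
                 labeled_fraction = 0.1, pct_full = 100))
  expect_error(cohort_summary(obs, data.frame(time_months = 1,
                                              n_glands = 0)), "zero total")
})

test_that("cohort summary agrees with direct trajectory-table statistics", {
  tr <- simulate_pnd(pnd_drift(), default_barriers(),
                     perturbation_arm("control"), c(1, 3), 500, seed = 42)
  obs <- tr[tr$surviving, c("time_months", "labeled_fraction")]
  names(obs)[2] <- "angular_fraction"
  tot <- data.frame(time_months = c(1, 3), n_glands = c(500, 500))
  s <- cohort_summary(obs, tot, full_threshold = 1)
  for (i in 1:2) {
    st <- surviving_stats(tr, s$time_months[i])
    expect_equal(s$mean_size_surviving[i], st$mean_size)
    expect_equal(s$survival_frequency[i], st$survival)
    expect_equal(s$pct_full[i], st$pct_full)
    expect_equal(s$labeled_fraction[i],
                 mean(tr$labeled_fraction[tr$time_months ==
                                            s$time_months[i]]))
  }
})

test_that("minimum angular distance is circular and symmetry-invariant", {
  expect_equal(min_angular_distance(c(0, 180)), 180)
  expect_equal(min_angular_distance(c(0, 120, 240)), 120)
  expect_equal(min_angular_distance(c(0, 90, 300)), 60)
  expect_error(min_angular_distance(45), "two angles")
  set.seed(43)
  for (i in 1:25) {
    a <- stats::runif(sample(2:5, 1), 0, 360)
    d0 <- min_angular_distance(a)
    rot <- stats::runif(1, 0, 360)
    expect_equal(min_angular_distance((a + rot) %% 360), d0,
                 tolerance = 1e-9)
    expect_equal(min_angular_distance((360 - a) %% 360), d0,
                 tolerance = 1e-9)
  }
})

test_that("two-sample KS statistic and p-value behave correctly", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:3, 4:6)$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 2.5))$statistic, 0.5)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")

  # brute-force double-loop ECDF comparison + stats::ks.test cross-check
  set.seed(44)
  for (i in 1:20) {
    x <- stats::rnorm(sample(10:40, 1))
    y <- stats::rnorm(sample(10:40, 1), mean = stats::runif(1, 0, 1))
    got <- ks_two_sample(x, y)
    brute <- max(vapply(c(x, y), function(p)
      abs(mean(x <= p) - mean(y <= p)), numeric(1)))
    expect_equal(got$statistic, brute, tolerance = 1e-12)
    ref <- suppressWarnings(stats::ks.test(x, y))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    # asymptotic p agrees with the exact p to coarse tolerance at these n
    expect_lt(abs(got$p_value - ref$p.value), 0.12)
  }
})

test_that("raw annotation tables are scored through the full pipeline", {
  raw <- data.frame(gland_id = 1:2, time_months = 3, arm = "control",
                    compartment = "upper", is_full = c(FALSE, TRUE))
  for (s in 1:3) {
    # gland 1: quarter-circle clone in every section; gland 2 full
    raw[[paste0("p1x_s", s)]] <- c(0, NA); raw[[paste0("p1y_s", s)]] <- c(1, NA)
    raw[[paste0("p2x_s", s)]] <- c(0, NA); raw[[paste0("p2y_s", s)]] <- c(0, NA)
    raw[[paste0("p3x_s", s)]] <- c(1, NA); raw[[paste0("p3y_s", s)]] <- c(0, NA)
  }
  raw$clone_top <- c(2, 0); raw$clone_bottom <- c(6, 10)
  raw$gland_top <- 0; raw$gland_bottom <- 10
  sc <- score_observations(raw)
  expect_equal(sc$angular_fraction, c(0.25, 1))
  expect_equal(sc$classification, c("partial", "full"))
  expect_equal(sc$rel_length, c(0.4, 1))
  expect_equal(sc$rel_midpoint, c(0.4, 0.5))
})
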