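#' Monte-Carlo mean surviving clone size curve
#'
#' Mean angular clone size among surviving glands at each requested time,
#' estimated from \code{n_sim} simulated glands. The seed is fixed per call,
#' so repeated evaluations at different parameters share common random
#' numbers, which damps the Monte-Carlo roughness of least-squares
#' objectives built on this curve. For the one-parameter orthodox model,
#' \code{\link{fit_orthodox}} exploits the exact time-rescaling property
#' instead of re-simulating per candidate rate.
#'
#' @param model "orthodox" or "pnd".
#' @param drift A \code{\link{drift_params}} object.
#' @param times Record times, months.
#' @param n_sim Simulated glands per evaluation (values below 100 trigger a
#'   noisy-objective warning).
#' @param seed Integer seed (common random numbers).
#' @param barriers,arm For \code{model = "pnd"}: \code{\link{barrier_params}}
#'   and \code{\link{perturbation_arm}}.
#' @param init_barriers Optional fixed initial barrier edges (pnd).
#' @return Numeric vector: mean surviving labeled fraction at each time
#'   (NaN where no gland survived).
#' @export
mean_size_curve <- function(model = c("orthodox", "pnd"), drift, times,
                            n_sim = 1000, seed = 1, barriers = NULL,
                            arm = perturbation_arm("control"),
                            init_barriers = NULL) {
  model <- match.arg(model)
  if (n_sim < 100)
    warning("n_sim < 100: Monte-Carlo objective will be noisy")
  tr <- if (model == "orthodox") {
    simulate_orthodox(drift, times, n_sim, seed = seed)
  } else {
    simulate_pnd(drift, barriers, arm, times, n_sim, seed = seed,
                 init_barriers = init_barriers)
  }
  vapply(times, function(tt) {
    x <- tr$labeled_fraction[tr$time_months == tt]
    mean(x[x > 0])
  }, numeric(1))
}

new_fit_result <- function(model, estimates, ci95, objective, n_sim, seed,
                           grid, converged = TRUE) {
  structure(list(model = model, estimates = estimates, ci95 = ci95,
                 objective = objective, n_sim = n_sim, seed = seed,
                 grid = grid, converged = converged),
            class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf("<drift_fit> model = %s, RSS = %.5g%s\n", x$model, x$objective,
              if (!x$converged) " (grid edge hit: not converged)" else ""))
  for (nm in names(x$estimates)) {
    ci <- x$ci95[[nm]]
    cat(sprintf("  %s = %.4g%s\n", nm, x$estimates[[nm]],
                if (!is.null(ci) && !any(is.na(ci)))
                  sprintf("  [95%% CI %.4g, %.4g]", ci[1], ci[2]) else ""))
  }
  invisible(x)
}

#' Least-squares fit of the orthodox neutral-drift model
#'
#' Grid search over the composite rate lambda/N^2 followed by derivative-free
#' refinement, minimizing the residual sum of squares between observed mean
#' clone sizes and the model's mean surviving-size curve. Because all rates
#' of the orthodox model are proportional to lambda, changing the rate is an
#' exact rescaling of time: the objective is evaluated against a single
#' simulated unit-rate reference curve (common random numbers across every
#' candidate), making it a deterministic, smooth function of the rate.
#'
#' @param observed Data frame with columns \code{time_months} and
#'   \code{mean_size} (at least 2 rows).
#' @param n_sites Stem-cell number N of the fitted ring.
#' @param grid Candidate lambda/N^2 values (/month); default a log-spaced
#'   grid over [0.003, 1].
#' @param n_sim Simulated glands behind the reference curve.
#' @param seed Integer master seed.
#' @return A \code{drift_fit} with estimate \code{lambda_over_n2}.
#' @export
fit_orthodox <- function(observed, n_sites = 8L,
                         grid = exp(seq(log(0.003), log(1), length.out = 16)),
                         n_sim = 2000, seed = 1) {
  if (nrow(observed) < 2) stop("need at least 2 observation points")
  if (stats::sd(observed$mean_size) == 0)
    warning("constant observations: objective is nearly flat")
  times <- observed$time_months
  # unit-composite-rate reference curve on a dense rescaled-time grid
  smin <- max(min(grid) * min(times[times > 0]), 1e-4)
  smax <- max(grid) * max(times)
  sgrid <- exp(seq(log(smin), log(smax), length.out = 300))
  ref <- mean_size_curve("orthodox", drift_params_from_composite(1, n_sites),
                         sgrid, n_sim = n_sim, seed = seed)
  curve_at <- function(s) { # s = rate * t, clamped to the reference grid
    out <- stats::approx(log(sgrid), ref, xout = log(pmax(s, smin)),
                         rule = 2)$y
    out[s <= 0] <- 1 / n_sites
    out
  }
  obj <- function(rate) sum((curve_at(rate * times) - observed$mean_size)^2)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  o <- stats::optimize(obj, lower = lo, upper = hi)
  est <- o$minimum
  converged <- !(i == 1 || i == length(grid))
  if (!converged)
    warning("best value at grid edge: fit flagged non-converged")
  new_fit_result("orthodox",
                 estimates = list(lambda_over_n2 = est),
                 ci95 = list(lambda_over_n2 = c(NA_real_, NA_real_)),
                 objective = o$objective, n_sim = n_sim, seed = seed,
                 grid = grid, converged = converged)
}

#' Constrain the barrier birth/death ratio from parietal-cell counts
#'
#' The stationary barrier count is Poisson(beta/mu) (immigration-death
#' process; the maximal-spacing placement rule shapes positions, not
#' counts). The ratio is estimated by minimizing the chi-square distance
#' between the observed per-gland count histogram and the Poisson law.
#' Counts alone cannot identify the absolute timescale: both the count law
#' and the placement law are invariant under rescaling time, so only
#' beta/mu is returned.
#'
#' @param counts Integer vector of per-gland parietal-cell (barrier) counts.
#' @param interval Search interval for beta/mu.
#' @return List with \code{beta_over_mu} and the attained \code{objective}.
#' @export
tune_barriers <- function(counts, interval = c(0.01, 10)) {
  if (!length(counts)) stop("empty count histogram")
  if (all(counts == 0)) stop("all counts zero: ratio tends to 0, not identifiable")
  kmax <- max(counts)
  obs <- tabulate(counts + 1L, nbins = kmax + 2L) / length(counts)
  chisq <- function(r) {
    p <- stats::dpois(0:kmax, r)
    p <- c(p, max(1 - sum(p), 1e-12)) # lumped tail bin
    sum((obs - p)^2 / pmax(p, 1e-12))
  }
  o <- stats::optimize(chisq, interval = interval)
  list(beta_over_mu = o$minimum, objective = o$objective)
}

#' Joint least-squares fit of the punctuated neutral drift model
#'
#' Fits (lambda/N^2, mu) jointly to control-arm and DMP-777-arm mean clone
#' size time courses, with the barrier birth/death ratio beta/mu fixed in
#' advance from parietal-cell count data (\code{\link{tune_barriers}}) -- a
#' two-stage design mirroring how the barrier census and the clone time
#' courses constrain different parts of the model. The control arm is
#' simulated from stationary initial barriers; the DMP arm starts
#' barrier-free with the recovery window active. Grid search over a 2-D
#' (lambda/N^2, mu) grid with one local log-scale refinement pass around the
#' best cell; common random numbers across evaluations.
#'
#' @param control_points,dmp_points Data frames with \code{time_months} and
#'   \code{mean_size}; \code{dmp_points} may be NULL (mu is then weakly
#'   identified and the fit warns).
#' @param beta_over_mu Fixed barrier count ratio.
#' @param n_sites Stem-cell number N.
#' @param rate_grid,mu_grid Candidate lambda/N^2 and mu values.
#' @param n_sim Simulated glands per arm per evaluation.
#' @param seed Integer master seed.
#' @param recovery_birth_rate,recovery_window DMP-777 recovery settings.
#' @param n_boot,boot_n_sim Bootstrap replicates and per-refit simulation
#'   size for the confidence intervals; \code{n_boot = 0} skips the CI.
#' @return A \code{drift_fit} with estimates \code{lambda_over_n2},
#'   \code{mu}, and \code{beta_over_mu}.
#' @export
fit_pnd <- function(control_points, dmp_points = NULL, beta_over_mu = 2.5,
                    n_sites = 8L,
                    rate_grid = exp(seq(log(0.05), log(1.2), length.out = 7)),
                    mu_grid = exp(seq(log(0.1), log(1.6), length.out = 7)),
                    n_sim = 500, seed = 1,
                    recovery_birth_rate = 5.0, recovery_window = 0.5,
                    n_boot = 0, boot_n_sim = 300) {
  pts <- rbind(
    if (!is.null(control_points))
      cbind(control_points[c("time_months", "mean_size")], arm = "control"),
    if (!is.null(dmp_points))
      cbind(dmp_points[c("time_months", "mean_size")], arm = "dmp777"))
  if (nrow(pts) < 3) stop("under-determined: need at least 3 data points")
  if (is.null(dmp_points))
    warning("no DMP-777 points: mu is weakly identified by the control arm")

  obj <- function(rate, mu) {
    drift <- drift_params_from_composite(rate, n_sites)
    bp <- barrier_params(birth_rate = beta_over_mu * mu, death_rate = mu,
                         recovery_birth_rate = recovery_birth_rate,
                         recovery_window = recovery_window)
    rss <- 0
    for (a in unique(pts$arm)) {
      sub <- pts[pts$arm == a, ]
      mu_hat <- mean_size_curve("pnd", drift, sub$time_months, n_sim = n_sim,
                                seed = seed, barriers = bp,
                                arm = perturbation_arm(a))
      rss <- rss + sum((mu_hat - sub$mean_size)^2)
    }
    rss
  }
  search <- function(rg, mg) {
    vals <- outer(rg, mg, Vectorize(obj))
    ij <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    list(rate = rg[ij[1]], mu = mg[ij[2]], rss = min(vals),
         edge = ij[1] %in% c(1, length(rg)) || ij[2] %in% c(1, length(mg)))
  }
  s1 <- search(rate_grid, mu_grid)
  refine <- function(center, grid) {
    step <- if (length(grid) > 1) mean(diff(log(grid))) else 0.3
    exp(log(center) + seq(-step, step, length.out = 5))
  }
  s2 <- search(refine(s1$rate, rate_grid), refine(s1$mu, mu_grid))
  if (s1$edge)
    warning("best value at grid edge: fit flagged non-converged")
  ci <- list(lambda_over_n2 = c(NA_real_, NA_real_),
             mu = c(NA_real_, NA_real_))
  fit <- new_fit_result("pnd",
                        estimates = list(lambda_over_n2 = s2$rate, mu = s2$mu,
                                         beta_over_mu = beta_over_mu),
                        ci95 = ci, objective = s2$rss, n_sim = n_sim,
                        seed = seed,
                        grid = list(rate = rate_grid, mu = mu_grid),
                        converged = !s1$edge)
  if (n_boot > 0) {
    fit <- bootstrap_ci(fit, control_points = control_points,
                        dmp_points = dmp_points, n_sites = n_sites,
                        n_boot = n_boot, boot_n_sim = boot_n_sim,
                        seed = seed + 1L)
  }
  fit
}

#' Parametric bootstrap confidence intervals for a model fit
#'
#' Regenerates observation-sized cohorts at the point estimate, refits each
#' pseudo-dataset, and takes the 2.5/97.5 percentiles of the refitted
#' parameters. Matches the simulation-based estimator without asymptotics.
#'
#' @param fit A \code{drift_fit} from \code{\link{fit_orthodox}} or
#'   \code{\link{fit_pnd}}.
#' @param control_points,dmp_points The fitted data, with an
#'   \code{n_clones} column giving the surviving-clone count behind each
#'   mean (defaults to 50 when absent).
#' @param n_sites Stem-cell number N.
#' @param n_boot Bootstrap replicates (values below 50 trigger a warning).
#' @param boot_n_sim Simulation size per refit evaluation.
#' @param seed Integer seed.
#' @return The fit with its \code{ci95} slot filled, plus a
#'   \code{bootstrap} element holding the resampled estimates.
#' @export
bootstrap_ci <- function(fit, control_points, dmp_points = NULL,
                         n_sites = 8L, n_boot = 200, boot_n_sim = 300,
                         seed = 1) {
  stopifnot(inherits(fit, "drift_fit"))
  if (n_boot < 50)
    warning("n_boot < 50: bootstrap percentiles will be unstable")
  nclones <- function(df) {
    if (is.null(df)) return(NULL)
    if (!"n_clones" %in% names(df)) df$n_clones <- 50L
    df
  }
  control_points <- nclones(control_points)
  dmp_points <- nclones(dmp_points)
  est <- fit$estimates
  drift <- drift_params_from_composite(est$lambda_over_n2, n_sites)

  sample_means <- function(points, arm_name, sim_seed) {
    if (is.null(points)) return(NULL)
    out <- points
    for (i in seq_len(nrow(points))) {
      tt <- points$time_months[i]
      sizes <- if (fit$model == "orthodox") {
        tr <- simulate_orthodox(drift, tt, 4 * points$n_clones[i],
                                seed = sim_seed + i)
        tr$labeled_fraction[tr$surviving]
      } else {
        bp <- barrier_params(birth_rate = est$beta_over_mu * est$mu,
                             death_rate = est$mu)
        tr <- simulate_pnd(drift, bp, perturbation_arm(arm_name), tt,
                           4 * points$n_clones[i], seed = sim_seed + i)
        tr$labeled_fraction[tr$surviving]
      }
      n_take <- min(points$n_clones[i], length(sizes))
      if (n_take == 0) { out$mean_size[i] <- NA; next }
      out$mean_size[i] <- mean(sizes[seq_len(n_take)])
    }
    out[!is.na(out$mean_size), , drop = FALSE]
  }

  set.seed(as.integer(seed))
  sub_seeds <- sample.int(2^30, n_boot)
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    cp <- sample_means(control_points, "control", sub_seeds[b])
    dp <- sample_means(dmp_points, "dmp777", sub_seeds[b] + 10000L)
    refit <- suppressWarnings(
      if (fit$model == "orthodox") {
        fit_orthodox(cp, n_sites = n_sites, n_sim = boot_n_sim,
                     seed = sub_seeds[b])
      } else {
        fit_pnd(cp, dp, beta_over_mu = est$beta_over_mu, n_sites = n_sites,
                rate_grid = exp(seq(log(est$lambda_over_n2 / 4),
                                    log(est$lambda_over_n2 * 4),
                                    length.out = 5)),
                mu_grid = exp(seq(log(est$mu / 4), log(est$mu * 4),
                                  length.out = 5)),
                n_sim = boot_n_sim, seed = sub_seeds[b])
      })
    boots[[b]] <- unlist(refit$estimates)
  }
  bmat <- do.call(rbind, boots)
  for (nm in names(fit$estimates)) {
    if (nm == "beta_over_mu") next
    qs <- stats::quantile(bmat[, nm], c(0.025, 0.975), names = FALSE)
    # percentile interval widened to contain the point estimate by definition
    fit$ci95[[nm]] <- c(min(qs[1], fit$estimates[[nm]]),
                        max(qs[2], fit$estimates[[nm]]))
  }
  fit$bootstrap <- bmat
  fit
}
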