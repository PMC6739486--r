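#' Default configuration for the end-to-end reproduction pipeline
#'
#' Collects every tunable of the analysis in one list: model parameters at
#' their fitted/constrained values (composite drift rate 0.3/month on an
#' N = 8 ring; barrier birth 1.0 and death 0.4 per month), the perturbation
#' arms, cohort sizes, and simulation sizes. Any element can be overridden
#' via \code{modifyList}-style arguments.
#'
#' @param ... Named overrides of the default entries.
#' @return A named list (class \code{reproduce_config}).
#' @export
reproduce_config <- function(...) {
  cfg <- list(
    n_sites = 8L,
    lambda_over_n2 = 0.3,       # /month, PND composite drift rate
    barrier_birth = 1.0,        # /month/gland
    barrier_death = 0.4,        # /month/barrier
    recovery_birth = 5.0,       # /month during post-ablation recovery
    recovery_window = 0.5,      # months
    muc6_scale = 2, muc6_onset = 0.25, muc6_duration = 0.75,
    clone_times = c(0.5, 3, 6, 12),
    n_glands = 1000L,           # glands per arm for clone-size curves
    n_glands_barriers = 1000L,  # glands for the stationary barrier census
    barrier_burn_in = 20,       # months
    n_muc6_vertical = c(27L, 34L),  # control / DT clones, vertical scoring
    n_muc6_angular = c(98L, 88L),   # control / DT clones, angular scoring
    fit_n_sim = 2000L,          # glands behind the orthodox cross-fit curve
    seed = 1L)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config entries: ",
                          paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  class(cfg) <- "reproduce_config"
  cfg
}

#' Run the full analysis pipeline and assemble a results report
#'
#' Wires the stages together: stationary barrier census, two-arm punctuated
#' drift simulation (control and DMP-777), monoclonal-conversion and mean
#' angular-size readouts, the orthodox cross-fit of the control-arm curve,
#' and the Muc6-DTR injury-response comparison (two-sample KS on vertical
#' versus angular clone size at one month). Fully deterministic given the
#' config seed.
#'
#' @param config A \code{\link{reproduce_config}}.
#' @param out_path Optional path for a JSON copy of the report (requires the
#'   jsonlite package).
#' @return A nested list report; all quantities are computed at run time.
#' @export
run_reproduce <- function(config = reproduce_config(), out_path = NULL) {
  stopifnot(inherits(config, "reproduce_config"))
  seed <- as.integer(config$seed)
  drift <- drift_params_from_composite(config$lambda_over_n2, config$n_sites)
  bp <- barrier_params(config$barrier_birth, config$barrier_death,
                       config$recovery_birth, config$recovery_window)

  # stage 1: stationary barrier census (constrains beta/mu)
  census <- stationary_barrier_distribution(bp, config$n_sites,
                                            config$n_glands_barriers,
                                            config$barrier_burn_in,
                                            seed = seed)
  tuned <- tune_barriers(census$counts)

  # stage 2: two-arm clone simulations
  arms <- list(control = perturbation_arm("control"),
               dmp777 = perturbation_arm("dmp777"))
  arm_stats <- lapply(seq_along(arms), function(i) {
    tr <- simulate_pnd(drift, bp, arms[[i]], config$clone_times,
                       config$n_glands, seed = seed + i)
    per_time <- lapply(config$clone_times, function(tt) {
      x <- tr$labeled_fraction[tr$time_months == tt]
      surv <- x[x > 0]
      list(time_months = tt,
           mean_size = mean(surv),
           survival = length(surv) / length(x),
           pct_full = 100 * mean(surv == 1))
    })
    names(per_time) <- paste0("m", config$clone_times)
    per_time
  })
  names(arm_stats) <- names(arms)

  # stage 3: orthodox cross-fit of the control-arm mean-size curve
  ctrl_curve <- data.frame(
    time_months = config$clone_times,
    mean_size = vapply(arm_stats$control, `[[`, numeric(1), "mean_size"))
  cross_fit <- fit_orthodox(ctrl_curve, n_sites = config$n_sites,
                            n_sim = config$fit_n_sim, seed = seed)

  # stage 4: PND fit on the two simulated arm curves (self-consistency)
  dmp_curve <- data.frame(
    time_months = config$clone_times,
    mean_size = vapply(arm_stats$dmp777, `[[`, numeric(1), "mean_size"))
  pnd_fit <- fit_pnd(ctrl_curve, dmp_curve, beta_over_mu = tuned$beta_over_mu,
                     n_sites = config$n_sites, n_sim = 400, seed = seed)

  # stage 5: Muc6-DTR injury response at one month, paper-scale cohorts
  vertical <- vertical_params()
  muc6 <- perturbation_arm("muc6_dtr", scale = config$muc6_scale,
                           onset = config$muc6_onset,
                           duration = config$muc6_duration)
  v_ctrl <- simulate_vertical(drift, vertical, perturbation_arm("control"),
                              1, config$n_muc6_vertical[1], seed = seed + 11)
  v_dt <- simulate_vertical(drift, vertical, muc6, 1,
                            config$n_muc6_vertical[2], seed = seed + 12)
  ks_vert <- ks_two_sample(v_ctrl$rel_length, v_dt$rel_length)
  ang <- function(a, n, s) {
    tr <- simulate_pnd(drift, bp, a, 1, n * config$n_sites, seed = s)
    x <- tr$labeled_fraction[tr$surviving]
    x[seq_len(min(n, length(x)))]
  }
  a_ctrl <- ang(perturbation_arm("control"), config$n_muc6_angular[1],
                seed + 13)
  a_dt <- ang(muc6, config$n_muc6_angular[2], seed + 14)
  ks_ang <- ks_two_sample(a_ctrl, a_dt)

  report <- list(
    version = "punctdrift-report/1",
    seed = seed,
    parameters = list(lambda_over_n2 = config$lambda_over_n2,
                      n_sites = config$n_sites,
                      barrier_birth = config$barrier_birth,
                      barrier_death = config$barrier_death),
    barrier_census = list(
      mean_count = mean(census$counts),
      histogram = as.list(table(census$counts)),
      beta_over_mu_tuned = tuned$beta_over_mu,
      mean_min_angular_distance_deg = mean(census$min_distance_deg)),
    clone_dynamics = arm_stats,
    orthodox_cross_fit = list(
      lambda_over_n2 = cross_fit$estimates$lambda_over_n2,
      objective = cross_fit$objective),
    pnd_fit = list(estimates = pnd_fit$estimates,
                   ci95 = pnd_fit$ci95,
                   objective = pnd_fit$objective),
    muc6_dtr = list(
      ks_vertical = ks_vert,
      ks_angular = ks_ang,
      mean_rel_length = c(control = mean(v_ctrl$rel_length),
                          dt = mean(v_dt$rel_length)),
      mean_angular = c(control = mean(a_ctrl), dt = mean(a_dt))))

  if (!is.null(out_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("writing the report requires the jsonlite package")
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}
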