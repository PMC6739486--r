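#' Synthetic cohort design
#'
#' Describes a clonal-density lineage-tracing experiment: cross-sectional
#' cohorts of independent glands sacrificed at each time point, scored for
#' multicolor clones. Default gland counts at 0.5, 3, 6 and 12 months match
#' the published angular-size dataset (40, 132, 103, 90 clones); 100 glands
#' are used at the 1- and 18-month points, where no count is printed.
#'
#' @param time_points Months post-induction.
#' @param glands_per_timepoint Labeled-clone target counts per time point.
#'   Internally the generator simulates enough glands that the expected
#'   number of surviving (scoreable) clones matches these counts.
#' @param angle_noise_sd Measurement jitter on annotation-point bearings,
#'   degrees.
#' @param color_probs Label probabilities of the four reporter colors.
#' @param base_clone_fraction Fraction of scored clones that are
#'   base-compartment clones (static geometry cluster).
#' @param upper_mean,upper_sd Long-term relative-length cluster of
#'   isthmus-spanning upper clones (0.80 +/- 0.20 at 18 months).
#' @param base_mean,base_sd Base-clone cluster (0.30 +/- 0.10).
#' @return An object of class \code{synthetic_design}.
#' @export
synthetic_design <- function(time_points = c(0.5, 1, 3, 6, 12, 18),
                             glands_per_timepoint = c(40, 100, 132, 103, 90,
                                                      100),
                             angle_noise_sd = 5,
                             color_probs = rep(0.25, 4),
                             base_clone_fraction = 0.3,
                             upper_mean = 0.80, upper_sd = 0.20,
                             base_mean = 0.30, base_sd = 0.10) {
  if (length(time_points) != length(glands_per_timepoint))
    stop("one gland count per time point required")
  if (any(glands_per_timepoint < 0) || angle_noise_sd < 0)
    stop("counts and noise sd must be >= 0")
  if (length(color_probs) != 4)
    stop("color_probs must have length 4 (the four reporter colors)")
  if (abs(sum(color_probs) - 1) > 1e-8 || any(color_probs < 0))
    stop("color_probs must be non-negative and sum to 1")
  structure(list(time_points = time_points,
                 glands_per_timepoint = as.integer(glands_per_timepoint),
                 angle_noise_sd = angle_noise_sd,
                 color_probs = color_probs,
                 base_clone_fraction = base_clone_fraction,
                 upper_mean = upper_mean, upper_sd = upper_sd,
                 base_mean = base_mean, base_sd = base_sd),
            class = "synthetic_design")
}

CONFETTI_COLORS <- c("green", "yellow", "red", "cyan")

# three annotation points for a labeled arc: P2 at the gland center, P1/P3
# on the clockwise start/end bearings of the arc, with Gaussian jitter on
# the boundary bearings (image-coordinate convention: y grows downward)
arc_to_points <- function(start_deg, span_deg, noise_sd) {
  n1 <- stats::rnorm(1, 0, noise_sd)
  n2 <- stats::rnorm(1, 0, noise_sd)
  # jittered span clipped away from 0 and 360 so fractions stay in (0, 1)
  eff <- min(max(span_deg + n1 + n2, 0.5), 359.5)
  b1 <- start_deg + n1
  b3 <- b1 - eff # clockwise end
  to_xy <- function(deg) {
    th <- deg * pi / 180
    c(cos(th), sin(th))
  }
  list(p1 = to_xy(b1), p2 = c(0, 0), p3 = to_xy(b3))
}

#' Generate a synthetic clone-annotation cohort
#'
#' Simulates cross-sectional gland cohorts under the punctuated (or
#' orthodox) drift model, converts each surviving clone's labeled arc into
#' 3-point annotations in three isthmus optical sections (with Gaussian
#' bearing jitter), assigns one of four reporter colors, attaches vertical
#' length/midpoint from the vertical-expansion model, and emits the raw
#' annotation schema consumed by \code{\link{score_observations}}. Glands
#' whose clone was lost by the sampling time are not scored (they enter the
#' survival denominator through \code{n_glands_simulated}).
#'
#' @param design A \code{\link{synthetic_design}}.
#' @param drift,barriers,arm Model parameters and perturbation arm.
#' @param vertical A \code{\link{vertical_params}}.
#' @param model "pnd" or "orthodox".
#' @param seed Integer seed; identical inputs give identical tables.
#' @return A list with \code{observations} (raw annotation data frame, one
#'   row per surviving clone) and \code{totals} (data frame
#'   \code{time_months}, \code{n_glands} of glands simulated per time
#'   point, the survival denominator).
#' @export
generate_clone_cohort <- function(design, drift, barriers,
                                  arm = perturbation_arm("control"),
                                  vertical = vertical_params(),
                                  model = c("pnd", "orthodox"),
                                  seed = 1) {
  stopifnot(inherits(design, "synthetic_design"))
  model <- match.arg(model)
  set.seed(as.integer(seed))
  n <- drift$n_sites
  rows <- list()
  totals <- data.frame(time_months = design$time_points,
                       n_glands = 0L)
  gid <- 0L
  for (k in seq_along(design$time_points)) {
    tt <- design$time_points[k]
    target <- design$glands_per_timepoint[k]
    if (target == 0) next
    # simulate enough glands that surviving clones exceed the target with
    # high probability (survival is at least the fixation floor 1/N)
    n_sim <- max(target * n * 2L, 40L)
    sub_seed <- sample.int(2^30, 1)
    tr <- if (model == "pnd") {
      simulate_pnd(drift, barriers, arm, tt, n_sim, seed = sub_seed)
    } else {
      simulate_orthodox(drift, tt, n_sim, seed = sub_seed)
    }
    surv <- which(tr$surviving)
    if (length(surv) > target) surv <- surv[seq_len(target)]
    totals$n_glands[k] <- if (length(surv))
      max(surv) else n_sim # glands examined to reach the scored clones
    vert <- simulate_vertical(drift, vertical, arm, tt,
                              max(length(surv), 1), seed = sub_seed + 1L)
    for (m in seq_along(surv)) {
      gid <- gid + 1L
      frac <- tr$labeled_fraction[surv[m]]
      full <- frac >= 1
      start <- stats::runif(1, 0, 360)
      row <- list(gland_id = gid, time_months = tt, arm = arm$arm,
                  compartment = "upper",
                  color = sample(CONFETTI_COLORS, 1,
                                 prob = design$color_probs),
                  is_full = full, true_fraction = frac)
      for (s in 1:3) {
        if (full) {
          pts <- list(p1 = c(NA, NA), p2 = c(NA, NA), p3 = c(NA, NA))
        } else {
          pts <- arc_to_points(start, frac * 360, design$angle_noise_sd)
        }
        row[[paste0("p1x_s", s)]] <- pts$p1[1]
        row[[paste0("p1y_s", s)]] <- pts$p1[2]
        row[[paste0("p2x_s", s)]] <- pts$p2[1]
        row[[paste0("p2y_s", s)]] <- pts$p2[2]
        row[[paste0("p3x_s", s)]] <- pts$p3[1]
        row[[paste0("p3y_s", s)]] <- pts$p3[2]
      }
      vm <- vert[vert$replicate_id == m, , drop = FALSE][1, ]
      row$gland_top <- 0; row$gland_bottom <- 1
      row$clone_top <- vm$rel_midpoint - vm$rel_length / 2
      row$clone_bottom <- vm$rel_midpoint + vm$rel_length / 2
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  obs <- if (length(rows)) do.call(rbind, rows) else empty_cohort_schema()
  list(observations = obs, totals = totals)
}

empty_cohort_schema <- function() {
  cols <- c("gland_id", "time_months", "arm", "compartment", "color",
            "is_full", "true_fraction",
            as.vector(outer(as.vector(outer(c("p1", "p2", "p3"), c("x", "y"),
                                            paste0)),
                            paste0("_s", 1:3), paste0)),
            "gland_top", "gland_bottom", "clone_top", "clone_bottom")
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  df
}

#' Generate synthetic parietal-cell cross-section observations
#'
#' Samples stationary barrier configurations and reports, per gland, the
#' parietal-cell count and the angular positions of the occupied edges
#' (edge midpoints plus bearing jitter).
#'
#' @param barriers A \code{\link{barrier_params}} with death rate > 0.
#' @param n_sites Edges per ring.
#' @param n_glands Glands to sample (default 175, the published per-section
#'   count sample size).
#' @param angle_noise_sd Jitter on angular positions, degrees.
#' @param burn_in Months simulated before sampling.
#' @param seed Integer seed.
#' @return Data frame with one row per gland: \code{gland_id}, \code{count},
#'   and a list-column \code{angles} (degrees in [0, 360)).
#' @export
generate_pc_observations <- function(barriers, n_sites = 8L,
                                     n_glands = 175L, angle_noise_sd = 5,
                                     burn_in = 20, seed = 1) {
  sb <- stationary_barrier_distribution(barriers, n_sites, n_glands,
                                        burn_in, seed = seed)
  angles <- lapply(seq_len(n_glands), function(g) {
    e <- which(sb$edges[g, ]) - 1L
    if (!length(e)) return(numeric(0))
    a <- ((e + 0.5) * 360 / n_sites +
            stats::rnorm(length(e), 0, angle_noise_sd)) %% 360
    if (anyDuplicated(a)) a <- (a + seq_along(a) * 1e-6) %% 360
    sort(a)
  })
  out <- data.frame(gland_id = seq_len(n_glands),
                    count = as.integer(sb$counts))
  out$angles <- angles
  out
}

#' Generate the clone-geometry scatter (length vs midpoint)
#'
#' Emulates the two-cluster clone geometry: by 18 months, isthmus-spanning
#' upper clones occupy about 80% (SD 20%) of the gland height in the upper
#' region, while base-localized clones occupy about 30% (SD 10%) at the
#' base. Earlier time points shrink the upper cluster mean along the
#' vertical-expansion model's expected-length curve; the quiescent base
#' cluster is static. Lengths are truncated to [0, 1] and midpoints placed
#' so clones stay inside the gland.
#'
#' @param design A \code{\link{synthetic_design}}.
#' @param n_clones Clones per time point.
#' @param times Time points (months); default the design's.
#' @param drift,vertical Parameters for the interpolation curve.
#' @param seed Integer seed.
#' @return Data frame with \code{time_months}, \code{compartment},
#'   \code{rel_length}, \code{rel_midpoint}.
#' @export
generate_geometry_scatter <- function(design, n_clones = 500,
                                      times = NULL,
                                      drift = drift_params_from_composite(0.3),
                                      vertical = vertical_params(),
                                      seed = 1) {
  stopifnot(inherits(design, "synthetic_design"))
  if (is.null(times)) times <- design$time_points
  set.seed(as.integer(seed))
  sat <- vertical$pit + vertical$isthmus + vertical$neck
  out <- list()
  for (tt in times) {
    n_base <- round(n_clones * design$base_clone_fraction)
    n_up <- n_clones - n_base
    # upper-cluster mean tracks the vertical model, reaching the long-term
    # cluster mean as the fronts saturate
    m_up <- design$upper_mean * expected_rel_length(drift, vertical, tt) / sat
    s_up <- design$upper_sd * m_up / design$upper_mean
    len_up <- pmin(1, pmax(0, stats::rnorm(n_up, m_up, s_up)))
    mid_up <- pmax(len_up / 2,
                   pmin(1 - len_up / 2,
                        stats::rnorm(n_up, vertical$pit +
                                       vertical$isthmus / 2, 0.05)))
    len_b <- pmin(1, pmax(0, stats::rnorm(n_base, design$base_mean,
                                          design$base_sd)))
    mid_b <- pmax(len_b / 2, 1 - len_b / 2) # anchored at the gland base
    out[[length(out) + 1L]] <- data.frame(
      time_months = tt,
      compartment = c(rep("upper", n_up), rep("base", n_base)),
      rel_length = c(len_up, len_b),
      rel_midpoint = c(mid_up, mid_b))
  }
  do.call(rbind, out)
}
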