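#' Initialize a gland state
#'
#' A gland cross-section is a ring of \code{n_sites} stem-cell sites indexed
#' 0..N-1; edge i lies between sites i and (i+1) mod N and may carry a
#' parietal-cell barrier. Clonal-density induction labels at most one site.
#'
#' @param n_sites Number of stem-cell sites (integer >= 2).
#' @param barrier_edges Integer vector of occupied edge indices in 0..N-1.
#' @param labeled_site Site index in 0..N-1 of the single labeled cell, or
#'   \code{NA} for an unlabeled gland.
#' @return An object of class \code{gland_state} with fields \code{labels}
#'   (integer vector, 0 = unlabeled, 1 = clone), \code{barrier_edges}, and
#'   \code{time} (months since induction).
#' @examples
#' g <- init_gland(8, barrier_edges = c(0, 4), labeled_site = 2)
#' @export
init_gland <- function(n_sites, barrier_edges = integer(0),
                       labeled_site = NA) {
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 2) stop("n_sites must be an integer >= 2")
  barrier_edges <- as.integer(barrier_edges)
  if (anyDuplicated(barrier_edges))
    stop("barrier_edges must be distinct")
  if (length(barrier_edges) &&
      (any(barrier_edges < 0) || any(barrier_edges >= n_sites)))
    stop("barrier edge indices must lie in 0..n_sites-1")
  labels <- integer(n_sites)
  if (!is.na(labeled_site)) {
    labeled_site <- as.integer(labeled_site)
    if (labeled_site < 0 || labeled_site >= n_sites)
      stop("labeled_site must lie in 0..n_sites-1")
    labels[labeled_site + 1L] <- 1L
  }
  structure(list(labels = labels, barrier_edges = sort(barrier_edges),
                 time = 0), class = "gland_state")
}

#' @export
print.gland_state <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<gland_state> %d sites, %d labeled, %d barriers, t = %g months\n",
              n, sum(x$labels > 0), length(x$barrier_edges), x$time))
  invisible(x)
}

#' Maximal-spacing barrier placement
#'
#' Newly born parietal-cell barriers tend to maximize the angular distance to
#' the standing barriers. Among unoccupied edges, returns one maximizing the
#' minimum circular distance to the occupied edges; ties are broken uniformly
#' at random, and placement is uniform over all edges when no barrier exists.
#'
#' @param n_sites Number of edges (= sites) on the ring.
#' @param barrier_edges Occupied edge indices.
#' @return A free edge index in 0..N-1.
#' @examples
#' set.seed(1)
#' place_barrier(8, c(0)) # 4: the unique antipodal edge
#' @export
place_barrier <- function(n_sites, barrier_edges = integer(0)) {
  n_sites <- as.integer(n_sites)
  occ <- rep(FALSE, n_sites)
  if (length(barrier_edges)) occ[as.integer(barrier_edges) + 1L] <- TRUE
  if (all(occ)) stop("all edges occupied: no free edge to place a barrier")
  place_barrier_core(occ)
}

# shared wrapper around the C++ Gillespie core; returns the raw matrices
run_core <- function(drift, record_times, n_replicates, seed,
                     beta = 0, mu = 0,
                     init = c("none", "stationary", "fixed"),
                     fixed_barriers = integer(0),
                     labeled_site = -1L,
                     recovery_beta = beta, recovery_end = 0,
                     lambda_scale = 1, lw_start = 0, lw_end = 0,
                     record_edges = FALSE) {
  stopifnot(inherits(drift, "drift_params"))
  record_times <- as.numeric(record_times)
  if (any(record_times < 0)) stop("record times must be >= 0")
  if (is.unsorted(record_times)) stop("record_times must be sorted")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pnd_core(drift$n_sites, drift$lambda_rate, beta, mu,
           record_times, as.integer(n_replicates),
           match(init, c("none", "stationary", "fixed")) - 1L,
           as.integer(fixed_barriers), as.integer(labeled_site),
           recovery_beta, recovery_end, lambda_scale, lw_start, lw_end,
           record_edges)
}

core_to_table <- function(res, record_times, arm = "control") {
  nrep <- nrow(res$labeled_fraction)
  nt <- length(record_times)
  data.frame(
    replicate_id = rep(seq_len(nrep), times = nt),
    time_months = rep(record_times, each = nrep),
    labeled_fraction = as.vector(res$labeled_fraction),
    surviving = as.vector(res$labeled_fraction) > 0,
    monoclonal = as.vector(res$labeled_fraction) == 1,
    barrier_count = as.vector(res$barrier_count),
    cohesive = as.vector(res$cohesive),
    arm = arm,
    stringsAsFactors = FALSE
  )
}

#' Simulate the orthodox one-parameter neutral-drift model
#'
#' Exact event-driven simulation on a barrier-free periodic ring of N cells.
#' Events occur at total rate N * lambda; at each event a uniformly chosen
#' cell is lost and one of its two nearest neighbors (chosen uniformly)
#' divides symmetrically to replace it. Each replicate starts from a single
#' labeled cell (clonal-density induction). Under these neutral rules the
#' labeled fraction is a martingale and a single labeled cell ultimately
#' fixes with probability 1/N.
#'
#' @param params A \code{\link{drift_params}} object.
#' @param record_times Sorted non-negative times (months) at which to record.
#' @param n_replicates Number of independent glands to simulate.
#' @param seed Integer seed; identical seeds give bit-identical tables.
#' @return A data.frame of trajectory records with columns
#'   \code{replicate_id}, \code{time_months}, \code{labeled_fraction},
#'   \code{surviving}, \code{monoclonal}, \code{barrier_count} (always 0),
#'   and \code{cohesive} (labeled set forms one contiguous arc).
#' @examples
#' tr <- simulate_orthodox(drift_params(1.92, 8), c(1, 3), 100, seed = 1)
#' mean(tr$labeled_fraction[tr$time_months == 3]) # about 1/8 by neutrality
#' @export
simulate_orthodox <- function(params, record_times, n_replicates,
                              seed = NULL) {
  res <- run_core(params, record_times, n_replicates, seed,
                  labeled_site = -1L)
  out <- core_to_table(res, record_times, arm = "orthodox")
  out$cohesive <- NULL
  cbind(out[, c("replicate_id", "time_months", "labeled_fraction",
                "surviving", "monoclonal", "barrier_count")],
        cohesive = as.vector(res$cohesive))
}

#' Simulate the punctuated neutral drift (PND) model
#'
#' Competing-event Gillespie simulation of neutral drift on a ring whose
#' edges can carry parietal-cell barriers. Drift events are restricted to
#' within barrier-delimited segments: a lost cell can only be replaced by a
#' same-segment nearest neighbor, and a cell walled in on both sides hosts
#' no drift event. Standing barriers die independently at rate mu (merging
#' adjacent segments, which opens a window for a burst of lateral clonal
#' expansion); new barriers are born at gland-level rate beta and placed at
#' maximal angular spacing (\code{\link{place_barrier}}).
#'
#' Arms: \code{control} starts from the stationary barrier configuration;
#' \code{dmp777} starts barrier-free with elevated barrier birth during the
#' recovery window (acute parietal-cell ablation, census restored within
#' about two weeks); \code{muc6_dtr} and \code{lambda_scale} multiply lambda
#' by \code{scale} during their window, leaving barriers untouched;
#' \code{lifespan_scale} multiplies mu by \code{scale}.
#'
#' @param drift A \code{\link{drift_params}} object.
#' @param barriers A \code{\link{barrier_params}} object.
#' @param arm A \code{\link{perturbation_arm}} (default control).
#' @param record_times,n_replicates,seed As in
#'   \code{\link{simulate_orthodox}}.
#' @param labeled_site Site index of the labeled cell, \code{NULL} for a
#'   uniformly random site (default), or \code{NA} for unlabeled glands
#'   (barrier dynamics only).
#' @param init_barriers \code{NULL} for the arm's default initial condition,
#'   or an explicit integer vector of edge indices.
#' @param record_edges If TRUE, attach the barrier-edge snapshots as
#'   attribute \code{"barrier_edges"} (a list, one logical
#'   replicate-by-edge matrix per record time).
#' @return A trajectory data.frame as in \code{\link{simulate_orthodox}}
#'   plus the \code{arm} column.
#' @export
simulate_pnd <- function(drift, barriers, arm = perturbation_arm("control"),
                         record_times, n_replicates, seed = NULL,
                         labeled_site = NULL, init_barriers = NULL,
                         record_edges = FALSE) {
  stopifnot(inherits(barriers, "barrier_params"))
  if (!inherits(arm, "perturbation_arm")) stop("arm must be a perturbation_arm")
  beta <- barriers$birth_rate
  mu <- barriers$death_rate
  init <- "stationary"
  recovery_beta <- beta
  recovery_end <- 0
  lambda_scale <- 1; lw_start <- 0; lw_end <- 0
  if (arm$arm == "dmp777") {
    init <- "none"
    recovery_beta <- barriers$recovery_birth_rate
    recovery_end <- barriers$recovery_window
  } else if (arm$arm %in% c("muc6_dtr", "lambda_scale")) {
    lambda_scale <- arm$scale
    lw_start <- arm$onset
    lw_end <- arm$onset + arm$duration
  } else if (arm$arm == "lifespan_scale") {
    mu <- mu * arm$scale
  }
  if (mu == 0 && init == "stationary" && is.null(init_barriers))
    init <- "none"  # no stationary law without barrier death
  fixed <- integer(0)
  if (!is.null(init_barriers)) {
    init <- "fixed"
    fixed <- as.integer(init_barriers)
  }
  lab <- if (is.null(labeled_site)) -1L
         else if (is.na(labeled_site)) -2L else as.integer(labeled_site)
  res <- run_core(drift, record_times, n_replicates, seed,
                  beta = beta, mu = mu, init = init, fixed_barriers = fixed,
                  labeled_site = lab,
                  recovery_beta = recovery_beta, recovery_end = recovery_end,
                  lambda_scale = lambda_scale, lw_start = lw_start,
                  lw_end = lw_end, record_edges = record_edges)
  out <- core_to_table(res, record_times, arm = arm$arm)
  if (record_edges) attr(out, "barrier_edges") <- res$barrier_edges
  out
}

#' Stationary barrier census and spacing statistics
#'
#' Simulates the barrier birth-death process alone (no clone labels) past a
#' burn-in and returns the per-gland barrier counts and, for glands hosting
#' exactly two barriers, the minimum pairwise circular distance in degrees.
#' The count process is an immigration-death process, so its stationary law
#' is Poisson(beta/mu) (truncated at the N available edges); the
#' maximal-spacing placement rule shapes positions but not counts.
#'
#' @param barriers A \code{\link{barrier_params}} object with death rate > 0.
#' @param n_sites Number of edges on the ring.
#' @param n_glands Number of independent glands to sample.
#' @param burn_in Months to simulate before sampling (default 20).
#' @param seed Integer seed.
#' @return A list with \code{counts} (integer vector, one per gland),
#'   \code{min_distance_deg} (minimum angular distances for count-2 glands),
#'   and \code{edges} (logical gland-by-edge occupancy matrix).
#' @export
stationary_barrier_distribution <- function(barriers, n_sites = 8L,
                                            n_glands = 1000L, burn_in = 20,
                                            seed = NULL) {
  stopifnot(inherits(barriers, "barrier_params"))
  if (barriers$death_rate <= 0)
    stop("death_rate must be > 0: no stationary state otherwise")
  drift <- drift_params(0, n_sites) # label process switched off
  res <- run_core(drift, burn_in, n_glands, seed,
                  beta = barriers$birth_rate, mu = barriers$death_rate,
                  init = "none", labeled_site = -2L, record_edges = TRUE)
  edges <- res$barrier_edges[[1]]
  counts <- rowSums(edges)
  two <- which(counts == 2)
  mind <- vapply(two, function(g) {
    ang <- (which(edges[g, ]) - 1 + 0.5) * 360 / n_sites
    min_angular_distance(ang)
  }, numeric(1))
  list(counts = as.integer(counts), min_distance_deg = mind, edges = edges)
}
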