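#' Simulate vertical clone expansion along the gland axis
#'
#' Clones nucleate spanning the isthmus and expand bidirectionally: stem-cell
#' divisions push progeny both upwards towards the pit and downwards into the
#' neck (the gland "conveyor"). The upper and lower fronts advance as
#' independent Poisson processes with rates \code{up_rate * lambda} and
#' \code{down_rate * lambda} events/month, each advance covering one cell
#' height. The upper front saturates at the pit top and the lower front at
#' the neck/base boundary, so the relative clone length saturates at
#' pit + isthmus + neck of the gland height (0.8 by default).
#'
#' Lambda-scaling arms (\code{muc6_dtr}, \code{lambda_scale}) multiply the
#' front rates by their factor inside the perturbation window, since front
#' advance is driven by division; barrier perturbations (\code{dmp777},
#' \code{lifespan_scale}) leave vertical dynamics unchanged.
#'
#' @param drift A \code{\link{drift_params}} object.
#' @param vertical A \code{\link{vertical_params}} object.
#' @param arm A \code{\link{perturbation_arm}}.
#' @param record_times Sorted non-negative record times, months.
#' @param n_replicates Number of clones.
#' @param seed Integer seed.
#' @return Data frame with columns \code{replicate_id}, \code{time_months},
#'   \code{arm}, \code{up_extent}, \code{down_extent}, \code{rel_length},
#'   \code{rel_midpoint} (0 = gland top).
#' @export
simulate_vertical <- function(drift, vertical,
                              arm = perturbation_arm("control"),
                              record_times, n_replicates, seed = NULL) {
  stopifnot(inherits(drift, "drift_params"),
            inherits(vertical, "vertical_params"),
            inherits(arm, "perturbation_arm"))
  record_times <- as.numeric(record_times)
  if (any(record_times < 0) || is.unsorted(record_times))
    stop("record_times must be sorted and >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  lam <- drift$lambda_rate
  step <- 1 / vertical$cells_per_gland
  scale_in <- if (arm$arm %in% c("muc6_dtr", "lambda_scale")) arm$scale else 1
  w0 <- arm$onset; w1 <- arm$onset + arm$duration

  # integrated front intensity over [0, t] under the piecewise-constant rate
  intensity <- function(rate, t) {
    base <- rate * lam * t
    extra <- rate * lam * (scale_in - 1) *
      pmax(0, pmin(t, w1) - pmin(t, w0))
    base + extra
  }
  nt <- length(record_times)
  up_counts <- matrix(0L, n_replicates, nt)
  dn_counts <- matrix(0L, n_replicates, nt)
  prev <- 0
  Iu_prev <- 0; Id_prev <- 0
  for (j in seq_len(nt)) {
    Iu <- intensity(vertical$up_rate, record_times[j])
    Id <- intensity(vertical$down_rate, record_times[j])
    du <- stats::rpois(n_replicates, Iu - Iu_prev)
    dd <- stats::rpois(n_replicates, Id - Id_prev)
    up_counts[, j] <- (if (j == 1) 0L else up_counts[, j - 1]) + du
    dn_counts[, j] <- (if (j == 1) 0L else dn_counts[, j - 1]) + dd
    Iu_prev <- Iu; Id_prev <- Id
  }
  up <- pmin(vertical$pit, up_counts * step)
  dn <- pmin(vertical$neck, dn_counts * step)
  rel_len <- up + vertical$isthmus + dn
  # isthmus spans [pit, pit + isthmus] in top-anchored gland coordinates
  top <- vertical$pit - up
  bottom <- vertical$pit + vertical$isthmus + dn
  data.frame(
    replicate_id = rep(seq_len(n_replicates), times = nt),
    time_months = rep(record_times, each = n_replicates),
    arm = arm$arm,
    up_extent = as.vector(up),
    down_extent = as.vector(dn),
    rel_length = as.vector(rel_len),
    rel_midpoint = as.vector((top + bottom) / 2),
    stringsAsFactors = FALSE
  )
}

#' Expected relative clone length under the vertical model
#'
#' Deterministic mean of \code{\link{simulate_vertical}}'s relative length,
#' used to interpolate clone-geometry clusters at early time points. The
#' expectation of a saturating Poisson front min(cap, step * K) with
#' K ~ Poisson(I) is evaluated exactly from the Poisson pmf.
#'
#' @inheritParams simulate_vertical
#' @param times Times (months) at which to evaluate.
#' @return Numeric vector of expected relative lengths.
#' @export
expected_rel_length <- function(drift, vertical, times,
                                arm = perturbation_arm("control")) {
  lam <- drift$lambda_rate
  step <- 1 / vertical$cells_per_gland
  scale_in <- if (arm$arm %in% c("muc6_dtr", "lambda_scale")) arm$scale else 1
  w0 <- arm$onset; w1 <- arm$onset + arm$duration
  mean_front <- function(rate, cap, t) {
    I <- rate * lam * t + rate * lam * (scale_in - 1) *
      max(0, min(t, w1) - min(t, w0))
    kmax <- ceiling(cap / step)
    k <- 0:(kmax - 1)
    # E min(cap, step K) = step * sum_{k<kmax} P(K > k), capped at cap
    sum(step * stats::ppois(k, I, lower.tail = FALSE)) -
      max(0, step * kmax - cap) * stats::ppois(kmax - 1, I,
                                               lower.tail = FALSE)
  }
  vapply(times, function(t) {
    vertical$isthmus + mean_front(vertical$up_rate, vertical$pit, t) +
      mean_front(vertical$down_rate, vertical$neck, t)
  }, numeric(1))
}
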