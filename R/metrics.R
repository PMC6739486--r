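#' Relative angular clone size from a 3-point annotation
#'
#' Clone extent around the gland circumference is scored from three points
#' per optical section: P1 on the clone's leading boundary, P2 at the gland
#' center, and P3 on the trailing boundary. The relative angular size is the
#' clockwise angle at P2 from the bearing of P1 to the bearing of P3,
#' divided by 360 degrees. "Clockwise" follows image coordinates (y grows
#' downward), i.e. the negative mathematical direction in standard x-y
#' coordinates; annotations from math-convention tools must be flipped.
#'
#' @param p1,p2,p3 Numeric length-2 vectors (x, y); P2 is the gland center.
#' @return The clone's fraction of the circumference, in [0, 1).
#' @examples
#' angular_fraction(c(1, 0), c(0, 0), c(-1, 0)) # 0.5 (antipodal)
#' angular_fraction(c(0, 1), c(0, 0), c(1, 0))  # 0.25
#' @export
angular_fraction <- function(p1, p2, p3) {
  pts <- list(p1 = p1, p2 = p2, p3 = p3)
  for (nm in names(pts))
    if (!is.numeric(pts[[nm]]) || length(pts[[nm]]) != 2 ||
        any(!is.finite(pts[[nm]])))
      stop(nm, " must be a finite numeric (x, y) pair")
  if (identical_pt(p1, p2) || identical_pt(p3, p2) || identical_pt(p1, p3))
    stop("coincident annotation points; record fully labeled glands with ",
         "is_full = TRUE instead of coincident boundaries")
  b1 <- atan2(p1[2] - p2[2], p1[1] - p2[1])
  b3 <- atan2(p3[2] - p2[2], p3[1] - p2[1])
  ((b1 - b3) / (2 * pi)) %% 1
}

identical_pt <- function(a, b) isTRUE(all(a == b))

#' Summarize isthmus-section fractions into one angular clone size
#'
#' Clones are scored in up to three optical sections spanning the isthmus
#' (top, center, lowest). The per-clone summary is the mean of the available
#' section fractions (\code{method = "mean"}, default) or their maximum.
#'
#' @param section_fractions Numeric vector of per-section fractions in
#'   [0, 1]; NAs are dropped.
#' @param method "mean" or "max".
#' @return A single summary fraction.
#' @export
isthmus_summary <- function(section_fractions, method = c("mean", "max")) {
  method <- match.arg(method)
  x <- section_fractions[!is.na(section_fractions)]
  if (!length(x)) stop("no isthmus section measurements present")
  if (any(x < 0 | x > 1)) stop("section fractions must lie in [0, 1]")
  if (method == "mean") mean(x) else max(x)
}

#' Classify a gland as fully or partially labeled
#'
#' @param angular_fraction Fraction of the circumference occupied, in [0, 1].
#' @param full_threshold Fractions at or above this are "full" (boundary
#'   inclusive). Use 1.0 for noise-free simulated states, 0.95 for measured
#'   data where jitter makes exact 1.0 unattainable.
#' @return "full" or "partial" (character, vectorized).
#' @export
classify_gland <- function(angular_fraction, full_threshold = 0.95) {
  if (any(angular_fraction < 0 | angular_fraction > 1, na.rm = TRUE))
    stop("angular_fraction must lie in [0, 1]")
  ifelse(angular_fraction >= full_threshold, "full", "partial")
}

#' Vertical clone metrics: relative length and midpoint
#'
#' Maps axial coordinates of a clone's endpoints to gland-relative units:
#' relative length is the clone span over the gland span, and the relative
#' midpoint is the clone center mapped to [0, 1] with 0 at the gland top
#' (pit) and 1 at the base.
#'
#' @param clone_top,clone_bottom Axial coordinates of the clone endpoints.
#' @param gland_top,gland_bottom Axial coordinates of the gland endpoints.
#' @return Named numeric vector \code{c(rel_length, rel_midpoint)}.
#' @examples
#' vertical_metrics(0, 5, 0, 10) # top half: length 0.5, midpoint 0.25
#' @export
vertical_metrics <- function(clone_top, clone_bottom, gland_top,
                             gland_bottom) {
  if (gland_top == gland_bottom) stop("gland has zero extent")
  if (clone_top == clone_bottom) stop("zero-length clone")
  # map to [0, 1] with 0 at the gland top regardless of axis orientation
  to_rel <- function(z) (z - gland_top) / (gland_bottom - gland_top)
  a <- to_rel(clone_top); b <- to_rel(clone_bottom)
  lo <- min(a, b); hi <- max(a, b)
  if (lo < -1e-9 || hi > 1 + 1e-9)
    stop("clone extends outside the gland")
  c(rel_length = hi - lo, rel_midpoint = (hi + lo) / 2)
}

#' Cross-sectional cohort summary
#'
#' Per-time-point clone statistics matching the lineage-tracing readouts:
#' mean angular size of surviving clones, clone survival frequency (labeled
#' glands over total glands scored), their product (the average labeled cell
#' fraction, conserved under neutral drift), and the percentage of labeled
#' glands that are fully labeled (monoclonal).
#'
#' @param observations Data frame with columns \code{time_months} and
#'   \code{angular_fraction} (one row per labeled gland/clone); an optional
#'   \code{is_full} logical column overrides threshold classification.
#' @param total_glands Data frame with columns \code{time_months} and
#'   \code{n_glands}: total glands scored per time point (labeled or not).
#' @param full_threshold Passed to \code{\link{classify_gland}} when
#'   \code{is_full} is absent.
#' @return Data frame keyed by \code{time_months} with columns
#'   \code{n_labeled}, \code{mean_size_surviving}, \code{survival_frequency},
#'   \code{labeled_fraction}, \code{pct_full}.
#' @export
cohort_summary <- function(observations, total_glands,
                           full_threshold = 0.95) {
  need <- c("time_months", "angular_fraction")
  if (!all(need %in% names(observations)))
    stop("observations need columns: ", paste(need, collapse = ", "))
  if (!all(c("time_months", "n_glands") %in% names(total_glands)))
    stop("total_glands needs columns time_months, n_glands")
  if (any(total_glands$n_glands <= 0))
    stop("zero total glands at some time point")
  out <- lapply(seq_len(nrow(total_glands)), function(i) {
    tt <- total_glands$time_months[i]
    nn <- total_glands$n_glands[i]
    obs <- observations[observations$time_months == tt, , drop = FALSE]
    nl <- nrow(obs)
    if (nl > nn) stop("more labeled clones than total glands at t = ", tt)
    if (nl == 0) {
      return(data.frame(time_months = tt, n_labeled = 0L,
                        mean_size_surviving = NA_real_,
                        survival_frequency = 0, labeled_fraction = 0,
                        pct_full = NA_real_))
    }
    full <- if ("is_full" %in% names(obs) && !all(is.na(obs$is_full)))
      obs$is_full
    else classify_gland(obs$angular_fraction, full_threshold) == "full"
    ms <- mean(obs$angular_fraction)
    sf <- nl / nn
    data.frame(time_months = tt, n_labeled = nl, mean_size_surviving = ms,
               survival_frequency = sf, labeled_fraction = ms * sf,
               pct_full = 100 * mean(full))
  })
  do.call(rbind, out)
}

#' Minimum pairwise angular distance
#'
#' The smallest circular distance between any pair of angles, in degrees:
#' for each pair, min(|a - b| mod 360, 360 - |a - b| mod 360).
#'
#' @param angles Numeric vector of at least two positions in degrees.
#' @return Minimum pairwise circular distance, degrees (in [0, 180]).
#' @examples
#' min_angular_distance(c(0, 90, 300)) # 60
#' @export
min_angular_distance <- function(angles) {
  if (length(angles) < 2) stop("need at least two angles")
  d <- abs(outer(angles, angles, "-")) %% 360
  d <- pmin(d, 360 - d)
  min(d[upper.tri(d)])
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' comes from the asymptotic Kolmogorov distribution evaluated at
#' sqrt(n_eff) * D with effective sample size n_eff = n_x n_y / (n_x + n_y).
#'
#' @param x,y Non-empty numeric samples.
#' @return List with \code{statistic} (D) and \code{p_value}.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  Fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  D <- max(abs(Fx - Fy))
  ne <- nx * ny / (nx + ny)
  lam <- sqrt(ne) * D
  # asymptotic Kolmogorov survival function Q(lam) = 2 sum (-1)^{k-1} e^{-2k^2 lam^2}
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))
  list(statistic = D, p_value = max(0, min(1, p)))
}

#' Score a raw clone-annotation table
#'
#' Applies the quantification pipeline to a table in the raw annotation
#' schema (one row per clone): 3-point angular scoring per isthmus section
#' (\code{\link{angular_fraction}}), section summary
#' (\code{\link{isthmus_summary}}), full/partial classification, and
#' vertical metrics (\code{\link{vertical_metrics}}).
#'
#' Expected columns: \code{gland_id}, \code{time_months}, \code{arm},
#' \code{compartment}, \code{is_full}, per-section points
#' \code{p1x_s<k>} ... \code{p3y_s<k>} for sections k = 1..3 (NA where a
#' section was not scored), and \code{clone_top}, \code{clone_bottom},
#' \code{gland_top}, \code{gland_bottom}.
#'
#' @param raw Data frame (or path to a CSV file) in the schema above.
#' @param full_threshold Threshold for full/partial classification of rows
#'   not already flagged \code{is_full}.
#' @param summary_method Passed to \code{\link{isthmus_summary}}.
#' @return Data frame of clone observations with columns \code{gland_id},
#'   \code{time_months}, \code{arm}, \code{compartment},
#'   \code{angular_fraction}, \code{is_full}, \code{classification},
#'   \code{rel_length}, \code{rel_midpoint}.
#' @export
score_observations <- function(raw, full_threshold = 0.95,
                               summary_method = "mean") {
  if (is.character(raw)) raw <- utils::read.csv(raw)
  n <- nrow(raw)
  af <- numeric(n)
  for (i in seq_len(n)) {
    if (isTRUE(raw$is_full[i])) { af[i] <- 1; next }
    secs <- numeric(0)
    for (k in 1:3) {
      p1 <- c(raw[[paste0("p1x_s", k)]][i], raw[[paste0("p1y_s", k)]][i])
      p3 <- c(raw[[paste0("p3x_s", k)]][i], raw[[paste0("p3y_s", k)]][i])
      p2 <- c(raw[[paste0("p2x_s", k)]][i], raw[[paste0("p2y_s", k)]][i])
      if (any(is.na(c(p1, p2, p3)))) next
      secs <- c(secs, angular_fraction(p1, p2, p3))
    }
    af[i] <- isthmus_summary(secs, method = summary_method)
  }
  vm <- t(mapply(vertical_metrics, raw$clone_top, raw$clone_bottom,
                 raw$gland_top, raw$gland_bottom))
  data.frame(gland_id = raw$gland_id, time_months = raw$time_months,
             arm = raw$arm, compartment = raw$compartment,
             angular_fraction = af, is_full = raw$is_full,
             classification = ifelse(raw$is_full, "full",
                                     classify_gland(af, full_threshold)),
             rel_length = vm[, "rel_length"],
             rel_midpoint = vm[, "rel_midpoint"],
             row.names = NULL)
}
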