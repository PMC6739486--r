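#' Drift parameters for the neutral-drift ring model
#'
#' The isthmus stem-cell compartment is modeled as a ring of \code{n_sites}
#' functionally equivalent cells. Each cell is lost (through displacement and
#' differentiation) at rate \code{lambda_rate} per month, and the vacancy is
#' filled by the symmetric division of one of its two nearest neighbors. The
#' quantity reported in fits is the composite rate
#' \eqn{\lambda/N^2} (per month), which sets the lateral drift timescale.
#'
#' @param lambda_rate Per-cell loss-and-replacement rate, events/month.
#' @param n_sites Effective stem-cell number N per circumferential section
#'   (integer, at least 2).
#' @return An object of class \code{drift_params}.
#' @examples
#' p <- drift_params(lambda_rate = 19.2, n_sites = 8)
#' lambda_over_n2(p) # 0.3 / month
#' @export
drift_params <- function(lambda_rate, n_sites = 8L) {
  stopifnot(is.numeric(lambda_rate), length(lambda_rate) == 1)
  if (lambda_rate < 0) stop("lambda_rate must be >= 0")
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 2) stop("n_sites must be an integer >= 2")
  structure(list(lambda_rate = lambda_rate, n_sites = n_sites),
            class = "drift_params")
}

#' @rdname drift_params
#' @param lambda_over_n2 Composite rate lambda/N^2 in /month; converted to the
#'   per-cell rate lambda = lambda_over_n2 * N^2.
#' @export
drift_params_from_composite <- function(lambda_over_n2, n_sites = 8L) {
  n_sites <- as.integer(n_sites)
  drift_params(lambda_over_n2 * n_sites^2, n_sites)
}

#' @rdname drift_params
#' @param params A \code{drift_params} object.
#' @export
lambda_over_n2 <- function(params) {
  stopifnot(inherits(params, "drift_params"))
  params$lambda_rate / params$n_sites^2
}

#' Barrier (parietal-cell) birth-death parameters
#'
#' Parietal cells form long-lived vertical walls that block lateral
#' stem-cell replacement; they are modeled as barriers occupying edges of the
#' stem-cell ring. Barriers are born as a gland-level Poisson process at
#' \code{birth_rate} per month (placed at maximal angular spacing) and each
#' standing barrier dies independently at \code{death_rate} per month, so the
#' mean barrier lifetime is 1/\code{death_rate} and the stationary count is
#' Poisson with mean \code{birth_rate}/\code{death_rate}. After acute
#' parietal-cell ablation (DMP-777), the census refills within about two
#' weeks, modeled by an elevated birth rate \code{recovery_birth_rate} for
#' the first \code{recovery_window} months.
#'
#' Defaults (birth 1.0/month, death 0.4/month) give a stationary mean of 2.5
#' barriers per cross-section and a mean barrier lifetime of 2.5 months,
#' consistent with observed per-section parietal-cell counts of 2-3 and a
#' reported parietal-cell lifespan of roughly 54 days.
#'
#' @param birth_rate Barrier births per gland per month.
#' @param death_rate Deaths per standing barrier per month.
#' @param recovery_birth_rate Elevated birth rate during post-ablation
#'   recovery, per month.
#' @param recovery_window Length of the recovery window, months.
#' @return An object of class \code{barrier_params}.
#' @export
barrier_params <- function(birth_rate = 1.0, death_rate = 0.4,
                           recovery_birth_rate = 5.0,
                           recovery_window = 0.5) {
  vals <- c(birth_rate, death_rate, recovery_birth_rate, recovery_window)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all barrier rates and windows must be finite and >= 0")
  structure(list(birth_rate = birth_rate, death_rate = death_rate,
                 recovery_birth_rate = recovery_birth_rate,
                 recovery_window = recovery_window),
            class = "barrier_params")
}

#' Vertical clone-expansion parameters
#'
#' The gland axis is split into pit, isthmus, neck, and base regions whose
#' height fractions sum to 1. A clone nucleates spanning the isthmus and its
#' upper and lower fronts advance as Poisson processes with rates
#' \code{up_rate * lambda} and \code{down_rate * lambda} (front advances per
#' stem-cell division; divisions displace progeny bidirectionally along the
#' gland conveyor). Each advance moves a front by one cell height
#' (1/\code{cells_per_gland} of the gland). Fronts saturate at the pit top
#' and at the neck/base boundary, so the relative clone length saturates at
#' pit + isthmus + neck (0.8 by default), matching the observed long-term
#' size of isthmus-spanning clones.
#'
#' @param pit,isthmus,neck,base Region height fractions, summing to 1.
#' @param up_rate,down_rate Front advances per stem-cell division.
#' @param cells_per_gland Gland height in cell diameters; one front advance
#'   covers 1/cells_per_gland of the gland height.
#' @return An object of class \code{vertical_params}.
#' @export
vertical_params <- function(pit = 0.3, isthmus = 0.2, neck = 0.3, base = 0.2,
                            up_rate = 0.1, down_rate = 0.1,
                            cells_per_gland = 20L) {
  fr <- c(pit, isthmus, neck, base)
  if (any(fr < 0)) stop("region fractions must be >= 0")
  if (abs(sum(fr) - 1) > 1e-8) stop("region fractions must sum to 1")
  if (up_rate < 0 || down_rate < 0) stop("front rates must be >= 0")
  structure(list(pit = pit, isthmus = isthmus, neck = neck, base = base,
                 up_rate = up_rate, down_rate = down_rate,
                 cells_per_gland = as.integer(cells_per_gland)),
            class = "vertical_params")
}

#' In-silico perturbation arms
#'
#' \describe{
#'   \item{control}{Barriers initialized from their stationary configuration.}
#'   \item{dmp777}{Acute parietal-cell ablation: all barriers deleted at
#'     t = 0, then elevated barrier birth during the recovery window.}
#'   \item{muc6_dtr}{Injury response of isthmus stem cells: the
#'     loss-and-replacement rate lambda is multiplied by \code{scale} during
#'     \code{[onset, onset + duration)}; barriers untouched. Defaults: scale
#'     2, onset 0.25 months (toxin given one week after induction), duration
#'     0.75 months (examined at one month).}
#'   \item{lambda_scale}{Generic lambda scaling over a window (used for
#'     perturbation-discrimination experiments).}
#'   \item{lifespan_scale}{Barrier death rate mu multiplied by \code{scale}
#'     (shorter barrier lifespan for scale > 1); applied for the whole run.}
#' }
#'
#' @param arm One of "control", "dmp777", "muc6_dtr", "lambda_scale",
#'   "lifespan_scale".
#' @param scale Multiplicative factor for the perturbed rate (must be > 0).
#' @param onset,duration Window of the perturbation, months (lambda-scaling
#'   arms only).
#' @return An object of class \code{perturbation_arm}.
#' @export
perturbation_arm <- function(arm = c("control", "dmp777", "muc6_dtr",
                                     "lambda_scale", "lifespan_scale"),
                             scale = 2, onset = 0.25, duration = 0.75) {
  arm <- match.arg(arm)
  if (scale <= 0) stop("scale must be > 0")
  if (onset < 0 || duration < 0) stop("onset and duration must be >= 0")
  structure(list(arm = arm, scale = scale, onset = onset,
                 duration = duration),
            class = "perturbation_arm")
}

# weeks <-> months conversion used for reporting (1 month = 30.44 days)
WEEKS_PER_MONTH <- 30.44 / 7

#' Per-cell replacement interval implied by a composite drift rate
#'
#' Converts a fitted composite rate lambda/N^2 and a stem-cell number N into
#' the implied per-cell loss-and-replacement interval 1/lambda, in weeks
#' (1 month = 30.44 days).
#'
#' @param lambda_over_n2 Composite rate, /month.
#' @param n_sites Stem-cell number N.
#' @return Interval between replacement events per cell, in weeks.
#' @examples
#' replacement_interval_weeks(0.03, 8) # about 2 weeks
#' @export
replacement_interval_weeks <- function(lambda_over_n2, n_sites) {
  if (lambda_over_n2 <= 0) stop("lambda_over_n2 must be > 0")
  lambda <- lambda_over_n2 * n_sites^2
  (1 / lambda) * WEEKS_PER_MONTH
}
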