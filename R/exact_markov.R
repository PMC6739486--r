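#' Exact small-system Markov oracle for neutral drift
#'
#' Enumerates all 2^N label configurations of a ring (or open chain, for a
#' single barrier-delimited segment) of N sites, builds the exact generator
#' of the continuous-time Markov chain defined by the drift rules (each
#' eligible cell is lost at rate lambda and replaced by a uniformly chosen
#' accessible nearest neighbor), and returns summaries by matrix
#' exponentiation. Intended as an independent brute-force oracle for the
#' event-driven simulators; refuses N > 6 (state space 2^N).
#'
#' @param params A \code{\link{drift_params}} with \code{n_sites <= 6}.
#' @param labeled_site Initially labeled site index (0-based).
#' @param topology "ring" (periodic, the barrier-free gland circumference) or
#'   "chain" (open ends, a single segment between two barriers).
#' @return A list with functions \code{survival_prob(t)} and
#'   \code{mean_fraction(t)} (vectorized in t), the scalar
#'   \code{fixation_prob}, and the generator matrix \code{Q}.
#' @examples
#' o <- exact_small_markov(drift_params(1, 4), labeled_site = 0)
#' o$fixation_prob          # 1/4: neutral fixation = initial fraction
#' o$survival_prob(1)       # exact P(clone not yet lost at 1 month)
#' @export
exact_small_markov <- function(params, labeled_site = 0,
                               topology = c("ring", "chain")) {
  stopifnot(inherits(params, "drift_params"))
  topology <- match.arg(topology)
  n <- params$n_sites
  if (n > 6) stop("state-space guard: exact oracle limited to n_sites <= 6")
  lam <- params$lambda_rate
  labeled_site <- as.integer(labeled_site)
  if (labeled_site < 0 || labeled_site >= n)
    stop("labeled_site must lie in 0..n_sites-1")

  ns <- 2^n
  configs <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  # row s+1 is the binary configuration of state id s, site 0 = last column
  state_id <- function(bits) sum(bits * 2^((n - 1):0)) + 1L

  neighbors <- function(i) { # 0-based site -> accessible 0-based neighbors
    if (topology == "ring") c((i - 1) %% n, (i + 1) %% n)
    else c(i - 1, i + 1)[c(i - 1 >= 0, i + 1 < n)]
  }

  Q <- matrix(0, ns, ns)
  for (s in seq_len(ns)) {
    bits <- configs[s, ]
    for (i in 0:(n - 1)) {
      nb <- neighbors(i)
      if (!length(nb)) next
      for (j in nb) {
        new <- bits
        new[n - i] <- bits[n - j] # site i adopts neighbor j's label
        s2 <- state_id(new)
        if (s2 != s) {
          rate <- lam / length(nb)
          Q[s, s2] <- Q[s, s2] + rate
        }
      }
    }
  }
  diag(Q) <- -rowSums(Q)

  k_of <- rowSums(configs)
  init <- integer(n); init[n - labeled_site] <- 1L
  s0 <- state_id(init)
  p0 <- numeric(ns); p0[s0] <- 1

  p_at <- function(t) {
    as.numeric(p0 %*% as.matrix(Matrix::expm(Matrix::Matrix(Q * t))))
  }
  survival_prob <- function(t)
    vapply(t, function(tt) 1 - p_at(tt)[1], numeric(1))
  mean_fraction <- function(t)
    vapply(t, function(tt) sum(p_at(tt) * k_of) / n, numeric(1))

  # absorption: states empty (id 1) and full (id ns); probability of hitting
  # full from s0 via the standard linear system on transient states
  transient <- setdiff(seq_len(ns), c(1L, ns))
  h <- numeric(ns); h[ns] <- 1
  if (length(transient)) {
    A <- Q[transient, transient, drop = FALSE]
    b <- -Q[transient, ns]
    h[transient] <- solve(A, b)
  }
  list(survival_prob = survival_prob, mean_fraction = mean_fraction,
       fixation_prob = h[s0], Q = Q)
}
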