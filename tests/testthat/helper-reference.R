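# Independent pure-R Gillespie reference for the punctuated drift rules.
# Deliberately written without reference to the package's C++ core so it can
# serve as a cross-check of the simulator (same model, different code path).
ref_pnd_final <- function(n, lambda, beta, mu, t_end, n_rep,
                          recov_beta = beta, recov_end = 0,
                          init = c("stationary", "none")) {
  init <- match.arg(init)
  out <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    bar <- rep(FALSE, n)
    if (init == "stationary" && mu > 0) {
      k <- stats::rpois(1, beta / mu)
      while (k > n) k <- stats::rpois(1, beta / mu)
      if (k > 0) for (i in seq_len(k)) {
        e <- place_barrier(n, which(bar) - 1L)
        bar[e + 1] <- TRUE
      }
    }
    lab <- rep(FALSE, n)
    lab[sample.int(n, 1)] <- TRUE
    t <- 0
    repeat {
      be <- if (t < recov_end) recov_beta else beta
      nl <- sum(lab)
      left_free <- !bar[((seq_len(n) - 2) %% n) + 1]
      right_free <- !bar[seq_len(n)]
      elig <- which(left_free | right_free)
      drift <- if (nl %in% c(0, n)) 0 else lambda * length(elig)
      tot <- drift + mu * sum(bar) + be
      if (tot == 0) break
      dt <- stats::rexp(1, tot)
      if (t < recov_end && t + dt > recov_end) { t <- recov_end; next }
      t <- t + dt
      if (t > t_end) break
      u <- stats::runif(1) * tot
      if (u < drift) {
        i <- if (length(elig) == 1) elig else sample(elig, 1)
        nbs <- c(if (left_free[i]) ((i - 2) %% n) + 1,
                 if (right_free[i]) (i %% n) + 1)
        j <- if (length(nbs) == 1) nbs else sample(nbs, 1)
        lab[i] <- lab[j]
      } else if (u < drift + mu * sum(bar)) {
        bs <- which(bar)
        bar[if (length(bs) == 1) bs else sample(bs, 1)] <- FALSE
      } else if (!all(bar)) {
        e <- place_barrier(n, which(bar) - 1L)
        bar[e + 1] <- TRUE
      }
    }
    out[r] <- sum(lab) / n
  }
  out
}
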