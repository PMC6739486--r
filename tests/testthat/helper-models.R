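# shared fixtures: the fitted model conditions used throughout the suite
pnd_drift <- function() drift_params_from_composite(0.3, 8)
default_barriers <- function() barrier_params()

surviving_stats <- function(tr, tt) {
  x <- tr$labeled_fraction[tr$time_months == tt]
  s <- x[x > 0]
  list(survival = mean(x > 0), mean_size = mean(s),
       pct_full = 100 * mean(s == 1), sizes = s, all = x)
}

# mean-size observation table from a trajectory table
curve_from_trajectories <- function(tr, times) {
  data.frame(
    time_months = times,
    mean_size = vapply(times, function(tt)
      surviving_stats(tr, tt)$mean_size, numeric(1)),
    n_clones = vapply(times, function(tt)
      sum(tr$time_months == tt & tr$surviving), numeric(1)))
}
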