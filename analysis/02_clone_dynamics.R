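#!/usr/bin/env Rscript
# Two-arm punctuated neutral drift simulation: lateral clone dynamics.
#
# Control glands start from the stationary barrier configuration; DMP-777
# glands start barrier-free (acute parietal-cell ablation) with the census
# recovering within two weeks. Both arms share the fitted composite drift
# rate lambda/N^2 = 0.3/month on an N = 8 ring. The script records clone
# survival, mean angular size of surviving clones, and the percentage of
# labeled glands reaching isthmus monoclonality, then writes per-arm
# trajectory tables and a summary keyed by (arm, time).

library(punctdrift)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 1L

drift <- drift_params_from_composite(0.3, 8)
bp <- barrier_params(birth_rate = 1.0, death_rate = 0.4,
                     recovery_birth_rate = 5.0, recovery_window = 0.5)
times <- c(0.5, 1, 3, 6, 12)
n_glands <- 2000L

rows <- list()
for (arm_name in c("control", "dmp777")) {
  tr <- simulate_pnd(drift, bp, perturbation_arm(arm_name), times, n_glands,
                     seed = seed + match(arm_name, c("control", "dmp777")))
  write.csv(tr, file.path(out_dir, paste0("trajectories_", arm_name, ".csv")),
            row.names = FALSE)
  for (tt in times) {
    x <- tr$labeled_fraction[tr$time_months == tt]
    s <- x[x > 0]
    rows[[length(rows) + 1]] <- data.frame(
      arm = arm_name, time_months = tt,
      survival = mean(x > 0), mean_size_surviving = mean(s),
      labeled_fraction = mean(x), pct_full = 100 * mean(s == 1))
  }
}
summary_df <- do.call(rbind, rows)
write.csv(summary_df, file.path(out_dir, "clone_dynamics_summary.csv"),
          row.names = FALSE)

print(summary_df, digits = 3)
c3 <- summary_df[summary_df$arm == "control" & summary_df$time_months == 3, ]
d3 <- summary_df[summary_df$arm == "dmp777" & summary_df$time_months == 3, ]
cat(sprintf("\nmonoclonal at 3 months: control %.0f%%, DMP-777 %.0f%%\n",
            c3$pct_full, d3$pct_full))
cat(sprintf("mean angular size at 3 months (control): %.0f%% of circumference\n",
            100 * c3$mean_size_surviving))
cat("labeled fraction (size x survival) is conserved near 1/8 at all times:\n")
print(aggregate(labeled_fraction ~ arm, summary_df,
                function(x) round(range(x), 3)))
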