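# punctdrift

Stochastic clonal dynamics of gastric corpus isthmus stem cells: the
orthodox neutral-drift model, a **punctuated neutral drift (PND)** model in
which lateral stem-cell replacement is blocked by long-lived parietal-cell
barriers, the clone/barrier quantification statistics, simulation-based
least-squares inference, in-silico perturbation arms, and a synthetic
lineage-tracing data generator.

## The problem and the models

Multicolor clonal-density lineage tracing in the mouse stomach corpus shows
isthmus stem-cell clones expanding rapidly *along* the gland but drifting
only slowly *around* its circumference toward monoclonality. Two models
frame this anisotropy:

* **Orthodox neutral drift.** A ring of $N$ equivalent stem cells; each
  cell is lost at rate $\lambda$ and replaced by symmetric division of a
  uniformly chosen nearest neighbor. The labeled fraction is a martingale,
  a single labeled cell fixes with probability $1/N$, and the fitted
  composite rate $\lambda/N^2$ sets the conversion timescale. Fitted to
  control clone sizes this gives $\lambda/N^2 \approx 0.03$/month — at
  $N = 8$ an implausible replacement interval of ~2 weeks per cell.
* **Punctuated neutral drift.** The same ring, but edges can carry
  parietal-cell barriers that block replacement. Drift is confined within
  barrier-delimited segments; barriers die at rate $\mu$ each (merging
  segments, releasing a burst of lateral expansion) and are born at
  gland-level rate $\beta$, placed at maximal angular spacing. The barrier
  census is an immigration–death process with stationary law
  Poisson($\beta/\mu$); defaults $\beta = 1.0$, $\mu = 0.4$/month give the
  observed 2–3 barriers per section. Within this model the drift rate is
  $\lambda/N^2 = 0.3$/month — ten-fold faster, comparable to the cell-cycle
  rate — and the slow orthodox estimate emerges as an artifact of fitting
  the wrong model.

The package also implements the DMP-777 arm (acute barrier ablation with
recovery), the Muc6-DTR arm (transient doubling of $\lambda$), the 3-point
angular clone scoring, vertical length/midpoint metrics, the minimum
angular distance statistic, a two-sample Kolmogorov–Smirnov test, and
parametric-bootstrap confidence intervals.

## Worked example

```r
library(punctdrift)

drift <- drift_params_from_composite(0.3, 8)   # lambda/N^2 = 0.3/month
bp    <- barrier_params(birth_rate = 1.0, death_rate = 0.4)

ctl <- simulate_pnd(drift, bp, perturbation_arm("control"),
                    record_times = c(0.5, 3), n_replicates = 2000, seed = 2)
s3 <- ctl$labeled_fraction[ctl$time_months == 3 & ctl$surviving]
mean(s3)           # 0.65  -- mean angular clone size at 3 months
100 * mean(s3 == 1) # 40   -- % of labeled glands monoclonal at 3 months

census <- stationary_barrier_distribution(bp, n_glands = 2000, seed = 4)
mean(census$counts)                    # 2.48 barriers per section
tune_barriers(census$counts)$beta_over_mu  # 2.49

obs <- data.frame(time_months = c(0.5, 3, 6, 12),
                  mean_size = c(0.41, 0.62, 0.81, 0.95))
fit_orthodox(obs, n_sites = 8, seed = 5)
#> <drift_fit> model = orthodox, RSS = 0.023479
#>   lambda_over_n2 = 0.04016
```

The last number is the package's central demonstration: the orthodox model
fitted to curves *generated by the punctuated model* at 0.3/month recovers
~0.03–0.04/month, an order of magnitude too slow.

The `analysis/` directory holds the full narrative pipeline as numbered
scripts (`01_barrier_census.R` … `06_reproduce_report.R`); each prints its
findings and writes tables under `results/`. `run_reproduce()` wires every
stage into a single JSON report.

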