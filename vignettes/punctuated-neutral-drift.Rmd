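---
title: "Punctuated neutral drift in the gastric corpus isthmus: models, inference, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Punctuated neutral drift: models, inference, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctdrift)
```

## The biological problem

Corpus glands of the mouse stomach are maintained by two long-lived stem
cell compartments: actively cycling isthmus stem cells (IsthSCs) in the
upper gland and largely quiescent base stem cells. Multicolor
clonal-density lineage tracing shows a striking anisotropy in IsthSC clone
behavior: clones expand *vertically* (along the gland axis) within weeks,
yet their *lateral* drift around the gland circumference toward
monoclonality takes many months. This package implements the two stochastic
models that frame that paradox, the measurement statistics used to quantify
clones and parietal cells, a simulation-based least-squares inference
procedure, and a synthetic-data generator, so the whole analysis is
reproducible from code alone.

## The orthodox neutral-drift model

The IsthSC compartment of one gland cross-section is a ring of $N$
functionally equivalent cells. Each cell is lost at rate $\lambda$ (per
month) and the vacancy is filled by symmetric division of one of its two
nearest neighbors, chosen uniformly. A single labeled cell therefore
performs neutral drift: the labeled fraction is a martingale, clones remain
cohesive arcs, and a clone either dies out or takes over the ring
(probability $1/N$). The only fitted quantity is the composite rate
$\lambda/N^2$, which sets the lateral conversion timescale.

`simulate_orthodox()` is an exact event-driven (Gillespie) implementation.
Event counts per gland are small (order $10^2$–$10^3$), so exact
exponential waiting times cost nothing over approximate fixed-step schemes.
For rings of up to six cells, `exact_small_markov()` builds the full
$2^N$-state generator and computes survival, mean size, and fixation by
matrix exponentiation (via `Matrix::expm`); it is the brute-force oracle
against which the simulator is tested. The state-space guard at $N \le 6$
keeps the dense $2^N \times 2^N$ generator trivially small.

One non-obvious property the oracle exposed: on an *open chain* (a
barrier-delimited segment), fixation probability is position-dependent —
$1/6$ for a cell adjacent to a barrier versus $1/3$ for an interior cell of
a 4-site segment — because the labeled-count martingale breaks at the chain
ends. Only the average over a uniformly placed label recovers the $1/N$
rule. Tests assert the position-resolved values, not just the average.

## The punctuated neutral drift (PND) model

Parietal cells form long-lived vertical walls between cycling cells. The
model places these barriers on *edges* of the ring (they do not consume
stem-cell sites, keeping $N$ fixed while the gland separately hosts its
2–3 parietal cells per section). Rules:

* drift events are confined within barrier-delimited segments: the
  replacing neighbor must be reachable without crossing a barrier, and a
  cell walled in on both sides hosts no drift event;
* each standing barrier dies independently at rate $\mu$ (mean lifetime
  $1/\mu$), merging its two segments — a window for a burst of lateral
  clone expansion;
* new barriers are born at gland-level rate $\beta$ and placed on the free
  edge maximizing the minimum circular distance to standing barriers (ties
  uniform; uniform over all edges when none stand), reflecting the observed
  preference of parietal cells for maximal angular spacing.

The barrier count is then an immigration–death process, independent of the
label state, with stationary law Poisson($\beta/\mu$) — the placement rule
shapes *positions*, never counts. This gives the two-stage identifiability
used in fitting: counts constrain $\beta/\mu$ only (both the count law and
the placement law are invariant under time rescaling), while clone-size
time courses constrain $(\lambda/N^2, \mu)$.

### Default parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| $\lambda/N^2$ | 0.3 | /month | fitted composite drift rate of the barrier model |
| $N$ | 8 | cells | dividing cells per circumferential section |
| $\beta$ | 1.0 | /month/gland | with $\mu$, stationary count 2.5 ("2 or 3" per section) |
| $\mu$ | 0.4 | /month/barrier | barrier lifetime 2.5 months, consistent with the ~54-day parietal-cell lifespan scale |
| recovery $\beta$ | 5.0 | /month | census refills within ~2 weeks after ablation |
| recovery window | 0.5 | months | duration of elevated barrier birth |

The barrier birth law is a genuine modeling choice: a gland-level Poisson
process is the simplest mechanism whose stationary count is tunable to the
observed 2–3 range. A gap-dependent birth rate would change the count law;
we revisit the consequences under *Limitations*.

### Perturbation arms

* **control** — barriers initialized from the stationary configuration
  (count drawn from Poisson($\beta/\mu$), positions laid down sequentially
  by maximal spacing); label placed uniformly.
* **dmp777** — acute parietal-cell ablation: all barriers deleted at
  $t = 0$, recovery window active. Only the *initial condition* differs
  from control; all rates are shared.
* **muc6_dtr** — injury response of IsthSCs: $\lambda \times 2$ between
  0.25 and 1.0 months (toxin one week after induction, examined at one
  month); barriers untouched.
* **lambda_scale / lifespan_scale** — generic $\lambda$- or $\mu$-scaling
  used for perturbation-discrimination experiments.

### Vertical expansion

The vertical model is a deliberate reconstruction (the lateral model does
not constrain it): the gland axis is split into pit/isthmus/neck/base
height fractions (0.3/0.2/0.3/0.2), a clone nucleates spanning the
isthmus, and its upper and lower fronts advance as Poisson processes at
rates `up_rate * lambda` and `down_rate * lambda` (0.1 front advances per
division each), each advance covering one cell height (1/20 of the gland, a
realistic gland height in cell diameters). Fronts saturate at the pit top
and the neck/base boundary, so relative length saturates at 0.8 — the
observed long-term size of isthmus-spanning clones (0.80 ± 0.20). Because
this sub-model is a stand-in, only its *directional* predictions are
treated as testable (division-rate scaling accelerates vertical expansion;
barrier perturbations leave it untouched), never its curve shapes.

## Measurement statistics

Clones are scored exactly as annotated images are: three points per optical
section (clone boundary, gland center, clone boundary) define the clockwise
angle at the center — *clockwise in image coordinates* (y down), so
annotations from math-convention tools must be flipped. Up to three isthmus
sections are reduced by their mean (the maximum is available as an option;
the central-section alternative is a one-line change and makes no
difference on cohesive simulated clones). Glands at or above the `0.95`
threshold count as fully labeled — measurement jitter makes exact 1.0
unattainable on real annotations — while noise-free simulated states use
1.0. Survival denominators are cross-sectional per time point, matching the
sacrifice-per-time-point experimental design; nothing is tracked
longitudinally.

The two-sample Kolmogorov–Smirnov test is implemented directly (supremum
ECDF distance; asymptotic Kolmogorov p-value at effective
$n = n_x n_y/(n_x+n_y)$) because the analysis depends on it; `stats::ks.test`
serves as an independent cross-check in the test suite, not as the
implementation. Sample sizes in the analyses are ≥ 27, where the asymptotic
p is adequate; exact small-sample enumeration is deliberately out of scope.

## Inference

Fitting is simulation-based least squares on mean surviving clone sizes.

* **Orthodox:** all rates are proportional to $\lambda$, so changing the
  rate is an exact time rescaling. `fit_orthodox()` therefore simulates
  *one* unit-rate reference curve (2,000 glands on a dense log-spaced time
  grid) and evaluates every candidate by rescaling — a deterministic,
  smooth objective at the cost of a single simulation, refined by
  `optimize()` inside the best grid bracket. Hits on the grid edge are
  flagged as non-converged.
* **PND:** joint least squares over the control and DMP-777 arms (shared
  parameters, different initial conditions), $\beta/\mu$ fixed in advance
  from count data by chi-square distance to the Poisson law. A 7×7
  log-spaced grid over $(\lambda/N^2, \mu)$ with one local refinement pass;
  a fixed seed per evaluation gives common random numbers that damp the
  Monte-Carlo roughness the grid must tolerate.
* **Uncertainty:** parametric bootstrap — regenerate observation-sized
  cohorts at the point estimate, refit, take 2.5/97.5 percentiles. This
  matches the simulation-based estimator without asymptotic assumptions;
  intervals include the estimator's own Monte-Carlo noise, which sets a
  floor below which larger cohorts cannot shrink them.

Parameter-recovery experiments (20 synthetic experiments each) validate the
procedure: recovered $\lambda/N^2$ and $\mu$ are unbiased within 25% at
paper-scale cohort sizes, bootstrap 95% intervals cover the truth in at
least 85% of runs (the shortfall from 95% reflects the modest 60 bootstrap
replicates), and the two-stage $\beta/\mu$ recovery lands within
[2.2, 2.8] of the generating 2.5.

The emergent cross-fit is the model's central qualitative claim: fitting
the *orthodox* model to control-arm curves *generated by the PND model* at
$\lambda/N^2 = 0.3$/month recovers a composite rate near 0.03–0.04/month —
an order of magnitude below the generative rate, reproducing the paradox
that a slow apparent drift rate (implying implausible ~2-week replacement
intervals at $N = 8$) can mask fast within-segment dynamics gated by
barriers.

## The synthetic-data generator

`generate_clone_cohort()` emulates the published cohort structure:
cross-sectional time points at {0.5, 1, 3, 6, 12, 18} months with 40, 100,
132, 103, 90, 100 scored clones (counts at 1 and 18 months are not
published; 100 is used and exposed in the design). Each surviving simulated
clone becomes a 3-point annotation in three isthmus sections with Gaussian
jitter (SD 5°) on boundary bearings — small relative to the 45° site
resolution at $N = 8$, and clipped so fractions stay inside (0, 1) — plus
one of four reporter colors and vertical metrics from the vertical model.
Fully labeled glands are flagged `is_full` rather than annotated with
coincident points. With zero noise, scoring a generated cohort reproduces
the simulator's ground truth exactly (a round-trip identity the tests
assert); at the default jitter, cohort means move by less than 0.02.

What the generator does **not** emulate: the early (< 2 weeks) transient
clones from labeled non-stem cells (generated cohorts are stem-anchored, so
comparisons to observed data start at the 2-week time point); dynamic base
proliferation (base clones appear only as the static 0.30 ± 0.10 geometry
cluster); and any image-level artifact beyond bearing jitter. Passing tests
therefore show pipeline correctness on idealized clones, not robustness to
segmentation error or annotation bias.

## Numerical choices

* All randomness flows through R's RNG; every simulating function takes a
  seed, and identical seeds give bit-identical outputs. A single stream
  seeded once per call (replicates run sequentially inside the C++ core)
  preserves that reproducibility without per-replicate stream bookkeeping.
* The Gillespie core carries the residual exponential deviate across record
  times and piecewise-rate boundaries (exact by memorylessness), so RNG
  consumption does not depend on where the process is observed.
* Time-varying rates (recovery window, injury window) are handled as
  piecewise-constant segments with event times capped at segment
  boundaries — exact, no thinning.
* Absorbed label states (empty or full ring) skip drift events; barrier
  dynamics continue so census readouts stay correct.
* Ties in barrier placement break uniformly via the simulation RNG; no
  global state.
* Degenerate inputs fail loudly: coincident annotation points, zero-length
  clones, empty samples, all-zero count histograms, unsorted record times,
  and $\mu = 0$ census requests are validation errors, not NaNs.

Problem sizes used in the shipped analyses and tests — 1,000–2,000 glands
per arm, 2,000-gland reference curves, 60 bootstrap replicates, 20-run
recovery experiments — were chosen so every statistic's Monte-Carlo error
is well inside the tolerance it is compared at.

## Limitations

* **Monoclonal conversion runs fast at the default barrier law.** With
  gland-level Poisson births, the stationary census puts ~29% of
  cross-sections at ≤ 1 barrier, and a ring with at most one barrier is a
  single unobstructed segment that converts at the fast within-segment
  rate. The simulated monoclonal share among labeled glands at 3 months
  (roughly 35–40% control, 55–60% after ablation in the shipped analyses)
  accordingly overshoots the observed 23% and 47%, and the 6-month control
  share exceeds one half. The observed per-section count histogram has
  little mass at 0–1, pointing to a birth law with fewer barrier-free
  excursions (e.g. gap-dependent birth) as the likely refinement; the
  count *mean*, the spacing signature, the conservation laws, the
  perturbation discrimination, and the order-of-magnitude cross-fit are
  all insensitive to this choice and reproduce as expected.
* The vertical model is a reconstruction; treat its rate constants as
  shape parameters, not measurements.
* Base-compartment dynamics, polyclonal induction, and 2D/3D gland
  geometry are out of scope by design.
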