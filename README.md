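# dgspace

Spatial-information analysis for dentate gyrus (DG) calcium imaging on a
circular treadmill belt, with a ground-truth synthetic-session generator.

Head-fixed mice walk on a 180 cm belt of four textures while granule-cell
activity is imaged at 15 frames/s; a rotary encoder plus RFID tags at the
texture boundaries report position. The scientific questions the pipeline
answers: how place-specific is each cell's activity, how much spatial
information does the population carry, and how do those quantities change
between experimental groups (e.g. manipulations that scale the response
gain of DG neurons)?

## What it computes

* **Session assembly** — position reconstruction from encoder + RFID
  telemetry (drift-corrected), dF/F from raw fluorescence (rolling
  10th-percentile baseline, optional neuropil coefficient), spatial binning,
  lossless session containers.
* **Significant transients** — zero-phase Butterworth filtering, the
  iterative 2σ / 0.5σ rolling-baseline rule, and distance-normalized
  activity (dF/F·s per cm).
* **Tuning** — AR(1) sparse deconvolution, occupancy-normalized circular
  tuning vectors over 100 bins, and the tuning index
  `|Σ_b w_b e^{iθ_b} / Σ_b w_b|` in [0, 1].
* **Tuning-curve model** — von Mises fits `B + A·e^{k(cos(θ−φ)−1)}` with
  bounded multi-start least squares, cross-validated
  `R² = 1 − ss_res/ss_tot` (75/25 within-bin splits, clipped to [0, 1],
  well-fitted ⇔ R² > 0.5), and peak width as circular variance
  `V = 1 − I₁(k)/I₀(k)`.
* **Information** — ridge multinomial decoding of 20 position bins from
  per-frame dF/F (chance 5 %), population and single-cell linear Fisher
  information as bias-corrected d′² on adjacent-bin pairs
  (`d′²·(2T−N−3)/(2T−2) − 2N/T`, unbiased for Gaussian responses),
  trial-shuffled surrogates that destroy noise correlations while preserving
  tuning exactly, and the 70 %-correct discrimination threshold
  `δ* = 2·Φ⁻¹(0.70)/√J`.
* **Group statistics** — a nested (cells-within-animals) two-level
  bootstrap with Bonferroni correction, and the behavioral discrimination
  index `(a − b)/(a + b)`.
* **Synthetic sessions** — Poisson events from gain-modulated von Mises
  rates, a shared log-normal gain source that induces realistic noise
  correlations, exponential calcium kernels, and full ground truth for
  recovery tests.

## Worked example

```r
library(dgspace)

cfg <- synthetic_config(n_neurons = 60, n_laps = 21, seed = 42)
sim <- simulate_session(cfg)          # session + ground truth
rpt <- run_analyze(sim$session,
                   params = list(n_splits = 5, subsample_draws = 3),
                   seed = 1)
print(rpt)
```

```
<dg_report> 60 neurons, 21 laps
  median activity      0.008424 dF/F.s/cm
  mean tuning index    0.245
  well-fitted fraction 0.08 (mean R2 0.14)
  decoder accuracy     47.8%
  discrim. threshold   4.74 cm
```

Reading the numbers: the median cell deposits ~0.008 dF/F·s of significant
calcium transients per cm traveled; the mean resultant of the
occupancy-normalized tuning curves is 0.245 (0 = untuned, 1 = all activity
in one bin); 8 % of cells pass the cross-validated R² > 0.5 von Mises
criterion at 21 laps; a 42-neuron subsample decodes the 20 position bins at
47.8 % correct against a 5 % chance level; and the population's Fisher
information supports discriminating belt positions ~4.7 cm apart at 70 %
correct. Per-neuron values live in `rpt$neurons`
(activity, tuning_index, B, A, k, phi_deg, V, r2_cv, well_fitted,
fisher_d2).

Group contrasts follow the same pattern:

```r
manifest <- run_simulate(c(control = 1, boosted = 2), n_animals = 4,
                         out_dir = "sim", config = cfg)
reports <- lapply(manifest$path, run_analyze, seed = 1, decode = FALSE)
run_compare(reports, n_boot = 10000, seed = 1)   # nested bootstrap + Bonferroni
```

A thin command-line wrapper with `simulate` / `analyze` / `compare`
subcommands is installed at `inst/cli/dgspace.R`.

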