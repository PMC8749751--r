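# bandgrowth

Age and growth inference for elasmobranchs from vertebral band counts.

Age-and-growth studies of skates and rays count the opaque/translucent band
pairs deposited in vertebral centra, validate that one pair forms per year,
convert counts into ages, back-calculate lengths at earlier ages from band
radii, and fit growth curves whose parameters (asymptotic length
*L*<sub>∞</sub>, growth coefficient *k*) feed demographic and fisheries
models. `bandgrowth` implements that entire desk workflow for specimen-level
data, with the reference system being a giant electric ray population from
the southern Gulf of California (bands completing each April, births pulsed
in August, females to 84 cm TL).

The package provides:

* **Reading precision** — percent agreement (exact/±1/±2 bands),
  Beamish–Fournier average percent error, Chang's coefficient of variation,
  age-bias tables, Bowker's test of symmetry.
* **Band periodicity** — marginal increment ratio
  MIR = (VR − R<sub>n</sub>)/(R<sub>n</sub> − R<sub>n−1</sub>), centrum edge
  analysis, Kruskal–Wallis with Dunn's post hoc, two-sample
  Kolmogorov–Smirnov.
* **Age adjustment** — unadjusted counts; adjustment to the reproductive
  cycle (first band 7/12 yr after birth); adjustment to the date of capture
  (months elapsed since the last April band).
* **Back-calculation** — radius-on-length regression with slope/elevation
  comparison between sexes, and the Francis proportion-based formula
  L<sub>i</sub> = −a/b + (L<sub>c</sub> + a/b)·VR<sub>i</sub>/VR<sub>c</sub>.
* **Growth fitting** — von Bertalanffy (3- and 2-parameter), Gompertz and
  logistic curves under a multiplicative lognormal error with the error
  scale σ concentrated analytically:
  −log L = (n/2)·log 2π + n·log σ̂ + n/2.
* **Uncertainty and selection** — profile-likelihood CIs (χ² cutoff 3.84),
  (L<sub>∞</sub>, k) likelihood-contour regions (cutoff 5.99), AIC, ΔAIC and
  Akaike weights.
* **Synthetic data** — a generator stating the same seasonal and error
  structure, so the whole pipeline is testable without raw data.

## Worked example

```r
library(bandgrowth)

pop <- generate_population(synthetic_config(), seed = 42)   # 245 fish
rc  <- generate_reader_counts(pop$specimens, seed = 43)
unlist(precision_report(rc))
#>    pa_exact pa_within_1 pa_within_2         ape          cv  n_compared
#>   68.571429   92.653061  100.000000    8.373735   11.842250  245.000000

reg <- fit_radius_length(pop$specimens)$female
dat <- expand_dataset(pop$specimens, age_scheme("adjusted_dc"), reg)
fits <- lapply(c("VBG3", "VBG2", "GG3", "LG3"),
               function(m) fit_model(m, dat$assigned_age, dat$length, seed = 1))
aic_table(fits)
#>  model p loglik   aic  aicc  delta     weight     support
#>   VBG3 3   2760 -5514 -5514    0.0  1.000e+00 substantial
#>    GG3 3   2562 -5117 -5117  397.2  5.575e-87        none
#>    LG3 3   2243 -4480 -4480 1034.5 2.254e-225        none
#>   VBG2 2   1665 -3327 -3327 2187.4  0.000e+00        none

best <- fits[[1]]
best
#> VBG3 fit: n = 1383, logL = 2760.13, sigma = 0.0329
#>   L_inf = 80.656 cm, k = 0.1689 /yr, t0 = -1.3915 yr
profile_ci(best, "t0")[c("lower", "upper")]      # (-1.411, -1.373)
contour_ci(best, n_grid = 61)[c("linf_ci", "k_ci")]
#> $linf_ci [1] 79.51 81.90    $k_ci [1] 0.164 0.174
```

Reading the output: paired readers agree exactly on 68.6% of fish and
within one band on 92.7% (the generator targets 69/95%); the 245 fish
expand to 1383 observed + back-calculated records; the generating model
family (VBG3) wins the AIC comparison with all the weight, and its
estimates bracket the generator truth: L<sub>∞</sub> = 81.87 cm falls
(just) inside the contour CI 79.5–81.9, k = 0.168 inside 0.164–0.174 and
t0 = −1.384 inside the profile CI −1.411 to −1.373 — the coverage expected
of a single stochastic replicate.

The full pipeline — precision, periodicity, three age schemes × four
models, CIs and a consolidated comparison table — runs as

```r
run_pipeline(run_config(out_dir = "run1", seed = 1))
```

or from the shell via `Rscript inst/cli/bandgrowth.R run-all --out run1
--seed 1` (verbs: `simulate`, `precision`, `periodicity`, `backcalc`,
`fit`, `compare`, `run-all`).

## Packaged reference tables

`load_fixture("table1" … "table4")` return the published monthly sample
sizes (summing to 245), the observed (245) and combined (1893) age–length
distributions in 2-cm bins, and the reference growth-parameter table whose
log-likelihood/AIC columns satisfy AIC = 2p − 2·logL; margins are asserted
on every load.

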