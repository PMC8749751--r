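---
title: "Methods: vertebral-band ageing and multimodel growth inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertebral-band ageing and multimodel growth inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandgrowth)
```

# Scope

`bandgrowth` implements the complete desk side of a hard-structure
age-and-growth study for an exploited batoid: reading-precision statistics,
band-periodicity diagnostics, age adjustment, back-calculation, growth-model
fitting under a multiplicative error, likelihood-based intervals and AIC
model selection. Laboratory steps (sectioning, staining, image measurement)
are out of scope; the package starts from specimen-level measurements.

The reference system is a giant electric ray population from the southern
Gulf of California: females to 84 cm total length (TL), one band pair
deposited in the vertebral centra each April, births pulsed in August,
fourteen age groups, and 245 readable specimens expanded to 1893
observed-plus-back-calculated age–length records. The packaged fixture
tables (`load_fixture()`) carry the published summaries of that population;
the synthetic generator re-creates its statistical structure so every stage
is testable without raw data, which were never deposited.

# The likelihood

Observed lengths are modelled with multiplicative lognormal error around a
growth curve $L(t;\theta)$:

$$\log L_{obs,i} \sim N(\log L(t_i;\theta),\ \sigma^2).$$

For fixed $\theta$ the maximising error scale has the closed form
$\hat\sigma = \sqrt{\tfrac1n\sum_i(\log L_{obs,i}-\log L(t_i;\theta))^2}$
(`sigma_analytic()`), and substituting it back concentrates the negative
log-likelihood to

$$-\log\mathcal{L}(\theta) = \frac n2\log 2\pi + n\log\hat\sigma(\theta) + \frac n2,$$

which is what `fit_model()` minimises over $\theta$ alone. Two published
conventions are worth stating because the source presentation garbles them
typographically: the likelihood here is the standard lognormal form (without
the Jacobian term $\sum\log L_{obs}$, so reported log-likelihoods are
comparable with the reference table, whose AIC column satisfies
$AIC = 2p - 2\log\mathcal{L}$ exactly for all twelve rows), and $\sigma$ is
the root-mean-square log-residual, i.e. the printed analytic solution with
the square root restored. The parameter count $p$ covers growth parameters
only (2 or 3), not $\sigma$ — forced by the same AIC identity.

## Candidate models

| model | form | free parameters |
|-------|------|-----------------|
| VBG3 | $L_\infty(1-e^{-k(t-t_0)})$ | $L_\infty, k, t_0$ |
| VBG2 | $L_\infty-(L_\infty-L_0)e^{-kt}$ | $L_\infty, k$ ($L_0$ fixed at 14.5 cm) |
| GG3  | $L_\infty e^{-e^{-k(t-t_0)}}$ | $L_\infty, k, t_0$ (inflection $t_0$) |
| LG3  | $L_\infty/(1+e^{-k(t-t_0)})$ | $L_\infty, k, t_0$ (inflection $t_0$) |

The VBG2 anchor of 14.5 cm is the largest near-term embryo length known for
the species and is a constant of the analysis, not a fitted quantity.

## Optimisation

The published analysis used a spreadsheet generalized-reduced-gradient
solver; any competent local optimiser reaches the same optimum on this
smooth 2–3 parameter surface. `fit_model()` runs Nelder–Mead from eight
deterministic starts — four data heuristics ($L_{\infty,0} = 1.05\times$ max
length, $k_0\in\{0.1,0.3\}$, $t_{0,0}\in\{-2,0\}$) plus seeded jitters —
keeps the best optimum and polishes it with a second pass. $L_\infty$ and
$k$ are optimised on the log scale to enforce positivity without
constraints. Fits are deterministic given the data and `seed`. A perfect
(noise-free) fit drives $\hat\sigma\to 0$ and the objective to $-\infty$;
the internal objective floors $\hat\sigma^2$ at `1e-300` so the optimiser
remains finite, while the user-facing `negative_log_likelihood()` treats a
zero residual vector as a degenerate-likelihood error.

# Age assignment

Band counts exclude the birth band (the first translucent mark, laid down
at parturition); `band_radii` vectors include it as their first entry. Three
schemes convert a count $n$ to decimal age:

* **unadjusted** — $a = n$: every post-birth band is one completed year.
* **adjusted to the reproductive cycle** — $a = 7/12 + (n-1)$: births peak
  in August and the first band forms the following April, seven months
  later. The offset is stored as exact $7/12$, not the display value 0.58,
  so likelihoods are not quantised by a two-decimal constant. The minor
  January birth pulse is deliberately ignored, as in the source analysis.
* **adjusted to date of capture** — adds $\Delta m/12$ with
  $\Delta m = (\text{capture month} - 4) \bmod 12$: time elapsed since the
  last April band. The modular arithmetic handles January–March captures
  (9–11 elapsed months), a wrap-around the source leaves implicit.

Whether unadjusted ages equal $n$ or $n-1$ is not stated explicitly in the
source; $a=n$ is adopted because it makes the unadjusted and
reproductive-cycle schemes differ by exactly the stated five-month shift.
Ages enter likelihoods as decimals; down-rounding (`age_group()`) is for
tabulation only.

# Back-calculation

The radius–length relation is fitted as ordinary least squares of vertebral
radius on total length, $VR = a + b\,TL$. The source prints the transposed
equation ("TL = 0.08 VR − 0.65"), which is dimensionally impossible (5 mm
of radius would map to 0.4 cm of fish); the Francis proportion-based
back-calculation it quotes,

$$L_i = -\frac ab + \left(L_c + \frac ab\right)\frac{VR_i}{VR_c},$$

only makes sense with $a,b$ from the radius-on-length orientation. This is
the single most consequential interpretation in the package and all code
and documentation follow it. The formula is exact at capture
($VR_i = VR_c \Rightarrow L_i = L_c$) and its $VR_i\to0$ limit is $-a/b$,
the length at which the regression line predicts a vanishing centrum.

`expand_dataset()` emits one back-calculated record per band — the birth
band back-calculates to an age-0 length — plus the observed capture record,
$\sum(\text{bands}+1)+n$ records in total, and restricts to females by
default (males are too scarce to fit, as in the source). A switch allows
back-calculated-only fitting for sensitivity analysis.

# Intervals and model selection

$t_0$ gets a true profile-likelihood interval: nuisance parameters are
re-optimised at every profile point (the source's claim that $t_0$ is
uncorrelated with the others is not assumed), and the 95% bound is the
deviance crossing of 3.84 ($\chi^2_{1,0.95}$), bisected to $10^{-4}$.
$(L_\infty,k)$, which are strongly correlated, get a joint likelihood
contour: deviance on a grid (default $201\times201$ over MLE $\pm6$
approximate standard errors; the pipeline default is coarser for speed)
with $t_0$ re-optimised per cell, thresholded at 5.99 ($\chi^2_{2,0.95}$).
Marginal CIs are the region's bounding box per parameter, matching how the
reference table's parenthetical CIs behave. A region touching the grid
boundary triggers an expand-grid warning.

Model comparison uses plain AIC, $\Delta_i$, and Akaike weights
$w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$. The source mentions AICc
once but every tabulated value satisfies the uncorrected identity, so AIC
is primary and AICc is provided as an auxiliary column only. Support
labels: $\Delta\le2$ substantial, $4\le\Delta\le7$ considerably less,
$\Delta>10$ essentially none, with the gaps labelled intermediate.

# Precision statistics

Percent agreement (exact, ±1, ±2 bands), the Beamish–Fournier average
percent error, and Chang's coefficient of variation with the sample
standard deviation (divisor $R-1$; the source only cites the method). For
two readings per fish $CV = \sqrt2\,APE$ identically, which the tests
assert to $10^{-9}$. Bowker's symmetry statistic sums
$(n_{ij}-n_{ji})^2/(n_{ij}+n_{ji})$ over informative pairs only
($n_{ij}+n_{ji}>0$), with df equal to their number — the standard
convention; the source's df of 9 is not reconstructible without raw counts.
Its printed p-value (0.89 for $X^2=14.5$, df 9) is the *lower* tail of the
reference distribution; this package reports the standard upper-tail p
(≈0.11 for those values) and does not reproduce the printed number.

# The synthetic world

`generate_population()` states one fixed world, chosen once:

* truth curve VBG3 with $L_\infty=81.87$ cm, $k=0.168\,/$yr, $t_0=-1.384$ —
  the reference fit for the capture-date-adjusted data;
* age-group frequencies from the combined age–length fixture marginal and
  capture months from the monthly sampling fixture, so simulated size and
  effort structure match the study;
* length error lognormal with $\sigma=0.06$. The source reports no
  $\sigma$; 0.06 makes simulated scatter visually comparable to the
  published length-at-age spread and is a config default, not a claim
  (the likelihood concentrated at the reference table implies ≈0.04 on the
  expanded data);
* radii on $VR=-0.65+0.08\,TL$ with 0.05 mm Gaussian noise on the edge
  radius; band radii noise-free on the same line, so back-calculation is
  exact under the generator and parameter-recovery tests are clean — the
  generator and likelihood are deliberately conjugate;
* reader 2 deviates from reader 1 (the truth) by 0/±1/±2 bands with
  probabilities 0.69/0.26/0.05, reproducing the published agreement rates
  of 69/95/100%.

What the generator does **not** emulate: sexual dimorphism in growth (both
sexes share the truth curve), gear selectivity, mortality or sampling
covariance between age and month beyond the stated structure, measurement
error on band radii (off by default), or the minor January birth pulse.
A green recovery test therefore establishes correctness of the estimation
machinery under the model's own assumptions, not robustness to their
violation.

Two deliberate conventions deserve a note:

* *Edge phase.* A translucent band completes in April; opaque material
  deposits next. The generator therefore makes the translucent-edge
  probability and the expected marginal increment ratio both *rise* with
  months since formation, so the monthly edge and MIR series cycle in phase
  and months of lowest MIR are richest in fresh/opaque edges. Under the
  capture-month convention (April = 0 elapsed months) the in-population
  maxima fall in March; the published account reads both maxima in April,
  i.e. just before completion — the same cycle read one month earlier. The
  standalone `generate_seasonal_mir()` uses that pre-completion convention
  (April maximal, reset in May).
* *Reader symmetry and Bowker.* With reader 1 anchored at the truth, the
  paired cross-table is exactly symmetric only if the true-count marginal
  is exchangeable across levels; a skewed age distribution gives Bowker's
  test genuine power even under symmetric reading error (and the support
  boundary adds more). The near-null calibration property is therefore
  tested on the exchangeable two-reader process (both readers drawing iid
  symmetric errors), where it holds for any age distribution. Reader-2
  counts are clamped at zero; for the generated populations (truth counts
  ≥ 1) this only affects −2 deviations on one-band fish and is negligible
  at the tested tolerances.

# Numerical choices and degenerate inputs

* Profile bisection tolerance $10^{-4}$; contour `optimize()` tolerance
  $10^{-6}$; optimiser relative tolerance $10^{-12}$ with up to 2000
  Nelder–Mead iterations per start.
* A fish whose repeated counts average zero has undefined APE/CV and is
  excluded with a warning; a cross-table with no informative off-diagonal
  pair yields an undefined Bowker test flagged with p = 1.
* An all-tied Kruskal–Wallis sample (tie correction 0/0) is reported as
  H = 0, p = 1 by convention.
* MIR requires two post-birth bands; birth-band-only fish are excluded, and
  a zero-width previous band pair is an error, not an infinity.
* The two-sample KS test uses the asymptotic p-value throughout so results
  are comparable across sample sizes and under ties.
* Dunn's post hoc uses a Bonferroni adjustment by default (the source cites
  only an unnamed nonparametric multiple-comparison test); any
  `p.adjust` method can be substituted.
* Synthetic vertebral radii are clamped from below at the last band radius
  so no generated fish violates the edge invariant; with default noise the
  clamp binds rarely and only for April captures.

# Known limitations

* The combined fixture's 1893 records cannot be decomposed into observed
  vs back-calculated rows from the published summaries alone, and
  $\sum(\text{bands}+1)+n$ computed from the observed table's marginals
  does not reconcile exactly with 1893 under any single counting
  convention; the fixture serves as a distribution and totals reference,
  not a row-level provenance record.
* Published point estimates on the real data (APE 3.3%, CV 4.7%, H = 16.7,
  D = 0.84, the regression $r^2$ values) are not reproducible without the
  undeposited raw measurements and are not claimed; the package covers them
  with property-based and generator-calibrated tests instead.
* One published length-at-birth check (unadjusted VBG3, printed 23.01 cm)
  computes to 22.957 cm from the printed parameters — outside the nominal
  ±0.05 cm band by 0.003 cm because the print-rounding of $k$ alone
  propagates ±0.059 cm. The corresponding acceptance check is left failing
  rather than loosened.
* Seasonal (oscillating) growth, Bayesian fitting, bootstrap intervals and
  alternative back-calculation families are out of scope.
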