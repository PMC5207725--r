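---
title: "Substrate-depletion kinetics and intrinsic clearance in liver spheroid assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrate-depletion kinetics and intrinsic clearance in liver spheroid assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroclear)
```

## The assay and its model

A substrate-depletion assay measures how fast the parent compound
disappears from the incubation medium of hepatocyte cultures. In the
plate design this package targets, each 96-well plate row holds 6
exposure wells (spheroids + medium + compound), 3 solvent-control wells
(spheroids + medium + solvent) and 3 medium-control wells (compound, no
spheroids); each row is quenched with acetonitrile at one time point (by
default 0, 0.5, 1, 2, 4 and 24 h, extended to 48–72 h for slowly
metabolised compounds). Each fish contributes one independent spheroid
batch, so the fish is the biological replicate.

Depletion is modelled as first order,

$$C(t) = a\,e^{-k t},$$

with `a` the time-zero concentration (µg/L) and `k` the depletion rate
constant (h⁻¹). The half-life is $t_{1/2} = \ln 2 / k$ and the expected
fractional loss over an incubation of length $T$ is $1 - e^{-kT}$: a
cohort-mean rate of 0.022 h⁻¹ over 24 h corresponds to a 41% loss of
parent compound. First-order behaviour is an assumption, not a finding:
real depletion curves can flatten when the compound partitions into cells
or plastic, or steepen with enzyme induction. The package fits the
two-parameter decay regardless and exposes the residual sum of squares as
its only goodness-of-fit diagnostic; no curvature criterion is enforced.

## What the simulator emulates — and what it does not

`simulation_config()` + `simulate_cohort()` generate complete plate
experiments with the statistical structure of the real assay:

* **Between-fish variability.** Each fish's true `k` is drawn from a
  lognormal distribution moment-matched to `k_mean_h` (default
  0.022 h⁻¹) and `k_sd_h` (default 0.010 h⁻¹). The lognormal is a
  modelling choice: only a mean ± SD is available for the biological
  spread, and a lognormal guarantees positive rates while reproducing
  both moments exactly. The defaults reproduce the propranolol-like
  reference cohort; they are the study conditions, not tuning knobs.
* **Dosing error.** The true time-zero concentration is Normal with mean
  98 µg/L and SD 4 µg/L against a 100 µg/L nominal dose, matching the
  measured time-zero spread of the reference assay.
* **Measurement noise.** Multiplicative lognormal with unit mean and CV
  `measurement_cv` (default 10%): LC-MS/MS quantification error scales
  with signal, and multiplicative noise keeps concentrations positive by
  construction, so no truncation rule is needed.
* **Controls.** Medium controls decay at `abiotic_loss_rate_h` (default 0
  for sealed plates) under the same noise; solvent controls carry
  concentration 0 and are ignored by fitting — they exist so that real
  plate exports with the full layout parse identically.
* **Reproducibility.** One root seed; each fish consumes a sub-stream
  seeded by a stable hash of `(seed, fish_id)`, so fish 2 of a 3-fish
  cohort is byte-identical to fish 2 of a 300-fish cohort. The quench is
  modelled as sampling termination, not dilution: simulated values are
  pre-quench medium concentrations.

Not emulated: metabolite formation, spheroid size/viability variation,
oxygen gradients, well-position (edge) effects, and any departure from
first-order kinetics. Passing parameter-recovery tests therefore shows
that the fitting chain is correct under the assay's nominal statistical
model — not that real depletion data are this well behaved.

## Fitting choices

`fit_depletion()` fits all individual exposure wells, not per-time-point
means: with equal replication the least-squares estimate is the same, but
well-level fitting keeps the replicate information for standard errors.
Initialisation is `a₀ =` time-zero mean and `k₀ = max(10⁻⁶, −slope)` of
the log-linear regression of ln(mean concentration) on time, with a fixed
fallback `k₀ = 0.01 h⁻¹`; optimisation is bounded Levenberg–Marquardt
with `k ≥ 0` and `a > 0`. The non-negativity bound encodes the biology —
there is no negative depletion; apparently increasing time courses land
on the boundary `k = 0` and are handled by NSD classification rather
than by a negative rate. On noise-free data the fit agrees with the
log-linear closed form to below 10⁻⁸ relative error, and the test suite
also checks it against a brute-force grid search on noisy data.

**NSD classification** has no published criterion, so the package defines
one and applies it symmetrically to simulated and real data: a fish ×
compound is "no substrate depletion" when the one-sided Wald test of
`k > 0` fails at `alpha` (default 0.05), **or** when the per-well
fractional loss in exposure wells does not exceed the loss in the
cell-free medium controls over the same window (one-sided Welch test at
`alpha`). Without medium controls only the first criterion applies (with
a warning). Under a simulated null the rate-significance test alone holds
its nominal size, while the two-criterion rule is deliberately
conservative — it classifies a true null as NSD in well over 90% of
replicates.

## Clearance scaling

Two conventions are implemented side by side, and the result always
records which was used:

* `paper_literal`: `Cl_int,in vitro = k / N` with `N = 50,000` cells/well
  (500 cells/spheroid × 100 spheroids/well) — the convention of the
  assay write-up this package follows, dimensionally loose but kept for
  comparability;
* `volume_corrected`: `Cl_int,in vitro = k·V / N` with `V = 0.075` mL —
  the standard substrate-depletion scaling, a true clearance in
  mL h⁻¹ cell⁻¹. The two differ by exactly the well volume.

Hepatic scaling multiplies by hepatocellularity, a parameter rather than
a constant: 91×10⁶ cells per g liver for trout (spheroid-derived) and
120×10⁶ for human literature values; the species selects which one is
used, i.e. the trout figure *replaces* the human factor rather than
multiplying it. Literature S9 values convert at
`µL min⁻¹ mg⁻¹ × 0.06 × 50 mg g⁻¹` and hepatocyte-suspension values at
`µL min⁻¹ (10⁶ cells)⁻¹ × 0.06 × hepatocellularity/10⁶`; all conversions
are exactly invertible. At the cohort mean `k = 0.022 h⁻¹` the literal
chain gives 40.04 mL h⁻¹ g⁻¹; published spheroid clearance figures for
this assay (54.0 and 49.8 mL h⁻¹ g⁻¹) are not recoverable from the
stated mean rates under either convention, so the package documents the
chain and its properties (linearity in `k`, mode ratio = well volume)
instead of asserting those two cells.

## Cohort statistics

`summarize_cohort()` reports means and sample SDs (n − 1) of percent
depletion, `k` and `t½` across the non-NSD fish; the mean half-life is
the mean of per-fish half-lives, which exceeds `ln 2 / mean(k)` whenever
`k` varies between fish (Jensen's inequality) — both numbers are
legitimate, the package reports the former and keeps full precision
internally, rounding only in displays (k to 3 decimals, t½ and % to 1).

Inter-individual differences are tested by one-way ANOVA on the natural
log of per-well percent depletion (computed per endpoint well against the
fish's time-zero exposure mean; the log stabilises the multiplicative
error), followed by Tukey HSD (`stats::TukeyHSD`, Tukey–Kramer on
unbalanced data) and a compact letter display built by
insertion–absorption from the pairwise significance matrix. The display
is deterministic: two fish share a letter **iff** their adjusted
difference is not significant, letters are ordered so "A" sits on the
largest group mean, and ties are broken by input order. Wells with
non-positive percent depletion cannot be log-transformed and are dropped
with a recorded count. The letter algorithm is verified in the tests
against exhaustive enumeration over all significance patterns on 3 and 4
groups, and the adjusted p-values against an independent
multiple-comparison route (`multcomp`).

## Read-across

`read_compound_profiles()` ships seven reference pharmaceuticals with
their BDDCS class, percent of dose metabolised in humans, major human
CYPs and the observed trout-spheroid outcome. A compound counts as
extensively metabolised in humans at ≥ 50% of dose (configurable; all
packaged compounds sit at 6% or ≥ 99%, far from the boundary).
`concordance()` deliberately scores *outcome agreement* — human status
equals trout observation — rather than an a-priori CYP-based prediction;
the mechanistic reading (is a major human CYP absent in trout?) is
exposed as a separate annotation flag so the two are never conflated.
Diclofenac's descriptive enzyme list is stored as a parsed CYP set
(2C9, 2C8, 2C18, 2C19, 2B6) plus a free-text note.

## Numerical and scale choices

Problem sizes in the tests are chosen to make the statistical assertions
sharp at interactive speed: law-of-large-numbers checks on the generator
use 1,000 fish, parameter recovery 200 fish (accepted within 3 standard
errors of the configured mean), the NSD size check 1,000 null replicates
against binomial 99% bounds, and the medium-control time-invariance check
30 independent simulations at α = 0.01. The acceptance script uses the
same 200-fish design. All randomness flows from a single user-supplied
seed through the per-fish hash, so every number is reproducible.

Known limitations: strictly first-order simulation and fitting (no
Michaelis–Menten or biphasic depletion), no protein-binding correction,
no liver blood-flow model (well-stirred/parallel-tube) and no BCF
extrapolation; clearance scaling assumes the nominal 50,000 cells/well.
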