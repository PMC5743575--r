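---
title: "FTIR pollen chemotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FTIR pollen chemotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenftir)
```

This vignette is the package's own account of the science it implements:
the measurement model behind the synthetic spectra, the preprocessing and
classification procedures, the statistics built on them, the parameters
that matter, and the choices we made where the design was genuinely open.

## 1. The measurement model and the synthetic generator

An FTIR transmission spectrum of a dried pollen film is, to a good
approximation, a non-negative mixture of absorption bands sitting on
instrumental artifacts. The generator's forward model for one measured
spectrum is

$$z(\nu) \;=\; b\, m(\nu) \;+\; a \;+\; c\,\tilde\nu \;+\; d\,\tilde\nu^2
\;+\; \varepsilon,$$

where $m(\nu) = \sum_k w_k \sum_{j \in k} A_j
\exp\!\big(-\tfrac12 (\nu - \nu_j)^2/\sigma_j^2\big)$ sums Gaussian bands of
five constituents (protein, lipid, carbohydrate, sporopollenin, CH-stretch)
weighted by composition $w$; $b$ is multiplicative scatter (optical path /
film thickness), $(a, c, d)$ a quadratic baseline on the axis rescaled to
$[-1, 1]$, and $\varepsilon$ i.i.d. Gaussian detector noise. These are
exactly the artifact classes EMSC removes, so with zero noise every
generated spectrum is exactly representable in the EMSC model span — a
property the tests assert.

Band centres follow the standard grass-pollen assignments (amide I/II at
1,650/1,540 cm⁻¹; lipids at 1,745, 1,712, 1,470, 1,170, 2,923 cm⁻¹;
carbohydrates within 1,200–900 cm⁻¹ including 1,164, 1,083, 1,076, 1,052,
1,023 cm⁻¹; sporopollenin at 1,668, 1,658, 1,625, 1,512, 850, 835, 815
cm⁻¹; the CH-stretch envelope at 3,050 and 2,960–2,830 cm⁻¹). Only centres
are documented in the literature we emulate; widths (Gaussian σ, 10–15 cm⁻¹
for sharp condensed-phase bands, 40 cm⁻¹ for the CH envelope) and relative
amplitudes are package defaults, standard for condensed-phase infrared
surrogates.

The sampling design mirrors a clonal growth experiment: three species ×
three populations (44–48 samples each, 380 in total), each genet divided
into four ramets grown under 2 temperatures × 2 nutrient levels, every
sample measured in three technical replicates (1,140 spectra), on a
descending 4,000–500 cm⁻¹ axis with 0.964 cm⁻¹ digital spacing.

### Effect sizes: surrogates, chosen once

No source quantifies the factor effects, so magnitudes are generator
surrogates chosen once, at design time, to reproduce two *qualitative*
targets and then frozen:

* the per-level classification gradient — species nearly perfect,
  populations good, growth conditions well above chance but clearly
  imperfect;
* the variability ordering — technical replicates < one genet across
  conditions < one population–condition cell < a whole population.

The defaults that realise this: species baselines differ by 15–50% in
protein/carbohydrate/lipid balance (the alpine species protein-rich);
population effects shift single constituents by 8–12%; warm growth raises
protein ×1.06 and lowers carbohydrate ×0.94; added nutrients raise protein
×1.045 and lipid ×1.03 while lowering carbohydrate ×0.965 and sporopollenin
×0.97; per-genet log-normal multipliers with σ = 0.05 are drawn once per
genet and shared by its four clones (this is what makes the Fisher
clustering analysis meaningful); scatter σ: 0.08 (log *b*), 0.02, 0.01,
0.01 for offset/linear/quadratic; noise σ = 10⁻⁴ absorbance, the realistic
order for a 32-scan DTGS transmission instrument. Noise interacts with the
axis: the second-derivative step amplifies white noise roughly with the
inverse square of band width *in points*, so a noise level that looks
innocuous on a coarse grid can dominate derivative spectra on the native
0.964 cm⁻¹ grid; 10⁻⁴ keeps the amide-region Pearson variability of
replicates well below the biological terms on the default axis.

Randomness is streamed: every genet and every sample derives its own
31-bit seed from the global seed, so subsetting or extending a design
(e.g. more replicates) never changes previously generated spectra, and a
fixed config + seed is bit-reproducible.

What the generator does *not* emulate: water-vapour/CO₂ lines, detector
nonlinearity, Mie scattering from intact grains, band-shape changes
(Lorentzian tails, hydrogen-bonding shifts), or correlated (pink) noise.
Passing tests on synthetic data therefore certify the *machinery* —
preprocessing exactness, selection behaviour, calibration of the
permutation test, scoring rules — not performance on any real instrument's
output.

## 2. Preprocessing

The canonical order is derivative → EMSC → replicate averaging.

**Savitzky–Golay second derivative** (degree 2, window 7 points — the
standard fingerprinting setting) suppresses baselines and sharpens
overlapping bands. The derivative is taken in index units: the axis is
uniform, and everything downstream is invariant to the constant factor a
physical-units derivative would add. At the spectrum edges the window
polynomial is fitted one-sidedly and evaluated at the shifted point, so no
axis points are lost; on any quadratic input the filter is exact (constant
second derivative), which the tests exploit as an oracle. The filter is
applied through `signal::sgolayfilt`, whose edge handling implements
exactly this policy.

**EMSC** fits each derivative spectrum to $\{1, m, \tilde\nu,
\tilde\nu^2\}$ by ordinary least squares and divides out the scale $b$.
The reference $m$ is the dataset mean, computed once before any modelling
— not recomputed per hierarchy node — because preprocessing precedes and
is independent of the model tree. $\tilde\nu \in [-1,1]$ keeps the
polynomial columns well conditioned. A spectrum with $|b| < 10^{-8}$
carries essentially none of the reference signal and cannot be corrected;
it is dropped with a warning rather than silently propagated. Correction
is idempotent and removes *any* artifact in the model span exactly
(properties under test at 10⁻¹⁰).

**Replicate averaging** is the arithmetic mean per sample id, ordering
stable by first occurrence, replicate column dropped.

**Variability statistic.** For a set of spectra, the mean over all
unordered pairs of $(1 - r) \times 10^4$ with $r$ the Pearson correlation
over 1,700–1,600 cm⁻¹. The $\times 10^4$ scaling reads the conventional
reporting of this statistic as a rescaled dissimilarity (values of order
10–100 for $r \approx 0.999$–$0.99$); the arithmetic mean is our
aggregator, as the convention leaves it unstated. Pairs involving a
zero-variance spectrum are skipped with a warning.

## 3. Sparse PLS discriminant analysis

Classification is PLS2 regression on a centred one-hot class matrix with
argmax decoding — the PLS-DA convention. Components are extracted by
NIPALS with X-deflation only; after the dense loading weight $w_k$
converges, the $\lfloor s\,p \rfloor$ entries smallest in absolute value
are zeroed, the survivors renormalised to unit norm, and extraction
continues with the sparsified weight (scores and deflation use it). With
$s = 0$ this is exactly dense NIPALS, which is the anchor for the test
oracles (an independently coded textbook NIPALS, and mixOmics' dense PLS
as a second, external cross-check).

Open choices and how we fixed them:

* **One `s` for all components** (a per-component sequential search is the
  obvious alternative; the joint search is cheaper and easier to
  reproduce). The searched grid is 0.90–0.99 by 0.01.
* **Renormalisation after thresholding**: yes — it keeps scores on a
  comparable scale across sparsity degrees.
* **Component count** is searched on the same CV grid (1–15 by default);
  the four-group interaction models are the exception and always use 10
  components, following the convention of the study design we emulate.
* **Tie-breaking**: minimum CV misclassification rate wins; among ties,
  higher sparsity, then fewer components (parsimony on both axes).
* **Folds are stratified** by class. Plain random 3-blocks at ~40 samples
  regularly produce training folds missing a class; stratification removes
  that failure mode without changing the estimand. A split that still
  lacks a class is re-randomised once, then errors.

## 4. The hierarchical classification tree

One model per node: a species model at the root, a population model per
species with ≥ 2 populations, a condition model per (species, population)
with ≥ 2 conditions — 13 models for the full design; nodes with a single
child class are label passthroughs. Validation samples are routed
root-to-leaf along *predicted* labels (hard routing), so an error at the
species level makes the population and condition scores automatically
wrong: per-level success rates are hierarchical by construction. The
218/162 train/validation split is stratified over species × population ×
condition cells with largest-remainder rounding, so the canonical totals
are hit exactly; strata smaller than two samples stay whole in training
with a warning.

## 5. Permutation test

The test statistic is the cross-validated success rate of the *entire*
selection procedure (sparsity and component search included). Each of the
`n_perm` permutations shuffles the labels and reruns that identical
procedure with its own fold split — so selection optimism appears
identically under the null, and no leakage can inflate significance. The
add-one estimator $p = (1 + \#\{SR_{perm} \ge SR_{obs}\})/(1 + n_{perm})$
is valid by exchangeability and has floor $1/(1+n_{perm})$; 999
permutations is the default, 99 the economical choice used in the
calibration experiments.

A discreteness consideration: the CV success rate takes at most $n+1$
values, and ties between observed and permuted statistics make the add-one
p-value conservative. At small $n$ (≈ 40) this tie mass visibly distorts
the null p-value distribution; the calibration experiment in the test
suite therefore uses 100 null samples, where the statistic is fine-grained
enough that 200 independent p-values pass a Kolmogorov–Smirnov uniformity
check at the 1% level. This is a property of the estimator, not of the
implementation.

## 6. Fisher clustering coefficient

For one population, PCA scores are computed by SVD of the column-centred
averaged spectra (deterministic sign: the largest-magnitude loading of
each component is positive), keeping the smallest number of components
explaining ≥ 99% of variance, capped at 10 (the cap matters: trailing
noise components would dilute both scatter traces). With genets as groups,

$$S_b = \sum_i n_i (\mu - \bar x_i)(\mu - \bar x_i)^{\mathsf T}, \qquad
  S_w = \sum_i \sum_j (\bar x_i - x_{ij})(\bar x_i - x_{ij})^{\mathsf T},$$

and the scalar coefficient is $\mathrm{FCC} =
\mathrm{tr}(S_b)/\mathrm{tr}(S_w)$. The trace ratio is our scalarisation
of the matrix ratio $S_b/S_w$: it is rotation-invariant, obeys the law of
total scatter $\mathrm{tr}(S_b) + \mathrm{tr}(S_w) = \sum_{ij}
\|x_{ij}-\mu\|^2$ (a test invariant at 10⁻¹⁰), and unlike a determinant
ratio is defined when some groups are small. Singleton groups contribute
nothing to $S_w$; if $S_w$ is identically zero the FCC is reported as
infinite rather than a number. High FCC = genotype rigidity; low FCC =
plasticity or noise.

## 7. Problem sizes used by the tests and the acceptance script

Simulation-backed checks choose sizes as the smallest that make the
property under test unambiguous: single-population experiments use 24–48
samples; multi-seed experiments (classification gradient, FCC contrast)
use a 4 cm⁻¹ grid over 1,800–800 cm⁻¹, which contains every constituent
band that drives the factors of the design except the CH envelope; the
end-to-end structural checks and the acceptance script run the full
380-sample design on the native 3,631-point axis. The permutation
calibration uses 200 repetitions × 99 permutations at n = 100, p = 15
(see §5).

## 8. Known limitations

* Generator realism as in §1; effect magnitudes are surrogates, and
  numerical FCC / success-rate values on synthetic data are not claims
  about any real dataset.
* The sparse step is hard thresholding of loading weights, not the
  penalised (L1) sparse PLS family; kernel and multiblock variants are out
  of scope.
* EMSC is the only scatter correction offered (no SNV/MSC/rubber-band);
  atmospheric compensation is not implemented.
* p-values for the nine populations are reported raw, without
  multiple-testing correction, matching the reporting convention of such
  studies; adjust externally if you need family-wise control.
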