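---
title: "Modelling silent antibiotic effects on the calf gut community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling silent antibiotic effects on the calf gut community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(calfscape)
```

## The problem

Sub-therapeutic, in-feed antibiotics (antimicrobial growth promoters) can
leave growth performance and routine blood chemistry untouched while still
reorganizing the gut microbial community — effects that pairwise group
comparisons miss.  `calfscape` implements an analysis chain built for that
situation, shaped around a longitudinal two-group calf trial: 12 animals,
half fed chlortetracycline (CTC) in the milk replacer (the `CON` group) and
half antibiotic-free (`EXP`), sampled at 3, 30 and 60 days of age.

The chain has four read-outs: a fitted community model (who co-occurs with
whom, and how treatment and age move each member), the energy landscape of
that model (which community compositions are stable, and how stability
shifts along the treatment-by-age gradient), association rules linking
taxa, physiology and treatment, and a causal network estimated from
per-animal changes over time.

## The community model

The observation unit is a per-sample state vector
$\sigma = (\sigma_1,\dots,\sigma_N)$: presence/absence of the retained
genera ($n_m$ binary components) followed by fecal chemical levels scaled
to $[0,1]$ ($n_c$ continuous components).  Each sample also carries an
environment $\epsilon = (\epsilon_a, \epsilon_s)$: the treatment indicator
(1 = antibiotic-fed) and the growth stage mapped onto $[0,1]$ by the fixed
dictionary $3\,\mathrm{d} \to 0$, $30\,\mathrm{d} \to 0.53$,
$60\,\mathrm{d} \to 1$.

The model is a pairwise maximum-entropy (Ising-like) distribution extended
with environment couplings:

$$P(\sigma \mid \epsilon) = \frac{e^{-E(\sigma\mid\epsilon)}}{\sum_{\sigma'} e^{-E(\sigma'\mid\epsilon)}},
\qquad
E(\sigma \mid \epsilon) = -\Big(\sum_{i<j} J_{ij}\sigma_i\sigma_j
 + \epsilon_a \sum_i g_i^a \sigma_i
 + \epsilon_s \sum_i g_i^s \sigma_i
 + \sum_i h_i \sigma_i\Big).$$

$J_{ij} > 0$ favours co-occurrence of components $i$ and $j$; $g_i^a$ is
component $i$'s responsiveness to the antibiotic; $g_i^s$ its preference
for the later growth stage; $h_i$ its baseline propensity.  The pair term
is summed over unordered pairs ($i<j$) and stored symmetrically — a
convention choice only (double counting would rescale $J$ by 2), recorded
in the serialized `meta.json` so exported couplings are unambiguous.

The environment is treated as a per-sample scalar pair shared by all
components: what varies per component is the coupling ($g_i^a$, $g_i^s$),
not the environment itself.

### Preprocessing conventions

* Presence means relative abundance **strictly above** 0.001.  The
  threshold itself counts as absent — the detection-limit reading.
* The prevalence filter keeps genera present in more than 2 and fewer
  than 35 of the samples (both bounds exclusive): components that are
  (nearly) always or never present carry no co-occurrence information and
  their $h_i$ would diverge.  Divergent biases that survive anyway are
  capped at $|h| \le 10$, which keeps every landscape energy finite.
* Chemicals are min–max scaled per analyte; a constant analyte maps to all
  zeros with a warning rather than NaN, so a degenerate input cannot take
  the whole fit down.
* The growth-stage value for day 30 is the literal constant 0.53, not a
  formula; `encode_environment()` refuses unknown days rather than
  interpolating.

### Estimation

Parameters are estimated by stochastic-approximation maximum likelihood
(Robbins–Monro).  The sufficient statistics of the model are the observed
means of $\sigma_i$, $\sigma_i\sigma_j$, $\epsilon_a\sigma_i$ and
$\epsilon_s\sigma_i$.  Each iteration advances a block of persistent Gibbs
chains per distinct environment, compares simulated statistics against the
observed ones, and nudges every parameter by
$a_t(\text{obs}-\text{sim})$ with $a_t = a_0/(1+t/\tau)$.  Binary
components are resampled from their conditional Bernoulli; continuous
components from the closed-form conditional $\propto e^{f\sigma_i}$ on
$[0,1]$ (a truncated exponential — the coherent maximum-likelihood
treatment of chemicals, which are therefore resampled rather than clamped
during fitting).  Reported parameters are tail averages over the final 20%
of iterations, which removes most of the Monte Carlo jitter of the final
iterate.

Defaults (`maxent_control()`): 5000 iterations, $a_0 = 0.2$, $\tau = 1000$,
100 chains per environment, one sweep per iteration.  On the recovery
harness used in the tests (N = 8, all parameters drawn from
$\mathcal{U}(-1,1)$, 2000 samples in each of the six
treatment-by-stage environments) this schedule recovers the generating
parameters with Pearson $r$ above 0.9 (the acceptance script reports the
exact value); gentler schedules with fewer chains and a faster-decaying
rate stall short of convergence on the same harness, which is why the
defaults are what they are.  $g^a$ ($g^s$) is estimated
only when the treatment (stage) actually varies in the data; otherwise it
is pinned at zero and the model gracefully reduces to the plain pairwise
maximum-entropy model.

### Significance: why the default is a bootstrap

Per-parameter p-values come from repeating the estimation `n_reps` times
(2000 by default) and scoring sign stability:
$p = 2\min(\hat F(0), 1-\hat F(0^-))$ with a floor of $1/(n_\text{reps}+1)$.
What the repeats resample is the crucial design choice:

* `method = "bootstrap"` (default) resamples the *samples* with
  replacement before each repeat.  The spread of the repeated estimates
  then tracks sampling variability, and under a null parameter the
  p-values are approximately uniform: in the package's calibration test a
  null $g^a$ is rejected at the 5% level in about 5% of synthetic
  datasets.
* `method = "rerun"` repeats the fit on the fixed data with fresh RNG
  only.  Its spread reflects the Monte Carlo noise of the estimator —
  useful as a *stability* diagnostic (is the sign of a reported coupling
  an artifact of the stochastic optimizer?), but far too small to stand in
  for sampling uncertainty: under the same null it "rejects" almost
  always.  It is kept, clearly labelled, for that diagnostic role.

### The landscape

A stable state is a community composition whose energy is strictly lower
than that of all single-flip neighbours.  `find_minima()` enumerates all
$2^{n_m}$ binary states (exact mode, refused above 20 binary components),
assigns every state to its minimum by steepest descent (ties broken toward
the lowest component index), and orders minima by energy — the state-space
axis of any landscape plot is therefore energy-ordered, a documented
convention since nothing canonical orders the hypercube.  Chemicals cannot
be flipped, so during landscape analysis they are clamped (dataset means
by default) and enter as an effective field on the taxa plus a constant
energy offset.  A landscape with no strict minimum (e.g. all parameters
zero) is reported as flat, with plateaus surfaced rather than silently
merged.  `landscape_over_gradient()` repeats this across
$\epsilon_a \in \{0,1\}$ and a growth-stage grid, tracking how stable
states appear, deepen or vanish along development under each treatment.

### Network and response classification

`build_network()` keeps couplings with $p \le \alpha$ (0.05 by default;
p-value only, with an optional $|J|$ floor left to the caller) and signs
them.  `classify_response()` places each component in the
$(g^s, g^a)$ quadrants: Group I ($g^s<0, g^a>0$), II ($g^s>0, g^a>0$),
III ($g^s<0, g^a<0$), IV ($g^s>0, g^a<0$).  The dead zone is 0 by default
— raw sign quadrants, exact zeros unclassified — because any nonzero
cutoff is a presentation choice, exposed as `delta`.

## Association rules

`build_transactions()` itemizes each sample (present taxa; phenotypes
median-split into `high`/`low`, ties deterministically high; an age-bin
item; the treatment flag `CTC`), and `mine_rules()` runs a level-wise
a-priori search with exact support/confidence/lift counting.  The default
thresholds (support 0.2, confidence 0.8) are honest placeholders — they
are reported in the output rather than hidden — since no canonical values
exist for this design; the mining itself is validated in the tests against
brute-force enumeration over all itemsets.

## Causal discovery

The causal stage estimates a linear non-Gaussian acyclic model by the
direct method: repeatedly select the most plausibly exogenous variable
(the one whose pairwise likelihood-ratio scores, built from the Hyvärinen
maximum-entropy approximation to differential entropy, least contradict it
being upstream), regress it out, recurse; then fill in the strengths
matrix $B$ by ordinary least squares along the recovered order.  $B$ is
deliberately **unpruned** — small strengths are reported, not zeroed —
because downstream interpretation (and the internal-standard check) needs
the raw coefficients.  Residual negentropy per variable is reported; if
every residual looks Gaussian the order is weakly identified and a warning
says so.  The tests assert both sides of identifiability: near-perfect
order recovery with uniform noise, decay toward chance with Gaussian
noise.

Two transforms precede estimation in `run_pipeline()`:

* **Log scale.**  Concentrations and abundances act multiplicatively, so
  fold changes are the scale on which a linear structural model is well
  specified.  On raw differences the skew/heteroscedasticity of the
  deltas routinely reversed the treatment edge in simulation.
* **Delta from baseline, baseline rows dropped.**  `delta_transform()`
  subtracts each animal's day-3 value and by default keeps the (all-zero)
  baseline rows, which is the faithful definition of the change table.
  For *estimation*, however, the pipeline drops them: a row that is
  identically zero whatever the treatment carries no signal about
  treatment response and, at n = 36, actively corrupts the
  non-Gaussianity-based direction search: with the zero rows included,
  recovery of the planted treatment-to-butyrate edge collapsed in
  simulation.  The treatment flag itself is appended after differencing,
  as a 0/1 column among the variables.

The **internal standard** is the validation trick this stage leans on: a
taxonomic family and its dominant genus form a nested pair whose direct
strength should be ≈ 1 (the family *is* mostly the genus).  A coefficient
within `1 ± 0.1` passes; a structurally absent edge fails with
coefficient 0.

## The synthetic-data module

The generator is first-class, tested code; it defines the conditions every
downstream claim is tested under.  `generate_study()` emulates the trial:
12 animals, balanced `CON`/`EXP`, days 3/30/60, 36 genera with
QIIME-classic taxonomy strings, 8 fecal chemicals, 4 serum analytes.
Genus intensities are log-normal (baseline spread across genera, a
per-animal random effect, stage trends, treatment shifts) normalized to
relative abundances — which produces realistic sparsity around the 0.001
presence threshold.  Under the `trial` profile the treatment raises a
methanogen-like genus (*Methanobrevibacter*), suppresses a
butyrate-producing *Lachnospiraceae* genus (*Dorea*) together with fecal
butyrate and serum IgA, and nudges about a third of the remaining genera —
effect sizes were fixed once, at values giving roughly those responder
fractions, and are multiplied by `effect_size` (0 under the `null`
profile).  Treatment effects scale with the growth-stage value: exposure
is cumulative, so day-3 samples are essentially unaffected and day-60
samples carry the full shift.  What the generator does *not* emulate:
sequencing noise and compositional artefacts of 16S processing,
immunoassay error structure, seasonal/batch effects, or taxon-specific
phylogenetic correlation.  Tests passing on these synthetics therefore
validate the machinery and its statistical calibration, not field
performance on real assays.

`generate_community()` draws exactly from the model itself (full
enumeration for all-binary systems up to N = 20, Gibbs otherwise) and is
the oracle half of the sampler/estimator test pair.  `generate_sem()`
produces shuffled-column linear non-Gaussian data with the true
permutation recorded, for the causal-recovery harness.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to run on
one CPU in minutes: the sampler oracle uses N ≤ 12 with $10^5$ draws
(total-variation tolerance 0.02); parameter recovery uses N = 8 with 2000
samples per environment and a 10 000-iteration schedule; significance
calibration uses 200 synthetic datasets at 200 repeats each with a
deliberately light fit (the bootstrap's calibration is what is under
test, not the fit's precision); causal recovery uses 100 seeds of a
3-variable chain at n = 5000; the pipeline property runs 20 study seeds.
Ties in steepest descent break toward the lowest component index;
enumeration indexes states with component 1 varying fastest; probabilities
are normalized after subtracting the maximum negative energy, so partition
sums cannot overflow.

## Known limitations

* Exact landscape/sampling paths stop at 20 binary components; beyond
  that only heuristic descent from chosen starts is offered.
* The stochastic-approximation stopping rule is a fixed iteration budget
  with tail averaging, not an adaptive convergence test; the trace is
  returned so users can judge convergence themselves.
* p-values are resampling-based and inherit the bootstrap's small-sample
  caveats at n = 36.
* Association-rule thresholds are design placeholders, not estimated
  quantities.
* The causal stage assumes linear effects on the log scale, no latent
  confounders and no time-lagged structure; per-group runs (`CON`-only,
  `EXP`-only) are row subsets, not a multi-group model.
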