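# calfscape

Detecting "silent" antibiotic effects in longitudinal microbiome studies —
effects that leave growth and routine blood chemistry untouched while
reorganizing the gut community.

`calfscape` is built around a two-group calf trial design: 12 animals, half
fed chlortetracycline (CTC) in the milk replacer (`CON`), half
antibiotic-free (`EXP`), sampled at 3, 30 and 60 days of age. It provides
four connected analyses plus a synthetic-data module that emulates the whole
study, so every stage is testable end to end with no external data.

## The model

The core is a pairwise maximum-entropy (Ising-like) community model extended
with environment couplings. Each sample is a state vector
σ = (σ₁,…,σ_N): presence/absence of the retained genera followed by fecal
chemical levels scaled to [0, 1]. With environment ε = (ε_a, ε_s)
(treatment indicator; growth stage mapped 3 d → 0, 30 d → 0.53, 60 d → 1):

    P(σ | ε) = exp(−E(σ|ε)) / Σ_σ' exp(−E(σ'|ε))
    E(σ | ε) = −( Σ_{i<j} J_ij σ_i σ_j + ε_a Σ_i g_i^a σ_i
                  + ε_s Σ_i g_i^s σ_i + Σ_i h_i σ_i )

J_ij > 0 favours co-occurrence of components i and j; g_i^a is component
i's responsiveness to the antibiotic; g_i^s its growth-stage preference;
h_i its baseline propensity. Parameters are estimated by
stochastic-approximation maximum likelihood (persistent Gibbs chains per
environment, Robbins–Monro updates), with bootstrap sign-stability
p-values. On top of the fit sit:

* **Energy landscape analysis** — stable community states (strict local
  minima on the hypercube), basins by steepest descent, and their evolution
  across the treatment × growth-stage gradient.
* **Signed interaction network** — the significant couplings J with their
  signs.
* **Response classification** — components placed in the (g^s, g^a)
  quadrants: Groups I–IV (e.g. Group I: suppressed late in development,
  boosted by the antibiotic).
* **Association rules** — a-priori mining over itemized samples (present
  taxa, median-split phenotypes, age bins, the `CTC` flag) with exact
  support/confidence/lift.
* **Causal discovery** — a direct-method linear non-Gaussian acyclic model
  (causal order by pairwise non-Gaussianity scores, unpruned strengths
  matrix by least squares) on per-animal log-scale changes from day 3,
  validated by taxonomically nested family/genus "internal standards"
  whose direct strength should be ≈ 1.

## Worked example

```r
library(calfscape)

study <- generate_study(n_animals = 12, seed = 1)   # mock calf trial
pp    <- preprocess_study(study)                    # binarize, filter, scale
length(pp$retained)                                 # 20 genera retained
ncol(pp$components$values)                          # 28 components (20 + 8)

fit <- fit_maxent(pp$components, pp$env,
                  maxent_control(n_iter = 1500, n_chains = 30), seed = 2)
cl  <- classify_response(fit$params)
subset(cl, component %in% c("Methanobrevibacter", "Dorea"))
#>             component       g_a       g_s group
#> 1               Dorea -2.632031 -2.591429   III
#> 20 Methanobrevibacter  3.321558  2.775778    II
```

The planted biology is recovered: the methanogen-like genus has g_a > 0
(raised by the antibiotic; Group II — a late-stage coloniser boosted by
CTC), the butyrate-producing genus g_a < 0 (suppressed; Group III). The
causal stage then quantifies the treatment's downstream effect:

```r
res <- run_pipeline(study, seed = 2, significance = FALSE)
res$causal$B["butyrate", "CTC"]
#> -0.6609706
```

a negative direct strength of treatment on fecal butyrate (log-scale
change from day 3): CTC suppresses butyrate production in this synthetic
study, mirroring the designed effect. `run_pipeline()` with
`significance = TRUE` adds bootstrap p-values and the signed interaction
network; `find_minima()` / `landscape_over_gradient()` map the stable
states of the fitted community.

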