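---
title: "Measuring SDM competence with skills networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring SDM competence with skills networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement problem

Shared decision making (SDM) is a patient-centred communication process in
which physician and patient jointly reach a treatment choice among multiple
acceptable options. Measuring a physician's *competence* in SDM is hard:
observer coding of recorded consultations (OPTION-12, OPTION-5, the 4HCS
"Invest in the End" subscale) is the reference standard but expensive, while
patient questionnaires such as the SDM-Q-9 are cheap but measure something
subtly different — patients report *whether and how much* each of nine
skills occurred, not *how well* it was performed. The two families of
measures notoriously disagree.

`sdmnet` implements a skills-network account of this gap. Each of the nine
SDM-Q-9 items is treated as a *skill* (a node); the physician-specific
pattern of association between skills across that physician's consultations
(the directed, weighted edges) is treated as a signature of how the
physician organises the skills — and it is this organisation, rather than
any single skill level, that is taken to carry competence information.
Three node parameters summarise a physician's network:

* **activation** of a skill — its adjusted level on the 0–5 item scale (the
  physician-specific model intercept with grand-mean-centred predictors);
* **outstrength** — the sum of retained outgoing edge weights, the degree
  to which showing the skill pulls the other skills along;
* **instrength** — the sum of retained incoming edge weights, the degree to
  which the skill is pulled along by the others.

Observer-rated competence is then regressed on these node parameters, and
the fitted weights allow competence to be *predicted* for physicians for
whom only patient ratings exist — the intended use case in routine care.

# The estimation model

For each outcome skill $k$, the package fits the multilevel regression

$$y_{ik} = \alpha_{p(i)} + \sum_{j \ne k} \beta_{p(i), jk}\,
  \tilde y_{ij} + \varepsilon_{ik},$$

where $i$ indexes consultations, $p(i)$ the physician, $\tilde y$ denotes
grand-mean-centred predictors, and the physician-specific intercept and
slopes are Normal deviations around population values (partial pooling:
every physician's estimates borrow strength from all other physicians'
data). The eight slopes of the model for outcome $k$ are the incoming edges
of node $k$; assembling all nine node models gives each physician a 9×9
directed weighted adjacency matrix.

Estimation is Bayesian via JAGS (three chains by default, seeded starting
values, split-chain Gelman–Rubin convergence checks). Priors are weakly
informative on the item scale: Normal(0, sd 100) on coefficients and
half-Cauchy(5) on scales. Each network is then **purged**: an edge is
retained only if the physician-specific coefficient's 95% equal-tailed
credible interval lies entirely above zero (the default, matching the idea
that a retained edge is an association credibly *higher than zero*); a
two-sided exclusion-of-zero variant is available via
`purge_rule = "two_sided"` for users who wish to keep credibly negative
edges. Purging only updates the retention mask — weights are preserved — so
it is idempotent and reversible.

Two genuinely open choices are worth flagging.

* **Activation.** The per-physician *model intercept* (with centred
  predictors, an adjusted item mean) and the *raw item mean* are both
  defensible definitions and nearly collinear on balanced data; the package
  defaults to the intercept and offers `activation = "raw_mean"`.
* **Purging level.** Purging is applied to the physician-specific
  coefficients, since each physician's network is purged individually; when
  a fixed-effects model is selected for an outcome, the physician-specific
  coefficient coincides with the population one.

# Fixed versus random effects, and the DIC focus

For every outcome the package can fit both a fixed-effects variant (one
coefficient vector for all physicians) and the random-effects variant, and
select by DIC with the conventional three-point relevance margin: the
random model must undercut the fixed model's DIC by at least 3.

DIC for the random-effects model is computed on the **marginal**
likelihood, with the physician deviations integrated out analytically
(Woodbury identity on per-physician sufficient statistics), so that the
comparison is focused on the population-level structure. This matters: DIC
on the conditional likelihood — deviance evaluated at the sampled random
effects — is unstable for exactly this comparison, because weakly shrunk
random effects can absorb residual noise and make the random model appear
to fit better even when the data contain no physician heterogeneity at all.
In calibration experiments with zero-heterogeneity data the marginal DIC
retains the fixed model in the large majority of replicates, while the
conditional version preferred the random model in a substantial fraction;
with realistic heterogeneity the random model wins decisively either way.
The effective number of parameters uses the classic
$p_D = \bar D - D(\bar\theta)$.

# From node parameters to competence

Observer ratings are scored per the formative model: unweighted item means,
rescaled to 0–100, averaged over raters within consultation and over
consultations within physician. Quality checks accompany the scores:

* a REML variance decomposition (physician / consultation-within-physician
  / residual) on per-rater composites, yielding the physician-level
  intraclass correlation;
* inter-rater reliability of the physician mean of $c$ consultations rated
  by $k$ raters, from a three-level crossed model with a rater main effect:
  $\mathrm{rel} = \sigma^2_p \big/ \{\sigma^2_p + \sigma^2_c/c +
  (\sigma^2_r \cdot \mathbb{1}[\text{random raters}] +
  \sigma^2_e)/(ck)\}$, reported in random-rater and fixed-rater variants.
  The exact three-level generalisation used in the literature is not fully
  specified anywhere; this Spearman–Brown-style composite is the package's
  documented choice. Note that the formula treats consultation-to-consult-
  ation variation as error in the physician-level mean, so perfect rater
  agreement yields reliability 1 only when consultation variance is also 0.

Prediction proceeds in two stages. **Screening**: for each observer
outcome, three Bayesian regressions (one per parameter type, each with all
nine skills' centred values) flag coefficients whose 95% interval excludes
zero; a skill is retained if any of its parameters is flagged for any
outcome. The interval is two-sided — the criterion is a *non-zero*
association. **Final model**: one Bayesian regression per outcome with the
three parameter types of every retained skill. $R$, $R^2$ and adjusted
$R^2$ are computed *per posterior draw* — model variance is the variance of
the linear predictor across physicians, $R^2 =$ model/(model+residual) —
and then summarised. This is deliberate: point transforms of posterior
means are mutually inconsistent ($\bar R^2 \ne (\bar R)^2$), so each
statistic is summarised from its own draw distribution. Predictions are an
exact linear form in the posterior-mean coefficients and stored grand
means, so any physician with complete node parameters can be scored without
sampling and without observer data.

# The synthetic-data generator

No clinical rating data ship with the package, so a generator provides
study-shaped data with known ground truth. Its generative model is the
simultaneous linear system

$$y = (I - B_p^{\mathsf T})^{-1} (\alpha_p + \varepsilon),
  \qquad \varepsilon \sim N(0, \mathrm{diag}(\sigma^2)),$$

discretized by rounding half away from zero and clipping to 0–5. This is
the natural joint model whose node-wise regressions correspond to the
estimation equations; with the default sparse, weak, mostly feed-forward
edge set the conditional coefficients track the structural ones closely,
which is what makes parameter-recovery experiments meaningful. Rounding
half away from zero (rather than banker's rounding) makes noise-free fixed
points well defined and parity-independent.

Default conditions mirror the reference study design: 29 physicians, 10
patient ratings each, 3 recorded consultations, 2 raters. Remaining
defaults were set once, a priori, to values a practitioner would call
realistic for this field, and are documented here:

* *Population network*: sparse positive edges (0.15–0.35) with eliciting
  preferences (skill 6) the most strongly influenced hub, sharing (2) and
  deliberating (7) the most influential sources, and planning (9) a sink —
  the qualitative profile reported for SDM consultations.
* *Structural intercepts*: back-transformed as $(I - B^{\mathsf T})\,\mu$
  from target reduced-form item means 2.8–3.4, because the reduced-form
  inverse amplifies intercepts and naive mid-scale values would push latent
  items off the 0–5 scale.
* *Heterogeneity*: intercept SD 0.20 and per-edge slope SD 0.06, giving
  physician activation spreads around 0.5 on the item scale and spectral
  radii comfortably below 1 (draws at radius ≥ 1 are rejected; the cap of
  1000 attempts signals an unstable specification).
* *True competence* is a documented linear combination of the skill-6 node
  parameters, scaled by a Monte-Carlo calibration constant (SD of the
  combined skill-6 deviation ≈ 0.99 at 4000 physicians) so that
  physician-level competence SDs are 6.4, 8.3 and 4.5 points for OPTION-12,
  OPTION-5 and the 4HCS subscale — the outcome spreads implied by published
  model-plus-residual variances at this study scale.
* *Observer noise* is specified on the 0–100 composite scale and converted
  exactly to the item scale (every variance component is drawn
  independently per item, so composites keep the specified variance ratios
  and the generator's physician-level ICC has the closed form
  $\sigma^2_p/\sigma^2_{\text{total}}$). Defaults are solved from targets
  ICC 0.40 and IRR 0.72 — midpoints of the plausible ranges at this design
  — with the known discretization variance discounted from the residual.

What the generator does *not* emulate: ordinal response processes (it
discretizes a Gaussian), informative missingness, patient covariates, and
rater drift. Floor effects, however, are real and intentional: the OPTION
instruments score low (means 12–16 on 0–100), so item-level clipping
compresses the lower tail and attenuates realized ICC/IRR somewhat below
the analytic targets — exactly the kind of attenuation real low-scoring
instruments suffer. Passing recovery tests on these data therefore shows
that the pipeline recovers the parameters of a faithful but idealised data
mechanism, not that it is robust to every feature of clinical ratings.

# Numerical choices and degenerate inputs

* Seeds: one master seed; every stage and chain derives its own stream via
  a documented integer hash (`derive_seed`), so adding draws to one stage
  never perturbs another and all derived seeds stay in 32-bit range.
* Credible intervals are equal-tailed quantile intervals.
* Split-chain Gelman–Rubin with threshold 1.1; structurally constant
  parameters are flagged degenerate rather than failed; non-convergence is
  a warning carrying the diagnostics, not a hard error.
* Zero-variance observer data (all composites identical) returns a flagged
  result instead of a REML fit; perfect within-physician agreement
  short-circuits the reliability model (REML is degenerate at the
  boundary) and reports reliability 1.
* Incomplete rating records are dropped listwise, with counts logged.
* Negative REML variance components are truncated at zero.
* Overparameterised final models ($p \ge n - 1$) are reported but the
  adjusted $R^2$ is refused.
* The Fruchterman–Reingold layout uses $|w|$ as attraction strength (the
  force model is defined for nonnegative weights); edge sign is shown by
  line style. Coordinates are centred and seed-deterministic.

# Problem sizes and MCMC budgets

Three presets are provided. `"paper"` reproduces the long-run schedule of
WinBUGS-era multilevel analyses (3 chains, 90 000 retained iterations after
60 000 burn-in, thinning 30). `"desk"` (3 × 1500, 500 burn-in) is the
package's default for simulation studies and interactive work: posterior
means of this model family stabilise far earlier than the historical
schedules assumed, and all recovery experiments in the test suite run at
this budget. `"fast"` (2 × 600) exists for smoke tests and triage only.
Validation experiments use 30 physicians × 30 ratings for network
recovery (the scale at which individual slopes start to be informative),
200–500 physicians for closed-form ICC/IRR recovery, and 20 replicates for
the screening and DIC calibration experiments.

# Known limitations

* **Edge direction is not identifiable from cross-sectional data.** The
  node-wise regression of item $k$ on the remaining items estimates the
  conditional-dependence structure of the joint distribution, and for any
  joint model the conditional coefficient of $y_j$ in the regression of
  $y_k$ contains a contribution from *both* directed effects — roughly
  $B_{jk} + B_{kj}\,\sigma_k^2/\sigma_j^2$ minus collider corrections. A
  directed edge estimate therefore carries an "echo" of the reverse edge.
  Individual edge weights and activations are still recovered well in
  simulation (pooled correlations with the generating structural weights
  above 0.7 at 30 physicians × 30 ratings), but summed outstrength and
  instrength mix the true outgoing and incoming profiles of a node and
  recover the generator's structural strength sums only to about 0.55–0.65
  — a ceiling set by the estimand, not by sampling effort. Interpretations
  of out- versus instrength from cross-sectional data should accordingly
  be made with care; only longitudinal designs give direction a firm
  statistical footing.
* Intercept-based activation is an *adjusted* item mean (other items held
  at their grand means) and is additionally shrunk by partial pooling; for
  strongly connected skills it can diverge noticeably from the raw
  per-physician item mean (pooled correlation ≈ 0.87 at the reference
  scale, lower for hub skills).
* Cross-sectional networks only: edges are associations across
  consultations, not temporal dynamics; no longitudinal vector
  autoregression.
* Purging by interval exclusion is not a sparsity prior; no lasso-type
  regularisation is offered.
* The node models use a Gaussian likelihood on 0–5 Likert outcomes;
  ordinal-likelihood variants are out of scope.
* Screening inherits the multiplicity behaviour of 27 simultaneous
  interval checks; with nine correlated parameters per model,
  multicollinearity makes single coefficients hard to interpret.
* No cross-validation: with ~30 physicians the models are validated by
  simulation recovery, not data partitioning.
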