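---
title: "Methods: Bayesian sex estimation for cremated remains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian sex estimation for cremated remains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cremsex)
```

## The problem

Cremation fragments, warps and shrinks bone. The pelvic and cranial
features that osteologists usually rely on for sex estimation rarely
survive a pyre, while robust postcranial articular fragments — radial
heads, tali, patellae, mandibular condyles — often do. `cremsex`
estimates the sex of a cremated individual from standardized linear
measurements (mm) of up to 21 such structures, taken on fully calcined
bone so that heat shrinkage is roughly homogeneous across the sample.
Because a single urn typically yields only one to three measurable
variables, and which variables survive differs from case to case, the
central requirement is tolerance to arbitrary missingness.

The reference parameters shipped with the package
(`italian_reference()`) encode per-sex summary statistics of a
Bronze/Iron-Age Italian cremation series (155 adults) whose sex labels
derive from gender-specific grave goods and urn iconography — a proxy
for biological sex, justified in high-gender-intensity burial
traditions but still a proxy; that caveat propagates to everything the
classifier learns.

## The model

For variable $v$ and sex $s \in \{M, F\}$ the measurement (after a
natural-log transform for two right-skewed variables) is modelled as
normal, $x_v \mid s \sim N(\mu_{vs}, \sigma_{vs}^2)$, with parameters
estimated by the sample mean and the $n-1$ standard deviation of the
training group. Given a case's observed subset $O$ and priors $\pi_M,
\pi_F$, the classifier combines the variables under conditional
independence (Gaussian naive Bayes):

$$
P(M \mid x_O) \;=\;
\frac{\pi_M \prod_{v \in O} f_{vM}(x_v)}
     {\pi_M \prod_{v \in O} f_{vM}(x_v) + \pi_F \prod_{v \in O} f_{vF}(x_v)}.
$$

Missing variables simply drop out of the product, so any subset from 1
to 19 variables yields a posterior. Two registry variables (axis
transverse diameter, talus head-neck length) show no significant
dimorphism in the training sample and are accepted as input but never
used. The default prior is 1:1 (adult sex ratio); 1.05:1 (sex ratio at
birth) is available and changes results only marginally, as the
likelihoods dominate.

All products are computed as sums of log densities, and posteriors are
clamped to $[10^{-12}, 1-10^{-12}]$: a single extreme measurement must
not collapse the posterior to an exact 0/1, both for numerical hygiene
and because the commingling diagnostics compare per-variable
posteriors that would otherwise saturate.

There is no modelling of correlation between variables. Skeletal
measurements of one individual are in reality positively correlated,
so joint posteriors from several variables are somewhat overconfident;
this is a documented assumption inherited from the method, and the
data generator can inject correlation to probe its cost.

## Dimorphism statistics

Per-variable dimorphism is screened with two-sample pooled-variance
t tests (Welch available as a companion), on the log scale where
flagged, at $\alpha = 0.05$ two-sided. Effect size is the
Chakraborty–Majumder index $D = 1 - \mathrm{OVL}$, where OVL is the
overlapping coefficient $\int \min(f_M, f_F)\,dx$ of the two fitted
normals, *each with its own standard deviation*. OVL is computed
analytically: equating log densities gives a quadratic whose real
roots are the crossing points; OVL is the sum of the matching normal
tail/interval masses. With equal variances this reduces to
$2\Phi(-|\mu_M-\mu_F|/2\sigma)$.

Using each group's own spread matters: for the lunate maximum length
(male 14.23/1.12 vs female 12.01/2.10) the exact two-crossing overlap
gives $D = 0.55$, while a pooled-SD shortcut gives 0.46. Two
numerical details proved necessary: interval membership is decided by
*log*-density comparison (raw densities underflow to a spurious tie
far in the tails), and the quadratic is solved with the
cancellation-free root formula (the naive formula loses ~6 digits when
the two standard deviations nearly coincide).

## Baselines

*Cut-off rule.* The univariate threshold is the density crossing
between the two means — the equal-prior Bayes boundary — falling back,
flagged, to the midpoint when very unequal spreads leave no interior
crossing. Values exactly at the threshold go to the female side so the
rule is total and deterministic. With several observed variables the
votes must be unanimous; any split is `ambiguous`. Published
historical cut-off values are deliberately not transcribed; thresholds
are re-derived from the reference parameters. Note one geometric
subtlety: with unequal variances the Gaussian posterior re-crosses 0.5
in the far tail (the wider distribution dominates again), where a
monotone cut-off necessarily disagrees with the posterior; the two
coincide on the region between the means, which is where real
measurements lie.

*Univariate logistic regression.* $\mathrm{logit}\,P(M\mid x) =
\beta_0 + \beta_1 x$ on the model scale, male coded 1, fitted by IRLS
(`stats::glm`, tolerance $10^{-8}$, 100 iterations). Complete
separation — non-overlapping classes, detected exactly, plus a slope
guard at $|\beta_1| > 50$ per model-scale unit — is reported as
non-convergence and prediction is refused rather than returning a
boundary fit. Confidence bands are Wald intervals on the linear
predictor, transformed; the band construction was not prescribed and
Wald is the documented choice. Multivariable logistic models are out
of scope: they cannot handle the missingness regime.

## Warnings: errors and commingling

Three rule-based diagnostics run on every prediction and never block
it:

1. **Outlier** — a measurement outside $\mu \pm 3\sigma$ of *both*
   sexes' reference distributions. Requiring both bands is a
   deliberate reading of an ambiguous rule: a value extreme for one
   sex but typical for the other is informative, not suspect.
2. **Inconsistency for few features** — with 2–4 contributing
   variables, any pair of equal-prior single posteriors differing by
   more than 0.33. The threshold "33%" is interpreted as an absolute
   probability difference of 0.33, consistent with its sibling rule
   being stated as 0.25.
3. **Inconsistency for several features** — with ≥5 variables, any
   single posterior deviating more than 0.25 from their median.

Single posteriors feeding rules 2–3 always use equal priors, even when
the joint posterior uses skewed ones, so the consistency check
reflects the data alone. Inconsistent per-variable evidence is the
package's commingling signal: bones of a male and a female mixed in
one deposit produce opposing posteriors. It is an indication for
re-examination, not proof of a second individual.

## Evaluation

`loocv()` refits the chosen predictor with each case held out; folds
that leave a variable with fewer than two reference observations in
either sex skip that variable, and cases left with nothing usable are
excluded and counted. Metrics use male as the positive class
(sensitivity = male recall). Post-hoc filtering declares cases whose
maximum posterior falls below a threshold (comparison inclusive,
"65% or more") ambiguous and recomputes accuracy over the retained
cases only, across the conventional ladder 50/65/75/85/90%. The 65%
threshold is the recommended reporting default: higher thresholds buy
little accuracy at a steep cost in classified cases. Reliability
curves bin $P(M)$ into ten equal-width bins and compare the mean
prediction with the observed male fraction. Screening is fixed once on
the full training set rather than re-run per fold: with 19 of 21
variables far below $\alpha$, per-fold re-screening would only add
noise at the margin.

One published performance figure is knowingly not reproduced: the
post-hoc F1 of 97.3 is arithmetically inconsistent with its own
precision (88.9) and sensitivity (85.7), which imply $\approx 87.3$;
it is treated as a typographical error.

## The synthetic generator

`generate_individuals()` emulates the training regime: per-sex normal
draws on the model scale (back-transformed to mm for log-flagged
variables), with each individual's observed-variable count drawn from
$\{1,\dots,5\}$ with weights $(0.35, 0.30, 0.20, 0.10, 0.05)$ — a
concrete encoding of "mostly one to three measurements" — and the
subset chosen uniformly among the 19 usable variables. Defaults use
the published Italian parameters, so the generator's dimorphism is the
real sample's. `generate_commingled()` splits each case's variables
between a male and a female donor, keeping ground truth.

What the generator does *not* emulate: the real co-occurrence
structure of measurements (which bones survive together, and that
well-preserved dimorphic variables like the radial head are observed
disproportionately often), within-individual size correlation (off by
default), inter-population differences, and measurement error. Tests
on synthetic data therefore validate the machinery — parameter
recovery, calibration of a well-specified model, warning behaviour
under known commingling — not field accuracy on real assemblages. In
particular, LOOCV on the synthetic emulation of the training sample
lands a few accuracy points below the published raw accuracy, exactly
because uniform variable availability discards the informative
co-occurrence pattern of the real data.

## Numerical and design choices

* Natural log for the two flagged transforms; log-scale parameters of
  the built-in model derive from published mm-scale summaries via
  $\mu_{\log} = \log(\text{mean})$, $\sigma_{\log} = \text{sd}/\text{mean}$
  (delta method), which matches the published log-scale means to
  printed precision.
* The suspect humerus trochlea measurement of one training individual
  is excluded at *measurement* level: the value leaves that variable's
  summary, the individual's other measurements stay.
* Variables with $n < 2$ in either sex (or zero spread) remain in the
  registry, are marked unusable, and are skipped with a notice.
* Model persistence is versioned JSON at 17 significant digits, giving
  bit-identical round-trips.
* Ties: posterior exactly 0.5 is always `ambiguous`; a measurement
  exactly at a cut-off threshold is female.
* Exported probabilities are written at 4 decimals; every output file
  embeds the package version and effective configuration as comment
  lines.

## Problem sizes used by the test suite

Property tests use 100–1000 random parameter draws; the overlap
analytic/quadrature agreement is checked to $10^{-6}$ on 1000 draws
and posterior log-domain arithmetic to $10^{-10}$. Parameter-recovery
and calibration checks draw 2000 synthetic individuals per sex (the
calibration band of 0.05 per bin is a seeded check — per-bin binomial
noise at this size is of comparable magnitude). The emulated
training-sample evaluation uses the published sample structure, 66
males and 89 females. These sizes are the package's chosen balance of
statistical resolution against a test suite that runs in about a
minute.

## Known limitations

Sex labels of the reference data are archaeological gender proxies;
the model is population-calibrated to Italian Bronze/Iron-Age material
(validated externally on Austrian Urnfield remains by its authors) and
should be re-fitted via `fit_reference()` for distant populations; the
independence assumption makes multi-variable posteriors overconfident;
and warnings are heuristics — they flag inconsistency, not identity of
individuals.
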