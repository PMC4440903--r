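---
title: "Methods: simulating and correcting regression toward the mean in deviance-based conformity designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and correcting regression toward the mean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtmconformity)
```

## The paradigm and why it needs a correction

In the deviance-based conformity task, a participant rates 180 items on a
1–6 Likert scale, learns after each rating how an ostensible group
supposedly rated the same item (a deviation of −2, −1, 0, +1 or +2 from
their own response; 30 occurrences of each nonzero value and 60 zeros, in
random order), and later re-rates all items. A presented group judgment
must stay on the scale, so when the participant's rating plus the drawn
deviation would fall outside 1–6, the deviation's sign is flipped before
display ("boundary reflection"). On a 1–6 scale with deviations of at most
2 the reflected judgment is always in bounds, which the code asserts rather
than handles; a zero deviation is never reflected.

The reflection rule makes the manipulated deviation a deterministic
function of the initial rating at the scale's edges: high ratings receive
downward deviations, low ratings upward ones. Since extreme measurements
regress toward the mean on re-test anyway, rating change as a function of
deviation mixes a genuine social-influence effect with a purely statistical
one. A control group whose deviations are drawn and reflected identically
but never displayed experiences the statistical component alone, and is the
basis of the correction.

## The correction model

All ratings are mean-centered within participant and session, which
removes session-level displacement and makes each participant's mean rating
change exactly zero. For item $i$ of control participant $k$, with
$c_{ik}$ the centered rating change and $r_{ik}$ the centered initial
rating, the package fits

$$c_{ik} = \beta_{1k} r_{ik} + \varepsilon_{ik}, \qquad
  \beta_{1k} = \gamma_{10} + \delta_{1k},$$

with $\varepsilon_{ik} \sim N(0, \sigma^2_\varepsilon)$ and
$\delta_{1k} \sim N(0, \sigma^2_\delta)$. Because the outcome is a
difference of two centered variables, the intercept is identically zero; it
is hard-constrained, not estimated. The fixed slope $\gamma_{10}$ is the
average RTM rate, and the corrected change for any item is
$\hat{s} = c - \gamma_{10} r$. The correction always uses the single fixed
slope — never per-participant slope predictions — because the estimated
average from the control group is the only quantity that transfers to
participants whose own changes are contaminated by the manipulation. BLUP
slopes are returned for diagnostics only.

Applying the correction to the control group itself is a falsification
check: if $\hat{s}$ still varied with the (suppressed) deviation beyond
chance, the correction would be removing the wrong thing. The acceptance
suite verifies that the type-I rate of this corrected control-group ANOVA
is nominal.

## Estimation

The marginal covariance of participant $k$'s changes is
$\sigma^2_\varepsilon (I + \lambda r_k r_k^\top)$ with
$\lambda = \sigma^2_\delta / \sigma^2_\varepsilon$. The REML criterion is
profiled over $\lambda$ alone: for fixed $\lambda$, the GLS slope and the
residual variance have closed forms through the rank-one inverse
$(I + \lambda r r^\top)^{-1} = I - \lambda r r^\top / (1 + \lambda
r^\top r)$, so the whole fit is a bounded scalar minimization on
$\log(\lambda + 10^{-10})$ over $\lambda \in [0, 10^3]$
(`stats::optimize`, tolerance $10^{-12}$). The boundary $\lambda = 0$ is a
legal solution, checked explicitly and reported as
$\sigma^2_\delta = 0$; ties prefer the boundary. REML is the default
criterion because it is the default of the reference mixed-model software
for this model class; full ML is available via `method = "ML"` and agrees
with REML within one standard error on well-conditioned data (tested).

The fixed slope is tested with $F = (\gamma_{10}/\mathrm{SE})^2$ on 1 and
Satterthwaite degrees of freedom: the variance of $\hat\gamma_{10}$ as a
function of $(\sigma^2_\varepsilon, \sigma^2_\delta)$ is differentiated by
central differences (relative step $10^{-5}$), and the components'
asymptotic covariance is twice the inverse of a numeric Hessian of the
$-2$ restricted log-likelihood (forward differences replace central ones
when a step would cross $\sigma^2_\delta < 0$). At the $\lambda = 0$
boundary the model is through-origin least squares and the residual
degrees of freedom $N - 1$ are exact, so they are used directly. The whole
fit — estimates, standard error, variance components, Satterthwaite df and
BLUPs — reproduces `lmer(c ~ 0 + r + (0 + r | participant))` with
`lmerTest` to at least five digits in the test suite, and matches a
brute-force full-matrix maximization of the same restricted likelihood by
a generic optimizer on toy data.

Exact fits (zero residual) are handled by flooring
$\sigma^2_\varepsilon$ at $10^{-30}$ so the reported variance stays
positive. Designs in which any participant has no variance in $r$, fewer
than two items, or fewer than two participants are rejected with explicit
errors.

## The data generator

The generator stands in for human data, which the paradigm's literature
does not deposit. Its model: item $i$ of participant $k$ has a stable
latent value $v_{ik} \sim N(\mu, \tau^2)$; session ratings are
$v + e_1$ and $v + e_2 + w_k d$, with occasion noise
$e \sim N(0, \omega^2)$, presented deviation $d$ (experimental group
only) and conformity weight
$w_k \sim N(\mu_w, \sigma_w^2)$. Occasion noise around a stable value is
precisely the mechanism of RTM: in continuous mode the population slope of
change on centered initial rating is $-\omega^2 / (\tau^2 + \omega^2)$,
which the tests verify empirically and use for parameter-recovery studies.

Defaults, chosen once as a realistic study configuration: 27 participants
per group and 180 items (the paradigm's standard scale); latent mean 3.5
(scale midpoint) and latent SD 1 rating unit; occasion noise derived so the
implied continuous RTM slope is −0.374, the control-group slope magnitude
the package's recovery studies target; conformity weight 0.15 rating units
per deviation unit with between-participant SD 0.05, a clearly detectable
but not saturating effect. These are generator calibrations, not estimates
from any dataset.

Further choices:

* **Latent values are drawn per participant**, not shared across
  participants, keeping item-level residuals independent within
  participants — the correction model treats items as exchangeable within
  participant and uses no cross-participant item structure. A
  `shared_items` flag exists for sensitivity analysis.
* **Discretization** rounds half-away-from-zero and clamps to 1–6,
  deliberately producing the floor/ceiling effects of real Likert data
  (and a steeper empirical RTM slope than the continuous closed form, as
  the worked example shows: −0.404 vs −0.374). Continuous mode exists so
  closed-form checks hold exactly.
* **Reflection in continuous mode** is applied against the rating
  projected onto the scale (round, then clamp), since presented feedback
  is a bounded design variable even when the simulated rating is not.
* **Seeding**: the master seed derives one deterministic substream per
  participant (an integer mix kept below $2^{31}$), so enlarging
  `n_per_group` never reshuffles existing participants, and the same seed
  reproduces the table byte for byte.
* The **deviation schedule** is an unconstrained uniform shuffle of the
  fixed multiset; the paradigm's descriptions impose no run-length
  constraints, so none are modeled. For item counts other than 180 the
  1:1:2:1:1 mix is scaled proportionally.

What the generator does *not* emulate: item-specific consensus (all
participants rating some faces high), participant-level scale-use styles,
fatigue or order effects, and any dependence of conformity on the level of
the initial rating. Passing tests therefore show that the estimator and
correction behave correctly under the stated generative model, not that
real rating data satisfy that model.

## Preprocessing and scoring conventions

* Binning to the three-level Deviation factor (*peers lower / equal /
  higher*) uses the **presented** (post-reflection) deviation in both
  groups; in the control group this is the determined-but-suppressed
  value. Zero-mean assertions use a tolerance of $10^{-9}$ rating units.
* Conformity scores correlate the change with the presented deviation at
  its five raw levels, not the binned factor. Control-group scores are
  computed against the suppressed deviation — they exist only for the
  falsification analyses.
* A participant with zero variance in either variable gets an undefined
  (NA) score with a warning and is excluded from aggregates; correlations
  of magnitude 1 are clamped to $1 - 10^{-12}$ before the Fisher-z
  transform (keeping $z$ finite at about 14.2) rather than dropped, so
  participant counts stay stable.

## Inference conventions

The mixed repeated-measures ANOVA uses the classical split-plot
decomposition. Sphericity is assessed by Mauchly's test on orthonormalized
contrasts of the pooled within-group covariance; when it rejects at
$\alpha = 0.05$, within-effect p-values are recomputed with degrees of
freedom multiplied by the Huynh–Feldt $\varepsilon$ (capped at 1), while
uncorrected df and $\varepsilon$ are reported alongside — the reporting
convention of the literature this package serves. Greenhouse–Geisser
$\varepsilon$ is returned for diagnostics. Effect sizes are generalized
eta-squared with every subject-related error stratum in the denominator,
so values are comparable across the mixed and single-group designs. The
decomposition, $\varepsilon$ values and Mauchly statistic are verified
against `aov` and `car::Anova` and against a loop-based sums-of-squares
oracle in the tests. Pairwise comparisons are paired t-tests with Holm's
step-down adjustment (`stats::p.adjust`); two-sample tests are
pooled-variance by design (the group sizes are equal and the literature's
reported degrees of freedom imply pooling); Cohen's d uses the sample SD
(one-sample), the difference SD (paired) or the pooled SD (two-sample).

## Problem sizes used in the checks

The acceptance suite runs the parameter-recovery study with 200 continuous
control simulations at 27 × 180 (slope within 3 SE of the closed form in
at least 99%), the self-falsification study with 500 null replicates at
the same scale (type-I rate within three binomial standard errors of
0.05), and the qualitative-pattern study with 100 discretized two-group
replicates. These sizes give the property checks adequate resolution while
keeping a full test run around a minute on one core.

## Known limitations

* The correction removes the *average* RTM component; if individual RTM
  rates correlate with individual conformity, the residual scores retain
  that coupling. The model quantifies slope heterogeneity
  ($\sigma^2_\delta$) but the correction deliberately does not use it.
* Under Likert discretization the RTM relation is mildly nonlinear near
  the scale boundaries, so a linear slope fitted on discretized control
  data absorbs an average of that nonlinearity; the falsification ANOVA
  on discretized data consequently sits slightly above the continuous-mode
  ideal.
* The hierarchical model assumes normal residuals; 1–6 Likert changes are
  discrete and bounded. At 180 items per participant the slope estimate is
  robust to this, but the variance components should be read as
  approximations.
* With generator defaults the simulated conformity effect is stronger than
  typical human effects; the defaults favor a well-identified test bed
  over matching any particular study's effect size.
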