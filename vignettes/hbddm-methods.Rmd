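---
title: "Dissociating cognitive and motor speed with a hierarchical drift diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating cognitive and motor speed with a hierarchical drift diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hbddm)
```

## The scientific problem

Timed neuropsychological assessments confound two different kinds of
slowing: slow information processing (a cognitive deficit) and slow motor
execution (a physical one).  The drift diffusion model (DDM) offers a way
to separate them.  In a two-alternative forced-choice task, noisy evidence
accumulates at mean rate $v$ (the drift rate) between two absorbing
boundaries separated by $a$; the accumulator starts at relative position
$z$, and everything outside the accumulation process — stimulus encoding
and the motor response — is summarised by the non-decision time $T_{er}$.
If drift rate is independent of motor demands, then a purely motor
manipulation (here: stiff versus soft response-button springs) should move
$T_{er}$ but leave $v$ untouched, while a cognitive load manipulation
(comparing strings of 3 versus 5 characters) should move $v$.  `hbddm`
implements the full analysis pipeline around that question: a synthetic
data generator for the 2 (spring) x 2 (set size) within-subject design,
the Wiener likelihood, hierarchical Bayesian estimation of nine candidate
parameter-by-condition structures, BPIC model selection, credible-interval
independence checks, posterior-predictive fit assessment, and behavioral
summaries.

## The likelihood

The density of first passage through one boundary at decision time $t$ is
computed with the standard small-time and large-time series
representations of the Wiener first-passage-time (WFPT) density, switching
automatically to whichever representation needs fewer terms for a
requested truncation error (default $10^{-7}$; `likelihood_config()`).
The diffusion coefficient is fixed at 1 — only the ratios of $v$, $a$ to
the noise scale are identified.

Across-trial variability enters three ways:

* **Drift** varies as $\mathcal N(v, sv)$ across trials.  This integral
  has a closed form (a Gaussian integral over the drift), which we use
  directly: it is exact and costs no quadrature nodes.
* **Starting point** varies uniformly over $z \pm sz/2$ and
  **non-decision time** uniformly over $T_{er} \pm st/2$.  Both are
  integrated by deterministic Gauss-Legendre quadrature
  (`quadrature_points` nodes per active dimension, default 11 for
  standalone density evaluation).  Dimensions whose parameter is 0 are
  skipped.

Model fitting (`fit()`) defaults to 5 quadrature nodes per dimension: for
the $st$ and $sz$ magnitudes this design produces (about 0.1), the
5-node density differs from a 21-node reference by less than 0.5%
anywhere, which is far below posterior uncertainty, while costing a fifth
of the 11-node rule.

Observed response times are modelled as a two-component mixture: with
probability $1 - p_{outlier}$ the WFPT density, with probability
$p_{outlier}$ a uniform contaminant on $(0, \text{rt\_ceiling}]$ whose
mass is split equally over the two responses (density
$1/(2\,\text{rt\_ceiling})$).  Following the study protocol the
contaminant probability is fixed at 5% and never estimated.  The support
of the contaminant distribution is not stated by the protocol; we use the
5.0 s response window, the only principled bound in the design, and make
it configurable.

**Response coding.**  We use accuracy coding: the upper boundary is the
correct response, so drift rates are positive and $z$ measures bias
toward correct responding.  The bias $z$ and the three variability
parameters are group-only nodes, shared by all subjects and all
conditions, in every candidate model.

## The synthetic-data generator

`generate_design()` reproduces the trial structure: two blocks (one per
spring condition, order counterbalanced across subjects), each opening
with 24 practice trials (balanced 12/12 across set sizes) followed by 150
experimental trials per condition cell, half match / half no-match, in
randomized interleaved order — 648 trials per subject, 600 experimental.
The exact per-block randomization constraints of the original task are
not documented; we impose exact balance and randomize order within the
practice and experimental segments.

`simulate_trials()` draws each trial's drift, start and non-decision time
from their across-trial distributions and integrates the diffusion path
by Euler-Maruyama steps (default $dt = 10^{-4}$ s).  At that step size
the joint distribution of simulated (response, RT) pairs agrees with the
numerically integrated likelihood to a Kolmogorov-Smirnov distance below
0.01 at $10^5$ trials (asserted in the test suite); halving $dt$ changes
nothing detectable at that sample size.  Trials that reach no boundary
within the 5 s window are emitted with a missing RT; at realistic
parameters they are vanishingly rare.  Practice trials are simulated with
the same parameters as experimental ones.

**Generating values.**  Recovery studies simulate from the fitted group
means of the restricted model (drift varies by set size only; boundary
separation and non-decision time vary by both factors), i.e. $v = 2.57 /
1.78$ for set sizes 3/5; $a$ = 1.78, 2.01 (soft) and 2.14, 2.20 (stiff);
$T_{er}$ = 0.58, 0.70 s (soft) and 0.62, 0.80 s (stiff).  Group-level
posteriors are all the study reports, so the remaining generator settings
are package choices, made once and documented here:

* Between-subject SDs 0.3 ($v$), 0.25 ($a$), 0.05 s ($T_{er}$) —
  typical of hierarchical DDM fits of practiced adult samples.
* Nuisance values $z = 0.5$ (the design is symmetric), $sv = 0.6$,
  $st = 0.1$ s, $sz = 0.1$.  With these values clean simulated data show
  about 96-97% accuracy and a response-time tail whose mean + 3 SD trim
  removes under 2% of trials, matching the magnitudes the empirical task
  reports.  Larger $sv$ produces noticeably heavier tails and trim rates
  well above anything observed.
* Contaminants: each trial is replaced, with probability
  `p_outlier = 0.05`, by a uniform RT over the response window and a
  fair-coin response; the flags live in a ground-truth ledger that the
  inference code never sees.

## Preprocessing

`preprocess()` applies, in the protocol's narrative order: (1) practice
removal; (2) participant exclusions — at-or-below-chance accuracy
(chance = 0.5 for this two-alternative task) in any single condition
cell, overall accuracy at or below the group mean minus 2 group SDs,
overall mean RT outside the group mean ± 2 group SDs, with group
statistics computed once before any exclusion; (3) per-participant RT
trimming — below 0.2 s or above the participant's mean + 3 SDs, with
thresholds computed in a single pass over all of that participant's
experimental trials pooled across conditions.  Whether the original
analysis computed its group statistics per condition or overall, and in
which order the rules ran, is not documented; our choices are explicit,
configurable at the function level, and the accounting report always
reconciles (trials in = practice + excluded-subject trials + trimmed +
retained).

One consequence matters for recovery studies: a mean + 3 SD trim applied
to data containing 5% uniform contaminants removes a multiple of what it
removes from empirical data, and the likelihood has no truncation
correction — the mixture component *is* the package's contaminant
treatment.  Recovery and model-recovery studies therefore fit the
practice-free, unfiltered experimental trials; the trimming rules are for
empirical-style use, where trim shares are small.

## Priors and sampling

Priors (`default_priors()`) are proper and weakly informative: group
means $v \sim \mathcal N(2, 3)$, $a \sim \mathcal N(1.5, 1)$ truncated
positive, $T_{er} \sim \mathcal N(0.4, 0.3)$ truncated nonnegative;
between-subject SDs half-normal with scale 1 ($v$, $a$) and 0.2
($T_{er}$); $z \sim \mathrm{Beta}(5,5)$, $sv \sim$ half-normal(2),
$st \sim$ half-normal(0.3) jointly constrained so every subject's
$T_{er} \ge st/2$, and $sz \sim \mathrm{Uniform}(0, \min(2z, 2(1-z)))$.

`fit()` samples by Metropolis-within-Gibbs with a centered
parameterization:

* **Group means** have truncated-normal full conditionals given the
  subject values and SDs and are drawn exactly (conjugate Gibbs).  With
  150-600 trials per subject the subject-level data are highly
  informative, the regime in which centered sampling mixes well; it also
  makes group-mean updates free of likelihood evaluations.  (A
  non-centered parameterization would instead couple every group-level
  move to a full-data likelihood pass.)
* **Group SDs and subject-level nodes** use single-site random-walk
  Metropolis.  A subject-node proposal only touches that subject's
  trials in the cells the node covers, so one sweep costs three
  likelihood passes over the data (one per parameter).
* **Group-only nuisance nodes** cost a full-data pass per proposal.  The
  bias $z$ is updated every iteration — it is strongly anti-correlated
  with the drift/sv block and starves the sampler when updated rarely —
  while $sv$, $st$, $sz$ and a fifth move rotate round-robin.  The fifth
  move is a joint scaling of $sv$ together with every drift node
  (subject values, group means, group SDs) by a common factor with the
  appropriate Jacobian: the posterior has a long ridge along which these
  rise together (choice accuracy constrains mainly their ratio), and the
  scaling move traverses it directly.
* Proposal scales adapt toward 44% acceptance during burn-in only, in
  windows of 50 iterations.

Initialization uses EZ-style moment estimates (accuracy, mean and
variance of correct RTs) per condition cell, averaged into the model's
node structure, with subject nodes started at the group values plus
jitter; if the likelihood is not finite at the start the fit
re-initializes with wider jitter up to a bounded retry count.  Defaults
follow the study protocol: 5000 iterations, 1000 burn-in, and two chains
rather than the protocol's single chain so that split-$\hat R$ is
defined.  The per-draw total deviance is recorded during sampling.

## Model comparison and checks

`deviance_components()` uses the classic plug-in definitions:
$\bar D$ is the mean posterior deviance, $p_D = \bar D - D(\bar\theta)$
with the deviance evaluated at posterior means, and

$$\mathrm{DIC} = \bar D + p_D, \qquad \mathrm{BPIC} = \bar D + 2 p_D.$$

The doubled penalty makes BPIC the more conservative criterion; lower is
better.  The plug-in evaluates subject-level nodes at their own posterior
means (the hierarchical-DIC convention of focusing the likelihood at the
subject level); a `plugin = "group"` switch substitutes the group means
instead.  Whether the original analysis plugged in at the subject or
group level is not stated; the default is the former.

`ci_overlap()` implements the independence check used to adjudicate the
drift-rate question: for a pair of condition posteriors (soft vs stiff
drift at each set size), does each 95% credible interval contain the
other posterior's mean?  Mutual containment is the criterion for "no
credible difference".

`posterior_predictive()` simulates replicate datasets of the observed
design from randomly drawn posterior parameter vectors (contaminant
mixture included) and compares observed 10/30/50/70/90% RT quantiles for
correct and error responses, per subject and condition, against the
replicate 2.5-97.5% envelope.  Cells with no error trials are reported
as missing, not zero.

## Behavioral statistics

`bf_model_comparison()` scores the four candidate effect structures
(spring, set size, both, both + interaction) against a subject-only null
on subject-by-cell means using the BIC approximation
$BF \approx \exp\{(\mathrm{BIC}_0 - \mathrm{BIC}_1)/2\}$ over
repeated-measures linear models.  This is a documented stand-in for
default-Cauchy-prior ANOVA Bayes factors, adequate for direction and
order of magnitude, not for reproducing published BF values digit for
digit.  It is scale-invariant in the response unit.  Pearson correlations
between subject-level posterior-mean parameters and assessment scores
(`correlation_matrix()`) carry an explicit caveat: hierarchical
shrinkage can distort such correlations, so they should be interpreted
with caution.

## Problem sizes and what recovery does (and does not) show

The package's scripted recovery study simulates 12 subjects with the
full 600-trial per-subject design (150 per condition cell) and fits with
the protocol's 5000/1000 iteration schedule on two chains; the test
suite uses smaller versions of the same studies (8 subjects, 100 trials
per cell, 2000-iteration chains for parameter recovery; 10 subjects at
the full 150 trials per cell for model recovery, where the BPIC penalty
gap needs well-identified subject-level nodes) so the full suite stays
fast.  The
per-subject trial count matters more than the subject count here: the
group-only variability parameters are identified by the total number of
trials, and their coupling with drift is what limits drift recovery.
At the scripted size the posterior means of the group drift, boundary
and non-decision nodes typically land within about 0.1 evidence units
(respectively 0.02 s) of the generating values; non-decision time is
recovered most sharply.  Recovery fits (and the scripted study) use
3-node quadrature for the $st$/$sz$ integrals — posterior means agree
with 5-node fits to within 0.03 at these variability magnitudes.  Two
caveats are worth stating plainly:

* The generating *sample* of subjects has a mean that differs from the
  group mean by $\sigma_{between}/\sqrt{N}$ — at 12 subjects that alone
  is 0.087 for $v$.  Recovery tolerances must be read against that
  floor.
* The across-trial variability parameters, $sz$ especially, are weakly
  identified at these trial counts; their posteriors lean on the prior,
  and their coupling with $v$ and $sv$ is the main driver of the
  residual spread in drift-rate recovery.  This mirrors what is known
  about full-DDM variability parameters generally.

The generator emulates the statistical structure the analysis assumes —
hierarchical normal heterogeneity, stationary parameters, uniform
contaminants.  Real data can violate all three (practice and fatigue
drifts, non-normal subject distributions, structured lapses), so passing
recovery here demonstrates internal consistency of the pipeline, not
validity of the model for any particular empirical dataset; the
posterior-predictive checks are the tool for the latter.

## Known limitations

* No truncation correction exists for RT-trimmed data; fit trimmed data
  only when the trimmed share is small (the empirical situation), and
  prefer fitting untrimmed data with the contaminant mixture otherwise.
* Bias and variability parameters cannot vary by condition, matching the
  candidate model space; models outside that space need other tools.
* The sampler is a random-walk scheme tuned for this model family; it is
  adequate at these problem sizes but no substitute for gradient-based
  samplers on much larger models.
* Bayes factors are BIC approximations, not default-prior ANOVA values.
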