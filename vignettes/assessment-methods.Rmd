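---
title: "Distinguishing self- from mutual assessment in dyadic contests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing self- from mutual assessment in dyadic contests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

When two parties fight over a resource — two animals over a territory, two
states over a disputed border — the weaker side usually loses, and it would
plainly do better to quit early. How does the loser decide when to give up?
Contest theory distinguishes two information regimes:

* **Self-assessment** (war-of-attrition family): each contestant persists
  until its own cost threshold is reached. The threshold scales with its
  fighting ability — *resource holding potential* (RHP) — so contest
  duration is set by the loser's RHP. Duration should *rise* with loser RHP
  and, more weakly, with winner RHP (strong losers take longer to exhaust,
  and winners of long contests tend to be strong because they outlasted a
  strong loser).
* **Mutual assessment** (sequential-assessment family): contestants compare
  themselves to the opponent and the weaker quits once the asymmetry is
  evident. Well-matched opponents need long to resolve the contest, so
  duration *rises* with loser RHP but *falls* with winner RHP.

A third mechanism, **cumulative assessment** (CAM), has self-determined
thresholds but lets opponents inflict costs on each other; it mimics the
mutual-assessment slope signature (duration falling in winner RHP) without
any information exchange. The sign patterns therefore support an asymmetric
inference: a *negative* winner slope is ambiguous (mutual assessment or
CAM), but *positive* slopes for both winner and loser RHP **rule mutual
assessment out**, because its diagnostic signal is duration declining in
winner RHP.

`contestRHP` implements the resulting two-step analysis for dyadic contest
tables — including interstate wars assembled from Correlates-of-War-style
files — together with a generative simulator that makes the whole pipeline
testable end to end.

## Step 1: which power measures are RHP correlates?

Candidate measures (for states: primary energy consumption, military
personnel, total and urban population, and the composite capability index
CINC) first have to earn the status of RHP correlates. For each contest one
side is designated *focal* and the other *opponent*; the relative power
difference
$$\mathrm{RPD} = \frac{P_i - P_j}{P_i + P_j} \in (-1, 1)$$
is computed from the focal side $i$'s perspective, and a mixed-effects
logistic regression of the binary outcome (1 = focal victory) on RPD is
fitted with crossed random intercepts for focal and opponent identity,
since the same contestant can appear in many contests. A measure passes the
screen when its slope is positive and the likelihood-ratio test against the
intercept-only model is significant. A significantly *negative* slope is
reported as anomalous, never as a correlate.

The focal/opponent labelling must carry no information about winning, or
the regression is circular. `assign_focal_roles()` lists contests by
duration (ascending, ties broken by contest id) and alternately designates
the winner focal and opponent, starting focal at rank 1. For an even number
of contests each role wins exactly half; `balance_check()` verifies the
counts and compares the duration distributions of focal- and opponent-won
contests (Welch t on log10 durations). The assignment is deterministic, so
reanalysis reproduces it exactly. Sort direction and the rank-1 convention
are arbitrary; both are fixed and documented so results are reproducible.

## Step 2: what drives contest duration?

For measures passing the screen, three Gaussian linear mixed models of
log10 duration are fitted — one each for winner power, loser power and the
winner-vs-loser RPD — with crossed random intercepts for winner and loser
identity. Winner, loser and relative power of one measure are usually far
too correlated for a joint multiple regression (`collinearity_report()`
quantifies this), which is why each predictor gets its own model. Each
slope is F-tested with Satterthwaite denominator degrees of freedom, and
the sign pattern is classified by `classify_assessment()`:

1. winner slope significantly negative **and** loser slope significantly
   positive → `mutual-or-CAM`;
2. both significantly positive → mutual assessment ruled out; if the
   loser's standardized slope exceeds the winner's → `pure-self-assessment`,
   otherwise `winner-dominated-attrition` (winners persisting beyond what
   victory strictly requires);
3. one side significantly positive and the other a positive trend
   (p < `trend_alpha`) → `mutual-ruled-out-attrition`;
4. otherwise `inconclusive`.

The relative-power slope never affects the category: a negative
duration–RPD association can arise spuriously under pure self-assessment,
so it is recorded in the verdict's rationale only. The rules are applied in
this fixed order, and any non-converged component model forces
`inconclusive` with a warning in the rationale.

Two interpretive choices deserve emphasis. *"Stronger association"* between
the winner and loser slopes is operationalized as a comparison of
standardized slopes (slope × predictor SD, on the common log10-duration
scale); comparing significance levels instead would conflate effect size
with precision. And the category names encode rule-out logic, not proof:
the diagnostic can rule mutual assessment out, but can never prove pure
self-assessment, because cumulative damage mimics mutual assessment's
signature.

Default thresholds are `alpha = 0.05` and `trend_alpha = 0.10`; the trend
band matches the convention of reporting 0.05 < p < 0.1 as a
non-significant trend.

## The mixed-model machinery

Both model families are implemented in the package behind one fitting
function, `cmm(formula, data, family)`, restricted to the model class the
analysis needs: at most two fixed predictors and one or two crossed random
intercepts.

* **Binomial** (victory models): the marginal likelihood integrates the
  random intercepts out by a Laplace approximation around their conditional
  mode, found by a penalised Newton iteration with step halving. The outer
  optimisation runs over the fixed effects and log random-effect standard
  deviations, from a fixed three-point multi-start grid (random-effect
  variance 0.1, 1, 4), so fits are deterministic. The Hessian of the joint
  log-density exploits the crossed-indicator structure (two diagonal blocks
  plus a co-occurrence block, factorized by Schur complement). In tests the
  Laplace log-likelihood and estimates are validated against 31-node
  adaptive Gauss–Hermite quadrature on single-factor fixtures, and the
  approximation error is far below inferential relevance in that regime;
  with all variance components at zero the fit reduces exactly to ordinary
  logistic regression. Apparent complete separation (unbounded likelihood)
  is flagged on the fitted object rather than silently returned.
* **Gaussian** (duration models): REML by default, with the fixed effects
  and residual variance profiled out analytically; the optimisation runs
  over log variance ratios with the same multi-start grid, evaluated in the
  random-effect dimension via the Woodbury identity. Variance components
  that reach the boundary are reported as exactly zero and flagged.
  Likelihood-ratio tests always compare maximum-likelihood fits; REML
  models are refitted by ML automatically, since restricted likelihoods are
  not comparable across fixed-effect structures.

For the duration F tests the denominator degrees of freedom use the
Satterthwaite approximation: the contrast variance $g(\phi) = c^\top
(X^\top V(\phi)^{-1} X)^{-1} c$ is differentiated numerically in the
variance parameters $\phi$ and combined with the inverse observed REML
information in $\mathrm{df} = 2 g^2 / (\nabla g^\top \mathrm{Cov}(\hat\phi)
\nabla g)$. Kenward–Roger is accepted as a request but falls through to
Satterthwaite with a note, and every test result records the method
actually used; the diagnostic consumes slope signs and approximate
p-values, for which the two approximations agree to well within decision
relevance (the df themselves agree with the reference Satterthwaite
implementation to ~0.03 on balanced fixtures). With every variance
component on the boundary the F test reduces exactly to the classical
regression F with $n - p$ denominator df.

Predictors are z-standardized before fitting by default (it conditions the
optimisation and makes slopes comparable across measures); slopes are
reported on both the standardized and raw scales, and all test statistics
are invariant to the choice.

## The generative simulator

`simulate_contests()` generates dyadic contest tables with the structure of
the real interstate-war data: a pool of states whose identities repeat
across contests (exercising the crossed random intercepts), five positive,
mutually correlated power measures per side, and a positive integer
duration in days. Latent RHP has a persistent between-state component
(log-normal — strictly positive and right-skewed, like national capability
data) and a contest-level component (`rhp_within_sd`) representing the
fluctuation of effective capabilities at the time a state enters a war;
measures are taken at the contest level, the analogue of year-of-entry
capability values. The within-state component is not a nicety: if state
power were perfectly persistent, the loser-identity random intercept would
absorb loser power completely — under attrition, duration *is* a function
of loser power — and the winner slope would vanish conditionally. Real
capability data vary between wars, and so does the generator.

The four mechanisms (each the simplest form that provably yields its
predicted slope pattern):

* `WOA`: persistences $T_k = a R_k^b \varepsilon_k$; the smaller $T$ loses
  and sets the duration. Duration rises with both sides' RHP, the loser's
  dominating.
* `SAM`: the stronger side wins with probability $\Phi(|\mathrm{RPD}|/s)$;
  duration $a\, e^{-|\mathrm{RPD}|/s} \varepsilon$ falls as the asymmetry
  grows — so duration rises in loser RHP and falls in winner RHP.
* `CAM`: WOA give-up times divided by $(1 + d\,R_{\mathrm{opp}})$; with
  $d = 0$ it reduces exactly to the WOA for the same random draws, and with
  $d > 0$ it reproduces the mutual-assessment signature without information
  exchange.
* `NULL`: fair-coin winner, duration independent of all powers — the
  diagnostic's false-positive control.

Defaults (per-measure loading 1 with log-scale noise 0.1; persistent RHP sd
0.4 and within-state sd 0.4 on the log scale; baseline 30 days; duration
noise sd 0.15; SAM sampling error 0.35; CAM damage rate 0.5) were fixed at
design time so that each mechanism's slope pattern is statistically
detectable at the validation scale of 200 contests from a 60-state pool —
the regime in which the recovery benchmarks below are meaningful — while
keeping the measures realistically right-skewed. They are study conditions,
not tuning knobs. Durations are rounded up to whole days, matching the
granularity of real war data (`round_days = FALSE` gives sub-day
resolution).

What the simulator does *not* emulate: assortative pairing (real
belligerents are often neighbours of similar capability), secular growth of
capabilities, coalition wars, measurement error correlated across measures,
and any within-contest escalation dynamics. Passing recovery benchmarks on
synthetic data therefore shows that the pipeline recovers the mechanisms
*under these generative assumptions*; it does not certify conclusions about
any particular real dataset.

## Validation harness

`recovery_experiment()` simulates replicate datasets under one mechanism,
runs the full two-step pipeline on each, and tallies verdicts;
`pipeline_validate()` wraps it for the three informative benchmark modes
and evaluates the tallies against pass thresholds (WOA →
self-assessment-family verdict in ≥ 90% of replicates and `mutual-or-CAM`
in ≤ 2%; SAM → `mutual-or-CAM` ≥ 90%; NULL → `inconclusive` ≥ 85%). The
validation default analyses the composite index (`cinc`) only: the other
four measures carry the same latent signal by construction, and runtime
scales linearly in measures. A measure that fails the victory screen is
tallied `inconclusive` — under the null mechanism the screen itself should
pass at roughly the nominal rate, which the harness also reports.

Replicate seeds derive deterministically from the base seed, so every run
is exactly reproducible. Problem sizes throughout (200 contests, 100
replicates per mode, 500 null replicates for the likelihood-ratio size
check at the 44-contest study scale) were chosen as the smallest scales at
which the Monte-Carlo error of the tallied rates is comfortably below the
decision margins they are compared against.

## Numerical and degenerate-input choices

* Optimizer: bounded quasi-Newton on the log-variance scale, gradient
  tolerance 1e-6, fixed three-point multi-start; all overridable via
  `cmm_control()`. If a likelihood-ratio comparison finds the reduced model
  above the full model, the full model is refitted from a wider fixed grid
  before the comparison is declared inconsistent.
* Variance parameters at the boundary are excluded from the Satterthwaite
  $\phi$ vector (they are not free parameters there); if every component is
  on the boundary the classical $n - p$ df are exact.
* `rpd(0, 0)` is a domain error, not 0/0; both-zero power pairs name the
  offending position.
* Duration day-count from dates is inclusive — a war starting and ending on
  the same date lasted one day — with the exclusive convention selectable.
* Missing capability values follow a per-measure policy by default: the
  dyad is dropped only from analyses of the affected measure. The
  alternative (`"drop"`) removes it entirely.
* Source-dialect sentinel values (−9, −8) are normalised to `NA` on read;
  sentinel month/day components of war dates are imputed to mid-year /
  mid-month and recorded in the load report, while a sentinel year makes
  the row a reported error.
* A state with several entry episodes in one war enters at its earliest
  entry date; war-level start and end are the earliest entry and latest
  exit across participants. "Transformed into another war" exits are
  treated per war, not per participant.

## Known limitations

* The assessment diagnostic is an exclusion test: `mutual-or-CAM` and the
  attrition categories bound what the data can say; none proves a
  mechanism.
* Satterthwaite df stand in for Kenward–Roger; on very small, unbalanced
  designs the two can differ visibly even when decisions do not change.
* The Laplace approximation degrades for binary responses with few
  observations per group and large random-effect variance; the quadrature
  cross-checks in the test suite cover the regime the pipeline operates in.
* Only dyadic contests are supported — no coalitions, no multi-party
  contests, no escalation-phase analysis.
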