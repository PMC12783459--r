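---
title: "Scoring decision-making expertise from arcade session logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring decision-making expertise from arcade session logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmxr)
```

## The measurement problem

A participant spends a fixed 30-minute budget in a virtual arcade of 21
machines spread over 5 rooms, trying to win as many tickets as possible.
The machines' payoff rates are unknown, heterogeneous, and partly
non-stationary: some games cap the number of plays (the mental rotation
machines allow two), and some pay diminishing yields on repeat plays.
Total tickets won is an overall performance measure, but it confounds
two abilities: being good *at* the games, and being good at deciding
*which* game to spend time in. The DMX score isolates the second
ability — the quality of exploration–exploitation time allocation —
from raw game skill.

## The DMX model

Every second of the 1800-second session is treated as a decision: stay
in the current game, or be on the way to another. The decision at
second $t$ is valued by how good the occupied game looks *given only
the experience accumulated strictly before* $t$:

1. **Experienced profitability.** For each game the participant has
   played, the profitability estimate is cumulative tickets earned in
   that game divided by cumulative seconds spent playing it (tickets
   are interpolated uniformly within a logged segment, since logs
   record per-segment totals).
2. **Imputation.** Games not yet sampled are assigned the arithmetic
   mean of the experienced profitabilities — the participant can only
   assume unexplored machines are, on average, like the ones tried so
   far. Before anything has been played, all 21 games are tied.
3. **Rank normalization.** The 21 values are converted to descending
   tie-averaged ranks (rank 1 = most profitable; two values tied across
   positions 12 and 13 both receive 12.5). Ranks always sum to
   $21 \cdot 22 / 2 = 231$. An alternative normalization — dividing
   each value by the sum so the shares add to 1 — is implemented
   (`sum_normalize()`, `normalization = "sum"`) but rejected as the
   default: once one game dominates, every other option collapses to a
   near-zero share and the score saturates.
4. **Valuation and aggregation.** The occupied game's rank $r_t$ maps
   affinely to a value $v_t = 100\,(21 - r_t)/20 \in [0, 100]$, and the
   DMX score is the mean of the 1800 per-second values.

The affine 0–100 convention is this package's documented choice: the
exact valuation table used in the original analysis is not public. The
convention is constrained by three facts — the score must be
order-isomorphic in rank, the uninformed all-tie state (rank 11) should
sit at the scale midpoint 50, and observed human scores average in the
low 50s with SDs near 11–14 on a 0–100 reading. Any strictly
decreasing affine map composed with the mean produces the same ordering
of participants, so correlation-level conclusions are unaffected by
this choice.

Two timing conventions matter and are fixed as follows. The estimate
used at second $t$ includes data strictly before $t$, so the first
second of any play is valued under the pre-play state (a session that
never leaves its first game therefore scores exactly 50 — it generates
no information against which its persistence could be judged). Travel
seconds are attributed to the destination game: the switch cost is part
of the decision to switch. Idle trailing seconds keep the previous
game's value.

## Cleaning rules

Raw logs carry three known recorder defects, each handled by
`clean_session_log()` and tallied in its report: a spurious trial row
emitted after the 1800 s limit (dropped); the final two summary rows
duplicated (the exact-duplicate pair is removed); and abbreviated
labels for the intermediate/expert Tower of Hanoi machines (mapped back
to catalog ids). A segment that *crosses* the limit is truncated at
1800 s with tickets prorated linearly — proration is the
least-assumption way to keep the partial play while honoring the rule
that nothing after the limit may influence the analysis. Cleaning is
total and idempotent.

## Psychometric summaries

`describe()` reports the battery used to judge whether a measure can
detect individual differences. The coefficient of variation is
$\mathrm{sd}/\mathrm{mean}$; for instruments whose minimum is not zero
(AOMTB: 11; NCS: −36) the adjusted variant divides by
$\mathrm{mean} - \mathrm{min}$ instead, otherwise a high floor would
masquerade as low relative spread. Skewness and excess kurtosis are the
bias-corrected sample statistics ($G_1$, $G_2$) that mainstream
statistics GUIs print; quartiles use linear interpolation (R type 7).
Normality is delegated to `stats::shapiro.test()`. Worth knowing:
the published adjusted CV of 0.108 for AOMTB is reproduced from the
printed mean/SD only to $10^{-3}$ (4.6/42.317 = 0.1087), because the
inputs were themselves rounded before printing; tests assert at that
tolerance rather than pretending to more precision than the inputs
carry.

## Meta-analysis

Correlations are pooled on the Fisher-z scale ($z = \operatorname{atanh} r$,
$SE = 1/\sqrt{n-3}$) and reported there, with a back-transform column
for convenience; means are pooled on their raw scale. `pool_fixed()`
implements inverse-variance fixed-effect pooling with normal CIs and
two-sided p-values. A second model, DerSimonian–Laird random effects
(`pool_effects(method = "dl")`), inflates the weights by the moment
estimate of between-study variance $\tau^2$ and reduces *exactly* to
the fixed-effect answer when $\tau^2$ truncates to zero.

Both are provided for a reason discovered during validation: with the
two studies' printed inputs, most published pooled values are
$\tau^2 = 0$ rows where the models coincide, but three published
quantities (the Tickets–NCS and DMX–AOMTB pooled correlations, and the
pooled Tickets mean with its confidence interval) are only reproduced
by the DL model. The package therefore defaults to the simpler
fixed-effect model, and `meta_table(..., method = "dl")` reproduces the
full published overall column. With two studies a random-effects
$\tau^2$ estimate rests on one degree of freedom and should be read as
"the published arithmetic", not as a recommended inference strategy.

## The synthetic world

`simulate_session()` and `simulate_cohort()` stand in for the VR
environment and the study samples; every analysis stage is testable
against them. The stated world is:

* **Catalog.** 21 games in 5 rooms; base rates are the quantiles of a
  lognormal(log 0.62, 0.5) — about 0.2 to 1.7 tickets/second — in a
  fixed scrambled order; the two mental rotation machines cap at 2
  plays; six games decay geometrically (factor 0.8 per completed play).
  True per-game reward magnitudes were never published, so the catalog
  is calibrated to printed summary statistics, not to real machines.
* **Sessions.** An agent repeatedly picks a machine (8 s travel per
  switch, including the walk from the lobby), plays for roughly the
  game's typical duration, and earns
  `round(skill × base_rate × decay^plays × duration × lognormal(0, 0.3))`
  tickets. Non-negative integer tickets with skill-proportional spread
  motivate the multiplicative noise. All randomness flows through one
  seed per call.
* **Policies.** `explore_then_exploit` samples unplayed machines for
  its exploration budget (900 s), then plays the best-experienced
  machine with probability `choice_accuracy`; lapses either perseverate
  in the current game or wander at random, per a `perseveration`
  tendency. `uniform_random_switcher`, `sticky_first_game`, and a
  true-rate `oracle` bracket the behavior space.
* **Cohorts.** Six latent traits (skill, selection ability, age, CRT,
  AOMTB, NCS propensities) are drawn from a standard MVN with a
  configurable correlation matrix. The default injects the qualitative
  structure the analyses look for: skill–selection 0.35, skill–CRT
  0.30, skill–age −0.25, AOMTB–NCS 0.30, CRT–NCS 0.25. Mappings:
  skill multiplier $e^{0.15 z}$; accuracy $\sigma(-2 + 2z)$ and
  perseveration $\sigma(1.5 - 1.5 z)$ in the selection trait;
  questionnaire items generated per instrument (CRT as Bernoulli items
  with logistic difficulties; Likert items as noisy discretizations,
  reverse-keyed items stored reversed so that scoring recovers them).

Calibrated against the studies' printed descriptives at n = 60–76,
default cohorts land at tickets ≈ 1500 (CV 0.33–0.38; published 0.324
and 0.374), DMX ≈ 56 (CV 0.24–0.32; published 0.208 and 0.276), about
12.6 unique games and 13.8 switches (published ≈ 13.1–13.5 and ≈ 18.2;
switch frequency is the one descriptive matched only qualitatively —
raising it further would push the DMX spread back out of its band).

What a green simulation test does *not* establish: that real
participants behave like these agents. The agents have no learning
curve within a game, no fatigue, no preference heterogeneity beyond
the two traits, and their ticket noise is stationary. The simulator
validates the *accounting* — that the scoring pipeline recovers, in
sign and rough magnitude, structure that is truly present — not the
psychology.

Two designed properties deserve emphasis. First, with uncorrelated
latent traits, tickets and DMX remain mechanically correlated within a
session (better selection raises both), so the null-recovery test
asserts near-zero correlations between session scores and
questionnaire/age scores, not among the session scores themselves.
Second, the true-rate `oracle` agent does **not** maximize DMX
(it averages ≈ 47): the score values consistency with *experienced*
profitability, and the oracle abandons a decayed machine whose
cumulative experienced rate still looks best. DMX is a measure of
information-consistent allocation, not of clairvoyant optimality.

## Numerical conventions and edge cases

* Ranking ties are exact floating-point equalities; the engine and the
  brute-force test oracle see identical tie sets because both derive
  rates from the same uniform within-segment interpolation.
* The engine is vectorized (cumulative 1800 × 21 matrices, ranks by
  column sweeps); a literal per-second loop in the test suite must
  agree exactly on short logs and to 1e−9 on scripted sessions.
* An empty or single-game log is valued 50 every second, not an error.
* A sum-normalization over an all-zero profitability vector is
  undefined as an operation (`sum_normalize()` errors); inside the
  scoring engine that state can only be the all-tie state and is
  valued at the 1/21 uniform share.
* `clean_session_log()` never errors; readers, by contrast, fail loudly
  with the offending column or row named.
* Fisher-z CIs use `qnorm(0.975)` ≈ 1.96; all printed comparisons are
  insensitive to the fourth decimal of the critical value.

## Limitations

Scale-level constants (the 0–100 affine map, the sum-variant scale
factor 50·21) are conventions, adequate for ordering and correlation
but not for comparing absolute scores against analyses that used a
different valuation. The reverse-keyed item identities for AOMTB are a
package convention (the published source does not list them); NCS uses
the common published keying of the 18-item short form. The AOMTB
response format is scored on six anchors (1–6) because only that
reading reproduces the instrument's printed 11–66 range, despite the
instrument sometimes being described as 5-point. Session-level
behavioral realism is limited as described above; in particular the
simulator should not be used to predict real switch-rate distributions.
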