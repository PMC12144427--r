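---
title: "Quantifying play-partner preferences in groups of juvenile rats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying play-partner preferences in groups of juvenile rats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(playpref)
library(dplyr)
```

## The problem

Juvenile rats housed in groups play-fight constantly, and the unit
interaction is the *nape attack*: one animal's snout contacts (or aims for)
the nape of a partner's neck. When six familiar males share an arena for a
20-minute session, each animal chooses, attack by attack, which of its five
potential partners to engage. `playpref` takes per-session logs of these
attacks — initiator, recipient, the recipient's defensive response
(no response, evasion, pin, or upright boxing), whether the defender
counterattacked (a *role reversal*), and how many partners were free at the
moment of the attack — and asks a chain of questions:

1. Is each group-day's distribution of play across partners distinguishable
   from every animal attacking its partners equally?
2. On days where it is, which directed dyads are preferred or avoided, and
   how strongly?
3. Are preferences reciprocal (play symmetry), stable across days, and
   concentrated on popular individuals?
4. What predicts being a preferred partner: play style (defensive tactics),
   play quality (role reversals, symmetry), proximity, or weight and
   dominance asymmetries?
5. Do apparent preferences survive a correction for partner availability?

The design emulated throughout is 8 groups of k = 6 males observed on
scored days 1, 3, 5 and 8 (postnatal days 30–40, the peak play period),
1200 s per session, with a round-robin tube test for dominance ranks and
dyadic proximity times recorded per day.

## The preference index

For initiator $i$ and recipient $j$ in a group of $k$ animals, with
$B_{ij}$ the attacks $i \to j$ and $B_i = \sum_j B_{ij}$, the partner
preference index is observed play over the equal-partner expectation:

$$I_{ij} = \frac{B_{ij}}{B_i / (k-1)}$$

$I = 1$ is chance; $I > 1$ more play than expected; $I \ge 2$ a strong
preference; $I \le 0.25$ avoidance. Two identities follow directly and are
enforced by tests to near machine precision: for every initiator with
$B_i > 0$ the mean of $I_{ij}$ over its $k-1$ partners is exactly 1, and
uniform play gives $I_{ij} = 1$ exactly.

```{r index}
m <- as_play_matrix(rbind(c(0, 20, 10, 10, 8, 2), matrix(0, 5, 6)))
thompson_index(m) |> filter(initiator == "A")
```

An initiator that launched no attacks has undefined indices and is flagged,
never silently dropped.

## Screening group-days for random play

Preference indices are only meaningful on days whose play distribution is
distinguishable from the equal-play expectation
$H_{ij} = B_i/(k-1)$. `mantel_screen()` measures the deviation

$$X^2 = \sum_{i \ne j,\; B_i > 0} \frac{(B_{ij} - B_i/(k-1))^2}{B_i/(k-1)}$$

and references it to a Monte-Carlo null in which each animal's $B_i$
attacks are redistributed uniformly at random over its $k-1$ partners
(9999 draws by default, add-one corrected, so $p \ge 1/(n_{perm}+1)$). A
small $p$ means play is significantly non-random; a day with $p \ge \alpha$
is *excluded* from all preference analyses, and the exclusion is carried
through the pipeline's bookkeeping. The alignment correlation $r$ between
the observed and expected matrices (reduced to dyadic dissimilarities
$d_{ij} = \max(B) - (B_{ij}+B_{ji})/2$) is reported descriptively.

This design was a genuinely open choice. The natural-looking alternative —
a label-permutation Mantel test correlating the two matrices' dyadic
dissimilarities — turns out to be confounded: because $B_{ij}$ scales with
$B_i$, the observed dissimilarities align with the expectation's row-total
structure *whatever* the preference structure, and in simulation that
construction flagged 24–46% of strongly structured days as "random" while
catching only 86% of truly uniform ones. The row-total-preserving
chi-square null separates the cases cleanly: measured over 500 uniform
group-days it excludes 93.8% (the correct $1-\alpha$ behaviour of a
fail-to-reject screen), while excluding 0 of 100 strongly structured days.
A day with no attacks at all raises a typed degenerate-input error rather
than returning a NaN.

## Symmetry, popularity, stability, dominance

*Symmetry* of a dyad is $1 - |B_{ij} - B_{ji}| / (B_{ij} + B_{ji})$: 1 is
perfectly reciprocal, 0 one-sided, undefined (flagged) for dyads that never
played. *Popularity* re-expresses each animal's outgoing proportions as
percentages: how much of each rater's play a target receives. Whether some
targets are consistently favoured is tested with a one-way
repeated-measures ANOVA over target identity (`popularity_anova()`), the
rater-day combinations acting as 20 repeated units, so the standard design
gives $F(5, 95)$; day-to-day change for one target uses its five raters as
units, $F(3, 12)$; group play totals across the study give $F(7, 21)$. The
engine is the classical two-way layout without replication
(`stats::aov`), $F = MS_{factor}/MS_{factor \times unit}$; sphericity is
deliberately not corrected by default (a Greenhouse–Geisser option exists)
so the printed dfs match the uncorrected convention, and Bonferroni
pairwise comparisons use the full family of level pairs (15 for six
targets).

*Stability* ranks each initiator's partners 1 (favourite) to 5 by the
proportion of play directed at them, and compares adjacent scored days:
today's favourite's rank yesterday, minus 1, is the favourite change
(0 = same favourite, 4 = yesterday's least favourite), and symmetrically
for the least favourite. Ties are broken by label order and flagged.
Ranks use proportions rather than raw counts, consistent with the
proportion-based networks; both are available from the same matrices.

*Dominance* comes from the tube test: every pair meets five times, a win
scores one point, ties score nothing, and animals are ranked by descending
tally (ties broken deterministically by label and flagged).

Daily *z-scores* of attacks initiated, $(x_i - \bar{x})/s$ within a
group-day, drive the above/below-the-group-norm heat maps; $|z| \ge 1.96$
is flagged as significantly above or below (the cutoff is configurable,
since "significantly above the mean" admits more than one reading), and a
zero-variance day yields flagged-undefined z-scores.

## Networks

`build_directed_network()` weights edges by the initiator's outgoing play
*proportions* (so edge weights are comparable between high and low
players) and sizes nodes by total attacks initiated;
`preference_network()` keeps only the strong ($I \ge 2$, solid) and
avoided ($I \le 0.25$, dashed) dyads. Sub-group structure is scored by
greedy weighted-modularity maximisation on the undirected total-play
network, with significance from permuting the 15 observed edge weights
across dyads (add-one corrected; the permutation p-values are verified
approximately uniform under weight-shuffled nulls). Eigenvector centrality
is computed per connected component (flagged when the session's network is
disconnected), normalised to a maximum of 1; dyads that never played carry
no centrality information and are treated as absent edges. Layouts are
deterministic (circular) so exports reproduce byte-for-byte.

## The two preference models

`build_feature_table()` assembles one row per classified directed dyad-day
(strongly preferred = 1, avoided = 0) on non-excluded days: the partner's
attack frequency toward the focal animal; the percentage of the focal
animal's attacks the partner answered with no response, evasion, or a pin,
and the percentage ending in a role reversal; the dyad's symmetry and
proximity seconds; and the focal-minus-partner weight (g) and
dominance-rank differences. A classified dyad with zero attacks at the
partner has undefined percentages; such rows are dropped with a logged
warning. `fit_binary_glmm()` then fits logistic mixed models by Laplace
approximation (`lme4::glmer`): play style/quality with a random intercept
for the initiating animal, and the dyadic-asymmetry model with crossed
random intercepts for initiator and partner (the natural reading when both
identities repeat across rows). Predictors enter untransformed, so odds
ratios are per unit (per percentage point, per gram, per rank). Reported
per effect: estimate, SE, $z$, two-sided $p$, OR $= e^{\hat\beta}$, and
Wald limits $\hat\beta \pm 1.96\,SE$ on both the estimate scale and the OR
scale. When every random-intercept variance estimates at the zero
boundary, the model falls back to an ordinary logistic fit and records
the fallback; complete separation raises a typed error suggesting a
penalized fit rather than returning absurd coefficients.

## Availability correction

Because two playing rats are unavailable to everyone else, apparent
preferences could be artefacts of who happened to be free.
`availability_adjusted_counts()` keeps only attacks launched while all
five partners were available, retallies the directed counts, and checks
each classified dyad against the initiator's median adjusted count across
its five partners: preferred dyads should sit above it, avoided dyads
below. Ties at the median count as failures (conservative) and are
flagged. `availability_sign_tests()` summarises each class with an exact
two-sided binomial test at $p = 1/2$
($p = \min(1,\, 2\min(P(X \le s), P(X \ge s)))$, computed by direct
summation).

## The synthetic study generator

`simulate_study()` generates the full study design so every stage is
testable without any recorded data. Its defaults are the study conditions,
set once:

* 8 groups × 6 males × days 1, 3, 5, 8; 1200-s sessions.
* Attack rates: one latent rate per animal, uniform on 20–60
  attacks/session; per-day counts Poisson around it.
* Partner choice: each animal's weight vector over its 5 partners is a
  symmetric Dirichlet draw, concentration 0.8 by default (strong
  idiosyncratic preferences; `Inf` gives exactly uniform choice), with
  optional planted directed dyads forced to a given weight (held fixed
  across days).
* Tactics: recipients whose weight from the initiator is at least 0.4
  (twice the uniform share — a strong preference in expectation) draw
  responses from the preferred-partner profile (29.58% no response,
  31.61% evasion, 30.53% pin, remainder boxing; role reversals 47.28% of
  attacks); all others from the non-preferred profile (14.81/29.63/11.11%,
  role reversals 2.38%). Role reversals are sampled only among answered
  attacks — an ignored attack cannot be counterattacked — with the
  conditional probability derived from the configured marginal.
* Day-to-day drift: each day's weights are independent log-normal jitters
  (sd 2 on the log scale) around the animal's fixed base preferences.
  Jittering the base rather than the previous day avoids perturbations
  compounding into one-hot vectors; at the default the median
  favourite-partner rank change between adjacent scored days is 1, i.e.
  favourites move by a rank or two while each animal's underlying profile
  stays put.
* Availability: 60% of attacks occur with all five partners free; of the
  rest, 97% still have at least two partners free, making the overall
  at-least-two marginal about 98.8%.
* Proximity: truncated normal, mean 287 s, sd 60 s (back-derived from the
  reported dyad-class means and standard errors).
* Body weight: normal, mean 110 g, sd 10 g — a realistic spread for male
  rats in this age window; the source tables report only weight
  *differences*, so the level is the package's own choice.
* Tube test: Bradley–Terry-style wins on latent gamma strengths, 5 trials
  per pair, 5% ties.

What the generator does *not* emulate: spatial movement (proximity seconds
are drawn, not derived from trajectories), occupancy dynamics
(availability is an independent per-attack draw, sufficient to exercise
the correction but not a queueing model of who is busy), bout structure
within sessions, and any developmental trend across days. Passing tests on
these synthetics therefore demonstrate that the *estimators and bookkeeping*
behave as specified — identities, calibration, power, coverage — not that
real rat groups satisfy the generative assumptions.

## Numerical choices and edge cases

* Permutation p-values always use the add-one estimator; with $n_{perm}$
  permutations no p can fall below $1/(n_{perm}+1)$.
* Classification boundaries are closed exactly as stated: strong at
  $I \ge 2$, avoided at $I \le 0.25$.
* Zero-attack rows, zero-play dyads, zero-variance days and empty
  matrices are flagged or raise typed errors (`playpref_*_error`); no
  stage returns silent NaNs.
* Mean squares at rounding-noise level (relative to the response scale)
  are treated as structural zeros so constant data give $F = 0$, not 0/0.
* Dominance and preference-rank ties break by label order and are flagged.
* All randomised stages take explicit seeds; the pipeline derives distinct
  per-group-day sub-seeds from the master seed, and a rerun with the same
  config is byte-identical.

## Problem sizes used in the tests

The shipped test-suite calibration experiments use: 500 uniform group-days
for the screen's type-I regression constant (frozen at 0.938 ± 0.03),
100 planted group-days for recovery (planted dyads re-detected as solid
edges in ≥ 80%, screen exclusions ≤ 10%), 100 replicates at 200 rows for
GLMM sign recovery, and 500 replicates for Wald-CI coverage
(measured 94.8%). These sizes keep the default suite comfortably
reproducible on a single CPU while leaving the binomial noise on each
calibrated rate well inside its test band.

## Known limitations

* The screen's exclusion decision is a fail-to-reject rule; on very low
  play volumes it will (correctly) exclude days simply for lack of power.
* The repeated-measures popularity ANOVA treats rater-day combinations as
  exchangeable units, as the printed $F(5, 95)$ design implies; it does
  not model rater identity separately from day.
* The GLMM acceptance surface is sign recovery and CI coverage on
  synthetic rows; reproducing the source tables' third-decimal
  coefficients would require the original deposited data.
* Day labels outside the scored set {1, 3, 5, 8} are rejected unless
  explicitly allowed, and overlapping bouts are represented only by their
  onset times.
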