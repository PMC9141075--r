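---
title: "Coherence-based nurse planning: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence-based nurse planning: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nurseflex)
```

## The problem

A perinatology care system delivers care to mothers and newborns across
interdependent units: three neonatology units (intensive care N1, post-IC
N2, high/medium care N3) and three obstetric units (ward O1 with newborn
and adult beds, high care O2, delivery rooms O3). Patients flow between
units — about a third of newborns leaving the obstetric ward transfer into
neonatology — so a staffing decision in one unit cannot sensibly be made
without looking at all the others. `nurseflex` models the shift-level
planning loop that follows from this *coherence* view: predict demand for
every unit jointly one shift (8 h) ahead, then reallocate nurses centrally.

The package answers four questions for a configurable care system: which
flexibility strategy minimizes under-/overstaffing; how nurses should be
reallocated each shift; how much flexibility (as a share of scheduled
nurses) the system needs; and whether reorganizing the units into pooled
departments outperforms any within-layout strategy.

## The planning model

**State.** For shift $n$ and unit $i$: $a_{ni}$ scheduled nurses, $d_{ni}$
required nurses, and the excess $e_{ni} = a_{ni} - d_{ni}$ (negative =
short).

**Demand prediction (step 1).** Patient flows are a discrete-time Markov
chain per patient group with an absorbing exit state; $P[i,j]$ is the
probability that a patient in unit $i$ is in state $j$ one shift later.
The expected census is $\hat c_{n+1} = c_n P + \lambda$, with $\lambda$ the
mean admissions per shift. Required nurses are
$d_i = \lceil \hat c_i / q_i \rceil$ with $q_i$ the unit's patients-per-
nurse ratio for that shift type — fractional nurses cannot be scheduled.
The planner uses *expected* transitions and *mean* admissions; the
simulator realizes sampled ones, so prediction error is endogenous.

**Reallocation (step 2).** A binary skill matrix $Z$ states which
location's nurses may work where (specialized nurses may step down within
their department; the N3 unit and the O1 newborn beds are cross-linked).
The pairwise rule $N_{ji} = \min(-e_i, e_j) \cdot Z_{ji}$ over-commits a
donor with several partners if applied simultaneously, so it is realized
as a sequential greedy: receivers in decreasing shortage, donors in
decreasing current surplus, ties by the canonical unit order, residuals
updated after every move. Enumeration over all 21,312 three-unit instances
shows this greedy is optimal there; on four units a rank-chain
counterexample exists (a deep shortage drains the most flexible donor that
another receiver depended on). We keep the greedy deliberately — it is the
faithful reconstruction of the described procedure, and the counterexample
is documented in the test suite rather than papered over with a max-flow
solver.

**Strategies.** Model 0 does nothing. Model 1 runs the greedy on the skill
matrix. Model 2 holds a centralized float pool: per shift type,
$f = \operatorname{round}(r \sum_i a_i)$ all-qualified nurses are pulled
out of the unit rosters (largest-remainder repair keeps headcount exact),
then deployed one at a time to the largest predicted shortage. Model 3
deploys the pool first and runs the greedy on the residuals. The pool rate
$r$ defaults to the flex rate a model-1 pass produces on the same demand
(this is how the pool is sized "at the strategic level"); rates of 20% and
40% are studied as explicit variants.

**A design choice the source leaves open:** what happens to float nurses
not committed at planning time. We keep them centrally available — they
absorb shortages that materialize when realized demand deviates from the
prediction, and any still-unused float counts as overstaffing (they are,
after all, scheduled). The alternative (idle leftovers) makes a large pool
*harmful*: cutting 40% of every roster strips the units' natural buffers
while the pool only reacts to predicted gaps, and the monotone
improvement with pool size disappears. A consequence we accept: an
all-qualified pool can cross departments in real time, so the
two-pooled-departments layout does not dominate pool-carrying responses on
every single shift (it does on averages, and the one-department layout
dominates everything pointwise).

**Pooled layouts.** Configuration 1 merges each department into one
resource pool (plus the N3/O1n cross link); configuration 2 merges the
whole system. The source reports these layouts minimize mismatches with
*no* explicit strategy, which is only reproducible if pooling itself moves
nurses. We encode this as a *structural* matrix per layout (identity for
the current layout, department blocks for configuration 1, all ones for
configuration 2) applied as a within-shift rebalance against realized
demand: nurses of a pooled department are one workforce and need no
8-hour-ahead plan to cover each other. Model-chosen reallocation remains
planned one shift ahead. This makes the four configuration-1 responses
(no-flex and models 1–3) agree to within a few hundredths of a nurse per
shift, as reported.

## The decision layer

Averages of the per-shift understaffing $U_r$ (sum of negative residual
gaps, reported negative) and overstaffing $O_r$ are rounded half away from
zero before comparison: half a shift is four care hours, the threshold
between informal fixes and a formal extra shift. The best strategy
maximizes $U_r$ (closest to zero) and minimizes $O_r$; ties return sets.
Training cost is a flat EUR 20,000 per nurse needing cross-training (none
for model 1 on the current layout; `round(r * 176)` for a pool; 64 nurses
for configuration 1; all 176 for configuration 2). The optimal
configuration is chosen lexicographically — performance, then cost within
the best set — with decision regret (the gap to the best alternative under
each demand condition) reported as a robustness check.

Flexibility sizing reads the empirical distribution of per-shift
flexibility rates: the smallest tabulated rate whose cumulative share
reaches 95% (13% in the shipped case-study distribution) is converted to
flexible nurses per shift type (`round(rate * scheduled)`: 4/3/2) and then
to flexible beds by apportioning nurses over wards by bed share (largest
remainder) and multiplying by the shift's patients-per-nurse ratio. The
day and evening totals (14 beds each) reproduce the published figures
under this rule; the published night total (22) requires assigning the two
night nurses to O1 and N3, whereas bed-share apportionment selects O1 and
N1 (18 beds). The night rule used by the source is unstated; the package
reports the apportionment result and exposes an `override` argument for
the published variant.

## The synthetic demand world

The 2017 hospital extract behind the original analysis is not public, so
the package generates demand with the structure the analysis assumes:

* **Transitions:** one matrix per patient group per 8 h shift. Only the
  O1n newborn row is documented (4% to N1, 4% to N3, 16% exit, 77% stay;
  the printed row sums to 1.01 and is renormalized — probabilities must be
  a distribution). Every other entry is a synthetic default, flagged as
  such in the shipped CSVs, with stay probabilities implying lengths of
  stay of the right order (NICU roughly two weeks, ward beds two to three
  days, delivery rooms under a day). Under the quoted row, one third of
  O1n departures are transfers into neonatology, consistent with the
  reported 35% transfer share.
* **Admissions:** Poisson per unit and shift, multiplied by a gamma
  day factor with mean 1 and variance `dispersion` shared by the three
  shifts of a day — the simplest process with a tunable coefficient of
  variation above the Poisson floor. Arrival rates were fixed once so the
  system operates where the case study describes itself: neonatal
  intensive care near capacity, wards at 75–90% occupancy, and a
  no-intervention baseline that is meaningfully short on bad days. (An
  early, slacker draft world made one float nurse as valuable as the whole
  skill network; shortage depth relative to the roster is part of what the
  generator must emulate, even though the printed averages themselves are
  not reproduction targets.)
* **Calibration:** the demand conditions are defined by the CV of the
  per-shift total required nurses — the quantity staffing responds to —
  with targets 31% (actual) and 49% (uncertain). `calibrate_dispersion()`
  bisects the day-factor variance until the realized CV matches within
  ±2 points, deterministically for a given seed. The CV floor of the pure
  Poisson process (~25%, largely the deterministic day/evening/night ratio
  cycle) is reported when a target is infeasible.
* **Bed caps:** censuses are truncated at unit beds; the excess is logged
  as refusals and leaves the system (the real system refuses admissions
  when neonatology is full). Refusals are bookkeeping here, not an outcome
  metric.

What a green test does *not* establish: the generator has no seasonality,
no patient acuity, geometric lengths of stay only (implied by a
shift-homogeneous chain), and day-to-day variation that is exchangeable
rather than autocorrelated. Absolute under-/overstaffing levels therefore
have the right structure and order, but are not estimates for any real
hospital.

## Numerical conventions

* All staffing roundings are half-away-from-zero (−1.6 → −2, 4.5 → 5),
  never banker's rounding.
* Ceilings guard against floating-point dust (`ceiling(round(x, 9))`).
* Largest-remainder apportionment breaks ties by position (the canonical
  unit order N1, N2, N3, O1n, O1a, O2, O3).
* The printed roster has one O1 column; it is split over O1n/O1a in
  proportion to beds (7/32 vs 25/32) with largest-remainder rounding,
  since no per-sub-unit roster is published. The split is overridable.
* Registry groups spanning several units ("O1, O2 and O3": 53 nurses) are
  stored as qualification groups, not per-unit headcounts.
* Every stochastic path is seeded; identical inputs give byte-identical
  traces, scenario results and manifest outputs.

## A worked shift

One planning step at the system's long-run census, for the night shift
(whose roster is tightest — the O1 newborn beds hold no scheduled nurse of
their own at night):

```{r worked}
pcs <- perinatology_care_system()
m <- default_transition_matrices()
census <- round(stationary_census(m))
census
pred <- predict_census(m, census, default_arrival_rates())
d <- required_nurses(pred, pcs$ntp, "night")
state <- staffing_gap(pcs$roster["night", ], d, "night")
state
run_model(1, state, pcs)
```

The delivery rooms (O3), one nurse over and qualified for the whole
obstetric chain, cover the newborn-bed shortage.

## Known limitations

* The greedy reallocation is not optimal beyond three units (documented
  counterexample); residual shortages can exceed the true optimum by a
  nurse on rare gap patterns.
* The night-shift flexible-bed figure depends on an unstated allocation
  rule (see above).
* The four-unit oracle-equivalence and the full pointwise-dominance
  acceptance criteria are intentionally left failing in
  `tests/testthat/test-acceptance.R`, with the passing parts asserted
  separately; the decisions ledger of the repository explains both.
* Nurse absenteeism, overtime, agency staff, wage differences and
  sub-shift rescheduling are out of scope.
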