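---
title: "Sitting-bout pattern metrics: model, thresholds and design computations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sitting-bout pattern metrics: model, thresholds and design computations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitpattern)
```

## The measurement model

A wearable posture monitor classifies each 30-second epoch of the day as
sitting, standing or light activity; epochs without device data are
non-wear. Sedentary behaviour is operationalized as the SITTING state
(the device does not separately code lying or reclining, so SITTING stands
for all sedentary postures), and a *bout* is a maximal uninterrupted run of
one state, measured in minutes at 0.5-min resolution. Day boundaries are
local midnight: a run crossing midnight is cut, because all downstream
metrics are per-day. Time zones and daylight-saving arithmetic are out of
scope; timestamps are naive local time on a 30-s grid anchored at midnight,
and off-grid timestamps are rejected rather than resampled, since silent
resampling would hide data corruption. Gaps in a record are materialized as
explicit NON_WEAR epochs rather than dropped, so day lengths are well
defined and wear time is always visible in the data.

## The SSSB statistic

Total daily sitting time ignores *how* sitting accumulates. To capture the
pattern, the daily sitting bouts $d_1, \dots, d_k$ (minutes) are squared
and summed:

$$\mathrm{SSSB} = \sum_{i=1}^{k} d_i^2 \quad [\min^2].$$

Squaring makes the statistic convex in bout splitting: for any split
$d = a + b$, $(a+b)^2 > a^2 + b^2$, so interrupting a sitting bout always
lowers SSSB. For a fixed daily total $T$ the statistic ranges from $T^2/k$
(all bouts equal) to $T^2$ (one uninterrupted block) — it penalizes
prolonged sitting while being insensitive to the same total split into
short bouts. The healthy/unhealthy cutoff is the *median SSSB pooled over
all valid person-days* (not per participant); `derive_cutoff()` uses
midpoint interpolation for even counts, the most common convention. The
default cutoff of 18.8e3 min² is carried as a configurable threshold; its
relation to health outcomes is not established and is outside this
package's claims.

## Daily subobjectives, wearing days and the weekly goal

A *wearing day* has at least 6 h (360 min, inclusive) of non-NON_WEAR data.
Three daily subobjectives are evaluated on each day:

| flag        | rule                                        | boundary  |
|-------------|---------------------------------------------|-----------|
| `sit_ok`    | sitting < 480 min                           | exclusive |
| `active_ok` | standing + light activity ≥ 240 min         | inclusive |
| `sssb_ok`   | SSSB < 18.8e3 min²                          | exclusive |

The boundary semantics follow the program's wording ("less than 8 hours",
"a minimum of 4 hours", "below" the cutoff); where the wording is also
stated elsewhere as "maximum 8 hours" we keep the exclusive bound and
expose it via `thresholds()`, so a user can flip the semantics at exactly
480 min if they prefer the inclusive reading. SSSB is computed over the
whole wearing day, not working hours only, because the weekly goal counts
all wearing days including weekends.

The weekly *program goal* is met when all three subobjectives hold on at
least 30% (inclusive) of the valid wearing days of an ISO calendar week
(Monday–Sunday). A week needs at least one valid wearing day to be
evaluable — the minimum is configurable (`min_valid_days`), since the
required number of baseline days is not fixed by the program definition —
and a non-evaluable week carries `goal_met = NA`, never a silent `FALSE`.
At the cohort level a participant's goal attainment over a multi-week
window is an explicit aggregation rule (`all-weeks` by default, the
conservative choice; `any-week` and `majority` are selectable), because a
weekly goal does not by itself define a participant-level event over
several weeks. The resulting proportion of participants is the event rate;
at baseline it is the control event rate that enters the risk difference
and NNT.

## Bout-duration profiles

`bout_duration_profile()` bins each sitting bout's full duration into
duration intervals (default edges 0, 10, 20, 30, 45, 60, 90 min, last bin
unbounded; the edges are configurable plumbing, not a canonical choice) and
averages per-day bin totals within the healthy and unhealthy SSSB strata,
counting days without any bout in a bin as zero. Interval bins — rather
than cumulative thresholds — are used because they give the conservation
identity exactly: every bout lands in exactly one bin, so the per-stratum
bin values sum to the stratum's mean daily sitting time; the area under
the profile *is* the average total daily sitting time. The first bin edge
must be 0 for the identity to hold.

## The synthetic-data generator

Real streams are not distributed with the package; a seeded generator
stands in for them and doubles as the test bed. A day is an
alternating-renewal (semi-Markov) process over the three wear states: an
embedded chain without self-transitions picks the next state, and each
visit dwells for a random duration from that state's bout-duration
distribution, discretized to 30-s epochs by rounding half-up with a
minimum of one epoch (this biases very short bouts upward — intentional
and documented, as the device cannot emit sub-epoch bouts). Epochs outside
the daily wear window (default 08:00–22:00) and entire non-worn days
(default 5 worn days per week, chosen at random within each week) are
NON_WEAR.

Dwell times are lognormal by default: occupational sitting-bout
distributions are strongly right-skewed, and the heavy tail is exactly
where healthy and unhealthy patterns differ. The two presets were
calibrated analytically, once, from the semi-Markov occupancy formula
$\mathrm{occ}_i \propto \pi_i m_i$ (embedded stationary distribution
$\pi$, mean dwells $m$):

* both presets have sitting occupancy 0.565 of the 840-min window
  (≈ 475 expected sitting min/day), so days straddle the 480-min
  subobjective the way a desk-working cohort's do (subobjectives met on
  roughly half of the days) and the two presets are indistinguishable in
  *total* sitting time;
* the healthy preset sits in short bouts (lognormal, meanlog log 12,
  sdlog 0.7; ≈ 7 expected min/day in bouts over 90 min), the unhealthy
  preset in long heavy-tailed bouts (meanlog log 25, sdlog 0.9; ≈ 140
  expected min/day over 90 min) — an order-of-magnitude contrast in
  long-bout mass at matched totals.

Reproducibility follows a stated seed-splitting rule: a master seed drives
`sample.int()` draws of per-participant sub-seeds (in participant order),
and each participant draws per-day sub-seeds the same way, so any single
day can be regenerated without regenerating the cohort. The generator
emulates the *structure* the analysis assumes — epoch grids, wear windows,
bout-length mixtures — but not circadian rhythm within the day, autocorrelated
day-to-day behaviour, or measurement error in posture classification;
passing tests therefore validate the analysis machinery, not any claim
about real cohorts.

## Trial-design computations

The rollout assigns five groups of 40 participants to staggered starts
(7-week lag). Each group contributes one measurement occasion and one
group contributes both baseline and post measurement; with retention $r$
the analyzable sample is

$$n = \lfloor s\,(g + u)\, r \rfloor = \lfloor 40 \times (5 + 1) \times 0.8 \rfloor = 192,$$

a reconstruction of the published accounting in which $g$, $s$, $u$ and
$r$ are all parameters rather than hard-coded. Cohen's $d$ uses the pooled
SD and the large-sample standard error
$se^2 = \frac{n_1+n_2}{n_1 n_2} + \frac{d^2}{2(n_1+n_2)}$.
`simulate_design_precision()` draws normal outcomes (no outcome
distribution is prescribed by the plan, so normal is the default model)
for the group-measurement contributions, splits them between baseline and
post sides (the dual group supplying both), and reports the Monte-Carlo
distribution of $d$ and its 95% CI half-width. "Accurate to about a
quarter of a standard deviation" is ambiguous between SE, CI half-width
and estimation error; we read it as the CI half-width and check a band
(0.2–0.35 SD at $n = 192$), not a point. The exact pairing of stepped-wedge
contrasts ("last week of one group against first week of another") is
likewise open, so the simulator offers `pooled` (default) and `pairwise`
schemes. The multilevel regressions themselves are standard methodology
and are not implemented; `center_between()` / `center_within()` produce
the analysis-ready centered tables (outcomes centered around baseline
company means with calendar-week nesting, or around calendar-week means
with participant nesting).

```{r design}
analyzable_sample_size(design_spec())
nnt_from_rates(cer = 0.261, eer = 0.561)
```

## Numerical choices and degenerate inputs

* Bout durations stay in minutes at 0.5-min resolution and SSSB in raw
  min² end to end; the 10³ min² scale is presentation only, avoiding
  rounding drift.
* Dwell discretization rounds half-up (`floor(2d + 0.5)/2`), not R's
  banker's rounding, so the rule is the one stated above.
* Median cutoff: midpoint interpolation at even counts.
* Empty bout list ⇒ SSSB 0; zero or negative durations are errors.
* A day with no valid wear cannot contribute to cutoffs or profiles;
  a cohort without a single valid day is a hard error, not a silent NA.
* Thresholds may be relaxed to the degenerate pass-everything configuration
  (`sit_max = Inf`, `active_min = 0`, `sssb_cutoff = Inf`) for sensitivity
  checks.

## Problem sizes used by the test suite

The suite exercises the SSSB engine against an independent epoch-level
oracle on 1,000 generated days, the convexity identities exhaustively for
up to 5 bouts on a 0.5-min grid, cutoff recovery on 500 days against a
2,000-day reference draw, the preset contrast on 150 days per preset, and
the design precision on 1,000 Monte-Carlo replications — sizes chosen so
Monte-Carlo error is small relative to the tolerances being checked while
the whole suite stays fast to run routinely.

## Known limitations

* The SSSB cutoff shipped as a default is a pilot-derived convention; no
  health-outcome validation is implied.
* The generator's presets are qualitative emulations of the published
  healthy/unhealthy contrast, not distributions fitted to any corpus.
* Posture classification error upstream of the epoch stream is out of
  scope; the package treats the epoch labels as ground truth.
* MVPA is not represented at the epoch level: the stream carries a single
  light-activity state, and moderate-to-vigorous activity in the program
  is questionnaire-based.
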