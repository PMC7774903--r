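---
title: "Methods: dominance onset, reversals and peri-event analysis in dyadic fly contests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominance onset, reversals and peri-event analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two male flies are confined with a contested resource they fight, and
in most pairings one male emerges socially dominant. Lunges are the act most
often counted to quantify aggression, but counting lunges says nothing about
*when* a hierarchy formed, and therefore nothing about which acts precede
its formation and which follow it. `flydom` implements an explicit,
behavior-independent criterion for the *onset* of dominance and for later
*reversals* of status, and builds the downstream analyses that the criterion
makes possible: onset-aligned peri-event descriptions of each aggressive
act, attribution of acts to the instantaneous dominant, and outcome-level
contingency analyses.

## The pursue-to-climb criterion

The diagnostic sequence is: one male pursues the other until the retreating
male leaves the floor by climbing the arena wall. The pursuer is classified
as dominant from that moment. The same criterion applied later with the
roles swapped identifies a reversal of status. The criterion is attractive
because it is independent of the specific aggressive acts under study
(avoiding circularity), because it gives each contest an alignment point for
within-contest time, and because it extends naturally to reversals.

Operationally (`find_diagnostic_instances()`, `build_timeline()`):

* a **pursuit bout** is a maximal run of frames on which the pursuer is
  within `pursuit_d_max_mm` (5 mm) of its opponent, moving at
  `pursuit_v_min_mm_s` (3 mm/s) or faster, oriented within
  `pursuit_theta_max_deg` (45°) of it, and not on the wall; gaps up to
  0.2 s are bridged and runs under 1 s discarded, in that fixed order
  (mask, then merge, then duration filter) so the segmentation is
  deterministic and oracle-checkable;
* a **climb** is wall occupancy sustained for `climb_min_s` (0.5 s). A
  top-down tracker cannot see height, so "leaves the floor" is encoded as
  radial position at or beyond `wall_fraction` (0.95) of the arena radius;
  an explicit `on_wall` annotation column overrides the proxy;
* a **diagnostic instance** exists when a climb by fly X starts during, or
  within `link_max_s` (2 s) after, a pursuit bout by the other fly whose
  target is X. The instance time is the climb start.

The first instance sets the onset; each later instance whose pursuer is the
current subordinate flips the status. Contests with no instance never
established a hierarchy; contests whose onset instance's pursuit was
already in progress at the first observed frame established it before
observation. Both classes are excluded from onset-aligned analyses, with
machine-readable reasons (`apply_exclusions()`).

Three judgment calls were genuinely open and are exposed as configuration:

* **How many instances confirm an onset?** "Consistently pursues" is not a
  count. The default `k_confirm = 1` keeps the criterion maximally explicit
  and falsifiable; requiring k repeated instances by the same pursuer is a
  config knob.
* **The pursuit-to-climb latency** `link_max_s = 2` s: the climb is the
  culmination of the pursuit, but no latency is published; 2 s is tight
  enough that an unrelated later climb does not link back to a stale
  pursuit.
* **Simultaneous opposite-role instances** at one timestamp (degenerate in
  practice) resolve in favor of the earlier-starting pursuit and are
  logged.

## Distinguishing pursuit from chase

Chasing is a long, high-speed trailing behavior, distinct from the shorter
pursuits that lead to establishment. The detector therefore first segments
all trailing bouts as pursuits and then re-labels as `chase` those lasting
at least `chase_min_s` (5 s) with mean speed at least `chase_v_min_mm_s`
(10 mm/s); the partition is exhaustive and exclusive, and only
pursuit-labeled bouts participate in the dominance criterion. The
quantitative thresholds are declared package defaults at plausible fly
scales — the acts are defined verbally in the literature — and every one of
them is a `detector_params()` entry intended to be calibrated against
annotated data.

The lunge detector is likewise a declared heuristic: a point event fires
where a fly displaces at least 1.5 mm within 0.1 s while within 3 mm of,
and oriented within 30° toward, its opponent; detections within 0.3 s
merge into the first. Fencing, wing flicks and boxing/tussling have no
kinematic detector here — in the source workflow they are scored manually —
so the pipeline consumes them from event tables (or simulator truth).

## Peri-event analysis

`align_and_bin()` shifts each contest's clock so 0 is dominance onset and
bins one behavior into half-open 1-min bins: counts per bin for point-like
acts (lunge, wing flick), fraction of bin time occupied (union over both
flies) for state-like acts (fence, box/tussle, chase). Bins not fully
covered by a contest's recording are missing, not zero. Per-bin medians and
interquartile envelopes (`summarize_perievent()`) use linear interpolation
between order statistics (R's type-7 quantile); the convention is arbitrary
but must be fixed for results to be testable. Bins supported by fewer than
5 contests are flagged.

`paired_window_test()` compares equal-length windows before and after
onset (1-min and 5-min are conventional) with a two-sided Wilcoxon
signed-rank test on the paired per-contest differences. The implementation
is the package's own: zero differences are dropped, tied absolute
differences mid-ranked, and for up to 25 informative pairs the null
distribution of the positive-rank sum is computed *exactly* by dynamic
programming over all sign assignments (valid under ties, unlike the
classical tables); larger samples use the normal approximation with
continuity and tie corrections. Contests lacking a full window are dropped
from that test only, with the per-test n reported. No correction is applied
across behaviors — each behavior's panel carries its own stars — and this
is flagged in the result metadata. Alignment always uses the initial onset;
post-reversal epochs are not re-aligned (phase-resolved attribution is the
job of `attribute_by_phase()`).

## Outcome analyses

`attribute_by_phase()` partitions each contest into unestablished /
A-dominant / B-dominant segments and tallies each act per fly per segment,
with derived summaries (fraction of events after onset, fraction of
post-onset events by the instantaneous dominant, counts within ±30 s of
each reversal — the window is configuration, since "clustering near
reversals" has no published width). `dominance_outcome_test()` tests a
pairing's focal-win proportion against chance with the exact binomial
(two-sided against 0.5; "chance levels" names no test, and the exact
binomial is the assumption-free choice) and compares two pairings with
Fisher's exact test. `lunge_count_comparisons()` compares dominant-male
lunge counts with the tie-corrected Kruskal–Wallis (3+ groups), the exact
rank-sum test (2 groups), or the sign test (paired).
`precocious_lunge_analysis()` compares pre-onset-lunge proportions between
a rematch cohort and a naive cohort with a 1-df chi-square (no Yates
correction by default, with Fisher's exact always reported alongside and
recommended when expected counts fall below 1), plus the within-rematch
comparison of early-lunging winners versus losers.

## The contest simulator

No trajectory or annotation data are published for this assay, so the
package carries a first-class generative model (`simulate_contest()`,
`simulate_cohort()`, `winner_rematch()`) whose defaults encode the study
conditions: 20-min contests at 30 frames/s in a 16-mm diameter enclosed
arena, and one contest in five containing at least one reversal. Each
contest draws a class (hierarchy established during observation, before
observation, or never — defaults 0.82/0.12/0.06, the latter two roughly in
the 2:1 ratio of the reported excluded contest counts), a log-normal onset
latency (median 300 s, shape 0.5: strictly positive and right-skewed, as
observed latencies are; both numbers are configuration, not claims), and a
geometric number of reversals when reversals occur.

Behavioral streams follow piecewise-linear rate profiles in time relative
to onset (`default_act_profiles()`), encoding the reproducible qualitative
sequence: fencing high from contest start to onset then sporadic;
boxing/tussling rising late, peaking in the final pre-onset minute,
collapsing at onset, and transiently recurring before each reversal; wing
flicks stepping up at onset; lunges nearly absent before onset and ramping
up after, attributed to the instantaneous dominant with probability
`lunge_dominant_fraction` (0.9) and clustering in the half-minute before
each reversal; chases absent before onset and consolidating minutes after.
No quantitative per-act rates are published for this assay: all magnitudes
are config parameters chosen once at plausible scales, and the synthetic
cohorts should be read as a test bed with known ground truth, not as a fit
to data.

Trajectories are synthesized so that every scripted act is kinematically
real: baseline movement is a correlated random walk (mean speed 4 mm/s,
20°/frame heading noise) softly reflected just inside the wall threshold;
pursuit and chase bouts move the pursued fly along a circular path with the
pursuer trailing at the trigger distance (2.5 mm); the terminal
pursue-to-climb bout spirals outward so the subordinate reaches the wall,
where it is pinned at 0.975 of the arena radius with `on_wall` set — the
generative model satisfies the detector's target pattern *by construction*,
which is what makes recovery rates a meaningful end-to-end test. Lunges are
staged as an approach to 2.8 mm, a 2-mm thrust in 0.1 s, and a short
retreat. One stated pseudo-random generator drives everything; per-contest
seeds are mixed deterministically from the cohort seed and contest index,
so cohorts are order-independent and each contest is independently
reproducible.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: tracking noise and identity swaps, wall-climbing
outside dominance events, jumping and flight, physiological or genetic
state beyond rate parameters, and any correlation structure between acts
beyond their shared dependence on onset and reversals. Detector thresholds
that recover 95%+ of simulated events are calibrated to the simulator's
(clean) kinematics; on real video they would need re-calibration against
manual annotation.

## Numerical and design choices

* Times are seconds (floats) on disk, frames internally; all intervals are
  half-open `[start, end)` and frames 0-based, making bin and segment
  assignment unambiguous at boundaries.
* Fly identities are carried as labels A/B by the files; identity
  *tracking* is out of scope (in the source workflow identity comes from a
  wing clip).
* The exact signed-rank and rank-sum nulls are computed on doubled
  (integerized) mid-ranks, so tied ranks are handled without approximation;
  brute-force enumeration oracles in the test suite verify all exact tests
  for small n.
* Validation errors are typed (`flydom_validation_error`,
  `flydom_config_error`, ...) and name offending rows.
* Problem sizes in the test suite (50-contest recovery cohorts, 100-contest
  reversal cohorts, 500×20 null calibration) were chosen as the smallest
  sizes at which the checked proportions have acceptance regions clearly
  separating correct from broken behavior.

## Known limitations

* The pursue-to-climb criterion requires a wall the subordinate can reach;
  arenas whose geometry suppresses climbing would starve the detector.
* `pre_established` detection needs the culminating pursuit to be visibly
  in progress at the first frame; a hierarchy formed during a recording gap
  is indistinguishable from one formed at the gap's end.
* The chi-square statistics of the original rematch analyses depend on
  cohort sizes that are not published, so only the procedures — not those
  specific statistics — are reproducible.
* With `k_confirm > 1`, onsets are declared at the k-th instance; the
  earlier instances are not retroactively re-interpreted.
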