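---
title: "Detecting and analyzing the incubation of social deficits from open-field dyad trajectories"
author: "dyadtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analyzing the incubation of social deficits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`dyadtrack` implements a complete longitudinal pipeline for social
phenotyping of mice in a square open field: a seeded agent-based generator
of one- and two-mouse trajectory cohorts with programmable treatment
effects, deterministic geometric classifiers for the static and dynamic
dyadic behavioral events used in automated tracking studies (contacts by
subtype, approaches, breaks, follows, movement bouts, rearing, center-zone
occupancy), per-session behavioral measures, and an inference layer built
on Z-score standardization to the control-group baseline with early/late
phase composites.

The motivating design is a protracted opioid-abstinence experiment: a
baseline session (S0), then five post-treatment sessions (S1 at 24 h, S2–S5
weekly), each consisting of a 15-minute solo habituation phase and a
25-minute interaction phase with a fresh unfamiliar newcomer in a
50 × 50 cm arena. The phenomenon of interest is *incubation*: motor and
exploratory suppression appears immediately after treatment and resolves
within about a week, while social deficits emerge progressively and peak
weeks later. The package's inference layer is built to expose exactly this
biphasic structure, and the synthetic-cohort generator is built to program
it (or ablate it) so that the whole chain can be validated by parameter
recovery.

# The trajectory model

Each animal is simulated at the pose level (mass center, nose, tail base,
plus a unitless posture channel) on a fixed frame grid (default 30 Hz).

**Locomotion.** Speed follows an Ornstein–Uhlenbeck process reflected at
zero, with mean `mean_speed` (default 6 cm/s, a realistic open-field
average for an adult laboratory mouse), reversion rate `speed_relaxation`
(1/s) and a stationary standard deviation fixed at 0.6 of the mean.
Heading diffuses with wrapped-normal increments (`turn_noise`,
rad/&radic;s), steered toward the interior within
`wall_avoidance_range` cm of a wall, and optionally biased toward or away
from the arena center (`center_bias`; the default −0.2 yields mild
thigmotaxis). While roaming, the speed target is inflated by the expected
fraction of time spent rearing so the session-mean speed tracks
`mean_speed`; the generator's contract is that the empirical mean speed of
a solo session stays within 15% of `mean_speed`.

**Rearing.** Explicit episodes with Poisson initiation (`rear_rate`,
events/min) and exponential durations (`rear_mean_duration`, s). During an
episode the posture channel rises above the detector threshold, the
nose–tail distance compresses to 0.45 of the body length, and translation
stops. The posture channel is a deliberate abstraction: upright posture is
not recoverable from 2-D poses, so the generator exposes it as its own
channel and the detector thresholds it.

**The social automaton.** Each animal in a dyad runs a behavioral
automaton with states *roam*, *approach*, *contact*, *break*, *follow* and
*avoid*. Approaches are initiated from roaming with hazard
`approach_rate`/min and steer the animal at its partner until the pair is
close enough for the contact servo to hold a flank-distance posture;
contact dwell times are exponential with mean `contact_dwell` s. On dwell
expiry the animal leaves the encounter — with probability
`follow_propensity` into a follow (tracking a slot 1.5 body lengths behind
the partner), otherwise with probability 0.5 into an assertive break
(speed surplus `break_assertiveness`) or back to roaming. A short
refractory period (2–4 s) after every encounter prevents immediate
re-engagement, so that bout *counts* are governed by initiation rates
rather than by bout *durations*.

Two further mechanisms make the approach drive a genuine sociability
parameter rather than only an initiation rate:

* **encounter acceptance** — when the partner closes in, the animal joins
  the contact with hazard proportional to its own `approach_rate`
  (10 × `approach_rate`/60 per second) and otherwise turns away into the
  avoid state;
* **proximity bias** — while roaming within five body lengths of the
  partner, heading is biased toward the partner in proportion to the
  approach drive, against a fixed repulsion; the two balance at the
  default 5 approaches/min, so a suppressed animal actively keeps its
  distance while an untreated animal is neutral.

Without these mechanisms a socially suppressed focal animal still
accumulates near-baseline contact and approach counts from
partner-initiated and incidental encounters, and programmed suppression
becomes nearly invisible to the detectors — which contradicts the
empirical observation the package is designed to reproduce, namely that
focal social counts drop while the partners' behavior is unchanged.
Newcomers are always simulated with untreated default parameters, and a
fresh newcomer identity is used in every session.

# The effect schedule

Treatment effects are expressed as per-session multipliers on the treated
group only: `motor_multipliers` scale `mean_speed` (default 1, 0.5, 0.7,
1, 1, 1 over S0–S5: a transient early suppression) and
`social_multipliers` scale `approach_rate` and `contact_dwell` (default
1, 1, 1, 0.5, 0.5, 0.5: late suppression only). Controls always receive
multipliers of exactly 1.

A per-mouse latent severity $s_i \sim N(0,1)$, drawn once per mouse from
its own seeded substream, couples the deficits: each base multiplier $m$
becomes $m^{\exp(\lambda s_i)}$ with `coupling_lambda` $=\lambda$ (default
0.5). The power form keeps multipliers positive, leaves null multipliers
($m = 1$) untouched, and makes a more severe mouse proportionally worse
wherever a deficit is programmed, which induces the positive correlation
between early motor and late social deficits that the prediction analysis
recovers. Treatment weight loss is `weight_base` + `weight_slope`
$\times\, s_i$ + noise (defaults 3 g, 1 g per unit severity, 0.1 g noise);
control losses are pure noise. With the pre-minus-post sign convention
used throughout (loss in positive grams), a larger loss therefore predicts
a *lower* late social Z-score, i.e. the weight-loss/late-deficit
correlation is negative in slope.

# Event detection

All detectors are deterministic geometric predicates over the frame grid,
sharing one post-processing rule and one set of kinematic definitions.

**Kinematics.** The mass center is smoothed with a centered moving average
(default 5 frames, truncated at the ends of each contiguous tracked
segment); speed is the norm of the smoothed per-frame displacement times
the frame rate; heading is the displacement direction, falling back to the
tail-to-nose axis below 0.1 cm/frame; the body length is the per-session
*median* nose to tail-base distance (robust to tracking outliers), and
dyadic thresholds expressed in body lengths use the mean of the two
animals' body lengths. Frames adjacent to tracking gaps carry no speed,
and no event may span a gap.

**Post-processing order.** Per-frame predicates are run-length encoded;
runs shorter than `min_event_frames` (default 3) are dropped *first*, and
surviving runs separated by at most `merge_gap_frames` (default 2) clean
frames are then merged. The order matters: dropping first means that
single-frame predicate flicker can never assemble into long spurious
events, while two solid bouts separated by a one-frame dropout still merge
into one.

**Strictness.** Every inequality in the predicates is strict, so values
exactly at a threshold (a speed of exactly 5 cm/s, a heading difference of
exactly 45°) fail the predicate.

The individual detectors:

* **moves / stops** — smoothed speed strictly above (complement: at or
  below) `speed_threshold`, default 5 cm/s.
* **contacts** — minimum over the nine point pairs of the two three-point
  skeletons strictly below `contact_dist_cm` (default 2 cm). The tracker
  this emulates decides contact by shape overlap, which point poses cannot
  reproduce; the skeleton minimum distance is the natural point-pose
  operationalization. Each bout is labeled by its modal frame subtype:
  `nose_nose` when the nose–nose pair is minimal, `nose_anogenital` when
  the focal-nose/partner-tail pair is minimal, `side_by_side` when neither
  nose pair is minimal and the body axes are within 30° of parallel or
  antiparallel, else `other_contact`. (A pure "flank pair minimal" rule is
  unsatisfiable for parallel offset bodies, whose nearest points are
  always end points; the precedence rule above is what the worked flank
  geometry requires.)
* **approaches** — started at the first frame with center distance
  strictly inside `approach_radius_bl` body lengths, strictly decreasing,
  focal strictly faster than the partner and the pair not in contact;
  ended at contact onset (`with_contact`), on zone exit, or when the
  distance has stopped decreasing for `merge_gap_frames` consecutive
  frames (`without_contact`). The requirement that the focal be the faster
  animal disambiguates who is approaching whom when both drift closer.
* **breaks** — from a contact end, distance strictly increasing and focal
  strictly faster at every one of the next `min_event_frames` frames, then
  extended while both conditions hold; at most one break per contact end.
* **follows** — both speeds strictly above the speed threshold, headings
  strictly less than 45° apart, and the focal center strictly inside the
  1 × 2 body-length rectangle extending backward from the leader's center
  along its heading.
* **rears** — posture channel strictly above `rear_posture_threshold`.
* **center zone** — the axis-aligned square of half the arena side
  (25 × 25 cm by default, configurable through `center_fraction`);
  distance in the center accumulates only displacement between
  consecutive in-center frames.

Moves are additionally split at the focal's contact-interval boundaries
into `isolated` and `in_contact` fragments (fragments shorter than the
minimum duration are dropped), which is what separates the early
(isolated-movement) from the late (in-contact-movement) arm of the
biphasic pattern.

Every detector has an independent frame-wise oracle in the test suite —
predicates evaluated per frame with explicit loops, run-length encoded by
a separate implementation — and the acceptance suite requires exact event
equality on 100 randomized simulated dyads.

# Session measures

Habituation sessions yield total distance, center distance, percent time
in center, and the rearing count/total/mean triplet (which satisfies
count × mean = total exactly). Interaction sessions yield the focal's
total distance, move counts (total, isolated, in contact), contact,
approach, follow and break counts, and the dyadic totals: static dyadic
events are moves in contact + stops in contact + contacts; dynamic dyadic
events are approaches + breaks + follows; each event counts once
regardless of subtype. The cohort measures table is long-format
`(mouse_id, group, session, measure, value)` with a completeness check.

# Statistics

**Standardization.** $Z = (X - \mu)/\sigma$ per measure, where $\mu,
\sigma$ are the mean and *sample* (n−1) standard deviation of the control
group at the baseline session. The sample estimator makes the
standardization idempotent on the reference cells: the saline S0 Z-scores
of every measure have mean 0 and standard deviation 1 exactly. Early
composites average S1–S2, late composites S3–S5. The combined social
score is the unweighted mean of the contact-count, approach-count and
total-dyadic-event Z-scores; the combined motor score averages the
habituation distance, center-distance and rearing-count Z-scores.

**ANOVA.** The mixed repeated-measures ANOVA uses the classical univariate
sum-of-squares decomposition (group between subjects, session or phase
within, subject-within-group error for the group effect), with group sizes
allowed to differ. The Greenhouse–Geisser epsilon is estimated from the
pooled within-group covariance through an orthonormal contrast basis and
applied *unconditionally* to both within-subject effects (no sphericity
pre-test, no Huynh–Feldt alternative): this matches the fractional
degrees-of-freedom convention of the analyses the package emulates, where
a six-session design prints df1 = 5ε. For k = 2 (the phase analyses)
ε = 1 exactly and the correction is inert.

**Post-hocs.** Tukey's studentized-range test is used for the per-session
group comparisons after the session ANOVAs; Fisher's LSD (unadjusted) for
the 2 × 2 phase analyses, where only a handful of planned comparisons are
made. Between-group simple effects at one within-factor level use the
pooled error $(MS_{subj} + (k-1)MS_{err})/k$ with Satterthwaite degrees of
freedom; within-group comparisons between two levels use the paired error
$2MS_{err}/n_g$. With two groups the Tukey adjustment coincides with the
unadjusted test.

**Regressions.** Ordinary least squares with the F-test of the slope;
$r^2$ is the squared Pearson correlation. A constant outcome returns
slope 0, $r^2 = 0$, p = 1 by convention (degenerate synthetic draws should
not crash a cohort analysis); a constant predictor is an error. All tests
are two-sided at α = 0.05. Welch's t (with Welch–Satterthwaite fractional
df) is provided for single comparisons such as the treatment weight-loss
contrast.

# What the generator does and does not emulate

The generator reproduces the *structure* that the inference layer needs:
realistic event rates (a few contacts and approaches per minute, tens of
movement bouts), arena-bounded thigmotaxic exploration, programmable
group-by-session effects, individual-severity coupling, and partner
neutrality. It does not emulate tracking noise artifacts (identity swaps,
missing frames are supported but not generated by default), depth-based
posture estimation, ultrasonic vocalizations, arena habituation across
sessions, or any pharmacokinetics: treatment is a pure parameter change.
Passing recovery tests therefore demonstrates that the detector/statistics
chain is correct and well calibrated on data whose ground truth is known —
not that the same effect sizes would be observed in real animals.

# Numerical and design choices

* Frame rate defaults to 30 Hz and is recovered from the timestamp column
  when reading trajectory files, never assumed silently; the trajectory
  dialect stores frames 0-based, coordinates in cm with origin at the
  lower-left corner, and all event intervals are half-open
  `[start_frame, end_frame)`.
* Tracking gaps are tolerated up to 10% of frames per track at read time;
  gaps split events and void adjacent speeds.
* All randomness passes through R's RNG: a session is fully determined by
  its seed, and cohort recordings use per-(mouse, session, phase) seeds
  derived arithmetically from the master seed, so changing one animal's
  stream leaves every other recording untouched.
* The per-session statistical layer treats a "five session" protocol as
  six recordings, S0 (baseline) plus S1–S5, which is what the phase
  composites require.
* Session-duration reductions used in the validation experiments (the
  package's own choices, made from pilot power analyses): type-I
  calibration uses 500 null cohorts of 6 + 6 mice with 2-minute
  interaction phases at 10 Hz; incubation recovery uses 11 + 10 mice with
  150-second phases; prediction recovery uses 20 treated + 10 control mice
  with 90-second phases, simulating habituation only for S0–S2 and
  controls only at S0, since those are the only cells the prediction
  regressions consume. Within the morphine group the null expectation of
  $r^2$ is $1/(n-1)$, which motivates the enlarged treated group there.

# Limitations

The social automaton is phenomenological: state dwell times are
exponential, steering is first-order, and the acceptance/avoidance
balance point (5 approaches/min) is a model constant, not an estimated
quantity. Directed social states move at engagement speeds that do not
scale with the roaming mean, so exploratory (motor) suppression largely
spares social counts; a residual coupling remains, because the speed
gates in the approach and movement predicates still see the slower
roaming, and a strong motor suppression therefore produces a mild
apparent social reduction in the same sessions. The recovery experiments
that target the incubation pattern consequently program social
suppression with motor multipliers of 1. The contact criterion differs from shape-overlap trackers, so
absolute contact counts are not directly comparable to tracker output.
The inference layer implements the univariate GG-corrected mixed ANOVA
only; multivariate or mixed-effects alternatives, and multiplicity
control across measures, are deliberately out of scope.

# A minimal run

```{r example}
library(dyadtrack)
cfg <- pipeline_config(
  design = cohort_design(n_morphine = 6, n_saline = 6,
                         habituation_duration = 120,
                         interaction_duration = 120,
                         frame_rate = 10, master_seed = 1),
  out_dir = "run1")
run_pipeline(cfg)
ana <- incubation_analysis(read_measures(file.path("run1", "measures.csv")),
                           read_manifest(file.path("run1", "manifest.yaml")))
print(ana)
```
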