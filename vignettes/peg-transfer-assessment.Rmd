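---
title: "Automated assessment of the FLS peg-transfer exercise: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated assessment of the FLS peg-transfer exercise: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegtransfer)
```

## The task and what the package computes

In the peg-transfer task of the Fundamentals of Laparoscopic Surgery (FLS)
programme, six rubber rings sit on one side of a 12-peg board. The trainee
lifts each ring with one Maryland dissector, hands it to the other
dissector in mid-air — without using the board or pegs for assistance — and
places it on a peg of the opposite side; the whole procedure is then
repeated in the reverse direction. Assessment is traditionally done by an
expert watching the recording; it is slow and partly subjective.

`pegtransfer` automates the assessment from *per-frame object detections*
(pegs, rubber rings, dissectors, and grab events — a dissector holding a
ring), which any object detector can produce. The package deliberately
starts downstream of the detector: its input is a JSON-Lines detection
stream, so the vision model is a pluggable component rather than a
dependency.

The pipeline is:

1. **Tracking** (`track_objects()`): greedy per-class nearest-centroid
   association turns detections into identity tracks.
2. **Board geometry** (`infer_board_geometry()`): peg positions, the left
   and right sides, and the board midline are inferred from the peg tracks
   themselves.
3. **State derivation** (`derive_grab_states()`,
   `derive_contact_states()`): boolean per-frame channels — is instrument
   L/R holding a ring (and which), is peg *k* occupied (and by which
   ring). These match the natural per-frame maxima of the task: at most 2
   grab channels and 12 contact channels.
4. **Debouncing** (`sliding_average_filter()`, `filter_timelines()`): a
   centred sliding-average threshold removes isolated false
   positive/negative detections; a `filter_report()` accounts for how many
   frame-channel cells changed.
5. **Session segmentation** (`segment_sessions()`): a session runs from a
   ring's pickup to its release; sessions carry holder intervals, end
   reason (placed / dropped / stream end) and origin/destination pegs.
6. **Transfers and pitfalls** (`assemble_transfers()`,
   `detect_pitfalls()`): sessions group into transfers; rule violations
   (missed handover, invalid handover, invalid pickup, invalid release)
   are detected.
7. **Scoring** (`measure_duration()`, `score_exercise()`): duration from
   first pickup to last release, and the pass/fail verdict.

`evaluate_stream()` composes all stages; `peg_main()` (and the `pegeval`
script) expose `evaluate`, `simulate` and `agreement` subcommands.

## Rules of the game: sessions, handovers, pitfalls

A **session** is the maximal interval over which some instrument
continuously holds one ring, with gaps up to a tolerance bridged. This
ring-centric reading (rather than one session per grab interval) makes the
handover logic directly expressible: during a correct mid-air handover the
ring never stops being held.

A **transfer** groups consecutive sessions of one ring from its leaving
one side of the board until it *rests on a peg of the opposite side*. A
placement back onto the origin side does not close the transfer — the ring
is still owed to the other side; it raises an `invalid_release` pitfall,
and a subsequent re-pickup from the origin side raises `invalid_pickup`.
This reading makes every pitfall kind reachable from a single top view.

A handover is **valid** when the ring changes instruments either (a)
mid-air, with both grabs overlapping in time on the ring, or (b) across a
short gap — at most `handover_gap_max` frames — with no peg contact of the
ring inside the gap. A completed transfer with no instrument change is a
`missed_handover`; a change that was not mid-air (across a drop or a rest)
is an `invalid_handover`. One sentence in the published description of
this rule states the opposite — that *differing* instruments at session
start and end indicate a missed handover — which contradicts the task
definition itself (the ring must be transferred to the other clamp). We
implement the reading consistent with the task and expose
`strict_paper_wording = TRUE` for the literal one.

**Verdict**: pass requires (i) at most `max_allowed_pitfalls` pitfalls
(default 0), (ii) duration within `time_limit_s` (default 300 s), and
(iii) every ring completing a handover-valid transfer in each direction
(both directions by default). The published account does not print its
exact pass/fail thresholds beyond naming the FLS criteria, so all three
are configurable.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `window_frames` | 15 | frames | debouncing window (~0.5 s at 30 fps) |
| `on_threshold` | 0.5 | — | windowed-mean level that switches a state on |
| `contact_tau` | 0.1 | — | min (ring ∩ peg)/ring-area overlap for contact |
| `gap_tol_frames` | 2 | frames | bridged gaps inside a session |
| `handover_gap_max` | 3 | frames | max gap for a valid cross-gap handover |
| `time_limit_s` | 300 | s | exercise time limit |
| `require_bidirectional` | true | — | both directions needed to pass |
| `max_allowed_pitfalls` | 0 | count | pitfalls tolerated |
| `max_jump_px` | 40 | px/frame | tracking association gate |
| `track_patience` | 10 | frames | track survival without detections |

A consistency constraint ties the gap tolerances to the debouncer: a
centred window of width $W$ can move a state edge by up to
$\lfloor W/2 \rfloor$ frames, so gaps finer than that resolution cannot be
adjudicated reliably. The pipeline therefore applies
`max(gap_tol_frames, ⌊W/2⌋ + 1)` when bridging session gaps and
`max(handover_gap_max, ⌊W/2⌋ + 1)` when judging cross-gap handovers; with
the default $W = 15$ both effective tolerances are 8 frames. Configured
values larger than the filter resolution are honoured as given.

## The debouncer

`sliding_average_filter()` computes, for every frame, the mean of the raw
boolean channel over the centred window of width `window_frames`
(truncated at the array edges) and switches the output on when the mean
reaches `on_threshold`. Consequences worth knowing:

* runs of stable state longer than the window are preserved away from run
  edges, and the filter is monotone in the threshold;
* with `threshold = 0.5` a clean step edge is reproduced exactly;
* under per-frame dropout with survival probability $p$, edges erode
  inward by roughly $W(0.5/p - 0.5)$ frames — the origin of the effective
  gap tolerance above.

The held-ring / occupying-ring attributes are re-sampled after filtering
as the modal identity over the same window among raw-true frames; frames
switched on by the filter with no raw support inherit the nearest
resolved identity.

`filter_report()` counts changed (frame, channel) cells — the false
positive/negative detections removed — against the per-frame channel
maxima (2 for grabs, 12 for contacts), and is summable across videos
before the percentage is recomputed. Percentages are reported with
conventional round-half-up at 2 decimals; note that
$301{,}825/(3{,}038{,}120 \times 2) = 4.967\%$ rounds to 4.97, not 4.96 —
we report the arithmetic value.

## Tracking design

The tracker is deliberately simple — greedy nearest-centroid association —
but hardened against the failure modes that detector noise actually
produces:

* **Constant-velocity prediction** (exponentially smoothed) keeps two
  objects moving in formation (the two dissectors during an exchange)
  from swapping identities.
* **Tentative tracks**: a track with fewer than 3 hits survives only one
  missed frame, so isolated spurious boxes do not linger as traps.
* **Gap-scaled, capped gates**: a track missing a few frames can re-catch
  a moving object, but a stale track cannot capture distant detections.
* **Fragment stitching**: when a track is dragged onto a spurious box on a
  frame where its true detection was deleted, the object continues under a
  fresh identity; fragments are re-joined by looking up the lane's
  position at the fragment's start time.
* **Shadow-lane merging**: spurious boxes riding on top of an object can
  capture part of its detections into an interleaved parallel lane; a lane
  whose positions track a better-supported lane's path is folded into it
  (a detector's non-maximum suppression would have removed most such
  boxes at the source).
* **Peg clustering**: pegs are static; peg track fragments are merged by
  position (25 px, well under the 60 px peg pitch) and frozen to their
  median boxes.

Instrument identity (`L`/`R`) is *not* read off track identity. The two
dissectors enter from opposite ports and their tips do not cross, so
whenever both are visible the left one is L; frames with a single visible
dissector inherit the label of the nearer of the two continuously tracked
instrument positions. This per-frame geometric labelling is immune to
tracking-identity swaps during exchanges, while still representing a
single instrument carrying a ring across the full board (the missed
handover case). This replaces a simpler design — labelling whole tracks by
their mean position over the first 30 frames — which proved brittle: one
identity swap mid-stream silently inverts every later handover.

## The simulator

`scenario_library()` scripts exercises on a 640×480 px top view: 12 pegs
in two 6-peg columns (x = 160 and 480, 60 px pitch), 40×40 px rings,
60×24 px dissectors, 30×30 px grab boxes, 30 fps. Rendering interpolates
object boxes linearly between scripted keyframes (lift to a transit
height, horizontal flight, descent; drops fall to the board); grab
detections are emitted exactly on held frames. The canonical schedule
performs one 60-frame carry per ring per direction with a 6-frame mid-air
overlap, picking rings top-down and placing them bottom-up so that a
descending ring crosses only empty pegs — from a single top view a ring
lowered across an occupied peg is indistinguishable from the ring resting
there, and the scripted exercises keep that ambiguity out of the ground
truth. The library covers a perfect run, each pitfall kind, an over-time
run (rendered at 5 fps so that a >300 s exercise stays a tractable frame
count) and a single-direction run.

Ground truth (sessions, transfers, pitfalls, duration, verdict) is
computed from the script, not from the rendered stream; the session table
is scripted directly and the same rule engine used for evaluation derives
transfers and pitfalls from it.

`inject_noise()` models detector errors: per-class i.i.d. false-negative
deletion and false-positive insertion (uniform position, class-typical
size), Gaussian box-centre jitter, and an optional burst mode (two-state
Markov chain, geometric run lengths) because real detector errors are
bursty. What the simulator does **not** model: perspective and occlusion,
correlated appearance changes, detector confidence structure, rings
resting against (not on) pegs, or 3D contact ambiguity. Passing the
closure and robustness checks therefore demonstrates the correctness and
noise-tolerance of the *event logic*, not the adequacy of any particular
detector.

## Validation performed by the package

* **Closure**: for every library scenario, noise-free evaluation recovers
  the scripted sessions, pitfall multiset and verdict exactly, and the
  duration within $(1 + W)/\mathrm{fps}$ seconds (`closure_check()`).
* **Robustness**: at `fp = fn = 0.10` and 2 px jitter, the verdict agrees
  with the scripted ground truth in at least 95% of 100 seeded runs
  cycling over the scenario library
  (`verdict_agreement_experiment()`; observed ≈ 99%).
* **Debouncer accuracy**: at symmetric flip noise `p = 0.15`, off-transition
  frame accuracy exceeds 99% (`filter_accuracy_experiment()`).
* **Statistics**: `cohen_kappa()` and `pearson_chi_square_2x2()` (the
  latter deliberately without continuity correction — with Yates
  correction the 2×2 comparison of 29/1 vs 28/2 drops from 0.35 to
  essentially 0) match direct-formula and `stats::chisq.test()` oracles to
  1e-12 on random tables.

These checks run in the test suite and in `scripts/acceptance.R`. Problem
sizes were chosen to keep a full run comfortable on a laptop: ~1,100-frame
scenarios, 100 noisy evaluations, 20 filter replicates.

## Numerical conventions and degenerate inputs

* Frames are 0-based; boxes are pixels, origin top-left, half-open on the
  max edges; detection streams sort by frame, class (peg, rubber,
  dissector, grab), then box coordinates.
* Reals serialise at 6 decimals in streams; durations and percentages are
  reported with conventional round-half-up at 2 decimals.
* Kappa is returned at full precision (rounding is the caller's choice);
  a degenerate all-agree table gives kappa 1; a zero marginal makes the
  chi-square an error of class `peg_undefined_statistic`.
* An exercise with no sessions has no duration: `measure_duration()`
  signals `peg_undefined_duration` rather than returning 0.
* Ties in assignment problems (grab-to-dissector, occupying ring) break
  by centroid distance, then deterministically by order, so identical
  inputs always give identical outputs.

## Known limitations

* The single top view cannot distinguish a ring resting on the board
  beneath a peg from genuine peg contact; a side view would be needed.
* The rule engine assumes at most one ring is carried at a time (true of
  the FLS task as specified).
* Duration is measured from first pickup to last release, so setup time
  before the first grab is excluded by construction.
* The robustness figures quantify behaviour under the simulator's i.i.d.
  noise model; bursty real-world failure modes are only approximated by
  the burst toggle.
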