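---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(photolearn)
```

This vignette is the package's own account of the analysis it implements:
the models and their assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the choices made where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The behavioral model

Trials are classified from lick evidence alone: a trial is a "lick" trial
iff at least one lick falls in the response window (1, 4] s after stimulus
onset (the stimulus lasts 1 s; the window is its offset plus 3 s). Licking
during the stimulus is permitted and ignored by the classification — a go
trial whose only licks precede the response window is a **miss**. This is
the reward contingency of the task; an internally inconsistent worked
example in our build contract suggested counting such trials as hits, but
that would break the stated invariant that miss trials have no
response-window licks, so the window rule wins (see the decisions ledger).

Learning is summarised per 50-trial bin (last partial bin dropped, so all
bins have equal variance) by `d' = Z(hit rate) − Z(FA rate)`. Rates of 0
or 1 would give infinite d'; they are clipped to `[1/(2n), 1 − 1/(2n)]`,
the standard log-linear correction. The source methods do not state how
extreme rates were handled; any bounded correction preserves the ordering
of thresholds, which is what downstream statistics consume.

The d' curve is fitted with `S(t) = a / (1 + exp(−(t − b)/c))`: `a` the
asymptotic sensitivity, `b` the inflection trial, `c` the steepness in
trials. Fitting is bounded least squares (`optim` L-BFGS-B) with a fixed
initialisation rule (`a0 = max(y)`, `b0` = midpoint, `c0` = span/10), so
it is deterministic. Because the four parameters live on scales that
differ by orders of magnitude (d' units vs trial numbers), `parscale` is
set per parameter — without it the finite-difference gradient in the
trial-number directions is numerically zero and the fit silently stays at
its initial value. The learning threshold inverts the fit in closed form:
`t = b − c·ln(a/criterion − 1)` for `a > criterion`, undefined otherwise
(undefined is a value, not an error).

Fluorescence **response curves** sit on a non-zero sensory floor (a
sustained stimulus response present from trial 1), which the pure
three-parameter sigmoid cannot represent. `fit_sigmoid(..., offset =
TRUE)` therefore adds a constant `d`; the normalized fit
`(S − S_start)/(S_end − S_start)` and its 0.5 crossing are unaffected by
`d`, and for decreasing curves (the tuned-away cohort) the same formula is
the normalized magnitude of change, so a threshold is defined for every
monotone fit. Note one subtlety the test suite pins down: the
normalisation is over the *observed* trial range, so the 0.5 crossing
equals the inflection `b` only when the run covers the full rise.

## Normalisation and windows

ΔF/F is per-trial `F/F0 − 1`, `F0` being the mean over a 0.5 s baseline
ending at the visual cue (−2 s). The alternative plain-ratio reading of
"frame-zero division" differs by a constant and is available as
`convention = "ratio"`; the default makes a no-change trace exactly 0.
Normalising twice is refused rather than silently compounded. All analysis
windows are half-open `[start, end)` on frame timestamps; the standard
windows are early (0–0.3 s), late (0.6–1 s), stimulus (0–1 s),
pre-stimulus (−1–0 s), and per-subject overrides (e.g. 0.2–0.5 s) are
plain arguments.

## Discrimination (AUC) and latency

Per frame, the AUC between two trial types is the Mann-Whitney statistic
(pair counting with ½ ties), computed from column ranks — the test suite
holds it equal to brute-force pair counting exactly. The null band
permutes the two class labels of the compared pair among their pooled
trials, one permutation per iteration applied to every frame (trial
shuffling, not per-frame shuffling), 100 iterations by default. The source
text describes shuffling "between go and no-go sounds" even for the
hit-vs-miss pair, whose members are all go trials; a null must destroy
exactly the contrast under test, so the pair-label shuffle is the default
and the literal go/no-go shuffle is available via `shuffle = "gonogo"`.
Significance is two-sided (`|AUC − null mean| > 3·null SD`, SD floored at
1e-6 against degenerate ties), and the latency is the earliest significant
frame at `t ≥ 0`; pre-stimulus frames are ineligible by construction.

**Onset** of a slow trace (choice trace, lick-rate trace) is the time of
the maximum of the discrete second difference after a centred moving
average. The build contract suggested a 3-frame average; at 30 Hz with
cross-trial difference traces this leaves the second difference dominated
by frame noise, and the argmax frequently landed in the plateau rather
than the rise. The default is therefore 7 frames (~230 ms), exposed as
`smooth_frames`; this deviation is recorded in the decisions ledger.
Second-derivative onset estimation is only meaningful on a rising segment:
where a signal relaxes back to baseline (end of the lick bout) its
levelling-off also has positive curvature. The acceptance battery
therefore estimates onsets on the segment `t ≤ 2 s`, which in the
generator's world predates every drive termination.

## Movement

Motion energy is one minus the Pearson correlation of ROI pixels between
consecutive frames; the first frame of a trial, and any transition
involving a zero-variance frame, get energy 0 (no information is not
movement). The threshold is mean + 3 SD of the pre-cue baseline energy
(SD floored at 1e-9), per trial; the composite "any ROI moving" vector is
the default, matching the strict any-movement flagging of the source
method. Movement onset is 0.2 s before the first crossing; truncation
keeps the bit-identical prefix strictly before the onset, maps onsets to
the photometry clock conservatively (nearest frame at or before), flags
fully truncated trials, and windowed movement-free responses go missing
("n.a.") below `min_samples` surviving frames rather than being imputed.

## The synthetic world

The generator's defaults are the stated conditions of the paradigm, chosen
once:

* **Behavior** — hit rate 0.70 → 0.82 and CR rate 0.30 → 0.92, both
  logistic in trial number with inflection `b = 900` and steepness
  `c = 100` trials over a 1600-trial run: d' crosses 1 near trial 900 and
  plateaus near 2.3 within 1200–2000 trials, the stated acquisition range.
  Novice performance is at chance (both lick rates ~0.7): novice mice lick
  for everything. The expert miss rate (~0.18) keeps at least 40 misses in
  the last 500 trials, the minimum the per-mouse choice test requires.
* **Stimulus component** — sustained drive of 0.06 ΔF/F during the 1 s go
  tone (0.25× for no-go), from 50 ms, with a 5× onset transient for the
  first 100 ms. The onset-dominated shape is characteristic of auditory
  thalamus population responses and realises the paradigm's stated
  fingerprint that stimulus identity is discriminable early (< 200 ms) in
  novices and experts alike.
* **Choice component** — a drive on lick trials from 200 ms lasting the
  lick bout, amplitude = 0.05 ΔF/F × the behavioral acquisition sigmoid
  (the "response curve is sigmoid-like" by construction), sign −1 for the
  tuned-away cohort.
* **Indicator** — difference-of-exponentials kernel, 50 ms rise / 400 ms
  decay (GCaMP6f-like), normalised to unit sum so a sustained drive of
  amplitude A plateaus at A. White noise (SD 0.1 per frame) is injected
  *before* convolution, per the build contract's signal model, so
  fluorescence noise carries the indicator's autocorrelation; the
  effective per-frame ΔF/F noise SD is `noise_sd · ‖k‖₂ ≈ 0.019`. This
  autocorrelation matters: ~120 post-onset frames contain only ~10–15
  independent noise samples, which is what makes a ±3 SD band with
  first-crossing latency usable at all (white per-frame noise would
  produce a spurious crossing in roughly a quarter of null runs).
* **Movement** — jaw motion spans every lick bout; an anticipatory body
  burst (onset ~0.5 s, duration 1.5 s) accompanies lick trials with
  probability 0.5 plus a spontaneous schedule rising with learning
  (0.15 → 0.6), reproducing the movement-probability growth across
  learning. Coupling into fluorescence defaults to **0** — the clean
  world, matching the paradigm's conclusion that choice signals are not
  movement artifacts; the `movement_only` preset (coupling 0.2 ΔF/F,
  bursts centred in the stimulus window, no evoked components) is the
  contaminated world used to show that truncation removes exactly the
  artifactual significance.
* **Licking** — first lick ~N(1.4, 0.25) s truncated to the response
  window, then a 6 Hz bout for 3 s. Lick onsets therefore trail the
  choice-ramp onset by more than a second; the paradigm's finding is the
  ordering (neural choice before motor output), which is what the
  acceptance battery asserts.
* **Frames** — 8-bit frames (default 32×32, tests use smaller) at 30 Hz:
  a static random texture, translated frame-to-frame inside an ROI during
  its movement intervals, plus per-pixel sensor noise.

What the generator does **not** emulate: bleaching and slow drifts,
hemodynamic or isosbestic artifacts, inter-trial correlations beyond the
learning schedules, day boundaries with session-specific offsets,
shaped early training (the 80 % no-go blocks), reward-delivery dynamics,
or realistic video (pose, whisking, illumination). A green test therefore
establishes that the *analysis* recovers what it claims from data with the
assumed statistical structure — not that real recordings satisfy those
assumptions.

## Statistics

Rank tests are implemented natively: exact conditional enumeration of the
permutation distribution when feasible (ties handled exactly), the exact
tie-free Mann-Whitney distribution for small samples, and the tie-corrected
normal approximation with continuity correction otherwise; the suite pins
the branches against each other and against `wilcox.test`. "Multiple group
correction" names no method in the source; Bonferroni was chosen as
order-free and conservative (`adjust_p`).

## Known limitations

* The sigmoid fit is a single deterministic bounded start; pathological
  curves could find a local minimum (the `converged` flag and `rss` are
  reported for exactly this reason).
* AUC latencies are first-crossing statistics and inherit the multiple-
  comparison behaviour of ±3 SD bands; they are calibrated against the
  generator's noise spectrum, not against arbitrary noise.
* The trial threshold of a response curve equals its inflection only when
  the observed range covers the full rise; truncated acquisitions bias it
  toward the centre of the observed range.
* Session I/O uses plain-text containers (JSON + CSV) rather than HDF5;
  the round trip is bit-exact but files are larger than binary formats.
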