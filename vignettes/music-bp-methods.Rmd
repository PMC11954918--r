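---
title: "Methods: tempo, loudness and beat-to-beat blood pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tempo, loudness and beat-to-beat blood pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musicbp)
```

## The question and the study design

Does expressive classical piano music move beat-to-beat blood pressure (BP),
and is it the music's tempo or its loudness that does the moving — and does
the answer depend on whether the listener's resting BP is already high?
`musicbp` implements the full analysis pipeline for a design that addresses
this with *computationally transposed* performances: eight expressive piano
pieces, each linearly sped up (about 1.8x to 3.8x), amplified, or both,
giving 30 track versions (one piece tolerates only a tempo change, so it has
two versions instead of four). Each simulated participant hears a randomized
9-track playlist — the 8 pieces in random order and version, closed by the
first piece again in a different version — after a 5-minute silent baseline.
Participants fall into two groups of 20: `H-bBP` (baseline BP above 140/90
mmHg) and `N-bBP` (below 140/90, above 60/90), with both groups hearing the
same 20 playlists.

The analysis unit is the *listen* (one participant hearing one track), and
each listen is reduced to six variables computed on baseline-normalised beat
values: the mean, sample standard deviation and range (max - min) of
systolic and of diastolic BP. Normalisation subtracts each participant's own
mean BP from the silent baseline, so every number is an excursion from that
person's resting state, in mmHg.

## The synthetic cohort: what it emulates and what it does not

The participant recordings behind the original analysis are not deposited,
so the package ships a first-class generator (`simulate_cohort()`) whose
defaults *are* the published study conditions. A beat of simulated systolic
pressure during a listen is

$$\mathrm{SBP}(t) = \mu_i + R_g + u_{il} + m(t)\,\big(d_i(t) +
\varepsilon(t)\big) + L\cdot[\text{loud version}]$$

where $\mu_i$ is the participant's baseline mean, $R_g$ the group mean
reactivity, $u_{il}$ a per-listen deviation, $d_i(t)$ a smooth slow drift
(three sinusoids with periods 150/75/40 s and random phases), and
$\varepsilon(t)$ white beat noise. The damping factor $m(t) = 1 - c$ during
tempo-altered (fast) tracks and $1$ otherwise implements the tempo-coupled
suppression of within-listen variability; fast tracks are also shorter
(source duration divided by the tempo factor), which independently shrinks
the range because a shorter listen gives the drift less time to explore its
swing. Diastolic pressure follows the same model with its own parameters and
is capped below systolic on every beat.

Calibration, all derived from published summary statistics before any
testing, and fixed:

* **Baseline means** 148.25/94.5 mmHg (H-bBP) and 123.0/78.35 (N-bBP);
  between-subject SDs back-derived from the group 95% CIs as
  $\text{half-width}\times\sqrt{20}/t_{0.975,19}$, giving 14.23/8.87
  (systolic H/N) and 6.65/6.71 (diastolic).
* **Reactivity means** 3.61/3.95 (H-bBP) and 10.12/9.38 (N-bBP) mmHg;
  between-listen SDs back-derived from the listen-level CIs ($n=180$) as
  $\text{half-width}\times\sqrt{180}/1.96$: 15.33/16.53 systolic and
  12.22/12.36 diastolic (H/N). With the listen as the analysis unit, all
  cross-listen spread is placed at the listen level rather than split into
  participant and listen components; the sampling error of the recovered
  group mean is the same either way.
* **Within-listen structure**: drift amplitudes 12/9 mmHg and beat-noise SDs
  2.0/1.5 mmHg (systolic/diastolic). The drift dominates because real
  beat-to-beat BP is strongly autocorrelated; a noise-dominated mix of the
  same total variance produces a range/SD ratio near 5.9 (the white-noise
  extreme-spacing value over ~250 beats), visibly larger than the reported
  ratio of about 4.1. This mix reproduces the reported magnitudes (about
  5/21 mmHg systolic SD/range, 3.8/16 diastolic).
* **Coupling** $c = 0.18$, matching the reported fast/slow within-listen SD
  ratio of about 0.82; **loudness effect** $L = 0$ mmHg, mirroring the null
  loudness result (configurable for power studies).
* **Heart rate** 70 bpm, constant; **baseline** 300 s; **question gaps**
  between pieces 20 s, left unlabelled so the segmentation step genuinely
  drops beats.

Piece durations are not published (only 29-40 min playlist totals), so
source durations are fixed package choices between 180 and 360 s per piece;
mixed playlists then land in that band.

What the generator does *not* model: baroreflex or Windkessel mechanics,
respiration and heart-rate variability, measurement artifacts, medication,
or any genuine coupling between the musical surface and the pressure signal
beyond the piecewise damping above. Passing tests therefore show that the
pipeline recovers the statistical structure it assumes — not that real
listeners behave this way.

## Stimuli, features and tertiles

Performances are note-event tables (onset, duration, pitch, key-strike
velocity 1-127) read from CSV or Standard MIDI Files. `transpose_performance()`
divides every onset, duration and beat time by the tempo factor — mean bpm
scales exactly — and scales velocities multiplicatively with round-half-even
rounding clamped to 1-127 (the published description says only "linearly
altered"; a multiplicative gain is the natural reading for loudness).
Playlist construction randomises piece order first, then version, then
draws the closing repeat's version uniformly from the first piece's
remaining versions (unspecified in the source; uniform is the least
informative choice). One master seed drives everything, with per-playlist
and per-participant sub-seeds derived deterministically.

Tempo summaries are computed on instantaneous tempo, $60/\mathrm{IBI}$ per
inter-beat interval, summarised by mean, sample SD ($n-1$ throughout the
package) and maximum. Mean-of-instantaneous rather than
total-beats-over-total-time was chosen because the feature summaries are
defined on beat annotations; the printed per-track means cannot
disambiguate the two, and synthetic beat grids are normalised so their
instantaneous mean equals the catalogue value exactly. Loudness summaries
are the same three statistics over a uniformly sampled sone series (10 Hz
by default; the extraction tool's internals are out of scope), with
`sones_to_dba()` mapping to A-weighted decibels via
$33.2\log_{10}(\text{sones}) + 28$.

Tracks are grouped into tertiles under six schemes (tempo/loudness x
mean/SD/max). The mean schemes use the published fixed cut points — 60/120
bpm, giving the uneven 12/8/10 split, and 12.72/16.48 sones, giving
10/10/10. For SD and maximum the published cut points describe an audio
extraction we do not reproduce, so the default is an equal 10/10/10 split of
the synthetic summaries (which is also how those groupings are described);
the published thresholds remain available via `mode = "fixed_thresholds"`.
Equal splits sort stably by (value, track id) and cut at $n/3$ and $2n/3$,
warning when ties straddle a cut.

## The statistical battery

All tests are two-sided and nonparametric, at a Bonferroni-controlled
threshold $\alpha = 0.05/6 = 0.0083$ for the six-variable family.

* **Mann-Whitney U** (`mann_whitney()`) for two-level contrasts: exact null
  distribution when both sides have at most 8 tie-free observations,
  otherwise the tie-corrected normal approximation with continuity
  correction.
* **Kruskal-Wallis + Dunn** (`kruskal_dunn()`) for multi-level contrasts,
  with the *override rule*: when the omnibus test rejects but no Dunn pair
  is individually below $\alpha$, the finding is reported as not significant
  (`overridden = TRUE`). Dunn p-values are unadjusted by default, with an
  optional within-family adjustment flag.
* **Surrogate safeguard** (`surrogate_null()`): each test's pooled data is
  re-allocated at random into groups of the original sizes 1000 times and
  the same test applied; the significant fraction should sit at $\alpha$,
  operationalised as "within 3 binomial standard errors above $\alpha$",
  with the median surrogate p-value reported as a secondary check. Because
  these are rank tests, the loop precomputes pooled ranks once and evaluates
  the tie-corrected asymptotic statistic directly — numerically identical to
  the reference implementations on the same split, and cheap enough for
  1000 iterations across the full battery. Over ~270 tests, one or two
  reports are expected to graze the 3-SE bound by chance; the test suite
  asserts calibration in aggregate rather than demanding a simultaneous
  pass.

`run_full_battery()` applies Mann-Whitney to every between-group contrast
(overall, per version, per alteration aggregate, per tertile subgroup) and
to the within-group two-level alteration contrasts (slow vs fast, quiet vs
loud), and Kruskal-Wallis + Dunn to the within-group version and tertile
contrasts — 45 comparisons x 6 variables. Version-level contrasts exclude
the one piece whose fast/both versions invert the tempo ordering (*La
Cathedrale Engloutie*, whose source is V2); it remains in every aggregate
and tertile dataset, consistent with its footnoted treatment.

## Numerical and degenerate-input choices

* Sample SD everywhere; segments are half-open $[\text{start}, \text{end})$,
  so a boundary beat belongs to the segment that starts there; beats outside
  all intervals are dropped and counted.
* All-tied data takes an explicit $p = 1$ path in both tests rather than
  erroring, so a zero-noise cohort flows through the full battery.
* The waveform stand-in uses a raised-cosine pulse (zero slope at trough and
  peak), keeping the sampling error of systolic/diastolic recovery quadratic
  in the sample interval; delineation is trough-to-trough on local minima,
  taking each cycle's diastole from its interior samples.
* Listen-level CIs are reported with normal quantiles by default and Student
  t on request, since the convention behind the published intervals is not
  stated.

## Problem sizes and reproducibility

The default cohort is 40 participants x (one 5-min baseline + 9 listens) at
70 beats/min — about 110,000 beats — and simulates in a few seconds. The
test suite runs the full design on that size, plus a 200-per-group
parameter-recovery check on a duration-reduced catalogue; the acceptance
script regenerates the default cohort from scratch at the seed it is given.
Identical seeds give bit-identical cohorts, playlists, surrogate reports and
pipeline artefacts.

```{r example}
config <- cohort_config(seed = 7)
cohort <- simulate_cohort(config)
summaries <- summarize_cohort(cohort)
sapply(split(summaries$sys_mean, summaries$group), mean)
```

## Known limitations

The generator's damping acts through the catalogue's `tempo_altered` flag,
not through tertile membership, so tertile contrasts inherit significance
from the version structure rather than being independently parameterised.
Loudness-series sampling is idealised (no spectral accumulation from faster
note rates, which the published feature extraction explicitly notes).
Between-participant differences in *reactivity* are not modelled separately
from listen-level spread. None of these affect the six summary variables'
definitions, but they bound what the synthetic results can say about real
recordings.
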