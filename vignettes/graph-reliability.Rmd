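---
title: "Test-retest reliability of EEG brain-graph metrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Test-retest reliability of EEG brain-graph metrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphrely)
```

## The problem

Whether a resting-state EEG brain graph is worth tracking over time depends
on how repeatable it is. `graphrely` implements the full chain needed to
answer that question for a two-session, two-condition (e.g. before and after
an acute bout of exercise) design:

1. cut each multichannel recording into overlapping epochs,
2. estimate band-resolved functional connectivity per epoch with two
   estimators — the weighted phase lag index (wPLI) and spectral magnitude
   coherence (Coh),
3. reduce each connectivity matrix to three weighted global graph outcomes —
   clustering coefficient (CC), characteristic path length (PL) and
   small-world index (SWI),
4. quantify relative reliability (two-way absolute-agreement single-rating
   intraclass correlation, ICC, with F-based 95% CIs) and absolute
   reliability (standard error of measurement, SEM, and coefficient of
   variation, CoV, with bootstrap CIs) across the two sessions, and
5. compare reliability between conditions with a paired bootstrap and
   Cohen's d, plus a 2x2 repeated-measures ANOVA and paired t tests on the
   outcomes themselves.

Because raw participant EEG of this kind is rarely shared, the package
carries a first-class synthetic study generator so every stage can be
validated end to end against known ground truth.

## Connectivity estimation

Each 8 s epoch is split into 1 s Hann-tapered segments with 50% overlap
(15 segments per epoch at 256 Hz), and both estimators are computed from the
same segment cross-spectra $S_{xy,s}(f) = X_s(f)\,\overline{Y_s(f)}$:

$$\mathrm{wPLI}(f) = \frac{\left|\sum_s \mathrm{Im}\, S_{xy,s}(f)\right|}
  {\sum_s \left|\mathrm{Im}\, S_{xy,s}(f)\right|},
  \qquad
  \mathrm{Coh}(f) = \frac{\left|\langle S_{xy}(f)\rangle_s\right|}
  {\sqrt{\langle S_{xx}(f)\rangle_s\,\langle S_{yy}(f)\rangle_s}}.$$

Band values are arithmetic means over the frequency bins whose center lies
in $[\mathrm{low}, \mathrm{high})$ — half-open so shared edges such as 8 Hz
(theta/alpha-1) are counted once. wPLI is defined as 0 when its denominator
vanishes (pure zero-lag coupling, the volume-conduction case it is designed
to discount); coherence is magnitude (not squared) coherence so both
estimators live on the same $[0, 1]$ scale, with squared coherence available
via a flag. A segment-based spectral estimator was chosen because the wPLI
ratio needs several observations per epoch to be meaningful; an
analytic-signal (instantaneous-phase) variant would be an alternative
formulation but is not implemented.

Band selection happens in the frequency domain; no separate time-domain
band-pass is applied. For linear spectral estimators the two are equivalent,
and skipping the filter avoids edge effects on short epochs. The five
analysis bands are theta (4–8 Hz), alpha-1 (8–10.5 Hz), alpha-2
(10.5–13 Hz), beta-1 (13–20 Hz) and beta-2 (20–30 Hz). Theta is sometimes
defined as 5–8 Hz in this literature; `default_bands(theta_low = 5)`
switches to that variant. Delta and gamma are excluded: on real scalp data
they are dominated by ocular and muscular artifact.

A practical note on null levels: with 15 half-overlapping Hann segments the
wPLI of two genuinely independent channels averages about 0.3 rather than
the ~0.25 expected from 15 independent observations, because overlapping
segments are correlated and the effective observation count is smaller. The
test suite checks the implementation against a null distribution simulated
directly from the defining ratios rather than against an
independent-segment approximation.

## Graph metrics

Connectivity stacks (one matrix per epoch, per participant, session,
condition, band and estimator) are min-max rescaled so that the off-diagonal
values of the whole stack span exactly $[0, 1]$. This is an affine map — the
"rank" of the extrema only locates them — and it preserves weight structure,
which a full rank transform would destroy. A stack whose values are all
identical cannot be rescaled and is reported as a degenerate-input error.
All edges are kept (fully weighted graphs, no threshold).

* **CC** — per-node geometric-mean triangle intensity
  $C_i = (W^{1/3})^3_{ii} / (k_i (k_i - 1))$, the weighted-clustering
  convention of the standard brain-connectivity toolbox; global CC is the
  node mean. Nodes with fewer than two neighbors contribute 0.
* **PL** — edge lengths are reciprocal weights; all-pairs shortest paths by
  Dijkstra's algorithm (via igraph); global PL is the mean over ordered
  pairs. Disconnected graphs are an error that names an unreachable pair
  (dense normalized stacks are effectively never disconnected: at most the
  single minimum edge is 0).
* **SWI** — per band $b$, CC and PL are normalized by the mean over the
  *other* bands and SWI$_b$ = normCC$_b$ / normPL$_b$. The phrase "mean of
  all other values over all frequency bands" admits a leave-one-band-out and
  an all-band reading; the two differ by a known smooth factor and the
  leave-one-out reading is implemented (it is also the one for which
  "other" is literal). SWI is invariant under joint rescaling of all CC, and
  separately of all PL, values.

Graph metrics are computed per epoch and then averaged (CC, PL); SWI is
computed from the epoch-averaged CC and PL. Computing one graph from the
epoch-averaged matrix instead is available via `aggregate_matrices = TRUE`
for sensitivity analysis. Whether the per-epoch or the averaged-matrix
variant matches any given historical analysis is usually undocumented; the
per-epoch variant is the default because the per-epoch connectivity grids
are the estimator's natural output.

## Reliability statistics

With $n$ subjects and $k$ sessions, the two-way mean squares MSR (rows =
subjects), MSC (columns = sessions) and MSE give

$$\mathrm{ICC} = \frac{MSR - MSE}{MSR + (k - 1)\,MSE + \frac{k}{n}(MSC - MSE)},$$

the single-rating absolute-agreement two-way ICC. Estimates below 0 are
reported as 0 (the raw value is kept internally so bootstrap distributions
are not truncated). The 95% CI is the F-distribution construction for this
ICC form, clamped to $[0, 1]$ for reporting. Categories follow the
conventional cut-offs — poor < 0.4, fair < 0.6, good < 0.75, excellent
otherwise — with boundary points assigned to the higher category (the
published ranges leave the boundaries unassigned; a deterministic rule is
required and is documented here).

Absolute reliability: $\mathrm{SEM} = SD_\mathrm{pooled}\sqrt{1 -
\mathrm{ICC}}$ with the between-subject SD pooled across sessions
(root-mean of per-session variances), and $\mathrm{CoV} = 100\,
\mathrm{SEM} / |\bar{y}|$ percent. No closed-form CI exists under this SEM
definition, so the CoV interval is a seeded participant-level percentile
bootstrap (2000 resamples by default) with the ICC re-estimated inside
every resample.

The condition comparison resamples participants with replacement `k_cycles`
times (default 1000) and recomputes the statistic per resample for both
conditions. The *same* resample index matrix drives both conditions — a
paired bootstrap, justified because the two conditions share participants —
so identical inputs give Cohen's d of exactly 0 rather than resampling
noise. ICC resamples use the raw estimate clamped into
$[-(1 - 10^{-6}), 1 - 10^{-6}]$ before the Fisher z transform; CoV
resamples stay on the raw percent scale. A resample whose table is constant
(ICC undefined) is recorded at the clamped minimum and counted. Cohen's d is
$|\mu_a - \mu_b|$ over the equal-weight pooled SD, reported sign-free.

The 2x2 repeated-measures ANOVA (exercise x session, both within-subject)
tests each effect against its own subject-by-effect error stratum, giving F
at $(1, n-1)$ degrees of freedom. An effect whose sum of squares is
numerically zero (for instance a perfectly additive condition shift, which
makes the interaction contrast exactly zero for every participant) is
reported as F = 0, p = 1 rather than as the floating-point dust of a 0/0
ratio. A paired t test on matched vectors that are exactly identical
returns t = 0, p = 1; a constant *nonzero* difference has zero variance and
is an error, since t would be unbounded.

## The synthetic generator

`generate_study()` emulates the target design: 15 participants x 2 sessions
(~1 week apart in the emulated protocol) x PRE/POST, 5-minute recordings at
256 Hz (the post-downsampling rate of the emulated processing chain), with
a 19-channel montage by default for desk-scale runs and 65 channels
available to mirror a full cap with restored reference.

Each analysis band gets a ring of coupled channel pairs. Every edge shares
a band-limited latent oscillation between its two channels, delayed at the
lagging channel by the sample delay matching the requested phase lag at the
band's center frequency, so wPLI sees a genuine non-zero lag. Latents are
FFT-filtered Gaussian noise (realistic spectral spread inside the band);
pure tones are available (`waveform = "sine"`) for analytic test cases.
Independent Gaussian sensor noise (`noise_sd`, default 2 against
unit-variance latents scaled by coupling strengths around 0.6) sets the
within-session estimation noise. The default is chosen on signal-to-noise
grounds: white noise spreads its power over the whole spectrum, so the
noise power falling *inside* a 2–10 Hz-wide analysis band is a small
fraction of `noise_sd`^2; at `noise_sd = 2` the in-band SNR of a coupled
pair sits near 2, where the estimators respond smoothly to coupling
strength. With much weaker noise the in-band SNR is in the hundreds, the
estimators saturate identically for every participant, and — because each
participant's stack is min-max normalized — the between-participant
variance that reliability feeds on would vanish.

Participant coupling strengths are drawn once per participant
(mean 0.6, SD 0.2, clipped to $[0, 1]$); session-2 strengths correlate with
session-1 strengths at `session_consistency` (default 0.8) on a latent
normal scale (Gaussian copula). The POST condition adds `condition_shift`
(default 0.1) to the strengths. These defaults are a judgment call — no
generative model for exercise-induced coupling changes exists to copy —
and are chosen so that defaults produce ICCs spread over the poor-to-
excellent range rather than saturating at either end.

`session_consistency = 1` is implemented as the exact-replication limit:
per-recording random substreams are keyed by (participant, condition,
session), except that consistency 1 collapses the session key, making
repeated sessions bit-identical. This gives the perfect-repeatability
contract (every downstream ICC exactly 1) a precise meaning; for any
consistency below 1 the sessions draw independent latent and noise
realizations, so downstream ICCs reflect both strength consistency and
estimation noise.

What the generator does **not** emulate: volume conduction (no head model,
so zero-lag spread across sensors is absent), artifacts (ocular, muscular,
sweat) and any artifact-removal chain, non-stationarity within a recording,
1/f background spectra, and spatially structured montages. Passing tests
therefore demonstrate correctness of the estimators and statistics and
sane end-to-end behavior on band-limited lag-coupled signals — not that any
particular reliability level will be observed on real scalp EEG.

`generate_two_way_table()` is the analytic oracle for the reliability
statistics: $y_{ij} = \mu + r_i + c_j + e_{ij}$ with known variance
components and analytic ICC
$\sigma^2_r / (\sigma^2_r + \sigma^2_c + \sigma^2_e)$. The test suite uses
it for parameter recovery (mean recovered ICC within ±0.05 of analytic
values 0.2/0.5/0.75/0.9 at n = 15, k = 2) and CI coverage (93–97% at
ICC 0.75).

## Numerical choices and degenerate inputs

* Latents are generated on a highly composite FFT length and sliced, so
  generation stays $O(n \log n)$ for any duration.
* Band bins are half-open $[\mathrm{low}, \mathrm{high})$; estimator values
  are clamped into $[0, 1]$ against $10^{-16}$-scale excursions.
* Constant channels make coherence undefined (zero auto-spectrum) and are
  an estimation error; wPLI's zero-denominator case is the documented
  0 convention.
* Constant connectivity stacks cannot be min-max rescaled: degenerate-input
  error.
* A constant two-way table has no variance: ICC error. A perfect-agreement
  table (MSC = MSE = 0) reports CI [1, 1].
* All randomness is seeded; per-recording and per-bootstrap substreams are
  derived from the base seed with a small integer mixer bounded below
  $2^{31}$, and seeded helpers restore the caller's RNG state.

## Problem sizes used by the shipped checks

The test suite validates the full-scale replica (15 x 2 x 2 recordings of
300 s at 256 Hz, 19 channels, both estimators, five bands, 50 epochs, 1000
bootstrap cycles) plus a reduced perfect-repeatability run; the oracle
comparisons use 200 random graphs/tables each; recovery and coverage use
1000 replicate tables per condition. `scripts/acceptance.R` re-runs the
replica at full study scale (300 s per recording, 50 epochs, 1000
bootstrap cycles) with 500 recovery/coverage replicates — sizes chosen so
a complete validation runs comfortably on a laptop-class single core while
leaving Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Sensor-space only; no source reconstruction or leakage correction, so
  coherence values on real data carry volume-conduction structure that the
  generator does not model.
* Only the single-rating absolute-agreement ICC form is provided (no
  consistency or average-measures forms, no Bland–Altman, no minimal
  detectable change), matching the analysis this package operationalizes.
* The PLI/PLV/amplitude-envelope family of estimators and nodal/regional
  graph metrics are out of scope; the analysis is global-level by design.
* EDF I/O is a minimal continuous-recording implementation (equal rates
  across signals, whole-second records) sufficient for round-tripping this
  package's recordings, not a general EDF+ reader.
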