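---
title: "Swarm decomposition and fetal cardiac valve timing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm decomposition and fetal cardiac valve timing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdus)
```

## The problem

A Doppler ultrasound (DUS) transducer held over a fetal heart returns an
audio-band signal whose high-frequency content is dominated by the four
valve motions of each beat -- mitral closing (Mc), aortic opening (Ao),
aortic closing (Ac) and mitral opening (Mo) -- while wall motion occupies a
much lower band. If the valve band can be isolated and the four clicks
located within each cardiac cycle, the classic systolic time intervals
follow from simple differences:

* ICT (isovolumic contraction) = Ao − Mc
* VET (ventricular ejection) = Ac − Ao
* IRT (isovolumic relaxation) = Mo − Ac
* PEP (pre-ejection period) = EDT + ICT, with EDT the electromechanical
  delay between the R wave and mitral closure (default 25 ms)
* STI (systolic time interval) = PEP + VET

These intervals index fetal cardiac performance and change with gestational
age, so the package also carries the cohort statistics needed to compare
gestational-age groups (early 16--29, mid 30--35, late 36--41 completed
weeks): group mean ± SE over subject means, Kruskal--Wallis across the
three groups, pairwise Mann--Whitney post hoc tests (raw p-values), and
Spearman correlations of each interval with age over adjacent group pairs.

## Swarm filtering

The band-selective primitive is a *swarm filter* (SwF): a virtual swarm of
`n_members` agents hunts a prey whose trajectory is the input sequence
$s[n]$. Each member $i$ holds a position $p_i[n]$ and velocity $v_i[n]$ and
updates, with time step $\delta$,

$$v_i[n] = v_i[n-1] + \delta\,(F_{Dr,i}[n] + F_{Coh,i}[n]), \qquad
  p_i[n] = p_i[n-1] + \delta\, v_i[n].$$

The driving force attracts members to the prey with finite agility,
$F_{Dr,i} = a\,(s[n] - p_i[n-1]) - d\,v_i[n-1]$; the cohesion force
$F_{Coh,i} = c\,(\bar p[n-1] - p_i[n-1])$ pulls members toward the swarm
mean and turns into a short-range repulsion below `repulsion_scale`
(disabled by default, which keeps the force model linear and the filter
exactly homogeneous of degree 1). The filter output is the swarm-mean
position.

Two design points deserve emphasis:

* **The drag term is essential.** Without it the swarm mean obeys an
  undamped resonator whose poles sit exactly on the unit circle: a tone at
  resonance grows without bound and there is no steady-state gain to
  calibrate. The drag $d$ models the members' finite agility and places the
  poles at radius $r = \sqrt{1-\delta d} < 1$.
* **The sweep is zero-phase by default.** A single causal sweep carries a
  phase lag at resonance, which would bias every event time late and spoil
  the shape agreement between a centre-frequency probe and its filtered
  copy. `swarm_filter()` therefore hunts the signal forward and then
  backward (the same trick `signal::filtfilt` uses), cancelling the phase
  exactly. A `direction = "forward"` option retains the causal variant.

For the swarm mean these choices give a second-order resonator whose
centre frequency and bandwidth follow from $(\delta, a, d)$;
`swf_preset(center_hz, fs, q)` inverts that relationship, with quality
factor `q = 1.5` by default and a raised pole-radius floor near Nyquist so
every preset keeps an interior gain maximum. The binding contract, however,
is the *measured* response: `calibrate_swf()` drives every preset with probe
sinusoids swept over (0, fs/2), records the steady-state RMS gain, and
stores the gain-maximising frequency and −3 dB bandwidth. The shipped
family is 12 presets log-spaced over 5--450 Hz at 1 kHz, wide enough
(`q = 1.5`) that adjacent passbands overlap and the family tiles the
spectrum; the calibration table ships as a CSV and is regenerated by the
same function.

## Swarm decomposition

`swarm_decompose()` runs a sifting-like loop: estimate the dominant
frequency of the current residual (argmax of a smoothed periodogram),
select the calibrated preset with the nearest centre in log-frequency,
extract one oscillatory component (OC), subtract it, and repeat until the
residual holds less than 1% of the input energy, eight components have been
extracted, or an extraction stops removing energy. Because the residual is
updated by exact subtraction, components plus residual reconstruct the
input to floating-point round-off by construction.

One OC extraction applies the selected filter `n_passes` times (default 2,
with an early stop when two consecutive passes correlate at 0.999) and then
rescales the result by its least-squares projection onto the extraction
input. The projection step matters: the filter's passband gain is not
exactly 1, and plain subtraction of an unscaled output can *increase*
residual energy; after projection the subtraction is an orthogonal
decomposition, so residual energy decreases monotonically. We deliberately
keep the pass count small -- repeated passes concentrate the output ever
more narrowly on the preset's centre, which is desirable for a pure tone
but starves the loop when real content (for example a 30 Hz wall tone
sitting midway between two preset centres) straddles a band edge. Two
passes with overlapping presets extract two-tone mixtures with component
correlations above 0.99 and leave under 1% residual energy on synthetic
Doppler.

`instantaneous_energy()` is the squared envelope of an OC and mirrors the
energy trace used to visualise beat structure.

## From components to valve events

* **Valve component.** `select_valve_component()` takes the highest-energy
  OC whose centre frequency is at least 100 Hz (falling back to the highest
  centre), reflecting the physiological split between wall (low) and valve
  (high) bands. The selection is data-driven rather than positional because
  which extraction iteration yields the valve band depends on the energy
  balance of the recording.
* **Envelope.** Rectify, low-pass with a zero-phase 4th-order Butterworth
  at 25 Hz, scale by $\pi/2$ (the mean of a rectified unit sinusoid is
  $2/\pi$, so the scaling makes a tone's envelope equal its amplitude), and
  clip filter ringing at zero. The correction is exact in the
  fine-sampling limit; at carrier frequencies commensurate with fs (e.g.
  300 Hz at 1 kHz) the discrete rectified mean deviates by a few percent,
  which is irrelevant for peak *timing*.
* **Cycle anchors.** Without a fetal ECG the cycle anchor is a surrogate R
  peak derived from the systolic burst: envelope maxima above
  median + 3·MAD, greedily thinned to a 250 ms minimum separation (fetal
  heart rate ≤ 240 bpm), snapped to the earliest comparable peak within
  100 ms (so the anchor locks onto the first click of the S1 complex even
  when the aortic click is marginally taller), shifted to the leading
  50%-height crossing, and advanced by 8 ms. The lead compensates the
  difference between the electromechanical delay (~15 ms from R to Mc) and
  the envelope rise time, so the surrogate lands within ~10 ms of the true
  R wave on clean synthetic data. A trailing diastolic click with no
  following beat to suppress it is removed by requiring accepted peaks to
  reach 70% of the median accepted height. In ECG-reference mode externally
  supplied R peaks are validated and used unchanged.
* **Segmentation and events.** Anchors delimit half-open RR segments;
  beats with RR outside 250--700 ms are discarded as segmentation faults.
  Each segment's envelope is z-normalized (n−1 denominator) and searched
  inside per-event windows relative to the anchor -- Mc 0--50, Ao 50--100,
  Ac 140--260, Mo 260--330 ms, clipped to the segment -- for the highest
  first-difference sign-change peak above a noise floor of 0.5 normalized
  units; ties break toward the earlier peak. A window without a qualifying
  peak yields a missing event: missingness is data, and a beat missing one
  event still contributes every interval that does not need it.

## The synthetic generator

`generate_dus()` is first-class, tested code, not a fixture: every pipeline
stage is validated against its ground truth. It emulates

* a quasi-periodic beat schedule, RR ~ Normal(420, 10) ms clipped to
  250--700 ms;
* four Gaussian-windowed 250 Hz tone bursts per beat at offsets
  15/55/195/270 ms with jitter SDs 3/4/5/4 ms -- values centred in the
  search windows and close to published group means. `burst_width_ms = 15`
  is the burst's full width at half maximum (Gaussian SD 6.4 ms), matching
  the few-tens-of-ms duration of real valve clicks; amplitudes
  (1, 0.85, 0.7, 0.6) make systole louder than diastole with mitral
  closure loudest, as in real Doppler audio;
* a 30 Hz wall-motion tone amplitude-modulated over each beat;
* white (optionally pink) noise scaled against the noiseless mixture to a
  requested SNR (default 10 dB), realised within ±0.5 dB by construction;
* output normalized to peak 0.9 like recorded audio, with the same factor
  applied to all stored truth tracks.

What it does *not* emulate: Doppler speckle, transducer or fetal movement,
signal dropout, maternal interference, or beat-to-beat morphology changes.
Passing tests on this generator therefore demonstrate that the algorithm
chain is correct and self-consistent under controlled conditions, not that
it is robust to every artefact of clinical recordings.

`generate_fecg()` places a QRS-shaped template exactly on the schedule to
exercise ECG-reference mode; `generate_cohort()` draws subject-level event
offsets from group distributions and synthesises one recording per subject;
`simulate_cohort_intervals()` skips the waveform and draws subject-level
interval means directly -- the surrogate used for the power analysis below.

## Statistics, and what the simulation can and cannot show

Group summaries report mean ± SE (SE = sd/√n over subject means).
Hypothesis tests go through `stats::kruskal.test` and `stats::wilcox.test`
(exact for small tie-free samples, normal approximation with continuity
correction otherwise; raw p-values, no multiplicity adjustment), wrapped so
that degenerate all-tied inputs return H = 0, p = 1. The test wrappers are
cross-checked in the suite against a hand-ranked H computation and a full
20-arrangement enumeration of the exact Mann--Whitney distribution. The age
"correlation" is implemented as Spearman rank correlation between age
(group rank, or gestational weeks when available) and the subject interval
mean over two pooled adjacent groups; this is an interpretation -- the
operational definition behind published correlation tables is not stated --
and is documented as such rather than asserted as a reproduction.

Reference group moments (means and SEs of RR, the four event timings and
the five intervals for 16/21/29 fetuses) are built into
`fetal_timing_reference()` and drive the cohort simulators, with
between-subject sd recovered as SE·√n. A caveat the package states plainly:
under a Gaussian surrogate at exactly those moments, Kruskal--Wallis power
at α = 0.05 over 200 replicates is only ≈ 0.62 for STI, ≈ 0.11 for IRT and
≈ 0.70 for PEP -- the printed IRT group means differ by at most 4 ms
against between-subject SDs of 9--17 ms. Significance on real recordings
at these sample sizes is therefore not implied by the surrogate, and the
acceptance suite reports this figure as measured rather than adjusting the
simulation toward significance.

## Numerical choices and degenerate inputs

* Determinism everywhere: swarm initial state is an evenly spaced ±1e−6
  spread around the first sample (its symmetry cancels in the mean), all
  generators take explicit seeds and restore the caller's RNG state, and
  repeated runs are bit-identical.
* Divergence guard: any member position exceeding 1e6 × max(|s|, 1e−6)
  aborts with "swarm diverged (reduce delta)"; the floor keeps the guard
  meaningful for silent inputs.
* Cohesion is capped per preset at 50% of the margin to the member
  stability boundary, so a near-Nyquist preset can never be destabilised by
  the cohesion force.
* Zero or constant signals: dominant-frequency estimation refuses them
  ("no oscillatory content"); decomposition of silence returns zero
  components; a zero-variance cycle segment is a "degenerate segment"
  error; identical samples in a test group give H = 0, p = 1.
* Indexing: half-open segments, event times in ms from the segment start,
  full precision in every persisted file (report-level rounding to 1
  decimal happens only in print methods).
* Problem sizes used by the shipped checks: two-tone decomposition on 10 s
  of signal, timing recovery on twenty 60 s recordings at 10 dB SNR, power
  and type-I simulations on 200 and 1000 replicates respectively -- sizes
  chosen so the full suite characterises the method while running in a few
  minutes on one core.

## Known limitations

* The original swarm-decomposition literature learns the
  parameter-response map with a genetic algorithm; this package replaces
  that with a deterministic empirical calibration, so parameterisations
  other than the shipped preset family should be calibrated before use.
* The exact functional form of the forces and the output tap are not fully
  pinned down in the source material; the damped prey-attraction/cohesion
  model here is the simplest member of the described family, and the
  measured frequency response -- not the internal force form -- is the
  interface other components rely on.
* Anchor detection assumes the systolic complex dominates the valve-band
  envelope; rhythms or pathologies that invert the S1/S2 energy balance
  would need the ECG-reference mode.
* The method is inherently offline (the zero-phase sweep needs the whole
  record); it is not suitable for real-time use.
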