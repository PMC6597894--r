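# swdus

Fetal cardiac valve timing from Doppler ultrasound via swarm decomposition.

A Doppler ultrasound (DUS) transducer over a fetal heart returns audio
whose high-frequency band carries the clicks of the four valve motions of
each beat — mitral closing (Mc), aortic opening (Ao), aortic closing (Ac),
mitral opening (Mo) — while wall motion sits in a low band. `swdus`

1. decomposes the single-channel signal into oscillatory components with
   **swarm filtering**: a virtual swarm of agents hunts the signal as prey,
   each member updating `v_i[n] = v_i[n-1] + δ(F_drive + F_cohesion)`,
   `p_i[n] = p_i[n-1] + δ v_i[n]`; the swarm-mean trajectory is a
   band-selective filter whose response is measured, not assumed, and a
   sifting-like loop peels off one dominant band at a time
   (`swarm_decompose()`), with exact additive reconstruction;
2. selects the valve-band component, envelopes it, anchors each cardiac
   cycle at the onset of the systolic burst (or at externally supplied
   fetal-ECG R peaks), and locates the four events inside physiological
   search windows (`run_event_pipeline()`);
3. converts event times to the systolic time intervals
   ICT = Ao−Mc, VET = Ac−Ao, IRT = Mo−Ac, PEP = EDT+ICT, STI = PEP+VET
   (`compute_intervals()`, electromechanical delay EDT = 25 ms by default);
4. compares gestational-age groups (early 16–29, mid 30–35, late 36–41
   weeks) with mean ± SE summaries, Kruskal–Wallis, pairwise Mann–Whitney
   post hoc tests and Spearman age correlations (`group_stats()`);
5. ships a fully parameterised synthetic DUS generator with ground truth
   (`generate_dus()`, `generate_cohort()`) so every stage is testable
   without recordings, plus WAV/CSV/YAML interfaces and a command-line
   front end (`inst/cli/swdus`).

It is aimed at biomedical-signal-processing researchers working on
non-invasive fetal cardiac assessment.

## Worked example

```r
library(swdus)

# one minute of synthetic fetal Doppler at 1 kHz, 10 dB SNR
d <- generate_dus(synth_config(duration_s = 60, snr_db = 10), seed = 1)
d
#> <synthetic_dus> 60 s @ 1000 Hz, 143 beats, SNR 10 dB (seed 1)

ev <- run_event_pipeline(d$signal)
ev
#> <valve_events> 142 beats (auto-anchor mode), valve component #2, 2 missing events
#>  beat_index anchor_time_s rr_ms t_mc_ms t_ao_ms t_ac_ms t_mo_ms ordered
#>           1         0.000   408      11      57     201     270    TRUE
#>           2         0.408   425      21      65     202     269    TRUE
#>           3         0.833   405      21      57     202     270    TRUE
#> ...

compute_intervals(ev)
#> <beat_intervals> 142 beats (EDT = 25 ms)
#>  beat_index rr_ms ict_ms vet_ms irt_ms pep_ms sti_ms flag_ordering
#>           1   408     46    144     69     71    215         FALSE
#>           2   425     44    137     67     69    206         FALSE
#> ...
```

The event columns are times in ms from the beat anchor (a surrogate R
peak); `ordered` confirms the physiological Mc < Ao < Ac < Mo sequence, and
each interval row follows from the event differences above plus the 25 ms
electromechanical delay. Feeding published per-group mean event timings
through the same arithmetic reproduces the published interval rows, e.g.
for the early-gestation group:

```r
compute_intervals(c(t_mc_ms = 14.51, t_ao_ms = 59.4,
                    t_ac_ms = 198.08, t_mo_ms = 275.57), edt_ms = 25)
#>  beat_index rr_ms ict_ms vet_ms irt_ms pep_ms sti_ms flag_ordering
#>           1    NA   44.9  138.7   77.5   69.9  208.6         FALSE
```

Group-level statistics over a cohort of subject summaries:

```r
cohort <- simulate_cohort_intervals(seed = 1)   # 16/21/29 subjects
group_stats(cohort, measures = c("sti_ms", "irt_ms", "pep_ms"),
            group_order = c("early", "mid", "late"))
```

## Command line

```sh
Rscript inst/cli/swdus simulate  --out-wav dus.wav --out-truth truth.csv --seed 1
Rscript inst/cli/swdus decompose --in dus.wav --out components.csv
Rscript inst/cli/swdus detect    --in dus.wav --out events.csv
Rscript inst/cli/swdus intervals --in events.csv --out intervals.csv
Rscript inst/cli/swdus stats     --in subjects.csv --out-csv report.csv --out-json report.json
```

`detect --r-peaks rpeaks.csv` switches to ECG-reference mode. Signals are
16-bit PCM mono WAV or `time_s,value` CSV; configuration is YAML (blocks
`swd`, `events`, `stats`, `synthetic`); logs go to stderr, results to
files.

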