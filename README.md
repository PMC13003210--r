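# mmbreath

Multimodal breath analysis from wearable impedance pneumography and
lung sounds.

## The problem

Acute asthma in children changes both *how* they breathe and *how their
breathing sounds*. A wearable that records transthoracic electrical
bioimpedance (impedance pneumography, IP — impedance rises with
inspiration) simultaneously with chest-wall acoustics can quantify both:
the IP signal yields breath-by-breath respiratory timings, and — because
it marks when each inspiration and expiration happens — it lets every
segment of lung-sound audio be attributed to a breathing phase, so
spectral features can be computed separately for inspiration and
expiration. `mmbreath` implements that full analysis chain for
researchers working with such recordings, plus a synthetic-recording
generator with ground-truth annotations so every stage can be validated
without patient data.

## What it computes

Per breath (an interbreath interval, IBI, running trough-to-trough in
the filtered IP signal with the peak marking the inspiration-to-
expiration transition):

- **5 timing features** — RR = 60/IBI (breaths/min), inspiration time
  Ti, expiration time Te, Te:Ti, and the inspiratory duty cycle Ti/IBI;
- **8 acoustic features** — normalized spectral integrated intensities
  (SIs) of the band-passed (100–1000 Hz) lung sound over the subbands
  100–300, 300–500, 500–800 and 800–1000 Hz, computed from 64-ms Hamming
  periodograms (75% overlap) separately for the inspiratory and
  expiratory phase. The four SIs of a phase are fractions of the total
  100–1000 Hz power and sum to 1.

The cascade: FIR-antialiased resampling (IP → 100 Hz, audio → 4 kHz);
amplitude-artifact removal (samples beyond 1.5×/0.5× the recording
median, linearly interpolated); zero-phase Kaiser FIR band-passes
(0.1–1 Hz nominal for IP, extendable to 1.4 Hz; 100–1000 Hz for audio);
windowed breath detection (32-s windows, 0.67-s minimum peak distance,
capping detectable rates at 60/0.67 = 89.55 bpm); a template-correlation
signal-quality index (duration CoV ≤ 0.3, template correlation > 0.7,
≥ 60% breath coverage per 32-s window); 5-MAD (timing) and 4-MAD
(acoustic intensity) sliding 30-breath outlier filters; an inner join
into the 13-feature multimodal breath table; 32-s/75%-overlap windowed
averaging with a final 5-MAD window-level filter and linear
interpolation. Cohort statistics use Wilcoxon signed-rank tests (paired
time points), rank-sum tests against controls with Benjamini–Hochberg
correction across the two comparisons, and a z-scored 2-D PCA with PC1
loading ranking.

## Worked example

```r
library(mmbreath)

# a 2-minute synthetic recording: 24 breaths/min, Ti/IBI 0.45,
# 3% breath-timing jitter, low sensor noise
set.seed(7)
ibi <- 60 / 24
nb <- ceiling(120 / ibi) + 2
plan <- breath_plan(ti = 0.45 * ibi * exp(rnorm(nb, 0, 0.03)),
                    te = 0.55 * ibi * exp(rnorm(nb, 0, 0.03)),
                    noise_sd = 0.002, seed = 7)
ip    <- generate_ip(plan, fs = 16, duration_s = 120)
audio <- generate_lung_sound(ip$truth,
                             acoustic_spec(inspiration_gain_db = 6,
                                           seed = 8), 120)
res <- process_recording(ip$trace, audio)

round(res$retention, 3)
#>    detected  quality_ok timing_kept  multimodal
#>          45           1           1           1
head(res$breaths[, c("breath_id", "RR", "Ti", "Te", "TiIBI",
                     "SI100_300_I", "SI500_800_E")], 4)
#>   breath_id       RR       Ti       Te     TiIBI SI100_300_I SI500_800_E
#> 1         1 24.39679 1.082093 1.377246 0.4399935   0.2466343   0.3562105
#> 2         2 24.12443 1.103027 1.384079 0.4434981   0.1985713   0.3594282
#> 3         3 23.46619 1.107698 1.449172 0.4332243   0.2066849   0.3686637
#> 4         4 24.01007 1.100426 1.398526 0.4403551   0.2409907   0.3477866
```

45 breaths are detected; every one passes quality control and the
outlier cascades (clean signal), and the fused table carries the
13-feature vector per breath (`ncol(res$breaths) - 2` id/onset columns
= 13). Recovered RR hovers around the generated 24 bpm and Ti/IBI
around 0.45; the SIs reflect the generator's flat 100–1000 Hz noise
(the 500–800 Hz band is widest, hence largest). `res$timeseries` holds
the 12 windowed rows (32-s windows, 8-s hop) used by cohort statistics.

Whole labeled cohorts come from `generate_cohort(asthma_cohort_spec())`
(admission-like, pre-discharge-like and control-like groups), are
processed with `process_cohort()` and compared with `analyze_cohort()`.
A command-line interface wraps the same steps:

```sh
Rscript -e 'mmbreath::mmbreath_cli()' all --out cohort_dir --seed 1
```

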