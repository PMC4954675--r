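# convotrace

Privacy-preserving conversation analysis in R: from frame-level acoustic
traces (energy, pitch, voicing — never words or voices) to a within-person
model of conversation enjoyment.

convotrace is for behavioral and mobile-sensing researchers who capture
everyday conversations with phone apps that, by design, keep no raw audio.
From a mono WAV file or a pre-computed frame table it

1. extracts per-frame **volume** (dBFS), **F0** (autocorrelation with octave
   disambiguation) and a **voiced** flag;
2. **diarizes** each conversation by k-means clustering of the 1-D frame
   volumes into four regimes — clothing noise > participant > other
   speakers > silence — followed by minimum-duration smoothing (1.5 s) and
   removal of the trailing end-of-conversation silence (60 s);
3. computes the five conversation-level predictors: length (min), % of time
   the participant spoke, turn-taking rate (turns/min), and the
   participant's volume and pitch variability;
4. applies auditable **QC rules** (negative speaking time, no
   non-participant time, turn rate or mean volume above mean + 3 SD, mean
   pitch above 255 Hz) and drops participants with fewer than 3 retained
   conversations;
5. fits the **two-level model**

   `rating_ij = gamma_0 + u_j + beta' z_ij + e_ij`,  `u_j ~ N(0, tau^2)`, `e_ij ~ N(0, sigma^2)`

   — a random intercept per person `j`, conversations `i` at level 1, the
   five z-scored predictors entered simultaneously, estimated by REML with
   Satterthwaite df (`lmerTest`), with broom-style `tidy()`/`glance()` and
   `autoplot()` methods.

Because such data are never deposited, the package includes a calibrated
synthetic-data generator (alternating two-speaker turn structure, four
volume regimes, adult F0 range 92–253 Hz, ratings with marginal mean 4.31
and SD 1.25 whose only non-zero standardized effect is −0.19 on % speaking
time) so the whole pipeline is testable end to end. It can also render
actual WAV audio (harmonic tones + noise) to exercise the acoustic front
end.

## Worked example

```r
library(convotrace)

cfg <- pipeline_config(
  generator = generator_config(
    n_participants = 8,
    conversations_per_participant = list(mean = 6, sd = 2, min = 3, max = 10),
    length_s = list(mean = 90, sd = 40, min = 45, max = 240)),
  seed = 42)
res <- run_pipeline(cfg, out_dir = "demo_run")
res$qc
#> <qc_result>
#>   retained: 51 of 52 conversations
#>   negative_speaking_time   0
#>   no_nonparticipant_time   0
#>   turn_rate_gt_3sd         1
#>   volume_gt_3sd            0
#>   pitch_gt_255             0
res$fit
#> <hlm_fit> REML, 51 conversations in 8 participants (converged)
#>   random-intercept var 0.5078, residual var 1.2221
#>          term estimate std.error   df statistic p.value
#>        length  -0.1540     0.195 41.3    -0.790  0.4338
#>  pct_speaking  -0.1577     0.190 44.6    -0.829  0.4115
#>     turn_rate  -0.0537     0.185 42.5    -0.290  0.7733
#>        vol_sd   0.3062     0.167 42.0     1.829  0.0745
#>      pitch_sd  -0.1445     0.238 17.0    -0.608  0.5514
```

The run directory holds every stage's table (`frames.csv`, `segments.csv`,
`features.csv`, `retained.csv`, `correlations.csv`, `model_fit.json`) plus
a `manifest.json` echoing the seed and every threshold. Here one
conversation was excluded for an abnormally high turn rate; each estimate
is in SD units of its predictor, so `pct_speaking = -0.158` means a
conversation one SD above that cohort's mean speaking share is rated about
0.16 points lower on the 1–7 scale, against the person's own baseline. At
this demo size the effect is within noise; the calibrated recovery check
below runs 200 cohorts of 36 participants.

A shell wrapper with the same stages is installed as `exec/convotrace`
(subcommands `run`, `simulate`, `diarize`, `features`, `qc`, `fit`; exit
codes 0/2/3 for success/config error/data error).

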