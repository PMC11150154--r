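# secsurge

Nocturnal blood-pressure surges in seconds ("sec-surges") are brief, acute
systolic BP elevations lasting several tens of seconds, typically triggered
by obstructive sleep apnea episodes or sympathetic bursts. They load the
cardiovascular system far beyond what conventional intermittent (every 30
minutes) nocturnal BP monitoring can see, and manually screening an
overnight beat-by-beat recording of 25,000–35,000 beats is impractical.
`secsurge` is an R toolkit for exactly this problem: it detects sec-surge
episodes in beat-by-beat systolic BP series, learns a physician-auditable
detection rule from expert labels, evaluates detections against labels, and
computes the standard nocturnal BP and per-surge severity variables.

The package is aimed at cardiovascular-monitoring researchers and
algorithm developers who need a complete, testable pipeline without access
to clinical recordings: a calibrated synthetic night generator stands in
for patient data, planting annotated surges whose per-night count, peak and
amplitude statistics match published severity figures.

## The method

**Candidate extraction.** Candidate peaks are strict local maxima of the
valid-beat SBP within a sliding 60 s window. For each peak the *start* is
located where stable pre-surge SBP ends (trailing window of 10 beats with
range ≤ 5 mmHg, walking backward from the peak) and the *end* is the first
beat whose SBP has decayed by 75% of the amplitude,

```
SBP(end) ≤ SBP(peak) − 0.75 · (SBP(peak) − SBP(start)).
```

Candidates below 15 mmHg amplitude are discarded.

**Features.** Each candidate is described by 48 features in six groups of
eight — reactivity phase, recovery phase, amplitude, upward, downward and
whole duration — all computable from (start, peak, end) and the beats
between them.

**Rule learning.** Every feature is swept over all observed thresholds and
scored by F-measure, `F = 2PR/(P+R)` with precision `P = TP/(TP+FP)` and
recall `R = TP/(TP+FN)`. The best feature per group (groups never
duplicated) enters an exhaustive grid search over per-feature quantile
grids; the learned classifier is a conjunction of inclusive threshold
conditions (`X ≥ A` / `X ≤ A`), so a physician can read exactly why a
candidate was accepted.

**Evaluation.** Detections match labels one-to-one when the detected peak
falls inside the label interval ± 10 s; recall/precision are reported
per night-level cross-validation fold (counts pooled within fold) with mean
± SD across folds.

**Variables.** From intermittent cuff readings: mean, SD, CV and ARV of
SBP. From detected surges: counts, peak, amplitude and durations, overall
and split into sleep-apnea-related vs non-related using polysomnography
event overlap.

## Worked example

```r
library(secsurge)

# one synthetic overnight recording (~25,000 beats, 7 h)
night <- generate_night(sim_config(), seed = 0)

# train the AND-rule on three other synthetic nights
nights <- lapply(1:3, function(s) {
  nt <- generate_night(sim_config(), seed = s)
  list(series = nt$series, labels = nt$labels)
})
model <- train_detector(nights)
model$rule
#> <decision_rule: 6 conditions, training F = 0.992>
#>   amplitude >= 15.01
#>   whole_sd_sbp >= 4.417
#>   down_ls_slope <= -0.355
#>   react_t75_t25_ratio <= 37.54
#>   rec_time_to_25 >= 0.9444
#>   up_ls_slope >= 0.3109

# detect on the held-out night and score against its labels
det <- detect_surges(night$series, model)
evaluate_detections(det, night$labels)
#> <eval_report: TP 32, FP 1, FN 2 | recall 0.941, precision 0.970, F 0.955>

# severity variables with sleep-apnea attribution
det <- categorize_sa(det, night$events)
surge_variables(night$series, det)
#> 33 surges (17 SA / 16 non-SA), mean peak 150.9 mmHg, mean amplitude 29.1 mmHg
```

The learned rule above reads directly as clinical criteria: an episode is a
sec-surge if it rises at least ~15 mmHg, varies enough overall, falls at a
genuine downward slope, and so on — no black box.

## Command-line use

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "secsurge.R", package = "secsurge"))')
Rscript $CLI simulate --seed 1 --out-dir nights --nights 20
Rscript $CLI train    --manifest nights/manifest.json --out model.json
Rscript $CLI detect   --series nights/night0001.csv --model model.json --out det.tsv
Rscript $CLI evaluate --series nights/night0001.csv --detections det.tsv \
                      --labels nights/night0001_labels.tsv --out report.json
```

File formats: beat series as CSV (`time_s,sbp,dbp,quality`), labels and
detections as TSV (`night_id,start_s,peak_s,end_s,class`), PSG events as
TSV (`night_id,kind,start_s,end_s`), configuration as YAML or JSON. Every
CLI run writes a JSON run-record next to its output.

## Limitations

The detector operates on systolic values only, assumes sinus rhythm (large
beat-to-beat variation as in atrial fibrillation defeats the stability
criterion), and the synthetic benchmark — however calibrated — cannot
substitute for clinical validation. See the methods vignette
(`vignettes/secsurge-methods.Rmd`) for the full account of the model,
parameter choices and what passing tests do and do not show.
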