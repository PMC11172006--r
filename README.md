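# taaft

Threshold-aware accumulative fine-tuning (TAAFT) for lung-ultrasound
classifiers, with the upstream M-mode preprocessing pipeline and a
downstream metadata subgroup audit.

## The problem

Deep-learning classifiers for point-of-care lung ultrasound (LUS) — here,
detection of **absent lung sliding**, the M-mode "barcode" pattern that
suggests pneumothorax — are usually trained at a single center and degrade
on clips from other institutions (different vendors, presets, gains,
depths). Annotated external LUS data are scarce, and every clip spent on
fine-tuning is a clip no longer available for validation. TAAFT is a
protocol for spending a limited external dataset optimally: it determines
the **minimum fraction of the external data** that must be used for
fine-tuning to reach predefined performance goals, while evaluating every
candidate model on both the most representative sample available and a
constant comparison set.

This package is for ML researchers and ultrasound groups who want to run or
study that protocol end to end at desk scale: it is model-agnostic (any
classifier satisfying a three-function contract plugs in), ships a
lightweight baseline classifier, and includes a synthetic multicenter LUS
generator so the entire pipeline is testable without patient data.

## The protocol

For one trial with parameter k (default 3):

1. Split the external dataset patient-wise into 2k folds of roughly equal
   clip counts (every patient's clips stay together).
2. Iteration 0: evaluate the pretrained base model M<sub>0</sub> on the
   **variable-sized validation set** (initially all data) and the
   **fixed-size validation set** (the constant union of the last k folds).
3. Iteration i = 1..k: move fold i into the training set
   (p<sub>train</sub> = i/2k), make an inner patient-wise 80/20
   train/secondary-validation split, upsample the positive class from a
   sequestered pool of candidate M-mode images to the source-domain class
   distribution (26% positive by default), fine-tune M<sub>0</sub> (always
   from M<sub>0</sub>, never from the previous iteration's model), and
   evaluate on both validation sets.

An experiment repeats this for n_trials = 5 independent patient-wise
splits. It **succeeds** if, at some proportion, the trial-wise mean
sensitivity and specificity on the variable-sized set meet the goals
(defaults 0.901 / 0.793); the smallest such proportion is selected, a final
model is fine-tuned at that proportion with a fresh split, and a **drift
check** re-evaluates it against M<sub>0</sub> on the original local holdout.

Upstream, each B-mode clip is segmented into 3-s windows, a pleural-line
ROI is located, columns are scored by summed brightness in the ROI band of
the first frame, and M-mode images (depth × time) are reconstructed from
the 10 brightest columns of each absent-sliding clip — the brightest is the
main example, the other 9 are sequestered into the upsampling pool — then
resized to 224×224.

Downstream, `audit_subgroups()` tests whether prediction correctness
(chi-squared independence, no continuity correction) and prediction error
|score − label| (one-way ANOVA) depend on vendor, probe, preset, depth bin
or institution, separately within ground-truth-positive examples
(sensitivity effects) and ground-truth-negative examples (specificity
effects), and computes a **within-subgroup fragility index** — the minimum
number of correctness flips inside one subgroup level that overturns a
significant chi-squared result — for every significant combination.

## Worked example

Train a baseline on a synthetic single-center cohort, watch it lose
specificity on a shifted multicenter cohort, and recover it with TAAFT:

```r
library(taaft)

local <- simulate_mmode_dataset(lus_config(
  n_patients = 40, positive_fraction = 0.26,
  institutions = default_institutions("local"), patient_prefix = "L", seed = 12))
lmain <- local$records[local$records$is_main, ]
m0 <- baseline_fit(local$images[lmain$mmode_id], lmain$label)

external <- simulate_mmode_dataset(lus_config(patient_prefix = "E", seed = 213))
external
#> <mmode_dataset> 380 M-mode images (173 main, 207 pooled) from 173 clips, 60 patients

emain <- external$records[external$records$is_main, ]
evaluate(predict_scores(m0, external$images[emain$mmode_id]), emain$label)
#> <lus_metrics> n=173  sens=1.000  spec=0.673  auc=1.000  acc=0.717 (thr=0.50)
#>  TP  FN  FP  TN
#>  23   0  49 101
```

The single-center model keeps perfect sensitivity but mislabels 49 of 150
sliding clips as absent (specificity 0.673): the external centers' weaker
sliding signature pushes their negatives across the locally learned
boundary. Now the experiment:

```r
exp <- run_experiment(external, m0, k = 3, n_trials = 5, seed = 1)
exp
#> <taaft_experiment> k=3, 5/5 trials complete, seed=1
#>   goals: sens >= 0.901, spec >= 0.793 on the variable-sized set
#>   SUCCESS: smallest qualifying proportion p_train = 0.1666667
#>    p_train iteration      set      metric      mean          sd n
#>  0.0000000         0 variable sensitivity 1.0000000 0.000000000 5
#>  0.0000000         0 variable specificity 0.6733333 0.000000000 5
#>  0.1666667         1 variable sensitivity 1.0000000 0.000000000 5
#>  0.1666667         1 variable specificity 0.9984127 0.003549314 5
#>  0.3333333         2 variable sensitivity 1.0000000 0.000000000 5
#>  0.3333333         2 variable specificity 1.0000000 0.000000000 5
#>  0.5000000         3 variable sensitivity 1.0000000 0.000000000 5
#>  0.5000000         3 variable specificity 1.0000000 0.000000000 5

fin <- finalize_model(external, m0, proportion = exp$selected_proportion, seed = 99)
fin$metrics
#> <lus_metrics> n=144  sens=1.000  spec=0.984  auc=1.000  acc=0.986 (thr=0.50)
```

Fine-tuning on one-sixth of the external data already lifts mean
specificity from 0.673 to 0.998 with sensitivity intact, so 1/6 is the
smallest qualifying proportion; the final model, fine-tuned at that
proportion on a fresh split, reaches specificity 0.984 on its own
variable-sized validation set. `drift_check(fin$model, m0, local_holdout)`
then verifies the fine-tuned model has not regressed on source-domain data,
and `audit_subgroups()` takes per-clip scores plus the manifest and flags
metadata subgroups that drive residual errors.

A command-line front end over the same functions (subcommands `simulate`,
`preprocess`, `split`, `taaft`, `audit`) is in
`inst/cli/taaft_cli.R`.

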