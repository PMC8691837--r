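# ghostflow

A desk-scale, end-to-end **simulated ghost cytometer** in R: compressive
motion-imaging waveforms from synthetic cell phantoms, the full
acquisition signal chain, fluorescence-threshold supervision, SVM and
1D-CNN label prediction, in-silico sorting, and the evaluation machinery
(repeated-sampling ROC/AUC, mean-ROC recovery rates, stratified
cross-validated macro-F1).

## Who this is for

Ghost motion imaging (GMI) classifies flowing cells from *stain-free*
one-dimensional waveforms instead of reconstructed images: a cell
crossing a static structured-illumination mask $H$ produces, on a
single-pixel detector,

$$G(t) = g\sum_{r,j} H[t-h+r,\,j]\, I[r,j] + b,$$

a discrete cross-correlation of the mask with the moving projected cell
image $I$ — one compressed random projection of the whole image per
cell, with over 100 samples per waveform. A classifier trained on
waveforms paired with fluorescence labels can then predict the label *in
silico* and drive a sorter in real time. `ghostflow` is for method
developers and students who want a fully inspectable, reproducible
software twin of that pipeline: every stage is a documented R function
with an exact or statistical oracle behind it, and every random draw is
seeded.

## Worked example

Two cell classes with identical size distributions that differ only in
internal texture — invisible to forward/side scatter, visible to the
compressive waveforms:

```r
library(ghostflow)

spec   <- benchmark_two_class_spec(n_per_class = 300, seed = 101)
events <- simulate_events(spec)           # phantoms -> waveforms -> events
events
#> <isgc_events> 600 events, 5 waveform modalities (dGMI, ssGMI, bsGMI,
#>   fsGMI, bfGMI), segment length 128
#>   classes: smooth, granular
#>   dropouts: 0

# supervise from the green fluorescence channel, not from ground truth
labels <- threshold_label(events,
                          label_rule("green", 1000, "granular", "smooth"))

# waveform SVM vs conventional scalars, 10 balanced samplings each
wf <- repeated_eval(events, labels, benchmark_svm_config(),
                    n_train_per_class = 150, n_test_per_class = 100,
                    positive = "granular")
sc <- repeated_eval(events, labels,
                    benchmark_svm_config(c("fsc_area", "ssc")),
                    n_train_per_class = 150, n_test_per_class = 100,
                    positive = "granular")
wf
#> <eval_result> 10 trials: AUC 0.981 +/- 0.011 (mean ROC AUC 0.984)
sc
#> <eval_result> 10 trials: AUC 0.497 +/- 0.041 (mean ROC AUC 0.502)

# sort on the decision boundary of the last trial's model
simulate_sort(events, wf$model, threshold = 0,
              target_class = "granular", labels = labels)
#> <sort_report> purity 85.2% (pre-sort 47.0%), yield 100.0%, 331 kept

estimate_throughput(parse_time("100us"))
#> [1] 10000
```

The waveform classifier separates what the scalar channels cannot
(AUC ≈ 0.98 vs ≈ 0.5): the two populations are size-matched, so FSC/SSC
carry no class signal, while the texture difference survives in the
compressive waveforms. Sorting at the decision boundary enriches the
target class accordingly, and the ideal throughput of the measurement is
the inverse acquisition time (100 µs/cell → 10,000 cells/s).

The six-class leukocyte-style pipeline is one call each:

```r
wbc <- simulate_events(wbc_like_spec(600, seed = 301))
cv  <- crossfold_eval(wbc, cnn_config(n_classes = 6, seed = 42,
                                      max_epochs = 150), k = 10)
cv
#> <crossfold_result> macro-F1 0.965 +/- 0.032 over 10 folds (best fold 2)
```

## Command line

A thin wrapper over the same functions ships in `exec/`:

```sh
ghostflow simulate   --config inst/extdata/example_run.yml --out ev.rds --seed 7
ghostflow evaluate   --events ev.rds --config inst/extdata/example_run.yml --out report.json
ghostflow sort       --events ev.rds --model model.rds --out sort.json
ghostflow throughput --acquisition-time 100us     # prints "10,000 cells/s"
ghostflow export-fcs --events ev.rds --out ev.fcs
```

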