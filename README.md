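# freqhar — frequency-band-enhanced activity recognition

`freqhar` recognizes human activities (stand, walk, jog, ...) from
body-worn triaxial accelerometer signals by exploiting the fact that each
activity has a characteristic frequency. It is aimed at researchers in
wearable-sensor human activity recognition who want a fully inspectable,
end-to-end implementation of frequency-emphasis ensembling that runs on a
laptop CPU.

## The method

For windows $x \in \mathbb{R}^{3\times w}$ sampled at $f_s$ Hz, the core
operator is FFT-domain filtering

$$x' = F_m(x, f) = \mathrm{ifft}\big(P(\mathrm{fft}(x), f)\big),$$

with $P$ a real per-bin gain on the one-sided spectrum (phase preserved,
conjugate half mirrored). Three phases:

1. **Importance discovery.** Train a 1D-VGG classifier on raw windows; on
   validation subjects, mask each FFT bin in $(0, f_s/2]$ in turn and record
   per-class recall. The bin whose occlusion hurts a class most is that
   class's *important frequency* $f_c$ (0 Hz if no mask hurts — the class is
   DC-dominated). This yields the bank
   $\mathcal{F} = \{f_c \mid c \in C\}$.
2. **Emphasis during training (DA).** For each class, build a band-emphasis
   filter centered on $f_c$ (peak / Gaussian / triangular window with
   maximum 1 and floor 0.5, or a random control) and train one model per
   class on filtered windows.
3. **Emphasis during testing (TTA + EL).** Each per-class model predicts on
   the test window passed through its own filter; the final label is the
   majority vote (deterministic tie-break by mean winning score, then class
   index).

An ablation harness evaluates all eight DA/TTA/EL combinations, and a
filter-comparison harness the four filter families. Because real corpora
can't ship with the package, a synthetic benchmark plants a known dominant
bin per class (plus one DC-only class, subject-level jitter, Gaussian
noise) so discovery and ensembling are testable against ground truth.

## Worked example

```r
library(freqhar)

bm <- generate_benchmark(seed = 1)   # 4 classes planted at bins {0,3,6,10}
bm$split
#> <dataset_split> w = 128, stride = 64 @ 64 Hz | classes: jog, run, stay, walk
#>   train: 288 windows / 8 subjects; valid: 144 / 4; test: 144 / 4

cfg <- model_config(4, 128, scale = "tiny", padding = "same")
tc  <- train_config(batch_size = 64, epochs = 15, seed = 1)

# Phase 1: train a baseline model, sweep masks, select important bins
m <- train_model(build_model(cfg, bm$split$class_set, init_seed = 1),
                 bm$split$train, tc)
curves <- mask_sweep(m, bm$split$valid)
curves
#> <importance_curves> 4 classes, 64 swept bins
#>   jog        baseline 0.944, min 0.000 at bin 6
#>   run        baseline 0.833, min 0.000 at bin 10
#>   stay       baseline 1.000, min 1.000 at bin 1
#>   walk       baseline 0.972, min 0.000 at bin 3
bank <- build_frequency_bank(curves)
as.data.frame(bank)
#>   class bin  hz
#> 1   jog   6 3.0
#> 2   run  10 5.0
#> 3  stay   0 0.0
#> 4  walk   3 1.5
recovery_score(bank, bm$bank)        # fraction of planted bins recovered
#> [1] 1
```

Masking bin 6 drives jog's recall from 0.94 to 0 — 3 Hz is what the model
uses to recognize jogging — while stay's recall never moves, so it resolves
to the DC component (0 Hz). All four planted frequencies are recovered
exactly.

```r
# Phases 2-3: full method (a) vs plain single model (h)
ab <- run_ablation(bm$split, bm$bank, "gaussian", configs = c("a", "h"),
                   seeds = 1, train_cfg = tc, model_cfg = cfg)
as.data.frame(ab)[, c("config", "DA", "TTA", "EL", "accuracy")]
#>   config    DA   TTA    EL  accuracy
#> 1      a  TRUE  TRUE  TRUE 1.0000000
#> 2      h FALSE FALSE FALSE 0.9305556
```

The frequency-emphasis ensemble lifts overall test accuracy from 0.93 to
1.00 on the benchmark.

A thin command-line front end over the same functions is installed at
`inst/cli/freqhar` (subcommands `simulate`, `discover`, `train-ensemble`,
`evaluate`, `ablation`, `compare-filters`; YAML config).

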