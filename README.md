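# instantemg

Gesture recognition from **instantaneous high-density surface EMG
(HD-sEMG) images** — for myoelectric-interface researchers and
biomedical-signal engineers who want a self-contained, testable
implementation of per-frame sEMG image classification.

## The idea

A 2-D electrode array over the forearm records the spatial potential
distribution of the underlying muscles. At one sampling instant the
channel values form a grayscale image

```
I(r, c) = (v(r, c) − v_min) / (v_max − v_min),   [v_min, v_max] = [−2.5, 2.5] mV
```

(an 8×16 image for a 128-channel band). Although each channel is a
zero-mean stochastic process, the *spatial* pattern of instantaneous
values is reproducible within a gesture and discriminative between
gestures, so single frames can be classified directly — no windowed
features — and latency is controlled afterwards by **simple majority
voting** over the per-frame decisions of a trailing window (the voted
label is the modal frame label; at 1000 Hz a 40-frame window costs
40 ms).

The frame classifier is an 8-layer ConvNet: 2 × conv(64, 3×3, same
padding) → 2 × locally connected (64 unshared 1×1 filters per grid
position) → dense 512, 512, 128 → G-way softmax, with ReLU everywhere,
batch norm on the input and before every non-linearity, dropout 0.5 on
layers 4–6; trained with plain SGD (batch 1000, 28 epochs, weight decay
1e-4, lr 0.1 ÷10 after epochs 16 and 24). Five classical baselines
(MLP, KNN, SVM, random forest, LDA) consume the same instantaneous
values as flat vectors. A synthetic HD-sEMG generator (gesture-specific
spatial amplitude fields modulating band-limited zero-mean noise, plus
an optional motor-unit action-potential train mode) makes the whole
pipeline testable offline; signal conditioning (power-line band-stop,
rectification + envelope low-pass, MVC normalisation, 3×3 spatial
median, decimation, circular-shift augmentation), the three published
cross-validation protocols, MAT/HDF5 IO and a CLI round it out.

## Worked example

Generate a 4-gesture synthetic dataset, train the ConvNet on the
odd-numbered trials, and vote over windows:

```r
library(instantemg)

spec <- synthetic_spec(n_gestures = 4, trials_per_gesture = 10,
                       fs = 1000, duration = 0.4, rest = 0.1,
                       snr = 5, seed = 101)
ds   <- synthesize(spec)                      # 40 labelled recordings
fold <- split_trials(1:10, "odd_even")[[1]]   # train {1,3,5,7,9}

tr <- stack_frames(dataset_subset(ds, trials = fold$train), "image",
                   decimate = 9)              # stride-decimated frames
te <- stack_frames(dataset_subset(ds, trials = fold$test), "image")

model <- build_convnet(convnet_spec(c(8, 16), n_classes = 4), seed = 1)
model <- train_convnet(model, tr$x, tr$y, train_spec(seed = 1))

probs <- predict_convnet(model, te$x)      # ~7 min of CPU training above
preds <- lapply(unique(te$segment), function(id) {
  rows <- te$segment == id
  frame_predictions(probs[rows, ], label = te$y[rows][1], segment = id)
})
vote_curve(preds, windows = c(1, 40))
```

```
#>   window accuracy sd
#> 1      1 0.948625 NA
#> 2     40 0.999875 NA
```

Window 1 is the raw single-frame accuracy (94.9% of the 8000 held-out
frames classified from one sampling instant each); voting over a
40-frame trailing window (40 ms of latency at 1000 Hz) lifts it to
99.99%, the characteristic steep accuracy-vs-window curve of
instantaneous-image recognition. The `sd` column is the across-subject
standard deviation (one subject here). The same `frame_predictions`
contract serves the baselines:

```r
fit <- fit_baseline(baseline_spec("rf"), stack_frames(ds, "vector")$x, ...)
```

A complete configured run (dataset → preprocessing → classifier →
voting curve → CSV/JSON results bundle):

```r
res <- run_experiment(preset_config("synthetic-demo", seed = 3),
                      out = "demo_results")
res$summary
```

```
#>   classifier window accuracy sd
#> 1        lda      1 0.277500 NA
#> 2        lda     20 0.375625 NA
#> 3        lda    Inf 0.500000 NA
```

LDA on raw instantaneous vectors sits barely above the 25% chance level
— the class information lives in the spatial *variance* pattern, not in
the mean, so linear discriminants have almost nothing to work with.
That is precisely the finding that motivates the image + ConvNet route:
on the full-size synthetic benchmark in the acceptance suite the
ConvNet reaches 94.9% single-frame and 99.99% 40-frame-voted accuracy
on the identical kind of data (and the random forest, which can carve
variance regions, 97.7%).

The command-line interface wraps the same machinery:

```sh
Rscript inst/cli/instantemg simulate --config cfg.json --out data.h5
Rscript inst/cli/instantemg run --preset synthetic-demo --seed 3 --out demo/
```

Verbs: `simulate`, `import`, `preprocess`, `train`, `predict`,
`evaluate`/`vote-curve`, `run`; global flags `--config`, `--seed`,
`--out`.

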