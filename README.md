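# flatnet — heat-map landmark localization for midsagittal vocal-tract images

Speech-production research, diagnosis of speech disorders and therapy
planning all need the same anatomical landmarks — tongue tip, velum tip,
lip vermillion borders, epiglottis, teeth, and so on — identified on
midsagittal images of the vocal tract, consistently across speakers and
articulations. Annotating them by hand does not scale. `flatnet`
implements an automatic localizer for a fixed 21-landmark catalogue on
2-D grayscale images, for phoneticians and biomedical-image researchers
who need reproducible landmark coordinates plus the machinery to train
and honestly evaluate such a model.

## The method

Each landmark `l` is represented as a *heat-map channel*: a target image

    H_l(x, y) = exp(-((x - x_l)^2 + (y - y_l)^2) / (2 sigma^2)),  sigma = 10 px, peak 1

and recovered from a predicted channel by the per-channel argmax

    (x_p, y_p)_l = argmax_{x,y} H_l(x, y).

The channels are generated by a pooling-free fully-convolutional
network: two consecutive 9×9 convolution layers run in five parallel
branches at different dilation rates (default 1, 2, 4, 8, 16), their
feature maps are concatenated and passed through a 5×5 and three 1×1
convolutions (ReLU throughout, tanh output), trained with the mean
absolute error against the target channels. No pooling, striding,
up/down-sampling or fully connected layers anywhere — spatial
resolution is preserved end to end. The 21 landmarks are split across 5
such networks (at most 5 channels each). Around the model sit:

* a keypoint-consistent augmentation pipeline (10 fixed transforms:
  noise, blur, rotations, translations, zooms and compositions) giving
  an ×11 corpus expansion with landmarks mapped analytically;
* a seeded synthetic phantom generator producing subjects × classes
  grids of schematic vocal-tract images with exact ground truth;
* an evaluation harness: per-landmark Euclidean distances, RMSE (px and
  cm), strict >5 px outlier rates, paired t-tests, randomized 10-fold
  CV and leave-one-subject-out (LoSo) protocols.

The convolution forward/backward passes are compiled (Rcpp +
RcppArmadillo, im2col + BLAS) so CPU-only training of scaled-down
configurations is practical.

## Worked example

Generate a small phantom corpus, expand it, train a reduced localizer
on one leave-one-subject-out fold and score the held-out subject:

```r
library(flatnet)

corpus <- generate_corpus(phantom_config(3, 4, image_size = c(64, 64),
                                         rng_seed = 7))
aug    <- augment_corpus(corpus, seed = 7)        # 12 originals -> 132 items
plan   <- make_loso_splits(aug)                   # 3 subject folds
fold   <- plan$folds[[1]]

fit <- flatnet_fit(aug[fold$train],
                   config  = flatnet_config(filters = c(f1 = 4, f2 = 8, f4 = 16,
                                                        f5 = 16, f6 = 8)),
                   control = train_control(max_epochs = 4, seed = 7))
print(fit)
#> <flatnet_localizer> 5 sub-networks (5+5+5+5+1 landmarks), input 64x64
#>   parameters: 171,709 total (34,349 per 5-output net)
#>   trained on 88 items; epochs per net: 4, 4, 4, 4, 4

pred <- predict(fit, aug[[fold$test[1]]])         # 21 rows: abbrev, x, y
d    <- euclidean_distance(aug[[fold$test[1]]]$landmarks, pred)
round(median(d), 2)
#> [1] 4.09
```

`median(d)` is the median distance in pixels between predicted and true
landmarks on an image of the *unseen* subject — here about 4 px at 64 px
resolution, against ~22 px for an untrained network. `rmse()`,
`outlier_rate()` and `build_report()` aggregate such records into the
full per-landmark / per-subject report; `run_experiment()` drives the
whole pipeline (synthesize → augment → split → train → predict →
report) from one configuration, and `compare_methods()` sets several
reports side by side with paired t-tests.

A thin command-line workbench over the same functions is installed at
`inst/cli/flatnet-cli.R` (subcommands `synth`, `augment`, `train`,
`predict`, `run-cv`, `run-loso`, `compare`).

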