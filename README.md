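# circleEMD

Circular empirical mode decomposition and task-state pattern
classification for spatial fMRI channel vectors.

## The problem

Multi-voxel pattern analysis decodes a subject's task state (here: the
rock / scissors / paper gestures of a motor experiment) from the spatial
pattern of BOLD amplitudes across a set of selected voxels at one time
point.  Empirical mode decomposition (EMD) separates such a pattern into
intrinsic mode functions (IMFs) carrying distinct spatial scales — but
conventional EMD distorts every IMF near the two ends of the sequence,
because its cubic-spline envelopes are unconstrained there (the *end
effect*).

A spatial channel sequence has no meaningful start or end, so this package
closes it into a ring.  Envelopes become **periodic cubic splines**: with
knots at the extrema $t_0 < \dots < t_{m-1}$ on a circle of circumference
$N$, gaps $h_j$ taken circularly, the second-derivative moments $M_j$
solve the cyclic tridiagonal system

$$\mu_j M_{j-1} + 2M_j + \lambda_j M_{j+1} = 6 f[t_{j-1}, t_j, t_{j+1}],
\qquad \mu_j = \tfrac{h_{j-1}}{h_{j-1}+h_j},\ \lambda_j = \tfrac{h_j}{h_{j-1}+h_j},$$

so the envelope is C² across the wrap-around seam and the end effect
vanishes.  Sifting then proceeds classically: subtract the envelope mean
$m(t) = [e_{\rm upp}(t)+e_{\rm low}(t)]/2$ until the IMF conditions hold
(extrema and zero-crossing counts within one of each other; envelope mean
numerically zero), extract, and repeat on the residual, giving
$x(t) = \sum_i C_i(t) + r(t)$ exactly.

Around the decomposition the package provides the full decoding workflow:
the standard preprocessing chain (hemodynamic shift, ROI and t-value
channel selection, outlier clipping, detrending, percent-change baseline
normalisation, spatial z-scoring) down to the canonical 240 × 200 sample
matrix; IMF-based feature construction; an RBF-kernel SVM, multinomial
logistic regression, and a 300/200/100 feed-forward network with dropout
and batch normalisation, all under run-wise 10-fold cross-validation with
weighted precision / recall / F1 reporting; and a synthetic-data generator
emulating the 10-run, 32-state experimental design end to end.

## Worked example

```r
library(circleEMD)

## a two-scale ring signal: 8-cycle + 2-cycle tones on 256 channels
i <- 0:255
x <- cos(2 * pi * 8 * i / 256) + cos(2 * pi * 2 * i / 256)
fit <- circle_emd(x)
fit
#> circle-EMD decomposition: 256 samples, 2 IMFs + residual
#> sift iterations per IMF: 1, 0
#> max reconstruction error: 0

cor(fit$imfs[1, ], cos(2 * pi * 8 * i / 256))   # fast tone -> IMF 1
#> [1] 0.9998873
spectral_separation(fit)$dominant_frequencies    # fast to slow, rad/channel
#> [1] 0.19634954 0.04908739

## end-to-end on an emulated study
sim <- make_emulated_study(seed = 7)
ds  <- preprocess_study(sim$study)
ds
#> study dataset: 240 samples x 200 channels; classes: rock (80), scissors (80), paper (80)

feats <- build_features(ds, "all_imfs")          # sum of IMFs, residual dropped
rep <- run_cross_validation(feats, ds$labels, ds$run_id,
                            classifier_spec("svm_rbf", seed = 1))
rep
#> 10-fold (run-wise) cross-validation, classifier svm_rbf
#> mean accuracy 1.0000  (weighted P 1.000 / R 1.000 / F1 1.000)
```

The decomposition correlates IMF 1 with the fast tone and IMF 2 with the
slow tone at > 0.999 each; on the default emulated study the planted class
patterns are strongly separable, so cross-validated accuracy saturates
(lower `class_amplitude` or raise `noise_sd` to move off the ceiling —
`make_emulated_study(class_amplitude = 0)` sits at chance, 1/3).

A thin command-line front end over the same functions is installed at
`inst/cli/circleEMD.R` with subcommands `simulate`, `decompose` and
`pipeline`.

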