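# msmra

Multi-source, multi-representation domain adaptation for cross-subject and
cross-session EEG emotion recognition.

## What problem this solves

EEG band-power statistics shift between subjects and between sessions, so an
emotion classifier trained on recorded subjects degrades on a new, unlabeled
one. `msmra` implements a complete pipeline for this setting, for
researchers working with multi-subject EEG feature corpora (62 channels x 5
bands differential-entropy features) or with synthetic stand-ins:

- **Differential-entropy features**: per trial, zero-phase Butterworth
  band-pass into Delta/Theta/Alpha/Beta/Gamma, then per 1 s window and
  channel the Gaussian differential entropy `0.5 * ln(2*pi*e*sigma^2)`,
  flattened to `windows x 310` (channel-major, band-minor), with optional
  per-recording z-scoring.
- **Two-partition multi-source grouping**: source recordings are paired,
  two per source domain — subjects within a session (cross-subject,
  N = 7 for 14 remaining subjects) or the two earlier sessions of a subject
  (cross-session, N = 1) — plus one unlabeled target recording.
- **Model**: a shared extractor (310 → 256 → 128 → 64, leaky-rectifier
  layers) feeds, per source domain, three parallel branch stacks producing
  48-, 32- and 16-wide representations, concatenated (96) into a per-domain
  softmax head.
- **Alignment**: every branch's source representations are pulled toward
  the target's with a multi-kernel Gaussian squared-MMD penalty
  (`||mean phi(X) - mean phi(Y)||^2_H`), summed over branches and domains.
- **Objective**: `sum_i (L_cls^i + alpha * MMD^i)` minimized by Adam
  (lr 0.01, batch 256, 50 epochs) with the dynamic weight
  `alpha(i) = 2 / (1 + exp(-10 i / epochs)) - 1`.
- **Inference**: uniform average of the N domain heads' softmax outputs.

A synthetic generator emulates a subject x session grid of recordings under
controlled covariate shift, so the whole pipeline is testable without the
license-gated EEG corpora. See the methods vignette
(`vignettes/msmra-methods.Rmd`) for the model, the design decisions and the
generator's shift family.

## Worked example

```r
library(msmra)

## a synthetic 5-subject x 2-session grid with the reference shift
grid <- generateFeatureGrid(synthConfig(seed = 1))
splits <- leaveOneOutSplits(grid, "cross_subject")
length(splits)   # 10 partitions, 2 source domains each

## train on one partition and score the held-out subject
fit <- trainMSMRA(splits[[1]], trainConfig(seed = 11))
tail(fit$history, 2)
#>    epoch     alpha     clsLoss        mmd  totalLoss
#> 49    48 0.9998646 0.008253302 0.10043044 0.10867014
#> 50    49 0.9998891 0.004097337 0.06713367 0.07122356
evaluateModel(fit$model, splits[[1]]@target)$accuracy
#> [1] 0.845
```

The history columns are the per-epoch means of the summed per-domain
cross-entropy, the total MMD across domains and branches, and the joint
objective; `alpha` is the adaptation weight at that epoch. The accuracy is
window-level on the held-out subject's recording. Disabling adaptation
(`trainConfig(adapt = FALSE)`) trains the same architecture with
`alpha = 0`, which is the no-adaptation baseline the acceptance suite
compares against.

The same pipeline is scriptable from the shell:

```sh
exec/msmra synth --out data/ --seed 7
exec/msmra run-scenario --data data/ --scenario cross_subject --seed 7 --out results/
```

Every run writes a JSON manifest (full configuration, seeds, partitions,
per-split results) sufficient to reproduce its accuracies exactly.

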