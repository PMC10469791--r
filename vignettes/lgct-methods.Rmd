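---
title: "Methods: a local-global convolutional transformer for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a local-global convolutional transformer for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lgct)
```

## The problem

Motor imagery (MI) -- the mental rehearsal of a movement -- modulates
sensorimotor rhythms: imagining a hand movement desynchronizes the mu
(~8-12 Hz) and beta (~13-30 Hz) oscillations over the motor cortex
*contralateral* to the imagined hand (event-related desynchronization, ERD).
A brain-computer interface decodes these band-power asymmetries from
epoched multichannel EEG. `lgct` implements a deep architecture for this
task that combines convolutional feature extraction with self-attention at
two scales: a *local* (windowed) transformer over raw samples, which shares
its receptive field with a 1-D CNN, and a *global* transformer over pooled
feature sequences.

## Preprocessing

Raw trials (`trials x channels x samples`) pass through:

1. **Channel selection** to a motor-cortex montage. The montage is
   partitioned by the 10-20 naming rule: `z`-suffixed labels are midline,
   odd numbers left, even numbers right, and left/right vectors are aligned
   as homologous mirror pairs (C3 with C4, FC1 with FC2, ...). For the
   20-channel motor set this yields 9 left + 9 right + 2 midline channels.
2. **Downsampling** by an integer factor, preceded by a zero-phase order-8
   Butterworth low-pass at 0.8 x the target Nyquist frequency.
3. **Three-band construction**: the network receives the raw signal plus
   two zero-phase order-4 Butterworth band-passes at 7-12 Hz (mu/alpha) and
   13-32 Hz (beta), in that fixed order.
4. **Z-scoring** per trial and channel, `z = (x - mu) / sigma` with the
   population (divide-by-N) standard deviation.

Open choices we pinned, and why:

* *Filter family and order are not dictated by the method.* We use
  zero-phase (forward-backward) Butterworth filters -- the standard choice
  in MI-EEG pipelines -- because zero phase preserves event timing inside
  the epoch. Filter edge effects inside the 4-s epoch are accepted; no
  padding beyond the trial is applied, which is a documented limitation.
* *Z-score scope.* Statistics are computed per trial and channel rather
  than over the whole training set; this matches the single-channel
  formulation of the normalization and keeps trials independent for
  cross-validation. A per-recording variant would couple trials and is a
  known sensitivity worth exploring.

## Architecture

Each of the three bands feeds an identical-structure branch with
independent weights; the branch outputs are concatenated and classified by
a single fully connected softmax layer.

**Temporal block.** Two parallel paths per electrode channel, sharing one
receptive field:

* a 1-D convolution (kernel `kernel_len` samples, `n_filters` filters,
  same padding), and
* a local-transformer path: each time sample is a token, lifted from a
  scalar to `token_embed_dim` by a shared linear map; sinusoidal positional
  encoding is added (`PE(pos, 2i) = sin(pos / 10000^(2i/d))`,
  `PE(pos, 2i+1) = cos(...)`); one post-norm encoder layer applies
  multi-head attention restricted to a banded window equal to
  `kernel_len`, a residual connection, layer normalization, a
  position-wise feed-forward of width `2 d_model`, and a second
  residual + layer norm; a linear map projects tokens back to `n_filters`.

The two paths are summed (a `temporal_fusion = "concat"` switch exists),
then batch-normalized, passed through ELU and mean-pooled over time
(`pool_len` / `pool_stride`). Raw samples are scalars, so some embedding is
required before attention can split heads; the shared linear lift is the
smallest such choice. Addition (rather than concatenation) of the CNN and
attention paths is the default because the fusion is described as adding
the two outputs into one temporal feature set.

**Spatial block.** Three depthwise paths across electrodes: one spatial
filter over all `C` channels, and one each over the left- and
right-hemisphere channel sets (midline channels excluded). The hemisphere
difference (left-path minus right-path features) is concatenated with the
all-channel features -- the network's built-in lateralization contrast.
The mirror-pair partition is used as is; the method deletes only midline
channels from the hemispheric paths.

**T-Dense block.** One T-Dense unit followed by a 1 x 1 dimension-reducing
convolution. The unit runs two branches in parallel, each with
`n_layers_per_branch = 3` densely connected layers (layer k receives the
unit input concatenated with all previous layer outputs, so its input width
is `K0 + (k-1) * growth`):

* a CNN branch (1-D convolutions, `growth` filters per layer), and
* a global-transformer branch (one encoder layer per dense layer over the
  pooled time axis, all positions attending to all positions, followed by a
  linear projection to `growth` channels).

Each layer applies batch normalization, ELU and dropout. The unit output is
the concatenation of all 2 x 3 layer outputs (width `6 * growth`), reduced
to `reduce_filters` channels. Widths of the transformer-branch layers must
be even (for the positional encoding) and divisible by the head count.

**Ablation variants.** `w/o_trans` removes the local and global attention
paths entirely (the forward pass performs zero attention evaluations);
`w/o_diff-hemi` keeps only the all-channel spatial path; `w/o_T-dense`
replaces the dense unit with a plain CNN stack of equal depth.

### Hyperparameters

The text of the method fixes the three bands, `h = 2` attention heads, the
loss, optimizer and schedule, but leaves kernel sizes, filter counts and
embedding widths to the (unreadable) architecture figures. We froze a
**reference configuration** from canonical MI-CNN practice: temporal kernel
25 samples (0.1 s at 250 Hz), 8 temporal filters, mean-pooling 75/15,
token width 16, 8 spatial filters per path, T-Dense growth 8 with
reduction to 16, ELU activation, dropout 0.5, Glorot-uniform
initialization with zero biases. Every value is a `model_config()` knob. A
**reduced configuration** (`reduced_config()`) scales all widths down
(4 temporal filters, kernel/window 13 at 125 Hz, token width 4, growth 4,
dropout 0.25) for CPU-scale work. With hyperparameters absent from the
source text, parameter counts of the reference configuration are our own;
they are not claimed to match any externally reported total.

## Training

Cross-entropy loss (predicted probabilities clamped at 1e-12), Adam with
learning rate 1e-4 (beta1 0.9, beta2 0.999, eps 1e-8), up to 800 epochs
with minibatches of 32, and early stopping: any strict decrease of the
validation loss resets a patience counter; training stops after 100 epochs
without improvement and the best-validation-loss weights are restored. "32
batches per epoch" in the protocol's phrasing is read as batch size 32; a
fixed 32-batches-per-epoch schedule is incompatible with the 180-trial
training folds involved. Validation loss (not accuracy) gates
checkpointing, as only the loss is mentioned. No learning-rate schedule,
weight decay or augmentation is used.

The engine is written in R with Rcpp/RcppArmadillo kernels for the banded
attention, 1-D convolutions and the large elementwise/normalization ops;
backward passes are derived analytically and verified against finite
differences in the test suite (no deep-learning framework is involved).
Dropout and shuffling draw from R's RNG, so one root seed fixes the entire
run. Local attention is implemented as a sliding window; the test suite
asserts its equivalence (within 1e-6) with a banded mask over the full
score matrix.

## Evaluation scenarios

* **Within-session**: stratified 10-fold CV on one session. The protocol
  does not name a validation set for these folds; since early stopping
  requires one, each fold uses one rotating non-test fold for validation
  and the remaining eight for training. This is the minimal departure that
  avoids validating on the test fold (a known leakage pattern).
* **Cross-session case 1**: train on all of session 1; session 2 is split
  in recorded order into a validation phase and a test phase (preserving
  within-session drift rather than shuffling it away).
* **Cross-session case 2**: train and validate (stratified 20% of session
  1) on session 1 only; all of session 2 is the test set.
* **Two-session**: stratified 10-fold CV over both sessions pooled.

Session-2 trials never enter a cross-session training set; the splits are
audited programmatically (`check_no_leakage()`). Fold accuracies aggregate
as mean and sample (n-1) SD; per-subject comparisons use a two-sided
paired t-test with the Pearson correlation reported alongside.

## Synthetic lateralized EEG

`generate_dataset()` emulates the MI data regime without any download:
250 Hz, 4-s trials, balanced classes, 200 trials per session, one or two
sessions. Each trial is per-channel pink noise (spectrally shaped white
noise, PSD proportional to `1/f`) plus ongoing ~10 Hz and ~20 Hz
oscillations with jittered frequency and phase. For hand classes the
oscillation amplitude over the contralateral hemisphere is multiplied by
`sqrt(1 - erd_depth)`, i.e. band power by `1 - erd_depth`. Four-class mode
maps feet to midline beta attenuation and tongue to global mu attenuation
-- a toy convention for exercising the 4-class path, not physiology.
Session 2 receives per-channel log-normal gain drift and a mu-frequency
shift, emulating between-day distribution change. Subject-level gains add
across-subject variability.

Default amplitudes (background 5 uV RMS, mu 12 uV, beta 6 uV) give a
mu-band SNR at which the hemispheric power ratio closely tracks
`1 - erd_depth`; the tests verify the measured Welch-PSD ratio against the
analytic expectation including the pink-noise floor. What the generator
does *not* emulate: volume conduction, ocular/muscular artifacts,
non-stationarity within a session, or realistic covariance structure
between electrodes. Passing the learnability checks therefore demonstrates
that the implementation can extract lateralized band-power structure
end to end -- not that it would attain any particular accuracy on real
recordings.

## Desk-scale evaluation sizes

`desk_benchmark()` fixes the package's standard CPU-scale recipe: the
4-channel hand-area montage (C3/C4/CP3/CP4, where ERD is strongest),
downsampling 250 to 125 Hz, the reduced model configuration, Adam at 1e-3
with batch 40, at most 20 epochs with patience 6, and three of the ten
within-session folds. These sizes were chosen once as a realistic
single-CPU workload; on easy (high-ERD) synthetic data the reduced model
reaches its accuracy plateau well inside this schedule. The acceptance
checks run this recipe at ERD depths 0, 0.4 and 0.8; the three trained
folds double as the repeats whose mean enters the monotonicity comparison.

## Numerical and degenerate-input choices

* Softmax rows are stabilized by max subtraction; masked positions are
  excluded before normalization and receive exactly zero weight. A fully
  masked query row is an error (the mask contract guarantees the diagonal).
* An even local window is refused rather than silently re-centred.
* Zero-variance channels make the Z-score undefined and raise an error
  naming the trial and channel.
* Prediction ties break toward the lowest class index, deterministically.
* Batch-norm running statistics (momentum 0.1) are buffers, not
  parameters; `count_parameters()` excludes them but includes scale/shift.
* Checkpoints store parameters as little-endian float64 so that
  `load_model(save_model(m))` reproduces forward outputs bit for bit;
  the trials-bundle interchange format stores float32 and is bit-exact
  from the first write onward.
* Degenerate paired t-tests (zero-variance, nonzero-mean differences)
  raise an error; identical vectors return t = 0, p = 1.

## Known limitations

* Real-data scale: the full two-dataset, 63-subject evaluation of the
  original study requires external downloads and GPU-scale training and is
  out of scope here; the package's empirical claims are limited to what
  its synthetic benchmark and test suite compute.
* The hemispheric partition assumes 10-20 labels with mirror-pair
  electrodes present; asymmetric montages are rejected.
* EDF support covers 16-bit EDF/EDF+ with a shared sampling rate across
  selected channels; GDF and BrainVision formats are not read.
* Filtering operates within the epoch; very short epochs (under roughly
  three filter time constants) will show edge effects.
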