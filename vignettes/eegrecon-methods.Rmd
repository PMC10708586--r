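---
title: "Methods: EEG digit decoding and adversarial stimulus reconstruction"
author: "eegrecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG digit decoding and adversarial stimulus reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what the synthetic experiments do and do
not demonstrate.

## The decoding model

An input epoch is a 14 × 250 matrix: 14 Emotiv-EPOC channels (AF3, F7, F3,
FC5, T7, P7, O1, then the right-hemisphere mirrors), 250 voltage samples at a
nominal 128 Hz, i.e. just under the full 2-s presentation window. Epochs are
standardized per channel, `(x − mean)/sd`, with an ε = 10⁻⁸ guard that maps
constant channels to zeros.

The classifier is a *depthwise* one-dimensional CNN: each convolution slides
a length-5 kernel along the time axis only, shares that kernel across the 14
channel rows, and mixes an incoming "filter" axis exactly as an ordinary
convolution mixes channels. Stage activations are therefore
(filters, 14, 250) — 14, 10 and 10 filters in the three stages of the full
profile. Each stage is convolution → leaky ReLU (α = 0.1) → batch
normalization → dropout (rate 0.2). The flattened third-stage activation
(10 · 14 · 250 = 35 000) feeds dense layers of 3500 and 2500 units; the
2500-unit activation is the *feature vector* handed to the generator, and a
final dense layer with log-softmax yields 10 class log-probabilities.
Training is plain SGD, learning rate 0.001, weight decay 5·10⁻⁵, on the
cross-entropy loss.

Batch normalization follows the textbook form
`(y − μ_B)/√(σ²_B + ε)` with per-feature batch statistics and **no learned
affine** — none appears in the defining equations we implement — though an
affine can be applied through the standalone `batch_normalize()`. Inference
uses exponential running averages (momentum 0.9, ε = 10⁻⁵); both constants
are unstated upstream and fixed here once. Dropout is the inverted variant:
a unit survives with probability 1 − p and is rescaled by 1/(1 − p), so
evaluation mode is the identity.

## The saliency GAN

The generator maps the feature vector to a single-channel image: dense
2500 → 100 → 20 000 (both bias-free), reshape to (50, 50, 8), four 4 × 4
transposed convolutions with six kernels and strides (2, 2), (3, 3), (1, 1),
(1, 1), and a final 2 × 2 stride-1 *valid* convolution. With "same"-style
transposed convolutions (output = input × stride) the spatial chain is
50 → 100 → 300 → 300 → 300, and the valid 2 × 2 step lands on **299**, which
is why 299 is the package's canonical image side: it is the only size that
makes the generator output and the discriminator chain (299 → 150 → 75 → 38,
flatten 38·38·2 = 2888) simultaneously consistent. The printed stride of 2
for the final convolution is arithmetically impossible from a 300-wide grid
and is implemented as stride 1.

Bias conventions were chosen to match the published weight counts where those
are internally consistent: generator dense layers and transposed convolutions
are bias-free (250 000, 2 000 000 and the first stage's 4·4·8·6 = 768 match
exactly), discriminator convolutions are bias-free (4·4·1·2 = 32 matches) and
the discriminator head carries a bias (2888 + 1 = 2889 matches). Counts that
no kernel arithmetic reproduces (768 repeated for the 6 → 6 stages, where
4·4·6·6 = 576; 33 for the final convolution, where 2·2·6·1 + 1 = 25; 130 for
the 2 → 2 discriminator stages, where 4·4·2·2 = 64) are implemented from the
kernel arithmetic; `count_parameters()` always reports true trainable
scalars.

Training alternates one discriminator and one generator Adam step
(lr 10⁻⁴, β = 0.9/0.999) per iteration, real label 1, fake label 0,
probabilities clamped at 10⁻⁷, with the non-saturating generator loss
`−mean log D(G(y))`. The one-to-one step ratio and the Adam betas are
unstated upstream; they are the conventional defaults.

## Transfer and reconstruction

After the saliency GAN trains, all weight tensors are copied into a fresh,
identically-specified pair (`transfer_weights()`, exact to the last bit — a
test asserts forward-pass equality) and fine-tuned with the *original*
white-on-black digit images as targets. Two open choices were fixed as
follows: the fine-tune learning rate is 0.1 × the base rate, and **both**
networks remain trainable (the upstream description says only that tuning
happens through cross-validation). Stimulus targets use the same canonical
side as the saliency targets, so no architectural change is needed at
transfer time. The fine-tune history tracks generator loss, discriminator
loss, and mean SSIM and CC against the targets.

## The augmentation GAN

One GAN per class synthesizes 14 × 250 EEG: latent 100-dimensional standard
normal (the input is unspecified upstream; noise is the conventional choice),
dense to (7, 125, 8), two stride-1 transposed convolutions with 1 × 4 kernels
and 8 kernels each, and a final stride-(2, 2) transposed convolution to
(14, 250). Two deliberate deviations from the printed architecture: the final
stage emits 1 channel rather than 30 (a 30-channel stack is not an EEG
signal), and its kernel is 2 × 4 rather than 1 × 4 — a height-1 kernel with
row stride 2 would leave every second channel row structurally zero.
Activations are leaky ReLU with slope 0.3; the discriminator is three 1 × 4
convolutions (6 kernels, strides 1, 2, 1, dropout 0.2) with flatten length
7·125·6 = 5250. Signals are scaled to unit absolute range for training and
rescaled by the training set's median amplitude on generation.
`augment_dataset()` appends n generated records per class with a `gan-`
provenance prefix on the record id (on the full corpus, 50 sets × 10 classes
would grow 9120 records to 9620).

## Metrics

* **SIM**: both maps normalized to unit sum, then the sum of pixelwise
  minima.
* **SSIM**: evaluated on every 11 × 11 sliding window with uniform weights
  (window size and weighting are unstated upstream; 11 with uniform weights
  is the simplest faithful reading of "L × L windows"), constants
  k₁ = (0.01 K)², k₂ = (0.03 K)², K inferred as 255 for 8-bit-range data and
  1.0 for unit-range data, overridable. Implemented with integral images;
  windowed statistics use the population convention.
* **CC**: Pearson correlation over all pixels.
* **Classification**: per-class one-vs-rest TP/TN/FP/FN; two F1 conventions
  are always reported — the arithmetic mean (precision + recall)/2, which
  this package adopts as its headline `f1` for parity with the convention it
  follows, and the standard harmonic mean as `f1_harmonic`. Cohen's kappa is
  computed per class from the binary formula and macro-averaged for more
  than two classes (the multiclass reduction is unstated upstream).
  Zero-denominator metrics surface as `NA`, never as 0, so averages are not
  silently inflated.

When `evaluate_saliency_per_class()` feeds SSIM, maps are first rescaled to
[0, 1] by their own maxima: unit-sum saliency maps otherwise have pixel
values of order 10⁻⁵, where the stabilization constants dominate and SSIM
saturates at 1 regardless of content.

## The synthetic data generator

Class k puts `A[k,c]·sin(2π f_k t + φ_c)` plus Gaussian noise on channel c —
class identity is a dominant oscillation frequency (defaults spread 2–29 Hz
across classes, inside the physiological delta-to-beta range and far below
the 64 Hz Nyquist limit), amplitudes default to 10 µV and noise sd to 2 µV,
and the per-channel phases are fixed by the seed. The defaults mirror the
real corpus's shape: 912 records per class, 10 classes, 9120 total, 14 × 250
at 128 Hz. Stimulus images are built-in 5 × 7 digit glyphs centered on a 9 × 9
canvas and nearest-neighbour upscaled (no external image download); saliency
ground truth is a Gaussian blur of the glyph mask normalized to unit sum — a
synthetic proxy standing in for fixation-derived maps, not an emulation of
them.

What this generator does *not* model: event-related potentials, 1/f spectral
background, artifacts, inter-subject variability, or any genuine
EEG-to-image statistical dependency. Passing tests on this data demonstrate
that the architectures are built exactly as specified, that the training
loops optimize their objectives, and that separable signals are separated —
they say nothing about decoding accuracy on real recordings. For the same
reason the headline accuracies reported for the real corpus (95.4 %
classification, SSIM 92.9 %, CC 97.28 %) are out of scope here: they require
the external dataset and long adversarial training.

## Profiles, problem sizes, numerical choices

The `"paper"` profile is the full architecture (its classifier carries a
~122-million-weight dense layer, so it is built and shape-checked in the
tests but not trained there). The `"desk"` profile keeps every stage and
only shrinks sizes: classifier filters (4, 4, 4) and dense (128, 64) — hence
a 64-element feature vector — and a generator reshape of (9, 9, 8). The desk
canonical side is **53**, because the generator's stage structure maps
9 → 18 → 54 → 54 → 54 → 53; the discriminator chain is then 53 → 27 → 14 → 7
(flatten 98). Desk experiments in the tests and acceptance script use 3
classes with 10–60 records per class, 40–150 classifier iterations and
25–300 GAN iterations — sizes chosen so the synthetic signal is learned to
convergence while the whole suite stays in the minutes range on one CPU.

Other fixed numerical choices: initialization is uniform on
±√(1/fan-in) with a per-network seed (default 42); trimming keeps the
*first* 250 samples of longer epochs (which 250 of the ~256 is unstated
upstream); records missing any of the 14 channels are dropped with a warning
rather than zero-filled; the Gaussian blur kernel truncates at 3σ with zero
padding; GAN probability clamping at 10⁻⁷ keeps the binary cross-entropy
finite; training aborts with an informative error on a non-finite loss.

## Known limitations

* Desk-scale adversarial runs improve SSIM/CC monotonically but do not reach
  visually compelling reconstructions; that requires full-scale training.
* The multiclass kappa reduction (macro-averaged one-vs-rest) is one of
  several defensible conventions.
* The engine is pure R over BLAS matrix multiplications; it is deterministic
  given a seed and thread count, but roughly an order of magnitude slower
  than a compiled deep-learning framework, which bounds the practical
  problem sizes.
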