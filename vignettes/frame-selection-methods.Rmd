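---
title: "Scoring and selecting informative otoscopy frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and selecting informative otoscopy frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otomif)
```

## The problem

A hand-held otoscope video of an ear examination contains hundreds of
frames, most of them diagnostically useless: the eardrum is out of frame or
only partly visible, it covers a tiny fraction of the image, or the frame is
blurred and focused on the canal wall instead of the membrane. Clinical
deep-learning work on otoscopy usually relies on an expert to hand-pick the
one good frame per video. `otomif` automates that step: every frame gets
three scores -- eardrum *view*, eardrum *coverage*, and image *clarity* --
which are fused by a weighted sum of their ranks into a single informative
score. The frames with the smallest fused score are the most informative
ones.

## The three per-frame scores

**Eardrum view score.** A 3-class classifier assigns each frame
probabilities of showing *no*, a *partial* or a *full* eardrum. Each class
carries an eardrum-area score (0, 0.5, 1) and the view score is the
expectation
$$S_{edv} = P_{full}\cdot 1 + P_{partial}\cdot 0.5 + P_{none}\cdot 0,$$
a number in $[0,1]$ that is large when the membrane is completely in view.
The classifier output is passed through a softmax so that $S_{edv}$ is a
true expectation; the score formula, not any particular backbone, is the
contract.

**Eardrum coverage score.** Pixel-accurate eardrum masks are expensive to
annotate, so the segmentation behind the coverage score is learned from
image-level labels only (eardrum present/absent). A class activation map
(Grad-CAM) of the binary classifier localises the evidence; two refinements
sharpen it:

1. *Adversarial climbing.* The input is perturbed for $T$ iterations along
   the gradient of
   $L = y_c - \sum_{k\neq c} y_k - L_{restrict}$, where $y_c$ is the target
   logit and
   $L_{restrict} = \lambda\,\lVert M \odot (\mathrm{CAM}(x_t) -
   \mathrm{CAM}(x_0))\rVert_1$
   with $M$ the mask of pixels above a fraction $\tau$ of the map maximum.
   The ascent amplifies class evidence in regions the classifier did not
   originally rely on, while the restriction keeps already-activated regions
   stable, so the activation map grows from the most discriminative part of
   the membrane toward its full extent. The maps along the trajectory are
   summed and the aggregate is min-max normalised.
2. *Background subtraction.* With a binary head the same climb can be run
   for the background class; subtracting the weighted background map,
   $\mathrm{map} = \mathrm{AdvCAM}_{fg}(x) - \lambda_{bc}\,
   \mathrm{AdvCAM}_{bg}(x)$ (negatives clamped, then normalised), suppresses
   background structure -- canal wall, wax-like highlights -- that leaks into
   the foreground map.

The mask is the set of pixels above $\tau$ times the map maximum, and the
coverage score is simply the mask fraction of the *whole* frame,
$S_{edc} = \#\{\text{mask}\} / \#\{\text{pixels}\}$.

**Clarity score.** Sharp otoscope frames show a long-tailed distribution of
signed edge responses; blurred ones concentrate near zero. Inside the
detected field of view (FOV) the package pools signed 3x3 Sobel responses,
fits a two-component Gaussian mixture by EM, and takes the standard
deviation $\sigma_{max}$ of the wider component. The blur score is
$S_{bl} = \sigma_{max}/(C_p + \epsilon)$ with $C_p$ the RMS contrast inside
the FOV. Separately, the squared Laplacian-of-Gaussian response locates the
sharpest point of the frame, and the focus score is its margin from the FOV
rim, $S_F = r_{FOV} - \lVert (x_f,y_f) - (x_{FOV},y_{FOV})\rVert$, clamped
at zero. The final blur score is the product $S_{blf} = S_{bl}\times S_F$:
a frame must be both globally sharp and focused near the centre of the FOV.

The FOV itself is found with a Hough-style circle transform: Sobel edge
pixels vote for circle centres along their gradient direction at each
candidate radius, and among the candidates the circle with the largest
lightness change $\Delta L$ between its interior and a $\Delta r$-wide
exterior annulus wins.

## Rank fusion

Raw score scales are incommensurable (a probability, a pixel fraction, a
product of a ratio and a length), so the fusion operates on ranks: rank 1
goes to the best (largest) raw value on each axis, and
$$S_I = 0.4\,\mathrm{Rank}(S_{edv}) + 0.2\,\mathrm{Rank}(S_{edc})
      + 0.4\,\mathrm{Rank}(S_{blf}).$$
A *smaller* $S_I$ means a *more* informative frame; `selectTopK()` returns
the $k$ smallest, breaking ties by the larger view score and then the
smaller frame index so selection is deterministic.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| climbing iterations $T$ | 30 | ascent steps; 0 reduces to Grad-CAM |
| step size $\epsilon$ | 0.008 | per-iteration step in $[0,1]$ intensity units |
| restriction weight $\lambda$ | 7 | stability of already-activated regions |
| mask threshold $\tau$ | 0.5 | fraction of map maximum, both for $M$ and final masks |
| background weight $\lambda_{bc}$ | 1 | strength of background subtraction |
| $\epsilon$ (blur score) | $10^{-6}$ | division guard in $S_{bl}$ |
| annulus width $\Delta r$ | 5 px | exterior ring of the FOV selector |
| radius range | $[0.25, 0.60]\cdot\min(H,W)$ | FOV search range |
| LoG scale $\sigma$ | 2 px | smoothing before the Laplacian |
| fusion weights | 0.4 / 0.2 / 0.4 | view / coverage / blur |

Because the ascent step is specified in intensity units of the original
$[0,1]$ image scale, the implementation scales the loss gradient to unit
max-abs and divides by the per-channel normalisation spread before stepping;
a raw-gradient step on this compact network would be numerically inert.

One deliberate departure from the obvious formulation: the background map is
subtracted from the foreground map at their **raw aggregated scale**, not
after per-map min-max normalisation. Both maps are gradient-weighted feature
sums from the same backbone and are therefore in the same units; on frames
that clearly contain an eardrum the background map is orders of magnitude
weaker, and normalising each map to $[0,1]$ first would inflate it and make
$\lambda_{bc}=1$ systematically erode the eardrum mask.

## The classifier

No deep-learning framework is assumed: the package implements a compact CNN
(two 3x3 convolution blocks, average pooling, global average pooling,
linear head) with exact forward and backward passes. That is what the
activation-map machinery needs anyway -- gradients of arbitrary logit
functionals with respect to both the last convolutional feature maps
(Grad-CAM) and the input image (climbing) -- and with a GAP + linear head
the Grad-CAM channel weights are exact rather than estimated. Training is
cross-entropy with Adam (learning rate 0.01 halved every 20 epochs, batch 8,
45 epochs, inputs resized to 64x64 and standardised per channel); the
checkpoint with the best validation accuracy is kept, ties broken by
training accuracy. The backbone is deliberately small so the whole test
suite trains it from scratch on a CPU in about a minute; a larger backbone
can be substituted wherever a `ConvNetClassifier` is accepted, since every
downstream stage only consumes logits, feature maps and gradients.

## What the synthetic generator emulates

All tests and the acceptance script run on generator output with exact
ground truth:

* a bright circular FOV on a dark surround, with a two-band (fine + coarse)
  noise texture, so Gaussian blur removes edge energy progressively across
  scales;
* an eardrum disk whose appearance is deliberately non-uniform: a pale
  discriminative core with a bright light reflex, fading to a weakly tinted
  translucent periphery. Image-level evidence concentrated in part of the
  object is precisely the regime in which weak supervision under-covers and
  climbing has something to expand;
* pale canal-wall highlights behind the membrane and, in eardrum-absent
  views, a dark canal recess, so the background class has positive evidence
  of its own;
* per-frame controls for visibility class (partial views place 25--75% of
  the disk outside the FOV), Gaussian blur, and a high-contrast sharp patch
  exempted from the blur that serves as the known focus point.

What it does **not** emulate: wax and specular highlights, photorealistic
membrane texture, camera motion, compression artefacts, or illumination
drift. Passing the property suite therefore shows the algorithms implement
their definitions and behave correctly on controlled geometry and blur; it
does not certify clinical performance.

A caveat worth stating plainly: on this synthetic regime the background
AdvCAM of an eardrum-present frame is close to empty (the background class
learns features, such as the canal recess, that rarely co-occur with an
eardrum), so background subtraction is nearly inert and the refined map's
benchmark advantage over plain climbing is small -- occasionally within
noise of a tie. On real data, where wax and canal structure appear inside
eardrum-present frames, the background map has more to subtract.

## Numerical choices and degenerate inputs

* Edge responses are sampled from the inner 72% of the FOV radius, keeping
  the Sobel support away from the rim and from the rim's blur-smeared
  transition, which would otherwise dominate the tail at high blur.
* The mixture EM is initialised from a seeded 2-means clustering, floors
  standard deviations at $10^{-8}$, and stops at a log-likelihood change
  below $10^{-6}$ or 100 iterations. A constant sample short-circuits to
  $\sigma_{max}=0$ with a degeneracy flag.
* A flat sharpness response returns focus point $(0,0)$ with a flag; ties
  break to the smallest row, then column.
* Frames whose FOV cannot be detected (an error of class `otomifNoFov`) are
  kept in the score table with $S_{blf}=0$, so rank denominators stay
  consistent and such frames can never win selection over a valid frame.
* Coordinates are 0-based $(x, y) =$ (column, row) everywhere; grayscale is
  BT.601 luma; images are decoded to floating point in $[0,1]$.
* Videos are written as lossless multi-page TIFF or PNG directories with an
  8-bit quantisation, so decoding reproduces the written pixels exactly.

## Problem sizes used by the test suite

Classifiers are trained on 200 generated 64x64 images; the segmentation
benchmark uses 30 held-out eardrum-present images; blur monotonicity uses 20
seeds by 5 blur levels at 160x160; FOV recovery uses 50 frames; end-to-end
selection uses 20 ten-frame videos. These sizes give stable means while the
whole suite, including training both classifiers from scratch, runs in a
coffee break on one CPU core.

## Known limitations

* The clinical headline numbers of the motivating problem (confusion
  matrices, absolute IoU of eardrum segmentation, human-equivalence rates)
  depend on clinical video collections and are out of reach of a synthetic
  benchmark; only orderings and formula-level behaviour are validated here.
* The compact CNN is a stand-in scale for a production backbone; its
  activation maps are coarse (stride 2 at 64x64 input).
* MP4/AVI decoding is not provided; decode such containers to PNG frames or
  multi-page TIFF first.
* Rank fusion weights are taken as fixed configuration; learning them is
  explicitly out of scope.
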