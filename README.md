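# otomif

Most-informative-frame selection for otoscopy videos.

A hand-held otoscope examination yields hundreds of video frames, and most
are diagnostically useless: the eardrum is absent or clipped, it covers a
tiny part of the image, or the frame is blurred and focused on the canal
wall. Clinical machine-learning pipelines for otoscopy usually depend on an
expert picking the one good frame per video by hand. `otomif` automates
that selection for anyone building such pipelines: it scores every frame on
three axes and extracts the top-k most informative frames.

## The method

Each frame receives:

* **Eardrum view score** — a 3-class classifier (no / partial / full
  eardrum) gives class probabilities; the score is the expected
  eardrum-area score
  `S_edv = P_full · 1 + P_partial · 0.5 + P_none · 0`.
* **Eardrum coverage score** — the eardrum is segmented *weakly*, from
  image-level labels only: a Grad-CAM of a binary (background/eardrum)
  classifier is expanded by iterative adversarial climbing (perturbing the
  input along the gradient of
  `L = y_c − Σ_{k≠c} y_k − λ‖M ⊙ (CAM(x_t) − CAM(x_0))‖₁`, 30 iterations)
  and refined by subtracting the weighted background map,
  `map = AdvCAM_fg(x) − λ_bc · AdvCAM_bg(x)`. The mask is the set of pixels
  above half the map maximum and `S_edc` is its fraction of the frame.
* **Final blur score** — signed Sobel edge responses inside the detected
  circular field of view (FOV) are fitted with a 2-component Gaussian
  mixture; `S_bl = σ_max / (C_p + ε)` (wider-component spread over RMS
  contrast) measures sharpness, and `S_F = r_FOV − ‖focus − centre‖`
  measures how centrally the frame is focused (the focus point is the
  argmax of the squared Laplacian-of-Gaussian response). The final score is
  the product `S_blf = S_bl × S_F`.

The three are fused by a weighted sum of their per-video ranks
(rank 1 = best raw value):

```
S_I = 0.4·Rank(S_edv) + 0.2·Rank(S_edc) + 0.4·Rank(S_blf)
```

A smaller `S_I` marks a more informative frame; `selectTopK()` returns the
k smallest. The package also ships a synthetic otoscope-frame generator
with exact ground truth (FOV circle, eardrum mask, visibility class, blur
level, focus location), a compact CNN with the exact gradient plumbing the
activation-map methods need, and the usual segmentation metrics (IoU, DSC,
accuracy, sensitivity, specificity, AUROC, Hausdorff distance, mean
boundary deviation). See the vignette `frame-selection-methods.Rmd` for
model details, parameter defaults and limitations.

## Worked example

Everything below runs on synthetic data with known ground truth: a 6-frame
"examination" in which frame 1 is designed to be the best (full eardrum,
zero blur, centred focus) and the rest are degraded.

```r
library(otomif)

demo  <- designBestFrameVideo(seed = 7, n = 6, imageSize = c(128, 128))
video <- file.path(tempdir(), "exam.tiff")
generateVideo(demo$specs, video, bestIndex = demo$bestIndex)
demo$bestIndex
#> [1] 1

bin  <- trainViewClassifier(generateShapesDataset(80, seed = 5),
                            epochs = 25, seed = 1)
view <- trainViewClassifier(generateShapesDataset(80, seed = 11,
                                                  classes = "view"),
                            epochs = 25, seed = 2)

res <- runPipeline(video, view, bin, pipelineConfig(topK = 2L, seed = 1L))
as.data.frame(res)[, c("frame_index", "s_edv", "s_edc", "s_blf", "s_i",
                       "selected")]
#>   frame_index     s_edv      s_edc      s_blf s_i selected
#> 1           0 0.5823968 0.06079102  0.0000000 4.6    FALSE
#> 2           1 0.8398808 0.17193604 39.1826197 1.4     TRUE
#> 3           2 0.6348933 0.03546143 82.4568498 2.6     TRUE
#> 4           3 0.6920425 0.07330322  0.0000000 3.2    FALSE
#> 5           4 0.6205692 0.05548096  0.6154782 3.6    FALSE
#> 6           5 0.1449890 0.03356934  0.0000000 5.6    FALSE
```

Reading the table: frame 1 has the most complete eardrum view
(`s_edv` 0.84), the largest eardrum coverage (`s_edc` 0.17) and a high
final blur score, so its weighted rank sum `s_i = 1.4` is the smallest and
it is selected first. Frames whose field of view or focus cannot be
assessed get `s_blf = 0` and can never outrank a valid frame. The designed
best frame is exactly the pipeline's first pick:

```r
S4Vectors::metadata(res)$selected
#> [1] 1 2
```

A thin command-line wrapper with `synth` / `train` / `score` subcommands is
installed under `inst/scripts/otomif-cli.R`.

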