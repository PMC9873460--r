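# slns — self-learning brain-tumor MRI segmentation and impact analysis

`slns` identifies brain tumors in 2-D MRI slices and quantifies their
impact. It is aimed at image-analysis researchers who want a fully
testable, dependency-light reference implementation of a self-learning
segmentation-plus-classification pipeline: every stage can be exercised
on a built-in synthetic brain phantom with exact ground truth, so no
external imaging data is needed.

The pipeline, in order:

1. **Phantom generator** — brain-like slices (skull ring, parenchyma,
   tumor core, enhancement rim) with Gaussian or Rician noise and exact
   label masks (`generate_phantom()`, `generate_dataset()`).
2. **Fuzzy-Gaussian denoising** — a 5×5 Gaussian response G minus a
   fuzzy-weighted high-frequency correction
   `f_z(p) · gain · (G − G⊗ω)`, where
   `f_z(p) = 1 / (1 + ((p − t_max)/k_max)^(2u_max))` (`denoise_image()`).
3. **GLCM texture** — grey-level co-occurrence counts
   `C(x,y) = #{(p,q) : I(p,q)=x, I(p+d_r, q+d_c)=y}` normalized to
   probabilities, with Haralick-style contrast, energy, homogeneity and
   entropy (`compute_glcm()`, `texture_stats()`).
4. **Fitness machinery** — Otsu between-class variance
   `ω₁ω₂(μ₁−μ₂)²`, fuzzy-entropy thresholding, intraclass correlation
   `σ²_seg/(σ²_seg+σ²_img)`, and the two-term partition fitness
   `p·N/k + q·Σ_seg(SP/n_seg)` (`interclass_variance()`,
   `fuzzy_entropy_threshold()`, `segment_fitness()`).
5. **HARIS segmentation** — elbow-initialized segment count,
   Mahalanobis pixel assignment `(x−μ)ᵀS⁻¹(x−μ)`, cost-driven
   merge/split adaptation, and stochastic seed-point refinement
   `sp_i = U₁·sp_{i−1} + U₂·(GB − sp_{i−1})` toward the global-best
   configuration (`run_haris()`).
6. **VAE augmentation** — a Gaussian-posterior variational autoencoder
   trained on the ELBO (reconstruction − KL) to generate extra training
   slices (`vae_train()`, `vae_sample()`, `vae_augment()`).
7. **Bidirectional recurrent classifier** — the sigmoid recurrences
   `ff_i = σ(W_i·pix_i + W·ff_{i−1} + b)` (and its right-to-left
   mirror) over patch rows, softmax tumor/non-tumor readout, trained
   with a monotonically decaying learning rate and class weights from a
   persisted self-learning memory (`rnn_train()`, `classify_image()`).
8. **Impact reporting** — tumor core / enhanced / whole areas, the
   texture-weighted damage index `ln(1+area)·(1+contrast)` with a
   bootstrap "erroneous index", longitudinal progression deltas, and
   colormap overlays (`impact_report()`, `progression()`).
9. **Evaluation** — confusion counts, sensitivity, specificity,
   accuracy, F1 and Dice, plus a seeded end-to-end phantom benchmark
   (`confusion_eval()`, `benchmark_phantoms()`).

## Worked example

```r
library(slns)

ph <- generate_phantom(phantom_spec(noise_sigma = 5, seed = 42))
print(ph$mask)
#> <label_mask 228 x 228>
#>   counts: 0=28932 1=3132 2=18267 3=1009 4=644

tm  <- tumor_masks(ph$mask)
seg <- run_haris(ph$image, haris_config(seed = 1), brain_mask = tm$brain)
print(seg)
#> <haris_segmentation: k=3, fitness=194.5, plateaued after 7 iterations>

best_segment_dice(seg$labels, tm$core)$dice
#> [1] 0.9995

impact_report(derive_regions(ph$mask), unclass(ph$image), seed = 1)
#> <impact_report: core 1009 px (index 13.978 +/- 0.618),
#>  enhanced 644 px (index 13.239 +/- 0.735),
#>  whole 1653 px (index 28.735 +/- 3.331)>
```

The phantom has 1009 core and 644 rim pixels; HARIS settles on three
brain-tissue segments after 7 iterations, and the segment matched to
the tumor core overlaps it with Dice 0.9995. The impact report gives
each region's damage index (log-area scaled by GLCM contrast) with the
half-width of its 95% bootstrap interval — the "erroneous index" that
progression tracking uses to decide whether growth is real.

A ready-made end-to-end run (phantom → denoise → texture → HARIS →
classifier → impact, with all artifacts and provenance written to an
output directory) is:

```r
res <- run_pipeline(pipeline_config(overrides = list(seed = 1)))
```

or, from a shell, via the thin CLI in `inst/scripts/slns`
(`slns simulate`, `slns segment`, `slns run`, ...).

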