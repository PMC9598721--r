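# avnlbp

Content-based retrieval of grayscale texture images, built for the setting
where archives (for instance medical CT/MRI/X-ray collections) must be
indexed compactly and searched by example despite noisy acquisitions. The
package implements the full stack as tested, composable R functions:

1. **AvN-LBP**, a sector-averaged local binary pattern. The `(2R+1)×(2R+1)`
   neighborhood of each pixel is partitioned into `p` angular sectors, each
   sector's intensities are averaged to `x'_n`, and the code is

   ```
   AvN-LBP = Σₙ S(x'_n − μ) 2ⁿ,   μ = (1/p) Σₙ x'_n,   S(x) = 1 iff x ≥ 0
   ```

   Thresholding sector *averages* against their own mean makes the code
   exactly invariant to illumination shifts and markedly more robust to
   additive noise than classic LBP (also provided, with bilinear circle
   sampling). Images are indexed by the histogram of codes over interior
   pixels (length `2^p`).

2. **Fuzzy ARTMAP (FAM)** — an incremental supervised classifier on
   complement-coded features in `[0,1]^d`, with choice competition
   `T_j = |AI∧W_j| / (α + |W_j|)`, vigilance `|AI∧W_j|/|AI| ≥ ρ`, match
   tracking, and fast/convex weight updates.

3. **DEFAM** — differential evolution over a population of trained FAM
   networks (fixed-capacity slot encoding, neighborhood-to-best mutation
   `V = x_r3 + F₁(x_best − x_r3) + F₂(x_r1 − x_r2)`, binomial crossover,
   elitist selection) minimizing a guarded fitness whose optimum is the
   smallest feasible network at full accuracy — it prunes the category
   proliferation that order- and noise-sensitive FAM training produces.

4. **Retrieval scoring** — per-query precision/recall against same-class
   relevance, aggregated to ARP (mean precision at a fixed depth) and ARR
   (mean recall at depth `max(n_relevant, 10)`), with plain-distance and
   classify-then-search ranking modes.

5. **Synthetic textures** — seeded sinusoidal-grating and Gaussian-random-
   field generators with class-distinct parameters, SNR-calibrated Gaussian
   noise, and stratified 40/30/30 splits, so the whole pipeline is testable
   without any external image archive.

Everything is tibble-first: feature tables, metrics, splits and evolution
traces are tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(avnlbp)

# the standard worked example: eight sector means -> decimal code
avn_lbp_code(c(160.33, 157.5, 172.66, 157.33, 161.66, 172.66, 192.83, 157.83))
#> [1] 100

# synthetic 3-class texture database, split, indexed with AvN-LBP
imgs  <- generate_textures(texture_spec(n_classes = 3, images_per_class = 10), seed = 1)
sp    <- split_dataset(imgs, seed = 2)                      # 40/30/30 stratified
h     <- compute_histograms(sp, nbhd_spec(p = 8, R = 3), variant = "avn")
train <- h[h$split == "train", ]; val <- h[h$split == "validation", ]
test  <- h[h$split == "test", ]

# a diverse FAM population (shuffled orders, jittered vigilance), then DE
nets <- fam_population(feature_matrix(train), train$label, n = 8,
                       params = fam_params(rho = 1, beta = 0.8),
                       rho_range = c(0.5, 0.9), seed = 3)
fit  <- defam_evolve(nets, feature_matrix(val), val$label,
                     de_params(catmin = 3, catmax = 20, generations = 20, seed = 4))
fit
#> <defam_fit> 20 generations | best fitness 0 (pcc 100.0%, 3 categories)

# classify-then-search retrieval, scored on the held-out test images
db <- index_images(train)
m  <- score_retrieval(db, test, k_precision = 4, classifier = fit$best_network)
retrieval_summary(m)
#> # A tibble: 1 × 3
#>   n_queries   ARP   ARR
#>       <int> <dbl> <dbl>
#> 1         9     1     1
```

Reading the output: the evolution reached the global optimum of its fitness
— a 3-category network (one hyperbox per class, `catmin = 3`) at 100%
validation accuracy — and the evolved classifier retrieves only same-class
images for every test query at depth 4 (`ARP = 1`), finding all relevant
images (`ARR = 1`). On noisier or more overlapping data the interesting
behavior is the trade-off recorded in `tidy(fit)` (the per-generation
fitness trace) and in per-query `m`.

A one-command version of the same workflow, writing histograms, networks,
trace and metrics as CSV/JSON artifacts, is

```r
run_pipeline(run_config(seed = 1, out_dir = "run1"))
```

and a thin CLI over the same functions lives at `inst/cli/avnlbp.R`
(subcommands `generate`, `extract`, `train-fam`, `evolve`, `retrieve`,
`evaluate`, `pipeline`).

## Layout

| Path | Contents |
| --- | --- |
| `R/descriptors.R` | LBP / AvN-LBP codes, sector geometry, histograms |
| `R/images.R` | PNG/TIFF/PGM IO, SNR-calibrated Gaussian noise |
| `R/fam.R` | Fuzzy ARTMAP training, prediction, serialization |
| `R/defam.R` | encoding, DE mutations, crossover, fitness, evolution |
| `R/retrieval.R` | indexing, ranking, precision/recall/ARP/ARR |
| `R/synthetic.R` | texture generators and stratified splits |
| `R/pipeline.R` | validated YAML config and end-to-end runner |
| `vignettes/avnlbp-methods.Rmd` | the models, parameters and design choices |
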