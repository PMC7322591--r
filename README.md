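# entropyDR

Screening colour fundus photographs for **referable diabetic retinopathy**
(grade ≥ 2 on the 0–4 severity scale) with local-entropy texture images and
a two-input ("bichannel") convolutional network — plus a seeded synthetic
fundus-phantom generator that makes the entire pipeline testable end to end
without downloading a single photograph.

## The method

Severer retinopathy produces more small structure — microaneurysms,
hemorrhages, exudates — and therefore more *local heterogeneity* in the
image. The pipeline turns that observation into features:

1. **Resize** the photograph to the working resolution (100 × 100).
2. Extract two monochrome views: the **luminance**
   `Y = 0.299 R + 0.587 G + 0.114 B` and the **green component** `G`
   (retinal pigments reflect green light preferentially, so `G` has the
   strongest vessel/lesion contrast).
3. Sharpen each view by **unsharp masking**:
   `UM(x) = clip(round(x + a·(x − G_σ x)), 0, 255)` with Gaussian blur
   `G_σ` (defaults σ = 2 px, a = 1).
4. Compute the **local Shannon-entropy image**: at every pixel, the entropy
   `E = −Σ_i P(i) log₂ P(i)` of the intensity histogram of the centred
   n × n window (default n = 9, reflective borders), rescaled by the fixed
   maximum `log₂ min(n², bins)` into [0, 1].
5. Feed the two entropy images to a **bichannel CNN**: per input, four
   blocks of [5×5 conv → ReLU → 2×2 max-pool] (reference filters
   32/64/64/128), flattened, concatenated, dense + dropout 0.3, sigmoid
   output; binary cross-entropy, Adam.
6. Evaluate with screening metrics: accuracy, sensitivity, specificity at a
   threshold (default 0.5), and ROC/AUC (trapezoidal = Mann–Whitney with
   midrank ties).

Class balancing with lossless flip/rotation augmentation, leakage-safe
stratified train/test splitting, and a grade-dependent phantom generator
(lesion counts Poisson with strictly increasing per-grade means 0, 2, 6,
12, 20) round out the toolkit. The methods vignette
(`vignettes/entropy-screening.Rmd`) documents every model assumption,
parameter default and numerical convention.

## Worked example

```r
library(entropyDR)

# a moderate-retinopathy phantom and its two network inputs
ph <- generate_phantom(phantom_spec(side = 100, grade = 3, seed = 7))
ph$image
#> <rgb_image 100 x 100, intensity range [0, 221]>
ph$record
#>        image_id grade referable
#> 1 phantom_g3_s7     3      TRUE

e_green <- make_channel_input(ph$image, "green")
e_green
#> <entropy_image 100 x 100, n = 9, bins = 256, unit-rescaled, range [0.2449, 0.9649]>

# grade-0 phantoms are smoother: their mean entropy is visibly lower
e0 <- make_channel_input(generate_phantom(phantom_spec(100, 0, seed = 7))$image, "green")
round(c(grade0 = mean(e0), grade3 = mean(e_green)), 3)
#> grade0 grade3
#>  0.665  0.691

# small end-to-end run (a few dozen phantoms; see below for the full bench)
res <- run_benchmark(n_per_class = 50, corpus_seed = 1,
                     config = benchmark_config(seed = 1, epochs = 4))
res$report
```

The per-grade entropy gap is what the classifier exploits: lesions raise
windowed intensity diversity, so referable phantoms score higher almost
everywhere in the disc.

A shell front-end with `generate-corpus`, `preprocess`, `build-dataset`,
`train`, `evaluate` and `run-all` subcommands lives at
`inst/cli/entropydr.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/entropydr.R", package = "entropyDR"))')" \
    run-all --out runs/demo --seed 7
```

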