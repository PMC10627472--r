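# woundseg

Chronic-wound care needs quantitative, repeatable measurements — boundary,
area, perimeter, dimensions, and a shape suggestion for the dressing —
where clinical practice still relies on subjective visual inspection.
`woundseg` is an R implementation of a conditional-GAN wound segmentation
pipeline with morphometric post-processing, aimed at people building or
studying automated wound-assessment tools: it trains a U-Net generator
against a patch-level discriminator to map a wound photograph `x` to a
binary wound mask, then measures every segmented region.

## The model

The generator G (U-Net: stride-2 4×4 convolutions down, transposed
convolutions up, skip connections, sigmoid output) produces a per-pixel
wound probability G(x). The discriminator D (six convolution stacks,
filters 64–512, final sigmoid) scores overlapping *patches* of the
(image, mask) pair as real or fake; the mean of its score matrix is the
scalar "patch-out". Training alternates

- discriminator: `L_D = α · (−E[log D(x,y)] − E[log(1 − D(x,G(x)))])`, α = 0.5,
- generator: `L_G = λ₁·L_adv + λ₂·L_rec`, λ₁ = 1, λ₂ = 100,

with `L_rec` the pixelwise |y − G(x)| and Adam (η = 0.002, β₁ = 0.5).
Predicted masks are cleaned (reconstruction opening, hole filling, area
floor), labeled into connected regions, and measured: area A, contour
perimeter r, bounding box, moment-equivalent axes, and the descriptors

- eccentricity `e = √(major² − minor²)/major`,
- circularity `Ω_c = A / r²` (a disk attains 1/(4π) ≈ 0.0796),
- rectangularity `ψ_R = A / (width × length)`,

from which an approximate shape is called (rectangle if ψ_R ≥ 0.85, else
circle if e ≤ 0.40, else ellipse) and the matching dimensions reported
(diameter / axes / width × length). Evaluation uses precision, recall,
Dice `2TP/(2TP+FP+FN)` and IoU `TP/(TP+FP+FN)`.

A seeded synthetic-scene generator (reddish wound shapes with exact
ground-truth masks over textured skin-toned backgrounds) makes the whole
pipeline testable without clinical data; see the methods vignette
(`vignettes/wound-segmentation-methods.Rmd`) for the model details and
design decisions.

## Worked example

```r
library(woundseg)

## two synthetic scenes with known shape ground truth
pairs <- generate_dataset(2, side = 128, seed = 4)
attr(pairs, "truth")[1:3, c("kind", "center_row", "center_col")]
#>                kind center_row center_col
#> 1 rounded_rectangle   87.24283   45.38956
#> 2           ellipse  112.16037   72.99772
#> 3 rounded_rectangle   63.00049  104.56530

## measure the first scene's mask (here: the ground truth itself)
res <- analyze_mask(pairs[[1]]$mask, image = pairs[[1]]$image)
print(res$table, digits = 3)
#>   label shape_call area_px perimeter_px width length major_axis minor_axis
#> 1     1  rectangle     429         77.9    26     17       29.3      19.13
#> 2     2  rectangle     365         70.5    20     19       22.8      21.08
#> 3     3    ellipse     109         38.1     9     15       15.2       9.08
#>   equivalent_diameter eccentricity circularity rectangularity
#> 1                23.4        0.758      0.0707          0.971
#> 2                21.6        0.378      0.0735          0.961
#> 3                11.8        0.803      0.0749          0.807
```

The two rounded rectangles are called `rectangle` (bounding box ≥ 96%
filled) and the elongated ellipse `ellipse` (e ≈ 0.80, box only 81%
filled); `res$overlay` carries the image with boundaries drawn green /
yellow / blue by area rank, and each row's dimensions are the ones a
clinician would read off for that shape (width × length for rectangles,
axes for ellipses, diameter for circles).

Training and segmentation run through the same API (`train_gan()`,
`segment_image()`, `evaluate_generator()`) or the bundled CLI:

```sh
inst/cli/woundseg synth --n 8 --side 64 --seed 7 --out data/
inst/cli/woundseg train --data data/ --config train.yaml --out run/
inst/cli/woundseg pipeline --weights run/ckpt_best.rds --image img.png --out out/
```

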