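# rnflseg

Automatic segmentation of the **retinal nerve fiber layer (RNFL)** in 2D
peripapillary B-scan OCT images, and RNFL thickness reporting per TSNIT
sector. The RNFL is the innermost retinal layer; its thinning along a
circular scan around the optic nerve head is a standard glaucoma
biomarker, so reliable, automatic delineation of the layer's two
boundaries in every scan column is the core measurement problem this
package addresses — for ophthalmic image-analysis researchers and for
anyone needing a classical, fully inspectable alternative to
deep-learning layer segmentation.

## Method

Three boundaries are extracted sequentially from the unrolled scan
(x = angle, y = depth, 3.87 µm/pixel):

1. **#1-UB** — the vitreous/RNFL transition. Opening by a disk ◯7
   suppresses bright vitreous artifacts; the first positive crossing of
   the vertical gradient ∇v+ per column, smoothed (N = 101) and refined by
   an active contour, gives the boundary.
2. **#2-AB** — the lower edge of the outer nuclear layer, used as an
   auxiliary reference. Opening/closing *by reconstruction* with ◯9 and
   plain ◯3 filtering clean the mid-retina; the first ∇v+ crossing in
   [UB+8, UB+260] above threshold 10 is selected. A blood-vessel shadow
   mask is computed by frequency-domain suppression of vertical structure
   plus morphological refinement, and the snake's external forces are
   cancelled inside it.
3. **#3-LB** — the RNFL/GCL transition. The image is flattened on #2-AB,
   cleaned with ◯3 reconstructions, a 31×3 closing (bridging vessel
   shadows) and an 11×3 opening; the first ∇v− crossing ≤ −3 in
   [UB+8, UB+60], smoothed (N = 15) and snake-refined with the rectified
   mask, is mapped back.

Each snake is a closed periodic B-spline contour iterated in the
frequency domain,
`U_ξ = H(ω)[a₁U_{ξ−1} + a₂U_{ξ−2} + ηQ_{ξ−1}F(ω)]` with
`H = 1/(γ+η+K)`, `K(ω) = α(2−2cos ω) + β(2−2cos ω)²`, whose fixed point is
the static force balance `(αD₂ + βD₄)u = ηq` (α = 0.5, β = 1, γ = η = 1).

Thickness is `w[k] = (LB[k] − UB[k])·3.87 µm`, averaged per TSNIT sector
(T, TS, NS, N, NI, TI) and globally (G).

A synthetic **phantom generator** produces layered B-scans with known
ground-truth boundaries, vessel shadows, floaters and multiplicative
speckle, so every stage is testable without clinical data.

## Worked example

```r
library(rnflseg)

ph  <- phantom_generate(phantom_spec(seed = 7, speckle_sd = 0.05))
res <- segment_rnfl(ph$image)
res$report
#> RNFL thickness by sector (um):
#>     T    TS    NS     N    NI    TI 
#>  85.7 115.9  85.0  77.6  85.0 116.0 
#> Global mean G: 91.0 um

boundary_mae(res$lb, ph$truth$lb_true)   # rows of error vs ground truth
#> [1] 0.3291
dice(rnfl_region(res$ub, res$lb, 496),
     rnfl_region(ph$truth$ub_true, ph$truth$lb_true, 496))
#> [1] 0.9914
```

The report gives the mean RNFL thickness in micrometers for each sector
of the scan circle and the global mean G; the phantom's double-hump
anatomy shows up as thick TS/TI sectors. MAE is the mean per-column
boundary error in pixel rows, and the Dice coefficient measures overlap
of the segmented RNFL region with the ground truth.

For real scans exported as 8-bit PNG/TIFF:

```r
img <- read_oct("scan.png", z_scale_um = 3.87)
res <- segment_rnfl(img)
write_report(res$report, "report.json")
write_boundaries(list(res$ub, res$ab, res$lb), "boundaries.csv")
```

or from a shell:

```sh
Rscript inst/cli/rnfl-segment.R scan.png --out report.json \
    --boundaries boundaries.csv --mask mask.png
Rscript inst/cli/rnfl-phantom.R --seed 1 --speckle-sd 0.05 \
    --out phantom.png --truth truth.csv
```

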