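---
title: "Methods: morphology-and-snake segmentation of the RNFL in peripapillary OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphology-and-snake segmentation of the RNFL in peripapillary OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The thickness of the retinal nerve fiber layer (RNFL), measured along a
circular OCT scan around the optic nerve head, is a standard glaucoma
biomarker. The unrolled B-scan is a 768 x 496 grayscale raster (x = angle
on the scan circle, y = depth, 3.87 um/pixel vertically) in which the RNFL
is the bright innermost band. Measuring its thickness requires delineating
two boundaries per column: the vitreous/RNFL transition (UB) and the
low-contrast RNFL/GCL transition (LB). Speckle noise, vitreous floaters and
the shadows cast by blood vessels crossing the scan circle are the
obstacles; the shadows in particular erase the LB locally.

`rnflseg` segments the layer in three sequential stages, each following the
same pattern: *morphological preprocessing* for robust coarse detection,
then a *frequency-domain active contour* for subpixel refinement.

## Stage structure

1. **UB.** An opening by a disk of radius 7 removes bright vitreous detail
   smaller than the structuring element (floaters, speckle spikes). The
   first positive vertical-gradient crossing above threshold 10 down each
   column gives a coarse curve; a circular 101-column moving average and
   the snake refine it.
2. **AB (auxiliary).** The lower edge of the outer nuclear layer is the
   strongest black-to-white transition below the RNFL and can be found
   reliably; it later serves as the flattening reference for the LB stage.
   Dark then bright details smaller than a disk of radius 9 are removed by
   opening/closing *by reconstruction* (which, unlike plain filters,
   restores the surviving structures exactly), plus a disk-3 opening and
   closing. Selection is restricted per column to rows `[UB+8, UB+260]`
   with threshold 10. The blood-vessel mask is computed here (below), and
   the snake runs with its external forces cancelled inside the mask.
3. **LB.** The image is rectified — every column shifted by an integer so
   the AB lands on a common row — which aligns the retina with the wide,
   flat structuring elements that follow: after disk-3 cleaning by
   reconstruction, a 31x3 closing bridges dark vessel-shadow gaps in the
   RNFL and an 11x3 opening removes narrow bright specks. The boundary is
   the first *negative* gradient crossing (<= -3) in `[UB+8, UB+60]`,
   smoothed with a narrow window (N = 15, preserving the real concavities
   of the LB), refined by the snake on the negative-gradient magnitude with
   the rectified, 5-px-dilated mask, and mapped back.

Thickness is `w[k] = (LB[k] - UB[k]) * 3.87` um, averaged over the TSNIT
sectors (Temporal 0-45 and 315-360 degrees, TS, NS, Nasal 135-225, NI, TI)
and globally (G).

### Coordinate convention

All gradients are forward differences `f[r+1] - f[r]` stored at row `r`, so
a reported boundary row `y` means the physical transition lies between rows
`y` and `y + 0.5` further down — i.e. at `y + 0.5` in pixel-center
coordinates. The phantom generator returns its ground truth in the same
convention, and the half-pixel offset cancels in any thickness, so no
calibration constant appears anywhere.

## The vessel-shadow mask

Shadows are columns, i.e. structures with nonzero horizontal frequency
concentrated near zero vertical frequency. A zero-phase frequency-domain
notch,

$$H_1(\omega_x,\omega_y) = 1 - \left(1 - e^{-\omega_x^2/2\sigma_x^2}\right)
  e^{-\omega_y^2/2\sigma_y^2},$$

with $\sigma_x = 2\pi\cdot 2/768$ and $\sigma_y = 2\pi\cdot 6/496$
(config-exposed as cycle counts `vm_notch_nx`, `vm_notch_ny`), passes DC
and all purely vertical variation while removing the shadows; the smooth
Gaussian profile avoids the ringing a brick-wall notch would create. The
nonnegative residual `max(0, filtered - I)` lights up exactly the shaded
pixels. Morphology then shapes it into a mask: opening by a 5-px horizontal
line (a shadow must have some width), reconstruction under the residual,
opening by a 51-px vertical line (it must span the retinal band), removal
of everything outside the rows strictly between UB and the pre-snake AB,
a second vertical opening, and binarisation at 10% of the maximum. Because
the filter passes DC the mask is invariant to global intensity offsets.

## The frequency-domain snake

Each boundary is a closed periodic contour with one node per image column
(the scan circle is closed, so the DFT applies without boundary tricks);
only the y-coordinates move. With nodal vector $u$ and DFT bins
$\omega_k = 2\pi k/S$, the internal (elasticity $\alpha$, stiffness
$\beta$) energy diagonalises as
$K(\omega) = \alpha(2-2\cos\omega) + \beta(2-2\cos\omega)^2$, and the
two-step iteration is

$$U_\xi = H(\omega)\left[a_1 U_{\xi-1} + a_2 U_{\xi-2}
  + \eta\, Q_{\xi-1} F(\omega)\right],\qquad
  H = \frac{1}{\gamma + \eta + K},\; a_1 = \gamma + 2\eta,\; a_2 = -\eta.$$

These coefficients are the package's own closed-form choice; they are
constructed so that (i) $H(0)(a_1+a_2)=1$, hence the contour mean is
preserved exactly under zero force, and (ii) the fixed point satisfies
$K(\omega)U = \eta Q F$, the static Euler-Lagrange balance
$(\alpha D_2 + \beta D_4)u = \eta q$ — any stable scheme with this fixed
point reaches the same equilibrium contour, which is what the tests verify
against a direct circulant solve. In the time domain the update is the
damped inertial step
$\eta(u_\xi - 2u_{\xi-1} + u_{\xi-2}) + \gamma(u_\xi - u_{\xi-1}) + K u_\xi
= \eta q$. Defaults $\alpha=0.5,\beta=1,\gamma=1,\eta=1$ are used for all
three boundaries.

$F(\omega) = (4+2\cos\omega)/6$ is the DFT of the periodic cubic B-spline
sampled at the nodes — with one node per column the shape function acts as
a mild spectral smoothing of the force term.

External forces are the vertical derivative of the stage's gradient-ridge
map, blurred with a 1-row Gaussian to widen the capture range and sampled
bilinearly at each node; nodes over masked columns receive zero force. The
ridge map is **normalized to unit maximum** before differentiation: the
explicit force step is stable only for field slopes of order one row per
row, and a node's equilibrium on a ridge does not depend on the ridge's
absolute height, so the normalisation removes an arbitrary intensity scale
without changing the minimiser. Convergence is declared at a maximum
per-node displacement below 0.01 rows (`tol`), capped at 500 iterations —
neither value is standardised elsewhere; they were fixed once from the
force-free relaxation rate of the slowest mode.

## Numerical choices and degenerate inputs

* **Morphology.** Disk footprints contain the pixels at Euclidean distance
  `<= r`; erosion treats out-of-image samples as +Inf and dilation as
  -Inf, so openings/closings cannot invent border structure.
  Reconstruction is geodesic dilation with 8-connectivity run to its exact
  fixed point (a raster-sweep + FIFO queue algorithm, not a fixed
  iteration count). Rectangle erosions/dilations are decomposed into line
  passes, which is exact for flat structuring elements. If floating-point
  drift ever leaves a marker above its mask it is clipped with a warning
  rather than an error, because the pipeline chains many operators on
  uint8-ranged floats.
* **Selection.** Columns with no qualifying gradient crossing are filled
  by circular linear interpolation (the ring topology makes "nearest
  neighbours" well defined) and flagged undetected; the snake provides the
  final position there. An image where *no* column qualifies raises a
  classed error (`rnflseg_no_boundary`).
* **Rectification** uses integer shifts with edge replication; subpixel
  resampling is deliberately avoided so that the morphology downstream
  operates on unmixed intensities.
* **Failure modes.** An LB above the UB in more than 5% of columns, or a
  UB/AB ordering violation, raises `rnflseg_inconsistent` — scans with
  truncated or discontinuous layers are invalid acquisitions and are
  re-taken in practice, so the package refuses rather than clamps. The CLI
  maps these classes to exit codes.
* The LB threshold `gamma = 3` is applied to the magnitude of the negative
  gradient (values `<= -3`): the printed constant is positive while the
  gradient of interest is negative, and the magnitude reading is the only
  consistent one. The UB stage's scan threshold is not separately
  standardised; it defaults to the AB value (10) and is configurable.

## The phantom generator

The generator emulates what the segmentation actually relies on: a layered
band structure (vitreous 12, RNFL 170, GCL+IPL 105, INL 55, OPL 110, ONL
30, a bright sub-ONL band 205, deep tissue 80), an RNFL thickness profile
of 20 rows baseline plus two 12-row von-Mises humps centered in the TS and
TI sectors (the anatomical double hump), smooth Gaussian-profile vessel
shadows (5 by default, FWHM 6-10 px, attenuation factors 0.35-0.5)
multiplying everything below the RNFL top, bright floater disks in the
vitreous, and multiplicative speckle `I = clip(clean * (1 + n))` with
`n ~ N(0, sd)` — the parameterisation under which robustness is usually
quoted for OCT, with sd up to 0.316 stressing the method far beyond the
0.003-0.03 estimated on real scans. A gamma-distributed speckle option was
considered and rejected for the validation path: the acceptance properties
are about boundary geometry, not noise statistics, and the Gaussian
parameterisation is the one whose sd the sweep controls directly.

Two intensity choices are deliberate. GCL+IPL (105) and OPL (110) differ
by less than the AB selection threshold (10): after the disk-9 closing by
reconstruction fills the thin dark INL, the residual inter-layer step must
not trigger the AB detector — in real scans the ONL lower edge is likewise
the dominant transition. And the minimum RNFL thickness (20 rows) exceeds
the disk-9 diameter threshold so the layer itself survives the AB-stage
filtering.

What the phantom does **not** model: curved-retina geometry, motion
artifacts, depth-dependent signal decay, correlated (physical) speckle,
vessel-induced boundary deformation. Passing tests therefore demonstrate
the method's geometric correctness and its robustness to the modelled
artifact classes, not clinical-grade accuracy on real scans.

## Problem sizes used in the validation suite

The automated suite runs the full pipeline on full-size (768 x 496)
phantoms: ten noisy vascular phantoms with speckle sd spanning 0.01-0.1
(five vessels, three floaters each), a robustness sweep at sd = 0.031,
0.1, 0.178, 0.316 and 0.5, and six structuring-element variants on a clean
phantom. Operator-level oracle checks use 200 random images up to 16 x 16,
where brute-force sliding-window and iterated-geodesic references are
affordable; snake equilibria are verified against dense circulant solves
at S = 16-64 nodes. These sizes were chosen as the smallest that exercise
every code path at deployment scale.

## Known limitations

* Parameters are tuned for the 768 x 496 Spectralis geometry; other
  instruments require rescaling the structuring elements and windows to
  the expected layer widths in pixels (all are in `stage_config()`).
* The AB snake runs in original (unrectified) space; only the LB stage
  rectifies. On strongly curved scans the wide AB smoothing window can
  bias the initialisation, which the snake then corrects only within its
  capture range (about 3 rows).
* Inside wide vessel shadows all three methods of record disagree with
  each other; the snake's interpolation is smooth but not evidence-based
  there, and the per-column `detected` flags should be consulted when
  thickness in shaded columns matters.
* DICOM / proprietary Spectralis containers are not parsed; export to
  8-bit PNG or TIFF first.
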