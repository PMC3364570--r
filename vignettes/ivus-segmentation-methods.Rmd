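---
title: "Contour detection in IVUS cross-sections: models, parameters and design notes"
author: "ivusseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour detection in IVUS cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5)
library(ivusseg)
```

Intravascular ultrasound (IVUS) renders cross-sections of a coronary artery
from a catheter inside the lumen. Quantitative plaque assessment needs two
closed contours per frame: the lumen border (blood / inner wall) and the
media-adventitia border (outer media / bright adventitia). Pull-backs
produce hundreds of frames, and speckle plus the catheter's own artifacts
(ring-down halo, guide-wire shadow) make manual tracing slow and automatic
delineation brittle. `ivusseg` implements an automatic two-border
segmentation built from four cooperating pieces, plus a phantom simulator
and error metrics so every part of the chain can be validated without
clinical data.

## The segmentation model

### Contourlet decomposition

The image is decomposed by a Laplacian pyramid (LP) into low-pass
approximations $a_1,\dots,a_J$ and band-pass details $b_1,\dots,b_J$, and
each $b_j$ is split by a directional filter bank (DFB) into $2^{l_j}$
orientation subbands $c_{j,k}$. The low-pass path drives initialization
(speckle fades with scale, geometry survives); the directional band-pass
path carries both the speckle and the edge detail, and is where despeckling
happens.

The LP uses the biorthogonal 9/7 filter pair normalized to unit DC gain, so
constants pass through unchanged; reconstruction is exact by construction
because each detail band stores the residual against the interpolated
coarser level. The DFB is realized lattice-free in the DFT domain: $2^l$
ideal fan (wedge) masks that partition the frequency plane, applied by FFT.
Each directional subband keeps the grid of its detail band, reconstruction
is the pointwise sum, and perfect reconstruction holds to machine precision
because the masks sum to one. This choice trades the critical sampling of
ladder-filter DFBs for three properties that matter here: exact
invertibility, unambiguous per-scale pooling (the sum over $k$ of the
filtered subbands *is* the DFB reconstruction), and subbands on the pixel
grid, which is what an image-domain diffusion filter wants to see.

```{r contourlet}
x <- matrix(rnorm(96 * 96), 96)
co <- contourlet_decompose(x, levels = 3, dfb_levels = c(2, 2, 3))
co
max(abs(contourlet_reconstruct(co) - x))
```

### Circle initialization by a multiresolution Hough transform

Both borders are roughly circular around the catheter, so initial contours
are circles found by a circular Hough transform (CHT) on Canny edge maps of
the low-pass bands, coarse to fine. At the coarsest band the full
accumulator is searched; the approximate lumen center (darkness-weighted
centroid of sub-threshold pixels in an annulus around the catheter) selects
the lumen circle, the media circle is the admissible candidate (center
within $D_c$ of the lumen center, radius larger) with the best combination
of votes and boundary gradient, and the lumen search is then re-run with its
maximum radius capped at half the media radius. At each finer level the
circles are rescaled and re-detected inside a window around the prediction.

Three scoring details are load-bearing, all motivated by the artifact model
rather than by clean-circle theory:

* Canny thresholds are fractions of the **99th percentile** of gradient
  magnitude, not of the maximum: the ring-down halo owns the global maximum,
  and thresholds tied to it silently delete the weaker lumen edge.
* Accumulator scores are votes **divided by circumference**: under uniform
  speckle-edge clutter raw votes grow linearly with radius, which biases
  every windowed search toward its largest admissible radius. Normalized
  scores measure arc coverage and leave ideal-circle peaks in place.
* The lumen is re-searched at every level anchored to the tracked media
  circle (center within $D_c$, radius in $[r_{\min}, r_{\text{media}}/2]$,
  votes only). The thin dark lumen annulus sits right next to the catheter
  and its ring-down; on the coarsest bands those structures alias together,
  so a lumen hypothesis chained level-to-level can lock onto an artifact it
  can never escape, while the media ring tracks reliably and constrains the
  lumen search region at every scale.

Search windows shrink geometrically with resolution (half-width
$\max(6, D_c/2s)$ at scale $1/s$) with a Gaussian prior of the same width:
the coarser level localizes the center to a couple of its pixels, and the
prior makes distant hypotheses pay for their distance without locking in a
one-cell coarse error. Failures at any level fall back to the rescaled
previous circle with a warning; initialization never aborts the pipeline.

### Despeckling by anisotropic diffusion of directional subbands

Each directional subband is filtered by Perona–Malik diffusion,
$\partial I/\partial t = \mathrm{div}[c(\|\nabla I\|)\nabla I]$ with
$c(s) = \exp(-(s/g)^2)$, explicit four-neighbour scheme, zero-flux
boundaries (the band mean is conserved exactly). The gradient threshold $g$
is adaptive per subband, 1.5 times the median absolute gradient: fine and
coarse subbands differ in dynamic range by an order of magnitude, and the
median gradient tracks each band's speckle floor while true edges sit far
above it. Defaults are 10 iterations at $\Delta t = 0.2$ (the explicit
scheme is stable for $\Delta t \le 0.25$). The filtered subbands are pooled
per scale and the pyramid is collapsed with the *untouched* low-pass band,
giving the despeckled image $I'$. With zero iterations the whole operator
is the identity, which pins the pooling convention.

An increasing conduction variant $\exp(1 + (s/g)^2)$ is available behind
`nonstandard_conduction = TRUE`; it anti-diffuses (sharpens) and is included
for study, not for use.

### Level sets without reinitialization

Both borders evolve as independent level-set fields $\phi$ under

$$\frac{\partial\phi}{\partial t} =
  \mu\left[\Delta\phi - \mathrm{div}\!\left(\frac{\nabla\phi}{|\nabla\phi|}\right)\right]
  + \lambda\,\delta_\alpha(\phi)\,\mathrm{div}\!\left(g\frac{\nabla\phi}{|\nabla\phi|}\right)
  + \nu\, g\,\delta_\alpha(\phi),$$

where $g = 1/(1+|\nabla(G_\sigma * I')|^2)$ is the edge indicator. The
$\mu$ term penalizes deviation of $\phi$ from a signed distance function, so
no reinitialization is ever performed and the binary start
$\phi_0 = \mp C$ (from the rasterized initial circles) is admissible. The
discretization is part of the package contract: 5-point Laplacian, central
differences everywhere, $|\nabla\phi|$ floored at $10^{-10}$, replicated
borders, cosine-regularized $\delta_\alpha$.

Parameter defaults, with units and reasons:

| parameter | default | role |
|---|---|---|
| $\mu$ | 0.04 | distance-penalty weight; $\mu\,\Delta t = 0.2 < 0.25$ keeps the explicit scheme stable |
| $\lambda$ | 7.0 | $g$-weighted length; high enough that a finger poked through the guide-wire shadow gap costs more than the area it gains (see below) |
| $\nu$ | $\mp 1.5$ | balloon: $-1.5$ expands the lumen field, $+1.5$ shrinks the media field, matching the geometry of circle starts |
| $\alpha$ | 1.5 px | Dirac/Heaviside regularization half-width |
| $\sigma$ | 1.5 px | edge-indicator smoothing (checked against 1.0, which is worse on despeckled input) |
| $C$ | 4 | binary initialization magnitude |
| $\Delta t$ | 5 | time step |
| `max_iter` | 500 | driven-phase cap; `tol = 1e-3` over 5 consecutive iterations stops earlier when the whole field settles |
| `refine_iter` | 100 | balloon-free settling phase |

Two of these deserve their design story. First, $\lambda = 7$: inside the
guide-wire shadow the image is featureless, $g \approx 1$, and an expanding
lumen front can leak through the gap in the lumen edge and run along the
shadow walls; the leak is energetically favorable roughly when
$\nu \cdot (\text{gap width}) \cdot (\text{depth})$ beats
$\lambda \cdot 2 \cdot (\text{depth})$, and at the default geometry
$\lambda = 5$ sits on the wrong side of that balance while $\lambda = 7$
does not. Second, the settling phase: the driven front equilibrates where
the balloon pressure balances the geodesic attraction, which is
systematically 1–2 px past the floor of the $g$ valley; releasing the
balloon ($\nu = 0$) for 100 iterations lets the length term pull the
contour back onto the edge and removes that bias for both borders at once.

Because each balloon pushes in one direction only, the starts must sit on
the correct side of their boundaries: the pipeline inflates the fitted
media circle by 10% before evolution (the fitted circle underestimates the
boundary wherever the eccentric interface bulges outward, and a bulge
beyond the edge valley's 2–3 px capture basin would otherwise be
unreachable by a shrinking front), while the lumen circle is used as
fitted — its absolute eccentricity is small enough to stay within the
basin, and deflating it would park the start on the ring-down tail.

The intensity scale matters for $g$: the pipeline feeds the level set the
despeckled image scaled to 0–255 so that boundary gradients are $O(10)$ and
the default weights behave as they do on 8-bit images. Final contours are
extracted as the marching-squares zero isocontour (largest closed
component); if the lumen contour crosses the media contour, the crossing
vertices are clamped 2 px inside it with a warning.

The `traditional` baseline is this same level-set module with the same
initialization run on the raw image instead of $I'$; the measured
difference between the two runs isolates the contribution of the
contourlet-domain despeckling.

## The phantom simulator

`phantom_spec()` / `generate_phantom()` synthesize cross-sections in polar
coordinates: two quasi-circular interfaces (base radius plus 2nd/3rd
Fourier harmonics) separate three layers with mean echogenicities 0.08
(blood pool), 0.25 (media band), 0.55 (adventitia); each polar sample is
multiplied by unit-mean Rayleigh speckle, optionally correlated by a small
polar Gaussian kernel; a bright exponentially-decaying ring-down annulus
surrounds the catheter, and a guide-wire sector (default 0.35 rad wide)
attenuates everything beyond the catheter to 25% — the two artifacts form
one merged model. The polar image is scan-converted with bilinear
interpolation and clipped to [0, 1]. The exact synthesized interfaces are
returned as ground truth.

Geometry defaults are pinned by the initializer's defaults: with the circle
search limited to radii 15–40 px and the lumen radius capped at half the
media radius, the vessel must satisfy
$r_{\text{lumen}} \le r_{\text{media}}/2$ with both in range; the package
uses base radii 16 and 36 px on a 384-px frame. Harmonic amplitudes (10%
and 5% for the lumen, 7% and 3.5% for the media) give moderately eccentric
vessels, so a circle is a good start but not the answer — the evolution
stage has real work to do. Cohorts (`phantom_batch()`) jitter radii
(±2 px), lumen offset (±3 px), harmonic phases and the wire angle with
per-item seeds derived from the batch seed, so any cohort is reproducible
bitwise.

What the simulator does *not* model: RF-level physics, beam-width dependent
lateral blur, calcification shadows, pull-back motion, or blood speckle
texture differences between 20 and 40 MHz transducers. Passing tests on
these phantoms demonstrates correct mechanics and robustness to Rayleigh
speckle and the two modeled artifacts — not clinical-grade accuracy on
in-vivo frames.

```{r phantom}
ph <- generate_phantom(phantom_spec(seed = 7))
ph
```

## Error metrics

`md_rmd(detected, reference)` measures, for every detected vertex $p$, the
exact distance $D(p)$ to the reference polyline (segment-wise, closing edge
included) with foot point $q$; MD is the mean of $D(p)$ in pixels, and RMD
is the mean of $D(p)/d(q, O)$ in percent, where $O$ is the vertex centroid
of the reference. The comparison is deliberately one-directional
(detected against reference); a symmetric variant is available separately
as `mean_symmetric_distance()`. Two conventions are fixed here because
their definitions are otherwise ambiguous: $q$ is always the nearest point
on the *reference* contour, and $O$ is the reference's vertex centroid.

```{r metrics}
md_rmd(circle_contour(0, 0, 55, 720), circle_contour(0, 0, 50, 720))
```

## Numerical choices and degenerate inputs

* Mirror (whole-sample symmetric) extension everywhere in the filter banks;
  odd sizes are mirror-padded to the next multiple of $2^J$ and cropped on
  reconstruction.
* The accumulator uses integer centers and radii; votes are box-smoothed
  3×3×3 before peak picking, and non-max suppression half-widths shrink
  with band scale so concentric coarse circles are not merged.
* Constant images: Canny warns and returns an empty edge map; the
  accumulator refuses to vote on it; the lumen-center estimate falls back
  to the frame center with a low-confidence flag.
* `evolve_step` aborts with a diagnostic if the field goes non-finite;
  `segment` returns `converged = FALSE` rather than erroring when the
  update norm never settles below `tol`.
* All contours are counter-clockwise closed polygons in 0-based,
  pixel-centered coordinates (x right, y down).

## Problem sizes

Routine validation uses 192-px phantoms (same vessel scale, quarter the
area); headline accuracy figures use the default 384-px frames and a
20-phantom cohort, the cohort size the evaluation protocol prescribes.
One full-resolution segmentation takes a few seconds on one core; the
20-phantom, two-method benchmark takes a few minutes.

## Known limitations

* The lumen's advantage from despeckling is small on these phantoms: the
  blood pool is dark, multiplicative speckle there has small absolute
  amplitude, and the shared CHT initialization is already accurate, so the
  raw-image baseline is genuinely competitive on the lumen border (it is
  clearly worse on the media-adventitia border, where speckle is strong).
* A guide-wire shadow wider than ~0.5 rad can defeat the λ-based
  leak-proofing at the default balloon strength.
* The initializer assumes one vessel roughly centered on the catheter;
  bifurcations and grossly eccentric catheters are out of scope.
* DICOM input is not supported; convert frames to PNG/TIFF first.
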