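---
title: "Image-based analysis of phase-separating lipid bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based analysis of phase-separating lipid bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayerphase)
```

## The problem and the representation

Ternary lipid mixtures of a saturated phospholipid (DPPC), a doubly
unsaturated phospholipid (DUPC) and cholesterol undergo spinodal
decomposition in coarse-grained molecular dynamics simulations: the bilayer
demixes into a liquid-ordered (Lo) phase rich in DPPC and cholesterol and a
liquid-disordered (Ld) phase rich in DUPC. Quantifying that process —
domain sizes, interface lengths, inter-leaflet coupling, thickness
differences, where membrane-anchored proteins sit — is awkward in Cartesian
coordinates but straightforward once each leaflet is treated as a
two-dimensional image.

`bilayerphase` implements that image paradigm. Every lipid is reduced to
one marker point (the PO4 phosphate bead for phospholipids, the ROH
hydroxyl bead for cholesterol, the centre of mass for a protein); markers
are rasterized onto a grid of nominally 1 x 1 Angstrom pixels and convolved
with a periodic Gaussian to produce per-species density maps. All
downstream quantities are functions of those maps. Internally everything is
in Angstrom; GRO files (nm) are converted on read and write.

This package assumes an essentially flat bilayer: leaflets are assigned by
the side of the global phosphate midplane and the two-dimensional
projection is meaningful only while the membrane does not undulate
appreciably. Frames where more than 5% of markers fall within 5 Angstrom
of the midplane trigger a warning rather than silent nonsense.

## Parameters that matter

* **Pixel size** — fixed at (nominally) 1 Angstrom: the grid is
  `round(L)` pixels across, so pixels are exactly square for integer boxes
  and within half a percent otherwise. Fields from different frames are
  never resampled onto a common grid; all per-frame metrics are intensive.
* **Lipid kernel width** (`lipid_kernel_width()`) — the standard deviation
  of the species Gaussian, derived from the equal-area assumption: each of
  the `n` lipids of a leaflet of area `A` occupies a circle of area `A/n`,
  whose radius `sqrt(A/(n*pi))` is the kernel width. For 3000 lipids in a
  400 Angstrom box this gives 4.1 Angstrom. We interpret the published
  "width" as the standard deviation, the default meaning of the smoothing
  parameter in the standard image filters this workflow builds on.
* **Canny smoothing** — 2.0 Angstrom, applied to the binary mask before
  gradients are taken.
* **Protein footprint width** — 20 Angstrom, half the ~40 Angstrom
  centre-of-mass contact distance of two bound proteins. Footprints are
  unit-normalised; only phase fractions under the footprint are consumed,
  so normalisation cancels in the classification.
* **Classification threshold** — a protein belongs to a phase only when
  that phase holds strictly more than 80% of its footprint; exactly 80% is
  interfacial.
* **Domain area filter** (`min_area`, default 100 squared Angstrom) —
  suppresses small islands when averaging domain radii.

## Phase masks and their noise

The Lo/Ld mask is the literal rule: `DUPC - DPPC > mean(DUPC - DPPC)`,
recomputed per leaflet per frame, ties to Lo. With ~53 squared Angstrom
per lipid and a 4.1 Angstrom kernel, each pixel's density averages only a
handful of markers, so the mask of any single frame is speckled with small
islands; this is intrinsic to the estimator, not an artefact of the
implementation (the per-pixel signal-to-noise of the difference field is
of order one). Two consequences matter:

* the mismatch fraction of two *independent* leaflets sits near 50%
  because each leaflet's mask is essentially a fair coin per correlation
  area — which is exactly the expected initial state of a demixing
  trajectory; and
* raw interface lengths include a large speckle contribution. For
  geometry-recovery work the package provides `clean_mask()`, an area
  opening that reassigns sub-threshold islands of either phase to their
  surroundings; with a 1000 squared Angstrom threshold a planted straight
  stripe of true boundary length 800 Angstrom measures ~880-930 Angstrom
  (the residual excess is genuine boundary roughness), while the raw mask
  measures ~2400. Cleaning is off by default: the raw numbers are the
  method's own.

The mean threshold also behaves best near balanced compositions; when one
phase covers only a small area fraction the threshold shifts toward the
majority phase and over-segments it. The circular-domain analysis in
`analysis/02_phase_maps.R` shows this honestly.

## Interface detection and measurement

`detect_interface()` is a fully periodic Canny detector: wrapped Gaussian
smoothing, Sobel gradients via circular shifts, non-maximum suppression
with the gradient magnitude sampled by linear interpolation on the 3x3
ring (whole plateaus are kept, guarded against FFT round-off ties), then
relative hysteresis (0.1/0.2 of the maximum) with periodic 8-connected
label propagation, and finally a sequential topology-preserving thinning
to one-pixel chains. The thinning uses the full 8-simple-point test —
classical two-subiteration schemes cannot thin two-pixel diagonal bands or
diagonalise staircases, which is precisely where length estimates go wrong.

Two length estimators are exposed. The default `"chain"` estimator counts
axial adjacencies as 1 and diagonal adjacencies as sqrt(2) pixels: it is
exact for axis-aligned and 45-degree interfaces (800 and 1131 Angstrom for
one stripe across a 400 Angstrom box, straight and diagonal) and about +5%
for a 50 Angstrom circle. The bare pixel sum (`method = "pixel"`) — the
simplest array-sum estimator — is kept for comparability but is not the
default: on a one-pixel chain it undercounts every diagonal step by
sqrt(2), a -10% bias on circles that exceeds the accuracy the rest of the
machinery delivers.

Domains are labelled with periodic 8-connected components (4-connectivity
fragments diagonal necks). `mean_domain_radius()` averages equivalent
radii `sqrt(area/pi)` of Ld domains after the area filter; the Lo "sea"
in a droplet morphology is a single percolating background component whose
equivalent radius is not a domain size, so Lo domains are only included on
request (`phase = "Lo"` or `"both"`).

## Leaflet surfaces and thickness

Leaflet surfaces interpolate the scattered phosphate z-coordinates.
Markers are binned to their pixels (averaged if shared) and the remaining
pixels are filled by periodic biharmonic (thin-plate) spline inpainting:
the discrete surface minimises the integrated squared Laplacian subject to
the marker-pixel values, solved as one sparse symmetric positive-definite
system. We chose this over scattered-data cubic interpolation plus 3x3
tiling because it is natively periodic (no seam artefacts by
construction), passes exactly through marker pixels, and reproduces
constant and planar fields; its interior accuracy at lipid sampling
density is ~0.05 Angstrom RMS on smooth test surfaces. One caveat is
shared by *any* periodic interpolant: a field that is itself not
box-periodic (a tilted plane) must jump somewhere, and the jump localises
in a band of roughly one marker spacing at the seam.

Thickness is upper minus lower surface, phosphate-to-phosphate;
non-positive pixels are counted as unphysical and excluded from
statistics. Per-phase statistics are keyed by the match-map category
(both-Lo, both-Ld, mismatch) with 0.5 Angstrom histogram bins (the
published distributions state no binning; 0.5 Angstrom resolves the
9 Angstrom Lo-Ld gap comfortably), and category fractions are computed
over the included pixels so the identity
`global mean = sum(fraction * category mean)` holds to machine precision.

## The synthetic generator

No reference trajectories are available, so every stage is validated
against a generator whose defaults mirror the simulated system: a 400
Angstrom square periodic box, 3000 lipids per leaflet at the 5:3:2
DPPC:DUPC:CHOL composition (751:450:299 per 1500, scaled by largest
remainder), blue-noise marker placement with a 5 Angstrom minimum distance
(liquid-like disorder without lattice moire on the 1 Angstrom grid), a
41 Angstrom mixed-phase leaflet separation and 45/36 Angstrom Lo/Ld
separations, 1 Angstrom z jitter, and a 3 Angstrom mixed compositional
band at planted interfaces so rasterized steps are not unphysically sharp.
Mixed frames realise the composition counts exactly by random permutation;
striped and circular frames assign species by region (DUPC inside the Ld
geometry, DPPC:CHOL at 751:299 outside), so their global counts follow the
planted geometry's area rather than the nominal composition.

Coarsening series emulate `L(t) ~ t^alpha` with circular Ld domains of
radius `r(t) = r_end (t/t_end)^alpha` at fixed total Ld area (default
fraction 0.2), so the domain count falls as `round(A/(pi r^2))` and the
true interface length `2 pi n r` decreases while the radius grows —
radius and interface length move oppositely, as they must. Domains sit on
a randomly jittered lattice (guaranteed non-overlap) with 2% log-normal
per-domain radius noise. A stripe-count-based generator was considered and
rejected: integer stripe counts quantise the characteristic length too
coarsely to test exponent recovery at the 0.05 level.

What the generator does **not** emulate: lipid diffusion and correlated
dynamics between frames, thermal undulations, composition fluctuations
inside a phase, partial cholesterol partitioning (planted geometries put
all cholesterol in Lo), protein-induced boundary deformation. Passing
recovery tests therefore demonstrates the estimators' correctness on known
geometry at realistic marker density and noise — not that the biological
conclusions of any particular simulation are right.

## Numerical choices and degenerate inputs

* Convolutions are exact circular convolutions via FFT with wrapped
  Gaussian kernels (images summed to 6 sigma); kernels wider than half the
  box are refused.
* Rasterization uses half-open pixels; shared pixels count multiply so no
  marker is silently merged. Points outside `[0, L)` are contract
  violations — wrap first.
* A constant difference field yields an all-Lo mask (strict inequality); a
  uniform mask yields an empty edge map, and an empty edge map has length
  zero. `mean_domain_radius()` with no surviving domain is an explicit
  error, not NA (the pipeline converts it to NA per frame and says so).
* Markers exactly on the leaflet midplane go to the upper leaflet with a
  warning. Fewer than 16 markers cannot define a surface.
* All generators are deterministic given a seed; the dart thrower errors
  out above ~52% disc coverage rather than looping forever.

## Problem sizes

Tests and the acceptance checks run the full study geometry (400 Angstrom
box, 6000 lipids) for the density/mask/mismatch pipeline, and 150-200
Angstrom boxes at the same areal lipid density for the surface-solve-heavy
stages; the biharmonic solve is the most expensive step (a few seconds at
200 x 200, cached operator aside) and its accuracy is resolution-
independent at fixed marker density. Coarsening fits use 10 frames per
condition. The whole validation suite completes in about a minute on one
core.

## Known limitations

* Interface lengths on raw (uncleaned) masks are dominated by speckle for
  single frames; they are comparable across frames and conditions (the
  speckle floor is stationary) but are not geometry estimates unless
  islands are removed.
* The mean threshold is a global per-leaflet rule; strongly asymmetric
  phase fractions bias it.
* Leaflet assignment assumes a flat bilayer; curvature and undulation are
  out of scope.
* Domain radii through the noisy pipeline are biased when true radii
  approach the island-filter scale; interface-length series are the more
  robust kinetic observable at small domain sizes.
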