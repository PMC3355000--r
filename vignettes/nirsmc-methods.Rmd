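---
title: "Methods: voxelized time-resolved Monte Carlo for NIRS probe design"
author: "nirsmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxelized time-resolved Monte Carlo for NIRS probe design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Functional near-infrared spectroscopy (NIRS) measures backscattered light
between a source and detectors placed on the scalp. How much of the detected
signal actually sampled the cerebral cortex — rather than scalp, skull or
cerebrospinal fluid (CSF) — depends strongly on the source–detector
separation and on the individual head anatomy, in particular the
low-scattering CSF layer that "guides" light along the inside of the skull
and the CSF-filled cortical folds. `nirsmc` models this chain end to end:
it builds a five-layer voxel head model (scalp = 1, skull = 2, CSF = 3,
gray matter = 4, white matter = 5 on a 1 mm grid, by default
256 × 256 × 92 voxels covering the top 9.2 cm of the head), transports
photon packets through it with a time-resolved Monte Carlo kernel, and
reduces the detected packets to the quantities a probe designer needs:
intensity and layer-ratio curves versus separation, the surface/cortex
cross-point, and spatial sensitivity profiles (SSPs).

# The transport model

Each of the `N` packets is launched with unit weight at the source,
pointing inward. Propagation alternates two phases.

**Free path.** An optical-depth budget `-ln(xi)` is drawn and spent voxel
by voxel along the ray: a voxel with total interaction coefficient
`mu_t = mu_a + mu_s` and intersected length `s` consumes `mu_t * s`. The
marching uses exact axis-plane crossing distances with a 1e-9 mm nudge
across faces; labels are looked up by flooring the continuous position
(0-based voxels spanning half-open 1 mm intervals). Elapsed time grows by
`s * n / c` with `c = 0.299792458 mm/ps` and `n` the local refractive
index. Per-tissue partial path lengths and a visited-layer bit mask are
accumulated for every packet.

**Interaction.** Where the budget runs out the packet deposits
`dw = w * mu_a / mu_t` into the local voxel (the absorption volume) and
scatters: the deflection cosine is drawn from the Henyey–Greenstein phase
function by its closed-form inverse CDF with anisotropy `g = 0.92` for all
five tissues, the azimuth uniformly on `[0, 2 pi)`, and the direction is
rotated in the packet's local frame.

At a tissue–air face the unpolarized Fresnel reflectance is computed from
the face normal (axis-aligned, as in voxel Monte Carlo codes generally);
beyond the critical angle the packet reflects deterministically, otherwise
it reflects with probability `R` or exits carrying its full current weight
(binary survival — simpler detector statistics than partial-weight
splitting, and unbiased). Internal tissue boundaries are index-matched by
default (all tissues `n = 1.4`, air `n = 1`); configuring per-tissue
indices enables internal Fresnel/Snell events at mismatched faces.
Exiting packets are detected if they land inside a detector aperture; all
others are ledgered as undetected exits.

**Termination.** Packets are gated at 1000 ps of flight time (the window
over which the photon-migration dynamics play out; a configurable
parameter) and low weights (< 1e-4) face Russian roulette with survival
probability 0.1. Every termination channel logs its residual weight, so the
run closes a conservation ledger:
`launched + roulette gain = deposited + exited + terminated`, exact to
1e-9 relative with roulette disabled (roulette gain accounts for the
unbiased weight boost of survivors).

## Scattering-coefficient convention

The bundled tissue table stores *reduced* scattering coefficients
`mu_s' = mu_s (1 - g)`. Two modes are provided, because combining a printed
`mu_s'` with an anisotropic phase function is ambiguous:

* `"reduced"` (default): `mu_s'` is used directly as the scattering rate
  while scattering remains Henyey–Greenstein with `g = 0.92` — the
  parameterization in which brain-tissue tables are usually printed.
* `"physical"`: the rate is rescaled to `mu_s = mu_s' / (1 - g)`, the
  similarity-consistent reading.

The choice changes absolute path statistics but has modest impact on the
weight-fraction (ratio) outputs. Validation against diffusion theory uses
`"physical"` with `g = 0`, where the two coincide.

## Numerical choices

* **Zero-scattering voxels.** A voxel with `mu_s = 0` supports no
  scattering events, so no interactions are sampled there; absorption is
  applied continuously as `exp(-mu_a s)` along the traversed segment. This
  makes the ballistic Beer–Lambert limit exact instead of holding only in
  expectation; wherever `mu_s > 0` the standard packet scheme applies.
* **Grid boundary.** The default head phantom touches the bottom grid face
  (a top-of-head acquisition), and slabs are laterally open; by default a
  packet crossing the grid box is terminated to the ledger
  (`boundary = "open"`). `boundary = "strict"` instead raises an error, the
  behavior appropriate for fully air-padded volumes where a box escape
  indicates a malformed model.
* **Reproducibility.** Every packet owns an RNG stream (splitmix64)
  derived from the master seed and the packet index, so results are
  bit-identical regardless of batching, and a run is reproducible from its
  manifest alone.
* **Time binning.** Fluence can be accumulated per (voxel, time bin) for
  migration snapshots; 1 ps bins to 1000 ps by default. This is memory
  heavy and off unless requested.

# Detectors and probe geometry

Detectors are disks of configurable radius flush with the surface,
accepting all exit angles (the field rarely reports apertures; 1.5 mm
radius is the op-level default). On the bundled folded-head phantom the
package uses 5 mm radius apertures: at the scaled-down packet count of
10^6 this yields hundreds to thousands of detections per separation out to
~5 cm, and the layer-*ratio* curves the design targets are insensitive to
the aperture area. For laterally homogeneous slabs, annular (ring)
detectors centered on the source are available — the standard trick for
collecting full-azimuth statistics when comparing against diffusion
theory.

`buildProbeLayout()` places the source on the anterior surface 6 cm below
the head top and walks the surface contour to set detectors at 1–10 cm
arc-length separations, either around the axial cross-section
("transverse") or over the vertex in the midsagittal plane ("sagittal").

# The head models

**Layered slab**: planar scalp/skull/CSF/gray layers over a white-matter
half-space; used for oracle comparisons (Beer–Lambert, diffusion theory)
and for the layer-counting identities (layer voxels = thickness × face
area, exactly).

**Folded head**: nested ellipsoidal shells (default semi-axes 80 × 100 ×
92 mm; scalp 3 mm, skull 7 mm, CSF 2 mm, gray matter 4 mm over a
white-matter core) with CSF-filled sulcus grooves (default eight, 2 mm
wide, 10 mm deep) and a midline interhemispheric fissure (3 mm wide, 30 mm
deep). A CSF-expansion factor ≥ 1 thickens the CSF layer, emulating
atrophy. The construction is deterministic and watertight. These defaults
are the study conditions used by the acceptance checks; they reproduce the
qualitative behavior the method is built to expose — the cortical signal
fraction overtaking the superficial fraction near 3 cm separation, and
deeper light penetration with expanded CSF.

**Synthetic T1 volumes** for the segmentation pipeline draw each voxel
from a Gaussian per tissue class with T1-like means (air 5, scalp 90,
skull 30, CSF 15, gray 60, white 85 arbitrary units); an "SNR 10" image
uses per-class standard deviations of one tenth of the class mean. The
generator emulates contrast and additive noise only — no bias field, no
partial-volume averaging, no Rician noise floor — so segmentation scores on
it bound what field MRI data would give from above.

# The segmentation pipeline

Stage 1 delineates the shell. Per slice, a variational level set with a
distance-regularization penalty (so no re-initialization is needed), an
edge-weighted length term and an area term shrinks from the image border
onto the scalp outline; the edge indicator is
`g = 1 / (1 + |grad(G_sigma * I)|^2)`. A second level set expands from a
seed disk at the slice centroid up to the inner skull boundary. Because
intermediate cortical edges would trap an expanding front on the raw
image, the inner evolution runs on the *skull-membership posterior* from a
K = 4 mixture of Gaussians fitted to head intensities — flat inside the
cranium, bright on the skull ring — scaled by 100 so its boundaries
register in the edge indicator like ordinary image edges. After each
evolution the contour is snapped within a ±2 px band by a midpoint
intensity threshold, which removes the sub-pixel bias of the discretized
flow. Region growing (seed-ordered flood fill) labels the connected scalp
(1) and skull (2) components of the shell, split at the mixture midpoint
threshold.

Stage 2 fits a K = 3 mixture of Gaussians to the intracranial intensities
(EM, monotone log-likelihood, variance floor with flagging) and assigns
CSF/gray/white by maximum posterior probability, components mapped to
tissues by ascending mean (T1 ordering, configurable). Ties break toward
the lower tissue code.

Parameter defaults (`mu = 0.2`, `lambda = 5`, `nu = ±1.5`, `tau = 1`,
`epsilon = 1.5` px, `sigma = 1.5` px, ≤ 600 iterations, stability
constraint `tau mu < 0.25`) follow the standard practice for this
formulation. Two defaults matter and were found empirically on phantoms:
the expanding seed disk must be larger than about `lambda / |nu|` pixels
or the curvature force collapses it, and the expansion weight must not
overpower the length term (`|nu| = 1.5` with `lambda = 5` stops cleanly at
the inner skull edge, `|nu| = 3` leaks through).

# Analysis definitions

* **Intensity curve**: total detected weight per detector versus
  separation.
* **Layer-ratio curves**: detected weight partitioned by the *deepest
  layer visited* — "surface" (scalp/skull only), "csf" (reached CSF, not
  the brain), "cortex" (reached gray or white matter). The partition makes
  the three curves sum to one at every separation and makes "signal from
  the cortex" well defined. A per-layer partial-pathlength-fraction
  variant is available (`method = "pathlength"`).
* **Cross-point**: the separation where the cortex fraction overtakes the
  surface fraction, linearly interpolated between grid points; multiple
  crossings report the smallest and a flag, no crossing reports a status.
* **SSP**: per-voxel path length × exit weight summed over the detected
  photons of one detector; additive over disjoint photon sets and
  normalizable to unit sum.

# Problem sizes used in the checks

The bundled test suite and the acceptance script run scaled-down problem
sizes chosen to keep the full pipeline exercised with tight statistics:
10^6 packets on the full 256 × 256 × 92 folded head for the layer-ratio
behavior (a few tens of seconds), 2 × 10^5 packets on a 12 × 12 × 6 cm
homogeneous slab for the diffusion-theory comparison, 10^6 draws for
sampler moments, and a 96 × 96 × 6 phantom for segmentation scoring. At
these sizes the surface/cortex crossing sits near 2.8 cm with the cortex
fraction a few points above 50% at the next grid separation, stable to
about ±1% across seeds.

# Known limitations

* Voxel surfaces have axis-aligned normals; specular behavior at oblique
  smooth surfaces is approximated by the staircase geometry.
* The deepest-layer partition attributes a packet wholly to its deepest
  excursion; packets that merely graze the cortex count as cortical
  signal. The pathlength variant softens this but changes the sum-to-one
  semantics from "packets" to "path shares".
* The segmentation pipeline assumes T1-like ordering and one head per
  image; it has no bias-field model and no multi-contrast support.
* With the time gate at 1000 ps, late diffuse photons at separations
  beyond ~6 cm are suppressed; intensity curves there reflect gated
  detection.
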