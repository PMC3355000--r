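# nirsmc

Time-resolved Monte Carlo simulation of near-infrared light transport in
five-layer voxel head models, for patient-oriented NIRS probe design.

Functional near-infrared spectroscopy (NIRS) detects backscattered light
between a source and detectors on the scalp. The design question is where
to put the detectors: at short source–detector separations most of the
detected light never leaves the scalp and skull, while at long separations
almost nothing comes back. `nirsmc` answers this quantitatively for a given
head model by simulating photon-packet transport through a voxelized
five-layer head (scalp, skull, cerebrospinal fluid, gray matter, white
matter; 1 mm isotropic voxels, 256 × 256 × 92 by default) and reporting,
per separation, the detected intensity and the fraction of detected weight
that actually sampled each layer group.

## The model

Photon packets of weight *w* alternate exponential free paths and
scattering interactions. A free path spends an optical-depth budget
−ln ξ voxel by voxel (Σᵢ μ_t,i sᵢ = −ln ξ across layers); at the
interaction the packet deposits Δw = w μₐ/μ_t locally and deflects with a
Henyey–Greenstein polar angle,

  p(cos θ) = (1 − g²) / [4π (1 + g² − 2g cos θ)^{3/2}],  g = 0.92,

and a uniform azimuth. Snell's law and the unpolarized Fresnel reflectance
govern the air surface; flight time accumulates as s·n/c, packets are gated
at 1000 ps, and Russian roulette terminates low weights unbiasedly. Every
detected packet records its per-layer partial path lengths and a
visited-layer mask, from which the package derives intensity–separation
curves, deepest-layer-visited ratio curves, the surface/cortex cross-point,
and spatial sensitivity profiles ("banana" maps). Tissue optical properties
at 690/780/830/800 nm are bundled (in mm⁻¹) and overridable.

Head models come from two sources:

* **Phantoms** — a layered slab, and a folded head of nested ellipsoidal
  shells with CSF-filled sulci and an interhemispheric fissure
  (`makeFoldedHeadPhantom()`), with a CSF-expansion factor to emulate
  atrophy.
* **Segmentation** — `segmentFiveLayers()` turns a T1-like volume into the
  five-layer model using variational level sets (distance-regularized, no
  re-initialization) for the scalp and inner-skull contours, seeded region
  growing for scalp/skull labeling, and a mixture-of-Gaussians maximum
  posterior classification for CSF/gray/white.

The transport kernel is C++ (Rcpp); volumes read and write as NIfTI
(`RNifti`) or raw + YAML sidecar.

## Worked example

```r
library(nirsmc)

lv  <- makeFoldedHeadPhantom(foldedHeadSpec())        # 256 x 256 x 92, 1 mm
lay <- buildProbeLayout(lv, separationsCm = 1:10, detRadiusMm = 5)
cfg <- simulationConfig(lv, lay, nPhotons = 1e5, seed = 1, wavelength = 800)
res <- runSimulation(cfg)
res
#> McResult: 100000 photons at 800 nm, 5734 detected
#>   ledger: deposited 6.046e+04, exited 3.7e+04, terminated 2539 (balance 3.95e-08)

head(intensityVsSeparation(res)[c("separation_cm", "intensity", "n")], 5)
#>   separation_cm  intensity    n
#> 1             1 1975.31961 3369
#> 2             2  525.20477 1313
#> 3             3  159.80792  559
#> 4             4   50.60068  248
#> 5             5   19.81472  130

cp <- crossPoint(res)
subset(cp$curves, separation_cm %in% 2:4,
       c(separation_cm, group, fraction))
#>    separation_cm   group   fraction
#> 2              2 surface 0.65384971
#> 12             2     csf 0.03478226
#> 22             2  cortex 0.31136803
#> 3              3 surface 0.42719195
#> 13             3     csf 0.07089709
#> 23             3  cortex 0.50191096
#> 4              4 surface 0.22593934
#> 14             4     csf 0.08514094
#> 24             4  cortex 0.68891972

cp$cross$separation_cm
#> [1] 2.820904
```

Reading the output: detected intensity falls steeply with separation (the
ledger confirms weight conservation to ~4e-8 here, with roulette gain
accounted). At 2 cm two thirds of the detected weight never left the
scalp/skull; by 4 cm two thirds of it reached the cortex. The surface and
cortex curves cross at ≈ 2.8 cm on this phantom — separations just beyond
the cross-point are where a majority-cortical signal meets a still-usable
intensity, which is the probe-design sweet spot.

Multi-wavelength runs (`runMultiwavelength(cfg, c(690, 780, 830))`), the
time-binned fluence (photon-migration snapshots), and spatial sensitivity
profiles (`sspDetectors =` in `simulationConfig()`) follow the same
pattern. A command-line wrapper with `phantom | segment | simulate |
analyze | pipeline` subcommands and a YAML config lives at
`inst/cli/nirsmc.R`; every run writes a JSON manifest sufficient to
reproduce it bit for bit.

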