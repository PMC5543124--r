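---
title: "Methods: segmenting, orienting and simulating the cardiac conduction system"
author: "conductionscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting, orienting and simulating the cardiac conduction system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures the package implements,
the parameters that matter with their defaults and units, what the
synthetic phantoms do and do not emulate, and the numerical choices made
where the design was genuinely open. All distances are in millimetres,
potentials in mV, times in ms, and diffusivities in mm²/ms; voxel indices
are 1-based and world coordinates are voxel-centre positions.

## Attenuation-band segmentation

Iodine-enhanced micro-CT separates soft tissues by differential
attenuation. In decreasing intensity: fat, working myocardium, paranodal
tissue, nodal tissue, connective tissue. The package represents this as
half-open intensity intervals `[lo, hi)` (`attenuation_bands`), assigned
per voxel with no spatial regularization (`classify_tissues`); a value
exactly at a boundary belongs to the upper band.

Three band estimators are provided. `percentile` cuts at fixed quantiles.
`kmeans_1d` is deterministic Lloyd iteration from range-spread centres;
it is faithful to its name, but on real volumes the background dominates
the voxel count and the k-means/multi-Otsu objective then prefers
*splitting the background mode* over separating small tissue classes —
a structural property of the objective, not an implementation detail.
`density_valley` (the default) finds the `n` modes of a kernel density
estimate, growing the bandwidth out of the ripple regime until exactly
`n` modes remain, and cuts at the density minima between them; this is
insensitive to class imbalance but still cannot resolve a class whose
voxel mass is a fraction of a percent (the paranodal projections are
~0.1% of the phantom: their density bump is buried under the myocardium
tail). Phantom workflows therefore use *calibrated* bands — midpoints
between the known class means (`phantom_bands`) — which is the
reproducible analogue of an operator thresholding against known
attenuation anchors, exactly as interactive segmentation tools are used
in practice.

Structure extraction follows the segmentation logic used on such data:

* **Sinus-node body**: seeded region growing (`region_grow`) in the node
  band — the maximal connected in-band component containing the seed.
  Connectivity defaults to 26-neighbour, matching interactive
  region-growing tools; the result is invariant to seed choice within a
  component.
* **Paranodal area**: connected components of the intermediate band lying
  within one voxel (26-connectivity) of the node body or the working
  myocardium — the "projections and islands". Components smaller than
  `min_component_voxels` (default 10, about half the volume of the
  smallest plausible projection) are discarded as noise speckle.
* **Conduction axis and Purkinje network**: region growing in the node
  band restricted to corridor masks. Corridors stand in for manual,
  landmark-guided semi-automatic segmentation; the phantom supplies them
  as dilations of the true structures. A decoy blob of node-band
  intensity in the ventricular wall verifies that growth does not escape
  the corridor.
* Labels are mutually exclusive with precedence node > paranodal > axis >
  purkinje > myocardium.

A pure intensity-band criterion is used for growing (no gradient
stopping); tolerances of interactive tools are not reproduced.

## Fiber orientation from the structure tensor

For image intensity $I$, the structure tensor is
$J = G_{\sigma_t} * (\nabla_{\sigma_g} I \otimes \nabla_{\sigma_g} I)$:
smooth at the gradient scale $\sigma_g$, differentiate by central
differences, form the six products, and average with a Gaussian at the
tensor scale $\sigma_t$. Gradients of an elongated texture are
perpendicular to it, so the fiber axis is the eigenvector of the
*smallest* eigenvalue of $J$ (closed over a sign flip; directions are
canonicalised with nonnegative z-component). Coherence is the
Westin-style linear measure $(\lambda_2-\lambda_3)/(\lambda_1+\lambda_2+\lambda_3)$
with eigenvalues sorted descending, clipped to $[0,1]$; voxels with
near-zero tensor trace are invalid, which also covers the eigenvalue-tie
case ($\lambda_2 \approx \lambda_3$ gives coherence ≈ 0 rather than an
arbitrary eigenvector choice being trusted). Defaults are
$\sigma_g = 1$ voxel pitch and $\sigma_t = 3$ pitches: at 28–73 µm pitch
this is near the myocyte-chain scale while still averaging several
texture grains.

**Helix angle.** Given a cardiac frame (long axis $\hat z$, centre), each
wall voxel gets a local frame: the transmural normal is the gradient of
the lightly smoothed distance transform of the wall mask — which works
for non-cylindrical shells — sign-disambiguated to point outward using
the radial direction from the long axis, with the radial direction
substituted outright where the transform is degenerate (the mid-wall
ridge, where the distance gradient vanishes). Circumferential is
$\hat c = \hat z \times \hat n$, longitudinal is $\hat z$ projected into
the tangent plane. The helix angle is the signed angle in $(-90°, 90°]$
between the fiber's tangent-plane projection and $\hat c$, positive
toward the longitudinal direction; fiber sign-ambiguity cancels in this
mapping. An absolute-angle variant (`absolute = TRUE`) folds the sign for
colour-map display; both are provided because published colour maps do
not always state which is shown. Angles are NA on the long axis, where
the fiber is orthogonal to the tangent plane, or where the orientation
field is invalid.

`helix_profile` reports the transmural profile: the mean angle in depth
bins (one bin per voxel of wall thickness), excluding bins at each
surface where the tensor window inevitably blends across the boundary.
The profile is the quantity the recovery tests assert (RMSE < 5° against
the linear ramp, excluding two boundary bins per side); per-voxel error
on the textured shell is noise-limited at roughly 5° RMSE by texture
granularity and is reported alongside.

## Morphometry

Length and width are operationalized as ranges of voxel-centre
coordinates projected onto the mask's principal-component axes, plus one
voxel pitch for the voxel footprint — the measurement protocol itself is
a package choice, since "length" and "width" of an irregular structure
are not otherwise defined. Minimal distances are Euclidean minima over
boundary-voxel centres (or landmark points), so they can differ from
true surface distances by up to one voxel diagonal; landmark references
(valve hinges are curves identified visually on renderings) enter as
point sets in configuration. Distances are surface-to-point, not
centroid-based.

## Monodomain electrophysiology

The transmembrane potential obeys
$\partial V/\partial t = \nabla\!\cdot\!(D \nabla V) - I_{ion}(V, s)$ on
the labelled voxel grid. The conductivity tensor is built per voxel as
$D = d_T I + (d_L - d_T)\, f f^{\mathsf T}$ from the fiber direction $f$
— eigenvalues $d_L$ along the fiber and $d_T$ across it, so plane-wave
speed scales as $\sqrt{d}$ and the velocity anisotropy approaches
$\sqrt{d_L/d_T}$ in the continuum limit. Where no fiber is defined the
isotropic fallback $\bar d I$ is used. Labels without conductivity
parameters insulate (connective tissue, fat, background) — monodomain
rather than bidomain, which is the standard choice at this scale.

The solver is explicit operator splitting: a conservative finite-volume
stencil for the diffusion term (face fluxes from averaged tensor
components, tangential gradients for the cross terms, no-flux at
non-conducting faces — total charge is conserved to round-off by
construction), then the reaction step with Rush–Larsen exponential
updates for gating variables and forward Euler for everything else.
The step must satisfy $dt \le h^2 / (2\,\mathrm{tr}(D)_{max})$; the
default is 0.9 times that limit, capped by the cell model's documented
stability step. Activation times are detected online as the first upward
crossing of the threshold (default −40 mV), linearly interpolated within
the step; voxels that never cross carry the NA sentinel.

**Cell models.** Three models share one surface: the ten Tusscher 2004
epicardial human ventricular model, the Courtemanche 1998 human atrial
model, and the Mitchell–Schaeffer two-variable model (mapped to mV with
rest at −80 and ~100 mV amplitude) for fast tissue runs. The stored
resting states are 30 s quiescent steady states settled with a stiff
solver, so rest is a fixed point of the update to well below
0.01 mV/s drift; published initial-condition tables are rounded and
settle by a few tenths of a mV. The same `calc()` equations drive both
the package's explicit stepper and a plain ODE right-hand side
(`ionic_rhs`) that an independent integrator (`deSolve::lsoda`) can
consume — the validation route for resting potentials and
action-potential return. The epicardial 2004 ten Tusscher variant is the
documented default ventricular cell; which variant/subtype the original
modelling studies used is not recoverable, so this is a package choice.
Stimuli are currents in model units (negative = depolarising), applied
to spherical sites or explicit voxel sets.

**Default conductivities** (configuration, not measurements): working
myocardium $d_L = 0.1$, $d_T = 0.025$ (CV ≈ 0.33 mm/ms longitudinal with
the two-variable model, 2:1 anisotropy), Purkinje $(0.9, 0.1)$ (≈3×
faster), node and compact axis $(0.004, 0.004)$ (≈5× slower, giving the
atrioventricular delay), paranodal intermediate $(0.025, 0.01)$.

**The virtual heart** (`run_virtual_heart`) stimulates the centre of the
node body for 2 ms and checks the physiological ordering on the phantom's
ground-truth regions: node first; all atrial voxels before any
ventricular voxel; Purkinje-coupled endocardial voxels before the
mid-wall voxel on the same transmural line (pairs built by projecting
junction voxels to mid-depth along the ellipsoidal radius). Failures are
reported in the returned ordering report, never silently passed. The
default cell model is Mitchell–Schaeffer in every region — the full
ionic models are supported per region via `model_assignment` but cost
roughly two orders of magnitude more at these grid sizes, so they are
validated at single-cell and small-tissue level instead. One genuinely
physical subtlety: *increasing* Purkinje $d_L$ increases the source–sink
mismatch where the slow axis meets the fast network, delaying ventricular
onset even as it shortens the spread of ventricular activation; the
package's contrast test therefore asserts the activation *duration*
(last minus first ventricular activation) shrinks when Purkinje $d_L$
doubles.

## Synthetic phantoms

`generate_phantom` builds a two-chamber heart at 250 µm pitch on a
44×44×72 grid (geometry proportional to the grid, so smaller grids give
similar, faster phantoms): a spherical atrial shell with an epicardial
fat cap; an ellipsoidal sinus node in the intercaval-like wall position
with three paranodal projections walking along the wall mid-surface; an
insulating connective disc; a truncated-ellipsoid ventricular shell with
a linear transmural helix (+60° endo to −60° epi); a slow conduction
axis crossing the insulation as the only atrio-ventricular pathway; a
binary-branching Purkinje tree on the endocardial surface with a
free-running root chord; and an off-corridor decoy blob at node-band
intensity. Intensities are class means (fat 200, myocardium 160,
paranodal 130, node 100, connective 70, background 20, arbitrary units;
the conduction structures share the node band, mirroring their shared
low attenuation) plus independent per-voxel Gaussian noise (sd 7, so the
smallest band gap of 30 is >4σ and the Gaussian-tail accuracy bound
Φ(g/2σ) − 0.02 is meaningful). The noise model is additive and
uncorrelated — no scanner characterization exists to emulate, and recovery
tests only need a calibrated difficulty. Label geometry never depends on
the noise parameters, and generation is bit-reproducible given the seed.

The *block* phantom's intensities carry **no oriented texture** — tissue
blocks are flat plus noise — so orientation recovery is validated on the
dedicated textured phantoms: `generate_fiber_test_volume` (rod lattices
or cross-gratings, constant along a known axis) and
`generate_shell_phantom`, a cylindrical shell whose texture is a dense
set of short rods drawn along the local helical fiber direction —
emulating densely packed, iodine-contrasted myocyte chains. Shell
defaults put 30 voxels across the wall (real micro-CT resolves hundreds;
an early, sparser texture could not support the steep 4°-per-voxel ramp
at any tensor scale, which is a sampling statement about texture, not a
tuning knob). What the phantoms do *not* emulate: CT physics (beam
hardening, scatter, reconstruction artifacts), anatomical realism
(trabeculation, septum, real node microstructure), spatially correlated
noise, or partial-volume mixtures — so passing tests demonstrate the
correctness and calibration of the algorithms, not their performance on
scanner data.

## Pipeline and reproducibility

`run_pipeline` chains phantom → segmentation → orientation → morphometry
→ simulation from a validated config (unknown keys are errors naming the
key), writes artifacts in open formats (uncompressed NIfTI, CSV, JSON)
and a manifest with parameters, stage timings and MD5 checksums. One
global seed fans out to stage seeds by fixed offsets; identical configs
reproduce identical checksums. `pipeline_report` renders a mid-slice
label map, the helix colour map and the isochrone map with the
morphometry and ordering tables. In phantom mode the helix map derives
from the structure tensor of the flat block phantom and is therefore
mostly noise by design (see above); the shell phantom is the
orientation-recovery demonstration.

Problem sizes used by the test-suite and the acceptance script — 64³
orientation volumes, a 128×128×40 shell, the 44×44×72 default heart and
a 36×36×56 reduced heart for paired contrasts, 200/1000-voxel cables —
were chosen to keep every quantity measurably converged at desk scale.

## I/O conventions and limitations

NIfTI (`.nii`/`.nii.gz`) is the metadata-carrying format (pitch in the
header; any numeric type round-trips). TIFF stacks are 16-bit unsigned —
the native depth of micro-CT reconstructions — and carry no voxel size,
so reading TIFF requires an explicit pitch. Anisotropic NIfTI input is
rejected unless resampling to isotropic is requested. Intensities are
never rescaled on read: the attenuation ordering is relative. Known
limitations: no DICOM; voxel-centre (not sub-voxel) morphometry; the
monodomain solver is explicit (no implicit diffusion), so very high
conductivities force small steps; Purkinje–myocardial coupling is plain
voxel adjacency with no discrete junction resistance; and the sinus node
is stimulated, not self-oscillating — no pacemaker cell model is
included.
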