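---
title: "Measuring contact angles of sessile biomolecular condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring contact angles of sessile biomolecular condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensateADSA)
```

## The measurement problem

Biomolecular condensates — protein-rich liquid droplets formed by
intracellular phase separation — wet or dry the surfaces they sediment
onto, and the contact angle $\theta$ of a sessile condensate quantifies
that interaction. For drops a few to a few tens of micrometres across,
$\theta$ can be measured by axisymmetric drop-shape analysis (ADSA) of
three-dimensional confocal stacks: the drop's axisymmetric profile is
extracted from the image and the Young–Laplace equation is fitted to it,
interpolating the image below pixel resolution at the contact line.

Two optical aberrations complicate this. Imaging an aqueous sample
through a high-NA oil-immersion objective shifts the focal plane, so
recorded z positions are stretched relative to true sample depth; and as
drops shrink toward the size of the point-spread function (PSF), their
apparent shape is increasingly that of the PSF, which is elongated
axially. This package implements the full analysis — synthetic stack
generation, segmentation, Young–Laplace fitting with an axial rescale
correction and quality/size filters — together with simulations of both
aberrations (a refraction ray tracer and a PSF convolution engine) that
justify the corrections, and Flory–Huggins binodal fitting of
cloud-point data to relate wetting to the degree of phase separation.

## The Young–Laplace model

A sessile drop with full rotational symmetry, in mechanical equilibrium
between Laplace and hydrostatic pressure, satisfies the arc-length
(Bashforth–Adams) form of the Young–Laplace equation. With $s$ the
distance along the surface from the apex, $\psi$ the local inclination
from the horizontal, $r$ the radial coordinate and $h$ the depth below
the apex:

$$\frac{d\psi}{ds} = \frac{2}{R_0} + \frac{h}{\ell_c^2}
  - \frac{\sin\psi}{r}, \qquad
  \frac{dr}{ds} = \cos\psi, \qquad
  \frac{dh}{ds} = \sin\psi,$$

where $R_0$ is the apex radius of curvature and $\ell_c$ the capillary
length. At the apex $\sin\psi / r \to 1/R_0$, which regularizes the
singularity. `integrate_profile()` integrates this system with a
fixed-step classical Runge–Kutta scheme (step at most `smax / 2000`; the
mesh-convergence test shows endpoint changes $< 10^{-6}$ µm under step
halving). In the limit $\ell_c \to \infty$ the solution is a spherical
cap, the reference shape used throughout the optical simulations.

### Fitting

`fit_profile()` fits the three-parameter family $(R_0, \ell_c, z_0)$,
where $z_0$ translates the theoretical profile vertically (in the
apex-origin convention used internally $z_0$ is the lab-frame apex
height, and that is how it is initialized). The objective is the mean
squared distance from each of the $N$ observed profile points to the
nearest of 1000 theoretical trial points evenly spaced in arc length
from 0 to $s_{\max}$:

$$\lambda(R_0, \ell_c, z_0, s_{\max}) = \frac{1}{N} \sum_{i=1}^{N}
  \left[(R_i - r_i)^2 + (Z_i - z_i)^2\right].$$

During optimization $s_{\max}$ is held at 1.2 times the smoothed
profile length (7-point centred moving average of the radii, windows
clipped at the ends, segments summed for $i = 4 \ldots N-1$). After
convergence the theoretical profile is re-integrated until it crosses
the substrate plane $z = 0$, $s_{\max}$ is redefined at the crossing,
and $\theta = |\psi(s_{\max})|$; the absolute value fixes the sign
convention so that a hemisphere reports 90°.

Numerical choices, each of which the test suite exercises:

* **Optimizer.** Nelder–Mead with relative tolerance $10^{-9}$ on
  $\lambda$, restarted from its own solution up to four times. A single
  pass at looser tolerance leaves the simplex collapsed partway along
  the curved valley that couples $R_0$, $\ell_c$ and $z_0$, with
  residual $\theta$ errors above 2° on large drops in the strongest
  gravity regime; the restarts reduce the noiseless recovery error
  below 0.12° across the whole design sweep ($\theta \in
  [70°, 130°]$, contact radii 12–35 µm, $\ell_c \in \{200, 1000\}$ µm).
* **$\ell_c$ parametrization.** $\ell_c$ is fitted in log space above a
  lower bound (default: twice the profile extent). Sessile condensates
  sit far below their capillary length, and without the bound the fit
  can buy a marginally lower $\lambda$ on noisy small drops by bending
  the profile with drop-scale gravity, biasing $\theta$ by several
  degrees. The bound is a config parameter (`lc_min`), not a hard-coded
  assumption.
* **$R_0$ initialization.** An algebraic (Kåsa) circle fit to the upper
  half of the profile, mirrored about the symmetry axis; if the fit
  quality gate fails, the optimization is restarted from 0.5× and 2×
  that radius and the best result kept.
* **Quality gate.** Results with $\lambda N / s_{\max} > 0.5$ µm are
  rejected as poorly fit (this grouping of the three symbols is the one
  with units of length), and results with contact radius below 10 µm
  are rejected as PSF-dominated. `quality_filter()` records the reason
  for every rejection.

## Synthetic confocal stacks

`voxelize()` renders the solid of revolution of a profile into a
two-channel stack: uniform interior fluorescence over background, and a
bright one-voxel reflection plane marking the substrate. Default voxel
spacing is 0.24 × 0.24 × 0.42 µm, typical of a 63×/1.4 oil-immersion
confocal stack; default intensities are 100 (interior) over 5
(background) with Gaussian noise of width 5 available via
`add_noise()`, which gives a cleanly bimodal histogram for direct Otsu
binarization. Membership is decided at voxel centres with no
antialiasing; the substrate plane is the bottom face of the base slice,
so slice centres sit at half-integer heights above it. The axial
aberration is *emulated* by `apply_axial_stretch()` (factor 1.2) and
*corrected* by `rescale_profile()` (factor 1/1.2); stretching a stack
and fitting with the correction recovers $\theta$ within 2°, while
omitting the correction leaves errors above 12° at $\theta = 120°$.

What the generator does not emulate: photobleaching, depth-dependent
intensity loss, dye partitioning (interior brightness is uniform), or
non-axisymmetric drops. Tests passing on these synthetic stacks
therefore validate the geometry and the pipeline logic, not robustness
to every real-world intensity artifact.

## Segmentation

`segment_stack()` follows the stack-to-profile protocol: slices below
the base plane (located by `find_base()` as the z index of maximum
xy-averaged reflection intensity, ties toward the lowest slice) are
discarded; the fluorescence channel is smoothed with a Gaussian filter
of voxel radius 2 ($\sigma$ = 1 voxel, truncated at 4$\sigma$,
edge-replicated padding so boundary slices are not darkened); a single
Otsu threshold is computed on the whole cropped volume; 26-connected
components are labelled; and components are kept only if they touch the
base and no other volume boundary. `extract_profile()` hole-fills each
xy slice, takes the equivalent-area disk radius $\sqrt{A/\pi}$,
augments it by the planar distance between the slice centroid and the
droplet's overall centroid axis (the absolute distance, as a mean
radius about the optimal symmetry axis), assigns z at slice centres,
and appends the apex point $(0, z_{\max})$ at the top of the highest
occupied slice. End-to-end, voxelized caps with contact radii of 12 µm
are recovered within one voxel everywhere and fitted within 2°.

## Simulating the optical aberrations

### Refraction ray tracer

`render_apparent_image()` builds the apparent confocal image of a
spherical cap by deterministic meridional ray tracing. For each nominal
focal position (stage coordinates, i.e. where rays would converge in
homogeneous immersion oil) a fan of rays uniform in pupil coordinate
spans the numerical aperture, refracts by Snell's law at the substrate
plane, and — for rays crossing the lateral cap surface — at the
spherical condensate–buffer interface. The ideal focus is replaced by
the cloud of pairwise ray crossings, and the recorded intensity is the
weighted fraction of crossings inside the fluorescent cap.

The intensity model is the package's own definition, fixed by requiring
it to reproduce two published, physically established consequences of
oil-into-water confocal imaging at NA 1.4: the apparent axial stretch
factor of ≈ 1.2, and its insensitivity to the condensate refractive
index (1.33 vs 1.41). Concretely:

* the planar refraction at the sample base is governed by the bulk
  aqueous medium for all rays (the condensate index enters only through
  the lateral cap surface);
* crossings are formed only between rays with the same refraction
  history — a hybrid crossing between a cap-refracted and an
  unrefracted ray is not a focus;
* each crossing is weighted by its Fresnel transmittance and by the
  square root of the local axial crossing concentration, tempering the
  dominance of the paraxial caustic cusp. This exponent is the one free
  knob of the model and was calibrated so that the fitted rescale
  factor over a $\theta \in \{90°, 110°, 120°, 130°\}$ panel is 1.2;
  the same calibration then reproduces, without further adjustment, the
  index-insensitivity (panels at condensate index 1.33 and 1.41 agree
  within 0.01), the exact identity factor of 1.000 for index-matched
  optics, the undistorted apparent contact radius at the base, and the
  monotone approach of the factor toward 1 as the buffer index
  approaches the oil index.

A fully literal geometric model — under-drop rays refracting directly
from oil into the condensate, and all pairwise crossings counted with
uniform weight — does *not* show the published index-insensitivity (it
yields 1.19 vs 1.32 for the two condensate indices), which is why the
published consequences, not ray-by-ray literalism, define this
component. `apparent_axial_scale()` scans candidate vertical shrink
factors (coarse grid 1.00–1.40 in steps of 0.02, refined to 0.005),
dividing apparent profile z by each candidate before fitting, and
returns the factor minimizing the summed $|\theta_{\rm fit} -
\theta_{\rm true}|$ over the panel.

### PSF blurring

`model_psf()` provides a separable anisotropic Gaussian PSF (defaults
$\sigma_{\rm lat}$ = 0.15 µm, $\sigma_{\rm ax}$ = 0.55 µm, axial FWHM
≈ 1.3 µm); `measure_psf_proxy()` emulates the bead-stack measurement
(detect spots, re-centre sub-voxel, average, subtract modal background,
normalize) and recovers a known generating Gaussian within 10% in both
widths. `convolve_with_psf()` performs zero-padded FFT convolution,
oracle-tested against a direct triple sum to $10^{-10}$.

`theta_vs_radius_study()` voxelizes caps of fixed true angle over a
radius panel, blurs them, and runs the full pipeline without the
minimum-radius filter. With the default PSF the fitted angle of a 120°
cap is within 0.03° of truth at a 26 µm contact radius (20× the axial
FWHM), rises monotonically as the radius shrinks, and exceeds the 2°
error band below ≈ 2 µm — the behaviour that motivates discarding
contact radii below 10 µm in real data, where the measured PSF (beads
imaged at depth) is considerably more diffuse than this clean Gaussian.
The default panel samples densely below 2 µm, where the distortion
rises well above the ≈ 0.5° voxel-quantization noise of the pipeline,
with sparse anchors at 5, 12 and 26 µm; at intermediate radii the PSF
effect is smaller than that quantization noise, so a dense panel there
would measure grid alignment, not optics.

## Flory–Huggins phase diagrams

Cloud-point data (volume fraction $\phi$, transition temperature
$T_p$) are fitted to Flory–Huggins theory with free energy per site

$$f(\phi) = \frac{\phi}{n}\ln\phi + (1-\phi)\ln(1-\phi)
  + \chi\,\phi(1-\phi), \qquad \chi(T) = A + B/T,$$

the minimal UCST-capable temperature dependence. `binodal_at_chi()`
solves the common-tangent conditions (equal exchange chemical potential
and equal osmotic pressure) with nested bracketed root finding, the
dilute branch parametrized logarithmically so deep quenches (dilute
compositions down to $10^{-250}$) remain solvable; solutions satisfy
both conditions to $10^{-8}$ and match a brute-force common-tangent
construction on a $10^5$-point grid to $10^{-4}$. Cloud points are
treated as binodal crossings (nucleation onset tracks the binodal, not
the spinodal). `fit_cloud_points()` exploits the fact that the binodal
value $\chi^*(\phi)$ is independent of $(A, B)$: it is computed once
per observation, a linear regression of $\chi^*$ on $1/T_p$ initializes
$(A, B)$, and the final least squares is on predicted vs observed
temperature. `delta_phi()` evaluates the binodal gap
$\Delta\phi = \phi_{\rm den} - \phi_{\rm dil}$ at a reference
temperature (default 295.15 K, the 22 °C of contact-angle
measurement); condensate water content is approximately
$1 - \Delta\phi$.

Generator defaults, chosen once as the package's standard study
conditions: chain length $n = 236$ sites (the residue count of the
model IDP construct), $A = -1$, $B = 501.5$ K, giving a critical
temperature of 320 K — in the range of published Flory–Huggins fits for
Ddx4-type IDP condensates. An $|A|$ of order 1 also makes a *relative*
recovery tolerance on $A$ meaningful; a near-zero entropic term would
make any relative error bound a statement about $A$'s arbitrary
magnitude rather than about the fit. The standard cloud-point panel
spans both binodal branches ($\phi$ from $10^{-4}$ to 0.4, 12 points,
as phase-diagram measurements do), which is what separates $A$ from
$B$: with points on one branch only, $1/T_p$ varies so little that the
two parameters are nearly collinear and 0.5 K of temperature noise
inflates into tens of percent of parameter error. With the two-branch
panel, parameters are recovered exactly (to $10^{-14}$) from noiseless
points and within 5% at 0.5 K noise.

## Problem sizes

The test suite and the reproduction script run at the following sizes,
chosen so every quantity is measured on the same footing as the study
it emulates while each stage stays comfortably within a desktop run:
ray-traced panels of four contact angles at 12 µm contact radius
(above the 10 µm acceptance floor) on a 0.25 µm rendering grid with 41
rays per focus; voxelized caps at 0.2–0.52 µm spacing (up to roughly
300 × 300 × 120 voxels for the largest PSF-study cap); profile fits on
90–120 point profiles with 1000 trial points; and 12-point cloud-point
panels.

## Known limitations

* The ray tracer is meridional (2D); skew rays are not traced. Its
  intensity model is calibrated, not derived from diffraction theory —
  vectorial PSF models (Gibson–Lanni, Richards–Wolf) are out of scope.
* The PSF study uses a clean Gaussian PSF; measured PSFs at depth are
  more diffuse and asymmetric, so the radius below which distortion
  matters is larger in real data than in this simulation.
* Line tension is deliberately not modelled as an alternative
  explanation of the small-radius angle rise.
* Contact-angle hysteresis, pendant drops and non-axisymmetric drops
  are out of scope; uncertainty estimation by bootstrap is future work.
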