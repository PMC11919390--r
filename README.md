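# condensateADSA

Contact-angle measurement of sessile biomolecular condensates by
axisymmetric drop-shape analysis (ADSA) of 3D confocal stacks.

Biomolecular condensates — liquid-like, protein-rich droplets formed by
intracellular phase separation — sediment onto surfaces and adopt
sessile-drop shapes whose contact angle θ quantifies wetting. This
package measures θ from two-channel confocal z-stacks (fluorescence +
reflected light marking the substrate) by:

1. **Segmentation** — locate the base plane from the reflection
   channel, Gaussian-smooth and Otsu-binarize the fluorescence volume,
   label 26-connected components, keep those touching only the base,
   and reduce each to an axisymmetric profile r(z) (equivalent-area
   disk radii, augmented by the slice-centre offset from the symmetry
   axis, apex appended).
2. **Young–Laplace fitting** — minimize the mean squared
   nearest-trial-point distance λ between the profile and integrated
   solutions of dψ/ds = 2/R₀ + h/ℓc² − sin ψ / r over (R₀, ℓc, z₀) by
   Nelder–Mead; θ = |ψ(s_max)| where the fitted profile crosses the
   substrate.
3. **Aberration handling** — profile z coordinates are rescaled by
   1/1.2 before fitting to undo the axial stretch of oil-immersion
   imaging into aqueous media; fits with λ·N/s_max > 0.5 µm or contact
   radius < 10 µm are discarded.

It also ships the simulations that justify those corrections — a
deterministic refraction ray tracer that reproduces the 1.2 axial
stretch factor independent of condensate refractive index, and a PSF
convolution study showing fitted angles inflating as drops shrink
toward the PSF — plus a synthetic-data generator (no real stacks are
required anywhere) and Flory–Huggins binodal fitting of cloud-point
data, yielding the degree of phase separation Δφ = φ_dense − φ_dilute.

## Worked example

Simulate a sessile condensate with known geometry, image it with the
axial aberration, and measure it back:

```r
library(condensateADSA)

profile <- sessile_profile(theta = 120, r_contact = 15, lc = 500)
stack   <- voxelize(profile)                    # two-channel 3D stack
stack   <- apply_axial_stretch(stack, 1.2)      # emulate the aberration
stack   <- add_noise(stack, noise_model(gaussian_sigma = 5, seed = 1))

measure_contact_angles(stack)                   # rescales by 1/1.2, fits
#>   id theta_deg   R0_um    lc_um    z0_um  smax_um   lambda_um2
#> 1  1  119.9598 17.3202 490.2885 25.94903 36.24061 0.0005728135
#>   contact_radius_um  quality_um n_points accepted reason
#> 1          15.00578 0.001185438       75     TRUE   <NA>
```

The fitted angle (119.96°) recovers the ground truth, the capillary
length (490 µm vs the generating 500 µm) and contact radius (15.01 µm)
are recovered too, and the quality metric sits far below the 0.5 µm
gate. Omitting the rescale
(`measure_contact_angles(stack, rescale_factor = 1)`) returns 132.2° —
the uncorrected bias the optics simulation explains.

Phase behaviour from cloud points:

```r
fh  <- fit_cloud_points(cloud_points, n_chain = 236)  # chi(T) = A + B/T
delta_phi(fh, T_ref = 295.15)$value                   # degree of phase separation
```

A command-line wrapper with `simulate`, `fit`, `phasediagram`,
`optics` and `study` subcommands is installed at
`inst/scripts/condensate-adsa`; every aberration-related constant
(1/1.2 rescale, 0.5 µm quality gate, 10 µm radius floor, refractive
indices, NA) is a documented, overridable default recorded in each
run's JSON manifest.

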