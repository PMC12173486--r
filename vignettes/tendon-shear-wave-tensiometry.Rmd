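---
title: "Shear wave tensiometry in twisted Achilles subtendons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear wave tensiometry in twisted Achilles subtendons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonwave)
```

## The scientific problem

Shear wave tensiometry infers axial tendon stress from the propagation
speed of an externally tapped transverse (shear) wave.  For a tensioned
beam the relationship is

$$\sigma = \rho_{\mathrm{eff}}\, c^2 - k' \mu,$$

with $\sigma$ the axial stress (Pa), $c$ the shear wave speed (m s$^{-1}$),
$\rho_{\mathrm{eff}}$ the effective density of the propagation medium
(kg m$^{-3}$), $k'$ a shear correction factor and $\mu$ the tangential
shear modulus.  For an isolated, uniformly loaded tendon,
$\rho_{\mathrm{eff}}$ equals the tissue density (1500 kg m$^{-3}$ for wet
tendon), so the slope of a $\sigma$-on-$c^2$ regression recovers the
density and the intercept estimates $-k'\mu$.

The Achilles tendon complicates this picture: it is a composite of three
subtendons -- lateral gastrocnemius (LG), medial gastrocnemius (MG) and
soleus (S) -- that twist helically along the free tendon, can be loaded
differentially by their muscles, and interact through frictionless
sliding contact.  This package provides a desk-scale pipeline to study
how twist and differential loading modulate per-subtendon wave speeds
and the apparent effective density, and an export path
(`write_feb()`) to a full-fidelity 3-D finite element solver for
cluster-scale studies.

## Geometry and mesh

The free tendon is an elliptical cylinder, linearly tapered from a
distal cross-section of 22.04 x 6.42 mm to a proximal one of
17.83 x 5.76 mm.  The free-tendon length varies across individuals and
is not pinned down by the cross-sectional data; we default to 60 mm, a
representative free Achilles length, and make it configurable -- all
wave-speed results are per-length quantities and insensitive to this
choice.

The cross-section is partitioned into three angular sectors in a
scaled-circle parametric domain, where sector area is exactly
proportional to angular span.  Default area fractions are
S = 0.52, MG = 0.26, LG = 0.22 (the soleus is the largest subtendon);
they are configuration inputs, not hard-coded truths.  Each subtendon is
a separate body (no shared nodes), mirroring the contact-coupled
full-fidelity model.  Each sector is meshed with a butterfly topology: a
bilinear quadrilateral core at the apex plus a transfinite annulus
block.  Sectors wider than about 100 degrees would make the bilinear
core non-convex, so they are split into equal conforming sub-wedges
(the soleus sector, 187.2 degrees, uses two).

With 45 axial slices, a 6 x 6 core and annulus radial divisions of
38 / 22 / 12 (LG / MG / S, per wedge), the per-subtendon element counts
are exactly 22140, 13500 and 16200 -- the reference full-fidelity mesh resolution --
by construction: each wedge contributes
$n_c^2 + 2 n_c n_r$ in-plane elements per slice.

Helical twist rotates each slice rigidly about the tendon axis by
`twist * (axial fraction from the proximal end)`, the proximal end held
fixed; fibre directions are the unit vectors along the rotated axial
element edges, so fibres wind helically with pitch angle
$\arctan(r\,\theta/L)$ at radius $r$.  Twist is an in-plane isometry:
per-slice radii, areas and interface lengths are preserved exactly.
Because of this, the cross-section-based (prismatic) mesh volume is
twist-invariant to machine precision, while the volume of the faceted
hexahedral solid changes at second order in the per-slice twist
increment; `mesh_volume()` exposes both measures and the invariance test
uses the prismatic one.

## Loading

Cohort loads are prescribed a priori on the undeformed distal
cross-sectional areas: both gastrocnemius subtendons carry the same
stress $\sigma_G$ and the soleus carries $\sigma_S = r\,\sigma_G$ with
$r \in \{1, 2, 0.5\}$, under total force conservation, giving
$\sigma_G = F/(A_{LG} + A_{MG} + r A_S)$.  A synthetic gait profile
(`synth_gait_profile()`) supplies the total force over 100 one-percent
gait increments: a smooth, non-negative, single-peaked curve peaking at
45 % of the cycle (late stance).  The profile emulates the shape of
musculoskeletal-model force estimates rather than digitising any
particular trace; its default 3300 N peak produces a peak uniform tendon
stress of about 30 MPa over the default distal area, a physiological
peak walking load.  Slopes of $c^2$ versus $\sigma$ are insensitive to
the profile's shape and magnitude.

## Reduced-order wave model

The full model excites a transverse plane wave over the whole distal
cross-section (half-sine displacement, 20 um amplitude, 250 us half
period) and integrates 3-D elastodynamics for 1 ms.  At desk scale we
replace this with three coupled tensioned shear beams, one per
subtendon centroid line:

$$\rho A_s\, \ddot u_s = (\sigma_s A_s + k' \mu A_s)\, u_s'' -
  \sum_{j} \kappa_{sj}(z)\,(u_s - u_j),$$

distal node displacement-driven, proximal node free.  Choices that
matter:

* **Contact closure.**  Frictionless sliding contact transmits
  surface-normal motion between neighbouring subtendons.  We reduce it
  to a distributed transverse spring
  $\kappa_{sj}(z) = \alpha\, \mu\, \ell_{sj}(z) / d_{sj}(z)$, where
  $\ell_{sj}$ is the shared sector-boundary length, $d_{sj}$ the
  in-plane centroid distance (so $\kappa$ has units N m$^{-2}$ and the
  ratio is a shear strain per unit relative displacement), and
  $\alpha$ the single dimensionless closure coefficient
  (default 0.1; 0 = free sliding, large = bonded).  $\alpha$ is
  reported with all outputs.
* **Uniform nominal stress.**  The a-priori distal-area stress is
  applied uniformly along each beam; the taper-induced axial stress
  gradient is a full-fidelity effect we deliberately exclude so that
  the decoupled beam has the exact closed-form speed
  $c = \sqrt{(\sigma + k'\mu)/\rho}$ and the regression pairs the same
  nominal stress the loading module prescribes.
* **Shear correction factor.**  $k'$ is not separately identifiable;
  it enters only as the lumped intercept $k'\mu$.  We default $k' = 1$
  for forward simulation and recover $-k'\mu$ as a free intercept in
  regression.
* **Twist coupling.**  Twist enters the reduced model only through the
  centroid-path geometry (helical arc length) and the taper-scaled
  adjacency weights; in-plane rotation changes neither $\ell$ nor $d$.
* **Numerics.**  Explicit central differences at half the combined
  CFL/coupling stability bound.  The output map inherits the mesh grid
  (dx = path length / 45, 10 us cadence, 1 ms window), but the internal
  spatial grid is refined fourfold: the half-sine onset carries a
  velocity step whose lattice-dispersion ringing at the coarse spacing
  measurably widens the pulse.  With the refinement, cross-correlation
  time-of-flight on the output maps matches the closed form to better
  than 1 %.
* **Boundaries.**  The proximal end is reflective (free) by design so
  that the directional filter is exercised exactly as in practice; an
  absorbing variant (`proximal_bc = "absorbing"`) exists for
  filter-validation studies, and the two agree within 3 %.

The discrete staggered (leapfrog) energy is conserved to machine
precision once the drive ends ($\kappa = 0$) and to well under 1 % with
coupling, which is the property test guarding the integrator.

## Wave speed measurement

Per subtendon, transverse displacements along the centroid line are
assembled into a spatiotemporal map (rows = position, columns = time).
Measurement follows the standard transient-elastography chain:

1. **Directional filter** (`directional_filter()`): 2-D FFT, zero the
   quadrants whose spatial/temporal frequency signs match (backward,
   proximal-to-distal content), inverse transform.  Only
   distal-to-proximal waves survive, as in vivo.
2. **Radon transform** (`radon_speed()`): projections over an angle
   grid (default 0.25 degree steps over 5--85 degrees), maximum
   absolute projection per angle, then a single ("first-order")
   Gaussian $a \exp(-((\theta-b)/c)^2)$ fitted to amplitude versus
   angle; the continuous centre $b$ gives sub-grid resolution, and
   speed is $(dx/dt)\cot b$.

Numerical choices worth recording:

* The transform runs on the **particle-velocity map** (centred temporal
  derivative) by default.  The displacement band of a half-sine pulse
  is broad and non-negative, which makes the Radon angle selectivity
  weak (misaligned projections hardly cancel) and biases the peak by
  over a degree on desk-scale maps; the zero-mean velocity waveform
  sharpens the peak an order of magnitude.  `signal = "displacement"`
  retains the literal behaviour.
* The Gaussian is fitted (nonlinear least squares, `port`, initialised
  from a log-domain parabola) on the contiguous window where amplitude
  exceeds 0.4 of the peak, then re-fitted on a sub-grid centred at the
  first-stage peak whose half width is the larger of 12 degrees and the
  first-stage fitted width (so broad peaks are never truncated).  The
  second stage decouples the centre from far-angle background (residual
  reflections and ringing); disabling it (`refine_window = NULL`)
  reproduces the single-stage estimate.
* Per-trace mean removal is applied before the transform to remove the
  quasi-static offset of sustained loading.
* Estimates carry flags (`low_signal`, `angle_at_boundary`,
  `poor_fit`) instead of silent failure.

On noiseless synthetic plane waves the estimator is accurate to better
than 1 % across 20--160 m s$^{-1}$ (covering in vivo and ultrasound
ranges) and to a few tenths of a percent at SNR 20 dB.  On reduced-order
simulations it retains a small systematic underestimate (about 1--3 %,
growing with speed) caused by residual reflected energy after filtering
on a 46-sample aperture; this inflates the fitted slope by roughly
+4 to +6 % -- within the same +-10 % deviation band the reference full-fidelity
analysis uses -- and is documented rather than calibrated away.

## Regression and the deviation flag

`fit_wave_speed_stress()` regresses stress on squared speed -- exactly
that direction -- so the slope is the effective-density estimate in
kg m$^{-3}$ and the intercept estimates $-k'\mu$.  The deviation flag is
strict: $|\hat\rho - 1500|/1500 > 0.10$ (exactly 10 % is not flagged).
Under rigid coupling with 2:1 differential loading the per-subtendon
slopes deviate in opposite directions (gastrocnemius below density,
soleus above, reversed at 1:2), reproducing the sign structure of the
full-fidelity slope tables; with the default weak coupling the modulation is
present but milder.

## What the synthetic data does and does not establish

The generator produces (a) gait force profiles with the stated shape
constraints and (b) plane-wave maps with known speed, optional single
reflection and seeded noise at a stated SNR.  Green tests therefore
establish: geometric fidelity of the mesh, exactness of load
partitioning, closed-form consistency of the decoupled wave model,
estimator accuracy on known-truth maps, and the qualitative
coupling/twist phenomenology.  They do **not** establish 3-D contact
mechanics, waveguide dispersion, viscoelastic attenuation, subcutaneous
tissue effects, or subject-specific anatomy -- all of which require the
exported FEBio models (or measurements) and are outside desk scale.
The printed full-fidelity slope values (e.g. 1465 for LG, uniform, no
twist) and the 28.9 m s$^{-1}$ peak inter-subtendon speed difference
are full-fidelity quantities: the latter additionally depends on
unprinted gait force magnitudes.

## Degenerate inputs and tie-breaks

Non-physical material parameters, degenerate geometry, zero areas,
negative effective tension, unstable time steps, non-monotone paths and
constant-speed regressions are rejected with informative errors.
Centroid-nearest-node ties are broken by lowest node index; the sector
start angle (default 0) and twist chirality are configurable because
left/right tendon handedness is not fixed by the problem.

## Limitations

The reduced model is one-dimensional per subtendon: it cannot represent
within-subtendon speed gradients, depth-dependent wave distortion, or
the taper-induced proximal stress rise, and its single coupling
coefficient is a closure, not a measured quantity.  Quantitative slope
values under differential loading therefore differ from full-fidelity
results; the pipeline's value at desk scale is the controlled recovery
of the tensioned-beam relationship and the direction and ordering of
coupling and twist effects.
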