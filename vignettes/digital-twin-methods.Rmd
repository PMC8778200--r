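---
title: "Methods: a particle digital twin of the Dynamic Colon Model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a particle digital twin of the Dynamic Colon Model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dcmtwin)
```

## The system being modelled

The Dynamic Colon Model (DCM) is a biorelevant dissolution apparatus: a
segmented, haustrated silicone tube mimicking the human proximal colon, whose
ten segments contract and relax pneumatically so that a peristaltic wave
(a propagating pressure wave, PPW) travels from the caecum end toward the
hepatic flexure. `dcmtwin` implements a digital twin of this device as a
coupled particle simulation:

* the **fluid** is weakly compressible Smoothed Particle Hydrodynamics
  (SPH): Lucy kernel, density by the discretised continuity equation, the
  Tait equation of state
  \(P = c_0^2 \rho_0 / 7\,[(\rho/\rho_0)^7 - 1]\),
  an unconditionally applied Monaghan-type viscous term acting as a real
  Newtonian viscosity, and explicit velocity-Verlet time stepping;
* the **membrane** is a lattice spring model (LSM): Hookean bonds between
  neighbouring wall particles (\(F_{ij} = k\,(r_{ij} - r_0)\)), Hookean
  tethers to each particle's build position, and a viscous damping force
  \(F_i = -k_{M,v} v_i\);
* **fluid-structure interaction** couples the two through a soft contact
  potential \(E_{ij} = A\,[1 + \cos(\pi r_{ij}/r_c)]\) (purely repulsive,
  finite-energy core) and a no-slip approximation that applies the same
  Monaghan viscous operator across fluid-wall pairs.

Motility is imposed as a per-segment schedule of radial forces on the mobile
membrane particles: an outward (relaxing) phase, an inward (contracting)
phase, and a longer linear taper of the inward force so that the tethers
restore the neutral position more slowly than the contraction built up, as
in the physical device. Segment \(k\) starts at offset
\((k-1)\,L_\mathrm{seg}/u_\mathrm{wave}\); the wave traverses the 0.24 m
section in exactly \(0.24/u_\mathrm{wave}\) s (60 s at 0.4 cm/s, 30 s at
0.8 cm/s).

## Geometry

The tube is 0.622 m long with a 0.04 m inner diameter; only the first
0.24 m is the actuated colon section, the rest is a rigid drain tank
separated by an end constriction (two static rings at 40% of the lumen
radius — the device's hepatic-flexure narrowing, which builds back pressure
when the wave arrives). Rings of 25 particles at an axial spacing of
6.283e-3 m give 100 rings (2500 particles per layer) over the full tube and
39 rings (975 particles) over the colon section. The 39 rings decompose
into 10 segments of 3 mobile rings each plus 9 shared boundary rings that
belong to neither neighbour (tethered only) — the only decomposition
consistent with both printed counts. Three longitudinal rows of fixed
particles (azimuths 90, 210, 330 degrees) shape the tri-chamber (haustral)
cross-section during contraction.

Two practical additions close the domain: end-cap walls at both tube ends
(the physical device is sealed), and a second, staggered membrane layer
(offset half a spacing axially, azimuthally, and radially outward). The
second layer matters: a single shell of particles at 5-6.3 mm spacing has
gap channels whose contact-energy barrier is far below the kinetic energy
of an agitated fluid particle, so particles tunnel straight through it.
The staggered cage closes those channels with real geometry rather than
with an artificially stiffened potential. Particle-count conventions in
the literature for this device quote one layer; `build_membrane()` builds
one layer by default and `build_domain()` uses two.

Fluid fills the colon section on a simple cubic lattice at spacing
\((m/\rho)^{1/3}\) (2.351 mm at full resolution), with a radial clearance
of 0.45 spacings from the wall circle and the z-lattice bottom-aligned so
the lowest layer starts within contact range of the wall. Sites are taken
bottom-up until the summed particle volume \(n\,m/\rho\) matches the
requested fill volume; 150 mL reproduces the expected ~11.5k particles at
full resolution. The printed particle count for the 200 mL case is not
consistent with its own mass/density arithmetic (it implies ~235 mL), so
the fill is volume-consistent instead of count-forced.

## The gravity question

The headline design decision of this package is that the production runs
are **gravity-free**, and it is worth being explicit about why.

The printed parameter set is: artificial sound speed \(c_0 = 0.1\) m/s,
time step 5e-4 s, membrane bond stiffness 0.1 N/m, tether stiffness
0.012 N/m, damping 0.01 kg/s. Under gravity, a 150-200 mL pool weighs
1.5-2 N. Two independent show-stoppers follow:

1. **The membrane cannot carry the pool.** The only anchoring of the
   membrane is its tethers (0.012 N/m each) and bonds to the three fixed
   rows (0.1 N/m each). Distributing 2 N over the ~1000 wetted membrane
   particles loads each tether with ~2 mN, i.e. a static deflection of
   ~0.2 m — ten lumen radii. In every numerical experiment the loaded
   membrane simply tears open and the pool falls through; this is not a
   resolution or stability artefact but force-balance arithmetic.
2. **The equation of state cannot hold a column.** At \(c_0 = 0.1\) m/s,
   supporting the ~230 Pa at the bottom of the pool requires
   \((\rho/\rho_0)^7 \approx 160\), i.e. the pool would compress to half
   its volume; hydrostatics in any meaningful sense requires
   \(c_0^2 \gg g\,d\).

Conversely, the same parameter set is entirely self-consistent for a
wall-driven flow without a body force: peak flow speeds of ~2 cm/s give
Mach 0.2 at \(c_0 = 0.1\) (the weakly compressible regime), the time step
sits at 1/20 of the CFL bound, and soft spring constants suffice because
the membrane carries no static load. The package therefore treats the
digital twin as a wall-driven, gravity-free system by default
(`run_config(gravity = 0)`); gravity can be enabled, but then a stiffer
`c0` must be chosen and the membrane constants no longer correspond to the
published device constants. Gravity-loaded physics is exercised instead by
the hydrostatic validation fixture, which uses dense rigid walls.

What is lost by this choice: the post-contraction gravity-driven levelling
of the pool, and any orientation dependence. What is kept: the
antegrade-then-retrograde flow signature during local contraction, which
is pressure- and wall-driven (contraction against the downstream
constriction), and the shear-rate structure near the wall.

## Numerical choices

* **Two-length scheme.** The continuity equation uses the smoothing length
  \(h = 4.71\)e-3 m and the momentum equation nominally uses
  \(h_M = 2h\). With the fluid lattice at 2.351 mm, a kernel of width
  \(4\,\Delta x\) puts the nearest-neighbour shell at \(q = 0.25\), below
  the Lucy kernel's inflection point \(q = 1/3\): the pressure interaction
  is then on the destabilising branch under compression (the classic
  Swegle instability), and every gravity- or compression-loaded test blew
  up within ~0.1 s. The pressure gradient is therefore evaluated with the
  kernel at \(h\) (nearest shell at \(q = 0.5\), stable branch), while the
  viscous term uses \(h_M\) throughout — which is also what the effective
  viscosity relation \(\nu = \alpha\,h_M\,c_0/10\) presumes. This is the
  package's reading of how a two-length scheme can have run at all.
* **Viscosity.** The Monaghan term is applied to all pairs (not only
  approaching ones), so it acts as a physical Newtonian viscosity with
  \(\nu = \alpha h_M c_0 / 10\); `alpha_from_viscosity()` inverts this.
  The plane-Poiseuille fixture recovers the target viscosity from the
  parabola curvature to within ~1% at the production resolution ratio.
* **Free surface.** The partially filled lumen has a gas space; fluid
  pressure is clamped at zero from below (\(P \ge 0\)). A free surface
  against gas cannot sustain tension, and letting the Tait EOS pull the
  stretched surface together drives tensile clumping (surface particles
  collapse into clusters and the simulation disintegrates).
* **No-slip.** Wall particles are rigid or membrane particles with their
  own velocities; the fluid-wall viscous term is doubled
  (`wall_visc_scale = 2`), the first-order mirror approximation (ghost
  velocity \(-v_f\)). Empirically this places the no-slip plane at the
  midpoint between the first wall and first fluid layers (plane-fit offset
  below 1e-5 m in the Poiseuille fixture); with plain coupling the plane
  sits 0.3-0.8 spacings inside the wall (a Navier slip).
* **Contact.** \(r_c = 1.2 \max(\Delta x, 5\,\mathrm{mm})\) covers the
  membrane lattice gaps; the peak repulsion is scaled to the governing
  load, `rho0 dx^2 max(3 g D, 0.2)` — the hydrostatic column weight when
  gravity is on, otherwise a dynamic-pressure floor (20 \(c_0^2\) at the
  printed \(c_0\)). This keeps the contact stiffness resolvable at the
  printed time step (\(\omega\,\Delta t \lesssim 0.5\)).
* **Initialisation.** Runs begin with a damped settling phase (velocities
  scaled by 0.98 per step, motility clock negative); when gravity is on it
  ramps linearly over the first 70% of the settle so the lattice loads the
  walls quasi-statically. Snapshots begin at \(t = 0\).
* **Neighbour search.** A Verlet pair list (skin \(0.5h\)) stores pairs
  with at least one fluid member and is rebuilt when any mobile particle
  has moved more than half the skin; membrane-membrane interactions run
  through the explicit bond list instead.
* **Integration.** Velocity Verlet; density advances by half-steps
  alongside the velocity kicks. Instability (speed above \(10 c_0\), or
  non-finite density) aborts with a diagnostic snapshot.

## Motility calibration

The device fixes the occlusion degree at 60 +/- 5% (and relaxes to about
-20%); the corresponding radial force amplitudes are not device constants,
so they are calibrated: bisection on the contraction amplitude in a dry
single-activated-segment domain until the peak occlusion of the segment's
middle ring hits the target, and likewise for the relaxation amplitude.
Monotonicity of occlusion in amplitude is checked as the bisection
proceeds. Phase durations (not published) are 0.3/0.3/1.4 segment periods
for relax/contract/slow-return, reproducing the qualitative wall-trace
shape: fast symmetric onset, slower return. Calibration is dry by design —
the device servo imposes its displacement regardless of load, and the
calibrated amplitudes are treated as device constants across fills.

## Rheology

The two NaCMC media follow power laws \(\tau = K \dot\gamma^n\) (LOVIS:
K = 0.04, n = 0.87; HIVIS: K = 0.20, n = 0.74). Over the quasi-linear
range 0-40 1/s a zero-intercept least-squares line (401 uniform samples)
gives effective Newtonian viscosities of ~26 and ~85 mPa s, which the
solver consumes through \(\alpha\). The zero intercept is deliberate — a
Newtonian fluid has \(\tau(0) = 0\); a free-intercept variant exists for
sensitivity checks. The printed goodness-of-fit of the original
measurement depends on the experimental sampling and is not a reproduction
target; the slope is.

## Analysis pipeline

* `rasterize_slice()` builds a phase-contrast-style pixel grid (default
  pixel 1.1 mm, slab 8 mm): mass-weighted mean streamwise velocity per
  pixel, nearest-neighbour fill of empty in-lumen pixels within one pixel,
  per-pixel flow rate \(q_i = v_i L^2\).
* `pixel_shear_map()` applies 3-point central differences. The printed
  convention divides the two-pixel-span difference by \(L\); the default
  `"standard"` dialect divides by \(2L\) and recovers exact gradients on
  linear fields, while `"as_printed"` returns exactly twice them (both are
  tested). Mask-adjacent pixels fall back to one-sided differences.
* `particle_shear_rate()` estimates \(\partial v_x/\partial y\) and
  \(\partial v_x/\partial z\) with the difference-form SPH gradient (wall
  particles contribute their own velocities), forms the reduced stress
  components \(\tau_{yx}, \tau_{zx}\), their Frobenius norm, and
  \(\dot\gamma = \lVert\tau\rVert/\eta\) — numerically the velocity-gradient
  norm, with the stress detour kept for parity with the phase-contrast
  convention.
* `bottom_wall_shear_series()` averages \(\dot\gamma\) over fluid within
  one smoothing length of the lowest (inner-layer) membrane surface in a
  segment's axial window.
* `cross_section_series()` reports mean, central-disc (the five-central-
  pixel analogue, radius 1.25 pixels) and top-4-pixel streamwise
  velocities plus the wall displacement of the nearest ring.
* `tss()` resamples two series onto the coarser grid over their common
  support (linear interpolation) and sums squared differences.
* `main_effects()` computes high-minus-low mean responses over the 2^3
  factorial (4 runs per level) with Welch t-tests; the experimental
  factors are wave speed (0.4/0.8 cm/s), medium (LOVIS/HIVIS) and fill
  volume (150/200 mL).

## Validation fixtures

* **Hydrostatic column** (gravity on, dense 4-layer bottom wall, laterally
  periodic): layer means of the kernel-smoothed Tait pressure match
  \(\rho_0 g \times\) depth below the settled surface to within 10%
  (measured ~3-6%). Fixture parameters differ from production where the
  physics demands: \(c_0 = 2.5\) m/s (weak compressibility requires
  \(c_0^2 \gg g d\)), kernel ratio \(h_M = 2.6\,\Delta x\) (the production
  4\(\Delta x\) viscous kernel is harmless, but a compressed column probes
  the pressure kernel), strong damping \(\alpha = 0.5\) (viscosity is
  irrelevant for statics), and quasi-static gravity ramping. The surface
  layer and the contact-supported bottom layer are excluded from the
  comparison (kernel truncation and wall standoff live there).
* **Plane Poiseuille** (no gravity, body force along the periodic flow
  direction, wall-resolution ratio 17): steady centreline within 5% of
  \(g_x \mathrm{gap}^2/(8\nu)\) (measured ~1.5%), and the fitted parabola
  curvature returns the target viscosity within 10% (measured ~1%) — the
  end-to-end check of the \(\alpha\)-viscosity calibration.
* **Linear shear fields**: lattices carrying \(v_x = c_y y + c_z z\)
  validate both shear estimators exactly (pixel stencil) or to ~2%
  (SPH gradient, interior).

## Problem sizes

Full resolution (11.5k-15k fluid particles, 5e-4 s steps, 66 s waves) is
sized for cluster hardware. The package's tests and the acceptance script
use the documented scaled-resolution mode: lattice spacing x2
(acceptance; ~1.9k fluid particles for 200 mL) or x3 (test-suite factorial
sweep; ~570), with \(h\), \(h_M\), \(\Delta t\) scaled proportionally and
\(\alpha\) recomputed so the physical viscosity is unchanged. Sweep cells
and the acceptance run simulate through the full cycle of segment 6 (the
wave has passed segments 1-6; segment-2 and segment-6 peak statistics are
complete by then), and wall-trace checks run the full wave dry. These
sizes are the package's choices for a single-CPU reproduction; finer
resolution sharpens near-wall gradients and raises peak shear estimates.

## Known limitations

* The neutral lumen is a plain cylinder shaped by the fixed rows during
  motion; the moulded haustral out-pocketing of the physical device is not
  reproduced, and the neutral volume is fixed.
* No gravity in production runs (see above), hence no post-wave levelling
  of the pool and no orientation effects.
* No surface tension, no turbulence model, and the media are Newtonian
  approximations of shear-thinning fluids; outside 0-40 1/s the real media
  deviate.
* Single antegrade waves only: no retrograde waves or high-amplitude
  propagating sequences.
* Scanner-data processing (DICOM and friends) is out of scope; the
  analysis operates on simulator snapshots or synthetic velocity fields,
  and comparisons against the original device measurements require scan
  series that are not publicly released.
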