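---
title: "Methods: desk-scale TG-43 characterization of an I-125 seed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale TG-43 characterization of an I-125 seed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`brachychar` characterizes a low-energy interstitial brachytherapy seed —
by default the GMS BT-125-1, an I-125 seed built around a 3.25 mm silver
marker rod in a welded titanium capsule — in the AAPM TG-43 formalism:

$$\dot D(r,\theta) \;=\; S_K \,\Lambda\,
  \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}\, g_L(r)\, F(r,\theta),$$

with the reference point at $r_0 = 1$ cm on the transverse axis
($\theta_0 = 90^\circ$).  The package provides both arms of a
characterization study: an analog photon Monte Carlo arm (air-kerma
strength in vacuum, dose tables in water and PMMA spheres, extraction of
$\Lambda$, $g(r)$, $F(r,\theta)$ and the phantom conversion factor
$P_{phant}$), and a synthetic thermoluminescent-dosimeter (TLD) arm that
emulates a six-seed measurement campaign in two PMMA phantoms with a
realistic noise model, analysed back to "experimental" parameters by the
same estimators a physicist would use.

## Seed geometry

The solid model is axisymmetric about $z$: a silver rod (length 0.325 cm,
diameter 0.050 cm, density 10.53 g/cm$^3$) carrying a 0.5 µm radioactive
coating on its lateral surface **and end faces** (the manufacturer does not
state whether the end faces are coated; uniform coverage is the default and
the emission locus is switchable via the geometry parameters), inside a
titanium capsule (length 0.45 cm, outer diameter 0.08 cm, wall 0.006 cm,
density 4.5 g/cm$^3$).  The "hemispherically shaped ends of 0.5 mm radius"
are modelled as spherical shells of outer radius 0.05 cm and the same wall
thickness, truncated by the capsule body cylinder (a 0.05 cm sphere on a
0.04 cm radius body necessarily pokes through the cylinder; the
intersection of sphere and cylinder closes the capsule at the stated
overall length).  The fill between coating and capsule interior is vacuum:
at 27–35 keV, 0.03 cm of any plausible fill gas is optically negligible.
The coating is an emission locus only; its attenuation (0.5 µm) is
ignored.  A second named configuration, `model-6711` (3.0 mm rod, 0.005 cm
wall), is bundled for benchmarking and not exercised by default.

Ray tracing classifies each point into one of five regions (marker,
coating, capsule wall, gap, exterior) that partition space; boundary
distances are found from the quadric surfaces with mid-interval
classification, which is robust to grazing hits.  The geometry is validated
in the tests against an independent signed-distance classifier, a 1 µm
ray-marching oracle, and closed-form solid volumes.

## Photon transport

The transport code is an analog history-by-history photon Monte Carlo with
three interaction channels and a 5 keV energy cutoff (which suppresses
titanium K x-rays, as is conventional for air-kerma strength):

* **Photoelectric absorption.** Terminates the photon.  In silver above
  the K edge (25.514 keV) the absorption is a K-shell capture with
  probability $1 - 1/J_K \approx 0.845$ and is followed, with fluorescence
  yield $\omega_K = 0.830$, by one K x-ray emitted isotropically —
  K$\alpha$ at 22.1 keV (80.7%) or K$\beta$ at 24.93 keV (19.3%).  These
  silver x-rays materially shape the emitted spectrum of silver-rod seeds
  (roughly one in six escaping photons) and pull the dose rate constant below
  its point-source value, because ~22 keV photons are attenuated much
  faster in water than the primary 27–35 keV lines.  An earlier design
  draft emitted a single 22.1 keV line with probability 0.83 for *every*
  above-edge absorption; that over-emits the soft component by ~19% and
  was replaced by the textbook chain above.
* **Incoherent (Compton) scattering.**  The core sampler is Kahn's
  rejection method for the free-electron Klein–Nishina distribution,
  verified in the tests against numerical integration of the differential
  cross-section.  On top of it, sampled angles are rejected against the
  same screened incoherent scattering function $S(x,Z)$ that defines the
  tabulated channel magnitude (see below), so the sampling density is
  $\propto \mathrm{KN}(\theta)\,S(x,Z)$.  This matters: with unmodified
  free-electron angles the binding-suppressed forward scatter stays in the
  beam and the radial dose function falls too slowly — the error exceeds
  10% beyond ~8 cm, larger than the "few percent" one might expect.  With
  the self-consistent rejection the simulated $g(r)$ tracks the published
  fifth-order fit within the 10% pointwise bound over 0.5–10 cm (asserted
  by the test suite at the default history budgets).
* **Coherent (Rayleigh) scattering.**  Direction change only, sampled from
  the Thomson shape modulated by a Thomas–Fermi-screened atomic form
  factor with an effective $Z$ per material.

Electrons are not transported: at $\le 35.5$ keV the secondary-electron
range in water (≪ 0.1 mm) is far below every cell size, so collision kerma
is dose.  The estimator is a track-length collision-kerma estimator: each
track segment through a scoring cell adds
$\ell \, E \, (\mu_{en}/\rho)(E)/V_{cell}$, with per-history variance
accumulation.  Per-history energy bookkeeping (emitted = locally deposited
+ escaped + killed below cutoff) balances to machine precision and is
asserted in the tests.

### Ring tallies and problem sizes

All scoring cells are full azimuthal rings bounded by two spheres and two
polar cones — exact by axisymmetry, and roughly three orders of magnitude
more efficient than the mm-scale voxels a general-purpose code must use.
That efficiency sets the package's study sizes: $2\times10^6$ histories
for the air-kerma-strength run and $5\times10^6$ for a full dose table
(configurable), which put the transverse-axis statistical errors at
0.4% (1 cm) to ~1.5% (10 cm) in seconds-to-minutes on one core.  The
statistical errors reported with every cell are the package's own; the
much smaller errors a $5\times10^9$-history production run would reach are
not reproduced.  Cells are thin shells (half-thickness 2% of the radius,
0.01 cm floor) and $\pm 5^\circ$ bands; volume-averaging bias from the
$1/r^2$ curvature is below 0.1% everywhere, well under the MC noise.

The air-kerma strength $S_K$ is scored in vacuum (15 cm sphere) in a thin
transverse ring at 10 cm ($\pm 0.05$ cm, $\pm 0.5^\circ$) — the ring
equivalent of the conventional small voxel — and multiplied by $d^2$.
With doses in keV/g per history and $S_K$ in keV cm$^2$/g per history,
their ratio is numerically $\Lambda$ in cGy h$^{-1}$ U$^{-1}$
(1 U = 1 µGy m$^2$ h$^{-1}$; the energy and time units cancel), so the
absolute source activity never enters.

## Cross-section tables

The 5–40 keV interaction tables for water, air, PMMA, titanium and silver
are vendored in `inst/extdata/` and rebuilt by `data-raw/xs_build.R`.
They are an approximate compilation: total attenuation and mass
energy-absorption anchors are taken from the standard reference
compilations (reliable to ~1–2% for the low-Z media, ~10–15% for Ti and
Ag), the incoherent component is Klein–Nishina integrated against a
one-parameter screened scattering function $S(x,Z)$ calibrated to the
water incoherent coefficient at 30 keV, the coherent component is a
Thomas–Fermi form-factor integral calibrated to the water coherent
coefficient at 30 keV, and the photoelectric component is defined as
anchor-total minus the two scatter parts, log-log interpolated between
anchors.  Stored totals therefore reproduce the anchors exactly, the
components sum exactly, photoelectric is monotone between edges, and the
silver K edge is represented by adjacent grid points at 25.513/25.515 keV
so no interpolation ever bridges the discontinuity.  Because the dose rate
constant is a water-to-air ratio at nearly the same energies, the dominant
table uncertainties largely cancel where it matters most; the titanium and
silver uncertainties act almost identically on both arms of the ratio.

## TG-43 extraction

* **Geometry function**: $G_L = \beta/(L r \sin\theta)$, with the TG-43U1
  long-axis limit $1/(r^2 - L^2/4)$ at $\theta \in \{0^\circ,
  180^\circ\}$ (needed for the 0° rows of the anisotropy tables) and
  $1/r^2$ for $L = 0$.  Verified against numeric line integration to
  $10^{-6}$.
* **$g(r)$** is normalized to exactly 1 at $r_0$ and fit by an unweighted
  fifth-order polynomial (the source work states no weights; residual
  diagnostics are returned so the choice is auditable).
* **$F(r,\theta)$** is normalized to exactly 1 at 90° per radius; because
  the seed is mirror-symmetric, $\theta$ and $180^\circ - \theta$ are
  averaged onto the 0–90° quadrant.  Per-radius quintic fits use $\theta$
  in radians so $p_0$ approximates $F(r,0)$.  Published fit coefficients
  beyond $p_0$ are not sign-consistent with $F(r,90^\circ)=1$ under any
  obvious angle unit, so the package fits its own coefficients and only
  $p_0$ is used for comparison (our fit of the published 0.7 cm column
  returns $p_0 = 0.298$, matching the published value).
* **$P_{phant}$**: both phantom runs score dose to a *water-equivalent
  detector* ($\mu_{en}/\rho$ of water), so the ratio is a pure
  phantom-material correction; detector (LiF) energy response belongs to
  the TLD chain.  At these energies PMMA attenuates slightly *less* per cm
  than water (0.409 vs 0.431 cm$^{-1}$ at 27.5 keV) and has ~15% higher
  electron density, so doses in the PMMA phantom exceed water at depth and
  $P_{phant}$ falls below 1, increasingly with distance (to roughly one
  half by 10 cm on the transverse axis).
* **Reconstruction** uses the quintic for $g$ when coefficients exist
  (table log-linear interpolation otherwise) and bilinear interpolation in
  $(r,\theta)$ for $F$ on the folded quadrant; queries beyond the table
  error unless extrapolation is explicitly allowed (then clamped).

## The synthetic TLD arm

The generator emulates the measurement campaign, not the TLD physics: no
glow curves, annealing or fading.  Ground truth is a `tg43_dataset` — for
self-contained studies the bundled `reference_dataset()` built from the
published characterization (with a smooth synthetic $P_{phant}$ surface,
labelled as such) — and readings are

reading = [true PMMA dose rate at the (jittered) hole] × [decay-weighted
exposure time] × [relative energy response 1.14/1.17] / [true calibration
slope] × [lognormal repetitive error].

* **Phantom I** (Λ and $g(r)$): seed axis perpendicular to the slab; 21
  holes, one per radius (0.5, 0.7, 1–10 cm), each successive hole rotated
  5° in azimuth so no dosimeter shadows another — all on the transverse
  plane.  **Phantom II** ($F$): radii 0.5–7 cm, angles 0–350° in 10° steps
  (at 0.5 cm, 20° steps through the odd multiples of 10° so the folded
  quadrant includes 90°).  Inter-dosimeter shadowing is not modelled (it
  cancels in the $F$ normalization and the spiral layout avoids it in
  phantom I).
* **Noise structure** mirrors how each budget component actually enters a
  campaign: repetitive reading noise (CV 4.5%) per reading; hole-position
  radial jitter drawn once per phantom instantiation (machining errors are
  frozen into a phantom), with $\sigma_r = 0.035/2.1$ cm chosen so the
  induced dose CV at 1 cm is 3.5% given the ~$-2.1$ cm$^{-1}$ log-slope of
  the dose profile there — the induced error then grows automatically
  toward the seed, reproducing the observation that agreement is worst at
  0.5 cm; calibration (2.6%), seed-strength (3.0%) and PMMA-to-water
  conversion (3.0%) factors drawn once per campaign.  All multiplicative
  errors are mean-one lognormal.
* **Decay and units**: half-life 59.4 d and 1 mCi = 1.270 U are vendored
  constants bridging the mCi seed strengths to U.  The default exposure of
  48 h keeps every dose well below the 10 Gy linearity bound of the
  calibration curve while being long enough that decay correction is a
  ~2% effect the chain must (and does) invert exactly.
* **TLD volume**: the 6×1 mm rod is represented by 5 points along its
  axis (orientation differs between the phantoms).  The analysis chain —
  like the original analysis — treats dosimeters as points, so the rod
  introduces a real ~4% systematic at the reference radius.  The
  parameter-recovery tests therefore run the generator with point
  dosimeters: they validate the statistical chain, and the finite-rod
  effect is reported as a known systematic rather than silently absorbed.
* In the noiseless, point-dosimeter limit the analysis chain inverts the
  generator to machine precision (asserted in the tests).  With the
  standard noise magnitudes, 200 replicate campaigns recover Λ with bias
  below 1% and replicate SD of ~6–7.5%, consistent with the 7.6% budget
  total: positioning and the campaign systematics act at full strength on
  Λ while the repetitive component is averaged over the six seeds.

What passing these tests shows about real data is deliberately limited:
the generator draws from smooth truth tables with the stated noise
structure; it cannot reveal TLD physics (fading, supralinearity), phantom
machining biases beyond a radial jitter, or spectral changes of the energy
response with depth.

## Uncertainty budgets

Budgets are named Type A/B components combined in quadrature with no
covariance; totals are displayed with one-decimal half-up rounding (full
precision retained internally).  The bundled measurement budget (seed
strength 3.0, positioning 3.5, calibration 2.6, conversion 3.0, repetitive
4.5; total 7.6%) and MC budget (statistics 3.2, positioning 3.5,
cross-sections 1.5, geometry 2.0, spectrum 0.2, dose deposition 0.5; total
5.4%) reproduce the published tables as printed — including the
positioning line inside the MC budget, which is unusual for a pure
simulation but kept as published.  $\%u_\Lambda = \sqrt{\%u_D^2 +
\%u_{S_K}^2}$.

## Numerical choices

Log-log linear interpolation on all cross-section grids (edge-aware for
silver); R's Mersenne-Twister RNG drives the compiled sampler so a single
integer seed makes every run — including full tallies — bit-for-bit
reproducible (default seed 20170914, sub-seeds for pipeline stages drawn
from the master seed); mid-interval classification for ray tracing with a
$10^{-9}$ cm boundary nudge; rejection sampling for both scatter channels
with iteration caps; quintic fits by QR (`lm.fit`) with explicit
rank-deficiency errors; cells validated disjoint at construction, with
zero-volume cells rejected.

## Known limitations

Collision kerma ≈ dose only holds because no cell is within ~0.1 mm of an
interface; the form-factor and scattering-function models are
one-parameter screening approximations calibrated at 30 keV (their error
is absorbed into the photoelectric component at the anchor energies, so
totals stay exact but the channel split carries a few-percent model
uncertainty); titanium/silver anchors carry ~10–15% uncertainty (largely
cancelling in Λ); interseed attenuation, well-chamber hardware, electron
transport and TLD reader physics are out of scope.  The simulated
$F(r,\theta)$ at $\theta < 20^\circ$ is sensitive to the end-weld model —
a thin hemispherical shell here — and sits well above the published values
at 0–10°, exactly the region where the published MC and measurement also
disagree; comparisons are therefore made at $\theta \ge 30^\circ$.
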