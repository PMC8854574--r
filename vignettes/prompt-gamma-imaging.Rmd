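---
title: "Prompt-gamma Compton imaging with pgcam: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt-gamma Compton imaging with pgcam: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In proton therapy the dose is deposited mostly at the end of the proton
track (the Bragg peak), so small range errors translate directly into
dose delivered to the wrong tissue. Prompt gamma (PG) rays — photons
emitted within about a nanosecond by proton-induced nuclear reactions in
the tissue — are emitted along the beam path with a sharp distal
fall-off that tracks the proton range, which makes them a handle for
*in vivo* range verification. A two-plane Compton camera images them
without mechanical collimation: a photon that Compton-scatters in a
thin *scatter* (S) crystal and is absorbed in a thicker *absorber* (A)
plane defines a cone of possible incidence directions, with apex at the
S interaction, axis through the two interaction points, and half-angle
$\omega$ fixed by the deposited energies through the Compton scattering
law,

$$\cos\omega \;=\; 1 - m_ec^2\!\left(\frac{1}{E_a} -
\frac{1}{E_s+E_a}\right),$$

valid when the photon deposits its full energy across the two planes.
`pgcam` implements the complete chain for studying such a camera at the
desk scale: a simplified photon-transport Monte Carlo with truth
labels, the detector response, coincidence building, event selection, a
machine-learning filter for full-energy events, three image
reconstruction algorithms, and distal fall-off metrics of the beam-axis
profile.

## Geometry and units

Energies are keV, lengths mm, times ns. The lab frame is right-handed
with the proton beam along +Y and the origin at the phantom centre;
"depth" is $y + 100$ mm, so the image frame is centred at a depth of
100 mm. The default scene is a $100\times200\times100$ mm$^3$ water
phantom surrounded by four identical modules facing the lateral
surfaces at a 50 mm standoff (scatter planes 100 mm from the beam
axis). Each module has one monolithic $50\times50\times15$ mm$^3$
scatter crystal and a $2\times2$ array of $50\times50\times25$ mm$^3$
absorber crystals of LaCl$_3$, separated by an adjustable focal
distance $F_d$ (default 15 mm). The $2\times2$ absorber array is
modelled gap-free, and housings, quartz windows and photosensors are
not modelled; the consequences are discussed under *Limitations*.

```{r}
library(pgcam)
scene <- build_scene(list(layout = "phantom", f_d = 15))
scene
```

## The photon-transport model

The simulator stands in for a full Monte Carlo particle-transport code.
It transports photons only, with three interactions:

* **Compton scattering** with the free-electron Klein–Nishina angular
  distribution (sampled by rejection against a uniform envelope — the
  relative cross-section never exceeds its forward value), depositing
  the electron energy locally and continuing the scattered photon;
* **photoelectric absorption**, depositing the remaining energy;
* **pair production** above 1022 keV, depositing $E - 1022$ keV locally
  and launching two back-to-back 511 keV annihilation photons
  (positron range neglected).

Free paths are exponential in the total linear attenuation; the process
is chosen proportionally to the partial coefficients; deposits below
1 keV are ignored and photons below 1 keV are absorbed locally.
Rayleigh scattering, Doppler broadening, electron transport and
bremsstrahlung are **not** modelled.

The phantom is *attenuation-only*: a photon interacting in the water is
removed without re-emission (a configurable budget of in-phantom
Compton scatters exists for robustness studies, default zero). This
removes the phantom-scatter background whose detailed shape depends on
full transport physics, and it licenses an exact importance-sampling
trick: emission directions can be restricted to fixed cones that cover
each module from every point of the source region, because a photon
aimed elsewhere can never produce a hit. Cone overlaps are removed by
thinning, so the accepted directions are exactly uniform over the union
of cones; the covered solid-angle fraction multiplies all efficiency
estimates. Production runs use this (`direction_bias = TRUE`);
efficiency benchmarks use plain isotropic emission.

Attenuation coefficients are shipped as TSV tables for LaCl$_3$ and
water. They are *synthetic*: the incoherent part is the exact
closed-form Klein–Nishina total cross-section times the electron
density; the photoelectric part is a per-atom power law
($\propto Z^{4.5} E^{-2.53}$) calibrated on standard lead values at 100
and 500 keV; pair production is the residual of standard water total
attenuation anchors, scaled to other materials by their
$\sum Z_i^2/M$. This analytic provenance (rather than a transcribed
compilation) bounds how closely attenuation-sensitive quantities can
reproduce published detector studies, and is the main reason the
package quotes wide tolerances on absolute efficiencies.

## Source model

The default source emulates the PG emission of a ~120 MeV proton pencil
beam stopping in water at a 107 mm range: four discrete lines at
2.3 MeV ($^{14}$N), 4.4 MeV ($^{12}$C), 5.25 MeV ($^{15}$O) and 6.1 MeV
($^{16}$O), each with a piecewise-linear depth-emission profile, a
transverse Gaussian spread of $\sigma = 3$ mm, prompt emission at
$t=0$, and a per-proton PG yield of 0.081 used to convert per-photon to
per-proton efficiencies. The 4.4 and 6.1 MeV profiles carry a
pronounced narrow production maximum just before the end of range over
a slowly varying plateau, and fall to zero at the range; the 2.3 and
5.25 MeV lines are broader without the end-of-range spike. The shapes
are the package's own stylized rendering of proton-induced PG
production (they are not fitted to measured data); the line *energies*,
beam spread, range and yield are the study conditions. Profile sampling
uses the exact inverse CDF of the piecewise-linear density, and
`truth_profile()` integrates the same analytic density over the profile
bins, so generator truth and sampled events share one definition.

The continuum between the lines is not generated; consequences for the
add-back spectrum and classifier evaluation are noted below.

## Detector response

Per history and crystal, deposits are merged to their energy-weighted
centroid (scintillation light cannot separate them), then smeared:

* energy: Gaussian with $\mathrm{FWHM}(E) = 4.5\%\cdot 500\,\mathrm{keV}
  \cdot\sqrt{E/500\,\mathrm{keV}}$ — the $1/\sqrt{E}$ photostatistics
  scaling anchored at the single calibrated point (22.5 keV FWHM at
  500 keV);
* position: per-axis Gaussian of 1.5 mm FWHM, clamped to the crystal;
* time: Gaussian coincidence jitter of 0.5 ns FWHM.

Crystals below the 100 keV threshold (applied after smearing) are
dropped. A coincidence requires the module's S crystal plus at least
one A crystal in the same history; $E_a$ is the add-back sum of that
module's absorber deposits, and the A position is taken from the
highest-energy absorber crystal, which best approximates the first
interaction of the scattered ray (the energy-weighted centroid across
crystals was evaluated and drags the cone axis toward later scatter
sites). The truth full-energy label is set when the *pre-smearing*
module deposit matches the emitted energy within 1 keV.

## Event selection

`selection_criteria()` applies a time-of-flight window (default
0–10 ns, measured from the proton-bunch emission time to the S hit)
followed by add-back energy windows. The carbon window is
4300–4600 keV; the windows for the other three lines (2200–2450,
5100–5350, 6000–6250 keV) follow the same asymmetric 150–300 keV style
around each peak. Presets: `all_pg` (1–7 MeV), `c12`, `four_lines`.

## Full-energy event classification

Only a fraction of coincidences deposit the photon's full energy; the
rest reconstruct a wrong cone angle. A gradient-boosted tree classifier
(140 trees, depth 4, minimum split loss 0.1, logistic output, decision
threshold 0.5) is trained per add-back energy bin (14 uniform bins over
200–7000 keV) on class-balanced samples, using the ten features a real
measurement provides: the two 3-D interaction positions in module-local
coordinates, $E_s$, $E_a$, the Compton angle from the energies, and the
Klein–Nishina probability of that angle at $E_\gamma = E_s + E_a$.
Features are standardized per bin with training-set statistics stored
in the model. Training data come from a dedicated geometry: uniform
200–7000 keV emissions from random positions in a 200 mm cube placed
50 mm from a single module's face. Kinematically invalid events are
excluded from training and scored 0 when classifying; bins with fewer
than 2000 events per class fall back to pass-through with a warning.

Desk-scale training uses on the order of $10^8$ emitted photons
(roughly $10^4$ events per class per bin); discrimination was observed
to saturate well below the configurable per-class cap of $5\times10^4$.
Only the boosted-tree family is provided; a feed-forward network
alternative would need a deep-learning backend that the package does
not depend on, and published comparisons report nearly identical
performance for this task.

A caution on evaluating the filter: the *purity gain*
(full-energy purity after / before selection) depends strongly on the
purity of the evaluation set — for a selector with sensitivity $s$ and
false-positive rate $f$ on a set with before-purity $p$ the gain is
$s/(ps + (1-p)f)$, which approaches 1 as $p \to 1$ no matter how good
the selector is. Add-back bins whose background is absent by
construction (the top bin of a spectrum whose emission stops at 7 MeV,
or a bin centred on a strong line of a discrete-line source) therefore
report gains near 1 that say nothing about the classifier. The
package's acceptance quantity is the overall gain across the 1–7 MeV
range of a held-out sample of the training distribution.

## Image reconstruction

All three algorithms consume the same cone list (apex at the S hit,
axis from the A hit toward the S hit, half-angle from the energies;
kinematically invalid events dropped) and fill a 2-D image grid. For
each module the image plane contains the beam axis and is parallel to
the module's detection planes ($x=0$ for modules facing the $x$
surfaces, $z=0$ for the others); modules sharing a plane pool their
events, and beam-axis profiles sum the planes' projections. Defaults:
$200\times200$ mm$^2$, $200\times200$ pixels (1 mm pitch); desk-scale
reconstructions in the tests use $100\times100$ pixels.

A geometric point that applies to the angular kernels: a cone is a
*direction-space* object, and evaluating an angular kernel on a plane
of pixels without the solid-angle-to-area Jacobian
$|\cos\beta|/r^2$ (with $r$ the apex–pixel distance and $\beta$ the
angle to the plane normal) systematically over-weights pixels far from
the apexes; with sources extended along the beam this pulled every
reconstructed maximum proximally by 10–15 mm. Back-projection and the
analytical algorithm therefore apply this Jacobian by default
(`area_weight = TRUE`), making the image an emission density per unit
plane area.

**Back-projection (BP).** Each pixel receives
$\exp(-\Delta\theta^2/2\sigma^2)$, where $\Delta\theta$ is the angular
distance between the apex→pixel ray and the cone surface
($\sigma = 1^\circ$ by default), weights are normalized to unit sum per
event, and events accumulate. An event whose cone leaves less total
kernel mass on the grid than about one fully-hit pixel
(`min_total = 1`) is treated as missing the plane and dropped — the
normalization would otherwise blow boundary-clipped cones up into edge
spikes.

**Stochastic origin ensemble (SOE).** Each event is first assigned a
uniform pixel of its *cone band* (pixels within
$\delta\theta = 1.5^\circ$ of the cone surface; bands smaller than 25
pixels are boundary-clipped artifacts and are dropped). Each iteration
then proposes, for as many randomly chosen events as there are events,
a uniform pixel of that event's band, accepted with probability
$\min\!\big(1, (\lambda'+1)/\lambda\big)$, where $\lambda$ counts the
occupancy of the current pixel including the moving event and
$\lambda'$ that of the proposed pixel excluding it. Total occupancy is
conserved exactly at every step. The image is the occupancy *averaged
over the post-burn-in iterations* (default: the second half): a single
final snapshot is one draw of a Markov chain and carries clumping noise
that makes the profile argmax erratic. At desk-scale statistics
(10–20k events on a $100\times100$ grid) the chain is demonstrably not
yet stationary after 1000 iterations — the density still drifts toward
the emission maximum for several thousand more — so `n_iter` should be
raised when the iteration budget is not itself the study condition.

**Analytical algorithm (AA).** The series inversion

$$f(\vec s) = \sum_{\text{events}}\ \sum_{n=0}^{N_{max}}
\frac{2n+1}{4\pi H_n(E_\gamma)}\,P_n(\cos\omega)\,
P_n(\hat s\cdot\hat t),
\qquad
H_n(E) = \int_{\cos\omega_{max}}^{\cos\omega_{min}}
\sigma(E,\cos\omega)\,P_n^2(\cos\omega)\,d\cos\omega,$$

with $\hat t$ the cone axis, $\hat s$ the apex→pixel direction,
$\sigma$ the Klein–Nishina differential cross-section and $P_n$ the
Legendre polynomials (Bonnet recurrence). $H_n$ is precomputed by
fixed-order Gauss–Legendre quadrature (order $\ge 2N_{max}+2$, exact
for the polynomial factor) on a 50 keV energy grid over 200–7000 keV
and interpolated linearly in energy; tables can be cached to disk and
regenerate bit-identically. $N_{max} = 70$ by default. Raw pixel values
may be negative; `clip_image()` provides the display view, and profile
projection clips by default.

The angular limits $[\omega_{min}, \omega_{max}]$ are the minimum and
maximum Compton angles the system can register. With 100 keV
per-crystal thresholds and multi-MeV photons these are wide: a 4.4 MeV
photon leaving just 100 keV in the scatter plane scatters by only
$4.2^\circ$, and a near-backscatter leaves the absorber threshold at
$\sim172^\circ$. The defaults are therefore $[4^\circ, 172^\circ]$;
narrowing them to a mid-range window discards the forward-scattering
bulk of high-energy events and visibly degrades the reconstruction.
Events outside the limits or the table's energy range are skipped and
counted.

Ties in image argmaxima resolve to the lowest linear pixel index; all
stochastic steps consume R's global generator, so `set.seed()` makes
every reconstruction reproducible.

## Profiles and fall-off metrics

`project_profile()` sums an image transverse to the beam axis and
rebins to 2.5 mm (the pitch that limits the accuracy of the maximum
position), conserving total intensity for full-band projection. The
full transverse width is the function default; the pipeline and the
acceptance analyses integrate only a 12 mm band centred on the beam
axis — the $\pm2\sigma$ envelope of the 3 mm pencil beam — because the
emission lives there while reconstruction background does not.
`falloff_metrics()` reports the maximum (centre of the maximal bin,
lowest-index tie-break) and the F90/F80/F50 positions, scanned distally
from the maximum and linearly interpolated between bin centres at the
first crossing below the corresponding fraction of the maximum; a
profile that never falls below a level reports that metric as absent.
Metrics are invariant under positive rescaling, and the positions are
ordered $F_{90} \le F_{80} \le F_{50}$ along depth.

## Reproducibility and problem sizes

Every stochastic stage draws from R's global generator; the pipeline
fans one run seed out to fixed per-stage child seeds, so stages are
individually reproducible. The desk-scale study conditions used
throughout the tests and the acceptance script are: $2\times10^5$
isotropic histories for point-source efficiencies; $4\times10^7$
direction-biased histories per phantom production run (over
$2\times10^4$ carbon-window coincidences); $1.5\times10^8$ histories
for classifier training; $100\times100$-pixel reconstructions with
1000 SOE iterations and $N_{max} = 70$.

## Limitations

* **Full-energy fractions run high.** Without passive materials
  (housings, windows), electron/positron escape, bremsstrahlung and
  fluorescence X-ray escape, fewer channels convert full deposits into
  partial ones, so the fraction of full-energy coincidences exceeds
  what a full transport simulation of a real detector predicts, at all
  energies. Absolute efficiencies are less affected (the geometry and
  the Compton part of the attenuation dominate, and the Compton part is
  exact).
* **Line-only source.** The PG continuum is not generated, so add-back
  regions between the lines are populated only by partial deposits,
  and per-bin classifier metrics there are not comparable to a
  continuous-spectrum study.
* **BP maxima are weakly determined.** The back-projected profile of an
  extended beam-line source is flat to within a percent over tens of
  mm around its maximum; the argmax of such a profile is not a robust
  range observable (the sharper SOE and AA profiles are).
* **Attenuation tables are analytic approximations**, as described
  above.
* The SOE stationarity caveat at 1000 iterations, above.
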