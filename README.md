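# pgcam — two-plane Compton camera toolkit for prompt-gamma range verification

Proton therapy deposits most of its dose at the end of the proton track
(the Bragg peak), so verifying the proton *range* in the patient is the
key safety problem of the modality. Prompt gamma (PG) rays — photons
emitted within a nanosecond by proton-induced nuclear reactions along
the track — fall off sharply at the end of the range and can be imaged
without mechanical collimation by a Compton camera: a photon that
scatters in a thin position-sensitive **scatter** (S) crystal and is
absorbed in an **absorber** (A) plane constrains its origin to a cone
with apex at the S interaction, axis through the two interaction
points, and half-angle ω given by the Compton scattering law

    cos ω = 1 − m_e c² (1/E_a − 1/(E_s + E_a)),

valid for events that deposit their full energy across the two planes.

`pgcam` implements, in R with compiled kernels, the complete analysis
chain for a four-module two-plane camera around a water phantom:

* a simplified photon-transport Monte Carlo (Klein–Nishina Compton
  scattering, photoelectric absorption, pair production; an
  attenuation-only phantom) producing truth-labelled scatter–absorber
  coincidences;
* the detector response (4.5% FWHM energy resolution at 500 keV with
  1/√E scaling, 1.5 mm FWHM 3-D position resolution, 100 keV
  per-crystal thresholds, 0.5 ns coincidence timing);
* time-of-flight and add-back energy-window event selection;
* a gradient-boosted classifier that identifies full-energy events from
  the ten measured features of each coincidence;
* three image-reconstruction algorithms — cone back-projection (BP),
  the stochastic origin ensemble (SOE, Metropolis reassignment of event
  origins on their cones with density-ratio acceptance
  min(1, (λ′+1)/λ)), and the analytical spherical-harmonics inversion
  (AA) with precomputed Klein–Nishina angular moments
  H_n(E) = ∫ σ(E, cos ω) P_n²(cos ω) d cos ω;
* beam-axis depth profiles with distal fall-off metrics (maximum
  position and the linearly interpolated F90/F80/F50 crossings).

The methods vignette (`vignettes/prompt-gamma-imaging.Rmd`) documents
the models, defaults and design choices in detail.

## Worked example

A point-like 1 MeV source 50 mm from a single module, the geometry used
to quote the camera's coincidence efficiency:

```r
library(pgcam)
set.seed(42)
scene <- build_scene(list(layout = "point", f_d = 15, standoff = 50))
src   <- source_model("point", position = c(0, 0, 0), energy = 1000)
sim   <- run_simulation(scene, 2e5, source = src)
sim
#> <pg_simulation> 2e+05 histories, 642 S&A coincidences
#>   efficiency per emitted photon: 3.210e-03 +/- 1.3e-04
mean(sim$events$full_energy)   # fraction of full-energy coincidences
#> 0.609

ev  <- sim$events[sim$events$full_energy, ]
img <- backproject(ev, image_grid("yz", pixels = 100))
image_argmax(img)[c("u", "v")]
#> $u
#> [1] 1
#> $v
#> [1] 1
```

Out of 2×10⁵ emitted photons, 642 produce a scatter–absorber
coincidence — a coincidence efficiency of 0.32%, the order expected for
a two-plane module with large monolithic crystals at 5 cm. About 61% of
those coincidences deposit the full 1 MeV (the toy transport omits
passive materials and electron escape, so this runs above what a full
detector simulation gives), and back-projecting their cones onto the
image plane recovers the source position to within one 2 mm pixel.

The full phantom pipeline — simulate, select, classify, reconstruct
with all three algorithms, and compare fall-off metrics against the
generator truth — is one call:

```r
res <- pipeline_run(pipeline_config(n_histories = 2e6, classifier = FALSE),
                    seed = 1, out_dir = "run1")
res$report$aa   # signed deviations (mm) of Max / F90 / F80 / F50
```

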