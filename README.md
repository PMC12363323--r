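# nasodose

Reduced-order modelling of intranasal spray targeting of the nasopharynx.

The nasopharynx — at the back of the nose, just past the merger of the two
nasal passages — is the dominant initial infection site for SARS-like
respiratory viruses and the natural target for sprayed antivirals and
vaccines. Standard package-insert technique ("Current Use", CU) holds the
bottle almost upright, and because sprayed droplets leave the nozzle at
~10 m/s their inertia carries most of the dose into the anterior nose.
Re-aiming the nozzle almost horizontally through the nasopharynx, slightly
toward the cheek ("Improved Use", IU), changes where the ballistic phase of
each droplet ends and can improve targeted delivery by orders of magnitude.

`nasodose` implements that analysis as an R package:

* **Transport simulator** — Lagrangian tracking (compiled RK4 core) of
  solid-cone spray releases (3,000 monodispersed droplets per diameter,
  1–24 µm, 10 m/s, 27.93° half-angle, 5 mm insertion, 1.5 g/mL) under
  Stokes drag with Cunningham slip, gravity and Saffman lift, in a
  parametric idealized nasal passage (entrance bend → near-horizontal
  barrel → nasopharyngeal down-turn, 90° total) with an analytic
  mass-conserving laminar flow field at 15 or 30 L/min. Output:
  nasopharyngeal deposition-efficiency curves per droplet diameter.
* **Stokes scaling** — the constant-Stokes-number law
  `D2 = D1 * sqrt(Q1/Q2)` (with an optional slip-corrected solve)
  projecting ideal droplet size ranges between inhalation rates.
* **Spray products** — log-normal mass distributions
  `m(x) = exp(-(ln x - ln x50)^2 / (2 ln^2 sigma_g)) / (sqrt(2*pi) x ln sigma_g)`
  with mass/count conversion; Flonase and Nasacort parameter sets built in.
* **Dose analysis** — distribution-weighted per-pump nasopharyngeal
  formulation mass, API (active ingredient) delivery, and the IU-over-CU
  improvement in orders of magnitude.
* **Sensitivity** — the five perturbed spray directions (1-mm circle at
  5 or 10 mm) and Pearson congruity of their deposition curves against the
  base IU curve.
* **Pipeline & fixtures** — a YAML-configured `run_pipeline()`, CSV/JSON
  artifacts, a synthetic deposition-curve generator for fixture-driven
  analysis, and a thin CLI wrapper (`inst/cli/nasodose.R`).

## Worked example

```r
library(nasodose)

aw <- airway_model()                 # idealized passage, 22.5 deg head tilt
fl <- flow_field(15)                 # resting inhalation, 15 L/min

iu <- deposition_curve(aw, fl, iu_axis(aw), 1:24, n_droplets = 500, seed = 42)
cu <- deposition_curve(aw, fl, cu_axis(aw), 1:24, n_droplets = 500, seed = 42)

print(project_range(size_range(5, 11, flow_lpm = 30), 15))
#> Ideal size range @ 15 L/min: [7.07, 15.56] um (cutoff 2.0%)

prod <- product_registry("Flonase")
est_iu <- delivery_estimate(prod, iu)
est_cu <- delivery_estimate(prod, cu)
print(est_iu)
#> Flonase, IU protocol @ 15 L/min: 14.5308 mg formulation, 7.3 mcg API per pump
print(est_cu)
#> Flonase, CU protocol @ 15 L/min: 3.8148 mg formulation, 1.9 mcg API per pump
improvement_oom(est_iu, est_cu)
#> [1] 0.5808557
```

Reading the output: projecting the `[5, 11]` µm ideal range identified at
30 L/min down to 15 L/min by the Stokes law gives `[7.07, 15.56]` µm — at
gentler inhalation, larger droplets become ideal. The per-pump estimates
weight each simulated curve by the Flonase droplet-mass distribution over
the 1–24 µm window: with this idealized single-tube geometry the improved
orientation delivers ~3.8× (0.58 orders of magnitude) more formulation to
the nasopharynx than the upright orientation. Absolute magnitudes depend
on anatomy — subject-specific CT-based studies report 2+ orders of
magnitude — but the direction and mechanism of the effect (upright axes
deposit anteriorly, shallow axes thread the passage) are reproduced; see
the methods vignette (`vignettes/nasodose-methods.Rmd`) for what the
idealization does and does not claim.

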