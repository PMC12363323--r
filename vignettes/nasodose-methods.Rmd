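---
title: "Modelling intranasal spray targeting of the nasopharynx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intranasal spray targeting of the nasopharynx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nasodose)
```

## The problem

The nasopharynx — the region at the back of the nose, just past the merger
of the two nasal passages — is the dominant initial site of infection for
SARS-like respiratory viruses, and therefore the natural target for sprayed
antivirals, vaccines and hygiene products. Package inserts for commercial
nasal sprays recommend holding the bottle almost upright ("current use",
CU). Because sprayed droplets leave the nozzle at around 10 m/s and are
inertia-dominated, an upright axis drives most of the formulation into the
anterior nose, far short of the target. Re-orienting the nozzle to a much
shallower, nearly horizontal axis aimed through the nasopharynx and
slightly toward the cheek ("improved use", IU) changes where the ballistic
phase of each droplet ends and can improve targeted delivery by orders of
magnitude.

`nasodose` implements that analysis as a tested pipeline:

1. a reduced-order Lagrangian droplet simulator in an idealized nasal
   passage (replacing the CT-based geometry + large-eddy airflow layer of a
   full CFD study),
2. the analysis layer defined on top of deposition-efficiency curves:
   Stokes-number scaling of ideal droplet size ranges across inhalation
   rates, log-normal spray-product size distributions,
   distribution-weighted per-pump nasopharyngeal dose and API (active
   pharmaceutical ingredient) delivery, the IU-over-CU improvement in
   orders of magnitude, and a spray-axis perturbation sensitivity analysis.

The central exchange format is the *deposition curve*: the fraction of a
3,000-droplet monodispersed release of each diameter (1–24 µm) that
reaches the nasopharynx, per spray protocol, inhalation rate and passage
side. Everything downstream consumes such curves, whether simulated,
loaded from CSV, or generated synthetically.

## The idealized airway

Real airway anatomies cannot be shipped with a package; the simulator
instead uses a parametric curved tube whose design captures the one
geometric fact the CU-vs-IU contrast depends on: the nasal passage is a
*bent duct*, entered steeply from below through the nostril, running
nearly horizontally through the main cavity, then turning downward into
the nasopharynx.

The centerline is a convex planar curve parameterized by arc length
fraction $s \in [0,1]$, with tangent elevation above the horizontal
interpolated linearly between control points; the default profile is
$45^\circ \to 12^\circ \to 5^\circ \to -45^\circ$ at
$s = 0, 0.12, 0.8, 1$: a $90^\circ$ total turn from an upward-posterior
nostril to a posterior-inferior outlet. A uniform-curvature
arc was rejected: with a $90^\circ$ turn over a 10 cm centerline its chord
deviates from the tube by ~19 mm, so no straight spray axis can thread a
~6 mm lumen, and the upright CU axis ends up the *best*-aligned direction —
the opposite of the anatomy being idealized. With the entrance-bend /
barrel / down-turn profile, the upright axis overshoots into the anterior
roof while a shallow axis threads the barrel, which is the mechanism the
analysis studies.

The tube radius follows a piecewise-linear profile (default 5.5–7 mm,
narrowest at the nasal-valve region $s \approx 0.12$), giving mid-passage
cross-sections of roughly 1.3 cm² and transit speeds of 2–4 m/s at
15 L/min — plausible for an adult main nasal passage. Named regions
partition $s$: vestibule ($<0.10$), anterior, mid, and nasopharynx
($\ge 0.85$). The model is inclined 22.5° forward (the recommended head
tilt), which fixes how laboratory gravity and the "vertical" CU bottle map
into the model frame. All dimensions are free parameters of
`airway_model()`; no subject-specific measurements are claimed.

The inhaled airflow is an analytic quasi-one-dimensional laminar field: a
parabolic (Poiseuille) axial profile on every local cross-section, scaled
so each section carries exactly the inhalation rate $Q$ (15 L/min for
resting breathing, 30 L/min for moderately heavy breathing). 15 L/min is
genuinely laminar in nasal airways; at 30 L/min a full study would resolve
turbulence, which is out of scope here — the same laminar profile is used
and the limitation acknowledged.

## Droplet transport

Each release is a solid-cone injection: `n_droplets` (default 3,000)
monodispersed droplets from the nozzle tip (5 mm beyond the nostril-plane
anchor), directions uniform over the solid angle of a 27.93° half-angle
cone, all at 10 m/s, formulation density 1.5 g/mL. Per droplet the
equation of motion integrates Stokes drag with Cunningham slip
($\tau = \rho_D D^2 C_c / 18\mu$; Millikan-fit
$C_c = 1 + \tfrac{2\lambda}{D}(1.257 + 0.4 e^{-1.1 D/2\lambda})$),
gravity, and Saffman–Mei shear lift (generalized Li–Ahmadi form,
$K = 2.594$) on the analytic radial shear of the parabolic profile. Air
properties are $\rho = 1.204$ kg/m³ and $\mu = 1.825\times10^{-5}$
kg/(m·s); coupling is one-way (droplets do not alter the air), Brownian
motion and evaporation are neglected — justified at the
$O(10^{-1})$ s time scales of direct nasopharyngeal transport.

Integration is classical RK4 with a $10^{-4}$ s flow time-step over a
0.25 s horizon. The drag term is stiff for micrometre droplets
($\tau \approx 5\,\mu$s at 1 µm), so each flow step is subdivided per
diameter into $h \le 2\tau$ sub-steps, keeping RK4 inside its stability
region; the still-air settling tests verify the closed-form terminal
velocity $v_t = \tau g$ to better than 1% across 1–24 µm. Wall contact is
a trap condition: when a sub-step crosses the lumen surface the crossing
is refined by bisection to $10^{-6}$ m and the droplet is assigned the
region at the crossing. Droplets crossing the outlet plane are *escaped*;
droplets leaving back through the nostril are counted separately and never
as deposition.

Nasopharyngeal delivery for a curve is **trapped in the terminal band plus
escaped through the outlet**, matching the bench-experiment convention in
which a printed cast terminates just before the nasopharynx and outflow is
collected as nasopharyngeal delivery. One visible consequence: in a single
smooth tube, low-inertia droplets (≲ 8 µm) simply ride the flow out of the
outlet, so simulated curves are *high* at small diameters for both
protocols rather than single-peaked as in a convoluted real anatomy, where
much of the fine fraction deposits on turbinate walls or continues to the
lungs past a nasopharynx-plane outlet. The properties the simulator is
relied on for — droplet conservation, terminal-velocity agreement, the IU
total exceeding the CU total at both flow rates, and the anterior shift of
large droplets — hold and are tested; the figure-style single-peaked /
near-zero curve *shapes* are provided by the synthetic fixture generator
when downstream code needs them. Passing tests therefore demonstrate the
direction and mechanism of the protocol effect, not subject-specific
deposition percentages, which would require the CT/LES layer.

Reproducibility: every (curve, diameter) pair derives its own seed from
the base seed, so curves are independent of execution order, and identical
(seed, configuration) runs are bitwise identical.

## Spray axes and their validation

* `cu_axis()` — vertical in the laboratory frame, anchored at one third of
  the lateral-to-septal distance from the lateral wall, inserted 5 mm.
* `iu_axis()` — from the nostril-plane centroid toward a point in the
  nasopharyngeal band offset toward the cheek (default: half the local
  radius laterally).
* `validate_iu_axis()` — the three placement criteria: (i) the extended
  axis reaches the nasopharyngeal sector, (ii) it does not cut the septal
  plane while inside the airway, (iii) its first wall intersection is
  posterior and lateral (or it leaves via the outlet). Criterion (i) is
  evaluated by nearest-point projection of the marched ray without a
  radial bound; the discriminating power against upright axes comes from
  (iii).

The sensitivity construction perturbs the IU axis through five points
equally spaced (72° apart) on a 1 mm circle perpendicular to the axis at 5
or 10 mm from the centroid — tilts of 11.31° and 5.71°. In a real nasal
cavity (~30 mm tall) all five perturbed axes remain anatomically valid; in
a ~6 mm tube the downward- and medial-tilted ones can exit anteriorly, so
validity is *reported per criterion* rather than assumed, and the
congruity statistic (Pearson r between each perturbed curve and the base
curve, two-sided p from the t-transform on $n-2$ df, with an exact
permutation option) is computed for all five regardless. In the default
geometry the median r across perturbed directions is ≈ 0.9 at full scale —
the improved orientation is robust to user tilt, the study's qualitative
sensitivity finding.

## Stokes scaling

The Stokes number $St = U \rho_D D^2 C_c / (18 \mu d)$ compares droplet
response time to the flow time scale through a flux section of diameter
$d$ and mean speed $U = Q/\text{area}$. Holding geometry fixed, equal
Stokes numbers at two inhalation rates give the projection
$D_2 = D_1\sqrt{Q_1/Q_2}$. `scale_diameter()` implements this law exactly
as printed (slip factor cancelled); because $C_c$ is in truth
size-dependent, `scale_diameter_slip()` also solves the full
$St$-equality numerically with the Cunningham factor — the two agree to
well under 1% at spray-relevant sizes and are reported side by side.
Projecting the $[5, 11]$ µm ideal range identified at 30 L/min down to
15 L/min gives $[7.07, 15.56]$ µm; scaling a 24 µm limit by $\sqrt{2}$
gives 33.94 µm. (The source text labels that last projection with the
higher flow rate even though the law, taken literally with
$Q_1 = 30 \to Q_2 = 15$, produces it at the lower rate; the implementation
follows the law as written and does not guess intent.) Display rounding is
two decimal places in µm.

Ideal ranges themselves come from `ideal_size_range()` — the diameters
achieving at least 2% nasopharyngeal deposition — and `generic_range()`
pools several cases by averaging the per-case minima and maxima.

## Products, dose and improvement

Droplet sizes in a sprayed shot follow a log-normal mass density
$$m(x) = \frac{1}{\sqrt{2\pi}\, x \ln \sigma_g}
  \exp\!\left(-\frac{(\ln x - \ln x_{50})^2}{2\ln^2\sigma_g}\right),$$
parameterized by the mass median diameter $x_{50}$ and geometric standard
deviation $\sigma_g$. Two measured over-the-counter products ship with the
package: Flonase ($x_{50} = 37.16$ µm, $\sigma_g = 2.080$, 104.51 mg per
pump, 50 mcg API per 100 mg) and Nasacort ($x_{50} = 43.81$ µm,
$\sigma_g = 1.994$, 97.64 mg per pump, 55 mcg per 110 mg). Interval
masses use the closed form through the log-normal CDF; the hand-written
density is cross-checked against adaptive quadrature to $10^{-8}$.
Count–mass conversion assumes spherical droplets at the 1.5 g/mL
formulation density, dividing the mass density by $x^3$ and normalizing
over a stated window (default the tracked 1–24 µm).

The per-pump nasopharyngeal dose weights a deposition curve by the product
mass density:
$$m_{dep} = M_{shot}\int_1^{24} \eta(x)\, m(x)\, dx,$$
with $\eta$ linearly interpolated between the integer-micron grid points
and zero outside 1–24 µm (droplets larger than that deposit mostly
anteriorly; the window is configurable). API mass is dose times
concentration; the printed-style report rounds to two *significant*
figures, which is the convention that reproduces all four published-style
reference values (0.96, 0.025, 0.92, 0.024 mcg) — fixed two-decimal
rounding does not. The improvement statistic is
$\log_{10}(m_{dep}^{IU}/m_{dep}^{CU})$ per matched case, summarized by the
sample mean and ($n-1$) standard deviation; zero-CU cases are flagged
infinite and excluded with a warning.

## Synthetic fixtures

`curve_template()` / `make_curve()` generate deposition curves as a single
Gaussian bump (peak height, peak diameter, width) plus truncated Gaussian
noise, clipped to $[0,1]$ — the shape of improved-orientation curves in
the source figures, with defaults at the reported peaks (46.5% at 13 µm
for IU; 0.53% at 14 µm for CU). This is a fixture choice, not a physics
claim: it lets the dose, improvement and correlation layers be exercised
deterministically and at closed-form expectations (e.g. two identical
shapes with a 100× peak ratio must give exactly 2.0 orders of magnitude).
`make_case_set()` jitters the templates into matched IU/CU pairs emulating
a multi-case study (the source design had 2 subjects × 2 nostrils × 2
flow rates = 8 cases).

## Numerical choices and problem sizes

* Centerline geometry is tabulated at 1,025 nodes; nearest-point location
  uses monotone bisection on the convex curve with a warm-start index per
  droplet. Flux conservation holds to $10^{-11}$ relative at every tested
  station (tolerance $10^{-6}$).
* Wall-crossing bisection stops at $10^{-6}$ m of segment length.
* Quadratures (`integrate`) run at relative tolerances of $10^{-10}$ to
  $10^{-12}$; interval mass fractions use the closed form.
* Degenerate inputs: zero cone angle collapses to the axis; zero CU dose
  flags infinite improvement; constant curves flag undefined correlation;
  empty ideal ranges are flagged, never silently dropped.
* The test suite runs the simulator at reduced cloud sizes (150–500
  droplets per diameter) chosen so the full suite completes in a couple of
  minutes while the tested contrasts remain far outside sampling noise;
  the acceptance script `scripts/acceptance.R` runs the sensitivity
  analysis at the full study scale (3,000 droplets per diameter across
  1–24 µm for the base and all five perturbed axes).

## Known limitations

* One idealized passage, not subject-specific anatomy: absolute
  deposition percentages are not comparable to CT-based results, only
  directions of effect and the analysis layer are.
* Laminar quasi-1D flow at both inhalation rates; no turbulence, no
  secondary flows in bends.
* No mucociliary clearance, evaporation, wall films, or droplet breakup;
  trapped droplets stay where they land.
* The left/right distinction is a mirror flag only.
* Perturbed-axis validity is geometry-limited in the slender tube (see
  above); the congruity statistic is unaffected.
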