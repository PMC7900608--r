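---
title: "Scar shape, simulated re-entry, and arrhythmic risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scar shape, simulated re-entry, and arrhythmic risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`lgerisk` implements a three-stage analysis of late gadolinium enhancement
(LGE) scar in nonischemic dilated cardiomyopathy:

1. **Morphometry** — six shape metrics computed per patient from segmented
   short-axis slices: interface area, volume, intensity entropy, mean
   transmurality, number of 4-connected components, and mean radiality.
2. **In-silico electrophysiology** — each slice is meshed into a 2D
   triangular finite-element model, scar microstructure is imposed by
   percolation, and a programmed electrical stimulation (PES) protocol
   attempts to induce re-entry; the per-patient count of induced
   re-entries becomes a seventh metric.
3. **Survival analysis** — entropy-balancing inverse-probability weights
   (IPW) decorrelate a target metric from baseline confounders, followed
   by weighted Cox regression with robust standard errors, a time-varying
   ICD model, tercile stratification, Kaplan-Meier curves and log-rank
   tests.

A synthetic-data module generates annular slices with controllable scar
patterns and confounded proportional-hazards cohorts so every stage is
testable end to end without patient data.

# Image model and geometry

Slices are row-major logical grids with isotropic in-plane spacing; pixel
centers sit at `(i - 0.5, j - 0.5) * spacing` and all geometry (angles,
chords, mesh nodes) derives from pixel centers. Masks round-trip through
0/255 PNG; intensities are stored as plain-text TSV so the round trip is
exact at double precision. The pipeline processes exactly the slices
present in a stack; deciding which slices qualify for analysis is the data
preparer's job.

# The six shape metrics

**Interface area.** The arc length of the border between LGE and surviving
myocardium internal to the myocardium, times slice thickness, summed over
slices. The border is measured as the number of 4-adjacent pixel pairs
with one pixel in LGE and one in non-LGE myocardium, times the pixel
spacing — the pixel-edge (Manhattan) boundary. This choice is exact,
orientation-consistent under 90° rotations, and directly checkable against
a brute-force pair-counting oracle; a smoothed-contour measure would be
systematically shorter (by 4/π for diagonal borders) but adds an arbitrary
smoothing scale. Borders against blood pool, background, or the
endo/epicardial surface contribute nothing — scar touching the surface
*loses* interface, which is the property that distinguishes this metric
from volume.

**Volume.** Pixel count × spacing² × thickness.

**Entropy.** Shannon entropy (bits) of the pooled LGE pixel intensities in
B = 32 equal-width bins spanning their range. The histogram convention was
an open choice; 32 bins on the enhanced region reproduces the magnitude
(~3.6 bits) conventionally reported for this quantity, and the limiting
behaviour (0 for constant intensity, log₂B for uniform) is tested.

**Mean transmurality.** K = 180 radial chords are cast from the blood-pool
centroid; each chord is sampled every 0.25 mm with nearest-pixel lookup;
chord transmurality is LGE extent over wall extent, averaged over chords
that cross LGE, then over slices containing LGE. This is the standard
clinical chord definition; the tests include a convergence check (doubling
K changes smooth-pattern values by < 0.01) and an analytic mid-wall band
whose value must be 0.5 ± 0.02.

**Components.** 4-connected regions per slice (two-pass union-find),
summed. Diagonal contact does not connect.

**Radiality.** The circular variance `1 − ‖mean resultant‖` of LGE pixel
angles about the blood-pool centroid, in [0, 1]: 0 when all scar sits at
one angle, 1 for angularly balanced scar. A bounded variance is consistent
with the reported population range (0.35 ± 0.18) of this metric.

**FWHM segmentation.** Scar = myocardium pixels with intensity at least
half the maximum inside a reference enhanced region. On a constant image
the rule degenerates to the whole myocardium, which is documented rather
than special-cased.

# Finite-element model and percolation

Each myocardium pixel is subdivided into a k × k grid of squares split
into two right triangles, with k = ⌈spacing·√2 / max_edge⌉ so that every
edge, including hypotenuses, respects the 250 μm default bound. Structured
subdivision was chosen over contour-conforming Delaunay meshing because it
is exact (mesh area equals pixel area to rounding), deterministic, and
label inheritance from pixels is unambiguous; the cost is a stair-step
boundary, which at these resolutions is below the scale of the physiology
of interest.

Percolation fibrosis removes each LGE *element* independently with
probability p (default 0.4). Removed elements are excluded from the
assembly entirely — they become internal no-flux boundaries — rather than
assigned zero conductivity, which would make the mass matrix singular.
Element-wise (as opposed to edge-wise) removal reproduces the
source–sink tortuosity that slows and fragments conduction inside scar.

# Monodomain solver

The ionic model is a two-variable phenomenological (Mitchell–Schaeffer
type) model with dimensionless V:

$$\partial_t V = \nabla\cdot(\sigma \nabla V)/(\beta C_m)
 + h V^2(1-V)/\tau_{in} - V/\tau_{out},\qquad
\partial_t h = \begin{cases}(1-h)/\tau_{open} & V < v_{gate}\\
 -h/\tau_{close} & V \ge v_{gate}\end{cases}$$

Defaults: τ_in 0.3, τ_out 6, τ_open 120, τ_close 150 ms, v_gate 0.13 —
a human-ventricle-like action potential (~240 ms) with restitution, the
minimal model that reproduces the mechanism under study: rate-dependent
conduction block at the scar interface. LGE remodeling multiplies
conductivity by 0.25 and τ_close by 1.5 by default, making scar permeable
at slow rates but blocking at short coupling intervals; both factors are
configuration.

Numerics: operator splitting per step with explicit reaction (gates
relaxed by exact exponentials), then an implicit mass-lumped P1 diffusion
solve `(M + Δt K)V = MV*` by Jacobi-preconditioned conjugate gradients
warm-started from the reaction state (a handful of iterations at Δt =
0.05 ms). The implicit step is unconditionally stable, so Δt is set by
reaction accuracy, not the mesh. Every upward crossing of V = 0.5 is
recorded per node; |V| > 2 aborts with a diagnostic. Convergence is
tested: halving Δt moves strip activation times by < 0.5 ms.

Conductivity is calibrated by bisection on a 20 × 5 mm strip until the
planar conduction velocity matches a target (default 0.6 m/s, a standard
human LV bulk value) within 1%. CV ∝ √σ and width-independence are tested
as physics invariants.

# Programmed stimulation and re-entry detection

Per slice realization: two S1 beats at 500 ms, then for each extrastimulus
level (up to two) the coupling interval is scanned downward in 10 ms steps
from 90% of the previous interval until capture fails (the ERP), and the
extrastimulus is delivered at ERP + 5 ms — an aggressive near-ERP
protocol that maximizes the chance of interface block. Capture is decided
by activation of a probe band 4–7 mm from the pacing site within 60 ms.
The pacing site is the endocardial boundary node nearest the angular
position of the scar centroid, so the site is "consistent with respect to
scar" across models. The stimulus covers nodes within 0.5 mm and uses
twice the diastolic threshold found by a doubling scan.

After *every* delivered extrastimulus a 600 ms observation window is
simulated from a checkpointed state; re-entry is declared when (a) some
node activates at least twice in the window and (b) activity outlives
the direct wavefront (an activation later than 250 ms after the
stimulus). Observing after each level, not only the last, prevents a
re-entry induced by S2 from corrupting the S3 scan; the protocol stops
at the first induced re-entry, as clinical PES does. The persistence
threshold excludes direct-wave echoes while catching circulating
activity; both thresholds are configuration.

State checkpointing (snapshots every 5 ms along the drive train) makes
the ERP scan cost linear rather than quadratic in the number of tested
coupling intervals, and quiescence detection ends observation windows
early once all activity has died.

# Desk-scale study conditions

The reference experiments run at sizes chosen once for a single CPU:

- **Controls** (`pes_control_study`): a homogeneous 20 × 10 mm sheet
  (negative: no obstacle, no heterogeneity, no re-entry) and a thin
  asymmetric-refractoriness ring — half an annulus with τ_close doubled,
  paced just outside the long-refractory half — the classic
  unidirectional-block construction (positive). The ring uses τ_close =
  80 ms and CV 0.25 m/s so its ~72 mm circuit exceeds the ~30 mm
  excitation wavelength.
- **Inducibility batch** (`reentry_interface_study`): 10 + 10 single-slice
  patients (stria extent 4.0–5.0 vs 0.9–1.5 rad) on a 4.5/8 mm annulus at
  0.7 mm pixels, 0.5 mm mesh edges, Δt 0.1 ms, CV 0.25 m/s, τ_close
  100 ms, LGE conductivity × 0.1, percolation p 0.4, 10 realizations per
  slice. The annulus circumference (~39 mm) sits just below the healthy
  wavelength (~40 mm), so the bare ring does not re-enter anatomically
  (verified), while percolated scar adds enough conduction delay for
  interface-mediated re-entry; a longer stria offers more interface at
  which block can occur and a longer intramural delay path, which is the
  mechanism the study quantifies directionally (large-interface mean
  re-entries ≥ small-interface mean).

These parameters emulate the mechanism, not the anatomy: absolute
re-entry counts at this scale are not comparable to full-size ventricular
models, which is why the associated acceptance check is directional.

# Synthetic cohort and the recovery experiment

Per patient a latent morphology scale u ~ N(0,1) sets the stria extent
(interface area monotone in u); confounders (age, LVEF, LV mass index,
NYHA III/IV, alcohol excess — synthetic values on realistic scales) are
drawn with correlation ρ to u (default 0.3); event times are exponential
with rate `h₀·exp(β·z_interface + Σγ·z_x)`; censoring is uniform on
(0, 2500) days, giving a ~10% event rate at the default h₀ = 7 × 10⁻⁵/day
— matching the order of the motivating cohort (10.3% events over a
~1600-day median follow-up). ICD assignment follows a logistic rule on
the confounders (~35% implant rate). With β = γ = 0 the event rate has
the closed form `1 − (1 − e^{−λc})/(λc)`, which the tests check at
n = 2000. The generator does not attempt photorealism: no intensity
texture beyond two-level Gaussian noise, no 3D anatomy, no measurement
error in the masks — so passing tests validate the estimators, not the
imaging chain.

For large simulation studies the generator can skip rasterization
(`render_slices = FALSE`) and use the closed-form band geometry for the
interface area (inflated by 4/π to match the Manhattan measure); the two
paths agree in ranking (Spearman > 0.99) and the statistical machinery
never sees the difference beyond scale.

**Coverage experiment.** `cox_recovery_study` generates 100 cohorts of
n = 1000 at HR 1.75 per SD with ρ = 0.4 but γ = 0, fits the weighted
univariate Cox model, and counts CI coverage. γ = 0 is deliberate: hazard
ratios are non-collapsible, so with γ ≠ 0 the marginal (weighted)
estimand differs slightly from the conditional β even under perfect
decorrelation, and a coverage experiment would then test the wrong
identity. With γ = 0 the univariate model is correctly specified, the
weights are still non-trivial (the confounders remain correlated with the
target), and nominal coverage (93–97/100) is the right expectation.

# IPW weights

The decorrelating weights minimize Σ wᵢ log(n·wᵢ) (KL divergence from
uniform) subject to Σw = n and zero *weighted* Pearson correlation
between the target metric and every confounder. Zero weighted correlation
is imposed exactly by three linear moment constraints per confounder
(weighted means of the centered target, centered confounder, and centered
cross-product all zero), so the problem is the classical entropy-balancing
program with a convex dual `log mean exp(λᵀc)`, solved by damped Newton
iteration on standardized constraint columns. The post-condition — every
weighted correlation below 10⁻⁶ — is verified on each call and the
function fails loudly otherwise (perfect target–confounder collinearity is
detected up front as infeasible).

Cox fitting itself (weighted partial likelihood, Efron ties, sandwich
variance, counting-process expansion for time-varying ICD) delegates to
the `survival` package; the tests verify it against a written-out
partial-likelihood oracle and a hand-expanded counting-process dataset, so
the wrapper's contract — per-SD hazard ratios with robust Wald CIs — is
checked independently of the library.

**Terciles.** Nearest-rank cutpoints at 33⅓/66⅔ percent with stable
(value, patient id) ordering, giving group sizes ⌊n/3⌋/⌈n/3⌉ (52/52/52 at
n = 156); indicator HRs versus the lowest tercile come from the same
weighted Cox machinery. No multiplicity correction is applied anywhere;
metrics are reported per-metric.

# Degenerate inputs and tie-breaks

- No LGE: all metrics 0 with a warning flag; no PES outcomes attempted.
- Empty blood pool on a slice with LGE: error (radiality undefined).
- Constant intensity: entropy 0; FWHM returns the whole myocardium.
- Percolation p = 0 / 1: identity / full removal, bit-reproducible per
  (seed, p).
- ERP scan: if the first coupling interval already fails, the scan walks
  upward (capped at 1.5× the previous interval); if delivery at ERP + 5 ms
  does not capture, the last captured interval is used.
- Protocol failures on a slice (S1 non-capture, no capture at any
  interval) are recorded per realization and never silently dropped.

# Known limitations

- 2D slice models with isotropic conductivity; no fiber architecture,
  no 3D, no bidomain, no defibrillation fields.
- The two-variable ionic model reproduces restitution and refractoriness,
  not ionic detail; absolute APD/ERP values are generic.
- The desk-scale inducibility study is directional by design; absolute
  re-entry counts do not transfer to full-size anatomies.
- Real hazard ratios from the motivating clinical cohort are not
  reproducible without the patient data; the survival stage is validated
  by synthetic recovery instead.
- The synthetic cohort draws covariates from simple parametric families;
  it emulates confounding structure, not clinical joint distributions.
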