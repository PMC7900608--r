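# lgerisk

Arrhythmic-risk analysis of late gadolinium enhancement (LGE) scar in
nonischemic dilated cardiomyopathy (NIDCM).

In patients with NIDCM, the *shape* of myocardial fibrosis — not just its
amount — carries prognostic information for ventricular arrhythmia and
sudden cardiac death. The quantity at the core of this package is the
**LGE–myocardium interface area**

> A<sub>int</sub> = Σ<sub>slices</sub> (arc length of the border between
> LGE and surviving myocardium, internal to the myocardium) × slice
> thickness   [cm²],

the surface across which electrically remodeled scar abuts excitable
tissue. Mechanistically, premature wavefronts can block along that
interface, re-enter the scar through a retrograde path, and emerge as a
re-entrant circuit; a longer interface offers more opportunities for
unidirectional block. `lgerisk` implements the full analysis chain around
that idea, for methodologists and modelers who want to reproduce or extend
it:

1. **Scar morphometry** from segmented short-axis slices: interface area,
   volume, intensity entropy (32-bin Shannon entropy of the enhanced
   region), chord-based mean transmurality, 4-connected component count,
   radiality (circular variance of scar angles about the blood pool), plus
   the full-width-half-maximum (FWHM) segmentation rule.
2. **In-silico electrophysiology**: slices are meshed into 2D triangular
   finite-element monodomain models (≤ 0.25 mm edges) with a two-variable
   restitution-capable ionic model; scar microstructure is imposed by
   percolation (random element removal); a programmed electrical
   stimulation protocol (S1 drive, near-ERP extrastimuli, 600 ms
   observation) counts inducible re-entries per patient.
3. **Survival analysis**: entropy-balancing inverse-probability weights
   that drive every weighted target–confounder correlation to zero,
   weighted Cox regression with per-SD hazard ratios and robust standard
   errors, a time-varying ICD model, tercile stratification, Kaplan–Meier
   curves and log-rank tests.

A synthetic-data module generates annular slices with controllable scar
patterns (stria / compact / patchy) and confounded proportional-hazards
cohorts, so the whole pipeline is testable without patient data.

## Worked example

Build a synthetic mid-wall stria pattern and compute its metric set:

```r
library(lgerisk)

s <- make_annulus_slice(128, 1.4, 8, endo_radius_mm = 15, epi_radius_mm = 25)
s <- paint_lge(s, "stria", angular_extent_rad = pi,
               radial_thickness_fraction = 0.3)
s <- synth_intensity(s, mu_healthy = 50, mu_lge = 110, sigma = 8, seed = 2)
p <- patient_record("example-01", list(s),
                    covariates = list(age = 57, lvef = 34),
                    followup_days = 1600, event = FALSE)
compute_patient_metrics(p)
#> LGE metrics for patient example-01:
#>   interface area        12.99 cm^2
#>   volume                 1.44 cm^3
#>   entropy               4.506 bits
#>   mean transmurality    0.288
#>   components                1
#>   mean radiality        0.363
#>   simulated reentries       0
```

A half-circumference mid-wall band on one slice exposes ~13 cm² of
interface while occupying only 1.4 cm³ — the kind of shape that drives
risk in the interface-area model. The mean transmurality (0.29) reflects
the band covering ~30% of the wall along the chords that cross it, and a
radiality of 0.36 reflects scar spread over half the circumference.

Estimate the adjusted hazard ratio on a synthetic confounded cohort:

```r
co <- make_synthetic_cohort(500, seed = 7, render_slices = FALSE)
fr <- attr(co, "frame")
fr$nyha34 <- as.numeric(fr$nyha34)
fr$alcohol_excess <- as.numeric(fr$alcohol_excess)
fr <- standardize_per_sd(fr, "interface_area_cm2")
w <- ipw_weights(fr, "interface_area_cm2",
                 c("age", "lvef", "lv_mass_index", "nyha34", "alcohol_excess"))
cox_fit(fr, "interface_area_cm2", weights = w)
#> Weighted Cox model: n = 500, events = 61
#>   interface_area_cm2       HR 2.23 (95% CI 1.56-3.18), p = 1.03e-05
```

The weights leave every confounder exactly uncorrelated with the target
(`attr(w, "max_abs_correlation")` is ~10⁻¹⁶) while staying as close to
uniform as the constraints allow; the hazard ratio is per standard
deviation of interface area.

The electrophysiology stage works the same way at any scale; the
pre-packaged desk-scale experiments are `pes_control_study()` (a
homogeneous sheet that must not re-enter, and an asymmetric-refractoriness
ring that must) and `reentry_interface_study()` (large- vs small-interface
patients under full programmed stimulation with percolation).

## Layout

- `R/` — image model and I/O, synthetic data, metrics, meshing and
  percolation, monodomain solver (`src/monodomain.cpp` core), PES
  protocol, survival analysis, study drivers.
- `vignettes/lgerisk-methods.Rmd` — model assumptions, parameter choices,
  numerical decisions, and what the synthetic data do and do not emulate.
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (brute-force pair counting, flood fill, a
  written-out Cox partial likelihood, a simplex optimizer for the
  weights).
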