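# Synthetic slices and cohorts: annular short-axis anatomy with paintable
# scar patterns, plus a confounded proportional-hazards survival cohort, so
# that every downstream stage (metrics, simulation, survival) is testable
# without patient data.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Pixel-center coordinates (mm) for an n1 x n2 grid at spacing s.
pixel_centers_mm <- function(d, spacing) {
  list(x = (seq_len(d[1]) - 0.5) * spacing,   # row coordinate
       y = (seq_len(d[2]) - 0.5) * spacing)   # column coordinate
}

#' Generate an annular short-axis slice
#'
#' Builds a [segmented_slice()] whose myocardium is the set of pixels with
#' center distance to `center_px` in `[endo_radius_mm, epi_radius_mm]` and
#' whose blood pool is the interior disc. The LGE mask starts empty; use
#' [paint_lge()] to add scar.
#'
#' @param grid_size grid side length in pixels.
#' @param pixel_spacing_mm in-plane spacing (mm).
#' @param slice_thickness_mm slice thickness (mm).
#' @param endo_radius_mm,epi_radius_mm endocardial / epicardial radii (mm),
#'   `0 < endo < epi`; the annulus must fit inside the grid.
#' @param center_px annulus center in pixel coordinates (defaults to the
#'   grid center).
#' @param slice_index slice position in the stack.
#' @return A `segmented_slice` with empty LGE mask.
#' @export
make_annulus_slice <- function(grid_size, pixel_spacing_mm, slice_thickness_mm,
                               endo_radius_mm, epi_radius_mm,
                               center_px = c(grid_size / 2, grid_size / 2),
                               slice_index = 1L) {
  if (!(endo_radius_mm > 0 && endo_radius_mm < epi_radius_mm))
    stop("spec error: need 0 < endo_radius_mm < epi_radius_mm")
  epi_px <- epi_radius_mm / pixel_spacing_mm
  if (center_px[1] - epi_px < 0 || center_px[1] + epi_px > grid_size ||
      center_px[2] - epi_px < 0 || center_px[2] + epi_px > grid_size)
    stop("spec error: annulus does not fit inside the grid")
  cc <- pixel_centers_mm(c(grid_size, grid_size), pixel_spacing_mm)
  cx <- center_px[1] * pixel_spacing_mm
  cy <- center_px[2] * pixel_spacing_mm
  r <- sqrt(outer((cc$x - cx)^2, (cc$y - cy)^2, `+`))
  myo <- r >= endo_radius_mm & r <= epi_radius_mm
  blood <- r < endo_radius_mm
  segmented_slice(slice_index, pixel_spacing_mm, slice_thickness_mm,
                  myo, matrix(FALSE, grid_size, grid_size), blood)
}

# Polar coordinates of every pixel center about the blood-pool centroid.
slice_polar <- function(slice) {
  d <- dim(slice$myocardium_mask)
  cc <- pixel_centers_mm(d, slice$pixel_spacing_mm)
  ctr <- bloodpool_centroid_mm(slice)
  dx <- matrix(cc$x - ctr[1], d[1], d[2])
  dy <- matrix(rep(cc$y - ctr[2], each = d[1]), d[1], d[2])
  list(r = sqrt(dx^2 + dy^2), theta = atan2(dy, dx))
}

bloodpool_centroid_mm <- function(slice) {
  idx <- which(slice$bloodpool_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty blood-pool mask")
  s <- slice$pixel_spacing_mm
  c((mean(idx[, 1]) - 0.5) * s, (mean(idx[, 2]) - 0.5) * s)
}

# smallest absolute circular difference between two angles
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# myocardium pixels whose 4 neighbours are all myocardium
interior_mask <- function(myo) {
  d <- dim(myo)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- myo
  myo &
    pad[1:d[1], 2:(d[2] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1)] &
    pad[2:(d[1] + 1), 1:d[2]] & pad[2:(d[1] + 1), 3:(d[2] + 2)]
}

#' Paint an LGE pattern onto an annular slice
#'
#' Adds scar to an annular myocardium in one of three canonical shapes:
#' \describe{
#'   \item{stria}{a mid-wall circumferential band spanning
#'     `angular_extent_rad` about `angular_center_rad`, confined to wall
#'     depths `radial_center_fraction +/- radial_thickness_fraction / 2` and
#'     eroded away from the endo/epicardial boundary, so it never touches
#'     non-myocardium.}
#'   \item{compact}{a single transmural sector of the same angular extent.}
#'   \item{patchy}{`n_patches` disjoint seeded blobs.}
#' }
#'
#' @param slice a `segmented_slice` with annular myocardium and nonempty
#'   blood pool.
#' @param kind `"stria"`, `"compact"` or `"patchy"`.
#' @param angular_center_rad,angular_extent_rad angular placement (radians).
#' @param radial_center_fraction,radial_thickness_fraction wall-depth
#'   placement, both in (0, 1).
#' @param n_patches number of blobs (patchy only).
#' @param seed RNG seed (patchy only); generation is seed-deterministic.
#' @return The slice with `lge_mask` replaced by the painted pattern.
#' @export
paint_lge <- function(slice, kind = c("stria", "compact", "patchy"),
                      angular_center_rad = 0, angular_extent_rad = pi,
                      radial_center_fraction = 0.5,
                      radial_thickness_fraction = 0.3,
                      n_patches = 5L, seed = 1L) {
  kind <- match.arg(kind)
  if (angular_extent_rad <= 0) stop("spec error: angular_extent_rad must be > 0")
  if (radial_center_fraction <= 0 || radial_center_fraction >= 1 ||
      radial_thickness_fraction <= 0 || radial_thickness_fraction >= 1)
    stop("spec error: radial fractions must lie in (0, 1)")
  myo <- slice$myocardium_mask
  if (!any(myo)) stop("spec error: empty myocardium")
  pol <- slice_polar(slice)
  rmin <- min(pol$r[myo]); rmax <- max(pol$r[myo])
  frac <- (pol$r - rmin) / (rmax - rmin)
  in_sector <- ang_diff(pol$theta, angular_center_rad) <= angular_extent_rad / 2
  lge <- switch(kind,
    stria = {
      lo <- radial_center_fraction - radial_thickness_fraction / 2
      hi <- radial_center_fraction + radial_thickness_fraction / 2
      interior_mask(myo) & in_sector & frac >= lo & frac <= hi
    },
    compact = myo & in_sector,
    patchy = with_seed(seed, {
      r_blob <- radial_thickness_fraction * (rmax - rmin) / 2
      cand <- which(interior_mask(myo))
      sel <- integer(0)
      d <- dim(myo)
      coords_mm <- cbind((((cand - 1) %% d[1]) + 0.5) * slice$pixel_spacing_mm,
                         ((cand - 1) %/% d[1] + 0.5) * slice$pixel_spacing_mm)
      for (try in seq_len(500L)) {
        if (length(sel) >= n_patches) break
        i <- sample(length(cand), 1L)
        if (length(sel) == 0L ||
            min(sqrt(rowSums((coords_mm[sel, , drop = FALSE] -
                              matrix(coords_mm[i, ], length(sel), 2,
                                     byrow = TRUE))^2))) >
              2 * r_blob + 2 * slice$pixel_spacing_mm)
          sel <- c(sel, i)
      }
      if (length(sel) < n_patches)
        stop("spec error: could not place ", n_patches, " disjoint patches")
      m <- matrix(FALSE, d[1], d[2])
      cc <- pixel_centers_mm(d, slice$pixel_spacing_mm)
      for (i in sel) {
        dist2 <- outer((cc$x - coords_mm[i, 1])^2, (cc$y - coords_mm[i, 2])^2, `+`)
        m <- m | (myo & dist2 <= r_blob^2)
      }
      m
    }))
  if (!any(lge)) stop("spec error: pattern does not intersect the myocardium")
  slice$lge_mask <- lge
  validate_slice(slice)
  slice
}

#' Synthesize a signal-intensity image for a segmented slice
#'
#' Draws per-pixel intensities `Normal(mu, sigma)` with `mu = mu_lge` inside
#' the LGE mask and `mu = mu_healthy` in the remaining myocardium, clipped at
#' zero; pixels outside the myocardium are 0. Seed-deterministic. Provides
#' input for the FWHM segmentation rule ([fwhm_segment()]).
#'
#' @param slice a `segmented_slice`.
#' @param mu_healthy,mu_lge mean intensities, `mu_lge > mu_healthy >= 0`.
#' @param sigma common noise SD (>= 0).
#' @param seed RNG seed.
#' @return The slice with an `intensity` matrix attached.
#' @export
synth_intensity <- function(slice, mu_healthy, mu_lge, sigma, seed = 1L) {
  if (sigma < 0) stop("spec error: sigma must be >= 0")
  if (!(mu_lge > mu_healthy && mu_healthy >= 0))
    stop("spec error: need mu_lge > mu_healthy >= 0")
  d <- dim(slice$myocardium_mask)
  img <- with_seed(seed, {
    x <- matrix(0, d[1], d[2])
    n_h <- sum(slice$myocardium_mask & !slice$lge_mask)
    n_l <- sum(slice$lge_mask)
    x[slice$myocardium_mask & !slice$lge_mask] <- stats::rnorm(n_h, mu_healthy, sigma)
    x[slice$lge_mask] <- stats::rnorm(n_l, mu_lge, sigma)
    pmax(x, 0)
  })
  slice$intensity <- img
  validate_slice(slice)
  slice
}

default_cohort_confounders <- function() {
  # Table-1-style baseline set: name, mean, sd (numeric) or prevalence (binary)
  list(
    age           = list(type = "numeric", mean = 56.1, sd = 14.5),
    lvef          = list(type = "numeric", mean = 36.7, sd = 11.8),
    lv_mass_index = list(type = "numeric", mean = 100.9, sd = 30.2),
    nyha34        = list(type = "binary", prevalence = 0.173),
    alcohol_excess = list(type = "binary", prevalence = 0.16))
}

default_cohort_geometry <- function() {
  list(grid_size = 48L, pixel_spacing_mm = 1.8, slice_thickness_mm = 8,
       endo_radius_mm = 12, epi_radius_mm = 22,
       extent_range_rad = c(0.4, 5.4), radial_center_fraction = 0.5,
       radial_thickness_fraction = 0.35)
}

# Analytic interface area (cm^2) of a painted stria band, used on the
# no-rendering fast path: two circumferential arcs plus two radial ends,
# inflated by 4/pi to match the Manhattan (pixel-edge) boundary measure
# that interface_area() uses on rendered masks.
stria_interface_analytic_cm2 <- function(geom, extent_rad) {
  wall <- geom$epi_radius_mm - geom$endo_radius_mm
  r_in <- geom$endo_radius_mm + (geom$radial_center_fraction -
          geom$radial_thickness_fraction / 2) * wall
  r_out <- geom$endo_radius_mm + (geom$radial_center_fraction +
           geom$radial_thickness_fraction / 2) * wall
  arc_mm <- extent_rad * (r_in + r_out) + 2 * (r_out - r_in)
  (4 / pi) * arc_mm * geom$slice_thickness_mm / 100
}

#' Generate a synthetic survival cohort with confounded scar morphology
#'
#' Per patient, a latent morphology scale `u ~ Normal(0, 1)` drives the
#' angular extent of a mid-wall stria pattern (so interface area is monotone
#' in `u`); baseline confounders are drawn with correlation
#' `confounding_correlation` to `u`; event times are exponential with rate
#' `baseline_hazard_per_day * exp(beta_interface_per_sd * z_interface +
#' sum(gamma * z_confounder))` where z denotes within-cohort
#' standardization; censoring is `Uniform(0, censoring_max_days)`; ICD
#' implantation is assigned by a logistic rule on the confounders, at a
#' uniform time before follow-up ends.
#'
#' @param n_patients cohort size (>= 2).
#' @param beta_interface_per_sd log hazard ratio per SD of interface area
#'   (default `log(1.75)`).
#' @param gamma_confounders named vector of per-SD log-hazard effects for
#'   confounders (defaults to a modest Table-1-style set; names must be a
#'   subset of the confounder names).
#' @param confounding_correlation correlation in `[0, 1)` between each
#'   confounder's latent score and `u`.
#' @param baseline_hazard_per_day positive baseline hazard (per day).
#' @param censoring_max_days upper limit of uniform censoring (days).
#' @param icd_assignment_logit named vector: logistic coefficients (plus
#'   `intercept`) for ICD assignment on standardized confounders.
#' @param seed RNG seed; generation is fully seed-deterministic.
#' @param render_slices if `TRUE` (default) each record carries a rendered
#'   annular slice with the painted stria; if `FALSE`, interface area is
#'   computed from the closed-form band geometry instead (fast path for
#'   large simulation studies).
#' @param geometry slice geometry list; see `default_cohort_geometry()`.
#' @return A list of [patient_record()] with attribute `"frame"`: a
#'   data.frame of per-patient covariates, interface area, z-scores, and
#'   outcome fields.
#' @export
make_synthetic_cohort <- function(n_patients,
                                  beta_interface_per_sd = log(1.75),
                                  gamma_confounders = c(age = 0.1, lvef = -0.15,
                                                        lv_mass_index = 0.1,
                                                        nyha34 = 0.4,
                                                        alcohol_excess = 0.3),
                                  confounding_correlation = 0.3,
                                  baseline_hazard_per_day = 7e-5,
                                  censoring_max_days = 2500,
                                  icd_assignment_logit = c(intercept = -0.6,
                                                           nyha34 = 0.8,
                                                           lvef = -0.5),
                                  seed = 1L,
                                  render_slices = TRUE,
                                  geometry = default_cohort_geometry()) {
  if (n_patients < 2) stop("spec error: n_patients must be >= 2")
  if (baseline_hazard_per_day <= 0 || censoring_max_days <= 0)
    stop("spec error: hazards and censoring horizon must be positive")
  if (confounding_correlation < 0 || confounding_correlation >= 1)
    stop("spec error: confounding_correlation must be in [0, 1)")
  conf <- default_cohort_confounders()
  stopifnot(all(setdiff(names(gamma_confounders), "") %in% names(conf)))
  rho <- confounding_correlation
  with_seed(seed, {
    n <- n_patients
    u <- stats::rnorm(n)
    # latent standardized scores, correlated rho with u
    zlat <- sapply(names(conf), function(nm)
      rho * u + sqrt(1 - rho^2) * stats::rnorm(n))
    covariates <- lapply(names(conf), function(nm) {
      c_def <- conf[[nm]]
      if (c_def$type == "numeric") c_def$mean + c_def$sd * zlat[, nm]
      else zlat[, nm] > stats::qnorm(1 - c_def$prevalence)
    })
    names(covariates) <- names(conf)

    geom <- geometry
    extent <- geom$extent_range_rad[1] +
      diff(geom$extent_range_rad) * stats::pnorm(u)
    if (render_slices) {
      slices <- lapply(seq_len(n), function(i) {
        s <- make_annulus_slice(geom$grid_size, geom$pixel_spacing_mm,
                                geom$slice_thickness_mm, geom$endo_radius_mm,
                                geom$epi_radius_mm)
        paint_lge(s, "stria", angular_center_rad = 0,
                  angular_extent_rad = extent[i],
                  radial_center_fraction = geom$radial_center_fraction,
                  radial_thickness_fraction = geom$radial_thickness_fraction)
      })
      iface <- vapply(slices, slice_interface_area_cm2, numeric(1))
    } else {
      slices <- NULL
      iface <- stria_interface_analytic_cm2(geom, extent)
    }
    z_iface <- as.numeric(scale(iface))

    gam <- rep(0, length(conf)); names(gam) <- names(conf)
    gam[names(gamma_confounders)] <- gamma_confounders
    lp <- beta_interface_per_sd * z_iface + as.numeric(zlat %*% gam)
    rate <- baseline_hazard_per_day * exp(lp)
    t_event <- stats::rexp(n, rate)
    t_cens <- stats::runif(n, 0, censoring_max_days)
    followup <- pmin(t_event, t_cens)
    event <- t_event <= t_cens

    icd_coefs <- icd_assignment_logit
    eta <- if ("intercept" %in% names(icd_coefs)) icd_coefs[["intercept"]] else 0
    for (nm in setdiff(names(icd_coefs), "intercept"))
      eta <- eta + icd_coefs[[nm]] * zlat[, nm]
    has_icd <- stats::runif(n) < stats::plogis(eta)
    icd_day <- ifelse(has_icd, stats::runif(n) * followup, NA_real_)

    ids <- sprintf("P%04d", seq_len(n))
    records <- lapply(seq_len(n), function(i) {
      patient_record(ids[i],
                     slices = if (render_slices) list(slices[[i]]) else list(),
                     covariates = lapply(covariates, `[[`, i),
                     followup_days = followup[i], event = event[i],
                     icd_day = if (has_icd[i]) icd_day[i] else NULL)
    })
    frame <- data.frame(patient_id = ids, as.data.frame(covariates),
                        interface_area_cm2 = iface, z_interface = z_iface,
                        u = u, followup_days = followup, event = event,
                        icd_day = icd_day, stringsAsFactors = FALSE)
    for (nm in names(conf))
      frame[[paste0("z_", nm)]] <- zlat[, nm]
    attr(records, "frame") <- frame
    records
  })
}
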