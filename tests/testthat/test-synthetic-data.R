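test_that("annulus pixel area matches the analytic ring area", {
  s <- make_annulus_slice(128, 1, 8, 15, 25)
  expect_lt(abs(sum(s$myocardium_mask) - pi * (25^2 - 15^2)) /
              (pi * (25^2 - 15^2)), 0.02)
  expect_false(any(s$lge_mask))
  expect_false(any(s$bloodpool_mask & s$myocardium_mask))
  expect_error(make_annulus_slice(128, 1, 8, 25, 15), "endo")
  expect_error(make_annulus_slice(32, 1, 8, 10, 20), "fit inside")
})

test_that("stria patterns stay interior and painting is deterministic", {
  s <- make_annulus_slice(64, 1, 8, 12, 22)
  st <- paint_lge(s, "stria", angular_extent_rad = pi,
                  radial_thickness_fraction = 0.3)
  # no LGE pixel 4-adjacent to non-myocardium
  d <- dim(st$lge_mask)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- !st$myocardium_mask
  touches <- st$lge_mask & (pad[1:d[1], 2:(d[2] + 1)] |
                            pad[3:(d[1] + 2), 2:(d[2] + 1)] |
                            pad[2:(d[1] + 1), 1:d[2]] |
                            pad[2:(d[1] + 1), 3:(d[2] + 2)])
  expect_false(any(touches))
  p1 <- paint_lge(s, "patchy", n_patches = 4, seed = 9)
  p2 <- paint_lge(s, "patchy", n_patches = 4, seed = 9)
  expect_identical(p1$lge_mask, p2$lge_mask)
  expect_equal(count_components(patient_record("x", list(p1),
                                               followup_days = 0)), 4L)
})

test_that("equal-count stria has strictly larger interface than compact", {
  s <- make_annulus_slice(96, 1, 8, 18, 30)
  st <- paint_lge(s, "stria", angular_extent_rad = 3.5,
                  radial_thickness_fraction = 0.35)
  n_target <- sum(st$lge_mask)
  # shrink the compact sector until its pixel count matches the stria
  f <- function(ext) sum(paint_lge(s, "compact",
                                   angular_extent_rad = ext)$lge_mask) - n_target
  ext <- stats::uniroot(f, c(0.2, 3.5))$root
  cp <- paint_lge(s, "compact", angular_extent_rad = ext)
  expect_lt(abs(sum(cp$lge_mask) - n_target) / n_target, 0.05)
  pa <- function(sl) patient_record("x", list(sl), followup_days = 0)
  expect_gt(interface_area(pa(st)), interface_area(pa(cp)))
})

test_that("stria interface area increases with angular extent", {
  s <- make_annulus_slice(64, 1.5, 8, 12, 22)
  extents <- seq(0.8, 4.8, length.out = 5)
  vals <- vapply(extents, function(e) {
    sl <- paint_lge(s, "stria", angular_extent_rad = e)
    interface_area(patient_record("x", list(sl), followup_days = 0))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("synthetic intensities honour masks, seed and the noise model", {
  s <- paint_lge(make_annulus_slice(48, 1.5, 8, 10, 18), "stria")
  s0 <- synth_intensity(s, 40, 100, 0, seed = 3)
  expect_setequal(unique(as.numeric(s0$intensity)), c(0, 40, 100))
  expect_true(all(s0$intensity[s0$lge_mask] == 100))
  a <- synth_intensity(s, 40, 100, 6, seed = 5)
  b <- synth_intensity(s, 40, 100, 6, seed = 5)
  expect_identical(a$intensity, b$intensity)
  expect_error(synth_intensity(s, 40, 100, -1), "sigma")
  expect_error(synth_intensity(s, 100, 40, 5), "mu_lge")
})

test_that("FWHM recovers the painted scar when the contrast is strong", {
  # mu_lge = 2 mu_healthy + 6 sigma: expect >= 99% agreement
  agree <- vapply(1:20, function(seed) {
    s <- paint_lge(make_annulus_slice(48, 1.5, 8, 10, 18), "stria",
                   angular_extent_rad = 2.5)
    s <- synth_intensity(s, 60, 2 * 60 + 6 * 10, 10, seed = seed)
    seg <- fwhm_segment(s, s$lge_mask)
    mean((seg == s$lge_mask)[s$myocardium_mask])
  }, numeric(1))
  expect_gte(mean(agree), 0.99)
})

test_that("cohort event rate matches the censoring integral when effects vanish", {
  co <- make_synthetic_cohort(2000, beta_interface_per_sd = 0,
                              gamma_confounders = c(age = 0),
                              confounding_correlation = 0,
                              seed = 42, render_slices = FALSE)
  fr <- attr(co, "frame")
  lam <- 7e-5; cmax <- 2500
  p_event <- 1 - (1 - exp(-lam * cmax)) / (lam * cmax)
  se <- sqrt(p_event * (1 - p_event) / 2000)
  expect_lt(abs(mean(fr$event) - p_event), 3 * se)
})

test_that("vanishing censoring horizon censors everyone", {
  co <- make_synthetic_cohort(50, censoring_max_days = 1e-6, seed = 1,
                              render_slices = FALSE)
  expect_false(any(attr(co, "frame")$event))
})

test_that("cohort generation is seed-deterministic and confounded as asked", {
  a <- make_synthetic_cohort(200, seed = 8, render_slices = FALSE)
  b <- make_synthetic_cohort(200, seed = 8, render_slices = FALSE)
  expect_identical(attr(a, "frame"), attr(b, "frame"))
  fr <- attr(a, "frame")
  # confounders correlate with the latent morphology scale
  expect_gt(cor(fr$u, fr$z_age), 0.1)
  expect_gt(cor(fr$interface_area_cm2, fr$z_age), 0.05)
  # ICD day present only for assigned patients, never after follow-up
  expect_true(all(is.na(fr$icd_day) | fr$icd_day <= fr$followup_days))
})

test_that("rendered and analytic interface areas agree on ranking", {
  ren <- make_synthetic_cohort(60, seed = 5, render_slices = TRUE)
  fr <- attr(ren, "frame")
  iface_measured <- vapply(ren, interface_area, numeric(1))
  expect_equal(iface_measured, fr$interface_area_cm2)
  ana <- make_synthetic_cohort(60, seed = 5, render_slices = FALSE)
  fa <- attr(ana, "frame")
  # same latent draws, interface strictly monotone in u on both paths
  expect_identical(fa$u, fr$u)
  expect_gt(cor(fr$interface_area_cm2, fa$interface_area_cm2,
                method = "spearman"), 0.99)
})
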