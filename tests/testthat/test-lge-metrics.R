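test_that("FWHM segmentation implements the half-maximum rule", {
  myo <- matrix(TRUE, 6, 6); f <- matrix(FALSE, 6, 6)
  roi <- f; roi[2:3, 2:3] <- TRUE
  img <- matrix(40, 6, 6); img[2:3, 2:3] <- 100
  s <- segmented_slice(1, 1, 8, myo, f, f, intensity = img)
  seg <- fwhm_segment(s, roi)
  expect_identical(seg, img >= 50)
  # constant image: everything is above half max
  s2 <- segmented_slice(1, 1, 8, myo, f, f, intensity = matrix(70, 6, 6))
  expect_identical(fwhm_segment(s2, roi), myo)
  expect_error(fwhm_segment(s2, f), "empty ROI")
  expect_error(fwhm_segment(segmented_slice(1, 1, 8, myo, f, f), roi),
               "no intensity")
})

test_that("interface area matches the stated worked examples", {
  pa <- function(s) patient_record("x", list(s), followup_days = 0)
  myo <- matrix(TRUE, 5, 5); f <- matrix(FALSE, 5, 5)
  # no LGE
  expect_equal(interface_area(pa(segmented_slice(1, 1, 8, myo, f, f))), 0)
  # LGE everywhere: no internal border
  expect_equal(interface_area(pa(segmented_slice(1, 1, 8, myo, myo, f))), 0)
  # one interior LGE pixel, 1 mm spacing, 8 mm thickness: 4 x 1 x 8 mm^2
  lge <- f; lge[3, 3] <- TRUE
  expect_equal(interface_area(pa(segmented_slice(1, 1, 8, myo, lge, f))), 0.32)
})

test_that("interface area equals the pair-counting oracle on random masks", {
  set.seed(101)
  for (k in 1:60) {
    s <- random_mask_slice()
    got <- interface_area(patient_record("x", list(s), followup_days = 0))
    pairs <- oracle_interface_pairs(s$lge_mask, s$myocardium_mask)
    expect_identical(got, pairs * s$pixel_spacing_mm * s$slice_thickness_mm / 100)
  }
})

test_that("volume follows the voxel formula and symmetries", {
  # 125 pixels at 2 mm spacing, 10 mm thickness: 125 * 4 * 10 / 1000 cm^3
  m2 <- matrix(TRUE, 15, 15); f2 <- matrix(FALSE, 15, 15)
  l2 <- f2; l2[seq_len(125)] <- TRUE
  p <- patient_record("x", list(segmented_slice(1, 2, 10, m2, l2, f2)),
                      followup_days = 0)
  expect_equal(lge_volume(p), 5.0)
  # rotation invariance
  pr <- patient_record("x", list(rotate_slice(p$slices[[1]])),
                       followup_days = 0)
  expect_equal(lge_volume(pr), 5.0)
  expect_equal(lge_volume(patient_record("x", list(
    segmented_slice(1, 2, 10, m2, f2, f2)), followup_days = 0)), 0)
})

test_that("entropy reproduces analytic values and the uniform limit", {
  m <- matrix(TRUE, 320, 320); f <- matrix(FALSE, 320, 320)
  # constant intensities: zero entropy
  p0 <- patient_record("x", list(segmented_slice(1, 1, 8, m, m, f,
                                                 intensity = matrix(7, 320, 320))),
                       followup_days = 0)
  expect_equal(lge_entropy(p0), 0)
  # two equal-mass well-separated levels: exactly 1 bit
  img <- matrix(10, 320, 320); img[, 161:320] <- 90
  p1 <- patient_record("x", list(segmented_slice(1, 1, 8, m, m, f,
                                                 intensity = img)),
                       followup_days = 0)
  expect_equal(lge_entropy(p1), 1.0)
  # uniform draw approaches log2(32) = 5 bits from below
  set.seed(3)
  img2 <- matrix(runif(320 * 320, 20, 120), 320, 320)
  p2 <- patient_record("x", list(segmented_slice(1, 1, 8, m, m, f,
                                                 intensity = img2)),
                       followup_days = 0)
  e <- lge_entropy(p2)
  expect_lt(e, 5)
  expect_gt(e, 4.95)
  # no LGE: zero with a warning flag
  pe <- patient_record("x", list(segmented_slice(1, 1, 8, m, f, f,
                                                 intensity = img)),
                       followup_days = 0)
  expect_equal(as.numeric(lge_entropy(pe)), 0)
  expect_match(attr(lge_entropy(pe), "warning"), "no LGE")
})

test_that("transmurality matches analytic chords on constructed annuli", {
  # LGE = full myocardium: transmurality 1
  s <- make_annulus_slice(64, 1, 8, 12, 22)
  s$lge_mask <- s$myocardium_mask
  p <- patient_record("x", list(s), followup_days = 0)
  expect_equal(as.numeric(mean_transmurality(p)), 1.0)
  # concentric mid-wall band covering half the wall at all angles: 0.5
  hi <- make_annulus_slice(200, 0.5, 8, 20, 40)
  hi <- paint_lge(hi, "stria", angular_extent_rad = 2 * pi,
                  radial_center_fraction = 0.5,
                  radial_thickness_fraction = 0.5)
  ph <- patient_record("x", list(hi), followup_days = 0)
  v <- as.numeric(mean_transmurality(ph))
  expect_lt(abs(v - 0.5), 0.02)
  # K-doubling changes the value by < 0.01 for smooth patterns
  v2 <- as.numeric(mean_transmurality(ph, K = 360L))
  expect_lt(abs(v - v2), 0.01)
})

test_that("component counting agrees with flood fill and 4-connectivity", {
  f <- matrix(FALSE, 6, 6); m <- matrix(TRUE, 6, 6)
  # two pixels touching only diagonally are two components
  lge <- f; lge[2, 2] <- TRUE; lge[3, 3] <- TRUE
  p <- patient_record("x", list(segmented_slice(1, 1, 8, m, lge, f)),
                      followup_days = 0)
  expect_equal(count_components(p), 2L)
  expect_equal(count_components(patient_record("x", list(
    segmented_slice(1, 1, 8, m, f, f)), followup_days = 0)), 0L)
  # random blob images against the independent flood-fill oracle
  set.seed(77)
  for (k in 1:15) {
    s <- random_mask_slice(d = c(30, 30), p_lge = 0.35)
    pk <- patient_record("x", list(s), followup_days = 0)
    expect_identical(count_components(pk),
                     oracle_flood_fill_components(s$lge_mask))
  }
})

test_that("component counting agrees with EBImage labeling", {
  # EBImage::bwlabel is an independent 4-connective implementation
  expect_true(requireNamespace("EBImage", quietly = TRUE))
  set.seed(31)
  for (k in 1:10) {
    s <- random_mask_slice(d = c(40, 40), p_lge = 0.3)
    pk <- patient_record("x", list(s), followup_days = 0)
    expect_identical(count_components(pk),
                     as.integer(max(EBImage::bwlabel(s$lge_mask * 1))))
  }
})

test_that("radiality spans its range on constructed patterns", {
  s <- make_annulus_slice(64, 1, 8, 12, 22)
  # all LGE at one angle: radiality ~ 0
  one <- paint_lge(s, "compact", angular_center_rad = 1,
                   angular_extent_rad = 0.12)
  p1 <- patient_record("x", list(one), followup_days = 0)
  expect_lt(as.numeric(mean_radiality(p1)), 0.01)
  # equal mass at opposite angles: resultant cancels, radiality 1
  two <- s
  two$lge_mask <- paint_lge(s, "compact", angular_center_rad = 0,
                            angular_extent_rad = 0.2)$lge_mask |
    paint_lge(s, "compact", angular_center_rad = pi,
              angular_extent_rad = 0.2)$lge_mask
  p2 <- patient_record("x", list(two), followup_days = 0)
  expect_lt(abs(as.numeric(mean_radiality(p2)) - 1), 0.01)
  # full ring: radiality 1 within discretization
  ring <- paint_lge(s, "stria", angular_extent_rad = 2 * pi)
  p3 <- patient_record("x", list(ring), followup_days = 0)
  expect_lt(abs(as.numeric(mean_radiality(p3)) - 1), 0.01)
})

test_that("metrics are invariant under 90-degree rotation", {
  p <- fixture_patient(extent = 2.4, with_intensity = TRUE)
  pr <- patient_record(p$patient_id, list(rotate_slice(p$slices[[1]])),
                       followup_days = 0)
  m1 <- compute_patient_metrics(p)
  m2 <- compute_patient_metrics(pr)
  expect_identical(m1$interface_area_cm2, m2$interface_area_cm2)
  expect_identical(m1$volume_cm3, m2$volume_cm3)
  expect_identical(m1$n_components, m2$n_components)
  expect_equal(m1$entropy_bits, m2$entropy_bits)
  expect_lt(abs(m1$mean_transmurality - m2$mean_transmurality), 0.01)
  expect_lt(abs(m1$mean_radiality - m2$mean_radiality), 0.01)
})

test_that("interface and volume scale correctly with pixel spacing", {
  s <- fixture_patient(extent = 2)$slices[[1]]
  s2 <- segmented_slice(1, 2 * s$pixel_spacing_mm, s$slice_thickness_mm,
                        s$myocardium_mask, s$lge_mask, s$bloodpool_mask)
  p1 <- patient_record("x", list(s), followup_days = 0)
  p2 <- patient_record("x", list(s2), followup_days = 0)
  expect_equal(interface_area(p2), 2 * interface_area(p1))
  expect_equal(lge_volume(p2), 4 * lge_volume(p1))
})

test_that("a patient with no LGE yields an all-zero flagged metric set", {
  s <- make_annulus_slice(32, 1.5, 8, 8, 14)
  p <- patient_record("Z", list(s), followup_days = 10)
  m <- compute_patient_metrics(p)
  expect_equal(m$interface_area_cm2, 0)
  expect_equal(m$volume_cm3, 0)
  expect_equal(m$entropy_bits, 0)
  expect_equal(m$mean_transmurality, 0)
  expect_equal(m$n_components, 0L)
  expect_equal(m$mean_radiality, 0)
  expect_true(any(grepl("no LGE", m$warnings)))
})

test_that("metrics are invariant to slice order", {
  s1 <- paint_lge(make_annulus_slice(48, 1.5, 8, 10, 18), "stria",
                  angular_extent_rad = 2)
  s2 <- paint_lge(make_annulus_slice(48, 1.5, 8, 10, 18, slice_index = 2L),
                  "compact", angular_extent_rad = 1)
  pa <- patient_record("x", list(s1, s2), followup_days = 0)
  s1b <- s1; s1b$slice_index <- 2L
  s2b <- s2; s2b$slice_index <- 1L
  pb <- patient_record("x", list(s1b, s2b), followup_days = 0)
  ma <- compute_patient_metrics(pa); mb <- compute_patient_metrics(pb)
  expect_equal(ma$interface_area_cm2, mb$interface_area_cm2)
  expect_equal(ma$n_components, mb$n_components)
  expect_equal(ma$mean_radiality, mb$mean_radiality)
})
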