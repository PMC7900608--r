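# Electrophysiology tests use a reduced strip (0.5 mm edges) so that the
# whole file runs in well under a minute; the acceptance suite repeats the
# calibration checks at the reference resolution.

test_that("no stimulus means no activation and a resting state", {
  s <- lgerisk:::strip_slice(6, 3, 1)
  m <- triangulate_slice(s, 0.5)
  rec <- integrate_monodomain(m, config = sim_config(duration_ms = 50))
  expect_true(all(lengths(rec$times) == 0))
  expect_true(all(abs(rec$V) < 1e-9))
})

test_that("without coupling only the stimulated nodes activate", {
  s <- lgerisk:::strip_slice(6, 3, 1)
  m <- triangulate_slice(s, 0.5)
  stim_nodes <- which(m$nodes[, 1] <= 0.5)
  cfg <- sim_config(duration_ms = 60, stimuli = list(
    list(nodes = stim_nodes, start_ms = 2, duration_ms = 2, amplitude = 1)))
  tis <- tissue_params(sigma_healthy = 1e-9)
  rec <- integrate_monodomain(m, tissue = tis, config = cfg)
  act <- which(lengths(rec$times) > 0)
  expect_true(all(act %in% stim_nodes))
  expect_gt(length(act), 0)
})

test_that("a paced strip activates once per node, later with distance", {
  s <- lgerisk:::strip_slice(15, 3, 1)
  m <- triangulate_slice(s, 0.5)
  stim_nodes <- which(m$nodes[, 1] <= 0.5)
  cfg <- sim_config(duration_ms = 120, stimuli = list(
    list(nodes = stim_nodes, start_ms = 2, duration_ms = 2, amplitude = 1)))
  rec <- integrate_monodomain(m, tissue = tissue_params(sigma_healthy = 0.3),
                              config = cfg)
  expect_true(all(lengths(rec$times) == 1))
  # activation time along the mid-line increases monotonically in x
  mid <- abs(m$nodes[, 2] - 1.5) < 0.26
  x <- m$nodes[mid, 1]
  tt <- vapply(rec$times[mid], `[[`, numeric(1), 1)
  ord <- order(x)
  expect_true(all(diff(tt[ord][x[ord] > 1.5]) >= 0))
  # V stays within the model bounds throughout (final state check)
  expect_true(all(rec$V > -0.05 & rec$V < 1.05))
})

test_that("conduction velocity scales as sqrt(sigma) and is width-stable", {
  s <- lgerisk:::strip_slice(20, 5, 1)
  m <- triangulate_slice(s, 0.5)
  cv1 <- measure_cv(m, tissue = tissue_params(sigma_healthy = 0.16))
  cv2 <- measure_cv(m, tissue = tissue_params(sigma_healthy = 0.32))
  expect_lt(abs(cv2 / cv1 - sqrt(2)), 0.05 * sqrt(2))
  # width independence beyond 2 mm
  s3 <- lgerisk:::strip_slice(20, 3, 1)
  cv3 <- measure_cv(triangulate_slice(s3, 0.5),
                    tissue = tissue_params(sigma_healthy = 0.16))
  expect_lt(abs(cv3 - cv1) / cv1, 0.02)
})

test_that("a percolated band slows conduction through it", {
  rows <- 20; cols <- 5
  myo <- matrix(TRUE, rows, cols)
  lge <- matrix(FALSE, rows, cols); lge[9:12, ] <- TRUE
  s <- segmented_slice(1, 1, 8, myo, lge, matrix(FALSE, rows, cols))
  m <- triangulate_slice(s, 0.5)
  tis <- tissue_params(sigma_healthy = 0.3, lge_conductivity_factor = 1,
                       lge_tau_close_factor = 1)
  cv_clean <- measure_cv(m, tissue = tis)
  mp <- percolate(m, 0.3, seed = 5)
  cv_perc <- measure_cv(mp, tissue = tis)
  expect_lt(cv_perc, cv_clean)
})

test_that("halving dt changes strip activation times by less than 0.5 ms", {
  s <- lgerisk:::strip_slice(20, 3, 1)
  m <- triangulate_slice(s, 0.5)
  tis <- tissue_params(sigma_healthy = 0.3)
  tfar <- function(dt) {
    sys <- lgerisk:::ep_system(m, ionic_params(), tis, dt)
    probe <- which.min((sys$xy[, 1] - 17)^2 + (sys$xy[, 2] - 1.5)^2)
    stim <- list(list(nodes = sys$used[sys$xy[, 1] <= 0.5], start_ms = 2,
                      duration_ms = 2, amplitude = 1))
    res <- lgerisk:::run_system(sys, ionic_params(), stim, 0, 120,
                                watch_nodes = probe, watch_min = 1L,
                                watch_after = 0)
    res$act_time[res$act_node == probe][1]
  }
  expect_lt(abs(tfar(0.05) - tfar(0.025)), 0.5)
})

test_that("calibration hits the target CV and is monotone and reproducible", {
  cal1 <- calibrate_conductivity(0.3, max_edge_mm = 0.5)
  expect_lt(abs(cal1$achieved_cv_mps - 0.3) / 0.3, 0.01)
  cal2 <- calibrate_conductivity(0.6, max_edge_mm = 0.5)
  cal3 <- calibrate_conductivity(0.9, max_edge_mm = 0.5)
  expect_true(cal1$sigma_healthy < cal2$sigma_healthy &&
                cal2$sigma_healthy < cal3$sigma_healthy)
  expect_identical(calibrate_conductivity(0.6, max_edge_mm = 0.5)$sigma_healthy,
                   cal2$sigma_healthy)
  expect_error(calibrate_conductivity(2), "target CV")
})

test_that("restitution is monotone, plateaus, and lengthens with LGE remodeling", {
  cls <- c(2000, 1000, 600, 450, 350, 300, 250)
  apd <- apd_restitution(ionic_params(), cls)
  cap <- !is.na(apd)
  expect_true(all(diff(apd[cap]) < 0))         # shorter CL, shorter APD
  expect_lt(abs(apd[1] - apd[2]) / apd[2], 0.01)  # plateau at long CL
  apd_lge <- apd_restitution(ionic_params(), cls, tau_close_factor = 1.5)
  both <- cap & !is.na(apd_lge)
  expect_true(all(apd_lge[both] > apd[both]))
  # capture failure is reported as NA at very short cycle lengths
  expect_true(anyNA(apd_restitution(ionic_params(), c(150))))
})
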