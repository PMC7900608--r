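# Monodomain electrophysiology on labeled meshes.
#
# The ionic model is a two-variable phenomenological (Mitchell-Schaeffer
# type) model with a dimensionless transmembrane potential V in [0, 1] and a
# recovery gate h:
#   dV/dt = div(sigma grad V) / (beta Cm) + h V^2 (1 - V)/tau_in - V/tau_out
#   dh/dt = (1 - h)/tau_open   if V <  v_gate
#         = -h/tau_close       if V >= v_gate
# LGE tissue is remodeled by scaling conductivity down
# (lge_conductivity_factor) and tau_close up (lge_tau_close_factor), which
# yields slower conduction and longer refractoriness inside scar: permeable
# at slow rates, prone to block at fast rates.

#' Ionic model parameters
#'
#' Defaults give a human-ventricle-like action potential (APD about 240 ms
#' at slow rate) with restitution: tau_in 0.3, tau_out 6, tau_open 120,
#' tau_close 150 ms, gate threshold 0.13.
#'
#' @param tau_in_ms,tau_out_ms,tau_open_ms,tau_close_ms positive time
#'   constants (ms).
#' @param v_gate gate threshold in (0, 1).
#' @return A list of class `ionic_params`.
#' @export
ionic_params <- function(tau_in_ms = 0.3, tau_out_ms = 6, tau_open_ms = 120,
                         tau_close_ms = 150, v_gate = 0.13) {
  stopifnot(tau_in_ms > 0, tau_out_ms > 0, tau_open_ms > 0, tau_close_ms > 0,
            v_gate > 0, v_gate < 1)
  structure(list(tau_in_ms = tau_in_ms, tau_out_ms = tau_out_ms,
                 tau_open_ms = tau_open_ms, tau_close_ms = tau_close_ms,
                 v_gate = v_gate), class = "ionic_params")
}

#' Tissue parameters
#'
#' @param sigma_healthy healthy-tissue conductivity (effective diffusivity
#'   scale; mm^2/ms after division by `surface_to_volume_times_capacitance`).
#' @param lge_conductivity_factor multiplier in (0, 1] applied inside LGE.
#' @param lge_tau_close_factor multiplier >= 1 applied to `tau_close` at
#'   nodes touching LGE elements.
#' @param surface_to_volume_times_capacitance positive scaling constant
#'   (beta * Cm).
#' @return A list of class `tissue_params`.
#' @export
tissue_params <- function(sigma_healthy = 0.2, lge_conductivity_factor = 0.25,
                          lge_tau_close_factor = 1.5,
                          surface_to_volume_times_capacitance = 1) {
  stopifnot(sigma_healthy > 0,
            lge_conductivity_factor > 0, lge_conductivity_factor <= 1,
            lge_tau_close_factor >= 1,
            surface_to_volume_times_capacitance > 0)
  structure(list(sigma_healthy = sigma_healthy,
                 lge_conductivity_factor = lge_conductivity_factor,
                 lge_tau_close_factor = lge_tau_close_factor,
                 surface_to_volume_times_capacitance =
                   surface_to_volume_times_capacitance),
            class = "tissue_params")
}

#' Simulation configuration
#'
#' @param dt_ms time step (default 0.05 ms; reaction explicit, diffusion
#'   implicit and unconditionally stable).
#' @param duration_ms total simulated time.
#' @param stimuli list of stimuli, each a list with `nodes` (mesh node
#'   indices), `start_ms`, `duration_ms`, `amplitude` (added to dV/dt,
#'   1/ms).
#' @param activation_threshold potential level whose upward crossings are
#'   recorded (default 0.5).
#' @param output_every_ms snapshot interval (bookkeeping only; activation
#'   counts are independent of it).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt_ms = 0.05, duration_ms = 500, stimuli = list(),
                       activation_threshold = 0.5, output_every_ms = Inf) {
  stopifnot(dt_ms > 0, duration_ms > 0)
  structure(list(dt_ms = dt_ms, duration_ms = duration_ms, stimuli = stimuli,
                 activation_threshold = activation_threshold,
                 output_every_ms = output_every_ms), class = "sim_config")
}

# Assemble the finite-element system on the non-removed elements.
# Returns node remapping, CSR arrays for A = M + dt*K, lumped mass, and
# per-node tau_close. `unit = TRUE` returns the sigma-independent split
# stiffness parts instead (for cheap reassembly during calibration).
ep_system <- function(mesh, ionic, tissue, dt_ms) {
  active <- mesh$label != ELEM_REMOVED
  el <- mesh$elements[active, , drop = FALSE]
  lab <- mesh$label[active]
  if (nrow(el) == 0L) stop("mesh has no active elements")
  used <- sort(unique(as.vector(el)))
  remap <- integer(nrow(mesh$nodes)); remap[used] <- seq_along(used)
  eln <- matrix(remap[el], nrow(el), 3)
  xy <- mesh$nodes[used, , drop = FALSE]
  x <- matrix(xy[eln, 1], ncol = 3); y <- matrix(xy[eln, 2], ncol = 3)
  # P1 gradients: b_i = y_j - y_k, c_i = x_k - x_j (cyclic)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  area <- abs(b[, 1] * cc[, 2] - b[, 2] * cc[, 1]) / 2
  beta_cm <- tissue$surface_to_volume_times_capacitance
  D <- tissue$sigma_healthy / beta_cm *
    ifelse(lab == ELEM_LGE, tissue$lge_conductivity_factor, 1)
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (bb in 1:3) {
    k <- k + 1L
    ii[[k]] <- eln[, a]; jj[[k]] <- eln[, bb]
    xx[[k]] <- D * (b[, a] * b[, bb] + cc[, a] * cc[, bb]) / (4 * area)
  }
  n <- length(used)
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  mdiag <- numeric(n)
  for (a in 1:3) {
    tab <- tapply(area / 3, eln[, a], sum)
    mdiag[as.integer(names(tab))] <- mdiag[as.integer(names(tab))] + tab
  }
  A <- Matrix::Diagonal(n, mdiag) + dt_ms * K
  Acsr <- as(as(A, "generalMatrix"), "RsparseMatrix")
  # nodes touching any LGE element get remodeled tau_close
  lge_nodes <- unique(as.vector(eln[lab == ELEM_LGE, , drop = FALSE]))
  tau_close <- rep(ionic$tau_close_ms, n)
  tau_close[lge_nodes] <- ionic$tau_close_ms * tissue$lge_tau_close_factor
  list(n = n, used = used, remap = remap, xy = xy,
       ap = Acsr@p, ai = Acsr@j, ax = Acsr@x, mdiag = mdiag,
       tau_close = tau_close, dt = dt_ms)
}

# low-level run on an assembled system; state in/out, absolute time
run_system <- function(sys, ionic, stimuli, t0, duration_ms,
                       V0 = NULL, h0 = NULL, act_thresh = 0.5,
                       stop_on_quiescent = FALSE, quiesce_tol = 0.005,
                       watch_nodes = integer(0), watch_min = 0L,
                       watch_after = -Inf, max_act = 64L) {
  if (is.null(V0)) V0 <- numeric(sys$n)
  if (is.null(h0)) h0 <- rep(1, sys$n)
  ns <- length(stimuli)
  starts <- vapply(stimuli, `[[`, numeric(1), "start_ms")
  durs <- vapply(stimuli, `[[`, numeric(1), "duration_ms")
  amps <- vapply(stimuli, `[[`, numeric(1), "amplitude")
  nodes <- lapply(stimuli, function(s) {
    sn <- sys$remap[s$nodes]
    sn <- sn[sn > 0L] - 1L                          # 0-based active indices
    if (length(sn) == 0L) stop("stimulus node set is empty on the active mesh")
    as.integer(sn)
  })
  res <- cpp_monodomain_run(sys$ap, sys$ai, sys$ax, sys$mdiag, sys$tau_close,
                            ionic$tau_in_ms, ionic$tau_out_ms,
                            ionic$tau_open_ms, ionic$v_gate, sys$dt, t0,
                            duration_ms,
                            if (ns) starts else numeric(0),
                            if (ns) durs else numeric(0),
                            if (ns) amps else numeric(0), nodes,
                            V0, h0, act_thresh, as.integer(max_act),
                            stop_on_quiescent, quiesce_tol,
                            as.integer(watch_nodes), as.integer(watch_min),
                            watch_after, 20L)
  if (!res$stable)
    stop("monodomain integration unstable (|V| > 2); reduce dt or stimulus")
  res
}

#' Integrate the monodomain model on a labeled mesh
#'
#' Solves the reaction-diffusion system with operator splitting (explicit
#' reaction, implicit mass-lumped P1 diffusion) and records every upward
#' crossing of the activation threshold per node.
#'
#' @param mesh a [triangulate_slice()] mesh (removed elements are excluded
#'   from the assembly and act as no-flux obstacles).
#' @param ionic an [ionic_params()].
#' @param tissue a [tissue_params()].
#' @param config a [sim_config()]; stimulus node indices refer to mesh nodes.
#' @return An `activation_record`: list with `times` (per mesh node, vector
#'   of activation times, ms), `node_ids` (mesh node indices of the active
#'   system), `V`, `h` (final state), `t_end`.
#' @export
integrate_monodomain <- function(mesh, ionic = ionic_params(),
                                 tissue = tissue_params(),
                                 config = sim_config()) {
  sys <- ep_system(mesh, ionic, tissue, config$dt_ms)
  res <- run_system(sys, ionic, config$stimuli, 0, config$duration_ms,
                    act_thresh = config$activation_threshold)
  times <- split(res$act_time, factor(sys$used[res$act_node],
                                      levels = seq_len(nrow(mesh$nodes))))
  structure(list(times = times, node_ids = sys$used, V = res$V, h = res$h,
                 t_end = res$t_end), class = "activation_record")
}

# a rectangular all-myocardium slice for conduction-velocity benchmarks
strip_slice <- function(length_mm = 20, width_mm = 5, spacing_mm = 1) {
  rows <- round(length_mm / spacing_mm); cols <- round(width_mm / spacing_mm)
  myo <- matrix(TRUE, rows, cols)
  segmented_slice(1L, spacing_mm, 8, myo, matrix(FALSE, rows, cols),
                  matrix(FALSE, rows, cols))
}

#' Measure conduction velocity on a rectangular strip
#'
#' Paces one end of an all-myocardium strip and measures the planar-wave
#' conduction velocity between two mid-line probes.
#'
#' @param strip_mesh mesh of a rectangular strip (e.g. from the internal
#'   strip builder used by [calibrate_conductivity()]); the strip's long
#'   axis must be x.
#' @param ionic,tissue,dt_ms model parameters.
#' @param probe_x_mm two probe x positions (>= 10 mm apart).
#' @return Conduction velocity in m/s (= mm/ms).
#' @export
measure_cv <- function(strip_mesh, ionic = ionic_params(),
                       tissue = tissue_params(), dt_ms = 0.05,
                       probe_x_mm = c(5, 15)) {
  stopifnot(diff(probe_x_mm) >= 10)
  sys <- ep_system(strip_mesh, ionic, tissue, dt_ms)
  measure_cv_system(sys, strip_mesh, ionic, dt_ms, probe_x_mm)
}

measure_cv_system <- function(sys, strip_mesh, ionic, dt_ms, probe_x_mm) {
  xy <- sys$xy
  ymid <- mean(range(xy[, 2]))
  probe <- vapply(probe_x_mm, function(px)
    which.min((xy[, 1] - px)^2 + (xy[, 2] - ymid)^2), integer(1))
  stim_nodes <- sys$used[xy[, 1] <= min(xy[, 1]) + 1.0]
  stim <- list(list(nodes = stim_nodes, start_ms = 2, duration_ms = 2,
                    amplitude = 1))
  dur <- 20 + diff(range(xy[, 1])) / 0.05       # generous even at 0.05 m/s
  res <- run_system(sys, ionic, stim, 0, dur,
                    watch_nodes = probe[2], watch_min = 1L, watch_after = 0)
  t1 <- res$act_time[res$act_node == probe[1]][1]
  t2 <- res$act_time[res$act_node == probe[2]][1]
  if (is.na(t1) || is.na(t2))
    stop("propagation failure: a probe was never activated")
  diff(probe_x_mm) / (t2 - t1)
}

#' Calibrate conductivity to a target conduction velocity
#'
#' Bisection on `sigma_healthy` until the strip conduction velocity matches
#' the target within 1% relative error. Deterministic: identical inputs
#' reproduce sigma bit-identically.
#'
#' @param target_cv_mps target CV in (0.1, 1.5) m/s (default 0.6, a
#'   standard human LV bulk value).
#' @param ionic an [ionic_params()].
#' @param dt_ms time step.
#' @param max_edge_mm mesh resolution of the benchmark strip.
#' @param sigma_bracket initial bisection bracket.
#' @param tissue template [tissue_params()] (its scaling constant is kept).
#' @return List with `sigma_healthy`, `achieved_cv_mps`, `iterations`.
#' @export
calibrate_conductivity <- function(target_cv_mps = 0.6,
                                   ionic = ionic_params(), dt_ms = 0.05,
                                   max_edge_mm = 0.25,
                                   sigma_bracket = c(0.005, 5),
                                   tissue = tissue_params()) {
  if (target_cv_mps <= 0.1 || target_cv_mps >= 1.5)
    stop("target CV must lie in (0.1, 1.5) m/s")
  slice <- strip_slice(20, 5, 1)
  mesh <- triangulate_slice(slice, max_edge_mm)
  cv_of <- function(sigma) {
    tt <- tissue
    tt$sigma_healthy <- sigma
    sys <- ep_system(mesh, ionic, tt, dt_ms)
    measure_cv_system(sys, mesh, ionic, dt_ms, c(5, 15))
  }
  lo <- sigma_bracket[1]; hi <- sigma_bracket[2]
  f_lo <- cv_of(lo) - target_cv_mps
  f_hi <- cv_of(hi) - target_cv_mps
  if (f_lo * f_hi > 0)
    stop("calibration error: initial sigma interval does not bracket the target CV")
  it <- 0L; achieved <- NA_real_; sig <- NA_real_
  repeat {
    it <- it + 1L
    sig <- (lo + hi) / 2
    cv <- cv_of(sig)
    achieved <- cv
    if (abs(cv - target_cv_mps) / target_cv_mps < 0.01 || it >= 60L) break
    if (cv < target_cv_mps) lo <- sig else hi <- sig
  }
  if (abs(achieved - target_cv_mps) / target_cv_mps >= 0.01)
    stop("calibration failed to converge to 1% of target")
  list(sigma_healthy = sig, achieved_cv_mps = achieved, iterations = it)
}

#' Single-cell APD restitution
#'
#' Paces a 0D cell with a drive train at each cycle length and returns the
#' action potential duration (time above `v_gate`) of the last beat; `NA`
#' when 1:1 capture is lost.
#'
#' @param ionic an [ionic_params()].
#' @param pacing_cls_ms vector of cycle lengths (ms).
#' @param n_beats beats per train (default 8).
#' @param dt_ms time step.
#' @param tau_close_factor optional multiplier on `tau_close` (LGE
#'   remodeling; >= 1 prolongs APD and refractoriness).
#' @return Numeric vector of APDs (ms), one per cycle length.
#' @export
apd_restitution <- function(ionic = ionic_params(), pacing_cls_ms,
                            n_beats = 8L, dt_ms = 0.05,
                            tau_close_factor = 1) {
  vapply(pacing_cls_ms, function(cl) {
    starts <- 5 + (seq_len(n_beats) - 1) * cl
    dur <- 5 + n_beats * cl + 600
    res <- cpp_cell_run(ionic$tau_in_ms, ionic$tau_out_ms, ionic$tau_open_ms,
                        ionic$tau_close_ms * tau_close_factor, ionic$v_gate,
                        dt_ms, dur, starts, 1, 1.2, 0, 1)
    last <- starts[n_beats]
    # 1:1 capture: one upstroke within 20 ms of every stimulus
    ok <- all(vapply(starts, function(s)
      any(res$up >= s & res$up < s + 20), logical(1))) &&
      length(res$up) == n_beats
    if (!ok) return(NA_real_)
    up_last <- res$up[res$up >= last][1]
    down_last <- res$down[res$down > up_last][1]
    if (is.na(down_last)) NA_real_ else down_last - up_last
  }, numeric(1))
}
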