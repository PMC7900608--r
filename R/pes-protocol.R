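# Simulated programmed electrical stimulation (PES): an S1 drive train,
# extrastimuli delivered just above the effective refractory period (found
# by scanning the coupling interval downward), a 600 ms observation window
# after each delivered extrastimulus, and re-entry detection on the
# activation record. Per-slice realizations differ in their percolation
# pattern; the per-patient metric is the total number of induced re-entries.

#' PES protocol configuration
#'
#' @param s1_count number of S1 drive beats (default 2).
#' @param s1_cl_ms S1 cycle length (default 500 ms).
#' @param max_extrastimuli maximum number of extrastimuli (default 2).
#' @param coupling_start_fraction first coupling interval as a fraction of
#'   the previous interval (default 0.9).
#' @param coupling_decrement_ms ERP scan step (default 10 ms).
#' @param erp_margin_ms delivery margin above the ERP (default 5 ms).
#' @param post_final_window_ms observation window after a delivered
#'   extrastimulus (600 ms).
#' @param realizations_per_slice percolation realizations per slice (10).
#' @param percolation_p element-removal probability inside LGE (default 0.4).
#' @param base_seed base RNG seed; realization r uses `base_seed + r`.
#' @param coupling_floor_ms shortest coupling interval scanned (default 60).
#' @param capture_window_ms window used to decide whether an extrastimulus
#'   captured (default 60 ms).
#' @param stim_radius_mm stimulated-region radius around the pacing node
#'   (default 0.5 mm).
#' @param dt_ms integration step (default 0.05 ms).
#' @param reentry_min_activations,reentry_persist_ms re-entry criterion: at
#'   least one node with this many post-stimulus activations, and activity
#'   persisting beyond this many ms after the final stimulus.
#' @return A list of class `pes_config`.
#' @export
pes_config <- function(s1_count = 2L, s1_cl_ms = 500, max_extrastimuli = 2L,
                       coupling_start_fraction = 0.9,
                       coupling_decrement_ms = 10, erp_margin_ms = 5,
                       post_final_window_ms = 600,
                       realizations_per_slice = 10L, percolation_p = 0.4,
                       base_seed = 1L, coupling_floor_ms = 60,
                       capture_window_ms = 60, stim_radius_mm = 0.5,
                       dt_ms = 0.05, reentry_min_activations = 2L,
                       reentry_persist_ms = 250) {
  stopifnot(s1_count >= 1, s1_cl_ms > 0, max_extrastimuli >= 1,
            coupling_start_fraction > 0, coupling_start_fraction < 1,
            coupling_decrement_ms > 0, erp_margin_ms > 0,
            post_final_window_ms > 0, realizations_per_slice >= 1,
            percolation_p >= 0, percolation_p <= 1, dt_ms > 0)
  structure(list(s1_count = as.integer(s1_count), s1_cl_ms = s1_cl_ms,
                 max_extrastimuli = as.integer(max_extrastimuli),
                 coupling_start_fraction = coupling_start_fraction,
                 coupling_decrement_ms = coupling_decrement_ms,
                 erp_margin_ms = erp_margin_ms,
                 post_final_window_ms = post_final_window_ms,
                 realizations_per_slice = as.integer(realizations_per_slice),
                 percolation_p = percolation_p,
                 base_seed = as.integer(base_seed),
                 coupling_floor_ms = coupling_floor_ms,
                 capture_window_ms = capture_window_ms,
                 stim_radius_mm = stim_radius_mm, dt_ms = dt_ms,
                 reentry_min_activations = as.integer(reentry_min_activations),
                 reentry_persist_ms = reentry_persist_ms),
            class = "pes_config")
}

#' Select the endocardial pacing site for a slice
#'
#' Returns the mesh node on the endocardial boundary (myocardium pixels
#' 4-adjacent to the blood pool) nearest the angular position of the LGE
#' mass centroid about the blood-pool centroid. Deterministic: ties are
#' broken by node index.
#'
#' @param slice a `segmented_slice` with LGE and a blood pool.
#' @param mesh the [triangulate_slice()] mesh of that slice.
#' @return A mesh node index.
#' @export
select_pacing_site <- function(slice, mesh) {
  if (!any(slice$lge_mask)) stop("slice has no LGE; pacing site is undefined")
  endo_pix <- slice$myocardium_mask &
    (adjacency_any(slice$bloodpool_mask, dim(slice$myocardium_mask)))
  if (!any(endo_pix)) stop("no endocardial boundary found")
  ctr <- bloodpool_centroid_mm(slice)
  pol <- slice_polar(slice)
  th_l <- pol$theta[slice$lge_mask]
  target <- atan2(mean(sin(th_l)), mean(cos(th_l)))   # circular mean angle
  idx <- which(endo_pix, arr.ind = TRUE)
  sp <- slice$pixel_spacing_mm
  px <- (idx[, 1] - 0.5) * sp; py <- (idx[, 2] - 0.5) * sp
  th_e <- atan2(py - ctr[2], px - ctr[1])
  best <- which.min(ang_diff(th_e, target))
  # nearest mesh node to the chosen endocardial pixel center
  d2 <- (mesh$nodes[, 1] - px[best])^2 + (mesh$nodes[, 2] - py[best])^2
  which.min(d2)
}

# pixels 4-adjacent to any TRUE pixel of mask
adjacency_any <- function(mask, d) {
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- mask
  pad[1:d[1], 2:(d[2] + 1)] | pad[3:(d[1] + 2), 2:(d[2] + 1)] |
    pad[2:(d[1] + 1), 1:d[2]] | pad[2:(d[1] + 1), 3:(d[2] + 2)]
}

#' Re-entry detection on an activation record
#'
#' Re-entry is declared when, within the observation window after the final
#' stimulus, (a) some node has at least `min_act` threshold up-crossings,
#' and (b) at least one up-crossing occurs later than
#' `t_final_stim_ms + persist_ms` (activity outliving the direct wavefront).
#'
#' @param act_node,act_time activation bookkeeping (node ids and times).
#' @param t_final_stim_ms onset time of the final delivered stimulus.
#' @param window_ms observation window (default 600 ms).
#' @param min_act,persist_ms criterion thresholds (defaults 2 and 250 ms).
#' @return List: `reentry` (logical), `n_post_stimulus_reactivations`,
#'   `last_activation_ms_after_final_stimulus`.
#' @export
detect_reentry <- function(act_node, act_time, t_final_stim_ms,
                           window_ms = 600, min_act = 2L, persist_ms = 250) {
  sel <- act_time > t_final_stim_ms & act_time <= t_final_stim_ms + window_ms
  node <- act_node[sel]; tt <- act_time[sel]
  if (length(node) == 0L)
    return(list(reentry = FALSE, n_post_stimulus_reactivations = 0L,
                last_activation_ms_after_final_stimulus = 0))
  counts <- table(node)
  n_re <- sum(pmax(as.integer(counts) - 1L, 0L))
  last <- max(tt) - t_final_stim_ms
  reentry <- any(counts >= min_act) && last > persist_ms
  list(reentry = reentry, n_post_stimulus_reactivations = as.integer(n_re),
       last_activation_ms_after_final_stimulus = last)
}

# doubling scan for the diastolic capture threshold on a quiescent mesh
diastolic_threshold <- function(sys, ionic, stim_nodes, far_nodes, pes) {
  amp <- 0.25
  for (i in 1:8) {
    stim <- list(list(nodes = stim_nodes, start_ms = 2, duration_ms = 2,
                      amplitude = amp))
    res <- run_system(sys, ionic, stim, 0, pes$capture_window_ms + 4,
                      watch_nodes = far_nodes,
                      watch_min = min(5L, length(far_nodes)), watch_after = 2)
    if (res$stopped == "watch") return(amp)
    amp <- amp * 2
  }
  stop("protocol error: stimulus fails to capture at any tested amplitude")
}

#' Run the programmed-stimulation protocol on one mesh realization
#'
#' Delivers `s1_count` S1 beats, then for each extrastimulus level scans the
#' coupling interval downward from `coupling_start_fraction` times the
#' previous interval until capture fails (the ERP), delivers the
#' extrastimulus at ERP + `erp_margin_ms`, and observes
#' `post_final_window_ms` of activity. Observation and re-entry detection
#' run after every delivered extrastimulus; the protocol stops early once
#' re-entry is detected.
#'
#' @param mesh a (typically percolated) `labeled_mesh`.
#' @param site pacing node index (see [select_pacing_site()]).
#' @param ionic,tissue model parameters; conductivity should be calibrated
#'   (see [calibrate_conductivity()]).
#' @param pes a [pes_config()].
#' @return A list of class `pes_outcome`: `slice_index`, `realization_seed`,
#'   `reentry`, `n_post_stimulus_reactivations`,
#'   `last_activation_ms_after_final_stimulus`, `erp_ms` (per level),
#'   `level` (extrastimulus level at which re-entry occurred, or NA).
#' @export
run_pes <- function(mesh, site, ionic = ionic_params(),
                    tissue = tissue_params(), pes = pes_config()) {
  sys <- ep_system(mesh, ionic, tissue, pes$dt_ms)
  xy0 <- mesh$nodes[site, ]
  d_site <- sqrt((sys$xy[, 1] - xy0[1])^2 + (sys$xy[, 2] - xy0[2])^2)
  stim_nodes <- sys$used[d_site <= pes$stim_radius_mm]
  if (length(stim_nodes) == 0L) stim_nodes <- sys$used[which.min(d_site)]
  far_local <- which(d_site >= 4 & d_site <= 7)
  if (length(far_local) < 5L) far_local <- which(d_site >= 3)
  far_nodes <- far_local                       # active-system indices
  amp <- 2 * diastolic_threshold(sys, ionic, stim_nodes, far_nodes, pes)
  stim_of <- function(t0) list(nodes = stim_nodes, start_ms = t0,
                               duration_ms = 2, amplitude = amp)
  snap_ms <- 5
  # --- S1 drive train ---
  t_s1 <- 10 + (seq_len(pes$s1_count) - 1) * pes$s1_cl_ms
  T_prev <- t_s1[pes$s1_count]                 # delivery time of last S1
  state <- run_system(sys, ionic, lapply(t_s1[-pes$s1_count], stim_of),
                      0, T_prev, max_act = 8L)
  erp_ms <- numeric(0)
  prev_interval <- pes$s1_cl_ms
  pending <- stim_of(T_prev)                   # stimulus opening this level
  all_act_node <- integer(0); all_act_time <- numeric(0)

  for (level in seq_len(pes$max_extrastimuli)) {
    ci_max <- snap_ms * floor(pes$coupling_start_fraction * prev_interval / snap_ms)
    ci_max <- max(ci_max, pes$coupling_floor_ms)
    # advance from the pending stimulus, snapshotting every snap_ms
    n_snap <- ci_max / snap_ms
    snaps <- vector("list", n_snap + 1)
    V <- state$V; h <- state$h
    snaps[[1]] <- list(V = V, h = h, t = T_prev)
    seg_act_n <- integer(0); seg_act_t <- numeric(0)
    for (si in seq_len(n_snap)) {
      st <- run_system(sys, ionic, list(pending), T_prev + (si - 1) * snap_ms,
                       snap_ms, V0 = V, h0 = h)
      V <- st$V; h <- st$h
      snaps[[si + 1]] <- list(V = V, h = h, t = T_prev + si * snap_ms)
      seg_act_n <- c(seg_act_n, st$act_node); seg_act_t <- c(seg_act_t, st$act_time)
    }
    if (level == 1L) {
      # S1 capture sanity: the last S1 must excite distant tissue
      s1_far <- sum(unique(seg_act_n[seg_act_t > T_prev]) %in% far_nodes)
      if (s1_far < min(3L, length(far_nodes)))
        stop("protocol error: S1 drive failed to capture the tissue")
    }
    all_act_node <- c(all_act_node, seg_act_n)
    all_act_time <- c(all_act_time, seg_act_t)
    # --- ERP scan: descend from ci_max ---
    capture_at <- function(ci) {
      sn <- snaps[[ci / snap_ms + 1]]
      t2 <- T_prev + ci
      res <- run_system(sys, ionic, list(stim_of(t2)), t2,
                        pes$capture_window_ms + 4, V0 = sn$V, h0 = sn$h,
                        watch_nodes = far_nodes,
                        watch_min = min(5L, length(far_nodes)),
                        watch_after = t2 + 2)
      res$stopped == "watch"
    }
    ci <- ci_max; erp <- NA_real_
    ci_up_max <- min(1.5 * prev_interval, pes$s1_cl_ms * 0.9)
    if (!capture_at(ci)) {
      # ERP above the scan start: step upward until capture, deliver there
      while (ci < ci_up_max - pes$coupling_decrement_ms && !capture_at(ci)) {
        ci <- ci + pes$coupling_decrement_ms
        if (ci / snap_ms + 1 > length(snaps)) {   # extend the snapshot line
          need <- ci / snap_ms - (length(snaps) - 1)
          for (k in seq_len(need)) {
            st <- run_system(sys, ionic, list(pending),
                             T_prev + (length(snaps) - 1) * snap_ms, snap_ms,
                             V0 = V, h0 = h)
            V <- st$V; h <- st$h
            snaps[[length(snaps) + 1]] <- list(V = V, h = h)
            all_act_node <- c(all_act_node, st$act_node)
            all_act_time <- c(all_act_time, st$act_time)
          }
        }
      }
      if (!capture_at(ci))
        stop("protocol error: extrastimulus never captures")
      erp <- ci - pes$coupling_decrement_ms    # refractory just below capture
      deliver_ci <- ci
    } else {
      while (ci - pes$coupling_decrement_ms >= pes$coupling_floor_ms &&
             capture_at(ci - pes$coupling_decrement_ms))
        ci <- ci - pes$coupling_decrement_ms
      erp <- ci - pes$coupling_decrement_ms    # first failing interval
      deliver_ci <- erp + pes$erp_margin_ms
      if (!capture_at(deliver_ci)) deliver_ci <- ci   # fall back to captured CI
    }
    erp_ms <- c(erp_ms, erp)
    t_deliver <- T_prev + deliver_ci
    sn <- snaps[[deliver_ci / snap_ms + 1]]
    # --- observation branch: deliver and watch the full window ---
    obs <- run_system(sys, ionic, list(stim_of(t_deliver)), t_deliver,
                      pes$post_final_window_ms + 4, V0 = sn$V, h0 = sn$h,
                      stop_on_quiescent = TRUE, max_act = 16L)
    det <- detect_reentry(obs$act_node, obs$act_time, t_deliver,
                          pes$post_final_window_ms,
                          pes$reentry_min_activations, pes$reentry_persist_ms)
    if (det$reentry || level == pes$max_extrastimuli) {
      all_act_node <- c(all_act_node, obs$act_node)
      all_act_time <- c(all_act_time, obs$act_time)
      return(structure(list(slice_index = mesh$slice_index,
                            realization_seed = mesh$percolation_seed,
                            reentry = det$reentry,
                            n_post_stimulus_reactivations =
                              det$n_post_stimulus_reactivations,
                            last_activation_ms_after_final_stimulus =
                              det$last_activation_ms_after_final_stimulus,
                            erp_ms = erp_ms,
                            level = if (det$reentry) level else NA_integer_,
                            act_node = sys$used[all_act_node],
                            act_time = all_act_time),
                       class = "pes_outcome"))
    }
    # continue the train: the delivered extrastimulus becomes the pending
    # stimulus of the next level
    state <- list(V = sn$V, h = sn$h)
    T_prev <- t_deliver
    prev_interval <- deliver_ci
    pending <- stim_of(t_deliver)
  }
}

#' @export
#' @method print pes_outcome
print.pes_outcome <- function(x, ...) {
  cat(sprintf(
    "PES outcome (slice %s, seed %s): reentry = %s, reactivations = %d, last activity %.0f ms\n",
    x$slice_index, x$realization_seed, x$reentry,
    x$n_post_stimulus_reactivations,
    x$last_activation_ms_after_final_stimulus))
  invisible(x)
}

#' Count inducible re-entries for a patient
#'
#' Runs the PES protocol on every slice containing LGE, with
#' `realizations_per_slice` independent percolation patterns per slice
#' (seeds `base_seed + 1 .. base_seed + realizations`), and sums the
#' induced re-entries. Protocol errors on a slice are recorded, not fatal.
#'
#' @param patient a [patient_record()].
#' @param ionic,tissue model parameters (conductivity pre-calibrated).
#' @param pes a [pes_config()].
#' @param max_edge_mm mesh resolution (default 0.25 mm).
#' @return Integer count, with attribute `"outcomes"`: a data.frame of all
#'   per-slice, per-realization outcomes (including error flags).
#' @export
simulated_reentries <- function(patient, ionic = ionic_params(),
                                tissue = tissue_params(),
                                pes = pes_config(), max_edge_mm = 0.25) {
  rows <- list()
  for (s in patient$slices) {
    if (!any(s$lge_mask)) next
    mesh <- triangulate_slice(s, max_edge_mm)
    site <- select_pacing_site(s, mesh)
    for (r in seq_len(pes$realizations_per_slice)) {
      seed <- pes$base_seed + r
      out <- tryCatch({
        pmesh <- percolate(mesh, pes$percolation_p, seed)
        o <- run_pes(pmesh, site, ionic, tissue, pes)
        data.frame(patient_id = patient$patient_id,
                   slice_index = s$slice_index, seed = seed,
                   reentry = o$reentry,
                   n_reactivations = o$n_post_stimulus_reactivations,
                   last_activity_ms = o$last_activation_ms_after_final_stimulus,
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(patient_id = patient$patient_id,
                   slice_index = s$slice_index, seed = seed, reentry = FALSE,
                   n_reactivations = NA_integer_, last_activity_ms = NA_real_,
                   error = conditionMessage(e), stringsAsFactors = FALSE))
      rows[[length(rows) + 1]] <- out
    }
  }
  outcomes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), slice_index = integer(0),
               seed = integer(0), reentry = logical(0),
               n_reactivations = integer(0), last_activity_ms = numeric(0),
               error = character(0))
  structure(sum(outcomes$reentry, na.rm = TRUE), outcomes = outcomes)
}
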