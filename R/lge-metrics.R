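# The six per-patient LGE shape metrics: interface area, volume, entropy,
# mean transmurality, number of 4-connected components, mean radiality;
# plus the FWHM segmentation rule. The simulated-re-entries count is filled
# in by the programmed-stimulation module.

#' LGE metric set
#'
#' Bundle of the per-patient scar-shape metrics. `simulated_reentries` is 0
#' until filled by [simulated_reentries()].
#'
#' @param patient_id patient identifier.
#' @param interface_area_cm2,volume_cm3,entropy_bits,mean_transmurality,n_components,mean_radiality
#'   metric values; see the individual metric functions.
#' @param simulated_reentries non-negative integer.
#' @param warnings character vector of degenerate-input flags.
#' @return An object of class `lge_metric_set`.
#' @export
lge_metric_set <- function(patient_id, interface_area_cm2 = 0, volume_cm3 = 0,
                           entropy_bits = 0, mean_transmurality = 0,
                           n_components = 0L, mean_radiality = 0,
                           simulated_reentries = 0L, warnings = character(0)) {
  stopifnot(interface_area_cm2 >= 0, volume_cm3 >= 0, entropy_bits >= 0,
            mean_transmurality >= 0, mean_transmurality <= 1,
            n_components >= 0, mean_radiality >= 0, mean_radiality <= 1,
            simulated_reentries >= 0)
  structure(list(patient_id = as.character(patient_id),
                 interface_area_cm2 = interface_area_cm2,
                 volume_cm3 = volume_cm3, entropy_bits = entropy_bits,
                 mean_transmurality = mean_transmurality,
                 n_components = as.integer(n_components),
                 mean_radiality = mean_radiality,
                 simulated_reentries = as.integer(simulated_reentries),
                 warnings = warnings),
            class = "lge_metric_set")
}

#' @export
#' @method print lge_metric_set
print.lge_metric_set <- function(x, ...) {
  cat(sprintf("LGE metrics for patient %s:\n", x$patient_id))
  cat(sprintf("  interface area     %8.2f cm^2\n", x$interface_area_cm2))
  cat(sprintf("  volume             %8.2f cm^3\n", x$volume_cm3))
  cat(sprintf("  entropy            %8.3f bits\n", x$entropy_bits))
  cat(sprintf("  mean transmurality %8.3f\n", x$mean_transmurality))
  cat(sprintf("  components         %8d\n", x$n_components))
  cat(sprintf("  mean radiality     %8.3f\n", x$mean_radiality))
  cat(sprintf("  simulated reentries%8d\n", x$simulated_reentries))
  if (length(x$warnings)) cat("  flags:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}

#' Full-width-half-maximum scar segmentation
#'
#' Returns the myocardium pixels whose intensity is at least half the
#' maximum intensity inside a reference enhanced region `roi_mask`. On a
#' constant image every myocardium pixel satisfies the rule, so the whole
#' myocardium is returned (degenerate but well defined).
#'
#' @param slice a `segmented_slice` with an intensity image.
#' @param roi_mask logical matrix, a nonempty subset of the myocardium mask.
#' @return Logical matrix of segmented scar pixels.
#' @export
fwhm_segment <- function(slice, roi_mask) {
  if (is.null(slice$intensity)) stop("slice has no intensity image")
  if (!any(roi_mask)) stop("empty ROI")
  if (any(roi_mask & !slice$myocardium_mask))
    stop("roi_mask must be a subset of the myocardium mask")
  thr <- 0.5 * max(slice$intensity[roi_mask])
  slice$myocardium_mask & slice$intensity >= thr
}

# unordered 4-adjacent pixel pairs (p in A, q in B): count across both
# grid orientations
adjacent_pair_count <- function(A, B) {
  d <- dim(A)
  n <- 0L
  if (d[1] > 1L) {
    up <- A[-1, , drop = FALSE] & B[-d[1], , drop = FALSE]
    dn <- A[-d[1], , drop = FALSE] & B[-1, , drop = FALSE]
    n <- n + sum(up) + sum(dn)
  }
  if (d[2] > 1L) {
    lf <- A[, -1, drop = FALSE] & B[, -d[2], drop = FALSE]
    rt <- A[, -d[2], drop = FALSE] & B[, -1, drop = FALSE]
    n <- n + sum(lf) + sum(rt)
  }
  n
}

# per-slice interface area in cm^2
slice_interface_area_cm2 <- function(s) {
  healthy <- s$myocardium_mask & !s$lge_mask
  n_pairs <- adjacent_pair_count(s$lge_mask, healthy)
  n_pairs * s$pixel_spacing_mm * s$slice_thickness_mm / 100
}

#' LGE-myocardium interface area
#'
#' Total arc length of the border between LGE and surviving myocardium,
#' multiplied by the slice thickness and summed over slices (cm^2). The arc
#' length on a slice is the number of unordered 4-adjacent pixel pairs with
#' one pixel in LGE and the other in non-LGE myocardium, times the pixel
#' spacing (the pixel-edge boundary measure). Borders between LGE and
#' non-myocardium (endo/epicardial surface, blood pool, background)
#' contribute nothing.
#'
#' @param patient a [patient_record()].
#' @return Interface area in cm^2.
#' @export
interface_area <- function(patient) {
  sum(vapply(patient$slices, slice_interface_area_cm2, numeric(1)))
}

#' LGE volume
#'
#' Sum over slices of LGE pixel count x spacing^2 x thickness, in cm^3.
#'
#' @param patient a [patient_record()].
#' @return Volume in cm^3.
#' @export
lge_volume <- function(patient) {
  sum(vapply(patient$slices, function(s)
    sum(s$lge_mask) * s$pixel_spacing_mm^2 * s$slice_thickness_mm / 1000,
    numeric(1)))
}

#' LGE intensity entropy
#'
#' Shannon entropy (bits) of the pooled signal intensities of all LGE
#' pixels across slices, histogrammed into `bins` equal-width bins spanning
#' the pooled range. Zero if all LGE intensities are equal; zero with a
#' warning flag if there is no LGE.
#'
#' @param patient a [patient_record()]; slices containing LGE must carry
#'   intensity images.
#' @param bins number of histogram bins (default 32).
#' @return Entropy in bits, with attribute `"warning"` when degenerate.
#' @export
lge_entropy <- function(patient, bins = 32L) {
  vals <- unlist(lapply(patient$slices, function(s) {
    if (!any(s$lge_mask)) return(numeric(0))
    if (is.null(s$intensity))
      stop("slice ", s$slice_index, " has LGE but no intensity image")
    s$intensity[s$lge_mask]
  }))
  if (length(vals) == 0L)
    return(structure(0, warning = "no LGE pixels"))
  lo <- min(vals); hi <- max(vals)
  if (hi == lo) return(0)
  b <- pmin(bins, 1L + floor((vals - lo) / (hi - lo) * bins))
  p <- tabulate(b, nbins = bins) / length(vals)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Sample masks along K radial chords from the blood-pool centroid.
# step_mm controls the sampling resolution along each chord.
chord_samples <- function(s, K, step_mm) {
  ctr <- bloodpool_centroid_mm(s)
  d <- dim(s$myocardium_mask)
  sp <- s$pixel_spacing_mm
  rmax <- sqrt(sum((d * sp)^2))           # grid diagonal: always reaches edge
  radii <- seq(step_mm / 2, rmax, by = step_mm)
  theta <- (seq_len(K) - 1) * 2 * pi / K
  # sample points: K x n_steps grids of row/col indices
  px <- outer(cos(theta), radii) + ctr[1]
  py <- outer(sin(theta), radii) + ctr[2]
  i <- floor(px / sp) + 1
  j <- floor(py / sp) + 1
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
  lin <- (pmin(pmax(j, 1), d[2]) - 1) * d[1] + pmin(pmax(i, 1), d[1])
  myo <- matrix(FALSE, K, length(radii)); lge <- myo
  myo[ok] <- s$myocardium_mask[lin[ok]]
  lge[ok] <- s$lge_mask[lin[ok]]
  list(myo = myo, lge = lge)
}

# per-slice mean chord transmurality (NA when slice has no LGE)
slice_transmurality <- function(s, K = 180L, step_mm = 0.25) {
  if (!any(s$lge_mask)) return(NA_real_)
  cs <- chord_samples(s, K, step_mm)
  wall <- rowSums(cs$myo)
  scar <- rowSums(cs$lge)
  sel <- scar > 0 & wall > 0
  if (!any(sel)) return(NA_real_)
  mean(pmin(scar[sel] / wall[sel], 1))
}

#' Mean LGE transmurality
#'
#' Chord-based transmurality: on each slice, `K` radial chords are cast from
#' the blood-pool centroid at uniform angles and sampled every `step_mm`;
#' a chord's transmurality is its LGE extent divided by its wall (myocardium)
#' extent, averaged over chords that cross LGE; the patient value is the
#' mean over slices containing LGE.
#'
#' @param patient a [patient_record()].
#' @param K number of chords per slice (default 180).
#' @param step_mm sampling step along each chord (default 0.25 mm).
#' @return Mean transmurality in `[0, 1]`; 0 with a warning attribute when
#'   the patient has no LGE.
#' @export
mean_transmurality <- function(patient, K = 180L, step_mm = 0.25) {
  v <- vapply(patient$slices, slice_transmurality, numeric(1),
              K = K, step_mm = step_mm)
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(structure(0, warning = "no LGE pixels"))
  mean(v)
}

# 4-connected component count of a logical matrix (two-pass union-find)
label_components4 <- function(mask) {
  d <- dim(mask)
  n <- sum(mask)
  if (n == 0L) return(0L)
  lab <- matrix(0L, d[1], d[2])
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nxt <- 0L
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j]) next
    up <- if (i > 1L && mask[i - 1L, j]) lab[i - 1L, j] else 0L
    lf <- if (j > 1L && mask[i, j - 1L]) lab[i, j - 1L] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
    } else if (up > 0L && lf > 0L) {
      ru <- find(up); rl <- find(lf)
      if (ru != rl) parent[ru] <- rl
      lab[i, j] <- rl
    } else lab[i, j] <- max(up, lf)
  }
  length(unique(vapply(seq_len(nxt), find, integer(1))))
}

#' Number of LGE components
#'
#' Total number of 4-connected LGE regions summed over all slices.
#'
#' @param patient a [patient_record()].
#' @return Non-negative integer count.
#' @export
count_components <- function(patient) {
  sum(vapply(patient$slices, function(s) label_components4(s$lge_mask),
             integer(1)))
}

# per-slice circular variance of LGE pixel angles (NA when no LGE)
slice_radiality <- function(s) {
  if (!any(s$lge_mask)) return(NA_real_)
  pol <- slice_polar(s)
  th <- pol$theta[s$lge_mask]
  1 - sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Mean LGE radiality
#'
#' Angular (circular) variance of the LGE pixel centers about the blood-pool
#' centroid: `1 - ||mean resultant vector||`, in `[0, 1]`; 0 when all LGE
#' sits at one angle, 1 for angularly balanced scar (e.g. a full ring).
#' Patient value is the mean over slices containing LGE.
#'
#' @param patient a [patient_record()].
#' @return Mean radiality in `[0, 1]`; 0 with a warning attribute when the
#'   patient has no LGE.
#' @export
mean_radiality <- function(patient) {
  for (s in patient$slices)
    if (any(s$lge_mask) && !any(s$bloodpool_mask))
      stop("empty blood pool on a slice with LGE")
  v <- vapply(patient$slices, slice_radiality, numeric(1))
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(structure(0, warning = "no LGE pixels"))
  mean(v)
}

#' Compute the full LGE metric set for a patient
#'
#' Assembles interface area, volume, entropy (when intensity images are
#' present), transmurality, component count and radiality.
#' `simulated_reentries` is left at 0 until [simulated_reentries()] fills it.
#'
#' @param patient a [patient_record()].
#' @param entropy_bins histogram bins for [lge_entropy()].
#' @return An [lge_metric_set()].
#' @export
compute_patient_metrics <- function(patient, entropy_bins = 32L) {
  warnings <- character(0)
  has_lge <- any(vapply(patient$slices, function(s) any(s$lge_mask), logical(1)))
  has_int <- all(vapply(patient$slices,
                        function(s) !any(s$lge_mask) || !is.null(s$intensity),
                        logical(1)))
  ent <- if (has_int) lge_entropy(patient, entropy_bins) else {
    warnings <- c(warnings, "no intensity images; entropy set to 0")
    0
  }
  tm <- mean_transmurality(patient)
  rad <- mean_radiality(patient)
  if (!has_lge) warnings <- c(warnings, "no LGE pixels")
  lge_metric_set(patient$patient_id,
                 interface_area_cm2 = interface_area(patient),
                 volume_cm3 = lge_volume(patient),
                 entropy_bits = as.numeric(ent),
                 mean_transmurality = as.numeric(tm),
                 n_components = count_components(patient),
                 mean_radiality = as.numeric(rad),
                 warnings = unique(c(warnings, attr(ent, "warning"),
                                     attr(tm, "warning"), attr(rad, "warning"))))
}
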