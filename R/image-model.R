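#' Segmented short-axis slice
#'
#' Container for one segmented short-axis LGE-CMR slice: a myocardium mask,
#' an LGE (scar) mask, a blood-pool mask and an optional signal-intensity
#' image, together with the in-plane pixel spacing and the slice thickness.
#'
#' All grids must share one shape; the LGE mask must be contained in the
#' myocardium mask and the blood pool must be disjoint from the myocardium.
#' Pixel centers sit at `(i - 0.5, j - 0.5) * pixel_spacing_mm` for 1-based
#' row/column indices `(i, j)`, and all geometry in the package is derived
#' from pixel centers.
#'
#' @param slice_index integer position of the slice in the stack (base 1).
#' @param pixel_spacing_mm isotropic in-plane pixel spacing in mm (> 0).
#' @param slice_thickness_mm slice thickness in mm (> 0).
#' @param myocardium_mask,lge_mask,bloodpool_mask logical matrices of one
#'   common shape.
#' @param intensity optional numeric matrix of non-negative signal
#'   intensities, same shape as the masks.
#' @return An object of class `segmented_slice`.
#' @export
segmented_slice <- function(slice_index, pixel_spacing_mm, slice_thickness_mm,
                            myocardium_mask, lge_mask, bloodpool_mask,
                            intensity = NULL) {
  x <- structure(
    list(slice_index = as.integer(slice_index),
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         myocardium_mask = myocardium_mask,
         lge_mask = lge_mask,
         bloodpool_mask = bloodpool_mask,
         intensity = intensity),
    class = "segmented_slice")
  validate_slice(x)
  x
}

#' Validate a segmented slice
#'
#' Checks every structural invariant of a [segmented_slice()] and stops with
#' an error naming the first violated rule.
#'
#' @param x a `segmented_slice`.
#' @return `x`, invisibly, if valid.
#' @export
validate_slice <- function(x) {
  stopifnot(inherits(x, "segmented_slice"))
  for (nm in c("myocardium_mask", "lge_mask", "bloodpool_mask"))
    if (!is.matrix(x[[nm]]) || !is.logical(x[[nm]]))
      stop("invariant violated: ", nm, " must be a logical matrix")
  d <- dim(x$myocardium_mask)
  if (!identical(dim(x$lge_mask), d) || !identical(dim(x$bloodpool_mask), d))
    stop("invariant violated: all grids must share one shape")
  if (!is.null(x$intensity)) {
    if (!is.matrix(x$intensity) || !identical(dim(x$intensity), d))
      stop("invariant violated: intensity must match mask shape")
    if (any(x$intensity < 0))
      stop("invariant violated: intensity must be non-negative")
  }
  if (!is.finite(x$pixel_spacing_mm) || x$pixel_spacing_mm <= 0)
    stop("invariant violated: pixel_spacing_mm must be > 0")
  if (!is.finite(x$slice_thickness_mm) || x$slice_thickness_mm <= 0)
    stop("invariant violated: slice_thickness_mm must be > 0")
  if (any(x$lge_mask & !x$myocardium_mask))
    stop("invariant violated: lge_mask must be a subset of myocardium_mask")
  if (any(x$bloodpool_mask & x$myocardium_mask))
    stop("invariant violated: bloodpool_mask must be disjoint from myocardium_mask")
  invisible(x)
}

#' @export
#' @method print segmented_slice
print.segmented_slice <- function(x, ...) {
  d <- dim(x$myocardium_mask)
  cat(sprintf(
    "Segmented slice %d: %d x %d px @ %.2f mm, thickness %.1f mm\n",
    x$slice_index, d[1], d[2], x$pixel_spacing_mm, x$slice_thickness_mm))
  cat(sprintf("  myocardium %d px, LGE %d px, blood pool %d px%s\n",
              sum(x$myocardium_mask), sum(x$lge_mask), sum(x$bloodpool_mask),
              if (is.null(x$intensity)) "" else ", with intensity"))
  invisible(x)
}

#' Patient record: slice stack, covariates and follow-up
#'
#' @param patient_id character scalar.
#' @param slices list of [segmented_slice()] objects; stored ordered by
#'   `slice_index`.
#' @param covariates named list or vector of baseline covariates
#'   (numeric or logical).
#' @param followup_days non-negative follow-up time in days.
#' @param event logical: did the arrhythmic endpoint occur at `followup_days`?
#' @param icd_day optional day of ICD implantation (`<= followup_days`).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, slices, covariates = list(),
                           followup_days = 0, event = FALSE, icd_day = NULL) {
  covariates <- as.list(covariates)
  if (anyDuplicated(names(covariates)))
    stop("invariant violated: covariate names must be unique")
  if (!is.finite(followup_days) || followup_days < 0)
    stop("invariant violated: followup_days must be >= 0")
  if (!is.null(icd_day) && icd_day > followup_days)
    stop("invariant violated: icd_day must be <= followup_days")
  for (s in slices) validate_slice(s)
  ord <- order(vapply(slices, `[[`, integer(1), "slice_index"))
  structure(
    list(patient_id = as.character(patient_id), slices = slices[ord],
         covariates = covariates, followup_days = as.numeric(followup_days),
         event = isTRUE(event), icd_day = icd_day),
    class = "patient_record")
}

#' @export
#' @method print patient_record
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient %s: %d slice(s), follow-up %.0f days, event = %s%s\n",
              x$patient_id, length(x$slices), x$followup_days, x$event,
              if (is.null(x$icd_day)) "" else sprintf(", ICD at day %.0f", x$icd_day)))
  invisible(x)
}

mask_to_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
}

png_to_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' Write a patient record to a directory
#'
#' Each mask is written as one 8-bit 0/255 grayscale PNG per slice
#' (`myo_<k>.png`, `lge_<k>.png`, `blood_<k>.png`), optional intensities as
#' plain-text TSV (`intensity_<k>.tsv`, exact at double precision), and
#' spacing, thickness, covariates and outcome in a `meta.json` sidecar.
#' [read_patient()] restores the record bit-exactly on masks and metadata.
#'
#' @param record a [patient_record()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_patient <- function(record, out_dir) {
  stopifnot(inherits(record, "patient_record"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  meta <- list(
    patient_id = record$patient_id,
    covariates = record$covariates,
    followup_days = record$followup_days,
    event = record$event,
    icd_day = record$icd_day,
    slices = lapply(record$slices, function(s)
      list(slice_index = s$slice_index,
           pixel_spacing_mm = s$pixel_spacing_mm,
           slice_thickness_mm = s$slice_thickness_mm,
           has_intensity = !is.null(s$intensity),
           shape = dim(s$myocardium_mask))))
  jsonlite::write_json(meta, file.path(out_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (s in record$slices) {
    k <- s$slice_index
    mask_to_png(s$myocardium_mask, file.path(out_dir, sprintf("myo_%d.png", k)))
    mask_to_png(s$lge_mask, file.path(out_dir, sprintf("lge_%d.png", k)))
    mask_to_png(s$bloodpool_mask, file.path(out_dir, sprintf("blood_%d.png", k)))
    if (!is.null(s$intensity))
      utils::write.table(format(s$intensity, digits = 17, trim = TRUE),
                         file.path(out_dir, sprintf("intensity_%d.tsv", k)),
                         sep = "\t", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
  }
  invisible(out_dir)
}

#' Read a patient record from a directory written by [write_patient()]
#'
#' @param stack_dir directory containing per-slice mask PNGs and `meta.json`.
#' @return A validated [patient_record()], slices ordered by index.
#' @export
read_patient <- function(stack_dir) {
  mf <- file.path(stack_dir, "meta.json")
  if (!file.exists(mf)) stop("missing metadata file: ", mf)
  meta <- jsonlite::read_json(mf)
  slices <- lapply(meta$slices, function(sm) {
    k <- sm$slice_index
    paths <- file.path(stack_dir, sprintf(c("myo_%d.png", "lge_%d.png",
                                            "blood_%d.png"), k))
    if (!all(file.exists(paths)))
      stop("missing mask file(s) for slice ", k, ": ",
           paste(basename(paths[!file.exists(paths)]), collapse = ", "))
    intensity <- NULL
    if (isTRUE(sm$has_intensity)) {
      ip <- file.path(stack_dir, sprintf("intensity_%d.tsv", k))
      if (!file.exists(ip)) stop("missing intensity file for slice ", k)
      intensity <- as.matrix(utils::read.table(ip, sep = "\t"))
      dimnames(intensity) <- NULL
    }
    segmented_slice(k, sm$pixel_spacing_mm, sm$slice_thickness_mm,
                    png_to_mask(paths[1]), png_to_mask(paths[2]),
                    png_to_mask(paths[3]), intensity)
  })
  cov <- lapply(meta$covariates, function(v) if (is.logical(v)) v else as.numeric(v))
  patient_record(meta$patient_id, slices, cov, meta$followup_days,
                 isTRUE(meta$event),
                 if (is.null(meta$icd_day)) NULL else as.numeric(meta$icd_day))
}

#' Assemble and write the per-patient cohort table
#'
#' Joins patient outcome fields and covariates with their LGE metric sets
#' (matched by `patient_id`) into one flat data frame, one row per patient,
#' and optionally writes it as CSV.
#'
#' @param records list of [patient_record()].
#' @param metrics list of [lge_metric_set()] objects, one per record.
#' @param path optional CSV output path.
#' @return The cohort `data.frame` (invisibly if `path` is given).
#' @export
write_cohort_table <- function(records, metrics, path = NULL) {
  ids <- vapply(records, `[[`, character(1), "patient_id")
  mids <- vapply(metrics, function(m) m$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient_id in records")
  miss <- setdiff(ids, mids)
  extra <- setdiff(mids, ids)
  if (length(miss) || length(extra))
    stop("join error: unmatched patient ids: ",
         paste(c(miss, extra), collapse = ", "))
  metric_cols <- c("interface_area_cm2", "volume_cm3", "entropy_bits",
                   "mean_transmurality", "n_components", "mean_radiality",
                   "simulated_reentries")
  rows <- lapply(records, function(r) {
    m <- metrics[[match(r$patient_id, mids)]]
    c(list(patient_id = r$patient_id),
      lapply(r$covariates, function(v) if (is.logical(v)) as.integer(v) else v),
      m[metric_cols],
      list(followup_days = r$followup_days, event = as.integer(r$event),
           icd_day = if (is.null(r$icd_day)) NA_real_ else r$icd_day))
  })
  if (length(rows) == 0L) {
    tab <- data.frame(patient_id = character(0))
  } else {
    tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Plot a segmented slice
#'
#' Base-graphics rendering: myocardium in grey, LGE in red, blood pool in
#' blue, over the intensity image when present.
#'
#' @param x a `segmented_slice`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
#' @method plot segmented_slice
plot.segmented_slice <- function(x, ...) {
  d <- dim(x$myocardium_mask)
  sp <- x$pixel_spacing_mm
  bg <- if (is.null(x$intensity)) matrix(0, d[1], d[2]) else x$intensity
  graphics::image(seq_len(d[1]) * sp, seq_len(d[2]) * sp, bg,
                  col = grDevices::grey.colors(64, 0, 1), asp = 1,
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("slice %d", x$slice_index), ...)
  overlay <- function(mask, col) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx)) graphics::points(idx[, 1] * sp, idx[, 2] * sp, pch = 15,
                                    col = col, cex = 25 / max(d))
  }
  overlay(x$myocardium_mask & !x$lge_mask, grDevices::adjustcolor("firebrick", 0.35))
  overlay(x$lge_mask, "gold")
  overlay(x$bloodpool_mask, grDevices::adjustcolor("steelblue", 0.4))
  invisible(x)
}
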