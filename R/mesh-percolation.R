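# Structured triangulation of segmented slices and percolation fibrosis.
# Each myocardium pixel is subdivided into a k x k grid of squares, each
# split into two right triangles, so that every edge is at most max_edge_mm
# (k = ceiling(spacing * sqrt(2) / max_edge)). Element labels are inherited
# from the pixel masks; percolation independently removes LGE elements with
# probability p, creating internal no-flux obstacles.

ELEM_HEALTHY <- 1L
ELEM_LGE <- 2L
ELEM_REMOVED <- 3L

#' Triangulate a segmented slice into a labeled finite-element mesh
#'
#' Deterministic structured meshing: each myocardium pixel is covered by
#' `2 k^2` congruent right triangles with legs `spacing / k`, where
#' `k = ceiling(spacing * sqrt(2) / max_edge_mm)` guarantees every edge
#' (including hypotenuses) is at most `max_edge_mm`. Only the myocardium is
#' meshed; each element carries the label of its source pixel (LGE or
#' healthy). Neighbouring pixels share nodes, so the mesh is conforming.
#'
#' @param slice a `segmented_slice` with nonempty myocardium.
#' @param max_edge_mm maximum element edge length in mm (default 0.25).
#' @return An object of class `labeled_mesh` with fields `nodes` (n x 2
#'   matrix, mm), `elements` (m x 3 node indices), `label` (per element:
#'   1 healthy, 2 LGE, 3 removed), `slice_index`, `subdivision`, and
#'   percolation provenance (`percolation_p`, `percolation_seed`).
#' @export
triangulate_slice <- function(slice, max_edge_mm = 0.25) {
  if (max_edge_mm <= 0) stop("max_edge_mm must be > 0")
  myo <- slice$myocardium_mask
  if (!any(myo)) stop("empty myocardium")
  sp <- slice$pixel_spacing_mm
  k <- ceiling(sp * sqrt(2) / max_edge_mm)
  h <- sp / k
  pix <- which(myo, arr.ind = TRUE)           # one row per myocardium pixel
  npix <- nrow(pix)
  # fine-lattice cell origins for every subdivided square of every pixel
  sub <- as.matrix(expand.grid(a = 0:(k - 1), b = 0:(k - 1)))
  # global fine-lattice integer coords of each square's lower corner
  gi <- rep((pix[, 1] - 1L) * k, each = k * k) + sub[, "a"]
  gj <- rep((pix[, 2] - 1L) * k, each = k * k) + sub[, "b"]
  # the four corners of each square, as fine-lattice keys
  d <- dim(myo)
  nkey1 <- d[1] * k + 1L                       # lattice rows
  key <- function(i, j) j * nkey1 + i + 1      # 0-based lattice -> key
  c00 <- key(gi, gj); c10 <- key(gi + 1L, gj)
  c01 <- key(gi, gj + 1L); c11 <- key(gi + 1L, gj + 1L)
  keys <- sort(unique(c(c00, c10, c01, c11)))
  idx <- function(kv) match(kv, keys)
  i00 <- idx(c00); i10 <- idx(c10); i01 <- idx(c01); i11 <- idx(c11)
  # two triangles per square: (00,10,11) and (00,11,01); both CCW-consistent
  elements <- rbind(cbind(i00, i10, i11), cbind(i00, i11, i01))
  dimnames(elements) <- NULL
  lab_pix <- ifelse(slice$lge_mask[myo], ELEM_LGE, ELEM_HEALTHY)
  lab_sq <- rep(lab_pix, each = k * k)
  label <- c(lab_sq, lab_sq)
  lat_i <- (keys - 1) %% nkey1                 # back to lattice coords
  lat_j <- (keys - 1) %/% nkey1
  nodes <- cbind(x = lat_i * h, y = lat_j * h)
  structure(list(nodes = nodes, elements = elements, label = label,
                 slice_index = slice$slice_index, subdivision = k,
                 spacing_mm = sp, edge_mm = h,
                 percolation_p = 0, percolation_seed = NA_integer_),
            class = "labeled_mesh")
}

#' @export
#' @method print labeled_mesh
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("Labeled mesh (slice %d): %d nodes, %d elements (edge %.3g mm)\n",
              x$slice_index, nrow(x$nodes), nrow(x$elements), x$edge_mm))
  cat(sprintf("  healthy %d | LGE %d | removed %d (p = %.2f, seed %s)\n",
              sum(x$label == ELEM_HEALTHY), sum(x$label == ELEM_LGE),
              sum(x$label == ELEM_REMOVED), x$percolation_p,
              as.character(x$percolation_seed)))
  invisible(x)
}

#' Impose percolation fibrosis on the LGE region of a mesh
#'
#' Each LGE element independently becomes `REMOVED` with probability `p`
#' (seed-deterministic); removed elements are excluded from the
#' finite-element assembly and act as internal no-flux obstacles. Healthy
#' elements are untouched.
#'
#' @param mesh a [triangulate_slice()] mesh.
#' @param p removal probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return The mesh with updated labels and provenance.
#' @export
percolate <- function(mesh, p, seed = 1L) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  lge <- which(mesh$label == ELEM_LGE)
  rm_idx <- with_seed(seed, lge[stats::runif(length(lge)) < p])
  mesh$label[rm_idx] <- ELEM_REMOVED
  mesh$percolation_p <- p
  mesh$percolation_seed <- as.integer(seed)
  mesh
}

#' Element areas of a labeled mesh
#' @param mesh a `labeled_mesh`.
#' @return Numeric vector of signed-free triangle areas (mm^2).
#' @export
element_areas <- function(mesh) {
  p1 <- mesh$nodes[mesh$elements[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$elements[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$elements[, 3], , drop = FALSE]
  abs((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
}

#' Write a mesh as plain-text node and element files
#'
#' `<stem>.nodes`: one `x y` pair (mm) per line; `<stem>.elems`: one
#' `n1 n2 n3 label` quadruple per line (1-based node indices), mirroring
#' common cardiac-simulation text formats.
#'
#' @param mesh a `labeled_mesh`.
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
write_mesh <- function(mesh, stem) {
  utils::write.table(mesh$nodes, paste0(stem, ".nodes"), row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cbind(mesh$elements, mesh$label), paste0(stem, ".elems"),
                     row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' Read a mesh written by [write_mesh()]
#' @param stem path stem used in [write_mesh()].
#' @return A `labeled_mesh` (provenance fields unset).
#' @export
read_mesh <- function(stem) {
  nodes <- as.matrix(utils::read.table(paste0(stem, ".nodes")))
  el <- as.matrix(utils::read.table(paste0(stem, ".elems")))
  dimnames(nodes) <- list(NULL, c("x", "y"))
  dimnames(el) <- NULL
  el_idx <- el[, 1:3, drop = FALSE]
  storage.mode(el_idx) <- "integer"
  structure(list(nodes = nodes, elements = el_idx,
                 label = as.integer(el[, 4]), slice_index = NA_integer_,
                 subdivision = NA_integer_, spacing_mm = NA_real_,
                 edge_mm = max(sqrt(rowSums((nodes[el[, 2], , drop = FALSE] -
                                             nodes[el[, 1], , drop = FALSE])^2))),
                 percolation_p = 0, percolation_seed = NA_integer_),
            class = "labeled_mesh")
}
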