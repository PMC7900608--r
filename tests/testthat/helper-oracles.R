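# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive implementation kept separate from the
# package's code paths.

# brute-force interface pair counting: loop over every pixel and its 4
# neighbours, count LGE / (myocardium minus LGE) pairs once
oracle_interface_pairs <- function(lge, myo) {
  d <- dim(lge)
  healthy <- myo & !lge
  cnt <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!lge[i, j]) next
    if (i > 1 && healthy[i - 1, j]) cnt <- cnt + 1L
    if (i < d[1] && healthy[i + 1, j]) cnt <- cnt + 1L
    if (j > 1 && healthy[i, j - 1]) cnt <- cnt + 1L
    if (j < d[2] && healthy[i, j + 1]) cnt <- cnt + 1L
  }
  cnt
}

# stack-based flood fill, 4-connectivity
oracle_flood_fill_components <- function(mask) {
  d <- dim(mask)
  seen <- matrix(FALSE, d[1], d[2])
  ncomp <- 0L
  for (i0 in seq_len(d[1])) for (j0 in seq_len(d[2])) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    ncomp <- ncomp + 1L
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (nb in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + nb
        if (q[1] >= 1 && q[1] <= d[1] && q[2] >= 1 && q[2] <= d[2] &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  ncomp
}

# written-out Cox partial log-likelihood (no ties), maximized numerically
oracle_cox_beta <- function(time, event, x) {
  stopifnot(!anyDuplicated(time[event]))
  logpl <- function(beta) {
    s <- 0
    for (i in which(event)) {
      risk <- time >= time[i]
      s <- s + x[i] * beta - log(sum(exp(x[risk] * beta)))
    }
    s
  }
  stats::optimize(logpl, c(-20, 20), maximum = TRUE, tol = 1e-10)$maximum
}

# entropy-balancing weights by brute force. The constraints (weights sum
# to n, weighted centered moments zero) are linear in w, so the feasible
# set is an affine subspace: parametrize it from a least-squares feasible
# point plus the constraint null space and minimize the entropy objective
# directly over the free coordinates.
oracle_ipw_weights <- function(t_raw, x) {
  n <- length(t_raw)
  tc <- t_raw - mean(t_raw); xc <- x - mean(x)
  A <- rbind(rep(1, n), tc, xc, tc * xc)
  b <- c(n, 0, 0, 0)
  w0 <- as.numeric(MASS::ginv(A) %*% b)        # min-norm feasible point
  N <- svd(A, nv = n)$v[, (qr(A)$rank + 1):n, drop = FALSE]  # null space
  obj <- function(y) {
    w <- w0 + as.numeric(N %*% y)
    if (any(w <= 0)) return(1e9 + sum(pmax(-w, 0)))
    sum(w * log(n * w))
  }
  y <- stats::optim(numeric(ncol(N)), obj, method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-15))$par
  y <- stats::optim(y, obj, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-15))$par
  w0 + as.numeric(N %*% y)
}

# random valid slice: blob-ish random masks on an annulus-free rectangle
random_mask_slice <- function(d = c(24, 24), p_myo = 0.7, p_lge = 0.4,
                              spacing = 1.3, thickness = 8) {
  myo <- matrix(stats::runif(prod(d)) < p_myo, d[1], d[2])
  lge <- myo & matrix(stats::runif(prod(d)) < p_lge, d[1], d[2])
  segmented_slice(1L, spacing, thickness, myo, lge,
                  matrix(FALSE, d[1], d[2]))
}

# rotate a matrix 90 degrees clockwise
rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])

rotate_slice <- function(s) {
  segmented_slice(s$slice_index, s$pixel_spacing_mm, s$slice_thickness_mm,
                  rot90(s$myocardium_mask), rot90(s$lge_mask),
                  rot90(s$bloodpool_mask),
                  if (is.null(s$intensity)) NULL else rot90(s$intensity))
}

# small valid patient with an annular slice and painted stria
fixture_patient <- function(extent = pi, kind = "stria", seed = 1,
                            grid = 48, spacing = 1.5, thickness = 8,
                            endo = 10, epi = 20, with_intensity = FALSE,
                            id = "T1") {
  s <- make_annulus_slice(grid, spacing, thickness, endo, epi)
  s <- paint_lge(s, kind, angular_extent_rad = extent, seed = seed)
  if (with_intensity) s <- synth_intensity(s, 40, 100, 6, seed = seed)
  patient_record(id, list(s), covariates = list(age = 60, lvef = 35),
                 followup_days = 1000, event = FALSE)
}

# draw a small no-ties dataset whose partial-likelihood optimum is interior
# (tiny samples can have monotone likelihood, where the MLE is infinite and
# an implementation comparison is meaningless)
draw_nondegenerate_cox_data <- function(n = 6) {
  repeat {
    fr <- data.frame(followup_days = sample(seq(0.5, 80, by = 0.73), n),
                     event = c(TRUE, TRUE, TRUE,
                               sample(c(TRUE, FALSE), n - 3, replace = TRUE)),
                     x = stats::rnorm(n),
                     patient_id = letters[seq_len(n)])
    b <- oracle_cox_beta(fr$followup_days, fr$event, fr$x)
    if (abs(b) < 5) return(fr)
  }
}
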