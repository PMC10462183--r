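# Pixelwise inversion of the SAIM intensity model I_j = A f(theta_j, H) + B.
#
# The objective is separable: for fixed H the model is linear in (A, B), so
# the profile SSE over H is computed in closed form.  Because the profile is
# oscillatory in H (the standing wave has period lambda / (2 n_b cos theta)),
# the fitter scans H on a coarse grid, refines the best local minima with a
# bounded derivative-free optimizer, and returns the global best among the
# refined seeds.  This is deterministic: identical inputs give bitwise
# identical fits regardless of how pixels are scheduled.

#' Fit options for the SAIM height fitter
#'
#' @param h_bounds_nm Search bounds for H in nm (default `c(0, 300)`); the
#'   fitted height is reported within these bounds (the interference pattern
#'   is periodic in H, so truths beyond one period alias back in-bounds).
#' @param h_step_nm Coarse-grid step in nm (default 1).
#' @param n_seeds Number of best coarse-grid local minima refined (default 3).
#' @param refine_tol_nm Absolute tolerance on H in the local refinement
#'   (default 1e-4 nm).
#' @param sse_rel_tol Relative SSE window within which minima count as tied;
#'   ties return the smallest H (default 1e-9).
#' @param amplitude_floor Minimum fitted amplitude for a pixel to enter the
#'   quality mask (default 0, i.e. require A > 0).
#' @return List of class `saim_fit_options`.
#' @export
saim_fit_options <- function(h_bounds_nm = c(0, 300), h_step_nm = 1,
                             n_seeds = 3, refine_tol_nm = 1e-4,
                             sse_rel_tol = 1e-9, amplitude_floor = 0) {
  stopifnot(length(h_bounds_nm) == 2, h_bounds_nm[1] >= 0,
            h_bounds_nm[2] > h_bounds_nm[1], h_step_nm > 0, n_seeds >= 1)
  structure(list(h_bounds_nm = h_bounds_nm, h_step_nm = h_step_nm,
                 n_seeds = n_seeds, refine_tol_nm = refine_tol_nm,
                 sse_rel_tol = sse_rel_tol, amplitude_floor = amplitude_floor),
            class = "saim_fit_options")
}

# Closed-form (A, B) for fixed H given the excitation vector f and
# per-pixel intensity stats.  Returns A, B, sse.  A is constrained >= 0:
# a negative unconstrained amplitude collapses to the constant fit.
.profile_ab <- function(f, y, sy = sum(y), syy_c = sum((y - sy / length(y))^2)) {
  n <- length(y)
  fm <- mean(f)
  sff_c <- sum((f - fm)^2)
  if (sff_c <= .Machine$double.eps * n) {
    return(list(A = 0, B = sy / n, sse = syy_c, degenerate = TRUE))
  }
  sfy_c <- sum(f * y) - fm * sy
  A <- sfy_c / sff_c
  if (A < 0) {
    return(list(A = 0, B = sy / n, sse = syy_c, degenerate = FALSE))
  }
  list(A = A, B = sy / n - A * fm, sse = max(syy_c - A * sfy_c, 0),
       degenerate = FALSE)
}

# local minima indices of a numeric vector (plateau-safe, includes endpoints)
.local_minima <- function(v) {
  n <- length(v)
  if (n == 1) return(1L)
  left <- c(Inf, v[-n])
  right <- c(v[-1], Inf)
  which(v <= left & v <= right)
}

#' Fit the SAIM model at a single pixel
#'
#' Minimizes `sum_j (I_j - A f(theta_j, H) - B)^2` over `(H, A, B)` by
#' profiling out the linear pair `(A, B)` and searching `H` with a coarse
#' scan plus bounded local refinement of the best seeds.
#'
#' @param intensities Numeric vector of intensities, one per grid angle.
#' @param grid An [angle_grid()] (length >= 3).
#' @param config An [optical_config()].
#' @param options A [saim_fit_options()].
#' @return List of class `pixel_fit` with `height_nm`, `amplitude`, `offset`,
#'   `sse`, `converged`, `degenerate`, `n_starts_used`.
#' @export
fit_pixel <- function(intensities, grid, config,
                      options = saim_fit_options()) {
  grid <- angle_grid(unclass(grid))
  if (length(grid) < 3) stop("need at least 3 angles", call. = FALSE)
  if (length(intensities) != length(grid)) {
    stop(sprintf("length mismatch: %d intensities vs %d angles",
                 length(intensities), length(grid)), call. = FALSE)
  }
  if (any(!is.finite(intensities))) stop("non-finite intensities", call. = FALSE)
  terms <- .excitation_terms(config, as.numeric(grid))
  fit <- .fit_pixel_terms(intensities, terms, options)
  structure(fit, class = "pixel_fit")
}

# precomputed H-grid quantities shared by every pixel of a stack
.h_grid_cache <- function(terms, options) {
  hb <- options$h_bounds_nm
  hgrid <- seq(hb[1], hb[2], by = options$h_step_nm)
  if (hgrid[length(hgrid)] < hb[2]) hgrid <- c(hgrid, hb[2])
  fmat <- .excitation_matrix(terms, hgrid)      # n_angles x n_H
  n <- nrow(fmat)
  fm <- colMeans(fmat)
  list(hgrid = hgrid, fmat = fmat, fm = fm,
       sff_c = colSums(fmat^2) - n * fm^2)
}

# core single-pixel fit against precomputed excitation terms; `sfy` may carry
# the precomputed crossprod(fmat, y) from a whole-stack pass
.fit_pixel_terms <- function(y, terms, options,
                             cache = .h_grid_cache(terms, options),
                             sfy = NULL) {
  n <- length(y)
  sy <- sum(y)
  syy_c <- sum((y - sy / n)^2)
  if (syy_c <= .Machine$double.eps * max(1, sy)^2) {
    # constant profile: H unidentifiable
    return(list(height_nm = NA_real_, amplitude = 0, offset = sy / n,
                sse = 0, converged = FALSE, degenerate = TRUE,
                n_starts_used = 0L))
  }
  hgrid <- cache$hgrid
  if (is.null(sfy)) sfy <- as.vector(crossprod(cache$fmat, y))

  # vectorized profile SSE over the H grid
  sfy_c <- sfy - cache$fm * sy
  A <- ifelse(cache$sff_c > .Machine$double.eps * n, sfy_c / cache$sff_c, 0)
  A[A < 0] <- 0
  sse_grid <- syy_c - A * sfy_c * (A > 0)

  cand <- .local_minima(sse_grid)
  cand <- cand[order(sse_grid[cand], hgrid[cand])]
  cand <- cand[seq_len(min(options$n_seeds, length(cand)))]

  obj <- function(h) {
    f <- .excitation_matrix(terms, h)[, 1]
    .profile_ab(f, y, sy, syy_c)$sse
  }
  best <- NULL
  for (i in cand) {
    lo <- hgrid[max(1, i - 1)]
    hi <- hgrid[min(length(hgrid), i + 1)]
    o <- if (hi > lo) {
      stats::optimize(obj, lower = lo, upper = hi, tol = options$refine_tol_nm)
    } else {
      list(minimum = hgrid[i], objective = sse_grid[i])
    }
    # the refined point must not be worse than its seed
    if (o$objective > sse_grid[i]) {
      o <- list(minimum = hgrid[i], objective = sse_grid[i])
    }
    tied <- !is.null(best) &&
      abs(o$objective - best$objective) <= options$sse_rel_tol * max(best$objective, .Machine$double.eps)
    if (is.null(best) || (tied && o$minimum < best$minimum) ||
        (!tied && o$objective < best$objective)) {
      best <- o
    }
  }
  h <- best$minimum
  ab <- .profile_ab(.excitation_matrix(terms, h)[, 1], y, sy, syy_c)
  list(height_nm = h, amplitude = ab$A, offset = ab$B, sse = ab$sse,
       converged = !ab$degenerate && ab$A > 0,
       degenerate = ab$degenerate, n_starts_used = length(cand))
}

#' Fit a SAIM angle stack pixelwise
#'
#' Applies the single-pixel fitter independently to every pixel of an angle
#' stack; per-pixel failures are recorded in the quality mask and never
#' abort the stack.  The computation is deterministic and independent of
#' pixel ordering.
#'
#' @param stack An `angle_stack` (see [simulate_saim_stack()] /
#'   [read_angle_stack()]).
#' @param config An [optical_config()].
#' @param options A [saim_fit_options()].
#' @return Object of class `height_map`: list of matrices `heights_nm`,
#'   `amplitude`, `offset`, `sse`, logical `converged` and `quality_mask`
#'   (converged and amplitude above the floor).  Non-converged pixels carry
#'   `NA` heights.
#' @export
fit_stack <- function(stack, config, options = saim_fit_options()) {
  stopifnot(inherits(stack, "angle_stack"))
  dims <- dim(stack$intensities)
  n_ang <- dims[1]
  nr <- dims[2]; nc <- dims[3]
  if (n_ang != length(stack$grid)) {
    stop("stack page count does not match angle grid", call. = FALSE)
  }
  terms <- .excitation_terms(config, as.numeric(stack$grid))
  cache <- .h_grid_cache(terms, options)
  Y <- matrix(stack$intensities, nrow = n_ang)   # n_angles x n_pixels
  SFY <- crossprod(cache$fmat, Y)                # n_H x n_pixels, one BLAS call

  h <- amp <- off <- sse <- rep(NA_real_, nr * nc)
  conv <- rep(FALSE, nr * nc)
  for (p in seq_len(nr * nc)) {
    fit <- .fit_pixel_terms(Y[, p], terms, options, cache, SFY[, p])
    h[p] <- fit$height_nm; amp[p] <- fit$amplitude
    off[p] <- fit$offset; sse[p] <- fit$sse
    conv[p] <- fit$converged
  }
  heights <- matrix(h, nr, nc)
  amplitude <- matrix(amp, nr, nc)
  converged <- matrix(conv, nr, nc)
  quality <- converged & amplitude > options$amplitude_floor
  heights[!quality] <- NA_real_
  structure(list(heights_nm = heights, amplitude = amplitude,
                 offset = matrix(off, nr, nc), sse = matrix(sse, nr, nc),
                 converged = converged, quality_mask = quality,
                 options = options),
            class = "height_map")
}

#' Glycocalyx thickness over cell subregions
#'
#' The glycocalyx thickness readout is the mean height of the membrane-dye
#' layer minus the mean height of the fibronectin reference layer on the
#' substrate, averaged over a square pixel subregion (conventionally
#' 100 x 100) within each cell.  Only quality-masked pixels contribute;
#' per-ROI pixel counts report the smaller of the two channels' usable
#' counts.
#'
#' @param dye_map,reference_map `height_map` objects of identical shape
#'   (dye = membrane label, reference = substrate fibronectin label).
#' @param rois Data frame with columns `roi_id`, `row0`, `col0` giving the
#'   1-based top-left corner of each square ROI.
#' @param size ROI edge length in pixels (default 100).
#' @return A tibble with one row per ROI: `roi_id`, `mean_height_dye_nm`,
#'   `mean_height_reference_nm`, `thickness_nm`, `n_pixels_used`.
#' @export
quantify_thickness <- function(dye_map, reference_map, rois, size = 100) {
  stopifnot(inherits(dye_map, "height_map"), inherits(reference_map, "height_map"))
  if (!identical(dim(dye_map$heights_nm), dim(reference_map$heights_nm))) {
    stop("height maps must share a shape", call. = FALSE)
  }
  rois <- as.data.frame(rois)
  stopifnot(all(c("roi_id", "row0", "col0") %in% names(rois)))
  dims <- dim(dye_map$heights_nm)
  out <- lapply(seq_len(nrow(rois)), function(i) {
    r0 <- rois$row0[i]; c0 <- rois$col0[i]
    if (r0 < 1 || c0 < 1 || r0 + size - 1 > dims[1] || c0 + size - 1 > dims[2]) {
      stop(sprintf("ROI '%s' falls outside the %d x %d image",
                   rois$roi_id[i], dims[1], dims[2]), call. = FALSE)
    }
    rr <- r0:(r0 + size - 1); cc <- c0:(c0 + size - 1)
    dye <- dye_map$heights_nm[rr, cc]
    ref <- reference_map$heights_nm[rr, cc]
    n_dye <- sum(!is.na(dye)); n_ref <- sum(!is.na(ref))
    if (n_dye == 0 || n_ref == 0) {
      stop(sprintf("ROI '%s' has no usable pixels", rois$roi_id[i]),
           call. = FALSE)
    }
    md <- mean(dye, na.rm = TRUE)
    mr <- mean(ref, na.rm = TRUE)
    tibble::tibble(roi_id = rois$roi_id[i],
                   mean_height_dye_nm = md,
                   mean_height_reference_nm = mr,
                   thickness_nm = md - mr,
                   n_pixels_used = min(n_dye, n_ref))
  })
  dplyr::bind_rows(out)
}
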