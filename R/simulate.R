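# Seeded synthetic-data generators.  Each generator is a pure function of
# its parameters and seed (bitwise reproducible), and its noiseless output
# is an exact image of the corresponding forward model, so every inverse
# computation in the package can be tested against known ground truth.

#' Phantom specification for synthetic height fields
#'
#' Ground-truth surface topographies emulating the morphologies seen on
#' cells: flat layers, height steps, fields of hemispherical bleb caps, and
#' interconnected ridge networks.
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param pattern One of `"flat"`, `"step"`, `"blebs"`, `"ridges"`.
#' @param base_height_nm Base surface height in nm (>= 0).
#' @param step_delta_nm Height added to the right half (`"step"`).
#' @param bleb_radius_px,bleb_height_nm,bleb_density Cap radius (pixels),
#'   cap height (nm) and expected caps per pixel (`"blebs"`).
#' @param ridge_scale_px,ridge_height_nm,ridge_coverage Band-pass scale,
#'   ridge elevation and area fraction covered by ridges (`"ridges"`).
#' @param seed Integer seed; the field is a pure function of (spec, seed).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64),
                         pattern = c("flat", "step", "blebs", "ridges"),
                         base_height_nm = 5,
                         step_delta_nm = 60,
                         bleb_radius_px = 6, bleb_height_nm = 120,
                         bleb_density = 0.002,
                         ridge_scale_px = 6, ridge_height_nm = 100,
                         ridge_coverage = 0.2,
                         seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(length(shape) == 2, all(shape >= 1), base_height_nm >= 0,
            bleb_height_nm >= 0, ridge_height_nm >= 0)
  structure(list(shape = as.integer(shape), pattern = pattern,
                 base_height_nm = base_height_nm,
                 step_delta_nm = step_delta_nm,
                 bleb_radius_px = bleb_radius_px,
                 bleb_height_nm = bleb_height_nm,
                 bleb_density = bleb_density,
                 ridge_scale_px = ridge_scale_px,
                 ridge_height_nm = ridge_height_nm,
                 ridge_coverage = ridge_coverage,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a ground-truth height field
#'
#' Deterministic given the spec (including its seed).  Blebs are
#' hemispherical caps of the stated radius sitting on the base height;
#' ridges are the thresholded upper tail of a band-pass random field,
#' elevated by the stated ridge height.
#'
#' @param spec A [phantom_spec()].
#' @return Numeric matrix of heights in nm.
#' @export
make_height_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  base <- matrix(spec$base_height_nm, nr, nc)
  switch(spec$pattern,
    flat = base,
    step = {
      base[, seq_len(nc) > nc / 2] <- spec$base_height_nm + spec$step_delta_nm
      base
    },
    blebs = withr::with_seed(spec$seed, {
      n_caps <- stats::rpois(1, spec$bleb_density * nr * nc)
      h <- base
      if (n_caps > 0) {
        rows <- stats::runif(n_caps, 1, nr)
        cols <- stats::runif(n_caps, 1, nc)
        rg <- row(h); cg <- col(h)
        r_px <- spec$bleb_radius_px
        for (k in seq_len(n_caps)) {
          d2 <- (rg - rows[k])^2 + (cg - cols[k])^2
          cap <- spec$base_height_nm +
            spec$bleb_height_nm * sqrt(pmax(1 - d2 / r_px^2, 0))
          h <- pmax(h, cap)
        }
      }
      h
    }),
    ridges = withr::with_seed(spec$seed, {
      noise <- matrix(stats::rnorm(nr * nc), nr, nc)
      band <- .gblur_safe(noise, spec$ridge_scale_px / 2) -
        .gblur_safe(noise, spec$ridge_scale_px * 2)
      thr <- stats::quantile(band, 1 - spec$ridge_coverage)
      base + spec$ridge_height_nm * (band > thr)
    })
  )
}

#' Simulate a SAIM angle-scan image stack
#'
#' The noiseless expectation at every (angle, pixel) is exactly the forward
#' intensity model `A f(theta_j, H) + B`; Poisson or Gaussian noise is then
#' applied independently per element.
#'
#' @param height_field Matrix of true heights (nm).
#' @param A_field,B_field Amplitude and offset fields (matrices or scalars,
#'   recycled to the height-field shape).
#' @param config An [optical_config()].
#' @param grid An [angle_grid()].
#' @param noise `list(type = "none")`, `list(type = "poisson")` (expected
#'   counts are the forward intensities), or
#'   `list(type = "gaussian", sd = )`.
#' @param seed Integer seed for the noise draw.
#' @return Object of class `angle_stack`: `grid`, `intensities` array
#'   (angle, row, col), `metadata` (channel, oxide thickness, seed).
#' @param channel Channel label stored in metadata.
#' @export
simulate_saim_stack <- function(height_field, A_field, B_field, config, grid,
                                noise = list(type = "none"), seed = 1L,
                                channel = "dye") {
  height_field <- as.matrix(height_field)
  nr <- nrow(height_field); nc <- ncol(height_field)
  A_field <- matrix(A_field, nr, nc)
  B_field <- matrix(B_field, nr, nc)
  if (any(height_field < 0)) stop("heights must be >= 0", call. = FALSE)
  grid <- angle_grid(unclass(grid))
  terms <- .excitation_terms(config, as.numeric(grid))
  n_ang <- length(grid)
  # f over (angles x pixels): phase = c_j * H_p
  ph <- outer(terms$c, as.vector(height_field))
  f <- terms$f0 + terms$a * cos(ph) + terms$b * sin(ph)
  expected <- sweep(f, 2, as.vector(A_field), `*`)
  expected <- sweep(expected, 2, as.vector(B_field), `+`)
  vals <- switch(noise$type,
    none = expected,
    poisson = withr::with_seed(seed,
      matrix(stats::rpois(length(expected), lambda = pmax(expected, 0)),
             n_ang)),
    gaussian = withr::with_seed(seed,
      expected + matrix(stats::rnorm(length(expected), sd = noise$sd), n_ang)),
    stop("unknown noise type: ", noise$type, call. = FALSE)
  )
  structure(list(grid = grid,
                 intensities = array(vals, dim = c(n_ang, nr, nc)),
                 metadata = list(channel = channel,
                                 d_oxide_nm = config$d_oxide_nm,
                                 noise = noise$type, seed = seed)),
            class = "angle_stack")
}

# per-bin probabilities of a periodically folded mono-exponential decay,
# shifted in time by t0; integrated exactly over each bin
.folded_decay_probs <- function(tau_ns, rep_period_ns, n_bins, t0_ns = 0) {
  edges <- seq(0, rep_period_ns, length.out = n_bins + 1)
  # fine sub-sampling of the shifted folded density, exact enough at 16x
  k <- 16L
  sub <- seq(0, rep_period_ns, length.out = n_bins * k + 1)
  mids <- (sub[-1] + sub[-length(sub)]) / 2
  tt <- (mids - t0_ns) %% rep_period_ns
  dens <- exp(-tt / tau_ns)
  p <- colSums(matrix(dens, nrow = k))
  p / sum(p)
}

#' Simulate a two-component FLIM decay image
#'
#' Per pixel, the expected decay is
#' `photons * [FB * decay(tau_bound) + (1 - FB) * decay(tau_free)]`, each
#' component a periodically folded mono-exponential normalized to unit
#' area (so `FB` is the bound component's intensity fraction), optionally
#' delayed by an instrument time shift; photons are drawn multinomially
#' per pixel.
#'
#' @param fb_field Matrix of true bound fractions in `[0, 1]`.
#' @param tau_free_ns,tau_bound_ns Component lifetimes in ns (> 0).
#' @param photons Expected photons per pixel (scalar or matrix).
#' @param rep_period_ns Laser repetition period in ns.
#' @param n_bins Number of time bins.
#' @param instrument_shift_ns Instrument delay injected into the decay
#'   (default 0); a calibration measurement simulated with the same shift
#'   removes it.
#' @param seed Integer seed (`NULL` for the noiseless expectation).
#' @return A [decay_image()] (counts are expectations when `seed = NULL`).
#' @export
simulate_decay_image <- function(fb_field, tau_free_ns, tau_bound_ns,
                                 photons, rep_period_ns = 12.5,
                                 n_bins = 256, instrument_shift_ns = 0,
                                 seed = 1L) {
  fb_field <- as.matrix(fb_field)
  if (any(fb_field < 0 | fb_field > 1)) stop("FB must be in [0, 1]", call. = FALSE)
  if (tau_free_ns <= 0 || tau_bound_ns <= 0) stop("lifetimes must be > 0", call. = FALSE)
  nr <- nrow(fb_field); nc <- ncol(fb_field)
  photons <- matrix(photons, nr, nc)
  p_free <- .folded_decay_probs(tau_free_ns, rep_period_ns, n_bins,
                                instrument_shift_ns)
  p_bound <- .folded_decay_probs(tau_bound_ns, rep_period_ns, n_bins,
                                 instrument_shift_ns)
  fb <- as.vector(fb_field)
  expected <- outer(p_bound, fb) + outer(p_free, 1 - fb)   # n_bins x n_pixels
  expected <- sweep(expected, 2, as.vector(photons), `*`)
  counts <- if (is.null(seed)) {
    expected
  } else {
    withr::with_seed(seed, {
      out <- matrix(0, n_bins, nr * nc)
      for (p in seq_len(nr * nc)) {
        np <- stats::rpois(1, photons[p])
        if (np > 0) {
          out[, p] <- stats::rmultinom(1, np, expected[, p])
        }
      }
      out
    })
  }
  decay_image(array(counts, dim = c(n_bins, nr, nc)),
              bin_width_ns = rep_period_ns / n_bins,
              rep_period_ns = rep_period_ns)
}

#' Simulate an isotopologue abundance row
#'
#' Binomial 13C labeling of an `n_carbons` skeleton with per-carbon label
#' probability `label_fraction`; abundances are the binomial probabilities
#' scaled by `total_signal`, optionally multiplied by mean-one lognormal
#' noise with the stated coefficient of variation (multiplicative MS
#' noise).
#'
#' @param n_carbons Carbon count (>= 1).
#' @param label_fraction Per-carbon 13C probability in `[0, 1]`.
#' @param total_signal Total signal area (> 0).
#' @param noise_cv Lognormal coefficient of variation (0 = noiseless).
#' @param seed Integer seed.
#' @return Numeric abundance vector `M0..Mn`.
#' @export
simulate_isotopologues <- function(n_carbons, label_fraction,
                                   total_signal = 1e6, noise_cv = 0,
                                   seed = 1L) {
  if (label_fraction < 0 || label_fraction > 1) {
    stop("label_fraction must be in [0, 1]", call. = FALSE)
  }
  stopifnot(n_carbons >= 1, total_signal > 0, noise_cv >= 0)
  ab <- total_signal * stats::dbinom(0:n_carbons, n_carbons, label_fraction)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    ab <- withr::with_seed(seed,
      ab * stats::rlnorm(length(ab), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  ab
}
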