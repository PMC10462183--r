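# Forward optical model of the silicon / thermal-oxide / buffer interference
# system used for scanning-angle interference microscopy (SAIM).  The sample
# sits above a reflective silicon substrate coated with a transparent oxide
# spacer; excitation at incidence angle theta_b sets up a standing wave whose
# intensity at height H above the oxide surface modulates fluorophore
# excitation.  Only the s (TE) polarization is modeled: the instrument keeps
# the circle-scanned beam s-polarized with a vortex half-wave plate.

#' Optical configuration of the SAIM substrate stack
#'
#' Bundles the physical constants of the buffer / oxide / silicon layer
#' system: vacuum excitation wavelength, refractive indices of the three
#' media, and the oxide spacer thickness (measured per chip in practice,
#' e.g. by spectral reflectometry).
#'
#' Default indices are literature values for aqueous imaging buffer, thermal
#' SiO2, and crystalline silicon near 560 nm; silicon is complex with a
#' non-negative imaginary part (absorbing substrate).  Real experiments
#' should supply the values appropriate to their laser line and chip.
#'
#' @param wavelength_nm Vacuum excitation wavelength in nm (> 0).
#' @param n_buffer Refractive index of the imaging medium (real, or complex
#'   with non-negative imaginary part).
#' @param n_oxide Refractive index of the oxide spacer.
#' @param n_silicon Complex refractive index of the silicon substrate;
#'   the imaginary part must be >= 0 (absorption convention).
#' @param d_oxide_nm Oxide thickness in nm (>= 0); chips are typically
#'   ~1900 nm thermal oxide.
#' @return An object of class `optical_config`.
#' @export
#' @examples
#' cfg <- optical_config(wavelength_nm = 560, d_oxide_nm = 1900)
optical_config <- function(wavelength_nm = 560,
                           n_buffer = 1.335,
                           n_oxide = 1.46,
                           n_silicon = complex(real = 4.05, imaginary = 0.04),
                           d_oxide_nm = 1900) {
  n_buffer <- as.complex(n_buffer)
  n_oxide <- as.complex(n_oxide)
  n_silicon <- as.complex(n_silicon)
  vals <- c(wavelength_nm, d_oxide_nm, Re(n_buffer), Re(n_oxide), Re(n_silicon),
            Im(n_buffer), Im(n_oxide), Im(n_silicon))
  if (!all(is.finite(vals))) {
    stop("optical_config: all parameters must be finite", call. = FALSE)
  }
  if (wavelength_nm <= 0) stop("wavelength_nm must be > 0", call. = FALSE)
  if (d_oxide_nm < 0) stop("d_oxide_nm must be >= 0", call. = FALSE)
  if (Re(n_buffer) <= 0 || Re(n_oxide) <= 0 || Re(n_silicon) <= 0) {
    stop("real parts of all refractive indices must be > 0", call. = FALSE)
  }
  if (Im(n_buffer) < 0 || Im(n_oxide) < 0 || Im(n_silicon) < 0) {
    stop("imaginary parts of refractive indices must be >= 0", call. = FALSE)
  }
  structure(
    list(wavelength_nm = wavelength_nm, n_buffer = n_buffer,
         n_oxide = n_oxide, n_silicon = n_silicon, d_oxide_nm = d_oxide_nm),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("SAIM optical configuration\n")
  cat(sprintf("  wavelength: %g nm (vacuum)\n", x$wavelength_nm))
  cat(sprintf("  n_buffer:   %s\n", format(x$n_buffer)))
  cat(sprintf("  n_oxide:    %s\n", format(x$n_oxide)))
  cat(sprintf("  n_silicon:  %s\n", format(x$n_silicon)))
  cat(sprintf("  d_oxide:    %g nm\n", x$d_oxide_nm))
  invisible(x)
}

#' Angle grid for a SAIM acquisition
#'
#' An ordered set of incidence angles in the imaging medium, measured in
#' degrees from the wafer normal.  The standard acquisition sweeps 32 angles
#' evenly spaced from 5 to 43.75 degrees.
#'
#' @param angles_deg Strictly increasing numeric vector, each angle in
#'   `[0, 90)`.
#' @return Object of class `angle_grid` (numeric vector of degrees).
#' @export
angle_grid <- function(angles_deg) {
  angles_deg <- as.numeric(angles_deg)
  if (any(!is.finite(angles_deg))) stop("angles must be finite", call. = FALSE)
  if (any(angles_deg < 0) || any(angles_deg >= 90)) {
    stop("angles must lie in [0, 90) degrees", call. = FALSE)
  }
  if (length(angles_deg) > 1 && any(diff(angles_deg) <= 0)) {
    stop("angles must be strictly increasing", call. = FALSE)
  }
  structure(angles_deg, class = "angle_grid")
}

#' Evenly spaced angle grid
#'
#' @param n_angles Number of angles (>= 2).
#' @param min_deg,max_deg Endpoints in degrees, `0 <= min < max < 90`; both
#'   endpoints are included.  Defaults reproduce the standard 32-angle
#'   5--43.75 degree sweep.
#' @return An [angle_grid()].
#' @export
#' @examples
#' default_angle_grid()          # 32 angles, 5 .. 43.75 deg
#' default_angle_grid(2, 0, 10)  # c(0, 10)
default_angle_grid <- function(n_angles = 32, min_deg = 5, max_deg = 43.75) {
  if (!is.finite(n_angles) || n_angles < 2) stop("n_angles must be >= 2", call. = FALSE)
  if (!is.finite(min_deg) || !is.finite(max_deg) ||
      min_deg < 0 || min_deg >= max_deg || max_deg >= 90) {
    stop("need 0 <= min_deg < max_deg < 90", call. = FALSE)
  }
  angle_grid(seq(min_deg, max_deg, length.out = n_angles))
}

# principal complex square root with the branch fixed so Im >= 0
# (decaying wave into an absorbing medium)
.csqrt_upper <- function(z) {
  s <- sqrt(as.complex(z))
  flip <- Im(s) < 0
  s[flip] <- -s[flip]
  s
}

#' Refraction angles in oxide and silicon
#'
#' Applies Snell's law through the buffer -> oxide -> silicon chain:
#' `n_b sin(theta_b) = n_ox sin(theta_ox) = n_Si sin(theta_Si)`.
#' Cosines are principal square roots of `1 - sin^2` with the branch chosen
#' so the imaginary part is non-negative.
#'
#' @param config An [optical_config()].
#' @param theta_b_deg Incidence angle(s) in the buffer, degrees in `[0, 90)`.
#' @return List with complex `theta_ox`, `theta_si` (radians) and the
#'   cosines `cos_b`, `cos_ox`, `cos_si` (vectorized over angles).
#' @export
refraction_angles <- function(config, theta_b_deg) {
  stopifnot(inherits(config, "optical_config"))
  if (any(!is.finite(theta_b_deg))) stop("non-finite angle", call. = FALSE)
  if (any(theta_b_deg < 0 | theta_b_deg >= 90)) {
    stop("theta_b_deg must be in [0, 90)", call. = FALSE)
  }
  th_b <- theta_b_deg * pi / 180
  sin_b <- as.complex(sin(th_b))
  sin_ox <- config$n_buffer * sin_b / config$n_oxide
  sin_si <- config$n_buffer * sin_b / config$n_silicon
  list(
    theta_ox = asin(sin_ox),
    theta_si = asin(sin_si),
    sin_ox = sin_ox, sin_si = sin_si,
    cos_b = as.complex(cos(th_b)),
    cos_ox = .csqrt_upper(1 - sin_ox^2),
    cos_si = .csqrt_upper(1 - sin_si^2)
  )
}

# TE admittances p0 (silicon), p1 (oxide), p2 (buffer); vectorized
.te_admittances <- function(config, theta_b_deg) {
  ang <- refraction_angles(config, theta_b_deg)
  list(ang = ang,
       p0 = config$n_silicon * ang$cos_si,
       p1 = config$n_oxide * ang$cos_ox,
       p2 = config$n_buffer * ang$cos_b)
}

#' Characteristic (transfer) matrix of the oxide layer, TE polarization
#'
#' With phase thickness `beta = k_ox d_ox cos(theta_ox)` and
#' `k_ox = 2 pi n_ox / lambda`, the 2x2 matrix has entries
#' `m11 = m22 = cos(beta)`, `m12 = -i sin(beta)/p1`, `m21 = -i p1 sin(beta)`,
#' where `p1 = n_ox cos(theta_ox)` is the oxide TE admittance.  For a
#' lossless oxide the matrix is unimodular.
#'
#' @inheritParams refraction_angles
#' @return List with complex `m11`, `m12`, `m21`, `m22`, `beta` and the
#'   admittances `p0`, `p1`, `p2` (vectorized over angles).
#' @export
characteristic_matrix <- function(config, theta_b_deg) {
  adm <- .te_admittances(config, theta_b_deg)
  if (any(abs(adm$p1) == 0)) {
    stop("degenerate geometry: oxide admittance p1 = 0", call. = FALSE)
  }
  k_ox <- 2 * pi * config$n_oxide / config$wavelength_nm
  beta <- k_ox * config$d_oxide_nm * adm$ang$cos_ox
  sb <- sin(beta)
  list(m11 = cos(beta), m12 = -1i * sb / adm$p1,
       m21 = -1i * adm$p1 * sb, m22 = cos(beta),
       beta = beta, p0 = adm$p0, p1 = adm$p1, p2 = adm$p2,
       theta_ox = adm$ang$theta_ox, theta_si = adm$ang$theta_si)
}

#' TE reflection coefficient of the oxide-on-silicon stack
#'
#' Standard stratified-media reflection coefficient from the characteristic
#' matrix, with the buffer as incident medium (admittance `p2`) and silicon
#' as substrate (`p0`):
#' `r_TE = ((m11 + m12 p0) p2 - (m21 + m22 p0)) /
#'         ((m11 + m12 p0) p2 + (m21 + m22 p0))`.
#' At `d_ox = 0` this reduces to the two-media Fresnel TE coefficient
#' `(p2 - p0)/(p2 + p0)`.
#'
#' @inheritParams refraction_angles
#' @return Complex reflection coefficient(s), vectorized over angles.
#' @export
reflection_te <- function(config, theta_b_deg) {
  m <- characteristic_matrix(config, theta_b_deg)
  top <- (m$m11 + m$m12 * m$p0) * m$p2 - (m$m21 + m$m22 * m$p0)
  bot <- (m$m11 + m$m12 * m$p0) * m$p2 + (m$m21 + m$m22 * m$p0)
  if (any(abs(bot) == 0)) {
    stop("degenerate geometry: zero reflection denominator", call. = FALSE)
  }
  top / bot
}

#' Full TE response of the stack at one angle
#'
#' Convenience wrapper collecting refraction angles, admittances,
#' characteristic-matrix entries and the reflection coefficient.
#'
#' @inheritParams refraction_angles
#' @return List of class `te_response`.
#' @export
te_response <- function(config, theta_b_deg) {
  m <- characteristic_matrix(config, theta_b_deg)
  structure(c(m, list(r_te = reflection_te(config, theta_b_deg))),
            class = "te_response")
}

#' Axial interference phase shift
#'
#' Phase accumulated by the reflected excitation path for a fluorophore at
#' height `H` above the oxide surface:
#' `phi = (4 pi / lambda) n_b H cos(theta_b)`.
#'
#' @inheritParams refraction_angles
#' @param height_nm Height(s) above the oxide surface in nm, `>= 0`.
#' @return Phase in radians (outer-combined if both arguments have length
#'   > 1 is NOT done; lengths must be compatible by recycling).
#' @export
phase_shift <- function(config, theta_b_deg, height_nm) {
  stopifnot(inherits(config, "optical_config"))
  if (any(!is.finite(height_nm)) || any(height_nm < 0)) {
    stop("height_nm must be finite and >= 0", call. = FALSE)
  }
  if (any(theta_b_deg < 0 | theta_b_deg >= 90)) {
    stop("theta_b_deg must be in [0, 90)", call. = FALSE)
  }
  4 * pi * Re(config$n_buffer) * height_nm *
    cos(theta_b_deg * pi / 180) / config$wavelength_nm
}

#' Excitation probability above the mirror stack
#'
#' Relative probability of exciting a fluorophore at height `H` under TE
#' illumination at `theta_b`:
#' `f = 1 + 2 Re(r) cos(phi) - 2 Im(r) sin(phi) + Re(r)^2 + Im(r)^2`,
#' algebraically equal to `|1 + r_TE e^{i phi}|^2` (direct + reflected field
#' interference).
#'
#' @inheritParams phase_shift
#' @return Non-negative excitation probability, vectorized over angles.
#' @export
excitation_probability <- function(config, theta_b_deg, height_nm) {
  r <- reflection_te(config, theta_b_deg)
  phi <- phase_shift(config, theta_b_deg, height_nm)
  1 + 2 * Re(r) * cos(phi) - 2 * Im(r) * sin(phi) + Re(r)^2 + Im(r)^2
}

#' Forward intensity model over an angle grid
#'
#' The affine intensity model fitted pixelwise in SAIM:
#' `I_j = A f(theta_j, H) + B` over the grid angles, in grid order.
#'
#' @param config An [optical_config()].
#' @param grid An [angle_grid()].
#' @param height_nm Scalar height in nm.
#' @param amplitude,offset Affine parameters A and B.
#' @return Numeric intensity vector, one entry per grid angle.
#' @export
forward_intensity <- function(config, grid, height_nm, amplitude, offset) {
  grid <- angle_grid(unclass(grid))
  if (length(grid) < 1) stop("empty angle grid", call. = FALSE)
  amplitude * excitation_probability(config, as.numeric(grid), height_nm) + offset
}

# Angle-dependent pieces of f(theta, H), reused by the fitter and the
# simulator: f(theta, H) = f0 + a cos(c H) + b sin(c H) with
# f0 = 1 + |r|^2, a = 2 Re(r), b = -2 Im(r), c = 4 pi n_b cos(theta)/lambda.
.excitation_terms <- function(config, angles_deg) {
  r <- reflection_te(config, angles_deg)
  list(f0 = 1 + Re(r)^2 + Im(r)^2,
       a = 2 * Re(r),
       b = -2 * Im(r),
       c = 4 * pi * Re(config$n_buffer) *
         cos(angles_deg * pi / 180) / config$wavelength_nm)
}

# n_angles x n_heights matrix of f(theta_j, H_k)
.excitation_matrix <- function(terms, heights_nm) {
  ph <- outer(terms$c, heights_nm)              # n_angles x n_H
  terms$f0 + terms$a * cos(ph) + terms$b * sin(ph)
}
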