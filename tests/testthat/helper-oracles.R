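# Independent oracles and small fixtures shared across tests.  Nothing here
# calls the package's optics internals: the point is a second, independent
# route to the same physics.

# Recursive (Airy) two-interface Fresnel summation for the TE reflection of
# a single film between buffer and substrate:
#   r = (r12 + r23 e^{2 i beta}) / (1 + r12 r23 e^{2 i beta})
# with per-interface Fresnel TE coefficients and film phase thickness beta.
airy_reflection_te <- function(wavelength_nm, n_buffer, n_oxide, n_silicon,
                               d_oxide_nm, theta_b_deg) {
  th <- theta_b_deg * pi / 180
  nb <- as.complex(n_buffer); nox <- as.complex(n_oxide)
  nsi <- as.complex(n_silicon)
  sb <- as.complex(sin(th)); cb <- as.complex(cos(th))
  upper <- function(z) {
    s <- sqrt(as.complex(z))
    ifelse(Im(s) < 0, -s, s)
  }
  sox <- nb * sb / nox
  cox <- upper(1 - sox^2)
  ssi <- nb * sb / nsi
  csi <- upper(1 - ssi^2)
  r12 <- (nb * cb - nox * cox) / (nb * cb + nox * cox)
  r23 <- (nox * cox - nsi * csi) / (nox * cox + nsi * csi)
  beta <- 2 * pi * nox / wavelength_nm * d_oxide_nm * cox
  (r12 + r23 * exp(2i * beta)) / (1 + r12 * r23 * exp(2i * beta))
}

# a pinned optical configuration used throughout the tests (560 nm line,
# ~1900 nm thermal oxide chip); values are fixed here, never defaults
test_config <- function(d_oxide_nm = 1900, wavelength_nm = 560) {
  optical_config(wavelength_nm = wavelength_nm, n_buffer = 1.338,
                 n_oxide = 1.46,
                 n_silicon = complex(real = 4.05, imaginary = 0.044),
                 d_oxide_nm = d_oxide_nm)
}

# FLIM acquisition constants pinned for tests: 80 MHz repetition
test_rep_period_ns <- 12.5

# amplitude/offset giving roughly `budget` expected photons per angle
photon_scale <- function(budget) list(A = budget / 2, B = budget / 50)
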