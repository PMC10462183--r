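# Forward optical model: Snell chain, characteristic matrix, TE reflection,
# phase and excitation probability.

test_that("refraction angles follow the Snell chain with the upper-branch cosine", {
  cfg <- test_config()
  # normal incidence and matched media are identity cases
  ang0 <- refraction_angles(cfg, 0)
  expect_equal(Mod(ang0$theta_ox), 0)
  expect_equal(Mod(ang0$theta_si), 0)
  cfg_match <- optical_config(560, 1.46, 1.46, 4.05 + 0.044i, 1900)
  angm <- refraction_angles(cfg_match, 25)
  expect_equal(Re(angm$theta_ox), 25 * pi / 180, tolerance = 1e-12)

  # independent high-precision evaluation of the Snell expression
  ang <- refraction_angles(optical_config(560, 1.33, 1.46, 4.05 + 0.044i, 1900),
                           43.75)
  expect_equal(Re(ang$theta_ox), asin(1.33 * sin(43.75 * pi / 180) / 1.46),
               tolerance = 1e-12)

  # Snell consistency n_b sin(theta_b) = n_ox sin(theta_ox) = n_Si sin(theta_Si)
  for (th in c(5, 20, 43.75, 60)) {
    a <- refraction_angles(cfg, th)
    lhs <- cfg$n_buffer * sin(as.complex(th * pi / 180))
    expect_equal(cfg$n_oxide * a$sin_ox, lhs, tolerance = 1e-12)
    expect_equal(cfg$n_silicon * a$sin_si, lhs, tolerance = 1e-12)
    expect_gte(Im(a$cos_si), 0)
  }
  expect_error(refraction_angles(cfg, 95), "\\[0, 90\\)")
  expect_error(refraction_angles(cfg, NaN), "finite")
})

test_that("characteristic matrix is unimodular with the stated entries", {
  cfg <- test_config()
  for (th in c(0, 17, 43.75)) {
    m <- characteristic_matrix(cfg, th)
    expect_equal(m$m11 * m$m22 - m$m12 * m$m21, 1 + 0i, tolerance = 1e-10)
    expect_equal(m$m11, cos(m$beta), tolerance = 1e-12)
    expect_equal(m$m12, -1i * sin(m$beta) / m$p1, tolerance = 1e-12)
  }
  # zero-thickness layer: identity matrix
  m0 <- characteristic_matrix(test_config(d_oxide_nm = 0), 20)
  expect_equal(m0$m11, 1 + 0i)
  expect_equal(m0$m12, 0 + 0i)
  expect_equal(m0$m21, 0 + 0i)
})

test_that("quarter-wave oxide zeroes the matrix diagonal", {
  # pick d so that beta = pi/2 at theta_b = 20 deg
  th <- 20
  sox <- 1.338 * sin(th * pi / 180) / 1.46
  cox <- sqrt(1 - sox^2)
  d_quarter <- 560 / (4 * 1.46 * cox)
  m <- characteristic_matrix(test_config(d_oxide_nm = d_quarter), th)
  expect_equal(Mod(m$m11), 0, tolerance = 1e-10)
  expect_equal(m$m12, -1i / m$p1, tolerance = 1e-10)
  expect_equal(m$m21, -1i * m$p1, tolerance = 1e-10)
})

test_that("reflection coefficient matches the independent Airy summation", {
  for (nsi in list(3.9, complex(real = 4.05, imaginary = 0.044))) {
    for (lam in c(488, 560, 642)) {
      for (d in c(0, 500, 1900, 3000)) {
        cfg <- optical_config(lam, 1.338, 1.46, nsi, d)
        ths <- seq(0, 60, by = 5)
        r_pkg <- reflection_te(cfg, ths)
        r_airy <- sapply(ths, function(t)
          airy_reflection_te(lam, 1.338, 1.46, nsi, d, t))
        expect_lt(max(abs(r_pkg - r_airy)), 1e-10)
      }
    }
  }
})

test_that("reflection limits: bare silicon, half-wave invariance, mirror", {
  # d_ox = 0 reduces to the two-media Fresnel TE coefficient
  cfg0 <- test_config(d_oxide_nm = 0)
  th <- 30
  r0 <- reflection_te(cfg0, th)
  csi <- sqrt(1 - (1.338 * sin(th * pi / 180) / cfg0$n_silicon)^2)
  p0 <- cfg0$n_silicon * csi
  p2 <- 1.338 * cos(th * pi / 180)
  expect_equal(r0, (p2 - p0) / (p2 + p0), tolerance = 1e-12)

  # adding a lossless half-wave of oxide leaves r unchanged
  sox <- 1.338 * sin(th * pi / 180) / 1.46
  d_half <- 560 / (2 * 1.46 * sqrt(1 - sox^2))
  r_half <- reflection_te(test_config(d_oxide_nm = d_half), th)
  expect_lt(abs(r_half - r0), 1e-10)

  # a very high-index substrate at d_ox = 0 acts as a mirror: r -> -1
  cfg_mirror <- optical_config(560, 1.338, 1.46, 1e6 + 0i, 0)
  expect_equal(reflection_te(cfg_mirror, 0), -1 + 0i, tolerance = 1e-4)

  # passivity: |r| <= 1 for these passive media
  expect_true(all(Mod(reflection_te(test_config(), seq(0, 60, 2))) <= 1 + 1e-10))
})

test_that("phase shift is the printed closed form", {
  cfg <- test_config()
  expect_equal(phase_shift(cfg, 20, 0), 0)
  # quarter-wavelength in medium at normal incidence gives phi = pi
  expect_equal(phase_shift(cfg, 0, 560 / (4 * 1.338)), pi, tolerance = 1e-12)
  # direct independent evaluation
  expect_equal(phase_shift(cfg, 30, 100),
               4 * pi * 1.338 * 100 * cos(30 * pi / 180) / 560,
               tolerance = 1e-12)
  expect_error(phase_shift(cfg, 20, -5), ">= 0")
})

test_that("excitation probability equals |1 + r e^{i phi}|^2 and its bounds", {
  cfg <- test_config()
  set.seed(42)
  for (i in 1:50) {
    th <- runif(1, 0, 60)
    H <- runif(1, 0, 300)
    f <- excitation_probability(cfg, th, H)
    r <- reflection_te(cfg, th)
    phi <- phase_shift(cfg, th, H)
    expect_equal(f, Mod(1 + r * exp(1i * phi))^2, tolerance = 1e-12)
    expect_gte(f, 0)
    expect_lte(f, (1 + Mod(r))^2 + 1e-12)
  }
})

test_that("excitation probability is periodic in H with the standing-wave period", {
  cfg <- test_config()
  th <- 15
  period <- 560 / (2 * 1.338 * cos(th * pi / 180))
  H <- c(0, 30, 77.7, 150)
  expect_equal(excitation_probability(cfg, th, H + period),
               excitation_probability(cfg, th, H), tolerance = 1e-9)
})

test_that("forward intensity is the affine model over the grid", {
  cfg <- test_config()
  g <- default_angle_grid()
  expect_length(g, 32)
  expect_equal(as.numeric(g)[1], 5)
  expect_equal(as.numeric(g)[32], 43.75)
  expect_equal(diff(as.numeric(g)), rep((43.75 - 5) / 31, 31))
  expect_equal(forward_intensity(cfg, g, 80, 0, 7), rep(7, 32))
  expect_equal(forward_intensity(cfg, g, 80, 1, 0),
               excitation_probability(cfg, as.numeric(g), 80))
  expect_equal(as.numeric(default_angle_grid(2, 0, 10)), c(0, 10))
  expect_error(default_angle_grid(2, 50, 95), "< 90")
})

test_that("invalid configurations are rejected", {
  expect_error(optical_config(wavelength_nm = -1), "wavelength")
  expect_error(optical_config(d_oxide_nm = -10), "d_oxide")
  expect_error(optical_config(n_silicon = 4 - 0.1i), "imaginary")
  expect_error(optical_config(n_buffer = -1.3), "real parts")
  expect_error(angle_grid(c(10, 5)), "increasing")
})
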