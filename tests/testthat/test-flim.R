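# Phasor transform, calibration, compartment segmentation and bound fraction.

omega1 <- 2 * pi / test_rep_period_ns

test_that("phasor transform matches limits and the mono-exponential closed form", {
  # all counts in the first bin: (G, S) -> (1, 0) as bins get fine
  counts <- array(0, c(512, 1, 1)); counts[1, 1, 1] <- 1000
  d <- decay_image(counts, test_rep_period_ns / 512, test_rep_period_ns)
  ph <- phasor_transform(d)
  expect_equal(ph$g[1, 1], 1, tolerance = 1e-3)
  expect_equal(ph$s[1, 1], 0, tolerance = 1e-2)

  # uniform counts over the full period: (0, 0) by orthogonality
  du <- decay_image(array(7, c(256, 1, 1)), test_rep_period_ns / 256,
                    test_rep_period_ns)
  phu <- phasor_transform(du)
  expect_equal(phu$g[1, 1], 0, tolerance = 1e-12)
  expect_equal(phu$s[1, 1], 0, tolerance = 1e-12)

  # simulated mono-exponential at the 2.5 ns calibration lifetime
  dm <- simulate_decay_image(matrix(0, 1, 1), tau_free_ns = 2.5,
                             tau_bound_ns = 3.4, photons = 1e6,
                             rep_period_ns = test_rep_period_ns,
                             n_bins = 256, seed = NULL)
  phm <- phasor_transform(dm)
  th <- mono_exponential_phasor(2.5, omega1)
  expect_lt(abs(phm$g[1, 1] - th["g"]), 1e-3)
  expect_lt(abs(phm$s[1, 1] - th["s"]), 1e-3)

  # zero-count pixels get the NA sentinel, not an error
  z <- array(0, c(16, 2, 1)); z[, 1, 1] <- 1
  phz <- phasor_transform(decay_image(z, test_rep_period_ns / 16,
                                      test_rep_period_ns))
  expect_true(is.na(phz$g[2, 1]))
  expect_false(is.na(phz$g[1, 1]))
})

test_that("mono-exponential phasors sit on the universal semicircle", {
  expect_equal(unname(mono_exponential_phasor(0, omega1)), c(1, 0))
  for (tau in c(0.1, 0.4, 2.5, 3.4, 20)) {
    gs <- mono_exponential_phasor(tau, omega1)
    expect_equal(unname((gs["g"] - 0.5)^2 + gs["s"]^2), 0.25, tolerance = 1e-12)
  }
  expect_lt(max(abs(mono_exponential_phasor(1e9, omega1))), 1e-8)
  expect_error(mono_exponential_phasor(-1, omega1), ">= 0")
})

test_that("phasor linearity: mixtures are intensity-weighted combinations", {
  n_bins <- 512
  mk <- function(tau) simulate_decay_image(matrix(1, 1, 1), tau, 1, 1e6,
                                           test_rep_period_ns, n_bins,
                                           seed = NULL)
  p1 <- phasor_transform(mk(0.6)); p2 <- phasor_transform(mk(3.1))
  for (w in c(0.25, 0.5, 0.9)) {
    mix <- mk(0.6)
    mix$counts <- w * mk(0.6)$counts + (1 - w) * mk(3.1)$counts
    pm <- phasor_transform(mix)
    expect_equal(pm$g[1, 1], w * p1$g[1, 1] + (1 - w) * p2$g[1, 1],
                 tolerance = 1e-10)
    expect_equal(pm$s[1, 1], w * p1$s[1, 1] + (1 - w) * p2$s[1, 1],
                 tolerance = 1e-10)
  }
})

test_that("random exponential mixtures stay inside the universal semicircle", {
  # any convex mixture of decaying exponentials maps inside the semicircle
  set.seed(5)
  nb <- 512
  t_ns <- (seq_len(nb) - 0.5) * test_rep_period_ns / nb
  for (i in 1:25) {
    taus <- runif(sample(1:4, 1), 0.1, 20)
    w <- runif(length(taus)); w <- w / sum(w)
    dens <- colSums(w * t(sapply(taus, function(tau)
      exp(-t_ns / tau) / (1 - exp(-test_rep_period_ns / tau)))))
    ph <- phasor_transform(decay_image(array(dens * 1e6, c(nb, 1, 1)),
                                       test_rep_period_ns / nb,
                                       test_rep_period_ns))
    # slack covers the finite-bin discretization of the transform
    expect_lte((ph$g[1, 1] - 0.5)^2 + ph$s[1, 1]^2, 0.25 + 1e-4)
  }
})

test_that("calibration removes an injected instrument distortion", {
  shift <- 0.8
  # reference measured with the same instrument shift
  dref <- simulate_decay_image(matrix(0, 1, 1), 2.5, 3.4, 1e6,
                               test_rep_period_ns, 256, shift, seed = NULL)
  pref <- phasor_transform(dref)
  ref <- calibration_reference(2.5, pref$g[1, 1], pref$s[1, 1])

  # calibrating the reference's own phasor returns the theoretical point
  pcal <- phasor_calibrate(pref, ref)
  th <- mono_exponential_phasor(2.5, omega1)
  expect_equal(pcal$g[1, 1], unname(th["g"]), tolerance = 1e-12)
  expect_equal(pcal$s[1, 1], unname(th["s"]), tolerance = 1e-12)

  # a distorted mono-exponential sample recovers its analytic phasor
  ds <- simulate_decay_image(matrix(1, 1, 1), 0.4, 1.8, 1e6,
                             test_rep_period_ns, 256, shift, seed = NULL)
  ps <- phasor_calibrate(phasor_transform(ds), ref)
  tha <- mono_exponential_phasor(1.8, omega1)
  expect_lt(abs(ps$g[1, 1] - tha["g"]), 1e-3)
  expect_lt(abs(ps$s[1, 1] - tha["s"]), 1e-3)

  # an undistorted instrument yields a unit correction
  p0 <- phasor_transform(simulate_decay_image(matrix(0.3, 1, 1), 0.4, 3.4,
                                              1e6, test_rep_period_ns, 1024,
                                              seed = NULL))
  ref_ideal <- calibration_reference(2.5, unname(th["g"]), unname(th["s"]))
  pid <- phasor_calibrate(p0, ref_ideal)
  expect_equal(pid$g, p0$g, tolerance = 1e-12)
  expect_error(calibration_reference(2.5, 0, 0), "modulation")
})

test_that("segmentation separates bright organelles from diffuse background", {
  gradient <- outer(seq(0, 1, length.out = 96), seq(1, 2, length.out = 96)) * 50
  blobs <- matrix(0, 96, 96)
  for (ctr in list(c(24, 24), c(70, 30), c(48, 72), c(80, 80))) {
    d2 <- (row(blobs) - ctr[1])^2 + (col(blobs) - ctr[2])^2
    blobs <- blobs + 400 * (d2 < 9)
  }
  m <- segment_compartments(gradient + blobs, blur_sigma = 12,
                            cell_quantile = 0.05)
  expect_gt(mean(m$mitochondrial[blobs > 0]), 0.95)
  expect_lt(mean(m$mitochondrial[blobs == 0]), 0.05)
  # masks are disjoint and inside the cell region
  expect_false(any(m$mitochondrial & m$cytosolic))

  # a uniform image has no organelle structure (and no cell region at all)
  expect_warning(mu <- segment_compartments(matrix(10, 32, 32)),
                 "empty cell region")
  expect_false(any(mu$mitochondrial))
  expect_warning(segment_compartments(matrix(0, 8, 8), cell_quantile = 1),
                 "empty cell region")
})

test_that("bound fraction is the normalized chord coordinate", {
  free <- mono_exponential_phasor(0.4, omega1)
  bound <- mono_exponential_phasor(3.4, omega1)
  ph <- structure(list(
    g = matrix(c(free["g"], bound["g"], (free["g"] + bound["g"]) / 2), 3, 1),
    s = matrix(c(free["s"], bound["s"], (free["s"] + bound["s"]) / 2), 3, 1),
    intensity = matrix(1, 3, 1), harmonic = 1L, omega = omega1),
    class = "phasor_image")
  fb <- bound_fraction(ph, free, bound)
  expect_equal(as.vector(fb$fb), c(0, 1, 0.5), tolerance = 1e-12)
  expect_error(bound_fraction(ph, free, free), "differ")
})

test_that("CSV export summarizes per-mask phasor and FB means", {
  ph <- structure(list(g = matrix(c(0.3, 0.5, 0.7, NA), 2, 2),
                       s = matrix(c(0.2, 0.3, 0.4, 0.1), 2, 2),
                       intensity = matrix(c(1, 1, 1, 0), 2, 2),
                       harmonic = 1L, omega = omega1),
                  class = "phasor_image")
  fb <- structure(list(fb = matrix(c(0.2, 0.4, 0.9, 0.5), 2, 2),
                       free_ref = c(1, 0), bound_ref = c(0, 0), masks = NULL),
                  class = "fb_map")
  masks <- list(left = matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2),
                empty = matrix(FALSE, 2, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  out <- export_phasor_csv(ph, fb, masks, path)
  expect_equal(out$mean_fb[out$mask == "left"], 0.3)
  expect_equal(out$n_pixels, c(2L, 0L))
  expect_true(is.na(out$mean_g[2]))
  reread <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(reread$mean_g, out$mean_g)
})
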