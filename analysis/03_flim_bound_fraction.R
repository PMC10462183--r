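#!/usr/bin/env Rscript
# Phasor-FLIM workflow on a simulated NADH decay image: calibrate against a
# 2.5 ns reference measured with the same (injected) instrument shift,
# segment mitochondria from cytosol on the companion intensity image, and
# export per-compartment bound-fraction summaries.

suppressMessages(library(glycoscape))
outdir <- "results/flim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

rep_period <- 12.5      # ns (80 MHz)
omega <- 2 * pi / rep_period
shift <- 0.7            # ns instrument delay baked into the simulation
taus <- c(free = 0.4, bound = 3.4)

# two-compartment ground truth: mitochondria (high FB) on a cytosolic field
fb_true <- matrix(0.25, 64, 64)
mito_true <- matrix(FALSE, 64, 64)
for (ctr in list(c(16, 20), c(40, 14), c(30, 44), c(52, 52))) {
  d2 <- (row(fb_true) - ctr[1])^2 + (col(fb_true) - ctr[2])^2
  mito_true <- mito_true | d2 < 20
}
fb_true[mito_true] <- 0.65

decay <- simulate_decay_image(fb_true, taus["free"], taus["bound"],
                              photons = 1e4, rep_period_ns = rep_period,
                              n_bins = 256, instrument_shift_ns = shift,
                              seed = 301)
ref_decay <- simulate_decay_image(matrix(0, 1, 1), 2.5, taus["bound"], 1e6,
                                  rep_period, 256, shift, seed = NULL)
pref <- phasor_transform(ref_decay)
ref <- calibration_reference(2.5, pref$g[1, 1], pref$s[1, 1])

phasor <- phasor_calibrate(phasor_transform(decay), ref)
fb <- bound_fraction(phasor,
                     mono_exponential_phasor(taus["free"], omega),
                     mono_exponential_phasor(taus["bound"], omega))

# mitochondrial intensity channel: brighter where FB is mitochondrial
intensity <- matrix(60, 64, 64) + 400 * mito_true
masks <- segment_compartments(intensity, blur_sigma = 12,
                              cell_quantile = 0.05)

summary <- export_phasor_csv(phasor, fb, masks,
                             path = file.path(outdir, "fb_summary.csv"),
                             per_pixel_path = file.path(outdir,
                                                        "phasor_pixels.csv"))
print(as.data.frame(summary))
cat(sprintf("mean |FB error| vs truth: %.4f\n", mean(abs(fb$fb - fb_true))))
cat(sprintf("segmentation captured %.1f%% of true mitochondrial pixels\n",
            100 * mean(masks$mitochondrial[mito_true])))
cat("summaries written to", outdir, "\n")
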