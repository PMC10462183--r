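#!/usr/bin/env Rscript
# Generate the synthetic inputs used by the downstream analyses: a pair of
# flat-layer SAIM angle stacks (membrane dye above a fibronectin reference,
# separated by a known 60 nm glycocalyx), plus bleb-cap and ridge-network
# topography phantoms, all with shot noise.  Ground truth goes in sidecar
# CSVs so the reconstruction step can be scored.

suppressMessages(library(glycoscape))
outdir <- "results/simulated"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- optical_config(wavelength_nm = 560, n_buffer = 1.338, n_oxide = 1.46,
                      n_silicon = complex(real = 4.05, imaginary = 0.044),
                      d_oxide_nm = 1900)
grid <- default_angle_grid(32, 5, 43.75)
noise <- list(type = "poisson")

write_truth <- function(h, path) {
  readr::write_csv(tibble::tibble(row = as.vector(row(h)),
                                  col = as.vector(col(h)),
                                  height_nm = as.vector(h)), path)
}

# flat dye (65 nm) and reference (5 nm) layers, ~1e4 photons/pixel
for (layer in list(list(name = "dye", h = 65, seed = 101),
                   list(name = "fibronectin", h = 5, seed = 102))) {
  hf <- make_height_field(phantom_spec(c(48, 48), "flat",
                                       base_height_nm = layer$h))
  st <- simulate_saim_stack(hf, 5000, 200, cfg, grid, noise,
                            seed = layer$seed, channel = layer$name)
  write_angle_stack(st, file.path(outdir, paste0(layer$name, ".tif")),
                    file.path(outdir, paste0(layer$name, "_angles.txt")))
  write_truth(hf, file.path(outdir, paste0(layer$name, "_truth.csv")))
}

# structured topographies: bleb caps and ridge networks on a 5 nm base
for (pat in c("blebs", "ridges")) {
  sp <- phantom_spec(c(48, 48), pat, base_height_nm = 5, seed = 7)
  hf <- make_height_field(sp)
  st <- simulate_saim_stack(hf, 5000, 200, cfg, grid, noise, seed = 200,
                            channel = pat)
  write_angle_stack(st, file.path(outdir, paste0(pat, ".tif")),
                    file.path(outdir, paste0(pat, "_angles.txt")))
  write_truth(hf, file.path(outdir, paste0(pat, "_truth.csv")))
  cat(sprintf("%s phantom: heights %.0f-%.0f nm over %d pixels\n",
              pat, min(hf), max(hf), length(hf)))
}
cat("simulated inputs written to", outdir, "\n")
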