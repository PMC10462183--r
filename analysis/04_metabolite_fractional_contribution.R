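#!/usr/bin/env Rscript
# Isotopologue analysis on simulated 13C6-glucose labeling data: three
# replicate samples per condition, conditions differing in labeling depth,
# summarized to relative amounts and fractional contributions.

suppressMessages(library(glycoscape))
outdir <- "results/metabolomics"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

# UDP-Glc / UDP-GlcNAc-like hexose skeletons under two labeling regimes
conditions <- data.frame(condition = c("low_glucose", "high_glucose"),
                         label_fraction = c(0.15, 0.45))
metabolites <- data.frame(metabolite = c("UDP-Glc", "UDP-GlcNAc"),
                          n_carbons = c(6, 8))

rows <- list()
seed <- 400
for (ci in seq_len(nrow(conditions))) {
  for (mi in seq_len(nrow(metabolites))) {
    for (rep in 1:3) {
      seed <- seed + 1
      ab <- simulate_isotopologues(metabolites$n_carbons[mi],
                                   conditions$label_fraction[ci],
                                   total_signal = 1e6, noise_cv = 0.1,
                                   seed = seed)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = sprintf("%s_rep%d", conditions$condition[ci], rep),
        condition = conditions$condition[ci],
        metabolite = metabolites$metabolite[mi],
        n_carbons = metabolites$n_carbons[mi],
        isotopologue_index = 0:metabolites$n_carbons[mi],
        area = ab,
        protein_conc = 1.0 + 0.1 * rep, cell_number = 1e6)
    }
  }
}
long <- dplyr::bind_rows(rows)
write_isotopologue_csv(long, file.path(outdir, "isotopologue_areas.csv"))

summ <- isotopologue_summary(long)
write_isotopologue_csv(summ, file.path(outdir, "fc_summary.csv"))

by_cond <- summ |>
  dplyr::mutate(condition = sub("_rep[0-9]+$", "", sample)) |>
  dplyr::group_by(condition, metabolite) |>
  dplyr::summarise(mean_fc = mean(fractional_contribution), .groups = "drop")
print(as.data.frame(by_cond))
cat("fractional contributions track the labeling depth (0.15 vs 0.45)\n")
cat("tables written to", outdir, "\n")
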