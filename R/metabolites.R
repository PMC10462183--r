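# 13C isotopologue arithmetic for targeted LC-MS metabolomics.
#
# After a 13C6-glucose pulse, each metabolite is observed as isotopologues
# M0..Mn (n = number of carbons).  Two derived quantities drive the
# downstream comparisons: the relative amount (sum over isotopologues) and
# the fractional contribution of 13C carbons to total carbon.

#' Relative metabolite amount
#'
#' Sum of all isotopologue signal areas of one metabolite.
#'
#' @param abundances Numeric vector `M0..Mn` of non-negative signal areas.
#' @return Scalar sum.
#' @export
#' @examples
#' relative_amount(c(3, 4, 5))  # 12
relative_amount <- function(abundances) {
  abundances <- as.numeric(abundances)
  if (any(!is.finite(abundances)) || any(abundances < 0)) {
    stop("abundances must be finite and >= 0", call. = FALSE)
  }
  sum(abundances)
}

#' Fractional contribution of 13C to total carbon
#'
#' For a metabolite with `n` carbons and isotopologue areas `M_0..M_n`:
#' `FC = sum_i i * M_i / (n * sum_i M_i)`, the fraction of the metabolite's
#' carbon atoms carrying a 13C label.  FC is in `[0, 1]` and invariant
#' under any positive rescaling of the areas.  No natural-abundance
#' correction is applied (see the package vignette for the caveat).
#'
#' @param abundances Numeric vector `M0..Mn`; its length minus one is the
#'   carbon count.
#' @param n_carbons Carbon count; defaults to `length(abundances) - 1`.
#' @return FC in `[0, 1]`, or `NA` with a warning when the total signal is
#'   zero (FC undefined).
#' @export
#' @examples
#' fractional_contribution(c(0, 0, 0, 10))  # 1: fully labeled, 3 carbons
fractional_contribution <- function(abundances,
                                    n_carbons = length(abundances) - 1L) {
  abundances <- as.numeric(abundances)
  if (any(!is.finite(abundances)) || any(abundances < 0)) {
    stop("abundances must be finite and >= 0", call. = FALSE)
  }
  if (n_carbons < 1) stop("n_carbons must be >= 1", call. = FALSE)
  if (length(abundances) != n_carbons + 1) {
    stop("need n_carbons + 1 isotopologue abundances (M0..Mn)", call. = FALSE)
  }
  total <- sum(abundances)
  if (total <= 0) {
    warning("zero total signal: fractional contribution undefined")
    return(NA_real_)
  }
  sum((seq_along(abundances) - 1L) * abundances) / (n_carbons * total)
}

#' Normalize metabolite values to protein and cell number
#'
#' Elementwise division by both normalizers; fractional contributions are
#' unchanged by this scaling (only relative amounts are affected).
#'
#' @param values Numeric vector of metabolite amounts.
#' @param protein_conc Positive protein concentration of the sample.
#' @param cell_number Positive cell count of the sample.
#' @return Normalized values.
#' @export
normalize_sample <- function(values, protein_conc = 1, cell_number = 1) {
  if (!is.finite(protein_conc) || protein_conc <= 0 ||
      !is.finite(cell_number) || cell_number <= 0) {
    stop("normalizers must be positive and finite", call. = FALSE)
  }
  values / (protein_conc * cell_number)
}

#' Per-sample, per-metabolite isotopologue summaries
#'
#' Takes a long-format table (`sample`, `metabolite`, `isotopologue_index`,
#' `area`, optionally `n_carbons`, `protein_conc`, `cell_number`) and
#' returns one row per (sample, metabolite) with the relative amount,
#' normalized relative amount and fractional contribution.  Missing
#' isotopologue indices are treated as zero areas with a warning; when
#' `n_carbons` is absent it is inferred as the largest index observed for
#' the metabolite across all samples.
#'
#' @param tbl Long-format data frame.
#' @return Tibble with columns `sample`, `metabolite`, `n_carbons`,
#'   `relative_amount`, `relative_amount_normalized`,
#'   `fractional_contribution`.
#' @export
isotopologue_summary <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("sample", "metabolite", "isotopologue_index", "area")
  if (!all(need %in% names(tbl))) {
    stop("table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(tbl$area < 0, na.rm = TRUE)) stop("negative areas", call. = FALSE)
  if (!"n_carbons" %in% names(tbl)) {
    tbl <- tbl |>
      dplyr::group_by(.data$metabolite) |>
      dplyr::mutate(n_carbons = max(.data$isotopologue_index)) |>
      dplyr::ungroup()
  }
  has_norm <- all(c("protein_conc", "cell_number") %in% names(tbl))
  missing_any <- FALSE
  out <- tbl |>
    dplyr::group_by(.data$sample, .data$metabolite, .data$n_carbons) |>
    dplyr::group_map(function(g, key) {
      nc <- key$n_carbons[1]
      ab <- numeric(nc + 1)
      ab[g$isotopologue_index + 1] <- g$area
      if (length(g$isotopologue_index) < nc + 1) missing_any <<- TRUE
      ra <- relative_amount(ab)
      ran <- if (has_norm) {
        normalize_sample(ra, g$protein_conc[1], g$cell_number[1])
      } else ra
      fc <- if (ra > 0) fractional_contribution(ab, nc) else NA_real_
      tibble::tibble(sample = key$sample, metabolite = key$metabolite,
                     n_carbons = nc, relative_amount = ra,
                     relative_amount_normalized = ran,
                     fractional_contribution = fc)
    }) |>
    dplyr::bind_rows()
  if (missing_any) {
    warning("missing isotopologue indices treated as zero areas")
  }
  out
}

#' Read / write long-format isotopologue tables
#'
#' Comma-delimited UTF-8 with a header row; columns as in
#' [isotopologue_summary()].
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_isotopologue_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample", "metabolite", "isotopologue_index", "area")
  if (!all(need %in% names(tbl))) {
    stop("isotopologue CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tbl
}

#' @rdname read_isotopologue_csv
#' @param tbl Table to write.
#' @export
write_isotopologue_csv <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}
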