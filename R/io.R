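# Readers and writers for the pipeline's on-disk formats.
#
# Image stacks travel as multi-page TIFF (page order = angle / time-bin
# order; no per-page metadata is assumed).  Floating-point TIFF storage is
# range-limited to [0, 1], so writers divide by a scale factor recorded in
# a one-line plain-text sidecar (<file>.scale) and readers multiply it
# back; the round trip is exact to float precision.  Angle lists are plain
# text, one angle in degrees per line.  All CSVs are comma-delimited UTF-8
# with header rows; heights are always in nm.

.write_scaled_tiff <- function(pages, path, bits = 32L) {
  # TIFF float storage is range-limited to [0, 1]; map affinely and record
  # the offset and scale in a sidecar so reading is lossless
  lo <- min(0, vapply(pages, min, numeric(1)))
  hi <- max(1e-12 + lo, vapply(pages, max, numeric(1)))
  scale <- hi - lo
  scaled <- lapply(pages, function(p) (p - lo) / scale)
  suppressWarnings(tiff::writeTIFF(scaled, path, bits.per.sample = bits,
                                   reduce = FALSE))
  writeLines(paste(format(lo, digits = 17), format(scale, digits = 17)),
             paste0(path, ".scale"))
  invisible(path)
}

.read_scaled_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".scale")
  aff <- c(0, 1)
  if (file.exists(sidecar)) {
    aff <- as.numeric(strsplit(readLines(sidecar)[1], " +")[[1]])
  }
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # collapse any stray channels
    p * aff[2] + aff[1]
  })
}

#' Read an angle list
#'
#' Plain text, one incidence angle in degrees per line; must be strictly
#' increasing.
#'
#' @param path File path.
#' @return An [angle_grid()].
#' @export
read_angle_file <- function(path) {
  angle_grid(as.numeric(readLines(path)))
}

#' Read a SAIM angle-scan stack
#'
#' Multi-page TIFF (one page per incidence angle, in acquisition order)
#' plus an angle list; the page count must equal the angle count.
#'
#' @param path_tiff Multi-page TIFF path.
#' @param path_angles Angle-list path (see [read_angle_file()]).
#' @param config An [optical_config()] recorded in the stack metadata.
#' @param channel Channel label.
#' @return An `angle_stack`.
#' @export
read_angle_stack <- function(path_tiff, path_angles, config,
                             channel = basename(path_tiff)) {
  grid <- read_angle_file(path_angles)
  pages <- .read_scaled_tiff(path_tiff)
  if (length(pages) != length(grid)) {
    stop(sprintf("page/angle mismatch: %d TIFF pages vs %d angles",
                 length(pages), length(grid)), call. = FALSE)
  }
  vals <- vapply(pages, identity, pages[[1]])
  intens <- aperm(vals, c(3, 1, 2))
  if (any(!is.finite(intens)) || any(intens < 0)) {
    stop("stack intensities must be finite and >= 0", call. = FALSE)
  }
  structure(list(grid = grid, intensities = intens,
                 metadata = list(channel = channel,
                                 d_oxide_nm = config$d_oxide_nm,
                                 source = path_tiff)),
            class = "angle_stack")
}

#' Write a SAIM angle-scan stack
#'
#' Writes the multi-page TIFF (with its `.scale` sidecar) and the matching
#' angle list.
#'
#' @param stack An `angle_stack`.
#' @param path_tiff,path_angles Output paths.
#' @return `path_tiff`, invisibly.
#' @export
write_angle_stack <- function(stack, path_tiff, path_angles) {
  stopifnot(inherits(stack, "angle_stack"))
  n_ang <- dim(stack$intensities)[1]
  pages <- lapply(seq_len(n_ang), function(j) {
    matrix(stack$intensities[j, , ], dim(stack$intensities)[2])
  })
  .write_scaled_tiff(pages, path_tiff)
  writeLines(format(as.numeric(stack$grid), digits = 15), path_angles)
  invisible(path_tiff)
}

#' Read the optical configuration from a YAML file
#'
#' Keys: `wavelength_nm`, `d_oxide_nm`, and `n_buffer` / `n_oxide` /
#' `n_silicon` each either a number or a `{re, im}` pair; an optional
#' `chips` map of per-chip `d_oxide_nm` overrides mirrors per-chip oxide
#' metrology.  Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param chip Optional chip id selecting a `d_oxide_nm` override.
#' @return An [optical_config()].
#' @export
read_optics_config <- function(path, chip = NULL) {
  raw <- yaml::read_yaml(path)
  allowed <- c("wavelength_nm", "d_oxide_nm", "n_buffer", "n_oxide",
               "n_silicon", "chips")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("unknown optics config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  as_index <- function(x) {
    if (is.list(x)) complex(real = x$re, imaginary = if (is.null(x$im)) 0 else x$im)
    else as.complex(x)
  }
  d_ox <- raw$d_oxide_nm
  if (!is.null(chip)) {
    if (is.null(raw$chips[[chip]])) stop("unknown chip id: ", chip, call. = FALSE)
    d_ox <- raw$chips[[chip]]$d_oxide_nm
  }
  optical_config(wavelength_nm = raw$wavelength_nm,
                 n_buffer = as_index(raw$n_buffer),
                 n_oxide = as_index(raw$n_oxide),
                 n_silicon = as_index(raw$n_silicon),
                 d_oxide_nm = d_ox)
}

#' Write height-map results and a reproducibility manifest
#'
#' Writes the height / amplitude / offset / SSE maps as float TIFFs, the
#' quality mask as an 8-bit TIFF, any tables as CSV, and a JSON manifest
#' listing every artifact with its MD5 checksum plus the configuration
#' hash and seed, so a run is reproducible from its manifest alone.
#'
#' @param results Named list; `height_map` entries, data frames, and plain
#'   matrices are all understood.
#' @param outdir Output directory (created if needed).
#' @param config Optional [optical_config()] hashed into the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return The manifest as a list, invisibly; written to
#'   `manifest.json` in `outdir`.
#' @export
write_outputs <- function(results, outdir, config = NULL, seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) {
    stop("output directory is not writable: ", outdir, call. = FALSE)
  }
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "height_map")) {
      for (layer in c("heights_nm", "amplitude", "offset", "sse")) {
        p <- file.path(outdir, sprintf("%s_%s.tif", nm, layer))
        m <- x[[layer]]
        m[is.na(m)] <- -1   # sentinel for masked pixels, never silent zero
        .write_scaled_tiff(list(m), p)
        files <- c(files, p, paste0(p, ".scale"))
      }
      pm <- file.path(outdir, sprintf("%s_quality_mask.tif", nm))
      suppressWarnings(tiff::writeTIFF(x$quality_mask * 1, pm,
                                       bits.per.sample = 8L))
      files <- c(files, pm)
    } else if (is.data.frame(x)) {
      p <- file.path(outdir, paste0(nm, ".csv"))
      readr::write_csv(x, p)
      files <- c(files, p)
    } else if (is.matrix(x)) {
      p <- file.path(outdir, paste0(nm, ".tif"))
      .write_scaled_tiff(list(x), p)
      files <- c(files, p, paste0(p, ".scale"))
    } else {
      stop("unsupported result type for '", nm, "'", call. = FALSE)
    }
  }
  cfg_hash <- if (!is.null(config)) {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    writeLines(jsonlite::toJSON(lapply(unclass(config), format), auto_unbox = TRUE), tmp)
    unname(tools::md5sum(tmp))
  } else NA_character_
  manifest <- list(
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    config_hash = cfg_hash,
    seed = if (is.null(seed)) NA_integer_ else seed
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
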