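# File formats
#
# FLIM cube: multi-frame TIFF, frame k = counts in TCSPC bin k, stored 16-bit
# (per-bin, per-pixel counts must be <= 65535; counts round-trip exactly),
# plus a JSON sidecar {bin_width_ns, rep_period_ns, pixel_size_um}.
# Lifetime maps: 32-bit float TIFF scaled by rep_period (quantisation below
# 1e-6 relative), photon totals as 16-bit TIFF.
# Curves/series: CSV with a '#'-prefixed provenance header.

sidecar_path <- function(path) sub("\\.tiff?$", "", path)

#' Write / read a FLIM stack as TIFF + JSON sidecar
#'
#' @param stack A [flim_stack()].
#' @param path Path of the TIFF cube; the sidecar is written next to it with
#'   the `.json` extension.
#' @return `write_flim_stack` returns the paths invisibly; `read_flim_stack`
#'   returns a [flim_stack()] (a 1 x 1 x n cube is the degenerate single-pixel
#'   case and still reads as a stack).
#' @export
write_flim_stack <- function(stack, path) {
  stopifnot(inherits(stack, "flim_stack"))
  if (max(stack$counts) > 65535)
    stop_format("per-bin counts exceed 65535: cannot store as 16-bit TIFF")
  d <- dim(stack$counts)
  frames <- lapply(seq_len(d[3]), function(k)
    matrix(stack$counts[, , k] / 65535, d[1], d[2]))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  sidecar <- paste0(sidecar_path(path), ".json")
  jsonlite::write_json(
    list(bin_width_ns = stack$bin_width, rep_period_ns = stack$rep_period,
         pixel_size_um = stack$pixel_size, n_bins = d[3]),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = path, sidecar = sidecar))
}

#' @rdname write_flim_stack
#' @export
read_flim_stack <- function(path) {
  sidecar <- paste0(sidecar_path(path), ".json")
  if (!file.exists(sidecar))
    stop_format(sprintf("missing JSON sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("bin_width_ns", "rep_period_ns", "pixel_size_um"))
    if (is.null(meta[[f]]))
      stop_format(sprintf("sidecar is missing required field `%s`", f))
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (!is.null(meta$n_bins) && length(frames) != meta$n_bins)
    stop_format(sprintf("frame count (%d) does not match sidecar n_bins (%d)",
                        length(frames), meta$n_bins))
  d <- dim(frames[[1]])
  counts <- vapply(frames, function(f) round(f * 65535), matrix(0, d[1], d[2]))
  dim(counts) <- c(d[1], d[2], length(frames))
  flim_stack(counts, meta$bin_width_ns, meta$rep_period_ns, meta$pixel_size_um)
}

#' Write / read an integer label image as TIFF
#'
#' @param labels Integer matrix (0 = background, labels <= 65535).
#' @param path TIFF path.
#' @export
write_label_image <- function(labels, path) {
  labels <- as.matrix(labels)
  if (max(labels) > 65535) stop_format("labels exceed 65535")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  img <- tiff::readTIFF(path)
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' Write / read a lifetime image as a TIFF pair
#'
#' The lifetime map is stored as 32-bit float TIFF scaled by the repetition
#' period (invalid pixels as 0 with a companion validity encoded by photon
#' counts below `min_photons`); photon totals as 16-bit TIFF. Metadata in a
#' JSON sidecar.
#'
#' @param img A [lifetime_image()].
#' @param path Base path; writes `<path>_tau.tif`, `<path>_photons.tif`,
#'   `<path>.json`.
#' @export
write_lifetime_image <- function(img, path) {
  stopifnot(inherits(img, "lifetime_image"))
  tau <- img$tau
  tau[is.na(tau)] <- 0
  tiff::writeTIFF(tau / img$rep_period, paste0(path, "_tau.tif"),
                  bits.per.sample = 32L, compression = "none")
  if (max(img$photons) > 65535)
    stop_format("photon totals exceed 65535: cannot store as 16-bit TIFF")
  tiff::writeTIFF(img$photons / 65535, paste0(path, "_photons.tif"),
                  bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(rep_period_ns = img$rep_period, pixel_size_um = img$pixel_size,
         min_photons = img$min_photons),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lifetime_image
#' @export
read_lifetime_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tau <- tiff::readTIFF(paste0(path, "_tau.tif")) * meta$rep_period_ns
  photons <- round(tiff::readTIFF(paste0(path, "_photons.tif")) * 65535)
  tau[photons < meta$min_photons] <- NA_real_
  structure(
    list(tau = tau, photons = photons, min_photons = meta$min_photons,
         rep_period = meta$rep_period_ns, pixel_size = meta$pixel_size_um),
    class = "lifetime_image"
  )
}

#' Read an IRF histogram from CSV
#'
#' Expects columns `bin_index` (from 0) and `counts`; binning metadata is
#' supplied by the caller (it travels with the decay data, not the IRF file).
#'
#' @param path CSV path.
#' @param bin_width,rep_period Binning in ns.
#' @return A [tcspc_histogram()].
#' @export
read_irf_csv <- function(path, bin_width, rep_period) {
  df <- read.csv(path, comment.char = "#")
  if (!all(c("bin_index", "counts") %in% names(df)))
    stop_format("IRF CSV must have columns `bin_index` and `counts`")
  n_bins <- as.integer(round(rep_period / bin_width))
  counts <- numeric(n_bins)
  idx <- df$bin_index + 1L
  if (any(idx < 1L | idx > n_bins))
    stop_format("IRF bin indices fall outside the repetition window")
  counts[idx] <- df$counts
  tcspc_histogram(counts, bin_width, rep_period)
}

#' @rdname read_irf_csv
#' @param irf A [tcspc_histogram()] to write.
#' @export
write_irf_csv <- function(irf, path) {
  stopifnot(inherits(irf, "tcspc_histogram"))
  write.csv(data.frame(bin_index = seq_along(irf$counts) - 1L,
                       counts = irf$counts),
            path, row.names = FALSE)
  invisible(path)
}

# CSV with a provenance comment header; read back with comment.char = "#".
write_csv_provenance <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# flimaggr %s%s%s",
                     as.character(packageVersion("flimaggr")),
                     if (!is.null(config_hash)) paste0(" config=", config_hash) else "",
                     if (!is.null(seed)) paste0(" seed=", seed) else ""),
             con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a curve or series CSV
#'
#' Generic reader for the package's CSV outputs (provenance comment lines
#' starting with `#` are skipped).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_curve_csv <- function(path) read.csv(path, comment.char = "#")
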