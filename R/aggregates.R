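#' Aggregate detection configuration
#'
#' @param lifetime_threshold Lifetime above which a valid pixel counts as
#'   aggregate, in ns. Default 5.0 (the red-puncta threshold).
#' @param min_particle_area Minimum connected-component area in px^2 for a
#'   particle to be kept. Default 4.
#' @param connectivity Pixel connectivity for components, 4 or 8. Default 8.
#' @return A validated list of class `aggregate_config`.
#' @export
aggregate_config <- function(lifetime_threshold = 5.0, min_particle_area = 4,
                             connectivity = 8) {
  if (lifetime_threshold <= 0)
    stop_invalid("`lifetime_threshold` must be positive")
  if (min_particle_area < 1)
    stop_invalid("`min_particle_area` must be >= 1")
  if (!connectivity %in% c(4, 8))
    stop_invalid("`connectivity` must be 4 or 8")
  structure(list(lifetime_threshold = lifetime_threshold,
                 min_particle_area = as.integer(min_particle_area),
                 connectivity = as.integer(connectivity)),
            class = "aggregate_config")
}

# Connected-component labelling of a logical mask. EBImage::bwlabel provides
# the 4-connected labelling; 8-connectivity merges 4-connected labels that
# touch diagonally, via union-find.
label_components <- function(mask, connectivity = 8) {
  mask <- as.matrix(mask)
  m <- matrix(as.numeric(mask != 0 & !is.na(mask)), nrow(mask), ncol(mask))
  lab <- matrix(as.integer(round(EBImage::imageData(EBImage::bwlabel(m)))),
                nrow(mask), ncol(mask))
  n <- max(lab)
  if (connectivity == 8 && n > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(n), find, integer(1))
      relab <- match(root, sort(unique(root)))
      lab[lab > 0L] <- relab[lab[lab > 0L]]
    }
  }
  lab
}

empty_report <- function(cfg) {
  structure(
    list(cells = data.frame(label = integer(0), cell_area_px = integer(0),
                            aggregate_area_px = integer(0),
                            particle_count = integer(0),
                            has_aggregate = logical(0),
                            area_fraction = numeric(0)),
         particles = data.frame(cell_label = integer(0),
                                particle_id = integer(0),
                                area_px = integer(0)),
         aggregate_mask = NULL,
         summary = list(percent_cells = NA_real_,
                        mean_area_fraction = NA_real_),
         config = cfg),
    class = "aggregate_report"
  )
}

#' Detect FLIM aggregates by lifetime threshold
#'
#' Aggregate pixels are valid pixels (photon total above the image's
#' `min_photons`) whose lifetime exceeds the threshold, inside a labelled
#' cell. Particles are connected components of those pixels within a single
#' cell — components spanning a cell boundary are split by the labels, and
#' components smaller than `min_particle_area` are discarded. Invalid
#' (low-photon) pixels never count as aggregate and are excluded from the
#' cell area, since a threshold on an undefined lifetime is meaningless.
#'
#' @param img A [lifetime_image()].
#' @param cells Integer cell-label matrix (0 = background) of the same shape.
#' @param cfg An [aggregate_config()].
#' @return Object of class `aggregate_report`: `$cells` per-cell data frame
#'   (`label`, `cell_area_px`, `aggregate_area_px`, `particle_count`,
#'   `has_aggregate`, `area_fraction`), `$particles` per-particle data frame,
#'   `$aggregate_mask` logical matrix of kept particles, `$summary` (percent
#'   of cells with aggregates, mean area fraction), `$config`.
#' @export
detect_aggregates <- function(img, cells, cfg = aggregate_config()) {
  stopifnot(inherits(img, "lifetime_image"))
  cells <- as.matrix(cells)
  if (!all(dim(cells) == dim(img$tau)))
    stop_incompatible("cell mask shape does not match the lifetime image")
  if (cfg$lifetime_threshold >= img$rep_period)
    stop_invalid("`lifetime_threshold` must lie within the repetition period")
  labs <- setdiff(sort(unique(as.vector(cells))), 0)
  if (!length(labs)) {
    warning("no cells in mask: returning an empty report")
    return(empty_report(cfg))
  }
  valid <- !is.na(img$tau)
  agg <- valid & !is.na(img$tau) & img$tau > cfg$lifetime_threshold & cells > 0
  kept_mask <- matrix(FALSE, nrow(cells), ncol(cells))
  cell_rows <- vector("list", length(labs))
  part_rows <- list()
  pid <- 0L
  for (i in seq_along(labs)) {
    L <- labs[i]
    in_cell <- cells == L
    cell_area <- sum(in_cell & valid)
    comp <- label_components(agg & in_cell, cfg$connectivity)
    areas <- if (max(comp) > 0L) tabulate(comp[comp > 0L]) else integer(0)
    keep <- which(areas >= cfg$min_particle_area)
    agg_area <- 0L
    for (k in keep) {
      pid <- pid + 1L
      part_rows[[pid]] <- data.frame(cell_label = L, particle_id = pid,
                                     area_px = areas[k])
      kept_mask[comp == k] <- TRUE
      agg_area <- agg_area + areas[k]
    }
    cell_rows[[i]] <- data.frame(label = L, cell_area_px = cell_area,
                                 aggregate_area_px = agg_area,
                                 particle_count = length(keep),
                                 has_aggregate = length(keep) >= 1L,
                                 area_fraction = if (cell_area > 0)
                                   agg_area / cell_area else NA_real_)
  }
  cells_df <- do.call(rbind, cell_rows)
  particles <- if (length(part_rows)) do.call(rbind, part_rows)
               else empty_report(cfg)$particles
  rep <- structure(
    list(cells = cells_df, particles = particles, aggregate_mask = kept_mask,
         summary = NULL, config = cfg),
    class = "aggregate_report"
  )
  rep$summary <- summarize_aggregation(rep)
  rep
}

#' Summary aggregation metrics
#'
#' The two headline metrics: the percentage of cells with at least one
#' detected aggregate, and the mean over cells of the aggregate area
#' fraction (aggregate area / cell area).
#'
#' @param report An `aggregate_report` from [detect_aggregates()].
#' @return List with `percent_cells` (0-100) and `mean_area_fraction`.
#' @export
summarize_aggregation <- function(report) {
  stopifnot(inherits(report, "aggregate_report"))
  cells <- report$cells
  if (!nrow(cells)) {
    warning("report contains no cells: summary metrics undefined")
    return(list(percent_cells = NA_real_, mean_area_fraction = NA_real_))
  }
  list(percent_cells = 100 * mean(cells$has_aggregate),
       mean_area_fraction = mean(cells$area_fraction, na.rm = TRUE))
}

#' @export
print.aggregate_report <- function(x, ...) {
  n <- nrow(x$cells)
  cat(sprintf("Aggregate report: %d cells, %d particles (threshold %.2f ns, min area %d px, %d-connectivity)\n",
              n, nrow(x$particles), x$config$lifetime_threshold,
              x$config$min_particle_area, x$config$connectivity))
  if (n)
    cat(sprintf("  %.1f%% of cells with aggregates; mean area fraction %.4f\n",
                x$summary$percent_cells, x$summary$mean_area_fraction))
  invisible(x)
}

#' Aggregate size distributions over timepoints
#'
#' Converts particle areas from px^2 to um^2 (`area * pixel_size^2`), bins
#' them and normalises per timepoint (one report per timepoint).
#'
#' @param reports A single `aggregate_report` or a list of them.
#' @param pixel_size Pixel size in micrometres.
#' @param bin_edges Area bin edges in um^2.
#' @return Data frame with `timepoint`, `bin_lo`, `bin_hi`, `frequency`;
#'   frequencies sum to 1 per timepoint with any particles, and the
#'   distribution is empty (all-zero) otherwise.
#' @export
size_distribution <- function(reports, pixel_size,
                              bin_edges = seq(0, 2, by = 0.1)) {
  if (pixel_size <= 0) stop_invalid("`pixel_size` must be positive")
  if (inherits(reports, "aggregate_report")) reports <- list(reports)
  n_bins <- length(bin_edges) - 1L
  out <- vector("list", length(reports))
  for (tp in seq_along(reports)) {
    areas <- reports[[tp]]$particles$area_px * pixel_size^2
    if (length(areas)) {
      idx <- findInterval(areas, bin_edges, rightmost.closed = TRUE)
      inside <- idx >= 1L & idx <= n_bins
      freq <- tabulate(idx[inside], nbins = n_bins)
      freq <- if (sum(freq)) freq / sum(freq) else rep(0, n_bins)
    } else freq <- rep(0, n_bins)
    out[[tp]] <- data.frame(timepoint = tp,
                            bin_lo = bin_edges[-length(bin_edges)],
                            bin_hi = bin_edges[-1], frequency = freq)
  }
  do.call(rbind, out)
}
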