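make_img <- function(tau, photons = 500, min_photons = 100) {
  structure(list(tau = tau, photons = matrix(photons, nrow(tau), ncol(tau)),
                 min_photons = min_photons, rep_period = 50, pixel_size = 0.1),
            class = "lifetime_image")
}

test_that("uniform native-lifetime images yield no particles", {
  tau <- matrix(3.3, 20, 20)
  cells <- matrix(1L, 20, 20)
  rep <- detect_aggregates(make_img(tau), cells)
  expect_equal(nrow(rep$particles), 0)
  expect_equal(rep$cells$area_fraction, 0)
  expect_equal(rep$summary$percent_cells, 0)
})

test_that("the minimum-area threshold is a sharp boundary", {
  tau <- matrix(3.3, 20, 20)
  tau[5, 5:7] <- 6  # 3-px line component
  cells <- matrix(1L, 20, 20)
  r4 <- detect_aggregates(make_img(tau), cells, aggregate_config(min_particle_area = 4))
  expect_equal(nrow(r4$particles), 0)
  r1 <- detect_aggregates(make_img(tau), cells, aggregate_config(min_particle_area = 1))
  expect_equal(r1$particles$area_px, 3)
})

test_that("connectivity 8 joins diagonal pixels, connectivity 4 does not", {
  tau <- matrix(3.3, 10, 10)
  tau[cbind(3:6, 3:6)] <- 6  # 4-px diagonal
  cells <- matrix(1L, 10, 10)
  r8 <- detect_aggregates(make_img(tau), cells,
                          aggregate_config(min_particle_area = 1, connectivity = 8))
  expect_equal(nrow(r8$particles), 1)
  expect_equal(r8$particles$area_px, 4)
  r4 <- detect_aggregates(make_img(tau), cells,
                          aggregate_config(min_particle_area = 1, connectivity = 4))
  expect_equal(nrow(r4$particles), 4)
})

test_that("particles spanning two cells are split at the boundary and invalid pixels never count", {
  tau <- matrix(3.3, 10, 10)
  tau[5:6, 4:7] <- 6
  tau[9, 9] <- NA  # invalid pixel
  cells <- matrix(1L, 10, 10)
  cells[, 6:10] <- 2L
  rep <- detect_aggregates(make_img(tau), cells, aggregate_config(min_particle_area = 1))
  expect_equal(sort(rep$particles$cell_label), c(1, 2))
  expect_equal(sum(rep$particles$area_px), 8)
  # invalid pixel excluded from cell area
  expect_equal(rep$cells$cell_area_px[rep$cells$label == 2], 50 - 1)
})

test_that("per-cell particle areas sum exactly to the aggregate area", {
  for (seed in c(41, 42, 43)) {
    sc <- quick_scene(seed = seed, puncta_tau = c(5.5, 7.6), photons = 400)
    img <- lifetime_image(sc$stack, quick_irf(), min_photons = 100)
    rep <- detect_aggregates(img, sc$truth$cell_labels)
    by_cell <- tapply(rep$particles$area_px, rep$particles$cell_label, sum)
    for (L in rep$cells$label) {
      expect_identical(rep$cells$aggregate_area_px[rep$cells$label == L],
                       unname(if (as.character(L) %in% names(by_cell))
                         as.integer(by_cell[[as.character(L)]]) else 0L))
    }
    expect_true(all(rep$cells$aggregate_area_px <= rep$cells$cell_area_px))
  }
})

test_that("lowering the lifetime threshold never decreases the aggregate area", {
  sc <- quick_scene(seed = 44, puncta_tau = c(5.2, 7.6), photons = 400)
  img <- lifetime_image(sc$stack, quick_irf(), min_photons = 100)
  areas <- vapply(c(6.5, 5.5, 5.0, 4.5, 4.0), function(thr) {
    rep <- detect_aggregates(img, sc$truth$cell_labels,
                             aggregate_config(lifetime_threshold = thr,
                                              min_particle_area = 1))
    sum(rep$cells$aggregate_area_px)
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("summary metrics follow their definitions and respond to aggregate-free cells", {
  cells_df <- data.frame(label = 1:10, cell_area_px = 100L,
                         aggregate_area_px = c(rep(2L, 3), rep(0L, 7)),
                         particle_count = c(rep(1L, 3), rep(0L, 7)),
                         has_aggregate = c(rep(TRUE, 3), rep(FALSE, 7)),
                         area_fraction = c(rep(0.02, 3), rep(0, 7)))
  rep <- structure(list(cells = cells_df, particles = NULL,
                        aggregate_mask = NULL, summary = NULL,
                        config = aggregate_config()),
                   class = "aggregate_report")
  s <- summarize_aggregation(rep)
  expect_equal(s$percent_cells, 30)
  expect_equal(s$mean_area_fraction, mean(cells_df$area_fraction))
  # adding an aggregate-free cell lowers both metrics
  rep$cells <- rbind(cells_df, within(cells_df[1, ], {
    label <- 11L; aggregate_area_px <- 0L; particle_count <- 0L
    has_aggregate <- FALSE; area_fraction <- 0
  }))
  s2 <- summarize_aggregation(rep)
  expect_lt(s2$percent_cells, s$percent_cells)
  expect_lt(s2$mean_area_fraction, s$mean_area_fraction)
})

test_that("an empty cell mask produces an empty report with a warning, not an error", {
  tau <- matrix(3.3, 10, 10)
  expect_warning(rep <- detect_aggregates(make_img(tau), matrix(0L, 10, 10)),
                 regexp = "no cells")
  expect_equal(nrow(rep$cells), 0)
  expect_true(is.na(rep$summary$percent_cells))
})

test_that("size distributions convert units, normalise, and track the generator", {
  rep1 <- structure(list(particles = data.frame(cell_label = 1L,
                                                particle_id = 1L,
                                                area_px = 25L)),
                    class = "aggregate_report")
  d <- size_distribution(rep1, pixel_size = 0.1, bin_edges = seq(0, 1, 0.05))
  expect_equal(sum(d$frequency), 1)
  expect_equal(d$bin_lo[d$frequency == 1], 0.25)  # 25 px^2 * (0.1 um)^2
  # shifting the generator's radius range up shifts the distribution mean up
  mean_area <- function(radius_range, seed) {
    spec <- scene_spec(image_size = c(96, 96), n_cells = 3,
                       puncta_per_cell = 2, puncta_radius_range = radius_range,
                       photons_per_pixel = 10, seed = seed)
    mean(simulate_flim_scene(spec)$truth$puncta$area_px)
  }
  small <- vapply(51:55, function(s) mean_area(c(2, 3), s), numeric(1))
  large <- vapply(51:55, function(s) mean_area(c(4, 5), s), numeric(1))
  expect_gt(mean(large), mean(small))
})

test_that("percent of cells with aggregates increases with the seeded puncta load", {
  levels <- 0:4
  pct <- matrix(NA_real_, length(levels), 10)
  for (i in seq_along(levels)) {
    for (s in 1:10) {
      sc <- quick_scene(seed = 600 + 17 * s, puncta_per_cell = levels[i],
                        puncta_tau = c(6, 7.6), n_cells = 2, photons = 200)
      img <- lifetime_image(sc$stack, quick_irf(), min_photons = 50)
      rep <- detect_aggregates(img, sc$truth$cell_labels)
      pct[i, s] <- rep$summary$percent_cells
    }
  }
  rho <- suppressWarnings(
    stats::cor(rep(levels, 10), as.vector(pct), method = "spearman"))
  expect_gt(rho, 0)
})
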