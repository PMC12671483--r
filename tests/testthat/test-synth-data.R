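test_that("generators are bit-identical under a fixed seed", {
  cfg <- movie_config(seed = 7, image_shape = c(96L, 96L),
                      cell_radius_um = 3, n_frames = 22L,
                      adhesion_spec = list(n = 5L, length_um = 2,
                                           width_um = 0.5,
                                           nucleation_frames = 1L,
                                           growth_rate_um_min = 0.2,
                                           margin_um = 0.3))
  a <- generate_timelapse(cfg)
  b <- generate_timelapse(cfg)
  expect_identical(a$movie$channels, b$movie$channels)
  expect_identical(a$truth$events, b$truth$events)
  ta <- generate_tirf_movie(cfg)
  tb <- generate_tirf_movie(cfg)
  expect_identical(ta$movie$channels$tirf, tb$movie$channels$tirf)
  expect_identical(ta$truth$events, tb$truth$events)
  expect_identical(generate_micropattern_scene("lines", seed = 3)$cargo,
                   generate_micropattern_scene("lines", seed = 3)$cargo)
  expect_identical(generate_scalar_fixtures(seed = 5)$flow,
                   generate_scalar_fixtures(seed = 5)$flow)
})

test_that("ground truth matches the configured scene", {
  cfg <- movie_config(seed = 2)
  tl <- generate_timelapse(cfg)
  expect_equal(nrow(tl$truth$adhesion_summary), cfg$adhesion_spec$n)
  expect_equal(max(tl$truth$adhesion_labels), cfg$adhesion_spec$n)
  # label-mask presence is consistent with nucleation frames
  for (i in seq_len(cfg$adhesion_spec$n)) {
    present <- vapply(seq_len(cfg$n_frames), function(f)
      any(tl$truth$adhesion_labels[, , f] == i), logical(1))
    expect_equal(which(present)[1],
                 tl$truth$adhesion_summary$t_appear_frame[i])
  }
  tv <- generate_tirf_movie(cfg)
  expect_equal(nrow(tv$truth$events), cfg$event_spec$n)
  # every event lies inside the cell mask
  ev <- tv$truth$events
  expect_true(all(tv$truth$cell_mask[cbind(round(ev$row), round(ev$col))]))
})

test_that("cell-mask area follows the protrusion schedule (polygon oracle)", {
  cfg <- movie_config(seed = 5)
  tl <- generate_timelapse(cfg)
  rfun <- rushquant:::edge_radius_fun(cfg)
  th <- seq(0, 2 * pi, length.out = 20001)[-1]
  for (f in c(1, 10, 20, 30)) {
    r <- rfun(th * 180 / pi, (f - 1) * cfg$frame_interval)
    area_analytic <- sum(r^2) * (th[2] - th[1]) / 2
    area_pixels <- sum(tl$truth$cell_masks[, , f]) * cfg$pixel_size^2
    expect_lt(abs(area_pixels - area_analytic) / area_analytic, 0.02)
  }
})

test_that("FA-biased and uniform event placement behave as configured", {
  cfg <- movie_config(seed = 8)
  cfg$event_spec$rho <- 1
  tv <- generate_tirf_movie(cfg)
  d <- brute_nearest_distance(tv$truth$events, tv$truth$fa_mask,
                              cfg$pixel_size)
  # all events within the stated radius of an adhesion pixel (+1 px for
  # the pixel-grid rounding of the oracle)
  expect_true(all(d <= cfg$event_spec$radius_um + cfg$pixel_size))
  expect_true(all(tv$truth$events$fa_biased))

  # rho = 0: mean nearest-FA distance matches a uniform-placement oracle
  d0 <- unlist(lapply(1:12, function(s) {
    cfg0 <- movie_config(seed = 400 + s)
    cfg0$event_spec$rho <- 0
    t0 <- generate_tirf_movie(cfg0)
    brute_nearest_distance(t0$truth$events, t0$truth$fa_mask,
                           cfg0$pixel_size)
  }))
  cfg_ref <- movie_config(seed = 401)
  cfg_ref$event_spec$rho <- 0
  ref <- generate_tirf_movie(cfg_ref)
  px <- which(ref$truth$cell_mask, arr.ind = TRUE)
  set.seed(99)
  j <- sample.int(nrow(px), 2e4, replace = TRUE)
  oracle <- brute_nearest_distance(
    data.frame(row = px[j, 1], col = px[j, 2]),
    ref$truth$fa_mask, cfg_ref$pixel_size)
  se <- sqrt(stats::var(d0) / length(d0) +
               stats::var(oracle) / length(oracle))
  expect_lt(abs(mean(d0) - mean(oracle)), 3 * se)
  expect_false(any(generate_tirf_movie(cfg_ref)$truth$events$fa_biased))
})

test_that("an isolated bright flash renders where the truth says", {
  cfg <- movie_config(seed = 21)
  cfg$event_spec$n <- 1L
  cfg$event_spec$amplitude <- 600
  tv <- generate_tirf_movie(cfg)
  ev <- tv$truth$events
  diffimg <- tv$movie$channels$tirf[, , ev$frame] -
    tv$movie$channels$tirf[, , ev$frame - 1]
  peak <- which(diffimg == max(diffimg), arr.ind = TRUE)[1, ]
  expect_lt(sqrt((peak[1] - ev$row)^2 + (peak[2] - ev$col)^2), 1.5)
})

test_that("the camera noise model is Poisson-limited at the stated gain", {
  gain <- 2
  set.seed(1)
  flat <- apply_camera_noise(matrix(400, 300, 300), gain = gain,
                             read_sd = 0)
  expect_true(all(flat >= 0))
  expect_lt(abs(stats::var(as.numeric(flat)) / mean(flat) - gain) / gain,
            0.1)
  expect_error(apply_camera_noise(matrix(1, 2, 2), gain = 0), "gain")
})

test_that("micropattern rasterizations are exact", {
  sc <- generate_micropattern_scene(
    "lines", geometry = list(shape = c(120L, 360L)), seed = 1)
  # 9 um lines at 0.1 um/pixel: stripes exactly 90 px wide, period 180 px
  runs <- rle(sc$pattern_mask[1, ])
  expect_identical(runs$lengths[runs$values], c(90L, 90L))
  expect_identical(sc$pattern_mask[, 1], sc$pattern_mask[, 181])
  dual <- generate_micropattern_scene("dual_lines", seed = 1)
  expect_identical(dual$second_mask, !dual$pattern_mask)
  expect_error(generate_micropattern_scene(
    "lines", geometry = list(line_width_um = 0)), "degenerate")
  expect_error(generate_micropattern_scene(
    "dots", geometry = list(dot_radius_um = 0)), "degenerate")
  # enrichment 1: cargo statistically uniform across the two mask phases
  flat <- generate_micropattern_scene("lines",
                                      geometry = list(enrichment = 1),
                                      seed = 2)
  on <- flat$cargo[flat$pattern_mask & flat$cell_mask]
  off <- flat$cargo[!flat$pattern_mask & flat$cell_mask]
  expect_lt(abs(mean(on) - mean(off)), 0.05 * mean(off))
})

test_that("scalar fixtures realize the requested log-normal schedule", {
  fx0 <- generate_scalar_fixtures(list(sdlog = 0, n_cells = 5L,
                                       surface_meanlog = rep(log(30), 4),
                                       total_meanlog = rep(log(300), 4)),
                                  seed = 1)
  expect_equal(unique(fx0$flow$surface), 30)
  big <- generate_scalar_fixtures(list(n_cells = 1e5L,
                                       time_points = 0,
                                       surface_meanlog = log(50),
                                       total_meanlog = log(500),
                                       sdlog = 0.25), seed = 3)
  expect_lt(abs(exp(mean(log(big$flow$surface))) - 50) / 50, 0.01)
  fx <- generate_scalar_fixtures(list(band_ratios = c(2)), seed = 1)
  expect_equal(fx$bands$upper / fx$bands$lower, fx$bands$true_ratio)
  expect_error(generate_scalar_fixtures(list(sdlog = -0.1)), "sdlog")
})
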