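# helper: paint a filled rectangle of the requested pixel area
paint_blob <- function(img, r0, c0, n_px, width = 10, value = 100) {
  rows <- ceiling(n_px / width)
  filled <- 0
  for (r in seq_len(rows)) {
    w <- min(width, n_px - filled)
    img[r0 + r - 1, c0:(c0 + w - 1)] <- value
    filled <- filled + w
  }
  img
}

test_that("the 0.6 um2 size filter keeps exactly the larger blobs", {
  img <- matrix(0, 120, 120)
  sizes <- c(40, 55, 62, 80, 110)  # px at 0.1 um/px: 0.40 .. 1.10 um2
  c0 <- 5
  for (s in sizes) {
    img <- paint_blob(img, 10, c0, s)
    c0 <- c0 + 20
  }
  seg <- segment_adhesions(img, pixel_size = 0.1, threshold = 50)
  expect_equal(nrow(seg$table), 3)
  expect_setequal(round(seg$table$area_um2, 2), c(0.62, 0.80, 1.10))
  # total object count (before filtering) matches a flood-fill oracle
  expect_equal(flood_fill_count(img > 50), length(sizes))
  lab_all <- rushquant:::label_components_cpp(img > 50, TRUE)
  expect_equal(max(lab_all), flood_fill_count(img > 50))
})

test_that("labelling is 8-connected and matches the flood-fill oracle", {
  set.seed(5)
  for (i in 1:5) {
    m <- matrix(stats::runif(40 * 40) < 0.35, 40, 40)
    lab <- rushquant:::label_components_cpp(m, TRUE)
    expect_equal(max(lab), flood_fill_count(m))
  }
  diag2 <- matrix(FALSE, 4, 4); diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_equal(max(rushquant:::label_components_cpp(diag2, TRUE)), 1)
})

test_that("degenerate marker images yield empty tables, not errors", {
  expect_equal(nrow(segment_adhesions(matrix(0, 30, 30), 0.1)$table), 0)
  expect_equal(nrow(segment_adhesions(matrix(7, 30, 30), 0.1)$table), 0)
})

test_that("segmentation is idempotent on its own binary output", {
  img <- paint_blob(matrix(0, 60, 60), 10, 10, 80)
  img <- paint_blob(img, 35, 30, 110)
  seg1 <- segment_adhesions(img, 0.1, threshold = 50)
  seg2 <- segment_adhesions(matrix(as.numeric(seg1$labels > 0),
                                   nrow(img), ncol(img)),
                            0.1, threshold = 0.5)
  expect_identical(seg1$labels > 0, seg2$labels > 0)
})

test_that("cargo intensity means follow pixel arithmetic", {
  lab <- matrix(0L, 10, 10)
  lab[2:4, 2:4] <- 1L
  lab[7:8, 7:9] <- 2L
  uni <- cargo_intensity_in_adhesions(matrix(7, 10, 10), lab)
  expect_true(all(uni$per_label$mean_cargo == 7))
  expect_equal(uni$per_cell, 7)
  cargo <- matrix(0, 10, 10)
  cargo[2, 2] <- 3; cargo[2, 3] <- 5
  lab2 <- matrix(0L, 10, 10); lab2[2, 2:3] <- 1L
  expect_equal(cargo_intensity_in_adhesions(cargo, lab2)$per_label$mean_cargo,
               4)
  set.seed(3)
  rnd <- matrix(stats::runif(100), 10, 10)
  res <- cargo_intensity_in_adhesions(rnd, lab)
  expect_equal(res$per_label$mean_cargo[1], mean(rnd[lab == 1]))
  expect_equal(res$per_cell, mean(rnd[lab > 0]))
  none <- cargo_intensity_in_adhesions(rnd, matrix(0L, 10, 10))
  expect_true(is.na(none$per_cell))
  expect_true(attr(none$per_cell, "no_adhesions"))
})

test_that("relative recruitment normalizes to the pre-release value", {
  expect_equal(relative_recruitment(c(10, 15, 20), 1), c(1, 1.5, 2))
  expect_equal(relative_recruitment(rep(4.2, 5)), rep(1, 5))
  expect_error(relative_recruitment(c(0, 1, 2), 1), "t0")
})

test_that("relative adhesion area sums track the label masks", {
  tab <- data.frame(frame = c(1, 1, 2, 2), area_um2 = c(1.0, 2.5, 3.0, 4.0))
  out <- adhesion_area_sum(tab, t0_frame = 1)
  expect_equal(out$total_area_um2, c(3.5, 7.0))
  expect_equal(out$relative_area, c(1, 2))
  expect_error(adhesion_area_sum(tab, t0_frame = 3), "reference")
  # against a pixel-count oracle on generator label masks
  tl <- generate_timelapse(movie_config(seed = 6))
  labs <- tl$truth$adhesion_labels
  tabs <- do.call(rbind, lapply(c(1, 15, 30), function(f) {
    data.frame(frame = f,
               area_um2 = as.numeric(table(labs[, , f][labs[, , f] > 0])) *
                 0.1^2)
  }))
  out2 <- adhesion_area_sum(tabs, t0_frame = 1)
  expect_equal(out2$total_area_um2,
               vapply(c(1, 15, 30),
                      function(f) sum(labs[, , f] > 0) * 0.01, numeric(1)))
})

test_that("the 4-area split is equal-count with Area 1 at the distal tip", {
  roi <- matrix(FALSE, 60, 20)
  roi[11:50, 6:13] <- TRUE  # 40 x 8 rectangle
  sub <- subdivide_adhesion_roi(roi, distal_tip = c(11, 9))
  expect_equal(sub$counts, rep(80, 4))
  expect_true(all(sub$masks[[1]] == (sub$assignment == 1)))
  # contiguous 10-row blocks from the tip inward
  expect_true(all(sub$assignment[11:20, 6:13] == 1))
  expect_true(all(sub$assignment[41:50, 6:13] == 4))
  expect_equal(sum(sub$assignment > 0), sum(roi))
  # irregular blob: counts within 1, partition covers the ROI
  set.seed(8)
  blob <- matrix(FALSE, 30, 30)
  blob[8:25, 10:14] <- TRUE
  blob[12:20, 15:17] <- TRUE
  subb <- subdivide_adhesion_roi(blob, c(8, 12))
  expect_lte(diff(range(subb$counts)), 1)
  expect_equal(sum(subb$counts), sum(blob))
  expect_equal(subb$assignment[8, 12], 1L)
  expect_error(subdivide_adhesion_roi(matrix(c(TRUE, TRUE), 1), c(1, 1)),
               "4 pixels")
  expect_error(subdivide_adhesion_roi(roi, c(1, 1)), "inside")
})

test_that("ground-truth distal tips land in Area 1 on generator adhesions", {
  tl <- generate_timelapse(movie_config(seed = 4))
  labs <- tl$truth$adhesion_labels[, , 30]
  for (lb in c(1, 3, 5)) {
    rec <- subset(tl$truth$adhesions, label == lb & frame == 30)
    sub <- subdivide_adhesion_roi(labs == lb, c(rec$tip_row, rec$tip_col))
    expect_equal(sub$assignment[rec$tip_row, rec$tip_col], 1L)
  }
})

test_that("tip-to-center profiles normalize per area and read the schedule", {
  roi <- matrix(FALSE, 20, 20); roi[5:16, 8:11] <- TRUE
  sub <- subdivide_adhesion_roi(roi, c(5, 9))
  const <- array(10, dim = c(20, 20, 12))
  pr <- tip_to_center_profile(const, sub, frame_interval = 1,
                              release_frame = 5)
  expect_false(attr(pr, "appeared"))
  expect_true(all(abs(as.matrix(pr[, 3:6]) - 1) < 1e-12))
  # a zero-baseline area is flagged, not divided
  stk <- array(10, dim = c(20, 20, 12))
  for (f in 1:12) {
    fr <- stk[, , f]
    fr[sub$masks[[2]]] <- 0
    stk[, , f] <- fr
  }
  fr <- stk[, , 9]; fr[roi] <- 40; stk[, , 9] <- fr
  pr2 <- tip_to_center_profile(stk, sub, frame_interval = 1,
                               release_frame = 5)
  expect_equal(attr(pr2, "flagged_areas"), 2)
  expect_true(all(is.na(pr2$area2)))
  # distal-first generator schedule: Area 1 crosses before Area 4
  tl <- generate_timelapse(movie_config(seed = 3))
  roi8 <- tl$truth$adhesion_labels[, , 30] == 8
  rec <- subset(tl$truth$adhesions, label == 8 & frame == 30)
  sub8 <- subdivide_adhesion_roi(roi8, c(rec$tip_row, rec$tip_col))
  pr8 <- tip_to_center_profile(tl$movie$channels$cargo, sub8,
                               frame_interval = 1, release_frame = 3)
  cross <- function(x, th) { i <- which(x >= th); if (length(i)) i[1] else Inf }
  expect_lte(cross(pr8$area1, 1.5), cross(pr8$area4, 1.5))
  expect_lt(cross(pr8$area1, 3), cross(pr8$area4, 3))
})

test_that("track filtering applies lifetime and edge-distance rules", {
  tr <- data.frame(track_id = 1:4,
                   lifetime_min = c(10, 15, 30, 40),
                   edge_distance_um = c(1, 1, 1, 5))
  kept <- filter_adhesion_tracks(tr, 15, 2)
  expect_equal(kept$track_id, c(2, 3))  # 15 min kept (>=), far track dropped
  # row-scan oracle on a random table
  set.seed(2)
  big <- data.frame(track_id = 1:200,
                    lifetime_min = stats::runif(200, 0, 40),
                    edge_distance_um = stats::runif(200, 0, 6))
  kept2 <- filter_adhesion_tracks(big, 15, 2)
  oracle <- big[big$lifetime_min >= 15 & big$edge_distance_um <= 2, ]
  expect_equal(kept2$track_id, oracle$track_id)
})

test_that("frame-linked tracks recover generator nucleation order", {
  cfg <- movie_config(seed = 9)
  tl <- generate_timelapse(cfg)
  tabs <- lapply(seq_len(cfg$n_frames), function(f)
    segment_adhesions(tl$movie$channels$marker[, , f], cfg$pixel_size,
                      cell_mask = tl$truth$cell_masks[, , f])$table)
  tracks <- track_adhesions(tabs, frame_interval = cfg$frame_interval)
  # the long-lived adhesions (nucleating by frame 10) yield long tracks
  expect_gte(sum(tracks$lifetime_min >= 15), 6)
  kept <- filter_adhesion_tracks(tracks, min_lifetime_min = 15,
                                 max_edge_distance_um = Inf)
  expect_true(all(kept$lifetime_min >= 15))
})

test_that("FN mode recruits more cargo into adhesions than collagen mode", {
  fn <- generate_timelapse(movie_config(seed = 3, condition = "FN"))
  col <- generate_timelapse(movie_config(seed = 3, condition = "collagen"))
  f <- 28  # matched post-release frame
  seg_fn <- segment_adhesions(fn$movie$channels$marker[, , f], 0.1)
  seg_col <- segment_adhesions(col$movie$channels$marker[, , f], 0.1)
  m_fn <- cargo_intensity_in_adhesions(fn$movie$channels$cargo[, , f],
                                       seg_fn$labels)$per_cell
  m_col <- cargo_intensity_in_adhesions(col$movie$channels$cargo[, , f],
                                        seg_col$labels)$per_cell
  expect_gt(m_fn, m_col)
})
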