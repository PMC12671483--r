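# Focal-adhesion segmentation, cargo recruitment and tip-to-center
# delivery profiles.

#' Segment focal adhesions in a marker image
#'
#' Global threshold (Otsu by default), 8-connected labelling, and removal of
#' objects whose area is not strictly larger than `min_area_um2` (default
#' 0.6 µm², read as a strict inequality). An empty or constant image yields
#' zero adhesions without error.
#'
#' @param marker_frame 2-D nonnegative numeric matrix (adhesion-marker
#'   channel).
#' @param pixel_size µm per pixel.
#' @param min_area_um2 minimum object area (µm², strict).
#' @param threshold `"otsu"` or an explicit numeric intensity threshold.
#' @param smooth_sigma optional Gaussian pre-smoothing SD in pixels
#'   (0 = off); a light denoising stand-in applied before thresholding.
#' @param cell_mask optional logical matrix; when supplied, the centroid
#'   distance to the cell edge (µm) is reported per adhesion.
#' @return List with `labels` (integer matrix, 0 = background) and `table`
#'   (data frame: `label`, `area_um2`, `centroid_row`, `centroid_col`,
#'   `mean_marker`, and `edge_distance_um` when `cell_mask` is given);
#'   the applied threshold is attached as attribute `threshold`.
#' @export
segment_adhesions <- function(marker_frame, pixel_size,
                              min_area_um2 = 0.6,
                              threshold = "otsu",
                              smooth_sigma = 0,
                              cell_mask = NULL) {
  stopifnot(is.matrix(marker_frame), all(marker_frame >= 0))
  img <- marker_frame
  if (smooth_sigma > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = smooth_sigma))
  empty <- function(thr) {
    out <- list(labels = matrix(0L, nrow(img), ncol(img)),
                table = data.frame(label = integer(0), area_um2 = numeric(0),
                                   centroid_row = numeric(0),
                                   centroid_col = numeric(0),
                                   mean_marker = numeric(0)))
    attr(out, "threshold") <- thr
    out
  }
  if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) == 0) return(empty(NA_real_))
    norm <- (img - rng[1]) / diff(rng)
    thr <- rng[1] + diff(rng) *
      EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else {
    thr <- as.numeric(threshold)
  }
  mask <- img > thr
  if (!any(mask)) return(empty(thr))
  lab <- label_components_cpp(mask, TRUE)
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts * pixel_size^2 > min_area_um2)
  if (length(keep) == 0) return(empty(thr))
  relab <- integer(length(counts))
  relab[keep] <- seq_along(keep)
  lab2 <- matrix(0L, nrow(img), ncol(img))
  nz <- lab > 0
  lab2[nz] <- relab[lab[nz]]
  tab <- do.call(rbind, lapply(seq_along(keep), function(i) {
    px <- which(lab2 == i, arr.ind = TRUE)
    data.frame(label = i,
               area_um2 = nrow(px) * pixel_size^2,
               centroid_row = mean(px[, 1]),
               centroid_col = mean(px[, 2]),
               mean_marker = mean(marker_frame[px]))
  }))
  if (!is.null(cell_mask)) {
    dm <- EBImage::distmap(matrix(as.numeric(cell_mask),
                                  nrow(cell_mask), ncol(cell_mask)))
    tab$edge_distance_um <- vapply(seq_len(nrow(tab)), function(i) {
      dm[round(tab$centroid_row[i]), round(tab$centroid_col[i])]
    }, numeric(1)) * pixel_size
  }
  out <- list(labels = lab2, table = tab)
  attr(out, "threshold") <- thr
  out
}

#' Mean cargo intensity inside segmented adhesions
#'
#' @param cargo_frame 2-D numeric matrix (cargo channel).
#' @param labels integer label matrix from [segment_adhesions()].
#' @return List with `per_label` (data frame `label`, `mean_cargo`) and
#'   `per_cell` (mean over all adhesion pixels; `NA` with attribute
#'   `no_adhesions = TRUE` when the mask is empty).
#' @export
cargo_intensity_in_adhesions <- function(cargo_frame, labels) {
  if (!all(dim(cargo_frame) == dim(labels)))
    stop("cargo frame and label mask must share dimensions")
  idx <- labels > 0
  if (!any(idx)) {
    per_cell <- NA_real_
    attr(per_cell, "no_adhesions") <- TRUE
    return(list(per_label = data.frame(label = integer(0),
                                       mean_cargo = numeric(0)),
                per_cell = per_cell))
  }
  means <- tapply(cargo_frame[idx], labels[idx], mean)
  list(per_label = data.frame(label = as.integer(names(means)),
                              mean_cargo = as.numeric(means)),
       per_cell = mean(cargo_frame[idx]))
}

#' Normalize a time series to its pre-release value
#'
#' Each value is divided by the value at `t0_index`, so the series reads as
#' relative recruitment with the pre-release point at exactly 1.
#'
#' @param series numeric vector of per-time-point values.
#' @param t0_index index of the reference (pre-release) time point.
#' @return Numeric vector, `series / series[t0_index]`.
#' @export
relative_recruitment <- function(series, t0_index = 1L) {
  if (t0_index < 1 || t0_index > length(series))
    stop("t0_index out of range")
  if (!is.finite(series[t0_index]) || series[t0_index] <= 0)
    stop("reference value at t0 must be > 0")
  series / series[t0_index]
}

#' Per-frame total adhesion area relative to a reference frame
#'
#' @param table adhesion table with columns `frame` and `area_um2`
#'   (e.g. row-bound per-frame tables from [segment_adhesions()]).
#' @param t0_frame reference frame.
#' @return Data frame `frame`, `total_area_um2`, `relative_area`.
#' @export
adhesion_area_sum <- function(table, t0_frame) {
  stopifnot(all(c("frame", "area_um2") %in% names(table)))
  sums <- tapply(table$area_um2, table$frame, sum)
  out <- data.frame(frame = as.integer(names(sums)),
                    total_area_um2 = as.numeric(sums))
  i0 <- match(t0_frame, out$frame)
  if (is.na(i0) || out$total_area_um2[i0] <= 0)
    stop("reference frame has no (or zero) adhesion area")
  out$relative_area <- out$total_area_um2 / out$total_area_um2[i0]
  out
}

#' Split an adhesion ROI into four equal areas from distal tip to proximal end
#'
#' ROI pixels are ranked by their projection onto the major axis oriented
#' from the distal tip toward the proximal end and split at the 25/50/75
#' quantiles of rank, giving four contiguous areas of equal pixel count
#' (within 1 pixel). Area 1 contains the distal tip.
#'
#' @param roi_mask logical matrix, one connected adhesion ROI.
#' @param distal_tip `c(row, col)` of the distal tip (inside the ROI).
#' @return List with `assignment` (integer matrix, 0 outside, 1-4 inside,
#'   1 = distal), `masks` (list of 4 logical matrices), `counts`.
#' @export
subdivide_adhesion_roi <- function(roi_mask, distal_tip) {
  px <- which(roi_mask, arr.ind = TRUE)
  n <- nrow(px)
  if (n < 4) stop("ROI must contain at least 4 pixels")
  tip <- as.numeric(distal_tip)
  if (!roi_mask[tip[1], tip[2]]) stop("distal tip must lie inside the ROI")
  ctr <- colMeans(px)
  cc <- sweep(px, 2, ctr)
  ax <- eigen(crossprod(cc) / n, symmetric = TRUE)$vectors[, 1]
  # orient the axis so the tip projects lowest (Area 1 holds the tip)
  if (sum((tip - ctr) * ax) > 0) ax <- -ax
  proj <- as.vector(cc %*% ax)
  ord <- order(proj)
  # equal counts +-1: distribute n over 4 groups
  sizes <- rep(n %/% 4, 4)
  extra <- n %% 4
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  grp <- rep(seq_len(4), times = sizes)
  assign_mat <- matrix(0L, nrow(roi_mask), ncol(roi_mask))
  assign_mat[px[ord, , drop = FALSE]] <- grp
  masks <- lapply(1:4, function(k) assign_mat == k)
  list(assignment = assign_mat, masks = masks,
       counts = vapply(masks, sum, numeric(1)))
}

#' Tip-to-center cargo delivery profile of one adhesion
#'
#' For each of the four sub-areas of an adhesion ROI, the mean cargo
#' intensity per frame is normalized to that area's intensity at a baseline
#' frame `baseline_offset_min` minutes before cargo appearance in the
#' adhesion. Appearance is the first frame at which the ROI cargo mean
#' exceeds `appear_mult` times the pre-release ROI mean.
#'
#' @param cargo_stack numeric array `rows x cols x frames`.
#' @param subdivision result of [subdivide_adhesion_roi()].
#' @param frame_interval minutes per frame.
#' @param release_frame frame of cargo release; frames before it define the
#'   pre-release baseline intensity.
#' @param appear_mult appearance threshold as a multiple of the pre-release
#'   ROI mean (default 1.5).
#' @param baseline_offset_min baseline offset before appearance (default
#'   2.5 min).
#' @return Data frame `frame`, `time_min`, `area1` .. `area4` (relative
#'   intensities; `NA` for an area whose baseline is not positive, flagged
#'   in attribute `flagged_areas`), with attributes `t_appear_frame` and
#'   `baseline_frame`.
#' @export
tip_to_center_profile <- function(cargo_stack, subdivision,
                                  frame_interval, release_frame,
                                  appear_mult = 1.5,
                                  baseline_offset_min = 2.5) {
  nfr <- dim(cargo_stack)[3]
  roi <- subdivision$assignment > 0
  roi_mean <- vapply(seq_len(nfr),
                     function(f) mean(cargo_stack[, , f][roi]), numeric(1))
  if (release_frame < 2) stop("release_frame must leave pre-release frames")
  pre <- mean(roi_mean[seq_len(release_frame - 1)])
  appear <- which(roi_mean > appear_mult * pre)
  appear <- appear[appear >= release_frame]
  # no crossing (e.g. constant cargo): fall back to the release frame as
  # the appearance reference
  appeared <- length(appear) > 0
  t_appear <- if (appeared) appear[1] else release_frame
  baseline_frame <- t_appear - round(baseline_offset_min / frame_interval)
  if (baseline_frame < 1)
    stop("baseline frame falls before the start of the movie")
  area_means <- sapply(1:4, function(k) {
    m <- subdivision$masks[[k]]
    vapply(seq_len(nfr), function(f) mean(cargo_stack[, , f][m]), numeric(1))
  })
  base <- area_means[baseline_frame, ]
  flagged <- which(!(base > 0))
  rel <- sweep(area_means, 2, base, `/`)
  rel[, flagged] <- NA_real_
  out <- data.frame(frame = seq_len(nfr),
                    time_min = (seq_len(nfr) - 1) * frame_interval,
                    area1 = rel[, 1], area2 = rel[, 2],
                    area3 = rel[, 3], area4 = rel[, 4])
  attr(out, "t_appear_frame") <- t_appear
  attr(out, "appeared") <- appeared
  attr(out, "baseline_frame") <- baseline_frame
  attr(out, "flagged_areas") <- flagged
  out
}

#' Link per-frame adhesion labels into tracks
#'
#' Nearest-centroid frame-to-frame linking with a maximum displacement gate.
#'
#' @param tables list of per-frame adhesion tables (one
#'   [segment_adhesions()] `table` per frame, in frame order).
#' @param frame_interval minutes per frame.
#' @param max_disp_px maximum centroid displacement between consecutive
#'   frames for a link (pixels).
#' @return Data frame with one row per track: `track_id`, `t_appear_frame`,
#'   `last_frame`, `lifetime_min`, `mean_area_um2`, and
#'   `edge_distance_um` (first-frame value, when available); per-frame
#'   links are attached as attribute `links` (`track_id`, `frame`,
#'   `label`, centroid columns).
#' @export
track_adhesions <- function(tables, frame_interval, max_disp_px = 5) {
  nfr <- length(tables)
  links <- list()
  active <- data.frame(track_id = integer(0), row = numeric(0),
                       col = numeric(0))
  next_id <- 1L
  for (f in seq_len(nfr)) {
    tab <- tables[[f]]
    assigned <- rep(NA_integer_, nrow(tab))
    if (nrow(tab) > 0 && nrow(active) > 0) {
      for (i in order(tab$area_um2, decreasing = TRUE)) {
        d <- sqrt((active$row - tab$centroid_row[i])^2 +
                    (active$col - tab$centroid_col[i])^2)
        j <- which.min(d)
        if (length(j) == 1 && d[j] <= max_disp_px) {
          assigned[i] <- active$track_id[j]
          active <- active[-j, , drop = FALSE]
        }
      }
    }
    new_active <- data.frame(track_id = integer(0), row = numeric(0),
                             col = numeric(0))
    for (i in seq_len(nrow(tab))) {
      id <- assigned[i]
      if (is.na(id)) { id <- next_id; next_id <- next_id + 1L }
      links[[length(links) + 1]] <- cbind(
        data.frame(track_id = id, frame = f), tab[i, , drop = FALSE])
      new_active <- rbind(new_active,
                          data.frame(track_id = id,
                                     row = tab$centroid_row[i],
                                     col = tab$centroid_col[i]))
    }
    active <- new_active
  }
  links <- if (length(links) > 0) do.call(rbind, links) else
    data.frame(track_id = integer(0), frame = integer(0))
  ids <- unique(links$track_id)
  summ <- do.call(rbind, lapply(ids, function(id) {
    li <- links[links$track_id == id, ]
    data.frame(track_id = id,
               t_appear_frame = min(li$frame),
               last_frame = max(li$frame),
               lifetime_min = (max(li$frame) - min(li$frame)) *
                 frame_interval,
               mean_area_um2 = mean(li$area_um2),
               edge_distance_um = if ("edge_distance_um" %in% names(li))
                 li$edge_distance_um[1] else NA_real_)
  }))
  if (is.null(summ))
    summ <- data.frame(track_id = integer(0), t_appear_frame = integer(0),
                       last_frame = integer(0), lifetime_min = numeric(0),
                       mean_area_um2 = numeric(0),
                       edge_distance_um = numeric(0))
  attr(summ, "links") <- links
  summ
}

#' Filter adhesion tracks by lifetime and cell-edge proximity
#'
#' Retains tracks with `lifetime_min >= min_lifetime_min` (>= semantics: a
#' track of exactly the minimum lifetime is kept) and, when an edge
#' distance is available, `edge_distance_um <= max_edge_distance_um`.
#'
#' @param tracks track summary data frame from [track_adhesions()].
#' @param min_lifetime_min minimum lifetime (default 15 min).
#' @param max_edge_distance_um maximum centroid distance to the cell edge
#'   (default 2 µm; `Inf` disables the edge criterion).
#' @return The filtered track data frame.
#' @export
filter_adhesion_tracks <- function(tracks, min_lifetime_min = 15,
                                   max_edge_distance_um = 2) {
  keep <- tracks$lifetime_min >= min_lifetime_min
  if ("edge_distance_um" %in% names(tracks)) {
    ed <- tracks$edge_distance_um
    keep <- keep & (is.na(ed) | ed <= max_edge_distance_um)
  }
  tracks[keep, , drop = FALSE]
}
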