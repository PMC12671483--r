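# Ratiometric exocytosis detection and the random-point spatial null.

#' Ratiometric stack: divide each frame by the previous
#'
#' Sudden fluorescence appearances (exocytic flashes) register as
#' high-ratio spots. A small offset `eps` is added to both numerator and
#' denominator to stabilize dark pixels.
#'
#' @param stack numeric array `rows x cols x frames` with at least 2
#'   frames.
#' @param eps stabilizing offset in intensity units (default 1, suited to
#'   16-bit-like integer data).
#' @return Array with `frames - 1` planes; plane `t` is
#'   `(frame[t+1] + eps) / (frame[t] + eps)`.
#' @export
ratiometric_stack <- function(stack, eps = 1) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 2)
    stop("need a stack with at least 2 frames")
  out <- array(0, dim = c(d[1], d[2], d[3] - 1))
  for (t in seq_len(d[3] - 1))
    out[, , t] <- (stack[, , t + 1] + eps) / (stack[, , t] + eps)
  out
}

#' Detect exocytosis events in a ratiometric stack
#'
#' Per ratio frame, pixels above `ratio_threshold` inside the cell mask are
#' labelled (8-connected); spots of at least `min_spot_px` pixels become
#' events at their intensity-weighted centroid. An event within
#' `merge_radius_px` of an event in the previous ratio frame is treated as
#' the decaying tail of the same exocytosis and merged away.
#'
#' @param ratio_stack array from [ratiometric_stack()].
#' @param cell_mask logical matrix restricting detection to the cell.
#' @param ratio_threshold ratio threshold, must be > 1 (default 2).
#' @param min_spot_px minimum spot size in pixels (default 2).
#' @param merge_radius_px merge radius against the previous frame
#'   (default 3).
#' @param frame_range optional `c(first, last)` ratio-frame window to
#'   restrict detection to (e.g. the pre-accumulation phase of a movie
#'   whose late frames carry trapped immobilized cargo); default: all
#'   ratio frames.
#' @return Data frame (`event_table`): `frame` (ratio-frame index, i.e. the
#'   event appears between movie frames `frame` and `frame + 1`), `row`,
#'   `col` (weighted centroid), `peak_ratio`, `n_pixels`.
#' @export
detect_events <- function(ratio_stack, cell_mask, ratio_threshold = 2,
                          min_spot_px = 2, merge_radius_px = 3,
                          frame_range = NULL) {
  if (ratio_threshold <= 1)
    stop("ratio_threshold must be > 1 (a constant movie has ratio 1)")
  d <- dim(ratio_stack)
  if (!all(dim(cell_mask) == d[1:2]))
    stop("cell mask and stack must share spatial dimensions")
  if (is.null(frame_range)) frame_range <- c(1L, d[3])
  events <- list()
  prev <- NULL
  for (t in seq(frame_range[1], min(frame_range[2], d[3]))) {
    fr <- ratio_stack[, , t]
    mask <- fr > ratio_threshold & cell_mask
    cur <- NULL
    spot_px <- NULL
    if (any(mask)) {
      lab <- label_components_cpp(mask, TRUE)
      counts <- tabulate(lab[lab > 0])
      keep <- which(counts >= min_spot_px)
      if (length(keep) > 0) {
        cur <- do.call(rbind, lapply(keep, function(k) {
          px <- which(lab == k, arr.ind = TRUE)
          w <- fr[px] - 1  # excess ratio as weight
          w <- pmax(w, 1e-9)
          data.frame(frame = t,
                     row = sum(px[, 1] * w) / sum(w),
                     col = sum(px[, 2] * w) / sum(w),
                     peak_ratio = max(fr[px]),
                     n_pixels = length(w))
        }))
        # pixels of accepted spots only: isolated noise pixels must not
        # suppress a genuine event in the next frame
        px <- which(matrix(lab %in% keep, d[1], d[2]), arr.ind = TRUE)
        spot_px <- data.frame(row = px[, 1], col = px[, 2])
        if (!is.null(prev) && nrow(prev) > 0) {
          dup <- vapply(seq_len(nrow(cur)), function(i) {
            any((prev$row - cur$row[i])^2 + (prev$col - cur$col[i])^2 <=
                  merge_radius_px^2)
          }, logical(1))
          cur <- cur[!dup, , drop = FALSE]
        }
      }
    }
    # carry spot pixels (merged or not) so chained decay stays suppressed
    prev <- spot_px
    if (!is.null(cur) && nrow(cur) > 0)
      events[[length(events) + 1]] <- cur
  }
  if (length(events) == 0)
    return(data.frame(frame = integer(0), row = numeric(0),
                      col = numeric(0), peak_ratio = numeric(0),
                      n_pixels = integer(0)))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Distance from each event to the nearest focal-adhesion pixel
#'
#' Uses the Euclidean distance transform of the FA mask; events inside an
#' adhesion get distance 0.
#'
#' @param events data frame with `row`, `col` (pixel coordinates, may be
#'   subpixel; they are rounded to the pixel grid for the lookup).
#' @param fa_mask logical matrix of segmented focal adhesions (nonempty).
#' @param pixel_size µm per pixel.
#' @return Numeric vector of distances in µm.
#' @export
nearest_fa_distances <- function(events, fa_mask, pixel_size) {
  if (!any(fa_mask)) stop("FA mask is empty")
  dm <- EBImage::distmap(matrix(as.numeric(!fa_mask),
                                nrow(fa_mask), ncol(fa_mask)))
  r <- pmin(pmax(round(events$row), 1), nrow(fa_mask))
  c_ <- pmin(pmax(round(events$col), 1), ncol(fa_mask))
  as.numeric(dm[cbind(r, c_)]) * pixel_size
}

#' Random points uniform over the cell mask
#'
#' The spatial null for the event-to-adhesion distance comparison.
#'
#' @param cell_mask nonempty logical matrix.
#' @param n number of points (>= 1).
#' @param seed integer seed; identical seeds give identical points.
#' @return Data frame `row`, `col` (pixel coordinates).
#' @export
random_null_points <- function(cell_mask, n, seed) {
  if (!any(cell_mask)) stop("cell mask is empty")
  if (n < 1) stop("n must be >= 1")
  px <- which(cell_mask, arr.ind = TRUE)
  with_seed_local(as.integer(seed), {
    j <- sample.int(nrow(px), n, replace = TRUE)
    data.frame(row = px[j, 1], col = px[j, 2])
  })
}

#' Compare event distances against the random null
#'
#' Two-sided unpaired comparison of nearest-adhesion distances of detected
#' events versus random points: Welch t test or a label-permutation test of
#' the mean difference.
#'
#' @param event_distances,null_distances numeric vectors (µm).
#' @param method `"t_test"` or `"permutation"`.
#' @param n_perm permutation count (default 2000).
#' @param seed seed for the permutation test.
#' @return A `distance_result` list: group distances, group means,
#'   `statistic` (t statistic or observed mean difference), `p_value`,
#'   `n_events`, `n_null`, `method`, `seed`.
#' @export
compare_distances <- function(event_distances, null_distances,
                              method = c("t_test", "permutation"),
                              n_perm = 2000L, seed = 1L) {
  method <- match.arg(method)
  if (length(event_distances) < 1 || length(null_distances) < 1)
    stop("both groups must be nonempty")
  if (method == "t_test" &&
      (length(event_distances) < 2 || length(null_distances) < 2))
    stop("the t test needs at least 2 observations per group")
  md <- mean(event_distances) - mean(null_distances)
  if (method == "t_test") {
    tt <- stats::t.test(event_distances, null_distances)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    pooled <- c(event_distances, null_distances)
    n1 <- length(event_distances)
    perm <- with_seed_local(as.integer(seed), {
      vapply(seq_len(n_perm), function(i) {
        j <- sample.int(length(pooled), n1)
        mean(pooled[j]) - mean(pooled[-j])
      }, numeric(1))
    })
    stat <- md
    p <- (1 + sum(abs(perm) >= abs(md))) / (n_perm + 1)
  }
  res <- list(event_distances = event_distances,
              null_distances = null_distances,
              mean_event = mean(event_distances),
              mean_null = mean(null_distances),
              mean_difference = md,
              statistic = stat, p_value = p,
              n_events = length(event_distances),
              n_null = length(null_distances),
              method = method, seed = as.integer(seed))
  class(res) <- "distance_result"
  res
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf(
    "Event-to-FA distances: events %.3g um (n=%d) vs null %.3g um (n=%d)\n",
    x$mean_event, x$n_events, x$mean_null, x$n_null))
  cat(sprintf("  %s: statistic %.3g, p = %.3g\n", x$method, x$statistic,
              x$p_value))
  invisible(x)
}
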