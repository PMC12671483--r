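# Protrusion/retraction dynamics, cargo polarity and micropattern
# enrichment.

#' Classify protruding, retracting and stable regions over time
#'
#' For each consecutive-frame interval, gained pixels (in the later mask
#' only) are protrusion, lost pixels (in the earlier mask only) are
#' retraction. Cumulative protruding/retracting regions are unions over the
#' whole sequence, the simplified equivalent of spatiotemporal track-map
#' ROIs.
#'
#' @param masks logical array `rows x cols x frames` (or list of logical
#'   matrices) of cell masks, at least 2 frames.
#' @return A `region_dynamics_map`: lists `gained` and `lost` (one logical
#'   matrix per interval), `stable` (intersection per interval), and
#'   `cumulative_protruding` / `cumulative_retracting` masks.
#' @export
edge_dynamics_map <- function(masks) {
  if (is.list(masks)) masks <- simplify2array(masks)
  d <- dim(masks)
  if (length(d) != 3 || d[3] < 2) stop("need at least 2 masks")
  n <- d[3]
  gained <- lost <- stable <- vector("list", n - 1)
  cum_p <- cum_r <- matrix(FALSE, d[1], d[2])
  for (f in 2:n) {
    a <- masks[, , f - 1]; b <- masks[, , f]
    if (!all(dim(a) == dim(b))) stop("mask shapes differ")
    gained[[f - 1]] <- b & !a
    lost[[f - 1]] <- a & !b
    stable[[f - 1]] <- a & b
    cum_p <- cum_p | gained[[f - 1]]
    cum_r <- cum_r | lost[[f - 1]]
  }
  out <- list(gained = gained, lost = lost, stable = stable,
              cumulative_protruding = cum_p,
              cumulative_retracting = cum_r)
  class(out) <- "region_dynamics_map"
  out
}

#' Relative cargo intensity in protruding vs retracting regions
#'
#' Mean cargo intensity inside the cumulative protruding and retracting
#' regions per frame, each normalized to its value at `t0` (reusing
#' [relative_recruitment()] semantics). An empty region yields `NA` values
#' flagged in the attribute `empty_regions`.
#'
#' @param cargo_stack numeric array `rows x cols x frames`.
#' @param dynamics a [edge_dynamics_map()] result.
#' @param t0 reference frame index.
#' @return Data frame `frame`, `protruding`, `retracting`.
#' @export
roi_intensity_dynamics <- function(cargo_stack, dynamics, t0 = 1L) {
  stopifnot(inherits(dynamics, "region_dynamics_map"))
  d <- dim(cargo_stack)
  nfr <- d[3]
  series <- function(mask) {
    if (!any(mask)) return(rep(NA_real_, nfr))
    raw <- vapply(seq_len(nfr),
                  function(f) mean(cargo_stack[, , f][mask]), numeric(1))
    relative_recruitment(raw, t0)
  }
  p <- series(dynamics$cumulative_protruding)
  r <- series(dynamics$cumulative_retracting)
  out <- data.frame(frame = seq_len(nfr), protruding = p, retracting = r)
  attr(out, "empty_regions") <-
    c(protruding = !any(dynamics$cumulative_protruding),
      retracting = !any(dynamics$cumulative_retracting))
  out
}

#' Length of the longest protrusion between two masks
#'
#' Maximum over newly gained pixels (`final` and not `initial`) of the
#' Euclidean distance to the initial mask, computed from the distance
#' transform of the initial mask complement; 0 when the final mask grew
#' nowhere.
#'
#' @param initial,final logical matrices of the same shape; `initial` must
#'   be nonempty.
#' @param pixel_size µm per pixel.
#' @return Longest protrusion length in µm.
#' @export
longest_protrusion_length <- function(initial, final, pixel_size) {
  if (!all(dim(initial) == dim(final))) stop("mask shapes differ")
  if (!any(initial)) stop("initial mask is empty")
  grown <- final & !initial
  if (!any(grown)) return(0)
  dm <- EBImage::distmap(matrix(as.numeric(!initial),
                                nrow(initial), ncol(initial)))
  max(dm[grown]) * pixel_size
}

#' Intensity line profile across a micropattern
#'
#' Bilinear-interpolated intensity at uniform steps along a line, each
#' position tagged as on- or off-pattern from the pattern mask.
#'
#' @param image numeric matrix.
#' @param line `c(r0, c0, r1, c1)` endpoints in pixel coordinates, inside
#'   the image.
#' @param pattern_mask logical matrix (pattern-positive pixels).
#' @param pixel_size µm per pixel.
#' @param step_px sampling step along the line in pixels (default 1).
#' @return A `profile_result` data frame: `position_um` (strictly
#'   increasing), `intensity`, `on_pattern`.
#' @export
pattern_line_profile <- function(image, line, pattern_mask, pixel_size,
                                 step_px = 1) {
  stopifnot(length(line) == 4)
  r0 <- line[1]; c0 <- line[2]; r1 <- line[3]; c1 <- line[4]
  len_px <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  if (len_px == 0) stop("zero-length sampling line")
  if (min(r0, r1) < 1 || max(r0, r1) > nrow(image) ||
      min(c0, c1) < 1 || max(c0, c1) > ncol(image))
    stop("line endpoints must lie inside the image")
  n <- floor(len_px / step_px) + 1
  tfrac <- (seq_len(n) - 1) * step_px / len_px
  rr <- r0 + tfrac * (r1 - r0)
  cc <- c0 + tfrac * (c1 - c0)
  bilinear <- function(img, r, c_) {
    r1i <- pmin(pmax(floor(r), 1), nrow(img) - 1)
    c1i <- pmin(pmax(floor(c_), 1), ncol(img) - 1)
    fr <- r - r1i; fc <- c_ - c1i
    img[cbind(r1i, c1i)] * (1 - fr) * (1 - fc) +
      img[cbind(r1i + 1, c1i)] * fr * (1 - fc) +
      img[cbind(r1i, c1i + 1)] * (1 - fr) * fc +
      img[cbind(r1i + 1, c1i + 1)] * fr * fc
  }
  out <- data.frame(
    position_um = tfrac * len_px * pixel_size,
    intensity = bilinear(image, rr, cc),
    on_pattern = pattern_mask[cbind(pmin(pmax(round(rr), 1), nrow(image)),
                                    pmin(pmax(round(cc), 1), ncol(image)))])
  class(out) <- c("profile_result", class(out))
  out
}

#' Cargo enrichment on pattern dots within the cell
#'
#' Mean cargo intensity on dot pixels inside the cell divided by the mean
#' on cell pixels outside the dots. Dots lying outside the cell are
#' excluded; an empty intersection is an error.
#'
#' @param cargo numeric matrix.
#' @param dot_mask,cell_mask logical matrices.
#' @return Enrichment ratio (dimensionless).
#' @export
dot_recruitment <- function(cargo, dot_mask, cell_mask) {
  on <- dot_mask & cell_mask
  off <- cell_mask & !dot_mask
  if (!any(on)) stop("no pattern dots inside the cell")
  if (!any(off)) stop("no off-dot cell pixels")
  mean(cargo[on]) / mean(cargo[off])
}
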