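# Scalar assay metrics: flow-cytometry-style surface delivery and
# immunoblot maturation ratios.

geomean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("geometric mean requires strictly positive finite samples")
  exp(mean(log(x)))  # log space for numerical stability
}

#' Surface delivery index over time points
#'
#' Per time point, the geometric mean of the surface signal is divided by
#' the geometric mean of the total signal, and the ratio at the reference
#' time point T0 is subtracted from every time point. The index is 0 at T0
#' by construction and invariant under common positive rescaling of all
#' signals.
#'
#' @param flow data frame with columns `time_point`, `surface`, `total`
#'   (per-cell samples, strictly positive).
#' @param t0 reference time point value (default: the smallest).
#' @return A `surface_delivery_series` data frame: `time_point`,
#'   `geomean_surface`, `geomean_total`, `ratio`, `index`.
#' @export
surface_delivery_index <- function(flow, t0 = NULL) {
  stopifnot(all(c("time_point", "surface", "total") %in% names(flow)))
  tps <- sort(unique(flow$time_point))
  if (is.null(t0)) t0 <- tps[1]
  if (!t0 %in% tps) stop("t0 is not among the time points")
  out <- do.call(rbind, lapply(tps, function(tp) {
    sub <- flow[flow$time_point == tp, ]
    gs <- geomean(sub$surface)
    gt <- geomean(sub$total)
    data.frame(time_point = tp, geomean_surface = gs,
               geomean_total = gt, ratio = gs / gt)
  }))
  out$index <- out$ratio - out$ratio[out$time_point == t0]
  class(out) <- c("surface_delivery_series", class(out))
  out
}

#' Mature/immature integrin maturation ratio from band intensities
#'
#' Upper (mature, fully glycosylated) band intensity divided by the lower
#' (immature, ER-resident) band intensity.
#'
#' @param upper,lower nonnegative band intensities (vectors of equal
#'   length); alternatively `upper` may be a data frame with columns
#'   `upper` and `lower`.
#' @return Numeric ratio(s); an error if any lower band is not positive.
#' @export
maturation_ratio <- function(upper, lower = NULL) {
  if (is.data.frame(upper)) {
    stopifnot(all(c("upper", "lower") %in% names(upper)))
    lower <- upper$lower
    upper <- upper$upper
  }
  if (any(upper < 0)) stop("band intensities must be >= 0")
  if (any(lower <= 0)) stop("lower (immature) band intensity must be > 0")
  upper / lower
}
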