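# Synthetic microscopy generator. Every generator is deterministic under its
# config seed and returns complete ground truth so downstream quantification
# can be tested without external movies.

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  expr
}

#' Configuration for synthetic time-lapse and TIRF movies
#'
#' Describes the scene the generator renders: a roughly circular cell whose
#' edge protrudes or retracts in angular sectors, elongated focal adhesions
#' that nucleate at a distal tip near the cell edge and grow inward, a
#' secretory-cargo schedule (ER texture until `release_frame`, a Golgi blob
#' for `golgi_residence` minutes, then either adhesion-targeted accumulation
#' in `"FN"` mode or diffuse membrane accumulation in `"collagen"` mode),
#' pHluorin-style exocytic flashes for TIRF movies, and a Poisson + Gaussian
#' camera noise model.
#'
#' @param image_shape image size in pixels, `c(rows, cols)`.
#' @param pixel_size µm per pixel.
#' @param frame_interval minutes between frames.
#' @param n_frames number of frames.
#' @param condition `"FN"` (adhesion-targeted surface accumulation) or
#'   `"collagen"` (diffuse membrane accumulation).
#' @param release_frame frame at which the cargo is released from the ER
#'   (the biotin-addition analog).
#' @param golgi_residence minutes the cargo spends in the Golgi after
#'   release (default 15).
#' @param cell_radius_um radius of the cell at frame 1.
#' @param protrusion_sectors list of sectors, each
#'   `list(angles = c(a1, a2), speed = v)` with angles in degrees and edge
#'   speed in µm/min (negative = retraction).
#' @param adhesion_spec list: `n` adhesions, `length_um`, `width_um`,
#'   `nucleation_frames` (recycled over adhesions), `growth_rate_um_min`
#'   (inward growth of the proximal end), `margin_um` (tip distance from
#'   the edge).
#' @param event_spec list for TIRF flashes: `n` events, `rho` (fraction
#'   placed within `radius_um` of an adhesion pixel), `amplitude`,
#'   `decay_frames` (exponential decay constant, frames), `radius_um`.
#' @param noise list: `gain` (camera photon gain; variance/mean of the
#'   Poisson stage), `read_sd` (Gaussian read noise SD, counts).
#' @param seed integer seed; identical seeds give bit-identical stacks.
#' @return A validated `movie_config` list.
#' @export
movie_config <- function(image_shape = c(160L, 160L),
                         pixel_size = 0.1,
                         frame_interval = 1,
                         n_frames = 30L,
                         condition = c("FN", "collagen"),
                         release_frame = 3L,
                         golgi_residence = 15,
                         cell_radius_um = 4.5,
                         protrusion_sectors = list(
                           list(angles = c(-50, 50), speed = 0.06),
                           list(angles = c(150, 210), speed = -0.03)),
                         adhesion_spec = list(n = 8L, length_um = 3,
                                              width_um = 0.75,
                                              nucleation_frames = c(1L, 1L, 1L, 4L, 6L, 8L, 10L, 19L),
                                              growth_rate_um_min = 0.2,
                                              margin_um = 0.3),
                         event_spec = list(n = 50L, rho = 0.8,
                                           amplitude = 120,
                                           decay_frames = 2,
                                           radius_um = 0.5),
                         noise = list(gain = 2, read_sd = 2),
                         seed = 1L) {
  condition <- match.arg(condition)
  cfg <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
              frame_interval = frame_interval, n_frames = as.integer(n_frames),
              condition = condition, release_frame = as.integer(release_frame),
              golgi_residence = golgi_residence,
              cell_radius_um = cell_radius_um,
              protrusion_sectors = protrusion_sectors,
              adhesion_spec = adhesion_spec, event_spec = event_spec,
              noise = noise, seed = as.integer(seed))
  if (cfg$pixel_size <= 0) stop("pixel_size must be > 0")
  if (cfg$n_frames < 2) stop("n_frames must be >= 2")
  if (cfg$release_frame >= cfg$n_frames)
    stop("release_frame must be < n_frames")
  if (!is.null(cfg$event_spec)) {
    rho <- cfg$event_spec$rho
    if (rho < 0 || rho > 1) stop("event_spec$rho must be in [0, 1]")
  }
  class(cfg) <- "movie_config"
  cfg
}

# --- geometry helpers ------------------------------------------------------

pixel_grid_um <- function(shape, pixel_size) {
  # pixel centers in µm; row 1 / col 1 center at 0.5 * pixel_size
  list(y = (seq_len(shape[1]) - 0.5) * pixel_size,
       x = (seq_len(shape[2]) - 0.5) * pixel_size)
}

# edge radius (µm) as a function of angle (deg) and time (min)
edge_radius_fun <- function(cfg) {
  sectors <- cfg$protrusion_sectors
  function(theta_deg, t_min) {
    r <- rep(cfg$cell_radius_um, length(theta_deg))
    th <- (theta_deg + 360) %% 360
    for (s in sectors) {
      a <- (s$angles + 360) %% 360
      inside <- if (a[1] <= a[2]) th >= a[1] & th <= a[2]
                else th >= a[1] | th <= a[2]
      r[inside] <- r[inside] + s$speed * t_min
    }
    pmax(r, 0.2)
  }
}

render_cell_mask <- function(cfg, t_min, center_um) {
  g <- pixel_grid_um(cfg$image_shape, cfg$pixel_size)
  dx <- outer(rep(1, cfg$image_shape[1]), g$x - center_um[2])
  dy <- outer(g$y - center_um[1], rep(1, cfg$image_shape[2]))
  rr <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx) * 180 / pi
  rfun <- edge_radius_fun(cfg)
  rr <= matrix(rfun(as.vector(th), t_min), nrow = cfg$image_shape[1])
}

# anisotropic Gaussian intensity kernel plus elliptical footprint of one
# adhesion; the long axis points radially (tip distal, body inward)
adhesion_render <- function(cfg, tip_um, inward_unit, length_um, width_um) {
  g <- pixel_grid_um(cfg$image_shape, cfg$pixel_size)
  dx <- outer(rep(1, cfg$image_shape[1]), g$x) -
    (tip_um[2] + inward_unit[2] * length_um / 2)
  dy <- outer(g$y, rep(1, cfg$image_shape[2])) -
    (tip_um[1] + inward_unit[1] * length_um / 2)
  d_long <- dy * inward_unit[1] + dx * inward_unit[2]
  d_perp <- -dy * inward_unit[2] + dx * inward_unit[1]
  s_long <- length_um / 4
  s_perp <- width_um / 4
  kern <- exp(-d_long^2 / (2 * s_long^2) - d_perp^2 / (2 * s_perp^2))
  foot <- (d_long / (length_um / 2))^2 + (d_perp / (width_um / 2))^2 <= 1
  list(kernel = kern, footprint = foot)
}

build_adhesions <- function(cfg, center_um) {
  sp <- cfg$adhesion_spec
  n <- sp$n
  rfun <- edge_radius_fun(cfg)
  # evenly spaced angles with a small seeded jitter, avoiding overlap
  ang <- (seq_len(n) - 1) * 360 / n + stats::runif(n, -8, 8)
  nuc <- rep_len(sp$nucleation_frames, n)
  t_last <- (cfg$n_frames - 1) * cfg$frame_interval
  lapply(seq_len(n), function(i) {
    t0 <- (nuc[i] - 1) * cfg$frame_interval
    a <- ang[i] * pi / 180
    u_out <- c(sin(a), cos(a))        # (row, col) direction outward
    # tip placed so the adhesion stays inside the cell for its whole life
    # (in retracting sectors the edge moves inward over time)
    tip_r <- min(rfun(ang[i], t0), rfun(ang[i], t_last)) - sp$margin_um
    tip <- center_um + u_out * tip_r
    list(id = i, angle = ang[i], nucleation_frame = nuc[i],
         tip_um = tip, inward = -u_out)
  })
}

adhesion_length_at <- function(cfg, adh, frame) {
  sp <- cfg$adhesion_spec
  if (frame < adh$nucleation_frame) return(0)
  dt_min <- (frame - adh$nucleation_frame) * cfg$frame_interval
  min(sp$length_um, sp$width_um + sp$growth_rate_um_min * dt_min)
}

#' Add Poisson photon noise and Gaussian read noise to an image
#'
#' The Poisson stage acts on photons (`counts / gain`), so on a flat patch
#' the variance/mean ratio of the output (before read noise) equals the
#' gain. Output is a nonnegative integer matrix/array.
#'
#' @param img nonnegative numeric matrix or array of expected counts.
#' @param gain camera photon gain (counts per photon).
#' @param read_sd read-noise standard deviation (counts); 0 disables.
#' @return Integer array of noisy counts, same shape as `img`.
#' @export
apply_camera_noise <- function(img, gain = 2, read_sd = 2) {
  if (gain <= 0) stop("gain must be > 0")
  photons <- stats::rpois(length(img), lambda = as.vector(img) / gain)
  counts <- gain * photons
  if (read_sd > 0) counts <- counts + stats::rnorm(length(img), 0, read_sd)
  out <- pmax(0, round(counts))
  storage.mode(out) <- "integer"
  array(out, dim = if (is.null(dim(img))) length(img) else dim(img))
}

new_synthetic_movie <- function(channels, cfg) {
  m <- list(channels = channels,
            pixel_size = cfg$pixel_size,
            frame_interval = cfg$frame_interval,
            condition = cfg$condition,
            seed = cfg$seed)
  class(m) <- "synthetic_movie"
  m
}

#' Generate a two-channel secretory-cargo time lapse with ground truth
#'
#' Channel `marker` renders elongated focal adhesions near the cell edge
#' (nucleating at their distal tip, growing inward); channel `cargo`
#' follows the trafficking schedule: perinuclear ER texture before
#' `release_frame`, a Golgi blob for `golgi_residence` minutes after
#' release, then adhesion-colocalized accumulation (`"FN"`) or uniform
#' membrane accumulation (`"collagen"`). Poisson photon noise and Gaussian
#' read noise are applied last.
#'
#' @param config a [movie_config()].
#' @return A list with elements `movie` (a `synthetic_movie`: channel
#'   arrays `rows x cols x frames`) and `truth` (cell masks, per-frame
#'   adhesion label masks, per-adhesion records with nucleation frame,
#'   lifetime, centroid path and distal-tip pixel, per-interval
#'   gained/lost masks, and the cargo intensity schedule).
#' @export
generate_timelapse <- function(config) {
  stopifnot(inherits(config, "movie_config"))
  cfg <- config
  with_seed_local(cfg$seed, {
    shp <- cfg$image_shape
    center <- c(shp[1], shp[2]) / 2 * cfg$pixel_size
    adhs <- build_adhesions(cfg, center)
    nfr <- cfg$n_frames

    marker <- array(0, dim = c(shp, nfr))
    cargo <- array(0, dim = c(shp, nfr))
    labels <- array(0L, dim = c(shp, nfr))
    cmasks <- array(FALSE, dim = c(shp, nfr))

    # cargo schedule amplitudes per frame (one row per frame)
    sched <- data.frame(frame = seq_len(nfr), er = 0, golgi = 0,
                        surface_adhesion = 0, surface_diffuse = 0)
    golgi_frames <- cfg$golgi_residence / cfg$frame_interval
    for (f in seq_len(nfr)) {
      since_rel <- f - cfg$release_frame
      if (since_rel < 0) {
        sched$er[f] <- 200
      } else if (since_rel < golgi_frames) {
        frac <- since_rel / golgi_frames
        sched$er[f] <- 200 * (1 - frac)
        sched$golgi[f] <- 350 * sin(pi * min(1, frac + 0.15))
      } else {
        ramp <- min(1, (since_rel - golgi_frames + 1) /
                      max(1, (nfr - cfg$release_frame - golgi_frames)))
        sched$er[f] <- 20
        sched$golgi[f] <- 60 * max(0, 1 - ramp * 2)
        if (cfg$condition == "FN") {
          sched$surface_adhesion[f] <- 500 * ramp
          sched$surface_diffuse[f] <- 25 * ramp
        } else {
          sched$surface_diffuse[f] <- 200 * ramp
        }
      }
    }

    # static textures (seeded once so frames differ only through schedule)
    g <- pixel_grid_um(shp, cfg$pixel_size)
    dx <- outer(rep(1, shp[1]), g$x - center[2])
    dy <- outer(g$y - center[1], rep(1, shp[2]))
    rr <- sqrt(dx^2 + dy^2)
    er_tex <- (rr > 0.5 & rr < max(1.1, 0.25 * cfg$cell_radius_um)) *
      (0.7 + 0.3 * matrix(stats::runif(prod(shp)), shp[1], shp[2]))
    golgi_center <- center + c(0.4, 0.7)
    golgi_tex <- exp(-((dy - 0.4)^2 + (dx - 0.7)^2) / (2 * 0.6^2))

    adh_table <- list()
    for (f in seq_len(nfr)) {
      t_min <- (f - 1) * cfg$frame_interval
      cm <- render_cell_mask(cfg, t_min, center)
      cmasks[, , f] <- cm
      mk <- matrix(20, shp[1], shp[2])  # marker background
      mk[cm] <- 40
      lab <- matrix(0L, shp[1], shp[2])
      adh_sig <- matrix(0, shp[1], shp[2])
      for (a in adhs) {
        L <- adhesion_length_at(cfg, a, f)
        if (L <= 0) next
        rend <- adhesion_render(cfg, a$tip_um, a$inward, L,
                                cfg$adhesion_spec$width_um)
        mk <- mk + 700 * rend$kernel
        adh_sig <- pmax(adh_sig, rend$kernel)
        lab[rend$footprint] <- a$id
        px <- which(rend$footprint, arr.ind = TRUE)
        ctr <- colMeans(px)
        # distal tip recorded as the footprint pixel nearest the geometric tip
        tip_rc <- a$tip_um / cfg$pixel_size + 0.5
        tip_px <- px[which.min((px[, 1] - tip_rc[1])^2 +
                                 (px[, 2] - tip_rc[2])^2), ]
        adh_table[[length(adh_table) + 1]] <- data.frame(
          label = a$id, frame = f,
          centroid_row = ctr[1], centroid_col = ctr[2],
          tip_row = tip_px[1], tip_col = tip_px[2],
          length_um = L, n_pixels = nrow(px))
      }
      labels[, , f] <- lab
      marker[, , f] <- mk

      cg <- matrix(20, shp[1], shp[2])
      cg <- cg + sched$er[f] * er_tex +
        sched$golgi[f] * golgi_tex +
        sched$surface_adhesion[f] * adh_sig
      cg[cm] <- cg[cm] + sched$surface_diffuse[f]
      cg[!cm] <- 10
      cargo[, , f] <- cg
    }

    marker <- apply_camera_noise(marker, cfg$noise$gain, cfg$noise$read_sd)
    cargo <- apply_camera_noise(cargo, cfg$noise$gain, cfg$noise$read_sd)

    adh_df <- do.call(rbind, adh_table)
    per_adh <- data.frame(
      label = vapply(adhs, `[[`, 0, "id"),
      t_appear_frame = vapply(adhs, `[[`, 0L, "nucleation_frame"))
    per_adh$lifetime_min <- (nfr - per_adh$t_appear_frame) * cfg$frame_interval

    gained <- lost <- vector("list", nfr - 1)
    for (f in 2:nfr) {
      gained[[f - 1]] <- cmasks[, , f] & !cmasks[, , f - 1]
      lost[[f - 1]] <- cmasks[, , f - 1] & !cmasks[, , f]
    }

    truth <- list(adhesions = adh_df, adhesion_summary = per_adh,
                  adhesion_labels = labels, cell_masks = cmasks,
                  gained = gained, lost = lost, cargo_schedule = sched,
                  center_um = center)
    list(movie = new_synthetic_movie(list(marker = marker, cargo = cargo),
                                     cfg),
         truth = truth)
  })
}

#' Generate a TIRF-style exocytosis flash movie with ground truth
#'
#' A dim membrane background carries an accumulating adhesion footprint
#' signal (the immobilized-cargo analog that makes the last frame
#' segmentable into focal adhesions) plus instantaneous Gaussian flashes.
#' A fraction `rho` of events is placed within `radius_um` of an adhesion
#' pixel, the rest uniformly over the cell mask; flash amplitude decays
#' exponentially with constant `decay_frames` after appearance.
#'
#' @param config a [movie_config()] with an `event_spec`.
#' @return List with `movie` (single channel `tirf`) and `truth`
#'   (`events` table with appearance frame, subpixel position, amplitude
#'   and `fa_biased` flag; static `cell_mask`; `fa_mask` of adhesion
#'   footprints).
#' @export
generate_tirf_movie <- function(config) {
  stopifnot(inherits(config, "movie_config"))
  cfg <- config
  es <- cfg$event_spec
  if (is.null(es)) stop("config must contain an event_spec")
  if (es$rho < 0 || es$rho > 1) stop("event_spec$rho must be in [0, 1]")
  with_seed_local(cfg$seed, {
    shp <- cfg$image_shape
    center <- c(shp[1], shp[2]) / 2 * cfg$pixel_size
    cm <- render_cell_mask(cfg, 0, center)

    adhs <- build_adhesions(cfg, center)
    fa_kernel <- matrix(0, shp[1], shp[2])
    fa_mask <- matrix(FALSE, shp[1], shp[2])
    for (a in adhs) {
      rend <- adhesion_render(cfg, a$tip_um, a$inward,
                              cfg$adhesion_spec$length_um,
                              cfg$adhesion_spec$width_um)
      fa_kernel <- pmax(fa_kernel, rend$kernel)
      fa_mask <- fa_mask | rend$footprint
    }
    fa_px <- which(fa_mask, arr.ind = TRUE)
    cell_px <- which(cm, arr.ind = TRUE)

    n <- es$n
    fa_biased <- stats::runif(n) < es$rho
    rows <- cols <- numeric(n)
    frames <- integer(n)
    rad_px <- es$radius_um / cfg$pixel_size
    min_sep_px <- 6
    min_sep_fr <- 3
    for (i in seq_len(n)) {
      for (try in 1:200) {
        f <- sample(3:(cfg$n_frames - 3L), 1)
        if (fa_biased[i]) {
          j <- sample(nrow(fa_px), 1)
          off_r <- stats::runif(1, 0, rad_px)
          off_a <- stats::runif(1, 0, 2 * pi)
          r <- fa_px[j, 1] + off_r * cos(off_a)
          c_ <- fa_px[j, 2] + off_r * sin(off_a)
          ri <- min(max(round(r), 1), shp[1])
          ci <- min(max(round(c_), 1), shp[2])
          if (!cm[ri, ci]) next
        } else {
          j <- sample(nrow(cell_px), 1)
          r <- cell_px[j, 1] + stats::runif(1, -0.5, 0.5)
          c_ <- cell_px[j, 2] + stats::runif(1, -0.5, 0.5)
        }
        if (i > 1) {
          d2 <- (rows[1:(i - 1)] - r)^2 + (cols[1:(i - 1)] - c_)^2
          clash <- d2 < min_sep_px^2 & abs(frames[1:(i - 1)] - f) < min_sep_fr
          if (any(clash)) next
        }
        rows[i] <- r; cols[i] <- c_; frames[i] <- f
        break
      }
      if (frames[i] == 0L) {  # fallback: accept last draw
        rows[i] <- r; cols[i] <- c_; frames[i] <- f
      }
    }

    stack <- array(0, dim = c(shp, cfg$n_frames))
    gy <- seq_len(shp[1]); gx <- seq_len(shp[2])
    sigma <- 1.2
    for (f in seq_len(cfg$n_frames)) {
      img <- matrix(20, shp[1], shp[2])
      img[cm] <- 80
      # trapped cargo marks adhesions only at the end of the movie, after
      # the event window, so the last frame is segmentable into FAs
      fa_frac <- if (f >= cfg$n_frames - 1L)
        (f - cfg$n_frames + 2L) / 2 else 0
      img <- img + 300 * fa_kernel * fa_frac
      live <- which(frames <= f & frames > f - 6 * es$decay_frames)
      for (i in live) {
        amp <- es$amplitude * exp(-(f - frames[i]) / es$decay_frames)
        win_r <- max(1, round(rows[i]) - 5):min(shp[1], round(rows[i]) + 5)
        win_c <- max(1, round(cols[i]) - 5):min(shp[2], round(cols[i]) + 5)
        kern <- outer(exp(-(gy[win_r] - rows[i])^2 / (2 * sigma^2)),
                      exp(-(gx[win_c] - cols[i])^2 / (2 * sigma^2)))
        img[win_r, win_c] <- img[win_r, win_c] + amp * kern
      }
      stack[, , f] <- img
    }
    stack <- apply_camera_noise(stack, cfg$noise$gain, cfg$noise$read_sd)

    events <- data.frame(frame = frames, row = rows, col = cols,
                         amplitude = rep_len(es$amplitude, n),
                         fa_biased = fa_biased)
    truth <- list(events = events, cell_mask = cm, fa_mask = fa_mask,
                  fa_kernel = fa_kernel)
    list(movie = new_synthetic_movie(list(tirf = stack), cfg),
         truth = truth)
  })
}

#' Generate a micropattern scene (lines, dual-ligand lines, or dots)
#'
#' Pattern masks are exact geometric rasterizations at pixel-center
#' precision; the cargo image is enriched on pattern-positive pixels inside
#' the cell by a stated multiplier.
#'
#' @param kind `"lines"`, `"dual_lines"` (alternating ligand stripes) or
#'   `"dots"`.
#' @param geometry list; relevant entries with defaults:
#'   `shape = c(200, 200)` px, `pixel_size = 0.1` µm/px,
#'   `line_width_um = 9`, `period_um = 2 * line_width_um`,
#'   `dot_radius_um = 1`, `dot_spacing_um = 4`, `cell_radius_um = 8`,
#'   `enrichment = 3`, `base_intensity = 100`, `noise_sd = 2`.
#' @param seed integer seed for the cargo noise.
#' @return List with `pattern_mask`, `second_mask` (dual lines only, else
#'   `NULL`), `cell_mask`, `cargo` image, `pixel_size`, `kind`.
#' @export
generate_micropattern_scene <- function(kind = c("lines", "dual_lines", "dots"),
                                        geometry = list(), seed = 1L) {
  kind <- match.arg(kind)
  geo <- utils::modifyList(list(shape = c(200L, 200L), pixel_size = 0.1,
                                line_width_um = 9, period_um = NULL,
                                dot_radius_um = 1, dot_spacing_um = 4,
                                cell_radius_um = 8, enrichment = 3,
                                base_intensity = 100, noise_sd = 2),
                           geometry)
  if (is.null(geo$period_um)) geo$period_um <- 2 * geo$line_width_um
  if (kind %in% c("lines", "dual_lines") && geo$line_width_um <= 0)
    stop("degenerate geometry: line width must be > 0")
  if (kind == "dots" && geo$dot_radius_um <= 0)
    stop("degenerate geometry: dot radius must be > 0")
  shp <- as.integer(geo$shape)
  ps <- geo$pixel_size
  x <- (seq_len(shp[2]) - 0.5) * ps
  y <- (seq_len(shp[1]) - 0.5) * ps

  second <- NULL
  if (kind %in% c("lines", "dual_lines")) {
    on_col <- (x %% geo$period_um) < geo$line_width_um
    pattern <- matrix(rep(on_col, each = shp[1]), shp[1], shp[2])
    if (kind == "dual_lines") second <- !pattern
  } else {
    pattern <- matrix(FALSE, shp[1], shp[2])
    centers <- expand.grid(
      cy = seq(geo$dot_spacing_um / 2, max(y), by = geo$dot_spacing_um),
      cx = seq(geo$dot_spacing_um / 2, max(x), by = geo$dot_spacing_um))
    for (k in seq_len(nrow(centers))) {
      dd <- outer((y - centers$cy[k])^2, (x - centers$cx[k])^2, `+`)
      pattern <- pattern | (dd <= geo$dot_radius_um^2)
    }
  }
  ctr <- c(mean(range(y)), mean(range(x)))
  cell <- outer((y - ctr[1])^2, (x - ctr[2])^2, `+`) <= geo$cell_radius_um^2

  with_seed_local(seed, {
    cargo <- matrix(5, shp[1], shp[2])
    cargo[cell] <- geo$base_intensity
    cargo[cell & pattern] <- geo$base_intensity * geo$enrichment
    if (geo$noise_sd > 0)
      cargo <- matrix(pmax(0, cargo +
                             stats::rnorm(prod(shp), 0, geo$noise_sd)),
                      shp[1], shp[2])
    list(pattern_mask = pattern, second_mask = second, cell_mask = cell,
         cargo = cargo, pixel_size = ps, kind = kind)
  })
}

#' Generate scalar assay fixtures (flow-cytometry and band-pair tables)
#'
#' Per-cell surface and total signals are log-normal with per-time-point
#' location parameters describing a true delivery schedule; band pairs are
#' generated at stated mature/immature ratios.
#'
#' @param spec list; entries with defaults: `time_points = c(0, 15, 30, 60)`
#'   (min), `n_cells = 200` per time point,
#'   `surface_meanlog` (one per time point, default a rising schedule),
#'   `total_meanlog` (default constant), `sdlog = 0.25`
#'   (`sdlog = 0` gives degenerate, exact log-normals; negative errors),
#'   `band_ratios = c(0.5, 1, 2)`, `band_lower_mean = 1000`,
#'   `band_noise_cv = 0.05`.
#' @param seed integer seed.
#' @return List with `flow` (data frame `cell_id`, `time_point`, `surface`,
#'   `total`), `bands` (data frame `lane`, `upper`, `lower`, `true_ratio`)
#'   and the resolved `spec`.
#' @export
generate_scalar_fixtures <- function(spec = list(), seed = 1L) {
  sp <- utils::modifyList(list(time_points = c(0, 15, 30, 60),
                               n_cells = 200L,
                               surface_meanlog = NULL,
                               total_meanlog = NULL,
                               sdlog = 0.25,
                               band_ratios = c(0.5, 1, 2),
                               band_lower_mean = 1000,
                               band_noise_cv = 0.05), spec)
  ntp <- length(sp$time_points)
  if (is.null(sp$surface_meanlog))
    sp$surface_meanlog <- log(50) + 0.8 * seq(0, 1, length.out = ntp)
  if (is.null(sp$total_meanlog))
    sp$total_meanlog <- rep(log(500), ntp)
  if (sp$sdlog < 0) stop("sdlog (log-normal scale) must be >= 0")
  if (sp$band_lower_mean <= 0) stop("band_lower_mean must be > 0")
  with_seed_local(seed, {
    flow <- do.call(rbind, lapply(seq_len(ntp), function(i) {
      data.frame(cell_id = seq_len(sp$n_cells),
                 time_point = sp$time_points[i],
                 surface = stats::rlnorm(sp$n_cells,
                                         sp$surface_meanlog[i], sp$sdlog),
                 total = stats::rlnorm(sp$n_cells,
                                       sp$total_meanlog[i], sp$sdlog))
    }))
    nb <- length(sp$band_ratios)
    lower <- sp$band_lower_mean *
      (1 + stats::rnorm(nb, 0, sp$band_noise_cv))
    bands <- data.frame(lane = seq_len(nb),
                        upper = lower * sp$band_ratios,
                        lower = lower,
                        true_ratio = sp$band_ratios)
    list(flow = flow, bands = bands, spec = sp)
  })
}
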