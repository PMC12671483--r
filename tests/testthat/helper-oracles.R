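# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# BFS flood-fill connected-component count (8-connected)
flood_fill_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  count
}

# event-driven two-state (free/bound) Gillespie simulation; returns the
# fraction of total time spent bound
gillespie_bound_fraction <- function(k_on, k_off, t_total, seed) {
  set.seed(seed)
  t <- 0; bound <- FALSE; t_bound <- 0
  while (t < t_total) {
    rate <- if (bound) k_off else k_on
    dt <- stats::rexp(1, rate)
    dt <- min(dt, t_total - t)
    if (bound) t_bound <- t_bound + dt
    t <- t + dt
    bound <- !bound
  }
  t_bound / t_total
}

# mean occupancy of the package's fixed-timestep engine on a single site
# with force switched off (n_motors = 0)
engine_bound_fraction <- function(k_on_times_d, k_off0, n_steps, dt, seed) {
  # realize k_off(0) = k_off0 through the catch term alone
  p <- suppressWarnings(clutch_params(
    n_motors = 0, n_sites = 1, k_on = k_on_times_d, d_int0 = 1, d_add = 0,
    koff_catch_rate = k_off0, koff_slip_rate = 0,
    kunfold_0 = 0, kfold_0 = 0, dt = dt,
    t_end = n_steps * dt, record_every = dt, seed = seed))
  tr <- simulate_adhesion_growth(p)
  mean(tr$bound_fraction[-1])
}

# brute-force nearest distance from points to mask pixels (µm)
brute_nearest_distance <- function(points, mask, pixel_size) {
  px <- which(mask, arr.ind = TRUE)
  vapply(seq_len(nrow(points)), function(i) {
    min(sqrt((px[, 1] - round(points$row[i]))^2 +
               (px[, 2] - round(points$col[i]))^2)) * pixel_size
  }, numeric(1))
}

# match detected events to ground truth within a space/time gate and return
# recall and precision
match_events <- function(detected, truth, max_px = 3, max_frame = 1) {
  used <- logical(nrow(detected)); matched <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((detected$row - truth$row[i])^2 +
                (detected$col - truth$col[i])^2)
    # truth frame f (movie indexing) appears in ratio frame f - 1
    ok <- which(d <= max_px &
                  abs(detected$frame - (truth$frame[i] - 1)) <= max_frame &
                  !used)
    if (length(ok) > 0) { matched[i] <- TRUE; used[ok[1]] <- TRUE }
  }
  c(recall = mean(matched),
    precision = if (nrow(detected) > 0) sum(used) / nrow(detected) else NA)
}

# default TIRF pipeline: generate, detect in the pre-accumulation window,
# measure nearest-FA distances of events and a size-matched random null
run_exo_pipeline <- function(seed, rho, null_seed_offset = 5000L) {
  cfg <- movie_config(seed = seed)
  cfg$event_spec$rho <- rho
  tv <- generate_tirf_movie(cfg)
  rs <- ratiometric_stack(tv$movie$channels$tirf)
  ev <- detect_events(rs, tv$truth$cell_mask,
                      frame_range = c(1, cfg$n_frames - 3))
  seg <- segment_adhesions(
    tv$movie$channels$tirf[, , cfg$n_frames], cfg$pixel_size)
  fa_mask <- seg$labels > 0
  d_ev <- nearest_fa_distances(ev, fa_mask, cfg$pixel_size)
  np <- random_null_points(tv$truth$cell_mask, nrow(ev),
                           seed = seed + null_seed_offset)
  d_null <- nearest_fa_distances(np, fa_mask, cfg$pixel_size)
  list(truth = tv$truth, events = ev, d_event = d_ev, d_null = d_null)
}
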