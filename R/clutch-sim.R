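#' Initial state of the clutch ensemble
#'
#' All sites start unbound with folded talin, at the initial integrin
#' density.
#'
#' @param params a [clutch_params()] object.
#' @return A `clutch_state` list: `time` (s), per-site `bound`, `extension`
#'   (nm) and `talin_unfolded` vectors, `d_int_current` (integrins/µm²),
#'   `retrograde_speed` (nm/s) and `cumulative_unfolding_events`.
#' @export
clutch_state <- function(params) {
  stopifnot(inherits(params, "clutch_params"))
  s <- list(time = 0,
            bound = rep(FALSE, params$n_sites),
            extension = rep(0, params$n_sites),
            talin_unfolded = rep(FALSE, params$n_sites),
            d_int_current = params$d_int0,
            retrograde_speed = if (params$n_motors > 0) params$unloaded_speed_v else 0,
            cumulative_unfolding_events = 0)
  class(s) <- "clutch_state"
  s
}

run_clutch_cpp <- function(state, params, n_steps, record_every_steps) {
  clutch_run_cpp(n_steps, record_every_steps, params$dt, state$time,
                 params$n_motors, params$stall_force,
                 params$unloaded_speed_v,
                 params$clutch_stiffness, params$substrate_stiffness,
                 params$k_on,
                 params$koff_catch_rate, params$koff_catch_force,
                 params$koff_slip_rate, params$koff_slip_force,
                 params$kunfold_0, params$kunfold_force, params$kfold_0,
                 params$d_int0, params$d_add, params$cap_factor,
                 state$extension, state$bound, state$talin_unfolded,
                 state$d_int_current)
}

cpp_result_to_state <- function(res, state) {
  out <- list(time = res$time,
              bound = res$bound,
              extension = res$extension,
              talin_unfolded = res$talin_unfolded,
              d_int_current = res$d_int_current,
              retrograde_speed = res$retrograde_speed,
              cumulative_unfolding_events =
                state$cumulative_unfolding_events +
                res$cumulative_unfolding_events)
  class(out) <- "clutch_state"
  out
}

#' Advance the clutch ensemble by one (or more) fixed time steps
#'
#' One update consists of: (1) retrograde speed from the linear motor
#' force-velocity relation, (2) loading of bound clutches through the
#' clutch/substrate series spring, (3) binding of free sites with
#' probability `1 - exp(-k_on * d_int * dt)`, (4) force-dependent unbinding
#' (catch-slip), (5) force-dependent talin unfolding and force-independent
#' refolding, (6) one reinforcement ([apply_reinforcement()] semantics) per
#' unfolding event. Transition probabilities use the exponential form, which
#' is bounded for arbitrarily large transient rates. Randomness comes from
#' R's RNG stream, so wrap calls in `set.seed()` for reproducibility.
#'
#' @param state a `clutch_state` as returned by [clutch_state()] or a
#'   previous call.
#' @param params a [clutch_params()] object.
#' @param n_steps number of `dt` steps to take (default 1).
#' @return The updated `clutch_state`.
#' @export
step_ensemble <- function(state, params, n_steps = 1L) {
  stopifnot(inherits(state, "clutch_state"),
            inherits(params, "clutch_params"))
  if (length(state$bound) != params$n_sites)
    stop("state and params disagree on n_sites")
  res <- run_clutch_cpp(state, params, as.integer(n_steps),
                        record_every_steps = 0L)
  cpp_result_to_state(res, state)
}

#' Apply one adhesion reinforcement event
#'
#' Called once per talin unfolding event: raises the integrin density by
#' `d_add`, capped at `cap_factor * d_int0`. The density never decreases
#' (the model describes adhesion growth only).
#'
#' @inheritParams step_ensemble
#' @return The state with updated `d_int_current`.
#' @export
apply_reinforcement <- function(state, params) {
  stopifnot(inherits(state, "clutch_state"),
            inherits(params, "clutch_params"))
  state$d_int_current <- min(state$d_int_current + params$d_add,
                             params$cap_factor * params$d_int0)
  state
}

#' Simulate adhesion growth driven by integrin availability
#'
#' Runs the clutch ensemble from `t = 0` to `t_end` and records the integrin
#' density normalized to its starting value on the `record_every` output
#' grid. Under reinforcement the normalized density starts at exactly 1, is
#' nondecreasing, and saturates at `cap_factor`. The run is fully
#' deterministic given `params$seed`.
#'
#' @param params a [clutch_params()] object.
#' @return A `growth_trace`: list with `times` (s), `normalized_density`,
#'   `unfolding_event_times` (s), `bound_fraction` (occupancy on the
#'   output grid), and `seed`.
#' @examples
#' tr <- simulate_adhesion_growth(clutch_params(t_end = 120, seed = 7))
#' max(tr$normalized_density)
#' @export
simulate_adhesion_growth <- function(params) {
  stopifnot(inherits(params, "clutch_params"))
  validate_clutch_params(params, strict = TRUE, warn = FALSE)
  rec_steps <- max(1L, as.integer(round(params$record_every / params$dt)))
  n_steps <- as.integer(round(params$t_end / params$dt))
  st <- clutch_state(params)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(params$seed)
  out <- run_clutch_cpp(st, params, n_steps, rec_steps)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  tr <- list(times = c(0, out$rec_time),
             normalized_density = c(1, out$rec_density),
             unfolding_event_times = out$unfold_times,
             bound_fraction = c(0, out$rec_bound) / params$n_sites,
             seed = params$seed)
  class(tr) <- "growth_trace"
  tr
}

#' Simulate growth traces over several seeds
#'
#' Child seeds are derived from `params$seed` by fixed unit increments.
#'
#' @param params a [clutch_params()] object.
#' @param n_seeds number of independent traces.
#' @return A list of `growth_trace` objects.
#' @export
simulate_adhesion_growth_multi <- function(params, n_seeds = 50L) {
  lapply(seq_len(n_seeds) - 1L, function(k) {
    p <- params
    p$seed <- params$seed + k
    simulate_adhesion_growth(p)
  })
}

#' Summarize a collection of growth traces
#'
#' @param traces a list of `growth_trace` objects sharing one output grid.
#' @param threshold optional normalized-density threshold; if given, the
#'   first crossing time per trace is reported (`NA` when never reached).
#' @return A data frame with `time_s`, `mean`, `sd`; when `threshold` is
#'   given, the per-trace crossing times are attached as attribute
#'   `time_to_threshold`.
#' @export
summarize_traces <- function(traces, threshold = NULL) {
  stopifnot(length(traces) >= 1)
  grids <- lapply(traces, `[[`, "times")
  for (g in grids[-1])
    if (length(g) != length(grids[[1]]) || any(g != grids[[1]]))
      stop("traces do not share a common output time grid")
  m <- do.call(cbind, lapply(traces, `[[`, "normalized_density"))
  out <- data.frame(time_s = grids[[1]],
                    mean = rowMeans(m),
                    sd = apply(m, 1, stats::sd))
  if (!is.null(threshold)) {
    ttt <- vapply(traces, function(tr) {
      i <- which(tr$normalized_density >= threshold)
      if (length(i) == 0) NA_real_ else tr$times[i[1]]
    }, numeric(1))
    attr(out, "time_to_threshold") <- ttt
  }
  out
}

#' @export
print.growth_trace <- function(x, ...) {
  cat(sprintf(
    "Adhesion growth trace: %d points over %.4g s, final density %.3f x (seed %d)\n",
    length(x$times), max(x$times),
    x$normalized_density[length(x$normalized_density)], x$seed))
  invisible(x)
}

#' Write growth traces and their summary to CSV
#'
#' @param traces list of `growth_trace` objects.
#' @param trace_csv,summary_csv,meta_json output paths (`NULL` to skip).
#' @param params the `clutch_params` used, echoed into `meta_json`.
#' @return Invisibly, the long-format trace data frame.
#' @export
write_growth_traces <- function(traces, trace_csv = NULL, summary_csv = NULL,
                                meta_json = NULL, params = NULL) {
  long <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(time_s = tr$times, seed = tr$seed,
               normalized_density = tr$normalized_density)
  }))
  if (!is.null(trace_csv))
    utils::write.csv(long, trace_csv, row.names = FALSE)
  if (!is.null(summary_csv))
    utils::write.csv(summarize_traces(traces), summary_csv,
                     row.names = FALSE)
  if (!is.null(meta_json) && !is.null(params))
    jsonlite::write_json(c(unclass(params),
                           list(seeds = vapply(traces, `[[`, 0L, "seed"))),
                         meta_json, auto_unbox = TRUE, digits = NA)
  invisible(long)
}
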