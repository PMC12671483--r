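#' Parameters for the stochastic motor-clutch adhesion simulator
#'
#' Bundles and validates all parameters of the motor-clutch model of adhesion
#' growth. Myosin motors pull actin retrogradely with a linear force-velocity
#' relation; explicit substrate binding sites are engaged by integrin clutches
#' whose binding propensity scales with the current (implicit) integrin
#' density; integrin-substrate bonds detach with a catch-slip off-rate and
#' talin unfolds with a Bell-type force-accelerated rate. Every talin
#' unfolding event reinforces the adhesion by raising the integrin density by
#' `d_add`, up to `cap_factor` times the initial density, so the model
#' describes adhesion growth only.
#'
#' The default kinetic constants are documented placeholder values drawn from
#' the published clutch-model lineage for fibronectin-binding integrins; all
#' of them are configuration, not code, and can be replaced wholesale (e.g.
#' from a JSON file via [read_clutch_config()]).
#'
#' @param n_motors number of myosin motors (count).
#' @param stall_force stall force per motor (pN).
#' @param unloaded_speed_v unloaded actin retrograde speed (nm/s).
#' @param clutch_stiffness spring constant of one clutch (pN/nm).
#' @param substrate_stiffness spring constant of the substrate (pN/nm);
#'   each engaged clutch loads through the series combination of the two.
#' @param n_sites number of explicit substrate binding sites.
#' @param site_area membrane area represented by the ensemble (µm²).
#' @param k_on binding rate per free site per unit integrin density
#'   (1/(s·(integrins/µm²))).
#' @param koff_catch_rate,koff_catch_force zero-force rate (1/s) and force
#'   scale (pN) of the catch (force-stabilized) exponential of the off-rate.
#' @param koff_slip_rate,koff_slip_force zero-force rate (1/s) and force
#'   scale (pN) of the slip (force-accelerated) exponential.
#' @param kunfold_0 zero-force talin unfolding rate (1/s).
#' @param kunfold_force force scale of talin unfolding (pN).
#' @param kfold_0 talin refolding rate (1/s), force-independent.
#' @param d_int0 initial integrin density (integrins/µm²).
#' @param d_add density increment per talin unfolding event
#'   (integrins/µm²). This is the integrin-availability dial: raising it
#'   models increased delivery of new integrins to the adhesion.
#' @param cap_factor maximum density as a multiple of `d_int0` (default 3:
#'   adhesions only grow to a bounded size).
#' @param dt simulation time step (s).
#' @param t_end simulated duration (s).
#' @param record_every output interval (s) for the growth trace.
#' @param seed integer seed making the trace fully reproducible.
#'
#' @return An object of class `clutch_params` (a validated named list).
#' @seealso [simulate_adhesion_growth()], [bond_off_rate()], [talin_rates()]
#' @examples
#' p <- clutch_params(t_end = 60, seed = 1)
#' bond_off_rate(0, p)
#' @export
clutch_params <- function(n_motors = 75,
                          stall_force = 2,
                          unloaded_speed_v = 110,
                          clutch_stiffness = 1,
                          substrate_stiffness = 10,
                          n_sites = 50,
                          site_area = 1,
                          k_on = 0.05,
                          koff_catch_rate = 1,
                          koff_catch_force = 4,
                          koff_slip_rate = 0.05,
                          koff_slip_force = 6,
                          kunfold_0 = 1e-4,
                          kunfold_force = 4,
                          kfold_0 = 0.05,
                          d_int0 = 1,
                          d_add = 0.01,
                          cap_factor = 3,
                          dt = 0.02,
                          t_end = 1800,
                          record_every = 1,
                          seed = 1L) {
  p <- list(n_motors = n_motors, stall_force = stall_force,
            unloaded_speed_v = unloaded_speed_v,
            clutch_stiffness = clutch_stiffness,
            substrate_stiffness = substrate_stiffness,
            n_sites = n_sites, site_area = site_area, k_on = k_on,
            koff_catch_rate = koff_catch_rate,
            koff_catch_force = koff_catch_force,
            koff_slip_rate = koff_slip_rate,
            koff_slip_force = koff_slip_force,
            kunfold_0 = kunfold_0, kunfold_force = kunfold_force,
            kfold_0 = kfold_0, d_int0 = d_int0, d_add = d_add,
            cap_factor = cap_factor, dt = dt, t_end = t_end,
            record_every = record_every, seed = as.integer(seed))
  class(p) <- "clutch_params"
  validate_clutch_params(p)
  p
}

#' @keywords internal
validate_clutch_params <- function(p, strict = FALSE, warn = TRUE) {
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all clutch parameters must be numeric")
  nonneg <- c("n_motors", "stall_force", "unloaded_speed_v",
              "clutch_stiffness", "substrate_stiffness", "site_area", "k_on",
              "koff_catch_rate", "koff_slip_rate", "kunfold_0", "kfold_0",
              "d_int0", "d_add")
  for (f in nonneg)
    if (p[[f]] < 0) stop("parameter '", f, "' must be >= 0")
  pos <- c("koff_catch_force", "koff_slip_force", "kunfold_force",
           "dt", "t_end", "record_every")
  for (f in pos)
    if (p[[f]] <= 0) stop("parameter '", f, "' must be > 0")
  if (p$cap_factor < 1) stop("cap_factor must be >= 1")
  if (p$n_sites < 1) stop("n_sites must be >= 1")
  # zero-force rates fix the fast timescale visible at configuration time;
  # force-loaded transitions are handled by the bounded exponential update
  max_rate0 <- max(p$k_on * p$cap_factor * p$d_int0,
                   p$koff_catch_rate + p$koff_slip_rate,
                   p$kunfold_0, p$kfold_0)
  # single steps tolerate any rate (bounded exponential probabilities);
  # a full simulation refuses a timestep that cannot resolve the kinetics
  if (strict && p$dt * max_rate0 >= 1)
    stop("dt * largest zero-force rate >= 1; decrease dt")
  if (warn && p$dt * max_rate0 >= 0.1)
    warning("dt * largest zero-force rate >= 0.1; ",
            "consider a smaller dt for accuracy")
  if (p$record_every < p$dt) stop("record_every must be >= dt")
  invisible(p)
}

#' Force-dependent integrin-substrate bond off-rate (catch-slip bond)
#'
#' Sum of two exponentials: a catch pathway whose rate decreases with force
#' and a slip pathway whose rate increases with force, giving the
#' characteristic off-rate minimum at intermediate force.
#'
#' @param force load on the bond (pN), scalar or vector, must be >= 0.
#' @param params a [clutch_params()] object.
#' @return Off-rate(s) in 1/s.
#' @examples
#' p <- clutch_params()
#' bond_off_rate(c(0, 5, 20), p)
#' @export
bond_off_rate <- function(force, params) {
  stopifnot(inherits(params, "clutch_params"))
  if (any(force < 0)) stop("force must be >= 0")
  r <- params$koff_catch_rate * exp(-force / params$koff_catch_force) +
    params$koff_slip_rate * exp(force / params$koff_slip_force)
  if (any(!is.finite(r))) stop("non-finite off-rate; force out of range")
  r
}

#' Force-dependent talin unfolding and refolding rates
#'
#' Unfolding follows a Bell-type exponential acceleration with force;
#' refolding is force-independent at its zero-force rate.
#'
#' @inheritParams bond_off_rate
#' @return A list with elements `k_unfold` and `k_fold` (1/s).
#' @export
talin_rates <- function(force, params) {
  stopifnot(inherits(params, "clutch_params"))
  if (any(force < 0)) stop("force must be >= 0")
  ku <- params$kunfold_0 * exp(force / params$kunfold_force)
  if (any(!is.finite(ku))) stop("non-finite unfolding rate")
  list(k_unfold = ku, k_fold = rep_len(params$kfold_0, length(force)))
}

#' Read clutch parameters from a JSON configuration file
#'
#' The file must contain a flat JSON object whose keys are
#' [clutch_params()] argument names; missing keys fall back to defaults.
#'
#' @param path path to a JSON file.
#' @return A `clutch_params` object.
#' @export
read_clutch_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(clutch_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown clutch parameter(s) in config: ", paste(bad, collapse = ", "))
  do.call(clutch_params, cfg)
}

#' @export
print.clutch_params <- function(x, ...) {
  cat("Motor-clutch model parameters\n")
  cat(sprintf("  %d motors x %.3g pN, v = %.3g nm/s\n",
              x$n_motors, x$stall_force, x$unloaded_speed_v))
  cat(sprintf("  %d sites, k_on = %.3g /(s (int/um^2)), d_int0 = %.3g, d_add = %.3g, cap = %.3g x\n",
              x$n_sites, x$k_on, x$d_int0, x$d_add, x$cap_factor))
  cat(sprintf("  dt = %.3g s, t_end = %.4g s, seed = %d\n",
              x$dt, x$t_end, x$seed))
  invisible(x)
}
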