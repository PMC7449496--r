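# Whole-cell electrophysiology model: a compact spontaneously beating
# iPSC-CM formulation hosting the IKs model, with per-current scale factors.
#
# The ODE right-hand side lives in src/cellmodel.c and is integrated with
# deSolve's compiled-code interface (lsoda). The same equations serve the
# paced adult-ventricular regime (no funny current, strong inward rectifier,
# periodic stimulus) used by the adult-translation module.

.STATE_NAMES <- c("vm", "m", "h", "j", "d", "f", "fca", "xr", "xs", "xf",
                  "nai", "cai", "ki")
.CURRENT_NAMES <- c("i_na", "i_cal", "i_kr", "i_ks", "i_k1", "i_f",
                    "i_nak", "i_ncx", "i_noise")
.SCALED_CURRENTS <- c("i_na", "i_cal", "i_kr", "i_k1", "i_f")
.KINETIC_CURRENTS <- c("i_na", "i_cal", "i_kr", "i_f")

#' Baseline iPSC-CM configuration
#'
#' Conductance densities (nS/pF), pump/exchanger scales (pA/pF) and
#' extracellular milieu (mM) of the shipped spontaneously beating baseline
#' cell. `conv` is the membrane-to-cytosol conversion factor Cm/(F*Vc)
#' (mM per pA/pF per ms, monovalent ions). These values are the package's
#' own calibration of a compact iPSC-CM formulation: they are chosen so the
#' baseline cell beats spontaneously with AP amplitude > 70 mV and maximum
#' diastolic potential < -40 mV, and so that IKs carries a meaningful share
#' of repolarization.
#'
#' @return named list of baseline parameters
#' @export
base_cell_config <- function() {
  list(
    g_na = 7, g_cal = 0.4, g_kr = 0.13, g_k1 = 0.04, g_f = 0.3,
    p_nak = 3, k_ncx = 600, g_bna = 0.0015, g_bca = 8e-4, g_pca = 0.12,
    nao = 140, ko = 5.4, cao = 1.8, conv = 1.04e-4
  )
}

#' Adult ventricular baseline configuration
#'
#' Same equation set as [base_cell_config()] re-parameterized for a paced
#' adult ventricular myocyte: no funny current, a strong inward rectifier
#' (quiescent resting potential near -85 mV), larger sodium current, and a
#' larger cytosol. The IKs conductance is left at the iPSC-CM value: the
#' adult-translation module sets it by scaling a fitted iPSC-CM variant.
#'
#' @return named list of baseline parameters
#' @export
adult_cell_config <- function() {
  cfg <- base_cell_config()
  cfg$g_f <- 0
  cfg$g_k1 <- 0.55
  cfg$g_na <- 12
  cfg$g_cal <- 0.35
  cfg$g_kr <- 0.15
  cfg$p_nak <- 3
  cfg
}

#' Whole-cell model parameters
#'
#' Combines an IKs parameter set with baseline conductances, multiplicative
#' scale factors for the five population-varied currents (INa, ICaL, IKr,
#' IK1, If) and kinetic (time-constant) scale factors for the four of them
#' that are gated (IK1 is instantaneous). IKs is never scaled here: variants
#' enter through `iks` itself.
#'
#' @param iks `iks_parameters` for the hosted IKs model
#' @param scale named conductance multipliers for `i_na`, `i_cal`, `i_kr`,
#'   `i_k1`, `i_f` (all >= 0; default 1)
#' @param kinetic_scale named time-constant multipliers for `i_na`, `i_cal`,
#'   `i_kr`, `i_f` (all > 0; default 1)
#' @param base baseline configuration list ([base_cell_config()] or
#'   [adult_cell_config()])
#' @param pacing list with `bcl` (ms; 0 disables pacing), `stim_amp`
#'   (pA/pF, negative = inward) and `stim_dur` (ms)
#' @param cell_id optional identifier carried through population tables
#' @return object of class `cell_parameters`
#' @export
cell_parameters <- function(iks = wt_iks_parameters(),
                            scale = c(i_na = 1, i_cal = 1, i_kr = 1,
                                      i_k1 = 1, i_f = 1),
                            kinetic_scale = c(i_na = 1, i_cal = 1,
                                              i_kr = 1, i_f = 1),
                            base = base_cell_config(),
                            pacing = list(bcl = 0, stim_amp = -40, stim_dur = 1),
                            cell_id = NA_integer_) {
  stopifnot(inherits(iks, "iks_parameters"))
  sc <- c(i_na = 1, i_cal = 1, i_kr = 1, i_k1 = 1, i_f = 1)
  if (!all(names(scale) %in% names(sc))) {
    stop("cell_parameters: unknown scale name(s): ",
         paste(setdiff(names(scale), names(sc)), collapse = ", "))
  }
  sc[names(scale)] <- scale
  if (any(sc < 0)) stop("cell_parameters: conductance scale factors must be >= 0")
  ks <- c(i_na = 1, i_cal = 1, i_kr = 1, i_f = 1)
  if (!all(names(kinetic_scale) %in% names(ks))) {
    stop("cell_parameters: unknown kinetic_scale name(s): ",
         paste(setdiff(names(kinetic_scale), names(ks)), collapse = ", "))
  }
  ks[names(kinetic_scale)] <- kinetic_scale
  if (any(ks <= 0)) stop("cell_parameters: kinetic scale factors must be > 0")
  if (pacing$bcl > 0 && pacing$bcl <= pacing$stim_dur) {
    stop("cell_parameters: bcl must exceed the stimulus duration")
  }
  structure(list(iks = iks, scale = sc, kinetic_scale = ks, base = base,
                 pacing = pacing, cell_id = cell_id),
            class = "cell_parameters")
}

#' Swap the IKs model of a cell
#'
#' @param p `cell_parameters`
#' @param iks replacement `iks_parameters` (e.g. a fitted mutant)
#' @return `cell_parameters` with the new IKs model
#' @export
set_iks <- function(p, iks) {
  stopifnot(inherits(p, "cell_parameters"), inherits(iks, "iks_parameters"))
  p$iks <- iks
  p
}

#' Scale the inward-rectifier conductance (IK1 rescue)
#'
#' Multiplies the IK1 scale factor; used to stabilize the diastolic
#' potential of cells showing repolarization failure.
#'
#' @param p `cell_parameters`
#' @param ik1_multiplier multiplier (> 0)
#' @return `cell_parameters`
#' @export
rescue_with_ik1 <- function(p, ik1_multiplier) {
  stopifnot(inherits(p, "cell_parameters"))
  if (!is.finite(ik1_multiplier) || ik1_multiplier <= 0) {
    stop("rescue_with_ik1: multiplier must be > 0")
  }
  p$scale[["i_k1"]] <- p$scale[["i_k1"]] * ik1_multiplier
  p
}

# flatten cell_parameters into the fixed-order parameter vector of the C RHS
.parms_vector <- function(p) {
  b <- p$base
  c(
    b$g_na * p$scale[["i_na"]],
    b$g_cal * p$scale[["i_cal"]],
    b$g_kr * p$scale[["i_kr"]],
    b$g_k1 * p$scale[["i_k1"]],
    b$g_f * p$scale[["i_f"]],
    p$iks$g_ks, p$iks$x1, p$iks$x2, p$iks$x3, p$iks$x4, p$iks$x5,
    b$p_nak, b$k_ncx, b$g_bna, b$g_bca, b$g_pca,
    p$kinetic_scale[["i_na"]], p$kinetic_scale[["i_cal"]],
    p$kinetic_scale[["i_kr"]], p$kinetic_scale[["i_f"]],
    p$pacing$stim_amp, p$pacing$stim_dur, p$pacing$bcl,
    b$nao, b$ko, b$cao, b$conv
  )
}

#' Default initial state
#'
#' State vector on the baseline cell's spontaneous limit cycle, sampled at
#' the maximum diastolic potential (computed once from a 400 s baseline run
#' and frozen here so steady-state searches start close to convergence).
#'
#' @return named numeric state vector
#' @export
default_cell_state <- function() {
  c(vm = -69.32837653, m = 0.04035475854, h = 0.1249601582,
    j = 0.02321708134, d = 0.0001807297625, f = 0.5874295805,
    fca = 0.5529983722, xr = 0.5953337919, xs = 0.1266414176,
    xf = 0.00489059737, nai = 12.91399878, cai = 0.0007873942341,
    ki = 109.0361656)
}

#' Quiescent initial state for the paced adult regime
#'
#' @return named numeric state vector near the adult resting potential
#' @export
default_adult_state <- function() {
  c(vm = -85, m = 0.0, h = 0.75, j = 0.75, d = 0, f = 1, fca = 1,
    xr = 0, xs = 0, xf = 0, nai = 8, cai = 1e-4, ki = 140)
}

.check_state <- function(state) {
  if (length(state) != 13) stop("state must have 13 elements")
  if (is.null(names(state))) names(state) <- .STATE_NAMES
  if (any(!is.finite(state))) stop("state contains non-finite values")
  gates <- state[2:10]
  if (any(gates < -1e-6 | gates > 1 + 1e-6)) stop("gate variables must lie in [0, 1]")
  if (any(state[11:13] <= 0)) stop("ion concentrations must be positive")
  state
}

#' Evaluate the model right-hand side
#'
#' Time derivative of the state at a single point, including an optional
#' injected noise current. Mainly a testing/diagnostic surface; simulation
#' goes through [simulate_cell()].
#'
#' @param state named 13-element state vector (see [default_cell_state()])
#' @param p `cell_parameters`
#' @param i_noise injected current (pA/pF, depolarizing > 0)
#' @param t time (ms), only relevant when pacing is enabled
#' @return list with `dstate` (named derivative vector) and `currents`
#'   (named current densities, pA/pF)
#' @export
cell_derivatives <- function(state, p, i_noise = 0, t = 0) {
  state <- .check_state(state)
  out <- deSolve::DLLfunc(
    y = unname(state), times = t, func = "cell_derivs",
    parms = .parms_vector(p), dllname = "iksvar",
    initfunc = "cell_initmod", initforc = "cell_initforc",
    forcings = matrix(c(t - 1, t + 1, i_noise, i_noise), ncol = 2),
    fcontrol = list(method = "constant", rule = 2),
    nout = 9, outnames = .CURRENT_NAMES
  )
  d <- out$dy
  names(d) <- .STATE_NAMES
  if (any(!is.finite(d))) stop("cell_derivatives: non-finite derivative (integration blow-up)")
  list(dstate = d, currents = out$var)
}

#' Simulate the whole-cell model
#'
#' Stiff adaptive integration (lsoda, compiled right-hand side) of the cell
#' for `duration` ms, optionally with the piecewise-constant physiological
#' noise current from [generate_noise()]. With noise, the maximum solver
#' step is capped at the noise update interval so every segment is sampled.
#'
#' @param p `cell_parameters`
#' @param initial named initial state (default [default_cell_state()])
#' @param duration simulated time (ms, > 0)
#' @param noise `noise_config` or `NULL`
#' @param dt_out output grid spacing (ms)
#' @param rtol,atol solver tolerances
#' @param hmax maximum solver step (ms); default 5, reduced to the noise
#'   update interval during noise runs
#' @param i_inject constant injected current (pA/pF, depolarizing > 0) held
#'   for the whole run; used to deliver pacing stimuli beat-by-beat.
#'   Mutually exclusive with `noise`.
#' @return object of class `sim_trace`: a data.frame with `time`, `vm`, all
#'   state variables and current densities; attributes `final_state`,
#'   `noise` (seed/amplitude record or NULL) and `solver`
#' @export
simulate_cell <- function(p, initial = default_cell_state(), duration,
                          noise = NULL, dt_out = 1, rtol = 1e-6, atol = 1e-8,
                          hmax = 5, i_inject = 0) {
  stopifnot(inherits(p, "cell_parameters"))
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop("simulate_cell: duration must be a positive number of ms")
  }
  if (i_inject != 0 && !is.null(noise)) {
    stop("simulate_cell: i_inject and noise are mutually exclusive")
  }
  initial <- .check_state(initial)
  times <- seq(0, duration, by = dt_out)
  if (times[length(times)] < duration) times <- c(times, duration)

  if (is.null(noise)) {
    forcings <- matrix(c(0, duration, i_inject, i_inject), ncol = 2)
    noise_rec <- NULL
  } else {
    stopifnot(inherits(noise, "noise_config"))
    sig <- generate_noise(noise, duration)
    forcings <- cbind(sig$time, sig$current)
    hmax <- min(hmax, noise$update_interval)
    noise_rec <- list(seed = noise$seed, sigma = noise$sigma,
                      update_interval = noise$update_interval)
  }

  sol <- deSolve::lsoda(
    y = unname(initial), times = times, func = "cell_derivs",
    parms = .parms_vector(p), dllname = "iksvar",
    initfunc = "cell_initmod", initforc = "cell_initforc",
    forcings = forcings, fcontrol = list(method = "constant", rule = 2),
    rtol = rtol, atol = atol, hmax = hmax, maxsteps = 50000,
    nout = 9, outnames = .CURRENT_NAMES
  )
  n_ok <- nrow(sol)
  if (n_ok < length(times)) {
    warning(sprintf("simulate_cell: solver stopped at t = %.1f ms (of %.1f requested)",
                    sol[n_ok, 1], duration))
  }
  tr <- as.data.frame(sol)
  names(tr) <- c("time", .STATE_NAMES, .CURRENT_NAMES)
  if (any(!is.finite(tr$vm))) {
    stop("simulate_cell: non-finite membrane voltage in trace (integration blow-up)")
  }
  # project out sub-tolerance integrator noise so gates stay in [0, 1]
  for (g in .STATE_NAMES[2:10]) tr[[g]] <- pmin(pmax(tr[[g]], 0), 1)
  final <- unlist(tr[nrow(tr), .STATE_NAMES])
  names(final) <- .STATE_NAMES
  structure(tr, class = c("sim_trace", "data.frame"),
            final_state = final, noise = noise_rec,
            solver = list(rtol = rtol, atol = atol, hmax = hmax, dt_out = dt_out))
}

#' Final state of a simulation trace
#'
#' @param trace `sim_trace`
#' @return named state vector at the last time point
#' @export
final_state <- function(trace) attr(trace, "final_state")

#' Probe whether a cell is spontaneously beating
#'
#' A cell is quiescent if its membrane voltage never crosses -20 mV upward
#' within a probe window.
#'
#' @param p `cell_parameters`
#' @param initial initial state
#' @param probe_duration probe length (ms, default 10 s)
#' @return logical: TRUE when beating
#' @export
is_beating <- function(p, initial = default_cell_state(), probe_duration = 10000) {
  tr <- simulate_cell(p, initial, probe_duration)
  any(diff(tr$vm > -20) == 1)
}

#' Run a cell to its periodic steady state
#'
#' Repeats 50 s windows until, for each tracked ion (Nai, Cai, Ki), the
#' per-beat minimum concentration changes by less than `tol` (relative)
#' between the first and last beat of the window. Total simulated time is
#' capped at `max_time`; at the cap the state is still returned with
#' `converged = FALSE`. A cell that stops beating is reported as converged
#' on quiescence with `quiescent = TRUE`.
#'
#' @param p `cell_parameters`
#' @param initial starting state
#' @param window window length (ms, default 50 s)
#' @param max_time total simulated-time cap (ms, default 600 s)
#' @param tol relative tolerance on per-beat minimum concentrations (default 1%)
#' @return list: `state` (final state), `converged`, `quiescent`,
#'   `time_s` (total simulated seconds)
#' @export
run_to_steady_state <- function(p, initial = default_cell_state(),
                                window = 50000, max_time = 600000, tol = 0.01) {
  stopifnot(inherits(p, "cell_parameters"))
  state <- .check_state(initial)
  elapsed <- 0
  while (elapsed < max_time) {
    tr <- simulate_cell(p, state, window, dt_out = 2)
    elapsed <- elapsed + window
    state <- final_state(tr)
    up <- which(diff(tr$vm > 0) == 1)
    if (length(up) < 3) {
      # not beating: quiescence is itself a (degenerate) steady state
      return(list(state = state, converged = TRUE, quiescent = TRUE,
                  time_s = elapsed / 1000))
    }
    first_beat <- tr[up[1]:up[2], c("nai", "cai", "ki")]
    last_beat <- tr[up[length(up) - 1]:up[length(up)], c("nai", "cai", "ki")]
    rel <- abs(vapply(first_beat, min, numeric(1)) -
                 vapply(last_beat, min, numeric(1))) /
           vapply(first_beat, min, numeric(1))
    if (all(rel < tol)) {
      return(list(state = state, converged = TRUE, quiescent = FALSE,
                  time_s = elapsed / 1000))
    }
  }
  list(state = state, converged = FALSE, quiescent = FALSE,
       time_s = elapsed / 1000)
}

#' Write a voltage trace as delimited text
#'
#' @param trace `sim_trace`
#' @param path output path
#' @param currents include current densities (default FALSE: time/vm only)
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path, currents = FALSE) {
  cols <- if (currents) c("time", .STATE_NAMES, .CURRENT_NAMES) else c("time", "vm")
  utils::write.csv(as.data.frame(trace)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read/write whole-cell parameter sets
#'
#' Structured text (YAML) with a schema version: the IKs parameters, the
#' conductance and kinetic scale factors, the baseline configuration and the
#' pacing settings.
#'
#' @param p `cell_parameters`
#' @param path file path
#' @return `write_cell_parameters` returns `path` invisibly;
#'   `read_cell_parameters` returns a `cell_parameters` object
#' @export
write_cell_parameters <- function(p, path) {
  stopifnot(inherits(p, "cell_parameters"))
  x <- list(
    schema = "iksvar-cell/1",
    iks = p$iks[c("x1", "x2", "x3", "x4", "x5", "g_ks")],
    scale = as.list(p$scale),
    kinetic_scale = as.list(p$kinetic_scale),
    base = p$base,
    pacing = p$pacing,
    cell_id = p$cell_id
  )
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_cell_parameters
#' @export
read_cell_parameters <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$schema) || !identical(x$schema, "iksvar-cell/1")) {
    stop("read_cell_parameters: unknown or missing schema version in ", path)
  }
  cell_parameters(
    iks = iks_parameters(x$iks$x1, x$iks$x2, x$iks$x3, x$iks$x4, x$iks$x5,
                         x$iks$g_ks),
    scale = unlist(x$scale),
    kinetic_scale = unlist(x$kinetic_scale),
    base = x$base,
    pacing = x$pacing,
    cell_id = if (is.null(x$cell_id)) NA_integer_ else x$cell_id
  )
}
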