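# Hodgkin-Huxley model of the slow delayed-rectifier potassium current (IKs).
#
# The current is
#   IKs  = G_Ks * x^2 * (Vm - E_K)
# with a single activation gate x governed by dx/dt = (x_inf - x)/tau_x,
#   x_inf(V)  = 1 / (1 + (x3/x1) * exp(V * (1/x4 - 1/x2)))
#   tau_x(V)  = 1 / (x1 * exp(V/x2) + x3 * exp(V/x4)) + x5
# The derived quantities x6 = x3/x1 and x7 = 1/x4 - 1/x2 parameterize the
# steady-state activation as a Boltzmann curve with
#   V_1/2 = -log(x6)/x7 and slope k = -1/x7 (x7 < 0 for an activating gate).

# exponentials are clamped so rates stay finite at unphysical voltages
.EXP_CLAMP <- 700

.safe_exp <- function(x) exp(pmin(pmax(x, -.EXP_CLAMP), .EXP_CLAMP))

#' IKs channel parameters
#'
#' Construct a validated parameter set for the two-state IKs gating model.
#' `x1`/`x3` are rate prefactors (1/ms), `x2`/`x4` voltage e-fold constants
#' (mV), `x5` a floor on the activation time constant (ms) and `g_ks` the
#' maximal conductance density (nS/pF). `g_ks = 0` is legal and denotes
#' complete channel block.
#'
#' @param x1,x3 rate prefactors (1/ms, > 0)
#' @param x2,x4 voltage e-fold constants (mV, nonzero)
#' @param x5 time-constant floor (ms, >= 0)
#' @param g_ks maximal conductance density (nS/pF, >= 0)
#' @return an object of class `iks_parameters` with derived fields `x6`
#'   (= x3/x1) and `x7` (= 1/x4 - 1/x2, must be negative so that activation
#'   increases with voltage)
#' @export
iks_parameters <- function(x1, x2, x3, x4, x5, g_ks) {
  vals <- c(x1 = x1, x2 = x2, x3 = x3, x4 = x4, x5 = x5, g_ks = g_ks)
  if (any(!is.finite(vals))) {
    stop("iks_parameters: all parameters must be finite numbers")
  }
  if (x1 <= 0 || x3 <= 0) stop("iks_parameters: rate prefactors x1, x3 must be > 0")
  if (x2 == 0 || x4 == 0) stop("iks_parameters: e-fold constants x2, x4 must be nonzero")
  if (x5 < 0) stop("iks_parameters: time-constant floor x5 must be >= 0")
  if (g_ks < 0) stop("iks_parameters: conductance g_ks must be >= 0")
  x6 <- x3 / x1
  x7 <- 1 / x4 - 1 / x2
  if (x7 >= 0) {
    stop("iks_parameters: 1/x4 - 1/x2 must be negative (activation must increase with voltage)")
  }
  structure(
    list(x1 = x1, x2 = x2, x3 = x3, x4 = x4, x5 = x5, g_ks = g_ks,
         x6 = x6, x7 = x7),
    class = "iks_parameters"
  )
}

#' @export
print.iks_parameters <- function(x, ...) {
  cat("IKs channel parameters\n")
  cat(sprintf("  x1 = %.6g 1/ms   x2 = %.6g mV\n", x$x1, x$x2))
  cat(sprintf("  x3 = %.6g 1/ms   x4 = %.6g mV\n", x$x3, x$x4))
  cat(sprintf("  x5 = %.6g ms     G_Ks = %.6g nS/pF\n", x$x5, x$g_ks))
  s <- activation_summary(x)
  cat(sprintf("  activation: V_1/2 = %.2f mV, slope k = %.2f mV\n",
              s$v_half, s$slope_k))
  invisible(x)
}

#' Wild-type IKs parameter defaults
#'
#' Shipped baseline parameterization of the wild-type iPSC-CM IKs model:
#' half-activation at -12 mV with a 14 mV Boltzmann slope, slow activation
#' (about 600 ms at 0 mV) with much faster deactivation at diastolic
#' voltages, and a maximal conductance of 0.2 nS/pF. These values are
#' configuration, not ground truth: they place V_1/2, k, tau and G_Ks in the
#' range reported for KCNQ1/KCNE1 currents in immature human cardiomyocytes,
#' and every variant is fitted as a *relative* change from this baseline.
#'
#' @return an `iks_parameters` object
#' @export
wt_iks_parameters <- function() {
  # x1, x2 set the rate scale; x3, x4 follow from V_1/2 = -12, k = 14
  v_half <- -12
  slope <- 14
  x1 <- 1.21e-3
  x2 <- 60
  x7 <- -1 / slope
  x6 <- exp(v_half / slope)
  x4 <- 1 / (x7 + 1 / x2)
  x3 <- x6 * x1
  iks_parameters(x1 = x1, x2 = x2, x3 = x3, x4 = x4, x5 = 20, g_ks = 0.2)
}

#' Steady-state IKs activation
#'
#' Open fraction of the activation gate at voltage `v`:
#' `1 / (1 + x6 * exp(v * x7))`. Strictly increasing in `v` for any valid
#' parameter set, with values in (0, 1).
#'
#' @param p `iks_parameters`
#' @param v membrane voltage (mV); vectorized
#' @return open fraction in (0, 1)
#' @export
activation_steady_state <- function(p, v) {
  stopifnot(inherits(p, "iks_parameters"))
  if (any(!is.finite(v))) stop("activation_steady_state: voltage must be finite")
  1 / (1 + p$x6 * .safe_exp(v * p$x7))
}

#' IKs activation time constant
#'
#' `tau_x(v) = 1 / (x1 * exp(v/x2) + x3 * exp(v/x4)) + x5` in ms. Always
#' strictly greater than the floor `x5`. Exponentials saturate at extreme
#' voltages instead of overflowing.
#'
#' @param p `iks_parameters`
#' @param v membrane voltage (mV); vectorized
#' @return time constant (ms)
#' @export
activation_tau <- function(p, v) {
  stopifnot(inherits(p, "iks_parameters"))
  if (any(!is.finite(v))) stop("activation_tau: voltage must be finite")
  1 / (p$x1 * .safe_exp(v / p$x2) + p$x3 * .safe_exp(v / p$x4)) + p$x5
}

#' IKs current density
#'
#' `IKs = g_ks * x_act^2 * (vm - e_k)` in pA/pF.
#'
#' @param p `iks_parameters`
#' @param x_act open fraction of the activation gate, in \[0, 1\]
#' @param vm membrane voltage (mV)
#' @param e_k potassium reversal potential (mV)
#' @return current density (pA/pF)
#' @export
iks_current <- function(p, x_act, vm, e_k) {
  stopifnot(inherits(p, "iks_parameters"))
  if (any(x_act < 0 | x_act > 1)) {
    stop("iks_current: open fraction x_act must lie in [0, 1]")
  }
  p$g_ks * x_act^2 * (vm - e_k)
}

#' Boltzmann summary of the steady-state activation curve
#'
#' Extracts the half-activation voltage and slope factor of the activation
#' curve in closed form: `v_half = -log(x6)/x7`, `slope_k = -1/x7`.
#'
#' @param p `iks_parameters`
#' @return list with `v_half` (mV) and `slope_k` (mV, > 0)
#' @export
activation_summary <- function(p) {
  stopifnot(inherits(p, "iks_parameters"))
  if (p$x7 >= 0) stop("activation_summary: non-activating parameterization (x7 >= 0)")
  list(v_half = -log(p$x6) / p$x7, slope_k = -1 / p$x7)
}

#' Build IKs kinetics realizing a target activation curve
#'
#' Inverse of [activation_summary()]: given a target half-activation voltage
#' and slope, returns the implied derived constants `x6 = exp(v_half/slope)`
#' and `x7 = -1/slope`.
#'
#' @param v_half half-activation voltage (mV)
#' @param slope_k Boltzmann slope factor (mV, > 0)
#' @return list with `x6`, `x7`
#' @export
activation_targets <- function(v_half, slope_k) {
  if (!is.finite(v_half) || !is.finite(slope_k) || slope_k <= 0) {
    stop("activation_targets: slope_k must be a positive finite number")
  }
  list(x6 = exp(v_half / slope_k), x7 = -1 / slope_k)
}

#' Voltage-clamp protocol
#'
#' An activation-style step protocol: hold at `holding_potential`, step to
#' each voltage in `step_voltages` for `step_duration`, and measure the
#' end-of-step current. "Current density" in this package means the
#' end-of-step current at `reference_voltage` (a protocol dialect switch:
#' set `measure = "step_end"`; a peak-tail dialect is not implemented).
#'
#' @param holding_potential holding voltage (mV)
#' @param step_voltages ordered step voltages (mV)
#' @param step_duration step length (ms, > 0)
#' @param reference_voltage the step at which current density is read; must
#'   be one of `step_voltages`
#' @param e_k potassium reversal potential (mV)
#' @param measure measurement dialect; only `"step_end"` is implemented
#' @return object of class `vc_protocol`
#' @export
voltage_clamp_protocol <- function(holding_potential = -80,
                                   step_voltages = seq(-80, 60, by = 10),
                                   step_duration = 2000,
                                   reference_voltage = 40,
                                   e_k = -88,
                                   measure = "step_end") {
  if (step_duration <= 0) stop("voltage_clamp_protocol: step_duration must be > 0")
  if (!reference_voltage %in% step_voltages) {
    stop("voltage_clamp_protocol: reference_voltage must be one of step_voltages")
  }
  measure <- match.arg(measure, "step_end")
  structure(
    list(holding_potential = holding_potential,
         step_voltages = as.numeric(step_voltages),
         step_duration = step_duration,
         reference_voltage = reference_voltage,
         e_k = e_k,
         measure = measure),
    class = "vc_protocol"
  )
}

#' Simulate an IKs voltage-clamp experiment
#'
#' For each protocol step the activation gate is integrated numerically from
#' its holding-potential steady state through `step_duration`, and the
#' end-of-step current density is recorded. The returned I-V table also
#' carries a Boltzmann fit (`v_half`, `slope_k`) of the normalized
#' end-of-step conductance, mirroring how activation curves are measured
#' from patch-clamp data.
#'
#' @param p `iks_parameters`
#' @param proto `vc_protocol`
#' @return list of class `iv_curve`: `iv` (data.frame voltage/current),
#'   `v_half`, `slope_k` (NA when the channel carries no current),
#'   `reference_current` (pA/pF at the reference voltage)
#' @export
simulate_voltage_clamp <- function(p, proto = voltage_clamp_protocol()) {
  stopifnot(inherits(p, "iks_parameters"), inherits(proto, "vc_protocol"))
  x0 <- activation_steady_state(p, proto$holding_potential)
  gate_rhs <- function(t, y, parms) {
    v <- parms
    list((activation_steady_state(p, v) - y) / activation_tau(p, v))
  }
  current <- vapply(proto$step_voltages, function(v) {
    sol <- deSolve::lsoda(
      y = x0, times = c(0, proto$step_duration), func = gate_rhs, parms = v,
      rtol = 1e-10, atol = 1e-12
    )
    x_end <- min(max(sol[nrow(sol), 2], 0), 1)
    iks_current(p, x_end, v, proto$e_k)
  }, numeric(1))

  iv <- data.frame(voltage = proto$step_voltages, current = current)
  ref_i <- current[match(proto$reference_voltage, proto$step_voltages)]

  # normalized end-of-step conductance; Boltzmann fit gives measured V1/2, k
  fit <- .fit_boltzmann(proto$step_voltages, current, proto$e_k)
  structure(
    list(iv = iv, v_half = fit$v_half, slope_k = fit$slope_k,
         reference_current = ref_i, protocol = proto),
    class = "iv_curve"
  )
}

# Boltzmann fit of normalized chord conductance from an I-V table.
# Conductance at the reversal potential is undefined; that point is dropped.
.fit_boltzmann <- function(voltage, current, e_k) {
  drive <- voltage - e_k
  keep <- abs(drive) > 1e-6
  g <- current[keep] / drive[keep]
  v <- voltage[keep]
  gmax <- max(g)
  if (!is.finite(gmax) || gmax <= 0) {
    return(list(v_half = NA_real_, slope_k = NA_real_))
  }
  gn <- g / gmax
  start <- list(v_half = v[which.min(abs(gn - 0.5))], slope_k = 10)
  fit <- try(minpack.lm::nlsLM(
    gn ~ 1 / (1 + exp((v_half - v) / slope_k)),
    start = start,
    lower = c(v_half = -200, slope_k = 0.1),
    upper = c(v_half = 200, slope_k = 100),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(v_half = NA_real_, slope_k = NA_real_))
  }
  co <- stats::coef(fit)
  list(v_half = unname(co["v_half"]), slope_k = unname(co["slope_k"]))
}

#' Mutant-to-WT relative current density
#'
#' Ratio of mutant to wild-type end-of-step current density at the
#' protocol's reference voltage.
#'
#' @param p_mut,p_wt `iks_parameters` for mutant and wild type
#' @param proto `vc_protocol`
#' @return dimensionless fraction (1 when the models coincide)
#' @export
relative_current_density <- function(p_mut, p_wt, proto = voltage_clamp_protocol()) {
  i_wt <- simulate_voltage_clamp(p_wt, proto)$reference_current
  if (!is.finite(i_wt) || abs(i_wt) < 1e-9) {
    stop("relative_current_density: WT current at the reference voltage is ~0; ratio ill-posed")
  }
  i_mut <- simulate_voltage_clamp(p_mut, proto)$reference_current
  i_mut / i_wt
}

#' Read/write IKs parameter files
#'
#' Plain-text `key = value` files with keys `x1..x5`, `g_ks`. Values are
#' written with 17 significant digits so the round trip is lossless at
#' double precision.
#'
#' @param p `iks_parameters`
#' @param path file path
#' @return `write_iks_parameters` returns `path` invisibly;
#'   `read_iks_parameters` returns an `iks_parameters` object
#' @export
write_iks_parameters <- function(p, path) {
  stopifnot(inherits(p, "iks_parameters"))
  keys <- c("x1", "x2", "x3", "x4", "x5", "g_ks")
  lines <- sprintf("%s = %.17g", keys, vapply(keys, function(k) p[[k]], numeric(1)))
  writeLines(c("# IKs channel parameters (1/ms, mV, ms, nS/pF)", lines), path)
  invisible(path)
}

#' @rdname write_iks_parameters
#' @export
read_iks_parameters <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("read_iks_parameters: malformed line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, character(1), 2))))
  names(vals) <- keys
  need <- c("x1", "x2", "x3", "x4", "x5", "g_ks")
  if (!all(need %in% keys)) {
    stop("read_iks_parameters: missing key(s): ", paste(setdiff(need, keys), collapse = ", "))
  }
  if (any(!is.finite(vals[need]))) stop("read_iks_parameters: non-numeric value(s)")
  iks_parameters(vals[["x1"]], vals[["x2"]], vals[["x3"]], vals[["x4"]],
                 vals[["x5"]], vals[["g_ks"]])
}
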