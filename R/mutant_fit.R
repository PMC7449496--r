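# Fitting per-variant IKs models to patch-clamp summary statistics:
# the shift in half-activation voltage (delta V_1/2), the change in
# Boltzmann slope (delta k) and the current density relative to wild type.
#
# The activation targets pin down only the derived constants x6 = x3/x1 and
# x7 = 1/x4 - 1/x2, leaving a 2-parameter family of (x1..x4) kinetics. That
# indeterminacy is resolved by choosing the member whose activation time
# constant deviates least (in the least-squares sense, over a voltage grid)
# from the wild-type tau(v): summary data carry no information about mutant
# time constants, so the fit perturbs them minimally.

#' Variant summary specification
#'
#' One variant's patch-clamp summary: shift in half-activation voltage,
#' change in activation slope, and current density relative to wild type.
#' A variant with unmeasurably small current is a *complete block*
#' (`complete_block = TRUE`, `rel_density` absent); a `rel_density <= 0`
#' is canonicalized to a complete block.
#'
#' @param name variant label
#' @param delta_v_half shift in V_1/2 vs WT (mV)
#' @param delta_slope change in Boltzmann slope k vs WT (mV)
#' @param rel_density fraction of WT current density (>= 0), or `NA` for a
#'   complete block; values > 1 denote gain of function
#' @param complete_block logical flag; forced `TRUE` when `rel_density` is
#'   absent or <= 0
#' @param density_se optional standard error of `rel_density` (fraction),
#'   for density-sensitivity runs
#' @return object of class `mutant_spec`
#' @export
mutant_spec <- function(name, delta_v_half = 0, delta_slope = 0,
                        rel_density = NA_real_, complete_block = FALSE,
                        density_se = NA_real_) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("mutant_spec: name must be a non-empty string")
  }
  if (!is.finite(delta_v_half) || !is.finite(delta_slope)) {
    stop("mutant_spec: delta_v_half and delta_slope must be finite")
  }
  block <- isTRUE(complete_block) || is.na(rel_density) || rel_density <= 0
  if (block) {
    rel_density <- NA_real_
  }
  structure(
    list(name = name, delta_v_half = delta_v_half, delta_slope = delta_slope,
         rel_density = rel_density, complete_block = block,
         density_se = density_se),
    class = "mutant_spec"
  )
}

#' @export
print.mutant_spec <- function(x, ...) {
  if (x$complete_block) {
    cat(sprintf("mutant_spec %s: complete IKs block (G_Ks = 0)\n", x$name))
  } else {
    cat(sprintf("mutant_spec %s: dV1/2 %+.2f mV, dk %+.2f mV, density %.3g x WT\n",
                x$name, x$delta_v_half, x$delta_slope, x$rel_density))
  }
  invisible(x)
}

#' Fit settings for [fit_mutant()]
#'
#' @param tau_grid voltages (mV) over which the mutant time constant is
#'   regularized toward the wild-type time constant
#' @param maxit optimizer iteration cap
#' @param density_tol relative tolerance on the achieved current-density
#'   ratio (fit fails loudly beyond it)
#' @param protocol voltage-clamp protocol used to calibrate the conductance
#' @return list of class `fit_config`
#' @export
fit_config <- function(tau_grid = seq(-80, 60, by = 5), maxit = 500,
                       density_tol = 0.01, protocol = voltage_clamp_protocol()) {
  structure(list(tau_grid = tau_grid, maxit = maxit,
                 density_tol = density_tol, protocol = protocol),
            class = "fit_config")
}

#' Fit a mutant IKs model to a variant's summary statistics
#'
#' The activation-curve targets (`v_half_WT + delta_v_half`,
#' `slope_WT + delta_slope`) are imposed exactly through the derived
#' constants `x6' = exp(v_half'/slope')`, `x7' = -1/slope'`. The remaining
#' freedom in `(x1, x2)` is used to keep the activation time constant as
#' close as possible to wild type over `config$tau_grid` (`x5` is frozen at
#' the WT value; no per-variant time-constant data exist). Finally `g_ks` is
#' rescaled so the simulated mutant/WT current-density ratio under
#' `config$protocol` equals `rel_density`; the scaling is exact because the
#' end-of-step current is linear in `g_ks` at fixed kinetics.
#'
#' Complete-block variants keep the WT kinetics with `g_ks = 0`.
#'
#' @param wt wild-type `iks_parameters`
#' @param spec `mutant_spec`
#' @param config `fit_config`
#' @return object of class `fit_result`: `params` (fitted
#'   `iks_parameters`), `achieved_delta_v_half` / `achieved_delta_slope`
#'   (mV, from the fitted model's closed-form activation summary),
#'   `achieved_rel_density` (from simulated voltage clamp), `tau_deviation`
#'   (root-mean-square tau difference from WT over the grid, ms),
#'   `converged`, and the optimizer diagnostics
#' @export
fit_mutant <- function(wt, spec, config = fit_config()) {
  stopifnot(inherits(wt, "iks_parameters"), inherits(spec, "mutant_spec"),
            inherits(config, "fit_config"))
  wt_sum <- activation_summary(wt)

  if (spec$complete_block) {
    params <- iks_parameters(wt$x1, wt$x2, wt$x3, wt$x4, wt$x5, g_ks = 0)
    return(structure(
      list(name = spec$name, params = params,
           achieved_delta_v_half = 0, achieved_delta_slope = 0,
           achieved_rel_density = 0, tau_deviation = 0,
           converged = TRUE, optim = NULL),
      class = "fit_result"
    ))
  }

  v_half_t <- wt_sum$v_half + spec$delta_v_half
  slope_t <- wt_sum$slope_k + spec$delta_slope
  if (slope_t <= 0) {
    stop(sprintf("fit_mutant(%s): target slope %.3g mV is not positive; the gate would not activate",
                 spec$name, slope_t))
  }

  if (spec$delta_v_half == 0 && spec$delta_slope == 0) {
    # unchanged kinetics: the tau-regularized optimum is the WT kinetics
    # themselves, and the density calibration reduces to pure g_ks scaling
    params <- iks_parameters(wt$x1, wt$x2, wt$x3, wt$x4, wt$x5,
                             g_ks = wt$g_ks * spec$rel_density)
    return(structure(
      list(name = spec$name, params = params,
           achieved_delta_v_half = 0, achieved_delta_slope = 0,
           achieved_rel_density = spec$rel_density, tau_deviation = 0,
           converged = TRUE, optim = NULL),
      class = "fit_result"
    ))
  }

  tg <- activation_targets(v_half_t, slope_t)

  tau_wt <- activation_tau(wt, config$tau_grid)

  # kinetics with (x6', x7') imposed, parameterized by theta = (log x1, log x2)
  build <- function(theta) {
    x1 <- exp(theta[1])
    x2 <- exp(theta[2])
    inv_x4 <- tg$x7 + 1 / x2
    if (abs(inv_x4) < 1e-8) return(NULL) # x4 degenerate
    list(x1 = x1, x2 = x2, x3 = tg$x6 * x1, x4 = 1 / inv_x4, x5 = wt$x5)
  }
  objective <- function(theta) {
    k <- build(theta)
    if (is.null(k)) return(1e12)
    tau <- 1 / (k$x1 * .safe_exp(config$tau_grid / k$x2) +
                  k$x3 * .safe_exp(config$tau_grid / k$x4)) + k$x5
    mean((tau - tau_wt)^2)
  }
  theta0 <- c(log(wt$x1), log(wt$x2))
  opt <- stats::optim(theta0, objective, method = "Nelder-Mead",
                      control = list(maxit = config$maxit, reltol = 1e-12))
  k <- build(opt$par)
  if (is.null(k)) stop(sprintf("fit_mutant(%s): optimizer ended in a degenerate kinetic region", spec$name))
  cand <- iks_parameters(k$x1, k$x2, k$x3, k$x4, k$x5, g_ks = wt$g_ks)

  # conductance calibration: current is linear in g_ks at fixed kinetics
  i_wt <- simulate_voltage_clamp(wt, config$protocol)$reference_current
  i_cand <- simulate_voltage_clamp(cand, config$protocol)$reference_current
  if (!is.finite(i_wt) || abs(i_wt) < 1e-9) {
    stop("fit_mutant: WT reference current is ~0; density calibration ill-posed")
  }
  g_fit <- wt$g_ks * spec$rel_density * i_wt / i_cand
  params <- iks_parameters(k$x1, k$x2, k$x3, k$x4, k$x5, g_ks = g_fit)

  fit_sum <- activation_summary(params)
  achieved_density <- relative_current_density(params, wt, config$protocol)
  tau_fit <- activation_tau(params, config$tau_grid)
  res <- structure(
    list(name = spec$name, params = params,
         achieved_delta_v_half = fit_sum$v_half - wt_sum$v_half,
         achieved_delta_slope = fit_sum$slope_k - wt_sum$slope_k,
         achieved_rel_density = achieved_density,
         tau_deviation = sqrt(mean((tau_fit - tau_wt)^2)),
         converged = opt$convergence == 0, optim = opt),
    class = "fit_result"
  )
  if (abs(achieved_density - spec$rel_density) > config$density_tol * max(spec$rel_density, 1)) {
    stop(sprintf("fit_mutant(%s): achieved density %.4f misses target %.4f beyond tolerance",
                 spec$name, achieved_density, spec$rel_density))
  }
  if (!res$converged) {
    warning(sprintf("fit_mutant(%s): optimizer did not formally converge (tau RMS residual %.3g ms)",
                    spec$name, res$tau_deviation))
  }
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result %s: dV1/2 %+.3f mV, dk %+.3f mV, density %.4f, tau RMS dev %.2f ms\n",
              x$name, x$achieved_delta_v_half, x$achieved_delta_slope,
              x$achieved_rel_density, x$tau_deviation))
  invisible(x)
}

#' Parse a mutant summary table
#'
#' Comma-delimited text with header
#' `name, delta_v_half, delta_slope, rel_density, complete_block[, density_se]`.
#' Rows with `rel_density` empty or <= 0, or an explicit block flag, become
#' complete-block specs.
#'
#' @param path path to the table
#' @return list of `mutant_spec`, one per row (empty list, with a warning,
#'   for a header-only file)
#' @export
parse_mutant_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("name", "delta_v_half", "delta_slope", "rel_density", "complete_block")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("parse_mutant_table: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("parse_mutant_table: empty mutant table ", path)
    return(list())
  }
  if (anyDuplicated(df$name)) {
    dup <- df$name[duplicated(df$name)][1]
    stop("parse_mutant_table: duplicate variant name '", dup, "' at row ",
         which(df$name == dup)[2])
  }
  has_se <- "density_se" %in% names(df)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    num <- function(col, allow_na = FALSE) {
      v <- suppressWarnings(as.numeric(row[[col]]))
      raw <- row[[col]]
      empty <- is.na(raw) || (is.character(raw) && !nzchar(trimws(raw)))
      if (is.na(v) && !empty) {
        stop(sprintf("parse_mutant_table: non-numeric '%s' in column %s, row %d", raw, col, i))
      }
      if (is.na(v) && !allow_na) {
        stop(sprintf("parse_mutant_table: missing value in column %s, row %d", col, i))
      }
      v
    }
    block_raw <- row[["complete_block"]]
    block <- if (is.logical(block_raw)) isTRUE(block_raw) else {
      bv <- suppressWarnings(as.numeric(block_raw))
      if (is.na(bv)) stop(sprintf("parse_mutant_table: non-numeric block flag row %d", i))
      bv != 0
    }
    mutant_spec(
      name = as.character(row[["name"]]),
      delta_v_half = num("delta_v_half"),
      delta_slope = num("delta_slope"),
      rel_density = num("rel_density", allow_na = TRUE),
      complete_block = block,
      density_se = if (has_se) num("density_se", allow_na = TRUE) else NA_real_
    )
  })
}

#' Write a mutant summary table
#'
#' Inverse of [parse_mutant_table()].
#'
#' @param specs list of `mutant_spec`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mutant_table <- function(specs, path) {
  df <- data.frame(
    name = vapply(specs, `[[`, character(1), "name"),
    delta_v_half = vapply(specs, `[[`, numeric(1), "delta_v_half"),
    delta_slope = vapply(specs, `[[`, numeric(1), "delta_slope"),
    rel_density = vapply(specs, `[[`, numeric(1), "rel_density"),
    complete_block = as.integer(vapply(specs, `[[`, logical(1), "complete_block")),
    density_se = vapply(specs, `[[`, numeric(1), "density_se"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Density-sensitivity variants of a spec
#'
#' Expands one non-blocked variant into several with the relative current
#' density multiplied by each entry of `multipliers` (used for
#' density-uncertainty sweeps, e.g. +/-4% and +/-8% of the measured
#' conductance scaling). A multiplier of 0 yields a complete-block spec.
#'
#' @param spec non-blocked `mutant_spec`
#' @param multipliers numeric fractions (>= 0)
#' @return list of `mutant_spec` with suffixed names
#' @export
scale_density_variants <- function(spec, multipliers) {
  stopifnot(inherits(spec, "mutant_spec"))
  if (spec$complete_block) stop("scale_density_variants: spec is a complete block")
  if (length(multipliers) == 0) return(list())
  if (any(!is.finite(multipliers) | multipliers < 0)) {
    stop("scale_density_variants: multipliers must be finite and >= 0")
  }
  lapply(multipliers, function(m) {
    mutant_spec(
      name = sprintf("%s_x%.4g", spec$name, m),
      delta_v_half = spec$delta_v_half,
      delta_slope = spec$delta_slope,
      rel_density = spec$rel_density * m,
      density_se = spec$density_se
    )
  })
}

#' Fit every variant in a table and write the results
#'
#' Runs [fit_mutant()] for each spec, writes one IKs parameter file per
#' variant plus a delimited fit summary into `out_dir`.
#'
#' @param wt wild-type `iks_parameters`
#' @param specs list of `mutant_spec` (e.g. from [parse_mutant_table()])
#' @param out_dir output directory (created if needed)
#' @param config `fit_config`
#' @return data.frame fit summary, invisibly; also written to
#'   `out_dir/fit_summary.csv`
#' @export
fit_mutant_table <- function(wt, specs, out_dir, config = fit_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- lapply(specs, function(s) fit_mutant(wt, s, config))
  for (f in fits) {
    write_iks_parameters(f$params, file.path(out_dir, paste0(f$name, ".iks")))
  }
  summary_df <- data.frame(
    name = vapply(fits, `[[`, character(1), "name"),
    achieved_delta_v_half = vapply(fits, `[[`, numeric(1), "achieved_delta_v_half"),
    achieved_delta_slope = vapply(fits, `[[`, numeric(1), "achieved_delta_slope"),
    achieved_rel_density = vapply(fits, `[[`, numeric(1), "achieved_rel_density"),
    tau_deviation = vapply(fits, `[[`, numeric(1), "tau_deviation"),
    g_ks = vapply(fits, function(f) f$params$g_ks, numeric(1)),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(summary_df, file.path(out_dir, "fit_summary.csv"), row.names = FALSE)
  invisible(summary_df)
}
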