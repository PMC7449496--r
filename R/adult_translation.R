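# Translation of fitted iPSC-CM IKs variants into a paced adult ventricular
# myocyte model: the variant's kinetics are kept verbatim and only the
# maximal conductance is rescaled (default x3.5) to the adult expression
# level; APD90 and triangulation are then read off steady paced beats at
# several cycle lengths.

#' Adult-translation configuration
#'
#' @param g_ks_scale conductance scaling from the iPSC-CM to the adult
#'   expression level (default 3.5)
#' @param bcl basic cycle lengths (ms; default 750, 1000, 1250)
#' @param stim_amp stimulus amplitude (pA/pF, negative = inward; default -40)
#' @param stim_dur stimulus duration (ms, default 1)
#' @param pre_beats paced beats to steady pacing before measurement
#'   (default 500)
#' @param base adult baseline configuration
#' @return object of class `adult_config`
#' @export
adult_config <- function(g_ks_scale = 3.5, bcl = c(750, 1000, 1250),
                         stim_amp = -40, stim_dur = 1, pre_beats = 500,
                         base = adult_cell_config()) {
  if (g_ks_scale <= 0) stop("adult_config: g_ks_scale must be > 0")
  if (any(bcl <= stim_dur)) stop("adult_config: bcl must exceed the stimulus duration")
  structure(list(g_ks_scale = g_ks_scale, bcl = bcl, stim_amp = stim_amp,
                 stim_dur = stim_dur, pre_beats = as.integer(pre_beats),
                 base = base),
            class = "adult_config")
}

#' Adapt an IKs model to the adult expression level
#'
#' Multiplies `g_ks` by `config$g_ks_scale`; all kinetic parameters
#' (`x1..x5`) are retained verbatim. A complete block stays a complete
#' block.
#'
#' @param iks fitted (or WT) `iks_parameters`
#' @param config `adult_config`
#' @return adult `iks_parameters`
#' @export
adapt_iks <- function(iks, config = adult_config()) {
  stopifnot(inherits(iks, "iks_parameters"))
  iks_parameters(iks$x1, iks$x2, iks$x3, iks$x4, iks$x5,
                 g_ks = iks$g_ks * config$g_ks_scale)
}

# one paced beat: stimulus phase (finely stepped) then the rest of the cycle
.paced_beat <- function(p, state, bcl, stim_amp, stim_dur, dt_out, rtol, atol) {
  tr1 <- simulate_cell(p, state, stim_dur, dt_out = min(dt_out, 0.25),
                       hmax = 0.25, i_inject = -stim_amp,
                       rtol = rtol, atol = atol)
  tr2 <- simulate_cell(p, final_state(tr1), bcl - stim_dur, dt_out = dt_out,
                       rtol = rtol, atol = atol)
  tr2$time <- tr2$time + stim_dur
  list(trace = rbind(as.data.frame(tr1)[-nrow(tr1), ], as.data.frame(tr2)),
       state = final_state(tr2))
}

#' Pace the adult model and measure the last beat
#'
#' Paces the adult cell for `config$pre_beats` conditioning beats at cycle
#' length `bcl`, then measures the final beat. APD is referenced to the
#' stimulus onset; the diastolic reference (MDP) is the minimum voltage of
#' the measured cycle. A beat that fails to repolarize to the 90% level is
#' flagged, not fatal.
#'
#' @param iks_adult adult `iks_parameters` (from [adapt_iks()])
#' @param bcl basic cycle length (ms)
#' @param config `adult_config`
#' @param initial starting state (default [default_adult_state()])
#' @return list: `apd30`, `apd50`, `apd90`, `triangulation` (ms), `peak`,
#'   `mdp`, `amplitude` (mV), `failure` (logical), `bcl`
#' @export
run_paced <- function(iks_adult, bcl, config = adult_config(),
                      initial = default_adult_state()) {
  stopifnot(inherits(iks_adult, "iks_parameters"))
  p <- cell_parameters(iks = iks_adult, base = config$base)
  state <- initial
  # conditioning beats: coarse output grid, state chaining only
  for (b in seq_len(config$pre_beats)) {
    bt <- .paced_beat(p, state, bcl, config$stim_amp, config$stim_dur,
                      dt_out = bcl, rtol = 1e-6, atol = 1e-8)
    state <- bt$state
  }
  bt <- .paced_beat(p, state, bcl, config$stim_amp, config$stim_dur,
                    dt_out = 0.5, rtol = 1e-6, atol = 1e-8)
  tr <- bt$trace
  peak <- max(tr$vm)
  ipk <- which.max(tr$vm)
  mdp <- min(tr$vm)
  amplitude <- peak - mdp
  level_time <- function(level) {
    thr <- peak - (level / 100) * (peak - mdp)
    post <- tr[ipk:nrow(tr), ]
    i2 <- which(post$vm <= thr)[1]
    if (is.na(i2)) return(NA_real_)
    if (i2 == 1) return(post$time[1])
    t1 <- post$time[i2 - 1]; v1 <- post$vm[i2 - 1]
    t2 <- post$time[i2]; v2 <- post$vm[i2]
    if (v2 == v1) t2 else t1 + (thr - v1) / (v2 - v1) * (t2 - t1)
  }
  a30 <- level_time(30); a50 <- level_time(50); a90 <- level_time(90)
  failure <- is.na(a90) || amplitude <= 40
  list(apd30 = a30, apd50 = a50, apd90 = a90,
       triangulation = if (is.na(a90) || is.na(a30)) NA_real_ else a90 - a30,
       peak = peak, mdp = mdp, amplitude = amplitude,
       failure = failure, bcl = bcl)
}

#' Calibrate the adult conductance scale against a target APD90
#'
#' Bisection on the `g_ks` multiplier applied to `iks` until the paced
#' adult APD90 at `bcl` matches `target_apd90` within `tol` ms. APD90 is
#' monotone decreasing in the IKs conductance, which the search verifies on
#' its initial bracket.
#'
#' @param iks reference `iks_parameters` (scale 1 = its own conductance)
#' @param target_apd90 target APD90 (ms)
#' @param bcl cycle length (ms)
#' @param config `adult_config` (its `g_ks_scale` is ignored here)
#' @param bracket initial multiplier bracket (default 0.05 .. 40)
#' @param tol APD90 tolerance (ms, default 1)
#' @param max_iter bisection cap
#' @return list: `scale` (the multiplier), `apd90` (achieved),
#'   `iterations`; errors with the bracketing values when the target is
#'   unreachable
#' @export
calibrate_scale <- function(iks, target_apd90, bcl, config = adult_config(),
                            bracket = c(0.05, 40), tol = 1, max_iter = 60) {
  apd_at <- function(s) {
    scaled <- iks_parameters(iks$x1, iks$x2, iks$x3, iks$x4, iks$x5,
                             g_ks = iks$g_ks * s)
    run_paced(scaled, bcl, config)$apd90
  }
  lo <- bracket[1]; hi <- bracket[2]
  a_lo <- apd_at(lo)  # low conductance -> long APD
  a_hi <- apd_at(hi)
  if (is.na(a_lo) || is.na(a_hi)) {
    stop("calibrate_scale: repolarization failure at a bracket end; narrow the bracket")
  }
  if (!(a_hi <= target_apd90 && target_apd90 <= a_lo)) {
    stop(sprintf("calibrate_scale: target %.1f ms outside reachable range [%.1f, %.1f] ms for multipliers [%g, %g]",
                 target_apd90, a_hi, a_lo, lo, hi))
  }
  it <- 0
  repeat {
    it <- it + 1
    mid <- sqrt(lo * hi)  # bisect in log space: conductances span decades
    a_mid <- apd_at(mid)
    if (abs(a_mid - target_apd90) < tol || it >= max_iter) {
      return(list(scale = mid, apd90 = a_mid, iterations = it))
    }
    if (a_mid > target_apd90) lo <- mid else hi <- mid
  }
}

#' Translate a set of fitted variants into the adult model
#'
#' Adapts each variant with [adapt_iks()] and measures APD90 and
#' triangulation at every configured cycle length.
#'
#' @param fits named list of `iks_parameters` (e.g. `params` of
#'   [fit_mutant()] results)
#' @param config `adult_config`
#' @return data.frame: one row per (variant, bcl) with `apd90`,
#'   `triangulation`, `failure`
#' @export
adult_translation_table <- function(fits, config = adult_config()) {
  rows <- list()
  for (nm in names(fits)) {
    adult <- adapt_iks(fits[[nm]], config)
    for (b in config$bcl) {
      m <- run_paced(adult, b, config)
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, bcl = b, apd90 = m$apd90, apd30 = m$apd30,
        triangulation = m$triangulation, peak = m$peak, mdp = m$mdp,
        failure = m$failure, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
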