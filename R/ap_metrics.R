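# Action-potential detection and morphology metrics, the physiological
# noise current, and the 40-beat noise statistics (triangulation and
# beat-to-beat variability of APD90).

#' Physiological noise-current configuration
#'
#' Additive Gaussian white noise, discretized as a piecewise-constant
#' current held over each update interval. The amplitude is the per-sample
#' standard deviation.
#'
#' @param sigma noise amplitude (pA/pF, >= 0; default 0.045)
#' @param update_interval hold interval (ms, > 0; default 1)
#' @param seed integer seed making the realization reproducible
#' @return object of class `noise_config`
#' @export
noise_config <- function(sigma = 0.045, update_interval = 1, seed = 1L) {
  if (!is.finite(sigma) || sigma < 0) stop("noise_config: sigma must be >= 0")
  if (!is.finite(update_interval) || update_interval <= 0) {
    stop("noise_config: update_interval must be > 0")
  }
  structure(list(sigma = sigma, update_interval = update_interval,
                 seed = as.integer(seed)),
            class = "noise_config")
}

# evaluate fn with a private RNG stream; global .Random.seed is untouched
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate a piecewise-constant noise-current realization
#'
#' Independent zero-mean normal draws with standard deviation
#' `config$sigma`, each held for `config$update_interval` ms. The same seed
#' always yields the same signal; the global RNG state is left untouched.
#'
#' @param config `noise_config`
#' @param duration signal length (ms, > 0)
#' @return data.frame with `time` (segment start, ms) and `current` (pA/pF);
#'   the last row repeats the final value at `duration` so the signal spans
#'   the full interval
#' @export
generate_noise <- function(config, duration) {
  stopifnot(inherits(config, "noise_config"))
  if (!is.finite(duration) || duration <= 0) {
    stop("generate_noise: duration must be > 0")
  }
  n <- ceiling(duration / config$update_interval)
  draws <- if (config$sigma == 0) rep(0, n) else {
    .with_seed(config$seed, function() stats::rnorm(n, mean = 0, sd = config$sigma))
  }
  t0 <- (seq_len(n) - 1) * config$update_interval
  data.frame(time = c(t0, duration), current = c(draws, draws[n]))
}

#' Detect action potentials in a voltage trace
#'
#' Upstrokes are located at the maximum of dVm/dt preceding each upward
#' 0 mV crossing; each AP segment runs upstroke-to-upstroke (the final
#' segment ends at the trace end and is kept only if the voltage
#' substantially repolarizes after its peak). Quiescent traces give an
#' empty list.
#'
#' @param trace `sim_trace` or any data.frame with `time` and `vm`
#' @return list of `ap_segment` objects, each with `time`, `vm`, `peak`,
#'   `mdp` (minimum vm after the peak), `t_upstroke`, `t_peak` and
#'   `cycle_length` (NA for the final, open-ended segment)
#' @export
detect_aps <- function(trace) {
  tt <- trace$time
  vm <- trace$vm
  cross <- which(vm[-length(vm)] <= 0 & vm[-1] > 0)
  if (length(cross) == 0) return(list())

  dvdt <- c(diff(vm) / diff(tt), 0)
  upstroke_idx <- integer(length(cross))
  prev_bound <- 1
  for (k in seq_along(cross)) {
    lo <- if (k == 1) 1 else {
      # search from the diastolic minimum between this crossing and the last
      between <- cross[k - 1]:cross[k]
      between[which.min(vm[between])]
    }
    win <- lo:cross[k]
    upstroke_idx[k] <- win[which.max(dvdt[win])]
  }
  # refine each upstroke instant by the parabolic vertex of dVm/dt around
  # its grid maximum, so APD is insensitive to the output-grid spacing
  refine <- function(i) {
    if (i <= 1 || i >= length(vm) - 1) return(tt[i])
    d0 <- dvdt[i - 1]; d1 <- dvdt[i]; d2 <- dvdt[i + 1]
    den <- d0 - 2 * d1 + d2
    if (!is.finite(den) || den >= 0) return(tt[i])
    frac <- 0.5 * (d0 - d2) / den
    tt[i] + max(-0.5, min(0.5, frac)) * (tt[i + 1] - tt[i])
  }
  bounds <- c(upstroke_idx, length(vm))
  segs <- vector("list", length(upstroke_idx))
  for (k in seq_along(upstroke_idx)) {
    idx <- bounds[k]:bounds[k + 1]
    v <- vm[idx]
    ipk <- which.max(v)
    mdp <- if (ipk < length(v)) min(v[ipk:length(v)]) else NA_real_
    segs[[k]] <- structure(
      list(time = tt[idx], vm = v,
           peak = v[ipk], mdp = mdp,
           t_upstroke = refine(idx[1]), t_peak = tt[idx[ipk]],
           cycle_length = if (k < length(upstroke_idx)) {
             tt[bounds[k + 1]] - tt[bounds[k]]
           } else NA_real_),
      class = "ap_segment")
  }
  # drop an open-ended final segment that has not substantially repolarized
  last <- segs[[length(segs)]]
  if (is.na(last$mdp) || last$mdp > -40) segs <- segs[-length(segs)]
  segs
}

.repol_failure <- function(msg) {
  stop(errorCondition(msg, class = c("repolarization_failure", "error", "condition")))
}

#' Action-potential duration at a repolarization level
#'
#' Time from the upstroke (maximal dVm/dt) to the first downward crossing of
#' `peak - (level/100) * (peak - mdp)` after the peak, by linear
#' interpolation. A segment that never recrosses the level signals a
#' repolarization failure (condition class `repolarization_failure`).
#'
#' @param segment `ap_segment` from [detect_aps()]
#' @param level percent repolarization: 30, 50 or 90
#' @return duration (ms)
#' @export
apd <- function(segment, level) {
  stopifnot(inherits(segment, "ap_segment"))
  if (!level %in% c(30, 50, 90)) stop("apd: level must be 30, 50 or 90")
  if (is.na(segment$mdp)) .repol_failure("segment has no post-peak data")
  thr <- segment$peak - (level / 100) * (segment$peak - segment$mdp)
  ipk <- which.max(segment$vm)
  v <- segment$vm
  tt <- segment$time
  after <- ipk:length(v)
  below <- which(v[after] <= thr)
  if (length(below) == 0) {
    .repol_failure(sprintf("AP never repolarizes to %d%% level", level))
  }
  i2 <- after[below[1]]
  if (i2 == ipk) return(tt[ipk] - segment$t_upstroke)
  i1 <- i2 - 1
  t_cross <- if (v[i2] == v[i1]) tt[i2] else {
    tt[i1] + (thr - v[i1]) / (v[i2] - v[i1]) * (tt[i2] - tt[i1])
  }
  t_cross - segment$t_upstroke
}

#' AP triangulation
#'
#' APD90 - APD30; larger values mean slower terminal repolarization.
#' Propagates the `repolarization_failure` condition from [apd()].
#'
#' @param segment `ap_segment`
#' @return triangulation (ms, >= 0)
#' @export
triangulation <- function(segment) {
  apd(segment, 90) - apd(segment, 30)
}

#' Morphology metrics of one AP
#'
#' @param segment `ap_segment`
#' @return list: `apd30`, `apd50`, `apd90` (ms), `peak`, `mdp`, `amplitude`
#'   (mV), `triangulation` (ms), `cycle_length` (ms, NA for a final segment)
#' @export
ap_morphology <- function(segment) {
  a30 <- apd(segment, 30)
  a50 <- apd(segment, 50)
  a90 <- apd(segment, 90)
  list(apd30 = a30, apd50 = a50, apd90 = a90,
       peak = segment$peak, mdp = segment$mdp,
       amplitude = segment$peak - segment$mdp,
       triangulation = a90 - a30,
       cycle_length = segment$cycle_length)
}

#' Beat-to-beat variability of APD90
#'
#' Mean of the absolute successive differences |APD90_n - APD90_{n+1}|
#' (39 differences for the canonical 40-beat series).
#'
#' @param apd90_series numeric vector of per-beat APD90 (length >= 2)
#' @return variability (ms, >= 0)
#' @export
beat_to_beat_variability <- function(apd90_series) {
  if (length(apd90_series) < 2) {
    stop("beat_to_beat_variability: need at least 2 beats")
  }
  mean(abs(diff(apd90_series)))
}

#' Early-afterdepolarization check for one AP
#'
#' Flags any positive voltage excursion exceeding `threshold` mV during the
#' repolarization phase (between the downward +10 mV crossing and the MDP).
#'
#' @param segment `ap_segment`
#' @param threshold minimum rise counted as an EAD (mV, default 1)
#' @return logical
#' @export
has_ead <- function(segment, threshold = 1) {
  v <- segment$vm
  ipk <- which.max(v)
  post <- v[ipk:length(v)]
  start <- which(post <= 10)[1]
  if (is.na(start)) return(FALSE)
  imdp <- which.min(post)
  if (imdp <= start) return(FALSE)
  w <- post[start:imdp]
  rises <- diff(w)
  if (all(rises <= 0)) return(FALSE)
  # total rise of each contiguous upward run
  r <- rle(rises > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  up_runs <- which(r$values)
  any(vapply(up_runs, function(i) sum(rises[starts[i]:ends[i]]), numeric(1)) > threshold)
}

#' Alternans check on an APD90 series
#'
#' Alternans = strictly alternating sign of successive APD90 differences
#' with mean |difference| above `threshold` over the inspected beats.
#'
#' @param apd90_series per-beat APD90 (uses the last `n_last` beats)
#' @param threshold mean absolute difference cut-off (ms, default 5)
#' @param n_last number of trailing beats inspected (default 6)
#' @return logical
#' @export
has_alternans <- function(apd90_series, threshold = 5, n_last = 6) {
  s <- utils::tail(apd90_series, n_last)
  if (length(s) < 3) return(FALSE)
  d <- diff(s)
  if (any(d == 0)) return(FALSE)
  alternating <- all(sign(d[-1]) * sign(d[-length(d)]) < 0)
  alternating && mean(abs(d)) > threshold
}

#' Run the physiological noise protocol on one cell
#'
#' Simulates the cell with the piecewise-constant noise current until
#' `n_beats` complete APs accrue (within a simulated-time cap), then returns
#' the beat-series statistics: per-beat APD90, mean triangulation and
#' beat-to-beat variability, with per-beat EAD flags.
#'
#' @param p `cell_parameters`
#' @param initial starting state (typically a steady state)
#' @param noise `noise_config`
#' @param n_beats beats to analyze (default 40)
#' @param max_time simulated-time cap (ms, default 90 s)
#' @param est_cycle_length optional cycle-length estimate (ms, e.g. from a
#'   noise-free metric run); when given, the simulated window is
#'   `(n_beats + 3) * est_cycle_length` (still capped at `max_time`)
#' @return object of class `beat_series_metrics`: `n_beats` (achieved),
#'   `apd90` (series, ms), `mean_triangulation` (ms), `b2b_variability`
#'   (ms), `ead_beats` (count), `repol_failure_beats` (count), `partial`
#'   (TRUE when fewer than `n_beats` usable beats accrued), `noise_seed`
#' @export
run_noise_protocol <- function(p, initial, noise = noise_config(),
                               n_beats = 40, max_time = 90000,
                               est_cycle_length = NULL) {
  stopifnot(inherits(p, "cell_parameters"), inherits(noise, "noise_config"))
  duration <- if (is.null(est_cycle_length) || !is.finite(est_cycle_length)) {
    max_time
  } else {
    min(max_time, (n_beats + 3) * est_cycle_length)
  }
  trace <- simulate_cell(p, initial, duration, noise = noise, dt_out = 1)
  segs <- detect_aps(trace)
  # drop the final open-ended segment from beat statistics
  segs <- Filter(function(s) !is.na(s$cycle_length), segs)
  if (length(segs) > n_beats) segs <- segs[seq_len(n_beats)]
  apd90 <- numeric(0)
  tria <- numeric(0)
  ead <- 0L
  failures <- 0L
  for (s in segs) {
    m <- tryCatch(list(a90 = apd(s, 90), tri = triangulation(s)),
                  repolarization_failure = function(e) NULL)
    if (is.null(m)) {
      failures <- failures + 1L
      next
    }
    apd90 <- c(apd90, m$a90)
    tria <- c(tria, m$tri)
    if (has_ead(s)) ead <- ead + 1L
  }
  structure(
    list(n_beats = length(apd90),
         apd90 = apd90,
         mean_triangulation = if (length(tria)) mean(tria) else NA_real_,
         b2b_variability = if (length(apd90) >= 2) {
           beat_to_beat_variability(apd90)
         } else NA_real_,
         ead_beats = ead,
         repol_failure_beats = failures,
         partial = length(apd90) < n_beats,
         noise_seed = noise$seed),
    class = "beat_series_metrics"
  )
}

#' Summary AP metrics of a noise-free run
#'
#' Mean morphology over all complete APs of a trace; used for the APD90
#' severity criterion and the inclusion screen.
#'
#' @param trace `sim_trace`
#' @return list: `apd30`, `apd50`, `apd90`, `triangulation`, `amplitude`,
#'   `peak`, `mdp`, `cycle_length` (means over beats), `n_beats`,
#'   `repol_failure_beats`, `ead_beats`, `alternans`
#' @export
trace_metrics <- function(trace) {
  segs <- Filter(function(s) !is.na(s$cycle_length), detect_aps(trace))
  if (length(segs) == 0) {
    return(list(apd30 = NA_real_, apd50 = NA_real_, apd90 = NA_real_,
                triangulation = NA_real_, amplitude = NA_real_,
                peak = NA_real_, mdp = NA_real_, cycle_length = NA_real_,
                n_beats = 0L, repol_failure_beats = 0L, ead_beats = 0L,
                alternans = FALSE))
  }
  ms <- lapply(segs, function(s) {
    tryCatch(ap_morphology(s), repolarization_failure = function(e) NULL)
  })
  ok <- !vapply(ms, is.null, logical(1))
  failures <- sum(!ok)
  ms <- ms[ok]
  eads <- sum(vapply(segs[ok], has_ead, logical(1)))
  if (length(ms) == 0) {
    return(list(apd30 = NA_real_, apd50 = NA_real_, apd90 = NA_real_,
                triangulation = NA_real_, amplitude = NA_real_,
                peak = NA_real_, mdp = NA_real_, cycle_length = NA_real_,
                n_beats = 0L, repol_failure_beats = failures,
                ead_beats = eads, alternans = FALSE))
  }
  avg <- function(f) mean(vapply(ms, `[[`, numeric(1), f))
  apd90s <- vapply(ms, `[[`, numeric(1), "apd90")
  list(apd30 = avg("apd30"), apd50 = avg("apd50"), apd90 = avg("apd90"),
       triangulation = avg("triangulation"), amplitude = avg("amplitude"),
       peak = avg("peak"), mdp = avg("mdp"),
       cycle_length = avg("cycle_length"),
       n_beats = length(ms), repol_failure_beats = failures,
       ead_beats = eads, alternans = has_alternans(apd90s))
}
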