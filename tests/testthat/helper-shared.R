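# Shared, lazily computed fixtures. The population experiment is the
# expensive piece (minutes); it is computed once per test run and reused by
# the population, severity and acceptance tests.

.shared <- new.env(parent = emptyenv())

# baseline WT cell at steady state with a 20 s noise-free trace
shared_wt_cell <- function() {
  if (is.null(.shared$wt_cell)) {
    p <- cell_parameters()
    ss <- run_to_steady_state(p)
    trace <- simulate_cell(p, ss$state, 20000)
    .shared$wt_cell <- list(p = p, steady = ss, trace = trace,
                            metrics = trace_metrics(trace))
  }
  .shared$wt_cell
}

# fitted mutants of the density ladder used across tests
shared_fits <- function() {
  if (is.null(.shared$fits)) {
    wt <- wt_iks_parameters()
    .shared$fits <- list(
      identity = fit_mutant(wt, mutant_spec("identity", 0, 0, 1))$params,
      d08 = fit_mutant(wt, mutant_spec("d08", 0, 0, 0.8))$params,
      d05 = fit_mutant(wt, mutant_spec("d05", 0, 0, 0.5))$params,
      d02 = fit_mutant(wt, mutant_spec("d02", 0, 0, 0.2))$params,
      block = fit_mutant(wt, mutant_spec("block", complete_block = TRUE))$params
    )
  }
  .shared$fits
}

# the seeded population experiment: 20-cell population, WT screen, and the
# density ladder {identity, 0.8, 0.5, 0.2, block} applied cell by cell
shared_experiment <- function() {
  if (is.null(.shared$experiment)) {
    cfg <- population_config(n = 20, seed = 42)
    pop <- screen_inclusion(generate_population(cfg), cfg)
    fits <- shared_fits()
    results <- lapply(names(fits), function(nm) {
      apply_mutant(pop, fits[[nm]], name = nm)
    })
    names(results) <- names(fits)
    .shared$experiment <- list(config = cfg, population = pop,
                               fits = fits, results = results)
  }
  .shared$experiment
}

# random IKs parameter sets with a valid activating gate
random_iks <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v_half <- runif(1, -40, 10)
    slope <- runif(1, 8, 25)
    x1 <- 10^runif(1, -3.5, -2.5)
    x2 <- runif(1, 25, 80)
    x7 <- -1 / slope
    x4 <- 1 / (x7 + 1 / x2)
    iks_parameters(x1, x2, exp(v_half / slope) * x1, x4,
                   x5 = runif(1, 0, 60), g_ks = runif(1, 0.05, 0.5))
  })
}

# a synthetic AP trace: linear rise to `peak`, hold, linear ramp to `mdp`
ramp_ap_trace <- function(peak = 40, mdp = -60, hold = 50, ramp = 100,
                          diastole = 400, dt = 0.1, n_beats = 2, rise = 2) {
  nr <- max(2, round(rise / dt))
  one <- c(seq(mdp, peak, length.out = nr + 1)[-(nr + 1)],
           rep(peak, hold / dt),
           seq(peak, mdp, length.out = max(2, round(ramp / dt)) + 1)[-1],
           rep(mdp, diastole / dt))
  vm <- c(rep(mdp, 100), rep(one, n_beats))
  data.frame(time = seq_along(vm) * dt, vm = vm)
}
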