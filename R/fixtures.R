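# Synthetic-data generation and end-to-end orchestration: random mutant
# summary tables shaped like automated patch-clamp variant screens, a
# single-config pipeline (fit -> population -> apply -> classify -> adult),
# and run manifests for reproducibility.

#' Fixture-generation configuration
#'
#' Ranges emulate the spread of variant summary statistics seen in
#' automated patch-clamp screens of KCNQ1: half-activation shifts of a few
#' tens of mV, modest slope changes, densities from near-zero loss to
#' ~1.5x gain of function, and a fraction of variants with unmeasurably
#' small current (complete block).
#'
#' @param n number of variants (>= 0)
#' @param dvh_range range of delta V_1/2 (mV)
#' @param dslope_range range of delta slope (mV); kept above `-slope_WT`
#' @param density_range range of relative current density
#' @param block_prob probability a variant is a complete block
#' @param seed integer seed
#' @return object of class `fixture_config`
#' @export
fixture_config <- function(n, dvh_range = c(-15, 30), dslope_range = c(-4, 8),
                           density_range = c(0.05, 1.5), block_prob = 0.2,
                           seed = 1L) {
  if (n < 0) stop("fixture_config: n must be >= 0")
  if (block_prob < 0 || block_prob > 1) stop("fixture_config: block_prob in [0,1]")
  if (density_range[1] < 0) stop("fixture_config: densities must be >= 0")
  structure(list(n = as.integer(n), dvh_range = dvh_range,
                 dslope_range = dslope_range, density_range = density_range,
                 block_prob = block_prob, seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a synthetic mutant summary table
#'
#' Draws `n` variants uniformly within the configured ranges (deterministic
#' from the seed) and writes a table parseable by [parse_mutant_table()].
#' For `n >= 10` the table is guaranteed to contain at least one
#' complete-block row and one gain-of-function row (density > 1).
#'
#' @param config `fixture_config`
#' @param path output path
#' @return the list of `mutant_spec` written, invisibly
#' @export
generate_mutant_fixtures <- function(config, path) {
  stopifnot(inherits(config, "fixture_config"))
  n <- config$n
  if (n == 0) {
    write_mutant_table(list(), path)
    return(invisible(list()))
  }
  specs <- .with_seed(config$seed, function() {
    dvh <- stats::runif(n, config$dvh_range[1], config$dvh_range[2])
    dsl <- stats::runif(n, config$dslope_range[1], config$dslope_range[2])
    dens <- stats::runif(n, config$density_range[1], config$density_range[2])
    blocked <- stats::runif(n) < config$block_prob
    if (n >= 10) {
      if (!any(blocked)) blocked[n] <- TRUE
      gof_possible <- config$density_range[2] > 1
      if (gof_possible && !any(dens > 1 & !blocked)) {
        k <- which(!blocked)[1]
        dens[k] <- stats::runif(1, 1, config$density_range[2])
      }
    }
    lapply(seq_len(n), function(i) {
      if (blocked[i]) {
        mutant_spec(sprintf("M%03d", i), round(dvh[i], 2), round(dsl[i], 2),
                    complete_block = TRUE)
      } else {
        mutant_spec(sprintf("M%03d", i), round(dvh[i], 2), round(dsl[i], 2),
                    rel_density = round(dens[i], 3))
      }
    })
  })
  write_mutant_table(specs, path)
  invisible(specs)
}

#' Default pipeline configuration
#'
#' @param mutant_table path to a mutant summary table
#' @param out_dir output directory
#' @param wt_params optional path to a WT IKs parameter file (default: the
#'   shipped [wt_iks_parameters()])
#' @param n,sigma,seed,noise_base_seed population settings
#' @param noise_sigma noise amplitude (pA/pF)
#' @param n_beats noise-protocol beats
#' @param criterion_threshold_pct,pathogenic_cutoff_pct,benign_cutoff_pct
#'   severity settings
#' @param adult run the adult translation stage (logical)
#' @param g_ks_scale,bcl,pre_beats adult-translation settings
#' @return nested configuration list
#' @export
pipeline_config <- function(mutant_table, out_dir,
                            wt_params = NULL,
                            n = 20, sigma = 0.4, seed = 1L,
                            noise_base_seed = 10000L,
                            noise_sigma = 0.045, n_beats = 40,
                            criterion_threshold_pct = 4,
                            pathogenic_cutoff_pct = 4.6,
                            benign_cutoff_pct = 0.25,
                            adult = FALSE, g_ks_scale = 3.5,
                            bcl = c(750, 1000, 1250), pre_beats = 500) {
  list(
    wt_params = wt_params,
    mutant_table = mutant_table,
    out_dir = out_dir,
    population = list(n = n, sigma = sigma, seed = seed,
                      noise_base_seed = noise_base_seed),
    noise = list(sigma = noise_sigma, n_beats = n_beats),
    severity = list(criterion_threshold_pct = criterion_threshold_pct,
                    pathogenic_cutoff_pct = pathogenic_cutoff_pct,
                    benign_cutoff_pct = benign_cutoff_pct),
    adult = list(enabled = adult, g_ks_scale = g_ks_scale, bcl = bcl,
                 pre_beats = pre_beats)
  )
}

.validate_pipeline_config <- function(cfg) {
  need <- c("mutant_table", "out_dir", "population", "noise", "severity", "adult")
  for (field in need) {
    if (is.null(cfg[[field]])) stop("pipeline config: missing field '", field, "'")
  }
  for (field in c("n", "sigma", "seed")) {
    if (is.null(cfg$population[[field]])) {
      stop("pipeline config: missing field 'population.", field, "'")
    }
  }
  if (!file.exists(cfg$mutant_table)) {
    stop("pipeline config: mutant_table file not found: ", cfg$mutant_table)
  }
  invisible(cfg)
}

#' Run the whole variant-classification pipeline
#'
#' Stages: fit every variant in the table; generate and screen the
#' population; apply each fitted variant; classify severity; optionally
#' translate every variant to the adult model. All tables are written under
#' `config$out_dir`, together with a YAML run manifest (config, seeds,
#' per-stage outputs and timings). With `resume = TRUE`, stages whose
#' outputs already exist are reloaded from the checkpoint instead of re-run.
#'
#' @param config nested list from [pipeline_config()], or the path of a YAML
#'   file with the same structure
#' @param resume reuse existing stage outputs (default FALSE)
#' @return the run manifest, invisibly
#' @export
run_pipeline <- function(config, resume = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ckpt <- file.path(out, "checkpoints")
  dir.create(ckpt, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("iksvar")),
                   config = config, stages = list())
  stamp <- function(stage, t0, outputs) {
    manifest$stages[[stage]] <<- list(
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2),
      outputs = outputs)
  }
  # abort with the failing stage's name; completed stages stay on disk
  at_stage <- function(stage, expr) {
    withCallingHandlers(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  wt <- if (is.null(config$wt_params)) {
    wt_iks_parameters()
  } else {
    read_iks_parameters(config$wt_params)
  }

  # --- stage: fit ---
  t0 <- Sys.time()
  at_stage("fit", {
    specs <- parse_mutant_table(config$mutant_table)
    if (length(specs) == 0) stop("mutant table is empty")
    fit_dir <- file.path(out, "fits")
    fit_summary <- fit_mutant_table(wt, specs, fit_dir)
    fits <- lapply(specs, function(s) {
      read_iks_parameters(file.path(fit_dir, paste0(s$name, ".iks")))
    })
    names(fits) <- vapply(specs, `[[`, character(1), "name")
  })
  stamp("fit", t0, list(dir = fit_dir))

  # --- stage: population ---
  t0 <- Sys.time()
  pop_ckpt <- file.path(ckpt, "population.rds")
  pcfg <- population_config(n = config$population$n,
                            sigma = config$population$sigma,
                            seed = config$population$seed,
                            noise_base_seed = config$population$noise_base_seed)
  at_stage("population", {
    if (resume && file.exists(pop_ckpt)) {
      pop <- readRDS(pop_ckpt)
    } else {
      pop <- screen_inclusion(generate_population(pcfg, iks = wt), pcfg,
                              noise_sigma = config$noise$sigma,
                              n_beats = config$noise$n_beats)
      saveRDS(pop, pop_ckpt)
    }
    manifest_path <- file.path(out, "population_manifest.csv")
    write_population_manifest(pop, manifest_path)
  })
  stamp("population", t0, list(manifest = manifest_path, checkpoint = pop_ckpt))

  # --- stage: apply ---
  t0 <- Sys.time()
  results <- list()
  result_paths <- character(0)
  at_stage("apply", for (nm in names(fits)) {
    res_ckpt <- file.path(ckpt, paste0("apply_", nm, ".rds"))
    if (resume && file.exists(res_ckpt)) {
      r <- readRDS(res_ckpt)
    } else {
      r <- apply_mutant(pop, fits[[nm]], name = nm)
      saveRDS(r, res_ckpt)
    }
    results[[nm]] <- r
    path <- file.path(out, paste0("results_", nm, ".csv"))
    write_mutant_results(r, path)
    result_paths <- c(result_paths, path)
  })
  stamp("apply", t0, list(results = result_paths))

  # --- stage: classify ---
  t0 <- Sys.time()
  scfg <- severity_config(
    criterion_threshold_pct = config$severity$criterion_threshold_pct,
    pathogenic_cutoff_pct = config$severity$pathogenic_cutoff_pct,
    benign_cutoff_pct = config$severity$benign_cutoff_pct)
  at_stage("classify", {
    reports <- lapply(results, severity_report, config = scfg)
    sev_path <- file.path(out, "severity.csv")
    write_severity_reports(reports, sev_path)
  })
  stamp("classify", t0, list(severity = sev_path))

  # --- stage: adult (optional) ---
  if (isTRUE(config$adult$enabled)) {
    t0 <- Sys.time()
    acfg <- adult_config(g_ks_scale = config$adult$g_ks_scale,
                         bcl = config$adult$bcl,
                         pre_beats = config$adult$pre_beats)
    at_stage("adult", {
      adult_tab <- adult_translation_table(fits, acfg)
      adult_path <- file.path(out, "adult_translation.csv")
      utils::write.csv(adult_tab, adult_path, row.names = FALSE)
    })
    stamp("adult", t0, list(table = adult_path))
  }

  manifest_file <- file.path(out, "run_manifest.yaml")
  yaml::write_yaml(manifest, manifest_file)
  invisible(manifest)
}

#' Reference cell with an elevated diastolic potential
#'
#' A deliberately fragile iPSC-CM: the background sodium conductance is
#' raised until the diastolic potential sits near -52 mV and the AP
#' amplitude barely clears the 70 mV inclusion bound. In this cell a
#' gain-of-function IKs variant (density > 1) depresses the amplitude below
#' 70 mV (repolarization failure), and doubling the IK1 scale factor
#' ([rescue_with_ik1()]) stabilizes the diastolic potential and restores a
#' full AP with the expected gain-of-function APD shortening.
#'
#' @param iks `iks_parameters` hosted by the cell (default WT)
#' @return `cell_parameters`
#' @export
depolarized_cell_parameters <- function(iks = wt_iks_parameters()) {
  b <- base_cell_config()
  b$g_bna <- 0.0165
  cell_parameters(iks = iks, base = b)
}
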