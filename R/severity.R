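# Long-QT severity statistic and classifier: a per-cell three-criterion
# test at a percent-change threshold, the population fraction meeting all
# three, and the pathogenic / unclassified / benign call.
#
# Criteria per cell (mutant vs the same cell's wild type, paired noise
# seeds): increase in mean AP triangulation across the 40-beat noise run,
# increase in beat-to-beat variability of APD90 across the same run, and
# increase in APD90 from the noise-free run. In GOF (short-QT) mode the
# APD90 criterion flips to shortening; the other two are unchanged.

#' Severity-classification configuration
#'
#' All comparisons are strict: a cell flags a criterion only when its
#' percent change *exceeds* the threshold, and a mutant is pathogenic or
#' benign only when its fraction is strictly beyond the cut-off.
#'
#' @param criterion_threshold_pct per-cell percent-change threshold
#'   (default 4)
#' @param pathogenic_cutoff_pct population-fraction cut-off above which a
#'   mutant is pathogenic (default 4.6)
#' @param benign_cutoff_pct population-fraction cut-off below which a
#'   mutant is benign (default 0.25)
#' @param mode `"LOF"` (long-QT; APD90 prolongation) or `"GOF"` (short-QT;
#'   APD90 shortening of at least the threshold)
#' @return object of class `severity_config`
#' @export
severity_config <- function(criterion_threshold_pct = 4,
                            pathogenic_cutoff_pct = 4.6,
                            benign_cutoff_pct = 0.25,
                            mode = c("LOF", "GOF")) {
  mode <- match.arg(mode)
  if (criterion_threshold_pct <= 0) stop("severity_config: threshold must be > 0")
  if (benign_cutoff_pct >= pathogenic_cutoff_pct) {
    stop("severity_config: benign cut-off must lie below the pathogenic cut-off")
  }
  if (benign_cutoff_pct <= 0) stop("severity_config: cut-offs must be > 0")
  structure(list(criterion_threshold_pct = criterion_threshold_pct,
                 pathogenic_cutoff_pct = pathogenic_cutoff_pct,
                 benign_cutoff_pct = benign_cutoff_pct,
                 mode = mode),
            class = "severity_config")
}

#' Per-cell criterion flags
#'
#' Percent change is `100 * (mutant - wt) / wt` per quantity; a criterion
#' flags when the change strictly exceeds the threshold (LOF). In GOF mode
#' the APD criterion instead flags a shortening of at least the threshold
#' (`-change >= threshold`). A zero WT quantity makes that criterion
#' undefined (`NA`) for the cell.
#'
#' @param wt,mut named lists/rows with `triangulation`, `bvr`, `apd90`
#' @param config `severity_config`
#' @return logical triple `c(triangulation, bvr, apd)`, possibly with NAs
#' @export
per_cell_flags <- function(wt, mut, config = severity_config()) {
  thr <- config$criterion_threshold_pct
  pct <- function(w, m) if (!is.finite(w) || w == 0) NA_real_ else 100 * (m - w) / w
  d_tri <- pct(wt$triangulation, mut$triangulation)
  d_bvr <- pct(wt$bvr, mut$bvr)
  d_apd <- pct(wt$apd90, mut$apd90)
  apd_flag <- if (config$mode == "GOF") {
    if (is.na(d_apd)) NA else -d_apd >= thr
  } else {
    if (is.na(d_apd)) NA else d_apd > thr
  }
  c(triangulation = if (is.na(d_tri)) NA else d_tri > thr,
    bvr = if (is.na(d_bvr)) NA else d_bvr > thr,
    apd = apd_flag)
}

# flags matrix (rows = cells) from a mutant_population_result at a threshold
.flags_matrix <- function(result, config) {
  df <- result$results[!result$results$failure, , drop = FALSE]
  if (nrow(df) == 0) {
    return(matrix(logical(0), ncol = 3,
                  dimnames = list(NULL, c("triangulation", "bvr", "apd"))))
  }
  t(vapply(seq_len(nrow(df)), function(i) {
    per_cell_flags(
      wt = list(triangulation = df$wt_triangulation[i], bvr = df$wt_bvr[i],
                apd90 = df$wt_apd90[i]),
      mut = list(triangulation = df$mut_triangulation[i], bvr = df$mut_bvr[i],
                 apd90 = df$mut_apd90[i]),
      config
    )
  }, logical(3)))
}

#' Fraction of cells meeting all three criteria
#'
#' `100 * (#cells with all three flags TRUE) / (#included cells)`. Cells
#' with an undefined criterion (zero WT quantity) cannot meet all three and
#' are excluded from the all-three numerator; they remain in the
#' denominator.
#'
#' @param flags logical matrix from per-cell flags (columns triangulation,
#'   bvr, apd)
#' @return percent in \[0, 100\]
#' @export
population_fraction <- function(flags) {
  if (is.null(dim(flags)) || nrow(flags) == 0) {
    stop("population_fraction: need at least one included cell")
  }
  all_three <- apply(flags, 1, function(r) !any(is.na(r)) && all(r))
  100 * sum(all_three) / nrow(flags)
}

#' Classify a severity fraction
#'
#' Pathogenic when strictly above the pathogenic cut-off, benign when
#' strictly below the benign cut-off, otherwise unclassified.
#'
#' @param fraction_all_three percent of cells meeting all three criteria
#' @param config `severity_config`
#' @return one of `"pathogenic"`, `"unclassified"`, `"benign"`
#' @export
classify <- function(fraction_all_three, config = severity_config()) {
  if (!is.finite(fraction_all_three) ||
      fraction_all_three < 0 || fraction_all_three > 100) {
    stop("classify: fraction must lie in [0, 100]")
  }
  if (fraction_all_three > config$pathogenic_cutoff_pct) return("pathogenic")
  if (fraction_all_three < config$benign_cutoff_pct) return("benign")
  "unclassified"
}

#' Severity report for one mutant population
#'
#' @param result `mutant_population_result` from [apply_mutant()]
#' @param config `severity_config`
#' @param sweep_thresholds additional thresholds (%) reported alongside the
#'   main one
#' @return object of class `severity_report`: per-criterion fractions,
#'   `fraction_all_three`, `n_included`, `repolarization_failure_pct`,
#'   `classification`, and `sweep` (fraction per threshold)
#' @export
severity_report <- function(result, config = severity_config(),
                            sweep_thresholds = c(4, 8, 10)) {
  stopifnot(inherits(result, "mutant_population_result"))
  flags <- .flags_matrix(result, config)
  if (nrow(flags) == 0) {
    stop(sprintf("severity_report(%s): no included cells survive the mutation",
                 result$name))
  }
  marginal <- function(col) {
    v <- flags[, col]
    100 * sum(v, na.rm = TRUE) / sum(!is.na(v))
  }
  frac <- population_fraction(flags)
  sweep <- vapply(sweep_thresholds, function(thr) {
    cfg <- config
    cfg$criterion_threshold_pct <- thr
    population_fraction(.flags_matrix(result, cfg))
  }, numeric(1))
  names(sweep) <- paste0("pct_", sweep_thresholds)
  structure(
    list(name = result$name,
         fraction_triangulation = marginal("triangulation"),
         fraction_bvr = marginal("bvr"),
         fraction_apd = marginal("apd"),
         fraction_all_three = frac,
         n_included = nrow(flags),
         repolarization_failure_pct = result$repolarization_failure_pct,
         classification = classify(frac, config),
         sweep = sweep,
         config = config),
    class = "severity_report"
  )
}

#' @export
print.severity_report <- function(x, ...) {
  cat(sprintf("severity_report %s: %.2f%% of %d cells meet all three criteria -> %s\n",
              x$name, x$fraction_all_three, x$n_included, x$classification))
  cat(sprintf("  marginals: triangulation %.1f%%, BVR %.1f%%, APD %.1f%%; repol failure %.1f%%\n",
              x$fraction_triangulation, x$fraction_bvr, x$fraction_apd,
              x$repolarization_failure_pct))
  invisible(x)
}

#' Threshold sweep across mutants
#'
#' Recomputes the all-three fraction of every mutant at each threshold and
#' reports whether the mutant ordering is stable (Spearman rank correlation
#' of each column against the first).
#'
#' @param results list of `mutant_population_result`
#' @param thresholds percent-change thresholds (default 4, 8, 10)
#' @param config base `severity_config`
#' @return list: `fractions` (matrix mutants x thresholds), `rank_stability`
#'   (Spearman correlation of each threshold's ordering with the first)
#' @export
threshold_sweep <- function(results, thresholds = c(4, 8, 10),
                            config = severity_config()) {
  if (length(results) < 2) stop("threshold_sweep: need at least 2 mutants")
  fr <- vapply(thresholds, function(thr) {
    cfg <- config
    cfg$criterion_threshold_pct <- thr
    vapply(results, function(r) population_fraction(.flags_matrix(r, cfg)),
           numeric(1))
  }, numeric(length(results)))
  rownames(fr) <- vapply(results, `[[`, character(1), "name")
  colnames(fr) <- paste0("pct_", thresholds)
  stability <- vapply(seq_along(thresholds), function(k) {
    suppressWarnings(stats::cor(fr[, 1], fr[, k], method = "spearman"))
  }, numeric(1))
  names(stability) <- colnames(fr)
  list(fractions = fr, rank_stability = stability)
}

#' Write severity reports as a delimited summary
#'
#' @param reports list of `severity_report`
#' @param path output path (CSV); a structured-text twin with suffix
#'   `.yaml` carries the same content machine-readably
#' @return `path`, invisibly
#' @export
write_severity_reports <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(name = r$name,
               fraction_all_three = r$fraction_all_three,
               fraction_triangulation = r$fraction_triangulation,
               fraction_bvr = r$fraction_bvr,
               fraction_apd = r$fraction_apd,
               n_included = r$n_included,
               repolarization_failure_pct = r$repolarization_failure_pct,
               classification = r$classification,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(lapply(reports, function(r) {
    r$config <- unclass(r$config)
    unclass(r)
  }), paste0(tools::file_path_sans_ext(path), ".yaml"))
  invisible(path)
}
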