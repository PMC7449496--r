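# The three-criterion severity statistic and the classifier.

test_that("per-cell flags use strict thresholds and handle degenerate WT values", {
  cfg <- severity_config()
  wt <- list(triangulation = 100, bvr = 2, apd90 = 300)
  expect_identical(unname(per_cell_flags(wt, wt, cfg)), c(FALSE, FALSE, FALSE))

  up5 <- list(triangulation = 105, bvr = 2.1, apd90 = 315)
  expect_identical(unname(per_cell_flags(wt, up5, cfg)), c(TRUE, TRUE, TRUE))

  # exactly +4.0% does not flag (strictly greater than)
  edge <- list(triangulation = 104, bvr = 2.2, apd90 = 330)
  expect_identical(unname(per_cell_flags(wt, edge, cfg)), c(FALSE, TRUE, TRUE))

  degen <- list(triangulation = 0, bvr = 2, apd90 = 300)
  f <- per_cell_flags(degen, up5, cfg)
  expect_true(is.na(f["triangulation"]))
})

test_that("GOF mode flips only the APD criterion to shortening", {
  gof <- severity_config(mode = "GOF")
  wt <- list(triangulation = 100, bvr = 2, apd90 = 300)
  shorter <- list(triangulation = 105, bvr = 2.2, apd90 = 288)  # -4%
  f <- per_cell_flags(wt, shorter, gof)
  expect_identical(unname(f), c(TRUE, TRUE, TRUE))  # -4% meets ">= threshold"
  barely <- list(triangulation = 105, bvr = 2.2, apd90 = 289)   # -3.7%
  expect_false(per_cell_flags(wt, barely, gof)[["apd"]])
  longer <- list(triangulation = 105, bvr = 2.2, apd90 = 315)
  expect_false(per_cell_flags(wt, longer, gof)[["apd"]])
})

test_that("the population fraction counts all-three cells over included cells", {
  flags <- matrix(FALSE, nrow = 100, ncol = 3,
                  dimnames = list(NULL, c("triangulation", "bvr", "apd")))
  flags[1:9, ] <- TRUE
  flags[10:20, 1] <- TRUE   # partial flags do not count
  expect_equal(population_fraction(flags), 9)
  expect_equal(population_fraction(flags[21:100, , drop = FALSE]), 0)
  # an NA criterion cannot satisfy all three
  flags[1, 2] <- NA
  expect_equal(population_fraction(flags), 8)
  expect_error(population_fraction(flags[0, , drop = FALSE]), "at least one")
})

test_that("classification boundaries are strict and total on [0, 100]", {
  cfg <- severity_config()
  expect_identical(classify(8.97, cfg), "pathogenic")
  expect_identical(classify(1.71, cfg), "unclassified")
  expect_identical(classify(0.09, cfg), "benign")
  expect_identical(classify(4.6, cfg), "unclassified")   # strictly "more than"
  expect_identical(classify(0.25, cfg), "unclassified")  # strictly "less than"
  expect_identical(classify(4.6 + 1e-9, cfg), "pathogenic")
  expect_identical(classify(0.25 - 1e-9, cfg), "benign")
  expect_identical(classify(0, cfg), "benign")
  expect_identical(classify(100, cfg), "pathogenic")
  for (x in seq(0, 100, by = 0.5)) {
    expect_true(classify(x, cfg) %in% c("pathogenic", "unclassified", "benign"))
  }
  expect_error(classify(-1, cfg), "\\[0, 100\\]")
  expect_error(classify(101, cfg), "\\[0, 100\\]")
})

test_that("severity config validates its cut-offs", {
  expect_error(severity_config(criterion_threshold_pct = 0), "> 0")
  expect_error(severity_config(pathogenic_cutoff_pct = 0.1,
                               benign_cutoff_pct = 0.25), "below")
  expect_s3_class(severity_config(mode = "GOF"), "severity_config")
})

# build a minimal mutant_population_result from given percent changes
fake_result <- function(name, d_tri, d_bvr, d_apd) {
  n <- length(d_tri)
  df <- data.frame(
    cell_id = seq_len(n),
    wt_apd90 = 300, wt_triangulation = 100, wt_bvr = 2,
    mut_apd90 = 300 * (1 + d_apd / 100),
    mut_triangulation = 100 * (1 + d_tri / 100),
    mut_bvr = 2 * (1 + d_bvr / 100),
    failure = FALSE, reason = "",
    d_apd90_pct = d_apd, d_triangulation_pct = d_tri, d_bvr_pct = d_bvr)
  structure(list(name = name, results = df,
                 repolarization_failure_pct = 0, n_wt_included = n),
            class = "mutant_population_result")
}

test_that("severity fractions are monotone non-increasing in the threshold", {
  set.seed(12)
  res <- fake_result("m", runif(200, 0, 15), runif(200, 0, 15), runif(200, 0, 15))
  fr <- vapply(c(4, 5, 8, 10, 15, 20), function(thr) {
    population_fraction(iksvar:::.flags_matrix(res, severity_config(thr)))
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("threshold sweep reports stable ranking for separated mutants", {
  res <- list(
    fake_result("severe", runif(100, 5, 30), runif(100, 5, 30), runif(100, 5, 30)),
    fake_result("mild", runif(100, 0, 8), runif(100, 0, 8), runif(100, 0, 8)),
    fake_result("benign", rep(0, 100), rep(0, 100), rep(0, 100))
  )
  sw <- threshold_sweep(res, thresholds = c(4, 8, 10))
  expect_equal(dim(sw$fractions), c(3, 3))
  expect_true(all(apply(sw$fractions, 1, function(r) all(diff(r) <= 0))))
  expect_true(all(sw$fractions["severe", ] >= sw$fractions["mild", ]))
  expect_error(threshold_sweep(res[1]), "at least 2")
})

test_that("severity reports aggregate marginals, classification and sweep", {
  exp <- shared_experiment()
  rep_block <- severity_report(exp$results$block)
  expect_lte(rep_block$fraction_all_three,
             min(rep_block$fraction_triangulation, rep_block$fraction_bvr,
                 rep_block$fraction_apd))
  expect_true(all(rep_block$sweep >= 0 & rep_block$sweep <= 100))
  expect_true(rep_block$classification %in%
                c("pathogenic", "unclassified", "benign"))

  path <- tempfile(fileext = ".csv")
  write_severity_reports(list(rep_block, severity_report(exp$results$identity)), path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 2)
  expect_true(file.exists(sub("\\.csv$", ".yaml", path)))
})
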