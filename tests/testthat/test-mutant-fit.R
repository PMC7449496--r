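# Fitting mutant IKs models to summary statistics, and mutant-table I/O.

test_that("the identity spec fits back to the wild type exactly", {
  wt <- wt_iks_parameters()
  f <- fit_mutant(wt, mutant_spec("id", 0, 0, 1))
  expect_identical(f$params$g_ks, wt$g_ks)
  expect_identical(f$params$x1, wt$x1)
  expect_identical(f$achieved_delta_v_half, 0)
  expect_identical(f$achieved_delta_slope, 0)
  expect_equal(f$achieved_rel_density, 1)
  expect_equal(f$tau_deviation, 0)
})

test_that("a complete-block spec keeps WT kinetics with zero conductance", {
  wt <- wt_iks_parameters()
  f <- fit_mutant(wt, mutant_spec("KO", complete_block = TRUE))
  expect_identical(f$params$g_ks, 0)
  expect_identical(f$params$x1, wt$x1)
  expect_identical(f$params$x4, wt$x4)
})

test_that("an activation shift is imposed exactly on the fitted curve", {
  wt <- wt_iks_parameters()
  f <- fit_mutant(wt, mutant_spec("shifted", delta_v_half = 14.8,
                                  delta_slope = 0, rel_density = 1))
  wt_sum <- activation_summary(wt)
  fit_sum <- activation_summary(f$params)
  expect_equal(fit_sum$v_half - wt_sum$v_half, 14.8, tolerance = 1e-6)
  expect_equal(fit_sum$slope_k, wt_sum$slope_k, tolerance = 1e-6)
})

test_that("fits recover targets and are deterministic", {
  wt <- wt_iks_parameters()
  set.seed(91)
  for (i in 1:10) {
    spec <- mutant_spec(sprintf("r%d", i),
                        delta_v_half = runif(1, -30, 30),
                        delta_slope = runif(1, -5, 10),
                        rel_density = runif(1, 0.05, 3))
    f1 <- fit_mutant(wt, spec)
    expect_lt(abs(f1$achieved_delta_v_half - spec$delta_v_half), 0.1)
    expect_lt(abs(f1$achieved_delta_slope - spec$delta_slope), 0.1)
    expect_lt(abs(f1$achieved_rel_density - spec$rel_density) / spec$rel_density, 0.01)
    f2 <- fit_mutant(wt, spec)
    expect_identical(f1$params$g_ks, f2$params$g_ks)
    expect_identical(f1$params$x1, f2$params$x1)
  }
})

test_that("infeasible slope targets are rejected", {
  wt <- wt_iks_parameters()   # slope 14 mV
  expect_error(fit_mutant(wt, mutant_spec("bad", 0, -14, 0.5)), "not positive")
  expect_error(fit_mutant(wt, mutant_spec("bad2", 0, -20, 0.5)), "not positive")
})

test_that("mutant tables parse, canonicalize blocks, and reject bad rows", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("name,delta_v_half,delta_slope,rel_density,complete_block",
               "A,14.8,0,0.68,0",
               "KO,0,0,,1",
               "Z,-3,1.5,0,0"), path)
  specs <- parse_mutant_table(path)
  expect_length(specs, 3)
  expect_equal(specs[[1]]$rel_density, 0.68)
  expect_false(specs[[1]]$complete_block)
  expect_true(specs[[2]]$complete_block)
  expect_true(specs[[3]]$complete_block)   # density 0 -> block

  writeLines(c("name,delta_v_half,delta_slope,rel_density,complete_block",
               "A,abc,0,0.5,0"), path)
  expect_error(parse_mutant_table(path), "row 1")

  writeLines(c("name,delta_v_half,delta_slope,rel_density,complete_block",
               "A,1,0,0.5,0", "A,2,0,0.4,0"), path)
  expect_error(parse_mutant_table(path), "duplicate")

  writeLines(c("name,delta_v_half,rel_density,complete_block", "A,1,0.5,0"), path)
  expect_error(parse_mutant_table(path), "missing column")

  writeLines("name,delta_v_half,delta_slope,rel_density,complete_block", path)
  expect_warning(specs <- parse_mutant_table(path), "empty")
  expect_length(specs, 0)
})

test_that("mutant tables round-trip through write and parse", {
  specs <- list(mutant_spec("A", 14.8, -1.5, 0.68),
                mutant_spec("KO", 0, 0, complete_block = TRUE),
                mutant_spec("G", -2, 3, 1.47, density_se = 0.04))
  path <- tempfile(fileext = ".csv")
  write_mutant_table(specs, path)
  back <- parse_mutant_table(path)
  for (i in seq_along(specs)) {
    expect_equal(back[[i]]$name, specs[[i]]$name)
    expect_equal(back[[i]]$rel_density, specs[[i]]$rel_density)
    expect_equal(back[[i]]$complete_block, specs[[i]]$complete_block)
  }
})

test_that("density-sensitivity variants scale and canonicalize", {
  spec <- mutant_spec("M", 5, 1, 0.25)
  out <- scale_density_variants(spec, c(0.92, 0.96, 1, 1.04, 1.08))
  expect_length(out, 5)
  expect_equal(vapply(out, `[[`, numeric(1), "rel_density"),
               0.25 * c(0.92, 0.96, 1, 1.04, 1.08))
  expect_length(scale_density_variants(spec, numeric(0)), 0)
  zero <- scale_density_variants(spec, 0)[[1]]
  expect_true(zero$complete_block)
  expect_error(scale_density_variants(spec, -1), ">= 0")
  blocked <- mutant_spec("KO", complete_block = TRUE)
  expect_error(scale_density_variants(blocked, 1), "complete block")
})

test_that("fit_mutant_table writes parameter files and a summary", {
  wt <- wt_iks_parameters()
  out <- tempfile()
  specs <- list(mutant_spec("a", 5, 0, 0.5),
                mutant_spec("ko", 0, 0, complete_block = TRUE))
  s <- fit_mutant_table(wt, specs, out)
  expect_true(file.exists(file.path(out, "a.iks")))
  expect_true(file.exists(file.path(out, "fit_summary.csv")))
  back <- read_iks_parameters(file.path(out, "ko.iks"))
  expect_identical(back$g_ks, 0)
  expect_equal(nrow(s), 2)
})
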