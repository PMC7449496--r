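# AP detection and metrics on constructed waveforms, and the noise model.

test_that("the noise generator is seeded, zero-mean and piecewise constant", {
  cfg <- noise_config(sigma = 0.045, update_interval = 1, seed = 99)
  s1 <- generate_noise(cfg, 5000)
  s2 <- generate_noise(cfg, 5000)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 5001)
  expect_identical(s1$current[5001], s1$current[5000])  # held last value

  zero <- generate_noise(noise_config(sigma = 0), 1000)
  expect_true(all(zero$current == 0))

  # the generator leaves the global RNG stream untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_noise(cfg, 1000)); after <- runif(1)
  expect_identical(before, after)

  expect_error(generate_noise(cfg, 0), "duration")
  expect_error(noise_config(sigma = -1), "sigma")
})

test_that("AP detection finds constructed spikes and ignores flat traces", {
  flat <- data.frame(time = 0:2000, vm = rep(-70, 2001))
  expect_length(detect_aps(flat), 0)

  two <- ramp_ap_trace(n_beats = 2)
  segs <- detect_aps(two)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$peak, 40)
  expect_equal(segs[[1]]$mdp, -60)
  # the independent oracle: count of upward 0 mV crossings
  crossings <- sum(two$vm[-nrow(two)] <= 0 & two$vm[-1] > 0)
  expect_equal(length(segs), crossings)
})

test_that("APD of a square pulse equals the pulse width", {
  # ~instant rise to +40, 200 ms hold, ~instant drop back to -60
  tr <- ramp_ap_trace(peak = 40, mdp = -60, hold = 200, ramp = 0.2,
                      diastole = 300, n_beats = 2, rise = 0.2)
  seg <- detect_aps(tr)[[1]]
  expect_equal(apd(seg, 90), 200, tolerance = 0.005)
  expect_equal(apd(seg, 30), 200, tolerance = 0.005)
  expect_lt(triangulation(seg), 0.5)
})

test_that("APD levels on a linear repolarization ramp match closed form", {
  # linear ramp peak->mdp over 100 ms: apd90 - apd30 = 0.6 * 100
  tr <- ramp_ap_trace(peak = 40, mdp = -60, hold = 50, ramp = 100, n_beats = 2)
  seg <- detect_aps(tr)[[1]]
  expect_equal(triangulation(seg), 60, tolerance = 1e-3)
  expect_lt(apd(seg, 30), apd(seg, 50))
  expect_lt(apd(seg, 50), apd(seg, 90))
  m <- ap_morphology(seg)
  expect_equal(m$amplitude, 100)
  expect_equal(m$triangulation, m$apd90 - m$apd30)
})

test_that("a segment that never recrosses its level signals repolarization failure", {
  seg <- structure(
    list(time = seq(0, 100, 0.5), vm = c(seq(-60, 40, length.out = 21),
                                         rep(35, 180)),
         peak = 40, mdp = -60, t_upstroke = 0, t_peak = 10,
         cycle_length = 100),
    class = "ap_segment")
  expect_error(apd(seg, 90), class = "repolarization_failure")
  expect_error(triangulation(seg), class = "repolarization_failure")
})

test_that("beat-to-beat variability is the mean absolute successive difference", {
  expect_equal(beat_to_beat_variability(rep(312.5, 40)), 0)
  expect_equal(beat_to_beat_variability(c(300, 310, 300)), 10)
  set.seed(4)
  s <- rnorm(40, 300, 5)
  expect_equal(beat_to_beat_variability(s), mean(abs(diff(s))))
  expect_length(diff(s), 39)
  expect_equal(beat_to_beat_variability(rev(s)), beat_to_beat_variability(s))
  expect_error(beat_to_beat_variability(300), "at least 2")
})

test_that("EAD and alternans detectors respond to constructed patterns", {
  # repolarization with a 5 mV bump between +10 mV and the MDP
  vm <- c(seq(-60, 40, length.out = 20), seq(40, -20, length.out = 60),
          seq(-20, -15, length.out = 10), seq(-15, -60, length.out = 45))
  seg <- structure(list(time = seq_along(vm), vm = vm, peak = 40, mdp = -60,
                        t_upstroke = 1, t_peak = 20, cycle_length = 135),
                   class = "ap_segment")
  expect_true(has_ead(seg))
  expect_false(has_ead(seg, threshold = 10))
  mono <- structure(list(time = 1:80,
                         vm = c(seq(-60, 40, length.out = 20),
                                seq(40, -60, length.out = 60)),
                         peak = 40, mdp = -60, t_upstroke = 1, t_peak = 20,
                         cycle_length = 80),
                    class = "ap_segment")
  expect_false(has_ead(mono))

  expect_true(has_alternans(c(300, 320, 300, 320, 300, 320)))
  expect_false(has_alternans(rep(300, 6)))
  expect_false(has_alternans(c(300, 302, 300, 302, 300, 302)))  # below 5 ms
  expect_false(has_alternans(seq(300, 350, by = 10)))           # monotone drift
})

test_that("metrics are stable under output-grid refinement", {
  wt <- shared_wt_cell()
  m1 <- wt$metrics
  tr2 <- simulate_cell(wt$p, wt$steady$state, 20000, dt_out = 0.5)
  m2 <- trace_metrics(tr2)
  expect_lt(abs(m1$apd90 - m2$apd90), 0.2)
})

test_that("the noise protocol is reproducible and insensitive to its length", {
  wt <- shared_wt_cell()
  nc <- noise_config(seed = 77)
  cl <- wt$metrics$cycle_length
  b1 <- run_noise_protocol(wt$p, wt$steady$state, nc, n_beats = 10,
                           est_cycle_length = cl)
  b2 <- run_noise_protocol(wt$p, wt$steady$state, nc, n_beats = 10,
                           est_cycle_length = cl)
  expect_identical(b1$apd90, b2$apd90)
  expect_equal(b1$n_beats, 10)

  # protocol-length insensitivity: mean triangulation and APD90 at 20 vs 40
  # beats agree closely on the reference cell
  b20 <- run_noise_protocol(wt$p, wt$steady$state, nc, n_beats = 20,
                            est_cycle_length = cl)
  b40 <- run_noise_protocol(wt$p, wt$steady$state, nc, n_beats = 40,
                            est_cycle_length = cl)
  expect_lt(abs(b20$mean_triangulation / b40$mean_triangulation - 1), 0.05)
  expect_lt(abs(mean(b20$apd90) / mean(b40$apd90) - 1), 0.02)
})
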