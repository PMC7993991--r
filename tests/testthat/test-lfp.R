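test_that("theta phase of a pure sinusoid advances 2*pi per period", {
  fs <- 1500
  tt <- seq(0, 10, by = 1 / fs)
  lfp <- list(fs = fs, time_s = tt, signal = cos(2 * pi * 8 * tt))
  ph <- theta_phase(lfp)
  # phase at t and t + 125 ms agree (one full cycle)
  i <- seq(2000, 10000, by = 17)
  dph <- wtrackseq:::wrap_pi(ph$phase[i + round(0.125 * fs)] - ph$phase[i])
  expect_lt(max(abs(dph)), 0.05)
  # phase error vs ground truth small away from the edges
  truth <- wtrackseq:::wrap_pi(2 * pi * 8 * tt[i])
  expect_lt(sqrt(mean(wtrackseq:::wrap_pi(ph$phase[i] - truth)^2)), 0.1)
  # constant signal errors
  expect_error(theta_phase(list(fs = fs, time_s = tt,
                                signal = rep(1, length(tt)))), "constant")
  # stop-band: a 20 Hz sinusoid leaves near-zero band amplitude
  ph20 <- theta_phase(list(fs = fs, time_s = tt,
                           signal = cos(2 * pi * 20 * tt)))
  expect_lt(stats::median(ph20$amplitude), 0.05)
})

test_that("phase locking matches circular closed forms", {
  fs <- 1500
  tt <- seq(0, 200, by = 1 / fs)
  phase <- structure(list(time_s = tt,
                          phase = wtrackseq:::wrap_pi(2 * pi * 8 * tt),
                          amplitude = rep(1, length(tt)), fs = fs),
                     class = "theta_phase")
  # all spikes at phase pi/2 (a quarter cycle in): resultant 1, p ~ 0
  st <- (seq_len(200) + 0.25) / 8
  pl <- phase_locking(st, phase)
  expect_gt(pl$resultant, 0.99)
  expect_lt(pl$p, 1e-10)
  expect_equal(pl$mean_phase, pi / 2, tolerance = 0.05)
  # uniform phases: resultant ~ 0, p > 0.05
  set.seed(5)
  stu <- sort(stats::runif(1000, 0, 200))
  plu <- phase_locking(stu, phase)
  expect_lt(plu$resultant, 0.1)
  expect_gt(plu$p, 0.05)
  # von Mises kappa = 1 sample: resultant ~ I1(1)/I0(1) = 0.446
  set.seed(6)
  n <- 4000
  vm <- numeric(0)
  while (length(vm) < n) {  # simple rejection sampler
    x <- stats::runif(n, -pi, pi)
    keep <- stats::runif(n) < exp(cos(x) - 1)
    vm <- c(vm, x[keep])
  }
  vm <- vm[seq_len(n)]
  rt <- rayleigh_test(vm)
  expect_equal(rt$rbar, besselI(1, 1) / besselI(1, 0), tolerance = 0.03)
  # < 30 spikes: undefined
  expect_null(phase_locking(st[1:10], phase))
})

test_that("theta cycles are segmented at the population minimum phase", {
  fs <- 1500
  tt <- seq(0, 300, by = 1 / fs)
  phase <- structure(list(time_s = tt,
                          phase = wtrackseq:::wrap_pi(2 * pi * 8 * tt),
                          amplitude = rep(1, length(tt)), fs = fs),
                     class = "theta_phase")
  loco <- data.frame(start_s = 0, end_s = 300)
  # three units locked at phase 0 -> boundary near +/- pi
  spikes <- do.call(rbind, lapply(1:3, function(u) {
    data.frame(unit_id = u, region = "CA1",
               time_s = seq_len(2000) / 8 + stats::rnorm(2000, 0, 0.004))
  }))
  cyc <- segment_theta_cycles(phase, spikes, loco)
  expect_gt(abs(cyc$boundary_phase), 0.8 * pi)
  expect_equal(stats::median(cyc$cycles$duration_s), 0.125,
               tolerance = 0.01)
  # cycles tile the masked time (no overlaps, ordered)
  expect_true(all(diff(cyc$cycles$start_s) > 0))
  expect_true(all(cyc$cycles$end_s[-nrow(cyc$cycles)] <=
                    cyc$cycles$start_s[-1] + 1e-9))
  # session fixture: median cycle duration ~ 1/theta
  s <- fix_session()
  cycs <- segment_theta_cycles(fix_phase(), s$spikes, fix_masks()$loco)
  expect_equal(stats::median(cycs$cycles$duration_s),
               1 / s$config$theta_hz, tolerance = 0.015)
})

test_that("SWR detection finds planted ripples and respects gates", {
  s <- fix_session()
  swrs <- detect_swrs(s$lfp, fix_masks()$immo)
  planted <- s$truth$swrs
  # recall 1 on planted events
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    any(swrs$start_s < planted$start_s[i] + planted$duration_s[i] &
          swrs$end_s > planted$start_s[i])
  }, logical(1))
  expect_true(all(hit))
  # false positives < 1 per 100 s
  extra <- nrow(swrs) - sum(hit)
  dur_total <- max(s$position$time_s)
  expect_lt(extra / dur_total * 100, 1)
  expect_true(all(swrs$peak_z >= 3))

  # a burst during running is rejected: shrink immobility away from one
  i <- which.max(planted$duration_s)
  immo2 <- fix_masks()$immo
  drop <- immo2$start_s <= planted$start_s[i] &
    immo2$end_s >= planted$start_s[i]
  sw2 <- detect_swrs(s$lfp, immo2[!drop, , drop = FALSE])
  expect_false(any(sw2$start_s < planted$start_s[i] + 0.01 &
                     sw2$end_s > planted$start_s[i]))
  # insufficient immobility errors
  expect_error(detect_swrs(s$lfp, immo2[1, , drop = FALSE][0, ]), "immobility")
})

test_that("band power and coherence behave on constructed channel pairs", {
  fs <- 600
  tt <- seq(0, 60, by = 1 / fs)
  set.seed(7)
  x <- cos(2 * pi * 8 * tt) + stats::rnorm(length(tt), 0, 0.5)
  mask <- data.frame(start_s = seq(0, 50, by = 10),
                     end_s = seq(5, 55, by = 10))
  # identical channels: coherence 1
  bp <- band_power_coherence(x, x, fs, mask)
  expect_equal(bp$band_coherence, 1, tolerance = 1e-9)
  # independent noise: band coherence small
  y <- stats::rnorm(length(tt))
  bp2 <- band_power_coherence(x, y, fs, mask)
  expect_lt(bp2$band_coherence, 0.3)
  # amplitude scaling leaves the z-scored power profile unchanged
  bp3 <- band_power_coherence(2 * x, y, fs, mask)
  expect_equal(bp3$zpower_x, bp2$zpower_x, tolerance = 1e-9)
  # short segments are rejected
  expect_error(band_power_coherence(x, y, fs,
                                    data.frame(start_s = 0, end_s = 1)),
               "segment")
})
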