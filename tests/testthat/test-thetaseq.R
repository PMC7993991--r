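test_that("weighted correlation matches the brute-force oracle", {
  # the spec example matrix, rows = space, columns = time
  pm <- matrix(c(.5, .1, 0, .1, .3, .1, 0, .1, .5), 3, byrow = TRUE)
  expect_equal(weighted_correlation(pm), oracle_wcorr(pm),
               tolerance = 1e-12)
  # random posteriors, random axes
  for (seed in 1:40) {
    D <- sample(5:30, 1); Tn <- sample(3:12, 1)
    pm <- random_pmat(D, Tn, seed)
    x <- (seq_len(D) - 0.5) * 2
    t <- (seq_len(Tn) - 1) * 0.01
    expect_lt(abs(weighted_correlation(pm, x, t) - oracle_wcorr(pm, x, t)),
              1e-12)
  }
  # delta posterior on a perfect diagonal: r = 1
  diag_pm <- diag(8)
  expect_equal(weighted_correlation(diag_pm), 1, tolerance = 1e-12)
  # uniform posterior: r undefined-as-zero covariance -> NA guarded
  expect_equal(weighted_correlation(matrix(1 / 40, 5, 8)), 0,
               tolerance = 1e-12)
  # zero mass or zero variance: NA
  expect_true(is.na(weighted_correlation(matrix(0, 3, 3))))
  expect_true(is.na(weighted_correlation(matrix(c(1, 0, 0), 3, 3))))
})

test_that("best-fit line matches the brute-force oracle exactly", {
  for (seed in 1:12) {
    D <- sample(15:30, 1); Tn <- sample(4:9, 1)
    pm <- random_pmat(D, Tn, 100 + seed)
    k <- sort(sample(0:(Tn + 3), Tn))
    got <- best_fit_line(pm, bin_cm = 2, dt_s = 0.01, k = k,
                         v_abs_range = c(1, 5), v_step = 0.5)
    want <- oracle_bfl(pm, 2, 0.01, k, 8, c(1, 5), 0.5)
    expect_equal(got$r_max, want$r_max, tolerance = 1e-12)
    expect_equal(got$v_mps, want$v_mps)
    expect_equal(got$rho_cm, want$rho_cm)
  }
})

test_that("best-fit line recovers planted ridges and analytic bounds", {
  # delta ridge at v = 5 m/s: position advances 5 cm per 10 ms bin
  D <- 100; Tn <- 10
  pm <- matrix(0, D, Tn)
  for (j in seq_len(Tn)) {
    bin <- 10 + round((j - 1) * 5 / 2)  # 2 cm bins
    pm[bin, j] <- 1
  }
  bf <- best_fit_line(pm)
  expect_equal(bf$r_max, 1)  # all mass within 8 cm of some line
  # a delta ridge under-determines v: any line within the 8 cm vicinity
  # of every point scores 1, so recovery needs a graded ridge whose
  # capture decays away from the true slope
  Tn2 <- 16
  pm2 <- matrix(0, D, Tn2)
  centers <- (seq_len(D) - 0.5) * 2
  for (j in seq_len(Tn2)) {
    ridge <- 19 + (j - 1) * 5  # v = 5 m/s
    w <- pmax(0, 1 - abs(centers - ridge) / 14)  # wider than the vicinity
    pm2[, j] <- w / sum(w)
  }
  bf2 <- best_fit_line(pm2)
  expect_lt(abs(bf2$v_mps - 5), 0.26)  # within one grid step
  # uniform posterior over 120 cm: R ~ (2d + bin)/extent = 0.15
  pmu <- matrix(1 / 60, 60, Tn)
  bfu <- best_fit_line(pmu)
  expect_equal(bfu$r_max, 0.15, tolerance = 0.02)
})

test_that("shuffle significance calibrates and is reproducible", {
  units <- fix_units()
  model <- fix_model_out()
  spk <- plant_sequence_event(units, "C-to-R", 140, seed = 21L)
  ev <- decode_event(model, spk, 0, 0.125)
  blk <- ev$pmat[model$n_bins + seq_len(model$n_bins), ]
  s1 <- shuffle_significance(blk, k = ev$k, n_shuffles = 150, seed = 5L)
  s2 <- shuffle_significance(blk, k = ev$k, n_shuffles = 150, seed = 5L)
  expect_identical(s1, s2)
  expect_true(s1$significant)
  expect_gt(s1$r, s1$r_hi)
  expect_warning(shuffle_significance(blk, k = ev$k, n_shuffles = 50,
                                      seed = 1L), "shuffles")
})

test_that("sequence classification flips under time reversal", {
  units <- fix_units()
  model <- fix_model_out()
  cand <- data.frame(cycle_id = 1L, trial_id = 1L, pos_cm = 140,
                     travel = "outbound")
  spk <- plant_sequence_event(units, "C-to-R", 140, seed = 31L)
  ev <- decode_event(model, spk, 0, 0.125)
  r_f <- classify_sequence(ev, cand, "R", n_shuffles = 150, seed = 7L)
  # reverse spike order in time
  spk_r <- spk
  spk_r$time_s <- 0.125 - spk_r$time_s
  spk_r <- spk_r[order(spk_r$time_s), ]
  ev_r <- decode_event(model, spk_r, 0, 0.125)
  r_b <- classify_sequence(ev_r, cand, "R", n_shuffles = 150, seed = 7L)
  expect_true(r_f$significant && r_b$significant)
  expect_equal(r_f$direction, "forward")
  expect_equal(r_b$direction, "reverse")
  expect_lt(abs(abs(r_b$slope_mps) - abs(r_f$slope_mps)), 0.6)
  # representation labels
  expect_equal(r_f$represents, "actual")
  r_alt <- classify_sequence(ev, cand, "L", n_shuffles = 150, seed = 7L)
  expect_equal(r_alt$represents, "alternative")
})

test_that("distance index reads quadrant masses correctly", {
  # constructed event: all mass ahead of the animal
  D <- 100
  mk_ev <- function(bins_per_col) {
    Tn <- length(bins_per_col)
    pm <- matrix(0, 2 * D, Tn)
    for (j in seq_len(Tn)) pm[bins_per_col[j], j] <- 1
    structure(list(pmat = pm, centers_s = seq_len(Tn) * 0.01,
                   k = seq_len(Tn) - 1L, tau = 0.02, step = 0.01,
                   n_bins = D, bin_left_cm = seq(0, 198, 2),
                   trajectories = c("C-to-L", "C-to-R")),
              class = "event_decode")
  }
  cand <- data.frame(cycle_id = 1L, trial_id = 1L, pos_cm = 100,
                     travel = "outbound")
  phases <- c(-2, -1, 1, 2)  # two first-half, two second-half windows
  ahead <- mk_ev(c(60, 60, 60, 60))   # bin 60 = 119 cm, ahead of 100
  di <- distance_index(list(list(ev = ahead, candidate = cand,
                                 decoded = "L", phases = phases)),
                       n_boot = 50)
  expect_equal(unname(di$index_first), 1)
  expect_equal(unname(di$index_second), 1)
  # symmetric mass about the animal: both indices 0
  sym <- mk_ev(c(45, 55, 45, 55))     # 89 cm and 109 cm, equal mass
  di0 <- distance_index(list(list(ev = sym, candidate = cand,
                                  decoded = "L", phases = phases)),
                        n_boot = 50)
  expect_equal(unname(di0$index_first), 0, tolerance = 1e-12)
  expect_equal(unname(di0$index_second), 0, tolerance = 1e-12)
  # planted look-ahead: start -20 cm, end +30 cm -> second-half index
  # exceeds first-half index
  la <- mk_ev(c(40, 45, 55, 62))
  dila <- distance_index(list(list(ev = la, candidate = cand,
                                   decoded = "L", phases = phases)),
                         n_boot = 50)
  expect_gt(dila$index_second, dila$index_first)
})

test_that("choice representation and coherent pairs aggregate correctly", {
  res <- data.frame(
    cycle_id = 1:8, trial_id = c(1, 1, 2, 2, 3, 3, 4, 4),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    represents = c("actual", "alternative", "actual", "actual",
                   "alternative", "actual", NA, "actual"),
    stringsAsFactors = FALSE)
  cr <- choice_representation(res)
  expect_equal(cr$session$n, 7)
  expect_equal(cr$session$pct_actual, 100 * 5 / 7)
  pt <- cr$per_trial[order(cr$per_trial$trial_id), ]
  expect_equal(pt$n_actual, c(1, 2, 1, 1))
  expect_equal(pt$n_alternative, c(1, 0, 1, 0))

  # coherent pairs: fully coupled streams
  ca1 <- data.frame(cycle_id = 1:10, significant = TRUE,
                    represents = rep(c("actual", "alternative"), 5),
                    stringsAsFactors = FALSE)
  pfc <- ca1
  cp <- coherent_pairs(ca1, pfc)
  expect_equal(cp$n_pairs, 10)
  expect_equal(cp$p_pfc_actual_given_ca1_actual, 1)
  expect_equal(cp$p_pfc_alt_given_ca1_alt, 1)
  # zero overlap: empty result, no error
  pfc2 <- pfc
  pfc2$cycle_id <- 101:110
  cp0 <- coherent_pairs(ca1, pfc2)
  expect_equal(cp0$n_pairs, 0)
  expect_true(is.na(cp0$p_pfc_actual_given_ca1_actual))
})

test_that("candidate gates apply unit count, speed and duration", {
  s <- fix_session()
  lin <- fix_linearized()
  cycles <- segment_theta_cycles(fix_phase(), s$spikes, fix_masks()$loco)
  cand5 <- find_candidates(cycles, s$spikes, lin, "CA1")
  cand10 <- find_candidates(cycles, s$spikes, lin, "CA1", min_units = 10)
  expect_true(all(cand5$n_active >= 5))
  expect_true(all(cand5$duration_s >= 0.1 & cand5$duration_s <= 0.2))
  expect_true(all(cand5$speed_cm_s > 10))
  expect_lte(nrow(cand10), nrow(cand5))
  # decode_event window count: a 150 ms event gives up to 14 windows
  model <- fix_model_out()
  spk <- plant_sequence_event(fix_units(), "C-to-R", 140,
                              duration_s = 0.15, rate_gain = 20, seed = 4L)
  ev <- decode_event(model, spk, 0, 0.15)
  expect_lte(length(ev$k), 14)
  expect_gte(length(ev$k), 3)
  expect_equal(max(ev$k), 13)
})
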