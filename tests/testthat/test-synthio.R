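test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_trials = 1), "n_trials")
  expect_error(sim_config(error_rate = 1.2), "error_rate")
  expect_error(sim_config(theta_hz = 5), "theta_hz")
  expect_error(sim_config(n_ca1 = 0), "counts")
})

test_that("behavior generation is deterministic and honors the task rules", {
  cfg <- sim_config(seed = 8L, n_trials = 12L)
  b1 <- gen_behavior(cfg)
  b2 <- gen_behavior(cfg)
  expect_identical(b1, b2)

  # error_rate = 0: all outbound trials alternate correctly
  cfg0 <- sim_config(seed = 9L, n_trials = 20L, error_rate = 0)
  b <- gen_behavior(cfg0)
  outb <- b$trials[b$trials$travel == "outbound", ]
  expect_true(all(outb$correct))
  expect_true(all(outb$choice[-1] != outb$choice[-nrow(outb)]))

  # trials alternate outbound/inbound and dwell follows each run
  expect_equal(unique(b$trials$travel[c(TRUE, FALSE)]), "outbound")
  expect_true(all(b$trials$dwell_start_s >= b$trials$run_end_s - 1e-9))
})

test_that("incorrect-outbound fraction matches the configured error rate", {
  cfg <- sim_config(seed = 10L, n_trials = 200L, error_rate = 0.25)
  b <- gen_behavior(cfg)
  outb <- b$trials[b$trials$travel == "outbound", ]
  # first outbound cannot be an error; binomial CI on the rest
  eligible <- outb[-1, ]
  phat <- mean(!eligible$correct)
  ci <- 0.25 + c(-1, 1) * 1.96 * sqrt(0.25 * 0.75 / nrow(eligible))
  expect_gt(phat, ci[1])
  expect_lt(phat, ci[2])
})

test_that("ensemble spikes are valid and rates are realistic", {
  s <- fix_session()
  spk <- s$spikes
  for (uid in unique(spk$unit_id)[1:10]) {
    st <- spk$time_s[spk$unit_id == uid]
    expect_true(all(diff(st) > 0))
  }
  # determinism of the full session
  s2 <- simulate_session(s$config)
  expect_identical(s$spikes, s2$spikes)
  expect_identical(s$lfp$signal, s2$lfp$signal)
})

test_that("LFP has a theta peak during locomotion and planted ripples", {
  s <- fix_session()
  cfg <- s$config
  # a long run segment
  tr <- s$trials[1, ]
  i0 <- floor(tr$run_start_s * 1500) + 1500 / 4
  seg <- s$lfp$signal[i0:(i0 + 4096)]
  sp <- stats::spec.pgram(stats::ts(seg, frequency = 1500), plot = FALSE,
                          spans = 5)
  fpeak <- sp$freq[which.max(sp$spec)]
  expect_lt(abs(fpeak - cfg$theta_hz), 1)

  # planted SWR count within the Poisson CI for the dwell time used
  swrs <- s$truth$swrs
  dwell <- sum(pmax(s$trials$dwell_end_s - s$trials$dwell_start_s - 0.6, 0))
  lam <- cfg$swr_rate_hz * dwell
  expect_gt(nrow(swrs), stats::qpois(0.005, lam))
  expect_lt(nrow(swrs), stats::qpois(0.995, lam) + 1)

  # swr_rate 0: no ripple-band bursts above 3 SD during immobility
  cfg0 <- sim_config(seed = 13L, n_trials = 6L, swr_rate_hz = 0)
  s0 <- simulate_session(cfg0)
  lin0 <- linearize(s0$position, cfg0$maze, s0$trials)
  immo <- mask_to_intervals(lin0$time_s,
                            locomotor_mask(lin0$speed_cm_s)$immobility)
  sw0 <- detect_swrs(s0$lfp, immo)
  expect_equal(nrow(sw0), 0)
})

test_that("replay content honors fidelity and reverse ordering", {
  cfg <- sim_config(seed = 14L, n_trials = 16L, replay_fidelity = 1)
  b <- gen_behavior(cfg)
  swrs <- plant_swrs(cfg, b)
  ok <- !is.na(swrs$upcoming_choice)
  expect_true(all(swrs$replay_trajectory[ok] ==
                    paste0("C-to-", swrs$upcoming_choice[ok])))

  ens <- gen_ensemble(cfg, b)
  rc <- gen_replay_content(cfg, b, ens, swrs)
  # per event, reverse replays have participation order exactly reversed
  # relative to field-center order along the planted trajectory
  for (i in which(ok & swrs$duration_s >= 0.05)[1:3]) {
    sel <- rc$time_s >= swrs$start_s[i] &
      rc$time_s <= swrs$start_s[i] + swrs$duration_s[i]
    ev <- rc[sel & rc$region == "CA1", ]
    first_spike <- tapply(ev$time_s, ev$unit_id, min)
    side <- if (grepl("L", swrs$replay_trajectory[i])) "L" else "R"
    ctr_col <- paste0("field_center_", side, "_cm")
    centers <- ens$units[[ctr_col]][match(as.integer(names(first_spike)),
                                          ens$units$unit_id)]
    rho <- stats::cor(centers, first_spike, method = "spearman")
    expect_equal(unname(rho),
                 if (swrs$direction[i] == "reverse") -1 else 1)
  }
})

test_that("planted sequence events decode with the planted slope sign", {
  units <- fix_units()
  model <- fix_model_out()
  spk <- plant_sequence_event(units, "C-to-L", 130, duration_s = 0.125,
                              seed = 3L)
  expect_gte(length(unique(spk$unit_id)), 5)
  ev <- decode_event(model, spk, 0, 0.125)
  blk <- ev$pmat[seq_len(model$n_bins), ]
  r <- weighted_correlation(blk, x = (seq_len(model$n_bins) - 0.5) * 2,
                            t = ev$k * 0.01)
  expect_gt(r, 0.5)
  # reverse flag flips the sweep
  spk_r <- plant_sequence_event(units, "C-to-L", 130, duration_s = 0.125,
                                reverse = TRUE, seed = 3L)
  ev_r <- decode_event(model, spk_r, 0, 0.125)
  blk_r <- ev_r$pmat[seq_len(model$n_bins), ]
  expect_lt(weighted_correlation(blk_r,
                                 x = (seq_len(model$n_bins) - 0.5) * 2,
                                 t = ev_r$k * 0.01), -0.5)
})
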