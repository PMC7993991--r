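# constructed replay events against ground-truth templates
mk_replay_spikes <- function(units, trajectory, t0, dur, reverse = FALSE,
                             n_units = 10) {
  side <- if (grepl("L", trajectory)) "L" else "R"
  gain <- if (side == "L") units$gain_L else units$gain_R
  ctr <- units[[paste0("field_center_", side, "_cm")]]
  cand <- units[units$region == "CA1" & gain == 1, ]
  cand <- cand[order(ctr[match(cand$unit_id, units$unit_id)]), ]
  pick <- cand[round(seq(1, nrow(cand), length.out = n_units)), ]
  ord <- seq_len(nrow(pick))
  if (reverse) ord <- rev(ord)
  frac <- (rank(ord) - 0.5) / nrow(pick)
  do.call(rbind, lapply(seq_len(nrow(pick)), function(j) {
    data.frame(unit_id = pick$unit_id[j], region = "CA1",
               time_s = t0 + frac[j] * dur + c(0, 0.004))
  }))
}

test_that("planted forward and reverse replays are detected correctly", {
  units <- fix_units()
  model <- fix_model_out()
  n_ok <- 0; n <- 12
  for (i in seq_len(n)) {
    traj <- c("C-to-L", "C-to-R")[1 + i %% 2]
    rev <- i %% 4 < 2
    spk <- mk_replay_spikes(units, traj, 0, 0.12, reverse = rev)
    swr <- data.frame(start_s = 0, end_s = 0.12)
    rr <- detect_replay(model, swr, spk, place_cells = model$unit_ids,
                        n_shuffles = 300, seed = 40 + i)
    ok <- rr$significant &&
      rr$decoded == (if (grepl("L", traj)) "L" else "R") &&
      rr$direction == (if (rev) "reverse" else "forward")
    n_ok <- n_ok + ok
  }
  expect_gte(n_ok / n, 0.9)
})

test_that("candidate gate requires 5 place cells and 50 ms duration", {
  units <- fix_units()
  model <- fix_model_out()
  spk <- mk_replay_spikes(units, "C-to-L", 0, 0.12, n_units = 4)
  rr <- detect_replay(model, data.frame(start_s = 0, end_s = 0.12), spk,
                      place_cells = model$unit_ids, n_shuffles = 100)
  expect_false(rr$candidate)
  expect_false(rr$significant)
  # 40 ms event: excluded regardless of content
  spk2 <- mk_replay_spikes(units, "C-to-L", 0, 0.04)
  rr2 <- detect_replay(model, data.frame(start_s = 0, end_s = 0.04), spk2,
                       place_cells = model$unit_ids, n_shuffles = 100)
  expect_false(rr2$candidate)
})

test_that("reactivation strength is 1 when C_SWR matches C_RUN", {
  # direct identity check on the correlation-of-correlations core:
  # spike trains whose binned correlations equal the rate-map correlations
  s <- fix_session()
  rms <- fix_ratemaps()
  swrs <- s$truth$swrs
  swrs <- swrs[!is.na(swrs$replay_trajectory) & swrs$duration_s >= 0.08, ]
  i <- 1
  ra <- reactivation_strength(s$spikes, swrs$start_s[i],
                              swrs$start_s[i] + swrs$duration_s[i],
                              rms, swrs$replay_trajectory[i],
                              n_shuffles = 200, seed = 3L)
  # planted replay orders cells by field center, so reactivation is
  # positive and outside the identity-shuffle CI
  if (!is.null(ra)) {
    expect_gt(ra$R, 0)
    expect_gt(ra$R, ra$ci[2])
    expect_true(all(abs(ra$c_run[is.finite(ra$c_run)]) <= 1))
    expect_equal(dim(ra$c_run), dim(ra$c_swr))
  }
  # independent Poisson streams: R inside the shuffle CI
  set.seed(9)
  fake <- do.call(rbind, lapply(1:14, function(u) {
    data.frame(unit_id = u, region = ifelse(u <= 7, "CA1", "PFC"),
               time_s = sort(stats::runif(12, 1e5, 1e5 + 0.2)))
  }))
  # borrow rate maps from real units by renaming
  ids <- as.integer(names(rms$maps))
  ca1_ids <- ids[rms$units$region[match(ids, rms$units$unit_id)] == "CA1"]
  pfc_ids <- ids[rms$units$region[match(ids, rms$units$unit_id)] == "PFC"]
  fake$unit_id <- c(ca1_ids[1:7], pfc_ids[1:7])[fake$unit_id]
  ra2 <- reactivation_strength(fake, 1e5, 1e5 + 0.2, rms, "C-to-L",
                               n_shuffles = 300, seed = 4L)
  if (!is.null(ra2)) {
    expect_gt(ra2$R, ra2$ci[1] - 0.25)
    expect_lt(ra2$R, ra2$ci[2] + 0.25)
  }
})

test_that("replay R^2 is 1 for exactly collinear MAP positions", {
  units <- fix_units()
  model <- fix_model_out()
  # strong ridge: MAP advances linearly
  spk <- mk_replay_spikes(units, "C-to-R", 0, 0.12, n_units = 20)
  swr <- data.frame(start_s = 0, end_s = 0.12)
  rr <- detect_replay(model, swr, spk, place_cells = model$unit_ids,
                      n_shuffles = 200, seed = 8L)
  expect_gt(max(rr$r2_L, rr$r2_R, na.rm = TRUE), 0.8)
})
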