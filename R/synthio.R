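## Synthetic W-track sessions with known ground truth.
##
## The generator emulates the continuous spatial alternation task: runs
## between reward wells at ~30 Hz position sampling, trajectory-selective
## CA1/PFC units spiking as inhomogeneous Poisson processes (thinning)
## with place tuning, theta-phase modulation with precession, optional
## theta-cycle skipping, a 1.5 kHz reference LFP with locomotor theta and
## planted ripple bursts, and SWR replay content whose trajectory matches
## the upcoming choice with configurable fidelity.

#' Simulation configuration for a synthetic W-track session
#'
#' Defaults describe a single behavioral session of the continuous
#' alternation task: ~40 traversals, 40 CA1 + 30 PFC units, 8 Hz theta,
#' SWRs at 0.3 Hz during immobility at wells.
#'
#' @param seed integer RNG seed; all randomness derives from it.
#' @param n_trials number of traversals (outbound + inbound runs); >= 2.
#' @param maze a [w_maze()] geometry.
#' @param n_ca1,n_pfc unit counts per region.
#' @param selectivity_frac fraction of trajectory-selective units.
#' @param field_width_cm Gaussian place-field SD for CA1 (PFC fields are
#'   twice as wide and lower-rate).
#' @param asymmetry field skew in \[-1, 1\]; positive skews mass toward
#'   later (travel-direction) positions, giving a positive asymmetry index.
#' @param precession_slope_deg_per_cm phase-precession slope (negative =
#'   phase advances with travel).
#' @param skip_frac fraction of units whose theta gain alternates between
#'   cycles (cycle skipping).
#' @param theta_hz theta frequency, in \[6, 12\].
#' @param swr_rate_hz SWR rate during immobility at wells.
#' @param replay_fidelity probability a planted replay depicts the
#'   upcoming outbound choice.
#' @param error_rate fraction of incorrect outbound trials.
#' @param run_speed_cm_s mean running speed.
#' @param peak_hz_ca1,peak_hz_pfc range of planted rate-map peak rates.
#' @param baseline_hz position-independent background rate.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_trials = 40L, maze = w_maze(),
                       n_ca1 = 40L, n_pfc = 30L,
                       selectivity_frac = 0.6, field_width_cm = 8,
                       asymmetry = 0, precession_slope_deg_per_cm = -8,
                       skip_frac = 0.2, theta_hz = 8, swr_rate_hz = 0.3,
                       replay_fidelity = 0.8, error_rate = 0.15,
                       run_speed_cm_s = 25,
                       peak_hz_ca1 = c(8, 20), peak_hz_pfc = c(4, 10),
                       baseline_hz = 0.15) {
  cfg <- list(seed = as.integer(seed), n_trials = as.integer(n_trials),
              maze = maze, n_ca1 = as.integer(n_ca1),
              n_pfc = as.integer(n_pfc),
              selectivity_frac = selectivity_frac,
              field_width_cm = field_width_cm, asymmetry = asymmetry,
              precession_slope_deg_per_cm = precession_slope_deg_per_cm,
              skip_frac = skip_frac, theta_hz = theta_hz,
              swr_rate_hz = swr_rate_hz, replay_fidelity = replay_fidelity,
              error_rate = error_rate, run_speed_cm_s = run_speed_cm_s,
              peak_hz_ca1 = peak_hz_ca1, peak_hz_pfc = peak_hz_pfc,
              baseline_hz = baseline_hz)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c("selectivity_frac", "skip_frac", "replay_fidelity", "error_rate")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (abs(cfg$asymmetry) > 1) stop("asymmetry must be in [-1, 1]")
  if (cfg$n_trials < 2) stop("n_trials must be >= 2")
  if (cfg$n_ca1 <= 0 || cfg$n_pfc <= 0) stop("unit counts must be > 0")
  if (cfg$theta_hz < 6 || cfg$theta_hz > 12) stop("theta_hz must be in [6, 12]")
  if (!inherits(cfg$maze, "maze_geometry")) stop("maze must be a maze_geometry")
  invisible(cfg)
}

POS_FS <- 30    # position sampling rate, Hz
LFP_FS <- 1500  # LFP sampling rate, Hz

## Planted theta oscillator with cycle-length jitter. Real theta wanders
## cycle to cycle (~10% of the period); without that wander the spike-train
## autocorrelogram of a theta-locked cell would have non-decaying theta
## peaks, which no real cell shows. Returns the cycle start times; spikes
## and LFP share the same oscillator so phase-recovery tests are exact.
plant_theta_oscillator <- function(theta_hz, t_max, jitter_s = 0.015,
                                   seed = 1L) {
  set.seed(seed)
  period <- 1 / theta_hz
  n <- ceiling((t_max + 2) / (0.7 * period))
  durs <- pmin(pmax(stats::rnorm(n, period, jitter_s), 0.7 * period),
               1.4 * period)
  starts <- c(0, cumsum(durs))
  starts[starts <= t_max + 1]
}

## Phase (radians, 0 at cycle start, wrapped to (-pi, pi]) and cycle index
## at arbitrary times, for a planted oscillator.
oscillator_phase <- function(starts, t) {
  i <- pmin(pmax(findInterval(t, starts), 1L), length(starts) - 1L)
  frac <- (t - starts[i]) / (starts[i + 1L] - starts[i])
  list(phase = wrap_pi(2 * pi * frac), cycle = i)
}

#' Generate W-track alternation behavior
#'
#' Simulates runs between wells at 30 Hz with trapezoidal speed profiles
#' and uniform 2-10 s immobility dwells at the wells. Outbound choices
#' follow the alternation rule with a configurable error rate; inbound
#' returns to the center well are always correct.
#'
#' @param cfg a [sim_config()].
#' @return list with `position` (time_s, x_cm, y_cm), `trials` (one row per
#'   traversal: travel, choice, correct, trajectory, run interval, beam
#'   trigger times, dwell interval at the destination well), and `truth`
#'   (per-sample arclength, trajectory label, moving flag, trial id).
#' @export
gen_behavior <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  maze <- cfg$maze
  dt <- 1 / POS_FS
  accel <- 40  # cm/s^2

  time_s <- numeric(0); xs <- numeric(0); ys <- numeric(0)
  arclen <- numeric(0); traj_lab <- character(0)
  moving <- logical(0); trial_id <- integer(0)
  trials <- list()
  t_now <- 0

  add_dwell <- function(well_xy, dur, tid) {
    n <- max(1L, round(dur * POS_FS))
    tt <- t_now + seq_len(n) * dt
    time_s <<- c(time_s, tt)
    xs <<- c(xs, well_xy[1] + stats::rnorm(n, 0, 0.3))
    ys <<- c(ys, well_xy[2] + stats::rnorm(n, 0, 0.3))
    arclen <<- c(arclen, rep(NA_real_, n))
    traj_lab <<- c(traj_lab, rep("none", n))
    moving <<- c(moving, rep(FALSE, n))
    trial_id <<- c(trial_id, rep(tid, n))
    t_now <<- tt[n]
  }

  last_side <- NULL
  at_center <- TRUE
  side_now <- NULL
  add_dwell(maze$wells$C, stats::runif(1, 2, 10), NA_integer_)

  for (tr in seq_len(cfg$n_trials)) {
    if (at_center) {
      travel <- "outbound"
      corr_choice <- if (is.null(last_side)) sample(c("L", "R"), 1) else
        setdiff(c("L", "R"), last_side)
      err <- stats::runif(1) < cfg$error_rate && !is.null(last_side)
      choice <- if (err) setdiff(c("L", "R"), corr_choice) else corr_choice
      correct <- identical(choice, corr_choice)
      trajectory <- paste0("C-to-", choice)
      dest <- maze$wells[[choice]]
      last_side <- choice
    } else {
      travel <- "inbound"
      choice <- side_now
      correct <- TRUE
      trajectory <- paste0(choice, "-to-C")
      dest <- maze$wells$C
    }
    path <- maze$paths[[trajectory]]
    plen <- maze$path_length_cm
    inbound <- travel == "inbound"

    # integrate a trapezoidal speed profile along the path
    s <- if (inbound) plen else 0
    t_run <- t_now
    run_t <- c(); run_s <- c(); run_v <- c()
    v <- 0
    repeat {
      t_run <- t_run + dt
      trav <- if (inbound) plen - s else s
      remain <- plen - trav
      v_target <- min(cfg$run_speed_cm_s, sqrt(2 * accel * max(remain, 0.5)))
      v <- min(v + accel * dt, v_target) * exp(stats::rnorm(1, 0, 0.03))
      s <- s + (if (inbound) -v else v) * dt
      done <- if (inbound) s <= 0 else s >= plen
      if (done) s <- if (inbound) 0 else plen
      run_t <- c(run_t, t_run); run_s <- c(run_s, s); run_v <- c(run_v, v)
      if (done) break
      if (t_run - t_now > 120) stop("runaway trial simulation")
    }
    xy <- path_point_at(path, run_s)
    n <- length(run_t)
    time_s <- c(time_s, run_t)
    xs <- c(xs, xy[, 1] + stats::rnorm(n, 0, 0.4))
    ys <- c(ys, xy[, 2] + stats::rnorm(n, 0, 0.4))
    arclen <- c(arclen, run_s)
    traj_lab <- c(traj_lab, rep(trajectory, n))
    moving <- c(moving, rep(TRUE, n))
    trial_id <- c(trial_id, rep(tr, n))

    run_start <- t_now + dt
    t_now <- run_t[n]
    # beam triggers: nose crossing within 2 cm of a well
    trav_s <- if (inbound) plen - run_s else run_s
    arr_trig <- run_t[which(trav_s >= plen - 2)[1]]
    dep_trig <- run_t[which(trav_s >= 2)[1]]

    dwell_dur <- stats::runif(1, 2, 10)
    dwell_start <- t_now
    add_dwell(dest, dwell_dur, NA_integer_)
    trials[[tr]] <- data.frame(
      trial_id = tr, travel = travel, choice = choice, correct = correct,
      trajectory = trajectory, run_start_s = run_start, run_end_s = arr_trig,
      departure_trigger_s = dep_trig, arrival_trigger_s = arr_trig,
      dwell_start_s = dwell_start, dwell_end_s = t_now,
      stringsAsFactors = FALSE)

    at_center <- inbound
    side_now <- if (inbound) NULL else choice
  }

  list(
    position = data.frame(time_s = time_s, x_cm = xs, y_cm = ys),
    trials = do.call(rbind, trials),
    truth = data.frame(time_s = time_s, arclength_cm = arclen,
                       trajectory = traj_lab, moving = moving,
                       trial_id = trial_id, stringsAsFactors = FALSE)
  )
}

## Per-unit ground-truth tuning parameters.
make_units <- function(cfg) {
  set.seed(cfg$seed + 2L)
  n <- cfg$n_ca1 + cfg$n_pfc
  region <- c(rep("CA1", cfg$n_ca1), rep("PFC", cfg$n_pfc))
  plen <- cfg$maze$path_length_cm
  sd_cm <- ifelse(region == "CA1", cfg$field_width_cm, 2 * cfg$field_width_cm)
  peak <- ifelse(region == "CA1",
                 stats::runif(n, cfg$peak_hz_ca1[1], cfg$peak_hz_ca1[2]),
                 stats::runif(n, cfg$peak_hz_pfc[1], cfg$peak_hz_pfc[2]))
  selective <- stats::runif(n) < cfg$selectivity_frac
  preferred <- sample(c("L", "R"), n, replace = TRUE)
  # on the non-preferred trajectory a selective cell fires at a low,
  # spatially diffuse rate (not a scaled copy of its field); the uniform
  # rate is set so |SI| clears the region threshold
  np_hz <- ifelse(region == "CA1", 0.02, 0.08) * peak
  gain_L <- ifelse(!selective | preferred == "L", 1, 0)
  gain_R <- ifelse(!selective | preferred == "R", 1, 0)
  center <- stats::runif(n, 10, plen - 10)
  # fields on the two side trajectories are displaced a few cm from each
  # other (path-equivalent cells are similar, not identical, across arms)
  jit <- ifelse(region == "CA1", 4, 8)
  data.frame(
    unit_id = seq_len(n), region = region, peak_hz = peak,
    field_center_cm = center,
    field_center_L_cm = pmin(pmax(center + stats::rnorm(n, 0, jit), 5),
                             plen - 5),
    field_center_R_cm = pmin(pmax(center + stats::rnorm(n, 0, jit), 5),
                             plen - 5),
    field_sd_cm = sd_cm, selective = selective,
    preferred = ifelse(selective, preferred, NA_character_),
    gain_L = gain_L, gain_R = gain_R, np_uniform_hz = np_hz,
    precession_slope_deg_per_cm = cfg$precession_slope_deg_per_cm,
    skip = stats::runif(n) < cfg$skip_frac,
    phi0 = stats::runif(n, 0.6 * pi, pi),
    stringsAsFactors = FALSE)
}

#' Generate trajectory-selective place/PFC spike trains
#'
#' Inhomogeneous-Poisson spiking by thinning: rate = place-field tuning x
#' trajectory-selectivity gain x normalized theta-phase gain (von Mises
#' shaped, preferred phase advancing linearly with within-field travel
#' distance = phase precession) x cycle-skipping gain, plus a small
#' position-independent baseline.
#'
#' @param cfg a [sim_config()].
#' @param behavior output of [gen_behavior()].
#' @return list with `spikes` (unit_id, region, time_s) and `units`
#'   (ground-truth tuning table).
#' @export
gen_ensemble <- function(cfg, behavior) {
  units <- make_units(cfg)
  tr_truth <- behavior$truth
  t_max <- max(tr_truth$time_s)
  osc <- plant_theta_oscillator(cfg$theta_hz, t_max, seed = cfg$seed + 7L)
  set.seed(cfg$seed + 3L)
  kappa <- 1.5
  # normalization so the expected in-field rate map peak equals peak_hz
  Eg <- besselI(kappa, 0) * exp(-kappa)
  g_max <- 1 / Eg
  skip_hi <- 1.95; skip_lo <- 0.05

  side_of <- function(traj) ifelse(grepl("L", traj), "L",
                            ifelse(grepl("R", traj), "R", NA))
  out <- vector("list", nrow(units))
  for (u in seq_len(nrow(units))) {
    info <- units[u, ]
    lam_max <- cfg$baseline_hz +
      info$peak_hz * g_max * (if (info$skip) skip_hi else 1) * 1.02
    n_cand <- stats::rpois(1, lam_max * t_max)
    tc <- sort(stats::runif(n_cand, 0, t_max))
    idx <- pmin(pmax(round(tc * POS_FS), 1L), nrow(tr_truth))
    lp <- tr_truth$arclength_cm[idx]
    traj <- tr_truth$trajectory[idx]
    mov <- tr_truth$moving[idx]
    lam <- rep(cfg$baseline_hz, n_cand)
    act <- mov & !is.na(lp)
    if (any(act)) {
      sd_e <- info$field_sd_cm * (1 - 0.6 * cfg$asymmetry)
      sd_l <- info$field_sd_cm * (1 + 0.6 * cfg$asymmetry)
      inbound <- grepl("-to-C", traj[act])
      ctr <- ifelse(side_of(traj[act]) == "L", info$field_center_L_cm,
                    info$field_center_R_cm)
      dx <- lp[act] - ctr
      # oriented: early side = approach side along travel
      early <- ifelse(inbound, dx > 0, dx < 0)
      sd_use <- ifelse(early, sd_e, sd_l)
      # note: for inbound, travel direction is decreasing arclength
      gain <- ifelse(side_of(traj[act]) == "L", info$gain_L, info$gain_R)
      # preferred/nonselective side: Gaussian field; non-preferred side:
      # low diffuse rate
      place <- ifelse(gain == 1, exp(-0.5 * (dx / sd_use)^2),
                      info$np_uniform_hz / info$peak_hz)
      gain <- 1
      d_in <- ifelse(inbound,
                     (ctr + 2.5 * info$field_sd_cm) - lp[act],
                     lp[act] - (ctr - 2.5 * info$field_sd_cm))
      slope_rad <- info$precession_slope_deg_per_cm * pi / 180
      mu <- info$phi0 + slope_rad * d_in
      op <- oscillator_phase(osc, tc[act])
      g_theta <- exp(kappa * (cos(op$phase - mu) - 1)) / Eg
      g_skip <- if (info$skip) {
        ifelse(op$cycle %% 2 == 0, skip_hi, skip_lo)
      } else 1
      lam[act] <- cfg$baseline_hz + info$peak_hz * place * gain * g_theta * g_skip
    }
    keep <- stats::runif(n_cand) < lam / lam_max
    st <- unique(tc[keep])
    if (length(st)) {
      out[[u]] <- data.frame(unit_id = info$unit_id, region = info$region,
                             time_s = st, stringsAsFactors = FALSE)
    }
  }
  spikes <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  spikes <- spikes[order(spikes$unit_id, spikes$time_s), ]
  rownames(spikes) <- NULL
  list(spikes = spikes, units = units)
}

#' Plant SWR times during immobility at wells
#'
#' Poisson event times at `swr_rate_hz` within each well dwell (0.3 s
#' margins), durations uniform 80-150 ms, each assigned a replay
#' trajectory equal to the upcoming outbound choice with probability
#' `replay_fidelity`, and a forward/reverse direction (50/50).
#'
#' @param cfg a [sim_config()].
#' @param behavior output of [gen_behavior()].
#' @return data.frame: swr_id, start_s, duration_s, upcoming choice,
#'   replay trajectory, direction.
#' @export
plant_swrs <- function(cfg, behavior) {
  set.seed(cfg$seed + 4L)
  trials <- behavior$trials
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(trials))) {
    d0 <- trials$dwell_start_s[i] + 0.3
    d1 <- trials$dwell_end_s[i] - 0.3
    if (d1 - d0 < 0.3) next
    n <- stats::rpois(1, cfg$swr_rate_hz * (d1 - d0))
    if (n == 0) next
    ts <- sort(stats::runif(n, d0, d1 - 0.15))
    durs <- stats::runif(n, 0.08, 0.15)
    nxt <- trials[trials$travel == "outbound" &
                    trials$run_start_s > trials$dwell_start_s[i], ]
    upcoming <- if (nrow(nxt)) nxt$choice[1] else NA_character_
    for (j in seq_len(n)) {
      k <- k + 1L
      ch <- upcoming
      if (!is.na(ch) && stats::runif(1) > cfg$replay_fidelity)
        ch <- setdiff(c("L", "R"), ch)
      rows[[k]] <- data.frame(
        swr_id = k, start_s = ts[j], duration_s = durs[j],
        upcoming_choice = upcoming,
        replay_trajectory = if (is.na(ch)) NA_character_ else paste0("C-to-", ch),
        direction = sample(c("forward", "reverse"), 1),
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(data.frame(swr_id = integer(0), start_s = numeric(0),
                                 duration_s = numeric(0),
                                 upcoming_choice = character(0),
                                 replay_trajectory = character(0),
                                 direction = character(0)))
  out <- do.call(rbind, rows)
  # drop overlapping events
  keep <- c(TRUE, diff(out$start_s) > 0.25)
  out <- out[keep, ]
  out$swr_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Generate the reference LFP channel
#'
#' 1.5 kHz signal: theta sinusoid (amplitude follows a smoothed locomotion
#' indicator) + white noise, with 200 Hz ripple bursts injected at planted
#' SWR times. The theta phase of the signal equals the planted oscillator
#' phase used for spiking, so phase-recovery tests are exact.
#'
#' @param cfg a [sim_config()].
#' @param behavior output of [gen_behavior()].
#' @param swrs planted SWR table from [plant_swrs()]; `NULL` plants one.
#' @return list: `fs`, `time_s`, `signal`, and the `swrs` table used.
#' @export
gen_lfp <- function(cfg, behavior, swrs = NULL) {
  if (is.null(swrs)) swrs <- plant_swrs(cfg, behavior)
  set.seed(cfg$seed + 5L)
  t_max <- max(behavior$truth$time_s)
  tt <- seq(0, t_max, by = 1 / LFP_FS)
  mov30 <- gauss_smooth(as.numeric(behavior$truth$moving), 0.25 * POS_FS)
  amp <- stats::approx(behavior$truth$time_s, mov30, tt, rule = 2)$y
  osc <- plant_theta_oscillator(cfg$theta_hz, t_max, seed = cfg$seed + 7L)
  sig <- amp * cos(oscillator_phase(osc, tt)$phase) +
    stats::rnorm(length(tt), 0, 0.3)
  for (i in seq_len(nrow(swrs))) {
    tc <- swrs$start_s[i] + swrs$duration_s[i] / 2
    sdv <- swrs$duration_s[i] / 5
    w <- abs(tt - tc) < 3 * sdv
    sig[w] <- sig[w] + exp(-0.5 * ((tt[w] - tc) / sdv)^2) *
      sin(2 * pi * 200 * (tt[w] - tc))
  }
  list(fs = LFP_FS, time_s = tt, signal = sig, swrs = swrs)
}

#' Plant time-compressed replay spike content inside SWRs
#'
#' Within each planted SWR of duration >= 50 ms, units with fields on the
#' planted trajectory fire two-spike bursts in field-center order along the
#' trajectory (reversed for reverse replays), compressed into the SWR
#' window.
#'
#' @param cfg a [sim_config()].
#' @param behavior output of [gen_behavior()].
#' @param ensemble output of [gen_ensemble()].
#' @param swrs planted SWR table.
#' @param n_ca1_units,n_pfc_units units recruited per event.
#' @return data.frame of additional spikes (unit_id, region, time_s).
#' @export
gen_replay_content <- function(cfg, behavior, ensemble, swrs,
                               n_ca1_units = 10, n_pfc_units = 6) {
  set.seed(cfg$seed + 6L)
  units <- ensemble$units
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(swrs))) {
    if (swrs$duration_s[i] < 0.05 || is.na(swrs$replay_trajectory[i])) next
    side <- if (grepl("L", swrs$replay_trajectory[i])) "L" else "R"
    gain <- if (side == "L") units$gain_L else units$gain_R
    ctr_col <- if (side == "L") "field_center_L_cm" else "field_center_R_cm"
    for (spec in list(c("CA1", n_ca1_units), c("PFC", n_pfc_units))) {
      cand <- units[units$region == spec[1] & gain > 0.5, ]
      if (nrow(cand) < 5) next
      cand <- cand[order(cand[[ctr_col]]), ]
      pick <- cand[round(seq(1, nrow(cand),
                             length.out = min(nrow(cand), as.numeric(spec[2])))), ]
      ord <- seq_len(nrow(pick))
      if (swrs$direction[i] == "reverse") ord <- rev(ord)
      frac <- (rank(ord) - 0.5) / nrow(pick)
      t0 <- swrs$start_s[i] + frac * (swrs$duration_s[i] - 0.006)
      for (j in seq_len(nrow(pick))) {
        k <- k + 1L
        rows[[k]] <- data.frame(unit_id = pick$unit_id[j],
                                region = pick$region[j],
                                time_s = c(t0[j], t0[j] + 0.004),
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(data.frame(unit_id = integer(0), region = character(0),
                                 time_s = numeric(0)))
  do.call(rbind, rows)
}

#' Generate a standalone theta-modulated spike train
#'
#' Inhomogeneous-Poisson train whose rate is modulated by a planted theta
#' oscillator with cycle-length jitter (see the generator's oscillator),
#' optionally cycle-skipping (theta gain alternating between cycles).
#' Intended for direct tests of autocorrelogram and cycle-skipping
#' estimators without a full session.
#'
#' @param duration_s train duration.
#' @param rate_hz mean firing rate.
#' @param theta_hz theta frequency (default 8).
#' @param kappa von Mises concentration of the theta modulation (default 2).
#' @param skip alternate theta gain between even/odd cycles.
#' @param jitter_s cycle-length jitter SD, s (default 0.015).
#' @param seed RNG seed.
#' @return numeric spike times, strictly increasing.
#' @export
gen_theta_spike_train <- function(duration_s, rate_hz, theta_hz = 8,
                                  kappa = 2, skip = FALSE,
                                  jitter_s = 0.015, seed = 1L) {
  osc <- plant_theta_oscillator(theta_hz, duration_s, jitter_s, seed)
  set.seed(seed + 1L)
  Eg <- besselI(kappa, 0) * exp(-kappa)
  skip_hi <- 1.95; skip_lo <- 0.05
  lam_max <- rate_hz / Eg * (if (skip) skip_hi else 1) * 1.02
  n <- stats::rpois(1, lam_max * duration_s)
  tc <- sort(stats::runif(n, 0, duration_s))
  op <- oscillator_phase(osc, tc)
  g <- exp(kappa * (cos(op$phase) - 1)) / Eg
  if (skip) g <- g * ifelse(op$cycle %% 2 == 0, skip_hi, skip_lo)
  lam <- rate_hz * g
  unique(tc[stats::runif(n) < lam / lam_max])
}

#' Encoding templates directly from ground-truth tuning
#'
#' Builds an [build_templates()]-compatible encoding model from the
#' planted unit tuning (Gaussian fields x trajectory gain) instead of
#' estimated rate maps, for recovery tests with a known encoder.
#'
#' @param units ground-truth unit table from [gen_ensemble()]/[make_units()].
#' @param maze a [w_maze()] geometry.
#' @param travel "outbound" or "inbound".
#' @param region optional region restriction.
#' @param bin_cm spatial bin (default 2).
#' @param rate_floor_hz template floor (default 0.01).
#' @return an `encoding_model` (see [build_templates()]).
#' @export
templates_from_truth <- function(units, maze, travel = "outbound",
                                 region = NULL, bin_cm = 2,
                                 rate_floor_hz = 0.01) {
  if (!is.null(region)) units <- units[units$region == region, ]
  bins <- seq(0, maze$path_length_cm - bin_cm, by = bin_cm)
  centers <- bins + bin_cm / 2
  f <- t(vapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    gL <- if (u$gain_L == 1) {
      exp(-0.5 * ((centers - u$field_center_L_cm) / u$field_sd_cm)^2) *
        u$peak_hz
    } else rep(u$np_uniform_hz, length(centers))
    gR <- if (u$gain_R == 1) {
      exp(-0.5 * ((centers - u$field_center_R_cm) / u$field_sd_cm)^2) *
        u$peak_hz
    } else rep(u$np_uniform_hz, length(centers))
    c(pmax(gL, rate_floor_hz), pmax(gR, rate_floor_hz))
  }, numeric(2 * length(centers))))
  trajs <- if (travel == "outbound") c("C-to-L", "C-to-R") else
    c("L-to-C", "R-to-C")
  structure(list(f = f, unit_ids = units$unit_id, bin_left_cm = bins,
                 trajectories = trajs, travel = travel,
                 n_bins = length(bins)),
            class = "encoding_model")
}

#' Plant one theta-timescale sequence event
#'
#' Constructs spikes for a single candidate event: the represented
#' position sweeps from `pos_cm - span_back_cm` to `pos_cm +
#' span_ahead_cm` (oriented along travel) over the event duration; units
#' with fields on the swept trajectory fire Poisson spikes at rate
#' `rate_gain` x their tuning evaluated at the swept position.
#'
#' @param units ground-truth unit table.
#' @param trajectory trajectory type swept.
#' @param pos_cm the animal's (nominal) position.
#' @param t0 event start time, s.
#' @param duration_s event duration (default 0.125).
#' @param span_back_cm,span_ahead_cm sweep extent behind/ahead (20, 30).
#' @param reverse sweep from ahead to behind instead.
#' @param rate_gain multiplier on tuning rates during the sweep
#'   (default 6, the theta-timescale compression of firing).
#' @param region restrict firing units (default "CA1").
#' @param seed RNG seed.
#' @return data.frame of spikes (unit_id, region, time_s); attribute
#'   `truth` holds the planted sweep (start/end position, velocity).
#' @export
plant_sequence_event <- function(units, trajectory, pos_cm, t0 = 0,
                                 duration_s = 0.125, span_back_cm = 20,
                                 span_ahead_cm = 30, reverse = FALSE,
                                 rate_gain = 6, region = "CA1", seed = 1L) {
  set.seed(seed)
  uu <- units[units$region == region, ]
  side <- if (grepl("L", trajectory)) "L" else "R"
  gain <- if (side == "L") uu$gain_L else uu$gain_R
  inbound <- grepl("-to-C", trajectory)
  orient <- if (inbound) -1 else 1
  p_from <- pos_cm - orient * span_back_cm
  p_to <- pos_cm + orient * span_ahead_cm
  if (reverse) { tmp <- p_from; p_from <- p_to; p_to <- tmp }
  dt <- 0.001
  tt <- seq(0, duration_s - dt, by = dt)
  xx <- p_from + (p_to - p_from) * tt / duration_s
  ctr <- if (side == "L") uu$field_center_L_cm else uu$field_center_R_cm
  out <- list()
  for (j in seq_len(nrow(uu))) {
    lam <- rate_gain * uu$peak_hz[j] * gain[j] *
      exp(-0.5 * ((xx - ctr[j]) / uu$field_sd_cm[j])^2)
    fire <- stats::runif(length(tt)) < lam * dt
    if (!any(fire)) next
    out[[length(out) + 1]] <- data.frame(
      unit_id = uu$unit_id[j], region = region,
      time_s = t0 + tt[fire] + stats::runif(sum(fire), 0, dt),
      stringsAsFactors = FALSE)
  }
  spk <- if (length(out)) do.call(rbind, out) else
    data.frame(unit_id = integer(0), region = character(0),
               time_s = numeric(0))
  spk <- spk[order(spk$time_s), ]
  rownames(spk) <- NULL
  attr(spk, "truth") <- list(
    trajectory = trajectory, pos_cm = pos_cm,
    start_cm = p_from, end_cm = p_to,
    v_cm_s = (p_to - p_from) / duration_s, reverse = reverse)
  spk
}

#' Simulate a complete synthetic session
#'
#' Orchestrates [gen_behavior()], [gen_ensemble()], [plant_swrs()],
#' [gen_lfp()] and [gen_replay_content()] into one session container.
#'
#' @param cfg a [sim_config()].
#' @param lfp generate the LFP channel (set `FALSE` to skip the largest
#'   component when only spikes/behavior are needed).
#' @return object of class `wtrack_session`: `config`, `position`,
#'   `trials`, `spikes`, `lfp`, and ground `truth` (behavior samples,
#'   unit tuning, planted SWRs).
#' @export
simulate_session <- function(cfg = sim_config(), lfp = TRUE) {
  beh <- gen_behavior(cfg)
  ens <- gen_ensemble(cfg, beh)
  swrs <- plant_swrs(cfg, beh)
  lf <- if (lfp) gen_lfp(cfg, beh, swrs) else NULL
  rep_spk <- gen_replay_content(cfg, beh, ens, swrs)
  spikes <- rbind(ens$spikes, rep_spk)
  spikes <- spikes[order(spikes$unit_id, spikes$time_s), ]
  # enforce strictly increasing spike times per unit
  dup <- duplicated(spikes[, c("unit_id", "time_s")])
  spikes <- spikes[!dup, ]
  rownames(spikes) <- NULL
  structure(list(
    config = cfg, position = beh$position, trials = beh$trials,
    spikes = spikes, lfp = lf,
    truth = list(behavior = beh$truth, units = ens$units, swrs = swrs)
  ), class = "wtrack_session")
}

#' @export
print.wtrack_session <- function(x, ...) {
  cat(sprintf(
    "wtrack_session: %d trials, %.0f s, %d units (%d CA1 / %d PFC), %d spikes, %d planted SWRs\n",
    nrow(x$trials), max(x$position$time_s),
    length(unique(x$spikes$unit_id)),
    sum(x$truth$units$region == "CA1"), sum(x$truth$units$region == "PFC"),
    nrow(x$spikes), nrow(x$truth$swrs)))
  invisible(x)
}
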