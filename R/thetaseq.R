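## Theta-sequence analysis: candidate theta-cycle events, fast-timescale
## decoding, sequence scoring (weighted correlation + best-fit-line
## goodness-of-fit), circular shuffle significance, forward/reverse
## classification, the distance index, choice representation and
## coherent CA1-PFC events.

#' Candidate theta-cycle events
#'
#' Theta cycles with at least `min_units` active units of the region,
#' mean running speed > `min_speed`, and duration within `dur_range`.
#'
#' @param cycles a [segment_theta_cycles()] result.
#' @param spikes spike table (unit_id, region, time_s).
#' @param linearized a [linearize()] table.
#' @param region "CA1" or "PFC".
#' @param min_units active-unit gate (default 5; 10 for the stricter
#'   control).
#' @param min_speed cm/s (default 10).
#' @param dur_range retained duration range, s (default c(0.1, 0.2)).
#' @return data.frame: cycle_id, start_s, end_s, duration_s, n_active,
#'   speed_cm_s, pos_cm, trajectory, trial_id, travel.
#' @export
find_candidates <- function(cycles, spikes, linearized, region,
                            min_units = 5, min_speed = 10,
                            dur_range = c(0.1, 0.2)) {
  cyc <- cycles$cycles
  spk <- spikes[spikes$region == region, ]
  out <- list()
  for (i in seq_len(nrow(cyc))) {
    if (cyc$duration_s[i] < dur_range[1] || cyc$duration_s[i] > dur_range[2])
      next
    inwin <- spk$time_s >= cyc$start_s[i] & spk$time_s < cyc$end_s[i]
    n_active <- length(unique(spk$unit_id[inwin]))
    if (n_active < min_units) next
    sel <- linearized$time_s >= cyc$start_s[i] &
      linearized$time_s < cyc$end_s[i]
    if (!any(sel)) next
    speed <- mean(linearized$speed_cm_s[sel])
    if (is.na(speed) || speed <= min_speed) next
    pos <- mean(linearized$linear_cm[sel], na.rm = TRUE)
    traj <- linearized$trajectory[sel]
    traj <- traj[traj != "none"]
    if (!length(traj) || is.na(pos)) next
    out[[length(out) + 1]] <- data.frame(
      cycle_id = i, start_s = cyc$start_s[i], end_s = cyc$end_s[i],
      duration_s = cyc$duration_s[i], n_active = n_active,
      speed_cm_s = speed, pos_cm = pos, trajectory = traj[1],
      trial_id = linearized$trial_id[sel][1],
      travel = if (grepl("^C", traj[1])) "outbound" else "inbound",
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

#' Decode one candidate event at the theta timescale
#'
#' 20 ms windows advanced in 10 ms steps across the event; joint
#' normalization across the two trajectories. Zero-spike windows are
#' dropped; fewer than 3 decodable windows drops the candidate.
#'
#' @param model an [build_templates()] encoding model.
#' @param spikes spike table restricted to model units' region (unit_id,
#'   time_s).
#' @param start_s,end_s event interval.
#' @param tau window length, s (default 0.02).
#' @param step window step, s (default 0.01).
#' @return list of class `event_decode`: `pmat` (2D x T joint posterior),
#'   `centers_s`, `k` (0-based original window indices of retained
#'   columns), `tau`, `step`, `model`; or `NULL` if undecodable.
#' @export
decode_event <- function(model, spikes, start_s, end_s,
                         tau = 0.02, step = 0.01) {
  starts <- seq(start_s, end_s - tau, by = step)
  if (length(starts) < 3) return(NULL)
  spk <- lapply(model$unit_ids, function(u)
    spikes$time_s[spikes$unit_id == u])
  cm <- count_in_windows(spk, starts, tau)
  keep <- colSums(cm) > 0
  if (sum(keep) < 3) return(NULL)
  pm <- posterior_matrix(model, cm[, keep, drop = FALSE], tau)
  structure(list(pmat = pm, centers_s = starts[keep] + tau / 2,
                 k = which(keep) - 1L, tau = tau, step = step,
                 n_bins = model$n_bins, bin_left_cm = model$bin_left_cm,
                 trajectories = model$trajectories),
            class = "event_decode")
}

#' Weighted correlation of a posterior probability matrix
#'
#' Posterior-mass-weighted Pearson correlation between spatial bin
#' positions and temporal bin times:
#' `r = covar(x, t) / sqrt(covar(x, x) * covar(t, t))` with all moments
#' weighted by the posterior mass.
#'
#' @param pmat D x T nonnegative matrix (rows = space, columns = time).
#' @param x spatial bin values (default bin index).
#' @param t temporal bin values (default bin index).
#' @return weighted correlation in \[-1, 1\], or NA when the total mass or
#'   a variance is zero.
#' @export
weighted_correlation <- function(pmat, x = seq_len(nrow(pmat)),
                                 t = seq_len(ncol(pmat))) {
  W <- sum(pmat)
  if (W <= 0) return(NA_real_)
  wx <- rowSums(pmat); wt <- colSums(pmat)
  Ex <- sum(wx * x) / W
  Et <- sum(wt * t) / W
  cxt <- as.numeric(t(x - Ex) %*% pmat %*% (t - Et)) / W
  cxx <- sum(wx * (x - Ex)^2) / W
  ctt <- sum(wt * (t - Et)^2) / W
  if (cxx <= 0 || ctt <= 0) return(NA_real_)
  cxt / sqrt(cxx * ctt)
}

#' Best-fit constant-velocity line through a posterior matrix
#'
#' Dense grid search over slope v (both signs, |v| from `v_abs_range[1]`
#' to `v_abs_range[2]` m/s in `v_step` steps) and intercept rho (every
#' spatial bin center). The score of a line is the average, over temporal
#' bins, of the posterior mass within `d_cm` of the line:
#' `R(v, rho) = (1/n) sum_k P(|pos - (rho + v * k * dt)| <= d)`.
#' Ties are broken toward the smallest |v|, then the smallest rho.
#'
#' @param pmat D x T posterior block for one trajectory.
#' @param bin_cm spatial bin width (default 2).
#' @param dt_s temporal bin step, s (default 0.01).
#' @param k 0-based temporal bin indices of the columns (default 0:(T-1));
#'   supply original indices when zero-spike windows were dropped.
#' @param d_cm vicinity half-width (default 8).
#' @param v_abs_range search range of |v| in m/s (default c(1, 15)).
#' @param v_step grid step in m/s (default 0.25).
#' @return list: `v_mps`, `rho_cm` (bin center), `r_max`.
#' @export
best_fit_line <- function(pmat, bin_cm = 2, dt_s = 0.01,
                          k = seq_len(ncol(pmat)) - 1L, d_cm = 8,
                          v_abs_range = c(1, 15), v_step = 0.25) {
  idx <- bfl_indices(nrow(pmat), k, bin_cm, dt_s, d_cm, v_abs_range, v_step)
  bfl_eval(pmat, idx)
}

## Precompute gather indices for the best-fit-line grid search; the
## geometry (D, temporal bins, grid) is shared across the shuffles of an
## event, so the per-shuffle cost reduces to prefix sums plus two gathers.
bfl_indices <- function(D, k, bin_cm, dt_s, d_cm, v_abs_range, v_step) {
  v_abs <- seq(v_abs_range[1], v_abs_range[2], by = v_step)
  vs <- as.vector(rbind(v_abs, -v_abs))  # |v| ascending, + before -
  Tn <- length(k)
  nv <- length(vs)
  rho_idx <- seq_len(D)
  li_hi <- matrix(0L, nv * D, Tn)
  li_lo <- matrix(0L, nv * D, Tn)
  for (j in seq_len(Tn)) {
    disp <- vs * 100 * k[j] * dt_s  # cm along the line at temporal bin k_j
    dhi <- floor((disp + d_cm) / bin_cm)
    dlo <- ceiling((disp - d_cm) / bin_cm)
    hi <- pmin(pmax(outer(dhi, rho_idx, "+"), 0L), D)      # nv x D
    lo <- pmin(pmax(outer(dlo - 1L, rho_idx, "+"), 0L), D)
    base <- (j - 1L) * (D + 1L) + 1L
    li_hi[, j] <- as.integer(hi) + base
    li_lo[, j] <- as.integer(lo) + base
  }
  list(li_hi = li_hi, li_lo = li_lo, vs = vs, D = D, Tn = Tn,
       bin_cm = bin_cm)
}

bfl_eval <- function(pmat, idx) {
  cps <- rbind(0, apply(pmat, 2, cumsum))  # (D+1) x T prefix sums
  cf <- as.vector(cps)
  r <- (rowSums(matrix(cf[idx$li_hi] - cf[idx$li_lo],
                       ncol = idx$Tn))) / idx$Tn
  # r is laid out (v, rho) with v fastest in |v|-ascending order; scanning
  # the transpose first-max implements the v-then-rho tie-break
  m <- matrix(r, nrow = length(idx$vs))
  i <- which.max(t(m))
  vi <- (i - 1L) %/% idx$D + 1L
  ri <- (i - 1L) %% idx$D + 1L
  list(r_max = m[vi, ri], v_mps = idx$vs[vi],
       rho_cm = (ri - 0.5) * idx$bin_cm)
}

## Split a joint (2D x T) posterior into per-trajectory blocks.
split_pmat <- function(pmat, n_bins) {
  list(L = pmat[seq_len(n_bins), , drop = FALSE],
       R = pmat[n_bins + seq_len(n_bins), , drop = FALSE])
}

#' Shuffle significance of theta-sequence scores for one trajectory block
#'
#' The space bins of each time column are circularly shifted by an
#' independent uniform offset (`mode = "space-circular"`, the default),
#' and the weighted correlation and best-fit goodness-of-fit are
#' recomputed per shuffle. A sequence is significant when its score is
#' outside the \[2.5, 97.5\] percentile band of the shuffled scores AND
#' its R_max exceeds the shuffles' 95th percentile.
#'
#' @param pmat D x T posterior block for one trajectory.
#' @param bin_cm,dt_s,k,d_cm,v_abs_range,v_step see [best_fit_line()].
#' @param n_shuffles number of shuffles (default 1000; < 100 warns).
#' @param seed RNG seed for the shuffle offsets.
#' @return list: r, r_lo, r_hi (2.5/97.5 shuffle percentiles), r_max,
#'   r_max_95, v_mps, rho_cm, p_r (two-sided), p_rmax, significant.
#' @export
shuffle_significance <- function(pmat, bin_cm = 2, dt_s = 0.01,
                                 k = seq_len(ncol(pmat)) - 1L, d_cm = 8,
                                 v_abs_range = c(1, 15), v_step = 0.25,
                                 n_shuffles = 1000, seed = 1L) {
  if (n_shuffles < 100) warning("fewer than 100 shuffles: low resolution")
  D <- nrow(pmat)
  x_cm <- (seq_len(D) - 0.5) * bin_cm
  idx <- bfl_indices(D, k, bin_cm, dt_s, d_cm, v_abs_range, v_step)
  r_obs <- weighted_correlation(pmat, x = x_cm, t = k * dt_s)
  bf <- bfl_eval(pmat, idx)
  set.seed(seed)
  r_sh <- rmax_sh <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    off <- sample.int(D, ncol(pmat), replace = TRUE) - 1L
    pm <- pmat
    for (j in seq_len(ncol(pmat))) {
      if (off[j] > 0) {
        pm[, j] <- pmat[c((D - off[j] + 1L):D, 1L:(D - off[j])), j]
      }
    }
    r_sh[s] <- weighted_correlation(pm, x = x_cm, t = k * dt_s)
    rmax_sh[s] <- bfl_eval(pm, idx)$r_max
  }
  r_sh <- r_sh[!is.na(r_sh)]
  qs <- stats::quantile(r_sh, c(0.025, 0.975), names = FALSE)
  rmax95 <- stats::quantile(rmax_sh, 0.95, names = FALSE)
  p_r <- 2 * min(mean(r_sh >= r_obs), mean(r_sh <= r_obs))
  list(r = r_obs, r_lo = qs[1], r_hi = qs[2],
       r_max = bf$r_max, r_max_95 = rmax95,
       v_mps = bf$v_mps, rho_cm = bf$rho_cm,
       p_r = p_r, p_rmax = mean(rmax_sh >= bf$r_max),
       significant = !is.na(r_obs) &&
         (r_obs < qs[1] || r_obs > qs[2]) && bf$r_max > rmax95)
}

#' Score and classify one candidate theta-sequence event
#'
#' Both trajectory blocks of the joint posterior are scored with
#' [shuffle_significance()]; the decoded trajectory is the significant
#' one (highest |r| when both pass). Direction is forward when the
#' weighted correlation is positive with the position axis oriented along
#' the running direction (outbound: increasing arclength; inbound:
#' decreasing). `represents` compares the decoded trajectory with the
#' trial's actual choice.
#'
#' @param ev an [decode_event()] result.
#' @param candidate one row of [find_candidates()].
#' @param actual_choice the trial's choice ("L"/"R").
#' @param n_shuffles,seed passed to [shuffle_significance()].
#' @param bin_cm spatial bin width (default 2).
#' @return one-row data.frame: r/R_max and shuffle stats per trajectory,
#'   significant flag, decoded trajectory, direction, slope_mps,
#'   start_rel_cm, end_rel_cm, represents.
#' @export
classify_sequence <- function(ev, candidate, actual_choice,
                              n_shuffles = 1000, seed = 1L, bin_cm = 2) {
  blocks <- split_pmat(ev$pmat, ev$n_bins)
  sc <- lapply(c(L = "L", R = "R"), function(side) {
    shuffle_significance(blocks[[side]], bin_cm = bin_cm, dt_s = ev$step,
                         k = ev$k, n_shuffles = n_shuffles,
                         seed = seed + (side == "R"))
  })
  sig <- vapply(sc, function(s) isTRUE(s$significant), logical(1))
  orient <- if (candidate$travel == "outbound") 1 else -1
  decoded <- NA_character_; direction <- NA_character_
  slope <- NA_real_; s_rel <- e_rel <- NA_real_; represents <- NA_character_
  if (any(sig)) {
    cand_sides <- names(sig)[sig]
    decoded <- cand_sides[which.max(vapply(cand_sides, function(s)
      abs(sc[[s]]$r), numeric(1)))]
    scd <- sc[[decoded]]
    direction <- if (orient * scd$r > 0) "forward" else "reverse"
    slope <- orient * scd$v_mps
    kk <- range(ev$k)
    line_pos <- scd$rho_cm + scd$v_mps * 100 * kk * ev$step
    s_rel <- orient * (line_pos[1] - candidate$pos_cm)
    e_rel <- orient * (line_pos[2] - candidate$pos_cm)
    represents <- if (decoded == actual_choice) "actual" else "alternative"
  }
  data.frame(
    cycle_id = candidate$cycle_id, trial_id = candidate$trial_id,
    r_L = sc$L$r, r_R = sc$R$r, rmax_L = sc$L$r_max, rmax_R = sc$R$r_max,
    p_r_L = sc$L$p_r, p_r_R = sc$R$p_r,
    significant = any(sig), decoded = decoded, direction = direction,
    slope_mps = slope, start_rel_cm = s_rel, end_rel_cm = e_rel,
    represents = represents, stringsAsFactors = FALSE)
}

#' Distance index of forward theta sequences
#'
#' Decoded probability within +/- 60 cm of the animal's position and
#' +/- half a cycle around the zero phase is folded into four quadrants:
#' II = (1st half, behind), III = (1st half, ahead), I = (2nd half,
#' behind), IV = (2nd half, ahead). The first-half index is
#' (III - II)/(III + II), the second-half index (IV - I)/(IV + I).
#'
#' @param events list of lists, each with `ev` (an [decode_event()]),
#'   `candidate` (row of [find_candidates()]), `decoded` ("L"/"R") and
#'   `phases` (theta phase at each retained window center, radians with 0
#'   at mid-cycle).
#' @param bin_cm spatial bin width (default 2).
#' @param window_cm spatial window half-width (default 60).
#' @param n_boot bootstrap resamples for the CI (default 500).
#' @param seed RNG seed for the bootstrap.
#' @return list: index_first, index_second, ci_first, ci_second,
#'   quadrants (named I-IV), n_events.
#' @export
distance_index <- function(events, bin_cm = 2, window_cm = 60,
                           n_boot = 500, seed = 1L) {
  per_event <- lapply(events, function(e) {
    blocks <- split_pmat(e$ev$pmat, e$ev$n_bins)
    pm <- blocks[[e$decoded]]
    orient <- if (e$candidate$travel == "outbound") 1 else -1
    centers <- (seq_len(nrow(pm)) - 0.5) * bin_cm
    rel <- orient * (centers - e$candidate$pos_cm)
    q <- c(I = 0, II = 0, III = 0, IV = 0)
    for (j in seq_len(ncol(pm))) {
      half <- if (e$phases[j] < 0) "first" else "second"
      sel_b <- rel >= -window_cm & rel < 0
      sel_a <- rel > 0 & rel <= window_cm
      if (half == "first") {
        q["II"] <- q["II"] + sum(pm[sel_b, j])
        q["III"] <- q["III"] + sum(pm[sel_a, j])
      } else {
        q["I"] <- q["I"] + sum(pm[sel_b, j])
        q["IV"] <- q["IV"] + sum(pm[sel_a, j])
      }
    }
    q
  })
  qm <- do.call(rbind, per_event)
  idx <- function(q) {
    c(first = unname((q["III"] - q["II"]) / (q["III"] + q["II"])),
      second = unname((q["IV"] - q["I"]) / (q["IV"] + q["I"])))
  }
  obs <- idx(colMeans(qm))
  set.seed(seed)
  bs <- replicate(n_boot, idx(colMeans(qm[sample.int(nrow(qm),
                                                     replace = TRUE), ,
                                          drop = FALSE])))
  list(index_first = obs["first"], index_second = obs["second"],
       ci_first = stats::quantile(bs[1, ], c(0.025, 0.975), names = FALSE,
                                  na.rm = TRUE),
       ci_second = stats::quantile(bs[2, ], c(0.025, 0.975), names = FALSE,
                                   na.rm = TRUE),
       quadrants = colMeans(qm), n_events = nrow(qm))
}

#' Percent of theta sequences representing the actual vs alternative choice
#'
#' @param results rbind of [classify_sequence()] rows (significant events
#'   carry `represents`).
#' @param segments optional character vector parallel to `results` with
#'   "before_cp"/"after_cp" labels; `NULL` pools everything.
#' @return list: `session` (per-segment % actual / % alternative and n),
#'   `per_trial` (trial_id, segment, n_actual, n_alternative).
#' @export
choice_representation <- function(results, segments = NULL) {
  sig <- results[results$significant & !is.na(results$represents), ,
                 drop = FALSE]
  seg <- if (is.null(segments)) rep("all", nrow(results)) else segments
  seg <- seg[results$significant & !is.na(results$represents)]
  if (!nrow(sig)) return(list(session = data.frame(), per_trial = data.frame()))
  session <- do.call(rbind, lapply(unique(seg), function(s) {
    r <- sig[seg == s, ]
    data.frame(segment = s, n = nrow(r),
               pct_actual = 100 * mean(r$represents == "actual"),
               pct_alternative = 100 * mean(r$represents == "alternative"),
               stringsAsFactors = FALSE)
  }))
  key <- interaction(sig$trial_id, seg, drop = TRUE)
  per_trial <- do.call(rbind, lapply(levels(key), function(kk) {
    r <- sig[key == kk, ]
    data.frame(trial_id = r$trial_id[1], segment = seg[key == kk][1],
               n_actual = sum(r$represents == "actual"),
               n_alternative = sum(r$represents == "alternative"),
               stringsAsFactors = FALSE)
  }))
  list(session = session, per_trial = per_trial)
}

#' Conditional representation of coherent CA1-PFC theta sequences
#'
#' Events are matched by shared theta cycle; reports
#' P(PFC = actual | CA1 = actual) and
#' P(PFC = alternative | CA1 = alternative) along with the marginal
#' P(PFC = actual) expected under independence.
#'
#' @param ca1,pfc [classify_sequence()] result tables with cycle_id and
#'   `represents`.
#' @param min_pairs minimum matched events (default 5); fewer returns a
#'   table with NA conditionals.
#' @return list: n_pairs, p_pfc_actual_given_ca1_actual,
#'   p_pfc_alt_given_ca1_alt, p_pfc_actual (marginal).
#' @export
coherent_pairs <- function(ca1, pfc, min_pairs = 5) {
  a <- ca1[ca1$significant & !is.na(ca1$represents), ]
  b <- pfc[pfc$significant & !is.na(pfc$represents), ]
  m <- merge(a[, c("cycle_id", "represents")],
             b[, c("cycle_id", "represents")],
             by = "cycle_id", suffixes = c("_ca1", "_pfc"))
  n <- nrow(m)
  marg <- if (nrow(b)) mean(b$represents == "actual") else NA_real_
  if (n < min_pairs) {
    return(list(n_pairs = n, p_pfc_actual_given_ca1_actual = NA_real_,
                p_pfc_alt_given_ca1_alt = NA_real_, p_pfc_actual = marg))
  }
  aa <- m$represents_ca1 == "actual"
  list(
    n_pairs = n,
    p_pfc_actual_given_ca1_actual =
      if (any(aa)) mean(m$represents_pfc[aa] == "actual") else NA_real_,
    p_pfc_alt_given_ca1_alt =
      if (any(!aa)) mean(m$represents_pfc[!aa] == "alternative") else NA_real_,
    p_pfc_actual = marg)
}
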