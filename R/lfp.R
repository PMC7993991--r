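## LFP analyses: theta phase, population-defined theta-cycle
## segmentation, SWR detection from the ripple-band envelope, single-unit
## phase locking, and band power / coherence summaries.

#' Instantaneous theta phase of a reference LFP channel
#'
#' Zero-phase 6-12 Hz band-pass followed by the analytic-signal angle.
#'
#' @param lfp list with `fs`, `time_s`, `signal` (a reference channel).
#' @param band pass band in Hz (default c(6, 12)).
#' @return list of class `theta_phase`: time_s, phase (radians, (-pi, pi]),
#'   amplitude (band envelope), fs.
#' @export
theta_phase <- function(lfp, band = c(6, 12)) {
  if (lfp$fs < 8 * band[2]) stop("sampling rate too low for the theta band")
  filt <- bandpass_fft(lfp$signal, lfp$fs, band[1], band[2], trans = 1)
  z <- analytic_signal(filt)
  structure(list(time_s = lfp$time_s, phase = Arg(z), amplitude = Mod(z),
                 fs = lfp$fs), class = "theta_phase")
}

## Phase of each spike by interpolation on the unwrapped phase series.
spike_phases <- function(spike_times, phase) {
  idx <- pmin(pmax(findInterval(spike_times, phase$time_s), 1L),
              length(phase$time_s))
  phase$phase[idx]
}

#' Spike-phase locking of one unit
#'
#' Circular mean, resultant length and Rayleigh p of spike theta phases
#' within a mask. Fewer than `min_spikes` spikes returns `NULL`.
#'
#' @param spike_times spike times, s.
#' @param phase a [theta_phase()] series.
#' @param mask_intervals data.frame (start_s, end_s); only spikes inside
#'   are used (e.g. locomotor periods). `NULL` uses all spikes.
#' @param min_spikes minimum spike count (default 30).
#' @return list: mean_phase, resultant, p, n; or `NULL`.
#' @export
phase_locking <- function(spike_times, phase, mask_intervals = NULL,
                          min_spikes = 30) {
  if (!is.null(mask_intervals)) {
    spike_times <- spike_times[in_intervals(spike_times, mask_intervals)]
  }
  if (length(spike_times) < min_spikes) return(NULL)
  ph <- spike_phases(spike_times, phase)
  rt <- rayleigh_test(ph)
  list(mean_phase = rt$mean, resultant = rt$rbar, p = rt$p, n = rt$n)
}

#' Segment theta cycles at the population minimum-firing phase
#'
#' A spike-phase histogram is averaged over all Rayleigh-significant
#' (p < 0.05) CA1 units during locomotion; the histogram minimum defines
#' the session's cycle-boundary phase, and cycles are cut at successive
#' upward crossings of that phase. Cycles outside \[min_dur, max_dur\] or
#' outside locomotion are dropped. With no phase-locked unit the boundary
#' falls back to the filtered-trace trough (phase pi), with a warning.
#'
#' @param phase a [theta_phase()] series.
#' @param spikes spike table (unit_id, region, time_s); CA1 rows are used.
#' @param loco_intervals locomotor intervals (start_s, end_s).
#' @param n_bins phase histogram bins (default 36).
#' @param min_dur,max_dur retained cycle duration bounds, s (0.05, 0.3).
#' @return list of class `theta_cycles`: `cycles` (start_s, end_s,
#'   duration_s), `boundary_phase`.
#' @export
segment_theta_cycles <- function(phase, spikes, loco_intervals,
                                 n_bins = 36, min_dur = 0.05, max_dur = 0.3) {
  ca1 <- spikes[spikes$region == "CA1", ]
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  hist_sum <- rep(0, n_bins); n_used <- 0L
  for (uid in unique(ca1$unit_id)) {
    st <- ca1$time_s[ca1$unit_id == uid]
    pl <- phase_locking(st, phase, loco_intervals)
    if (is.null(pl) || pl$p >= 0.05) next
    ph <- spike_phases(st[in_intervals(st, loco_intervals)], phase)
    h <- tabulate(pmin(findInterval(ph, edges, rightmost.closed = TRUE),
                       n_bins), nbins = n_bins)
    hist_sum <- hist_sum + h / sum(h)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    warning("no phase-locked CA1 units; using trough (phase pi) boundaries")
    boundary <- pi
  } else {
    sm <- gauss_smooth(rep(hist_sum, 3), 1)[(n_bins + 1):(2 * n_bins)]
    boundary <- (edges[which.min(sm)] + edges[which.min(sm) + 1]) / 2
  }
  # upward crossings of the boundary phase on the wrapped series
  rel <- wrap_pi(phase$phase - boundary)
  cross <- which(diff(sign(rel)) > 0 & abs(diff(rel)) < pi) + 1L
  ct <- phase$time_s[cross]
  if (length(ct) < 2) {
    return(structure(list(cycles = data.frame(start_s = numeric(0),
                                              end_s = numeric(0),
                                              duration_s = numeric(0)),
                          boundary_phase = boundary),
                     class = "theta_cycles"))
  }
  cyc <- data.frame(start_s = ct[-length(ct)], end_s = ct[-1])
  cyc$duration_s <- cyc$end_s - cyc$start_s
  cyc <- cyc[cyc$duration_s >= min_dur & cyc$duration_s <= max_dur, ]
  keep <- in_intervals(cyc$start_s, loco_intervals) &
    in_intervals(cyc$end_s - 1e-9, loco_intervals)
  cyc <- cyc[keep, ]
  rownames(cyc) <- NULL
  structure(list(cycles = cyc, boundary_phase = boundary),
            class = "theta_cycles")
}

#' Detect sharp-wave ripples from the ripple-band envelope
#'
#' Per-channel 150-250 Hz band-pass, Hilbert envelope smoothed with a 4 ms
#' Gaussian; events are contiguous periods with envelope > `threshold_sd`
#' SD above the mean (mean/SD estimated over immobility) on at least one
#' channel, wholly during immobility, extended to where the envelope
#' crosses the mean.
#'
#' @param lfp list with `fs`, `time_s`, `signal` (single channel) or
#'   `signals` (list of channels).
#' @param immobile_intervals immobility intervals (start_s, end_s).
#' @param threshold_sd detection threshold (default 3).
#' @param band ripple band, Hz.
#' @param smooth_s envelope smoothing SD, s (default 0.004).
#' @param min_core_s minimum duration the envelope must stay above
#'   threshold (default 0.015 s); chance crossings of Gaussian envelope
#'   noise are shorter than real ripples (>= 15 ms).
#' @param min_immobility_s minimum total immobility needed to estimate the
#'   envelope mean/SD (default 10).
#' @return data.frame of class in column form: start_s, end_s, duration_s,
#'   peak_z; with attribute `eligible` marking duration >= 50 ms.
#' @export
detect_swrs <- function(lfp, immobile_intervals, threshold_sd = 3,
                        band = c(150, 250), smooth_s = 0.004,
                        min_core_s = 0.015, min_immobility_s = 10) {
  chans <- if (!is.null(lfp$signals)) lfp$signals else list(lfp$signal)
  imm <- in_intervals(lfp$time_s, immobile_intervals)
  if (sum(imm) / lfp$fs < min_immobility_s) {
    stop("less than ", min_immobility_s, " s immobility: cannot estimate ",
         "ripple envelope statistics")
  }
  above <- rep(FALSE, length(lfp$time_s))
  zmax <- rep(-Inf, length(lfp$time_s))
  abovemean <- rep(FALSE, length(lfp$time_s))
  for (ch in chans) {
    env <- Mod(analytic_signal(bandpass_fft(ch, lfp$fs, band[1], band[2],
                                            trans = 10)))
    env <- gauss_smooth(env, smooth_s * lfp$fs)
    mu <- mean(env[imm]); sdv <- stats::sd(env[imm])
    z <- (env - mu) / sdv
    above <- above | (z > threshold_sd)
    abovemean <- abovemean | (z > 0)
    zmax <- pmax(zmax, z)
  }
  core <- mask_to_intervals(lfp$time_s, above & imm)
  core <- core[core$end_s - core$start_s >= min_core_s, , drop = FALSE]
  if (nrow(core) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), peak_z = numeric(0)))
  }
  # extend each core event to the surrounding above-mean period
  ext <- mask_to_intervals(lfp$time_s, abovemean)
  res <- lapply(seq_len(nrow(core)), function(i) {
    j <- which(ext$start_s <= core$start_s[i] & ext$end_s >= core$end_s[i])
    if (length(j)) c(ext$start_s[j[1]], ext$end_s[j[1]])
    else c(core$start_s[i], core$end_s[i])
  })
  res <- unique(do.call(rbind, res))
  out <- data.frame(start_s = res[, 1], end_s = res[, 2])
  out$duration_s <- out$end_s - out$start_s
  out$peak_z <- vapply(seq_len(nrow(out)), function(i) {
    w <- lfp$time_s >= out$start_s[i] & lfp$time_s < out$end_s[i]
    max(zmax[w])
  }, numeric(1))
  out <- out[order(out$start_s), ]
  rownames(out) <- NULL
  out
}

#' Theta-band power and coherence of an LFP channel pair
#'
#' Welch spectra over masked segments; power is z-scored per frequency
#' across segments of the session, coherence is magnitude-squared. Band
#' means over 6-12 Hz are reported. Segments shorter than `min_seg_s` are
#' skipped.
#'
#' @param x,y two LFP channels (equal length numeric vectors).
#' @param fs sampling rate, Hz.
#' @param mask_intervals analysis intervals (start_s, end_s) on the
#'   channel time base starting at `t0`.
#' @param t0 time of the first sample, s.
#' @param band band of interest (default c(6, 12)).
#' @param min_seg_s minimum segment length, s (default 2).
#' @return list: freq, zpower_x, zpower_y (z-scored log-power profiles),
#'   coherence (per frequency), band_power_x, band_power_y,
#'   band_coherence.
#' @export
band_power_coherence <- function(x, y, fs, mask_intervals, t0 = 0,
                                 band = c(6, 12), min_seg_s = 2) {
  segs <- mask_intervals[mask_intervals$end_s - mask_intervals$start_s >=
                           min_seg_s, , drop = FALSE]
  if (nrow(segs) == 0) stop("no analysis segment of at least ", min_seg_s, " s")
  px <- py <- cxy <- NULL
  pxs <- pys <- list()
  sxx <- syy <- sxy <- NULL
  for (i in seq_len(nrow(segs))) {
    i0 <- max(1L, floor((segs$start_s[i] - t0) * fs) + 1L)
    i1 <- min(length(x), ceiling((segs$end_s[i] - t0) * fs))
    sp <- welch_spectra(x[i0:i1], y[i0:i1], fs, seg_s = 1)
    pxs[[i]] <- sp$pxx; pys[[i]] <- sp$pyy
    if (is.null(sxx)) { sxx <- sp$pxx; syy <- sp$pyy; sxy <- sp$pxy }
    else { sxx <- sxx + sp$pxx; syy <- syy + sp$pyy; sxy <- sxy + sp$pxy }
    freq <- sp$freq
  }
  zscore_rows <- function(lst) {
    m <- do.call(rbind, lapply(lst, log))
    mu <- colMeans(m); sdv <- apply(m, 2, stats::sd)
    sdv[sdv == 0] <- 1
    colMeans(sweep(sweep(m, 2, mu), 2, sdv, "/"))
  }
  # with a single segment the z-scored profile is flat zero by construction
  zx <- if (length(pxs) > 1) zscore_rows(pxs) else rep(0, length(freq))
  zy <- if (length(pys) > 1) zscore_rows(pys) else rep(0, length(freq))
  coh <- Mod(sxy)^2 / (sxx * syy)
  inb <- freq >= band[1] & freq <= band[2]
  list(freq = freq, zpower_x = zx, zpower_y = zy, coherence = coh,
       band_power_x = mean(zx[inb]), band_power_y = mean(zy[inb]),
       band_coherence = mean(coh[inb]))
}
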