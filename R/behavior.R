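## Behavioral preprocessing: speed estimation, linearization onto the
## idealized trajectory paths, well-event refinement from beam triggers,
## and locomotor/immobility masks.

#' Running speed from a position trace
#'
#' Position is smoothed with a Gaussian kernel (default SD 83 ms, i.e. a
#' quarter-second support) to suppress 30 Hz tracking jitter, then speed is
#' the centered finite difference of the smoothed trace.
#'
#' @param position data.frame with time_s, x_cm, y_cm.
#' @param smooth_sd_s Gaussian SD in seconds.
#' @return numeric speed in cm/s, same length as the trace.
#' @export
compute_speed <- function(position, smooth_sd_s = 0.25 / 3) {
  dt <- stats::median(diff(position$time_s))
  sdn <- smooth_sd_s / dt
  xs <- gauss_smooth(position$x_cm, sdn)
  ys <- gauss_smooth(position$y_cm, sdn)
  n <- length(xs)
  vx <- (xs[c(2:n, n)] - xs[c(1, 1:(n - 1))]) /
    (position$time_s[c(2:n, n)] - position$time_s[c(1, 1:(n - 1))])
  vy <- (ys[c(2:n, n)] - ys[c(1, 1:(n - 1))]) /
    (position$time_s[c(2:n, n)] - position$time_s[c(1, 1:(n - 1))])
  sqrt(vx^2 + vy^2)
}

#' Linearize a position trace onto the maze's idealized paths
#'
#' Each sample inside a trial's run interval is projected onto the
#' idealized polyline of that trial's trajectory type; linear position is
#' arclength along the path (0 at the center well). Samples farther than
#' `max_dist_cm` from the path, or outside any run, get trajectory "none"
#' and NA linear position.
#'
#' @param position data.frame (time_s, x_cm, y_cm).
#' @param maze a [w_maze()] geometry.
#' @param trials trial table with trajectory, run_start_s, run_end_s.
#' @param speed optional precomputed speed (else [compute_speed()]).
#' @param max_dist_cm samples farther than this from every path are
#'   labeled "none" (default 20).
#' @return `linearized_session` data.frame: time_s, x_cm, y_cm, speed_cm_s,
#'   linear_cm, trajectory, trial_id.
#' @export
linearize <- function(position, maze, trials, speed = NULL,
                      max_dist_cm = 20) {
  if (is.null(speed)) speed <- compute_speed(position)
  n <- nrow(position)
  out <- data.frame(time_s = position$time_s, x_cm = position$x_cm,
                    y_cm = position$y_cm, speed_cm_s = speed,
                    linear_cm = NA_real_, trajectory = "none",
                    trial_id = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(trials))) {
    sel <- position$time_s >= trials$run_start_s[i] &
      position$time_s <= trials$run_end_s[i]
    if (!any(sel)) next
    pr <- project_to_path(cbind(position$x_cm[sel], position$y_cm[sel]),
                          maze$paths[[trials$trajectory[i]]])
    lin <- pr$arclength
    lin[pr$dist > max_dist_cm] <- NA_real_
    out$linear_cm[sel] <- lin
    out$trajectory[sel] <- ifelse(is.na(lin), "none", trials$trajectory[i])
    out$trial_id[sel] <- trials$trial_id[i]
  }
  class(out) <- c("linearized_session", "data.frame")
  out
}

#' Refine well entry/exit times from beam triggers
#'
#' Entry is the first time speed falls to <= 4 cm/s before the arrival
#' trigger; exit is the first time speed rises above 4 cm/s after the
#' departure trigger. Triggers with no qualifying sample within
#' `search_s` are dropped with a warning.
#'
#' @param linearized a [linearize()] table (needs time_s, speed_cm_s).
#' @param trials trial table with arrival_trigger_s and dwell_end_s (used
#'   as the departure reference for the destination-well dwell).
#' @param search_s search window around each trigger, seconds.
#' @return trials with well_entry_s and well_exit_s columns added.
#' @export
detect_well_events <- function(linearized, trials, search_s = 5) {
  tt <- linearized$time_s
  sp <- linearized$speed_cm_s
  entry <- exit <- rep(NA_real_, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    trig <- trials$arrival_trigger_s[i]
    win <- which(tt >= trig - search_s & tt <= trig + search_s & sp <= 4)
    if (length(win)) {
      below <- win[tt[win] <= trig]
      # first time point of the contiguous slow period containing the trigger
      cand <- if (length(below)) below else win
      runs <- cumsum(c(1L, diff(cand) > 1L))
      entry[i] <- tt[cand[runs == runs[length(runs)]][1]]
      if (!length(below)) entry[i] <- tt[win[1]]
    } else {
      warning("no sub-4 cm/s sample near arrival trigger of trial ",
              trials$trial_id[i], "; event dropped")
      next
    }
    dep <- trials$dwell_end_s[i]
    aft <- which(tt >= dep - 0.5 & sp > 4)
    exit[i] <- if (length(aft)) tt[aft[1]] else tt[length(tt)]
  }
  trials$well_entry_s <- entry
  trials$well_exit_s <- exit
  trials
}

#' Locomotor and immobility masks from speed
#'
#' Locomotion is speed > 5 cm/s, immobility speed <= 4 cm/s; the 4-5 cm/s
#' hysteresis band belongs to neither.
#'
#' @param speed numeric speed, cm/s.
#' @return list of logical vectors `locomotion` and `immobility`.
#' @export
locomotor_mask <- function(speed) {
  list(locomotion = speed > 5, immobility = speed <= 4)
}

#' Before/after choice-point segmentation of a trial
#'
#' The before-CP segment is the center stem (linear position < CP
#' arclength); the after-CP segment starts 10 cm beyond the choice point
#' (linear position >= CP + 10); the 0-10 cm gap belongs to neither.
#'
#' @param linear_cm linear positions of a trial's samples.
#' @param maze a [w_maze()] geometry.
#' @return character vector: "before_cp", "after_cp" or "gap"/NA.
#' @export
cp_segment <- function(linear_cm, maze) {
  out <- rep(NA_character_, length(linear_cm))
  ok <- !is.na(linear_cm)
  out[ok & linear_cm < maze$cp_cm] <- "before_cp"
  out[ok & linear_cm >= maze$cp_cm + 10] <- "after_cp"
  out[ok & is.na(out)] <- "gap"
  out
}
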