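## Linearized firing-rate maps, place-cell criterion, trajectory
## selectivity, spatial field detection, and field asymmetry.

#' Linearized firing-rate map for one unit on one trajectory type
#'
#' Spike counts and occupancy in 2-cm bins over locomotor samples
#' (speed > 5 cm/s, SWR times excluded), each smoothed with a 4-cm-SD
#' Gaussian before dividing. Bins with raw occupancy <= 20 ms carry no
#' rate estimate.
#'
#' @param spike_times spike times (s) of one unit.
#' @param linearized a [linearize()] table.
#' @param trajectory one of the four trajectory types.
#' @param maze a [w_maze()] geometry.
#' @param bin_cm spatial bin width (default 2).
#' @param smooth_sd_cm Gaussian SD (default 4).
#' @param swr_intervals optional data.frame (start_s, end_s) excluded from
#'   both occupancy and spikes.
#' @param min_occupancy_s minimum raw occupancy per retained bin (0.02).
#' @return list of class `rate_map`: bin_left_cm, rate_hz, occupancy_s,
#'   peak_hz, n_spikes (spikes retained in the map), trajectory.
#' @export
compute_rate_map <- function(spike_times, linearized, trajectory, maze,
                             bin_cm = 2, smooth_sd_cm = 4,
                             swr_intervals = NULL, min_occupancy_s = 0.02) {
  edges <- seq(0, maze$path_length_cm, by = bin_cm)
  nb <- length(edges) - 1L
  dt <- stats::median(diff(linearized$time_s))
  sel <- linearized$trajectory == trajectory &
    linearized$speed_cm_s > 5 & !is.na(linearized$linear_cm)
  if (!is.null(swr_intervals) && nrow(swr_intervals)) {
    sel <- sel & !in_intervals(linearized$time_s, swr_intervals)
  }
  if (!any(sel)) {
    return(structure(list(bin_left_cm = edges[-length(edges)],
                          rate_hz = rep(NA_real_, nb),
                          occupancy_s = rep(0, nb), peak_hz = NA_real_,
                          n_spikes = 0L, trajectory = trajectory),
                     class = "rate_map"))
  }
  # occupancy
  pos <- linearized$linear_cm[sel]
  occ <- tabulate(pmin(pmax(findInterval(pos, edges,
                                         rightmost.closed = TRUE), 1L), nb),
                  nbins = nb) * dt
  # assign each spike the linear position of the nearest retained sample
  tsel <- linearized$time_s[sel]
  if (length(spike_times)) {
    idx <- findInterval(spike_times, tsel)
    idx0 <- pmax(idx, 1L)
    idx1 <- pmin(idx + 1L, length(tsel))
    near <- ifelse(abs(spike_times - tsel[idx0]) <=
                     abs(tsel[idx1] - spike_times), idx0, idx1)
    keep <- abs(spike_times - tsel[near]) <= dt  # spike during a retained sample
    spos <- pos[near[keep]]
  } else spos <- numeric(0)
  cnt <- tabulate(pmin(pmax(findInterval(spos, edges,
                                         rightmost.closed = TRUE), 1L), nb),
                  nbins = nb)
  sdn <- smooth_sd_cm / bin_cm
  occ_s <- gauss_smooth(occ, sdn, normalize_edges = FALSE)
  cnt_s <- gauss_smooth(cnt, sdn, normalize_edges = FALSE)
  rate <- ifelse(occ > min_occupancy_s & occ_s > 0, cnt_s / occ_s, NA_real_)
  structure(list(bin_left_cm = edges[-length(edges)],
                 rate_hz = rate, occupancy_s = occ,
                 raw_count = cnt,
                 peak_hz = if (all(is.na(rate))) NA_real_ else max(rate, na.rm = TRUE),
                 n_spikes = length(spos), trajectory = trajectory),
            class = "rate_map")
}

#' Rate maps for all units on all four trajectory types
#'
#' Units with fewer than `min_spikes` spikes in the session are skipped.
#'
#' @param spikes spike table (unit_id, region, time_s).
#' @param linearized a [linearize()] table.
#' @param maze a [w_maze()] geometry.
#' @param swr_intervals optional intervals excluded from maps.
#' @param min_spikes session spike-count inclusion gate (default 100).
#' @param ... passed to [compute_rate_map()].
#' @return list of class `rate_map_set`: `maps[[unit]][[trajectory]]`,
#'   `units` (unit_id, region, peak_hz across maps, place_cell flag).
#' @export
compute_rate_maps <- function(spikes, linearized, maze, swr_intervals = NULL,
                              min_spikes = 100, ...) {
  ids <- sort(unique(spikes$unit_id))
  maps <- list(); rows <- list()
  for (uid in ids) {
    su <- spikes[spikes$unit_id == uid, ]
    if (nrow(su) < min_spikes) next
    m <- lapply(TRAJECTORIES, function(tr)
      compute_rate_map(su$time_s, linearized, tr, maze,
                       swr_intervals = swr_intervals, ...))
    names(m) <- TRAJECTORIES
    maps[[as.character(uid)]] <- m
    pk <- suppressWarnings(max(vapply(m, function(x)
      ifelse(is.na(x$peak_hz), -Inf, x$peak_hz), numeric(1))))
    rows[[as.character(uid)]] <- data.frame(
      unit_id = uid, region = su$region[1],
      peak_hz = ifelse(is.finite(pk), pk, NA_real_),
      place_cell = is.finite(pk) && pk >= 3, stringsAsFactors = FALSE)
  }
  structure(list(maps = maps, units = do.call(rbind, rows)),
            class = "rate_map_set")
}

#' Trajectory selectivity index
#'
#' `SI = (FR_L - FR_R) / (FR_L + FR_R)` where FR is the occupancy-weighted
#' mean of the linearized rate map on the L-/R-side trajectory of one
#' travel type. A cell is trajectory-selective when |SI| exceeds the
#' region threshold (0.4 in CA1, 0.2 in PFC). Requires a peak rate >= 3 Hz
#' on at least one of the two maps.
#'
#' @param map_L,map_R [compute_rate_map()] results for the L- and R-side
#'   trajectories of one travel type.
#' @param region "CA1" or "PFC".
#' @return list: FR_L, FR_R, SI, selective, preferred ("L"/"R"); or `NULL`
#'   when undefined (no 3 Hz peak, or FR_L + FR_R = 0).
#' @export
selectivity_index <- function(map_L, map_R, region = c("CA1", "PFC")) {
  region <- match.arg(region)
  pk <- suppressWarnings(max(c(map_L$peak_hz, map_R$peak_hz), na.rm = TRUE))
  if (!is.finite(pk) || pk < 3) return(NULL)
  wmean <- function(m) {
    ok <- !is.na(m$rate_hz) & m$occupancy_s > 0
    if (!any(ok)) return(0)
    sum(m$rate_hz[ok] * m$occupancy_s[ok]) / sum(m$occupancy_s[ok])
  }
  fl <- wmean(map_L); fr <- wmean(map_R)
  if (fl + fr == 0) return(NULL)
  si <- (fl - fr) / (fl + fr)
  thr <- if (region == "CA1") 0.4 else 0.2
  list(FR_L = fl, FR_R = fr, SI = si, selective = abs(si) > thr,
       preferred = if (fl >= fr) "L" else "R")
}

#' Detect spatial fields on a rate map
#'
#' Peaks with a 20-cm minimum separation (greedy suppression, largest
#' first); each field is the maximal contiguous run of bins around a peak
#' with rate > 10% of that peak, kept when at least 8 cm long. Returns an
#' empty list when no peak reaches 3 Hz.
#'
#' @param map a [compute_rate_map()] result.
#' @param min_peak_hz place-field peak gate (default 3).
#' @param min_sep_cm minimum peak separation (default 20).
#' @param min_size_cm minimum field extent (default 8).
#' @return list of fields: start_cm, end_cm (half-open bin span), peak_cm,
#'   peak_hz, center_cm (extent midpoint), size_cm.
#' @export
detect_fields <- function(map, min_peak_hz = 3, min_sep_cm = 20,
                          min_size_cm = 8) {
  r <- map$rate_hz
  bw <- diff(map$bin_left_cm[1:2])
  n <- length(r)
  rv <- ifelse(is.na(r), -Inf, r)
  # local maxima (plateau-tolerant: strictly greater than one neighbor,
  # not less than the other)
  left <- c(-Inf, rv[-n]); right <- c(rv[-1], -Inf)
  cand <- which(rv >= left & rv >= right & (rv > left | rv > right) &
                  is.finite(rv) & rv >= min_peak_hz)
  if (!length(cand)) return(list())
  cand <- cand[order(rv[cand], decreasing = TRUE)]
  peaks <- integer(0)
  for (p in cand) {
    if (!length(peaks) ||
        all(abs(map$bin_left_cm[p] - map$bin_left_cm[peaks]) >= min_sep_cm)) {
      peaks <- c(peaks, p)
    }
  }
  fields <- list()
  for (p in sort(peaks)) {
    thr <- rv[p] * 0.1
    lo <- p; while (lo > 1 && is.finite(rv[lo - 1]) && rv[lo - 1] > thr) lo <- lo - 1
    hi <- p; while (hi < n && is.finite(rv[hi + 1]) && rv[hi + 1] > thr) hi <- hi + 1
    size <- (hi - lo + 1) * bw
    if (size < min_size_cm) next
    start <- map$bin_left_cm[lo]; end <- map$bin_left_cm[hi] + bw
    fields[[length(fields) + 1]] <- list(
      start_cm = start, end_cm = end, peak_cm = map$bin_left_cm[p] + bw / 2,
      peak_hz = rv[p], center_cm = (start + end) / 2, size_cm = size,
      bins = lo:hi)
  }
  fields
}

#' Spatial field asymmetry index
#'
#' The field's rate profile is resampled into 10 bins of 10% field length
#' relative to the field center; `AI = (A_R - A_L) / (A_R + A_L)` with
#' A_L/A_R the trapezoidal areas left/right of center. A negative AI means
#' an extended initial tail (for travel in the +x direction).
#'
#' @param map a [compute_rate_map()] result.
#' @param field one element of [detect_fields()].
#' @param center "midpoint" (default) or "peak" defines x = 0.
#' @param min_size_cm minimum field extent for the analysis (default 20).
#' @return list: AI, A_L, A_R, profile (10 resampled rates), or `NULL`
#'   when the field is too small or the area is zero.
#' @export
asymmetry_index <- function(map, field, center = c("midpoint", "peak"),
                            min_size_cm = 20) {
  center <- match.arg(center)
  if (field$size_cm < min_size_cm) return(NULL)
  c0 <- if (center == "midpoint") field$center_cm else field$peak_cm
  half <- max(c0 - field$start_cm, field$end_cm - c0)
  xs <- c0 + seq(-1, 1, length.out = 11) * half  # 10 bins of 10% field length
  bw <- diff(map$bin_left_cm[1:2])
  centers <- map$bin_left_cm + bw / 2
  ok <- !is.na(map$rate_hz)
  prof <- stats::approx(centers[ok], map$rate_hz[ok], xs, rule = 2)$y
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * 0.1  # relative length
  A_L <- trap(prof[1:6])   # five 10%-length bins with x < 0
  A_R <- trap(prof[6:11])
  if (A_L + A_R == 0) return(NULL)
  list(AI = (A_R - A_L) / (A_R + A_L), A_L = A_L, A_R = A_R, profile = prof)
}
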