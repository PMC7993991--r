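## Memoryless Poisson Bayesian decoder over (linear position x trajectory
## type). For a window of duration tau with spike counts n_i and encoding
## templates f_i(x, tr):
##   P(x, tr | spikes) = C * (prod_i f_i(x, tr)^{n_i}) * exp(-tau * sum_i f_i)
## with a uniform prior and C normalizing jointly over both trajectories.
## Computation is in log space.

#' Build an encoding model for one travel type
#'
#' Templates are the linearized rate maps of the two trajectories of one
#' travel type (outbound: C-to-L vs C-to-R; inbound: L-to-C vs R-to-C),
#' floored at `rate_floor_hz` so off-field spikes never yield zero
#' likelihood. Units lacking a defined map on a trajectory get the floor
#' everywhere there.
#'
#' @param rate_maps a [compute_rate_maps()] result.
#' @param travel "outbound" or "inbound".
#' @param region restrict to units of this region ("CA1", "PFC"), or
#'   `NULL` for all.
#' @param rate_floor_hz template floor (default 0.01).
#' @param min_units minimum usable units (default 5).
#' @return list of class `encoding_model`: `f` (units x 2D state matrix,
#'   states = L-trajectory bins then R-trajectory bins), `unit_ids`,
#'   `bin_left_cm`, `trajectories`, `travel`, `n_bins`.
#' @export
build_templates <- function(rate_maps, travel = c("outbound", "inbound"),
                            region = NULL, rate_floor_hz = 0.01,
                            min_units = 5) {
  travel <- match.arg(travel)
  trajs <- if (travel == "outbound") c("C-to-L", "C-to-R") else
    c("L-to-C", "R-to-C")
  uids <- rate_maps$units$unit_id
  if (!is.null(region)) uids <- uids[rate_maps$units$region == region]
  rows <- list(); ids <- c()
  bins <- NULL
  for (uid in uids) {
    m <- rate_maps$maps[[as.character(uid)]]
    if (is.null(bins)) bins <- m[[trajs[1]]]$bin_left_cm
    if (!identical(m[[trajs[1]]]$bin_left_cm, bins) ||
        !identical(m[[trajs[2]]]$bin_left_cm, bins)) {
      stop("mismatched bin grids across templates")
    }
    tmpl <- unlist(lapply(trajs, function(tr) {
      r <- m[[tr]]$rate_hz
      r[is.na(r)] <- rate_floor_hz
      pmax(r, rate_floor_hz)
    }))
    # require some signal on at least one trajectory
    if (all(tmpl <= rate_floor_hz)) next
    rows[[length(rows) + 1]] <- tmpl
    ids <- c(ids, uid)
  }
  if (length(rows) < min_units) {
    stop("fewer than ", min_units, " units with defined maps for ", travel)
  }
  structure(list(f = do.call(rbind, rows), unit_ids = ids,
                 bin_left_cm = bins, trajectories = trajs, travel = travel,
                 n_bins = length(bins)),
            class = "encoding_model")
}

#' Posterior over (position, trajectory) for one window of spike counts
#'
#' @param model an [build_templates()] encoding model.
#' @param counts integer spike counts per model unit in the window.
#' @param tau window duration, s.
#' @return numeric posterior over the 2D joint states (sums to 1); the
#'   first `n_bins` entries are the L-side trajectory.
#' @export
posterior_column <- function(model, counts, tau) {
  stopifnot(tau > 0, length(counts) == nrow(model$f), all(counts >= 0))
  ll <- as.numeric(t(log(model$f)) %*% counts) - tau * colSums(model$f)
  p <- exp(ll - logsumexp(ll))
  p / sum(p)
}

## Spike counts per (unit x window): windows are half-open [t, t+tau).
count_in_windows <- function(spikes_by_unit, starts, tau) {
  m <- matrix(0L, nrow = length(spikes_by_unit), ncol = length(starts))
  for (i in seq_along(spikes_by_unit)) {
    st <- spikes_by_unit[[i]]
    if (!length(st)) next
    m[i, ] <- vapply(starts, function(s)
      sum(st >= s & st < s + tau), integer(1))
  }
  m
}

## Vectorized posterior for many windows: returns states x T matrix.
posterior_matrix <- function(model, counts_mat, tau) {
  logf <- log(model$f)
  const <- tau * colSums(model$f)
  ll <- t(logf) %*% counts_mat - const  # states x T
  mx <- apply(ll, 2, max)
  p <- exp(sweep(ll, 2, mx))
  sweep(p, 2, colSums(p), "/")
}

#' Behavioral-timescale decoding of position and choice
#'
#' 120 ms windows advanced in 60 ms steps over locomotor samples
#' (speed > 5 cm/s), excluding positions within 15 cm of any reward well
#' and all SWR times. Per window the maximum a posteriori (MAP) position
#' and trajectory are compared with the animal's actual linear position
#' and trial choice. Windows with zero spikes across units are flagged
#' undecodable and excluded from accuracy.
#'
#' @param model an [build_templates()] encoding model.
#' @param spikes spike table (unit_id, time_s).
#' @param linearized a [linearize()] table.
#' @param trials trial table (for choices); only trials whose travel
#'   matches the model are decoded.
#' @param maze a [w_maze()] geometry.
#' @param tau window length, s (default 0.12).
#' @param step window step, s (default 0.06).
#' @param well_margin_cm exclusion radius around wells (default 15).
#' @param swr_intervals optional SWR intervals to exclude.
#' @return list of class `behavioral_decode`: `windows` (center_s,
#'   trial_id, actual_cm, map_cm, map_trajectory, actual_choice, decoded
#'   choice, correct, error_cm, n_spikes), `accuracy` (fraction of
#'   decodable windows with correct choice), `median_error_cm`,
#'   `n_undecodable`.
#' @export
decode_behavioral <- function(model, spikes, linearized, trials, maze,
                              tau = 0.12, step = 0.06, well_margin_cm = 15,
                              swr_intervals = NULL) {
  trials <- trials[trials$travel == model$travel, , drop = FALSE]
  spk <- lapply(model$unit_ids, function(u)
    spikes$time_s[spikes$unit_id == u])
  plen <- maze$path_length_cm
  res <- list()
  for (i in seq_len(nrow(trials))) {
    t0 <- trials$run_start_s[i]; t1 <- trials$run_end_s[i]
    starts <- seq(t0, t1 - tau, by = step)
    if (!length(starts)) next
    centers <- starts + tau / 2
    # actual linear position at window centers
    ok <- linearized$trajectory != "none" & !is.na(linearized$linear_cm)
    actual <- stats::approx(linearized$time_s[ok], linearized$linear_cm[ok],
                            centers, rule = 2)$y
    speed <- stats::approx(linearized$time_s, linearized$speed_cm_s,
                           centers, rule = 2)$y
    keep <- speed > 5 & actual > well_margin_cm & actual < plen - well_margin_cm
    if (!is.null(swr_intervals) && nrow(swr_intervals)) {
      keep <- keep & !in_intervals(centers, swr_intervals)
    }
    if (!any(keep)) next
    starts <- starts[keep]; centers <- centers[keep]; actual <- actual[keep]
    cm <- count_in_windows(spk, starts, tau)
    nspk <- colSums(cm)
    pm <- posterior_matrix(model, cm, tau)
    map_state <- apply(pm, 2, which.max)  # ties: lowest state index
    nb <- model$n_bins
    bw <- diff(model$bin_left_cm[1:2])
    map_traj_idx <- ifelse(map_state > nb, 2L, 1L)
    map_bin <- ifelse(map_state > nb, map_state - nb, map_state)
    map_cm <- model$bin_left_cm[map_bin] + bw / 2
    decoded <- c("L", "R")[map_traj_idx]
    actual_choice <- trials$choice[i]
    res[[length(res) + 1]] <- data.frame(
      center_s = centers, trial_id = trials$trial_id[i],
      actual_cm = actual, map_cm = map_cm,
      decoded_choice = decoded, actual_choice = actual_choice,
      correct = decoded == actual_choice,
      error_cm = abs(map_cm - actual), n_spikes = nspk,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no decodable windows")
  w <- do.call(rbind, res)
  dec <- w[w$n_spikes > 0, ]
  structure(list(
    windows = w,
    accuracy = mean(dec$correct),
    median_error_cm = stats::median(dec$error_cm),
    n_undecodable = sum(w$n_spikes == 0)
  ), class = "behavioral_decode")
}
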