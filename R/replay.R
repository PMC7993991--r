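## Replay-sequence detection inside SWRs and CA1-PFC reactivation
## strength per trajectory template.

#' Detect replay sequences within SWR events
#'
#' Candidate events are SWRs (duration >= 50 ms, during immobility at
#' wells) in which at least `min_cells` place cells fired. Each candidate
#' is decoded in 10 ms non-overlapping bins; the decoded trajectory is the
#' one holding more posterior mass, and the R-squared of an ordinary
#' linear regression of its MAP positions on temporal bin is compared
#' with a Monte-Carlo null built by permuting the temporal bins (time
#' shuffle; p < 0.05, ties counted). Direction comes from the regression
#' slope sign relative to the trajectory's travel orientation.
#'
#' @param model an [build_templates()] encoding model (outbound CA1
#'   templates for the classic analysis).
#' @param swrs SWR table (start_s, end_s or duration_s).
#' @param spikes spike table (unit_id, region, time_s).
#' @param place_cells unit ids counting toward the candidate gate
#'   (place cells); defaults to the model's units.
#' @param tau bin length, s (default 0.01).
#' @param n_shuffles Monte-Carlo reps (default 1000).
#' @param seed RNG seed.
#' @param min_cells candidate gate (default 5).
#' @return data.frame: swr_id, candidate, n_cells, per-trajectory r2,
#'   p-values, significant, decoded trajectory, direction, slope_cm_s.
#' @export
detect_replay <- function(model, swrs, spikes, place_cells = NULL,
                          tau = 0.01, n_shuffles = 1000, seed = 1L,
                          min_cells = 5) {
  if (is.null(place_cells)) place_cells <- model$unit_ids
  if (is.null(swrs$end_s)) swrs$end_s <- swrs$start_s + swrs$duration_s
  spk <- lapply(model$unit_ids, function(u)
    spikes$time_s[spikes$unit_id == u])
  nb <- model$n_bins
  bw <- diff(model$bin_left_cm[1:2])
  out <- list()
  for (i in seq_len(nrow(swrs))) {
    dur <- swrs$end_s[i] - swrs$start_s[i]
    row <- data.frame(swr_id = i, candidate = FALSE, n_cells = 0L,
                      r2_L = NA_real_, r2_R = NA_real_,
                      p_L = NA_real_, p_R = NA_real_, significant = FALSE,
                      decoded = NA_character_, direction = NA_character_,
                      slope_cm_s = NA_real_, stringsAsFactors = FALSE)
    if (dur >= 0.05) {
      insel <- spikes$time_s >= swrs$start_s[i] &
        spikes$time_s < swrs$end_s[i] & spikes$unit_id %in% place_cells
      row$n_cells <- length(unique(spikes$unit_id[insel]))
      row$candidate <- row$n_cells >= min_cells
    }
    if (row$candidate) {
      starts <- seq(swrs$start_s[i], swrs$end_s[i] - tau, by = tau)
      cm <- count_in_windows(spk, starts, tau)
      keep <- colSums(cm) > 0
      if (sum(keep) >= 3) {
        pm <- posterior_matrix(model, cm[, keep, drop = FALSE], tau)
        kk <- which(keep)
        set.seed(seed + i)
        stats_tr <- lapply(1:2, function(trk) {
          block <- pm[(trk - 1) * nb + seq_len(nb), , drop = FALSE]
          mp <- (apply(block, 2, which.max) - 0.5) * bw
          r2 <- suppressWarnings(stats::cor(mp, kk))^2
          if (is.na(r2)) r2 <- 0
          slope <- stats::cov(mp, kk) / stats::var(kk) / tau
          # a time shuffle permutes the MAP sequence, so the null R^2 is
          # the squared correlation of the permuted MAP positions
          sh <- vapply(seq_len(n_shuffles), function(s) {
            r <- suppressWarnings(stats::cor(mp[sample.int(length(mp))], kk))
            if (is.na(r)) 0 else r^2
          }, numeric(1))
          list(r2 = r2, slope = slope,
               p = (1 + sum(sh >= r2)) / (n_shuffles + 1),
               thr = stats::quantile(sh, 0.95, names = FALSE))
        })
        row$r2_L <- stats_tr[[1]]$r2; row$r2_R <- stats_tr[[2]]$r2
        row$p_L <- stats_tr[[1]]$p; row$p_R <- stats_tr[[2]]$p
        # the decoded trajectory is fixed first (greater posterior mass),
        # then its sequential structure is tested once; testing both
        # trajectories and OR-ing would double the false-positive rate.
        # The Monte-Carlo p counts ties (heavy with few decodable bins).
        mass <- c(sum(pm[seq_len(nb), ]), sum(pm[nb + seq_len(nb), ]))
        pick <- which.max(mass)
        row$decoded <- c("L", "R")[pick]
        if (stats_tr[[pick]]$p < 0.05) {
          row$significant <- TRUE
          slope <- stats_tr[[pick]]$slope
          orient <- if (model$travel == "outbound") 1 else -1
          row$direction <- if (orient * slope > 0) "forward" else "reverse"
          row$slope_cm_s <- slope
        }
      }
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' CA1-PFC reactivation strength of one SWR event
#'
#' C_RUN is the N x M matrix of Pearson correlations between the
#' linearized rate maps (on one trajectory type) of each active CA1 cell
#' and each active PFC cell; C_SWR correlates their 10 ms binned,
#' z-transformed spike trains within the event. The reactivation strength
#' R is the Pearson correlation between the two vectorized matrices; a
#' 95% CI under cell-identity permutation of C_SWR rows is attached.
#'
#' @param spikes spike table (unit_id, region, time_s).
#' @param start_s,end_s event interval.
#' @param rate_maps a [compute_rate_maps()] result.
#' @param trajectory trajectory type for the C_RUN template.
#' @param bin_s spike-train bin, s (default 0.01).
#' @param min_cells minimum active CA1 and PFC cells (default 5).
#' @param n_shuffles identity permutations (default 1000).
#' @param seed RNG seed.
#' @return list: R, n_ca1, n_pfc, ci (shuffle 2.5/97.5 percentiles),
#'   c_run, c_swr; or `NULL` when too few active cells.
#' @export
reactivation_strength <- function(spikes, start_s, end_s, rate_maps,
                                  trajectory, bin_s = 0.01, min_cells = 5,
                                  n_shuffles = 1000, seed = 1L) {
  insel <- spikes$time_s >= start_s & spikes$time_s < end_s
  ev <- spikes[insel, ]
  edges <- seq(start_s, end_s + bin_s - 1e-12, by = bin_s)
  nbin <- length(edges) - 1L
  if (nbin < 3) return(NULL)
  act <- unique(ev[, c("unit_id", "region")])
  ca1 <- act$unit_id[act$region == "CA1"]
  pfc <- act$unit_id[act$region == "PFC"]
  # only cells with rate maps (i.e. passing inclusion) participate
  ca1 <- ca1[as.character(ca1) %in% names(rate_maps$maps)]
  pfc <- pfc[as.character(pfc) %in% names(rate_maps$maps)]
  ztrain <- function(uid) {
    h <- tabulate(pmin(findInterval(
      ev$time_s[ev$unit_id == uid], edges, rightmost.closed = TRUE), nbin),
      nbins = nbin)
    if (stats::sd(h) == 0) return(NULL)
    (h - mean(h)) / stats::sd(h)
  }
  z_ca1 <- Filter(Negate(is.null), stats::setNames(lapply(ca1, ztrain),
                                                   as.character(ca1)))
  z_pfc <- Filter(Negate(is.null), stats::setNames(lapply(pfc, ztrain),
                                                   as.character(pfc)))
  if (length(z_ca1) < min_cells || length(z_pfc) < min_cells) return(NULL)
  mapvec <- function(uid) {
    m <- rate_maps$maps[[uid]][[trajectory]]
    r <- m$rate_hz; r[is.na(r)] <- 0
    r
  }
  run_ca1 <- vapply(names(z_ca1), mapvec,
                    numeric(length(mapvec(names(z_ca1)[1]))))
  run_pfc <- vapply(names(z_pfc), mapvec, numeric(nrow(run_ca1)))
  c_run <- suppressWarnings(stats::cor(run_ca1, run_pfc))
  zc <- do.call(cbind, z_ca1); zp <- do.call(cbind, z_pfc)
  c_swr <- stats::cor(zc, zp)
  ok <- is.finite(c_run) & is.finite(c_swr)
  if (sum(ok) < 4 || stats::sd(c_run[ok]) == 0 || stats::sd(c_swr[ok]) == 0)
    return(NULL)
  R <- stats::cor(as.vector(c_run[ok]), as.vector(c_swr[ok]))
  set.seed(seed)
  sh <- vapply(seq_len(n_shuffles), function(s) {
    perm <- sample.int(nrow(c_swr))
    cs <- c_swr[perm, , drop = FALSE]
    okp <- is.finite(c_run) & is.finite(cs)
    if (sum(okp) < 4) return(NA_real_)
    suppressWarnings(stats::cor(as.vector(c_run[okp]), as.vector(cs[okp])))
  }, numeric(1))
  list(R = R, n_ca1 = length(z_ca1), n_pfc = length(z_pfc),
       ci = stats::quantile(sh, c(0.025, 0.975), names = FALSE, na.rm = TRUE),
       c_run = c_run, c_swr = c_swr)
}
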