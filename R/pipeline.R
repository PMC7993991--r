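## Pipeline orchestration: run every analysis stage in dependency order on
## a (synthetic or loaded) session, collect tidy result tables, and record
## provenance (config hash, seed, per-result hashes) so reruns can be
## verified bit-for-bit.

#' Run the full analysis pipeline on a session
#'
#' Stages: behavior (speed, linearization, well events, masks) ->
#' rate maps / selectivity -> LFP (theta phase, cycles, SWRs) ->
#' behavioral decoding -> theta sequences -> cycle skipping -> phase
#' precession -> replay + reactivation -> choice/outcome prediction.
#' Stages that need more data than the session provides (e.g. too few
#' incorrect trials for outcome prediction) record an explanatory string
#' instead of failing the run.
#'
#' @param session a [simulate_session()] result (or [read_session()]
#'   output plus a `config`).
#' @param n_shuffles shuffles for sequence/replay significance (default
#'   200; the reference analysis uses 1000 - reduce only for speed).
#' @param max_theta_events cap on scored theta candidates per region
#'   (default Inf).
#' @param out_dir optional directory: tidy CSV results + provenance JSON.
#' @param verbose print stage progress.
#' @return list of class `wtrack_results` with per-stage results and
#'   `hashes` (digest of every stage output).
#' @export
run_pipeline <- function(session, n_shuffles = 200, max_theta_events = Inf,
                         out_dir = NULL, verbose = FALSE) {
  cfg <- session$config
  maze <- cfg$maze
  seed0 <- cfg$seed
  say <- function(...) if (verbose) message(...)
  res <- list(config_hash = digest::digest(cfg), seed = seed0)

  say("behavior")
  lin <- linearize(session$position, maze, session$trials)
  trials <- detect_well_events(lin, session$trials)
  masks <- locomotor_mask(lin$speed_cm_s)
  loco_iv <- mask_to_intervals(lin$time_s, masks$locomotion)
  immo_iv <- mask_to_intervals(lin$time_s, masks$immobility)
  res$trials <- trials

  say("lfp")
  swr_iv <- data.frame(start_s = numeric(0), end_s = numeric(0))
  phase <- NULL; cycles <- NULL
  if (!is.null(session$lfp)) {
    phase <- theta_phase(session$lfp)
    swrs <- detect_swrs(session$lfp, immo_iv)
    swr_iv <- swrs[, c("start_s", "end_s")]
    res$swrs <- swrs
  }

  say("ratemaps")
  rm_set <- compute_rate_maps(session$spikes, lin, maze,
                              swr_intervals = swr_iv)
  res$units <- rm_set$units
  sel_rows <- list()
  for (uid in names(rm_set$maps)) {
    reg <- rm_set$units$region[rm_set$units$unit_id == as.integer(uid)]
    for (travel in c("outbound", "inbound")) {
      trs <- if (travel == "outbound") c("C-to-L", "C-to-R") else
        c("L-to-C", "R-to-C")
      si <- selectivity_index(rm_set$maps[[uid]][[trs[1]]],
                              rm_set$maps[[uid]][[trs[2]]], reg)
      if (is.null(si)) next
      sel_rows[[length(sel_rows) + 1]] <- data.frame(
        unit_id = as.integer(uid), region = reg, travel = travel,
        FR_L = si$FR_L, FR_R = si$FR_R, SI = si$SI,
        selective = si$selective, preferred = si$preferred,
        stringsAsFactors = FALSE)
    }
  }
  res$selectivity <- if (length(sel_rows)) do.call(rbind, sel_rows) else
    data.frame()

  if (!is.null(phase)) {
    say("theta cycles")
    cycles <- segment_theta_cycles(phase, session$spikes, loco_iv)
    res$theta_boundary_phase <- cycles$boundary_phase
    res$n_theta_cycles <- nrow(cycles$cycles)
  }

  say("behavioral decode")
  res$behavioral_decode <- lapply(
    stats::setNames(c("outbound", "inbound"), c("outbound", "inbound")),
    function(travel) {
      tryCatch({
        model <- build_templates(rm_set, travel, region = "CA1")
        d <- decode_behavioral(model, session$spikes, lin, trials, maze,
                               swr_intervals = swr_iv)
        list(accuracy = d$accuracy, median_error_cm = d$median_error_cm,
             n_windows = nrow(d$windows), n_undecodable = d$n_undecodable)
      }, error = function(e) conditionMessage(e))
    })

  say("theta sequences")
  res$theta_sequences <- list()
  if (!is.null(cycles)) {
    for (region in c("CA1", "PFC")) {
      cand <- find_candidates(cycles, session$spikes, lin, region)
      if (!nrow(cand)) {
        res$theta_sequences[[region]] <- "no candidate events"
        next
      }
      if (nrow(cand) > max_theta_events) {
        cand <- cand[seq_len(max_theta_events), ]
      }
      rows <- list(); segs <- character(0)
      for (i in seq_len(nrow(cand))) {
        travel <- cand$travel[i]
        model <- tryCatch(build_templates(rm_set, travel, region = region),
                          error = function(e) NULL)
        if (is.null(model)) next
        ev <- decode_event(model,
                           session$spikes[session$spikes$region == region, ],
                           cand$start_s[i], cand$end_s[i])
        if (is.null(ev)) next
        trial <- trials[trials$trial_id == cand$trial_id[i], ]
        if (!nrow(trial)) next
        rows[[length(rows) + 1]] <- classify_sequence(
          ev, cand[i, ], trial$choice[1], n_shuffles = n_shuffles,
          seed = seed0 + 97L * i)
        segs <- c(segs, cp_segment(cand$pos_cm[i], maze))
      }
      if (length(rows)) {
        tab <- do.call(rbind, rows)
        tab$segment <- segs
        tab$region <- region
        res$theta_sequences[[region]] <- tab
      } else res$theta_sequences[[region]] <- "no scorable events"
    }
  }

  say("cycle skipping")
  run_iv <- loco_iv
  csi_rows <- list()
  for (uid in names(rm_set$maps)) {
    st <- session$spikes$time_s[session$spikes$unit_id == as.integer(uid)]
    acg <- compute_acg(st, run_iv)
    if (is.null(acg)) next
    csi <- cycle_skipping_index(acg)
    csi_rows[[length(csi_rows) + 1]] <- data.frame(
      unit_id = as.integer(uid),
      region = rm_set$units$region[rm_set$units$unit_id == as.integer(uid)],
      rel_theta_power = acg$rel_theta_power,
      theta_modulated = acg$theta_modulated,
      csi = if (is.null(csi)) NA_real_ else csi$csi,
      stringsAsFactors = FALSE)
  }
  res$cycle_skipping <- if (length(csi_rows)) do.call(rbind, csi_rows) else
    data.frame()

  say("phase precession")
  prec_rows <- list()
  if (!is.null(phase)) {
    for (uid in names(rm_set$maps)) {
      st <- session$spikes$time_s[session$spikes$unit_id == as.integer(uid)]
      for (tr in TRAJECTORIES) {
        flds <- detect_fields(rm_set$maps[[uid]][[tr]])
        for (f in flds) {
          fit <- field_precession(st, phase, f, lin, tr)
          if (is.null(fit)) next
          prec_rows[[length(prec_rows) + 1]] <- data.frame(
            unit_id = as.integer(uid), trajectory = tr,
            field_start_cm = f$start_cm, field_end_cm = f$end_cm,
            slope_deg_per_cm = fit$slope_deg_per_cm, r = fit$r, p = fit$p,
            n = fit$n, significant = fit$significant,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res$phase_precession <- if (length(prec_rows)) do.call(rbind, prec_rows)
    else data.frame()

  say("field asymmetry")
  ai_rows <- list()
  if (nrow(res$phase_precession)) {
    pp <- res$phase_precession
    for (i in which(pp$significant)) {
      uid <- as.character(pp$unit_id[i])
      map <- rm_set$maps[[uid]][[pp$trajectory[i]]]
      flds <- detect_fields(map)
      if (!length(flds)) next
      # highest-peak field of the unit on that trajectory only
      best <- flds[[which.max(vapply(flds, `[[`, numeric(1), "peak_hz"))]]
      if (abs(best$start_cm - pp$field_start_cm[i]) > 1e-6) next
      ai <- asymmetry_index(map, best)
      if (is.null(ai)) next
      ai_rows[[length(ai_rows) + 1]] <- data.frame(
        unit_id = pp$unit_id[i], trajectory = pp$trajectory[i],
        AI = ai$AI, stringsAsFactors = FALSE)
    }
  }
  res$field_asymmetry <- if (length(ai_rows)) do.call(rbind, ai_rows) else
    data.frame()

  say("replay + reactivation")
  res$replay <- "no SWRs detected"
  if (!is.null(session$lfp) && nrow(res$swrs)) {
    swr_use <- res$swrs[res$swrs$duration_s >= 0.05, , drop = FALSE]
    res$swrs_eligible <- swr_use
    pc <- rm_set$units$unit_id[rm_set$units$place_cell &
                                 rm_set$units$region == "CA1"]
    repl <- tryCatch({
      model <- build_templates(rm_set, "outbound", region = "CA1")
      detect_replay(model, swr_use, session$spikes, place_cells = pc,
                    n_shuffles = n_shuffles, seed = seed0 + 11L)
    }, error = function(e) conditionMessage(e))
    res$replay <- repl
    if (is.data.frame(repl)) {
      ra <- list()
      for (i in which(repl$significant)) {
        traj <- paste0("C-to-", repl$decoded[i])
        r <- reactivation_strength(session$spikes, swr_use$start_s[i],
                                   swr_use$end_s[i], rm_set, traj,
                                   n_shuffles = min(n_shuffles, 500),
                                   seed = seed0 + 13L * i)
        if (is.null(r)) next
        ra[[length(ra) + 1]] <- data.frame(
          swr_id = repl$swr_id[i], trajectory = traj, R = r$R,
          ci_lo = r$ci[1], ci_hi = r$ci[2], n_ca1 = r$n_ca1,
          n_pfc = r$n_pfc, direction = repl$direction[i],
          stringsAsFactors = FALSE)
      }
      res$reactivation <- if (length(ra)) do.call(rbind, ra) else
        data.frame()
    }
  }

  say("prediction")
  res$choice_prediction <- list()
  for (region in names(res$theta_sequences)) {
    tab <- res$theta_sequences[[region]]
    if (!is.data.frame(tab)) next
    for (seg in c("before_cp", "after_cp")) {
      cr <- choice_representation(tab[tab$segment == seg, , drop = FALSE])
      pt <- cr$per_trial
      key <- paste(region, seg, sep = ".")
      if (!is.data.frame(pt) || !nrow(pt)) {
        res$choice_prediction[[key]] <- "no sequences in segment"
        next
      }
      pt <- pt[pt$n_actual >= 1 & pt$n_alternative >= 1, , drop = FALSE]
      lab <- trials$choice[match(pt$trial_id, trials$trial_id)]
      res$choice_prediction[[key]] <- tryCatch(
        predict_choice(pt[, c("n_actual", "n_alternative")], lab,
                       n_perm = min(n_shuffles, 500), seed = seed0 + 17L),
        error = function(e) conditionMessage(e))
    }
  }
  res$outcome_prediction <- "insufficient replay/reactivation data"
  if (is.data.frame(res$replay) && !is.null(res$reactivation) &&
      is.data.frame(res$reactivation) && nrow(res$reactivation)) {
    feats <- outcome_features(res$reactivation, res$swrs_eligible, trials)
    res$outcome_prediction <- lapply(feats, function(fx) {
      tryCatch(predict_outcome(fx$X, fx$correct,
                               n_perm = min(n_shuffles, 500),
                               seed = seed0 + 19L),
               error = function(e) conditionMessage(e))
    })
  }

  res$hashes <- lapply(res[setdiff(names(res), "hashes")], digest::digest)
  class(res) <- "wtrack_results"
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

## Per-trial outcome features: mean reactivation strength for the actual
## vs the alternative upcoming trajectory over SWRs in the pre-trial well
## dwell, split by replay direction.
outcome_features <- function(reactivation, swrs, trials) {
  out <- list()
  for (dir in c("forward", "reverse")) {
    ra <- reactivation[reactivation$direction == dir, , drop = FALSE]
    if (!nrow(ra)) next
    rows <- list()
    outb <- trials[trials$travel == "outbound", ]
    for (i in seq_len(nrow(outb))) {
      pre0 <- if (i == 1) 0 else outb$run_end_s[i - 1]
      sel <- ra$swr_id %in%
        which(swrs$start_s > pre0 & swrs$start_s < outb$run_start_s[i])
      if (!any(sel)) next
      act_traj <- paste0("C-to-", outb$choice[i])
      r_act <- ra$R[sel & ra$trajectory == act_traj]
      r_alt <- ra$R[sel & ra$trajectory != act_traj]
      rows[[length(rows) + 1]] <- data.frame(
        trial_id = outb$trial_id[i],
        R_actual = if (length(r_act)) mean(r_act) else 0,
        R_alternative = if (length(r_alt)) mean(r_alt) else 0,
        correct = outb$correct[i])
    }
    if (!length(rows)) next
    ft <- do.call(rbind, rows)
    out[[dir]] <- list(X = ft[, c("R_actual", "R_alternative")],
                       correct = ft$correct, trial_id = ft$trial_id)
  }
  out
}

#' Write pipeline results as tidy CSV tables plus provenance JSON
#'
#' @param res a [run_pipeline()] result.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res)) {
    x <- res[[nm]]
    if (is.data.frame(x) && nrow(x)) {
      utils::write.csv(x, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  if (is.list(res$theta_sequences)) {
    for (rg in names(res$theta_sequences)) {
      tab <- res$theta_sequences[[rg]]
      if (is.data.frame(tab) && nrow(tab)) {
        utils::write.csv(tab, file.path(out_dir,
                                        paste0("theta_sequences_", rg, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  prov <- list(config_hash = res$config_hash, seed = res$seed,
               hashes = res$hashes,
               package_version =
                 as.character(utils::packageVersion("wtrackseq")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.wtrack_results <- function(x, ...) {
  cat("wtrack_results (config", substr(x$config_hash, 1, 8), ")\n")
  cat("  stages:", paste(setdiff(names(x),
                                 c("config_hash", "seed", "hashes")),
                         collapse = ", "), "\n")
  invisible(x)
}
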