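## Session container I/O: plain columnar CSV tables plus a JSON metadata
## file with provenance (config, seed, package version, config hash).
## The LFP channel is stored as a single-column CSV with its sampling
## rate in the metadata.

## Format numeric columns at 17 significant digits so the CSV round-trip
## is bit-exact (read.csv parses them straight back to doubles).
precise <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write a session to a directory container
#'
#' @param session a [simulate_session()] result (or compatible list).
#' @param dir output directory (created if needed).
#' @param lfp write the LFP channel too (largest file).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, lfp = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(precise(session$position), file.path(dir, "position.csv"),
                   row.names = FALSE)
  utils::write.csv(precise(session$spikes), file.path(dir, "spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(precise(session$trials), file.path(dir, "trials.csv"),
                   row.names = FALSE)
  if (lfp && !is.null(session$lfp)) {
    utils::write.csv(precise(data.frame(signal = session$lfp$signal)),
                     file.path(dir, "lfp.csv"), row.names = FALSE)
  }
  cfg <- session$config
  meta <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "maze")],
    maze = list(stem_cm = cfg$maze$stem_cm,
                path_length_cm = cfg$maze$path_length_cm,
                cp_cm = cfg$maze$cp_cm),
    lfp_fs = if (!is.null(session$lfp)) session$lfp$fs else NULL,
    config_hash = digest::digest(cfg),
    package_version = as.character(utils::packageVersion("wtrackseq"))
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read a session container written by [write_session()]
#'
#' @param dir container directory.
#' @return list with position, spikes, trials, lfp (or NULL) and meta.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  lfp <- NULL
  if (file.exists(file.path(dir, "lfp.csv"))) {
    sig <- utils::read.csv(file.path(dir, "lfp.csv"))$signal
    lfp <- list(fs = meta$lfp_fs, signal = sig,
                time_s = (seq_along(sig) - 1) / meta$lfp_fs)
  }
  list(
    position = utils::read.csv(file.path(dir, "position.csv")),
    spikes = utils::read.csv(file.path(dir, "spikes.csv")),
    trials = utils::read.csv(file.path(dir, "trials.csv")),
    lfp = lfp, meta = meta
  )
}
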