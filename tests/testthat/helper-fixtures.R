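# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; no data files.

.fix <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# mid-sized session with LFP shared by the lfp / thetaseq / replay tests
fix_session <- function() {
  fix_get("session", function() simulate_session(sim_config(seed = 42L,
                                                            n_trials = 30L)))
}

fix_linearized <- function() {
  fix_get("lin", function() {
    s <- fix_session()
    linearize(s$position, s$config$maze, s$trials)
  })
}

fix_masks <- function() {
  fix_get("masks", function() {
    lin <- fix_linearized()
    m <- locomotor_mask(lin$speed_cm_s)
    list(loco = mask_to_intervals(lin$time_s, m$locomotion),
         immo = mask_to_intervals(lin$time_s, m$immobility))
  })
}

fix_ratemaps <- function() {
  fix_get("rms", function() {
    s <- fix_session()
    compute_rate_maps(s$spikes, fix_linearized(), s$config$maze,
                      swr_intervals = fix_session()$truth$swrs[
                        , c("start_s", "duration_s")] |>
                        (\(d) data.frame(start_s = d$start_s,
                                         end_s = d$start_s + d$duration_s))())
  })
}

fix_phase <- function() {
  fix_get("phase", function() theta_phase(fix_session()$lfp))
}

# ground-truth units + analytic templates for constructed-event tests
fix_units <- function() {
  fix_get("units", function() wtrackseq:::make_units(sim_config(seed = 42L)))
}

fix_model_out <- function() {
  fix_get("model_out", function()
    templates_from_truth(fix_units(), w_maze(), "outbound", region = "CA1"))
}

# brute-force oracle for the weighted correlation: plain double sums
oracle_wcorr <- function(pmat, x = seq_len(nrow(pmat)),
                         t = seq_len(ncol(pmat))) {
  W <- 0; Sx <- 0; St <- 0
  for (i in seq_len(ncol(pmat))) for (j in seq_len(nrow(pmat))) {
    W <- W + pmat[j, i]; Sx <- Sx + pmat[j, i] * x[j]
    St <- St + pmat[j, i] * t[i]
  }
  Ex <- Sx / W; Et <- St / W
  cxt <- cxx <- ctt <- 0
  for (i in seq_len(ncol(pmat))) for (j in seq_len(nrow(pmat))) {
    cxt <- cxt + pmat[j, i] * (x[j] - Ex) * (t[i] - Et)
    cxx <- cxx + pmat[j, i] * (x[j] - Ex)^2
    ctt <- ctt + pmat[j, i] * (t[i] - Et)^2
  }
  cxt / sqrt(cxx * ctt)
}

# brute-force oracle for the best-fit-line score: per-line mass scan
oracle_bfl <- function(pmat, bin_cm, dt_s, k, d_cm, v_abs_range, v_step) {
  D <- nrow(pmat)
  centers <- (seq_len(D) - 0.5) * bin_cm
  v_abs <- seq(v_abs_range[1], v_abs_range[2], by = v_step)
  vs <- as.vector(rbind(v_abs, -v_abs))
  best <- list(r_max = -Inf, v_mps = NA_real_, rho_cm = NA_real_)
  for (v in vs) for (ri in seq_len(D)) {
    rho <- centers[ri]
    acc <- 0
    for (j in seq_along(k)) {
      line <- rho + v * 100 * k[j] * dt_s
      acc <- acc + sum(pmat[abs(centers - line) <= d_cm, j])
    }
    r <- acc / length(k)
    if (r > best$r_max + 1e-15) {
      best <- list(r_max = r, v_mps = v, rho_cm = rho)
    }
  }
  best
}

# brute-force Poisson-Bayes posterior: literal per-state evaluation
oracle_posterior <- function(f, counts, tau) {
  p <- apply(f, 2, function(fx) prod(fx^counts) * exp(-tau * sum(fx)))
  p / sum(p)
}

random_pmat <- function(D, Tn, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(D * Tn), D, Tn)
  sweep(m, 2, colSums(m), "/")  # each column a probability vector
}
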