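# A minimal hand-built linearized table: uniform back-and-forth coverage
# of one trajectory at constant speed.
flat_linearized <- function(trajectory = "C-to-L", speed = 20,
                            n_pass = 40, seed = 1) {
  set.seed(seed)
  plen <- w_maze()$path_length_cm
  arc <- rep(c(seq(0, plen, by = speed / 30),
               seq(plen, 0, by = -speed / 30)), n_pass / 2)
  n <- length(arc)
  data.frame(time_s = seq_len(n) / 30, x_cm = 0, y_cm = 0,
             speed_cm_s = speed, linear_cm = arc,
             trajectory = trajectory, trial_id = 1L,
             stringsAsFactors = FALSE)
}

test_that("uniform Poisson unit gives a flat map and no place-cell flag", {
  lin <- flat_linearized()
  set.seed(2)
  dur <- max(lin$time_s)
  st <- sort(stats::runif(stats::rpois(1, 2 * dur), 0, dur))
  m <- compute_rate_map(st, lin, "C-to-L", w_maze())
  ok <- !is.na(m$rate_hz)
  expect_gt(sum(ok), 90)
  expect_lt(abs(mean(m$rate_hz[ok]) - 2), 0.3)
  expect_lt(m$peak_hz, 3)  # not a place cell

  # mass conservation before smoothing: sum(count) equals retained spikes
  expect_equal(sum(m$raw_count), m$n_spikes)
})

test_that("a planted Gaussian field is recovered in peak and center", {
  lin <- flat_linearized(n_pass = 40, seed = 3)
  set.seed(4)
  lam <- function(x) 10 * exp(-0.5 * ((x - 100) / 8)^2)
  # thinning on the trajectory samples
  dt <- 1 / 30
  p_fire <- lam(lin$linear_cm) * dt
  fire <- stats::runif(nrow(lin)) < p_fire
  st <- lin$time_s[fire]
  m <- compute_rate_map(st, lin, "C-to-L", w_maze())
  expect_lt(abs(m$peak_hz - 10) / 10, 0.2)
  pk_cm <- m$bin_left_cm[which.max(m$rate_hz)] + 1
  expect_lt(abs(pk_cm - 100), 4)
})

test_that("selectivity index follows the printed formula and thresholds", {
  mk <- function(rate) {
    structure(list(bin_left_cm = seq(0, 198, 2), rate_hz = rep(rate, 100),
                   occupancy_s = rep(1, 100), peak_hz = rate),
              class = "rate_map")
  }
  si <- selectivity_index(mk(15), mk(5), "CA1")
  expect_equal(si$SI, 0.5)
  expect_true(si$selective)
  expect_equal(si$preferred, "L")
  # antisymmetry under L/R swap
  si_sw <- selectivity_index(mk(5), mk(15), "CA1")
  expect_equal(si_sw$SI, -0.5)
  # region thresholds: |SI| = 0.35 is selective in PFC, not CA1
  si_ca1 <- selectivity_index(mk(13.5), mk(6.5), "CA1")
  expect_equal(si_ca1$SI, 0.35)
  expect_false(si_ca1$selective)
  si_pfc <- selectivity_index(mk(13.5), mk(6.5), "PFC")
  expect_true(si_pfc$selective)
  # equal rates: SI = 0
  expect_equal(selectivity_index(mk(8), mk(8), "CA1")$SI, 0)
  # sub-3 Hz peaks: undefined
  expect_null(selectivity_index(mk(2.5), mk(2), "CA1"))
})

test_that("field detection applies peak separation and size gates", {
  mkmap <- function(rate) {
    structure(list(bin_left_cm = seq(0, by = 2,
                                     length.out = length(rate)),
                   rate_hz = rate, occupancy_s = rep(1, length(rate)),
                   peak_hz = max(rate)), class = "rate_map")
  }
  x <- seq(1, 199, by = 2)
  # single Gaussian bump -> one field containing the peak
  f1 <- detect_fields(mkmap(8 * exp(-0.5 * ((x - 60) / 10)^2)))
  expect_length(f1, 1)
  expect_true(f1[[1]]$start_cm <= 60 && f1[[1]]$end_cm >= 60)
  # two bumps 15 cm apart merge (< 20 cm separation -> one peak kept)
  f2 <- detect_fields(mkmap(8 * exp(-0.5 * ((x - 60) / 6)^2) +
                              7 * exp(-0.5 * ((x - 75) / 6)^2)))
  expect_length(f2, 1)
  # two bumps 60 cm apart stay separate
  f3 <- detect_fields(mkmap(8 * exp(-0.5 * ((x - 60) / 6)^2) +
                              7 * exp(-0.5 * ((x - 120) / 6)^2)))
  expect_length(f3, 2)
  # narrow bump (< 8 cm above 10% of peak) rejected
  f4 <- detect_fields(mkmap(8 * exp(-0.5 * ((x - 60) / 1.2)^2)))
  expect_length(f4, 0)
  # no 3 Hz peak -> empty
  expect_length(detect_fields(mkmap(2.5 * exp(-0.5 * ((x - 60) / 10)^2))),
                0)
})

test_that("asymmetry index matches analytic values on ramps", {
  mkmap <- function(rate) {
    structure(list(bin_left_cm = seq(0, by = 2, length.out = length(rate)),
                   rate_hz = rate, occupancy_s = rep(1, length(rate)),
                   peak_hz = max(rate)), class = "rate_map")
  }
  x <- seq(1, 199, by = 2)
  # linear ramp 0 -> peak over [50, 90], center at midpoint -> AI = 0.5
  ramp <- pmax(0, pmin((x - 50) / 40, 1)) * 10
  ramp[x > 90] <- 0
  field <- list(start_cm = 50, end_cm = 90, center_cm = 70, peak_cm = 89,
                size_cm = 40)
  ai <- asymmetry_index(mkmap(ramp), field)
  expect_equal(ai$AI, 0.5, tolerance = 0.06)
  expect_equal(ai$A_L, 0.125 * 10, tolerance = 0.1)
  expect_equal(ai$A_R, 0.375 * 10, tolerance = 0.15)
  # mirrored ramp -> AI = -0.5 (sign flip under spatial mirroring)
  rampm <- rev(ramp)  # value at x equals the ramp at 200 - x
  fieldm <- list(start_cm = 110, end_cm = 150, center_cm = 130,
                 peak_cm = 111, size_cm = 40)
  aim <- asymmetry_index(mkmap(rampm), fieldm)
  expect_equal(aim$AI, -ai$AI, tolerance = 1e-6)
  # symmetric triangle -> AI = 0
  tri <- pmax(0, 1 - abs(x - 100) / 20) * 8
  ftri <- list(start_cm = 80, end_cm = 120, center_cm = 100, peak_cm = 100,
               size_cm = 40)
  expect_equal(asymmetry_index(mkmap(tri), ftri)$AI, 0, tolerance = 1e-9)
  # under-sized fields are rejected
  small <- list(start_cm = 50, end_cm = 64, center_cm = 57, peak_cm = 57,
                size_cm = 14)
  expect_null(asymmetry_index(mkmap(ramp), small))
})

test_that("selective CA1 fraction tracks the planted fraction", {
  s <- fix_session()
  rms <- fix_ratemaps()
  units <- s$truth$units
  got <- vapply(as.character(units$unit_id[units$region == "CA1"]),
                function(id) {
    if (is.null(rms$maps[[id]])) return(NA)
    si <- selectivity_index(rms$maps[[id]][["C-to-L"]],
                            rms$maps[[id]][["C-to-R"]], "CA1")
    if (is.null(si)) NA else si$selective
  }, logical(1))
  phat <- mean(got, na.rm = TRUE)
  p0 <- s$config$selectivity_frac
  n <- sum(!is.na(got))
  ci <- p0 + c(-1, 1) * 1.96 * sqrt(p0 * (1 - p0) / n)
  expect_gt(phat, ci[1])
  expect_lt(phat, ci[2])
})
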