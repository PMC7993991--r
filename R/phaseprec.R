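## Circular-linear regression of spike theta phase on within-field
## position (phase precession). The slope maximizes the mean resultant
## length of (phase - 2*pi*a*x); the correlation and its p-value follow
## the circular-linear association statistic of Kempter et al. (2012).

#' Circular-linear fit of phase on position
#'
#' Slope (cycles/cm) from a dense grid search of the mean resultant
#' length, refined with [stats::optimize()]; the circular-linear
#' correlation r between the phases and the fitted linear phase variable.
#'
#' Because the slope is *selected* by maximizing the resultant over a
#' grid of candidate slopes, an asymptotic p-value for the resulting
#' correlation is badly anticonservative (the search behaves like a
#' periodogram scan). The p-value is therefore a permutation p on the
#' selection statistic itself: phases are shuffled against positions and
#' the maximal grid resultant recomputed (`n_perm` times, tie-counting).
#'
#' @param positions linear positions, cm.
#' @param phases spike theta phases, radians.
#' @param slope_bound search bound on |slope| in cycles/cm (default 0.05,
#'   i.e. 18 deg/cm).
#' @param min_spikes minimum spike count (default 10); fewer returns
#'   `NULL`.
#' @param n_perm phase permutations for the p-value (default 200).
#' @param seed RNG seed for the permutations.
#' @return list: slope_cyc_per_cm, slope_deg_per_cm, phi0 (phase offset at
#'   x = 0), r, p, n.
#' @export
circular_linear_fit <- function(positions, phases, slope_bound = 0.05,
                                min_spikes = 10, n_perm = 200, seed = 1L) {
  n <- length(positions)
  if (n < min_spikes || length(unique(positions)) < 2) return(NULL)
  grid <- seq(-slope_bound, slope_bound, length.out = 401)
  # M[a, j] = exp(-i * 2 pi * a * x_j); max_a |M z|/n is the selection
  # statistic for phase vector z = exp(i phases)
  M <- exp(-1i * 2 * pi * outer(grid, positions))
  stat <- function(z) max(Mod(M %*% z)) / n
  z_obs <- exp(1i * phases)
  r_grid <- Mod(M %*% z_obs) / n
  a0 <- grid[which.max(r_grid)]
  stepw <- diff(grid[1:2])
  resultant <- function(a)
    Mod(mean(exp(1i * (phases - 2 * pi * a * positions))))
  opt <- stats::optimize(resultant,
                         lower = max(-slope_bound, a0 - 2 * stepw),
                         upper = min(slope_bound, a0 + 2 * stepw),
                         maximum = TRUE, tol = 1e-7)
  a <- opt$maximum
  phi0 <- Arg(mean(exp(1i * (phases - 2 * pi * a * positions))))
  # circular-circular correlation between phase and fitted phase 2*pi*a*x
  theta <- wrap_pi(2 * pi * abs(a) * positions)
  phi_bar <- Arg(mean(exp(1i * phases)))
  theta_bar <- Arg(mean(exp(1i * theta)))
  sp <- sin(phases - phi_bar); st <- sin(theta - theta_bar)
  denom <- sqrt(sum(sp^2) * sum(st^2))
  r <- if (denom > 0) sum(sp * st) / denom else 0
  if (a < 0) r <- -r
  obs <- stat(z_obs)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (stat(z_obs[sample.int(n)]) >= obs) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (n_perm + 1)
  list(slope_cyc_per_cm = a, slope_deg_per_cm = a * 360, phi0 = phi0,
       r = r, p = p, n = n)
}

#' Phase precession of one unit within one spatial field
#'
#' Spikes during locomotion whose linear position falls inside the field
#' are regressed with [circular_linear_fit()]; positions are expressed as
#' within-field travel distance so a negative slope always means the
#' phase advances as the field is crossed, for both travel directions.
#'
#' @param spike_times spike times of the unit, s.
#' @param phase a [theta_phase()] series (reference channel).
#' @param field one element of [detect_fields()].
#' @param linearized a [linearize()] table.
#' @param trajectory trajectory type whose traversals are used.
#' @param min_spikes minimum in-field spikes (default 10).
#' @return the [circular_linear_fit()] result plus `significant`
#'   (p < 0.05), or `NULL` when too few spikes.
#' @export
field_precession <- function(spike_times, phase, field, linearized,
                             trajectory, min_spikes = 10) {
  sel <- linearized$trajectory == trajectory & linearized$speed_cm_s > 5 &
    !is.na(linearized$linear_cm) &
    linearized$linear_cm >= field$start_cm &
    linearized$linear_cm <= field$end_cm
  if (!any(sel)) return(NULL)
  tt <- linearized$time_s[sel]
  dt <- stats::median(diff(linearized$time_s))
  idx <- findInterval(spike_times, tt)
  idx0 <- pmax(idx, 1L)
  keep <- abs(spike_times - tt[idx0]) <= dt
  st <- spike_times[keep]
  if (length(st) < min_spikes) return(NULL)
  lp <- stats::approx(linearized$time_s[sel], linearized$linear_cm[sel],
                      st, rule = 2)$y
  inbound <- grepl("-to-C", trajectory)
  x <- if (inbound) field$end_cm - lp else lp - field$start_cm
  ph <- spike_phases(st, phase)
  fit <- circular_linear_fit(x, ph, min_spikes = min_spikes)
  if (is.null(fit)) return(NULL)
  fit$significant <- !is.na(fit$p) && fit$p < 0.05
  fit
}
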