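## Circular statistics. Only the handful of quantities the pipeline needs:
## circular mean / resultant length, the Rayleigh uniformity test, and the
## circular-linear association used by the phase-precession fit.

#' Circular mean and resultant length
#' @param phases numeric vector of angles in radians.
#' @return list with `mean` (radians in (-pi, pi]) and `r` (mean resultant
#'   length in \[0, 1\]).
#' @export
circ_mean_resultant <- function(phases) {
  z <- mean(exp(1i * phases))
  list(mean = Arg(z), r = Mod(z))
}

#' Rayleigh test of circular uniformity
#'
#' Standard approximation for the p-value of the Rayleigh statistic
#' `Z = n * rbar^2`, accurate for n >= 10.
#'
#' @param phases angles in radians.
#' @return list with `rbar`, `mean`, `p`, `n`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  cm <- circ_mean_resultant(phases)
  Z <- n * cm$r^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  list(rbar = cm$r, mean = cm$mean, p = p, n = n)
}

## Wrap angles into (-pi, pi].
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
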