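## W-track geometry: three reward wells (center C, left L, right R), a
## center stem from C to the choice point (CP), a crossbar, and two side
## arms descending to the side wells. The four trajectory types traverse
## idealized polyline paths; linear position is arclength along the path
## with 0 at the center well, increasing toward the side well for both
## travel directions.

TRAJECTORIES <- c("C-to-L", "L-to-C", "C-to-R", "R-to-C")

#' Construct a W-track maze geometry
#'
#' @param stem_cm length of the center stem (center well to choice point).
#' @param cross_cm half-width of the crossbar (choice point to arm top).
#' @param arm_cm length of each side arm (arm top to side well).
#' @return object of class `maze_geometry`: well coordinates, idealized
#'   path polylines for the four trajectory types, path length and
#'   choice-point arclength (all cm).
#' @export
w_maze <- function(stem_cm = 80, cross_cm = 40, arm_cm = 80) {
  stopifnot(stem_cm > 0, cross_cm > 0, arm_cm > 0)
  C <- c(0, 0); CP <- c(0, stem_cm)
  Ltop <- c(-cross_cm, stem_cm); Rtop <- c(cross_cm, stem_cm)
  L <- c(-cross_cm, stem_cm - arm_cm); R <- c(cross_cm, stem_cm - arm_cm)
  out_l <- rbind(C, CP, Ltop, L)
  out_r <- rbind(C, CP, Rtop, R)
  paths <- list(
    `C-to-L` = out_l, `L-to-C` = out_l,
    `C-to-R` = out_r, `R-to-C` = out_r
  )
  structure(list(
    wells = list(C = C, L = L, R = R),
    paths = paths,
    stem_cm = stem_cm,
    path_length_cm = stem_cm + cross_cm + arm_cm,
    cp_cm = stem_cm
  ), class = "maze_geometry")
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat("W-track geometry: stem", x$stem_cm, "cm, path length",
      x$path_length_cm, "cm, choice point at", x$cp_cm, "cm\n")
  invisible(x)
}

## Cumulative arclength of polyline vertices.
path_cumlen <- function(p) {
  d <- sqrt(rowSums(diff(p)^2))
  c(0, cumsum(d))
}

## (x, y) on the polyline at arclength s (clamped to the path).
path_point_at <- function(p, s) {
  cl <- path_cumlen(p)
  s <- pmin(pmax(s, 0), cl[length(cl)])
  seg <- pmin(findInterval(s, cl, rightmost.closed = TRUE),
              nrow(p) - 1L)
  frac <- (s - cl[seg]) / (cl[seg + 1L] - cl[seg])
  p[seg, , drop = FALSE] + (p[seg + 1L, , drop = FALSE] - p[seg, , drop = FALSE]) * frac
}

## Project 2D points onto the polyline: per-sample arclength of the
## nearest point, plus the orthogonal distance.
project_to_path <- function(xy, p) {
  cl <- path_cumlen(p)
  n <- nrow(xy)
  best_d2 <- rep(Inf, n)
  best_s <- rep(NA_real_, n)
  for (seg in seq_len(nrow(p) - 1L)) {
    a <- p[seg, ]; b <- p[seg + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((xy[, 1] - a[1]) * ab[1] + (xy[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
    d2 <- (xy[, 1] - px)^2 + (xy[, 2] - py)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- cl[seg] + t[upd] * sqrt(len2)
  }
  list(arclength = best_s, dist = sqrt(best_d2))
}
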