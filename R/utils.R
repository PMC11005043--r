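## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded generator calls do
#' not disturb the caller's random stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

## Derive a child seed from a base seed and an index, kept below 2^31
## (double arithmetic stays exact well beyond these magnitudes).
childSeed <- function(seed, index) {
  (as.numeric(seed) * 1009 + as.numeric(index) * 9973) %% 2147483547
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

crossv <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## Dihedral angle (degrees) defined by four points (rows or vectors).
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- crossv(b1, b2); n2 <- crossv(b2, b3)
  m1 <- crossv(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

## Place a new atom D given positions A, B, C, the bond length C-D, the
## angle B-C-D (degrees) and the torsion A-B-C-D (degrees).  Standard
## internal-to-Cartesian (NeRF) construction.
placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- unitv(c - b)
  n <- unitv(crossv(b - a, bc))
  m <- cbind(bc, crossv(n, bc), n)
  as.numeric(m %*% d2 + c)
}

## Angle at vertex b (degrees) of the triangle a-b-c.
vecAngle <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

## Population standard deviation (ddof = 0).
sdPop <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

## Fisher-Pearson moment skewness and excess kurtosis.
momentSkewness <- function(x) {
  m <- mean(x); s <- x - m
  m2 <- mean(s^2)
  if (m2 < .Machine$double.eps) return(NaN)
  mean(s^3) / m2^1.5
}

momentKurtosis <- function(x) {
  m <- mean(x); s <- x - m
  m2 <- mean(s^2)
  if (m2 < .Machine$double.eps) return(NaN)
  mean(s^4) / m2^2 - 3
}

stopifneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(what, " must be finite and non-negative")
  invisible(x)
}
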