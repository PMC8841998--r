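# Akima-family local cubic interpolation.
#
# Implemented in-package because the calibration fit needs (a) the modified
# ("makima") slope rule that tempers overshoot between unevenly spaced
# calibrators — important around a non-monotone hook apex — and (b) direct
# access to the Hermite representation for root finding; pracma exposes only
# point evaluation of the original Akima rule (used as a cross-check).

# Node slopes for Akima interpolation. x strictly increasing, length >= 5.
# method "akima": Akima's 1970 weights w_left = |m[i+1] - m[i]|,
# w_right = |m[i-1] - m[i-2]|. method "makima": adds |m[i+1] + m[i]|/2 terms
# so that distant-segment agreement damps the slope (MATLAB's variant).
#' @noRd
akima_slopes <- function(x, y, method = c("makima", "akima")) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(n >= 5, length(y) == n, all(diff(x) > 0))
  m <- diff(y) / diff(x)
  # quadratic end extension of segment slopes (Akima's rule)
  m <- c(3 * m[1] - 2 * m[2], 2 * m[1] - m[2], m,
         2 * m[n - 1] - m[n - 2], 3 * m[n - 1] - 2 * m[n - 2])
  # node i has left segment m[i+1], right segment m[i+2] in padded indexing
  ml2 <- m[seq_len(n)]        # m[i-2]
  ml1 <- m[seq_len(n) + 1]    # m[i-1] (left)
  mr1 <- m[seq_len(n) + 2]    # m[i]   (right)
  mr2 <- m[seq_len(n) + 3]    # m[i+1]
  w1 <- abs(mr2 - mr1)        # weight on the LEFT slope
  w2 <- abs(ml1 - ml2)        # weight on the RIGHT slope
  if (method == "makima") {
    w1 <- w1 + abs(mr2 + mr1) / 2
    w2 <- w2 + abs(ml1 + ml2) / 2
  }
  t <- (w1 * ml1 + w2 * mr1) / (w1 + w2)
  flat <- !is.finite(t) | (w1 + w2) == 0
  t[flat] <- ((ml1 + mr1) / 2)[flat]
  t
}

# Vectorised piecewise cubic Hermite evaluation with linear continuation of
# the end slopes outside [min(x), max(x)].
#' @noRd
hermite_eval <- function(x, y, d, xi) {
  n <- length(x)
  i <- findInterval(xi, x, all.inside = TRUE)
  h <- x[i + 1] - x[i]
  s <- (xi - x[i]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  out <- h00 * y[i] + h10 * h * d[i] + h01 * y[i + 1] + h11 * h * d[i + 1]
  lo <- xi < x[1]
  hi <- xi > x[n]
  out[lo] <- y[1] + d[1] * (xi[lo] - x[1])
  out[hi] <- y[n] + d[n] * (xi[hi] - x[n])
  out
}
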