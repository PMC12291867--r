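# Monotone I-spline basis (integrated M-splines, Ramsay 1988 form).
# Order-2 M-splines are piecewise linear, so each I-spline is a piecewise
# quadratic rising from 0 at its support start to 1 at the top knot —
# non-negative coefficients then guarantee a monotone fitted transform.

# M-spline recursion; t = full knot vector, i = basis index, k = order
mspline_eval <- function(x, t, i, k) {
  if (k == 1) {
    den <- t[i + 1] - t[i]
    if (den <= 0) return(numeric(length(x)))
    top <- max(t)
    inside <- x >= t[i] & (x < t[i + 1] | (x == top & t[i + 1] == top))
    return(ifelse(inside, 1 / den, 0))
  }
  den <- (k - 1) * (t[i + k] - t[i])
  if (den <= 0) return(numeric(length(x)))
  k * ((x - t[i]) * mspline_eval(x, t, i, k - 1) +
         (t[i + k] - x) * mspline_eval(x, t, i + 1, k - 1)) / den
}

#' Monotone I-spline basis over a predictor's observed range
#'
#' Builds `n_splines` integrated M-splines of order 2 with knots at
#' quantiles of the supplied values (default: evenly spaced probabilities,
#' i.e. min / median / max for the default 3 splines). Each basis function
#' is 0 at and below the start of its support, 1 at and above the top knot,
#' and non-decreasing in between; evaluation clamps outside the knot range.
#'
#' @param values Numeric values whose quantiles position the knots (at
#'   least 3 distinct).
#' @param n_splines Number of basis functions (default 3).
#' @param knot_quantiles Probabilities of the knot quantiles; default
#'   `seq(0, 1, length.out = n_splines)`.
#' @return Object of class `ispline_basis` with `$knots`, `$order`,
#'   `$n_splines` and an evaluator usable via [ispline_evaluate()].
#' @export
ispline_basis <- function(values, n_splines = 3, knot_quantiles = NULL) {
  if (length(unique(values)) < 3)
    abort("degenerate predictor: fewer than 3 distinct values")
  if (n_splines < 2) abort("need at least 2 basis functions")
  if (is.null(knot_quantiles))
    knot_quantiles <- seq(0, 1, length.out = n_splines)
  order <- 2L
  kq <- sort(knot_quantiles)
  knots <- as.numeric(quantile(values, kq, type = 7))
  if (knots[1] >= knots[length(knots)])
    abort("degenerate knot range")
  # de-duplicate interior knots that collapse onto each other
  knots <- knots[!duplicated(knots)]
  n <- as.integer(order + (length(knots) - 2))
  a <- knots[1]; b <- knots[length(knots)]
  t_full <- c(rep(a, order), knots[-c(1, length(knots))], rep(b, order))
  structure(list(knots = knots, order = order, n_splines = n,
                 t_full = t_full),
            class = "ispline_basis")
}

#' Evaluate an I-spline basis
#'
#' @param basis An [ispline_basis()].
#' @param x Values at which to evaluate (clamped to the knot range).
#' @return Matrix `length(x)` x `n_splines`; column i is basis function i.
#' @export
ispline_evaluate <- function(basis, x) {
  t_raw <- basis$t_full
  k <- basis$order
  n <- basis$n_splines
  b_top <- max(t_raw)
  a_bot <- min(t_raw)
  xc <- pmin(pmax(x, a_bot), b_top)
  t_pad <- c(t_raw, b_top)           # t[m + k + 1] defined up to m = n
  j <- findInterval(xc, t_raw)       # rightmost index with t[j] <= x
  j <- pmin(pmax(j, k), n)           # clamp to the nontrivial intervals
  out <- matrix(0, length(x), n)
  for (i in seq_len(n)) {
    col <- numeric(length(x))
    col[j >= i + k] <- 1            # fully past the support
    mid <- which(j >= i & j < i + k)
    if (length(mid)) {
      acc <- numeric(length(mid))
      for (m in i:min(i + k - 1, n)) {  # m ranges i..j; j < i+k here
        cm <- (t_pad[m + k + 1] - t_pad[m]) / (k + 1)
        if (cm > 0) {
          v <- mspline_eval(xc[mid], t_pad, m, k + 1) * cm
          v[j[mid] < m] <- 0
          acc <- acc + v
        }
      }
      col[mid] <- acc
    }
    out[, i] <- pmin(pmax(col, 0), 1)
  }
  out
}
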