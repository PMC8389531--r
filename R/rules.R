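#' Nested Clenshaw-Curtis quadrature rule on the unit interval
#'
#' Builds the one-dimensional Clenshaw-Curtis rule of a given level with the
#' nested growth \eqn{m(0) = 1}, \eqn{m(l) = 2^l + 1}. Points are the
#' cosine-spaced abscissae mapped to \eqn{[0, 1]}; weights are normalized to a
#' probability measure (they sum to 1), so the rule approximates expectations
#' under the uniform distribution on the unit interval. The level-0 rule is
#' the single midpoint with weight 1. Rules are nested: every point of level
#' \eqn{l} reappears, bitwise identically, in level \eqn{l + 1}, which is what
#' makes sparse-grid combinations of these rules reuse model evaluations.
#'
#' @param level Non-negative integer quadrature level.
#' @return An object of class \code{cc_rule}: a list with \code{level},
#'   \code{points} (increasing, symmetric about 0.5), \code{weights}
#'   (summing to 1), \code{size}, and barycentric weights \code{bary} used by
#'   \code{\link{lagrange_basis}}.
#' @examples
#' clenshaw_curtis_rule(0)$points   # 0.5
#' clenshaw_curtis_rule(1)$weights  # 1/6, 2/3, 1/6
#' @export
clenshaw_curtis_rule <- function(level) {
  if (length(level) != 1L || is.na(level) || level < 0 || level != round(level))
    stop("'level' must be a single non-negative integer", call. = FALSE)
  level <- as.integer(level)
  key <- as.character(level)
  cached <- .rule_cache[[key]]
  if (!is.null(cached)) return(cached)

  if (level == 0L) {
    rule <- structure(
      list(level = 0L, points = 0.5, weights = 1.0, size = 1L, bary = 1.0),
      class = "cc_rule")
    .rule_cache[[key]] <- rule
    return(rule)
  }

  n <- as.integer(2^level)
  m <- n + 1L
  # lower half from exact dyadic fractions, upper half mirrored so that the
  # point set is exactly symmetric and exactly nested across levels
  x <- numeric(m)
  x[1L] <- 0
  for (j in seq_len(n %/% 2L - 1L)) x[j + 1L] <- (1 - cospi(j / n)) / 2
  x[n %/% 2L + 1L] <- 0.5
  x[(n %/% 2L + 2L):m] <- 1 - rev(x[seq_len(n %/% 2L)])

  bary <- barycentric_weights(x)
  w <- cc_weights_from_basis(x, bary)

  rule <- structure(
    list(level = level, points = x, weights = w, size = m, bary = bary),
    class = "cc_rule")
  .rule_cache[[key]] <- rule
  rule
}

.rule_cache <- new.env(parent = emptyenv())

## Barycentric interpolation weights 1 / prod_{k != j} (x_j - x_k), rescaled
## for numerical range (any common factor cancels in the second barycentric
## form).
barycentric_weights <- function(x) {
  m <- length(x)
  bw <- numeric(m)
  for (j in seq_len(m)) {
    d <- x[j] - x[-j]
    # scale each factor by 4 to keep products away from underflow at high m
    bw[j] <- 1 / prod(4 * d)
  }
  bw / max(abs(bw))
}

## Quadrature weights as exact integrals of the Lagrange cardinal basis over
## [0, 1] (Gauss-Legendre of sufficient order), then symmetrized. This makes
## the rule exact for all polynomials up to degree m - 1 by construction.
cc_weights_from_basis <- function(x, bary) {
  m <- length(x)
  gq <- pracma::gaussLegendre(m + 2L, 0, 1)
  B <- lagrange_basis_all(x, bary, gq$x)     # length(gq$x) x m
  w <- as.numeric(crossprod(B, gq$w))
  (w + rev(w)) / 2
}

## All m cardinal polynomials evaluated at the vector xs (rows = xs).
lagrange_basis_all <- function(points, bary, xs) {
  m <- length(points)
  out <- matrix(0, nrow = length(xs), ncol = m)
  for (r in seq_along(xs)) {
    d <- xs[r] - points
    hit <- which(d == 0)
    if (length(hit) > 0L) {
      out[r, hit[1L]] <- 1
    } else {
      t <- bary / d
      out[r, ] <- t / sum(t)
    }
  }
  out
}

#' Lagrange cardinal polynomial of a 1D rule
#'
#' Evaluates the \code{j}-th Lagrange cardinal polynomial of a
#' \code{\link{clenshaw_curtis_rule}} at \code{x}, using the numerically
#' stable second barycentric form. The cardinal property holds exactly at the
#' rule's own points: the value is 1 at point \code{j} and 0 at every other
#' collocation point.
#'
#' @param rule A \code{cc_rule}.
#' @param j Point index, 1-based, \code{1 <= j <= rule$size}.
#' @param x Evaluation point(s) in \eqn{[0, 1]}; vectorized.
#' @return Numeric vector of basis values, same length as \code{x}.
#' @export
lagrange_basis <- function(rule, j, x) {
  stopifnot(inherits(rule, "cc_rule"))
  if (length(j) != 1L || is.na(j) || j < 1L || j > rule$size || j != round(j))
    stop("'j' must be an integer in 1..", rule$size, call. = FALSE)
  lagrange_basis_all(rule$points, rule$bary, x)[, as.integer(j)]
}
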