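#' Tensor-product collocation grid
#'
#' Builds the full tensor product of one-dimensional Clenshaw-Curtis rules
#' with per-dimension levels given by a multi-index. The number of points is
#' the product of the 1D sizes \eqn{m_i}, which is what makes isotropic
#' tensor grids infeasible beyond a handful of inputs and motivates the
#' sparse combination of \code{\link{sparse_grid_plan}}.
#'
#' @param index Integer vector of non-negative quadrature levels, one per
#'   input dimension.
#' @return A list with \code{index}, \code{points} (a matrix with one row per
#'   collocation point on the unit hypercube; the first dimension varies
#'   fastest), and \code{weights} (product-rule weights summing to 1).
#' @examples
#' nrow(tensor_grid(c(2, 2))$points)  # 25
#' @export
tensor_grid <- function(index) {
  index <- check_index(index)
  rules <- lapply(index, clenshaw_curtis_rule)
  pts <- as.matrix(expand.grid(lapply(rules, `[[`, "points"),
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  w <- Reduce(function(a, b) kronecker(b, a), lapply(rules, `[[`, "weights"))
  list(index = index, points = pts, weights = as.numeric(w))
}

#' Combination-technique coefficients of an admissible index set
#'
#' For each member \eqn{l} of a downward-closed index set \eqn{\Lambda},
#' computes \eqn{c_l = \sum_{z \in \{0,1\}^d,\, l + z \in \Lambda} (-1)^{|z|}}.
#' The resulting signed integer coefficients express the sparse-grid
#' interpolant as a telescoping linear combination of tensor-product
#' interpolants; they always sum to 1.
#'
#' @param index_set A list of multi-indices forming an admissible
#'   (downward-closed) set.
#' @return A named integer vector, one entry per member, named by the
#'   comma-separated multi-index.
#' @export
combination_coefficients <- function(index_set) {
  index_set <- check_index_set(index_set)
  if (!is_admissible(index_set))
    stop("'index_set' is not admissible (not downward closed)", call. = FALSE)
  keys <- vapply(index_set, index_key, character(1L))
  out <- integer(length(index_set))
  names(out) <- keys
  for (n in seq_along(index_set)) {
    l <- index_set[[n]]
    # z_i = 1 requires l + e_i in Lambda (downward closure), so only those
    # dimensions can contribute; the enumeration stays tiny for sparse sets
    active <- which(vapply(seq_along(l), function(i) {
      li <- l; li[i] <- li[i] + 1L
      index_key(li) %in% keys
    }, logical(1L)))
    cc <- 1L  # z = 0 term
    if (length(active) > 0L) {
      for (mask in seq_len(2L^length(active) - 1L)) {
        z <- as.integer(intToBits(mask))[seq_along(active)]
        li <- l
        li[active] <- li[active] + z
        if (index_key(li) %in% keys) cc <- cc + (-1L)^sum(z)
      }
    }
    out[n] <- cc
  }
  out
}

#' Sparse-grid sampling plan from an admissible index set
#'
#' Assembles the combination-technique plan for an admissible set of
#' quadrature-order multi-indices: the signed coefficients and the
#' deduplicated union of all member tensor grids. Because the 1D rules are
#' nested, coinciding points across member grids are bitwise identical and
#' deduplication is exact.
#'
#' @inheritParams combination_coefficients
#' @return An object of class \code{sparse_grid_plan}: a list with
#'   \code{dimension}, \code{index_set}, \code{coefficients} (named integer
#'   vector from \code{\link{combination_coefficients}}), and
#'   \code{unique_points} (matrix, one row per distinct collocation point).
#' @export
sparse_grid_plan <- function(index_set) {
  index_set <- check_index_set(index_set)
  coef <- combination_coefficients(index_set)
  pts <- do.call(rbind, lapply(index_set, function(l) tensor_grid(l)$points))
  keys <- point_keys(pts)
  keep <- !duplicated(keys)
  up <- pts[keep, , drop = FALSE]
  rownames(up) <- keys[keep]
  structure(
    list(dimension = length(index_set[[1L]]),
         index_set = index_set,
         coefficients = coef,
         unique_points = up),
    class = "sparse_grid_plan")
}

#' @export
print.sparse_grid_plan <- function(x, ...) {
  cat("Sparse-grid plan: d =", x$dimension,
      "|", length(x$index_set), "multi-indices |",
      nrow(x$unique_points), "unique points\n")
  invisible(x)
}

## Tensor-product Lagrange interpolant of one member grid at a single point.
tensor_interpolant_at <- function(index, values, x) {
  rules <- lapply(index, clenshaw_curtis_rule)
  grid <- tensor_grid(index)
  f <- lookup_values(values, grid$points)
  basis <- lapply(seq_along(rules), function(i)
    as.numeric(lagrange_basis_all(rules[[i]]$points, rules[[i]]$bary, x[i])))
  w <- Reduce(function(a, b) kronecker(b, a), basis)
  sum(w * f)
}

#' Evaluate the combination-technique interpolant
#'
#' Evaluates the sparse-grid surrogate
#' \eqn{\tilde e(x) = \sum_{l \in \Lambda} c_l\, p_l(x)}, where \eqn{p_l} is
#' the tensor-product Lagrange interpolant of member grid \eqn{l}. The
#' surrogate reproduces the stored value exactly at every collocation point
#' and, because the coefficients sum to 1, reproduces constants everywhere.
#'
#' @param plan A \code{\link{sparse_grid_plan}}.
#' @param values Named numeric vector mapping collocation points to model
#'   values; names are the point keys used in
#'   \code{rownames(plan$unique_points)} (as produced by
#'   \code{\link{campaign_values}} or \code{\link{plan_value_map}}).
#' @param x A point in the unit hypercube (numeric vector of length
#'   \code{plan$dimension}) or a matrix of such rows.
#' @return Numeric vector of surrogate values, one per row of \code{x}.
#' @export
interpolate_plan <- function(plan, values, x) {
  stopifnot(inherits(plan, "sparse_grid_plan"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != plan$dimension)
    stop("'x' must have ", plan$dimension, " columns", call. = FALSE)
  active <- which(plan$coefficients != 0L)
  out <- numeric(nrow(x))
  for (r in seq_len(nrow(x))) {
    acc <- 0
    for (n in active) {
      acc <- acc + plan$coefficients[[n]] *
        tensor_interpolant_at(plan$index_set[[n]], values, x[r, ])
    }
    out[r] <- acc
  }
  out
}

#' Mean and variance of the sparse-grid surrogate under uniform inputs
#'
#' Computes the first two moments of the combination-technique surrogate with
#' respect to the uniform probability measure on the unit hypercube. The mean
#' applies the signed combination of product quadrature rules to the stored
#' values; the variance applies the same quadrature to the squared surrogate
#' (whose values at the collocation points are the squared model values) and
#' subtracts the squared mean, clipping small negative round-off at zero.
#'
#' @inheritParams interpolate_plan
#' @return A list with \code{mean} and \code{variance}.
#' @export
plan_moments <- function(plan, values) {
  stopifnot(inherits(plan, "sparse_grid_plan"))
  m1 <- 0
  m2 <- 0
  for (n in which(plan$coefficients != 0L)) {
    grid <- tensor_grid(plan$index_set[[n]])
    f <- lookup_values(values, grid$points)
    cl <- plan$coefficients[[n]]
    m1 <- m1 + cl * sum(grid$weights * f)
    m2 <- m2 + cl * sum(grid$weights * f^2)
  }
  list(mean = m1, variance = max(m2 - m1^2, 0))
}

#' Build a value map for a plan by evaluating a function on the unit cube
#'
#' Convenience wrapper: evaluates \code{fn} at every unique collocation point
#' of the plan and returns the named value vector expected by
#' \code{\link{interpolate_plan}} and \code{\link{plan_moments}}.
#'
#' @inheritParams interpolate_plan
#' @param fn Function taking a numeric vector (one unit-cube point) and
#'   returning a scalar.
#' @return Named numeric vector keyed by collocation point.
#' @export
plan_value_map <- function(plan, fn) {
  stopifnot(inherits(plan, "sparse_grid_plan"))
  pts <- plan$unique_points
  vals <- apply(pts, 1L, fn)
  names(vals) <- rownames(pts)
  vals
}

#' Serialize a sparse-grid plan to JSON
#'
#' Writes \code{dimension}, the index set, the combination coefficients and
#' the unique collocation points (row-major) to a JSON file that
#' \code{\link{read_plan}} round-trips losslessly.
#'
#' @inheritParams interpolate_plan
#' @param path Output file path.
#' @param input_names Optional character vector of input names stored
#'   alongside the points.
#' @return \code{path}, invisibly.
#' @export
write_plan <- function(plan, path, input_names = NULL) {
  stopifnot(inherits(plan, "sparse_grid_plan"))
  obj <- list(
    dimension = plan$dimension,
    index_set = lapply(plan$index_set, as.integer),
    coefficients = as.list(plan$coefficients),
    points = apply(plan$unique_points, 1L, as.numeric, simplify = FALSE),
    input_names = input_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a sparse-grid plan from JSON
#'
#' @param path File written by \code{\link{write_plan}}.
#' @return A \code{\link{sparse_grid_plan}}.
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  index_set <- lapply(obj$index_set, function(l) as.integer(unlist(l)))
  sparse_grid_plan(index_set)
}
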