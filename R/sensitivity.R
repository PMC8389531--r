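## Shifted Legendre polynomials, orthonormal under the uniform measure on
## [0, 1]: phi_k(x) = sqrt(2k + 1) P_k(2x - 1). Returns a matrix with one
## column per degree 0..kmax.
legendre_matrix <- function(x, kmax) {
  n <- length(x)
  t <- 2 * x - 1
  P <- matrix(0, nrow = n, ncol = kmax + 1L)
  P[, 1L] <- 1
  if (kmax >= 1L) P[, 2L] <- t
  if (kmax >= 2L) {
    for (k in 2:kmax)
      P[, k + 1L] <- ((2 * k - 1) * t * P[, k] - (k - 1) * P[, k - 1L]) / k
  }
  sweep(P, 2L, sqrt(2 * seq(0L, kmax) + 1), `*`)
}

## 1D transfer matrix T[j, k] = int_0^1 L_j(x) phi_k(x) dx for one rule:
## projects the Lagrange cardinal basis onto the orthonormal Legendre basis.
## Gauss-Legendre quadrature of order > degree(L_j * phi_k) makes it exact.
rule_transfer_matrix <- function(rule) {
  m <- rule$size
  gq <- pracma::gaussLegendre(m + 2L, 0, 1)
  B <- lagrange_basis_all(rule$points, rule$bary, gq$x)   # nq x m
  Phi <- legendre_matrix(gq$x, m - 1L)                    # nq x m
  crossprod(B * gq$w, Phi)                                # m x m
}

## Multiply array mode `mode` by t(M): contracts grid index j_i against the
## transfer matrix to produce degree index k_i.
mode_multiply <- function(arr, M, mode) {
  dims <- dim(arr)
  d <- length(dims)
  perm <- c(mode, setdiff(seq_len(d), mode))
  a <- aperm(arr, perm)
  mat <- matrix(a, nrow = dims[mode])
  out <- crossprod(M, mat)                                # K x rest
  newdims <- c(ncol(M), dims[-mode])
  out <- array(out, dim = newdims)
  aperm(out, order(perm))
}

#' Convert the sparse-grid surrogate to an orthonormal Legendre expansion
#'
#' Projects each accepted tensor-product Lagrange interpolant onto the
#' tensor basis of shifted Legendre polynomials orthonormal under the
#' uniform measure on the unit hypercube, and combines the projections with
#' the combination-technique coefficients. Since each member interpolant is
#' a polynomial of per-dimension degree \eqn{m_i - 1}, the projection is
#' exact and the expansion evaluates identically to the interpolant. The
#' squared coefficients of the result carry the variance decomposition used
#' by \code{\link{sobol_indices}}.
#'
#' @inheritParams interpolate_plan
#' @return A named numeric vector of expansion coefficients; names are
#'   comma-separated per-dimension polynomial degrees (degree 0 is the
#'   mean term).
#' @export
to_orthogonal_expansion <- function(plan, values) {
  stopifnot(inherits(plan, "sparse_grid_plan"))
  acc <- new.env(parent = emptyenv())
  for (n in which(plan$coefficients != 0L)) {
    l <- plan$index_set[[n]]
    cl <- plan$coefficients[[n]]
    rules <- lapply(l, clenshaw_curtis_rule)
    m <- vapply(rules, `[[`, integer(1L), "size")
    grid <- tensor_grid(l)
    f <- lookup_values(values, grid$points)
    arr <- array(f, dim = m)
    for (i in seq_along(l))
      arr <- mode_multiply(arr, rule_transfer_matrix(rules[[i]]), i)
    degs <- as.matrix(expand.grid(lapply(m, function(mi) seq(0L, mi - 1L)),
                                  KEEP.OUT.ATTRS = FALSE))
    vals <- as.numeric(arr)
    for (r in seq_along(vals)) {
      k <- index_key(degs[r, ])
      old <- acc[[k]]
      acc[[k]] <- if (is.null(old)) cl * vals[r] else old + cl * vals[r]
    }
  }
  keys <- ls(acc)
  out <- vapply(keys, function(k) acc[[k]], numeric(1L))
  names(out) <- keys
  out
}

#' Evaluate an orthonormal Legendre expansion
#'
#' @param expansion Coefficients from \code{\link{to_orthogonal_expansion}}.
#' @param x Unit-cube point (vector) or matrix of rows.
#' @return Numeric vector of expansion values.
#' @export
evaluate_expansion <- function(expansion, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  degs <- do.call(rbind, lapply(names(expansion), key_to_index))
  kmax <- max(degs)
  out <- numeric(nrow(x))
  for (r in seq_len(nrow(x))) {
    Phi <- legendre_matrix(x[r, ], kmax)   # d x (kmax+1)
    basis <- vapply(seq_along(expansion), function(j) {
      prod(Phi[cbind(seq_len(ncol(degs)), degs[j, ] + 1L)])
    }, numeric(1L))
    out[r] <- sum(expansion * basis)
  }
  out
}

#' Sobol sensitivity indices from an orthonormal expansion
#'
#' By Parseval's identity the total variance of the surrogate is the sum of
#' squared expansion coefficients over all nonzero degree tuples; the
#' partial variance \eqn{D_u} of an input subset \eqn{u} collects the tuples
#' whose support (set of dimensions with nonzero degree) equals \eqn{u}; and
#' the Sobol index is \eqn{S_u = D_u / D}. Indices over all observed subsets
#' and the first-order vector are reported. A constant surrogate has zero
#' variance and its indices are flagged undefined rather than returned as
#' \code{NaN}.
#'
#' @inheritParams evaluate_expansion
#' @return An object of class \code{sobol_report}: list with
#'   \code{total_variance}, \code{partial_variances} (named by subset, e.g.
#'   \code{"1"}, \code{"1,3"}), \code{indices}, \code{first_order} (length-d
#'   vector) and \code{defined}.
#' @export
sobol_indices <- function(expansion) {
  degs <- do.call(rbind, lapply(names(expansion), key_to_index))
  d <- ncol(degs)
  nz <- rowSums(degs) > 0L
  D <- sum(expansion[nz]^2)
  if (!any(nz)) {
    partial <- stats::setNames(numeric(0L), character(0L))
  } else {
    support <- vapply(seq_len(nrow(degs)), function(r)
      paste(which(degs[r, ] > 0L), collapse = ","), character(1L))
    partial <- tapply(expansion[nz]^2, support[nz], sum)
    partial <- partial[order(nchar(names(partial)), names(partial))]
    partial <- stats::setNames(as.numeric(partial), names(partial))
  }
  # variances at the round-off floor of the mean term are indistinguishable
  # from a constant surrogate
  zero_key <- index_key(rep(0L, d))
  a0 <- if (zero_key %in% names(expansion)) expansion[[zero_key]] else 0
  defined <- D > (1e-10 * max(1, abs(a0)))^2
  indices <- if (defined) partial / D else partial * NA_real_
  first <- numeric(d)
  if (defined) {
    for (i in seq_len(d)) {
      k <- as.character(i)
      if (k %in% names(indices)) first[i] <- indices[[k]]
    }
  } else first[] <- NA_real_
  structure(list(total_variance = D,
                 partial_variances = stats::setNames(as.numeric(partial),
                                                    names(partial)),
                 indices = indices,
                 first_order = first,
                 defined = defined),
            class = "sobol_report")
}

#' @export
print.sobol_report <- function(x, ...) {
  if (!x$defined) {
    cat("Sobol report: constant surrogate, indices undefined\n")
    return(invisible(x))
  }
  cat("Sobol report: total variance", format(x$total_variance, digits = 6), "\n")
  ord <- order(x$indices, decreasing = TRUE)
  show <- utils::head(ord, 10L)
  for (i in show)
    cat(sprintf("  S_{%s} = %.4f\n", names(x$indices)[i], x$indices[i]))
  invisible(x)
}

#' Write a Sobol report to JSON and CSV
#'
#' @param report A \code{\link{sobol_indices}} result.
#' @param json_path,csv_path Output paths; \code{NULL} skips that format.
#'   The CSV has columns \code{subset} and \code{index}, sorted by index
#'   descending.
#' @return Invisibly, the report.
#' @export
write_sobol_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "sobol_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(total_variance = report$total_variance,
           defined = report$defined,
           indices = as.list(report$indices),
           partial_variances = as.list(report$partial_variances),
           first_order = report$first_order),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    df <- data.frame(subset = names(report$indices),
                     index = as.numeric(report$indices))
    df <- df[order(-df$index), ]
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(report)
}
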