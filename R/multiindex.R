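#' Forward neighbors of a quadrature-order multi-index
#'
#' The forward neighbors of \eqn{l} are \eqn{\{l + e_i : 1 \le i \le d\}},
#' one per input dimension; they are the candidate refinements the adaptive
#' sampler may evaluate next.
#'
#' @param l Integer vector of non-negative quadrature orders.
#' @return A list of integer vectors, one per dimension.
#' @export
forward_neighbors <- function(l) {
  l <- check_index(l)
  lapply(seq_along(l), function(i) { l[i] <- l[i] + 1L; l })
}

#' Backward neighbors of a quadrature-order multi-index
#'
#' The backward neighbors of \eqn{l} are \eqn{\{l - e_i : l_i > 0\}}; the
#' zero index has none.
#'
#' @inheritParams forward_neighbors
#' @return A list of integer vectors (possibly empty).
#' @export
backward_neighbors <- function(l) {
  l <- check_index(l)
  pos <- which(l > 0L)
  lapply(pos, function(i) { l[i] <- l[i] - 1L; l })
}

#' Is a multi-index set admissible (downward closed)?
#'
#' A set of quadrature-order multi-indices is admissible when every backward
#' neighbor of every member is itself a member. Admissibility is what makes
#' the combination-technique coefficients well defined, so the sparse-grid
#' constructors refuse non-admissible sets.
#'
#' @param index_set A list of integer vectors, all of the same length.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
is_admissible <- function(index_set) {
  index_set <- check_index_set(index_set)
  keys <- vapply(index_set, index_key, character(1L))
  for (l in index_set) {
    for (b in backward_neighbors(l)) {
      if (!(index_key(b) %in% keys)) return(FALSE)
    }
  }
  TRUE
}

check_index <- function(l) {
  if (length(l) < 1L || anyNA(l) || any(l < 0) || any(l != round(l)))
    stop("a multi-index must be a vector of non-negative integers", call. = FALSE)
  as.integer(l)
}

check_index_set <- function(index_set) {
  if (!is.list(index_set) || length(index_set) == 0L)
    stop("'index_set' must be a non-empty list of multi-indices", call. = FALSE)
  index_set <- lapply(index_set, check_index)
  d <- unique(lengths(index_set))
  if (length(d) != 1L)
    stop("all multi-indices must have the same dimension", call. = FALSE)
  index_set
}
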