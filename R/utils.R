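# Internal helpers shared across modules.

## Canonical string key for a point in the unit hypercube. Nested
## Clenshaw-Curtis abscissae are generated from dyadic fractions j/2^l, so
## coinciding points across levels are bitwise-identical doubles and %.17g
## round-trips them exactly; no tolerance is needed for deduplication.
point_key <- function(x) paste(sprintf("%.17g", x), collapse = "|")

point_keys <- function(points) {
  apply(points, 1L, point_key)
}

## Canonical string key for a quadrature-order multi-index.
index_key <- function(l) paste(as.integer(l), collapse = ",")

key_to_index <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All randomness in the package flows through explicit integer seeds.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Look up stored model values for a matrix of points; error on gaps.
lookup_values <- function(values, points) {
  keys <- point_keys(points)
  miss <- setdiff(keys, names(values))
  if (length(miss) > 0L)
    stop("missing model values for ", length(miss), " collocation point(s), e.g. ",
         miss[[1L]], call. = FALSE)
  unname(values[keys])
}
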