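## Validate an evaluation table: every configuration must carry the same
## seed list and (config_id, seed) pairs must be unique.
check_evaluation_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("config_id", "seed", "energy") %in% names(table)))
  if (anyDuplicated(table[, c("config_id", "seed")]))
    stop("duplicate (config_id, seed) pairs in evaluation table", call. = FALSE)
  seeds_by_cfg <- split(table$seed, table$config_id)
  ref <- sort(seeds_by_cfg[[1L]])
  ok <- vapply(seeds_by_cfg, function(s) identical(sort(s), ref), logical(1L))
  if (!all(ok))
    stop("ragged seed coverage: every configuration needs the same seed list",
         call. = FALSE)
  invisible(table)
}

#' Probability box of per-seed empirical cdfs
#'
#' For each replica seed, forms the empirical cdf of the energies over all
#' parametric configurations, then takes the pointwise minimum and maximum
#' over seeds. The band between the two envelopes is the probability box:
#' its slant reflects parametric (epistemic) spread while its horizontal
#' width reflects seed-driven (aleatoric) spread.
#'
#' @param table Evaluation table: data frame with columns \code{config_id},
#'   \code{seed}, \code{energy} (one row per configuration-replica pair, the
#'   same seed list for every configuration).
#' @return An object of class \code{pbox}: list with \code{per_seed_cdfs}
#'   (named list of \code{\link[stats]{ecdf}} functions), \code{lower} and
#'   \code{upper} envelope step functions, and the pooled jump locations
#'   \code{knots}.
#' @export
pbox <- function(table) {
  check_evaluation_table(table)
  if (length(unique(table$config_id)) < 2L)
    stop("need at least 2 configurations per seed to form a p-box",
         call. = FALSE)
  by_seed <- split(table$energy, table$seed)
  cdfs <- lapply(by_seed, stats::ecdf)
  xs <- sort(unique(table$energy))
  F <- vapply(cdfs, function(f) f(xs), numeric(length(xs)))
  lo <- apply(F, 1L, min)
  hi <- apply(F, 1L, max)
  structure(list(
    per_seed_cdfs = cdfs,
    lower = stats::stepfun(xs, c(0, lo), right = FALSE),
    upper = stats::stepfun(xs, c(0, hi), right = FALSE),
    knots = xs), class = "pbox")
}

#' @export
print.pbox <- function(x, ...) {
  cat("Probability box over", length(x$per_seed_cdfs), "per-seed ecdfs,",
      length(x$knots), "distinct energies\n")
  invisible(x)
}

## Generalized inverse of a nondecreasing right-continuous step function
## with the given jump locations: F^-(q) = min{x : F(x) >= q}.
step_inverse <- function(F, knots, q) {
  vals <- F(knots)
  i <- which(vals >= q - 1e-12)
  if (length(i) == 0L) return(knots[length(knots)])
  knots[i[1L]]
}

#' Confidence interval extracted from a probability box
#'
#' Forms the conservative two-sided interval
#' \eqn{[\bar P^{-}(\alpha/2),\ \underline P^{-}(1 - \alpha/2)]} from the
#' envelope cdfs, where \eqn{\alpha = 1 - } \code{level} and the generalized
#' inverses use the infimum convention. Because the upper envelope dominates
#' every per-seed cdf (and the lower one is dominated by them), this
#' interval contains the corresponding quantile interval of each individual
#' seed and is therefore conservative: it accounts for both parametric and
#' seed-driven uncertainty.
#'
#' @param p A \code{\link{pbox}}.
#' @param level Coverage level in (0, 1), e.g. 0.95.
#' @param convention \code{"envelope"} (default) inverts the envelope step
#'   functions; \code{"per_seed_extremes"} instead takes the extreme
#'   per-seed quantiles, the alternative ordering sometimes used for p-box
#'   summaries.
#' @return List with \code{lo}, \code{hi}, and \code{width = hi - lo}.
#' @export
pbox_interval <- function(p, level,
                          convention = c("envelope", "per_seed_extremes")) {
  stopifnot(inherits(p, "pbox"), level > 0, level < 1)
  convention <- match.arg(convention)
  a <- (1 - level) / 2
  if (convention == "envelope") {
    lo <- step_inverse(p$upper, p$knots, a)
    hi <- step_inverse(p$lower, p$knots, 1 - a)
  } else {
    qs <- vapply(p$per_seed_cdfs, function(f)
      c(step_inverse(f, stats::knots(f), a),
        step_inverse(f, stats::knots(f), 1 - a)), numeric(2L))
    lo <- min(qs[1L, ])
    hi <- max(qs[2L, ])
  }
  list(lo = lo, hi = hi, width = hi - lo)
}

#' Biased moment-based sample skewness
#'
#' \eqn{m_3 / m_2^{3/2}} with central sample moments \eqn{m_k} (no bias
#' correction); the convention of \code{e1071} type 1.
#'
#' @param x Numeric sample.
#' @return Scalar skewness.
#' @export
sample_skewness <- function(x) e1071::skewness(x, type = 1)

#' Biased moment-based sample excess kurtosis
#'
#' \eqn{m_4 / m_2^2 - 3}; zero for a Gaussian in the large-sample limit.
#'
#' @inheritParams sample_skewness
#' @return Scalar excess kurtosis.
#' @export
sample_excess_kurtosis <- function(x) e1071::kurtosis(x, type = 1)

#' Skewness region label
#'
#' Rule-of-thumb classification of distribution symmetry:
#' \code{"A"} (approximately symmetric) for \eqn{|skew| < 0.5}, \code{"B"}
#' (moderately skewed) for \eqn{0.5 \le |skew| \le 1}, \code{"C"} (highly
#' skewed) for \eqn{|skew| > 1}.
#'
#' @param skewness Scalar skewness value.
#' @return \code{"A"}, \code{"B"} or \code{"C"}.
#' @export
skewness_region <- function(skewness) {
  s <- abs(skewness)
  if (s < 0.5) "A" else if (s <= 1.0) "B" else "C"
}

#' Shape statistics of a replica ensemble with bootstrap intervals
#'
#' Computes the biased moment-based skewness and excess kurtosis of a sample
#' (typically the replica energies of one parametric configuration) together
#' with percentile bootstrap confidence intervals and the A/B/C symmetry
#' region of the point skewness. The bootstrap resamples the replicas with
#' replacement under an explicit integer seed; the caller's RNG state is
#' left untouched.
#'
#' @param x Numeric sample of at least 3 values.
#' @param n_boot Number of bootstrap resamples (0 skips the intervals).
#' @param ci_level Confidence level of the percentile intervals.
#' @param seed Integer seed for the resampling.
#' @return List with \code{skewness}, \code{ex_kurtosis}, \code{region},
#'   \code{skewness_ci}, \code{ex_kurtosis_ci} (length-2 vectors or
#'   \code{NULL}), \code{defined}, \code{n}, \code{n_boot},
#'   \code{ci_level}.
#' @export
shape_stats <- function(x, n_boot = 2000L, ci_level = 0.90, seed = 1L) {
  stopifnot(is.numeric(x), length(x) >= 3L, n_boot >= 0L,
            ci_level > 0, ci_level < 1)
  if (stats::var(x) == 0)
    return(list(skewness = NA_real_, ex_kurtosis = NA_real_, region = NA_character_,
                skewness_ci = NULL, ex_kurtosis_ci = NULL, defined = FALSE,
                n = length(x), n_boot = as.integer(n_boot), ci_level = ci_level))
  sk <- sample_skewness(x)
  ku <- sample_excess_kurtosis(x)
  sk_ci <- ku_ci <- NULL
  if (n_boot > 0L) {
    boot <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        xb <- sample(x, replace = TRUE)
        c(sample_skewness(xb), sample_excess_kurtosis(xb))
      }, numeric(2L))
    })
    a <- (1 - ci_level) / 2
    sk_ci <- unname(stats::quantile(boot[1L, ], c(a, 1 - a), na.rm = TRUE))
    ku_ci <- unname(stats::quantile(boot[2L, ], c(a, 1 - a), na.rm = TRUE))
  }
  list(skewness = sk, ex_kurtosis = ku, region = skewness_region(sk),
       skewness_ci = sk_ci, ex_kurtosis_ci = ku_ci, defined = TRUE,
       n = length(x), n_boot = as.integer(n_boot), ci_level = ci_level)
}

#' Per-configuration shape report for an evaluation table
#'
#' Applies \code{\link{shape_stats}} to the replica ensemble of every
#' parametric configuration.
#'
#' @inheritParams pbox
#' @inheritParams shape_stats
#' @return Data frame with one row per configuration: the ensemble mean
#'   energy, skewness and excess kurtosis with bootstrap CI bounds, and the
#'   A/B/C region label.
#' @export
shape_report <- function(table, n_boot = 2000L, ci_level = 0.90, seed = 1L) {
  check_evaluation_table(table)
  cfgs <- sort(unique(table$config_id))
  rows <- lapply(seq_along(cfgs), function(i) {
    x <- table$energy[table$config_id == cfgs[i]]
    s <- shape_stats(x, n_boot = n_boot, ci_level = ci_level,
                     seed = seed + i - 1L)
    data.frame(config_id = cfgs[i], mean_energy = mean(x),
               skewness = s$skewness,
               skewness_lo = if (is.null(s$skewness_ci)) NA_real_ else s$skewness_ci[1L],
               skewness_hi = if (is.null(s$skewness_ci)) NA_real_ else s$skewness_ci[2L],
               ex_kurtosis = s$ex_kurtosis,
               ex_kurtosis_lo = if (is.null(s$ex_kurtosis_ci)) NA_real_ else s$ex_kurtosis_ci[1L],
               ex_kurtosis_hi = if (is.null(s$ex_kurtosis_ci)) NA_real_ else s$ex_kurtosis_ci[2L],
               region = s$region)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Raw, aleatoric and epistemic views of an evaluation table
#'
#' Splits a complete (configuration x seed) table into the three sample sets
#' used to contrast uncertainty sources: all raw energies
#' (\eqn{n_{config} \times n_{seed}} values), the per-seed averages over
#' configurations (aleatoric view, one value per seed), and the
#' per-configuration averages over seeds (epistemic view, one value per
#' configuration).
#'
#' @inheritParams pbox
#' @return List with \code{raw}, \code{per_seed_means},
#'   \code{per_config_means}.
#' @export
ensemble_decomposition <- function(table) {
  check_evaluation_table(table)
  list(raw = table$energy,
       per_seed_means = as.numeric(tapply(table$energy, table$seed, mean)),
       per_config_means = as.numeric(tapply(table$energy, table$config_id, mean)))
}

#' Write a p-box summary to JSON
#'
#' @param p A \code{\link{pbox}}.
#' @param path Output JSON path.
#' @param levels Coverage levels for which envelope intervals are reported.
#' @return \code{path}, invisibly.
#' @export
write_pbox_report <- function(p, path, levels = c(0.95)) {
  stopifnot(inherits(p, "pbox"))
  ints <- lapply(levels, function(lv) {
    ci <- pbox_interval(p, lv)
    list(level = lv, lo = ci$lo, hi = ci$hi, width = ci$width)
  })
  obj <- list(n_seeds = length(p$per_seed_cdfs),
              knots = p$knots,
              lower = p$lower(p$knots),
              upper = p$upper(p$knots),
              intervals = ints)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
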