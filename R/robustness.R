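#' Coefficient of variation of a uniform distribution
#'
#' For a uniform variable on \eqn{[lo, hi]} the CV is the analytic
#' \eqn{|(hi - lo)/\sqrt{12}\, /\, ((lo + hi)/2)|}. For symmetric
#' \eqn{\pm 15\%} bounds about any positive nominal this is
#' \eqn{0.15/\sqrt{3} \approx 0.0866}, independent of the nominal value.
#'
#' @param lo,hi Interval bounds, \code{lo <= hi}; the midpoint must be
#'   nonzero.
#' @return Non-negative scalar CV.
#' @examples
#' uniform_cv(0.85, 1.15)  # 0.0866...
#' uniform_cv(280, 320)    # 0.0385...
#' @export
uniform_cv <- function(lo, hi) {
  stopifnot(lo <= hi)
  mid <- (lo + hi) / 2
  if (mid == 0)
    stop("CV undefined for a zero-mean interval", call. = FALSE)
  abs(((hi - lo) / sqrt(12)) / mid)
}

#' Mean input coefficient of variation of an input space
#'
#' Averages the analytic uniform CVs of all parameters. With
#' \code{all_pm15 = TRUE} every parameter is treated as if bounded at
#' \eqn{\pm 15\%} of its nominal (CV \eqn{= 0.15/\sqrt 3} each), the
#' convention under which 14 such inputs give a mean CV of 0.087; by default
#' each parameter's actual bounds are used (so a reduced temperature range
#' lowers the mean).
#'
#' @param space An \code{\link{input_space}}.
#' @param all_pm15 Use the uniform \eqn{\pm 15\%} convention for every
#'   parameter.
#' @return Scalar mean CV.
#' @export
mean_input_cv <- function(space, all_pm15 = FALSE) {
  stopifnot(inherits(space, "input_space"))
  p <- space$parameters
  if (all_pm15) return(0.15 / sqrt(3))
  mean(mapply(uniform_cv, p$lo, p$hi))
}

#' Uncertainty amplification ratio from two coefficients of variation
#'
#' The CVR is the absolute output CV divided by the mean input CV; values
#' above 1 mean the computation amplifies the assumed input variability,
#' values below 1 mean it damps it.
#'
#' @param output_cv Output coefficient of variation (ensemble-averaged, or
#'   the mean of per-replica CVs).
#' @param input_cv Mean input coefficient of variation (must be positive).
#' @return Scalar ratio.
#' @examples
#' cv_ratio(0.0094, 0.087)  # ~0.11: strong damping under ensemble averaging
#' cv_ratio(0.047, 0.087)   # ~0.54: five-fold weaker damping per replica
#' @export
cv_ratio <- function(output_cv, input_cv) {
  stopifnot(input_cv > 0)
  abs(output_cv) / input_cv
}

cv_of <- function(x) {
  mu <- mean(x)
  if (mu == 0) stop("CV undefined: zero mean output", call. = FALSE)
  abs(stats::sd(x) / mu)
}

#' CVR with ensemble averaging
#'
#' The uncertainty amplification factor in its ensemble-averaged form: the
#' output CV is the (absolute) coefficient of variation of the
#' per-configuration ensemble-mean energies, divided by the mean input CV.
#' Values below 1 mean the calculation damps the assumed input uncertainty;
#' above 1, it amplifies it. The replica seeds are never part of the input
#' CV: their mean and variance carry no meaning.
#'
#' @inheritParams pbox
#' @inheritParams mean_input_cv
#' @return An object of class \code{cv_report}: list with \code{mode},
#'   \code{input_cvs}, \code{mean_input_cv}, \code{output_cv}, \code{cvr},
#'   \code{amplification}.
#' @export
cvr_ensemble <- function(table, space, all_pm15 = FALSE) {
  check_evaluation_table(table)
  stopifnot(inherits(space, "input_space"))
  means <- as.numeric(tapply(table$energy, table$config_id, mean))
  out_cv <- cv_of(means)
  in_cv <- mean_input_cv(space, all_pm15 = all_pm15)
  cvr <- cv_ratio(out_cv, in_cv)
  structure(list(mode = "ensemble",
                 input_cvs = stats::setNames(
                   mapply(uniform_cv, space$parameters$lo, space$parameters$hi),
                   space$parameters$name),
                 mean_input_cv = in_cv, output_cv = out_cv,
                 cvr = cvr, amplification = cvr > 1),
            class = "cv_report")
}

#' CVR without ensemble averaging (per replica)
#'
#' The replica-resolved amplification factor: for each seed the CV of the
#' energies over configurations is computed, the absolute per-seed CVs are
#' averaged over the \eqn{S} seeds, and the ratio to the mean input CV is
#' taken. Averaging over seeds removes aleatoric spread, so this per-seed
#' ratio always dominates \code{\link{cvr_ensemble}}; their contrast
#' measures how much ensemble averaging suppresses the seed-driven
#' uncertainty.
#'
#' @inheritParams cvr_ensemble
#' @return A \code{cv_report} with \code{mode = "per_seed"} and the
#'   additional field \code{per_seed_cvs}.
#' @export
cvr_per_seed <- function(table, space, all_pm15 = FALSE) {
  check_evaluation_table(table)
  stopifnot(inherits(space, "input_space"))
  per_seed <- vapply(split(table$energy, table$seed), cv_of, numeric(1L))
  out_cv <- mean(abs(per_seed))
  in_cv <- mean_input_cv(space, all_pm15 = all_pm15)
  cvr <- cv_ratio(out_cv, in_cv)
  structure(list(mode = "per_seed",
                 input_cvs = stats::setNames(
                   mapply(uniform_cv, space$parameters$lo, space$parameters$hi),
                   space$parameters$name),
                 mean_input_cv = in_cv, output_cv = out_cv,
                 per_seed_cvs = per_seed,
                 cvr = cvr, amplification = cvr > 1),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("CVR (%s): mean input CV %.4f, output CV %.4f, CVR %.3f (%s)\n",
              x$mode, x$mean_input_cv, x$output_cv, x$cvr,
              if (x$amplification) "amplification" else "damping"))
  invisible(x)
}

#' Write a CV report to JSON
#'
#' @param report A \code{cv_report}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  obj <- list(mode = report$mode,
              mean_input_cv = report$mean_input_cv,
              output_cv = report$output_cv,
              cvr = report$cvr,
              amplification = report$amplification,
              input_cvs = as.list(report$input_cvs))
  if (!is.null(report$per_seed_cvs))
    obj$per_seed_cvs <- as.list(report$per_seed_cvs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
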