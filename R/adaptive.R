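#' Variance-change refinement error of a candidate multi-index
#'
#' The error indicator used by the dimension-adaptive sampler: the absolute
#' change in surrogate variance that accepting the candidate would cause,
#' \eqn{\epsilon_l = |\mathrm{Var}(\Lambda \cup \{l\}) -
#' \mathrm{Var}(\Lambda)|}, with both variances computed by
#' \code{\link{plan_moments}}. Candidates refining a direction along which
#' the model is constant score exactly zero.
#'
#' @param index_set Accepted admissible index set \eqn{\Lambda}.
#' @param candidate Multi-index such that \eqn{\Lambda \cup \{candidate\}}
#'   is admissible.
#' @param values Named value map covering the union grid of
#'   \eqn{\Lambda \cup \{candidate\}}.
#' @return Non-negative scalar \eqn{\epsilon_l}.
#' @export
refinement_error <- function(index_set, candidate, values) {
  index_set <- check_index_set(index_set)
  candidate <- check_index(candidate)
  extended <- c(index_set, list(candidate))
  if (!is_admissible(extended))
    stop("candidate ", index_key(candidate),
         " is not admissible for the current index set", call. = FALSE)
  v0 <- plan_moments(sparse_grid_plan(index_set), values)$variance
  v1 <- plan_moments(sparse_grid_plan(extended), values)$variance
  abs(v1 - v0)
}

## Order a list of multi-indices lexicographically; used for deterministic
## candidate sweeps and tie-breaking.
lex_order <- function(indices) {
  if (length(indices) == 0L) return(integer(0L))
  M <- do.call(rbind, indices)
  do.call(order, as.data.frame(M))
}

#' Run a dimension-adaptive sampling campaign
#'
#' Starting from the single midpoint configuration
#' (\eqn{\Lambda = \{(0, \ldots, 0)\}}), alternates a look-ahead step —
#' evaluating the model ensemble at the new collocation points of every
#' admissible forward neighbor — with acceptance of the candidate whose
#' variance-change indicator \code{\link{refinement_error}} is largest (ties
#' broken toward the lexicographically smallest index). Every parametric
#' configuration is evaluated once per seed in \code{seeds} and the refined
#' quantity of interest is the ensemble average over those seeds
#' (\code{quantity = "ensemble_mean"}), or the first seed alone
#' (\code{quantity = "single_seed"}). Look-ahead evaluations count against
#' the budget when they are computed; the loop stops when the next
#' look-ahead would exceed the budget, when no admissible candidates remain,
#' when every remaining candidate's indicator is zero (up to round-off; an
#' exactly reproduced model offers nothing to refine), or when the largest
#' indicator drops below \code{tol}. All evaluations are cached, so no
#' (configuration, seed) pair is ever run twice.
#'
#' @param model Function \code{(xi, seed) -> scalar}, where \code{xi} is a
#'   named vector of physical parameter values.
#' @param space An \code{\link{input_space}}.
#' @param seeds Integer vector of replica seeds, reused identically for
#'   every configuration.
#' @param budget Maximum number of model evaluations (including look-ahead);
#'   must cover at least the initial midpoint ensemble.
#' @param quantity \code{"ensemble_mean"} or \code{"single_seed"}.
#' @param tol Absolute stopping tolerance on the largest indicator; the
#'   default 0 disables it so the campaign runs to its budget.
#' @return An object of class \code{uq_campaign}: list with
#'   \code{accepted} (final \eqn{\Lambda}), \code{plan}
#'   (\code{\link{sparse_grid_plan}} over \eqn{\Lambda}), \code{values}
#'   (per-configuration quantity of interest keyed by unit-cube point),
#'   \code{table} (the evaluation table: one row per (configuration, seed)),
#'   \code{moments}, \code{history} (one row per accepted refinement),
#'   \code{evaluations_used}, and the campaign settings.
#' @export
run_campaign <- function(model, space, seeds, budget,
                         quantity = c("ensemble_mean", "single_seed"),
                         tol = 0) {
  stopifnot(inherits(space, "input_space"), is.function(model),
            length(seeds) >= 1L, budget >= 1)
  quantity <- match.arg(quantity)
  seeds_used <- if (quantity == "single_seed") seeds[1L] else seeds
  d <- space$dimension
  if (budget < length(seeds_used))
    stop("budget must cover at least one full ensemble (",
         length(seeds_used), " evaluations)", call. = FALSE)

  env <- new.env(parent = emptyenv())
  env$values <- numeric(0L)          # point key -> QoI (ensemble mean)
  env$config_ids <- character(0L)    # point keys in evaluation order
  env$rows <- list()                 # evaluation table rows
  env$used <- 0L

  evaluate_points <- function(pts) {
    keys <- point_keys(pts)
    new <- which(!(keys %in% names(env$values)))
    cost <- length(new) * length(seeds_used)
    if (env$used + cost > budget) return(FALSE)
    for (r in new) {
      u <- pts[r, ]
      xi <- to_physical(space, u)
      energies <- vapply(seeds_used, function(s) {
        val <- tryCatch(model(xi, s), error = function(e)
          stop("model evaluation failed at configuration [",
               paste(signif(xi, 6), collapse = ", "), "], seed ", s, ": ",
               conditionMessage(e), call. = FALSE))
        as.numeric(val)
      }, numeric(1L))
      cid <- length(env$config_ids) + 1L
      env$config_ids <- c(env$config_ids, keys[r])
      env$rows[[cid]] <- data.frame(
        config_id = cid, as.list(xi), seed = seeds_used,
        energy = energies, check.names = FALSE)
      v <- mean(energies)
      names(v) <- keys[r]
      env$values <- c(env$values, v)
      env$used <- env$used + length(seeds_used)
    }
    TRUE
  }

  zero <- rep(0L, d)
  accepted <- list(zero)
  if (!evaluate_points(tensor_grid(zero)$points))
    stop("budget too small for the initial midpoint ensemble", call. = FALSE)

  history <- list()
  iter <- 0L
  repeat {
    # admissible forward neighbors of the accepted set, lexicographic order
    acc_keys <- vapply(accepted, index_key, character(1L))
    cands <- list()
    for (l in accepted) {
      for (f in forward_neighbors(l)) {
        k <- index_key(f)
        if (!(k %in% acc_keys) && !(k %in% names(cands)) &&
            is_admissible(c(accepted, list(f))))
          cands[[k]] <- f
      }
    }
    if (length(cands) == 0L) break
    cands <- cands[lex_order(cands)]

    # look-ahead: evaluate each candidate's new points, stop if unaffordable
    exhausted <- FALSE
    for (cand in cands) {
      new_pts <- sparse_grid_plan(c(accepted, list(cand)))$unique_points
      if (!evaluate_points(new_pts)) { exhausted <- TRUE; break }
    }
    if (exhausted) break

    eps <- vapply(cands, function(cand)
      refinement_error(accepted, cand, env$values), numeric(1L))
    # refinements whose variance change is pure round-off carry no
    # information; treating them as exact zeros keeps inactive dimensions
    # from being refined when the surrogate already reproduces the model
    var_acc <- plan_moments(sparse_grid_plan(accepted), env$values)$variance
    eps[eps <= 1e-10 * max(1, var_acc)] <- 0
    if (max(eps) == 0) break            # no informative candidate remains
    if (tol > 0 && max(eps) < tol) break
    best <- which(eps == max(eps))[1L]  # candidates are in lex order already

    accepted <- c(accepted, list(cands[[best]]))
    iter <- iter + 1L
    var_now <- plan_moments(sparse_grid_plan(accepted), env$values)$variance
    history[[iter]] <- data.frame(
      iteration = iter, accepted = index_key(cands[[best]]),
      epsilon = unname(eps[best]), max_epsilon = max(eps),
      variance = var_now, evaluations_used = env$used)
  }

  plan <- sparse_grid_plan(accepted)
  table <- do.call(rbind, env$rows)
  rownames(table) <- NULL
  structure(list(
    accepted = accepted,
    plan = plan,
    values = env$values,
    table = table,
    moments = plan_moments(plan, env$values),
    history = if (length(history) > 0L) do.call(rbind, history) else
      data.frame(iteration = integer(), accepted = character(),
                 epsilon = numeric(), max_epsilon = numeric(),
                 variance = numeric(), evaluations_used = integer()),
    evaluations_used = env$used,
    budget = budget,
    seeds = seeds_used,
    quantity = quantity,
    space = space), class = "uq_campaign")
}

#' @export
print.uq_campaign <- function(x, ...) {
  cat("Adaptive campaign:", length(x$accepted), "accepted multi-indices,",
      length(x$values), "configurations,", x$evaluations_used, "of",
      x$budget, "evaluations\n")
  cat(sprintf("QoI (%s over %d seed%s): mean %.4f, variance %.6g\n",
              x$quantity, length(x$seeds), if (length(x$seeds) == 1L) "" else "s",
              x$moments$mean, x$moments$variance))
  invisible(x)
}

#' Shorthand for a campaign's configuration-to-value map
#'
#' @param campaign A \code{\link{run_campaign}} result.
#' @return The named value vector usable with \code{\link{interpolate_plan}}.
#' @export
campaign_values <- function(campaign) {
  stopifnot(inherits(campaign, "uq_campaign"))
  campaign$values
}

#' Evaluate a fixed set of configurations over a seed ensemble
#'
#' Fixed-plan counterpart of \code{\link{run_campaign}}: runs the model at
#' every supplied configuration for every seed (the same seed list for each
#' configuration) and returns the evaluation table. With 63 configurations
#' and 25 seeds this performs the bookkeeping of a 1575-execution ensemble
#' campaign.
#'
#' @inheritParams run_campaign
#' @param configs Matrix of unit-cube points, one configuration per row
#'   (for example from \code{\link{sample_configurations}}).
#' @return A data frame with columns \code{config_id}, one column per input
#'   parameter, \code{seed}, and \code{energy}.
#' @export
evaluate_configurations <- function(model, space, configs, seeds) {
  stopifnot(inherits(space, "input_space"), is.matrix(configs),
            ncol(configs) == space$dimension, length(seeds) >= 1L)
  rows <- vector("list", nrow(configs))
  for (r in seq_len(nrow(configs))) {
    xi <- to_physical(space, configs[r, ])
    energies <- vapply(seeds, function(s) as.numeric(model(xi, s)),
                       numeric(1L))
    rows[[r]] <- data.frame(config_id = r, as.list(xi), seed = seeds,
                            energy = energies, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
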