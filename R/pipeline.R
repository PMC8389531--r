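#' Write an evaluation table to CSV
#'
#' Plain-text persistence of the (configuration, seed) -> energy table:
#' columns \code{config_id}, one per input parameter, \code{seed},
#' \code{energy}. Numeric columns are written with 17 significant digits so
#' the round trip through \code{\link{read_evaluation_table}} is lossless.
#'
#' @param table Evaluation table data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_evaluation_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an evaluation table from CSV
#'
#' @param path CSV written by \code{\link{write_evaluation_table}} (or any
#'   CSV with the same dialect).
#' @return Evaluation table data frame.
#' @export
read_evaluation_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df$config_id <- as.integer(df$config_id)
  df$seed <- as.integer(df$seed)
  for (nm in setdiff(names(df), c("config_id", "seed")))
    df[[nm]] <- as.numeric(df[[nm]])
  df
}

## Build (space, model) from a pipeline configuration list.
resolve_model <- function(config) {
  spec <- config$model
  name <- if (is.null(spec$name)) "mock" else spec$name
  switch(name,
    mock = {
      space <- default_input_space()
      args <- spec[setdiff(names(spec), "name")]
      cfg <- do.call(mock_config, c(list(space = space), args))
      list(space = space, model = mock_esmacs_model(cfg), name = "mock")
    },
    g_function = {
      a <- as.numeric(spec$a)
      space <- unit_input_space(length(a))
      list(space = space,
           model = function(xi, seed) g_function(as.numeric(xi), a),
           name = "g_function")
    },
    ishigami = {
      a <- if (is.null(spec$a)) 7 else spec$a
      b <- if (is.null(spec$b)) 0.1 else spec$b
      space <- unit_input_space(3L)
      list(space = space,
           model = function(xi, seed) ishigami(as.numeric(xi), a, b),
           name = "ishigami")
    },
    stop("unknown model '", name, "'", call. = FALSE))
}

#' Run the full uncertainty-quantification pipeline
#'
#' Orchestrates every stage over one output directory: builds the model and
#' input space, generates the evaluation table (adaptively via
#' \code{\link{run_campaign}}, or at a fixed number of space-filling
#' configurations), then computes Sobol indices from the sparse-grid
#' surrogate (adaptive mode), the probability box with envelope confidence
#' intervals, the per-configuration shape report, and both CVR modes. All
#' artifacts are plain CSV/JSON; \code{manifest.json} snapshots the
#' configuration so the identical run can be reproduced bit-for-bit.
#'
#' @param config A configuration list, or the path to a YAML/JSON file
#'   containing one. Recognized fields: \code{model} (list with
#'   \code{name} \code{"mock"}, \code{"g_function"} or \code{"ishigami"}
#'   plus model arguments), \code{mode} (\code{"adaptive"} or
#'   \code{"fixed"}), \code{seeds} (integer vector of replica seeds),
#'   \code{budget} and \code{quantity} and \code{tol} (adaptive mode),
#'   \code{n_configs} and \code{sample_seed} (fixed mode), \code{pbox_level},
#'   \code{n_boot}, \code{boot_seed}, \code{ci_level}, \code{all_pm15}.
#' @param out_dir Output directory, created if needed.
#' @return The manifest, invisibly: a list with the config snapshot, stage
#'   output paths, row/configuration counts and elapsed time.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]

  mode <- if (is.null(config$mode)) "adaptive" else config$mode
  seeds <- if (is.null(config$seeds)) 1:25 else as.integer(unlist(config$seeds))
  rm_ <- resolve_model(config)
  space <- rm_$space
  model <- rm_$model
  paths <- list()

  if (mode == "adaptive") {
    budget <- if (is.null(config$budget)) 500L else as.integer(config$budget)
    quantity <- if (is.null(config$quantity)) "ensemble_mean" else config$quantity
    tol <- if (is.null(config$tol)) 0 else as.numeric(config$tol)
    campaign <- run_campaign(model, space, seeds, budget,
                             quantity = quantity, tol = tol)
    table <- campaign$table
    paths$plan <- file.path(out_dir, "plan.json")
    write_plan(campaign$plan, paths$plan, input_names = space$parameters$name)
    paths$history <- file.path(out_dir, "history.csv")
    utils::write.csv(campaign$history, paths$history, row.names = FALSE)
    expansion <- to_orthogonal_expansion(campaign$plan, campaign$values)
    paths$sobol <- file.path(out_dir, "sobol.json")
    paths$sobol_csv <- file.path(out_dir, "sobol.csv")
    write_sobol_report(sobol_indices(expansion),
                       json_path = paths$sobol, csv_path = paths$sobol_csv)
    moments <- campaign$moments
  } else if (mode == "fixed") {
    n_configs <- if (is.null(config$n_configs)) 63L else as.integer(config$n_configs)
    sample_seed <- if (is.null(config$sample_seed)) 1L else as.integer(config$sample_seed)
    configs <- sample_configurations(space, n_configs, sample_seed)
    table <- evaluate_configurations(model, space, configs, seeds)
    means <- as.numeric(tapply(table$energy, table$config_id, mean))
    moments <- list(mean = mean(means), variance = stats::var(means))
  } else stop("unknown mode '", mode, "'", call. = FALSE)

  paths$table <- file.path(out_dir, "table.csv")
  write_evaluation_table(table, paths$table)

  n_configs_out <- length(unique(table$config_id))
  all_pm15 <- isTRUE(config$all_pm15)
  if (n_configs_out >= 2L) {
    pb <- pbox(table)
    lvl <- if (is.null(config$pbox_level)) 0.95 else as.numeric(config$pbox_level)
    paths$pbox <- file.path(out_dir, "pbox.json")
    write_pbox_report(pb, paths$pbox, levels = lvl)
    if (length(seeds) >= 3L) {   # shape measures need >= 3 replicas
      n_boot <- if (is.null(config$n_boot)) 2000L else as.integer(config$n_boot)
      boot_seed <- if (is.null(config$boot_seed)) 42L else as.integer(config$boot_seed)
      ci_level <- if (is.null(config$ci_level)) 0.90 else as.numeric(config$ci_level)
      shapes <- shape_report(table, n_boot = n_boot, ci_level = ci_level,
                             seed = boot_seed)
      paths$shapes <- file.path(out_dir, "shapes.csv")
      utils::write.csv(shapes, paths$shapes, row.names = FALSE)
    }
    paths$cvr <- file.path(out_dir, "cvr.json")
    cvr_e <- cvr_ensemble(table, space, all_pm15 = all_pm15)
    cvr_s <- cvr_per_seed(table, space, all_pm15 = all_pm15)
    jsonlite::write_json(
      list(mean_input_cv = cvr_e$mean_input_cv,
           ensemble = list(output_cv = cvr_e$output_cv, cvr = cvr_e$cvr),
           per_seed = list(output_cv = cvr_s$output_cv, cvr = cvr_s$cvr)),
      paths$cvr, auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    config = config,
    mode = mode,
    model = rm_$name,
    seeds = seeds,
    n_configurations = n_configs_out,
    n_evaluations = nrow(table),
    moments = moments,
    paths = lapply(paths, basename),
    elapsed_seconds = proc.time()[["elapsed"]] - t0)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Re-run a pipeline from a persisted manifest
#'
#' Reads \code{manifest.json} from a previous \code{\link{run_pipeline}}
#' output directory and executes the identical configuration into a new
#' directory; all stochastic stages are seeded from the snapshot, so the
#' evaluation table reproduces byte-for-byte.
#'
#' @param manifest_path Path to a \code{manifest.json}.
#' @param out_dir New output directory.
#' @return The new manifest, invisibly.
#' @export
rerun_pipeline <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  run_pipeline(man$config, out_dir)
}
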