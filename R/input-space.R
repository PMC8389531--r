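#' Construct an uncertain-input space
#'
#' An input space is an ordered set of independent uniformly distributed
#' parameters, each with a nominal value and \code{[lo, hi]} bounds. All
#' sparse-grid mathematics lives on the unit hypercube; the input space owns
#' the affine map between unit coordinates and physical parameter values.
#'
#' @param parameters A data frame with columns \code{name}, \code{nominal},
#'   \code{lo}, \code{hi} and optionally \code{group}
#'   (\code{"physical"} or \code{"solver"}).
#' @return An object of class \code{input_space}.
#' @seealso \code{\link{default_input_space}}, \code{\link{unit_input_space}}
#' @export
input_space <- function(parameters) {
  stopifnot(is.data.frame(parameters),
            all(c("name", "nominal", "lo", "hi") %in% names(parameters)))
  if (anyDuplicated(parameters$name))
    stop("parameter names must be unique", call. = FALSE)
  if (any(parameters$lo >= parameters$hi))
    stop("each parameter needs lo < hi", call. = FALSE)
  if (any(parameters$nominal < parameters$lo | parameters$nominal > parameters$hi))
    stop("each nominal value must lie within [lo, hi]", call. = FALSE)
  if (is.null(parameters$group)) parameters$group <- "solver"
  structure(list(parameters = parameters, dimension = nrow(parameters)),
            class = "input_space")
}

#' @export
print.input_space <- function(x, ...) {
  cat("Input space with", x$dimension, "uniform parameters\n")
  print(x$parameters, row.names = FALSE)
  invisible(x)
}

#' Default study input space for the binding-affinity workflow
#'
#' Fourteen uniformly distributed simulation parameters: four physical
#' controls (thermostat target temperature, barostat pressure target,
#' equilibration and production durations) and ten solver controls. All
#' parameters except the temperature get bounds at +/-15\% of their nominal
#' value; the temperature is restricted to \eqn{[280, 320]} K around a
#' nominal 300 K on physical grounds. Nominal values for the non-temperature
#' parameters are synthetic placeholders in plausible simulation units; only
#' the bounds' relative width enters the unit-cube mathematics.
#'
#' @return An \code{\link{input_space}} of dimension 14.
#' @examples
#' sp <- default_input_space()
#' sp$dimension
#' subset(sp$parameters, name == "setTemperature")
#' @export
default_input_space <- function() {
  pm15 <- function(name, nominal, group) {
    data.frame(name = name, nominal = nominal,
               lo = 0.85 * nominal, hi = 1.15 * nominal, group = group)
  }
  pars <- rbind(
    data.frame(name = "setTemperature", nominal = 300, lo = 280, hi = 320,
               group = "physical"),
    pm15("BerendsenPressureTarget", 1.01325, "physical"),
    pm15("time_eq1",                2.0,     "physical"),
    pm15("time_sim1",               4.0,     "physical"),
    pm15("initTemperature_eq1",     50,      "solver"),
    pm15("timestep",                2.0,     "solver"),
    pm15("cutoff",                  12.0,    "solver"),
    pm15("switchdist",              10.0,    "solver"),
    pm15("pairlistdist",            13.5,    "solver"),
    pm15("margin",                  0.48,    "solver"),
    pm15("langevinDamping",         5.0,     "solver"),
    pm15("langevinPistonPeriod",    100.0,   "solver"),
    pm15("langevinPistonDecay",     50.0,    "solver"),
    pm15("box_pad",                 14.0,    "solver"))
  input_space(pars)
}

#' Unit-hypercube input space
#'
#' Convenience space with \code{d} parameters uniform on \eqn{[0, 1]}; the
#' affine map is the identity. Used to run the analytic benchmark functions
#' through the campaign machinery.
#'
#' @param d Dimension.
#' @param names Optional parameter names; defaults to \code{x1..xd}.
#' @return An \code{\link{input_space}}.
#' @export
unit_input_space <- function(d, names = paste0("x", seq_len(d))) {
  input_space(data.frame(name = names, nominal = 0.5, lo = 0, hi = 1,
                         group = "solver"))
}

#' Map unit-cube coordinates to physical parameter values
#'
#' @param space An \code{\link{input_space}}.
#' @param u Numeric vector in \eqn{[0,1]^d} or a matrix of such rows.
#' @return A named numeric vector, or a matrix with named columns.
#' @export
to_physical <- function(space, u) {
  stopifnot(inherits(space, "input_space"))
  p <- space$parameters
  if (is.null(dim(u))) {
    stopifnot(length(u) == space$dimension)
    out <- p$lo + u * (p$hi - p$lo)
    names(out) <- p$name
    out
  } else {
    stopifnot(ncol(u) == space$dimension)
    out <- sweep(sweep(u, 2L, p$hi - p$lo, `*`), 2L, p$lo, `+`)
    colnames(out) <- p$name
    out
  }
}

#' Map physical parameter values to unit-cube coordinates
#'
#' @inheritParams to_physical
#' @param xi Named numeric vector of physical values (or matrix of rows).
#' @export
from_physical <- function(space, xi) {
  stopifnot(inherits(space, "input_space"))
  p <- space$parameters
  if (is.null(dim(xi))) {
    xi <- xi[p$name]
    (as.numeric(xi) - p$lo) / (p$hi - p$lo)
  } else {
    xi <- xi[, p$name, drop = FALSE]
    sweep(sweep(xi, 2L, p$lo, `-`), 2L, p$hi - p$lo, `/`)
  }
}

#' Space-filling sample of parametric configurations
#'
#' Draws \code{n} configurations from the input space by Latin hypercube
#' sampling on the unit cube, under an explicit integer seed. Used for
#' fixed-plan campaigns where the configuration count (for example 63) is
#' imposed rather than discovered adaptively.
#'
#' @inheritParams to_physical
#' @param n Number of configurations.
#' @param seed Integer seed controlling the draw.
#' @return A matrix of unit-cube points, one row per configuration.
#' @export
sample_configurations <- function(space, n, seed) {
  stopifnot(inherits(space, "input_space"), n >= 1)
  d <- space$dimension
  with_local_seed(seed, lhs::randomLHS(as.integer(n), d))
}
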