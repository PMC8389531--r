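#' Configuration for the synthetic binding-energy simulator
#'
#' Defines the planted structure of \code{\link{mock_esmacs}}: a smooth
#' low-effective-dimension trend over the input space plus a seed-indexed
#' skewed noise term. Defaults emulate the broad statistics of an
#' ensemble-MD binding-affinity campaign: a pooled mean near
#' \eqn{-34.5} kcal/mol, a pooled spread of roughly 1.5 kcal/mol dominated by
#' the replica (seed) noise, mild positive ensemble skewness, and a trend in
#' which the temperature carries most of the parametric variance, followed by
#' the solvent-box padding and the nonbonded cutoff.
#'
#' @param space An \code{\link{input_space}}; trend coefficient names must be
#'   parameter names of this space.
#' @param base_energy Trend level in kcal/mol (negative: a binding energy).
#' @param linear Named vector of linear trend coefficients on centred
#'   unit-cube coordinates (kcal/mol per unit coordinate).
#' @param quadratic Named vector of quadratic trend coefficients, centred so
#'   they do not shift the trend mean.
#' @param seed_noise_scale Standard deviation (kcal/mol) of the aleatoric
#'   noise attached to each seed; 0 switches the aleatoric channel off.
#' @param seed_noise_skew Shape parameter of the skew-normal noise family;
#'   positive values give right-skewed replica ensembles, 0 gives Gaussian.
#' @param seed_mix Interaction knob in \eqn{[0, 1)}: 0 (default) makes the
#'   noise depend on the seed only, so per-seed empirical cdfs are coherent
#'   translations of one another; positive values modulate the noise
#'   amplitude with the first active input, breaking that coherence.
#' @return An object of class \code{mock_config}.
#' @export
mock_config <- function(space = default_input_space(),
                        base_energy = -34.5,
                        linear = c(setTemperature = 2.0, box_pad = 0.6,
                                   cutoff = 0.4),
                        quadratic = c(setTemperature = 0.5),
                        seed_noise_scale = 1.4,
                        seed_noise_skew = 4,
                        seed_mix = 0) {
  stopifnot(inherits(space, "input_space"))
  nm <- space$parameters$name
  bad <- setdiff(c(names(linear), names(quadratic)), nm)
  if (length(bad) > 0L)
    stop("trend coefficients refer to unknown parameters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(seed_noise_scale >= 0, seed_mix >= 0, seed_mix < 1)
  structure(list(space = space, base_energy = base_energy, linear = linear,
                 quadratic = quadratic, seed_noise_scale = seed_noise_scale,
                 seed_noise_skew = seed_noise_skew, seed_mix = seed_mix),
            class = "mock_config")
}

## Centred unit-variance skew-normal draw for a given integer seed, via the
## delta parameterization Z = delta|Z1| + sqrt(1-delta^2) Z2. Depends on the
## seed only, so the same seed yields the same noise in every configuration.
seed_noise_draw <- function(seed, alpha) {
  with_local_seed(seed, {
    z <- stats::rnorm(2L)
    if (alpha == 0) return(z[1L])
    delta <- alpha / sqrt(1 + alpha^2)
    s <- delta * abs(z[1L]) + sqrt(1 - delta^2) * z[2L]
    mu <- delta * sqrt(2 / pi)
    (s - mu) / sqrt(1 - mu^2)
  })
}

#' Synthetic ensemble-MD binding-energy evaluation
#'
#' Deterministic stand-in for one ensemble-MD workflow execution: maps a
#' physical parametric configuration and an integer random seed to a scalar
#' binding energy in kcal/mol. The value is a smooth trend in the inputs
#' (dominated by a configurable handful of active parameters) plus a
#' seed-indexed draw from a centred skew-normal family, so replica ensembles
#' have the planted spread and skewness and per-seed cdfs across
#' configurations are coherent. Identical arguments always return
#' bitwise-identical energies; no global random state is touched.
#'
#' @param cfg A \code{\link{mock_config}}.
#' @param xi Named numeric vector of physical parameter values inside the
#'   configuration's input box.
#' @param seed Integer replica seed.
#' @return Binding energy in kcal/mol (negative).
#' @export
mock_esmacs <- function(cfg, xi, seed) {
  stopifnot(inherits(cfg, "mock_config"))
  p <- cfg$space$parameters
  xi <- xi[p$name]
  if (anyNA(xi) || any(xi < p$lo - 1e-9) || any(xi > p$hi + 1e-9))
    stop("'xi' must supply every parameter within its [lo, hi] bounds",
         call. = FALSE)
  u <- from_physical(cfg$space, xi)
  names(u) <- p$name
  e <- cfg$base_energy
  for (nm in names(cfg$linear))
    e <- e + cfg$linear[[nm]] * (u[[nm]] - 0.5)
  for (nm in names(cfg$quadratic))
    e <- e + cfg$quadratic[[nm]] * ((u[[nm]] - 0.5)^2 - 1 / 12)
  if (cfg$seed_noise_scale > 0) {
    eps <- seed_noise_draw(seed, cfg$seed_noise_skew)
    amp <- cfg$seed_noise_scale
    if (cfg$seed_mix > 0) {
      lead <- names(cfg$linear)[1L]
      amp <- amp * (1 + cfg$seed_mix * (u[[lead]] - 0.5))
    }
    e <- e + amp * eps
  }
  unname(e)
}

#' Wrap a mock configuration as a campaign model
#'
#' @param cfg A \code{\link{mock_config}}.
#' @return A function \code{(xi, seed) -> energy} suitable for
#'   \code{\link{run_campaign}} and \code{\link{evaluate_configurations}}.
#' @export
mock_esmacs_model <- function(cfg) {
  function(xi, seed) mock_esmacs(cfg, xi, seed)
}

#' Sobol g-function benchmark
#'
#' The standard variance-decomposition benchmark
#' \eqn{g(\xi) = \prod_i (|4\xi_i - 2| + a_i)/(1 + a_i)} on the unit
#' hypercube; small \eqn{a_i} make input \eqn{i} influential.
#'
#' @param xi Point in the unit hypercube.
#' @param a Non-negative coefficient vector, same length as \code{xi}.
#' @return Scalar function value.
#' @seealso \code{\link{g_function_sobol}} for the closed-form indices.
#' @export
g_function <- function(xi, a) {
  stopifnot(length(xi) == length(a), all(a >= 0))
  prod((abs(4 * xi - 2) + a) / (1 + a))
}

#' Closed-form Sobol indices of the g-function
#'
#' Partial variances are \eqn{D_i = (1/3)/(1 + a_i)^2} and the total variance
#' is \eqn{D = \prod_i (1 + D_i) - 1}; the index of a subset \eqn{u} is
#' \eqn{\prod_{i \in u} D_i / D}.
#'
#' @param a Non-negative coefficient vector.
#' @return List with \code{first_order} (vector \eqn{S_i}) and
#'   \code{total_variance}.
#' @export
g_function_sobol <- function(a) {
  Di <- (1 / 3) / (1 + a)^2
  D <- prod(1 + Di) - 1
  list(first_order = Di / D, total_variance = D, partial_first = Di)
}

#' Ishigami benchmark function
#'
#' \eqn{f(x) = \sin x_1 + a \sin^2 x_2 + b x_3^4 \sin x_1} with
#' \eqn{x_i = \pi(2\xi_i - 1)}, i.e. the unit cube mapped to
#' \eqn{[-\pi, \pi]^3}. A classic test with a strong interaction between
#' inputs 1 and 3 and an exactly zero first-order index for input 3.
#'
#' @param xi Point in the unit cube, length 3.
#' @param a,b Shape constants (defaults 7 and 0.1).
#' @return Scalar function value.
#' @export
ishigami <- function(xi, a = 7, b = 0.1) {
  stopifnot(length(xi) == 3L)
  x <- pi * (2 * xi - 1)
  sin(x[1L]) + a * sin(x[2L])^2 + b * x[3L]^4 * sin(x[1L])
}

#' Closed-form Ishigami variance decomposition
#'
#' @inheritParams ishigami
#' @return List with \code{first_order} (\eqn{S_1, S_2, S_3}),
#'   \code{interaction_13} (\eqn{S_{13}}) and \code{total_variance}.
#' @export
ishigami_sobol <- function(a = 7, b = 0.1) {
  D1 <- b * pi^4 / 5 + b^2 * pi^8 / 50 + 1 / 2
  D2 <- a^2 / 8
  D13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  D <- D1 + D2 + D13
  list(first_order = c(D1, D2, 0) / D, interaction_13 = D13 / D,
       total_variance = D)
}
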