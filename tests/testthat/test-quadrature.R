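test_that("Clenshaw-Curtis rules have the nested structure and exact low levels", {
  r0 <- clenshaw_curtis_rule(0)
  expect_equal(r0$points, 0.5)
  expect_equal(r0$weights, 1.0)
  expect_equal(r0$size, 1L)

  r1 <- clenshaw_curtis_rule(1)
  expect_equal(r1$points, c(0, 0.5, 1))
  expect_equal(r1$weights, c(1 / 6, 2 / 3, 1 / 6), tolerance = 1e-14)

  r2 <- clenshaw_curtis_rule(2)
  expect_equal(r2$size, 5L)
  expect_true(all(c(0, 0.5, 1) %in% r2$points))

  # nesting is exact (bitwise) across several levels
  for (l in 0:4) {
    lo <- clenshaw_curtis_rule(l)$points
    hi <- clenshaw_curtis_rule(l + 1)$points
    expect_true(all(lo %in% hi))
  }
  expect_error(clenshaw_curtis_rule(-1), "non-negative")
})

test_that("rule invariants: sizes, symmetry, unit weights, polynomial exactness", {
  for (l in 0:6) {
    r <- clenshaw_curtis_rule(l)
    expect_identical(r$size, if (l == 0) 1L else as.integer(2^l + 1))
    expect_true(all(diff(r$points) > 0))
    expect_equal(r$points, 1 - rev(r$points))
    expect_lt(abs(sum(r$weights) - 1), 1e-12)
    # degree <= m - 1 monomials integrate exactly against the uniform measure
    for (k in seq(0, r$size - 1)) {
      expect_lt(abs(sum(r$weights * r$points^k) - 1 / (k + 1)), 1e-10)
    }
  }
})

test_that("Lagrange cardinal polynomials interpolate and reproduce hand values", {
  r1 <- clenshaw_curtis_rule(1)
  expect_equal(lagrange_basis(r1, 2, 0.5), 1.0)
  expect_equal(lagrange_basis(r1, 1, 0.5), 0.0)
  # L_0(x) = (x - 0.5)(x - 1) / ((0 - 0.5)(0 - 1)) at x = 0.25
  expect_equal(lagrange_basis(r1, 1, 0.25), 0.375)
  expect_error(lagrange_basis(r1, 4, 0.1), "1\\.\\.3")

  # cardinality at every node of a deeper rule, and partition of unity
  r3 <- clenshaw_curtis_rule(3)
  for (j in seq_len(r3$size)) {
    vals <- lagrange_basis(r3, j, r3$points)
    expect_equal(vals, as.numeric(seq_len(r3$size) == j), tolerance = 1e-12)
  }
  xs <- seq(0, 1, length.out = 17)
  tot <- Reduce(`+`, lapply(seq_len(r3$size), function(j)
    lagrange_basis(r3, j, xs)))
  expect_equal(tot, rep(1, length(xs)), tolerance = 1e-12)
})

test_that("tensor grids have product structure", {
  expect_equal(nrow(tensor_grid(c(2, 2))$points), 25L)

  tg0 <- tensor_grid(c(0, 0, 0))
  expect_equal(tg0$points, matrix(0.5, 1, 3))
  expect_equal(tg0$weights, 1.0)

  tg <- tensor_grid(c(1, 0))
  expect_equal(nrow(tg$points), 3L)
  expect_true(all(tg$points[, 2] == 0.5))
  expect_lt(abs(sum(tg$weights) - 1), 1e-12)
})

test_that("combination coefficients follow the telescoping identity", {
  expect_equal(combination_coefficients(list(c(0L, 0L))),
               c("0,0" = 1L))

  cc <- combination_coefficients(list(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(cc[["0,0"]], -1L)
  expect_equal(cc[["1,0"]], 1L)
  expect_equal(cc[["0,1"]], 1L)

  cc2 <- combination_coefficients(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(cc2[["1,1"]], 1L)
  expect_equal(sum(cc2 != 0L), 1L)

  expect_error(combination_coefficients(list(c(0, 0), c(1, 1))), "admissible")
})

test_that("combination coefficients sum to 1 on randomly grown admissible sets", {
  for (rep in 1:10) {
    set.seed(rep)
    d <- sample(2:4, 1)
    idx <- list(rep(0L, d))
    # grow by accepting random admissible forward neighbors
    for (step in 1:8) {
      keys <- vapply(idx, function(l) paste(l, collapse = ","), character(1))
      cands <- list()
      for (l in idx) for (f in forward_neighbors(l)) {
        k <- paste(f, collapse = ",")
        if (!(k %in% keys) && is_admissible(c(idx, list(f)))) cands[[k]] <- f
      }
      idx <- c(idx, cands[sample(length(cands), 1)])
    }
    expect_true(is_admissible(idx))
    expect_equal(sum(combination_coefficients(idx)), 1L)
  }
})

test_that("sparse-grid interpolant reproduces nodes, constants and low-degree functions", {
  plan <- sparse_grid_plan(list(c(0, 0), c(1, 0), c(0, 1)))
  ones <- plan_value_map(plan, function(x) 1.0)
  set.seed(1)
  probes <- matrix(runif(200), ncol = 2)
  expect_equal(interpolate_plan(plan, ones, probes), rep(1, 100),
               tolerance = 1e-12)

  vx <- plan_value_map(plan, function(x) x[1])
  expect_equal(interpolate_plan(plan, vx, c(0.25, 0.9)), 0.25,
               tolerance = 1e-12)

  # stored values reproduced exactly at every collocation point
  at_nodes <- interpolate_plan(plan, vx, plan$unique_points)
  expect_equal(at_nodes, unname(vx[rownames(plan$unique_points)]),
               tolerance = 1e-12)

  expect_error(interpolate_plan(plan, vx[-1], c(0.5, 0.5)), "missing model values")
})

test_that("full-box combination agrees with the corner tensor interpolant", {
  L <- 2
  plan <- sparse_grid_plan(full_box(L, 2))
  f <- function(x) exp(x[1]) * cos(x[2])
  vals <- plan_value_map(plan, f)
  set.seed(7)
  probes <- matrix(runif(40), ncol = 2)
  combined <- interpolate_plan(plan, vals, probes)
  # corner tensor interpolant assembled directly from the cardinal basis
  r <- clenshaw_curtis_rule(L)
  grid <- tensor_grid(c(L, L))
  fg <- apply(grid$points, 1, f)
  corner <- apply(probes, 1, function(x) {
    b1 <- vapply(seq_len(r$size), function(j) lagrange_basis(r, j, x[1]),
                 numeric(1))
    b2 <- vapply(seq_len(r$size), function(j) lagrange_basis(r, j, x[2]),
                 numeric(1))
    sum(fg * kronecker(b2, b1))
  })
  expect_equal(combined, corner, tolerance = 1e-12)
})

test_that("surrogate moments match analytic and Monte-Carlo references", {
  # constants
  p0 <- sparse_grid_plan(list(c(0L, 0L)))
  m0 <- plan_moments(p0, plan_value_map(p0, function(x) 3.5))
  expect_equal(m0$mean, 3.5)
  expect_equal(m0$variance, 0)

  # uniform moments of f(x) = x
  p1 <- sparse_grid_plan(list(0L, 1L))
  m1 <- plan_moments(p1, plan_value_map(p1, function(x) x[1]))
  expect_equal(m1$mean, 0.5, tolerance = 1e-12)
  expect_equal(m1$variance, 1 / 12, tolerance = 1e-12)

  # sum of independent uniforms on the full level-1 box
  pb <- sparse_grid_plan(full_box(1, 2))
  mb <- plan_moments(pb, plan_value_map(pb, function(x) x[1] + x[2]))
  expect_equal(mb$mean, 1.0, tolerance = 1e-12)
  expect_equal(mb$variance, 1 / 6, tolerance = 1e-12)

  # Monte-Carlo oracle for a polynomial the level-2 box reproduces exactly
  f <- function(x) x[1]^2 + x[1] * x[2]
  p2 <- sparse_grid_plan(full_box(2, 2))
  v2 <- plan_moments(p2, plan_value_map(p2, f))
  set.seed(42)
  n <- 1e6
  u1 <- runif(n); u2 <- runif(n)
  fs <- u1^2 + u1 * u2
  mc_var <- var(fs)
  se <- sd((fs - mean(fs))^2) / sqrt(n)
  expect_lt(abs(v2$variance - mc_var), 3 * se)
})

test_that("plans serialize to JSON and round-trip", {
  plan <- sparse_grid_plan(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 0)))
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, path, input_names = c("a", "b"))
  back <- read_plan(path)
  expect_equal(back$coefficients, plan$coefficients)
  expect_equal(back$unique_points, plan$unique_points)
})
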