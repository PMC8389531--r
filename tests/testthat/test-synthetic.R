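test_that("default input space matches the study design", {
  sp <- default_input_space()
  expect_equal(sp$dimension, 14L)
  temp <- subset(sp$parameters, name == "setTemperature")
  expect_equal(c(temp$lo, temp$hi), c(280, 320))
  expect_equal(temp$nominal, 300)
  others <- subset(sp$parameters, name != "setTemperature")
  expect_equal(others$lo, 0.85 * others$nominal, tolerance = 1e-12)
  expect_equal(others$hi, 1.15 * others$nominal, tolerance = 1e-12)
  expect_setequal(unique(sp$parameters$group), c("physical", "solver"))
})

test_that("unit-cube and physical coordinates round-trip", {
  sp <- default_input_space()
  set.seed(1)
  u <- matrix(runif(5 * 14), ncol = 14)
  xi <- to_physical(sp, u)
  expect_equal(from_physical(sp, xi), u, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(to_physical(sp, rep(0.5, 14))["setTemperature"]), 300)
})

test_that("the mock simulator is deterministic and validates its inputs", {
  cfg <- mock_config()
  xi <- to_physical(cfg$space, rep(0.3, 14))
  expect_identical(mock_esmacs(cfg, xi, 17L), mock_esmacs(cfg, xi, 17L))
  expect_false(mock_esmacs(cfg, xi, 1L) == mock_esmacs(cfg, xi, 2L))

  bad <- xi
  bad[["setTemperature"]] <- 500
  expect_error(mock_esmacs(cfg, bad, 1L), "bounds")
  expect_error(mock_config(linear = c(nonexistent = 1)), "unknown parameters")
})

test_that("the mock campaign reproduces the planted ensemble statistics", {
  cfg <- mock_config()
  sp <- cfg$space
  tab <- evaluate_configurations(mock_esmacs_model(cfg), sp,
                                 sample_configurations(sp, 63, seed = 11), 1:25)
  expect_equal(nrow(tab), 1575L)
  expect_lt(abs(mean(tab$energy) - (-34.5)), 0.5)
  expect_lt(abs(sd(tab$energy) - 1.6) / 1.6, 0.30)
  expect_true(all(tab$energy < 0))

  # aleatoric channel off: every ensemble is a point mass
  cfg0 <- mock_config(seed_noise_scale = 0)
  tab0 <- evaluate_configurations(mock_esmacs_model(cfg0), sp,
                                  sample_configurations(sp, 5, seed = 2), 1:6)
  within <- sapply(split(tab0$energy, tab0$config_id), var)
  expect_equal(unname(within), rep(0, 5))
})

test_that("planted skewness is recovered by the shape statistics", {
  cfg <- mock_config(seed_noise_skew = 4)
  sp <- cfg$space
  tab <- evaluate_configurations(mock_esmacs_model(cfg), sp,
                                 sample_configurations(sp, 40, seed = 21),
                                 1:100)
  sk <- sapply(split(tab$energy, tab$config_id), sample_skewness)
  expect_gt(mean(sk), 0)

  # symmetric noise family gives no systematic skewness
  cfgS <- mock_config(seed_noise_skew = 0)
  tabS <- evaluate_configurations(mock_esmacs_model(cfgS), sp,
                                  sample_configurations(sp, 40, seed = 22),
                                  1:100)
  skS <- sapply(split(tabS$energy, tabS$config_id), sample_skewness)
  expect_lt(abs(mean(skS)), mean(sk))
})

test_that("the adaptive campaign discovers the planted effective dimension", {
  cfg <- mock_config()
  sp <- cfg$space
  camp <- run_campaign(mock_esmacs_model(cfg), sp, seeds = 1:5, budget = 800)
  accepted <- do.call(rbind, camp$accepted[-1])
  expect_gt(nrow(accepted), 0)
  active <- match(names(cfg$linear), sp$parameters$name)
  in_active <- apply(accepted, 1, function(l) all(which(l > 0) %in% active))
  expect_gte(mean(in_active), 0.8)
})

test_that("planted first-order Sobol structure of the noise-free trend is recovered", {
  cfg <- mock_config(seed_noise_scale = 0)
  sp <- cfg$space
  camp <- run_campaign(mock_esmacs_model(cfg), sp, seeds = 1L, budget = 400,
                       quantity = "single_seed")
  rep_ <- sobol_indices(to_orthogonal_expansion(camp$plan, camp$values))

  # analytic decomposition of the linear + centred quadratic trend
  b <- cfg$linear; q <- cfg$quadratic
  D <- numeric(sp$dimension)
  names(D) <- sp$parameters$name
  for (nm in names(b)) D[nm] <- D[nm] + b[[nm]]^2 / 12
  for (nm in names(q)) D[nm] <- D[nm] + q[[nm]]^2 / 180
  expect_equal(rep_$first_order, unname(D / sum(D)), tolerance = 0.05)
})

test_that("benchmark functions match their closed forms", {
  # midpoint value of the g-function is prod a_i / (1 + a_i)
  a <- c(0, 1, 9, 99)
  expect_equal(g_function(rep(0.5, 4), a), prod(a / (1 + a)))
  expect_equal(g_function_sobol(c(0, 0))$first_order, c(3 / 7, 3 / 7),
               tolerance = 1e-12)
  # large a freezes an input
  gs <- g_function_sobol(c(0, 1e9))
  expect_equal(gs$first_order[1], 1, tolerance = 1e-12)

  ex <- ishigami_sobol(7, 0.1)
  expect_equal(ex$first_order[1], 0.3139, tolerance = 1e-3)
  expect_equal(ex$first_order[2], 0.4424, tolerance = 1e-3)
  expect_equal(ex$first_order[3], 0)
  # b = 0 removes the interaction entirely
  expect_equal(ishigami_sobol(7, 0)$interaction_13, 0)
  # midpoint maps to the origin where the function vanishes
  expect_equal(ishigami(rep(0.5, 3)), 0, tolerance = 1e-12)
})
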