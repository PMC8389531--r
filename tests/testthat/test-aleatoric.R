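test_that("p-box envelopes bracket every per-seed ecdf", {
  # degenerate: identical samples for every seed collapse the box
  tab <- make_table(configs = c(-36, -35, -34), seeds = 1:4,
                    energy_fn = function(cfg, s) cfg)
  pb <- pbox(tab)
  expect_equal(pb$lower(pb$knots), pb$upper(pb$knots))
  expect_equal(pb$upper(-35), 2 / 3)

  # disjoint supports: envelopes split apart
  tab2 <- make_table(configs = 1:2, seeds = 1:2,
                     energy_fn = function(cfg, s) (cfg - 1) + (s - 1) * 10)
  pb2 <- pbox(tab2)
  expect_equal(pb2$upper(1), 1)
  expect_equal(pb2$lower(9.9), 0)
  expect_equal(pb2$lower(10), 0.5)

  # dominance fuzz: envelope below/above every per-seed cdf at random probes
  set.seed(3)
  tab3 <- make_table(configs = rnorm(15), seeds = 1:6,
                     energy_fn = function(cfg, s) cfg + 0.3 * s + 0.1 * cfg * s)
  pb3 <- pbox(tab3)
  probes <- runif(1000, min(tab3$energy) - 1, max(tab3$energy) + 1)
  for (f in pb3$per_seed_cdfs) {
    expect_true(all(pb3$lower(probes) <= f(probes) + 1e-12))
    expect_true(all(f(probes) <= pb3$upper(probes) + 1e-12))
  }

  expect_error(pbox(make_table(1, 1:3, function(cfg, s) s)), "at least 2")
  bad <- make_table(configs = 1:3, seeds = 1:2, function(cfg, s) cfg)
  bad <- bad[-1, ]
  expect_error(pbox(bad), "ragged")
})

test_that("envelope intervals are conservative, translation-aware and monotone in level", {
  # seeds are shifted copies: envelope width = per-seed width + shift
  delta <- 0.7
  configs <- sort(rnorm(40))
  tab <- make_table(configs = configs, seeds = 0:4,
                    energy_fn = function(cfg, s) cfg + s * delta / 4)
  pb <- pbox(tab)
  ci_env <- pbox_interval(pb, 0.9)
  single <- pbox(make_table(configs, seeds = c(0, 0.001)[1:2],
                            energy_fn = function(cfg, s) cfg))
  ci_one <- pbox_interval(single, 0.9)
  expect_equal(ci_env$width, ci_one$width + delta, tolerance = 1e-9)

  # degenerate box: interval equals the ecdf's own quantile interval
  q <- quantile(configs, c(0.05, 0.95), type = 1)
  expect_equal(ci_one$lo, unname(q[1]))
  expect_equal(ci_one$hi, unname(q[2]))

  # monotone in coverage level
  w <- vapply(c(0.5, 0.8, 0.9, 0.95), function(lv)
    pbox_interval(pb, lv)$width, numeric(1))
  expect_true(all(diff(w) >= 0))

  # envelope interval dominates every individual per-seed interval
  ci_seed <- pbox_interval(pb, 0.9, convention = "per_seed_extremes")
  expect_lte(ci_seed$lo, ci_env$lo + 1e-12)
  expect_gte(ci_seed$hi, ci_env$hi - 1e-12)
  for (f in pb$per_seed_cdfs) {
    ks <- knots(f)
    lo_s <- ks[which(f(ks) >= 0.05)[1]]
    hi_s <- ks[which(f(ks) >= 0.95)[1]]
    expect_gte(hi_s - lo_s, 0)
    expect_lte(hi_s - lo_s, ci_env$width + 1e-12)
  }
})

test_that("shape statistics match reference distributions and classify regions", {
  withr::with_seed(11, {
    z <- rnorm(2e5)
    expect_equal(sample_excess_kurtosis(z), 0, tolerance = 0.05)
    expect_equal(sample_skewness(z), 0, tolerance = 0.02)

    e <- rexp(2e5)
    s <- shape_stats(e, n_boot = 0)
    expect_equal(s$skewness, 2, tolerance = 0.1)
    expect_equal(s$region, "C")
  })

  s2 <- shape_stats(c(-1, -1, 1, 1), n_boot = 0)
  expect_equal(s2$skewness, 0)
  expect_equal(s2$region, "A")

  expect_equal(skewness_region(0.49), "A")
  expect_equal(skewness_region(-0.7), "B")
  expect_equal(skewness_region(1.01), "C")

  s0 <- shape_stats(rep(1, 10), n_boot = 10)
  expect_false(s0$defined)
})

test_that("bootstrap intervals are seeded, reproducible and cover the point estimate", {
  x <- withr::with_seed(2, rnorm(25, sd = 1.3))
  s1 <- shape_stats(x, n_boot = 300, seed = 9)
  s2 <- shape_stats(x, n_boot = 300, seed = 9)
  expect_identical(s1$skewness_ci, s2$skewness_ci)

  covered <- 0L
  cases <- withr::with_seed(4, replicate(40, rnorm(25), simplify = FALSE))
  for (i in seq_along(cases)) {
    s <- shape_stats(cases[[i]], n_boot = 200, seed = i)
    if (s$skewness >= s$skewness_ci[1] && s$skewness <= s$skewness_ci[2])
      covered <- covered + 1L
  }
  expect_gte(covered / 40, 0.99)
})

test_that("the three uncertainty views have the expected sizes and variances", {
  sp <- default_input_space()
  cfg <- mock_config(space = sp)
  tab <- evaluate_configurations(mock_esmacs_model(cfg), sp,
                                 sample_configurations(sp, 12, seed = 5), 1:8)
  dec <- ensemble_decomposition(tab)
  expect_equal(length(dec$raw), 96L)
  expect_equal(length(dec$per_seed_means), 8L)
  expect_equal(length(dec$per_config_means), 12L)
  expect_gte(var(dec$raw), var(dec$per_config_means))
  expect_gte(var(dec$raw), var(dec$per_seed_means))

  # energy depending only on the seed: epistemic view is constant
  tab_s <- make_table(1:5, 1:4, function(cfg, s) 10 + s)
  dec_s <- ensemble_decomposition(tab_s)
  expect_equal(var(dec_s$per_config_means), 0)

  # energy depending only on the configuration: aleatoric view is constant
  tab_c <- make_table(1:5, 1:4, function(cfg, s) 10 + cfg)
  dec_c <- ensemble_decomposition(tab_c)
  expect_equal(var(dec_c$per_seed_means), 0)
})

test_that("per-configuration shape report labels rows and writes CI bounds", {
  sp <- default_input_space()
  cfg <- mock_config(space = sp, seed_noise_skew = 6)
  tab <- evaluate_configurations(mock_esmacs_model(cfg), sp,
                                 sample_configurations(sp, 6, seed = 8), 1:25)
  rep_ <- shape_report(tab, n_boot = 100, seed = 3)
  expect_equal(nrow(rep_), 6L)
  expect_true(all(rep_$region %in% c("A", "B", "C")))
  expect_true(all(rep_$skewness_lo <= rep_$skewness))
  expect_true(all(rep_$skewness <= rep_$skewness_hi))
})
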