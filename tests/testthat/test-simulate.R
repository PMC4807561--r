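test_that("noiseless simulation is recovered exactly by the pipeline", {
  cfg <- simulation_config(n_genes = 120, noise_sd = 0, seed = 101)
  sim <- simulate_compact_data(cfg)
  m <- compact(sim$expression, reference = "carbohydrate",
               comparison = "ethanol")
  rec <- score_recovery(sim$truth, m)
  expect_equal(rec$fraction, 1.0)
  expect_equal(rec$n, 120L)
  expect_equal(nrow(rec$confusion), 0L)
  # cell-for-cell: planted spec counts equal the recovered matrix
  planted <- oracle_compact(setNames(as.list(sim$truth$ref), sim$truth$gene),
                            setNames(as.list(sim$truth$cmp), sim$truth$gene),
                            27L)
  expect_equal(unname(m$counts), planted)
})

test_that("explicit per-cell pattern specs are honoured and validated", {
  spec <- data.frame(ref = c(0L, 13L), cmp = c(26L, 0L), n = c(5L, 7L))
  cfg <- simulation_config(n_genes = 20, noise_sd = 0, pattern_spec = spec,
                           seed = 5)
  sim <- simulate_compact_data(cfg)
  m <- compact(sim$expression, reference = "carbohydrate",
               comparison = "ethanol")
  expect_equal(m$counts[1, 27], 5L)
  expect_equal(m$counts[14, 1], 7L)
  expect_equal(m$counts[14, 14], 8L)  # unassigned genes default to null/null

  bad <- data.frame(ref = 0L, cmp = 0L, n = 50L)
  expect_error(simulate_compact_data(
    simulation_config(n_genes = 20, pattern_spec = bad, seed = 1)),
    "exceed n_genes")

  # all-null planting puts every gene in the central diagonal cell
  sim0 <- simulate_compact_data(
    simulation_config(n_genes = 30, noise_sd = 0, pattern_spec = "null",
                      seed = 6))
  m0 <- compact(sim0$expression, reference = "carbohydrate",
                comparison = "ethanol")
  expect_equal(m0$counts[14, 14], 30L)
  expect_equal(sum(m0$counts), 30L)
})

test_that("simulation is reproducible from its seed", {
  cfg <- simulation_config(n_genes = 40, seed = 7)
  s1 <- simulate_compact_data(cfg)
  s2 <- simulate_compact_data(cfg)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(s1$truth$ref, s2$truth$ref)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  expect_identical(readLines(file.path(d1, "expression.tsv")),
                   readLines(file.path(d2, "expression.tsv")))
  # the written pair passes read validation and round-trips
  back <- read_expression_table(file.path(d1, "expression.tsv"),
                                file.path(d1, "annotation.tsv"))
  expect_equal(back$values, s1$expression$values, tolerance = 1e-9)
})

test_that("planted-effect bands keep truth inside its levels", {
  cfg <- simulation_config(n_genes = 200, noise_sd = 0, seed = 9)
  sim <- simulate_compact_data(cfg)
  eff <- attr(sim$truth, "effects")
  cut <- log2(cfg$fold_threshold)
  nonnull <- abs(eff) > cfg$null_ceiling + 1e-12
  expect_true(all(abs(eff[nonnull]) >= cut + cfg$effect_margin - 1e-12))
  expect_true(all(abs(eff[nonnull]) <= cut + 2 * cfg$effect_margin + 1e-12))
  expect_true(all(abs(eff[!nonnull]) <= cfg$null_ceiling + 1e-12))
})

test_that("recovery degrades with noise and improves with replicates", {
  frac <- function(noise, reps, seed) {
    sim <- simulate_compact_data(
      simulation_config(n_genes = 300, noise_sd = noise,
                        n_replicates = reps, seed = seed))
    m <- compact(sim$expression, reference = "carbohydrate",
                 comparison = "ethanol")
    score_recovery(sim$truth, m)$fraction
  }
  seeds <- 1:3
  lo_noise <- mean(vapply(seeds, function(s) frac(0.1, 4L, s), 1))
  hi_noise <- mean(vapply(seeds, function(s) frac(0.8, 4L, s), 1))
  expect_gt(lo_noise, hi_noise)
  few_reps <- mean(vapply(seeds, function(s) frac(0.5, 2L, s), 1))
  many_reps <- mean(vapply(seeds, function(s) frac(0.5, 8L, s), 1))
  expect_gt(many_reps, few_reps)
  # mistakes land adjacent in level space: recovered cells of miscalled
  # genes should still be mostly near-null shifts, not sign flips
  sim <- simulate_compact_data(
    simulation_config(n_genes = 500, noise_sd = 0.6, seed = 11))
  m <- compact(sim$expression, reference = "carbohydrate",
               comparison = "ethanol")
  rec <- score_recovery(sim$truth, m)
  expect_lt(rec$fraction, 1)
  expect_gt(sum(rec$confusion$count), 0)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(fold_threshold = 1), "fold_threshold")
  expect_error(simulation_config(null_ceiling = 0.7), "null_ceiling")
  expect_error(simulation_config(effect_margin = 0), "effect_margin")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(times = c(6, 1)), "strictly increasing")
})
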