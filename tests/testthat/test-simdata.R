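test_that("clone proportions are Dirichlet rows summing to one", {
  for (reg in c("decoy", "lump")) {
    rho <- sample_clone_proportions(5, m = 3, regime = reg, seed = 2)
    expect_equal(dim(rho), c(3, 5))
    expect_equal(rowSums(rho), rep(1, 3))
    expect_true(all(rho > 0))
  }
})

test_that("decoy shapes are systematically unequal, lump agglomerated", {
  # decoy expected shapes are (5, 10, ..., 5k): later clones get larger
  # proportions on average; lump proportions concentrate near 1/k
  k <- 5
  dec <- t(vapply(1:100, function(s) {
    sample_clone_proportions(k, 1, "decoy", seed = s)[1, ]
  }, numeric(k)))
  lum <- t(vapply(1:100, function(s) {
    sample_clone_proportions(k, 1, "lump", seed = s)[1, ]
  }, numeric(k)))
  expect_gt(mean(dec[, k]), mean(dec[, 1]))
  expect_lt(max(abs(colMeans(lum) - 1 / k)), 0.03)
  # decoy proportions are stochastically more dispersed than lump
  expect_gt(mean(apply(dec, 1, stats::sd)), mean(apply(lum, 1, stats::sd)))
})

test_that("false-variant VAF model matches its quadrature moments", {
  mom <- fv_vaf_moments(step = 1e-4)
  expect_lt(abs(mom$mean - 0.0282), 1e-3)
  expect_lt(abs(mom$median - 0.0258), 1e-3)
  # density is negligible beyond VAF 0.2 relative to 0.01
  expect_lt(fv_vaf_density(0.2) / fv_vaf_density(0.01), 1e-6)

  draws <- sample_false_variant_vafs(2e5, seed = 42)
  expect_lt(abs(mean(draws) - mom$mean), 1e-3)
  expect_lt(abs(stats::median(draws) - mom$median), 1e-3)
  expect_length(sample_false_variant_vafs(0), 0)
})

test_that("false-variant counts follow the configured fraction exactly", {
  sim <- generate_sim_dataset(sim_config(k = 3, m = 1, n = 500,
                                         fv_fraction = 0.10, seed = 5))
  expect_equal(sum(sim$truth$clone == "FV"), 50)
  expect_equal(sum(sim$truth$clone != "FV"), 450)
  sim2 <- generate_sim_dataset(sim_config(k = 3, m = 1, n = 500,
                                          fv_fraction = 0.025, seed = 5))
  expect_equal(sum(sim2$truth$clone == "FV"), 12)
})

test_that("per-clone mean VAF recovers half the clone proportion", {
  cfg <- sim_config(k = 3, m = 2, n = 600, seed = 8)
  sim <- generate_sim_dataset(cfg)
  F <- compute_vaf(sim$table)
  for (y in 1:3) {
    idx <- sim$truth$clone == paste0("C", y)
    n_y <- sum(idx)
    for (i in 1:2) {
      target <- sim$expected_vafs[i, y]
      se <- sqrt(target * (1 - target) / cfg$mean_depth / n_y)
      expect_lt(abs(mean(F[i, idx]) - target), 3 * se + 1e-4)
    }
  }
})

test_that("single fully clonal population sits at VAF one half", {
  sim <- generate_sim_dataset(sim_config(k = 1, m = 1, n = 200, seed = 9))
  expect_equal(unname(sim$expected_vafs[1, 1]), 0.5)
  expect_equal(mean(compute_vaf(sim$table)), 0.5, tolerance = 0.01)
})

test_that("generated datasets validate, partition and reproduce exactly", {
  cfg <- sim_config(k = 3, m = 2, n = 300, fv_fraction = 0.05, seed = 10)
  a <- generate_sim_dataset(cfg)
  b <- generate_sim_dataset(cfg)
  expect_identical(tibble::as_tibble(a$table), tibble::as_tibble(b$table))
  expect_identical(a$truth, b$truth)
  # labels partition all variants
  expect_equal(nrow(a$truth), 300)
  expect_true(all(a$truth$clone %in% c(paste0("C", 1:3), "FV")))
  # the table round-trips through the text format and validation
  dir <- withr::local_tempdir()
  write_sim_dataset(a, dir)
  vt <- read_variant_table(file.path(dir, "variants.tsv"))
  expect_identical(total_counts(vt), total_counts(a$table))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           col_types = readr::cols())
  expect_equal(truth$clone, a$truth$clone)
})

test_that("depth model floors at one read and honors the mean", {
  sim <- generate_sim_dataset(sim_config(k = 2, m = 1, n = 800,
                                         mean_depth = 30, depth_sd = 8,
                                         seed = 11))
  tot <- total_counts(sim$table)
  expect_true(all(tot >= 1))
  expect_equal(mean(tot), 30, tolerance = 1)
})
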