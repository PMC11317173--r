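test_that("clone-number RMSE matches hand arithmetic", {
  expect_equal(clone_number_rmse(c(2, 3), c(2, 3)), 0)
  expect_equal(clone_number_rmse(c(3, 5), c(2, 3)), sqrt(5 / 2))
  expect_equal(clone_number_rmse(4, 2), 2)
  expect_error(clone_number_rmse(1:3, 1:2), "equal-length")
})

test_that("ARI identities: equality, permutation, symmetry", {
  x <- rep(c("a", "b", "c"), times = c(10, 15, 5))
  expect_equal(adjusted_rand_index(x, x), 1)
  perm <- c(a = "z", b = "x", c = "y")[x]
  expect_equal(adjusted_rand_index(x, perm), 1)
  set.seed(3)
  y <- sample(c("p", "q"), length(x), replace = TRUE)
  expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
})

test_that("ARI matches the pair-counting formula on fixed tables", {
  # perfectly aligned 2x2 diagonal table
  ct <- list(u = rbind(c(10, 0), c(0, 10)), a = c(10, 10), p = c(10, 10),
             n = 20)
  expect_equal(adjusted_rand_index(ct), 1)
  # independent table: agreement at chance level; the finite-sample value
  # of the pair-counting formula is (40 - 8100/190) / (90 - 8100/190)
  ct0 <- list(u = rbind(c(5, 5), c(5, 5)), a = c(10, 10), p = c(10, 10),
              n = 20)
  expect_equal(adjusted_rand_index(ct0),
               (40 - 8100 / 190) / (90 - 8100 / 190))
  expect_lt(abs(adjusted_rand_index(ct0)), 0.06)
  # degenerate single-cluster-both-sides convention
  ct1 <- list(u = matrix(7, 1, 1), a = 7, p = 7, n = 7)
  expect_equal(adjusted_rand_index(ct1), 1)
})

test_that("ARI agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(11)
  for (trial in 1:10) {
    x <- sample(1:4, 60, replace = TRUE)
    y <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("membership score matches its worked examples", {
  # perfect prediction
  x <- rep(c("A", "B", "FV"), times = c(30, 60, 10))
  expect_equal(membership_score(x, x), 100)
  # off-diagonal confusion: best injection picks the diagonal
  ct <- list(u = rbind(c(40, 10), c(10, 40)), n = 100)
  expect_equal(membership_score(ct), 80)
  # one predicted cluster against two equal answer clusters
  truth <- rep(c("A", "B"), each = 50)
  pred <- rep("P", 100)
  expect_equal(membership_score(truth, pred), 50)
})

test_that("membership score is relabeling-invariant and bounded", {
  set.seed(13)
  truth <- sample(c("A", "B", "C"), 80, replace = TRUE)
  pred <- sample(c("x", "y", "z", "w"), 80, replace = TRUE)
  s1 <- membership_score(truth, pred)
  relabeled <- c(x = "q1", y = "q2", z = "q3", w = "q4")[pred]
  expect_equal(membership_score(truth, relabeled), s1)
  expect_gte(s1, 0)
  expect_lte(s1, 100)
})

test_that("assignment DP equals brute-force enumeration", {
  set.seed(17)
  for (trial in 1:25) {
    ka <- sample(2:6, 1)
    kp <- sample(2:8, 1)
    u <- matrix(rpois(ka * kp, 8), ka, kp)
    rownames(u) <- paste0("a", seq_len(ka))
    colnames(u) <- paste0("p", seq_len(kp))
    expect_equal(declone:::sm_assignment(u)$weight,
                 brute_force_injection(u))
  }
})

test_that("false-variant isolation follows match and recall rules", {
  truth <- rep(c("C1", "C2", "FV"), times = c(40, 40, 20))
  # perfect: isolated
  expect_true(fv_isolation_detected(truth, truth))
  # empty predicted FV set: not isolated
  pred_none <- ifelse(truth == "FV", "C1", truth)
  expect_false(fv_isolation_detected(pred_none, truth))
  # 60% recall with matched labels: isolated
  pred60 <- truth
  pred60[which(truth == "FV")[1:8]] <- "C1"
  expect_true(fv_isolation_detected(pred60, truth))
  # 40% recall: not isolated
  pred40 <- truth
  pred40[which(truth == "FV")[1:12]] <- "C1"
  expect_false(fv_isolation_detected(pred40, truth))
  # undefined without true false variants
  expect_true(is.na(fv_isolation_detected(truth, rep("C1", length(truth)))))
})

test_that("decomposition scoring wires predictions to the truth", {
  sim <- generate_sim_dataset(sim_config(k = 2, m = 1, n = 300, seed = 19))
  fit <- suppressWarnings(declone(sim$table, declone_config(seed = 19)))
  ev <- evaluate_decomposition(fit, sim$truth)
  expect_equal(ev$k_true, 2)
  expect_gte(ev$s_m, 0)
  expect_lte(ev$s_m, 100)
  expect_gte(ev$ari, -1)
  expect_true(is.na(ev$fv_isolated))
})
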