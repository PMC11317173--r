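test_that("subset enumeration is complete and deterministically ordered", {
  expect_length(enumerate_candidate_subsets(3), 7)
  expect_length(enumerate_candidate_subsets(1), 1)
  expect_length(enumerate_candidate_subsets(10), 1023)
  subs <- enumerate_candidate_subsets(3)
  expect_equal(subs[1:3], list(1L, 2L, 3L))
  expect_equal(subs[[4]], c(1L, 2L))
  expect_equal(subs[[7]], 1:3)
})

test_that("subclone rule passes at the exact null and rejects off-sum sets", {
  fix <- make_cluster_vafs(c(0.30, 0.20), n_per = 100, sd = 0.004, seed = 2)
  ok <- subclone_rule_test(fix$F, fix$Theta, c(1, 2))
  expect_true(ok$pass)
  expect_gt(ok$combined_p, 0.05)
  expect_lt(abs(ok$per_sample_t), 3)

  bad <- make_cluster_vafs(c(0.30, 0.30), n_per = 100, sd = 0.004, seed = 2)
  rej <- subclone_rule_test(bad$F, bad$Theta, c(1, 2))
  expect_false(rej$pass)
  expect_lt(rej$combined_p, 0.01)
  expect_gt(abs(rej$per_sample_t), 10)
})

test_that("subclone rule is invariant to cluster order within the subset", {
  fix <- make_cluster_vafs(c(0.25, 0.15, 0.10), n_per = 80, sd = 0.005,
                           seed = 3)
  a <- subclone_rule_test(fix$F, fix$Theta, c(1, 2, 3))
  b <- subclone_rule_test(fix$F, fix$Theta, c(3, 1, 2))
  expect_equal(a$pass, b$pass)
  expect_equal(a$combined_p, b$combined_p)
})

test_that("clusters with fewer than two members invalidate the subset", {
  F <- matrix(c(0.3, 0.2, 0.21, 0.19), nrow = 1)
  Theta <- onehot_theta(c(1, 2, 2, 2), 3L)
  t1 <- subclone_rule_test(F, Theta, c(1, 2))
  expect_false(t1$pass)
})

test_that("individual-clone selection maximizes the combined p-value", {
  fix <- make_cluster_vafs(c(0.30, 0.20, 0.28), n_per = 100, sd = 0.004,
                           seed = 4)
  tests <- lapply(enumerate_candidate_subsets(3), function(s) {
    subclone_rule_test(fix$F, fix$Theta, s)
  })
  best <- select_individual_clones(tests)
  expect_equal(best$cluster_subset, c(1L, 2L))

  # no passing subset is a restart signal
  bad <- make_cluster_vafs(c(0.1, 0.1), n_per = 100, sd = 0.003, seed = 5)
  tests_bad <- lapply(enumerate_candidate_subsets(2), function(s) {
    subclone_rule_test(bad$F, bad$Theta, s)
  })
  expect_null(select_individual_clones(tests_bad))
})

test_that("sum rule accepts the exact superclone sum and rejects others", {
  fix <- make_cluster_vafs(c(0.25, 0.15, 0.10), n_per = 100, sd = 0.004,
                           seed = 6)
  ok <- sum_rule_test(fix$F, fix$Theta, superclone = 1,
                      subclone_subset = c(2, 3))
  expect_true(ok$pass)

  far <- make_cluster_vafs(c(0.40, 0.15, 0.10), n_per = 100, sd = 0.004,
                           seed = 6)
  rej <- sum_rule_test(far$F, far$Theta, 1, c(2, 3))
  expect_false(rej$pass)
})

test_that("sum rule requires the null in every sample", {
  # sample 1 satisfies 0.25 = 0.15 + 0.10; sample 2 violates it
  set.seed(8)
  n_per <- 80
  F <- rbind(
    c(rnorm(n_per, 0.25, 0.004), rnorm(n_per, 0.15, 0.004),
      rnorm(n_per, 0.10, 0.004)),
    c(rnorm(n_per, 0.40, 0.004), rnorm(n_per, 0.15, 0.004),
      rnorm(n_per, 0.10, 0.004))
  )
  Theta <- onehot_theta(rep(1:3, each = n_per), 4L)
  rej <- sum_rule_test(F, Theta, 1, c(2, 3))
  expect_false(rej$pass)
})

test_that("phylogeny construction classifies ancestral clones", {
  fix <- make_cluster_vafs(c(0.25, 0.15, 0.10), n_per = 100, sd = 0.004,
                           seed = 9)
  st <- build_phylogeny(fix$F, fix$Theta, individual = c(2, 3))
  expect_s3_class(st, "clone_structure")
  expect_equal(st$individual, c(2L, 3L))
  expect_equal(st$ancestral, 1L)
  expect_equal(nrow(st$edges), 1)
  expect_equal(sort(st$edges$subclones[[1]]), c(2L, 3L))

  # two plain subclones: no ancestral clusters, no edges
  two <- make_cluster_vafs(c(0.30, 0.20), n_per = 100, sd = 0.004, seed = 10)
  st2 <- build_phylogeny(two$F, two$Theta, individual = c(1, 2))
  expect_equal(st2$ancestral, integer(0))
  expect_equal(nrow(st2$edges), 0)

  # an unexplainable leftover cluster signals a restart
  orphan <- make_cluster_vafs(c(0.07, 0.30, 0.20), n_per = 100, sd = 0.004,
                              seed = 11)
  expect_null(build_phylogeny(orphan$F, orphan$Theta, individual = c(2, 3)))
})

test_that("single clone at 0.5 stands alone as the individual set", {
  fix <- make_cluster_vafs(0.5, n_per = 120, sd = 0.005, seed = 12)
  st <- declone:::check_clone_structure(fix$F, fix$Theta, 0.01)
  expect_equal(st$individual, 1L)
  expect_equal(st$ancestral, integer(0))
})

test_that("exhaustive subset evaluation matches the fast selection path", {
  for (seed in 1:4) {
    means <- switch(seed,
                    c(0.25, 0.15, 0.10),
                    c(0.30, 0.12, 0.08, 0.42),
                    c(0.20, 0.20, 0.10),
                    c(0.45, 0.05, 0.28, 0.22, 0.50))
    fix <- make_cluster_vafs(means, n_per = 60, sd = 0.004, seed = seed)
    tests <- lapply(enumerate_candidate_subsets(length(means)), function(s) {
      subclone_rule_test(fix$F, fix$Theta, s)
    })
    slow <- select_individual_clones(tests)
    stats <- declone:::cluster_vaf_stats(fix$F, fix$Theta)
    fast <- declone:::best_individual_subset(stats, 0.01)
    if (is.null(slow)) {
      expect_null(fast)
    } else {
      expect_equal(slow$cluster_subset, sort(fast$subset))
      expect_equal(slow$combined_p, fast$combined_p, tolerance = 1e-12)
    }
  }
})
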