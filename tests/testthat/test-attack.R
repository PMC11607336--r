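# The attack framework: balancing arithmetic, features, the fold
# protocol, the five attackers, and suite reporting.

test_that("balancing keeps min(m, k) per class with exact leftovers", {
  set.seed(1)
  for (trial in 1:20) {
    m <- sample(3:40, 1); k <- sample(3:40, 1); L <- 4
    d <- membership_dataset(matrix(runif(m * L), m),
                            matrix(runif(k * L), k))
    b <- balance_attack_data(d, seed = trial)
    n <- min(m, k)
    expect_length(b$member_idx, n)
    expect_length(b$nonmember_idx, n)
    expect_false(anyDuplicated(b$member_idx) > 0)
    expect_false(anyDuplicated(b$nonmember_idx) > 0)
    expect_length(b$leftover_idx, abs(m - k))
    if (m > k) {
      expect_identical(b$leftover_group, "member")
      expect_setequal(c(b$member_idx, b$leftover_idx), seq_len(m))
    } else if (k > m) {
      expect_identical(b$leftover_group, "nonmember")
      expect_setequal(c(b$nonmember_idx, b$leftover_idx), seq_len(k))
    } else {
      expect_identical(b$leftover_group, "none")
    }
  }
})

test_that("feature mapping is identity or a descending sort", {
  v <- c(0.1, 0.9, 0.5)
  expect_equal(attack_features(v, multilabel = TRUE)[1, ], v)
  expect_equal(attack_features(v, multilabel = FALSE)[1, ],
               c(0.9, 0.5, 0.1))
  m <- rbind(c(0.2, 0.8), c(0.7, 0.1))
  expect_equal(attack_features(m[, 2:1], multilabel = FALSE),
               attack_features(m, multilabel = FALSE))
})

test_that("threshold attack scores are the mean confidence margin", {
  d <- membership_dataset(rbind(rep(0.5, 4), rep(1, 4)),
                          rbind(c(0.9, 0.1, 0.9, 0.1)))
  s <- threshold_attack(d)
  expect_equal(s$score[s$group == "member"], c(0, 0.5))
  expect_equal(s$score[s$group == "nonmember"], 0.4)
  expect_equal(nrow(s), 3)
})

test_that("every sample is scored exactly once, leftovers included", {
  set.seed(2)
  for (dims in list(c(23, 11), c(10, 10), c(9, 30))) {
    m <- dims[1]; k <- dims[2]
    d <- membership_dataset(matrix(runif(m * 6), m),
                            matrix(runif(k * 6), k))
    s <- run_trained_attack(d, "logistic", attack_config(seed = 3))
    expect_equal(nrow(s), m + k)
    expect_equal(sum(s$group == "member"), m)
    expect_equal(sum(s$group == "nonmember"), k)
    expect_false(anyDuplicated(s[, c("group", "index")]) > 0)
    expect_true(all(s$score >= 0 & s$score <= 1))
  }
})

test_that("degenerate fold requests are rejected", {
  d <- membership_dataset(matrix(runif(8), 2), matrix(runif(8), 2))
  expect_error(run_trained_attack(d, "logistic",
                                  attack_config(n_folds = 3, seed = 1)),
               "too few")
  expect_error(attack_config(n_folds = 1), ">= 2")
  expect_error(attack_config(attack_models = "oracle"))
})

test_that("trained attacks separate a confident-vs-diffuse construction", {
  # confidence-shaped leakage (members pushed to 0/1) is nonlinear in
  # the raw probabilities: the forest and the margin attack pick it up
  d <- separable_membership(m = 120, k = 120, L = 10, seed = 4)
  s <- run_trained_attack(d, "random_forest", attack_config(seed = 5))
  expect_gte(attack_metrics(s$score,
                            as.integer(s$group == "member"))$advantage,
             0.5)
  st <- threshold_attack(d)
  expect_gte(attack_metrics(st$score,
                            as.integer(st$group == "member"))$advantage,
             0.5)
  # a mean-shift construction is linearly separable: logistic finds it
  set.seed(6)
  d2 <- membership_dataset(matrix(runif(120 * 10, 0.3, 1), 120),
                           matrix(runif(120 * 10, 0, 0.7), 120))
  s2 <- run_trained_attack(d2, "logistic", attack_config(seed = 7))
  expect_gte(attack_metrics(s2$score,
                            as.integer(s2$group == "member"))$advantage,
             0.5)
})

test_that("suite reports one entry per configured model and a sane best", {
  d <- separable_membership(m = 40, k = 40, L = 6, seed = 6)
  cfg <- attack_config(attack_models = c("threshold", "logistic", "knn"),
                       seed = 7)
  rep_ <- run_attack_suite(d, cfg)
  expect_setequal(names(rep_$models), c("threshold", "logistic", "knn"))
  expect_true(rep_$best %in% names(rep_$models))
  expect_equal(rep_$best_advantage,
               max(vapply(rep_$models,
                          function(m) m$metrics$advantage, numeric(1))))
  for (m in rep_$models) expect_equal(nrow(m$scores), 80)

  cfg2 <- attack_config(attack_models = c("threshold", "logistic"),
                        seed = 7)
  rep2 <- run_attack_suite(d, cfg2)
  expect_setequal(names(rep2$models), c("threshold", "logistic"))
  expect_identical(rep2$models$threshold$scores, rep_$models$threshold$scores)
})

test_that("the five attackers are all runnable and seeded reproducibly", {
  d <- null_membership(m = 60, k = 60, L = 5, seed = 8)
  cfg <- attack_config(seed = 9)
  r1 <- run_attack_suite(d, cfg)
  r2 <- run_attack_suite(d, cfg)
  expect_setequal(names(r1$models),
                  c("threshold", "logistic", "knn", "random_forest", "mlp"))
  for (mt in names(r1$models)) {
    expect_identical(r1$models[[mt]]$scores, r2$models[[mt]]$scores)
  }
})
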