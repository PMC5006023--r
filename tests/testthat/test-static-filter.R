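test_that("sub-problem enumeration pairs typical points of every two stages", {
  sim <- generate_cohort(generator_config(seed = 1))
  des <- stage_design(c(H = 1, CIR = 4, HCC = 7), onset_point = 7,
                      lookback = 3)
  subs <- enumerate_subproblems(sim$dataset, des)
  expect_equal(nrow(subs), 3) # N_s(N_s - 1)/2 with N_s = 3
  expect_setequal(paste(subs$stage_a, subs$stage_b),
                  c("H CIR", "H HCC", "CIR HCC"))
  expect_equal(subs$time_b[subs$stage_a == "H" & subs$stage_b == "CIR"], 4)

  two <- generate_cohort(generator_config(n_time = 4,
                                          stage_map = c("A", "A", "B", "B"),
                                          shift_onset = 3, seed = 1))
  des2 <- stage_design(c(A = 2, B = 4), onset_point = 4, lookback = 2)
  expect_equal(nrow(enumerate_subproblems(two$dataset, des2)), 1)

  des_bad <- stage_design(c(H = 1, CIR = 4), onset_point = 7, lookback = 3)
  expect_error(enumerate_subproblems(sim$dataset, des_bad), "typical point")
})

test_that("N_s = 4 stages give 6 sub-problems", {
  sim <- generate_cohort(generator_config(
    n_time = 4, stage_map = c("A", "B", "C", "D"), shift_onset = 3, seed = 2))
  des <- stage_design(c(A = 1, B = 2, C = 3, D = 4), onset_point = 4,
                      lookback = 2)
  expect_equal(nrow(enumerate_subproblems(sim$dataset, des)), 6)
})

test_that("RFE ranks the informative feature on top across repeated runs", {
  withr::with_seed(99, {
    y <- rep(c(0, 1), each = 10)
    x <- cbind(f1 = y + rnorm(20, 0, 0.2),
               matrix(rnorm(20 * 4), 20, dimnames = list(NULL, paste0("f", 2:5))))
  })
  # oracle: single-feature CV accuracy puts f1 far ahead
  single_acc <- vapply(colnames(x), function(f) {
    folds <- withr::with_seed(1, dynratio:::stratified_folds(factor(y), 5))
    dynratio:::cv_accuracy(x[, f, drop = FALSE], factor(y), folds, 1)
  }, numeric(1))
  expect_equal(names(which.max(single_acc)), "f1")
  expect_gt(single_acc["f1"], max(single_acc[-1]))

  top <- vapply(1:50, function(r) {
    svm_rfe_rank(x, y, seed = r)$ranking[1]
  }, character(1))
  expect_gte(sum(top == "f1"), 45)
})

test_that("RFE boundary cases: one feature, separability, determinism", {
  y <- rep(c(0, 1), each = 5)
  x1 <- matrix(rnorm(10), 10, dimnames = list(NULL, "only"))
  res1 <- svm_rfe_rank(x1, y, seed = 1)
  expect_equal(res1$ranking, "only")
  expect_equal(nrow(res1$trace), 1)

  # f2 alone separates; f1 is noise -> best subset is exactly {f2}
  withr::with_seed(3, {
    f2 <- c(rnorm(5, -2, 0.1), rnorm(5, 2, 0.1))
    x2 <- cbind(f1 = rnorm(10), f2 = f2)
  })
  res2 <- svm_rfe_rank(x2, y, seed = 7)
  expect_equal(res2$best_subset, "f2")
  # oracle: exact CV accuracy of every subset with the same folds
  folds <- withr::with_seed(7, dynratio:::stratified_folds(factor(y), 5))
  accs <- vapply(list("f1", "f2", c("f1", "f2")), function(ss) {
    dynratio:::cv_accuracy(x2[, ss, drop = FALSE], factor(y), folds, 1)
  }, numeric(1))
  expect_equal(max(accs), accs[2]) # {f2} attains the maximum
  expect_equal(max(res2$trace$cv_accuracy), accs[2])

  expect_identical(svm_rfe_rank(x2, y, seed = 5)$ranking,
                   svm_rfe_rank(x2, y, seed = 5)$ranking)
  expect_error(svm_rfe_rank(x2, c(0, rep(1, 9)), seed = 1),
               "insufficient-data")
  expect_error(svm_rfe_rank(x2, y, elim_fraction = 1), "elim_fraction")
})

test_that("the retained union recovers the planted biomarker pair", {
  hits <- vapply(1:3, function(sd) {
    sim <- generate_cohort(generator_config(seed = sd))
    des <- stage_design(c(H = 1, CIR = 4, HCC = 7), onset_point = 7,
                        lookback = 3)
    kept <- retained_features(sim$dataset, des, n_repeats = 15, seed = sd)
    planted <- unlist(sim$truth$planted_pairs[c("feature_i", "feature_j")])
    all(planted %in% kept)
  }, logical(1))
  expect_true(all(hits))
})

test_that("retained_features is reproducible and rejects an empty union", {
  sim <- generate_cohort(generator_config(m = 12, seed = 2))
  des <- stage_design(c(H = 1, CIR = 4, HCC = 7), onset_point = 7,
                      lookback = 3)
  a <- retained_features(sim$dataset, des, n_repeats = 4, seed = 10)
  b <- retained_features(sim$dataset, des, n_repeats = 4, seed = 10)
  expect_identical(as.character(a), as.character(b))
  expect_identical(attr(a, "selection"), attr(b, "selection"))
  # canonical order
  expect_identical(as.character(a),
                   sim$dataset$features[sim$dataset$features %in% a])

  expect_error(
    retained_features(sim$dataset, des, n_repeats = 2,
                      selection_threshold = 1.01, seed = 1),
    "retained no feature"
  )
})

test_that("a pure-noise column does not evict informative features", {
  des <- stage_design(c(H = 1, CIR = 4, HCC = 7), onset_point = 7,
                      lookback = 3)
  ok <- vapply(1:10, function(sd) {
    sim <- generate_cohort(generator_config(m = 10, n_planted_pairs = 1,
                                            seed = sd))
    ds <- sim$dataset
    kept <- retained_features(ds, des, n_repeats = 5, seed = sd)
    planted <- unlist(sim$truth$planted_pairs[c("feature_i", "feature_j")])
    informative_kept <- intersect(kept, planted)

    aug <- ds$data
    aug$zz_noise <- withr::with_seed(1000 + sd,
                                     exp(rnorm(nrow(aug), 2, 0.1)))
    ds2 <- ts_dataset(aug, stage_map = ds$stage_map)
    kept2 <- retained_features(ds2, des, n_repeats = 5, seed = sd)
    all(informative_kept %in% kept2)
  }, logical(1))
  expect_gte(sum(ok), 9)
})
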