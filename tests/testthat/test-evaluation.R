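# two-group dataset where g1/g2 separates model from control at late points
eval_ds <- function(seed = 1, delta = 10, n_time = 4, noise = 0.05) {
  withr::with_seed(seed, {
    tab <- expand.grid(subject = sprintf("%s%d", rep(c("c", "m"), each = 5),
                                         1:5),
                       time = seq_len(n_time), stringsAsFactors = FALSE)
    tab$group <- ifelse(grepl("^c", tab$subject), "control", "model")
    late <- tab$time >= 3 & tab$group == "model"
    tab$g1 <- exp(1 + delta * 0.1 * late * (tab$time - 2) +
                    rnorm(nrow(tab), 0, noise))
    tab$g2 <- exp(1 + rnorm(nrow(tab), 0, noise))
    ts_dataset(tab, stage_map = rep(c("pre", "post"), each = n_time / 2))
  })
}

test_that("group tests: null gives p = 1 on mirrored data, shift gives tiny p", {
  # identical values in both groups -> t = 0, p = 1
  tab <- expand.grid(subject = sprintf("s%d", 1:6), time = 1,
                     stringsAsFactors = FALSE)
  tab$group <- rep(c("control", "model"), each = 3)
  tab$a <- rep(c(1, 2, 3), 2)
  tab$b <- 1
  ds <- ts_dataset(tab, stage_map = "S")
  gt <- group_tests(ds, c("a", "b"), stage_points = 1)
  expect_equal(gt$p_value, 1, tolerance = 1e-12)

  # 10-sigma shift: p below 1e-3, agreeing with a hand-computed Welch t
  ds2 <- eval_ds(delta = 10)
  gt2 <- group_tests(ds2, c("g1", "g2"), stage_points = 3:4)
  expect_true(all(gt2$p_value < 1e-3))
  rs <- ratio_series(ds2, "g1", "g2")
  m <- rs$value[rs$time == 3 & rs$group == "model"]
  cc <- rs$value[rs$time == 3 & rs$group == "control"]
  tstat <- (mean(m) - mean(cc)) / sqrt(var(m) / 5 + var(cc) / 5)
  expect_equal(abs(tstat),
               abs(stats::t.test(m, cc)$statistic[[1]]), tolerance = 1e-12)

  # a point with one group absent reports NA
  ds3 <- eval_ds()
  ds3$data <- ds3$data[!(ds3$data$group == "control" & ds3$data$time == 4), ]
  expect_warning(gt3 <- group_tests(ds3, c("g1", "g2"), stage_points = 4),
                 "insufficient")
  expect_true(is.na(gt3$p_value))
})

test_that("paired tests pair within subject and flag degenerate differences", {
  ds <- eval_ds(delta = 10)
  pt <- paired_tests(ds, c("g1", "g2"), reference_point = 2,
                     stage_points = 3:4)
  expect_equal(pt$n_pairs, c(5, 5))
  expect_true(all(pt$p_value < 0.05))

  # oracle: paired t closed form on the differences
  rs <- ratio_series(ds, "g1", "g2", group = "model")
  d3 <- rs$value[rs$time == 3] - rs$value[rs$time == 2]
  t_hand <- mean(d3) / (sd(d3) / sqrt(5))
  expect_equal(pt$p_value[1], 2 * stats::pt(-abs(t_hand), df = 4),
               tolerance = 1e-12)

  # identical paired values -> zero-variance differences, NA with flag
  tab <- expand.grid(subject = sprintf("s%d", 1:4), time = 1:2,
                     stringsAsFactors = FALSE)
  tab$group <- "model"
  tab$a <- rep(c(1, 2, 3, 4), 2)
  tab$b <- 1
  dsc <- ts_dataset(tab, stage_map = c("X", "Y"))
  ptc <- paired_tests(dsc, c("a", "b"), reference_point = 1, stage_points = 2)
  expect_true(is.na(ptc$p_value))
  expect_true(ptc$degenerate)

  # subjects missing at the reference point drop out of the pairing
  ds4 <- eval_ds()
  ds4$data <- ds4$data[!(ds4$data$subject == "m1" & ds4$data$time == 2), ]
  pt4 <- paired_tests(ds4, c("g1", "g2"), reference_point = 2,
                      stage_points = 3)
  expect_equal(pt4$n_pairs, 4)
})

test_that("the screen demands simultaneous significance and is monotone", {
  rep_tbl <- tibble::tibble(
    feature_i = rep(c("a", "a", "b"), each = 2),
    feature_j = rep(c("b", "c", "c"), each = 2),
    test = rep(c("group", "paired"), 3),
    p_value = c(0.01, 0.02, 0.03, 0.06, 0.01, NA)
  )
  sc <- screen_candidates(rep_tbl)
  expect_equal(sc$pass[sc$feature_i == "a" & sc$feature_j == "b"], TRUE)
  expect_equal(sc$pass[sc$feature_i == "a" & sc$feature_j == "c"], FALSE)
  expect_equal(sc$pass[sc$feature_i == "b"], FALSE)
  expect_match(sc$reason[sc$feature_i == "b"], "missing")

  # lowering any p-value never flips pass -> fail
  shrunk <- rep_tbl
  shrunk$p_value <- shrunk$p_value / 2
  sc2 <- screen_candidates(shrunk)
  expect_true(all(sc2$pass >= sc$pass, na.rm = TRUE))
})

test_that("AUC equals exhaustive pair counting, with Hanley-McNeil SE", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.85), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75) # 3 of 4 pairs concordant
  expect_equal(r$auc, auc_oracle(c(0.9, 0.8), c(0.7, 0.85)))

  # perfect separation
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)

  # randomized datasets up to 50 samples, with ties
  withr::with_seed(21, {
    for (rep in 1:20) {
      n <- sample(4:50, 1)
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
      r <- roc_auc(scores, labels)
      expect_equal(r$auc, auc_oracle(scores[labels], scores[!labels]))
      # complement symmetry
      expect_equal(roc_auc(-scores, labels)$auc, 1 - r$auc)
      # independent cross-check against pROC
      if (requireNamespace("pROC", quietly = TRUE)) {
        expect_equal(r$auc,
                     as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                    quiet = TRUE,
                                                    direction = "<"))))
      }
    }
  })

  # Hanley-McNeil SE at a hand value
  r2 <- roc_auc(c(0.9, 0.8, 0.7, 0.85), c(TRUE, TRUE, FALSE, FALSE))
  a <- 0.75; q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  expect_equal(r2$se, sqrt((a * (1 - a) + (q1 - a^2) + (q2 - a^2)) / 4))

  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})

test_that("the Youden cut-off maximizes J with ties toward specificity", {
  r <- roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$cutoff, 10) # score >= cutoff is called positive

  # near-null labels give AUC near 0.5
  withr::with_seed(5, {
    sc <- rnorm(400)
    lab <- sample(rep(c(TRUE, FALSE), 200))
  })
  expect_lt(abs(roc_auc(sc, lab)$auc - 0.5), 0.1)
})

test_that("PCA summary reports variance explained on autoscaled data", {
  # rank-1 latent structure -> PC1 close to everything
  withr::with_seed(2, {
    z <- rnorm(30)
    x1 <- cbind(z, 2 * z, -z) + matrix(rnorm(90, 0, 1e-8), 30)
  })
  p1 <- pca_summary(x1)
  expect_gt(p1$var_explained[1], 0.999)

  # i.i.d. noise: PC1+PC2 near 2/10 of the variance
  withr::with_seed(3, x2 <- matrix(rnorm(1000), 100, 10))
  p2 <- pca_summary(x2)
  expect_lt(abs(p2$cum_pc12 - 0.2), 0.1)

  expect_warning(pca_summary(cbind(x2, const = 1)), "constant")
  expect_error(pca_summary(x2[1:2, ]), ">= 3 samples")
})

test_that("trajectories report group means with standard errors", {
  tab <- expand.grid(subject = sprintf("s%d", 1:3), time = 1:2,
                     stringsAsFactors = FALSE)
  tab$group <- "model"
  tab$a <- c(1, 2, 3, 4, 4, 4)
  tab$b <- 1
  ds <- ts_dataset(tab, stage_map = c("X", "Y"))
  tr <- trajectory_summary(ds, c("a", "b"))
  expect_equal(tr$mean[tr$time == 1], 2)
  expect_equal(tr$se[tr$time == 1], sd(1:3) / sqrt(3), tolerance = 1e-6)
  expect_equal(tr$se[tr$time == 2], 0)

  tab1 <- tab[tab$subject == "s1" | tab$time == 1, ]
  ds1 <- suppressWarnings(ts_dataset(tab1, stage_map = c("X", "Y")))
  tr1 <- trajectory_summary(ds1, c("a", "b"))
  expect_true(is.na(tr1$se[tr1$time == 2]))
})

test_that("candidate evaluation assembles screen plus ROC per ratio", {
  ds <- eval_ds(delta = 10)
  subset <- tibble::tibble(feature_i = "g1", feature_j = "g2")
  rep_ <- evaluate_candidates(ds, subset, stage_points = 3:4,
                              reference_point = 2)
  expect_equal(nrow(rep_), 1)
  expect_true(rep_$pass)
  expect_gt(rep_$auc, 0.9)
  tests <- attr(rep_, "tests")
  expect_equal(nrow(tests), 4) # 2 group + 2 paired
  roc <- attr(rep_, "roc")[["g1/g2"]]
  expect_s3_class(roc, "roc_result")
  # positives are the model samples at stage points, negatives pre-stage
  expect_equal(roc$n_pos, 10)
  expect_equal(roc$n_neg, 10)
})
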