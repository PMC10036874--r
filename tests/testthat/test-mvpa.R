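test_that("feature selection keeps the top-k training voxels with a stable tie-break", {
  X <- matrix(rnorm(20 * 248), 20, 248)
  pd <- make_pd(X, rep(c("CSplus", "CSminus"), 10))
  expect_equal(select_features(pd, "all_roi_voxels"), 1:248)

  # k largest mean absolute signal, training data only
  X2 <- matrix(0.1, 10, 5)
  X2[, 2] <- 3; X2[, 4] <- 2
  pd2 <- make_pd(X2, rep(c("CSplus", "CSminus"), 5))
  expect_equal(select_features(pd2, "top_k_univariate", k = 2), c(2, 4))

  # exact ties straddling the cutoff retain the lowest voxel index
  X3 <- cbind(rep(1, 10), rep(2, 10), rep(2, 10), rep(0.5, 10))
  pd3 <- make_pd(X3, rep(c("CSplus", "CSminus"), 5))
  expect_equal(select_features(pd3, "top_k_univariate", k = 2), c(2, 3))
  expect_equal(select_features(pd3, "top_k_univariate", k = 3), c(2, 3, 1))

  expect_error(select_features(pd3, "top_k_univariate", k = 300), "exceeds")
  pd500 <- make_pd(matrix(rnorm(10 * 500), 10, 500), rep(c("CSplus", "CSminus"), 5))
  expect_length(select_features(pd500, "top_k_univariate", k = 300), 300)
})

test_that("cross-classification is perfect on separable data and inverted on swapped labels", {
  u <- rnorm(40)
  signal <- outer(rep(c(1, -1), each = 10), u)
  pd <- make_pd(signal + matrix(rnorm(20 * 40, 0, 0.01), 20, 40),
                rep(c("CSplus", "CSminus"), each = 10))
  self <- cross_classify(pd, pd)
  expect_equal(self$accuracy, 1)
  expect_length(self$decision, 20)

  # test set with class means swapped: the classifier is anti-aligned
  swapped <- make_pd(-signal, rep(c("CSplus", "CSminus"), each = 10))
  expect_lte(cross_classify(pd, swapped)$accuracy, 0.5)

  one_class <- make_pd(signal, rep("CSplus", 20))
  expect_error(cross_classify(one_class, pd), "single class")
  empty <- pattern_dataset(signal[0, , drop = FALSE],
                           data.frame(cs_type = character(0)), "p01")
  expect_error(cross_classify(pd, empty), "empty")
})

test_that("the max-margin classifier agrees with an independent SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(14)
  diffs <- replicate(30, {
    ytr <- rep(c(1, -1), each = 12)
    u <- rnorm(60, 0, 0.3)
    Xtr <- matrix(rnorm(24 * 60), 24, 60) + outer(ytr, u)
    Xte <- matrix(rnorm(24 * 60), 24, 60) + outer(ytr, u)
    tr <- make_pd(Xtr, ifelse(ytr > 0, "CSplus", "CSminus"))
    te <- make_pd(Xte, ifelse(ytr > 0, "CSplus", "CSminus"))
    acc <- cross_classify(tr, te)$accuracy
    m <- e1071::svm(Xtr, factor(ytr), kernel = "linear", cost = 1, scale = FALSE)
    acc_ref <- mean(as.numeric(as.character(predict(m, Xte))) == ytr)
    c(acc, acc_ref)
  })
  expect_lt(mean(abs(diffs[1, ] - diffs[2, ])), 0.05)
  expect_lt(max(abs(diffs[1, ] - diffs[2, ])), 0.2)
})

test_that("permutation nulls are seeded, chance-centred, and reduce to the observed accuracy under the identity permutation", {
  cfg <- synth_config(n_participants = 2, pattern_effect = 1)
  p <- simulate_participant(cfg, "p01", seed = 3)
  tr <- subset_patterns(p$patterns$imagery_acquisition, modality = "imagine")
  te <- subset_patterns(p$patterns$visual_acquisition, modality = "view")
  nv <- participant_null(tr, te, n_perm = 400, seed = 5)
  expect_length(nv, 400)
  expect_true(all(nv >= 0 & nv <= 1))
  expect_equal(mean(nv), 0.5, tolerance = 0.03)
  expect_identical(nv, participant_null(tr, te, n_perm = 400, seed = 5))

  # identity permutation reproduces the observed accuracy exactly
  y <- ifelse(tr$labels$cs_type == "CSplus", 1, -1)
  Ktr <- tcrossprod(tr$X) + 1
  Kx <- te$X %*% t(tr$X) + 1
  yte <- ifelse(te$labels$cs_type == "CSplus", 1, -1)
  acc_id <- fearcond:::svm_perm_acc_cpp(Ktr, Kx, y, yte,
                                        matrix(seq_along(y), 1), 1)
  expect_equal(as.numeric(acc_id), cross_classify(tr, te)$accuracy)
})

test_that("the group bootstrap null matches its closed-form moments", {
  # degenerate nulls: the group null is constant
  nulls <- matrix(0.5, 5, 100)
  g <- group_bootstrap_null(nulls, n_boot = 50, seed = 1)
  expect_length(g, 50)
  expect_true(all(g == 0.5))

  set.seed(2)
  nulls <- matrix(rnorm(6 * 2000, 0.5, 0.1), 6, 2000)
  g <- group_bootstrap_null(nulls, n_boot = 4000, seed = 3)
  expect_equal(mean(g), mean(rowMeans(nulls)), tolerance = 0.005)
  # var of the mean of independent draws = mean participant variance / n
  v_exp <- mean(apply(nulls, 1, var)) / 6
  expect_lt(abs(var(g) - v_exp), 0.15 * v_exp)

  expect_error(group_bootstrap_null(matrix(0.5, 1, 10)), "2 participants")
  expect_error(group_bootstrap_null(list()), "2 participants")
})

test_that("empirical p-values use the add-one estimator", {
  null <- seq(0, 1, length.out = 9999)
  expect_equal(empirical_p(2, null), 1e-4)        # above every draw
  expect_equal(empirical_p(-1, null), 1)          # below every draw
  expect_equal(empirical_p(median(null), null), 0.5, tolerance = 0.01)
  expect_true(empirical_p(0.5, c(0.4, 0.6)) > 0)
})

test_that("the two-level group inference is deterministic and chance-anchored", {
  cfg <- synth_config(n_participants = 4, pattern_effect = 0)
  r1 <- run_crossclass_experiment(cfg, n_perm = 120, n_boot = 120, seed = 21)
  r2 <- run_crossclass_experiment(cfg, n_perm = 120, n_boot = 120, seed = 21)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$group_null, r2$group_null)
  expect_equal(mean(r1$group_null), 0.5, tolerance = 0.02)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  expect_equal(r1$group_mean, mean(r1$participant_accuracy))
})
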