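## ROI multivoxel cross-classification: linear max-margin decoding of
## CS+ vs CS- with per-participant label-permutation nulls and a
## group-level bootstrap null.

cs_sign <- function(cs_type) ifelse(cs_type == "CSplus", 1, -1)

#' Select classifier feature voxels
#'
#' Either all ROI voxels, or the `k` voxels with the largest univariate
#' signal (mean absolute parameter estimate) computed on the *training*
#' trials only, so no information from the test set leaks into feature
#' selection. Ties at the cutoff keep the lowest voxel index.
#'
#' @param train a `pattern_dataset` of training trials.
#' @param rule `"all_roi_voxels"` or `"top_k_univariate"`.
#' @param k number of voxels retained under the top-k rule.
#' @return Integer vector of voxel indices.
#' @export
select_features <- function(train, rule = c("all_roi_voxels", "top_k_univariate"),
                            k = 300) {
  rule <- match.arg(rule)
  n_vox <- ncol(train$X)
  if (rule == "all_roi_voxels") return(seq_len(n_vox))
  stopifnot(k >= 1)
  if (k > n_vox)
    stop(sprintf("k = %d exceeds the %d ROI voxels", k, n_vox), call. = FALSE)
  score <- colMeans(abs(train$X))
  order(-score, seq_len(n_vox))[seq_len(k)]
}

gram_pair <- function(Xtr, Xte) {
  list(train = tcrossprod(Xtr) + 1,                 # +1 absorbs the bias
       cross = Xte %*% t(Xtr) + 1)
}

#' Train-on-one-set, test-on-another linear SVM classification
#'
#' Trains a linear maximum-margin classifier (hinge loss, fixed cost `C`)
#' on the training patterns' CS labels and reports the fraction of test
#' trials classified correctly. Training and testing sets are distinct
#' trial sets (e.g. imagine trials of the imagery acquisition phase vs
#' view trials of the visual acquisition phase).
#'
#' @param train,test `pattern_dataset` objects with a `cs_type` label.
#' @param features voxel indices to use (default all; see
#'   [select_features()]).
#' @param cost SVM regularisation constant C.
#' @return List with `accuracy`, `decision` values, `predicted` labels,
#'   `n_train`, `n_test`.
#' @export
cross_classify <- function(train, test, features = NULL, cost = 1) {
  y_tr <- cs_sign(train$labels$cs_type)
  y_te <- cs_sign(test$labels$cs_type)
  if (length(unique(y_tr)) < 2)
    stop("training set contains a single class", call. = FALSE)
  if (length(y_te) == 0) stop("test set is empty", call. = FALSE)
  if (is.null(features)) features <- seq_len(ncol(train$X))
  Ks <- gram_pair(train$X[, features, drop = FALSE],
                  test$X[, features, drop = FALSE])
  f <- svm_decision_cpp(Ks$train, Ks$cross, y_tr, cost)
  pred <- ifelse(f > 0, "CSplus", "CSminus")
  list(accuracy = mean(pred == test$labels$cs_type),
       decision = f, predicted = pred,
       n_train = length(y_tr), n_test = length(y_te))
}

#' Per-participant label-permutation null distribution
#'
#' Repeats the cross-classification `n_perm` times with the *training*
#' labels permuted uniformly at random (test labels untouched), recording
#' the test accuracy of each retrained classifier.
#'
#' @inheritParams cross_classify
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return Numeric vector of length `n_perm` of null accuracies.
#' @export
participant_null <- function(train, test, n_perm = 10000, seed = 1L,
                             features = NULL, cost = 1) {
  stopifnot(n_perm >= 1)
  y_tr <- cs_sign(train$labels$cs_type)
  y_te <- cs_sign(test$labels$cs_type)
  if (is.null(features)) features <- seq_len(ncol(train$X))
  Ks <- gram_pair(train$X[, features, drop = FALSE],
                  test$X[, features, drop = FALSE])
  with_local_seed(seed, {
    perms <- t(vapply(seq_len(n_perm),
                      function(i) sample.int(length(y_tr)),
                      integer(length(y_tr))))
    as.numeric(svm_perm_acc_cpp(Ks$train, Ks$cross, y_tr, y_te, perms, cost))
  })
}

#' Group-level bootstrap null of mean accuracy
#'
#' Each bootstrap iteration draws, uniformly with replacement, one
#' accuracy from every participant's permutation null and records the
#' across-participant mean, building the null distribution of the group
#' mean accuracy.
#'
#' @param per_participant_nulls matrix (participants x permutations) or
#'   list of equal-length numeric vectors.
#' @param n_boot number of bootstrap iterations.
#' @param seed integer seed.
#' @return Numeric vector of length `n_boot` of null group means.
#' @export
group_bootstrap_null <- function(per_participant_nulls, n_boot = 10000,
                                 seed = 1L) {
  if (is.list(per_participant_nulls))
    per_participant_nulls <- do.call(rbind, per_participant_nulls)
  if (is.null(dim(per_participant_nulls)) ||
      nrow(per_participant_nulls) < 2 || ncol(per_participant_nulls) < 1)
    stop("need permutation nulls (equal length) from at least 2 participants",
         call. = FALSE)
  n_p <- nrow(per_participant_nulls)
  n_perm <- ncol(per_participant_nulls)
  with_local_seed(seed, {
    idx <- matrix(sample.int(n_perm, n_p * n_boot, replace = TRUE), n_p, n_boot)
    vals <- matrix(per_participant_nulls[cbind(rep(seq_len(n_p), n_boot),
                                               as.vector(idx))],
                   n_p, n_boot)
    colMeans(vals)
  })
}

#' One-sided empirical p-value against a null distribution
#'
#' Add-one (rank) estimator: `p = (1 + #\{null >= observed\}) / (1 + n)`,
#' testing for accuracy above chance; never returns exactly zero.
#'
#' @param observed observed group mean accuracy.
#' @param group_null numeric null vector.
#' @return p-value in (0, 1].
#' @export
empirical_p <- function(observed, group_null) {
  stopifnot(length(group_null) > 0)
  (1 + sum(group_null >= observed)) / (1 + length(group_null))
}

#' Full two-level cross-classification inference for a group
#'
#' For every participant: select features on the training set, classify,
#' and build the label-permutation null; then aggregate the per-participant
#' nulls into the group bootstrap null and compare the observed group mean
#' accuracy to it.
#'
#' @param train_list,test_list lists of `pattern_dataset`s, one pair per
#'   participant (training and held-out testing trial sets).
#' @param n_perm permutations per participant.
#' @param n_boot group bootstrap iterations.
#' @param seed integer seed (per-participant seeds are derived from it).
#' @param feature_rule,k see [select_features()].
#' @param cost SVM cost.
#' @return A `crossclass_result`: per-participant accuracies, group mean,
#'   group null vector, empirical p, and the resampling sizes.
#' @export
crossclass_group <- function(train_list, test_list, n_perm = 10000,
                             n_boot = 10000, seed = 1L,
                             feature_rule = "all_roi_voxels", k = 300,
                             cost = 1) {
  stopifnot(length(train_list) == length(test_list), length(train_list) >= 2)
  n_p <- length(train_list)
  acc <- numeric(n_p)
  nulls <- matrix(NA_real_, n_p, n_perm)
  for (i in seq_len(n_p)) {
    feats <- select_features(train_list[[i]], feature_rule, k)
    acc[i] <- cross_classify(train_list[[i]], test_list[[i]],
                             features = feats, cost = cost)$accuracy
    nulls[i, ] <- participant_null(train_list[[i]], test_list[[i]],
                                   n_perm = n_perm,
                                   seed = derive_seed(seed, paste0("perm-", i)),
                                   features = feats, cost = cost)
  }
  gnull <- group_bootstrap_null(nulls, n_boot = n_boot,
                                seed = derive_seed(seed, "boot"))
  structure(list(
    participant_accuracy = acc,
    group_mean = mean(acc),
    participant_nulls = nulls,
    group_null = gnull,
    p_value = empirical_p(mean(acc), gnull),
    n_perm = n_perm, n_boot = n_boot, seed = seed), class = "crossclass_result")
}

#' @export
print.crossclass_result <- function(x, ...) {
  cat(sprintf(paste0("<crossclass_result> n = %d participants\n",
                     "  group mean accuracy %.3f (null mean %.3f), p = %.4g\n",
                     "  n_perm = %d, n_boot = %d\n"),
              length(x$participant_accuracy), x$group_mean,
              mean(x$group_null), x$p_value, x$n_perm, x$n_boot))
  invisible(x)
}

#' Simulate a group and run one cross-classification analysis
#'
#' Convenience wrapper: simulates `n_participants` synthetic participants
#' under `config`, extracts the requested training and testing trial sets
#' (phase and modality selectors), and runs [crossclass_group()].
#'
#' @param config a [synth_config()].
#' @param train,test character vectors `c(phase, modality)`, e.g.
#'   `c("imagery_acquisition", "imagine")`.
#' @param n_participants group size (default from `config`).
#' @param n_perm,n_boot resampling sizes.
#' @param seed integer seed.
#' @param feature_rule,k see [select_features()].
#' @return A `crossclass_result`.
#' @export
run_crossclass_experiment <- function(config,
                                      train = c("imagery_acquisition", "imagine"),
                                      test = c("visual_acquisition", "view"),
                                      n_participants = config$n_participants,
                                      n_perm = 500, n_boot = 500, seed = 1L,
                                      feature_rule = "all_roi_voxels", k = 300) {
  train_list <- vector("list", n_participants)
  test_list <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    pid <- sprintf("p%02d", i)
    part <- simulate_participant(config, pid,
                                 seed = derive_seed(seed, paste0("part-", pid)))
    train_list[[i]] <- subset_patterns(part$patterns[[train[1]]],
                                       modality = train[2])
    test_list[[i]] <- subset_patterns(part$patterns[[test[1]]],
                                      modality = test[2])
  }
  crossclass_group(train_list, test_list, n_perm = n_perm, n_boot = n_boot,
                   seed = seed, feature_rule = feature_rule, k = k)
}
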