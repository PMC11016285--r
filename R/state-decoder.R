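# feature columns for a decoder feature set: value + 10-trial SD per measure
decoder_columns <- function(feature_set = c("measures", "movement_index")) {
  feature_set <- match.arg(feature_set)
  if (feature_set == "measures")
    c("pupil", "pupil_sd10", "face", "face_sd10",
      "locomotion", "locomotion_sd10")
  else
    c("pupil", "pupil_sd10", "movement_index", "movement_index_sd10")
}

# median-pairwise-distance RBF bandwidth -> e1071 gamma
median_heuristic_gamma <- function(X) {
  n <- nrow(X)
  idx <- if (n > 400) sample.int(n, 400) else seq_len(n)
  d <- stats::dist(X[idx, , drop = FALSE])
  med <- stats::median(d)
  if (!is.finite(med) || med <= 0) med <- 1
  1 / (2 * med^2)
}

svm_fold_accuracy <- function(X_tr, y_tr, X_te, y_te, cost, gamma) {
  fit <- e1071::svm(X_tr, factor(y_tr), kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  mean(as.character(stats::predict(fit, X_te)) == y_te)
}

# balanced, class-stratified fold assignment; returns per-trial fold id
stratified_folds <- function(y, folds) {
  fold_of <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold_of[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds),
                                                     length(idx))
  }
  fold_of
}

decode_core <- function(X, y, folds, cost, n_shuffles, seed,
                        permute_cols = NULL) {
  set.seed(derive_seed(seed, 1L))
  fold_of <- stratified_folds(y, folds)
  fold_sets <- lapply(seq_len(folds), function(f) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    # standardization from training-fold statistics only
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1
    X_tr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    X_te <- sweep(sweep(X[te, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    if (!is.null(permute_cols)) {
      # feature-subset surrogate: shuffle excluded features across training
      # trials only; the test set is untouched
      for (cc in permute_cols)
        X_tr[, cc] <- X_tr[sample.int(nrow(X_tr)), cc]
    }
    list(X_tr = X_tr, y_tr = y[tr], X_te = X_te, y_te = y[te],
         gamma = median_heuristic_gamma(X_tr))
  })

  acc <- mean(vapply(fold_sets, function(fs)
    svm_fold_accuracy(fs$X_tr, fs$y_tr, fs$X_te, fs$y_te, cost, fs$gamma),
    numeric(1)))

  shuffled <- vapply(seq_len(n_shuffles), function(r) {
    mean(vapply(fold_sets, function(fs) {
      y_sh <- fs$y_tr[sample.int(length(fs$y_tr))]
      svm_fold_accuracy(fs$X_tr, y_sh, fs$X_te, fs$y_te, cost, fs$gamma)
    }, numeric(1)))
  }, numeric(1))

  z <- (acc - mean(shuffled)) / stats::sd(shuffled)
  list(accuracy = acc, z = z, shuffled = shuffled,
       n_test_total = length(y))
}

#' Decode performance state from arousal features
#'
#' Binary classification of optimal-state trials against one other
#' stereotype with an RBF-kernel support vector machine, using the
#' pre-stimulus value and 10-trial rolling SD of each measure as features.
#' Classes are balanced by seeded subsampling to the minority count;
#' features are standardized with training-fold statistics only; accuracy
#' is the mean over 5 stratified test folds, and significance is the
#' z-score of that accuracy against classifiers retrained on
#' training-label-permuted surrogates.
#'
#' @param features per-trial feature data.frame from [trial_features()].
#' @param labels per-trial stereotype labels.
#' @param comparison the stereotype to discriminate from `"optimal"`
#'   (e.g. `"disengaged"`, `"bias_left"`).
#' @param feature_set `"measures"` (six features) or `"movement_index"`
#'   (four features; index value + index SD replace face and locomotion).
#' @param n_shuffles label-permutation replicates (default 1000).
#' @param folds cross-validation folds (default 5).
#' @param cost SVM regularization constant (default 1).
#' @param seed integer seed (subsampling, folds, shuffles).
#' @param min_per_class minimum complete trials per class (default 25).
#' @param max_per_class cap on balanced per-class trial count; classes larger
#'   than this are subsampled down to it (default `Inf`).
#' @return Object of class `decoder_result`: `accuracy`, `z`, `n_per_class`,
#'   `shuffled` (null accuracies), `comparison`, `feature_set`.
#' @export
decode_state <- function(features, labels, comparison = "disengaged",
                         feature_set = c("measures", "movement_index"),
                         n_shuffles = 1000, folds = 5, cost = 1, seed = 1,
                         min_per_class = 25, max_per_class = Inf) {
  feature_set <- match.arg(feature_set)
  cols <- decoder_columns(feature_set)
  abort_if(!all(cols %in% names(features)),
           "features are missing decoder columns")
  X_all <- as.matrix(features[, cols])
  ok <- stats::complete.cases(X_all)
  cls <- labels %in% c("optimal", comparison) & ok
  y <- labels[cls]
  X <- X_all[cls, , drop = FALSE]
  n_min <- min(table(factor(y, levels = c("optimal", comparison))))
  if (n_min < min_per_class) {
    warning(sprintf("fewer than %d complete trials in a class; skipping",
                    min_per_class), call. = FALSE)
    return(NULL)
  }
  n_min <- min(n_min, max_per_class)
  set.seed(derive_seed(seed, 0L))
  keep <- unlist(lapply(c("optimal", comparison), function(g) {
    idx <- which(y == g)
    sort(sample(idx, n_min))
  }))
  res <- decode_core(X[keep, , drop = FALSE], y[keep], folds, cost,
                     n_shuffles, seed)
  structure(list(accuracy = res$accuracy, z = res$z,
                 n_per_class = n_min, shuffled = res$shuffled,
                 comparison = comparison, feature_set = feature_set),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("State decoder optimal vs %s: accuracy %.1f%%, z = %.1f (n = %d/class)\n",
              x$comparison, 100 * x$accuracy, x$z, x$n_per_class))
  invisible(x)
}

#' Feature-subset contribution to state decoding
#'
#' Re-runs the state decoder with all features outside `keep_set` permuted
#' across trials within each training fold (test folds untouched),
#' isolating the information carried by the kept measures. Each kept
#' measure contributes its pre-stimulus value and its 10-trial SD.
#'
#' @param features,labels,comparison,n_shuffles,folds,cost,seed,min_per_class
#'   as in [decode_state()].
#' @param max_per_class cap on balanced per-class trial count, as in
#'   [decode_state()].
#' @param keep_set subset of `c("pupil", "face", "locomotion",
#'   "movement_index")` to keep intact. Including `"movement_index"`
#'   switches to the four-feature movement-index set.
#' @return A `decoder_result` for the kept subset.
#' @export
feature_contribution <- function(features, labels, comparison = "disengaged",
                                 keep_set, n_shuffles = 1000, folds = 5,
                                 cost = 1, seed = 1, min_per_class = 25,
                                 max_per_class = Inf) {
  abort_if(missing(keep_set) || length(keep_set) == 0,
           "keep_set must name at least one measure")
  all_measures <- c("pupil", "face", "locomotion", "movement_index")
  abort_if(!all(keep_set %in% all_measures),
           "keep_set must be a subset of pupil/face/locomotion/movement_index")
  feature_set <- if ("movement_index" %in% keep_set) "movement_index"
                 else "measures"
  cols <- decoder_columns(feature_set)
  keep_cols <- unlist(lapply(keep_set, function(m) c(m, paste0(m, "_sd10"))))
  permute_cols <- setdiff(cols, keep_cols)

  X_all <- as.matrix(features[, cols])
  ok <- stats::complete.cases(X_all)
  cls <- labels %in% c("optimal", comparison) & ok
  y <- labels[cls]
  X <- X_all[cls, , drop = FALSE]
  n_min <- min(table(factor(y, levels = c("optimal", comparison))))
  if (n_min < min_per_class) {
    warning("fewer complete trials than the per-class minimum; skipping",
            call. = FALSE)
    return(NULL)
  }
  n_min <- min(n_min, max_per_class)
  set.seed(derive_seed(seed, 0L))
  keep <- unlist(lapply(c("optimal", comparison), function(g) {
    idx <- which(y == g)
    sort(sample(idx, n_min))
  }))
  res <- decode_core(X[keep, , drop = FALSE], y[keep], folds, cost,
                     n_shuffles, seed,
                     permute_cols = if (length(permute_cols)) permute_cols
                                    else NULL)
  structure(list(accuracy = res$accuracy, z = res$z, n_per_class = n_min,
                 shuffled = res$shuffled, comparison = comparison,
                 feature_set = feature_set, keep_set = keep_set),
            class = "decoder_result")
}
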