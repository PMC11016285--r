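#' Map state-id labels to stereotype names
#'
#' Translates per-trial discrete state ids (from [discretize()]) into the
#' fitted model's stereotype names, with `"indeterminate"` for trials below
#' the confidence threshold.
#'
#' @param labels integer state ids with `NA` for indeterminate trials.
#' @param stereotypes a [classify_stereotypes()] map (or character vector).
#' @return Character vector of stereotype names per trial.
#' @export
stereotype_labels <- function(labels, stereotypes) {
  st <- if (inherits(stereotypes, "stereotype_map")) stereotypes$stereotype
        else as.character(stereotypes)
  out <- rep("indeterminate", length(labels))
  ok <- !is.na(labels)
  out[ok] <- st[labels[ok]]
  out
}

#' State probability binned by an arousal measure
#'
#' Bins trials by the value of a measure (equal-count quantile bins by
#' default) and reports, per bin, the proportion of trials in each
#' stereotype and in the indeterminate condition. Bins with fewer than
#' `min_count` trials are kept in the output but flagged so downstream fits
#' can drop them.
#'
#' @param features per-trial feature data.frame from [trial_features()].
#' @param labels per-trial stereotype labels (character, from
#'   [stereotype_labels()]) or state ids with `stereotypes` supplied.
#' @param measure feature column to bin by (default `"pupil"`).
#' @param n_bins number of quantile bins (default 10).
#' @param min_count minimum trials for a bin to be usable in fits
#'   (default 20).
#' @param stereotypes optional `stereotype_map` when `labels` are state ids.
#' @return Object of class `binned_state_prob`: data.frame `bins` with bin
#'   center/count/usable flag and one probability column per stereotype;
#'   attribute `data_range` (range of the measure).
#' @export
binned_state_prob <- function(features, labels, measure = "pupil",
                              n_bins = 10, min_count = 20,
                              stereotypes = NULL) {
  abort_if(!measure %in% names(features),
           sprintf("feature column '%s' not present", measure))
  if (!is.character(labels)) labels <- stereotype_labels(labels, stereotypes)
  x <- features[[measure]]
  ok <- !is.na(x)
  x <- x[ok]; labels <- labels[ok]
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(x, breaks = qs, include.lowest = TRUE)
  cats <- c(STEREOTYPES, "indeterminate")
  tab <- table(bin, factor(labels, levels = cats))
  counts <- rowSums(tab)
  probs <- sweep(as.matrix(tab), 1L, pmax(counts, 1L), "/")
  centers <- tapply(x, bin, mean)
  bins <- data.frame(center = as.numeric(centers),
                     count = as.integer(counts),
                     usable = as.integer(counts) >= min_count)
  bins <- cbind(bins, as.data.frame.matrix(probs))
  structure(list(bins = bins, measure = measure, min_count = min_count),
            class = "binned_state_prob", data_range = range(x))
}

# weighted r-squared of predictions on held-out bins
weighted_r2 <- function(obs, pred, w) {
  mu <- sum(w * obs) / sum(w)
  1 - sum(w * (obs - pred)^2) / sum(w * (obs - mu)^2)
}

#' Optimal pupil diameter from a polynomial fit
#'
#' Fits polynomials of degree 1..`max_degree` to optimal-state occupancy
#' probability across pupil-diameter bins, selecting the degree at the elbow
#' of the 5-fold cross-validated test r-squared curve: the smallest degree
#' that already captures at least `1 - elbow_frac` of the total
#' cross-validated r-squared gain over the linear fit. A final polynomial of
#' that degree is fit to all usable bins
#' (weighted by trial count) and the optimal pupil diameter is the argmax of
#' the fitted curve restricted to the observed data range.
#'
#' @param binned a `binned_state_prob` over pupil diameter.
#' @param state stereotype column to fit (default `"optimal"`).
#' @param max_degree largest polynomial degree scanned (default 6).
#' @param folds cross-validation folds over bins (default 5).
#' @param elbow_frac elbow threshold as a fraction of the total r-squared
#'   gain (default 0.1).
#' @param seed seed for the fold assignment.
#' @return Object of class `optimal_pupil_fit`: `degree`, `coefficients`,
#'   `optimal` (diameter), `cv_r2` (per degree), `data_range`.
#' @export
fit_optimal_pupil <- function(binned, state = "optimal", max_degree = 6,
                              folds = 5, elbow_frac = 0.1, seed = 1) {
  b <- binned$bins[binned$bins$usable, , drop = FALSE]
  abort_if(nrow(b) < 5, "need at least 5 usable bins")
  x <- b$center; y <- b[[state]]; w <- b$count
  max_degree <- min(max_degree, nrow(b) - 2L)

  set.seed(derive_seed(seed, 0L))
  fold_of <- integer(nrow(b))
  fold_of[sample.int(nrow(b))] <- rep_len(seq_len(folds), nrow(b))
  cv_r2 <- numeric(max_degree)
  for (d in seq_len(max_degree)) {
    obs <- pred <- wt <- numeric(0)
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      if (sum(tr) <= d) next
      fit <- stats::lm(y[tr] ~ stats::poly(x[tr], d, raw = TRUE),
                       weights = w[tr])
      px <- vapply(x[!tr], function(xi)
        sum(stats::coef(fit) * xi^(0:d)), numeric(1))
      obs <- c(obs, y[!tr]); pred <- c(pred, px); wt <- c(wt, w[!tr])
    }
    cv_r2[d] <- weighted_r2(obs, pred, wt)
  }

  # elbow of the test-r2 increase: the smallest degree already capturing at
  # least (1 - elbow_frac) of the total cross-validated r2 gain over the
  # linear fit (robust to non-monotone r2 at high degrees)
  best_d <- which.max(cv_r2)
  total_gain <- cv_r2[best_d] - cv_r2[1]
  degree <- 1L
  if (best_d > 1L && total_gain > 0) {
    for (d in seq_len(best_d)) {
      if (cv_r2[best_d] - cv_r2[d] <= elbow_frac * total_gain) {
        degree <- d
        break
      }
    }
  }

  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE), weights = w)
  coefs <- stats::coef(fit)
  # argmax restricted to the range supported by the fit (the usable bin
  # centers); outside it a high-degree polynomial is pure extrapolation
  rng <- range(x)
  grid <- seq(rng[1], rng[2], length.out = 2001)
  curve <- vapply(grid, function(xi) sum(coefs * xi^(0:degree)), numeric(1))
  structure(list(degree = degree, coefficients = unname(coefs),
                 optimal = grid[which.max(curve)], cv_r2 = cv_r2,
                 data_range = rng, state = state),
            class = "optimal_pupil_fit")
}

#' @export
print.optimal_pupil_fit <- function(x, ...) {
  cat(sprintf("Optimal pupil fit: degree %d, optimal diameter %.3f\n",
              x$degree, x$optimal))
  invisible(x)
}

#' Distance from the optimal pupil diameter
#'
#' Normalizes each trial's pupil diameter to its signed and absolute
#' distance from the subject's optimal diameter, and summarizes mean
#' absolute distance per stereotype.
#'
#' @param features per-trial feature data.frame (needs `pupil`).
#' @param fit an `optimal_pupil_fit` (or a numeric optimal diameter).
#' @param labels optional per-trial stereotype labels for the summary.
#' @return List: `distance`, `abs_distance` (per trial), and, when labels
#'   are given, `by_state` (mean |distance| per stereotype).
#' @export
align_to_optimal <- function(features, fit, labels = NULL) {
  opt <- if (inherits(fit, "optimal_pupil_fit")) fit$optimal else fit
  d <- features$pupil - opt
  out <- list(distance = d, abs_distance = abs(d), optimal = opt)
  if (!is.null(labels)) {
    out$by_state <- tapply(abs(d), labels, mean, na.rm = TRUE)
  }
  out
}

# standardized quadratic design matrix: z-scored values and sd10s, squared
# z-values, pairwise products of z-values
quadratic_design <- function(features, measures) {
  zs <- lapply(measures, function(m) {
    v <- features[[m]]
    (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  })
  names(zs) <- measures
  X <- list()
  for (m in measures) {
    X[[m]] <- zs[[m]]
    sd_col <- paste0(m, "_sd10")
    abort_if(!sd_col %in% names(features),
             sprintf("feature column '%s' not present", sd_col))
    v <- features[[sd_col]]
    X[[sd_col]] <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    X[[paste0(m, "_sq")]] <- zs[[m]]^2
  }
  if (length(measures) > 1L) {
    pairs <- utils::combn(measures, 2L)
    for (j in seq_len(ncol(pairs)))
      X[[paste0(pairs[1, j], "_x_", pairs[2, j])]] <-
        zs[[pairs[1, j]]] * zs[[pairs[2, j]]]
  }
  as.data.frame(X, check.names = FALSE)
}

#' Quadratic regression of state probability on arousal features
#'
#' Least-squares regression of a state's per-trial posterior probability on
#' standardized measure values, their 10-trial rolling SDs, squared values,
#' and pairwise value interactions. Value and SD columns are z-scored;
#' squared and interaction terms are products of the z-scored values (so a
#' negative quadratic coefficient directly indicates an inverted-U).
#' Reports 5-fold cross-validated r-squared.
#'
#' @param features per-trial feature data.frame.
#' @param state_prob per-trial target: posterior probability of a stereotype
#'   (soft), or a 0/1 indicator.
#' @param measures feature set: e.g. `c("pupil", "face", "locomotion")` or
#'   `c("pupil", "movement_index")`.
#' @param folds cross-validation folds (default 5).
#' @param seed fold-assignment seed.
#' @return Object of class `state_regression`: `coefficients` (named,
#'   without intercept), `intercept`, `cv_r2`, `n`.
#' @export
quadratic_state_regression <- function(features, state_prob,
                                       measures = c("pupil", "face",
                                                    "locomotion"),
                                       folds = 5, seed = 1) {
  X <- quadratic_design(features, measures)
  keep <- stats::complete.cases(X) & !is.na(state_prob)
  X <- X[keep, , drop = FALSE]
  y <- state_prob[keep]
  n <- nrow(X)
  abort_if(n < 10 * ncol(X), "too few complete trials for the design")
  dat <- cbind(y = y, X)
  fit <- stats::lm(y ~ ., data = dat)

  set.seed(derive_seed(seed, 0L))
  fold_of <- integer(n)
  fold_of[sample.int(n)] <- rep_len(seq_len(folds), n)
  obs <- pred <- numeric(0)
  for (f in seq_len(folds)) {
    ftr <- stats::lm(y ~ ., data = dat[fold_of != f, , drop = FALSE])
    pr <- stats::predict(ftr, newdata = dat[fold_of == f, , drop = FALSE])
    obs <- c(obs, y[fold_of == f]); pred <- c(pred, pr)
  }
  cv_r2 <- weighted_r2(obs, pred, rep(1, length(obs)))
  cf <- stats::coef(fit)
  structure(list(coefficients = stats::setNames(cf[-1], colnames(X)),
                 intercept = unname(cf[1]), cv_r2 = cv_r2, n = n,
                 measures = measures),
            class = "state_regression")
}

#' State-conditioned pupil-movement correlation
#'
#' Pearson correlation between pre-stimulus pupil diameter and the movement
#' index, computed separately over the trials of each stereotype with at
#' least `min_trials` complete trials.
#'
#' @param features per-trial feature data.frame (needs `pupil` and
#'   `movement_index`).
#' @param labels per-trial stereotype labels.
#' @param min_trials minimum trials per stereotype (default 10).
#' @return Named numeric vector of correlations (NA below `min_trials`).
#' @export
state_conditioned_correlation <- function(features, labels, min_trials = 10) {
  groups <- setdiff(unique(labels), "indeterminate")
  out <- stats::setNames(rep(NA_real_, length(groups)), groups)
  for (g in groups) {
    idx <- which(labels == g & !is.na(features$pupil) &
                   !is.na(features$movement_index))
    if (length(idx) >= min_trials)
      out[g] <- stats::cor(features$pupil[idx],
                           features$movement_index[idx])
  }
  out
}

#' Variability change around optimal-state transitions
#'
#' Extracts a rolling-SD feature on trials within a +/- `window` around each
#' entry into and exit from the optimal state, subtracts the window-start
#' baseline (the value at offset `-window`), and averages across transitions
#' within a session, then across sessions. Transitions whose window crosses
#' a session edge are dropped.
#'
#' @param labels_per_session list of per-session state-id label vectors.
#' @param features feature data.frame with a `session` column.
#' @param stereotypes `stereotype_map` for the fitted model.
#' @param measure rolling-SD column (default `"pupil_sd10"`).
#' @param window half-width in trials (default 10).
#' @return List with `entry` and `exit` data.frames (`offset`,
#'   `mean_change`, `n_transitions`) and scalar summaries
#'   `mean_entry_change` / `mean_exit_change` (mean change over positive
#'   offsets). Empty (with a warning) when no optimal epochs exist.
#' @export
transition_aligned_variability <- function(labels_per_session, features,
                                           stereotypes,
                                           measure = "pupil_sd10",
                                           window = 10) {
  st <- if (inherits(stereotypes, "stereotype_map")) stereotypes$stereotype
        else as.character(stereotypes)
  optimal_ids <- which(st == "optimal")
  offsets <- -window:window
  entry_mat <- list(); exit_mat <- list()

  for (s in seq_along(labels_per_session)) {
    labels <- labels_per_session[[s]]
    x <- features[[measure]][features$session == s]
    n <- length(labels)
    is_opt <- !is.na(labels) & labels %in% optimal_ids
    ep <- label_epochs(ifelse(is_opt, 1L, 2L))
    opt_ep <- ep[ep$state == 1L, , drop = FALSE]
    sess_entry <- list(); sess_exit <- list()
    for (i in seq_len(nrow(opt_ep))) {
      t_entry <- opt_ep$start[i]
      t_exit <- opt_ep$start[i] + opt_ep$length[i]
      if (t_entry - window >= 1L && t_entry + window <= n) {
        vals <- x[t_entry + offsets]
        sess_entry[[length(sess_entry) + 1L]] <- vals - vals[1L]
      }
      if (t_exit - window >= 1L && t_exit + window <= n) {
        vals <- x[t_exit + offsets]
        sess_exit[[length(sess_exit) + 1L]] <- vals - vals[1L]
      }
    }
    if (length(sess_entry))
      entry_mat[[length(entry_mat) + 1L]] <-
        colMeans(do.call(rbind, sess_entry), na.rm = TRUE)
    if (length(sess_exit))
      exit_mat[[length(exit_mat) + 1L]] <-
        colMeans(do.call(rbind, sess_exit), na.rm = TRUE)
  }

  if (length(entry_mat) == 0 && length(exit_mat) == 0) {
    warning("no optimal-state transitions with full windows", call. = FALSE)
    return(list(entry = NULL, exit = NULL,
                mean_entry_change = NA_real_, mean_exit_change = NA_real_))
  }
  summarize <- function(mats, n_trans) {
    if (length(mats) == 0) return(NULL)
    data.frame(offset = offsets,
               mean_change = colMeans(do.call(rbind, mats), na.rm = TRUE),
               n_sessions = length(mats))
  }
  entry <- summarize(entry_mat)
  exit <- summarize(exit_mat)
  list(entry = entry, exit = exit,
       mean_entry_change = if (!is.null(entry))
         mean(entry$mean_change[entry$offset > 0], na.rm = TRUE)
       else NA_real_,
       mean_exit_change = if (!is.null(exit))
         mean(exit$mean_change[exit$offset > 0], na.rm = TRUE)
       else NA_real_)
}
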