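#' Tuning constants of the classification pipeline
#'
#' @param C soft-margin regularisation of the linear SVM (default 1).
#' @param max_features cap on features accepted during one greedy search
#'   run (default 30).
#' @param consensus_cap cap on the final consensus vector (default 31).
#' @param sens_threshold sensitivity gate for candidate acceptance
#'   (default 0.75).
#' @param spec_threshold specificity gate (default 0.5).
#' @param k_outer outer cross-validation folds (default 3).
#' @param k_middle middle-layer folds / selection repetitions (default 5).
#' @param k_inner inner folds used to score candidate feature sets
#'   (default 5).
#' @return list of class `classify_params`.
#' @export
classify_params <- function(C = 1, max_features = 30, consensus_cap = 31,
                            sens_threshold = 0.75, spec_threshold = 0.5,
                            k_outer = 3, k_middle = 5, k_inner = 5) {
  structure(
    list(
      C = C, max_features = max_features, consensus_cap = consensus_cap,
      sens_threshold = sens_threshold, spec_threshold = spec_threshold,
      k_outer = k_outer, k_middle = k_middle, k_inner = k_inner
    ),
    class = "classify_params"
  )
}

#' Trial-grouped, condition-stratified fold assignment
#'
#' Assigns whole trials (so all 6 sub-segments of a trial share a fold) to
#' `k` folds by seeded shuffle, separately per condition so that
#' per-condition trial counts across folds differ by at most one.
#'
#' @param condition condition label per segment.
#' @param trial_id trial id per segment (a trial never spans conditions).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return a `fold_plan`: list with `folds` (list of k integer vectors of
#'   segment indices), `k`, and `trial_fold` (named vector trial -> fold).
#' @export
make_fold_plan <- function(condition, trial_id, k, seed = 1) {
  stopifnot(length(condition) == length(trial_id), k >= 2)
  trials <- !duplicated(trial_id)
  trial_cond <- stats::setNames(condition[trials], trial_id[trials])
  with_seed(seed, {
    trial_fold <- integer(0)
    for (cond in unique(trial_cond)) {
      ids <- names(trial_cond)[trial_cond == cond]
      n <- length(ids)
      if (n < k) stop("fewer trials than folds for condition ", cond)
      ids <- sample(ids)
      sizes <- rep(n %/% k, k)
      extra <- n %% k
      if (extra > 0) {
        bump <- sample(k, extra)
        sizes[bump] <- sizes[bump] + 1L
      }
      fold_of <- rep(seq_len(k), times = sizes)
      trial_fold <- c(trial_fold, stats::setNames(fold_of, ids))
    }
    folds <- lapply(seq_len(k), function(f) {
      unname(which(trial_fold[as.character(trial_id)] == f))
    })
    structure(list(folds = folds, k = k, trial_fold = trial_fold),
      class = "fold_plan"
    )
  })
}

#' Train a linear soft-margin SVM
#'
#' Wraps a linear-kernel C-classification SVM and extracts the explicit
#' decision function: `d(x) = x . w + b`, predicting the first factor level
#' of `y` when `d(x) > 0`.
#'
#' @param X numeric feature matrix, samples x features.
#' @param y two-level factor (first level = "positive"/first condition).
#' @param C regularisation constant.
#' @param tolerance termination tolerance of the quadratic-programming
#'   solver (default 0.001; tighten for near-exact solutions).
#' @return list of class `linear_svm` with `w`, `b`, `levels`.
#' @export
train_linear_svm <- function(X, y, C = 1, tolerance = 0.001) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("need exactly two classes in 'y'")
  fit <- e1071::svm(
    x = X, y = y, kernel = "linear", cost = C,
    scale = FALSE, type = "C-classification", tolerance = tolerance
  )
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient the decision function so that positive values mean level 1
  dv <- X %*% w + b
  pred <- predict(fit, X)
  agree <- mean((dv > 0) == (pred == levels(y)[1]))
  if (agree < 0.5) {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, levels = levels(y)), class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  dv <- as.matrix(newdata) %*% object$w + object$b
  factor(ifelse(dv > 0, object$levels[1], object$levels[2]),
    levels = object$levels
  )
}

#' Rank features by two-sample t-test p-value
#'
#' Pooled-variance two-sample t-test per feature column, p-values sorted
#' ascending. Ties keep original column order; zero-pooled-variance
#' (constant) features are assigned p = 1 and therefore rank last.
#'
#' @param X feature matrix, samples x features.
#' @param y two-level factor.
#' @return integer vector of feature indices in rank order, with the
#'   p-values in attribute `"p"` (in original column order).
#' @export
rank_features <- function(X, y) {
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2)
  g1 <- y == levels(y)[1]
  n1 <- sum(g1)
  n2 <- sum(!g1)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[!g1, , drop = FALSE])
  v1 <- apply(X[g1, , drop = FALSE], 2, stats::var)
  v2 <- apply(X[!g1, , drop = FALSE], 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, (m1 - m2) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2), 1)
  ord <- order(p, seq_along(p))
  attr(ord, "p") <- p
  ord
}

#' Cross-validated accuracy of a fixed feature set
#'
#' Trial-grouped `k`-fold cross-validation of the linear SVM restricted to
#' the given features; pooled over the k test folds.
#'
#' @param X feature matrix, samples x features.
#' @param y two-level factor (first level defines sensitivity).
#' @param trial_id trial id per sample (fold grouping).
#' @param features integer feature indices to use.
#' @param k folds (default 5).
#' @param C SVM regularisation.
#' @param plan optionally a precomputed `fold_plan` (so that all candidate
#'   sets of one search run are scored on identical folds).
#' @param seed seed for the fold plan when `plan` is NULL.
#' @return named numeric: `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate_feature_set <- function(X, y, trial_id, features, k = 5, C = 1,
                                 plan = NULL, seed = 1) {
  if (length(features) == 0) stop("empty feature set")
  y <- factor(y, levels = levels(as.factor(y)))
  if (is.null(plan)) plan <- make_fold_plan(as.character(y), trial_id, k, seed)
  lev <- levels(droplevels(y))
  correct1 <- 0L
  correct2 <- 0L
  n1 <- 0L
  n2 <- 0L
  for (f in seq_len(plan$k)) {
    test <- plan$folds[[f]]
    train <- setdiff(seq_along(y), test)
    model <- train_linear_svm(X[train, features, drop = FALSE], y[train], C)
    pred <- predict(model, X[test, features, drop = FALSE])
    is1 <- y[test] == lev[1]
    correct1 <- correct1 + sum(pred[is1] == y[test][is1])
    correct2 <- correct2 + sum(pred[!is1] == y[test][!is1])
    n1 <- n1 + sum(is1)
    n2 <- n2 + sum(!is1)
  }
  c(
    accuracy = (correct1 + correct2) / (n1 + n2),
    sensitivity = correct1 / n1,
    specificity = correct2 / n2
  )
}

#' Greedy constraint-gated feature subset selection
#'
#' Starting from the top t-test-ranked feature, candidates are tried in
#' rank order; a candidate is kept only if, scored by inner
#' cross-validation together with the accepted set, (a) accuracy is at
#' least the best accuracy of all previously accepted sets, (b) while the
#' best sensitivity is below `sens_threshold` the sensitivity must not
#' drop, and (c) while the best specificity is below `spec_threshold` the
#' specificity must strictly improve. The search stops when the ranking is
#' exhausted, `max_features` are accepted, or the consecutive-rejection
#' streak exceeds `max(ceiling(0.1 * F), 100)` candidates for `F` available
#' features.
#'
#' @param X feature matrix (training data of one selection run).
#' @param y two-level factor.
#' @param trial_id trial ids for fold grouping.
#' @param ranked integer feature ranking from [rank_features()] (computed
#'   on this run's training data).
#' @param params a [classify_params()].
#' @param seed seed for the inner fold plan.
#' @return list with `selected` (indices in acceptance order), `trace`
#'   (tibble: feature, accepted, accuracy, sensitivity, specificity), and
#'   `final` (scores of the accepted set).
#' @export
greedy_select <- function(X, y, trial_id, ranked = rank_features(X, y),
                          params = classify_params(), seed = 1) {
  n_feat <- ncol(X)
  streak_limit <- max(ceiling(0.1 * n_feat), 100)
  plan <- make_fold_plan(as.character(y), trial_id, params$k_inner, seed)
  selected <- ranked[1]
  sc <- evaluate_feature_set(X, y, trial_id, selected,
    C = params$C, plan = plan
  )
  best_acc <- sc[["accuracy"]]
  best_sens <- sc[["sensitivity"]]
  best_spec <- sc[["specificity"]]
  trace <- list(tibble::tibble(
    feature = ranked[1], accepted = TRUE,
    accuracy = sc[["accuracy"]], sensitivity = sc[["sensitivity"]],
    specificity = sc[["specificity"]]
  ))
  streak <- 0L
  for (idx in ranked[-1]) {
    if (length(selected) >= params$max_features) break
    if (streak > streak_limit) break
    sc <- evaluate_feature_set(X, y, trial_id, c(selected, idx),
      C = params$C, plan = plan
    )
    ok <- sc[["accuracy"]] >= best_acc &&
      (best_sens >= params$sens_threshold || sc[["sensitivity"]] >= best_sens) &&
      (best_spec >= params$spec_threshold || sc[["specificity"]] > best_spec)
    trace[[length(trace) + 1]] <- tibble::tibble(
      feature = idx, accepted = ok,
      accuracy = sc[["accuracy"]], sensitivity = sc[["sensitivity"]],
      specificity = sc[["specificity"]]
    )
    if (ok) {
      selected <- c(selected, idx)
      best_acc <- max(best_acc, sc[["accuracy"]])
      best_sens <- max(best_sens, sc[["sensitivity"]])
      best_spec <- max(best_spec, sc[["specificity"]])
      streak <- 0L
    } else {
      streak <- streak + 1L
    }
  }
  list(
    selected = selected,
    trace = dplyr::bind_rows(trace),
    final = c(
      accuracy = best_acc, sensitivity = best_sens,
      specificity = best_spec
    )
  )
}

#' Consensus over repeated feature selections
#'
#' Counts how often each feature was selected across the runs (normally 5).
#' The consensus keeps features selected at least twice; if that is empty,
#' features selected at least once. If the result is longer than the mean
#' run length, only the `cap` (default 31) most frequently selected
#' features are kept, ties broken by the better (smaller) rank.
#'
#' @param selections list of integer vectors (one per run).
#' @param rank_lookup optional numeric vector over all features giving a
#'   rank score (smaller = better) used only for tie-breaks.
#' @param cap maximum consensus length (default 31).
#' @return list with `consensus` (ordered indices), `counts` (named counts
#'   over the union), `mean_run_length`.
#' @export
consensus_select <- function(selections, rank_lookup = NULL, cap = 31) {
  stopifnot(length(selections) >= 1)
  if (all(lengths(selections) == 0)) {
    stop("all selection runs are empty (degenerate data)")
  }
  nbar <- mean(lengths(selections))
  all_feats <- unlist(selections)
  counts <- table(all_feats)
  feats <- as.integer(names(counts))
  cnt <- as.integer(counts)
  keep <- cnt >= 2
  if (!any(keep)) keep <- cnt >= 1
  feats_k <- feats[keep]
  cnt_k <- cnt[keep]
  tie <- if (is.null(rank_lookup)) feats_k else rank_lookup[feats_k]
  ord <- order(-cnt_k, tie, feats_k)
  feats_k <- feats_k[ord]
  cnt_k <- cnt_k[ord]
  if (length(feats_k) > nbar) {
    feats_k <- feats_k[seq_len(min(cap, length(feats_k)))]
    cnt_k <- cnt_k[seq_len(length(feats_k))]
  }
  list(
    consensus = feats_k,
    counts = stats::setNames(cnt_k, feats_k),
    mean_run_length = nbar
  )
}

#' Nested cross-validated pairwise classification
#'
#' The full three-layer procedure for one condition pair: an outer 3-fold
#' split estimates generalisation; inside each outer training set, a
#' middle 5-fold loop repeats t-test ranking plus greedy selection (scored
#' by inner 5-fold cross-validation) five times; the consensus of the five
#' selections trains a linear SVM on the whole outer training set, which is
#' then scored on the held-out outer fold. Correct counts are pooled over
#' the three outer test folds, so `n` equals the total number of segments.
#' All folds group by trial: sub-segments of one trial never straddle a
#' train/test boundary at any layer.
#'
#' @param features a `feature_table` (or plain matrix).
#' @param labels condition label per segment.
#' @param trial_id trial id per segment.
#' @param pair character(2): the two conditions to classify; the first
#'   defines sensitivity.
#' @param params a [classify_params()].
#' @param seed seed controlling every fold split of this run.
#' @return a `classification_outcome`: list with `h0` (pooled correct
#'   count), `n`, `accuracy`, `sensitivity`, `specificity`, `pair`,
#'   `n_features` (mean consensus length over outer folds), `selection`
#'   (per outer fold: consensus, counts, mean run length), `outer_plan`,
#'   `middle_plans`, `seed`.
#' @export
nested_classify <- function(features, labels, trial_id, pair,
                            params = classify_params(), seed = 1) {
  X <- if (inherits(features, "feature_table")) features$values else as.matrix(features)
  stopifnot(length(labels) == nrow(X), length(pair) == 2)
  sel_rows <- labels %in% pair
  X <- X[sel_rows, , drop = FALSE]
  y <- factor(labels[sel_rows], levels = pair)
  tid <- trial_id[sel_rows]
  n <- length(y)

  outer_plan <- make_fold_plan(as.character(y), tid, params$k_outer,
    seed = derive_seed(seed, 1)
  )
  h0 <- 0L
  c1 <- 0L
  c2 <- 0L
  n1 <- 0L
  n2 <- 0L
  selections <- list()
  middle_plans <- list()
  for (f in seq_len(params$k_outer)) {
    test <- outer_plan$folds[[f]]
    train <- setdiff(seq_len(n), test)
    Xtr <- X[train, , drop = FALSE]
    ytr <- y[train]
    ttr <- tid[train]
    middle_plan <- make_fold_plan(as.character(ytr), ttr, params$k_middle,
      seed = derive_seed(seed, 100 + f)
    )
    middle_plans[[f]] <- middle_plan
    runs <- vector("list", params$k_middle)
    best_rank <- rep(Inf, ncol(X)) # best rank position seen per feature
    for (r in seq_len(params$k_middle)) {
      mtrain <- setdiff(seq_along(ytr), middle_plan$folds[[r]])
      ranked <- rank_features(Xtr[mtrain, , drop = FALSE], ytr[mtrain])
      best_rank <- pmin(best_rank, order(ranked))
      runs[[r]] <- greedy_select(
        Xtr[mtrain, , drop = FALSE], ytr[mtrain], ttr[mtrain],
        ranked = ranked, params = params,
        seed = derive_seed(seed, 1000 + 10 * f + r)
      )$selected
    }
    cons <- consensus_select(runs,
      rank_lookup = best_rank,
      cap = params$consensus_cap
    )
    selections[[f]] <- cons
    model <- train_linear_svm(Xtr[, cons$consensus, drop = FALSE], ytr,
      C = params$C
    )
    pred <- predict(model, X[test, cons$consensus, drop = FALSE])
    is1 <- y[test] == pair[1]
    c1 <- c1 + sum(pred[is1] == y[test][is1])
    c2 <- c2 + sum(pred[!is1] == y[test][!is1])
    n1 <- n1 + sum(is1)
    n2 <- n2 + sum(!is1)
  }
  h0 <- c1 + c2
  structure(
    list(
      h0 = as.integer(h0), n = as.integer(n),
      accuracy = h0 / n,
      sensitivity = c1 / n1, specificity = c2 / n2,
      n_class = c(n1, n2),
      pair = pair,
      n_features = mean(vapply(selections, function(s) length(s$consensus), numeric(1))),
      selection = selections,
      outer_plan = outer_plan,
      middle_plans = middle_plans,
      seed = seed
    ),
    class = "classification_outcome"
  )
}

#' @export
print.classification_outcome <- function(x, ...) {
  cat(sprintf(
    "<classification_outcome> %s vs %s: %d/%d correct (%.1f%%), sens %.2f, spec %.2f, %.1f features\n",
    x$pair[1], x$pair[2], x$h0, x$n, 100 * x$accuracy,
    x$sensitivity, x$specificity, x$n_features
  ))
  invisible(x)
}
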