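test_that("fold plans stratify by condition and never split a trial", {
  cond <- rep(c("A", "B"), each = 150)
  tid <- rep(1:50, each = 6)
  fp <- make_fold_plan(cond, tid, 3, seed = 1)
  # partition of all segments
  all_idx <- sort(unlist(fp$folds))
  expect_identical(all_idx, 1:300)
  # per-condition trial counts 9/8/8 in some order
  per_cond <- sapply(fp$folds, function(f) {
    c(
      A = length(unique(tid[f][cond[f] == "A"])),
      B = length(unique(tid[f][cond[f] == "B"]))
    )
  })
  expect_identical(sort(per_cond["A", ]), c(8L, 8L, 9L))
  expect_identical(sort(per_cond["B", ]), c(8L, 8L, 9L))
  # all 6 sub-segments of a trial share a fold
  for (f in fp$folds) {
    expect_true(all(table(tid[f]) == 6))
  }
  expect_error(
    make_fold_plan(rep("A", 12), rep(1:2, each = 6), 3),
    "fewer trials than folds"
  )
})

test_that("the linear SVM separates, respects symmetry and flips with labels", {
  set.seed(2)
  P <- matrix(rnorm(40), 20, 2)
  X <- rbind(P + 3, P - 3)
  y <- factor(rep(c("a", "b"), each = 20), levels = c("a", "b"))
  m <- train_linear_svm(X, y, C = 1)
  expect_identical(as.character(predict(m, X)), as.character(y))

  # classes mirrored through the origin: unbiased separating plane
  Xs <- rbind(P + 2, -(P + 2))
  ms <- train_linear_svm(Xs, y, C = 1, tolerance = 1e-10)
  expect_lt(abs(ms$b), 1e-6)

  # flipping the labels negates the decision function
  m2 <- train_linear_svm(X, factor(y, levels = c("b", "a")), C = 1)
  expect_equal(m2$w, -m$w, tolerance = 1e-6)
  expect_equal(m2$b, -m$b, tolerance = 1e-6)

  expect_error(train_linear_svm(X, factor(rep("a", 40))), "two classes")
})

test_that("t-test ranking finds planted effects and demotes degenerate features", {
  # planted 3-sigma shift among 99 null features ranks first almost always
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 100), 40, 100)
    X[1:20, 1] <- X[1:20, 1] + 3
    y <- factor(rep(c("a", "b"), each = 20))
    rank_features(X, y)[1] == 1
  }, logical(1))
  expect_gte(mean(hits), 0.99)

  # under the null p-values are uniform
  set.seed(5)
  X0 <- matrix(rnorm(60 * 1000), 60, 1000)
  y0 <- factor(rep(c("a", "b"), each = 30))
  p <- attr(rank_features(X0, y0), "p")
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)

  # constant features rank last with p = 1
  Xc <- cbind(X0[, 1:5], 7)
  r <- rank_features(Xc, y0)
  expect_identical(r[6], 6L)
  expect_identical(attr(r, "p")[6], 1)
})

test_that("feature-set evaluation pools folds and balances its accounting", {
  d <- make_labelled_features(
    n_trials_per_class = 10, n_features = 5,
    n_informative = 0, seed = 7
  )
  # a perfectly separating feature scores 1.0
  Xp <- cbind(ifelse(d$condition == "A", 1, -1), d$X)
  sc <- evaluate_feature_set(Xp, d$condition, d$trial_id, 1, k = 5)
  expect_equal(sc[["accuracy"]], 1)

  # accuracy decomposes exactly into class accuracies
  sc2 <- evaluate_feature_set(d$X, d$condition, d$trial_id, 1:5, k = 5)
  n1 <- sum(d$condition == "A")
  n2 <- sum(d$condition == "B")
  expect_equal(
    sc2[["accuracy"]],
    (sc2[["sensitivity"]] * n1 + sc2[["specificity"]] * n2) / (n1 + n2)
  )
  expect_error(
    evaluate_feature_set(d$X, d$condition, d$trial_id, integer(0)),
    "empty"
  )
})

test_that("label permutation drives feature-set evaluation to chance", {
  accs <- vapply(1:50, function(s) {
    d <- make_labelled_features(
      n_trials_per_class = 8, n_features = 4,
      n_informative = 2, delta = 2, seed = 400 + s
    )
    set.seed(s)
    perm_tr <- sample(unique(d$trial_id))
    lab_of <- stats::setNames(
      d$condition[!duplicated(d$trial_id)],
      perm_tr
    )
    yperm <- as.character(lab_of[as.character(d$trial_id)])
    evaluate_feature_set(d$X, yperm, d$trial_id, 1:4, k = 4, seed = s)[["accuracy"]]
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("greedy selection caps its size and survives noise floods", {
  d <- make_labelled_features(
    n_trials_per_class = 10, n_features = 300,
    n_informative = 8, delta = 1.2, seed = 9
  )
  res <- greedy_select(d$X, factor(d$condition), d$trial_id, seed = 1)
  expect_lte(length(res$selected), 30)
  expect_identical(res$selected[1], rank_features(d$X, factor(d$condition))[1])
  expect_true(all(res$trace$feature[res$trace$accepted] %in% res$selected))
  # the rejection streak never exceeds max(ceil(0.1 F), 100) + 1 candidates
  runs <- rle(!res$trace$accepted)
  expect_lte(max(runs$lengths[runs$values]), 101)

  # one informative feature in a sea of noise is always found and the cap
  # holds; uninformative passengers that tie the accuracy are permitted by
  # the greater-or-equal acceptance rule
  found <- 0L
  capped <- 0L
  n_rep <- 15L
  for (s in seq_len(n_rep)) {
    dd <- make_labelled_features(
      n_trials_per_class = 8, n_features = 2000,
      n_informative = 1, delta = 3, seed = 100 + s
    )
    r <- greedy_select(dd$X, factor(dd$condition), dd$trial_id, seed = s)
    found <- found + (1L %in% r$selected)
    capped <- capped + (length(r$selected) <= 30)
  }
  expect_gte(found / n_rep, 0.95)
  expect_identical(capped, n_rep)
})

test_that("consensus selection follows the 2-of-5 rule with its fallbacks", {
  same <- replicate(5, c(4L, 7L, 9L), simplify = FALSE)
  cs <- consensus_select(same)
  expect_setequal(cs$consensus, c(4L, 7L, 9L))
  expect_true(all(cs$counts == 5))

  # pairwise-disjoint runs fall back to count >= 1 and are trimmed to 31
  disjoint <- lapply(0:4, function(k) (k * 10 + 1):(k * 10 + 10))
  cd <- consensus_select(disjoint, rank_lookup = seq_len(100))
  expect_length(cd$consensus, 31)
  expect_identical(cd$consensus, 1:31) # tie-break by rank
  expect_equal(cd$mean_run_length, 10)

  cc <- consensus_select(list(1L, 1L, 1L, 1L, c(1L, 2L)))
  expect_identical(cc$consensus, 1L)

  expect_error(
    consensus_select(list(integer(0), integer(0))),
    "degenerate"
  )
})

test_that("nested classification pools 300 test segments from 25+25 trials
           and is leak-free and deterministic", {
  d <- make_labelled_features(
    n_trials_per_class = 25, n_features = 26,
    n_informative = 5, delta = 1.2, seed = 33
  )
  out <- nested_classify(d$X, d$condition, d$trial_id, c("A", "B"), seed = 17)
  expect_identical(out$n, 300L)
  expect_identical(
    out$h0,
    as.integer(round(
      out$sensitivity * out$n_class[1] + out$specificity * out$n_class[2]
    ))
  )
  expect_lte(max(vapply(
    out$selection,
    function(s) length(s$consensus), numeric(1)
  )), 31)

  # outer folds partition trials; middle folds stay inside the outer train set
  tid <- d$trial_id
  outer_trials <- lapply(out$outer_plan$folds, function(f) unique(tid[f]))
  expect_identical(sort(unlist(outer_trials)), 1:50)
  expect_identical(sum(lengths(outer_trials)), 50L)
  for (f in seq_along(out$middle_plans)) {
    train_tr <- setdiff(1:50, outer_trials[[f]])
    mid_tr <- unique(unlist(lapply(
      out$middle_plans[[f]]$folds,
      function(ix) unique(tid[tid %in% train_tr][ix])
    )))
    expect_true(all(mid_tr %in% train_tr))
  }

  rerun <- nested_classify(d$X, d$condition, d$trial_id, c("A", "B"), seed = 17)
  expect_identical(rerun$h0, out$h0)
  expect_identical(rerun$selection[[1]]$consensus, out$selection[[1]]$consensus)

  # informative features separate well above the critical chance count
  expect_gte(out$h0, critical_count(150, 300, 0.05))
})
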