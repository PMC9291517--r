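test_that("stratified split honors the floor convention and determinism", {
  co <- simulate_loadings(1, n = 54)
  co$group[1:33] <- "control"; co$group[34:54] <- "tr"
  sp <- split_train_test(co, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 43)  # floor(0.8 * 54)
  expect_equal(nrow(sp$test), 11)
  expect_setequal(c(sp$train$subject_id, sp$test$subject_id), co$subject_id)
  # stratification: both classes on both sides, proportions close
  expect_equal(sum(sp$train$group == "tr"), 17)  # largest-remainder allocation
  sp2 <- split_train_test(co, 0.8, seed = 3)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  expect_error(split_train_test(co, 1.0), "strictly between")
  expect_error(split_train_test(co[1:4, ], 0.8), "too small")
})

test_that("borderline SMOTE balances classes with exact convex combinations", {
  tr <- simulate_three_groups(7, n_control = 20, n_tr = 5, n_healthy = 4)
  bal <- suppressWarnings(borderline_smote(tr, k_neighbors = 5, seed = 2))
  expect_equal(unname(table(bal$group)[c("control", "healthy", "tr")]),
               rep(20, 3), ignore_attr = TRUE)
  # originals retained unchanged
  expect_equal(dplyr::filter(bal, !.synthetic)[, names(tr)], tr)
  # every synthetic point is an exact convex combination of two originals of
  # its own minority class (brute force over all pairs)
  cols <- paste0("s", 1:6)
  X <- as.matrix(tr[, cols])
  for (i in which(bal$.synthetic)) {
    z <- as.numeric(bal[i, cols])
    g <- bal$group[i]
    members <- which(tr$group == g)
    ok <- FALSE
    for (a in members) for (b in setdiff(members, a)) {
      ab <- X[b, ] - X[a, ]
      u <- sum((z - X[a, ]) * ab) / sum(ab^2)
      if (u > 0 && u < 1 && sqrt(sum((X[a, ] + u * ab - z)^2)) < 1e-9) ok <- TRUE
    }
    expect_true(ok)
  }
  # already balanced input is returned unchanged
  even <- dplyr::filter(tr, group != "healthy")[c(1:5, 21:25), ]
  expect_equal(borderline_smote(even, seed = 1)[, names(even)], even)
  # degenerate minority errors
  bad <- tr[c(1:20, 21), ]
  expect_error(suppressWarnings(borderline_smote(bad, seed = 1)), "fewer than 2")
})

test_that("lasso dominance finds an informative mode and echoes its settings", {
  d <- simulate_loadings(3)
  dom <- lasso_dominance(d, n_repeats = 60, seed = 3)
  expect_true(all(dom$dominance >= 0 & dom$dominance <= 1))
  expect_equal(attr(dom, "n_repeats"), 60)
  expect_gt(dom$dominance[1], 0.9)
  expect_equal(which.max(dom$dominance), 1L)
  expect_equal(select_top_modes(dom, min(4, sum(dom$dominance > 0)))[1], 1L)
  # constant column excluded with zero dominance
  d2 <- d; d2$s5 <- 1
  expect_warning(dom2 <- lasso_dominance(d2, n_repeats = 20, seed = 1), "constant")
  expect_equal(dom2$dominance[5], 0)
})

test_that("top-mode selection orders by dominance with index tie-break", {
  mk <- function(dom) {
    r <- tibble::tibble(mode = seq_along(dom), dominance = dom)
    class(r) <- c("rv_dominance", class(r)); r
  }
  expect_equal(select_top_modes(mk(c(0.9, 0.1, 0.8, 0.7, 0.6)), 4), c(1, 3, 4, 5))
  expect_equal(select_top_modes(mk(c(0.9, 0.8, 0.8, 0.1)), 2), c(1, 2))
  expect_error(select_top_modes(mk(c(0.5, 0, 0, 0)), 4), "non-zero")
})

test_that("logistic classifier separates separable data and validates input", {
  set.seed(8)
  n <- 30
  df <- tibble::tibble(
    subject_id = sprintf("p%02d", 1:n),
    group = rep(c("tr", "control"), each = n / 2),
    subgroup = "none",
    s1 = c(rnorm(n / 2, 3), rnorm(n / 2, -3)),
    s2 = rnorm(n))
  clf <- fit_classifier(df, c(1, 2), seed = 1)
  rep <- evaluate(clf, df)
  expect_equal(rep$metrics$accuracy, 1)
  expect_equal(rep$auc, 1)
  p <- predict(clf, df)
  expect_true(all(p >= 0 & p <= 1))
  # monotone in the informative loading for a 1-mode model
  clf1 <- fit_classifier(df, 1, seed = 1)
  grid <- df[order(df$s1), ]
  expect_true(all(diff(predict(clf1, grid)) >= -1e-12) ||
                all(diff(predict(clf1, grid)) <= 1e-12))
  bad <- df; bad$group <- "tr"
  expect_error(fit_classifier(bad, 1, seed = 1), "single class")
  expect_error(fit_classifier(df, integer(0), seed = 1), "non-empty")
})

test_that("label-permuted data gives chance-level cross-validated AUC", {
  aucs <- vapply(1:20, function(s) {
    d <- simulate_loadings(s + 300, informative = FALSE, n = 30, p = 5)
    sp <- split_train_test(d, 0.7, seed = s)
    clf <- suppressWarnings(fit_classifier(sp$train, 1:5, seed = s))
    r <- evaluate(clf, sp$test)
    r$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("report metrics follow the printed confusion-matrix formulas", {
  # hand-built probabilities realizing TP=9, FN=2, TN=9, FP=1
  y <- c(rep(1, 11), rep(0, 10))
  p <- c(rep(0.9, 9), rep(0.1, 2), rep(0.1, 9), rep(0.9, 1))
  rep <- classification_report(p, y)
  expect_equal(unlist(rep$confusion), c(tn = 9, fp = 1, fn = 2, tp = 9))
  expect_equal(rep$metrics$recall, 9 / 11)
  expect_equal(rep$metrics$precision, 9 / 10)
  expect_equal(rep$metrics$accuracy, 18 / 21)
  pr <- 9 / 10; rc <- 9 / 11
  expect_equal(rep$metrics$f1, 2 * pr * rc / (pr + rc))
  # perfect classifier
  perfect <- classification_report(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unlist(perfect$metrics), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  expect_equal(perfect$auc, 1)
  # all-positive predictor on balanced labels
  allpos <- classification_report(rep(0.9, 10), rep(c(0, 1), 5))
  expect_equal(allpos$metrics$recall, 1)
  expect_equal(allpos$metrics$precision, 0.5)
  expect_equal(allpos$metrics$accuracy, 0.5)
  # ROC invariants
  expect_equal(rep$roc$fpr[1], 0); expect_equal(rep$roc$tpr[1], 0)
  expect_equal(utils::tail(rep$roc$fpr, 1), 1)
  expect_true(all(diff(rep$roc$fpr) >= 0))
  # single-class test: metrics computed, AUC undefined
  onecls <- classification_report(c(0.6, 0.7), c(1, 1))
  expect_true(is.na(onecls$auc))
  expect_equal(onecls$metrics$recall, 1)
})

test_that("trapezoid AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rep(c(0, 1), each = 25)
  p <- stats::plogis(y * 1.2 + rnorm(50))
  rep <- classification_report(p, y)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, p))))
  expect_equal(rep$auc, ref, tolerance = 1e-10)
})

test_that("SMOTE touches only the training side of the pipeline", {
  d <- simulate_three_groups(5, n_control = 20, n_tr = 8, n_healthy = 6)
  res <- suppressWarnings(classify_pipeline(d, n_repeats = 20, top_modes = 2, seed = 4))
  expect_false(any(grepl("smote", res$split$test$subject_id)))
  expect_true(all(res$split$test$subject_id %in% d$subject_id))
  # every non-original training row is flagged synthetic
  expect_setequal(dplyr::filter(res$balanced, !.synthetic)$subject_id,
                  res$split$train$subject_id)
})
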