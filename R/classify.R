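# TR-vs-control classification on PCA loadings: stratified splitting,
# Borderline-SMOTE balancing of the two minority groups, lasso stability
# feature selection (dominance probabilities), regularized logistic
# classification, and the printed evaluation metrics.
#
# A "labeled cohort" is a tibble with subject_id, group (healthy / control /
# tr), subgroup, and loading columns s1..sm; the binary label is
# y = 1 for TR patients, y = 0 otherwise.

mode_cols <- function(df) grep("^s[0-9]+$", names(df), value = TRUE)

cohort_y <- function(df) as.integer(df$group == "tr")

#' Stratified train/test split of a labeled cohort
#'
#' Partitions subjects into train and test, stratified by the binary TR
#' label. The train size is `floor(train_fraction * n)` overall, allocated
#' across classes by largest remainder, so e.g. 54 subjects at 0.8 give
#' 43 train / 11 test. Deterministic given the seed.
#'
#' @param cohort loadings tibble (see [pca_loadings()]).
#' @param train_fraction fraction of subjects in the training set.
#' @param seed integer seed.
#' @return list with `train` and `test` tibbles (disjoint, exhaustive).
#' @export
split_train_test <- function(cohort, train_fraction = 0.8, seed = 1L) {
  n <- nrow(cohort)
  if (n < 5) abort("cohort too small to split (need >= 5 subjects)")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1 (both sides must be non-empty)")
  }
  y <- cohort_y(cohort)
  n_train <- floor(train_fraction * n)
  cls <- sort(unique(y))
  raw <- vapply(cls, function(c) sum(y == c) * train_fraction, numeric(1))
  base <- floor(raw)
  left <- n_train - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  set.seed(seed)
  train_idx <- unlist(lapply(seq_along(cls), function(i) {
    members <- which(y == cls[i])
    sample(members, base[i])
  }))
  train <- cohort[sort(train_idx), ]
  test <- cohort[setdiff(seq_len(n), train_idx), ]
  for (side in list(train, test)) {
    if (length(unique(cohort_y(side))) < 2) {
      abort("a class is absent from one side of the split; stratification failed at these sizes")
    }
  }
  list(train = train, test = test)
}

#' Borderline-SMOTE balancing of the training cohort
#'
#' Upsamples every minority group (by the three-way group tag; in the default
#' cohort the minorities are TR patients and healthy volunteers, the majority
#' the comorbid controls) to the majority count. A minority sample is
#' *borderline* when, among its `k_neighbors` nearest neighbors in the full
#' training set, at least half but not all belong to other groups; synthetic
#' samples are convex combinations `x + u * (x' - x)`, `u ~ U(0, 1)`, of a
#' borderline sample `x` and one of its nearest neighbors `x'` within the
#' same minority group. Originals are retained unchanged and flagged by the
#' `.synthetic` column.
#'
#' @param train training tibble.
#' @param k_neighbors neighborhood size (default 5; clamped with a warning if
#'   a class is too small).
#' @param seed integer seed.
#' @return balanced tibble; already-balanced input is returned unchanged.
#' @export
borderline_smote <- function(train, k_neighbors = 5, seed = 1L) {
  if (k_neighbors < 1) abort("k_neighbors must be >= 1")
  cols <- mode_cols(train)
  X <- as.matrix(train[, cols])
  counts <- table(train$group)
  n_maj <- max(counts)
  minorities <- names(counts)[counts < n_maj]
  out <- dplyr::mutate(train, .synthetic = FALSE)
  if (length(minorities) == 0) return(out)
  set.seed(seed)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  for (g in minorities) {
    members <- which(train$group == g)
    n_g <- length(members)
    if (n_g < 2) abort(sprintf("minority group '%s' has fewer than 2 members; cannot upsample", g))
    k <- k_neighbors
    if (k > nrow(train) - 1) {
      warn(sprintf("k_neighbors clamped to %d (training set size)", nrow(train) - 1))
      k <- nrow(train) - 1
    }
    k_in <- min(k, n_g - 1)
    if (k_in < k) warn(sprintf("within-group neighbors for '%s' clamped to %d", g, k_in))
    # borderline ("danger") rule on neighbors in the whole training set
    danger <- members[vapply(members, function(i) {
      nb <- order(D[i, ])[seq_len(k)]
      m_other <- sum(train$group[nb] != g)
      m_other >= k / 2 && m_other < k
    }, logical(1))]
    if (length(danger) == 0) {
      warn(sprintf("no borderline samples in minority group '%s'; using all members as seeds", g))
      danger <- members
    }
    need <- n_maj - n_g
    seeds <- danger[(seq_len(need) - 1) %% length(danger) + 1]
    synth <- matrix(0, need, length(cols))
    for (s in seq_len(need)) {
      i <- seeds[s]
      nb_in <- members[members != i][order(D[i, members[members != i]])][seq_len(k_in)]
      j <- nb_in[sample.int(k_in, 1)]
      u <- runif(1)
      synth[s, ] <- X[i, ] + u * (X[j, ] - X[i, ])
    }
    add <- train[seeds, ]
    add[, cols] <- as.data.frame(synth)
    add$subject_id <- sprintf("%s_smote%03d", g, seq_len(need))
    add$.synthetic <- TRUE
    out <- dplyr::bind_rows(out, add)
  }
  out
}

#' Lasso dominance probabilities for PCA modes
#'
#' Stability selection by repeated intercept-free lasso fits of the binary
#' label on the loadings: for each of `n_repeats` random subsets (fraction
#' `subset_fraction`, without replacement, redrawn until both classes are
#' present), an L1-regularized linear model is fit with the regularization
#' strength chosen by 3-fold cross-validation over a 100-value path; a
#' mode's dominance is the fraction of repeats in which its weight is
#' non-zero.
#'
#' @param train training tibble (possibly SMOTE-balanced).
#' @param n_repeats number of subset fits (default 1000).
#' @param subset_fraction subset size as a fraction of the training set.
#' @param seed integer seed.
#' @return an `rv_dominance`: tibble with `mode` (index), `dominance`, plus
#'   attributes `n_repeats` and `subset_fraction`.
#' @export
lasso_dominance <- function(train, n_repeats = 1000, subset_fraction = 0.8, seed = 1L) {
  cols <- mode_cols(train)
  X <- as.matrix(train[, cols])
  y <- cohort_y(train)
  keep <- apply(X, 2, function(c) stats::sd(c) > 0)
  if (!all(keep)) {
    warn(sprintf("excluding %d constant loading column(s); their dominance is 0", sum(!keep)))
  }
  Xk <- X[, keep, drop = FALSE]
  n <- nrow(Xk)
  m <- floor(subset_fraction * n)
  set.seed(seed)
  counts <- numeric(ncol(Xk))
  for (r in seq_len(n_repeats)) {
    for (try in 1:100) {
      idx <- sample.int(n, m)
      if (length(unique(y[idx])) == 2) break
    }
    # stratified 3-fold assignment keeps both classes in every CV training set
    yi <- y[idx]
    foldid <- integer(length(yi))
    for (c in unique(yi)) {
      members <- which(yi == c)
      foldid[members] <- sample(rep_len(1:3, length(members)))
    }
    cv <- glmnet::cv.glmnet(Xk[idx, , drop = FALSE], yi, family = "gaussian",
                            intercept = FALSE, standardize = FALSE,
                            foldid = foldid, nlambda = 100, maxit = 1e5)
    w <- as.vector(coef(cv, s = "lambda.min"))[-1]
    counts <- counts + (abs(w) > 0)
  }
  dom <- numeric(length(cols))
  dom[keep] <- counts / n_repeats
  res <- tibble::tibble(mode = seq_along(cols), dominance = dom)
  attr(res, "n_repeats") <- n_repeats
  attr(res, "subset_fraction") <- subset_fraction
  class(res) <- c("rv_dominance", class(res))
  res
}

#' Select the most dominant PCA modes
#'
#' @param result an `rv_dominance`.
#' @param n number of modes (default 4). Ties are broken by lower mode index.
#' @return integer mode indices, sorted by decreasing dominance.
#' @export
select_top_modes <- function(result, n = 4) {
  nz <- sum(result$dominance > 0)
  if (nz < n) {
    abort(sprintf("only %d mode(s) have non-zero dominance (need %d): %s",
                  nz, n, paste(result$mode[result$dominance > 0], collapse = ", ")))
  }
  ord <- order(-result$dominance, result$mode)
  sort_by_dom <- result$mode[ord]
  sort_by_dom[seq_len(n)]
}

#' Dominance bar chart
#'
#' @param object an `rv_dominance`.
#' @param top_n highlight the top-n modes (default 4).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rv_dominance <- function(object, top_n = 4, ...) {
  sel <- select_top_modes(object, min(top_n, sum(object$dominance > 0)))
  d <- dplyr::mutate(tibble::as_tibble(object), selected = .data$mode %in% sel)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$mode), y = .data$dominance,
                                  fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = "PCA mode", y = "dominance probability") +
    ggplot2::theme_minimal()
}

#' Fit the TR logistic classifier on selected modes
#'
#' Ridge-regularized logistic regression of the binary TR label on the
#' selected loadings, with the regularization strength chosen by 3-fold
#' cross-validation (AUC criterion when class sizes permit, otherwise
#' deviance). Decision threshold 0.5.
#'
#' @param train training tibble.
#' @param modes integer mode indices (from [select_top_modes()]).
#' @param seed integer seed (controls CV fold assignment).
#' @return an `rv_classifier`.
#' @export
fit_classifier <- function(train, modes, seed = 1L) {
  if (length(modes) == 0) abort("modes must be non-empty")
  cols <- paste0("s", modes)
  X <- as.matrix(train[, cols])
  pad <- ncol(X) == 1  # glmnet needs >= 2 columns; pad with an inert zero
  if (pad) X <- cbind(X, 0)
  y <- cohort_y(train)
  if (length(unique(y)) < 2) abort("training data contain a single class")
  set.seed(seed)
  # stratified 3-fold assignment
  foldid <- integer(length(y))
  for (c in unique(y)) {
    members <- which(y == c)
    foldid[members] <- sample(rep_len(1:3, length(members)))
  }
  measure <- if (min(table(y, foldid)) >= 4) "auc" else "deviance"
  # explicit ridge path: glmnet's automatic lambda sequence for alpha = 0
  # stops far above the unpenalized fit, which squashes all probabilities
  # toward the class prior
  lam <- 10^seq(3, -6, length.out = 100)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0, lambda = lam,
                          type.measure = measure, foldid = foldid, maxit = 1e5)
  # AUC is a ranking criterion: on well-separated data it plateaus at its
  # maximum over a wide range of lambda, and the conventional tie-break
  # (largest lambda) yields probabilities squashed toward the class prior.
  # Among models with equal CV score, prefer the least-penalized one.
  better <- if (measure == "auc") cv$cvm >= max(cv$cvm) - 1e-10 else
    cv$cvm <= min(cv$cvm) + 1e-10
  lambda_sel <- min(cv$lambda[better])
  structure(list(fit = cv, modes = modes, measure = measure,
                 lambda = lambda_sel, pad = pad,
                 cv_value = if (measure == "auc") max(cv$cvm) else min(cv$cvm)),
            class = "rv_classifier")
}

#' @export
print.rv_classifier <- function(x, ...) {
  cat(sprintf("<rv_classifier> logistic model on modes {%s}; CV %s = %.3f\n",
              paste(x$modes, collapse = ", "), x$measure, x$cv_value))
  invisible(x)
}

#' @export
predict.rv_classifier <- function(object, newdata, type = "prob", ...) {
  X <- as.matrix(newdata[, paste0("s", object$modes)])
  if (isTRUE(object$pad)) X <- cbind(X, 0)
  p <- as.vector(predict(object$fit, newx = X, s = object$lambda, type = "response"))
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' @export
tidy.rv_classifier <- function(x, ...) {
  co <- as.vector(coef(x$fit, s = x$lambda))
  if (isTRUE(x$pad)) co <- co[-length(co)]
  tibble::tibble(term = c("(Intercept)", paste0("s", x$modes)), estimate = co)
}

#' Evaluate a classifier on the test set
#'
#' Confusion counts at probability threshold 0.5 and the standard metrics
#' computed directly from them: accuracy = (TN + TP) / (TN + TP + FN + FP),
#' precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F1 = 2 * precision * recall / (precision + recall). The ROC curve is a
#' threshold sweep over the predicted probabilities and the AUC its
#' trapezoid-rule area (undefined for a single-class test set).
#'
#' @param classifier an `rv_classifier`.
#' @param test test tibble (never SMOTE-balanced).
#' @return an `rv_report`: list with `confusion`, `metrics`, `roc`, `auc`.
#' @export
evaluate <- function(classifier, test) {
  if (nrow(test) == 0) abort("test set is empty")
  classification_report(predict(classifier, test), cohort_y(test))
}

#' @rdname evaluate
#' @param p predicted probabilities of the positive (TR) class.
#' @param y binary labels (1 = TR).
#' @param threshold decision threshold (default 0.5).
#' @export
classification_report <- function(p, y, threshold = 0.5) {
  pred <- as.integer(p >= threshold)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tp <- sum(pred == 1 & y == 1)
  div <- function(a, b) if (b == 0) 0 else a / b
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  metrics <- tibble::tibble(
    accuracy = (tn + tp) / (tn + tp + fn + fp),
    precision = precision, recall = recall,
    f1 = div(2 * recall * precision, recall + precision))
  # ROC threshold sweep
  if (length(unique(y)) == 2) {
    th <- c(Inf, sort(unique(p), decreasing = TRUE))
    roc <- tibble::tibble(
      threshold = th,
      tpr = vapply(th, function(t) mean(p[y == 1] >= t), numeric(1)),
      fpr = vapply(th, function(t) mean(p[y == 0] >= t), numeric(1)))
    if (utils::tail(roc$fpr, 1) < 1 || utils::tail(roc$tpr, 1) < 1) {
      roc <- dplyr::bind_rows(roc, tibble::tibble(threshold = -Inf, tpr = 1, fpr = 1))
    }
    auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  } else {
    roc <- tibble::tibble(threshold = numeric(), tpr = numeric(), fpr = numeric())
    auc <- NA_real_
  }
  structure(list(
    confusion = tibble::tibble(tn = tn, fp = fp, fn = fn, tp = tp),
    metrics = metrics, roc = roc, auc = auc, n_test = length(y)),
    class = "rv_report")
}

#' @export
print.rv_report <- function(x, ...) {
  with(x$confusion, cat(sprintf("<rv_report> n=%d  TN=%d FP=%d FN=%d TP=%d\n",
                                x$n_test, tn, fp, fn, tp)))
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f  AUC %s\n",
              x$metrics$accuracy, x$metrics$precision, x$metrics$recall,
              x$metrics$f1, ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' @export
tidy.rv_report <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.rv_report <- function(x, ...) {
  dplyr::bind_cols(x$confusion, x$metrics, tibble::tibble(auc = x$auc, n_test = x$n_test))
}

#' ROC curve plot
#'
#' @param object an `rv_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rv_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Run the full classification stage on a loadings table
#'
#' Convenience wrapper chaining [split_train_test()], [borderline_smote()],
#' [lasso_dominance()], [select_top_modes()], [fit_classifier()] and
#' [evaluate()], with sub-seeds derived deterministically from `seed`.
#'
#' @param cohort loadings tibble.
#' @param train_fraction,smote_k,n_repeats,subset_fraction,top_modes stage
#'   parameters (defaults 0.8, 5, 1000, 0.8, 4).
#' @param seed integer seed.
#' @return list with `split`, `balanced`, `dominance`, `modes`, `classifier`,
#'   `report`.
#' @export
classify_pipeline <- function(cohort, train_fraction = 0.8, smote_k = 5,
                              n_repeats = 1000, subset_fraction = 0.8,
                              top_modes = 4, seed = 1L) {
  split <- split_train_test(cohort, train_fraction, seed = derive_seed(seed, 1))
  balanced <- borderline_smote(split$train, smote_k, seed = derive_seed(seed, 2))
  dominance <- lasso_dominance(balanced, n_repeats, subset_fraction,
                               seed = derive_seed(seed, 3))
  modes <- select_top_modes(dominance, top_modes)
  clf <- fit_classifier(balanced, modes, seed = derive_seed(seed, 4))
  report <- evaluate(clf, split$test)
  list(split = split, balanced = balanced, dominance = dominance,
       modes = modes, classifier = clf, report = report)
}
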