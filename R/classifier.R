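#' Rank-based AUROC
#'
#' Area under the ROC curve via the Mann-Whitney identity: the fraction
#' of (positive, negative) score pairs ranked concordantly, ties counting
#' one half (midranks).
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels; the positive class is the second factor
#'   level (or `positive`).
#' @param positive optional explicit positive-class label.
#' @return AUROC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (!is.factor(labels)) labels <- factor(labels)
  if (nlevels(labels) != 2) stop("need exactly two classes")
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

rf_fit <- function(xtr, ytr, ntree) {
  randomForest::randomForest(x = xtr, y = ytr, ntree = ntree)
}

rf_score <- function(fit, xte, positive)
  stats::predict(fit, xte, type = "prob")[, positive]

loocv_auc <- function(x, y, ntree, positive) {
  scores <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    fit <- rf_fit(x[-i, , drop = FALSE], y[-i], ntree)
    scores[i] <- rf_score(fit, x[i, , drop = FALSE], positive)
  }
  roc_auc(scores, y, positive)
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Nested random-forest classification with recursive feature selection
#'
#' The full workflow: outer stratified k-fold cross-validation; within
#' each outer training set, features are ranked by mean-decrease-Gini
#' importance of a forest on all features, and a recursive feature
#' elimination over a size grid (powers of two up to min(p, 64), plus p)
#' is scored by leave-one-out AUROC to pick the feature-set size; the
#' final model for the fold is trained on the outer-train subjects with
#' the selected features and evaluated once on the held-out fold. AUROC,
#' accuracy, sensitivity and specificity (0.5 posterior threshold) are
#' averaged over folds; importances are averaged across folds; the
#' consensus set is the intersection of all folds' selections.
#'
#' @param features subjects x variables numeric matrix (no NAs).
#' @param labels two-level factor per subject; the second level is the
#'   positive class for AUROC/sensitivity.
#' @param n_outer outer folds (default 5).
#' @param ntree trees per forest (default 500).
#' @param size_grid optional vector of candidate feature-set sizes.
#' @param seed integer seed; fixes folds and forests.
#' @return object of class `cv_report`: `folds` (per-fold metrics and
#'   selected features), `metrics` (averaged), `importance` (mean
#'   mean-decrease-Gini per feature), `consensus_features`, `scores`
#'   (out-of-fold positive-class probability per subject).
#' @export
nested_rf_classify <- function(features, labels, n_outer = 5, ntree = 500,
                               size_grid = NULL, seed = 1L) {
  features <- as.matrix(features)
  if (anyNA(features)) stop("features must be complete")
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must have two levels")
  if (min(table(y)) < 2) stop("need >= 2 subjects per class")
  positive <- levels(y)[2]
  p <- ncol(features)
  if (is.null(size_grid)) {
    size_grid <- 2^(1:6)
    size_grid <- unique(c(size_grid[size_grid < min(p, 64)], min(p, 64), p))
    size_grid <- size_grid[size_grid <= p]
  }
  set.seed(seed)
  folds <- stratified_folds(y, n_outer)
  fold_out <- vector("list", n_outer)
  imp_sum <- stats::setNames(numeric(p), colnames(features))
  oof_scores <- rep(NA_real_, length(y))
  for (f in seq_len(n_outer)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2) stop("class absent from outer-train")
    xtr <- features[tr, , drop = FALSE]; ytr <- y[tr]
    rank_fit <- rf_fit(xtr, ytr, ntree)
    imp <- randomForest::importance(rank_fit, type = 2)[, 1]
    ord <- order(imp, decreasing = TRUE)
    best_auc <- -Inf; best_size <- size_grid[1]
    for (s in sort(size_grid)) {
      auc_s <- loocv_auc(xtr[, ord[seq_len(s)], drop = FALSE], ytr,
                         ntree, positive)
      # ties go to the larger set: correlated informative features carry
      # indistinguishable inner scores and should not be discarded
      if (auc_s >= best_auc) { best_auc <- auc_s; best_size <- s }
    }
    sel <- colnames(features)[ord[seq_len(best_size)]]
    final <- rf_fit(xtr[, sel, drop = FALSE], ytr, ntree)
    sc <- rf_score(final, features[te, sel, drop = FALSE], positive)
    oof_scores[te] <- sc
    pred <- factor(ifelse(sc >= 0.5, positive, levels(y)[1]),
                   levels = levels(y))
    cm <- table(truth = y[te], pred = pred)
    tp <- cm[positive, positive]; tn <- cm[1, 1]
    fn <- cm[positive, 1]; fp <- cm[1, positive]
    fold_auc <- if (length(unique(y[te])) == 2)
      roc_auc(sc, y[te], positive) else NA_real_
    fimp <- randomForest::importance(final, type = 2)[, 1]
    imp_sum[names(fimp)] <- imp_sum[names(fimp)] + fimp
    fold_out[[f]] <- list(
      selected = sel, size = best_size, inner_auc = best_auc,
      auroc = fold_auc,
      accuracy = (tp + tn) / sum(cm),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      confusion = cm)
  }
  metrics <- c(
    auroc = mean(vapply(fold_out, `[[`, numeric(1), "auroc"),
                 na.rm = TRUE),
    accuracy = mean(vapply(fold_out, `[[`, numeric(1), "accuracy")),
    sensitivity = mean(vapply(fold_out, `[[`, numeric(1), "sensitivity"),
                       na.rm = TRUE),
    specificity = mean(vapply(fold_out, `[[`, numeric(1), "specificity"),
                       na.rm = TRUE))
  consensus <- Reduce(intersect, lapply(fold_out, `[[`, "selected"))
  structure(list(folds = fold_out, metrics = metrics,
                 importance = sort(imp_sum / n_outer, decreasing = TRUE),
                 consensus_features = consensus,
                 scores = oof_scores, labels = y, positive = positive,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report (", length(x$folds), "outer folds )\n")
  cat(sprintf(
    "  AUROC %.3f | accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
    x$metrics["auroc"], x$metrics["accuracy"], x$metrics["sensitivity"],
    x$metrics["specificity"]))
  cat("  consensus features:", length(x$consensus_features), "\n")
  invisible(x)
}

#' Temporal-CoV feature matrix for stability classification
#'
#' Turns a [stability_profile()] into a subjects x taxa matrix of
#' temporal coefficients of variation, plus one indicator column per
#' taxon absent (all-zero) in at least one subject, flagging CoV values
#' that are 0 by convention rather than by constancy.
#'
#' @param profile a [stability_profile()].
#' @return numeric matrix ready for [nested_rf_classify()].
#' @export
cov_feature_matrix <- function(profile) {
  stopifnot(inherits(profile, "stability_profile"))
  m <- profile$cov_taxa
  m[is.na(m)] <- 0
  absent <- which(colSums(m == 0) > 0)
  if (length(absent)) {
    flags <- (m[, absent, drop = FALSE] == 0) * 1
    colnames(flags) <- paste0(colnames(m)[absent], "_absent")
    m <- cbind(m, flags)
  }
  m
}

#' Integrate top predictors across datasets
#'
#' Takes the importance-ranked top k features of each per-dataset
#' [nested_rf_classify()] report, namespaces them by dataset, pools the
#' matching columns into one matrix and re-runs the nested workflow on
#' it.
#'
#' @param reports named list of `cv_report`s, one per dataset.
#' @param matrices named list of the matching subjects x variables
#'   matrices (same subject order across datasets).
#' @param labels class labels per subject.
#' @param k_per_dataset how many top features per dataset (default 5).
#' @param ... passed to [nested_rf_classify()].
#' @return a `cv_report` for the integrated model; feature names carry
#'   a `dataset.` prefix.
#' @export
integrate_top_features <- function(reports, matrices, labels,
                                   k_per_dataset = 5, ...) {
  if (length(reports) < 2) stop("need >= 2 source datasets")
  if (k_per_dataset < 1) stop("k_per_dataset must be >= 1")
  stopifnot(identical(names(reports), names(matrices)))
  blocks <- lapply(names(reports), function(nm) {
    imp <- reports[[nm]]$importance
    top <- names(imp)[seq_len(min(k_per_dataset, length(imp)))]
    top <- intersect(top, colnames(matrices[[nm]]))
    blk <- matrices[[nm]][, top, drop = FALSE]
    colnames(blk) <- paste(nm, top, sep = ".")
    blk
  })
  integrated <- do.call(cbind, blocks)
  if (ncol(integrated) == 0) stop("empty integrated feature set")
  nested_rf_classify(integrated, labels, ...)
}
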