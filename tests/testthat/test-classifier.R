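test_that("roc_auc matches pair enumeration and its extremes", {
  lab <- factor(c("n", "n", "p", "p"), levels = c("n", "p"))
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), lab), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), lab), 0)
  lab2 <- factor(c("p", "n", "p", "n"), levels = c("n", "p"))
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), lab2), 0.75)
  set.seed(44)
  for (i in 1:10) {
    sc <- sample(seq(0, 1, 0.05), 14, replace = TRUE)  # with ties
    y <- sample(c(TRUE, FALSE), 14, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(sc, factor(y, levels = c(FALSE, TRUE)),
                         positive = "TRUE"),
                 auc_brute(sc, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, factor(rep("a", 3), levels = c("a", "b"))),
               "both classes")
  # equivalence with the Mann-Whitney U statistic on tie-free input
  sc <- c(2.3, 1.1, 3.7, 0.4, 2.9, 1.8)
  y <- factor(c("p", "n", "p", "n", "p", "n"), levels = c("n", "p"))
  U <- unname(wilcox.test(sc[y == "p"], sc[y == "n"],
                          exact = TRUE)$statistic)
  expect_equal(roc_auc(sc, y), U / 9, tolerance = 1e-12)
})

test_that("a perfectly separating feature gives AUROC 1 in every fold", {
  set.seed(1)
  n <- 24
  y <- factor(rep(c("HS", "LS"), each = n / 2))
  feats <- cbind(sep = ifelse(y == "LS", 1, 0) + rnorm(n, sd = 0.01),
                 noise = rnorm(n))
  rownames(feats) <- paste0("s", 1:n)
  rep <- nested_rf_classify(feats, y, ntree = 100, seed = 2)
  aucs <- vapply(rep$folds, `[[`, numeric(1), "auroc")
  expect_true(all(aucs == 1))
  expect_true("sep" %in% rep$consensus_features)
})

test_that("planted informative features are found; permuted labels are not", {
  set.seed(5)
  n <- 40; p <- 60; n_inf <- 8
  y <- factor(rep(c("HS", "LS"), each = n / 2))
  feats <- matrix(rnorm(n * p), n, p,
                  dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
  feats[y == "LS", 1:n_inf] <- feats[y == "LS", 1:n_inf] + 2
  rep <- nested_rf_classify(feats, y, ntree = 150, seed = 3)
  expect_gte(rep$metrics[["auroc"]], 0.85)
  expect_gte(sum(paste0("f", 1:n_inf) %in% rep$consensus_features), 4)
  # label permutation null, a few seeds
  null_auc <- vapply(1:3, function(s) {
    set.seed(400 + s)
    yp <- sample(y)
    nested_rf_classify(feats, yp, ntree = 100,
                       seed = s)$metrics[["auroc"]]
  }, numeric(1))
  expect_gt(mean(null_auc), 0.3)
  expect_lt(mean(null_auc), 0.7)
})

test_that("fold bookkeeping: confusion sums, consensus containment, determinism", {
  set.seed(9)
  n <- 30; y <- factor(rep(c("HS", "LS"), 15))
  feats <- matrix(rnorm(n * 12), n, 12,
                  dimnames = list(paste0("s", 1:n), paste0("f", 1:12)))
  feats[, 1] <- feats[, 1] + ifelse(y == "LS", 1.5, 0)
  r1 <- nested_rf_classify(feats, y, ntree = 100, seed = 7)
  r2 <- nested_rf_classify(feats, y, ntree = 100, seed = 7)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$scores, r2$scores)
  for (f in r1$folds)
    expect_true(all(r1$consensus_features %in% f$selected))
  # confusion matrices jointly cover every subject exactly once
  expect_equal(sum(vapply(r1$folds, function(f) sum(f$confusion),
                          numeric(1))), n)
  expect_true(all(!is.na(r1$scores)))
  expect_true(all(vapply(r1$folds, function(f) sum(f$confusion),
                         numeric(1)) > 0))
})

test_that("outer-fold test subjects cannot leak into selection", {
  # perturbing a TEST subject's features must not change that fold's
  # selected feature set; perturbing a TRAIN subject may
  set.seed(13)
  n <- 20; y <- factor(rep(c("HS", "LS"), 10))
  feats <- matrix(rnorm(n * 8), n, 8,
                  dimnames = list(paste0("s", 1:n), paste0("f", 1:8)))
  r1 <- nested_rf_classify(feats, y, n_outer = 4, ntree = 80, seed = 5)
  # find which subjects were in fold 1's test set by reproducing folds
  set.seed(5)
  folds <- microstab:::stratified_folds(y, 4)
  test_subj <- which(folds == 1)
  feats2 <- feats
  feats2[test_subj, ] <- feats2[test_subj, ] + 100
  r2 <- nested_rf_classify(feats2, y, n_outer = 4, ntree = 80, seed = 5)
  expect_identical(r1$folds[[1]]$selected, r2$folds[[1]]$selected)
  expect_identical(r1$folds[[1]]$size, r2$folds[[1]]$size)
})

test_that("CoV feature matrix has subject rows and flags absent taxa", {
  sim <- simulate_cohort(cohort_scenario(n_subjects = 16, n_taxa = 30,
                                         depth_mean = 3000), seed = 3)
  rare <- suppressWarnings(rarefy_cohort(sim$cohort, 2000, seed = 1))
  prof <- stability_profile(rare, seed = 1)
  m <- cov_feature_matrix(prof)
  expect_equal(nrow(m), 16)
  expect_true(all(is.finite(m)))
  expect_true(any(grepl("_absent$", colnames(m))) ||
                all(rare$counts > 0))
})

test_that("driver-taxon CoV separates planted classes near the top", {
  # CoV from four timepoints is noisy, so the check is that a majority
  # of the ten drivers land in the top decile of 200 taxa and that the
  # median driver rank is inside the decile
  stats_per_seed <- vapply(1:3, function(s) {
    sim <- simulate_cohort(cohort_scenario(n_subjects = 60, n_taxa = 200,
                                           depth_mean = 10000), seed = s)
    rare <- suppressWarnings(rarefy_cohort(sim$cohort, 6000, seed = 1))
    cm <- cov_by_subject(rare$counts, rare$samples$subject)
    cm[is.na(cm)] <- 0
    cls <- setNames(sim$truth$class, sim$truth$subject)[rownames(cm)]
    sepr <- apply(cm, 2, function(v) {
      n1 <- sum(cls == "LS"); n0 <- sum(cls == "HS")
      sp <- sqrt(((n1 - 1) * var(v[cls == "LS"]) +
                    (n0 - 1) * var(v[cls == "HS"])) / (n1 + n0 - 2))
      abs(mean(v[cls == "LS"]) - mean(v[cls == "HS"])) / (sp + 1e-12)
    })
    rk <- rank(-sepr)[sim$driver_taxa]
    c(frac = mean(rk <= ncol(cm) / 10), med = median(rk))
  }, numeric(2))
  expect_gte(mean(stats_per_seed["frac", ]), 0.5)
  expect_lte(median(stats_per_seed["med", ]), 20)
})

test_that("integration of top features never loses much and is invariant to duplication", {
  set.seed(21)
  n <- 30; y <- factor(rep(c("HS", "LS"), 15))
  inf <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(paste0("s", 1:n), paste0("i", 1:10)))
  inf[y == "LS", 1:3] <- inf[y == "LS", 1:3] + 2
  noise <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(paste0("s", 1:n), paste0("z", 1:10)))
  r_inf <- nested_rf_classify(inf, y, ntree = 100, seed = 2)
  r_noise <- nested_rf_classify(noise, y, ntree = 100, seed = 2)
  r_int <- integrate_top_features(
    list(inf = r_inf, noise = r_noise),
    list(inf = inf, noise = noise), y, k_per_dataset = 5,
    ntree = 100, seed = 2)
  expect_gte(r_int$metrics[["auroc"]],
             r_inf$metrics[["auroc"]] - 0.1)
  # duplicated dataset: namespaced consensus reduces to the single set
  r_dup <- integrate_top_features(
    list(a = r_inf, b = r_inf), list(a = inf, b = inf), y,
    k_per_dataset = 5, ntree = 100, seed = 2)
  stripped <- unique(sub("^[ab]\\.", "", r_dup$consensus_features))
  top5 <- names(r_inf$importance)[1:5]
  expect_true(all(stripped %in% top5))
  expect_error(integrate_top_features(list(a = r_inf, b = r_noise),
                                      list(a = inf, b = noise), y,
                                      k_per_dataset = 0), "k_per_dataset")
})
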