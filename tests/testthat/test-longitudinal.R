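test_that("rmcorr is exact on parallel-line constructions", {
  subj <- rep(c("a", "b", "c"), each = 4)
  x <- rep(1:4, 3)
  y_up <- x + rep(c(0, 5, 10), each = 4)
  up <- rmcorr_test(x, y_up, subj)
  expect_equal(up$r, 1)
  expect_equal(up$p, 0)
  dn <- rmcorr_test(x, -x + rep(c(0, 5, 10), each = 4), subj)
  expect_equal(dn$r, -1)
  expect_equal(up$df, 12 - 3 - 1)
})

test_that("rmcorr matches the ANCOVA normal-equations oracle", {
  set.seed(55)
  for (i in 1:20) {
    ns <- sample(4:7, 1); nt <- sample(3:5, 1)
    subj <- rep(paste0("s", seq_len(ns)), each = nt)
    x <- rnorm(ns * nt)
    y <- 0.4 * x + rnorm(ns * nt) + rep(rnorm(ns, sd = 2), each = nt)
    got <- rmcorr_test(x, y, subj)
    want <- rmcorr_brute(x, y, subj)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("rmcorr is invariant to per-subject constant shifts", {
  set.seed(8)
  subj <- rep(paste0("s", 1:5), each = 4)
  x <- rnorm(20); y <- rnorm(20)
  base <- rmcorr_test(x, y, subj)
  shift_x <- x + rep(c(10, -3, 7, 0, 100), each = 4)
  shift_y <- y + rep(c(-5, 2, 0, 50, 1), each = 4)
  shifted <- rmcorr_test(shift_x, shift_y, subj)
  expect_equal(shifted$r, base$r, tolerance = 1e-12)
  expect_equal(shifted$p, base$p, tolerance = 1e-12)
})

test_that("rmcorr drops thin subjects and the matrix form agrees pairwise", {
  set.seed(12)
  subj <- c(rep("a", 4), rep("b", 4), "c")
  x <- rnorm(9); y <- rnorm(9)
  expect_warning(rmcorr_test(x, y, subj), "c")
  m <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("u", "v", "w")))
  sub20 <- rep(paste0("s", 1:5), each = 4)
  rm <- rmcorr_matrix(m, sub20)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    single <- rmcorr_test(m[, pair[1]], m[, pair[2]], sub20)
    expect_equal(rm$r[pair[1], pair[2]], single$r, tolerance = 1e-12)
    expect_equal(rm$p[pair[1], pair[2]], single$p, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the hand step-up and is monotone", {
  expect_equal(bh_adjust(c(0.005, 0.04, 0.05)), c(0.015, 0.05, 0.05))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  set.seed(4)
  p <- runif(50)
  expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  expect_true(all(bh_adjust(p) >= p))
  # families adjusted independently
  fam <- rep(c("x", "y"), each = 25)
  qf <- bh_adjust(p, family = fam)
  expect_equal(qf[fam == "x"], bh_brute(p[fam == "x"]), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("mixed-model differential testing flags planted group shifts", {
  set.seed(66)
  ns <- 30; nt <- 4; p <- 40; n_true <- 6
  subj <- rep(paste0("s", 1:ns), each = nt)
  grp <- rep(rep(c("HS", "LS"), each = ns / 2), each = nt)
  feats <- matrix(rnorm(ns * nt * p), ns * nt, p,
                  dimnames = list(NULL, paste0("f", 1:p)))
  feats <- feats + rep(rnorm(ns, sd = 0.5), each = nt)  # subject effect
  feats[grp == "LS", 1:n_true] <- feats[grp == "LS", 1:n_true] + 1
  res <- differential_longitudinal(feats, grp, subj)
  hits <- res$feature[res$significant]
  expect_gte(sum(paste0("f", 1:n_true) %in% hits), n_true - 1)
  false_hits <- setdiff(hits, paste0("f", 1:n_true))
  expect_lte(length(false_hits), 3)
  expect_true(all(res$significant == (res$p < 0.05 & res$q < 0.15),
                  na.rm = TRUE))
  # constant feature is skipped with a note
  feats[, p] <- 1
  res2 <- differential_longitudinal(feats[, c(p - 1, p)], grp, subj)
  expect_identical(res2$note[2], "constant")
  expect_true(is.na(res2$p[2]))
})

test_that("null differential features are flagged at no more than chance", {
  set.seed(99)
  ns <- 24; nt <- 3; p <- 60
  subj <- rep(paste0("s", 1:ns), each = nt)
  grp <- rep(rep(c("HS", "LS"), each = ns / 2), each = nt)
  rates <- vapply(1:5, function(i) {
    subj_eff <- matrix(rnorm(ns * p, sd = 0.5), ns, p)
    feats <- matrix(rnorm(ns * nt * p), ns * nt, p,
                    dimnames = list(NULL, paste0("f", 1:p))) +
      subj_eff[rep(seq_len(ns), each = nt), ]
    res <- differential_longitudinal(feats, grp, subj)
    mean(res$significant, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(rates), 0.07)
})

test_that("stratified PERMANOVA agrees with vegan and nails extremes", {
  set.seed(10)
  m <- matrix(rpois(120, 30) + 1, 12, 10)
  rownames(m) <- paste0("s", 1:12)
  d <- vegan::vegdist(m, "bray")
  fac <- factor(rep(c("A", "B"), 6))
  got <- permanova_stratified(d, fac, strata = NULL, n_perm = 199,
                              seed = 3)
  ref <- vegan::adonis2(d ~ fac, permutations = 199)
  expect_equal(got$F, ref$F[1], tolerance = 1e-10)
  expect_equal(got$R2, ref$R2[1], tolerance = 1e-10)
  # perfectly separating factor -> minimal p
  two <- rbind(matrix(c(100, 0), 10, 2, byrow = TRUE) + rpois(20, 1),
               matrix(c(0, 100), 10, 2, byrow = TRUE) + rpois(20, 1))
  rownames(two) <- paste0("t", 1:20)
  d2 <- vegan::vegdist(two, "bray")
  sep <- factor(rep(c("A", "B"), each = 10))
  got2 <- permanova_stratified(d2, sep, n_perm = 99, seed = 1)
  expect_equal(got2$p, 1 / 100)
  # full-rank one-hot factor on 3 samples -> R2 = 1
  d3 <- dist(matrix(c(0, 1, 5), 3, 1))
  got3 <- permanova_stratified(d3, factor(c("a", "b", "c")),
                               n_perm = 19, seed = 1)
  expect_equal(got3$R2, 1, tolerance = 1e-10)
  expect_error(permanova_stratified(d3, rep(1, 3)), "constant")
})

test_that("within-stratum permutations never move values across subjects", {
  set.seed(20)
  n_subj <- 6; nt <- 4
  subj <- rep(paste0("s", 1:n_subj), each = nt)
  m <- matrix(rpois(n_subj * nt * 8, 20) + 1, n_subj * nt, 8)
  rownames(m) <- paste0("x", seq_len(nrow(m)))
  d <- vegan::vegdist(m, "bray")
  # a variable constant within each subject is invariant under
  # within-subject permutation, so every permuted F equals F_obs and
  # the permutation p-value is 1
  v <- rep(rnorm(n_subj), each = nt)
  fit <- permanova_stratified(d, v, strata = subj, n_perm = 99, seed = 2)
  expect_equal(fit$p, 1)
})
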