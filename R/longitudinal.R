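#' Repeated-measures correlation
#'
#' Estimates the common within-subject association between two
#' longitudinally measured variables via the ANCOVA formulation: y is
#' modelled with a separate intercept per subject and a shared slope in x.
#' Algebraically this reduces to the Pearson correlation of the
#' within-subject-centered x and y, with the ANCOVA error degrees of
#' freedom df = N - k - 1 (N complete pairs, k subjects). p is two-sided
#' from the t distribution on that df.
#'
#' @param x,y numeric vectors of paired longitudinal measurements.
#' @param subject subject ID per observation.
#' @return object of class `rmcorr_fit`: list with `r`, `df`, `p`,
#'   `slope`, `n_obs`, `n_subjects`. Subjects with < 2 complete pairs are
#'   dropped with a warning; fewer than 2 usable subjects is an error.
#' @export
rmcorr_test <- function(x, y, subject) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]; subject <- as.character(subject)[ok]
  cnt <- table(subject)
  drop <- names(cnt)[cnt < 2]
  if (length(drop)) {
    warning("dropping subjects with <2 complete pairs: ",
            paste(drop, collapse = ", "))
    keep <- !(subject %in% drop)
    x <- x[keep]; y <- y[keep]; subject <- subject[keep]
  }
  k <- length(unique(subject))
  if (k < 2) stop("need at least 2 subjects with >=2 complete pairs")
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  n <- length(x)
  df <- n - k - 1
  if (df < 1) stop("not enough observations: df = ", df)
  ssx <- sum(xc^2)
  if (ssx == 0) stop("x is constant within every subject")
  slope <- sum(xc * yc) / ssx
  ssy <- sum(yc^2)
  r <- if (ssy == 0) 0 else sum(xc * yc) / sqrt(ssx * ssy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  structure(list(r = r, df = df, p = p, slope = slope, n_obs = n,
                 n_subjects = k), class = "rmcorr_fit")
}

#' @export
print.rmcorr_fit <- function(x, ...) {
  cat(sprintf("rmcorr: r = %.4f, df = %d, p = %.4g (%d obs, %d subjects)\n",
              x$r, x$df, x$p, x$n_obs, x$n_subjects))
  invisible(x)
}

#' All-pairs repeated-measures correlation matrix
#'
#' Vectorised rmcorr over every column pair of a samples x variables
#' matrix: each column is centered within subject and the Pearson
#' correlation matrix of the centered data is the matrix of rmcorr r
#' values (identical to running [rmcorr_test()] per pair), with common
#' df = N - k - 1.
#'
#' @param mat numeric matrix, observations x variables (no NAs).
#' @param subject subject ID per row.
#' @return list with `r` (variables x variables), `p` (same shape),
#'   `df`.
#' @export
rmcorr_matrix <- function(mat, subject) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("rmcorr_matrix requires complete data")
  subject <- as.character(subject)
  k <- length(unique(subject))
  n <- nrow(mat)
  df <- n - k - 1
  if (df < 1) stop("not enough observations for df = N - k - 1 >= 1")
  cen <- apply(mat, 2, function(v) v - stats::ave(v, subject))
  ss <- colSums(cen^2)
  cp <- crossprod(cen)
  denom <- sqrt(outer(ss, ss))
  r <- ifelse(denom > 0, cp / denom, 0)
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(r) <- 1; diag(p) <- 0
  list(r = r, p = p, df = df)
}

#' Benjamini-Hochberg adjustment within declared families
#'
#' Step-up false-discovery-rate adjustment. When `family` is given, the
#' adjustment is applied separately within each family of tests.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs passed through).
#' @param family optional vector assigning each p to a test family.
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  q <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    idx <- which(family == f)
    q[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  q
}

#' Mixed-model longitudinal differential testing
#'
#' Per-feature linear mixed model `feature ~ group + covariates +
#' (1 | subject)`: the group coefficient is tested (Satterthwaite t),
#' p-values are BH-adjusted across features, and a feature is flagged
#' significant when p < `p_max` AND q < `q_max` (defaults 0.05 / 0.15).
#' Features intended to be abundances should be CLR-transformed first;
#' continuous phenotypes are conventionally cube-root transformed.
#'
#' @param features numeric matrix, observations x features (e.g. CLR
#'   values over all samples).
#' @param group two-level factor per observation (constant within
#'   subject), e.g. LS/HS.
#' @param subject subject ID per observation (random intercept).
#' @param covariates optional data.frame of fixed-effect adjustments
#'   (e.g. sex, age) per observation.
#' @param p_max,q_max dual significance thresholds.
#' @return data.frame (one row per feature): `feature`, `estimate`
#'   (group coefficient), `p`, `q`, `significant`; skipped features
#'   (constant or singular fits) carry NA and a `note`.
#' @export
differential_longitudinal <- function(features, group, subject,
                                      covariates = NULL,
                                      p_max = 0.05, q_max = 0.15) {
  features <- as.matrix(features)
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have two levels")
  dat <- data.frame(.group = group, .subject = factor(subject))
  form <- ".y ~ .group + (1 | .subject)"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (anyNA(covariates)) stop("covariates must be complete")
    dat <- cbind(dat, covariates)
    form <- paste(".y ~ .group +",
                  paste(colnames(covariates), collapse = " + "),
                  "+ (1 | .subject)")
  }
  form <- stats::as.formula(form)
  res <- data.frame(feature = colnames(features),
                    estimate = NA_real_, p = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  for (j in seq_len(ncol(features))) {
    yj <- features[, j]
    if (stats::sd(yj) == 0) { res$note[j] <- "constant"; next }
    dat$.y <- yj
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(form, data = dat,
                       control = lme4::lmerControl(
                         check.conv.singular = lme4::.makeCC(
                           action = "ignore", tol = 1e-4))))),
      error = function(e) NULL)
    if (is.null(fit)) { res$note[j] <- "fit failed"; next }
    co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
    rn <- paste0(".group", levels(group)[2])
    if (is.null(co) || !rn %in% rownames(co)) {
      res$note[j] <- "no group coefficient"; next
    }
    res$estimate[j] <- co[rn, "Estimate"]
    res$p[j] <- co[rn, "Pr(>|t|)"]
  }
  res$q <- bh_adjust(res$p)
  res$significant <- !is.na(res$p) & res$p < p_max & res$q < q_max
  res
}

#' Subject-stratified PERMANOVA
#'
#' Distance-based permutational multivariate ANOVA for one explanatory
#' variable, with permutations restricted to shuffle the variable's
#' values only within each subject's samples (the conservative reading of
#' stratification for longitudinal factors). The pseudo-F comes from the
#' Gower-centered inner-product decomposition; for a single centered
#' predictor x, SS_model = (x'Gx)/(x'x) with df 1 (a factor uses its
#' full indicator hat matrix).
#'
#' @param d `dist` or square matrix of dissimilarities.
#' @param variable numeric or factor explanatory values per sample.
#' @param strata subject IDs per sample; `NULL` for free permutation.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @return object of class `permanova_fit`: `F`, `R2`, `p`, `df`,
#'   `n_perm`.
#' @export
permanova_stratified <- function(d, variable, strata = NULL,
                                 n_perm = 9999, seed = 1L) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (length(variable) != n) stop("variable must align with samples")
  A <- -0.5 * m^2
  G <- sweep(A, 1, rowMeans(A))
  G <- sweep(G, 2, colMeans(G))
  ss_total <- sum(diag(G))
  X <- stats::model.matrix(~v, data.frame(v = variable))[, -1, drop = FALSE]
  if (all(apply(X, 2, stats::sd) == 0)) stop("variable is constant")
  df_model <- qr(scale(X, scale = FALSE))$rank
  df_resid <- n - df_model - 1
  ss_model_fun <- function(Xp) {
    Xc <- scale(Xp, scale = FALSE)
    qrX <- qr(Xc)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    sum(Q * (G %*% Q))
  }
  ss_m <- ss_model_fun(X)
  f_obs <- (ss_m / df_model) / ((ss_total - ss_m) / df_resid)
  set.seed(seed)
  idx_by_stratum <- if (is.null(strata)) list(seq_len(n)) else
    split(seq_len(n), as.character(strata))
  perms <- matrix(seq_len(n), n, n_perm)
  for (b in seq_len(n_perm))
    for (idx in idx_by_stratum)
      if (length(idx) > 1) perms[idx, b] <- idx[sample.int(length(idx))]
  if (df_model == 1 && ncol(X) == 1) {
    # single-predictor fast path: SS_model = (xc' G xc) / (xc' xc)
    Xp <- matrix(X[perms, 1], n, n_perm)
    Xp <- sweep(Xp, 2, colMeans(Xp))
    ss_b <- colSums(Xp * (G %*% Xp)) / colSums(Xp^2)
    f_perm <- (ss_b / df_model) / ((ss_total - ss_b) / df_resid)
  } else {
    f_perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      ss_b <- ss_model_fun(X[perms[, b], , drop = FALSE])
      f_perm[b] <- (ss_b / df_model) / ((ss_total - ss_b) / df_resid)
    }
  }
  p <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)
  structure(list(F = f_obs, R2 = ss_m / ss_total, p = p,
                 df = c(model = df_model, residual = df_resid),
                 n_perm = n_perm, stratified = !is.null(strata)),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA%s: F = %.3f, R2 = %.4f, p = %.4g (%d permutations)\n",
    if (x$stratified) " (stratified)" else "", x$F, x$R2, x$p, x$n_perm))
  invisible(x)
}
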