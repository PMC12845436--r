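#' Per-subject microbial instability score
#'
#' The instability of a subject's microbiota is the unweighted mean
#' Bray-Curtis dissimilarity over all C(T,2) pairs of that subject's
#' samples across timepoints (for four timepoints, six pairs). Scores lie
#' in [0, 1]; larger means a less stable community.
#'
#' @param d `dist` or matrix of Bray-Curtis dissimilarities over the
#'   cohort's samples.
#' @param x the matching [cohort_table].
#' @param consecutive_only if TRUE, average only consecutive-timepoint
#'   pairs instead of all pairs (default FALSE: all pairs).
#' @return named numeric vector of instability scores, one per subject
#'   with >= 2 samples (others excluded with a warning).
#' @export
instability_score <- function(d, x, consecutive_only = FALSE) {
  ii <- intra_inter_distances(d, x)
  intra <- ii$intra
  if (consecutive_only) {
    ord <- levels(x$samples$timepoint)
    pos_a <- match(intra$timepoint_a, ord)
    pos_b <- match(intra$timepoint_b, ord)
    intra <- intra[abs(pos_a - pos_b) == 1, , drop = FALSE]
  }
  out <- tapply(intra$distance, intra$subject, mean)
  out[unique(intra$subject)]
}

#' Stratify subjects into low- and high-stability groups
#'
#' Finds a data-driven threshold in a bimodal distribution of instability
#' scores and labels subjects above it low-stability ("LS") and below it
#' high-stability ("HS").
#'
#' Method `"gmm2"` fits a two-component univariate Gaussian mixture and
#' places the threshold at the equal-posterior point between the component
#' means; `"kde_valley"` takes the minimum of a kernel density estimate
#' between the two largest modes. If the fitted components merge (mean
#' separation below `min_separation` pooled SDs) the fit refuses to assign
#' classes unless `force = TRUE`.
#'
#' @param scores named numeric vector of per-subject instability.
#' @param method `"gmm2"` (default) or `"kde_valley"`.
#' @param seed integer seed for the mixture EM initialisation.
#' @param min_separation minimal mean separation, in pooled-SD units,
#'   below which the distribution is declared unimodal (default 1).
#' @param force assign classes even when bimodality is not supported.
#' @return object of class `stability_strata`: list with `threshold`,
#'   `method`, `classes` (factor LS/HS per subject), `posterior`
#'   (P(high-instability component) per subject, gmm2 only), `fit`
#'   (component parameters), `bimodal` flag.
#' @export
stratify_bimodal <- function(scores, method = c("gmm2", "kde_valley"),
                             seed = 1L, min_separation = 1, force = FALSE) {
  method <- match.arg(method)
  if (length(scores) < 10) stop("need at least 10 subjects to stratify")
  if (stats::sd(scores) == 0) {
    if (!force) stop("scores are constant; no bimodal structure")
  }
  set.seed(seed)
  if (method == "gmm2") {
    fit <- mclust::Mclust(scores, G = 2, modelNames = "V", verbose = FALSE)
    if (is.null(fit))
      fit <- mclust::Mclust(scores, G = 2, modelNames = "E", verbose = FALSE)
    if (is.null(fit)) stop("two-component mixture fit failed")
    mu <- fit$parameters$mean
    sdv <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sdv) == 1) sdv <- rep(sdv, 2)
    pro <- fit$parameters$pro
    lo <- which.min(mu); hi <- which.max(mu)
    pooled <- sqrt(mean(sdv^2))
    sep <- (mu[hi] - mu[lo]) / pooled
    bimodal <- sep >= min_separation
    # equal-posterior crossing between the component means
    f <- function(t) pro[hi] * stats::dnorm(t, mu[hi], sdv[hi]) -
      pro[lo] * stats::dnorm(t, mu[lo], sdv[lo])
    thr <- tryCatch(stats::uniroot(f, c(mu[lo], mu[hi]))$root,
                    error = function(e) (mu[lo] + mu[hi]) / 2)
    post_hi <- fit$z[, hi]
    names(post_hi) <- names(scores)
    params <- list(means = unname(mu[c(lo, hi)]),
                   sds = unname(sdv[c(lo, hi)]),
                   proportions = unname(pro[c(lo, hi)]),
                   separation = unname(sep))
  } else {
    dens <- stats::density(scores, n = 2048)
    peaks <- which(diff(sign(diff(dens$y))) == -2) + 1
    if (length(peaks) < 2) {
      bimodal <- FALSE
      thr <- stats::median(scores)
      params <- list(modes = dens$x[peaks])
      sep <- 0
    } else {
      top2 <- sort(peaks[order(dens$y[peaks], decreasing = TRUE)][1:2])
      seg <- seq(top2[1], top2[2])
      thr <- dens$x[seg[which.min(dens$y[seg])]]
      params <- list(modes = dens$x[top2])
      sep <- Inf
      bimodal <- TRUE
    }
    post_hi <- NULL
  }
  if (!bimodal && !force) {
    warning("no supported bimodality (separation ", signif(sep, 3),
            "); classes not assigned, use force = TRUE to override")
    classes <- NULL
  } else {
    classes <- factor(ifelse(scores > thr, "LS", "HS"),
                      levels = c("LS", "HS"))
    names(classes) <- names(scores)
  }
  structure(list(threshold = thr, method = method, classes = classes,
                 posterior = post_hi, fit = params, bimodal = bimodal,
                 scores = scores, seed = seed),
            class = "stability_strata")
}

#' @export
print.stability_strata <- function(x, ...) {
  cat("stability_strata (", x$method, "): threshold = ",
      signif(x$threshold, 4), "\n", sep = "")
  if (!is.null(x$classes)) {
    tab <- table(x$classes)
    cat("  LS (unstable): ", tab[["LS"]], "   HS (stable): ", tab[["HS"]],
        "\n", sep = "")
  } else cat("  classes not assigned (no supported bimodality)\n")
  invisible(x)
}

#' Temporal coefficient of variation
#'
#' CoV = sample SD / mean of a non-negative feature across a subject's
#' timepoints. An all-zero series (absent taxon) has CoV 0; a zero-mean
#' series with nonzero values is undefined (NA).
#'
#' @param values numeric vector (>= 2 timepoints, all >= 0).
#' @return scalar CoV with attribute `absent` when the series is all zero.
#' @export
temporal_cov <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 timepoints")
  if (any(values < 0)) stop("CoV requires non-negative values")
  m <- mean(values)
  if (m == 0) {
    out <- if (all(values == 0)) 0 else NA_real_
    attr(out, "absent") <- all(values == 0)
    return(out)
  }
  stats::sd(values) / m
}

#' Per-subject CoV matrix of features across timepoints
#'
#' Applies [temporal_cov()] to every subject x feature series of a
#' samples-by-features matrix (rarefied taxon counts or alpha indices).
#'
#' @param mat numeric matrix, samples x features, non-negative.
#' @param subject subject ID per row of `mat`.
#' @return matrix subjects x features of CoV values (absent features 0).
#' @export
cov_by_subject <- function(mat, subject) {
  mat <- as.matrix(mat)
  subjects <- unique(subject)
  out <- matrix(NA_real_, length(subjects), ncol(mat),
                dimnames = list(subjects, colnames(mat)))
  for (s in subjects) {
    sub <- mat[subject == s, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, stats::sd)
    cv <- ifelse(mu > 0, sdv / mu, ifelse(sdv == 0, 0, NA_real_))
    out[s, ] <- cv
  }
  out
}

#' Build per-subject stability profiles
#'
#' Convenience wrapper combining instability scores, LS/HS stratification
#' and the temporal CoV of alpha-diversity indices into one table.
#'
#' @param x rarefied [cohort_table].
#' @param method stratification method passed to [stratify_bimodal()].
#' @param seed seed for the stratification.
#' @return list of class `stability_profile`: `profile` data.frame
#'   (subject, instability, class, cov of each alpha index), `strata`
#'   the [stratify_bimodal()] fit, `cov_taxa` subjects x taxa CoV matrix.
#' @export
stability_profile <- function(x, method = "gmm2", seed = 1L) {
  d <- bray_curtis(x)
  score <- instability_score(d, x)
  strata <- stratify_bimodal(score, method = method, seed = seed)
  alpha <- alpha_diversity(x)
  am <- as.matrix(alpha[, c("shannon", "simpson", "richness", "pielou")])
  rownames(am) <- alpha$sample_id
  subj <- x$samples[alpha$sample_id, "subject"]
  cov_alpha <- cov_by_subject(am, subj)
  cov_taxa <- cov_by_subject(x$counts, x$samples$subject)
  keep <- names(score)
  prof <- data.frame(subject = keep, instability = as.numeric(score),
                     class = if (is.null(strata$classes)) NA
                             else as.character(strata$classes[keep]),
                     stringsAsFactors = FALSE)
  prof <- cbind(prof, cov_alpha[keep, , drop = FALSE])
  colnames(prof)[4:7] <- paste0("cov_", c("shannon", "simpson",
                                          "richness", "pielou"))
  rownames(prof) <- NULL
  structure(list(profile = prof, strata = strata,
                 cov_taxa = cov_taxa[keep, , drop = FALSE]),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("stability_profile:", nrow(x$profile), "subjects\n")
  cat("  instability range: ",
      paste(signif(range(x$profile$instability), 3), collapse = " - "),
      "\n", sep = "")
  print(x$strata)
  invisible(x)
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney U test: exact when both groups have <= 25
#' observations and no ties, normal approximation with tie correction
#' otherwise. U is reported for the first group (number of pairs where a
#' first-group value exceeds a second-group value, ties counting 1/2).
#'
#' @param values numeric vector.
#' @param labels two-level grouping aligned to `values`.
#' @return list with `U`, `p`, group `n`s and the group level order.
#' @export
compare_group_dispersion <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  g1 <- values[labels == levels(labels)[1]]
  g2 <- values[labels == levels(labels)[2]]
  if (!length(g1) || !length(g2)) stop("one group is empty")
  exact <- length(g1) <= 25 && length(g2) <= 25 &&
    !anyDuplicated(c(g1, g2))
  wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       n = c(length(g1), length(g2)), levels = levels(labels))
}
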