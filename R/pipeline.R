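#' Default pipeline configuration
#'
#' Aggregates the tunable parameters of every stage. Values can be
#' overridden by a named list or a YAML file (see [read_pipeline_config()]).
#'
#' @param ... overrides of the defaults.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    abundance_threshold = 0.001,  # 0.1% mean relative abundance
    rarefaction_depth = 18164,
    pseudocount = 0.5,
    stratify_method = "gmm2",
    rmcorr_r_min = 0.3,           # diet/phenotype association cutoff
    network_r_min = 0.5,
    network_q_max = 0.05,
    n_permutations = 9999,
    cv_folds = 5,
    cv_ntree = 500,
    k_per_dataset = 5,
    seed = 1L
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of config keys (see [pipeline_config()]).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

derive_seed <- function(seed, offset) (as.integer(seed) + offset) %% 2147483647L

#' Run the full stability analysis pipeline
#'
#' Executes the complete workflow on a cohort (real or simulated):
#' abundance filter, rarefaction, alpha diversity and Bray-Curtis
#' distances, per-subject instability and LS/HS stratification, temporal
#' CoV, mixed-model differential tests of CLR abundances between groups,
#' rmcorr diet/phenotype-taxon associations per group, subject-stratified
#' PERMANOVA of covariates, neutral-model fits per group, co-abundance
#' networks per group with module/role annotation and comparison, and the
#' three classifier workflows (CoV features, baseline features,
#' integration). Every stochastic stage derives its seed from
#' `config$seed`, so a rerun with the same inputs and config is
#' bit-identical.
#'
#' @param cohort a [cohort_table].
#' @param covariates a [covariate_table] aligned by subject/timepoint.
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, all tables are written
#'   as TSV/JSON with a config-hash header.
#' @return list of class `pipeline_result` with one element per stage.
#' @export
run_full <- function(cohort, covariates, config = pipeline_config(),
                     outdir = NULL) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(covariates, "covariate_table"))
  seed <- as.integer(config$seed)
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("stage filter: ", ncol(cohort$counts), " taxa in")
  filtered <- filter_low_abundance(cohort, config$abundance_threshold)
  say("stage filter: ", ncol(filtered$counts), " taxa retained")

  depth <- min(config$rarefaction_depth, min(rowSums(filtered$counts)))
  rare <- suppressWarnings(rarefy_cohort(filtered, depth,
                                         seed = derive_seed(seed, 1)))
  say("stage rarefy: depth ", depth, ", ", nrow(rare$counts), " samples")

  alpha <- alpha_diversity(rare)
  d <- bray_curtis(rare)
  prof <- stability_profile(rare, method = config$stratify_method,
                            seed = derive_seed(seed, 2))
  classes <- prof$strata$classes
  if (is.null(classes))
    stop("stage stability: no supported bimodality, cannot stratify")
  say("stage stability: threshold ", signif(prof$strata$threshold, 4),
      "; LS ", sum(classes == "LS"), " / HS ", sum(classes == "HS"))

  # sample-level group labels for longitudinal stages
  subj <- rare$samples$subject
  grp <- factor(as.character(classes[subj]), levels = c("HS", "LS"))
  clr <- clr_transform(rare, config$pseudocount)
  diff_res <- differential_longitudinal(clr, grp, subj)
  say("stage differential: ", sum(diff_res$significant, na.rm = TRUE),
      " significant features")

  # phenotype/diet contrasts between groups: cube-root transformed
  # (signed), random intercept per subject
  cov_grp <- factor(as.character(classes[covariates$subject]),
                    levels = c("HS", "LS"))
  cbrt <- function(v) sign(v) * abs(v)^(1 / 3)
  diff_pheno <- differential_longitudinal(apply(covariates$values, 2,
                                                cbrt),
                                          cov_grp, covariates$subject)
  say("stage phenotype differential: ",
      sum(diff_pheno$significant, na.rm = TRUE), " significant")

  # rmcorr associations: each covariate vs each taxon, per group, on the
  # covariate timepoints (samples matched by subject + timepoint)
  assoc <- rmcorr_associations(clr, rare, covariates, classes,
                               r_min = config$rmcorr_r_min)
  say("stage rmcorr: ", sum(assoc$significant, na.rm = TRUE),
      " significant diet/phenotype-taxon associations")

  perma <- permanova_covariates(d, rare, covariates,
                                n_perm = config$n_permutations,
                                seed = derive_seed(seed, 3))
  say("stage permanova: ", nrow(perma), " covariates tested")

  ncm <- lapply(split(names(classes), classes), function(subs) {
    fit_ncm(subset_cohort(rare, samples = subj %in% subs))
  })
  say("stage ncm: LS R2 ", signif(ncm$LS$R2, 3), ", HS R2 ",
      signif(ncm$HS$R2, 3))

  nets <- lapply(split(names(classes), classes), function(subs) {
    idx <- subj %in% subs
    net <- build_network(clr[idx, , drop = FALSE], subj[idx],
                         r_min = config$network_r_min,
                         q_max = config$network_q_max)
    if (nrow(net$edges) > 0) {
      net <- detect_modules(net, seed = derive_seed(seed, 4))
      net <- zi_pi(net)
    }
    net
  })
  netcmp <- compare_networks(nets$LS, nets$HS)
  say("stage networks: LS ", nrow(nets$LS$edges), " edges, HS ",
      nrow(nets$HS$edges), " edges; LS-only ", netcmp$a_only)

  # classifiers: (a) CoV features; (b) baseline CLR abundances;
  # (c) integration of both datasets' top features
  covm <- cov_feature_matrix(prof)
  labels <- classes[rownames(covm)]
  cv_cov <- nested_rf_classify(covm, labels, n_outer = config$cv_folds,
                               ntree = config$cv_ntree,
                               seed = derive_seed(seed, 5))
  base_tp <- levels(rare$samples$timepoint)[1]
  base_idx <- rare$samples$timepoint == base_tp
  baseline <- clr[base_idx, , drop = FALSE]
  rownames(baseline) <- rare$samples$subject[base_idx]
  baseline <- baseline[intersect(rownames(covm), rownames(baseline)), ,
                       drop = FALSE]
  lab_base <- classes[rownames(baseline)]
  cv_base <- nested_rf_classify(baseline, lab_base,
                                n_outer = config$cv_folds,
                                ntree = config$cv_ntree,
                                seed = derive_seed(seed, 6))
  common <- intersect(rownames(covm), rownames(baseline))
  cv_int <- integrate_top_features(
    list(cov = cv_cov, baseline = cv_base),
    list(cov = covm[common, , drop = FALSE],
         baseline = baseline[common, , drop = FALSE]),
    labels = classes[common], k_per_dataset = config$k_per_dataset,
    n_outer = config$cv_folds, ntree = config$cv_ntree,
    seed = derive_seed(seed, 7))
  say("stage classify: CoV AUROC ", round(cv_cov$metrics["auroc"], 3),
      ", baseline AUROC ", round(cv_base$metrics["auroc"], 3),
      ", integrated AUROC ", round(cv_int$metrics["auroc"], 3))

  res <- structure(list(
    filtered = filtered, rarefied = rare, alpha = alpha, distances = d,
    profile = prof, differential = diff_res,
    differential_phenotypes = diff_pheno, associations = assoc,
    permanova = perma, ncm = ncm, networks = nets,
    network_comparison = netcmp,
    classifiers = list(cov = cv_cov, baseline = cv_base,
                       integrated = cv_int),
    config = config, log = log_lines), class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(res, outdir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' rmcorr associations between covariates and taxa, per stability group
#'
#' Pairs each covariate observation with the matching sample's CLR value
#' (same subject and timepoint) and computes the repeated-measures
#' correlation for every covariate x taxon pair within each LS/HS group,
#' with BH adjustment per group (one family per group).
#'
#' @param clr samples x taxa CLR matrix (rownames = sample IDs).
#' @param cohort the matching [cohort_table].
#' @param covariates a [covariate_table].
#' @param classes named LS/HS factor per subject.
#' @param r_min,q_max significance rule `|r| > r_min & q < q_max`.
#' @return data.frame: group, covariate, taxon, r, p, q, significant.
#' @export
rmcorr_associations <- function(clr, cohort, covariates, classes,
                                r_min = 0.3, q_max = 0.05) {
  meta <- cohort$samples
  key_s <- paste(meta$subject, as.character(meta$timepoint))
  key_c <- paste(covariates$subject, covariates$timepoint)
  hit <- match(key_c, key_s)
  ok <- !is.na(hit)
  out <- list()
  for (g in levels(classes)) {
    subs <- names(classes)[classes == g]
    sel <- ok & covariates$subject %in% subs
    rows <- hit[sel]
    cv <- covariates$values[sel, , drop = FALSE]
    ab <- clr[meta$sample_id[rows], , drop = FALSE]
    sub_ids <- covariates$subject[sel]
    for (v in colnames(cv)) {
      xv <- cv[, v]
      if (all(is.na(xv)) || stats::sd(xv, na.rm = TRUE) == 0) next
      rr <- vapply(colnames(ab), function(tx) {
        f <- tryCatch(suppressWarnings(
          rmcorr_test(xv, ab[, tx], sub_ids)),
          error = function(e) NULL)
        if (is.null(f)) c(NA_real_, NA_real_) else c(f$r, f$p)
      }, numeric(2))
      out[[length(out) + 1]] <- data.frame(
        group = g, covariate = v, taxon = colnames(ab),
        r = rr[1, ], p = rr[2, ], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$q <- bh_adjust(res$p, family = res$group)
  res$significant <- !is.na(res$r) & abs(res$r) > r_min & res$q < q_max
  res
}

#' Subject-stratified PERMANOVA of every covariate
#'
#' Runs [permanova_stratified()] for each covariate against the
#' community dissimilarities of the matching samples (subject +
#' timepoint), covariates standardised first.
#'
#' @param d `dist` over the cohort's samples.
#' @param cohort the matching [cohort_table].
#' @param covariates a [covariate_table].
#' @param n_perm,seed permutation settings.
#' @return data.frame: covariate, F, R2, p, n.
#' @export
permanova_covariates <- function(d, cohort, covariates, n_perm = 999,
                                 seed = 1L) {
  meta <- cohort$samples
  key_s <- paste(meta$subject, as.character(meta$timepoint))
  key_c <- paste(covariates$subject, covariates$timepoint)
  hit <- match(key_c, key_s)
  m <- as.matrix(d)
  out <- lapply(colnames(covariates$values), function(v) {
    xv <- covariates$values[, v]
    sel <- !is.na(hit) & !is.na(xv)
    if (sum(sel) < 6 || stats::sd(xv[sel]) == 0) return(NULL)
    rows <- meta$sample_id[hit[sel]]
    fit <- permanova_stratified(m[rows, rows], scale(xv[sel])[, 1],
                                strata = covariates$subject[sel],
                                n_perm = n_perm, seed = seed)
    data.frame(covariate = v, F = fit$F, R2 = fit$R2, p = fit$p,
               n = sum(sel), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

config_hash <- function(config) {
  s <- paste(names(config), vapply(config, paste, character(1),
                                   collapse = ","),
             sep = "=", collapse = ";")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1000000L
}

write_tsv_stamped <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(sprintf("# microstab config_hash=%d seed=%d",
                     config_hash(config), as.integer(config$seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
}

#' Write all pipeline outputs to a directory
#'
#' Numeric tables as TSV (with a config-hash/seed header comment) and
#' summaries as JSON; rerunning with the same inputs, config and seed
#' reproduces every file byte-for-byte.
#'
#' @param res a `pipeline_result`.
#' @param outdir output directory (created if needed).
#' @export
write_pipeline_result <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  p <- function(f) file.path(outdir, f)
  write_tsv_stamped(res$profile$profile, p("stability_profile.tsv"), cfg)
  write_tsv_stamped(res$alpha, p("alpha_diversity.tsv"), cfg)
  write_tsv_stamped(res$differential, p("differential.tsv"), cfg)
  write_tsv_stamped(res$differential_phenotypes,
                    p("differential_phenotypes.tsv"), cfg)
  write_tsv_stamped(res$associations, p("rmcorr_associations.tsv"), cfg)
  write_tsv_stamped(res$permanova, p("permanova.tsv"), cfg)
  for (g in names(res$networks)) {
    write_tsv_stamped(res$networks[[g]]$edges,
                      p(sprintf("network_%s_edges.tsv", g)), cfg)
    write_tsv_stamped(res$networks[[g]]$nodes,
                      p(sprintf("network_%s_nodes.tsv", g)), cfg)
  }
  ncm_sum <- lapply(res$ncm, function(f)
    list(Nm = f$Nm, m = f$m, R2 = f$R2,
         detection_limit = f$detection_limit))
  summary <- list(
    config = unclass(cfg),
    threshold = res$profile$strata$threshold,
    n_ls = sum(res$profile$profile$class == "LS"),
    n_hs = sum(res$profile$profile$class == "HS"),
    ncm = ncm_sum,
    network_comparison = res$network_comparison[c("shared", "a_only",
                                                 "b_only")],
    classifier_metrics = lapply(res$classifiers, function(cv)
      as.list(cv$metrics)),
    log = res$log)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(res)
}
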