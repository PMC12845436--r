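#' Define a synthetic longitudinal cohort scenario
#'
#' Collects the data-generating assumptions for [simulate_cohort()]:
#' per-subject latent log-abundance trajectories follow an AR(1) process
#' whose innovation SD is drawn from a two-component mixture (the
#' subject-level "instability" knob, producing the bimodal low-/high-
#' stability structure), counts are multinomial at a log-normally drawn
#' depth, and covariates carry planted group effects: lipid phenotypes
#' shifted upwards in low-stability subjects and diet variables coupled to
#' designated driver taxa in low-stability subjects only.
#'
#' The defaults mirror the study design this generator emulates: 51
#' subjects sampled at 4 timepoints, ~200 taxa, and roughly half the
#' subjects in the unstable component.
#'
#' @param n_subjects number of subjects (default 51).
#' @param timepoints number of fecal sampling timepoints (default 4,
#'   labelled T0 < T9 < T14 < T52 when 4).
#' @param n_taxa number of taxa (default 200).
#' @param depth_mean,depth_sdlog log-normal read-depth parameters
#'   (default 25000 reads, sdlog 0.25).
#' @param stability_mixture list with `mean_low`, `mean_high`, `sd`,
#'   `mixing`: innovation-SD mixture on the latent scale. `mixing` is the
#'   probability of the high-innovation (low-stability) component.
#' @param ar_rho AR(1) autocorrelation of latent log-abundances in [0,1).
#' @param n_drivers number of driver taxa whose innovation SD is
#'   amplified in low-stability subjects.
#' @param driver_boost multiplicative innovation-SD amplification for
#'   driver taxa in LS subjects.
#' @param diet_coupling fraction in [0, 1) of each driver taxon's
#'   stationary latent variance that is explained by its assigned diet
#'   variable in LS subjects (0 = no coupling). Drivers are coupled
#'   round-robin to the fiber and amino-acid intake variables.
#' @param phenotype_effect mean upward shift (in SD units) of lipid
#'   phenotypes in LS subjects (0 = no effect).
#' @param base_sigma between-taxon SD of the shared mean log-abundances
#'   (controls community unevenness).
#' @param subject_sigma SD of each subject's persistent deviation from
#'   the shared taxon means (controls inter-individual distance).
#' @return list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_subjects = 51, timepoints = 4, n_taxa = 200,
                            depth_mean = 25000, depth_sdlog = 0.25,
                            stability_mixture = list(mean_low = 1.4,
                                                     mean_high = 2.1,
                                                     sd = 0.08,
                                                     mixing = 0.5),
                            ar_rho = 0.5, n_drivers = 10,
                            driver_boost = 2, diet_coupling = 0.5,
                            phenotype_effect = 0.8, base_sigma = 1.5,
                            subject_sigma = 1) {
  sm <- stability_mixture
  if (sm$mean_low >= sm$mean_high)
    stop("degenerate mixture: mean_low must be < mean_high")
  if (sm$mixing <= 0 || sm$mixing >= 1) stop("mixing must be in (0,1)")
  if (ar_rho < 0 || ar_rho >= 1) stop("ar_rho must be in [0,1)")
  if (sm$sd <= 0 || base_sigma <= 0) stop("variances must be > 0")
  if (diet_coupling < 0 || diet_coupling >= 1)
    stop("diet_coupling must be in [0,1)")
  structure(list(n_subjects = n_subjects, timepoints = timepoints,
                 n_taxa = n_taxa, depth_mean = depth_mean,
                 depth_sdlog = depth_sdlog, stability_mixture = sm,
                 ar_rho = ar_rho, n_drivers = n_drivers,
                 driver_boost = driver_boost,
                 diet_coupling = diet_coupling,
                 phenotype_effect = phenotype_effect,
                 base_sigma = base_sigma, subject_sigma = subject_sigma),
            class = "cohort_scenario")
}

#' Simulate a longitudinal cohort with planted ground truth
#'
#' Generates counts, covariates and a truth record under a
#' [cohort_scenario]. Each subject s has a personal equilibrium
#' log-abundance profile `mu_s ~ N(mu_taxon, subject_sigma^2)` (the
#' persistent individual signature driving inter-individual distances);
#' the realised latent profile follows a stationary AR(1) around it with
#' stationary SD `sigma_s` drawn from the two-component mixture (driver
#' taxa get `sigma_s * driver_boost` in low-stability subjects), so zero
#' innovation SD gives a constant expected composition over time.
#' Counts are multinomial from softmax(latent) at log-normal depth.
#' In LS subjects a `diet_coupling` fraction of each driver taxon's
#' latent variance is replaced by the subject's standardized intake of
#' an assigned diet variable (fiber or an amino acid) at the nearest
#' covariate visit, planting within-subject diet-taxon correlations that
#' exist in the LS group only; lipid phenotypes (LDL-C, TC, TC/HDL-C,
#' ApoB) get a `phenotype_effect` SD upward shift in LS subjects. Covariates are observed at 3 timepoints (no week-9 visit),
#' matching the design in which bloods and diet records skip one fecal
#' visit.
#'
#' @param scenario a [cohort_scenario].
#' @param seed integer seed; fully determines the output.
#' @return list with `cohort` ([cohort_table]), `covariates`
#'   ([covariate_table] of diet + phenotypes), `truth` (data.frame:
#'   subject, true class, innovation SD) and `driver_taxa` (taxon IDs).
#' @export
simulate_cohort <- function(scenario = cohort_scenario(), seed = 1L) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  set.seed(seed)
  ns <- scenario$n_subjects; nt <- scenario$timepoints
  p <- scenario$n_taxa
  sm <- scenario$stability_mixture
  tp_labels <- if (nt == 4) c("T0", "T9", "T14", "T52") else
    paste0("T", seq_len(nt) - 1)
  subjects <- sprintf("S%02d", seq_len(ns))
  taxa <- sprintf("taxon%03d", seq_len(p))
  # subject-level instability: innovation SD from two-component mixture
  is_ls <- stats::rbinom(ns, 1, sm$mixing) == 1
  sigma <- ifelse(is_ls, stats::rnorm(ns, sm$mean_high, sm$sd),
                  stats::rnorm(ns, sm$mean_low, sm$sd))
  sigma <- pmax(sigma, 0.01)
  mu_taxa <- stats::rnorm(p, 0, scenario$base_sigma)  # shared taxon means
  # driver taxa sit in the upper-middle abundance range: abundant enough
  # to stay detectable after rarefaction, but below the community
  # dominants so their amplified dynamics do not drag every other
  # taxon's relative abundance along through compositional closure
  n_skip <- min(15L, max(0L, p - scenario$n_drivers))
  drivers <- taxa[order(mu_taxa, decreasing = TRUE)[
    n_skip + seq_len(min(scenario$n_drivers, p - n_skip))]]
  rho <- scenario$ar_rho
  # diet: 6 variables at 3 covariate timepoints; innovations reused for
  # the driver-taxon coupling so LS taxa track diet swings
  n_diet <- 6
  cov_tp <- if (nt == 4) c("T0", "T14", "T52") else tp_labels
  diet_names <- c("fiber", "leucine", "isoleucine", "valine", "dairy",
                  "energy")
  counts <- matrix(0, ns * nt, p)
  sample_ids <- character(ns * nt)
  samp_subject <- character(ns * nt)
  samp_tp <- character(ns * nt)
  diet_vals <- array(stats::rnorm(ns * length(cov_tp) * n_diet),
                     dim = c(ns, length(cov_tp), n_diet))
  # round-robin assignment of drivers to the fiber/amino-acid variables,
  # and the covariate visit nearest each fecal timepoint
  driver_idx <- match(drivers, taxa)
  driver_diet <- rep(seq_len(4), length.out = length(drivers))
  visit_of <- if (nt == 4) c(1, 1, 2, 3) else
    pmin(seq_len(nt), length(cov_tp))
  cpl <- scenario$diet_coupling
  row <- 0
  for (s in seq_len(ns)) {
    sig_t <- rep(sigma[s], p)
    if (is_ls[s]) sig_t[driver_idx] <- sigma[s] * scenario$driver_boost
    mu_s <- mu_taxa + stats::rnorm(p, 0, scenario$subject_sigma)
    z <- stats::rnorm(p)  # standardized AR(1) state, stationary sd 1
    for (t in seq_len(nt)) {
      if (t > 1) z <- rho * z + stats::rnorm(p, 0, sqrt(1 - rho^2))
      zt <- z
      if (is_ls[s] && cpl > 0) {
        # LS drivers: part of the latent deviation IS the subject's diet
        # deviation at the nearest covariate visit (variance split keeps
        # the stationary SD at sigma * driver_boost)
        dz <- diet_vals[s, visit_of[t], driver_diet]
        zt[driver_idx] <- sqrt(cpl) * dz + sqrt(1 - cpl) * z[driver_idx]
      }
      lat <- mu_s + sig_t * zt
      depth <- round(stats::rlnorm(1, log(scenario$depth_mean),
                                   scenario$depth_sdlog))
      prob <- exp(lat - max(lat)); prob <- prob / sum(prob)
      row <- row + 1
      counts[row, ] <- stats::rmultinom(1, depth, prob)[, 1]
      sample_ids[row] <- paste0(subjects[s], "_", tp_labels[t])
      samp_subject[row] <- subjects[s]
      samp_tp[row] <- tp_labels[t]
    }
  }
  dimnames(counts) <- list(sample_ids, taxa)
  cohort <- cohort_table(counts, samp_subject, samp_tp,
                         timepoint_order = tp_labels)
  # covariates: diet densities + lipid phenotypes with LS shift
  pheno_names <- c("LDL_C", "TC", "TC_HDL_ratio", "ApoB", "FBG", "TG")
  lipid <- c("LDL_C", "TC", "TC_HDL_ratio", "ApoB")
  n_obs <- ns * length(cov_tp)
  cov_mat <- matrix(NA_real_, n_obs, n_diet + length(pheno_names),
                    dimnames = list(NULL, c(diet_names, pheno_names)))
  cov_subject <- rep(subjects, each = length(cov_tp))
  cov_timep <- rep(cov_tp, ns)
  for (s in seq_len(ns)) for (ti in seq_along(cov_tp)) {
    i <- (s - 1) * length(cov_tp) + ti
    cov_mat[i, seq_len(n_diet)] <- diet_vals[s, ti, ]
    ph <- stats::rnorm(length(pheno_names))
    if (is_ls[s])
      ph[pheno_names %in% lipid] <- ph[pheno_names %in% lipid] +
        scenario$phenotype_effect
    cov_mat[i, n_diet + seq_along(pheno_names)] <- ph
  }
  covariates <- covariate_table(
    cov_mat, cov_subject, cov_timep,
    kinds = stats::setNames(c(rep("diet", n_diet),
                              rep("phenotype", length(pheno_names))),
                            c(diet_names, pheno_names)))
  truth <- data.frame(subject = subjects,
                      class = ifelse(is_ls, "LS", "HS"),
                      innovation_sd = sigma, stringsAsFactors = FALSE)
  list(cohort = cohort, covariates = covariates, truth = truth,
       driver_taxa = drivers, scenario = scenario, seed = seed)
}

#' Simulate a community assembled under the Sloan neutral model
#'
#' Each taxon's relative abundance in each sample is drawn from the Sloan
#' beta approximation `Beta(Nm * p_i, Nm * (1 - p_i))` around its
#' metacommunity abundance `p_i`; reads are proportional to the drawn
#' abundance, quantised at the detection limit (`floor(depth * p)`), so a
#' taxon is observed exactly when its abundance exceeds 1/depth and the
#' occurrence frequencies follow the neutral beta-CDF prediction that
#' [fit_ncm()] assumes.
#'
#' @param n_samples,n_taxa community dimensions.
#' @param Nm metacommunity size times immigration rate (> 0).
#' @param metacommunity optional abundance vector summing to 1; default
#'   is a log-normal species-abundance distribution.
#' @param depth reads per sample (default 10000).
#' @param seed integer seed.
#' @return a [cohort_table] (each sample its own "subject", one
#'   timepoint).
#' @export
simulate_neutral_community <- function(n_samples, n_taxa, Nm,
                                       metacommunity = NULL,
                                       depth = 10000, seed = 1L) {
  if (Nm <= 0) stop("Nm must be > 0")
  set.seed(seed)
  if (is.null(metacommunity)) {
    metacommunity <- stats::rlnorm(n_taxa, 0, 2)
    metacommunity <- metacommunity / sum(metacommunity)
  }
  if (abs(sum(metacommunity) - 1) > 1e-8)
    stop("metacommunity must sum to 1")
  counts <- matrix(0, n_samples, n_taxa)
  for (j in seq_len(n_taxa)) {
    a <- Nm * metacommunity[j]; b <- Nm * (1 - metacommunity[j])
    pj <- stats::rbeta(n_samples, a, b)
    counts[, j] <- floor(depth * pj)
  }
  empty <- rowSums(counts) == 0
  if (any(empty)) counts[empty, which.max(metacommunity)] <- 1
  dimnames(counts) <- list(sprintf("N%03d", seq_len(n_samples)),
                           sprintf("taxon%03d", seq_len(n_taxa)))
  cohort_table(counts, subject = rownames(counts),
               timepoint = rep("T0", n_samples))
}
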