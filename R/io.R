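#' Read a longitudinal cohort from TSV files
#'
#' Reads a count table and a sample metadata table and validates them into
#' a [cohort_table]. The count file may have samples in rows (default) or
#' taxa in rows; orientation is auto-detected by matching the header / first
#' column against the metadata sample IDs and can be forced with
#' `orientation`.
#'
#' @param counts_path TSV with a header row; first column holds row IDs.
#' @param metadata_path TSV with columns `sample_id`, `subject`,
#'   `timepoint` (extra columns are ignored).
#' @param orientation `"auto"`, `"samples"` (samples in rows) or `"taxa"`
#'   (taxa in rows, i.e. the transposed convention common for ASV tables).
#' @param timepoint_order optional explicit ordering of timepoint labels.
#' @param taxonomy_path optional TSV of rank strings, first column = taxon ID.
#' @return a [cohort_table].
#' @export
read_cohort <- function(counts_path, metadata_path, orientation = "auto",
                        timepoint_order = NULL, taxonomy_path = NULL) {
  orientation <- match.arg(orientation, c("auto", "samples", "taxa"))
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- ids
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "subject", "timepoint")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample IDs in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  if (orientation == "auto") {
    in_rows <- mean(rownames(mat) %in% meta$sample_id)
    in_cols <- mean(colnames(mat) %in% meta$sample_id)
    orientation <- if (in_cols > in_rows) "taxa" else "samples"
  }
  if (orientation == "taxa") mat <- t(mat)
  missing_meta <- setdiff(rownames(mat), meta$sample_id)
  if (length(missing_meta))
    stop("samples absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  meta <- meta[match(rownames(mat), meta$sample_id), ]
  tax <- NULL
  if (!is.null(taxonomy_path)) {
    traw <- utils::read.delim(taxonomy_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
    tax <- traw[, -1, drop = FALSE]
    rownames(tax) <- as.character(traw[[1]])
  }
  cohort_table(mat, meta$subject, meta$timepoint,
               timepoint_order = timepoint_order, taxonomy = tax)
}

#' Write a cohort table to TSV files
#'
#' Inverse of [read_cohort()]: a read -> write -> read round trip
#' reproduces the cohort exactly.
#'
#' @param x a [cohort_table].
#' @param counts_path,metadata_path output TSV paths.
#' @export
write_cohort <- function(x, counts_path, metadata_path) {
  stopifnot(inherits(x, "cohort_table"))
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- x$samples
  meta$timepoint <- as.character(meta$timepoint)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Drop taxa below a mean relative-abundance threshold
#'
#' Taxa whose average relative abundance across all samples is strictly
#' below `threshold` (default 0.1%) are removed; the per-sample relative
#' abundance is computed first and then averaged over samples, which makes
#' the filter robust to unequal sequencing depth. The sample set is never
#' changed.
#'
#' @param x a [cohort_table].
#' @param threshold fraction in (0, 1); default 0.001 (= 0.1%).
#' @return filtered [cohort_table] with an attribute `removed_taxa`.
#' @export
filter_low_abundance <- function(x, threshold = 0.001) {
  stopifnot(inherits(x, "cohort_table"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  mean_ra <- colMeans(relative_abundance(x))
  keep <- mean_ra >= threshold
  if (!any(keep)) stop("abundance filter removed all taxa")
  out <- subset_cohort(x, taxa = which(keep))
  attr(out, "removed_taxa") <- colnames(x$counts)[!keep]
  out
}

#' Construct a longitudinal covariate table
#'
#' Holds subject-level measurements repeated over timepoints (phenotypes,
#' diet, activity, early-life factors, fecal markers). Missing values stay
#' as explicit NA; consumers declare pairwise- or listwise-complete
#' behaviour themselves.
#'
#' @param values numeric matrix or data.frame, observations x variables.
#' @param subject,timepoint one entry per observation row.
#' @param kinds optional named character vector mapping variable ->
#'   one of "phenotype", "diet", "activity", "early_life", "fecal".
#' @return object of class `covariate_table`.
#' @export
covariate_table <- function(values, subject, timepoint, kinds = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("variables must be uniquely named")
  n <- nrow(values)
  if (length(subject) != n || length(timepoint) != n)
    stop("subject and timepoint must have one entry per observation")
  if (!is.null(kinds)) {
    bad <- setdiff(kinds, c("phenotype", "diet", "activity", "early_life",
                            "fecal"))
    if (length(bad)) stop("unknown variable kinds: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(values = values,
                 subject = as.character(subject),
                 timepoint = as.character(timepoint),
                 kinds = kinds),
            class = "covariate_table")
}

#' @export
print.covariate_table <- function(x, ...) {
  cat("covariate_table:", nrow(x$values), "observations x",
      ncol(x$values), "variables,", length(unique(x$subject)),
      "subjects\n")
  invisible(x)
}

#' Energy-adjust dietary intakes to nutrient densities
#'
#' Each nutrient variable is re-expressed as intake per 1000 kcal of total
#' energy (intake / (energy/1000)). The three macronutrients, when named,
#' are additionally expressed as percent of total energy using the Atwater
#' factors 4/4/9 kcal per gram for protein/carbohydrate/fat.
#'
#' @param diet a [covariate_table] of dietary variables.
#' @param energy_var name of the total energy column (kcal).
#' @param macronutrients named character vector mapping roles
#'   `protein`/`carbohydrate`/`fat` to column names (in grams); roles not
#'   present in the table are skipped.
#' @return a [covariate_table] with nutrient-density values; macronutrient
#'   percent-of-energy columns are appended with suffix `_pct_energy`.
#' @export
derive_nutrient_density <- function(diet, energy_var,
                                    macronutrients = c(
                                      protein = "protein",
                                      carbohydrate = "carbohydrate",
                                      fat = "fat")) {
  stopifnot(inherits(diet, "covariate_table"))
  v <- diet$values
  if (!energy_var %in% colnames(v)) stop("energy variable not found: ",
                                         energy_var)
  energy <- v[, energy_var]
  bad <- which(!is.na(energy) & energy <= 0)
  if (length(bad))
    stop("non-positive energy at observation(s): ",
         paste(bad, collapse = ", "))
  nutr <- setdiff(colnames(v), energy_var)
  dens <- v
  dens[, nutr] <- v[, nutr] / (energy / 1000)
  kcal_per_g <- c(protein = 4, carbohydrate = 4, fat = 9)
  macronutrients <- macronutrients[macronutrients %in% colnames(v)]
  for (role in names(macronutrients)) {
    col <- macronutrients[[role]]
    pct <- 100 * v[, col] * kcal_per_g[[role]] / energy
    dens <- cbind(dens, pct)
    colnames(dens)[ncol(dens)] <- paste0(col, "_pct_energy")
  }
  covariate_table(dens, diet$subject, diet$timepoint, diet$kinds)
}

#' Derive the short-chain fatty acid panel
#'
#' Totals the three major SCFAs (acetate + propionate + butyrate), computes
#' each one's percentage share of that total, and sums the branched-chain
#' fatty acids (isobutyrate + isovalerate). Shares are NA when the total
#' is zero.
#'
#' @param raw data.frame with numeric columns `acetate`, `propionate`,
#'   `butyrate`, `isobutyrate`, `isovalerate`, `valerate` (umol/g).
#' @return data.frame with added columns `total_scfa`, `bcfa`,
#'   `acetate_pct`, `propionate_pct`, `butyrate_pct`.
#' @export
derive_scfa_panel <- function(raw) {
  acids <- c("acetate", "propionate", "butyrate", "isobutyrate",
             "isovalerate", "valerate")
  if (!all(acids %in% colnames(raw)))
    stop("missing acid columns: ",
         paste(setdiff(acids, colnames(raw)), collapse = ", "))
  raw <- as.data.frame(raw)
  if (any(raw[acids] < 0, na.rm = TRUE))
    stop("negative concentrations are not allowed")
  total <- raw$acetate + raw$propionate + raw$butyrate
  raw$total_scfa <- total
  raw$bcfa <- raw$isobutyrate + raw$isovalerate
  share <- function(a) ifelse(total > 0, 100 * a / total, NA_real_)
  raw$acetate_pct <- share(raw$acetate)
  raw$propionate_pct <- share(raw$propionate)
  raw$butyrate_pct <- share(raw$butyrate)
  raw
}
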