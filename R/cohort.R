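#' Construct a longitudinal cohort table
#'
#' A `cohort_table` binds a samples x taxa count matrix to longitudinal
#' metadata: every sample belongs to one subject and one ordinal timepoint,
#' and each (subject, timepoint) pair occurs at most once. This is the
#' central container consumed by all downstream stages (rarefaction,
#' diversity, stability scoring, neutral-model fitting, networks).
#'
#' @param counts non-negative integer matrix, samples in rows, taxa in
#'   columns; must have unique row (sample) and column (taxon) names.
#' @param subject character vector, one subject ID per sample.
#' @param timepoint vector of timepoint labels per sample (e.g. "T0",
#'   "T9"); coerced to an ordered factor.
#' @param timepoint_order optional character vector giving the temporal
#'   ordering of the labels; defaults to a numeric sort of the digits
#'   embedded in each label (so "T0" < "T9" < "T14" < "T52").
#' @param taxonomy optional data.frame of rank strings, one row per taxon,
#'   rownames matching `colnames(counts)`.
#' @return an object of class `cohort_table`: a list with elements
#'   `counts`, `samples` (data.frame sample_id/subject/timepoint) and
#'   `taxonomy`.
#' @export
cohort_table <- function(counts, subject, timepoint, timepoint_order = NULL,
                         taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and taxon colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon IDs")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0))
    stop("samples with zero total count: ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  storage.mode(counts) <- "double"
  n <- nrow(counts)
  if (length(subject) != n || length(timepoint) != n)
    stop("subject and timepoint must have one entry per sample")
  subject <- as.character(subject)
  tp_chr <- as.character(timepoint)
  if (is.null(timepoint_order)) {
    lev <- unique(tp_chr)
    num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", lev)))
    timepoint_order <- if (anyNA(num)) sort(lev) else lev[order(num)]
  }
  if (!all(tp_chr %in% timepoint_order))
    stop("timepoint labels outside timepoint_order: ",
         paste(setdiff(tp_chr, timepoint_order), collapse = ", "))
  key <- paste(subject, tp_chr, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, timepoint) pairs: ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if (!all(colnames(counts) %in% rownames(taxonomy)))
      stop("taxonomy missing entries for some taxa")
    taxonomy <- taxonomy[colnames(counts), , drop = FALSE]
  }
  samples <- data.frame(
    sample_id = rownames(counts),
    subject = subject,
    timepoint = factor(tp_chr, levels = timepoint_order, ordered = TRUE),
    stringsAsFactors = FALSE
  )
  rownames(samples) <- samples$sample_id
  structure(list(counts = counts, samples = samples, taxonomy = taxonomy),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " taxa\n", sep = "")
  cat("  subjects:  ", length(unique(x$samples$subject)), "\n", sep = "")
  cat("  timepoints:", paste(levels(x$samples$timepoint), collapse = " < "),
      "\n")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$counts)

#' Subset a cohort table by samples and/or taxa
#'
#' @param x a `cohort_table`.
#' @param samples,taxa index vectors (logical, integer or names) applied to
#'   rows and columns of the count matrix; missing means keep all.
#' @return a `cohort_table` restricted to the selection.
#' @export
subset_cohort <- function(x, samples = NULL, taxa = NULL) {
  stopifnot(inherits(x, "cohort_table"))
  counts <- x$counts
  meta <- x$samples
  if (!is.null(samples)) {
    counts <- counts[samples, , drop = FALSE]
    meta <- meta[rownames(counts), , drop = FALSE]
  }
  if (!is.null(taxa)) counts <- counts[, taxa, drop = FALSE]
  if (ncol(counts) == 0) stop("selection removed all taxa")
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[colnames(counts), , drop = FALSE]
  cohort_table(counts, meta$subject, as.character(meta$timepoint),
               timepoint_order = levels(meta$timepoint), taxonomy = tax)
}

#' Relative abundances of a cohort table
#'
#' @param x a `cohort_table` or count matrix (samples x taxa).
#' @return matrix of per-sample relative abundances (rows sum to 1).
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "cohort_table")) x$counts else as.matrix(x)
  sweep(m, 1, rowSums(m), "/")
}
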