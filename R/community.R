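#' Rarefy a cohort to even sequencing depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (one draw per sample). Samples with fewer reads than `depth` are
#' dropped with a warning.
#'
#' @param x a [cohort_table].
#' @param depth target reads per sample (integer >= 1).
#' @param seed integer seed controlling the subsampling.
#' @return rarefied [cohort_table]; dropped samples recorded in attribute
#'   `dropped_samples`.
#' @export
rarefy_cohort <- function(x, depth, seed = 1L) {
  stopifnot(inherits(x, "cohort_table"), depth >= 1)
  depth <- as.integer(depth)
  totals <- rowSums(x$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("rarefaction depth exceeds every sample's total")
  dropped <- rownames(x$counts)[!keep]
  if (length(dropped))
    warning("dropped ", length(dropped), " sample(s) below depth ", depth,
            ": ", paste(dropped, collapse = ", "))
  sub <- subset_cohort(x, samples = which(keep))
  set.seed(seed)
  # cohort_table guarantees integer counts; vegan's "observed counts"
  # heads-up fires on small fixtures and is muffled
  rare <- withCallingHandlers(
    vegan::rrarefy(sub$counts, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- sub
  out$counts <- rare
  attr(out, "dropped_samples") <- dropped
  attr(out, "depth") <- depth
  out
}

#' Centered log-ratio transform
#'
#' Adds a pseudocount to the counts, closes each sample to relative
#' abundance, and applies clr: `clr_ij = log(p_ij) - mean_j log(p_ij)`.
#' Rows of the result sum to zero.
#'
#' @param x a [cohort_table] or count matrix (samples x taxa).
#' @param pseudocount positive value added to every count before closure
#'   (default 0.5).
#' @return numeric matrix, samples x taxa, rows centered to 0.
#' @export
clr_transform <- function(x, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  m <- if (inherits(x, "cohort_table")) x$counts else as.matrix(x)
  m <- m + pseudocount
  p <- sweep(m, 1, rowSums(m), "/")
  lp <- log(p)
  lp - rowMeans(lp)
}

#' Per-sample alpha diversity
#'
#' Shannon entropy in nats (base-e), Simpson's index 1 - sum(p^2),
#' observed richness, and Pielou's evenness H / log(richness) (0 for a
#' single-taxon sample).
#'
#' @param x a [cohort_table] (ideally rarefied) or count matrix.
#' @return data.frame with columns `sample_id`, `shannon`, `simpson`,
#'   `richness`, `pielou`.
#' @export
alpha_diversity <- function(x) {
  m <- if (inherits(x, "cohort_table")) x$counts else as.matrix(x)
  if (any(rowSums(m) == 0)) stop("empty sample")
  shannon <- vegan::diversity(m, index = "shannon")
  simpson <- vegan::diversity(m, index = "simpson")
  richness <- rowSums(m > 0)
  pielou <- ifelse(richness > 1, shannon / log(richness), 0)
  data.frame(sample_id = rownames(m), shannon = as.numeric(shannon),
             simpson = as.numeric(simpson), richness = as.numeric(richness),
             pielou = as.numeric(pielou), stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over taxa, for every
#' sample pair. Zero for identical profiles, one for disjoint supports.
#'
#' @param x a [cohort_table] (rarefied counts or relative abundances) or
#'   numeric matrix samples x taxa.
#' @return a `dist` object with sample labels.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "cohort_table")) x$counts else as.matrix(x)
  if (any(rowSums(m) == 0)) stop("zero-sum sample")
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: eigendecomposition
#' of the Gower double-centered matrix -D^2/2. Axes are ordered by
#' eigenvalue; negative eigenvalues (from non-Euclidean dissimilarities
#' such as Bray-Curtis) are reported, never clipped.
#'
#' @param d a `dist` object or square symmetric matrix.
#' @param k number of axes to keep (default all with positive eigenvalue,
#'   capped at n - 1).
#' @return list of class `pcoa_ord`: `points` (samples x axes),
#'   `eigenvalues` (all n), `explained` (fraction of the positive
#'   eigenvalue sum per kept axis).
#' @export
pcoa_ordination <- function(d, k = NULL) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(m)
  A <- -0.5 * m^2
  # Gower centering: A - rowmean - colmean + grand mean (second sweep's
  # column means already absorb the grand-mean term)
  G <- sweep(A, 1, rowMeans(A))
  G <- sweep(G, 2, colMeans(G))
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  if (is.null(k)) k <- min(sum(pos), n - 1)
  k <- min(k, sum(pos))
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("PCo", seq_len(k))
  structure(list(points = pts, eigenvalues = e$values,
                 explained = e$values[seq_len(k)] / sum(e$values[pos])),
            class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat("PCoA ordination:", nrow(x$points), "samples,", ncol(x$points),
      "axes\n")
  cat("  axis 1-2 explained:",
      paste0(round(100 * x$explained[seq_len(min(2, length(x$explained)))],
                   1), "%", collapse = ", "), "\n")
  if (any(x$eigenvalues < 0))
    cat("  negative eigenvalues present (min ",
        signif(min(x$eigenvalues), 3), ")\n", sep = "")
  invisible(x)
}

#' Intra- and inter-individual dissimilarities
#'
#' Splits a sample-by-sample dissimilarity matrix into intra-individual
#' distances (all pairs of one subject's samples across timepoints) and
#' inter-individual distances (all pairs of different subjects within the
#' same timepoint).
#'
#' @param d `dist` or matrix over the cohort's samples.
#' @param x the matching [cohort_table].
#' @return list with data.frames `intra` (subject, pair timepoints,
#'   distance) and `inter` (timepoint, subject pair, distance). Subjects
#'   with a single sample are excluded from `intra` with a warning.
#' @export
intra_inter_distances <- function(d, x) {
  stopifnot(inherits(x, "cohort_table"))
  m <- as.matrix(d)
  meta <- x$samples
  m <- m[meta$sample_id, meta$sample_id]
  singletons <- names(which(table(meta$subject) < 2))
  if (length(singletons))
    warning("subjects with <2 samples excluded from intra: ",
            paste(singletons, collapse = ", "))
  intra <- do.call(rbind, lapply(
    setdiff(unique(meta$subject), singletons), function(s) {
      idx <- which(meta$subject == s)
      pr <- utils::combn(idx, 2)
      data.frame(subject = s,
                 timepoint_a = as.character(meta$timepoint[pr[1, ]]),
                 timepoint_b = as.character(meta$timepoint[pr[2, ]]),
                 distance = m[cbind(pr[1, ], pr[2, ])],
                 stringsAsFactors = FALSE)
    }))
  inter <- do.call(rbind, lapply(levels(meta$timepoint), function(tp) {
    idx <- which(meta$timepoint == tp)
    if (length(idx) < 2) return(NULL)
    pr <- utils::combn(idx, 2)
    data.frame(timepoint = tp,
               subject_a = meta$subject[pr[1, ]],
               subject_b = meta$subject[pr[2, ]],
               distance = m[cbind(pr[1, ], pr[2, ])],
               stringsAsFactors = FALSE)
  }))
  list(intra = intra, inter = inter)
}
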