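#' Fit the Sloan neutral community model
#'
#' Relates each taxon's occurrence frequency across samples to its mean
#' relative abundance under neutral assembly. With detection limit
#' `d = 1/depth`, the predicted occurrence of a taxon at metacommunity
#' abundance p is `f_pred(p) = 1 - pbeta(d, Nm*p, Nm*(1-p))`. The single
#' parameter Nm (metacommunity size x immigration) is estimated by least
#' squares of observed on predicted frequencies, minimised over log(Nm).
#' Goodness of fit is `R2 = 1 - SSE/SST`, which is negative when the
#' community fits worse than the constant model (a meaningful outcome for
#' deterministically assembled communities). A 95% Wilson binomial band
#' around `f_pred` at n samples classifies each taxon as above, within or
#' below the neutral prediction.
#'
#' @param x a [cohort_table] of rarefied (equal-depth) counts, or a count
#'   matrix samples x taxa.
#' @param detection_limit optional override of d; default 1/(mean depth).
#' @param nm_range log10 search bounds for Nm (default 1e-2 .. 1e7; a fit
#'   at the upper bound indicates the deterministic step-function limit).
#' @return object of class `ncm_fit`: `Nm`, `m` (immigration probability
#'   = Nm / mean depth), `R2`, `detection_limit`, `n_samples`, and `taxa`
#'   (data.frame: taxon, p, f_obs, f_pred, lower, upper, class).
#' @export
fit_ncm <- function(x, detection_limit = NULL, nm_range = c(1e-2, 1e7)) {
  m <- if (inherits(x, "cohort_table")) x$counts else as.matrix(x)
  n <- nrow(m)
  depth <- mean(rowSums(m))
  d <- if (is.null(detection_limit)) 1 / depth else detection_limit
  p <- colMeans(sweep(m, 1, rowSums(m), "/"))
  f_obs <- colMeans(m > 0)
  pred <- function(log_nm) {
    nm <- exp(log_nm)
    1 - stats::pbeta(d, nm * p, nm * (1 - p))
  }
  sse <- function(log_nm) sum((f_obs - pred(log_nm))^2)
  opt <- stats::optimize(sse, log(nm_range))
  nm_hat <- exp(opt$minimum)
  f_pred <- pred(opt$minimum)
  sst <- sum((f_obs - mean(f_obs))^2)
  r2 <- 1 - opt$objective / sst
  # 95% Wilson interval for a binomial proportion f_pred over n samples
  z <- stats::qnorm(0.975)
  centre <- (f_pred + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(f_pred * (1 - f_pred) / n + z^2 / (4 * n^2)) /
    (1 + z^2 / n)
  lower <- pmax(0, centre - half)
  upper <- pmin(1, centre + half)
  cls <- ifelse(f_obs > upper, "above",
                ifelse(f_obs < lower, "below", "within"))
  taxa <- data.frame(taxon = colnames(m), p = unname(p),
                     f_obs = unname(f_obs), f_pred = unname(f_pred),
                     lower = unname(lower), upper = unname(upper),
                     class = unname(cls), stringsAsFactors = FALSE)
  structure(list(Nm = nm_hat, m = nm_hat / depth, R2 = r2,
                 detection_limit = d, n_samples = n, taxa = taxa,
                 at_bound = nm_hat >= nm_range[2] * 0.99 ||
                   nm_hat <= nm_range[1] * 1.01),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral community model: Nm = %.1f, R2 = %.3f\n",
              x$Nm, x$R2))
  cat(sprintf("  m = %.4g, detection limit = %.3g, %d samples\n",
              x$m, x$detection_limit, x$n_samples))
  print(table(x$taxa$class))
  if (x$at_bound) cat("  note: Nm at search bound\n")
  invisible(x)
}

#' Neutral-model predicted occurrence frequency
#'
#' @param p mean relative abundance(s).
#' @param Nm neutral parameter.
#' @param detection_limit d.
#' @return predicted occurrence frequency, monotone non-decreasing in p.
#' @export
ncm_predict <- function(p, Nm, detection_limit) {
  1 - stats::pbeta(detection_limit, Nm * p, Nm * (1 - p))
}
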