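# Small in-code fixtures shared across test files.

# A tiny deterministic cohort: ns subjects x nt timepoints x p taxa.
make_toy_cohort <- function(ns = 4, nt = 4, p = 6, seed = 1, depth = 500) {
  set.seed(seed)
  subj <- rep(sprintf("S%d", seq_len(ns)), each = nt)
  tp <- rep(paste0("T", seq_len(nt) - 1), ns)
  counts <- matrix(rpois(ns * nt * p, lambda = depth / p), ns * nt, p)
  counts[counts == 0] <- 1
  dimnames(counts) <- list(paste(subj, tp, sep = "_"),
                           paste0("taxon", seq_len(p)))
  cohort_table(counts, subj, tp)
}

# Brute-force oracles, intentionally naive and independent of the
# package implementations.
bc_brute <- function(x, y) sum(abs(x - y)) / sum(x + y)

shannon_brute <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

simpson_brute <- function(counts) {
  p <- counts / sum(counts)
  1 - sum(p^2)
}

clr_brute <- function(row, pseudo) {
  v <- row + pseudo
  v <- v / sum(v)
  log(v) - mean(log(v))
}

auc_brute <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s0))
}

bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# rmcorr by explicit ANCOVA normal equations: y ~ subject dummies + x.
rmcorr_brute <- function(x, y, subject) {
  subject <- factor(subject)
  X <- cbind(stats::model.matrix(~ subject - 1), x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  slope <- beta[length(beta)]
  resid_full <- y - X %*% beta
  X0 <- stats::model.matrix(~ subject - 1)
  beta0 <- solve(t(X0) %*% X0, t(X0) %*% y)
  resid_0 <- y - X0 %*% beta0
  ss_err <- sum(resid_full^2)
  ss_x <- sum(resid_0^2) - ss_err
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  df <- length(y) - nlevels(subject) - 1
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
}
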