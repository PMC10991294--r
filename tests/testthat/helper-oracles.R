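# Independent brute-force oracles. These deliberately use explicit loops and
# sum formulas rather than the package's (or base R's vectorised) code paths.

oracle_var <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}

# overestimated-variance t: rest variance divided by the group's own n
oracle_overestim_t <- function(xg, xr) {
  ng <- length(xg)
  mg <- sum(xg) / ng
  mr <- sum(xr) / length(xr)
  vg <- oracle_var(xg)
  vr <- oracle_var(xr)
  se2 <- vg / ng + vr / ng
  if (se2 == 0) {
    return(list(t = 0, df = 1, p = 1))
  }
  t <- (mg - mr) / sqrt(se2)
  df <- se2^2 / ((vg / ng)^2 / (ng - 1) + (vr / ng)^2 / (ng - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_wald_z <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  m1 <- sum(x1) / n1; m0 <- sum(x0) / n0
  se <- sqrt(oracle_var(x1) / n1 + oracle_var(x0) / n0)
  if (se == 0) {
    if (m1 == m0) return(list(z = 0, p = 1))
    return(list(z = NA_real_, p = NA_real_))
  }
  z <- (m1 - m0) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

oracle_log2fc <- function(m_g, m_r, eps = 1e-9) {
  log2((exp(m_g) - 1 + eps) / (exp(m_r) - 1 + eps))
}

# Benjamini-Hochberg by the step-up definition, loop form
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  padj <- numeric(n)
  running_min <- 1
  for (i in seq(n, 1)) {
    val <- p[ord[i]] * n / i
    running_min <- min(running_min, val)
    padj[ord[i]] <- running_min
  }
  padj
}

# P(X >= k), X ~ Hypergeometric(N, K, n), by direct enumeration of choose()
oracle_hyper_p <- function(k, K, n, N) {
  if (k <= 0) return(1)
  total <- 0
  for (j in seq(k, min(K, n))) {
    total <- total + choose(K, j) * choose(N - K, n - j)
  }
  total / choose(N, n)
}

# concentric-bin oracle: loop over rings with explicit interval checks
oracle_bin <- function(x, y, cx, cy, r0, w, B) {
  d <- sqrt((x - cx)^2 + (y - cy)^2) - r0
  if (d <= 0) return(0L)
  for (k in seq_len(B)) {
    if (d > (k - 1) * w && d <= k * w) return(k)
  }
  NA_integer_
}

# per-element membership-signature classifier for exclusive intersections
oracle_exclusive <- function(sets) {
  universe <- unique(unlist(sets))
  out <- list()
  for (el in universe) {
    sig <- paste(names(sets)[vapply(sets, function(s) el %in% s, TRUE)],
                 collapse = "&")
    out[[sig]] <- c(out[[sig]], el)
  }
  out
}

wilcox_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
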