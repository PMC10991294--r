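log2fc_from_logmeans <- function(m_g, m_r, eps = 1e-9) {
  log2((expm1(m_g) + eps) / (expm1(m_r) + eps))
}

#' Rank cluster marker genes with the overestimated-variance t test
#'
#' For each gene, the target group (mean `m_g`, variance `s_g^2`, size
#' `n_g`) is contrasted against all other observations (mean `m_r`,
#' variance `s_r^2`) with
#' `t = (m_g - m_r) / sqrt(s_g^2 / n_g + s_r^2 / n_g)` — the rest-group
#' variance term is divided by the *group* size, conservatively inflating
#' the standard error for large rest groups. Degrees of freedom follow
#' Welch-Satterthwaite under the same substitution. The fold change is
#' computed on de-logged means: `log2((e^m_g - 1 + eps)/(e^m_r - 1 + eps))`
#' with `eps = 1e-9`. P-values are two-sided; `padj` is Benjamini-Hochberg
#' within the group.
#'
#' @param norm Log-normalised [count_matrix()].
#' @param labels A [cluster_graph()] result or named vector of labels.
#' @param group The cluster label to contrast against the rest.
#' @param min_group_size Groups smaller than this are refused (testing tiny
#'   subclusters is unreliable); default 10, set lower deliberately.
#' @return A data.frame of class `deg_table` sorted by decreasing `t`:
#'   `gene`, `group`, `mean_in`, `mean_rest`, `log2fc`, `statistic`, `pval`,
#'   `padj`.
#' @export
rank_markers <- function(norm, labels, group, min_group_size = 10) {
  stopifnot_norm(norm, "rank_markers")
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else labels
  lab <- lab[colnames(norm$values)]
  sel <- !is.na(lab) & lab == group
  n_g <- sum(sel)
  n_r <- sum(!sel & !is.na(lab))
  if (n_g < 2 || n_r < 1) stop("group and rest must both be populated")
  if (n_g < min_group_size) {
    stop("group has ", n_g, " observations (< min_group_size = ",
         min_group_size, "); marker testing skipped")
  }
  x <- as.matrix(norm$values)
  xg <- x[, sel, drop = FALSE]
  xr <- x[, !sel & !is.na(lab), drop = FALSE]
  m_g <- rowMeans(xg)
  m_r <- rowMeans(xr)
  s2_g <- apply(xg, 1, stats::var)
  s2_r <- apply(xr, 1, stats::var)
  se2 <- s2_g / n_g + s2_r / n_g
  t_stat <- ifelse(se2 > 0, (m_g - m_r) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((s2_g / n_g)^2 / (n_g - 1) +
                          (s2_r / n_g)^2 / (n_g - 1)),
               1)
  pval <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df = df), 1)
  out <- data.frame(gene = rownames(x), group = as.character(group),
                    mean_in = m_g, mean_rest = m_r,
                    log2fc = log2fc_from_logmeans(m_g, m_r),
                    statistic = t_stat, pval = pval,
                    padj = stats::p.adjust(pval, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$statistic, out$gene, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Wald-type condition contrast within a (sub)cluster
#'
#' Two-group z contrast on log-normalised values:
#' `z = (m_1 - m_0) / sqrt(s_1^2/n_1 + s_0^2/n_0)` with a two-sided normal
#' p-value. A deliberate normal-approximation simplification of
#' regression-based Wald testing on counts.
#'
#' @param norm Log-normalised [count_matrix()]; `obs_meta` must contain
#'   `condition_key`.
#' @param condition_key Column of `obs_meta` holding the condition.
#' @param group1,group0 Condition labels contrasted (group1 minus group0).
#' @param subset Optional logical/index vector of observations (e.g. one
#'   subcluster).
#' @return A `deg_table` data.frame (`statistic` is z); genes degenerate in
#'   both groups with equal means get z = 0, p = 1; genes with zero pooled
#'   SE but unequal means are flagged in a `degenerate` column and skipped
#'   (p = NA).
#' @export
condition_wald_test <- function(norm, condition_key = "condition",
                                group1, group0, subset = NULL) {
  stopifnot_norm(norm, "condition_wald_test")
  cond <- norm$obs_meta[[condition_key]]
  if (is.null(cond)) stop("obs_meta lacks column '", condition_key, "'")
  x <- as.matrix(norm$values)
  if (!is.null(subset)) {
    x <- x[, subset, drop = FALSE]
    cond <- cond[subset]
  }
  s1 <- cond == group1
  s0 <- cond == group0
  n1 <- sum(s1); n0 <- sum(s0)
  if (n1 < 2 || n0 < 2) stop("both condition groups need >= 2 observations")
  x1 <- x[, s1, drop = FALSE]
  x0 <- x[, s0, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- apply(x1, 1, stats::var)
  v0 <- apply(x0, 1, stats::var)
  se <- sqrt(v1 / n1 + v0 / n0)
  z <- ifelse(se > 0, (m1 - m0) / se, ifelse(m1 == m0, 0, NA_real_))
  pval <- ifelse(is.na(z), NA_real_, 2 * stats::pnorm(-abs(z)))
  pval[!is.na(z) & z == 0 & se == 0] <- 1
  out <- data.frame(gene = rownames(x), group = as.character(group1),
                    mean_in = m1, mean_rest = m0,
                    log2fc = log2fc_from_logmeans(m1, m0),
                    statistic = z, pval = pval,
                    padj = NA_real_,
                    degenerate = is.na(z),
                    stringsAsFactors = FALSE, row.names = NULL)
  ok <- !out$degenerate
  out$padj[ok] <- stats::p.adjust(out$pval[ok], method = "BH")
  out <- out[order(-abs(out$statistic), out$gene, method = "radix",
                   na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Threshold-filter a DEG table
#'
#' Keeps genes with `pval < p_max` (strict) and a log2 fold change strictly
#' beyond `lfc_min_abs` in the requested direction, mirroring cutoffs such
#' as "pval < 0.05, log2 fold change > 1.6".
#'
#' @param table A `deg_table`.
#' @param p_max Strict p-value bound (default 0.05).
#' @param lfc_min_abs Strict absolute log2FC bound (default 1.6).
#' @param direction `"up"`, `"down"`, or `"both"`.
#' @param use_padj Filter on `padj` instead of raw `pval`.
#' @return Character vector of gene ids (possibly empty), in table order.
#' @export
filter_degs <- function(table, p_max = 0.05, lfc_min_abs = 1.6,
                        direction = c("up", "down", "both"),
                        use_padj = FALSE) {
  direction <- match.arg(direction)
  if (!nrow(table)) stop("empty DEG table")
  p <- if (use_padj) table$padj else table$pval
  keep <- !is.na(p) & p < p_max
  keep <- keep & switch(direction,
                        up = table$log2fc > lfc_min_abs,
                        down = table$log2fc < -lfc_min_abs,
                        both = abs(table$log2fc) > lfc_min_abs)
  table$gene[keep]
}

#' Exclusive and inclusive intersections of named gene sets
#'
#' Exclusive mode classifies every member of the union by its exact
#' membership signature (the sizes partition the union, as in an UpSet
#' plot); inclusive mode reports, for each nonempty subset of sets, the
#' plain intersection regardless of other sets.
#'
#' @param sets Named list (1-20) of character vectors.
#' @return A list of class `intersection_result` with `exclusive` and
#'   `inclusive`: each a list keyed by subset (set names joined with `&`)
#'   holding the member vector; sizes via `lengths()`.
#' @export
exclusive_intersections <- function(sets) {
  if (!length(sets) || length(sets) > 20) {
    stop("between 1 and 20 sets supported")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1)
  sig <- apply(memb, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  exclusive <- split(universe, sig)
  # all nonempty subsets for inclusive mode
  n <- length(sets)
  inclusive <- list()
  for (mask in seq_len(2^n - 1)) {
    in_t <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    key <- paste(names(sets)[in_t], collapse = "&")
    inclusive[[key]] <- Reduce(intersect, sets[in_t])
    if (!(key %in% names(exclusive))) exclusive[[key]] <- character(0)
  }
  ord <- order(names(exclusive))
  structure(list(exclusive = exclusive[ord],
                 inclusive = inclusive[order(names(inclusive))],
                 union_size = length(universe)),
            class = "intersection_result")
}

#' Hypergeometric over-representation of gene sets in a query
#'
#' For each set, `p = P(X >= k)` with
#' `X ~ Hypergeometric(N = |universe|, K = |set in universe|, n = |query|)`
#' and `k` the observed overlap; Benjamini-Hochberg correction across sets.
#' Query genes outside the universe are dropped with a warning.
#'
#' @param query Character vector of genes of interest.
#' @param sets Named list of gene sets (vectors or `members` lists).
#' @param universe Character vector of all testable genes.
#' @return A data.frame of class `enrichment_result`: `set`, `overlap`,
#'   `set_size`, `query_size`, `universe_size`, `pval`, `padj`, sorted by
#'   `pval`.
#' @export
over_representation <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  members <- lapply(sets, function(s) {
    m <- if (is.list(s)) s$members else s
    intersect(unique(m), universe)
  })
  N <- length(universe)
  n <- length(query)
  K <- lengths(members)
  k <- vapply(members, function(m) length(intersect(m, query)), 0L)
  pval <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pval <- pmin(pval, 1)
  out <- data.frame(set = names(sets), overlap = k, set_size = K,
                    query_size = n, universe_size = N, pval = pval,
                    padj = stats::p.adjust(pval, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$pval, out$set, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Cluster similarity from top marker overlap
#'
#' Jaccard index of the top-`k_top` ranked markers of every pair of
#' clusters (default 20 genes per cluster).
#'
#' @param markers Named list: per cluster, marker genes ranked best-first.
#' @param k_top Markers per cluster used (default 20); clusters with fewer
#'   use all of theirs (flagged via a warning).
#' @return Symmetric cluster x cluster matrix in `[0, 1]` with unit
#'   diagonal.
#' @export
cluster_similarity <- function(markers, k_top = 20) {
  short <- names(markers)[lengths(markers) < k_top]
  if (length(short)) {
    warning("cluster(s) with fewer than k_top markers use all: ",
            paste(short, collapse = ", "))
  }
  tops <- lapply(markers, utils::head, n = k_top)
  n <- length(tops)
  S <- matrix(1, n, n, dimnames = list(names(tops), names(tops)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        inter <- length(intersect(tops[[i]], tops[[j]]))
        uni <- length(union(tops[[i]], tops[[j]]))
        S[i, j] <- S[j, i] <- if (uni == 0) 0 else inter / uni
      }
    }
  }
  S
}
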