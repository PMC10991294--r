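#' Quality-control thresholds
#'
#' Bounds are inclusive: "at least" reads/genes means `>=`, "maximum" means
#' `<=`. Any unset (`NULL`/`NA`) bound is skipped. The defaults reproduce the
#' spatial filter used for stab-wound sections (>= 1500 reads, <= 45%
#' mitochondrial fraction); for droplet single-cell data use e.g.
#' `qc_thresholds(min_genes = 1000, max_reads = 50000, max_mito_fraction =
#' 0.25)`.
#'
#' @param min_reads,max_reads Total-count bounds per observation.
#' @param min_genes Minimum genes detected (count > 0).
#' @param max_mito_fraction Maximum mitochondrial read fraction in `[0, 1]`.
#' @param mito_prefix Gene-symbol prefix identifying mitochondrial genes.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_reads = 1500, max_reads = NULL,
                          min_genes = NULL, max_mito_fraction = 0.45,
                          mito_prefix = "mt-") {
  chk <- function(x) is.null(x) || (is.numeric(x) && length(x) == 1)
  stopifnot(chk(min_reads), chk(max_reads), chk(min_genes),
            chk(max_mito_fraction))
  if (!is.null(max_mito_fraction) &&
      (max_mito_fraction < 0 || max_mito_fraction > 1)) {
    stop("max_mito_fraction must lie in [0, 1]")
  }
  if (!is.null(min_reads) && !is.null(max_reads) && min_reads > max_reads) {
    stop("min_reads exceeds max_reads")
  }
  structure(list(min_reads = min_reads, max_reads = max_reads,
                 min_genes = min_genes,
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Filter low-quality observations
#'
#' @param counts A raw [count_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return The filtered `count_matrix`; the number removed per rule is
#'   reported via `message()`.
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds()) {
  stopifnot_raw(counts, "qc_filter")
  v <- counts$values
  reads <- Matrix::colSums(v)
  keep <- rep(TRUE, ncol(v))
  th <- thresholds
  report <- character()
  if (!is.null(th$min_reads)) {
    drop <- reads < th$min_reads
    report <- c(report, sprintf("%d below min_reads", sum(drop & keep)))
    keep <- keep & !drop
  }
  if (!is.null(th$max_reads)) {
    drop <- reads > th$max_reads
    report <- c(report, sprintf("%d above max_reads", sum(drop & keep)))
    keep <- keep & !drop
  }
  if (!is.null(th$min_genes)) {
    detected <- Matrix::colSums(v > 0)
    drop <- detected < th$min_genes
    report <- c(report, sprintf("%d below min_genes", sum(drop & keep)))
    keep <- keep & !drop
  }
  if (!is.null(th$max_mito_fraction)) {
    mito <- startsWith(rownames(v), th$mito_prefix)
    mito_frac <- if (any(mito)) {
      Matrix::colSums(v[mito, , drop = FALSE]) / pmax(reads, 1)
    } else rep(0, ncol(v))
    drop <- mito_frac > th$max_mito_fraction
    report <- c(report, sprintf("%d above max_mito_fraction",
                                sum(drop & keep)))
    keep <- keep & !drop
  }
  if (!any(keep)) stop("all observations filtered")
  message("qc_filter: removed ", sum(!keep), " of ", ncol(v), " (",
          paste(report, collapse = "; "), ")")
  counts[, keep]
}

#' Depth-normalise and log-transform counts
#'
#' Counts-per-N normalisation: every observation is scaled to sum exactly
#' `target` (default 10,000), then `log(1 + x)` (natural log) is applied.
#'
#' @param counts Raw [count_matrix()].
#' @param target Target count depth (> 0).
#' @return A [count_matrix()] with `layer = "normalized_log"`.
#' @export
normalize_log_cpm <- function(counts, target = 10000) {
  stopifnot_raw(counts, "normalize_log_cpm")
  if (!is.numeric(target) || target <= 0) stop("target must be > 0")
  v <- counts$values
  totals <- Matrix::colSums(v)
  if (any(totals == 0)) {
    stop("zero-total observation(s): ",
         paste(utils::head(colnames(v)[totals == 0], 5), collapse = ", "))
  }
  sc <- v %*% Matrix::Diagonal(x = target / totals)
  sc@x <- log1p(sc@x)
  dimnames(sc) <- dimnames(v)
  count_matrix(sc, rownames(v), colnames(v), counts$obs_meta,
               layer = "normalized_log")
}

#' Select highly variable genes by binned dispersion
#'
#' Dispersion of the de-logged values (`expm1`) is computed per gene as
#' variance / mean; genes are placed into 20 equal-frequency mean-expression
#' bins and a robust z-score (median / MAD) of dispersion is taken within
#' each bin. The top-`n` z-scores are returned, ties broken alphabetically
#' by gene id.
#'
#' @param norm A log-normalised [count_matrix()].
#' @param n Number of genes to return (default 2000).
#' @param n_bins Number of mean-expression bins.
#' @return Character vector of `n` gene ids (fewer if fewer genes have
#'   finite dispersion), sorted by decreasing z-score.
#' @export
select_hvg <- function(norm, n = 2000, n_bins = 20) {
  stopifnot_norm(norm, "select_hvg")
  if (!is.numeric(n) || n <= 0) stop("n must be a positive integer")
  v <- norm$values
  x <- expm1(as.matrix(v))
  mu <- rowMeans(x)
  vr <- apply(x, 1, stats::var)
  disp <- ifelse(mu > 0, vr / mu, NA_real_)
  ok <- is.finite(disp)
  genes <- rownames(v)[ok]
  disp <- disp[ok]
  mu_ok <- mu[ok]
  if (!length(genes)) stop("no gene with finite dispersion")
  nb <- max(1, min(n_bins, length(genes)))
  bins <- cut(rank(mu_ok, ties.method = "first"),
              breaks = nb, labels = FALSE, include.lowest = TRUE)
  z <- disp
  for (b in unique(bins)) {
    sel <- bins == b
    med <- stats::median(disp[sel])
    md <- stats::mad(disp[sel])
    if (md == 0) md <- 1  # degenerate bin: center only
    z[sel] <- (disp[sel] - med) / md
  }
  ord <- order(-z, genes, method = "radix")
  genes[ord][seq_len(min(n, length(genes)))]
}

#' Graph-based clustering of observations
#'
#' Selected genes are standardised (z-scores clipped at |z| = 10), projected
#' onto principal components, connected in a k-nearest-neighbour graph, and
#' partitioned by Leiden modularity optimisation. Deterministic for a fixed
#' seed.
#'
#' @param norm Log-normalised [count_matrix()].
#' @param genes Genes to use (e.g. from [select_hvg()]); default all.
#' @param k Neighbours in the kNN graph.
#' @param n_pcs Principal components retained.
#' @param resolution Leiden resolution parameter.
#' @param seed Integer seed.
#' @return A list of class `cluster_labels`: `labels` (named integer vector,
#'   contiguous from 0, largest cluster first) and the parameters used.
#' @export
cluster_graph <- function(norm, genes = NULL, k = 15, n_pcs = 50,
                          resolution = 1.0, seed = 0L) {
  stopifnot_norm(norm, "cluster_graph")
  v <- norm$values
  n_obs <- ncol(v)
  if (k >= n_obs) stop("k must be smaller than the number of observations")
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(v))
    if (length(missing_g)) stop("unknown gene(s): ",
                                paste(utils::head(missing_g, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  x <- as.matrix(v)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  sdv[sdv == 0] <- 1
  z <- (x - mu) / sdv
  z[z > 10] <- 10
  z[z < -10] <- -10
  n_pcs <- min(n_pcs, nrow(z) - 1, n_obs - 1)
  set.seed(as.integer(seed))
  pcs <- stats::prcomp(t(z), center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  d <- as.matrix(stats::dist(pcs))
  diag(d) <- Inf
  nn <- apply(d, 1, function(row) order(row)[seq_len(k)])
  edges <- cbind(rep(seq_len(n_obs), each = k), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  raw <- igraph::membership(comm)
  # relabel contiguous from 0, largest community first (ties: first member)
  sizes <- table(raw)
  first_member <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.integer(sizes), first_member)
  relabel <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
  labels <- relabel[as.character(raw)]
  names(labels) <- colnames(v)
  structure(list(labels = labels,
                 params = list(k = k, n_pcs = n_pcs,
                               resolution = resolution, seed = seed)),
            class = "cluster_labels")
}

#' Remove additive batch effects per gene
#'
#' Per batch and gene, subtracts the batch mean and adds back the global
#' mean — a deliberate linear stand-in for heavier integration methods.
#'
#' @param norm Log-normalised [count_matrix()] whose `obs_meta` has a
#'   `batch` column.
#' @return Batch-centred `count_matrix` (dense values in sparse storage).
#' @export
batch_center <- function(norm) {
  stopifnot_norm(norm, "batch_center")
  batch <- norm$obs_meta$batch
  if (is.null(batch)) stop("obs_meta must contain a 'batch' column")
  x <- as.matrix(norm$values)
  global_mu <- rowMeans(x)
  for (b in unique(batch)) {
    sel <- batch == b
    if (sum(sel) == 1) {
      warning("batch '", b, "' has a single observation; passthrough")
      next
    }
    x[, sel] <- x[, sel] - rowMeans(x[, sel, drop = FALSE]) + global_mu
  }
  count_matrix(x, rownames(x), colnames(x), norm$obs_meta,
               layer = "normalized_log")
}

#' Downsample groups to equal size
#'
#' Each group is subsampled without replacement to the minimum group size.
#'
#' @param counts A [count_matrix()] (either layer).
#' @param group_key Column of `obs_meta` defining groups.
#' @param seed Integer seed.
#' @return The subsampled `count_matrix` (original column order preserved).
#' @export
downsample_groups <- function(counts, group_key, seed = 0L) {
  grp <- counts$obs_meta[[group_key]]
  if (is.null(grp)) stop("obs_meta lacks column '", group_key, "'")
  if (any(is.na(grp))) stop("missing group labels")
  tab <- table(grp)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab == 0)) stop("empty group")
  n_min <- min(tab)
  set.seed(as.integer(seed))
  keep <- unlist(lapply(names(tab), function(g) {
    ids <- which(grp == g)
    if (length(ids) > n_min) sort(sample(ids, n_min)) else ids
  }))
  counts[, sort(keep)]
}

#' Score observations for a gene set against matched controls
#'
#' All genes are ranked by mean expression and cut into `n_bins`
#' equal-frequency bins; for each target gene, `ctrl_size` control genes are
#' sampled without replacement from its bin. The score per observation is
#' the mean over target genes minus the mean over the pooled control genes.
#'
#' @param norm Log-normalised [count_matrix()].
#' @param set A gene set (list with `name`, `members`) or character vector.
#' @param n_bins Number of expression bins (default 25).
#' @param ctrl_size Controls sampled per target gene (default 50).
#' @param seed Integer seed.
#' @return A list of class `gene_score`: `scores` (named numeric per
#'   observation), `set_name`, `used_genes`, `control_genes`, `params`.
#' @export
score_gene_set <- function(norm, set, n_bins = 25, ctrl_size = 50,
                           seed = 0L) {
  stopifnot_norm(norm, "score_gene_set")
  if (is.character(set)) set <- list(name = "set", members = set)
  members <- unique(set$members)
  v <- norm$values
  present <- intersect(members, rownames(v))
  if (!length(present)) stop("no gene-set member present in the matrix")
  if (length(present) < length(members)) {
    warning(length(members) - length(present),
            " absent gene-set member(s) dropped")
  }
  mu <- Matrix::rowMeans(v)
  nb <- max(1, min(n_bins, nrow(v)))
  bins <- cut(rank(mu, ties.method = "first"), breaks = nb, labels = FALSE,
              include.lowest = TRUE)
  names(bins) <- rownames(v)
  set.seed(as.integer(seed))
  ctrl <- character()
  for (g in present) {
    pool <- setdiff(names(bins)[bins == bins[g]], present)
    if (!length(pool)) pool <- setdiff(names(bins), present)
    ctrl <- c(ctrl, sample(pool, min(ctrl_size, length(pool))))
  }
  ctrl <- unique(ctrl)
  target_mean <- Matrix::colMeans(v[present, , drop = FALSE])
  ctrl_mean <- if (length(ctrl)) {
    Matrix::colMeans(v[ctrl, , drop = FALSE])
  } else rep(0, ncol(v))
  scores <- target_mean - ctrl_mean
  structure(list(scores = scores, set_name = set$name,
                 used_genes = present, control_genes = ctrl,
                 params = list(n_bins = n_bins, ctrl_size = ctrl_size,
                               seed = seed)),
            class = "gene_score")
}
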