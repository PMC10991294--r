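#' Select training genes for cell-to-spot mapping
#'
#' Union over clusters of each cluster's top-k ranked marker genes,
#' intersected with the genes detected in the spatial panel, sorted
#' deterministically.
#'
#' @param sc_markers Named list: per cluster, a character vector of marker
#'   genes ranked best-first (e.g. from [rank_markers()]).
#' @param spatial_genes Genes present in the spatial matrix.
#' @param top_k Markers taken per cluster (default 20).
#' @return Sorted character vector of training genes.
#' @export
select_training_genes <- function(sc_markers, spatial_genes, top_k = 20) {
  stopifnot(top_k >= 1)
  top <- unlist(lapply(sc_markers, utils::head, n = top_k),
                use.names = FALSE)
  out <- sort(intersect(unique(top), spatial_genes))
  if (!length(out)) stop("no training gene detected in the spatial panel")
  out
}

#' Probabilistic mapping of single cells onto spatial spots
#'
#' Learns a soft assignment `M` (cells x spots, rows on the probability
#' simplex via a row-softmax parameterisation) by full-batch gradient ascent
#' on the summed per-gene cosine similarity between the spatial expression
#' of each training gene and its expression predicted from the mapped cells,
#' `L = sum_g cos(G[, g], t(M) S[, g])`. A step that would decrease `L` is
#' rejected and the learning rate halved, so the objective is non-decreasing
#' over accepted steps.
#'
#' Both matrices should be log-normalised; each training gene is
#' unit-normalised across cells / spots before the cosine.
#'
#' @param sc Log-normalised [count_matrix()] of cells.
#' @param spatial Log-normalised [count_matrix()] of spots.
#' @param training_genes Genes used in the objective (present in both).
#' @param iters Gradient-ascent iterations (default 1000).
#' @param lr Initial learning rate (default 0.1).
#' @param seed Seed for the small-noise initialisation of the logits.
#' @param verbose Log the objective every 100 iterations.
#' @return A list of class `mapping_matrix`: `M` (row-stochastic cells x
#'   spots), `objective` (final L), `trace` (L per iteration),
#'   `training_genes`, `gene_cosines` (final per-gene cosine).
#' @export
fit_mapping <- function(sc, spatial, training_genes, iters = 1000, lr = 0.1,
                        seed = 0L, verbose = FALSE) {
  stopifnot_norm(sc, "fit_mapping")
  stopifnot_norm(spatial, "fit_mapping")
  if (ncol(spatial$values) < 2) stop("need at least 2 spots")
  miss <- setdiff(training_genes,
                  intersect(rownames(sc$values), rownames(spatial$values)))
  if (length(miss)) {
    stop("training gene(s) absent from a matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  S <- t(as.matrix(sc$values[training_genes, , drop = FALSE]))     # cells x genes
  G <- t(as.matrix(spatial$values[training_genes, , drop = FALSE])) # spots x genes
  gnorm <- sqrt(colSums(G^2))
  zero <- gnorm == 0
  if (any(zero)) {
    warning(sum(zero), " training gene(s) all-zero in the spatial matrix; dropped")
    if (all(zero)) stop("all training genes are zero in the spatial matrix")
    S <- S[, !zero, drop = FALSE]
    G <- G[, !zero, drop = FALSE]
    training_genes <- training_genes[!zero]
    gnorm <- gnorm[!zero]
  }
  snorm <- sqrt(colSums(S^2))
  snorm[snorm == 0] <- 1
  S <- sweep(S, 2, snorm, "/")
  G <- sweep(G, 2, gnorm, "/")

  n_cells <- nrow(S)
  n_spots <- nrow(G)
  set.seed(as.integer(seed))
  # logits start at a small multiple of the cell-spot similarity (identical
  # cells get identical rows) plus tiny seeded noise as a tie-break
  sim0 <- S %*% t(G)
  sc0 <- stats::sd(sim0)
  if (!is.finite(sc0) || sc0 == 0) sc0 <- 1
  W <- 0.01 * sim0 / sc0 +
    matrix(stats::rnorm(n_cells * n_spots, sd = 1e-9), n_cells, n_spots)
  lr_max <- lr * 100

  softmax_rows <- function(w) {
    e <- exp(w - apply(w, 1, max))
    e / rowSums(e)
  }
  objective <- function(M) {
    Q <- crossprod(M, S)                 # spots x genes
    qn <- sqrt(colSums(Q^2))
    qn[qn == 0] <- .Machine$double.eps
    list(L = sum(colSums(G * Q) / qn), Q = Q, qn = qn)
  }

  M <- softmax_rows(W)
  ob <- objective(M)
  trace <- numeric(iters + 1)
  trace[1] <- ob$L
  for (it in seq_len(iters)) {
    cosg <- colSums(G * ob$Q) / ob$qn
    # dL/dQ[s,g] = G[s,g]/qn_g - cos_g * Q[s,g]/qn_g^2
    D <- sweep(G, 2, ob$qn, "/") -
      sweep(ob$Q, 2, cosg / ob$qn^2, "*")
    dM <- S %*% t(D)                      # cells x spots
    # softmax backprop per row
    dW <- M * (dM - rowSums(dM * M))
    repeat {
      W_new <- W + lr * dW
      M_new <- softmax_rows(W_new)
      ob_new <- objective(M_new)
      if (ob_new$L >= ob$L || lr < 1e-12) break
      lr <- lr / 2
    }
    if (ob_new$L >= ob$L) {
      W <- W_new; M <- M_new; ob <- ob_new
      lr <- min(lr * 1.05, lr_max)  # regrow after accepted steps
    }
    trace[it + 1] <- ob$L
    if (verbose && it %% 100 == 0) {
      message(sprintf("iter %d: L = %.6f (lr %.3g)", it, ob$L, lr))
    }
  }
  dimnames(M) <- list(rownames(S), rownames(G))
  cosg <- colSums(G * ob$Q) / ob$qn
  structure(list(M = M, objective = ob$L, trace = trace,
                 training_genes = training_genes,
                 gene_cosines = stats::setNames(cosg, training_genes)),
            class = "mapping_matrix")
}

#' Per-cluster spatial probability
#'
#' Sums the mapping rows of each cluster's cells and renormalises so every
#' cluster row sums to 1 — the spatial probability profile of the cluster.
#'
#' @param mapping A [fit_mapping()] result.
#' @param cell_clusters Named vector, cluster label per cell id.
#' @return Cluster x spot matrix with unit row sums (empty clusters get a
#'   zero row with a warning).
#' @export
cluster_spot_probability <- function(mapping, cell_clusters) {
  M <- mapping$M
  lab <- cell_clusters[rownames(M)]
  if (any(is.na(lab))) stop("every cell must carry a cluster label")
  clusters <- sort(unique(as.character(cell_clusters)))
  P <- matrix(0, length(clusters), ncol(M),
              dimnames = list(clusters, colnames(M)))
  for (cl in clusters) {
    rows <- which(lab == cl)
    if (!length(rows)) {
      warning("cluster '", cl, "' has no cells; zero row")
      next
    }
    s <- colSums(M[rows, , drop = FALSE])
    P[cl, ] <- s / sum(s)
  }
  P
}

#' Deconvolve spots by greedy hard assignment under nuclei counts
#'
#' Repeatedly assigns the globally highest-probability (cell, spot) pair
#' among still-unassigned cells and spots with remaining nuclei capacity;
#' ties broken by cell id then spot id. Each cell is assigned to at most one
#' spot and each spot receives exactly its nuclei count.
#'
#' @param mapping A [fit_mapping()] result.
#' @param nuclei_counts Named integer vector, nuclei per spot (subset of the
#'   mapped spots; missing spots get 0). `sum(nuclei_counts)` must not
#'   exceed the number of cells.
#' @param cell_clusters Named vector of cluster labels per cell.
#' @return A list of class `deconvolution_result`: `assignment` (data.frame
#'   cell_id, barcode), `composition` (spot x cluster count matrix) and
#'   `nuclei`.
#' @export
deconvolve <- function(mapping, nuclei_counts, cell_clusters) {
  M <- mapping$M
  cap <- stats::setNames(rep(0L, ncol(M)), colnames(M))
  unknown <- setdiff(names(nuclei_counts), colnames(M))
  if (length(unknown)) stop("nuclei counts for unmapped spot(s): ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  cap[names(nuclei_counts)] <- as.integer(nuclei_counts)
  if (sum(cap) > nrow(M)) stop("total nuclei exceed available cells")
  ord <- order(-as.vector(M),
               rep(rownames(M), times = ncol(M)),
               rep(colnames(M), each = nrow(M)),
               method = "radix")
  cells_left <- stats::setNames(rep(TRUE, nrow(M)), rownames(M))
  assign_cell <- character(0)
  assign_spot <- character(0)
  n_needed <- sum(cap)
  ri <- ((ord - 1) %% nrow(M)) + 1
  ci <- ((ord - 1) %/% nrow(M)) + 1
  for (t in seq_along(ord)) {
    if (length(assign_cell) == n_needed) break
    i <- ri[t]; s <- ci[t]
    if (cells_left[i] && cap[s] > 0) {
      assign_cell <- c(assign_cell, rownames(M)[i])
      assign_spot <- c(assign_spot, colnames(M)[s])
      cells_left[i] <- FALSE
      cap[s] <- cap[s] - 1L
    }
  }
  clusters <- sort(unique(as.character(cell_clusters)))
  comp <- matrix(0L, ncol(M), length(clusters),
                 dimnames = list(colnames(M), clusters))
  if (length(assign_cell)) {
    lab <- as.character(cell_clusters[assign_cell])
    tab <- table(factor(assign_spot, levels = colnames(M)),
                 factor(lab, levels = clusters))
    comp <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  }
  structure(list(assignment = data.frame(cell_id = assign_cell,
                                         barcode = assign_spot,
                                         stringsAsFactors = FALSE),
                 composition = comp,
                 nuclei = stats::setNames(as.integer(nuclei_counts),
                                          names(nuclei_counts))),
            class = "deconvolution_result")
}

#' Radial cluster-abundance profiles
#'
#' Mean per-cluster spatial probability over the spots of each concentric
#' ring, rows ordered by average-linkage hierarchical clustering on
#' correlation distance (clusters with similar radial localisation end up
#' adjacent).
#'
#' @param P Cluster x spot probability matrix
#'   ([cluster_spot_probability()]).
#' @param bins A [assign_concentric_bins()] result on the same spots.
#' @return Cluster x bin matrix (columns `bin1..binB`, `NA` for empty bins),
#'   rows in dendrogram leaf order; the `hclust` object is attached as
#'   attribute `"hclust"`.
#' @export
radial_cluster_profiles <- function(P, bins) {
  B <- bins$params$n_bins
  b <- bins$bins[colnames(P)]
  prof <- matrix(NA_real_, nrow(P), B,
                 dimnames = list(rownames(P), paste0("bin", seq_len(B))))
  for (k in seq_len(B)) {
    sel <- which(!is.na(b) & b == k)
    if (length(sel)) {
      prof[, k] <- rowMeans(P[, sel, drop = FALSE])
    } else {
      warning("bin ", k, " is empty; NA column")
    }
  }
  if (nrow(prof) > 2) {
    cc <- suppressWarnings(stats::cor(t(prof[, colSums(!is.na(prof)) > 0,
                                             drop = FALSE])))
    cc[!is.finite(cc)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    prof <- prof[hc$order, , drop = FALSE]
    attr(prof, "hclust") <- hc
  }
  prof
}
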