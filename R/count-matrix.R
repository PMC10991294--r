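#' Gene-by-observation count matrix with observation metadata
#'
#' `count_matrix` is the central container of the package: a sparse
#' gene x observation matrix (genes in rows) together with per-observation
#' metadata and a layer flag recording whether the values are raw integer
#' counts or log-normalised expression.
#'
#' @param values A matrix or sparse `Matrix` with genes in rows and
#'   observations (spots or cells) in columns. Dimnames, when present, must
#'   agree with `gene_ids` / `obs_ids`.
#' @param gene_ids Character vector of unique gene identifiers (symbols).
#' @param obs_ids Character vector of unique observation identifiers
#'   (barcodes).
#' @param obs_meta Optional `data.frame` of per-observation fields (e.g.
#'   `sample`, `condition`, `batch`, `cluster`), one row per observation.
#' @param layer Either `"raw"` (nonnegative integers) or `"normalized_log"`.
#'
#' @return An object of class `count_matrix` with elements `values`
#'   (a `dgCMatrix`), `obs_meta` and `layer`.
#' @examples
#' m <- count_matrix(matrix(0:5, nrow = 3), gene_ids = c("a", "b", "c"),
#'                   obs_ids = c("s1", "s2"))
#' dim(m)
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         obs_ids = colnames(values), obs_meta = NULL,
                         layer = c("raw", "normalized_log")) {
  layer <- match.arg(layer)
  if (is.null(gene_ids) || is.null(obs_ids)) {
    stop("gene_ids and obs_ids are required (or supply dimnames)")
  }
  gene_ids <- as.character(gene_ids)
  obs_ids <- as.character(obs_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(obs_ids)) stop("duplicate obs_ids")
  v <- methods::as(methods::as(methods::as(values, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(v) != length(gene_ids) || ncol(v) != length(obs_ids)) {
    stop("dimensions of values do not match gene_ids/obs_ids")
  }
  dimnames(v) <- list(gene_ids, obs_ids)
  if (layer == "raw") {
    x <- v@x
    if (any(x < 0) || any(x != trunc(x))) {
      stop("raw layer must contain nonnegative integers")
    }
  }
  if (is.null(obs_meta)) {
    obs_meta <- data.frame(row.names = obs_ids)
  } else {
    obs_meta <- as.data.frame(obs_meta)
    if (nrow(obs_meta) != length(obs_ids)) {
      stop("obs_meta must have one row per observation")
    }
    rownames(obs_meta) <- obs_ids
  }
  structure(list(values = v, obs_meta = obs_meta, layer = layer),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d observations, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  if (ncol(x$obs_meta) > 0) {
    cat("  obs_meta:", paste(colnames(x$obs_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a count matrix
#'
#' @param x A [count_matrix()].
#' @param genes,obs Index vectors (names, integers or logical) over genes and
#'   observations; missing means keep all.
#' @param ... Unused.
#' @return A `count_matrix` restricted to the requested genes/observations;
#'   `obs_meta` is subset in step.
#' @export
`[.count_matrix` <- function(x, genes, obs, ...) {
  v <- x$values
  if (!missing(genes)) v <- v[genes, , drop = FALSE]
  if (!missing(obs)) v <- v[, obs, drop = FALSE]
  meta <- x$obs_meta[colnames(v), , drop = FALSE]
  count_matrix(v, rownames(v), colnames(v), meta, layer = x$layer)
}

gene_ids <- function(x) rownames(x$values)
obs_ids <- function(x) colnames(x$values)

stopifnot_raw <- function(x, what) {
  if (x$layer != "raw") stop(what, " requires the raw count layer")
}
stopifnot_norm <- function(x, what) {
  if (x$layer != "normalized_log") stop(what, " requires the normalized_log layer")
}
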