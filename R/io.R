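#' Read a 10x-style MatrixMarket count triplet
#'
#' Reads a sparse gene x observation count matrix from a MatrixMarket
#' coordinate file plus line-aligned feature and barcode tables, the layout
#' produced by the common droplet/array pipelines.
#'
#' @param matrix_path Path to the `.mtx` coordinate file. Raw counts must use
#'   the "coordinate integer" (or all-integer real) dialect.
#' @param features_path Path to a headerless TSV whose first column is the
#'   gene identifier, one line per matrix row.
#' @param barcodes_path Path to a headerless TSV whose first column is the
#'   observation barcode, one line per matrix column.
#' @param obs_meta Optional data.frame of per-observation metadata.
#' @return A [count_matrix()] with `layer = "raw"`.
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path,
                        obs_meta = NULL) {
  m <- Matrix::readMM(matrix_path)
  feats <- utils::read.delim(features_path, header = FALSE,
                             colClasses = "character")[[1]]
  bcs <- utils::read.delim(barcodes_path, header = FALSE,
                           colClasses = "character")[[1]]
  if (nrow(m) != length(feats) || ncol(m) != length(bcs)) {
    stop(sprintf("matrix is %d x %d but %d features / %d barcodes supplied",
                 nrow(m), ncol(m), length(feats), length(bcs)))
  }
  count_matrix(m, feats, bcs, obs_meta = obs_meta, layer = "raw")
}

#' Write a count matrix as MatrixMarket triplet plus feature/barcode tables
#'
#' @param x A [count_matrix()].
#' @param dir Output directory; created if missing. Files `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv` are written (raw counts as coordinate
#'   integer, normalised values as coordinate real).
#' @return Invisibly, the directory.
#' @export
write_counts <- function(x, dir) {
  if (!inherits(x, "count_matrix")) stop("x must be a count_matrix")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- x$values
  if (x$layer == "raw") {
    # Matrix::writeMM always emits "real"; rewrite header + integer entries
    # so raw counts round-trip through the coordinate-integer dialect.
    tm <- methods::as(v, "TsparseMatrix")
    o <- order(tm@j, tm@i)
    con <- file(file.path(dir, "matrix.mtx"), "w")
    writeLines("%%MatrixMarket matrix coordinate integer general", con)
    writeLines(sprintf("%d %d %d", nrow(v), ncol(v), length(tm@x)), con)
    writeLines(sprintf("%d %d %d", tm@i[o] + 1L, tm@j[o] + 1L,
                       as.integer(tm@x[o])), con)
    close(con)
  } else {
    Matrix::writeMM(v, file.path(dir, "matrix.mtx"))
  }
  writeLines(rownames(v), file.path(dir, "features.tsv"))
  writeLines(colnames(v), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a Visium-style tissue positions table
#'
#' Expects the standard columns `barcode`, `in_tissue`, `array_row`,
#' `array_col`, `pxl_row_in_fullres`, `pxl_col_in_fullres` (with or without a
#' header line). Pixel coordinates are converted to micrometers at read time;
#' all downstream geometry is in micrometers.
#'
#' @param path CSV path.
#' @param um_per_px Scale factor, micrometers per full-resolution pixel
#'   (default 1, i.e. coordinates already in micrometers). Must be > 0.
#' @param filter_in_tissue If `TRUE` (default) keep only `in_tissue == 1`
#'   rows; otherwise all rows are kept and the flag preserved.
#' @return A data.frame (class `spot_table`) with columns `barcode`, `x_um`,
#'   `y_um`, `in_tissue` and (if present in the file or added later)
#'   `cluster`.
#' @export
read_spot_positions <- function(path, um_per_px = 1, filter_in_tissue = TRUE) {
  if (!is.numeric(um_per_px) || length(um_per_px) != 1 || um_per_px <= 0) {
    stop("um_per_px must be a single positive number")
  }
  first <- readLines(path, n = 1)
  has_header <- grepl("barcode", first, fixed = TRUE)
  cols <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) < length(cols)) stop("tissue positions file needs columns: ",
                                      paste(cols, collapse = ", "))
    colnames(df)[seq_along(cols)] <- cols
  }
  missing_cols <- setdiff(cols, colnames(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    barcode = as.character(df$barcode),
    x_um = df$pxl_col_in_fullres * um_per_px,
    y_um = df$pxl_row_in_fullres * um_per_px,
    in_tissue = as.logical(df$in_tissue == 1),
    stringsAsFactors = FALSE
  )
  if ("cluster" %in% colnames(df)) out$cluster <- as.character(df$cluster)
  if (filter_in_tissue) out <- out[out$in_tissue, , drop = FALSE]
  if (anyDuplicated(out$barcode)) stop("duplicate barcodes in positions file")
  if (!all(is.finite(out$x_um)) || !all(is.finite(out$y_um))) {
    stop("non-finite spot coordinates")
  }
  rownames(out) <- NULL
  class(out) <- c("spot_table", "data.frame")
  out
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' member genes within a set are deduplicated with a warning.
#'
#' @param path GMT path.
#' @return A named list of gene sets, each a list with `name`, `description`
#'   and `members` (unique character vector).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields: ", ln)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("gene set '%s': duplicate members deduplicated", f[1]))
      members <- unique(members)
    }
    list(name = f[1], description = f[2], members = members)
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#' @param sets List of gene sets as returned by [read_gene_sets()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write records as a deterministic TSV
#'
#' Writes a data.frame as UTF-8 TSV with header. Rows are stably sorted on
#' `sort_keys` so repeated runs of a seeded pipeline produce byte-identical
#' files. Non-finite numerics are written as `NA`.
#'
#' @param records A data.frame of homogeneous records.
#' @param path Output path.
#' @param sort_keys Character vector of column names to stable-sort on
#'   (default none: input order kept).
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path, sort_keys = character()) {
  records <- as.data.frame(records)
  bad <- vapply(records, function(col) is.list(col) || is.function(col),
                logical(1))
  if (any(bad)) {
    stop("unserializable column(s): ",
         paste(colnames(records)[bad], collapse = ", "))
  }
  if (length(sort_keys)) {
    missing_keys <- setdiff(sort_keys, colnames(records))
    if (length(missing_keys)) stop("unknown sort key(s): ",
                                   paste(missing_keys, collapse = ", "))
    ord <- do.call(order, c(unname(records[sort_keys]),
                            list(method = "radix")))
    records <- records[ord, , drop = FALSE]
  }
  num <- vapply(records, is.numeric, logical(1))
  for (j in which(num)) {
    col <- records[[j]]
    col[!is.finite(col)] <- NA
    records[[j]] <- col
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a flat key/value config file
#'
#' Minimal YAML-style `key: value` reader for pipeline configuration (paths,
#' scale factor, seeds). Comments (`#`) and blank lines are ignored; values
#' that parse as numbers are returned numeric. Nested structure is not
#' supported.
#'
#' @param path Config path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln)
    key <- trimws(m[2])
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num) && nzchar(val)) num else val
  }
  out
}
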