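#' Radial template model functions
#'
#' Returns the continuous form of a named template model on the normalised
#' boundary distance x in `[0, 1]`. Descending models (enriched at the
#' lesion core): `linear_descending` 1 - x; `immediate_descending`
#' (1 - x)^4; `late_descending` 1 - x^4; `abrupt_descending` a logistic drop
#' at x = 0.5 with slope 0.05. Each ascending model is 1 minus its
#' descending mirror.
#'
#' @param name Template name.
#' @return A function of x.
#' @keywords internal
template_fun <- function(name) {
  base <- switch(sub("_(de|a)scending$", "", name),
    linear = function(x) 1 - x,
    immediate = function(x) (1 - x)^4,
    late = function(x) 1 - x^4,
    abrupt = function(x) 1 / (1 + exp((x - 0.5) / 0.05)),
    stop("unknown template model: ", name)
  )
  if (grepl("_ascending$", name)) function(x) 1 - base(x) else base
}

template_names <- function() {
  as.vector(outer(c("abrupt", "immediate", "late", "linear"),
                  c("ascending", "descending"), paste, sep = "_"))
}

#' Build the template library at bin centres
#'
#' Evaluates the eight template models at the bin centres
#' `x_k = (k - 1/2) / B`, k = 1..B.
#'
#' @param B Number of concentric bins (>= 4; default 13).
#' @return A named list of class `template_library`: numeric vectors of
#'   length `B` with values in `[0, 1]`.
#' @export
build_templates <- function(B = 13) {
  if (!is.numeric(B) || B < 4) stop("B must be >= 4")
  B <- as.integer(B)
  x <- (seq_len(B) - 0.5) / B
  lib <- lapply(template_names(), function(m) template_fun(m)(x))
  names(lib) <- template_names()
  structure(lib, class = "template_library", n_bins = B)
}

#' Annotate a lesion core
#'
#' @param lesion_id Identifier string.
#' @param center `(x, y)` in micrometers (circle geometry).
#' @param radius_um Core radius r0 > 0 (circle geometry).
#' @param polygon Alternatively, a two-column matrix of vertex coordinates
#'   (um) describing a simple polygon.
#' @return A list of class `lesion_annotation`.
#' @export
lesion_annotation <- function(lesion_id, center = NULL, radius_um = NULL,
                              polygon = NULL) {
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2 || nrow(polygon) < 3) {
      stop("polygon needs >= 3 (x, y) vertices")
    }
    if (polygon_self_intersects(polygon)) stop("polygon self-intersects")
    geom <- list(type = "polygon", vertices = polygon)
  } else {
    if (is.null(center) || is.null(radius_um)) {
      stop("supply center + radius_um, or polygon")
    }
    if (radius_um <= 0) stop("radius_um must be > 0")
    geom <- list(type = "circle", center = as.numeric(center),
                 radius_um = as.numeric(radius_um))
  }
  structure(list(lesion_id = as.character(lesion_id), geometry = geom),
            class = "lesion_annotation")
}

# segment intersection test for the polygon-simplicity check
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  for (a in seq_len(n - 2)) {
    for (b in seq(a + 2, n)) {
      if (a == 1 && b == n) next  # adjacent via wraparound
      if (segments_cross(v[idx[a, 1], ], v[idx[a, 2], ],
                         v[idx[b, 1], ], v[idx[b, 2], ])) return(TRUE)
    }
  }
  FALSE
}

point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

dist_to_segment <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  t <- if (len2 == 0) 0 else
    pmin(1, pmax(0, ((px - a[1]) * abx + (py - a[2]) * aby) / len2))
  sqrt((a[1] + t * abx - px)^2 + (a[2] + t * aby - py)^2)
}

#' Boundary distance of points to a lesion annotation
#'
#' Zero inside (or on) the geometry, Euclidean distance to the geometry
#' boundary outside.
#'
#' @param x,y Point coordinates (um).
#' @param lesion A [lesion_annotation()].
#' @return Numeric vector of distances (um).
#' @export
boundary_distance <- function(x, y, lesion) {
  g <- lesion$geometry
  if (g$type == "circle") {
    pmax(0, sqrt((x - g$center[1])^2 + (y - g$center[2])^2) - g$radius_um)
  } else {
    v <- g$vertices
    n <- nrow(v)
    dmin <- rep(Inf, length(x))
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      dmin <- pmin(dmin, dist_to_segment(x, y, v[i, ], v[j, ]))
    }
    dmin[point_in_polygon(x, y, v)] <- 0
    dmin
  }
}

#' Bin spots into concentric circles around a lesion
#'
#' Bin 0 is the annotation interior (boundary distance 0); bin k >= 1 holds
#' spots with boundary distance in `((k-1) w, k w]` (upper edge inclusive).
#' Spots beyond `B * w` or in excluded clusters are unassigned (`NA`).
#'
#' @param spots A spot table ([read_spot_positions()]) with `barcode`,
#'   `x_um`, `y_um` and, if exclusions are requested, `cluster`.
#' @param lesion A [lesion_annotation()].
#' @param binwidth_um Ring width w in micrometers (default 95).
#' @param n_bins Number of rings B (default 13).
#' @param exclude_clusters Cluster labels whose spots are unassigned.
#' @return A list of class `bin_assignment`: `bins` (named integer vector,
#'   `NA` = unassigned), `dist_um`, and the parameters.
#' @export
assign_concentric_bins <- function(spots, lesion, binwidth_um = 95,
                                   n_bins = 13,
                                   exclude_clusters = character()) {
  stopifnot(binwidth_um > 0, n_bins >= 1)
  if (length(exclude_clusters) && is.null(spots$cluster)) {
    stop("cluster exclusions requested but spots carry no cluster labels")
  }
  d <- boundary_distance(spots$x_um, spots$y_um, lesion)
  span <- n_bins * binwidth_um
  k <- as.integer(ceiling(d / binwidth_um))
  # enforce d in ((k-1) w, k w] exactly against floating-point edge effects
  k <- ifelse(d <= (k - 1) * binwidth_um, k - 1L, k)
  k <- ifelse(d > k * binwidth_um, k + 1L, k)
  bins <- ifelse(d == 0, 0L, ifelse(d > span, NA_integer_, k))
  if (length(exclude_clusters)) {
    bins[spots$cluster %in% exclude_clusters] <- NA_integer_
  }
  names(bins) <- spots$barcode
  names(d) <- spots$barcode
  if (!any(bins == 0L, na.rm = TRUE)) {
    warning("no spot inside the lesion annotation (bin 0 empty)")
  }
  if (!any(!is.na(bins))) stop("zero spots assigned to any bin")
  structure(list(bins = bins, dist_um = d,
                 params = list(binwidth_um = binwidth_um, n_bins = n_bins,
                               exclude_clusters = exclude_clusters,
                               lesion_id = lesion$lesion_id)),
            class = "bin_assignment")
}

#' Bin-wise mean expression profiles of genes or gene sets
#'
#' For each feature, the mean normalised expression over the spots of each
#' ring 1..B (bin 0, the core interior, is excluded by default). A gene-set
#' feature's per-spot value is the mean over its member genes. Profiles are
#' min-max scaled; constant profiles are flagged and later excluded from
#' screening.
#'
#' @param norm Log-normalised [count_matrix()] of spots.
#' @param bins A [assign_concentric_bins()] result on the same barcodes.
#' @param features Character vector of gene ids, and/or a named list of gene
#'   sets (each a character vector or a `members` list). Default: all genes.
#' @param include_core If `TRUE`, bin 0 is prepended to the profile (not
#'   used by screening).
#' @return A data.frame of class `gradient_profiles`: one row per feature
#'   with `feature`, `kind` ("gene"/"gene_set"), `constant` flag,
#'   `incomplete` flag and matrix columns `profile` and `scaled` (length-B
#'   rows).
#' @export
compute_profiles <- function(norm, bins, features = NULL,
                             include_core = FALSE) {
  stopifnot_norm(norm, "compute_profiles")
  B <- bins$params$n_bins
  b <- bins$bins[colnames(norm$values)]
  if (any(is.na(names(b)))) stop("bins do not cover the expression barcodes")
  if (is.null(features)) features <- rownames(norm$values)
  if (is.character(features)) {
    feat_list <- stats::setNames(as.list(features), features)
    kinds <- rep("gene", length(features))
  } else {
    feat_list <- lapply(features, function(f) {
      if (is.list(f)) f$members else f
    })
    if (is.null(names(feat_list)) || any(!nzchar(names(feat_list)))) {
      stop("gene-set features must be named")
    }
    kinds <- rep("gene_set", length(feat_list))
  }
  ks <- if (include_core) 0:B else 1:B
  spot_sets <- lapply(ks, function(k) which(!is.na(b) & b == k))
  prof <- matrix(NA_real_, length(feat_list), length(ks),
                 dimnames = list(names(feat_list), paste0("bin", ks)))
  v <- norm$values
  for (i in seq_along(feat_list)) {
    members <- intersect(feat_list[[i]], rownames(v))
    if (!length(members)) next
    spot_val <- if (length(members) == 1) v[members, ] else
      Matrix::colMeans(v[members, , drop = FALSE])
    prof[i, ] <- vapply(spot_sets, function(s) {
      if (length(s)) mean(spot_val[s]) else NA_real_
    }, numeric(1))
  }
  rng <- t(apply(prof, 1, function(p) {
    if (all(is.na(p))) c(NA_real_, NA_real_) else range(p, na.rm = TRUE)
  }))
  constant <- !is.finite(rng[, 1]) | !is.finite(rng[, 2]) |
    rng[, 2] == rng[, 1]
  scaled <- (prof - rng[, 1]) / ifelse(constant, 1, rng[, 2] - rng[, 1])
  incomplete <- apply(prof, 1, anyNA)
  out <- data.frame(feature = names(feat_list), kind = kinds,
                    constant = constant, incomplete = incomplete,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$profile <- prof
  out$scaled <- scaled
  attr(out, "n_bins") <- B
  attr(out, "include_core") <- include_core
  attr(out, "lesion_id") <- bins$params$lesion_id
  class(out) <- c("gradient_profiles", "data.frame")
  out
}

#' Screen radial profiles against template models
#'
#' Pearson correlation of each feature's min-max-scaled ring profile (bins
#' 1..B) with every template; a one-sided p-value for r > 0 from
#' `t = r sqrt((B - 2) / (1 - r^2))` with `B - 2` degrees of freedom. The
#' best model is the argmax of r (ties alphabetical). Genes with raw total
#' counts not exceeding `min_total_counts` are omitted (gene sets are
#' exempt).
#'
#' @param profiles A [compute_profiles()] result.
#' @param templates A [build_templates()] library on the same B.
#' @param min_total_counts Strict lower bound on raw per-gene totals
#'   (default 50, i.e. "> 50 counts"). Requires `raw_totals`.
#' @param raw_totals Named numeric vector of raw per-gene totals (from the
#'   unnormalised matrix); only needed when filtering genes.
#' @return A data.frame of class `screening_result`: `feature`, `kind`,
#'   `lesion_id`, `best_model`, `r`, `p_value`, plus per-model columns
#'   `r.<model>` and `p.<model>`, sorted ascending by `p_value`.
#' @export
screen_profiles <- function(profiles, templates, min_total_counts = 50,
                            raw_totals = NULL) {
  B <- attr(profiles, "n_bins")
  if (attr(templates, "n_bins") != B) {
    stop("profile length does not match template library")
  }
  keep <- !profiles$constant & !profiles$incomplete
  if (!is.null(min_total_counts) && any(profiles$kind == "gene")) {
    if (is.null(raw_totals)) {
      stop("raw_totals required to apply the total-count filter to genes")
    }
    totals <- raw_totals[profiles$feature]
    keep <- keep & (profiles$kind != "gene" |
                      (!is.na(totals) & totals > min_total_counts))
  }
  pf <- profiles[keep, , drop = FALSE]
  sc <- pf$scaled
  if (attr(profiles, "include_core")) sc <- sc[, -1, drop = FALSE]
  mods <- names(templates)
  rmat <- matrix(NA_real_, nrow(pf), length(mods),
                 dimnames = list(NULL, mods))
  for (m in mods) {
    tv <- templates[[m]]
    rmat[, m] <- apply(sc, 1, function(y) {
      if (stats::sd(y) == 0 || stats::sd(tv) == 0) return(NA_real_)
      stats::cor(y, tv)
    })
  }
  tstat <- rmat * sqrt((B - 2) / pmax(1 - rmat^2, .Machine$double.eps))
  pmat <- stats::pt(tstat, df = B - 2, lower.tail = FALSE)
  pmat <- pmin(pmax(pmat, .Machine$double.xmin), 1)
  best_idx <- apply(rmat, 1, function(r) {
    # argmax r, ties by alphabetical model name (mods is sorted)
    which(r == max(r, na.rm = TRUE))[1]
  })
  out <- data.frame(feature = pf$feature, kind = pf$kind,
                    lesion_id = attr(profiles, "lesion_id"),
                    best_model = mods[best_idx],
                    r = rmat[cbind(seq_len(nrow(pf)), best_idx)],
                    p_value = pmat[cbind(seq_len(nrow(pf)), best_idx)],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$r_all <- rmat
  out$p_all <- pmat
  out$profile <- pf$profile
  out <- out[order(out$p_value, out$feature, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_bins") <- B
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Merge screening results across lesions
#'
#' The merged profile is the bin-wise mean of the per-lesion ring means; for
#' each template the per-lesion correlations and p-values are averaged
#' (`p_value_mean`). The reported best model is the argmax of the mean r;
#' output is sorted ascending by `p_value_mean`.
#'
#' @param results List of [screen_profiles()] results with identical B and
#'   template sets (one per lesion).
#' @return A `screening_result`-like data.frame with `p_value_mean`, mean
#'   `r`, the merged profile, and an optional Benjamini-Hochberg column
#'   `padj` over `p_value_mean`.
#' @export
merge_lesions <- function(results) {
  if (!length(results)) stop("need at least one lesion result")
  if (length(results) == 1) {
    out <- results[[1]]
    out$p_value_mean <- out$p_value
    out$padj <- stats::p.adjust(out$p_value_mean, method = "BH")
    return(out)
  }
  Bs <- vapply(results, attr, 1, which = "n_bins")
  if (length(unique(Bs)) != 1) stop("mismatched bin counts across lesions")
  feats <- Reduce(intersect, lapply(results, `[[`, "feature"))
  mods <- colnames(results[[1]]$r_all)
  rs <- lapply(results, function(x) {
    x$r_all[match(feats, x$feature), , drop = FALSE]
  })
  ps <- lapply(results, function(x) {
    x$p_all[match(feats, x$feature), , drop = FALSE]
  })
  profs <- lapply(results, function(x) {
    x$profile[match(feats, x$feature), , drop = FALSE]
  })
  r_mean <- Reduce(`+`, rs) / length(rs)
  p_mean <- Reduce(`+`, ps) / length(ps)
  prof_mean <- Reduce(`+`, profs) / length(profs)
  best_idx <- apply(r_mean, 1, function(r) {
    which(r == max(r, na.rm = TRUE))[1]
  })
  i1 <- match(feats, results[[1]]$feature)
  out <- data.frame(feature = feats, kind = results[[1]]$kind[i1],
                    lesion_id = "merged",
                    best_model = mods[best_idx],
                    r = r_mean[cbind(seq_along(feats), best_idx)],
                    p_value_mean = p_mean[cbind(seq_along(feats), best_idx)],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$r_all <- r_mean
  out$p_all <- p_mean
  out$profile <- prof_mean
  out$padj <- stats::p.adjust(out$p_value_mean, method = "BH")
  out <- out[order(out$p_value_mean, out$feature, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_bins") <- Bs[1]
  class(out) <- c("screening_result", "data.frame")
  out
}
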