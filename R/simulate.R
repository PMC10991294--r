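#' Configuration for the spatial lesion simulator
#'
#' The defaults describe a Visium-like capture area with a single circular
#' lesion: a 40 x 40 square lattice at 100 um pitch (1600 spots), a lesion
#' core of radius 200 um at the centre, 1-10 cells per spot, and negative
#' binomial counts. Radial structure is planted per descending template model
#' (100 genes each at amplitude 2 by default), with the remaining genes
#' spatially flat.
#'
#' @param n_side Spots per lattice side (square grid) — `n_side^2` spots.
#' @param pitch_um Centre-to-centre spot spacing in micrometers.
#' @param hex If `TRUE`, offset alternate rows by half a pitch (hexagonal
#'   packing); default square lattice.
#' @param lesion_center Numeric `(x, y)` in micrometers; default grid centre.
#' @param core_radius_um Lesion core radius r0 in micrometers.
#' @param n_genes Total number of genes.
#' @param n_gradient_genes Named integer vector: planted genes per template
#'   model (any template name from [build_templates()]).
#' @param amplitude Fold-increase amplitude a of planted gradients: the NB
#'   mean at normalised boundary distance x is `mu * (1 + a * f(x))`.
#' @param baseline_meanlog,baseline_sdlog Log-normal law for per-gene
#'   baseline means `mu_g`.
#' @param dispersion NB dispersion theta (per single cell); variance is
#'   `mu + mu^2/theta`.
#' @param cells_per_spot Integer range, cells captured per spot (1-10).
#' @param libsize_sdlog Log-normal sd of the per-spot library-size factor.
#' @param n_bins,binwidth_um Geometry used to normalise boundary distance:
#'   `x = clamp(d / (n_bins * binwidth), 0, 1)`, matching the screening
#'   defaults (13 bins of 95 um).
#' @param seed Integer seed fixing all draws.
#' @return A list of class `spatial_sim_config`.
#' @export
spatial_sim_config <- function(n_side = 40, pitch_um = 100, hex = FALSE,
                               lesion_center = NULL, core_radius_um = 200,
                               n_genes = 4000,
                               n_gradient_genes = NULL,
                               amplitude = 2,
                               baseline_meanlog = log(5), baseline_sdlog = 1,
                               dispersion = 10,
                               cells_per_spot = c(1L, 10L),
                               libsize_sdlog = 0.15,
                               n_bins = 13, binwidth_um = 95,
                               seed = 1L) {
  if (is.null(n_gradient_genes)) {
    # planted genes stay a ~10% minority of the transcriptome (100 per
    # descending template at the 4000-gene default)
    per <- min(100L, n_genes %/% 40L)
    n_gradient_genes <- c(linear_descending = per, immediate_descending = per,
                          abrupt_descending = per, late_descending = per)
  }
  stopifnot(n_side >= 2, pitch_um > 0, core_radius_um > 0, n_genes >= 1,
            all(n_gradient_genes >= 0), amplitude >= 0, dispersion > 0,
            length(cells_per_spot) == 2, cells_per_spot[1] >= 1,
            cells_per_spot[1] <= cells_per_spot[2])
  if (sum(n_gradient_genes) > n_genes) {
    stop("more gradient genes than total genes")
  }
  extent <- (n_side - 1) * pitch_um
  if (is.null(lesion_center)) lesion_center <- c(extent / 2, extent / 2)
  if (lesion_center[1] < 0 || lesion_center[1] > extent ||
      lesion_center[2] < 0 || lesion_center[2] > extent) {
    stop("lesion centre outside the lattice")
  }
  structure(list(n_side = n_side, pitch_um = pitch_um, hex = hex,
                 lesion_center = lesion_center,
                 core_radius_um = core_radius_um, n_genes = n_genes,
                 n_gradient_genes = n_gradient_genes, amplitude = amplitude,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, dispersion = dispersion,
                 cells_per_spot = as.integer(cells_per_spot),
                 libsize_sdlog = libsize_sdlog,
                 n_bins = n_bins, binwidth_um = binwidth_um,
                 seed = as.integer(seed)),
            class = "spatial_sim_config")
}

#' Simulate a spatial transcriptomics section with a focal lesion
#'
#' Counts at each spot are the sum of its 1-10 constituent cells' negative
#' binomial draws (sum law: NB with mean and size scaled by the cell
#' number), so deconvolution truth is well defined. For a planted gene with
#' template f, the per-cell NB mean at a spot with normalised boundary
#' distance x is `mu * (1 + a * f(x))`; other genes are spatially constant.
#'
#' @param config A [spatial_sim_config()].
#' @return A list with `counts` (a raw [count_matrix()]), `spots` (a spot
#'   table with barcode, x_um, y_um, in_tissue), and `truth` — a list with
#'   `genes` (gene, template, amplitude), `spots` (barcode, boundary distance
#'   `dist_um`, normalised distance `x_norm`, true bin, `n_cells`,
#'   `lib_factor`) and the lesion geometry.
#' @export
simulate_spatial <- function(config = spatial_sim_config()) {
  stopifnot(inherits(config, "spatial_sim_config"))
  set.seed(config$seed)
  cfg <- config

  xs <- rep(seq_len(cfg$n_side) - 1, times = cfg$n_side) * cfg$pitch_um
  ys <- rep(seq_len(cfg$n_side) - 1, each = cfg$n_side) * cfg$pitch_um
  if (cfg$hex) {
    odd <- (ys / cfg$pitch_um) %% 2 == 1
    xs[odd] <- xs[odd] + cfg$pitch_um / 2
  }
  n_spots <- length(xs)
  barcodes <- sprintf("SPOT_%04d", seq_len(n_spots))

  d_center <- sqrt((xs - cfg$lesion_center[1])^2 +
                   (ys - cfg$lesion_center[2])^2)
  dist_um <- pmax(0, d_center - cfg$core_radius_um)
  span <- cfg$n_bins * cfg$binwidth_um
  x_norm <- pmin(pmax(dist_um / span, 0), 1)
  bin_true <- ifelse(d_center <= cfg$core_radius_um, 0L,
                     ifelse(dist_um > span, NA_integer_,
                            as.integer(ceiling(dist_um / cfg$binwidth_um))))

  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  mu <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  template <- rep(NA_character_, cfg$n_genes)
  idx <- 0
  for (m in names(cfg$n_gradient_genes)) {
    k <- cfg$n_gradient_genes[[m]]
    if (k > 0) {
      template[idx + seq_len(k)] <- m
      idx <- idx + k
    }
  }
  amp <- ifelse(is.na(template), 0, cfg$amplitude)

  n_cells <- sample(seq(cfg$cells_per_spot[1], cfg$cells_per_spot[2]),
                    n_spots, replace = TRUE)
  lib <- stats::rlnorm(n_spots, 0, cfg$libsize_sdlog)

  # spot-level spatial factor per gene: rows genes, cols spots
  counts <- matrix(0L, cfg$n_genes, n_spots)
  for (g in seq_len(cfg$n_genes)) {
    f <- if (is.na(template[g])) rep(0, n_spots)
         else template_fun(template[g])(x_norm)
    mean_cell <- mu[g] * (1 + amp[g] * f) * lib
    counts[g, ] <- stats::rnbinom(n_spots, mu = mean_cell * n_cells,
                                  size = cfg$dispersion * n_cells)
  }
  dimnames(counts) <- list(genes, barcodes)

  spots <- data.frame(barcode = barcodes, x_um = xs, y_um = ys,
                      in_tissue = TRUE, stringsAsFactors = FALSE)
  class(spots) <- c("spot_table", "data.frame")

  cm <- count_matrix(counts, genes, barcodes, layer = "raw")
  truth <- list(
    genes = data.frame(gene = genes, template = template, amplitude = amp,
                       baseline_mean = mu, stringsAsFactors = FALSE),
    spots = data.frame(barcode = barcodes, dist_um = dist_um,
                       x_norm = x_norm, bin_true = bin_true,
                       n_cells = n_cells, lib_factor = lib,
                       stringsAsFactors = FALSE),
    lesion = list(center = cfg$lesion_center,
                  radius_um = cfg$core_radius_um)
  )
  list(counts = cm, spots = spots, truth = truth)
}

#' Configuration for the single-cell injury simulator
#'
#' Emulates a droplet scRNA-seq experiment on an injured cortex: cell-type
#' clusters with identity markers, injury-restricted reactive subpopulations
#' of the three glial types that share a planted inflammatory program on top
#' of a type-specific reactivity program, a proliferation program expressed
#' by a fraction of reactive cells, and batch structure as per-batch
#' multiplicative gene factors.
#'
#' @param cell_types Character vector of types; the first `n_reactive_types`
#'   get a reactive state in the injured condition.
#' @param n_reactive_types How many leading types are reactive glia.
#' @param n_per_group Cells per (type, state, condition, batch) combination.
#' @param conditions Length-2: intact then injured condition label.
#' @param batches Batch labels.
#' @param n_genes Total genes.
#' @param n_shared,n_prolif,n_react_per_type,n_identity_per_type Program
#'   sizes (disjoint gene blocks).
#' @param lfc_shared,lfc_react,lfc_prolif,lfc_identity log2 fold changes of
#'   the planted programs.
#' @param prolif_fraction Fraction of reactive cells expressing the
#'   proliferation program.
#' @param baseline_meanlog,baseline_sdlog Log-normal law for baseline means.
#' @param dispersion NB dispersion theta.
#' @param libsize_sdlog Log-normal sd of per-cell library factors.
#' @param batch_sdlog Log-normal sd of per-(batch, gene) factors; the first
#'   batch is the reference (factor 1). `0` disables batch effects.
#' @param seed Integer seed.
#' @return A list of class `sc_sim_config`.
#' @export
sc_sim_config <- function(cell_types = c("astro", "micro", "opc", "neuron"),
                          n_reactive_types = 3,
                          n_per_group = 100,
                          conditions = c("INT", "CTRL_3dpi"),
                          batches = c("b1", "b2"),
                          n_genes = 2000,
                          n_shared = 50, n_prolif = 30,
                          n_react_per_type = 40, n_identity_per_type = 50,
                          lfc_shared = 2, lfc_react = 2, lfc_prolif = 2,
                          lfc_identity = 3,
                          prolif_fraction = 0.3,
                          baseline_meanlog = log(0.5), baseline_sdlog = 1.2,
                          dispersion = 2, libsize_sdlog = 0.2,
                          batch_sdlog = 0.1,
                          seed = 1L) {
  stopifnot(length(cell_types) >= n_reactive_types, n_reactive_types >= 1,
            n_per_group >= 2, length(conditions) == 2, length(batches) >= 1,
            dispersion > 0, prolif_fraction >= 0, prolif_fraction <= 1)
  n_program <- n_shared + n_prolif +
    n_reactive_types * n_react_per_type +
    length(cell_types) * n_identity_per_type
  if (n_program > n_genes) stop("program genes exceed n_genes")
  structure(list(cell_types = cell_types,
                 n_reactive_types = n_reactive_types,
                 n_per_group = n_per_group, conditions = conditions,
                 batches = batches, n_genes = n_genes, n_shared = n_shared,
                 n_prolif = n_prolif, n_react_per_type = n_react_per_type,
                 n_identity_per_type = n_identity_per_type,
                 lfc_shared = lfc_shared, lfc_react = lfc_react,
                 lfc_prolif = lfc_prolif, lfc_identity = lfc_identity,
                 prolif_fraction = prolif_fraction,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion, libsize_sdlog = libsize_sdlog,
                 batch_sdlog = batch_sdlog, seed = as.integer(seed)),
            class = "sc_sim_config")
}

#' Simulate droplet scRNA-seq data with injury-reactive glial states
#'
#' @param config A [sc_sim_config()].
#' @return A list with `counts` (raw [count_matrix()] whose `obs_meta` holds
#'   sample/condition/batch) and `truth`: per-cell type/state/proliferation
#'   flags and the planted program gene lists (`shared_inflammatory`,
#'   `proliferation`, `reactivity` per type, `identity` per type).
#' @export
simulate_scrna <- function(config = sc_sim_config()) {
  stopifnot(inherits(config, "sc_sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  pos <- 0
  take <- function(n) {
    out <- genes[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  reactive_types <- cfg$cell_types[seq_len(cfg$n_reactive_types)]
  programs <- list(shared_inflammatory = take(cfg$n_shared),
                   proliferation = take(cfg$n_prolif))
  programs$reactivity <- stats::setNames(
    lapply(reactive_types, function(t) take(cfg$n_react_per_type)),
    reactive_types)
  programs$identity <- stats::setNames(
    lapply(cfg$cell_types, function(t) take(cfg$n_identity_per_type)),
    cfg$cell_types)

  overlap <- unlist(programs, use.names = FALSE)
  if (anyDuplicated(overlap)) stop("program gene lists overlap")

  mu <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  names(mu) <- genes

  # cell roster
  intact <- cfg$conditions[1]
  injured <- cfg$conditions[2]
  roster <- expand.grid(type = cfg$cell_types, state = "homeostatic",
                        condition = cfg$conditions, batch = cfg$batches,
                        stringsAsFactors = FALSE)
  roster <- rbind(roster,
                  expand.grid(type = reactive_types, state = "reactive",
                              condition = injured, batch = cfg$batches,
                              stringsAsFactors = FALSE))
  cells <- roster[rep(seq_len(nrow(roster)), each = cfg$n_per_group), ]
  n_cells <- nrow(cells)
  cells$cell_id <- sprintf("CELL_%05d", seq_len(n_cells))
  cells$proliferating <- cells$state == "reactive" &
    stats::runif(n_cells) < cfg$prolif_fraction
  rownames(cells) <- NULL

  lib <- stats::rlnorm(n_cells, 0, cfg$libsize_sdlog)
  batch_factor <- matrix(1, cfg$n_genes, length(cfg$batches),
                         dimnames = list(genes, cfg$batches))
  if (cfg$batch_sdlog > 0 && length(cfg$batches) > 1) {
    for (b in cfg$batches[-1]) {
      batch_factor[, b] <- stats::rlnorm(cfg$n_genes, 0, cfg$batch_sdlog)
    }
  }

  # per-gene log2 effect per (type, state, prolif) group
  counts <- matrix(0L, cfg$n_genes, n_cells,
                   dimnames = list(genes, cells$cell_id))
  grp <- interaction(cells$type, cells$state, cells$proliferating,
                     cells$batch, drop = TRUE)
  for (g_lvl in levels(grp)) {
    sel <- which(grp == g_lvl)
    type <- cells$type[sel[1]]
    state <- cells$state[sel[1]]
    prolif <- cells$proliferating[sel[1]]
    batch <- cells$batch[sel[1]]
    lfc <- stats::setNames(numeric(cfg$n_genes), genes)
    lfc[programs$identity[[type]]] <- cfg$lfc_identity
    if (state == "reactive") {
      lfc[programs$reactivity[[type]]] <-
        lfc[programs$reactivity[[type]]] + cfg$lfc_react
      lfc[programs$shared_inflammatory] <-
        lfc[programs$shared_inflammatory] + cfg$lfc_shared
      if (prolif) {
        lfc[programs$proliferation] <-
          lfc[programs$proliferation] + cfg$lfc_prolif
      }
    }
    mean_g <- mu * 2^lfc * batch_factor[, batch]
    for (i in sel) {
      counts[, i] <- stats::rnbinom(cfg$n_genes, mu = mean_g * lib[i],
                                    size = cfg$dispersion)
    }
  }

  meta <- data.frame(sample = paste(cells$condition, cells$batch, sep = "_"),
                     condition = cells$condition, batch = cells$batch,
                     stringsAsFactors = FALSE)
  cm <- count_matrix(counts, genes, cells$cell_id, obs_meta = meta,
                     layer = "raw")
  list(counts = cm,
       truth = list(cells = cells, programs = programs, baseline_mean = mu))
}

#' Mix single cells into multi-cell spots
#'
#' Builds a synthetic spot matrix as sums of 1-10 sampled cells each, with
#' full composition ground truth — the fixture for testing probabilistic
#' mapping and nuclei-count deconvolution.
#'
#' @param sc A raw [count_matrix()] of cells.
#' @param cell_clusters Named character vector, cluster per cell id.
#' @param n_spots Number of spots; total cells drawn must not exceed
#'   `ncol(sc)`.
#' @param cells_per_spot Integer range of cells per spot.
#' @param seed Integer seed.
#' @return A list with `counts` (spot [count_matrix()]), `assignment`
#'   (data.frame cell_id, barcode), `nuclei` (named per-spot cell counts) and
#'   `fractions` (spot x cluster true composition fractions).
#' @export
simulate_mixture <- function(sc, cell_clusters, n_spots = 100,
                             cells_per_spot = c(1L, 10L), seed = 1L) {
  stopifnot(inherits(sc, "count_matrix"), sc$layer == "raw")
  set.seed(as.integer(seed))
  n_per <- sample(seq(cells_per_spot[1], cells_per_spot[2]), n_spots,
                  replace = TRUE)
  if (sum(n_per) > ncol(sc$values)) {
    stop("not enough cells to fill the requested spots")
  }
  chosen <- sample(colnames(sc$values), sum(n_per))
  barcodes <- sprintf("MIX_%04d", seq_len(n_spots))
  spot_of <- rep(barcodes, times = n_per)
  agg <- Matrix::sparseMatrix(
    i = match(spot_of, barcodes), j = seq_along(chosen), x = 1,
    dims = c(n_spots, length(chosen)))
  vals <- sc$values[, chosen, drop = FALSE] %*% Matrix::t(agg)
  colnames(vals) <- barcodes
  clusters <- sort(unique(cell_clusters))
  frac <- t(vapply(barcodes, function(b) {
    cl <- cell_clusters[chosen[spot_of == b]]
    tab <- table(factor(cl, levels = clusters))
    as.numeric(tab) / length(cl)
  }, numeric(length(clusters))))
  dimnames(frac) <- list(barcodes, clusters)
  list(counts = count_matrix(vals, rownames(vals), barcodes, layer = "raw"),
       assignment = data.frame(cell_id = chosen, barcode = spot_of,
                               stringsAsFactors = FALSE),
       nuclei = stats::setNames(n_per, barcodes),
       fractions = frac)
}
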