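test_that("build_templates returns 8 length-B curves with mirror symmetry", {
  lib <- build_templates(13)
  expect_length(lib, 8)
  expect_true(all(vapply(lib, length, 1L) == 13))
  expect_true(all(unlist(lib) >= 0 & unlist(lib) <= 1))
  for (m in c("linear", "immediate", "late", "abrupt")) {
    expect_equal(lib[[paste0(m, "_ascending")]] +
                   lib[[paste0(m, "_descending")]], rep(1, 13))
    expect_true(all(diff(lib[[paste0(m, "_descending")]]) <= 0))
  }
  # bin centres: with B = 10, bin 6 sits at x = 0.55
  lib10 <- build_templates(10)
  expect_equal(lib10$linear_descending[6], 0.45)
  expect_equal(lesionscape:::template_fun("linear_descending")(0.5), 0.5)
  expect_error(build_templates(3), ">= 4")
})

test_that("lesion_annotation validates geometry", {
  expect_error(lesion_annotation("L", center = c(0, 0), radius_um = 0),
               "> 0")
  expect_error(lesion_annotation("L"), "supply")
  # bow-tie polygon self-intersects
  bad <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(lesion_annotation("L", polygon = bad), "self-intersects")
  ok <- lesion_annotation("L", polygon = rbind(c(0, 0), c(2, 0), c(2, 2),
                                               c(0, 2)))
  expect_equal(boundary_distance(c(1, 3), c(1, 1), ok), c(0, 1))
})

test_that("assign_concentric_bins follows the interval arithmetic", {
  lesion <- lesion_annotation("L", center = c(0, 0), radius_um = 50)
  spots <- data.frame(barcode = c("core", "ring1", "edge", "far", "out"),
                      x_um = c(50, 100, 50 + 95, 50 + 96, 50 + 13 * 95 + 1),
                      y_um = 0, in_tissue = TRUE)
  ba <- assign_concentric_bins(spots, lesion, binwidth_um = 95, n_bins = 13)
  expect_equal(unname(ba$bins),
               c(0L, 1L, 1L, 2L, NA))  # d = 0, 50, 95 (edge incl.), 96, 1236
  # spot with d = 1235 exactly is still bin 13
  spots2 <- data.frame(barcode = "b", x_um = 50 + 1235, y_um = 0,
                       in_tissue = TRUE)
  expect_warning(ba2 <- assign_concentric_bins(spots2, lesion), "bin 0 empty")
  expect_equal(unname(ba2$bins), 13L)
})

test_that("bin assignment matches the brute-force oracle on random spots", {
  set.seed(31)
  for (trial in 1:5) {
    cx <- runif(1, -100, 100); cy <- runif(1, -100, 100)
    r0 <- runif(1, 20, 200); w <- runif(1, 50, 120); B <- sample(4:15, 1)
    n <- 400
    x <- runif(n, -2000, 2000); y <- runif(n, -2000, 2000)
    spots <- data.frame(barcode = sprintf("s%04d", 1:n), x_um = x, y_um = y,
                        in_tissue = TRUE)
    lesion <- lesion_annotation("L", center = c(cx, cy), radius_um = r0)
    got <- suppressWarnings(
      assign_concentric_bins(spots, lesion, binwidth_um = w, n_bins = B))
    want <- vapply(seq_len(n),
                   function(i) oracle_bin(x[i], y[i], cx, cy, r0, w, B),
                   integer(1))
    expect_identical(unname(got$bins), want)
  }
})

test_that("cluster exclusions and error paths behave", {
  lesion <- lesion_annotation("L", center = c(0, 0), radius_um = 10)
  spots <- data.frame(barcode = c("a", "b"), x_um = c(5, 50), y_um = 0,
                      in_tissue = TRUE, cluster = c("I", "III"))
  ba <- assign_concentric_bins(spots, lesion, binwidth_um = 95, n_bins = 13,
                               exclude_clusters = "III")
  expect_true(is.na(ba$bins[["b"]]))
  spots$cluster <- NULL
  expect_error(assign_concentric_bins(spots, lesion,
                                      exclude_clusters = "III"),
               "no cluster labels")
  far <- data.frame(barcode = "z", x_um = 1e6, y_um = 0, in_tissue = TRUE)
  expect_error(suppressWarnings(assign_concentric_bins(far, lesion)),
               "zero spots")
})

test_that("compute_profiles averages per ring, scales, and flags constants", {
  # 3 rings, 2 spots each, engineered values
  lesion <- lesion_annotation("L", center = c(0, 0), radius_um = 10)
  d <- c(5, 5, 50, 60, 150, 160, 250, 260)
  spots <- data.frame(barcode = sprintf("s%d", 1:8), x_um = 10 + d - 10,
                      y_um = 0, in_tissue = TRUE)
  spots$x_um <- c(5, 6, 10 + 50, 10 + 60, 10 + 150, 10 + 160, 10 + 250,
                  10 + 260)
  ba <- assign_concentric_bins(spots, lesion, binwidth_um = 100, n_bins = 3)
  x <- rbind(gA = c(9, 9, 4, 6, 2, 4, 0, 2),
             gB = rep(2, 8),
             gC = c(1, 1, 3, 3, 4, 4, 8, 8))
  colnames(x) <- spots$barcode
  norm <- count_matrix(x, rownames(x), colnames(x),
                       layer = "normalized_log")
  pf <- compute_profiles(norm, ba)
  expect_equal(unname(pf$profile["gA", ]), c(5, 3, 1))  # core excluded
  expect_equal(unname(pf$scaled["gA", ]), c(1, 0.5, 0))
  expect_true(pf$constant[pf$feature == "gB"])
  # gene-set of one member identical to the gene
  pf2 <- compute_profiles(norm, ba, features = list(solo = "gA",
                                                    pair = c("gA", "gC")))
  expect_equal(unname(pf2$profile["solo", ]), c(5, 3, 1))
  expect_equal(unname(pf2$profile["pair", ]),
               c((5 + 3) / 2, (3 + 4) / 2, (1 + 8) / 2))
  # include_core prepends bin 0
  pf3 <- compute_profiles(norm, ba, include_core = TRUE)
  expect_equal(unname(pf3$profile["gA", ]), c(9, 5, 3, 1))
})

test_that("screen_profiles ranks exact template matches at r = 1", {
  B <- 13
  lib <- build_templates(B)
  prof <- matrix(lib$linear_descending, 1, B,
                 dimnames = list("gX", paste0("bin", 1:B)))
  pf <- data.frame(feature = "gX", kind = "gene", constant = FALSE,
                   incomplete = FALSE)
  pf$profile <- prof
  pf$scaled <- prof
  attr(pf, "n_bins") <- B
  attr(pf, "include_core") <- FALSE
  attr(pf, "lesion_id") <- "L"
  class(pf) <- c("gradient_profiles", "data.frame")
  res <- screen_profiles(pf, lib, min_total_counts = NULL)
  expect_equal(res$best_model, "linear_descending")
  expect_equal(res$r, 1)
  expect_lt(res$p_value, 1e-10)
})

test_that("the >50 total count filter is strict", {
  B <- 13
  lib <- build_templates(B)
  prof <- matrix(rep(lib$linear_descending, 2), 2, B, byrow = TRUE,
                 dimnames = list(c("g50", "g51"), paste0("bin", 1:B)))
  pf <- data.frame(feature = c("g50", "g51"), kind = "gene",
                   constant = FALSE, incomplete = FALSE)
  pf$profile <- prof
  pf$scaled <- prof
  attr(pf, "n_bins") <- B
  attr(pf, "include_core") <- FALSE
  attr(pf, "lesion_id") <- "L"
  class(pf) <- c("gradient_profiles", "data.frame")
  res <- screen_profiles(pf, lib, min_total_counts = 50,
                         raw_totals = c(g50 = 50, g51 = 51))
  expect_identical(res$feature, "g51")
  expect_error(screen_profiles(pf, lib, min_total_counts = 50), "raw_totals")
})

test_that("screening is invariant to affine feature rescaling", {
  set.seed(12)
  B <- 13
  lib <- build_templates(B)
  y <- lib$late_descending + rnorm(B, sd = 0.05)
  mk <- function(vals, id) {
    rng <- range(vals)
    prof <- matrix(vals, 1, B, dimnames = list(id, paste0("bin", 1:B)))
    pf <- data.frame(feature = id, kind = "gene", constant = FALSE,
                     incomplete = FALSE)
    pf$profile <- prof
    pf$scaled <- (prof - rng[1]) / diff(rng)
    attr(pf, "n_bins") <- B
    attr(pf, "include_core") <- FALSE
    attr(pf, "lesion_id") <- "L"
    class(pf) <- c("gradient_profiles", "data.frame")
    pf
  }
  r1 <- screen_profiles(mk(y, "a"), lib, min_total_counts = NULL)
  r2 <- screen_profiles(mk(3 + 10 * y, "a"), lib, min_total_counts = NULL)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_identical(r1$best_model, r2$best_model)
})

test_that("merge_lesions averages p-values and profiles as stated", {
  sim <- simulate_spatial(spatial_sim_config(
    n_side = 16, n_genes = 60,
    n_gradient_genes = c(linear_descending = 10), core_radius_um = 100,
    seed = 13))
  lesion <- lesion_annotation("L1", center = sim$truth$lesion$center,
                              radius_um = sim$truth$lesion$radius_um)
  ba <- assign_concentric_bins(sim$spots, lesion, n_bins = 6)
  norm <- normalize_log_cpm(sim$counts)
  pf <- compute_profiles(norm, ba)
  res <- screen_profiles(pf, build_templates(6),
                         raw_totals = Matrix::rowSums(sim$counts$values))
  # identical duplicate lesions == single lesion
  merged <- merge_lesions(list(res, res))
  single <- merge_lesions(list(res))
  i <- match(single$feature, merged$feature)
  expect_equal(merged$p_value_mean[i], single$p_value_mean, tolerance = 1e-12)
  expect_identical(merged$best_model[i], single$best_model)
  # arithmetic mean of per-lesion p for each model
  res2 <- res
  res2$p_all <- res2$p_all * 3  # fake a second lesion with different p
  res2$p_all[res2$p_all > 1] <- 1
  m2 <- merge_lesions(list(res, res2))
  j <- match(res$feature[1], m2$feature)
  mod <- m2$best_model[j]
  k <- match(res$feature[1], res2$feature)
  expect_equal(unname(m2$p_all[j, mod]),
               unname(mean(c(res$p_all[1, mod], res2$p_all[k, mod]))))
  expect_false(is.unsorted(m2$p_value_mean))
})
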