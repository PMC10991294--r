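test_that("rank_markers matches the closed-form worked examples", {
  # group (1,2,3) vs rest (0,0,0,0): t = 2 / sqrt(1/3)
  x <- matrix(c(1, 2, 3, 0, 0, 0, 0), 1, 7,
              dimnames = list("g1", sprintf("o%d", 1:7)))
  norm <- count_matrix(x, "g1", colnames(x), layer = "normalized_log")
  lab <- stats::setNames(c(1, 1, 1, 0, 0, 0, 0), colnames(x))
  tb <- rank_markers(norm, lab, group = 1, min_group_size = 2)
  expect_equal(tb$statistic, 2 / sqrt(1 / 3), tolerance = 1e-12)
  # group (1,2,3) vs rest (0,1,0,1): overestimated SE = 2/3, t = 2.25
  x2 <- matrix(c(1, 2, 3, 0, 1, 0, 1), 1, 7,
               dimnames = list("g1", sprintf("o%d", 1:7)))
  norm2 <- count_matrix(x2, "g1", colnames(x2), layer = "normalized_log")
  tb2 <- rank_markers(norm2, lab, group = 1, min_group_size = 2)
  expect_equal(tb2$statistic, 2.25, tolerance = 1e-12)
  # |t_overestim| <= |t_welch| when n_rest >= n_group
  welch <- (2 - 0.5) / sqrt(1 / 3 + (1 / 3) / 4)
  expect_lte(abs(tb2$statistic), abs(welch))
  # log2fc example: log-means ln(4), ln(2) -> log2(3/1)
  expect_equal(lesionscape:::log2fc_from_logmeans(log(4), log(2)),
               log2(3), tolerance = 1e-6)
})

test_that("rank_markers equals the brute-force oracle on random matrices", {
  for (trial in 1:20) {
    set.seed(trial)
    n_obs <- 40
    x <- matrix(round(rexp(50 * n_obs, 0.5), 3), 50, n_obs,
                dimnames = list(sprintf("g%02d", 1:50),
                                sprintf("o%02d", 1:n_obs)))
    norm <- count_matrix(x, rownames(x), colnames(x),
                         layer = "normalized_log")
    ng <- sample(5:20, 1)
    lab <- stats::setNames(c(rep(1, ng), rep(0, n_obs - ng)), colnames(x))
    tb <- rank_markers(norm, lab, group = 1, min_group_size = 2)
    i <- match("g01", tb$gene)
    want <- oracle_overestim_t(x["g01", 1:ng], x["g01", (ng + 1):n_obs])
    expect_equal(tb$statistic[i], want$t, tolerance = 1e-10)
    expect_equal(tb$pval[i], want$p, tolerance = 1e-10)
    expect_equal(tb$log2fc[i],
                 oracle_log2fc(mean(x["g01", 1:ng]),
                               mean(x["g01", (ng + 1):n_obs])),
                 tolerance = 1e-10)
    expect_equal(tb$padj, oracle_bh(tb$pval), tolerance = 1e-10)
  }
})

test_that("rank_markers handles degenerate genes and refuses tiny groups", {
  x <- matrix(5, 2, 6, dimnames = list(c("flat", "g"), sprintf("o%d", 1:6)))
  x["g", ] <- c(1, 2, 3, 1, 2, 3)
  norm <- count_matrix(x, rownames(x), colnames(x),
                       layer = "normalized_log")
  lab <- stats::setNames(rep(c(1, 0), each = 3), colnames(x))
  tb <- rank_markers(norm, lab, group = 1, min_group_size = 2)
  i <- match("flat", tb$gene)
  expect_equal(tb$statistic[i], 0)
  expect_equal(tb$pval[i], 1)
  expect_error(rank_markers(norm, lab, group = 1, min_group_size = 10),
               "min_group_size")
})

test_that("condition_wald_test matches the formula and its symmetries", {
  x <- matrix(c(2, 4, 0, 0), 1, 4,
              dimnames = list("g1", sprintf("o%d", 1:4)))
  meta <- data.frame(condition = c("T", "T", "C", "C"))
  norm <- count_matrix(x, "g1", colnames(x), meta,
                       layer = "normalized_log")
  tb <- condition_wald_test(norm, "condition", "T", "C")
  expect_equal(tb$statistic, 3)
  expect_equal(tb$pval, 2 * pnorm(-3), tolerance = 1e-12)
  # swapped labels negate z, keep p
  tb2 <- condition_wald_test(norm, "condition", "C", "T")
  expect_equal(tb2$statistic, -tb$statistic)
  expect_equal(tb2$pval, tb$pval)
  # identical groups -> z = 0, p = 1
  x3 <- matrix(c(1, 2, 1, 2), 1, 4, dimnames = dimnames(x))
  norm3 <- count_matrix(x3, "g1", colnames(x3), meta,
                        layer = "normalized_log")
  tb3 <- condition_wald_test(norm3, "condition", "T", "C")
  expect_equal(tb3$statistic, 0)
  expect_equal(tb3$pval, 1)
  # degenerate: zero variance, unequal means -> flagged, p NA
  x4 <- matrix(c(1, 1, 0, 0), 1, 4, dimnames = dimnames(x))
  norm4 <- count_matrix(x4, "g1", colnames(x4), meta,
                        layer = "normalized_log")
  tb4 <- condition_wald_test(norm4, "condition", "T", "C")
  expect_true(tb4$degenerate)
  expect_true(is.na(tb4$pval))
})

test_that("condition_wald_test equals the oracle on random fixtures", {
  for (trial in 1:20) {
    set.seed(100 + trial)
    x <- matrix(round(rnorm(50 * 40, 5), 3), 50, 40,
                dimnames = list(sprintf("g%02d", 1:50),
                                sprintf("o%02d", 1:40)))
    meta <- data.frame(condition = rep(c("A", "B"), each = 20))
    norm <- count_matrix(x, rownames(x), colnames(x), meta,
                         layer = "normalized_log")
    tb <- condition_wald_test(norm, "condition", "B", "A")
    g <- sample(rownames(x), 1)
    i <- match(g, tb$gene)
    want <- oracle_wald_z(x[g, 21:40], x[g, 1:20])
    expect_equal(tb$statistic[i], want$z, tolerance = 1e-10)
    expect_equal(tb$pval[i], want$p, tolerance = 1e-10)
  }
})

test_that("filter_degs applies strict cutoffs in each direction", {
  tb <- data.frame(gene = sprintf("g%d", 1:5),
                   log2fc = c(2.0, 1.6, -2.0, 0.5, 1.7),
                   pval = c(0.01, 0.01, 0.04, 0.001, 0.05),
                   padj = c(0.02, 0.02, 0.08, 0.01, 0.10))
  class(tb) <- c("deg_table", "data.frame")
  expect_equal(filter_degs(tb, 0.05, 1.6, "up"), "g1")   # g2 lfc==1.6, g5 p==0.05
  expect_equal(filter_degs(tb, 0.05, 1.6, "down"), "g3")
  expect_setequal(filter_degs(tb, 0.05, 1.6, "both"), c("g1", "g3"))
  expect_equal(filter_degs(tb, 0.05, 1.6, "both", use_padj = TRUE), "g1")
  expect_error(filter_degs(tb[0, ]), "empty")
})

test_that("BH adjustment is monotone in p-value rank", {
  set.seed(77)
  p <- runif(200)^2
  padj <- oracle_bh(p)
  ord <- order(p)
  expect_false(is.unsorted(padj[ord]))
  expect_true(all(padj >= p))
  expect_equal(stats::p.adjust(p, "BH"), padj, tolerance = 1e-12)
})

test_that("exclusive_intersections partitions the union; matches oracle", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = "c")
  res <- exclusive_intersections(sets)
  expect_equal(sort(res$exclusive[["A"]]), "a")
  expect_equal(sort(res$exclusive[["B"]]), "d")
  expect_equal(sort(res$exclusive[["A&B"]]), "b")
  expect_equal(sort(res$exclusive[["A&B&C"]]), "c")
  expect_equal(sum(lengths(res$exclusive)), 4)
  # inclusive mode ignores other sets
  expect_setequal(res$inclusive[["A&B"]], c("b", "c"))
  # disjoint sets: only singletons nonempty
  res2 <- exclusive_intersections(list(X = "x", Y = "y"))
  expect_equal(lengths(res2$exclusive)[c("X", "Y")], c(X = 1L, Y = 1L))
  expect_equal(length(res2$exclusive[["X&Y"]]), 0)
  # random 5 sets vs brute-force element classification
  set.seed(1)
  rnd <- lapply(1:5, function(i) sample(sprintf("g%03d", 1:100),
                                        sample(10:60, 1)))
  names(rnd) <- LETTERS[1:5]
  got <- exclusive_intersections(rnd)$exclusive
  want <- oracle_exclusive(rnd)
  for (key in names(want)) {
    expect_setequal(got[[key]], want[[key]])
  }
  expect_equal(sum(lengths(got)), length(unique(unlist(rnd))))
  expect_error(exclusive_intersections(rep(list(letters), 21)), "20")
})

test_that("over_representation reproduces the exact hypergeometric example", {
  # N=20, K=5, n=4, k=3 -> 155/4845
  universe <- sprintf("u%02d", 1:20)
  set5 <- universe[1:5]
  query <- c(universe[1:3], universe[10])
  res <- over_representation(query, list(S = set5), universe)
  expect_equal(res$pval, 155 / 4845, tolerance = 1e-12)
  expect_equal(res$pval, oracle_hyper_p(3, 5, 4, 20), tolerance = 1e-12)
  # k = 0 -> p = 1
  res0 <- over_representation(universe[10:12], list(S = universe[1:5]),
                              universe)
  expect_equal(res0$pval, 1)
  # query == universe forces k = K, p = 1
  resU <- over_representation(universe, list(S = set5), universe)
  expect_equal(resU$pval, 1)
  expect_warning(over_representation(c(query, "alien"), list(S = set5),
                                     universe), "outside")
  expect_error(over_representation(query, list(S = set5), character()),
               "empty universe")
})

test_that("over_representation matches the oracle on random draws", {
  set.seed(5)
  universe <- sprintf("u%03d", 1:80)
  for (trial in 1:20) {
    K <- sample(5:40, 1)
    n <- sample(5:40, 1)
    s <- sample(universe, K)
    q <- sample(universe, n)
    res <- over_representation(q, list(S = s), universe)
    expect_equal(res$pval,
                 oracle_hyper_p(length(intersect(s, q)), K, n, 80),
                 tolerance = 1e-10)
  }
})

test_that("cluster_similarity is Jaccard on top-k lists", {
  a <- sprintf("g%02d", 1:20)
  b <- c(sprintf("g%02d", 1:10), sprintf("h%02d", 1:10))
  S <- cluster_similarity(list(c1 = a, c2 = b, c3 = rev(a)), k_top = 20)
  expect_equal(diag(S), c(c1 = 1, c2 = 1, c3 = 1))
  expect_equal(S["c1", "c2"], 10 / 30)
  expect_equal(S["c1", "c3"], 1)  # same set, different order
  expect_true(isSymmetric(S))
  S2 <- cluster_similarity(list(x = c("a"), y = c("b")), k_top = 1)
  expect_equal(S2["x", "y"], 0)
  expect_warning(cluster_similarity(list(x = "a", y = letters), k_top = 5),
                 "fewer than k_top")
})
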