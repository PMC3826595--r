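# Distances, group linkage, MDS, PCA projection and clustering order

test_that("pairwise distances match simple geometric facts", {
  x <- expression_matrix(matrix(c(0, 0, 3, 4, 0, 0), 2, 3,
                                dimnames = list(c("p1", "p2"),
                                                c("a", "b", "c"))))
  d <- pairwise_distance(x)
  expect_equal(d["a", "b"], 5) # 3-4-5 triangle
  expect_equal(d["a", "c"], 0) # identical samples
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))

  # correlation distance ignores positive scaling
  set.seed(2)
  y <- matrix(rnorm(20), 10, 2, dimnames = list(sprintf("p%02d", 1:10),
                                                c("s", "scaled")))
  y[, 2] <- 2.5 * y[, 1]
  dc <- pairwise_distance(expression_matrix(y), metric = "one_minus_pearson")
  expect_equal(dc["s", "scaled"], 0, tolerance = 1e-12)

  expect_error(pairwise_distance(x, probes = character(0)), "empty")
  expect_error(pairwise_distance(x, probes = "nope"), "absent")
})

test_that("group linkage handles singletons, symmetry and disjointness", {
  x <- toy_matrix(8, 5, seed = 3)
  d <- pairwise_distance(x)
  groups <- c(s01 = "g1", s02 = "g1", s03 = "g2", s04 = "g2", s05 = "g3")
  gl <- group_linkage(d, groups, "g1", "g2")
  expect_identical(gl$n_pairs, 4L)
  expect_equal(gl$mean_linkage, mean(d[c("s01", "s02"), c("s03", "s04")]))
  sym <- group_linkage(d, groups, "g2", "g1")
  expect_equal(sym$mean_linkage, gl$mean_linkage)
  expect_equal(sym$se, gl$se)

  single <- group_linkage(d, groups, "g3", "g1")
  expect_identical(single$n_pairs, 2L)
  one_v_one <- group_linkage(d, c(s01 = "a", s03 = "b"), "a", "b")
  expect_equal(one_v_one$mean_linkage, d["s01", "s03"])
  expect_identical(one_v_one$se, 0)

  expect_error(group_linkage(d, groups, "g1", "g1"), "disjoint")
  expect_error(group_linkage(d, groups, "g1", "missing"), "non-empty")
})

test_that("mean squared group distance matches the closed form", {
  # two groups separated by delta on the first 50 of 400 probes:
  # E[d^2] = sum(delta^2) + 2 m sigma^2
  set.seed(19)
  m <- 400
  n <- 10
  sigma <- 0.5
  delta <- 1
  x <- matrix(rnorm(m * 2 * n, 0, sigma), m, 2 * n)
  x[1:50, (n + 1):(2 * n)] <- x[1:50, (n + 1):(2 * n)] + delta
  dimnames(x) <- list(sprintf("p%03d", 1:m), sprintf("s%02d", 1:(2 * n)))
  d <- pairwise_distance(expression_matrix(x))
  groups <- setNames(rep(c("a", "b"), each = n), colnames(x))
  pairs_sq <- as.vector(d[1:n, (n + 1):(2 * n)])^2
  expected <- 50 * delta^2 + 2 * m * sigma^2
  se <- sd(pairs_sq) / sqrt(length(pairs_sq))
  expect_lt(abs(mean(pairs_sq) - expected), 3 * se)
  # and the package statistic sits on the same scale
  gl <- group_linkage(d, groups, "a", "b")
  expect_lt(abs(gl$mean_linkage^2 - expected), 3 * (2 * gl$mean_linkage * gl$se + se))
})

test_that("stemness gradient orders tumor groups by distance to ESC", {
  co <- simulate_cohort(cohort_design(seed = 71))
  ann <- co$annotations
  grp <- ifelse(ann$tissue == "reference", ann$reference_class,
                ifelse(ann$tissue == "tumor",
                       paste0(ann$age_group, "_tumor"), "non_tumor"))
  names(grp) <- ann$sample_id
  d <- pairwise_distance(co$expr)
  tab <- group_linkage_table(d, grp[grp != "hepatic_day20"], "ESC")
  expect_identical(tab$group_a,
                   c("young_tumor", "elderly_tumor", "non_tumor"))
})

test_that("classical MDS embeds Euclidean configurations exactly", {
  # collinear points with distances 1, 1, 2
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ord <- suppressWarnings(classical_mds(d3, k = 1))
  expect_equal(unname(abs(ord$points["a", 1] - ord$points["c", 1])), 2,
               tolerance = 1e-9)
  expect_equal(unname(abs(ord$points["a", 1] - ord$points["b", 1])), 1,
               tolerance = 1e-9)

  # a seeded planar point set is reconstructed to 1e-8
  set.seed(23)
  pts <- matrix(rnorm(2 * 12), 12, 2)
  rownames(pts) <- sprintf("s%02d", 1:12)
  d <- as.matrix(dist(pts))
  ord2 <- classical_mds(d, k = 2)
  rec <- as.matrix(dist(ord2$points))
  expect_lt(max(abs(rec - d)), 1e-8)

  # degenerate all-zero distances collapse to the origin
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(classical_mds(z, k = 2)$points == 0))

  # k above the positive-eigenvalue count warns and truncates
  expect_warning(tr <- classical_mds(d3, k = 2), "truncated")
  expect_identical(ncol(tr$points), 1L)
})

test_that("PCA explains variance exactly on a line and conserves total variance", {
  # samples exactly on a line in expression space
  set.seed(31)
  u <- rnorm(15)
  scores <- seq(-2, 2, length.out = 6)
  x <- outer(u, scores) + 5
  dimnames(x) <- list(sprintf("p%02d", 1:15), sprintf("s%d", 1:6))
  fit <- pca_fit(expression_matrix(x))
  expect_equal(fit$var_explained[1], 1, tolerance = 1e-12)

  y <- toy_matrix(20, 8, seed = 33)
  fit2 <- pca_fit(y)
  expect_equal(sum(fit2$var_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(fit2$var_explained) <= 1e-12))
  total_var <- sum(apply(t(y), 2, var))
  expect_equal(sum(fit2$sdev^2), total_var, tolerance = 1e-9)
})

test_that("PCA projection is consistent with the fit and centers on the fit mean", {
  y <- toy_matrix(20, 8, seed = 35)
  fit <- pca_fit(y)
  proj <- pca_project(fit, y)
  expect_equal(unname(proj), unname(fit$points), tolerance = 1e-9)

  mean_sample <- expression_matrix(
    matrix(rowMeans(y), nrow(y), 1, dimnames = list(rownames(y), "mean")))
  at_origin <- pca_project(fit, mean_sample)
  expect_lt(max(abs(at_origin)), 1e-9)

  expect_error(pca_project(fit, y[-1, ]), "missing fit probe")
})

test_that("PCA recovers a planted two-factor structure", {
  set.seed(37)
  m <- 100
  n <- 40
  u <- rnorm(m); u <- u / sqrt(sum(u^2))
  v <- rnorm(m); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
  x <- outer(u, rnorm(n, 0, 4)) + outer(v, rnorm(n, 0, 2)) +
    matrix(rnorm(m * n, 0, 0.05), m, n)
  dimnames(x) <- list(sprintf("p%03d", 1:m), sprintf("s%02d", 1:n))
  fit <- pca_fit(expression_matrix(x))
  basis <- fit$rotation[, 1:2]
  angle_to_plane <- function(w) {
    proj <- basis %*% crossprod(basis, w)
    acos(min(1, sqrt(sum(proj^2)) / sqrt(sum(w^2)))) * 180 / pi
  }
  expect_lt(angle_to_plane(u), 10)
  expect_lt(angle_to_plane(v), 10)
})

test_that("average-linkage ordering is deterministic and matches the oracle", {
  # forced first merge
  d <- matrix(10, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 1
  res <- hclust_order(d)
  expect_identical(res$heights[1], 1)
  # a and b merge first, so they sit adjacent in the leaf order
  expect_identical(abs(diff(match(c("a", "b"), res$order))), 1L)

  two <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("y", "x"), c("y", "x")))
  expect_identical(sort(hclust_order(two)$order), c("x", "y"))

  # merge heights equal a brute-force agglomeration on random instances
  set.seed(41)
  for (rep in 1:5) {
    pts <- matrix(rnorm(8 * 3), 8, 3)
    rownames(pts) <- letters[1:8]
    dm <- as.matrix(dist(pts))
    res <- hclust_order(dm)
    expect_equal(sort(res$heights), oracle_upgma_heights(dm),
                 tolerance = 1e-9)
  }

  # expression-matrix input returns both row and column orders
  x <- toy_matrix(6, 5, seed = 43)
  hm <- hclust_order(x)
  expect_identical(sort(hm$row_order), sort(rownames(x)))
  expect_identical(sort(hm$col_order), sort(colnames(x)))
})
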