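# Distance and ordination machinery: signature-restricted sample distances,
# average-linkage group-to-reference distances with standard errors (the
# stemness statistic), classical MDS, PCA with reference-axis projection, and
# average-linkage leaf ordering for heat-map export.

#' Pairwise sample distances
#'
#' Euclidean distance on log2 values (default) or one minus the Pearson
#' correlation of the sample profiles, optionally restricted to a signature's
#' probes.
#'
#' @param x an [expression_matrix()].
#' @param probes optional probe restriction (character vector or `signature`).
#' @param metric `"euclidean"` or `"one_minus_pearson"`.
#' @param z_score standardize each probe row (mean 0, sd 1) before measuring
#'   distances; off by default.
#' @return symmetric sample-by-sample distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(x, probes = NULL,
                              metric = c("euclidean", "one_minus_pearson"),
                              z_score = FALSE) {
  metric <- match.arg(metric)
  x <- expression_matrix(x)
  if (!is.null(probes)) {
    if (inherits(probes, "signature")) probes <- probes$probe_id
    if (length(probes) == 0L) stop("probe restriction is empty")
    missing_p <- setdiff(probes, rownames(x))
    if (length(missing_p) > 0L) {
      stop("restriction probes absent from matrix: ",
           paste(utils::head(missing_p, 5L), collapse = ", "))
    }
    x <- x[probes, , drop = FALSE]
  }
  if (z_score) {
    mu <- rowMeans(x)
    sd_ <- apply(x, 1L, stats::sd)
    sd_[sd_ == 0] <- 1
    x <- (x - mu) / sd_
  }
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(t(x), method = "euclidean")),
    one_minus_pearson = 1 - stats::cor(x)
  )
  diag(d) <- 0
  d
}

#' Average-linkage distance between two sample groups
#'
#' The stemness statistic: the mean over all inter-group sample-pair
#' distances, with the naive standard error (sample sd of the pair distances
#' over the square root of the pair count; pairs sharing a sample are not
#' independent, so a bootstrap over samples is available via
#' [group_linkage_bootstrap_se()]). Singleton-vs-singleton comparisons get
#' `se = 0` by convention.
#'
#' @param d distance matrix from [pairwise_distance()].
#' @param groups named character vector mapping sample id to group label (a
#'   partition of the samples).
#' @param a,b the two group labels to compare (must be disjoint, i.e.
#'   different labels).
#' @return data frame row of class `group_distance`: `group_a`, `group_b`,
#'   `mean_linkage`, `se`, `n_pairs`.
#' @export
group_linkage <- function(d, groups, a, b) {
  if (a == b) stop("groups must be disjoint")
  members_a <- names(groups)[groups == a]
  members_b <- names(groups)[groups == b]
  if (length(members_a) == 0L || length(members_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (length(intersect(members_a, members_b)) > 0L) {
    stop("groups overlap")
  }
  missing_s <- setdiff(c(members_a, members_b), rownames(d))
  if (length(missing_s) > 0L) {
    stop("samples absent from distance matrix: ",
         paste(utils::head(missing_s, 5L), collapse = ", "))
  }
  pairs <- as.vector(d[members_a, members_b, drop = FALSE])
  n_pairs <- length(pairs)
  se <- if (n_pairs > 1L) stats::sd(pairs) / sqrt(n_pairs) else 0
  structure(data.frame(group_a = a, group_b = b,
                       mean_linkage = mean(pairs), se = se,
                       n_pairs = n_pairs, stringsAsFactors = FALSE),
            class = c("group_distance", "data.frame"))
}

#' Bootstrap standard error of a group linkage distance
#'
#' Resamples samples within each group (with replacement) and recomputes the
#' mean inter-group pair distance; the SE is the standard deviation of the
#' bootstrap means. Accounts for the dependence among pair distances that the
#' naive SE of [group_linkage()] ignores.
#'
#' @inheritParams group_linkage
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return the [group_linkage()] row with `se` replaced by the bootstrap SE.
#' @export
group_linkage_bootstrap_se <- function(d, groups, a, b, B = 1000, seed) {
  if (missing(seed)) stop("a seed is required")
  base <- group_linkage(d, groups, a, b)
  members_a <- names(groups)[groups == a]
  members_b <- names(groups)[groups == b]
  set.seed(seed)
  boots <- vapply(seq_len(B), function(i) {
    ra <- sample(members_a, replace = TRUE)
    rb <- sample(members_b, replace = TRUE)
    mean(d[ra, rb])
  }, numeric(1L))
  base$se <- stats::sd(boots)
  base
}

#' Linkage distances of every group to one reference group
#'
#' @inheritParams group_linkage
#' @param reference the reference group label (e.g. `"ESC"`).
#' @return data frame with one [group_linkage()] row per non-reference group,
#'   ordered by ascending `mean_linkage`.
#' @export
group_linkage_table <- function(d, groups, reference) {
  others <- setdiff(unique(groups), reference)
  rows <- lapply(others, function(g) group_linkage(d, groups, g, reference))
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_linkage), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distances and embeds samples on the top-k
#' eigenvectors. When the distances are Euclidean-embeddable in k dimensions
#' the embedding reproduces them exactly. If fewer than `k` positive
#' eigenvalues exist, the embedding is truncated with a warning.
#'
#' @param d distance matrix from [pairwise_distance()].
#' @param k number of dimensions.
#' @return object of class `ordination`: list with `sample_ids`, `points`
#'   (samples x dimensions), `eig` (all eigenvalues).
#' @export
classical_mds <- function(d, k = 2) {
  if (k < 1L) stop("k must be at least 1")
  d <- as.matrix(d)
  n <- nrow(d)
  if (k > n - 1L) stop("k cannot exceed n - 1")
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  n_pos <- sum(fit$eig > max(fit$eig) * 1e-9)
  if (n_pos == 0L) {
    # degenerate all-zero distances: everything at the origin
    pts <- matrix(0, n, k)
  } else if (n_pos < k) {
    warning("only ", n_pos, " positive eigenvalue(s); embedding truncated ",
            "from ", k, " to ", n_pos, " dimension(s)")
    pts <- as.matrix(fit$points)[, seq_len(n_pos), drop = FALSE]
  } else {
    pts <- as.matrix(fit$points)
  }
  rownames(pts) <- rownames(d)
  structure(list(sample_ids = rownames(d), points = pts, eig = fit$eig),
            class = "ordination")
}

#' Principal component analysis of samples
#'
#' Probe-wise mean-centered PCA (no scaling); axes ordered by decreasing
#' explained variance. The centering vector and rotation basis are retained
#' so that new cohorts can be projected into the same space with
#' [pca_project()].
#'
#' @param x an [expression_matrix()].
#' @param probes optional probe restriction (character vector or `signature`).
#' @return object of class `pca_ordination`: list with `sample_ids`, `points`,
#'   `var_explained` (fractions, non-increasing), `sdev`, `rotation`,
#'   `center`, `probe_ids`.
#' @export
pca_fit <- function(x, probes = NULL) {
  x <- expression_matrix(x)
  if (!is.null(probes)) {
    if (inherits(probes, "signature")) probes <- probes$probe_id
    if (length(probes) == 0L) stop("probe restriction is empty")
    x <- x[probes, , drop = FALSE]
  }
  if (ncol(x) < 2L) stop("PCA needs at least 2 samples")
  fit <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  var_axis <- fit$sdev^2
  structure(list(sample_ids = colnames(x), points = fit$x,
                 var_explained = var_axis / sum(var_axis), sdev = fit$sdev,
                 rotation = fit$rotation, center = fit$center,
                 probe_ids = rownames(x)),
            class = c("pca_ordination", "ordination"))
}

#' Project new samples onto fitted principal axes
#'
#' Centers the new samples with the FIT cohort's probe means and applies the
#' fitted rotation, so e.g. tumor groups can be placed along a
#' reference-derived differentiation axis; group centroids along PC1 then
#' order the groups along that axis.
#'
#' @param fit a `pca_ordination` from [pca_fit()].
#' @param x an [expression_matrix()] containing the fit probes.
#' @return matrix of coordinates (samples x components).
#' @export
pca_project <- function(fit, x) {
  stopifnot(inherits(fit, "pca_ordination"))
  x <- expression_matrix(x)
  missing_p <- setdiff(fit$probe_ids, rownames(x))
  if (length(missing_p) > 0L) {
    stop("new matrix missing fit probe(s): ",
         paste(utils::head(missing_p, 5L), collapse = ", "))
  }
  centered <- t(x[fit$probe_ids, , drop = FALSE] - fit$center)
  centered %*% fit$rotation
}

#' Average-linkage leaf order for heat maps
#'
#' Agglomerative average-linkage (UPGMA) clustering with a deterministic
#' leaf order: items are fed to the clusterer sorted by id, so distance ties
#' break by id rather than input order. Given an expression matrix, both the
#' probe (row) and sample (column) orders are returned; given a distance
#' matrix or `dist`, a single item order is returned.
#'
#' @param x an [expression_matrix()], a symmetric distance matrix, or a
#'   `dist` object.
#' @param metric distance metric used when `x` is an expression matrix.
#' @return for an expression matrix, list with `row_order`, `col_order` and
#'   the two `hclust` trees; for distances, list with `order` (leaf ids),
#'   `heights` (merge heights) and the `hclust` tree.
#' @export
hclust_order <- function(x, metric = c("euclidean", "one_minus_pearson")) {
  metric <- match.arg(metric)
  one <- function(d) {
    d <- as.matrix(d)
    ids <- sort(rownames(d))
    d <- stats::as.dist(d[ids, ids])
    if (length(ids) < 2L) {
      return(list(order = ids, heights = numeric(0), tree = NULL))
    }
    tree <- stats::hclust(d, method = "average")
    list(order = ids[tree$order], heights = tree$height, tree = tree)
  }
  if (inherits(x, "dist")) return(one(x))
  x_mat <- as.matrix(x)
  if (isSymmetric(unname(x_mat)) &&
      !is.null(rownames(x_mat)) && !is.null(colnames(x_mat)) &&
      identical(rownames(x_mat), colnames(x_mat)) &&
      all(diag(x_mat) == 0)) {
    return(one(x_mat))
  }
  x_mat <- expression_matrix(x_mat)
  rows <- one(pairwise_distance(t(x_mat), metric = metric))
  cols <- one(pairwise_distance(x_mat, metric = metric))
  list(row_order = rows$order, col_order = cols$order,
       row_tree = rows$tree, col_tree = cols$tree)
}
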