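# Weighted-voting classification with signal-to-noise (S2N) weights.
#
# Per probe, w = (mu1 - mu2) / (sigma1 + sigma2) with population (divide-by-n)
# standard deviations per class, and decision boundary b = (mu1 + mu2) / 2.
# A sample x casts the vote v = w (x - b) per probe; positive votes favor
# class 1. V1 is the summed positive vote mass, V2 the absolute summed
# negative mass; the winner takes the sample and the prediction strength
# PS = (V_win - V_lose) / (V_win + V_lose) measures the margin.

# internal: per-class means and population sds for a probe subset
.class_stats <- function(x, y) {
  n1 <- sum(y == 1L)
  n2 <- sum(y == 2L)
  x1 <- x[, y == 1L, drop = FALSE]
  x2 <- x[, y == 2L, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  s1 <- sqrt(pmax(rowMeans(x1^2) - m1^2, 0))
  s2 <- sqrt(pmax(rowMeans(x2^2) - m2^2, 0))
  list(m1 = m1, m2 = m2, s1 = s1, s2 = s2, n1 = n1, n2 = n2)
}

#' Train a signal-to-noise weighted-voting panel
#'
#' Computes per-probe S2N weights `(mu1 - mu2)/(sigma1 + sigma2)` (population
#' standard deviations per class, matching the original weighted-voting
#' formulation) and decision boundaries `(mu1 + mu2)/2`, and orders probes by
#' descending absolute weight (ties broken by probe id). Degenerate probes
#' with `sigma1 + sigma2 = 0` are dropped with a message.
#'
#' @param x an [expression_matrix()].
#' @param labels two-class [class_labels()] parallel to the columns; class 1
#'   is voted for by positive votes.
#' @param probes optional probe id restriction (e.g. a candidate pool from a
#'   differential-expression intersection); a `signature` is accepted.
#' @return object of class `signature_panel`: data frame with `probe_id`,
#'   `weight`, `boundary`, ordered by descending `|weight|`; attribute
#'   `class_names`.
#' @export
train_panel <- function(x, labels, probes = NULL) {
  x <- expression_matrix(x)
  labels <- .binary_labels(x, labels)
  y <- labels$labels
  if (sum(y == 1L) < 2L || sum(y == 2L) < 2L) {
    stop("both classes need at least 2 samples")
  }
  if (!is.null(probes)) {
    if (inherits(probes, "signature")) probes <- probes$probe_id
    missing_p <- setdiff(probes, rownames(x))
    if (length(missing_p) > 0L) {
      stop("probes absent from matrix: ",
           paste(utils::head(missing_p, 5L), collapse = ", "))
    }
    x <- x[probes, , drop = FALSE]
  }
  st <- .class_stats(x, y)
  denom <- st$s1 + st$s2
  degenerate <- denom == 0
  if (any(degenerate)) {
    message("dropping ", sum(degenerate),
            " probe(s) with zero spread in both classes")
  }
  w <- (st$m1 - st$m2)[!degenerate] / denom[!degenerate]
  b <- ((st$m1 + st$m2) / 2)[!degenerate]
  ids <- rownames(x)[!degenerate]
  ord <- order(-abs(w), ids)
  panel <- data.frame(probe_id = ids[ord], weight = w[ord],
                      boundary = b[ord],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(panel, class = c("signature_panel", "data.frame"),
            class_names = labels$class_names)
}

# internal vote kernel: weights/boundaries (already truncated) vs one or more
# sample columns; returns per-sample V1, V2
.vote_mass <- function(weight, boundary, xs) {
  votes <- weight * (xs - boundary)
  v1 <- colSums(pmax(votes, 0))
  v2 <- colSums(pmax(-votes, 0))
  cbind(v1 = v1, v2 = v2)
}

# internal: turn vote masses into a prediction row set
.vote_calls <- function(vm, class_names) {
  v1 <- vm[, "v1"]
  v2 <- vm[, "v2"]
  winner <- ifelse(v1 > v2, 1L, ifelse(v2 > v1, 2L, NA_integer_))
  v_win <- pmax(v1, v2)
  v_lose <- pmin(v1, v2)
  total <- v_win + v_lose
  ps <- ifelse(is.na(winner) | total == 0, 0, (v_win - v_lose) / total)
  data.frame(predicted = ifelse(is.na(winner), NA_character_,
                                class_names[winner]),
             predicted_index = winner, v_win = v_win, v_lose = v_lose,
             ps = ps, row.names = NULL, stringsAsFactors = FALSE)
}

#' Predict samples with a weighted-voting panel
#'
#' Applies the per-probe vote `v = w (x - b)`; positive vote mass `V1` backs
#' class 1 and negative mass `V2` backs class 2. The larger side wins and the
#' prediction strength `PS = (V_win - V_lose)/(V_win + V_lose)` is the vote
#' margin in `[0, 1]`. Exact vote ties leave the sample undecided
#' (`predicted = NA`, `PS = 0`); undecided samples count as errors in
#' evaluation.
#'
#' @param object a `signature_panel` from [train_panel()].
#' @param newdata an [expression_matrix()] covering the panel probes, or a
#'   named numeric vector for a single sample.
#' @param top_k optional truncation to the top-k probes by absolute weight.
#' @param ... unused.
#' @return data frame with one row per sample: `sample_id`, `predicted`,
#'   `predicted_index`, `v_win`, `v_lose`, `ps`.
#' @export
predict.signature_panel <- function(object, newdata, top_k = NULL, ...) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, ncol = 1L,
                      dimnames = list(names(newdata), "sample_1"))
  }
  if (!is.null(top_k)) {
    if (top_k < 1L || top_k > nrow(object)) {
      stop("top_k must lie in 1..panel size (", nrow(object), ")")
    }
    object_rows <- seq_len(top_k)
  } else {
    object_rows <- seq_len(nrow(object))
  }
  ids <- object$probe_id[object_rows]
  missing_p <- setdiff(ids, rownames(newdata))
  if (length(missing_p) > 0L) {
    stop("sample(s) missing panel probe(s): ",
         paste(utils::head(missing_p, 5L), collapse = ", "))
  }
  xs <- newdata[ids, , drop = FALSE]
  vm <- .vote_mass(object$weight[object_rows], object$boundary[object_rows], xs)
  out <- .vote_calls(vm, attr(object, "class_names"))
  cbind(data.frame(sample_id = colnames(newdata), stringsAsFactors = FALSE),
        out)
}

# internal LOOCV engine. X: pool-restricted matrix; y: integer 1/2 labels;
# sizes: panel sizes to evaluate per fold (ranking recomputed inside each
# fold). Returns list(errors = error per size, calls = prediction index
# matrix folds x sizes (NA = tie), ps = matrix of prediction strengths).
.loocv_by_size <- function(X, y, sizes) {
  n <- ncol(X)
  ids <- rownames(X)
  S1 <- rowSums(X[, y == 1L, drop = FALSE])
  S2 <- rowSums(X[, y == 2L, drop = FALSE])
  Q1 <- rowSums(X[, y == 1L, drop = FALSE]^2)
  Q2 <- rowSums(X[, y == 2L, drop = FALSE]^2)
  n1 <- sum(y == 1L)
  n2 <- sum(y == 2L)
  if (n1 < 2L || n2 < 2L) stop("both classes need at least 2 samples")
  if ((n1 - 1L) < 1L || (n2 - 1L) < 1L) {
    stop("a leave-one-out fold would lose a class entirely")
  }
  sizes <- as.integer(sizes)
  if (any(sizes < 1L) || any(sizes > nrow(X))) {
    stop("panel sizes must lie in 1..", nrow(X))
  }
  calls <- matrix(NA_integer_, n, length(sizes))
  psm <- matrix(0, n, length(sizes))
  max_k <- max(sizes)
  for (i in seq_len(n)) {
    xi <- X[, i]
    if (y[i] == 1L) {
      m1 <- (S1 - xi) / (n1 - 1L)
      q1 <- (Q1 - xi^2) / (n1 - 1L)
      m2 <- S2 / n2
      q2 <- Q2 / n2
    } else {
      m1 <- S1 / n1
      q1 <- Q1 / n1
      m2 <- (S2 - xi) / (n2 - 1L)
      q2 <- (Q2 - xi^2) / (n2 - 1L)
    }
    s1 <- sqrt(pmax(q1 - m1^2, 0))
    s2 <- sqrt(pmax(q2 - m2^2, 0))
    denom <- s1 + s2
    w <- ifelse(denom == 0, 0, (m1 - m2) / denom)
    ord <- order(-abs(w), ids)[seq_len(max_k)]
    v <- w[ord] * (xi[ord] - (m1[ord] + m2[ord]) / 2)
    pos <- cumsum(pmax(v, 0))
    neg <- cumsum(pmax(-v, 0))
    v1 <- pos[sizes]
    v2 <- neg[sizes]
    calls[i, ] <- ifelse(v1 > v2, 1L, ifelse(v2 > v1, 2L, NA_integer_))
    tot <- v1 + v2
    psm[i, ] <- ifelse(is.na(calls[i, ]) | tot == 0, 0, abs(v1 - v2) / tot)
  }
  wrong <- is.na(calls) | calls != y
  list(errors = colMeans(wrong), calls = calls, ps = psm)
}

#' Leave-one-out cross-validated error of the weighted-voting classifier
#'
#' For every sample, the panel is retrained without that sample — including
#' the S2N ranking and `top_k` truncation, so feature selection does not leak
#' the held-out sample — and the sample is then predicted. Undecided vote
#' ties count as errors.
#'
#' Set `refit_ranking = FALSE` to rank once on the full data and only refit
#' the weights per fold; this reproduces the optimistically biased variant
#' sometimes used historically and exists for comparison only.
#'
#' @inheritParams train_panel
#' @param top_k panel size (top probes by absolute weight); `NULL` uses all.
#' @param refit_ranking recompute the ranking inside each fold (default).
#' @return list with `error` (misclassified + undecided over n) and
#'   `predictions` (per-sample data frame with held-out call, correctness and
#'   prediction strength).
#' @export
loocv_error <- function(x, labels, top_k = NULL, probes = NULL,
                        refit_ranking = TRUE) {
  x <- expression_matrix(x)
  labels <- .binary_labels(x, labels)
  y <- labels$labels
  if (ncol(x) < 4L) stop("LOOCV needs at least 4 samples")
  if (!is.null(probes)) {
    if (inherits(probes, "signature")) probes <- probes$probe_id
    x <- x[probes, , drop = FALSE]
  }
  if (!refit_ranking && !is.null(top_k)) {
    # biased variant: freeze the full-data ranking, refit weights in-fold
    full <- train_panel(x, labels)
    x <- x[full$probe_id[seq_len(min(top_k, nrow(full)))], , drop = FALSE]
    top_k <- NULL
  }
  k <- if (is.null(top_k)) nrow(x) else top_k
  res <- .loocv_by_size(x, y, k)
  predictions <- data.frame(
    sample_id = colnames(x),
    true_class = labels$class_names[y],
    predicted = ifelse(is.na(res$calls[, 1L]), NA_character_,
                       labels$class_names[res$calls[, 1L]]),
    ps = res$ps[, 1L],
    correct = !is.na(res$calls[, 1L]) & res$calls[, 1L] == y,
    stringsAsFactors = FALSE
  )
  list(error = res$errors[1L], predictions = predictions)
}

#' Scan candidate panel sizes by LOOCV error
#'
#' Computes the leave-one-out error at each candidate size (sharing the
#' per-fold ranking across sizes, so results match [loocv_error()] run per
#' size) and selects the LARGEST size achieving the minimum error — the
#' largest panel with the best discrimination.
#'
#' @inheritParams loocv_error
#' @param sizes candidate panel sizes (each within the probe pool).
#' @return object of class `panel_scan`: list with `sizes`, `errors`,
#'   `selected`, `min_error`.
#' @export
panel_scan <- function(x, labels, sizes, probes = NULL) {
  x <- expression_matrix(x)
  labels <- .binary_labels(x, labels)
  if (!is.null(probes)) {
    if (inherits(probes, "signature")) probes <- probes$probe_id
    x <- x[probes, , drop = FALSE]
  }
  if (length(sizes) < 1L) stop("at least one candidate size required")
  sizes <- sort(unique(as.integer(sizes)))
  res <- .loocv_by_size(x, labels$labels, sizes)
  min_error <- min(res$errors)
  selected <- max(sizes[res$errors == min_error])
  structure(list(sizes = sizes, errors = res$errors, selected = selected,
                 min_error = min_error),
            class = "panel_scan")
}

#' @export
print.panel_scan <- function(x, ...) {
  cat("<panel_scan> selected size ", x$selected, " (LOOCV error ",
      format(x$min_error, digits = 3), ")\n", sep = "")
  print(data.frame(size = x$sizes, loocv_error = x$errors), row.names = FALSE)
  invisible(x)
}

#' Permutation test of the LOOCV classification error
#'
#' Class labels are permuted uniformly `B` times and the full leave-one-out
#' error is recomputed for each permutation (ranking redone inside every
#' fold). The p-value is `(1 + #\{null error <= observed\}) / (B + 1)`.
#'
#' @inheritParams loocv_error
#' @param B number of permutations (the default supports p-values down to
#'   about 1/1000).
#' @param seed integer seed for the permutations.
#' @return object of class `permutation_test`: list with `observed_error`,
#'   `null_errors`, `B`, `p_value`.
#' @export
permutation_test <- function(x, labels, top_k = NULL, B = 1000, seed,
                             probes = NULL) {
  if (missing(seed)) stop("a seed is required")
  if (B < 1L) stop("B must be at least 1")
  x <- expression_matrix(x)
  labels <- .binary_labels(x, labels)
  if (!is.null(probes)) {
    if (inherits(probes, "signature")) probes <- probes$probe_id
    x <- x[probes, , drop = FALSE]
  }
  y <- labels$labels
  k <- if (is.null(top_k)) nrow(x) else top_k
  observed <- .loocv_by_size(x, y, k)$errors[1L]
  set.seed(seed)
  null_errors <- vapply(seq_len(B), function(b) {
    .loocv_by_size(x, sample(y), k)$errors[1L]
  }, numeric(1L))
  p <- (1 + sum(null_errors <= observed)) / (B + 1)
  structure(list(observed_error = observed, null_errors = null_errors,
                 B = B, p_value = p),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("<permutation_test> observed LOOCV error ",
      format(x$observed_error, digits = 3), ", B = ", x$B,
      ", p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Validate a fixed panel on an external cohort
#'
#' Applies a trained (non-retrained) panel to independent samples and
#' summarizes class calls, prediction strengths and the confusion table.
#' Undecided vote ties count as errors.
#'
#' @param panel a `signature_panel` from [train_panel()].
#' @param x external [expression_matrix()] covering the panel probes.
#' @param labels true two-class labels of the external samples (same class
#'   names as the panel).
#' @param top_k optional truncation to the top-k probes.
#' @return list with `predictions` (per-sample data frame), `confusion`
#'   (true x predicted table including an `undecided` column) and `error`.
#' @export
validate_panel <- function(panel, x, labels, top_k = NULL) {
  x <- expression_matrix(x)
  if (ncol(x) == 0L) stop("external cohort is empty")
  labels <- .binary_labels(x, labels)
  class_names <- attr(panel, "class_names")
  if (!identical(labels$class_names, class_names)) {
    stop("external labels use classes (",
         paste(labels$class_names, collapse = ", "),
         ") but the panel was trained on (",
         paste(class_names, collapse = ", "), ")")
  }
  pred <- predict(panel, x, top_k = top_k)
  true_class <- class_names[labels$labels]
  predicted <- ifelse(is.na(pred$predicted), "undecided", pred$predicted)
  confusion <- table(true = factor(true_class, class_names),
                     predicted = factor(predicted,
                                        c(class_names, "undecided")))
  correct <- !is.na(pred$predicted) & pred$predicted == true_class
  list(predictions = cbind(pred,
                           data.frame(true_class = true_class,
                                      correct = correct,
                                      stringsAsFactors = FALSE)),
       confusion = confusion,
       error = mean(!correct))
}
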