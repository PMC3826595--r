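#' Per-probe Welch two-sample t tests
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' computed for every probe row. Class 1 is the contrast class, so
#' `log2_fc = mean(class 1) - mean(class 2)` and a positive statistic means
#' higher expression in class 1. `fold` is the signed linear fold change:
#' `2^log2_fc` for up probes, `-2^(-log2_fc)` for down probes.
#'
#' Probes with zero variance in both classes get `t = 0`, `p = 1` by
#' convention.
#'
#' @param x an [expression_matrix()].
#' @param labels a two-class [class_labels()] (or factor/character vector)
#'   parallel to the matrix columns.
#' @return data frame with columns `probe_id`, `mean_1`, `mean_2`,
#'   `log2_fc`, `fold`, `t_stat`, `df`, `p_value`.
#' @export
welch_t <- function(x, labels) {
  x <- expression_matrix(x)
  labels <- .binary_labels(x, labels)
  y <- labels$labels
  n1 <- sum(y == 1L)
  n2 <- sum(y == 2L)
  if (n1 < 2L || n2 < 2L) stop("both classes need at least 2 samples")
  x1 <- x[, y == 1L, drop = FALSE]
  x2 <- x[, y == 2L, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  degenerate <- se2 == 0
  t_stat[degenerate] <- 0
  df[degenerate] <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[degenerate] <- 1
  lfc <- m1 - m2
  data.frame(probe_id = rownames(x), mean_1 = m1, mean_2 = m2,
             log2_fc = lfc,
             fold = ifelse(lfc >= 0, 2^lfc, -2^(-lfc)),
             t_stat = t_stat, df = df, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Storey positive-FDR q-values
#'
#' Single-lambda estimator of the null proportion,
#' `pi0 = min(1, #\{p > lambda\} / (m (1 - lambda)))` with `lambda = 0.5` by
#' default, followed by the step-up construction on the sorted p-values:
#' `q_(i) = min_(j >= i) pi0 m p_(j) / j`, capped at 1 and mapped back to the
#' input order. Forcing `pi0 = 1` recovers Benjamini-Hochberg step-up values.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param lambda tuning point of the pi0 estimator.
#' @param pi0 optional override of the estimated null proportion.
#' @return q-values, parallel to `p`.
#' @export
storey_q <- function(p, lambda = 0.5, pi0 = NULL) {
  m <- length(p)
  if (m < 1L) stop("at least one p-value required")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (is.null(pi0)) {
    pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  }
  ord <- order(p)
  p_sorted <- p[ord]
  q_sorted <- pmin(1, pi0 * m * p_sorted / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Attach q-values to a Welch test table
#'
#' @param results a data frame from [welch_t()].
#' @inheritParams storey_q
#' @return `results` with a `q_value` column appended.
#' @export
add_q_values <- function(results, lambda = 0.5, pi0 = NULL) {
  results$q_value <- storey_q(results$p_value, lambda = lambda, pi0 = pi0)
  results
}

#' Select a differential signature at a q-value threshold
#'
#' Probes with `q <= q_threshold` (ties at the threshold included, so counts
#' are reproducible), with direction `up`/`down` from the sign of the fold
#' change in the contrast class, ordered by ascending q then probe id.
#'
#' @param results a data frame from [welch_t()] + [add_q_values()].
#' @param q_threshold q-value cutoff.
#' @param contrast optional contrast name carried on the signature.
#' @return object of class `signature`: data frame with `probe_id`,
#'   `direction`, `q_value`, `log2_fc`; attributes `q_threshold`, `contrast`
#'   and `universe` (all tested probe ids).
#' @export
select_signature <- function(results, q_threshold, contrast = "") {
  if (is.null(results$q_value)) stop("q-values missing; run add_q_values() first")
  keep <- results$q_value <= q_threshold
  sig <- results[keep, c("probe_id", "q_value", "log2_fc"), drop = FALSE]
  sig$direction <- ifelse(sig$log2_fc >= 0, "up", "down")
  sig <- sig[order(sig$q_value, sig$probe_id),
             c("probe_id", "direction", "q_value", "log2_fc")]
  rownames(sig) <- NULL
  if (nrow(sig) == 0L) message("signature at q <= ", q_threshold, " is empty")
  structure(sig, class = c("signature", "data.frame"),
            q_threshold = q_threshold, contrast = contrast,
            universe = results$probe_id)
}

#' Intersect two differential signatures (the Venn filter)
#'
#' Emulates a two-contrast intersection filter: probes differential in both
#' the age contrast and the tumor contrast. Directions are taken from
#' signature `a` (conventionally the age contrast); input and intersection
#' sizes are reported via `message()` for Venn-style bookkeeping.
#'
#' @param a,b `signature` objects over the same probe universe.
#' @return a `signature` with the intersected probes, ordered as in `a`.
#' @export
intersect_signatures <- function(a, b) {
  stopifnot(inherits(a, "signature"), inherits(b, "signature"))
  ua <- attr(a, "universe")
  ub <- attr(b, "universe")
  if (length(intersect(ua, ub)) == 0L) {
    stop("signatures come from disjoint probe universes")
  }
  keep <- a$probe_id %in% b$probe_id
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  message("signature intersection: |a| = ", nrow(a), ", |b| = ", nrow(b),
          ", |a & b| = ", nrow(out))
  structure(out, class = c("signature", "data.frame"),
            q_threshold = attr(a, "q_threshold"),
            contrast = paste0(attr(a, "contrast"), " & ", attr(b, "contrast")),
            universe = intersect(ua, ub))
}

#' Count up- and down-regulated probes of a signature
#'
#' @param sig a `signature`.
#' @return named integer vector `c(up = ..., down = ...)`; the two counts
#'   always sum to the signature size.
#' @export
up_down_split <- function(sig) {
  stopifnot(inherits(sig, "signature"))
  c(up = sum(sig$direction == "up"), down = sum(sig$direction == "down"))
}

#' Run a full differential-expression contrast
#'
#' Welch tests, Storey q-values and threshold selection in one call.
#'
#' @inheritParams welch_t
#' @inheritParams select_signature
#' @return list with `results` (full per-probe table) and `signature`.
#' @export
de_contrast <- function(x, labels, q_threshold = 0.05, contrast = "") {
  results <- add_q_values(welch_t(x, labels))
  list(results = results,
       signature = select_signature(results, q_threshold, contrast))
}
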