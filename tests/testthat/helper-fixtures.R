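# Shared fixtures and independent brute-force oracles.

# small deterministic expression matrix
toy_matrix <- function(n_probes = 6, n_samples = 4, seed = 1) {
  set.seed(seed)
  expression_matrix(
    matrix(rnorm(n_probes * n_samples, 7, 1), n_probes, n_samples,
           dimnames = list(sprintf("p%02d", seq_len(n_probes)),
                           sprintf("s%02d", seq_len(n_samples)))))
}

# two-class matrix with a planted mean shift on the first n_shift probes
shifted_matrix <- function(n_probes = 50, n_per_class = 5, n_shift = 10,
                           delta = 3, sd = 0.3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n_probes * n, 5, sd), n_probes, n,
              dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n))))
  x[seq_len(n_shift), seq_len(n_per_class)] <-
    x[seq_len(n_shift), seq_len(n_per_class)] + delta
  labels <- class_labels(rep(1:2, each = n_per_class), c("A", "B"))
  list(expr = x, labels = labels)
}

# independent weighted-vote oracle: per-probe votes summed one at a time
oracle_vote <- function(weight, boundary, x) {
  v1 <- 0
  v2 <- 0
  for (i in seq_along(weight)) {
    v <- weight[i] * (x[i] - boundary[i])
    if (v > 0) v1 <- v1 + v else v2 <- v2 + abs(v)
  }
  v1 <- unname(v1)
  v2 <- unname(v2)
  winner <- if (v1 > v2) 1L else if (v2 > v1) 2L else NA_integer_
  ps <- if (is.na(winner) || v1 + v2 == 0) 0 else abs(v1 - v2) / (v1 + v2)
  list(v1 = v1, v2 = v2, winner = winner, ps = ps)
}

# brute-force UPGMA: clusters merged at the mean of original cross-pair
# distances; returns the sorted merge heights
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  sort(heights)
}

# exact two-sided Fisher p for a 2x2 table by full hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  probs <- vapply(max(0, c1 - r2):min(r1, c1), function(a) {
    stats::dhyper(a, r1, r2, c1)
  }, numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating all label assignments
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_stat <- function(idx) {
    aa <- pooled[idx]
    bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  u_obs <- u_stat(seq_len(na))
  mid <- na * (n - na) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2L, u_stat)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}
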