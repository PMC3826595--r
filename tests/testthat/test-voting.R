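# Signal-to-noise weighted voting: training, prediction, LOOCV, panel scan,
# permutation test, external validation

make_panel <- function(weights, boundaries, ids = NULL,
                       class_names = c("A", "B")) {
  if (is.null(ids)) ids <- sprintf("p%02d", seq_along(weights))
  ord <- order(-abs(weights), ids)
  structure(data.frame(probe_id = ids[ord], weight = weights[ord],
                       boundary = boundaries[ord], stringsAsFactors = FALSE),
            class = c("signature_panel", "data.frame"),
            class_names = class_names)
}

test_that("S2N weights and boundaries match the hand-worked example", {
  # one probe: class 1 = {0, 2} (mu 1, pop-sd 1), class 2 = {-2, 0}
  x <- expression_matrix(matrix(c(0, 2, -2, 0), 1, 4,
                                dimnames = list("p1", paste0("s", 1:4))))
  labels <- class_labels(c(1L, 1L, 2L, 2L), c("A", "B"))
  panel <- train_panel(x, labels)
  expect_equal(panel$weight, (1 - (-1)) / (1 + 1), tolerance = 1e-12)
  expect_equal(panel$boundary, 0)

  # equal class means give zero weight; swapping classes negates weights
  x2 <- rbind(x, p2 = c(1, 3, 1, 3))
  x2 <- expression_matrix(x2)
  p2 <- train_panel(x2, labels)
  expect_equal(p2$weight[p2$probe_id == "p2"], 0)
  swapped <- train_panel(x2, class_labels(c(2L, 2L, 1L, 1L), c("A", "B")))
  expect_equal(swapped$weight[match(p2$probe_id, swapped$probe_id)],
               -p2$weight)
  expect_equal(swapped$boundary[match(p2$probe_id, swapped$probe_id)],
               p2$boundary)
})

test_that("panels order probes by |weight| with id tie-breaks and drop degenerates", {
  x <- expression_matrix(matrix(
    c(0, 2, -2, 0,   # w = 1
      5, 5, 5, 5,    # degenerate: zero spread both classes
      0, 1, 1, 0,    # equal class means: w = 0
      2, 0, 0, -2),  # w = 1 (tie with row 1)
    4, 4, byrow = TRUE,
    dimnames = list(c("pb", "pz", "pc", "pa"), paste0("s", 1:4))))
  labels <- class_labels(c(1L, 1L, 2L, 2L), c("A", "B"))
  expect_message(panel <- train_panel(x, labels), "zero spread")
  expect_false("pz" %in% panel$probe_id)
  expect_identical(panel$probe_id[1:2], c("pa", "pb")) # tie broken by id
  expect_true(all(diff(abs(panel$weight)) <= 1e-12))
})

test_that("prediction strength follows the vote-margin formula", {
  panel <- make_panel(c(1, 1), c(0, 0))
  # votes 3 (class A) and -1 (class B): PS = (3 - 1)/(3 + 1)
  pred <- predict(panel, c(p01 = 3, p02 = -1))
  expect_identical(pred$predicted, "A")
  expect_equal(pred$v_win, 3)
  expect_equal(pred$v_lose, 1)
  expect_equal(pred$ps, 0.5)

  # single decisive vote: PS = 1
  one <- make_panel(1, 0)
  p1 <- predict(one, c(p01 = 1))
  expect_identical(p1$predicted, "A")
  expect_equal(p1$ps, 1)

  # exact tie: undecided, PS = 0
  tie <- predict(panel, c(p01 = 1, p02 = -1))
  expect_true(is.na(tie$predicted))
  expect_equal(tie$ps, 0)

  expect_error(predict(panel, c(p01 = 1)), "missing panel probe")
  expect_error(predict(panel, c(p01 = 1, p02 = 2), top_k = 3), "top_k")
})

test_that("predict agrees exactly with the brute-force vote oracle", {
  set.seed(101)
  for (rep in 1:50) {
    k <- 20
    w <- rnorm(k)
    b <- rnorm(k)
    panel <- make_panel(w, b)
    x <- rnorm(k)
    names(x) <- sprintf("p%02d", 1:k)
    pred <- predict(panel, x)
    oracle <- oracle_vote(panel$weight, panel$boundary,
                          x[panel$probe_id])
    expect_equal(pred$v_win, max(oracle$v1, oracle$v2), tolerance = 1e-12)
    expect_equal(pred$v_lose, min(oracle$v1, oracle$v2), tolerance = 1e-12)
    expect_identical(pred$predicted_index, oracle$winner)
    expect_equal(pred$ps, oracle$ps, tolerance = 1e-12)
    expect_gte(pred$ps, 0)
    expect_lte(pred$ps, 1)
  }
})

test_that("class calls are invariant under positive rescaling of the data", {
  fix <- shifted_matrix(seed = 5)
  panel <- train_panel(fix$expr, fix$labels)
  scaled_panel <- train_panel(expression_matrix(fix$expr * 3), fix$labels)
  p1 <- predict(panel, fix$expr)
  p2 <- predict(scaled_panel, expression_matrix(fix$expr * 3))
  expect_identical(p1$predicted, p2$predicted)
  expect_equal(p1$ps, p2$ps, tolerance = 1e-9)
})

test_that("LOOCV is zero on separable data and invariant to sample order", {
  fix <- shifted_matrix(n_shift = 20, delta = 4, sd = 0.2, seed = 6)
  cv <- loocv_error(fix$expr, fix$labels, top_k = 10)
  expect_identical(cv$error, 0)
  expect_true(all(cv$predictions$correct))

  perm <- sample(ncol(fix$expr))
  labp <- class_labels(fix$labels$labels[perm], fix$labels$class_names)
  cvp <- loocv_error(fix$expr[, perm], labp, top_k = 10)
  expect_identical(cvp$error, cv$error)

  expect_error(loocv_error(fix$expr[, 1:3],
                           class_labels(c(1L, 1L, 2L), c("A", "B"))),
               "at least 4")
})

test_that("the biased fixed-ranking LOOCV variant is at least as optimistic", {
  set.seed(12)
  x <- expression_matrix(matrix(rnorm(200 * 16), 200, 16,
                                dimnames = list(sprintf("p%03d", 1:200),
                                                sprintf("s%02d", 1:16))))
  labels <- simulate_null_labels(16, seed = 12)
  fair <- loocv_error(x, labels, top_k = 20)$error
  biased <- loocv_error(x, labels, top_k = 20, refit_ranking = FALSE)$error
  expect_lte(biased, fair)
})

test_that("panel_scan selects the largest size among error minimizers", {
  fix <- shifted_matrix(n_probes = 80, n_shift = 25, delta = 4, sd = 0.2,
                        seed = 7)
  scan <- panel_scan(fix$expr, fix$labels, c(5, 10, 20, 40))
  expect_identical(scan$min_error, 0)
  expect_identical(scan$selected, 40L) # all sizes separate: largest wins
  # scan errors agree with loocv_error run size by size
  for (k in scan$sizes) {
    expect_identical(scan$errors[scan$sizes == k],
                     loocv_error(fix$expr, fix$labels, top_k = k)$error)
  }
  single <- panel_scan(fix$expr, fix$labels, 10)
  expect_identical(single$selected, 10L)
  expect_error(panel_scan(fix$expr, fix$labels, integer(0)), "at least one")
})

test_that("permutation test is reproducible and bounded by its formula", {
  fix <- shifted_matrix(n_probes = 60, n_shift = 20, delta = 4, sd = 0.2,
                        seed = 9)
  pt <- permutation_test(fix$expr, fix$labels, top_k = 10, B = 99, seed = 17)
  expect_identical(pt$p_value,
                   (1 + sum(pt$null_errors <= pt$observed_error)) / 100)
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  # strongly separated classes: observed error 0, p at most modest
  expect_identical(pt$observed_error, 0)
  expect_lte(pt$p_value, 0.05)
  pt2 <- permutation_test(fix$expr, fix$labels, top_k = 10, B = 99, seed = 17)
  expect_identical(pt2$null_errors, pt$null_errors)
  expect_error(permutation_test(fix$expr, fix$labels, B = 99), "seed")
})

test_that("validation of a frozen panel reproduces resubstitution and guards input", {
  fix <- shifted_matrix(seed = 13)
  panel <- train_panel(fix$expr, fix$labels)
  val <- validate_panel(panel, fix$expr, fix$labels, top_k = 10)
  resub <- predict(panel, fix$expr, top_k = 10)
  expect_identical(val$predictions$predicted, resub$predicted)
  expect_equal(val$error,
               mean(resub$predicted != fix$labels$class_names[fix$labels$labels]))
  expect_identical(sum(val$confusion), ncol(fix$expr))

  missing_probe <- fix$expr[-1, ]
  expect_error(validate_panel(panel, expression_matrix(missing_probe),
                              fix$labels),
               "missing panel probe")
})

test_that("held-out validation error tracks the LOOCV estimate on a fresh cohort", {
  d <- cohort_design(n_young = 15, n_elderly = 15, n_probes = 400,
                     n_age_de = 25, n_tumor_de = 25, overlap = 10,
                     effect_size_log2 = 1, noise_sd_log2 = 0.6,
                     n_axis = 50, n_reference = 2, seed = 41)
  train <- simulate_cohort(d)
  fresh <- simulate_cohort(d, cohort_seed = 42)
  age <- cohort_contrast(train, "age")
  cv <- loocv_error(age$expr, age$labels, top_k = 20)
  panel <- train_panel(age$expr, age$labels)
  fresh_age <- cohort_contrast(fresh, "age")
  val <- validate_panel(panel, fresh_age$expr, fresh_age$labels, top_k = 20)
  n <- ncol(fresh_age$expr)
  p_hat <- max(cv$error, 1 / n)
  se <- sqrt(p_hat * (1 - p_hat) / n)
  expect_lte(abs(val$error - cv$error), 2 * se + 1e-9)
})
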