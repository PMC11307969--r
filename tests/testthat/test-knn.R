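toy_reference <- function() {
  set.seed(12)
  expr <- matrix(runif(5 * 4, 1, 100), 5, 4,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("r%d", 1:4)))
  expr
}

ranking_from_labels <- function(labels_best_to_worst) {
  # synthetic ranking with strictly decreasing rho and generic sample ids
  n <- length(labels_best_to_worst)
  ids <- sprintf("r%02d", seq_len(n))
  structure(data.frame(sample_id = ids, rho = seq(1, -1, length.out = n),
                       stringsAsFactors = FALSE),
            query_id = "q", class = c("neighbor_ranking", "data.frame"))
}

labels_for <- function(labs) {
  stats::setNames(labs, sprintf("r%02d", seq_along(labs)))
}

test_that("spearman_rho matches trivial and hand-derived cases", {
  x <- c(2, 5, 9, 11)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, rev(x)), -1)
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_rho(c(3, 3, 3), c(1, 2, 3)), "constant")
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("spearman_rho equals the closed-form rank formula on all length-4 permutations", {
  x <- c(3, 8, 20, 41)
  perms <- pdxomics:::.all_permutations(4)
  for (i in seq_len(nrow(perms))) {
    y <- x[perms[i, ]]
    expect_equal(spearman_rho(x, y), oracle_spearman_distinct(x, y))
  }
})

test_that("spearman_rho averages ranks under ties (hand-computed fixture)", {
  x <- c(1, 2, 2, 4, 5)
  y <- c(3, 3, 5, 6, 6)
  # ranks x: 1, 2.5, 2.5, 4, 5; ranks y: 1.5, 1.5, 3, 4.5, 4.5
  rx <- c(1, 2.5, 2.5, 4, 5)
  ry <- c(1.5, 1.5, 3, 4.5, 4.5)
  expect_equal(spearman_rho(x, y), oracle_pearson(rx, ry))
  expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
})

test_that("rank_neighbors orders by rho with id tie-break and matches the pairwise oracle", {
  expr <- toy_reference()
  q <- expr[, 1] * 3 + 0.01 # monotone image of reference sample r1
  rk <- rank_neighbors(q, expr, query_id = "q")
  expect_identical(rk$sample_id[1], "r1")
  expect_equal(rk$rho[1], 1)
  expect_equal(nrow(rk), 4)

  oracle_rho <- vapply(colnames(expr), function(s) oracle_spearman(q, expr[, s]),
                       numeric(1))
  expect_equal(stats::setNames(rk$rho, rk$sample_id),
               oracle_rho[order(-oracle_rho, names(oracle_rho))])

  # exactly equal rho -> deterministic id order
  dup <- cbind(expr, expr[, 4, drop = FALSE])
  colnames(dup) <- c(colnames(expr), "r0")
  rk2 <- rank_neighbors(q, dup)
  tied <- rk2$sample_id[rk2$rho == rk2$rho[match("r4", rk2$sample_id)]]
  expect_identical(tied, sort(tied))
})

test_that("constant reference samples are excluded with a warning, constant query errors", {
  expr <- toy_reference()
  expr[, 2] <- 7
  expect_warning(rk <- rank_neighbors(expr[, 1], expr[, -1]), "constant")
  expect_false("r2" %in% rk$sample_id)
  expect_error(rank_neighbors(rep(1, 5), expr[, -2]), "constant")
})

test_that("classify_knn applies the worst-neighbor tie-break iteratively", {
  # degenerate k = 1: top neighbor's label, no removal
  rk <- ranking_from_labels(c("A", "B", "A"))
  labs <- labels_for(c("A", "B", "A"))
  res <- classify_knn(rk, labs, k = 1)
  expect_identical(res$predicted_label, "A")
  expect_identical(res$removed_for_tiebreak, 0L)

  # hand-simulated tie-break: (A,A,B,B,A,B) at k=6 -> 3-3 tie,
  # drop worst (B), A wins 3-2 on the remaining five
  rk6 <- ranking_from_labels(c("A", "A", "B", "B", "A", "B"))
  labs6 <- labels_for(c("A", "A", "B", "B", "A", "B"))
  res6 <- classify_knn(rk6, labs6, k = 6)
  expect_identical(res6$predicted_label, "A")
  expect_identical(res6$removed_for_tiebreak, 1L)

  # single-class reference: that label for every k
  rk1 <- ranking_from_labels(rep("Z", 5))
  labs1 <- labels_for(rep("Z", 5))
  for (k in 1:5) {
    expect_identical(classify_knn(rk1, labs1, k)$predicted_label, "Z")
  }

  # (A,B,A,B) at k=4: one removal leaves A=2, B=1
  rk4 <- ranking_from_labels(c("A", "B", "A", "B"))
  labs4 <- labels_for(c("A", "B", "A", "B"))
  res4 <- classify_knn(rk4, labs4, k = 4)
  expect_identical(res4$predicted_label, "A")
  expect_identical(res4$removed_for_tiebreak, 1L)

  # (A,B,B,A) at k=4 needs two removals: one drop re-ties at 2-1? no --
  # dropping the worst A leaves (A,B,B): B wins after a single removal;
  # a genuine two-step case is (A,A,B,B,C,C) at k=6
  rk6c <- ranking_from_labels(c("A", "A", "B", "B", "C", "C"))
  labs6c <- labels_for(c("A", "A", "B", "B", "C", "C"))
  res6c <- classify_knn(rk6c, labs6c, k = 6)
  expect_identical(res6c$predicted_label, "A")
  expect_identical(res6c$removed_for_tiebreak, 3L)

  expect_error(classify_knn(rk4, labs4, k = 0), "positive integer")
  expect_error(classify_knn(rk4, labs4, k = 5), "exceeds")
})

test_that("agreement is counted over the original top-10 window", {
  labs_seq <- c(rep("A", 7), rep("B", 3), rep("A", 5))
  rk <- ranking_from_labels(labs_seq)
  labs <- labels_for(labs_seq)
  res <- classify_knn(rk, labs, k = 15)
  expect_identical(res$predicted_label, "A")
  expect_equal(res$agreement, 0.7)
  expect_equal(agreement_score(rk, labs, "A"), 0.7)
  expect_equal(agreement_score(rk, labs, "B"), 0.3)
  expect_equal(agreement_score(rk, labs, "C"), 0)
  comp <- top_label_composition(rk, labs)
  expect_equal(comp[["A"]], 0.7)
  expect_equal(sum(comp), 1)
})

test_that("agreement takes values on the tenths grid with >= 10 references", {
  set.seed(31)
  for (i in 1:20) {
    labs_seq <- sample(c("A", "B"), 12, replace = TRUE)
    rk <- ranking_from_labels(labs_seq)
    res <- classify_knn(rk, labels_for(labs_seq), k = sample(1:12, 1))
    expect_true(res$agreement %in% ((0:10) / 10))
  }
})

test_that("classification is invariant to monotone transforms and permutations", {
  sim <- simulate_reference_cohort(seed = 21, n_genes = 400, n_per_class = 5)
  ref <- sim$reference
  q <- simulate_query_samples(seed = 22, sim, n_queries = 1)$queries
  base <- classify_cohort(q, ref, k = 3)

  # strictly increasing transform of the query leaves ranks untouched
  for (f in list(function(v) v^3, function(v) log1p(v), function(v) 5 * v + 2)) {
    qq <- q
    qq[, 1] <- f(qq[, 1])
    expect_identical(classify_cohort(qq, ref, k = 3)$predicted_label,
                     base$predicted_label)
  }

  # consistent gene shuffle and reference sample shuffle change nothing
  set.seed(23)
  pg <- sample(rownames(ref$expression))
  ps <- sample(colnames(ref$expression))
  ref2 <- reference_cohort(ref$expression[pg, ps], ref$labels[ps], ref$metadata)
  shuffled <- classify_cohort(q[pg, , drop = FALSE], ref2, k = 3)
  expect_identical(shuffled$predicted_label, base$predicted_label)
  expect_identical(shuffled$agreement, base$agreement)
})

test_that("classify_knn agrees with the brute-force oracle on random small cohorts", {
  for (seed in 0:99) {
    case <- random_small_cohort(seed)
    rk <- rank_neighbors(case$query, case$expr)
    got <- classify_knn(rk, case$labels, case$k)
    want <- oracle_knn(case$query, case$expr, case$labels, case$k)
    expect_identical(got$predicted_label, want$predicted,
                     label = sprintf("prediction at seed %d", seed))
    expect_identical(got$removed_for_tiebreak, as.integer(want$removed),
                     label = sprintf("tie-break count at seed %d", seed))
  }
})

test_that("LOOCV selects k by mean accuracy with smallest-k ties", {
  sim <- simulate_reference_cohort(seed = 1)
  rep1 <- loocv_select_k(sim$reference, categories = "class", k_grid = 5)
  expect_identical(rep1$chosen_k, 5L) # singleton grid

  rep2 <- loocv_select_k(sim$reference, categories = "class", k_grid = 1:14)
  # strongly separable cohort: perfect for every k below the class size
  expect_true(all(rep2$accuracy == 1))
  expect_identical(rep2$chosen_k, 1L) # all tie -> smallest

  expect_error(loocv_select_k(sim$reference, categories = "class",
                              k_grid = integer()), "empty")
  expect_error(loocv_select_k(sim$reference, categories = "nope"), "unknown")
})

test_that("LOOCV on shuffled labels sits at chance level", {
  sim <- simulate_reference_cohort(seed = 2)
  set.seed(77)
  shuffled <- sim$reference
  shuffled$metadata$class[] <- sample(shuffled$metadata$class)
  rep <- loocv_select_k(shuffled, categories = "class", k_grid = 6)
  n <- ncol(shuffled$expression)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(rep$accuracy[1, 1] - 1 / 3), 3 * se)
})

test_that("samples missing a subgroup label are excluded from that category", {
  sim <- simulate_reference_cohort(seed = 4, n_per_class = 6)
  partial <- sim$reference$metadata$class
  partial <- partial[-(1:3)] # drop labels for three samples
  ref <- reference_cohort(sim$reference$expression, sim$reference$labels,
                          list(partial = partial))
  rep <- loocv_select_k(ref, categories = "partial", k_grid = 3)
  expect_true(rep$accuracy[1, 1] >= 0 && rep$accuracy[1, 1] <= 1)
  # with k >= the labeled-sample count the precondition fails
  expect_error(loocv_select_k(ref, categories = "partial", k_grid = 15), "below")
})

test_that("classify_cohort handles batches, empty input and per-query failures", {
  sim <- simulate_reference_cohort(seed = 5, n_per_class = 4)
  ref <- sim$reference

  empty <- ref$expression[, 0, drop = FALSE]
  out0 <- classify_cohort(empty, ref, k = 3)
  expect_identical(nrow(out0), 0L)

  # a reference sample duplicated as query at k = 1 recovers its own label
  q <- ref$expression[, c(1, 5), drop = FALSE]
  colnames(q) <- c("q1", "q2")
  out <- classify_cohort(q, ref, k = 1)
  expect_identical(out$predicted_label,
                   unname(ref$labels[colnames(ref$expression)[c(1, 5)]]))

  # one poisoned query does not abort the batch
  qbad <- cbind(q, bad = rep(1, nrow(q)))
  out2 <- suppressWarnings(classify_cohort(qbad, ref, k = 1))
  expect_identical(nrow(out2), 2L)
  expect_match(attr(out2, "errors")[["bad"]], "constant")
})

test_that("the refknn model interface wraps fit and predict coherently", {
  sim <- simulate_reference_cohort(seed = 6, n_per_class = 5)
  fit <- refknn(sim$reference, k = 6)
  q <- simulate_query_samples(seed = 61, sim, n_queries = 6)
  pred <- predict(fit, q$queries)
  expect_identical(pred, classify_cohort(q$queries, sim$reference, k = 6))
  expect_identical(predict(fit, q$queries, k = 3)$k, rep(3L, 6))
  expect_output(print(fit), "k = 6")
  expect_output(print(summary(fit)), "class sizes")
  expect_error(refknn(sim$reference, k = 0), "positive integer")
  one_class <- reference_cohort(sim$reference$expression,
                                stats::setNames(rep("A", ncol(sim$reference$expression)),
                                                colnames(sim$reference$expression)))
  expect_error(refknn(one_class), "2 distinct")
})
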