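#' Spearman rank correlation
#'
#' Pearson correlation of average-fractional ranks. A constant input vector
#' makes the correlation undefined and raises an error rather than silently
#' returning 0.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A single correlation in \[-1, 1\].
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
spearman_rho <- function(x, y) {
  .assert(length(x) == length(y), "x and y must have equal length")
  .assert(length(x) >= 2, "need >= 2 observations for rank correlation")
  .assert(!anyNA(x) && !anyNA(y), "missing values not allowed")
  rx <- rank(x)
  ry <- rank(y)
  .assert(stats::sd(rx) > 0 && stats::sd(ry) > 0,
          "Spearman correlation undefined: constant input vector")
  stats::cor(rx, ry)
}

#' Rank reference samples by correlation with a query
#'
#' Computes the Spearman correlation between one query expression profile and
#' every reference sample over their (already intersected) common genes, and
#' returns the reference samples sorted by correlation, best first. Exactly
#' equal correlations are ordered by reference sample id so the ranking is
#' deterministic across runs and platforms. Reference samples with constant
#' expression have no defined correlation and are dropped with a warning.
#'
#' @param query Numeric vector of expression values, named by gene, or a
#'   one-column matrix.
#' @param reference Numeric genes-by-samples matrix over the same genes.
#' @param query_id Identifier used in the result (defaults to the column name
#'   or `"query"`).
#' @return An object of class `"neighbor_ranking"`: a data.frame with columns
#'   `sample_id` and `rho`, sorted by decreasing `rho`.
#' @export
rank_neighbors <- function(query, reference, query_id = NULL) {
  if (is.matrix(query)) {
    .assert(ncol(query) == 1, "query must be a single expression profile")
    if (is.null(query_id)) query_id <- colnames(query)
    query <- stats::setNames(query[, 1], rownames(query))
  }
  if (is.null(query_id)) query_id <- "query"
  .assert(is.matrix(reference) && !is.null(colnames(reference)),
          "reference must be a matrix with sample colnames")
  .assert(length(query) == nrow(reference),
          "query and reference must cover the same genes")
  if (!is.null(names(query)) && !is.null(rownames(reference))) {
    .assert(identical(names(query), rownames(reference)),
            "query and reference gene ids are not aligned")
  }
  .assert(length(query) >= 2, "need >= 2 genes")
  rq <- rank(query)
  .assert(stats::sd(rq) > 0,
          "query '", query_id, "' has constant expression; correlation undefined")
  rr <- apply(reference, 2, rank)
  ok <- apply(rr, 2, stats::sd) > 0
  if (!all(ok)) {
    warning("excluding reference sample(s) with constant expression: ",
            .fmt_ids(colnames(reference)[!ok]))
    rr <- rr[, ok, drop = FALSE]
  }
  .assert(ncol(rr) >= 1, "all reference samples had undefined correlation")
  rho <- as.vector(stats::cor(rq, rr))
  ids <- colnames(rr)
  ord <- order(-rho, ids)
  structure(
    data.frame(sample_id = ids[ord], rho = rho[ord], stringsAsFactors = FALSE),
    query_id = query_id,
    class = c("neighbor_ranking", "data.frame")
  )
}

#' Majority-vote k-NN classification with worst-neighbor tie-breaking
#'
#' Predicts the plurality label among the `k` most strongly correlated
#' reference samples. A tied plurality is resolved by dropping the single
#' worst-correlated sample in the current window and re-voting; the removal
#' iterates until the plurality is unique (guaranteed at window size 1).
#' The agreement score is the proportion of the top 10 most strongly
#' correlated samples (the original ranking, before any tie-break removal)
#' that carry the final predicted label.
#'
#' @param ranking A `"neighbor_ranking"` from [rank_neighbors()].
#' @param labels Named character vector mapping reference sample ids to class
#'   labels; must cover every ranked sample.
#' @param k Number of neighbors to vote, `1 <= k <= nrow(ranking)`.
#' @return An object of class `"knn_classification"`: a list with
#'   `query_id`, `predicted_label`, `k_used`, `agreement`,
#'   `top_neighbor_labels` (first `max(k, 10)` labels) and
#'   `removed_for_tiebreak`.
#' @export
classify_knn <- function(ranking, labels, k) {
  .assert(inherits(ranking, "neighbor_ranking"), "ranking must come from rank_neighbors()")
  n <- nrow(ranking)
  .assert(n >= 1, "empty neighbor ranking")
  .assert(length(k) == 1 && k >= 1 && k == floor(k), "k must be a positive integer")
  .assert(k <= n, "k = ", k, " exceeds the ", n, " available reference samples")
  missing <- setdiff(ranking$sample_id, names(labels))
  .assert(length(missing) == 0, "no label for reference sample(s): ", .fmt_ids(missing))
  labs <- as.character(labels[ranking$sample_id])

  window <- labs[seq_len(k)]
  removed <- 0L
  repeat {
    tab <- table(window)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) {
      predicted <- winners
      break
    }
    window <- window[-length(window)] # drop the worst-correlated in the window
    removed <- removed + 1L
  }

  top_n <- min(10L, n)
  structure(list(
    query_id = attr(ranking, "query_id"),
    predicted_label = predicted,
    k_used = as.integer(k),
    agreement = mean(labs[seq_len(top_n)] == predicted),
    top_neighbor_labels = labs[seq_len(min(max(k, 10L), n))],
    removed_for_tiebreak = removed
  ), class = "knn_classification")
}

#' Agreement of a prediction with the top correlated neighbors
#'
#' Fraction of the `top_n` most strongly correlated reference samples whose
#' label equals the predicted label. When fewer than `top_n` neighbors exist,
#' all of them are used.
#'
#' @inheritParams classify_knn
#' @param predicted Predicted class label.
#' @param top_n Window size; the conventional agreement window is 10.
#' @return A fraction in \[0, 1\].
#' @export
agreement_score <- function(ranking, labels, predicted, top_n = 10) {
  .assert(nrow(ranking) >= 1, "empty neighbor ranking")
  labs <- as.character(labels[ranking$sample_id])
  .assert(!anyNA(labs), "missing labels for ranked samples")
  idx <- seq_len(min(top_n, length(labs)))
  mean(labs[idx] == predicted)
}

#' Composition of the top correlated neighbors by label
#'
#' By-label histogram of the first `top_n` entries of a ranking: the fraction
#' of the agreement window occupied by each reference class.
#'
#' @inheritParams agreement_score
#' @return Named numeric vector of fractions summing to 1.
#' @export
top_label_composition <- function(ranking, labels, top_n = 10) {
  .assert(nrow(ranking) >= 1, "empty neighbor ranking")
  labs <- as.character(labels[ranking$sample_id])
  idx <- seq_len(min(top_n, length(labs)))
  tab <- table(labs[idx])
  stats::setNames(as.numeric(tab) / length(idx), names(tab))
}

# Internal: vote on a precomputed (rho-desc, id-tiebroken) label sequence.
# Same rule as classify_knn but without the ranking-object plumbing; used by
# the LOOCV loop where rankings are derived from a cached correlation matrix.
.vote_knn <- function(labs, k) {
  window <- labs[seq_len(k)]
  repeat {
    tab <- table(window)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) return(winners)
    window <- window[-length(window)]
  }
}

#' Leave-one-out cross-validated selection of k
#'
#' Each cohort sample is held out in turn and classified against the rest by
#' Spearman k-NN, separately for every metadata category and every candidate
#' k. A sample missing a subgroup label in a category is excluded from that
#' category entirely (it neither votes nor is scored). The chosen k maximizes
#' the mean accuracy across categories, ties going to the smallest k.
#'
#' @param reference A [reference_cohort()].
#' @param categories Character vector of metadata category names to assess;
#'   defaults to all categories of the cohort.
#' @param k_grid Candidate values of k (positive integers).
#' @return An object of class `"loocv_report"`: list with `k_grid`,
#'   `accuracy` (categories x k matrix) and `chosen_k`.
#' @export
loocv_select_k <- function(reference, categories = names(reference$metadata),
                           k_grid = 1:25) {
  .assert(inherits(reference, "reference_cohort"), "reference must be a reference_cohort")
  .assert(length(k_grid) >= 1, "k_grid must not be empty")
  .assert(all(k_grid >= 1 & k_grid == floor(k_grid)), "k_grid must contain positive integers")
  .assert(length(categories) >= 1, "no metadata categories to assess")
  missing_cat <- setdiff(categories, names(reference$metadata))
  .assert(length(missing_cat) == 0, "unknown metadata categories: ", .fmt_ids(missing_cat))
  k_grid <- sort(unique(as.integer(k_grid)))

  expr <- reference$expression
  ids <- colnames(expr)
  # one rank pass per sample, then all pairwise Spearman correlations at once
  rr <- apply(expr, 2, rank)
  sds <- apply(rr, 2, stats::sd)
  .assert(all(sds > 0), "constant-expression cohort sample(s): ",
          .fmt_ids(ids[sds == 0]))
  C <- stats::cor(rr)

  acc <- matrix(NA_real_, length(categories), length(k_grid),
                dimnames = list(categories, as.character(k_grid)))
  for (cat in categories) {
    sub <- reference$metadata[[cat]]
    sub <- sub[!is.na(sub)]
    sub <- sub[names(sub) %in% ids]
    .assert(length(unique(sub)) >= 2,
            "category '", cat, "' needs >= 2 subgroups with labeled samples")
    members <- names(sub)
    .assert(max(k_grid) < length(members),
            "max(k_grid) must be below the ", length(members),
            " labeled samples of category '", cat, "'")
    hits <- matrix(0L, length(members), length(k_grid))
    for (i in seq_along(members)) {
      s <- members[i]
      others <- setdiff(members, s)
      rho <- C[s, others]
      ord <- order(-rho, others)
      labs <- as.character(sub[others[ord]])
      for (j in seq_along(k_grid)) {
        hits[i, j] <- as.integer(.vote_knn(labs, k_grid[j]) == sub[[s]])
      }
    }
    acc[cat, ] <- colMeans(hits)
  }

  mean_acc <- colMeans(acc)
  chosen_k <- k_grid[which.max(mean_acc)] # ties resolve to the smallest k
  structure(list(k_grid = k_grid, accuracy = acc, chosen_k = chosen_k),
            class = "loocv_report")
}

#' Classify a batch of query samples against a reference cohort
#'
#' Restricts queries and reference to their shared (coding) genes, ranks the
#' reference by Spearman correlation per query and applies the k-NN majority
#' vote. A failing query (for example one with constant expression) does not
#' abort the batch: it is reported in the `"errors"` attribute of the result.
#'
#' @param queries Numeric genes-by-samples matrix of query profiles.
#' @param reference A [reference_cohort()].
#' @param k Number of neighbors (6 is the conventional pan-cancer choice; 15
#'   was optimal for pancreatic-adenocarcinoma subtype metadata).
#' @param genes Optional gene-model table for coding-gene restriction.
#' @return A data.frame with one row per classified query: `query_id`,
#'   `predicted_label`, `k`, `agreement`, `removed_for_tiebreak` and
#'   `top10_labels` (comma-separated). Failed queries are recorded as a named
#'   character vector in `attr(result, "errors")`.
#' @export
classify_cohort <- function(queries, reference, k = 6, genes = NULL) {
  .assert(inherits(reference, "reference_cohort"), "reference must be a reference_cohort")
  if (ncol(queries) == 0) {
    out <- data.frame(query_id = character(), predicted_label = character(),
                      k = integer(), agreement = numeric(),
                      removed_for_tiebreak = integer(),
                      top10_labels = character(), stringsAsFactors = FALSE)
    attr(out, "errors") <- character()
    return(out)
  }
  common <- intersect_coding_genes(queries, reference$expression, genes)
  results <- list()
  errors <- character()
  for (q in colnames(common$a)) {
    res <- tryCatch({
      ranking <- rank_neighbors(common$a[, q, drop = FALSE], common$b)
      classify_knn(ranking, reference$labels, k)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[q] <- conditionMessage(res)
    } else {
      results[[q]] <- data.frame(
        query_id = q,
        predicted_label = res$predicted_label,
        k = res$k_used,
        agreement = res$agreement,
        removed_for_tiebreak = res$removed_for_tiebreak,
        top10_labels = paste(res$top_neighbor_labels[seq_len(min(10, length(res$top_neighbor_labels)))],
                             collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(results, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(query_id = character(), predicted_label = character(),
                      k = integer(), agreement = numeric(),
                      removed_for_tiebreak = integer(),
                      top10_labels = character(), stringsAsFactors = FALSE)
  }
  attr(out, "errors") <- errors
  out
}
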