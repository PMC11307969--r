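#' Construct a labeled reference cohort
#'
#' Bundles a genes-by-samples expression matrix with per-sample class labels
#' and optional named metadata categories (each a named vector of subgroup
#' labels covering a subset of samples).
#'
#' @param expression Numeric genes-by-samples matrix (see [read_expression()]).
#' @param labels Named character vector, one class label per expression sample.
#' @param metadata Named list of named character vectors; each element is a
#'   metadata category mapping sample ids to subgroup labels. Samples absent
#'   from a category are simply unlabeled there.
#' @return An object of class `"reference_cohort"`.
#' @export
reference_cohort <- function(expression, labels, metadata = list()) {
  validate_expression(expression)
  labels <- stats::setNames(as.character(labels), names(labels))
  missing <- setdiff(colnames(expression), names(labels))
  .assert(length(missing) == 0, "unlabeled reference sample(s): ", .fmt_ids(missing))
  labels <- labels[colnames(expression)]
  .assert(!anyNA(labels), "NA labels are not allowed")
  .assert(is.list(metadata), "metadata must be a named list of named vectors")
  if (length(metadata) > 0) {
    .assert(!is.null(names(metadata)) && all(nzchar(names(metadata))),
            "every metadata category needs a name")
    for (cat in names(metadata)) {
      extra <- setdiff(names(metadata[[cat]]), colnames(expression))
      .assert(length(extra) == 0, "metadata category '", cat,
              "' labels unknown sample(s): ", .fmt_ids(extra))
    }
  }
  structure(list(expression = expression, labels = labels, metadata = metadata),
            class = "reference_cohort")
}

#' @export
print.reference_cohort <- function(x, ...) {
  cat("Reference cohort:", ncol(x$expression), "samples,",
      nrow(x$expression), "genes\n")
  cat("Classes:", paste(names(table(x$labels)), table(x$labels),
                        sep = "=", collapse = ", "), "\n")
  if (length(x$metadata) > 0) {
    cat("Metadata categories:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read reference labels from TSV
#'
#' Two-column `sample_id`, `label` table.
#'
#' @param path Path to the TSV.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("sample_id", "label") %in% names(df)),
          "label table needs columns sample_id and label")
  stats::setNames(as.character(df$label), as.character(df$sample_id))
}

#' Read sample metadata from long-format TSV
#'
#' Three-column `sample_id`, `category`, `subgroup` table; returns the named
#' list of per-category subgroup maps that [reference_cohort()] expects.
#'
#' @param path Path to the TSV.
#' @return Named list of named character vectors.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("sample_id", "category", "subgroup") %in% names(df)),
          "metadata table needs columns sample_id, category, subgroup")
  lapply(split(df, df$category), function(d) {
    stats::setNames(as.character(d$subgroup), as.character(d$sample_id))
  })
}

#' Fit a Spearman k-nearest-neighbor reference classifier
#'
#' The "fit" of a reference-cohort k-NN classifier is the cohort itself plus
#' the choice of k: prediction ranks the cohort by Spearman correlation with
#' each query over the shared coding genes and takes the (tie-broken)
#' majority label among the top k. `k` can be fixed directly or selected by
#' leave-one-out cross-validation over metadata categories with
#' [loocv_select_k()].
#'
#' @param expression Reference genes-by-samples matrix, or a
#'   [reference_cohort()] (in which case `labels`/`metadata` are taken from
#'   it).
#' @param labels Named character vector of class labels (ignored when
#'   `expression` is already a cohort).
#' @param k Number of neighbors to vote at prediction time; default 6.
#' @param metadata Optional named list of metadata categories.
#' @param genes Optional gene-model table used to restrict predictions to
#'   coding genes.
#' @return An object of class `"refknn"` with `predict`, `print` and
#'   `summary` methods.
#' @examples
#' sim <- simulate_reference_cohort(seed = 1)
#' fit <- refknn(sim$reference, k = 6)
#' qs <- sim$reference$expression[, 1:2]
#' predict(fit, qs)
#' @export
refknn <- function(expression, labels = NULL, k = 6, metadata = list(),
                   genes = NULL) {
  cohort <- if (inherits(expression, "reference_cohort")) {
    expression
  } else {
    reference_cohort(expression, labels, metadata)
  }
  .assert(length(unique(cohort$labels)) >= 2,
          "classification needs >= 2 distinct reference classes")
  .assert(length(k) == 1 && k >= 1 && k == floor(k) && k <= ncol(cohort$expression),
          "k must be a positive integer no larger than the cohort size")
  structure(list(reference = cohort, k = as.integer(k), genes = genes),
            class = "refknn")
}

#' Predict classes for new samples from a fitted reference k-NN classifier
#'
#' @param object A `"refknn"` fit.
#' @param newdata Numeric genes-by-samples matrix of query profiles.
#' @param k Override of the fitted k.
#' @param ... Unused.
#' @return The [classify_cohort()] data.frame of per-query results.
#' @export
predict.refknn <- function(object, newdata, k = object$k, ...) {
  classify_cohort(newdata, object$reference, k = k, genes = object$genes)
}

#' @export
print.refknn <- function(x, ...) {
  cat("Spearman k-NN reference classifier (k =", x$k, ")\n")
  print(x$reference)
  invisible(x)
}

#' @export
summary.refknn <- function(object, ...) {
  tab <- table(object$reference$labels)
  structure(list(k = object$k,
                 n_samples = ncol(object$reference$expression),
                 n_genes = nrow(object$reference$expression),
                 class_sizes = tab,
                 categories = names(object$reference$metadata)),
            class = "summary.refknn")
}

#' @export
print.summary.refknn <- function(x, ...) {
  cat("Spearman k-NN reference classifier\n")
  cat("  k:", x$k, "\n")
  cat("  reference:", x$n_samples, "samples x", x$n_genes, "genes\n")
  cat("  class sizes:\n")
  print(x$class_sizes)
  if (length(x$categories) > 0) {
    cat("  metadata categories:", paste(x$categories, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.loocv_report <- function(x, ...) {
  cat("LOOCV k-selection over ", nrow(x$accuracy),
      if (nrow(x$accuracy) == 1) " category" else " categories",
      " and k in {", paste(range(x$k_grid), collapse = ".."), "}\n", sep = "")
  cat("Chosen k:", x$chosen_k, "(mean accuracy",
      round(mean(x$accuracy[, as.character(x$chosen_k)]), 3), ")\n")
  invisible(x)
}

#' Plot LOOCV accuracy against k
#'
#' One line per metadata category plus the across-category mean whose maximum
#' defines the chosen k.
#'
#' @param x A `"loocv_report"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.loocv_report <- function(x, ...) {
  graphics::matplot(x$k_grid, t(x$accuracy), type = "b", pch = 1,
                    xlab = "k", ylab = "LOOCV accuracy", lty = 1, ...)
  graphics::lines(x$k_grid, colMeans(x$accuracy), lwd = 2)
  graphics::abline(v = x$chosen_k, lty = 2)
  graphics::legend("bottomright", legend = c(rownames(x$accuracy), "mean"),
                   col = c(seq_len(nrow(x$accuracy)), 1),
                   lwd = c(rep(1, nrow(x$accuracy)), 2), lty = 1, bty = "n")
  invisible(x)
}
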