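#' Read a cell-type proportions table
#'
#' Samples-by-cell-types TSV as emitted by deconvolution tools (first column
#' `sample_id`, remaining columns one per cell type, values in \[0, 1\]).
#'
#' @param path Path to the TSV.
#' @param source Optional tool name recorded as the `"source"` attribute.
#' @return Numeric samples-by-cell-types matrix.
#' @export
read_proportions <- function(path, source = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  validate_proportions(m)
  attr(m, "source") <- source
  m
}

validate_proportions <- function(p) {
  .assert(is.matrix(p) && is.numeric(p), "proportions must be a numeric matrix")
  .assert(!is.null(rownames(p)) && !is.null(colnames(p)),
          "proportions need sample rownames and cell-type colnames")
  .assert(!anyNA(p), "proportions contain missing values")
  .assert(all(p >= 0), "proportions must be non-negative")
  .assert(all(rowSums(p) <= 1 + 1e-6),
          "row sums exceed 1 for sample(s): ",
          .fmt_ids(rownames(p)[rowSums(p) > 1 + 1e-6]))
  invisible(p)
}

#' Harmonize cell-type names across deconvolution tools
#'
#' Renames (and merges, by summation) proportion columns according to a
#' user-supplied mapping, e.g. `"Macrophage M0" -> "macrophage"`. Cell types
#' absent from the mapping keep their original name.
#'
#' @param p Proportions matrix.
#' @param mapping Named character vector: `names(mapping)` are source column
#'   names, values the harmonized names. Alternatively a two-column
#'   data.frame `source_name`, `harmonized_name`.
#' @return Proportions matrix with harmonized (possibly merged) columns.
#' @export
harmonize_cell_types <- function(p, mapping) {
  if (is.data.frame(mapping)) {
    mapping <- stats::setNames(as.character(mapping$harmonized_name),
                               as.character(mapping$source_name))
  }
  new_names <- ifelse(colnames(p) %in% names(mapping),
                      mapping[colnames(p)], colnames(p))
  out <- t(rowsum(t(p), group = new_names))
  out <- out[, unique(new_names), drop = FALSE]
  attr(out, "source") <- attr(p, "source")
  out
}

#' Renormalize proportions after excluding cell types
#'
#' Deconvolution of bulk tumor RNA-seq assigns most mass to "uncharacterized"
#' (likely cancer) cells; to compare the remaining composition across samples
#' those columns are dropped and each row rescaled to sum to one.
#'
#' @param p Proportions matrix.
#' @param excluded Character vector of cell-type columns to drop (strict
#'   subset of the columns).
#' @return Renormalized proportions over the retained cell types.
#' @examples
#' p <- matrix(c(0.5, 0.3, 0.2), 1, 3,
#'             dimnames = list("s1", c("uncharacterized", "CAF", "T_cell")))
#' renormalize_excluding(p, "uncharacterized")
#' @export
renormalize_excluding <- function(p, excluded) {
  validate_proportions(p)
  if (length(excluded) == 0) return(p)
  unknown <- setdiff(excluded, colnames(p))
  .assert(length(unknown) == 0, "unknown cell type(s): ", .fmt_ids(unknown))
  keep <- setdiff(colnames(p), excluded)
  .assert(length(keep) >= 1, "cannot exclude every cell type")
  out <- p[, keep, drop = FALSE]
  mass <- rowSums(out)
  .assert(all(mass > 0), "zero remaining mass after exclusion for sample(s): ",
          .fmt_ids(rownames(out)[mass == 0]))
  out <- out / mass
  attr(out, "source") <- attr(p, "source")
  out
}

#' Read a marker set from TSV or JSON-like list
#'
#' Two-column TSV `name`, `gene_id`; all rows must share one set name.
#'
#' @param path Path to the TSV.
#' @return List with `name` and `genes` (unique gene ids).
#' @export
read_marker_set <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("name", "gene_id") %in% names(df)),
          "marker table needs columns name and gene_id")
  .assert(length(unique(df$name)) == 1, "marker table must describe one set")
  marker_set(df$name[1], df$gene_id)
}

#' Construct a marker set
#'
#' @param name Set name, e.g. `"fibroblast"`.
#' @param genes Non-empty character vector of marker gene ids (duplicates are
#'   dropped).
#' @return List with `name` and `genes`.
#' @export
marker_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  .assert(length(genes) >= 1, "marker set must contain >= 1 gene")
  list(name = as.character(name), genes = genes)
}

#' Marker-panel signature score
#'
#' Per-sample mean of `log2(rpkm + 1)` over the marker genes present in the
#' matrix — the construction behind a "fibroblast score". Averaging on the
#' log scale keeps single very highly expressed markers from dominating the
#' panel. Markers absent from the matrix are dropped with a warning; at least
#' one must be present.
#'
#' @param expr RPKM expression matrix (genes x samples).
#' @param markers A [marker_set()] or plain character vector of gene ids.
#' @return Named numeric vector of per-sample scores.
#' @examples
#' expr <- matrix(c(3, 1), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' signature_score(expr, c("g1", "g2")) # (log2(4) + log2(2)) / 2 = 1.5
#' @export
signature_score <- function(expr, markers) {
  validate_expression(expr)
  if (is.list(markers)) markers <- markers$genes
  markers <- unique(as.character(markers))
  present <- intersect(markers, rownames(expr))
  if (length(present) < length(markers)) {
    warning("marker gene(s) absent from expression matrix: ",
            .fmt_ids(setdiff(markers, present)))
  }
  .assert(length(present) >= 1, "no marker gene present in the expression matrix")
  colMeans(log2(expr[present, , drop = FALSE] + 1))
}

# All permutations of 1..n as an (n! x n) integer matrix; used for the exact
# permutation distribution of Spearman's rho at small n.
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  blocks <- lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
  })
  do.call(rbind, blocks)
}

# Two-sided p-value for Spearman's rho: exact permutation distribution for
# n <= exact_max (valid under ties), t-approximation otherwise.
.spearman_p <- function(x, y, exact_max = 9L) {
  n <- length(x)
  rho <- spearman_rho(x, y)
  if (n <= exact_max) {
    rx <- rank(x)
    ry <- rank(y)
    perms <- .all_permutations(n)
    ry_perm <- matrix(ry[perms], nrow(perms))
    rho_all <- as.vector(stats::cor(rx, t(ry_perm)))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = min(p, 1))
}

#' Correlate a signature score with predicted cell-type proportions
#'
#' Benchmarks a deconvolution tool's output: for each cell type, the Spearman
#' correlation between a marker-panel score and that tool's predicted
#' fraction across the shared samples, with a two-sided p-value — exact
#' permutation distribution of rho when n is at most 9 (appropriate for
#' cohorts of ~10 biopsies, where the t-approximation is unreliable),
#' t-approximation otherwise. A constant score or constant proportion column
#' leaves rho undefined (reported as NA).
#'
#' @param scores Named numeric vector from [signature_score()].
#' @param p Proportions matrix (samples x cell types).
#' @param min_n Minimum number of shared samples required.
#' @return Data.frame with one row per cell type: `cell_type`, `n`, `rho`,
#'   `p_value`; the scores used are attached as attribute `"scores"`.
#' @export
correlate_score_with_proportions <- function(scores, p, min_n = 3) {
  validate_proportions(p)
  shared <- intersect(names(scores), rownames(p))
  .assert(length(shared) >= min_n,
          "need >= ", min_n, " shared samples, found ", length(shared))
  s <- scores[shared]
  out <- lapply(colnames(p), function(ct) {
    y <- p[shared, ct]
    if (stats::sd(s) == 0 || stats::sd(y) == 0) {
      data.frame(cell_type = ct, n = length(shared), rho = NA_real_,
                 p_value = NA_real_, stringsAsFactors = FALSE)
    } else {
      r <- .spearman_p(s, y)
      data.frame(cell_type = ct, n = length(shared), rho = r$rho,
                 p_value = r$p_value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  attr(out, "scores") <- s
  out
}
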