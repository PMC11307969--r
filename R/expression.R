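#' Read a genes-by-samples expression matrix from TSV
#'
#' The expected dialect is gene-major: a header row of sample identifiers,
#' a first column of gene identifiers, and one row per gene. Values must be
#' non-negative and gene/sample identifiers unique.
#'
#' @param path Path to a tab-separated expression table.
#' @param unit Unit of the stored values, `"counts"` or `"rpkm"`. Recorded as
#'   the `"unit"` attribute of the returned matrix.
#' @return A numeric matrix (genes x samples) with gene ids as rownames,
#'   sample ids as colnames and a `"unit"` attribute.
#' @seealso [write_expression()], [compute_rpkm()]
#' @export
read_expression <- function(path, unit = c("counts", "rpkm")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(df) >= 2, "expression table needs a gene-id column plus >= 1 sample column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  validate_expression(m)
  attr(m, "unit") <- unit
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: gene ids in the first column (`gene_id`
#' header), sample ids as the remaining column headers. Values are written at
#' full double precision so that a read/write round trip is lossless.
#'
#' @param x Numeric genes-by-samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared validity checks for an expression matrix: numeric, named, unique ids,
# no negative or missing values.
validate_expression <- function(x) {
  .assert(is.matrix(x) && is.numeric(x), "expression must be a numeric matrix")
  .assert(!is.null(rownames(x)) && !is.null(colnames(x)),
          "expression matrix must have gene rownames and sample colnames")
  .assert(!anyDuplicated(rownames(x)), "duplicated gene ids: ",
          .fmt_ids(unique(rownames(x)[duplicated(rownames(x))])))
  .assert(!anyDuplicated(colnames(x)), "duplicated sample ids: ",
          .fmt_ids(unique(colnames(x)[duplicated(colnames(x))])))
  .assert(!anyNA(x), "expression matrix contains missing values")
  .assert(all(x >= 0), "expression matrix contains negative values")
  invisible(x)
}

#' Read a gene-annotation table
#'
#' A two-or-three-column TSV with `gene_id`, `max_transcript_length` (the
#' maximal mature transcript length of the gene, in base pairs) and optionally
#' `is_coding` (logical; assumed `TRUE` when absent). Computing transcript
#' lengths from a GTF is out of scope; this consumes a precomputed table.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with columns `gene_id`, `max_transcript_length`,
#'   `is_coding`.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("gene_id", "max_transcript_length") %in% names(df)),
          "annotation table needs columns gene_id and max_transcript_length")
  if (is.null(df$is_coding)) df$is_coding <- TRUE
  df$is_coding <- as.logical(df$is_coding)
  gene_models(df$gene_id, df$max_transcript_length, df$is_coding)
}

#' Construct a gene-model table
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param max_transcript_length Integer vector (>= 1) of maximal mature
#'   transcript lengths in base pairs.
#' @param is_coding Logical vector; protein-coding status.
#' @return A validated data.frame with one row per gene.
#' @export
gene_models <- function(gene_id, max_transcript_length, is_coding = TRUE) {
  df <- data.frame(gene_id = as.character(gene_id),
                   max_transcript_length = as.numeric(max_transcript_length),
                   is_coding = rep_len(as.logical(is_coding), length(gene_id)),
                   stringsAsFactors = FALSE)
  .assert(!anyDuplicated(df$gene_id), "duplicated gene ids in annotation: ",
          .fmt_ids(unique(df$gene_id[duplicated(df$gene_id)])))
  .assert(!anyNA(df$max_transcript_length) && all(df$max_transcript_length >= 1),
          "max_transcript_length must be >= 1 bp for every gene")
  .assert(!anyNA(df$is_coding), "is_coding must be TRUE/FALSE for every gene")
  df
}

#' Read per-sample library sizes
#'
#' Two-column TSV `sample_id`, `total_reads`. Library sizes are total aligned
#' reads supplied externally rather than inferred as column sums, because
#' intersection-strict counting under-counts the library.
#'
#' @param path Path to the TSV.
#' @return A named numeric vector of library sizes.
#' @export
read_library_sizes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("sample_id", "total_reads") %in% names(df)),
          "library-size table needs columns sample_id and total_reads")
  stats::setNames(as.numeric(df$total_reads), as.character(df$sample_id))
}

#' RPKM normalisation
#'
#' Converts raw gene-level read counts to reads per kilobase of transcript per
#' million mapped reads, using the maximal mature transcript length of each
#' gene:
#' \deqn{RPKM_{gs} = \frac{C_{gs}}{(N_s/10^6)\,(L_g/10^3)}}
#' where \eqn{C_{gs}} is the read count of gene g in sample s, \eqn{N_s} the
#' library size of sample s, and \eqn{L_g} the maximal mature transcript
#' length of gene g in base pairs.
#'
#' @param counts Numeric genes-by-samples count matrix (see
#'   [read_expression()]).
#' @param genes Gene-model table from [gene_models()] / [read_gene_models()];
#'   every gene in `counts` must be annotated.
#' @param library_sizes Named numeric vector of total mapped reads per sample;
#'   every sample in `counts` must be present and positive.
#' @return Matrix of the same shape with `"unit"` attribute `"rpkm"`.
#' @examples
#' counts <- matrix(c(1000, 50), 2, 1,
#'                  dimnames = list(c("g1", "g2"), "s1"))
#' ann <- gene_models(c("g1", "g2"), c(1000, 500))
#' compute_rpkm(counts, ann, c(s1 = 1e6))
#' @export
compute_rpkm <- function(counts, genes, library_sizes) {
  validate_expression(counts)
  missing_genes <- setdiff(rownames(counts), genes$gene_id)
  .assert(length(missing_genes) == 0,
          "no annotation (max transcript length) for gene(s): ",
          .fmt_ids(missing_genes))
  missing_samples <- setdiff(colnames(counts), names(library_sizes))
  .assert(length(missing_samples) == 0,
          "no library size for sample(s): ", .fmt_ids(missing_samples))
  libs <- library_sizes[colnames(counts)]
  .assert(!anyNA(libs) && all(libs > 0),
          "library sizes must be positive for every sample")
  len <- genes$max_transcript_length[match(rownames(counts), genes$gene_id)]
  rpkm <- counts / (rep(libs / 1e6, each = nrow(counts)) * (len / 1e3))
  attr(rpkm, "unit") <- "rpkm"
  rpkm
}

#' Restrict two expression matrices to their shared coding genes
#'
#' Classification against a reference cohort is computed with respect to all
#' coding genes; both matrices are cut down to the identical, identically
#' ordered set of protein-coding genes present in both (ordered as in `a`).
#'
#' @param a,b Expression matrices (genes x samples).
#' @param genes Gene-model table; genes absent from it are treated as
#'   non-coding. `NULL` means all shared genes are used.
#' @return A list with elements `a` and `b`, both restricted to the shared
#'   coding genes.
#' @export
intersect_coding_genes <- function(a, b, genes = NULL) {
  validate_expression(a)
  validate_expression(b)
  shared <- intersect(rownames(a), rownames(b))
  if (!is.null(genes)) {
    coding <- genes$gene_id[genes$is_coding]
    shared <- shared[shared %in% coding]
  }
  .assert(length(shared) >= 2,
          "need >= 2 shared coding genes for rank correlation, found ",
          length(shared))
  list(a = a[shared, , drop = FALSE], b = b[shared, , drop = FALSE])
}
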