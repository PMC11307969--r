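#' Read a MAF-like somatic variant table
#'
#' Tab-separated table with one row per variant call. The native column set
#' is `patient_id`, `sample_id`, `sample_class` (`biopsy`/`pdx`/`normal`),
#' `gene`, `variant_key` (canonical `chrom:pos:ref:alt`), `protein_change`,
#' `gnomad_af`, `exac_af`, `dbsnp_id`, `cgc_role` (comma-separated subset of
#' `oncogene`, `tumor_suppressor`) and `cosmic_exact_match`. Standard MAF
#' column names can be consumed through `column_map`.
#'
#' @param path Path to the TSV.
#' @param column_map Optional named character vector mapping native field
#'   names to the file's column names, e.g.
#'   `c(gene = "Hugo_Symbol", sample_id = "Tumor_Sample_Barcode")`.
#' @return A validated variant data.frame.
#' @export
read_variants <- function(path, column_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(column_map)) {
    for (field in names(column_map)) {
      src <- column_map[[field]]
      .assert(src %in% names(df), "mapped column '", src, "' not in file")
      df[[field]] <- df[[src]]
    }
  }
  as_variant_table(df)
}

#' Coerce and validate a variant table
#'
#' Fills optional columns (`protein_change`, `gnomad_af`, `exac_af`,
#' `dbsnp_id`, `cgc_role`, `cosmic_exact_match`) with their empty defaults
#' and checks field invariants.
#'
#' @param df A data.frame carrying at least `patient_id`, `sample_id`,
#'   `sample_class`, `gene`, `variant_key`.
#' @return The validated data.frame.
#' @export
as_variant_table <- function(df) {
  required <- c("patient_id", "sample_id", "sample_class", "gene", "variant_key")
  missing <- setdiff(required, names(df))
  .assert(length(missing) == 0, "variant table lacks column(s): ", .fmt_ids(missing))
  if (is.null(df$protein_change)) df$protein_change <- ""
  if (is.null(df$gnomad_af)) df$gnomad_af <- NA_real_
  if (is.null(df$exac_af)) df$exac_af <- NA_real_
  if (is.null(df$dbsnp_id)) df$dbsnp_id <- ""
  if (is.null(df$cgc_role)) df$cgc_role <- ""
  if (is.null(df$cosmic_exact_match)) df$cosmic_exact_match <- FALSE
  df$dbsnp_id[is.na(df$dbsnp_id)] <- ""
  df$cgc_role[is.na(df$cgc_role)] <- ""
  df$cosmic_exact_match <- as.logical(df$cosmic_exact_match)
  df$cosmic_exact_match[is.na(df$cosmic_exact_match)] <- FALSE
  bad_class <- setdiff(unique(df$sample_class), c("biopsy", "pdx", "normal"))
  .assert(length(bad_class) == 0, "unknown sample_class value(s): ",
          .fmt_ids(bad_class))
  .assert(all(nzchar(df$variant_key)), "empty variant_key in row(s): ",
          .fmt_ids(which(!nzchar(df$variant_key))))
  for (col in c("gnomad_af", "exac_af")) {
    v <- df[[col]]
    .assert(all(is.na(v) | (v >= 0 & v <= 1)), col, " must lie in [0, 1]")
  }
  df
}

# does the comma-separated role string contain the given role token?
.has_role <- function(cgc_role, role) {
  vapply(strsplit(as.character(cgc_role), ","),
         function(tokens) role %in% trimws(tokens), logical(1))
}

#' Whitelist test for annotated somatic variants
#'
#' A variant is whitelisted — shielded from the population-frequency and
#' dbSNP filters — when its gene is a Cancer Gene Census oncogene AND the
#' exact mutation is listed in COSMIC, or when its gene is a Cancer Gene
#' Census tumor suppressor (no COSMIC match required).
#'
#' @param v Variant data.frame (see [as_variant_table()]).
#' @return Logical vector; the triggering reason per record is attached as
#'   attribute `"reason"` (`""` where not whitelisted,
#'   `"whitelisted_oncogene_cosmic"` / `"whitelisted_tsg"`, TSG reported
#'   first when both apply).
#' @export
is_whitelisted <- function(v) {
  v <- as_variant_table(v)
  onc <- .has_role(v$cgc_role, "oncogene") & v$cosmic_exact_match
  tsg <- .has_role(v$cgc_role, "tumor_suppressor")
  reason <- ifelse(tsg, "whitelisted_tsg",
                   ifelse(onc, "whitelisted_oncogene_cosmic", ""))
  structure(onc | tsg, reason = reason)
}

#' Population-frequency and dbSNP filter
#'
#' Removes variants with population allele frequency above 0.001 in GnomAD or
#' ExAC (strict inequality; a missing frequency never exceeds the threshold)
#' or carrying a dbSNP identifier — unless the variant is whitelisted (see
#' [is_whitelisted()]).
#'
#' @param v Variant data.frame.
#' @param gnomad_threshold GnomAD allele-frequency cutoff (default 0.001).
#' @param exac_threshold ExAC cutoff; defaults to the shared GnomAD value.
#' @return Data.frame of per-record decisions: `variant_key`, `sample_id`,
#'   `kept`, `reasons` (comma-separated codes among `pop_freq_gnomad`,
#'   `pop_freq_exac`, `dbsnp`, `whitelisted_oncogene_cosmic`,
#'   `whitelisted_tsg`).
#' @export
population_filter <- function(v, gnomad_threshold = 0.001,
                              exac_threshold = gnomad_threshold) {
  v <- as_variant_table(v)
  wl <- is_whitelisted(v)
  flag_gnomad <- !is.na(v$gnomad_af) & v$gnomad_af > gnomad_threshold
  flag_exac <- !is.na(v$exac_af) & v$exac_af > exac_threshold
  flag_dbsnp <- nzchar(v$dbsnp_id)
  germline_like <- flag_gnomad | flag_exac | flag_dbsnp
  kept <- !germline_like | wl

  reasons <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    if (!germline_like[i]) next
    if (wl[i]) {
      reasons[i] <- attr(wl, "reason")[i]
    } else {
      reasons[i] <- paste(c("pop_freq_gnomad", "pop_freq_exac", "dbsnp")[
        c(flag_gnomad[i], flag_exac[i], flag_dbsnp[i])], collapse = ",")
    }
  }
  data.frame(variant_key = v$variant_key, sample_id = v$sample_id,
             kept = kept, reasons = reasons, stringsAsFactors = FALSE)
}

#' PDX-only recurrence filter
#'
#' Flags suspected xenograft-specific artifacts: a variant key carried by
#' more than one PDX sample but by no patient biopsy is removed from every
#' record that carries it. Recurrence is counted over distinct PDX sample ids
#' by default, or distinct patients with `by_patient = TRUE`.
#'
#' @param v Variant data.frame.
#' @param by_patient Count recurrence per patient rather than per PDX sample.
#' @return Logical vector, `TRUE` where the record is removed as
#'   PDX-only-recurrent.
#' @export
pdx_recurrence_filter <- function(v, by_patient = FALSE) {
  v <- as_variant_table(v)
  is_pdx <- v$sample_class == "pdx"
  is_biopsy <- v$sample_class == "biopsy"
  unit <- if (by_patient) v$patient_id else v$sample_id
  n_pdx <- vapply(split(unit[is_pdx], v$variant_key[is_pdx]),
                  function(u) length(unique(u)), integer(1))
  biopsy_keys <- unique(v$variant_key[is_biopsy])
  recurrent <- names(n_pdx)[n_pdx >= 2 & !(names(n_pdx) %in% biopsy_keys)]
  v$variant_key %in% recurrent
}

#' Full somatic-variant filtering pipeline
#'
#' Applies [population_filter()] and then, on its survivors, the
#' [pdx_recurrence_filter()]. By default the whitelist does not shield a
#' variant from the recurrence filter, since recurrence targets suspected
#' artifacts rather than germline leakage (`shield_whitelisted` restores
#' shielding). The result is deterministic and independent of row order.
#'
#' @param v Variant data.frame.
#' @param gnomad_threshold,exac_threshold Population-frequency cutoffs.
#' @param by_patient Passed to [pdx_recurrence_filter()].
#' @param shield_whitelisted Exempt whitelisted variants from the recurrence
#'   filter.
#' @return A list of class `"variant_filter_result"`: `kept` (surviving
#'   records), `decisions` (per input record: `variant_key`, `sample_id`,
#'   `kept`, `reasons`) and `summary` (named counts per reason code plus
#'   `n_input` and `n_kept`).
#' @export
filter_variants <- function(v, gnomad_threshold = 0.001,
                            exac_threshold = gnomad_threshold,
                            by_patient = FALSE, shield_whitelisted = FALSE) {
  v <- as_variant_table(v)
  if (nrow(v) == 0) {
    decisions <- data.frame(variant_key = character(), sample_id = character(),
                            kept = logical(), reasons = character(),
                            stringsAsFactors = FALSE)
    summary <- c(n_input = 0L, n_kept = 0L)
    return(structure(list(kept = v, decisions = decisions, summary = summary),
                     class = "variant_filter_result"))
  }
  pop <- population_filter(v, gnomad_threshold, exac_threshold)
  survivors <- v[pop$kept, , drop = FALSE]
  recur <- pdx_recurrence_filter(survivors, by_patient = by_patient)
  if (shield_whitelisted) recur <- recur & !is_whitelisted(survivors)

  kept <- pop$kept
  kept[pop$kept] <- !recur
  reasons <- pop$reasons
  idx <- which(pop$kept)[recur]
  reasons[idx] <- ifelse(nzchar(reasons[idx]),
                         paste(reasons[idx], "pdx_only_recurrent", sep = ","),
                         "pdx_only_recurrent")

  decisions <- data.frame(variant_key = v$variant_key, sample_id = v$sample_id,
                          kept = kept, reasons = reasons,
                          stringsAsFactors = FALSE)
  codes <- c("pop_freq_gnomad", "pop_freq_exac", "dbsnp",
             "whitelisted_oncogene_cosmic", "whitelisted_tsg",
             "pdx_only_recurrent")
  counts <- vapply(codes, function(code) {
    sum(vapply(strsplit(reasons, ","), function(r) code %in% r, logical(1)))
  }, integer(1))
  summary <- c(counts, n_input = nrow(v), n_kept = sum(kept))
  structure(list(kept = v[kept, , drop = FALSE], decisions = decisions,
                 summary = summary),
            class = "variant_filter_result")
}

#' @export
print.variant_filter_result <- function(x, ...) {
  cat("Somatic variant filter:", x$summary[["n_kept"]], "of",
      x$summary[["n_input"]], "records kept\n")
  drop <- x$summary[setdiff(names(x$summary), c("n_input", "n_kept"))]
  drop <- drop[drop > 0]
  if (length(drop) > 0) {
    cat("Reason codes:\n")
    for (nm in names(drop)) cat("  ", nm, ": ", drop[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Write a variant table or decision log to TSV
#'
#' @param x Data.frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
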