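#' Simulate a labeled reference expression cohort
#'
#' Generates a multi-class cohort with class-specific transcriptional
#' signatures, emulating a labeled reference such as a tumor-type compendium.
#' Each gene g gets a baseline log2 expression drawn uniformly from
#' `baseline_range`; each class elevates its own disjoint block of signature
#' genes by `log2_effect`, and each class is split into two nested subgroups
#' that elevate a smaller block by `subgroup_effect`. Gaussian noise of sd
#' `noise_sd` is added on the log2 scale and the matrix returned as
#' `2^(log2 value)` (RPKM-like, strictly positive). Defaults give three
#' classes of 15 samples with a 50-gene signature at effect 4 and noise 0.5 —
#' a strongly separable cohort whose within-class rank correlation exceeds
#' every between-class one.
#'
#' @param seed Integer RNG seed (mandatory; the generator is fully
#'   deterministic given the configuration).
#' @param n_genes Total number of genes.
#' @param class_labels Character vector of class names (>= 2).
#' @param n_per_class Samples per class (recycled; each >= 2).
#' @param n_signature_genes Signature genes per class.
#' @param log2_effect Signature elevation on the log2 scale.
#' @param noise_sd Log2-scale Gaussian noise sd.
#' @param subgroup_effect Elevation of the nested-subgroup signature.
#' @param n_subgroup_genes Signature genes per subgroup.
#' @param baseline_range Range of baseline log2 expression.
#' @return List with `reference` (a [reference_cohort()] carrying metadata
#'   categories `class` and `subtype`) and `truth` (data.frame `sample_id`,
#'   `class`, `subgroup`).
#' @export
simulate_reference_cohort <- function(seed,
                                      n_genes = 500,
                                      class_labels = c("classA", "classB", "classC"),
                                      n_per_class = 15,
                                      n_signature_genes = 50,
                                      log2_effect = 4,
                                      noise_sd = 0.5,
                                      subgroup_effect = log2_effect / 2,
                                      n_subgroup_genes = ceiling(n_signature_genes / 2),
                                      baseline_range = c(1, 8)) {
  .assert(!missing(seed), "seed is mandatory")
  .assert(length(class_labels) >= 2, "need >= 2 classes")
  n_per_class <- rep_len(n_per_class, length(class_labels))
  .assert(all(n_per_class >= 2), "each class needs >= 2 samples")
  n_classes <- length(class_labels)
  needed <- n_classes * (n_signature_genes + 2 * n_subgroup_genes)
  .assert(n_genes >= needed, "n_genes too small for the requested signatures (need >= ",
          needed, ")")
  set.seed(seed)

  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  n_samples <- sum(n_per_class)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  classes <- rep(class_labels, n_per_class)
  # split each class into two nested subgroups, alternating
  subgroups <- paste0(classes, ".s", unlist(lapply(n_per_class, function(n) {
    rep_len(1:2, n)
  })))

  # disjoint signature blocks: class blocks first, then subgroup blocks
  pool <- seq_len(n_genes)
  class_sig <- list()
  sub_sig <- list()
  offset <- 0
  for (cl in class_labels) {
    class_sig[[cl]] <- pool[offset + seq_len(n_signature_genes)]
    offset <- offset + n_signature_genes
  }
  for (cl in class_labels) {
    for (s in 1:2) {
      sub_sig[[paste0(cl, ".s", s)]] <- pool[offset + seq_len(n_subgroup_genes)]
      offset <- offset + n_subgroup_genes
    }
  }

  baseline <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
  log2_expr <- matrix(baseline, n_genes, n_samples)
  for (j in seq_len(n_samples)) {
    log2_expr[class_sig[[classes[j]]], j] <-
      log2_expr[class_sig[[classes[j]]], j] + log2_effect
    log2_expr[sub_sig[[subgroups[j]]], j] <-
      log2_expr[sub_sig[[subgroups[j]]], j] + subgroup_effect
  }
  log2_expr <- log2_expr + matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                                  n_genes, n_samples)
  expr <- 2^log2_expr
  dimnames(expr) <- list(gene_ids, sample_ids)
  attr(expr, "unit") <- "rpkm"

  labels <- stats::setNames(classes, sample_ids)
  metadata <- list(class = labels,
                   subtype = stats::setNames(subgroups, sample_ids))
  truth <- data.frame(sample_id = sample_ids, class = classes,
                      subgroup = subgroups, stringsAsFactors = FALSE)
  params <- list(gene_ids = gene_ids, baseline = baseline,
                 class_signatures = class_sig, subgroup_signatures = sub_sig,
                 log2_effect = log2_effect, subgroup_effect = subgroup_effect,
                 noise_sd = noise_sd, class_labels = class_labels)
  list(reference = reference_cohort(expr, labels, metadata), truth = truth,
       params = params)
}

#' Simulate query samples from the class generators of a reference cohort
#'
#' Draws new samples from the same generative process as an existing
#' [simulate_reference_cohort()] result — identical gene baselines and
#' class-signature blocks, fresh noise — for parameter-recovery experiments:
#' classify the held-out draws against the cohort and count how many recover
#' their generating class.
#'
#' @param seed Integer RNG seed for the fresh noise (mandatory).
#' @param cohort The list returned by [simulate_reference_cohort()].
#' @param n_queries Number of query samples; classes assigned round-robin.
#' @param noise_sd Log2-scale noise sd; defaults to the cohort's own.
#' @return List with `queries` (genes x samples matrix) and `truth`
#'   (data.frame `sample_id`, `class`).
#' @export
simulate_query_samples <- function(seed, cohort, n_queries = 30,
                                   noise_sd = cohort$params$noise_sd) {
  .assert(!missing(seed), "seed is mandatory")
  .assert(is.list(cohort) && !is.null(cohort$params),
          "cohort must come from simulate_reference_cohort()")
  set.seed(seed)
  p <- cohort$params
  n_genes <- length(p$gene_ids)
  classes <- rep_len(p$class_labels, n_queries)
  sample_ids <- sprintf("Q%03d", seq_len(n_queries))
  log2_expr <- matrix(p$baseline, n_genes, n_queries)
  for (j in seq_len(n_queries)) {
    sig <- p$class_signatures[[classes[j]]]
    log2_expr[sig, j] <- log2_expr[sig, j] + p$log2_effect
  }
  log2_expr <- log2_expr + matrix(stats::rnorm(n_genes * n_queries, 0, noise_sd),
                                  n_genes, n_queries)
  queries <- 2^log2_expr
  dimnames(queries) <- list(p$gene_ids, sample_ids)
  list(queries = queries,
       truth = data.frame(sample_id = sample_ids, class = classes,
                          stringsAsFactors = FALSE))
}

#' Simulate bulk expression mixtures with known cell-type fractions
#'
#' Emulates bulk tumor RNA-seq as convex mixtures of component profiles
#' (cancer, cancer-associated fibroblasts, macrophages, T cells by default).
#' Every component shares a common baseline profile but elevates its own
#' disjoint marker block by `marker_log2_boost` on the log2 scale. The CAF
#' fraction is drawn uniformly over `caf_range` (the quantity a fibroblast
#' score should recover); the remaining mass is split among the other
#' components by a symmetric Dirichlet draw. Multiplicative log-normal noise
#' of sd `noise_sd` (log2 scale) is applied to the mixed profile.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_samples Number of bulk samples.
#' @param n_genes Number of genes.
#' @param components Component (cell-type) names; must include `caf_name`.
#' @param caf_name The component whose fraction is drawn from `caf_range`.
#' @param n_markers Marker genes per component.
#' @param marker_log2_boost Marker elevation in the owning component.
#' @param caf_range Range of the CAF fraction across samples.
#' @param noise_sd Log2-scale noise sd (0.1 = low noise).
#' @param baseline_range Range of baseline log2 expression.
#' @return List with `expression` (genes x samples, RPKM-like),
#'   `proportions` (samples x components; true fractions, rows sum to 1) and
#'   `markers` (named list of per-component marker gene ids).
#' @export
simulate_bulk_mixtures <- function(seed,
                                   n_samples = 20,
                                   n_genes = 400,
                                   components = c("cancer", "CAF", "macrophage", "T_cell"),
                                   caf_name = "CAF",
                                   n_markers = 25,
                                   marker_log2_boost = 6,
                                   caf_range = c(0.05, 0.6),
                                   noise_sd = 0.1,
                                   baseline_range = c(1, 6)) {
  .assert(!missing(seed), "seed is mandatory")
  .assert(length(components) >= 2, "need >= 2 mixture components")
  .assert(caf_name %in% components, "components must include '", caf_name, "'")
  .assert(n_genes >= length(components) * n_markers,
          "n_genes too small for the marker blocks")
  set.seed(seed)

  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  sample_ids <- sprintf("B%03d", seq_len(n_samples))
  baseline <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
  markers <- list()
  profiles <- matrix(NA_real_, n_genes, length(components),
                     dimnames = list(gene_ids, components))
  for (i in seq_along(components)) {
    idx <- (i - 1) * n_markers + seq_len(n_markers)
    markers[[components[i]]] <- gene_ids[idx]
    prof <- baseline
    prof[idx] <- prof[idx] + marker_log2_boost
    profiles[, i] <- 2^prof
  }

  others <- setdiff(components, caf_name)
  caf_f <- stats::runif(n_samples, caf_range[1], caf_range[2])
  rest <- matrix(stats::rgamma(n_samples * length(others), shape = 1),
                 n_samples, length(others))
  rest <- rest / rowSums(rest) * (1 - caf_f)
  fractions <- matrix(NA_real_, n_samples, length(components),
                      dimnames = list(sample_ids, components))
  fractions[, caf_name] <- caf_f
  fractions[, others] <- rest

  bulk <- profiles %*% t(fractions)
  if (noise_sd > 0) {
    bulk <- bulk * 2^matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                            n_genes, n_samples)
  }
  dimnames(bulk) <- list(gene_ids, sample_ids)
  attr(bulk, "unit") <- "rpkm"
  list(expression = bulk, proportions = fractions, markers = markers)
}

#' Simulate a somatic variant table with known filter outcomes
#'
#' Emits the configured number of records per filtering category, with a
#' truth label stating the expected pipeline decision for each record.
#' Categories: `pop_frequent` (GnomAD AF above threshold, removed), `dbsnp`
#' (rsID, removed), `oncogene_rescued` (GnomAD-frequent + rsID but CGC
#' oncogene with exact COSMIC match, kept), `tsg_rescued` (rsID but CGC
#' tumor suppressor, kept), `pdx_recurrent` (pairs of records sharing a
#' variant key across two PDX samples with no biopsy support, removed) and
#' `clean` (kept). The default scenario is the 10-record toy table: 2
#' population-filtered, 1 whitelist rescue, 1 PDX-recurrent pair, 5 clean —
#' 6 records surviving.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_pop_frequent,n_dbsnp,n_oncogene_rescued,n_tsg_rescued Counts of
#'   singleton biopsy records per category.
#' @param n_pdx_recurrent Number of PDX-only recurrent variant *pairs* (2
#'   records each).
#' @param n_clean Count of clean somatic records.
#' @return List with `variants` (data.frame accepted by [filter_variants()])
#'   and `truth` (data.frame `variant_key`, `sample_id`, `category`,
#'   `expect_kept`).
#' @export
simulate_variant_table <- function(seed,
                                   n_pop_frequent = 1,
                                   n_dbsnp = 1,
                                   n_oncogene_rescued = 1,
                                   n_tsg_rescued = 0,
                                   n_pdx_recurrent = 1,
                                   n_clean = 5) {
  .assert(!missing(seed), "seed is mandatory")
  set.seed(seed)
  genes <- c("KRAS", "TP53", "SMAD4", "CDKN2A", "MSH6", "ARID1A", "GATA6",
             "RNF43", "TGFBR2", "BRCA2")
  new_key <- local({
    counter <- 0L
    function() {
      counter <<- counter + 1L
      sprintf("chr%d:%d:%s:%s", sample(1:22, 1),
              sample(1e6:2e8, 1) + counter, sample(c("A", "C", "G", "T"), 1),
              sample(c("A", "C", "G", "T"), 1))
    }
  })
  rows <- list()
  emit <- function(n, category, expect_kept, maker) {
    for (i in seq_len(n)) {
      r <- maker()
      r$category <- category
      r$expect_kept <- expect_kept
      rows[[length(rows) + 1L]] <<- r
    }
  }
  biopsy <- function(patient) list(patient_id = patient,
                                   sample_id = paste0(patient, "_biopsy"),
                                   sample_class = "biopsy")
  base_record <- function(patient = sprintf("P%02d", sample(1:20, 1))) {
    c(biopsy(patient),
      list(gene = sample(genes, 1), variant_key = new_key(),
           protein_change = "", gnomad_af = NA_real_, exac_af = NA_real_,
           dbsnp_id = "", cgc_role = "", cosmic_exact_match = FALSE))
  }
  emit(n_pop_frequent, "pop_frequent", FALSE, function() {
    r <- base_record()
    r$gnomad_af <- stats::runif(1, 0.002, 0.2)
    r
  })
  emit(n_dbsnp, "dbsnp", FALSE, function() {
    r <- base_record()
    r$dbsnp_id <- sprintf("rs%d", sample(1e3:1e7, 1))
    r
  })
  emit(n_oncogene_rescued, "oncogene_rescued", TRUE, function() {
    r <- base_record()
    r$gene <- "KRAS"
    r$gnomad_af <- stats::runif(1, 0.002, 0.01)
    r$dbsnp_id <- sprintf("rs%d", sample(1e3:1e7, 1))
    r$cgc_role <- "oncogene"
    r$cosmic_exact_match <- TRUE
    r
  })
  emit(n_tsg_rescued, "tsg_rescued", TRUE, function() {
    r <- base_record()
    r$gene <- "TP53"
    r$dbsnp_id <- sprintf("rs%d", sample(1e3:1e7, 1))
    r$cgc_role <- "tumor_suppressor"
    r
  })
  for (i in seq_len(n_pdx_recurrent)) {
    key <- new_key()
    gene <- sample(genes, 1)
    for (patient in sprintf("P%02d", sample(21:40, 2))) {
      rows[[length(rows) + 1L]] <- list(
        patient_id = patient, sample_id = paste0(patient, "_pdx"),
        sample_class = "pdx", gene = gene, variant_key = key,
        protein_change = "", gnomad_af = NA_real_, exac_af = NA_real_,
        dbsnp_id = "", cgc_role = "", cosmic_exact_match = FALSE,
        category = "pdx_recurrent", expect_kept = FALSE)
    }
  }
  emit(n_clean, "clean", TRUE, function() base_record())

  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(patient_id = character(), sample_id = character(),
                     sample_class = character(), gene = character(),
                     variant_key = character(), protein_change = character(),
                     gnomad_af = numeric(), exac_af = numeric(),
                     dbsnp_id = character(), cgc_role = character(),
                     cosmic_exact_match = logical(), category = character(),
                     expect_kept = logical(), stringsAsFactors = FALSE)
  }
  truth <- df[c("variant_key", "sample_id", "category", "expect_kept")]
  variants <- df[setdiff(names(df), c("category", "expect_kept"))]
  list(variants = variants, truth = truth)
}

#' Simulate two-arm xenograft growth measurements
#'
#' Per-animal tumor volumes follow exponential growth
#' `V(t) = V0 * exp(rate * t)` with multiplicative log-normal measurement
#' noise; a responder arm switches to `responder_rate` (regression when
#' negative) after `infusion_day`, mimicking adoptive TIL transfer. Volumes
#' are converted back to caliper width/length pairs under the fixed
#' convention `length = 1.5 * width`, consistent with the volume formula
#' `width^2 * length / 2`.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param arms Arm names (>= 2; the first arm is the responder when
#'   `responder = TRUE`).
#' @param n_per_arm Animals per arm.
#' @param days Measurement days.
#' @param baseline_volume Volume at day 0 in mm^3.
#' @param growth_rate Per-day exponential growth rate, recycled across arms.
#' @param noise_sd Log2-scale measurement noise sd.
#' @param responder Apply the post-infusion rate switch to the first arm.
#' @param infusion_day Day the first arm switches rate.
#' @param responder_rate Post-infusion per-day rate of the first arm.
#' @return Data.frame `animal_id`, `group`, `day`, `width_mm`, `length_mm`,
#'   `volume_mm3` (noise-free truth in `true_volume_mm3`).
#' @export
simulate_growth_measurements <- function(seed,
                                         arms = c("TIL", "no_TIL"),
                                         n_per_arm = 5,
                                         days = seq(0, 28, by = 7),
                                         baseline_volume = 100,
                                         growth_rate = 0.08,
                                         noise_sd = 0.1,
                                         responder = FALSE,
                                         infusion_day = 7,
                                         responder_rate = -0.12) {
  .assert(!missing(seed), "seed is mandatory")
  .assert(length(arms) >= 2, "need >= 2 arms")
  set.seed(seed)
  growth_rate <- rep_len(growth_rate, length(arms))
  rows <- list()
  for (a in seq_along(arms)) {
    for (m in seq_len(n_per_arm)) {
      animal <- sprintf("%s_m%02d", arms[a], m)
      v0 <- baseline_volume * 2^stats::rnorm(1, 0, noise_sd)
      for (d in days) {
        if (responder && a == 1L && d > infusion_day) {
          true_v <- v0 * exp(growth_rate[a] * infusion_day +
                               responder_rate * (d - infusion_day))
        } else {
          true_v <- v0 * exp(growth_rate[a] * d)
        }
        v <- true_v * 2^stats::rnorm(1, 0, noise_sd)
        w <- (v / 0.75)^(1 / 3) # solves v = w^2 * (1.5 w) / 2
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = animal, group = arms[a], day = d,
          width_mm = w, length_mm = 1.5 * w,
          volume_mm3 = v, true_volume_mm3 = true_v,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate per-group survival records
#'
#' Event times are exponential with the stated per-group hazard. Each subject
#' is independently censored with probability `censoring_rate`, in which case
#' the recorded time is uniform on (0, event time).
#'
#' @param seed Integer RNG seed (mandatory).
#' @param hazards Named numeric vector of per-day hazards, one per group.
#' @param n_per_group Subjects per group (recycled).
#' @param censoring_rate Probability a subject is censored, in \[0, 1\].
#' @return Data.frame `subject_id`, `group`, `time`, `event`.
#' @export
simulate_survival_records <- function(seed,
                                      hazards = c(grew = 0.004, did_not_grow = 0.004),
                                      n_per_group = c(8, 13),
                                      censoring_rate = 0.2) {
  .assert(!missing(seed), "seed is mandatory")
  .assert(!is.null(names(hazards)) && all(hazards > 0),
          "hazards must be a named positive vector")
  set.seed(seed)
  n_per_group <- rep_len(n_per_group, length(hazards))
  rows <- list()
  for (g in seq_along(hazards)) {
    for (i in seq_len(n_per_group[g])) {
      t_event <- stats::rexp(1, hazards[g])
      censored <- stats::runif(1) < censoring_rate
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("%s_%02d", names(hazards)[g], i),
        group = names(hazards)[g],
        time = if (censored) stats::runif(1, 0, t_event) else t_event,
        event = !censored, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate growth and survival inputs together
#'
#' Convenience wrapper bundling [simulate_growth_measurements()] and
#' [simulate_survival_records()] under one seed (the survival stream uses
#' `seed + 1`).
#'
#' @param seed Integer RNG seed (mandatory).
#' @param growth Named list of arguments for
#'   [simulate_growth_measurements()].
#' @param survival Named list of arguments for
#'   [simulate_survival_records()].
#' @return List with `growth` and `survival` data.frames.
#' @export
simulate_growth_and_survival <- function(seed, growth = list(), survival = list()) {
  .assert(!missing(seed), "seed is mandatory")
  list(growth = do.call(simulate_growth_measurements, c(list(seed = seed), growth)),
       survival = do.call(simulate_survival_records, c(list(seed = seed + 1), survival)))
}
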