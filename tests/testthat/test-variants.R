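variant_row <- function(...) {
  defaults <- list(patient_id = "P01", sample_id = "P01_biopsy",
                   sample_class = "biopsy", gene = "GENE",
                   variant_key = "chr1:100:A:T", protein_change = "",
                   gnomad_af = NA_real_, exac_af = NA_real_, dbsnp_id = "",
                   cgc_role = "", cosmic_exact_match = FALSE)
  args <- list(...)
  defaults[names(args)] <- args
  as.data.frame(defaults, stringsAsFactors = FALSE)
}

test_that("whitelisting requires COSMIC confirmation for oncogenes but not TSGs", {
  onc_no_cosmic <- variant_row(cgc_role = "oncogene", cosmic_exact_match = FALSE)
  expect_false(as.vector(is_whitelisted(onc_no_cosmic)))

  onc_cosmic <- variant_row(cgc_role = "oncogene", cosmic_exact_match = TRUE)
  wl <- is_whitelisted(onc_cosmic)
  expect_true(as.vector(wl))
  expect_identical(attr(wl, "reason"), "whitelisted_oncogene_cosmic")

  for (flag in c(TRUE, FALSE)) {
    tsg <- variant_row(cgc_role = "tumor_suppressor", cosmic_exact_match = flag)
    expect_true(as.vector(is_whitelisted(tsg)))
  }

  expect_false(as.vector(is_whitelisted(variant_row(cgc_role = ""))))
  both <- variant_row(cgc_role = "oncogene,tumor_suppressor",
                      cosmic_exact_match = FALSE)
  expect_true(as.vector(is_whitelisted(both))) # TSG listing suffices
})

test_that("population filter applies the strict 0.001 threshold with whitelist override", {
  over <- variant_row(gnomad_af = 0.002)
  d <- population_filter(over)
  expect_false(d$kept)
  expect_identical(d$reasons, "pop_freq_gnomad")

  boundary <- variant_row(gnomad_af = 0.001)
  expect_true(population_filter(boundary)$kept) # strict inequality

  missing_af <- variant_row()
  expect_true(population_filter(missing_af)$kept)

  rescued <- variant_row(dbsnp_id = "rs123", cgc_role = "tumor_suppressor")
  d2 <- population_filter(rescued)
  expect_true(d2$kept)
  expect_identical(d2$reasons, "whitelisted_tsg")

  exac <- variant_row(exac_af = 0.01, dbsnp_id = "rs9")
  d3 <- population_filter(exac)
  expect_false(d3$kept)
  expect_identical(d3$reasons, "pop_freq_exac,dbsnp")

  # per-resource override
  d4 <- population_filter(variant_row(exac_af = 0.01), exac_threshold = 0.05)
  expect_true(d4$kept)
})

test_that("PDX recurrence needs >= 2 PDX samples and no biopsy support", {
  pdx <- function(p, key) variant_row(patient_id = p,
                                      sample_id = paste0(p, "_pdx"),
                                      sample_class = "pdx", variant_key = key)
  biopsy <- function(p, key) variant_row(patient_id = p,
                                         sample_id = paste0(p, "_biopsy"),
                                         variant_key = key)
  two_pdx <- rbind(pdx("P1", "k1"), pdx("P2", "k1"))
  expect_identical(pdx_recurrence_filter(two_pdx), c(TRUE, TRUE))

  with_biopsy <- rbind(two_pdx, biopsy("P3", "k1"))
  expect_identical(pdx_recurrence_filter(with_biopsy), rep(FALSE, 3))

  single <- pdx("P1", "k2")
  expect_identical(pdx_recurrence_filter(single), FALSE)

  # same sample id twice is one PDX sample, not two
  dup <- rbind(pdx("P1", "k3"), pdx("P1", "k3"))
  expect_identical(pdx_recurrence_filter(dup), c(FALSE, FALSE))

  # patient-level counting collapses two samples of one patient
  same_patient <- rbind(pdx("P1", "k4"),
                        variant_row(patient_id = "P1", sample_id = "P1_pdx2",
                                    sample_class = "pdx", variant_key = "k4"))
  expect_identical(pdx_recurrence_filter(same_patient), c(TRUE, TRUE))
  expect_identical(pdx_recurrence_filter(same_patient, by_patient = TRUE),
                   c(FALSE, FALSE))
})

test_that("the toy MAF fixture filters to exactly 6 surviving records", {
  path <- system.file("extdata", "toy_variants_synthetic.maf",
                      package = "pdxomics")
  v <- read_variants(path)
  expect_identical(nrow(v), 10L)
  res <- filter_variants(v)
  expect_identical(res$summary[["n_kept"]], 6L)
  expect_identical(sum(res$decisions$kept), 6L)

  by_key <- stats::setNames(res$decisions$reasons, res$decisions$variant_key)
  expect_identical(unname(by_key["chr1:27022894:G:A"]),
                   "pop_freq_gnomad,pop_freq_exac")
  expect_identical(unname(by_key["chr18:19751245:C:T"]), "dbsnp")
  expect_identical(unname(by_key["chr12:25398284:C:T"]),
                   "whitelisted_oncogene_cosmic")
  expect_identical(unname(by_key[names(by_key) == "chr17:56435161:T:C"]),
                   rep("pdx_only_recurrent", 2))
})

test_that("the pipeline is idempotent and independent of row order", {
  path <- system.file("extdata", "toy_variants_synthetic.maf",
                      package = "pdxomics")
  v <- read_variants(path)
  first <- filter_variants(v)
  second <- filter_variants(first$kept)
  expect_identical(second$kept, first$kept, ignore_attr = TRUE)
  expect_true(all(second$decisions$kept))

  set.seed(123)
  for (i in 1:100) {
    perm <- sample(nrow(v))
    res <- filter_variants(v[perm, ])
    expect_identical(res$decisions$kept,
                     first$decisions$kept[perm],
                     label = sprintf("shuffle %d", i))
  }
})

test_that("whitelisted variants are never removed for population reasons", {
  set.seed(9)
  for (i in 1:20) {
    v <- random_variant_table(i, n = 40)
    res <- filter_variants(v)
    wl <- is_whitelisted(v)
    dropped_pop <- !res$decisions$kept &
      grepl("pop_freq|dbsnp", res$decisions$reasons)
    expect_false(any(dropped_pop & wl))
  }
})

test_that("survivor sets equal the brute-force reimplementation on random tables", {
  for (seed in 1:50) {
    v <- random_variant_table(seed, n = sample(5:50, 1))
    got <- filter_variants(v)$decisions$kept
    want <- oracle_variant_filter(v)
    expect_identical(got, want, label = sprintf("seed %d", seed))
  }
})

test_that("the whitelist shield flag exempts rescued variants from recurrence removal", {
  pdx_wl <- function(p) variant_row(patient_id = p, sample_id = paste0(p, "_pdx"),
                                    sample_class = "pdx", variant_key = "k9",
                                    cgc_role = "tumor_suppressor")
  v <- rbind(pdx_wl("P1"), pdx_wl("P2"))
  expect_identical(filter_variants(v)$decisions$kept, c(FALSE, FALSE))
  expect_identical(filter_variants(v, shield_whitelisted = TRUE)$decisions$kept,
                   c(TRUE, TRUE))
})

test_that("empty tables and malformed input are handled explicitly", {
  empty <- variant_row()[0, ]
  res <- filter_variants(empty)
  expect_identical(res$summary[["n_input"]], 0L)
  expect_identical(nrow(res$kept), 0L)

  bad <- variant_row(sample_class = "organoid")
  expect_error(filter_variants(bad), "sample_class")
  nokey <- variant_row(variant_key = "")
  expect_error(filter_variants(nokey), "variant_key")
  expect_error(filter_variants(variant_row(gnomad_af = 1.5)), "0, 1")
})

test_that("MAF column mapping renames standard columns", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(paste("Hugo_Symbol", "Tumor_Sample_Barcode", "patient_id",
                     "sample_class", "variant_key", sep = "\t"),
               paste("KRAS", "S1", "P1", "biopsy", "chr12:1:G:A", sep = "\t")),
             path)
  v <- read_variants(path, column_map = c(gene = "Hugo_Symbol",
                                          sample_id = "Tumor_Sample_Barcode"))
  expect_identical(v$gene[1], "KRAS")
  expect_identical(v$sample_id[1], "S1")
})

test_that("the synthetic variant scenario reproduces its own truth labels", {
  for (seed in c(3, 14, 60)) {
    sim <- simulate_variant_table(seed, n_pop_frequent = 2, n_dbsnp = 2,
                                  n_oncogene_rescued = 1, n_tsg_rescued = 2,
                                  n_pdx_recurrent = 2, n_clean = 4)
    res <- filter_variants(sim$variants)
    expect_identical(res$decisions$kept, sim$truth$expect_kept)
  }
  empty <- simulate_variant_table(1, n_pop_frequent = 0, n_dbsnp = 0,
                                  n_oncogene_rescued = 0, n_tsg_rescued = 0,
                                  n_pdx_recurrent = 0, n_clean = 0)
  expect_identical(nrow(empty$variants), 0L)
  all_clean <- simulate_variant_table(2, n_pop_frequent = 0, n_dbsnp = 0,
                                      n_oncogene_rescued = 0, n_tsg_rescued = 0,
                                      n_pdx_recurrent = 0, n_clean = 7)
  expect_true(all(filter_variants(all_clean$variants)$decisions$kept))
})
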