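# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and base shortcuts like rank()/cor()) so that agreement with
# them is evidence, not tautology.

# average-fractional ranks by pairwise counting, O(n^2)
oracle_ranks <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (1 + sum(v == v[i])) / 2
  }, numeric(1))
}

# Pearson correlation from first principles
oracle_pearson <- function(a, b) {
  da <- a - sum(a) / length(a)
  db <- b - sum(b) / length(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_ranks(x), oracle_ranks(y))
}

# closed-form Spearman for distinct values: 1 - 6*sum(d^2)/(n(n^2-1))
oracle_spearman_distinct <- function(x, y) {
  n <- length(x)
  d <- oracle_ranks(x) - oracle_ranks(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# k-NN vote by definition: rank reference samples by (rho desc, id asc),
# tally the top-k window, and on a tied plurality repeatedly drop the last
# (worst) entry of the window until the maximum is unique.
oracle_knn <- function(query, reference, labels, k) {
  rho <- vapply(colnames(reference), function(s) {
    oracle_spearman(query, reference[, s])
  }, numeric(1))
  ids <- colnames(reference)
  ord <- order(-rho, ids)
  labs <- as.character(labels[ids[ord]])
  window <- labs[seq_len(k)]
  removed <- 0
  while (TRUE) {
    counts <- sapply(unique(window), function(l) sum(window == l))
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1) break
    window <- window[-length(window)]
    removed <- removed + 1
  }
  list(predicted = top, removed = removed)
}

# random small cohort for oracle-equivalence sweeps; integer-valued
# expression from a small alphabet so rank ties occur regularly
random_small_cohort <- function(seed) {
  set.seed(seed)
  n_genes <- sample(2:6, 1)
  n_ref <- sample(2:8, 1)
  repeat {
    expr <- matrix(sample(1:5, n_genes * n_ref, replace = TRUE), n_genes, n_ref,
                   dimnames = list(sprintf("g%d", seq_len(n_genes)),
                                   sprintf("r%02d", seq_len(n_ref))))
    query <- sample(1:5, n_genes, replace = TRUE)
    # keep only instances where every correlation is defined
    if (length(unique(query)) > 1 &&
        all(apply(expr, 2, function(v) length(unique(v)) > 1))) break
  }
  labels <- stats::setNames(sample(c("A", "B", "C"), n_ref, replace = TRUE),
                            colnames(expr))
  k <- sample(seq_len(n_ref), 1)
  list(expr = expr, query = stats::setNames(as.numeric(query), rownames(expr)),
       labels = labels, k = k)
}

# exact hypergeometric tail/two-sided probabilities for a 2x2 table by
# explicit enumeration with binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  xs <- lo:hi
  probs <- choose(c1, xs) * choose(n - c1, r1 - xs) / choose(n, r1)
  p_obs <- probs[xs == a]
  list(one = min(sum(probs[xs >= a]), sum(probs[xs <= a]), 1),
       two = min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1))
}

# brute-force variant pipeline: evaluate the three predicates by definition,
# row by row, with the recurrence pass over population-filter survivors
oracle_variant_filter <- function(v, threshold = 0.001) {
  wl <- logical(nrow(v))
  popfail <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    roles <- trimws(strsplit(v$cgc_role[i], ",")[[1]])
    wl[i] <- ("oncogene" %in% roles && isTRUE(v$cosmic_exact_match[i])) ||
      ("tumor_suppressor" %in% roles)
    popfail[i] <- (!is.na(v$gnomad_af[i]) && v$gnomad_af[i] > threshold) ||
      (!is.na(v$exac_af[i]) && v$exac_af[i] > threshold) ||
      nzchar(v$dbsnp_id[i])
  }
  kept <- !popfail | wl
  surv <- v[kept, , drop = FALSE]
  for (key in unique(surv$variant_key)) {
    rows <- surv[surv$variant_key == key, ]
    n_pdx <- length(unique(rows$sample_id[rows$sample_class == "pdx"]))
    n_biopsy <- sum(rows$sample_class == "biopsy")
    if (n_pdx >= 2 && n_biopsy == 0) {
      kept[kept & v$variant_key == key] <- FALSE
    }
  }
  kept
}

# random variant table exercising every predicate combination
random_variant_table <- function(seed, n = 30) {
  set.seed(seed)
  keys <- sprintf("chr1:%d:A:T", sample(1:15, n, replace = TRUE))
  data.frame(
    patient_id = sprintf("P%02d", sample(1:6, n, replace = TRUE)),
    sample_id = sprintf("S%02d", sample(1:10, n, replace = TRUE)),
    sample_class = sample(c("biopsy", "pdx", "normal"), n, replace = TRUE),
    gene = sample(c("KRAS", "TP53", "XYZ"), n, replace = TRUE),
    variant_key = keys,
    protein_change = "",
    gnomad_af = ifelse(runif(n) < 0.5, NA, runif(n, 0, 0.01)),
    exac_af = ifelse(runif(n) < 0.5, NA, runif(n, 0, 0.01)),
    dbsnp_id = ifelse(runif(n) < 0.3, sprintf("rs%d", sample(1e5, n)), ""),
    cgc_role = sample(c("", "oncogene", "tumor_suppressor",
                        "oncogene,tumor_suppressor"), n, replace = TRUE),
    cosmic_exact_match = runif(n) < 0.4,
    stringsAsFactors = FALSE
  )
}
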