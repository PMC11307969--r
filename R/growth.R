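#' Caliper-based tumor volume
#'
#' The standard subcutaneous xenograft volume formula
#' `width x width x length / 2` (mm^3), with width the shorter caliper axis.
#'
#' @param width,length Caliper measurements in mm, strictly positive;
#'   vectorized.
#' @return Tumor volumes in mm^3.
#' @examples
#' tumor_volume(4, 6) # 48
#' @export
tumor_volume <- function(width, length) {
  .assert(all(width > 0) && all(length > 0),
          "caliper measurements must be strictly positive")
  width^2 * length / 2
}

#' Read caliper growth measurements
#'
#' TSV with columns `animal_id`, `group`, `day`, `width_mm`, `length_mm`.
#' Rows where width exceeds length are swapped (with a warning) to enforce
#' the convention that width is the shorter axis.
#'
#' @param path Path to the TSV.
#' @return Data.frame of measurements with a `volume_mm3` column appended.
#' @export
read_growth_measurements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("animal_id", "group", "day", "width_mm", "length_mm")
  missing <- setdiff(required, names(df))
  .assert(length(missing) == 0, "measurement table lacks column(s): ",
          .fmt_ids(missing))
  swap <- df$width_mm > df$length_mm
  if (any(swap)) {
    warning("width > length in ", sum(swap), " row(s); axes swapped")
    tmp <- df$width_mm[swap]
    df$width_mm[swap] <- df$length_mm[swap]
    df$length_mm[swap] <- tmp
  }
  df$volume_mm3 <- tumor_volume(df$width_mm, df$length_mm)
  df
}

# Holm-Sidak step-down adjustment: order p ascending, adjust the i-th as
# 1 - (1 - p)^(m - i + 1), and enforce monotonicity by running maximum.
holm_sidak <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Per-timepoint multiple t tests on tumor growth curves
#'
#' Compares tumor volumes between two arms with one t test per shared
#' measurement day and a Holm-Sidak adjustment across days — the "multiple t
#' test" family of analyses. Welch (unequal-variance) tests are the default;
#' `var_equal = TRUE` selects the pooled-variance test and
#' `adjust = "none"` disables the correction. Days with fewer than two
#' animals in either arm are skipped with a warning.
#'
#' @param data Measurement data.frame with columns `animal_id`, `group`,
#'   `day` and either `volume_mm3` or `width_mm`/`length_mm`.
#' @param groups Character vector of the two arm names to compare.
#' @param var_equal Use the pooled-variance t test.
#' @param adjust `"holm-sidak"` (default) or `"none"`.
#' @return Object of class `"growth_curve_test"`: data.frame with one row per
#'   tested day (`day`, `n1`, `n2`, `mean_diff`, `t`, `df`, `p`, `p_adj`).
#' @export
growth_curve_test <- function(data, groups, var_equal = FALSE,
                              adjust = c("holm-sidak", "none")) {
  adjust <- match.arg(adjust)
  .assert(length(groups) == 2, "exactly two groups must be compared")
  if (is.null(data$volume_mm3)) {
    .assert(all(c("width_mm", "length_mm") %in% names(data)),
            "need volume_mm3 or width_mm/length_mm columns")
    data$volume_mm3 <- tumor_volume(data$width_mm, data$length_mm)
  }
  data <- data[data$group %in% groups, , drop = FALSE]
  .assert(all(groups %in% data$group), "group(s) absent from the data: ",
          .fmt_ids(setdiff(groups, data$group)))

  days <- sort(unique(data$day))
  rows <- list()
  skipped <- integer()
  for (d in days) {
    v1 <- data$volume_mm3[data$day == d & data$group == groups[1]]
    v2 <- data$volume_mm3[data$day == d & data$group == groups[2]]
    if (length(v1) < 2 || length(v2) < 2) {
      skipped <- c(skipped, d)
      next
    }
    tt <- stats::t.test(v1, v2, var.equal = var_equal)
    rows[[length(rows) + 1L]] <- data.frame(
      day = d, n1 = length(v1), n2 = length(v2),
      mean_diff = mean(v1) - mean(v2),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0) {
    warning("skipped day(s) with < 2 animals per arm: ", .fmt_ids(skipped))
  }
  .assert(length(rows) > 0, "no shared day with >= 2 animals in both arms")
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "holm-sidak") holm_sidak(out$p) else out$p
  structure(out, groups = groups, adjust = adjust,
            class = c("growth_curve_test", "data.frame"))
}

#' @export
print.growth_curve_test <- function(x, ...) {
  cat("Per-day t tests:", attr(x, "groups")[1], "vs", attr(x, "groups")[2],
      "(", attr(x, "adjust"), "adjustment over", nrow(x), "days )\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Mean growth curves with standard errors
#'
#' Group mean tumor volume by day with SEM error bars, the conventional
#' cumulative growth-curve display.
#'
#' @param data Measurement data.frame (see [growth_curve_test()]).
#' @param groups Optional subset of groups to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_growth_curves <- function(data, groups = NULL, ...) {
  if (is.null(data$volume_mm3)) {
    data$volume_mm3 <- tumor_volume(data$width_mm, data$length_mm)
  }
  if (!is.null(groups)) data <- data[data$group %in% groups, , drop = FALSE]
  agg <- stats::aggregate(volume_mm3 ~ day + group, data, function(v) {
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))
  })
  agg <- cbind(agg[c("day", "group")], as.data.frame(agg$volume_mm3))
  grs <- unique(agg$group)
  graphics::plot(range(agg$day), range(c(agg$mean - agg$sem, agg$mean + agg$sem)),
                 type = "n", xlab = "day", ylab = "tumor volume (mm^3)", ...)
  for (i in seq_along(grs)) {
    a <- agg[agg$group == grs[i], ]
    graphics::lines(a$day, a$mean, col = i, type = "b", pch = 16)
    graphics::arrows(a$day, a$mean - a$sem, a$day, a$mean + a$sem,
                     angle = 90, code = 3, length = 0.03, col = i)
  }
  graphics::legend("topleft", legend = grs, col = seq_along(grs), lty = 1,
                   bty = "n")
  invisible(agg)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test of association in a 2x2 contingency table (rows:
#' exposure +/-; columns: outcome +/-), as used for take-rate associations.
#' The one-sided p-value is the smaller hypergeometric tail at the observed
#' count; the two-sided p-value sums the probabilities of all tables (at
#' fixed margins) no more probable than the observed one.
#'
#' @param x A 2x2 matrix of non-negative counts, or a length-4 vector
#'   `(a, b, c, d)` read row-wise.
#' @return Object of class `"fisher_exact"`: list with `table`,
#'   `p_one_sided`, `p_two_sided` and the sample odds ratio `odds_ratio`.
#' @examples
#' fisher_exact(c(3, 0, 8, 18)) # PD-L1+ take-rate style table
#' @export
fisher_exact <- function(x) {
  if (is.matrix(x)) {
    .assert(all(dim(x) == c(2, 2)), "need a 2x2 table")
    x <- as.vector(t(x))
  }
  .assert(length(x) == 4, "need 4 counts (a, b, c, d)")
  .assert(all(x >= 0) && all(x == floor(x)), "counts must be non-negative integers")
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  n <- a + b + c + d
  .assert(n > 0, "empty table")
  r1 <- a + b
  c1 <- a + c
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  upper <- sum(probs[support >= a])
  lower <- sum(probs[support <= a])
  two <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  structure(list(
    table = matrix(c(a, b, c, d), 2, 2, byrow = TRUE),
    p_one_sided = min(upper, lower, 1),
    p_two_sided = min(two, 1),
    odds_ratio = (a * d) / (b * c)
  ), class = "fisher_exact")
}

#' @export
print.fisher_exact <- function(x, ...) {
  cat("Fisher's exact test\n")
  print(x$table)
  cat(sprintf("one-sided p = %.4g, two-sided p = %.4g, odds ratio = %.3g\n",
              x$p_one_sided, x$p_two_sided, x$odds_ratio))
  invisible(x)
}

#' Kaplan-Meier curves and log-rank comparison of two groups
#'
#' Estimates per-group Kaplan-Meier survival and compares the pair with the
#' log-rank test (`rho = 1` selects the Peto-Peto/Wilcoxon-type weighting).
#'
#' @param data Data.frame with columns `subject_id`, `group`, `time`
#'   (positive) and `event` (logical or 0/1).
#' @param groups Optional pair of group names; defaults to the two groups
#'   present.
#' @param rho Weighting passed to [survival::survdiff()]; 0 = log-rank.
#' @return Object of class `"survival_comparison"`: list with the
#'   [survival::survfit] object `fit`, `chisq`, `df` and `p_value`.
#' @export
survival_compare <- function(data, groups = NULL, rho = 0) {
  required <- c("subject_id", "group", "time", "event")
  missing <- setdiff(required, names(data))
  .assert(length(missing) == 0, "survival table lacks column(s): ",
          .fmt_ids(missing))
  if (!is.null(groups)) {
    .assert(length(groups) == 2, "exactly two groups must be compared")
    data <- data[data$group %in% groups, , drop = FALSE]
    empty <- setdiff(groups, data$group)
    .assert(length(empty) == 0, "group(s) without subjects: ", .fmt_ids(empty))
  }
  .assert(length(unique(data$group)) == 2, "need exactly two groups")
  .assert(all(data$time > 0), "survival times must be positive")
  data$event <- as.integer(as.logical(data$event))
  .assert(sum(data$event) >= 1, "need >= 1 event for a survival comparison")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = data)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = data,
                           rho = rho)
  df <- length(sd$n) - 1
  structure(list(fit = fit, chisq = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat("Two-group survival comparison (log-rank family)\n")
  cat(sprintf("chi-squared = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}

#' @export
plot.survival_comparison <- function(x, ...) {
  graphics::plot(x$fit, col = 1:2, xlab = "time (days)",
                 ylab = "survival probability", ...)
  graphics::legend("topright", legend = sub("^group=", "", names(x$fit$strata)),
                   col = 1:2, lty = 1, bty = "n")
  invisible(x)
}
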