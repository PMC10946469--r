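## Carrier-prevalence estimation, enrichment against a background
## population rate, and manifest-style group comparisons. Exact tests are
## dispatched to the standard stats:: implementations.

#' Estimate carrier prevalence in a cohort
#'
#' A patient is a carrier iff they harbor at least one variant whose
#' verdict is in `classes_counted` (prevalence is estimated assuming one
#' qualifying variant per carrier). With `dedup_families = TRUE` exactly
#' one carrier per `family_id` is retained and the denominator is reduced
#' by the number of removed relatives, so a sibling pair sharing a variant
#' is counted once.
#'
#' @param cohort A [CohortManifest-class].
#' @param classifications Data frame with columns `patient_id` and
#'   `verdict` (e.g. from [classifyVariants()]).
#' @param classes_counted Verdicts that make a patient a carrier.
#' @param dedup_families Collapse carrier relatives to one per family.
#' @return A [PrevalenceResult-class]; `byGroup` splits on the clinical
#'   suspicion flag (`suspected` / `not_suspected`).
#' @export
carrierPrevalence <- function(cohort, classifications,
                              classes_counted = c("pathogenic",
                                                  "likely_pathogenic"),
                              dedup_families = FALSE) {
  stopifnot(is(cohort, "CohortManifest"))
  man <- cohort@data
  if (nrow(man) == 0L)
    stop("empty cohort")
  unknown <- setdiff(unique(classifications$patient_id), man$patient_id)
  if (length(unknown))
    stop("classifications reference unknown patient(s): ",
         paste(unknown, collapse = ", "))
  hits <- classifications[classifications$verdict %in% classes_counted, ,
                          drop = FALSE]
  man$carrier <- man$patient_id %in% hits$patient_id
  removed <- character()
  if (dedup_families) {
    for (fam in unique(man$family_id[man$carrier])) {
      ids <- man$patient_id[man$carrier & man$family_id == fam]
      if (length(ids) > 1L)
        removed <- c(removed, ids[-1L])
    }
    man <- man[!(man$patient_id %in% removed), , drop = FALSE]
  }
  grp <- ifelse(man$suspected, "suspected", "not_suspected")
  byg <- do.call(rbind, lapply(c("suspected", "not_suspected"), function(g) {
    sel <- grp == g
    data.frame(group = g, n = sum(sel), carriers = sum(man$carrier[sel]),
               fraction = if (sum(sel)) sum(man$carrier[sel]) / sum(sel)
                          else NA_real_,
               stringsAsFactors = FALSE)
  }))
  new("PrevalenceResult",
      nTotal = nrow(man), nCarriers = sum(man$carrier),
      prevalence = sum(man$carrier) / nrow(man), byGroup = byg,
      dedupApplied = dedup_families)
}

#' Exact binomial enrichment test against a background rate
#'
#' Tests whether `k` carriers among `n` patients exceed a background
#' carrier fraction `p0`. `"greater"` reports the exact upper tail
#' P(X >= k); `"two_sided"` uses the minimum-likelihood convention (sum of
#' all outcome probabilities not exceeding P(X = k)), as implemented by
#' [stats::binom.test()].
#'
#' @param k Carrier count.
#' @param n Cohort size.
#' @param p0 Background carrier fraction, in (0, 1).
#' @param alternative `"greater"` (default: the hypothesis is enrichment)
#'   or `"two_sided"`.
#' @return A [TestResult-class] with method `"binomial"`.
#' @examples
#' pValue(binomialEnrichment(7, 59, 0.01))
#' @export
binomialEnrichment <- function(k, n, p0,
                               alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must lie strictly between 0 and 1")
  if (k < 0 || k > n)
    stop("k must satisfy 0 <= k <= n")
  ht <- stats::binom.test(k, n, p = p0,
                          alternative = sub("_", ".", alternative))
  .TestResult("binomial", c(carriers = as.numeric(k)), ht$p.value)
}

#' Compare a 2x2 categorical table between groups
#'
#' Pearson's chi-square test without continuity correction when every
#' observed cell is at least 5; otherwise Fisher's exact test (the
#' dispatch uses observed, not expected, counts). The default two-sided
#' Fisher p follows the minimum-likelihood convention of
#' [stats::fisher.test()]; one-sided alternatives are available.
#'
#' @param table A 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (Fisher branch only; the chi-square branch is inherently two-sided).
#' @return A [TestResult-class] with method `"chi_square"` or
#'   `"fisher_exact"`.
#' @examples
#' res <- compareCategorical(matrix(c(4, 31, 11, 14), nrow = 2))
#' testMethod(res)  # "fisher_exact": a cell is < 5
#' @export
compareCategorical <- function(table,
                               alternative = c("two.sided", "less",
                                               "greater")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in contingency table")
  if (any(table < 5)) {
    ht <- stats::fisher.test(table, alternative = alternative)
    .TestResult("fisher_exact", c(odds_ratio = unname(ht$estimate)),
                ht$p.value)
  } else {
    ht <- stats::chisq.test(table, correct = FALSE)
    .TestResult("chi_square", c(X_squared = unname(ht$statistic)),
                ht$p.value)
  }
}

#' Compare a continuous variable between two groups
#'
#' One-way analysis-of-variance F test for two groups (equivalent to the
#' squared equal-variance t statistic).
#'
#' @param values_a,values_b Numeric vectors, each with at least two finite
#'   values.
#' @return A [TestResult-class] with method `"f_test"`.
#' @export
compareContinuous <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least two finite values")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0)
    stop("degenerate (zero) variance in both groups")
  dat <- data.frame(value = c(values_a, values_b),
                    group = factor(rep(c("a", "b"),
                                       c(length(values_a),
                                         length(values_b)))))
  av <- stats::anova(stats::lm(value ~ group, data = dat))
  .TestResult("f_test", c(F = av$`F value`[1L]), av$`Pr(>F)`[1L])
}
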