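## Generics and accessors; slot access stays internal to the package.

#' Extract the underlying data frame of a container
#'
#' @param x A `VariantSet`, `CohortManifest` or `CnvCallSet`.
#' @return The contained data frame (a copy).
#' @export
setGeneric("recordTable", function(x) standardGeneric("recordTable"))

#' @rdname recordTable
#' @export
setMethod("recordTable", "VariantSet", function(x) x@data)

#' @rdname recordTable
#' @export
setMethod("recordTable", "CohortManifest", function(x) x@data)

#' @rdname recordTable
#' @export
setMethod("recordTable", "CnvCallSet", function(x) x@data)

#' Gene symbols of a panel
#' @param x A `GenePanel`.
#' @return Character vector of gene symbols.
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "GenePanel",
          function(x) mcols(x@ranges)$symbol)

#' Inheritance mode per panel gene
#' @param x A `GenePanel`.
#' @return Named character vector (`dominant`/`recessive`), named by symbol.
#' @export
setGeneric("inheritanceMode", function(x) standardGeneric("inheritanceMode"))

#' @rdname inheritanceMode
#' @export
setMethod("inheritanceMode", "GenePanel", function(x) {
  stats::setNames(mcols(x@ranges)$inheritance, mcols(x@ranges)$symbol)
})

#' Allele-frequency cutoff per panel gene
#' @param x A `GenePanel`.
#' @return Named numeric vector of cutoffs, named by symbol.
#' @export
setGeneric("afCutoff", function(x) standardGeneric("afCutoff"))

#' @rdname afCutoff
#' @export
setMethod("afCutoff", "GenePanel", function(x) {
  stats::setNames(mcols(x@ranges)$af_cutoff, mcols(x@ranges)$symbol)
})

#' Genomic intervals of a panel
#' @param x A `GenePanel`.
#' @return A `GRanges` with the panel metadata columns.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname geneRanges
#' @export
setMethod("geneRanges", "GenePanel", function(x) x@ranges)

#' Genome build of a container
#' @param x A `GenePanel`.
#' @return Build label string.
#' @export
setGeneric("genomeBuild", function(x) standardGeneric("genomeBuild"))

#' @rdname genomeBuild
#' @export
setMethod("genomeBuild", "GenePanel", function(x) x@build)

#' Verdict of a classification-like object
#' @param x A `Classification` or `ClinGenAssessment`.
#' @return The five-tier verdict string.
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname verdict
#' @export
setMethod("verdict", "Classification", function(x) x@verdict)

#' @rdname verdict
#' @export
setMethod("verdict", "ClinGenAssessment", function(x) x@verdict)

#' Evidence codes of a profile
#' @param x An `EvidenceProfile`.
#' @return Character vector of codes.
#' @export
setGeneric("evidenceCodes", function(x) standardGeneric("evidenceCodes"))

#' @rdname evidenceCodes
#' @export
setMethod("evidenceCodes", "EvidenceProfile", function(x) x@codes)

#' Total rubric score of a CNV assessment
#' @param x A `ClinGenAssessment`.
#' @return Numeric total score.
#' @export
setGeneric("totalScore", function(x) standardGeneric("totalScore"))

#' @rdname totalScore
#' @export
setMethod("totalScore", "ClinGenAssessment", function(x) x@totalScore)

#' P-value of a test result
#' @param x A `TestResult`.
#' @return Numeric p-value.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname pValue
#' @export
setMethod("pValue", "TestResult", function(x) x@p.value)

#' Test method label of a result
#' @param x A `TestResult`.
#' @return One of `chi_square`, `fisher_exact`, `f_test`, `binomial`.
#' @export
setGeneric("testMethod", function(x) standardGeneric("testMethod"))

#' @rdname testMethod
#' @export
setMethod("testMethod", "TestResult", function(x) x@method)

#' Carrier counts of a prevalence result
#' @param x A `PrevalenceResult`.
#' @return Named list with `n_total`, `n_carriers`, `prevalence`,
#'   `by_group`, `dedup_applied`.
#' @export
setGeneric("carrierCounts", function(x) standardGeneric("carrierCounts"))

#' @rdname carrierCounts
#' @export
setMethod("carrierCounts", "PrevalenceResult", function(x) {
  list(n_total = x@nTotal, n_carriers = x@nCarriers,
       prevalence = x@prevalence, by_group = x@byGroup,
       dedup_applied = x@dedupApplied)
})

## show -------------------------------------------------------------------

setMethod("show", "GenePanel", function(object) {
  mc <- mcols(object@ranges)
  cat("GenePanel with", length(object@ranges), "genes (",
      sum(mc$inheritance == "dominant"), "dominant,",
      sum(mc$inheritance == "recessive"), "recessive ) on build",
      object@build, "\n")
  cat("  af cutoffs:",
      paste(sprintf("%s=%g", names(table(mc$af_cutoff)),
                    as.vector(table(mc$af_cutoff))), collapse = ", "),
      "genes\n")
})

setMethod("show", "VariantSet", function(object) {
  df <- object@data
  cat("VariantSet with", nrow(df), "observations in",
      length(unique(df$patient_id)), "patients,",
      length(unique(df$gene)), "genes\n")
})

setMethod("show", "CohortManifest", function(object) {
  df <- object@data
  cat("CohortManifest with", nrow(df), "patients (",
      sum(df$suspected), "with clinical suspicion )\n")
})

setMethod("show", "CnvCallSet", function(object) {
  df <- object@data
  cat("CnvCallSet with", nrow(df), "calls (",
      sum(df$cnv_type == "loss"), "loss /", sum(df$cnv_type == "gain"),
      "gain )\n")
})

setMethod("show", "EvidenceProfile", function(object) {
  lab <- vapply(object@codes, function(cd) {
    if (cd %in% names(object@strengths))
      paste0(cd, "[", object@strengths[[cd]], "]") else cd
  }, character(1))
  cat("EvidenceProfile:", if (length(lab)) paste(lab, collapse = " ")
      else "(empty)", "\n")
})

setMethod("show", "Classification", function(object) {
  cat("Classification:", object@verdict, "\n")
  if (length(object@rationale))
    cat("  rules fired:", paste(object@rationale, collapse = "; "), "\n")
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult [%s]: statistic = %s, p = %.4g\n",
              object@method,
              if (all(is.na(object@statistic))) "NA"
              else sprintf("%.4g", object@statistic[1L]),
              object@p.value))
})

setMethod("show", "PrevalenceResult", function(object) {
  cat(sprintf("PrevalenceResult: %d / %d carriers (%.1f%%)%s\n",
              object@nCarriers, object@nTotal, 100 * object@prevalence,
              if (object@dedupApplied) ", family-deduplicated" else ""))
  if (nrow(object@byGroup)) {
    for (i in seq_len(nrow(object@byGroup)))
      cat(sprintf("  %s: %d / %d (%.1f%%)\n", object@byGroup$group[i],
                  object@byGroup$carriers[i], object@byGroup$n[i],
                  100 * object@byGroup$fraction[i]))
  }
})

setMethod("show", "ClinGenAssessment", function(object) {
  cat(sprintf("ClinGenAssessment: total score %.2f -> %s\n",
              object@totalScore, object@verdict))
  if (length(object@assessments))
    cat("  criteria:",
        paste(sprintf("%s=%+.2f", names(object@assessments),
                      object@assessments), collapse = ", "), "\n")
})
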