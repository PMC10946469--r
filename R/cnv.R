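## SNP-array QC, CNV call filtering, candidate-gene overlap, span
## computation and ClinGen copy-number-loss scoring. CNV *detection*
## (LRR/BAF segmentation) is out of scope: the module consumes call files.

#' SNP and sample quality control
#'
#' A SNP is removed iff its cluster-separation score is strictly below
#' `min_cluster_sep` (0.27 itself passes); a sample fails iff its call
#' rate is not strictly above `min_call_rate`.
#'
#' @param snps Data frame with `snp_id`, `cluster_separation`.
#' @param samples Data frame with `sample_id`, `call_rate`.
#' @param min_cluster_sep Cluster-separation bound (default 0.27).
#' @param min_call_rate Call-rate bound (default 0.975).
#' @return List with `snps_pass`, `snps_removed`, `samples_pass`,
#'   `samples_failed` data frames.
#' @export
snpQc <- function(snps, samples, min_cluster_sep = 0.27,
                  min_call_rate = 0.975) {
  stopifnot(all(c("snp_id", "cluster_separation") %in% colnames(snps)),
            all(c("sample_id", "call_rate") %in% colnames(samples)))
  snp_ok <- snps$cluster_separation >= min_cluster_sep
  smp_ok <- samples$call_rate > min_call_rate
  list(snps_pass = snps[snp_ok, , drop = FALSE],
       snps_removed = snps[!snp_ok, , drop = FALSE],
       samples_pass = samples[smp_ok, , drop = FALSE],
       samples_failed = samples[!smp_ok, , drop = FALSE])
}

#' Filter CNV calls by supporting-SNP count
#'
#' Retains calls supported by at least `min_snps` consecutive SNPs; no
#' minimal size restriction is applied.
#'
#' @param calls A [CnvCallSet-class].
#' @param min_snps Minimum number of supporting SNPs (default 10).
#' @return A [CnvCallSet-class] of retained calls.
#' @export
cnvFilter <- function(calls, min_snps = 10) {
  stopifnot(is(calls, "CnvCallSet"))
  df <- calls@data
  CnvCallSet(df[df$n_snps >= min_snps, , drop = FALSE])
}

#' Candidate genes overlapped by a CNV call
#'
#' Returns the panel genes whose interval intersects the call's interval
#' by at least one base pair (closed-interval convention: a call ending
#' exactly at a gene's start overlaps it by 1 bp).
#'
#' @param call A one-row data frame (a row of [recordTable()] of a
#'   [CnvCallSet-class]) or a [CnvCallSet-class] with one call.
#' @param panel A [GenePanel-class] on the same genome build.
#' @return Character vector of overlapped gene symbols.
#' @export
overlapCandidateGenes <- function(call, panel) {
  stopifnot(is(panel, "GenePanel"))
  if (is(call, "CnvCallSet")) call <- call@data
  call <- as.data.frame(call)
  stopifnot(nrow(call) == 1L)
  build <- call$genome_build %||% genomeBuild(panel)
  if (!is.null(build) && !is.na(build) && build != genomeBuild(panel))
    stop("genome build mismatch: call is ", build, ", panel is ",
         genomeBuild(panel))
  gr <- GRanges(normalizeChrom(call$chrom),
                IRanges(as.integer(call$start), as.integer(call$end)))
  ## a call on a chromosome with no panel gene is a legitimate empty
  ## result, not a seqlevel mismatch worth warning about
  hits <- suppressWarnings(
    findOverlaps(gr, geneRanges(panel), minoverlap = 1L))
  geneSymbols(panel)[S4Vectors::subjectHits(hits)]
}

#' CNV span in megabases
#'
#' Closed-interval length `(end - start + 1) / 1e6`, rounded half up to
#' one decimal.
#'
#' @param call A one-row CNV call (data frame row or single-call
#'   [CnvCallSet-class]).
#' @return Span in Mb, one decimal.
#' @examples
#' cnvSpanMb(data.frame(start = 71561194, end = 84303230))
#' @export
cnvSpanMb <- function(call) {
  if (is(call, "CnvCallSet")) call <- call@data
  call <- as.data.frame(call)
  stopifnot(nrow(call) == 1L, call$start <= call$end)
  roundHalfUp((call$end - call$start + 1) / 1e6, 1)
}

#' Load the ClinGen copy-number-loss rubric
#'
#' The section-based point rubric ships as an editable CSV
#' (`inst/extdata/clingen_loss_rubric.csv`): criterion IDs, default
#' points and allowed point ranges per criterion.
#'
#' @param path Optional path to an alternative rubric CSV.
#' @return Data frame of rubric criteria.
#' @export
clingenRubric <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "clingen_loss_rubric.csv",
                        package = "affpanel", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Score a copy-number loss against the ClinGen rubric
#'
#' Sums assessed points over the selected criteria (at most one per
#' rubric section) and maps the total to the five-tier verdict bands:
#' >= 0.99 pathogenic; 0.90-0.98 likely pathogenic; -0.89-0.89 uncertain;
#' -0.98 to -0.90 likely benign; <= -0.99 benign. Criteria take their
#' rubric default points unless the assessment overrides them (sections
#' 2, 4 and 5 are evidence-strength judgements, so explicit per-assessment
#' points are accepted for any criterion).
#'
#' @param evidence Either a character vector of criterion IDs (scored at
#'   rubric defaults) or a named numeric vector of assessed points, named
#'   by criterion ID (`NA` points fall back to the default).
#' @param rubric Rubric table from [clingenRubric()].
#' @return A [ClinGenAssessment-class].
#' @examples
#' clingenLossScore(c(`1A` = 0, `2A` = 0, `3C` = 0.9, `4C` = 0, `5G` = 0))
#' @export
clingenLossScore <- function(evidence, rubric = clingenRubric()) {
  if (is.character(evidence))
    evidence <- stats::setNames(rep(NA_real_, length(evidence)), evidence)
  ids <- names(evidence)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("evidence must be named by criterion IDs")
  unknown <- setdiff(ids, rubric$criterion_id)
  if (length(unknown))
    stop("unknown rubric criterion ID(s): ",
         paste(unknown, collapse = ", "))
  sec <- rubric$section[match(ids, rubric$criterion_id)]
  if (anyDuplicated(sec))
    stop("at most one criterion may be selected per rubric section ",
         "(section ", sec[duplicated(sec)][1L], " selected twice)")
  pts <- as.numeric(evidence)
  def <- rubric$default_points[match(ids, rubric$criterion_id)]
  pts[is.na(pts)] <- def[is.na(pts)]
  if (any(pts < -1 | pts > 1))
    stop("assessed points must lie in [-1, 1]")
  total <- sum(pts)
  verdict <- if (total >= 0.99) "pathogenic"
    else if (total >= 0.90) "likely_pathogenic"
    else if (total > -0.90) "uncertain_significance"
    else if (total > -0.99) "likely_benign"
    else "benign"
  new("ClinGenAssessment", totalScore = total, verdict = verdict,
      assessments = stats::setNames(pts, ids))
}
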