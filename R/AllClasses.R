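#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end findOverlaps
#' @importFrom IRanges IRanges
NULL

## Controlled vocabularies -----------------------------------------------

#' Controlled vocabularies used across the package
#'
#' Consequence classes follow ANNOVAR-style exonic/splicing annotation
#' collapsed to the categories the filtering funnel distinguishes; zygosity
#' and ClinVar assertion values are the ones the readers accept.
#'
#' @name vocabularies
#' @keywords internal
NULL

.CONSEQUENCES <- c("nonsynonymous", "stopgain", "stoploss", "splicing",
                   "utr", "frameshift_indel", "inframe_indel",
                   "synonymous", "other")

## consequence classes kept by the funnel's consequence stage
.RETAINED_CONSEQUENCES <- c("nonsynonymous", "stopgain", "stoploss",
                            "splicing", "utr", "frameshift_indel",
                            "inframe_indel")

## loss-of-function classes; "splicing" only at canonical +/-1/2 sites
.LOF_CONSEQUENCES <- c("stopgain", "stoploss", "frameshift_indel", "splicing")

.ZYGOSITIES <- c("het", "hom", "hemi")

.CLINVAR <- c("pathogenic", "likely_pathogenic", "uncertain",
              "likely_benign", "benign", "conflicting", "absent")

.VERDICTS <- c("pathogenic", "likely_pathogenic", "uncertain_significance",
               "likely_benign", "benign")

.INHERITANCE <- c("dominant", "recessive")

.STRENGTHS <- c("very_strong", "strong", "moderate", "supporting",
                "stand_alone")

## required columns of a variant table
.VARIANT_COLS <- c("patient_id", "chrom", "pos", "ref", "alt", "gene",
                   "consequence", "zygosity", "qd", "af_db1", "af_db2",
                   "cadd", "clinvar")

.MANIFEST_COLS <- c("patient_id", "suspected", "family_id", "sex", "bp_use",
                    "bp_years", "gc_long_term", "center", "age_at_aff",
                    "osteoporosis_flag", "bilateral_flag")

.CNV_COLS <- c("patient_id", "chrom", "start", "end", "cnv_type", "n_snps")

## GenePanel --------------------------------------------------------------

#' GenePanel: a candidate-gene panel with inheritance modes and intervals
#'
#' Holds one row per gene: symbol, inheritance mode (dominant/recessive),
#' the allele-frequency cutoff used by the rarity filter, an X-linked flag,
#' and the gene's genomic interval as a [GenomicRanges::GRanges] (1-based,
#' closed).
#'
#' @slot ranges A `GRanges` with metadata columns `symbol`, `inheritance`,
#'   `af_cutoff`, `is_x_linked`.
#' @slot build Genome build label, e.g. `"GRCh37"`.
#'
#' @seealso [loadGenePanel()], [defaultGenePanel()]
#' @export
setClass("GenePanel",
         representation(ranges = "GRanges", build = "character"))

setValidity("GenePanel", function(object) {
  mc <- mcols(object@ranges)
  need <- c("symbol", "inheritance", "af_cutoff", "is_x_linked")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing panel metadata columns:",
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(mc$symbol))
    return("duplicate gene symbol in panel")
  if (!all(mc$inheritance %in% .INHERITANCE))
    return("inheritance must be 'dominant' or 'recessive'")
  if (any(mc$af_cutoff <= 0 | mc$af_cutoff > 1))
    return("af_cutoff must lie in (0, 1]")
  if (length(object@build) != 1L)
    return("build must be a single string")
  TRUE
})

#' Construct a GenePanel from a data frame
#'
#' @param df A data frame with columns `symbol`, `inheritance`, `chrom`,
#'   `start`, `end`, and optionally `af_cutoff` (auto-assigned from the
#'   inheritance mode when missing: 0.001 dominant, 0.01 recessive) and
#'   `is_x_linked`.
#' @param build Genome build label.
#' @return A [GenePanel-class] object.
#' @export
GenePanel <- function(df, build = "GRCh37") {
  df <- as.data.frame(df)
  need <- c("symbol", "inheritance", "chrom", "start", "end")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    stop("panel contains no genes")
  df$symbol <- toupper(as.character(df$symbol))
  df$inheritance <- tolower(as.character(df$inheritance))
  bad <- setdiff(unique(df$inheritance), .INHERITANCE)
  if (length(bad))
    stop("unknown inheritance token(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$symbol))
    stop("duplicate gene symbol(s): ",
         paste(unique(df$symbol[duplicated(df$symbol)]), collapse = ", "))
  if (is.null(df$af_cutoff)) df$af_cutoff <- NA_real_
  df$af_cutoff <- ifelse(is.na(df$af_cutoff),
                         ifelse(df$inheritance == "dominant", 0.001, 0.01),
                         as.numeric(df$af_cutoff))
  chrom <- normalizeChrom(df$chrom)
  if (is.null(df$is_x_linked)) df$is_x_linked <- chrom == "X"
  if (any(df$start > df$end))
    stop("gene interval with start > end")
  gr <- GRanges(chrom, IRanges(as.integer(df$start), as.integer(df$end)))
  mcols(gr) <- S4Vectors::DataFrame(symbol = df$symbol,
                                    inheritance = df$inheritance,
                                    af_cutoff = df$af_cutoff,
                                    is_x_linked = as.logical(df$is_x_linked))
  new("GenePanel", ranges = gr, build = build)
}

## VariantSet -------------------------------------------------------------

#' VariantSet: annotated per-patient variant observations
#'
#' One row per (patient, variant) observation with ANNOVAR-style
#' annotation: consequence class, zygosity, quality-by-depth (QD),
#' population allele frequencies from two reference databases (1000
#' Genomes-like and gnomAD-like), CADD score and ClinVar assertion.
#' Numeric fields may be `NA` ("absent"), never silently zero; an absent
#' allele frequency means the variant was not observed in that database and
#' is treated as 0 for threshold comparisons (see the provenance flag
#' `af_absent` that the readers add).
#'
#' Optional columns understood downstream: `splice_canonical` (logical;
#' splicing variants default to canonical +/-1/2 sites, `FALSE` marks a
#' non-canonical splice-region variant that must not count as
#' loss-of-function), `evidence_extra` (comma-separated curated ACMG codes
#' merged into the automatic evidence profile) and `evidence_override`
#' (semicolon-separated `CODE=strength` strength overrides).
#'
#' @slot data A data frame with at least the columns listed in the details.
#' @seealso [readVariantTable()], [filterFunnel()], [classifyVariants()]
#' @export
setClass("VariantSet", representation(data = "data.frame"))

setValidity("VariantSet", function(object) {
  df <- object@data
  miss <- setdiff(.VARIANT_COLS, colnames(df))
  if (length(miss))
    return(paste("missing variant column(s):", paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (any(!nzchar(df$ref)) || any(!nzchar(df$alt)))
    return("ref and alt alleles must be non-empty")
  if (any(df$ref == df$alt))
    return("ref and alt alleles must differ")
  if (any(df$pos < 1L))
    return("pos must be >= 1")
  for (col in c("af_db1", "af_db2")) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad))
      return(sprintf("%s outside [0,1] at row %d", col, bad[1L]))
  }
  if (any(!is.na(df$qd) & df$qd < 0))
    return("qd must be non-negative")
  if (!all(df$consequence %in% .CONSEQUENCES))
    return("unknown consequence class")
  if (!all(df$zygosity %in% .ZYGOSITIES))
    return("unknown zygosity")
  if (!all(df$clinvar %in% .CLINVAR))
    return("unknown clinvar assertion")
  TRUE
})

#' Construct a VariantSet from a data frame
#'
#' Coerces types, normalizes chromosome labels and fills optional columns;
#' validates value ranges and controlled vocabularies.
#'
#' @param df Data frame of variant observations (see [VariantSet-class]).
#' @return A [VariantSet-class] object.
#' @export
VariantSet <- function(df) {
  df <- as.data.frame(df)
  miss <- setdiff(.VARIANT_COLS, colnames(df))
  if (length(miss))
    stop("variant table is missing column(s): ",
         paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  df$chrom <- normalizeChrom(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- as.character(df$ref)
  df$alt <- as.character(df$alt)
  df$gene <- toupper(as.character(df$gene))
  df$consequence <- as.character(df$consequence)
  df$zygosity <- as.character(df$zygosity)
  for (col in c("qd", "af_db1", "af_db2", "cadd"))
    df[[col]] <- as.numeric(df[[col]])
  df$clinvar <- as.character(df$clinvar)
  df$clinvar[is.na(df$clinvar) | df$clinvar == ""] <- "absent"
  ## provenance: absent frequency = not observed in that database
  df$af_absent <- is.na(df$af_db1) & is.na(df$af_db2)
  if (is.null(df$splice_canonical))
    df$splice_canonical <- ifelse(df$consequence == "splicing", TRUE, NA)
  if (is.null(df$evidence_extra))
    df$evidence_extra <- rep("", nrow(df))
  if (is.null(df$evidence_override))
    df$evidence_override <- rep("", nrow(df))
  df$evidence_extra[is.na(df$evidence_extra)] <- ""
  df$evidence_override[is.na(df$evidence_override)] <- ""
  rownames(df) <- NULL
  new("VariantSet", data = df)
}

## CohortManifest ---------------------------------------------------------

#' CohortManifest: the patient manifest of an AFF cohort
#'
#' One row per patient: clinical suspicion flag for a monogenic bone
#' disorder, family identifier (shared by relatives), sex, bisphosphonate
#' use and duration, long-term glucocorticoid use, recruiting center and
#' further covariates.
#'
#' @slot data A data frame with the manifest columns.
#' @seealso [loadManifest()], [carrierPrevalence()]
#' @export
setClass("CohortManifest", representation(data = "data.frame"))

setValidity("CohortManifest", function(object) {
  df <- object@data
  miss <- setdiff(.MANIFEST_COLS, colnames(df))
  if (length(miss))
    return(paste("missing manifest column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$patient_id))
    return("duplicate patient_id in manifest")
  if (any(!df$bp_use & !is.na(df$bp_years)))
    return("bp_years present for a patient with bp_use = FALSE")
  TRUE
})

#' Construct a CohortManifest from a data frame
#'
#' @param df Data frame of patients (see [CohortManifest-class]).
#' @return A [CohortManifest-class] object.
#' @export
CohortManifest <- function(df) {
  df <- as.data.frame(df)
  miss <- setdiff(.MANIFEST_COLS, colnames(df))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "))
  df$suspected <- as.logical(df$suspected)
  df$family_id <- as.character(df$family_id)
  df$bp_use <- as.logical(df$bp_use)
  df$bp_years <- as.numeric(df$bp_years)
  df$gc_long_term <- as.logical(df$gc_long_term)
  rownames(df) <- NULL
  new("CohortManifest", data = df)
}

## CnvCallSet -------------------------------------------------------------

#' CnvCallSet: SNP-array copy-number calls
#'
#' PennCNV-style segments: patient, interval (1-based closed), type
#' (loss/gain), number of supporting consecutive SNPs and genome build.
#' An optional `gene_count` column carries the number of protein-coding
#' genes the segment spans (an input attribute used by the ClinGen
#' section-3 tiers, not recomputed from a bundled gene model).
#'
#' @slot data A data frame of calls.
#' @seealso [readCnvCalls()], [cnvFilter()], [clingenLossScore()]
#' @export
setClass("CnvCallSet", representation(data = "data.frame"))

setValidity("CnvCallSet", function(object) {
  df <- object@data
  miss <- setdiff(.CNV_COLS, colnames(df))
  if (length(miss))
    return(paste("missing CNV column(s):", paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (any(df$start > df$end)) return("CNV with start > end")
  if (any(df$n_snps < 1L)) return("n_snps must be >= 1")
  if (!all(df$cnv_type %in% c("loss", "gain")))
    return("cnv_type must be 'loss' or 'gain'")
  TRUE
})

#' Construct a CnvCallSet from a data frame
#'
#' @param df Data frame of CNV calls (see [CnvCallSet-class]).
#' @param build Genome build label applied where the table has none.
#' @return A [CnvCallSet-class] object.
#' @export
CnvCallSet <- function(df, build = "GRCh37") {
  df <- as.data.frame(df)
  miss <- setdiff(.CNV_COLS, colnames(df))
  if (length(miss))
    stop("CNV table is missing column(s): ", paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  df$chrom <- normalizeChrom(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$cnv_type <- tolower(as.character(df$cnv_type))
  df$n_snps <- as.integer(df$n_snps)
  if (is.null(df$genome_build)) df$genome_build <- build
  if (is.null(df$gene_count)) df$gene_count <- NA_integer_
  rownames(df) <- NULL
  new("CnvCallSet", data = df)
}

## Small result classes ---------------------------------------------------

#' EvidenceProfile: a set of ACMG evidence codes with strengths
#'
#' Codes are the standard tokens (PVS1; PS1-PS4; PM1-PM6; PP1-PP5; BA1;
#' BS1-BS4; BP1-BP7). Each code carries its default strength from its
#' prefix (PVS very strong, PS strong, PM moderate, PP supporting, BA
#' stand-alone, BS strong-benign, BP supporting-benign) unless overridden,
#' e.g. `PVS1` applied at `strong` for a truncating variant that may escape
#' nonsense-mediated decay.
#'
#' @slot codes Character vector of code tokens (unique).
#' @slot strengths Named character vector of strength overrides (may be
#'   empty); names are codes, values one of `very_strong`, `strong`,
#'   `moderate`, `supporting`, `stand_alone`.
#' @seealso [combineAcmg()], [autoAssignEvidence()]
#' @export
setClass("EvidenceProfile",
         representation(codes = "character", strengths = "character"))

setValidity("EvidenceProfile", function(object) {
  if (anyDuplicated(object@codes))
    return("a code may appear at most once")
  bad <- object@codes[!grepl("^(PVS1|PS[1-4]|PM[1-6]|PP[1-5]|BA1|BS[1-4]|BP[1-7])$",
                             object@codes)]
  if (length(bad))
    return(paste("unknown ACMG code token(s):", paste(bad, collapse = ", ")))
  if (length(object@strengths)) {
    if (is.null(names(object@strengths)) ||
        !all(names(object@strengths) %in% object@codes))
      return("strength overrides must be named by codes in the profile")
    if (!all(object@strengths %in% .STRENGTHS))
      return("unknown strength token")
  }
  TRUE
})

#' Construct an EvidenceProfile
#'
#' @param codes Character vector of ACMG code tokens.
#' @param strengths Optional named character vector of strength overrides.
#' @return An [EvidenceProfile-class] object.
#' @export
EvidenceProfile <- function(codes = character(), strengths = character()) {
  new("EvidenceProfile", codes = unique(as.character(codes)),
      strengths = strengths)
}

#' Classification: a five-tier pathogenicity verdict
#'
#' @slot verdict One of `pathogenic`, `likely_pathogenic`,
#'   `uncertain_significance`, `likely_benign`, `benign`.
#' @slot rationale Character vector of combination rules that fired.
#' @export
setClass("Classification",
         representation(verdict = "character", rationale = "character"))

setValidity("Classification", function(object) {
  if (length(object@verdict) != 1L || !(object@verdict %in% .VERDICTS))
    return("verdict must be one of the five tiers")
  TRUE
})

#' TestResult: a hypothesis-test outcome
#'
#' @slot method One of `chi_square`, `fisher_exact`, `f_test`, `binomial`.
#' @slot statistic Named numeric statistic (may be `NA` for exact tests).
#' @slot p.value P-value in \[0, 1\].
#' @export
setClass("TestResult",
         representation(method = "character", statistic = "numeric",
                        p.value = "numeric"))

setValidity("TestResult", function(object) {
  if (!is.na(object@p.value) &&
      (object@p.value < 0 || object@p.value > 1))
    return("p.value must lie in [0, 1]")
  TRUE
})

.TestResult <- function(method, statistic, p.value)
  new("TestResult", method = method, statistic = statistic,
      p.value = as.numeric(p.value))

#' PrevalenceResult: carrier prevalence in a cohort
#'
#' @slot nTotal Number of patients counted (after any family
#'   deduplication).
#' @slot nCarriers Number of carriers.
#' @slot prevalence `nCarriers / nTotal`.
#' @slot byGroup Data frame with one row per suspicion group (`group`,
#'   `n`, `carriers`, `fraction`).
#' @slot dedupApplied Whether one-carrier-per-family deduplication was
#'   applied.
#' @seealso [carrierPrevalence()]
#' @export
setClass("PrevalenceResult",
         representation(nTotal = "integer", nCarriers = "integer",
                        prevalence = "numeric", byGroup = "data.frame",
                        dedupApplied = "logical"))

setValidity("PrevalenceResult", function(object) {
  if (object@nCarriers < 0L || object@nCarriers > object@nTotal)
    return("0 <= nCarriers <= nTotal violated")
  if (object@nTotal > 0L &&
      abs(object@prevalence - object@nCarriers / object@nTotal) > 1e-12)
    return("prevalence must equal nCarriers / nTotal")
  TRUE
})

#' ClinGenAssessment: a scored copy-number-loss rubric assessment
#'
#' @slot totalScore Sum of assessed points over the rubric sections.
#' @slot verdict Five-tier verdict from the score bands (>= 0.99
#'   pathogenic; 0.90 to 0.98 likely pathogenic; -0.89 to 0.89 uncertain;
#'   -0.98 to -0.90 likely benign; <= -0.99 benign).
#' @slot assessments Named numeric vector of assessed points per criterion.
#' @seealso [clingenLossScore()]
#' @export
setClass("ClinGenAssessment",
         representation(totalScore = "numeric", verdict = "character",
                        assessments = "numeric"))
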