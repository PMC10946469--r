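## Readers and writers for variant tables, gene panels, manifests,
## CNV call files and JSON reports. TSV is the canonical dialect; the VCF
## reader is a deliberate v4.2 subset (GT plus INFO keys mapped via
## `vcf_map`), not a full VCF implementation.

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix so `"chr6"` and `"6"` compare equal;
#' idempotent.
#'
#' @param x Character (or coercible) vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalizeChrom(c("chr6", "6", "chrX"))
#' @export
normalizeChrom <- function(x) {
  sub("^chr", "", as.character(x))
}

#' Round half away from zero
#'
#' Reported percentages and CNV spans use commercial (half-up) rounding at
#' the stated precision, not banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read an annotated variant table
#'
#' Reads either the canonical tab-separated dialect (one row per
#' (patient, variant) observation, header naming the mandatory columns) or
#' a minimal VCF subset in which per-record annotation lives in INFO keys
#' and carriers are identified from the per-sample GT field (`0/1`, `1/0`
#' het; `1/1` hom; haploid `1` hemi; `0/0` and `./.` not reported).
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param vcf_map Named list mapping variant fields to INFO keys for the
#'   VCF dialect. Defaults map `gene`=GENE, `consequence`=CSQCLASS,
#'   `qd`=QD, `af_db1`=AF1, `af_db2`=AF2, `cadd`=CADD, `clinvar`=CLNSIG.
#' @return A [VariantSet-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' df <- data.frame(patient_id = "P1", chrom = "chr7", pos = 100,
#'                  ref = "G", alt = "T", gene = "COL1A2",
#'                  consequence = "stopgain", zygosity = "het", qd = 21,
#'                  af_db1 = 0.0005, af_db2 = NA, cadd = 44,
#'                  clinvar = "absent")
#' write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' readVariantTable(tf)
#' @export
readVariantTable <- function(path, dialect = c("tsv", "vcf"),
                             vcf_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (dialect == "tsv") {
    chr_cols <- c("patient_id", "chrom", "ref", "alt", "gene",
                  "consequence", "zygosity", "clinvar", "evidence_extra",
                  "evidence_override")
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    cc <- stats::setNames(rep("character", sum(hdr %in% chr_cols)),
                          intersect(hdr, chr_cols))
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            na.strings = c("NA", "", "."),
                            colClasses = cc)
    miss <- setdiff(.VARIANT_COLS, colnames(df))
    if (length(miss))
      stop("variant table is missing column(s): ",
           paste(miss, collapse = ", "))
    for (col in c("af_db1", "af_db2")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(!is.na(v) & (v < 0 | v > 1))
      if (length(bad))
        stop(sprintf("%s outside [0,1] at row %d", col, bad[1L]))
    }
    VariantSet(df)
  } else {
    .readVariantVcf(path, vcf_map)
  }
}

.DEFAULT_VCF_MAP <- list(gene = "GENE", consequence = "CSQCLASS", qd = "QD",
                         af_db1 = "AF1", af_db2 = "AF2", cadd = "CADD",
                         clinvar = "CLNSIG")

.readVariantVcf <- function(path, vcf_map = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("the VCF dialect requires the VariantAnnotation package")
  map <- utils::modifyList(.DEFAULT_VCF_MAP, as.list(vcf_map %||% list()))
  vcf <- VariantAnnotation::readVcf(path, genome = "GRCh37")
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt))
    stop("VCF dialect requires a GT FORMAT field")
  getInfo <- function(field, default) {
    key <- map[[field]]
    if (!is.null(key) && key %in% colnames(info)) {
      v <- info[[key]]
      if (is(v, "List") || is.list(v))
        v <- vapply(v, function(e) if (length(e)) as.character(e[[1L]])
                    else NA_character_, character(1))
      as.character(v)
    } else rep(default, nrow(gt))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  base <- data.frame(
    chrom = normalizeChrom(as.character(seqnames(rr))),
    pos = start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(as.list(VariantAnnotation::alt(vcf)),
                 function(a) as.character(a[[1L]]), character(1)),
    gene = getInfo("gene", NA_character_),
    consequence = getInfo("consequence", "other"),
    qd = num(getInfo("qd", NA_character_)),
    af_db1 = num(getInfo("af_db1", NA_character_)),
    af_db2 = num(getInfo("af_db2", NA_character_)),
    cadd = num(getInfo("cadd", NA_character_)),
    clinvar = {
      cv <- getInfo("clinvar", "absent")
      cv[is.na(cv)] <- "absent"
      cv
    },
    stringsAsFactors = FALSE)
  out <- list()
  for (s in colnames(gt)) {
    g <- gsub("\\|", "/", gt[, s])
    zyg <- rep(NA_character_, length(g))
    zyg[g %in% c("0/1", "1/0")] <- "het"
    zyg[g == "1/1"] <- "hom"
    zyg[g == "1"] <- "hemi"
    keep <- !is.na(zyg)
    if (!any(keep)) next
    rec <- base[keep, , drop = FALSE]
    rec$patient_id <- s
    rec$zygosity <- zyg[keep]
    out[[s]] <- rec
  }
  df <- if (length(out)) do.call(rbind, out) else
    cbind(base[0, , drop = FALSE], patient_id = character(),
          zygosity = character())
  VariantSet(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a variant table to TSV
#'
#' Inverse of [readVariantTable()] for the TSV dialect; round-trips all
#' modeled fields.
#'
#' @param vs A [VariantSet-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeVariantTable <- function(vs, path) {
  stopifnot(is(vs, "VariantSet"))
  df <- vs@data
  df$af_absent <- NULL
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Load a candidate-gene panel
#'
#' Reads a TSV with columns `symbol`, `inheritance`, `chrom`, `start`,
#' `end` and optional `af_cutoff` override. Genes of dominant-class
#' disorders receive the stringent rarity cutoff of 0.001, recessive-class
#' genes 0.01 (a single disease allele of a recessive disorder need not be
#' extremely rare in the population), unless overridden per row.
#'
#' @param path Path to a panel TSV, or `NULL` for the bundled default
#'   37-gene monogenic bone-disorder panel.
#' @param build Genome build label.
#' @return A [GenePanel-class].
#' @seealso [defaultGenePanel()]
#' @export
loadGenePanel <- function(path = NULL, build = "GRCh37") {
  if (is.null(path))
    path <- system.file("extdata", "gene_panel.tsv", package = "affpanel",
                        mustWork = TRUE)
  if (!file.exists(path))
    stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", ""))
  if (nrow(df) == 0L)
    stop("panel contains no genes")
  GenePanel(df, build = build)
}

#' The bundled 37-gene monogenic bone-disorder panel
#'
#' Fifteen genes of dominantly inherited bone disorders (including the
#' X-linked PLS3 and PHEX, grouped with the dominant cutoff class) and 22
#' genes of recessively inherited disorders. Interval coordinates are
#' approximate GRCh37 gene spans (a reconstruction; see the panel file
#' header).
#'
#' @return A [GenePanel-class] with 37 genes.
#' @export
defaultGenePanel <- function() loadGenePanel(NULL)

#' Load a patient manifest
#'
#' @param path Path to a manifest TSV with the columns of
#'   [CohortManifest-class].
#' @return A [CohortManifest-class].
#' @export
loadManifest <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  CohortManifest(df)
}

#' Write a patient manifest to TSV
#'
#' @param cohort A [CohortManifest-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeManifest <- function(cohort, path) {
  stopifnot(is(cohort, "CohortManifest"))
  utils::write.table(cohort@data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a CNV call table
#'
#' Accepts a PennCNV-rawcnv-like TSV with columns `patient_id`, `chrom`,
#' `start`, `end`, `cnv_type`, `n_snps` and optional `genome_build`,
#' `gene_count`.
#'
#' @param path Path to the TSV.
#' @param build Genome build applied where the table has none.
#' @return A [CnvCallSet-class].
#' @export
readCnvCalls <- function(path, build = "GRCh37") {
  if (!file.exists(path))
    stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  CnvCallSet(df, build = build)
}

#' Read SNP and sample QC tables
#'
#' @param snp_path TSV with columns `snp_id`, `cluster_separation`.
#' @param sample_path TSV with columns `sample_id`, `call_rate`.
#' @return A list with data frames `snps` and `samples`.
#' @export
readSnpQc <- function(snp_path, sample_path) {
  rd <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    utils::read.table(p, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  snps <- rd(snp_path)
  samples <- rd(sample_path)
  if (any(snps$cluster_separation < 0 | snps$cluster_separation > 1))
    stop("cluster_separation outside [0,1]")
  if (any(samples$call_rate < 0 | samples$call_rate > 1))
    stop("call_rate outside [0,1]")
  list(snps = snps, samples = samples)
}

#' Write an analysis report
#'
#' Serializes a report list (per-variant classifications, per-group
#' counts, test results, effective configuration) to JSON or, for the
#' per-variant table alone, to TSV.
#'
#' @param results A named list; data frames are serialized column-wise.
#' @param path Output path.
#' @param format `"json"` (full report) or `"tsv"` (the `classifications`
#'   element only).
#' @return Invisibly, `path`.
#' @export
writeReport <- function(results, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    if (is.null(results$classifications))
      stop("TSV report requires a 'classifications' data frame")
    utils::write.table(results$classifications, path, sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Path to a JSON report written by [writeReport()].
#' @return The report list.
#' @export
readReport <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
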