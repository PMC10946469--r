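## The variant-retention funnel: quality-by-depth filter, consequence
## restriction, inheritance-aware allele-frequency filter, and
## genotype-pattern flagging. Stage order is fixed (qd -> consequence ->
## frequency) and the funnel is idempotent.

.variantKey <- function(df) {
  paste(df$patient_id, df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

.emptyTrace <- function() {
  data.frame(variant_key = character(), patient_id = character(),
             gene = character(), stage_removed = character(),
             retained = logical(), stringsAsFactors = FALSE)
}

.trace <- function(df, stage) {
  if (nrow(df) == 0L) return(.emptyTrace())
  data.frame(variant_key = .variantKey(df), patient_id = df$patient_id,
             gene = df$gene, stage_removed = stage,
             retained = stage == "none", stringsAsFactors = FALSE)
}

#' Quality-by-depth (QD) filter
#'
#' Removes variants whose QD (QUAL normalized by allele depth) is <= 5.
#' Variants with an absent QD -- e.g. externally validated calls merged
#' into the table -- are retained with a warning: the QD filter targets
#' raw caller output.
#'
#' @param vs A [VariantSet-class].
#' @param threshold QD threshold; variants with `qd <= threshold` are
#'   removed (default 5).
#' @return A list with `variants` (retained [VariantSet-class]) and
#'   `trace` (one row per input variant: `stage_removed` is `"qd"` or
#'   `"none"`).
#' @export
qdFilter <- function(vs, threshold = 5) {
  stopifnot(is(vs, "VariantSet"))
  df <- vs@data
  if (nrow(df) == 0L)
    return(list(variants = vs, trace = .emptyTrace()))
  absent <- is.na(df$qd)
  if (any(absent))
    warning(sum(absent), " variant(s) without a QD score retained")
  removed <- !absent & df$qd <= threshold
  trace <- .trace(df, ifelse(removed, "qd", "none"))
  list(variants = VariantSet(df[!removed, , drop = FALSE]), trace = trace)
}

#' Consequence-class filter
#'
#' Restricts the analysis to nonsynonymous, stopgain, stoploss and
#' splicing variants, UTR variants and exonic indels; synonymous and other
#' (e.g. intergenic) classes are removed.
#'
#' @param vs A [VariantSet-class].
#' @return A list with `variants` (retained) and `trace`.
#' @export
consequenceFilter <- function(vs) {
  stopifnot(is(vs, "VariantSet"))
  df <- vs@data
  if (nrow(df) == 0L)
    return(list(variants = vs, trace = .emptyTrace()))
  removed <- !(df$consequence %in% .RETAINED_CONSEQUENCES)
  trace <- .trace(df, ifelse(removed, "consequence", "none"))
  list(variants = VariantSet(df[!removed, , drop = FALSE]), trace = trace)
}

#' Inheritance-aware allele-frequency filter
#'
#' A variant is retained iff the maximum of its two reference-database
#' frequencies (absent treated as 0: not observed is the rarest state) is
#' strictly below the cutoff of its gene -- 0.001 for dominant-class
#' genes, 0.01 for recessive-class genes in the default panel. Variants in
#' genes not on the panel are dropped with a warning.
#'
#' @param vs A [VariantSet-class].
#' @param panel A [GenePanel-class].
#' @return A list with `variants` (retained) and `trace` (stage
#'   `"frequency"` for removals; off-panel rows are absent from the
#'   output set and marked `"frequency"` in the trace as well).
#' @export
frequencyFilter <- function(vs, panel) {
  stopifnot(is(vs, "VariantSet"), is(panel, "GenePanel"))
  df <- vs@data
  if (nrow(df) == 0L)
    return(list(variants = vs, trace = .emptyTrace()))
  cutoffs <- afCutoff(panel)
  offpanel <- !(df$gene %in% names(cutoffs))
  if (any(offpanel))
    warning(sum(offpanel), " variant(s) in genes outside the panel dropped")
  maxaf <- pmax(ifelse(is.na(df$af_db1), 0, df$af_db1),
                ifelse(is.na(df$af_db2), 0, df$af_db2))
  cut <- rep(NA_real_, nrow(df))
  cut[!offpanel] <- cutoffs[df$gene[!offpanel]]
  removed <- offpanel | maxaf >= cut
  trace <- .trace(df, ifelse(removed, "frequency", "none"))
  list(variants = VariantSet(df[!removed, , drop = FALSE]), trace = trace)
}

#' Run the full variant-retention funnel
#'
#' Applies [qdFilter()], [consequenceFilter()] and [frequencyFilter()] in
#' that fixed order and merges the per-stage traces so that every input
#' variant has exactly one trace row (`stage_removed` in
#' `qd`/`consequence`/`frequency`/`none`).
#'
#' @param vs A [VariantSet-class].
#' @param panel A [GenePanel-class].
#' @param qd_threshold QD threshold passed to [qdFilter()].
#' @return A list with `variants` (retained [VariantSet-class]) and
#'   `trace`.
#' @export
filterFunnel <- function(vs, panel, qd_threshold = 5) {
  s1 <- qdFilter(vs, threshold = qd_threshold)
  s2 <- consequenceFilter(s1$variants)
  s3 <- frequencyFilter(s2$variants, panel)
  trace <- rbind(s1$trace[s1$trace$stage_removed != "none", , drop = FALSE],
                 s2$trace[s2$trace$stage_removed != "none", , drop = FALSE],
                 s3$trace)
  rownames(trace) <- NULL
  list(variants = s3$variants, trace = trace)
}

#' Flag inheritance-consistent genotype patterns
#'
#' For each (patient, gene) pair among the retained variants:
#' heterozygous (or homozygous) variants in dominant-class genes flag
#' `dominant_het`; hemizygous genotypes (X-linked genes in males) flag
#' `hemizygous`; in recessive-class genes a homozygous variant flags
#' `recessive_hom`, two or more distinct heterozygous variants flag
#' `recessive_compound_het` (phase-unaware: no trio data, so any two
#' retained heterozygous variants in one gene count, with phase unknown),
#' and exactly one heterozygous variant flags `recessive_carrier` --
#' carrier findings remain reportable.
#'
#' @param vs A [VariantSet-class] of retained (already filtered) variants.
#' @param panel A [GenePanel-class].
#' @return Data frame with columns `patient_id`, `gene`, `pattern`,
#'   `n_variants`.
#' @export
genotypePatterns <- function(vs, panel) {
  stopifnot(is(vs, "VariantSet"), is(panel, "GenePanel"))
  df <- vs@data
  inh <- inheritanceMode(panel)
  out <- list()
  if (nrow(df)) {
    keys <- unique(df[, c("patient_id", "gene")])
    for (i in seq_len(nrow(keys))) {
      pid <- keys$patient_id[i]; g <- keys$gene[i]
      if (!(g %in% names(inh))) next
      zy <- df$zygosity[df$patient_id == pid & df$gene == g]
      pattern <- if (any(zy == "hemi")) {
        "hemizygous"
      } else if (inh[[g]] == "dominant") {
        "dominant_het"
      } else if (any(zy == "hom")) {
        "recessive_hom"
      } else if (sum(zy == "het") >= 2L) {
        "recessive_compound_het"
      } else {
        "recessive_carrier"
      }
      out[[length(out) + 1L]] <-
        data.frame(patient_id = pid, gene = g, pattern = pattern,
                   n_variants = length(zy), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(patient_id = character(), gene = character(),
                      pattern = character(), n_variants = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
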