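## ACMG/AMP classification: the full evidence-combination engine used for
## case variants, and the filter-based proxy classifier used where
## manually curating evidence for every variant is impractical (large
## control sets).

#' Load the ACMG combining-rule table
#'
#' The published combining matrix ships as an editable CSV (see
#' `inst/extdata/acmg_combining_rules.csv`) so refined combining
#' recommendations can be swapped in without code changes.
#'
#' @param path Optional path to an alternative rules CSV.
#' @return Data frame of combining rules.
#' @export
acmgRules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "acmg_combining_rules.csv",
                        package = "affpanel", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

## default strength from the code prefix; benign-side codes are tracked
## separately from pathogenic-side codes
.codeSide <- function(code) ifelse(grepl("^B", code), "benign", "pathogenic")

.defaultStrength <- function(code) {
  ifelse(grepl("^PVS", code), "very_strong",
  ifelse(grepl("^PS", code), "strong",
  ifelse(grepl("^PM", code), "moderate",
  ifelse(grepl("^PP", code), "supporting",
  ifelse(grepl("^BA", code), "stand_alone",
  ifelse(grepl("^BS", code), "strong", "supporting"))))))
}

## effective strength counts of a profile:
## vs/s/m/p pathogenic side, ba/bs/bp benign side
.strengthCounts <- function(profile) {
  codes <- profile@codes
  if (!length(codes))
    return(c(vs = 0, s = 0, m = 0, p = 0, ba = 0, bs = 0, bp = 0))
  str <- .defaultStrength(codes)
  ov <- profile@strengths
  if (length(ov)) str[match(names(ov), codes)] <- unname(ov)
  side <- .codeSide(codes)
  c(vs = sum(side == "pathogenic" & str == "very_strong"),
    s  = sum(side == "pathogenic" & str == "strong"),
    m  = sum(side == "pathogenic" & str == "moderate"),
    p  = sum(side == "pathogenic" & str == "supporting"),
    ba = sum(side == "benign" & str == "stand_alone"),
    bs = sum(side == "benign" & str == "strong"),
    bp = sum(side == "benign" & str == "supporting"))
}

.ruleMatches <- function(rule, n) {
  chk <- function(field, value) {
    lo <- rule[[paste0(field, "_min")]] %||% NA
    hi <- rule[[paste0(field, "_max")]] %||% NA
    (is.na(lo) || value >= lo) && (is.na(hi) || value <= hi)
  }
  chk("vs", n[["vs"]]) && chk("s", n[["s"]]) && chk("m", n[["m"]]) &&
    chk("p", n[["p"]]) && chk("ba", n[["ba"]]) && chk("bs", n[["bs"]]) &&
    chk("bp", n[["bp"]])
}

#' Combine ACMG evidence into a five-tier verdict
#'
#' Applies the standard combining matrix: the pathogenic arm (pathogenic,
#' then likely pathogenic rules) and the benign arm (benign, then likely
#' benign rules) are evaluated on the effective strength counts; if both
#' arms are satisfied the evidence is contradictory and the verdict is
#' uncertain significance, as it is when no rule fires. The combiner is a
#' pure function of the profile.
#'
#' @param evidence An [EvidenceProfile-class] (or character vector of
#'   codes, coerced with default strengths).
#' @param rules Combining-rule table from [acmgRules()].
#' @return A [Classification-class].
#' @examples
#' verdict(combineAcmg(c("PVS1", "PM2")))           # likely_pathogenic
#' verdict(combineAcmg(c("PVS1", "PS1", "PM2")))    # pathogenic
#' verdict(combineAcmg(c("BA1")))                   # benign
#' verdict(combineAcmg(character()))                # uncertain_significance
#' @export
combineAcmg <- function(evidence, rules = acmgRules()) {
  if (is.character(evidence))
    evidence <- EvidenceProfile(evidence)
  stopifnot(is(evidence, "EvidenceProfile"))
  validObject(evidence)
  n <- .strengthCounts(evidence)
  fired <- vapply(seq_len(nrow(rules)),
                  function(i) .ruleMatches(rules[i, ], n), logical(1))
  hit <- rules[fired, , drop = FALSE]
  pathArm <- hit$verdict %in% c("pathogenic", "likely_pathogenic")
  benArm <- hit$verdict %in% c("benign", "likely_benign")
  if (any(pathArm) && any(benArm))
    return(new("Classification", verdict = "uncertain_significance",
               rationale = c("conflicting_evidence", hit$rule_id)))
  if (any(pathArm)) {
    v <- if ("pathogenic" %in% hit$verdict) "pathogenic"
         else "likely_pathogenic"
    return(new("Classification", verdict = v,
               rationale = hit$rule_id[pathArm]))
  }
  if (any(benArm)) {
    v <- if ("benign" %in% hit$verdict) "benign" else "likely_benign"
    return(new("Classification", verdict = v,
               rationale = hit$rule_id[benArm]))
  }
  new("Classification", verdict = "uncertain_significance",
      rationale = character())
}

## is this row's consequence loss-of-function? splicing only at canonical
## +/-1/2 sites (splice_canonical FALSE marks a non-canonical site)
.isLof <- function(df) {
  lof <- df$consequence %in% .LOF_CONSEQUENCES
  spl <- df$consequence == "splicing"
  canon <- if (!is.null(df$splice_canonical)) {
    !vapply(df$splice_canonical, isFALSE, logical(1))
  } else rep(TRUE, nrow(df))
  lof & (!spl | canon)
}

.maxAf <- function(df) {
  pmax(ifelse(is.na(df$af_db1), 0, df$af_db1),
       ifelse(is.na(df$af_db2), 0, df$af_db2))
}

#' Automatically assign ACMG evidence codes from variant annotation
#'
#' Assigns the automatable subset of codes: PM2 for extreme rarity
#' (maximum database frequency < `pm2_max_af`, absent treated as 0), PP3
#' for computational support (CADD strictly > `pp3_cadd`), PVS1 for
#' loss-of-function consequences (stopgain, stoploss, frameshift indel,
#' canonical-site splicing), PS1 for a ClinVar pathogenic assertion, PP5
#' for a ClinVar likely-pathogenic assertion and BP6 for a ClinVar
#' (likely) benign assertion. Manually curated codes are merged from the
#' variant's `evidence_extra` / `evidence_override` columns by
#' [classifyVariants()].
#'
#' @param variant A one-row data frame of variant annotation (a row of
#'   [recordTable()] of a [VariantSet-class]).
#' @param pm2_max_af PM2 rarity bound (default 1e-4).
#' @param pp3_cadd PP3 CADD bound, strict (default 15).
#' @return An [EvidenceProfile-class].
#' @export
autoAssignEvidence <- function(variant, pm2_max_af = 1e-4, pp3_cadd = 15) {
  df <- as.data.frame(variant)
  stopifnot(nrow(df) == 1L)
  codes <- character()
  if (.maxAf(df) < pm2_max_af) codes <- c(codes, "PM2")
  if (!is.na(df$cadd) && df$cadd > pp3_cadd) codes <- c(codes, "PP3")
  if (.isLof(df)) codes <- c(codes, "PVS1")
  if (df$clinvar == "pathogenic") codes <- c(codes, "PS1")
  if (df$clinvar == "likely_pathogenic") codes <- c(codes, "PP5")
  if (df$clinvar %in% c("benign", "likely_benign"))
    codes <- c(codes, "BP6")
  EvidenceProfile(codes)
}

#' Filter-based proxy classification
#'
#' The scalable stand-in for manual ACMG curation: a variant lands in the
#' (likely) pathogenic bucket iff it is (i) extremely rare (maximum
#' database frequency < `pm2_max_af`), (ii) computationally supported
#' (CADD > `pp3_cadd`, or CADD unavailable for a loss-of-function
#' consequence -- an indel without a CADD score satisfies (ii) only if it
#' is loss-of-function), and (iii) loss-of-function or asserted
#' (likely) pathogenic in ClinVar. The (likely) benign bucket is ClinVar
#' (likely) benign assertions; everything else is a VUS. Bucket verdicts
#' are reported as `likely_pathogenic` / `likely_benign` since the proxy
#' does not separate the certain from the likely tier.
#'
#' @param variant A one-row data frame of variant annotation.
#' @param pm2_max_af Rarity bound (default 1e-4).
#' @param pp3_cadd CADD bound, strict (default 15).
#' @return A [Classification-class].
#' @export
proxyClassify <- function(variant, pm2_max_af = 1e-4, pp3_cadd = 15) {
  df <- as.data.frame(variant)
  stopifnot(nrow(df) == 1L)
  v <- .proxyVerdicts(df, pm2_max_af, pp3_cadd)
  rationale <- switch(v,
    likely_pathogenic = c("proxy_rare", "proxy_computational",
                          if (.isLof(df)) "proxy_lof" else "proxy_clinvar"),
    likely_benign = "proxy_clinvar_benign",
    character())
  new("Classification", verdict = v, rationale = rationale)
}

## vectorized proxy rule over a variant data frame
.proxyVerdicts <- function(df, pm2_max_af = 1e-4, pp3_cadd = 15) {
  lof <- .isLof(df)
  rare <- .maxAf(df) < pm2_max_af
  comp <- (!is.na(df$cadd) & df$cadd > pp3_cadd) | (is.na(df$cadd) & lof)
  known <- df$clinvar %in% c("pathogenic", "likely_pathogenic")
  path <- rare & comp & (lof | known)
  ben <- !path & df$clinvar %in% c("benign", "likely_benign")
  ifelse(path, "likely_pathogenic",
         ifelse(ben, "likely_benign", "uncertain_significance"))
}

.parseCodes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  toupper(trimws(strsplit(x, "[,;]")[[1L]]))
}

.parseOverrides <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  parts <- trimws(strsplit(x, ";")[[1L]])
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=")
  stats::setNames(vapply(kv, function(p) trimws(p[2L]), character(1)),
                  vapply(kv, function(p) toupper(trimws(p[1L])),
                         character(1)))
}

#' Classify every variant of a set
#'
#' With `engine = "acmg"` each variant's automatic evidence
#' ([autoAssignEvidence()]) is merged with curated codes from the
#' `evidence_extra` column and strength overrides from
#' `evidence_override`, then combined by [combineAcmg()]. With
#' `engine = "proxy"` the filter-based [proxyClassify()] rule is applied
#' instead.
#'
#' @param vs A [VariantSet-class].
#' @param engine `"acmg"` or `"proxy"`.
#' @param rules Combining-rule table (ACMG engine only).
#' @param pm2_max_af,pp3_cadd Evidence thresholds (see
#'   [autoAssignEvidence()]).
#' @return Data frame with one row per variant: identifiers, `verdict`,
#'   `codes` (space-separated effective evidence, ACMG engine only),
#'   `rationale`, plus `consequence`, `zygosity` and `cadd` carried over
#'   for reporting.
#' @export
classifyVariants <- function(vs, engine = c("acmg", "proxy"),
                             rules = acmgRules(), pm2_max_af = 1e-4,
                             pp3_cadd = 15) {
  engine <- match.arg(engine)
  stopifnot(is(vs, "VariantSet"))
  df <- vs@data
  n <- nrow(df)
  verdicts <- character(n); codes <- character(n); rat <- character(n)
  if (engine == "proxy" && n) {
    verdicts <- .proxyVerdicts(df, pm2_max_af, pp3_cadd)
    rat <- ifelse(verdicts == "likely_pathogenic", "proxy_filter",
                  ifelse(verdicts == "likely_benign",
                         "proxy_clinvar_benign", ""))
  } else for (i in seq_len(n)) {
    row <- df[i, , drop = FALSE]
    prof <- autoAssignEvidence(row, pm2_max_af = pm2_max_af,
                               pp3_cadd = pp3_cadd)
    extra <- .parseCodes(row$evidence_extra)
    ov <- .parseOverrides(row$evidence_override)
    prof <- EvidenceProfile(c(prof@codes, extra),
                            ov[names(ov) %in% c(prof@codes, extra)])
    cl <- combineAcmg(prof, rules = rules)
    lab <- vapply(prof@codes, function(cd) {
      if (cd %in% names(prof@strengths))
        paste0(cd, "[", prof@strengths[[cd]], "]") else cd
    }, character(1))
    codes[i] <- paste(lab, collapse = " ")
    verdicts[i] <- cl@verdict
    rat[i] <- paste(cl@rationale, collapse = ";")
  }
  data.frame(variant_key = if (n) .variantKey(df) else character(),
             patient_id = df$patient_id, gene = df$gene,
             verdict = verdicts, codes = codes, rationale = rat,
             consequence = df$consequence, zygosity = df$zygosity,
             cadd = df$cadd, stringsAsFactors = FALSE)
}

#' Report VUS with strong computational support
#'
#' Selects, from classified variants, those of uncertain significance
#' with a CADD score at or above `cadd_min`, plus uncertain-significance
#' indels for which no CADD score is available.
#'
#' @param classified Data frame from [classifyVariants()].
#' @param cadd_min Inclusive CADD bound (default 20).
#' @return The qualifying subset of `classified`.
#' @export
vusCaddReport <- function(classified, cadd_min = 20) {
  stopifnot(all(c("verdict", "cadd", "consequence") %in%
                colnames(classified)))
  vus <- classified$verdict == "uncertain_significance"
  indel <- classified$consequence %in% c("frameshift_indel",
                                         "inframe_indel")
  keep <- vus & ((!is.na(classified$cadd) & classified$cadd >= cadd_min) |
                 (is.na(classified$cadd) & indel))
  out <- classified[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
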