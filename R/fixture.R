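## The bundled worked example: a 60-patient AFF cohort (15 with clinical
## suspicion of a monogenic bone disorder, including a sibling pair; 45
## without), its nine (likely) pathogenic panel variants, thirteen
## high-CADD VUS in twelve patients, and a 12.7 Mb chromosome-6 deletion.
## Everything is built in code so every pipeline stage is testable with no
## external data. Evidence codes are reconstructed minimal sets consistent
## with each variant's printed consequence/CADD/ClinVar attributes and
## verdict; population frequencies of the planted variants are recorded as
## absent ("not observed"), consistent with all of them having survived
## the rarity filter.

#' The worked 60-patient AFF example cohort
#'
#' Builds, fully in code, an AFF cohort manifest of 60 patients
#' (identifiers `S1`-`S15` carry clinical suspicion of a monogenic bone
#' disorder, `NS1`-`NS45` do not; `S6`/`S7` are siblings sharing a family
#' identifier), a variant table with nine (likely) pathogenic variants in
#' `PLS3`, `ALPL`, `COL1A2`, `LRP5` and `TCIRG1` plus thirteen
#' uncertain-significance variants (CADD >= 20 or indels without a CADD
#' score) in twelve patients, a chromosome-6 deletion call
#' (6:71,561,194-84,303,230, 87 protein-coding genes, overlapping the
#' panel gene `TENT5A`), and the deletion's copy-number-loss rubric
#' assessment. In that assessment only the gene-count section contributes
#' points (`3C` at its +0.90 default); criterion `2A` is recorded as
#' evaluated but assessed at 0 points -- an explicit override of its +1.0
#' rubric default, preserving the worked example's total of 0.9 (see the
#' methods vignette).
#'
#' Variant evidence codes are reconstructed minimal sets: the truncating
#' variants of `COL1A2` (C-propeptide region) and `TCIRG1` and the
#' canonical splice variant of `LRP5` carry `PVS1` downgraded to strong
#' (possible escape from nonsense-mediated decay / uncertain splice
#' consequence), which yields their likely-pathogenic verdicts.
#'
#' @return A list with elements `cohort` ([CohortManifest-class]),
#'   `variants` ([VariantSet-class]), `cnv` ([CnvCallSet-class]),
#'   `cnv_evidence` (named numeric vector of assessed rubric points) and
#'   `snp_qc` (list of example SNP/sample QC tables).
#' @examples
#' fx <- affExampleCohort()
#' fx$cohort
#' @export
affExampleCohort <- function() {
  list(cohort = .exampleManifest(),
       variants = .exampleVariants(),
       cnv = .exampleCnv(),
       cnv_evidence = c(`1A` = 0, `2A` = 0, `3C` = 0.9, `4C` = 0,
                        `5G` = 0),
       snp_qc = .exampleSnpQc())
}

.exampleManifest <- function() {
  s_id <- paste0("S", 1:15)
  ns_id <- paste0("NS", 1:45)
  ## suspected group: 10 female / 5 male; 13 bisphosphonate users;
  ## 4 long-term glucocorticoid users; centers 13 EMC / 2 LUMC
  s <- data.frame(
    patient_id = s_id,
    suspected = TRUE,
    family_id = ifelse(s_id %in% c("S6", "S7"), "FAM_SIB",
                       paste0("F_", s_id)),
    sex = ifelse(s_id %in% c("S1", "S2", "S10", "S12", "S13"),
                 "male", "female"),
    bp_use = !(s_id %in% c("S5", "S14")),
    bp_years = NA_real_,
    gc_long_term = s_id %in% c("S9", "S12", "S13", "S14"),
    center = ifelse(s_id %in% c("S14", "S15"), "LUMC", "EMC"),
    age_at_aff = seq(46, 74, by = 2),
    osteoporosis_flag = s_id != "S10",
    bilateral_flag = s_id %in% paste0("S", 1:9),
    stringsAsFactors = FALSE)
  s$bp_years[s$bp_use] <- round(seq(3, 12, length.out = sum(s$bp_use)), 1)
  ## non-suspected group: 34 female / 11 male; 44 users; 31 GC users;
  ## centers 40 EMC / 5 LUMC
  ns <- data.frame(
    patient_id = ns_id,
    suspected = FALSE,
    family_id = paste0("F_", ns_id),
    sex = ifelse(ns_id %in% c("NS7", paste0("NS", 10:19)),
                 "male", "female"),
    bp_use = ns_id != "NS20",
    bp_years = NA_real_,
    gc_long_term = ns_id %in% paste0("NS", 1:31),
    center = ifelse(ns_id %in% paste0("NS", 41:45), "LUMC", "EMC"),
    age_at_aff = rep(seq(50, 78, by = 2), 3),
    osteoporosis_flag = !(ns_id %in% paste0("NS", 38:45)),
    bilateral_flag = ns_id %in% paste0("NS", 1:22),
    stringsAsFactors = FALSE)
  ns$bp_years[ns$bp_use] <- round(seq(4, 14, length.out = sum(ns$bp_use)), 1)
  CohortManifest(rbind(s, ns))
}

.exampleVariants <- function() {
  v <- function(patient, chrom, pos, ref, alt, gene, consequence, cadd,
                clinvar, extra = "", override = "") {
    data.frame(patient_id = patient, chrom = chrom, pos = pos, ref = ref,
               alt = alt, gene = gene, consequence = consequence,
               zygosity = "het", qd = 25, af_db1 = NA_real_,
               af_db2 = NA_real_, cadd = cadd, clinvar = clinvar,
               evidence_extra = extra, evidence_override = override,
               stringsAsFactors = FALSE)
  }
  plp <- rbind(
    ## two PLS3 single-base deletions (X-linked osteoporosis), pathogenic
    v("S1", "X", 114830000, "CT", "C", "PLS3", "frameshift_indel",
      NA, "pathogenic"),
    v("S2", "X", 114801000, "AT", "A", "PLS3", "frameshift_indel",
      NA, "pathogenic"),
    ## ALPL canonical splice-donor variant (hypophosphatasia), pathogenic
    v("S3", "1", 21890000, "T", "A", "ALPL", "splicing", 16,
      "pathogenic"),
    ## COL1A2 C-propeptide stopgain: PVS1 at strong (possible NMD escape)
    v("S4", "7", 94056000, "G", "T", "COL1A2", "stopgain", 44, "absent",
      override = "PVS1=strong"),
    ## ALPL in-frame single-residue deletion; curated PM4 + PP4
    v("S5", "1", 21887000, "AGAC", "A", "ALPL", "inframe_indel", NA,
      "likely_pathogenic", extra = "PM4,PP4"),
    ## COL1A2 triple-helical glycine substitution shared by the siblings
    v("S6", "7", 94040000, "G", "A", "COL1A2", "nonsynonymous", 26,
      "pathogenic"),
    v("S7", "7", 94040000, "G", "A", "COL1A2", "nonsynonymous", 26,
      "pathogenic"),
    ## LRP5 canonical splice-donor variant; PVS1 at strong
    v("S15", "11", 68201000, "G", "A", "LRP5", "splicing", 22, "absent",
      override = "PVS1=strong"),
    ## TCIRG1 stopgain in a non-suspected patient (recessive carrier);
    ## PVS1 at strong (shortened protein or NMD)
    v("NS2", "11", 67810000, "C", "T", "TCIRG1", "stopgain", 39,
      "likely_pathogenic", override = "PVS1=strong"))
  vus <- rbind(
    v("S8", "17", 48270000, "ACAA", "A", "COL1A1", "inframe_indel", NA,
      "uncertain"),
    v("S9", "11", 68193000, "G", "T", "LRP5", "nonsynonymous", 20,
      "uncertain"),
    v("S10", "8", 22046000, "G", "A", "BMP1", "nonsynonymous", 33,
      "uncertain"),
    v("S11", "7", 94049000, "G", "A", "COL1A2", "nonsynonymous", 25,
      "uncertain"),
    v("NS2", "17", 79809000, "G", "A", "P4HB", "nonsynonymous", 30,
      "uncertain"),
    v("NS2", "18", 60020000, "A", "G", "TNFRSF11A", "nonsynonymous", 22,
      "uncertain"),
    v("NS3", "11", 46320000, "G", "A", "CREB3L1", "nonsynonymous", 35,
      "uncertain"),
    v("NS4", "11", 67813000, "C", "T", "TCIRG1", "nonsynonymous", 32,
      "uncertain"),
    v("NS5", "11", 75277000, "C", "T", "SERPINH1", "nonsynonymous", 29,
      "uncertain"),
    v("NS6", "3", 145830000, "C", "T", "PLOD2", "nonsynonymous", 26,
      "uncertain"),
    v("NS7", "1", 43220000, "C", "A", "LEPRE1", "nonsynonymous", 26,
      "uncertain"),
    v("NS8", "17", 79812000, "A", "G", "P4HB", "nonsynonymous", 22,
      "uncertain"),
    v("NS9", "X", 22100000, "A", "G", "PHEX", "nonsynonymous", 20,
      "uncertain"))
  VariantSet(rbind(plp, vus))
}

.exampleCnv <- function() {
  CnvCallSet(data.frame(
    patient_id = "NS24", chrom = "6", start = 71561194, end = 84303230,
    cnv_type = "loss", n_snps = 6000, genome_build = "GRCh37",
    gene_count = 87, stringsAsFactors = FALSE))
}

.exampleSnpQc <- function() {
  list(snps = data.frame(
         snp_id = c("rs0001", "rs0002", "rs0003", "rs0004"),
         cluster_separation = c(0.95, 0.27, 0.26, 0.10),
         stringsAsFactors = FALSE),
       samples = data.frame(
         sample_id = c("S1", "NS1", "LOWCALL"),
         call_rate = c(0.998, 0.991, 0.97),
         stringsAsFactors = FALSE))
}
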