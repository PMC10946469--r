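# Builders for small in-code fixtures used across the suite.

# one variant observation with sensible defaults, overridable per field
mkVariant <- function(patient_id = "P1", chrom = "1", pos = 21890000L,
                      ref = "C", alt = "T", gene = "ALPL",
                      consequence = "nonsynonymous", zygosity = "het",
                      qd = 30, af_db1 = NA_real_, af_db2 = NA_real_,
                      cadd = NA_real_, clinvar = "absent", ...) {
  data.frame(patient_id = patient_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene = gene, consequence = consequence,
             zygosity = zygosity, qd = qd, af_db1 = af_db1,
             af_db2 = af_db2, cadd = cadd, clinvar = clinvar, ...,
             stringsAsFactors = FALSE)
}

mkVariantSet <- function(...) VariantSet(rbind(...))

# a two-gene panel: one dominant (COL1A2), one recessive (TCIRG1)
mkPanel <- function() {
  GenePanel(data.frame(
    symbol = c("COL1A2", "TCIRG1", "ALPL", "LRP5", "PLS3"),
    inheritance = c("dominant", "recessive", "dominant", "dominant",
                    "dominant"),
    chrom = c("7", "11", "1", "11", "X"),
    start = c(1000L, 1000L, 1000L, 5000L, 1000L),
    end = c(2000L, 2000L, 2000L, 6000L, 2000L),
    stringsAsFactors = FALSE))
}

# random variant table for property-style tests (attributes independent)
randomVariants <- function(n, panel = mkPanel()) {
  genes <- geneSymbols(panel)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    mkVariant(patient_id = sample(paste0("P", 1:6), 1L),
              chrom = "1", pos = 1000L + i, ref = "A",
              alt = sample(c("G", "T"), 1L),
              gene = sample(genes, 1L),
              consequence = sample(c("nonsynonymous", "stopgain",
                                     "synonymous", "splicing", "other",
                                     "frameshift_indel"), 1L),
              zygosity = sample(c("het", "hom"), 1L, prob = c(0.8, 0.2)),
              qd = round(stats::runif(1L, 0, 40), 2),
              af_db1 = if (stats::runif(1) < 0.4) NA_real_ else
                signif(stats::runif(1L, 0, 0.02), 3),
              af_db2 = if (stats::runif(1) < 0.6) NA_real_ else
                signif(stats::runif(1L, 0, 0.02), 3),
              cadd = if (stats::runif(1) < 0.3) NA_real_ else
                round(stats::runif(1L, 0, 45), 1),
              clinvar = sample(c("absent", "uncertain", "pathogenic",
                                 "likely_pathogenic", "benign",
                                 "likely_benign"), 1L))
  }))
  VariantSet(df)
}
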