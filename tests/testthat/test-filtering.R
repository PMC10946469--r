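# The variant-retention funnel and genotype-pattern flagging.

test_that("QD filter removes <= 5, keeps absent QD with a warning", {
  vs <- mkVariantSet(mkVariant(patient_id = "A", qd = 5.0),
                     mkVariant(patient_id = "B", qd = 5.01),
                     mkVariant(patient_id = "C", qd = NA))
  expect_warning(res <- qdFilter(vs), "without a QD")
  kept <- recordTable(res$variants)$patient_id
  expect_setequal(kept, c("B", "C"))
  expect_equal(res$trace$stage_removed[res$trace$patient_id == "A"], "qd")

  empty <- qdFilter(VariantSet(recordTable(vs)[0, ]))
  expect_equal(nrow(recordTable(empty$variants)), 0L)
  expect_equal(nrow(empty$trace), 0L)
})

test_that("consequence filter keeps coding/splicing/UTR/indel classes only", {
  keepers <- c("nonsynonymous", "stopgain", "stoploss", "splicing", "utr",
               "frameshift_indel", "inframe_indel")
  removed <- c("synonymous", "other")
  vs <- do.call(mkVariantSet, lapply(seq_along(c(keepers, removed)),
    function(i) mkVariant(patient_id = paste0("P", i), pos = 21890000L + i,
                          consequence = c(keepers, removed)[i])))
  res <- consequenceFilter(vs)
  expect_setequal(recordTable(res$variants)$consequence, keepers)
  expect_equal(sum(res$trace$stage_removed == "consequence"), 2L)
})

test_that("frequency filter applies the gene's inheritance-class cutoff", {
  panel <- mkPanel()
  vs <- mkVariantSet(
    mkVariant(patient_id = "A", gene = "COL1A2", chrom = "7",
              af_db1 = 0.002),                     # dominant: 0.002 >= 0.001
    mkVariant(patient_id = "B", gene = "TCIRG1", chrom = "11",
              af_db1 = 0.005),                     # recessive: 0.005 < 0.01
    mkVariant(patient_id = "C", gene = "COL1A2", chrom = "7",
              af_db1 = NA, af_db2 = NA),           # absent: rarest state
    mkVariant(patient_id = "D", gene = "COL1A2", chrom = "7",
              af_db1 = 0.001),                     # boundary: strict "<"
    mkVariant(patient_id = "E", gene = "COL1A2", chrom = "7",
              af_db1 = 5e-4, af_db2 = 0.003))      # max over databases
  res <- frequencyFilter(vs, panel)
  expect_setequal(recordTable(res$variants)$patient_id, c("B", "C"))
})

test_that("variants in off-panel genes are dropped with a warning", {
  vs <- mkVariantSet(mkVariant(gene = "NOTONPANEL"))
  expect_warning(res <- frequencyFilter(vs, mkPanel()), "outside the panel")
  expect_equal(nrow(recordTable(res$variants)), 0L)
})

test_that("the funnel conserves counts and is idempotent", {
  panel <- mkPanel()
  set.seed(42)
  for (rep in 1:5) {
    vs <- randomVariants(40, panel)
    res <- suppressWarnings(filterFunnel(vs, panel))
    expect_equal(nrow(res$trace), nrow(recordTable(vs)))
    expect_equal(sum(res$trace$retained),
                 nrow(recordTable(res$variants)))
    expect_true(all(res$trace$retained ==
                    (res$trace$stage_removed == "none")))
    again <- suppressWarnings(filterFunnel(res$variants, panel))
    expect_equal(recordTable(again$variants),
                 recordTable(res$variants))
    expect_true(all(again$trace$retained))
  }
})

test_that("genotype patterns follow inheritance mode", {
  panel <- mkPanel()
  vs <- mkVariantSet(
    # one het stopgain in a recessive gene: reportable carrier
    mkVariant(patient_id = "P1", gene = "TCIRG1", chrom = "11",
              consequence = "stopgain"),
    # two distinct hets in a recessive gene, same patient: compound het
    mkVariant(patient_id = "P2", gene = "TCIRG1", chrom = "11",
              pos = 1100L),
    mkVariant(patient_id = "P2", gene = "TCIRG1", chrom = "11",
              pos = 1200L),
    # hom in a recessive gene
    mkVariant(patient_id = "P3", gene = "TCIRG1", chrom = "11",
              zygosity = "hom"),
    # het in a dominant gene
    mkVariant(patient_id = "P4", gene = "COL1A2", chrom = "7"),
    # hemizygous male X genotype under the dominant pathway
    mkVariant(patient_id = "P5", gene = "PLS3", chrom = "X",
              zygosity = "hemi"))
  pat <- genotypePatterns(vs, panel)
  got <- setNames(pat$pattern, pat$patient_id)
  expect_equal(got[["P1"]], "recessive_carrier")
  expect_equal(got[["P2"]], "recessive_compound_het")
  expect_equal(got[["P3"]], "recessive_hom")
  expect_equal(got[["P4"]], "dominant_het")
  expect_equal(got[["P5"]], "hemizygous")
})

test_that("genotype patterns agree with brute-force zygosity multisets", {
  panel <- mkPanel()
  inh <- inheritanceMode(panel)
  # independent oracle: classify each (patient, gene) zygosity multiset
  oracle <- function(df) {
    keys <- unique(df[, c("patient_id", "gene")])
    out <- character(nrow(keys))
    for (i in seq_len(nrow(keys))) {
      zy <- sort(df$zygosity[df$patient_id == keys$patient_id[i] &
                             df$gene == keys$gene[i]])
      out[i] <-
        if ("hemi" %in% zy) "hemizygous"
        else if (inh[[keys$gene[i]]] == "dominant") "dominant_het"
        else if ("hom" %in% zy) "recessive_hom"
        else if (sum(zy == "het") >= 2) "recessive_compound_het"
        else "recessive_carrier"
    }
    cbind(keys, pattern = out)
  }
  set.seed(7)
  for (rep in 1:10) {
    vs <- randomVariants(25, panel)
    got <- genotypePatterns(vs, panel)
    want <- oracle(recordTable(vs))
    key <- function(d) paste(d$patient_id, d$gene)
    expect_setequal(paste(key(got), got$pattern),
                    paste(key(want), want$pattern))
  }
})
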