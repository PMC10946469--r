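# Domain types and readers: variant tables (TSV and minimal VCF), gene
# panels, manifests, CNV calls, reports.

test_that("TSV variant tables round-trip losslessly", {
  tf <- tempfile(fileext = ".tsv")
  vs <- mkVariantSet(
    mkVariant(af_db1 = 0.0005, zygosity = "het"),
    mkVariant(patient_id = "P2", pos = 21890100L, consequence = "stopgain",
              cadd = 39, clinvar = "likely_pathogenic"))
  writeVariantTable(vs, tf)
  back <- readVariantTable(tf)
  expect_equal(nrow(recordTable(back)), 2L)
  expect_equal(recordTable(back)$af_db1[1L], 0.0005)
  cols <- setdiff(colnames(recordTable(vs)), "af_absent")
  expect_equal(recordTable(back)[cols], recordTable(vs)[cols])
})

test_that("absent numeric fields stay absent and are flagged, never zeroed", {
  tf <- tempfile(fileext = ".tsv")
  writeVariantTable(mkVariantSet(mkVariant(af_db1 = NA, af_db2 = NA,
                                           qd = NA)), tf)
  df <- recordTable(readVariantTable(tf))
  expect_true(is.na(df$af_db1) && is.na(df$af_db2) && is.na(df$qd))
  expect_true(df$af_absent)
})

test_that("frequency outside [0,1] is rejected with the row number", {
  tf <- tempfile(fileext = ".tsv")
  df <- mkVariant(af_db1 = 1.5)
  write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readVariantTable(tf), "af_db1.*row 1")
})

test_that("missing mandatory columns are named in the error", {
  tf <- tempfile(fileext = ".tsv")
  df <- mkVariant()
  df$zygosity <- NULL
  write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readVariantTable(tf), "zygosity")
})

test_that("VCF GT codes map to zygosity and only carriers are reported", {
  skip_if_not_installed("VariantAnnotation")
  # enumerate GT codes against the expected zygosity per sample
  gts <- c(SA = "0/0", SB = "0/1", SC = "1/0", SD = "1/1", SE = "./.")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"Class\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Qual by depth\">",
    "##INFO=<ID=AF1,Number=1,Type=Float,Description=\"db1 AF\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", names(gts)), collapse = "\t"),
    paste(c("chr7", "94040000", ".", "G", "A", "100", "PASS",
            "GENE=COL1A2;CSQCLASS=nonsynonymous;QD=21.5;AF1=0.0002;CADD=26",
            "GT", unname(gts)), collapse = "\t"))
  tf <- tempfile(fileext = ".vcf")
  writeLines(vcf, tf)
  vs <- recordTable(readVariantTable(tf, dialect = "vcf"))
  expect_setequal(vs$patient_id, c("SB", "SC", "SD"))
  expect_equal(vs$zygosity[match(c("SB", "SC", "SD"), vs$patient_id)],
               c("het", "het", "hom"))
  expect_equal(unique(vs$chrom), "7")  # "chr" prefix stripped
  expect_equal(unique(vs$gene), "COL1A2")
  expect_equal(unique(vs$af_db1), 2e-4)

  # haploid male X genotype maps to hemizygous
  vcf2 <- sub("0/0\t0/1\t1/0\t1/1\t\\./\\.", "1\t0\t0/1\t0/0\t0/0",
              paste(vcf, collapse = "\n"))
  writeLines(strsplit(vcf2, "\n")[[1]], tf)
  vs2 <- recordTable(readVariantTable(tf, dialect = "vcf"))
  expect_equal(vs2$zygosity[vs2$patient_id == "SA"], "hemi")
})

test_that("the bundled panel has 37 genes, 15 at the 0.001 cutoff", {
  panel <- defaultGenePanel()
  expect_length(geneSymbols(panel), 37L)
  expect_equal(sum(afCutoff(panel) == 0.001), 15L)
  expect_equal(sum(afCutoff(panel) == 0.01), 22L)
  # dominant rows auto-assign the stringent cutoff
  expect_true(all(afCutoff(panel)[inheritanceMode(panel) == "dominant"]
                  == 0.001))
  # X-linked genes grouped with the dominant cutoff class
  expect_true(all(c("PLS3", "PHEX") %in%
                  names(which(afCutoff(panel) == 0.001))))
})

test_that("panel loading rejects degenerate input", {
  tf <- tempfile(fileext = ".tsv")
  writeLines("symbol\tinheritance\tchrom\tstart\tend", tf)
  expect_error(loadGenePanel(tf), "no genes")
  writeLines(c("symbol\tinheritance\tchrom\tstart\tend",
               "ALPL\tdominant\t1\t1\t10",
               "ALPL\tdominant\t1\t1\t10"), tf)
  expect_error(loadGenePanel(tf), "[Dd]uplicate")
  writeLines(c("symbol\tinheritance\tchrom\tstart\tend",
               "ALPL\tmaternal\t1\t1\t10"), tf)
  expect_error(loadGenePanel(tf), "inheritance")
})

test_that("manifests round-trip and reject duplicate patients", {
  fx <- affExampleCohort()
  tf <- tempfile(fileext = ".tsv")
  writeManifest(fx$cohort, tf)
  back <- loadManifest(tf)
  expect_equal(recordTable(back), recordTable(fx$cohort))
  df <- recordTable(fx$cohort)
  df$patient_id[2] <- df$patient_id[1]
  expect_error(CohortManifest(df), "[Dd]uplicate")
})

test_that("JSON reports round-trip their counts", {
  fx <- affExampleCohort()
  rep <- runCasePipeline(pipelineConfig(manifest = fx$cohort,
                                        variants = fx$variants))
  tf <- tempfile(fileext = ".json")
  writeReport(rep[c("prevalence_acmg", "classifications")], tf)
  back <- readReport(tf)
  expect_equal(back$prevalence_acmg$n_carriers,
               rep$prevalence_acmg$n_carriers)
  expect_equal(back$prevalence_acmg$n_total, rep$prevalence_acmg$n_total)
  expect_equal(table(back$classifications$verdict),
               table(rep$classifications$verdict))
})

test_that("chromosome normalization is idempotent and chr6 == 6", {
  labs <- c("chr6", "6", "chrX", "X", "chr22")
  expect_equal(normalizeChrom(labs), c("6", "6", "X", "X", "22"))
  expect_equal(normalizeChrom(normalizeChrom(labs)), normalizeChrom(labs))
})
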