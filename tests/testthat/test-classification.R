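# The ACMG evidence-combination engine, the automatic evidence assigner
# and the filter-based proxy classifier.

test_that("combiner reproduces canonical rule-table lookups", {
  expect_equal(verdict(combineAcmg(c("PVS1", "PM2"))), "likely_pathogenic")
  expect_equal(verdict(combineAcmg(c("PVS1", "PS1", "PM2"))), "pathogenic")
  expect_equal(verdict(combineAcmg(c("BA1"))), "benign")
  expect_equal(verdict(combineAcmg(character())), "uncertain_significance")
  expect_equal(verdict(combineAcmg(c("BS1", "BP4"))), "likely_benign")
  # conflicting arms resolve to uncertain significance
  expect_equal(verdict(combineAcmg(c("PVS1", "PM2", "BA1"))),
               "uncertain_significance")
  # unknown tokens are rejected
  expect_error(combineAcmg(c("PX9")), "unknown")
})

test_that("combiner equals the exhaustive oracle for all sets of size <= 3", {
  universe <- c("PVS1", "PS1", "PS2", "PM2", "PM4", "PP3", "PP5",
                "BA1", "BS1", "BS2", "BP4", "BP6")
  sets <- list(character())
  sets <- c(sets, as.list(universe))
  sets <- c(sets, combn(universe, 2, simplify = FALSE),
            combn(universe, 3, simplify = FALSE))
  for (cs in sets)
    expect_equal(verdict(combineAcmg(cs)), richardsOracle(cs),
                 info = paste(cs, collapse = "+"))
})

test_that("strength overrides change the effective combination", {
  # PVS1 downgraded to strong for possible NMD escape
  prof <- EvidenceProfile(c("PVS1", "PM2", "PP3"),
                          c(PVS1 = "strong"))
  expect_equal(verdict(combineAcmg(prof)), "likely_pathogenic")
  expect_equal(richardsOracle(c("PVS1", "PM2", "PP3"),
                              c(PVS1 = "strong")),
               "likely_pathogenic")
  # at full strength the same profile is pathogenic (VS + M + P)
  expect_equal(verdict(combineAcmg(c("PVS1", "PM2", "PP3"))), "pathogenic")
})

test_that("automatic evidence assignment maps annotation to codes", {
  p <- autoAssignEvidence(mkVariant(consequence = "stopgain",
                                    af_db1 = 1e-5, cadd = 39))
  expect_setequal(evidenceCodes(p), c("PVS1", "PM2", "PP3"))
  # PP3 bound is strict
  p <- autoAssignEvidence(mkVariant(cadd = 15.0, af_db1 = 0.5))
  expect_false("PP3" %in% evidenceCodes(p))
  expect_false("PM2" %in% evidenceCodes(p))
  # ClinVar mappings
  expect_true("PS1" %in% evidenceCodes(
    autoAssignEvidence(mkVariant(clinvar = "pathogenic"))))
  expect_true("PP5" %in% evidenceCodes(
    autoAssignEvidence(mkVariant(clinvar = "likely_pathogenic"))))
  expect_setequal(evidenceCodes(
    autoAssignEvidence(mkVariant(clinvar = "benign", af_db1 = 0.3))),
    "BP6")
  # PM2 boundary is strict and absent frequencies count as zero
  expect_true("PM2" %in% evidenceCodes(autoAssignEvidence(mkVariant())))
  expect_false("PM2" %in% evidenceCodes(
    autoAssignEvidence(mkVariant(af_db2 = 1e-4))))
  # non-canonical splice-region variants are not loss-of-function
  expect_true("PVS1" %in% evidenceCodes(autoAssignEvidence(
    mkVariant(consequence = "splicing"))))
  expect_false("PVS1" %in% evidenceCodes(autoAssignEvidence(
    mkVariant(consequence = "splicing", splice_canonical = FALSE))))
})

test_that("proxy classification implements the three-criterion filter", {
  # rare truncating variant with high CADD and a ClinVar assertion
  expect_equal(verdict(proxyClassify(
    mkVariant(consequence = "stopgain", cadd = 39,
              clinvar = "pathogenic"))), "likely_pathogenic")
  # fails computational support
  expect_equal(verdict(proxyClassify(
    mkVariant(af_db1 = 1e-5, cadd = 12))), "uncertain_significance")
  # ClinVar benign bucket
  expect_equal(verdict(proxyClassify(mkVariant(clinvar = "benign"))),
               "likely_benign")
  # indel without CADD qualifies only when loss-of-function
  expect_equal(verdict(proxyClassify(
    mkVariant(consequence = "frameshift_indel", cadd = NA))),
    "likely_pathogenic")
  expect_equal(verdict(proxyClassify(
    mkVariant(consequence = "inframe_indel", cadd = NA,
              clinvar = "likely_pathogenic"))), "uncertain_significance")
  # not rare: fails criterion (i)
  expect_equal(verdict(proxyClassify(
    mkVariant(consequence = "stopgain", cadd = 39, af_db1 = 5e-4))),
    "uncertain_significance")
})

test_that("proxy is not more permissive than the ACMG engine, except for
           supporting-level ClinVar assertions", {
  # the one documented asymmetry: a rare non-LOF variant with CADD > 15
  # and a ClinVar likely-pathogenic assertion passes the proxy filter,
  # but its automatable profile {PM2, PP3, PP5} is only 1 moderate + 2
  # supporting -- below the combining matrix's likely-pathogenic bar
  set.seed(11)
  for (rep in 1:8) {
    vs <- randomVariants(40)
    df <- recordTable(vs)
    proxy <- classifyVariants(vs, engine = "proxy")
    for (i in which(proxy$verdict == "likely_pathogenic")) {
      row <- df[i, , drop = FALSE]
      full <- combineAcmg(autoAssignEvidence(row))
      pp5_only <- row$clinvar == "likely_pathogenic" &&
        !(row$consequence %in% c("stopgain", "stoploss",
                                 "frameshift_indel", "splicing"))
      expect_true(verdict(full) %in% c("pathogenic", "likely_pathogenic")
                  || pp5_only, info = paste("row", i))
    }
  }
  # and the exception class really is the only gap
  gap <- mkVariant(consequence = "nonsynonymous", cadd = 30,
                   clinvar = "likely_pathogenic")
  expect_equal(verdict(proxyClassify(gap)), "likely_pathogenic")
  expect_equal(verdict(combineAcmg(autoAssignEvidence(gap))),
               "uncertain_significance")
})

test_that("proxy and engine carrier sets differ only by variants lacking
           both LOF status and a ClinVar assertion", {
  fx <- affExampleCohort()
  rep <- runCasePipeline(pipelineConfig(manifest = fx$cohort,
                                        variants = fx$variants))
  acmg <- rep$classifications
  proxy <- rep$proxy_classifications
  plp <- c("pathogenic", "likely_pathogenic")
  onlyAcmg <- setdiff(acmg$variant_key[acmg$verdict %in% plp],
                      proxy$variant_key[proxy$verdict %in% plp])
  expect_true(length(onlyAcmg) > 0)
  df <- recordTable(fx$variants)
  for (k in onlyAcmg) {
    row <- df[match(k, acmg$variant_key), ]
    lof <- row$consequence %in% c("stopgain", "stoploss",
                                  "frameshift_indel", "splicing")
    known <- row$clinvar %in% c("pathogenic", "likely_pathogenic")
    # the in-frame deletion without CADD: clinically classifiable, but
    # invisible to the proxy's computational-support criterion
    expect_false(lof && known)
  }
  expect_true(length(setdiff(proxy$variant_key[proxy$verdict %in% plp],
                             acmg$variant_key[acmg$verdict %in% plp]))
              == 0)
})

test_that("VUS report applies the CADD >= 20 or no-score-indel rule", {
  cl <- data.frame(
    patient_id = paste0("P", 1:5),
    verdict = c("uncertain_significance", "uncertain_significance",
                "uncertain_significance", "uncertain_significance",
                "likely_pathogenic"),
    cadd = c(20, 19.9, NA, NA, 45),
    consequence = c("nonsynonymous", "nonsynonymous", "inframe_indel",
                    "nonsynonymous", "stopgain"),
    stringsAsFactors = FALSE)
  out <- vusCaddReport(cl)
  expect_setequal(out$patient_id, c("P1", "P3"))
})
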