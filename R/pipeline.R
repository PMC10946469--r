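## Orchestration: chains filtering -> classification -> prevalence and the
## CNV and enrichment stages over a single validated configuration. All
## thresholds live in the configuration with the analysis defaults, so
## sensitivity analyses (e.g. CADD 15 vs 20) are flag changes. Every
## report embeds the full effective configuration and seed.

#' Build a pipeline configuration
#'
#' Inputs may be given as file paths (read with the package readers) or as
#' already-constructed objects; `NULL` panel means the bundled default.
#'
#' @param panel A [GenePanel-class] or panel TSV path (`NULL` = bundled
#'   default panel).
#' @param manifest A [CohortManifest-class] or manifest TSV path.
#' @param variants A [VariantSet-class] or variant-table path.
#' @param cnv Optional [CnvCallSet-class] or CNV TSV path.
#' @param variant_dialect `"tsv"` or `"vcf"` for a `variants` path.
#' @param qd_threshold QD removal bound (`<=`, default 5).
#' @param pm2_max_af PM2 / proxy rarity bound (default 1e-4).
#' @param pp3_cadd PP3 / proxy CADD bound, strict (default 15).
#' @param vus_cadd_min VUS report CADD bound, inclusive (default 20).
#' @param cnv_min_snps CNV supporting-SNP bound (default 10).
#' @param enrichment_alternative `"greater"` or `"two_sided"`.
#' @param dedup_families Deduplicate carrier relatives (default `TRUE`
#'   for the control-comparable proxy estimate).
#' @param background_rate Background carrier fraction for enrichment
#'   (default 0.01).
#' @param seed Integer seed recorded in every report.
#' @return A validated list of class `pipeline_config`.
#' @export
pipelineConfig <- function(panel = NULL, manifest = NULL, variants = NULL,
                           cnv = NULL, variant_dialect = "tsv",
                           qd_threshold = 5, pm2_max_af = 1e-4,
                           pp3_cadd = 15, vus_cadd_min = 20,
                           cnv_min_snps = 10,
                           enrichment_alternative = "greater",
                           dedup_families = TRUE,
                           background_rate = 0.01, seed = 1L) {
  if (qd_threshold < 0) stop("qd_threshold must be non-negative")
  for (nm in c("pm2_max_af", "background_rate")) {
    v <- get(nm)
    if (v <= 0 || v >= 1) stop(nm, " must lie strictly in (0, 1)")
  }
  if (cnv_min_snps < 1) stop("cnv_min_snps must be >= 1")
  if (!enrichment_alternative %in% c("greater", "two_sided"))
    stop("enrichment_alternative must be 'greater' or 'two_sided'")
  cfg <- list(panel = panel, manifest = manifest, variants = variants,
              cnv = cnv, variant_dialect = variant_dialect,
              qd_threshold = qd_threshold, pm2_max_af = pm2_max_af,
              pp3_cadd = pp3_cadd, vus_cadd_min = vus_cadd_min,
              cnv_min_snps = cnv_min_snps,
              enrichment_alternative = enrichment_alternative,
              dedup_families = dedup_families,
              background_rate = background_rate, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

.effectiveConfig <- function(config) {
  cfg <- unclass(config)
  cfg$panel <- if (is.character(cfg$panel)) cfg$panel else
    if (is.null(cfg$panel)) "bundled_default" else "in_memory"
  for (nm in c("manifest", "variants", "cnv"))
    cfg[[nm]] <- if (is.character(cfg[[nm]])) cfg[[nm]]
                 else if (is.null(cfg[[nm]])) NULL else "in_memory"
  cfg
}

.resolvePanel <- function(x) {
  if (is(x, "GenePanel")) x
  else if (is.null(x)) defaultGenePanel()
  else loadGenePanel(x)
}

.resolveManifest <- function(x) {
  if (is(x, "CohortManifest")) x else loadManifest(x)
}

.resolveVariants <- function(x, dialect = "tsv") {
  if (is(x, "VariantSet")) x else readVariantTable(x, dialect = dialect)
}

.resolveCnv <- function(x) {
  if (is(x, "CnvCallSet")) x else readCnvCalls(x)
}

#' Run the case pipeline: filtering, classification, prevalence
#'
#' Chains the variant-retention funnel, both classification layers (full
#' ACMG engine and filter-based proxy), genotype-pattern flagging,
#' carrier-prevalence estimation (ACMG verdicts, with and without family
#' deduplication; proxy verdicts with the configured deduplication), the
#' VUS/CADD report, and the manifest group comparison of long-term
#' glucocorticoid use.
#'
#' @param config A [pipelineConfig()] with `manifest` and `variants` set.
#' @return A report list with elements `config`, `trace`,
#'   `classifications` (ACMG), `proxy_classifications`,
#'   `genotype_patterns`, `patient_verdicts`, `prevalence_acmg`,
#'   `prevalence_acmg_dedup`, `prevalence_proxy`, `vus_report`,
#'   `enrichment` and `gc_comparison`.
#' @export
runCasePipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$manifest)) stop("config error: manifest is required")
  if (is.null(config$variants)) stop("config error: variants are required")
  panel <- .resolvePanel(config$panel)
  cohort <- .resolveManifest(config$manifest)
  vs <- .resolveVariants(config$variants, config$variant_dialect)
  funnel <- filterFunnel(vs, panel, qd_threshold = config$qd_threshold)
  retained <- funnel$variants
  acmg <- classifyVariants(retained, engine = "acmg",
                           pm2_max_af = config$pm2_max_af,
                           pp3_cadd = config$pp3_cadd)
  proxy <- classifyVariants(retained, engine = "proxy",
                            pm2_max_af = config$pm2_max_af,
                            pp3_cadd = config$pp3_cadd)
  patterns <- genotypePatterns(retained, panel)
  prevAcmg <- carrierPrevalence(cohort, acmg, dedup_families = FALSE)
  prevAcmgDedup <- carrierPrevalence(cohort, acmg, dedup_families = TRUE)
  prevProxy <- carrierPrevalence(cohort, proxy,
                                 dedup_families = config$dedup_families)
  pc <- carrierCounts(prevProxy)
  enr <- binomialEnrichment(pc$n_carriers, pc$n_total,
                            config$background_rate,
                            alternative = config$enrichment_alternative)
  man <- recordTable(cohort)
  gc_tab <- rbind(c(sum(man$gc_long_term & man$suspected),
                    sum(!man$gc_long_term & man$suspected)),
                  c(sum(man$gc_long_term & !man$suspected),
                    sum(!man$gc_long_term & !man$suspected)))
  gc_test <- compareCategorical(gc_tab)
  ## per-patient verdict: the most severe verdict among the patient's
  ## classified variants, "none" for patients without retained variants
  rank <- c(pathogenic = 1, likely_pathogenic = 2,
            uncertain_significance = 3, likely_benign = 4, benign = 5)
  pv <- vapply(man$patient_id, function(pid) {
    v <- acmg$verdict[acmg$patient_id == pid]
    if (!length(v)) "none" else names(sort(rank[unique(v)]))[1L]
  }, character(1))
  list(config = .effectiveConfig(config),
       trace = funnel$trace,
       classifications = acmg,
       proxy_classifications = proxy,
       genotype_patterns = patterns,
       patient_verdicts = data.frame(patient_id = man$patient_id,
                                     suspected = man$suspected,
                                     verdict = unname(pv),
                                     stringsAsFactors = FALSE),
       prevalence_acmg = carrierCounts(prevAcmg),
       prevalence_acmg_dedup = carrierCounts(prevAcmgDedup),
       prevalence_proxy = pc,
       vus_report = vusCaddReport(acmg, cadd_min = config$vus_cadd_min),
       enrichment = list(method = testMethod(enr), p_value = pValue(enr),
                         k = pc$n_carriers, n = pc$n_total,
                         p0 = config$background_rate),
       gc_comparison = list(method = testMethod(gc_test),
                            p_value = pValue(gc_test),
                            table = gc_tab))
}

#' Run the enrichment comparison alone
#'
#' @param config A [pipelineConfig()] (supplies sidedness, background
#'   rate and seed).
#' @param k Carrier count.
#' @param n Cohort size.
#' @param p0 Background fraction (default: the configured one).
#' @return Report list with the test result and the effective config.
#' @export
runEnrichment <- function(config = pipelineConfig(), k, n,
                          p0 = config$background_rate) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- binomialEnrichment(k, n, p0,
                            alternative = config$enrichment_alternative)
  list(config = .effectiveConfig(config),
       enrichment = list(method = testMethod(res), p_value = pValue(res),
                         k = k, n = n, p0 = p0,
                         alternative = config$enrichment_alternative))
}

#' Run the CNV stage
#'
#' Filters calls by supporting-SNP count, computes each retained call's
#' span and candidate-gene overlap, and scores supplied rubric evidence.
#'
#' @param config A [pipelineConfig()] with `cnv` set.
#' @param evidence Optional named numeric vector (or list keyed by
#'   `patient_id:chrom:start-end`) of rubric points per call; a plain
#'   named vector is applied to a single retained call.
#' @return Report list with per-call rows (`span_mb`, `overlap_genes`,
#'   `score`, `verdict`) and the effective config.
#' @export
runCnv <- function(config = pipelineConfig(), evidence = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$cnv)) stop("config error: cnv calls are required")
  panel <- .resolvePanel(config$panel)
  calls <- .resolveCnv(config$cnv)
  kept <- cnvFilter(calls, min_snps = config$cnv_min_snps)
  df <- recordTable(kept)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    call <- df[i, , drop = FALSE]
    genes <- overlapCandidateGenes(call, panel)
    res <- list(patient_id = call$patient_id, chrom = call$chrom,
                start = call$start, end = call$end,
                cnv_type = call$cnv_type, n_snps = call$n_snps,
                span_mb = cnvSpanMb(call),
                overlap_genes = genes)
    if (!is.null(evidence) && call$cnv_type == "loss") {
      ass <- clingenLossScore(evidence)
      res$score <- totalScore(ass)
      res$verdict <- verdict(ass)
    }
    res
  })
  list(config = .effectiveConfig(config),
       n_input_calls = nrow(recordTable(calls)),
       n_retained_calls = nrow(df),
       calls = rows)
}

#' Run the synthetic-data generator and write its files
#'
#' @param config A [simulationConfig()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`manifest.tsv`, `variants.tsv`).
#' @export
runSimulate <- function(config = simulationConfig(), dir = tempdir()) {
  sim <- generateCohort(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, "manifest.tsv")
  vp <- file.path(dir, "variants.tsv")
  writeManifest(sim$cohort, mp)
  writeVariantTable(sim$variants, vp)
  invisible(c(manifest = mp, variants = vp))
}
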