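## Synthetic-cohort generation: plants (likely) pathogenic carriers at
## group-specific rates and a Poisson background of VUS, with attributes
## drawn from a small grammar (consequence, frequency, CADD, ClinVar) --
## the analysis never inspects sequence context, so no nucleotide-level
## simulation is needed. Defaults mirror the worked 60-patient cohort: a
## 15/45 suspected/non-suspected split, carrier rates 8/15 and 1/45, one
## sibling pair, and a 1% background carrier rate in controls.

#' Build a simulation configuration
#'
#' @param n_patients Cohort size (default 60).
#' @param prop_suspected Fraction with clinical suspicion (default 0.25).
#' @param carrier_rate_suspected,carrier_rate_unsuspected Probability that
#'   a patient of each group carries a (likely) pathogenic panel variant
#'   (defaults 8/15 and 1/45).
#' @param background_vus_rate Mean number of uncertain-significance panel
#'   variants per patient (Poisson; default 0.8).
#' @param n_families_with_siblings Number of sibling pairs sharing family
#'   identifier and carrier status (default 1).
#' @param background_pathogenic_rate_controls Carrier fraction planted in
#'   synthetic control populations (default 0.01).
#' @param seed Integer seed; all generation is reproducible from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulationConfig <- function(n_patients = 60,
                             prop_suspected = 0.25,
                             carrier_rate_suspected = 8 / 15,
                             carrier_rate_unsuspected = 1 / 45,
                             background_vus_rate = 0.8,
                             n_families_with_siblings = 1,
                             background_pathogenic_rate_controls = 0.01,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              prop_suspected = prop_suspected,
              carrier_rate_suspected = carrier_rate_suspected,
              carrier_rate_unsuspected = carrier_rate_unsuspected,
              background_vus_rate = background_vus_rate,
              n_families_with_siblings = as.integer(n_families_with_siblings),
              background_pathogenic_rate_controls =
                background_pathogenic_rate_controls,
              seed = as.integer(seed))
  fr <- c("prop_suspected", "carrier_rate_suspected",
          "carrier_rate_unsuspected",
          "background_pathogenic_rate_controls")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0, 1]")
  if (cfg$n_patients < 1L)
    stop("n_patients must be positive")
  if (cfg$background_vus_rate < 0)
    stop("background_vus_rate must be non-negative")
  class(cfg) <- "simulation_config"
  cfg
}

.emptyVariantFrame <- function() {
  data.frame(patient_id = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             gene = character(), consequence = character(),
             zygosity = character(), qd = numeric(), af_db1 = numeric(),
             af_db2 = numeric(), cadd = numeric(), clinvar = character(),
             stringsAsFactors = FALSE)
}

## attribute grammar for one planted (likely) pathogenic variant: drawn to
## satisfy the proxy rule (rare + computational support + LOF/ClinVar)
.plantPathogenic <- function(patient_id, panel) {
  mc <- mcols(geneRanges(panel))
  i <- sample(length(mc$symbol), 1L)
  lof <- sample(c("stopgain", "frameshift_indel", "splicing"), 1L)
  data.frame(patient_id = patient_id,
             chrom = as.character(seqnames(geneRanges(panel)))[i],
             pos = start(geneRanges(panel))[i] + sample(1000L, 1L),
             ref = "C", alt = if (lof == "frameshift_indel") "CA" else "T",
             gene = mc$symbol[i], consequence = lof,
             zygosity = if (mc$is_x_linked[i]) "het" else
               sample(c("het", "hom"), 1L, prob = c(0.95, 0.05)),
             qd = round(stats::runif(1, 10, 60), 1),
             af_db1 = NA_real_, af_db2 = NA_real_,
             cadd = if (lof == "frameshift_indel") NA_real_ else
               round(stats::runif(1, 25, 45), 1),
             clinvar = sample(c("pathogenic", "likely_pathogenic",
                                "absent"), 1L),
             stringsAsFactors = FALSE)
}

## one background VUS: attributes drawn to fail the proxy rule (missense,
## no ClinVar assertion)
.plantVus <- function(patient_id, panel) {
  mc <- mcols(geneRanges(panel))
  i <- sample(length(mc$symbol), 1L)
  data.frame(patient_id = patient_id,
             chrom = as.character(seqnames(geneRanges(panel)))[i],
             pos = start(geneRanges(panel))[i] + sample(1000L, 1L),
             ref = "G", alt = "A",
             gene = mc$symbol[i], consequence = "nonsynonymous",
             zygosity = "het",
             qd = round(stats::runif(1, 10, 60), 1),
             af_db1 = signif(stats::runif(1, 0, 5e-4), 3),
             af_db2 = NA_real_,
             cadd = round(stats::runif(1, 10, 35), 1),
             clinvar = sample(c("uncertain", "absent"), 1L),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic AFF cohort
#'
#' Assigns suspicion flags by `prop_suspected`, plants one (likely)
#' pathogenic variant per carrier at the group-specific rates (attributes
#' satisfy the filter-based proxy rule), adds a Poisson background of VUS
#' per patient (attributes fail the proxy rule), and makes sibling pairs
#' share family identifier and carrier status. Byte-identical output for
#' identical configurations.
#'
#' @param config A [simulationConfig()].
#' @param panel A [GenePanel-class] (default: the bundled panel).
#' @return List with `cohort` ([CohortManifest-class]) and `variants`
#'   ([VariantSet-class]).
#' @export
generateCohort <- function(config = simulationConfig(),
                           panel = defaultGenePanel()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_patients
  out <- local({
    set.seed(config$seed)
    n_susp <- round(n * config$prop_suspected)
    suspected <- c(rep(TRUE, n_susp), rep(FALSE, n - n_susp))
    ids <- ifelse(suspected, paste0("SIM_S", seq_len(n)),
                  paste0("SIM_NS", seq_len(n)))
    family <- paste0("FAM", seq_len(n))
    ## sibling pairs: consecutive patients within the same group share a
    ## family; the second sibling mirrors the first's carrier status
    sib_first <- integer()
    if (config$n_families_with_siblings > 0L && n >= 2L) {
      cand <- which(suspected[-n] == suspected[-1L])
      cand <- cand[seq_len(min(length(cand),
                               config$n_families_with_siblings))]
      for (i in cand) family[i + 1L] <- family[i]
      sib_first <- cand
    }
    rate <- ifelse(suspected, config$carrier_rate_suspected,
                   config$carrier_rate_unsuspected)
    carrier <- stats::runif(n) < rate
    for (i in sib_first) carrier[i + 1L] <- carrier[i]
    man <- data.frame(
      patient_id = ids, suspected = suspected, family_id = family,
      sex = sample(c("female", "male"), n, replace = TRUE,
                   prob = c(0.73, 0.27)),
      bp_use = stats::runif(n) < 0.95, bp_years = NA_real_,
      gc_long_term = stats::runif(n) < ifelse(suspected, 4 / 15, 31 / 45),
      center = sample(c("EMC", "LUMC"), n, replace = TRUE,
                      prob = c(53, 7)),
      age_at_aff = round(stats::rnorm(n, 62.8, 12.7), 1),
      osteoporosis_flag = stats::runif(n) < 0.85,
      bilateral_flag = stats::runif(n) < 0.52,
      stringsAsFactors = FALSE)
    man$bp_years[man$bp_use] <- round(pmax(
      stats::rnorm(sum(man$bp_use), 8.6, 4.9), 0.5), 1)
    rows <- list()
    for (i in seq_len(n)) {
      if (carrier[i]) {
        pv <- .plantPathogenic(ids[i], panel)
        ## the second sibling carries the same variant as the first
        if ((i - 1L) %in% sib_first && carrier[i - 1L]) {
          pv <- rows[[paste0("p", i - 1L)]]
          pv$patient_id <- ids[i]
        }
        rows[[paste0("p", i)]] <- pv
      }
      nv <- stats::rpois(1L, config$background_vus_rate)
      for (k in seq_len(nv))
        rows[[paste0("v", i, "_", k)]] <- .plantVus(ids[i], panel)
    }
    df <- if (length(rows)) do.call(rbind, rows) else .emptyVariantFrame()
    list(cohort = CohortManifest(man), variants = VariantSet(df))
  })
  out
}

#' Generate a synthetic control-population variant table
#'
#' Emulates, at configurable desk scale, a reference-population exome set
#' in which a fraction `background_rate` of individuals carry one
#' proxy-qualifying (likely) pathogenic panel variant. Used to exercise
#' the enrichment comparison end-to-end.
#'
#' @param n Number of control individuals.
#' @param background_rate Carrier fraction to plant.
#' @param seed Integer seed.
#' @param panel A [GenePanel-class].
#' @return A [VariantSet-class] of the carriers' variants (non-carriers
#'   contribute no rows); the number of individuals is carried in the
#'   `n_individuals` attribute.
#' @export
generateControlPopulation <- function(n, background_rate, seed = 1L,
                                      panel = defaultGenePanel()) {
  if (background_rate < 0 || background_rate > 1)
    stop("background_rate must lie in [0, 1]")
  vs <- local({
    set.seed(seed)
    carrier <- which(stats::runif(n) < background_rate)
    rows <- lapply(carrier, function(i)
      .plantPathogenic(sprintf("CTRL%06d", i), panel))
    df <- if (length(rows)) do.call(rbind, rows) else .emptyVariantFrame()
    VariantSet(df)
  })
  attr(vs, "n_individuals") <- as.integer(n)
  vs
}
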