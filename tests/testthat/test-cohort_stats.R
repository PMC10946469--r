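# Carrier prevalence, binomial enrichment, and group comparisons.

test_that("carrier prevalence counts patients, not variants", {
  fx <- affExampleCohort()
  cl <- classifyVariants(fx$variants, engine = "acmg")
  prev <- carrierPrevalence(fx$cohort, cl)
  cc <- carrierCounts(prev)
  expect_equal(cc$n_carriers, 9L)
  expect_equal(cc$n_total, 60L)
  expect_equal(cc$prevalence, 9 / 60)
  byg <- cc$by_group
  expect_equal(byg$carriers[byg$group == "suspected"], 8L)
  expect_equal(byg$carriers[byg$group == "not_suspected"], 1L)

  # NS2 carries a P/LP variant and two VUS: counted once
  expect_gt(sum(cl$patient_id == "NS2"), 1L)
})

test_that("family deduplication keeps one carrier per family", {
  fx <- affExampleCohort()
  cl <- classifyVariants(fx$variants, engine = "acmg")
  prev <- carrierPrevalence(fx$cohort, cl, dedup_families = TRUE)
  cc <- carrierCounts(prev)
  expect_equal(cc$n_carriers, 8L)
  expect_equal(cc$n_total, 59L)
  expect_true(cc$dedup_applied)
})

test_that("prevalence rejects empty cohorts and unknown patients", {
  fx <- affExampleCohort()
  cl <- classifyVariants(fx$variants)
  empty <- CohortManifest(recordTable(fx$cohort)[0, ])
  expect_error(carrierPrevalence(empty, cl), "empty")
  cl$patient_id[1] <- "GHOST"
  expect_error(carrierPrevalence(fx$cohort, cl), "GHOST")
})

test_that("prevalence is invariant under row permutations", {
  fx <- affExampleCohort()
  cl <- classifyVariants(fx$variants)
  set.seed(3)
  man <- recordTable(fx$cohort)
  a <- carrierCounts(carrierPrevalence(fx$cohort, cl))
  b <- carrierCounts(carrierPrevalence(
    CohortManifest(man[sample(nrow(man)), ]),
    cl[sample(nrow(cl)), ]))
  expect_equal(a$n_carriers, b$n_carriers)
  expect_equal(a$by_group$carriers, b$by_group$carriers)
})

test_that("binomial enrichment equals direct tail summation", {
  # closed-form enumeration oracle
  tailSum <- function(k, n, p0)
    sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
  expect_equal(pValue(binomialEnrichment(2, 10, 0.2)),
               tailSum(2, 10, 0.2), tolerance = 1e-12)
  expect_equal(pValue(binomialEnrichment(0, 59, 0.01)), 1.0)
  expect_lt(pValue(binomialEnrichment(7, 59, 0.01)), 1e-4)
  for (k in c(1, 3, 5, 9)) {
    expect_equal(pValue(binomialEnrichment(k, 12, 0.3)),
                 tailSum(k, 12, 0.3), tolerance = 1e-12)
    # the upper-tail p grows as the observed count shrinks
    expect_lte(pValue(binomialEnrichment(k, 12, 0.3)),
               pValue(binomialEnrichment(k - 1, 12, 0.3)))
  }
  # two-sided minlike: sum of outcome probabilities <= P(X = k)
  minlike <- function(k, n, p0) {
    pr <- dbinom(0:n, n, p0)
    sum(pr[pr <= pr[k + 1] * (1 + 1e-7)])
  }
  expect_equal(pValue(binomialEnrichment(8, 20, 0.2,
                                         alternative = "two_sided")),
               minlike(8, 20, 0.2), tolerance = 1e-9)
  expect_error(binomialEnrichment(2, 10, 0), "p0")
  expect_error(binomialEnrichment(11, 10, 0.2), "k must")
})

test_that("categorical dispatch: Fisher when any observed cell < 5", {
  res <- compareCategorical(matrix(c(4, 31, 11, 14), nrow = 2))
  expect_equal(testMethod(res), "fisher_exact")
  res2 <- compareCategorical(matrix(c(10, 10, 10, 10), nrow = 2))
  expect_equal(testMethod(res2), "chi_square")
  expect_equal(pValue(res2), 1.0)
  expect_error(compareCategorical(matrix(c(0, 0, 3, 4), nrow = 2)),
               "margin")
})

test_that("Fisher p equals hypergeometric enumeration over fixed margins", {
  # exhaustive-enumeration oracle (minlike convention)
  fisherOracle <- function(tab) {
    a <- tab[1, 1]
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n2):min(k, m)
    pr <- dhyper(support, m, n2, k)
    pobs <- dhyper(a, m, n2, k)
    sum(pr[pr <= pobs * (1 + 1e-7)])
  }
  tables <- list(matrix(c(4, 31, 11, 14), 2),
                 matrix(c(1, 9, 11, 3), 2),
                 matrix(c(2, 7, 8, 2), 2),
                 matrix(c(3, 3, 4, 12), 2))
  for (tab in tables) {
    res <- compareCategorical(tab)
    expect_equal(testMethod(res), "fisher_exact")
    expect_equal(pValue(res), fisherOracle(tab), tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
  }
})

test_that("chi-square converges to Fisher as counts grow", {
  # the exact and asymptotic tests approach each other under count
  # scaling (the absolute difference decays roughly as n^-1/2), and on
  # strongly associated tables both are small together
  bases <- list(c(5, 7, 6, 8), c(6, 5, 9, 8), c(4, 9, 7, 5) * 2,
                c(10, 6, 5, 9))
  for (b in bases) {
    d <- vapply(c(4L, 40L), function(k) {
      tab <- matrix(b * k, nrow = 2)
      abs(pValue(compareCategorical(tab)) - fisher.test(tab)$p.value)
    }, numeric(1))
    expect_lt(d[2], d[1] + 1e-9)
  }
  strong <- matrix(c(40, 5, 8, 42), nrow = 2)
  expect_lt(pValue(compareCategorical(strong)), 1e-6)
  expect_lt(fisher.test(strong)$p.value, 1e-6)
})

test_that("two-group F test equals the squared t statistic", {
  set.seed(9)
  for (rep in 1:10) {
    a <- rnorm(6 + rep, mean = 60, sd = 12)
    b <- rnorm(9, mean = 64, sd = 10)
    res <- compareContinuous(a, b)
    expect_equal(testMethod(res), "f_test")
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(unname(res@statistic["F"]), unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(pValue(res), tt$p.value, tolerance = 1e-10)
  }
  # equal means with positive pooled variance: F = 0, p = 1
  res0 <- compareContinuous(c(1, 2, 3), c(3, 2, 1))
  expect_equal(unname(res0@statistic["F"]), 0)
  expect_equal(pValue(res0), 1)
  expect_error(compareContinuous(1, c(1, 2)), "at least two")
  expect_error(compareContinuous(c(1, 1), c(1, 1)), "variance")
})
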