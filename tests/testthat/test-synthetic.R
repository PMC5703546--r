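test_that("identical seeds give byte-identical output bundles", {
  d <- smallDesign(9, nGenes = 20L, nBackgroundSites = 40L,
                   chromLength = 600000,
                   tesGroupCounts = c(`500` = 5L, `1000` = 5L, none = 10L))
  o1 <- file.path(tempfile(), "a"); o2 <- file.path(tempfile(), "b")
  g1 <- generateSynthetic(d, outdir = o1)
  g2 <- generateSynthetic(d, outdir = o2)
  m1 <- unname(tools::md5sum(sort(unlist(g1$files))))
  m2 <- unname(tools::md5sum(sort(unlist(g2$files))))
  expect_identical(m1, m2)
  # a different seed changes the bundle
  g3 <- generateSynthetic(smallDesign(10, nGenes = 20L, nBackgroundSites = 40L,
                                      chromLength = 600000,
                                      tesGroupCounts = c(`500` = 5L,
                                                         `1000` = 5L,
                                                         none = 10L)),
                          outdir = file.path(tempfile(), "c"))
  expect_false(identical(m1, unname(tools::md5sum(sort(unlist(g3$files))))))
})

test_that("replicate concordance extremes behave as planted", {
  # full concordance, no noise: every planted stage site reaches consensus
  d1 <- smallDesign(4, replicateConcordance = 1, noiseLevel = 0)
  gs1 <- generateSynthetic(d1)
  for (st in gs1$bundle$stages) {
    planted <- sum(grepl(paste0("(^|&)", st, "(&|$)"),
                         gs1$truth$sites$pattern))
    cons <- replicateConsensus(gs1$bundle$peaks[[st]]$rep1,
                               gs1$bundle$peaks[[st]]$rep2, st)
    expect_identical(length(cons), planted)
  }
  # zero concordance: only the always-concordant flank sites survive
  d0 <- smallDesign(4, replicateConcordance = 0)
  gs0 <- generateSynthetic(d0)
  cons0 <- replicateConsensus(gs0$bundle$peaks$d0$rep1,
                              gs0$bundle$peaks$d0$rep2, "d0")
  expect_identical(length(cons0), sum(gs0$truth$sites$isFlank))
  # and with no flank-bump genes at all, the consensus is empty
  dEmpty <- smallDesign(4, replicateConcordance = 0,
                        tesGroupCounts = c(`500` = 0L, `1000` = 0L, none = 60L))
  gsE <- generateSynthetic(dEmpty)
  expect_length(replicateConsensus(gsE$bundle$peaks$d0$rep1,
                                   gsE$bundle$peaks$d0$rep2, "d0"), 0L)
})

test_that("truth tables are consistent with the design", {
  d <- smallDesign(12)
  gs <- generateSynthetic(d)
  expect_identical(as.integer(table(gs$truth$tes_groups)[c("TES_PLUS_500",
                                                           "TES_PLUS_1000",
                                                           "NONE")]),
                   unname(d$tesGroupCounts))
  expect_identical(nrow(gs$truth$sites),
                   d$nBackgroundSites + sum(d$tesGroupCounts[c("500", "1000")]))
  # planted background pattern allocation matches the design fractions
  bg <- gs$truth$sites[!gs$truth$sites$isFlank, ]
  alloc <- table(bg$pattern)
  expect_identical(sum(alloc), d$nBackgroundSites)
  fr <- d$patternFractions
  expect_true(all(abs(alloc[names(fr)] - d$nBackgroundSites * fr) <= 1))
  # expression classes are consistent with groups at the planted fidelity
  up <- names(gs$truth$expression_classes)[gs$truth$expression_classes == "UP"]
  expect_true(all(gs$truth$tes_groups[up] == "TES_PLUS_1000"))
})

test_that("infeasible designs fail before writing anything", {
  tooBig <- smallDesign(2, chromLength = 60000, nGenes = 3L,
                        nBackgroundSites = 4000L,
                        tesGroupCounts = c(`500` = 1L, `1000` = 1L, none = 1L))
  expect_error(generateSynthetic(tooBig), "infeasible")
})

test_that("shuffled truth labels drop recovery to chance level", {
  run <- cachedRun("default_run", syntheticDesign(seed = 23))
  truthShuffled <- run$gs$truth
  set.seed(1)
  truthShuffled$tes_groups[] <- sample(truthShuffled$tes_groups)
  v <- verifyTruth(run$report, truthShuffled)
  # chance level for a 50/50/100 cohort is ~ 0.375; genuine recovery is ~1
  expect_lt(v$tes_recovery, 0.6)
})
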