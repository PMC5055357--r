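mkTable <- function(nPairs, n = 20, m = 15, seed = 1) {
  set.seed(seed)
  cells <- sample(n * m, nPairs)
  interactionTable(
    data.frame(chemical = sprintf("c%d", (cells - 1) %% n + 1),
               protein = sprintf("p%d", (cells - 1) %/% n + 1),
               label = "active"),
    chemIds = sprintf("c%d", 1:n), protIds = sprintf("p%d", 1:m))
}

test_that("fold plans partition the positives into near-equal folds", {
  tab <- mkTable(20)
  folds <- makeFolds(tab, k = 10, seed = 3)
  expect_true(all(table(folds$fold) == 2))       # 20 pairs over 10 folds
  expect_identical(folds, makeFolds(tab, k = 10, seed = 3))
  tab2 <- mkTable(47, seed = 2)
  f2 <- makeFolds(tab2, k = 10, seed = 5)
  sizes <- table(f2$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  # union of folds covers every positive exactly once
  pp <- positivePairs(tab2)
  expect_setequal(paste(f2$i, f2$j), paste(pp$i, pp$j))
  expect_error(makeFolds(mkTable(5), k = 10), "at least 10")
})

test_that("top-percent cutoff floors with a minimum of one", {
  expect_equal(topPercentCutoff(3500, 0.01), 35L)
  expect_equal(topPercentCutoff(100, 0.001), 1L)
  expect_equal(topPercentCutoff(200, 0.10), 20L)
  expect_error(topPercentCutoff(0, 0.01), "candidateCount")
  expect_error(topPercentCutoff(100, 0), "fraction")
})

test_that("TPR at cutoff counts held-out ranks at or below the cutoff", {
  expect_equal(tprAtCutoff(c(1, 1, 1), 35), 1)
  expect_equal(tprAtCutoff(c(40, 50), 35), 0)
  expect_equal(tprAtCutoff(c(1, 2, 40), 35), 2 / 3)
  expect_true(is.na(tprAtCutoff(integer(0), 35)))
})

test_that("NT, L and Tc strata follow the bucket rules", {
  # chemical c1 has 2 total targets, one hidden -> 1 training -> NT2;
  # protein p1 has 3 training ligands -> L1to5
  tab <- interactionTable(
    data.frame(chemical = c("c1", "c2", "c3", "c4"),
               protein = c("p2", "p1", "p1", "p1"),
               label = "active"),
    chemIds = sprintf("c%d", 1:4), protIds = c("p1", "p2"))
  cat1 <- categorize(1, 2, tab, NULL)
  expect_equal(cat1$nt, "NT2")
  cat2 <- categorize(1, 1, tab, NULL)
  expect_equal(cat2$l, "L1to5")
  # max training similarity 0.85 lands in the (0.8, 0.9] bucket
  C <- similarityMatrix(sprintf("c%d", 1:4),
                        data.frame(a = c(1, 1), b = c(2, 3),
                                   score = c(0.85, 0.6)))
  expect_equal(categorize(1, 1, tab, C)$tc, "Tc0.8to0.9")
  # boundary: exactly 0.5 is included in the lowest bucket
  C2 <- similarityMatrix(sprintf("c%d", 1:4),
                         data.frame(a = 1, b = 2, score = 0.5))
  expect_equal(categorize(1, 1, tab, C2)$tc, "Tc0.5to0.6")
  # no retained similarity -> TcNone stratum
  expect_equal(categorize(1, 1, tab, similarityMatrix(sprintf("c%d", 1:4)))$tc,
               "TcNone")
  # NT1: chemical with its only association hidden; NT3: three or more
  tabN <- interactionTable(
    data.frame(chemical = c("c2", "c2", "c2"),
               protein = c("p1", "p2", "p3"), label = "active"),
    chemIds = c("c1", "c2"), protIds = sprintf("p%d", 1:3))
  expect_equal(categorize(1, 1, tabN, NULL)$nt, "NT1")
  tab3 <- interactionTable(
    data.frame(chemical = "c1", protein = sprintf("p%d", 1:3),
               label = "active"),
    chemIds = "c1", protIds = sprintf("p%d", 1:4))
  expect_equal(categorize(1, 4, tab3, NULL)$nt, "NT3")
})

test_that("ligand buckets increment by five with an open top bucket", {
  expect_equal(dualOCCF:::.lBucket(3L), "L1to5")
  expect_equal(dualOCCF:::.lBucket(5L), "L1to5")
  expect_equal(dualOCCF:::.lBucket(6L), "L6to10")
  expect_equal(dualOCCF:::.lBucket(15L), "L11to15")
  expect_equal(dualOCCF:::.lBucket(16L), "L16to20")
  expect_equal(dualOCCF:::.lBucket(30L), "L21more")
  expect_equal(dualOCCF:::.lBucket(0L), "L1to5")  # held-out orphan protein
})

test_that("benchmark with a perfect oracle reaches TPR 1 and is reproducible", {
  spec <- syntheticSpec(nChemicals = 30, mProteins = 24, kBlocks = 3,
                        density = 0.5, withinProb = 0.5, crossProb = 0.05,
                        seed = 8)
  dat <- generateSynthetic(spec)
  cfg <- occfConfig(rank = 6, nIter = 40, seed = 2, pChem = 0.75,
                    pProt = 0.1)
  folds <- makeFolds(dat$observed, k = 5, seed = 9)
  rep1 <- runBenchmark(dat$observed, dat$C, dat$T, cfg, folds,
                       topFraction = 0.25)
  rep2 <- runBenchmark(dat$observed, dat$C, dat$T, cfg, folds,
                       topFraction = 0.25)
  expect_identical(rep1@results, rep2@results)   # deterministic rerun
  s <- tprSummary(rep1, "overall")
  expect_gte(s$tpr, 0)
  expect_lte(s$tpr, 1)
  # TPR curves are non-decreasing in the cutoff in every category
  for (view in c("overall", "NTxL", "NTxTc")) {
    sm <- tprSummary(rep1, view, cutoffs = c(1, 3, 6, 12, 24))
    for (cc in unique(sm$category))
      expect_true(all(diff(sm$tpr[sm$category == cc]) >= 0))
  }
  # category populations partition the held-out pairs in both views
  d <- rep1@results
  expect_equal(sum(tprSummary(rep1, "NTxL")$n), nrow(d))
  expect_equal(sum(tprSummary(rep1, "NTxTc")$n), nrow(d))
  # paired t-test runs on two reports over the same folds
  tt <- tprTTest(rep1, rep2)
  expect_true(is.na(tt$p.value) || tt$p.value >= 0)
})

test_that("random scores achieve TPR near the cutoff/candidate null", {
  # rank of a held-out pair under random scoring is uniform on
  # 1..candidates; with 1000 candidates and cutoff 10 the null is 0.01
  set.seed(123)
  nPairs <- 4000
  ranks <- sample.int(1000, nPairs, replace = TRUE)
  tpr <- tprAtCutoff(ranks, 10)
  se <- sqrt(0.01 * 0.99 / nPairs)
  expect_lt(abs(tpr - 0.01), 3 * se)
})

test_that("held-out ranking excludes training positives from candidates", {
  # chemical with 2 training positives: candidate panel shrinks by 2
  U <- matrix(1, 1, 1)
  V <- matrix(runif(10), 10, 1)
  fm <- new("FactorModel", U = U, V = V, objectiveTrace = numeric(0),
            chemIds = character(0), protIds = character(0))
  r <- scoreRank(fm, 1, 5L, exclude = c(1L, 2L))
  expect_equal(r$nCandidates, 8L)
})
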