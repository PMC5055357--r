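test_that("objective matches hand-computed values on tiny cases", {
  # no observed pairs, zero factors: every entry contributes pWt * pImp^2
  tab0 <- interactionTable(data.frame(chemical = character(0),
                                      protein = character(0),
                                      label = character(0)),
                           chemIds = c("c1", "c2"), protIds = c("p1", "p2"))
  cfg <- occfConfig(pWt = 0.1, pImp = 0.1, pReg = 0, pChem = 0, pProt = 0,
                    rank = 1, nIter = 0)
  zero <- new("FactorModel", U = matrix(0, 2, 1), V = matrix(0, 2, 1),
              objectiveTrace = numeric(0), chemIds = character(0),
              protIds = character(0))
  expect_equal(objectiveValue(tab0, zero, cfg = cfg), 4 * 0.1 * 0.1^2)
  # one observed pair, unit rank-1 factors at that pair
  tab1 <- interactionTable(data.frame(chemical = "c1", protein = "p1",
                                      label = "active"),
                           chemIds = c("c1", "c2"), protIds = c("p1", "p2"))
  cfg1 <- occfConfig(pWt = 0.1, pImp = 0.1, pReg = 0.1, pChem = 0,
                     pProt = 0, rank = 1, nIter = 0)
  m1 <- new("FactorModel", U = matrix(c(1, 0), 2, 1),
            V = matrix(c(1, 0), 2, 1), objectiveTrace = numeric(0),
            chemIds = character(0), protIds = character(0))
  # (1,1) fits exactly; the three unobserved entries give 3*0.1*0.01;
  # Frobenius penalty 0.1 * (1 + 1)
  expect_equal(objectiveValue(tab1, m1, cfg = cfg1), 0.003 + 0.2)
})

test_that("chemical Laplacian term vanishes when all profile rows agree", {
  ids <- sprintf("c%d", 1:4)
  full <- t(combn(4, 2))
  C <- similarityMatrix(ids, data.frame(a = full[, 1], b = full[, 2],
                                        score = 1))
  tab <- interactionTable(data.frame(chemical = "c1", protein = "p1",
                                     label = "active"),
                          chemIds = ids, protIds = c("p1", "p2"))
  U <- matrix(rep(c(0.3, 0.7), each = 4), 4, 2)
  V <- matrix(runif(4), 2, 2)
  model <- new("FactorModel", U = U, V = V, objectiveTrace = numeric(0),
               chemIds = character(0), protIds = character(0))
  cfg0 <- occfConfig(pChem = 0, pProt = 0, rank = 2)
  cfgC <- occfConfig(pChem = 5, pProt = 0, rank = 2)
  expect_equal(objectiveValue(tab, model, C, NULL, cfgC),
               objectiveValue(tab, model, C, NULL, cfg0))
})

test_that("objective and update agree with the naive dense oracle", {
  for (seed in 1:25) {
    inst <- randomInstance(seed, withOverrides = seed %% 2 == 0)
    expect_equal(
      objectiveValue(inst$tab, inst$model, inst$C, inst$Tm, inst$cfg),
      naiveObjective(inst$tab, inst$model, inst$C, inst$Tm, inst$cfg),
      tolerance = 1e-10)
    stepped <- updateStep(inst$model, inst$tab, inst$C, inst$Tm, inst$cfg)
    oracle <- naiveUpdate(inst$tab, inst$model, inst$C, inst$Tm, inst$cfg)
    expect_equal(factorU(stepped), oracle$U, tolerance = 1e-10)
    expect_equal(factorV(stepped), oracle$V, tolerance = 1e-10)
    expect_gte(min(factorU(stepped)), 0)
    expect_gte(min(factorV(stepped)), 0)
  }
})

test_that("initialization is seeded, strictly positive and scale-bounded", {
  cfg <- occfConfig(rank = 4, seed = 42)
  m1 <- initializeFactors(10, 6, cfg)
  m2 <- initializeFactors(10, 6, cfg)
  expect_identical(factorU(m1), factorU(m2))
  expect_identical(factorV(m1), factorV(m2))
  expect_gt(min(factorU(m1)), 0)
  expect_lte(max(factorU(m1)), 1 / sqrt(4))
  m3 <- initializeFactors(10, 6, occfConfig(rank = 4, seed = 43))
  expect_false(identical(factorU(m1), factorU(m3)))
})

test_that("the objective trace never increases across random instances", {
  for (seed in 26:40) {
    inst <- randomInstance(seed, withOverrides = seed %% 3 == 0)
    cfg <- initialize(inst$cfg, nIter = 30L)
    fm <- suppressWarnings(fitOccf(inst$tab, inst$C, inst$Tm, cfg))
    tr <- objectiveTrace(fm)
    expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)),
                info = sprintf("seed %d", seed))
  }
})

test_that("a fully observed all-ones matrix is recovered at rank 1", {
  ids <- sprintf("c%d", 1:4)
  pids <- sprintf("p%d", 1:4)
  tab <- interactionTable(expand.grid(chemical = ids, protein = pids,
                                      label = "active",
                                      stringsAsFactors = FALSE),
                          chemIds = ids, protIds = pids)
  cfg <- occfConfig(pWt = 1, pImp = 0, pReg = 1e-6, pChem = 0, pProt = 0,
                    rank = 1, nIter = 400, seed = 7)
  fm <- fitOccf(tab, cfg = cfg)
  P <- factorU(fm) %*% t(factorV(fm))
  expect_lt(max(abs(P - 1)), 1e-3)
})

test_that("zero iterations return the initialization unchanged", {
  inst <- randomInstance(99)
  cfg <- initialize(inst$cfg, nIter = 0L)
  fm <- fitOccf(inst$tab, inst$C, inst$Tm, cfg)
  init <- initializeFactors(inst$n, inst$m, cfg)
  expect_identical(factorU(fm), factorU(init))
  expect_length(objectiveTrace(fm), 1L)
})

test_that("over-parameterized rank warns but fits", {
  inst <- randomInstance(7, n = 4, m = 3)
  cfg <- occfConfig(rank = 10, nIter = 3, seed = 1)
  expect_warning(fm <- fitOccf(inst$tab, inst$C, inst$Tm, cfg),
                 "over-parameterized")
  expect_equal(ncol(factorU(fm)), 10L)
})

test_that("raw scores are inner products with deterministic tie-breaks", {
  U <- matrix(c(2, 0), 2, 1)
  V <- matrix(c(1, 3, 2), 3, 1)
  fm <- new("FactorModel", U = U, V = V, objectiveTrace = numeric(0),
            chemIds = c("a", "b"), protIds = c("p1", "p2", "p3"))
  expect_equal(unname(predictScores(fm, 1)), c(2, 6, 4))
  expect_equal(unname(predictScores(fm, 2)), c(0, 0, 0))
  expect_error(predictScores(fm, 5), "out of range")
  top <- predictTopK(fm, 1, k = 2)
  expect_equal(top$protein, c(2L, 3L))
  expect_equal(top$rank, 1:2)
  # all-equal scores: ranks follow protein index
  tied <- predictTopK(fm, 2, k = 3)
  expect_equal(tied$protein, 1:3)
  # column permutation of both factors leaves scores unchanged
  perm <- predictScores(new("FactorModel", U = cbind(0, U), V = cbind(0, V),
                            objectiveTrace = numeric(0),
                            chemIds = character(0), protIds = character(0)),
                        1)
  expect_equal(perm, unname(predictScores(fm, 1)))
  # excluding everything leaves no candidates
  expect_equal(nrow(predictTopK(fm, 1, k = 5, exclude = 1:3)), 0L)
})

test_that("scoreRank agrees with predictTopK ordering", {
  set.seed(31)
  fm <- new("FactorModel", U = matrix(runif(8), 2, 4),
            V = matrix(runif(24), 6, 4), objectiveTrace = numeric(0),
            chemIds = character(0), protIds = character(0))
  full <- predictTopK(fm, 1, k = 6)
  for (k in 1:6) {
    r <- scoreRank(fm, 1, full$protein[k])
    expect_equal(r$rank, k)
    expect_equal(r$nCandidates, 6L)
  }
  ex <- scoreRank(fm, 1, full$protein[3], exclude = full$protein[1])
  expect_equal(ex$rank, 2L)
})

test_that("degenerate fixtures fit without similarity information", {
  for (fx in degenerateCases()) {
    cfg <- occfConfig(rank = 2, nIter = 20, seed = 3,
                      pChem = 0.75, pProt = 0.1)
    fm <- suppressWarnings(fitOccf(fx$observed, fx$C, fx$T, cfg))
    expect_gte(min(factorU(fm)), 0)
    tr <- objectiveTrace(fm)
    expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
  }
  # dense all-positive fixture: low-rank structure is exactly recoverable
  dense <- degenerateCases()$dense
  cfg <- occfConfig(pWt = 1, pImp = 0, pReg = 1e-6, pChem = 0, pProt = 0,
                    rank = 4, nIter = 400, seed = 5)
  fm <- fitOccf(dense$observed, cfg = cfg)
  P <- factorU(fm) %*% t(factorV(fm))
  expect_lt(max(abs(P - 1)), 1e-2)
})
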