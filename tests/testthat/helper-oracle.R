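# Independent naive oracles, deliberately written as explicit dense
# loops so they share no code path with the package's sparse
# decomposition.

# dense weight / target matrices of the one-class scheme
denseScheme <- function(tab, cfg) {
  n <- nChemicals(tab)
  m <- nProteins(tab)
  W <- matrix(cfg@pWt, n, m)
  Rt <- matrix(cfg@pImp, n, m)
  pp <- positivePairs(tab)
  for (k in seq_len(nrow(pp))) {
    W[pp$i[k], pp$j[k]] <- 1
    Rt[pp$i[k], pp$j[k]] <- 1
  }
  ov <- cfg@weightOverride
  if (!is.null(ov)) for (k in seq_len(nrow(ov)))
    W[ov$i[k], ov$j[k]] <- ov$value[k]
  ov <- cfg@targetOverride
  if (!is.null(ov)) for (k in seq_len(nrow(ov)))
    Rt[ov$i[k], ov$j[k]] <- ov$value[k]
  list(W = W, Rt = Rt)
}

denseLaplacianPenalty <- function(S, M) {
  A <- as.matrix(simMatrix(S))
  total <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A)))
    total <- total + 0.5 * A[i, j] * sum((M[i, ] - M[j, ])^2)
  total
}

naiveObjective <- function(tab, model, C, Tm, cfg) {
  s <- denseScheme(tab, cfg)
  U <- factorU(model)
  V <- factorV(model)
  P <- U %*% t(V)
  total <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
    total <- total + s$W[i, j] * (s$Rt[i, j] - P[i, j])^2
  total <- total + cfg@pReg * (sum(U^2) + sum(V^2))
  if (!is.null(C)) total <- total + cfg@pChem * denseLaplacianPenalty(C, U)
  if (!is.null(Tm)) total <- total + cfg@pProt * denseLaplacianPenalty(Tm, V)
  total
}

naiveUpdate <- function(tab, model, C, Tm, cfg) {
  s <- denseScheme(tab, cfg)
  U <- factorU(model)
  V <- factorV(model)
  eps <- cfg@epsilon
  n <- nrow(U)
  m <- nrow(V)
  Cd <- if (!is.null(C)) as.matrix(simMatrix(C)) else matrix(0, n, n)
  Td <- if (!is.null(Tm)) as.matrix(simMatrix(Tm)) else matrix(0, m, m)
  Dc <- diag(rowSums(Cd), n)
  Dt <- diag(rowSums(Td), m)
  numU <- (s$W * s$Rt) %*% V + cfg@pChem * Cd %*% U
  denU <- (s$W * (U %*% t(V))) %*% V + cfg@pReg * U + cfg@pChem * Dc %*% U
  U2 <- U * pmax(numU, 0) / pmax(denU, eps)
  numV <- t(s$W * s$Rt) %*% U2 + cfg@pProt * Td %*% V
  denV <- t(s$W * (U2 %*% t(V))) %*% U2 + cfg@pReg * V + cfg@pProt * Dt %*% V
  V2 <- V * pmax(numV, 0) / pmax(denV, eps)
  list(U = U2, V = V2)
}

# random small problem instance for oracle-equivalence checks
randomInstance <- function(seed, n = NULL, m = NULL, r = NULL,
                           withOverrides = FALSE, withSim = TRUE) {
  set.seed(seed)
  if (is.null(n)) n <- sample(2:10, 1)
  if (is.null(m)) m <- sample(2:8, 1)
  if (is.null(r)) r <- sample(1:3, 1)
  nPos <- sample(1:max(1, floor(n * m / 3)), 1)
  cells <- sample(n * m, nPos)
  pairs <- data.frame(
    chemical = sprintf("c%d", (cells - 1) %% n + 1),
    protein = sprintf("p%d", (cells - 1) %/% n + 1),
    label = "active")
  pairs <- pairs[!duplicated(pairs), ]
  tab <- interactionTable(pairs, chemIds = sprintf("c%d", 1:n),
                          protIds = sprintf("p%d", 1:m))
  rndSim <- function(ids) {
    k <- length(ids)
    if (k < 2) return(similarityMatrix(ids))
    combs <- t(combn(k, 2))
    keep <- runif(nrow(combs)) < 0.4
    similarityMatrix(ids, data.frame(a = combs[keep, 1],
                                     b = combs[keep, 2],
                                     score = runif(sum(keep))))
  }
  C <- if (withSim) rndSim(chemIds(tab)) else NULL
  Tm <- if (withSim) rndSim(protIds(tab)) else NULL
  wo <- to <- NULL
  if (withOverrides) {
    nov <- sample(1:4, 1)
    wo <- data.frame(i = sample(n, nov, replace = TRUE),
                     j = sample(m, nov, replace = TRUE),
                     value = runif(nov))
    wo <- wo[!duplicated(wo[, c("i", "j")]), ]
    to <- data.frame(i = sample(n, nov, replace = TRUE),
                     j = sample(m, nov, replace = TRUE),
                     value = runif(nov))
    to <- to[!duplicated(to[, c("i", "j")]), ]
  }
  cfg <- occfConfig(pWt = runif(1, 0.05, 0.9), pImp = runif(1, 0, 0.9),
                    pReg = runif(1, 0, 0.5), pChem = runif(1, 0, 1),
                    pProt = runif(1, 0, 1), rank = r, nIter = 5,
                    seed = seed, weightOverride = wo, targetOverride = to)
  model <- initializeFactors(n, m, cfg)
  list(tab = tab, C = C, Tm = Tm, cfg = cfg, model = model,
       n = n, m = m, r = r)
}

# minimal independent MCL: dense, no pruning, cluster extraction by
# connected components of the converged flow's nonzero structure
referenceMcl <- function(adj, inflation = 2, iters = 200) {
  n <- nrow(adj)
  M <- adj
  diag(M) <- 1
  norm <- function(M) sweep(M, 2, pmax(colSums(M), 1e-300), "/")
  M <- norm(M)
  for (k in seq_len(iters)) M <- norm((M %*% M)^inflation)
  link <- (M > 1e-6) | t(M > 1e-6)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(link[v, ] & comp == 0L))
    }
  }
  comp
}

# do two labelings describe the same partition?
samePartition <- function(a, b) {
  length(a) == length(b) &&
    identical(as.integer(match(a, unique(a))),
              as.integer(match(b, unique(b))))
}
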