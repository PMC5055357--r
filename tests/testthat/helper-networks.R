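# shared network fixtures for the clustering tests

cliqueNetwork <- function(bridgeWeight = 0.05) {
  # two 4-cliques (1-4, 5-8) joined by one weak bridge 4-5
  edges <- NULL
  for (g in list(1:4, 5:8)) {
    cmb <- t(combn(g, 2))
    edges <- rbind(edges, data.frame(a = cmb[, 1], b = cmb[, 2],
                                     cosine = 0.9))
  }
  if (bridgeWeight > 0)
    edges <- rbind(edges, data.frame(a = 4, b = 5, cosine = bridgeWeight))
  edges$tc <- 0
  edges$structuralNovel <- TRUE
  new("ProfileNetwork", nodes = sprintf("d%d", 1:8), edges = edges)
}

adjacencyOf <- function(net) {
  n <- length(net@nodes)
  A <- matrix(0, n, n)
  e <- net@edges
  A[cbind(e$a, e$b)] <- e$cosine
  A[cbind(e$b, e$a)] <- e$cosine
  A
}
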