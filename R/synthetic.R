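#' Specification of a synthetic block-model dataset
#'
#' Defaults define the package's standard desk-scale instance: 200
#' chemicals and 100 proteins in 4 latent blocks; true interactions
#' with probability 0.9 within a block and 0.02 across blocks
#' (the similar-chemicals-bind-similar-targets principle in its
#' strongest modular form); 5 percent of true pairs observed (a sparse
#' observed matrix of roughly one known target per chemical, matching
#' the sparsity regime of genome-wide association corpora); similarity
#' signal 0.8 with Gaussian jitter of sd 0.1; 20 percent of observed
#' positives held out.
#'
#' @param nChemicals,mProteins,kBlocks world dimensions.
#' @param density fraction of true pairs observed.
#' @param withinProb,crossProb within/cross block interaction
#'   probabilities.
#' @param similaritySignal similarity added for same-block pairs.
#' @param noiseSd similarity jitter standard deviation.
#' @param holdoutFraction fraction of observed positives held out.
#' @param seed integer seed.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nChemicals = 200L, mProteins = 100L,
                          kBlocks = 4L, density = 0.05,
                          withinProb = 0.9, crossProb = 0.02,
                          similaritySignal = 0.8, noiseSd = 0.1,
                          holdoutFraction = 0.2, seed = 1L) {
    new("SyntheticSpec", nChemicals = as.integer(nChemicals),
        mProteins = as.integer(mProteins), kBlocks = as.integer(kBlocks),
        density = density, withinProb = withinProb, crossProb = crossProb,
        similaritySignal = similaritySignal, noiseSd = noiseSd,
        holdoutFraction = holdoutFraction, seed = as.integer(seed))
}

# block-structured similarity: signal for same-block pairs plus
# independent Gaussian jitter, clipped to [0, 1], zero diagonal
.blockSimilarity <- function(block, signal, noiseSd, ids) {
    n <- length(block)
    i <- rep(seq_len(n), times = n)
    j <- rep(seq_len(n), each = n)
    up <- i < j
    i <- i[up]; j <- j[up]
    base <- ifelse(block[i] == block[j], signal, 0)
    val <- pmin(1, pmax(0, base + rnorm(length(i), 0, noiseSd)))
    .similarityFromTriplets(ids, i, j, val)
}

#' Generate a synthetic block-model dataset
#'
#' Chemicals and proteins are assigned to \code{kBlocks} latent blocks
#' (balanced, contiguous). True pairs are drawn independently with the
#' within/cross block probabilities; the observed positive table is a
#' Bernoulli sample of the true pairs at the given density; a fraction
#' of the observed positives is then held out for evaluation.
#' Similarity matrices for both sides reflect block co-membership with
#' independent jitter. Fully seeded and reproducible.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with elements \code{truth} (data.frame \code{i},
#'   \code{j}), \code{observed} (training
#'   \linkS4class{InteractionTable}), \code{heldout} (data.frame
#'   \code{chemical}, \code{protein}, \code{i}, \code{j}), \code{C},
#'   \code{T} (\linkS4class{SimilarityMatrix}), \code{chemBlock},
#'   \code{protBlock} (integer block labels) and \code{spec}.
#' @export
generateSynthetic <- function(spec = syntheticSpec()) {
    n <- spec@nChemicals
    m <- spec@mProteins
    k <- spec@kBlocks
    chemIds <- sprintf("chem%04d", seq_len(n))
    protIds <- sprintf("prot%04d", seq_len(m))
    .withSeed(spec@seed, {
        chemBlock <- sort(rep_len(seq_len(k), n))
        protBlock <- sort(rep_len(seq_len(k), m))
        same <- outer(chemBlock, protBlock, `==`)
        prob <- ifelse(same, spec@withinProb, spec@crossProb)
        true <- matrix(runif(n * m) < prob, n, m)
        ti <- which(true, arr.ind = TRUE)
        truth <- data.frame(i = ti[, 1], j = ti[, 2])
        truth <- truth[order(truth$i, truth$j), , drop = FALSE]
        rownames(truth) <- NULL
        obs <- runif(nrow(truth)) <= spec@density
        if (!any(obs))
            stop("spec yields zero observed positives; raise density")
        oi <- truth$i[obs]
        oj <- truth$j[obs]
        nHold <- floor(spec@holdoutFraction * length(oi))
        holdIdx <- if (nHold > 0) sample.int(length(oi), nHold) else integer(0)
        hi <- oi[holdIdx]; hj <- oj[holdIdx]
        keep <- setdiff(seq_along(oi), holdIdx)
        pairs <- data.frame(chemical = chemIds[oi[keep]],
                            protein = protIds[oj[keep]],
                            label = "active")
        observed <- interactionTable(pairs, chemIds = chemIds,
                                     protIds = protIds)
        C <- .blockSimilarity(chemBlock, spec@similaritySignal,
                              spec@noiseSd, chemIds)
        T <- .blockSimilarity(protBlock, spec@similaritySignal,
                              spec@noiseSd, protIds)
        list(truth = truth, observed = observed,
             heldout = data.frame(chemical = chemIds[hi],
                                  protein = protIds[hj], i = hi, j = hj),
             C = C, T = T, chemBlock = chemBlock, protBlock = protBlock,
             spec = spec)
    })
}

#' Edge-case synthetic fixtures
#'
#' A list of small degenerate datasets exercising the corners every
#' module must tolerate: a single-chemical world, a single-protein
#' world, a cold-start chemical with no observed pair, empty
#' similarity matrices (the fit reduces to plain weighted matrix
#' factorization), and a fully observed all-positive dense matrix.
#'
#' @return Named list of lists with elements \code{observed}, \code{C},
#'   \code{T} (similarities may be empty matrices).
#' @export
degenerateCases <- function() {
    mk <- function(pairs, chemIds, protIds) {
        tab <- interactionTable(pairs, chemIds = chemIds, protIds = protIds)
        list(observed = tab,
             C = similarityMatrix(chemIds),
             T = similarityMatrix(protIds))
    }
    singleChem <- mk(data.frame(chemical = "c1",
                                protein = c("p1", "p2"),
                                label = "active"),
                     "c1", c("p1", "p2", "p3"))
    singleProt <- mk(data.frame(chemical = c("c1", "c2"),
                                protein = "p1", label = "active"),
                     c("c1", "c2", "c3"), "p1")
    coldStart <- mk(data.frame(chemical = c("c1", "c2"),
                               protein = c("p1", "p2"), label = "active"),
                    c("c1", "c2", "c3"), c("p1", "p2", "p3"))
    dense <- mk(expand.grid(chemical = sprintf("c%d", 1:4),
                            protein = sprintf("p%d", 1:4),
                            label = "active",
                            stringsAsFactors = FALSE)[, c(1, 2, 3)],
                sprintf("c%d", 1:4), sprintf("p%d", 1:4))
    list(singleChemical = singleChem, singleProtein = singleProt,
         coldStart = coldStart, dense = dense)
}
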