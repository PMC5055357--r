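#' Cosine similarity between two latent drug profiles
#'
#' Standard cosine of two rows of the chemical factor matrix U; since
#' U is nonnegative the value lies in [0, 1].
#'
#' @param U nonnegative chemical factor matrix.
#' @param i,j row indices.
#' @return Cosine similarity, or NA when either row is all zero.
#' @export
cosineProfileSimilarity <- function(U, i, j) {
    ui <- U[i, ]; uj <- U[j, ]
    ni <- sqrt(sum(ui^2)); nj <- sqrt(sum(uj^2))
    if (ni == 0 || nj == 0) return(NA_real_)
    min(1, sum(ui * uj) / (ni * nj))
}

#' Build the latent-profile drug-drug network
#'
#' Computes all pairwise cosine similarities between rows of U and
#' keeps an edge when the similarity strictly exceeds the profile
#' threshold (default 0.3). Each edge carries the structural Tanimoto
#' similarity of the pair (0 when absent from C) and a flag
#' \code{structuralNovel} marking pairs whose structural similarity is
#' below the structural threshold (default 0.5) — drugs with similar
#' predicted target profiles but dissimilar structures, the candidates
#' of interest for repurposing.
#'
#' @param U nonnegative chemical factor matrix (drugs x rank).
#' @param C optional chemical \linkS4class{SimilarityMatrix} aligned
#'   with the rows of U.
#' @param ids optional drug identifiers (defaults to C's ids or
#'   row numbers).
#' @param cosThreshold profile-similarity threshold (edge kept iff
#'   cosine > threshold).
#' @param structThreshold structural-similarity threshold for the
#'   novelty flag.
#' @return A \linkS4class{ProfileNetwork}.
#' @export
buildRepurposingNetwork <- function(U, C = NULL, ids = NULL,
                                    cosThreshold = 0.3,
                                    structThreshold = 0.5) {
    if (cosThreshold < 0 || cosThreshold > 1 ||
        structThreshold < 0 || structThreshold > 1)
        stop("thresholds must be in [0, 1]")
    n <- nrow(U)
    if (is.null(ids))
        ids <- if (!is.null(C)) C@ids else as.character(seq_len(n))
    if (!is.null(C) && length(C@ids) != n)
        stop("C does not match the rows of U")
    nrm <- sqrt(rowSums(U^2))
    ok <- nrm > 0
    G <- U %*% t(U)
    cosm <- G / outer(pmax(nrm, .Machine$double.xmin),
                      pmax(nrm, .Machine$double.xmin))
    pairs <- which(upper.tri(cosm), arr.ind = TRUE)
    a <- pairs[, 1]; b <- pairs[, 2]
    cosv <- pmin(1, cosm[pairs])
    keep <- ok[a] & ok[b] & cosv > cosThreshold
    a <- a[keep]; b <- b[keep]; cosv <- cosv[keep]
    tc <- if (!is.null(C) && length(a))
        as.numeric(C@sim[cbind(a, b)]) else rep(0, length(a))
    edges <- data.frame(a = as.integer(a), b = as.integer(b),
                        cosine = cosv, tc = tc,
                        structuralNovel = tc < structThreshold)
    if (nrow(edges) == 0L)
        edges <- data.frame(a = integer(0), b = integer(0),
                            cosine = numeric(0), tc = numeric(0),
                            structuralNovel = logical(0))
    new("ProfileNetwork", nodes = as.character(ids), edges = edges)
}

#' Markov clustering of a profile network
#'
#' Standard MCL on the cosine-weighted adjacency matrix: self-loops of
#' weight 1 are added, columns are normalized to a stochastic flow
#' matrix, and expansion (matrix power) alternates with inflation
#' (entrywise power followed by renormalization) and pruning of small
#' entries until the flow matrix is stationary. Rows with nonzero
#' diagonal (attractors) define the clusters; a node reachable from
#' several attractor rows is assigned to the cluster of its
#' lowest-index attractor. Disconnected components are never merged.
#'
#' @param network a \linkS4class{ProfileNetwork}.
#' @param expansion integer matrix-power exponent (default 2).
#' @param inflation entrywise power (default 2).
#' @param pruneThreshold entries below this are zeroed each iteration.
#' @param maxIter iteration limit; if reached before convergence the
#'   clusters of the last iterate are returned with
#'   \code{converged = FALSE}.
#' @return A \linkS4class{ClusterSet}.
#' @export
mclCluster <- function(network, expansion = 2L, inflation = 2,
                       pruneThreshold = 1e-5, maxIter = 100L) {
    n <- length(network@nodes)
    if (n == 0L) stop("network has no nodes")
    M <- matrix(0, n, n)
    e <- network@edges
    if (nrow(e)) {
        M[cbind(e$a, e$b)] <- e$cosine
        M[cbind(e$b, e$a)] <- e$cosine
    }
    diag(M) <- 1  # self-loops
    normalize <- function(M) sweep(M, 2, pmax(colSums(M),
                                              .Machine$double.xmin), "/")
    M <- normalize(M)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        Mexp <- M
        for (k in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
        Minf <- normalize(Mexp^inflation)
        Minf[Minf < pruneThreshold] <- 0
        Minf <- normalize(Minf)
        if (max(abs(Minf - M)) < 1e-8) {
            M <- Minf
            converged <- TRUE
            break
        }
        M <- Minf
    }
    if (!converged)
        warning("MCL did not converge within maxIter; using last iterate")
    attractors <- which(diag(M) > pruneThreshold)
    owner <- integer(n)
    for (a in attractors) {
        members <- which(M[a, ] > pruneThreshold)
        free <- members[owner[members] == 0L]
        owner[free] <- a
    }
    owner[owner == 0L] <- which(owner == 0L)  # numerical orphans: singletons
    membership <- as.integer(match(owner, sort(unique(owner))))
    new("ClusterSet", nodes = network@nodes, membership = membership,
        converged = converged)
}

#' Fraction of drug pairs sharing a known target
#'
#' For a list of drug pairs, the fraction whose two drugs have at
#' least one common active target in the interaction table.
#'
#' @param pairs data.frame with columns \code{a} and \code{b}
#'   (chemical ids).
#' @param table an \linkS4class{InteractionTable}.
#' @return Fraction in [0, 1], or NA for an empty pair list.
#' @export
sharedTargetFraction <- function(pairs, table) {
    if (nrow(pairs) == 0L) return(NA_real_)
    pos <- positiveMatrix(table)
    ia <- match(pairs$a, table@chemIds)
    ib <- match(pairs$b, table@chemIds)
    if (anyNA(ia) || anyNA(ib)) stop("pair references an unknown chemical")
    shares <- vapply(seq_len(nrow(pairs)), function(k)
        any(pos[ia[k], ] & pos[ib[k], ]), logical(1))
    mean(shares)
}
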