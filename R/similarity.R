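# internal constructor from upper-triangle triplets (i < j)
.similarityFromTriplets <- function(ids, i, j, x) {
    n <- length(ids)
    keep <- x != 0
    i <- i[keep]; j <- j[keep]; x <- x[keep]
    s <- sparseMatrix(i = c(i, j), j = c(j, i), x = c(x, x), dims = c(n, n),
                      dimnames = list(ids, ids))
    new("SimilarityMatrix", ids = as.character(ids), sim = s)
}

#' Construct a SimilarityMatrix from pairwise scores
#'
#' @param ids character entity identifiers.
#' @param pairs data.frame with columns \code{a}, \code{b} (ids or
#'   1-based indices) and \code{score} in [0, 1]; each unordered pair
#'   at most once; self pairs are ignored (the diagonal is structural).
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
similarityMatrix <- function(ids, pairs = NULL) {
    if (is.null(pairs) || nrow(pairs) == 0L)
        return(.similarityFromTriplets(ids, integer(0), integer(0),
                                       numeric(0)))
    a <- pairs$a
    b <- pairs$b
    if (is.character(a)) a <- match(a, ids)
    if (is.character(b)) b <- match(b, ids)
    if (anyNA(a) || anyNA(b)) stop("pair references an unknown id")
    i <- pmin(a, b); j <- pmax(a, b)
    off <- i != j
    .similarityFromTriplets(ids, i[off], j[off], pairs$score[off])
}

#' Tanimoto similarity between two fingerprint bit sets
#'
#' \eqn{|a \cap b| / |a \cup b|}; two empty sets have similarity 0.
#' This is 1 minus the Tanimoto dissimilarity used for ECFP-style
#' fingerprints.
#'
#' @param a,b integer vectors of set-bit positions.
#' @return Similarity in [0, 1].
#' @examples
#' tanimotoSimilarity(c(1, 2, 3), c(2, 3, 4))  # 0.5
#' @export
tanimotoSimilarity <- function(a, b) {
    a <- unique(a); b <- unique(b)
    u <- length(union(a, b))
    if (u == 0L) return(0)
    length(intersect(a, b)) / u
}

#' Build the chemical-chemical similarity matrix from fingerprints
#'
#' Pairwise Tanimoto similarity over the fingerprint set; similarities
#' below the noise threshold (default 0.5) are treated as noise and set
#' to 0 (a value exactly at the threshold is retained).
#'
#' @param fps a \linkS4class{FingerprintSet}.
#' @param noiseThreshold minimum retained similarity, in [0, 1].
#' @return A \linkS4class{SimilarityMatrix} over the fingerprint ids.
#' @export
buildChemicalSimilarity <- function(fps, noiseThreshold = 0.5) {
    if (noiseThreshold < 0 || noiseThreshold > 1)
        stop("noiseThreshold must be in [0, 1]")
    n <- length(fps@ids)
    sizes <- lengths(fps@bits)
    ii <- rep(seq_len(n), times = lengths(fps@bits))
    B <- sparseMatrix(i = ii, j = unlist(fps@bits) + 1L, x = 1,
                      dims = c(n, max(1L, fps@nbits)))
    inter <- as(as(tcrossprod(B), "generalMatrix"),
                "TsparseMatrix")  # |a inter b|
    keep <- inter@i < inter@j
    i <- inter@i[keep] + 1L
    j <- inter@j[keep] + 1L
    uni <- sizes[i] + sizes[j] - inter@x[keep]
    tani <- ifelse(uni > 0, inter@x[keep] / uni, 0)
    ok <- tani >= noiseThreshold
    .similarityFromTriplets(fps@ids, i[ok], j[ok], tani[ok])
}

#' Build the protein-protein similarity matrix from BLAST bit scores
#'
#' The directed similarity of query p1 to subject p2 is the ratio of
#' the pair's bit score to the query's self-hit bit score,
#' \eqn{t(p_1, p_2) = d_{bit}(p_1, p_2) / d_{bit}(p_1, p_1)}, clipped
#' to [0, 1]. The symmetric similarity is the arithmetic mean of the
#' two directed ratios, with a missing direction contributing 0.
#'
#' @param hits data.frame of filtered hits (\code{query},
#'   \code{subject}, \code{bitscore}), e.g. from
#'   \code{\link{readBlastTabular}}; self hits supply the self scores
#'   when \code{selfScores} is NULL.
#' @param selfScores optional named numeric vector of self-hit bit
#'   scores; must cover every protein occurring as a query.
#' @param ids optional explicit protein vocabulary.
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
buildProteinSimilarity <- function(hits, selfScores = NULL, ids = NULL) {
    if (is.null(selfScores)) {
        self <- hits[hits$query == hits$subject, , drop = FALSE]
        selfScores <- setNames(self$bitscore, self$query)
    }
    if (is.null(ids))
        ids <- unique(c(hits$query, hits$subject, names(selfScores)))
    cross <- hits[hits$query != hits$subject, , drop = FALSE]
    missing <- setdiff(unique(cross$query), names(selfScores))
    if (length(missing))
        stop(sprintf("no self bit score for protein(s): %s",
                     paste(missing, collapse = ", ")))
    n <- length(ids)
    qi <- match(cross$query, ids)
    si <- match(cross$subject, ids)
    ratio <- pmin(1, pmax(0, cross$bitscore / selfScores[cross$query]))
    directed <- sparseMatrix(i = qi, j = si, x = ratio, dims = c(n, n))
    s <- (directed + Matrix::t(directed)) / 2
    Matrix::diag(s) <- 0
    s <- drop0(s)
    tr <- .spTriplets(s)
    up <- tr$i < tr$j
    .similarityFromTriplets(ids, tr$i[up], tr$j[up],
                            pmin(1, pmax(0, tr$x[up])))
}

#' Apply the noise threshold to a precomputed similarity matrix
#'
#' Entries strictly below the threshold are treated as noise and set
#' to 0 (the rule applied to chemical similarities during
#' construction, default 0.5); a value exactly at the threshold is
#' retained. Useful for precomputed or simulated matrices that were
#' not built through \code{\link{buildChemicalSimilarity}}.
#'
#' @param S a \linkS4class{SimilarityMatrix}.
#' @param threshold minimum retained similarity.
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
thresholdSimilarity <- function(S, threshold = 0.5) {
    tr <- .spTriplets(S@sim)
    up <- tr$i < tr$j & tr$x >= threshold
    .similarityFromTriplets(S@ids, tr$i[up], tr$j[up], tr$x[up])
}

#' Randomly subsample a similarity matrix
#'
#' Each unordered nonzero pair is independently retained with the given
#' probability (sampling pairs, not directed entries, preserves
#' symmetry). Used for similarity-ablation experiments in which half
#' of the similarity information is ignored.
#'
#' @param S a \linkS4class{SimilarityMatrix}.
#' @param keepFraction retention probability in [0, 1].
#' @param seed integer seed.
#' @return A \linkS4class{SimilarityMatrix}.
#' @export
subsampleSimilarity <- function(S, keepFraction, seed = 1L) {
    if (keepFraction < 0 || keepFraction > 1)
        stop("keepFraction must be in [0, 1]")
    tr <- .spTriplets(S@sim)
    up <- tr$i < tr$j
    i <- tr$i[up]; j <- tr$j[up]; x <- tr$x[up]
    keep <- .withSeed(seed, runif(length(i)) <= keepFraction)
    .similarityFromTriplets(S@ids, i[keep], j[keep], x[keep])
}

#' Graph-Laplacian quadratic form
#'
#' Computes \eqn{tr(M'(D - S)M) = \frac12 \sum_{ij} S_{ij}
#' \|M_{i\cdot} - M_{j\cdot}\|^2}, the smoothness penalty forcing
#' similar entities to have similar latent rows. Nonnegative for any
#' nonnegative similarity (the Laplacian is positive semidefinite).
#'
#' @param S a \linkS4class{SimilarityMatrix}.
#' @param M numeric matrix with one row per entity.
#' @return Scalar penalty value.
#' @export
laplacianQuadratic <- function(S, M) {
    M <- as.matrix(M)
    if (nrow(M) != length(S@ids))
        stop("row count of M must equal the number of entities")
    deg <- Matrix::rowSums(S@sim)
    cross <- sum(M * as.matrix(S@sim %*% M))
    sum(deg * rowSums(M^2)) - cross
}

#' Read / write similarity triplets
#'
#' TSV exchange format for precomputed similarity matrices: header
#' columns \code{id_a}, \code{id_b}, \code{score}, one row per
#' unordered pair.
#'
#' @param path file path.
#' @param ids optional explicit vocabulary for the reader.
#' @return \code{readSimilarity}: a \linkS4class{SimilarityMatrix};
#'   \code{writeSimilarity}: the path, invisibly.
#' @export
readSimilarity <- function(path, ids = NULL) {
    d <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(id_a = "character", id_b = "character"))
    if (!all(c("id_a", "id_b", "score") %in% names(d)))
        stop("similarity file needs id_a, id_b, score columns")
    if (is.null(ids)) ids <- unique(c(d$id_a, d$id_b))
    similarityMatrix(ids, data.frame(a = d$id_a, b = d$id_b,
                                     score = as.numeric(d$score)))
}

#' @rdname readSimilarity
#' @param S a \linkS4class{SimilarityMatrix} to write.
#' @export
writeSimilarity <- function(S, path) {
    tr <- .spTriplets(S@sim)
    up <- tr$i < tr$j
    d <- data.frame(id_a = S@ids[tr$i[up]], id_b = S@ids[tr$j[up]],
                    score = tr$x[up])
    d <- d[order(d$id_a, d$id_b), , drop = FALSE]
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
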