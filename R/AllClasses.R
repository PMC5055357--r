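#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal crossprod tcrossprod rowSums colSums t drop0 diag isSymmetric
#' @importFrom stats runif rnorm setNames t.test
#' @importFrom utils read.delim write.table head
NULL

# triplet view (1-based i, j, x) of any Matrix sparse matrix
.spTriplets <- function(m) {
    tm <- as(m, "TsparseMatrix")
    x <- if (is(tm, "nMatrix")) rep(1, length(tm@i)) else tm@x
    list(i = tm@i + 1L, j = tm@j + 1L, x = x)
}

.validIds <- function(ids, what) {
    if (!is.character(ids) || length(ids) < 1L)
        return(sprintf("%s ids must be a non-empty character vector", what))
    if (anyDuplicated(ids))
        return(sprintf("duplicate %s ids", what))
    if (any(is.na(ids)) || any(ids == ""))
        return(sprintf("missing/empty %s ids", what))
    TRUE
}

#' InteractionTable: labeled sparse chemical-protein associations
#'
#' Container for a bipartite chemical-protein association network. Each
#' aggregated (chemical, protein) pair carries an activity label:
#' \code{active} (e.g. IC50 at or below the activity threshold),
#' \code{inactive} (all records above the threshold) or \code{ambiguous}
#' (records on both sides). Pairs never assayed are simply absent
#' (unknown). The active pairs define the observed-positive indicator
#' matrix used by the one-class factorization.
#'
#' @slot chemIds character vector of chemical identifiers (rows).
#' @slot protIds character vector of protein identifiers (columns).
#' @slot pairs data.frame with columns \code{chemical}, \code{protein},
#'   \code{label} (one row per aggregated pair).
#' @slot positives sparse pattern matrix (\code{ngCMatrix}) of the
#'   active pairs, dimension \code{length(chemIds) x length(protIds)}.
#'
#' @aliases InteractionTable-class
#' @exportClass InteractionTable
setClass("InteractionTable",
    representation(chemIds = "character", protIds = "character",
                   pairs = "data.frame", positives = "Matrix"))

setValidity("InteractionTable", function(object) {
    v <- .validIds(object@chemIds, "chemical"); if (!isTRUE(v)) return(v)
    v <- .validIds(object@protIds, "protein"); if (!isTRUE(v)) return(v)
    p <- object@pairs
    need <- c("chemical", "protein", "label")
    if (!all(need %in% names(p)))
        return("pairs must have columns chemical, protein, label")
    if (nrow(p)) {
        if (!all(p$chemical %in% object@chemIds))
            return("pairs reference unknown chemical ids")
        if (!all(p$protein %in% object@protIds))
            return("pairs reference unknown protein ids")
        if (!all(p$label %in% c("active", "inactive", "ambiguous")))
            return("labels must be active/inactive/ambiguous")
        if (anyDuplicated(paste(p$chemical, p$protein, sep = "\r")))
            return("duplicate (chemical, protein) pair after aggregation")
    }
    if (!identical(dim(object@positives),
                   c(length(object@chemIds), length(object@protIds))))
        return("positives matrix dimension mismatch")
    act <- p[p$label == "active", , drop = FALSE]
    tr <- .spTriplets(object@positives)
    key1 <- sort(paste(match(act$chemical, object@chemIds),
                       match(act$protein, object@protIds)))
    key2 <- sort(paste(tr$i, tr$j))
    if (!identical(key1, key2))
        return("positives matrix does not match active-labeled pairs")
    TRUE
})

#' SimilarityMatrix: symmetric sparse entity-entity similarity
#'
#' Symmetric nonnegative similarity among a set of entities (chemicals
#' or proteins), stored sparsely with a structurally zero diagonal: the
#' diagonal cancels in the graph-Laplacian quadratic form
#' \eqn{tr(M'(D - S)M)}, so self-similarity is never stored and the
#' degree of an entity is the sum of its off-diagonal similarities.
#'
#' @slot ids character vector of entity identifiers.
#' @slot sim sparse symmetric numeric matrix (values in [0, 1], zero
#'   diagonal).
#'
#' @aliases SimilarityMatrix-class
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
    representation(ids = "character", sim = "Matrix"))

setValidity("SimilarityMatrix", function(object) {
    v <- .validIds(object@ids, "entity"); if (!isTRUE(v)) return(v)
    s <- object@sim
    n <- length(object@ids)
    if (!identical(dim(s), c(n, n))) return("similarity dimension mismatch")
    x <- s@x
    if (length(x) && (min(x) < 0 || max(x) > 1))
        return("similarity values must lie in [0, 1]")
    if (any(Matrix::diag(s) != 0)) return("diagonal must be stored as zero")
    if (!Matrix::isSymmetric(s, tol = 0)) return("similarity must be symmetric")
    TRUE
})

#' FingerprintSet: chemical fingerprints as bit sets
#'
#' Per-chemical circular-substructure (ECFP-style) fingerprints, stored
#' as sorted 0-based positions of set bits within a declared bit-vector
#' length.
#'
#' @slot ids character vector of chemical identifiers.
#' @slot nbits integer, declared fingerprint length in bits.
#' @slot bits list of integer vectors (0-based set-bit positions), one
#'   per chemical.
#'
#' @aliases FingerprintSet-class
#' @exportClass FingerprintSet
setClass("FingerprintSet",
    representation(ids = "character", nbits = "integer", bits = "list"))

setValidity("FingerprintSet", function(object) {
    v <- .validIds(object@ids, "chemical"); if (!isTRUE(v)) return(v)
    if (length(object@bits) != length(object@ids))
        return("one bit set required per chemical")
    if (object@nbits < 1L) return("nbits must be positive")
    ok <- vapply(object@bits, function(b)
        !anyNA(b) && !is.unsorted(b) && !anyDuplicated(b) &&
            (length(b) == 0L || (min(b) >= 0L && max(b) < object@nbits)),
        logical(1))
    if (!all(ok)) return("bit positions must be unique, sorted, in [0, nbits)")
    TRUE
})

#' OccfConfig: hyper-parameters of the one-class factorization
#'
#' Holds the weighted one-class matrix factorization settings. Defaults
#' are the benchmark setting of the method: unobserved-entry weight
#' \code{pWt = 0.1}, imputed target for unobserved entries
#' \code{pImp = 0.1}, Tikhonov coefficient \code{pReg = 0.1}, chemical
#' graph coefficient \code{pChem = 0.75}, protein graph coefficient
#' \code{pProt = 0.1}, rank \code{r = 300} and 400 multiplicative
#' update iterations. A jointly optimized alternative documented for
#' the same benchmark is \code{pChem = pProt = 0.25}.
#'
#' @slot pWt numeric in [0, 1], weight of unobserved entries.
#' @slot pImp numeric in [0, 1], imputed target for unobserved entries.
#' @slot pReg nonnegative Tikhonov regularization coefficient.
#' @slot pChem nonnegative chemical-graph regularization coefficient.
#' @slot pProt nonnegative protein-graph regularization coefficient.
#' @slot rank positive integer, factorization rank.
#' @slot nIter nonnegative integer, number of update iterations.
#' @slot seed integer seed for factor initialization.
#' @slot epsilon positive division guard for multiplicative updates.
#' @slot tol nonnegative early-stop tolerance on the relative objective
#'   decrease; 0 disables early stopping (the default, fixed budget).
#' @slot weightOverride,targetOverride optional data.frame overrides
#'   (\code{i}, \code{j}, \code{value}) replacing the global weight /
#'   target at selected entries.
#'
#' @aliases OccfConfig-class
#' @exportClass OccfConfig
setClass("OccfConfig",
    representation(pWt = "numeric", pImp = "numeric", pReg = "numeric",
                   pChem = "numeric", pProt = "numeric", rank = "integer",
                   nIter = "integer", seed = "integer", epsilon = "numeric",
                   tol = "numeric",
                   weightOverride = "ANY", targetOverride = "ANY"))

setValidity("OccfConfig", function(object) {
    in01 <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
    if (!in01(object@pWt)) return("pWt must be in [0, 1]")
    if (!in01(object@pImp)) return("pImp must be in [0, 1]")
    nn <- function(x) length(x) == 1L && is.finite(x) && x >= 0
    if (!nn(object@pReg)) return("pReg must be >= 0")
    if (!nn(object@pChem)) return("pChem must be >= 0")
    if (!nn(object@pProt)) return("pProt must be >= 0")
    if (object@rank < 1L) return("rank must be a positive integer")
    if (object@nIter < 0L) return("nIter must be >= 0")
    if (!(object@epsilon > 0)) return("epsilon must be > 0")
    if (!nn(object@tol)) return("tol must be >= 0")
    for (ov in list(object@weightOverride, object@targetOverride)) {
        if (is.null(ov)) next
        if (!is.data.frame(ov) || !all(c("i", "j", "value") %in% names(ov)))
            return("overrides must be data.frames with columns i, j, value")
        if (nrow(ov) && (min(ov$value) < 0 || max(ov$value) > 1))
            return("override values must be in [0, 1]")
    }
    TRUE
})

#' FactorModel: nonnegative low-rank factor pair
#'
#' The fitted factor matrices of the one-class factorization. Row
#' \code{i} of \code{U} is the latent profile of chemical \code{i} (the
#' low-rank drug profile); row \code{j} of \code{V} is the latent
#' profile of protein \code{j}. The raw predicted interaction score is
#' the inner product \code{U[i, ] \%*\% V[j, ]}.
#'
#' @slot U nonnegative numeric matrix, chemicals x rank.
#' @slot V nonnegative numeric matrix, proteins x rank.
#' @slot objectiveTrace numeric vector of objective values (element 1
#'   at initialization, then one per iteration).
#' @slot chemIds,protIds identifiers carried over from the training
#'   interaction table (may be empty for anonymous fits).
#'
#' @aliases FactorModel-class
#' @exportClass FactorModel
setClass("FactorModel",
    representation(U = "matrix", V = "matrix", objectiveTrace = "numeric",
                   chemIds = "character", protIds = "character"))

setValidity("FactorModel", function(object) {
    if (ncol(object@U) != ncol(object@V))
        return("U and V must share the rank dimension")
    if (length(object@U) && min(object@U) < 0) return("U must be nonnegative")
    if (length(object@V) && min(object@V) < 0) return("V must be nonnegative")
    if (length(object@chemIds) && length(object@chemIds) != nrow(object@U))
        return("chemIds length must match nrow(U)")
    if (length(object@protIds) && length(object@protIds) != nrow(object@V))
        return("protIds length must match nrow(V)")
    TRUE
})

#' ScoreHistogram: binned raw-score distributions by activity class
#'
#' Raw prediction scores of labeled (active / inactive / ambiguous)
#' pairs binned into half-open intervals \code{[lo, lo + width)} of
#' width 0.05 by default. Scores above the outlier limit (1.10 by
#' default) are excluded and counted separately.
#'
#' @slot binWidth numeric bin width in score units.
#' @slot upperLimit numeric; scores strictly above are outliers.
#' @slot breaks numeric vector of left bin edges.
#' @slot counts integer matrix, bins x classes
#'   (\code{active}, \code{inactive}, \code{ambiguous}).
#' @slot fractions numeric matrix of per-class normalized counts
#'   (columns sum to 1; all-NA column when a class has no scores).
#' @slot nOutliers integer, number of excluded scores.
#'
#' @aliases ScoreHistogram-class
#' @exportClass ScoreHistogram
setClass("ScoreHistogram",
    representation(binWidth = "numeric", upperLimit = "numeric",
                   breaks = "numeric", counts = "matrix",
                   fractions = "matrix", nOutliers = "integer"))

setValidity("ScoreHistogram", function(object) {
    if (!(object@binWidth > 0)) return("binWidth must be > 0")
    if (any(object@counts < 0)) return("counts must be nonnegative")
    if (!identical(colnames(object@counts),
                   c("active", "inactive", "ambiguous")))
        return("count columns must be active, inactive, ambiguous")
    for (cl in colnames(object@fractions)) {
        f <- object@fractions[, cl]
        if (all(is.na(f))) next
        if (abs(sum(f) - 1) > 1e-8)
            return(sprintf("fractions of class %s must sum to 1", cl))
    }
    TRUE
})

#' ScoreCalibration: fitted per-bin score adjustment
#'
#' The fitted mixture weight \code{w1} (fraction of true observations
#' that are active, estimated by matching the ambiguous-score histogram
#' to a convex combination of the active and inactive histograms), the
#' implied inactive/active inflation ratio \code{w2/w1}, and the
#' adjusted per-bin score \eqn{B_i = pos_i / (pos_i +
#' floor(ratio \cdot neg_i))} with empty bins filled by linear
#' interpolation between the nearest informative neighbours.
#'
#' @slot w1 numeric in [0, 1], active mixture weight.
#' @slot inflationRatio numeric, \code{(1 - w1) / w1}.
#' @slot binWidth,upperLimit binning parameters (see
#'   \linkS4class{ScoreHistogram}).
#' @slot breaks numeric left bin edges.
#' @slot binScoreRaw numeric per-bin adjusted score, NA where both
#'   counts are zero.
#' @slot binScore numeric per-bin adjusted score with NAs interpolated.
#'
#' @aliases ScoreCalibration-class
#' @exportClass ScoreCalibration
setClass("ScoreCalibration",
    representation(w1 = "numeric", inflationRatio = "numeric",
                   binWidth = "numeric", upperLimit = "numeric",
                   breaks = "numeric", binScoreRaw = "numeric",
                   binScore = "numeric"))

setValidity("ScoreCalibration", function(object) {
    if (object@w1 < 0 || object@w1 > 1) return("w1 must be in [0, 1]")
    b <- object@binScore
    if (any(!is.na(b) & (b < 0 | b > 1)))
        return("bin scores must be in [0, 1]")
    TRUE
})

#' ProfileNetwork: latent-profile drug-drug similarity network
#'
#' Drug-drug network built from cosine similarities of the rows of the
#' chemical factor matrix U. An edge is kept when the cosine similarity
#' exceeds the profile threshold; each edge also carries the structural
#' (Tanimoto) similarity and a flag marking structurally novel pairs
#' (high profile similarity, structural similarity below 0.5) — the
#' repurposing-relevant pairs.
#'
#' @slot nodes character vector of drug identifiers.
#' @slot edges data.frame with columns \code{a}, \code{b} (node
#'   indices, a < b), \code{cosine}, \code{tc}, \code{structuralNovel}.
#'
#' @aliases ProfileNetwork-class
#' @exportClass ProfileNetwork
setClass("ProfileNetwork",
    representation(nodes = "character", edges = "data.frame"))

setValidity("ProfileNetwork", function(object) {
    e <- object@edges
    need <- c("a", "b", "cosine", "tc", "structuralNovel")
    if (!all(need %in% names(e)))
        return("edges must have columns a, b, cosine, tc, structuralNovel")
    n <- length(object@nodes)
    if (nrow(e)) {
        if (min(e$a) < 1 || max(e$b) > n || any(e$a >= e$b))
            return("edge endpoints must satisfy 1 <= a < b <= n")
        if (min(e$cosine) < 0 || max(e$cosine) > 1)
            return("cosine weights must be in [0, 1]")
    }
    TRUE
})

#' ClusterSet: a partition of network nodes
#'
#' Result of Markov clustering: a partition of the network nodes into
#' disjoint, covering, non-empty clusters.
#'
#' @slot nodes character vector of node identifiers.
#' @slot membership integer cluster index per node (1-based,
#'   consecutive).
#' @slot converged logical; FALSE when the iteration limit was reached
#'   before the flow matrix became stationary.
#'
#' @aliases ClusterSet-class
#' @exportClass ClusterSet
setClass("ClusterSet",
    representation(nodes = "character", membership = "integer",
                   converged = "logical"))

setValidity("ClusterSet", function(object) {
    m <- object@membership
    if (length(m) != length(object@nodes))
        return("one membership per node required")
    if (length(m)) {
        if (anyNA(m) || min(m) != 1L || !identical(sort(unique(m)),
                                                   seq_len(max(m))))
            return("membership must use consecutive cluster ids from 1")
    }
    TRUE
})

#' SyntheticSpec: parameters of the block-model synthetic generator
#'
#' Defines a desk-scale synthetic chemical-protein world: chemicals and
#' proteins partitioned into k latent blocks; true interactions drawn
#' with a high within-block and low cross-block probability; similarity
#' matrices that reflect block co-membership with Gaussian jitter; a
#' sparse observed sample of the true pairs; and a held-out subset of
#' the observed positives for evaluation.
#'
#' @slot nChemicals,mProteins,kBlocks positive integers.
#' @slot density fraction of true pairs that are observed.
#' @slot withinProb,crossProb within/cross-block true-interaction
#'   probabilities (informative instances need withinProb > crossProb).
#' @slot similaritySignal similarity added for same-block pairs.
#' @slot noiseSd standard deviation of similarity jitter.
#' @slot holdoutFraction fraction of observed positives held out.
#' @slot seed integer seed.
#'
#' @aliases SyntheticSpec-class
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(nChemicals = "integer", mProteins = "integer",
                   kBlocks = "integer", density = "numeric",
                   withinProb = "numeric", crossProb = "numeric",
                   similaritySignal = "numeric", noiseSd = "numeric",
                   holdoutFraction = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    if (object@nChemicals < 1L || object@mProteins < 1L || object@kBlocks < 1L)
        return("nChemicals, mProteins, kBlocks must be positive")
    p01 <- function(x) x >= 0 && x <= 1
    if (!p01(object@density)) return("density must be in [0, 1]")
    if (!p01(object@withinProb) || !p01(object@crossProb))
        return("interaction probabilities must be in [0, 1]")
    if (!p01(object@similaritySignal))
        return("similaritySignal must be in [0, 1]")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (!p01(object@holdoutFraction))
        return("holdoutFraction must be in [0, 1]")
    TRUE
})

#' BenchmarkReport: stratified held-out ranking results
#'
#' Per held-out positive pair: the cross-validation fold, the rank of
#' the true protein among the chemical's candidate proteins (training
#' positives excluded), the candidate count, and the NT / L / Tc
#' stratification labels. Summaries (TPR at cutoff ranks, mean and
#' s.e.m. over folds) are computed by \code{\link{tprSummary}}.
#'
#' @slot results data.frame with columns \code{fold}, \code{chemical},
#'   \code{protein}, \code{rank}, \code{nCandidates}, \code{nt},
#'   \code{l}, \code{tc}.
#' @slot nFolds integer number of folds.
#' @slot topFraction numeric fraction defining the headline cutoff.
#' @slot cutoff integer headline cutoff rank.
#'
#' @aliases BenchmarkReport-class
#' @exportClass BenchmarkReport
setClass("BenchmarkReport",
    representation(results = "data.frame", nFolds = "integer",
                   topFraction = "numeric", cutoff = "integer"))

setValidity("BenchmarkReport", function(object) {
    need <- c("fold", "chemical", "protein", "rank", "nCandidates",
              "nt", "l", "tc")
    if (!all(need %in% names(object@results)))
        return("results is missing required columns")
    TRUE
})
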