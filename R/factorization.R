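#' Create a configuration for the one-class factorization
#'
#' Defaults are the benchmark parameter setting of the method:
#' \code{pWt = pImp = pReg = 0.1}, \code{rank = 300},
#' \code{pChem = 0.75}, \code{pProt = 0.1}, \code{nIter = 400}
#' (a jointly optimized alternative is \code{pChem = pProt = 0.25}).
#' Observed positive entries receive weight 1 and regression target 1;
#' every unobserved entry receives weight \code{pWt} and imputed target
#' \code{pImp} (the assumed probability that an untested pair is a true
#' association). Optional per-entry overrides replace the global weight
#' or target at selected entries, e.g. to encode prior knowledge.
#'
#' @param pWt,pImp,pReg,pChem,pProt,rank,nIter,seed,epsilon,tol see
#'   \linkS4class{OccfConfig}.
#' @param weightOverride,targetOverride optional data.frames with
#'   columns \code{i}, \code{j}, \code{value} (1-based entry indices).
#' @return An \linkS4class{OccfConfig}.
#' @export
occfConfig <- function(pWt = 0.1, pImp = 0.1, pReg = 0.1, pChem = 0.75,
                       pProt = 0.1, rank = 300L, nIter = 400L, seed = 1L,
                       epsilon = 1e-12, tol = 0,
                       weightOverride = NULL, targetOverride = NULL) {
    new("OccfConfig", pWt = pWt, pImp = pImp, pReg = pReg, pChem = pChem,
        pProt = pProt, rank = as.integer(rank), nIter = as.integer(nIter),
        seed = as.integer(seed), epsilon = epsilon, tol = tol,
        weightOverride = weightOverride, targetOverride = targetOverride)
}

# Weight/target scheme: global (w0, t0) for unobserved entries plus a
# sparse support where (weight, target) differ from the global values —
# the observed positives (1, 1) and any per-entry overrides.
.scheme <- function(table, cfg) {
    w0 <- cfg@pWt
    t0 <- cfg@pImp
    pp <- positivePairs(table)
    n <- nChemicals(table)
    m <- nProteins(table)
    key <- pp$i + n * (pp$j - 1)
    sup <- data.frame(i = pp$i, j = pp$j,
                      w = rep(1, nrow(pp)), t = rep(1, nrow(pp)))
    addOverride <- function(sup, ov, field) {
        if (is.null(ov) || nrow(ov) == 0L) return(sup)
        if (any(ov$i < 1 | ov$i > n | ov$j < 1 | ov$j > m))
            stop("override index out of range")
        k <- ov$i + n * (ov$j - 1)
        hit <- match(k, sup$i + n * (sup$j - 1))
        newRows <- is.na(hit)
        if (any(newRows)) {
            sup <- rbind(sup, data.frame(i = ov$i[newRows],
                                         j = ov$j[newRows],
                                         w = w0, t = t0))
            hit <- match(k, sup$i + n * (sup$j - 1))
        }
        sup[[field]][hit] <- ov$value
        sup
    }
    sup <- addOverride(sup, cfg@weightOverride, "w")
    sup <- addOverride(sup, cfg@targetOverride, "t")
    # entries identical to the global scheme contribute nothing
    sup <- sup[sup$w != w0 | sup$t != t0, , drop = FALSE]
    list(w0 = w0, t0 = t0, n = n, m = m,
         i = sup$i, j = sup$j, w = sup$w, t = sup$t)
}

# model predictions restricted to the scheme support entries
.supportScores <- function(U, V, sch) {
    if (length(sch$i) == 0L) return(numeric(0))
    rowSums(U[sch$i, , drop = FALSE] * V[sch$j, , drop = FALSE])
}

#' Evaluate the regularized one-class objective
#'
#' Computes the weighted squared reconstruction error over all entries
#' (observed positives against target 1 with weight 1; unobserved
#' entries against the imputed target with the down-weighting), the
#' Tikhonov penalty on both factors, and the two graph-Laplacian
#' smoothness penalties. The global-weight part is evaluated through
#' the Gram identity
#' \eqn{\sum_{ij}(UV')_{ij}^2 = tr((U'U)(V'V))}, so no dense
#' chemicals-by-proteins array is ever materialized.
#'
#' @param table training \linkS4class{InteractionTable}.
#' @param model a \linkS4class{FactorModel}.
#' @param C,T chemical / protein \linkS4class{SimilarityMatrix}
#'   (or NULL for no graph term).
#' @param cfg an \linkS4class{OccfConfig}.
#' @return Scalar objective value.
#' @export
objectiveValue <- function(table, model, C = NULL, T = NULL, cfg) {
    U <- model@U
    V <- model@V
    n <- nChemicals(table)
    m <- nProteins(table)
    if (nrow(U) != n || nrow(V) != m)
        stop("factor dimensions do not match the interaction table")
    sch <- .scheme(table, cfg)
    s1 <- sum(colSums(U) * colSums(V))
    s2 <- sum(crossprod(U) * crossprod(V))
    base <- sch$w0 * (n * m * sch$t0^2 - 2 * sch$t0 * s1 + s2)
    p <- .supportScores(U, V, sch)
    corr <- sum(sch$w * (sch$t - p)^2 - sch$w0 * (sch$t0 - p)^2)
    val <- base + corr + cfg@pReg * (sum(U^2) + sum(V^2))
    if (!is.null(C) && cfg@pChem > 0)
        val <- val + cfg@pChem * laplacianQuadratic(C, U)
    if (!is.null(T) && cfg@pProt > 0)
        val <- val + cfg@pProt * laplacianQuadratic(T, V)
    val
}

#' Seeded random initialization of the factor pair
#'
#' Entries are drawn i.i.d. uniform on \code{(0, 1/sqrt(rank)]}
#' (strictly positive so no entry is trapped at zero by the
#' multiplicative updates; the scale keeps initial inner products of
#' order 1). Bit-identical for identical seeds.
#'
#' @param n,m numbers of chemicals and proteins.
#' @param cfg an \linkS4class{OccfConfig} (uses \code{rank},
#'   \code{seed}).
#' @return A \linkS4class{FactorModel} with an empty objective trace.
#' @export
initializeFactors <- function(n, m, cfg) {
    r <- cfg@rank
    uv <- .withSeed(cfg@seed, {
        list(U = matrix((1 - runif(n * r)) / sqrt(r), n, r),
             V = matrix((1 - runif(m * r)) / sqrt(r), m, r))
    })
    new("FactorModel", U = uv$U, V = uv$V, objectiveTrace = numeric(0),
        chemIds = character(0), protIds = character(0))
}

# One round of multiplicative updates. U is updated first; the V
# update uses the refreshed U (alternating half-steps). With the
# global scheme the dense weight structure is never materialized:
#   (W o Rt) V  = w0*t0 * 1 (1'V) + A V,   A sparse on the support
#   (W o UV')V  = w0 * U (V'V)    + B V,   B sparse on the support
# with A = w*t - w0*t0 and B = (w - w0) * (UV') at support entries.
# one multiplicative half-step updating the "row" factor M against the
# fixed "column" factor N; (si, sj) index the scheme support from the
# row side (si into M, sj into N), A is the sparse numerator correction
.halfStep <- function(M, N, w0, t0, si, sj, dw, A, graph, deg,
                      coefGraph, pReg, eps) {
    r <- ncol(M)
    numer <- if (w0 * t0 > 0)
        matrix(w0 * t0 * colSums(N), nrow(M), r, byrow = TRUE)
    else matrix(0, nrow(M), r)
    numer <- numer + as.matrix(A %*% N)
    denom <- w0 * (M %*% crossprod(N)) + pReg * M
    if (length(si)) {
        p <- rowSums(M[si, , drop = FALSE] * N[sj, , drop = FALSE])
        B <- sparseMatrix(i = si, j = sj, x = dw * p, dims = dim(A))
        denom <- denom + as.matrix(B %*% N)
    }
    if (!is.null(graph) && coefGraph > 0) {
        numer <- numer + coefGraph * as.matrix(graph %*% M)
        denom <- denom + coefGraph * (deg * M)
    }
    M * pmax(numer, 0) / pmax(denom, eps)
}

.updateOnce <- function(U, V, sch, ctx, cfg) {
    dw <- sch$w - sch$w0
    U <- .halfStep(U, V, sch$w0, sch$t0, sch$i, sch$j, dw, ctx$A,
                   ctx$Cs, ctx$degC, cfg@pChem, cfg@pReg, cfg@epsilon)
    V <- .halfStep(V, U, sch$w0, sch$t0, sch$j, sch$i, dw, ctx$At,
                   ctx$Ts, ctx$degT, cfg@pProt, cfg@pReg, cfg@epsilon)
    list(U = U, V = V)
}

.makeContext <- function(table, C, T, cfg, sch) {
    n <- sch$n; m <- sch$m
    A <- sparseMatrix(i = sch$i, j = sch$j,
                      x = sch$w * sch$t - sch$w0 * sch$t0,
                      dims = c(n, m))
    list(A = A, At = Matrix::t(A),
         Cs = if (!is.null(C)) C@sim else NULL,
         degC = if (!is.null(C)) Matrix::rowSums(C@sim) else NULL,
         Ts = if (!is.null(T)) T@sim else NULL,
         degT = if (!is.null(T)) Matrix::rowSums(T@sim) else NULL)
}

#' Apply one round of multiplicative updates
#'
#' One alternating update of U then V (graph-regularized weighted NMF
#' style). Nonnegativity is preserved by construction and the objective
#' never increases beyond numerical tolerance.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param table training \linkS4class{InteractionTable}.
#' @param C,T similarity matrices or NULL.
#' @param cfg an \linkS4class{OccfConfig}.
#' @return The updated \linkS4class{FactorModel}.
#' @export
updateStep <- function(model, table, C = NULL, T = NULL, cfg) {
    sch <- .scheme(table, cfg)
    ctx <- .makeContext(table, C, T, cfg, sch)
    uv <- .updateOnce(model@U, model@V, sch, ctx, cfg)
    initialize(model, U = uv$U, V = uv$V)
}

#' Fit the dual-regularized one-class factorization
#'
#' Runs the seeded initialization followed by a fixed budget of
#' multiplicative update rounds, recording the objective after
#' initialization and after every round. Deterministic given the
#' configuration seed. With \code{tol > 0}, stops early once the
#' relative objective decrease falls below \code{tol}.
#'
#' @param table training \linkS4class{InteractionTable}.
#' @param C,T chemical / protein similarity matrices (NULL disables
#'   the corresponding graph term).
#' @param cfg an \linkS4class{OccfConfig}.
#' @return A fitted \linkS4class{FactorModel} carrying the table's ids
#'   and the objective trace.
#' @examples
#' dat <- generateSynthetic(syntheticSpec(nChemicals = 30, mProteins = 20,
#'                                        kBlocks = 2, seed = 7))
#' cfg <- occfConfig(rank = 5, nIter = 50, seed = 7)
#' fm <- fitOccf(dat$observed, dat$C, dat$T, cfg)
#' head(objectiveTrace(fm))
#' @export
fitOccf <- function(table, C = NULL, T = NULL, cfg = occfConfig()) {
    n <- nChemicals(table)
    m <- nProteins(table)
    if (!is.null(C) && length(C@ids) != n)
        stop("chemical similarity dimension does not match the table")
    if (!is.null(T) && length(T@ids) != m)
        stop("protein similarity dimension does not match the table")
    if (cfg@rank > min(n, m))
        warning("rank exceeds min(n, m); model is over-parameterized")
    model <- initializeFactors(n, m, cfg)
    sch <- .scheme(table, cfg)
    ctx <- .makeContext(table, C, T, cfg, sch)
    U <- model@U
    V <- model@V
    trace <- numeric(cfg@nIter + 1L)
    objOf <- function(U, V) {
        objectiveValue(table,
                       new("FactorModel", U = U, V = V,
                           objectiveTrace = numeric(0),
                           chemIds = character(0), protIds = character(0)),
                       C, T, cfg)
    }
    trace[1L] <- objOf(U, V)
    used <- 1L
    for (it in seq_len(cfg@nIter)) {
        uv <- .updateOnce(U, V, sch, ctx, cfg)
        U <- uv$U
        V <- uv$V
        used <- it + 1L
        trace[used] <- objOf(U, V)
        if (cfg@tol > 0 && it > 1L) {
            rel <- (trace[used - 1L] - trace[used]) /
                max(abs(trace[used - 1L]), .Machine$double.eps)
            if (rel >= 0 && rel < cfg@tol) break
        }
    }
    new("FactorModel", U = U, V = V, objectiveTrace = trace[seq_len(used)],
        chemIds = table@chemIds, protIds = table@protIds)
}

#' Raw predicted scores for one chemical
#'
#' The raw score of chemical i against protein j is the inner product
#' of their latent profiles, \code{U[i, ] \%*\% V[j, ]}; nonnegative by
#' construction.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param chemical 1-based chemical row index.
#' @return Numeric vector of length \code{nrow(V)} (named when protein
#'   ids are available).
#' @export
predictScores <- function(model, chemical) {
    if (length(chemical) != 1L || is.na(chemical) || chemical < 1L ||
        chemical > nrow(model@U))
        stop("chemical index out of range")
    s <- as.numeric(model@V %*% model@U[chemical, ])
    if (length(model@protIds)) names(s) <- model@protIds
    s
}

#' Top-k ranked target predictions for one chemical
#'
#' Proteins are sorted by descending raw score with ties broken by
#' ascending protein index (deterministic). Training positives are
#' excluded from the candidate list before ranking.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param chemical 1-based chemical row index.
#' @param k number of predictions to return.
#' @param exclude integer vector of protein indices to drop from the
#'   candidates (typically the chemical's training positives).
#' @return data.frame with columns \code{protein} (index),
#'   \code{score}, \code{rank}; protein ids added when available.
#' @export
predictTopK <- function(model, chemical, k, exclude = integer(0)) {
    if (k < 1L) stop("k must be >= 1")
    s <- as.numeric(model@V %*% model@U[chemical, ])
    cand <- setdiff(seq_len(nrow(model@V)), exclude)
    cand <- cand[order(-s[cand], cand)]
    top <- head(cand, k)
    out <- data.frame(protein = top, score = s[top],
                      rank = seq_along(top))
    if (length(model@protIds)) out$proteinId <- model@protIds[top]
    out
}

#' Rank of one candidate protein for one chemical
#'
#' Rank of protein \code{j} among the chemical's candidates under
#' descending score, ties broken by ascending index — the substrate of
#' the true-positive-rate benchmark.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param chemical chemical row index.
#' @param protein protein index whose rank is requested.
#' @param exclude protein indices removed from the candidates (must
#'   not contain \code{protein}).
#' @return list with \code{rank} and \code{nCandidates}.
#' @export
scoreRank <- function(model, chemical, protein, exclude = integer(0)) {
    s <- as.numeric(model@V %*% model@U[chemical, ])
    cand <- setdiff(seq_len(nrow(model@V)), exclude)
    if (!protein %in% cand) stop("protein was excluded from the candidates")
    sj <- s[protein]
    better <- sum(s[cand] > sj) +
        sum(s[cand] == sj & cand < protein)
    list(rank = better + 1L, nCandidates = length(cand))
}
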