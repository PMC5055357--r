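#' Assign observed positive pairs to cross-validation folds
#'
#' Uniform random partition of the table's active pairs into \code{k}
#' folds of as-equal-as-possible size, seeded and reproducible.
#'
#' @param table an \linkS4class{InteractionTable}.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return data.frame with columns \code{chemical}, \code{protein}
#'   (ids), \code{i}, \code{j} (indices) and \code{fold} in
#'   \code{1..k}.
#' @export
makeFolds <- function(table, k = 10L, seed = 1L) {
    pp <- positivePairs(table)
    if (nrow(pp) < k)
        stop(sprintf("need at least %d positive pairs for %d folds", k, k))
    perm <- .withSeed(seed, sample.int(nrow(pp)))
    fold <- integer(nrow(pp))
    fold[perm] <- rep_len(seq_len(k), nrow(pp))
    data.frame(chemical = table@chemIds[pp$i], protein = table@protIds[pp$j],
               i = pp$i, j = pp$j, fold = fold)
}

#' Top-percentile cutoff rank
#'
#' Rank cutoff corresponding to a fraction of the candidate panel:
#' \code{floor(fraction * candidateCount)}, at least 1. A 3,500-protein
#' panel at the top 1 percent gives rank 35.
#'
#' @param candidateCount number of candidate proteins.
#' @param fraction fraction in (0, 1].
#' @return Integer cutoff rank.
#' @examples
#' topPercentCutoff(3500, 0.01)  # 35
#' @export
topPercentCutoff <- function(candidateCount, fraction) {
    if (candidateCount < 1L) stop("candidateCount must be >= 1")
    if (!(fraction > 0 && fraction <= 1))
        stop("fraction must be in (0, 1]")
    max(1L, as.integer(floor(fraction * candidateCount)))
}

#' True positive rate at a cutoff rank
#'
#' Fraction of held-out positive pairs whose predicted rank is at or
#' below the cutoff (recall / recovery at top-k).
#'
#' @param ranks integer ranks of held-out positives.
#' @param cutoff cutoff rank.
#' @return TPR in [0, 1], or NA for an empty rank list.
#' @export
tprAtCutoff <- function(ranks, cutoff) {
    if (length(ranks) == 0L) return(NA_real_)
    mean(ranks <= cutoff)
}

# stratification labels --------------------------------------------------

.ntClass <- function(trainCount) {
    # a held-out chemical with its only association hidden is NT1
    c("NT1", "NT2", "NT3")[min(trainCount + 1L, 3L)]
}

.lBucket <- function(ligandCount) {
    if (ligandCount >= 21L) return("L21more")
    b <- (max(ligandCount, 1L) - 1L) %/% 5L
    sprintf("L%dto%d", b * 5L + 1L, b * 5L + 5L)
}

.tcBucket <- function(maxSim) {
    if (maxSim < 0.5) return("TcNone")
    d <- min(ceiling(round(maxSim, 10) * 10) / 10, 1)
    if (d < 0.6) d <- 0.6  # lowest bucket [0.5, 0.6] is closed at 0.5
    sprintf("Tc%.1fto%.1f", d - 0.1, d)
}

#' Stratification category of a held-out pair
#'
#' Assigns the benchmark strata of a held-out (chemical, protein)
#' pair relative to a training table: the NT class from the chemical's
#' remaining training positives plus the hidden pair itself (NT1 = the
#' cold-start case, NT3 = three or more known targets); the L bucket
#' from the protein's training ligand count in increments of 5 with an
#' open top bucket L21more; and the Tc bucket from the chemical's
#' maximum similarity to chemicals that have training positives, in
#' intervals \code{(d - 0.1, d]} with the lowest bucket closed at 0.5
#' (chemicals with no retained similarity fall in \code{TcNone}).
#'
#' @param chemical,protein 1-based indices of the held-out pair.
#' @param trainTable the training \linkS4class{InteractionTable} (with
#'   the pair held out).
#' @param C chemical \linkS4class{SimilarityMatrix} (or NULL: all
#'   pairs TcNone).
#' @return list with \code{nt}, \code{l}, \code{tc} labels.
#' @export
categorize <- function(chemical, protein, trainTable, C = NULL) {
    pos <- positiveMatrix(trainTable)
    nt <- .ntClass(sum(pos[chemical, ]))
    l <- .lBucket(sum(pos[, protein]))
    tc <- "TcNone"
    if (!is.null(C)) {
        trained <- which(Matrix::rowSums(pos) > 0)
        trained <- setdiff(trained, chemical)
        if (length(trained)) {
            maxSim <- max(C@sim[chemical, trained])
            tc <- .tcBucket(maxSim)
        }
    }
    list(nt = nt, l = l, tc = tc)
}

#' Ranks of held-out positive pairs under a fitted model
#'
#' Convenience wrapper around \code{\link{scoreRank}} for a set of
#' held-out pairs (e.g. the synthetic generator's hold-out set): each
#' pair's protein is ranked among the chemical's candidates with the
#' chemical's training positives excluded.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param trainTable the training \linkS4class{InteractionTable}.
#' @param heldout data.frame with integer columns \code{i}, \code{j}.
#' @return data.frame with columns \code{i}, \code{j}, \code{rank},
#'   \code{nCandidates}.
#' @export
heldoutRanks <- function(model, trainTable, heldout) {
    pos <- positiveMatrix(trainTable)
    rows <- lapply(seq_len(nrow(heldout)), function(k) {
        i <- heldout$i[k]
        j <- heldout$j[k]
        r <- scoreRank(model, i, j, exclude = which(pos[i, ]))
        data.frame(i = i, j = j, rank = r$rank,
                   nCandidates = r$nCandidates)
    })
    do.call(rbind, rows)
}

#' Run the stratified cross-validation benchmark
#'
#' For each fold: the fold's positive pairs are hidden, the model is
#' fitted on the remaining data, and every held-out pair is ranked
#' among the chemical's candidate proteins (training positives
#' excluded, ties broken by ascending protein index) and stratified by
#' NT / L / Tc category. Use \code{\link{tprSummary}} for per-category
#' TPR means and standard errors over folds.
#'
#' @param table full \linkS4class{InteractionTable}.
#' @param C,T similarity matrices (C also drives the Tc strata).
#' @param cfg an \linkS4class{OccfConfig}; each fold is fitted with a
#'   fold-derived seed.
#' @param folds fold assignment from \code{\link{makeFolds}}.
#' @param topFraction fraction defining the headline cutoff rank
#'   (default 0.01, i.e. top 1 percent of the protein panel).
#' @return A \linkS4class{BenchmarkReport}.
#' @export
runBenchmark <- function(table, C = NULL, T = NULL, cfg = occfConfig(),
                         folds, topFraction = 0.01) {
    nFolds <- max(folds$fold)
    m <- nProteins(table)
    res <- vector("list", nFolds)
    for (f in seq_len(nFolds)) {
        held <- folds[folds$fold == f, , drop = FALSE]
        trainTable <- dropPositives(table, held)
        cfgFold <- initialize(cfg, seed = .childSeed(cfg@seed, f))
        model <- fitOccf(trainTable, C, T, cfgFold)
        pos <- positiveMatrix(trainTable)
        rows <- lapply(seq_len(nrow(held)), function(k) {
            i <- held$i[k]; j <- held$j[k]
            excl <- which(pos[i, ])
            r <- scoreRank(model, i, j, exclude = excl)
            cat0 <- categorize(i, j, trainTable, C)
            data.frame(fold = f, chemical = held$chemical[k],
                       protein = held$protein[k], rank = r$rank,
                       nCandidates = r$nCandidates, nt = cat0$nt,
                       l = cat0$l, tc = cat0$tc)
        })
        res[[f]] <- do.call(rbind, rows)
    }
    results <- do.call(rbind, res)
    cutoff <- topPercentCutoff(m, topFraction)
    new("BenchmarkReport", results = results, nFolds = as.integer(nFolds),
        topFraction = topFraction, cutoff = as.integer(cutoff))
}

#' Summarize a benchmark report as TPR per category and cutoff
#'
#' @param report a \linkS4class{BenchmarkReport}.
#' @param view \code{"overall"}, \code{"NTxL"} or \code{"NTxTc"}.
#' @param cutoffs integer cutoff ranks (default: the report's headline
#'   cutoff).
#' @return data.frame with columns \code{category}, \code{cutoff},
#'   \code{tpr} (pooled), \code{tprMean}, \code{tprSe} (mean and
#'   s.e.m. of per-fold TPRs), \code{n} (pairs).
#' @export
tprSummary <- function(report, view = c("overall", "NTxL", "NTxTc"),
                       cutoffs = NULL) {
    view <- match.arg(view)
    if (is.null(cutoffs)) cutoffs <- report@cutoff
    d <- report@results
    cat0 <- switch(view,
                   overall = rep("all", nrow(d)),
                   NTxL = paste0(d$nt, d$l),
                   NTxTc = paste0(d$nt, d$tc))
    out <- list()
    for (cc in sort(unique(cat0))) {
        sel <- d[cat0 == cc, , drop = FALSE]
        for (ct in cutoffs) {
            perFold <- vapply(split(sel$rank, sel$fold),
                              tprAtCutoff, numeric(1), cutoff = ct)
            se <- if (length(perFold) > 1L)
                stats::sd(perFold) / sqrt(length(perFold)) else NA_real_
            out[[length(out) + 1L]] <- data.frame(
                category = cc, cutoff = ct,
                tpr = tprAtCutoff(sel$rank, ct),
                tprMean = mean(perFold), tprSe = se, n = nrow(sel))
        }
    }
    do.call(rbind, out)
}

#' Paired t-test between per-fold TPR values of two reports
#'
#' Compares two methods evaluated on the same fold plan by a paired
#' t-test over the per-fold TPR values at a common cutoff.
#'
#' @param reportA,reportB \linkS4class{BenchmarkReport}s on the same
#'   folds.
#' @param cutoff cutoff rank (default: reportA's headline cutoff).
#' @return The \code{htest} object from \code{\link[stats]{t.test}}.
#' @export
tprTTest <- function(reportA, reportB, cutoff = NULL) {
    if (is.null(cutoff)) cutoff <- reportA@cutoff
    tprOf <- function(rep) vapply(
        split(rep@results$rank, rep@results$fold),
        tprAtCutoff, numeric(1), cutoff = cutoff)
    a <- tprOf(reportA)
    b <- tprOf(reportB)
    t.test(a, b, paired = TRUE)
}
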