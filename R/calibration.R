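#' Bin labeled raw scores into an activity-class histogram
#'
#' Scores are assigned to half-open bins \code{[lo, lo + width)} of
#' width 0.05 by default; raw scores above the outlier limit (1.10 by
#' default) are regarded as outliers and excluded. Per class (active,
#' inactive, ambiguous) the histogram stores raw counts and normalized
#' fractions.
#'
#' @param scores numeric raw prediction scores of labeled pairs.
#' @param labels character vector (\code{active}/\code{inactive}/
#'   \code{ambiguous}), same length as \code{scores}.
#' @param binWidth bin width in score units.
#' @param upperLimit outlier limit; scores strictly above are dropped.
#' @return A \linkS4class{ScoreHistogram}.
#' @export
binScores <- function(scores, labels, binWidth = 0.05, upperLimit = 1.10) {
    if (!(binWidth > 0)) stop("binWidth must be > 0")
    if (length(scores) != length(labels))
        stop("scores and labels must have the same length")
    if (!all(labels %in% .LABELS))
        stop("labels must be active/inactive/ambiguous")
    keep <- scores <= upperLimit
    nOut <- sum(!keep)
    scores <- scores[keep]
    labels <- labels[keep]
    nbins <- floor(upperLimit / binWidth) + 1L  # last bin holds == limit
    breaks <- (seq_len(nbins) - 1L) * binWidth
    bin <- pmin(floor(scores / binWidth) + 1L, nbins)
    counts <- matrix(0L, nbins, 3L,
                     dimnames = list(NULL, .LABELS))
    for (cl in .LABELS) {
        t <- tabulate(bin[labels == cl], nbins)
        counts[, cl] <- t
    }
    fractions <- apply(counts, 2, function(ct)
        if (sum(ct) == 0) rep(NA_real_, length(ct)) else ct / sum(ct))
    new("ScoreHistogram", binWidth = binWidth, upperLimit = upperLimit,
        breaks = breaks, counts = counts, fractions = fractions,
        nOutliers = as.integer(nOut))
}

#' Fit the active mixture weight from a score histogram
#'
#' The ambiguous-score distribution is modeled as a convex mixture of
#' the active and inactive distributions,
#' \eqn{A_i \approx w_1 p_i + (1 - w_1) N_i}, and \eqn{w_1} is chosen
#' to minimize the summed squared error
#' \eqn{E_{sum}(w_1) = \sum_i [A_i - \{w_1 p_i + (1-w_1) N_i\}]^2}.
#' The least-squares minimizer has the closed form
#' \eqn{w_1 = \sum_i (p_i - N_i)(A_i - N_i) / \sum_i (p_i - N_i)^2},
#' clipped to [0, 1].
#'
#' @param hist a \linkS4class{ScoreHistogram} with all three classes
#'   populated.
#' @return \code{w1} in [0, 1].
#' @export
fitMixtureWeight <- function(hist) {
    f <- hist@fractions
    if (any(apply(f, 2, function(x) all(is.na(x)))))
        stop("all three activity classes must be present to fit w1")
    d <- f[, "active"] - f[, "inactive"]
    denom <- sum(d^2)
    if (denom < .Machine$double.eps)
        stop("degenerate histogram: active and inactive fractions coincide")
    w1 <- sum(d * (f[, "ambiguous"] - f[, "inactive"])) / denom
    min(1, max(0, w1))
}

#' Summed mixture error E_sum at a given weight
#'
#' @param hist a \linkS4class{ScoreHistogram}.
#' @param w1 candidate active mixture weight.
#' @return The summed squared error.
#' @export
mixtureError <- function(hist, w1) {
    f <- hist@fractions
    sum((f[, "ambiguous"] -
         (w1 * f[, "active"] + (1 - w1) * f[, "inactive"]))^2)
}

#' Adjusted score for one histogram bin
#'
#' \eqn{B_i = pos / (pos + \lfloor ratio \cdot neg \rfloor)}: the
#' inactive count is inflated by the inactive/active mixture ratio
#' (5.25 for the fitted weights w1 = 0.16, w2 = 0.84) and rounded
#' down before forming the positive fraction.
#'
#' @param posCount,negCount nonnegative active / inactive counts.
#' @param inflationRatio positive inflation factor for the negatives.
#' @return \eqn{B_i} in [0, 1], or NA when both counts are zero.
#' @examples
#' adjustedBinScore(100, 10, 5.25)  # 100 / (100 + floor(52.5))
#' @export
adjustedBinScore <- function(posCount, negCount, inflationRatio) {
    if (any(posCount < 0) || any(negCount < 0))
        stop("counts must be nonnegative")
    if (!(inflationRatio > 0)) stop("inflationRatio must be > 0")
    infl <- floor(inflationRatio * negCount)
    out <- ifelse(posCount + infl == 0, NA_real_,
                  posCount / (posCount + infl))
    out
}

# fill NA bins by linear interpolation between nearest non-NA
# neighbours; constant extension at the ends
.interpolateBins <- function(b) {
    if (all(is.na(b))) return(b)
    idx <- which(!is.na(b))
    out <- b
    for (k in which(is.na(b))) {
        lo <- idx[idx < k]
        hi <- idx[idx > k]
        if (length(lo) == 0L) out[k] <- b[hi[1]]
        else if (length(hi) == 0L) out[k] <- b[lo[length(lo)]]
        else {
            l <- lo[length(lo)]; h <- hi[1]
            out[k] <- b[l] + (b[h] - b[l]) * (k - l) / (h - l)
        }
    }
    out
}

#' Fit a score calibration from a labeled histogram
#'
#' Estimates the active mixture weight (unless supplied), derives the
#' inflation ratio \code{w2/w1}, and computes the adjusted per-bin
#' scores from the active and (inflated) inactive counts. Bins with no
#' counts are filled by linear interpolation between the nearest
#' informative neighbours so every raw score maps to a defined value.
#'
#' @param hist a \linkS4class{ScoreHistogram}.
#' @param w1 optional externally supplied mixture weight.
#' @return A \linkS4class{ScoreCalibration}.
#' @export
fitCalibration <- function(hist, w1 = NULL) {
    if (is.null(w1)) w1 <- fitMixtureWeight(hist)
    if (w1 <= 0) stop("w1 must be positive to form the inflation ratio")
    ratio <- (1 - w1) / w1
    raw <- adjustedBinScore(hist@counts[, "active"],
                            hist@counts[, "inactive"], ratio)
    new("ScoreCalibration", w1 = w1, inflationRatio = ratio,
        binWidth = hist@binWidth, upperLimit = hist@upperLimit,
        breaks = hist@breaks, binScoreRaw = raw,
        binScore = .interpolateBins(raw))
}

#' Apply a fitted calibration to raw scores
#'
#' Each raw score is mapped to the adjusted score of its bin; scores
#' above the outlier limit clamp to the top retained bin.
#'
#' @param scores numeric raw scores.
#' @param calibration a \linkS4class{ScoreCalibration}.
#' @return Numeric adjusted scores in [0, 1].
#' @export
calibrateScores <- function(scores, calibration) {
    nbins <- length(calibration@breaks)
    bin <- pmin(floor(scores / calibration@binWidth) + 1L, nbins)
    bin <- pmax(bin, 1L)
    calibration@binScore[bin]
}
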