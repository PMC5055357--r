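.LABELS <- c("active", "inactive", "ambiguous")

#' Construct an InteractionTable from labeled pairs
#'
#' Builds the container from an already-aggregated pair list. The
#' vocabularies default to the ids observed in the pairs (in order of
#' first appearance) but may be supplied explicitly to include
#' entities without any observed pair (cold-start chemicals).
#'
#' @param pairs data.frame with columns \code{chemical}, \code{protein},
#'   \code{label} (values \code{active}, \code{inactive},
#'   \code{ambiguous}); at most one row per pair.
#' @param chemIds,protIds optional explicit vocabularies.
#' @return An \linkS4class{InteractionTable}.
#' @examples
#' tab <- interactionTable(data.frame(
#'     chemical = c("c1", "c1", "c2"),
#'     protein  = c("p1", "p2", "p1"),
#'     label    = c("active", "inactive", "active")))
#' positiveMatrix(tab)
#' @export
interactionTable <- function(pairs, chemIds = NULL, protIds = NULL) {
    if (is.null(chemIds)) chemIds <- unique(as.character(pairs$chemical))
    if (is.null(protIds)) protIds <- unique(as.character(pairs$protein))
    if (length(chemIds) == 0L) chemIds <- "(none)"
    if (length(protIds) == 0L) protIds <- "(none)"
    pairs <- as.data.frame(pairs)[, c("chemical", "protein", "label")]
    pairs$chemical <- as.character(pairs$chemical)
    pairs$protein <- as.character(pairs$protein)
    pairs$label <- as.character(pairs$label)
    act <- pairs[pairs$label == "active", , drop = FALSE]
    pos <- sparseMatrix(i = match(act$chemical, chemIds),
                        j = match(act$protein, protIds),
                        dims = c(length(chemIds), length(protIds)))
    new("InteractionTable", chemIds = chemIds, protIds = protIds,
        pairs = pairs, positives = pos)
}

#' Number of chemicals / proteins in an InteractionTable
#' @param object an \linkS4class{InteractionTable}.
#' @return Integer count.
#' @export
nChemicals <- function(object) length(object@chemIds)

#' @rdname nChemicals
#' @export
nProteins <- function(object) length(object@protIds)

#' Observed positive pairs as 0-based or 1-based index pairs
#'
#' @param object an \linkS4class{InteractionTable}.
#' @return data.frame with integer columns \code{i} (chemical row) and
#'   \code{j} (protein column), 1-based.
#' @export
positivePairs <- function(object) {
    tr <- .spTriplets(object@positives)
    data.frame(i = tr$i, j = tr$j)[order(tr$i, tr$j), , drop = FALSE]
}

#' Convert an IC50 concentration from mass to molar units
#'
#' Mass concentrations (common for some database records) are converted
#' to micromolar by dividing by the molecular weight:
#' \eqn{\mu M = (\mu g/L) / (g/mol)}.
#'
#' @param value IC50 in micrograms per liter (nonnegative).
#' @param molecularWeight molecular weight in g/mol (positive).
#' @return IC50 in micromolar.
#' @examples
#' ic50ToMicromolar(1000, 100)  # 10 uM
#' @export
ic50ToMicromolar <- function(value, molecularWeight) {
    if (any(!is.finite(molecularWeight)) || any(molecularWeight <= 0))
        stop("molecularWeight must be > 0")
    if (any(!is.finite(value)) || any(value < 0))
        stop("value must be >= 0")
    value / molecularWeight
}

# normalize one record's IC50 to micromolar; mw only needed for ug/L
.ic50ToUM <- function(value, unit, mw, line) {
    u <- sub("^µ", "u", trimws(unit))  # accept micro sign
    fac <- c("pM" = 1e-6, "nM" = 1e-3, "uM" = 1, "mM" = 1e3, "M" = 1e6)
    if (u %in% names(fac)) return(value * fac[[u]])
    if (u %in% c("ug/L", "ng/mL")) {
        if (is.na(mw))
            stop(sprintf(
                "line %d: unit %s requires a molecular_weight column", line, u))
        return(ic50ToMicromolar(value, mw))
    }
    stop(sprintf("line %d: unknown IC50 unit '%s'", line, unit))
}

#' Read chemical-protein interaction records and label activity
#'
#' Reads a tab-separated file of assay records with header columns
#' \code{chemical_id}, \code{protein_id} and either an explicit
#' \code{label} column (\code{active}/\code{inactive}/\code{ambiguous},
#' e.g. curated drug-target rows) or \code{ic50_value} +
#' \code{ic50_unit} columns (optionally \code{molecular_weight} for
#' mass-unit records). Records for the same pair are aggregated: if all
#' IC50 records fall at or below the activity threshold the pair is
#' \code{active}; if all fall above it the pair is \code{inactive}; if
#' records exist in both ranges the pair is \code{ambiguous}. Pairs
#' never mentioned are unknown and not stored.
#'
#' @param path TSV file path.
#' @param ic50Threshold activity threshold in micromolar (default 10).
#' @param chemIds,protIds optional explicit vocabularies.
#' @return An \linkS4class{InteractionTable}.
#' @export
readInteractions <- function(path, ic50Threshold = 10,
                             chemIds = NULL, protIds = NULL) {
    if (!(ic50Threshold > 0)) stop("ic50Threshold must be > 0")
    d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("chemical_id", "protein_id") %in% names(d)))
        stop("interactions file needs chemical_id and protein_id columns")
    hasLabel <- "label" %in% names(d)
    hasIC <- all(c("ic50_value", "ic50_unit") %in% names(d))
    if (nrow(d) && !hasLabel && !hasIC)
        stop("need either a label column or ic50_value + ic50_unit columns")
    classes <- character(nrow(d))
    for (k in seq_len(nrow(d))) {
        line <- k + 1L  # header is line 1
        lab <- if (hasLabel) trimws(as.character(d$label[k])) else ""
        if (!is.na(lab) && nzchar(lab)) {
            if (!lab %in% .LABELS)
                stop(sprintf("line %d: unknown activity label '%s'",
                             line, lab))
            classes[k] <- lab
        } else if (hasIC) {
            val <- suppressWarnings(as.numeric(d$ic50_value[k]))
            if (is.na(val))
                stop(sprintf("line %d: malformed ic50_value '%s'",
                             line, d$ic50_value[k]))
            mw <- if ("molecular_weight" %in% names(d))
                suppressWarnings(as.numeric(d$molecular_weight[k])) else NA
            um <- .ic50ToUM(val, as.character(d$ic50_unit[k]), mw, line)
            classes[k] <- if (um <= ic50Threshold) "active" else "inactive"
        } else {
            stop(sprintf("line %d: record has neither label nor IC50", line))
        }
    }
    if (nrow(d)) {
        key <- paste(d$chemical_id, d$protein_id, sep = "\r")
        agg <- vapply(split(classes, key), function(cl) {
            if ("ambiguous" %in% cl) return("ambiguous")
            if ("active" %in% cl && "inactive" %in% cl) return("ambiguous")
            cl[1]
        }, character(1))
        first <- !duplicated(key)
        ord <- key[first]
        pairs <- data.frame(chemical = d$chemical_id[first],
                            protein = d$protein_id[first],
                            label = unname(agg[ord]),
                            stringsAsFactors = FALSE)
    } else {
        pairs <- data.frame(chemical = character(0), protein = character(0),
                            label = character(0))
    }
    interactionTable(pairs, chemIds = chemIds, protIds = protIds)
}

#' Derive a training table with some positive pairs removed
#'
#' Removes the given positive pairs (e.g. a cross-validation fold or
#' the generator's hold-out set) from the table; the removed pairs
#' become unknown, all other pairs and both vocabularies are kept.
#'
#' @param object an \linkS4class{InteractionTable}.
#' @param heldout data.frame with columns \code{chemical} and
#'   \code{protein} (ids) identifying active pairs to drop.
#' @return An \linkS4class{InteractionTable} on the same vocabularies.
#' @export
dropPositives <- function(object, heldout) {
    key <- paste(object@pairs$chemical, object@pairs$protein, sep = "\r")
    drop <- key %in% paste(heldout$chemical, heldout$protein, sep = "\r") &
        object@pairs$label == "active"
    interactionTable(object@pairs[!drop, , drop = FALSE],
                     chemIds = object@chemIds, protIds = object@protIds)
}
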