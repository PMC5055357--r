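#' Construct a FingerprintSet
#'
#' @param ids character chemical identifiers.
#' @param bits list of integer vectors of 0-based set-bit positions.
#' @param nbits declared fingerprint length in bits.
#' @return A \linkS4class{FingerprintSet}.
#' @export
fingerprintSet <- function(ids, bits, nbits) {
    bits <- lapply(bits, function(b) sort(unique(as.integer(b))))
    new("FingerprintSet", ids = as.character(ids), bits = bits,
        nbits = as.integer(nbits))
}

# hex string -> 0-based bit positions, big-endian within each byte
# (bit 0 is the most significant bit of the first byte)
.hexToBits <- function(hex, nbits, line) {
    hex <- trimws(hex)
    nbytes <- ceiling(nbits / 8)
    if (nchar(hex) != 2L * nbytes || grepl("[^0-9a-fA-F]", hex))
        stop(sprintf(
            "line %d: hex string length %d inconsistent with %d bits",
            line, nchar(hex), nbits))
    bytes <- strtoi(substring(hex, seq(1, nchar(hex), 2),
                              seq(2, nchar(hex), 2)), 16L)
    pos <- integer(0)
    for (b in seq_along(bytes)) {
        if (bytes[b] == 0L) next
        on <- which(bitwAnd(bytes[b], bitwShiftL(1L, 7:0)) != 0L)
        pos <- c(pos, (b - 1L) * 8L + on - 1L)
    }
    if (length(pos) && max(pos) >= nbits)
        stop(sprintf("line %d: set bit beyond declared length %d",
                     line, nbits))
    pos
}

.bitsToHex <- function(bits, nbits) {
    nbytes <- ceiling(nbits / 8)
    bytes <- integer(nbytes)
    for (p in bits) {
        b <- p %/% 8L + 1L
        bytes[b] <- bitwOr(bytes[b], bitwShiftL(1L, 7L - p %% 8L))
    }
    paste(sprintf("%02X", bytes), collapse = "")
}

#' Read chemical fingerprints from a hex-encoded TSV
#'
#' Expects a tab-separated file with header columns \code{id},
#' \code{nbits} and \code{hex}: per chemical, the fingerprint length in
#' bits and the bit vector as a hexadecimal string (bit 0 is the most
#' significant bit of the first byte). All rows must declare the same
#' length. Round-trips with \code{\link{writeFingerprints}}.
#'
#' @param path TSV file path.
#' @return A \linkS4class{FingerprintSet}.
#' @export
readFingerprints <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(id = "character", hex = "character"))
    if (!all(c("id", "nbits", "hex") %in% names(d)))
        stop("fingerprint file needs id, nbits, hex columns")
    if (nrow(d) == 0L) stop("fingerprint file has no rows")
    nbits <- unique(as.integer(d$nbits))
    if (length(nbits) != 1L)
        stop("all fingerprints must declare the same bit length")
    bits <- lapply(seq_len(nrow(d)), function(k)
        .hexToBits(d$hex[k], nbits, k + 1L))
    fingerprintSet(d$id, bits, nbits)
}

#' Write chemical fingerprints as a hex-encoded TSV
#'
#' @param fps a \linkS4class{FingerprintSet}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeFingerprints <- function(fps, path) {
    hex <- vapply(fps@bits, .bitsToHex, character(1), nbits = fps@nbits)
    d <- data.frame(id = fps@ids, nbits = fps@nbits, hex = hex)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read protein-protein BLAST hits in 12-column tabular format
#'
#' Parses the standard tabular alignment format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart,
#' qend, sstart, send, e-value, bit score). Hits with e-value above the
#' threshold are discarded; duplicate (query, subject) hits keep the
#' maximum bit score.
#'
#' @param path file path (no header, 12 tab-separated columns).
#' @param evalueThreshold maximum e-value retained (default 1e-5).
#' @return data.frame with columns \code{query}, \code{subject},
#'   \code{bitscore}.
#' @export
readBlastTabular <- function(path, evalueThreshold = 1e-5) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        return(data.frame(query = character(0), subject = character(0),
                          bitscore = numeric(0)))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 12L)
    if (length(short))
        stop(sprintf("line %d: expected 12 tab-separated columns, found %d",
                     short[1], lengths(parts)[short[1]]))
    q <- vapply(parts, `[[`, character(1), 1L)
    s <- vapply(parts, `[[`, character(1), 2L)
    ev <- as.numeric(vapply(parts, `[[`, character(1), 11L))
    bit <- as.numeric(vapply(parts, `[[`, character(1), 12L))
    if (anyNA(ev) || anyNA(bit))
        stop("malformed e-value or bit score field")
    keep <- ev <= evalueThreshold
    d <- data.frame(query = q[keep], subject = s[keep],
                    bitscore = bit[keep], stringsAsFactors = FALSE)
    if (nrow(d)) {
        key <- paste(d$query, d$subject, sep = "\r")
        best <- vapply(split(d$bitscore, key), max, numeric(1))
        first <- !duplicated(key)
        d <- d[first, , drop = FALSE]
        d$bitscore <- unname(best[key[first]])
        rownames(d) <- NULL
    }
    d
}

#' Write ranked predictions to a TSV file
#'
#' Writes one row per prediction with columns \code{chemical_id},
#' \code{protein_id}, \code{raw_score}, \code{adjusted_score} (empty
#' when no calibration was applied) and \code{rank}, sorted by chemical
#' id then rank. Output is deterministic (byte-identical for identical
#' input).
#'
#' @param predictions data.frame with columns \code{chemical},
#'   \code{protein}, \code{score}, \code{rank} and optionally
#'   \code{adjusted}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writePredictions <- function(predictions, path) {
    p <- as.data.frame(predictions)
    if (!all(c("chemical", "protein", "score", "rank") %in% names(p)))
        stop("predictions need chemical, protein, score, rank columns")
    if (!"adjusted" %in% names(p)) p$adjusted <- rep(NA_real_, nrow(p))
    p <- p[order(p$chemical, p$rank), , drop = FALSE]
    out <- data.frame(chemical_id = p$chemical, protein_id = p$protein,
                      raw_score = sprintf("%.10g", p$score),
                      adjusted_score = ifelse(is.na(p$adjusted), "",
                                              sprintf("%.10g", p$adjusted)),
                      rank = p$rank)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(colnames(out), collapse = "\t"), con)
    if (nrow(out))
        writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
    invisible(path)
}

#' Read a predictions TSV written by writePredictions
#'
#' @param path file path.
#' @return data.frame with columns \code{chemical}, \code{protein},
#'   \code{score}, \code{adjusted}, \code{rank}.
#' @export
readPredictions <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chemical_id = "character",
                                   protein_id = "character"))
    data.frame(chemical = d$chemical_id, protein = d$protein_id,
               score = as.numeric(d$raw_score),
               adjusted = suppressWarnings(as.numeric(d$adjusted_score)),
               rank = as.integer(d$rank), stringsAsFactors = FALSE)
}
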