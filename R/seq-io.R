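#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases and converts T to U, so that DNA input (e.g. cDNA-derived
#' construct sequences) and RNA input are handled identically downstream.
#' `N` is retained as a degenerate base: it never matches a fixed consensus
#' position and never pairs in a stem.
#'
#' @param raw a single non-empty character string over `{A,C,G,T,U,N}`
#'   (case-insensitive).
#' @return The normalized RNA string (uppercase, `{A,C,G,U,N}`).
#' @examples
#' normalizeSequence("atgcagt")  # "AUGCAGU"
#' @export
normalizeSequence <- function(raw) {
    if (!is.character(raw) || length(raw) != 1L || is.na(raw))
        stop("'raw' must be a single character string")
    if (!nzchar(raw))
        stop("sequence is empty")
    up <- chartr("t", "T", toupper(raw))
    bad <- regexpr("[^ACGTUN]", up)
    if (bad > 0L)
        stop(sprintf("invalid character '%s' at position %d (0-based %d)",
                     substr(up, bad, bad), bad, bad - 1L))
    chartr("T", "U", up)
}

#' Read transcript sequences from a FASTA file
#'
#' Reads a (possibly line-folded) multi-record FASTA file and returns the
#' normalized RNA sequences. Record ids are the first whitespace-delimited
#' token of each header; the remainder is kept as the description.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::RNAStringSet] named by record id, with the
#'   descriptions in `mcols()$description`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 demo", "ACGT", "ACGT"), fa)
#' readTranscripts(fa)
#' @export
readTranscripts <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L)
        stop("no FASTA records in ", path)
    headers <- names(raw)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    if (any(!nzchar(ids)))
        stop("FASTA record with empty id")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
    seqs <- as.character(raw)
    if (any(!nzchar(seqs)))
        stop("empty sequence for record(s): ",
             paste(ids[!nzchar(seqs)], collapse = ", "))
    out <- Biostrings::RNAStringSet(vapply(seqs, normalizeSequence, ""))
    names(out) <- ids
    S4Vectors::mcols(out)$description <- desc
    out
}

#' Write transcript sequences to a FASTA file
#'
#' @param x a named [Biostrings::RNAStringSet] (or named character vector of
#'   normalized sequences).
#' @param path output path.
#' @param width line-fold width.
#' @return Invisibly, `path`.
#' @export
writeTranscripts <- function(x, path, width = 70L) {
    if (is.character(x))
        x <- Biostrings::RNAStringSet(vapply(x, normalizeSequence, ""))
    if (is.null(names(x)) || any(!nzchar(names(x))))
        stop("all records must be named")
    desc <- S4Vectors::mcols(x)$description
    if (!is.null(desc) && any(nzchar(desc))) {
        y <- x
        names(y) <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
        Biostrings::writeXStringSet(y, path, width = width)
    } else {
        Biostrings::writeXStringSet(x, path, width = width)
    }
    invisible(path)
}

## single-sequence coercion used across modules: accepts character,
## RNAString(Set)/DNAString(Set) of length 1; returns normalized string
.asRnaString <- function(x, what = "sequence") {
    if (is(x, "XStringSet")) {
        if (length(x) != 1L)
            stop(what, " must be a single sequence")
        x <- as.character(x[[1L]])
    } else if (is(x, "XString")) {
        x <- as.character(x)
    }
    normalizeSequence(x)
}
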