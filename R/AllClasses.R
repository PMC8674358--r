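#' Scanner configuration
#'
#' Tunable parameters of the endomotif scanner. The consensus heptamer
#' itself (C-N-G-C-A-G-N, scission between offsets 2 and 3) is fixed; these
#' settings govern how far a mismatch may stray from it and what counts as
#' an acceptable enclosing hairpin.
#'
#' @slot maxMismatch integer, mismatches tolerated at the five fixed
#'   consensus positions (0 or 1).
#' @slot flankWindow integer, nt searched on either side of the heptamer
#'   for stem pairing partners.
#' @slot maxLoopLen integer, maximum loop length (>= 7, the heptamer).
#' @slot minPairs integer, minimum base pairs for a canonical stem.
#' @slot maxUnpaired integer, maximum bulged/internal (skipped) bases
#'   tolerated within the stem.
#' @slot minStemScore numeric, minimum weighted stem score
#'   (G.C = 3, A.U = 2, G.U = 1).
#' @slot allowGUWobble logical, whether G.U pairs may contribute.
#' @slot maxBulgeRun integer, maximum consecutive skips on one strand.
#'
#' @seealso [scannerConfig()]
#' @export
setClass("ScannerConfig",
    representation(
        maxMismatch   = "integer",
        flankWindow   = "integer",
        maxLoopLen    = "integer",
        minPairs      = "integer",
        maxUnpaired   = "integer",
        minStemScore  = "numeric",
        allowGUWobble = "logical",
        maxBulgeRun   = "integer"
    )
)

setValidity("ScannerConfig", function(object) {
    msg <- character()
    if (!object@maxMismatch %in% c(0L, 1L))
        msg <- c(msg, "maxMismatch must be 0 or 1")
    if (object@maxLoopLen < 7L)
        msg <- c(msg, "maxLoopLen must be >= 7 (the consensus heptamer)")
    if (object@flankWindow < object@maxLoopLen)
        msg <- c(msg, "flankWindow must be >= maxLoopLen")
    if (object@minPairs < 0L || object@maxUnpaired < 0L ||
        object@maxBulgeRun < 0L || object@minStemScore < 0)
        msg <- c(msg, "all counts and scores must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Create a scanner configuration
#'
#' Defaults follow the reference calibration of the scanner: a 60-nt
#' flanking window (the endomotif is judged in the context of its 55-60
#' flanking bases), loops up to 9 nt, and a canonical stem requiring at
#' least 5 pairs, at most 2 unpaired stem bases, and weighted score >= 12.
#'
#' @param maxMismatch mismatches tolerated at the five fixed consensus
#'   positions (0 or 1).
#' @param flankWindow nt searched either side of the heptamer for pairing.
#' @param maxLoopLen maximum loop length in nt.
#' @param minPairs minimum number of base pairs in a canonical stem.
#' @param maxUnpaired maximum skipped (bulged) bases within the stem.
#' @param minStemScore minimum weighted stem score.
#' @param allowGUWobble allow G.U wobble pairs.
#' @param maxBulgeRun maximum consecutive skips on one strand.
#' @return A [ScannerConfig-class] object.
#' @examples
#' scannerConfig(minPairs = 6)
#' @export
scannerConfig <- function(maxMismatch = 1, flankWindow = 60, maxLoopLen = 9,
                          minPairs = 5, maxUnpaired = 2, minStemScore = 12,
                          allowGUWobble = TRUE, maxBulgeRun = 2) {
    new("ScannerConfig",
        maxMismatch   = as.integer(maxMismatch),
        flankWindow   = as.integer(flankWindow),
        maxLoopLen    = as.integer(maxLoopLen),
        minPairs      = as.integer(minPairs),
        maxUnpaired   = as.integer(maxUnpaired),
        minStemScore  = as.numeric(minStemScore),
        allowGUWobble = isTRUE(allowGUWobble),
        maxBulgeRun   = as.integer(maxBulgeRun))
}

#' Endomotif scan result
#'
#' Container returned by [scanTranscripts()]: one row per endomotif hit in
#' `hits(x)` and one row per transcript in `calls(x)`.
#'
#' `hits(x)` columns (positions 0-based): `transcript_id`, `start`,
#' `heptamer`, `n_mismatch`, `category` (EXACT_CANONICAL /
#' VARIANT_CANONICAL / SUBPAR), `loop_start`, `loop_end`, `n_pairs`,
#' `n_unpaired`, `stem_score`, `cleavage_boundary`.
#'
#' `calls(x)` columns: `transcript_id`, `transcript_class` (RIDD /
#' RIDDLE_SUBPAR / RIDDLE_NONE), `n_exact`, `n_variant`, `n_subpar`.
#'
#' @slot hits data.frame of classified endomotif hits.
#' @slot calls data.frame of per-transcript classifications.
#' @slot config the [ScannerConfig-class] used.
#' @export
setClass("RiddScanResult",
    representation(hits = "data.frame", calls = "data.frame",
                   config = "ScannerConfig")
)

#' Cleavage profile
#'
#' Per-position tally of mapped fragment 3' ends on one reference
#' transcript, with hotspot calls and GC-site bookkeeping. Built by
#' [tallyProfile()].
#'
#' @slot refId reference transcript id.
#' @slot endCounts named integer vector: 0-based end position -> read count.
#' @slot nMapped number of OK-status mapped ends.
#' @slot nGC number of mapped ends at a G.C dinucleotide.
#' @slot gcFraction `nGC / nMapped` (NA when nothing mapped).
#' @slot hotspots data.frame (`end_pos`, `count`, `is_gc`), count-descending.
#' @slot hotspotMin count threshold used for hotspot calling.
#' @export
setClass("CleavageProfile",
    representation(refId = "character", endCounts = "integer",
                   nMapped = "integer", nGC = "integer",
                   gcFraction = "numeric", hotspots = "data.frame",
                   hotspotMin = "integer")
)

setValidity("CleavageProfile", function(object) {
    msg <- character()
    if (sum(object@endCounts) != object@nMapped)
        msg <- c(msg, "endCounts must sum to nMapped")
    if (object@nGC > object@nMapped)
        msg <- c(msg, "nGC cannot exceed nMapped")
    if (length(msg)) msg else TRUE
})
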