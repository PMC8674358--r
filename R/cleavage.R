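## ---- cleavage-fragment 3'-end mapping --------------------------------------
## Fragments produced by IRE1 digestion are ligated to a known 3' adapter,
## cloned and Sanger sequenced. A read is therefore fragment + adapter; the
## reference index aligned to the fragment's last base identifies the
## cleavage position, and the (last base, next reference base) dinucleotide
## records whether the cut fell at a G.C site.

#' Default 3' adapter used for fragment ligation
#' @return The adapter as a DNA string.
#' @export
defaultAdapter <- function() "CAAGCAGAAGACGGCATACGAGATCGTGAT"

.asDnaString <- function(x, what = "read") {
    if (is(x, "XStringSet")) x <- as.character(x[[1L]])
    if (is(x, "XString")) x <- as.character(x)
    up <- toupper(x)
    if (grepl("[^ACGTN]", up))
        stop(what, " must be a DNA string over A/C/G/T/N")
    up
}

#' Trim the 3' adapter from fragment reads
#'
#' Locates the leftmost occurrence of the adapter's first `seedLen` bases
#' with at most `seedMaxMismatch` mismatches and returns the read prefix
#' before it. Reads without a seed hit get status `NO_ADAPTER`; reads that
#' are all adapter get status `EMPTY_FRAGMENT`.
#'
#' @param reads character vector or `DNAStringSet` of reads (named; names
#'   become read ids).
#' @param adapter adapter DNA string.
#' @param seedLen length of the adapter prefix used as the search seed.
#' @param seedMaxMismatch mismatches tolerated in the seed.
#' @return data.frame with `read_id`, `fragment`, `status`
#'   (OK / NO_ADAPTER / EMPTY_FRAGMENT).
#' @export
trimAdapter <- function(reads, adapter = defaultAdapter(), seedLen = 12L,
                        seedMaxMismatch = 1L) {
    adapter <- .asDnaString(adapter, "adapter")
    if (seedLen > nchar(adapter))
        stop("seedLen exceeds the adapter length")
    seed <- Biostrings::DNAString(substr(adapter, 1L, seedLen))
    rid <- names(reads)
    reads <- if (is(reads, "XStringSet")) as.character(reads)
             else as.character(reads)
    if (is.null(rid)) rid <- paste0("read_", seq_along(reads))
    frag <- character(length(reads))
    status <- character(length(reads))
    for (k in seq_along(reads)) {
        r <- .asDnaString(reads[k])
        m <- Biostrings::matchPattern(seed, Biostrings::DNAString(r),
                                      max.mismatch = seedMaxMismatch,
                                      with.indels = FALSE)
        if (length(m) == 0L) {
            frag[k] <- NA_character_
            status[k] <- "NO_ADAPTER"
        } else {
            cut <- min(Biostrings::start(m))
            frag[k] <- substr(r, 1L, cut - 1L)
            status[k] <- if (cut == 1L) "EMPTY_FRAGMENT" else "OK"
        }
    }
    data.frame(read_id = rid, fragment = frag, status = status)
}

#' Map a fragment's 3' end onto the reference transcript
#'
#' Fragments are assumed sense-strand and 5'-anchored (primer-defined), so
#' mapping is a semiglobal alignment: the fragment aligns end to end, the
#' reference has free end gaps (match +1, mismatch -1, gap -2 per base). An
#' exact/near-exact substring fast path is tried first; when several
#' equal-best placements end at distinct reference positions the read is
#' AMBIGUOUS. A placement with identity below `minIdentity` is NO_MATCH,
#' and a fragment reaching the reference 3' terminus is AT_3PRIME_TERMINUS
#' (its cleavage dinucleotide is undefined).
#'
#' @param fragment adapter-trimmed fragment (DNA string).
#' @param reference reference transcript (RNA string, `XString(Set)` or
#'   character); its U bases pair with fragment T bases.
#' @param minIdentity minimum fraction of fragment bases matching.
#' @param refId reference id recorded in the output.
#' @return One-row data.frame: `ref_id`, `status`, `end_pos` (0-based index
#'   of the fragment's last base on the reference), `last_nt`, `next_nt`,
#'   `is_gc`.
#' @export
mapEnd <- function(fragment, reference, minIdentity = 0.95,
                   refId = "reference") {
    refR <- .asRnaString(reference, "reference")
    refD <- Biostrings::DNAString(chartr("U", "T", refR))
    frag <- .asDnaString(fragment, "fragment")
    if (!nzchar(frag))
        stop("fragment is empty")
    fl <- nchar(frag)
    L <- nchar(refR)
    res <- function(status, end0 = NA_integer_) {
        last_nt <- next_nt <- NA_character_
        is_gc <- NA
        if (!is.na(end0)) {
            last_nt <- substr(refR, end0 + 1L, end0 + 1L)
            if (end0 + 1L < L) {
                next_nt <- substr(refR, end0 + 2L, end0 + 2L)
                is_gc <- last_nt == "G" && next_nt == "C"
            } else {
                status <- "AT_3PRIME_TERMINUS"
            }
        }
        data.frame(ref_id = refId, status = status, end_pos = end0,
                   last_nt = last_nt, next_nt = next_nt, is_gc = is_gc)
    }
    pat <- Biostrings::DNAString(frag)
    ## fast path: exact, then substitution-only within the identity budget
    for (k in 0:floor((1 - minIdentity) * fl)) {
        m <- Biostrings::matchPattern(pat, refD, max.mismatch = k,
                                      with.indels = FALSE)
        if (length(m) == 0L) next
        nmm <- Biostrings::neditStartingAt(pat, refD,
                                           starting.at =
                                               Biostrings::start(m),
                                           with.indels = FALSE)
        bestEnds <- unique(Biostrings::end(m)[nmm == min(nmm)])
        if (length(bestEnds) > 1L)
            return(res("AMBIGUOUS"))
        return(res("OK", bestEnds - 1L))
    }
    ## full semiglobal alignment (needed only when indels are present)
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                   baseOnly = FALSE,
                                                   type = "DNA")
    aln <- Biostrings::pairwiseAlignment(pat, refD, type = "global-local",
                                         substitutionMatrix = sm,
                                         gapOpening = 0, gapExtension = 2)
    if (Biostrings::nmatch(aln) / fl < minIdentity)
        return(res("NO_MATCH"))
    res("OK", Biostrings::end(Biostrings::subject(aln)) - 1L)
}

#' Trim and map a full read set
#'
#' Pipeline convenience: [trimAdapter()] then [mapEnd()] for every read,
#' carrying trimming failures through as statuses so that the statuses
#' partition the read set.
#'
#' @inheritParams trimAdapter
#' @inheritParams mapEnd
#' @return data.frame with one row per read: `read_id`, `ref_id`, `status`,
#'   `end_pos`, `last_nt`, `next_nt`, `is_gc`.
#' @export
mapFragmentEnds <- function(reads, reference, adapter = defaultAdapter(),
                            seedLen = 12L, seedMaxMismatch = 1L,
                            minIdentity = 0.95, refId = "reference") {
    tr <- trimAdapter(reads, adapter, seedLen, seedMaxMismatch)
    rows <- lapply(seq_len(nrow(tr)), function(k) {
        if (tr$status[k] != "OK")
            return(data.frame(ref_id = refId, status = tr$status[k],
                              end_pos = NA_integer_,
                              last_nt = NA_character_,
                              next_nt = NA_character_, is_gc = NA))
        mapEnd(tr$fragment[k], reference, minIdentity, refId)
    })
    out <- do.call(rbind, rows)
    cbind(read_id = tr$read_id, out)
}

#' Tally mapped 3' ends into a cleavage profile
#'
#' Counts OK-status ends per reference position, tallies G.C-site ends,
#' and calls hotspots: positions attracting at least `hotspotMin` reads
#' (default `max(3, ceiling(0.05 * nMapped))`).
#'
#' @param ends data.frame from [mapFragmentEnds()] (or rbind of
#'   [mapEnd()] rows).
#' @param reference the reference transcript.
#' @param hotspotMin hotspot count threshold (`NULL` for the default).
#' @return A [CleavageProfile-class].
#' @export
tallyProfile <- function(ends, reference, hotspotMin = NULL) {
    refs <- unique(ends$ref_id[!is.na(ends$ref_id)])
    if (length(refs) > 1L)
        stop("ends from mixed references: ", paste(refs, collapse = ", "))
    ok <- ends[ends$status == "OK", , drop = FALSE]
    nMapped <- nrow(ok)
    if (nMapped == 0L) {
        warning("no OK-status ends; gc_fraction undefined")
        return(new("CleavageProfile",
                   refId = if (length(refs)) refs else NA_character_,
                   endCounts = integer(0), nMapped = 0L, nGC = 0L,
                   gcFraction = NA_real_,
                   hotspots = data.frame(end_pos = integer(),
                                         count = integer(),
                                         is_gc = logical()),
                   hotspotMin = NA_integer_))
    }
    if (is.null(hotspotMin))
        hotspotMin <- max(3L, ceiling(0.05 * nMapped))
    refR <- .asRnaString(reference, "reference")
    cnt <- table(ok$end_pos)
    endCounts <- setNames(as.integer(cnt), names(cnt))
    nGC <- sum(ok$is_gc, na.rm = TRUE)
    hs <- endCounts[endCounts >= hotspotMin]
    hs <- hs[order(-hs, as.integer(names(hs)))]
    pos <- as.integer(names(hs))
    hotspots <- data.frame(
        end_pos = pos, count = as.integer(hs),
        is_gc = substr(refR, pos + 1L, pos + 1L) == "G" &
                substr(refR, pos + 2L, pos + 2L) == "C")
    new("CleavageProfile", refId = refs, endCounts = endCounts,
        nMapped = nMapped, nGC = as.integer(nGC),
        gcFraction = nGC / nMapped, hotspots = hotspots,
        hotspotMin = as.integer(hotspotMin))
}

#' @rdname CleavageProfile-class
#' @export
setMethod("endCounts", "CleavageProfile", function(x) x@endCounts)
#' @rdname CleavageProfile-class
#' @export
setMethod("nMapped", "CleavageProfile", function(x) x@nMapped)
#' @rdname CleavageProfile-class
#' @export
setMethod("gcFraction", "CleavageProfile", function(x) x@gcFraction)
#' @rdname CleavageProfile-class
#' @export
setMethod("hotspots", "CleavageProfile", function(x) x@hotspots)

setMethod("show", "CleavageProfile", function(object) {
    cat("CleavageProfile for", object@refId, "\n")
    cat(sprintf("  %d mapped ends at %d positions; %d (%.1f%%) at G.C sites\n",
                object@nMapped, length(object@endCounts), object@nGC,
                100 * object@gcFraction))
    cat(sprintf("  %d hotspot(s) at count >= %d\n",
                nrow(object@hotspots), object@hotspotMin))
})

#' GC-dinucleotide enrichment of cleavage ends
#'
#' Exact binomial test of the number of G.C-site ends against the
#' reference's background G.C-dinucleotide density (fraction of positions
#' `i` with base `G` followed by base `C`).
#'
#' @param profile a [CleavageProfile-class] with at least one mapped end.
#' @param reference the reference transcript.
#' @return data.frame: `n_gc`, `n_mapped`, `background_p`, `p_value`
#'   (two-sided).
#' @export
gcEnrichment <- function(profile, reference) {
    stopifnot(is(profile, "CleavageProfile"))
    if (profile@nMapped < 1L)
        stop("undefined test: no mapped ends")
    refR <- .asRnaString(reference, "reference")
    x <- strsplit(refR, "", fixed = TRUE)[[1L]]
    L <- length(x)
    bg <- sum(x[-L] == "G" & x[-1L] == "C") / (L - 1L)
    if (bg == 0 || bg == 1) {
        warning("degenerate background GC density (", bg, ")")
        pv <- if ((bg == 0 && profile@nGC > 0) ||
                  (bg == 1 && profile@nGC < profile@nMapped)) 0 else 1
    } else {
        pv <- binom.test(profile@nGC, profile@nMapped, p = bg,
                         alternative = "two.sided")$p.value
    }
    data.frame(n_gc = profile@nGC, n_mapped = profile@nMapped,
               background_p = bg, p_value = pv)
}
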