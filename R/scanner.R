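## ---- endomotif scanner -----------------------------------------------------
## The consensus loop is the heptamer C-N-G-C-A-G-N with scission between the
## third (G) and fourth (C) nucleotides; the five fixed offsets are
## 0:C 2:G 3:C 4:A 5:G (0-based within the heptamer). A canonical endomotif
## additionally requires a sufficiently stable hairpin stem enclosing the
## loop, assembled from the flanking bases.

.CONSENSUS_OFFSETS <- c(0L, 2L, 3L, 4L, 5L)
.CONSENSUS_BASES   <- c("C", "G", "C", "A", "G")

## weighted pair "stability" proxy: G.C = 3, A.U = 2, G.U = 1 (if enabled);
## N never pairs
.pairWeight <- function(a, b, allowGU) {
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    if (a == "C" && b == "G") return(3)
    if (a == "A" && b == "U") return(2)
    if (allowGU && a == "G" && b == "U") return(1)
    0
}

#' Locate consensus loop matches
#'
#' Slides a 7-nt window along the sequence and reports every window whose
#' five fixed consensus positions (C.G.CAG., offsets 0,2,3,4,5) mismatch the
#' consensus at no more than `maxMismatch` positions. An `N` in the sequence
#' never counts as a match. The cleavage boundary of a match is fixed at
#' `start + 3` (scission between the loop's third and fourth nucleotides),
#' regardless of where a tolerated mismatch lies.
#'
#' @param seq a normalized RNA string (see [normalizeSequence()]), or an
#'   object coercible to one.
#' @param config a [ScannerConfig-class]; only `maxMismatch` is used here.
#' @return data.frame with 0-based `start`, `heptamer`, `n_mismatch`,
#'   `mismatch_positions` (list column of heptamer offsets), and
#'   `cleavage_boundary`; zero rows if the sequence is shorter than 7 nt.
#' @examples
#' findLoopMatches("CAUGUCCGCAGCGCAUG", scannerConfig())
#' @export
findLoopMatches <- function(seq, config = scannerConfig()) {
    seq <- .asRnaString(seq)
    n <- nchar(seq)
    empty <- data.frame(start = integer(), heptamer = character(),
                        n_mismatch = integer(), cleavage_boundary = integer())
    empty$mismatch_positions <- list()
    if (n < 7L)
        return(empty[, c("start", "heptamer", "n_mismatch",
                         "mismatch_positions", "cleavage_boundary")])
    x <- strsplit(seq, "", fixed = TRUE)[[1L]]
    nwin <- n - 6L
    mm <- matrix(FALSE, nrow = nwin, ncol = 5L)
    for (k in seq_along(.CONSENSUS_OFFSETS)) {
        off <- .CONSENSUS_OFFSETS[k]
        mm[, k] <- x[seq_len(nwin) + off] != .CONSENSUS_BASES[k]
    }
    nmm <- rowSums(mm)
    keep <- which(nmm <= config@maxMismatch)
    out <- data.frame(
        start = keep - 1L,
        heptamer = vapply(keep, function(i)
            paste(x[i:(i + 6L)], collapse = ""), ""),
        n_mismatch = as.integer(nmm[keep]),
        cleavage_boundary = keep + 2L)
    out$mismatch_positions <- lapply(keep, function(i)
        .CONSENSUS_OFFSETS[mm[i, ]])
    out[, c("start", "heptamer", "n_mismatch", "mismatch_positions",
            "cleavage_boundary")]
}

## exhaustive zip extension from a fixed loop: at each (i, j) either pair,
## skip one base on one side (a bulge, while the per-side run and the total
## skip budget allow), or stop. Returns the best continuation; trailing
## skips are never charged because a skip only scores through a later pair.
.zipBest <- function(x, i, j, lmin, rmax, runL, runR, budget, maxRun, wob) {
    best <- list(score = 0, li = integer(0), ri = integer(0), skips = 0L)
    if (i < lmin || j > rmax)
        return(best)
    w <- .pairWeight(x[i], x[j], wob)
    if (w > 0) {
        sub <- .zipBest(x, i - 1L, j + 1L, lmin, rmax, 0L, 0L,
                        budget, maxRun, wob)
        cand <- list(score = w + sub$score, li = c(i, sub$li),
                     ri = c(j, sub$ri), skips = sub$skips)
        if (.contBetter(cand, best)) best <- cand
    }
    if (budget > 0L) {
        if (runL < maxRun) {
            sub <- .zipBest(x, i - 1L, j, lmin, rmax, runL + 1L, runR,
                            budget - 1L, maxRun, wob)
            if (length(sub$li)) {
                cand <- list(score = sub$score, li = sub$li, ri = sub$ri,
                             skips = sub$skips + 1L)
                if (.contBetter(cand, best)) best <- cand
            }
        }
        if (runR < maxRun) {
            sub <- .zipBest(x, i, j + 1L, lmin, rmax, runL, runR + 1L,
                            budget - 1L, maxRun, wob)
            if (length(sub$li)) {
                cand <- list(score = sub$score, li = sub$li, ri = sub$ri,
                             skips = sub$skips + 1L)
                if (.contBetter(cand, best)) best <- cand
            }
        }
    }
    best
}

.contBetter <- function(a, b) {
    if (a$score != b$score) return(a$score > b$score)
    if (length(a$li) != length(b$li)) return(length(a$li) > length(b$li))
    a$skips < b$skips
}

#' Enumerate the best hairpin enclosing a loop match
#'
#' For every candidate loop interval containing the matched heptamer (loop
#' length between 7 and `maxLoopLen`), a stem is zipped outward from the
#' loop: bases are paired one at a time, and when the next pair is invalid
#' one base on one side may be skipped (a bulge), with at most `maxBulgeRun`
#' consecutive skips per strand and at most `maxUnpaired` skips in total.
#' Pairing partners are restricted to `flankWindow` nt on either side of the
#' heptamer. All skip placements are explored, so the returned hairpin
#' attains the maximum weighted stem score over every nested single-hairpin
#' pairing honouring those constraints.
#'
#' Ties are broken by more pairs, fewer unpaired bases, shorter loop, then
#' smaller loop start.
#'
#' @param seq the normalized RNA string the match came from.
#' @param match a single-row data.frame as returned by [findLoopMatches()]
#'   (or a list with a `start` element).
#' @param config a [ScannerConfig-class].
#' @return A list with 0-based `loop_start`, `loop_end` (half-open),
#'   `pairs` (two-column 0-based index matrix, outermost pair first),
#'   `n_pairs`, `n_unpaired`, `stem_score`; or `NULL` when no pair can be
#'   formed.
#' @export
enumerateHairpin <- function(seq, match, config = scannerConfig()) {
    seq <- .asRnaString(seq)
    n <- nchar(seq)
    s0 <- as.integer(match$start)
    if (s0 < 0L || s0 + 7L > n)
        stop("match does not lie within the sequence")
    x <- strsplit(seq, "", fixed = TRUE)[[1L]]
    lmin <- max(1L, s0 - config@flankWindow + 1L)
    rmax <- min(n, s0 + 7L + config@flankWindow)
    best <- NULL
    bestKey <- NULL
    for (L in 7L:config@maxLoopLen) {
        for (ls in max(0L, s0 + 7L - L):s0) {
            le <- ls + L
            if (le > n) next
            i1 <- ls            # 1-based index of base left of the loop
            j1 <- le + 1L       # 1-based index of base right of the loop
            if (i1 < 1L || j1 > n) next
            cont <- .zipBest(x, i1, j1, lmin, rmax, 0L, 0L,
                             config@maxUnpaired, config@maxBulgeRun,
                             config@allowGUWobble)
            if (cont$score <= 0) next
            key <- c(cont$score, length(cont$li), -cont$skips, -L, -ls)
            if (is.null(bestKey) || .keyBetter(key, bestKey)) {
                bestKey <- key
                best <- list(
                    loop_start = ls, loop_end = le,
                    pairs = cbind(i = rev(cont$li) - 1L,
                                  j = rev(cont$ri) - 1L),
                    n_pairs = length(cont$li),
                    n_unpaired = cont$skips,
                    stem_score = cont$score)
            }
        }
    }
    best
}

.keyBetter <- function(a, b) {
    for (k in seq_along(a)) {
        if (a[k] > b[k]) return(TRUE)
        if (a[k] < b[k]) return(FALSE)
    }
    FALSE
}

#' Classify a loop match given its best hairpin
#'
#' A hit is canonical when its hairpin passes every structural threshold
#' (`n_pairs >= minPairs`, `n_unpaired <= maxUnpaired`,
#' `stem_score >= minStemScore`, loop length `<= maxLoopLen`); canonical
#' hits are EXACT_CANONICAL or VARIANT_CANONICAL according to the loop
#' mismatch count, and everything else is SUBPAR.
#'
#' @param match one loop match (single-row data.frame or list).
#' @param hairpin the result of [enumerateHairpin()] (may be `NULL`).
#' @param config a [ScannerConfig-class].
#' @return Category string: `"EXACT_CANONICAL"`, `"VARIANT_CANONICAL"` or
#'   `"SUBPAR"`.
#' @export
classifyHit <- function(match, hairpin, config = scannerConfig()) {
    ok <- !is.null(hairpin) &&
        hairpin$n_pairs >= config@minPairs &&
        hairpin$n_unpaired <= config@maxUnpaired &&
        hairpin$stem_score >= config@minStemScore &&
        (hairpin$loop_end - hairpin$loop_start) <= config@maxLoopLen
    if (!ok)
        return("SUBPAR")
    if (as.integer(match$n_mismatch) == 0L) "EXACT_CANONICAL"
    else "VARIANT_CANONICAL"
}

## scan one sequence; returns list(hits = data.frame, class = character)
.scanOne <- function(seq, id, config) {
    matches <- findLoopMatches(seq, config)
    cols <- c("transcript_id", "start", "heptamer", "n_mismatch", "category",
              "loop_start", "loop_end", "n_pairs", "n_unpaired",
              "stem_score", "cleavage_boundary")
    if (nrow(matches) == 0L) {
        h <- data.frame(transcript_id = character(), start = integer(),
                        heptamer = character(), n_mismatch = integer(),
                        category = character(), loop_start = integer(),
                        loop_end = integer(), n_pairs = integer(),
                        n_unpaired = integer(), stem_score = numeric(),
                        cleavage_boundary = integer())
        return(list(hits = h[, cols], class = "RIDDLE_NONE"))
    }
    rows <- lapply(seq_len(nrow(matches)), function(k) {
        m <- matches[k, ]
        hp <- enumerateHairpin(seq, m, config)
        cat <- classifyHit(m, hp, config)
        data.frame(
            transcript_id = id, start = m$start, heptamer = m$heptamer,
            n_mismatch = m$n_mismatch, category = cat,
            loop_start = if (is.null(hp)) NA_integer_ else hp$loop_start,
            loop_end = if (is.null(hp)) NA_integer_ else hp$loop_end,
            n_pairs = if (is.null(hp)) 0L else hp$n_pairs,
            n_unpaired = if (is.null(hp)) NA_integer_ else hp$n_unpaired,
            stem_score = if (is.null(hp)) 0 else hp$stem_score,
            cleavage_boundary = m$cleavage_boundary)
    })
    h <- do.call(rbind, rows)[, cols]
    cls <- if (any(h$category %in% c("EXACT_CANONICAL", "VARIANT_CANONICAL")))
        "RIDD"
    else "RIDDLE_SUBPAR"
    list(hits = h, class = cls)
}

#' Scan one transcript
#'
#' Runs the full per-transcript pipeline: loop matching, hairpin
#' enumeration, hit classification and the transcript-level call. A
#' transcript is RIDD when it carries at least one canonical hit,
#' RIDDLE_SUBPAR when it has loop matches but none canonical, and
#' RIDDLE_NONE when it has no loop match at all.
#'
#' @param seq a normalized RNA string or single-sequence object.
#' @param config a [ScannerConfig-class].
#' @param id transcript id used in the output.
#' @return A list with `hits` (data.frame, see
#'   [RiddScanResult-class]) and `transcript_class`.
#' @export
scanTranscript <- function(seq, config = scannerConfig(), id = "transcript") {
    res <- .scanOne(.asRnaString(seq), id, config)
    list(hits = res$hits, transcript_class = res$class)
}

#' Scan a set of transcripts
#'
#' @param x a named [Biostrings::RNAStringSet] (as from
#'   [readTranscripts()]) or a named character vector of sequences.
#' @param config a [ScannerConfig-class].
#' @return A [RiddScanResult-class].
#' @examples
#' seqs <- c(t1 = "GCGCGCGCUGCAGCCGCGCGC",
#'           t2 = paste(rep("A", 50), collapse = ""))
#' res <- scanTranscripts(seqs)
#' calls(res)
#' @export
scanTranscripts <- function(x, config = scannerConfig()) {
    if (is(x, "XStringSet")) {
        ids <- names(x)
        seqs <- as.character(x)
    } else {
        ids <- names(x)
        seqs <- as.character(x)
    }
    if (is.null(ids) || any(!nzchar(ids)))
        stop("all transcripts must be named")
    if (anyDuplicated(ids))
        stop("duplicate transcript ids")
    per <- lapply(seq_along(seqs), function(k)
        .scanOne(normalizeSequence(seqs[k]), ids[k], config))
    hits <- do.call(rbind, lapply(per, `[[`, "hits"))
    rownames(hits) <- NULL
    calls <- data.frame(
        transcript_id = ids,
        transcript_class = vapply(per, `[[`, "", "class"),
        n_exact = vapply(per, function(p)
            sum(p$hits$category == "EXACT_CANONICAL"), 0L),
        n_variant = vapply(per, function(p)
            sum(p$hits$category == "VARIANT_CANONICAL"), 0L),
        n_subpar = vapply(per, function(p)
            sum(p$hits$category == "SUBPAR"), 0L))
    new("RiddScanResult", hits = hits, calls = calls, config = config)
}

#' @rdname RiddScanResult-class
#' @export
setMethod("hits", "RiddScanResult", function(x) x@hits)

#' @rdname RiddScanResult-class
#' @export
setMethod("calls", "RiddScanResult", function(x) x@calls)

setMethod("show", "RiddScanResult", function(object) {
    tab <- table(factor(object@calls$transcript_class,
                        c("RIDD", "RIDDLE_SUBPAR", "RIDDLE_NONE")))
    cat("RiddScanResult:", nrow(object@calls), "transcript(s),",
        nrow(object@hits), "hit(s)\n")
    cat(sprintf("  RIDD: %d  RIDDLE_SUBPAR: %d  RIDDLE_NONE: %d\n",
                tab[1L], tab[2L], tab[3L]))
})

#' Predict fragment lengths from cleavage boundaries
#'
#' Cutting a transcript at `k` internal boundaries yields `k + 1` fragments
#' whose lengths always sum to the transcript length. For the double
#' cleavage of an XBP1u-like substrate the middle fragment is the excised
#' intron.
#'
#' @param x a transcript (string/XString) or its integer length.
#' @param boundaries strictly increasing integer cleavage boundaries,
#'   each in `1 .. length - 1` (a boundary `b` is the bond 3' of base
#'   `b - 1`, 0-based).
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @examples
#' predictFragments(876, c(500, 526))  # 5' exon, 26-nt intron, 3' exon
#' @export
predictFragments <- function(x, boundaries = integer()) {
    len <- if (is.numeric(x) && length(x) == 1L) as.integer(x)
           else nchar(.asRnaString(x))
    if (len < 1L) stop("transcript length must be positive")
    b <- as.integer(boundaries)
    if (length(b)) {
        if (any(diff(b) <= 0L))
            stop("boundaries must be strictly increasing")
        if (any(b <= 0L | b >= len))
            stop("cleavage boundary out of range: boundaries must lie in 1..",
                 len - 1L)
    }
    diff(c(0L, b, len))
}

#' Write scanner outputs as TSV (and optional BED)
#'
#' @param x a [RiddScanResult-class].
#' @param hitsPath,callsPath,bedPath output paths (`NULL` to skip). The BED
#'   track contains one single-base feature per canonical cleavage boundary
#'   (0-based half-open, transcript id as chrom).
#' @return Invisibly, `x`.
#' @export
writeScanResult <- function(x, hitsPath = NULL, callsPath = NULL,
                            bedPath = NULL) {
    stopifnot(is(x, "RiddScanResult"))
    if (!is.null(hitsPath))
        write.table(x@hits, hitsPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    if (!is.null(callsPath))
        write.table(x@calls, callsPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    if (!is.null(bedPath)) {
        h <- x@hits[x@hits$category %in%
                    c("EXACT_CANONICAL", "VARIANT_CANONICAL"), ]
        bed <- data.frame(chrom = h$transcript_id,
                          start = h$cleavage_boundary,
                          end = h$cleavage_boundary + 1L,
                          name = paste0(h$category, "_", h$start))
        write.table(bed, bedPath, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    invisible(x)
}
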