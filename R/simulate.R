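## ---- seeded synthetic-data generators --------------------------------------
## Deterministic generators emulating the statistical structure of each
## assay, so every analysis module is testable offline with known truth.

## evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()),
                    add = TRUE)
        }
        set.seed(as.integer(seed))
    }
    code
}

.RNA_BASES <- c("A", "C", "G", "U")

.randRna <- function(n) paste(sample(.RNA_BASES, n, replace = TRUE),
                              collapse = "")

.revCompRna <- function(s) chartr("ACGU", "UGCA",
                                  paste(rev(strsplit(s, "")[[1L]]),
                                        collapse = ""))

#' Describe a hairpin implant
#'
#' @param category `"EXACT"`, `"VARIANT"`, `"SUBPAR"` or `"NONE"`. EXACT
#'   and VARIANT implants are built to satisfy the default canonical
#'   thresholds; SUBPAR implants carry a consensus loop on a stem too weak
#'   to pass; NONE contributes no motif at all.
#' @param stemLen stem arm length in bp (forced to 2 for SUBPAR).
#' @param loopLen loop length in nt (>= 7; the heptamer sits at the loop
#'   5' end, padding follows it).
#' @param position 0-based start of the implant block (left stem arm), or
#'   `NA` for random placement.
#' @param gcStemFraction fraction of stem pairs that are G.C.
#' @return A classed list consumed by [simulateTranscript()].
#' @export
implantSpec <- function(category = c("EXACT", "VARIANT", "SUBPAR", "NONE"),
                        stemLen = 7L, loopLen = 7L, position = NA,
                        gcStemFraction = 0.75) {
    category <- match.arg(category)
    stemLen <- as.integer(stemLen)
    loopLen <- as.integer(loopLen)
    if (loopLen < 7L)
        stop("loopLen must be >= 7 (the consensus heptamer)")
    if (category == "SUBPAR")
        stemLen <- 2L
    if (category %in% c("EXACT", "VARIANT")) {
        nGC <- round(gcStemFraction * stemLen)
        score <- 3 * nGC + 2 * (stemLen - nGC)
        if (stemLen < 5L || score < 12)
            stop("EXACT/VARIANT implants must satisfy the canonical ",
                 "thresholds (stemLen >= 5 and weighted score >= 12)")
    }
    structure(list(category = category, stemLen = stemLen,
                   loopLen = loopLen, position = position,
                   gcStemFraction = gcStemFraction),
              class = "implantSpec")
}

## build one implant block; returns list(block, boundaryOffset)
.buildImplant <- function(spec) {
    n1 <- sample(.RNA_BASES, 1L)
    n2 <- sample(.RNA_BASES, 1L)
    hept <- c("C", n1, "G", "C", "A", "G", n2)
    if (spec$category == "VARIANT") {
        off <- sample(c(0L, 2L, 3L, 4L, 5L), 1L)
        hept[off + 1L] <- sample(setdiff(.RNA_BASES, hept[off + 1L]), 1L)
    }
    pad <- if (spec$loopLen > 7L)
        sample(.RNA_BASES, spec$loopLen - 7L, replace = TRUE)
    else character()
    loop <- paste(c(hept, pad), collapse = "")
    nGC <- round(spec$gcStemFraction * spec$stemLen)
    armBases <- sample(c(sample(c("G", "C"), nGC, replace = TRUE),
                         sample(c("A", "U"), spec$stemLen - nGC,
                                replace = TRUE)))
    arm <- paste(armBases, collapse = "")
    block <- paste0(arm, loop, .revCompRna(arm))
    ## scission after the loop's third base: block-relative boundary
    list(block = block, boundaryOffset = spec$stemLen + 3L)
}

#' Simulate a transcript with implanted endomotifs
#'
#' Generates a uniform-background random transcript carrying the requested
#' hairpin implants, then rejection-samples the background until a scan
#' under `config` reports canonical hits exactly at the implant boundaries
#' (and, for NONE-only transcripts, no loop match anywhere), so the truth
#' labels are guaranteed.
#'
#' @param length transcript length in nt.
#' @param implants list of [implantSpec()] objects.
#' @param seed RNG seed (the generator is a pure function of seed + spec).
#' @param config the [ScannerConfig-class] the truth is guaranteed against.
#' @param maxTries rejection-sampling budget.
#' @return List with `sequence` (RNA string) and `truth` (data.frame:
#'   `position`, `category`, `cleavage_boundary`, one row per non-NONE
#'   implant).
#' @export
simulateTranscript <- function(length, implants = list(implantSpec()),
                               seed = NULL, config = scannerConfig(),
                               maxTries = 1000L) {
    .withSeed(seed, {
        if (is.null(implants)) implants <- list()
        implants <- implants[vapply(implants, function(s)
            s$category != "NONE", TRUE)]
        widths <- vapply(implants, function(s)
            2L * s$stemLen + s$loopLen, 0L)
        if (sum(widths) > length)
            stop("implants do not fit within the transcript length")
        ## fix implant positions once (truth must not drift across tries)
        pos <- vapply(implants, function(s) as.integer(s$position),
                      0L)
        if (anyNA(pos)) {
            for (tries in seq_len(100L)) {
                pos2 <- pos
                free <- which(is.na(pos2))
                pos2[free] <- sort(sample.int(
                    max(1L, length - max(widths, 0L)), length(free))) - 1L
                if (!.implantsOverlap(pos2, widths, length)) {
                    pos <- pos2
                    break
                }
            }
            if (anyNA(pos) || .implantsOverlap(pos, widths, length))
                stop("could not place implants without overlap")
        } else if (.implantsOverlap(pos, widths, length)) {
            stop("implants overlap or exceed the transcript length")
        }
        truth <- data.frame(
            position = pos,
            category = vapply(implants, `[[`, "", "category"),
            cleavage_boundary = pos + vapply(implants, function(s)
                s$stemLen + 3L, 0L))
        canonical <- truth$cleavage_boundary[
            truth$category %in% c("EXACT", "VARIANT")]
        for (tries in seq_len(maxTries)) {
            built <- lapply(implants, .buildImplant)
            seq <- .assembleTranscript(length, pos, built)
            sc <- scanTranscript(seq, config)
            h <- sc$hits
            can <- h$cleavage_boundary[h$category %in%
                c("EXACT_CANONICAL", "VARIANT_CANONICAL")]
            okCanonical <- setequal(can, canonical) &&
                all(vapply(seq_len(nrow(truth)), function(k) {
                    if (truth$category[k] == "EXACT")
                        any(h$category == "EXACT_CANONICAL" &
                            h$cleavage_boundary ==
                                truth$cleavage_boundary[k])
                    else if (truth$category[k] == "VARIANT")
                        any(h$category == "VARIANT_CANONICAL" &
                            h$cleavage_boundary ==
                                truth$cleavage_boundary[k])
                    else TRUE
                }, TRUE))
            okNone <- nrow(truth) > 0L || nrow(h) == 0L
            if (okCanonical && okNone)
                return(list(sequence = seq, truth = truth))
        }
        stop("rejection sampling failed after ", maxTries, " draws")
    })
}

.implantsOverlap <- function(pos, widths, length) {
    if (!length(pos)) return(FALSE)
    o <- order(pos)
    p <- pos[o]; w <- widths[o]
    any(p + w > c(p[-1L], length))
}

.assembleTranscript <- function(length, pos, built) {
    x <- strsplit(.randRna(length), "")[[1L]]
    for (k in seq_along(built)) {
        b <- strsplit(built[[k]]$block, "")[[1L]]
        x[(pos[k] + 1L):(pos[k] + length(b))] <- b
    }
    paste(x, collapse = "")
}

#' Simulate a paired RNA-seq/GRO-seq count dataset
#'
#' Negative-binomial counts (variance `mu + dispersion * mu^2`) for a
#' 2 genotype x 2 treatment x `nRep` replicate design in both assays, with
#' three implanted gene classes:
#' \describe{
#'   \item{RIDD}{steady-state decay: mean multiplied by `2^effectLog2fc`
#'     in (RNASEQ, WT, TG8H) only — nascent transcription flat.}
#'   \item{TRANSCRIPTIONAL}{transcriptional shutdown: effect in both
#'     assays, WT TG8H only.}
#'   \item{INDEPENDENT}{IRE1-independent decay: effect in RNASEQ TG8H for
#'     both WT and KO.}
#' }
#' All remaining genes are null. Baseline means are log-normal.
#'
#' @param nGenes total genes.
#' @param nRidd,nTranscriptional,nIndependent implanted class sizes.
#' @param effectLog2fc implanted effect (log2; negative = decrease).
#' @param dispersion NB dispersion.
#' @param baselineMeanLog,baselineSdLog log-normal baseline parameters
#'   (natural log).
#' @param nRep replicates per design cell.
#' @param seed RNG seed.
#' @return List with `rna`, `gro` (count `SummarizedExperiment`s) and
#'   `truth` (data.frame `gene_id`, `class`).
#' @export
simulateCountData <- function(nGenes = 2000L, nRidd = 12L,
                              nTranscriptional = 10L, nIndependent = 10L,
                              effectLog2fc = -1.0, dispersion = 0.1,
                              baselineMeanLog = 5, baselineSdLog = 1,
                              nRep = 3L, seed = NULL) {
    if (nRidd + nTranscriptional + nIndependent > nGenes)
        stop("implanted classes exceed nGenes")
    if (dispersion <= 0)
        stop("dispersion must be positive")
    .withSeed(seed, {
        genes <- sprintf("gene_%04d", seq_len(nGenes))
        class <- rep("NULL", nGenes)
        class[seq_len(nRidd)] <- "RIDD"
        class[nRidd + seq_len(nTranscriptional)] <- "TRANSCRIPTIONAL"
        class[nRidd + nTranscriptional + seq_len(nIndependent)] <-
            "INDEPENDENT"
        mu0 <- exp(rnorm(nGenes, baselineMeanLog, baselineSdLog))
        mult <- 2^effectLog2fc
        design <- expand.grid(replicate = seq_len(nRep),
                              treatment = .TREATMENTS,
                              genotype = .GENOTYPES,
                              stringsAsFactors = FALSE)
        sim <- function(assayType) {
            m <- matrix(0L, nGenes, nrow(design))
            cn <- sprintf("%s_%s_%s_%d", assayType, design$genotype,
                          design$treatment, design$replicate)
            for (j in seq_len(nrow(design))) {
                mu <- mu0
                tg <- design$treatment[j] == "TG8H"
                wt <- design$genotype[j] == "WT"
                hit <- (class == "RIDD" & assayType == "RNASEQ" & wt & tg) |
                    (class == "TRANSCRIPTIONAL" & wt & tg) |
                    (class == "INDEPENDENT" & assayType == "RNASEQ" & tg)
                mu[hit] <- mu[hit] * mult
                m[, j] <- rnbinom(nGenes, mu = mu, size = 1 / dispersion)
            }
            dimnames(m) <- list(genes, cn)
            makeCountAssay(m, design$genotype, design$treatment,
                           design$replicate, assayType)
        }
        rna <- sim("RNASEQ")
        gro <- sim("GROSEQ")
        list(rna = rna, gro = gro,
             truth = data.frame(gene_id = genes, class = class))
    })
}

#' Simulate adapter-ligated cleavage-fragment reads
#'
#' Each read is the reference 5' portion up to a cleavage boundary (drawn
#' with the given weights) followed by the 3' adapter, with optional
#' uniform substitution errors — mimicking Sanger reads of cloned,
#' RtcB-ligated IRE1 digestion fragments.
#'
#' @param reference the reference transcript (RNA).
#' @param cutSites data.frame with columns `boundary` (internal cleavage
#'   boundaries) and `weight` (sampling weights, >= 0, not all zero).
#' @param nReads number of reads.
#' @param errorRate per-base substitution probability.
#' @param adapter adapter DNA string appended 3' of each fragment.
#' @param seed RNG seed.
#' @return List with `reads` (named character vector, DNA) and `truth`
#'   (data.frame `read_id`, `boundary`).
#' @export
simulateFragmentReads <- function(reference, cutSites, nReads = 100L,
                                  errorRate = 0, adapter = defaultAdapter(),
                                  seed = NULL) {
    refR <- .asRnaString(reference, "reference")
    refD <- chartr("U", "T", refR)
    L <- nchar(refD)
    b <- as.integer(cutSites$boundary)
    w <- as.numeric(cutSites$weight)
    if (any(b <= 0L | b >= L))
        stop("boundaries must be internal (1..length-1)")
    if (any(w < 0) || sum(w) == 0)
        stop("weights must be >= 0 and not all zero")
    .withSeed(seed, {
        pick <- sample(seq_along(b), nReads, replace = TRUE, prob = w)
        ids <- sprintf("read_%04d", seq_len(nReads))
        reads <- vapply(pick, function(k) {
            r <- paste0(substr(refD, 1L, b[k]), adapter)
            if (errorRate > 0) {
                x <- strsplit(r, "")[[1L]]
                err <- which(runif(length(x)) < errorRate)
                for (i in err)
                    x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
                r <- paste(x, collapse = "")
            }
            r
        }, "")
        names(reads) <- ids
        list(reads = reads,
             truth = data.frame(read_id = ids, boundary = b[pick]))
    })
}
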