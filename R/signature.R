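## ---- RIDD / RIDDLE gene-signature scoring ----------------------------------

#' Built-in signature gene sets
#'
#' The RIDD set contains validated endomotif-bearing decay substrates; the
#' RIDDLE set contains validated endomotif-lacking substrates.
#'
#' @return Character vector of gene symbols.
#' @export
riddGenes <- function() c("BLOC1S1", "PIGQ", "TGOLN2", "DGAT2", "WT1",
                          "GBA", "CD59", "BMP4")

#' @rdname riddGenes
#' @export
riddleGenes <- function() c("BCAM", "CCDC69", "MFAP2", "SNN", "SIX2",
                            "AIM2", "OAS2", "CFAP45", "TNFAIP8L1")

.checkStrata <- function(strata, n) {
    if (is.null(strata)) strata <- rep("all", n)
    if (length(strata) != n)
        stop("strata must have one label per sample")
    as.character(strata)
}

#' Z-score expression per gene within strata
#'
#' Standardizes each gene row to mean 0, sample (n-1) standard deviation 1,
#' independently within each stratum (e.g. disease type). Zero-variance
#' genes become all-zero rows with a warning.
#'
#' @param expr numeric matrix, genes x samples, with dimnames.
#' @param strata optional per-sample stratum labels; `NULL` treats all
#'   samples as one stratum. Every stratum needs >= 2 samples.
#' @return Matrix of Z-scores with the same dimensions.
#' @export
zscoreByGene <- function(expr, strata = NULL) {
    expr <- as.matrix(expr)
    strata <- .checkStrata(strata, ncol(expr))
    z <- expr
    flat <- character()
    for (s in unique(strata)) {
        sel <- strata == s
        if (sum(sel) < 2L)
            stop("insufficient samples in stratum '", s, "' (need >= 2)")
        sub <- expr[, sel, drop = FALSE]
        mu <- rowMeans(sub)
        sdv <- apply(sub, 1L, sd)
        zz <- (sub - mu) / sdv
        zz[sdv == 0, ] <- 0
        flat <- union(flat, rownames(expr)[sdv == 0])
        z[, sel] <- zz
    }
    if (length(flat))
        warning("zero-variance gene(s) set to Z = 0: ",
                paste(head(flat, 5L), collapse = ", "),
                if (length(flat) > 5L) " ...")
    z
}

#' Score samples against a gene signature
#'
#' Per-sample mean Z-score over the signature members present in the
#' matrix (duplicate listings count once; absent members are skipped and
#' counted), followed by a within-stratum median split: scores above the
#' stratum median are HIGH, scores at or below it are LOW.
#'
#' @param zexpr a Z-scored matrix from [zscoreByGene()].
#' @param genes signature members (e.g. [riddGenes()], [riddleGenes()]).
#' @param strata optional per-sample stratum labels (as used for
#'   Z-scoring).
#' @param minFractionPresent minimum fraction of the signature that must be
#'   present in the matrix.
#' @return data.frame: `sample`, `stratum`, `score`, `group` (HIGH/LOW),
#'   `n_genes_used`.
#' @export
scoreSamples <- function(zexpr, genes, strata = NULL,
                         minFractionPresent = 0.5) {
    zexpr <- as.matrix(zexpr)
    strata <- .checkStrata(strata, ncol(zexpr))
    genes <- unique(as.character(genes))
    if (length(genes) == 0L)
        stop("empty gene set")
    present <- intersect(genes, rownames(zexpr))
    if (length(present) < minFractionPresent * length(genes))
        stop("too few signature genes present (",
             length(present), "/", length(genes), "); missing: ",
             paste(setdiff(genes, present), collapse = ", "))
    score <- colMeans(zexpr[present, , drop = FALSE])
    group <- character(length(score))
    for (s in unique(strata)) {
        sel <- strata == s
        med <- median(score[sel])
        group[sel] <- ifelse(score[sel] > med, "HIGH", "LOW")
    }
    data.frame(sample = colnames(zexpr), stratum = strata,
               score = unname(score), group = group,
               n_genes_used = length(present))
}
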