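## ---- integrated RNA-seq / GRO-seq decay-candidate filter -------------------

.GENOTYPES  <- c("WT", "KO")
.TREATMENTS <- c("DMSO", "TG8H")

#' Assemble a count matrix with its design metadata
#'
#' Wraps a gene x sample integer count matrix and the 2x2 design
#' (genotype WT/KO, treatment DMSO/TG8H) into a
#' [SummarizedExperiment::SummarizedExperiment], the container consumed by
#' every downstream step.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames
#'   required), samples in columns (colnames required).
#' @param genotype,treatment,replicate per-sample factors/integers.
#' @param assayType `"RNASEQ"` or `"GROSEQ"`.
#' @return A `SummarizedExperiment` with assay `"counts"`,
#'   `colData(genotype, treatment, replicate)` and
#'   `metadata()$assayType`.
#' @export
makeCountAssay <- function(counts, genotype, treatment, replicate,
                           assayType = c("RNASEQ", "GROSEQ")) {
    assayType <- match.arg(assayType)
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have row (gene) and column (sample) names")
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    if (anyDuplicated(rownames(counts)))
        stop("duplicate gene ids")
    genotype <- factor(as.character(genotype), .GENOTYPES)
    treatment <- factor(as.character(treatment), .TREATMENTS)
    if (anyNA(genotype) || anyNA(treatment))
        stop("genotype must be WT/KO and treatment DMSO/TG8H")
    if (length(genotype) != ncol(counts) ||
        length(treatment) != ncol(counts))
        stop("metadata length does not match the number of samples")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = matrix(as.integer(counts),
                                      nrow = nrow(counts),
                                      dimnames = dimnames(counts))),
        colData = S4Vectors::DataFrame(genotype = genotype,
                                       treatment = treatment,
                                       replicate = as.integer(replicate)))
    S4Vectors::metadata(se)$assayType <- assayType
    se
}

.assayCounts <- function(se) {
    if (is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, "counts")
    else as.matrix(se)
}

#' TMM effective scaling factors
#'
#' Trimmed-mean-of-M-values normalization: a reference sample is chosen as
#' the one whose 75th-percentile count fraction is closest to the mean, and
#' each sample's composition factor is the weighted mean of gene-wise log2
#' ratios against it after trimming extremes of log-ratio (default 30%) and
#' of absolute expression (default 5%). The returned factors fold the
#' library size into the TMM composition factor (factor = TMM factor x
#' library size) and are normalized to multiply to 1, so dividing each
#' column by its factor places all samples on a common scale.
#'
#' @param se a count `SummarizedExperiment` (see [makeCountAssay()]) or a
#'   count matrix.
#' @param logratioTrim,absTrim trim fractions for the M-values and the
#'   absolute-expression ranks.
#' @return Named numeric vector of per-sample scaling factors (geometric
#'   mean 1).
#' @examples
#' m <- matrix(rpois(400, 50), 200, 2,
#'             dimnames = list(paste0("g", 1:200), c("a", "b")))
#' tmmNormFactors(cbind(m[, 1] * 2L, m[, 2]))
#' @export
tmmNormFactors <- function(se, logratioTrim = 0.30, absTrim = 0.05) {
    m <- .assayCounts(se)
    if (ncol(m) < 2L)
        stop("need at least 2 samples")
    if (nrow(m) < 2L)
        stop("degenerate input: need at least 2 genes to trim")
    lib <- colSums(m)
    if (any(lib == 0))
        stop("degenerate input: all-zero sample ",
             paste(colnames(m)[lib == 0], collapse = ", "))
    f <- edgeR::calcNormFactors(m, method = "TMM",
                                logratioTrim = logratioTrim,
                                sumTrim = absTrim)
    eff <- f * lib
    eff <- eff / exp(mean(log(eff)))
    setNames(eff, colnames(m))
}

#' Keep genes expressed above a CPM threshold
#'
#' Retains exactly the genes with counts-per-million above `cpmThreshold`
#' in at least `minSamples` samples. CPM is computed on raw library sizes
#' (before any TMM scaling), matching the standard pre-normalization
#' expression filter.
#'
#' @param se a count `SummarizedExperiment` or matrix.
#' @param cpmThreshold CPM cutoff (exclusive).
#' @param minSamples minimum number of samples above the cutoff.
#' @return The input subset to the kept genes (same class).
#' @export
filterExpressed <- function(se, cpmThreshold = 1.0, minSamples = 3L) {
    m <- .assayCounts(se)
    cpm <- t(t(m) / colSums(m)) * 1e6
    keep <- rowSums(cpm > cpmThreshold) >= minSamples
    se[keep, ]
}

#' Joint expression filter over the concatenated dual-assay dataset
#'
#' Applies [filterExpressed()] to the column-concatenated RNA-seq + GRO-seq
#' matrix and subsets both assays to the surviving genes, so the two
#' datasets stay gene-matched.
#'
#' @param rna,gro count `SummarizedExperiment`s sharing the same genes.
#' @inheritParams filterExpressed
#' @return List with elements `rna` and `gro`.
#' @export
filterExpressedJoint <- function(rna, gro, cpmThreshold = 1.0,
                                 minSamples = 3L) {
    mr <- .assayCounts(rna); mg <- .assayCounts(gro)
    if (!identical(rownames(mr), rownames(mg)))
        stop("rna and gro must share the same genes in the same order")
    m <- cbind(mr, mg)
    cpm <- t(t(m) / colSums(m)) * 1e6
    keep <- rowSums(cpm > cpmThreshold) >= minSamples
    list(rna = rna[keep, ], gro = gro[keep, ])
}

## log2 CPM on TMM effective library sizes with a prior count
.logCpm <- function(m, priorCount = 0.5) {
    f <- edgeR::calcNormFactors(m, method = "TMM")
    edgeR::cpm(edgeR::DGEList(counts = m, norm.factors = f),
               log = TRUE, prior.count = priorCount)
}

## limma-style scaled-F moments fit of gene-wise variances: estimates the
## prior df d0 and prior variance s0^2 from the distribution of log s^2
.fitFDistMoments <- function(s2, df) {
    ok <- is.finite(s2) & s2 > 0
    if (sum(ok) < 2L)
        return(list(df.prior = Inf,
                    var.prior = if (any(ok)) mean(s2[ok]) else 1))
    z <- log(s2[ok])
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- var(e) - trigamma(df / 2)
    if (is.na(evar) || evar <= 0)
        return(list(df.prior = Inf, var.prior = exp(mean(e))))
    d0 <- 2 * .trigammaInverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    list(df.prior = d0, var.prior = s0)
}

## Newton solve of trigamma(x) = y on x > 0
.trigammaInverse <- function(y) {
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (iter in 1:50) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
        x <- x + dif
        if (-dif / x < 1e-8) break
    }
    x
}

## two-group (TG8H vs DMSO) log2FC and pooled variance for one stratum
.strataContrast <- function(lcpm, treatment) {
    tg <- treatment == "TG8H"; dm <- treatment == "DMSO"
    n1 <- sum(tg); n2 <- sum(dm)
    fc <- rowMeans(lcpm[, tg, drop = FALSE]) -
          rowMeans(lcpm[, dm, drop = FALSE])
    v1 <- apply(lcpm[, tg, drop = FALSE], 1L, var)
    v2 <- apply(lcpm[, dm, drop = FALSE], 1L, var)
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    list(fc = fc, s2 = s2, df = n1 + n2 - 2, n1 = n1, n2 = n2)
}

#' Differential statistics for the dual-assay contrast set
#'
#' Computes, per gene, the TG8H-vs-DMSO log2 fold change in each of the
#' four strata (WT/KO x RNA-seq/GRO-seq) on prior-count-stabilized log-CPM,
#' plus a two-sided moderated t-test p-value for the WT RNA-seq contrast
#' (empirical-Bayes variance shrinkage towards a scaled-F prior estimated
#' by the method of moments), its BH FDR, and the grand-mean log-CPM across
#' all samples of both assays. With `moderate = FALSE` an ordinary pooled
#' two-sample t-test is used instead; genes with zero variance then get
#' p = 1 and `degenerate = TRUE`.
#'
#' All fold changes are TG8H relative to DMSO, so decay shows as negative
#' values.
#'
#' @param rna,gro gene-matched count `SummarizedExperiment`s (see
#'   [makeCountAssay()]); every (genotype, treatment) cell needs >= 2
#'   replicates.
#' @param priorCount prior count for the log-CPM transform.
#' @param moderate use empirical-Bayes variance moderation.
#' @return data.frame with columns `gene_id`, `log2fc_wt_rna`, `p_wt_rna`,
#'   `fdr_wt_rna`, `log2fc_ko_rna`, `log2fc_wt_gro`, `log2fc_ko_gro`,
#'   `avg_expr`, `degenerate`.
#' @export
deStats <- function(rna, gro, priorCount = 0.5, moderate = TRUE) {
    if (!identical(rownames(rna), rownames(gro)))
        stop("rna and gro must share the same genes in the same order")
    pieces <- list(RNASEQ = rna, GROSEQ = gro)
    lcpms <- list()
    contrasts <- list()
    for (asy in names(pieces)) {
        se <- pieces[[asy]]
        cd <- SummarizedExperiment::colData(se)
        m <- .assayCounts(se)
        for (g in .GENOTYPES) for (tr in .TREATMENTS) {
            nrep <- sum(cd$genotype == g & cd$treatment == tr)
            if (nrep < 2L)
                stop(sprintf(
                    "insufficient replication in stratum (%s, %s, %s): %d",
                    asy, g, tr, nrep))
        }
        lcpm <- .logCpm(m, priorCount)
        lcpms[[asy]] <- lcpm
        for (g in .GENOTYPES) {
            sel <- cd$genotype == g
            contrasts[[paste(g, asy, sep = "_")]] <-
                .strataContrast(lcpm[, sel, drop = FALSE],
                                cd$treatment[sel])
        }
    }
    wt <- contrasts[["WT_RNASEQ"]]
    degenerate <- !is.finite(wt$s2) | wt$s2 == 0
    if (moderate) {
        fit <- .fitFDistMoments(wt$s2, wt$df)
        if (is.finite(fit$df.prior)) {
            s2post <- (fit$df.prior * fit$var.prior + wt$df * wt$s2) /
                (fit$df.prior + wt$df)
            dfTotal <- wt$df + fit$df.prior
        } else {
            s2post <- rep(fit$var.prior, length(wt$s2))
            dfTotal <- Inf
        }
        tstat <- wt$fc / sqrt(s2post * (1 / wt$n1 + 1 / wt$n2))
        p <- 2 * pt(-abs(tstat), dfTotal)
        degenerate <- degenerate & s2post == 0
    } else {
        se2 <- wt$s2 * (1 / wt$n1 + 1 / wt$n2)
        tstat <- ifelse(se2 > 0, wt$fc / sqrt(se2), NA_real_)
        p <- ifelse(is.na(tstat), 1, 2 * pt(-abs(tstat), wt$df))
    }
    p[!is.finite(p)] <- 1
    avg <- rowMeans(cbind(lcpms$RNASEQ, lcpms$GROSEQ))
    data.frame(
        gene_id = rownames(rna),
        log2fc_wt_rna = unname(wt$fc),
        p_wt_rna = unname(p),
        fdr_wt_rna = bhFdr(unname(p)),
        log2fc_ko_rna = unname(contrasts[["KO_RNASEQ"]]$fc),
        log2fc_wt_gro = unname(contrasts[["WT_GROSEQ"]]$fc),
        log2fc_ko_gro = unname(contrasts[["KO_GROSEQ"]]$fc),
        avg_expr = unname(avg),
        degenerate = unname(degenerate))
}

#' Benjamini-Hochberg step-up FDR
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return q-values in the original order; elementwise `q >= p`.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFdr <- function(pvals) {
    if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvals, method = "BH")
}

#' Apply the decay-candidate filter chain
#'
#' Retains genes passing every enabled criterion:
#' \enumerate{
#'   \item significance: `p_wt_rna <= sigAlpha` and `fdr_wt_rna <= sigAlpha`;
#'   \item IRE1 dependence: `log2fc_ko_rna - log2fc_wt_rna >= minKoMinusWt`;
#'   \item expression: `avg_expr >= minAvgExpr`;
#'   \item decay vs transcription: by default keeps
#'     `log2fc_wt_rna - log2fc_wt_gro <= rnaMinusGroCut` (steady-state RNA
#'     falls below nascent transcription, the biological direction);
#'     `literalSignMode = TRUE` keeps `>= rnaMinusGroCut` instead,
#'     reproducing the literal removal sentence of the source protocol;
#'   \item fold change (optional): `log2fc_wt_rna <= -log2(wtFoldCut)`.
#' }
#'
#' @param stats a data.frame as returned by [deStats()] (or read from a
#'   precomputed TSV with the same columns).
#' @param sigAlpha significance level for p and FDR.
#' @param minKoMinusWt minimum KO-minus-WT log2FC difference.
#' @param minAvgExpr minimum grand-mean log-CPM.
#' @param rnaMinusGroCut cut on `log2fc_wt_rna - log2fc_wt_gro`.
#' @param wtFoldCut minimum WT RNA-seq fold decrease (linear scale).
#' @param useFoldCriterion enable criterion 5.
#' @param literalSignMode flip the direction of criterion 4 (see above).
#' @return List with `flags` (per-gene data.frame of `pass_*` logicals) and
#'   `survivors` (character vector of gene ids passing all enabled
#'   criteria).
#' @export
applyFilterChain <- function(stats, sigAlpha = 0.05, minKoMinusWt = 0.5,
                             minAvgExpr = 1.0, rnaMinusGroCut = -0.3,
                             wtFoldCut = 1.4, useFoldCriterion = TRUE,
                             literalSignMode = FALSE) {
    need <- c("gene_id", "log2fc_wt_rna", "p_wt_rna", "fdr_wt_rna",
              "log2fc_ko_rna", "log2fc_wt_gro", "avg_expr")
    miss <- setdiff(need, colnames(stats))
    if (length(miss))
        stop("incomplete stats: missing column(s) ",
             paste(miss, collapse = ", "))
    num <- stats[, setdiff(need, "gene_id")]
    if (anyNA(num))
        stop("incomplete stats: NA values for gene(s) ",
             paste(head(stats$gene_id[rowSums(is.na(num)) > 0], 5L),
                   collapse = ", "))
    if (wtFoldCut <= 1)
        stop("wtFoldCut must exceed 1")
    rnaGro <- stats$log2fc_wt_rna - stats$log2fc_wt_gro
    flags <- data.frame(
        gene_id = stats$gene_id,
        pass_sig = stats$p_wt_rna <= sigAlpha & stats$fdr_wt_rna <= sigAlpha,
        pass_ko_wt = stats$log2fc_ko_rna - stats$log2fc_wt_rna >=
            minKoMinusWt,
        pass_avg_expr = stats$avg_expr >= minAvgExpr,
        pass_rna_gro = if (literalSignMode) rnaGro >= rnaMinusGroCut
                       else rnaGro <= rnaMinusGroCut,
        pass_fold = stats$log2fc_wt_rna <= -log2(wtFoldCut))
    enabled <- c("pass_sig", "pass_ko_wt", "pass_avg_expr", "pass_rna_gro",
                 if (useFoldCriterion) "pass_fold")
    ok <- Reduce(`&`, flags[enabled])
    list(flags = flags, survivors = stats$gene_id[ok])
}

#' Read a count TSV plus sample metadata TSV into count assays
#'
#' The counts TSV has a gene-id column followed by one column per sample;
#' the metadata TSV has columns `sample`, `assay` (RNASEQ/GROSEQ),
#' `genotype`, `treatment`, `replicate`.
#'
#' @param countsPath,metaPath file paths.
#' @return A list of `SummarizedExperiment`s, one per assay present.
#' @export
readCountAssays <- function(countsPath, metaPath) {
    cnt <- read.delim(countsPath, check.names = FALSE)
    meta <- read.delim(metaPath)
    m <- as.matrix(cnt[, -1L, drop = FALSE])
    rownames(m) <- cnt[[1L]]
    out <- list()
    for (asy in unique(meta$assay)) {
        mi <- meta[meta$assay == asy & meta$sample %in% colnames(m), ]
        if (nrow(mi) == 0L) next
        out[[asy]] <- makeCountAssay(m[, mi$sample, drop = FALSE],
                                     mi$genotype, mi$treatment,
                                     mi$replicate, assayType = asy)
    }
    out
}
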