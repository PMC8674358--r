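## small matched design used across tests: 2 genotypes x 2 treatments x n reps
makeSE <- function(counts, assayType = "RNASEQ", nRep = 3) {
    design <- expand.grid(replicate = seq_len(nRep),
                          treatment = c("DMSO", "TG8H"),
                          genotype = c("WT", "KO"),
                          stringsAsFactors = FALSE)
    colnames(counts) <- sprintf("%s_%s_%s_%d", assayType, design$genotype,
                                design$treatment, design$replicate)
    makeCountAssay(counts, design$genotype, design$treatment,
                   design$replicate, assayType)
}

test_that("TMM effective factors satisfy the closed-form identities", {
    set.seed(41)
    base <- matrix(rpois(1000, 60), 500, 2,
                   dimnames = list(paste0("g", 1:500), c("a", "b")))
    same <- cbind(a = base[, 1], b = base[, 1])
    expect_equal(unname(tmmNormFactors(same)), c(1, 1), tolerance = 1e-12)

    doubled <- cbind(a = 2L * base[, 1], b = base[, 1])
    expect_equal(unname(tmmNormFactors(doubled)),
                 c(sqrt(2), 1 / sqrt(2)), tolerance = 1e-6)
    ## factors multiply to 1
    expect_equal(prod(tmmNormFactors(base)), 1, tolerance = 1e-12)

    one <- matrix(c(5L, 9L), 1, 2,
                  dimnames = list("g1", c("a", "b")))
    expect_error(tmmNormFactors(one), "degenerate")
    zero <- base; zero[, 2] <- 0L
    expect_error(tmmNormFactors(zero), "all-zero sample")
})

test_that("expression filter keeps genes by CPM in enough samples", {
    ## library size exactly 1e7 so CPM == count / 10
    n <- 12L
    m <- rbind(g_hi3 = c(rep(11L, 3), rep(0L, n - 3)),  # CPM 1.1 in 3 samples
               g_low = rep(9L, n),                      # CPM 0.9 everywhere
               g_two = c(rep(50L, 2), rep(0L, n - 2)))  # CPM 5.0 in 2 samples
    m <- rbind(m, filler = 1e7L - colSums(m))
    colnames(m) <- paste0("s", seq_len(n))
    kept <- rownames(filterExpressed(m, cpmThreshold = 1.0, minSamples = 3))
    expect_true("g_hi3" %in% kept)
    expect_false("g_low" %in% kept)
    expect_false("g_two" %in% kept)
})

test_that("deStats: null genes give fc 0 and p 1; strata are validated", {
    set.seed(42)
    nRep <- 3L
    base <- matrix(rpois(200 * 12, 100), 200, 12,
                   dimnames = list(sprintf("g%03d", 1:200), NULL))
    ## make every sample identical so all contrasts are exactly null
    ident <- matrix(rep(base[, 1], 12), 200, 12,
                    dimnames = dimnames(base))
    rna <- makeSE(ident); gro <- makeSE(ident, "GROSEQ")
    st <- deStats(rna, gro)
    expect_equal(st$log2fc_wt_rna, rep(0, 200), tolerance = 1e-10)
    expect_equal(st$log2fc_wt_gro, rep(0, 200), tolerance = 1e-10)
    expect_true(all(st$p_wt_rna > 1 - 1e-8))
    expect_true(all(st$fdr_wt_rna >= st$p_wt_rna - 1e-12))

    ## degenerate policy without moderation
    st2 <- deStats(rna, gro, moderate = FALSE)
    expect_true(all(st2$p_wt_rna == 1))
    expect_true(all(st2$degenerate))

    ## a stratum with < 2 replicates errors by name
    bad <- makeSE(base[, c(1, 1:11)], nRep = 3)
    SummarizedExperiment::colData(bad)$treatment[1:2] <- "TG8H"
    expect_error(deStats(bad, gro), "insufficient replication")
})

test_that("deStats recovers an implanted 2-fold decrease", {
    ## 100 genes carry a true -1 log2FC in (WT, TG8H, RNASEQ); with low
    ## biological dispersion the estimate lands within +/-0.3 of -1 for
    ## at least 95% of them
    sim <- simulateCountData(nGenes = 2000, nRidd = 100,
                             nTranscriptional = 0, nIndependent = 0,
                             dispersion = 0.005, baselineMeanLog = 6.5,
                             seed = 43)
    st <- deStats(sim$rna, sim$gro)
    ridd <- st$gene_id %in%
        sim$truth$gene_id[sim$truth$class == "RIDD"]
    frac <- mean(abs(st$log2fc_wt_rna[ridd] - (-1)) <= 0.3)
    expect_gte(frac, 0.95)
    ## null genes center on zero
    expect_lt(abs(mean(st$log2fc_wt_rna[!ridd])), 0.1)
})

test_that("variance moderation matches the limma moments fit", {
    skip_if_not_installed("limma")
    set.seed(44)
    s2 <- 0.05 * stats::rf(2000, 4, 10)
    fit <- riddscan:::.fitFDistMoments(s2, 4)
    ref <- limma::fitFDist(s2, df1 = 4)
    expect_equal(fit$var.prior, ref$scale, tolerance = 1e-6)
    expect_equal(fit$df.prior, ref$df2, tolerance = 1e-6)
    for (y in c(0.01, 0.5, 2, 20))
        expect_equal(riddscan:::.trigammaInverse(y),
                     limma::trigammaInverse(y), tolerance = 1e-6)
})

test_that("BH step-up matches the hand computation and its invariants", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(1.0), 1.0)
    expect_equal(bhFdr(c(0.5, 0.5)), c(0.5, 0.5))
    expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")

    set.seed(45)
    for (r in 1:10) {
        p <- runif(sample(5:50, 1))
        q <- bhFdr(p)
        expect_equal(q, oracleBH(p))
        expect_true(all(q >= p))
        expect_true(all(q <= 1))
        perm <- sample(length(p))
        expect_equal(bhFdr(p[perm]), q[perm])
        ## monotone in p ranks
        expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
})

test_that("filter chain applies each criterion as specified", {
    stats <- data.frame(
        gene_id = c("geneA", "geneB", "geneC"),
        log2fc_wt_rna = c(-1.0, -1.0, -1.0),
        p_wt_rna = c(0.01, 0.2, 0.01),
        fdr_wt_rna = c(0.03, 0.3, 0.03),
        log2fc_ko_rna = c(0.0, 0.0, -0.9),
        log2fc_wt_gro = c(-0.1, -0.1, -0.1),
        log2fc_ko_gro = 0,
        avg_expr = 5.0)
    fr <- applyFilterChain(stats)
    expect_identical(fr$survivors, "geneA")
    expect_false(fr$flags$pass_sig[2])
    expect_false(fr$flags$pass_ko_wt[3])
    ## per-criterion flags populated for every gene
    expect_true(all(!is.na(as.matrix(fr$flags[, -1]))))

    ## literal sign mode flips criterion 4
    litStats <- stats[1, ]
    litStats$log2fc_wt_gro <- -2.0   # rna - gro = +1.0
    expect_length(applyFilterChain(litStats)$survivors, 0)
    expect_identical(
        applyFilterChain(litStats, literalSignMode = TRUE)$survivors,
        "geneA")

    ## fold criterion can be disabled
    mild <- stats[1, ]
    mild$log2fc_wt_rna <- -0.4      # fails 1.4-fold, passes the rest
    mild$log2fc_ko_rna <- 0.2       # keep KO-WT = 0.6 above the cut
    expect_length(applyFilterChain(mild)$survivors, 0)
    expect_identical(
        applyFilterChain(mild, useFoldCriterion = FALSE)$survivors, "geneA")

    expect_error(applyFilterChain(stats[, -3]), "incomplete stats")
})

test_that("filter chain is monotone and order-independent", {
    set.seed(46)
    stats <- data.frame(
        gene_id = sprintf("g%03d", 1:300),
        log2fc_wt_rna = rnorm(300, -0.5, 1),
        p_wt_rna = runif(300)^2)
    stats$fdr_wt_rna <- pmin(1, stats$p_wt_rna * 2)
    stats$log2fc_ko_rna <- rnorm(300, 0, 0.5)
    stats$log2fc_wt_gro <- rnorm(300, 0, 0.5)
    stats$log2fc_ko_gro <- rnorm(300, 0, 0.5)
    stats$avg_expr <- rnorm(300, 3, 2)
    base <- applyFilterChain(stats)
    ## survivors = intersection of per-criterion pass sets
    f <- base$flags
    expect_setequal(base$survivors,
                    f$gene_id[f$pass_sig & f$pass_ko_wt & f$pass_avg_expr &
                              f$pass_rna_gro & f$pass_fold])
    tighter <- list(
        applyFilterChain(stats, sigAlpha = 0.01),
        applyFilterChain(stats, minKoMinusWt = 1.0),
        applyFilterChain(stats, minAvgExpr = 3),
        applyFilterChain(stats, rnaMinusGroCut = -0.6),
        applyFilterChain(stats, wtFoldCut = 2))
    for (t in tighter) {
        expect_lte(length(t$survivors), length(base$survivors))
        expect_true(all(t$survivors %in% base$survivors))
    }
})

test_that("filter chain recovers implanted decay genes (low dispersion)", {
    ## mechanics check under dispersion where the moderated t has power:
    ## survivors should be exactly the RIDD implants, with the
    ## transcriptional and IRE1-independent implants removed by the
    ## nascent-transcription and KO-WT criteria respectively
    sim <- simulateCountData(nGenes = 1000, nRidd = 12,
                             nTranscriptional = 10, nIndependent = 10,
                             dispersion = 0.002, baselineMeanLog = 7,
                             baselineSdLog = 0.5, seed = 47)
    st <- deStats(sim$rna, sim$gro)
    fr <- applyFilterChain(st)
    truthRidd <- sim$truth$gene_id[sim$truth$class == "RIDD"]
    expect_setequal(fr$survivors, truthRidd)
})
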