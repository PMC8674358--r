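## Independent exhaustive-search oracle for the maximum weighted stem score
## of a single nested hairpin around a consensus loop match. Formulated as
## a memoized recursion over the *next outward pair* (enumerating both gap
## sizes directly), unlike the scanner's step-wise zip extension.

oraclePairWeight <- function(a, b, allowGU = TRUE) {
    p <- paste(sort(c(a, b)), collapse = "")
    if (p == "CG") return(3)
    if (p == "AU") return(2)
    if (allowGU && p == "GU") return(1)
    0
}

## maximum stem score over all nested pairings for one fixed loop [ls, le)
## (0-based, within seq), honouring flankWindow / maxUnpaired / maxBulgeRun
oracleLoopScore <- function(x, ls, le, s0, cfg) {
    n <- length(x)
    lmin <- max(1L, s0 - cfg@flankWindow + 1L)
    rmax <- min(n, s0 + 7L + cfg@flankWindow)
    memo <- new.env(parent = emptyenv())
    rec <- function(i, j, budget) {
        if (i < lmin || j > rmax) return(0)
        key <- paste(i, j, budget)
        if (!is.null(memo[[key]])) return(memo[[key]])
        best <- 0
        for (gi in 0:min(cfg@maxBulgeRun, budget)) {
            a <- i - gi
            if (a < lmin) break
            for (gj in 0:min(cfg@maxBulgeRun, budget - gi)) {
                b <- j + gj
                if (b > rmax) break
                w <- oraclePairWeight(x[a], x[b], cfg@allowGUWobble)
                if (w > 0) {
                    cand <- w + rec(a - 1L, b + 1L, budget - gi - gj)
                    if (cand > best) best <- cand
                }
            }
        }
        memo[[key]] <- best
        best
    }
    rec(ls, le + 1L, cfg@maxUnpaired)
}

## best score over all candidate loops containing the heptamer at s0
oracleStemScore <- function(seq, s0, cfg = scannerConfig()) {
    x <- strsplit(seq, "", fixed = TRUE)[[1L]]
    n <- length(x)
    best <- 0
    for (L in 7L:cfg@maxLoopLen) {
        for (ls in max(0L, s0 + 7L - L):s0) {
            le <- ls + L
            if (le > n || ls < 1L || le >= n) next
            sc <- oracleLoopScore(x, ls, le, s0, cfg)
            if (sc > best) best <- sc
        }
    }
    best
}

## hand BH step-up, independent of p.adjust, for cross-checks
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- pmin(1, p[o] * m / seq_len(m))
    q <- rev(cummin(rev(q)))
    out <- numeric(m)
    out[o] <- q
    out
}

randomRna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")
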