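test_that("adapter trimming finds the seed and returns the prefix", {
    ad <- defaultAdapter()
    tr <- trimAdapter(c(r1 = paste0("AAGTT", ad)))
    expect_identical(tr$fragment, "AAGTT")
    expect_identical(tr$status, "OK")

    none <- trimAdapter(c(r1 = "ACGTACGTACGTACGTACGT"))
    expect_identical(none$status, "NO_ADAPTER")
    expect_true(is.na(none$fragment))

    ## one mismatch inside the 12-nt seed is still trimmed
    mm <- ad
    substr(mm, 3, 3) <- "T"
    tr2 <- trimAdapter(c(r1 = paste0("GGCCAAT", mm)))
    expect_identical(tr2$fragment, "GGCCAAT")
    expect_identical(tr2$status, "OK")

    ## read that is all adapter
    tr3 <- trimAdapter(c(r1 = ad))
    expect_identical(tr3$status, "EMPTY_FRAGMENT")
})

test_that("3' end mapping follows the hand-checked examples", {
    ref <- "AAGCAAGCAA"
    hit <- mapEnd("AAGCAAG", ref)
    expect_identical(hit$status, "OK")
    expect_equal(hit$end_pos, 6L)
    expect_identical(c(hit$last_nt, hit$next_nt), c("G", "C"))
    expect_true(hit$is_gc)

    expect_identical(mapEnd("TTTT", ref)$status, "NO_MATCH")
    expect_identical(mapEnd("AAGCAAGCAA", ref)$status,
                     "AT_3PRIME_TERMINUS")
    ## repeated short fragment has two equal-best end positions
    expect_identical(mapEnd("AAGC", ref)$status, "AMBIGUOUS")
})

test_that("error-free prefix reads round-trip through trim + map", {
    set.seed(61)
    ref <- randomRna(300)
    sim <- simulateFragmentReads(ref,
                                 data.frame(boundary = c(60, 150, 151, 260),
                                            weight = c(1, 2, 1, 1)),
                                 nReads = 60, seed = 62)
    ends <- mapFragmentEnds(sim$reads, ref, refId = "ref")
    expect_true(all(ends$status == "OK"))
    expect_equal(ends$end_pos, sim$truth$boundary - 1L)
    ## statuses partition the read set and counts add up
    prof <- tallyProfile(ends, ref)
    expect_equal(sum(endCounts(prof)), sum(ends$status == "OK"))
    expect_equal(nMapped(prof), 60L)
})

test_that("reads with substitution errors still map within identity", {
    set.seed(63)
    ref <- randomRna(500)
    sim <- simulateFragmentReads(ref, data.frame(boundary = 200, weight = 1),
                                 nReads = 20, errorRate = 0.01, seed = 64)
    ends <- mapFragmentEnds(sim$reads, ref, refId = "ref")
    okk <- ends$status == "OK"
    expect_gte(mean(okk), 0.9)
    expect_true(all(ends$end_pos[okk] == 199L))
})

test_that("profiles tally GC ends and call hotspots", {
    ## construct a reference with known GC positions and exact per-site
    ## read counts
    set.seed(65)
    ref <- randomRna(400)
    x <- strsplit(ref, "")[[1]]
    gcPos <- which(x[-length(x)] == "G" & x[-1] == "C") - 1L  # 0-based
    gcPos <- gcPos[gcPos > 50 & gcPos < 350]
    nonGc <- setdiff(51:349, c(gcPos, gcPos + 1L, gcPos - 1L))
    s1 <- gcPos[1]; s2 <- gcPos[2]; other <- nonGc[1]
    mkReads <- function(pos, n, tag)
        setNames(rep(paste0(chartr("U", "T", substr(ref, 1, pos + 1)),
                            defaultAdapter()), n),
                 paste0(tag, seq_len(n)))
    reads <- c(mkReads(s1, 10, "a"), mkReads(s2, 5, "b"),
               mkReads(other, 2, "c"))
    ends <- mapFragmentEnds(reads, ref, refId = "ref")
    prof <- tallyProfile(ends, ref)
    expect_equal(nMapped(prof), 17L)
    expect_equal(prof@nGC, 15L)
    expect_equal(gcFraction(prof), 15 / 17)
    hs <- hotspots(prof)
    expect_equal(hs$end_pos, c(s1, s2))
    expect_equal(hs$count, c(10L, 5L))
    expect_true(all(hs$is_gc))

    ## single-position pile-up is a single hotspot
    prof1 <- tallyProfile(mapFragmentEnds(mkReads(s1, 10, "z"), ref,
                                          refId = "ref"), ref)
    expect_equal(nrow(hotspots(prof1)), 1L)
    expect_equal(hotspots(prof1)$count, 10L)

    ## empty OK set is a warning, not an error
    noAd <- data.frame(read_id = "r", ref_id = "ref", status = "NO_ADAPTER",
                       end_pos = NA_integer_, last_nt = NA_character_,
                       next_nt = NA_character_, is_gc = NA)
    expect_warning(p0 <- tallyProfile(noAd, ref), "undefined")
    expect_true(is.na(gcFraction(p0)))

    ## mixed references are rejected
    mixed <- ends; mixed$ref_id[1] <- "other"
    expect_error(tallyProfile(mixed, ref), "mixed")
})

test_that("mutating a hotspot GC to UA flips is_gc without moving ends", {
    set.seed(66)
    ref <- randomRna(300)
    x <- strsplit(ref, "")[[1]]
    gcPos <- which(x[-length(x)] == "G" & x[-1] == "C") - 1L
    s1 <- gcPos[gcPos > 100 & gcPos < 250][1]
    reads <- setNames(rep(paste0(chartr("U", "T", substr(ref, 1, s1 + 1)),
                                 defaultAdapter()), 5),
                      paste0("r", 1:5))
    before <- mapFragmentEnds(reads, ref, refId = "ref")
    y <- x; y[s1 + 1] <- "U"; y[s1 + 2] <- "A"
    mutRef <- paste(y, collapse = "")
    after <- mapFragmentEnds(reads, mutRef, refId = "ref")
    expect_true(all(before$is_gc))
    expect_true(all(after$status == "OK"))
    expect_equal(after$end_pos, before$end_pos)
    expect_false(any(after$is_gc))
})

test_that("GC enrichment uses the exact binomial against background", {
    ## all-GC ends against background 0.1: two-sided tail is p^10
    prof <- new("CleavageProfile", refId = "ref",
                endCounts = setNames(10L, "5"), nMapped = 10L, nGC = 10L,
                gcFraction = 1, hotspots = data.frame(), hotspotMin = 3L)
    ## reference engineered to background_p = 0.1: 40 positions, 4 GC
    ref <- paste0(strrep("GCAAAAAAAA", 4), "A")
    en <- gcEnrichment(prof, ref)
    expect_equal(en$background_p, 0.1)
    expect_equal(en$p_value, 0.1^10, tolerance = 1e-6)

    ## observed fraction equal to background is central
    prof2 <- new("CleavageProfile", refId = "ref",
                 endCounts = setNames(10L, "5"), nMapped = 10L, nGC = 1L,
                 gcFraction = 0.1, hotspots = data.frame(), hotspotMin = 3L)
    expect_gte(gcEnrichment(prof2, ref)$p_value, 0.5)

    ## p decreases monotonically in n_gc
    ps <- vapply(0:10, function(g) {
        pr <- new("CleavageProfile", refId = "ref",
                  endCounts = setNames(10L, "5"), nMapped = 10L,
                  nGC = as.integer(g), gcFraction = g / 10,
                  hotspots = data.frame(), hotspotMin = 3L)
        gcEnrichment(pr, ref)$p_value
    }, 0)
    expect_true(all(diff(ps[2:11]) < 1e-12))

    ## degenerate background
    expect_warning(en0 <- gcEnrichment(prof, strrep("A", 50)), "degenerate")
    expect_equal(en0$p_value, 0)
})
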