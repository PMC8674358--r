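# riddscan

Tools for the two endoribonuclease modalities of IRE1α, the
endoplasmic-reticulum stress sensor of the unfolded-protein response.

IRE1α cleaves RNA in two ways. **RIDD** (regulated IRE1-dependent decay)
is precise: it requires a stem-loop *endomotif* whose loop carries the
7-nt consensus `CNG|CAGN`, with scission between the loop's third (G) and
fourth (C) nucleotides — the same chemistry that excises the 26-nt intron
of XBP1u mRNA. **RIDDLE** (RIDD lacking endomotif) is promiscuous:
phospho-oligomeric IRE1α degrades transcripts without any canonical
motif, preferentially cutting at G·C dinucleotide steps.

`riddscan` is for RNA biologists and computational groups studying this
system. It provides:

* **Endomotif scanning** — locate consensus loops, enumerate the best
  enclosing hairpin within a 60-nt flanking window (weighted pairing
  G·C = 3, A·U = 2, G·U = 1, bounded bulges), and classify hits
  (`EXACT_CANONICAL` / `VARIANT_CANONICAL` / `SUBPAR`) and transcripts
  (`RIDD` / `RIDDLE_SUBPAR` / `RIDDLE_NONE`).
* **Decay-candidate filtering** — the integrated steady-state (RNA-seq)
  vs nascent (GRO-seq) analysis: CPM expression filter, TMM
  normalization, moderated t-statistics, and the four-criterion chain
  (significance; KO−WT ≥ 0.5; mean expression ≥ 1; steady-state falling
  ≥ 0.3 log2 below nascent; optional 1.4-fold cut).
* **Cleavage-fragment mapping** — trim the 3′ ligation adapter from
  Sanger reads, map each fragment's 3′ end by semiglobal alignment, tally
  cleavage dinucleotides, call hotspots, and test GC-site enrichment
  with an exact binomial test.
* **Signature scoring** — per-sample mean Z-scores over the validated
  RIDD and RIDDLE gene sets with within-stratum median splits.
* **Seeded simulators** for all three input types, with guaranteed truth
  labels (implanted hairpins, implanted decay/transcription effects,
  chosen cleavage sites).

Coordinates are 0-based half-open throughout; a cleavage boundary *b* is
the bond between bases *b* − 1 and *b*.

## Worked example

```r
library(riddscan)

tx <- c(XBP1_probe = "CAUGUCCGCAGCGCAUG",        # 17-nt stem-loop probe
        stemloop   = "GCGCGCGCUGCAGCCGCGCGC",    # perfect 7-bp hairpin
        polyA      = paste(rep("A", 40), collapse = ""))
res <- scanTranscripts(tx)
calls(res)
#>   transcript_id transcript_class n_exact n_variant n_subpar
#> 1    XBP1_probe    RIDDLE_SUBPAR       0         0        1
#> 2      stemloop             RIDD       1         0        1
#> 3         polyA      RIDDLE_NONE       0         0        0

hits(res)[, c("transcript_id", "start", "heptamer", "category",
              "n_pairs", "stem_score", "cleavage_boundary")]
#>   transcript_id start heptamer        category n_pairs stem_score cleavage_boundary
#> 1    XBP1_probe     5  CCGCAGC          SUBPAR       5         11                 8
#> 2      stemloop     7  CUGCAGC EXACT_CANONICAL       7         21                10
#> 3      stemloop    10  CAGCCGC          SUBPAR       4         12                13
```

The probe's consensus loop is found at 0-based position 5 with its
scission boundary at 8 (between the G and C of `CCG|CAGC`); in a 17-nt
probe there is not enough flank to build a canonical stem, so the hit is
`SUBPAR`. The constructed hairpin transcript carries an exact canonical
endomotif (7 pairs, stem score 21) and is called `RIDD`; its second,
overlapping loop match has too few pairs and stays `SUBPAR`.

Fragment sizes from cleavage boundaries — for an 876-nt XBP1u-like
substrate cut at both splice-site endomotifs:

```r
predictFragments(876, c(500, 526))
#> [1] 500  26 350
```

i.e. the 5′ exon, the 26-nt intron, and the 3′ exon.

A command-line front end over the same functions is installed at
`inst/scripts/riddscan.R` (subcommands `scan`, `fragments`, `filter`,
`cleavage`, `score`, `simulate`).

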