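test_that("IUPAC matching follows the standard code table", {
    expect_true(iupacMatch("TATAWAAR", "TATAAAAG"))
    expect_false(iupacMatch("TATAWAAR", "TATACAAG"))  # standard W excludes C
    expect_true(iupacMatch("SSRCGCC", "GCGCGCC"))
    expect_error(iupacMatch("TATA", "TAT"), "length")
    # legacy dialect: W = A/C
    legacy <- iupacCodes(w = "AC")
    expect_true(iupacMatch("TATAWAAR", "TATACAAG", codes = legacy))
    expect_false(iupacMatch("TATAWAAR", "TATATAAG", codes = legacy))
})

test_that("a planted TATA box is found at its TSS-relative offsets", {
    set.seed(3)
    seq <- randomDna(201)
    # offset -31 corresponds to string position 70 (windowUp = 100)
    substr(seq, 70, 77) <- "TATAAAAG"
    hits <- scanMotifs(c(P1 = seq), data.frame(name = "TATA",
                                               consensus = "TATAWAAR"))
    expect_true(any(hits$start == -31 & hits$end == -24))
    expect_true(all(vapply(seq_len(nrow(hits)), function(i)
        iupacMatch("TATAWAAR", hits$match[i]), logical(1))))
})

test_that("scanner equals the consensus-expansion brute-force oracle", {
    set.seed(17)
    defs <- corePromoterMotifs()
    for (trial in 1:40) {
        L <- sample(10:30, 1)
        seq <- randomDna(L)
        for (m in seq_len(nrow(defs))) {
            expected <- bruteForceScan(seq, defs$consensus[m])
            got <- scanMotifs(c(P = seq), defs[m, ], windowUp = 0)
            expect_equal(got$start + 1L, expected,
                         info = paste(defs$name[m], seq))
        }
    }
})

test_that("scanner agrees with Biostrings degenerate matching", {
    set.seed(23)
    seq <- randomDna(500)
    for (cons in c("TATAWAAR", "RGWYV", "SSRCGCC")) {
        got <- scanMotifs(c(P = seq), data.frame(name = "M", consensus = cons),
                          windowUp = 0)
        ref <- Biostrings::matchPattern(cons, Biostrings::DNAString(seq),
                                        fixed = FALSE)
        expect_equal(got$start + 1L, BiocGenerics::start(ref))
    }
})

test_that("overlapping occurrences and empty inputs are handled", {
    # AAAA.. yields overlapping RGWYV? use a self-overlapping TATA-like case
    seq <- "TATATAAATATAAAA"
    hits <- scanMotifs(c(P = seq),
                       data.frame(name = "W8", consensus = "TATAWAAR"),
                       windowUp = 0)
    expected <- bruteForceScan(seq, "TATAWAAR")
    expect_equal(hits$start + 1L, expected)
    empty <- scanMotifs(c(P = seq), data.frame(name = character(),
                                               consensus = character()))
    expect_equal(nrow(empty), 0L)
    expect_error(scanMotifs(c(P = "ACGX"), corePromoterMotifs()),
                 "non-nucleotide")
})

test_that("minus-strand scanning equals scanning the reverse complement", {
    set.seed(29)
    chrom <- Biostrings::DNAStringSet(c(chr1 = randomDna(2000)))
    tss <- data.frame(gene_id = c("P", "M"), chrom = "chr1",
                      strand = c("+", "-"), tss = 1000L)
    ps <- buildCorePromoters(tss)
    seqs <- promoterSeqs(ps, chrom)
    hits_minus <- scanMotifs(seqs["chr1:1000:-"])
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(as.character(seqs[["chr1:1000:+"]]))))
    hits_manual <- scanMotifs(stats::setNames(rc, "chr1:1000:-"))
    expect_equal(hits_minus, hits_manual)
})

test_that("variant-motif overlap uses closed-interval intersection", {
    hits <- data.frame(promoter_id = "P1", motif = "TATA",
                       start = -31L, end = -24L, match = "TATAAAAG")
    map <- data.frame(key = c("v_sub", "v_far", "v_del"),
                      promoter_id = "P1",
                      offset = c(-28L, -40L, -25L),
                      offset_start = c(-28L, -40L, -25L),
                      offset_end = c(-28L, -40L, -23L))
    pairs <- variantMotifOverlap(map, hits)
    expect_setequal(pairs$key, c("v_sub", "v_del"))  # the deletion shares -24
    expect_false("v_far" %in% pairs$key)
})

test_that("motif-variant counts separate distinct and occurrence tallies", {
    pairs <- data.frame(key = c("v1", "v1", "v2"),
                        promoter_id = "P1",
                        motif = c("DPE", "DPE", "TATA"),
                        motif_start = c(10L, 14L, -30L),
                        motif_end = c(14L, 18L, -23L),
                        offset_start = c(12L, 14L, -28L),
                        offset_end = c(12L, 14L, -28L))
    presence <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE), 2,
                       dimnames = list(c("v1", "v2"),
                                       c("POP1", "POP2", "POP3")))
    counts <- motifVariantCounts(pairs, presence)
    bm <- counts$by_motif
    # v1 overlaps two DPE instances: 2 pairs, 1 distinct variant
    expect_equal(bm$pairs[bm$motif == "DPE"], 2L)
    expect_equal(bm$distinct[bm$motif == "DPE"], 1L)
    expect_equal(bm$occurrences[bm$motif == "DPE"], 2L)   # v1 in 2 pops
    expect_equal(bm$occurrences[bm$motif == "TATA"], 2L)  # v2 in 2 pops
    expect_equal(counts$total_distinct, 2L)
    expect_equal(counts$total_occurrences, 4L)
    expect_equal(unname(counts$by_population["DPE", ]),
                 c(1L, 1L, 0L))
    # distinct <= occurrences always
    expect_true(all(bm$distinct <= bm$occurrences))
})
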