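test_that("normalisation trims suffix then prefix and keeps indel anchors", {
    expect_equal(normalizeVariant("chr1", 100L, "AT", "AG"),
                 data.frame(chrom = "chr1", pos = 101L, ref = "T", alt = "G"))
    expect_equal(normalizeVariant("chr1", 100L, "CAA", "CA"),
                 data.frame(chrom = "chr1", pos = 100L, ref = "CA", alt = "C"))
    expect_equal(normalizeVariant("chr1", 100L, "A", "AT")$alt, "AT")
    expect_error(normalizeVariant("chr1", 100L, "A", "A"), "identical")
    expect_error(normalizeVariant("chr1", 100L, "AX", "AG"), "A/C/G/T")
})

test_that("normalisation is idempotent on random variants", {
    set.seed(42)
    bases <- c("A", "C", "G", "T")
    for (i in 1:200) {
        ref <- paste(sample(bases, sample(1:5, 1), replace = TRUE),
                     collapse = "")
        alt <- paste(sample(bases, sample(1:5, 1), replace = TRUE),
                     collapse = "")
        if (ref == alt) next
        n1 <- normalizeVariant("chr1", 1000L, ref, alt)
        n2 <- normalizeVariant(n1$chrom, n1$pos, n1$ref, n1$alt)
        expect_identical(n2, n1)
    }
})

test_that("variant typing is determined by allele lengths alone", {
    expect_equal(classifyVariantType(c("A", "A", "AT", "AT"),
                                     c("G", "AT", "A", "GC")),
                 c("substitution", "insertion", "deletion", "substitution"))
})

test_that("the 12 ordered SNV pairs split 4 transitions / 8 transversions", {
    bases <- c("A", "C", "G", "T")
    pairs <- expand.grid(ref = bases, alt = bases,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$ref != pairs$alt, ]
    tr <- isTransition(pairs$ref, pairs$alt)
    expect_equal(sum(tr), 4L)
    expect_equal(sum(!tr), 8L)
    expect_equal(sum(tr) / sum(!tr), 0.5)
    expect_true(isTransition("A", "G"))
    expect_false(isTransition("A", "C"))
    expect_error(isTransition("AT", "A"), "single-base")
})

test_that("Ts/Tv ratio counts SNVs only and is NA without transversions", {
    ref <- c("A", "C", "G", "A", "A")
    alt <- c("G", "T", "A", "C", "AT")   # 3 transitions, 1 transversion, 1 indel
    expect_equal(tsTvRatio(ref, alt), 3)
    expect_true(is.na(tsTvRatio(c("A", "AT"), c("AC", "A"))))  # indels only
    expect_true(is.na(tsTvRatio("A", "G")))  # no transversions
})

test_that("simulated SNV Ts/Tv matches an independent per-variant count", {
    set.seed(11)
    n <- 1000
    partners_ts <- c(A = "G", G = "A", C = "T", T = "C")
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    is_ts <- runif(n) < 0.78
    alt <- character(n)
    for (i in seq_len(n)) {
        alt[i] <- if (is_ts[i]) partners_ts[[ref[i]]]
                  else sample(setdiff(c("A", "C", "G", "T"),
                                      c(ref[i], partners_ts[[ref[i]]])), 1)
    }
    # oracle: direct loop
    ts <- 0L; tv <- 0L
    for (i in seq_len(n)) {
        if (paste(sort(c(ref[i], alt[i])), collapse = "") %in% c("AG", "CT"))
            ts <- ts + 1L else tv <- tv + 1L
    }
    expect_equal(tsTvRatio(ref, alt), ts / tv)
    p_hat <- ts / n
    expect_lt(abs(p_hat - 0.78), 3 * sqrt(0.78 * 0.22 / n))
})

test_that("VCF loading matches a brute-force genotype rescan", {
    set.seed(5)
    manifest <- data.frame(
        sample = sprintf("S%03d", 1:50),
        population = rep(c("POP1", "POP2"), each = 25),
        continent = rep(c("AFR", "EAS"), each = 25))
    recs <- data.frame(chrom = "chr1",
                       pos = sort(sample(950:1050, 20)),
                       id = ".", ref = "A", alt = "G")
    gtv <- sample(c("0/0", "0/1", "1/1", "./."), 20 * 50, replace = TRUE,
                  prob = c(0.7, 0.2, 0.05, 0.05))
    gt <- matrix(gtv, nrow = 20)
    vcf <- writeToyVcf(tempfile(fileext = ".vcf"), manifest, recs, gt)
    ps <- buildCorePromoters(data.frame(gene_id = "G", chrom = "chr1",
                                        strand = "+", tss = 1000L))
    co <- loadCohortVariants(vcf, ps, manifest)
    expect_equal(length(co), nrow(recs))
    # oracle: naive per-line rescan of carrier counts
    for (r in seq_len(nrow(recs))) {
        carr <- gt[r, ] %in% c("0/1", "1/1", "1/0", "1/1")
        k <- variantKey("chr1", recs$pos[r], "A", "G")
        expect_equal(unname(carrierCounts(co)[k, "POP1"]), sum(carr[1:25]))
        expect_equal(unname(carrierCounts(co)[k, "POP2"]), sum(carr[26:50]))
    }
})

test_that("multi-allelic sites split into one record per alternate allele", {
    manifest <- data.frame(sample = c("S1", "S2", "S3"),
                           population = "POP1", continent = "AFR")
    recs <- data.frame(chrom = "chr1", pos = 1000L, id = "rs99",
                       ref = "A", alt = "G,T")
    gt <- matrix(c("0/1", "0/2", "1/2"), nrow = 1)
    vcf <- writeToyVcf(tempfile(fileext = ".vcf"), manifest, recs, gt)
    ps <- buildCorePromoters(data.frame(gene_id = "G", chrom = "chr1",
                                        strand = "+", tss = 1000L))
    co <- loadCohortVariants(vcf, ps, manifest)
    expect_equal(length(co), 2L)
    cc <- carrierCounts(co)
    expect_equal(unname(cc["chr1:1000:A:G", "POP1"]), 2L)  # S1, S3
    expect_equal(unname(cc["chr1:1000:A:T", "POP1"]), 2L)  # S2, S3
    expect_true(all(variantTable(co)$rsid == "rs99"))
})

test_that("samples missing from the manifest are an error", {
    manifest <- data.frame(sample = "S1", population = "POP1",
                           continent = "AFR")
    recs <- data.frame(chrom = "chr1", pos = 1000L, id = ".",
                       ref = "A", alt = "G")
    gt <- matrix(c("0/1", "0/0"), nrow = 1)
    vcf <- writeToyVcf(tempfile(fileext = ".vcf"),
                       data.frame(sample = c("S1", "S2")), recs, gt)
    ps <- buildCorePromoters(data.frame(gene_id = "G", chrom = "chr1",
                                        strand = "+", tss = 1000L))
    expect_error(loadCohortVariants(vcf, ps, manifest), "S2")
})

test_that("carrier filter drives presence and drops absent variants", {
    co <- toyCohort()
    f2 <- applyCarrierFilter(co, 2)
    pm <- presenceMatrix(f2)
    key1 <- variantTable(f2)$key[1]
    expect_equal(sum(pm[1, ]), 1L)                # YRI only
    expect_true(pm["chr1:1005:T:A", "JPT"])
    expect_false(pm["chr1:950:A:G", "ESN"])
    # carriers={YRI:1, ESN:1, JPT:2} keeps only JPT
    expect_equal(names(which(pm["chr1:1020:CAA:C", ])), "JPT")
    # min=1 limit: presence = any carrier
    f1 <- applyCarrierFilter(co, 1)
    expect_identical(presenceMatrix(f1), carrierCounts(f1) >= 1L)
    expect_error(applyCarrierFilter(co, 0), ">= 1")
})

test_that("raising the carrier floor never increases population counts", {
    co <- toyCohort()
    counts <- sapply(1:4, function(m)
        colSums(presenceMatrix(applyCarrierFilter(co, m))))
    for (p in seq_len(nrow(counts)))
        expect_true(all(diff(counts[p, ]) <= 0))
})

test_that("type counts are conserved per population and overall", {
    co <- toyCohort(minCarriers = 2)
    v <- variantTable(co)
    expect_equal(sum(v$vtype == "substitution") +
                 sum(v$vtype == "insertion") +
                 sum(v$vtype == "deletion"), nrow(v))
    sr <- populationSummary(co)
    expect_equal(sr$substitution + sr$insertion + sr$deletion, sr$total)
})
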