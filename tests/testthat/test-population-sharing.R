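test_that("presence sets map to the four sharing classes", {
    man <- toyManifest()
    cls <- classifySharing(list("YRI",
                                c("YRI", "ESN"),
                                c("YRI", "CHB"),
                                c("YRI", "PUR", "CHB")), man)
    expect_equal(as.character(cls),
                 c("private_to_population", "private_to_continent",
                   "shared_across_continents",
                   "shared_across_all_continents"))
    expect_error(classifySharing(list(character()), man), "empty")
    expect_error(classifySharing(list("XXX"), man), "unknown")
})

test_that("classification partitions all random presence sets exhaustively", {
    set.seed(19)
    man <- toyManifest()
    pops <- man$population
    for (i in 1:300) {
        ps <- sample(pops, sample(seq_along(pops), 1))
        cls <- classifySharing(list(ps), man)
        expect_false(is.na(cls))
        # independent re-derivation from first principles
        conts <- unique(man$continent[match(ps, man$population)])
        truth <- if (length(ps) == 1) "private_to_population"
            else if (length(conts) == 1) "private_to_continent"
            else if (length(conts) == length(unique(man$continent)))
                "shared_across_all_continents"
            else "shared_across_continents"
        expect_equal(as.character(cls), truth)
    }
})

test_that("one-continent manifests make every multi-population variant
           private to continent", {
    man <- toyManifest()
    man$continent <- "ALL"
    cls <- classifySharing(list("YRI", c("YRI", "JPT"),
                                unique(man$population)), man)
    expect_equal(as.character(cls),
                 c("private_to_population", "private_to_continent",
                   "private_to_continent"))
})

test_that("spectra count each present variant once under its global class", {
    co <- toyCohort(minCarriers = 2)
    sp <- sharingSpectrum(co)
    yri <- sp[sp$population == "YRI", ]
    # YRI sees: private (950), private-continent (960), shared (975), all (1005)
    expect_equal(yri$count, c(1L, 1L, 1L, 1L))
    jpt <- sp[sp$population == "JPT", ]
    # JPT sees: the universal variant and its own private 1020 deletion
    expect_equal(sum(jpt$count), 2L)
    expect_equal(jpt$count[jpt$class == "private_to_population"], 1L)
    # proportions sum to 1 where the population has variants
    for (p in unique(sp$population)) {
        tot <- sp$total[sp$population == p][1]
        if (tot > 0)
            expect_equal(sum(sp$proportion[sp$population == p]), 1,
                         tolerance = 1e-9)
    }
})

test_that("spectra equal a brute-force double-loop recount", {
    set.seed(31)
    man <- toyManifest()
    pops <- man$population
    n <- 120
    carriers <- matrix(0L, n, length(pops),
                       dimnames = list(NULL, pops))
    for (i in seq_len(n)) {
        ps <- sample(pops, sample(seq_along(pops), 1))
        carriers[i, ps] <- 2L + stats::rpois(length(ps), 1)
    }
    v <- data.frame(chrom = "chr1", pos = seq_len(n) + 500L,
                    ref = "A", alt = "G")
    v$key <- sprintf("k%03d", seq_len(n))
    co <- applyCarrierFilter(CohortVariants(v, carriers, NULL, man), 2)
    sp <- sharingSpectrum(co)
    cls <- as.character(classifySharing(presenceMatrix(co), man))
    for (p in pops) {
        for (cl in unique(sp$class)) {
            cnt <- 0L
            for (i in seq_len(nrow(presenceMatrix(co)))) {
                if (presenceMatrix(co)[i, p] && cls[i] == cl) cnt <- cnt + 1L
            }
            expect_equal(sp$count[sp$population == p & sp$class == cl], cnt)
        }
    }
    # per-population totals equal the population's variant count
    tot <- tapply(sp$count, sp$population, sum)
    expect_equal(as.vector(tot[pops]),
                 as.vector(colSums(presenceMatrix(co))))
})

test_that("chi-squared comparison equals the direct (O-E)^2/E sum", {
    r <- compareSpectrum(c(10, 10, 10, 10), rep(0.25, 4))
    expect_equal(r$statistic, 0)
    expect_equal(r$p.value, 1)
    expect_equal(r$df, 3)

    r2 <- compareSpectrum(c(50, 0, 0, 50), rep(0.25, 4))
    expect_equal(r2$statistic, 100)   # hand sum: 2*(25^2/25) + 2*(25^2/25)
    expect_equal(r2$p.value, stats::pchisq(100, 3, lower.tail = FALSE))

    set.seed(37)
    for (i in 1:50) {
        obs <- stats::rpois(4, 20) + 1
        p <- stats::runif(4); p <- p / sum(p)
        r3 <- compareSpectrum(obs, p)
        exp_counts <- sum(obs) * p
        expect_equal(r3$statistic, sum((obs - exp_counts)^2 / exp_counts))
    }
    expect_error(compareSpectrum(c(1, 2, 3, 4), c(0.2, 0.3, 0.2, 0.2)),
                 "sum to 1")
    expect_error(compareSpectrum(c(0, 0, 0, 0), rep(0.25, 4)), "positive")
    expect_error(compareSpectrum(c(5, 5), c(1, 0)), "pool")
})

test_that("common-variant report ranks by carriers with declared tie-break", {
    co <- toyCohort(minCarriers = 2)
    rep_ <- commonVariantReport(co, topK = 3)
    yri <- rep_[rep_$population == "YRI", ]
    expect_equal(yri$key[1], "chr1:950:A:G")   # 5 carriers, rank 1
    expect_equal(yri$carriers[1], 5L)
    # ties (3 variants at 2 carriers in YRI) break by position order
    expect_equal(yri$key[2], "chr1:960:C:T")
    expect_true(all(diff(yri$carriers) <= 0))
    expect_true(all(rep_$class %in% c("private_to_population",
                                      "private_to_continent",
                                      "shared_across_continents",
                                      "shared_across_all_continents")))
})
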