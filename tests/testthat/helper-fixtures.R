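# shared in-code fixtures for the unit tests

toyManifest <- function() {
    pops <- c("YRI", "ESN", "PUR", "CLM", "CHB", "JPT")
    conts <- c("AFR", "AFR", "AMR", "AMR", "EAS", "EAS")
    data.frame(sample = sprintf("S%02d", seq_along(pops)),
               population = pops, continent = conts)
}

# cohort of hand-picked variants with known carrier patterns
toyCohort <- function(minCarriers = NA) {
    v <- data.frame(
        chrom = "chr1",
        pos = c(950L, 960L, 975L, 1005L, 1020L),
        ref = c("A", "C", "G", "T", "CAA"),
        alt = c("G", "T", "GTT", "A", "C"),
        rsid = c("rs1", NA, NA, "rs4", NA))
    carriers <- rbind(
        c(5, 0, 0, 0, 0, 0),   # private to YRI
        c(3, 2, 0, 0, 0, 0),   # private to AFR
        c(2, 0, 4, 0, 0, 0),   # AFR + AMR (shared, not all)
        c(2, 2, 2, 2, 2, 2),   # everywhere
        c(1, 1, 0, 0, 0, 2))   # only JPT passes min=2
    colnames(carriers) <- toyManifest()$population
    map <- data.frame(
        key = variantKey("chr1", v$pos, v$ref, v$alt),
        promoter_id = "chr1:1000:+",
        offset = c(-50L, -40L, -24L, 5L, 21L),
        offset_start = c(-50L, -40L, -24L, 5L, 21L),
        offset_end = c(-50L, -40L, -24L, 5L, 22L))
    co <- CohortVariants(v, carriers, map, toyManifest())
    if (!is.na(minCarriers)) co <- applyCarrierFilter(co, minCarriers)
    co
}

# write a small VCF for reader tests
writeToyVcf <- function(path, manifest, records, gt) {
    hdr <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chr1,length=100000>",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", manifest$sample), collapse = "\t"))
    body <- paste(records$chrom, records$pos, records$id, records$ref,
                  records$alt, ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, body), path)
    path
}

# brute-force IUPAC scan oracle: expand the consensus into every concrete
# sequence it allows and substring-search each
bruteForceScan <- function(seq, consensus, codes = iupacCodes()) {
    cc <- strsplit(toupper(consensus), "")[[1]]
    sets <- lapply(cc, function(k) codes[[k]])
    combos <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
    words <- apply(combos[, rev(seq_along(sets)), drop = FALSE], 1L,
                   paste, collapse = "")
    L <- length(cc)
    starts <- integer()
    for (s in seq_len(max(0L, nchar(seq) - L + 1L))) {
        if (substring(seq, s, s + L - 1L) %in% words)
            starts <- c(starts, s)
    }
    sort(starts)
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
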