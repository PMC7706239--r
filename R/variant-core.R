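#' @include AllClasses.R
NULL

#' Canonical distinct-variant key
#'
#' The distinct-variant identity used throughout the package:
#' \code{chrom:pos:ref:alt} of the normalised representation.
#'
#' @param chrom,pos,ref,alt Vectors describing normalised variants.
#' @return Character vector of keys.
#' @export
variantKey <- function(chrom, pos, ref, alt) {
    paste(chrom, pos, ref, alt, sep = ":")
}

#' Normalise variants to their minimal left-aligned representation
#'
#' Trims the common suffix, then the common prefix, of \code{ref}/\code{alt}
#' (always leaving at least one base on each side, so pure indels keep their
#' anchor base) and advances \code{pos} by the trimmed prefix length.
#'
#' @param chrom,pos,ref,alt Parallel vectors; \code{ref}/\code{alt} are
#'   non-empty A/C/G/T strings (case-insensitive).
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @examples
#' normalizeVariant("chr1", 100L, "AT", "AG")   # pos 101, T>G
#' normalizeVariant("chr1", 100L, "CAA", "CA")  # pos 100, CA>C
#' @export
normalizeVariant <- function(chrom, pos, ref, alt) {
    ref <- toupper(ref); alt <- toupper(alt)
    if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt)))
        stop("ref and alt must be non-empty A/C/G/T strings")
    if (any(ref == alt))
        stop("ref and alt are identical at ",
             variantKey(chrom, pos, ref, alt)[which(ref == alt)[1]])
    n <- length(ref)
    pos <- as.integer(pos)
    out_pos <- pos; out_ref <- ref; out_alt <- alt
    for (i in seq_len(n)) {
        r <- strsplit(ref[i], "")[[1]]
        a <- strsplit(alt[i], "")[[1]]
        # suffix first, then prefix (keeps indels left-aligned and anchored)
        while (length(r) > 1L && length(a) > 1L &&
               r[length(r)] == a[length(a)]) {
            r <- r[-length(r)]; a <- a[-length(a)]
        }
        shift <- 0L
        while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
            r <- r[-1]; a <- a[-1]; shift <- shift + 1L
        }
        out_pos[i] <- pos[i] + shift
        out_ref[i] <- paste(r, collapse = "")
        out_alt[i] <- paste(a, collapse = "")
    }
    data.frame(chrom = chrom, pos = out_pos, ref = out_ref, alt = out_alt)
}

#' Classify variant type from allele lengths
#'
#' Type is determined solely by allele lengths of the normalised variant:
#' longer alt = insertion, shorter = deletion, equal = substitution
#' (multi-base equal-length changes count as substitutions).
#'
#' @param ref,alt Normalised allele strings (vectorised).
#' @return Character vector: \code{"substitution"}, \code{"insertion"} or
#'   \code{"deletion"}.
#' @export
classifyVariantType <- function(ref, alt) {
    dl <- nchar(alt) - nchar(ref)
    ifelse(dl > 0L, "insertion", ifelse(dl < 0L, "deletion", "substitution"))
}

#' Transition test for single-base substitutions
#'
#' A substitution is a transition when it stays within the purines
#' \{A, G\} or within the pyrimidines \{C, T\}; all other single-base
#' changes are transversions.
#'
#' @param ref,alt Single-base allele strings (vectorised).
#' @return Logical vector.
#' @export
isTransition <- function(ref, alt) {
    if (any(nchar(ref) != 1L | nchar(alt) != 1L))
        stop("isTransition is defined only for single-base substitutions")
    ref <- toupper(ref); alt <- toupper(alt)
    (ref %in% c("A", "G") & alt %in% c("A", "G")) |
        (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

#' Transition/transversion ratio
#'
#' Ratio of transitions to transversions among single-base substitutions;
#' indels and multi-base substitutions are ignored.  \code{NA} when there
#' are no transversions (including the no-substitutions case).
#'
#' @param x A \code{CohortVariants}, or a character vector of ref alleles.
#' @param alt Alt alleles when \code{x} is a ref vector.
#' @param population Optional population name: restrict to variants present
#'   in that population (requires a \code{CohortVariants} with presence).
#' @return A single numeric ratio, or \code{NA} if undefined.
#' @export
tsTvRatio <- function(x, alt = NULL, population = NULL) {
    if (methods::is(x, "CohortVariants")) {
        v <- x@variants
        if (!is.null(population)) {
            if (!population %in% colnames(x@presence))
                stop("unknown population: ", population)
            v <- v[x@presence[, population], , drop = FALSE]
        }
        ref <- v$ref; alt <- v$alt
    } else {
        ref <- x
        if (is.null(alt)) stop("'alt' required when 'x' is not a cohort")
    }
    snv <- nchar(ref) == 1L & nchar(alt) == 1L
    if (!any(snv)) return(NA_real_)
    ts <- sum(isTransition(ref[snv], alt[snv]))
    tv <- sum(snv) - ts
    if (tv == 0L) NA_real_ else ts / tv
}

#' Read a sample-to-population manifest
#'
#' @param path TSV with header columns \code{sample}, \code{population},
#'   \code{continent}.
#' @return data.frame with those columns.
#' @export
readPopulationManifest <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", comment.char = "")
    names(df) <- tolower(names(df))
    miss <- setdiff(c("sample", "population", "continent"), names(df))
    if (length(miss))
        stop("manifest lacks columns: ", paste(miss, collapse = ", "))
    .checkManifest(df)
    df[c("sample", "population", "continent")]
}

.checkManifest <- function(manifest) {
    split_cont <- tapply(manifest$continent, manifest$population,
                         function(x) length(unique(x)))
    if (any(split_cont > 1L))
        stop("populations mapped to more than one continent: ",
             paste(names(split_cont)[split_cont > 1L], collapse = ", "))
    if (anyDuplicated(manifest$sample))
        stop("duplicated samples in manifest")
    invisible(TRUE)
}

# affected genomic span of a normalised variant; insertions report the
# two flanking bases of the insertion gap
.affectedSpan <- function(pos, ref, alt) {
    vtype <- classifyVariantType(ref, alt)
    anchored <- substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
    start <- pos
    end <- pos + nchar(ref) - 1L
    ins <- vtype == "insertion" & anchored
    del <- vtype == "deletion" & anchored
    start[del] <- pos[del] + 1L
    start[ins] <- pos[ins]
    end[ins] <- pos[ins] + 1L
    data.frame(gstart = start, gend = pmax(end, start), insertion_gap = ins)
}

#' Load cohort variants from a multi-sample VCF
#'
#' Reads a VCF (plain or bgzipped) with GT genotypes, splits multi-allelic
#' sites into one record per alternate allele, normalises each record,
#' restricts to records whose affected span falls inside at least one
#' core-promoter window, and counts per-population carriers (individuals
#' with >= 1 alternate allele).  The returned cohort is unfiltered: apply
#' \code{\link{applyCarrierFilter}} to impose the minimum-carriers-per-
#' population presence rule.
#'
#' TSS-relative offsets: a substitution's affected span is its replaced
#' bases; a deletion's span is its deleted bases (anchor excluded); an
#' insertion occupies the single inter-base point one offset downstream (in
#' transcription direction) of its anchor.  A record is assigned to a
#' promoter when that span intersects the window; the recorded
#' \code{offset} is the transcriptionally first in-window affected
#' position.
#'
#' @param vcfPath Path to the VCF.
#' @param promoters A \code{PromoterSet}.
#' @param manifest data.frame (\code{sample}, \code{population},
#'   \code{continent}) covering every VCF sample, or a path to such a TSV.
#' @return A \code{\link[=CohortVariants-class]{CohortVariants}}.
#' @export
loadCohortVariants <- function(vcfPath, promoters, manifest) {
    if (is.character(manifest) && length(manifest) == 1L &&
        file.exists(manifest))
        manifest <- readPopulationManifest(manifest)
    manifest <- as.data.frame(manifest)
    .checkManifest(manifest)
    vcf <- VariantAnnotation::readVcf(vcfPath)
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt))
        stop("VCF has no GT genotype field")
    samples <- colnames(gt)
    missing_samples <- setdiff(samples, manifest$sample)
    if (length(missing_samples))
        stop("samples absent from manifest: ",
             paste(missing_samples, collapse = ", "))
    rr <- SummarizedExperiment::rowRanges(vcf)
    refs <- as.character(rr$REF)
    alts <- rr$ALT                       # DNAStringSetList
    chroms <- as.character(GenomeInfoDb::seqnames(rr))
    poss <- GenomicRanges::start(rr)

    nogt <- apply(gt, 1L, function(g) all(g %in% c(".", "./.", ".|.")))
    if (any(nogt)) {
        warning(sum(nogt), " VCF record(s) without genotypes skipped")
    }
    ids <- names(rr)
    rsid <- ifelse(grepl("^rs", ids), sub(":.*$", "", ids), NA_character_)

    # expand multi-allelic sites: one record per (row, alt allele)
    nalt <- lengths(alts)
    row_i <- rep(seq_along(refs), nalt)
    alt_i <- unlist(lapply(nalt, seq_len), use.names = FALSE)
    keep <- !nogt[row_i]
    row_i <- row_i[keep]; alt_i <- alt_i[keep]
    alt_chr <- unlist(lapply(alts, as.character), use.names = FALSE)[keep]
    if (!length(row_i))
        return(.emptyCohort(manifest))

    # sample-level carrier calls per expanded record
    carrier <- matrix(FALSE, length(row_i), length(samples),
                      dimnames = list(NULL, samples))
    for (a in sort(unique(alt_i))) {
        pat <- paste0("(^|[/|])", a, "($|[/|])")
        hit <- matrix(grepl(pat, gt), nrow = nrow(gt))
        sel <- which(alt_i == a)
        carrier[sel, ] <- hit[row_i[sel], , drop = FALSE]
    }

    norm <- normalizeVariant(chroms[row_i], poss[row_i], refs[row_i], alt_chr)
    key <- variantKey(norm$chrom, norm$pos, norm$ref, norm$alt)

    # merge records that normalise to the same variant (carrier-level OR)
    uk <- unique(key)
    ki <- match(key, uk)
    merged <- matrix(FALSE, length(uk), length(samples),
                     dimnames = list(uk, samples))
    for (j in seq_along(key))
        merged[ki[j], ] <- merged[ki[j], ] | carrier[j, ]
    firsts <- !duplicated(key)
    variants <- data.frame(key = key[firsts],
                           chrom = norm$chrom[firsts],
                           pos = norm$pos[firsts],
                           ref = norm$ref[firsts],
                           alt = norm$alt[firsts],
                           rsid = rsid[row_i][firsts])
    variants <- variants[match(uk, variants$key), ]
    variants$vtype <- classifyVariantType(variants$ref, variants$alt)

    map <- .mapToPromoters(variants, promoters)
    in_prom <- variants$key %in% map$key
    variants <- variants[in_prom, , drop = FALSE]
    merged <- merged[in_prom, , drop = FALSE]
    if (!nrow(variants))
        return(.emptyCohort(manifest))

    pop <- manifest$population[match(samples, manifest$sample)]
    pops <- sort(unique(manifest$population))
    carriers <- vapply(pops, function(p)
        as.integer(rowSums(merged[, pop == p, drop = FALSE])),
        integer(nrow(merged)))
    if (nrow(variants) == 1L)
        carriers <- matrix(carriers, nrow = 1L, dimnames = list(NULL, pops))
    rownames(carriers) <- variants$key
    rownames(variants) <- NULL
    methods::new("CohortVariants",
                 variants = variants, carriers = carriers,
                 presence = carriers >= 1L, map = map,
                 manifest = manifest, minCarriers = NA_integer_)
}

.emptyCohort <- function(manifest) {
    pops <- sort(unique(manifest$population))
    v <- data.frame(key = character(), chrom = character(), pos = integer(),
                    ref = character(), alt = character(),
                    rsid = character(), vtype = character())
    m <- matrix(0L, 0L, length(pops), dimnames = list(NULL, pops))
    methods::new("CohortVariants", variants = v, carriers = m,
                 presence = m >= 1L,
                 map = data.frame(key = character(), promoter_id = character(),
                                  offset = integer(), offset_start = integer(),
                                  offset_end = integer()),
                 manifest = manifest, minCarriers = NA_integer_)
}

# assign variants to promoters and compute TSS-relative offset spans
.mapToPromoters <- function(variants, promoters) {
    empty <- data.frame(key = character(), promoter_id = character(),
                        offset = integer(), offset_start = integer(),
                        offset_end = integer())
    if (!nrow(variants) || !length(promoters)) return(empty)
    sp <- .affectedSpan(variants$pos, variants$ref, variants$alt)
    q <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(sp$gstart, sp$gend))
    gr <- promoters@promoters
    ov <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
    if (!length(ov)) return(empty)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    strand <- as.character(GenomicRanges::strand(gr))[si]
    tss <- gr$tss[si]
    o1 <- .offsetOf(strand, tss, sp$gstart[qi])
    o2 <- .offsetOf(strand, tss, sp$gend[qi])
    ostart <- pmin(o1, o2); oend <- pmax(o1, o2)
    ins <- sp$insertion_gap[qi]
    # insertion point: downstream flank of the gap in transcription direction
    ostart[ins] <- oend[ins]
    up <- promoters@windowUp; down <- promoters@windowDown
    in_window <- oend >= -up & ostart <= down
    qi <- qi[in_window]; si <- si[in_window]
    ostart <- ostart[in_window]; oend <- oend[in_window]
    data.frame(key = variants$key[qi],
               promoter_id = gr$promoter_id[si],
               offset = as.integer(pmax(ostart, -up)),
               offset_start = as.integer(ostart),
               offset_end = as.integer(oend))
}

#' Apply the minimum-carriers-per-population presence filter
#'
#' A variant is \emph{present} in a population when it has at least
#' \code{minCarriers} carriers there; variants present in no population are
#' dropped.  The study convention is \code{minCarriers = 2} ("at least two
#' individuals per population").
#'
#' @param cohort A \code{CohortVariants}.
#' @param minCarriers Positive integer (default 2).
#' @return A filtered \code{CohortVariants} with its presence matrix set.
#' @export
applyCarrierFilter <- function(cohort, minCarriers = 2L) {
    stopifnot(methods::is(cohort, "CohortVariants"))
    minCarriers <- as.integer(minCarriers)
    if (is.na(minCarriers) || minCarriers < 1L)
        stop("'minCarriers' must be >= 1")
    presence <- cohort@carriers >= minCarriers
    keep <- rowSums(presence) > 0L
    variants <- cohort@variants[keep, , drop = FALSE]
    rownames(variants) <- NULL
    methods::new("CohortVariants",
                 variants = variants,
                 carriers = cohort@carriers[keep, , drop = FALSE],
                 presence = presence[keep, , drop = FALSE],
                 map = cohort@map[cohort@map$key %in% variants$key, ,
                                  drop = FALSE],
                 manifest = cohort@manifest,
                 minCarriers = minCarriers)
}

#' Write the annotated variant table as TSV
#'
#' One row per (variant, promoter) assignment: identity and type columns,
#' promoter and offsets, per-population carrier counts and presence flags.
#'
#' @param cohort A \code{CohortVariants}.
#' @param path Output TSV path.
#' @return The merged data.frame, invisibly.
#' @export
writeVariantTable <- function(cohort, path) {
    v <- cohort@variants
    m <- cohort@map
    df <- merge(m, v, by = "key", sort = FALSE)
    cc <- as.data.frame(cohort@carriers[df$key, , drop = FALSE])
    names(cc) <- paste0("carriers_", names(cc))
    pp <- as.data.frame(cohort@presence[df$key, , drop = FALSE])
    names(pp) <- paste0("present_", names(pp))
    out <- cbind(df, cc, pp)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(out)
}
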