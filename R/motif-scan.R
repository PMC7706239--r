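#' @include AllClasses.R
NULL

#' IUPAC degenerate nucleotide code table
#'
#' Returns the mapping from one-letter IUPAC nucleotide codes to the base
#' sets they allow.  The standard table defines W = \{A, T\}; a legacy
#' dialect found in some printed motif definitions instead uses W = \{A, C\}
#' and is selectable for exact replication of analyses that used it.
#'
#' @param w Either \code{"AT"} (standard IUPAC, default) or \code{"AC"}
#'   (legacy dialect).
#' @return Named list mapping each code to a character vector of bases.
#' @export
iupacCodes <- function(w = c("AT", "AC")) {
    w <- match.arg(w)
    codes <- list(
        A = "A", C = "C", G = "G", T = "T",
        R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
        W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
        B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
        V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
    if (w == "AC") codes$W <- c("A", "C")
    codes
}

#' Default core-promoter motif definitions
#'
#' The four canonical core-promoter elements with their degenerate
#' consensus sequences: BRE (TFIIB recognition element) SSRCGCC, TATA box
#' TATAWAAR, Inr (initiator) YYANWYY and DPE (downstream promoter element)
#' RGWYV.
#'
#' @return data.frame with columns \code{name} and \code{consensus}.
#' @export
corePromoterMotifs <- function() {
    data.frame(name = c("BRE", "TATA", "INR", "DPE"),
               consensus = c("SSRCGCC", "TATAWAAR", "YYANWYY", "RGWYV"))
}

#' Read motif definitions from a TSV
#'
#' @param path TSV with header columns \code{name} and \code{consensus}.
#' @return data.frame with those columns (consensus upper-cased and
#'   validated against the IUPAC alphabet).
#' @export
readMotifDefs <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", comment.char = "")
    names(df) <- tolower(names(df))
    miss <- setdiff(c("name", "consensus"), names(df))
    if (length(miss))
        stop("motif table lacks columns: ", paste(miss, collapse = ", "))
    df$consensus <- toupper(df$consensus)
    bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", df$consensus)
    if (any(bad))
        stop("invalid consensus for motif ", df$name[which(bad)[1]])
    df[c("name", "consensus")]
}

#' Match a DNA string against an IUPAC consensus of the same length
#'
#' @param consensus IUPAC consensus string.
#' @param seq DNA string of the same length (A/C/G/T).
#' @param codes IUPAC table from \code{\link{iupacCodes}}.
#' @return \code{TRUE} iff every base of \code{seq} lies in the base set the
#'   corresponding consensus code allows.
#' @examples
#' iupacMatch("TATAWAAR", "TATAAAAG")  # TRUE
#' iupacMatch("TATAWAAR", "TATACAAG")  # FALSE: W excludes C
#' @export
iupacMatch <- function(consensus, seq, codes = iupacCodes()) {
    consensus <- toupper(consensus); seq <- toupper(seq)
    if (nchar(consensus) != nchar(seq))
        stop("consensus and sequence lengths differ (",
             nchar(consensus), " vs ", nchar(seq), ")")
    cc <- strsplit(consensus, "")[[1]]
    sc <- strsplit(seq, "")[[1]]
    if (any(!cc %in% names(codes)))
        stop("non-IUPAC character in consensus: ",
             cc[which(!cc %in% names(codes))[1]])
    all(mapply(function(code, base) base %in% codes[[code]], cc, sc))
}

# IUPAC consensus -> regular expression of character classes
.iupacRegex <- function(consensus, codes) {
    cc <- strsplit(toupper(consensus), "")[[1]]
    bad <- which(!cc %in% names(codes))
    if (length(bad))
        stop("non-IUPAC character in consensus: ", cc[bad[1]])
    paste(vapply(cc, function(k) {
        b <- codes[[k]]
        if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
    }, character(1)), collapse = "")
}

#' Scan transcription-oriented promoter sequences for IUPAC motifs
#'
#' Reports every occurrence (all offsets, overlaps included) of each
#' consensus in each promoter sequence.  Sequences must already be oriented
#' 5'->3' in transcription direction (see \code{\link{promoterSeqs}});
#' position \code{i} of a sequence corresponds to TSS-relative offset
#' \code{i - 1 - windowUp}.  Ambiguous bases (\code{N}) in the sequence
#' never match.
#'
#' @param seqs Named character vector or \link[Biostrings]{DNAStringSet} of
#'   promoter sequences (names = promoter ids).
#' @param defs Motif definitions (\code{name}, \code{consensus});
#'   default \code{\link{corePromoterMotifs}()}.
#' @param windowUp Upstream window half-width used to express hit positions
#'   as TSS-relative offsets (default 100).
#' @param codes IUPAC table from \code{\link{iupacCodes}}.
#' @return data.frame of hits: \code{promoter_id}, \code{motif},
#'   \code{start}, \code{end} (TSS-relative, inclusive), \code{match}
#'   (the matched sequence).
#' @export
scanMotifs <- function(seqs, defs = corePromoterMotifs(), windowUp = 100L,
                       codes = iupacCodes()) {
    if (methods::is(seqs, "DNAStringSet")) {
        nm <- names(seqs)
        seqs <- as.character(seqs)
        names(seqs) <- nm
    }
    if (is.null(names(seqs)))
        stop("'seqs' must be named by promoter id")
    seqs <- toupper(seqs)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
        stop("non-nucleotide characters in sequence ",
             names(seqs)[which(bad)[1]])
    defs <- as.data.frame(defs)
    out <- vector("list", nrow(defs) * length(seqs))
    k <- 0L
    for (m in seq_len(nrow(defs))) {
        L <- nchar(defs$consensus[m])
        # lookahead makes overlapping occurrences visible to the regex scan
        pat <- paste0("(?=", .iupacRegex(defs$consensus[m], codes), ")")
        for (s in seq_along(seqs)) {
            hits <- gregexpr(pat, seqs[s], perl = TRUE)[[1]]
            if (hits[1] == -1L) next
            starts <- as.integer(hits)
            k <- k + 1L
            out[[k]] <- data.frame(
                promoter_id = names(seqs)[s],
                motif = defs$name[m],
                start = starts - 1L - as.integer(windowUp),
                end = starts - 2L - as.integer(windowUp) + L,
                match = substring(seqs[s], starts, starts + L - 1L))
        }
    }
    if (!k)
        return(data.frame(promoter_id = character(), motif = character(),
                          start = integer(), end = integer(),
                          match = character()))
    res <- do.call(rbind, out[seq_len(k)])
    res[order(res$promoter_id, res$motif, res$start), , drop = FALSE] |>
        (\(d) { rownames(d) <- NULL; d })()
}

#' Intersect variant offset spans with motif hits
#'
#' Pairs each (variant, promoter) offset span with every motif occurrence
#' it intersects (closed intervals on the TSS-relative axis; an insertion's
#' span is its single inter-base point).
#'
#' @param cohort A \code{CohortVariants}, or a data.frame with columns
#'   \code{key}, \code{promoter_id}, \code{offset_start}, \code{offset_end}.
#' @param hits Motif hits from \code{\link{scanMotifs}}.
#' @return data.frame of pairs: \code{key}, \code{promoter_id},
#'   \code{motif}, \code{motif_start}, \code{motif_end},
#'   \code{offset_start}, \code{offset_end}.
#' @export
variantMotifOverlap <- function(cohort, hits) {
    map <- if (methods::is(cohort, "CohortVariants")) cohort@map
           else as.data.frame(cohort)
    hits <- as.data.frame(hits)
    if (!nrow(map) || !nrow(hits))
        return(data.frame(key = character(), promoter_id = character(),
                          motif = character(), motif_start = integer(),
                          motif_end = integer(), offset_start = integer(),
                          offset_end = integer()))
    j <- merge(map, hits, by = "promoter_id", suffixes = c("", ".hit"))
    ov <- j$offset_start <= j$end & j$offset_end >= j$start
    j <- j[ov, , drop = FALSE]
    res <- data.frame(key = j$key, promoter_id = j$promoter_id,
                      motif = j$motif, motif_start = j$start,
                      motif_end = j$end, offset_start = j$offset_start,
                      offset_end = j$offset_end)
    res <- res[order(res$key, res$promoter_id, res$motif, res$motif_start), ,
               drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Per-population, per-motif variant counts
#'
#' Tabulates motif-affecting variation three ways: \code{pairs} counts
#' every (variant, motif occurrence) pair; \code{distinct} counts unique
#' variants per motif; \code{occurrences} counts (variant, motif,
#' population) triples over the populations where each variant is present
#' (the "times" tally: one variant present in three populations contributes
#' three).  The per-population matrix counts distinct variants per motif
#' and population.
#'
#' @param pairs Output of \code{\link{variantMotifOverlap}}.
#' @param presence Logical presence matrix (variants x populations) with
#'   variant keys as rownames, e.g. \code{presenceMatrix(cohort)}.
#' @return List with \code{by_motif} (data.frame: motif, pairs, distinct,
#'   occurrences), \code{by_population} (motif x population matrix of
#'   distinct variant counts), \code{total_distinct} (variants hitting any
#'   motif) and \code{total_occurrences}.
#' @export
motifVariantCounts <- function(pairs, presence) {
    pairs <- as.data.frame(pairs)
    motifs <- sort(unique(pairs$motif))
    pops <- colnames(presence)
    if (!nrow(pairs)) {
        by_motif <- data.frame(motif = character(), pairs = integer(),
                               distinct = integer(), occurrences = integer())
        return(list(by_motif = by_motif,
                    by_population = matrix(0L, 0L, length(pops),
                                           dimnames = list(NULL, pops)),
                    total_distinct = 0L, total_occurrences = 0L))
    }
    miss <- setdiff(unique(pairs$key), rownames(presence))
    if (length(miss))
        stop("variants missing from presence matrix: ",
             paste(utils::head(miss, 3), collapse = ", "))
    uniq <- unique(pairs[c("key", "motif")])
    npops <- rowSums(presence)[uniq$key]
    by_motif <- data.frame(
        motif = motifs,
        pairs = as.integer(table(factor(pairs$motif, motifs))),
        distinct = as.integer(table(factor(uniq$motif, motifs))),
        occurrences = as.integer(tapply(npops, factor(uniq$motif, motifs),
                                        sum, default = 0L)))
    by_population <- vapply(pops, function(p) {
        pres <- presence[uniq$key, p]
        as.integer(table(factor(uniq$motif[pres], motifs)))
    }, integer(length(motifs)))
    if (length(motifs) == 1L)
        by_population <- matrix(by_population, 1L,
                                dimnames = list(NULL, pops))
    rownames(by_population) <- motifs
    anykeys <- unique(pairs$key)
    list(by_motif = by_motif, by_population = by_population,
         total_distinct = length(anykeys),
         total_occurrences = sum(rowSums(presence)[anykeys]))
}
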