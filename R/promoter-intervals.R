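#' @include AllClasses.R
NULL

#' Read a TSS annotation from BED6 or a headered TSV
#'
#' Accepts either a BED6 file (columns chrom, start, end, name, score,
#' strand; 0-based half-open) or a tab-separated table with a header naming
#' at least \code{gene_id}, \code{chrom}, \code{strand} and \code{tss}
#' (1-based), optionally \code{transcript_id}.  For BED input the TSS is the
#' strand-appropriate end of the feature: \code{start + 1} on \code{+},
#' \code{end} on \code{-} (single-base features encode the TSS itself).
#'
#' @param path Path to the annotation file.
#' @param format \code{"auto"} (default; a header containing \code{tss}
#'   selects TSV, otherwise BED), \code{"bed"} or \code{"tsv"}.
#' @return data.frame with columns \code{gene_id}, \code{transcript_id},
#'   \code{chrom}, \code{strand}, \code{tss}.  Empty input yields an empty
#'   data.frame with a warning.
#' @export
readTssAnnotation <- function(path, format = c("auto", "bed", "tsv")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("TSS annotation file not found: ", path)
    lines <- readLines(path)
    lines <- lines[!grepl("^(#|track|browser)", lines)]
    nonblank <- which(nzchar(trimws(lines)))
    if (!length(nonblank)) {
        warning("TSS annotation '", basename(path), "' is empty")
        return(data.frame(gene_id = character(), transcript_id = character(),
                          chrom = character(), strand = character(),
                          tss = integer()))
    }
    if (format == "auto") {
        hdr <- strsplit(lines[nonblank[1]], "\t")[[1]]
        format <- if ("tss" %in% tolower(hdr)) "tsv" else "bed"
    }
    if (format == "tsv") .readTssTsv(lines, path) else .readTssBed(lines, path)
}

.readTssTsv <- function(lines, path) {
    df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                            colClasses = "character", comment.char = "")
    names(df) <- tolower(names(df))
    need <- c("gene_id", "chrom", "strand", "tss")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("TSS table '", basename(path), "' lacks columns: ",
             paste(miss, collapse = ", "))
    tss <- suppressWarnings(as.integer(df$tss))
    bad <- which(is.na(tss) | tss < 1L)
    if (length(bad))
        stop("malformed TSS coordinate in '", basename(path),
             "' at line ", bad[1] + 1L)          # +1 for the header line
    badstr <- which(!df$strand %in% c("+", "-"))
    if (length(badstr))
        stop("missing or malformed strand in '", basename(path),
             "' at line ", badstr[1] + 1L)
    data.frame(gene_id = df$gene_id,
               transcript_id = if (!is.null(df$transcript_id))
                   df$transcript_id else NA_character_,
               chrom = df$chrom, strand = df$strand, tss = tss)
}

.readTssBed <- function(lines, path) {
    parts <- strsplit(lines, "\t")
    nf <- lengths(parts)
    short <- which(nf < 6L & nzchar(trimws(lines)))
    if (length(short))
        stop("BED line ", short[1], " of '", basename(path),
             "' has ", nf[short[1]], " fields; BED6 (with strand) required")
    keep <- which(nzchar(trimws(lines)))
    parts <- parts[keep]
    f <- function(i) vapply(parts, `[[`, character(1), i)
    start0 <- suppressWarnings(as.integer(f(2)))
    end0 <- suppressWarnings(as.integer(f(3)))
    bad <- which(is.na(start0) | is.na(end0) | start0 < 0L | end0 <= start0)
    if (length(bad))
        stop("malformed coordinates on BED line ", keep[bad[1]],
             " of '", basename(path), "'")
    strand <- f(6)
    badstr <- which(!strand %in% c("+", "-"))
    if (length(badstr))
        stop("missing strand on BED line ", keep[badstr[1]],
             " of '", basename(path), "'")
    # BED is 0-based half-open: TSS = start+1 on '+', = end on '-'
    tss <- ifelse(strand == "+", start0 + 1L, end0)
    data.frame(gene_id = f(4), transcript_id = NA_character_,
               chrom = f(1), strand = strand, tss = as.integer(tss))
}

#' Build strand-aware core-promoter intervals around TSSs
#'
#' Each TSS is extended \code{windowUp} bp upstream and \code{windowDown} bp
#' downstream \emph{in transcription direction}, so the genomic span is
#' \code{[tss - windowUp, tss + windowDown]} on \code{+} and
#' \code{[tss - windowDown, tss + windowUp]} on \code{-}.  Records sharing
#' (chrom, tss, strand) collapse into one promoter whose \code{gene_ids} is
#' the union of their genes.
#'
#' @param records data.frame of TSS records as returned by
#'   \code{\link{readTssAnnotation}} (columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{tss}).
#' @param windowUp,windowDown Non-negative window half-widths in bp
#'   (default 100 and 100, i.e. TSS +/- 100).
#' @return A \code{\link[=PromoterSet-class]{PromoterSet}}.
#' @examples
#' tss <- data.frame(gene_id = c("A", "B"), chrom = "chr1",
#'                   strand = "+", tss = 1000L)
#' ps <- buildCorePromoters(tss)
#' promoterIds(ps)
#' @export
buildCorePromoters <- function(records, windowUp = 100L, windowDown = 100L) {
    windowUp <- as.integer(windowUp); windowDown <- as.integer(windowDown)
    if (is.na(windowUp) || is.na(windowDown) || windowUp < 0L || windowDown < 0L)
        stop("'windowUp' and 'windowDown' must be non-negative")
    records <- as.data.frame(records)
    if (!nrow(records)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr)$promoter_id <- character()
        S4Vectors::mcols(gr)$tss <- integer()
        S4Vectors::mcols(gr)$gene_ids <- IRanges::CharacterList()
        return(methods::new("PromoterSet", promoters = gr,
                            windowUp = windowUp, windowDown = windowDown))
    }
    if (any(!records$strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    key <- paste(records$chrom, records$tss, records$strand, sep = ":")
    first <- !duplicated(key)
    uk <- key[first]
    genes <- lapply(split(records$gene_id, factor(key, levels = uk)),
                    function(g) sort(unique(g)))
    chrom <- records$chrom[first]
    tss <- as.integer(records$tss[first])
    strand <- records$strand[first]
    start <- ifelse(strand == "+", tss - windowUp, tss - windowDown)
    end <- ifelse(strand == "+", tss + windowDown, tss + windowUp)
    if (any(start < 1L))
        stop("promoter window extends below position 1 (TSS at ",
             tss[which(start < 1L)[1]], ")")
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start, end),
                                 strand = strand)
    gr$promoter_id <- sprintf("%s:%d:%s", chrom, tss, strand)
    gr$tss <- tss
    gr$gene_ids <- IRanges::CharacterList(unname(genes))
    methods::new("PromoterSet", promoters = gr,
                 windowUp = windowUp, windowDown = windowDown)
}

# offset of a genomic position relative to a TSS, transcription direction
.offsetOf <- function(strand, tss, pos) {
    plus <- rep_len(strand == "+", max(length(strand), length(pos)))
    ifelse(plus, pos - tss, tss - pos)
}

#' TSS-relative offset of genomic positions within a promoter
#'
#' Maps genomic coordinates to signed TSS-relative offsets for one promoter
#' of a \code{PromoterSet}: offset = pos - TSS on \code{+}, TSS - pos on
#' \code{-}; the TSS maps to 0, negative offsets are upstream of
#' transcription.  Positions outside the \code{-windowUp..+windowDown}
#' window return \code{NA}.
#'
#' @param promoters A \code{PromoterSet}.
#' @param promoterId A single promoter identifier from
#'   \code{promoterIds(promoters)}.
#' @param pos Vector of 1-based genomic positions.
#' @return Integer vector of offsets (\code{NA} outside the window).
#' @examples
#' ps <- buildCorePromoters(data.frame(gene_id = "A", chrom = "chr1",
#'                                     strand = "-", tss = 1000L))
#' tssRelativeOffset(ps, promoterIds(ps), c(990L, 1000L, 1200L))
#' @export
tssRelativeOffset <- function(promoters, promoterId, pos) {
    stopifnot(methods::is(promoters, "PromoterSet"), length(promoterId) == 1L)
    gr <- promoters@promoters
    i <- match(promoterId, gr$promoter_id)
    if (is.na(i))
        stop("unknown promoter: ", promoterId)
    if (any(pos < 1L))
        stop("genomic positions must be >= 1")
    off <- .offsetOf(as.character(GenomicRanges::strand(gr)[i]), gr$tss[i], pos)
    off[off < -promoters@windowUp | off > promoters@windowDown] <- NA_integer_
    as.integer(off)
}

#' Convert TSS-relative offsets back to genomic positions
#'
#' Inverse of \code{\link{tssRelativeOffset}} for offsets within the window.
#'
#' @inheritParams tssRelativeOffset
#' @param offset Integer vector of TSS-relative offsets.
#' @return Integer vector of 1-based genomic positions.
#' @export
genomicPosition <- function(promoters, promoterId, offset) {
    stopifnot(methods::is(promoters, "PromoterSet"), length(promoterId) == 1L)
    gr <- promoters@promoters
    i <- match(promoterId, gr$promoter_id)
    if (is.na(i))
        stop("unknown promoter: ", promoterId)
    if (any(offset < -promoters@windowUp | offset > promoters@windowDown,
            na.rm = TRUE))
        stop("offset outside promoter window")
    s <- as.character(GenomicRanges::strand(gr)[i])
    as.integer(if (s == "+") gr$tss[i] + offset else gr$tss[i] - offset)
}

#' Export promoters as BED6 and as a gene table
#'
#' \code{promotersToBed} writes one BED6 line per promoter (0-based
#' half-open, name = promoter_id, score 0).  \code{promoterTable} returns
#' (and optionally writes) a data.frame with a comma-separated
#' \code{gene_ids} column.
#'
#' @param promoters A \code{PromoterSet}.
#' @param path Output file path (for \code{promoterTable}, optional).
#' @return \code{promotersToBed}: the path, invisibly.
#'   \code{promoterTable}: a data.frame.
#' @export
promotersToBed <- function(promoters, path) {
    gr <- promoters@promoters
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     name = gr$promoter_id,
                     score = 0L,
                     strand = as.character(GenomicRanges::strand(gr)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname promotersToBed
#' @export
promoterTable <- function(promoters, path = NULL) {
    gr <- promoters@promoters
    df <- data.frame(promoter_id = gr$promoter_id,
                     chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     strand = as.character(GenomicRanges::strand(gr)),
                     tss = gr$tss,
                     genomic_start = GenomicRanges::start(gr),
                     genomic_end = GenomicRanges::end(gr),
                     gene_ids = vapply(gr$gene_ids, paste,
                                       character(1), collapse = ","))
    if (!is.null(path))
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    df
}

#' Extract transcription-oriented promoter sequences
#'
#' Slices the \code{-windowUp..+windowDown} window of each promoter from a
#' reference genome and orients it 5'->3' in transcription direction
#' (minus-strand windows are reverse-complemented), ready for
#' \code{\link{scanMotifs}}.
#'
#' @param promoters A \code{PromoterSet}.
#' @param genome A \link[Biostrings]{DNAStringSet} named by chromosome, or a
#'   path to a FASTA file.
#' @return \code{DNAStringSet} named by promoter_id; position \code{i}
#'   corresponds to offset \code{i - 1 - windowUp}.
#' @export
promoterSeqs <- function(promoters, genome) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    gr <- promoters@promoters
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    miss <- setdiff(unique(chr), names(genome))
    if (length(miss))
        stop("chromosomes absent from genome: ", paste(miss, collapse = ", "))
    seqs <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
        s <- Biostrings::subseq(genome[[chr[i]]],
                                GenomicRanges::start(gr)[i],
                                GenomicRanges::end(gr)[i])
        if (as.character(GenomicRanges::strand(gr)[i]) == "-")
            s <- Biostrings::reverseComplement(s)
        as.character(s)
    }, character(1)))
    names(seqs) <- gr$promoter_id
    seqs
}
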