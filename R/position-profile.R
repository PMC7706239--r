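#' @include AllClasses.R
NULL

#' Variant density across TSS-relative offsets
#'
#' Tabulates one count per (variant, promoter) offset assignment across the
#' \code{-windowUp..+windowDown} axis (a variant mapped to two promoters
#' contributes twice; set \code{distinct = TRUE} to count each variant
#' once, at its first assignment).  Offsets below 0 are upstream of
#' transcription, offset 0 is the TSS.
#'
#' @param cohort A \code{CohortVariants}, or a data.frame with columns
#'   \code{key} and \code{offset}.
#' @param windowUp,windowDown Window half-widths defining the axis
#'   (default 100/100).
#' @param distinct Count distinct variants instead of (variant, promoter)
#'   pairs.
#' @return List of class \code{offsetHistogram}: \code{counts} (named
#'   integer vector over the full offset axis), \code{upstream_total}
#'   (offsets < 0), \code{downstream_total} (offsets > 0), \code{tss_total}
#'   (offset 0) and \code{total}.
#' @export
offsetHistogram <- function(cohort, windowUp = 100L, windowDown = 100L,
                            distinct = FALSE) {
    map <- if (methods::is(cohort, "CohortVariants")) cohort@map
           else as.data.frame(cohort)
    off <- map$offset
    if (distinct && nrow(map))
        off <- off[!duplicated(map$key)]
    axis <- seq(-as.integer(windowUp), as.integer(windowDown))
    if (length(off) && any(off < min(axis) | off > max(axis)))
        stop("offset outside the promoter window: interval/variant mismatch")
    counts <- table(factor(off, levels = axis))
    counts <- stats::setNames(as.integer(counts), as.character(axis))
    structure(list(counts = counts,
                   upstream_total = sum(counts[axis < 0]),
                   downstream_total = sum(counts[axis > 0]),
                   tss_total = unname(counts[as.character(0)]),
                   total = sum(counts)),
              class = "offsetHistogram")
}

#' @export
print.offsetHistogram <- function(x, ...) {
    cat("TSS-relative offset histogram:", x$total, "assignments\n")
    cat("  upstream (<0):", x$upstream_total,
        " TSS (0):", x$tss_total,
        " downstream (>0):", x$downstream_total, "\n")
    invisible(x)
}

#' Write an offset histogram as TSV
#'
#' @param hist An \code{offsetHistogram}.
#' @param path Output TSV path (columns \code{offset}, \code{count}).
#' @return The path, invisibly.
#' @export
writeOffsetHistogram <- function(hist, path) {
    utils::write.table(
        data.frame(offset = as.integer(names(hist$counts)),
                   count = hist$counts),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Split offset-bearing features into upstream / downstream / spanning
#'
#' Any feature table carrying TSS-relative spans (e.g. short tandem
#' repeats, motif hits) is split by side: wholly negative offsets are
#' upstream, wholly positive downstream, and spans crossing offset 0 are
#' reported separately as spanning.
#'
#' @param features data.frame with columns \code{start} and \code{end}
#'   (TSS-relative, inclusive, start <= end).
#' @return Named integer vector: \code{upstream}, \code{downstream},
#'   \code{spanning}.
#' @examples
#' sideCounts(data.frame(start = c(-40, 3, -2), end = c(-20, 15, 4)))
#' @export
sideCounts <- function(features) {
    features <- as.data.frame(features)
    if (!nrow(features))
        return(c(upstream = 0L, downstream = 0L, spanning = 0L))
    if (any(features$start > features$end))
        stop("feature spans must satisfy start <= end")
    up <- features$end < 0
    down <- features$start > 0
    c(upstream = sum(up), downstream = sum(down),
      spanning = sum(!up & !down))
}
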