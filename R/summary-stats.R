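#' @include AllClasses.R
NULL

#' Per-population summary row
#'
#' One summary row per population: variants present there, known/novel
#' split, type counts (substitution / insertion / deletion) and the Ts/Tv
#' ratio of that population's single-base substitutions.  Percentages are
#' computed from the row's own total.
#'
#' @param cohort A filtered \code{CohortVariants} whose variant table
#'   carries a \code{known} flag (see \code{\link{annotateNovelty}}; absent
#'   flags yield NA known/novel columns).
#' @param population A population name, or \code{NULL} for all populations.
#' @return data.frame with columns \code{population}, \code{total},
#'   \code{known}, \code{novel}, \code{known_pct}, \code{novel_pct},
#'   \code{substitution}, \code{insertion}, \code{deletion},
#'   \code{substitution_pct}, \code{insertion_pct}, \code{deletion_pct},
#'   \code{ts}, \code{tv}, \code{ts_tv}.
#' @export
populationSummary <- function(cohort, population = NULL) {
    stopifnot(methods::is(cohort, "CohortVariants"))
    pops <- colnames(cohort@presence)
    if (is.null(population)) population <- pops
    bad <- setdiff(population, pops)
    if (length(bad))
        stop("population(s) absent from cohort: ", paste(bad, collapse = ", "))
    v <- cohort@variants
    has_known <- !is.null(v$known)
    res <- do.call(rbind, lapply(population, function(p) {
        sel <- cohort@presence[, p]
        tot <- sum(sel)
        sub <- sum(sel & v$vtype == "substitution")
        ins <- sum(sel & v$vtype == "insertion")
        del <- sum(sel & v$vtype == "deletion")
        kn <- if (has_known) sum(sel & v$known) else NA_integer_
        snv <- sel & nchar(v$ref) == 1L & nchar(v$alt) == 1L
        ts <- if (any(snv)) sum(isTransition(v$ref[snv], v$alt[snv])) else 0L
        tv <- sum(snv) - ts
        pct <- function(x) if (tot > 0) 100 * x / tot else NA_real_
        data.frame(population = p, total = tot,
                   known = kn, novel = if (has_known) tot - kn else NA_integer_,
                   known_pct = pct(kn), novel_pct = pct(tot - kn),
                   substitution = sub, insertion = ins, deletion = del,
                   substitution_pct = pct(sub), insertion_pct = pct(ins),
                   deletion_pct = pct(del),
                   ts = ts, tv = tv,
                   ts_tv = if (tv > 0) ts / tv else NA_real_)
    }))
    rownames(res) <- NULL
    res
}

#' Aggregate per-population summary rows
#'
#' Two aggregation schemes are supported because published per-population
#' tables mix them: \code{mean_of_rows} averages every column across rows
#' (count columns as plain means, percentage columns as means of row
#' percentages), while \code{pooled} sums the count columns and derives
#' percentages from the summed counts.  The two agree exactly when all
#' rows have equal totals.
#'
#' @param rows data.frame of summary rows (\code{\link{populationSummary}}
#'   output, or any table with a \code{total} column plus count /
#'   \code{*_pct} / \code{ts_tv} columns).
#' @param scheme \code{"mean_of_rows"} or \code{"pooled"}.
#' @return One-row data.frame of aggregates (unrounded).
#' @export
aggregateRows <- function(rows, scheme = c("mean_of_rows", "pooled")) {
    scheme <- match.arg(scheme)
    rows <- as.data.frame(rows)
    if (!nrow(rows)) stop("at least one summary row is required")
    count_cols <- intersect(c("total", "known", "novel", "substitution",
                              "insertion", "deletion", "ts", "tv"),
                            names(rows))
    pct_cols <- grep("_pct$", names(rows), value = TRUE)
    out <- data.frame(row.names = NULL, scheme = scheme)
    if (scheme == "mean_of_rows") {
        for (cc in count_cols) out[[cc]] <- mean(rows[[cc]])
        for (pc in pct_cols) out[[pc]] <- mean(rows[[pc]])
        if ("ts_tv" %in% names(rows))
            out$ts_tv <- mean(rows$ts_tv, na.rm = TRUE)
    } else {
        for (cc in count_cols) out[[cc]] <- sum(rows[[cc]])
        for (pc in pct_cols) {
            base <- sub("_pct$", "", pc)
            out[[pc]] <- if (base %in% names(rows))
                100 * sum(rows[[base]]) / sum(rows$total) else NA_real_
        }
        out$ts_tv <- if (all(c("ts", "tv") %in% names(rows)) &&
                         sum(rows$tv) > 0)
            sum(rows$ts) / sum(rows$tv) else NA_real_
    }
    out
}

#' Round an aggregate row to presentation precision
#'
#' Half-up rounding: counts to integers, percentages and ratios to one /
#' two decimals, applied only at presentation.
#'
#' @param row One-row data.frame from \code{\link{aggregateRows}}.
#' @return The row with rounded values.
#' @export
presentationRound <- function(row) {
    half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d
    for (nm in names(row)) {
        if (nm == "scheme") next
        if (grepl("_pct$", nm)) row[[nm]] <- half_up(row[[nm]], 1)
        else if (nm == "ts_tv") row[[nm]] <- half_up(row[[nm]], 2)
        else row[[nm]] <- half_up(row[[nm]], 0)
    }
    row
}

#' Bundled published per-population core-promoter variant summary
#'
#' Loads the package's snapshot of a published per-population summary of
#' core-promoter variants called from the 1000 Genomes exome cohort (25
#' populations; minimum two carriers per population): total variants,
#' known/novel split against the 1000 Genomes catalog, type counts and
#' Ts/Tv ratio, with the percentages as printed.  Used as the worked
#' example for the aggregation schemes.
#'
#' @param path Optional path to an alternative TSV with the same columns.
#' @return data.frame with one row per population.
#' @export
readPopulationSummaryTable <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "population_variant_summary.tsv",
                            package = "CorePromVar", mustWork = TRUE)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            comment.char = "")
    int_cols <- c("total", "known", "novel", "substitution", "insertion",
                  "deletion")
    for (cc in intersect(int_cols, names(df)))
        df[[cc]] <- as.integer(df[[cc]])
    df
}

#' Write a summary table as TSV
#'
#' @param rows Summary rows (\code{\link{populationSummary}} output).
#' @param path Output TSV path.
#' @param aggregate Append aggregate rows under both schemes.
#' @return The path, invisibly.
#' @export
writeSummaryTable <- function(rows, path, aggregate = TRUE) {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (aggregate) {
        agg <- rbind(aggregateRows(rows, "mean_of_rows"),
                     aggregateRows(rows, "pooled"))
        suppressWarnings(utils::write.table(
            agg, path, sep = "\t", quote = FALSE,
            row.names = FALSE, append = TRUE))
    }
    invisible(path)
}
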