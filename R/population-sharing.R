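#' @include AllClasses.R
NULL

.sharingLevels <- c("private_to_population", "private_to_continent",
                    "shared_across_continents", "shared_across_all_continents")

#' Classify population presence patterns into four sharing classes
#'
#' Each variant's set of populations where it is present maps to exactly
#' one of four mutually exclusive classes: \emph{private to population}
#' (one population), \emph{private to continent} (several populations, all
#' in one continent), \emph{shared across continents} (at least two but not
#' all manifest continents) and \emph{shared across all continents} (at
#' least one population in every continent the manifest defines).
#'
#' @param presence Either a logical matrix (variants x populations,
#'   population names as columns) or a list of character vectors of
#'   population codes.
#' @param manifest data.frame with columns \code{population} and
#'   \code{continent} (sample column optional).
#' @return Factor with the four sharing classes as levels.
#' @examples
#' man <- data.frame(population = c("YRI", "ESN", "CHB"),
#'                   continent = c("AFR", "AFR", "EAS"))
#' classifySharing(list("YRI", c("YRI", "ESN"), c("YRI", "CHB")), man)
#' @export
classifySharing <- function(presence, manifest) {
    manifest <- unique(as.data.frame(manifest)[c("population", "continent")])
    if (is.matrix(presence)) {
        pops <- colnames(presence)
        presence <- apply(presence, 1L, function(r) pops[r], simplify = FALSE)
    }
    all_conts <- unique(manifest$continent)
    cls <- vapply(presence, function(ps) {
        if (!length(ps)) stop("empty presence set cannot be classified")
        unknown <- setdiff(ps, manifest$population)
        if (length(unknown))
            stop("unknown population(s): ", paste(unknown, collapse = ", "))
        conts <- unique(manifest$continent[match(ps, manifest$population)])
        if (length(ps) == 1L) .sharingLevels[1]
        else if (length(conts) == 1L) .sharingLevels[2]
        else if (length(conts) < length(all_conts)) .sharingLevels[3]
        else .sharingLevels[4]
    }, character(1))
    factor(cls, levels = .sharingLevels)
}

#' Per-population sharing spectra
#'
#' For each population, every variant present there contributes once under
#' its \emph{global} sharing class (so a variant present everywhere adds a
#' shared-across-all-continents count to every population's spectrum).
#'
#' @param cohort A \code{CohortVariants} (filtered, so presence reflects
#'   the minimum-carrier rule).
#' @return data.frame with one row per (population, class): columns
#'   \code{population}, \code{class}, \code{count}, \code{proportion},
#'   \code{total}.  Proportions within a population sum to 1.
#' @export
sharingSpectrum <- function(cohort) {
    stopifnot(methods::is(cohort, "CohortVariants"))
    presence <- cohort@presence
    cls <- classifySharing(presence, cohort@manifest)
    pops <- colnames(presence)
    res <- do.call(rbind, lapply(pops, function(p) {
        counts <- table(cls[presence[, p]])
        total <- sum(counts)
        data.frame(population = p, class = .sharingLevels,
                   count = as.integer(counts[.sharingLevels]),
                   proportion = if (total > 0)
                       as.numeric(counts[.sharingLevels]) / total
                   else rep(NA_real_, 4L),
                   total = total)
    }))
    rownames(res) <- NULL
    res
}

#' Goodness-of-fit comparison of a sharing spectrum against reference
#' proportions
#'
#' Chi-squared goodness-of-fit of observed four-class counts against
#' expected counts \code{total * reference} (3 degrees of freedom),
#' suitable for contrasting a core-promoter spectrum with genome-wide
#' reference proportions.  Reference proportions are an input (e.g. read
#' from a published genome-wide table), never derived here.
#'
#' @param observed Integer vector of observed class counts (length >= 2).
#' @param reference Numeric vector of reference proportions, same length,
#'   summing to 1.
#' @return List with \code{statistic}, \code{df}, \code{p.value},
#'   \code{expected}.
#' @export
compareSpectrum <- function(observed, reference) {
    if (length(observed) != length(reference))
        stop("observed and reference lengths differ")
    if (sum(observed) <= 0)
        stop("observed total must be positive")
    if (abs(sum(reference) - 1) > 1e-6)
        stop("reference proportions must sum to 1 (got ",
             format(sum(reference)), ")")
    expected <- sum(observed) * reference
    if (any(expected == 0))
        stop("zero expected count; pool categories before testing")
    ct <- suppressWarnings(stats::chisq.test(observed, p = reference))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p.value = unname(ct$p.value), expected = expected)
}

#' Read a genome-wide reference spectrum table
#'
#' @param path TSV with header \code{population} plus the four sharing
#'   class columns (proportions).
#' @return data.frame keyed by population.
#' @export
readReferenceSpectrum <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            comment.char = "")
    names(df) <- tolower(names(df))
    miss <- setdiff(c("population", .sharingLevels), names(df))
    if (length(miss))
        stop("reference table lacks columns: ", paste(miss, collapse = ", "))
    df[c("population", .sharingLevels)]
}

#' Most-widespread variants per population
#'
#' Ranks each population's variants by within-population carrier count
#' (ties broken deterministically by chrom, pos, ref, alt) and annotates
#' the global sharing class, supporting statements such as "55 variants
#' shared in 109 of 110 individuals" or "19 of the 27 most common variants
#' were private".
#'
#' @param cohort A filtered \code{CohortVariants}.
#' @param topK Number of top variants per population (default 10).
#' @return data.frame: \code{population}, \code{rank}, \code{key},
#'   \code{carriers}, \code{class}.
#' @export
commonVariantReport <- function(cohort, topK = 10L) {
    stopifnot(methods::is(cohort, "CohortVariants"))
    cls <- classifySharing(cohort@presence, cohort@manifest)
    v <- cohort@variants
    res <- lapply(colnames(cohort@carriers), function(p) {
        idx <- which(cohort@presence[, p])
        if (!length(idx)) return(NULL)
        cc <- cohort@carriers[idx, p]
        ord <- order(-cc, v$chrom[idx], v$pos[idx], v$ref[idx], v$alt[idx])
        take <- utils::head(ord, topK)
        data.frame(population = p, rank = seq_along(take),
                   key = v$key[idx][take], carriers = as.integer(cc[take]),
                   class = as.character(cls[idx][take]))
    })
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(population = character(), rank = integer(),
                          key = character(), carriers = integer(),
                          class = character())
    rownames(out) <- NULL
    out
}
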