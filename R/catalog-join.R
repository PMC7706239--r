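#' @include AllClasses.R
NULL

#' Read a known-variant catalog snapshot
#'
#' @param path TSV with header columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} and optionally \code{rsid} and \code{source}.
#'   Coordinates are normalised with the same rules as cohort variants so
#'   keys are comparable.
#' @return data.frame with columns \code{key}, \code{rsid}, \code{source}.
#' @export
readKnownCatalog <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", comment.char = "")
    names(df) <- tolower(names(df))
    miss <- setdiff(c("chrom", "pos", "ref", "alt"), names(df))
    if (length(miss))
        stop("known catalog lacks columns: ", paste(miss, collapse = ", "))
    norm <- normalizeVariant(df$chrom, as.integer(df$pos), df$ref, df$alt)
    data.frame(key = variantKey(norm$chrom, norm$pos, norm$ref, norm$alt),
               rsid = if (!is.null(df$rsid)) df$rsid else NA_character_,
               source = if (!is.null(df$source)) df$source else NA_character_)
}

#' Flag variants as known or novel against a catalog
#'
#' A variant is \emph{known} when its normalised coordinate key appears in
#' the catalog, or (fallback) when it carries an rsID listed there;
#' otherwise it is \emph{novel}.  Adds a logical \code{known} column to the
#' cohort's variant table and tabulates per-population known/novel counts
#' and percentages over the populations where each variant is present.
#'
#' @param cohort A \code{CohortVariants}.
#' @param catalog data.frame from \code{\link{readKnownCatalog}} (or any
#'   data.frame with \code{key} and optionally \code{rsid} columns).
#' @return List: \code{cohort} (with \code{known} flag),
#'   \code{by_population} (data.frame: population, total, known, novel,
#'   known_pct, novel_pct), \code{overall} (the same for all distinct
#'   variants).
#' @export
annotateNovelty <- function(cohort, catalog) {
    stopifnot(methods::is(cohort, "CohortVariants"))
    catalog <- as.data.frame(catalog)
    v <- cohort@variants
    known <- v$key %in% catalog$key
    if (!is.null(catalog$rsid)) {
        crs <- catalog$rsid[!is.na(catalog$rsid) & nzchar(catalog$rsid)]
        known <- known | (!is.na(v$rsid) & v$rsid %in% crs)
    }
    v$known <- known
    cohort@variants <- v
    pops <- colnames(cohort@presence)
    by_pop <- do.call(rbind, lapply(pops, function(p) {
        sel <- cohort@presence[, p]
        tot <- sum(sel); kn <- sum(known & sel)
        data.frame(population = p, total = tot, known = kn,
                   novel = tot - kn,
                   known_pct = if (tot > 0) 100 * kn / tot else NA_real_,
                   novel_pct = if (tot > 0) 100 * (tot - kn) / tot
                               else NA_real_)
    }))
    overall <- data.frame(total = nrow(v), known = sum(known),
                          novel = sum(!known),
                          known_pct = 100 * mean(known),
                          novel_pct = 100 * mean(!known))
    list(cohort = cohort, by_population = by_pop, overall = overall)
}

#' Read an eQTL table snapshot
#'
#' @param path TSV with header columns \code{rsid} and/or \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}; plus \code{gene}, \code{tissue},
#'   \code{p} and optionally \code{beta_sign}.
#' @return data.frame with a \code{key} column when coordinates are
#'   available.
#' @export
readEqtlTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", comment.char = "")
    names(df) <- tolower(names(df))
    if (!"p" %in% names(df))
        stop("eQTL table lacks a 'p' column")
    df$p <- as.numeric(df$p)
    if (any(is.na(df$p) | df$p <= 0 | df$p > 1))
        stop("eQTL p-values must lie in (0, 1]")
    if (all(c("chrom", "pos", "ref", "alt") %in% names(df))) {
        norm <- normalizeVariant(df$chrom, as.integer(df$pos), df$ref, df$alt)
        df$key <- variantKey(norm$chrom, norm$pos, norm$ref, norm$alt)
    }
    df
}

#' Join variants with an eQTL table
#'
#' Matches eQTL rows to cohort variants by normalised coordinate key when
#' the table carries coordinates, and by rsID otherwise (both are
#' supported; key matches take precedence).  An association is significant
#' when \code{p < alpha} (strict); a variant is \emph{expression-altering}
#' when significant in at least one tissue.  The per-variant best tissue
#' (minimum p) is reported.
#'
#' @param cohort A \code{CohortVariants}.
#' @param eqtl data.frame from \code{\link{readEqtlTable}}.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return List: \code{associations} (matched rows with
#'   \code{significant}), \code{altering_keys} (expression-altering variant
#'   keys), \code{best} (per matched variant: key, gene, tissue, p),
#'   \code{fraction_altering} (over all distinct cohort variants).
#' @export
joinEqtl <- function(cohort, eqtl, alpha = 0.05) {
    stopifnot(methods::is(cohort, "CohortVariants"))
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
        stop("'alpha' must lie in (0, 1)")
    eqtl <- as.data.frame(eqtl)
    v <- cohort@variants
    if (!is.null(eqtl$key)) {
        m <- match(eqtl$key, v$key)
    } else if (!is.null(eqtl$rsid)) {
        m <- match(eqtl$rsid, v$rsid, incomparables = NA)
    } else stop("eQTL table needs 'key' (coordinates) or 'rsid' columns")
    hit <- !is.na(m)
    assoc <- eqtl[hit, , drop = FALSE]
    assoc$key <- v$key[m[hit]]
    assoc$significant <- assoc$p < alpha
    altering <- unique(assoc$key[assoc$significant])
    best <- NULL
    if (nrow(assoc)) {
        ord <- order(assoc$key, assoc$p)
        a <- assoc[ord, , drop = FALSE]
        best <- a[!duplicated(a$key),
                  intersect(c("key", "gene", "tissue", "p", "significant"),
                            names(a)), drop = FALSE]
        rownames(best) <- NULL
    }
    list(associations = assoc, altering_keys = altering, best = best,
         fraction_altering = if (nrow(v)) length(altering) / nrow(v)
                             else NA_real_)
}

#' Read a GWAS-trait table snapshot
#'
#' @param path TSV with header columns \code{rsid}, \code{trait} and
#'   optionally \code{ancestry}.
#' @return data.frame with those columns.
#' @export
readGwasTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", comment.char = "",
                            quote = "")
    names(df) <- tolower(names(df))
    miss <- setdiff(c("rsid", "trait"), names(df))
    if (length(miss))
        stop("GWAS table lacks columns: ", paste(miss, collapse = ", "))
    if (any(!nzchar(df$rsid)))
        stop("GWAS rsIDs must be non-empty")
    df
}

#' Join variants with GWAS-trait records
#'
#' Matches on rsID (variants without an rsID are skipped; their number is
#' reported via a message).  Each matched trait is annotated with the
#' continents of the populations where the variant is present, and a
#' trait-by-continent presence matrix is built to distinguish traits shared
#' across continents from population- or continent-specific ones.
#'
#' @param cohort A filtered \code{CohortVariants}.
#' @param gwas data.frame from \code{\link{readGwasTable}}.
#' @return List: \code{matches} (key, rsid, trait, continents),
#'   \code{trait_by_continent} (logical matrix), \code{n_skipped}
#'   (variants lacking rsIDs).
#' @export
joinGwas <- function(cohort, gwas) {
    stopifnot(methods::is(cohort, "CohortVariants"))
    gwas <- as.data.frame(gwas)
    v <- cohort@variants
    no_rs <- sum(is.na(v$rsid) | !nzchar(v$rsid))
    if (no_rs)
        message(no_rs, " variant(s) lack rsIDs and cannot match GWAS records")
    m <- match(gwas$rsid, v$rsid, incomparables = NA)
    hit <- !is.na(m)
    if (!any(hit))
        return(list(matches = data.frame(key = character(),
                                         rsid = character(),
                                         trait = character(),
                                         continents = character()),
                    trait_by_continent = matrix(FALSE, 0L, 0L),
                    n_skipped = no_rs))
    man <- unique(cohort@manifest[c("population", "continent")])
    conts_of <- function(key) {
        pres <- cohort@presence[key, ]
        sort(unique(man$continent[match(names(pres)[pres], man$population)]))
    }
    keys <- v$key[m[hit]]
    cl <- lapply(keys, conts_of)
    matches <- data.frame(key = keys, rsid = gwas$rsid[hit],
                          trait = gwas$trait[hit],
                          continents = vapply(cl, paste, character(1),
                                              collapse = ","))
    traits <- sort(unique(matches$trait))
    all_conts <- sort(unique(man$continent))
    tbc <- matrix(FALSE, length(traits), length(all_conts),
                  dimnames = list(traits, all_conts))
    for (i in seq_len(nrow(matches)))
        tbc[matches$trait[i], cl[[i]]] <- TRUE
    list(matches = matches, trait_by_continent = tbc, n_skipped = no_rs)
}
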