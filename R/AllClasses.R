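#' @include AllGenerics.R
NULL

#' PromoterSet: strand-aware core-promoter intervals
#'
#' A \code{PromoterSet} holds one interval per core promoter, anchored at a
#' transcription start site (TSS) and extended \code{windowUp} bp upstream and
#' \code{windowDown} bp downstream in the direction of transcription.  The
#' TSS itself occupies TSS-relative offset 0, so each interval spans
#' \code{windowUp + windowDown + 1} genomic positions.  Promoter identity is
#' the triple (chromosome, TSS, strand); TSS records sharing that triple are
#' merged and their gene identifiers pooled, so one promoter may serve
#' several genes and one gene may own several promoters.
#'
#' @slot promoters A \link[GenomicRanges]{GRanges} with one range per
#'   promoter and metadata columns \code{promoter_id} (unique character),
#'   \code{tss} (1-based genomic TSS coordinate) and \code{gene_ids}
#'   (\link[IRanges]{CharacterList} of genes sharing the promoter).
#' @slot windowUp,windowDown Single non-negative integers: bp upstream /
#'   downstream of the TSS in transcription direction (default 100 each).
#'
#' @section Accessors:
#' \describe{
#'   \item{\code{promoterIds(x)}}{character vector of promoter identifiers.}
#'   \item{\code{promoterRanges(x)}}{the underlying \code{GRanges}.}
#'   \item{\code{windowUp(x)}, \code{windowDown(x)}}{window half-widths.}
#'   \item{\code{length(x)}}{number of promoters.}
#' }
#'
#' @seealso \code{\link{buildCorePromoters}}, \code{\link{tssRelativeOffset}}
#' @aliases promoterIds promoterRanges windowUp windowDown
#' @name PromoterSet-class
#' @exportClass PromoterSet
setClass("PromoterSet",
    representation(
        promoters  = "GRanges",
        windowUp   = "integer",
        windowDown = "integer"
    )
)

setValidity("PromoterSet", function(object) {
    gr <- object@promoters
    up <- object@windowUp
    down <- object@windowDown
    msg <- character()
    if (length(up) != 1L || is.na(up) || up < 0L)
        msg <- c(msg, "'windowUp' must be a single non-negative integer")
    if (length(down) != 1L || is.na(down) || down < 0L)
        msg <- c(msg, "'windowDown' must be a single non-negative integer")
    need <- c("promoter_id", "tss", "gene_ids")
    miss <- setdiff(need, colnames(S4Vectors::mcols(gr)))
    if (length(miss))
        return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
    if (anyDuplicated(gr$promoter_id))
        msg <- c(msg, "'promoter_id' values must be unique")
    if (length(gr)) {
        if (!all(GenomicRanges::width(gr) == up + down + 1L))
            msg <- c(msg, "all interval widths must equal windowUp + windowDown + 1")
        inside <- gr$tss >= GenomicRanges::start(gr) & gr$tss <= GenomicRanges::end(gr)
        if (!all(inside))
            msg <- c(msg, "every interval must contain its TSS")
        if (any(!as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
            msg <- c(msg, "strand must be '+' or '-' for every promoter")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname PromoterSet-class
#' @param x A \code{PromoterSet}.
#' @export
setMethod("promoterIds", "PromoterSet", function(x) x@promoters$promoter_id)

#' @rdname PromoterSet-class
#' @export
setMethod("promoterRanges", "PromoterSet", function(x) x@promoters)

#' @rdname PromoterSet-class
#' @export
setMethod("windowUp", "PromoterSet", function(x) x@windowUp)

#' @rdname PromoterSet-class
#' @export
setMethod("windowDown", "PromoterSet", function(x) x@windowDown)

#' @rdname PromoterSet-class
#' @export
setMethod("length", "PromoterSet", function(x) length(x@promoters))

setMethod("show", "PromoterSet", function(object) {
    cat("PromoterSet with", length(object), "core promoters\n")
    cat("  window: -", object@windowUp, " .. +", object@windowDown,
        " (TSS = offset 0, ", object@windowUp + object@windowDown + 1L,
        " positions)\n", sep = "")
    if (length(object)) {
        chr <- unique(as.character(GenomeInfoDb::seqnames(object@promoters)))
        cat("  seqnames:", paste(utils::head(chr, 5), collapse = ", "),
            if (length(chr) > 5) "..." else "", "\n")
    }
})

#' CohortVariants: normalised promoter variants with population structure
#'
#' A \code{CohortVariants} object holds the distinct, normalised variants of
#' a multi-population cohort restricted to core-promoter windows, together
#' with per-population carrier counts, the variant-to-promoter offset map,
#' and the sample manifest.  A \emph{carrier} is an individual with at least
#' one alternate allele; a variant is \emph{present} in a population when it
#' has at least \code{minCarriers} carriers there (the presence matrix is
#' recomputed by \code{\link{applyCarrierFilter}}).
#'
#' The distinct-variant key is \code{chrom:pos:ref:alt} after normalisation;
#' rsIDs are annotation only.
#'
#' @slot variants \code{data.frame}, one row per distinct variant: columns
#'   \code{key}, \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{rsid} (NA when absent), \code{vtype} (substitution / insertion /
#'   deletion) plus any annotation columns added downstream (e.g.
#'   \code{known}).
#' @slot carriers integer matrix (variants x populations) of carrier counts;
#'   rownames are variant keys.
#' @slot presence logical matrix, same shape: presence after the
#'   minimum-carrier filter (before filtering it reflects \code{carriers >= 1}).
#' @slot map \code{data.frame}, one row per (variant, promoter) assignment:
#'   \code{key}, \code{promoter_id}, \code{offset} (TSS-relative offset of
#'   the transcriptionally first affected in-window base),
#'   \code{offset_start}, \code{offset_end} (affected span, transcription
#'   direction).
#' @slot manifest \code{data.frame} with columns \code{sample},
#'   \code{population}, \code{continent}.
#' @slot minCarriers integer; \code{NA} until \code{applyCarrierFilter} has
#'   been applied.
#'
#' @section Accessors:
#' \code{variantTable(x)}, \code{carrierCounts(x)}, \code{presenceMatrix(x)},
#' \code{promoterMap(x)}, \code{cohortManifest(x)}, \code{populationNames(x)},
#' \code{continentNames(x)}, \code{length(x)} (number of distinct variants).
#'
#' @seealso \code{\link{loadCohortVariants}}, \code{\link{applyCarrierFilter}},
#'   \code{\link{classifySharing}}, \code{\link{sharingSpectrum}}
#' @aliases variantTable carrierCounts presenceMatrix promoterMap
#'   cohortManifest populationNames continentNames
#' @name CohortVariants-class
#' @exportClass CohortVariants
setClass("CohortVariants",
    representation(
        variants    = "data.frame",
        carriers    = "matrix",
        presence    = "matrix",
        map         = "data.frame",
        manifest    = "data.frame",
        minCarriers = "integer"
    )
)

setValidity("CohortVariants", function(object) {
    v <- object@variants
    msg <- character()
    need <- c("key", "chrom", "pos", "ref", "alt", "rsid", "vtype")
    miss <- setdiff(need, colnames(v))
    if (length(miss))
        return(paste("variants lacks columns:", paste(miss, collapse = ", ")))
    if (anyDuplicated(v$key))
        msg <- c(msg, "variant keys must be unique")
    if (nrow(v) != nrow(object@carriers) || nrow(v) != nrow(object@presence))
        msg <- c(msg, "carriers/presence must have one row per variant")
    if (!identical(colnames(object@carriers), colnames(object@presence)))
        msg <- c(msg, "carriers and presence must share population columns")
    if (!all(colnames(object@carriers) %in% object@manifest$population))
        msg <- c(msg, "carrier columns must be populations of the manifest")
    if (nrow(v) && any(object@carriers < 0))
        msg <- c(msg, "carrier counts must be >= 0")
    mneed <- c("key", "promoter_id", "offset", "offset_start", "offset_end")
    mmiss <- setdiff(mneed, colnames(object@map))
    if (length(mmiss))
        msg <- c(msg, paste("map lacks columns:", paste(mmiss, collapse = ", ")))
    if (!all(object@map$key %in% v$key))
        msg <- c(msg, "map keys must exist in the variant table")
    if (length(msg)) msg else TRUE
})

#' Construct a CohortVariants object
#'
#' Low-level constructor; most users obtain a cohort from
#' \code{\link{loadCohortVariants}}.  Useful to assemble small cohorts
#' directly from tables, e.g. in examples and simulations.
#'
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} and optionally \code{rsid}; \code{key} and
#'   \code{vtype} are derived if absent.
#' @param carriers integer matrix (variants x populations).
#' @param map data.frame of (variant, promoter) offset assignments (may be
#'   empty; columns as in the class description).
#' @param manifest data.frame with columns \code{sample}, \code{population},
#'   \code{continent} (a population-level manifest with one pseudo-sample per
#'   population is accepted).
#' @return A \code{CohortVariants} with presence set to \code{carriers >= 1}
#'   and \code{minCarriers = NA} (i.e. unfiltered).
#' @export
CohortVariants <- function(variants, carriers, map = NULL, manifest) {
    variants <- as.data.frame(variants)
    if (is.null(variants$rsid)) variants$rsid <- NA_character_
    if (is.null(variants$vtype))
        variants$vtype <- classifyVariantType(variants$ref, variants$alt)
    if (is.null(variants$key))
        variants$key <- variantKey(variants$chrom, variants$pos,
                                   variants$ref, variants$alt)
    carriers <- as.matrix(carriers)
    storage.mode(carriers) <- "integer"
    rownames(carriers) <- variants$key
    if (is.null(map))
        map <- data.frame(key = character(), promoter_id = character(),
                          offset = integer(), offset_start = integer(),
                          offset_end = integer())
    methods::new("CohortVariants",
        variants = variants, carriers = carriers,
        presence = carriers >= 1L, map = as.data.frame(map),
        manifest = as.data.frame(manifest), minCarriers = NA_integer_)
}

#' @rdname CohortVariants-class
#' @param x A \code{CohortVariants}.
#' @export
setMethod("variantTable", "CohortVariants", function(x) x@variants)

#' @rdname CohortVariants-class
#' @export
setMethod("carrierCounts", "CohortVariants", function(x) x@carriers)

#' @rdname CohortVariants-class
#' @export
setMethod("presenceMatrix", "CohortVariants", function(x) x@presence)

#' @rdname CohortVariants-class
#' @export
setMethod("promoterMap", "CohortVariants", function(x) x@map)

#' @rdname CohortVariants-class
#' @export
setMethod("cohortManifest", "CohortVariants", function(x) x@manifest)

#' @rdname CohortVariants-class
#' @export
setMethod("populationNames", "CohortVariants", function(x) colnames(x@carriers))

#' @rdname CohortVariants-class
#' @export
setMethod("continentNames", "CohortVariants", function(x)
    sort(unique(x@manifest$continent)))

#' @rdname CohortVariants-class
#' @export
setMethod("length", "CohortVariants", function(x) nrow(x@variants))

setMethod("show", "CohortVariants", function(object) {
    cat("CohortVariants:", nrow(object@variants), "distinct variants,",
        ncol(object@carriers), "populations,",
        length(unique(object@manifest$continent)), "continents\n")
    if (!is.na(object@minCarriers))
        cat("  presence filter: >=", object@minCarriers,
            "carriers per population\n")
    else
        cat("  unfiltered (presence = any carrier)\n")
    if (nrow(object@variants)) {
        tab <- table(object@variants$vtype)
        cat("  types:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
    cat("  promoter assignments:", nrow(object@map), "\n")
})
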