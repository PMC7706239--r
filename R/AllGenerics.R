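#' @rdname PromoterSet-class
#' @export
setGeneric("promoterIds", function(x) standardGeneric("promoterIds"))

#' @rdname PromoterSet-class
#' @export
setGeneric("promoterRanges", function(x) standardGeneric("promoterRanges"))

#' @rdname PromoterSet-class
#' @export
setGeneric("windowUp", function(x) standardGeneric("windowUp"))

#' @rdname PromoterSet-class
#' @export
setGeneric("windowDown", function(x) standardGeneric("windowDown"))

#' @rdname CohortVariants-class
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname CohortVariants-class
#' @export
setGeneric("carrierCounts", function(x) standardGeneric("carrierCounts"))

#' @rdname CohortVariants-class
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname CohortVariants-class
#' @export
setGeneric("promoterMap", function(x) standardGeneric("promoterMap"))

#' @rdname CohortVariants-class
#' @export
setGeneric("cohortManifest", function(x) standardGeneric("cohortManifest"))

#' @rdname CohortVariants-class
#' @export
setGeneric("populationNames", function(x) standardGeneric("populationNames"))

#' @rdname CohortVariants-class
#' @export
setGeneric("continentNames", function(x) standardGeneric("continentNames"))
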