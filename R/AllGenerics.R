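#' Accessors for WindowProfile, SpikeInLibrary and SwitchingModel objects
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x the object.
#' @return `windowWidth`: integer width in bp; `isNormalized`: logical;
#'   `profileValues`: named list of per-window numeric vectors;
#'   `chromSizes`: named integer vector; `sampleId`, `condition`,
#'   `treatment`: character; `spikeReads`, `experimentalReads`,
#'   `yieldFactor`: numeric; `switchProb`: numeric.
#' @name accessors
#' @examples
#' wp <- windowCounts(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 75)),
#'                    c(chr1 = 1000))
#' windowWidth(wp)
#' isNormalized(wp)
NULL

#' @rdname accessors
#' @export
setGeneric("windowWidth", function(x) standardGeneric("windowWidth"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("spikeReads", function(x) standardGeneric("spikeReads"))
#' @rdname accessors
#' @export
setGeneric("experimentalReads", function(x) standardGeneric("experimentalReads"))
#' @rdname accessors
#' @export
setGeneric("yieldFactor", function(x) standardGeneric("yieldFactor"))
#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname accessors
#' @export
setGeneric("treatment", function(x) standardGeneric("treatment"))
#' @rdname accessors
#' @export
setGeneric("switchProb", function(x) standardGeneric("switchProb"))

#' @rdname accessors
#' @export
setMethod("windowWidth", "WindowProfile", function(x) x@windowWidth)
#' @rdname accessors
#' @export
setMethod("isNormalized", "WindowProfile", function(x) x@normalized)
#' @rdname accessors
#' @export
setMethod("profileValues", "WindowProfile", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("chromSizes", "WindowProfile", function(x) x@chromSizes)
#' @rdname accessors
#' @export
setMethod("sampleId", "WindowProfile", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("sampleId", "SpikeInLibrary", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("spikeReads", "SpikeInLibrary", function(x) x@readsSpike)
#' @rdname accessors
#' @export
setMethod("experimentalReads", "SpikeInLibrary", function(x) x@readsExperimental)
#' @rdname accessors
#' @export
setMethod("yieldFactor", "SpikeInLibrary", function(x) x@yieldFactor)
#' @rdname accessors
#' @export
setMethod("condition", "SpikeInLibrary", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("treatment", "SpikeInLibrary", function(x) x@treatment)
#' @rdname accessors
#' @export
setMethod("switchProb", "SwitchingModel", function(x) x@pSwitch)
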