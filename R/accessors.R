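#' Accessors for omrplate classes
#'
#' Small accessor generics for the geometry and layout classes: well
#' centre, radius, chord abscissae, target area fractions and alignment
#' direction of a \linkS4class{WellGeometry}; grid dimensions of a
#' \linkS4class{PlateLayout}.
#'
#' @param object a \linkS4class{WellGeometry} or \linkS4class{PlateLayout}.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases wellCenter wellRadius chordXs areaFractions alignDirection
NULL

#' @rdname accessors
#' @export
setGeneric("wellCenter", function(object) standardGeneric("wellCenter"))
#' @rdname accessors
#' @export
setGeneric("wellRadius", function(object) standardGeneric("wellRadius"))
#' @rdname accessors
#' @export
setGeneric("chordXs", function(object) standardGeneric("chordXs"))
#' @rdname accessors
#' @export
setGeneric("areaFractions", function(object) standardGeneric("areaFractions"))
#' @rdname accessors
#' @export
setGeneric("alignDirection", function(object) standardGeneric("alignDirection"))

#' @rdname accessors
setMethod("wellCenter", "WellGeometry", function(object) object@center)
#' @rdname accessors
setMethod("wellRadius", "WellGeometry", function(object) object@radius)
#' @rdname accessors
setMethod("chordXs", "WellGeometry", function(object) object@chordXs)
#' @rdname accessors
setMethod("areaFractions", "WellGeometry", function(object) {
  ## slot stores fractions left to right (Areas 4,3,2,1); report by label
  f <- rev(object@fractions)
  names(f) <- paste0("area", 1:4)
  f
})
#' @rdname accessors
setMethod("alignDirection", "WellGeometry", function(object) object@direction)
#' @rdname accessors
setMethod("wellRadius", "PlateLayout", function(object) object@wellRadius)

setMethod("show", "WellGeometry", function(object) {
  cat("WellGeometry\n")
  cat(sprintf("  center: (%g, %g)   radius: %g\n",
              object@center[1], object@center[2], object@radius))
  cat(sprintf("  chords (x/R): %s\n",
              paste(sprintf("%.4f", object@chordXs), collapse = ", ")))
  cat(sprintf("  area fractions (Areas 4,3,2,1): %s\n",
              paste(sprintf("%.2f", object@fractions), collapse = ", ")))
  cat(sprintf("  alignment direction: (%g, %g)\n",
              object@direction[1], object@direction[2]))
})

setMethod("show", "StimulusSpec", function(object) {
  tot <- object@leadWhiteS + object@gratingS + object@tailWhiteS
  cat("StimulusSpec\n")
  cat(sprintf("  segments: %g s white | %g s grating | %g s white (%g s total)\n",
              object@leadWhiteS, object@gratingS, object@tailWhiteS, tot))
  cat(sprintf("  bars: %g px wide, %g px/s right-to-left, %s profile",
              object@barWidth, object@speed, object@profile))
  if (object@profile == "sine")
    cat(sprintf(" (%g deg edge)", object@edgeDeg))
  cat(sprintf("\n  frame rate: %g fps (%d frames)\n",
              object@frameRate, nFrames(object)))
})

setMethod("show", "PlateLayout", function(object) {
  sz <- imageSize(object)
  cat(sprintf("PlateLayout: %d x %d wells (%d total)\n",
              object@rows, object@cols, object@rows * object@cols))
  cat(sprintf("  well radius %g px, pitch %g px, image %d x %d px\n",
              object@wellRadius, object@pitch, sz[1], sz[2]))
})

setMethod("show", "BehaviorParams", function(object) {
  cat(sprintf("BehaviorParams ('%s')\n", object@phenotype))
  cat(sprintf("  pAlign: %g   driftGain: %g R/s   noiseSd: %g R/sqrt(s)\n",
              object@pAlign, object@driftGain, object@noiseSd))
})

setMethod("show", "ActivityTrace", function(object) {
  cat(sprintf("ActivityTrace: %d bins over %g s (baseline %g s)\n",
              length(object@time), max(object@time), object@baselineS))
  cat(sprintf("  interruptions at: %s s\n",
              paste(object@interruptions, collapse = ", ")))
})
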