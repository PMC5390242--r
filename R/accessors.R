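#' Accessors for InvarianceDynamics classes
#'
#' Accessor generics for the package's S4 containers. `stimulusInfo` returns
#' the (object, transformation, level) manifest aligned to the stimulus
#' dimension; `images` the named list of image matrices; `spikeEvents` the
#' long spike-event table; `rateArray` the numeric rate array;
#' `activations` the units x stimuli matrix; `dissimilarities` the
#' stimulus x stimulus distance matrix.
#'
#' @param x an InvarianceDynamics object.
#' @return The corresponding slot content; see the class documentation.
#' @name accessors
#' @aliases stimulusInfo images spikeEvents rateArray activations
#'   dissimilarities
NULL

#' @rdname accessors
#' @export
setGeneric("stimulusInfo", function(x) standardGeneric("stimulusInfo"))
#' @rdname accessors
#' @export
setGeneric("images", function(x) standardGeneric("images"))
#' @rdname accessors
#' @export
setGeneric("spikeEvents", function(x) standardGeneric("spikeEvents"))
#' @rdname accessors
#' @export
setGeneric("rateArray", function(x) standardGeneric("rateArray"))
#' @rdname accessors
#' @export
setGeneric("activations", function(x) standardGeneric("activations"))
#' @rdname accessors
#' @export
setGeneric("dissimilarities", function(x) standardGeneric("dissimilarities"))

#' @rdname accessors
#' @export
setMethod("stimulusInfo", "StimulusSet", function(x) x@info)
#' @rdname accessors
#' @export
setMethod("stimulusInfo", "SpikeTable", function(x) x@stimulusInfo)
#' @rdname accessors
#' @export
setMethod("stimulusInfo", "ResponseTensor", function(x) x@stimulusInfo)
#' @rdname accessors
#' @export
setMethod("stimulusInfo", "ActivationMatrix", function(x) x@stimulusInfo)

#' @rdname accessors
#' @export
setMethod("images", "StimulusSet", function(x) x@images)
#' @rdname accessors
#' @export
setMethod("spikeEvents", "SpikeTable", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("rateArray", "ResponseTensor", function(x) x@rates)
#' @rdname accessors
#' @export
setMethod("activations", "ActivationMatrix", function(x) x@activations)
#' @rdname accessors
#' @export
setMethod("dissimilarities", "DissimilarityMatrix", function(x) x@values)

setMethod("show", "StimulusSet", function(object) {
  info <- object@info
  cat("StimulusSet:", nrow(info), "images,",
      length(unique(info$object_id)), "objects,",
      paste(object@canvas, collapse = "x"), "px canvas\n")
  lv <- info[info$level > 0, ]
  if (nrow(lv)) {
    spread <- tapply(lv$realized_delta,
                     list(lv$object_id, lv$level),
                     function(d) diff(range(d)) / mean(d))
    cat(sprintf("  max relative delta spread within (object, level): %.3g\n",
                max(spread, na.rm = TRUE)))
  }
})

setMethod("show", "SpikeTable", function(object) {
  cat("SpikeTable:", object@nNeurons, "neurons,",
      nrow(object@stimulusInfo), "stimuli,",
      object@nRepeats, "repeats,",
      nrow(object@events), "spikes in [",
      object@span[1], ",", object@span[2], ") ms\n")
})

setMethod("show", "ResponseTensor", function(object) {
  d <- dim(object@rates)
  if (length(d) == 3L) {
    cat(sprintf("ResponseTensor: %d neurons x %d stimuli x %d reps, window %g-%g ms\n",
                d[1], d[2], d[3], object@windowMs[1], object@windowMs[2]))
  } else {
    cat(sprintf("ResponseTensor: %d neurons x %d stimuli x %d reps x %d bins (%g-%g ms)\n",
                d[1], d[2], d[3], d[4], object@windowMs[1], object@windowMs[2]))
  }
})

setMethod("show", "ActivationMatrix", function(object) {
  cat(sprintf("ActivationMatrix [%s]: %d units x %d stimuli\n",
              object@source, nrow(object@activations), ncol(object@activations)))
})

setMethod("show", "DissimilarityMatrix", function(object) {
  v <- object@values
  cat(sprintf("DissimilarityMatrix [%s]: %d x %d, mean off-diagonal %.3f (%d NA)\n",
              object@source, nrow(v), ncol(v),
              mean(v[lower.tri(v)], na.rm = TRUE),
              sum(is.na(v[lower.tri(v)]))))
})

setMethod("show", "InvarianceTable", function(object) {
  cat("InvarianceTable:", length(unique(object@perNeuron$neuron_id)),
      "neurons, alpha =", object@alpha, "\n")
  print(object@summary, digits = 3, row.names = FALSE)
})

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult (chance =", format(object@chance, digits = 3), ")\n")
  a <- object@accuracy[object@accuracy$direction == "mean", , drop = FALSE]
  if (nrow(a)) print(a, digits = 3, row.names = FALSE)
  if (nrow(object@timeCourse))
    cat("  time course over", length(unique(object@timeCourse$bin_center_ms)),
        "bins\n")
  if (length(object@bootstrap))
    cat("  bootstrap:", nrow(object@bootstrap$latencies), "resamples\n")
})
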