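#' @import methods
NULL

TRANSFORMATIONS <- c("size", "position", "rotation", "view")

#' StimulusSet: balanced object images plus their transformation manifest
#'
#' Container for a set of grayscale object images indexed by
#' (object, transformation, level) together with the solved transformation
#' parameters and the realized net pixel change of every image relative to
#' the reference view of its object. A complete set holds, per object, one
#' reference image (level 0) and each of the four identity-preserving
#' transformations (size, position, rotation, view) at two change levels.
#'
#' @slot images named list of integer matrices (0--255, background 0); names
#'   follow `<object>_<transformation>_<level>`.
#' @slot info data.frame with one row per image: `object_id`,
#'   `transformation`, `level`, `parameter` (the solved scalar transformation
#'   parameter), `target_delta`, `realized_delta` (intensity-pixel units).
#' @slot canvas integer(2), image height and width in pixels.
#' @slot tolerance numeric(1), relative tolerance used when balancing the
#'   net pixel change across transformations.
#'
#' @seealso [buildStimulusSet()], [renderObject()], [netPixelChange()]
#' @export
setClass("StimulusSet",
  slots = c(
    images = "list",
    info = "data.frame",
    canvas = "integer",
    tolerance = "numeric"
  )
)

setValidity("StimulusSet", function(object) {
  msg <- character()
  info <- object@info
  needed <- c("object_id", "transformation", "level", "parameter",
              "target_delta", "realized_delta")
  if (!all(needed %in% names(info)))
    msg <- c(msg, paste("info must have columns:", paste(needed, collapse = ", ")))
  if (length(object@images) != nrow(info))
    msg <- c(msg, "one image per info row required")
  key <- paste(info$object_id, info$transformation, info$level, sep = "_")
  if (!identical(sort(names(object@images)), sort(key)))
    msg <- c(msg, "image names must match info (object_transformation_level)")
  dims <- vapply(object@images, function(im) identical(dim(im), object@canvas),
                 logical(1))
  if (!all(dims)) msg <- c(msg, "all images must match the canvas dimensions")
  rng <- vapply(object@images, function(im) min(im) >= 0 && max(im) <= 255,
                logical(1))
  if (!all(rng)) msg <- c(msg, "image intensities must lie in [0, 255]")
  ## structural completeness: per object 1 reference + 4 transformations x levels
  for (ob in unique(info$object_id)) {
    sub <- info[info$object_id == ob, ]
    if (sum(sub$transformation == "reference") != 1)
      msg <- c(msg, paste0("object ", ob, " needs exactly one reference image"))
    lv <- sort(unique(sub$level[sub$level > 0]))
    for (tr in TRANSFORMATIONS)
      if (!all(lv %in% sub$level[sub$transformation == tr]))
        msg <- c(msg, paste0("object ", ob, " missing levels for ", tr))
  }
  if (length(msg)) msg else TRUE
})

#' SpikeTable: spike events with trial and stimulus metadata
#'
#' The lingua franca between the population simulator and all analyses:
#' a long table of spike events (neuron, trial, stimulus, spike time in ms
#' relative to image onset) plus a trial table mapping trials to stimuli and
#' repetition indices, and the stimulus manifest.
#'
#' @slot events data.frame: `neuron_id`, `trial_id`, `stimulus_id`,
#'   `spike_time_ms`.
#' @slot trials data.frame: `trial_id`, `stimulus_id`, `rep`.
#' @slot stimulusInfo data.frame: `stimulus_id`, `object_id`,
#'   `transformation`, `level`.
#' @slot nNeurons integer(1) number of neurons (neuron ids are 1..nNeurons).
#' @slot nRepeats integer(1) repetitions per stimulus.
#' @slot span numeric(2) recorded window \[ms\] relative to image onset.
#' @slot config list, the simulation configuration that produced the table
#'   (empty for tables read from file).
#'
#' @seealso [simulatePopulation()], [windowRates()]
#' @export
setClass("SpikeTable",
  slots = c(
    events = "data.frame",
    trials = "data.frame",
    stimulusInfo = "data.frame",
    nNeurons = "integer",
    nRepeats = "integer",
    span = "numeric",
    config = "list"
  )
)

setValidity("SpikeTable", function(object) {
  msg <- character()
  ev <- object@events
  if (!all(c("neuron_id", "trial_id", "stimulus_id", "spike_time_ms") %in% names(ev)))
    msg <- c(msg, "events needs neuron_id, trial_id, stimulus_id, spike_time_ms")
  if (nrow(ev)) {
    if (any(ev$spike_time_ms < object@span[1] | ev$spike_time_ms >= object@span[2]))
      msg <- c(msg, sprintf("spike times must lie in [%g, %g) ms",
                            object@span[1], object@span[2]))
    if (any(ev$neuron_id < 1L | ev$neuron_id > object@nNeurons))
      msg <- c(msg, "neuron ids out of range")
  }
  tr <- object@trials
  if (nrow(tr)) {
    reps <- table(tr$stimulus_id)
    if (length(unique(reps)) > 1L || reps[1] != object@nRepeats)
      msg <- c(msg, "every stimulus must have exactly nRepeats trials")
  }
  if (length(msg)) msg else TRUE
})

#' ResponseTensor: trial-resolved firing rates
#'
#' Firing rates per (neuron, stimulus, repetition), either for a single
#' named time window (3D array) or per time bin (4D array with bins as the
#' fourth dimension). The stimulus dimension carries the
#' (object, transformation, level) manifest.
#'
#' @slot rates numeric array, neurons x stimuli x repetitions \[x bins\], sp/s.
#' @slot stimulusInfo data.frame aligned to the stimulus dimension:
#'   `stimulus_id`, `object_id`, `transformation`, `level`.
#' @slot windowMs numeric(2) the rate window, or the spanned period for
#'   binned tensors.
#' @slot binCenters numeric, bin centers in ms (length 0 for windowed
#'   tensors).
#'
#' @seealso [windowRates()], [binnedRates()]
#' @export
setClass("ResponseTensor",
  slots = c(
    rates = "array",
    stimulusInfo = "data.frame",
    windowMs = "numeric",
    binCenters = "numeric"
  )
)

setValidity("ResponseTensor", function(object) {
  msg <- character()
  d <- dim(object@rates)
  if (!(length(d) %in% c(3L, 4L)))
    msg <- c(msg, "rates must be a 3D or 4D array")
  if (length(d) >= 2 && d[2] != nrow(object@stimulusInfo))
    msg <- c(msg, "stimulus dimension must match stimulusInfo rows")
  if (length(d) == 4L && d[4] != length(object@binCenters))
    msg <- c(msg, "fourth dimension must match binCenters")
  if (length(d) == 3L && length(object@binCenters))
    msg <- c(msg, "windowed tensors must have empty binCenters")
  if (any(object@rates < 0)) msg <- c(msg, "rates must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ActivationMatrix: model-unit (or neural) activations per stimulus
#'
#' A units x stimuli matrix of activations with a source label and the
#' stimulus manifest aligned to its columns. Used both for computational
#' models (pixel, V1-Gabor, file-based deep features) and for neural data
#' (neurons x stimuli mean rates).
#'
#' @slot activations numeric matrix, units x stimuli; all finite.
#' @slot source character(1), e.g. "pixel", "v1", "external:conv5", "neural".
#' @slot stimulusInfo data.frame: `stimulus_id`, `object_id`,
#'   `transformation`, `level`, one row per column.
#'
#' @seealso [pixelFeatures()], [v1Features()], [rdm()], [unitInvariance()]
#' @export
setClass("ActivationMatrix",
  slots = c(
    activations = "matrix",
    source = "character",
    stimulusInfo = "data.frame"
  )
)

setValidity("ActivationMatrix", function(object) {
  msg <- character()
  if (ncol(object@activations) != nrow(object@stimulusInfo))
    msg <- c(msg, "column count must equal stimulus count")
  if (!all(is.finite(object@activations)))
    msg <- c(msg, "activations must be finite")
  if (length(object@source) != 1L)
    msg <- c(msg, "source must be a single label")
  if (length(msg)) msg else TRUE
})

#' DissimilarityMatrix: 1 - correlation distances between stimuli
#'
#' Symmetric stimulus x stimulus matrix of representational dissimilarities,
#' computed as one minus the Pearson correlation between activation columns.
#' Entries lie in \[0, 2\]; the diagonal is 0. Entries may be NA where a
#' column had zero variance.
#'
#' @slot values numeric matrix, stimuli x stimuli.
#' @slot source character(1) label of the representation.
#'
#' @seealso [rdm()], [rdmMatch()], [splitHalfReliability()]
#' @export
setClass("DissimilarityMatrix",
  slots = c(
    values = "matrix",
    source = "character"
  )
)

setValidity("DissimilarityMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12, check.attributes = FALSE)))
    msg <- c(msg, "matrix must be symmetric")
  if (any(abs(diag(v)) > 1e-12, na.rm = TRUE)) msg <- c(msg, "diagonal must be 0")
  if (any(v < -1e-12 | v > 2 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "values must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' InvarianceTable: per-neuron tuning-correlation invariance
#'
#' Per-neuron tuning correlations between responses to reference and
#' transformed images across objects, with significance flags, plus
#' per-condition summaries and pairwise between-transformation tests.
#'
#' @slot perNeuron data.frame: `neuron_id`, `transformation`, `level`, `r`,
#'   `p`, `invariant` (logical, p < alpha; NA where r undefined).
#' @slot summary data.frame per transformation x level: `mean_r`, `sem_r`,
#'   `n_defined`, `n_invariant`, `fraction_invariant`, `mean_r_invariant`.
#' @slot pairwise data.frame of pairwise transformation comparisons per
#'   level: sign-rank p on correlations and two-proportion chi-square on
#'   invariant fractions.
#' @slot alpha numeric(1) significance level used for the invariant flag.
#'
#' @seealso [invarianceTable()], [invarianceCovariation()]
#' @export
setClass("InvarianceTable",
  slots = c(
    perNeuron = "data.frame",
    summary = "data.frame",
    pairwise = "data.frame",
    alpha = "numeric"
  )
)

setValidity("InvarianceTable", function(object) {
  msg <- character()
  s <- object@summary
  if (nrow(s) && any(s$fraction_invariant < 0 | s$fraction_invariant > 1, na.rm = TRUE))
    msg <- c(msg, "fraction_invariant must lie in [0, 1]")
  p <- object@perNeuron
  if (nrow(p) && any(abs(p$r) > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' DecodingResult: cross-generalization population decoding output
#'
#' Accuracy of a linear readout trained on reference-image trials and
#' tested on transformed-image trials (and vice versa), with trial-wise
#' correctness, optional per-bin time courses with peak latencies, and an
#' optional neuron-bootstrap latency block.
#'
#' @slot accuracy data.frame: `transformation`, `level`, `direction`
#'   ("ref_to_trans", "trans_to_ref", "mean"), `accuracy`, `n_test`.
#' @slot correctness list of logical vectors of per-trial correctness,
#'   named `<transformation>_<level>_<direction>`.
#' @slot timeCourse data.frame (possibly empty): `bin_center_ms`,
#'   `transformation`, `level`, `accuracy`.
#' @slot peakLatency data.frame (possibly empty): `transformation`, `level`,
#'   `peak_latency_ms`.
#' @slot bootstrap list (possibly empty): `latencies` (resample x condition
#'   matrix of peak latencies, ms), `pairs` (data.frame of pairwise order
#'   fractions and sign-rank p-values), `flat_fraction`.
#' @slot chance numeric(1), 1 / number of decoded objects.
#'
#' @seealso [generalizationAccuracy()], [binnedDecoding()],
#'   [bootstrapLatencies()]
#' @export
setClass("DecodingResult",
  slots = c(
    accuracy = "data.frame",
    correctness = "list",
    timeCourse = "data.frame",
    peakLatency = "data.frame",
    bootstrap = "list",
    chance = "numeric"
  )
)

setValidity("DecodingResult", function(object) {
  msg <- character()
  a <- object@accuracy
  if (nrow(a) && any(a$accuracy < 0 | a$accuracy > 1, na.rm = TRUE))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(object@chance) == 1 && (object@chance <= 0 || object@chance > 1))
    msg <- c(msg, "chance must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
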