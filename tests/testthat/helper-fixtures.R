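## shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## small 4-object balanced set on a 64 px canvas (fast)
smallShapes <- function() {
  randomShapes(4, seed = 42, canvas = c(64L, 64L), baseRadius = 13)
}

smallSpec <- function() balanceSpec(shiftRange = c(0, 10))

smallStimuli <- function() {
  cached("smallStimuli", function() buildStimulusSet(smallShapes(), smallSpec()))
}

## the full 10-object study design (slow; reused by scenario + acceptance)
fullStimuli <- function() {
  cached("fullStimuli", function() buildStimulusSet(randomShapes(10, seed = 7042)))
}

## stimulus manifest without images, for simulator/analysis tests
makeManifest <- function(nObjects = 8) {
  objects <- sprintf("obj%02d", seq_len(nObjects))
  ref <- data.frame(object_id = objects, transformation = "reference", level = 0L)
  trans <- expand.grid(object_id = objects,
                       transformation = c("size", "position", "rotation", "view"),
                       level = 1:2, stringsAsFactors = FALSE)
  rbind(ref, trans[order(trans$object_id), ])
}

## hand-rolled SpikeTable for oracle tests
makeSpikeTable <- function(events, manifest, nNeurons, nRepeats,
                           span = c(0, 400)) {
  info <- manifest
  info$stimulus_id <- paste(info$object_id, info$transformation, info$level,
                            sep = "_")
  info <- info[, c("stimulus_id", "object_id", "transformation", "level")]
  nS <- nrow(info)
  trials <- data.frame(trial_id = seq_len(nS * nRepeats),
                       stimulus_id = rep(info$stimulus_id, times = nRepeats),
                       rep = rep(seq_len(nRepeats), each = nS))
  new("SpikeTable", events = events, trials = trials, stimulusInfo = info,
      nNeurons = as.integer(nNeurons), nRepeats = as.integer(nRepeats),
      span = span, config = list())
}

## windowed ResponseTensor straight from an array
makeTensor <- function(rates, manifest, window = c(50, 200)) {
  info <- manifest
  info$stimulus_id <- paste(info$object_id, info$transformation, info$level,
                            sep = "_")
  info <- info[, c("stimulus_id", "object_id", "transformation", "level")]
  new("ResponseTensor", rates = rates, stimulusInfo = info,
      windowMs = window, binCenters = numeric())
}

makeBinnedTensor <- function(rates, manifest, centers, period = c(0, 200)) {
  info <- manifest
  info$stimulus_id <- paste(info$object_id, info$transformation, info$level,
                            sep = "_")
  info <- info[, c("stimulus_id", "object_id", "transformation", "level")]
  new("ResponseTensor", rates = rates, stimulusInfo = info,
      windowMs = period, binCenters = centers)
}

## small ActivationMatrix over an arbitrary manifest
makeActs <- function(m, manifest, source = "neural") {
  info <- manifest
  info$stimulus_id <- paste(info$object_id, info$transformation, info$level,
                            sep = "_")
  info <- info[, c("stimulus_id", "object_id", "transformation", "level")]
  new("ActivationMatrix", activations = m, source = source,
      stimulusInfo = info)
}
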