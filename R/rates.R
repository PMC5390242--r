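#' Analysis configuration
#'
#' @param rateWindow numeric(2) window for static firing rates, ms after
#'   image onset.
#' @param binWidth time-bin width for time-resolved analyses, ms; must
#'   divide the presentation period.
#' @param period numeric(2) presentation period covered by the bins, ms.
#' @param alpha significance level for the invariant-neuron flag.
#' @param nBootstrap number of neuron-bootstrap resamples.
#' @param shrinkage shrinkage intensity for the linear readout's pooled
#'   covariance: "auto" or a number in \[0, 1\].
#' @param seed seed for bootstrap resampling and trial shuffles.
#' @return list with class `"AnalysisConfig"`.
#' @export
analysisConfig <- function(rateWindow = c(50, 200), binWidth = 20,
                           period = c(0, 200), alpha = 0.05,
                           nBootstrap = 100, shrinkage = "auto", seed = 1) {
  stopIfNot(rateWindow[1] < rateWindow[2], "rateWindow must be increasing")
  stopIfNot(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  span <- period[2] - period[1]
  stopIfNot(abs(span / binWidth - round(span / binWidth)) < 1e-9,
            "binWidth must divide the presentation period (%g ms)", span)
  stopIfNot(nBootstrap >= 2, "nBootstrap must be >= 2")
  structure(list(rateWindow = rateWindow, binWidth = binWidth,
                 period = period, alpha = alpha,
                 nBootstrap = as.integer(nBootstrap),
                 shrinkage = shrinkage, seed = seed),
            class = "AnalysisConfig")
}

eventIndices <- function(spikes) {
  info <- spikes@stimulusInfo
  ev <- spikes@events
  tr <- spikes@trials
  stimIdx <- match(tr$stimulus_id, info$stimulus_id)[match(ev$trial_id, tr$trial_id)]
  repIdx <- tr$rep[match(ev$trial_id, tr$trial_id)]
  list(stim = stimIdx, rep = repIdx, neuron = ev$neuron_id, t = ev$spike_time_ms)
}

#' Trial-resolved firing rates in a time window
#'
#' Counts spikes per (neuron, stimulus, repetition) in the window and
#' divides by the window length, giving rates in sp/s.
#'
#' @param spikes a [SpikeTable-class].
#' @param window numeric(2) window in ms after image onset.
#' @return A windowed (3D) [ResponseTensor-class].
#' @export
windowRates <- function(spikes, window = c(50, 200)) {
  stopIfNot(window[1] >= spikes@span[1] && window[2] <= spikes@span[2],
            "window must lie within the recorded span [%g, %g]",
            spikes@span[1], spikes@span[2])
  info <- spikes@stimulusInfo
  nN <- spikes@nNeurons; nS <- nrow(info); nR <- spikes@nRepeats
  if (nrow(spikes@events) == 0L) {
    warning("empty spike table: returning a zero tensor")
    counts <- array(0, dim = c(nN, nS, nR))
  } else {
    ix <- eventIndices(spikes)
    keep <- ix$t >= window[1] & ix$t < window[2]
    lin <- ix$neuron[keep] + nN * (ix$stim[keep] - 1L) +
      nN * nS * (ix$rep[keep] - 1L)
    counts <- array(tabulate(lin, nbins = nN * nS * nR), dim = c(nN, nS, nR))
  }
  new("ResponseTensor", rates = counts / ((window[2] - window[1]) / 1000),
      stimulusInfo = info, windowMs = window, binCenters = numeric())
}

#' Trial-resolved firing rates per time bin
#'
#' @param spikes a [SpikeTable-class].
#' @param binWidth bin width, ms.
#' @param period numeric(2) period covered, ms.
#' @return A binned (4D) [ResponseTensor-class]; bin centers are stored in
#'   `binCenters`.
#' @export
binnedRates <- function(spikes, binWidth = 20, period = c(0, 200)) {
  stopIfNot(period[1] >= spikes@span[1] && period[2] <= spikes@span[2],
            "period must lie within the recorded span")
  nBins <- as.integer(round((period[2] - period[1]) / binWidth))
  info <- spikes@stimulusInfo
  nN <- spikes@nNeurons; nS <- nrow(info); nR <- spikes@nRepeats
  if (nrow(spikes@events) == 0L) {
    warning("empty spike table: returning a zero tensor")
    counts <- array(0, dim = c(nN, nS, nR, nBins))
  } else {
    ix <- eventIndices(spikes)
    keep <- ix$t >= period[1] & ix$t < period[2]
    bin <- pmin(floor((ix$t[keep] - period[1]) / binWidth) + 1L, nBins)
    lin <- ix$neuron[keep] + nN * (ix$stim[keep] - 1L) +
      nN * nS * (ix$rep[keep] - 1L) + nN * nS * nR * (bin - 1L)
    counts <- array(tabulate(lin, nbins = nN * nS * nR * nBins),
                    dim = c(nN, nS, nR, nBins))
  }
  centers <- period[1] + (seq_len(nBins) - 0.5) * binWidth
  new("ResponseTensor", rates = counts / (binWidth / 1000),
      stimulusInfo = info, windowMs = period, binCenters = centers)
}

#' Shuffle repetition indices independently within each neuron
#'
#' Neurons recorded in separate sessions have no common trial structure;
#' assembling them into a pseudo-population therefore involves an
#' arbitrary alignment of repetition indices. This seeded shuffle breaks
#' any spurious trial-by-trial coupling the simulator (or a recording
#' merge) may impose, while leaving each neuron's marginal responses
#' untouched.
#'
#' @param tensor a [ResponseTensor-class].
#' @param seed integer seed.
#' @return A [ResponseTensor-class] with repetitions permuted per neuron
#'   (the same permutation for every stimulus within a neuron, drawn
#'   independently across neurons).
#' @export
shuffleRepetitions <- function(tensor, seed = 1) {
  r <- tensor@rates
  nN <- dim(r)[1]; nR <- dim(r)[3]
  set.seed(childSeed(seed, 211))
  for (i in seq_len(nN)) {
    perm <- sample.int(nR)
    if (length(dim(r)) == 3L) r[i, , ] <- r[i, , perm]
    else r[i, , , ] <- r[i, , perm, ]
  }
  initialize(tensor, rates = r)
}
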