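#' Pixel-model activations
#'
#' The simplest model representation: one unit per pixel, activation equal
#' to the stored 8-bit intensity. Columns follow the stimulus-set order.
#'
#' @param stimuli a [StimulusSet-class].
#' @return An [ActivationMatrix-class] with `height * width` units.
#' @export
pixelFeatures <- function(stimuli) {
  info <- stimulusInfo(stimuli)
  dims <- lapply(images(stimuli), dim)
  stopIfNot(length(unique(vapply(dims, paste, character(1), collapse = "x"))) == 1,
            "images must share dimensions")
  keys <- paste(info$object_id, info$transformation, info$level, sep = "_")
  acts <- vapply(keys, function(k) as.numeric(images(stimuli)[[k]]),
                 numeric(prod(dims[[1]])))
  colnames(acts) <- keys
  new("ActivationMatrix", activations = acts, source = "pixel",
      stimulusInfo = asStimulusInfo(info))
}

#' Gabor filter bank parameters for the V1 model
#'
#' @param frequencies spatial frequencies, cycles per pixel.
#' @param nOrientations number of evenly spaced orientations.
#' @param phases filter phases, radians (2 by default: even and odd).
#' @param stride grid stride of the sampled unit positions, px.
#' @param sigmaCycles Gaussian envelope width in units of the wavelength.
#' @param c50 semi-saturation constant of the divisive output
#'   normalization (small value makes responses contrast-invariant).
#' @return list with class `"gaborBank"`.
#' @export
gaborBank <- function(frequencies = c(0.05, 0.1, 0.2, 0.4),
                      nOrientations = 8,
                      phases = c(0, pi / 2),
                      stride = 4,
                      sigmaCycles = 0.56,
                      c50 = 1e-6) {
  stopIfNot(all(frequencies > 0), "frequencies must be positive")
  stopIfNot(nOrientations >= 1, "need >= 1 orientation")
  stopIfNot(stride >= 1, "stride must be >= 1")
  structure(list(frequencies = frequencies,
                 nOrientations = as.integer(nOrientations),
                 phases = phases, stride = as.integer(stride),
                 sigmaCycles = sigmaCycles, c50 = c50),
            class = "gaborBank")
}

gaborKernel <- function(freq, theta, phase, sigmaCycles) {
  lambda <- 1 / freq
  sigma <- sigmaCycles * lambda
  half <- max(3L, ceiling(2.5 * sigma))
  g <- seq(-half, half)
  X <- matrix(g, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  Y <- matrix(g, 2 * half + 1, 2 * half + 1)
  xr <- X * cos(theta) + Y * sin(theta)
  env <- exp(-(X^2 + Y^2) / (2 * sigma^2))
  k <- env * cos(2 * pi * freq * xr + phase)
  k - mean(k)  # zero-mean: no response to constant images
}

## 'same' convolution via FFT, kernel centred
convolveFFT <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  H <- h + kh - 1L; W <- w + kw - 1L
  A <- matrix(0, H, W); A[1:h, 1:w] <- img
  K <- matrix(0, H, W); K[1:kh, 1:kw] <- kernel
  full <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (H * W)
  r0 <- (kh - 1L) %/% 2L; c0 <- (kw - 1L) %/% 2L
  full[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)]
}

#' V1-model activations: rectified, divisively normalized Gabor energy
#'
#' Convolves each image with a bank of zero-mean Gabor filters (spatial
#' frequencies x orientations x phases), half-wave rectifies the
#' responses, samples them on a stride grid, and divisively normalizes
#' each unit by the pooled response energy across orientations and phases
#' at the same position and frequency. The input is scaled to \[0, 1\];
#' with a small semi-saturation constant the normalized responses are
#' invariant to global intensity scaling.
#'
#' @param stimuli a [StimulusSet-class].
#' @param bank a [gaborBank()].
#' @return An [ActivationMatrix-class] with
#'   `positions x frequencies x orientations x phases` units.
#' @export
v1Features <- function(stimuli, bank = gaborBank()) {
  info <- stimulusInfo(stimuli)
  canvas <- stimuli@canvas
  maxKernel <- 2L * max(3L, ceiling(2.5 * bank$sigmaCycles / min(bank$frequencies))) + 1L
  stopIfNot(maxKernel <= min(canvas),
            "largest filter (%d px) exceeds the image size", maxKernel)
  thetas <- (seq_len(bank$nOrientations) - 1) * pi / bank$nOrientations
  kernels <- list()
  for (f in seq_along(bank$frequencies))
    for (o in seq_along(thetas))
      for (ph in seq_along(bank$phases))
        kernels[[paste(f, o, ph)]] <-
          gaborKernel(bank$frequencies[f], thetas[o], bank$phases[ph],
                      bank$sigmaCycles)
  rows <- seq(1, canvas[1], by = bank$stride)
  cols <- seq(1, canvas[2], by = bank$stride)
  keys <- paste(info$object_id, info$transformation, info$level, sep = "_")
  nPerChan <- length(rows) * length(cols)
  nUnits <- nPerChan * length(kernels)
  acts <- matrix(0, nUnits, length(keys))
  colnames(acts) <- keys
  for (j in seq_along(keys)) {
    img <- images(stimuli)[[keys[j]]] / 255
    resp <- vector("list", length(kernels))
    for (kk in seq_along(kernels))
      resp[[kk]] <- pmax(convolveFFT(img, kernels[[kk]]), 0)[rows, cols]
    ## divisive normalization: pool energy over orientation x phase per frequency
    col <- numeric(0)
    for (f in seq_along(bank$frequencies)) {
      idx <- which(vapply(strsplit(names(kernels), " "),
                          function(s) as.integer(s[1]) == f, logical(1)))
      pool <- Reduce(`+`, lapply(resp[idx], function(m) m^2))
      denom <- sqrt(pool / length(idx)) + bank$c50
      for (kk in idx) col <- c(col, as.numeric(resp[[kk]] / denom))
    }
    acts[, j] <- col
  }
  new("ActivationMatrix", activations = acts, source = "v1",
      stimulusInfo = asStimulusInfo(info))
}

#' Load externally computed unit activations (e.g. deep-network features)
#'
#' Ingests a delimited numeric matrix (units x stimuli) and validates it
#' against a stimulus manifest: the columns must map one-to-one, in
#' order, onto the manifest stimuli. Deep-network activations exported
#' elsewhere enter the analysis through this adapter; the network itself
#' is never run here.
#'
#' @param path delimited matrix file (no header; columns = stimuli), or a
#'   numeric matrix.
#' @param manifest data.frame with `object_id`, `transformation`, `level`
#'   (e.g. [stimulusInfo()] of the set the activations were computed on).
#' @param source label recorded on the result (prefixed "external:").
#' @param sep field separator for file input.
#' @return An [ActivationMatrix-class].
#' @export
loadExternalFeatures <- function(path, manifest, source = "external",
                                 sep = ",") {
  m <- if (is.matrix(path)) path
       else as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  manifest <- asStimulusInfo(manifest)
  stopIfNot(ncol(m) == nrow(manifest),
            "activation columns (%d) must match manifest stimuli (%d)",
            ncol(m), nrow(manifest))
  stopIfNot(all(is.finite(m)), "activations contain non-finite entries")
  dimnames(m) <- list(NULL, manifest$stimulus_id)
  new("ActivationMatrix", activations = m,
      source = if (startsWith(source, "external") || source %in%
                     c("pixel", "v1", "neural")) source
               else paste0("external:", source),
      stimulusInfo = manifest)
}

#' Write an ActivationMatrix as a delimited file plus manifest
#'
#' @param acts an [ActivationMatrix-class].
#' @param path output matrix path; the stimulus manifest is written to
#'   `<path>.manifest.csv`.
#' @return `path`, invisibly.
#' @export
writeActivationMatrix <- function(acts, path) {
  utils::write.table(activations(acts), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(stimulusInfo(acts), paste0(path, ".manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Unit-level invariance of a model representation
#'
#' Treats every model unit exactly like a neuron: for each transformation
#' and level, the Pearson correlation across objects between the unit's
#' activations for the reference images and for the transformed images,
#' averaged over units with a defined correlation.
#'
#' @param acts an [ActivationMatrix-class] covering the full stimulus
#'   design.
#' @return data.frame: `transformation`, `level`, `mean_r`, `sem_r`,
#'   `n_defined` (units with non-degenerate tuning), `n_units`.
#' @export
unitInvariance <- function(acts) {
  info <- stimulusInfo(acts)
  a <- activations(acts)
  stopIfNot(nrow(a) >= 2, "need >= 2 units")
  refSel <- which(info$transformation == "reference")
  refSel <- refSel[order(info$object_id[refSel])]
  out <- list(); k <- 0L
  anyDefined <- FALSE
  for (tr in TRANSFORMATIONS) for (lev in sort(unique(info$level[info$level > 0]))) {
    sel <- which(info$transformation == tr & info$level == lev)
    if (!length(sel)) next
    sel <- sel[order(info$object_id[sel])]
    r <- rowCorrelations(a[, refSel, drop = FALSE], a[, sel, drop = FALSE])
    if (any(!is.na(r))) anyDefined <- TRUE
    k <- k + 1L
    out[[k]] <- data.frame(transformation = tr, level = lev,
                           mean_r = if (all(is.na(r))) NA_real_
                                    else mean(r, na.rm = TRUE),
                           sem_r = sem(r), n_defined = sum(!is.na(r)),
                           n_units = nrow(a))
  }
  stopIfNot(anyDefined, "all units are degenerate (zero variance across objects)")
  do.call(rbind, out)
}

#' Representational dissimilarity matrix
#'
#' One minus the Pearson correlation, over units, between the activation
#' patterns of every pair of stimuli. Stimuli whose activation column has
#' zero variance yield NA entries (reported via a warning).
#'
#' @param acts an [ActivationMatrix-class] (or a plain units x stimuli
#'   matrix).
#' @return A [DissimilarityMatrix-class].
#' @export
rdm <- function(acts) {
  a <- if (is(acts, "ActivationMatrix")) activations(acts) else as.matrix(acts)
  src <- if (is(acts, "ActivationMatrix")) acts@source else "matrix"
  stopIfNot(nrow(a) >= 2, "need >= 2 units")
  sds <- apply(a, 2, stats::sd)
  d <- 1 - suppressWarnings(stats::cor(a))
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance stimulus column(s): NA dissimilarities",
                    sum(sds == 0)))
    d[sds == 0, ] <- NA; d[, sds == 0] <- NA
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2  # exact symmetry against rounding
  new("DissimilarityMatrix", values = d, source = src)
}

#' Match between two dissimilarity matrices
#'
#' The Pearson correlation between the strict lower triangles of two
#' dissimilarity matrices over the same stimuli (4005 pairs for 90
#' stimuli); NA entries are excluded pairwise.
#'
#' @param model,target [DissimilarityMatrix-class] objects of equal size
#'   and stimulus order.
#' @param method "pearson" (default) or "spearman".
#' @return named numeric: `r`, `p`, `n` (number of pairs used).
#' @export
rdmMatch <- function(model, target, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  mv <- dissimilarities(model); tv <- dissimilarities(target)
  stopIfNot(identical(dim(mv), dim(tv)),
            "matrices must cover the same stimuli")
  lt <- lower.tri(mv)
  x <- mv[lt]; y <- tv[lt]
  ok <- is.finite(x) & is.finite(y)
  stopIfNot(sum(ok) >= 3, "fewer than 3 valid dissimilarity pairs")
  if (method == "pearson") return(corTestSafe(x[ok], y[ok]))
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
  c(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Spearman-Brown prophecy correction
#'
#' Adjusts a split-half correlation r to estimate the reliability of the
#' full sample: rc = 2r / (1 + r).
#'
#' @param r split-half correlation(s) in (-1, 1\].
#' @return corrected correlation(s).
#' @examples
#' spearmanBrown(c(0, 1/3, 1))  # 0, 0.5, 1
#' @export
spearmanBrown <- function(r) 2 * r / (1 + r)

#' Split-half reliability of a neural dissimilarity structure
#'
#' Repeatedly splits the neurons into two random disjoint halves (the
#' first half larger by one for odd counts), computes the dissimilarity
#' matrix of each half, and correlates their lower triangles. The mean
#' split-half correlation r underestimates the full-population
#' reliability and is therefore also reported Spearman-Brown corrected,
#' rc = 2r / (1 + r).
#'
#' @param neural an [ActivationMatrix-class] of neurons x stimuli (>= 4
#'   neurons), e.g. trial-averaged window rates.
#' @param nSplits number of random splits.
#' @param seed integer seed.
#' @param forceHalves optional list `list(half1, half2)` of neuron index
#'   vectors overriding the random splits (one deterministic split).
#' @return list: `r` (mean split-half correlation), `rc` (mean corrected
#'   correlation), `n_splits`, `per_split` (data.frame `split`, `r`,
#'   `rc`).
#' @export
splitHalfReliability <- function(neural, nSplits = 20, seed = 1,
                                 forceHalves = NULL) {
  a <- activations(neural)
  nN <- nrow(a)
  stopIfNot(nN >= 4, "need >= 4 neurons")
  splits <- if (!is.null(forceHalves)) list(forceHalves) else {
    set.seed(childSeed(seed, 877))
    lapply(seq_len(nSplits), function(s) {
      perm <- sample.int(nN)
      half <- ceiling(nN / 2)
      list(perm[seq_len(half)], perm[(half + 1):nN])
    })
  }
  rs <- vapply(splits, function(sp) {
    d1 <- rdm(a[sp[[1]], , drop = FALSE])
    d2 <- rdm(a[sp[[2]], , drop = FALSE])
    unname(rdmMatch(d1, d2)["r"])
  }, numeric(1))
  per <- data.frame(split = seq_along(rs), r = rs, rc = spearmanBrown(rs))
  list(r = mean(rs), rc = mean(spearmanBrown(rs)),
       n_splits = length(rs), per_split = per)
}

#' Rank candidate representations by their match to a target RDM
#'
#' Generic layer-selection helper: computes each candidate's
#' dissimilarity matrix and its correlation with the target's, returning
#' candidates ordered by decreasing match.
#'
#' @param candidates named list of [ActivationMatrix-class] objects.
#' @param target a [DissimilarityMatrix-class] (e.g. from neural data).
#' @return data.frame: `candidate`, `r`, `p`, ordered by decreasing `r`.
#' @export
rankByMatch <- function(candidates, target) {
  stopIfNot(length(candidates) >= 1, "need at least one candidate")
  rows <- lapply(names(candidates), function(nm) {
    m <- rdmMatch(rdm(candidates[[nm]]), target)
    data.frame(candidate = nm, r = unname(m["r"]), p = unname(m["p"]))
  })
  out <- do.call(rbind, rows)
  out[order(-out$r), ]
}
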