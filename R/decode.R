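#' Multi-class linear discriminant readout with shrinkage covariance
#'
#' Fits a linear discriminant with a covariance matrix shared across
#' classes (equal priors). With more neurons than training trials the
#' pooled covariance is singular, so its off-diagonal part is shrunk
#' toward the diagonal: S(lambda) = (1 - lambda) S + lambda diag(S).
#' `shrinkage = "auto"` selects lambda by the analytic
#' variance-minimizing estimator for the diagonal target
#' (Schafer-Strimmer); `shrinkage = 1` reduces the readout to a
#' nearest-class-mean rule after per-dimension standardization;
#' `shrinkage = 0` is the classical LDA and errors if the pooled
#' covariance is singular. Constant (zero-variance) features are dropped
#' before fitting. Prediction is the argmax discriminant with the lowest
#' class index winning ties.
#'
#' @param x numeric matrix, trials x features.
#' @param y class labels (>= 2 classes, >= 2 trials per class).
#' @param shrinkage "auto" or a number in \[0, 1\].
#' @return object of class `"linearReadout"` with a `predict` method.
#' @export
fitLinearReadout <- function(x, y, shrinkage = "auto") {
  x <- as.matrix(x)
  y <- factor(y)
  stopIfNot(nlevels(y) >= 2, "need >= 2 classes")
  stopIfNot(all(table(y) >= 2), "need >= 2 trials per class")
  stopIfNot(nrow(x) == length(y), "x rows must match labels")
  keep <- apply(x, 2, stats::sd) > 0
  stopIfNot(any(keep), "all features are constant")
  xk <- x[, keep, drop = FALSE]
  p <- ncol(xk)
  M <- do.call(rbind, lapply(levels(y), function(cl)
    colMeans(xk[y == cl, , drop = FALSE])))
  rownames(M) <- levels(y)
  centered <- xk - M[as.integer(y), , drop = FALSE]
  n <- nrow(xk)
  S <- crossprod(centered) / (n - nlevels(y))
  if (identical(shrinkage, "auto")) {
    ## Schafer-Strimmer lambda* for the diagonal target, computed from the
    ## empirical variance of the off-diagonal covariance entries
    w <- centered
    nEff <- n - nlevels(y)
    Ssq <- crossprod(w^2) / nEff
    varS <- (Ssq - S^2) * nEff / ((nEff - 1) * nEff)
    num <- sum(varS[upper.tri(varS)])
    den <- sum(S[upper.tri(S)]^2)
    lambda <- if (den <= 0) 1 else max(0, min(1, num / den))
  } else {
    stopIfNot(is.numeric(shrinkage) && shrinkage >= 0 && shrinkage <= 1,
              "shrinkage must be \"auto\" or in [0, 1]")
    lambda <- shrinkage
  }
  Sh <- (1 - lambda) * S
  diag(Sh) <- diag(S)
  Sinv <- tryCatch(solve(Sh), error = function(e)
    stop("pooled covariance is singular: increase shrinkage (default \"auto\")",
         call. = FALSE))
  W <- Sinv %*% t(M)                      # p x k discriminant weights
  b <- -0.5 * colSums(t(M) * W)           # k intercepts (equal priors)
  structure(list(weights = W, intercepts = b, classes = levels(y),
                 keep = keep, lambda = lambda),
            class = "linearReadout")
}

#' @param object a fitted `"linearReadout"`.
#' @param newdata trials x features matrix (same feature count as fit).
#' @param ... unused.
#' @rdname fitLinearReadout
#' @export
predict.linearReadout <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  scores <- newdata[, object$keep, drop = FALSE] %*% object$weights
  scores <- sweep(scores, 2, object$intercepts, "+")
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

conditionTrials <- function(tensor, transformation, level, bin = NULL) {
  info <- tensor@stimulusInfo
  sel <- which(info$transformation == transformation & info$level == level)
  sel <- sel[order(info$object_id[sel])]
  stopIfNot(length(sel) > 0, "condition %s level %s not present",
            transformation, level)
  r <- if (is.null(bin)) tensor@rates[, sel, , drop = FALSE]
       else tensor@rates[, sel, , bin, drop = FALSE]
  dim(r) <- dim(r)[1:3]
  nS <- length(sel); nR <- dim(r)[3]
  ## trials x neurons; trial order: stimulus-major within repetition
  X <- t(matrix(r, nrow = dim(r)[1]))
  labels <- factor(rep(info$object_id[sel], times = nR))
  list(x = X, y = labels,
       trial_key = paste(rep(info$stimulus_id[sel], times = nR),
                         rep(seq_len(nR), each = nS), sep = "@"))
}

decodeDirection <- function(train, test, shrinkage, permuteSeed = NULL) {
  y <- train$y
  if (!is.null(permuteSeed)) {
    set.seed(permuteSeed)
    y <- sample(y)
  }
  fit <- fitLinearReadout(train$x, y, shrinkage = shrinkage)
  pred <- predict(fit, test$x)
  as.character(pred) == as.character(test$y)
}

#' Cross-condition generalization decoding accuracy
#'
#' Trains the linear readout on reference-image trials and tests it on
#' transformed-image trials, and vice versa; test trials are never part of
#' training (the two conditions are disjoint sets of presentations).
#' Reports the accuracy of each direction and their mean, with per-trial
#' correctness vectors for rank-sum comparisons between conditions.
#'
#' @param tensor a windowed [ResponseTensor-class].
#' @param transformation,level the transformed condition to generalize to.
#' @param config an [analysisConfig()].
#' @param permuteSeed if non-NULL, training labels are randomly permuted
#'   with this seed (chance-level control).
#' @return A [DecodingResult-class].
#' @export
generalizationAccuracy <- function(tensor, transformation, level,
                                   config = analysisConfig(),
                                   permuteSeed = NULL) {
  ref <- conditionTrials(tensor, "reference", 0)
  trans <- conditionTrials(tensor, transformation, level)
  stopIfNot(length(ref$y) == length(trans$y),
            "reference and transformed conditions must have equal repetition counts")
  stopIfNot(!any(ref$trial_key %in% trans$trial_key),
            "train/test leakage: shared trials between conditions")
  c1 <- decodeDirection(ref, trans, config$shrinkage, permuteSeed)
  c2 <- decodeDirection(trans, ref, config$shrinkage,
                        if (is.null(permuteSeed)) NULL else permuteSeed + 1L)
  key <- paste(transformation, level, sep = "_")
  acc <- data.frame(
    transformation = transformation, level = level,
    direction = c("ref_to_trans", "trans_to_ref", "mean"),
    accuracy = c(mean(c1), mean(c2), mean(c(c1, c2))),
    n_test = c(length(c1), length(c2), length(c1) + length(c2)))
  new("DecodingResult", accuracy = acc,
      correctness = stats::setNames(list(c1, c2),
        paste(key, c("ref_to_trans", "trans_to_ref"), sep = "_")),
      timeCourse = data.frame(), peakLatency = data.frame(),
      bootstrap = list(), chance = 1 / nlevels(ref$y))
}

binnedAccuracy <- function(tensor, transformation, level, config,
                           neurons = NULL) {
  centers <- tensor@binCenters
  vapply(seq_along(centers), function(b) {
    ref <- conditionTrials(tensor, "reference", 0, bin = b)
    trans <- conditionTrials(tensor, transformation, level, bin = b)
    if (!is.null(neurons)) {
      ref$x <- ref$x[, neurons, drop = FALSE]
      trans$x <- trans$x[, neurons, drop = FALSE]
    }
    ok1 <- tryCatch(decodeDirection(ref, trans, config$shrinkage),
                    error = function(e) NA)
    ok2 <- tryCatch(decodeDirection(trans, ref, config$shrinkage),
                    error = function(e) NA)
    both <- c(ok1, ok2)
    if (all(is.na(both))) NA_real_ else mean(both, na.rm = TRUE)
  }, numeric(1))
}

peakLatencyOf <- function(acc, centers) {
  ## earliest maximal bin; all-NA (degenerate) time courses -> earliest bin
  if (all(is.na(acc))) return(centers[1])
  centers[which.max(acc)]
}

#' Time-resolved generalization decoding
#'
#' Repeats the cross-condition decoding independently in every time bin
#' (training and testing within the same bin) and reports the accuracy
#' time course and its peak latency (earliest maximal bin center).
#'
#' @param tensor a binned (4D) [ResponseTensor-class].
#' @param transformation,level the transformed condition.
#' @param config an [analysisConfig()].
#' @return A [DecodingResult-class] with `timeCourse` and `peakLatency`
#'   filled in.
#' @export
binnedDecoding <- function(tensor, transformation, level,
                           config = analysisConfig()) {
  stopIfNot(length(dim(tensor@rates)) == 4L, "tensor must be binned (4D)")
  centers <- tensor@binCenters
  acc <- binnedAccuracy(tensor, transformation, level, config)
  info <- tensor@stimulusInfo
  nObj <- length(unique(info$object_id[info$transformation == "reference"]))
  new("DecodingResult",
      accuracy = data.frame(),
      correctness = list(),
      timeCourse = data.frame(bin_center_ms = centers,
                              transformation = transformation,
                              level = level, accuracy = acc),
      peakLatency = data.frame(transformation = transformation, level = level,
                               peak_latency_ms = peakLatencyOf(acc, centers)),
      bootstrap = list(), chance = 1 / nObj)
}

#' Neuron-bootstrap statistics of decoding peak latencies
#'
#' Resamples neurons with replacement (keeping the population size),
#' recomputes the binned generalization decoding for each requested
#' condition, and takes the peak latency of each resampled time course.
#' For every pair of conditions it reports the fraction of resamples in
#' which the first condition peaks later than the second, and a two-sided
#' Wilcoxon sign-rank p-value across the paired resample latencies.
#'
#' @param tensor a binned (4D) [ResponseTensor-class].
#' @param conditions list of `c(transformation, level)` pairs (or a
#'   data.frame with columns `transformation`, `level`).
#' @param config an [analysisConfig()]; `nBootstrap` and `seed` control
#'   the resampling.
#' @return list: `latencies` (resamples x conditions matrix, ms), `pairs`
#'   (data.frame `condition_a`, `condition_b`,
#'   `fraction_a_later`, `p_signrank`), `flat_fraction` (share of
#'   resampled time courses that were degenerate and fell back to the
#'   earliest bin).
#' @export
bootstrapLatencies <- function(tensor, conditions,
                               config = analysisConfig()) {
  stopIfNot(length(dim(tensor@rates)) == 4L, "tensor must be binned (4D)")
  if (is.data.frame(conditions))
    conditions <- lapply(seq_len(nrow(conditions)), function(i)
      c(conditions$transformation[i], conditions$level[i]))
  nN <- dim(tensor@rates)[1]
  centers <- tensor@binCenters
  condNames <- vapply(conditions, function(cd) paste(cd[1], cd[2], sep = "_"),
                      character(1))
  B <- config$nBootstrap
  lat <- matrix(NA_real_, B, length(conditions),
                dimnames = list(NULL, condNames))
  nFlat <- 0L
  set.seed(childSeed(config$seed, 631))
  picks <- matrix(sample.int(nN, nN * B, replace = TRUE), nrow = B)
  for (b in seq_len(B)) {
    neurons <- picks[b, ]
    for (j in seq_along(conditions)) {
      acc <- binnedAccuracy(tensor, conditions[[j]][1],
                            as.integer(conditions[[j]][2]), config,
                            neurons = neurons)
      if (all(is.na(acc)) || (max(acc, na.rm = TRUE) == min(acc, na.rm = TRUE)))
        nFlat <- nFlat + 1L
      lat[b, j] <- peakLatencyOf(acc, centers)
    }
  }
  pairs <- list(); k <- 0L
  if (length(conditions) >= 2) {
    cmb <- utils::combn(seq_along(conditions), 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; bb <- cmb[2, j]
      k <- k + 1L
      pairs[[k]] <- data.frame(
        condition_a = condNames[a], condition_b = condNames[bb],
        fraction_a_later = mean(lat[, a] > lat[, bb]),
        p_signrank = suppressWarnings(
          stats::wilcox.test(lat[, a], lat[, bb], paired = TRUE)$p.value))
    }
  }
  list(latencies = lat,
       pairs = if (k) do.call(rbind, pairs) else data.frame(),
       flat_fraction = nFlat / (B * length(conditions)))
}

#' Decoding restricted to neuron or object subsets
#'
#' Runs the static generalization decoding on a subset of neurons (e.g.
#' the most invariant ones) or a subset of objects (chance level is
#' recomputed as 1 / number of objects kept).
#'
#' @param tensor a windowed [ResponseTensor-class].
#' @param transformation,level the transformed condition.
#' @param neuronSubset integer indices of neurons to keep (NULL = all).
#' @param objectSubset character object ids to keep (NULL = all; >= 2).
#' @param config an [analysisConfig()].
#' @return A [DecodingResult-class].
#' @export
subsetDecoding <- function(tensor, transformation, level,
                           neuronSubset = NULL, objectSubset = NULL,
                           config = analysisConfig()) {
  r <- tensor@rates
  info <- tensor@stimulusInfo
  if (!is.null(neuronSubset)) {
    stopIfNot(length(neuronSubset) > 0, "neuron subset is empty")
    stopIfNot(all(neuronSubset >= 1 & neuronSubset <= dim(r)[1]),
              "neuron subset references unknown neurons")
    r <- r[neuronSubset, , , drop = FALSE]
  }
  if (!is.null(objectSubset)) {
    stopIfNot(length(objectSubset) >= 2, "object subset needs >= 2 objects")
    stopIfNot(all(objectSubset %in% info$object_id),
              "object subset references unknown ids: %s",
              paste(setdiff(objectSubset, info$object_id), collapse = ", "))
    keep <- info$object_id %in% objectSubset
    r <- r[, keep, , drop = FALSE]
    info <- info[keep, , drop = FALSE]
  }
  sub <- new("ResponseTensor", rates = r, stimulusInfo = info,
             windowMs = tensor@windowMs, binCenters = tensor@binCenters)
  generalizationAccuracy(sub, transformation, level, config)
}

#' Rank neurons by tuning correlation for one transformation
#'
#' @param table an [InvarianceTable-class].
#' @param transformation,level condition whose tuning correlation ranks
#'   the neurons.
#' @param k how many top neurons to return.
#' @return integer neuron ids, strongest tuning correlation first.
#' @export
topNeurons <- function(table, transformation, level = 2, k = 20) {
  per <- table@perNeuron
  sub <- per[per$transformation == transformation & per$level == level, ]
  sub <- sub[order(-sub$r, sub$neuron_id), ]
  utils::head(sub$neuron_id[!is.na(sub$r)], k)
}
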