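#' Pipeline run configuration
#'
#' Bundles the stage configurations of the end-to-end analysis into one
#' object driven by a single master seed, from which every stage derives
#' its own stream. Any field can be overridden from a YAML file with the
#' same (nested) keys.
#'
#' @param seed master seed; recorded (with a configuration hash) in the
#'   header of every numeric output file.
#' @param outDir output directory of the run.
#' @param nObjects number of objects in the stimulus design.
#' @param canvas canvas size in px (square).
#' @param viewLevels numeric(2) view parameters defining the two change
#'   levels.
#' @param balance a [balanceSpec()].
#' @param population a [populationConfig()] (its seed is overridden by a
#'   stream derived from `seed`).
#' @param analysis an [analysisConfig()].
#' @param bootstrapConditions data.frame (`transformation`, `level`) of
#'   conditions entering the binned decoding + bootstrap latency stage.
#' @param stages character vector of stages to run, a subset of
#'   `c("stimuli", "simulate", "invariance", "decode", "models")`; stages
#'   not run must find their upstream artifacts in `outDir`.
#' @param runV1 also compute the (slow) V1-Gabor model features in the
#'   models stage.
#' @return list with class `"RunConfig"`.
#' @export
runConfig <- function(seed = 1, outDir = "invariance_run",
                      nObjects = 10, canvas = 128,
                      viewLevels = c(0.45, 0.95),
                      balance = balanceSpec(),
                      population = populationConfig(),
                      analysis = analysisConfig(),
                      bootstrapConditions = data.frame(
                        transformation = c("size", "position", "rotation", "view"),
                        level = 2L),
                      stages = c("stimuli", "simulate", "invariance",
                                 "decode", "models"),
                      runV1 = FALSE) {
  known <- c("stimuli", "simulate", "invariance", "decode", "models")
  stopIfNot(all(stages %in% known), "unknown stage(s): %s",
            paste(setdiff(stages, known), collapse = ", "))
  structure(list(seed = seed, outDir = outDir, nObjects = nObjects,
                 canvas = canvas, viewLevels = viewLevels,
                 balance = balance, population = population,
                 analysis = analysis,
                 bootstrapConditions = bootstrapConditions,
                 stages = stages, runV1 = runV1),
            class = "RunConfig")
}

#' Read a RunConfig from a YAML file
#'
#' Flat or nested keys matching the [runConfig()] arguments; unknown keys
#' are rejected. Nested sections `balance`, `population`, `analysis`
#' override fields of the respective sub-configurations.
#'
#' @param path YAML file.
#' @return list with class `"RunConfig"`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  top <- c("seed", "outDir", "nObjects", "canvas", "viewLevels",
           "stages", "runV1")
  bad <- setdiff(names(y), c(top, "balance", "population", "analysis",
                             "bootstrapConditions"))
  stopIfNot(length(bad) == 0, "unknown config key(s): %s",
            paste(bad, collapse = ", "))
  for (k in intersect(top, names(y))) args[[k]] <- y[[k]]
  if (!is.null(y$balance)) args$balance <- do.call(balanceSpec, y$balance)
  if (!is.null(y$population)) args$population <- do.call(populationConfig, y$population)
  if (!is.null(y$analysis)) args$analysis <- do.call(analysisConfig, y$analysis)
  if (!is.null(y$bootstrapConditions))
    args$bootstrapConditions <- as.data.frame(y$bootstrapConditions)
  do.call(runConfig, args)
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

requireArtifact <- function(path, stage, producer) {
  if (!file.exists(path))
    stop(sprintf(
      "stage '%s' failed: required artifact '%s' is missing (produced by stage '%s')",
      stage, path, producer), call. = FALSE)
  path
}

#' Run the full balanced-invariance analysis pipeline
#'
#' Executes the enabled stages in order -- balanced stimulus generation,
#' population simulation, per-neuron invariance, population decoding, and
#' model comparison -- writing every product to the run directory:
#' stimulus PNGs + manifest, the spike-event CSV, invariance tables and
#' time courses, decoding accuracies, time courses and bootstrap
#' latencies, model invariances, dissimilarity matrices and reliability,
#' and a one-file summary. Outputs are byte-identical across runs with
#' the same configuration and seed; every numeric CSV carries the seed
#' and a configuration hash in a header comment.
#'
#' @param config a [runConfig()].
#' @return the run directory, invisibly.
#' @export
runPipeline <- function(config = runConfig()) {
  stopIfNot(inherits(config, "RunConfig"), "config must be a RunConfig")
  out <- config$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hashed <- unclass(config)
  hashed$outDir <- NULL  # paths are not part of the scientific configuration
  hash <- configHash(hashed)
  seed <- config$seed
  stamp <- function(df, name) writeStampedCsv(df, file.path(out, name),
                                              seed = seed, hash = hash)
  stimDir <- file.path(out, "stimuli")

  if ("stimuli" %in% config$stages) {
    withStage("stimuli", {
      shapes <- randomShapes(config$nObjects, seed = childSeed(seed, 1),
                             canvas = rep(as.integer(config$canvas), 2))
      stimuli <- buildStimulusSet(shapes, spec = config$balance,
                                  viewLevels = config$viewLevels)
      writeStimulusSet(stimuli, stimDir)
    })
  }
  downstream <- c("simulate", "invariance", "decode", "models")
  needStimuli <- any(downstream %in% config$stages)
  needSpikes <- any(downstream[-1] %in% config$stages)
  stimuli <- if (needStimuli) withStage("stimuli",
    readStimulusSet(dirname(requireArtifact(file.path(stimDir, "manifest.csv"),
                                            "stimuli", "stimuli"))))

  spikesPath <- file.path(out, "spikes.csv")
  if ("simulate" %in% config$stages) {
    withStage("simulate", {
      pop <- config$population
      pop$seed <- childSeed(seed, 2)
      spikes <- simulatePopulation(stimuli, pop)
      writeSpikeTable(spikes, spikesPath)
    })
  }
  if (needSpikes) {
    spikes <- withStage("simulate",
      readSpikeTable(requireArtifact(spikesPath, "simulate", "simulate")))
    an <- config$analysis
    tensor <- windowRates(spikes, an$rateWindow)
    tensor <- shuffleRepetitions(tensor, seed = childSeed(seed, 3))
    binned <- binnedRates(spikes, an$binWidth, an$period)
    binned <- shuffleRepetitions(binned, seed = childSeed(seed, 3))
  }

  if ("invariance" %in% config$stages) {
    withStage("invariance", {
      inv <- invarianceTable(tensor, an)
      stamp(inv@perNeuron, "invariance.csv")
      stamp(inv@summary, "invariance_summary.csv")
      stamp(inv@pairwise, "invariance_pairwise.csv")
      dyn <- binnedInvariance(binned, an)
      stamp(dyn$timeCourse, "invariance_timecourse.csv")
      stamp(dyn$peakLatency, "invariance_peak_latency.csv")
      stamp(dyn$affineVsNonaffine, "invariance_affine_vs_nonaffine.csv")
      cov <- invarianceCovariation(inv)
      covDf <- do.call(rbind, lapply(names(cov), function(lev) {
        idx <- which(upper.tri(cov[[lev]]$r), arr.ind = TRUE)
        data.frame(level = lev,
                   transformation_a = TRANSFORMATIONS[idx[, 1]],
                   transformation_b = TRANSFORMATIONS[idx[, 2]],
                   r = cov[[lev]]$r[idx], p = cov[[lev]]$p[idx])
      }))
      stamp(covDf, "invariance_covariation.csv")
      per <- inv@perNeuron
      n <- length(unique(per$neuron_id))
      cooc <- list(); k <- 0L
      pairs <- utils::combn(TRANSFORMATIONS, 2)
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1, j]; b <- pairs[2, j]
        fa <- per$invariant[per$transformation == a & per$level == 2]
        fb <- per$invariant[per$transformation == b & per$level == 2]
        fa[is.na(fa)] <- FALSE; fb[is.na(fb)] <- FALSE
        obs <- c(sum(fa & fb), sum(!fa & fb), sum(fa & !fb), sum(!fa & !fb))
        tst <- cooccurrenceTest(obs, sum(fa), sum(fb), n)
        k <- k + 1L
        cooc[[k]] <- data.frame(
          transformation_a = a, transformation_b = b,
          obs_both = obs[1], obs_b_only = obs[2], obs_a_only = obs[3],
          obs_neither = obs[4], chisq = tst$statistic,
          p_df1 = tst$p_df1, p_df3 = tst$p_df3)
      }
      stamp(do.call(rbind, cooc), "cooccurrence.csv")
    })
  }

  if ("decode" %in% config$stages) {
    withStage("decode", {
      accs <- list(); k <- 0L
      for (tr in TRANSFORMATIONS) for (lev in 1:2) {
        res <- generalizationAccuracy(tensor, tr, lev, an)
        k <- k + 1L
        accs[[k]] <- res@accuracy
      }
      static <- do.call(rbind, accs)
      static$chance <- 1 / config$nObjects
      stamp(static, "decoding_static.csv")
      tcs <- list(); k <- 0L
      for (i in seq_len(nrow(config$bootstrapConditions))) {
        tr <- config$bootstrapConditions$transformation[i]
        lev <- config$bootstrapConditions$level[i]
        res <- binnedDecoding(binned, tr, lev, an)
        k <- k + 1L
        tcs[[k]] <- res@timeCourse
      }
      stamp(do.call(rbind, tcs), "decoding_timecourse.csv")
      boot <- bootstrapLatencies(binned, config$bootstrapConditions, an)
      latDf <- data.frame(resample = rep(seq_len(nrow(boot$latencies)),
                                         ncol(boot$latencies)),
                          condition = rep(colnames(boot$latencies),
                                          each = nrow(boot$latencies)),
                          latency_ms = as.numeric(boot$latencies))
      stamp(latDf, "decoding_bootstrap_latencies.csv")
      stamp(boot$pairs, "decoding_latency_pairs.csv")
    })
  }

  if ("models" %in% config$stages) {
    withStage("models", {
      px <- pixelFeatures(stimuli)
      modelInv <- cbind(model = "pixel", unitInvariance(px))
      mats <- list(pixel = px)
      if (isTRUE(config$runV1)) {
        v1 <- v1Features(stimuli)
        modelInv <- rbind(modelInv, cbind(model = "v1", unitInvariance(v1)))
        mats$v1 <- v1
      }
      neuralMat <- apply(tensor@rates, c(1, 2), mean)
      colnames(neuralMat) <- tensor@stimulusInfo$stimulus_id
      neural <- new("ActivationMatrix", activations = neuralMat,
                    source = "neural",
                    stimulusInfo = tensor@stimulusInfo)
      modelInv <- rbind(modelInv, cbind(model = "neural", unitInvariance(neural)))
      stamp(modelInv, "model_invariance.csv")
      neuralRdm <- rdm(neural)
      matches <- rankByMatch(mats, neuralRdm)
      rel <- splitHalfReliability(neural, nSplits = 20,
                                  seed = childSeed(seed, 4))
      stamp(data.frame(candidate = c(matches$candidate, "it_reliability"),
                       r = c(matches$r, rel$rc), p = c(matches$p, NA)),
            "model_rdm_match.csv")
      rdmDf <- as.data.frame(dissimilarities(neuralRdm))
      names(rdmDf) <- tensor@stimulusInfo$stimulus_id
      stamp(cbind(stimulus_id = tensor@stimulusInfo$stimulus_id, rdmDf),
            "neural_rdm.csv")
    })
  }
  complete <- all(file.exists(file.path(out,
    c("invariance_summary.csv", "decoding_static.csv", "cooccurrence.csv",
      "model_rdm_match.csv"))))
  if (complete) {
    summary <- reportSummary(out, quiet = TRUE)
    stamp(summary$overview, "summary.csv")
  } else {
    message("partial run (stages: ", paste(config$stages, collapse = ", "),
            "): summary not written")
  }
  invisible(out)
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts of a run directory and assembles the headline
#' tables: per-condition mean invariance, invariance and decoding peak
#' latencies, static decoding accuracies with the chance level,
#' co-occurrence statistics, and model RDM matches. Errors listing the
#' missing files if the run is incomplete. Re-running on an unchanged
#' directory returns identical tables.
#'
#' @param dir run directory.
#' @param quiet suppress printing.
#' @return list of data.frames (`overview`, `invariance`, `decoding`,
#'   `cooccurrence`, `models`), invisibly when printing.
#' @export
reportSummary <- function(dir, quiet = FALSE) {
  needed <- c("invariance_summary.csv", "invariance_peak_latency.csv",
              "decoding_static.csv", "decoding_latency_pairs.csv",
              "cooccurrence.csv", "model_rdm_match.csv")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing))
    stop("incomplete run; missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  inv <- readStampedCsv(file.path(dir, "invariance_summary.csv"))
  lat <- readStampedCsv(file.path(dir, "invariance_peak_latency.csv"))
  dec <- readStampedCsv(file.path(dir, "decoding_static.csv"))
  pairs <- readStampedCsv(file.path(dir, "decoding_latency_pairs.csv"))
  cooc <- readStampedCsv(file.path(dir, "cooccurrence.csv"))
  mods <- readStampedCsv(file.path(dir, "model_rdm_match.csv"))
  decMean <- dec[dec$direction == "mean", ]
  overview <- merge(
    merge(inv[, c("transformation", "level", "mean_r", "fraction_invariant")],
          lat, by = c("transformation", "level")),
    decMean[, c("transformation", "level", "accuracy", "chance")],
    by = c("transformation", "level"))
  overview <- overview[order(overview$level,
                             match(overview$transformation, TRANSFORMATIONS)), ]
  rownames(overview) <- NULL
  out <- list(overview = overview, invariance = inv, decoding = dec,
              latencyPairs = pairs, cooccurrence = cooc, models = mods)
  if (!quiet) {
    cat("== Invariance and decoding by condition ==\n")
    print(overview, digits = 3, row.names = FALSE)
    cat(sprintf("\nChance decoding level: %.0f%%\n", 100 * decMean$chance[1]))
    cat("\n== Bootstrap latency order fractions ==\n")
    print(pairs, digits = 3, row.names = FALSE)
    cat("\n== Invariance co-occurrence (level 2) ==\n")
    print(cooc, digits = 3, row.names = FALSE)
    cat("\n== Model RDM match to the neural RDM ==\n")
    print(mods, digits = 3, row.names = FALSE)
  }
  invisible(out)
}
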