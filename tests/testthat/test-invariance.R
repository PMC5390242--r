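test_that("window and binned rates match a brute-force event recount", {
  man <- makeManifest(2)          # 18 stimuli
  nN <- 3; nR <- 2
  set.seed(7)
  info <- man
  info$stimulus_id <- paste(info$object_id, info$transformation, info$level,
                            sep = "_")
  nS <- nrow(info)
  ev <- data.frame(
    neuron_id = sample(nN, 300, TRUE),
    trial_id = sample(nS * nR, 300, TRUE),
    stimulus_id = NA, spike_time_ms = runif(300, 0, 400))
  trialsStim <- rep(info$stimulus_id, times = nR)
  ev$stimulus_id <- trialsStim[ev$trial_id]
  spikes <- makeSpikeTable(ev, man, nN, nR)
  tensor <- windowRates(spikes, c(50, 200))
  r <- rateArray(tensor)
  ## brute force: count events per (neuron, stimulus, repetition) by looping
  trRep <- rep(seq_len(nR), each = nS)
  for (i in 1:nN) for (s in c(1, 7, 18)) for (k in 1:nR) {
    tid <- which(trialsStim == info$stimulus_id[s] & trRep == k)
    cnt <- sum(ev$neuron_id == i & ev$trial_id == tid &
                 ev$spike_time_ms >= 50 & ev$spike_time_ms < 200)
    expect_equal(r[i, s, k], cnt / 0.15)
  }
  ## binned rates recount in a chosen bin
  binned <- binnedRates(spikes, 20, c(0, 200))
  expect_equal(length(binned@binCenters), 10)
  b <- 4   # 60-80 ms
  rb <- rateArray(binned)
  tid <- which(trialsStim == info$stimulus_id[2] & trRep == 1)
  cnt <- sum(ev$neuron_id == 2 & ev$trial_id == tid &
               ev$spike_time_ms >= 60 & ev$spike_time_ms < 80)
  expect_equal(rb[2, 2, 1, b], cnt / 0.02)
  ## simple rate arithmetic: 3 spikes in 150 ms is 20 sp/s
  expect_equal(3 / 0.15, 20)
  ## empty table warns and yields zeros
  empty <- makeSpikeTable(ev[0, ], man, nN, nR)
  expect_warning(t0 <- windowRates(empty), "empty")
  expect_true(all(rateArray(t0) == 0))
})

test_that("tuning correlation matches the covariance-formula oracle and its contract", {
  expect_equal(unname(tuningCorrelation(1:5, 1:5)["r"]), 1)
  expect_equal(unname(tuningCorrelation(c(1, 2, 3), c(3, 2, 1))["r"]), -1)
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10)
    got <- tuningCorrelation(x, y)
    ## independent oracle: explicit covariance formula + t transform
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tstat <- r * sqrt(8 / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = 8)
    expect_equal(unname(got["r"]), r, tolerance = 1e-10)
    expect_equal(unname(got["p"]), p, tolerance = 1e-10)
    ## symmetry and affine invariance
    expect_equal(unname(tuningCorrelation(y, x)["r"]), r, tolerance = 1e-12)
    expect_equal(unname(tuningCorrelation(2 * x + 3, y)["r"]), r,
                 tolerance = 1e-10)
  }
  expect_true(is.na(tuningCorrelation(rep(1, 5), rnorm(5))["r"]))
  expect_error(tuningCorrelation(1:2, 1:2), ">= 3")
})

test_that("the invariance table summarizes a perfectly invariant population correctly", {
  man <- makeManifest(8)
  cfg <- populationConfig(nNeurons = 30, peakRateRange = c(60, 100),
                          invarianceStrength = 1, seed = 12)
  tensor <- windowRates(simulatePopulation(man, cfg))
  inv <- invarianceTable(tensor)
  expect_s4_class(inv, "InvarianceTable")
  expect_equal(nrow(inv@perNeuron), 30 * 8)
  expect_true(all(inv@summary$mean_r > 0.9))
  expect_true(all(inv@summary$fraction_invariant > 0.9))
  ## mean among invariant neurons is at least the overall mean
  ok <- !is.na(inv@summary$mean_r_invariant)
  expect_true(all(inv@summary$mean_r_invariant[ok] >= inv@summary$mean_r[ok] - 1e-9))
  ## missing stimulus cells are reported by name
  broken <- tensor
  keep <- !(broken@stimulusInfo$transformation == "rotation" &
              broken@stimulusInfo$level == 2)
  broken@rates <- broken@rates[, keep, , drop = FALSE]
  broken@stimulusInfo <- broken@stimulusInfo[keep, ]
  expect_error(invarianceTable(broken), "rotation/level 2")
})

test_that("null invariance yields alpha-level invariant fractions and calibrated pairwise tests", {
  man <- makeManifest(10)
  strength <- matrix(1, 4, 2, dimnames = list(
    c("size", "position", "rotation", "view"), c("1", "2")))
  strength["view", ] <- 0
  fracs <- c(); chiNonsig <- 0; nSeeds <- 10
  for (sd in seq_len(nSeeds)) {
    cfg <- populationConfig(nNeurons = 60, invarianceStrength = strength,
                            seed = 100 + sd)
    inv <- invarianceTable(windowRates(simulatePopulation(man, cfg)))
    fracs <- c(fracs,
               inv@summary$fraction_invariant[inv@summary$transformation == "view"])
    ## size vs position have equal strength: fraction test should be quiet
    pw <- inv@pairwise
    p <- pw$p_fraction_chisq[pw$transformation_a == "size" &
                               pw$transformation_b == "position" & pw$level == 2]
    if (is.na(p) || p > 0.05) chiNonsig <- chiNonsig + 1
  }
  ## the false-positive rate of the invariant flag is about alpha
  expect_gt(mean(fracs), 0.01)
  expect_lt(mean(fracs), 0.10)
  expect_gte(chiNonsig, 0.9 * nSeeds)
})

test_that("binned invariance finds peaks with the earliest-bin tie rule", {
  man <- makeManifest(5)
  nN <- 6; nS <- nrow(man); nR <- 2; nBins <- 3
  centers <- c(10, 30, 50)
  set.seed(13)
  base <- matrix(rnorm(nN * 5, 10, 2), nN, 5)      # neurons x objects tuning
  rates <- array(rep(5, nN * nS * nR * nBins), c(nN, nS, nR, nBins))
  info <- man
  oid <- match(info$object_id, sort(unique(info$object_id)))
  noise <- matrix(rnorm(nN * 5, 10, 2), nN, 5)
  mixFor <- c(0.2, 1, 0.6)   # per-bin tuning preservation -> peak at bin 2
  for (s in seq_len(nS)) for (b in seq_len(nBins)) {
    w <- if (info$transformation[s] == "reference") 1 else mixFor[b]
    v <- w * base[, oid[s]] + (1 - w) * noise[, oid[s]]
    for (k in seq_len(nR)) rates[, s, k, b] <- pmax(v, 0)
  }
  tens <- makeBinnedTensor(rates, man, centers)
  dyn <- binnedInvariance(tens, analysisConfig(binWidth = 20, period = c(0, 60)))
  expect_true(all(dyn$peakLatency$peak_latency_ms == 30))
  ## tie between bins 2 and 3 resolves to the earlier center
  rates2 <- rates; rates2[, , , 3] <- rates[, , , 2]
  dyn2 <- binnedInvariance(makeBinnedTensor(rates2, man, centers),
                           analysisConfig(binWidth = 20, period = c(0, 60)))
  expect_true(all(dyn2$peakLatency$peak_latency_ms == 30))
})

test_that("configured invariance latency differences are recovered from time courses", {
  man <- makeManifest(8)
  hits <- 0; nSeeds <- 10
  lat <- c(size = 0, position = 0, rotation = 0, view = 60)
  for (sd in seq_len(nSeeds)) {
    cfg <- populationConfig(nNeurons = 40, invarianceLatency = lat,
                            peakRateRange = c(50, 90), seed = 200 + sd)
    dyn <- binnedInvariance(binnedRates(simulatePopulation(man, cfg)))
    pk <- dyn$peakLatency
    dv <- pk$peak_latency_ms[pk$transformation == "view" & pk$level == 1] -
      pk$peak_latency_ms[pk$transformation == "size" & pk$level == 1]
    if (dv > 0) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * nSeeds)
})

test_that("invariance covariation detects shared gain and perfect duplication", {
  set.seed(21)
  n <- 80
  shared <- runif(n, 0, 0.8)
  per <- expand.grid(neuron_id = 1:n,
                     transformation = c("size", "position", "rotation", "view"),
                     level = 1:2, stringsAsFactors = FALSE)
  per$r <- pmin(shared[per$neuron_id] + rnorm(nrow(per), 0, 0.1), 1)
  per$p <- 0.5; per$invariant <- FALSE
  ## make one pair an exact duplicate
  per$r[per$transformation == "position"] <- per$r[per$transformation == "size"]
  tab <- new("InvarianceTable", perNeuron = per,
             summary = data.frame(fraction_invariant = numeric()),
             pairwise = data.frame(), alpha = 0.05)
  cov <- invarianceCovariation(tab)
  r1 <- cov[["1"]]$r
  expect_equal(r1["size", "position"], 1, tolerance = 1e-12)
  expect_true(all(r1[upper.tri(r1)] > 0))
  expect_equal(r1, t(r1))
  ## independent invariances decorrelate
  per$r <- rnorm(nrow(per), 0.4, 0.15)
  tab2 <- new("InvarianceTable", perNeuron = per,
              summary = data.frame(fraction_invariant = numeric()),
              pairwise = data.frame(), alpha = 0.05)
  r2 <- invarianceCovariation(tab2)[["1"]]$r
  expect_true(all(abs(r2[upper.tri(r2)]) < 0.35))
})

test_that("expected co-occurrence counts follow the independence products", {
  expect_equal(unname(expectedCooccurrence(51, 57, 127)$expected),
               c(23, 34, 28, 42))
  expect_equal(unname(expectedCooccurrence(0, 5, 20)$expected),
               c(0, 5, 0, 15))
  expect_equal(unname(expectedCooccurrence(20, 20, 20)$expected),
               c(20, 0, 0, 0))
  expect_error(expectedCooccurrence(30, 5, 20), "\\[0, n\\]")
})

test_that("the co-occurrence chi-square is exact on its oracle and calibrated under the null", {
  ex <- expectedCooccurrence(51, 57, 127)
  expect_equal(cooccurrenceTest(round(ex$unrounded) + c(1, -1, -1, 1) * 0,
                                51, 57, 127)$statistic,
               sum((round(ex$unrounded) - ex$unrounded)^2 / ex$unrounded),
               tolerance = 1e-12)
  ## observed equal to (unrounded) expectations gives exactly zero
  obs0 <- c(22.8898, 34.1102, 28.1102, 41.8898)
  stat0 <- sum((obs0 - ex$unrounded)^2 / ex$unrounded)
  expect_lt(stat0, 1e-6)
  ## null calibration: independent flags, margins observed, df = 1
  set.seed(31)
  rej <- replicate(400, {
    a <- runif(127) < 0.4; b <- runif(127) < 0.45
    obs <- c(sum(a & b), sum(!a & b), sum(a & !b), sum(!a & !b))
    cooccurrenceTest(obs, sum(a), sum(b), 127)$p_df1 < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
  ## tiny expected cells carry a warning note
  expect_match(cooccurrenceTest(c(0, 2, 0, 18), 0, 2, 20)$warning, "below 1")
})
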