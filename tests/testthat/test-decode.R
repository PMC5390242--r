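test_that("the shrinkage discriminant matches closed-form and reference fits", {
  set.seed(41)
  ## well-separated classes are learnt perfectly
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  fit <- fitLinearReadout(x, y)
  expect_equal(mean(predict(fit, x) == y), 1)
  ## shrinkage 1 equals the nearest-class-mean rule after per-dimension
  ## standardization by the pooled within-class variance
  x2 <- matrix(rnorm(60 * 3, sd = c(1, 4, 0.5)), 60, 3, byrow = TRUE)
  y2 <- rep(c("a", "b", "c"), each = 20)
  x2[y2 == "b", 1] <- x2[y2 == "b", 1] + 2
  x2[y2 == "c", 2] <- x2[y2 == "c", 2] + 3
  fit1 <- fitLinearReadout(x2, y2, shrinkage = 1)
  M <- rbind(colMeans(x2[y2 == "a", ]), colMeans(x2[y2 == "b", ]),
             colMeans(x2[y2 == "c", ]))
  centered <- x2 - M[as.integer(factor(y2)), ]
  v <- colSums(centered^2) / (60 - 3)
  xt <- matrix(rnorm(30), 10, 3)
  oracle <- apply(xt, 1, function(row)
    c("a", "b", "c")[which.min(colSums((t(M) - row)^2 / v))])
  expect_equal(as.character(predict(fit1, xt)), oracle)
  ## duplicated feature columns leave diagonal-shrinkage predictions unchanged
  fitDup <- fitLinearReadout(cbind(x2, x2), y2, shrinkage = 1)
  expect_equal(as.character(predict(fitDup, cbind(xt, xt))),
               as.character(predict(fit1, xt)))
  ## shrinkage 0 agrees with the classical LDA reference implementation
  skip_if_not_installed("MASS")
  fit0 <- fitLinearReadout(x2, y2, shrinkage = 0)
  ref <- MASS::lda(x2, grouping = y2)
  expect_equal(as.character(predict(fit0, xt)),
               as.character(predict(ref, xt)$class))
  ## singular covariance without shrinkage points at the remedy
  xs <- cbind(x2[, 1], x2[, 1], x2[, 2])
  expect_error(fitLinearReadout(xs, y2, shrinkage = 0), "shrinkage")
})

test_that("prediction ties resolve to the lowest class index", {
  x <- rbind(matrix(c(-1, 0), 5, 2, byrow = TRUE) + rnorm(10, sd = 1e-3),
             matrix(c(1, 0), 5, 2, byrow = TRUE) + rnorm(10, sd = 1e-3))
  y <- rep(c("a", "b"), each = 5)
  fit <- fitLinearReadout(x, y, shrinkage = 1)
  ## a point exactly between symmetric class means scores (near) equal;
  ## force exact equality by zeroing the weights' effect
  fit$weights[] <- 0
  fit$intercepts[] <- 0
  expect_equal(as.character(predict(fit, matrix(0, 1, 2))), "a")
})

test_that("cross-condition generalization is perfect for an invariant code and chance for permuted labels", {
  man <- makeManifest(6)
  nN <- 20; nS <- nrow(man); nR <- 6
  set.seed(43)
  pattern <- matrix(rnorm(nN * 6, 10, 3), nN, 6)
  oid <- match(man$object_id, sort(unique(man$object_id)))
  rates <- array(0, c(nN, nS, nR))
  for (s in seq_len(nS)) for (k in seq_len(nR))
    rates[, s, k] <- pmax(pattern[, oid[s]] + rnorm(nN, 0, 0.3), 0)
  tens <- makeTensor(rates, man)
  res <- generalizationAccuracy(tens, "view", 2)
  expect_equal(res@chance, 1 / 6)
  expect_equal(res@accuracy$accuracy[res@accuracy$direction == "mean"], 1)
  expect_equal(res@accuracy$n_test[res@accuracy$direction == "mean"], 2 * 6 * nR)
  ## permuted training labels drop accuracy into the chance band
  accs <- sapply(1:10, function(s)
    generalizationAccuracy(tens, "view", 2,
                           permuteSeed = s)@accuracy$accuracy[3])
  n <- 10 * 2 * 6 * nR
  expect_lt(abs(mean(accs) - 1 / 6), 1.96 * sqrt((1 / 6) * (5 / 6) / n) + 0.02)
  ## decoding the reference against itself would leak trials
  expect_error(generalizationAccuracy(tens, "reference", 0), "leakage")
})

test_that("decoding is invariant to per-neuron affine rate rescaling without shrinkage", {
  man <- makeManifest(5)
  nN <- 6; nS <- nrow(man); nR <- 8
  set.seed(44)
  pattern <- matrix(rnorm(nN * 5, 10, 3), nN, 5)
  oid <- match(man$object_id, sort(unique(man$object_id)))
  rates <- array(0, c(nN, nS, nR))
  for (s in seq_len(nS)) for (k in seq_len(nR))
    rates[, s, k] <- pmax(pattern[, oid[s]] + rnorm(nN, 0, 2), 0)
  cfg <- analysisConfig(shrinkage = 0)
  base <- generalizationAccuracy(makeTensor(rates, man), "size", 1, cfg)
  gains <- runif(nN, 0.5, 3); offsets <- runif(nN, 0, 5)
  scaled <- rates * gains + offsets      # recycles along the neuron dimension
  res <- generalizationAccuracy(makeTensor(scaled, man), "size", 1, cfg)
  expect_equal(res@accuracy$accuracy, base@accuracy$accuracy, tolerance = 1e-9)
})

test_that("binned decoding places peaks by signal timing with earliest-bin ties", {
  man <- makeManifest(5)
  nN <- 15; nS <- nrow(man); nR <- 6; nBins <- 5
  centers <- seq(10, 90, by = 20)
  set.seed(45)
  pattern <- matrix(rnorm(nN * 5, 0, 1), nN, 5)
  oid <- match(man$object_id, sort(unique(man$object_id)))
  snr <- c(0, 0, 0.25, 0.5, 1)  # ramp gentle enough not to saturate accuracy
  rates <- array(0, c(nN, nS, nR, nBins))
  for (s in seq_len(nS)) for (k in seq_len(nR)) for (b in seq_len(nBins))
    rates[, s, k, b] <- pmax(10 + snr[b] * pattern[, oid[s]] + rnorm(nN, 0, 2), 0)
  tens <- makeBinnedTensor(rates, man, centers, period = c(0, 100))
  cfg <- analysisConfig(binWidth = 20, period = c(0, 100))
  bd <- binnedDecoding(tens, "position", 2, cfg)
  acc <- bd@timeCourse$accuracy
  ## no-signal bins decode at chance (binomial band around 0.2)
  expect_lt(max(abs(acc[1:2] - 0.2)), 1.96 * sqrt(0.2 * 0.8 / 60) + 0.05)
  expect_equal(bd@peakLatency$peak_latency_ms, 90)
})

test_that("bootstrap latency statistics separate shifted time courses and are deterministic", {
  man <- makeManifest(5)
  nN <- 12; nS <- nrow(man); nR <- 6; nBins <- 4
  centers <- seq(10, 70, by = 20)
  set.seed(46)
  pattern <- matrix(rnorm(nN * 5), nN, 5)
  oid <- match(man$object_id, sort(unique(man$object_id)))
  snrA <- c(0, 3, 0.5, 0.1)              # condition size peaks in bin 2
  snrB <- c(0, 0, 3, 0.5)                # condition view: same course, one bin later
  rates <- array(0, c(nN, nS, nR, nBins))
  for (s in seq_len(nS)) for (k in seq_len(nR)) for (b in seq_len(nBins)) {
    snr <- if (man$transformation[s] == "view") snrB else snrA
    rates[, s, k, b] <- pmax(10 + snr[b] * pattern[, oid[s]] + rnorm(nN, 0, 0.2), 0)
  }
  tens <- makeBinnedTensor(rates, man, centers, period = c(0, 80))
  cfg <- analysisConfig(binWidth = 20, period = c(0, 80), nBootstrap = 30,
                        seed = 5)
  boot <- bootstrapLatencies(tens, list(c("view", "1"), c("size", "1")), cfg)
  expect_equal(dim(boot$latencies), c(30, 2))
  expect_true(all(boot$latencies %in% centers))
  expect_equal(boot$pairs$fraction_a_later, 1)    # noise-free one-bin shift
  boot2 <- bootstrapLatencies(tens, list(c("view", "1"), c("size", "1")), cfg)
  expect_identical(boot$latencies, boot2$latencies)
  ## statistically identical conditions whose peak bin is ambiguous give an
  ## intermediate order fraction (no systematic latency advantage)
  snrFlat <- c(0, 1.1, 1.1, 0.2)
  rates2 <- rates
  for (s in which(man$transformation %in% c("view", "size")))
    for (k in seq_len(nR)) for (b in seq_len(nBins))
      rates2[, s, k, b] <- pmax(10 + snrFlat[b] * pattern[, oid[s]] +
                                  rnorm(nN, 0, 1.5), 0)
  tens2 <- makeBinnedTensor(rates2, man, centers, period = c(0, 80))
  boot3 <- bootstrapLatencies(tens2, list(c("view", "1"), c("size", "1")), cfg)
  fr <- boot3$pairs$fraction_a_later
  frOpp <- mean(boot3$latencies[, 2] > boot3$latencies[, 1])
  expect_lt(abs(fr - frOpp), 0.5)  # no strong asymmetry either way
  expect_lt(fr, 0.95)
})

test_that("subset decoding recomputes chance and validates its subsets", {
  man <- makeManifest(6)
  nN <- 18; nS <- nrow(man); nR <- 6
  set.seed(47)
  pattern <- matrix(rnorm(nN * 6, 10, 3), nN, 6)
  oid <- match(man$object_id, sort(unique(man$object_id)))
  rates <- array(0, c(nN, nS, nR))
  for (s in seq_len(nS)) for (k in seq_len(nR))
    rates[, s, k] <- pmax(pattern[, oid[s]] + rnorm(nN, 0, 1), 0)
  tens <- makeTensor(rates, man)
  objs <- sort(unique(man$object_id))[1:4]
  res <- subsetDecoding(tens, "size", 1, objectSubset = objs)
  expect_equal(res@chance, 0.25)
  full <- subsetDecoding(tens, "size", 1, neuronSubset = seq_len(nN))
  ref <- generalizationAccuracy(tens, "size", 1)
  expect_equal(full@accuracy$accuracy, ref@accuracy$accuracy)
  expect_error(subsetDecoding(tens, "size", 1, objectSubset = c("obj01", "zzz")),
               "unknown ids")
  expect_error(subsetDecoding(tens, "size", 1, neuronSubset = integer()),
               "empty")
})

test_that("informative neuron subsets beat random subsets of the same size", {
  man <- makeManifest(6)
  nN <- 24; nS <- nrow(man); nR <- 6
  oid <- match(man$object_id, sort(unique(man$object_id)))
  wins <- 0; nSeeds <- 10
  for (sd in seq_len(nSeeds)) {
    set.seed(500 + sd)
    pattern <- matrix(rnorm(nN * 6, 10, 3), nN, 6)
    informative <- 1:8       # only these carry tuning into the transformed images
    rates <- array(0, c(nN, nS, nR))
    for (s in seq_len(nS)) for (k in seq_len(nR)) {
      mu <- rep(10, nN)
      if (man$transformation[s] == "reference") mu <- pattern[, oid[s]]
      else mu[informative] <- pattern[informative, oid[s]]
      rates[, s, k] <- pmax(mu + rnorm(nN, 0, 2), 0)
    }
    tens <- makeTensor(rates, man)
    accTop <- subsetDecoding(tens, "view", 2,
                             neuronSubset = informative)@accuracy$accuracy[3]
    rnd <- sample(setdiff(seq_len(nN), informative), 8)
    accRnd <- subsetDecoding(tens, "view", 2,
                             neuronSubset = rnd)@accuracy$accuracy[3]
    if (accTop >= accRnd) wins <- wins + 1
  }
  expect_gte(wins, 0.9 * nSeeds)
})
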