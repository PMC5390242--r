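test_that("pixel features are a lossless flattening of the images", {
  set <- smallStimuli()
  px <- pixelFeatures(set)
  expect_s4_class(px, "ActivationMatrix")
  expect_equal(nrow(activations(px)), 64 * 64)
  expect_equal(ncol(activations(px)), 36)
  info <- stimulusInfo(px)
  key <- paste(info$object_id[5], info$transformation[5], info$level[5],
               sep = "_")
  expect_equal(matrix(activations(px)[, 5], 64, 64),
               images(set)[[key]], ignore_attr = TRUE)
})

test_that("Gabor units prefer their orientation and ignore uniform and rescaled input", {
  bank <- gaborBank(frequencies = 0.125, nOrientations = 2, phases = 0,
                    stride = 8)
  ## build a minimal one-object stimulus set holding test patterns
  h <- 48
  grating <- matrix(rep(round(127 * (1 + sin(2 * pi * 0.125 * (1:h)))), each = h),
                    h, h)                 # vertical grating (varies along x)
  blank <- matrix(0L, h, h)
  imgs <- list(grating, blank, grating, grating %/% 2L, grating, grating,
               grating, grating, grating)
  man <- makeManifest(1)
  keys <- paste(man$object_id, man$transformation, man$level, sep = "_")
  names(imgs) <- keys
  info <- cbind(man, parameter = 0, target_delta = 0, realized_delta = 0)
  set <- new("StimulusSet", images = imgs, info = info,
             canvas = c(48L, 48L), tolerance = 1e-3)
  v1 <- v1Features(set, bank)
  a <- activations(v1)
  nPos <- nrow(a) / 2                      # orientation-major unit blocks
  vert <- a[1:nPos, 1]                     # theta = 0: varies along x
  horiz <- a[(nPos + 1):(2 * nPos), 1]
  expect_gt(mean(vert), 2 * mean(horiz))
  ## zero image: zero-mean filters give zero response
  expect_equal(max(abs(a[, 2])), 0)
  ## global intensity scaling cancels in the divisive normalization
  full <- a[, 3]; halfI <- a[, 4]
  expect_lt(max(abs(full - halfI)), 0.02 * max(abs(full)))
})

test_that("external feature files round-trip and are validated", {
  set <- smallStimuli()
  px <- pixelFeatures(set)
  path <- withr::local_tempfile(fileext = ".csv")
  writeActivationMatrix(px, path)
  back <- loadExternalFeatures(path, stimulusInfo(set), source = "pixelcopy")
  expect_equal(unname(activations(back)), unname(activations(px)))
  expect_match(back@source, "^external:")
  ## and feed downstream analyses unchanged
  expect_equal(unitInvariance(back)$mean_r, unitInvariance(px)$mean_r)
  ## column-count mismatch and non-finite entries are rejected
  expect_error(loadExternalFeatures(activations(px)[, 1:10],
                                    stimulusInfo(set)), "match manifest")
  badm <- activations(px)[1:5, ]; badm[1, 1] <- NA
  expect_error(loadExternalFeatures(badm, stimulusInfo(set)), "non-finite")
})

test_that("unit invariance equals its per-unit oracle and detects preserved tuning", {
  man <- makeManifest(6)
  nU <- 12
  set.seed(61)
  ref <- matrix(rnorm(nU * 6), nU, 6)
  acts <- matrix(rnorm(nU * nrow(man)), nU, nrow(man))
  oid <- match(man$object_id, sort(unique(man$object_id)))
  ## size columns copy the reference tuning exactly; others stay random
  for (s in which(man$transformation %in% c("reference", "size")))
    acts[, s] <- ref[, oid[s]]
  am <- makeActs(acts, man, "pixel")
  ui <- unitInvariance(am)
  expect_equal(ui$mean_r[ui$transformation == "size"], c(1, 1), tolerance = 1e-12)
  other <- ui$mean_r[ui$transformation != "size"]
  expect_true(all(abs(other) < 0.35))
  ## oracle: direct per-unit correlation for one condition
  sel <- which(man$transformation == "view" & man$level == 2)
  sel <- sel[order(man$object_id[sel])]
  refSel <- which(man$transformation == "reference")
  refSel <- refSel[order(man$object_id[refSel])]
  rs <- sapply(seq_len(nU), function(u) cor(acts[u, refSel], acts[u, sel]))
  expect_equal(ui$mean_r[ui$transformation == "view" & ui$level == 2],
               mean(rs), tolerance = 1e-10)
})

test_that("dissimilarity matrices obey their contract and match the direct formula", {
  set.seed(62)
  a <- matrix(rnorm(5 * 6), 5, 6)
  a[, 2] <- -a[, 1]                       # anti-correlated pair
  d <- rdm(a)
  v <- dissimilarities(d)
  expect_equal(diag(v), rep(0, 6))
  expect_equal(v[1, 2], 2, tolerance = 1e-12)
  expect_equal(v, t(v))
  for (i in 1:5) for (j in 1:6)
    expect_equal(v[i, j], 1 - cor(a[, i], a[, j]), tolerance = 1e-10)
  ## zero-variance columns become NA with a warning
  a2 <- a; a2[, 3] <- 7
  expect_warning(d2 <- rdm(a2), "zero-variance")
  expect_true(all(is.na(dissimilarities(d2)[3, -3])))
  expect_equal(dissimilarities(d2)[3, 3], 0)
})

test_that("RDM match is perfect on itself, null under permutation, affine-invariant", {
  set.seed(63)
  a <- matrix(rnorm(8 * 20), 8, 20)
  d <- rdm(a)
  expect_equal(unname(rdmMatch(d, d)["r"]), 1, tolerance = 1e-12)
  expect_equal(unname(rdmMatch(d, d)["n"]), 20 * 19 / 2)
  ## permuted stimulus order decorrelates an unstructured matrix
  perm <- sample(20)
  dperm <- new("DissimilarityMatrix",
               values = dissimilarities(d)[perm, perm], source = "perm")
  expect_lt(abs(rdmMatch(dperm, d)["r"]), 0.3)
  ## affine transform of the values leaves the match unchanged
  daff <- new("DissimilarityMatrix",
              values = (dissimilarities(d) * 0.4) |>
                (\(m) {diag(m) <- 0; m})(), source = "aff")
  expect_equal(unname(rdmMatch(daff, d)["r"]), 1, tolerance = 1e-12)
})

test_that("Spearman-Brown correction is exact, monotone, and realized by duplicated halves", {
  expect_equal(spearmanBrown(c(0, 1 / 3, 1)), c(0, 0.5, 1))
  r <- seq(-0.9, 1, by = 0.05)
  expect_true(all(diff(spearmanBrown(r)) > 0))
  expect_true(all(spearmanBrown(r[r >= 0]) >= r[r >= 0]))
  ## duplicated populations in opposite halves correlate perfectly
  man <- makeManifest(6)
  set.seed(64)
  half <- matrix(rnorm(6 * nrow(man)), 6, nrow(man))
  acts <- makeActs(rbind(half, half), man)
  rel <- splitHalfReliability(acts, forceHalves = list(1:6, 7:12))
  expect_equal(rel$r, 1, tolerance = 1e-10)
  expect_equal(rel$rc, 1, tolerance = 1e-10)
  ## random splits: rc >= r on every split with positive r
  acts2 <- makeActs(rbind(half, half) + matrix(rnorm(12 * nrow(man), 0, 0.3),
                                               12), man)
  rel2 <- splitHalfReliability(acts2, nSplits = 8, seed = 2)
  ok <- rel2$per_split$r >= 0
  expect_true(all(rel2$per_split$rc[ok] >= rel2$per_split$r[ok]))
  rel2b <- splitHalfReliability(acts2, nSplits = 8, seed = 2)
  expect_identical(rel2$per_split, rel2b$per_split)
})

test_that("candidates are ranked by their match to the target RDM", {
  man <- makeManifest(5)
  set.seed(65)
  neural <- matrix(rnorm(10 * nrow(man)), 10, nrow(man))
  target <- rdm(makeActs(neural, man))
  near <- neural + matrix(rnorm(length(neural), 0, 0.4), nrow(neural))
  far <- matrix(rnorm(length(neural)), nrow(neural))
  ranked <- rankByMatch(list(noisyCopy = makeActs(near, man),
                             unrelated = makeActs(far, man)), target)
  expect_equal(ranked$candidate[1], "noisyCopy")
  expect_gt(ranked$r[1], ranked$r[2])
})

test_that("pixel-model invariance decreases from small to large changes", {
  set <- smallStimuli()
  px <- pixelFeatures(set)
  ui <- unitInvariance(px)
  for (tr in c("size", "position", "rotation")) {
    r1 <- ui$mean_r[ui$transformation == tr & ui$level == 1]
    r2 <- ui$mean_r[ui$transformation == tr & ui$level == 2]
    expect_gt(r1, r2)
  }
})
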