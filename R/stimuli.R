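#' Balance specification for equating net pixel change
#'
#' Bundles the solver settings used to equate the net pixel change across
#' transformations: the relative matching tolerance and the search range of
#' each scalar transformation parameter. All ranges bracket the identity
#' parameter (scale 1, shift 0, angle 0, view 0).
#'
#' @param tolerance relative tolerance for matching a net-pixel-change
#'   target (dimensionless, > 0).
#' @param scaleRange numeric(2) increasing; size search runs from
#'   `scaleRange[2]` (identity, must be 1) down to `scaleRange[1]`.
#' @param shiftRange numeric(2) `c(0, max)` horizontal shift range, px.
#' @param angleRange numeric(2) `c(0, max)` in-plane rotation range, deg.
#' @param viewRange numeric(2) `c(0, max <= 1)` view parameter range.
#' @param maxIter bisection iteration cap.
#' @param gridPoints dense-grid size for the non-monotone fallback.
#' @return list with class `"BalanceSpec"`.
#' @export
balanceSpec <- function(tolerance = 1e-3,
                        scaleRange = c(0.25, 1),
                        shiftRange = c(0, 20),
                        angleRange = c(0, 170),
                        viewRange = c(0, 1),
                        maxIter = 60L,
                        gridPoints = 512L) {
  stopIfNot(tolerance > 0, "tolerance must be positive")
  stopIfNot(scaleRange[1] > 0 && scaleRange[2] == 1,
            "scaleRange must be (min > 0, 1]")
  stopIfNot(shiftRange[1] == 0 && shiftRange[2] > 0,
            "shiftRange must start at the identity shift 0")
  stopIfNot(angleRange[1] == 0 && angleRange[2] > 0,
            "angleRange must start at the identity angle 0")
  stopIfNot(viewRange[1] == 0 && viewRange[2] > 0 && viewRange[2] <= 1,
            "viewRange must be (0, max <= 1]")
  structure(list(tolerance = tolerance, scaleRange = scaleRange,
                 shiftRange = shiftRange, angleRange = angleRange,
                 viewRange = viewRange, maxIter = as.integer(maxIter),
                 gridPoints = as.integer(gridPoints)),
            class = "BalanceSpec")
}

## map the scalar search parameter p (0 = identity) to render arguments
transformArgs <- function(transformation, p, spec) {
  switch(transformation,
    size     = list(scale = 1 - p * (1 - spec$scaleRange[1]), param = 1 - p * (1 - spec$scaleRange[1])),
    position = list(shift = c(p * spec$shiftRange[2], 0), param = p * spec$shiftRange[2]),
    rotation = list(angle = p * spec$angleRange[2], param = p * spec$angleRange[2]),
    view     = list(view = p * spec$viewRange[2], param = p * spec$viewRange[2]),
    stop(sprintf("unknown transformation '%s'", transformation), call. = FALSE)
  )
}

renderAt <- function(shape, transformation, p, spec) {
  args <- transformArgs(transformation, p, spec)
  args$param <- NULL
  do.call(renderObject, c(list(shape = shape), args))
}

#' Solve a transformation parameter for a net-pixel-change target
#'
#' Finds, by bracketed bisection on the scalar transformation parameter,
#' the size / position / rotation / view magnitude whose rendered image
#' differs from the reference by a given net pixel change. Net change is
#' assumed locally monotone in the parameter magnitude; if bisection does
#' not land within tolerance (possible for rotation, where net change can
#' plateau), a dense grid scan followed by bisection within the best
#' bracket is used.
#'
#' @param shape an [ObjectShape-class].
#' @param transformation one of "size", "position", "rotation", "view".
#' @param target net-pixel-change target (intensity-pixel units, >= 0).
#' @param spec a [balanceSpec()].
#' @return list: `parameter` (the transformation's natural parameter:
#'   scale factor, shift px, angle deg, or view), `realized` net change,
#'   `image` (the rendered image), `iterations`.
#' @export
solveBalance <- function(shape, transformation, target, spec = balanceSpec()) {
  stopIfNot(target >= 0, "target must be nonnegative")
  ref <- renderObject(shape)
  f <- function(p) netPixelChange(ref, renderAt(shape, transformation, p, spec))
  if (target == 0) {
    return(list(parameter = transformArgs(transformation, 0, spec)$param,
                realized = 0, image = ref, iterations = 0L))
  }
  fmax <- f(1)
  if (fmax < target) {
    stop(sprintf(
      "%s: target net change %.0f exceeds the maximum achievable %.0f for %s",
      shape@objectId, target, fmax, transformation), call. = FALSE)
  }
  bisect <- function(lo, hi, flo, fhi) {
    best <- if (abs(flo - target) < abs(fhi - target)) c(lo, flo) else c(hi, fhi)
    it <- 0L
    while (it < spec$maxIter) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm - target) < abs(best[2] - target)) best <- c(mid, fm)
      if (abs(fm - target) / target <= spec$tolerance) break
      if (fm < target) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
      it <- it + 1L
    }
    list(p = best[1], realized = best[2], iterations = it)
  }
  sol <- bisect(0, 1, 0, fmax)
  if (abs(sol$realized - target) / target > spec$tolerance) {
    ## non-monotone fallback: dense scan, then bisection in the best bracket
    grid <- seq(0, 1, length.out = spec$gridPoints)
    fg <- vapply(grid, f, numeric(1))
    i <- which.min(abs(fg - target))
    lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
    sol2 <- bisect(lo, hi, f(lo), f(hi))
    if (abs(sol2$realized - target) < abs(sol$realized - target)) sol <- sol2
    if (abs(sol$realized - target) / target > spec$tolerance)
      stop(sprintf(
        "%s/%s: could not match target %.0f within tolerance (best %.0f)",
        shape@objectId, transformation, target, sol$realized), call. = FALSE)
  }
  list(parameter = transformArgs(transformation, sol$p, spec)$param,
       realized = sol$realized,
       image = renderAt(shape, transformation, sol$p, spec),
       iterations = sol$iterations)
}

#' Build a balanced stimulus set
#'
#' The view transformation at the two requested view levels defines, per
#' object, the two net-pixel-change targets (the small and large change
#' levels). Size, position and rotation magnitudes are then solved so that
#' each produces the same net image change as the view change at that
#' level. The result is `n_objects x (1 reference + 4 transformations x
#' 2 levels)` images (90 for 10 objects) in which, within every object and
#' level, all four transformations have equal net pixel change up to the
#' balancing tolerance.
#'
#' @param shapes list of [ObjectShape-class] objects (>= 1; 10 for the
#'   full design).
#' @param spec a [balanceSpec()].
#' @param viewLevels numeric(2) increasing view parameters defining change
#'   levels 1 and 2.
#' @return A [StimulusSet-class].
#' @export
buildStimulusSet <- function(shapes, spec = balanceSpec(),
                             viewLevels = c(0.45, 0.95)) {
  stopIfNot(length(viewLevels) == 2 && viewLevels[1] < viewLevels[2],
            "viewLevels must be two increasing view parameters")
  stopIfNot(all(viewLevels <= spec$viewRange[2]),
            "viewLevels must lie within the view search range")
  images <- list(); rows <- list()
  canvas <- shapes[[1]]@canvas
  for (shape in shapes) {
    ob <- shape@objectId
    ref <- renderObject(shape)
    key <- paste(ob, "reference", 0, sep = "_")
    images[[key]] <- ref
    rows[[key]] <- data.frame(object_id = ob, transformation = "reference",
                              level = 0L, parameter = 0,
                              target_delta = 0, realized_delta = 0)
    deltas <- numeric(2)
    for (lev in 1:2) {
      vimg <- renderObject(shape, view = viewLevels[lev])
      deltas[lev] <- netPixelChange(ref, vimg)
      key <- paste(ob, "view", lev, sep = "_")
      images[[key]] <- vimg
      rows[[key]] <- data.frame(object_id = ob, transformation = "view",
                                level = lev, parameter = viewLevels[lev],
                                target_delta = deltas[lev],
                                realized_delta = deltas[lev])
    }
    if (!(deltas[1] < deltas[2]))
      stop(sprintf("%s: view level deltas are not increasing (%.0f >= %.0f)",
                   ob, deltas[1], deltas[2]), call. = FALSE)
    for (tr in c("size", "position", "rotation")) {
      for (lev in 1:2) {
        sol <- tryCatch(solveBalance(shape, tr, deltas[lev], spec),
                        error = function(e) stop(sprintf(
                          "balancing %s level %d for %s failed: %s",
                          tr, lev, ob, conditionMessage(e)), call. = FALSE))
        key <- paste(ob, tr, lev, sep = "_")
        images[[key]] <- sol$image
        rows[[key]] <- data.frame(object_id = ob, transformation = tr,
                                  level = lev, parameter = sol$parameter,
                                  target_delta = deltas[lev],
                                  realized_delta = sol$realized)
      }
    }
  }
  info <- do.call(rbind, rows[names(images)])
  rownames(info) <- NULL
  set <- new("StimulusSet", images = images, info = info,
             canvas = canvas, tolerance = spec$tolerance)
  sp <- balanceSpread(set)
  if (max(sp$relative_spread) > 5 * spec$tolerance)
    stop(sprintf("balanced set exceeds tolerance: max relative spread %.2g",
                 max(sp$relative_spread)), call. = FALSE)
  set
}

#' Relative spread of realized net changes within each (object, level)
#'
#' @param set a [StimulusSet-class].
#' @return data.frame with `object_id`, `level`, `relative_spread`
#'   ((max - min) / mean over the four transformations) and `ratio`
#'   (max / min).
#' @export
balanceSpread <- function(set) {
  info <- stimulusInfo(set)
  lv <- info[info$level > 0, ]
  out <- do.call(rbind, lapply(split(lv, list(lv$object_id, lv$level), drop = TRUE),
    function(g) data.frame(object_id = g$object_id[1], level = g$level[1],
                           relative_spread = diff(range(g$realized_delta)) /
                             mean(g$realized_delta),
                           ratio = max(g$realized_delta) / min(g$realized_delta))))
  rownames(out) <- NULL
  out[order(out$object_id, out$level), ]
}

#' Write / read a stimulus set as PNG images plus a manifest CSV
#'
#' Images are written as 8-bit grayscale PNG named
#' `<object>_<transformation>_<level>.png`; the manifest CSV records
#' `object_id, transformation, level, parameter, realized_delta,
#' target_delta, image_path`.
#'
#' @param set a [StimulusSet-class].
#' @param dir output directory (created if needed).
#' @return `writeStimulusSet` returns the manifest path invisibly;
#'   `readStimulusSet` returns a [StimulusSet-class].
#' @export
writeStimulusSet <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  info <- stimulusInfo(set)
  paths <- character(nrow(info))
  for (i in seq_len(nrow(info))) {
    key <- paste(info$object_id[i], info$transformation[i], info$level[i],
                 sep = "_")
    paths[i] <- file.path(dir, paste0(key, ".png"))
    png::writePNG(set@images[[key]] / 255, paths[i])
  }
  manifest <- cbind(info, image_path = basename(paths))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' @param tolerance balancing tolerance recorded in the restored set.
#' @rdname writeStimulusSet
#' @export
readStimulusSet <- function(dir, tolerance = 1e-3) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  images <- list()
  for (i in seq_len(nrow(manifest))) {
    key <- paste(manifest$object_id[i], manifest$transformation[i],
                 manifest$level[i], sep = "_")
    im <- png::readPNG(file.path(dir, manifest$image_path[i]))
    if (length(dim(im)) == 3L) im <- im[, , 1]
    images[[key]] <- matrix(as.integer(round(im * 255)), nrow(im), ncol(im))
  }
  info <- manifest[, c("object_id", "transformation", "level", "parameter",
                       "target_delta", "realized_delta")]
  new("StimulusSet", images = images, info = info,
      canvas = dim(images[[1]]), tolerance = tolerance)
}
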