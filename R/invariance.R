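#' Tuning correlation between reference and transformed responses
#'
#' The per-neuron invariance measure: the Pearson correlation, across
#' objects, between mean responses to the reference images and mean
#' responses to the transformed images. A preserved object preference
#' gives r near 1; unrelated tuning gives r near 0. The two-sided p-value
#' comes from the standard t transform of r.
#'
#' @param ref,trans numeric vectors of per-object mean rates (same object
#'   order, >= 3 objects).
#' @param method "pearson" (default) or "spearman".
#' @return named numeric: `r`, `p`, `n`. `r` and `p` are NA when either
#'   vector has zero variance (degenerate tuning).
#' @export
tuningCorrelation <- function(ref, trans, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopIfNot(length(ref) == length(trans), "vectors must have equal length")
  stopIfNot(length(ref) >= 3, "need >= 3 objects")
  if (method == "pearson") return(corTestSafe(ref, trans))
  if (stats::sd(ref) == 0 || stats::sd(trans) == 0)
    return(c(r = NA_real_, p = NA_real_, n = length(ref)))
  ct <- suppressWarnings(stats::cor.test(ref, trans, method = "spearman"))
  c(r = unname(ct$estimate), p = ct$p.value, n = length(ref))
}

## mean over repetitions -> neurons x objects matrix for one condition
conditionMeans <- function(tensor, transformation, level, bin = NULL) {
  info <- tensor@stimulusInfo
  sel <- which(info$transformation == transformation & info$level == level)
  sel <- sel[order(info$object_id[sel])]
  if (is.null(bin)) {
    m <- apply(tensor@rates[, sel, , drop = FALSE], c(1, 2), mean)
  } else {
    m <- apply(tensor@rates[, sel, , bin, drop = FALSE], c(1, 2), mean)
  }
  colnames(m) <- info$object_id[sel]
  m
}

checkCells <- function(info, levels = 1:2) {
  missing <- character()
  for (tr in c("reference", TRANSFORMATIONS)) {
    lv <- if (tr == "reference") 0 else levels
    for (l in lv)
      if (!any(info$transformation == tr & info$level == l))
        missing <- c(missing, paste0(tr, "/level ", l))
  }
  if (length(missing))
    stop("stimulus cells missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
}

## vectorized per-neuron Pearson r between rows of two matrices
rowCorrelations <- function(A, B) {
  A <- A - rowMeans(A); B <- B - rowMeans(B)
  den <- sqrt(rowSums(A^2) * rowSums(B^2))
  r <- rowSums(A * B) / den
  r[den == 0] <- NA_real_
  r
}

#' Per-neuron invariance table with summaries and pairwise tests
#'
#' Computes, for every neuron and every transformation x level cell, the
#' tuning correlation between trial-averaged responses to the reference
#' and the transformed images, flags neurons with p below `alpha` as
#' invariant, and summarizes per condition (mean r, SEM, fraction
#' invariant, mean r among invariant neurons). Transformations are
#' compared pairwise within each level by a two-sided Wilcoxon sign-rank
#' test on the per-neuron correlations and by a two-proportion chi-square
#' test on the invariant fractions. Neurons with degenerate (zero
#' variance) tuning are recorded as NA and excluded pairwise; their count
#' is reported in the summary.
#'
#' @param tensor a windowed [ResponseTensor-class] containing the
#'   reference and all transformation x level cells.
#' @param config an [analysisConfig()].
#' @param method correlation type, "pearson" or "spearman".
#' @return An [InvarianceTable-class].
#' @export
invarianceTable <- function(tensor, config = analysisConfig(),
                            method = "pearson") {
  info <- tensor@stimulusInfo
  checkCells(info)
  refM <- conditionMeans(tensor, "reference", 0)
  nN <- nrow(refM)
  per <- list(); k <- 0L
  for (tr in TRANSFORMATIONS) for (lev in 1:2) {
    trM <- conditionMeans(tensor, tr, lev)
    rp <- t(vapply(seq_len(nN), function(i)
      tuningCorrelation(refM[i, ], trM[i, ], method = method)[c("r", "p")],
      numeric(2)))
    k <- k + 1L
    per[[k]] <- data.frame(neuron_id = seq_len(nN), transformation = tr,
                           level = lev, r = rp[, 1], p = rp[, 2],
                           invariant = rp[, 2] < config$alpha)
  }
  perNeuron <- do.call(rbind, per)
  summarize <- function(g) {
    inv <- g$invariant
    data.frame(transformation = g$transformation[1], level = g$level[1],
               mean_r = mean(g$r, na.rm = TRUE), sem_r = sem(g$r),
               n_defined = sum(!is.na(g$r)),
               n_invariant = sum(inv, na.rm = TRUE),
               fraction_invariant = sum(inv, na.rm = TRUE) / max(sum(!is.na(g$r)), 1),
               mean_r_invariant = if (any(inv, na.rm = TRUE))
                 mean(g$r[which(inv)]) else NA_real_)
  }
  groups <- split(perNeuron, list(perNeuron$transformation, perNeuron$level))
  summary <- do.call(rbind, lapply(groups, summarize))
  summary <- summary[order(summary$level,
                           match(summary$transformation, TRANSFORMATIONS)), ]
  rownames(summary) <- NULL
  pw <- list(); k <- 0L
  pairs <- utils::combn(TRANSFORMATIONS, 2)
  for (lev in 1:2) for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ra <- perNeuron$r[perNeuron$transformation == a & perNeuron$level == lev]
    rb <- perNeuron$r[perNeuron$transformation == b & perNeuron$level == lev]
    ok <- !is.na(ra) & !is.na(rb)
    pSign <- if (sum(ok) >= 3)
      suppressWarnings(stats::wilcox.test(ra[ok], rb[ok], paired = TRUE)$p.value)
      else NA_real_
    na_ <- sum(perNeuron$invariant[perNeuron$transformation == a &
                                     perNeuron$level == lev], na.rm = TRUE)
    nb_ <- sum(perNeuron$invariant[perNeuron$transformation == b &
                                     perNeuron$level == lev], na.rm = TRUE)
    nda <- summary$n_defined[summary$transformation == a & summary$level == lev]
    ndb <- summary$n_defined[summary$transformation == b & summary$level == lev]
    pChi <- if (nda >= 2 && ndb >= 2)
      suppressWarnings(stats::prop.test(c(na_, nb_), c(nda, ndb),
                                        correct = FALSE)$p.value)
      else NA_real_
    k <- k + 1L
    pw[[k]] <- data.frame(level = lev, transformation_a = a,
                          transformation_b = b, p_signrank = pSign,
                          p_fraction_chisq = pChi)
  }
  new("InvarianceTable", perNeuron = perNeuron,
      summary = summary, pairwise = do.call(rbind, pw),
      alpha = config$alpha)
}

#' Time-resolved invariance: per-bin tuning correlations and peak latency
#'
#' Computes the mean tuning correlation across neurons in every time bin
#' for each transformation x level, its peak latency (center of the
#' maximal bin, earliest bin on ties), and a per-bin two-sided rank-sum
#' comparison of the affine invariances (size, position; per-neuron mean)
#' against the non-affine ones (rotation, view).
#'
#' @param tensor a binned (4D) [ResponseTensor-class].
#' @param config an [analysisConfig()].
#' @return list: `timeCourse` (data.frame `bin_center_ms`,
#'   `transformation`, `level`, `mean_r`, `sem_r`, `n`), `peakLatency`
#'   (data.frame `transformation`, `level`, `peak_latency_ms`),
#'   `affineVsNonaffine` (data.frame `bin_center_ms`, `level`,
#'   `p_ranksum`).
#' @export
binnedInvariance <- function(tensor, config = analysisConfig()) {
  stopIfNot(length(dim(tensor@rates)) == 4L, "tensor must be binned (4D)")
  info <- tensor@stimulusInfo
  checkCells(info)
  centers <- tensor@binCenters
  nBins <- length(centers)
  tc <- list(); cmp <- list(); ki <- 0L; kc <- 0L
  perNeuronR <- array(NA_real_,
                      dim = c(dim(tensor@rates)[1], 4, 2, nBins),
                      dimnames = list(NULL, TRANSFORMATIONS, NULL, NULL))
  for (b in seq_len(nBins)) {
    refM <- conditionMeans(tensor, "reference", 0, bin = b)
    for (tr in TRANSFORMATIONS) for (lev in 1:2) {
      trM <- conditionMeans(tensor, tr, lev, bin = b)
      r <- rowCorrelations(refM, trM)
      perNeuronR[, tr, lev, b] <- r
      ki <- ki + 1L
      tc[[ki]] <- data.frame(bin_center_ms = centers[b], transformation = tr,
                             level = lev,
                             mean_r = if (all(is.na(r))) NA_real_ else
                               mean(r, na.rm = TRUE),
                             sem_r = sem(r), n = sum(!is.na(r)))
    }
    for (lev in 1:2) {
      aff <- rowMeans(perNeuronR[, c("size", "position"), lev, b], na.rm = TRUE)
      non <- rowMeans(perNeuronR[, c("rotation", "view"), lev, b], na.rm = TRUE)
      ok <- is.finite(aff) & is.finite(non)
      kc <- kc + 1L
      cmp[[kc]] <- data.frame(
        bin_center_ms = centers[b], level = lev,
        p_ranksum = if (sum(ok) >= 3)
          suppressWarnings(stats::wilcox.test(aff[ok], non[ok])$p.value)
          else NA_real_)
    }
  }
  timeCourse <- do.call(rbind, tc)
  peak <- do.call(rbind, lapply(split(timeCourse,
      list(timeCourse$transformation, timeCourse$level)), function(g) {
    g <- g[order(g$bin_center_ms), ]
    i <- which.max(g$mean_r)  # earliest bin on ties (which.max takes first)
    data.frame(transformation = g$transformation[1], level = g$level[1],
               peak_latency_ms = g$bin_center_ms[i])
  }))
  rownames(peak) <- NULL
  list(timeCourse = timeCourse, peakLatency = peak,
       affineVsNonaffine = do.call(rbind, cmp))
}

#' Covariation of invariances across neurons
#'
#' For every pair of transformations, the Pearson correlation across
#' neurons between their tuning correlations: a positive value means that
#' neurons strongly invariant to one transformation tend to be strongly
#' invariant to the other.
#'
#' @param table an [InvarianceTable-class].
#' @return list per level of 4 x 4 matrices `r` and `p` (NA diagonal kept
#'   at 1 / 0 respectively; cells with fewer than 3 jointly defined
#'   neurons are NA).
#' @export
invarianceCovariation <- function(table) {
  per <- table@perNeuron
  out <- list()
  for (lev in sort(unique(per$level))) {
    rmat <- matrix(NA_real_, 4, 4, dimnames = list(TRANSFORMATIONS, TRANSFORMATIONS))
    pmat <- rmat
    diag(rmat) <- 1; diag(pmat) <- 0
    for (a in TRANSFORMATIONS) for (b in TRANSFORMATIONS) {
      if (a == b) next
      ra <- per$r[per$transformation == a & per$level == lev]
      rb <- per$r[per$transformation == b & per$level == lev]
      ct <- corTestSafe(ra, rb)
      rmat[a, b] <- ct["r"]; pmat[a, b] <- ct["p"]
    }
    out[[as.character(lev)]] <- list(r = rmat, p = pmat)
  }
  out
}

#' Expected co-occurrence counts under independence
#'
#' Given that `nA` of `n` neurons are invariant to transformation A and
#' `nB` to transformation B, the counts expected in the four cells
#' (both, B only, A only, neither) if the two properties were distributed
#' independently: products of the marginal proportions times `n`.
#'
#' @param nA,nB invariant counts for A and B.
#' @param n total neurons.
#' @return list: `expected` (rounded counts, order both / B-only / A-only /
#'   neither) and `unrounded`.
#' @examples
#' expectedCooccurrence(51, 57, 127)$expected  # 23 34 28 42
#' @export
expectedCooccurrence <- function(nA, nB, n) {
  stopIfNot(nA >= 0 && nB >= 0 && nA <= n && nB <= n,
            "counts must lie in [0, n]")
  pA <- nA / n; pB <- nB / n
  unrounded <- n * c(both = pA * pB, b_only = (1 - pA) * pB,
                     a_only = pA * (1 - pB), neither = (1 - pA) * (1 - pB))
  list(expected = round(unrounded), unrounded = unrounded)
}

#' Chi-square test of invariance co-occurrence against independence
#'
#' Compares the observed 4-cell co-occurrence counts (both, B only,
#' A only, neither) with the counts expected under independent
#' distribution of the two invariances, using the statistic
#' sum((O - E)^2 / E). By default the unrounded expectations enter the
#' statistic; `rounded = TRUE` uses integer-rounded expectations instead
#' (matching back-of-envelope arithmetic on printed counts). Because the
#' appropriate degrees of freedom for this comparison are debatable (the
#' four cells carry one free dimension once both margins are taken as
#' given, three if only the total is), p-values under df = 1 and df = 3
#' are both reported.
#'
#' @param observed integer(4), order both / B-only / A-only / neither.
#' @param nA,nB,n marginal invariant counts and total neurons.
#' @param rounded use rounded expectations in the statistic.
#' @return list: `statistic`, `expected`, `p_df1`, `p_df3`, `warning`
#'   (message when any expected cell is below 1, else NULL).
#' @export
cooccurrenceTest <- function(observed, nA, nB, n, rounded = FALSE) {
  stopIfNot(length(observed) == 4, "observed must have 4 cells")
  stopIfNot(sum(observed) == n, "observed must sum to n")
  exp_ <- expectedCooccurrence(nA, nB, n)
  E <- if (rounded) exp_$expected else exp_$unrounded
  warn <- NULL
  if (any(E < 1))
    warn <- sprintf("%d expected cell(s) below 1; chi-square approximation unreliable",
                    sum(E < 1))
  contrib <- (observed - E)^2 / E
  contrib[E == 0 & observed == 0] <- 0  # empty margin: no discrepancy
  stat <- sum(contrib)
  list(statistic = stat, expected = E,
       p_df1 = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       p_df3 = stats::pchisq(stat, df = 3, lower.tail = FALSE),
       warning = warn)
}
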