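#' @include scan-mle.R
NULL

#' Two-QTL grid-search result
#'
#' Best ordered pair of QTL positions on one chromosome under the
#' additive two-QTL half-sib regression model, with nested-model F tests
#' and per-QTL standardized effects.
#'
#' @slot chromosome chromosome scanned.
#' @slot positionA,positionB QTL positions in cM, A < B.
#' @slot flankA,flankB flanking marker names per QTL.
#' @slot f2vs0 F statistic of the two-QTL model against no QTL (2 df).
#' @slot f2vs1 F statistic against the best single-QTL model (1 df).
#' @slot effects data.frame: per-QTL effect in SD units with SE.
#' @slot phase `"repulsion"` (opposite-sign effects) or `"coupling"`.
#' @slot n daughters used.
#' @export
setClass("TwoQTLResult",
         representation(chromosome = "integer", positionA = "numeric",
                        positionB = "numeric", flankA = "character",
                        flankB = "character", f2vs0 = "numeric",
                        f2vs1 = "numeric", effects = "data.frame",
                        phase = "character", n = "integer"))

setMethod("show", "TwoQTLResult", function(object) {
  cat(sprintf(
    "TwoQTLResult chr %d: A at %.1f cM, B at %.1f cM (%s); F(2vs0)=%.2f F(2vs1)=%.2f\n",
    object@chromosome, object@positionA, object@positionB, object@phase,
    object@f2vs0, object@f2vs1))
})

# centered predictor matrix x = 2 P(A) - 1 at grid positions
.regressionX <- function(genotypes, chromosome, grid, mapFunction) {
  P <- transmissionProb(genotypes, chromosome = chromosome, query = grid,
                        mapFunction = mapFunction)
  2 * P - 1
}

# single-predictor F statistics for all columns of X against y
.scanF <- function(y, X) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  sxy <- as.numeric(crossprod(Xc, yc))
  ok <- sxx > 1e-12
  beta <- rss1 <- Fv <- rep(NA_real_, ncol(X))
  beta[ok] <- sxy[ok] / sxx[ok]
  rss1[ok] <- pmax(syy - sxy[ok]^2 / sxx[ok], 0)
  Fv[ok] <- (syy - rss1[ok]) / (rss1[ok] / (n - 2))
  list(F = Fv, beta = beta, rss1 = rss1, rss0 = syy, ok = ok)
}

#' Single-QTL genome scan by half-sib regression
#'
#' Least-squares interval mapping for a single-sire half-sib family: at
#' each grid position the trait is regressed on
#' x_i = P_i(A) - P_i(M) = 2 P_i(A) - 1, and the 1-df F statistic
#' F = (RSS0 - RSS1) / (RSS1 / (n - 2)) is recorded. Significance classes
#' require permutation thresholds (see [permuteThresholds()] and
#' [classifyF()]).
#'
#' @inheritParams scanMle
#' @param thresholds optional [permuteThresholds()] table used to classify
#'   the peak.
#' @return a [ScanResult-class]; its `table` has columns `position`,
#'   `stat` (F), `beta`, `skipped` (monomorphic positions).
#' @export
scanRegression <- function(y, genotypes, chromosome, step = 1,
                           mapFunction = "haldane", minDaughters = 30,
                           thresholds = NULL) {
  al <- .alignTrait(y, genotypes)
  if (length(al$y) < minDaughters)
    stop("need >= ", minDaughters, " daughters with phenotype and genotypes")
  map <- linkageMap(genotypes)
  grid <- scanGrid(map, chromosome, step)
  X <- .regressionX(genotypes, chromosome, grid, mapFunction)[al$ids, ,
                                                             drop = FALSE]
  sf <- .scanF(al$y, X)
  n <- length(al$y)
  tab <- data.frame(position = grid, stat = sf$F, beta = sf$beta,
                    skipped = !sf$ok)
  if (all(is.na(sf$F))) stop("no polymorphic position on chromosome ",
                             chromosome)
  pk <- which.max(sf$F)
  sdPhen <- stats::sd(al$y)
  eff <- 2 * sf$beta[pk]  # class contrast: x differs by 2 between A and M
  lodEquiv <- (n / 2) * log10(sf$rss0 / sf$rss1)
  ci <- supportInterval(grid, lodEquiv, drop = 1)
  notes <- if (any(!sf$ok))
    sprintf("monomorphic_positions_skipped:%d", sum(!sf$ok)) else character()
  cls <- if (is.null(thresholds)) "none" else classifyF(sf$F[pk], thresholds)
  new("ScanResult", table = tab, statistic = "F",
      chromosome = as.integer(chromosome), peakPosition = grid[pk],
      peakValue = sf$F[pk], interval = as.numeric(ci), effect = eff,
      effectSD = eff / sdPhen, sigClass = cls,
      flankingMarkers = .flankNames(map, chromosome, grid[pk]),
      method = "regression", n = as.integer(n), notes = notes)
}

#' Chromosome-wide and experiment-wide permutation thresholds
#'
#' Phenotypes are permuted against the genotype rows; the maximum F over
#' the chromosome is recorded per permutation and thresholds are its
#' empirical quantiles. Experiment-wide levels use a Bonferroni-style
#' adjustment of the chromosome-wise tail over the 26 autosomes.
#'
#' @inheritParams scanRegression
#' @param n number of permutations (>= 100; 1000 matches the published
#'   convention).
#' @param seed RNG seed; identical seeds give bit-identical thresholds.
#' @param alphas chromosome-wide significance levels.
#' @param nAutosomes genome size used for the experiment-wide adjustment.
#' @return data.frame (`scope`, `alpha`, `threshold`) with attributes
#'   `n_permutations`, `seed`, `maxF` (the permutation maxima).
#' @export
permuteThresholds <- function(y, genotypes, chromosome, n = 1000, seed = 1,
                              step = 1, mapFunction = "haldane",
                              alphas = c(0.05, 0.01), nAutosomes = 26) {
  stopifnot(n >= 100)
  al <- .alignTrait(y, genotypes)
  map <- linkageMap(genotypes)
  grid <- scanGrid(map, chromosome, step)
  X <- .regressionX(genotypes, chromosome, grid, mapFunction)[al$ids, ,
                                                              drop = FALSE]
  nd <- length(al$y)
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  ok <- sxx > 1e-12
  set.seed(seed)
  Yp <- vapply(seq_len(n), function(i) sample(al$y), numeric(nd))
  Yc <- sweep(Yp, 2, colMeans(Yp))
  syy <- colSums(Yc^2)
  SXY <- crossprod(Xc[, ok, drop = FALSE], Yc)        # positions x perms
  R2 <- sweep(SXY^2, 1, sxx[ok], "/")
  R2 <- sweep(R2, 2, syy, "/")
  Fmat <- (nd - 2) * R2 / (1 - R2)
  maxF <- apply(Fmat, 2, max)
  out <- rbind(
    data.frame(scope = "chromosome", alpha = alphas,
               threshold = as.numeric(stats::quantile(maxF, 1 - alphas))),
    data.frame(scope = "experiment", alpha = alphas,
               threshold = as.numeric(
                 stats::quantile(maxF, 1 - alphas / nAutosomes))))
  # thresholds must be nondecreasing as alpha decreases within scope
  structure(out, n_permutations = n, seed = seed, maxF = maxF,
            class = c("permutationThresholds", "data.frame"))
}

#' Classify a peak F statistic against permutation thresholds
#'
#' Published convention for the regression route: chromosome-wide
#' P < 0.05 suggestive, chromosome-wide P < 0.01 significant,
#' experiment-wide P < 0.05 highly significant. Stars `*`/`**`/`***`
#' (`****` for experiment-wide P < 0.01) are attached as an attribute.
#'
#' @param f peak F statistic.
#' @param thresholds a [permuteThresholds()] table.
#' @return class string with attribute `stars`.
#' @export
classifyF <- function(f, thresholds) {
  get_thr <- function(scope, alpha) {
    i <- thresholds$scope == scope & abs(thresholds$alpha - alpha) < 1e-12
    if (any(i)) thresholds$threshold[i][1] else Inf
  }
  cls <- "none"; stars <- ""
  if (f > get_thr("chromosome", 0.05)) { cls <- "suggestive"; stars <- "*" }
  if (f > get_thr("chromosome", 0.01)) { cls <- "significant"; stars <- "**" }
  if (f > get_thr("experiment", 0.05)) { cls <- "highly significant"
                                         stars <- "***" }
  if (f > get_thr("experiment", 0.01)) stars <- "****"
  structure(cls, stars = stars)
}

#' Bootstrap confidence interval for QTL position
#'
#' Daughters are resampled with replacement; the regression-scan peak
#' position is recorded per resample and the percentile interval of the
#' peaks is returned. Degenerate resamples (no polymorphic position) are
#' redrawn and counted.
#'
#' @inheritParams scanRegression
#' @param n bootstrap resamples (1000 matches the published convention).
#' @param seed RNG seed.
#' @param level coverage level (default 0.95).
#' @return numeric `c(lo, hi)` cM with attributes `peaks`, `n_redrawn`,
#'   `seed`.
#' @export
bootstrapCi <- function(y, genotypes, chromosome, n = 1000, seed = 1,
                        level = 0.95, step = 1, mapFunction = "haldane") {
  al <- .alignTrait(y, genotypes)
  map <- linkageMap(genotypes)
  grid <- scanGrid(map, chromosome, step)
  X <- .regressionX(genotypes, chromosome, grid, mapFunction)[al$ids, ,
                                                              drop = FALSE]
  nd <- length(al$y)
  set.seed(seed)
  peaks <- numeric(n)
  redrawn <- 0L
  for (b in seq_len(n)) {
    repeat {
      idx <- sample.int(nd, nd, replace = TRUE)
      sf <- .scanF(al$y[idx], X[idx, , drop = FALSE])
      if (any(sf$ok)) break
      redrawn <- redrawn + 1L
    }
    peaks[b] <- grid[which.max(sf$F)]
  }
  qs <- stats::quantile(peaks, c((1 - level) / 2, 1 - (1 - level) / 2))
  structure(as.numeric(qs), peaks = peaks, n_redrawn = redrawn, seed = seed)
}

#' QTL heritability from nested residual mean squares
#'
#' Proportion of phenotypic variance accounted for by the QTL:
#' 1 - RMS(full) / RMS(reduced), from the residual mean squares of the
#' regression fits with and without the QTL. Negative values (sampling
#' noise) are clipped to 0 and flagged.
#'
#' @param rssFull,rssReduced residual sums of squares of the full
#'   (QTL) and reduced (no-QTL) models.
#' @param dfFull,dfReduced residual degrees of freedom.
#' @return proportion in \[0, 1\] with attribute `clipped`.
#' @export
qtlHeritability <- function(rssFull, rssReduced, dfFull, dfReduced) {
  rmsF <- rssFull / dfFull
  rmsR <- rssReduced / dfReduced
  if (!is.finite(rmsF) || !is.finite(rmsR) || rmsF <= 0 || rmsR <= 0)
    stop("residual mean squares must be positive")
  h <- 1 - rmsF / rmsR
  structure(max(h, 0), clipped = h < 0)
}

#' Two-QTL grid search on one chromosome
#'
#' Fits the additive model y ~ x(A) + x(B) over ordered position pairs on
#' a coarse grid, excluding pairs closer than `minSep` cM (collinearity
#' guard). F(2vs0) tests the pair against no QTL, F(2vs1) against the
#' best single-QTL fit on the chromosome. Effects are reported in
#' phenotypic SD units with standard errors; repulsion/coupling phase
#' from the effect signs.
#'
#' @inheritParams scanRegression
#' @param step pair grid step in cM (default 2).
#' @param minSep minimum separation between the two QTL in cM (default 5).
#' @return a [TwoQTLResult-class].
#' @export
scanTwoQtl <- function(y, genotypes, chromosome, step = 2, minSep = 5,
                       mapFunction = "haldane", minDaughters = 30) {
  al <- .alignTrait(y, genotypes)
  if (length(al$y) < minDaughters)
    stop("need >= ", minDaughters, " daughters with phenotype and genotypes")
  map <- linkageMap(genotypes)
  if (nrow(mapTable(map, chromosome)) < 3)
    stop("two-QTL search needs >= 3 markers on the chromosome")
  grid <- scanGrid(map, chromosome, step)
  X <- .regressionX(genotypes, chromosome, grid, mapFunction)[al$ids, ,
                                                              drop = FALSE]
  yv <- al$y
  n <- length(yv)
  yc <- yv - mean(yv)
  syy <- sum(yc^2)
  Xc <- sweep(X, 2, colMeans(X))
  single <- .scanF(yv, X)
  rss1star <- min(single$rss1, na.rm = TRUE)

  best <- list(rss2 = Inf)
  S <- crossprod(Xc)             # precomputed cross-products
  sy <- as.numeric(crossprod(Xc, yc))
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      if (grid[j] - grid[i] < minSep) next
      det <- S[i, i] * S[j, j] - S[i, j]^2
      if (det < 1e-10) next
      b1 <- (S[j, j] * sy[i] - S[i, j] * sy[j]) / det
      b2 <- (S[i, i] * sy[j] - S[i, j] * sy[i]) / det
      rss2 <- syy - b1 * sy[i] - b2 * sy[j]
      if (rss2 < best$rss2)
        best <- list(i = i, j = j, b1 = b1, b2 = b2, rss2 = rss2, det = det)
    }
  }
  if (!is.finite(best$rss2)) stop("no admissible position pair on chromosome ",
                                  chromosome)
  rss2 <- max(best$rss2, 1e-12)
  sig2 <- rss2 / (n - 3)
  f20 <- ((syy - rss2) / 2) / sig2
  f21 <- (rss1star - rss2) / sig2
  seb1 <- sqrt(sig2 * S[best$j, best$j] / best$det)
  seb2 <- sqrt(sig2 * S[best$i, best$i] / best$det)
  sdPhen <- stats::sd(yv)
  eff <- data.frame(qtl = c("A", "B"), position = grid[c(best$i, best$j)],
                    effect_sd = 2 * c(best$b1, best$b2) / sdPhen,
                    se_sd = 2 * c(seb1, seb2) / sdPhen)
  new("TwoQTLResult", chromosome = as.integer(chromosome),
      positionA = grid[best$i], positionB = grid[best$j],
      flankA = .flankNames(map, chromosome, grid[best$i]),
      flankB = .flankNames(map, chromosome, grid[best$j]),
      f2vs0 = f20, f2vs1 = f21, effects = eff,
      phase = if (sign(best$b1) != sign(best$b2)) "repulsion" else "coupling",
      n = as.integer(n))
}
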