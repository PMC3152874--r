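#' @include linkage.R
NULL

#' Log-transform trait values for QTL analysis
#'
#' Natural-log transform applied to all traits before mapping, for
#' normality. Zeros receive an offset of half the smallest positive value
#' (zeros only; positives are logged as-is). The transform is recorded in
#' attributes.
#'
#' @param values nonnegative trait values.
#' @return log-scale values with attributes `transform`, `zero_offset`,
#'   `n_zero`.
#' @export
transformTrait <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stop("trait values must be nonnegative")
  posv <- values[!is.na(values) & values > 0]
  if (!length(posv)) stop("all-zero trait cannot be log-transformed")
  delta <- min(posv) / 2
  zero <- !is.na(values) & values == 0
  out <- log(ifelse(zero, delta, values))
  structure(out, transform = "natural log", zero_offset = delta,
            n_zero = sum(zero))
}

#' Finite-mixture log-likelihood of a backcross QTL model
#'
#' At a scan position each daughter carries the Awassi sire allele with
#' probability `p_i`; the trait is modelled as a two-component normal
#' mixture with class means `mu` = (mu_A, mu_M) and common SD `sigma`:
#' sum_i ln\[p_i phi(y_i; mu_A, sigma) + (1 - p_i) phi(y_i; mu_M, sigma)\].
#'
#' @param y trait values (analysis scale).
#' @param p per-daughter P(transmitted allele = A), in \[0, 1\].
#' @param mu length-2 numeric, class means (A then M).
#' @param sigma common SD, positive.
#' @return log-likelihood (scalar).
#' @export
mixtureLogLik <- function(y, p, mu, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  stopifnot(length(mu) == 2, length(p) == length(y),
            all(p >= 0 & p <= 1), all(is.finite(y)))
  mix <- p * stats::dnorm(y, mu[1], sigma) +
    (1 - p) * stats::dnorm(y, mu[2], sigma)
  sum(log(pmax(mix, .Machine$double.xmin)))
}

# EM for the homoscedastic two-normal mixture at one position.
# Returns loglik floored at the no-QTL loglik (nested null).
.emPosition <- function(y, p, null, maxit = 200, tol = 1e-8) {
  n <- length(y)
  muA <- null$mu + 0.5 * null$sd
  muM <- null$mu - 0.5 * null$sd
  sig <- null$sd
  llPrev <- -Inf; ll <- -Inf; converged <- FALSE
  for (it in seq_len(maxit)) {
    dA <- stats::dnorm(y, muA, sig)
    dM <- stats::dnorm(y, muM, sig)
    mix <- pmax(p * dA + (1 - p) * dM, .Machine$double.xmin)
    ll <- sum(log(mix))
    if (is.finite(llPrev) && abs(ll - llPrev) < tol * (abs(ll) + tol)) {
      converged <- TRUE
      break
    }
    llPrev <- ll
    w <- p * dA / mix
    sA <- sum(w); sM <- n - sA
    if (sA > 1e-10) muA <- sum(w * y) / sA
    if (sM > 1e-10) muM <- sum((1 - w) * y) / sM
    sig <- sqrt(sum(w * (y - muA)^2 + (1 - w) * (y - muM)^2) / n)
    sig <- max(sig, 1e-10)
  }
  if (ll < null$ll) {  # EM drifted below the nested no-QTL optimum
    list(ll = null$ll, muA = null$mu, muM = null$mu, sigma = null$sd,
         converged = converged, iter = it)
  } else {
    list(ll = ll, muA = muA, muM = muM, sigma = sig,
         converged = converged, iter = it)
  }
}

#' Classify a LOD score
#'
#' Printed LOD classes for the mixture-ML scan: below 1.75 none,
#' \[1.75, 2) suggestive, \[2, 3\] significant, above 3 highly
#' significant.
#'
#' @param lod LOD score(s), nonnegative.
#' @return character class per value.
#' @examples
#' classifyLod(c(1.74, 1.9, 2.2, 3.4))
#' @export
classifyLod <- function(lod) {
  if (any(lod < 0, na.rm = TRUE)) stop("LOD must be nonnegative")
  ifelse(lod > 3, "highly significant",
         ifelse(lod >= 2, "significant",
                ifelse(lod >= 1.75, "suggestive", "none")))
}

#' 1-LOD support interval from a scan profile
#'
#' Widest contiguous grid region containing the peak on which the
#' statistic stays within `drop` of its maximum, clipped at the
#' chromosome ends. Ties at the maximum are broken leftmost and flagged.
#'
#' @param positions grid positions in cM.
#' @param stat statistic per position (LOD scale).
#' @param drop drop-off defining the interval (default 1 LOD).
#' @return numeric `c(lo, hi)` with attributes `peak` and `tied`.
#' @export
supportInterval <- function(positions, stat, drop = 1) {
  stopifnot(length(positions) == length(stat), length(stat) >= 1)
  pk <- which(stat == max(stat, na.rm = TRUE))[1]
  tied <- sum(stat == max(stat, na.rm = TRUE), na.rm = TRUE) > 1
  thr <- stat[pk] - drop
  lo <- pk
  while (lo > 1 && !is.na(stat[lo - 1]) && stat[lo - 1] >= thr) lo <- lo - 1
  hi <- pk
  while (hi < length(stat) && !is.na(stat[hi + 1]) && stat[hi + 1] >= thr)
    hi <- hi + 1
  structure(c(positions[lo], positions[hi]), peak = positions[pk],
            tied = tied)
}

#' Standardize a QTL effect to phenotypic SD units
#'
#' The class-mean contrast (Awassi minus Merino) divided by the residual
#' SD of the no-QTL model; positive values mean the Awassi allele raises
#' the trait.
#'
#' @param muA,muM fitted class means at the peak.
#' @param sdNull phenotypic (no-QTL residual) SD on the analysis scale.
#' @return effect in SD units.
#' @export
standardizedEffect <- function(muA, muM, sdNull) {
  if (sdNull <= 0) stop("phenotypic SD must be positive")
  (muA - muM) / sdNull
}

.alignTrait <- function(y, genotypes) {
  ids <- daughters(genotypes)
  if (!is.null(names(y))) {
    common <- intersect(ids, names(y)[!is.na(y)])
    list(y = as.numeric(y[common]), ids = common)
  } else {
    stopifnot(length(y) == length(ids))
    keep <- !is.na(y)
    list(y = y[keep], ids = ids[keep])
  }
}

.flankNames <- function(map, chromosome, position) {
  m <- mapTable(map, chromosome)
  L <- max(which(m$position <= position))
  R <- min(which(m$position >= position))
  c(m$marker[L], m$marker[R])
}

#' Single-QTL genome scan by finite-mixture maximum likelihood
#'
#' At every grid position the transmitted-allele probabilities from the
#' flanking markers define a two-component normal mixture which is
#' maximized by EM (posterior allele weights; weighted class means and a
#' pooled SD). LOD(pos) = \[max loglik - no-QTL loglik\] / ln 10. The peak
#' is classified by [classifyLod()], its 1-LOD support interval and
#' SD-unit effect are attached.
#'
#' @param y trait values on the analysis scale, named by daughter id (or
#'   in `daughters(genotypes)` order); `NA`s are dropped.
#' @param genotypes a [TransmissionMatrix-class].
#' @param chromosome chromosome to scan.
#' @param step grid step in cM (default 1).
#' @param mapFunction `"haldane"` (default) or `"kosambi"`.
#' @param minDaughters minimum informative daughters (default 30).
#' @return a [ScanResult-class]; its `table` has columns `position`,
#'   `stat` (LOD), `mu_A`, `mu_M`, `sigma`, `converged`.
#' @export
scanMle <- function(y, genotypes, chromosome, step = 1,
                    mapFunction = "haldane", minDaughters = 30) {
  al <- .alignTrait(y, genotypes)
  if (length(al$y) < minDaughters)
    stop("need >= ", minDaughters, " daughters with phenotype and genotypes")
  map <- linkageMap(genotypes)
  grid <- scanGrid(map, chromosome, step)
  P <- transmissionProb(genotypes, chromosome = chromosome, query = grid,
                        mapFunction = mapFunction)
  P <- P[al$ids, , drop = FALSE]
  yv <- al$y
  n <- length(yv)
  mu0 <- mean(yv)
  s0 <- sqrt(mean((yv - mu0)^2))
  null <- list(mu = mu0, sd = s0,
               ll = sum(stats::dnorm(yv, mu0, s0, log = TRUE)))
  res <- lapply(seq_along(grid), function(j)
    .emPosition(yv, P[, j], null))
  lod <- vapply(res, function(r) (r$ll - null$ll) / log(10), numeric(1))
  lod <- pmax(lod, 0)
  tab <- data.frame(position = grid, stat = lod,
                    mu_A = vapply(res, `[[`, numeric(1), "muA"),
                    mu_M = vapply(res, `[[`, numeric(1), "muM"),
                    sigma = vapply(res, `[[`, numeric(1), "sigma"),
                    converged = vapply(res, `[[`, logical(1), "converged"))
  pk <- which.max(lod)
  ci <- supportInterval(grid, lod, drop = 1)
  sdPhen <- stats::sd(yv)
  eff <- tab$mu_A[pk] - tab$mu_M[pk]
  notes <- character()
  if (attr(ci, "tied")) notes <- c(notes, "tied_peak_leftmost")
  if (any(!tab$converged))
    notes <- c(notes, sprintf("em_not_converged:%d", sum(!tab$converged)))
  new("ScanResult", table = tab, statistic = "LOD",
      chromosome = as.integer(chromosome), peakPosition = grid[pk],
      peakValue = lod[pk], interval = as.numeric(ci), effect = eff,
      effectSD = standardizedEffect(tab$mu_A[pk], tab$mu_M[pk], sdPhen),
      sigClass = classifyLod(lod[pk]),
      flankingMarkers = .flankNames(map, chromosome, grid[pk]),
      method = "mle", n = as.integer(n), notes = notes)
}

# two fully informative markers `spacing` cM apart, QTL midway:
# simulate one replicate and return the transmission matrix inputs
.powerDesign <- function(n, spacing, mapFunction = "haldane") {
  map <- LinkageMap(data.frame(chromosome = 1L, marker = c("L", "R"),
                               position = c(0, spacing)))
  r <- .mapFun(mapFunction)(spacing / 2)
  list(map = map, r = r)
}

#' Monte-Carlo power of the single-QTL scan
#'
#' Simulates a single-sire backcross: a biallelic QTL midway between two
#' fully informative markers, a unit-variance normal trait with an
#' `effect` SD additive contrast between transmitted-allele classes, and
#' the mixture-ML interval scan over the marker bracket. A replicate is
#' detected when the maximum LOD exceeds the point-wise `alpha` threshold
#' qchisq(1 - alpha, 1) / (2 ln 10) (0.834 at alpha = 0.05).
#'
#' @param n daughters per replicate (>= 10).
#' @param effect QTL contrast in phenotypic SD units, nonnegative.
#' @param alpha point-wise Type I error, in (0, 1).
#' @param spacing marker interval width in cM (default 20; the QTL sits
#'   midway).
#' @param nrep Monte-Carlo replicates.
#' @param step scan step in cM.
#' @param seed RNG seed (recorded in the result).
#' @return list: `power`, `se` (binomial), `nrep`, `threshold`, `seed`.
#' @export
estimatePower <- function(n = 172, effect = 0.4, alpha = 0.05, spacing = 20,
                          nrep = 2000, step = 1, seed = 1) {
  stopifnot(n >= 10, effect >= 0, alpha > 0, alpha < 1)
  set.seed(seed)
  des <- .powerDesign(n, spacing)
  thr <- stats::qchisq(1 - alpha, df = 1) / (2 * log(10))
  grid <- scanGrid(des$map, 1, step)
  hits <- logical(nrep)
  for (rep in seq_len(nrep)) {
    g <- stats::rbinom(n, 1, 0.5)                  # QTL allele (1 = A)
    recL <- stats::runif(n) < des$r
    recR <- stats::runif(n) < des$r
    gl <- ifelse(recL, 1 - g, g)
    gr <- ifelse(recR, 1 - g, g)
    alle <- cbind(ifelse(gl == 1, "A", "M"), ifelse(gr == 1, "A", "M"))
    rownames(alle) <- sprintf("d%d", seq_len(n))
    tm <- TransmissionMatrix(alle, des$map)
    yv <- (g - 0.5) * effect + stats::rnorm(n)
    sc <- scanMle(yv, tm, 1, step = step)
    hits[rep] <- sc@peakValue > thr
  }
  p <- mean(hits)
  list(power = p, se = sqrt(p * (1 - p) / nrep), nrep = nrep,
       threshold = thr, seed = seed)
}
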