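#' @include AllGenerics.R
NULL

woodCurve <- function(a, b, c, t) a * t^b * exp(-c * t)

#' Expected yield under a fitted Wood curve
#'
#' Evaluates W(t) = a t^b exp(-c t) at days `t`.
#'
#' @param object a [WoodFit-class].
#' @param t days in milk, strictly positive.
#' @return expected yield, same length as `t`.
#' @examples
#' f <- fitWood(data.frame(day = seq(2, 200, 2),
#'                         value = woodRecords(10, 0.4, 0.015,
#'                                             seq(2, 200, 2))))
#' predictYield(f, 100)
#' @export
setGeneric("predictYield", function(object, t) standardGeneric("predictYield"))

#' @rdname predictYield
#' @export
setMethod("predictYield", "WoodFit", function(object, t) {
  if (any(t <= 0)) stop("t must be strictly positive")
  woodCurve(object@a, object@b, object@c, t)
})

#' Peak of a Wood lactation curve
#'
#' The curve peaks at t_max = b/c with maximum yield
#' maxY = a (b/c)^b exp(-b). For b = 0 the curve is monotone declining and
#' the boundary maximum (0, a) is returned.
#'
#' @param object a [WoodFit-class].
#' @return named numeric `c(t_max, maxY)`.
#' @export
lactationPeak <- function(object) {
  stopifnot(is(object, "WoodFit"))
  b <- object@b; c <- object@c; a <- object@a
  if (b == 0) return(c(t_max = 0, maxY = a))
  if (c <= 0) return(c(t_max = NA_real_, maxY = NA_real_))
  tmax <- b / c
  c(t_max = tmax, maxY = a * tmax^b * exp(-b))
}

#' Noise-free Wood curve records (helper for examples and simulation)
#'
#' @param a,b,c Wood parameters.
#' @param days vector of record days.
#' @return yield values at `days`.
#' @export
woodRecords <- function(a, b, c, days) woodCurve(a, b, c, days)

.checkRecords <- function(records) {
  if (!all(c("day", "value") %in% names(records)))
    stop("records need columns 'day' and 'value'")
  if (any(records$day < 1)) stop("days in milk must be >= 1")
  if (any(records$value < 0)) stop("yields must be nonnegative")
  records
}

#' Log-linear least-squares fit of the Wood model
#'
#' The Wood curve is log-linear: ln W = k + b ln t - c t with k = ln(a).
#' Zero yields cannot enter the log fit and are excluded (their count is
#' recorded in the fit flags).
#'
#' @param records data.frame with columns `day` and `value` for one
#'   ewe-by-lactation.
#' @return a [WoodFit-class] with `rss` on the log scale. A fitted decline
#'   rate c <= 0 is retained but flagged `"non_declining"`; a negative rise
#'   exponent is refit at the boundary b = 0 and flagged `"b_clamped"`.
#' @export
fitWoodLogLinear <- function(records) {
  records <- .checkRecords(records)
  pos <- records[records$value > 0, , drop = FALSE]
  nZero <- nrow(records) - nrow(pos)
  if (nrow(pos) < 3 || length(unique(pos$day)) < 3)
    stop("unfittable curve: need >= 3 positive records on distinct days")
  ly <- log(pos$value); lt <- log(pos$day)
  fit <- lm(ly ~ lt + pos$day)
  cf <- coef(fit)
  k <- cf[[1]]; b <- cf[[2]]; c <- -cf[[3]]
  flags <- if (nZero) paste0("zeros_excluded:", nZero) else character()
  if (b < 0) {
    fit <- lm(ly ~ pos$day)
    k <- coef(fit)[[1]]; b <- 0; c <- -coef(fit)[[2]]
    flags <- c(flags, "b_clamped")
  }
  if (c <= 0) {
    flags <- c(flags, "non_declining")
    warning("fitted decline rate c <= 0: non-declining curve retained with flag")
  }
  out <- WoodFit(a = exp(k), b = b, c = c, nObs = nrow(pos),
                 rss = sum(residuals(fit)^2), converged = TRUE, flags = flags)
  attr(out, "vcov") <- {
    v <- suppressWarnings(diag(vcov(fit)))  # perfect fits warn in summary.lm
    if (length(v) == 3) c(k = v[[1]], b = v[[2]], c = v[[3]])
    else c(k = v[[1]], b = 0, c = v[[2]])
  }
  out
}

.rssNatural <- function(fit, records) {
  pos <- records[records$value > 0, , drop = FALSE]
  sum((pos$value - woodCurve(fit@a, fit@b, fit@c, pos$day))^2)
}

#' Nonlinear least-squares refinement of a Wood fit
#'
#' Refines a log-scale fit by Levenberg-Marquardt least squares on the
#' natural scale. If the optimizer fails or does not improve the
#' natural-scale residual sum of squares, the initial fit is returned with
#' a `"non_converged"` flag rather than a worse estimate.
#'
#' @param records data.frame with `day` and `value`.
#' @param init a [WoodFit-class] starting point (e.g. from
#'   [fitWoodLogLinear()]).
#' @return a [WoodFit-class] with `rss` on the natural scale.
#' @export
fitWoodNLS <- function(records, init) {
  records <- .checkRecords(records)
  stopifnot(is(init, "WoodFit"))
  pos <- records[records$value > 0, , drop = FALSE]
  if (nrow(pos) < 3) stop("unfittable curve: need >= 3 positive records")
  rss0 <- .rssNatural(init, records)
  ft <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(value ~ a * day^b * exp(-c * day), data = pos,
                      start = list(a = init@a, b = max(init@b, 1e-6),
                                   c = max(init@c, 1e-6)),
                      lower = c(a = 1e-10, b = 0, c = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(ft)) {
    out <- WoodFit(init@a, init@b, init@c, nObs = nrow(pos), rss = rss0,
                   converged = FALSE,
                   flags = union(init@flags, "non_converged"))
    return(out)
  }
  cf <- coef(ft)
  rss1 <- sum(residuals(ft)^2)
  if (!is.finite(rss1) || rss1 > rss0) {
    return(WoodFit(init@a, init@b, init@c, nObs = nrow(pos), rss = rss0,
                   converged = FALSE,
                   flags = union(init@flags, "non_converged")))
  }
  flags <- setdiff(init@flags, "non_declining")
  if (cf[["c"]] <= 0) flags <- c(flags, "non_declining")
  if (cf[["c"]] <= 1e-8 && abs(cf[["b"]]) <= 1e-8)
    flags <- union(flags, "flat_boundary")
  WoodFit(a = max(cf[["a"]], 1e-10), b = cf[["b"]], c = cf[["c"]],
          nObs = nrow(pos), rss = rss1, converged = TRUE, flags = flags)
}

#' Fit the Wood model to one lactation
#'
#' Log-linear fit followed (by default) by natural-scale nonlinear
#' refinement; the composition never increases the natural-scale residual
#' sum of squares relative to the log-linear start.
#'
#' @param records data.frame with `day` and `value`.
#' @param refine refine on the natural scale via [fitWoodNLS()]?
#' @return a [WoodFit-class].
#' @export
fitWood <- function(records, refine = TRUE) {
  init <- suppressWarnings(fitWoodLogLinear(records))
  out <- if (refine) fitWoodNLS(records, init) else init
  attr(out, "vcov") <- attr(init, "vcov")
  out
}

#' Two-stage population fit with inverse-variance shrinkage
#'
#' Approximates a nonlinear mixed-model fit of many lactation curves: each
#' ewe-by-lactation curve is fitted separately, then its log-scale
#' parameters (k, b, c) are shrunk toward fixed-effect-adjusted population
#' means with weights inverse to the per-curve sampling variance
#' (method-of-moments between-lactation variance). Adjusted parameters are
#' reported at the reference level of every fixed-effect factor, so all
#' lactations are standardized to a common management class.
#'
#' @param records data.frame with `ewe_id`, `lactation_id`, `day`, `value`.
#' @param covariates optional data.frame keyed by `ewe_id` and
#'   `lactation_id` whose remaining columns are categorical fixed effects
#'   (age class, parity, birth type, milking frequency, season). The first
#'   factor level is the reference; a level carried by a single lactation
#'   is non-estimable and is pooled with the reference (flagged).
#' @param refine passed to [fitWood()].
#' @return list with `fits` (per-lactation data.frame: raw, shrunk and
#'   reference-standardized k, b, c plus diagnostics), `populationMean`,
#'   `betweenVar`, `shrinkageWeights`, and `effects` (fixed-effect
#'   coefficient tables per parameter).
#' @export
fitPopulation <- function(records, covariates = NULL, refine = TRUE) {
  stopifnot(all(c("ewe_id", "lactation_id", "day", "value") %in% names(records)))
  key <- interaction(records$ewe_id, records$lactation_id, drop = TRUE)
  groups <- split(records, key)
  if (length(groups) < 2) stop("need >= 2 lactations for a population fit")

  fits <- lapply(groups, function(g)
    tryCatch(suppressWarnings(fitWood(g[c("day", "value")], refine = refine)),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (sum(ok) < 2) stop("fewer than 2 fittable lactations")
  ids <- do.call(rbind, lapply(groups[ok], function(g)
    data.frame(ewe_id = g$ewe_id[1], lactation_id = g$lactation_id[1])))
  est <- t(vapply(fits[ok], function(f) c(f@k, f@b, f@c), numeric(3)))
  colnames(est) <- c("k", "b", "c")
  vars <- t(vapply(fits[ok], function(f) {
    v <- attr(f, "vcov")
    if (is.null(v)) c(k = NA_real_, b = NA_real_, c = NA_real_) else v
  }, numeric(3)))
  vars[!is.finite(vars)] <- stats::median(vars[is.finite(vars)], na.rm = TRUE)

  # fixed-effect design at the lactation level
  X <- NULL; flags <- character()
  if (!is.null(covariates)) {
    cov <- merge(ids, covariates, by = c("ewe_id", "lactation_id"),
                 all.x = TRUE, sort = FALSE)
    cov <- cov[match(paste(ids$ewe_id, ids$lactation_id),
                     paste(cov$ewe_id, cov$lactation_id)), , drop = FALSE]
    fac <- setdiff(names(cov), c("ewe_id", "lactation_id"))
    for (f in fac) {
      cov[[f]] <- factor(cov[[f]])
      tab <- table(cov[[f]])
      thin <- names(tab)[tab < 2]
      keepRef <- levels(cov[[f]])[1]
      if (length(thin)) {
        flags <- c(flags, sprintf(
          "factor '%s': level(s) %s non-estimable, pooled with reference '%s'",
          f, paste(thin, collapse = "/"), keepRef))
        lv <- as.character(cov[[f]])
        lv[lv %in% thin] <- keepRef
        cov[[f]] <- factor(lv, levels = setdiff(levels(cov[[f]]), thin))
      }
    }
    fac <- fac[vapply(cov[fac], nlevels, integer(1)) >= 2]
    X <- if (length(fac)) model.matrix(reformulate(fac), data = cov)
         else matrix(1, nrow(est), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- matrix(1, nrow(est), 1, dimnames = list(NULL, "(Intercept)"))
  }

  shrunk <- est; adjusted <- est; weights <- est
  popMean <- numeric(3); betweenVar <- numeric(3)
  names(popMean) <- names(betweenVar) <- colnames(est)
  effects <- list()
  xref <- X[1, , drop = FALSE] * 0; xref[1, 1] <- 1  # reference level row
  for (j in colnames(est)) {
    w <- 1 / pmax(vars[, j], 1e-10)
    fit <- lm.wfit(X, est[, j], w)
    mu <- X %*% fit$coefficients
    muRef <- as.numeric(xref %*% fit$coefficients)
    resid <- est[, j] - mu
    sb2 <- max(0, sum(w * resid^2) / sum(w) - mean(vars[, j]))
    B <- sb2 / (sb2 + vars[, j])
    shrunk[, j] <- mu + B * resid
    adjusted[, j] <- shrunk[, j] - (mu - muRef)
    weights[, j] <- B
    popMean[j] <- muRef
    betweenVar[j] <- sb2
    effects[[j]] <- fit$coefficients
  }

  fitsDf <- cbind(ids,
                  as.data.frame(est),
                  setNames(as.data.frame(shrunk), paste0(colnames(est), "_shrunk")),
                  setNames(as.data.frame(adjusted), paste0(colnames(est), "_adj")),
                  n_obs = vapply(fits[ok], function(f) f@nObs, integer(1)),
                  rss = vapply(fits[ok], function(f) f@rss, numeric(1)),
                  converged = vapply(fits[ok], function(f) f@converged, logical(1)),
                  flags = vapply(fits[ok], function(f)
                    paste(f@flags, collapse = ";"), character(1)))
  fitsDf$a_adj <- exp(fitsDf$k_adj)
  rownames(fitsDf) <- NULL
  list(fits = fitsDf, populationMean = popMean, betweenVar = betweenVar,
       shrinkageWeights = weights, effects = effects, flags = flags)
}

#' Read long-format phenotype records
#'
#' CSV with header `ewe_id, lactation_id, day, trait, value`.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readPhenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ewe_id", "lactation_id", "day", "trait", "value")
  if (!all(need %in% names(ph)))
    stop("phenotype file needs columns ", paste(need, collapse = ", "))
  if (any(ph$day < 1)) stop("days in milk must be >= 1")
  if (any(ph$value < 0, na.rm = TRUE)) stop("trait values must be nonnegative")
  ph
}

#' Write per-lactation Wood fits as CSV
#'
#' @param fits the `fits` data.frame from [fitPopulation()].
#' @param path output path.
#' @export
writeWoodFits <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE)
  invisible(path)
}
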