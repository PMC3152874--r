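#' @include wood-fit.R
NULL

#' Cumulative yield under a Wood curve
#'
#' The integral of W over [0, T] has the closed form
#' a c^-(b+1) * gamma_inc(b+1, cT), with gamma_inc the lower incomplete
#' gamma function (computed exactly as `gamma(b+1) * pgamma(cT, b+1)`).
#'
#' @param object a [WoodFit-class].
#' @param T upper day limit, nonnegative (vectorized).
#' @return cumulative yield; `NA` for a flagged non-declining curve.
#' @examples
#' f <- WoodFit(a = 2, b = 1e-9, c = 0.01)
#' cumulativeYield(f, 100)  # ~ 2 * (1 - exp(-1)) / 0.01
#' @export
setGeneric("cumulativeYield", function(object, T) standardGeneric("cumulativeYield"))

#' @rdname cumulativeYield
#' @export
setMethod("cumulativeYield", "WoodFit", function(object, T) {
  if (any(T < 0)) stop("T must be nonnegative")
  a <- object@a; b <- object@b; c <- object@c
  if (c <= 0) return(rep(NA_real_, length(T)))
  a * c^-(b + 1) * gamma(b + 1) * stats::pgamma(c * T, shape = b + 1)
})

#' Lactation persistency
#'
#' Expected yield at day `T` relative to the peak yield:
#' PersY(T) = W(T) / maxY, in (0, 1]. Day 100 is the standard sheep
#' reference. For a flagged non-declining curve persistency is undefined
#' and returned as `NA` with a `reason` attribute.
#'
#' @param object a [WoodFit-class].
#' @param T reference day (default 100).
#' @return persistency ratio in (0, 1].
#' @export
persistency <- function(object, T = 100) {
  stopifnot(is(object, "WoodFit"), T > 0)
  if ("non_declining" %in% object@flags || object@c <= 0)
    return(structure(NA_real_, reason = "non_declining_curve"))
  pk <- lactationPeak(object)
  min(1, predictYield(object, T) / pk[["maxY"]])
}

#' Extended lactation
#'
#' Production sustained beyond the standard lactation, as the ratio
#' [CumY(to) - CumY(from)] / CumY(from) with the window defaulting to
#' (100, 300] days; larger values mean a more extended lactation.
#'
#' @param object a [WoodFit-class].
#' @param from,to window bounds in days.
#' @return nonnegative ratio; `NA` with a `reason` attribute when
#'   CumY(from) is zero or the curve is non-declining.
#' @export
extendedLactation <- function(object, from = 100, to = 300) {
  stopifnot(is(object, "WoodFit"), to > from, from > 0)
  cy <- cumulativeYield(object, c(from, to))
  if (any(is.na(cy)))
    return(structure(NA_real_, reason = "non_declining_curve"))
  if (cy[1] <= 0)
    return(structure(NA_real_, reason = "zero_cumulative_yield"))
  (cy[2] - cy[1]) / cy[1]
}

#' Component yields, somatic cell score and useful yield
#'
#' Converts composition percentages and somatic cell counts into yields:
#' PY = protein% x MY / 100 (same for FY, LY), SCS = log10(SCC),
#' SCY = SCS x MY, and the cheese-merit index UY = FY + 1.85 x PY.
#'
#' @param MY milk yield (mass or volume units).
#' @param proteinPct,fatPct,lactosePct composition in percent, in
#'   \[0, 100\].
#' @param SCC raw somatic cell count (cells/mL); must be positive for SCS,
#'   otherwise SCS and SCY are `NA`.
#' @return data.frame with columns PY, FY, LY, SCS, SCY, UY (vectorized).
#' @examples
#' componentYields(2, 5.5, 6.5, 4.8, 1e6)
#' @export
componentYields <- function(MY, proteinPct, fatPct, lactosePct, SCC) {
  if (any(MY < 0)) stop("MY must be nonnegative")
  pct <- cbind(proteinPct, fatPct, lactosePct)
  if (any(pct < 0 | pct > 100, na.rm = TRUE))
    stop("percentages must lie in [0, 100]")
  PY <- proteinPct * MY / 100
  FY <- fatPct * MY / 100
  LY <- lactosePct * MY / 100
  SCS <- ifelse(!is.na(SCC) & SCC > 0, log10(SCC), NA_real_)
  data.frame(PY = PY, FY = FY, LY = LY, SCS = SCS,
             SCY = SCS * MY, UY = FY + 1.85 * PY)
}

#' Build component-yield records from raw milk and composition records
#'
#' Composition is sampled weekly while milk yield is recorded every other
#' day; each composition day is paired with the nearest milk-yield record
#' (earlier day on ties) before applying [componentYields()].
#'
#' @param records long phenotype data.frame (`ewe_id`, `lactation_id`,
#'   `day`, `trait`, `value`) with traits `MY`, `protein_pct`, `fat_pct`,
#'   `lactose_pct`, `SCC`.
#' @return long data.frame of records for traits MY, PY, FY, LY, UY, SCY.
#' @export
buildComponentRecords <- function(records) {
  out <- list(records[records$trait == "MY", , drop = FALSE])
  key <- interaction(records$ewe_id, records$lactation_id, drop = TRUE)
  for (g in split(records, key)) {
    my <- g[g$trait == "MY", , drop = FALSE]
    comp <- g[g$trait != "MY", , drop = FALSE]
    if (!nrow(my) || !nrow(comp)) next
    days <- sort(unique(comp$day))
    nearest <- vapply(days, function(d) {
      i <- which.min(abs(my$day - d) + 1e-9 * (my$day > d))
      my$value[i]
    }, numeric(1))
    wide <- data.frame(day = days)
    for (tr in c("protein_pct", "fat_pct", "lactose_pct", "SCC"))
      wide[[tr]] <- comp$value[match(paste(days, tr),
                                     paste(comp$day, comp$trait))]
    cy <- componentYields(nearest, wide$protein_pct, wide$fat_pct,
                          wide$lactose_pct, wide$SCC)
    for (tr in c("PY", "FY", "LY", "UY", "SCY")) {
      v <- cy[[tr]]
      keep <- !is.na(v)
      if (!any(keep)) next
      out[[length(out) + 1]] <- data.frame(
        ewe_id = g$ewe_id[1], lactation_id = g$lactation_id[1],
        day = days[keep], trait = tr, value = pmax(v[keep], 0))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Derive persistency and extended-lactation traits from fitted curves
#'
#' For every ewe x lactation x trait Wood fit, computes persistency at day
#' `T`, extended lactation over (`T`, `Tend`], cumulative yields and the
#' curve peak; multiple lactations of one ewe are averaged.
#'
#' @param fits data.frame with columns `ewe_id`, `trait`, `a`, `b`, `c`
#'   (one row per fitted curve; extra columns ignored). Non-declining
#'   curves yield `NA` trait values.
#' @param T standard lactation reference day (default 100).
#' @param Tend extended-lactation cut-off (default 300).
#' @return data.frame (one row per ewe x trait): `persistency`,
#'   `extended_lactation`, `cum100`, `cum300`, `t_max`, `max_y`.
#' @export
deriveTraitTable <- function(fits, T = 100, Tend = 300) {
  stopifnot(all(c("ewe_id", "trait", "a", "b", "c") %in% names(fits)))
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    f <- tryCatch(WoodFit(fits$a[i], fits$b[i], fits$c[i]),
                  error = function(e) NULL)
    if (is.null(f))
      return(data.frame(ewe_id = fits$ewe_id[i], trait = fits$trait[i],
                        persistency = NA_real_, extended_lactation = NA_real_,
                        cum100 = NA_real_, cum300 = NA_real_,
                        t_max = NA_real_, max_y = NA_real_))
    cy <- cumulativeYield(f, c(T, Tend))
    pk <- lactationPeak(f)
    data.frame(ewe_id = fits$ewe_id[i], trait = fits$trait[i],
               persistency = as.numeric(persistency(f, T)),
               extended_lactation = as.numeric(extendedLactation(f, T, Tend)),
               cum100 = cy[1], cum300 = cy[2],
               t_max = pk[["t_max"]], max_y = pk[["maxY"]])
  })
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(
    tab[c("persistency", "extended_lactation", "cum100", "cum300",
          "t_max", "max_y")],
    by = tab[c("ewe_id", "trait")], FUN = function(x) mean(x, na.rm = TRUE))
  for (cn in names(agg)[-(1:2)]) agg[[cn]][!is.finite(agg[[cn]])] <- NA_real_
  agg[order(agg$trait, agg$ewe_id), , drop = FALSE]
}

#' Descriptive statistics of persistency and extended lactation
#'
#' One row per trait x measure with n (non-missing), mean, SD, min and
#' max, mirroring a descriptive-statistics table of a lactation study.
#'
#' @param table a derived-trait table from [deriveTraitTable()].
#' @return data.frame with columns `measure`, `trait`, `n`, `mean`, `sd`,
#'   `min`, `max`. SD is `NA` for a single observation.
#' @export
summarizeTraits <- function(table) {
  if (!nrow(table)) stop("empty derived-trait table")
  out <- list()
  for (measure in c("persistency", "extended_lactation")) {
    for (tr in unique(table$trait)) {
      x <- table[[measure]][table$trait == tr]
      x <- x[!is.na(x)]
      out[[length(out) + 1]] <- data.frame(
        measure = measure, trait = tr, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        min = if (length(x)) min(x) else NA_real_,
        max = if (length(x)) max(x) else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise correlations among persistency and extended-lactation traits
#'
#' Pearson correlations on pairwise-complete observations; a cell with
#' fewer than `minPairs` complete pairs is reported missing.
#'
#' @param table a derived-trait table from [deriveTraitTable()].
#' @param minPairs minimum complete pairs per cell (default 3).
#' @return symmetric correlation matrix (rows/cols
#'   `pers_<trait>`/`ext_<trait>`) with unit diagonal.
#' @export
traitCorrelations <- function(table, minPairs = 3) {
  traits <- sort(unique(table$trait))
  ewes <- sort(unique(table$ewe_id))
  wide <- matrix(NA_real_, length(ewes), 2 * length(traits),
                 dimnames = list(ewes, c(paste0("pers_", traits),
                                         paste0("ext_", traits))))
  idx <- match(table$ewe_id, ewes)
  for (i in seq_along(traits)) {
    sel <- table$trait == traits[i]
    wide[idx[sel], i] <- table$persistency[sel]
    wide[idx[sel], length(traits) + i] <- table$extended_lactation[sel]
  }
  p <- ncol(wide)
  cm <- diag(1, p)
  dimnames(cm) <- list(colnames(wide), colnames(wide))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    ok <- !is.na(wide[, i]) & !is.na(wide[, j])
    cm[i, j] <- cm[j, i] <-
      if (sum(ok) >= minPairs) stats::cor(wide[ok, i], wide[ok, j])
      else NA_real_
  }
  cm
}
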