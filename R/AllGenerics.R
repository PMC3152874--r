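#' @include AllClasses.R
NULL

#' @describeIn LinkageMap-class Marker names, in map order.
#' @param x a `LinkageMap` or `TransmissionMatrix`.
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))
setMethod("markerNames", "LinkageMap", function(x) x@map$marker)
setMethod("markerNames", "TransmissionMatrix", function(x) markerNames(x@map))

#' @describeIn LinkageMap-class Chromosome ids present in the map.
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
setMethod("chromosomes", "LinkageMap", function(x) sort(unique(x@map$chromosome)))
setMethod("chromosomes", "TransmissionMatrix", function(x) chromosomes(x@map))

#' @describeIn LinkageMap-class The map as a data.frame, optionally one
#'   chromosome.
#' @param chromosome optional chromosome id to subset to.
#' @export
mapTable <- function(x, chromosome = NULL) {
  if (is(x, "TransmissionMatrix")) x <- x@map
  stopifnot(is(x, "LinkageMap"))
  m <- x@map
  if (!is.null(chromosome)) {
    m <- m[m$chromosome == chromosome, , drop = FALSE]
    if (!nrow(m)) stop("chromosome ", chromosome, " not in map")
  }
  rownames(m) <- NULL
  m
}

#' @describeIn TransmissionMatrix-class Daughter identifiers.
#' @param x a `TransmissionMatrix`.
#' @export
daughters <- function(x) {
  stopifnot(is(x, "TransmissionMatrix"))
  rownames(x@alleles)
}

#' @describeIn TransmissionMatrix-class Allele matrix (daughters x markers).
#' @export
alleles <- function(x) {
  stopifnot(is(x, "TransmissionMatrix"))
  x@alleles
}

#' @describeIn TransmissionMatrix-class The underlying [LinkageMap-class].
#' @export
linkageMap <- function(x) {
  stopifnot(is(x, "TransmissionMatrix"))
  x@map
}

#' @describeIn WoodFit-class Named parameter vector (a, k, b, c).
#' @param object a `WoodFit`.
#' @param ... ignored.
#' @export
setMethod("coef", "WoodFit", function(object, ...)
  c(a = object@a, k = object@k, b = object@b, c = object@c))

#' @describeIn ScanResult-class Per-position scan statistics.
#' @param x a `ScanResult`.
#' @export
scanTable <- function(x) {
  stopifnot(is(x, "ScanResult"))
  x@table
}

#' @describeIn ScanResult-class Peak summary as a one-row data.frame
#'   (position, statistic, interval, flanking markers, effect, class).
#' @export
scanPeak <- function(x) {
  stopifnot(is(x, "ScanResult"))
  data.frame(chromosome = x@chromosome, position = x@peakPosition,
             statistic = x@statistic, value = x@peakValue,
             ci_lo = x@interval[1], ci_hi = x@interval[2],
             flank_left = x@flankingMarkers[1],
             flank_right = x@flankingMarkers[2],
             effect = x@effect, effect_sd = x@effectSD,
             class = x@sigClass, n = x@n, method = x@method)
}

setMethod("show", "LinkageMap", function(object) {
  m <- object@map
  cat("LinkageMap:", nrow(m), "markers on", length(unique(m$chromosome)),
      "chromosomes;", sprintf("%.0f cM total\n",
      sum(tapply(m$position, m$chromosome, max))))
})

setMethod("show", "TransmissionMatrix", function(object) {
  a <- object@alleles
  cat("TransmissionMatrix:", nrow(a), "daughters x", ncol(a), "markers;",
      sprintf("%.1f%% unknown\n", 100 * mean(is.na(a))))
})

setMethod("show", "WoodFit", function(object) {
  cat(sprintf("WoodFit: a=%.4g b=%.4g c=%.4g (n=%d, rss=%.4g)%s\n",
              object@a, object@b, object@c, object@nObs, object@rss,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]")
              else ""))
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf(
    "ScanResult (%s, %s): chr %d peak %s=%.3f at %.1f cM [%.1f-%.1f], %s\n",
    object@method, object@statistic, object@chromosome, object@statistic,
    object@peakValue, object@peakPosition, object@interval[1],
    object@interval[2], object@sigClass))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nDaughters, "daughters,", object@nMarkers,
      "markers /", object@nChromosomes, "autosomes,", nrow(object@qtl),
      "QTL, seed", object@seed, "\n")
})
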