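#' @import methods
NULL

#' Linkage map of microsatellite markers
#'
#' Holds marker positions (centimorgans, within-chromosome, origin at the
#' first mapped marker) for a framework map over sheep autosomes.
#'
#' @slot map data.frame with columns `chromosome` (integer), `marker`
#'   (character, unique), `position` (numeric cM, nondecreasing within
#'   chromosome).
#'
#' @examples
#' m <- LinkageMap(data.frame(chromosome = 1L,
#'                            marker = c("M1", "M2"),
#'                            position = c(0, 20)))
#' markerNames(m)
#' @export
setClass("LinkageMap", representation(map = "data.frame"))

setValidity("LinkageMap", function(object) {
  m <- object@map
  msg <- character()
  need <- c("chromosome", "marker", "position")
  if (!all(need %in% names(m)))
    return(paste("map must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(m$marker)) msg <- c(msg, "marker names must be unique")
  if (any(m$position < 0)) msg <- c(msg, "positions must be nonnegative")
  if (any(is.na(m$chromosome)) || any(m$chromosome < 1))
    msg <- c(msg, "chromosome ids must be positive integers")
  ord <- unlist(lapply(split(m$position, m$chromosome),
                       function(p) is.unsorted(p)), use.names = FALSE)
  if (any(ord)) msg <- c(msg, "positions must be nondecreasing within chromosome")
  if (length(msg)) msg else TRUE
})

#' @describeIn LinkageMap-class Constructor; rows are sorted by chromosome
#'   and position.
#' @param map data.frame with columns `chromosome`, `marker`, `position`.
#' @export
LinkageMap <- function(map) {
  map <- as.data.frame(map)
  if ("position_cM" %in% names(map) && !"position" %in% names(map))
    names(map)[names(map) == "position_cM"] <- "position"
  map$chromosome <- as.integer(map$chromosome)
  map$marker <- as.character(map$marker)
  map$position <- as.numeric(map$position)
  map <- map[order(map$chromosome, map$position), , drop = FALSE]
  rownames(map) <- NULL
  new("LinkageMap", map = map[c("chromosome", "marker", "position")])
}

#' Transmitted sire alleles of a single-sire backcross family
#'
#' Daughter-by-marker matrix of the sire allele each daughter inherited
#' (`"A"` Awassi, `"M"` Merino, `NA` unknown/uninformative), tied to a
#' [LinkageMap-class].
#'
#' @slot alleles character matrix, rows daughters, columns markers in map
#'   order.
#' @slot map the [LinkageMap-class] the columns refer to.
#' @export
setClass("TransmissionMatrix",
         representation(alleles = "matrix", map = "LinkageMap"))

setValidity("TransmissionMatrix", function(object) {
  a <- object@alleles
  msg <- character()
  if (!identical(colnames(a), markerNames(object@map)))
    msg <- c(msg, "allele columns must match map markers (same order)")
  bad <- !(a %in% c("A", "M") | is.na(a))
  if (any(bad)) msg <- c(msg, "alleles must be 'A', 'M' or NA")
  if (is.null(rownames(a))) msg <- c(msg, "daughters must be named (rownames)")
  if (length(msg)) msg else TRUE
})

#' @describeIn TransmissionMatrix-class Constructor; columns are reordered
#'   to map order.
#' @param alleles character matrix of transmitted alleles.
#' @param map a [LinkageMap-class].
#' @export
TransmissionMatrix <- function(alleles, map) {
  alleles <- as.matrix(alleles)
  mode(alleles) <- "character"
  alleles[alleles %in% c("", "NA", "unknown")] <- NA_character_
  mk <- markerNames(map)
  if (is.null(colnames(alleles))) {
    if (ncol(alleles) != length(mk))
      stop("allele matrix has ", ncol(alleles), " columns but map has ",
           length(mk), " markers")
    colnames(alleles) <- mk
  }
  missing <- setdiff(mk, colnames(alleles))
  if (length(missing))
    stop("markers absent from allele matrix: ", paste(missing, collapse = ", "))
  alleles <- alleles[, mk, drop = FALSE]
  if (is.null(rownames(alleles)))
    rownames(alleles) <- sprintf("D%03d", seq_len(nrow(alleles)))
  new("TransmissionMatrix", alleles = alleles, map = map)
}

#' Fitted Wood lactation curve
#'
#' Parameters of W(t) = a t^b exp(-c t) for one ewe-by-lactation, with fit
#' diagnostics. `k = ln(a)` is the log-scale intercept.
#'
#' @slot a positive scale (yield units).
#' @slot k log-scale intercept, `ln(a)`.
#' @slot b nonnegative rise exponent.
#' @slot c decline rate per day (positive for a declining curve).
#' @slot nObs number of positive records fitted.
#' @slot rss residual sum of squares (scale given by `flags`/method).
#' @slot converged logical, optimizer convergence.
#' @slot flags character vector of quality flags (e.g. `"non_declining"`).
#' @export
setClass("WoodFit",
         representation(a = "numeric", k = "numeric", b = "numeric",
                        c = "numeric", nObs = "integer", rss = "numeric",
                        converged = "logical", flags = "character"))

setValidity("WoodFit", function(object) {
  msg <- character()
  if (object@a <= 0) msg <- c(msg, "a must be positive")
  if (abs(object@k - log(object@a)) > 1e-8 * max(1, abs(object@k)))
    msg <- c(msg, "k must equal ln(a)")
  if (object@b < 0) msg <- c(msg, "b must be nonnegative")
  if (object@nObs < 3L) msg <- c(msg, "nObs must be >= 3")
  if (length(msg)) msg else TRUE
})

#' @describeIn WoodFit-class Constructor; `k` is derived as `ln(a)` and a
#'   nonpositive decline rate is flagged `"non_declining"`.
#' @param a,b,c Wood parameters.
#' @param nObs,rss,converged,flags fit diagnostics.
#' @export
WoodFit <- function(a, b, c, nObs = 3L, rss = NA_real_, converged = TRUE,
                    flags = character()) {
  if (c <= 0) flags <- union(flags, "non_declining")
  new("WoodFit", a = a, k = log(a), b = b, c = c, nObs = as.integer(nObs),
      rss = rss, converged = converged, flags = flags)
}

#' Genome-scan result for one trait on one chromosome
#'
#' Per-position LOD (mixture-ML route) or F statistics (half-sib regression
#' route), the peak, its support/confidence interval, the standardized QTL
#' effect and a significance class.
#'
#' @slot table data.frame of per-position statistics (`position`, `stat`,
#'   plus method-specific columns).
#' @slot statistic `"LOD"` or `"F"`.
#' @slot chromosome chromosome scanned.
#' @slot peakPosition cM position of the maximum.
#' @slot peakValue statistic at the peak.
#' @slot interval numeric length-2, support/confidence interval in cM.
#' @slot effect trait-unit contrast (Awassi minus Merino) on the analysis
#'   scale at the peak.
#' @slot effectSD effect in phenotypic standard-deviation units.
#' @slot sigClass one of `"none"`, `"suggestive"`, `"significant"`,
#'   `"highly significant"`.
#' @slot flankingMarkers names of markers flanking the peak.
#' @slot method fitting route (`"mle"` or `"regression"`).
#' @slot n daughters used.
#' @slot notes character flags (tied peaks, non-converged positions, ...).
#' @export
setClass("ScanResult",
         representation(table = "data.frame", statistic = "character",
                        chromosome = "integer", peakPosition = "numeric",
                        peakValue = "numeric", interval = "numeric",
                        effect = "numeric", effectSD = "numeric",
                        sigClass = "character", flankingMarkers = "character",
                        method = "character", n = "integer",
                        notes = "character"))

#' Synthetic backcross study configuration
#'
#' All knobs of the synthetic-study generator. Defaults emulate the mapping
#' design the package targets: a single-sire (Awassi x Merino) x Merino
#' backcross of 172 daughters genotyped at 189 microsatellites over 26
#' autosomes, milk yield recorded every second day and composition weekly,
#' with Wood-shaped lactation curves.
#'
#' @slot nDaughters number of backcross ewes.
#' @slot nChromosomes autosome count.
#' @slot nMarkers total marker count across the genome.
#' @slot chromosomeLengths cM length per autosome.
#' @slot informativeness probability a marker is sire-informative.
#' @slot missingRate per-cell missing-genotype probability.
#' @slot qtl data.frame of simulated QTL: `chromosome`, `position`,
#'   `target` (one of `"direct"`, `"k"`, `"b"`, `"c"`), `effectSD`
#'   (genotype contrast in phenotypic SD units on the analysis scale).
#' @slot qtlTrait derived trait the effect size is calibrated on
#'   (`"persistency"` or `"extended_lactation"`).
#' @slot woodMean population means of (k, b, c) for daily milk yield.
#' @slot woodSD between-ewe SDs of (k, b, c).
#' @slot noiseSD lognormal measurement noise SD (log scale).
#' @slot myEvery days between milk-yield records.
#' @slot compositionEvery days between composition records.
#' @slot lactationLength c(min, shape, scale) of the attrition model:
#'   length = min(300, min + Weibull(shape, scale)).
#' @slot composition baselines: protein, fat, lactose percent and SCC
#'   (thousand cells/mL) at day 100, with linear day trends.
#' @slot seed integer seed recorded in every output.
#' @export
setClass("SimulationConfig",
         representation(nDaughters = "integer", nChromosomes = "integer",
                        nMarkers = "integer", chromosomeLengths = "numeric",
                        informativeness = "numeric", missingRate = "numeric",
                        qtl = "data.frame", qtlTrait = "character",
                        woodMean = "numeric", woodSD = "numeric",
                        noiseSD = "numeric", myEvery = "integer",
                        compositionEvery = "integer",
                        lactationLength = "numeric", composition = "list",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  rate_ok <- function(x) length(x) == 1 && x >= 0 && x <= 1
  if (!rate_ok(object@informativeness))
    msg <- c(msg, "informativeness must be a rate in [0, 1]")
  if (!rate_ok(object@missingRate))
    msg <- c(msg, "missingRate must be a rate in [0, 1]")
  if (length(object@chromosomeLengths) != object@nChromosomes)
    msg <- c(msg, "one chromosome length per chromosome required")
  if (object@nMarkers < object@nChromosomes)
    msg <- c(msg, "need at least one marker per chromosome")
  if (nrow(object@qtl) &&
      !all(object@qtl$target %in% c("direct", "k", "b", "c")))
    msg <- c(msg, "qtl$target must be one of direct, k, b, c")
  if (nrow(object@qtl) && any(!is.finite(object@qtl$effectSD)))
    msg <- c(msg, "qtl effect sizes must be finite")
  if (!all(c("k", "b", "c") %in% names(object@woodMean)))
    msg <- c(msg, "woodMean must name k, b, c")
  if (length(msg)) msg else TRUE
})
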