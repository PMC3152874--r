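#' @include AllGenerics.R
NULL

#' Map functions: genetic distance to recombination fraction
#'
#' Haldane (no crossover interference; the package default) and Kosambi
#' map functions. Distances are in centimorgans.
#'
#' @param d genetic distance in cM, nonnegative (vectorized).
#' @return recombination fraction in \[0, 0.5).
#' @examples
#' haldane(20)  # ~0.1648
#' @export
haldane <- function(d) {
  if (any(d < 0)) stop("map distance must be nonnegative")
  0.5 * (1 - exp(-2 * d / 100))
}

#' @rdname haldane
#' @export
kosambi <- function(d) {
  if (any(d < 0)) stop("map distance must be nonnegative")
  0.5 * tanh(2 * d / 100)
}

.mapFun <- function(mapFunction = c("haldane", "kosambi")) {
  switch(match.arg(mapFunction), haldane = haldane, kosambi = kosambi)
}

#' Evaluation grid along one chromosome
#'
#' Positions from the first to the last mapped marker at the given step,
#' always including every marker position.
#'
#' @param map a [LinkageMap-class].
#' @param chromosome chromosome id.
#' @param step grid step in cM (default 1).
#' @return strictly increasing positions in cM.
#' @export
scanGrid <- function(map, chromosome, step = 1) {
  m <- mapTable(map, chromosome)
  pos <- m$position
  if (length(pos) == 1) return(pos)
  sort(unique(c(seq(min(pos), max(pos), by = step), pos)))
}

# transmitted-allele probability for one daughter at many query positions,
# conditioning on the nearest informative flanking markers
.transProbRow <- function(row, pos, query, mapf) {
  inf <- which(!is.na(row))
  if (!length(inf)) return(rep(0.5, length(query)))
  ip <- pos[inf]
  isA <- row[inf] == "A"
  li <- findInterval(query, ip)           # nearest informative at/left
  ri <- length(ip) - findInterval(-query, rev(-ip)) + 1  # nearest at/right
  out <- numeric(length(query))
  for (q in seq_along(query)) {
    L <- li[q]; R <- ri[q]
    if (L >= 1 && ip[L] == query[q]) { out[q] <- as.numeric(isA[L]); next }
    if (R <= length(ip) && ip[R] == query[q]) { out[q] <- as.numeric(isA[R]); next }
    hasL <- L >= 1; hasR <- R <= length(ip)
    if (hasL && hasR) {
      rL <- mapf(query[q] - ip[L]); rR <- mapf(ip[R] - query[q])
      tLA <- if (isA[L]) 1 - rL else rL
      tAR <- if (isA[R]) 1 - rR else rR
      tLM <- 1 - tLA
      tMR <- 1 - tAR
      out[q] <- tLA * tAR / (tLA * tAR + tLM * tMR)
    } else if (hasL) {
      rL <- mapf(query[q] - ip[L])
      out[q] <- if (isA[L]) 1 - rL else rL
    } else if (hasR) {
      rR <- mapf(ip[R] - query[q])
      out[q] <- if (isA[R]) 1 - rR else rR
    } else out[q] <- 0.5
  }
  out
}

#' Transmitted-sire-allele probability at a chromosomal position
#'
#' Probability that a daughter inherited the Awassi (A) sire allele at a
#' query position, conditional on her nearest informative flanking
#' markers, assuming no crossover interference. At an informative typed
#' marker the probability is exactly 0 or 1; with no informative marker on
#' the chromosome it is 1/2.
#'
#' @param genotypes allele vector for one daughter over the chromosome's
#'   markers (`"A"`/`"M"`/`NA`, map order), or a
#'   [TransmissionMatrix-class] (all daughters).
#' @param map a [LinkageMap-class] (ignored if `genotypes` is a
#'   `TransmissionMatrix`).
#' @param chromosome chromosome id.
#' @param query query position(s) in cM within the chromosome span.
#' @param mapFunction `"haldane"` (default) or `"kosambi"`.
#' @return vector of P(A) per query (single daughter) or a daughters x
#'   positions matrix.
#' @export
transmissionProb <- function(genotypes, map = NULL, chromosome, query,
                             mapFunction = "haldane") {
  mapf <- .mapFun(mapFunction)
  if (is(genotypes, "TransmissionMatrix")) {
    map <- linkageMap(genotypes)
    m <- mapTable(map, chromosome)
    if (any(query < min(m$position) | query > max(m$position)))
      stop("query position outside chromosome span")
    al <- alleles(genotypes)[, m$marker, drop = FALSE]
    if (all(is.na(al)))
      warning("no informative markers on chromosome ", chromosome,
              "; returning 1/2")
    pat <- apply(al, 1, paste, collapse = "\r")
    upat <- !duplicated(pat)
    pr <- vapply(which(upat), function(i)
      .transProbRow(al[i, ], m$position, query, mapf), numeric(length(query)))
    pr <- if (is.null(dim(pr))) matrix(pr, ncol = 1) else t(pr)
    out <- pr[match(pat, pat[upat]), , drop = FALSE]
    dimnames(out) <- list(rownames(al), NULL)
    return(out)
  }
  m <- mapTable(map, chromosome)
  stopifnot(length(genotypes) == nrow(m))
  if (any(query < min(m$position) | query > max(m$position)))
    stop("query position outside chromosome span")
  if (all(is.na(genotypes)))
    warning("no informative markers on chromosome ", chromosome,
            "; returning 1/2")
  .transProbRow(as.character(genotypes), m$position, query, mapf)
}

#' Read a linkage map from CSV
#'
#' Columns `chromosome, marker, position_cM` (or `position`).
#'
#' @param path file path.
#' @return a [LinkageMap-class].
#' @export
readLinkageMap <- function(path)
  LinkageMap(utils::read.csv(path, stringsAsFactors = FALSE))

#' @describeIn readLinkageMap Write the map back to CSV.
#' @param map a [LinkageMap-class].
#' @export
writeLinkageMap <- function(map, path) {
  m <- mapTable(map)
  names(m)[names(m) == "position"] <- "position_cM"
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Read a sire-transmission genotype matrix from CSV
#'
#' Rows are daughters (first column `daughter_id`), remaining columns are
#' markers with cells in `{A, M, NA}`.
#'
#' @param path file path.
#' @param map the [LinkageMap-class] the columns refer to.
#' @return a [TransmissionMatrix-class].
#' @export
readTransmissionMatrix <- function(path, map) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- g[[1]]
  mat <- as.matrix(g[-1])
  rownames(mat) <- as.character(ids)
  TransmissionMatrix(mat, map)
}

#' @describeIn readTransmissionMatrix Write genotypes back to CSV.
#' @param genotypes a [TransmissionMatrix-class].
#' @export
writeTransmissionMatrix <- function(genotypes, path) {
  df <- data.frame(daughter_id = daughters(genotypes),
                   alleles(genotypes), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
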