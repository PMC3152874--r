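# shared fixture builders (all data generated in code)

# two-marker chromosome, optionally with given spacing
tinyMap <- function(spacing = 20, chromosome = 1L)
  LinkageMap(data.frame(chromosome = chromosome, marker = c("L", "R"),
                        position = c(0, spacing)))

# evenly spaced fully informative marker chromosome
evenMap <- function(nMarkers = 6, spacing = 20, chromosome = 1L)
  LinkageMap(data.frame(chromosome = chromosome,
                        marker = sprintf("M%d", seq_len(nMarkers)),
                        position = seq(0, by = spacing,
                                       length.out = nMarkers)))

# simulate fully informative transmitted alleles along one chromosome
# (Haldane switch process); returns 0/1 matrix
simTransmitted <- function(n, positions) {
  g <- matrix(0L, n, length(positions))
  g[, 1] <- stats::rbinom(n, 1, 0.5)
  if (length(positions) > 1) {
    r <- haldane(diff(positions))
    for (j in 2:length(positions)) {
      flip <- stats::runif(n) < r[j - 1]
      g[, j] <- ifelse(flip, 1L - g[, j - 1], g[, j - 1])
    }
  }
  g
}

asTM <- function(g01, map) {
  al <- matrix(ifelse(g01 == 1, "A", "M"), nrow(g01),
               dimnames = list(sprintf("d%03d", seq_len(nrow(g01))),
                               markerNames(map)))
  TransmissionMatrix(al, map)
}

# marker genotypes + trait with a QTL at a marker (fully informative)
simMarkerTrait <- function(n, effect, map, qtlIndex, seed) {
  set.seed(seed)
  g <- simTransmitted(n, mapTable(map)$position)
  y <- (g[, qtlIndex] - 0.5) * effect + stats::rnorm(n)
  list(tm = asTM(g, map), y = y, g = g)
}

# independent enumeration oracle for the transmitted-allele probability:
# sum over the two transmitted states at the query, weighting each by the
# prior 1/2 and the two flanking-interval transition probabilities
enumProbA <- function(sL, sR, rL, rR) {
  joint <- function(s) {
    tl <- if (is.na(sL)) 0.5 else if (identical(s, sL)) 1 - rL else rL
    tr <- if (is.na(sR)) 1 else if (identical(s, sR)) 1 - rR else rR
    if (is.na(sL) && is.na(sR)) return(0.5)
    0.5 * tl * tr
  }
  joint("A") / (joint("A") + joint("M"))
}
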