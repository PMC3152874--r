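#' @include scan-regression.R
NULL

#' Build a synthetic-study configuration
#'
#' Defaults emulate the single-sire (Awassi x Merino) x Merino backcross
#' mapping design: 172 daughters, 189 microsatellites over 26 autosomes,
#' milk yield recorded every second day, composition weekly, Wood-shaped
#' curves with between-ewe parameter variation and lactation lengths that
#' thin out sharply after day 100.
#'
#' @param nDaughters daughters in the family.
#' @param nChromosomes autosomes.
#' @param nMarkers genome-wide marker count.
#' @param chromosomeLengths cM per autosome (default: declining 240 to 50,
#'   a sheep-like ~3800 cM genome).
#' @param informativeness probability a marker is sire-informative.
#' @param missingRate per-cell missing-genotype rate.
#' @param qtl data.frame (`chromosome`, `position`, `target`, `effectSD`);
#'   `target` is `"direct"` (calibrated shift of the derived trait via the
#'   decline rate) or a Wood parameter `"k"`/`"b"`/`"c"`.
#' @param qtlTrait derived trait effect sizes are calibrated on
#'   (`"persistency"` or `"extended_lactation"`, analysis/log scale).
#' @param woodMean,woodSD population means and between-ewe SDs of
#'   (k, b, c) for daily milk yield.
#' @param noiseSD lognormal measurement noise SD (log scale).
#' @param myEvery,compositionEvery recording intervals in days.
#' @param lactationLength `c(min, shape, scale)`: length =
#'   min(300, min + Weibull(shape, scale)) days.
#' @param composition list of `c(base, slope)` for protein/fat/lactose
#'   percent and SCC (1000 cells/mL at day 100; log-linear day trend).
#' @param seed top-level seed; per-stage streams are derived from it.
#' @return a [SimulationConfig-class].
#' @export
simConfig <- function(nDaughters = 172, nChromosomes = 26, nMarkers = 189,
                      chromosomeLengths = round(seq(240, 50,
                                                    length.out = nChromosomes)),
                      informativeness = 0.9, missingRate = 0.05,
                      qtl = data.frame(chromosome = integer(),
                                       position = numeric(),
                                       target = character(),
                                       effectSD = numeric()),
                      qtlTrait = "persistency",
                      woodMean = c(k = log(1.5), b = 0.45, c = 0.027),
                      woodSD = c(k = 0.25, b = 0.08, c = 0.006),
                      noiseSD = 0.15, myEvery = 2, compositionEvery = 7,
                      lactationLength = c(min = 50, shape = 1.5, scale = 120),
                      composition = list(protein = c(base = 5.5, slope = 1.2),
                                         fat = c(base = 6.5, slope = 1.8),
                                         lactose = c(base = 4.8, slope = -0.3),
                                         scc = c(base = 150, slope = 0.8)),
                      seed = 1) {
  new("SimulationConfig", nDaughters = as.integer(nDaughters),
      nChromosomes = as.integer(nChromosomes), nMarkers = as.integer(nMarkers),
      chromosomeLengths = as.numeric(chromosomeLengths),
      informativeness = informativeness, missingRate = missingRate,
      qtl = as.data.frame(qtl), qtlTrait = qtlTrait, woodMean = woodMean,
      woodSD = woodSD, noiseSD = noiseSD, myEvery = as.integer(myEvery),
      compositionEvery = as.integer(compositionEvery),
      lactationLength = as.numeric(lactationLength),
      composition = composition, seed = as.integer(seed))
}

#' Simulate a framework linkage map
#'
#' Markers are allocated to autosomes proportionally to chromosome length
#' (at least one each); the first and last markers anchor the chromosome
#' ends and interior positions are drawn uniformly.
#'
#' @param config a [SimulationConfig-class].
#' @param seed RNG seed (default derived from the config seed).
#' @return a [LinkageMap-class].
#' @export
simulateMap <- function(config, seed = config@seed + 101L) {
  set.seed(seed)
  len <- config@chromosomeLengths
  nmk <- config@nMarkers
  base <- pmax(1, floor(nmk * len / sum(len)))
  while (sum(base) > nmk) base[which.max(base)] <- base[which.max(base)] - 1
  while (sum(base) < nmk) {
    frac <- nmk * len / sum(len) - base
    base[which.max(frac)] <- base[which.max(frac)] + 1
  }
  rows <- lapply(seq_len(config@nChromosomes), function(chr) {
    k <- base[chr]
    pos <- if (k == 1) round(len[chr] / 2, 1)
           else if (k == 2) c(0, len[chr])
           else c(0, sort(round(stats::runif(k - 2, 1, len[chr] - 1), 1)),
                  len[chr])
    data.frame(chromosome = chr,
               marker = sprintf("C%02dM%02d", chr, seq_len(k)),
               position = pos)
  })
  LinkageMap(do.call(rbind, rows))
}

#' Simulate transmitted sire haplotypes for a backcross family
#'
#' The sire haplotype each daughter inherits is a two-state Markov
#' process along every chromosome with inter-marker switch probability
#' haldane(distance) (no interference). Markers are masked to unknown at
#' the configured informativeness and missingness rates. True transmitted
#' states at the configured QTL positions are returned separately for
#' recovery testing.
#'
#' @param map a [LinkageMap-class].
#' @param config a [SimulationConfig-class].
#' @param seed RNG seed.
#' @return list: `genotypes` ([TransmissionMatrix-class]), `qtlStates`
#'   (daughters x QTL matrix of `"A"`/`"M"`).
#' @export
simulateBackcross <- function(map, config, seed = config@seed + 202L) {
  set.seed(seed)
  n <- config@nDaughters
  ids <- sprintf("E%03d", seq_len(n))
  qtl <- config@qtl
  alleleCols <- list(); qtlCols <- list()
  for (chr in chromosomes(map)) {
    m <- mapTable(map, chr)
    qpos <- qtl$position[qtl$chromosome == chr]
    pos <- sort(unique(c(m$position, qpos)))
    g <- matrix(0L, n, length(pos))
    g[, 1] <- stats::rbinom(n, 1, 0.5)
    if (length(pos) > 1) {
      r <- haldane(diff(pos))
      for (j in 2:length(pos)) {
        flip <- stats::runif(n) < r[j - 1]
        g[, j] <- ifelse(flip, 1L - g[, j - 1], g[, j - 1])
      }
    }
    mk <- match(m$position, pos)
    am <- matrix(ifelse(g[, mk, drop = FALSE] == 1, "A", "M"), n,
                 dimnames = list(ids, m$marker))
    alleleCols[[as.character(chr)]] <- am
    if (length(qpos)) {
      qi <- match(qpos, pos)
      qm <- matrix(ifelse(g[, qi, drop = FALSE] == 1, "A", "M"), n)
      colnames(qm) <- sprintf("chr%d@%g", chr, qpos)
      qtlCols[[as.character(chr)]] <- qm
    }
  }
  alle <- do.call(cbind, alleleCols)
  # uninformative markers: the whole column is unknown
  uninf <- stats::runif(ncol(alle)) > config@informativeness
  alle[, uninf] <- NA_character_
  # sporadic missing genotypes
  miss <- matrix(stats::runif(length(alle)) < config@missingRate,
                 nrow = nrow(alle))
  alle[miss] <- NA_character_
  qtlStates <- if (length(qtlCols)) do.call(cbind, qtlCols) else
    matrix(character(), n, 0)
  rownames(qtlStates) <- ids
  list(genotypes = TransmissionMatrix(alle, map), qtlStates = qtlStates)
}

# analysis-scale (log) derived trait of a parameter triple; closed forms
# (ln persistency = b ln(Tc/b) - cT + b; extended lactation from the
# regularized lower incomplete gamma) keep this cheap inside calibration
.traitValue <- function(k, b, c, trait, T = 100, Tend = 300) {
  b <- max(b, 1e-6); c <- max(c, 1e-6)
  if (trait == "persistency") {
    min(0, b * log(T * c / b) - c * T + b)
  } else {
    gT <- stats::pgamma(c * T, b + 1)
    gE <- stats::pgamma(c * Tend, b + 1)
    log(gE - gT) - log(gT)
  }
}

# shift c so the log-scale derived trait moves by exactly `delta`
.shiftCForTrait <- function(k, b, c, delta, trait) {
  target <- .traitValue(k, b, c, trait) + delta
  fn <- function(cc) .traitValue(k, b, cc, trait) - target
  lo <- max(b / 100, 1e-5) + 1e-6   # keep the peak before day 100
  hi <- 0.5
  if (fn(lo) * fn(hi) > 0) return(c)  # out of range: leave unchanged
  stats::uniroot(fn, c(lo, hi), tol = 1e-10)$root
}

#' Simulate longitudinal lactation records
#'
#' Per ewe, Wood parameters (k, b, c) are drawn from the population
#' distributions and QTL effects are applied to the configured targets:
#' either a Wood-parameter shift or (default `"direct"`) a decline-rate
#' adjustment calibrated so the realized genotype contrast of the
#' analysis-scale derived trait equals the configured SD-units effect.
#' Milk yield is generated on the recording grid with multiplicative
#' lognormal noise; composition percentages and somatic cell counts
#' follow smooth baseline day trends so all component yields are
#' constructible downstream.
#'
#' @param qtlStates daughters x QTL matrix of true transmitted alleles
#'   (from [simulateBackcross()]; may have zero columns).
#' @param config a [SimulationConfig-class].
#' @param seed RNG seed.
#' @return list: `records` (long phenotype data.frame), `truth`
#'   (per-ewe true parameters and analysis-scale derived trait values).
#' @export
simulateLactations <- function(qtlStates, config, seed = config@seed + 303L) {
  set.seed(seed)
  n <- config@nDaughters
  ids <- if (!is.null(rownames(qtlStates))) rownames(qtlStates) else
    sprintf("E%03d", seq_len(n))
  mu <- config@woodMean; sdv <- config@woodSD
  k <- stats::rnorm(n, mu[["k"]], sdv[["k"]])
  b <- pmax(stats::rnorm(n, mu[["b"]], sdv[["b"]]), 0.05)
  c <- pmax(stats::rnorm(n, mu[["c"]], sdv[["c"]]), 0.004)
  trait <- config@qtlTrait
  qtl <- config@qtl
  base0 <- vapply(seq_len(n), function(i)
    .traitValue(k[i], b[i], c[i], trait), numeric(1))
  sigma0 <- stats::sd(base0)
  if (nrow(qtl)) {
    for (q in seq_len(nrow(qtl))) {
      gA <- qtlStates[, q] == "A"
      delta <- qtl$effectSD[q] * sigma0
      if (qtl$target[q] == "direct") {
        for (i in seq_len(n)) {
          sh <- if (gA[i]) delta / 2 else -delta / 2
          c[i] <- .shiftCForTrait(k[i], b[i], c[i], sh, trait)
        }
      } else {
        par <- qtl$target[q]
        # calibrate the parameter step so the mean derived-trait contrast
        # equals delta on the analysis scale
        contrast <- function(s) {
          mean(vapply(seq_len(n), function(i) {
            p <- c(k = k[i], b = b[i], c = c[i])
            up <- p; up[par] <- up[par] + s / 2
            dn <- p; dn[par] <- dn[par] - s / 2
            .traitValue(up["k"], up["b"], up["c"], trait) -
              .traitValue(dn["k"], dn["b"], dn["c"], trait)
          }, numeric(1))) - delta
        }
        s <- tryCatch(stats::uniroot(contrast, c(-2, 2) *
                                       max(sdv[[par]], 1e-3) * 10,
                                     extendInt = "yes", tol = 1e-8)$root,
                      error = function(e) 0)
        shift <- ifelse(gA, s / 2, -s / 2)
        if (par == "k") k <- k + shift
        if (par == "b") b <- pmax(b + shift, 0.02)
        if (par == "c") c <- pmax(c + shift, 0.002)
      }
    }
  }
  ll <- config@lactationLength
  L <- pmin(300, round(ll[1] + stats::rweibull(n, ll[2], ll[3])))
  L <- pmax(L, 40)
  cmp <- config@composition
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    myDays <- seq(config@myEvery, L[i], by = config@myEvery)
    my <- woodCurve(exp(k[i]), b[i], c[i], myDays) *
      exp(stats::rnorm(length(myDays), 0, config@noiseSD))
    cDays <- seq(config@compositionEvery, L[i], by = config@compositionEvery)
    nc <- length(cDays)
    pct <- function(p) pmin(pmax(
      p[["base"]] + p[["slope"]] * (cDays - 100) / 100 +
        stats::rnorm(nc, 0, 0.15), 0.5), 15)
    scc <- round(cmp$scc[["base"]] * 1000 *
                   exp(cmp$scc[["slope"]] * (cDays - 100) / 100 +
                         stats::rnorm(nc, 0, 0.4)))
    recs[[i]] <- rbind(
      data.frame(ewe_id = ids[i], lactation_id = 1L, day = myDays,
                 trait = "MY", value = my),
      data.frame(ewe_id = ids[i], lactation_id = 1L, day = cDays,
                 trait = rep(c("protein_pct", "fat_pct", "lactose_pct", "SCC"),
                             each = nc),
                 value = c(pct(cmp$protein), pct(cmp$fat), pct(cmp$lactose),
                           pmax(scc, 1000))))
  }
  final <- vapply(seq_len(n), function(i)
    .traitValue(k[i], b[i], c[i], trait), numeric(1))
  truth <- data.frame(ewe_id = ids, k = k, b = b, c = c,
                      lactation_length = L, trait_value = final)
  if (ncol(qtlStates))
    truth <- cbind(truth, as.data.frame(qtlStates))
  list(records = do.call(rbind, recs), truth = truth,
       baselineSD = sigma0, seed = seed)
}

#' Generate a complete synthetic study bundle
#'
#' Runs map, genotype and phenotype simulation from one configuration and
#' (optionally) writes every standard input file plus a truth file for
#' recovery tests. Fully reproducible from the configuration seed.
#'
#' @param config a [SimulationConfig-class].
#' @param dir optional output directory; created if missing. Writes
#'   `map.csv`, `genotypes.csv`, `phenotypes.csv`, `truth.json`,
#'   `config.yaml`.
#' @return (invisibly when writing) list: `map`, `genotypes`, `qtlStates`,
#'   `records`, `truth`, `config`.
#' @export
simulateStudy <- function(config = simConfig(), dir = NULL) {
  map <- simulateMap(config)
  bc <- simulateBackcross(map, config)
  lact <- simulateLactations(bc$qtlStates, config)
  bundle <- list(map = map, genotypes = bc$genotypes,
                 qtlStates = bc$qtlStates, records = lact$records,
                 truth = lact$truth, baselineSD = lact$baselineSD,
                 config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLinkageMap(map, file.path(dir, "map.csv"))
    writeTransmissionMatrix(bc$genotypes, file.path(dir, "genotypes.csv"))
    utils::write.csv(lact$records, file.path(dir, "phenotypes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config@seed,
           qtl = config@qtl,
           qtl_trait = config@qtlTrait,
           baseline_sd = lact$baselineSD,
           ewes = lact$truth),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    writeSimConfig(config, file.path(dir, "config.yaml"))
  }
  invisible(bundle)
}

#' Read/write a simulation configuration as YAML
#'
#' @param config a [SimulationConfig-class].
#' @param path YAML file path.
#' @export
writeSimConfig <- function(config, path) {
  sl <- sapply(slotNames(config), function(s) slot(config, s),
               simplify = FALSE)
  sl$qtl <- if (nrow(sl$qtl)) lapply(seq_len(nrow(sl$qtl)), function(i)
    as.list(sl$qtl[i, ])) else list()
  sl$woodMean <- as.list(sl$woodMean)
  sl$woodSD <- as.list(sl$woodSD)
  sl$lactationLength <- as.list(sl$lactationLength)
  sl$composition <- lapply(sl$composition, as.list)
  yaml::write_yaml(sl, path, precision = 15)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  sl <- yaml::read_yaml(path)
  qtl <- if (length(sl$qtl)) do.call(rbind, lapply(sl$qtl, as.data.frame))
         else data.frame(chromosome = integer(), position = numeric(),
                         target = character(), effectSD = numeric())
  simConfig(nDaughters = sl$nDaughters, nChromosomes = sl$nChromosomes,
            nMarkers = sl$nMarkers,
            chromosomeLengths = unlist(sl$chromosomeLengths),
            informativeness = sl$informativeness,
            missingRate = sl$missingRate, qtl = qtl, qtlTrait = sl$qtlTrait,
            woodMean = unlist(sl$woodMean), woodSD = unlist(sl$woodSD),
            noiseSD = sl$noiseSD, myEvery = sl$myEvery,
            compositionEvery = sl$compositionEvery,
            lactationLength = unlist(sl$lactationLength),
            composition = lapply(sl$composition, unlist), seed = sl$seed)
}
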