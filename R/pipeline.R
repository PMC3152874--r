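#' @include simulate.R
NULL

#' Cross-validate a map / genotype / phenotype bundle
#'
#' Checks marker-name agreement between map and genotypes, the allele
#' alphabet, daughter-id agreement between genotypes and phenotypes, and
#' day ranges. Mismatched marker sets are errors; phenotyped ewes without
#' genotypes are warnings (such ewes contribute to descriptive trait
#' tables but are excluded from scans).
#'
#' @param map a [LinkageMap-class].
#' @param genotypes a [TransmissionMatrix-class].
#' @param phenotypes long phenotype data.frame.
#' @param strict stop on errors (default TRUE)?
#' @return data.frame report (`level`, `message`); zero rows for a clean
#'   bundle.
#' @export
validateInputs <- function(map, genotypes, phenotypes, strict = TRUE) {
  rep <- list()
  add <- function(level, msg) rep[[length(rep) + 1]] <<-
    data.frame(level = level, message = msg)
  extra <- setdiff(colnames(alleles(genotypes)), markerNames(map))
  if (length(extra))
    add("error", paste("genotype markers absent from map:",
                       paste(extra, collapse = ", ")))
  missing <- setdiff(markerNames(map), colnames(alleles(genotypes)))
  if (length(missing))
    add("error", paste("map markers absent from genotypes:",
                       paste(missing, collapse = ", ")))
  bad <- setdiff(unique(as.vector(alleles(genotypes))), c("A", "M", NA))
  if (length(bad))
    add("error", paste("invalid allele codes:", paste(bad, collapse = ", ")))
  phEwes <- unique(phenotypes$ewe_id)
  orphan <- setdiff(phEwes, daughters(genotypes))
  if (length(orphan))
    add("warning", paste0("phenotyped ewes without genotypes (excluded from ",
                          "scans): ", paste(orphan, collapse = ", ")))
  if (any(phenotypes$day < 1) || any(phenotypes$day > 400))
    add("warning", "phenotype days outside the plausible 1-400 range")
  out <- if (length(rep)) do.call(rbind, rep) else
    data.frame(level = character(), message = character())
  if (strict && any(out$level == "error"))
    stop("input validation failed:\n",
         paste(out$message[out$level == "error"], collapse = "\n"))
  out
}

.stageSeeds <- function(seed)
  c(simulate = seed, fit = seed + 1000L, scan = seed + 2000L,
    permutation = seed + 3000L, bootstrap = seed + 4000L)

# fit Wood curves per ewe x lactation x trait and return the fits table
.fitCurveTable <- function(records) {
  yieldTraits <- intersect(c("MY", "PY", "FY", "LY", "UY", "SCY"),
                           unique(records$trait))
  out <- list()
  for (tr in yieldTraits) {
    rt <- records[records$trait == tr, , drop = FALSE]
    key <- interaction(rt$ewe_id, rt$lactation_id, drop = TRUE)
    for (g in split(rt, key)) {
      f <- tryCatch(suppressWarnings(fitWood(g[c("day", "value")])),
                    error = function(e) NULL)
      if (is.null(f)) next
      out[[length(out) + 1]] <- data.frame(
        ewe_id = g$ewe_id[1], lactation_id = g$lactation_id[1], trait = tr,
        a = f@a, k = f@k, b = f@b, c = f@c, n_obs = f@nObs, rss = f@rss,
        converged = f@converged, flags = paste(f@flags, collapse = ";"))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full simulate / fit / derive / scan pipeline
#'
#' Executes every stage on a synthetic study (or a loaded bundle) and
#' writes publication-shaped outputs: the derived-trait table, its
#' descriptive summary and correlation matrix, mixture-ML peak and
#' regression peak tables, optional two-QTL results, per-chromosome scan
#' profiles (CSV and PDF), and a JSON run manifest tying every output to
#' the configuration, seeds and input checksums.
#'
#' @param config a [SimulationConfig-class] (simulated inputs) or a list
#'   with file paths `map`, `genotypes`, `phenotypes` (loaded inputs).
#' @param outdir output directory.
#' @param seed top-level seed; per-stage seeds are derived and printed in
#'   the manifest.
#' @param traits milk traits to map (subset of MY, PY, FY, LY, UY, SCY).
#' @param measures derived measures to map (`"persistency"`,
#'   `"extended_lactation"`).
#' @param chromosomes chromosomes to scan (default: all in the map).
#' @param step scan step in cM.
#' @param nPermutations permutations per chromosome for thresholds.
#' @param nBootstrap bootstrap resamples for the CI of detected
#'   regression peaks (0 disables).
#' @param twoQtl also run the two-QTL grid search per chromosome?
#' @param makePlots write per-chromosome scan profile PDFs?
#' @return list with the derived table, scan results, peak tables and the
#'   manifest (also written to `outdir`).
#' @export
runPipeline <- function(config, outdir, seed = NULL,
                        traits = "MY",
                        measures = c("persistency", "extended_lactation"),
                        chromosomes = NULL, step = 2, nPermutations = 1000,
                        nBootstrap = 0, twoQtl = FALSE, makePlots = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, start) timings[[stage]] <<-
    round(as.numeric(difftime(Sys.time(), start, units = "secs")), 3)

  # --- stage: inputs -------------------------------------------------
  s <- Sys.time()
  if (is(config, "SimulationConfig")) {
    if (!is.null(seed)) config@seed <- as.integer(seed)
    seeds <- .stageSeeds(config@seed)
    bundle <- simulateStudy(config, dir = file.path(outdir, "inputs"))
  } else {
    seeds <- .stageSeeds(if (is.null(seed)) 1L else as.integer(seed))
    map <- readLinkageMap(config$map)
    bundle <- list(map = map,
                   genotypes = readTransmissionMatrix(config$genotypes, map),
                   records = readPhenotypes(config$phenotypes),
                   config = config)
  }
  report <- validateInputs(bundle$map, bundle$genotypes, bundle$records)
  tick("inputs", s)

  # --- stage: curve fitting and derived traits -----------------------
  s <- Sys.time()
  records <- buildComponentRecords(bundle$records)
  fits <- .fitCurveTable(records)
  writeWoodFits(fits, file.path(outdir, "wood_fits.csv"))
  derived <- deriveTraitTable(fits)
  utils::write.csv(derived, file.path(outdir, "derived_traits.csv"),
                   row.names = FALSE)
  utils::write.csv(summarizeTraits(derived),
                   file.path(outdir, "trait_summary.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(traitCorrelations(derived)),
                   file.path(outdir, "trait_correlations.csv"))
  tick("derive", s)

  # --- stage: scans --------------------------------------------------
  s <- Sys.time()
  if (is.null(chromosomes)) chromosomes <- chromosomes(bundle$map)
  gen <- bundle$genotypes
  scanRows <- list(); regRows <- list(); twoRows <- list()
  profiles <- list()
  for (measure in measures) for (tr in intersect(traits, derived$trait)) {
    d <- derived[derived$trait == tr, , drop = FALSE]
    vals <- d[[measure]]
    names(vals) <- d$ewe_id
    vals <- vals[!is.na(vals) & names(vals) %in% daughters(gen)]
    if (length(vals) < 30) next
    y <- transformTrait(vals)
    label <- paste(measure, tr, sep = "_")
    for (chr in chromosomes) {
      if (nrow(mapTable(bundle$map, chr)) < 1) next
      mle <- tryCatch(scanMle(y, gen, chr, step = step),
                      error = function(e) NULL)
      thr <- tryCatch(
        permuteThresholds(y, gen, chr, n = nPermutations,
                          seed = seeds[["permutation"]] + chr, step = step),
        error = function(e) NULL)
      reg <- tryCatch(scanRegression(y, gen, chr, step = step,
                                     thresholds = thr),
                      error = function(e) NULL)
      if (!is.null(mle)) {
        pkRow <- cbind(trait = label, scanPeak(mle))
        scanRows[[length(scanRows) + 1]] <- pkRow
        profiles[[length(profiles) + 1]] <-
          cbind(trait = label, chromosome = chr, method = "mle",
                scanTable(mle)[c("position", "stat")])
      }
      if (!is.null(reg)) {
        pk <- scanPeak(reg)
        pk$stars <- attr(reg@sigClass, "stars")
        if (nBootstrap > 0 && !is.null(thr) &&
            reg@peakValue > thr$threshold[thr$scope == "chromosome" &
                                          thr$alpha == 0.05][1]) {
          ci <- bootstrapCi(y, gen, chr, n = nBootstrap,
                            seed = seeds[["bootstrap"]] + chr, step = step)
          pk$ci_lo <- ci[1]; pk$ci_hi <- ci[2]
        }
        # QTL heritability from the nested regression fits at the peak
        nr <- reg@n
        fpk <- reg@peakValue
        rssRatio <- 1 / (1 + fpk / (nr - 2))       # RSS_full / RSS_reduced
        pk$h2_qtl <- as.numeric(qtlHeritability(rssRatio, 1, nr - 2, nr - 1))
        regRows[[length(regRows) + 1]] <- pk
        profiles[[length(profiles) + 1]] <-
          cbind(trait = label, chromosome = chr, method = "regression",
                scanTable(reg)[c("position", "stat")])
      }
      if (twoQtl) {
        tq <- tryCatch(scanTwoQtl(y, gen, chr), error = function(e) NULL)
        if (!is.null(tq))
          twoRows[[length(twoRows) + 1]] <- data.frame(
            trait = label, chromosome = chr, pos_a = tq@positionA,
            pos_b = tq@positionB,
            flank_a = paste(tq@flankA, collapse = "-"),
            flank_b = paste(tq@flankB, collapse = "-"),
            f_2vs0 = tq@f2vs0, f_2vs1 = tq@f2vs1,
            effect_a_sd = tq@effects$effect_sd[1],
            se_a = tq@effects$se_sd[1],
            effect_b_sd = tq@effects$effect_sd[2],
            se_b = tq@effects$se_sd[2], phase = tq@phase)
      }
    }
  }
  mlePeaks <- if (length(scanRows)) do.call(rbind, scanRows) else NULL
  regPeaks <- if (length(regRows)) do.call(rbind, regRows) else NULL
  twoPeaks <- if (length(twoRows)) do.call(rbind, twoRows) else NULL
  prof <- if (length(profiles)) do.call(rbind, profiles) else NULL
  if (!is.null(mlePeaks))
    utils::write.csv(mlePeaks, file.path(outdir, "peaks_mle.csv"),
                     row.names = FALSE)
  if (!is.null(regPeaks))
    utils::write.csv(regPeaks, file.path(outdir, "peaks_regression.csv"),
                     row.names = FALSE)
  if (!is.null(twoPeaks))
    utils::write.csv(twoPeaks, file.path(outdir, "two_qtl.csv"),
                     row.names = FALSE)
  if (!is.null(prof))
    utils::write.csv(prof, file.path(outdir, "scan_profiles.csv"),
                     row.names = FALSE)
  if (makePlots && !is.null(prof)) {
    grDevices::pdf(file.path(outdir, "scan_profiles.pdf"), width = 7,
                   height = 4)
    for (lb in unique(prof$trait)) for (chr in unique(prof$chromosome)) {
      pp <- prof[prof$trait == lb & prof$chromosome == chr, , drop = FALSE]
      if (!nrow(pp)) next
      for (mth in unique(pp$method)) {
        pm <- pp[pp$method == mth, ]
        graphics::plot(pm$position, pm$stat, type = "l",
                       xlab = "position (cM)",
                       ylab = if (mth == "mle") "LOD" else "F",
                       main = sprintf("%s chr %s (%s)", lb, chr, mth))
      }
    }
    grDevices::dev.off()
  }
  tick("scan", s)

  # --- manifest ------------------------------------------------------
  inputFiles <- list.files(file.path(outdir, "inputs"), full.names = TRUE)
  checksums <- if (length(inputFiles)) {
    cs <- tools::md5sum(inputFiles)
    names(cs) <- basename(inputFiles)
    as.list(cs)
  } else list()
  cfgPath <- file.path(outdir, "inputs", "config.yaml")
  manifest <- list(
    package_version = as.character(utils::packageVersion("lactQTL")),
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    seeds = as.list(seeds),
    config_hash = if (file.exists(cfgPath))
      unname(tools::md5sum(cfgPath)) else NA,
    input_checksums = checksums,
    validation = report,
    stages = timings,
    status = "complete")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(derived = derived, fits = fits, mlePeaks = mlePeaks,
                 regPeaks = regPeaks, twoQtl = twoPeaks,
                 profiles = prof, manifest = manifest, validation = report,
                 outdir = outdir))
}
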