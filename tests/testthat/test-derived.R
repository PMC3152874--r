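test_that("cumulative yield matches closed forms and quadrature", {
  f <- WoodFit(2, 1e-9, 0.01)
  expect_equal(cumulativeYield(f, 0), 0)
  expect_equal(cumulativeYield(f, 100), 2 * (1 - exp(-1)) / 0.01,
               tolerance = 1e-6)
  expect_error(cumulativeYield(f, -1), "nonnegative")

  f2 <- WoodFit(1, 0.5, 0.02)
  q <- integrate(function(t) predictYield(f2, t), 0, 100,
                 rel.tol = 1e-12)$value
  expect_equal(cumulativeYield(f2, 100), q, tolerance = 1e-8)

  # monotone nondecreasing in T
  Ts <- seq(0, 300, by = 10)
  expect_true(all(diff(cumulativeYield(f2, Ts)) >= 0))
})

test_that("persistency follows the curve-shape definition", {
  expect_equal(persistency(WoodFit(3, 1e-12, 0.01)), exp(-1),
               tolerance = 1e-6)
  # at the peak day persistency is exactly one
  f <- WoodFit(2, 0.5, 0.004)          # t_max = 125
  expect_equal(persistency(f, T = 125), 1)
  # flat-curve limit approaches one
  expect_gt(persistency(WoodFit(2, 1e-12, 1e-6)), 0.999)
  # non-declining curves have undefined persistency, with a reason
  nd <- suppressWarnings(WoodFit(2, 0.3, -0.01))
  p <- persistency(nd)
  expect_true(is.na(p))
  expect_equal(attr(p, "reason"), "non_declining_curve")
  # flatter decline (smaller c) is always more persistent
  cs <- seq(0.005, 0.05, by = 0.005)
  ps <- vapply(cs, function(cc) persistency(WoodFit(2, 0.4, cc)), numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("extended lactation matches its closed form and composition", {
  el <- extendedLactation(WoodFit(5, 1e-12, 0.01))
  expect_equal(as.numeric(el), (exp(-1) - exp(-3)) / (1 - exp(-1)),
               tolerance = 1e-6)
  expect_lt(extendedLactation(WoodFit(5, 0.3, 0.2)), 1e-4)
  f <- WoodFit(2, 0.6, 0.02)
  cy <- cumulativeYield(f, c(100, 300))
  expect_equal(as.numeric(extendedLactation(f)), (cy[2] - cy[1]) / cy[1])
  expect_gte(extendedLactation(f), 0)
})

test_that("component yields follow the printed arithmetic", {
  cy <- componentYields(MY = 2, proteinPct = 5, fatPct = 8, lactosePct = 4,
                        SCC = 1e6)
  expect_equal(cy$PY, 0.1)
  expect_equal(cy$FY, 0.16)
  expect_equal(cy$LY, 0.08)
  expect_equal(cy$SCS, 6)
  expect_equal(cy$SCY, 12)
  expect_equal(cy$UY, 0.16 + 1.85 * 0.1)
  # useful yield identity from unit fat and protein yields
  u <- componentYields(MY = 100, proteinPct = 1, fatPct = 1,
                       lactosePct = 1, SCC = 100)
  expect_equal(u$UY, u$FY + 1.85 * u$PY)
  expect_equal(componentYields(100, 1, 1, 1, 100)$FY + 0.85, 1.85)
  # MY = 0 kills all yields; SCC <= 0 kills the score
  z <- componentYields(0, 5, 6, 4, 1e5)
  expect_equal(unlist(z[c("PY", "FY", "LY", "SCY", "UY")]),
               c(PY = 0, FY = 0, LY = 0, SCY = 0, UY = 0))
  expect_true(is.na(componentYields(1, 5, 6, 4, 0)$SCS))
  expect_error(componentYields(-1, 5, 6, 4, 100), "nonnegative")
  expect_error(componentYields(1, 120, 6, 4, 100), "\\[0, 100\\]")
  # linear in MY at fixed percentages
  a <- componentYields(1, 5, 6, 4, 1e5)
  b <- componentYields(3, 5, 6, 4, 1e5)
  expect_equal(unlist(b[c("PY", "FY", "LY", "UY", "SCY")]),
               3 * unlist(a[c("PY", "FY", "LY", "UY", "SCY")]))
})

test_that("derived-trait summaries mirror the descriptive-table layout", {
  one <- data.frame(ewe_id = "e1", trait = "MY", persistency = 0.5,
                    extended_lactation = 0.4, cum100 = 1, cum300 = 2,
                    t_max = 20, max_y = 3)
  s <- summarizeTraits(one)
  r <- s[s$measure == "persistency" & s$trait == "MY", ]
  expect_equal(r$n, 1)
  expect_equal(r$mean, 0.5)
  expect_true(is.na(r$sd))
  expect_equal(c(r$min, r$max), c(0.5, 0.5))
  expect_error(summarizeTraits(one[0, ]), "empty")
})

test_that("synthetic cohort reproduces the trait ordering and correlations", {
  cfg <- simConfig(nDaughters = 50, nChromosomes = 2, nMarkers = 6,
                   chromosomeLengths = c(100, 80), seed = 5)
  b <- simulateStudy(cfg)
  recs <- buildComponentRecords(b$records)
  expect_true(all(recs$day[recs$trait == "MY"] %% 2 == 0))
  fits <- lapply(split(recs, interaction(recs$ewe_id, recs$trait, drop = TRUE)),
                 function(g) {
    f <- tryCatch(suppressWarnings(fitWood(g[c("day", "value")])),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(ewe_id = g$ewe_id[1], trait = g$trait[1], a = f@a, b = f@b,
               c = f@c)
  })
  fits <- do.call(rbind, fits)
  tab <- deriveTraitTable(fits)
  s <- summarizeTraits(tab)
  pers <- s[s$measure == "persistency", ]
  # useful yield persists more than raw milk (composition rises as milk falls)
  expect_lt(pers$mean[pers$trait == "MY"], pers$mean[pers$trait == "UY"])

  cm <- traitCorrelations(tab)
  expect_true(all(diag(cm) == 1))
  expect_equal(cm, t(cm))
  # persistency and extended lactation of milk share the Wood decline rate
  expect_gt(cm["pers_MY", "ext_MY"], 0.5)
})

test_that("correlation cells with too few complete pairs are missing", {
  tab <- data.frame(ewe_id = c("a", "b", "c", "a", "b"),
                    trait = c("MY", "MY", "MY", "PY", "PY"),
                    persistency = c(0.2, 0.3, 0.4, 0.5, 0.6),
                    extended_lactation = c(0.3, 0.4, 0.5, 0.8, 0.9),
                    cum100 = 1, cum300 = 2, t_max = 10, max_y = 1)
  cm <- traitCorrelations(tab)
  expect_true(is.na(cm["pers_MY", "pers_PY"]))   # only 2 complete pairs
  expect_equal(cm["pers_MY", "ext_MY"], 1)       # exactly proportional
})
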