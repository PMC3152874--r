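test_that("regression F at an informative marker is one-way ANOVA", {
  m <- LinkageMap(data.frame(chromosome = 1, marker = c("a", "b"),
                             position = c(0, 10)))
  # textbook fixture: two groups of four
  y <- c(4.1, 3.8, 4.4, 4.0, 5.2, 5.6, 5.1, 5.3)
  g <- c(0, 0, 0, 0, 1, 1, 1, 1)
  tm <- asTM(cbind(g, g), m)
  sc <- scanRegression(y, tm, 1, step = 5, minDaughters = 8)
  # hand-computed one-way ANOVA
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum((y - ave(y, g))^2)
  fExp <- (rss0 - rss1) / (rss1 / 6)
  expect_equal(scanTable(sc)$stat[scanTable(sc)$position == 0], fExp,
               tolerance = 1e-10)
  expect_equal(sc@peakValue, fExp, tolerance = 1e-10)
  # effect at the marker: class contrast (allele "A" is the g == 1 class)
  tab <- scanTable(sc)
  expect_equal(2 * tab$beta[tab$position == 0],
               mean(y[g == 1]) - mean(y[g == 0]), tolerance = 1e-10)
})

test_that("regression and mixture scans agree where information is complete", {
  m <- evenMap(4, 20)
  sim <- simMarkerTrait(80, 0.9, m, qtlIndex = 3, seed = 7)
  reg <- scanRegression(sim$y, sim$tm, 1, step = 2)
  mle <- scanMle(sim$y, sim$tm, 1, step = 2)
  # the two routes localize the QTL to the same region
  expect_lt(abs(reg@peakPosition - mle@peakPosition), 10)
  # LOD-F identity at fully informative positions
  n <- length(sim$y)
  rt <- scanTable(reg); mt <- scanTable(mle)
  for (pos in mapTable(m)$position) {
    fv <- rt$stat[rt$position == pos]
    expect_equal(mt$stat[mt$position == pos],
                 (n / 2) * log10(1 + fv / (n - 2)), tolerance = 1e-6)
  }
  # scan-wide effect sizes agree across the two routes at the peak
  expect_equal(reg@effectSD, mle@effectSD, tolerance = 0.1)
})

test_that("permutation thresholds are reproducible, ordered and label-invariant", {
  m <- evenMap(5, 20)
  set.seed(13)
  g <- simTransmitted(80, mapTable(m)$position)
  tm <- asTM(g, m)
  y <- rnorm(80)
  t1 <- permuteThresholds(y, tm, 1, n = 200, seed = 99, step = 4)
  t2 <- permuteThresholds(y, tm, 1, n = 200, seed = 99, step = 4)
  expect_identical(t1$threshold, t2$threshold)
  # stricter alpha, higher threshold; experiment-wide above chromosome-wide
  thr <- function(scope, a) t1$threshold[t1$scope == scope & t1$alpha == a]
  expect_gte(thr("chromosome", 0.01), thr("chromosome", 0.05))
  expect_gte(thr("experiment", 0.05), thr("chromosome", 0.05))
  expect_gte(thr("experiment", 0.01), thr("experiment", 0.05))
  expect_equal(attr(t1, "n_permutations"), 200)
  # renaming daughters does not change the thresholds
  al <- alleles(tm)
  rownames(al) <- sprintf("ewe_%03d", seq_len(nrow(al)))
  t3 <- permuteThresholds(y, TransmissionMatrix(al, m), 1, n = 200,
                          seed = 99, step = 4)
  expect_identical(t1$threshold, t3$threshold)
  # more permutations refine, not move, the 5% threshold
  t4 <- permuteThresholds(y, tm, 1, n = 1000, seed = 7, step = 4)
  expect_lt(abs(thr("chromosome", 0.05) -
                t4$threshold[t4$scope == "chromosome" & t4$alpha == 0.05]) /
            thr("chromosome", 0.05), 0.25)
  expect_error(permuteThresholds(y, tm, 1, n = 50), ">= 100")
})

test_that("peak classification follows the permutation-star convention", {
  thr <- data.frame(scope = c("chromosome", "chromosome", "experiment",
                              "experiment"),
                    alpha = c(0.05, 0.01, 0.05, 0.01),
                    threshold = c(5, 7, 9, 12))
  expect_equal(as.character(classifyF(4, thr)), "none")
  expect_equal(as.character(classifyF(6, thr)), "suggestive")
  expect_equal(attr(classifyF(6, thr), "stars"), "*")
  expect_equal(as.character(classifyF(8, thr)), "significant")
  expect_equal(as.character(classifyF(10, thr)), "highly significant")
  expect_equal(attr(classifyF(13, thr), "stars"), "****")
})

test_that("bootstrap position intervals collapse and widen appropriately", {
  m <- evenMap(5, 20)
  sim <- simMarkerTrait(120, 2, m, qtlIndex = 3, seed = 19)
  ci <- bootstrapCi(sim$y, sim$tm, 1, n = 200, seed = 3, step = 4)
  expect_lte(ci[1], 40); expect_gte(ci[2], 40)
  expect_lt(ci[2] - ci[1], 20)        # huge effect: tight interval
  # bit-reproducible under the seed
  ci2 <- bootstrapCi(sim$y, sim$tm, 1, n = 200, seed = 3, step = 4)
  expect_identical(attr(ci, "peaks"), attr(ci2, "peaks"))
  # null data: peaks wander over most of the chromosome
  set.seed(4)
  y0 <- rnorm(120)
  ci0 <- bootstrapCi(y0, sim$tm, 1, n = 200, seed = 5, step = 4)
  expect_gt(ci0[2] - ci0[1], 40)
})

test_that("QTL heritability follows the residual-mean-square formula", {
  expect_equal(as.numeric(qtlHeritability(10, 10, 5, 5)), 0)
  expect_equal(as.numeric(qtlHeritability(0.95 * 170, 1.0 * 171, 170, 171)),
               0.05, tolerance = 1e-12)
  h <- qtlHeritability(1.02 * 170, 1.0 * 171, 170, 171)
  expect_equal(as.numeric(h), 0)
  expect_true(attr(h, "clipped"))
  expect_error(qtlHeritability(-1, 1, 5, 5), "positive")
})

test_that("two-QTL search recovers a repulsion pair and nests correctly", {
  m <- evenMap(6, 20)   # 0..100 cM
  set.seed(37)
  n <- 400
  g <- simTransmitted(n, mapTable(m)$position)
  # QTL at markers 2 (20 cM) and 5 (80 cM), opposite signs (repulsion)
  y <- (g[, 2] - 0.5) * 0.55 - (g[, 5] - 0.5) * 0.5 + rnorm(n)
  tq <- scanTwoQtl(y, asTM(g, m), 1, step = 4)
  expect_s4_class(tq, "TwoQTLResult")
  expect_lt(tq@positionA, tq@positionB)
  expect_equal(tq@phase, "repulsion")
  expect_lt(abs(tq@positionA - 20), 15)
  expect_lt(abs(tq@positionB - 80), 15)
  expect_true(sign(tq@effects$effect_sd[1]) != sign(tq@effects$effect_sd[2]))
  expect_gte(tq@f2vs0, 0)
  expect_gte(tq@f2vs1, 0)
  expect_error(scanTwoQtl(y, asTM(g[, 1:2], evenMap(2, 20)), 1),
               ">= 3 markers")
})

test_that("the 2-vs-1 test stays small when one QTL suffices", {
  m <- evenMap(6, 20)
  set.seed(41)
  crit <- qf(0.95, 1, 172 - 3)
  below <- replicate(40, {
    g <- simTransmitted(172, mapTable(m)$position)
    y <- (g[, 3] - 0.5) * 0.8 + rnorm(172)
    scanTwoQtl(y, asTM(g, m), 1, step = 10)@f2vs1 < crit
  })
  expect_gte(mean(below), 0.8)
})
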