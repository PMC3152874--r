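test_that("trait log-transform handles zeros by the half-minimum rule", {
  expect_equal(as.numeric(transformTrait(c(1, exp(1), exp(2)))), c(0, 1, 2))
  v <- transformTrait(c(0, 0.4, 2))
  expect_equal(attr(v, "zero_offset"), 0.2)
  expect_equal(as.numeric(v[1]), log(0.2))
  expect_equal(attr(v, "n_zero"), 1)
  expect_error(transformTrait(c(-1, 2)), "nonnegative")
  expect_error(transformTrait(c(0, 0)), "all-zero")
})

test_that("mixture likelihood reduces correctly and matches enumeration", {
  set.seed(3)
  y <- rnorm(6, 1, 0.7)
  # degenerate mixture: every daughter certainly carries A
  expect_equal(mixtureLogLik(y, rep(1, 6), c(1.2, -9), 0.7),
               sum(dnorm(y, 1.2, 0.7, log = TRUE)))
  # null identity: equal means make the mixture a single normal for any p
  p <- runif(6)
  expect_equal(mixtureLogLik(y, p, c(0.8, 0.8), 0.5),
               sum(dnorm(y, 0.8, 0.5, log = TRUE)))
  expect_error(mixtureLogLik(y, p, c(0, 1), 0), "positive")

  # n = 4 brute force: sum over all 2^4 genotype configurations
  y4 <- c(0.1, 1.4, -0.6, 0.9)
  p4 <- c(0.2, 0.9, 0.5, 0.7)
  mu <- c(0.8, -0.3); sig <- 0.6
  lik <- 0
  for (cfgId in 0:15) {
    g <- as.integer(intToBits(cfgId)[1:4])     # 1 = carries A
    w <- prod(ifelse(g == 1, p4, 1 - p4))
    lik <- lik + w * prod(dnorm(y4, ifelse(g == 1, mu[1], mu[2]), sig))
  }
  expect_equal(mixtureLogLik(y4, p4, mu, sig), log(lik), tolerance = 1e-12)
})

test_that("LOD classes follow the printed cut-offs", {
  expect_equal(classifyLod(3.4), "highly significant")
  expect_equal(classifyLod(1.9), "suggestive")
  expect_equal(classifyLod(1.74), "none")
  expect_equal(classifyLod(c(0, 1.75, 2, 3, 3.001)),
               c("none", "suggestive", "significant", "significant",
                 "highly significant"))
  expect_error(classifyLod(-0.1), "nonnegative")
})

test_that("1-LOD support intervals drop off and clip correctly", {
  # monotone profile peaking at the last position: right-clipped
  pos <- 0:10
  expect_equal(as.numeric(supportInterval(pos, pos / 5)),
               c(5, 10))
  # quadratic profile with known 1-LOD roots at 4 and 6
  grid <- seq(0, 10, by = 0.5)
  lod <- 3 - (grid - 5)^2
  expect_equal(as.numeric(supportInterval(grid, lod)), c(4, 6))
  # flat profile: the whole chromosome, tie flagged leftmost
  fl <- supportInterval(pos, rep(2, 11))
  expect_equal(as.numeric(fl), c(0, 10))
  expect_true(attr(fl, "tied"))
  expect_equal(attr(fl, "peak"), 0)
})

test_that("standardized effects are antisymmetric in allele labels", {
  expect_equal(standardizedEffect(1, 1, 2), 0)
  expect_equal(standardizedEffect(1.2, 0.6, 1.5),
               -standardizedEffect(0.6, 1.2, 1.5))
  expect_error(standardizedEffect(1, 0, 0), "positive")
})

test_that("mixture scan equals two-group regression at informative markers", {
  m <- evenMap(3, 20)
  sim <- simMarkerTrait(60, 0.8, m, qtlIndex = 2, seed = 17)
  sc <- scanMle(sim$y, sim$tm, 1, step = 5)
  tab <- scanTable(sc)
  n <- length(sim$y)
  for (mkPos in c(0, 20, 40)) {
    g <- sim$g[, mkPos / 20 + 1]
    rss0 <- sum((sim$y - mean(sim$y))^2)
    rss1 <- sum((sim$y - ave(sim$y, g))^2)
    lodExp <- (n / 2) * log10(rss0 / rss1)
    expect_equal(tab$stat[tab$position == mkPos], lodExp, tolerance = 1e-6)
  }
  # the scan reports the mixture loglik maximum: it can only improve on the
  # EM starting point and the no-QTL model
  pk <- which.max(tab$stat)
  p <- transmissionProb(sim$tm, chromosome = 1, query = tab$position[pk])
  llPeak <- mixtureLogLik(sim$y, as.numeric(p), c(tab$mu_A[pk], tab$mu_M[pk]),
                          tab$sigma[pk])
  mu0 <- mean(sim$y); s0 <- sqrt(mean((sim$y - mu0)^2))
  expect_gte(llPeak, sum(dnorm(sim$y, mu0, s0, log = TRUE)) - 1e-8)
  expect_gte(llPeak, mixtureLogLik(sim$y, as.numeric(p),
                                   c(mu0 + s0 / 2, mu0 - s0 / 2), s0))
})

test_that("null LOD at a fixed informative position is chi-square calibrated", {
  # LRT of 2 means vs 1 at a fully informative position: LOD ~ chisq(1)/(2 ln 10),
  # mean about 0.217
  m1 <- LinkageMap(data.frame(chromosome = 1, marker = "only", position = 0))
  set.seed(23)
  lods <- replicate(400, {
    g <- rbinom(120, 1, 0.5)
    tm <- asTM(matrix(g, ncol = 1), m1)
    scanMle(rnorm(120), tm, 1)@peakValue
  })
  expect_equal(mean(lods), 1 / (2 * log(10)), tolerance = 0.2)
  # and the pointwise alpha = 0.05 threshold is exceeded ~5% of the time
  thr <- qchisq(0.95, 1) / (2 * log(10))
  expect_lt(abs(mean(lods > thr) - 0.05), 0.03)
})

test_that("null chromosome scans rarely reach the suggestive class", {
  m <- evenMap(6, 20)
  set.seed(29)
  hits <- replicate(120, {
    g <- simTransmitted(100, mapTable(m)$position)
    tm <- asTM(g, m)
    scanMle(rnorm(100), tm, 1, step = 4)@peakValue >= 1.75
  })
  expect_gte(mean(!hits), 0.92)
})

test_that("with no QTL the design's rejection rate sits near alpha", {
  # the scan maximum over the bracket inflates the pointwise level a little
  p0 <- estimatePower(n = 172, effect = 0, alpha = 0.05, nrep = 400,
                      seed = 4)
  expect_gte(p0$power, 0.02)
  expect_lte(p0$power, 0.12)
})

test_that("scan preconditions and notes are enforced", {
  m <- evenMap(3, 20)
  sim <- simMarkerTrait(20, 0.5, m, 2, seed = 31)
  expect_error(scanMle(sim$y, sim$tm, 1), ">= 30")
  sim2 <- simMarkerTrait(40, 0.5, m, 2, seed = 32)
  sc <- scanMle(sim2$y, sim2$tm, 1, step = 10)
  expect_s4_class(sc, "ScanResult")
  expect_true(all(scanTable(sc)$stat >= 0))
})
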