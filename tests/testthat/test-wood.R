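test_that("noiseless Wood records are recovered exactly", {
  days <- seq(2, 200, 2)
  rec <- data.frame(day = days, value = woodRecords(10, 0.4, 0.015, days))
  f <- fitWoodLogLinear(rec)
  expect_equal(unname(coef(f)[c("a", "b", "c")]), c(10, 0.4, 0.015),
               tolerance = 1e-6)
  # nonlinear refinement from a perturbed start also recovers the truth
  init <- WoodFit(10 * 1.5, 0.4 * 1.5, 0.015 * 1.5)
  f2 <- fitWoodNLS(rec, init)
  expect_equal(unname(coef(f2)[c("a", "b", "c")]), c(10, 0.4, 0.015),
               tolerance = 1e-5)
})

test_that("noisy fits are unbiased to within 2% on average", {
  set.seed(11)
  days <- seq(2, 200, 2)
  mu <- woodRecords(10, 0.4, 0.015, days)
  est <- t(replicate(100, {
    rec <- data.frame(day = days, value = mu * exp(rnorm(length(days), 0, 0.1)))
    coef(fitWood(rec))[c("a", "b", "c")]
  }))
  expect_lt(abs(mean(est[, "a"]) / 10 - 1), 0.02)
  expect_lt(abs(mean(est[, "b"]) / 0.4 - 1), 0.02)
  expect_lt(abs(mean(est[, "c"]) / 0.015 - 1), 0.02)
})

test_that("unfittable curves raise errors and degenerate fits are flagged", {
  expect_error(fitWoodLogLinear(data.frame(day = c(2, 4), value = c(1, 2))),
               "unfittable")
  # zero yields are excluded, then too few points remain
  expect_error(fitWoodLogLinear(
    data.frame(day = 1:5, value = c(1, 2, 0, 0, 0))), "unfittable")
  # constant records: flat-curve boundary, no decline
  rec <- data.frame(day = seq(5, 100, 5), value = rep(7, 20))
  f <- suppressWarnings(fitWood(rec))
  expect_equal(unname(coef(f)["a"]), 7, tolerance = 1e-4)
  expect_true(any(c("non_declining", "flat_boundary") %in% f@flags))
})

test_that("refinement never increases natural-scale residual error", {
  set.seed(21)
  days <- seq(2, 150, 2)
  for (i in 1:20) {
    a <- runif(1, 1, 10); b <- runif(1, 0.1, 0.8); c <- runif(1, 0.01, 0.05)
    rec <- data.frame(day = days,
                      value = woodRecords(a, b, c, days) *
                        exp(rnorm(length(days), 0, 0.2)))
    init <- suppressWarnings(fitWoodLogLinear(rec))
    ref <- fitWoodNLS(rec, init)
    rssNat <- function(f) sum((rec$value -
      predictYield(f, rec$day))^2)
    expect_lte(rssNat(ref), rssNat(init) * (1 + 1e-10))
  }
  # an already-optimal start is a fixed point (within tolerance)
  rec <- data.frame(day = days, value = woodRecords(5, 0.3, 0.02, days))
  opt <- WoodFit(5, 0.3, 0.02)
  again <- fitWoodNLS(rec, opt)
  expect_equal(unname(coef(again)), unname(coef(opt)), tolerance = 1e-6)
})

test_that("curve peak matches the closed form and the curve is unimodal", {
  expect_equal(unname(lactationPeak(WoodFit(1, 0.5, 0.01))["t_max"]), 50)
  expect_equal(unname(lactationPeak(WoodFit(1, 0.5, 0.01))["maxY"]),
               50^0.5 * exp(-0.5), tolerance = 1e-12)
  expect_equal(unname(lactationPeak(WoodFit(7, 0, 0.02))), c(0, 7))
  expect_equal(predictYield(WoodFit(1, 0, 0.01), 100), exp(-1),
               tolerance = 1e-12)
  expect_error(predictYield(WoodFit(1, 0.5, 0.01), 0), "positive")

  set.seed(31)
  for (i in 1:100) {
    f <- WoodFit(runif(1, 0.5, 5), runif(1, 0.1, 1), runif(1, 0.005, 0.05))
    pk <- lactationPeak(f)
    # maxY is the maximum over a dense grid that includes t_max
    grid <- sort(c(pk[["t_max"]], seq(0.01, 300, by = 0.01)))
    w <- predictYield(f, grid)
    expect_equal(max(w), pk[["maxY"]], tolerance = 1e-8)
    expect_equal(w[grid == pk[["t_max"]]], pk[["maxY"]], tolerance = 1e-12)
    # nonincreasing beyond the peak
    post <- w[grid >= pk[["t_max"]]]
    expect_true(all(diff(post) <= 1e-12))
    expect_equal(predictYield(f, pk[["t_max"]] + 1e-9), pk[["maxY"]],
                 tolerance = 1e-6)
  }
})

test_that("population fit shrinks toward the mean and recovers fixed effects", {
  set.seed(41)
  days <- seq(2, 120, 2)
  mk <- function(ewe, kTrue) {
    v <- woodRecords(exp(kTrue), 0.4, 0.02, days) *
      exp(rnorm(length(days), 0, 0.25))
    data.frame(ewe_id = ewe, lactation_id = 1, day = days, value = v)
  }
  # identical truth: shrunk estimates are strictly less dispersed than raw
  recs <- do.call(rbind, lapply(1:25, function(i) mk(sprintf("e%02d", i), log(5))))
  fp <- fitPopulation(recs, refine = FALSE)
  expect_lt(sd(fp$fits$k_shrunk), sd(fp$fits$k))
  expect_lt(sd(fp$fits$b_shrunk), sd(fp$fits$b))

  # two parity groups differing only in k by a known contrast
  contrast <- 0.5
  recs2 <- rbind(
    do.call(rbind, lapply(1:20, function(i) mk(sprintf("p1_%02d", i), log(5)))),
    do.call(rbind, lapply(1:20, function(i) mk(sprintf("p2_%02d", i),
                                               log(5) + contrast))))
  cov2 <- data.frame(ewe_id = unique(recs2$ewe_id), lactation_id = 1,
                     parity = rep(c("1", "2"), each = 20))
  fp2 <- fitPopulation(recs2, covariates = cov2, refine = FALSE)
  expect_equal(unname(fp2$effects$k["parity2"]), contrast, tolerance = 0.05)
  # standardization removes the parity contrast: adjusted group means agree
  grp <- substr(fp2$fits$ewe_id, 1, 2)
  adjContrast <- diff(tapply(fp2$fits$k_adj, grp, mean))
  rawContrast <- diff(tapply(fp2$fits$k, grp, mean))
  expect_lt(abs(adjContrast), 0.05)
  expect_gt(rawContrast, 0.4)

  expect_error(fitPopulation(mk("solo", log(5))), ">= 2 lactations")
})

test_that("a factor level with a single lactation is pooled with the reference", {
  set.seed(43)
  days <- seq(2, 120, 2)
  recs <- do.call(rbind, lapply(1:8, function(i) {
    v <- woodRecords(5, 0.4, 0.02, days) * exp(rnorm(length(days), 0, 0.2))
    data.frame(ewe_id = sprintf("e%d", i), lactation_id = 1, day = days,
               value = v)
  }))
  cov <- data.frame(ewe_id = sprintf("e%d", 1:8), lactation_id = 1,
                    season = c(rep("s1", 7), "s2"))
  fp <- fitPopulation(recs, covariates = cov, refine = FALSE)
  expect_match(paste(fp$flags, collapse = " "), "non-estimable")
  expect_false("seasons2" %in% names(fp$effects$k))
})
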