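test_that("lognormal threshold grid matches the closed-form moments", {
  g <- lognormalThresholdGrid(15.63446045, 6.01160431, 1001)
  expect_equal(g$sdlog^2, 0.1380, tolerance = 1e-3)
  expect_equal(g$mulog, 2.6805, tolerance = 1e-3)
  # weight is maximal (0) at the grid midpoint x = mu (N odd => on grid)
  expect_equal(max(g$logw), 0, tolerance = 1e-12)
  expect_equal(which.max(g$logw), 501)
  expect_true(all(diff(g$z) > 0))
  # weighted quadrature recovers the lognormal mean within 0.1%
  w <- exp(g$logw)
  expect_equal(sum(w * g$z) / sum(w), 15.63446045, tolerance = 1e-3)
  expect_error(lognormalThresholdGrid(-1, 2, 100), "positive")
  expect_error(lognormalThresholdGrid(10, 0, 100), "positive")

  expect_equal(deltaThreshold(20)$z, 20)
  expect_error(deltaThreshold(-1), "non-negative")
})

test_that("zero exposure and zero hazard give the exact limits", {
  e0 <- gutsExperiment(c(0, 0), c(0, 22), c(10, 9, 8), c(0, 10, 22))
  for (cfg in list(gutsConfig(N = 200, M = 500),
                   gutsConfig(dist = "delta", N = 1, M = 500),
                   gutsConfig(model = "it", M = 500))) {
    p <- setNames(c(0.07, 0.1, 2, 10, 4), c("hb", "ke", "kk", "mn", "sd"))
    p <- p[paramNames(cfg)]
    s <- survivalProbabilities(e0, p, cfg)
    expect_equal(s$survival, exp(-0.07 * c(0, 10, 22)), tolerance = 1e-12)
  }
  # hb = 0, kk = 0: survival is identically 1 despite exposure
  e <- loadDiazinon()[[1]]
  s <- survivalProbabilities(e, c(0, 0.1, 0, 15, 6),
                             gutsConfig(N = 100, M = 1000))
  expect_equal(s$survival, rep(1, 23), tolerance = 1e-12)
})

test_that("fast recursion equals the naive double sum on random instances", {
  set.seed(101)
  for (r in 1:20) {
    inst <- randomInstance()
    p <- inst$params
    cfg <- gutsConfig(N = 50, M = 200)
    S <- survivalProbabilities(inst$exp, p, cfg)$survival
    g <- lognormalThresholdGrid(p[["mn"]], p[["sd"]], 50)
    Sn <- naiveSurvivalSum(concentrations(inst$exp),
                           exposureTimes(inst$exp), p[["hb"]], p[["ke"]],
                           p[["kk"]], obsTimes(inst$exp), g$z, g$logw, 200)
    expect_lt(max(abs(S - Sn) / pmax(abs(Sn), 1e-300)), 1e-12)
  }
})

test_that("survival curves satisfy their invariants on random inputs", {
  set.seed(102)
  for (r in 1:25) {
    inst <- randomInstance()
    cfg <- gutsConfig(N = 80, M = 400)
    for (flavour in list(inst$params,
                         inst$params[c("hb", "ke", "mn", "sd")])) {
      cfgF <- if (length(flavour) == 4) gutsConfig(model = "it", M = 400)
      else cfg
      S <- survivalProbabilities(inst$exp, flavour, cfgF)$survival
      expect_equal(S[1], 1)
      expect_true(all(diff(S) <= 1e-12))
      expect_true(all(S >= 0 & S <= 1 + 1e-12))
    }
  }
})

test_that("background mortality factors out exactly", {
  set.seed(103)
  inst <- randomInstance()
  cfg <- gutsConfig(N = 60, M = 300)
  p0 <- inst$params
  p0[["hb"]] <- 0
  phb <- inst$params
  phb[["hb"]] <- 0.12
  S0 <- survivalProbabilities(inst$exp, p0, cfg)$survival
  Shb <- survivalProbabilities(inst$exp, phb, cfg)$survival
  expect_equal(Shb, S0 * exp(-0.12 * obsTimes(inst$exp)), tolerance = 1e-12)
})

test_that("SD is the delta limit and IT the large-kk limit of Proper", {
  e <- loadDiazinon()[[1]]
  # lognormal with tiny sd approaches the shared-threshold (SD) model
  pSD <- c(hb = 0.02, ke = 0.1, kk = 1.5, mn = 12)
  sSD <- survivalProbabilities(e, pSD,
                               gutsConfig(dist = "delta", N = 1, M = 5000))
  pNarrow <- c(pSD, sd = 1e-6)
  sNarrow <- survivalProbabilities(e, pNarrow,
                                   gutsConfig(N = 1000, M = 5000))
  expect_lt(max(abs(sSD$survival - sNarrow$survival)), 1e-3)
  # Proper with huge kk approaches individual tolerance
  pIT <- c(hb = 0.02, ke = 0.1, mn = 12, sd = 5)
  sIT <- survivalProbabilities(e, pIT, gutsConfig(model = "it", M = 20000))
  pBig <- c(hb = 0.02, ke = 0.1, kk = 1e6, mn = 12, sd = 5)
  sBig <- survivalProbabilities(e, pBig, gutsConfig(N = 4000, M = 20000))
  expect_lt(max(abs(sIT$survival - sBig$survival)), 1e-2)
})

test_that("IT survival follows the threshold CDF at the running maximum", {
  # monotone increasing damage: running max equals the current value
  e <- gutsExperiment(c(100, 100), c(0, 20), c(30, 25, 20, 15),
                      c(0, 5, 10, 20))
  p <- c(hb = 0.01, ke = 0.2, mn = 30, sd = 10)
  s <- survivalProbabilities(e, p, gutsConfig(model = "it", M = 10000))
  D <- damageAt(c(100, 100), c(0, 20), 0.2, obsTimes(e))
  sigma2 <- log1p(10^2 / 30^2)
  expect_equal(s$survival,
               exp(-0.01 * obsTimes(e)) *
                 plnorm(D, log(30) - sigma2 / 2, sqrt(sigma2),
                        lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("doubling N and M converges the survival curve", {
  set.seed(104)
  inst <- randomInstance()
  p <- inst$params
  S1 <- survivalProbabilities(inst$exp, p, gutsConfig(N = 100, M = 500))
  S2 <- survivalProbabilities(inst$exp, p, gutsConfig(N = 200, M = 1000))
  S4 <- survivalProbabilities(inst$exp, p, gutsConfig(N = 400, M = 2000))
  d12 <- max(abs(S1$survival - S2$survival))
  d24 <- max(abs(S2$survival - S4$survival))
  expect_lt(d24, d12 + 1e-12)
})

test_that("improper parameters flag the curve unavailable", {
  e <- loadDiazinon()[[1]]
  expect_warning(s <- survivalProbabilities(e, c(-0.1, 0.1, 3, 20, 10),
                                            gutsConfig(N = 10, M = 100)),
                 "improper")
  expect_true(all(is.na(s$survival)))
  expect_identical(attr(s, "status"), "improper")
  expect_error(survivalProbabilities(e, c(0.1, 3, 20, 10), gutsConfig()),
               "expected 5 parameters")
})
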