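test_that("quadrature oracle reproduces the exact no-damage limits", {
  p <- c(hb = 0.07, ke = 0.1, kk = 2, mn = 10, sd = 4)
  expect_equal(bruteForceSurvival(c(0, 0), c(0, 10), p, 6),
               exp(-0.07 * 6), tolerance = 1e-8)
  p0 <- replace(p, 3, 0)  # kk = 0: exposure cannot kill
  expect_equal(bruteForceSurvival(c(120, 120), c(0, 10), p0, 6),
               exp(-0.07 * 6), tolerance = 1e-8)
  expect_equal(bruteForceSurvival(c(120, 120), c(0, 10), p, 0), 1)
})

test_that("naive sum with a single threshold reduces to the SD formula", {
  e <- loadDiazinon()[[1]]
  hb <- 0.03; ke <- 0.1; kk <- 1.5; mn <- 8; M <- 2000
  Sn <- naiveSurvivalSum(concentrations(e), exposureTimes(e), hb, ke, kk,
                         obsTimes(e), z = mn, logw = 0, M = M)
  g <- refineTimeGrid(obsTimes(e), M)
  D <- damageAt(concentrations(e), exposureTimes(e), ke, g$tau)
  Ssd <- vapply(seq_along(obsTimes(e)), function(i) {
    excess <- pmax(D[seq_len(g$cut[i])] - mn, 0)
    exp(-kk * g$dtau * sum(excess) - hb * obsTimes(e)[i])
  }, 0)
  expect_equal(Sn, Ssd, tolerance = 1e-12)
  # and matches the engine's delta flavour
  Se <- survivalProbabilities(e, c(hb, ke, kk, mn),
                              gutsConfig(dist = "delta", N = 1, M = M))
  expect_equal(Se$survival, Ssd, tolerance = 1e-12)
})

test_that("the forward simulator honours seeds and degenerate limits", {
  # hb = 0 and no exposure: nobody dies
  sim <- simulateSurvival(c(0, 0), c(0, 10), 0:10,
                          c(hb = 0, ke = 0.1, kk = 2, mn = 10, sd = 4),
                          gutsConfig(N = 10, M = 1000), n0 = 40, seed = 3)
  expect_true(all(survivors(sim) == 40))
  # determinism
  p <- c(hb = 0.02, ke = 0.1, kk = 2, mn = 12, sd = 5)
  e <- loadDiazinon()[[1]]
  s1 <- simulateSurvival(concentrations(e), exposureTimes(e), 0:22, p,
                         gutsConfig(N = 10, M = 2000), n0 = 50, seed = 9)
  s2 <- simulateSurvival(concentrations(e), exposureTimes(e), 0:22, p,
                         gutsConfig(N = 10, M = 2000), n0 = 50, seed = 9)
  expect_identical(survivors(s1), survivors(s2))
  expect_error(simulateSurvival(concentrations(e), exposureTimes(e), 0:22,
                                c(-1, 0.1, 2, 12, 5),
                                gutsConfig(), n0 = 10), "improper")
})

test_that("SD simulation agrees with the delta-threshold engine", {
  e <- loadDiazinon()[[2]]
  p <- c(hb = 0.03, ke = 0.1, kk = 1.5, mn = 9)
  cfg <- gutsConfig(dist = "delta", N = 1, M = 5000)
  sim <- simulateSurvival(concentrations(e), exposureTimes(e), 0:22, p,
                          cfg, n0 = 8000, seed = 17)
  S <- survivalProbabilities(e, p, cfg)$survival
  se <- sqrt(pmax(S * (1 - S), 1e-10) / 8000)
  expect_lt(max(abs(survivors(sim) / 8000 - S) / se), 3.5)
})

test_that("IT simulation kills at the first threshold crossing", {
  # monotone damage, no background: survivors at t are exactly those whose
  # threshold exceeds D(t)
  p <- c(hb = 0, ke = 0.3, mn = 20, sd = 6)
  cfg <- gutsConfig(model = "it", M = 5000)
  sim <- simulateSurvival(c(80, 80), c(0, 15), c(0, 3, 8, 15), p, cfg,
                          n0 = 4000, seed = 13)
  D <- damageAt(c(80, 80), c(0, 15), 0.3, c(0, 3, 8, 15))
  sigma2 <- log1p(36 / 400)
  expected <- 4000 * plnorm(D, log(20) - sigma2 / 2, sqrt(sigma2),
                            lower.tail = FALSE)
  expect_true(all(abs(survivors(sim) - expected) <=
                    3 * sqrt(4000 * 0.25) + 1))
})
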