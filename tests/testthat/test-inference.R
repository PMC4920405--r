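test_that("log-posterior guards the prior support", {
  exps <- loadDiazinon()
  cfg <- gutsConfig(N = 100, M = 1000)
  b <- priorBounds(cfg)
  expect_identical(unname(b$lower), rep(0, 5))
  expect_identical(unname(b$upper[3]), 30)
  p <- c(hb = 0.05, ke = 0.1, kk = 3, mn = 20, sd = 10)
  expect_true(is.finite(logPosterior(p, exps, b, cfg)))
  for (bad in list(replace(p, 3, 31), replace(p, 1, -0.01),
                   replace(p, 2, NaN), replace(p, 4, Inf)))
    expect_identical(logPosterior(bad, exps, b, cfg), -Inf)
  # inside the bounds the posterior equals the likelihood (uniform prior)
  expect_equal(logPosterior(p, exps, b, cfg),
               totalLogLikelihood(exps, p, cfg)$value)
})

test_that("MAP search improves on its start and respects the box", {
  # background-only data: hb has a closed-form MLE, the other parameters
  # are unidentified
  set.seed(31)
  hbTrue <- 0.1
  yt <- 0:15
  y <- c(60, cummin(60 - cumsum(rmultinom(1, 60,
    c(-diff(exp(-hbTrue * yt)), exp(-hbTrue * 15)))[1:15])))[1:16]
  y <- cummin(pmax(y, 0))
  e <- gutsExperiment(c(0, 0), c(0, 15), y, yt)
  cfg <- gutsConfig(N = 50, M = 500)
  start <- c(hb = 0.05, ke = 0.1, kk = 3, mn = 20, sd = 10)
  lpStart <- logPosterior(start, list(e), config = cfg)
  map <- suppressWarnings(findMAP(start, list(e), config = cfg,
                                  maxfeval = 5000))
  expect_gte(map$value, lpStart)
  expect_true(all(map$par >= 0 & map$par <= c(1, 1, 30, 40, 20)))
  # closed-form hb MLE for exponential survival with terminal cell
  nll <- function(hb) -sum(-diff(c(y, 0)) *
                             log(-diff(c(exp(-hb * yt), 0))))
  hbHat <- optimize(nll, c(0.001, 1))$minimum
  expect_equal(unname(map$par["hb"]), hbHat, tolerance = 0.05)

  expect_error(findMAP(c(-1, 0.1, 3, 20, 10), list(e), config = cfg),
               "no feasible start")
  # deterministic: repeated runs agree exactly and leave the RNG unchanged
  set.seed(77)
  before <- .Random.seed
  map2 <- suppressWarnings(findMAP(start, list(e), config = cfg,
                                   maxfeval = 5000))
  expect_identical(.Random.seed, before)
  expect_identical(map2$par, map$par)
})

test_that("the adaptive sampler is correct on a known bivariate normal", {
  rho <- 0.6
  prec <- solve(matrix(c(1, rho, rho, 1), 2))
  target <- function(p) -0.5 * drop(t(p) %*% prec %*% p)
  post <- runMCMC(c(a = 0.5, b = 0.5), nIter = 30000, nAdapt = 10000,
                  seed = 42, logPost = target)
  draws <- posteriorDraws(post)[10001:30000, ]
  expect_lt(max(abs(colMeans(draws))), 0.08)
  expect_equal(unname(cov(draws)), matrix(c(1, rho, rho, 1), 2),
               tolerance = 0.12)
  expect_gt(acceptanceRate(post), 0.3)
  expect_lt(acceptanceRate(post), 0.5)
})

test_that("posterior draws respect bounds and seeds reproduce exactly", {
  exps <- loadDiazinon()
  cfg <- gutsConfig(N = 100, M = 1000)
  init <- c(hb = 0.055, ke = 0.092, kk = 1.8, mn = 15.6, sd = 6.0)
  p1 <- suppressWarnings(runMCMC(init, exps, config = cfg, nIter = 800,
                                 nAdapt = 400, seed = 7))
  p2 <- suppressWarnings(runMCMC(init, exps, config = cfg, nIter = 800,
                                 nAdapt = 400, seed = 7))
  expect_identical(posteriorDraws(p1), posteriorDraws(p2))
  expect_true(all(is.finite(logPosteriorValues(p1))))
  d <- posteriorDraws(p1)
  expect_true(all(d >= 0))
  expect_true(all(d[, "kk"] <= 30))
  expect_error(runMCMC(c(-1, 0.1, 3, 20, 10), exps, config = cfg,
                       nIter = 10, nAdapt = 5), "infeasible")
})

test_that("posterior summaries have ordered quantiles and correct maxpost", {
  draws <- matrix(rnorm(4000), 1000, 4,
                  dimnames = list(NULL, c("hb", "ke", "mn", "sd")))
  logp <- rowSums(draws)
  post <- new("GutsPosterior", draws = draws, logp = logp,
              acceptanceRate = 0.4, meta = list())
  tab <- summarisePosterior(post, burnIn = 100)
  expect_identical(rownames(tab), c("hb", "ke", "mn", "sd"))
  expect_true(all(tab$q0.025 <= tab$q0.5 & tab$q0.5 <= tab$q0.975))
  expect_equal(unname(unlist(tab["hb", "maxpost"])),
               draws[which.max(logp), "hb"][[1]])
  # identical draws collapse all quantiles
  same <- matrix(rep(c(1, 2), each = 50), 50, 2,
                 dimnames = list(NULL, c("a", "b")))
  postSame <- new("GutsPosterior", draws = same, logp = rep(0, 50),
                  acceptanceRate = 0.4, meta = list())
  tabSame <- summarisePosterior(postSame, burnIn = 10)
  expect_true(all(tabSame$q0.025 == tabSame$q0.975))
  expect_error(summarisePosterior(post, burnIn = 1000), "no draws")
})
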