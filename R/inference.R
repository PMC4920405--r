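#' Default prior bounds
#'
#' Uniform priors with lower bounds 0 for all parameters and no upper bound
#' except for the killing rate \code{kk}, which gets an upper bound of 30
#' l/(day nmol): the \code{kk} posterior has a fat tail, and a bound this
#' large is practically indistinguishable from the individual-tolerance
#' regime \code{kk = Inf}.
#'
#' @param config a \code{\linkS4class{GutsConfig}}.
#' @param kkBound upper prior bound on \code{kk} (default 30).
#' @return list with numeric vectors \code{lower} and \code{upper}, named by
#'   parameter.
#' @export
priorBounds <- function(config = gutsConfig(), kkBound = 30) {
  nm <- paramNames(config)
  lower <- setNames(rep(0, length(nm)), nm)
  upper <- setNames(rep(Inf, length(nm)), nm)
  if ("kk" %in% nm) upper[["kk"]] <- kkBound
  list(lower = lower, upper = upper)
}

#' Log-posterior density (up to a constant)
#'
#' Uniform priors inside \code{bounds} contribute a constant, so inside the
#' bounds the log-posterior equals the total log-likelihood; any NaN,
#' infinite or negative parameter, or one exceeding its upper bound, gives
#' \code{-Inf}.
#'
#' @param params numeric parameter vector.
#' @param experiments list of \code{\linkS4class{GutsExperiment}} objects.
#' @param bounds prior bounds as from \code{\link{priorBounds}}.
#' @param config a \code{\linkS4class{GutsConfig}}.
#' @return a single number (possibly \code{-Inf}).
#' @export
logPosterior <- function(params, experiments, bounds = priorBounds(config),
                         config = gutsConfig()) {
  p <- as.numeric(params)
  if (anyNA(p) || any(is.infinite(p)) || any(p < bounds$lower) ||
      any(p > bounds$upper)) return(-Inf)
  tot <- 0
  for (ex in experiments) {
    tot <- tot + .loglikValue(ex, p, config)
    if (tot == -Inf) break
  }
  tot
}

#' Maximum a-posteriori search (bounded Hooke-Jeeves pattern search)
#'
#' Maximises \code{\link{logPosterior}} with the derivative-free
#' Hooke-Jeeves algorithm (\code{pracma::hooke_jeeves}) inside a box.
#' Deterministic given the start and settings.
#'
#' @param start feasible starting parameter vector; default
#'   \code{c(0.05, 0.1, 3, 20, 10)} restricted to the flavour's parameters.
#' @param experiments list of \code{\linkS4class{GutsExperiment}} objects.
#' @param lower,upper search box; defaults: lower 0, upper
#'   \code{c(1, 1, 30, 40, 20)} restricted to the flavour.
#' @param bounds prior bounds (see \code{\link{priorBounds}}).
#' @param config a \code{\linkS4class{GutsConfig}}.
#' @param maxfeval maximum number of function evaluations.
#' @param seed integer seed fixing the pattern search's randomised
#'   coordinate exploration order, so the search is fully deterministic;
#'   the caller's RNG state is restored afterwards.
#' @return list with \code{par} (named optimum) and \code{value}
#'   (log-posterior at the optimum).
#' @export
findMAP <- function(start = NULL, experiments, lower = NULL, upper = NULL,
                    bounds = priorBounds(config), config = gutsConfig(),
                    maxfeval = 50000L, seed = 1L) {
  nm <- paramNames(config)
  full <- c(hb = 0.05, ke = 0.1, kk = 3, mn = 20, sd = 10)
  fullUp <- c(hb = 1, ke = 1, kk = 30, mn = 40, sd = 20)
  if (is.null(start)) start <- full[nm]
  if (is.null(lower)) lower <- setNames(rep(0, length(nm)), nm)
  if (is.null(upper)) upper <- fullUp[nm]
  start <- .orderParams(start, config)
  if (!is.finite(logPosterior(start, experiments, bounds, config)))
    stop("no feasible start: log-posterior is -Inf at the starting point")
  obj <- function(p) {
    lp <- suppressWarnings(logPosterior(p, experiments, bounds, config))
    if (is.finite(lp)) -lp else 1e10
  }
  # the pattern search randomises its coordinate exploration order; pin it
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  opt <- pracma::hooke_jeeves(as.numeric(start), obj, lb = as.numeric(lower),
                              ub = as.numeric(upper), tol = 1e-8,
                              maxfeval = maxfeval)
  par <- setNames(opt$xmin, nm)
  list(par = par, value = -opt$fmin, feval = opt$count)
}

#' Robust adaptive Metropolis sampling of the parameter posterior
#'
#' Random-walk Metropolis whose proposal covariance factor is adapted
#' (Vihola-style rank-one updates) toward a target acceptance rate during
#' the adaptation phase, then frozen.  The initial proposal covariance is
#' diagonal with standard deviations equal to 10\% of the initial parameter
#' values, plus a small jitter to avoid degeneracy when a component is 0.
#'
#' @param init feasible initial parameter vector (typically the MAP).
#' @param experiments list of \code{\linkS4class{GutsExperiment}} objects.
#' @param bounds prior bounds (see \code{\link{priorBounds}}).
#' @param config a \code{\linkS4class{GutsConfig}}.
#' @param nIter total number of iterations (default 50000).
#' @param nAdapt length of the adaptation phase (default 20000).
#' @param targetAccept target acceptance rate (default 0.4).
#' @param seed integer seed; the run is fully reproducible.
#' @param logPost optional replacement log-density \code{function(p)}
#'   (used by the sampler self-tests on closed-form targets); when given,
#'   \code{experiments}/\code{bounds}/\code{config} are ignored.
#' @return a \code{\linkS4class{GutsPosterior}}.
#' @export
runMCMC <- function(init, experiments = NULL, bounds = priorBounds(config),
                    config = gutsConfig(), nIter = 50000L, nAdapt = 20000L,
                    targetAccept = 0.4, seed = 1L, logPost = NULL) {
  if (is.null(logPost)) {
    init <- .orderParams(init, config)
    logPost <- function(p) logPosterior(p, experiments, bounds, config)
  }
  d <- length(init)
  x <- as.numeric(init)
  lp <- logPost(x)
  if (!is.finite(lp)) stop("infeasible init: log-posterior is -Inf")
  set.seed(seed)
  # lower-triangular proposal factor; 10% of init as std devs, jittered
  S <- diag(sqrt((x / 10)^2 + .Machine$double.eps), d)
  draws <- matrix(NA_real_, nIter, d,
                  dimnames = list(NULL, names(init)))
  logp <- numeric(nIter)
  acc <- logical(nIter)
  gamma <- 2 / 3
  for (i in seq_len(nIter)) {
    u <- rnorm(d)
    prop <- x + as.numeric(S %*% u)
    lpp <- logPost(prop)
    alpha <- if (is.finite(lpp)) min(1, exp(lpp - lp)) else 0
    if (runif(1) < alpha) {
      x <- prop
      lp <- lpp
      acc[i] <- TRUE
    }
    draws[i, ] <- x
    logp[i] <- lp
    if (i <= nAdapt) {
      eta <- min(1, d * i^(-gamma))
      un2 <- sum(u^2)
      if (un2 > 0) {
        Su <- as.numeric(S %*% u)
        Mnew <- tcrossprod(S) + (eta * (alpha - targetAccept) / un2) *
          tcrossprod(Su)
        ch <- tryCatch(t(chol(Mnew)), error = function(e) NULL)
        if (!is.null(ch)) S <- ch
      }
    }
  }
  post <- if (nIter > nAdapt) mean(acc[(nAdapt + 1):nIter]) else mean(acc)
  new("GutsPosterior", draws = draws, logp = logp, acceptanceRate = post,
      meta = list(seed = seed, nIter = nIter, nAdapt = nAdapt,
                  targetAccept = targetAccept, config = config,
                  bounds = bounds, overallAcceptance = mean(acc)))
}

#' Posterior summary table
#'
#' Per parameter: the value at the highest-log-posterior draw
#' (\code{maxpost}) and the empirical 2.5\%, 50\% and 97.5\% quantiles of
#' the post-burn-in chain (unthinned by default; thinning is mainly useful
#' for plotting).
#'
#' @param sample a \code{\linkS4class{GutsPosterior}}.
#' @param burnIn number of initial draws to discard (default 10000).
#' @param thin keep every \code{thin}-th post-burn-in draw (default 1).
#' @return data.frame with one row per parameter and columns
#'   \code{maxpost}, \code{q0.025}, \code{q0.5}, \code{q0.975}.
#' @export
summarisePosterior <- function(sample, burnIn = 10000L, thin = 1L) {
  n <- nrow(sample@draws)
  if (burnIn >= n) stop("burnIn leaves no draws")
  keep <- seq.int(burnIn + 1L, n, by = thin)
  kept <- sample@draws[keep, , drop = FALSE]
  q <- t(apply(kept, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE))
  out <- data.frame(maxpost = sample@draws[which.max(sample@logp), ],
                    q[, 1], q[, 2], q[, 3])
  colnames(out) <- c("maxpost", "q0.025", "q0.5", "q0.975")
  rownames(out) <- colnames(sample@draws)
  out
}
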