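#' Log-uniform threshold grid with lognormal importance weights
#'
#' Deterministic replacement for Monte-Carlo threshold sampling: thresholds
#' are \eqn{z_j = e^{x_j}} with \eqn{x_j} equidistant on
#' \eqn{[\mu - 4\sigma, \mu + 4\sigma]}, where \eqn{\mu = \ln m - \sigma^2/2}
#' and \eqn{\sigma^2 = \ln(1 + s^2/m^2)} are the log-scale parameters of the
#' lognormal distribution with mean \code{mn} and standard deviation
#' \code{sd}.  The log importance weight of each grid point is
#' \eqn{-(\mu - \ln z_j)^2 / (2\sigma^2)} (up to a constant fixed later by
#' normalising the survival vector by its first element).
#'
#' @param mn,sd mean and standard deviation of the threshold distribution
#'   (damage units); both must be positive.
#' @param N number of grid points (at least 2).
#' @return list with \code{z} (increasing thresholds), \code{logw}
#'   (log weights), and the log-scale parameters \code{mulog}, \code{sdlog}.
#' @export
lognormalThresholdGrid <- function(mn, sd, N) {
  if (!is.finite(mn) || !is.finite(sd) || mn <= 0 || sd <= 0)
    stop("mn and sd must be positive for the lognormal threshold grid")
  if (N < 2L) stop("N must be at least 2")
  sigma2 <- log1p(sd^2 / mn^2)
  sigma <- sqrt(sigma2)
  mu <- log(mn) - sigma2 / 2
  x <- (mu - 4 * sigma) + (0:(N - 1L)) * (8 * sigma / (N - 1L))
  list(z = exp(x), logw = -(mu - x)^2 / (2 * sigma2),
       mulog = mu, sdlog = sigma)
}

#' Degenerate (delta) threshold: all individuals share one threshold
#'
#' @param mn the common threshold (damage units), non-negative.
#' @return list with \code{z = mn} and \code{logw = 0} (a single-point grid).
#' @export
deltaThreshold <- function(mn) {
  if (!is.finite(mn) || mn < 0)
    stop("mn must be finite and non-negative for the delta threshold")
  list(z = mn, logw = 0)
}

#' Random threshold sample (plain Monte-Carlo alternative to the grid)
#'
#' Draws \code{N} ordered thresholds from the lognormal distribution with
#' mean \code{mn} and standard deviation \code{sd}; all importance weights
#' are zero.  The deterministic grid of
#' \code{\link{lognormalThresholdGrid}} is the default used by the engine;
#' this sampler exists for cross-checks and for users who prefer plain
#' Monte-Carlo.
#'
#' @inheritParams lognormalThresholdGrid
#' @param seed integer seed for reproducibility.
#' @return list with \code{z}, \code{logw} (all zero), \code{mulog},
#'   \code{sdlog}.
#' @export
sampleThresholds <- function(mn, sd, N, seed = 1L) {
  if (!is.finite(mn) || !is.finite(sd) || mn <= 0 || sd <= 0)
    stop("mn and sd must be positive")
  sigma2 <- log1p(sd^2 / mn^2)
  mu <- log(mn) - sigma2 / 2
  set.seed(seed)
  list(z = sort(rlnorm(N, mu, sqrt(sigma2))), logw = rep(0, N),
       mulog = mu, sdlog = sqrt(sigma2))
}

# internal: survival probabilities as a bare numeric vector plus status;
# assumes arity already checked
.survivalVector <- function(experiment, params, config, thresholds = NULL) {
  p <- .orderParams(params, config)
  if (anyNA(p) || any(!is.finite(p)) || any(p < 0))
    return(list(S = rep(NA_real_, length(experiment@yTime)),
                status = "improper"))
  yt <- experiment@yTime
  if (config@model == "it") {
    if (p[["mn"]] <= 0 || p[["sd"]] <= 0)
      return(list(S = rep(NA_real_, length(yt)), status = "improper"))
    sigma2 <- log1p(p[["sd"]]^2 / p[["mn"]]^2)
    S <- .guts_survival_it(experiment@conc, experiment@concTime, yt,
                           p[["hb"]], p[["ke"]],
                           log(p[["mn"]]) - sigma2 / 2, sqrt(sigma2),
                           config@M)
    return(list(S = S, status = "ok"))
  }
  if (is.null(thresholds)) {
    if (config@dist == "delta") {
      thresholds <- deltaThreshold(p[["mn"]])
    } else {
      if (p[["mn"]] <= 0 || p[["sd"]] <= 0)
        return(list(S = rep(NA_real_, length(yt)), status = "improper"))
      thresholds <- lognormalThresholdGrid(p[["mn"]], p[["sd"]], config@N)
    }
  }
  S <- .guts_survival_proper(experiment@conc, experiment@concTime, yt,
                             p[["hb"]], p[["kk"]], p[["ke"]],
                             thresholds$z, thresholds$logw, config@M)
  list(S = S, status = "ok")
}

#' Population survival probabilities at the observation times
#'
#' Computes \eqn{S_\theta(t_i)}, the probability for a random member of the
#' population to survive until each observation time, for the configured
#' model flavour.  For GUTS Proper and GUTS-SD this uses the fast
#' O(N)+O(M) suffix-sum recursion over the threshold grid; for GUTS-IT,
#' survival is the threshold CDF evaluated at the running damage maximum,
#' times the background-survival factor \eqn{e^{-h_b t}}.
#'
#' @param experiment a \code{\linkS4class{GutsExperiment}}.
#' @param params numeric parameter vector for the flavour (see
#'   \code{\link{paramNames}}); wrong arity is an error, improper values
#'   (negative/NaN/infinite) yield a curve of \code{NA}s with a warning.
#' @param config a \code{\linkS4class{GutsConfig}}.
#' @param thresholds optional explicit threshold set (a list with \code{z}
#'   and \code{logw}, e.g. from \code{\link{sampleThresholds}}); default is
#'   the deterministic importance grid.
#' @return data.frame with columns \code{time} and \code{survival}; the
#'   attribute \code{"status"} is \code{"ok"} or \code{"improper"}.
#' @examples
#' exps <- loadDiazinon()
#' s <- survivalProbabilities(exps[[1]],
#'   c(hb = 0.05, ke = 0.1, kk = 3, mn = 20, sd = 10), gutsConfig())
#' head(s)
#' @export
survivalProbabilities <- function(experiment, params, config = gutsConfig(),
                                  thresholds = NULL) {
  if (checkParameters(params, config) == "wrong_arity")
    stop(sprintf("expected %d parameters (%s) for this flavour, got %d",
                 length(paramNames(config)),
                 paste(paramNames(config), collapse = ", "), length(params)))
  res <- .survivalVector(experiment, params, config, thresholds)
  if (res$status != "ok")
    warning("improper parameter values; survival probabilities set to NA")
  out <- data.frame(time = experiment@yTime, survival = res$S)
  attr(out, "status") <- res$status
  out
}
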