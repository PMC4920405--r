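# Multinomial-kernel log-likelihood of interval death counts.
#
# With survivors y_0 >= y_1 >= ... >= y_n observed at t_0 < ... < t_n and
# survival probabilities S_i = S_theta(t_i), the deaths per observation
# window are multinomial with cell probabilities S_{i-1} - S_i (a terminal
# cell S_n covers survival beyond t_n, with y_{n+1} = 0 and S_{n+1} = 0).
# The theta-independent multinomial coefficient is omitted throughout.

# internal fast path: plain double, -Inf on improper parameters
.loglikValue <- function(experiment, params, config) {
  sv <- .survivalVector(experiment, params, config)
  if (sv$status != "ok") return(-Inf)
  .loglikFromS(sv$S, experiment@y)
}

.loglikFromS <- function(S, y) {
  dS <- pmax(-diff(c(S, 0)), 0)
  deaths <- -diff(c(y, 0))
  pos <- deaths > 0
  if (any(pos & dS <= 1e-300)) return(-Inf)
  sum(deaths[pos] * log(dS[pos]))
}

#' Log-likelihood of one survival experiment
#'
#' Evaluates the multinomial-kernel log-likelihood
#' \eqn{\sum_i (y_{i-1} - y_i) \ln(S_{i-1} - S_i)} (terminal cell included,
#' constant omitted) for one experiment.  Windows with zero deaths
#' contribute 0 even when their probability is 0; a window with deaths but
#' non-positive probability makes the value \code{-Inf}.
#'
#' @inheritParams survivalProbabilities
#' @return list with \code{value} (real or \code{-Inf}), \code{status}
#'   (\code{"ok"} or \code{"improper_params"}) and \code{warnings}
#'   (character).  Wrong parameter arity is a hard error; improper values
#'   give \code{value = -Inf} with \code{status = "improper_params"}.
#' @examples
#' exps <- loadDiazinon()
#' logLikelihood(exps[[1]],
#'   c(hb = 0.05, ke = 0.1, kk = 3, mn = 20, sd = 10), gutsConfig())$value
#' @export
logLikelihood <- function(experiment, params, config = gutsConfig()) {
  if (checkParameters(params, config) == "wrong_arity")
    stop(sprintf("expected %d parameters (%s) for this flavour, got %d",
                 length(paramNames(config)),
                 paste(paramNames(config), collapse = ", "), length(params)))
  sv <- .survivalVector(experiment, params, config)
  if (sv$status != "ok") {
    w <- "improper parameter values; log-likelihood set to -Inf"
    warning(w)
    return(list(value = -Inf, status = "improper_params", warnings = w))
  }
  list(value = .loglikFromS(sv$S, experiment@y), status = "ok",
       warnings = character())
}

#' Total log-likelihood over several experiments
#'
#' Sums \code{\link{logLikelihood}} over independent experiments;
#' \code{-Inf} propagates.
#'
#' @param experiments list of \code{\linkS4class{GutsExperiment}} objects.
#' @inheritParams survivalProbabilities
#' @return as \code{\link{logLikelihood}}.
#' @examples
#' exps <- loadDiazinon()
#' totalLogLikelihood(exps, c(hb = 0.05473022, ke = 0.09215698,
#'   kk = 1.80652237, mn = 15.63446045, sd = 6.01160431), gutsConfig())$value
#' @export
totalLogLikelihood <- function(experiments, params, config = gutsConfig()) {
  if (!length(experiments)) stop("at least one experiment is required")
  parts <- lapply(experiments, logLikelihood, params = params,
                  config = config)
  list(value = sum(vapply(parts, `[[`, 0, "value")),
       status = if (any(vapply(parts, `[[`, "", "status") !=
                       "ok")) "improper_params" else "ok",
       warnings = unique(unlist(lapply(parts, `[[`, "warnings"))))
}
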