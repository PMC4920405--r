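#' @useDynLib gutsBayes, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats dlnorm plnorm qlnorm quantile rexp rlnorm rmultinom rnorm runif integrate setNames
#' @importFrom utils read.csv write.csv head
NULL

#' Survival experiment: exposure and survivor-count time series
#'
#' A \code{GutsExperiment} couples one measured exposure time series
#' (concentration vs. time, linearly interpolated between measurements) with
#' one survivor-count time series observed on the same time origin.  It is
#' the basic data unit for threshold-hazard (GUTS) survival modelling.
#'
#' @slot conc numeric, non-negative exposure concentrations (e.g. nmol/l).
#' @slot concTime numeric, strictly increasing measurement times (days),
#'   starting at 0.
#' @slot y numeric, non-increasing survivor counts; \code{y[1]} is the number
#'   of individuals at the start.
#' @slot yTime numeric, strictly increasing observation times (days),
#'   starting at 0.
#' @slot label character, free-text identifier.
#'
#' @details Observation times may extend beyond the last exposure
#'   measurement; the exposure is then extrapolated as constant at the last
#'   measured concentration.
#' @export
setClass("GutsExperiment",
  representation(conc = "numeric", concTime = "numeric",
                 y = "numeric", yTime = "numeric", label = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@conc) != length(object@concTime))
      msg <- c(msg, "conc and concTime must have equal length")
    if (length(object@y) != length(object@yTime))
      msg <- c(msg, "y and yTime must have equal length")
    if (length(object@conc) < 2L)
      msg <- c(msg, "at least two exposure time points are required")
    if (length(object@y) < 2L)
      msg <- c(msg, "at least two survivor observations are required")
    if (anyNA(object@conc) || anyNA(object@concTime) ||
        anyNA(object@y) || anyNA(object@yTime))
      msg <- c(msg, "missing values are not allowed")
    else {
      if (any(object@conc < 0))
        msg <- c(msg, "concentrations must be non-negative")
      if (length(object@concTime) && object@concTime[1] != 0)
        msg <- c(msg, "exposure times must start at 0")
      if (is.unsorted(object@concTime, strictly = TRUE))
        msg <- c(msg, "exposure times must be strictly increasing")
      if (length(object@yTime) && object@yTime[1] != 0)
        msg <- c(msg, "observation times must start at 0")
      if (is.unsorted(object@yTime, strictly = TRUE))
        msg <- c(msg, "observation times must be strictly increasing")
      if (any(diff(object@y) > 0))
        msg <- c(msg, "survivor counts must be non-increasing")
      if (any(object@y < 0) || any(object@y != round(object@y)))
        msg <- c(msg, "survivor counts must be non-negative integers")
      if (length(object@y) && object@y[1] < 1)
        msg <- c(msg, "the initial survivor count must be at least 1")
    }
    if (length(msg)) msg else TRUE
  })

#' Model configuration: flavour and discretisation sizes
#'
#' Selects the model flavour -- the threshold distribution (\code{lognormal}
#' or \code{delta}) crossed with the death mechanism (\code{proper} or
#' \code{it}) -- together with the two discretisation sizes: \code{N}
#' threshold grid points and \code{M} time grid points.
#'
#' The three canonical flavours are: GUTS Proper
#' (\code{lognormal}/\code{proper}, 5 parameters), GUTS-SD
#' (\code{delta}/\code{proper}, 4 parameters, no \code{sd}) and GUTS-IT
#' (\code{lognormal}/\code{it}, 4 parameters, no \code{kk}).
#'
#' @slot dist character, \code{"lognormal"} or \code{"delta"}.
#' @slot model character, \code{"proper"} or \code{"it"}.
#' @slot N integer, threshold grid size (default 1000).
#' @slot M integer, time grid size (default 10000).
#' @export
setClass("GutsConfig",
  representation(dist = "character", model = "character",
                 N = "integer", M = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@dist %in% c("lognormal", "delta"))
      msg <- c(msg, "dist must be 'lognormal' or 'delta'")
    if (!object@model %in% c("proper", "it"))
      msg <- c(msg, "model must be 'proper' or 'it'")
    if (object@dist == "delta" && object@model == "it")
      msg <- c(msg, "the delta distribution requires model 'proper' (GUTS-SD)")
    if (object@N < 1L) msg <- c(msg, "N must be a positive integer")
    if (object@M < 1L) msg <- c(msg, "M must be a positive integer")
    if (length(msg)) msg else TRUE
  })

#' Posterior sample from the adaptive Metropolis sampler
#'
#' @slot draws numeric matrix, one row per iteration, one column per
#'   parameter (named).
#' @slot logp numeric, log-posterior value of each draw.
#' @slot acceptanceRate numeric, realised acceptance fraction after the
#'   adaptation phase.
#' @slot meta list with the run settings (seed, n_adapt, target acceptance,
#'   the \code{GutsConfig} used, prior bounds).
#' @export
setClass("GutsPosterior",
  representation(draws = "matrix", logp = "numeric",
                 acceptanceRate = "numeric", meta = "list"),
  validity = function(object) {
    if (nrow(object@draws) != length(object@logp))
      "draws and logp must have matching length" else TRUE
  })

#' Construct a validated survival experiment
#'
#' @param conc non-negative exposure concentrations.
#' @param concTime strictly increasing exposure measurement times, first 0.
#' @param counts non-increasing survivor counts.
#' @param countTime strictly increasing observation times, first 0.
#' @param label free-text identifier.
#' @return A \code{\linkS4class{GutsExperiment}}.
#' @examples
#' gutsExperiment(c(10, 0), c(0, 2), c(20, 18, 15), c(0, 1, 2))
#' @export
gutsExperiment <- function(conc, concTime, counts, countTime, label = "") {
  new("GutsExperiment", conc = as.numeric(conc),
      concTime = as.numeric(concTime), y = as.numeric(counts),
      yTime = as.numeric(countTime), label = as.character(label))
}

#' Construct a model configuration
#'
#' @param dist threshold distribution, \code{"lognormal"} (default) or
#'   \code{"delta"}.
#' @param model death mechanism, \code{"proper"} (default) or \code{"it"}.
#' @param N threshold grid size, default 1000.
#' @param M time grid size, default 10000.
#' @return A \code{\linkS4class{GutsConfig}}.
#' @examples
#' gutsConfig()                      # GUTS Proper
#' gutsConfig(dist = "delta")        # GUTS-SD
#' gutsConfig(model = "it")          # GUTS-IT
#' @export
gutsConfig <- function(dist = c("lognormal", "delta"),
                       model = c("proper", "it"),
                       N = 1000L, M = 10000L) {
  dist <- match.arg(tolower(dist[1]), c("lognormal", "delta"))
  model <- match.arg(tolower(model[1]), c("proper", "it"))
  new("GutsConfig", dist = dist, model = model,
      N = as.integer(N), M = as.integer(M))
}

#' @describeIn gutsExperiment Exposure concentrations.
#' @param x a \code{GutsExperiment}.
#' @export
concentrations <- function(x) x@conc

#' @describeIn gutsExperiment Exposure measurement times.
#' @export
exposureTimes <- function(x) x@concTime

#' @describeIn gutsExperiment Survivor counts.
#' @export
survivors <- function(x) x@y

#' @describeIn gutsExperiment Survivor observation times.
#' @export
obsTimes <- function(x) x@yTime

#' Posterior draws matrix
#' @param x a \code{GutsPosterior}.
#' @return numeric matrix of draws (iterations x parameters).
#' @export
posteriorDraws <- function(x) x@draws

#' Log-posterior values of the stored draws
#' @param x a \code{GutsPosterior}.
#' @export
logPosteriorValues <- function(x) x@logp

#' Realised acceptance rate (after adaptation)
#' @param x a \code{GutsPosterior}.
#' @export
acceptanceRate <- function(x) x@acceptanceRate

setMethod("show", "GutsExperiment", function(object) {
  cat("GutsExperiment", if (nzchar(object@label))
    paste0("'", object@label, "'") else "", "\n")
  cat("  exposure: ", length(object@conc), " measurements on [0, ",
      max(object@concTime), "] days, peak ", max(object@conc), "\n", sep = "")
  cat("  survival: ", object@y[1], " -> ", object@y[length(object@y)],
      " individuals over ", length(object@y) - 1L, " observation windows\n",
      sep = "")
})

setMethod("show", "GutsConfig", function(object) {
  flavour <- if (object@dist == "delta") "GUTS-SD"
  else if (object@model == "it") "GUTS-IT" else "GUTS Proper"
  cat("GutsConfig:", flavour,
      sprintf("(dist = %s, model = %s, N = %d, M = %d)\n",
              object@dist, object@model, object@N, object@M))
})

setMethod("show", "GutsPosterior", function(object) {
  cat("GutsPosterior:", nrow(object@draws), "draws of",
      ncol(object@draws), "parameters\n")
  cat("  acceptance rate (post-adaptation):",
      round(object@acceptanceRate, 3), "\n")
  cat("  best log-posterior:", max(object@logp), "\n")
})
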