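# Posterior predictive death counts per observation window.
#
# One retained parameter draw -> one survival curve -> one multinomial draw
# of per-window deaths (n0 trials, cell probabilities S_{i-1} - S_i plus a
# terminal beyond-t_n cell), so the predictive spread blends parametric and
# demographic stochasticity.

.predictDeathsMatrix <- function(scenario, posterior, burnIn, nDraws, seed) {
  n <- nrow(posterior@draws)
  if (burnIn >= n) stop("burnIn leaves no posterior draws")
  n0 <- scenario@y[1]
  if (n0 < 1) stop("the initial count n0 must be at least 1")
  config <- posterior@meta$config
  if (is.null(config)) config <- gutsConfig()
  set.seed(seed)
  idx <- sample.int(n - burnIn, nDraws, replace = TRUE) + burnIn
  nw <- length(scenario@yTime) - 1L
  deaths <- matrix(NA_real_, nDraws, nw)
  for (k in seq_len(nDraws)) {
    sv <- .survivalVector(scenario, posterior@draws[idx[k], ], config)
    p <- pmax(-diff(c(sv$S, 0)), 0)  # n windows + terminal cell
    stopifnot(length(p) == nw + 1L)
    deaths[k, ] <- rmultinom(1, n0, p)[seq_len(nw)]
  }
  deaths
}

.quantileTable <- function(deaths) {
  q <- t(apply(deaths, 2, quantile, probs = c(0.025, 0.5, 0.975),
               names = FALSE))
  out <- data.frame(ytd = seq_len(nrow(q)), q[, 1], q[, 2], q[, 3])
  colnames(out) <- c("ytd", "q0.025", "q0.5", "q0.975")
  out
}

#' Posterior predictive deaths per observation window
#'
#' For a new exposure scenario (exposure series, prediction time points and
#' an initial count \code{n0 = survivors(scenario)[1]}; any remaining counts
#' are ignored), draws per-window death counts from the posterior
#' predictive distribution and tabulates their empirical quantiles.  The
#' terminal beyond-\code{t_n} cell is sampled but not reported.
#'
#' @param scenario a \code{\linkS4class{GutsExperiment}} holding the new
#'   exposure, the prediction times and the initial count.
#' @param posterior a \code{\linkS4class{GutsPosterior}} from
#'   \code{\link{runMCMC}}.
#' @param burnIn posterior draws to discard (default 10000).
#' @param nDraws number of predictive draws (default 4000).
#' @param seed integer seed.
#' @return data.frame with columns \code{ytd} (window index 1..n),
#'   \code{q0.025}, \code{q0.5}, \code{q0.975}.
#' @export
predictDeaths <- function(scenario, posterior, burnIn = 10000L,
                          nDraws = 4000L, seed = 1L) {
  .quantileTable(.predictDeathsMatrix(scenario, posterior, burnIn, nDraws,
                                      seed))
}

#' Validate posterior predictions against measured survivors
#'
#' As \code{\link{predictDeaths}}, but the scenario's survivor counts are
#' real observations: the table gains a \code{measured} column (per-window
#' measured deaths \eqn{y_{i-1} - y_i}) and a coverage summary reports the
#' fraction of windows whose measured deaths fall inside the central 95\%
#' predictive interval.
#'
#' @inheritParams predictDeaths
#' @return list with \code{table} (columns \code{ytd}, \code{measured},
#'   \code{q0.025}, \code{q0.5}, \code{q0.975}) and \code{coverage}.
#' @export
validatePredictions <- function(scenario, posterior, burnIn = 10000L,
                                nDraws = 4000L, seed = 1L) {
  tab <- .quantileTable(.predictDeathsMatrix(scenario, posterior, burnIn,
                                             nDraws, seed))
  measured <- -diff(scenario@y)
  tab <- data.frame(ytd = tab$ytd, measured = measured, tab[, -1],
                    check.names = FALSE)
  list(table = tab,
       coverage = mean(measured >= tab$q0.025 & measured <= tab$q0.975))
}

#' Write a result table as CSV
#'
#' Serialises a posterior summary (\code{\link{summarisePosterior}}) or
#' prediction table (\code{\link{predictDeaths}}) with a header row, as
#' \code{write.csv} would.
#'
#' @param table a data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(table, path) {
  write.csv(table, path, row.names = !is.null(rownames(table)) &&
              !identical(rownames(table), as.character(seq_len(nrow(table)))))
  invisible(path)
}
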