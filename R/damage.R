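#' Refined time grid for the hazard integral
#'
#' Refines the span of the observation times \code{t_0 = 0 < ... < t_n} to an
#' equidistant grid of \code{M} points \code{tau_l = l * t_n / M},
#' \code{l = 0, ..., M-1}, covering \code{[0, t_n)}.
#'
#' @param survivalTimes strictly increasing observation times, first 0.
#' @param M number of grid points; must be at least the number of
#'   observation intervals.
#' @return list with \code{tau} (grid times), \code{dtau} (spacing) and
#'   \code{cut}: for each observation time, the number of grid points
#'   strictly before it (the index delimiting the damage values that enter
#'   the hazard integral up to that time).
#' @export
refineTimeGrid <- function(survivalTimes, M) {
  n <- length(survivalTimes) - 1L
  if (M < n) stop("M must be at least the number of observation intervals")
  tn <- survivalTimes[length(survivalTimes)]
  dtau <- tn / M
  list(tau = (0:(M - 1L)) * dtau, dtau = dtau,
       cut = pmin(M, ceiling(survivalTimes / dtau - 1e-9)))
}

#' Damage trajectory on a refined time grid
#'
#' Solves the damage kinetics \eqn{dD/dt = k_e (C(t) - D)}, with
#' \eqn{D(0) = 0} and \eqn{C(t)} linearly interpolated between measured
#' concentrations, exactly (closed form per exposure segment) at every grid
#' point.  Beyond the last exposure measurement, \eqn{C(t)} is held constant
#' at the last measured value.
#'
#' @param experiment a \code{\linkS4class{GutsExperiment}} (its exposure
#'   series is used).
#' @param ke dominant rate constant (1/day), non-negative.
#' @param grid a grid as returned by \code{\link{refineTimeGrid}}, or a
#'   single integer \code{M} (the grid is then built from the experiment's
#'   observation times).
#' @return list with \code{tau}, \code{D} (damage at each grid point) and
#'   \code{dtau}.
#' @examples
#' e <- gutsExperiment(c(100, 100), c(0, 10), c(10, 10), c(0, 10))
#' d <- damageOnGrid(e, ke = 0.1, grid = 1000)
#' max(d$D)  # approaches 100 * (1 - exp(-1))
#' @export
damageOnGrid <- function(experiment, ke, grid) {
  if (!is.finite(ke) || ke < 0) stop("ke must be finite and non-negative")
  if (is.numeric(grid) && length(grid) == 1L)
    grid <- refineTimeGrid(experiment@yTime, as.integer(grid))
  tn <- grid$dtau * length(grid$tau)
  D <- .guts_damage_grid(experiment@conc, experiment@concTime, ke, tn,
                         length(grid$tau))
  list(tau = grid$tau, D = D, dtau = grid$dtau)
}

#' Exact damage at arbitrary times
#'
#' Closed-form damage \eqn{D(t)} for piecewise-linear exposure, evaluated at
#' sorted times \code{t} (used by the quadrature oracle and the
#' individual-tolerance model's exact-at-observation correction).
#'
#' @param conc,concTime exposure series (as in
#'   \code{\link{gutsExperiment}}).
#' @param ke dominant rate constant (1/day).
#' @param t sorted, non-negative query times.
#' @return numeric vector of damage values.
#' @export
damageAt <- function(conc, concTime, ke, t) {
  if (!is.finite(ke) || ke < 0) stop("ke must be finite and non-negative")
  if (is.unsorted(t)) stop("query times must be sorted")
  .guts_damage_at(as.numeric(conc), as.numeric(concTime), ke, as.numeric(t))
}
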