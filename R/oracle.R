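# Slow, independent reference implementations used for testing: a 2-D
# quadrature of the survival integral, the literal O(N*M) double sum, and an
# individual-level forward simulator.  None of these share code with the
# fast engine beyond the closed-form damage evaluator.

#' Brute-force survival probability by nested quadrature
#'
#' Directly integrates
#' \eqn{S_\theta(t) = \int \exp[-k_k \int_0^t \max(D(\tau)-z, 0) d\tau
#' - h_b t] f_\theta(z) dz}
#' with adaptive quadrature over \eqn{\tau} (inner) nested inside adaptive
#' quadrature over \eqn{z} against the lognormal threshold density (outer).
#' Thousands of times slower than the engine; used as an accuracy oracle.
#'
#' @param conc,concTime exposure series.
#' @param params named parameter vector \code{(hb, ke, kk, mn, sd)} (for a
#'   delta threshold, \code{(hb, ke, kk, mn)}).
#' @param t single time at which to evaluate survival.
#' @param config a \code{\linkS4class{GutsConfig}} (its \code{dist} selects
#'   the threshold distribution; \code{N}/\code{M} are not used).
#' @return survival probability (scalar), accurate to about 1e-6.
#' @export
bruteForceSurvival <- function(conc, concTime, params, t,
                               config = gutsConfig()) {
  p <- .orderParams(params, config)
  if (any(!is.finite(p)) || any(p < 0)) stop("improper parameters")
  if (t == 0) return(1)
  # dense scan to bracket the (possibly narrow) regions where D > z; the
  # excess is zero outside them and a blind adaptive rule can miss them
  scanT <- seq(0, t, length.out = 8192L)
  scanD <- damageAt(conc, concTime, p[["ke"]], scanT)
  hazardIntegral <- function(z) {
    if (z >= max(scanD)) return(0)
    over <- scanD > z
    runs <- rle(over)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    tot <- 0
    for (r in which(runs$values)) {
      lo <- scanT[max(1L, starts[r] - 1L)]
      hi <- scanT[min(length(scanT), ends[r] + 1L)]
      fEx <- function(tau) {
        ord <- order(tau)  # integrate() evaluates at unsorted abscissae
        D <- numeric(length(tau))
        D[ord] <- damageAt(conc, concTime, p[["ke"]], tau[ord])
        pmax(D - z, 0)
      }
      iv <- integrate(fEx, lo, hi, subdivisions = 1000L, rel.tol = 1e-9,
                      abs.tol = 1e-12, stop.on.error = FALSE)
      tot <- tot +
        if (iv$message %in% c("OK", "roundoff error was detected")) {
          iv$value
        } else {
          # very narrow excess region: adaptive rule balks; composite
          # Simpson on a dense local grid is ample at this width
          tt <- seq(lo, hi, length.out = 2001L)
          h <- tt[2] - tt[1]
          v <- fEx(tt)
          h / 3 * sum(v * c(1, rep(c(4, 2), 999), 4, 1))
        }
    }
    tot
  }
  if (config@dist == "delta")
    return(exp(-p[["kk"]] * hazardIntegral(p[["mn"]]) - p[["hb"]] * t))
  sigma2 <- log1p(p[["sd"]]^2 / p[["mn"]]^2)
  mu <- log(p[["mn"]]) - sigma2 / 2
  sig <- sqrt(sigma2)
  # refine the damage maximum locally (the scan grid slightly undershoots)
  iMax <- which.max(scanD)
  win <- scanT[c(max(1L, iMax - 1L), min(length(scanT), iMax + 1L))]
  Dmax <- max(damageAt(conc, concTime, p[["ke"]],
                       seq(win[1], win[2], length.out = 2001L)))
  # thresholds above Dmax are never exceeded: analytic tail contribution;
  # below, the exponential factor varies smoothly on (0, Dmax]
  tailMass <- plnorm(Dmax, mu, sig, lower.tail = FALSE)
  integrand <- function(z) {
    vapply(z, function(zz) {
      exp(-p[["kk"]] * hazardIntegral(zz)) * dlnorm(zz, mu, sig)
    }, 0)
  }
  lo <- qlnorm(1e-13, mu, sig)
  core <- 0
  if (Dmax > lo) {
    iv <- integrate(integrand, lo, Dmax, subdivisions = 1000L,
                    rel.tol = 1e-8, abs.tol = 1e-12,
                    stop.on.error = FALSE)
    if (!iv$message %in% c("OK", "roundoff error was detected"))
      stop("outer quadrature failed: ", iv$message)
    core <- iv$value
  }
  exp(-p[["hb"]] * t) * (core + tailMass)
}

#' Literal O(N*M) double-sum survival probabilities
#'
#' Evaluates the discretised survival approximation by the naive double
#' loop over threshold grid points and damage grid points, with explicitly
#' supplied grids and weights -- an algebraic identity check for the fast
#' suffix-sum recursion, which must agree to floating-point accumulation
#' accuracy when fed the same grids.
#'
#' @param conc,concTime exposure series.
#' @param hb,ke,kk scalar parameters.
#' @param tPoints observation times (first 0).
#' @param z,logw explicit threshold grid and log importance weights.
#' @param M time-grid size.
#' @return numeric vector of survival probabilities at \code{tPoints},
#'   normalised by the first unnormalised element.
#' @export
naiveSurvivalSum <- function(conc, concTime, hb, ke, kk, tPoints, z, logw,
                             M) {
  grid <- refineTimeGrid(tPoints, M)
  D <- damageAt(conc, concTime, ke, grid$tau)
  unnorm <- vapply(seq_along(tPoints), function(i) {
    Di <- D[seq_len(grid$cut[i])]
    sum(vapply(seq_along(z), function(j) {
      excess <- Di[Di > z[j]] - z[j]
      exp(-kk * grid$dtau * sum(excess) + logw[j])
    }, 0))
  }, 0)
  exp(-hb * tPoints) * unnorm / unnorm[1]
}

#' Individual-level forward simulation of a survival experiment
#'
#' Simulates each of \code{n0} individuals: a threshold \code{z} is drawn
#' from the configured distribution, the cumulative hazard
#' \eqn{H(t) = k_k \int_0^t \max(D-z, 0) d\tau + h_b t} is accumulated on a
#' fine grid, and the death time is found by inverting \eqn{H} at a
#' standard-exponential variate (linear interpolation between grid points).
#' Under the individual-tolerance flavour the toxic death is instead the
#' first threshold crossing.  Deaths are binned into the observation
#' windows.
#'
#' @param conc,concTime exposure series.
#' @param obsTimes observation times (first 0).
#' @param params parameter vector for the flavour.
#' @param config a \code{\linkS4class{GutsConfig}}; \code{M} sets the
#'   simulation grid size.
#' @param n0 number of individuals.
#' @param seed integer seed.
#' @return a \code{\linkS4class{GutsExperiment}} with simulated counts.
#' @export
simulateSurvival <- function(conc, concTime, obsTimes, params,
                             config = gutsConfig(), n0 = 70L, seed = 1L) {
  p <- .orderParams(params, config)
  if (checkParameters(p, config) != "proper") stop("improper parameters")
  tn <- obsTimes[length(obsTimes)]
  M <- config@M
  dtau <- tn / M
  tau <- (0:(M - 1L)) * dtau
  D <- damageAt(conc, concTime, p[["ke"]], tau)
  set.seed(seed)
  z <- if (config@dist == "delta") rep(p[["mn"]], n0)
  else {
    sigma2 <- log1p(p[["sd"]]^2 / p[["mn"]]^2)
    rlnorm(n0, log(p[["mn"]]) - sigma2 / 2, sqrt(sigma2))
  }
  hb <- p[["hb"]]
  deathTime <- rep(Inf, n0)
  if (config@model == "it") {
    runmax <- cummax(D)
    bg <- if (hb > 0) rexp(n0) / hb else rep(Inf, n0)
    for (i in seq_len(n0)) {
      cross <- which(runmax > z[i])[1]
      tox <- if (is.na(cross)) Inf else tau[cross]
      deathTime[i] <- min(tox, bg[i])
    }
  } else {
    kk <- p[["kk"]]
    E <- rexp(n0)
    chunk <- 512L
    for (s in seq(1L, n0, by = chunk)) {
      ii <- s:min(s + chunk - 1L, n0)
      # cumulative hazard rows: individuals, cols: grid times
      excess <- pmax(outer(z[ii], D, function(zz, dd) dd - zz), 0)
      # trapezoid-rule cumulative hazard (right-endpoint cumsum minus half
      # the end contributions): bias O(dtau^2) instead of O(dtau)
      cumEx <- t(apply(excess, 1, cumsum))
      cumEx <- cumEx - (excess + excess[, 1]) / 2
      H <- kk * dtau * cumEx +
        matrix(hb * tau, length(ii), M, byrow = TRUE)
      for (r in seq_along(ii)) {
        jj <- which(H[r, ] >= E[ii[r]])[1]
        if (is.na(jj)) next
        if (jj == 1L) { deathTime[ii[r]] <- 0; next }
        h0 <- H[r, jj - 1L]; h1 <- H[r, jj]
        frac <- if (h1 > h0) (E[ii[r]] - h0) / (h1 - h0) else 0
        deathTime[ii[r]] <- tau[jj - 1L] + frac * dtau
      }
    }
  }
  counts <- vapply(obsTimes, function(t) sum(deathTime > t), 0)
  gutsExperiment(conc, concTime, counts, obsTimes,
                 label = sprintf("simulated (seed %d)", seed))
}
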