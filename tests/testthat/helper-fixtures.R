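# shared fixtures built in code

mapParams <- c(hb = 0.05473022, ke = 0.09215698, kk = 1.80652237,
               mn = 15.63446045, sd = 6.01160431)

# a random pulsed-exposure experiment with a valid (non-increasing) count
# series; used by property-style tests
randomInstance <- function(nSeg = 4, nObs = 5, n0 = 20) {
  Ct <- c(0, sort(runif(nSeg - 1, 0.5, 8)))
  C <- runif(nSeg, 0, 120)
  yt <- c(0, sort(runif(nObs - 1, 0.5, 10)))
  y <- pmax(n0 - cumsum(c(0, sample(0:3, nObs - 1, replace = TRUE))), 0)
  list(exp = gutsExperiment(C, Ct, y, yt),
       params = c(hb = runif(1, 0, 0.1), ke = runif(1, 0.05, 0.5),
                  kk = runif(1, 0.5, 5), mn = runif(1, 5, 30),
                  sd = runif(1, 2, 10)))
}
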