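## shared fixtures: the default partition and small plates, plus a
## uniform-over-disk sampler used as the Monte Carlo occupancy oracle

defaultGeom <- computeAreaPartition()

sampleDisk <- function(n, radius = 1, center = c(0, 0)) {
  th <- runif(n, 0, 2 * pi)
  rr <- radius * sqrt(runif(n))
  cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
}

## exact area fraction between two chords of the unit disk by numerical
## integration of the half-width 2*sqrt(1-x^2) (independent of the
## closed-form segment area used by the solver)
integratedFraction <- function(lo, hi) {
  stats::integrate(function(x) 2 * sqrt(1 - x^2), lo, hi,
                   rel.tol = 1e-12)$value / pi
}
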