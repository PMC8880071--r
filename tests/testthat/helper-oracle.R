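# Independent brute-force oracle for the implicit flux equation: progressive
# grid scan for the sign change of the residual
#   f(Jv) = Jv - Lp(T) * (dP - sigma * R * T * (Cf - Cp) * exp(Jv / k)),
# which is strictly increasing in Jv.  The interval is narrowed by scanning
# 1000 subintervals at a time until the final pass runs at the requested
# step, so the returned value is within `step` of the root.  Shares no code
# with the package's Newton solver.
grid_scan_flux <- function(lp0, dh_over_r, sigma, k, tmp, temperature,
                           c_feed, c_permeate, t_ref = 293.15,
                           step = 1e-6) {
  lp <- lp0 * exp(-dh_over_r * (1 / temperature - 1 / t_ref))
  osm <- sigma * 0.083145 * temperature * (c_feed - c_permeate)
  f <- function(j) j - lp * (tmp - osm * exp(j / k))
  lo <- 0
  hi <- lp * tmp
  repeat {
    js <- seq(lo, hi, length.out = 1001L)
    i <- which(f(js) >= 0)[1]
    lo <- js[max(1L, i - 1L)]
    hi <- js[i]
    if (hi - lo <= step * 1000) break
  }
  js <- seq(lo, hi, by = step)
  js[which(f(js) >= 0)[1]]
}

# Random physically plausible SKM parameter set + operating state.
random_skm_case <- function() {
  list(lp0 = runif(1, 0.5, 10), dh_over_r = runif(1, 0, 5000),
       sigma = runif(1, 0.5, 1), k = runif(1, 2, 40),
       tmp = runif(1, 2, 20), temperature = runif(1, 288, 313),
       c_feed = runif(1, 1e-3, 3e-2))
}
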