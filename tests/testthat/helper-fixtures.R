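# shared fixtures built in code

# championship 400 m and mile performances used as the worked two-trial example
coe_trials <- function() {
  list(short = run_trial(duration = 47.05, distance = 400),
       long = run_trial(duration = 227.33, distance = 1609))
}

# independent 2x2 linear-solve oracle for the two-trial calibration
two_trial_oracle <- function(t1, v1, t2, v2, c = 0.0185) {
  A <- rbind(c(1, t1), c(1, t2))
  y <- c(v1 * (1 + c * t1), v2 * (1 + c * t2))
  sol <- solve(A, y)
  list(MAnS = sol[1], b = sol[2])
}

# random strictly-decreasing speed parameters (canonical b = c * MAS)
random_params <- function(c = 0.0185) {
  MAnS <- runif(1, 6, 12)
  MAS <- runif(1, 2, 0.8 * MAnS)
  reri_params(MAnS, b = c * MAS, c = c)
}

# bisection oracle for the race-time inversion, independent of the quadratic
invert_oracle <- function(params, d, lo = 1e-6, hi = 1e7) {
  f <- function(t) speed_at(params, t) * t - d
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}
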