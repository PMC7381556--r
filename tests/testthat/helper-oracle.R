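# Independent oracle for the clearance-rate closed form: numerically
# integrate dF/dt = -(f/V) F forward and root-find the f that reproduces the
# observed end-of-assay fluorescence. Never calls the package's estimator.
ode_feeding_rate <- function(F0, Ft, V, t, interval = c(-20, 20)) {
  integrate_Ft <- function(f) {
    out <- deSolve::ode(y = c(F = F0), times = c(0, t),
                        func = function(time, state, parms) {
                          list(-parms$f / parms$V * state)
                        },
                        parms = list(f = f, V = V),
                        method = "lsoda", rtol = 1e-12, atol = 1e-12)
    out[nrow(out), "F"]
  }
  stats::uniroot(function(f) integrate_Ft(f) - Ft, interval = interval,
                 tol = 1e-12)$root
}
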