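# shared fixtures for the test suite (all built in code)

# water at 25 C, used by the frozen film-model oracle values
water25 <- qcmd_constants(eta_l = 8.9e-4, rho_l = 0.997)

# a small synthetic trace with a known constant offset and simple shapes;
# not physical, just structurally valid
make_toy_trace <- function(n = 200, dt = 0.02, offset = 0, seed = 42) {
  set.seed(seed)
  tm <- seq(-1, by = dt, length.out = n)
  f <- matrix(offset + rnorm(2 * n, sd = 0.05), ncol = 2)
  d <- matrix(abs(rnorm(2 * n, sd = 0.02)), ncol = 2)
  qcmd_trace(tm, f, d, overtones = c(3, 7),
             annotations = c(lipid_start = 0))
}

# noise-free preset traces are reused across several files; cache them
preset_clean <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]]))
      cache[[name]] <<- baseline_correct(simulate_trace(name, noise = FALSE))
    cache[[name]]
  }
})

preset_noisy <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]]))
      cache[[name]] <<- baseline_correct(simulate_trace(name))
    cache[[name]]
  }
})
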