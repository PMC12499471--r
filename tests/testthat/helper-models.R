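# Shared fixtures: a droplet-scale assay setup (cooling at 6 C/min) with an
# illustrative power-law rate, all built in code.
droplet_model <- function() rate_model(gamma = 1e-3, n = 8)
droplet_protocol <- function() protocol(k = 0.1, S = 1e-5)

# Weibull scale of the ramp supercooling distribution, computed independently
# of the package internals.
weib_scale <- function(model, prot) {
  s <- model$n + 1
  (prot$k * s / (prot$S * model$gamma))^(1 / s)
}

# central-difference gradient for delta-method checks
numeric_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
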