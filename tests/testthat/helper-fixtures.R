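# shared fixtures: all synthetic, built in code

# log-uniform random parameter draws in an explicit-Euler-stable range
draw_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kinetic_parameters(
      k_a = 10^runif(1, 4, 6.5),          # M^-1 h^-1
      ag_total = 10^runif(1, -0.3, 0.5),  # ~0.5-3 uM
      k_int = 10^runif(1, -2, 0),
      k_efflux = 10^runif(1, -2, 0)
    )
  })
}

# canonical biexponential plasma shape used across tests
test_plasma_cfg <- list(A1 = 18, alpha = 0.35, A2 = 12, beta = 0.00912)

test_input_pidg <- function() biexponential_input(test_plasma_cfg)

test_input_uM <- function(injection) {
  f <- test_input_pidg()
  input_function(function(t) pidg_to_molar(f(t), injection), unit = "uM")
}

constant_input_uM <- function(value) {
  input_function(function(t) rep(value, length(t)), unit = "uM")
}
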