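# Shared fixtures and independent oracles. Everything here is computed from
# first principles, never by calling the code paths under test.

wt_params <- function(kinact = 0.0011) {
  kinetic_params(Km = 3.69, kcat = 4.25, kinact = kinact, label = "wt-like")
}

wt_cond <- function(E0 = 1.7, S0 = 40) reaction_conditions(E0 = E0, S0 = S0)

# Closed-form product curve when substrate is effectively constant at S0:
# the active-enzyme ODE becomes linear, Ea(t) = E0 exp(-kinact f t) with
# f = S0/(Km+S0), and integrating the rate gives
# P(t) = (kcat/kinact) E0_mM (1 - exp(-kinact f t)).
closed_form_P <- function(params, cond, t_min) {
  f <- cond$S0 / (params$Km + cond$S0)
  t_s <- t_min * 60
  (params$kcat / params$kinact) * (cond$E0 / 1000) *
    (1 - exp(-params$kinact * f * t_s))
}

# Brute-force zero-intercept polynomial least squares via explicit normal
# equations (X'X) b = X'y.
normal_eq_poly <- function(t, p, degree) {
  X <- outer(t, seq_len(degree), `^`)
  solve(t(X) %*% X, t(X) %*% p)[, 1]
}

template_fasta <- function() {
  system.file("extdata", "bsadc_template_synthetic.fasta", package = "adcstab")
}

ddg_fixture <- function() {
  system.file("extdata", "ddg_combinations.tsv", package = "adcstab")
}

# Sampling grid spanning ~1.5 half-lives of a decay constant (per minute),
# the window within which polynomial differentiation tracks an exponential.
decay_grid <- function(lambda_per_min, n = 9) {
  seq(0, 1.5 * log(2) / lambda_per_min, length.out = n)
}
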