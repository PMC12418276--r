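# Shared fixtures: a reference vesicle and quick synthetic spike builders.

v_ref <- function(N0 = 5e-20) {
  vesicle_params(R_v = 150e-9, D_ves = 1e-11, n_electrons = 2L, N0 = N0)
}

# Noise-free constant-rate spike: closed form i = nF k N0 exp(-k t).
const_k_spike <- function(k = 100, T_end = 0.25, dt = 5e-5, v = v_ref()) {
  t <- seq(0, T_end, by = dt)
  forward_current(rate_trajectory(t, rep(k, length(t))), v)
}

# Deterministic scenarios (fixed vesicle draw) used across tests.
sc_fixed <- function(archetype, ...) {
  scenario(archetype, R_v_sdlog = 0, N0_sdlog = 0, ...)
}

# Local trapezoid (tests avoid reaching into the package namespace).
trapz_t <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2
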