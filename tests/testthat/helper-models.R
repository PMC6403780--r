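# Shared fixture builders: every fixture is constructed in code.

minimal_chain <- function(n = 3L) chain_spec(n, spacing = 3L,
                                             bond_length = 0.2,
                                             bond_angle = 120)

study_params <- function(sigma = 10, u_g = 0)
  energy_params(pK = 9, sigma = sigma, eps_t = 1, u_g = u_g)

random_params <- function() {
  energy_params(pK = runif(1, 4, 10), sigma = runif(1, 0, 4),
                psi = runif(1, 0.2, 2), omega = runif(1, 0.2, 2),
                u_t = runif(1, 0, 1.5), u_g = runif(1, 0, 1.5))
}

random_state <- function(chain) {
  roto_microstate(sample(0:1, chain$n_sites, replace = TRUE),
                  sample(1:3, chain$n_rotatable, replace = TRUE), chain)
}

rel_err <- function(a, b) abs(a - b) / pmax(1e-12, abs(b))
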