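# Brute-force enumeration references. Used by the test suite and the
# self-test subcommand as ground truth; never by the solver path. Iteration
# order over states is lexicographic (first index fastest) for reproducible
# debugging output.

logsum10 <- function(lw) {
  m <- max(lw)
  if (!is.finite(m)) return(-Inf)
  m + log10(sum(10^(lw - m)))
}

#' Brute-force enumeration of the rigid site-binding chain
#'
#' Sums the full Hamiltonian (nearest-neighbour term plus, optionally, the
#' screened Debye-Hueckel long-range pair sum over sites separated by at
#' least two positions, with collinear distances `|j - i| * b`) over all
#' `2^n_sites` ionization states.
#'
#' @param n_sites number of sites (capped at 20).
#' @param params an [energy_params()] (`pK` and the rigid weight `u`).
#' @param cond a [solution_conditions()] (scalar pH).
#' @param include_lr include the long-range term (default: `cond$lr_enabled`).
#' @param b site separation in nm.
#' @return A list of class `exact_ensemble`: `log_partition` (natural log),
#'   `Omega`, `theta`, `nu`, `D`, `h` (pair-correlation matrix, upper
#'   triangle), `states`, `log_weights` (decimal logs).
#' @export
enumerate_rigid <- function(n_sites, params, cond,
                            include_lr = cond$lr_enabled, b = 0.2) {
  if (n_sites > 20L) stop("enumeration guard: n_sites must be <= 20",
                          call. = FALSE)
  n <- as.integer(n_sites)
  S <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(S) <- NULL
  mu <- cond$pH - params$pK
  eps <- nlog10(params$u)
  nu <- rowSums(S)
  D <- if (n > 1L) rowSums(S[, -n, drop = FALSE] * S[, -1L, drop = FALSE])
  else numeric(nrow(S))
  Fr <- mu * nu + ifelse(D > 0, eps * D, 0)
  if (include_lr && n > 2L) {
    pot <- screened_potential(cond$ionic_strength, cond$bjerrum_length)
    for (i in seq_len(n - 2L)) for (j in (i + 2L):n)
      Fr <- Fr + dh_pair((j - i) * b, pot) * S[, i] * S[, j]
  }
  lw <- -Fr
  lz <- logsum10(lw)
  p <- 10^(lw - lz)
  theta <- colSums(p * S)
  h <- matrix(NA_real_, n, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    h[i, j] <- sum(p * S[, i] * S[, j])
  Dbar <- sum(p * D)
  structure(list(log_partition = lz * log(10), Omega = -lz * log(10),
                 theta = theta, nu = sum(theta), D = Dbar, h = h,
                 states = S, log_weights = lw),
            class = "exact_ensemble")
}

#' Brute-force enumeration of the SBRIS chain
#'
#' Sums over all `2^N * 3^(N-1)` roto-microstates of the minimal-model
#' flexible chain, using [reduced_free_energy()] for the energies and
#' [site_positions()] for the explicit geometry. Besides the ionization
#' observables it returns the per-bond gauche probabilities and the exact
#' ensemble-averaged squared inter-site distances, both unconditional and
#' conditioned on the pair being protonated.
#'
#' @param chain a flexible [chain_spec()] with at most 6 sites.
#' @param params an [energy_params()].
#' @param cond a [solution_conditions()] (scalar pH).
#' @param include_lr include the long-range term (default: `cond$lr_enabled`).
#' @return A list of class `exact_ensemble` with fields `log_partition`,
#'   `Omega`, `theta`, `nu`, `g`, `D`, `h`, `p_gauche`, `msd`
#'   (`<d_ij^2>`), `msd_cond` (`<d_ij^2 | s_i = s_j = 1>`), `states`
#'   (data frame of s and c vectors) and `log_weights`.
#' @export
enumerate_sbris <- function(chain, params, cond,
                            include_lr = cond$lr_enabled) {
  N <- chain$n_sites; M <- chain$n_rotatable
  if (!chain$flexible) stop("`chain` must be flexible (spacing >= 2)",
                            call. = FALSE)
  if (N > 6L) stop("enumeration guard: n_sites must be <= 6", call. = FALSE)
  cond_use <- cond
  cond_use$lr_enabled <- include_lr
  s_states <- as.matrix(expand.grid(rep(list(0:1), N)))
  c_states <- as.matrix(expand.grid(rep(list(1:3), M)))
  colnames(s_states) <- colnames(c_states) <- NULL
  ns <- nrow(s_states); nc <- nrow(c_states)
  lw <- matrix(NA_real_, ns, nc)
  d2 <- array(NA_real_, c(nc, N, N))
  for (kc in seq_len(nc)) {
    cc <- c_states[kc, ]
    pos <- site_positions(cc, chain, sites_only = TRUE)
    d2[kc, , ] <- as.matrix(stats::dist(pos))^2
    for (ks in seq_len(ns)) {
      st <- roto_microstate(s_states[ks, ], cc, chain)
      lw[ks, kc] <- -reduced_free_energy(st, chain, params, cond_use)
    }
  }
  lz <- logsum10(as.vector(lw))
  p <- 10^(lw - lz)                       # ns x nc probability table
  theta <- as.vector(t(s_states) %*% rowSums(p))
  gauche <- c_states != 1L
  pc_marg <- colSums(p)                   # probability of each conformation
  p_gauche <- as.vector(t(gauche) %*% pc_marg)
  D <- 0
  h <- matrix(NA_real_, N, N)
  msd <- msd_cond <- matrix(NA_real_, N, N)
  ps_marg <- rowSums(p)
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    both <- s_states[, i] * s_states[, j]
    h[i, j] <- sum(ps_marg * both)
    msd[i, j] <- sum(pc_marg * d2[, i, j])
    num <- sum((both %*% p) * d2[, i, j])
    msd_cond[i, j] <- if (h[i, j] > 0) num / h[i, j] else NA_real_
    if (j == i + 1L) D <- D + h[i, j]
  }
  structure(list(log_partition = lz * log(10), Omega = -lz * log(10),
                 theta = theta, nu = sum(theta), g = sum(p_gauche), D = D,
                 h = h, p_gauche = p_gauche, msd = msd, msd_cond = msd_cond,
                 states = list(s = s_states, c = c_states),
                 log_weights = lw),
            class = "exact_ensemble")
}
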