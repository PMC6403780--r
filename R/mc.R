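# R front end of the constant-pH Monte Carlo simulator (C++ core).

#' Monte Carlo run configuration
#'
#' Defaults are the full production protocol of the validation study:
#' 5e7 equilibration and 4.5e8 production configurations, bond-rotation /
#' site-toggle trial probabilities 0.999 / 0.001, and averages over 8
#' independent replicas. Scale these down for quick checks.
#'
#' @param steps_equilibration configurations discarded before sampling.
#' @param steps_production configurations sampled after equilibration.
#' @param p_bond_move probability of proposing a bond rotation (the
#'   complementary move is a protonation toggle).
#' @param n_replicas independent replicas averaged (seeded `seed + 0:(k-1)`).
#' @param seed base RNG seed.
#' @param sampling_stride sample every this many configurations.
#' @param check_every if > 0, recompute the total energy every this many
#'   steps and track the worst incremental-vs-total drift (debug mode).
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(steps_equilibration = 5e7, steps_production = 4.5e8,
                      p_bond_move = 0.999, n_replicas = 8L, seed = 1L,
                      sampling_stride = 10L, check_every = 0) {
  stopifnot(steps_equilibration >= 0, steps_production > 0,
            p_bond_move >= 0, p_bond_move <= 1, n_replicas >= 1,
            sampling_stride >= 1)
  structure(list(steps_equilibration = steps_equilibration,
                 steps_production = steps_production,
                 p_bond_move = p_bond_move,
                 p_site_move = 1 - p_bond_move,
                 n_replicas = as.integer(n_replicas),
                 seed = as.integer(seed),
                 sampling_stride = as.integer(sampling_stride),
                 check_every = check_every),
            class = "mc_config")
}

mc_args <- function(chain, params, cond) {
  list(n_sites = chain$n_sites, spacing = chain$spacing,
       bond_length = chain$bond_length, bond_angle = chain$bond_angle,
       rot_index = chain$rotatable_index,
       pK = params$pK, sigma = params$sigma, psi = params$psi,
       omega = params$omega, u_t = params$u_t, u_g = params$u_g,
       pH = cond$pH, ionic_strength = cond$ionic_strength,
       bjerrum_length = cond$bjerrum_length, lr_enabled = cond$lr_enabled)
}

#' Full reduced free energy of a roto-microstate (simulator route)
#'
#' Evaluates the same Hamiltonian as [reduced_free_energy()] through the
#' Monte Carlo engine's incremental bookkeeping code path; used to
#' cross-check the two implementations against each other.
#'
#' @param state a [roto_microstate()].
#' @inheritParams reduced_free_energy
#' @return Reduced free energy in decimal-log units.
#' @export
mc_state_energy <- function(state, chain, params, cond) {
  a <- mc_args(chain, params, cond)
  do.call(.mc_energy_cpp, c(a, list(s = as.integer(state$s),
                                    c = as.integer(state$c))))
}

#' Run the constant-pH Monte Carlo simulation at one state point
#'
#' Metropolis sampling of roto-microstates at fixed pH: each replica starts
#' from the all-trans, fully deprotonated state, equilibrates, then averages
#' the degree of protonation and the gauche fraction over production
#' samples. Replica `k` uses seed `mc$seed + k - 1`; identical
#' configurations reproduce identical trajectories.
#'
#' @param chain a [chain_spec()] (flexible, or single-site).
#' @param params an [energy_params()].
#' @param cond a [solution_conditions()] (scalar pH).
#' @param mc an [mc_config()].
#' @param track_states record joint-state visit counts (only for tiny
#'   systems; used by the detailed-balance test).
#' @return A list of class `mc_estimate` with `theta`, `p_gauche` (means),
#'   `stderr_theta`, `stderr_p_gauche` (across replicas), `replicas` (per
#'   replica results) and `max_drift`.
#' @export
run_mc <- function(chain, params, cond, mc = mc_config(),
                   track_states = FALSE) {
  if (!chain$flexible && chain$n_sites > 1L)
    stop("the MC simulator models the flexible minimal chain ",
         "(spacing >= 2)", call. = FALSE)
  a <- mc_args(chain, params, cond)
  reps <- vector("list", mc$n_replicas)
  for (k in seq_len(mc$n_replicas)) {
    set.seed(mc$seed + k - 1L)
    reps[[k]] <- do.call(.mc_run_cpp, c(a, list(
      steps_eq = mc$steps_equilibration,
      steps_prod = mc$steps_production,
      p_bond_move = mc$p_bond_move,
      sampling_stride = mc$sampling_stride,
      check_every = mc$check_every,
      track_states = track_states,
      s_init = integer(0), c_init = integer(0))))
  }
  th <- vapply(reps, `[[`, numeric(1L), "theta")
  pg <- vapply(reps, `[[`, numeric(1L), "p_gauche")
  sem <- function(v) if (length(v) > 1L && !anyNA(v))
    stats::sd(v) / sqrt(length(v)) else NA_real_
  out <- list(theta = mean(th), p_gauche = mean(pg),
              stderr_theta = sem(th), stderr_p_gauche = sem(pg),
              theta_replicas = th, p_gauche_replicas = pg,
              max_drift = max(vapply(reps, `[[`, numeric(1L), "max_drift")),
              replicas = reps, seeds = mc$seed + seq_len(mc$n_replicas) - 1L)
  class(out) <- "mc_estimate"
  out
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("<mc_estimate> theta = %.5f +/- %.5f, p_gauche = %.5f +/- %.5f (%d replicas)\n",
              x$theta, x$stderr_theta, x$p_gauche, x$stderr_p_gauche,
              length(x$theta_replicas)))
  invisible(x)
}

#' Monte Carlo titration over a (pH, ionic strength) grid
#'
#' Runs [run_mc()] at every grid point and assembles the same table schema
#' as [titrate()] plus standard-error columns.
#'
#' @inheritParams run_mc
#' @param pH numeric vector of pH values.
#' @param ionic_strength numeric vector of ionic strengths (mol/L).
#' @param bjerrum_length Bjerrum length (nm).
#' @param lr_enabled include the long-range term.
#' @return A data frame of class `mc_titration` with columns `pH`,
#'   `ionic_strength`, `theta`, `stderr_theta`, `p_gauche`,
#'   `stderr_p_gauche`.
#' @export
mc_titration <- function(chain, params, pH, ionic_strength,
                         mc = mc_config(), bjerrum_length = 0.7,
                         lr_enabled = TRUE) {
  rows <- list()
  for (I in ionic_strength) for (p in pH) {
    cond <- solution_conditions(p, I, bjerrum_length, lr_enabled)
    est <- run_mc(chain, params, cond, mc)
    rows[[length(rows) + 1L]] <- data.frame(
      pH = p, ionic_strength = I, theta = est$theta,
      stderr_theta = est$stderr_theta, p_gauche = est$p_gauche,
      stderr_p_gauche = est$stderr_p_gauche)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mc_titration", "data.frame")
  out
}
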