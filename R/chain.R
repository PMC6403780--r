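#' Chain geometry and topology of a linear weak polyelectrolyte
#'
#' Builds the minimal-model chain: `n_sites` identical ionizable sites placed
#' every `spacing` backbone nodes, joined by bonds of fixed length and fixed
#' valence angle. When `spacing >= 2`, exactly one bond of every inter-site
#' segment is rotatable (trans / gauche+ / gauche-); all other bonds are
#' frozen in the trans state. `spacing = 1` yields the degenerate rigid chain
#' (no rotatable bonds) in which consecutive sites are separated by
#' `bond_length`, the site separation used by the rigid-chain solver.
#'
#' @param n_sites number of ionizable sites (>= 1).
#' @param spacing number of backbone nodes between consecutive sites (>= 1).
#' @param bond_length bond length in nm.
#' @param bond_angle valence angle in degrees (angle between the two bonds
#'   meeting at a node), strictly between 0 and 180.
#' @param rotatable_index which bond of each inter-site segment rotates
#'   (1-based within the segment). Default: the middle bond,
#'   `spacing %/% 2 + 1`. Ignored for `spacing = 1`.
#' @return An object of class `chain_spec` with derived counts `n_nodes`,
#'   `n_bonds`, `n_rotatable`, the node index of every site (`site_nodes`,
#'   1-based) and the bond index of every rotatable bond (`rotatable_bonds`).
#' @examples
#' chain_spec(50, 3, 0.2, 120)   # 148 nodes, 147 bonds, 49 rotatable bonds
#' @export
chain_spec <- function(n_sites, spacing = 3, bond_length = 0.2,
                       bond_angle = 120, rotatable_index = NULL) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1 ||
      n_sites != round(n_sites))
    stop("`n_sites` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing < 1 ||
      spacing != round(spacing))
    stop("`spacing` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(bond_length) || bond_length <= 0)
    stop("`bond_length` must be > 0", call. = FALSE)
  if (!is.numeric(bond_angle) || bond_angle <= 0 || bond_angle >= 180)
    stop("`bond_angle` must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  n_sites <- as.integer(n_sites); spacing <- as.integer(spacing)
  n_nodes <- spacing * (n_sites - 1L) + 1L
  n_bonds <- n_nodes - 1L
  flexible <- spacing >= 2L
  n_rotatable <- if (flexible) n_sites - 1L else 0L
  if (is.null(rotatable_index))
    rotatable_index <- min(spacing - 1L, spacing %/% 2L + 1L)
  rotatable_index <- as.integer(rotatable_index)
  # the torsion of a segment's last bond acts beyond the next site, so only
  # bonds 1..spacing-1 of a segment are admissible rotors
  if (flexible && (rotatable_index < 1L || rotatable_index > spacing - 1L))
    stop("`rotatable_index` must lie in 1..(spacing - 1)", call. = FALSE)
  site_nodes <- (seq_len(n_sites) - 1L) * spacing + 1L
  rotatable_bonds <- if (flexible)
    (seq_len(n_rotatable) - 1L) * spacing + rotatable_index else integer(0)
  structure(list(
    n_sites = n_sites, spacing = spacing, bond_length = bond_length,
    bond_angle = bond_angle, rotatable_index = rotatable_index,
    n_nodes = n_nodes, n_bonds = n_bonds, n_rotatable = n_rotatable,
    site_nodes = site_nodes, rotatable_bonds = rotatable_bonds,
    flexible = flexible
  ), class = "chain_spec")
}

#' Rigid linear chain of equally spaced ionizable sites
#'
#' Convenience constructor for the rigid degenerate case: collinear sites a
#' distance `b` apart and no conformational degrees of freedom.
#'
#' @param n_sites number of ionizable sites.
#' @param b separation between consecutive sites in nm.
#' @return A `chain_spec` with `spacing = 1` and `n_rotatable = 0`.
#' @export
rigid_chain <- function(n_sites, b = 0.2) {
  chain_spec(n_sites, spacing = 1L, bond_length = b)
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf(
    "<chain_spec> %d sites / %d nodes / %d bonds (%d rotatable)\n",
    x$n_sites, x$n_nodes, x$n_bonds, x$n_rotatable))
  cat(sprintf("  bond length %g nm, valence angle %g deg, spacing %d\n",
              x$bond_length, x$bond_angle, x$spacing))
  invisible(x)
}

#' Short-range energy parameters of the SBRIS model
#'
#' All reduced energies are stored in decimal-log units: a term `E` in the
#' reduced free energy contributes a statistical weight `10^(-E)`. Weights and
#' energies are interchangeable specifications: give either the Boltzmann
#' weights (`sigma`, `u_t`, `u_g`, `u`) or the energies
#' (`p_sigma = -log10(sigma)`, `eps_t = -log10(u_t)`,
#' `eps_g = -log10(u_g)`, `epsilon = -log10(u)`), not both.
#'
#' @param pK site protonation constant (identical sites).
#' @param sigma Boltzmann weight of a gauche bond state.
#' @param psi,omega weights coupling two consecutive gauche states of the
#'   same (`psi`) or opposite (`omega`) orientation; both 1 for
#'   independently rotating bonds.
#' @param u_t,u_g weights of the short-range interaction between adjacent
#'   protonated sites joined through a trans / gauche bond. `u_g = 0` encodes
#'   an infinitely penalized (forbidden) gauche state between charged sites.
#' @param u nearest-neighbour interaction weight of the rigid chain.
#' @param p_sigma,eps_t,eps_g,epsilon the same quantities as decimal-log
#'   energies (alternatives to the weight arguments).
#' @param tau triplet interaction energy; carried for completeness, must be 0.
#' @return An object of class `energy_params`.
#' @examples
#' energy_params(pK = 9, sigma = 10, eps_t = 1, u_g = 0)
#' @export
energy_params <- function(pK = 9, sigma = 1, psi = 1, omega = 1,
                          u_t = 1, u_g = 1, u = 1,
                          p_sigma = NULL, eps_t = NULL, eps_g = NULL,
                          epsilon = NULL, tau = 0) {
  pick <- function(weight, energy, wname, ename) {
    if (!is.null(energy)) {
      if (!missing(weight) && !identical(weight, 1))
        stop(sprintf("give either `%s` or `%s`, not both", wname, ename),
             call. = FALSE)
      10^(-energy)
    } else weight
  }
  sigma <- pick(sigma, p_sigma, "sigma", "p_sigma")
  u_t <- pick(u_t, eps_t, "u_t", "eps_t")
  u_g <- pick(u_g, eps_g, "u_g", "eps_g")
  u <- pick(u, epsilon, "u", "epsilon")
  w <- c(sigma = sigma, psi = psi, omega = omega, u_t = u_t, u_g = u_g, u = u)
  if (any(!is.finite(w)) || any(w < 0))
    stop("all statistical weights must be finite and >= 0", call. = FALSE)
  if (!identical(tau, 0) && !isTRUE(all(tau == 0)))
    stop("triplet terms `tau` are carried at the type level only and must be 0",
         call. = FALSE)
  structure(list(pK = pK, sigma = sigma, psi = psi, omega = omega,
                 u_t = u_t, u_g = u_g, u = u, tau = 0), class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat(sprintf(
    "<energy_params> pK = %g, sigma = %g (p_sigma = %g), psi = %g, omega = %g\n",
    x$pK, x$sigma, -log10(x$sigma), x$psi, x$omega))
  cat(sprintf("  u_t = %g (eps_t = %g), u_g = %g (eps_g = %g), rigid u = %g\n",
              x$u_t, -log10(x$u_t), x$u_g, -log10(x$u_g), x$u))
  invisible(x)
}

#' Solution conditions: pH, ionic strength and screening
#'
#' @param pH solution pH (may be a vector when used as a grid elsewhere;
#'   scalar here).
#' @param ionic_strength ionic strength in mol/L (> 0).
#' @param bjerrum_length Bjerrum length in nm; the default 0.7 nm corresponds
#'   to water at 298 K, which fixes the temperature implicitly.
#' @param lr_enabled logical; include the screened long-range pair term.
#' @return An object of class `solution_conditions`, carrying also the
#'   derived inverse Debye length `kappa` (1/nm).
#' @export
solution_conditions <- function(pH, ionic_strength, bjerrum_length = 0.7,
                                lr_enabled = TRUE) {
  if (!is.numeric(ionic_strength) || any(ionic_strength <= 0))
    stop("`ionic_strength` must be > 0", call. = FALSE)
  if (!is.numeric(bjerrum_length) || bjerrum_length <= 0)
    stop("`bjerrum_length` must be > 0", call. = FALSE)
  structure(list(pH = pH, ionic_strength = ionic_strength,
                 bjerrum_length = bjerrum_length,
                 lr_enabled = isTRUE(lr_enabled),
                 kappa = debye_kappa(ionic_strength)),
            class = "solution_conditions")
}

#' @export
print.solution_conditions <- function(x, ...) {
  cat(sprintf(
    "<solution_conditions> pH = %s, I = %g M, lB = %g nm, kappa = %g 1/nm (LR %s)\n",
    paste(signif(x$pH, 4), collapse = ", "), x$ionic_strength,
    x$bjerrum_length, x$kappa, if (x$lr_enabled) "on" else "off"))
  invisible(x)
}

#' Joint ionization/conformation microstate
#'
#' A roto-microstate pairs a protonation vector `s` (0/1 per site) with a
#' conformation vector `c` over the rotatable bonds, each element one of
#' `"t"`, `"g+"`, `"g-"` (or the integer codes 1, 2, 3).
#'
#' @param s integer vector of protonation indicators, length `n_sites`.
#' @param c conformation states of the rotatable bonds, length `n_rotatable`.
#' @param chain a [chain_spec()] used to validate the lengths.
#' @return An object of class `roto_microstate`.
#' @export
roto_microstate <- function(s, c = integer(0), chain = NULL) {
  s <- as.integer(s)
  if (any(!s %in% c(0L, 1L)))
    stop("`s` must contain only 0/1", call. = FALSE)
  c <- conf_code(c)
  if (!is.null(chain)) {
    if (length(s) != chain$n_sites)
      stop("length(s) must equal chain$n_sites", call. = FALSE)
    if (length(c) != chain$n_rotatable)
      stop("length(c) must equal chain$n_rotatable", call. = FALSE)
  }
  structure(list(s = s, c = c), class = "roto_microstate")
}

# map "t"/"g+"/"g-" (or 1/2/3) to integer codes 1/2/3
conf_code <- function(c) {
  if (is.character(c)) {
    m <- match(c, c("t", "g+", "g-"))
    if (anyNA(m)) stop("conformation states must be 't', 'g+' or 'g-'",
                       call. = FALSE)
    m
  } else {
    c <- as.integer(c)
    if (any(!c %in% 1:3))
      stop("integer conformation codes must be 1 (t), 2 (g+) or 3 (g-)",
           call. = FALSE)
    c
  }
}

# -log10 of a weight, mapping 0 -> +Inf
nlog10 <- function(w) ifelse(w == 0, Inf, -log10(w))

#' Exact reduced free energy of a roto-microstate
#'
#' Evaluates, in decimal-log units (statistical weight `10^(-F)`), the sum of
#' the three contributions of the full Hamiltonian: the conformational term
#' (one `p_sigma` per gauche bond plus the `psi`/`omega` couplings between
#' consecutive rotatable bonds), the protonation term
#' `sum_i (pH - pK) s_i` plus the short-range `eps_t`/`eps_g` interaction of
#' each adjacent protonated pair according to the state of the bond joining
#' them, and - when `cond$lr_enabled` - the screened Debye-Hueckel pair sum
#' over charged sites separated by at least two site positions, with
#' distances taken from the explicit three-dimensional conformation.
#'
#' Forbidden configurations (any factor of weight 0, e.g. `u_g = 0` with both
#' flanking sites protonated and the bond gauche) return `+Inf`.
#'
#' @param state a [roto_microstate()].
#' @param chain a [chain_spec()].
#' @param params an [energy_params()].
#' @param cond a [solution_conditions()] (scalar pH).
#' @return The reduced free energy (decimal-log units); `+Inf` for zero-weight
#'   states.
#' @export
reduced_free_energy <- function(state, chain, params, cond) {
  s <- state$s; cc <- state$c
  if (length(s) != chain$n_sites || length(cc) != chain$n_rotatable)
    stop("state is inconsistent with `chain`", call. = FALSE)
  p_sigma <- nlog10(params$sigma)
  F_rot <- 0
  if (length(cc)) {
    gauche <- cc != 1L
    F_rot <- sum(p_sigma * gauche)
    if (length(cc) > 1L) {
      a <- cc[-length(cc)]; b <- cc[-1L]
      both_g <- a != 1L & b != 1L
      same <- both_g & a == b
      opp <- both_g & a != b
      F_rot <- F_rot + sum(nlog10(params$psi) * same) +
        sum(nlog10(params$omega) * opp)
    }
  }
  mu <- cond$pH - params$pK
  F_p <- mu * sum(s)
  if (chain$n_sites > 1L) {
    pair_on <- s[-length(s)] * s[-1L]
    if (chain$flexible) {
      eps_bond <- ifelse(cc == 1L, nlog10(params$u_t), nlog10(params$u_g))
    } else {
      eps_bond <- rep(nlog10(params$u), chain$n_sites - 1L)
    }
    F_p <- F_p + sum(ifelse(pair_on == 1L, eps_bond, 0))
  }
  F_lr <- 0
  if (cond$lr_enabled && sum(s) > 1L) {
    charged <- which(s == 1L)
    if (chain$flexible) {
      pos <- site_positions(cc, chain, sites_only = TRUE)
      d <- as.matrix(stats::dist(pos))
    } else {
      d <- abs(outer(seq_len(chain$n_sites), seq_len(chain$n_sites), "-")) *
        chain$bond_length
    }
    pot <- screened_potential(cond$ionic_strength, cond$bjerrum_length)
    for (a in seq_along(charged)) {
      for (b in seq_along(charged)) {
        i <- charged[a]; j <- charged[b]
        if (j > i + 1L) F_lr <- F_lr + dh_pair(d[i, j], pot)
      }
    }
  }
  F_rot + F_p + F_lr
}
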