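# Transfer-matrix engine for the SB (2x2), RIS (3x3) and SBRIS (6x6) chains.
#
# All scans run in the log domain: running vectors are renormalized after
# every multiplication and a decimal-log scale is accumulated, so partition
# functions remain representable at extreme pH for long chains. Site- and
# bond-resolved observables are computed exactly by projector insertion
# (replacing one transfer matrix by its protonated- or gauche-selecting
# part), never by finite differences.

sb_matrix <- function(z, u) matrix(c(1, z, 1, z * u), 2L, 2L, byrow = TRUE)

ris_matrix <- function(sigma, psi = 1, omega = 1) {
  matrix(c(1, sigma, sigma,
           1, sigma * psi, sigma * omega,
           1, sigma * omega, sigma * psi), 3L, 3L, byrow = TRUE)
}

# 6x6 super-matrix of one ionization-bearing rotatable bond: 3x3 blocks
# indexed by the protonation of the two flanking sites; the protonated/
# protonated block carries the diagonal short-range factor diag(u_t, u_g,
# u_g) acting on the state of the connecting bond.
sbris_matrix <- function(z, U, u_t, u_g) {
  ud <- c(u_t, u_g, u_g)
  B <- matrix(0, 6L, 6L)
  B[1:3, 1:3] <- U
  B[1:3, 4:6] <- U * z
  B[4:6, 1:3] <- U
  B[4:6, 4:6] <- sweep(U, 2L, ud, "*") * z
  B
}

norm_vec <- function(v, lv) {
  m <- max(v)
  if (m <= 0) list(v = v, l = -Inf) else list(v = v / m, l = lv + log10(m))
}

# Chain context: matrices `mats` (list, possibly empty), start row vector r,
# end column vector tv, plus per-type column masks for projector insertion.
# masks: named list of integer column sets; rmask: named list of index sets
# that survive projection at the r level (position 0).
tm_ctx <- function(mats, r, tv, masks = list(), rmask = list()) {
  M <- length(mats)
  dim <- length(r)
  P <- matrix(0, M + 1L, dim); lp <- numeric(M + 1L)
  nv <- norm_vec(r, 0); P[1L, ] <- nv$v; lp[1L] <- nv$l
  if (M) for (k in seq_len(M)) {
    nv <- norm_vec(drop(P[k, ] %*% mats[[k]]), lp[k])
    P[k + 1L, ] <- nv$v; lp[k + 1L] <- nv$l
  }
  S <- matrix(0, M + 1L, dim); ls <- numeric(M + 1L)
  nv <- norm_vec(tv, 0); S[M + 1L, ] <- nv$v; ls[M + 1L] <- nv$l
  if (M) for (k in rev(seq_len(M))) {
    nv <- norm_vec(drop(mats[[k]] %*% S[k + 1L, ]), ls[k + 1L])
    S[k, ] <- nv$v; ls[k] <- nv$l
  }
  logXi <- log10(sum(P[1L, ] * S[1L, ])) + lp[1L] + ls[1L]
  proj <- lapply(masks, function(cols) {
    lapply(mats, function(B) { Bp <- B; Bp[, -cols] <- 0; Bp })
  })
  # RS[[type]][[q]] = projected(B_q) %*% S[q+1], with log scale ls[q+1]
  RS <- lapply(proj, function(pl) {
    if (!M) return(NULL)
    vapply(seq_len(M),
           function(q) drop(pl[[q]] %*% S[q + 1L, ]), numeric(dim))
  })
  list(mats = mats, r = r, tv = tv, M = M, dim = dim,
       P = P, lp = lp, S = S, ls = ls, logXi = logXi,
       masks = masks, rmask = rmask, proj = proj, RS = RS)
}

# <indicator at position pos> for a single insertion. pos = 0 projects the
# start vector (only meaningful when an rmask for `type` exists).
tm_single <- function(ctx, pos, type) {
  if (pos == 0L) {
    v <- numeric(ctx$dim); keep <- ctx$rmask[[type]]
    v[keep] <- ctx$P[1L, keep]
    val <- sum(v * ctx$S[1L, ])
    lg <- ctx$lp[1L] + ctx$ls[1L]
  } else {
    val <- sum(ctx$P[pos, ] * ctx$RS[[type]][, pos])
    lg <- ctx$lp[pos] + ctx$ls[pos + 1L]
  }
  if (val <= 0) return(0)
  10^(log10(val) + lg - ctx$logXi)
}

# <product of indicators> for an arbitrary merged insertion list
# (positions strictly increasing; each a column mask; pos 0 allowed).
tm_expect <- function(ctx, pos, type) {
  stopifnot(!is.unsorted(pos, strictly = TRUE))
  i <- 1L
  if (pos[1L] == 0L) {
    v <- numeric(ctx$dim); keep <- ctx$rmask[[type[1L]]]
    v[keep] <- ctx$P[1L, keep]
    lv <- ctx$lp[1L]
    k <- 1L
    i <- 2L
  } else {
    k <- pos[1L]
    v <- ctx$P[k, ]
    lv <- ctx$lp[k]
  }
  # v is the running vector before matrix k; consume matrices k..last pos
  last <- pos[length(pos)]
  if (last >= k) {
    for (m in k:last) {
      B <- if (i <= length(pos) && pos[i] == m) {
        B <- ctx$proj[[type[i]]][[m]]; i <- i + 1L; B
      } else ctx$mats[[m]]
      nv <- norm_vec(drop(v %*% B), lv)
      v <- nv$v; lv <- nv$l
      if (!is.finite(lv)) return(0)
    }
    k <- last + 1L
  }
  val <- sum(v * ctx$S[k, ])
  if (val <= 0) return(0)
  10^(log10(val) + lv + ctx$ls[k] - ctx$logXi)
}

# All ordered pair expectations <A at p, B at q> for p < q. posA/posB are the
# admissible matrix positions of each indicator (0 allowed for A via rmask).
# Returns a (M+1) x M matrix W with W[p + 1, q] for p in posA, q in posB,
# q > p; unfilled entries NA.
tm_pair_matrix <- function(ctx, typeA, posA, typeB, posB) {
  M <- ctx$M
  W <- matrix(NA_real_, M + 1L, max(M, 1L))
  RSB <- ctx$RS[[typeB]]
  for (p in posA) {
    if (p >= M) next
    if (p == 0L) {
      v <- numeric(ctx$dim); keep <- ctx$rmask[[typeA]]
      v[keep] <- ctx$P[1L, keep]
      lv <- ctx$lp[1L]
    } else {
      v <- drop(ctx$P[p, ] %*% ctx$proj[[typeA]][[p]])
      lv <- ctx$lp[p]
    }
    nv <- norm_vec(v, lv); v <- nv$v; lv <- nv$l
    if (!is.finite(lv)) { W[p + 1L, ] <- 0; next }
    for (q in (p + 1L):M) {
      # v currently holds the projected product up to matrix q - 1
      if (q %in% posB) {
        val <- sum(v * RSB[, q])
        W[p + 1L, q] <- if (val <= 0) 0 else
          10^(log10(val) + lv + ctx$ls[q + 1L] - ctx$logXi)
      }
      if (q < M) {
        nv <- norm_vec(drop(v %*% ctx$mats[[q]]), lv)
        v <- nv$v; lv <- nv$l
        if (!is.finite(lv)) { if (q < M) W[p + 1L, (q + 1L):M] <- 0; break }
      }
    }
  }
  W
}

## ---------------------------------------------------------------- SB chain

rigid_ctx <- function(n_sites, z, u) {
  Tm <- sb_matrix(z, u)
  tm_ctx(rep(list(Tm), n_sites), r = c(1, 0), tv = c(1, 1),
         masks = list(site = 2L))
}

#' Log partition function of the rigid site-binding chain
#'
#' Exact semi-grand canonical partition function of `n_sites` two-state
#' sites with nearest-neighbour interaction weight `u` and reduced activity
#' `z = K * a_H = 10^(pK - pH)`, from the 2x2 transfer matrix.
#'
#' @param n_sites number of sites (>= 1).
#' @param z reduced proton activity (>= 0).
#' @param u nearest-neighbour Boltzmann weight (>= 0).
#' @return `log(Xi)` (natural log).
#' @examples
#' exp(sb_partition(1, z = 2, u = 1))   # 1 + z
#' @export
sb_partition <- function(n_sites, z, u) {
  stopifnot(n_sites >= 1, z >= 0, u >= 0)
  ctx <- rigid_ctx(n_sites, z, u)
  ctx$logXi * log(10)
}

#' Exact observables of the rigid site-binding chain
#'
#' Site-resolved protonation probabilities and pair correlations computed by
#' projector insertion in the transfer-matrix product (no finite
#' differences).
#'
#' @inheritParams sb_partition
#' @param pairs optional integer matrix (2 columns) of site pairs for which
#'   `<s_i s_j>` is requested.
#' @return A list of class `ensemble_observables`: `log_partition` (natural
#'   log), `theta` (per site), `nu`, `D` (mean adjacent protonated pairs),
#'   and `pair_corr` (data frame, if `pairs` given).
#' @export
sb_observables <- function(n_sites, z, u, pairs = NULL) {
  stopifnot(n_sites >= 1, z >= 0, u >= 0)
  ctx <- rigid_ctx(n_sites, z, u)
  theta <- vapply(seq_len(n_sites), function(i) tm_single(ctx, i, "site"),
                  numeric(1L))
  D <- if (n_sites > 1L)
    sum(vapply(seq_len(n_sites - 1L), function(i)
      tm_expect(ctx, c(i, i + 1L), c("site", "site")), numeric(1L))) else 0
  pc <- NULL
  if (!is.null(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    if (any(pairs < 1L | pairs > n_sites)) stop("pair index out of range",
                                                call. = FALSE)
    val <- apply(pairs, 1L, function(ij) {
      ij <- sort(ij)
      if (ij[1L] == ij[2L]) theta[ij[1L]]
      else tm_expect(ctx, ij, c("site", "site"))
    })
    pc <- data.frame(i = pairs[, 1L], j = pairs[, 2L], h = val)
  }
  structure(list(log_partition = ctx$logXi * log(10), theta = theta,
                 nu = sum(theta), D = D, pair_corr = pc),
            class = "ensemble_observables")
}

# full upper-triangular h_ij matrix of the rigid chain (internal)
rigid_pair_corr <- function(ctx) {
  n <- ctx$M
  h <- matrix(NA_real_, n, n)
  W <- tm_pair_matrix(ctx, "site", seq_len(n - 1L), "site", seq_len(n))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) h[i, j] <- W[i + 1L, j]
  h
}

## ---------------------------------------------------------------- RIS chain

#' Gauche fraction and partition function of the neutral RIS chain
#'
#' Exact per-bond gauche probability of `n_bonds` three-state bonds with
#' statistical weights `sigma` (gauche), `psi` and `omega` (consecutive
#' gauche pairs of equal / opposite orientation), via projector insertion in
#' the 3x3 transfer-matrix product.
#'
#' @param n_bonds number of rotatable bonds (>= 1).
#' @param sigma gauche weight (>= 0).
#' @param psi,omega consecutive-gauche coupling weights.
#' @return A list with `fraction` (mean per-bond gauche probability),
#'   `p_gauche` (per bond) and `log_partition` (natural log).
#' @examples
#' ris_gauche_fraction(10, sigma = 1)$fraction   # 2/3
#' @export
ris_gauche_fraction <- function(n_bonds, sigma, psi = 1, omega = 1) {
  stopifnot(n_bonds >= 1, sigma >= 0, psi >= 0, omega >= 0)
  U <- ris_matrix(sigma, psi, omega)
  ctx <- tm_ctx(rep(list(U), n_bonds), r = c(1, 0, 0), tv = c(1, 1, 1),
                masks = list(gauche = 2:3))
  pg <- vapply(seq_len(n_bonds), function(a) tm_single(ctx, a, "gauche"),
               numeric(1L))
  list(fraction = mean(pg), p_gauche = pg,
       log_partition = ctx$logXi * log(10))
}

## -------------------------------------------------------------- SBRIS chain

# Effective parameters after the LEIP shifts: pK -> pK - x, p_sigma ->
# p_sigma + x_sigma.
shifted_params <- function(params, pH, x = 0, x_sigma = 0) {
  list(z = 10^(params$pK - x - pH),
       sigma = params$sigma * 10^(-x_sigma))
}

# SBRIS context of the minimal-model chain (one rotatable, ionization-
# bearing bond between consecutive sites). The first site's activity factor
# is absorbed into the start vector r = (q, z q): this is the single
# committed end convention, fixed by equality with brute-force enumeration.
sbris_ctx <- function(chain, params, pH, x = 0, x_sigma = 0) {
  if (!chain$flexible)
    stop("SBRIS engine requires a flexible chain (spacing >= 2)",
         call. = FALSE)
  sp <- shifted_params(params, pH, x, x_sigma)
  U <- ris_matrix(sp$sigma, params$psi, params$omega)
  B <- sbris_matrix(sp$z, U, params$u_t, params$u_g)
  M <- chain$n_rotatable
  ctx <- tm_ctx(rep(list(B), M),
                r = c(1, 0, 0, sp$z, 0, 0), tv = rep(1, 6L),
                masks = list(site = 4:6, gauche = c(2L, 3L, 5L, 6L),
                             both = 5:6, gplus = c(2L, 5L),
                             gminus = c(3L, 6L)),
                rmask = list(site = 4:6))
  ctx$z <- sp$z; ctx$sigma_eff <- sp$sigma
  ctx
}

# matrix position of site i in the SBRIS scan (site 1 lives on r, pos 0)
site_pos <- function(i) i - 1L

#' Log partition function of the SBRIS chain
#'
#' Exact partition function over all roto-microstates (ionization vector x
#' conformation vector) of the minimal-model chain under the short-range
#' Hamiltonian (long-range terms excluded; they enter through the LEIP
#' shifts). Computed from the 6x6 super-matrix product with log-domain
#' renormalization.
#'
#' @param chain a flexible [chain_spec()].
#' @param params an [energy_params()].
#' @param pH solution pH (scalar).
#' @param shifts optional [leip_corrections()]; applied as `pK - x`,
#'   `p_sigma + x_sigma` before matrix construction.
#' @return `log(Xi_SBRIS)` (natural log).
#' @export
sbris_partition <- function(chain, params, pH, shifts = NULL) {
  x <- if (is.null(shifts)) 0 else shifts$x
  xs <- if (is.null(shifts)) 0 else shifts$x_sigma
  ctx <- sbris_ctx(chain, params, pH, x, xs)
  ctx$logXi * log(10)
}

#' Exact observables of the SBRIS chain
#'
#' Site protonation probabilities, per-bond gauche probabilities, their
#' sums `nu` and `g`, the adjacent protonated-pair count `D`, and requested
#' pair correlations `<s_i s_j>`, all exact under the (optionally shifted)
#' short-range Hamiltonian.
#'
#' @inheritParams sbris_partition
#' @param pairs optional 2-column matrix of site pairs for `<s_i s_j>`.
#' @return A list of class `ensemble_observables` with fields
#'   `log_partition`, `theta`, `nu`, `g`, `D`, `p_gauche`, `pair_corr`.
#' @export
sbris_observables <- function(chain, params, pH, shifts = NULL,
                              pairs = NULL) {
  x <- if (is.null(shifts)) 0 else shifts$x
  xs <- if (is.null(shifts)) 0 else shifts$x_sigma
  ctx <- sbris_ctx(chain, params, pH, x, xs)
  n <- chain$n_sites; M <- ctx$M
  theta <- vapply(seq_len(n), function(i) tm_single(ctx, site_pos(i), "site"),
                  numeric(1L))
  pg <- vapply(seq_len(M), function(a) tm_single(ctx, a, "gauche"),
               numeric(1L))
  D <- sum(vapply(seq_len(n - 1L), function(i)
    tm_expect(ctx, c(site_pos(i), site_pos(i + 1L)),
              c("site", "site")), numeric(1L)))
  pc <- NULL
  if (!is.null(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    if (any(pairs < 1L | pairs > n)) stop("pair index out of range",
                                          call. = FALSE)
    val <- apply(pairs, 1L, function(ij) {
      ij <- sort(ij)
      if (ij[1L] == ij[2L]) theta[ij[1L]]
      else tm_expect(ctx, site_pos(ij), c("site", "site"))
    })
    pc <- data.frame(i = pairs[, 1L], j = pairs[, 2L], h = val)
  }
  structure(list(log_partition = ctx$logXi * log(10), theta = theta,
                 nu = sum(theta), g = sum(pg), D = D, p_gauche = pg,
                 pair_corr = pc),
            class = "ensemble_observables")
}

#' @export
print.ensemble_observables <- function(x, ...) {
  cat("<ensemble_observables>\n")
  cat(sprintf("  ln Xi = %.6g, nu = %.6g", x$log_partition, x$nu))
  if (!is.null(x$g)) cat(sprintf(", g = %.6g", x$g))
  cat(sprintf(", D = %.6g\n", x$D))
  cat("  theta:", paste(signif(x$theta, 4), collapse = " "), "\n")
  if (!is.null(x$p_gauche) && length(x$p_gauche))
    cat("  p_gauche:", paste(signif(x$p_gauche, 4), collapse = " "), "\n")
  invisible(x)
}

# Full site-site correlation matrix h[i, j] = <s_i s_j> (upper triangle).
sbris_pair_corr <- function(ctx, n_sites) {
  W <- tm_pair_matrix(ctx, "site", 0:(ctx$M - 1L), "site", seq_len(ctx$M))
  h <- matrix(NA_real_, n_sites, n_sites)
  for (i in seq_len(n_sites - 1L)) for (j in (i + 1L):n_sites)
    h[i, j] <- W[site_pos(i) + 1L, site_pos(j)]
  h
}

# Covariance block needed by the LEIP Jacobian, all via exact projector
# insertion: Var(nu), Cov(nu, g), Var(g) (and the gauche singles).
sbris_covariances <- function(ctx, n_sites, need_g = TRUE) {
  M <- ctx$M
  theta <- vapply(seq_len(n_sites), function(i)
    tm_single(ctx, site_pos(i), "site"), numeric(1L))
  nu <- sum(theta)
  h <- sbris_pair_corr(ctx, n_sites)
  ss <- sum(h[upper.tri(h)], na.rm = TRUE)
  m_nn <- 2 * ss + nu                       # <nu^2>
  out <- list(theta = theta, nu = nu, h = h, var_nu = m_nn - nu^2)
  if (need_g && M > 0L) {
    pg <- vapply(seq_len(M), function(a) tm_single(ctx, a, "gauche"),
                 numeric(1L))
    g <- sum(pg)
    Wsg <- tm_pair_matrix(ctx, "site", 0:(M - 1L), "gauche", seq_len(M))
    Wgs <- tm_pair_matrix(ctx, "gauche", seq_len(M - 1L), "site", seq_len(M))
    sg <- 0
    for (i in seq_len(n_sites)) {
      p <- site_pos(i)
      for (a in seq_len(M)) {
        sg <- sg + if (a > p) Wsg[p + 1L, a]
        else if (a < p) Wgs[a + 1L, p]
        else tm_single(ctx, p, "both")   # same position: s=1 AND gauche
      }
    }
    Wgg <- tm_pair_matrix(ctx, "gauche", seq_len(max(M - 1L, 1L)), "gauche",
                          seq_len(M))
    gg <- if (M > 1L) {
      tot <- 0
      for (a in seq_len(M - 1L)) tot <- tot +
          sum(Wgg[a + 1L, (a + 1L):M], na.rm = TRUE)
      tot
    } else 0
    out$p_gauche <- pg; out$g <- g
    out$cov_nu_g <- sg - nu * g
    out$var_g <- (2 * gg + g) - g^2
  }
  out
}
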