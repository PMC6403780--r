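# Exact ensemble-averaged squared inter-site distances <d_ij^2>_0 under the
# short-range SBRIS ensemble, by contracting protonation-decorated
# generator super-matrices: each 6x6 transfer-matrix entry is expanded with
# the 5x5 Flory generator of the segment state it introduces (30x30 blocks),
# so the scan accumulates both the statistical weight and the squared
# displacement exactly - no sampling anywhere in the solver path.

lift_row <- function(v6) {
  v <- numeric(30L)
  v[(seq_len(6L) - 1L) * 5L + 1L] <- v6
  v
}

lift_col <- function(v6) {
  v <- numeric(30L)
  v[(seq_len(6L) - 1L) * 5L + 5L] <- v6
  v
}

# 30x30 generator super-matrix from a 6x6 SBRIS matrix; `gens` are the three
# per-state 5x5 segment generators. `site_cols` optionally restricts the
# new-site columns (protonation projector for conditional averages).
build_super_generator <- function(B, gens, site_cols = NULL) {
  G <- matrix(0, 30L, 30L)
  for (stn in seq_len(6L)) {
    if (!is.null(site_cols) && !(stn %in% site_cols)) next
    cn <- (stn - 1L) %% 3L + 1L
    jj <- (stn - 1L) * 5L + (1:5)
    for (stp in seq_len(6L)) {
      if (B[stp, stn] == 0) next
      ii <- (stp - 1L) * 5L + (1:5)
      G[ii, jj] <- B[stp, stn] * gens[[cn]]
    }
  }
  G
}

# <d_ij^2> (or the protonation-conditioned variant) from an SBRIS context.
msd_engine <- function(ctx, gens, i, j, conditional = FALSE) {
  stopifnot(i >= 1L, j <= ctx$M + 1L, i < j)
  BG <- build_super_generator(ctx$mats[[1L]], gens)
  if (conditional) {
    BGp <- build_super_generator(ctx$mats[[1L]], gens, site_cols = 4:6)
    if (i == 1L) {
      v6 <- numeric(6L); v6[4:6] <- ctx$P[1L, 4:6]
      lv <- ctx$lp[1L]
    } else {
      v6 <- drop(ctx$P[i - 1L, ] %*% ctx$proj[["site"]][[i - 1L]])
      lv <- ctx$lp[i - 1L]
    }
  } else {
    v6 <- ctx$P[i, ]
    lv <- ctx$lp[i]
  }
  v <- lift_row(v6)
  for (m in i:(j - 1L)) {
    use <- if (conditional && m == j - 1L) BGp else BG
    nv <- norm_vec(drop(v %*% use), lv)
    v <- nv$v; lv <- nv$l
    if (!is.finite(lv)) return(NA_real_)
  }
  val <- sum(v * lift_col(ctx$S[j, ]))
  if (val <= 0) return(NA_real_)
  num <- 10^(log10(val) + lv + ctx$ls[j] - ctx$logXi)
  if (!conditional) return(num)
  hij <- if (i == 1L) tm_expect(ctx, c(0L, j - 1L), c("site", "site"))
  else tm_expect(ctx, c(i - 1L, j - 1L), c("site", "site"))
  if (hij <= 0) NA_real_ else num / hij
}

#' Ensemble-averaged squared distance between two sites
#'
#' Exact `<d_ij^2>` over the (optionally shifted) short-range SBRIS
#' ensemble, computed by generator super-matrix contraction. With
#' `conditional = TRUE` the average is restricted to roto-microstates in
#' which both sites are protonated (a sensitivity variant; the solver uses
#' the unconditional average).
#'
#' @param i,j site indices, `i < j`.
#' @param chain a flexible [chain_spec()].
#' @param params an [energy_params()].
#' @param pH solution pH (scalar).
#' @param shifts optional [leip_corrections()].
#' @param conditional condition on `s_i = s_j = 1`.
#' @return `<d_ij^2>` in nm^2.
#' @export
mean_square_distance <- function(i, j, chain, params, pH, shifts = NULL,
                                 conditional = FALSE) {
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("`i` and `j` must differ", call. = FALSE)
  if (i > j) { k <- i; i <- j; j <- k }
  if (i < 1L || j > chain$n_sites) stop("site index out of range",
                                        call. = FALSE)
  x <- if (is.null(shifts)) 0 else shifts$x
  xs <- if (is.null(shifts)) 0 else shifts$x_sigma
  ctx <- sbris_ctx(chain, params, pH, x, xs)
  gens <- segment_transforms(chain)$generators
  msd_engine(ctx, gens, i, j, conditional = conditional)
}

# Sweep version used by the LEIP solver: all <d_ij^2> and <s_i s_j> for
# j >= i + 2 in O(N^2) matrix-vector products. Returns the upper-triangular
# matrices msd and h.
msd_pair_sweep <- function(ctx, gens, n_sites) {
  BG <- build_super_generator(ctx$mats[[1L]], gens)
  msd <- matrix(NA_real_, n_sites, n_sites)
  h <- sbris_pair_corr(ctx, n_sites)
  for (i in seq_len(n_sites - 2L)) {
    v <- lift_row(ctx$P[i, ])
    lv <- ctx$lp[i]
    for (j in (i + 1L):n_sites) {
      nv <- norm_vec(drop(v %*% BG), lv)
      v <- nv$v; lv <- nv$l
      if (!is.finite(lv)) break
      if (j >= i + 2L) {
        val <- sum(v * lift_col(ctx$S[j, ]))
        msd[i, j] <- if (val <= 0) NA_real_ else
          10^(log10(val) + lv + ctx$ls[j] - ctx$logXi)
      }
    }
  }
  list(msd = msd, h = h)
}
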