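# Explicit chain geometry: rigid bond lengths, rigid valence angles, discrete
# dihedrals (trans = 180 deg, gauche+/- = +/-60 deg, i.e. states 120 deg
# apart). Rotating one bond rigidly rotates everything downstream.

dihedral_angle <- function(code) c(pi, pi / 3, -pi / 3)[code]

unit3 <- function(v) v / sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place node k+2 from nodes (k-1, k, k+1) coordinates, the valence angle and
# the dihedral of bond (k, k+1). `ang` is the angle between successive bond
# VECTORS (pi - valence angle); phi follows the IUPAC torsion convention
# (trans = pi).
nerf_place <- function(A, B, C, l, ang, phi) {
  bc <- unit3(C - B)
  n <- unit3(cross3(B - A, bc))
  m <- cross3(n, bc)
  C + l * (cos(ang) * bc + sin(ang) * (cos(phi) * m - sin(phi) * n))
}

#' Node (or site) coordinates of a conformation
#'
#' Builds the three-dimensional coordinates of every backbone node for a
#' given conformation of the rotatable bonds. All bond lengths equal
#' `chain$bond_length`, all valence angles equal `chain$bond_angle`; frozen
#' bonds are held in trans, and each rotatable bond takes the dihedral of its
#' state (t, g+, g- at 180, +60, -60 degrees). The chain starts in a
#' canonical pose (first bond along x, second in the xy plane) consistent
#' with an all-trans upstream continuation, so every inter-site segment is
#' geometrically equivalent.
#'
#' @param c conformation vector of the rotatable bonds (codes or
#'   `"t"`/`"g+"`/`"g-"`).
#' @param chain a [chain_spec()].
#' @param sites_only if `TRUE`, return only the rows of the ionizable sites.
#' @return A numeric matrix (nm) with one row per node (or site) and columns
#'   x, y, z.
#' @export
site_positions <- function(c, chain, sites_only = FALSE) {
  cc <- conf_code(c)
  if (length(cc) != chain$n_rotatable)
    stop("length(c) must equal chain$n_rotatable", call. = FALSE)
  K <- chain$n_nodes
  l <- chain$bond_length
  ang <- pi * (180 - chain$bond_angle) / 180
  phi <- rep(pi, max(chain$n_bonds, 1L))
  if (length(cc)) phi[chain$rotatable_bonds] <- dihedral_angle(cc)
  r <- matrix(0, K, 3L)
  if (K >= 2L) r[2L, ] <- c(l, 0, 0)
  if (K >= 3L) r[3L, ] <- r[2L, ] + l * c(cos(ang), sin(ang), 0)
  if (K >= 4L) {
    for (k in 2L:(K - 2L)) {
      # dihedral of bond k (nodes k, k+1) places node k+2
      r[k + 2L, ] <- nerf_place(r[k - 1L, ], r[k, ], r[k + 1L, ], l, ang,
                                phi[k])
    }
  }
  colnames(r) <- c("x", "y", "z")
  if (sites_only) r[chain$site_nodes, , drop = FALSE] else r
}

# Local frame at a site node: columns (u, v, w) with u the incoming bond
# direction and w the normal of the last two incoming bonds.
site_frame <- function(r, node) {
  u <- unit3(r[node, ] - r[node - 1L, ])
  w <- unit3(cross3(r[node - 1L, ] - r[node - 2L, ], u))
  v <- cross3(w, u)
  cbind(u, v, w)
}

# Per-state rigid transform of one inter-site segment: displacement ell (in
# the frame of the segment start) and frame rotation A. Extracted numerically
# from a probe chain; homogeneous across segments because the internal bond
# pattern repeats. Cached per geometry.
.segment_cache <- new.env(parent = emptyenv())

segment_transforms <- function(chain) {
  key <- paste(chain$spacing, chain$bond_length, chain$bond_angle,
               chain$rotatable_index, sep = "/")
  hit <- .segment_cache[[key]]
  if (!is.null(hit)) return(hit)
  probe <- chain_spec(4L, chain$spacing, chain$bond_length, chain$bond_angle,
                      chain$rotatable_index)
  out <- lapply(1:3, function(st) {
    cc <- c(1L, st, 1L)
    r <- site_positions(cc, probe)
    n2 <- probe$site_nodes[2L]; n3 <- probe$site_nodes[3L]
    F2 <- site_frame(r, n2); F3 <- site_frame(r, n3)
    list(ell = drop(t(F2) %*% (r[n3, ] - r[n2, ])), A = t(F2) %*% F3)
  })
  # Flory-style 5x5 generator per state: serial products accumulate the
  # squared norm of the composed segment displacements in entry [1, 5].
  gen <- lapply(out, function(tr) {
    G <- matrix(0, 5L, 5L)
    G[1L, 1L] <- 1
    G[1L, 2:4] <- 2 * drop(tr$ell %*% tr$A)
    G[1L, 5L] <- sum(tr$ell^2)
    G[2:4, 2:4] <- tr$A
    G[2:4, 5L] <- tr$ell
    G[5L, 5L] <- 1
    G
  })
  res <- list(transforms = out, generators = gen)
  .segment_cache[[key]] <- res
  res
}

#' Write conformations as xyz snapshots
#'
#' Writes one or more conformations to a plain-text xyz file for inspection
#' in a molecular viewer. Ionizable sites are labelled `N` (or `P` when a
#' protonation vector marks them charged), inert nodes `C`.
#'
#' @param conformations a conformation vector or a list of them.
#' @param chain a [chain_spec()].
#' @param path output file path.
#' @param s optional protonation vector (or list, matching `conformations`).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(conformations, chain, path, s = NULL) {
  if (!is.list(conformations)) conformations <- list(conformations)
  if (!is.null(s) && !is.list(s)) s <- list(s)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(conformations)) {
    r <- site_positions(conformations[[k]], chain)
    lab <- rep("C", chain$n_nodes)
    lab[chain$site_nodes] <- "N"
    if (!is.null(s)) lab[chain$site_nodes[s[[k]] == 1L]] <- "P"
    writeLines(as.character(chain$n_nodes), con)
    writeLines(sprintf("frame %d", k), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", lab, r[, 1], r[, 2], r[, 3]), con)
  }
  invisible(path)
}
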