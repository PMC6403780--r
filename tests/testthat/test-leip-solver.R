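test_that("phi0 vanishes for uncharged chains and one-term sums add up", {
  ch <- rigid_chain(3)
  pars <- energy_params(pK = 9, epsilon = 1.5)
  cond <- solution_conditions(25, 0.01)      # z -> 0, uncharged
  sh <- leip_corrections()
  expect_lt(phi0(sh, ch, pars, cond, mode = "rigid"), 1e-12)
  # rigid N=3: single long-range pair (1,3) at distance 2b
  cond2 <- solution_conditions(7, 0.01)
  ob <- sb_observables(3, 10^(9 - 7), pars$u, pairs = rbind(c(1, 3)))
  pot <- screened_potential(0.01)
  expect_equal(phi0(sh, ch, pars, cond2, mode = "rigid"),
               dh_pair(2 * 0.2, pot) * ob$pair_corr$h, tolerance = 1e-12)
  # saturation: h_ij -> 1, phi0 -> plain pair sum
  condsat <- solution_conditions(-12, 0.01)
  n <- 5
  ch5 <- rigid_chain(n)
  plain <- 0
  for (i in 1:(n - 2)) for (j in (i + 2):n)
    plain <- plain + dh_pair((j - i) * 0.2, pot)
  expect_equal(phi0(sh, ch5, pars, condsat, mode = "rigid"), plain,
               tolerance = 1e-6)
})

test_that("LR disabled pins every correction to zero", {
  ch <- rigid_chain(8)
  pars <- energy_params(pK = 9, epsilon = 1.5)
  cond <- solution_conditions(7, 0.01, lr_enabled = FALSE)
  s1 <- solve_rigid(ch, pars, cond, correct_eps = TRUE)
  expect_identical(c(s1$x, s1$x_eps), c(0, 0))
  expect_true(s1$converged)
  chf <- minimal_chain(6)
  s2 <- solve_flexible(chf, study_params(), cond)
  expect_identical(c(s2$x, s2$x_sigma), c(0, 0))
})

test_that("x grows as the ionic strength drops (weaker screening)", {
  ch <- rigid_chain(10)
  pars <- energy_params(pK = 9, epsilon = 1.5)
  xs <- vapply(c(1, 0.1, 0.01, 0.001), function(I)
    solve_rigid(ch, pars, solution_conditions(7, I))$x, numeric(1))
  expect_true(all(diff(xs) > 0))
  expect_true(all(xs >= 0))
})

test_that("rigid LEIP titration tracks full-LR enumeration within 0.01", {
  ch <- rigid_chain(10)
  pars <- energy_params(pK = 9, epsilon = 1.5)
  start <- NULL
  for (p in seq(12, 3, by = -1)) {
    cond <- solution_conditions(p, 0.01)
    sol <- solve_rigid(ch, pars, cond, start = start)
    start <- sol$x
    expect_true(sol$converged)
    th <- mean(sb_observables(10, 10^(9 - sol$x - p), pars$u)$theta)
    ex <- mean(enumerate_rigid(10, pars, cond)$theta)
    expect_lt(abs(th - ex), 0.011)
  }
})

test_that("flexible LEIP matches full roto-microstate enumeration within 0.02", {
  ch <- minimal_chain(3)
  pars <- study_params(sigma = 10, u_g = 0)
  start <- NULL
  for (p in seq(12, 3, by = -1)) {
    cond <- solution_conditions(p, 0.01)
    sol <- solve_flexible(ch, pars, cond, start = start)
    start <- c(sol$x, sol$x_sigma)
    expect_true(sol$converged)
    ob <- sbris_observables(ch, pars, p, sol)
    en <- enumerate_sbris(ch, pars, cond)
    expect_lt(abs(mean(ob$theta) - mean(en$theta)), 0.02)
    expect_lt(abs(mean(ob$p_gauche) - mean(en$p_gauche)), 0.02)
  }
})

test_that("x_sigma vanishes at high pH", {
  ch <- minimal_chain(10)
  pars <- study_params(sigma = 10, u_g = 0)
  sol <- solve_flexible(ch, pars, solution_conditions(13, 0.01))
  expect_lt(abs(sol$x_sigma), 1e-3)
  expect_lt(abs(sol$x), 1e-2)
})

test_that("Gibbs-Bogoliubov bound dominates the exact free energy", {
  ch <- rigid_chain(8)
  pars <- energy_params(pK = 9, epsilon = 1.5)
  set.seed(31)
  for (p in c(5, 7, 9)) {
    cond <- solution_conditions(p, 0.01)
    ex <- enumerate_rigid(8, pars, cond)
    sol <- solve_rigid(ch, pars, cond)
    b_opt <- gb_bound(sol, ch, pars, cond)
    expect_gte(b_opt, ex$Omega - 1e-9)
    # arbitrary shifts still bound from above
    for (k in 1:4) {
      sh <- leip_corrections(x = runif(1, -0.5, 1.5),
                             x_eps = runif(1, -0.3, 0.3))
      expect_gte(gb_bound(sh, ch, pars, cond), ex$Omega - 1e-9)
    }
    # local minimum at the solution
    for (dx in c(-0.1, 0.1)) {
      sh <- leip_corrections(x = sol$x + dx)
      expect_gt(gb_bound(sh, ch, pars, cond), b_opt)
    }
  }
})

test_that("bound is stationary and consistent with the derivative forms", {
  # flexible chain: numerical stationarity of the bound at the solution
  ch <- minimal_chain(4)
  pars <- study_params(sigma = 10, u_g = 0)
  cond <- solution_conditions(6, 0.01)
  sol <- solve_flexible(ch, pars, cond)
  b0 <- gb_bound(sol, ch, pars, cond)
  d <- 1e-3
  for (k in 1:2) {
    sp <- leip_corrections(x = sol$x + d * (k == 1),
                           x_sigma = sol$x_sigma + d * (k == 2))
    sm <- leip_corrections(x = sol$x - d * (k == 1),
                           x_sigma = sol$x_sigma - d * (k == 2))
    grad <- (gb_bound(sp, ch, pars, cond) -
               gb_bound(sm, ch, pars, cond)) / (2 * d)
    expect_lt(abs(grad), 5e-3)   # first-order stationary
    expect_gt(gb_bound(sp, ch, pars, cond), b0 - 1e-10)
    expect_gt(gb_bound(sm, ch, pars, cond), b0 - 1e-10)
  }
  # Gibbs-Bogoliubov inequality with the exactly enumerated <Delta H>_0:
  # the production bound replaces <phi(d) s_i s_j> by the factorized
  # phi(sqrt(<d^2>)) <s_i s_j>, which can undershoot by the truncation
  # error, so the strict inequality is asserted on the exact average
  ex <- enumerate_sbris(ch, pars, cond)
  sh_pars <- energy_params(pK = pars$pK - sol$x,
                           sigma = pars$sigma * 10^(-sol$x_sigma),
                           u_t = pars$u_t, u_g = pars$u_g)
  en0 <- enumerate_sbris(ch, sh_pars, cond, include_lr = FALSE)
  pot <- screened_potential(cond$ionic_strength)
  n <- ch$n_sites
  phi0_ex <- 0
  for (kc in seq_len(nrow(en0$states$c))) {
    pos <- site_positions(en0$states$c[kc, ], ch, sites_only = TRUE)
    for (ks in seq_len(nrow(en0$states$s))) {
      w <- 10^(en0$log_weights[ks, kc] - en0$log_partition / log(10))
      s <- en0$states$s[ks, ]
      for (i in seq_len(n - 2)) for (j in (i + 2):n)
        if (s[i] && s[j])
          phi0_ex <- phi0_ex +
            w * dh_pair(sqrt(sum((pos[j, ] - pos[i, ])^2)), pot)
    }
  }
  b_exact_dh <- -en0$log_partition + log(10) *
    (phi0_ex - sol$x * en0$nu - sol$x_sigma * en0$g)
  expect_gte(b_exact_dh, ex$Omega - 1e-9)
  # the factorized production bound sits within the truncation error
  expect_gte(b0, ex$Omega - 0.05)
  # LR off: bound equals Omega0 equals the exact Omega
  coff <- solution_conditions(6, 0.01, lr_enabled = FALSE)
  sh0 <- leip_corrections()
  exoff <- enumerate_sbris(ch, pars, coff, include_lr = FALSE)
  expect_equal(gb_bound(sh0, ch, pars, coff), exoff$Omega,
               tolerance = 1e-9)
})

test_that("frozen flexible chain reduces to the rigid solver", {
  ch <- minimal_chain(8)
  pars <- energy_params(pK = 9, sigma = 0, u_t = 10^(-1.5))
  cond <- solution_conditions(7, 0.01)
  solf <- solve_flexible(ch, pars, cond)   # var(g)=0 -> x_sigma pinned
  expect_identical(solf$x_sigma, 0)
  rch <- rigid_chain(8)
  rpars <- energy_params(pK = 9, epsilon = 1.5)
  dmat <- as.matrix(dist(site_positions(rep(1, 7), ch, sites_only = TRUE)))
  solr <- solve_rigid(rch, rpars, cond, distances = dmat)
  expect_equal(solf$x, solr$x, tolerance = 1e-7)
})

test_that("titration grids: ideal limit, warm-start continuation, schema", {
  # eps_t = 0 and LR off: exact Henderson-Hasselbalch
  ch <- minimal_chain(5)
  pars <- energy_params(pK = 9, sigma = 1, u_t = 1)
  tt <- titrate(ch, pars, pH = c(7, 8, 9, 10), ionic_strength = 0.1,
                lr_enabled = FALSE)
  expect_equal(tt$theta, 1 / (1 + 10^(tt$pH - 9)), tolerance = 1e-10)
  expect_true(all(c("pH", "ionic_strength", "theta", "p_gauche", "x",
                    "x_sigma", "omega0", "omega_bound", "converged",
                    "iterations", "residual") %in% names(tt)))
  # theta decreases with pH, p_gauche within [0, 1], all points converged
  pars2 <- study_params(sigma = 10, u_g = 0)
  tt2 <- titrate(minimal_chain(12), pars2, pH = seq(11, 3, by = -1),
                 ionic_strength = 0.01)
  expect_true(all(tt2$converged))
  o <- order(tt2$pH)
  expect_true(all(diff(tt2$theta[o]) < 1e-8))
  expect_true(all(tt2$p_gauche >= 0 & tt2$p_gauche <= 1))
  expect_true(all(is.finite(tt2$omega_bound)))
})
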