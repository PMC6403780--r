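test_that("SB partition function matches closed forms and enumeration", {
  z <- 2.3
  expect_equal(exp(sb_partition(1, z, 0.7)), 1 + z)
  # independent sites
  expect_equal(sb_partition(6, z, 1), 6 * log(1 + z))
  # N=3, z=1, u=0.5: brute-force over the 8 ionization states
  # (states 110 and 011 carry u, 111 carries u^2): Xi = 6.25
  expect_equal(exp(sb_partition(3, 1, 0.5)), 6.25, tolerance = 1e-12)
  en <- enumerate_rigid(3, energy_params(pK = 9, u = 0.5),
                        solution_conditions(9, 1, lr_enabled = FALSE),
                        include_lr = FALSE)
  expect_equal(sb_partition(3, 1, 0.5), en$log_partition,
               tolerance = 1e-12)
})

test_that("SB observables are exact (projector route vs enumeration)", {
  ob <- sb_observables(1, 1, 1)
  expect_equal(ob$theta, 0.5)
  ob6 <- sb_observables(6, 2.5, 1)
  expect_equal(ob6$theta, rep(2.5 / 3.5, 6))
  # N=3, z=1, u=0.5: theta_middle = 2.25/6.25
  ob3 <- sb_observables(3, 1, 0.5, pairs = rbind(c(1, 2), c(1, 3)))
  expect_equal(ob3$theta[2], 0.36, tolerance = 1e-12)
  en <- enumerate_rigid(3, energy_params(pK = 9, u = 0.5),
                        solution_conditions(9, 1, lr_enabled = FALSE),
                        include_lr = FALSE)
  expect_equal(ob3$theta, en$theta, tolerance = 1e-12)
  expect_equal(ob3$pair_corr$h, c(en$h[1, 2], en$h[1, 3]),
               tolerance = 1e-12)
  expect_error(sb_observables(3, 1, 0.5, pairs = rbind(c(1, 5))),
               "out of range")
})

test_that("RIS gauche fraction reproduces the analytic limits", {
  expect_equal(ris_gauche_fraction(10, 1)$fraction, 2 / 3,
               tolerance = 1e-12)
  expect_equal(ris_gauche_fraction(10, 10)$fraction, 20 / 21,
               tolerance = 1e-12)
  expect_equal(ris_gauche_fraction(5, 0)$fraction, 0)
  expect_equal(exp(ris_gauche_fraction(1, 2)$log_partition), 5)
})

test_that("SBRIS engine equals enumeration on randomized small systems", {
  set.seed(101)
  for (k in 1:25) {
    n <- sample(2:4, 1)
    ch <- chain_spec(n, spacing = sample(2:3, 1))
    pars <- random_params()
    pH <- runif(1, 2, 12)
    en <- enumerate_sbris(ch, pars,
                          solution_conditions(pH, 0.1, lr_enabled = FALSE),
                          include_lr = FALSE)
    expect_lt(rel_err(sbris_partition(ch, pars, pH), en$log_partition),
              1e-10)
    ob <- sbris_observables(ch, pars, pH,
                            pairs = cbind(1, n))
    expect_lt(max(rel_err(ob$theta, en$theta)), 1e-10)
    expect_lt(max(rel_err(ob$p_gauche, en$p_gauche)), 1e-10)
    expect_lt(rel_err(ob$nu, en$nu), 1e-10)
    expect_lt(rel_err(ob$D + 1, en$D + 1), 1e-10)
    expect_lt(rel_err(ob$pair_corr$h + 1, en$h[1, n] + 1), 1e-10)
  }
})

test_that("SBRIS limits: deprotonated -> RIS; frozen trans -> SB", {
  ch <- minimal_chain(5)
  pars <- energy_params(pK = 9, sigma = 1.8, u_t = 0.4, u_g = 0.1)
  # z -> 0: partition reduces to the neutral RIS chain
  lp <- sbris_partition(ch, pars, pH = 25)
  expect_equal(lp, ris_gauche_fraction(4, 1.8)$log_partition,
               tolerance = 1e-8)
  # sigma -> 0: all-trans frozen, reduces to SB with u = u_t
  pars0 <- energy_params(pK = 9, sigma = 0, u_t = 0.4, u_g = 0.1)
  pH <- 8.2
  lp0 <- sbris_partition(ch, pars0, pH)
  expect_equal(lp0, sb_partition(5, 10^(9 - pH), 0.4), tolerance = 1e-10)
})

test_that("projector theta agrees with finite differences of ln Xi in mu_i", {
  # heterogeneous per-site activity via a custom matrix list
  ch <- minimal_chain(4)
  pars <- energy_params(pK = 9, sigma = 2, psi = 0.7, omega = 1.2,
                        u_t = 0.5, u_g = 0.2)
  pH <- 8.4
  base <- leip:::sbris_ctx(ch, pars, pH)
  th <- vapply(1:4, function(i) leip:::tm_single(base, i - 1L, "site"),
               numeric(1))
  U <- leip:::ris_matrix(2, 0.7, 1.2)
  z0 <- 10^(9 - pH)
  lnXi <- function(zs) {
    mats <- lapply(2:4, function(i)
      leip:::sbris_matrix(zs[i], U, 0.5, 0.2))
    ctx <- leip:::tm_ctx(mats, r = c(1, 0, 0, zs[1], 0, 0), tv = rep(1, 6))
    ctx$logXi   # decimal log
  }
  d <- 1e-4
  for (i in 1:4) {
    zp <- rep(z0, 4); zm <- rep(z0, 4)
    zp[i] <- z0 * 10^(d); zm[i] <- z0 * 10^(-d)   # mu_i -> mu_i -/+ d
    fd <- (lnXi(zp) - lnXi(zm)) / (2 * d)
    expect_equal(th[i], fd, tolerance = 1e-6)
  }
})

test_that("gauche+ and gauche- are equally probable in the symmetric chain", {
  ch <- minimal_chain(4)
  pars <- energy_params(pK = 9, sigma = 2.2, psi = 0.8, omega = 1.1,
                        u_t = 0.5, u_g = 0.3)
  ctx <- leip:::sbris_ctx(ch, pars, 7.5)
  for (a in 1:3) {
    pp <- leip:::tm_single(ctx, a, "gplus")
    pm <- leip:::tm_single(ctx, a, "gminus")
    expect_equal(pp, pm, tolerance = 1e-12)
  }
})

test_that("shifts enter as pK - x and p_sigma + x_sigma", {
  ch <- minimal_chain(4)
  pars <- energy_params(pK = 9, sigma = 2, u_t = 0.5)
  sh <- leip_corrections(x = 0.8, x_sigma = 0.3)
  ob <- sbris_observables(ch, pars, 7, shifts = sh)
  pars_eq <- energy_params(pK = 9 - 0.8, sigma = 2 * 10^(-0.3), u_t = 0.5)
  ob_eq <- sbris_observables(ch, pars_eq, 7)
  expect_equal(ob$theta, ob_eq$theta, tolerance = 1e-12)
  expect_equal(ob$p_gauche, ob_eq$p_gauche, tolerance = 1e-12)
})

test_that("log-domain scan stays finite for N = 50 at extreme pH", {
  ch <- chain_spec(50)
  pars <- study_params()
  for (pH in c(-2, 2, 16)) {
    lp <- sbris_partition(ch, pars, pH)
    expect_true(is.finite(lp))
    ob <- sbris_observables(ch, pars, pH)
    expect_true(all(is.finite(ob$theta)))
    expect_true(all(ob$theta >= 0 & ob$theta <= 1))
    expect_true(all(ob$p_gauche >= 0 & ob$p_gauche <= 1))
  }
})
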