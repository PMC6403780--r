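test_that("coordinates preserve bond lengths and valence angles", {
  set.seed(3)
  ch <- chain_spec(5)
  for (k in 1:5) {
    cc <- sample(1:3, 4, replace = TRUE)
    r <- site_positions(cc, ch)
    bonds <- diff(r)
    expect_equal(sqrt(rowSums(bonds^2)), rep(0.2, ch$n_bonds),
                 tolerance = 1e-12)
    for (nd in 2:(ch$n_nodes - 1)) {
      a <- r[nd - 1, ] - r[nd, ]; b <- r[nd + 1, ] - r[nd, ]
      ang <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
      expect_equal(ang, 120, tolerance = 1e-9)
    }
  }
})

test_that("all-trans chain is a planar zigzag matching direct trigonometry", {
  ch <- chain_spec(3)
  r <- site_positions(c(1, 1), ch)
  expect_true(all(abs(r[, 3]) < 1e-12))          # planar
  # successive bond vectors alternate +/-60 degrees about x:
  # every second node advances by 2 * l * cos(30 deg) along x
  l <- 0.2
  expect_equal(unname(r[3, 1] - r[1, 1]), l + l * cos(pi / 3),
               tolerance = 1e-12)
  expect_equal(unname(r[3, 2] - r[1, 2]), l * sin(pi / 3),
               tolerance = 1e-12)
  # distance between sites 1 and 2 (nodes 1 and 4) by hand:
  d14 <- sqrt(sum((r[4, ] - r[1, ])^2))
  hand <- sqrt((2 * l + l * cos(pi / 3))^2 + (l * sin(pi / 3))^2)
  expect_equal(d14, hand, tolerance = 1e-12)
})

test_that("rotating one bond is a rigid motion of the downstream part", {
  ch <- chain_spec(4)
  base <- site_positions(c(1, 1, 1), ch)
  rot <- site_positions(c(1, 2, 1), ch)      # rotate the middle c bond
  jb <- ch$rotatable_bonds[2]                 # 1-based bond index
  up <- seq_len(jb + 1L)                      # nodes up to the bond end
  expect_equal(rot[up, ], base[up, ], tolerance = 1e-12)
  # downstream pairwise distances are preserved (rigid rotation)
  dn <- (jb + 2L):ch$n_nodes
  expect_equal(as.matrix(dist(rot[dn, ])), as.matrix(dist(base[dn, ])),
               tolerance = 1e-12)
  # and distances among upstream nodes unchanged trivially
  expect_equal(as.matrix(dist(rot[up, ])), as.matrix(dist(base[up, ])),
               tolerance = 1e-12)
})

test_that("dihedral states map to 180/+60/-60 torsions", {
  ch <- chain_spec(3)
  tors <- function(r, k) {  # torsion about bond k (nodes k, k+1)
    b1 <- r[k, ] - r[k - 1, ]; b2 <- r[k + 1, ] - r[k, ]
    b3 <- r[k + 2, ] - r[k + 1, ]
    n1 <- leip:::cross3(b1, b2); n2 <- leip:::cross3(b2, b3)
    m1 <- leip:::cross3(n1, b2 / sqrt(sum(b2^2)))
    atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  }
  for (st in 1:3) {
    r <- site_positions(c(st, 1), ch)
    phi <- tors(r, ch$rotatable_bonds[1])
    target <- c(180, 60, -60)[st]
    expect_equal(abs(phi), abs(target), tolerance = 1e-9)
    if (st > 1) expect_equal(sign(phi), sign(target))
  }
})

test_that("mean square distances agree exactly with enumeration", {
  set.seed(23)
  for (k in 1:8) {
    n <- sample(3:4, 1)
    ch <- chain_spec(n, spacing = sample(2:3, 1))
    pars <- random_params()
    pH <- runif(1, 3, 11)
    en <- enumerate_sbris(ch, pars,
                          solution_conditions(pH, 0.1, lr_enabled = FALSE),
                          include_lr = FALSE)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      expect_lt(rel_err(mean_square_distance(i, j, ch, pars, pH),
                        en$msd[i, j]), 1e-10)
      if (is.finite(en$msd_cond[i, j]))
        expect_lt(rel_err(mean_square_distance(i, j, ch, pars, pH,
                                               conditional = TRUE),
                          en$msd_cond[i, j]), 1e-10)
    }
  }
})

test_that("frozen and free limits of the distance average", {
  ch <- chain_spec(4)
  pars0 <- energy_params(pK = 9, sigma = 0)
  r <- site_positions(c(1, 1, 1), ch, sites_only = TRUE)
  for (j in 2:4)
    expect_equal(mean_square_distance(1, j, ch, pars0, 7),
                 sum((r[j, ] - r[1, ])^2), tolerance = 1e-10)
  # uncharged sigma=1 chain: plain average over equally weighted conformers
  ch3 <- chain_spec(3)
  p1 <- energy_params(pK = 9, sigma = 1)
  confs <- expand.grid(1:3, 1:3)
  d2 <- apply(confs, 1, function(cc) {
    p <- site_positions(as.integer(cc), ch3, sites_only = TRUE)
    sum((p[3, ] - p[1, ])^2)
  })
  expect_equal(mean_square_distance(1, 3, ch3, p1, 20), mean(d2),
               tolerance = 1e-9)
  # bounded by the all-trans (maximal) squared distance
  set.seed(5)
  for (k in 1:5) {
    pars <- random_params()
    v <- mean_square_distance(1, 4, ch, pars, runif(1, 3, 11))
    rmax <- site_positions(c(1, 1, 1), ch, sites_only = TRUE)
    expect_lte(v, sum((rmax[4, ] - rmax[1, ])^2) + 1e-12)
    expect_gt(v, 0)
  }
  expect_error(mean_square_distance(2, 2, ch, pars0, 7), "differ")
})

test_that("xyz writer round-trips node counts and coordinates", {
  ch <- chain_spec(3)
  f <- tempfile(fileext = ".xyz")
  write_xyz(list(c(1, 1), c(2, 3)), ch, f, s = list(c(1, 0, 0), c(0, 1, 1)))
  lines <- readLines(f)
  expect_equal(length(lines), 2 * (2 + ch$n_nodes))
  expect_equal(as.integer(lines[1]), ch$n_nodes)
  r <- site_positions(c(1, 1), ch)
  first <- as.numeric(strsplit(lines[3], " ")[[1]][2:4])
  expect_equal(first, unname(r[1, ]), tolerance = 1e-6)
  unlink(f)
})
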