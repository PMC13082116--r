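test_that("local gain follows the damped-oscillator closed form", {
  expect_equal(local_gain(0, 10, 0.3), 1 + 0i)
  # at resonance l = 1 / (2 i zeta): magnitude 1/(2 zeta), phase -pi/2
  l <- local_gain(10, 10, 0.5)
  expect_equal(Mod(l), 1.0)
  expect_equal(Arg(l), -pi / 2)
  expect_equal(Mod(local_gain(10, 10, 0.3)), 1 / 0.6, tolerance = 1e-12)
  expect_error(local_gain(5, -1, 0.3), class = "walksum_error_params")
})

test_that("bare resolvent reduces to the identity and to (I - C)^(-1)", {
  n <- 5
  cn0 <- connectome(matrix(0, n, n),
                    matrix(20, n, n) - diag(20, n))
  H <- bare_resolvent(cn0)
  for (k in c(1, 45, 89))
    expect_equal(H$H[, , k], diag(1 + 0i, n))

  cn <- random_connectome(3)
  Hdc <- walksum:::resolvent_matrix(cn$weights, 0, 0.01)
  expect_equal(Im(Hdc), matrix(0, nrow(Hdc), ncol(Hdc)))
  expect_equal(Re(Hdc), solve(diag(nrow(Hdc)) - cn$weights))
})

test_that("two-node bare resolvent matches the hand closed form and the walk oracle", {
  c12 <- 0.5
  cn <- connectome(matrix(c(0, c12, c12, 0), 2), matrix(c(0, 60, 60, 0), 2))
  for (sgn in c(-1, 1)) {
    f <- 10; T <- 0.010
    z <- exp(sgn * 2i * pi * f * T)
    hand <- matrix(c(1, z * c12, z * c12, 1), 2) / (1 - z^2 * c12^2)
    H <- bare_resolvent(cn, frequency_grid(c(5, 10)), phase_sign = sgn)
    expect_equal(H$H[, , 2], hand, tolerance = 1e-12)
    S <- walk_sum_truncated(cn, 10, K = 500, phase_sign = sgn)
    expect_lt(max(Mod(H$H[, , 2] - S)), 1e-10)
  }
})

test_that("truncated walk sum obeys its defining recursion and tail bound", {
  cn <- random_connectome(11, n = 6, radius = 0.5)
  z <- exp(-2i * pi * 10 * 0.01)
  expect_equal(walk_sum_truncated(cn, 10, K = 0), diag(1 + 0i, 6))
  expect_equal(walk_sum_truncated(cn, 10, K = 1),
               diag(1 + 0i, 6) + z * cn$weights)
  K <- 60
  H <- bare_resolvent(cn, frequency_grid(10))
  err <- max(Mod(H$H[, , 1] - walk_sum_truncated(cn, 10, K = K)))
  expect_lt(err, max(0.5^(K + 1) / (1 - 0.5), 1e-12))
})

test_that("dressed resolvent honours both operator readings", {
  n <- 3
  cn0 <- connectome(matrix(0, n, n), matrix(25, n, n) - diag(25, n))
  g <- frequency_grid(c(5, 10, 20))
  l <- local_gain(g$f, 10, 0.3)
  Hlit <- dressed_resolvent(cn0, g, 10, 0.3, reading = "literal")
  Hgain <- dressed_resolvent(cn0, g, 10, 0.3, reading = "gain")
  for (k in 1:3) {
    expect_equal(Hlit$H[, , k], diag(1 / l[k], n), tolerance = 1e-12)
    expect_equal(Hgain$H[, , k], diag(l[k], n), tolerance = 1e-12)
  }

  # l -> 1 limit: dressing vanishes, both readings collapse onto bare
  cn <- random_connectome(5, n = 6, radius = 0.6)
  Hb <- bare_resolvent(cn, g)
  for (rd in c("literal", "gain")) {
    Hd <- dressed_resolvent(cn, g, omega0 = 1e5, zeta = 1e-5, reading = rd)
    expect_equal(Hd$H, Hb$H, tolerance = 1e-6)
  }
})

test_that("dressed readings match their own truncated series", {
  c12 <- 0.5
  cn <- connectome(matrix(c(0, c12, c12, 0), 2), matrix(c(0, 60, 60, 0), 2))
  g <- frequency_grid(8)
  l <- local_gain(8, 10, 0.3)
  # gain reading: sum_k l^(k+1) (z C)^k
  Hg <- dressed_resolvent(cn, g, 10, 0.3, reading = "gain")
  Sg <- walk_sum_truncated(cn, 8, K = 500, omega0 = 10, zeta = 0.3)
  expect_lt(max(Mod(Hg$H[, , 1] - Sg)), 1e-10)
  # literal reading: (l I - l z C)^(-1) = (1/l) sum_k (z C)^k
  Hl <- dressed_resolvent(cn, g, 10, 0.3, reading = "literal")
  Sl <- walk_sum_truncated(cn, 8, K = 500) / l
  expect_lt(max(Mod(Hl$H[, , 1] - Sl)), 1e-10)
})

test_that("group-wise dressing reduces to the homogeneous case and to hand algebra", {
  cn <- make_connectome(synth_config(n_nodes = 12, seed = 8))
  part <- partition_by_degree(cn)
  g <- frequency_grid(c(6, 11))
  pm <- matrix(rep(c(9, 0.25), each = 3), nrow = 3,
               dimnames = list(NULL, c("omega0", "zeta")))
  for (rd in c("literal", "gain")) {
    Hhet <- heterogeneous_dressed_resolvent(cn, g, part, pm, reading = rd)
    Hhom <- dressed_resolvent(cn, g, 9, 0.25, reading = rd)
    expect_equal(Hhet$H, Hhom$H, tolerance = 1e-12)
  }

  # three nodes, three single-node groups: hand-built diagonal gain algebra
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 0.3; W[2, 3] <- W[3, 2] <- 0.2
  D <- matrix(35, 3, 3); diag(D) <- 0
  cn3 <- connectome(W, D)
  p3 <- partition_by_degree(cn3, n_groups = 3)
  pm3 <- cbind(omega0 = c(11, 9, 7), zeta = c(0.2, 0.3, 0.4))
  f <- 9; z <- exp(-2i * pi * f * 0.01)
  lvec <- sapply(p3$group_of + 1, function(r)
    local_gain(f, pm3[r, "omega0"], pm3[r, "zeta"]))
  L <- diag(lvec)
  hand_lit <- solve(L - L %*% (z * cn3$weights))
  hand_gain <- solve(diag(3) - L %*% (z * cn3$weights)) %*% L
  Hl <- heterogeneous_dressed_resolvent(cn3, frequency_grid(f), p3, pm3,
                                        reading = "literal")
  Hg <- heterogeneous_dressed_resolvent(cn3, frequency_grid(f), p3, pm3,
                                        reading = "gain")
  expect_equal(Hl$H[, , 1], hand_lit, tolerance = 1e-12)
  expect_equal(Hg$H[, , 1], hand_gain, tolerance = 1e-12)

  # the fitted hub/non-hub parameter pattern runs cleanly on a hub network
  pm_fit <- cbind(omega0 = c(7.5, 6.5, 6.0), zeta = c(0.20, 0.15, 0.15))
  Hfit <- heterogeneous_dressed_resolvent(fixture_connectome(),
                                          frequency_grid(c(8, 10)),
                                          partition_by_degree(fixture_connectome()),
                                          pm_fit)
  expect_true(all(is.finite(Mod(Hfit$H))))
})

test_that("field symmetries: conjugate frequency, zero delay, channel recomposition", {
  cn <- random_connectome(9, n = 8, radius = 0.7)
  for (sgn in c(-1, 1)) {
    Hp <- walksum:::resolvent_matrix(cn$weights, 12, 0.01, phase_sign = sgn)
    Hm <- walksum:::resolvent_matrix(cn$weights, -12, 0.01, phase_sign = sgn)
    expect_equal(Hm, Conj(Hp), tolerance = 1e-12)
  }
  # T = 0 and no dressing: purely real transfer (Q identically zero)
  H0 <- walksum:::resolvent_matrix(cn$weights, 12, 0)
  expect_equal(Im(H0), matrix(0, 8, 8))

  H <- bare_resolvent(cn, frequency_grid(c(4, 17)))
  expect_equal(channel_I(H) + 1i * channel_Q(H), H$H)
  expect_equal(channel_Q(H, abs = TRUE), abs(Im(H$H)))

  # the two phase conventions are complex conjugates of each other
  Hm1 <- bare_resolvent(cn, frequency_grid(c(4, 17)), phase_sign = -1)
  Hp1 <- bare_resolvent(cn, frequency_grid(c(4, 17)), phase_sign = +1)
  expect_equal(Hm1$H, Conj(Hp1$H), tolerance = 1e-14)
})

test_that("off-diagonal phase is continuous across the default grid", {
  cn <- connectome(matrix(c(0, 0.6, 0.6, 0), 2), matrix(c(0, 70, 70, 0), 2))
  H <- bare_resolvent(cn)
  ph <- Arg(H$H[1, 2, ])
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi       # wrap into (-pi, pi]
  expect_lt(max(abs(dph)), 0.5)
})

test_that("field serialisation round-trips", {
  cn <- random_connectome(21, n = 5, radius = 0.5)
  H <- dressed_resolvent(cn, frequency_grid(c(3, 7)), 9, 0.3)
  dir <- tempfile()
  write_field(H, dir)
  H2 <- read_field(dir)
  expect_equal(H2$H, H$H, tolerance = 1e-14)
  expect_equal(H2$f, H$f)
  expect_equal(H2$reading, H$reading)
})
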