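test_that("distance binning follows the half-open equal-width rule", {
  b <- bin_by_distance(c(1, 2, 3), c(10, 50, 90), n_bins = 2)
  expect_equal(b$edges, c(10, 50, 90))
  expect_equal(b$count, c(1, 2))           # [10,50) holds d=10; [50,90] rest
  expect_equal(b$mean, c(1, 2.5))

  # constant field: every nonempty bin mean equals the constant
  d <- runif(40, 5, 100)
  bc <- bin_by_distance(rep(3.3, 40), d, n_bins = 5)
  expect_true(all(abs(bc$mean[!bc$empty] - 3.3) < 1e-12))
  expect_equal(sum(bc$count), 40)

  # zero / missing distances are excluded but counted
  bz <- bin_by_distance(1:5, c(0, 10, 20, NA, 30), n_bins = 2)
  expect_equal(bz$n_excluded, 2)
  expect_equal(sum(bz$count), 3)

  expect_error(bin_by_distance(1:3, c(5, 5, 5)), class = "walksum_error_bins")
  expect_error(bin_by_distance(1:3, c(1, 2, 3), n_bins = 1),
               class = "walksum_error_bins")
})

test_that("profile bin counts cover the upper triangle", {
  cn <- fixture_connectome()
  H <- bare_resolvent(cn, frequency_grid(c(5, 10)))
  prof <- distance_profile(H, cn$distances)
  n <- nrow(cn$weights)
  expect_equal(sum(prof$count) + prof$n_excluded, n * (n - 1) / 2)
  expect_equal(dim(prof$mean_I), c(20, 2))
})

test_that("channel-distance correlation is a midrank Spearman", {
  f <- frequency_grid(10)
  # monotone increasing channel values with distance -> rho = 1
  n <- 6
  D <- as.matrix(dist(cbind(seq(0, 100, length.out = n), 0, 0)))
  Hm <- array(0i, c(n, n, 1))
  Hm[, , 1] <- D + 1i * D^1.3              # any increasing transform
  fld <- as_field(Hm, 10)
  expect_equal(channel_distance_rho(fld, D, "I", 10), 1)
  expect_equal(channel_distance_rho(fld, D, "Q", 10), 1)

  # constant channel -> degenerate ranks -> NA
  Hc <- array(2 + 0i, c(n, n, 1))
  expect_true(is.na(channel_distance_rho(as_field(Hc, 10), D, "I", 10)))

  # ties handled by midranks: agree with the brute-force oracle
  set.seed(4)
  for (r in 1:10) {
    x <- sample(1:8, 30, replace = TRUE)     # heavy ties
    y <- runif(30)
    expect_equal(suppressWarnings(cor(x, y, method = "spearman")),
                 spearman_brute(x, y), tolerance = 1e-12)
  }

  expect_error(channel_distance_rho(fld, D, "Q", 10, min_distance = 1000),
               class = "walksum_error_pairs")

  # min-distance thresholding restricts the pair set
  rho_all <- channel_distance_rho(fld, D, "Q", 10)
  rho_far <- channel_distance_rho(fld, D, "Q", 10, min_distance = 50)
  expect_equal(rho_far, 1)
  expect_equal(rho_all, 1)
})

test_that("crossover localisation interpolates between grid points", {
  f <- seq(11.5, 14, by = 0.5)
  expect_equal(q_crossover(c(0.4, 0.3, 0.10, -0.15, 0.1, 0.2), f), 12.70)
  expect_true(is.na(q_crossover(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), f)))
  expect_equal(q_crossover(c(0.3, 0.2, 0, -0.1, -0.2, -0.3), f), 12.5)
  # a leading negative stretch is ignored until rho first turns positive
  expect_equal(q_crossover(c(-0.2, 0.2, 0.2, -0.2, -0.3, -0.1), f),
               12.5 + 0.5 * 0.2 / 0.4)
})

test_that("divergence and convergence frequency follow the argmin tie rules", {
  f <- seq(1, 3, by = 0.5)
  d <- channel_divergence(rep(0.2, 5), rep(0.2, 5), f)
  expect_equal(d$D, rep(0, 5))
  expect_equal(d$omega_c, 1)               # ties -> lowest frequency
  d2 <- channel_divergence(c(0, 0, 0, 0, 0), c(0.1, -0.3, 0.2, -0.3, 0.4), f)
  expect_equal(d2$omega_c, 1.5)
  # adding a constant to both series leaves D unchanged
  d3 <- channel_divergence(c(0, 0, 0, 0, 0) + 0.7,
                           c(0.1, -0.3, 0.2, -0.3, 0.4) + 0.7, f)
  expect_equal(d3$D, d2$D)
})

test_that("salience is the combined pair variance of the two channels", {
  n <- 5
  cn0 <- connectome(matrix(0, n, n), matrix(30, n, n) - diag(30, n))
  H0 <- bare_resolvent(cn0, frequency_grid(c(5, 10)))
  expect_equal(salience(H0), c(0, 0))

  H <- bare_resolvent(fixture_connectome(), frequency_grid(c(5, 10, 20)))
  S <- salience(H)
  brute <- sapply(1:3, function(k) {
    M <- H$H[, , k]
    var(Re(M)[upper.tri(M)]) + var(Im(M)[upper.tri(M)])
  })
  expect_equal(S, brute, tolerance = 1e-12)
  # variance is homogeneous of degree 2
  H2 <- H; H2$H <- 3 * H$H
  expect_equal(salience(H2), 9 * S, tolerance = 1e-12)
  expect_equal(max(salience(H, normalise = TRUE)), 1)
})

test_that("the prediction battery produces a complete, hand-checkable report", {
  cn <- fixture_connectome()
  H <- fixture_bare()
  rep <- evaluate_predictions(H, cn$distances, n_perm = 200)
  expect_s3_class(rep, "channel_report")
  for (cc in c("c1", "c2", "c3", "c4", "c5"))
    expect_true(is.logical(rep[[cc]]$pass))
  expect_equal(rep$divergence, rep$rho_Q - rep$rho_I)

  # C3 verdict equals a direct recomputation of the 80 mm bin
  prof <- distance_profile(H, cn$distances)
  lr_bin <- findInterval(80, prof$edges, rightmost.closed = TRUE,
                         all.inside = TRUE)
  bands <- band_scheme()
  by_band <- sapply(seq_len(nrow(bands)), function(b) {
    sel <- H$f >= bands$f_lo[b] & H$f <= bands$f_hi[b]
    mean(prof$mean_I[lr_bin, sel])
  })
  expect_equal(isTRUE(all(by_band > 0)), rep$c3$pass)
  expect_equal(unname(rep$c3$band_I_long_range), by_band, tolerance = 1e-12)

  # C1 on the study conditions: routing rises with distance below crossover
  expect_true(rep$c1$pass)
  expect_lt(rep$c1$p_perm, 0.05)
  expect_true(rep$c4$pass)
  expect_true(rep$c5$pass)

  # zero-coupling network: C1 must fail but the report stays well-formed
  n <- 8
  cn0 <- connectome(matrix(0, n, n), cn$distances[1:n, 1:n])
  rep0 <- evaluate_predictions(bare_resolvent(cn0), cn0$distances,
                               n_perm = 50)
  expect_false(rep0$c1$pass)
  expect_true(is.na(rep0$q_crossover_hz))

  # a grid missing the alpha band is a named failure
  Hh <- bare_resolvent(cn, frequency_grid(seq(20, 45, 0.5)))
  expect_error(evaluate_predictions(Hh, cn$distances),
               class = "walksum_error_grid")
})

test_that("divergence statistics are rank-invariant to per-frequency rescaling", {
  cn <- fixture_connectome()
  H <- bare_resolvent(cn, frequency_grid(c(5, 10, 20, 30)))
  H2 <- H
  for (k in 1:4) H2$H[, , k] <- H$H[, , k] * (0.3 + k)
  ri <- rho_profile(H, cn$distances, "I"); ri2 <- rho_profile(H2, cn$distances, "I")
  rq <- rho_profile(H, cn$distances, "Q"); rq2 <- rho_profile(H2, cn$distances, "Q")
  expect_equal(channel_divergence(ri, rq, H$f)$D,
               channel_divergence(ri2, rq2, H$f)$D, tolerance = 1e-12)
})

test_that("group profile comparison detects identity and rank reversal", {
  cn <- fixture_connectome()
  H <- bare_resolvent(cn, frequency_grid(seq(1, 45, 1)))
  same <- compare_group_profiles(H, H, cn$distances)
  expect_equal(unname(same), rep(1, 5))
  flip <- H; flip$H <- -H$H
  rev <- compare_group_profiles(H, flip, cn$distances)
  expect_equal(unname(rev), rep(-1, 5))
  Hg <- bare_resolvent(cn, frequency_grid(seq(2, 44, 1)))
  expect_error(compare_group_profiles(H, Hg, cn$distances),
               class = "walksum_error_grid")
})
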