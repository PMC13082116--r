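test_that("Welch auto-spectrum localises a pure sinusoid", {
  fs <- 128; t <- seq(0, 20, by = 1 / fs)[-1]
  x <- rbind(sin(2 * pi * 10 * t), rnorm(length(t), sd = 0.1))
  csd <- welch_csd(x, fs, nperseg = 256)
  peak <- csd$f[which.max(Re(apply(csd$S, 3, function(M) M[1, 1])))]
  expect_equal(peak, 10, tolerance = 0.5)
  expect_error(welch_csd(x[, 1:100], fs, nperseg = 256),
               class = "walksum_error_samples")
})

test_that("coherency invariants hold on estimator output", {
  cn <- make_connectome(synth_config(n_nodes = 6, seed = 12))
  ts <- suppressWarnings(make_timeseries(cn, fs = 64, duration = 60,
                                         noise_seed = 2))
  coh <- coherency(welch_csd(ts, nperseg = 128))
  nb <- dim(coh$H)[3]
  for (b in c(2, nb %/% 2, nb)) {
    M <- coh$H[, , b]
    expect_equal(Mod(diag(M)), rep(1, 6), tolerance = 1e-10)
    expect_true(all(Mod(M) <= 1 + 1e-9))
    expect_equal(M, Conj(t(M)), tolerance = 1e-10)
  }

  # two identical channels: unit coherency magnitude everywhere
  x <- matrix(rnorm(4096), 1)
  xx <- rbind(x, x)
  chh <- coherency(welch_csd(xx, 64, nperseg = 256))
  expect_equal(Mod(chh$H[1, 2, ]), rep(1, dim(chh$H)[3]), tolerance = 1e-9)
})

test_that("coherency normalisation matches scalar arithmetic", {
  S <- array(0i, c(2, 2, 1))
  S[, , 1] <- matrix(c(4, 1 - 2i, 1 + 2i, 9), 2)
  csd <- structure(list(S = S, f = 5, fs = 64, n_segments = 10,
                        meta = list()), class = "csd")
  ch <- coherency(csd)
  expect_equal(ch$H[1, 2, 1], (1 + 2i) / sqrt(4 * 9))
  expect_equal(ch$H[1, 1, 1], 1 + 0i)

  # diagonal CSD -> identity coherency
  Sd <- array(0i, c(2, 2, 1)); Sd[, , 1] <- diag(c(2, 5))
  chd <- coherency(structure(list(S = Sd, f = 5, fs = 64, n_segments = 1,
                                  meta = list()), class = "csd"))
  expect_equal(chd$H[, , 1], diag(1 + 0i, 2))

  # perfectly coherent off-diagonal: magnitude exactly 1
  Sc <- array(0i, c(2, 2, 1))
  Sc[, , 1] <- matrix(c(4, 6, 6, 9), 2)
  chc <- coherency(structure(list(S = Sc, f = 5, fs = 64, n_segments = 1,
                                  meta = list()), class = "csd"))
  expect_equal(Mod(chc$H[1, 2, 1]), 1)

  Sz <- array(0i, c(2, 2, 1)); Sz[, , 1] <- diag(c(0, 5))
  expect_error(coherency(structure(list(S = Sz, f = 5, fs = 64,
                                        n_segments = 1, meta = list()),
                                   class = "csd")),
               class = "walksum_error_autospectrum")
})

test_that("independent channels show only the known estimator bias", {
  # theory + Monte-Carlo: E|coh|^2 ~ 1/n_segments for independent noise
  fs <- 64; nper <- 128
  mean_abs <- function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(2 * fs * 120), 2)
    coh <- coherency(welch_csd(x, fs, nperseg = nper))
    mean(Mod(coh$H[1, 2, ]))
  }
  got <- mean_abs(1)
  oracle <- sapply(2:6, mean_abs)          # fresh-noise Monte-Carlo oracle
  expect_lt(abs(got - mean(oracle)), 2 * sd(oracle) + 0.02)
  # and the bias scale itself is ~ sqrt(pi/(4 n_seg))
  nseg <- floor((fs * 120 - nper) / (nper / 2)) + 1
  expect_lt(abs(got - sqrt(pi / (4 * nseg))), 0.03)
})

test_that("grid mapping picks nearest FFT bins", {
  S <- array(1i, c(2, 2, 5))
  coh <- structure(list(H = S, f = c(0, 2, 4, 6, 8)),
                   class = "coherency_field")
  cg <- coherency_on_grid(coh, f = c(1.9, 6.4))
  expect_equal(cg$f_actual, c(2, 6))
  expect_equal(dim(cg$H)[3], 2)
})

test_that("empirical coherency converges to the transfer-implied coherency", {
  cn <- make_connectome(synth_config(n_nodes = 16, seed = 5))
  ts <- make_timeseries(cn, fs = 128, duration = 600, noise_seed = 9)
  coh <- coherency_on_grid(coherency(welch_csd(ts, nperseg = 256)),
                           frequency_grid()$f)
  imp <- implied_coherency(bare_resolvent(cn))
  pe <- as.vector(apply(coh$H, 3, function(M) M[upper.tri(M)]))
  pi_ <- as.vector(apply(imp$H, 3, function(M) M[upper.tri(M)]))
  expect_gt(cor(Re(pe), Re(pi_)), 0.9)
  expect_gt(cor(Mod(pe), Mod(pi_)), 0.9)
})

test_that("empirical channel battery mirrors the model conventions", {
  cn <- make_connectome(synth_config(n_nodes = 16, seed = 5))
  imp <- implied_coherency(bare_resolvent(cn))
  rep <- empirical_channels(imp, cn$distances, n_perm = 50)
  expect_s3_class(rep, "channel_report")
  expect_equal(rep$settings$q_stat, "abs")

  # identity coherency: no distance structure, C1 fails
  n <- 8
  Hid <- array(0i, c(n, n, 89))
  for (k in 1:89) Hid[, , k] <- diag(1 + 0i, n)
  idf <- structure(list(H = Hid, f = frequency_grid()$f),
                   class = "coherency_field")
  rid <- empirical_channels(idf, cn$distances[1:n, 1:n], n_perm = 50)
  expect_false(rid$c1$pass)

  # conjugation: I untouched, signed Q negated, |Im| statistics unchanged
  conj_f <- imp; conj_f$H <- Conj(imp$H)
  expect_equal(rho_profile(conj_f, cn$distances, "I"),
               rho_profile(imp, cn$distances, "I"))
  expect_equal(rho_profile(conj_f, cn$distances, "absQ"),
               rho_profile(imp, cn$distances, "absQ"))
  expect_equal(rho_profile(conj_f, cn$distances, "Q"),
               -rho_profile(imp, cn$distances, "Q"))
})

test_that("dominance ratio and dimensionality match hand decompositions", {
  n <- 4
  v <- complex(real = rnorm(n), imaginary = rnorm(n))
  Hr1 <- array(0i, c(n, n, 1)); Hr1[, , 1] <- v %o% Conj(v)
  expect_equal(dominance_ratio(as_field(Hr1, 10), 10), Inf)

  Hid <- array(0i, c(n, n, 1)); Hid[, , 1] <- diag(1 + 0i, n)
  expect_equal(dominance_ratio(as_field(Hid, 10), 10), 1)

  set.seed(8)
  M <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  Hm <- array(0i, c(n, n, 1)); Hm[, , 1] <- M
  sv <- sqrt(sort(Re(eigen(Conj(t(M)) %*% M)$values), decreasing = TRUE))
  expect_equal(dominance_ratio(as_field(Hm, 10), 10), sv[1] / sv[2],
               tolerance = 1e-10)

  # dimensionality: single channel, proportional channels, orthogonal channels
  P <- 10
  Ip <- rnorm(P)
  mk_field <- function(Ivec, Qvec) {
    nn <- 5                               # 5 nodes -> 10 pairs
    H <- array(0i, c(nn, nn, 1))
    M <- matrix(0, nn, nn); M[upper.tri(M)] <- Ivec
    Q <- matrix(0, nn, nn); Q[upper.tri(Q)] <- Qvec
    H[, , 1] <- (M + t(M)) + 1i * (Q + t(Q))
    as_field(H, 10)
  }
  expect_equal(communication_dimensionality(mk_field(Ip, rep(0, P)), f = 10), 1)
  expect_equal(communication_dimensionality(mk_field(Ip, 2.5 * Ip), f = 10), 1,
               tolerance = 1e-10)
  Qo <- rnorm(P); Qo <- Qo - Ip * sum(Qo * Ip) / sum(Ip^2)
  Qo <- Qo * sqrt(sum(Ip^2) / sum(Qo^2))  # orthogonal, equal norm
  expect_equal(communication_dimensionality(mk_field(Ip, Qo), f = 10), 2,
               tolerance = 1e-10)
})
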