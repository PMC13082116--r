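# shared fixtures, built once per test run

fixture_env <- new.env(parent = emptyenv())

# default hub-routed ring connectome (the study conditions)
fixture_connectome <- function() {
  if (is.null(fixture_env$conn)) fixture_env$conn <- make_connectome()
  fixture_env$conn
}

fixture_bare <- function() {
  if (is.null(fixture_env$bare))
    fixture_env$bare <- bare_resolvent(fixture_connectome())
  fixture_env$bare
}

# small random symmetric connectome with a prescribed spectral radius
random_connectome <- function(seed, n = NULL, radius = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(4:12, 1)
  if (is.null(radius)) radius <- runif(1, 0.3, 0.85)
  W <- matrix(runif(n * n), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W <- W / max(Mod(eigen(W, only.values = TRUE)$values)) * radius
  D <- matrix(runif(n * n, 10, 150), n, n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  connectome(W, D)
}

# brute-force Spearman: midrank + Pearson, independent of stats::cor(spearman)
spearman_brute <- function(x, y) {
  rx <- rank(x)   # ties.method = "average" = midranks
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# scalar single-unit Wilson-Cowan reference integrator (oracle for the
# coupled simulator in its uncoupled, noise-free, undriven limit)
wc_single_unit_oracle <- function(p, E0 = 0.1, I0 = 0.1) {
  sig <- function(x, a, th) 1 / (1 + exp(-a * (x - th)))
  n_steps <- round(p$duration * 1000 / p$dt)
  E <- E0; I <- I0
  out <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    inp_e <- p$c1 * E - p$c2 * I + p$P
    inp_i <- p$c3 * E - p$c4 * I
    dE <- (-E + sig(inp_e, p$a_e, p$theta_e)) * (p$dt / p$tau_e)
    dI <- (-I + sig(inp_i, p$a_i, p$theta_i)) * (p$dt / p$tau_i)
    E <- E + dE; I <- I + dI
    out[s] <- E
  }
  out
}

# add seeded relative noise to the finite entries of a distance profile
perturb_profile <- function(prof, sd_frac, seed) {
  set.seed(seed)
  for (f in c("mean_I", "mean_Q", "mean_absQ")) {
    s <- stats::sd(prof[[f]], na.rm = TRUE)
    ok <- is.finite(prof[[f]])
    prof[[f]][ok] <- prof[[f]][ok] + stats::rnorm(sum(ok), sd = sd_frac * s)
  }
  prof
}

# wrap a complex n x n x nf array as a field on grid f (test scaffolding)
as_field <- function(H, f) {
  structure(list(H = H, f = f, T = 0.010), class = "resolvent_field")
}
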