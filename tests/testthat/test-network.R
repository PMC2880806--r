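test_that("propagator formula, stability flag and validation", {
  p0 <- build_propagator(matrix(0, 3, 3), alpha = 1, dt = 0.1)
  expect_equal(p0$A, diag(0.9, 3))
  expect_true(p0$stable)
  p <- build_propagator(matrix(c(0, 0.5, 0.5, 0), 2), alpha = 1, dt = 0.1)
  expect_equal(p$A, matrix(c(0.9, 0.05, 0.05, 0.9), 2))
  expect_equal(p$spectral_radius, 0.95)
  expect_true(p$stable)
  # alpha = 0, dt = 1: any W eigenvalue with |1 + lambda| >= 1 is unstable
  W3 <- diag(c(0.2, -0.5, 0.1))
  pu <- build_propagator(W3, alpha = 0, dt = 1)
  expect_false(pu$stable)
  expect_equal(pu$spectral_radius, 1.2)
  expect_warning(build_propagator(W3, alpha = 2, dt = 1), "coarse")
  expect_error(build_propagator(matrix(0, 2, 3), 1, 0.1), "square")
})

test_that("linear simulation matches the matrix-power oracle without noise", {
  W <- matrix(c(0, 0.4, 0.2, 0.1), 2)
  p <- build_propagator(W, alpha = 1, dt = 0.2)
  u0 <- c(1, -2)
  u <- simulate_linear(p, noise_sds = 0, T = 15, u0 = u0, seed = 1)
  oracle <- u0
  for (k in 1:15) {
    oracle <- drop(p$A %*% oracle)
    expect_equal(unname(u[k + 1, ]), oracle, tolerance = 1e-12)
  }
})

test_that("uncoupled nodes are AR(1) with the closed-form variance", {
  p <- build_propagator(matrix(0, 2, 2), alpha = 1, dt = 0.1)
  u <- simulate_linear(p, noise_sds = c(1, 2), T = 2e5, seed = 2)
  v_theory <- c(1, 4) / (1 - 0.9^2)
  v_emp <- apply(u[-1, ], 2, var)
  expect_lt(max(abs(v_emp - v_theory) / v_theory), 0.05)
  expect_identical(u, simulate_linear(p, noise_sds = c(1, 2), T = 2e5,
                                      seed = 2))
})

test_that("unstable propagator is refused with the spectral radius named", {
  p <- build_propagator(diag(0.5, 2), alpha = 0.1, dt = 1)
  expect_false(p$stable)
  expect_error(simulate_linear(p, 1, 10), "spectral radius")
  expect_silent(simulate_linear(p, 1, 10, override = TRUE))
})

test_that("identity saturation reduces the nonlinear path to the linear one", {
  W <- matrix(c(0, 0.3, 0.3, 0), 2)
  p <- build_propagator(W, alpha = 1, dt = 0.1)
  cfg <- network_config(W, alpha = 1, dt = 0.1, noise_sds = 0.5)
  ul <- simulate_linear(p, 0.5, T = 500, seed = 7)
  un <- simulate_nonlinear(cfg, T = 500, seed = 7)
  expect_identical(ul, un) # bitwise, shared noise stream
})

test_that("bounded saturation keeps states bounded; fixed point is correct", {
  sig <- function(x) tanh(x)
  W <- matrix(0.8, 3, 3); diag(W) <- 0
  cfg <- network_config(W, alpha = 0.5, dt = 0.1, noise_sds = 0,
                        saturation = sig)
  u <- simulate_nonlinear(cfg, T = 2000, u0 = c(3, -2, 1), seed = 1)
  bnd <- (1 * max(rowSums(abs(W)))) / 0.5 # sup|Theta| * ||W||_inf / alpha
  expect_true(all(abs(u[nrow(u), ]) <= bnd + 1e-9))
  # constant input, identity saturation: converges to (alpha I - W)^{-1} I
  W2 <- matrix(c(0, 0.2, 0.2, 0), 2)
  I0 <- c(0.3, -0.1)
  cfg2 <- network_config(W2, alpha = 1, dt = 0.1, noise_sds = 0,
                         external_input = I0)
  u2 <- simulate_nonlinear(cfg2, T = 3000, seed = 1)
  expect_equal(unname(u2[nrow(u2), ]),
               drop(solve(diag(2) - W2, I0)), tolerance = 1e-6)
})

test_that("stationary covariance solves the discrete Lyapunov equation", {
  # A = 0 exactly (alpha*dt = 1, W = 0): one-step fixed point C = Sigma
  expect_warning(p0 <- build_propagator(matrix(0, 2, 2), alpha = 1, dt = 1))
  cm0 <- stationary_covariance(p0, noise_sds = c(1, 3))
  expect_equal(cm0$C, diag(c(1, 9)), tolerance = 1e-9)
  # W = 0, A = cI: geometric series sigma^2 / (1 - c^2)
  p <- build_propagator(matrix(0, 3, 3), alpha = 1, dt = 0.2) # c = 0.8
  cm <- stationary_covariance(p, noise_sds = c(1, 2, 0.5))
  expect_equal(diag(cm$C), c(1, 4, 0.25) / (1 - 0.64), tolerance = 1e-8)
  expect_lt(max(abs(cm$C - diag(diag(cm$C)))), 1e-9)
  # residual check: C satisfies the equation
  resid <- cm$C - (p$A %*% cm$C %*% t(p$A) + diag(c(1, 4, 0.25)))
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("symmetric W with isotropic noise shares eigenvectors with C", {
  set.seed(42)
  M <- matrix(rnorm(36), 6)
  W <- (M + t(M)) / 20
  p <- build_propagator(W, alpha = 1, dt = 0.1)
  stopifnot(p$stable)
  cm <- stationary_covariance(p, noise_sds = 1)
  ew <- eigen(W, symmetric = TRUE)
  # simultaneous diagonalization oracle: rotate C into W's eigenbasis
  D <- t(ew$vectors) %*% cm$C %*% ew$vectors
  expect_lt(max(abs(D - diag(diag(D)))), 1e-8)
  # pairwise eigenvector cosines: mode k of C vs eigenvector k of W
  cos_k <- vapply(1:6, function(k)
    abs(sum(cm$eigenvectors[, k] * ew$vectors[, k])), numeric(1))
  expect_true(all(cos_k > 0.999))
  # eigenvalue order of C follows the descending order of W's eigenvalues
  expect_equal(order(diag(D), decreasing = TRUE), seq_len(6))
})

test_that("empirical modes converge to the analytic covariance", {
  W <- matrix(c(0, .3, .1, .3, 0, .2, .1, .2, 0), 3)
  p <- build_propagator(W, alpha = 1, dt = 0.1)
  u <- simulate_linear(p, noise_sds = 1, T = 2e5, seed = 9)
  emp <- empirical_modes(u, burn_in = 100)
  ana <- stationary_covariance(p, noise_sds = 1)
  relF <- norm(emp$C - ana$C, "F") / norm(ana$C, "F")
  expect_lt(relF, 0.05)
  # iid unit-variance noise: covariance ~ identity
  set.seed(3)
  X <- matrix(rnorm(4e5), ncol = 4)
  ei <- empirical_modes(X)
  expect_lt(norm(ei$C - diag(4), "F") / norm(diag(4), "F"), 0.05)
  # rank-1 series: single nonzero eigenvalue, eigenvector along v
  v <- c(1, 2, -2) / 3
  s <- sin(seq(0, 20, length.out = 500))
  r1 <- suppressWarnings(empirical_modes(outer(s, v)))
  expect_lt(r1$eigenvalues[2] / r1$eigenvalues[1], 1e-10)
  expect_gt(abs(sum(r1$eigenvectors[, 1] * v)), 0.999)
})

test_that("increasing one node's noise increases only its own variance", {
  p <- build_propagator(matrix(0, 3, 3), alpha = 1, dt = 0.1)
  c1 <- stationary_covariance(p, noise_sds = c(1, 1, 1))$C
  c2 <- stationary_covariance(p, noise_sds = c(1, 2, 1))$C
  expect_gt(c2[2, 2], c1[2, 2])
  expect_equal(c2[-2, -2], c1[-2, -2], tolerance = 1e-10)
})

test_that("mode occupancy reflects eigenvalue ratios", {
  # rank-1 series occupies its single dominant mode all the time
  v <- c(1, 1) / sqrt(2)
  s <- rnorm(200)
  series <- outer(s, v)
  m <- suppressWarnings(empirical_modes(series))
  occ <- mode_occupancy(series, m)
  expect_equal(occ$occupancy[1], 1)
  # two independent modes with variance ratio 4: shares 0.8 / 0.2
  p <- build_propagator(matrix(0, 2, 2), alpha = 1, dt = 0.1)
  u <- simulate_linear(p, noise_sds = c(2, 1), T = 1e5, seed = 4)
  mm <- empirical_modes(u)
  occ2 <- mode_occupancy(u[-1, ], mm)
  expect_equal(occ2$variance_share[1], 0.8, tolerance = 0.03)
  expect_gt(occ2$occupancy[1], occ2$occupancy[2])
  # isotropic system: equal occupancies within Monte-Carlo tolerance
  ui <- simulate_linear(p, noise_sds = 1, T = 1e5, seed = 5)
  occ3 <- mode_occupancy(ui[-1, ], empirical_modes(ui))
  expect_lt(abs(occ3$occupancy[1] - 0.5), 0.05)
  expect_error(mode_occupancy(u[, 1, drop = FALSE], mm), "mismatch")
})

test_that("Kuramoto index bounds and fixtures", {
  n <- 5; Tt <- 50
  same <- matrix(1.3, Tt, n)
  expect_equal(kuramoto_index(same), rep(1, Tt))
  spread <- matrix(rep(2 * pi * (0:(n - 1)) / n, each = Tt), Tt, n)
  expect_lt(max(kuramoto_index(spread)), 1e-12)
  opp <- cbind(rep(0.4, Tt), rep(0.4 + pi, Tt))
  expect_lt(max(kuramoto_index(opp)), 1e-12)
  # bounds and global phase-shift invariance on random phases
  set.seed(6)
  ph <- matrix(runif(200, -pi, pi), 40, 5)
  r <- kuramoto_index(ph)
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(r, kuramoto_index(ph + 1.1), tolerance = 1e-12)
})

test_that("analytic-signal phases recover frequency, sign and duplicates", {
  tt <- seq(0, 100, by = 0.1)
  x <- cos(0.7 * tt)
  ph <- extract_phases(cbind(x, x, -x))
  # unwrapped slope of the phase ~ 0.7 (drop edges)
  core <- 100:900
  d <- diff(ph[core, 1])
  d <- (d + pi) %% (2 * pi) - pi # unwrap the 2*pi jumps
  slope <- mean(d) / 0.1
  expect_lt(abs(slope - 0.7) / 0.7, 0.01)
  expect_equal(ph[, 1], ph[, 2])
  dphi <- (ph[core, 3] - ph[core, 1]) %% (2 * pi)
  expect_lt(max(abs(dphi - pi)), 0.01)
  expect_warning(extract_phases(cbind(x, rep(2, length(tt)))), "undefined")
})

test_that("covariance modes export as a TSV mode table", {
  p <- build_propagator(matrix(c(0, .3, .3, 0), 2), 1, 0.1)
  cm <- stationary_covariance(p, noise_sds = 1)
  f <- tempfile(fileext = ".tsv")
  write_modes(cm, f)
  d <- read.delim(f)
  expect_equal(d$eigenvalue, cm$eigenvalues, tolerance = 1e-10)
  expect_equal(sum(d$weight_share), 1, tolerance = 1e-10)
  expect_equal(unname(as.matrix(d[, c("v1", "v2")])),
               t(cm$eigenvectors), tolerance = 1e-10)
})

test_that("connectivity matrices round-trip as delimited text", {
  W <- matrix(rnorm(9), 3)
  f <- tempfile(fileext = ".tsv")
  write_connectivity(W, f)
  expect_equal(read_connectivity(f), W, tolerance = 1e-12)
  colnames(W) <- c("a", "b", "c")
  write_connectivity(W, f, labeled = TRUE)
  W2 <- read_connectivity(f, labeled = TRUE)
  expect_equal(unname(W2), unname(W), tolerance = 1e-12)
  expect_equal(colnames(W2), c("a", "b", "c"))
})
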