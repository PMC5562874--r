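test_that("bump lifting: support, mirror symmetry, restrict recovers the
           coarse state", {
  spec <- std_spec()
  par <- model_params(kappa = 30, beta = 5, h = 0.9, p = 0.7, kernel = spec)
  cfg <- eqfree_config(N = 1024, M = 50)
  # the microstructure lift tiles one third of the interval with spiking
  # cells, so its self-consistent width is the deterministic one: at any
  # other width the restricted crossings sit where the lifted profile
  # actually crosses threshold, not at the requested edges
  xi <- c(0, bump_width(30, 0.9, spec)[2])
  dx <- 2 * pi / 1024
  set.seed(51)
  U <- lift_bump(xi, par, cfg)
  x <- ring_grid(1024, pi)
  outside <- x < xi[1] - dx / 2 | x > xi[2] + dx / 2
  expect_true(all(U[outside, ] == 0L))
  # mirror symmetry about the midpoint of the rounded interval
  i1 <- round((xi[1] + pi) / dx); i2 <- round((xi[2] + pi) / dx)
  idx <- (i1:i2) + 1
  expect_true(all(U[idx, ] == U[rev(idx), ]))

  # restriction directly after lifting reproduces the coarse state within
  # the Monte-Carlo tolerance of the crossing estimator
  set.seed(52)
  cfg2 <- eqfree_config(N = 1024, M = 400)
  r <- restrict_ensemble(lift_bump(xi, par, cfg2), par, reference = xi[1])
  expect_equal(r$n_extinct, 0L)
  # the crossing estimator carries an O(strip-width) bias on top of the
  # Monte-Carlo error; strips average four cells here
  expect_lt(max(abs(r$xi - xi)), 3 * dx)
})

test_that("wave lifting: strip frequencies match the distribution; p = 1
           gives a pure spiking strip behind the front; seeded", {
  spec <- std_spec()
  par <- preset("wave")$params
  wp <- wave_pmf(30, 1, 0.4, spec, "fast", 8)
  cfg <- eqfree_config(N = 1024, M = 2000)
  xi <- c(-2 * wp$c, wp$c)
  set.seed(53)
  U <- lift_wave(xi, par, cfg, wpmf = wp)
  x <- ring_grid(1024, pi)
  for (j in c(-2, -1, 0)) {
    inside <- x >= (j + 0.1) * wp$c + xi[2] - wp$c &
      x <= (j + 0.9) * wp$c + xi[2] - wp$c
    emp <- c(mean(U[inside, ] == -1L), mean(U[inside, ] == 0L),
             mean(U[inside, ] == 1L))
    pr <- wp$rho[, as.character(j)]
    n <- sum(inside) * 2000
    expect_true(all(abs(emp - pr) <= 4 * sqrt(pr * (1 - pr) / n) + 1e-12))
  }

  par1 <- det_params(kappa = 30, h = 1, spec = spec)
  par1$p <- 1
  wp1 <- wave_pmf(30, 1, 1, spec, "fast", 8)
  set.seed(54)
  U1 <- lift_wave(xi, par1, eqfree_config(N = 1024, M = 20), wpmf = wp1)
  # the spiking strip sits one strip width behind the front edge
  behind <- x >= xi[2] - 2 * wp$c + 0.1 * wp$c &
    x <= xi[2] - wp$c - 0.1 * wp$c
  expect_true(all(U1[behind, ] == 1L))

  set.seed(99); a <- lift_wave(xi, par, cfg, wpmf = wp)
  set.seed(99); b <- lift_wave(xi, par, cfg, wpmf = wp)
  expect_identical(a, b)
})

test_that("restriction: exact for replicated states, extinction marker,
           1/sqrt(M) error scaling", {
  spec <- std_spec()
  par <- preset("bump")$params
  set.seed(55)
  st0 <- fixture_initial_condition("bump_seed", 512)
  tr <- simulate_automaton(st0, par, 40)
  st <- tr$U[, 41]
  pr <- threshold_crossings(synaptic_input(lattice_state(st, pi), par))
  U <- matrix(rep(st, 7), ncol = 7)
  r <- restrict_ensemble(U, par)
  expect_equal(unname(r$xi), c(pr$x[pr$rising][1], pr$x[!pr$rising][1]),
               tolerance = 1e-10)

  r0 <- restrict_ensemble(matrix(0L, 512, 5), par)
  expect_equal(unname(r0$xi), c(0, 0))
  expect_equal(r0$n_extinct, 5L)

  # standard error of the restricted crossings shrinks like 1/sqrt(M)
  cfg <- eqfree_config(N = 512, M = 1)
  sd_of_mean <- function(M, reps = 24) {
    cfgM <- eqfree_config(N = 512, M = M)
    v <- vapply(seq_len(reps), function(i)
      restrict_ensemble(lift_bump(c(0, 1.55), par, cfgM), par,
                        reference = 0)$xi[2], numeric(1))
    sd(v)
  }
  set.seed(56)
  s10 <- sd_of_mean(10); s100 <- sd_of_mean(100); s1000 <- sd_of_mean(1000)
  expect_lt(s100 / s10, 0.6)      # expect ~ 1/sqrt(10) = 0.32
  expect_lt(s1000 / s100, 0.6)
})

test_that("deterministic coarse bump: fixed point near the interface width
           and a contracting residual history", {
  spec <- std_spec()
  par <- det_params(kappa = 30, h = 1, spec = spec)
  cfg <- eqfree_config(N = 1024, M = 12, lift_mode = "strips_regular")
  Delta <- bump_width(30, 1, spec)[2]
  dx <- 2 * pi / 1024
  Fb <- function(xi) residual_bump(xi, par, cfg, deterministic = TRUE)
  ns <- newton_damped(Fb, c(0, Delta + 0.05), damping = 0.5, tol = 2e-3,
                      maxit = 30, eps_fd = 0.02, max_step = 0.1)
  expect_true(ns$converged)
  expect_lt(abs(ns$x[2] - Delta), 1.5 * dx)
  # the residual history reaches the tolerance from a coarse start
  expect_lt(min(ns$residuals), 2e-3)
  expect_gt(ns$residuals[1], min(ns$residuals))
})

test_that("coarse Jacobian-vector products scale linearly in the increment,
           with an M-dependent noise floor in the stochastic case", {
  spec <- std_spec()
  par <- det_params(kappa = 30, h = 1, spec = spec)
  cfg <- eqfree_config(N = 512, M = 12, lift_mode = "strips_regular")
  Delta <- bump_width(30, 1, spec)[2]
  xi <- c(0, Delta)
  v <- c(0.6, 0.8)
  phi0 <- coarse_map(xi, "bump", par, cfg, deterministic = TRUE)
  jvp <- function(eps) sqrt(sum((coarse_map(xi + eps * v, "bump", par, cfg,
                                            deterministic = TRUE) - phi0)^2))
  eps <- c(1e-3, 1e-2, 1e-1)
  nrm <- vapply(eps, jvp, numeric(1))
  # slope on the resolved scales is near 1 (an O(eps) law); below the grid
  # scale the response is quantised away
  expect_lt(abs(log10(nrm[3] / nrm[2]) - 1), 0.5)
  expect_lt(jvp(1e-6), 2 * 2 * pi / 512)

  # stochastic wave: common-random-number JVPs follow the O(eps) law at
  # large eps and flatten at a floor that drops as M grows
  parw <- preset("wave")$params
  wp <- wave_pmf(30, 1, 0.4, spec, "fast", 8)
  floor_of <- function(M) {
    cfgM <- eqfree_config(N = 512, M = M)
    p0 <- with_fixed_seed(function()
      coarse_map(c(-2 * wp$c, wp$c), "wave", parw, cfgM, wpmf = wp), 7)
    vapply(c(1e-4, 1e-1), function(eps) {
      pe <- with_fixed_seed(function()
        coarse_map(c(-2 * wp$c, wp$c) + eps * v, "wave", parw, cfgM,
                   wpmf = wp), 7)
      sqrt(sum((pe - p0)^2))
    }, numeric(1))
  }
  set.seed(57)
  fl10 <- floor_of(10); fl200 <- floor_of(200)
  # at eps = 1e-4 the noise floor dominates and is smaller for larger M;
  # at eps = 0.1 both follow the O(eps) response
  expect_lt(fl200[1], fl10[1])
  expect_lt(abs(fl200[2] - fl10[2]) / fl10[2], 0.5)
})

test_that("forward differences are exact on affine maps and recover the bump
           stability eigenvalues at the deterministic fixed point", {
  A <- matrix(c(2, -1, 0.5, 3), 2, 2)
  b <- c(1, -2)
  F <- function(x) as.vector(A %*% x) + b
  J <- fd_jacobian(F, c(0.3, -0.7), eps = 1e-3)
  expect_equal(J, A, tolerance = 1e-10)

  spec <- std_spec()
  par <- det_params(kappa = 30, h = 1, spec = spec)
  cfg <- eqfree_config(N = 4096, M = 12, lift_mode = "strips_regular")
  Delta <- bump_width(30, 1, spec)[2]
  Fb <- function(xi) residual_bump(xi, par, cfg, deterministic = TRUE)
  ns <- newton_damped(Fb, c(0, Delta), damping = 0.5, tol = 1e-3,
                      maxit = 25, eps_fd = 0.02, max_step = 0.1)
  G <- function(xi) coarse_map(xi, "bump", par, cfg, deterministic = TRUE)
  J <- fd_jacobian(G, ns$x, eps = 0.03)
  ev <- sort(Mod(eigen(J, only.values = TRUE)$values))
  # the coarse map inherits the exact translation invariance of the lattice
  # dynamics (neutral mode of modulus 1); its second mode composes the lift
  # and restriction responses, so its magnitude differs from the bare
  # interface eigenvalue, but the stability classification agrees: the wide
  # bump is a coarse contraction
  expect_lt(abs(ev[2] - 1), 0.05)
  expect_lt(ev[1], 1)
  expect_true(bump_eigs(Delta, spec)$stable)
})

test_that("pseudo-arclength continuation traverses folds of a closed-form
           benchmark", {
  # the circle x^2 + gamma^2 = 1 has folds at gamma = +/-1
  res <- function(x, gamma) x^2 + gamma^2 - 1
  br <- arclength_continue(res, x0 = 1, gamma0 = 0, ds = 0.05,
                           n_steps = 200, tol = 1e-11)
  expect_gt(nrow(br), 150)
  expect_lt(max(br$residual), 1e-10)
  expect_gte(sum(br$fold), 2)
  folds <- br$gamma[br$fold]
  expect_lt(min(abs(abs(folds) - 1)), 0.05)
  # the branch covers both signs of x (it passed through the folds)
  expect_lt(min(br$x1), -0.5)
  expect_gt(max(br$x1), 0.5)
})

test_that("analytic bump branch in gain stabilises at a saddle-node fold", {
  spec <- std_spec()
  h <- 1
  res <- function(D, kappa) kappa * kernel_interval_integral(0, D, spec) -
    3 * h
  br <- arclength_continue(res, x0 = bump_width(40, h, spec)[2],
                           gamma0 = 40, ds = -0.4, n_steps = 150,
                           tol = 1e-10,
                           eig_fn = function(D, kappa)
                             bump_eigs(D, spec)$values[-1],
                           stop_fn = function(D, kappa)
                             D < 0.2 || D > 4 || kappa > 80)
  expect_gte(sum(br$fold), 1)
  fold_k <- br$gamma[br$fold][1]
  # the fold sits at the gain where the cumulative kernel integral peaks
  kap_sn <- 3 * h / stats::optimize(function(D)
    kernel_interval_integral(0, D, spec), c(0.2, 1.5),
    maximum = TRUE)$objective
  expect_lt(abs(fold_k - kap_sn) / kap_sn, 0.03)
  # stability flips across the fold: wide segment stable, narrow unstable
  wide <- br$x1 > 1; narrow <- br$x1 < 0.6
  expect_true(all(br$stable[wide]))
  expect_true(all(!br$stable[narrow]))
})

test_that("coarse wave residual vanishes on the coarse travelling wave and
           couples speed to width", {
  spec <- std_spec()
  par <- preset("wave")$params
  wp <- wave_pmf(30, 1, 0.4, spec, "fast", 8)
  cfg <- eqfree_config(N = 1024, M = 200)
  xi <- c(-2 * wp$c, wp$c)
  r <- with_fixed_seed(function()
    residual_wave(c(xi, wp$c), par, cfg, wpmf = wp), 58)
  expect_equal(r[1], xi[1])
  expect_equal(r[3], 0)
  expect_lt(abs(r[2]), 0.05)
  # the speed row vanishes iff c = (xi2 - xi1) / 3
  r2 <- with_fixed_seed(function()
    residual_wave(c(xi, wp$c * 1.2), par, cfg, wpmf = wp), 58)
  expect_equal(r2[3], 0.2 * wp$c, tolerance = 1e-12)
})
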