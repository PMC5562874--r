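test_that("bump profile hits threshold at both edges and is mirror
           symmetric", {
  spec <- std_spec()
  kappa <- 30; h <- 0.9
  Delta <- bump_width(kappa, h, spec)[2]   # wide root of the localized pair
  expect_equal(bump_meso_profile(0, 0, Delta, kappa, spec), h,
               tolerance = 1e-10)
  expect_equal(bump_meso_profile(Delta, 0, Delta, kappa, spec), h,
               tolerance = 1e-10)
  set.seed(31)
  for (i in 1:10) {
    d <- runif(1, -1, 1); z <- runif(1, 0, 1)
    expect_equal(
      bump_meso_profile(d + Delta / 2 + z, d, d + Delta, kappa, spec),
      bump_meso_profile(d + Delta / 2 - z, d, d + Delta, kappa, spec),
      tolerance = 1e-12)
  }
})

test_that("bump width solves the threshold equation and matches bisection", {
  spec <- std_spec()
  for (kappa in c(20, 30, 45)) {
    roots <- bump_width(kappa, 0.9, spec)
    for (D in roots)
      expect_lt(abs(kappa * kernel_interval_integral(0, D, spec) - 2.7),
                1e-9)
    # bisection oracle on the narrow/wide pair inside (0, L)
    g <- function(D) kappa * kernel_interval_integral(0, D, spec) - 2.7
    lo <- 1e-6; hi <- 0.79  # global max of the cumulative kernel integral
    if (g(lo) * g(hi) < 0) {
      bis <- uniroot(g, c(lo, hi), tol = 1e-12)$root
      expect_equal(min(roots), bis, tolerance = 1e-9)
    }
  }
  # threshold too high: no solution
  expect_error(bump_width(5, 5, spec), "no bump")
})

test_that("strip microstates converge uniformly to the mesoscopic bump,
           including permuted strips", {
  spec <- std_spec()
  kappa <- 30
  eta <- c(0, 1.5)
  xs <- seq(-pi, pi, length.out = 301)
  Jb <- bump_meso_profile(xs, eta[1], eta[2], kappa, spec)
  par <- det_params(kappa = kappa, h = 0.9, spec = spec)

  strip_J <- function(part) partition_synaptic_input(xs, part, par)

  errs <- vapply(c(1, 2, 4, 8, 16), function(m)
    max(abs(strip_J(strip_bump_state(eta[1], eta[2], m)) - Jb)), numeric(1))
  expect_true(all(diff(errs) < 0))
  e64 <- max(abs(strip_J(strip_bump_state(eta[1], eta[2], 64)) - Jb))
  expect_lt(e64, 1e-2 * kappa)

  set.seed(32)
  perm <- replicate(64, sample(3), simplify = FALSE)
  e64p <- max(abs(strip_J(strip_bump_state(eta[1], eta[2], 64,
                                           permute = perm)) - Jb))
  expect_lt(e64p, 2e-2 * kappa)

  # structure: 3m strips cycling -1, 0, 1, plus the quiescent outside
  part <- strip_bump_state(eta[1], eta[2], 4)
  inside <- part[part$left >= eta[1] - 1e-12 & part$right <= eta[2] + 1e-12, ]
  expect_equal(sum(inside$right - inside$left), eta[2] - eta[1])
  expect_equal(sum(partition_label_at(part, seq(0.01, 1.49, by = 0.005)) == 1),
               sum(partition_label_at(part, seq(0.01, 1.49, by = 0.005)) == -1),
               tolerance = 3)

  # the strip state is not an equilibrium of the deterministic dynamics
  st <- partition_to_state(strip_bump_state(eta[1], eta[2], 4), 1024)
  out <- deterministic_step(st, det_params(kappa = 30, h = 0.9, spec = spec))
  expect_false(identical(unclass(st), unclass(out)))
})

test_that("bump interface eigenvalues: translation mode, closed form vs dense
           solver, stability criterion", {
  spec <- std_spec()
  for (Delta in c(0.8, 1.2, 1.711, 2.3)) {
    be <- bump_eigs(Delta, spec)
    ev <- eigen(be$matrix)
    # translation eigenpair is exactly -1 with eigenvector (1,1)
    expect_equal(be$values[1], -1)
    i1 <- which.min(abs(ev$values - (-1)))
    expect_equal(ev$values[i1], -1, tolerance = 1e-12)
    v <- ev$vectors[, i1]
    expect_lt(abs(abs(v[1]) - abs(v[2])), 1e-12)
    # the width eigenvalue matches the dense decomposition
    expect_equal(sort(be$values), sort(ev$values), tolerance = 1e-12)
    # stability iff the kernel is inhibitory at the bump width
    expect_identical(be$stable, periodic_kernel(Delta, spec) < 0)
  }
})

test_that("two-bump solution: translation eigenvalue -1, symmetric real
           matrix, closed forms match the dense solver", {
  spec <- std_spec()
  mb <- multibump_solve(30, 0.9, spec)
  expect_equal(mb$values[1], -1)
  expect_equal(mb$matrix, t(mb$matrix), tolerance = 1e-14)
  ev <- eigen(mb$matrix, symmetric = TRUE)
  expect_equal(sort(mb$values), sort(ev$values), tolerance = 1e-12)
  # the all-ones mode really is an eigenvector with eigenvalue -1
  expect_equal(as.vector(mb$matrix %*% rep(1, 4)), rep(-1, 4),
               tolerance = 1e-12)
  # crossings are the symmetric two-bump arrangement
  expect_equal(mb$xi[2] - mb$xi[1], mb$xi[4] - mb$xi[3])
  expect_error(multibump_solve(30, 0.9, std_spec(L = 2 * pi)), "pi")
})

test_that("travelling wave: speed equals width, threshold values at the
           activity edges, stability matrix structure", {
  spec <- std_spec()
  ws <- wave_solve(30, 1, spec)
  expect_equal(ws$c, ws$Delta)
  expect_equal(diff(ws$xi), 3 * ws$Delta)
  # mesoscopic profile attains h exactly at both activity-set edges
  expect_equal(wave_meso_profile(-2 * ws$Delta, ws$Delta, 30, spec), 1,
               tolerance = 1e-10)
  expect_equal(wave_meso_profile(ws$Delta, ws$Delta, 30, spec), 1,
               tolerance = 1e-10)

  # translation mode: row sums are 1, all-ones eigenvector with eigenvalue 1
  M <- wave_stability_matrix(ws$Delta, spec)
  expect_equal(rowSums(M), rep(1, 7), tolerance = 1e-14)
  # spectrum agrees with the characteristic-polynomial roots
  cp <- pracma::charpoly(M)
  pr <- polyroot(rev(cp))
  ev <- eigen(M, only.values = TRUE)$values
  # the matrix has a triple zero eigenvalue; polyroot resolves a root of
  # multiplicity three only to ~eps^(1/3), so compare the simple roots
  expect_equal(sort(Mod(ev))[4:7], sort(Mod(pr))[4:7], tolerance = 1e-6)

  # stability flips with gain: stable at kappa = 38, unstable at kappa = 30
  # (threshold h = 0.9)
  s38 <- wave_solve(38, 0.9, spec)
  s30 <- wave_solve(30, 0.9, spec)
  expect_true(s38$stable)
  expect_false(s30$stable)
})

test_that("perturbed-wave interface map: fixed point at zero, linearisation
           equals the stability matrix, validity guard", {
  spec <- std_spec()
  kappa <- 38; h <- 0.9
  ws <- wave_solve(kappa, h, spec)
  expect_equal(perturbed_wave_step(rep(0, 7), ws$Delta, kappa, h, spec),
               rep(0, 7), tolerance = 1e-12)
  M <- wave_stability_matrix(ws$Delta, spec)
  ee <- 1e-6
  Jfd <- vapply(1:7, function(j) {
    d <- rep(0, 7)
    s <- if (j == 3) -1 else 1       # keep delta3 <= delta4
    d[j] <- s * ee
    perturbed_wave_step(d, ws$Delta, kappa, h, spec) / (s * ee)
  }, numeric(7))
  expect_lt(max(abs(Jfd - M)), 1e-5)
  expect_error(perturbed_wave_step(c(0, 0, 0.1, 0.05, 0, 0, 0),
                                   ws$Delta, kappa, h, spec), "validity")
})

test_that("partition dynamics: wave shifts rigidly, trivial fixed point,
           agreement with the fine lattice", {
  spec <- std_spec()
  par <- det_params(kappa = 30, h = 1, spec = spec)
  ws <- wave_solve(30, 1, spec)
  out <- partition_step(ws$partition, par)
  # expected: the input partition shifted right by Delta (compare labels at
  # off-boundary sample points; canonicalisation may move the seam)
  xs <- seq(-pi + 1e-4, pi - 1e-4, length.out = 2001)
  expect_true(mean(partition_label_at(out, xs) ==
                     partition_label_at(ws$partition, xs - ws$Delta)) >
                0.999)

  rest <- circle_partition(-pi, pi, 0L, pi)
  out2 <- partition_step(rest, par)
  expect_equal(nrow(out2), 1)
  expect_identical(out2$label, 0L)

  # strip bump: continuum step agrees with the fine-lattice step nodewise
  part <- strip_bump_state(0, 1.5, 8)
  par2 <- det_params(kappa = 30, h = 0.9, spec = spec)
  pstep <- partition_step(part, par2)
  N <- 4096
  lstep <- deterministic_step(partition_to_state(part, N), par2)
  agree <- mean(partition_label_at(pstep, ring_grid(N, pi)) ==
                  unclass(lstep))
  expect_gte(agree, 0.999)
})

test_that("bump midpoint curvature: zero slope, stencil agreement, dimple
           onset along the branch", {
  spec <- std_spec()
  kappa <- 40; h <- 1
  Delta <- bump_width(kappa, h, spec)[2]   # wide root of the localized pair
  # mirror symmetry forces a critical point at the midpoint
  ee <- 1e-6
  slope <- (bump_meso_profile(Delta / 2 + ee, 0, Delta, kappa, spec) -
              bump_meso_profile(Delta / 2 - ee, 0, Delta, kappa, spec)) / (2 * ee)
  expect_lt(abs(slope), 1e-8)
  # closed-form curvature vs a 5-point stencil
  hh <- 1e-4
  xs <- Delta / 2 + hh * (-2:2)
  Js <- bump_meso_profile(xs, 0, Delta, kappa, spec)
  stencil <- sum(c(-1, 16, -30, 16, -1) * Js) / (12 * hh^2)
  expect_equal(bump_center_curvature(Delta, kappa, spec), stencil,
               tolerance = 1e-5)

  # along the wide branch the curvature changes sign once: single hump at
  # low gain, dimple at high gain (midpoint becomes a local minimum); the
  # wide stable root is the first one past the cumulative-integral maximum
  wide <- function(k) { r <- bump_width(k, h, spec); r[r > 0.79][1] }
  curv <- function(k) bump_center_curvature(wide(k), k, spec)
  expect_lt(curv(35), 0)
  expect_gt(curv(55), 0)
  D55 <- wide(55)
  mid <- bump_meso_profile(D55 / 2, 0, D55, 55, spec)
  near <- bump_meso_profile(D55 / 2 + c(-0.05, 0.05), 0, D55, 55, spec)
  expect_true(all(near > mid))
})

test_that("heterogeneous bump residual: homogeneous reduction and Newton
           convergence under weak modulation", {
  hom <- std_spec()
  Delta <- bump_width(30, 0.9, hom)[2]
  for (d in c(-0.7, 0, 0.4)) {
    r <- het_bump_residual(c(d, d + Delta), 30, 0.9, hom)
    expect_lt(max(abs(r)), 1e-10)
  }
  het <- std_spec(W0 = 0.01, s = 0.5)
  xi <- c(-Delta / 2, Delta / 2)
  for (it in 1:20) {
    Fv <- het_bump_residual(xi, 30, 0.9, het)
    if (max(abs(Fv)) < 1e-11) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      xp <- xi; xp[j] <- xp[j] + 1e-7
      J[, j] <- (het_bump_residual(xp, 30, 0.9, het) - Fv) / 1e-7
    }
    xi <- xi - 0.8 * solve(J, Fv)
  }
  expect_lt(max(abs(het_bump_residual(xi, 30, 0.9, het))), 1e-10)
})
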