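#' Mesoscopic bump profile
#'
#' `J_b(x, eta1, eta2) = (kappa/3) int_{eta1}^{eta2} W(x - y) dy`, the limit of
#' the strip-microstate synaptic profile as the number of strips grows: in the
#' limit exactly one third of the window contributes to the spiking set.
#'
#' @param x evaluation positions.
#' @param eta1,eta2 window edges, `eta1 < eta2`.
#' @param kappa synaptic gain.
#' @param spec a [kernel_spec()].
#' @return Numeric vector `J_b(x)`.
#' @export
bump_meso_profile <- function(x, eta1, eta2, kappa, spec) {
  stopifnot(eta1 < eta2)
  kappa / 3 * kernel_interval_integral(x - eta2, x - eta1, spec)
}

# all roots of a scalar function on a grid-bracketed interval
.all_roots <- function(g, lo, hi, n = 2000, tol = 1e-13) {
  xs <- seq(lo, hi, length.out = n)
  gv <- vapply(xs, g, numeric(1))
  sc <- which(gv[-n] * gv[-1] < 0)
  exact <- xs[gv == 0]
  roots <- vapply(sc, function(i)
    stats::uniroot(g, c(xs[i], xs[i + 1]), tol = tol)$root, numeric(1))
  sort(unique(c(exact, roots)))
}

#' Bump width from the threshold condition
#'
#' Solves `3 h = kappa int_0^Delta W(y) dy` for the bump width. Both a narrow
#' and a wide root typically exist above the saddle-node gain; all roots are
#' returned sorted (narrow first). The construction proper requires
#' `Delta < L`; on the ring the same threshold condition continues the wide
#' branch up to widths approaching the full circumference (the finite domain
#' caps the achievable width), so roots are sought on `(0, 2L)`.
#'
#' @param kappa,h gain and threshold (> 0).
#' @param spec a [kernel_spec()].
#' @return Numeric vector of widths (possibly length > 1).
#' @export
bump_width <- function(kappa, h, spec) {
  stopifnot(kappa > 0, h > 0)
  g <- function(D) kappa * kernel_interval_integral(0, D, spec) - 3 * h
  roots <- .all_roots(g, 1e-9, 2 * spec$L - 1e-6, n = 4000)
  if (length(roots) == 0)
    stop("no bump exists at these parameters (kappa = ", kappa,
         ", h = ", h, ")", call. = FALSE)
  roots
}

#' Interface stability of the bump
#'
#' Assembles the 2x2 linearisation of the implicit interface evolution at the
#' bump fixed point, `[[-W(0), W(Delta)], [W(Delta), -W(0)]] / (W(0) -
#' W(Delta))`. Its translation eigenvalue is -1 exactly (eigenvector
#' proportional to (1, 1)); the second eigenvalue
#' `-(W(0) + W(Delta)) / (W(0) - W(Delta))` governs width perturbations and
#' the bump is stable when its modulus is below 1, i.e. when `W(Delta) < 0`
#' given `W(0) > 0`.
#'
#' @param Delta bump width.
#' @param spec a [kernel_spec()].
#' @return List with `matrix`, `values` (translation first), `vectors`
#'   (columns matching `values`), `stable`.
#' @export
bump_eigs <- function(Delta, spec) {
  W0 <- periodic_kernel(0, spec)
  WD <- periodic_kernel(Delta, spec)
  if (abs(W0 - WD) < 1e-12)
    stop("singular normalisation: W(0) = W(Delta)", call. = FALSE)
  M <- matrix(c(-W0, WD, WD, -W0), 2, 2) / (W0 - WD)
  lam2 <- -(W0 + WD) / (W0 - WD)
  list(matrix = M,
       values = c(-1, lam2),
       vectors = cbind(c(1, 1) / sqrt(2), c(-1, 1) / sqrt(2)),
       stable = abs(lam2) < 1)
}

#' Symmetric two-bump solution on the ring of half-length pi
#'
#' Constructs the even two-bump state whose threshold crossings are
#' `(-pi - Delta, -pi + Delta, pi - Delta, pi + Delta)/2`, with `Delta`
#' solving the superposed threshold condition, and assembles the 4x4
#' interface stability matrix (normalisation
#' `alpha = -W(0) + W(Delta) - W(pi) + W(pi - Delta)`). The translation
#' eigenvalue is -1 with eigenvector (1,1,1,1); the other three eigenvalues
#' have printed closed forms against the mode vectors (1,1,-1,-1),
#' (1,-1,1,-1), (1,-1,-1,1).
#'
#' @param kappa,h gain and threshold.
#' @param spec a [kernel_spec()]; its half-length must be pi (the construction
#'   is specific to that domain).
#' @return List with `Delta` (all roots), `xi` (crossings for the first
#'   root), `matrix`, `values`, `vectors`, `stable` for the widest root.
#' @export
multibump_solve <- function(kappa, h, spec) {
  if (abs(spec$L - pi) > 1e-8)
    stop("the two-bump construction requires a domain of half-length pi",
         call. = FALSE)
  two_bump_J <- function(x, Delta) {
    bump_meso_profile(x, (-pi - Delta) / 2, (-pi + Delta) / 2, kappa, spec) +
      bump_meso_profile(x, (pi - Delta) / 2, (pi + Delta) / 2, kappa, spec)
  }
  g <- function(D) two_bump_J((pi + D) / 2, D) - h
  roots <- .all_roots(g, 1e-9, pi - 1e-9)
  if (length(roots) == 0)
    stop("no two-bump solution at these parameters", call. = FALSE)
  # select the observable branch: the root with the smallest non-neutral
  # spectral radius (the stable two-bump when one exists)
  radius <- vapply(roots, function(D) {
    W0 <- periodic_kernel(0, spec); WD <- periodic_kernel(D, spec)
    Wp <- periodic_kernel(pi, spec); WpD <- periodic_kernel(pi - D, spec)
    den <- W0 - WD + Wp - WpD
    max(abs(c((-W0 + WD + Wp - WpD) / den, (-W0 - WD - Wp - WpD) / den,
              (-W0 - WD + Wp + WpD) / den)))
  }, numeric(1))
  Delta <- roots[which.min(radius)]
  xi <- c(-pi - Delta, -pi + Delta, pi - Delta, pi + Delta) / 2
  W0 <- periodic_kernel(0, spec);      WD <- periodic_kernel(Delta, spec)
  Wp <- periodic_kernel(pi, spec);     WpD <- periodic_kernel(pi - Delta, spec)
  alpha <- -W0 + WD - Wp + WpD
  M <- matrix(c(W0, -WD,  Wp, -WpD,
                -WD,  W0, -WpD, Wp,
                Wp, -WpD,  W0, -WD,
                -WpD, Wp, -WD,  W0), 4, 4, byrow = TRUE) / alpha
  den <- W0 - WD + Wp - WpD
  vals <- c(-1,
            (-W0 + WD + Wp - WpD) / den,
            (-W0 - WD - Wp - WpD) / den,
            (-W0 - WD + Wp + WpD) / den)
  vecs <- cbind(c(1, 1, 1, 1), c(1, 1, -1, -1),
                c(1, -1, 1, -1), c(1, -1, -1, 1)) / 2
  list(Delta = roots, xi = xi, matrix = M, values = vals, vectors = vecs,
       stable = all(abs(vals[-1]) < 1))
}

#' Travelling wave of the deterministic model
#'
#' Solves `h = kappa int_Delta^{2 Delta} W(y) dy` for the wave width. The wave
#' has partition refractory `[-2 Delta, -Delta)`, spiking `[-Delta, 0)`,
#' quiescent elsewhere; it advances by `c = Delta` per step and its activity
#' set is `[-2 Delta, Delta]` (width `3 Delta`).
#'
#' @param kappa,h gain and threshold.
#' @param spec a [kernel_spec()].
#' @param branch `"upper"` (wide root, default), `"lower"`, or `"all"`.
#' @return For `"all"`, the numeric vector of roots. Otherwise a list of class
#'   `interface_wave` with `Delta`, `c`, `xi = c(-2 Delta, Delta)`,
#'   `partition`, eigenvalues of the wave-perturbation matrix and `stable`.
#' @export
wave_solve <- function(kappa, h, spec, branch = c("upper", "lower", "all")) {
  branch <- match.arg(branch)
  g <- function(D) kappa * kernel_interval_integral(D, 2 * D, spec) - h
  roots <- .all_roots(g, 1e-9, spec$L / 2)
  if (length(roots) == 0)
    stop("no travelling wave at these parameters (kappa = ", kappa,
         ", h = ", h, ")", call. = FALSE)
  if (branch == "all") return(roots)
  Delta <- if (branch == "upper") max(roots) else min(roots)
  part <- circle_partition(
    left  = c(-spec$L, -2 * Delta, -Delta, 0),
    right = c(-2 * Delta, -Delta, 0, spec$L),
    label = c(0L, -1L, 1L, 0L), L = spec$L)
  ei <- wave_stability_eigs(Delta, spec)
  structure(list(Delta = Delta, c = Delta, xi = c(-2 * Delta, Delta),
                 partition = part, kappa = kappa, h = h,
                 values = ei$values, stable = ei$stable),
            class = "interface_wave")
}

#' @export
print.interface_wave <- function(x, ...) {
  cat(sprintf("<interface_wave> Delta = c = %.6g, activity [-2D, D], %s\n",
              x$Delta, if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' Mesoscopic travelling-wave profile
#'
#' `J_tw(z) = kappa int_{-Delta}^0 W(z - y) dy`.
#'
#' @param z positions (wave frame).
#' @param Delta wave width.
#' @param kappa gain.
#' @param spec a [kernel_spec()].
#' @return Numeric vector.
#' @export
wave_meso_profile <- function(z, Delta, kappa, spec) {
  kappa * kernel_interval_integral(z, z + Delta, spec)
}

#' Wave-perturbation stability matrix
#'
#' Assembles the 7x7 one-step linearisation of the interface dynamics for a
#' class of perturbations in the wake of the wave (two extra small intervals
#' behind the front), with normalisation `alpha = W(2 Delta) - W(Delta)`. Row
#' sums equal 1, so the all-ones vector is an eigenvector with eigenvalue 1:
#' the neutral translation mode. The wave is linearly stable when all other
#' eigenvalues lie inside the unit circle. The kernel is evaluated through its
#' periodic extension (the base kernel differs by less than 1e-12 at the
#' standard scales except at `4 Delta`, where images matter on the ring).
#'
#' @param Delta wave width.
#' @param spec a [kernel_spec()].
#' @return The 7x7 matrix.
#' @export
wave_stability_matrix <- function(Delta, spec) {
  w1 <- periodic_kernel(Delta, spec)
  w2 <- periodic_kernel(2 * Delta, spec)
  w4 <- periodic_kernel(4 * Delta, spec)
  a <- w2 - w1
  if (abs(a) < 1e-12)
    stop("singular normalisation: W(2 Delta) = W(Delta)", call. = FALSE)
  M <- matrix(0, 7, 7)
  M[1, 3] <- a; M[2, 4] <- a
  M[3, 3] <- -w1; M[3, 4] <- w1; M[3, 6] <- -w1; M[3, 7] <- w2
  M[4, 5] <- a; M[5, 6] <- a; M[6, 7] <- a
  M[7, 3] <- w4; M[7, 4] <- -w4; M[7, 6] <- w2; M[7, 7] <- -w1
  M / a
}

#' Eigenvalues of the wave-perturbation matrix
#'
#' @inheritParams wave_stability_matrix
#' @return List with `values` (translation mode first), `max_nontranslational`
#'   (largest remaining modulus) and `stable`.
#' @export
wave_stability_eigs <- function(Delta, spec) {
  ev <- eigen(wave_stability_matrix(Delta, spec), only.values = TRUE)$values
  itr <- which.min(Mod(ev - 1))
  rest <- ev[-itr]
  list(values = c(ev[itr], rest),
       max_nontranslational = max(Mod(rest)),
       stable = max(Mod(rest)) < 1)
}

#' One step of the nonlinear perturbed-wave interface map
#'
#' Evolves the 7-vector of interface perturbations `delta` of the travelling
#' wave (two extra intervals in the wake). Five components are index shifts;
#' the two remaining components solve scalar threshold equations by bracketed
#' root finding. Valid while `delta[3] < delta[4]` (the perturbation intervals
#' keep their ordering); outside that region the map is undefined and an error
#' is raised.
#'
#' @param delta length-7 perturbation vector.
#' @param Delta unperturbed wave width.
#' @param kappa,h gain and threshold.
#' @param spec a [kernel_spec()].
#' @return The evolved 7-vector.
#' @export
perturbed_wave_step <- function(delta, Delta, kappa, h, spec) {
  stopifnot(length(delta) == 7)
  if (delta[3] > delta[4])
    stop("perturbation left validity region: delta[3] >= delta[4]",
         call. = FALSE)
  d <- delta
  # int over the two spiking intervals of w(z - y) dy as a function of z
  spikes_int <- function(z) {
    kernel_interval_integral(z - (-3 * Delta + d[4]),
                             z - (-3 * Delta + d[3]), spec) +
      kernel_interval_integral(z - d[7], z - (-Delta + d[6]), spec)
  }
  solve_edge <- function(base, d0) {
    g <- function(dd) spikes_int(base + dd) - h / kappa
    lo <- d0 - Delta / 2; hi <- d0 + Delta / 2
    for (i in 1:30) {
      if (g(lo) * g(hi) < 0) break
      lo <- lo - Delta / 4; hi <- hi + Delta / 4
      if (i == 30) stop("perturbation left validity region: no bracket",
                        call. = FALSE)
    }
    stats::uniroot(g, c(lo, hi), tol = 1e-13)$root
  }
  out <- numeric(7)
  out[1] <- d[3]; out[2] <- d[4]
  out[4] <- d[5]; out[5] <- d[6]; out[6] <- d[7]
  out[3] <- solve_edge(-2 * Delta, d[3])
  out[7] <- solve_edge(Delta, d[7])
  out
}

#' Curvature of the bump profile at its midpoint
#'
#' Second spatial derivative of `J_b(x, 0, Delta)` at `x = Delta/2`, in closed
#' form: `(2 kappa / 3) W'(Delta / 2)` (the first derivative vanishes by the
#' bump's mirror symmetry). Negative curvature means a single-hump profile;
#' positive curvature means the maximum has split and the profile has a dimple
#' at its centre.
#'
#' @param Delta bump width.
#' @param kappa gain.
#' @param spec a [kernel_spec()].
#' @return Scalar curvature.
#' @export
bump_center_curvature <- function(Delta, kappa, spec) {
  2 * kappa / 3 * periodic_kernel_deriv(Delta / 2, spec)
}

#' Threshold residual of a bump under heterogeneous coupling
#'
#' For the cosine-modulated coupling `W(x - y)(1 + W0 cos(y/s))`, returns the
#' two edge residuals
#' `(kappa/3) int_{xi1}^{xi2} W(xi_i - y)(1 + W0 cos(y/s)) dy - h`,
#' `i = 1, 2`. With `W0 = 0` the residual vanishes at any translate of the
#' homogeneous bump; with `W0 > 0` translation invariance is broken and the
#' zero set consists of isolated branches.
#'
#' @param xi length-2 vector of bump edges, `xi[1] < xi[2]`.
#' @param kappa,h gain and threshold.
#' @param spec a [kernel_spec()] (fields `W0`, `s` supply the heterogeneity).
#' @return Length-2 residual vector.
#' @export
het_bump_residual <- function(xi, kappa, h, spec) {
  stopifnot(length(xi) == 2, xi[1] < xi[2])
  c(kappa / 3 * heterogeneous_interval_integral(xi[1], xi[1], xi[2], spec) - h,
    kappa / 3 * heterogeneous_interval_integral(xi[2], xi[1], xi[2], spec) - h)
}
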