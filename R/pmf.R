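#' Single-neuron transition matrices in the Heaviside limit
#'
#' Column-stochastic 3x3 matrices over the state order (-1, 0, 1). `Q_ge`
#' applies where the expected synaptic input reaches threshold (quiescent
#' neurons fire surely); `Q_lt` applies elsewhere (quiescent neurons stay
#' quiescent). The two matrices differ only in the quiescent column.
#'
#' @param p refractory-release probability in (0, 1].
#' @return List with matrices `Q_lt` and `Q_ge`.
#' @export
transition_matrices <- function(p) {
  stopifnot(p > 0, p <= 1)
  Q <- function(f) matrix(c(1 - p, 0,     1,
                            p,     1 - f, 0,
                            0,     f,     0),
                          3, 3, byrow = TRUE,
                          dimnames = list(c("-1", "0", "1"),
                                          c("-1", "0", "1")))
  list(Q_lt = Q(0), Q_ge = Q(1))
}

#' Per-position state distribution object
#'
#' A 3 x N matrix of probabilities over the states (-1, 0, 1) at each ring
#' node; every column sums to 1.
#'
#' @param P 3 x N probability matrix (rows ordered -1, 0, 1).
#' @param x node positions.
#' @param dropped optional count of discarded ensemble members (for empirical
#'   distributions).
#' @return An object of class `state_pmf`.
#' @export
state_pmf <- function(P, x, dropped = NULL) {
  stopifnot(nrow(P) == 3, ncol(P) == length(x))
  cs <- colSums(P)
  if (any(abs(cs - 1) > 1e-8))
    stop("state_pmf columns must sum to 1", call. = FALSE)
  rownames(P) <- c("-1", "0", "1")
  structure(list(P = P, x = x), dropped = dropped, class = "state_pmf")
}

#' @export
print.state_pmf <- function(x, ...) {
  cat(sprintf("<state_pmf> %d positions\n", length(x$x)))
  invisible(x)
}

#' Stationary bump probability mass function
#'
#' Piecewise-constant pmf of the mean-field closure: quiescent with
#' probability 1 outside the active interval `[0, Delta]`; inside, the
#' normalised unit eigenvector of `Q_ge`, `p/(1+2p) (1/p, 1, 1)`. At `p = 1`
#' this is the uniform (1/3, 1/3, 1/3) occupancy whose expected synaptic
#' profile equals the deterministic bump profile.
#'
#' @param Delta bump width.
#' @param p refractory-release probability.
#' @param x node positions at which to tabulate (the active interval is
#'   `[0, Delta]`; shift `x` to reposition the bump).
#' @return A [state_pmf()].
#' @export
bump_pmf <- function(Delta, p, x) {
  inside <- x >= 0 & x <= Delta
  P <- matrix(0, 3, length(x))
  P[2, ] <- 1
  mu_in <- p / (1 + 2 * p) * c(1 / p, 1, 1)
  P[, inside] <- mu_in
  state_pmf(P, x)
}

#' Bump width of the stochastic (mean-field) bump
#'
#' Solves the compatibility condition
#' `h = kappa p / (1 + 2p) int_0^Delta W(Delta - y) dy`. At `p = 1` the
#' condition coincides with the deterministic threshold equation and the
#' returned widths equal [bump_width()].
#'
#' @param kappa,h gain and threshold.
#' @param p refractory-release probability.
#' @param spec a [kernel_spec()].
#' @return Numeric vector of widths (all roots in `(0, L)`, sorted).
#' @export
bump_width_stochastic <- function(kappa, h, p, spec) {
  stopifnot(kappa > 0, h > 0, p > 0, p <= 1)
  g <- function(D) kappa * p / (1 + 2 * p) *
    kernel_interval_integral(0, D, spec) - h
  roots <- .all_roots(g, 1e-9, 2 * spec$L - 1e-6, n = 4000)
  if (length(roots) == 0)
    stop("no stochastic bump at these parameters", call. = FALSE)
  roots
}

#' Per-strip return operators for the travelling wave
#'
#' Partitions the co-moving domain of circumference `c * n_strips` into strips
#' `I_j = [j c, (j+1) c)`, `j = -n_strips/2, ..., n_strips/2 - 1`, and builds
#' for each strip the product of `n_strips` single-step matrices, each `Q_ge`
#' or `Q_lt` according to whether the strip's midpoint, shifted back by `c k`
#' (k = 0 the earliest step, applied rightmost), lies in the wave's activity
#' set `[-2c, c)`.
#'
#' @param c wave speed (strip width, > 0).
#' @param p refractory-release probability.
#' @param n_strips even integer >= 4 (the domain is `n_strips` strips).
#' @return Named list of 3x3 column-stochastic matrices, names `j = -T/2,
#'   ..., T/2 - 1`.
#' @export
wave_strip_operators <- function(c, p, n_strips) {
  stopifnot(c > 0, n_strips >= 4, n_strips %% 2 == 0)
  Q <- transition_matrices(p)
  S <- c * n_strips
  js <- seq(-n_strips / 2, n_strips / 2 - 1)
  out <- lapply(js, function(j) {
    z <- (j + 0.5) * c
    R <- diag(3)
    for (k in 0:(n_strips - 1)) {
      zz <- z - c * k
      zz <- ((zz + 2 * c) %% S) - 2 * c   # wrap into [-2c, S - 2c)
      Qk <- if (zz >= -2 * c && zz < c) Q$Q_ge else Q$Q_lt
      R <- Qk %*% R                        # earliest step rightmost
    }
    R
  })
  names(out) <- as.character(js)
  out
}

# normalised right unit eigenvector of a stochastic matrix via null space
.unit_eigvec <- function(R, tol = 1e-9) {
  ns <- pracma::nullspace(diag(3) - R)
  if (is.null(ns) || ncol(ns) == 0)
    stop("no unit eigenvector found", call. = FALSE)
  if (ncol(ns) > 1)
    stop("degenerate strip: unit eigenvalue is not simple", call. = FALSE)
  v <- ns[, 1]
  if (sum(v) < 0) v <- -v
  v[v < 0 & v > -1e-12] <- 0
  if (any(v < 0))
    stop("unit eigenvector has negative entries", call. = FALSE)
  v / sum(v)
}

#' Travelling-wave probability mass function
#'
#' Computes the per-strip distribution of the stochastic travelling wave on a
#' co-moving domain of `n_strips` strips of width `c`.
#'
#' In `"fast"` mode the speed is fixed to the deterministic wave width
#' (`c = Delta` from [wave_solve()]) and each strip's distribution is the unit
#' eigenvector of its return operator: `n_strips` decoupled 3x3 eigenproblems.
#' In `"full"` mode the speed is an unknown coupled to the distributions
#' through the threshold condition
#' `h = kappa (rho_{-1})_1 int_{-c}^0 W(c - y) dy`; the full nonlinear system
#' is solved by Newton iteration seeded from the fast solution.
#'
#' @param kappa,h gain and threshold.
#' @param p refractory-release probability.
#' @param spec a [kernel_spec()].
#' @param mode `"fast"` or `"full"`.
#' @param n_strips even integer >= 4.
#' @return An object of class `wave_pmf`: list with `c`, `n_strips`, `rho`
#'   (3 x n_strips matrix, columns indexed by strip `j`), `R` (operator
#'   list) and `mode`.
#' @export
wave_pmf <- function(kappa, h, p, spec, mode = c("fast", "full"),
                     n_strips = 8) {
  mode <- match.arg(mode)
  Delta <- wave_solve(kappa, h, spec, branch = "upper")$Delta
  cc <- Delta
  R <- wave_strip_operators(cc, p, n_strips)
  rho <- vapply(R, .unit_eigvec, numeric(3))
  if (mode == "full") {
    # unknowns: all rho entries + c; equations: fixed-point + normalisation
    # per strip, plus the threshold condition
    Tn <- n_strips
    pack <- function(rho, cc) c(as.vector(rho), cc)
    Fsys <- function(v) {
      rh <- matrix(v[1:(3 * Tn)], 3, Tn)
      cv <- v[3 * Tn + 1]
      if (cv <= 0) return(rep(1e6, 3 * Tn + 1))
      Rv <- wave_strip_operators(cv, p, Tn)
      res <- numeric(3 * Tn + 1)
      for (i in seq_len(Tn)) {
        r <- rh[, i] - Rv[[i]] %*% rh[, i]
        r[3] <- sum(rh[, i]) - 1       # replace one redundant row
        res[(3 * i - 2):(3 * i)] <- r
      }
      i_m1 <- which(names(Rv) == "-1")
      # spiking-state component of the strip just behind the front
      res[3 * Tn + 1] <- -h +
        kappa * rh[3, i_m1] * kernel_interval_integral(cv, 2 * cv, spec)
      res
    }
    v <- pack(rho, cc)
    for (it in 1:40) {
      Fv <- Fsys(v)
      if (max(abs(Fv)) < 1e-12) break
      J <- matrix(0, length(v), length(v))
      ee <- 1e-7
      for (j in seq_along(v)) {
        vp <- v; vp[j] <- vp[j] + ee
        J[, j] <- (Fsys(vp) - Fv) / ee
      }
      dv <- tryCatch(solve(J, Fv), error = function(e) NULL)
      if (is.null(dv)) {
        warning("full-mode Newton hit a singular Jacobian; ",
                "returning fast solution")
        break
      }
      v <- v - dv
      if (it == 40) warning("full-mode Newton did not converge; ",
                            "result may be inaccurate")
    }
    rho <- matrix(v[1:(3 * Tn)], 3, Tn)
    cc <- v[3 * Tn + 1]
    R <- wave_strip_operators(cc, p, n_strips)
  }
  colnames(rho) <- names(R)
  rownames(rho) <- c("-1", "0", "1")
  structure(list(c = cc, n_strips = n_strips, rho = rho, R = R, mode = mode,
                 p = p, kappa = kappa, h = h),
            class = "wave_pmf")
}

#' @export
print.wave_pmf <- function(x, ...) {
  cat(sprintf("<wave_pmf> c=%.5g, %d strips (%s mode, p=%g)\n",
              x$c, x$n_strips, x$mode, x$p))
  invisible(x)
}

#' Tabulate a wave pmf on a lattice
#'
#' Positions the wave so that its activity set `[-2c, c)` maps onto
#' `[xi2 - 3c, xi2)`, assigns each node to a strip, and returns the nodewise
#' distribution. Nodes beyond the co-moving domain are assigned the nearest
#' outermost strip (far from the wave the distribution is quiescent-
#' dominated).
#'
#' @param wpmf a [wave_pmf()].
#' @param x node positions.
#' @param xi2 position of the wave front (falling threshold crossing).
#' @param L domain half-length.
#' @return A [state_pmf()].
#' @export
wave_pmf_on_grid <- function(wpmf, x, xi2, L) {
  cc <- wpmf$c; Tn <- wpmf$n_strips
  z <- x - xi2 + cc                      # wave frame: activity [-2c, c)
  z <- ((z + L) %% (2 * L)) - L          # wrap to the simulation ring
  j <- floor(z / cc)
  j[j < -Tn / 2] <- -Tn / 2
  j[j > Tn / 2 - 1] <- Tn / 2 - 1
  P <- wpmf$rho[, as.character(j), drop = FALSE]
  state_pmf(unname(P), x)
}

#' Draw a microscopic state from a nodewise distribution
#'
#' Independent categorical draw per node (one uniform variate per node, in
#' index order), so draws are reproducible under a fixed seed.
#'
#' @param pmf a [state_pmf()].
#' @param L domain half-length.
#' @return A [lattice_state()].
#' @export
sample_pmf <- function(pmf, L = pi) {
  P <- pmf$P
  r <- stats::runif(ncol(P))
  cum1 <- P[1, ]; cum2 <- P[1, ] + P[2, ]
  u <- ifelse(r < cum1, -1L, ifelse(r < cum2, 0L, 1L))
  lattice_state(u, L)
}
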