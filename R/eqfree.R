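#' Configuration of the coarse time-stepper
#'
#' @param N lattice size used by the microscopic evolution.
#' @param M realisations per coarse evaluation.
#' @param T_evolve microscopic steps per coarse step (>= 1; the evolution
#'   stage cannot be skipped).
#' @param eps_fd finite-difference increment for coarse Jacobians.
#' @param damping Newton damping factor in (0, 1].
#' @param ds pseudo-arclength step.
#' @param crn use common random numbers across the evaluations of one
#'   Jacobian/Newton solve (reduces variance of coarse derivatives).
#' @param lift_mode `"microstructure"` (random strip motifs, mirrored for
#'   symmetry), `"pmf"` (samples of the analytic bump distribution) or
#'   `"strips_regular"` (the deterministic 3m-strip state; for deterministic
#'   coarse runs).
#' @param strip_m strip width in grid cells for `"strips_regular"` (`NULL` =
#'   1 cell).
#' @param poisson_mean_cells mean extra strip width (in grid cells) of the
#'   microstructure sampler; strip widths are `1 + Poisson(mean)`.
#' @param flip_prob probability of reversing the state-cycling direction
#'   after each strip.
#' @return An object of class `eqfree_config`.
#' @export
eqfree_config <- function(N = 1024, M = 100, T_evolve = 1, eps_fd = 1e-6,
                          damping = 1, ds = 0.5, crn = TRUE,
                          lift_mode = c("microstructure", "pmf",
                                        "strips_regular"),
                          poisson_mean_cells = 3, flip_prob = 0.5,
                          strip_m = NULL) {
  lift_mode <- match.arg(lift_mode)
  stopifnot(M >= 1, T_evolve >= 1, eps_fd > 0, damping > 0, damping <= 1)
  structure(list(N = as.integer(N), M = as.integer(M),
                 T_evolve = as.integer(T_evolve), eps_fd = eps_fd,
                 damping = damping, ds = ds, crn = crn,
                 lift_mode = lift_mode,
                 poisson_mean_cells = poisson_mean_cells,
                 flip_prob = flip_prob, strip_m = strip_m),
            class = "eqfree_config")
}

# cycle through the ternary states in direction d
.cycle_state <- function(s, d) {
  idx <- match(s, c(-1L, 0L, 1L))
  c(-1L, 0L, 1L)[((idx - 1 + d) %% 3) + 1]
}

#' Lifting operator for bumps
#'
#' Maps a pair of threshold crossings to an ensemble of microscopic states
#' compatible with it. Every sample is quiescent outside the rounded interval
#' and mirror-symmetric about its midpoint. In `"microstructure"` mode the
#' left half is tiled left-to-right with strips of random width (1 + Poisson
#' cells) whose labels cycle through the three states in a direction that
#' reverses with probability `flip_prob` after each strip, then reflected. In
#' `"pmf"` mode nodes are drawn independently from the analytic bump
#' distribution positioned on the interval.
#'
#' @param xi length-2 coarse state (threshold crossings, `xi[1] < xi[2]`).
#' @param params a [model_params()].
#' @param cfg an [eqfree_config()].
#' @return An `N x M` integer matrix of states.
#' @export
lift_bump <- function(xi, params, cfg) {
  L <- params$kernel$L
  N <- cfg$N
  dx <- 2 * L / N
  width <- xi[2] - xi[1]
  if (width < 2 * dx)
    stop("lift-degenerate: interval narrower than 2 grid cells",
         call. = FALSE)
  if (width > 2 * L - 2 * dx)
    stop("lift-degenerate: interval covers the whole ring", call. = FALSE)
  i1 <- as.integer(round((xi[1] + L) / dx))    # node indices, 0-based
  i2 <- i1 + as.integer(round(width / dx))     # may wrap past the seam
  U <- matrix(0L, N, cfg$M)
  x <- ring_grid(N, L)
  rel <- (x - xi[1]) %% (2 * L)                # distance from the left edge
  if (cfg$lift_mode == "strips_regular") {
    # strips of fixed width anchored at each edge (mirror symmetric); the M
    # ensemble members carry uniformly shifted strip phases, so the ensemble
    # average of the restricted crossings approaches the infinite-strip
    # limit (edge-phase bias integrates to zero) and the coarse map responds
    # smoothly to sub-cell edge displacements
    sw <- (cfg$strip_m %||% 1L) * dx
    lefthalf <- rel < width / 2
    righthalf <- rel >= width / 2 & rel <= width
    for (mm in seq_len(cfg$M)) {
      phase <- 3 * (mm - 1) / cfg$M
      u <- integer(N)
      idxl <- floor(rel[lefthalf] / sw + phase)
      u[lefthalf] <- c(-1L, 0L, 1L)[(idxl %% 3) + 1]
      idxr <- floor((width - rel[righthalf]) / sw + phase)
      u[righthalf] <- c(-1L, 0L, 1L)[(idxr %% 3) + 1]
      U[, mm] <- u
    }
    return(U)
  }
  if (cfg$lift_mode == "pmf") {
    pmf <- bump_pmf(width, params$p, ifelse(rel <= width, rel, -1))
    for (m in seq_len(cfg$M)) U[, m] <- unclass(sample_pmf(pmf, L))
    return(U)
  }
  n_cells <- i2 - i1 + 1
  half <- ceiling(n_cells / 2)
  for (m in seq_len(cfg$M)) {
    lab <- integer(n_cells)
    s <- sample(c(-1L, 0L, 1L), 1)
    d <- 1L
    pos <- 1
    while (pos <= half) {
      len <- 1 + stats::rpois(1, cfg$poisson_mean_cells)
      lab[pos:min(pos + len - 1, half)] <- s
      pos <- pos + len
      s <- .cycle_state(s, d)
      if (stats::runif(1) < cfg$flip_prob) d <- -d
    }
    lab[(n_cells - half + 1):n_cells] <- rev(lab[1:half])
    U[(i1:i2) %% N + 1, m] <- lab
  }
  U
}

#' Lifting operator for travelling waves
#'
#' Draws each sample nodewise from the travelling-wave distribution with
#' speed `c = (xi[2] - xi[1]) / 3`, positioned so the activity set matches
#' `[xi[1], xi[2])`. The distribution carries the wave's characteristic
#' microstructure (spiking strip just behind the front, refractory wake), so
#' lifted ensembles evolve as waves rather than bumps.
#'
#' @inheritParams lift_bump
#' @param wpmf optionally, a precomputed [wave_pmf()] (it only depends on `p`
#'   and the strip count, so it can be reused along a branch).
#' @param n_strips strip count when `wpmf` is not supplied.
#' @return An `N x M` integer matrix of states.
#' @export
lift_wave <- function(xi, params, cfg, wpmf = NULL, n_strips = 8) {
  L <- params$kernel$L
  cc <- (xi[2] - xi[1]) / 3
  if (cc < 2 * L / cfg$N)
    stop("lift-degenerate: speed below one grid cell", call. = FALSE)
  if (is.null(wpmf)) {
    wpmf <- wave_pmf(params$kappa, params$h, params$p, params$kernel,
                     mode = "fast", n_strips = n_strips)
  }
  wpmf$c <- cc                           # reposition strips at the lifted speed
  x <- ring_grid(cfg$N, L)
  pmf <- wave_pmf_on_grid(wpmf, x, xi[2], L)
  U <- matrix(0L, cfg$N, cfg$M)
  for (m in seq_len(cfg$M)) U[, m] <- unclass(sample_pmf(pmf, L))
  U
}

#' Restriction operator
#'
#' Estimates the coarse state from an ensemble: for each member, the
#' synaptic profile is interpolated linearly between nodes and the rising and
#' falling crossings bounding its principal active interval are extracted;
#' members without crossings contribute the extinction marker (0, 0). The
#' coarse state is the ensemble mean. Crossings are unwrapped to the
#' half-ring around a reference point before averaging so that a bump or wave
#' near the seam is averaged consistently.
#'
#' @param U an `N x M` integer matrix of states.
#' @param params a [model_params()].
#' @param reference optional position near which crossings are unwrapped
#'   (defaults to the circular position of the first member's crossing).
#' @return List with `xi` (length-2 mean), `per_sample` (M x 2 matrix) and
#'   `n_extinct`.
#' @export
restrict_ensemble <- function(U, params, reference = NULL) {
  L <- params$kernel$L
  N <- nrow(U)
  wfft <- stats::fft(.kernel_weights(N, params))
  Jm <- .synaptic_ensemble(U, params, wfft)
  per <- matrix(0, ncol(U), 2)
  n_ext <- 0L
  for (m in seq_len(ncol(U))) {
    pr <- .principal_pair(Jm[, m], params$h, L)
    if (anyNA(pr)) { n_ext <- n_ext + 1L; next }
    width <- (pr[2] - pr[1]) %% (2 * L)
    if (is.null(reference)) reference <- pr[1]
    x1 <- reference + (((pr[1] - reference) + L) %% (2 * L)) - L
    per[m, ] <- c(x1, x1 + width)
  }
  # extinct members contribute the (0, 0) marker to the mean
  list(xi = colMeans(per), per_sample = per, n_extinct = n_ext)
}

#' Coarse time-stepper
#'
#' Lift, evolve `T_evolve` microscopic steps, restrict.
#'
#' @param xi length-2 coarse state.
#' @param pattern `"bump"` or `"wave"` (selects the lifting operator).
#' @param params a [model_params()].
#' @param cfg an [eqfree_config()].
#' @param deterministic evolve with the deterministic rule (Heaviside,
#'   p = 1).
#' @param wpmf optional precomputed [wave_pmf()] passed to [lift_wave()].
#' @return Length-2 coarse state; `(0, 0)` flags coarse extinction. The
#'   number of extinct realisations is attached as attribute `n_extinct`.
#' @export
coarse_map <- function(xi, pattern = c("bump", "wave"), params, cfg,
                       deterministic = FALSE, wpmf = NULL) {
  pattern <- match.arg(pattern)
  U <- if (pattern == "bump") lift_bump(xi, params, cfg)
       else lift_wave(xi, params, cfg, wpmf = wpmf)
  wfft <- stats::fft(.kernel_weights(nrow(U), params))
  for (t in seq_len(cfg$T_evolve))
    U <- .step_ensemble(U, params, wfft, deterministic = deterministic)
  r <- restrict_ensemble(U, params, reference = xi[1])
  structure(r$xi, n_extinct = r$n_extinct)
}

# signed minimal circular difference a - b on a ring of circumference circ
.circ_diff <- function(a, b, circ) {
  d <- (a - b) %% circ
  ifelse(d > circ / 2, d - circ, d)
}

#' Coarse residuals for Newton / continuation
#'
#' `residual_bump` pins the translation mode by its first component:
#' `F = (xi1, xi2 - (Phi_b(xi))_2)`. `residual_wave` additionally carries the
#' speed: `F = (xi1, xi2 + c T - (Phi_tw(xi))_2 (mod ring), c - (xi2 -
#' xi1)/3)`; the front of a rigidly translating wave advances by `c` per
#' microscopic step, so the residual vanishes on the coarse wave. Coarse
#' extinction returns a large sentinel so that a Newton corrector backtracks
#' instead of converging to the trivial state.
#'
#' @param xi length-2 coarse state.
#' @param params a [model_params()].
#' @param cfg an [eqfree_config()].
#' @param deterministic,wpmf passed to [coarse_map()].
#' @return Residual vector (length 2 for the bump, 3 for the wave).
#' @export
residual_bump <- function(xi, params, cfg, deterministic = FALSE) {
  phi <- tryCatch(
    coarse_map(xi, "bump", params, cfg, deterministic = deterministic),
    error = function(e) c(0, 0))
  if (all(phi == 0)) return(c(xi[1], 1e6))
  c(xi[1], xi[2] - phi[2])
}

#' @rdname residual_bump
#' @param xic length-3 vector `(xi1, xi2, c)`.
#' @export
residual_wave <- function(xic, params, cfg, deterministic = FALSE,
                          wpmf = NULL) {
  xi <- xic[1:2]; cc <- xic[3]
  phi <- tryCatch(
    coarse_map(xi, "wave", params, cfg, deterministic = deterministic,
               wpmf = wpmf),
    error = function(e) c(0, 0))
  if (all(phi == 0)) return(c(xi[1], 1e6, 1e6))
  L <- params$kernel$L
  c(xi[1],
    .circ_diff(xi[2] + cc * cfg$T_evolve, phi[2], 2 * L),
    cc - (xi[2] - xi[1]) / 3)
}

#' Forward finite-difference Jacobian
#'
#' One forward difference per coordinate; exact for affine maps. When the
#' evaluations of `F` are stochastic, pass a function that fixes its own
#' random numbers (see `with_fixed_seed`) so all columns share one noise
#' realisation.
#'
#' @param F function from length-n numeric to length-m numeric.
#' @param x evaluation point.
#' @param eps increment.
#' @param F0 optionally, a precomputed `F(x)`.
#' @return An m x n Jacobian matrix.
#' @export
fd_jacobian <- function(F, x, eps = 1e-6, F0 = NULL) {
  if (is.null(F0)) F0 <- F(x)
  J <- matrix(0, length(F0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + eps
    J[, j] <- (F(xp) - F0) / eps
  }
  J
}

#' Evaluate a function under a fixed RNG substream
#'
#' Runs `expr`-like function `f(...)` after seeding the generator, restoring
#' the caller's RNG state afterwards. Used to implement common random numbers
#' in coarse Jacobians and Newton solves.
#'
#' @param f function to call.
#' @param seed integer seed.
#' @param ... arguments to `f`.
#' @return The value of `f(...)`.
#' @export
with_fixed_seed <- function(f, seed, ...) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  f(...)
}

#' Damped Newton iteration with finite-difference Jacobians
#'
#' `x_{k+1} = x_k - damping * J^{-1} F(x_k)`; stops when the residual
#' infinity-norm falls below `tol` or after `maxit` iterations.
#'
#' @param F residual function.
#' @param x0 starting point.
#' @param damping damping factor in (0, 1].
#' @param tol residual tolerance.
#' @param maxit iteration cap.
#' @param eps_fd finite-difference increment.
#' @param max_step clamp on the Newton step 2-norm (useful when the residual
#'   is a noisy coarse estimate).
#' @return List with `x`, `residuals` (infinity-norm history, one entry per
#'   iterate including the start), `converged`, `iterations`.
#' @export
newton_damped <- function(F, x0, damping = 1, tol = 1e-10, maxit = 30,
                          eps_fd = 1e-6, max_step = Inf) {
  x <- x0
  hist <- numeric(0)
  best <- list(x = x0, r = Inf)
  for (k in seq_len(maxit)) {
    Fv <- F(x)
    r <- max(abs(Fv))
    hist <- c(hist, r)
    if (r < best$r) best <- list(x = x, r = r)
    if (r < tol)
      return(list(x = x, residuals = hist, converged = TRUE,
                  iterations = k - 1))
    J <- fd_jacobian(F, x, eps = eps_fd, F0 = Fv)
    dx <- tryCatch(solve(J, Fv), error = function(e) NULL)
    if (is.null(dx))
      stop("singular Jacobian in Newton iteration", call. = FALSE)
    nrm <- sqrt(sum(dx^2))
    if (nrm > max_step) dx <- dx * max_step / nrm
    x <- x - damping * dx
  }
  Fv <- F(x); r <- max(abs(Fv)); hist <- c(hist, r)
  if (r < best$r) best <- list(x = x, r = r)
  list(x = best$x, residuals = hist, converged = r < tol,
       iterations = maxit)
}

#' Pseudo-arclength continuation
#'
#' Follows the solution branch of `residual(x, gamma) = 0` in the extended
#' space `(x, gamma)` with a secant predictor and a bordered Newton corrector,
#' traversing folds (sign changes of `d gamma / ds`). Works identically for
#' analytic residuals (interface theory) and coarse time-stepper residuals.
#'
#' @param residual function `(x, gamma) -> numeric(length(x))`.
#' @param x0 converged starting state.
#' @param gamma0 starting parameter value.
#' @param ds arclength step (sign sets the initial direction of `gamma`).
#' @param n_steps number of continuation steps.
#' @param tol corrector tolerance.
#' @param maxit corrector iteration cap.
#' @param eps_fd finite-difference increment.
#' @param ds_min step-halving floor; the branch stops early when reached.
#' @param eig_fn optional `function(x, gamma) -> complex vector` evaluated at
#'   accepted points (e.g. coarse Jacobian eigenvalues).
#' @param stop_fn optional `function(x, gamma) -> logical`; `TRUE` stops the
#'   branch (e.g. a width leaving the localised regime).
#' @return A tibble of class `nca_branch`: columns `step`, `gamma`, the state
#'   components `x1`, `x2`, ..., `residual`, `fold` (`TRUE` where
#'   `d gamma/ds` changes sign), and when `eig_fn` is given `eigenvalues`
#'   (list column), `max_mod`, `stable`.
#' @export
arclength_continue <- function(residual, x0, gamma0, ds, n_steps,
                               tol = 1e-10, maxit = 25, eps_fd = 1e-7,
                               ds_min = NULL, eig_fn = NULL,
                               stop_fn = NULL) {
  if (is.null(ds_min)) ds_min <- abs(ds) / 64
  n <- length(x0)
  ext <- function(v) list(x = v[seq_len(n)], gamma = v[n + 1])
  Fext <- function(v) {
    out <- tryCatch(residual(v[seq_len(n)], v[n + 1]),
                    error = function(e) rep(NA_real_, n))
    if (anyNA(out) || any(!is.finite(out))) rep(1e6, n) else out
  }
  # converge the starting point at fixed gamma
  st <- newton_damped(function(x) residual(x, gamma0), x0, tol = tol,
                      maxit = maxit, eps_fd = eps_fd)
  if (!st$converged)
    stop("continuation: starting point did not converge", call. = FALSE)
  v0 <- c(st$x, gamma0)
  # second point by a small natural-parameter step
  g1 <- gamma0 + sign(ds) * max(abs(ds) / 4, 1e-4)
  st1 <- newton_damped(function(x) residual(x, g1), st$x, tol = tol,
                       maxit = maxit, eps_fd = eps_fd)
  if (!st1$converged)
    stop("continuation: could not take the first step", call. = FALSE)
  v1 <- c(st1$x, g1)
  rows <- list()
  add_row <- function(step, v, res) {
    e <- ext(v)
    row <- tibble::tibble(step = step, gamma = e$gamma,
                          !!!stats::setNames(as.list(e$x),
                                             paste0("x", seq_len(n))),
                          residual = res, fold = FALSE)
    if (!is.null(eig_fn)) {
      ev <- eig_fn(e$x, e$gamma)
      row$eigenvalues <- list(ev)
      row$max_mod <- max(Mod(ev))
      row$stable <- all(Mod(ev) < 1)
    }
    rows[[length(rows) + 1]] <<- row
  }
  add_row(0L, v0, max(abs(Fext(v0))))
  add_row(1L, v1, max(abs(Fext(v1))))
  vk <- v1; vkm <- v0
  h <- abs(ds)
  step <- 1L
  while (step < n_steps) {
    tan <- vk - vkm
    tan <- tan / sqrt(sum(tan^2))
    accepted <- FALSE
    while (!accepted) {
      vg <- vk + h * tan
      ok <- TRUE
      for (it in seq_len(maxit)) {
        Fv <- Fext(vg)
        Nv <- sum((vg - vk) * tan) - h
        R <- c(Fv, Nv)
        if (max(abs(R)) < tol) break
        Jx <- matrix(0, n, n + 1)
        for (j in seq_len(n + 1)) {
          vp <- vg; vp[j] <- vp[j] + eps_fd
          Jx[, j] <- (Fext(vp) - Fv) / eps_fd
        }
        J <- rbind(Jx, tan)
        dv <- tryCatch(solve(J, R), error = function(e) NULL)
        if (is.null(dv) || !all(is.finite(dv))) { ok <- FALSE; break }
        vg <- vg - dv
        if (it == maxit) ok <- FALSE
      }
      if (ok) {
        accepted <- TRUE
      } else {
        h <- h / 2
        if (h < ds_min) break
      }
    }
    if (!accepted) break
    step <- step + 1L
    add_row(step, vg, max(abs(Fext(vg))))
    # fold: sign change of the gamma component of the secant
    k <- length(rows)
    dg1 <- rows[[k]]$gamma - rows[[k - 1]]$gamma
    dg0 <- rows[[k - 1]]$gamma - rows[[k - 2]]$gamma
    if (dg1 * dg0 < 0) rows[[k - 1]]$fold <- TRUE
    vkm <- vk; vk <- vg
    h <- min(h * 1.3, abs(ds))
    if (!is.null(stop_fn) && isTRUE(stop_fn(ext(vg)$x, ext(vg)$gamma))) break
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nca_branch", class(out))
  out
}

#' Coarse linear stability from the finite-difference Jacobian
#'
#' Eigenvalues of the forward-difference Jacobian of the coarse time-stepper
#' at a coarse state. Translation invariance of the lattice dynamics makes
#' (1, 1) an eigenvector with eigenvalue near 1 (the neutral mode); the
#' remaining eigenvalue governs coarse stability of the pattern width. For
#' stochastic dynamics the evaluations share one random-number stream when
#' `seed` is given (common random numbers).
#'
#' @param xi length-2 coarse state.
#' @param pattern `"bump"` or `"wave"`.
#' @param params a [model_params()].
#' @param cfg an [eqfree_config()].
#' @param eps finite-difference increment (default: four grid cells).
#' @param seed integer seed for common random numbers (`NULL` = use the
#'   current stream).
#' @param deterministic,wpmf passed to [coarse_map()].
#' @return List with `values` (translation mode first), `jacobian`,
#'   `max_nontranslational`, `stable`.
#' @export
coarse_stability <- function(xi, pattern, params, cfg,
                             eps = 8 * params$kernel$L / cfg$N,
                             seed = NULL, deterministic = FALSE,
                             wpmf = NULL) {
  G <- function(x) {
    f <- function() coarse_map(x, pattern, params, cfg,
                               deterministic = deterministic, wpmf = wpmf)
    if (is.null(seed)) f() else with_fixed_seed(f, seed)
  }
  J <- fd_jacobian(G, xi, eps = eps)
  ev <- eigen(J, only.values = TRUE)$values
  itr <- which.min(Mod(ev - 1))
  rest <- ev[-itr]
  list(values = c(ev[itr], rest), jacobian = J,
       max_nontranslational = max(Mod(rest)),
       stable = max(Mod(rest)) < 1)
}
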