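#' Model parameters for the three-state automaton
#'
#' @param kappa synaptic gain (> 0).
#' @param beta firing-rate steepness; `Inf` selects the Heaviside limit with
#'   the convention that input exactly at threshold fires (`Theta(0) = 1`,
#'   consistent with the active-set definition `J >= h`).
#' @param h firing threshold.
#' @param p refractory-release probability in (0, 1].
#' @param kernel a [kernel_spec()].
#' @return An object of class `nca_params`.
#' @export
model_params <- function(kappa = 30, beta = 5, h = 0.9, p = 0.7,
                         kernel = kernel_spec()) {
  stopifnot(kappa > 0, beta > 0, p > 0, p <= 1,
            inherits(kernel, "kernel_spec"))
  structure(list(kappa = kappa, beta = beta, h = h, p = p, kernel = kernel),
            class = "nca_params")
}

#' @export
print.nca_params <- function(x, ...) {
  cat(sprintf("<nca_params> kappa=%g beta=%s h=%g p=%g (kernel: %s, L=%g)\n",
              x$kappa, if (is.infinite(x$beta)) "Inf (Heaviside)" else x$beta,
              x$h, x$p, x$kernel$convention, x$kernel$L))
  invisible(x)
}

#' Ring grid positions
#'
#' `N` evenly spaced nodes `x_i = -L + i 2L/N`, `i = 0, ..., N-1`. The
#' periodic endpoint `x = L` is identified with `x = -L` and not duplicated.
#'
#' @param N number of neurons.
#' @param L half-length of the domain.
#' @return Numeric vector of node positions.
#' @export
ring_grid <- function(N, L) -L + (0:(N - 1)) * 2 * L / N

#' Microscopic lattice state
#'
#' A configuration `u` in {-1, 0, 1}^N on the ring grid: -1 refractory,
#' 0 quiescent, 1 spiking.
#'
#' @param u integer vector with entries in {-1, 0, 1}.
#' @param L half-length of the ring.
#' @return An object of class `lattice_state` (integer vector with attributes
#'   `L` and `x`, the node positions).
#' @export
lattice_state <- function(u, L = pi) {
  u <- as.integer(u)
  if (!all(u %in% c(-1L, 0L, 1L)))
    stop("state entries must lie in {-1, 0, 1}", call. = FALSE)
  structure(u, L = L, x = ring_grid(length(u), L), class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  tb <- table(factor(unclass(x), levels = c(-1, 0, 1)))
  cat(sprintf("<lattice_state> N=%d L=%g  [-1]:%d [0]:%d [1]:%d\n",
              length(x), attr(x, "L"), tb[[1]], tb[[2]], tb[[3]]))
  invisible(x)
}

# kernel weight vector for circular convolution on an N-node ring
.kernel_weights <- function(N, params) {
  L <- params$kernel$L
  periodic_kernel((0:(N - 1)) * 2 * L / N, params$kernel)
}

# J for an ensemble: U is an N x M matrix of states, wfft = fft(weights)
.synaptic_ensemble <- function(U, params, wfft = NULL) {
  N <- nrow(U)
  if (is.null(wfft)) wfft <- stats::fft(.kernel_weights(N, params))
  S <- (U == 1L) * 1
  JF <- stats::mvfft(S) * wfft
  Re(stats::mvfft(JF, inverse = TRUE)) / N * params$kappa *
    (2 * params$kernel$L / N)
}

#' Mesoscopic synaptic input profile
#'
#' `J(x_i) = kappa (2L/N) sum_j W(x_i - x_j) [u_j = 1]`, evaluated by circular
#' convolution (FFT); identical to direct double-loop summation to rounding
#' error.
#'
#' @param state a [lattice_state()].
#' @param params a [model_params()].
#' @return An object of class `meso_field`: list with the profile `J`, the
#'   threshold `h`, node positions `x` and the domain half-length `L`.
#' @export
synaptic_input <- function(state, params) {
  U <- matrix(unclass(state), ncol = 1)
  J <- .synaptic_ensemble(U, params)[, 1]
  meso_field(J, params$h, attr(state, "L"))
}

#' Construct a mesoscopic field object
#'
#' @param J numeric vector of synaptic input values at the ring nodes.
#' @param h firing threshold.
#' @param L domain half-length.
#' @return An object of class `meso_field`.
#' @export
meso_field <- function(J, h, L = pi) {
  structure(list(J = J, h = h, L = L, x = ring_grid(length(J), L)),
            class = "meso_field")
}

#' @export
print.meso_field <- function(x, ...) {
  cr <- threshold_crossings(x)
  cat(sprintf("<meso_field> N=%d h=%g max(J)=%.4g crossings=%d\n",
              length(x$J), x$h, max(x$J), nrow(cr)))
  invisible(x)
}

#' Firing rate function
#'
#' Sigmoid `1 / (1 + exp(-beta (I - h)))`; in the Heaviside limit
#' (`beta = Inf`) returns 1 when `I >= h`, else 0.
#'
#' @param I synaptic input value(s).
#' @param params a [model_params()].
#' @return Firing probabilities in \[0, 1\].
#' @export
firing_rate <- function(I, params) {
  if (is.infinite(params$beta)) return(as.numeric(I >= params$h))
  stats::plogis(params$beta * (I - params$h))
}

# shared single-step kernel for an ensemble matrix; one uniform draw per
# neuron per step, consumed in column-major (fixed index) order
.step_ensemble <- function(U, params, wfft = NULL, deterministic = FALSE) {
  J <- .synaptic_ensemble(U, params, wfft)
  if (deterministic) {
    active <- J >= params$h
    Unew <- matrix(0L, nrow(U), ncol(U))
    Unew[U == 1L] <- -1L
    Unew[U == 0L & active] <- 1L
    return(Unew)
  }
  q <- firing_rate(J, params)
  r <- matrix(stats::runif(length(U)), nrow(U), ncol(U))
  Unew <- matrix(0L, nrow(U), ncol(U))
  Unew[U == 1L] <- -1L
  ref <- U == -1L
  Unew[ref] <- ifelse(r[ref] < params$p, 0L, -1L)
  qui <- U == 0L
  Unew[qui] <- ifelse(r[qui] < q[qui], 1L, 0L)
  Unew
}

#' One synchronous stochastic update
#'
#' Each neuron is updated independently given the shared synaptic profile `J`
#' computed once from the input state: spiking -> refractory surely;
#' refractory -> quiescent with probability `p`; quiescent -> spiking with
#' probability `f(J(x_i))`. Uses one uniform draw per neuron in fixed index
#' order, so runs are bit-reproducible under a fixed seed.
#'
#' @param state a [lattice_state()].
#' @param params a [model_params()].
#' @return The updated [lattice_state()].
#' @export
stochastic_step <- function(state, params) {
  U <- matrix(unclass(state), ncol = 1)
  lattice_state(.step_ensemble(U, params)[, 1], attr(state, "L"))
}

#' One deterministic update (Heaviside, p = 1 limit)
#'
#' Applies the rule: spiking -> refractory; quiescent and `J >= h` -> spiking;
#' everything else -> quiescent.
#'
#' @inheritParams stochastic_step
#' @return The updated [lattice_state()].
#' @export
deterministic_step <- function(state, params) {
  U <- matrix(unclass(state), ncol = 1)
  lattice_state(.step_ensemble(U, params, deterministic = TRUE)[, 1],
                attr(state, "L"))
}

#' Simulate the automaton
#'
#' Evolves an initial state for `steps` synchronous updates, recording every
#' microscopic state and mesoscopic profile.
#'
#' @param state0 initial [lattice_state()].
#' @param params a [model_params()].
#' @param steps number of updates (>= 0).
#' @param deterministic if `TRUE` use [deterministic_step()] dynamics.
#' @return An object of class `nca_trajectory`: list with integer state matrix
#'   `U` (N x (steps+1)), profile matrix `J`, `params`, times and node
#'   positions.
#' @export
simulate_automaton <- function(state0, params, steps,
                               deterministic = FALSE) {
  stopifnot(steps >= 0)
  N <- length(state0)
  U <- matrix(0L, N, steps + 1)
  U[, 1] <- unclass(state0)
  wfft <- stats::fft(.kernel_weights(N, params))
  Jm <- matrix(NA_real_, N, steps + 1)
  Jm[, 1] <- .synaptic_ensemble(U[, 1, drop = FALSE], params, wfft)[, 1]
  if (steps > 0) {
    for (t in seq_len(steps)) {
      U[, t + 1] <- .step_ensemble(U[, t, drop = FALSE], params, wfft,
                                   deterministic = deterministic)[, 1]
      Jm[, t + 1] <- .synaptic_ensemble(U[, t + 1, drop = FALSE], params,
                                        wfft)[, 1]
    }
  }
  structure(list(U = U, J = Jm, params = params,
                 t = 0:steps, x = attr(state0, "x"),
                 L = attr(state0, "L")),
            class = "nca_trajectory")
}

#' @export
print.nca_trajectory <- function(x, ...) {
  cat(sprintf("<nca_trajectory> N=%d, t = 0..%d\n",
              nrow(x$U), max(x$t)))
  invisible(x)
}

#' Threshold crossings of a mesoscopic profile
#'
#' Locates the points where the piecewise-linear interpolant of `J` through
#' the ring nodes crosses the threshold `h`, classifying each crossing as
#' rising (`J` increasing, left edge of an active interval) or falling. On the
#' periodic domain the crossing count is always even.
#'
#' @param field a [meso_field()], or a numeric vector `J` (then `h`, `L` must
#'   be given).
#' @param h,L threshold and half-length when `field` is a bare vector.
#' @return A tibble with columns `x` (crossing position) and `rising`
#'   (logical); zero rows when `J` never reaches `h`.
#' @export
threshold_crossings <- function(field, h = NULL, L = NULL) {
  if (inherits(field, "meso_field")) {
    J <- field$J; h <- field$h; L <- field$L
  } else {
    J <- field
    stopifnot(!is.null(h), !is.null(L))
  }
  N <- length(J)
  x <- ring_grid(N, L)
  dx <- 2 * L / N
  active <- J >= h
  nxt <- c(2:N, 1)
  flip <- which(active != active[nxt])
  if (length(flip) == 0)
    return(tibble::tibble(x = numeric(0), rising = logical(0)))
  xi <- vapply(flip, function(i) {
    j <- nxt[i]
    dJ <- J[j] - J[i]
    frac <- if (dJ == 0) 0.5 else (h - J[i]) / dJ
    frac <- min(max(frac, 0), 1)
    x[i] + frac * dx
  }, numeric(1))
  rising <- active[nxt[flip]]
  ord <- order(xi)
  tibble::tibble(x = xi[ord], rising = rising[ord])
}

# principal active interval: the crossing pair enclosing the global maximum
# of J; returns c(NA, NA) if there are no crossings
.principal_pair <- function(J, h, L) {
  cr <- threshold_crossings(J, h, L)
  if (nrow(cr) == 0) return(c(NA_real_, NA_real_))
  N <- length(J)
  xmax <- ring_grid(N, L)[which.max(J)]
  ris <- cr$x[cr$rising]
  fal <- cr$x[!cr$rising]
  # left edge: nearest rising crossing at or before xmax (cyclically)
  dris <- (xmax - ris) %% (2 * L)
  x1 <- ris[which.min(dris)]
  dfal <- (fal - xmax) %% (2 * L)
  x2 <- fal[which.min(dfal)]
  c(x1, x2)
}

#' Per-time widths of the active sub-intervals
#'
#' Pairs rising and falling threshold crossings at each recorded time and
#' returns the widths `Delta_i(t) = xi_{2i} - xi_{2i-1}` of the active
#' sub-intervals. Times with no crossings yield a single `NA` width.
#'
#' @param traj an `nca_trajectory` from [simulate_automaton()].
#' @return A tibble with columns `t`, `interval` (index), `xi_lo`, `xi_hi`,
#'   `width`.
#' @export
width_series <- function(traj) {
  L <- traj$L
  purrr::map_dfr(seq_along(traj$t), function(k) {
    cr <- threshold_crossings(traj$J[, k], traj$params$h, L)
    if (nrow(cr) == 0)
      return(tibble::tibble(t = traj$t[k], interval = 1L,
                            xi_lo = NA_real_, xi_hi = NA_real_,
                            width = NA_real_))
    # rotate so the list starts with a rising crossing
    i0 <- which(cr$rising)[1]
    idx <- c(i0:nrow(cr), seq_len(i0 - 1))
    xs <- cr$x[idx]; rs <- cr$rising[idx]
    lo <- xs[rs]; hi <- xs[!rs]
    w <- (hi - lo) %% (2 * L)
    tibble::tibble(t = traj$t[k], interval = seq_along(w),
                   xi_lo = lo, xi_hi = hi, width = w)
  })
}

#' Empirical state distribution of an aligned ensemble
#'
#' Aligns each member of an ensemble of microscopic states on a common frame
#' (bump: shift by the active-interval centre; wave front: shift by the
#' falling crossing) and tabulates per-position frequencies of the three
#' states. Members whose profile never reaches threshold are dropped and
#' counted.
#'
#' @param states an N x M integer matrix of states (columns are members), or a
#'   list of [lattice_state()]s.
#' @param params a [model_params()].
#' @param align `"bump_center"` or `"wave_front"`.
#' @param L domain half-length (defaults to the kernel's).
#' @return A [state_pmf()] with attribute `dropped` (number of members without
#'   crossings).
#' @export
aligned_histogram <- function(states, params,
                              align = c("bump_center", "wave_front"),
                              L = params$kernel$L) {
  align <- match.arg(align)
  if (is.list(states)) states <- do.call(cbind, lapply(states, unclass))
  N <- nrow(states)
  dx <- 2 * L / N
  wfft <- stats::fft(.kernel_weights(N, params))
  Jm <- .synaptic_ensemble(states, params, wfft)
  counts <- matrix(0, 3, N)
  dropped <- 0L
  for (m in seq_len(ncol(states))) {
    pr <- .principal_pair(Jm[, m], params$h, L)
    if (anyNA(pr)) { dropped <- dropped + 1L; next }
    width <- (pr[2] - pr[1]) %% (2 * L)
    shift <- if (align == "bump_center") pr[1] + width / 2 else pr[2]
    ks <- as.integer(round(shift / dx))
    u <- states[((seq_len(N) - 1 + ks) %% N) + 1, m]
    counts[1, ] <- counts[1, ] + (u == -1L)
    counts[2, ] <- counts[2, ] + (u == 0L)
    counts[3, ] <- counts[3, ] + (u == 1L)
  }
  kept <- ncol(states) - dropped
  if (kept == 0)
    stop("all ensemble members extinct (no threshold crossings)",
         call. = FALSE)
  state_pmf(counts / kept, ring_grid(N, L), dropped = dropped)
}
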