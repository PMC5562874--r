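#' Mexican-hat synaptic kernel specification
#'
#' Defines the difference-of-Gaussians coupling kernel
#' `w(x) = c1 exp(-k1 x^2) - c2 exp(-k2 x^2)` on the ring of half-length `L`,
#' together with its periodic extension and an optional multiplicative
#' heterogeneity `1 + W0 cos(y/s)` applied in the synaptic integral.
#'
#' Three amplitude/width conventions are provided because the printed form
#' `A1 sqrt(B1/L) exp(-4 B1 x^2) - A2 sqrt(B2/L) exp(-4 B2 x^2)` evaluated at
#' the standard parameter set (A1 = 5.25, A2 = 5, B1 = 0.2, B2 = 0.3) yields
#' `w(0) < 0`, i.e. an inverted hat, which contradicts the requirement of
#' short-range excitation with a positive global maximum at the origin:
#' \describe{
#'   \item{`"swapped_B"`}{exchanges B1 and B2 (default; `w(0) > 0`, genuine
#'     Mexican hat with narrow excitation).}
#'   \item{`"literal"`}{the formula exactly as printed.}
#'   \item{`"inverse_width"`}{amplitude `A sqrt(1/(L B))`, exponent
#'     `-4 x^2 / B`; an exact joint rescaling of `"swapped_B"`, so all
#'     gain-valued observables coincide between the two.}
#' }
#'
#' @param A1,A2 excitatory / inhibitory amplitude factors (dimensionless, > 0).
#' @param B1,B2 width parameters (> 0).
#' @param L half-length of the ring domain `[-L, L)`.
#' @param n_images number of periodic images summed on each side (>= 1).
#'   The Gaussian tails make 3 images accurate to well below 1e-12 at the
#'   standard scales.
#' @param convention one of `"swapped_B"`, `"literal"`, `"inverse_width"`.
#' @param W0 heterogeneity amplitude (0 = homogeneous coupling).
#' @param s heterogeneity length scale (> 0).
#'
#' @return An object of class `kernel_spec`.
#' @export
#' @examples
#' spec <- kernel_spec()
#' base_kernel(0, spec)
#' periodic_kernel(c(-1, 0, 1), spec)
kernel_spec <- function(A1 = 5.25, A2 = 5, B1 = 0.2, B2 = 0.3, L = pi,
                        n_images = 3L,
                        convention = c("swapped_B", "literal", "inverse_width"),
                        W0 = 0, s = 0.5) {
  convention <- match.arg(convention)
  stopifnot(A1 > 0, A2 > 0, B1 > 0, B2 > 0, L > 0, s > 0, n_images >= 1)
  gp <- switch(convention,
    literal       = list(c1 = A1 * sqrt(B1 / L), k1 = 4 * B1,
                         c2 = A2 * sqrt(B2 / L), k2 = 4 * B2),
    swapped_B     = list(c1 = A1 * sqrt(B2 / L), k1 = 4 * B2,
                         c2 = A2 * sqrt(B1 / L), k2 = 4 * B1),
    inverse_width = list(c1 = A1 * sqrt(1 / (L * B1)), k1 = 4 / B1,
                         c2 = A2 * sqrt(1 / (L * B2)), k2 = 4 / B2))
  structure(
    list(A1 = A1, A2 = A2, B1 = B1, B2 = B2, L = L,
         n_images = as.integer(n_images), convention = convention,
         W0 = W0, s = s,
         c1 = gp$c1, k1 = gp$k1, c2 = gp$c2, k2 = gp$k2),
    class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf(
    "<kernel_spec> %s: A1=%g A2=%g B1=%g B2=%g L=%g n_images=%d w(0)=%.4g\n",
    x$convention, x$A1, x$A2, x$B1, x$B2, x$L, x$n_images, base_kernel(0, x)))
  if (x$W0 != 0)
    cat(sprintf("  heterogeneous: W0=%g s=%g\n", x$W0, x$s))
  invisible(x)
}

#' Base (non-periodic) synaptic kernel
#'
#' @param x positions (numeric vector).
#' @param spec a [kernel_spec()].
#' @return Numeric vector of synaptic weights `w(x)`.
#' @export
base_kernel <- function(x, spec) {
  spec$c1 * exp(-spec$k1 * x^2) - spec$c2 * exp(-spec$k2 * x^2)
}

#' Periodic extension of the synaptic kernel
#'
#' `W(x) = sum_k w(x + 2 L k)` over `k = -n_images, ..., n_images`.
#'
#' @inheritParams base_kernel
#' @return Numeric vector `W(x)`.
#' @export
periodic_kernel <- function(x, spec) {
  out <- 0
  for (k in -spec$n_images:spec$n_images)
    out <- out + base_kernel(x + 2 * spec$L * k, spec)
  out
}

#' Spatial derivative of the periodic kernel
#'
#' @inheritParams base_kernel
#' @return Numeric vector `W'(x)`.
#' @export
periodic_kernel_deriv <- function(x, spec) {
  out <- 0
  for (k in -spec$n_images:spec$n_images) {
    y <- x + 2 * spec$L * k
    out <- out - 2 * spec$k1 * y * spec$c1 * exp(-spec$k1 * y^2) +
                 2 * spec$k2 * y * spec$c2 * exp(-spec$k2 * y^2)
  }
  out
}

# definite integral of c * exp(-k y^2) over [a, b], closed form
.gauss_int <- function(cc, k, a, b) {
  cc * 0.5 * sqrt(pi / k) * (pracma::erf(sqrt(k) * b) - pracma::erf(sqrt(k) * a))
}

#' Exact interval integral of the periodic kernel
#'
#' Computes `int_a^b W(y) dy` in closed form via the Gaussian antiderivative
#' (error function), summed over the periodic images. Vectorised over `a`/`b`.
#'
#' @param a,b integration limits (the caller orients, `a <= b` for a positive
#'   orientation; the antiderivative form is valid for any order).
#' @param spec a [kernel_spec()].
#' @return Numeric vector of integrals.
#' @export
kernel_interval_integral <- function(a, b, spec) {
  out <- 0
  for (k in -spec$n_images:spec$n_images) {
    sh <- 2 * spec$L * k
    out <- out + .gauss_int(spec$c1, spec$k1, a + sh, b + sh) -
                 .gauss_int(spec$c2, spec$k2, a + sh, b + sh)
  }
  out
}

# modulation integral int_a^b W(x - y) cos(y / s) dy by adaptive quadrature
.modulation_integral <- function(x, a, b, spec) {
  if (a == b) return(0)
  stats::integrate(function(y) periodic_kernel(x - y, spec) * cos(y / spec$s),
                   a, b, rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 1000L)$value
}

#' Interval integral of the heterogeneous coupling
#'
#' Computes `int_a^b W(x - y) (1 + W0 cos(y/s)) dy`, the synaptic weight that a
#' point `x` receives from an active interval `[a, b]` under the
#' cosine-modulated coupling. With `W0 = 0` this reduces exactly to
#' `kernel_interval_integral(x - b, x - a, spec)`. The homogeneous part is
#' evaluated in closed form; the modulation term has no elementary
#' antiderivative against the Gaussian pair and is evaluated by adaptive
#' quadrature (absolute tolerance ~1e-12).
#'
#' @param x receiving position (scalar).
#' @param a,b active interval, `a <= b`.
#' @param spec a [kernel_spec()] (its `W0` and `s` fields control the
#'   heterogeneity).
#' @return Scalar integral value.
#' @export
heterogeneous_interval_integral <- function(x, a, b, spec) {
  stopifnot(a <= b)
  hom <- kernel_interval_integral(x - b, x - a, spec)
  if (spec$W0 == 0) return(hom)
  hom + spec$W0 * .modulation_integral(x, a, b, spec)
}
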