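#' Labelled partition of the ring
#'
#' Represents a continuum microscopic state as an ordered list of half-open
#' intervals `[left, right)` with labels in {-1, 0, 1}, covering `[-L, L)`
#' exactly. Canonicalisation sorts the intervals, drops empty ones and merges
#' adjacent intervals sharing a label.
#'
#' @param left,right interval endpoints (equal-length numeric vectors).
#' @param label integer labels in {-1, 0, 1}.
#' @param L domain half-length.
#' @return An object of class `circle_partition` (a data frame with columns
#'   `left`, `right`, `label` and attribute `L`).
#' @export
circle_partition <- function(left, right, label, L = pi) {
  stopifnot(length(left) == length(right), length(left) == length(label))
  d <- data.frame(left = left, right = right, label = as.integer(label))
  d <- d[d$right - d$left > 1e-14, , drop = FALSE]
  d <- d[order(d$left), , drop = FALSE]
  if (nrow(d)) {
    tot <- sum(d$right - d$left)
    if (abs(tot - 2 * L) > 1e-9)
      stop("intervals must cover the circle: total length ", tot,
           " != ", 2 * L, call. = FALSE)
    if (any(abs(d$left[-1] - d$right[-nrow(d)]) > 1e-9))
      stop("intervals must be contiguous", call. = FALSE)
    # merge same-label neighbours
    keep <- c(TRUE, d$label[-1] != d$label[-nrow(d)])
    grp <- cumsum(keep)
    d <- data.frame(left  = tapply(d$left, grp, min),
                    right = tapply(d$right, grp, max),
                    label = d$label[keep])
  }
  structure(d, L = L, class = c("circle_partition", "data.frame"))
}

#' @export
print.circle_partition <- function(x, ...) {
  cat(sprintf("<circle_partition> L=%g, %d intervals\n", attr(x, "L"),
              nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Label of a partition at given positions
#'
#' @param part a [circle_partition()].
#' @param x positions (wrapped into `[-L, L)`).
#' @return Integer vector of labels.
#' @export
partition_label_at <- function(part, x) {
  L <- attr(part, "L")
  xw <- ((x + L) %% (2 * L)) - L
  idx <- findInterval(xw, part$left)
  idx[idx < 1] <- nrow(part)  # numeric fuzz below the first left endpoint
  part$label[idx]
}

#' Sample a partition onto the lattice
#'
#' @param part a [circle_partition()].
#' @param N number of nodes.
#' @return A [lattice_state()].
#' @export
partition_to_state <- function(part, N) {
  L <- attr(part, "L")
  lattice_state(partition_label_at(part, ring_grid(N, L)), L)
}

# --- interval set algebra on [-L, L) ---------------------------------------
# sets are matrices with columns l, r (disjoint, sorted, within [-L, L))

.iv_norm <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(matrix(numeric(0), 0, 2))
  m <- m[m[, 2] - m[, 1] > 1e-13, , drop = FALSE]
  if (nrow(m) == 0) return(matrix(numeric(0), 0, 2))
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    if (m[i, 1] <= out[nrow(out), 2] + 1e-13)
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    else out <- rbind(out, m[i, ])
  }
  out
}

.iv_complement <- function(m, L) {
  m <- .iv_norm(m)
  if (nrow(m) == 0) return(matrix(c(-L, L), 1, 2))
  # gaps: (-L, l1), (r1, l2), ..., (rk, L)
  gaps <- cbind(c(-L, m[, 2]), c(m[, 1], L))
  .iv_norm(gaps)
}

.iv_intersect <- function(a, b) {
  a <- .iv_norm(a); b <- .iv_norm(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(numeric(0), 0, 2))
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    l <- max(a[i, 1], b[j, 1]); r <- min(a[i, 2], b[j, 2])
    if (r - l > 1e-13) out <- rbind(out, c(l, r))
  }
  .iv_norm(out)
}

.iv_union <- function(a, b) .iv_norm(rbind(a, b))

# pullback set of a partition as an interval matrix
.part_set <- function(part, k) {
  d <- part[part$label == k, , drop = FALSE]
  .iv_norm(cbind(d$left, d$right))
}

#' Mesoscopic profile generated by a partition
#'
#' `J(x) = kappa sum over spiking intervals of int W(x - y) dy`, evaluated in
#' closed form.
#'
#' @param x positions.
#' @param part a [circle_partition()].
#' @param params a [model_params()].
#' @return Numeric vector `J(x)`.
#' @export
partition_synaptic_input <- function(x, part, params) {
  sp <- .part_set(part, 1L)
  out <- numeric(length(x))
  if (nrow(sp)) for (i in seq_len(nrow(sp)))
    out <- out + kernel_interval_integral(x - sp[i, 2], x - sp[i, 1],
                                          params$kernel)
  params$kappa * out
}

#' One deterministic step of the continuum partition dynamics
#'
#' Computes the synaptic profile generated by the spiking set, locates its
#' threshold crossings by dense scanning plus bracketed root refinement, forms
#' the active set, and applies the pullback-set map: the new refractory set is
#' the old spiking set; the new spiking set is the quiescent part of the
#' active region; everything else becomes quiescent.
#'
#' @param part a [circle_partition()].
#' @param params a [model_params()].
#' @param n_scan number of scan points used to bracket threshold crossings.
#' @param max_crossings resolution guard: more crossings than this raises an
#'   error.
#' @return The evolved [circle_partition()].
#' @export
partition_step <- function(part, params, n_scan = 2048, max_crossings = 32) {
  L <- attr(part, "L")
  g <- function(x) partition_synaptic_input(x, part, params) - params$h
  xs <- seq(-L, L, length.out = n_scan + 1)
  gv <- g(xs)
  sc <- which(gv[-length(gv)] * gv[-1] < 0)
  if (length(sc) > max_crossings)
    stop("continuum evolution under-resolved: more than ", max_crossings,
         " threshold crossings", call. = FALSE)
  roots <- vapply(sc, function(i)
    stats::uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-12)$root, numeric(1))
  # active set X_>= = {x : g(x) >= 0}: classify the segments between roots
  pts <- c(-L, sort(roots), L)
  iv <- matrix(numeric(0), 0, 2)
  for (k in seq_len(length(pts) - 1)) {
    if (g((pts[k] + pts[k + 1]) / 2) >= 0)
      iv <- rbind(iv, c(pts[k], pts[k + 1]))
  }
  active <- .iv_norm(iv)
  X1  <- .part_set(part, 1L)
  X0  <- .part_set(part, 0L)
  new1 <- .iv_intersect(X0, active)
  newm1 <- X1
  new0 <- .iv_complement(.iv_union(new1, newm1), L)
  lab_rows <- function(m, k) if (nrow(m) == 0) NULL else cbind(m, k)
  segs <- rbind(lab_rows(newm1, -1), lab_rows(new0, 0), lab_rows(new1, 1))
  circle_partition(segs[, 1], segs[, 2], segs[, 3], L)
}

#' Regular strip microstate for the bump construction
#'
#' Splits `[eta1, eta2)` into `3m` equal strips cycling through the labels
#' -1, 0, 1 (so each label occupies exactly one third of the window), with the
#' rest of the ring quiescent; `3m + 2` intervals in total before
#' canonicalisation. Optionally permutes each triplet of strips.
#'
#' @param eta1,eta2 window edges, `eta1 < eta2`.
#' @param m number of strip triplets (>= 1).
#' @param permute `FALSE` for the regular pattern, `TRUE` to draw a random
#'   permutation per triplet, or a list of `m` permutations of `1:3`.
#' @param L domain half-length.
#' @return A [circle_partition()].
#' @export
strip_bump_state <- function(eta1, eta2, m, permute = FALSE, L = pi) {
  stopifnot(eta1 < eta2, m >= 1)
  edges <- eta1 + (0:(3 * m)) / (3 * m) * (eta2 - eta1)
  base <- c(-1L, 0L, 1L)
  labels <- integer(3 * m)
  for (j in seq_len(m)) {
    perm <- if (isFALSE(permute)) 1:3
            else if (isTRUE(permute)) sample(3)
            else permute[[j]]
    labels[(3 * j - 2):(3 * j)] <- base[perm]
  }
  lefts <- c(-L, edges[-length(edges)], eta2)
  rights <- c(eta1, edges[-1], L)
  labs <- c(0L, labels, 0L)
  keep <- rights - lefts > 1e-14
  circle_partition(lefts[keep], rights[keep], labs[keep], L)
}
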