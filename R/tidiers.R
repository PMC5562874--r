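#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trajectory into per-time macroscopic variables
#'
#' @param x an `nca_trajectory`.
#' @param ... unused.
#' @return A tibble with one row per time: `t`, `xi1`, `xi2` (edges of the
#'   principal active interval), `width`, `n_crossings`.
#' @export
tidy.nca_trajectory <- function(x, ...) {
  L <- x$L
  purrr::map_dfr(seq_along(x$t), function(k) {
    J <- x$J[, k]
    cr <- threshold_crossings(J, x$params$h, L)
    pr <- .principal_pair(J, x$params$h, L)
    w <- if (anyNA(pr)) NA_real_ else (pr[2] - pr[1]) %% (2 * L)
    tibble::tibble(t = x$t[k], xi1 = pr[1], xi2 = pr[2], width = w,
                   n_crossings = nrow(cr))
  })
}

#' @rdname tidy.nca_trajectory
#' @export
glance.nca_trajectory <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(steps = max(x$t), N = nrow(x$U),
                 mean_width = mean(td$width, na.rm = TRUE),
                 extinct = all(is.na(td$width[length(td$width)])))
}

#' Tidy a nodewise state distribution
#'
#' @param x a [state_pmf()].
#' @param ... unused.
#' @return A tibble with columns `x`, `state` (-1/0/1) and `prob`.
#' @export
tidy.state_pmf <- function(x, ...) {
  pos <- x$x
  pr <- as.vector(x$P)
  tibble::tibble(x = rep(pos, each = 3),
                 state = rep(c(-1L, 0L, 1L), length(pos)),
                 prob = pr)
}

#' Tidy a travelling-wave pmf into per-strip probabilities
#'
#' @param x a [wave_pmf()].
#' @param ... unused.
#' @return A tibble with columns `strip` (index j), `z_lo`, `z_hi` (strip
#'   extent in the wave frame), `state`, `prob`.
#' @export
tidy.wave_pmf <- function(x, ...) {
  js <- as.integer(colnames(x$rho))
  cc <- x$c; P <- x$rho
  tibble::tibble(strip = rep(js, each = 3),
                 z_lo = rep(js * cc, each = 3),
                 z_hi = rep((js + 1) * cc, each = 3),
                 state = rep(c(-1L, 0L, 1L), length(js)),
                 prob = as.vector(P))
}

#' @rdname tidy.wave_pmf
#' @export
glance.wave_pmf <- function(x, ...) {
  tibble::tibble(c = x$c, n_strips = x$n_strips, p = x$p, mode = x$mode)
}

#' One-row summary of an interface wave
#'
#' @param x an `interface_wave` from [wave_solve()].
#' @param ... unused.
#' @return A tibble with `Delta`, `c`, `xi1`, `xi2`, `max_nontranslational`,
#'   `stable`.
#' @export
glance.interface_wave <- function(x, ...) {
  mods <- Mod(x$values[-1])
  tibble::tibble(Delta = x$Delta, c = x$c, xi1 = x$xi[1], xi2 = x$xi[2],
                 max_nontranslational = max(mods), stable = x$stable)
}

#' Space-time plot of a trajectory
#'
#' @param object an `nca_trajectory`.
#' @param what `"state"` (microscopic) or `"input"` (mesoscopic profile).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.nca_trajectory <- function(object, what = c("state", "input"),
                                    ...) {
  what <- match.arg(what)
  N <- nrow(object$U)
  d <- tidyr::expand_grid(t = object$t, x = object$x)
  d <- d[order(d$t, d$x), ]
  if (what == "state") {
    d$value <- as.vector(object$U)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$t,
                                    fill = factor(.data$value))) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_manual(
        values = c("-1" = "#2166ac", "0" = "#66bd63", "1" = "#fee08b"),
        name = "state") +
      ggplot2::labs(x = "x", y = "t")
  } else {
    d$value <- as.vector(object$J)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$t,
                                    fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "J") +
      ggplot2::labs(x = "x", y = "t")
  }
}

#' Stacked-probability plot of a state distribution
#'
#' @param object a [state_pmf()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.state_pmf <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$prob,
                                  fill = factor(.data$state))) +
    ggplot2::geom_col(position = "stack", width = diff(object$x[1:2])) +
    ggplot2::scale_fill_manual(
      values = c("-1" = "#2166ac", "0" = "#66bd63", "1" = "#fee08b"),
      name = "state") +
    ggplot2::labs(x = "x", y = "probability")
}

#' Bifurcation-diagram plot of a continuation branch
#'
#' Plots the branch in the `(gamma, width)` plane, marking folds and (when
#' stability information is present) distinguishing stable from unstable
#' segments.
#'
#' @param object an `nca_branch` from [arclength_continue()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.nca_branch <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$width <- if ("x2" %in% names(d)) d$x2 - d$x1 else d$x1
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$gamma, y = .data$width))
  if ("stable" %in% names(d)) {
    p <- p + ggplot2::geom_path(ggplot2::aes(linetype = !.data$stable)) +
      ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                                `TRUE` = "dashed"),
                                     labels = c("stable", "unstable"),
                                     name = NULL)
  } else p <- p + ggplot2::geom_path()
  p + ggplot2::geom_point(data = d[d$fold, ], colour = "red", size = 2) +
    ggplot2::labs(x = "gamma", y = "width")
}

#' @importFrom rlang .data
NULL
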