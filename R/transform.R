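#' Build the variance-stabilizing transform from a fitted curve
#'
#' Constructs the canonical variance-stabilizing transformation
#' `t(x) = integral from 0 to x of 1 / sigma(u) du` by composite trapezoidal
#' integration of the reciprocal fitted SD on a uniform grid, with monotone
#' piecewise-linear interpolation between grid points. Above `x_max` the
#' transform extends linearly with slope `1 / sigma(x_max)`; below 0 (possible
#' for log Poisson p-value signals) it extends by reflection with slope
#' `1 / sigma(mu_min)`. `t(0) = 0` by construction.
#'
#' @param curve An `mv_curve` from [fit_sigma_curve()].
#' @param x_max Upper end of the integration grid; must be at least the
#'   curve's fitted mean range (defaults to exactly that). Training pipelines
#'   typically pass the maximum observed signal so the whole track is covered
#'   by the integrated region.
#' @param n_grid Number of integration grid points (>= 64, default 4096).
#' @return A `vst_model` of kind `"empirical"`.
#' @export
build_vst_transform <- function(curve, x_max = NULL, n_grid = 4096) {
  if (!inherits(curve, "mv_curve")) {
    stop_data("build_vst_transform() needs an mv_curve")
  }
  x_max <- x_max %||% curve$mu_max
  if (x_max < curve$mu_max) {
    stop_usage(sprintf("x_max (%g) must cover the curve domain (max %g)",
                       x_max, curve$mu_max))
  }
  if (n_grid < 64) {
    stop_usage("n_grid must be at least 64")
  }
  xs <- seq(0, x_max, length.out = n_grid)
  sig <- predict(curve, xs)
  if (any(!is.finite(sig)) || any(sig <= 0)) {
    abort("internal error: fitted sigma is not strictly positive on the grid")
  }
  f <- 1 / sig
  h <- xs[2] - xs[1]
  ts <- c(0, cumsum((f[-1] + f[-n_grid]) / 2 * h))
  new_vst_model(
    kind = "empirical",
    grid = list(x = xs, t = ts),
    slope_right = 1 / sig[n_grid],
    slope_left = 1 / predict(curve, curve$mu_min),
    params = list(x_max = x_max, n_grid = n_grid),
    curve_meta = list(
      b = curve$b, beta = curve$beta, spar = curve$spar,
      sigma_floor = curve$sigma_floor, zero_bin = curve$zero_bin,
      signal_type = curve$signal_type, train_chroms = curve$train_chroms
    )
  )
}

new_vst_model <- function(kind, params = list(), grid = NULL,
                          slope_right = NULL, slope_left = NULL,
                          curve_meta = NULL) {
  structure(
    list(kind = kind, params = params, grid = grid,
         slope_right = slope_right, slope_left = slope_left,
         curve_meta = curve_meta),
    class = "vst_model"
  )
}

#' Analytic transforms
#'
#' Constructors for the standard alternatives to the learned transform:
#' `log_transform()` is `log(x + offset)` (variance-stabilizing when the SD is
#' proportional to the mean), `log_affine_transform()` is `log(a*x + b)`,
#' `asinh_transform()` is the inverse hyperbolic sine (variance-stabilizing
#' when the SD is proportional to `sqrt(mu^2 + 1)`), and
#' `identity_transform()` leaves values untouched (uniform-variance
#' assumption).
#'
#' @param offset Offset `c` in `log(x + c)` (default 1).
#' @return A `vst_model`.
#' @export
log_transform <- function(offset = 1) {
  new_vst_model("log_offset", params = list(offset = offset))
}

#' @rdname log_transform
#' @param a,b Coefficients of `log(a*x + b)` (defaults 1, 1).
#' @export
log_affine_transform <- function(a = 1, b = 1) {
  new_vst_model("log_affine", params = list(a = a, b = b))
}

#' @rdname log_transform
#' @export
asinh_transform <- function() new_vst_model("asinh")

#' @rdname log_transform
#' @export
identity_transform <- function() new_vst_model("identity")

#' @export
print.vst_model <- function(x, ...) {
  p <- switch(x$kind,
    empirical = sprintf("grid of %d points on [0, %g]",
                        length(x$grid$x), x$params$x_max),
    log_offset = sprintf("log(x + %g)", x$params$offset),
    log_affine = sprintf("log(%g*x + %g)", x$params$a, x$params$b),
    asinh = "asinh(x)",
    identity = "identity"
  )
  cat(sprintf("# vst_model [%s]: %s\n", x$kind, p))
  invisible(x)
}

#' Apply a transform to numeric signal values
#'
#' @param model A `vst_model`.
#' @param x Numeric vector of signal values.
#' @return Transformed values; strictly increasing in `x`.
#' @export
transform_values <- function(model, x) {
  if (!inherits(model, "vst_model")) {
    stop_data("not a vst_model")
  }
  switch(model$kind,
    empirical = {
      g <- model$grid
      x_max <- g$x[length(g$x)]
      t_max <- g$t[length(g$t)]
      out <- approx(g$x, g$t, pmin(pmax(x, 0), x_max), rule = 2)$y
      hi <- x > x_max
      if (any(hi)) out[hi] <- t_max + (x[hi] - x_max) * model$slope_right
      lo <- x < 0
      if (any(lo)) out[lo] <- -abs(x[lo]) * model$slope_left
      out
    },
    log_offset = {
      arg <- x + model$params$offset
      check_log_domain(arg, sprintf("log(x + %g)", model$params$offset))
      log(arg)
    },
    log_affine = {
      arg <- model$params$a * x + model$params$b
      check_log_domain(arg, sprintf("log(%g*x + %g)", model$params$a, model$params$b))
      log(arg)
    },
    asinh = asinh(x),
    identity = x
  )
}

check_log_domain <- function(arg, label) {
  bad <- which(arg <= 0)
  if (length(bad)) {
    stop_data(sprintf(
      "%s undefined for %d value(s) (first offending indices: %s)",
      label, length(bad),
      paste(head(bad, 5), collapse = ", ")))
  }
}

#' Transform a signal track
#'
#' Applies a transform value-wise, leaving the interval structure untouched.
#'
#' @param track A signal-track tibble (columns `chrom`, `start`, `end`,
#'   `value`).
#' @param model A `vst_model`.
#' @param warn_extension Warn when values beyond the model's integration grid
#'   are transformed via the linear extension (default `TRUE`).
#' @return The track with transformed `value`.
#' @export
apply_transform <- function(track, model, warn_extension = TRUE) {
  validate_track(track)
  if (identical(model$kind, "empirical") && warn_extension) {
    x_max <- model$params$x_max
    n_over <- sum(track$value > x_max)
    if (n_over > 0) {
      warn(sprintf(
        "%d value(s) above the training maximum (%g); linear extension used",
        n_over, x_max))
    }
  }
  track$value <- transform_values(model, track$value)
  track
}

#' Mean-variance relationship implied by a transform
#'
#' Every monotone transform implicitly assumes a mean-variance relationship:
#' the SD it stabilizes is the reciprocal of its derivative,
#' `sigma_implied(u) = 1 / t'(u)`. For the empirical transform the derivative
#' is taken by a central difference at the integration grid spacing; analytic
#' kinds use their closed-form derivatives (`log(x + c)` implies `u + c`,
#' `asinh` implies `sqrt(u^2 + 1)`, identity implies 1).
#'
#' @param model A `vst_model`.
#' @param u Signal values.
#' @return Numeric vector of implied SDs. For the empirical kind, values of
#'   `u` outside the integration grid use the boundary derivative; their count
#'   is attached as attribute `n_out_of_domain`.
#' @export
implied_sigma <- function(model, u) {
  switch(model$kind,
    empirical = {
      g <- model$grid
      x_max <- g$x[length(g$x)]
      h <- g$x[2] - g$x[1]
      lo <- pmax(u - h / 2, 0)
      hi <- pmin(u + h / 2, x_max)
      tlo <- approx(g$x, g$t, lo, rule = 2)$y
      thi <- approx(g$x, g$t, hi, rule = 2)$y
      out <- (hi - lo) / (thi - tlo)
      oob <- u < 0 | u > x_max
      if (any(oob)) {
        out[u < 0] <- 1 / model$slope_left
        out[u > x_max] <- 1 / model$slope_right
      }
      structure(out, n_out_of_domain = sum(oob))
    },
    log_offset = u + model$params$offset,
    log_affine = (model$params$a * u + model$params$b) / model$params$a,
    asinh = sqrt(u^2 + 1),
    identity = rep(1, length(u))
  )
}

#' @describeIn build_vst_transform Tidy the transform: its lookup grid.
#' @param x A `vst_model`.
#' @param n For analytic kinds, number of grid points to tabulate on
#'   `[0, 100]`.
#' @param ... Unused.
#' @export
tidy.vst_model <- function(x, n = 256, ...) {
  if (identical(x$kind, "empirical")) {
    tibble(x = x$grid$x, t = x$grid$t)
  } else {
    xs <- seq(0, 100, length.out = n)
    tibble(x = xs, t = transform_values(x, xs))
  }
}

#' @export
autoplot.vst_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$x, y = .data$t)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "input signal", y = "transformed signal",
                  title = sprintf("Transform (%s)", object$kind))
}
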