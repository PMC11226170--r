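# Simple map and profile plots (base graphics).

#' Plot a tomogram as an image
#'
#' @param x a [tomogram()].
#' @param main title (default the feature label).
#' @param ... passed to [graphics::image()].
#' @export
plot.tomogram <- function(x, main = x$feature, ...) {
  v <- x$values
  v[is.na(v)] <- min(v, na.rm = TRUE)
  image(t(v)[, nrow(v):1], col = hcl.colors(64, "viridis"), axes = FALSE,
        main = main, asp = 1, ...)
  invisible(x)
}

#' Plot a sinogram (angle vs translation)
#'
#' @param x a [sinogram()].
#' @param main title.
#' @param ... passed to [graphics::image()].
#' @export
plot.sinogram <- function(x, main = x$feature, ...) {
  image(x$x_grid, x$angles, t(x$values), col = hcl.colors(64, "viridis"),
        xlab = "x (um)", ylab = "projection angle (deg)", main = main, ...)
  invisible(x)
}

#' Plot a 1-D scattering profile
#'
#' @param x a [profile1d()].
#' @param log_y logarithmic intensity axis.
#' @param ... passed to [graphics::plot()].
#' @export
plot.profile1d <- function(x, log_y = TRUE, ...) {
  plot(x$q_grid, x$intensity, type = "l",
       log = if (log_y && all(x$intensity > 0)) "y" else "",
       xlab = "q (1/A)", ylab = "intensity (a.u.)", ...)
  invisible(x)
}

#' Plot an azimuthal intensity profile
#'
#' @param x an [azim_profile()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.azim_profile <- function(x, ...) {
  plot(x$phi_grid, x$intensity, type = "l",
       xlab = "phi (deg)", ylab = "intensity (a.u.)", ...)
  invisible(x)
}

#' Plot an MFA distribution
#'
#' @param x an `mfa_distribution` from [nnls_regularized()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.mfa_distribution <- function(x, ...) {
  mv <- x$mfa_values %||% seq_along(x$weights)
  plot(mv, x$weights, type = "h", xlab = "MFA (deg)", ylab = "weight", ...)
  invisible(x)
}
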