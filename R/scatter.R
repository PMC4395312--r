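# Covariance-ellipse morphometry of a projected motor pool.
#
# The scatter index (SI) is pi times the product of the two eigenvalues of
# the 2-D covariance matrix of neuron coordinates: the area of an ellipse
# centered at the pool mean whose axes are the principal directions, with
# "radii" equal to the directional variances. Directional scattering is the
# per-axis sample SD.

#' Sample covariance matrix of a 2-D point cloud
#'
#' Unbiased (n - 1 denominator) sample covariance of the `x` and `y`
#' columns, about the sample mean.
#'
#' @param points Data frame with numeric columns `x`, `y` and at least 3
#'   rows.
#' @return A symmetric 2x2 matrix with dimnames `c("x", "y")`.
#' @examples
#' pool_covariance(data.frame(x = c(1, -1, 0, 0), y = c(0, 0, 1, -1)))
#' @export
pool_covariance <- function(points) {
  check_xy(points)
  if (nrow(points) < 3) {
    stop_insufficient(sprintf("covariance needs >= 3 points, got %d.", nrow(points)))
  }
  m <- cov(cbind(x = points$x, y = points$y))
  (m + t(m)) / 2
}

#' Scatter index of a motor pool
#'
#' Computes the covariance matrix of the pooled neuron coordinates, its
#' eigendecomposition, and the scatter index
#' `SI = pi * lambda1 * lambda2` (the covariance-ellipse area), together
#' with the directional standard deviations `sd_ml = sd(x)` and
#' `sd_dv = sd(y)` and the ellipse parameters (center, orientation, and
#' semi-axes `sqrt(lambda)` -- the SDs along the principal directions).
#'
#' For an axis-aligned pool (`cov_xy = 0`) the SI equals
#' `pi * sd_ml^2 * sd_dv^2`; a correlated pool always has a smaller SI than
#' its directional SDs alone would suggest.
#'
#' @param points Data frame with numeric columns `x`, `y` and at least 3
#'   rows (e.g. from [project_pool()] or [sim_pool()]).
#' @return An object of class `scatter_result`: a list with `n`, `center`,
#'   `cov`, `lambda` (eigenvalues, decreasing), `si`, `sd_ml`, `sd_dv`,
#'   `semi_axes` (`sqrt(lambda)`), `angle` (orientation of the major axis,
#'   radians from +X). Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' res <- scatter_index(sim_pool(500, sigma_ml = 0.11, sigma_dv = 0.13, seed = 1))
#' glance(res)
#' @export
scatter_index <- function(points) {
  S <- pool_covariance(points)
  e <- eigen(S, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  v1 <- e$vectors[, 1]
  structure(
    list(
      n = nrow(points),
      center = c(x = mean(points$x), y = mean(points$y)),
      cov = S,
      lambda = lambda,
      si = pi * lambda[1] * lambda[2],
      sd_ml = sqrt(S[1, 1]),
      sd_dv = sqrt(S[2, 2]),
      semi_axes = sqrt(lambda),
      angle = atan2(v1[2], v1[1])
    ),
    class = "scatter_result"
  )
}

#' Directional scattering of a pool
#'
#' Sample standard deviations of the medio-lateral (`x`) and dorso-ventral
#' (`y`) coordinates, each with the n - 1 denominator.
#'
#' @param points Data frame with columns `x`, `y` and at least 2 rows.
#' @return A one-row tibble with columns `sd_ml`, `sd_dv`.
#' @export
directional_scatter <- function(points) {
  check_xy(points)
  if (nrow(points) < 2) {
    stop_insufficient(sprintf("directional scatter needs >= 2 points, got %d.",
                              nrow(points)))
  }
  tibble::tibble(sd_ml = sd(points$x), sd_dv = sd(points$y))
}

#' @export
print.scatter_result <- function(x, ...) {
  cat("<scatter_result>", x$n, "neurons\n")
  cat(sprintf("  SI = %.6g  (sd_ml = %.4g, sd_dv = %.4g)\n",
              x$si, x$sd_ml, x$sd_dv))
  cat(sprintf("  eigenvalues = (%.6g, %.6g), major-axis angle = %.3g rad\n",
              x$lambda[1], x$lambda[2], x$angle))
  invisible(x)
}

#' @rdname scatter_index
#' @param x A `scatter_result`.
#' @param ... Unused.
#' @export
tidy.scatter_result <- function(x, ...) {
  tibble::tibble(
    component = c("major", "minor"),
    eigenvalue = x$lambda,
    semi_axis = x$semi_axes,
    angle = c(x$angle, x$angle + pi / 2)
  )
}

#' @rdname scatter_index
#' @export
glance.scatter_result <- function(x, ...) {
  tibble::tibble(
    n_neurons = x$n,
    sd_ml = x$sd_ml, sd_dv = x$sd_dv,
    cov_xy = x$cov[1, 2],
    lambda_1 = x$lambda[1], lambda_2 = x$lambda[2],
    si = x$si
  )
}
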