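# Serial-section geometry: rigid fiducial alignment, lateral-edge reference
# curve, intercept-based diameter normalization, anterior-posterior
# projection.

split_sections <- function(series) {
  stopifnot(is.data.frame(series))
  need <- c("section_index", "record_type", "x", "y")
  miss <- setdiff(need, names(series))
  if (length(miss)) {
    stop_format(paste0("trace table is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  split(series, series$section_index)
}

# least-squares rigid transform (rotation + translation, no scaling)
# mapping point rows of `p` onto `q`; 2-D Kabsch via SVD
fit_rigid <- function(p, q) {
  stopifnot(nrow(p) == nrow(q), ncol(p) == 2, ncol(q) == 2)
  pc <- colMeans(p); qc <- colMeans(q)
  pp <- sweep(p, 2, pc); qq <- sweep(q, 2, qc)
  H <- t(pp) %*% qq
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, d)) %*% t(s$u)
  t_vec <- qc - as.vector(R %*% pc)
  fitted <- sweep(p %*% t(R), 2, -t_vec)
  list(R = R, t = t_vec,
       theta = atan2(R[2, 1], R[1, 1]),
       residual_rms = sqrt(mean(rowSums((fitted - q)^2))))
}

apply_rigid_section <- function(sec, R, t_vec) {
  is_axis <- sec$record_type == "axis"
  xy <- cbind(sec$x, sec$y) %*% t(R)
  xy[!is_axis, 1] <- xy[!is_axis, 1] + t_vec[1]
  xy[!is_axis, 2] <- xy[!is_axis, 2] + t_vec[2]
  sec$x <- xy[, 1]
  sec$y <- xy[, 2]
  sec
}

section_refs <- function(sec, section_index) {
  refs <- sec[sec$record_type == "optical_ref", , drop = FALSE]
  if (nrow(refs) != 4) {
    stop_geometry(sprintf("section %s has %d optical reference points (4 required).",
                          section_index, nrow(refs)))
  }
  refs <- refs[order(refs$order_index), ]
  m <- cbind(refs$x, refs$y)
  sv <- svd(scale(m, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    stop_geometry(sprintf("optical reference points of section %s are degenerate (collinear or coincident).",
                          section_index))
  }
  m
}

#' Rigidly align a serial-section series on its optical reference points
#'
#' Each section is mapped by the least-squares rigid transform (rotation and
#' translation, no scaling) that best matches its four optical reference
#' points to those of the template (first) section. The transform is applied
#' to neurons and all landmarks; the mid-sagittal axis vector is rotated
#' only. With `canonical = TRUE` (default) the whole aligned series is then
#' brought into anatomical coordinates by one global rigid motion placing
#' the mean central canal at the origin and the mean mid-sagittal axis along
#' +Y (dorsal); a global rigid motion leaves the scatter index unchanged.
#'
#' @param series A trace tibble (see [sim_series()] or [read_series()]).
#' @param canonical Recenter/reorient the aligned series anatomically.
#' @return The aligned trace tibble, with an `alignment` attribute: a tibble
#'   of per-section rotation, translation, and RMS fiducial residual
#'   (retrievable with [alignment_report()]).
#' @examples
#' series <- sim_series(seed = 1, n_sections = 8, neurons_per_pool = 15)
#' aligned <- align_series(series)
#' alignment_report(aligned)
#' @export
align_series <- function(series, canonical = TRUE) {
  secs <- split_sections(series)
  template <- section_refs(secs[[1]], names(secs)[1])
  report <- vector("list", length(secs))
  aligned <- vector("list", length(secs))
  for (i in seq_along(secs)) {
    refs <- section_refs(secs[[i]], names(secs)[i])
    fit <- fit_rigid(refs, template)
    aligned[[i]] <- apply_rigid_section(secs[[i]], fit$R, fit$t)
    report[[i]] <- tibble::tibble(
      section_index = secs[[i]]$section_index[1],
      theta = fit$theta, tx = fit$t[1], ty = fit$t[2],
      residual_rms = fit$residual_rms
    )
  }
  out <- dplyr::bind_rows(aligned)

  if (canonical) {
    canal <- out[out$record_type == "central_canal", c("x", "y")]
    ax <- out[out$record_type == "axis", c("x", "y")]
    a <- colMeans(as.matrix(ax))
    a <- a / sqrt(sum(a^2))
    theta <- atan2(a[1], a[2])   # rotate mean axis onto (0, 1)
    R <- rotation2(theta)
    c0 <- as.vector(R %*% colMeans(as.matrix(canal)))
    is_axis <- out$record_type == "axis"
    xy <- cbind(out$x, out$y) %*% t(R)
    xy[!is_axis, 1] <- xy[!is_axis, 1] - c0[1]
    xy[!is_axis, 2] <- xy[!is_axis, 2] - c0[2]
    out$x <- xy[, 1]
    out$y <- xy[, 2]
  }
  attr(out, "alignment") <- dplyr::bind_rows(report)
  out
}

#' Per-section alignment and normalization reports
#'
#' Accessors for the diagnostic tables attached by [align_series()] and
#' [normalize_series()].
#'
#' @param series A trace tibble returned by [align_series()] or
#'   [normalize_series()].
#' @return A tibble of per-section diagnostics, or `NULL` if absent.
#' @export
alignment_report <- function(series) attr(series, "alignment")

#' @rdname alignment_report
#' @export
normalization_report <- function(series) attr(series, "normalization")

#' Fit the lateral-edge reference curve of one section
#'
#' Interpolating cubic spline through the five lateral-edge landmark points,
#' parameterized by cumulative chord length. The curve passes through all
#' five points exactly and is evaluable at any parameter value within its
#' range.
#'
#' @param points Data frame with columns `x`, `y`: the five lateral-edge
#'   points ordered along the edge (dorsal to ventral or the reverse).
#' @return An object of class `reference_curve` with fields `fx`, `fy`
#'   (spline functions of arc parameter), `knots`, and `range`.
#' @examples
#' edge <- data.frame(x = cos(seq(70, -70, length.out = 5) * pi / 180),
#'                    y = sin(seq(70, -70, length.out = 5) * pi / 180))
#' curve <- fit_reference_curve(edge)
#' curve_points(curve, seq(0, max(curve$range), length.out = 9))
#' @export
fit_reference_curve <- function(points) {
  check_xy(points, "points")
  if (nrow(points) != 5) {
    stop_geometry(sprintf("reference curve needs exactly 5 lateral-edge points, got %d.",
                          nrow(points)))
  }
  d <- sqrt(diff(points$x)^2 + diff(points$y)^2)
  if (any(d < 1e-12)) stop_geometry("duplicate lateral-edge points.")
  t_knots <- c(0, cumsum(d))
  structure(
    list(fx = splinefun(t_knots, points$x, method = "fmm"),
         fy = splinefun(t_knots, points$y, method = "fmm"),
         knots = t_knots,
         range = range(t_knots),
         points = tibble::tibble(x = points$x, y = points$y)),
    class = "reference_curve"
  )
}

#' @rdname fit_reference_curve
#' @param curve A `reference_curve`.
#' @param t Arc parameter value(s).
#' @export
curve_points <- function(curve, t) {
  stopifnot(inherits(curve, "reference_curve"))
  tibble::tibble(t = t, x = curve$fx(t), y = curve$fy(t))
}

#' @export
print.reference_curve <- function(x, ...) {
  cat("<reference_curve> through 5 points, arc length",
      format(x$range[2], digits = 4), "\n")
  invisible(x)
}

#' Intercept of the reference curve with the canal perpendicular
#'
#' Finds the intersection of a section's lateral-edge reference curve with
#' the line through the central canal perpendicular to the mid-sagittal
#' axis. If the line crosses the curve more than once, the intersection on
#' the lateral (positive-X) side nearest the canal is returned. The root is
#' located to a tolerance of 1e-10 in the curve parameter.
#'
#' @param curve A `reference_curve` from [fit_reference_curve()].
#' @param central_canal Length-2 numeric, the canal position.
#' @param axis Length-2 numeric, the mid-sagittal axis direction (need not
#'   be normalized).
#' @return A one-row tibble with columns `t`, `x`, `y`, `distance` (distance
#'   from the canal).
#' @export
intercept_point <- function(curve, central_canal, axis) {
  stopifnot(inherits(curve, "reference_curve"))
  a <- axis / sqrt(sum(axis^2))
  lateral <- c(a[2], -a[1])        # +X side when axis points dorsally
  g <- function(t) {
    (curve$fx(t) - central_canal[1]) * a[1] +
      (curve$fy(t) - central_canal[2]) * a[2]
  }
  grid <- seq(curve$range[1], curve$range[2], length.out = 512)
  gv <- g(grid)
  roots <- grid[abs(gv) < 1e-14]
  flips <- which(gv[-1] * gv[-length(gv)] < 0)
  for (k in flips) {
    roots <- c(roots, uniroot(g, c(grid[k], grid[k + 1]), tol = 1e-10)$root)
  }
  if (!length(roots)) {
    stop_geometry("the canal perpendicular does not intersect the reference curve.")
  }
  pts <- tibble::tibble(
    t = roots,
    x = curve$fx(roots), y = curve$fy(roots)
  )
  pts$u <- (pts$x - central_canal[1]) * lateral[1] +
    (pts$y - central_canal[2]) * lateral[2]
  pts$distance <- sqrt((pts$x - central_canal[1])^2 + (pts$y - central_canal[2])^2)
  lat <- pts[pts$u > 0, , drop = FALSE]
  if (!nrow(lat)) {
    stop_geometry("no intersection on the lateral side of the canal.")
  }
  lat <- lat[order(lat$distance), ][1, c("t", "x", "y", "distance")]
  tibble::as_tibble(lat)
}

section_intercept_distance <- function(sec, section_index) {
  edge <- sec[sec$record_type == "lateral_edge", , drop = FALSE]
  if (nrow(edge) != 5) {
    stop_geometry(sprintf("section %s has %d lateral-edge points (5 required).",
                          section_index, nrow(edge)))
  }
  edge <- edge[order(edge$order_index), c("x", "y")]
  canal <- sec[sec$record_type == "central_canal", c("x", "y")]
  ax <- sec[sec$record_type == "axis", c("x", "y")]
  if (nrow(canal) != 1 || nrow(ax) != 1) {
    stop_geometry(sprintf("section %s must have exactly one central canal and one axis record.",
                          section_index))
  }
  curve <- fit_reference_curve(edge)
  ip <- intercept_point(curve, c(canal$x, canal$y), c(ax$x, ax$y))
  ip$distance
}

#' Normalize section diameters to constant hemicord units
#'
#' Corrects the physiological diameter increase at the cervical enlargement.
#' For each section the distance from the central canal to the lateral-edge
#' intercept (see [intercept_point()]) is measured; the per-section
#' distances are denoised with a cross-validated smoothing spline over
#' section index; and each section is rescaled isotropically about its
#' central canal so that the smoothed intercept distance becomes
#' `reference_diameter` everywhere. The default `reference_diameter = 1`
#' expresses all coordinates in normalized hemicord units (canal-to-edge
#' distance one); `reference_diameter = "mean"` instead preserves the series
#' mean diameter.
#'
#' Sections whose intercept cannot be computed are dropped with a warning
#' rather than failing the series. With fewer than 4 valid sections the
#' smoothing step falls back to the raw distances (with a warning).
#'
#' @param series An aligned trace tibble (see [align_series()]).
#' @param reference_diameter Target intercept distance: a positive number,
#'   or `"mean"` for the series mean of the smoothed distances.
#' @param smooth Use the smoothing spline (`TRUE`, default); `FALSE` uses
#'   raw per-section distances.
#' @return The normalized trace tibble, with a `normalization` attribute
#'   (per-section raw and smoothed distances and scale factors;
#'   see [normalization_report()]).
#' @export
normalize_series <- function(series, reference_diameter = 1, smooth = TRUE) {
  secs <- split_sections(series)
  idx <- as.numeric(names(secs))
  d_raw <- rep(NA_real_, length(secs))
  for (i in seq_along(secs)) {
    d_raw[i] <- tryCatch(
      section_intercept_distance(secs[[i]], names(secs)[i]),
      motorpool_error_geometry = function(e) {
        warn(sprintf("section %s dropped: %s", names(secs)[i], conditionMessage(e)))
        NA_real_
      }
    )
  }
  ok <- !is.na(d_raw) & d_raw > 0
  if (any(!is.na(d_raw) & d_raw <= 0)) {
    stop_geometry("non-positive intercept distance encountered.")
  }
  if (sum(ok) < 2) stop_geometry("fewer than 2 sections with a valid intercept.")

  d_hat <- d_raw
  if (smooth && sum(ok) >= 4) {
    fit <- tryCatch(smooth.spline(idx[ok], d_raw[ok]), error = function(e) NULL)
    if (!is.null(fit)) d_hat[ok] <- predict(fit, idx[ok])$y
  } else if (smooth) {
    warn("fewer than 4 valid sections; using raw intercept distances.")
  }
  if (any(d_hat[ok] <= 0)) stop_geometry("smoothed intercept distance is non-positive.")

  D <- if (identical(reference_diameter, "mean")) {
    mean(d_hat[ok])
  } else {
    stopifnot(is.numeric(reference_diameter), reference_diameter > 0)
    reference_diameter
  }

  out <- vector("list", sum(ok))
  j <- 0L
  for (i in seq_along(secs)) {
    if (!ok[i]) next
    j <- j + 1L
    sec <- secs[[i]]
    sc <- D / d_hat[i]
    canal <- sec[sec$record_type == "central_canal", c("x", "y")]
    pts <- sec$record_type != "axis"
    sec$x[pts] <- canal$x + sc * (sec$x[pts] - canal$x)
    sec$y[pts] <- canal$y + sc * (sec$y[pts] - canal$y)
    out[[j]] <- sec
  }
  res <- dplyr::bind_rows(out)
  attr(res, "alignment") <- attr(series, "alignment")
  attr(res, "normalization") <- tibble::tibble(
    section_index = idx, d_raw = d_raw, d_smooth = d_hat,
    scale = ifelse(ok, D / d_hat, NA_real_), kept = ok
  )
  res
}

#' Project a motor pool along the anterior-posterior axis
#'
#' Pools the in-plane coordinates of all neurons carrying the given pool
#' label across sections, discarding the section (z) dimension -- the planar
#' point cloud on which the scatter index is computed.
#'
#' @param series An aligned, normalized trace tibble.
#' @param pool Pool label, `"ventral"` (medial pool) or `"dorsal"`.
#' @return A tibble of pooled neuron coordinates (`x`, `y`, plus
#'   `section_index` and, when present, `neuron_id`), with attributes
#'   `pool_label` and `n_neurons`. Empty pools give a zero-row tibble.
#' @export
project_pool <- function(series, pool = c("ventral", "dorsal")) {
  pool <- match.arg(pool)
  stopifnot(is.data.frame(series))
  rows <- series[series$record_type == "neuron" &
                   !is.na(series$pool_label) & series$pool_label == pool, ,
                 drop = FALSE]
  keep <- intersect(c("x", "y", "section_index", "neuron_id"), names(rows))
  out <- tibble::as_tibble(rows[, keep])
  attr(out, "pool_label") <- pool
  attr(out, "n_neurons") <- nrow(out)
  out
}

#' Run the full geometry pipeline and summarize pool scatter
#'
#' Convenience wrapper chaining [align_series()], [normalize_series()],
#' [project_pool()] and [scatter_index()] for each pool present in the
#' series.
#'
#' @param series A trace tibble.
#' @param align,normalize Toggle the respective stages.
#' @param reference_diameter Passed to [normalize_series()].
#' @return A tibble with one row per pool: metadata, `n_neurons`, `sd_ml`,
#'   `sd_dv`, `si`.
#' @examples
#' series <- sim_series(seed = 7, n_sections = 12, neurons_per_pool = 25)
#' series_scatter(series)
#' @export
series_scatter <- function(series, align = TRUE, normalize = TRUE,
                           reference_diameter = 1) {
  s <- series
  if (align) s <- align_series(s)
  if (normalize) s <- normalize_series(s, reference_diameter = reference_diameter)
  pools <- unique(stats::na.omit(s$pool_label))
  meta_cols <- intersect(c("animal_id", "genotype", "housing", "age_weeks"),
                         names(s))
  meta <- tibble::as_tibble(s[1, meta_cols])
  purrr::map_dfr(pools, function(p) {
    pts <- project_pool(s, p)
    res <- scatter_index(pts)
    dplyr::bind_cols(meta,
                     tibble::tibble(pool = p, n_neurons = res$n,
                                    sd_ml = res$sd_ml, sd_dv = res$sd_dv,
                                    si = res$si))
  })
}
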