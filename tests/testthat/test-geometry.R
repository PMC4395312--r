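# Rigid alignment, reference curve, intercepts, diameter normalization,
# anterior-posterior projection.

test_that("aligning an already-aligned series is the identity", {
  s <- clean_series(seed = 1)
  a <- align_series(s, canonical = FALSE)
  rep <- alignment_report(a)
  expect_lt(max(rep$residual_rms), 1e-12)
  expect_lt(max(abs(rep$theta)), 1e-12)
  expect_equal(a$x, s$x, tolerance = 1e-12)
  expect_equal(a$y, s$y, tolerance = 1e-12)
})

test_that("a known rigid distortion of one section is inverted exactly", {
  s <- clean_series(seed = 2)
  distorted <- s
  pick <- distorted$section_index == 3
  sec <- distorted[pick, ]
  sec_t <- apply_global_rigid(sec, theta = 30 * pi / 180, shift = c(0.2, -0.1))
  distorted[pick, ] <- sec_t
  a <- align_series(distorted, canonical = FALSE)
  expect_lt(max(abs(a$x - s$x)), 1e-9)
  expect_lt(max(abs(a$y - s$y)), 1e-9)
  expect_lt(max(alignment_report(a)$residual_rms), 1e-9)
})

test_that("noisy optical references leave residuals at the noise scale", {
  set.seed(99)
  noise_sd <- 0.01
  s <- clean_series(seed = 3, n_sections = 12, neurons_per_pool = 30)
  noisy <- s
  is_ref <- noisy$record_type == "optical_ref"
  noisy$x[is_ref] <- noisy$x[is_ref] + rnorm(sum(is_ref), 0, noise_sd)
  noisy$y[is_ref] <- noisy$y[is_ref] + rnorm(sum(is_ref), 0, noise_sd)
  a <- align_series(noisy, canonical = FALSE)
  rms <- alignment_report(a)$residual_rms
  expect_lt(median(rms[-1]), 3 * noise_sd)
  expect_gt(median(rms[-1]), noise_sd / 10)
  neurons_in <- s[s$record_type == "neuron", ]
  neurons_out <- a[a$record_type == "neuron", ]
  displacement <- sqrt((neurons_out$x - neurons_in$x)^2 +
                         (neurons_out$y - neurons_in$y)^2)
  expect_lt(max(displacement), 3 * noise_sd * 4) # template noise adds a shared offset
})

test_that("degenerate optical references raise a geometry error naming the section", {
  s <- clean_series(seed = 4)
  bad <- s
  is_ref <- bad$record_type == "optical_ref" & bad$section_index == 2
  bad$x[is_ref] <- 1:4          # collinear
  bad$y[is_ref] <- 2 * (1:4)
  expect_error(align_series(bad), class = "motorpool_error_geometry",
               regexp = "section 2")
})

test_that("the reference curve interpolates its points and handles symmetry", {
  # collinear points: the spline is the line
  line_pts <- data.frame(x = seq(0, 1, length.out = 5), y = seq(0, 2, length.out = 5))
  cv <- fit_reference_curve(line_pts)
  q <- curve_points(cv, seq(cv$range[1], cv$range[2], length.out = 33))
  expect_lt(max(abs(q$y - 2 * q$x)), 1e-12)

  # points on the unit circle: interior error below 2e-3
  th <- seq(70, -70, length.out = 5) * pi / 180
  circ <- data.frame(x = cos(th), y = sin(th))
  cvc <- fit_reference_curve(circ)
  tt <- seq(cvc$knots[2], cvc$knots[4], length.out = 101)
  qc <- curve_points(cvc, tt)
  expect_lt(max(abs(sqrt(qc$x^2 + qc$y^2) - 1)), 2e-3)

  # reversed input: same point set traced backwards
  cvr <- fit_reference_curve(circ[5:1, ])
  fwd <- curve_points(cvc, cvc$knots)
  bwd <- curve_points(cvr, cvr$knots)
  expect_equal(bwd$x, rev(fwd$x), tolerance = 1e-12)
  expect_equal(bwd$y, rev(fwd$y), tolerance = 1e-12)

  expect_error(fit_reference_curve(data.frame(x = c(1, 1, 2, 3, 4),
                                              y = c(1, 1, 2, 3, 4))),
               class = "motorpool_error_geometry")
})

test_that("intercept_point solves analytic circle and line cases", {
  th <- seq(70, -70, length.out = 5) * pi / 180
  circ <- data.frame(x = cos(th), y = sin(th))
  cv <- fit_reference_curve(circ)

  ip <- intercept_point(cv, c(0, 0), c(0, 1))
  expect_equal(c(ip$x, ip$y), c(1, 0), tolerance = 1e-9)
  expect_equal(ip$distance, 1, tolerance = 1e-9)

  # canal displaced along the axis: analytic chord intersection
  ip2 <- intercept_point(cv, c(0, 0.5), c(0, 1))
  expect_equal(c(ip2$x, ip2$y), c(sqrt(0.75), 0.5), tolerance = 2e-3)

  # vertical-line curve with a vertical axis
  vert <- data.frame(x = rep(0.8, 5), y = seq(-1, 1, length.out = 5))
  cvv <- fit_reference_curve(vert)
  ip3 <- intercept_point(cvv, c(0, 0), c(0, 1))
  expect_equal(c(ip3$x, ip3$y), c(0.8, 0), tolerance = 1e-9)

  # no lateral intersection
  far <- data.frame(x = seq(-3, -2, length.out = 5), y = seq(-1, 1, length.out = 5))
  expect_error(intercept_point(fit_reference_curve(far), c(0, 0), c(0, 1)),
               class = "motorpool_error_geometry")
})

test_that("normalization is the identity when all intercept distances agree", {
  s <- clean_series(seed = 5)
  a <- align_series(s, canonical = FALSE)
  n <- normalize_series(a)
  rep <- normalization_report(n)
  expect_equal(rep$d_raw, rep(1, nrow(rep)), tolerance = 1e-9)
  expect_equal(rep$scale, rep(1, nrow(rep)), tolerance = 1e-6)
  expect_equal(n$x, a$x, tolerance = 1e-6)
})

test_that("enlargement-only distortion is corrected to ground truth", {
  s <- sim_series(seed = 6, enlargement_amplitude = 0.3,
                  rigid_jitter_translation = 0, rigid_jitter_rotation = 0,
                  landmark_noise = 0)
  n <- normalize_series(align_series(s))
  for (pool in c("ventral", "dorsal")) {
    got <- project_pool(n, pool)
    truth <- series_truth(s, pool)
    ds_got <- directional_scatter(got)
    ds_true <- directional_scatter(
      data.frame(x = truth$x_true, y = truth$y_true))
    expect_rel_equal(ds_got$sd_ml, ds_true$sd_ml, 0.01)
    expect_rel_equal(ds_got$sd_dv, ds_true$sd_dv, 0.01)
  }
})

test_that("align + normalize is idempotent", {
  s <- sim_series(seed = 7, enlargement_amplitude = 0.25)
  once <- normalize_series(align_series(s))
  twice <- normalize_series(align_series(once))
  expect_equal(twice$record_type, once$record_type)  # same rows, same order
  expect_lt(max(abs(once$x - twice$x)), 1e-4)
  expect_lt(max(abs(once$y - twice$y)), 1e-4)
})

test_that("spline smoothing damps a single noisy intercept outlier", {
  s <- sim_series(seed = 8, n_sections = 20, enlargement_amplitude = 0,
                  rigid_jitter_translation = 0, rigid_jitter_rotation = 0,
                  landmark_noise = 0)
  out <- s
  pick <- out$record_type == "lateral_edge" & out$section_index == 10
  out$x[pick] <- out$x[pick] * 1.3   # one section's edge scaled up
  out$y[pick] <- out$y[pick] * 1.3
  n <- normalize_series(align_series(out, canonical = FALSE))
  rep <- normalization_report(n)
  r10 <- rep[rep$section_index == 10, ]
  expect_equal(r10$d_raw, 1.3, tolerance = 1e-6)
  expect_lt(abs(r10$d_smooth - 1), abs(r10$d_raw - 1))
})

test_that("projection pools, partitions and conserves neurons", {
  s <- clean_series(seed = 9, n_sections = 6, neurons_per_pool = 13)
  a <- normalize_series(align_series(s))
  pv <- project_pool(a, "ventral")
  pd <- project_pool(a, "dorsal")
  expect_equal(nrow(pv) + nrow(pd), sum(a$record_type == "neuron"))
  expect_equal(attr(pv, "n_neurons"), 13)
  # zero distortion: projected points equal ground truth exactly
  truth <- series_truth(s, "ventral")
  got <- pv[order(pv$neuron_id), ]
  expect_equal(got$x, truth$x_true, tolerance = 1e-9)
  expect_equal(got$y, truth$y_true, tolerance = 1e-9)
})

test_that("a global rigid motion of the whole series leaves SI unchanged", {
  s <- sim_series(seed = 10, n_sections = 10, neurons_per_pool = 25,
                  enlargement_amplitude = 0.2)
  base <- series_scatter(s)
  for (par in list(c(0.7, 0.3, -0.4), c(-1.2, 1.0, 2.0))) {
    moved <- apply_global_rigid(s, par[1], par[2:3])
    res <- series_scatter(moved)
    expect_equal(res$si, base$si, tolerance = 1e-9)
  }
})
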