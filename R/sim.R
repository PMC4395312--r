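# Synthetic serial-section and cohort generator.
#
# Coordinate convention (shared with the geometry module): X = medio-lateral
# (lateral positive), Y = dorso-ventral (dorsal positive), origin at the
# central canal, normalized hemicord units (canal -> lateral grey-matter edge
# distance = 1 in the undistorted section).

# fixed section geometry: five lateral-edge landmarks on the hemicord
# boundary arc (dorsal -> ventral), four extra-tissue optical fiducials
.edge_angles_deg <- c(70, 35, 0, -35, -70)
.optical_refs <- matrix(c(1.7, 1.7, -1.7, 1.7, -1.7, -1.7, 1.7, -1.7),
                        ncol = 2, byrow = TRUE)

base_lateral_edge <- function(radius = 1) {
  th <- .edge_angles_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th))
}

#' Draw a synthetic motor pool from a bivariate normal
#'
#' Generates `n` neuron positions with the given medio-lateral and
#' dorso-ventral standard deviations and ML-DV correlation, standing in for
#' the soma positions of a retrogradely labeled motor pool in normalized
#' hemicord units.
#'
#' @param n Number of neurons (>= 1).
#' @param center Length-2 numeric, pool center `(ml, dv)`.
#' @param sigma_ml,sigma_dv Positive directional standard deviations.
#' @param corr Correlation between ML and DV coordinates, in (-1, 1).
#' @param seed Optional integer seed; identical seeds give identical pools.
#' @return A tibble with columns `x`, `y`.
#' @examples
#' pool <- sim_pool(200, sigma_ml = 0.11, sigma_dv = 0.13, seed = 1)
#' sapply(pool, sd)
#' @export
sim_pool <- function(n, center = c(0, 0), sigma_ml, sigma_dv, corr = 0,
                     seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop_parameter("`n` must be a single integer >= 1.")
  }
  if (!is.numeric(sigma_ml) || sigma_ml <= 0 || !is.numeric(sigma_dv) || sigma_dv <= 0) {
    stop_parameter("`sigma_ml` and `sigma_dv` must be positive.")
  }
  if (!is.numeric(corr) || abs(corr) >= 1) {
    stop_parameter("`corr` must lie strictly between -1 and 1.")
  }
  with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    tibble::tibble(
      x = center[1] + sigma_ml * z1,
      y = center[2] + sigma_dv * (corr * z1 + sqrt(1 - corr^2) * z2)
    )
  })
}

#' Relative section-diameter profile along the anterior-posterior axis
#'
#' Smooth unimodal (Gaussian-shaped) multiplicative diameter profile that
#' emulates the physiological widening of cervical sections at the level of
#' the cervical enlargement, peaking at the series mid-point.
#'
#' @param section_index Integer vector of 0-based section indices.
#' @param n_sections Total number of sections in the series.
#' @param amplitude Relative diameter increase at the peak (>= 0);
#'   `0.3` means the mid-series diameter is 1.3 times the baseline.
#' @param width Width of the profile in sections (Gaussian SD).
#' @return Numeric vector of per-section scale factors (>= 1).
#' @export
enlargement_profile <- function(section_index, n_sections, amplitude = 0.2,
                                width = 5) {
  if (amplitude < 0) stop_parameter("`amplitude` must be >= 0.")
  if (width <= 0) stop_parameter("`width` must be positive.")
  mid <- (n_sections - 1) / 2
  1 + amplitude * exp(-0.5 * ((section_index - mid) / width)^2)
}

default_pools <- function() {
  # NH wildtype ventral directional SDs as printed; dorsal pool uses an
  # isotropic SD derived from its scatter index (SI = pi * sigma^4)
  tibble::tibble(
    pool_label = c("ventral", "dorsal"),
    center_ml = c(0.45, 0.65),
    center_dv = c(-0.35, -0.30),
    sigma_ml = c(0.11, (0.00089 / pi)^0.25),
    sigma_dv = c(0.13, (0.00089 / pi)^0.25),
    corr = c(0, 0)
  )
}

#' Simulate a serial-section trace series for one animal
#'
#' Generates an ordered series of coronal sections. Each motor pool is drawn
#' once as a 2-D point cloud (the ground truth, retained in `x_true`,
#' `y_true`), its neurons are distributed across sections, and each section
#' is then distorted the way real serial sections are: tissue content
#' (neurons and lateral-edge landmarks) is scaled by the enlargement profile
#' at that section, landmark positions receive measurement noise, and the
#' whole section -- including the four extra-tissue optical reference points
#' -- is perturbed by a random per-section rigid transform (mounting jitter).
#' Optical reference fiducials are not scaled by the enlargement profile
#' because they lie outside the tissue.
#'
#' @param animal_id,genotype,housing,age_weeks Metadata carried in the trace.
#' @param pools Tibble describing the pools to draw, with columns
#'   `pool_label`, `center_ml`, `center_dv`, `sigma_ml`, `sigma_dv`, `corr`;
#'   defaults to the normally housed wildtype parameters.
#' @param n_sections Number of sections (>= 5; default 30).
#' @param neurons_per_pool Neurons per pool (default 60).
#' @param enlargement_amplitude,enlargement_width Diameter profile, see
#'   [enlargement_profile()].
#' @param rigid_jitter_translation SD of the per-section rigid translation
#'   (normalized units, per axis).
#' @param rigid_jitter_rotation SD of the per-section rigid rotation (radians).
#' @param landmark_noise SD of additive measurement noise on the five
#'   lateral-edge landmarks (normalized units).
#' @param z_spacing_um Nominal section spacing in micrometers (default 40).
#' @param seed Optional integer seed.
#' @return A trace tibble with one row per record and columns `animal_id`,
#'   `genotype`, `housing`, `age_weeks`, `section_index`, `z_um`,
#'   `record_type` (`central_canal`, `axis`, `optical_ref`, `lateral_edge`,
#'   `neuron`), `x`, `y`, `pool_label`, `order_index`, `neuron_id`, and the
#'   pre-distortion ground truth `x_true`, `y_true` (neurons only).
#' @examples
#' series <- sim_series(seed = 1, n_sections = 10, neurons_per_pool = 20)
#' dplyr::count(series, record_type)
#' @export
sim_series <- function(animal_id = "sim_01", genotype = "wt", housing = "NH",
                       age_weeks = 12L, pools = default_pools(),
                       n_sections = 30, neurons_per_pool = 60,
                       enlargement_amplitude = 0.2, enlargement_width = 5,
                       rigid_jitter_translation = 0.05,
                       rigid_jitter_rotation = 0.05,
                       landmark_noise = 0.01,
                       z_spacing_um = 40, seed = NULL) {
  if (n_sections < 5) stop_parameter("`n_sections` must be >= 5.")
  if (enlargement_amplitude < 0) stop_parameter("`enlargement_amplitude` must be >= 0.")
  if (any(pools$sigma_ml <= 0) || any(pools$sigma_dv <= 0)) {
    stop_parameter("pool sigmas must be positive.")
  }
  if (any(abs(pools$corr) >= 1)) stop_parameter("pool `corr` must be in (-1, 1).")

  with_seed(seed, {
    idx <- seq_len(n_sections) - 1L
    scales <- enlargement_profile(idx, n_sections, enlargement_amplitude,
                                  enlargement_width)

    neurons <- purrr::pmap_dfr(pools, function(pool_label, center_ml, center_dv,
                                               sigma_ml, sigma_dv, corr) {
      pts <- sim_pool(neurons_per_pool, c(center_ml, center_dv),
                      sigma_ml, sigma_dv, corr)
      tibble::tibble(
        pool_label = pool_label,
        neuron_id = seq_len(neurons_per_pool),
        section_index = sample(idx, neurons_per_pool, replace = TRUE),
        x_true = pts$x, y_true = pts$y
      )
    })

    edge0 <- base_lateral_edge()
    sections <- purrr::map_dfr(idx, function(i) {
      s <- scales[i + 1L]
      theta <- rnorm(1, 0, rigid_jitter_rotation)
      shift <- rnorm(2, 0, rigid_jitter_translation)
      R <- rotation2(theta)
      rig <- function(m) sweep(m %*% t(R), 2, -shift)

      canal <- rig(matrix(c(0, 0), 1))
      ax <- matrix(c(0, 1), 1) %*% t(R)
      refs <- rig(.optical_refs)
      edge <- rig(s * edge0 +
                    matrix(rnorm(10, 0, landmark_noise), ncol = 2))

      nsec <- dplyr::filter(neurons, .data$section_index == i)
      nxy <- rig(s * cbind(nsec$x_true, nsec$y_true))

      dplyr::bind_rows(
        tibble::tibble(record_type = "central_canal", x = canal[, 1], y = canal[, 2],
                       pool_label = NA_character_, order_index = 1L,
                       neuron_id = NA_integer_, x_true = NA_real_, y_true = NA_real_),
        tibble::tibble(record_type = "axis", x = ax[, 1], y = ax[, 2],
                       pool_label = NA_character_, order_index = 1L,
                       neuron_id = NA_integer_, x_true = NA_real_, y_true = NA_real_),
        tibble::tibble(record_type = "optical_ref", x = refs[, 1], y = refs[, 2],
                       pool_label = NA_character_, order_index = 1:4,
                       neuron_id = NA_integer_, x_true = NA_real_, y_true = NA_real_),
        tibble::tibble(record_type = "lateral_edge", x = edge[, 1], y = edge[, 2],
                       pool_label = NA_character_, order_index = 1:5,
                       neuron_id = NA_integer_, x_true = NA_real_, y_true = NA_real_),
        tibble::tibble(record_type = "neuron", x = nxy[, 1], y = nxy[, 2],
                       pool_label = nsec$pool_label, order_index = NA_integer_,
                       neuron_id = nsec$neuron_id,
                       x_true = nsec$x_true, y_true = nsec$y_true)
      ) |>
        dplyr::mutate(section_index = i, z_um = i * z_spacing_um,
                      .before = "record_type")
    })

    dplyr::mutate(sections,
                  animal_id = animal_id, genotype = genotype,
                  housing = housing, age_weeks = as.integer(age_weeks),
                  .before = "section_index")
  })
}

#' Link behavioral performance to the scatter index
#'
#' Generates synthetic per-animal behavioral readouts linearly linked to the
#' scatter index, `response = intercept + slope * si + noise`, emulating the
#' reported correlation between grid-walk performance and motor-pool
#' scattering. Which variable plays predictor downstream is configurable in
#' [si_behavior_regression()]; this generator always produces the response
#' from the supplied SI values.
#'
#' @param si Numeric vector of per-animal scatter-index values.
#' @param slope,intercept Linear link coefficients.
#' @param noise_sd Residual SD (>= 0).
#' @param seed Optional integer seed.
#' @return A tibble with columns `si`, `response`.
#' @export
sim_behavior_link <- function(si, slope, intercept = 0, noise_sd = 0,
                              seed = NULL) {
  if (noise_sd < 0) stop_parameter("`noise_sd` must be >= 0.")
  with_seed(seed, {
    tibble::tibble(
      si = as.numeric(si),
      response = intercept + slope * as.numeric(si) +
        rnorm(length(si), 0, noise_sd)
    )
  })
}

sigma_from_presets <- function(row) {
  # per-pool (sigma_ml, sigma_dv) means and SEMs; where directional SDs are
  # unreported, derive them from the scatter index (SI = pi sd_ml^2 sd_dv^2)
  if (!is.na(row$sd_ml_mean) && !is.na(row$sd_dv_mean)) {
    return(list(ml = row$sd_ml_mean, ml_sem = row$sd_ml_sem,
                dv = row$sd_dv_mean, dv_sem = row$sd_dv_sem))
  }
  if (!is.na(row$sd_dv_mean)) {
    ml <- sqrt(row$si_mean / pi) / row$sd_dv_mean
    ml_sem <- ml * row$si_sem / (2 * row$si_mean)
    return(list(ml = ml, ml_sem = ml_sem,
                dv = row$sd_dv_mean, dv_sem = row$sd_dv_sem))
  }
  iso <- (row$si_mean / pi)^0.25
  iso_sem <- iso * row$si_sem / (4 * row$si_mean)
  list(ml = iso, ml_sem = iso_sem, dv = iso, dv_sem = iso_sem)
}

# draw one animal's pool parameters (per-animal sigma around the published
# group means, between-animal SD = sem * sqrt(n)); falls back to the default
# pools for groups without published scatter values
draw_pool_params <- function(housing, genotype, age_weeks = 12) {
  pre <- preset_scatter()
  pre <- pre[pre$housing == housing & pre$genotype == genotype &
               pre$age_weeks == age_weeks, ]
  if (!nrow(pre)) return(default_pools())
  purrr::map_dfr(seq_len(nrow(pre)), function(i) {
    sg <- sigma_from_presets(pre[i, ])
    tibble::tibble(
      pool_label = pre$pool[i],
      center_ml = ifelse(pre$pool[i] == "ventral", 0.45, 0.65),
      center_dv = ifelse(pre$pool[i] == "ventral", -0.35, -0.30),
      sigma_ml = max(rnorm(1, sg$ml, sg$ml_sem * sqrt(pre$n[i])), 0.02),
      sigma_dv = max(rnorm(1, sg$dv, sg$dv_sem * sqrt(pre$n[i])), 0.02),
      corr = 0
    )
  })
}

#' Simulate a full study cohort
#'
#' Generates all cohort tables at the published group parameters (see
#' [preset_behavior()], [preset_scatter()], [preset_synapse()],
#' [preset_pnn()]): ladder-rung behavior at 4, 8 and 12 weeks (per-animal
#' values are 3-trial means), per-animal motor-pool scatter measured on
#' freshly drawn pools, per-neuron synapse counts, and PNN coverage
#' categories. Each assay uses its own published group size, mirroring the
#' study's distinct sub-cohorts. A ground-truth table records the per-animal
#' directional SDs actually drawn, for recovery tests.
#'
#' Between-animal variability is `sem * sqrt(n)` from the preset tables. For
#' behavior, a shared per-animal latent factor induces correlation across
#' timepoints (needed for repeated-measures analysis) and each recorded
#' value is the mean of three simulated trials.
#'
#' @param groups Tibble with columns `housing`, `genotype` selecting the
#'   groups to simulate; defaults to all six.
#' @param age_weeks Age at which the scatter assay is simulated (4 or 12).
#' @param n_neurons Neurons per simulated pool for the scatter assay.
#' @param synapse_neurons Neurons counted per animal for the synapse assay.
#' @param pnn_neurons Neurons scored per animal for the PNN assay.
#' @param include_series If `TRUE`, also generate a full serial-section
#'   trace series per scatter-assay animal (slower); extra arguments `...`
#'   are passed to [sim_series()].
#' @param behavior_presets,scatter_presets,synapse_presets,pnn_presets
#'   Preset tables in the format of [preset_behavior()] etc.; override to
#'   simulate hypothetical group parameters (e.g. zero residual SD).
#' @param seed Optional integer seed.
#' @param ... Passed to [sim_series()] when `include_series = TRUE`.
#' @return A named list of tibbles: `behavior`, `scatter`, `truth`,
#'   `synapse`, `pnn`, and (optionally) `series`, a named list of trace
#'   tibbles.
#' @examples
#' coh <- sim_cohort(seed = 1, n_neurons = 30)
#' head(coh$scatter)
#' @export
sim_cohort <- function(groups = NULL, age_weeks = 12L, n_neurons = 60,
                       synapse_neurons = 30, pnn_neurons = 50,
                       include_series = FALSE,
                       behavior_presets = preset_behavior(),
                       scatter_presets = preset_scatter(),
                       synapse_presets = preset_synapse(),
                       pnn_presets = preset_pnn(),
                       seed = NULL, ...) {
  if (is.null(groups)) {
    groups <- tidyr::crossing(housing = c("NH", "EE_birth", "EE_4wk"),
                              genotype = c("wt", "mut"))
  }
  with_seed(seed, {
    ## behavior -----------------------------------------------------------
    beh_pre <- dplyr::inner_join(behavior_presets, groups,
                                 by = c("housing", "genotype"))
    behavior <- if (nrow(beh_pre) == 0) tibble::tibble() else beh_pre |>
      dplyr::group_by(.data$housing, .data$genotype) |>
      dplyr::group_map(function(g, key) {
        n <- g$n[1]
        u <- rnorm(n)       # shared latent animal factor
        v <- rnorm(n)
        purrr::map_dfr(seq_len(nrow(g)), function(t) {
          sd_ct <- g$crossing_time_sem[t] * sqrt(g$n[t])
          sd_sl <- g$slips_sem[t] * sqrt(g$n[t])
          ids <- seq_len(n)
          ct <- vapply(ids, function(i) {
            latent <- g$crossing_time_mean[t] + u[i] * sd_ct * sqrt(2 / 3)
            mean(latent + rnorm(3, 0, sd_ct))
          }, numeric(1))
          sl <- vapply(ids, function(i) {
            latent <- g$slips_mean[t] + v[i] * sd_sl * sqrt(2 / 3)
            mean(latent + rnorm(3, 0, sd_sl))
          }, numeric(1))
          tibble::tibble(
            animal_id = sprintf("%s_%s_beh%02d", key$housing, key$genotype, ids),
            housing = key$housing, genotype = key$genotype,
            timepoint_weeks = g$timepoint_weeks[t],
            crossing_time_s = pmax(ct, 0), slips = pmax(sl, 0)
          )
        })
      }) |>
      dplyr::bind_rows()

    ## scatter + ground truth --------------------------------------------
    sc_pre <- scatter_presets |>
      dplyr::filter(.data$age_weeks == !!age_weeks) |>
      dplyr::inner_join(groups, by = c("housing", "genotype"))
    truth <- list(); scatter <- list(); series <- list()
    for (grp in split(sc_pre, interaction(sc_pre$housing, sc_pre$genotype, drop = TRUE))) {
      n_anim <- max(grp$n)
      for (a in seq_len(n_anim)) {
        aid <- sprintf("%s_%s_sc%02d", grp$housing[1], grp$genotype[1], a)
        pool_rows <- list()
        for (p in seq_len(nrow(grp))) {
          if (a > grp$n[p]) next
          sg <- sigma_from_presets(grp[p, ])
          s_ml <- max(rnorm(1, sg$ml, sg$ml_sem * sqrt(grp$n[p])), 0.02)
          s_dv <- max(rnorm(1, sg$dv, sg$dv_sem * sqrt(grp$n[p])), 0.02)
          truth[[length(truth) + 1L]] <- tibble::tibble(
            animal_id = aid, housing = grp$housing[p], genotype = grp$genotype[p],
            age_weeks = grp$age_weeks[p], pool = grp$pool[p],
            sigma_ml = s_ml, sigma_dv = s_dv, si_true = pi * s_ml^2 * s_dv^2
          )
          pts <- sim_pool(n_neurons, c(0, 0), s_ml, s_dv, 0)
          res <- scatter_index(pts)
          scatter[[length(scatter) + 1L]] <- tibble::tibble(
            animal_id = aid, housing = grp$housing[p], genotype = grp$genotype[p],
            age_weeks = grp$age_weeks[p], pool = grp$pool[p],
            n_neurons = n_neurons, sd_ml = res$sd_ml, sd_dv = res$sd_dv,
            si = res$si
          )
          pool_rows[[length(pool_rows) + 1L]] <- tibble::tibble(
            pool_label = grp$pool[p],
            center_ml = ifelse(grp$pool[p] == "ventral", 0.45, 0.65),
            center_dv = ifelse(grp$pool[p] == "ventral", -0.35, -0.30),
            sigma_ml = s_ml, sigma_dv = s_dv, corr = 0
          )
        }
        if (include_series && length(pool_rows)) {
          series[[aid]] <- sim_series(
            animal_id = aid, genotype = grp$genotype[1], housing = grp$housing[1],
            age_weeks = grp$age_weeks[1], pools = dplyr::bind_rows(pool_rows),
            neurons_per_pool = n_neurons, ...
          )
        }
      }
    }

    ## synapse counts -----------------------------------------------------
    syn_pre <- dplyr::inner_join(synapse_presets, groups,
                                 by = c("housing", "genotype"))
    synapse <- purrr::pmap_dfr(syn_pre, function(housing, genotype, n,
                                                 excitatory_mean, excitatory_sem,
                                                 inhibitory_mean, inhibitory_sem) {
      purrr::map_dfr(seq_len(n), function(a) {
        lam_e <- max(rnorm(1, excitatory_mean, excitatory_sem * sqrt(n)), 0.05)
        lam_i <- max(rnorm(1, inhibitory_mean, inhibitory_sem * sqrt(n)), 0.05)
        tibble::tibble(
          animal_id = sprintf("%s_%s_syn%02d", housing, genotype, a),
          housing = housing, genotype = genotype,
          neuron_id = seq_len(synapse_neurons),
          excitatory_count = rpois(synapse_neurons, lam_e),
          inhibitory_count = rpois(synapse_neurons, lam_i)
        )
      })
    })

    ## PNN categories -----------------------------------------------------
    pnn_pre <- dplyr::inner_join(pnn_presets, groups,
                                 by = c("housing", "genotype"))
    pnn <- purrr::pmap_dfr(
      pnn_pre[, c("housing", "genotype", "n", "p_none", "p_weak", "p_strong")],
      function(housing, genotype, n, p_none, p_weak, p_strong) {
        purrr::map_dfr(seq_len(n), function(a) {
          cats <- sample(c("none", "weak", "strong"), pnn_neurons,
                         replace = TRUE, prob = c(p_none, p_weak, p_strong))
          tibble::tibble(
            animal_id = sprintf("%s_%s_pnn%02d", housing, genotype, a),
            housing = housing, genotype = genotype,
            neuron_id = seq_len(pnn_neurons), category = cats
          )
        })
      })

    out <- list(behavior = behavior,
                scatter = dplyr::bind_rows(scatter),
                truth = dplyr::bind_rows(truth),
                synapse = synapse, pnn = pnn)
    if (include_series) out$series <- series
    out
  })
}
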