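#' Published group parameters used by the cohort simulator
#'
#' These tables carry the per-group summary statistics of the enriched-
#' environment study of *Sema3F*-mutant motor-pool plasticity that the
#' synthetic cohort generator emulates: ladder-rung (grid walk) behavior,
#' motor-pool scatter, per-neuron synapse counts, and perineuronal-net (PNN)
#' coverage categories. Values are group means with their standard errors
#' (SEM) and group sizes `n` (animals); the generator converts SEMs to
#' between-animal standard deviations as `sem * sqrt(n)`.
#'
#' Housing conditions are `NH` (normal housing), `EE_birth` (enriched
#' environment from birth), and `EE_4wk` (enriched environment from 4 weeks
#' of age); genotypes are `wt` and `mut`.
#'
#' @return A tibble, one row per group (and per timepoint, pool, or category
#'   where applicable):
#' \describe{
#'   \item{`preset_behavior()`}{`housing`, `genotype`, `timepoint_weeks`, `n`,
#'     `crossing_time_mean`, `crossing_time_sem`, `slips_mean`, `slips_sem`.
#'     Per-animal values are means over 3 ladder-rung trials.}
#'   \item{`preset_scatter()`}{`housing`, `genotype`, `age_weeks`, `pool`
#'     (`ventral` = medial pool, LMCm; `dorsal` = lateral pool), `n`,
#'     `si_mean`, `si_sem` (scatter index, normalized hemicord units squared),
#'     `sd_ml_mean`, `sd_ml_sem`, `sd_dv_mean`, `sd_dv_sem` (directional SDs,
#'     normalized units; `NA` where the study reports only the SI).}
#'   \item{`preset_synapse()`}{`housing`, `genotype`, `n`,
#'     `excitatory_mean`, `excitatory_sem` (vGlut1 puncta per neuron),
#'     `inhibitory_mean`, `inhibitory_sem` (vGAT puncta per neuron);
#'     12-week-old animals.}
#'   \item{`preset_pnn()`}{`housing`, `genotype`, `n`, `p_none`, `p_weak`,
#'     `p_strong` (category probabilities summing to 1) plus the
#'     corresponding percentage SEMs; 4-week-old animals.}
#' }
#' @examples
#' preset_scatter()
#' preset_behavior()
#' @name presets
NULL

#' @rdname presets
#' @export
preset_behavior <- function() {
  tibble::tribble(
    ~housing,   ~genotype, ~timepoint_weeks, ~n,  ~crossing_time_mean, ~crossing_time_sem, ~slips_mean, ~slips_sem,
    "NH",       "wt",      4L,               14L, 11.74,               0.86,               1.00,        0.22,
    "NH",       "wt",      8L,               14L, 9.48,                0.75,               1.10,        0.23,
    "NH",       "wt",      12L,              13L, 9.41,                0.67,               0.82,        0.14,
    "NH",       "mut",     4L,               12L, 25.58,               2.56,               3.11,        0.66,
    "NH",       "mut",     8L,               12L, 18.92,               1.64,               2.61,        0.56,
    "NH",       "mut",     12L,              12L, 18.31,               1.89,               2.03,        0.37,
    "EE_birth", "wt",      4L,               10L, 10.37,               0.76,               1.00,        0.21,
    "EE_birth", "wt",      8L,               10L, 12.63,               0.90,               0.83,        0.16,
    "EE_birth", "wt",      12L,              10L, 11.00,               0.98,               0.47,        0.09,
    "EE_birth", "mut",     4L,               9L,  16.74,               1.71,               1.67,        0.49,
    "EE_birth", "mut",     8L,               9L,  15.85,               1.54,               1.07,        0.17,
    "EE_birth", "mut",     12L,              9L,  13.48,               1.19,               0.59,        0.15,
    "EE_4wk",   "wt",      4L,               19L, 15.19,               1.17,               1.81,        0.24,
    "EE_4wk",   "wt",      8L,               19L, 12.61,               1.01,               1.00,        0.15,
    "EE_4wk",   "wt",      12L,              19L, 11.75,               0.62,               1.00,        0.24,
    "EE_4wk",   "mut",     4L,               11L, 34.06,               2.09,               5.30,        0.59,
    "EE_4wk",   "mut",     8L,               11L, 23.91,               2.17,               2.24,        0.32,
    "EE_4wk",   "mut",     12L,              11L, 21.55,               2.22,               2.394,       0.314
  )
}

#' @rdname presets
#' @export
preset_scatter <- function() {
  tibble::tribble(
    ~housing,   ~genotype, ~age_weeks, ~pool,     ~n,  ~si_mean, ~si_sem,  ~sd_ml_mean, ~sd_ml_sem, ~sd_dv_mean, ~sd_dv_sem,
    "NH",       "wt",      12L,        "ventral", 7L,  0.00069,  0.00012,  0.11,        0.0061,     0.13,        0.0076,
    "NH",       "mut",     12L,        "ventral", 5L,  0.00124,  0.00015,  0.12,        0.0080,     0.18,        0.0114,
    "NH",       "wt",      12L,        "dorsal",  7L,  0.00089,  0.00015,  NA,          NA,         NA,          NA,
    "NH",       "mut",     12L,        "dorsal",  5L,  0.00102,  0.00027,  NA,          NA,         NA,          NA,
    "EE_birth", "wt",      12L,        "ventral", 5L,  0.00084,  0.00024,  0.1149,      0.0068,     0.1372,      0.0108,
    "EE_birth", "mut",     12L,        "ventral", 3L,  0.00065,  0.00007,  0.0979,      0.0074,     0.1506,      0.0104,
    "EE_birth", "wt",      12L,        "dorsal",  5L,  0.00102,  0.00021,  NA,          NA,         NA,          NA,
    "EE_birth", "mut",     12L,        "dorsal",  3L,  0.00113,  0.00050,  NA,          NA,         NA,          NA,
    "EE_4wk",   "wt",      12L,        "ventral", 8L,  0.00045,  0.00004,  0.1068,      0.0021,     0.1157,      0.0031,
    "EE_4wk",   "mut",     12L,        "ventral", 3L,  0.00113,  0.00041,  0.1121,      0.004982,   0.1642,      0.0375,
    "EE_4wk",   "wt",      12L,        "dorsal",  8L,  0.00065,  0.00006,  NA,          NA,         NA,          NA,
    "EE_4wk",   "mut",     12L,        "dorsal",  3L,  0.00066,  0.00015,  NA,          NA,         NA,          NA,
    "NH",       "wt",      4L,         "ventral", 5L,  0.00124,  0.00020,  NA,          NA,         0.1587,      0.0139,
    "NH",       "mut",     4L,         "ventral", 5L,  0.00371,  0.00071,  NA,          NA,         0.2486,      0.0204,
    "NH",       "wt",      4L,         "dorsal",  5L,  0.00141,  0.00030,  NA,          NA,         NA,          NA,
    "NH",       "mut",     4L,         "dorsal",  5L,  0.00132,  0.00021,  NA,          NA,         NA,          NA,
    "EE_birth", "wt",      4L,         "ventral", 5L,  0.00130,  0.00023,  NA,          NA,         0.1564,      0.0109,
    "EE_birth", "mut",     4L,         "ventral", 5L,  0.00212,  0.00049,  NA,          NA,         0.1923,      0.0154,
    "EE_birth", "wt",      4L,         "dorsal",  5L,  0.00106,  0.00023,  NA,          NA,         NA,          NA,
    "EE_birth", "mut",     4L,         "dorsal",  5L,  0.00151,  0.00032,  NA,          NA,         NA,          NA
  )
}

#' @rdname presets
#' @export
preset_synapse <- function() {
  tibble::tribble(
    ~housing,   ~genotype, ~n, ~excitatory_mean, ~excitatory_sem, ~inhibitory_mean, ~inhibitory_sem,
    "NH",       "wt",      3L, 8.32,             0.90,            133.5,            10.52,
    "NH",       "mut",     3L, 8.13,             0.67,            127.3,            28.76,
    "EE_birth", "wt",      3L, 15.99,            2.51,            122.5,            3.85,
    "EE_birth", "mut",     3L, 16.81,            3.88,            125.0,            6.63,
    "EE_4wk",   "wt",      3L, 8.70,             0.93,            119.4,            12.0,
    "EE_4wk",   "mut",     3L, 8.43,             0.24,            113.2,            2.15
  )
}

#' @rdname presets
#' @export
preset_pnn <- function() {
  out <- tibble::tribble(
    ~housing,   ~genotype, ~n, ~pct_none, ~pct_none_sem, ~pct_weak, ~pct_weak_sem, ~pct_strong, ~pct_strong_sem,
    "NH",       "wt",      3L, 63.6,      3.4,           30.7,      2.5,           5.7,         1.7,
    "NH",       "mut",     3L, 70.4,      3.0,           27.2,      2.5,           2.4,         0.6,
    "EE_birth", "wt",      3L, 66.6,      6.8,           29.0,      5.3,           4.4,         2.0,
    "EE_birth", "mut",     3L, 71.6,      9.4,           25.9,      8.6,           2.6,         0.8
  )
  tot <- out$pct_none + out$pct_weak + out$pct_strong
  dplyr::mutate(out,
    p_none = .data$pct_none / tot,
    p_weak = .data$pct_weak / tot,
    p_strong = .data$pct_strong / tot
  )
}
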