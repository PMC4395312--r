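# Cohort-level statistics mirroring the study's analysis policy:
# normality-gated two-group tests, the repeated-measures interaction test,
# scatter-vs-performance regression, and category/count comparisons.

group_summary <- function(x) {
  tibble::tibble(n = length(x), mean = mean(x),
                 sem = if (length(x) > 1) sem(x) else NA_real_)
}

#' Two-group comparison with the normality-gated test policy
#'
#' Compares two groups of per-animal values the way the study's behavioral
#' and anatomical comparisons are run: under `policy = "auto"`, each group
#' is screened with a Shapiro-Wilk normality test at `alpha_normality`; if
#' both pass, an unpaired two-tailed Student's t-test is used, otherwise a
#' two-tailed Mann-Whitney test (exact for combined N <= 20 without ties,
#' normal approximation with tie and continuity correction otherwise).
#'
#' @param data Data frame with one row per animal.
#' @param value Column of per-animal values (tidy-eval).
#' @param group Grouping column with exactly two levels (tidy-eval).
#' @param policy `"auto"` (normality-gated), `"t"`, or `"mann_whitney"`.
#' @param alpha_normality Significance level of the Shapiro-Wilk gate.
#' @return A one-row tibble: group labels, `n`, `mean`, `sem` per group,
#'   `normality_p1`/`normality_p2` (when screened), `test_used`,
#'   `statistic`, `p_value`.
#' @examples
#' d <- data.frame(g = rep(c("wt", "mut"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' compare_groups(d, y, g, policy = "mann_whitney")
#' @export
compare_groups <- function(data, value, group,
                           policy = c("auto", "t", "mann_whitney"),
                           alpha_normality = 0.05) {
  policy <- match.arg(policy)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- as.character(g[keep])
  lev <- unique(g)
  if (length(lev) != 2) stop_parameter("`group` must have exactly two levels.")
  a <- v[g == lev[1]]; b <- v[g == lev[2]]
  if (length(a) < 2 || length(b) < 2) {
    stop_insufficient("each group needs at least 2 values.")
  }

  sum_a <- group_summary(a); sum_b <- group_summary(b)
  norm_p <- c(NA_real_, NA_real_)

  if (policy == "auto") {
    if (length(a) < 3 || length(b) < 3) {
      stop_insufficient("`auto` policy needs >= 3 values per group for the normality screen.")
    }
    shap <- function(x) {
      if (diff(range(x)) < .Machine$double.eps^0.5) return(0) # constant: not normal
      shapiro.test(x)$p.value
    }
    norm_p <- c(shap(a), shap(b))
    policy <- if (all(norm_p > alpha_normality)) "t" else "mann_whitney"
  }

  if (identical(sort(a), sort(b)) && diff(range(v)) < .Machine$double.eps^0.5) {
    warn("both groups are identical and constant; returning p = 1 by convention.")
    stat <- if (policy == "t") 0 else length(a) * length(b) / 2
    res <- list(statistic = stat, p.value = 1)
  } else if (policy == "t") {
    res <- t.test(a, b, var.equal = TRUE)
  } else {
    exact <- (length(a) + length(b)) <= 20 &&
      !any(duplicated(c(a, b)))
    res <- suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = TRUE)
    )
  }

  tibble::tibble(
    group1 = lev[1], group2 = lev[2],
    n1 = sum_a$n, mean1 = sum_a$mean, sem1 = sum_a$sem,
    n2 = sum_b$n, mean2 = sum_b$mean, sem2 = sum_b$sem,
    normality_p1 = norm_p[1], normality_p2 = norm_p[2],
    test_used = if (policy == "t") "t" else "mann_whitney",
    statistic = unname(res$statistic),
    p_value = min(max(res$p.value, 0), 1)
  )
}

#' Repeated-measures interaction test for longitudinal behavior
#'
#' Two-way mixed ANOVA with one between-subjects factor (default genotype)
#' and one within-subjects factor (default timepoint), returning the
#' interaction F-test -- the study's criterion for a developmental change in
#' the genotype effect. Animals missing any timepoint are dropped
#' (complete-case) with a warning. No sphericity correction is applied.
#'
#' @param data Long-format data frame, one row per animal x timepoint.
#' @param value Response column (tidy-eval), e.g. crossing time.
#' @param between,within,subject Factor columns (tidy-eval).
#' @return A one-row tibble: `test_used`, `effect`, `df1`, `df2`,
#'   `statistic` (interaction F), `p_value`, `n_subjects`, `n_dropped`.
#' @examples
#' coh <- sim_cohort(groups = data.frame(housing = "NH", genotype = c("wt", "mut")),
#'                   seed = 2)
#' rm_anova_interaction(coh$behavior, crossing_time_s)
#' @export
rm_anova_interaction <- function(data, value, between = genotype,
                                 within = timepoint_weeks,
                                 subject = animal_id) {
  df <- tibble::tibble(
    value = rlang::eval_tidy(rlang::enquo(value), data),
    between = factor(rlang::eval_tidy(rlang::enquo(between), data)),
    within = factor(rlang::eval_tidy(rlang::enquo(within), data)),
    subject = factor(rlang::eval_tidy(rlang::enquo(subject), data))
  )
  n_levels <- nlevels(df$within)
  counts <- table(df$subject)
  complete <- names(counts)[counts == n_levels]
  dropped <- setdiff(levels(df$subject), complete)
  if (length(dropped)) {
    warn(sprintf("%d subject(s) without all %d timepoints dropped.",
                 length(dropped), n_levels))
    df <- df[df$subject %in% complete, ]
    df$subject <- droplevels(df$subject)
  }
  per_cell <- table(unique(df[, c("subject", "between")])$between)
  if (any(per_cell < 2) || length(per_cell) < 2) {
    stop_insufficient("need >= 2 subjects per between-group level.")
  }
  fit <- aov(value ~ between * within + Error(subject / within), data = df)
  strata <- summary(fit)
  tab <- NULL
  for (s in strata) {
    rows <- rownames(s[[1]])
    if (any(grepl("between:within", rows))) tab <- s[[1]]
  }
  i <- grep("between:within", rownames(tab))
  r <- grep("Residuals", rownames(tab))
  tibble::tibble(
    test_used = "rm_anova_2way",
    effect = "between:within",
    df1 = tab$Df[i], df2 = tab$Df[r],
    statistic = tab$`F value`[i],
    p_value = tab$`Pr(>F)`[i],
    n_subjects = nlevels(df$subject),
    n_dropped = length(dropped)
  )
}

#' Regression of the scatter index on behavioral performance
#'
#' Ordinary least squares linking per-animal motor-pool scattering to
#' grid-walk performance, with a two-sided t-test of slope = 0. The default
#' orientation regresses SI on crossing time (slope in SI units per second,
#' matching the reported slope's magnitude); the reverse orientation is
#' available.
#'
#' @param data Data frame with one row per animal.
#' @param si,behavior Columns holding the scatter index and the behavioral
#'   readout (tidy-eval; defaults `si`, `crossing_time_s`).
#' @param orientation `"si_on_behavior"` (default) or `"behavior_on_si"`.
#' @return A one-row tibble: `orientation`, `n`, `slope`, `slope_se`,
#'   `statistic`, `p_value`, `r_squared`.
#' @export
si_behavior_regression <- function(data, si = si, behavior = crossing_time_s,
                                   orientation = c("si_on_behavior",
                                                   "behavior_on_si")) {
  orientation <- match.arg(orientation)
  s <- rlang::eval_tidy(rlang::enquo(si), data)
  b <- rlang::eval_tidy(rlang::enquo(behavior), data)
  keep <- is.finite(s) & is.finite(b)
  s <- s[keep]; b <- b[keep]
  if (length(s) < 3) stop_insufficient("regression needs >= 3 animals.")
  xy <- if (orientation == "si_on_behavior") list(y = s, x = b) else list(y = b, x = s)
  if (sd(xy$x) < .Machine$double.eps^0.5) {
    stop_parameter("predictor has zero variance.")
  }
  fit <- lm(y ~ x, data = xy)
  cf <- summary(fit)$coefficients
  tibble::tibble(
    orientation = orientation,
    n = length(s),
    intercept = cf[1, 1],
    slope = cf[2, 1], slope_se = cf[2, 2],
    statistic = cf[2, 3], p_value = cf[2, 4],
    r_squared = summary(fit)$r.squared
  )
}

oneway_p <- function(value, group) {
  # one-way ANOVA with the constant-response convention F = 0, p = 1
  if (diff(range(value)) < .Machine$double.eps^0.5) {
    warn("response is constant across groups; returning F = 0, p = 1.")
    return(list(F = 0, p = 1,
                df1 = length(unique(group)) - 1,
                df2 = length(value) - length(unique(group))))
  }
  tab <- summary(aov(value ~ factor(group)))[[1]]
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df1 = tab$Df[1], df2 = tab$Df[2])
}

#' Compare PNN category distributions across groups
#'
#' Converts per-neuron perineuronal-net scores (`none`/`weak`/`strong`) into
#' per-animal category fractions and runs, for each category, a one-way
#' ANOVA across the genotype-by-housing groups -- the animal is the
#' statistical unit.
#'
#' @param data Data frame with columns `animal_id`, `genotype`, `housing`,
#'   `category` (one row per neuron).
#' @return A tibble with one row per category: `category`, `n_groups`,
#'   `n_animals`, `df1`, `df2`, `statistic` (F), `p_value`, plus per-group
#'   mean fractions in a list column `group_means`.
#' @examples
#' coh <- sim_cohort(seed = 3)
#' compare_pnn_categories(coh$pnn)
#' @export
compare_pnn_categories <- function(data) {
  cats <- c("none", "weak", "strong")
  bad <- setdiff(unique(data$category), cats)
  if (length(bad)) {
    stop_format(paste0("unknown PNN category: ", paste(bad, collapse = ", ")))
  }
  per_animal <- data |>
    dplyr::count(.data$animal_id, .data$genotype, .data$housing, .data$category) |>
    dplyr::group_by(.data$animal_id, .data$genotype, .data$housing) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(c("animal_id", "genotype", "housing"))),
      category = cats, fill = list(fraction = 0)
    ) |>
    dplyr::mutate(group = paste(.data$genotype, .data$housing, sep = ":"))

  purrr::map_dfr(cats, function(cc) {
    d <- dplyr::filter(per_animal, .data$category == cc)
    res <- oneway_p(d$fraction, d$group)
    means <- d |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(mean_fraction = mean(.data$fraction), .groups = "drop")
    tibble::tibble(
      category = cc,
      n_groups = length(unique(d$group)),
      n_animals = length(unique(d$animal_id)),
      df1 = res$df1, df2 = res$df2,
      statistic = res$F, p_value = res$p,
      group_means = list(means)
    )
  })
}

#' Pairwise synapse-count comparisons across housing conditions
#'
#' Averages per-neuron excitatory and inhibitory synapse counts within each
#' animal (the animal is the statistical unit) and runs pairwise unpaired
#' two-tailed Student's t-tests between housing conditions within each
#' genotype, separately for the two markers.
#'
#' @param data Data frame with columns `animal_id`, `genotype`, `housing`,
#'   `excitatory_count`, `inhibitory_count` (one row per neuron).
#' @param holm Apply a Holm correction across the comparisons (off by
#'   default, mirroring per-comparison reporting).
#' @return A tibble with one row per genotype x marker x housing pair:
#'   group sizes, means, SEMs, `statistic`, `p_value` (and `p_holm` if
#'   requested).
#' @export
compare_synapse_counts <- function(data, holm = FALSE) {
  per_animal <- data |>
    dplyr::group_by(.data$animal_id, .data$genotype, .data$housing) |>
    dplyr::summarise(excitatory = mean(.data$excitatory_count),
                     inhibitory = mean(.data$inhibitory_count),
                     .groups = "drop")
  out <- list()
  for (gt in unique(per_animal$genotype)) {
    dgt <- dplyr::filter(per_animal, .data$genotype == gt)
    housings <- unique(dgt$housing)
    if (length(housings) < 2) next
    pairs <- utils::combn(housings, 2, simplify = FALSE)
    for (marker in c("excitatory", "inhibitory")) {
      for (pr in pairs) {
        a <- dgt[[marker]][dgt$housing == pr[1]]
        b <- dgt[[marker]][dgt$housing == pr[2]]
        if (length(a) < 3 || length(b) < 3) {
          stop_insufficient("need >= 3 animals per housing group.")
        }
        if (identical(sort(a), sort(b)) &&
            diff(range(c(a, b))) < .Machine$double.eps^0.5) {
          warn("identical constant groups; returning p = 1 by convention.")
          res <- list(statistic = 0, p.value = 1)
        } else {
          res <- t.test(a, b, var.equal = TRUE)
        }
        out[[length(out) + 1L]] <- tibble::tibble(
          genotype = gt, marker = marker,
          housing1 = pr[1], housing2 = pr[2],
          n1 = length(a), mean1 = mean(a), sem1 = sem(a),
          n2 = length(b), mean2 = mean(b), sem2 = sem(b),
          test_used = "t",
          statistic = unname(res$statistic), p_value = res$p.value
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (holm) res$p_holm <- stats::p.adjust(res$p_value, method = "holm")
  res
}
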