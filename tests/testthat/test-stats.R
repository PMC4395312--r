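# Statistics layer: exact Mann-Whitney vs enumeration, normality-gated
# policy, repeated-measures interaction, regression, category and count
# comparisons.

test_that("exact Mann-Whitney matches full enumeration", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
  res <- compare_groups(d, y, g, policy = "mann_whitney")
  expect_equal(res$p_value, 0.1)                 # 2/20 assignments as extreme
  expect_equal(res$p_value, mw_exact_p(1:3, 4:6))
  expect_equal(unname(res$statistic), 0)

  # random small instances without ties against the enumeration oracle
  set.seed(42)
  for (i in 1:60) {
    m <- sample(3:5, 1); n <- sample(3:5, 1)
    v <- sample(1:50, m + n)           # distinct values: exact path
    a <- v[1:m]; b <- v[(m + 1):(m + n)]
    dd <- data.frame(g = rep(c("a", "b"), c(m, n)), y = c(a, b))
    res <- compare_groups(dd, y, g, policy = "mann_whitney")
    expect_equal(res$p_value, mw_exact_p(a, b), tolerance = 1e-12)
  }
})

test_that("identical groups sit at the null center with p = 1", {
  d <- data.frame(g = rep(c("a", "b"), each = 4), y = rep(c(3, 1, 4, 1), 2))
  expect_equal(compare_groups(d, y, g, policy = "t")$p_value, 1)
  expect_equal(suppressWarnings(
    compare_groups(d, y, g, policy = "mann_whitney"))$p_value, 1)

  const <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(2, 6))
  expect_warning(res <- compare_groups(const, y, g, policy = "t"),
                 "identical")
  expect_equal(res$p_value, 1)
})

test_that("the auto policy routes by Shapiro-Wilk normality", {
  set.seed(7)
  normal <- data.frame(g = rep(c("a", "b"), each = 12),
                       y = rnorm(24, rep(c(0, 1), each = 12)))
  res_n <- compare_groups(normal, y, g, policy = "auto")
  expect_equal(res_n$test_used, "t")
  expect_gt(min(res_n$normality_p1, res_n$normality_p2), 0.05)

  skewed <- data.frame(g = rep(c("a", "b"), each = 12),
                       y = c(exp(rnorm(12, 0, 2)), exp(rnorm(12, 1, 2))))
  res_s <- compare_groups(skewed, y, g, policy = "auto")
  expect_equal(res_s$test_used, "mann_whitney")

  expect_error(compare_groups(normal[c(1, 13), ], y, g),
               class = "motorpool_error_insufficient_data")
})

test_that("summaries report mean and SEM = SD/sqrt(N) exactly", {
  d <- data.frame(g = rep(c("a", "b"), c(3, 4)),
                  y = c(1, 2, 6, 2, 4, 4, 10))
  res <- compare_groups(d, y, g, policy = "t")
  expect_equal(res$mean1, 3)
  expect_equal(res$sem1, sd(c(1, 2, 6)) / sqrt(3))
  expect_equal(res$n2, 4)
  expect_equal(res$sem2, sd(c(2, 4, 4, 10)) / sqrt(4))
})

test_that("a purely additive genotype effect yields no interaction", {
  set.seed(11)
  d <- tidyr::crossing(animal_id = sprintf("a%02d", 1:12),
                       timepoint_weeks = c(4, 8, 12))
  d$genotype <- ifelse(d$animal_id <= "a06", "wt", "mut")
  d$y <- 10 + 5 * (d$genotype == "mut") - 0.2 * d$timepoint_weeks +
    rnorm(nrow(d), 0, 0.8)
  res <- rm_anova_interaction(d, y)
  expect_gt(res$p_value, 0.05)
  # main between effect is large by construction
  between_p <- summary(aov(y ~ genotype + Error(animal_id),
                           data = d))[[1]][[1]]["genotype", "Pr(>F)"]
  expect_lt(between_p, 1e-4)
})

test_that("incomplete animals are dropped with a warning", {
  d <- tidyr::crossing(animal_id = sprintf("a%02d", 1:10),
                       timepoint_weeks = c(4, 8, 12))
  d$genotype <- ifelse(d$animal_id <= "a05", "wt", "mut")
  set.seed(3)
  d$y <- rnorm(nrow(d))
  d <- d[-1, ]   # a01 misses one timepoint
  expect_warning(res <- rm_anova_interaction(d, y), "dropped")
  expect_equal(res$n_subjects, 9)
  expect_equal(res$n_dropped, 1)
})

test_that("the mutant-vs-wildtype developmental interaction is detectable", {
  # published ladder-rung means: mutants improve 25.58 -> 18.31 s while
  # wildtypes change 11.74 -> 9.41 s; the interaction should be picked up
  # in most simulated cohorts
  set.seed(19)
  hits <- replicate(30, {
    coh <- sim_cohort(groups = data.frame(housing = "NH",
                                          genotype = c("wt", "mut")),
                      scatter_presets = preset_scatter()[0, ],
                      synapse_presets = preset_synapse()[0, ],
                      pnn_presets = preset_pnn()[0, ])
    rm_anova_interaction(coh$behavior, crossing_time_s)$p_value < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("regression recovers exact and noiseless links", {
  triv <- data.frame(si = c(0, 1, 2), crossing_time_s = c(0, 1, 2))
  res <- suppressWarnings(si_behavior_regression(triv))
  expect_equal(res$slope, 1, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)

  set.seed(5)
  si <- runif(40, 4e-4, 2e-3)
  link <- sim_behavior_link(si, slope = 8.098e-5, intercept = 2e-4, noise_sd = 0)
  fit <- suppressWarnings(
    si_behavior_regression(link, si = si, behavior = response,
                           orientation = "behavior_on_si"))
  expect_equal(fit$slope, 8.098e-5, tolerance = 1e-10)

  const <- data.frame(si = c(1, 2, 3), crossing_time_s = rep(2, 3))
  expect_error(si_behavior_regression(const),
               class = "motorpool_error_parameter")
})

test_that("PNN category comparisons detect shifted distributions only", {
  # identical fractions in every animal: F = 0, p = 1 by convention
  flat <- tidyr::crossing(animal_id = sprintf("a%d", 1:8), neuron = 1:10)
  flat$genotype <- ifelse(flat$animal_id <= "a4", "wt", "mut")
  flat$housing <- "NH"
  flat$category <- rep(c(rep("none", 7), rep("weak", 2), "strong"), 8)
  ws <- capture_warnings(res <- compare_pnn_categories(flat))
  expect_match(ws, "constant", all = FALSE)
  expect_equal(res$p_value[res$category == "none"], 1)
  expect_equal(res$statistic[res$category == "none"], 0)

  # equal probabilities across groups: rejections stay near the 5% level
  pp <- preset_pnn()
  pp[, c("p_none", "p_weak", "p_strong")] <-
    tibble::tibble(p_none = 0.65, p_weak = 0.30, p_strong = 0.05)
  set.seed(23)
  hits <- replicate(25, {
    coh <- sim_cohort(pnn_presets = pp,
                      behavior_presets = preset_behavior()[0, ],
                      scatter_presets = preset_scatter()[0, ],
                      synapse_presets = preset_synapse()[0, ])
    compare_pnn_categories(coh$pnn)$p_value[1] < 0.05
  })
  expect_lt(mean(hits), 0.3)

  # one group strongly shifted: detected in most replicates
  pp2 <- preset_pnn()
  pp2[4, c("p_none", "p_weak", "p_strong")] <- as.list(c(0.2, 0.6, 0.2))
  set.seed(24)
  hits2 <- replicate(15, {
    coh <- sim_cohort(pnn_presets = pp2,
                      behavior_presets = preset_behavior()[0, ],
                      scatter_presets = preset_scatter()[0, ],
                      synapse_presets = preset_synapse()[0, ])
    compare_pnn_categories(coh$pnn)$p_value[1] < 0.05
  })
  expect_gt(mean(hits2), 0.5)

  expect_error(compare_pnn_categories(
    data.frame(animal_id = "a", genotype = "wt", housing = "NH",
               category = "medium")),
    class = "motorpool_error_format")
})

test_that("synapse comparisons treat the animal as the statistical unit", {
  # two animals' neuron counts permuted within animal: identical means -> p = 1
  d <- tidyr::crossing(animal_id = sprintf("a%d", 1:6), neuron_id = 1:4)
  d$genotype <- "wt"
  d$housing <- rep(c("NH", "EE_birth"), each = 12)
  d$excitatory_count <- rep(c(8, 9, 10, 9), 6)
  d$inhibitory_count <- rep(c(120, 130, 125, 125), 6)
  ws <- capture_warnings(res <- compare_synapse_counts(d))
  expect_match(ws, "identical", all = FALSE)
  expect_true(all(res$p_value == 1))

  too_few <- d[d$animal_id != "a1", ]
  expect_error(compare_synapse_counts(too_few),
               class = "motorpool_error_insufficient_data")
})
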