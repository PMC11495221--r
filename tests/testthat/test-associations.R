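make_assoc_table <- function(n = 300, seed = 50, ...) {
  simulate_association_cohort(n = n, seed = seed, ...)
}

test_that("preprocessing logs the right analytes and Z-scores the whole cohort", {
  coh <- simulate_cohort(cohort_sim_spec(seed = 51))
  pp <- preprocess_cohort(coh)
  sc <- attr(pp, "scaling")
  expect_setequal(sc$log_transformed, gmnet_log_analytes())
  expect_false("ratio_ab4240" %in% sc$log_transformed)
  expect_false("abeta42" %in% sc$log_transformed)
  for (v in c("nfl", "ratio_ab4240", "small_world")) {
    x <- pp[[v]][!is.na(pp[[v]])]
    expect_equal(mean(x), 0, tolerance = 1e-10)
    expect_equal(sd(x), 1, tolerance = 1e-10)
  }
  # the ratio column is only rescaled, never logged
  raw <- coh$ratio_ab4240
  expect_equal(pp$ratio_ab4240, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)
})

test_that("non-positive analyte values abort with subject and analyte named", {
  coh <- simulate_cohort(cohort_sim_spec(n_mc = 10, n_nc = 10, n_families = 5,
                                         seed = 52))
  coh$nfl[3] <- 0
  expect_error(preprocess_cohort(coh), "nfl")
  expect_error(preprocess_cohort(coh), coh$subject_id[3])
})

test_that("stage assignment follows the amyloid-ratio and CDR rule", {
  expect_equal(assign_stage(0.010, 0), 1L)
  expect_equal(assign_stage(0.051, 0), 2L)
  expect_equal(assign_stage(0.091, 0.5), 3L)
  expect_equal(assign_stage(0.120, 2), 4L)
  # the boundary value is abnormal (normal is strictly below the cutoff)
  expect_gte(assign_stage(0.019, 0), 2L)
  expect_equal(assign_stage(NA, 1), NA_integer_)
  expect_equal(assign_stage(0.005, 3), 1L)  # normal ratio trumps CDR
  expect_equal(assign_stage(c(0.01, 0.05), c(0, 0.5)), c(1L, 3L))
})

test_that("tiered fits expose coefficients, interaction tests and sample size", {
  tab <- make_assoc_table(n = 400, seed = 53)
  r1 <- fit_association(tab, "predictor", tier = 1)
  expect_null(r1$interaction)
  expect_equal(r1$n, 400)
  r2 <- fit_association(tab, "predictor", tier = 2)
  expect_false(is.null(r2$interaction))
  r3 <- fit_association(tab, "predictor", tier = 3)
  expect_error(fit_association(tab, "nope", tier = 2))

  # missing predictor values reduce n (complete-case per model)
  tab2 <- tab; tab2$predictor[1:40] <- NA
  expect_equal(fit_association(tab2, "predictor", tier = 2)$n, 360)
})

test_that("tier 3 requires age and adjusts for it", {
  tab <- make_assoc_table(n = 200, seed = 54)
  tab$age <- rnorm(200, 40, 10)
  r3 <- fit_association(tab, "predictor", tier = 3)
  expect_true("age" %in% r3$coefficients$term)
})

test_that("duplicated predictors raise a rank-deficiency error", {
  tab <- make_assoc_table(n = 100, seed = 55)
  tab$age <- tab$predictor  # age collinear with the predictor
  expect_error(fit_association(tab, "predictor", tier = 3), "collinear")
})

test_that("group slopes equal stratified per-group regressions", {
  tab <- make_assoc_table(n = 500, seed = 56)
  r2 <- fit_association(tab, "predictor", tier = 2)
  gs <- group_slopes(r2)
  for (gr in c("carrier", "non-carrier")) {
    sub <- tab[tab$mutation_status == gr, ]
    oracle <- coef(lm(small_world ~ predictor + sex, data = sub))["predictor"]
    # stratified fits re-estimate the sex term per group, so agreement is
    # up to that shared-covariate constraint, not exact
    expect_equal(gs$slope[gs$group == gr], unname(oracle), tolerance = 5e-3)
  }
  # slope algebra: carrier slope = predictor + interaction coefficient, exactly
  cf <- coef(r2$fit)
  expect_equal(gs$slope[gs$group == "carrier"],
               unname(cf["predictor"] + cf["predictor:mutation_statuscarrier"]),
               tolerance = 1e-12)
  expect_equal(gs$slope[gs$group == "non-carrier"], unname(cf["predictor"]),
               tolerance = 1e-12)
  expect_error(group_slopes(fit_association(tab, "predictor", tier = 1)),
               "tier")
})

test_that("group slopes and CIs agree with emmeans' marginal trends", {
  skip_if_not_installed("emmeans")
  tab <- make_assoc_table(n = 350, seed = 57)
  r2 <- fit_association(tab, "predictor", tier = 2)
  gs <- group_slopes(r2)
  emt <- as.data.frame(emmeans::emtrends(r2$fit, "mutation_status",
                                         var = "predictor"))
  for (gr in c("non-carrier", "carrier")) {
    expect_equal(gs$slope[gs$group == gr],
                 emt$predictor.trend[emt$mutation_status == gr],
                 tolerance = 1e-8)
    expect_equal(gs$se[gs$group == gr],
                 emt$SE[emt$mutation_status == gr], tolerance = 1e-8)
  }
})

test_that("slope CIs cover the truth at the nominal rate (quick calibration)", {
  hits <- 0; reps <- 60
  for (i in seq_len(reps)) {
    tab <- simulate_association_cohort(n = 350, slope_carrier = -0.7,
                                       slope_noncarrier = -0.7, seed = 600 + i)
    gs <- group_slopes(fit_association(tab, "predictor", tier = 2))
    row <- gs[gs$group == "carrier", ]
    hits <- hits + (row$ci_lower <= -0.7 && -0.7 <= row$ci_upper)
  }
  expect_gt(hits / reps, 0.85)
})

test_that("stage-slope machinery: Tukey with two groups equals the plain t-test", {
  set.seed(58)
  n <- 120
  tab <- data.frame(
    subject_id = paste0("S", 1:n),
    sex = sample(c("male", "female"), n, TRUE),
    stage = rep(c(1, 2), each = n / 2),
    predictor = rnorm(n)
  )
  tab$small_world <- -0.3 * tab$predictor - 0.4 * tab$predictor * (tab$stage == 2) +
    rnorm(n, 0, 0.5)
  si <- stage_interaction(tab, "predictor")
  expect_lt(si$joint$p, 0.05)
  expect_equal(nrow(si$pairwise), 1)
  # with k = 2, ptukey(sqrt(2)|t|) reduces to the two-sided t probability
  fit <- lm(small_world ~ predictor * factor(stage) + sex, tab)
  t_unadj <- summary(fit)$coefficients["predictor:factor(stage)2", ]
  expect_equal(si$pairwise$p_tukey, unname(t_unadj["Pr(>|t|)"]), tolerance = 1e-8)
})

test_that("stage-slope post hocs match emmeans' Tukey-adjusted contrasts", {
  skip_if_not_installed("emmeans")
  set.seed(59)
  n <- 240
  tab <- data.frame(
    subject_id = paste0("S", 1:n),
    sex = sample(c("male", "female"), n, TRUE),
    stage = sample(1:4, n, TRUE),
    predictor = rnorm(n)
  )
  tab$small_world <- -0.2 * tab$predictor - 0.35 * tab$predictor * tab$stage +
    rnorm(n, 0, 0.4)
  si <- stage_interaction(tab, "predictor")
  expect_false(is.null(si$pairwise))
  emt <- emmeans::emtrends(lm(small_world ~ predictor * factor(stage) + sex, tab),
                           "stage", var = "predictor")
  emp <- as.data.frame(emmeans::contrast(emt, "pairwise", adjust = "tukey"))
  expect_equal(sort(si$pairwise$p_tukey), sort(emp$p.value), tolerance = 1e-6)
})

test_that("stages with fewer than 3 subjects are excluded with a warning", {
  set.seed(60)
  n <- 63
  tab <- data.frame(subject_id = paste0("S", 1:n),
                    sex = sample(c("male", "female"), n, TRUE),
                    stage = c(rep(1, 30), rep(2, 31), rep(3, 2)),
                    predictor = rnorm(n))
  tab$small_world <- rnorm(n)
  expect_warning(si <- stage_interaction(tab, "predictor"), "3")
  expect_setequal(si$stages_used, c("1", "2"))
})

test_that("spearman matrix is symmetric, monotone-invariant and matches ranks", {
  set.seed(61)
  tab <- data.frame(a = rnorm(30))
  tab$b <- exp(tab$a)            # monotone transform: rho = 1
  tab$c <- rnorm(30)
  m <- spearman_matrix(tab, c("a", "b", "c"))
  expect_equal(m["a", "b"], 1)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  # rank-then-Pearson oracle
  expect_equal(m["a", "c"], oracle_pearson(rank(tab$a), rank(tab$c)),
               tolerance = 1e-12)
  # all-missing pair flagged
  tab$d <- NA_real_
  tab$d[1:2] <- 1:2
  m2 <- spearman_matrix(tab, c("a", "c", "d"))
  expect_true(is.na(m2["a", "d"]))
})
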