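#' Preprocess a cohort table for association modelling
#'
#' Natural-log transforms the eight analytes with skewed assay distributions
#' (pTau, tTau, SNAP-25, Ng, NfL, VILIP-1, YKL-40, sTREM2 — the amyloid
#' peptides and the Abeta42/40 ratio stay on their native scale), then
#' Z-scores every analysis variable using the mean and sd of the entire
#' cohort so slope estimates are comparable across predictors. Missing
#' values propagate. Subgroup models reuse this cohort-level scaling.
#'
#' @param table A `cohort_table`.
#' @param variables Columns to standardize; defaults to the analytes, the
#'   two ratio columns and the small-world outcome (those present).
#' @return The transformed `cohort_table`, with the applied centers/scales
#'   in attribute `scaling`.
#' @export
preprocess_cohort <- function(table, variables = NULL) {
  logv <- intersect(gmnet_log_analytes(), names(table))
  for (v in logv) {
    x <- table[[v]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      stop("non-positive ", v, " value for subject ",
           paste(table$subject_id[bad], collapse = ", "),
           ": cannot log-transform")
    }
    table[[v]] <- log(x)
  }
  if (is.null(variables)) {
    variables <- intersect(c(gmnet_analytes(), "ratio_ab4240", "ratio_ptau_ab42",
                             "small_world", "total_gm_volume"), names(table))
  }
  centers <- scales <- stats::setNames(numeric(length(variables)), variables)
  for (v in variables) {
    x <- table[[v]]
    centers[v] <- mean(x, na.rm = TRUE)
    scales[v] <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(scales[v]) || scales[v] == 0) {
      stop("cannot Z-score constant or empty column: ", v)
    }
    table[[v]] <- (x - centers[v]) / scales[v]
  }
  attr(table, "scaling") <- list(log_transformed = logv,
                                 center = centers, scale = scales)
  table
}

#' Assign disease-severity stage from amyloid status and CDR
#'
#' Stage 1: normal pTau/Abeta42 ratio (strictly below the cutoff, i.e. no
#' underlying amyloid), regardless of CDR. With an abnormal ratio (at or
#' above the cutoff), CDR 0 gives stage 2, CDR 0.5 stage 3, and CDR >= 1
#' stage 4. A missing ratio leaves the stage unassigned (`NA`). Vectorized.
#'
#' @param ratio_ptau_ab42 CSF pTau/Abeta42 ratio(s), >= 0.
#' @param cdr Clinical dementia rating(s) in 0, 0.5, 1, 2, 3.
#' @param cutoff Abnormality cutoff (default 0.019; the boundary value
#'   itself is abnormal).
#' @return Integer stage(s) in 1..4 or `NA`.
#' @export
assign_stage <- function(ratio_ptau_ab42, cdr, cutoff = 0.019) {
  stopifnot(all(ratio_ptau_ab42 >= 0, na.rm = TRUE),
            all(cdr %in% c(0, 0.5, 1, 2, 3) | is.na(cdr)))
  ifelse(is.na(ratio_ptau_ab42), NA_integer_,
         ifelse(ratio_ptau_ab42 < cutoff, 1L,
                ifelse(cdr == 0, 2L, ifelse(cdr == 0.5, 3L, 4L))))
}

.check_rank <- function(fit) {
  al <- stats::alias(fit)$Complete
  if (!is.null(al) && nrow(al)) {
    stop("rank-deficient design; collinear term(s): ",
         paste(rownames(al), collapse = ", "))
  }
  invisible(fit)
}

.wald_ci <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = est - z * se, upper = est + z * se)
}

#' Fit a tiered CSF-biomarker / network association model
#'
#' Ordinary least squares on complete cases with three nested fixed-effect
#' structures: tier 1 `outcome ~ predictor + sex`; tier 2 adds mutation
#' status and its interaction with the predictor
#' (`outcome ~ predictor * mutation_status + sex`); tier 3 additionally
#' adjusts for age as a main effect. Confidence intervals are Wald
#' (normal-approximation) intervals; the interaction t and p come from the
#' fitted model's predictor-by-mutation coefficient.
#'
#' @param table A preprocessed `cohort_table` (predictor and outcome
#'   Z-scored; see [preprocess_cohort()]).
#' @param predictor,outcome Column names.
#' @param tier Model tier, 1, 2 or 3.
#' @return An object of class `model_result`.
#' @export
fit_association <- function(table, predictor, outcome = "small_world", tier = 2L) {
  stopifnot(tier %in% 1:3, predictor %in% names(table),
            outcome %in% names(table))
  rhs <- switch(as.character(tier),
    "1" = paste(predictor, "+ sex"),
    "2" = paste(predictor, "* mutation_status + sex"),
    "3" = paste(predictor, "* mutation_status + sex + age"))
  dat <- table
  dat$mutation_status <- factor(dat$mutation_status,
                                levels = c("non-carrier", "carrier"))
  dat$sex <- factor(dat$sex)
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  use <- stats::complete.cases(dat[, c(outcome, predictor, "sex",
                                       if (tier >= 2) "mutation_status",
                                       if (tier == 3) "age")])
  if (sum(use) < 10) stop("fewer than 10 complete cases for ", predictor)
  fit <- stats::lm(fml, data = dat[use, , drop = FALSE])
  .check_rank(fit)
  sm <- summary(fit)$coefficients
  ci <- .wald_ci(sm[, 1], sm[, 2])
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      ci_lower = ci[, 1], ci_upper = ci[, 2],
                      t = sm[, 3], p = sm[, 4], row.names = NULL)
  int_term <- paste0(predictor, ":mutation_statuscarrier")
  interaction <- if (tier >= 2 && int_term %in% rownames(sm)) {
    list(t = unname(sm[int_term, 3]), p = unname(sm[int_term, 4]))
  } else NULL
  structure(list(outcome = outcome, predictor = predictor, tier = as.integer(tier),
                 coefficients = coefs, interaction = interaction,
                 n = sum(use), fit = fit, vcov = stats::vcov(fit)),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("model_result (tier %d): %s ~ %s, n = %d\n",
              x$tier, x$outcome, x$predictor, x$n))
  print(x$coefficients, digits = 3)
  if (!is.null(x$interaction)) {
    cat(sprintf("interaction: t = %.2f, p = %.4g\n",
                x$interaction$t, x$interaction$p))
  }
  invisible(x)
}

#' Estimated marginal predictor slope within a mutation-status group
#'
#' The non-carrier slope is the predictor main effect; the carrier slope
#' adds the interaction coefficient. Standard errors come from the fitted
#' coefficient covariance (delta method on the linear combination), so the
#' group slopes and the interaction statistic are internally consistent.
#'
#' @param result A tier >= 2 `model_result`.
#' @param group `"carrier"` or `"non-carrier"`; default both.
#' @return Data.frame with group, slope, se and Wald 95% CI.
#' @export
group_slopes <- function(result, group = c("non-carrier", "carrier")) {
  stopifnot(inherits(result, "model_result"))
  if (result$tier < 2) stop("group slopes require a tier >= 2 model (with interaction)")
  group <- match.arg(group, several.ok = TRUE)
  cn <- colnames(result$vcov)
  int_term <- paste0(result$predictor, ":mutation_statuscarrier")
  out <- lapply(group, function(gr) {
    w <- stats::setNames(numeric(length(cn)), cn)
    w[result$predictor] <- 1
    if (gr == "carrier") w[int_term] <- 1
    est <- sum(w * stats::coef(result$fit)[cn])
    se <- sqrt(drop(t(w) %*% result$vcov %*% w))
    data.frame(group = gr, slope = est, se = se,
               ci_lower = est - stats::qnorm(0.975) * se,
               ci_upper = est + stats::qnorm(0.975) * se)
  })
  do.call(rbind, out)
}

#' Disease-stage by predictor interaction within mutation carriers
#'
#' Restricted to carriers, fits `outcome ~ predictor * stage + sex` with
#' stage as a factor (stages with fewer than 3 subjects are excluded with a
#' warning), tests the joint predictor-by-stage interaction with an F test,
#' and — when that test is significant at `alpha` — compares all pairwise
#' stage slopes with Tukey's HSD (studentized-range distribution, residual
#' df from the single fitted model).
#'
#' @param table Preprocessed `cohort_table` restricted to carriers, with a
#'   `stage` column (see [assign_stage()]).
#' @param predictor Predictor column name.
#' @param outcome Outcome column name.
#' @param alpha Significance level gating the post hocs.
#' @return List with the fitted `model_result`-like fit, `joint` (F, df, p),
#'   per-stage `slopes`, and `pairwise` (NULL unless the joint test passes).
#' @export
stage_interaction <- function(table, predictor, outcome = "small_world",
                              alpha = 0.05) {
  stopifnot("stage" %in% names(table))
  dat <- table[!is.na(table$stage), , drop = FALSE]
  counts <- table(dat$stage)
  small <- names(counts)[counts < 3]
  if (length(small)) {
    warning("excluding stage(s) with < 3 subjects: ", paste(small, collapse = ", "))
    dat <- dat[!(dat$stage %in% as.numeric(small)), , drop = FALSE]
  }
  if (length(unique(dat$stage)) < 2) stop("need at least 2 stages represented")
  dat$stage <- factor(dat$stage)
  dat$sex <- factor(dat$sex)
  use <- stats::complete.cases(dat[, c(outcome, predictor, "sex", "stage")])
  dat <- dat[use, , drop = FALSE]
  full <- stats::lm(stats::as.formula(paste(outcome, "~", predictor, "* stage + sex")),
                    data = dat)
  .check_rank(full)
  reduced <- stats::lm(stats::as.formula(paste(outcome, "~", predictor, "+ stage + sex")),
                       data = dat)
  an <- stats::anova(reduced, full)
  joint <- list(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
                p = an$`Pr(>F)`[2])

  stages <- levels(dat$stage)
  cf <- stats::coef(full); V <- stats::vcov(full); cn <- names(cf)
  slope_weight <- function(s) {
    w <- stats::setNames(numeric(length(cn)), cn)
    w[predictor] <- 1
    it <- paste0(predictor, ":stage", s)
    if (it %in% cn) w[it] <- 1
    w
  }
  slopes <- do.call(rbind, lapply(stages, function(s) {
    w <- slope_weight(s)
    est <- sum(w * cf); se <- sqrt(drop(t(w) %*% V %*% w))
    data.frame(stage = s, slope = est, se = se)
  }))

  pairwise <- NULL
  if (!is.na(joint$p) && joint$p < alpha) {
    k <- length(stages)
    df <- stats::df.residual(full)
    combs <- utils::combn(stages, 2)
    pairwise <- do.call(rbind, apply(combs, 2, function(pr) {
      w <- slope_weight(pr[1]) - slope_weight(pr[2])
      est <- sum(w * cf); se <- sqrt(drop(t(w) %*% V %*% w))
      tstat <- est / se
      data.frame(stage_a = pr[1], stage_b = pr[2], diff = est, se = se,
                 t = tstat,
                 p_tukey = stats::ptukey(sqrt(2) * abs(tstat), nmeans = k,
                                         df = df, lower.tail = FALSE))
    }, simplify = FALSE))
  }
  list(fit = full, joint = joint, slopes = slopes, pairwise = pairwise,
       n = nrow(dat), stages_used = stages)
}

#' Pairwise-complete Spearman correlations between biomarkers
#'
#' @param table A `cohort_table`.
#' @param analytes Columns to correlate (default: the analytes present).
#' @param min_pairs Minimum complete pairs per cell; cells below it are
#'   flagged `NA`.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `n_pairs` holds the complete-pair counts.
#' @export
spearman_matrix <- function(table, analytes = NULL, min_pairs = 3L) {
  if (is.null(analytes)) analytes <- intersect(gmnet_analytes(), names(table))
  stopifnot(length(analytes) >= 2, all(analytes %in% names(table)))
  X <- as.matrix(table[, analytes, drop = FALSE])
  rho <- stats::cor(X, method = "spearman", use = "pairwise.complete.obs")
  ok <- !is.na(X)
  npairs <- crossprod(ok * 1)
  rho[npairs < min_pairs] <- NA_real_
  diag(rho) <- 1
  attr(rho, "n_pairs") <- npairs
  rho
}
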