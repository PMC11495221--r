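#' Z-score biomarkers to a young non-carrier reference
#'
#' Standardizes the listed variables by the mean and sd of the young
#' non-carrier subset (non-carriers under `age_cutoff` years), the reference
#' population assumed free of preclinical disease. Applied before trajectory
#' fitting so that carrier departures are in reference-sd units.
#'
#' @param table A `cohort_table` with `mutation_status` and `age`.
#' @param variables Columns to standardize.
#' @param age_cutoff Upper age bound of the reference subset (default 40).
#' @return The transformed table; attribute `reference` records membership,
#'   means and sds.
#' @export
zscore_to_reference <- function(table, variables, age_cutoff = 40) {
  stopifnot(all(variables %in% names(table)))
  ref <- table$mutation_status == "non-carrier" & table$age < age_cutoff
  if (!any(ref)) stop("empty reference subset (non-carriers under ", age_cutoff, ")")
  centers <- scales <- stats::setNames(numeric(length(variables)), variables)
  for (v in variables) {
    m <- mean(table[[v]][ref], na.rm = TRUE)
    s <- stats::sd(table[[v]][ref], na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("zero-variance reference variable: ", v)
    centers[v] <- m; scales[v] <- s
    table[[v]] <- (table[[v]] - m) / s
  }
  attr(table, "reference") <- list(member = ref, n = sum(ref),
                                   center = centers, scale = scales)
  table
}

# Cauchy(0, prior_scale) coefficient priors written as the gamma scale
# mixture of normals (beta_j | lam_j ~ N(0, scale^2/lam_j), lam_j ~
# Gamma(1/2, 1/2) gives a Cauchy marginal exactly); the conditionally
# normal form lets the sampler's block updater handle the fixed effects.
#' Prepare biomarker columns for trajectory fitting
#'
#' Applies the trajectory-stage preprocessing in order: natural log for the
#' skewed analytes (see [gmnet_log_analytes()]), then Z-scoring to the young
#' non-carrier reference via [zscore_to_reference()]. Amyloid peptides, the
#' ratios, the small-world coefficient and total grey-matter volume are
#' standardized without a log step.
#'
#' @param table A `cohort_table`.
#' @param variables Columns to prepare.
#' @param age_cutoff Reference age bound, years.
#' @return The transformed table (see [zscore_to_reference()] for the
#'   attached reference metadata).
#' @export
prepare_trajectory_table <- function(table, variables, age_cutoff = 40) {
  for (v in intersect(gmnet_log_analytes(), variables)) {
    x <- table[[v]]
    if (any(!is.na(x) & x <= 0)) stop("non-positive ", v, " value: cannot log-transform")
    table[[v]] <- log(x)
  }
  zscore_to_reference(table, variables, age_cutoff = age_cutoff)
}

.traj_model_string <- "model {
  for (i in 1:N) {
    y[i] ~ dnorm(inprod(X[i, ], beta) + u[fam[i]], tau_e)
  }
  for (j in 1:P) {
    beta[j] ~ dnorm(0, lam[j] * pow(prior_scale, -2))
    lam[j] ~ dgamma(0.5, 0.5)
  }
  for (f in 1:F) { u[f] ~ dnorm(0, tau_u) }
  sigma_e ~ dt(0, pow(prior_scale, -2), 1) T(0,)
  sigma_u ~ dt(0, pow(prior_scale, -2), 1) T(0,)
  tau_e <- pow(sigma_e, -2)
  tau_u <- pow(sigma_u, -2)
}"

# split-chain potential scale reduction factor (each chain halved)
rhat_split <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(ch) {
    n <- length(ch) %/% 2
    list(ch[seq_len(n)], ch[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit a Bayesian RCS biomarker trajectory over EYO
#'
#' Gaussian linear mixed model sampled by MCMC: fixed effects for the two
#' restricted-cubic-spline EYO terms, mutation status, their interactions
#' and covariates; a family random intercept; Cauchy(0, 2.5) priors on the
#' standardized coefficients and half-Cauchy(0, 2.5) on the two scale
#' parameters. The first half of `iter` is warmup. The outcome should be
#' standardized (see [zscore_to_reference()]); `sex` is always a covariate
#' and the small-world outcome additionally adjusts for total grey-matter
#' volume.
#'
#' @param table A `cohort_table` with `eyo`, `mutation_status`, `family_id`,
#'   covariates and the standardized outcome.
#' @param outcome Outcome column name.
#' @param covariates Covariate column names (character columns become 0/1
#'   dummies against their first level; numeric columns enter as given).
#' @param basis Optional [rcs_basis()]; defaults to knots at the 0.1/0.5/0.9
#'   quantiles of the analysis sample's pooled EYO.
#' @param chains,iter,thin MCMC settings (total iterations per chain; the
#'   first half is discarded as warmup; kept draws are thinned by `thin`).
#' @param adapt Adaptation iterations for the sampler.
#' @param prior_scale Scale of the Cauchy priors.
#' @param seed Integer seed; per-chain RNG seeds are split from it.
#' @param quiet Suppress sampler progress output.
#' @return An object of class `trajectory_fit`: named posterior `draws`
#'   matrix (fixed effects plus `sigma_family`, `sigma_resid`), the basis,
#'   split-chain convergence statistics per parameter (`rhat`), and fit
#'   metadata. Warns if any rhat exceeds 1.01.
#' @export
fit_trajectory <- function(table, outcome, covariates = c("sex"),
                           basis = NULL, chains = 4L, iter = 2000L,
                           thin = 2L, adapt = 500L, prior_scale = 2.5,
                           seed = 1L, quiet = TRUE) {
  stopifnot(outcome %in% names(table), "family_id" %in% names(table),
            "eyo" %in% names(table), "sex" %in% covariates)
  need <- c(outcome, "eyo", "mutation_status", "family_id", covariates)
  use <- stats::complete.cases(table[, need, drop = FALSE])
  dat <- table[use, , drop = FALSE]
  if (nrow(dat) < 20) stop("fewer than 20 complete cases for ", outcome)
  if (is.null(basis)) basis <- rcs_basis(dat$eyo)
  B <- rcs_eval(basis, dat$eyo)
  mut <- as.numeric(dat$mutation_status == "carrier")
  X <- cbind(intercept = 1, B, mutation = mut,
             B * mut)
  colnames(X)[(ncol(B) + 3):ncol(X)] <- paste0(colnames(B), "_x_mutation")
  for (cv in covariates) {
    v <- dat[[cv]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      if (nlevels(v) > 2) stop("covariate ", cv, " has more than 2 levels")
      col <- as.numeric(v == levels(v)[2])
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0(cv, "_", levels(v)[2])
    } else {
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- cv
    }
  }
  fam <- as.integer(factor(dat$family_id))
  # centring the non-intercept columns only shifts the intercept but
  # decorrelates it from the sampler's coefficient updates
  col_means <- colMeans(X[, -1, drop = FALSE])
  Xc <- X
  Xc[, -1] <- sweep(X[, -1, drop = FALSE], 2, col_means)
  warmup <- iter %/% 2
  n_keep <- iter - warmup
  inits <- lapply(seq_len(chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = split_seed(seed, paste0("chain", k)))
  })
  rjags::load.module("glm", quiet = TRUE)  # block updater for the fixed effects
  jm <- rjags::jags.model(textConnection(.traj_model_string),
                          data = list(N = nrow(Xc), P = ncol(Xc), X = Xc,
                                      fam = fam, F = max(fam),
                                      y = dat[[outcome]],
                                      prior_scale = prior_scale),
                          inits = inits, n.chains = chains,
                          n.adapt = adapt, quiet = quiet)
  update(jm, warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("beta", "sigma_u", "sigma_e"),
                              n.iter = n_keep, thin = thin,
                              progress.bar = "none")
  nm <- colnames(samp[[1]])
  pretty <- nm
  pretty[match(paste0("beta[", seq_len(ncol(X)), "]"), nm)] <- colnames(X)
  pretty[nm == "sigma_u"] <- "sigma_family"
  pretty[nm == "sigma_e"] <- "sigma_resid"
  rhat <- vapply(seq_along(nm), function(j) {
    rhat_split(lapply(samp, function(ch) as.numeric(ch[, j])))
  }, numeric(1))
  names(rhat) <- pretty
  if (any(rhat > 1.01, na.rm = TRUE)) {
    warning("convergence statistic above 1.01 for: ",
            paste(pretty[rhat > 1.01], collapse = ", "))
  }
  draws <- do.call(rbind, lapply(samp, as.matrix))
  colnames(draws) <- pretty
  # map the centred-design intercept back to the original parameterization
  slope_cols <- colnames(X)[-1]
  draws[, "intercept"] <- draws[, "intercept"] -
    draws[, slope_cols, drop = FALSE] %*% col_means
  structure(list(outcome = outcome, draws = draws, basis = basis,
                 terms = colnames(X), rhat = rhat,
                 chains = chains, iter = iter, warmup = warmup, thin = thin,
                 n_draws = nrow(draws), n = nrow(dat),
                 n_families = max(fam)),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("trajectory_fit: %s, n = %d (%d families), %d draws (%d chains), max rhat %.3f\n",
              x$outcome, x$n, x$n_families, x$n_draws, x$chains, max(x$rhat)))
  qs <- t(apply(x$draws, 2, stats::quantile, c(0.5, 0.025, 0.975)))
  colnames(qs) <- c("median", "2.5%", "97.5%")
  print(round(qs, 3))
  invisible(x)
}

#' Posterior carrier-minus-non-carrier difference curve over EYO
#'
#' At every grid point the difference of the group means is the mutation
#' main effect plus the spline-by-mutation interaction terms evaluated on
#' the basis; its posterior is summarized by the mean and central credible
#' bands at the 95, 99 and 99.5% levels.
#'
#' @param fit A [fit_trajectory()] result.
#' @param grid EYO grid (default -25 to 10 by 0.5 years).
#' @return An object of class `divergence_estimate`.
#' @export
difference_curve <- function(fit, grid = seq(-25, 10, by = 0.5)) {
  stopifnot(inherits(fit, "trajectory_fit"), length(grid) >= 1)
  B <- rcs_eval(fit$basis, grid)
  terms <- c("mutation", paste0(colnames(B), "_x_mutation"))
  stopifnot(all(terms %in% colnames(fit$draws)))
  D <- fit$draws[, terms, drop = FALSE] %*% t(cbind(1, B))
  levels <- c("95" = 0.95, "99" = 0.99, "99.5" = 0.995)
  bands <- lapply(levels, function(l) {
    a <- (1 - l) / 2
    list(lower = apply(D, 2, stats::quantile, a),
         upper = apply(D, 2, stats::quantile, 1 - a))
  })
  structure(list(outcome = fit$outcome, grid = grid,
                 mean = colMeans(D), bands = bands),
            class = "divergence_estimate")
}

#' Divergence point of the carrier / non-carrier difference
#'
#' The earliest grid EYO from which the requested credible band excludes 0
#' both there and at every later grid point (sustained exclusion; the
#' pointwise-first-exclusion rule is available via `sustained = FALSE` for
#' sensitivity). Returns `NA` if exclusion is never sustained.
#'
#' @param est A [difference_curve()] result.
#' @param level One of `"95"`, `"99"`, `"99.5"` (default `"99"`).
#' @param sustained Require exclusion through the end of the grid?
#' @return The divergence EYO (years) or `NA`.
#' @export
divergence_point <- function(est, level = "99", sustained = TRUE) {
  stopifnot(inherits(est, "divergence_estimate"))
  level <- match.arg(as.character(level), names(est$bands))
  b <- est$bands[[level]]
  excl <- b$lower > 0 | b$upper < 0
  if (!any(excl)) return(NA_real_)
  if (!sustained) return(est$grid[which(excl)[1]])
  ok <- rev(cumprod(rev(excl))) == 1  # TRUE where exclusion holds to grid end
  if (!any(ok)) return(NA_real_)
  est$grid[which(ok)[1]]
}
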