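#' Default analyte generating parameters for the cohort simulator
#'
#' Per analyte: the non-carrier arithmetic mean and sd on the assay scale
#' (matched to published ADAD cohort descriptives), the EYO at which the
#' carrier mean starts departing from the non-carrier mean, the standardized
#' carrier effect at EYO 0 (in units of the non-carrier log-scale sd; the
#' departure is a piecewise-linear hinge on the log scale), and the fraction
#' of values missing completely at random. Amyloid and tau markers diverge
#' earliest, axonal (NfL) and inflammation (YKL-40) markers around the time
#' grey-matter networks change, and sTREM2 close to symptom onset.
#'
#' @return A data.frame with one row per analyte.
#' @export
analyte_defaults <- function() {
  data.frame(
    analyte        = gmnet_analytes(),
    nc_mean        = c(1407, 15698, 14, 169, 3.6, 1563, 793, 133, 133, 0.47),
    nc_sd          = c(466, 4418, 5, 55, 1.3, 741, 544, 50, 66, 0.22),
    divergence_eyo = c(-22, -5, -19, -18, -16, -15, -12, -15, -12, -3),
    mc_effect      = c(-1.5, -0.3, 2.2, 2.0, 1.2, 1.3, 2.0, 1.0, 1.5, 0.8),
    missing_fraction = c(0, 0, 0, 0, 0.07, 0.07, 0.53, 0.07, 0.07, 0.54),
    stringsAsFactors = FALSE
  )
}

#' Specification for synthetic cohorts
#'
#' Describes a two-group (mutation carrier / non-carrier) family cohort on a
#' shared EYO timeline. EYO is visit age minus the family's onset age, so the
#' generator draws a family onset age and an EYO per subject and derives age
#' from them. Carrier biomarker means depart from the (EYO-flat) non-carrier
#' means after each analyte's divergence EYO via a linear hinge on the log
#' scale; the small-world coefficient declines linearly for carriers after
#' its own divergence EYO.
#'
#' @param n_mc,n_nc Carrier and non-carrier counts (defaults mirror the
#'   cohort this emulates: 216 and 136).
#' @param n_families Number of families; subjects are assigned to families
#'   at random with every family nonempty.
#' @param eyo_range Range of EYO, years.
#' @param onset_age_range Family mean onset age window, years.
#' @param analytes Data.frame as [analyte_defaults()]; per-analyte means,
#'   hinge locations, effects and missingness.
#' @param family_sd Family random-intercept sd on the standardized log scale.
#' @param residual_sd Residual sd on the standardized log scale.
#' @param shared_factor_loading Optional loading of a per-subject latent
#'   factor shared across analytes (0 disables; the joint correlation
#'   structure among analytes is otherwise unspecified).
#' @param cdr_cutpoints EYO cutpoints at which carrier CDR steps through
#'   0, 0.5, 1, 2, 3.
#' @param smallworld_baseline,smallworld_sd Mean and sd of the small-world
#'   coefficient in non-carriers.
#' @param smallworld_divergence_eyo,smallworld_decline Carrier hinge EYO and
#'   decline per year for the small-world coefficient.
#' @param gm_volume_baseline,gm_volume_sd,gm_volume_decline Total grey-matter
#'   volume (ml) baseline, sd, and carrier decline per year after the
#'   small-world hinge.
#' @param p_male Probability a subject is male.
#' @param seed Integer seed.
#' @return A `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_mc = 216L, n_nc = 136L, n_families = 100L,
                            eyo_range = c(-30, 10),
                            onset_age_range = c(40, 55),
                            analytes = analyte_defaults(),
                            family_sd = 0.3, residual_sd = 0.954,
                            shared_factor_loading = 0,
                            cdr_cutpoints = c(-3, 3, 8, 12),
                            smallworld_baseline = 1.62, smallworld_sd = 0.055,
                            smallworld_divergence_eyo = -12,
                            smallworld_decline = 0.011,
                            gm_volume_baseline = 620, gm_volume_sd = 55,
                            gm_volume_decline = 4,
                            p_male = 0.42, seed = 1L) {
  stopifnot(n_mc >= 0, n_nc >= 0, n_families >= 1,
            n_families <= n_mc + n_nc,
            family_sd > 0, residual_sd > 0,
            all(analytes$missing_fraction >= 0),
            all(analytes$missing_fraction <= 1),
            all(analytes$nc_mean > 0), all(analytes$nc_sd > 0),
            length(cdr_cutpoints) == 4, !is.unsorted(cdr_cutpoints))
  structure(as.list(environment()), class = "cohort_sim_spec")
}

# standardized carrier departure profile: 0 before the hinge, linear after,
# scaled so the profile equals `effect` at EYO 0
hinge_profile <- function(eyo, divergence_eyo, effect) {
  stopifnot(divergence_eyo < 0)
  effect * pmax(0, eyo - divergence_eyo) / (-divergence_eyo)
}

#' Simulate a DIAN-like cohort table with known ground truth
#'
#' Generates subjects with family ids, mutation status, sex, EYO (= visit
#' age minus family onset age), CDR (a monotone step function of EYO for
#' carriers), ten log-normal CSF analytes, the small-world coefficient and
#' total grey-matter volume, with per-analyte missingness applied completely
#' at random. The generating parameters (divergence EYOs, effects, family
#' structure) are attached as the `ground_truth` attribute so recovery can
#' be tested.
#'
#' @param spec A [cohort_sim_spec()].
#' @param seed Optional seed override.
#' @return A `cohort_table` data.frame with attribute `ground_truth`.
#' @export
simulate_cohort <- function(spec = cohort_sim_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  n <- spec$n_mc + spec$n_nc
  status <- sample(c(rep("carrier", spec$n_mc), rep("non-carrier", spec$n_nc)))
  family <- sample(rep_len(seq_len(spec$n_families), n))
  onset_age <- stats::runif(spec$n_families, spec$onset_age_range[1],
                            spec$onset_age_range[2])
  eyo <- stats::runif(n, spec$eyo_range[1], spec$eyo_range[2])
  age <- onset_age[family] + eyo
  sex <- ifelse(stats::rbinom(n, 1, spec$p_male) == 1, "male", "female")
  carrier <- status == "carrier"

  cdr <- rep(0, n)
  cp <- spec$cdr_cutpoints
  cdr[carrier] <- cut(eyo[carrier], c(-Inf, cp, Inf),
                      labels = FALSE, right = FALSE)
  cdr[carrier] <- c(0, 0.5, 1, 2, 3)[cdr[carrier]]

  an <- spec$analytes
  total_sd <- sqrt(spec$family_sd^2 + spec$residual_sd^2 +
                   spec$shared_factor_loading^2)
  latent <- stats::rnorm(n)  # shared factor (inactive at loading 0)
  tab <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    family_id = sprintf("F%03d", family),
                    mutation_status = status, sex = sex,
                    age = age, eyo = eyo, cdr = cdr,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(an))) {
    sigma_log <- sqrt(log(1 + (an$nc_sd[i] / an$nc_mean[i])^2))
    mu_log <- log(an$nc_mean[i]) - sigma_log^2 / 2
    u_f <- stats::rnorm(spec$n_families, 0, spec$family_sd)
    z <- u_f[family] + stats::rnorm(n, 0, spec$residual_sd) +
      spec$shared_factor_loading * latent
    z <- z + carrier * total_sd *
      hinge_profile(eyo, an$divergence_eyo[i], an$mc_effect[i])
    val <- exp(mu_log + sigma_log * z / total_sd)
    if (an$missing_fraction[i] > 0) {
      val[stats::runif(n) < an$missing_fraction[i]] <- NA_real_
    }
    tab[[an$analyte[i]]] <- val
  }
  tab$ratio_ab4240 <- tab$abeta42 / tab$abeta40
  tab$ratio_ptau_ab42 <- tab$ptau / tab$abeta42

  u_sw <- stats::rnorm(spec$n_families, 0, spec$smallworld_sd / 3)
  sw_hinge <- pmax(0, eyo - spec$smallworld_divergence_eyo)
  tab$small_world <- spec$smallworld_baseline + u_sw[family] +
    stats::rnorm(n, 0, spec$smallworld_sd) -
    carrier * spec$smallworld_decline * sw_hinge
  tab$total_gm_volume <- spec$gm_volume_baseline +
    stats::rnorm(n, 0, spec$gm_volume_sd) -
    carrier * spec$gm_volume_decline * sw_hinge

  gt <- list(divergence_eyo = stats::setNames(an$divergence_eyo, an$analyte),
             mc_effect = stats::setNames(an$mc_effect, an$analyte),
             smallworld_divergence_eyo = spec$smallworld_divergence_eyo,
             smallworld_decline = spec$smallworld_decline,
             family = family, onset_age = onset_age,
             cdr_cutpoints = spec$cdr_cutpoints,
             family_sd = spec$family_sd, residual_sd = spec$residual_sd,
             total_sd = total_sd, seed = seed)
  out <- as_cohort_table(tab)
  attr(out, "ground_truth") <- gt
  out
}

#' Write the generating ground truth of a simulated cohort as JSON
#'
#' @param table A cohort from [simulate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(table, path) {
  gt <- attr(table, "ground_truth")
  if (is.null(gt)) stop("table carries no ground_truth attribute")
  # named vectors as JSON objects, not nameless arrays
  gt <- rapply(gt, function(x) if (is.null(names(x))) x else as.list(x),
               how = "replace")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a minimal association cohort with known per-group slopes
#'
#' Generates standardized predictor/outcome pairs whose true linear slope
#' differs by mutation status, for calibration of the association models
#' (confidence-interval coverage, interaction type-I error). Variables are
#' generated on the standardized scale, so fits need no preprocessing.
#'
#' @param n Number of subjects.
#' @param slope_carrier,slope_noncarrier True standardized slopes (defaults
#'   mirror the strongest axonal-damage association: carrier -0.76,
#'   non-carrier -0.44).
#' @param frac_carrier Fraction of carriers.
#' @param sex_effect Additive outcome shift for males.
#' @param residual_sd Outcome residual sd.
#' @param seed Integer seed.
#' @return A `cohort_table` with columns `mutation_status`, `sex`,
#'   `predictor`, `small_world`.
#' @export
simulate_association_cohort <- function(n = 350, slope_carrier = -0.76,
                                        slope_noncarrier = -0.44,
                                        frac_carrier = 0.6, sex_effect = 0.1,
                                        residual_sd = 0.6, seed = 1L) {
  set.seed(seed)
  carrier <- stats::rbinom(n, 1, frac_carrier) == 1
  sex <- ifelse(stats::rbinom(n, 1, 0.42) == 1, "male", "female")
  x <- stats::rnorm(n)
  slope <- ifelse(carrier, slope_carrier, slope_noncarrier)
  y <- slope * x + sex_effect * (sex == "male") + stats::rnorm(n, 0, residual_sd)
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    mutation_status = ifelse(carrier, "carrier", "non-carrier"),
                    sex = sex, age = stats::runif(n, 25, 60),
                    predictor = x, small_world = y,
                    stringsAsFactors = FALSE)
  as_cohort_table(out)
}
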