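# Synthetic piglet cohorts emulating the study design: four age groups of
# eight male piglets, a single 120 ug sublingual dose and a rich 14-point
# sampling schedule over 24 h with LOQ censoring at 4 pg/mL.

#' Age-group specification for cohort generation
#'
#' @param label group label (e.g. `"8d"`).
#' @param n number of subjects (>= 1).
#' @param bw_mean,bw_sd body weight mean and SD, kg.
#' @param bw_range observed body-weight range `c(min, max)`, kg. Sampling
#'   truncates at this range widened by `range_pad` SDs on each side, so the
#'   target mean/SD are preserved while implausible weights are excluded.
#' @param bsa_mean,bsa_sd body surface area mean and SD, m^2.
#' @param gfr_mean,gfr_sd glomerular filtration rate mean and SD,
#'   mL/min/m^2.
#' @param age_days age in days (used as the continuous `AGE` covariate).
#' @param range_pad widening of the truncation range, in SD units.
#' @return list of class `age_group_spec`.
#' @export
age_group_spec <- function(label, n, bw_mean, bw_sd, bw_range,
                           bsa_mean, bsa_sd, gfr_mean, gfr_sd, age_days,
                           range_pad = 1.5) {
  stopifnot(n >= 1, bw_sd >= 0, bsa_sd >= 0, gfr_sd >= 0,
            length(bw_range) == 2)
  if (bw_range[1] > bw_mean || bw_range[2] < bw_mean)
    stop("bw_range must bracket the mean")
  structure(list(label = label, n = as.integer(n), bw_mean = bw_mean,
                 bw_sd = bw_sd, bw_range = bw_range, bsa_mean = bsa_mean,
                 bsa_sd = bsa_sd, gfr_mean = gfr_mean, gfr_sd = gfr_sd,
                 age_days = age_days, range_pad = range_pad),
            class = "age_group_spec")
}

#' Built-in piglet age-group presets
#'
#' Descriptive statistics of the four study groups (8 days, 4 weeks,
#' 7 weeks, 6 months; n = 8 male piglets each). Two variants of the 7-week
#' body weight circulate in the study report; `"table"` (15.8 +/- 1.98 kg)
#' is the default, `"animals"` gives 13.9 +/- 2.74 kg.
#'
#' @param seven_week which 7-week body-weight variant to use.
#' @return list of four [age_group_spec] objects.
#' @export
piglet_age_groups <- function(seven_week = c("table", "animals")) {
  seven_week <- match.arg(seven_week)
  wk7 <- if (seven_week == "table") c(15.8, 1.98, 14.0, 19.0)
         else c(13.9, 2.74, 9.0, 19.0)
  list(
    age_group_spec("8d",  8, 2.01, 0.43, c(1.54, 2.64),  0.16, 0.02,
                   40.8,  8.62,  8),
    age_group_spec("4w",  8, 10.0, 1.69, c(7.0, 12.0),   0.46, 0.05,
                   67.4,  11.54, 28),
    age_group_spec("7w",  8, wk7[1], wk7[2], wk7[3:4],   0.59, 0.08,
                   106.5, 18.69, 49),
    age_group_spec("6m",  8, 112.9, 9.11, c(100.0, 124.0), 2.42, 0.13,
                   136.3, 13.48, 180))
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  if (lo > mean + 6 * sd || hi < mean - 6 * sd)
    stop("infeasible truncation: range excludes mean +/- 6 SD")
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a virtual cohort
#'
#' Body weight is drawn from a truncated normal per group; BSA and GFR are
#' deterministic allometric functions of the realized body weight
#' (exponents 2/3 and 3/4) times log-normal noise whose variance is
#' calibrated so each group's mean and SD approximate the specification.
#' BSA and GFR are therefore realistically correlated with BW — the
#' interesting regime for covariate selection.
#'
#' @param specs one [age_group_spec] or a list of them (default: the four
#'   study groups).
#' @param seed integer seed; same seed, same table.
#' @return data frame with columns `id`, `group`, `BW` (kg), `BSA` (m^2),
#'   `GFR` (mL/min/m^2), `AGE` (days).
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' table(cohort$group)
#' @export
generate_cohort <- function(specs = piglet_age_groups(), seed = NULL) {
  if (inherits(specs, "age_group_spec")) specs <- list(specs)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(specs, function(sp) {
    pad <- sp$range_pad * sp$bw_sd
    lo <- max(sp$bw_range[1] - pad, 0.1 * sp$bw_mean)
    hi <- sp$bw_range[2] + pad
    bw <- rtruncnorm1(sp$n, sp$bw_mean, sp$bw_sd, lo, hi)
    cv_bw <- sp$bw_sd / sp$bw_mean
    s_bsa <- sqrt(max((sp$bsa_sd / sp$bsa_mean)^2 - (2 / 3 * cv_bw)^2, 1e-4))
    s_gfr <- sqrt(max((sp$gfr_sd / sp$gfr_mean)^2 - (3 / 4 * cv_bw)^2, 1e-4))
    bsa <- sp$bsa_mean * (bw / sp$bw_mean)^(2 / 3) *
      exp(rnorm(sp$n, 0, s_bsa))
    gfr <- sp$gfr_mean * (bw / sp$bw_mean)^(3 / 4) *
      exp(rnorm(sp$n, 0, s_gfr))
    data.frame(group = sp$label, BW = bw, BSA = bsa, GFR = gfr,
               AGE = sp$age_days, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(id = sprintf("S%02d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Study design: dose, schedule and censoring policy
#'
#' Defaults reproduce the study: a single 120 ug (1.2e8 pg) sublingual
#' dose and 14 nominal post-dose samples from 5 min to 24 h, with a
#' pre-dose placeholder at t = 0, LOQ 4 pg/mL.
#'
#' @param dose dose in pg.
#' @param times strictly increasing post-dose sampling times, h.
#' @param loq limit of quantification, pg/mL.
#' @param censor `"drop"` removes below-LOQ observations (as in the
#'   analysis dataset), `"flag"` keeps them with `bloq = 1`, `"none"`
#'   disables censoring.
#' @return list of class `study_design`.
#' @export
study_design <- function(dose = 1.2e8,
                         times = c(5 / 60, 0.25, 0.5, 0.75, 1, 1.5, 2, 3,
                                   4, 6, 8, 10, 12, 24),
                         loq = 4, censor = c("drop", "flag", "none")) {
  censor <- match.arg(censor)
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing and > 0")
  if (dose <= 0) stop("dose must be > 0")
  structure(list(dose = dose, times = times, loq = loq, censor = censor),
            class = "study_design")
}

#' Generate a complete synthetic study
#'
#' Builds the cohort, simulates concentrations under the model, applies the
#' censoring policy, and optionally writes the dataset plus a YAML "truth"
#' sidecar (model parameters, per-subject eta draws and the seed) for
#' parameter-recovery experiments.
#'
#' @param model a [pop_model]; defaults to [reference_model()].
#' @param groups list of [age_group_spec]; default the four study groups.
#' @param design a [study_design()].
#' @param seed integer seed (controls cohort and residual draws).
#' @param path optional basename: writes `<path>.csv` (dataset) and
#'   `<path>_truth.yaml` (sidecar).
#' @return list with `dataset` (a [pk_dataset]), `cohort`, `eta` (matrix of
#'   generating random effects), `model` and `seed`.
#' @examples
#' study <- generate_study(seed = 42)
#' study$dataset
#' @export
generate_study <- function(model = reference_model(),
                           groups = piglet_age_groups(),
                           design = study_design(), seed = NULL,
                           path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_cohort(groups, seed = NULL)
  ds <- simulate_population(model, cohort, design, seed = NULL)
  ds$provenance <- if (is.null(seed)) "generated study" else
    paste0("generated study seed=", seed)
  eta <- attr(ds, "eta")
  if (!is.null(path)) {
    write_pk_dataset(ds, paste0(path, ".csv"))
    yaml::write_yaml(list(
      seed = seed, theta = as.list(model$theta),
      omega = as.list(model$omega), sigma = model$sigma,
      covariates = if (nrow(model$covariates)) model$covariates else NULL,
      bio_scale = model$bio_scale,
      eta = lapply(seq_len(nrow(eta)), function(i) as.list(eta[i, ])),
      subjects = cohort$id,
      design = list(dose = design$dose, times = design$times,
                    loq = design$loq, censor = design$censor)),
      paste0(path, "_truth.yaml"))
  }
  list(dataset = ds, cohort = cohort, eta = eta, model = model, seed = seed)
}
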