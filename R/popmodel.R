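# Hierarchical population layer: fixed effects, centered power covariate
# models, diagonal inter-individual variability, and the log-scale additive
# residual (exponential error on the linear scale).

#' Population pharmacokinetic model specification
#'
#' Fixed effects for the nine structural parameters, a diagonal
#' inter-individual variance matrix (variances of log-scale etas, except
#' `Bio` whose eta acts on the logit scale by default), a residual SD on the
#' log-concentration scale, and a table of centered power covariate effects
#' `theta * (cov/center)^exponent`.
#'
#' @param theta named vector of typical values (units as in
#'   [structural_params()]).
#' @param omega named vector of IIV variances; names must be structural
#'   parameter names; parameters absent or zero carry no random effect.
#' @param sigma residual SD on the log scale (0.228 corresponds to 22.8% CV).
#' @param covariates data frame with columns `param`, `cov`, `exponent`,
#'   `center`, or a list of such rows; `NULL` for none.
#' @param fix_theta,fix_omega character vectors of parameter names whose
#'   theta / IIV variance is fixed (never updated by estimation). Zero
#'   omegas are always fixed.
#' @param fix_sigma logical.
#' @param fix_covariates integer indices of covariate rows with fixed
#'   exponents.
#' @param bio_scale `"logit"` (default; realized fractions stay in (0,1)) or
#'   `"exp"` for an exponential eta on `Bio`.
#' @return object of class `pop_model`.
#' @seealso [reference_model()] for the canonical estimates.
#' @export
pop_model <- function(theta, omega = NULL, sigma = 0.228, covariates = NULL,
                      fix_theta = character(), fix_omega = character(),
                      fix_sigma = FALSE, fix_covariates = integer(),
                      bio_scale = c("logit", "exp")) {
  bio_scale <- match.arg(bio_scale)
  th <- setNames(numeric(9), .PAR_NAMES)
  if (!all(names(theta) %in% .PAR_NAMES))
    stop("unknown theta name(s): ",
         paste(setdiff(names(theta), .PAR_NAMES), collapse = ", "))
  if (!all(.PAR_NAMES %in% names(theta)))
    stop("theta must provide all of: ", paste(.PAR_NAMES, collapse = ", "))
  th[names(theta)] <- theta
  validate_structural_params(th)
  om <- setNames(numeric(9), .PAR_NAMES)
  if (!is.null(omega)) {
    if (!all(names(omega) %in% .PAR_NAMES))
      stop("unknown omega name(s): ",
           paste(setdiff(names(omega), .PAR_NAMES), collapse = ", "))
    if (any(omega < 0)) stop("omega variances must be >= 0")
    om[names(omega)] <- omega
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  cov_df <- normalize_cov_table(covariates)
  if (nrow(cov_df)) {
    if (!all(cov_df$param %in% .PAR_NAMES))
      stop("covariate effect on unknown parameter")
    if (any(cov_df$center <= 0)) stop("covariate centering constant must be > 0")
  }
  structure(list(theta = th, omega = om, sigma = sigma,
                 covariates = cov_df,
                 fix_theta = intersect(fix_theta, .PAR_NAMES),
                 fix_omega = union(intersect(fix_omega, .PAR_NAMES),
                                   .PAR_NAMES[om == 0]),
                 fix_sigma = isTRUE(fix_sigma),
                 fix_covariates = as.integer(fix_covariates),
                 bio_scale = bio_scale),
            class = "pop_model")
}

normalize_cov_table <- function(covariates) {
  if (is.null(covariates))
    return(data.frame(param = character(), cov = character(),
                      exponent = numeric(), center = numeric(),
                      stringsAsFactors = FALSE))
  if (is.data.frame(covariates)) df <- covariates
  else df <- do.call(rbind, lapply(covariates, as.data.frame))
  if (is.null(df$center)) df$center <- 10
  df[c("param", "cov", "exponent", "center")]
}

#' A single centered power covariate effect
#'
#' @param param structural parameter the effect acts on.
#' @param cov covariate column name in the dataset (e.g. `"BW"`).
#' @param exponent power exponent (initial value when estimated).
#' @param center centering constant in the covariate's units (default the
#'   typical 10 kg body weight).
#' @return one-row data frame suitable for `pop_model(covariates = ...)`.
#' @export
covariate_effect <- function(param, cov, exponent = 0, center = 10) {
  data.frame(param = param, cov = cov, exponent = exponent, center = center,
             stringsAsFactors = FALSE)
}

#' Canonical population model of the piglet study
#'
#' The final dual-input two-compartment model with body weight (centered on
#' 10 kg) as a power covariate on CL/F (exponent 1.03) and V1/F (0.691),
#' log-normal IIV on CL, V1, Ka1, V2, D1 and (logit-scale) Bio, the IIV of
#' Q, Ka2 and Tlag fixed to zero, and a 22.8% CV residual.
#'
#' @param covariates include the body-weight effects (default) or strip them
#'   for a covariate-free base model.
#' @return a [pop_model].
#' @examples
#' m <- reference_model()
#' individual_parameters(m, covariates = c(BW = 10))
#' @export
reference_model <- function(covariates = TRUE) {
  pop_model(
    theta = c(CL = 395, V1 = 131, Q = 32, V2 = 436, Ka1 = 0.275,
              Ka2 = 0.399, Bio = 0.86, Tlag = 1, D1 = 0.16),
    omega = c(CL = 0.175, V1 = 0.641, Ka1 = 0.0903, V2 = 0.634,
              D1 = 0.485, Bio = 0.627),
    sigma = 0.228,
    covariates = if (covariates)
      rbind(covariate_effect("CL", "BW", 1.03, 10),
            covariate_effect("V1", "BW", 0.691, 10)))
}

#' @export
print.pop_model <- function(x, ...) {
  cat("pop_model (dual-input two-compartment, log-scale additive residual)\n")
  cat("  theta:", paste(sprintf("%s=%g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  act <- x$omega[x$omega > 0]
  cat("  IIV var:", if (length(act))
    paste(sprintf("%s=%g", names(act), act), collapse = ", ") else "none",
    "| sigma:", x$sigma, "\n")
  if (nrow(x$covariates))
    cat("  covariates:",
        paste(sprintf("%s on %s (exp %g, center %g)", x$covariates$cov,
                      x$covariates$param, x$covariates$exponent,
                      x$covariates$center), collapse = "; "), "\n")
  invisible(x)
}

eta_names <- function(model) .PAR_NAMES[model$omega > 0]

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

# Typical parameters with covariate effects applied (eta = 0), natural scale.
typical_params <- function(model, covariates, subject = NULL) {
  covariates <- as.list(covariates)
  p <- model$theta
  cv <- model$covariates
  for (i in seq_len(nrow(cv))) {
    val <- covariates[[cv$cov[i]]]
    if (is.null(val) || is.na(val))
      stop("missing covariate ", cv$cov[i], " for parameter ", cv$param[i],
           if (!is.null(subject)) paste0(" (subject ", subject, ")") else "")
    mult <- (val / cv$center[i])^cv$exponent[i]
    if (cv$param[i] == "Bio")
      p["Bio"] <- invlogit(logit(p["Bio"]) + cv$exponent[i] *
                             log(val / cv$center[i]))
    else p[cv$param[i]] <- p[cv$param[i]] * mult
  }
  p
}

apply_eta <- function(model, p_typ, eta) {
  en <- eta_names(model)
  stopifnot(length(eta) == length(en))
  for (k in seq_along(en)) {
    nm <- en[k]
    if (nm == "Bio" && model$bio_scale == "logit")
      p_typ["Bio"] <- invlogit(logit(p_typ["Bio"]) + eta[k])
    else p_typ[nm] <- p_typ[nm] * exp(eta[k])
  }
  p_typ
}

#' Realized individual parameters
#'
#' Combines the typical values, the subject's covariates through the
#' centered power models, and a vector of random effects:
#' `theta * (cov/center)^exponent * exp(eta)` for log-normal parameters and
#' a logit-scale shift for `Bio`.
#'
#' @param model a [pop_model].
#' @param covariates named vector/list of the subject's covariate values.
#' @param eta random-effect vector, one entry per parameter with positive
#'   IIV variance, in the order of `names(model$omega[model$omega > 0])`;
#'   defaults to zeros.
#' @param subject optional id used in error messages.
#' @return a [structural_params] vector.
#' @export
individual_parameters <- function(model, covariates, eta = NULL,
                                  subject = NULL) {
  en <- eta_names(model)
  if (is.null(eta)) eta <- numeric(length(en))
  p <- apply_eta(model, typical_params(model, covariates, subject), eta)
  validate_structural_params(p)
  structure(p, class = "structural_params")
}

#' Simulate one subject's observations
#'
#' Draws `eta ~ N(0, Omega)` (unless supplied), builds the individual
#' profile and applies the exponential residual
#' `C_obs = C_pred * exp(eps)`, `eps ~ N(0, sigma^2)`.
#'
#' @param model a [pop_model].
#' @param covariates named covariate vector for the subject.
#' @param times observation times (h, > 0).
#' @param dose dose in pg.
#' @param seed optional integer seed for reproducibility.
#' @param eta optional fixed random-effect vector (bypasses the draw).
#' @return numeric vector of simulated concentrations (pg/mL) with
#'   attributes `eta` and `pred` (the noise-free individual curve).
#' @export
simulate_individual <- function(model, covariates, times, dose,
                                seed = NULL, eta = NULL) {
  if (!is.null(seed)) set.seed(seed)
  en <- eta_names(model)
  if (is.null(eta))
    eta <- rnorm(length(en), 0, sqrt(model$omega[en]))
  p <- individual_parameters(model, covariates, eta)
  pred <- concentration_profile(p, dose, times)
  obs <- pred * exp(rnorm(length(times), 0, model$sigma))
  attr(obs, "eta") <- setNames(eta, en)
  attr(obs, "pred") <- pred
  obs
}

#' Simulate a whole study cohort
#'
#' One record set per subject: a pre-dose placeholder at t = 0 (mdv = 1), a
#' dose record, and one observation per design time. Censoring below the
#' LOQ can flag (`bloq = 1`) or drop the affected records, matching what
#' [apply_loq_filter()] would remove.
#'
#' @param model a [pop_model].
#' @param cohort data frame with column `id` and the covariate columns the
#'   model needs (e.g. from [generate_cohort()]).
#' @param design a [study_design()] list (dose pg, times h, loq, censor).
#' @param seed optional integer seed.
#' @return a [pk_dataset]; the matrix of eta draws is attached as
#'   `attr(, "eta")`.
#' @export
simulate_population <- function(model, cohort, design, seed = NULL) {
  if (!nrow(cohort)) stop("empty cohort")
  if (!is.null(seed)) set.seed(seed)
  en <- eta_names(model)
  etas <- matrix(rnorm(nrow(cohort) * length(en)), nrow(cohort),
                 length(en), byrow = TRUE)
  etas <- sweep(etas, 2, sqrt(model$omega[en]), `*`)
  dimnames(etas) <- list(cohort$id, en)
  covcols <- setdiff(names(cohort), "id")
  recs <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    covs <- as.list(cohort[i, covcols, drop = FALSE])
    obs <- simulate_individual(model, covs, design$times, design$dose,
                               eta = etas[i, ])
    sub <- data.frame(
      id = cohort$id[i],
      time = c(0, 0, design$times),
      amt = c(NA, design$dose, rep(NA, length(design$times))),
      dv = c(NA, NA, as.numeric(obs)),
      evid = c(0L, 1L, rep(0L, length(design$times))),
      mdv = c(1L, 1L, rep(0L, length(design$times))),
      stringsAsFactors = FALSE)
    sub$bloq <- as.integer(sub$evid == 0L & sub$mdv == 0L &
                             !is.na(sub$dv) & sub$dv < design$loq)
    for (cv in covcols) sub[[cv]] <- cohort[[cv]][i]
    recs[[i]] <- sub
  }
  d <- do.call(rbind, recs)
  if (identical(design$censor, "drop"))
    d <- d[!(d$bloq == 1L), , drop = FALSE]
  ds <- pk_dataset(d, loq = design$loq,
                   provenance = if (is.null(seed)) "simulated" else
                     paste0("simulated seed=", seed))
  attr(ds, "eta") <- etas
  ds
}

#' Serialize a population model to YAML
#' @param model a [pop_model].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(model, path) {
  yaml::write_yaml(list(
    theta = as.list(model$theta), omega = as.list(model$omega),
    sigma = model$sigma,
    covariates = if (nrow(model$covariates)) model$covariates else NULL,
    fix_theta = model$fix_theta, fix_omega = model$fix_omega,
    fix_sigma = model$fix_sigma, fix_covariates = model$fix_covariates,
    bio_scale = model$bio_scale), path)
  invisible(path)
}

#' Read a population model from YAML
#' @param path file written by [write_model_yaml()].
#' @return a [pop_model].
#' @export
read_model_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  covs <- if (!is.null(y$covariates)) as.data.frame(y$covariates) else NULL
  om <- unlist(y$omega)
  pop_model(theta = unlist(y$theta), omega = om[om > 0], sigma = y$sigma,
            covariates = covs,
            fix_theta = as.character(unlist(y$fix_theta)),
            fix_omega = as.character(unlist(y$fix_omega)),
            fix_sigma = isTRUE(y$fix_sigma),
            fix_covariates = as.integer(unlist(y$fix_covariates)),
            bio_scale = if (is.null(y$bio_scale)) "logit" else y$bio_scale)
}
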