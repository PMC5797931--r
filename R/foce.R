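# First-order conditional estimation.
#
# The residual is additive on the log-concentration scale, so the FOCE
# approximation carries no eta-interaction term in the residual variance:
# for each subject the conditional mode eta_hat of the joint density is
# located by a damped Gauss-Newton search, the model is linearized in eta
# around eta_hat, and the subject's -2 log marginal likelihood becomes
#   n log(2 pi) + log|Sigma| + r' Sigma^-1 r,
#   Sigma = J Omega J' + sigma^2 I,  r = y - f(eta_hat) + J eta_hat.
# The full 2 pi constant is always included, so OFV differences between
# nested models are well defined and the value matches exact-likelihood
# oracles on linear-Gaussian models.

# ---- estimation-scale parameter packing -----------------------------------

pack_map <- function(model) {
  rows <- list()
  for (nm in setdiff(.PAR_NAMES, model$fix_theta))
    rows[[length(rows) + 1]] <- data.frame(
      kind = "theta", name = nm, label = nm,
      transform = if (nm == "Bio") "logit" else "log",
      stringsAsFactors = FALSE)
  cv <- model$covariates
  for (i in setdiff(seq_len(nrow(cv)), model$fix_covariates))
    rows[[length(rows) + 1]] <- data.frame(
      kind = "cov", name = as.character(i),
      label = paste0(cv$cov[i], "_on_", cv$param[i]),
      transform = "identity", stringsAsFactors = FALSE)
  for (nm in setdiff(.PAR_NAMES[model$omega > 0], model$fix_omega))
    rows[[length(rows) + 1]] <- data.frame(
      kind = "omega", name = nm, label = paste0("IIV_", nm),
      transform = "log", stringsAsFactors = FALSE)
  if (!model$fix_sigma)
    rows[[length(rows) + 1]] <- data.frame(
      kind = "sigma", name = "sigma", label = "sigma",
      transform = "log", stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

to_est_scale <- function(value, transform) {
  switch(transform, log = log(value), logit = logit(value),
         identity = value)
}
from_est_scale <- function(x, transform) {
  switch(transform, log = exp(x), logit = invlogit(x), identity = x)
}
# derivative of reporting value w.r.t. the estimation-scale coordinate
dreport_dest <- function(x, transform) {
  switch(transform, log = exp(x),
         logit = invlogit(x) * (1 - invlogit(x)), identity = 1)
}

pack_params <- function(model, map = pack_map(model)) {
  vapply(seq_len(nrow(map)), function(i) {
    v <- switch(map$kind[i],
                theta = model$theta[[map$name[i]]],
                cov = model$covariates$exponent[as.integer(map$name[i])],
                omega = model$omega[[map$name[i]]],
                sigma = model$sigma)
    to_est_scale(v, map$transform[i])
  }, numeric(1))
}

unpack_params <- function(model, est, map = pack_map(model)) {
  for (i in seq_len(nrow(map))) {
    v <- from_est_scale(est[i], map$transform[i])
    switch(map$kind[i],
           theta = { model$theta[[map$name[i]]] <- v },
           cov = { model$covariates$exponent[as.integer(map$name[i])] <- v },
           omega = { model$omega[[map$name[i]]] <- v },
           sigma = { model$sigma <- v })
  }
  model
}

# ---- per-subject data ------------------------------------------------------

split_subjects <- function(ds) {
  if (!ds$log_scale)
    stop("dataset must be log-transformed (see log_transform_obs)")
  d <- ds$data
  covcols <- setdiff(names(d), c(.MANDATORY_COLS, "bloq"))
  lapply(split(d, d$id), function(sub) {
    dose_rows <- sub[sub$evid == 1L, , drop = FALSE]
    obs <- sub[sub$evid == 0L & sub$mdv == 0L, , drop = FALSE]
    list(id = sub$id[1], dose = dose_rows$amt[1], times = obs$time,
         y = obs$dv, covariates = as.list(sub[1, covcols, drop = FALSE]))
  })
}

# ---- objective -------------------------------------------------------------

.PENALTY <- 1e10

# fast path: per-subject inner step in C++ for the structural PK model
make_ofv <- function(model0, ds) {
  subjects <- split_subjects(ds)
  map <- pack_map(model0)
  cache <- new.env(parent = emptyenv())
  en <- eta_names(model0)  # eta structure is fixed for the whole fit
  eta_idx <- match(.PAR_NAMES, en, nomatch = 0L) - 1L
  for (s in subjects)  # covariate availability is structural: check once
    typical_params(model0, s$covariates, s$id)
  fn <- function(est, details = FALSE) {
    model <- unpack_params(model0, est, map)
    omega <- unname(model$omega[en])
    # extreme estimation-scale values can overflow/underflow; such points
    # get a flat finite penalty so the line search backs off
    if (any(!is.finite(omega)) || any(omega <= 0) ||
        !is.finite(model$sigma) || model$sigma <= 0 ||
        any(!is.finite(model$theta)))
      return(if (details) list(ofv = .PENALTY, subjects = NULL) else
        .PENALTY)
    bio_logit <- model$bio_scale == "logit"
    total <- 0
    det_list <- if (details) vector("list", length(subjects))
    for (i in seq_along(subjects)) {
      s <- subjects[[i]]
      p_typ <- tryCatch(typical_params(model, s$covariates, s$id),
                        error = function(e) NULL)
      if (is.null(p_typ) || any(!is.finite(p_typ)) ||
          any(p_typ[setdiff(.PAR_NAMES, "Bio")] <= 0) ||
          p_typ[["Bio"]] <= 0 || p_typ[["Bio"]] >= 1) {
        total <- total + .PENALTY
        next
      }
      key <- paste0("s", i)
      eta0 <- if (!is.null(cache[[key]])) cache[[key]] else
        numeric(length(en))
      r <- .foce_inner_cpp(unname(p_typ), eta_idx, bio_logit, s$y, s$times,
                           s$dose, omega, model$sigma, eta0)
      if (!isTRUE(r$ok)) { total <- total + .PENALTY; next }
      if (length(en)) cache[[key]] <- r$eta
      total <- total + r$ofv
      if (details) det_list[[i]] <- r
    }
    if (details) list(ofv = total, subjects = det_list) else total
  }
  attr(fn, "map") <- map
  attr(fn, "subjects") <- subjects
  fn
}

#' FOCE objective function value
#'
#' -2 times the FOCE-approximate marginal log-likelihood of a
#' log-transformed, LOQ-filtered dataset under a population model, with the
#' full `n log(2 pi)` constant included.
#'
#' @param model a [pop_model].
#' @param ds a log-scale [pk_dataset].
#' @param at optional estimation-scale parameter vector at which to
#'   evaluate (advanced; defaults to the model's own values).
#' @return the OFV (scalar).
#' @export
conditional_objective <- function(model, ds, at = NULL) {
  fn <- make_ofv(model, ds)
  if (is.null(at)) at <- pack_params(model)
  fn(at)
}

# ---- generic single-subject engine (reference implementation) -------------

#' FOCE contribution of one subject for an arbitrary model function
#'
#' Reference implementation of the inner step used by the estimation
#' engine, for any prediction function `f(eta)`: damped Gauss-Newton search
#' for the conditional mode with a forward-difference Jacobian, then the
#' FOCE-linearized -2 log marginal likelihood. Exact on models linear
#' in `eta`.
#'
#' @param f function mapping an eta vector to predictions (same scale and
#'   length as `y`).
#' @param y observation vector (log scale for concentration models).
#' @param omega vector of positive IIV variances (diagonal Omega); may be
#'   empty for a fixed-effects model.
#' @param sigma residual SD.
#' @param eta_start starting value for the mode search.
#' @return list with `ofv`, `eta` (conditional mode), `f` (predictions at
#'   the mode) and `J` (Jacobian at the mode).
#' @export
foce_subject_ofv <- function(f, y, omega, sigma, eta_start = NULL) {
  n <- length(y); sig2 <- sigma^2; ne <- length(omega)
  if (ne == 0) {
    r <- y - f(numeric(0))
    return(list(ofv = n * log(2 * pi * sig2) + sum(r^2) / sig2,
                eta = numeric(0), f = f(numeric(0)), J = NULL))
  }
  if (any(omega <= 0)) stop("omega entries must be > 0 (drop fixed zeros)")
  oinv <- 1 / omega
  eta <- if (is.null(eta_start)) numeric(ne) else eta_start
  h <- 1e-5
  qval <- function(e, fe) sum((y - fe)^2) / sig2 + sum(e^2 * oinv)
  fe <- f(eta)
  q <- qval(eta, fe)
  jac <- function(e, fe) {
    J <- matrix(0, n, ne)
    for (k in seq_len(ne)) {
      e2 <- e; e2[k] <- e2[k] + h
      J[, k] <- (f(e2) - fe) / h
    }
    J
  }
  for (iter in 1:50) {
    J <- jac(eta, fe)
    r <- y - fe
    g <- -crossprod(J, r) / sig2 + oinv * eta
    if (max(abs(2 * g)) < 1e-6) break
    H <- crossprod(J) / sig2 + diag(oinv, ne)
    d <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(d)) break
    alpha <- 1; improved <- FALSE
    for (ls in 1:25) {
      e_try <- eta + alpha * as.numeric(d)
      f_try <- tryCatch(f(e_try), error = function(e) rep(NA_real_, n))
      if (all(is.finite(f_try))) {
        q_try <- qval(e_try, f_try)
        if (q_try <= q + 1e-12) {
          no_move <- abs(q - q_try) < 1e-10 * (abs(q) + 1) && ls == 1
          eta <- e_try; fe <- f_try; q <- q_try; improved <- TRUE
          if (no_move) iter <- 51
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!improved || iter > 50) break
  }
  J <- jac(eta, fe)
  Sig <- J %*% (omega * t(J)); diag(Sig) <- diag(Sig) + sig2
  r <- y - fe + J %*% eta
  L <- chol(Sig)
  z <- backsolve(L, r, transpose = TRUE)
  list(ofv = n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2),
       eta = as.numeric(eta), f = fe, J = J)
}

# ---- outer optimization ----------------------------------------------------

central_grad <- function(fn, x, rel_step = 1e-4) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- rel_step * max(abs(x[i]), 1)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}

#' Fit a population model by FOCE
#'
#' Minimizes the conditional objective over all non-fixed parameters on an
#' unconstrained estimation scale (log for positive parameters, logit for
#' `Bio`, identity for covariate exponents), using BFGS with central
#' finite-difference gradients (relative step 1e-4). The covariance step
#' inverts the Hessian of OFV/2 and maps standard errors to the reporting
#' scale by the delta method; random-effect variances are reported as
#' variances with SD-scale relative standard errors.
#'
#' @param model a [pop_model] defining structure, fixes and starting
#'   values (or see `init`).
#' @param ds a log-transformed, LOQ-filtered [pk_dataset].
#' @param init optional [pop_model] carrying alternative starting values.
#' @param covariance `"hessian"` (default) or `"none"` to skip the step.
#' @param control list: `maxit` (default 300), `reltol` (1e-9),
#'   `grad_step` (1e-4).
#' @return object of class `fit_result`: final model, `ofv`, `aic`,
#'   estimate table with SE/RSE, covariance and correlation matrices,
#'   condition number, EBEs, shrinkage, convergence report.
#' @export
fit_foce <- function(model, ds, init = NULL,
                     covariance = c("hessian", "none"), control = list()) {
  covariance <- match.arg(covariance)
  ctl <- modifyList(list(maxit = 300, reltol = 1e-9, grad_step = 1e-4,
                         restarts = 3, grad_tol = 0.5), control)
  fn <- make_ofv(model, ds)
  map <- attr(fn, "map")
  subjects <- attr(fn, "subjects")
  if (any(model$omega[setdiff(.PAR_NAMES, model$fix_omega)] > 0) &&
      length(subjects) < 2)
    stop("at least 2 subjects are required to estimate IIV")
  est0 <- pack_params(if (is.null(init)) model else init, map)
  gr <- function(x) central_grad(fn, x, ctl$grad_step)
  # BFGS with restarts: quasi-Newton curvature resets help on surfaces with
  # mild non-smoothness (absorption lag/duration kinks at sampling times)
  opt <- optim(est0, fn, gr, method = "BFGS",
               control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  for (r in seq_len(ctl$restarts)) {
    gn <- max(abs(gr(opt$par)))
    if (gn < ctl$grad_tol) break
    opt2 <- optim(opt$par, fn, gr, method = "BFGS",
                  control = list(maxit = ctl$maxit, reltol = ctl$reltol))
    if (opt2$value > opt$value - 1e-7 * (abs(opt$value) + 1)) {
      if (opt2$value < opt$value) opt <- opt2
      break
    }
    opt <- opt2
  }
  status <- if (opt$convergence == 0) "converged" else
    paste0("not converged (optim code ", opt$convergence, ")")
  final <- unpack_params(model, opt$par, map)
  npar <- length(opt$par)
  # report a cache-independent OFV at the final estimates
  ofv <- conditional_objective(final, ds)
  grad_final <- gr(opt$par)

  est_rep <- vapply(seq_len(nrow(map)), function(i)
    from_est_scale(opt$par[i], map$transform[i]), numeric(1))
  tab <- data.frame(parameter = map$label, kind = map$kind,
                    estimate = est_rep, se = NA_real_, rse = NA_real_,
                    stringsAsFactors = FALSE)
  cov_rep <- cor_mat <- NULL
  cn <- NA_real_
  if (covariance == "hessian" && opt$convergence == 0) {
    H <- tryCatch(
      optimHess(opt$par, function(x) fn(x) / 2, function(x) gr(x) / 2),
      error = function(e) NULL)
    cov_est <- if (!is.null(H))
      tryCatch(solve(H), error = function(e) NULL) else NULL
    if (is.null(cov_est) || any(!is.finite(cov_est)) ||
        any(diag(cov_est) <= 0)) {
      warning("covariance step failed (singular or non-PD Hessian); ",
              "standard errors not available")
    } else {
      D <- diag(vapply(seq_len(nrow(map)), function(i)
        dreport_dest(opt$par[i], map$transform[i]), numeric(1)),
        nrow(map))
      cov_rep <- D %*% cov_est %*% D
      dimnames(cov_rep) <- list(map$label, map$label)
      tab$se <- sqrt(diag(cov_rep))
      tab$rse <- rse_percent(tab$estimate, tab$se,
                             ifelse(tab$kind == "omega", "omega",
                                    ifelse(tab$kind == "sigma", "sigma",
                                           "fixed")))
      cor_mat <- cov2cor_safe(cov_rep)
      cn <- condition_number(cor_mat)$cn
    }
  }

  det <- fn(opt$par, details = TRUE)
  en <- eta_names(final)
  ebes <- matrix(0, length(subjects), length(en),
                 dimnames = list(vapply(subjects, `[[`, "", "id"), en))
  for (i in seq_along(subjects))
    if (length(en)) ebes[i, ] <- det$subjects[[i]]$eta
  shr <- shrinkage_pct(ebes, final$omega[en])

  structure(list(model = final, ofv = ofv, aic = ofv + 2 * npar,
                 npar = npar, estimates = tab, cov = cov_rep,
                 cor = cor_mat, condition_number = cn,
                 ebes = ebes, shrinkage = shr,
                 convergence = list(status = status,
                                    counts = opt$counts,
                                    grad_norm = max(abs(grad_final))),
                 n_subjects = length(subjects),
                 n_obs = sum(vapply(subjects, function(s) length(s$y),
                                    numeric(1))),
                 map = map, est = opt$par),
            class = "fit_result")
}

cov2cor_safe <- function(m) {
  s <- sqrt(diag(m))
  m / tcrossprod(s)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("FOCE fit:", x$convergence$status, "| OFV", round(x$ofv, 3),
      "| AIC", round(x$aic, 3), "\n")
  cat("  subjects:", x$n_subjects, "| observations:", x$n_obs,
      "| estimated parameters:", x$npar, "\n")
  if (!is.na(x$condition_number))
    cat("  condition number:", signif(x$condition_number, 4), "\n")
  print(transform(x$estimates, estimate = signif(estimate, 4),
                  se = signif(se, 3), rse = round(rse, 2)),
        row.names = FALSE)
  invisible(x)
}

# ---- posthoc step, shrinkage, reporting ------------------------------------

#' Empirical Bayes estimates (posthoc step)
#'
#' Conditional modes of the random effects per subject at fixed population
#' parameters, with the realized individual parameters attached.
#'
#' @param object a `fit_result` or a [pop_model].
#' @param ds a log-scale [pk_dataset].
#' @return list with `eta` (subjects x etas matrix), `params` (named list
#'   of [structural_params]) and `table` (data frame of both).
#' @export
compute_ebes <- function(object, ds) {
  model <- if (inherits(object, "fit_result")) object$model else object
  fn <- make_ofv(model, ds)
  det <- fn(pack_params(model), details = TRUE)
  subjects <- attr(fn, "subjects")
  en <- eta_names(model)
  eta <- matrix(0, length(subjects), length(en),
                dimnames = list(vapply(subjects, `[[`, "", "id"), en))
  params <- vector("list", length(subjects))
  names(params) <- rownames(eta)
  for (i in seq_along(subjects)) {
    if (length(en)) eta[i, ] <- det$subjects[[i]]$eta
    params[[i]] <- individual_parameters(model, subjects[[i]]$covariates,
                                         eta[i, ], subjects[[i]]$id)
  }
  tabs <- do.call(rbind, lapply(params, function(p)
    as.data.frame(as.list(unclass(p)))))
  tab <- cbind(data.frame(id = rownames(eta), stringsAsFactors = FALSE),
               tabs, eta)
  rownames(tab) <- NULL
  list(eta = eta, params = params, table = tab)
}

#' Eta shrinkage
#'
#' `100 * (1 - SD(eta_hat) / omega_sd)` per IIV element, with the sample
#' standard deviation (n - 1 denominator). 100% means the EBEs carry no
#' individual information; below 30% is conventionally acceptable.
#'
#' @param ebes matrix of EBEs (subjects x etas) with column names.
#' @param omega named vector of IIV variances for those columns.
#' @return named vector of shrinkage percentages; `NA` where the variance
#'   is fixed to zero.
#' @export
shrinkage_pct <- function(ebes, omega) {
  out <- setNames(rep(NA_real_, length(omega)), names(omega))
  for (nm in names(omega)) {
    if (omega[[nm]] > 0 && nm %in% colnames(ebes) && nrow(ebes) >= 2)
      out[nm] <- 100 * (1 - sd(ebes[, nm]) / sqrt(omega[[nm]]))
  }
  out
}

#' Relative standard errors by reporting convention
#'
#' Fixed effects: `100 * SE / estimate`. Random-effect variances (reported
#' as variances): `100 * SE / (2 * estimate)`, i.e. the SD-scale RSE by the
#' delta method. Residual SD: `100 * SE / estimate`.
#'
#' @param estimate,se numeric vectors on the reporting scale.
#' @param type `"fixed"`, `"omega"` or `"sigma"` (recycled).
#' @return RSE in percent; `NA` with a warning for zero estimates.
#' @examples
#' rse_percent(395, 31.8, "fixed")    # 8.05
#' rse_percent(0.175, 0.0462, "omega") # 13.2
#' @export
rse_percent <- function(estimate, se, type = "fixed") {
  type <- rep(type, length.out = length(estimate))
  out <- ifelse(type == "omega", 100 * se / (2 * estimate),
                100 * se / estimate)
  zero <- !is.na(estimate) & estimate == 0
  if (any(zero & !is.na(se) & se > 0)) {
    warning("RSE undefined for zero estimate")
    out[zero & se > 0] <- NA_real_
  }
  out[zero & !is.na(se) & se == 0] <- 0
  out
}

#' Parameter precision table of a fit
#'
#' @param fit a `fit_result` whose covariance step succeeded.
#' @return data frame `parameter`, `kind`, `estimate`, `se`, `rse`
#'   (percent), plus `shrinkage` for IIV rows.
#' @export
rse_table <- function(fit) {
  if (all(is.na(fit$estimates$se)))
    stop("covariance step unavailable; no standard errors")
  tab <- fit$estimates
  tab$shrinkage <- NA_real_
  iiv <- tab$kind == "omega"
  tab$shrinkage[iiv] <- fit$shrinkage[sub("^IIV_", "", tab$parameter[iiv])]
  tab
}

#' Condition number of an estimate correlation matrix
#'
#' Ratio of the largest to the smallest eigenvalue; values below the
#' threshold (default 1000) are conventionally acceptable.
#'
#' @param m a correlation (or covariance, converted internally) matrix.
#' @param threshold acceptability cut-off.
#' @return list with `cn` and logical `acceptable`.
#' @export
condition_number <- function(m, threshold = 1000) {
  if (!isTRUE(all.equal(unname(diag(m)), rep(1, nrow(m)), tolerance = 1e-8)))
    m <- cov2cor_safe(m)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    warning("correlation matrix not positive definite; condition number infinite")
    return(list(cn = Inf, acceptable = FALSE))
  }
  cn <- max(ev) / min(ev)
  list(cn = cn, acceptable = cn < threshold)
}

#' Chi-square OFV drop thresholds for covariate testing
#'
#' @param p_forward,p_backward significance levels (df = 1) for forward
#'   inclusion and backward retention.
#' @return named vector with the corresponding OFV-difference thresholds
#'   (6.635 and 10.828 at the defaults).
#' @export
scm_thresholds <- function(p_forward = 0.01, p_backward = 0.001) {
  c(forward = qchisq(1 - p_forward, df = 1),
    backward = qchisq(1 - p_backward, df = 1))
}

#' Export a fit result
#'
#' Writes a flat delimited parameter table (`<path>.csv`) and a YAML
#' summary (`<path>.yaml`) with OFV, AIC, condition number, convergence
#' report and shrinkage.
#'
#' @param fit a `fit_result`.
#' @param path output basename.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  tab <- fit$estimates
  iiv <- tab$kind == "omega"
  tab$shrinkage <- NA_real_
  tab$shrinkage[iiv] <- fit$shrinkage[sub("^IIV_", "", tab$parameter[iiv])]
  write.csv(tab, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(ofv = fit$ofv, aic = fit$aic, npar = fit$npar,
                        condition_number = fit$condition_number,
                        convergence = fit$convergence,
                        shrinkage = as.list(fit$shrinkage),
                        n_subjects = fit$n_subjects, n_obs = fit$n_obs),
                   paste0(path, ".yaml"))
  invisible(path)
}
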