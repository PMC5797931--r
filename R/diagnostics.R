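# Goodness-of-fit quantities and the visual predictive check.
#
# CWRES uses the FOCE linearization around each subject's conditional mode:
# with J the Jacobian of the log-scale predictions in eta at eta_hat, the
# marginal mean is f(eta_hat) - J eta_hat and the covariance
# J Omega J' + sigma^2 I; CWRES is the inverse matrix square root of that
# covariance applied to the centered observations. Everything is computed
# on the log-concentration (estimation) scale.

subject_pred_fn <- function(model, s) {
  p_typ <- typical_params(model, s$covariates, s$id)
  function(eta) {
    conc <- concentration_profile(apply_eta(model, p_typ, eta), s$dose,
                                  s$times)
    if (any(conc <= 0)) stop("non-positive prediction for subject ", s$id)
    log(conc)
  }
}

fd_jacobian <- function(f, eta, f0 = f(eta), h = 1e-5) {
  J <- matrix(0, length(f0), length(eta))
  for (k in seq_along(eta)) {
    e2 <- eta; e2[k] <- e2[k] + h
    J[, k] <- (f(e2) - f0) / h
  }
  J
}

inv_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) <= 0) stop("singular covariance")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' FOCE-linearized conditional weighted residuals
#'
#' The residual transform underlying [cwres()], usable for any model with
#' predictions linearized in the random effects: with marginal mean
#' `f_hat - J eta` and covariance `J Omega J' + sigma^2 I`, returns the
#' inverse-matrix-square-root-whitened residuals of one subject. For a
#' correctly specified model that is linear in `eta` these are exactly
#' standard normal.
#'
#' @param y observations (estimation scale).
#' @param f_hat predictions at the conditional mode `eta`.
#' @param J Jacobian of the predictions in `eta` at the mode.
#' @param eta the conditional mode.
#' @param omega vector of IIV variances.
#' @param sigma residual SD.
#' @return vector of whitened residuals.
#' @export
cwres_transform <- function(y, f_hat, J, eta, omega, sigma) {
  if (!length(eta)) return((y - f_hat) / sigma)
  Sig <- J %*% (omega * t(J))
  diag(Sig) <- diag(Sig) + sigma^2
  W <- inv_sqrt(Sig)
  as.numeric(W %*% (y - (f_hat - J %*% eta)))
}

#' Conditional weighted residuals
#'
#' @param fit a `fit_result` (or a [pop_model], in which case the EBEs are
#'   computed at its parameter values).
#' @param ds the log-scale [pk_dataset] that was fitted.
#' @return numeric vector of CWRES, one per retained observation, in
#'   dataset order; subject ids and times attached as attributes.
#' @export
cwres <- function(fit, ds) {
  g <- gof_table(fit, ds)
  structure(g$cwres, id = g$id, time = g$time)
}

#' Goodness-of-fit table
#'
#' Per retained observation: the observation, the population prediction
#' PRED (eta = 0), the individual prediction IPRED (eta = EBE), CWRES, time
#' after dose and subject id. Predictions are on the log scale, matching
#' the estimation scale; `exp()` recovers concentrations.
#'
#' @inheritParams cwres
#' @return data frame with columns `id`, `time`, `obs`, `pred`, `ipred`,
#'   `cwres`.
#' @export
gof_table <- function(fit, ds) {
  model <- if (inherits(fit, "fit_result")) fit$model else fit
  eb <- compute_ebes(model, ds)
  fn <- make_ofv(model, ds)
  subjects <- attr(fn, "subjects")
  en <- eta_names(model)
  omega <- unname(model$omega[en])
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    if (!length(s$y)) next  # fully censored subject: no GOF rows
    f <- subject_pred_fn(model, s)
    eta <- if (length(en)) eb$eta[s$id, ] else numeric(0)
    ipred <- f(eta)
    pred <- f(numeric(length(en)))
    J <- if (length(en)) fd_jacobian(f, eta, ipred) else NULL
    res <- tryCatch(
      cwres_transform(s$y, ipred, J, eta, omega, model$sigma),
      error = function(e) stop("singular FOCE covariance for subject ",
                               s$id))
    out[[i]] <- data.frame(id = s$id, time = s$times, obs = s$y,
                           pred = pred, ipred = ipred, cwres = res,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Visual predictive check table
#'
#' Simulates replicate datasets under the model with the original design
#' (each subject's covariates, dose and retained nominal sampling times),
#' optionally re-applies the LOQ exclusion to the simulated observations,
#' and summarizes, per nominal time: the observed percentiles, the median
#' of each simulated percentile across replicates, and its confidence band.
#' Defaults follow the study configuration: 1,000 simulations, the
#' 5th/50th/95th percentiles (an inter-percentile range of 90%), and 95%
#' confidence intervals. No smoothing is applied; plotting is left to the
#' consumer.
#'
#' @param object a `fit_result` or [pop_model].
#' @param ds the [pk_dataset] supplying design and observations (linear or
#'   log scale; log-scale observations are exponentiated for summarising).
#' @param nsim number of simulated replicates (>= 100).
#' @param percentiles percentiles to track, in percent.
#' @param ci confidence level of the simulated-percentile bands.
#' @param seed integer seed.
#' @param loq_filter apply the dataset's LOQ exclusion rule to simulated
#'   observations before computing percentiles (mirrors the analysis-set
#'   construction).
#' @return data frame of class `vpc_table`: `time`, `n_obs`, observed
#'   percentiles `obs_p*`, and per percentile the simulated median
#'   `sim_p*_md` and band `sim_p*_lo`/`sim_p*_hi`; `nsim` as attribute.
#' @export
vpc <- function(object, ds, nsim = 1000, percentiles = c(5, 50, 95),
                ci = 0.95, seed = NULL, loq_filter = TRUE) {
  model <- if (inherits(object, "fit_result")) object$model else object
  if (nsim < 100) stop("nsim must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  percentiles <- sort(percentiles)
  d <- ds$data
  obs <- d[d$evid == 0L & d$mdv == 0L, , drop = FALSE]
  yobs <- if (ds$log_scale) exp(obs$dv) else obs$dv
  times <- obs$time
  nominal <- sort(unique(times))
  if (!all(times %in% nominal)) stop("times not alignable to nominal schedule")
  covcols <- setdiff(names(d), c(.MANDATORY_COLS, "bloq"))
  sub_ids <- unique(d$id)
  en <- eta_names(model)

  # per-subject design and noise-free predicted basis
  subj <- lapply(sub_ids, function(sid) {
    rows <- d[d$id == sid, , drop = FALSE]
    list(id = sid, times = rows$time[rows$evid == 0L & rows$mdv == 0L],
         dose = rows$amt[rows$evid == 1L][1],
         covs = as.list(rows[1, covcols, drop = FALSE]))
  })

  pct_by_time <- function(tv, yv) {
    vapply(nominal, function(tm) {
      sel <- tv == tm
      if (!any(sel)) return(rep(NA_real_, length(percentiles)))
      quantile(yv[sel], percentiles / 100, names = FALSE)
    }, numeric(length(percentiles)))
  }
  obs_pct <- pct_by_time(times, yobs)

  sims <- array(NA_real_, c(length(percentiles), length(nominal), nsim))
  for (r in seq_len(nsim)) {
    tv <- numeric(0); yv <- numeric(0)
    for (s in subj) {
      eta <- rnorm(length(en), 0, sqrt(model$omega[en]))
      p <- individual_parameters(model, s$covs, eta)
      conc <- concentration_profile(p, s$dose, s$times) *
        exp(rnorm(length(s$times), 0, model$sigma))
      keep <- if (loq_filter) conc >= ds$loq else rep(TRUE, length(conc))
      tv <- c(tv, s$times[keep]); yv <- c(yv, conc[keep])
    }
    sims[, , r] <- pct_by_time(tv, yv)
  }
  alpha <- (1 - ci) / 2
  out <- data.frame(time = nominal,
                    n_obs = vapply(nominal, function(tm) sum(times == tm),
                                   numeric(1)))
  for (k in seq_along(percentiles)) {
    p <- percentiles[k]
    out[[paste0("obs_p", p)]] <- obs_pct[k, ]
    out[[paste0("sim_p", p, "_md")]] <-
      apply(sims[k, , , drop = FALSE], 2, median, na.rm = TRUE)
    out[[paste0("sim_p", p, "_lo")]] <-
      apply(sims[k, , , drop = FALSE], 2, quantile, probs = alpha,
            na.rm = TRUE)
    out[[paste0("sim_p", p, "_hi")]] <-
      apply(sims[k, , , drop = FALSE], 2, quantile, probs = 1 - alpha,
            na.rm = TRUE)
  }
  attr(out, "nsim") <- nsim
  attr(out, "percentiles") <- percentiles
  class(out) <- c("vpc_table", "data.frame")
  out
}
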