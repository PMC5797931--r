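# Stepwise covariate modeling: forward inclusion / backward elimination of
# centered power covariate effects, judged by OFV drops against chi-square
# (df = 1) thresholds — 6.635 (p < 0.01) forward, 10.828 (p < 0.001) for
# backward retention.

#' A covariate candidate for stepwise selection
#'
#' @param param target structural parameter (e.g. `"CL"`).
#' @param cov covariate column (e.g. `"BW"`, `"GFR"`, `"AGE"`, `"BSA"`).
#' @param center centering value in the covariate's units.
#' @return one-row data frame (class `covariate_candidate`).
#' @export
covariate_candidate <- function(param, cov, center = 10) {
  structure(data.frame(param = param, cov = cov, center = center,
                       stringsAsFactors = FALSE),
            class = c("covariate_candidate", "data.frame"))
}

#' Default candidate scope of the study
#'
#' Continuous covariates BW, BSA, AGE and GFR on clearance and central
#' volume (extendable to the absorption-related parameters `Ka1`, `Bio`,
#' `D1`). Centering: BW 10 kg; other covariates at their 4-week typical
#' values (BSA 0.46 m^2, GFR 67.4 mL/min/m^2, AGE 28 d).
#'
#' @param params target parameters to scan.
#' @param covs covariate columns to scan.
#' @return list of [covariate_candidate] rows.
#' @export
default_candidates <- function(params = c("CL", "V1"),
                               covs = c("BW", "BSA", "AGE", "GFR")) {
  centers <- c(BW = 10, BSA = 0.46, GFR = 67.4, AGE = 28)
  out <- list()
  for (p in params) for (cv in covs)
    out[[length(out) + 1]] <- covariate_candidate(p, cv,
                                                  center = centers[[cv]])
  out
}

add_candidate <- function(model, cand, exponent = 0) {
  model$covariates <- rbind(model$covariates,
                            covariate_effect(cand$param, cand$cov,
                                             exponent, cand$center))
  model
}

drop_covariate <- function(model, i) {
  model$covariates <- model$covariates[-i, , drop = FALSE]
  rownames(model$covariates) <- NULL
  model
}

#' Test one covariate candidate against a base model
#'
#' Fits the base model extended with the candidate (exponent initialized
#' at 0, i.e. no effect) and reports the OFV drop
#' `dOFV = OFV_base - OFV_extended` with the threshold decision.
#'
#' @param base a `fit_result` for the base model (used both for the
#'   reference OFV and as warm start).
#' @param candidate a [covariate_candidate].
#' @param ds log-scale [pk_dataset].
#' @param threshold OFV-drop significance threshold (default forward,
#'   6.635).
#' @param control passed to [fit_foce()].
#' @return list with `dofv`, `included` (logical), `fit` (extended
#'   `fit_result`) and `threshold`.
#' @export
evaluate_candidate <- function(base, candidate, ds,
                               threshold = scm_thresholds()[["forward"]],
                               control = list()) {
  if (!inherits(base, "fit_result")) stop("base must be a fit_result")
  ext_model <- add_candidate(base$model, candidate)
  fit <- tryCatch(
    fit_foce(ext_model, ds, covariance = "none", control = control),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence$status != "converged")
    return(list(dofv = NA_real_, included = FALSE, fit = fit,
                threshold = threshold, skipped = TRUE))
  dofv <- base$ofv - fit$ofv
  list(dofv = dofv, included = is.finite(dofv) && dofv > threshold,
       fit = fit, threshold = threshold, skipped = FALSE)
}

#' Stepwise covariate modeling
#'
#' Forward stage: repeatedly refit every remaining candidate on top of the
#' current model and add the one with the largest OFV drop exceeding the
#' forward threshold (ties broken by declaration order). Backward stage:
#' repeatedly remove the selected effect whose removal worsens the OFV
#' least, as long as that worsening does not exceed the backward threshold.
#' All parameters are re-estimated at every step.
#'
#' @param model base [pop_model] (typically covariate-free).
#' @param candidates list of [covariate_candidate] rows (see
#'   [default_candidates()]).
#' @param ds log-scale [pk_dataset].
#' @param forward,backward OFV-drop thresholds; defaults are the
#'   chi-square df = 1 quantiles at p = 0.01 and p = 0.001.
#' @param control passed to [fit_foce()].
#' @return list of class `scm_result`: `final` (`fit_result`), `trace`
#'   (data frame of every decision) and `selected` (covariate table of the
#'   final model).
#' @export
run_scm <- function(model, candidates, ds,
                    forward = scm_thresholds()[["forward"]],
                    backward = scm_thresholds()[["backward"]],
                    control = list()) {
  trace <- data.frame(step = integer(), stage = character(),
                      candidate = character(), dofv = numeric(),
                      threshold = numeric(), decision = character(),
                      stringsAsFactors = FALSE)
  note <- function(step, stage, cand, dofv, thr, dec)
    rbind(trace, data.frame(step = step, stage = stage, candidate = cand,
                            dofv = dofv, threshold = thr, decision = dec,
                            stringsAsFactors = FALSE))
  cand_label <- function(cd) paste0(cd$cov, "_on_", cd$param)
  current <- fit_foce(model, ds, covariance = "none", control = control)
  remaining <- candidates
  step <- 0L
  # forward inclusion
  while (length(remaining)) {
    step <- step + 1L
    evals <- lapply(remaining, function(cd)
      evaluate_candidate(current, cd, ds, forward, control))
    dofvs <- vapply(evals, function(e)
      ifelse(is.na(e$dofv), -Inf, e$dofv), numeric(1))
    for (k in seq_along(remaining))
      trace <- note(step, "forward", cand_label(remaining[[k]]), dofvs[k],
                    forward,
                    if (isTRUE(evals[[k]]$skipped)) "skipped (no convergence)"
                    else if (dofvs[k] > forward) "qualifies" else "rejected")
    best <- which.max(dofvs)  # ties: first in declaration order
    if (!length(best) || dofvs[best] <= forward) break
    trace <- note(step, "forward", cand_label(remaining[[best]]),
                  dofvs[best], forward, "included")
    current <- evals[[best]]$fit
    remaining <- remaining[-best]
  }
  # backward elimination (only effects added by the forward stage)
  n_base_cov <- nrow(model$covariates)
  repeat {
    sel <- seq_len(nrow(current$model$covariates))
    sel <- sel[sel > n_base_cov]
    if (!length(sel)) break
    step <- step + 1L
    worsenings <- numeric(length(sel)); fits <- vector("list", length(sel))
    for (k in seq_along(sel)) {
      red <- drop_covariate(current$model, sel[k])
      fits[[k]] <- tryCatch(
        fit_foce(red, ds, covariance = "none", control = control),
        error = function(e) NULL)
      worsenings[k] <- if (is.null(fits[[k]])) Inf else
        fits[[k]]$ofv - current$ofv
    }
    lab <- vapply(sel, function(i)
      paste0(current$model$covariates$cov[i], "_on_",
             current$model$covariates$param[i]), character(1))
    least <- which.min(worsenings)
    for (k in seq_along(sel))
      trace <- note(step, "backward", lab[k], worsenings[k], backward,
                    if (worsenings[k] > backward) "retained" else
                      "removable")
    if (worsenings[least] > backward) break
    trace <- note(step, "backward", lab[least], worsenings[least],
                  backward, "removed")
    current <- fits[[least]]
  }
  structure(list(final = current, trace = trace,
                 selected = current$model$covariates),
            class = "scm_result")
}

#' @export
print.scm_result <- function(x, ...) {
  cat("stepwise covariate modeling:", nrow(x$selected),
      "effect(s) in the final model\n")
  if (nrow(x$selected))
    cat(paste0("  ", x$selected$cov, " on ", x$selected$param,
               " (exponent ", signif(x$selected$exponent, 3), ")",
               collapse = "\n"), "\n")
  cat("final OFV:", round(x$final$ofv, 3), "\n")
  invisible(x)
}

#' Export an SCM trace as delimited text
#' @param scm an `scm_result`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_scm_trace <- function(scm, path) {
  write.csv(scm$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
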