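# Structural kinetics: dual-input two-compartment model.
#
# A fraction Bio of the dose is released at a zero-order rate over D1 hours
# into a first (buccal) depot that empties into the central compartment at
# rate Ka1. The remaining 1 - Bio sits in a second (gastrointestinal) depot
# that starts first-order release at rate Ka2 after a lag time Tlag. The
# disposition is a linear two-compartment model with central elimination.
# All parameters are apparent (scaled by the unknown bioavailability F,
# fixed to 1 internally).

.PAR_NAMES <- c("CL", "V1", "Q", "V2", "Ka1", "Ka2", "Bio", "Tlag", "D1")

#' Structural (individual-level) kinetic parameters
#'
#' Bundles the nine apparent parameters of the dual-input two-compartment
#' model. Units: `CL`, `Q` in L/h; `V1`, `V2` in L; `Ka1`, `Ka2` in 1/h;
#' `Bio` a fraction in (0, 1); `Tlag`, `D1` in h.
#'
#' @param CL,V1,Q,V2,Ka1,Ka2,Bio,Tlag,D1 scalar parameter values.
#' @return A named numeric vector of class `structural_params`.
#' @examples
#' structural_params(CL = 395, V1 = 131, Q = 32, V2 = 436,
#'                   Ka1 = 0.275, Ka2 = 0.399, Bio = 0.86,
#'                   Tlag = 1, D1 = 0.16)
#' @export
structural_params <- function(CL, V1, Q, V2, Ka1, Ka2, Bio, Tlag, D1) {
  p <- c(CL = CL, V1 = V1, Q = Q, V2 = V2, Ka1 = Ka1, Ka2 = Ka2,
         Bio = Bio, Tlag = Tlag, D1 = D1)
  validate_structural_params(p)
  structure(p, class = "structural_params")
}

validate_structural_params <- function(p) {
  if (!all(.PAR_NAMES %in% names(p)))
    stop("structural parameters must contain: ",
         paste(.PAR_NAMES, collapse = ", "))
  p <- p[.PAR_NAMES]
  if (any(!is.finite(p))) stop("non-finite structural parameter")
  pos <- setdiff(.PAR_NAMES, "Bio")
  if (any(p[pos] <= 0))
    stop("structural parameters must be > 0: ",
         paste(pos[p[pos] <= 0], collapse = ", "))
  if (p["Bio"] <= 0 || p["Bio"] >= 1) stop("Bio must lie in (0, 1)")
  invisible(p)
}

as_param_vector <- function(params) {
  p <- unclass(params)[.PAR_NAMES]
  if (any(is.na(p))) stop("missing structural parameter")
  as.numeric(p)
}

#' Closed-form concentration-time profile
#'
#' Evaluates the plasma concentration of the dual-input two-compartment model
#' by superposition of the two absorption inputs convolved with the
#' bi-exponential disposition (eigenvalues from the micro-constants
#' k10 = CL/V1, k12 = Q/V1, k21 = Q/V2). Near-degenerate absorption rates
#' (Ka within 1e-8 of a disposition eigenvalue) switch to the analytic limit
#' expression, so the evaluation never returns NaN for valid parameters.
#'
#' @param params a [structural_params] vector (or named vector with the same
#'   elements).
#' @param dose administered dose in pg (120 ug = 1.2e8 pg).
#' @param times sampling times in hours since dose, non-negative.
#' @return concentrations in pg/mL, one per time; exactly 0 at `t = 0`.
#' @examples
#' p <- structural_params(395, 131, 32, 436, 0.275, 0.399, 0.86, 1, 0.16)
#' concentration_profile(p, dose = 1.2e8, times = c(0, 0.5, 1, 2, 6, 24))
#' @export
concentration_profile <- function(params, dose, times) {
  p <- as_param_vector(params)
  validate_structural_params(setNames(p, .PAR_NAMES))
  if (dose < 0) stop("dose must be >= 0")
  if (any(times < 0) || any(!is.finite(times))) stop("times must be finite and >= 0")
  if (is.unsorted(times)) stop("times must be sorted")
  .conc_profile_cpp(p, dose, as.numeric(times))
}

#' Disposition eigenvalues and micro-constants
#'
#' @param params a [structural_params] vector.
#' @return list with `k10`, `k12`, `k21`, `lambda1`, `lambda2`
#'   (`lambda1 > lambda2 > 0`, both 1/h).
#' @export
disposition_rates <- function(params) {
  p <- as_param_vector(params)
  k10 <- p[1] / p[2]; k12 <- p[3] / p[2]; k21 <- p[3] / p[4]
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  list(k10 = k10, k12 = k12, k21 = k21,
       lambda1 = (s + disc) / 2, lambda2 = (s - disc) / 2)
}

#' Numerically integrated concentration profile (ODE oracle)
#'
#' Stiff-capable numerical solution of the four-state system (two depots,
#' central, peripheral), integrated piecewise across the discontinuities at
#' `D1` (end of zero-order release) and `Tlag` (release of the second depot).
#' Used as an independent check of [concentration_profile()] and as a
#' fallback.
#'
#' @inheritParams concentration_profile
#' @param tol relative integration tolerance, in (0, 1e-3].
#' @return concentrations in pg/mL at `times`.
#' @export
concentration_profile_ode <- function(params, dose, times, tol = 1e-10) {
  st <- state_amounts(params, dose, times, tol = tol)
  p <- as_param_vector(params)
  st[, "central"] / (p[2] * 1000)
}

#' Compartment amounts over time (numerical)
#'
#' @inheritParams concentration_profile_ode
#' @return matrix with columns `time`, `depot1`, `depot2`, `central`,
#'   `peripheral`, `eliminated` (amounts in pg).
#' @export
state_amounts <- function(params, dose, times, tol = 1e-10) {
  p <- as_param_vector(params)
  validate_structural_params(setNames(p, .PAR_NAMES))
  if (!is.numeric(tol) || tol <= 0 || tol > 1e-3)
    stop("tol must lie in (0, 1e-3]")
  if (is.unsorted(times) || any(times < 0)) stop("times must be sorted and >= 0")
  CL <- p[1]; V1 <- p[2]; Q <- p[3]; V2 <- p[4]
  Ka1 <- p[5]; Ka2 <- p[6]; Bio <- p[7]; Tlag <- p[8]; D1 <- p[9]
  k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
  R0 <- Bio * dose / D1

  deriv <- function(t, y, parms) {
    list(c(parms$rate - Ka1 * y[1],
           -Ka2 * y[2],
           Ka1 * y[1] + Ka2 * y[2] + k21 * y[4] - (k10 + k12) * y[3],
           k12 * y[3] - k21 * y[4],
           k10 * y[3]))
  }

  tmax <- max(times, D1, Tlag)
  breaks <- sort(unique(c(0, D1, Tlag, tmax)))
  breaks <- breaks[breaks <= tmax]
  y <- c(depot1 = 0, depot2 = 0, central = 0, peripheral = 0, eliminated = 0)
  out <- matrix(NA_real_, length(times), 6,
                dimnames = list(NULL, c("time", "depot1", "depot2", "central",
                                        "peripheral", "eliminated")))
  out[, "time"] <- times
  if (any(times == 0)) out[times == 0, -1] <- 0
  atol <- max(tol * dose, 1e-12)
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    if (t0 >= Tlag && y["depot2"] == 0 && t0 == Tlag)
      y["depot2"] <- (1 - Bio) * dose
    seg_times <- times[times > t0 & times <= t1]
    tt <- sort(unique(c(t0, seg_times, t1)))
    sol <- deSolve::lsoda(y, tt, deriv,
                          parms = list(rate = if (t0 < D1) R0 else 0),
                          rtol = tol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed for parameters: ",
           paste(sprintf("%s=%g", .PAR_NAMES, p), collapse = ", "))
    if (length(seg_times))
      out[match(seg_times, times), -1] <- sol[match(seg_times, sol[, "time"]), -1]
    y <- sol[nrow(sol), -1]
    names(y) <- c("depot1", "depot2", "central", "peripheral", "eliminated")
  }
  out
}

#' Export a concentration profile as delimited text
#'
#' @param params,dose,times as in [concentration_profile()].
#' @param path output file path (CSV with columns `time`, `conc`).
#' @return the data frame written, invisibly.
#' @export
write_profile <- function(params, dose, times, path) {
  df <- data.frame(time = times,
                   conc = concentration_profile(params, dose, times))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
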