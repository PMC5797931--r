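# Shared fixtures and independent oracles used across the test files.

table2_params <- function() {
  structural_params(CL = 395, V1 = 131, Q = 32, V2 = 436, Ka1 = 0.275,
                    Ka2 = 0.399, Bio = 0.86, Tlag = 1, D1 = 0.16)
}

study_times <- function() {
  c(5 / 60, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 24)
}

DOSE_PG <- 1.2e8

# random valid structural parameter draws (log-uniform over plausible ranges)
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lu <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
    structural_params(CL = lu(50, 2000), V1 = lu(20, 500), Q = lu(5, 100),
                      V2 = lu(50, 1000), Ka1 = lu(0.05, 5),
                      Ka2 = lu(0.05, 5), Bio = runif(1, 0.05, 0.95),
                      Tlag = runif(1, 0.2, 3), D1 = runif(1, 0.05, 1))
  })
}

# mixed relative/absolute agreement: strict relative where the curve is
# appreciable, with the denominator floored at 1e-4 of Cmax because the ODE
# oracle's absolute-tolerance noise dominates the far tail (values there sit
# orders of magnitude below the assay LOQ)
max_mixed_err <- function(a, b) {
  max(abs(a - b) / (abs(b) + 1e-4 * max(abs(b))))
}

# a noise-free dataset: exact model predictions as observations
noise_free_dataset <- function(model, cohort, design = study_design(censor = "none")) {
  recs <- lapply(seq_len(nrow(cohort)), function(i) {
    covs <- as.list(cohort[i, setdiff(names(cohort), "id"), drop = FALSE])
    p <- individual_parameters(model, covs)
    conc <- concentration_profile(p, design$dose, design$times)
    df <- data.frame(id = cohort$id[i], time = c(0, design$times),
                     amt = c(design$dose, rep(NA, length(design$times))),
                     dv = c(NA, conc),
                     evid = c(1L, rep(0L, length(design$times))),
                     mdv = c(1L, rep(0L, length(design$times))))
    for (cv in setdiff(names(cohort), "id")) df[[cv]] <- cohort[[cv]][i]
    df
  })
  pk_dataset(do.call(rbind, recs))
}

# exact -2 log marginal likelihood of the linear random-intercept toy
# y_ij = theta + eta_i + eps_ij
exact_linear_nll <- function(y, theta, omega, sigma) {
  n <- length(y)
  Sig <- matrix(omega, n, n)
  diag(Sig) <- omega + sigma^2
  r <- y - theta
  as.numeric(n * log(2 * pi) + determinant(Sig)$modulus +
               t(r) %*% solve(Sig, r))
}

# adaptive 64-node Gauss-Hermite -2 log marginal likelihood for a
# one-eta model with additive N(0, sigma^2) error
agh_nll <- function(f, y, omega, sigma, nodes = 64) {
  gh <- pracma::gaussHermite(nodes)
  n <- length(y)
  h <- function(e) sum((y - f(e))^2) / (2 * sigma^2) + e^2 / (2 * omega)
  mode <- optimize(h, c(-8, 8))$minimum
  hpp <- (h(mode + 1e-4) - 2 * h(mode) + h(mode - 1e-4)) / 1e-8
  s <- 1 / sqrt(hpp)
  joint <- function(e)
    exp(-sum((y - f(e))^2) / (2 * sigma^2)) / (2 * pi * sigma^2)^(n / 2) *
    exp(-e^2 / (2 * omega)) / sqrt(2 * pi * omega)
  L <- sqrt(2) * s * sum(gh$w * exp(gh$x^2) *
                           vapply(mode + sqrt(2) * s * gh$x, joint,
                                  numeric(1)))
  -2 * log(L)
}

# reduced single-input model (Bio -> 1 limit): three-state ODE written
# independently of the package's kinetics
single_input_ode <- function(params, dose, times, tol = 1e-11) {
  p <- unclass(params)
  k10 <- p[["CL"]] / p[["V1"]]; k12 <- p[["Q"]] / p[["V1"]]
  k21 <- p[["Q"]] / p[["V2"]]
  R0 <- dose / p[["D1"]]; ka <- p[["Ka1"]]; D1 <- p[["D1"]]
  deriv <- function(t, y, parms)
    list(c(parms$rate - ka * y[1],
           ka * y[1] + k21 * y[3] - (k10 + k12) * y[2],
           k12 * y[2] - k21 * y[3]))
  run <- function(y0, tt, rate)
    deSolve::lsoda(y0, tt, deriv, parms = list(rate = rate), rtol = tol,
                   atol = tol * dose)
  tmax <- max(times, D1)
  y <- c(0, 0, 0)
  out <- rep(NA_real_, length(times))
  seg1 <- sort(unique(c(0, times[times <= D1], D1)))
  s1 <- run(y, seg1, R0)
  out[times <= D1] <- s1[match(times[times <= D1], s1[, 1]), 3]
  y <- s1[nrow(s1), -1]
  if (any(times > D1)) {
    seg2 <- sort(unique(c(D1, times[times > D1])))
    s2 <- run(y, seg2, 0)
    out[times > D1] <- s2[match(times[times > D1], s2[, 1]), 3]
  }
  out[times == 0] <- 0
  out / (p[["V1"]] * 1000)
}
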