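test_that("objective collapses to the fixed-effects likelihood when IIV is zero", {
  m <- pop_model(theta = reference_model()$theta, sigma = 0.2,
                 covariates = reference_model()$covariates)
  cohort <- data.frame(id = c("A", "B"), BW = c(5, 20))
  ds <- simulate_population(m, cohort, study_design(censor = "none"),
                            seed = 2)
  lds <- log_transform_obs(ds)
  ofv <- conditional_objective(m, lds)
  # analytic: -2 sum log N(y; log pred, sigma^2)
  manual <- 0
  for (s in c("A", "B")) {
    rows <- lds$data[lds$data$id == s & lds$data$mdv == 0, ]
    pred <- log(concentration_profile(
      individual_parameters(m, c(BW = rows$BW[1])), DOSE_PG, rows$time))
    manual <- manual - 2 * sum(dnorm(rows$dv, pred, 0.2, log = TRUE))
  }
  expect_equal(ofv, manual, tolerance = 1e-10)
})

test_that("one-subject linear toy matches the exact Gaussian marginal", {
  set.seed(12)
  theta <- 1.3; omega <- 0.4; sigma <- 0.25
  for (i in 1:5) {
    y <- theta + rnorm(1, 0, sqrt(omega)) + rnorm(6, 0, sigma)
    r <- foce_subject_ofv(function(e) rep(theta + sum(e), 6), y, omega,
                          sigma)
    expect_equal(r$ofv, exact_linear_nll(y, theta, omega, sigma),
                 tolerance = 1e-8)
  }
})

test_that("one-eta nonlinear toy agrees with 64-node adaptive quadrature", {
  skip_if_not_installed("pracma")
  tt <- c(0.5, 1, 2, 4, 8); k <- 0.5; A <- 100
  omega <- 0.3; sigma <- 0.15
  f <- function(e) log(A) - k * exp(if (length(e)) e else 0) * tt
  set.seed(9)
  for (i in 1:10) {
    y <- f(rnorm(1, 0, sqrt(omega))) + rnorm(5, 0, sigma)
    r <- foce_subject_ofv(f, y, omega, sigma)
    expect_lt(abs(r$ofv - agh_nll(f, y, omega, sigma)), 0.1)
  }
})

test_that("the compiled inner step matches the reference implementation", {
  m <- reference_model()
  st <- generate_study(seed = 21)
  lds <- log_transform_obs(apply_loq_filter(st$dataset)$dataset)
  subs <- poppkdual:::split_subjects(lds)
  en <- poppkdual:::eta_names(m)
  ei <- match(poppkdual:::.PAR_NAMES, en, nomatch = 0L) - 1L
  for (s in subs[c(3, 9, 17)]) {
    ptyp <- poppkdual:::typical_params(m, s$covariates)
    fpred <- function(eta)
      log(concentration_profile(poppkdual:::apply_eta(m, ptyp, eta),
                                s$dose, s$times))
    r_ref <- foce_subject_ofv(fpred, s$y, unname(m$omega[en]), m$sigma)
    r_cpp <- poppkdual:::.foce_inner_cpp(unname(ptyp), ei, TRUE, s$y,
                                         s$times, s$dose,
                                         unname(m$omega[en]), m$sigma,
                                         numeric(length(en)))
    expect_equal(r_cpp$ofv, r_ref$ofv, tolerance = 1e-6)
    expect_equal(as.numeric(r_cpp$eta), r_ref$eta, tolerance = 1e-4)
  }
})

test_that("noise-free data returns the generating fixed effects", {
  m <- pop_model(theta = reference_model()$theta, sigma = 0.1,
                 fix_sigma = TRUE,
                 covariates = reference_model()$covariates)
  cohort <- data.frame(id = sprintf("P%d", 1:4), BW = c(2, 8, 15, 60))
  lds <- log_transform_obs(noise_free_dataset(m, cohort))
  init <- m
  init$theta <- m$theta * c(1.4, 0.7, 1.3, 0.75, 1.3, 0.8, 1, 1.15, 1.3)
  init$theta["Bio"] <- 0.75
  init$covariates$exponent <- c(0.8, 0.9)
  fit <- fit_foce(m, lds, init = init, covariance = "none",
                  control = list(reltol = 1e-13, restarts = 6))
  truth <- c(m$theta, m$covariates$exponent)
  est <- fit$estimates$estimate[seq_along(truth)]
  expect_lt(max(abs(est - truth) / truth), 1e-4)
  expect_equal(fit$aic, fit$ofv + 2 * fit$npar)
  expect_equal(fit$convergence$status, "converged")
})

test_that("posthoc estimates behave in the prior- and likelihood-dominated limits", {
  theta <- reference_model()$theta
  cohort <- data.frame(id = c("A", "B"), BW = c(10, 10))
  # prior dominates: omega -> 0 pulls the modes to zero
  m_small <- pop_model(theta = theta, omega = c(CL = 1e-10), sigma = 0.2)
  st <- simulate_population(m_small, cohort, study_design(censor = "none"),
                            seed = 4)
  lds <- log_transform_obs(st)
  eb <- compute_ebes(m_small, lds)
  expect_lt(max(abs(eb$eta)), 1e-4)
  # likelihood dominates: sigma -> 0 on noise-free single-eta data
  # recovers the generating eta
  m_one <- pop_model(theta = theta, omega = c(CL = 0.3), sigma = 1e-5)
  eta_gen <- c(0.35, -0.42)
  recs <- lapply(1:2, function(i) {
    p <- individual_parameters(m_one, c(BW = 10),
                               setNames(eta_gen[i], "CL"))
    conc <- concentration_profile(p, DOSE_PG, study_times())
    data.frame(id = cohort$id[i], time = c(0, study_times()),
               amt = c(DOSE_PG, rep(NA, 14)), dv = c(NA, conc),
               evid = c(1L, rep(0L, 14)), mdv = c(1L, rep(0L, 14)),
               BW = 10)
  })
  lds2 <- log_transform_obs(pk_dataset(do.call(rbind, recs)))
  eb2 <- compute_ebes(m_one, lds2)
  expect_equal(as.numeric(eb2$eta[, "CL"]), eta_gen, tolerance = 1e-3)
  # determinism: recomputing gives identical modes
  eb2b <- compute_ebes(m_one, lds2)
  expect_identical(eb2$eta, eb2b$eta)
})

test_that("shrinkage follows its defining formula", {
  ebes <- matrix(0, 10, 1, dimnames = list(NULL, "CL"))
  expect_equal(unname(shrinkage_pct(ebes, c(CL = 0.2))), 100)
  set.seed(1)
  x <- rnorm(50)
  x <- (x - mean(x)) / sd(x) * 0.3  # sample SD exactly 0.3
  ebes2 <- matrix(x, ncol = 1, dimnames = list(NULL, "CL"))
  expect_equal(unname(shrinkage_pct(ebes2, c(CL = 0.09))), 0,
               tolerance = 1e-10)
  ebes3 <- matrix(c(0.1, -0.1), ncol = 1, dimnames = list(NULL, "CL"))
  expect_equal(unname(shrinkage_pct(ebes3, c(CL = 0.04))),
               100 * (1 - sd(c(0.1, -0.1)) / 0.2), tolerance = 1e-10)
  expect_equal(round(unname(shrinkage_pct(ebes3, c(CL = 0.04))), 1), 29.3)
  expect_true(is.na(shrinkage_pct(ebes3, c(CL = 0))[["CL"]]))
})

test_that("RSE conventions reproduce the reporting arithmetic", {
  expect_equal(round(rse_percent(395, 31.8, "fixed"), 2), 8.05)
  expect_equal(round(rse_percent(0.175, 0.0462, "omega"), 2), 13.20)
  expect_equal(round(rse_percent(0.228, 0.0291, "sigma"), 2), 12.76)
  expect_equal(rse_percent(5, 0, "fixed"), 0)
  expect_warning(out <- rse_percent(0, 1, "fixed"), "zero estimate")
  expect_true(is.na(out))
})

test_that("condition numbers come from correlation-matrix eigenvalues", {
  expect_equal(condition_number(diag(3))$cn, 1)
  m <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(condition_number(m)$cn, 9, tolerance = 1e-12)
  rho <- 1499 / 1501  # eigenvalue ratio (1+rho)/(1-rho) = 1500
  big <- matrix(c(1, rho, rho, 1), 2)
  cn <- condition_number(big)
  expect_equal(cn$cn, 1500, tolerance = 1e-9)
  expect_false(cn$acceptable)
  expect_true(condition_number(m)$acceptable)
  expect_warning(res <- condition_number(matrix(c(1, 1, 1, 1), 2)),
                 "not positive definite")
  expect_equal(res$cn, Inf)
})

test_that("the covariance step yields finite SEs and a precision table", {
  m <- reference_model()
  m$fix_theta <- c("Q", "V2", "Ka1", "Ka2", "Bio", "Tlag", "D1")
  m$fix_omega <- union(m$fix_omega, c("Ka1", "V2", "D1", "Bio"))
  m$fix_covariates <- 2L  # keep the BW-on-V1 exponent at its value
  st <- generate_study(reference_model(), seed = 71)
  lds <- log_transform_obs(apply_loq_filter(st$dataset)$dataset)
  fit <- fit_foce(m, lds)
  expect_true(all(is.finite(fit$estimates$se)))
  expect_true(all(fit$estimates$se > 0))
  tab <- rse_table(fit)
  expect_true(all(c("estimate", "se", "rse", "shrinkage") %in% names(tab)))
  iiv <- tab$kind == "omega"
  expect_equal(tab$rse[iiv],
               100 * tab$se[iiv] / (2 * tab$estimate[iiv]))
  expect_true(all(is.finite(tab$shrinkage[iiv])))
  expect_true(is.finite(fit$condition_number) || fit$condition_number > 0)
  # clearance is precisely estimated in a rich design
  expect_lt(tab$rse[tab$parameter == "CL"], 30)
  # flat export: parameter table + YAML summary
  base <- file.path(tempdir(), "fit_export")
  write_fit_result(fit, base)
  flat <- read.csv(paste0(base, ".csv"))
  expect_true(all(c("parameter", "estimate", "se", "rse", "shrinkage") %in%
                    names(flat)))
  y <- yaml::read_yaml(paste0(base, ".yaml"))
  expect_equal(y$ofv, fit$ofv, tolerance = 1e-8)
  expect_equal(y$npar, fit$npar)
})

test_that("chi-square thresholds match the df = 1 quantiles", {
  th <- scm_thresholds()
  expect_equal(round(th[["forward"]], 3), 6.635)
  expect_equal(round(th[["backward"]], 3), 10.828)
})
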