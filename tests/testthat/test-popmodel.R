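test_that("individual parameters reproduce the covariate model arithmetic", {
  m <- reference_model()
  p10 <- individual_parameters(m, c(BW = 10))
  expect_equal(unname(p10["CL"]), 395)
  expect_equal(unname(p10["V1"]), 131)
  # exponential IIV doubles clearance at eta = log 2
  en <- names(m$omega[m$omega > 0])
  eta <- setNames(numeric(length(en)), en)
  eta["CL"] <- log(2)
  expect_equal(unname(individual_parameters(m, c(BW = 10), eta)["CL"]), 790)
  # centered power model at 2.01 kg
  p2 <- individual_parameters(m, c(BW = 2.01))
  expect_equal(unname(p2["CL"]), 395 * 0.201^1.03, tolerance = 1e-12)
  expect_equal(unname(p2["CL"]), 75.6, tolerance = 2e-3)
  expect_error(individual_parameters(m, c(BSA = 0.4), subject = "X1"),
               "missing covariate BW")
})

test_that("Bio random effects act on the logit scale and stay in (0, 1)", {
  m <- reference_model()
  en <- names(m$omega[m$omega > 0])
  draws <- vapply(seq_len(200), function(i) {
    eta <- setNames(numeric(length(en)), en)
    eta["Bio"] <- rnorm(1, 0, sqrt(m$omega["Bio"]))
    individual_parameters(m, c(BW = 10), eta)[["Bio"]]
  }, numeric(1))
  expect_true(all(draws > 0 & draws < 1))
  eta <- setNames(numeric(length(en)), en)
  eta["Bio"] <- 0.5
  expect_equal(individual_parameters(m, c(BW = 10), eta)[["Bio"]],
               1 / (1 + exp(-(log(0.86 / 0.14) + 0.5))), tolerance = 1e-12)
})

test_that("degenerate variability yields the deterministic typical profile", {
  m0 <- pop_model(theta = reference_model()$theta, sigma = 1e-12,
                  covariates = reference_model()$covariates)
  obs <- simulate_individual(m0, c(BW = 10), study_times(), DOSE_PG,
                             seed = 1)
  typ <- concentration_profile(table2_params(), DOSE_PG, study_times())
  expect_equal(as.numeric(obs), typ, tolerance = 1e-9)
})

test_that("residual variability matches sigma on the log scale", {
  m <- pop_model(theta = reference_model()$theta, sigma = 0.228,
                 covariates = reference_model()$covariates)
  set.seed(42)
  reps <- replicate(10000,
                    simulate_individual(m, c(BW = 10), times = 2,
                                        dose = DOSE_PG)[1])
  v <- var(log(reps))
  expect_equal(v, 0.228^2, tolerance = 0.05)
})

test_that("seeded simulation is reproducible, different seeds differ", {
  m <- reference_model()
  a <- simulate_individual(m, c(BW = 10), study_times(), DOSE_PG, seed = 7)
  b <- simulate_individual(m, c(BW = 10), study_times(), DOSE_PG, seed = 7)
  d <- simulate_individual(m, c(BW = 10), study_times(), DOSE_PG, seed = 8)
  expect_identical(a, b)
  expect_false(identical(as.numeric(a), as.numeric(d)))
})

test_that("population simulation produces the expected record layout", {
  m <- reference_model()
  cohort <- generate_cohort(seed = 3)
  des <- study_design(censor = "none")
  ds <- simulate_population(m, cohort, des, seed = 5)
  expect_equal(sum(ds$data$evid == 0 & ds$data$mdv == 0), 32 * 14)
  expect_equal(sum(ds$data$evid == 1), 32)
  # without variability all subjects of equal BW have identical profiles
  m0 <- pop_model(theta = m$theta, sigma = 1e-12,
                  covariates = m$covariates)
  flat <- data.frame(id = c("A", "B"), BW = 10)
  ds0 <- simulate_population(m0, flat, des)
  a <- ds0$data$dv[ds0$data$id == "A" & ds0$data$mdv == 0]
  b <- ds0$data$dv[ds0$data$id == "B" & ds0$data$mdv == 0]
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("population medians converge to the typical values (log-normal)", {
  m <- reference_model()
  set.seed(11)
  en <- names(m$omega[m$omega > 0])
  etas <- sapply(en, function(nm) rnorm(4000, 0, sqrt(m$omega[[nm]])))
  pars <- t(apply(etas, 1, function(e)
    unclass(individual_parameters(m, c(BW = 10), e))))
  # each log-normal parameter's median is its typical value
  expect_equal(median(pars[, "CL"]), 395, tolerance = 0.03)
  expect_equal(median(pars[, "V1"]), 131, tolerance = 0.04)
  expect_equal(median(pars[, "Ka1"]), 0.275, tolerance = 0.03)
  # and the simulated concentration median tracks the typical curve in the
  # elimination phase, where the profile is monotone in the dominant etas
  cohort <- data.frame(id = sprintf("S%04d", 1:3000), BW = 10)
  des <- study_design(times = c(6, 10), censor = "none")
  ds <- simulate_population(m, cohort, des, seed = 11)
  typ <- concentration_profile(table2_params(), DOSE_PG, c(6, 10))
  med <- tapply(ds$data$dv[ds$data$mdv == 0],
                ds$data$time[ds$data$mdv == 0], median)
  expect_equal(as.numeric(med), typ, tolerance = 0.1)
})

test_that("model YAML serialization round-trips", {
  m <- reference_model()
  path <- tempfile(fileext = ".yaml")
  write_model_yaml(m, path)
  back <- read_model_yaml(path)
  expect_equal(back$theta, m$theta)
  expect_equal(back$omega, m$omega)
  expect_equal(back$sigma, m$sigma)
  expect_equal(back$covariates, m$covariates)
  expect_equal(sort(back$fix_omega), sort(m$fix_omega))
  expect_equal(back$bio_scale, m$bio_scale)
})

test_that("model construction validates its inputs", {
  th <- reference_model()$theta
  expect_error(pop_model(theta = th[-1]), "must provide all")
  expect_error(pop_model(theta = th, omega = c(CL = -0.1)), ">= 0")
  expect_error(pop_model(theta = th, sigma = 0), "sigma")
  expect_error(pop_model(theta = th,
                         covariates = covariate_effect("XX", "BW", 1)),
               "unknown parameter")
})
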