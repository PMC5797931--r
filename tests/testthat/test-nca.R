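test_that("terminal slope is exact on a mono-exponential curve", {
  tt <- c(1, 2, 4, 6, 8)
  cc <- 100 * exp(-0.5 * tt)
  lz <- lambda_z(tt, cc)
  expect_equal(lz$lambda_z, 0.5, tolerance = 1e-10)
  expect_equal(lz$adj_r2, 1, tolerance = 1e-10)
  expect_equal(half_life(lz$lambda_z), log(2) / 0.5, tolerance = 1e-10)
})

test_that("too few terminal points yields a no-estimate result", {
  lz <- lambda_z(c(1, 2, 3), c(10, 8, 5))  # only 2 points after the max
  expect_true(is.na(lz$lambda_z))
  ai <- auc_inf(c(1, 2, 3), c(10, 8, 5), lz$lambda_z)
  expect_true(is.na(ai$auc_inf))
  expect_false(is.na(ai$auc_last))  # AUC to last is still reported
  expect_true(is.na(half_life(lz$lambda_z)))
})

test_that("terminal slope converges to the slow disposition eigenvalue", {
  p <- table2_params()
  lam2 <- disposition_rates(p)$lambda2
  # once the faster absorption/disposition modes have decayed (the slow
  # eigenvalue's coefficient is small, so this takes until ~48 h), the
  # fitted terminal slope is the eigenvalue
  tt <- seq(48, 96, by = 4)
  conc <- concentration_profile(p, DOSE_PG, tt)
  lz <- lambda_z(c(24, tt), concentration_profile(p, DOSE_PG, c(24, tt)))
  expect_equal(lz$lambda_z, lam2, tolerance = 0.05)
  # within the 24 h sampling window the apparent slope is still a mixture
  # and overestimates the asymptotic rate
  lz24 <- lambda_z(study_times(),
                   concentration_profile(p, DOSE_PG, study_times()))
  expect_gt(lz24$lambda_z, lam2)
})

test_that("log-trapezoid AUC follows its defining rules", {
  # equal concentrations: rectangle
  expect_equal(auc_to_last(c(0, 2), c(5, 5)), 10)
  # exact on an exponential between samples
  tt <- c(1e-4, 1:10)
  cc <- 100 * exp(-1 * tt)
  expect_equal(auc_to_last(tt, cc), 100 * (1 - exp(-10)), tolerance = 0.005)
  # guards
  expect_error(auc_to_last(1, 10), "at least 2")
  expect_error(auc_to_last(c(2, 1), c(1, 2)), "strictly increasing")
  expect_error(auc_to_last(c(1, 2), c(-1, 2)), ">= 0")
  # zero endpoint falls back to the linear trapezoid
  expect_equal(auc_to_last(c(0, 1), c(0, 10)), 5)
})

test_that("log-trapezoid never exceeds the linear trapezoid when declining", {
  set.seed(5)
  for (i in 1:25) {
    c1 <- runif(1, 1, 100)
    c2 <- runif(1, 0.01, c1 * 0.99)
    dt <- runif(1, 0.1, 5)
    logt <- auc_to_last(c(0, dt), c(c1, c2))
    lint <- (c1 + c2) * dt / 2
    expect_lte(logt, lint + 1e-12)
  }
})

test_that("AUC is additive over interval partitions", {
  tt <- c(0.5, 1, 2, 4, 8, 12)
  cc <- c(20, 35, 30, 14, 4, 1.2)
  whole <- auc_to_last(tt, cc)
  split_at <- 3
  part <- auc_to_last(tt[1:split_at], cc[1:split_at]) +
    auc_to_last(tt[split_at:6], cc[split_at:6])
  expect_equal(whole, part, tolerance = 1e-12)
})

test_that("extrapolation arithmetic and quality flags", {
  ai <- auc_inf(c(1, 2, 4, 6), c(80, 40, 20, 10), lambda_z = 0.5)
  expect_equal(ai$tail, 10 / 0.5)
  expect_equal(ai$auc_inf, ai$auc_last + 20)
  expect_equal(ai$extrap_pct, 100 * 20 / ai$auc_inf)
  # a fat tail gets flagged, nothing is dropped
  fat <- auc_inf(c(1, 2, 3), c(12, 11, 10.5), lambda_z = 0.05)
  expect_true(fat$extrap_flag)
  expect_gt(fat$extrap_pct, 20)
})

test_that("half-life identities", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.6931 / 2), 2, tolerance = 1e-4)
  expect_equal(half_life(0.5), 1.386, tolerance = 1e-3)
})

test_that("model-based NCA recovers dose/CL per subject", {
  m <- pop_model(theta = reference_model()$theta, sigma = 0.2,
                 covariates = reference_model()$covariates)
  cohort <- data.frame(id = c("A", "B"), BW = c(10, 3))
  lds <- log_transform_obs(noise_free_dataset(m, cohort))
  grid <- c(seq(0.02, 1, 0.02), seq(1.05, 3, 0.05), seq(3.1, 48, 0.1))
  tab <- nca(m, lds, grid = grid)
  cl <- vapply(c(10, 3), function(bw) 395 * (bw / 10)^1.03, numeric(1))
  expect_equal(tab$auc_inf, DOSE_PG / (cl * 1000), tolerance = 0.01)
  expect_true(all(tab$auc_inf >= tab$auc_last))
  expect_equal(tab$t_half, log(2) / tab$lambda_z, tolerance = 1e-12)
})

test_that("observed-mode NCA and the group summary run end to end", {
  m <- reference_model()
  st <- generate_study(seed = 66)
  lds <- log_transform_obs(apply_loq_filter(st$dataset)$dataset)
  tab <- nca(m, lds, mode = "observed")
  expect_equal(nrow(tab), length(unique(lds$data$id)))
  summ <- nca_summary(tab, st$cohort[, c("id", "group")])
  expect_true(all(c("8d", "4w", "7w", "6m") %in% summ$group))
  # younger piglets are exposed far more than the oldest group
  auc8 <- summ$auc_inf_mean[summ$group == "8d"]
  auc6m <- summ$auc_inf_mean[summ$group == "6m"]
  expect_gt(auc8, auc6m)
})
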