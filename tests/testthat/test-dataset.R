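make_flat_table <- function(n_subj = 4, times = study_times()) {
  do.call(rbind, lapply(seq_len(n_subj), function(i) {
    data.frame(id = sprintf("S%02d", i), time = c(0, times),
               amt = c(DOSE_PG, rep(NA, length(times))),
               dv = c(NA, 50 * exp(-0.3 * times) + i),
               evid = c(1L, rep(0L, length(times))),
               mdv = c(1L, rep(0L, length(times))),
               BW = 2 + i, stringsAsFactors = FALSE)
  }))
}

test_that("write/read round-trips a dataset identically", {
  ds <- pk_dataset(make_flat_table(), loq = 4, provenance = "fixture")
  path <- tempfile(fileext = ".csv")
  write_pk_dataset(ds, path)
  back <- read_pk_dataset(path, loq = 4)
  expect_equal(back$data[names(ds$data)], ds$data, tolerance = 1e-12)
  # tab-delimited round trip too
  path2 <- tempfile(fileext = ".tsv")
  write_pk_dataset(ds, path2)
  back2 <- read_pk_dataset(path2, loq = 4)
  expect_equal(back2$data[names(ds$data)], ds$data, tolerance = 1e-12)
})

test_that("a full-study file yields 32 x (1 dose + 14 observations) = 480 records", {
  tab <- do.call(rbind, lapply(1:32, function(i) {
    data.frame(id = sprintf("P%02d", i), time = c(0, study_times()),
               amt = c(DOSE_PG, rep(NA, 14)),
               dv = c(NA, seq(5, 70, length.out = 14)),
               evid = c(1L, rep(0L, 14)), mdv = c(0L, rep(0L, 14)))
  }))
  # the time-0 dose row carries no dv; mdv is derived from missing dv
  tab$mdv <- NULL
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE, na = "NA")
  ds <- read_pk_dataset(path)
  expect_equal(nrow(ds$data), 480)
  expect_equal(sum(ds$data$evid == 1), 32)
  expect_equal(sum(ds$data$evid == 0 & ds$data$mdv == 0), 448)
})

test_that("NA observations in pre-dose rows become placeholders, not errors", {
  tab <- data.frame(id = "A", time = c(0, 0, 1, 2),
                    amt = c(NA, 100, NA, NA), dv = c(NA, NA, 9, 5),
                    evid = c(0L, 1L, 0L, 0L))
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE, na = "NA")
  ds <- read_pk_dataset(path)
  pre <- ds$data[ds$data$time == 0 & ds$data$evid == 0, ]
  expect_equal(pre$mdv, 1L)
  expect_equal(sum(ds$data$mdv == 0), 2)
})

test_that("missing mandatory columns and non-numeric fields are rejected", {
  tab <- make_flat_table(1)
  path <- tempfile(fileext = ".csv")
  write.csv(tab[setdiff(names(tab), "time")], path, row.names = FALSE)
  expect_error(read_pk_dataset(path), "configuration error")
  tab2 <- make_flat_table(1)
  tab2$dv <- as.character(tab2$dv)
  tab2$dv[3] <- "oops"
  write.csv(tab2, path, row.names = FALSE, na = "NA")
  expect_error(read_pk_dataset(path), "parse error.*row 3")
})

test_that("column maps rename columns, directly and via YAML config", {
  tab <- make_flat_table(1)
  names(tab)[names(tab) == "dv"] <- "CONC"
  names(tab)[names(tab) == "id"] <- "SUBJ"
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE, na = "NA")
  ds <- read_pk_dataset(path, column_map = c(id = "SUBJ", dv = "CONC"))
  expect_equal(sum(ds$data$mdv == 0), 14)
  cfg <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(columns = list(id = "SUBJ", dv = "CONC"),
                        loq = 2.5), cfg)
  ds2 <- read_pk_dataset(path, column_map = cfg)
  expect_equal(ds2$loq, 2.5)
  expect_equal(ds2$data$dv, ds$data$dv)
})

test_that("record validation enforces the event-record invariants", {
  tab <- make_flat_table(1)
  bad <- tab; bad$time[2] <- -1
  expect_error(pk_dataset(bad), "time")
  bad <- tab; bad$dv[2] <- -5
  expect_error(pk_dataset(bad), "> 0 before log")
  bad <- tab; bad$BW[3] <- 99
  expect_error(pk_dataset(bad), "varies within subject")
  bad <- tab[tab$evid == 0, ]
  expect_error(pk_dataset(bad), "no dose record at time 0")
})

test_that("LOQ filtering removes the right records and reports the fraction", {
  times <- 1:10
  tab <- data.frame(id = "A", time = c(0, times),
                    amt = c(100, rep(NA, 10)),
                    dv = c(NA, c(10, 8, 3.9, 6, 0.5, 5, 2.2, 9, 7, 11)),
                    evid = c(1L, rep(0L, 10)), mdv = c(1L, rep(0L, 10)))
  ds <- pk_dataset(tab, loq = 4)
  out <- apply_loq_filter(ds)
  expect_equal(out$n_excluded, 3)
  expect_equal(out$excluded_fraction, 30)
  expect_equal(sum(out$dataset$data$evid == 0 & out$dataset$data$mdv == 0), 7)
  expect_equal(sum(out$dataset$data$evid == 1), 1)  # dose untouched
  # no-op when nothing is below the threshold
  none <- apply_loq_filter(ds, loq = 0.1)
  expect_equal(none$excluded_fraction, 0)
  expect_equal(none$dataset$data, ds$data)
  expect_error(apply_loq_filter(ds, loq = -2), "loq")
  # record counts: filtered + excluded = original observations
  expect_equal(out$n_excluded +
                 sum(out$dataset$data$evid == 0 & out$dataset$data$mdv == 0),
               out$n_obs)
})

test_that("log transform is correct, guarded and inverse of exp", {
  tab <- make_flat_table(2)
  ds <- pk_dataset(tab)
  lds <- log_transform_obs(ds)
  obs <- lds$data$evid == 0 & lds$data$mdv == 0
  expect_equal(exp(lds$data$dv[obs]), ds$data$dv[ds$data$evid == 0 &
                                                   ds$data$mdv == 0])
  expect_true(lds$log_scale)
  expect_error(log_transform_obs(lds), "already on the log scale")
  # log(1) = 0
  one <- pk_dataset(data.frame(id = "A", time = c(0, 1), amt = c(10, NA),
                               dv = c(NA, 1), evid = c(1L, 0L),
                               mdv = c(1L, 0L)))
  expect_equal(log_transform_obs(one)$data$dv[2], 0)
})

test_that("filtering and transforming commute on surviving records", {
  tab <- make_flat_table(3)
  obs <- tab$evid == 0
  # positive everywhere, with the late tail dipping below the 4 pg/mL LOQ
  tab$dv[obs] <- 2.5 + 6 * exp(-0.4 * tab$time[obs]) +
    0.3 * as.integer(factor(tab$id[obs]))
  ds <- pk_dataset(tab, loq = 4)
  a <- log_transform_obs(apply_loq_filter(ds)$dataset)
  b_full <- log_transform_obs(ds)
  keep <- !(b_full$data$evid == 0 & b_full$data$mdv == 0 &
              b_full$data$dv < log(4))
  b <- b_full$data[keep, ]
  rownames(b) <- NULL
  expect_equal(a$data, b)
})
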