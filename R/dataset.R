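# NONMEM-style longitudinal PK event tables.
#
# A pk_dataset wraps a data frame of event records with the conventional
# columns: id, time (h), amt (dose, pg), dv (observed concentration, pg/mL,
# or its natural log once transformed), evid (1 dose / 0 observation), mdv
# (1 = dv missing/ignored), bloq (below the quantification limit), plus any
# covariate columns (BW, BSA, GFR, AGE, group).

.MANDATORY_COLS <- c("id", "time", "amt", "dv", "evid", "mdv")

#' Construct and validate a PK event dataset
#'
#' @param data data frame with at least columns `id`, `time`, `amt`, `dv`,
#'   `evid`, `mdv`; a `bloq` flag column is added if absent. Any further
#'   columns are carried along as covariates.
#' @param loq limit of quantification in pg/mL (stored; filtering is a
#'   separate step, see [apply_loq_filter()]).
#' @param log_scale are the observation `dv` values already natural logs?
#' @param provenance free-text note (file path or generator seed).
#' @return object of class `pk_dataset`; records sorted by `(id, time)`.
#' @export
pk_dataset <- function(data, loq = 4, log_scale = FALSE, provenance = "") {
  stopifnot(is.data.frame(data))
  miss <- setdiff(.MANDATORY_COLS, names(data))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (!"bloq" %in% names(data)) data$bloq <- 0L
  data <- data[order(data$id, data$time, -data$evid), , drop = FALSE]
  rownames(data) <- NULL
  ds <- structure(list(data = data, loq = loq, log_scale = isTRUE(log_scale),
                       provenance = provenance),
                  class = "pk_dataset")
  validate_pk_dataset(ds)
  ds
}

validate_pk_dataset <- function(ds) {
  d <- ds$data
  bad_row <- function(i, msg) stop("record ", i, ": ", msg, call. = FALSE)
  if (any(!is.finite(d$time)))
    bad_row(which(!is.finite(d$time))[1], "time must be finite")
  if (any(d$time < 0)) bad_row(which(d$time < 0)[1], "time must be >= 0")
  if (!all(d$evid %in% c(0L, 1L)))
    bad_row(which(!d$evid %in% c(0L, 1L))[1], "evid must be 0 or 1")
  if (!all(d$mdv %in% c(0L, 1L)))
    bad_row(which(!d$mdv %in% c(0L, 1L))[1], "mdv must be 0 or 1")
  dose <- d$evid == 1L
  if (any(is.na(d$amt[dose]) | d$amt[dose] <= 0))
    bad_row(which(dose)[which(is.na(d$amt[dose]) | d$amt[dose] <= 0)][1],
            "dose record needs amt > 0")
  if (any(!is.na(d$dv[dose])))
    bad_row(which(dose & !is.na(d$dv))[1],
            "dose record must not carry an observation")
  obs <- d$evid == 0L & d$mdv == 0L
  if (any(is.na(d$dv[obs])))
    bad_row(which(obs)[which(is.na(d$dv[obs]))][1],
            "observation record with mdv = 0 needs a dv value")
  if (!ds$log_scale && any(d$dv[obs] <= 0))
    bad_row(which(obs)[which(d$dv[obs] <= 0)][1],
            "observations must be > 0 before log transform")
  for (s in unique(d$id)) {
    rows <- d[d$id == s, , drop = FALSE]
    if (!any(rows$evid == 1L & rows$time == 0))
      stop("subject ", s, " has no dose record at time 0")
    covs <- intersect(c("BW", "BSA", "GFR", "AGE", "group"), names(rows))
    for (cv in covs)
      if (length(unique(rows[[cv]])) > 1L)
        stop("subject ", s, ": covariate ", cv,
             " varies within subject (single-occasion study)")
  }
  invisible(ds)
}

#' @export
print.pk_dataset <- function(x, ...) {
  d <- x$data
  obs <- d$evid == 0L & d$mdv == 0L
  cat("pk_dataset:", length(unique(d$id)), "subjects,", nrow(d), "records (",
      sum(d$evid == 1L), "doses,", sum(obs), "observations )\n")
  cat("  LOQ:", x$loq, "pg/mL | scale:",
      if (x$log_scale) "log" else "linear", "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Observation records of a dataset
#' @param ds a [pk_dataset].
#' @return data frame of rows with `evid == 0` and `mdv == 0`.
#' @export
observations <- function(ds) {
  d <- ds$data
  d[d$evid == 0L & d$mdv == 0L, , drop = FALSE]
}

#' Dose records of a dataset
#' @param ds a [pk_dataset].
#' @return data frame of rows with `evid == 1`.
#' @export
doses <- function(ds) ds$data[ds$data$evid == 1L, , drop = FALSE]

.default_column_map <- c(id = "id", time = "time", amt = "amt", dv = "dv",
                         evid = "evid", mdv = "mdv")

#' Read a delimited NONMEM-style event table
#'
#' Accepts comma- or tab-delimited text with a header. Column names are
#' resolved through `column_map` (defaults to the conventional
#' id/time/amt/dv/evid/mdv names, case-insensitively). An `mdv` column is
#' derived from missing `dv` when absent, so "NA" observations in pre-dose
#' rows become non-observation placeholders rather than errors.
#'
#' @param path file to read.
#' @param column_map named character vector mapping the canonical names
#'   (`id`, `time`, `amt`, `dv`, `evid`, `mdv`) to the file's column names;
#'   entries may be omitted for `mdv`/`evid` (derived) and for columns whose
#'   names already match. May also be the path of a YAML file with fields
#'   `columns:` and optionally `loq:`.
#' @param loq limit of quantification to store (pg/mL).
#' @return a validated [pk_dataset].
#' @export
read_pk_dataset <- function(path, column_map = NULL, loq = 4) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(column_map) && length(column_map) == 1L &&
      file.exists(column_map) && grepl("\\.ya?ml$", column_map)) {
    cfg <- yaml::read_yaml(column_map)
    if (!is.null(cfg$loq)) loq <- cfg$loq
    column_map <- unlist(cfg$columns)
  }
  cmap <- .default_column_map
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("NA", "", "."))
  lookup <- function(canon, required = TRUE) {
    hit <- match(tolower(cmap[[canon]]), tolower(names(raw)))
    if (is.na(hit)) {
      if (required)
        stop("configuration error: column '", cmap[[canon]],
             "' (", canon, ") not found in ", path)
      return(NULL)
    }
    raw[[hit]]
  }
  num <- function(x, what) {
    if (is.null(x)) return(NULL)
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      stop("parse error: non-numeric ", what, " at data row ", bad[1],
           " ('", x[bad[1]], "')")
    v
  }
  d <- data.frame(id = as.character(lookup("id")),
                  time = num(lookup("time"), "time"),
                  amt = num(lookup("amt"), "amount"),
                  dv = num(lookup("dv"), "observation"),
                  stringsAsFactors = FALSE)
  evid <- lookup("evid", required = FALSE)
  d$evid <- if (is.null(evid)) as.integer(!is.na(d$amt) & d$amt > 0) else
    as.integer(num(evid, "evid"))
  mdv <- lookup("mdv", required = FALSE)
  d$mdv <- if (is.null(mdv)) as.integer(d$evid == 1L | is.na(d$dv)) else
    as.integer(num(mdv, "mdv"))
  used <- unique(c(cmap, "evid", "mdv"))
  extra <- setdiff(names(raw), names(raw)[tolower(names(raw)) %in% tolower(used)])
  for (cv in extra) d[[cv]] <- raw[[cv]]
  pk_dataset(d, loq = loq, provenance = path)
}

#' Write a dataset as delimited text
#'
#' @param ds a [pk_dataset].
#' @param path output path; `.tsv` extension writes tab-delimited, anything
#'   else comma-delimited.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(ds, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(ds$data, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Exclude observations below the limit of quantification
#'
#' Removes observation records with `dv < loq` (dose and placeholder records
#' are untouched) and reports the excluded percentage of observation records.
#'
#' @param ds a [pk_dataset] on the linear concentration scale.
#' @param loq threshold in pg/mL; defaults to the dataset's stored LOQ.
#' @return list with `dataset` (filtered [pk_dataset]) and
#'   `excluded_fraction` (percent of observations removed), plus counts
#'   `n_excluded` and `n_obs`.
#' @export
apply_loq_filter <- function(ds, loq = ds$loq) {
  if (ds$log_scale)
    stop("apply the LOQ filter before the log transform")
  if (!is.numeric(loq) || loq <= 0) stop("loq must be > 0")
  d <- ds$data
  obs <- d$evid == 0L & d$mdv == 0L
  drop <- obs & d$dv < loq
  n_obs <- sum(obs)
  out <- ds
  out$data <- d[!drop, , drop = FALSE]
  rownames(out$data) <- NULL
  out$loq <- loq
  if (n_obs > 0 && sum(drop) == n_obs)
    warning("all observations fall below the LOQ; empty analysis set")
  list(dataset = out,
       excluded_fraction = if (n_obs == 0) 0 else 100 * sum(drop) / n_obs,
       n_excluded = sum(drop), n_obs = n_obs)
}

#' Natural-log transform of the observations
#'
#' Replaces observation `dv` values by their natural logarithm and marks the
#' dataset as log-scale, so a second transform is refused. Apply
#' [apply_loq_filter()] first so no non-positive observations remain.
#'
#' @param ds a [pk_dataset] on the linear scale.
#' @return the transformed [pk_dataset].
#' @export
log_transform_obs <- function(ds) {
  if (ds$log_scale)
    stop("dataset is already on the log scale")
  d <- ds$data
  obs <- d$evid == 0L & d$mdv == 0L
  if (any(d$dv[obs] <= 0)) {
    i <- which(obs)[which(d$dv[obs] <= 0)][1]
    stop("record ", i, " (subject ", d$id[i], ", t = ", d$time[i],
         " h): non-positive observation cannot be log-transformed")
  }
  d$dv[obs] <- log(d$dv[obs])
  ds$data <- d
  ds$log_scale <- TRUE
  ds
}
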