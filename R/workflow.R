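# Command-line style workflow driver wiring the modules together:
# simulate, fit, scm, vpc, nca and an end-to-end recover subcommand.

parse_args <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1 <= length(argv) && !startsWith(argv[i + 1], "--")) {
        out[[key]] <- argv[i + 1]; i <- i + 2
      } else { out[[key]] <- TRUE; i <- i + 1 }
    } else { out$subcommand <- c(out$subcommand, a); i <- i + 1 }
  }
  out
}

workflow_usage <- function() {
  paste(
    "usage: poppk <subcommand> [--options]",
    "subcommands:",
    "  simulate --seed S --out DIR [--model model.yaml] [--censor drop|flag|none]",
    "  fit      --data data.csv --out DIR [--model model.yaml] [--no-covariance]",
    "  scm      --data data.csv --out DIR [--model model.yaml]",
    "  vpc      --data data.csv --out DIR [--model model.yaml] [--nsim N] [--seed S]",
    "  nca      --data data.csv --out DIR [--model model.yaml] [--mode ebe|observed]",
    "  recover  --seed S --out DIR [--model model.yaml]",
    "All stochastic subcommands require --seed; every run writes a",
    "manifest.yaml with the configuration needed to reproduce it.",
    sep = "\n")
}

#' Run a workflow subcommand
#'
#' Thin command-line entry point over the package functions; see
#' `inst/scripts/poppk-cli.R` for the Rscript wrapper. Subcommands:
#' `simulate` (synthetic study + truth sidecar), `fit` (FOCE fit files),
#' `scm` (trace + final model), `vpc` (percentile table), `nca`
#' (secondary-parameter table), `recover` (simulate, fit and compare
#' estimates against the generating truth).
#'
#' @param argv character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, invisibly (0 on success); output files are
#'   written under `--out`.
#' @export
run_workflow <- function(argv) {
  args <- parse_args(argv)
  sub <- args$subcommand[1]
  valid <- c("simulate", "fit", "scm", "vpc", "nca", "recover")
  if (is.null(sub) || !sub %in% valid) {
    message(workflow_usage())
    return(invisible(1L))
  }
  out <- tryCatch({
    run_workflow_impl(sub, args)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(out)
}

need <- function(args, key, what = key) {
  if (is.null(args[[key]])) stop("missing required --", key, " (", what, ")")
  args[[key]]
}

fresh_path <- function(dir, name, force) {
  p <- file.path(dir, name)
  if (file.exists(p) && !force)
    stop(p, " exists; use --force to overwrite")
  p
}

run_workflow_impl <- function(sub, args) {
  outdir <- need(args, "out", "output directory")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  force <- isTRUE(args$force) || identical(args$force, "TRUE")
  model <- if (!is.null(args$model)) read_model_yaml(args$model) else
    reference_model()
  manifest <- list(subcommand = sub,
                   args = args[setdiff(names(args), "subcommand")],
                   package_version = as.character(
                     utils::packageVersion("poppkdual")),
                   r_version = R.version.string)
  load_data <- function() {
    ds <- read_pk_dataset(need(args, "data", "dataset path"))
    flt <- apply_loq_filter(ds)
    log_transform_obs(flt$dataset)
  }
  if (sub == "simulate") {
    seed <- as.integer(need(args, "seed"))
    censor <- if (is.null(args$censor)) "drop" else args$censor
    base <- fresh_path(outdir, "study.csv", force)
    generate_study(model, design = study_design(censor = censor),
                   seed = seed, path = sub("\\.csv$", "", base))
  } else if (sub == "fit") {
    lds <- load_data()
    fit <- fit_foce(model, lds,
                    covariance = if (isTRUE(args[["no-covariance"]]))
                      "none" else "hessian")
    fresh_path(outdir, "fit.csv", force)
    write_fit_result(fit, file.path(outdir, "fit"))
    write_model_yaml(fit$model, file.path(outdir, "final_model.yaml"))
  } else if (sub == "scm") {
    lds <- load_data()
    base <- model
    base$covariates <- base$covariates[0, , drop = FALSE]
    res <- run_scm(base, default_candidates(), lds)
    fresh_path(outdir, "scm_trace.csv", force)
    write_scm_trace(res, file.path(outdir, "scm_trace.csv"))
    write_model_yaml(res$final$model, file.path(outdir, "final_model.yaml"))
  } else if (sub == "vpc") {
    lds <- load_data()
    seed <- as.integer(need(args, "seed"))
    nsim <- if (is.null(args$nsim)) 1000 else as.integer(args$nsim)
    tab <- vpc(model, lds, nsim = nsim, seed = seed)
    p <- fresh_path(outdir, "vpc.csv", force)
    write.csv(as.data.frame(tab), p, row.names = FALSE, quote = FALSE)
  } else if (sub == "nca") {
    lds <- load_data()
    mode <- if (is.null(args$mode)) "ebe" else args$mode
    tab <- nca(model, lds, mode = mode)
    p <- fresh_path(outdir, "nca.csv", force)
    write.csv(tab, p, row.names = FALSE, quote = FALSE)
  } else if (sub == "recover") {
    seed <- as.integer(need(args, "seed"))
    study <- generate_study(model, seed = seed)
    lds <- log_transform_obs(apply_loq_filter(study$dataset)$dataset)
    fit <- fit_foce(model, lds, covariance = "none")
    truth <- pack_map(model)
    est_tab <- fit$estimates
    truth_rep <- vapply(seq_len(nrow(truth)), function(i)
      from_est_scale(pack_params(model, truth)[i], truth$transform[i]),
      numeric(1))
    cmp <- data.frame(parameter = est_tab$parameter,
                      truth = truth_rep, estimate = est_tab$estimate,
                      rel_err_pct = 100 * (est_tab$estimate - truth_rep) /
                        truth_rep)
    p <- fresh_path(outdir, "recovery.csv", force)
    write.csv(cmp, p, row.names = FALSE, quote = FALSE)
  }
  manifest$seed <- args$seed
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(NULL)
}
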