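#' Write a run manifest
#'
#' Every output directory gets exactly one `manifest.json` recording the
#' seed, a digest of the configuration/inputs, the package version and a
#' timestamp, so that a rerun with identical inputs can be recognised and
#' reproduced.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed used for the run (or `NA`).
#' @param input_files Character vector of input paths (may be empty).
#' @param config_hash Digest string for the configuration.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(out_dir, seed, input_files = character(0),
                           config_hash = NA_character_) {
  manifest <- list(
    tool = "gadnca",
    tool_version = as.character(utils::packageVersion("gadnca")),
    seed = seed,
    config_hash = config_hash,
    input_files = input_files,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

file_hash <- function(path) unname(tools::md5sum(path))

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_cohort_config(config, tmp)
  file_hash(tmp)
}

#' Simulate a cohort and write its CSVs
#'
#' @param config A [cohort_config()], or a path to a JSON config.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config's seed.
#' @param verbose Print a per-group summary line.
#' @return Invisibly, a list with the output paths and the cohort.
#' @export
cmd_simulate <- function(config, out_dir, seed = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_cohort_config(config)
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  cohort_csv <- file.path(out_dir, "cohort.csv")
  dosing_csv <- file.path(out_dir, "dosing.csv")
  write_cohort_csv(cohort, cohort_csv, dosing_csv)
  write_cohort_config(config, file.path(out_dir, "config.json"))
  write_manifest(out_dir, config$seed, config_hash = config_hash(config))
  if (verbose) {
    message(sprintf("simulated %d subjects (%s) with seed %d",
                    sum(config$group_sizes),
                    paste(config$group_sizes, collapse = "/"), config$seed))
  }
  invisible(list(cohort_csv = cohort_csv, dosing_csv = dosing_csv,
                 cohort = cohort))
}

#' Run per-subject NCA over cohort CSVs
#'
#' Produces a wide parameter table (one row per evaluable subject, the full
#' NCA parameter set plus diagnostics) and a failure listing for subjects
#' that could not be analysed.
#'
#' @param cohort_csv,dosing_csv Input CSVs (see [write_cohort_csv()]). A
#'   subject present in the cohort but missing from the dosing table is a
#'   hard error, since clearance requires the dose.
#' @param out_dir Output directory.
#' @param verbose One log line per subject.
#' @param ... Passed to [run_nca()] (e.g. `lambda_z_window`, `clast`).
#' @return Invisibly, a list with `parameters`, `failures` and `status`
#'   (0 = all evaluable, 3 = some subjects not evaluable).
#' @export
cmd_nca <- function(cohort_csv, dosing_csv, out_dir, verbose = FALSE, ...) {
  profiles <- read_cohort_csv(cohort_csv, dosing_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- nca_cohort(profiles, ...)
  if (verbose) {
    for (i in seq_len(NROW(res$parameters))) {
      r <- res$parameters[i, ]
      message(sprintf("%s [%s] CL=%.2f mL/min flags=[%s]",
                      r$subject_id, r$group, r$cl, r$quality_flags))
    }
    for (i in seq_len(nrow(res$failures))) {
      message(sprintf("%s [%s] NOT EVALUABLE: %s", res$failures$subject_id[i],
                      res$failures$group[i], res$failures$reason[i]))
    }
  }
  utils::write.csv(res$parameters, file.path(out_dir, "parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(res$failures, file.path(out_dir, "failures.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, NA_integer_,
                 input_files = c(cohort_csv, dosing_csv),
                 config_hash = paste(file_hash(cohort_csv),
                                     file_hash(dosing_csv), sep = "+"))
  invisible(list(parameters = res$parameters, failures = res$failures,
                 status = if (nrow(res$failures)) 3L else 0L))
}

#' Compare groups from a parameter table CSV
#'
#' Writes the comparison report as JSON plus a human-readable text rendering
#' (values rounded to one decimal in the text only).
#'
#' @param parameters_csv Path to the wide parameter CSV from [cmd_nca()].
#' @param out_dir Output directory.
#' @param parameters Parameter columns to test (default: standard NCA set).
#' @return Invisibly, a list with the `group_comparison_report` and
#'   `status` (0, or 2 when only one group is present and the comparison is
#'   skipped).
#' @export
cmd_compare <- function(parameters_csv, out_dir,
                        parameters = c("auc_last", "auc_inf",
                                       "auc_extrapolated_pct",
                                       "auc_inf_per_dose", "cmax",
                                       "cmax_per_dose", "cl", "v_ss", "v_z",
                                       "t_half_beta", "t_half_eff")) {
  table <- utils::read.csv(parameters_csv, stringsAsFactors = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  parameters <- intersect(parameters, names(table))
  if (length(unique(table$group)) < 2L) {
    warning("only one group present: writing summary, skipping comparison",
            call. = FALSE)
    summ <- summarize_groups(table, parameters)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    return(invisible(list(report = NULL, status = 2L)))
  }
  report <- compare_groups(table, parameters)
  jsonlite::write_json(report_to_list(report),
                       file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  write_manifest(out_dir, NA_integer_, input_files = parameters_csv,
                 config_hash = file_hash(parameters_csv))
  invisible(list(report = report, status = 0L))
}

#' Run the whole pipeline: simulate, NCA, compare
#'
#' @param config A [cohort_config()] or JSON path.
#' @param out_dir Output directory; stage outputs land in subdirectories
#'   `simulate/`, `nca/`, `compare/`.
#' @param seed Optional seed override.
#' @param verbose Passed to the stages.
#' @param ... Passed to [run_nca()].
#' @return Invisibly, a list with each stage's result and an overall
#'   `status`.
#' @export
cmd_all <- function(config, out_dir, seed = NULL, verbose = FALSE, ...) {
  sim <- cmd_simulate(config, file.path(out_dir, "simulate"), seed = seed,
                      verbose = verbose)
  nca <- cmd_nca(sim$cohort_csv, file.path(out_dir, "simulate", "dosing.csv"),
                 file.path(out_dir, "nca"), verbose = verbose, ...)
  cmp <- cmd_compare(file.path(out_dir, "nca", "parameters.csv"),
                     file.path(out_dir, "compare"))
  invisible(list(simulate = sim, nca = nca, compare = cmp,
                 status = max(nca$status, cmp$status)))
}

#' Command-line entry point
#'
#' Thin argv dispatcher used by the `gadnca` Rscript (see
#' `system.file("cli", "gadnca.R", package = "gadnca")`). Subcommands:
#' `simulate`, `nca`, `compare`, `all`. Flags: `--config PATH`,
#' `--cohort PATH`, `--dosing PATH`, `--parameters PATH`, `--seed INT`,
#' `--out-dir DIR`, `--lambda-z-window LO,HI`, `--clast pred|obs`,
#' `--verbose`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status: 0 success, 2 validation failure, 3 partial
#'   (some subjects not evaluable).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: gadnca <simulate|nca|compare|all> [flags]",
    "  simulate --config cfg.json --out-dir DIR [--seed N] [--verbose]",
    "  nca      --cohort cohort.csv --dosing dosing.csv --out-dir DIR",
    "           [--lambda-z-window LO,HI] [--clast pred|obs] [--verbose]",
    "  compare  --parameters parameters.csv --out-dir DIR",
    "  all      --config cfg.json --out-dir DIR [--seed N] [--verbose]",
    sep = "\n")
  if (!length(argv)) { message(usage); return(2L) }
  sub <- argv[1]
  opts <- parse_flags(argv[-1])
  if (inherits(opts, "error")) {
    message("error: ", conditionMessage(opts)); return(2L)
  }
  run <- function() {
    out_dir <- opts$`out-dir`
    if (is.null(out_dir)) stop("--out-dir is required", call. = FALSE)
    verbose <- isTRUE(opts$verbose)
    nca_args <- list()
    if (!is.null(opts$`lambda-z-window`)) {
      nca_args$lambda_z_window <-
        as.numeric(strsplit(opts$`lambda-z-window`, ",")[[1]])
    }
    if (!is.null(opts$clast)) nca_args$clast <- opts$clast
    switch(sub,
      simulate = {
        if (is.null(opts$config)) stop("--config is required", call. = FALSE)
        cmd_simulate(opts$config, out_dir, seed = opts$seed,
                     verbose = verbose)
        0L
      },
      nca = {
        if (is.null(opts$cohort) || is.null(opts$dosing)) {
          stop("--cohort and --dosing are required", call. = FALSE)
        }
        do.call(cmd_nca, c(list(opts$cohort, opts$dosing, out_dir,
                                verbose = verbose), nca_args))$status
      },
      compare = {
        if (is.null(opts$parameters)) {
          stop("--parameters is required", call. = FALSE)
        }
        cmd_compare(opts$parameters, out_dir)$status
      },
      all = {
        if (is.null(opts$config)) stop("--config is required", call. = FALSE)
        do.call(cmd_all, c(list(opts$config, out_dir, seed = opts$seed,
                                verbose = verbose), nca_args))$status
      },
      { message("unknown subcommand: ", sub, "\n", usage); 2L })
  }
  tryCatch(run(), error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
}

parse_flags <- function(args) {
  tryCatch({
    opts <- list()
    i <- 1L
    while (i <= length(args)) {
      a <- args[i]
      if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
      key <- substring(a, 3)
      if (key == "verbose") {
        opts$verbose <- TRUE
        i <- i + 1L
      } else {
        if (i == length(args)) stop("flag --", key, " needs a value",
                                    call. = FALSE)
        val <- args[i + 1L]
        opts[[key]] <- if (key == "seed") as.integer(val) else val
        i <- i + 2L
      }
    }
    opts
  }, error = function(e) e)
}
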