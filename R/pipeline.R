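# CSV schemas, configuration and the simulate -> invert -> fit -> report
# pipeline.
#
# CSV dialect: UTF-8, comma-separated, mandatory header, '.' decimal, pCa as
# positive decimal (e.g. 4.5).

MEASUREMENT_COLUMNS <- c("trabecula_id", "probe", "sl_um", "pca",
                         "treatment", "i_pp", "i_pt", "i_tp", "i_tt",
                         "force")

#' Read and validate a measurement table
#'
#' @param path CSV file with one row per steady-state measurement and at
#'   least the columns `trabecula_id, probe, sl_um, pca, treatment, i_pp,
#'   i_pt, i_tp, i_tt, force`.
#' @return Data frame of measurements.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, MEASUREMENT_COLUMNS, path)
  df
}

check_columns <- function(df, required, context = "input") {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", context,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Invert polarized intensities for every measurement row
#'
#' Applies [invert_intensities()] row-wise, appending `p2`, `p4`, `scale`,
#' `feasibility_flag` and the `i_pt`/`i_tp` discrepancy metric.
#'
#' @param records Measurement data frame (see [read_measurements()]).
#' @return The data frame with order-parameter columns appended.
#' @export
invert_records <- function(records) {
  check_columns(records, c("i_pp", "i_pt", "i_tp", "i_tt"), "records")
  res <- lapply(seq_len(nrow(records)), function(i) {
    inv <- invert_intensities(list(i_pp = records$i_pp[i],
                                   i_pt = records$i_pt[i],
                                   i_tp = records$i_tp[i],
                                   i_tt = records$i_tt[i]))
    c(p2 = inv$order_params$p2, p4 = inv$order_params$p4,
      scale = inv$scale,
      feasibility_flag = as.numeric(inv$order_params$feasibility_flag),
      ipt_itp_diff = inv$ipt_itp_diff)
  })
  cbind(records, as.data.frame(do.call(rbind, res)))
}

#' Fit Hill curves for every (trabecula, condition) cell
#'
#' Groups inverted records by trabecula, probe, sarcomere length and
#' treatment, fits the Hill equation to the `<P2>`-pCa and force-pCa series
#' (force with baseline fixed at 0), and assembles the per-preparation fit
#' report consumed by [build_summary_table()].  Force fits are skipped (row
#' of `NA`) when the force range is negligible (e.g. under full myosin
#' inhibition the titration is flat and the Hill parameters are
#' unidentified); such rows carry `degenerate = TRUE`.
#'
#' @param records Data frame from [invert_records()] (must contain `p2`).
#' @return Fit-report data frame: one row per (trabecula, probe, sl_um,
#'   treatment, response_kind) with `pca50`, `se_pca50`, `n_h`, `se_nh`,
#'   `baseline`, `amplitude`, `fmax`, `resp_pca6`, `resp_pca45`, `delta`,
#'   `converged`, `degenerate`.
#' @export
fit_records <- function(records) {
  check_columns(records, c(MEASUREMENT_COLUMNS, "p2"), "records")
  keys <- unique(records[c("trabecula_id", "probe", "sl_um", "treatment")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- merge(records, keys[i, , drop = FALSE])
    for (kind in c("p2", "force")) {
      y <- if (kind == "p2") sub$p2 else sub$force
      cv <- titration_curve(sub$pca, y, kind, probe = keys$probe[i],
                            sl_um = keys$sl_um[i],
                            treatment = keys$treatment[i],
                            trabecula_id = keys$trabecula_id[i])
      fit <- NULL
      if (kind == "force" && diff(range(y)) < 1e-9 * max(abs(y), 1)) {
        fit <- NULL           # flat force curve: unidentified
      } else {
        fit <- tryCatch(
          fit_hill(cv, fix_baseline = if (kind == "force") 0 else NULL),
          error = function(e) NULL)
      }
      d <- tryCatch(delta_p2(cv), error = function(e) NA_real_)
      at <- function(target) {
        hit <- abs(sub$pca - target) < 1e-6
        if (any(hit)) mean(y[hit]) else NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        trabecula_id = keys$trabecula_id[i], probe = keys$probe[i],
        sl_um = keys$sl_um[i], treatment = keys$treatment[i],
        response_kind = kind,
        pca50 = if (is.null(fit)) NA_real_ else fit$pca50,
        se_pca50 = if (is.null(fit)) NA_real_ else fit$se_pca50,
        n_h = if (is.null(fit)) NA_real_ else fit$n_h,
        se_nh = if (is.null(fit)) NA_real_ else fit$se_nh,
        baseline = if (is.null(fit)) NA_real_ else fit$baseline,
        amplitude = if (is.null(fit)) NA_real_ else fit$amplitude,
        fmax = if (kind == "force") {
          if (is.null(fit)) max(y) else fit$baseline + fit$amplitude
        } else NA_real_,
        resp_pca6 = at(6.0), resp_pca45 = at(4.5), delta = d,
        converged = if (is.null(fit)) FALSE else fit$converged,
        degenerate = if (is.null(fit)) TRUE else fit$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run configuration for the analysis pipeline
#'
#' @param stages Subset of `c("simulate", "invert", "fit", "report")`, run
#'   in that order.
#' @param seed Master seed for the simulate stage.
#' @param out_dir Output directory (created if needed).
#' @param input Path to a measurement CSV (required when `"simulate"` is
#'   not among the stages).
#' @param n_trabeculae,probe,treatments Simulate-stage settings.
#' @param noise A [noise_model()].
#' @param layout Summary-table layout for the report stage.
#' @param alpha Significance level for flags, in (0, 1).
#' @return A list of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "invert", "fit", "report"),
                       seed = 1L, out_dir = tempfile("fiberpol_run_"),
                       input = NULL, n_trabeculae = 5L, probe = "cTnC-C",
                       treatments = "control", noise = noise_model(),
                       layout = "table1", alpha = 0.05) {
  stages <- match.arg(stages, c("simulate", "invert", "fit", "report"),
                      several.ok = TRUE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  if (!"simulate" %in% stages && (is.null(input) || !file.exists(input))) {
    stop("without a simulate stage, 'input' must name an existing CSV",
         call. = FALSE)
  }
  structure(list(stages = stages, seed = as.integer(seed),
                 out_dir = out_dir, input = input,
                 n_trabeculae = n_trabeculae, probe = probe,
                 treatments = treatments, noise = noise, layout = layout,
                 alpha = alpha),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [run_config()]; the `noise`
#' key may be a mapping with `intensity_cv`, `force_cv`, `pca50_sd`,
#' `baseline_p2_sd`.
#'
#' @param path YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  nm <- if (is.null(y$noise)) noise_model() else do.call(noise_model, y$noise)
  run_config(stages = y$stages %||% c("simulate", "invert", "fit", "report"),
             seed = y$seed %||% 1L,
             out_dir = y$out_dir %||% tempfile("fiberpol_run_"),
             input = y$input,
             n_trabeculae = y$n_trabeculae %||% 5L,
             probe = y$probe %||% "cTnC-C",
             treatments = y$treatments %||% "control",
             noise = nm,
             layout = y$layout %||% "table1",
             alpha = y$alpha %||% 0.05)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(
    config[setdiff(names(config), "out_dir")],
    auto_unbox = TRUE, force = TRUE, digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

#' Execute the analysis pipeline
#'
#' Runs the selected stages in order: `simulate` (synthetic cohort, writes
#' `records.csv` and `records.truth.csv`), `invert` (intensities to order
#' parameters, `inverted.csv`), `fit` (Hill fits, `fit_report.csv`),
#' `report` (summary table, `summary.csv` and `summary.txt`).  Every output
#' carries the configuration hash in a header comment line; a plain-text
#' log records seeds, package version and the defaults in force.  Re-running
#' with the same configuration and seed is byte-identical.
#'
#' @param config A [run_config()] or path to a YAML config.
#' @return Invisibly, a list with the in-memory stage outputs and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  paths <- list()
  log_lines <- c(sprintf("fiberpol %s",
                         as.character(utils::packageVersion("fiberpol"))),
                 sprintf("config_hash: %s", hash),
                 sprintf("seed: %d", config$seed),
                 sprintf("stages: %s", paste(config$stages, collapse = ",")),
                 sprintf("noise: intensity_cv=%g force_cv=%g pca50_sd=%g baseline_p2_sd=%g",
                         config$noise$intensity_cv, config$noise$force_cv,
                         config$noise$pca50_sd, config$noise$baseline_p2_sd),
                 "defaults: static uniaxial optical model; force fits with baseline 0; delta-closure p4 companion; alpha flags are single paired t-tests (no multiple-testing correction)")

  write_out <- function(df, name) {
    p <- file.path(config$out_dir, name)
    con <- file(p, "w", encoding = "UTF-8")
    writeLines(sprintf("# fiberpol config_hash=%s", hash), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    paths[[name]] <<- p
    p
  }

  records <- truth <- NULL
  if ("simulate" %in% config$stages) {
    sim <- generate_cohort(config$n_trabeculae, probe = config$probe,
                           noise = config$noise,
                           master_seed = config$seed,
                           treatments = config$treatments)
    records <- sim$records
    truth <- sim$truth
    write_out(records, "records.csv")
    write_out(truth, "records.truth.csv")
  } else {
    records <- read_measurements(config$input)
  }

  inverted <- fits <- summary_tbl <- NULL
  if ("invert" %in% config$stages) {
    inverted <- invert_records(records)
    write_out(inverted, "inverted.csv")
  }
  if ("fit" %in% config$stages) {
    if (is.null(inverted)) inverted <- invert_records(records)
    fits <- fit_records(inverted)
    write_out(fits, "fit_report.csv")
  }
  if ("report" %in% config$stages) {
    if (is.null(fits)) fits <- fit_records(invert_records(records))
    summary_tbl <- build_summary_table(fits, layout = config$layout,
                                       alpha = config$alpha)
    write_out(as.data.frame(summary_tbl), "summary.csv")
    txt <- file.path(config$out_dir, "summary.txt")
    writeLines(c(sprintf("# fiberpol config_hash=%s", hash),
                 format_summary_table(summary_tbl)), txt)
    paths[["summary.txt"]] <- txt
  }
  log_path <- file.path(config$out_dir, "run.log")
  writeLines(log_lines, log_path)
  paths[["run.log"]] <- log_path
  invisible(list(records = records, truth = truth, inverted = inverted,
                 fits = fits, summary = summary_tbl, paths = paths,
                 config_hash = hash))
}
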