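# Pipeline entry points binding the stages into the two workflows:
# characterise-then-predict and predict-then-decompose. Everything flows
# through files named in a JSON config; no hidden state between runs.
# A thin command-line wrapper over these functions is installed at
# exec/ribocap.

pipeline_keys <- c("seed", "output_dir", "params_file", "verbosity",
                   "simulate", "characterise", "predict", "generate")

#' Read and validate a pipeline configuration
#'
#' @param config Path to a JSON config file, or an equivalent named list.
#'   Recognised top-level keys: `seed`, `output_dir`, `params_file`,
#'   `verbosity`, and one block per stage (`simulate`, `characterise`,
#'   `predict`, `generate`). Unknown keys are rejected.
#' @return A validated config list of class `ribocap_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop_input(sprintf("config file '%s' does not exist", config))
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop_input("config must be a file path or a list")
  unknown <- setdiff(names(config), pipeline_keys)
  if (length(unknown) > 0) {
    stop_input(paste0("unknown config key(s): ",
                      paste(unknown, collapse = ", ")))
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$output_dir <- config$output_dir %||% "."
  config$verbosity <- config$verbosity %||% "info"
  structure(config, class = c("ribocap_config", "list"))
}

pipeline_params <- function(config) {
  if (!is.null(config$params_file)) {
    read_model_params(config$params_file)
  } else {
    model_params()
  }
}

pipeline_log <- function(config, ...) {
  if (identical(config$verbosity, "quiet")) return(invisible())
  message("[ribocap] ", sprintf(...))
}

# machine-readable provenance: enough to reproduce deterministic stages
write_provenance <- function(config, stage, outputs) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$output_dir,
                    paste0("provenance_", stage, ".json"))
  jsonlite::write_json(list(
    stage = stage,
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ribocap")),
    outputs = as.character(outputs),
    timestamp = format(Sys.time(), tz = "UTC")
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the simulation stage
#'
#' Simulates either a capacity heat-map grid (`simulate$lengths`,
#' `simulate$gammas`, `simulate$rbs_strength`) or a table of explicit
#' species designs (`simulate$designs_file`, a constructs CSV), and writes
#' `capacities.csv` to the output directory.
#'
#' @param config A config path or list (see [pipeline_config()]).
#' @return The capacity tibble, invisibly.
#' @export
run_simulate <- function(config) {
  config <- pipeline_config(config)
  sim <- config$simulate
  if (is.null(sim)) stop_input("config has no 'simulate' block")
  params <- pipeline_params(config)
  assay <- assay_config(model_params = params)
  if (!is.null(sim$designs_file)) {
    designs <- as_constructs(as_tibble(
      utils::read.csv(sim$designs_file, stringsAsFactors = FALSE)))
    out <- designs |>
      dplyr::mutate(capacity = map_dbl(seq_len(nrow(designs)), function(i) {
        normalized_capacity(designs[i, ], params)
      }))
  } else {
    for (k in c("lengths", "gammas", "rbs_strength")) {
      if (is.null(sim[[k]])) {
        stop_input(sprintf("simulate block needs '%s' (or a designs_file)", k))
      }
    }
    out <- capacity_grid(sim$lengths, sim$gammas, sim$rbs_strength, assay)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$output_dir, "capacities.csv")
  utils::write.csv(out, path, row.names = FALSE)
  write_provenance(config, "simulate", path)
  pipeline_log(config, "simulate: wrote %d capacities to %s", nrow(out), path)
  invisible(out)
}

#' Run the characterisation stage (lysate plate to gamma table)
#'
#' Reads a lysate plate CSV (`characterise$plate_file`) and a construct
#' annotation CSV (`characterise$constructs_file`, columns `name`,
#' `rbs_strength`, `length_bp`), extracts per-well maximal GFP rates,
#' normalizes against the monitor-alone wells (sample label
#' `characterise$monitor_sample`, default `"monitor_alone"`), averages
#' replicates, and inverts the model to a gamma estimate per construct.
#' Writes `gamma_table.csv`.
#'
#' @param config A config path or list.
#' @return The gamma tibble, invisibly.
#' @export
run_characterise <- function(config) {
  config <- pipeline_config(config)
  ch <- config$characterise
  if (is.null(ch)) stop_input("config has no 'characterise' block")
  for (k in c("plate_file", "constructs_file")) {
    if (is.null(ch[[k]])) {
      stop_input(sprintf("characterise block needs '%s'", k))
    }
  }
  monitor_sample <- ch$monitor_sample %||% "monitor_alone"
  params <- pipeline_params(config)
  assay <- assay_config(model_params = params)

  plate <- read_plate_csv(ch$plate_file)
  stats_tbl <- well_statistics(plate, mode = "lysate")
  ref_rows <- dplyr::filter(stats_tbl, .data$sample == monitor_sample)
  if (nrow(ref_rows) == 0) {
    stop_input(sprintf(
      "no monitor-alone reference wells (sample == '%s') in the plate",
      monitor_sample))
  }
  reference <- mean(ref_rows$raw_max_rate)
  annot <- as_tibble(utils::read.csv(ch$constructs_file,
                                     stringsAsFactors = FALSE))
  caps <- stats_tbl |>
    dplyr::filter(.data$sample != monitor_sample) |>
    dplyr::mutate(capacity = .data$raw_max_rate / reference) |>
    dplyr::inner_join(annot, by = c(sample = "name")) |>
    dplyr::rename(construct = "sample")
  if (nrow(caps) == 0) {
    stop_input("no test wells matched the construct annotation table")
  }
  gammas <- infer_gamma_batch(
    caps[c("construct", "capacity", "rbs_strength", "length_bp")],
    assay = assay)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$output_dir, "gamma_table.csv")
  utils::write.csv(gammas, path, row.names = FALSE)
  write_provenance(config, "characterise", path)
  pipeline_log(config, "characterise: %d gamma estimates to %s",
               nrow(gammas), path)
  invisible(gammas)
}

#' Run the prediction stage (designs to predicted burden)
#'
#' Reads operon designs (`predict$designs_file`: columns `operon`, `name`,
#' `rbs_strength`, `promoter`, `plasmid_conc`), joins per-gene gamma and
#' length from a gamma table (`predict$gamma_file`, as written by
#' [run_characterise()]), predicts normalized in vitro capacity per operon,
#' maps it in vivo through the calibration for `predict$condition`
#' (`predict$calibration` gives `slope`/`intercept`, or `predict$pairs_file`
#' provides points to fit), and, when `predict$measured_file` (columns
#' `operon`, `measured_in_vivo`) is given, appends the burden decomposition.
#' Writes `predictions.csv`.
#'
#' @param config A config path or list.
#' @return The prediction tibble, invisibly.
#' @export
run_predict <- function(config) {
  config <- pipeline_config(config)
  pr <- config$predict
  if (is.null(pr)) stop_input("config has no 'predict' block")
  for (k in c("designs_file", "gamma_file", "condition")) {
    if (is.null(pr[[k]])) stop_input(sprintf("predict block needs '%s'", k))
  }
  params <- pipeline_params(config)
  assay <- assay_config(model_params = params)

  designs <- as_tibble(utils::read.csv(pr$designs_file,
                                       stringsAsFactors = FALSE))
  need <- c("operon", "name", "rbs_strength", "promoter", "plasmid_conc")
  missing_cols <- setdiff(need, names(designs))
  if (length(missing_cols) > 0) {
    stop_input(paste0("designs table lacks column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  gammas <- as_tibble(utils::read.csv(pr$gamma_file,
                                      stringsAsFactors = FALSE))
  designs <- dplyr::left_join(
    designs, gammas[c("construct", "gamma", "length_bp")],
    by = c(name = "construct"))
  if (any(is.na(designs$gamma))) {
    stop_input(paste0(
      "no gamma estimate for gene(s): ",
      paste(unique(designs$name[is.na(designs$gamma)]), collapse = ", ")))
  }

  if (!is.null(pr$calibration)) {
    fit <- structure(
      list(slope = pr$calibration$slope,
           intercept = pr$calibration$intercept,
           r_squared = NA_real_, condition = pr$condition,
           n_points = NA_integer_, model = NULL,
           data = tibble(in_vitro = numeric(), in_vivo = numeric())),
      class = "ribocap_calibration")
  } else if (!is.null(pr$pairs_file)) {
    pairs <- as_tibble(utils::read.csv(pr$pairs_file,
                                       stringsAsFactors = FALSE))
    if ("condition" %in% names(pairs)) {
      pairs <- dplyr::filter(pairs, .data$condition == pr$condition)
    }
    fit <- fit_calibration(pairs, condition = pr$condition)
  } else {
    stop_input("predict block needs 'calibration' or 'pairs_file'")
  }

  out <- designs |>
    dplyr::group_by(.data$operon) |>
    dplyr::group_modify(function(df, key) {
      op <- operon_design(
        df[c("name", "rbs_strength", "length_bp", "gamma")],
        promoter = df$promoter[1], plasmid_conc = df$plasmid_conc[1])
      tibble(n_cistrons = nrow(df),
             predicted_in_vitro = predict_in_vitro(op, assay))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      predicted_in_vivo = predict_in_vivo(.data$predicted_in_vitro, fit),
      condition = pr$condition)

  if (!is.null(pr$measured_file)) {
    measured <- as_tibble(utils::read.csv(pr$measured_file,
                                          stringsAsFactors = FALSE))
    if (!all(c("operon", "measured_in_vivo") %in% names(measured))) {
      stop_input("measured table needs columns operon, measured_in_vivo")
    }
    out <- dplyr::inner_join(out, measured, by = "operon")
    dec <- decompose_burden(out$predicted_in_vivo, out$measured_in_vivo,
                            name = out$operon)
    out <- dplyr::bind_cols(
      out, dec[c("metabolic_component", "expression_component",
                 "over_predicted")])
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$output_dir, "predictions.csv")
  utils::write.csv(out, path, row.names = FALSE)
  write_provenance(config, "predict", path)
  pipeline_log(config, "predict: %d operon predictions to %s",
               nrow(out), path)
  invisible(out)
}

#' Run the synthetic-data stage
#'
#' Writes a complete demo dataset (see [generate_demo_dataset()]) into
#' `generate$dir` (default `<output_dir>/demo`), using the pipeline seed.
#' Generator fields (`n_constructs`, `noise_cv`, `metabolic_penalty`, ...)
#' may be overridden inside the `generate` block.
#'
#' @param config A config path or list.
#' @return The generated library, invisibly.
#' @export
run_generate <- function(config) {
  config <- pipeline_config(config)
  gen <- config$generate %||% list()
  dir <- gen$dir %||% file.path(config$output_dir, "demo")
  gen$dir <- NULL
  cfg_args <- modifyList(list(seed = config$seed), gen)
  cfg <- do.call(generator_config, cfg_args)
  res <- generate_demo_dataset(dir, cfg)
  write_provenance(config, "generate",
                   unlist(res[c("plate", "constructs", "pairs", "truth")]))
  pipeline_log(config, "generate: demo dataset in %s", dir)
  invisible(res$library)
}
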