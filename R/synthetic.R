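# Ground-truth-known synthetic data for every pipeline stage. The generator
# emulates the statistical structure of the real assays: lysate kinetics
# whose maximal windowed GFP rate carries the capacity signal, in vivo
# kinetics with sigmoidal growth and per-OD GFP production, and paired
# in vitro / in vivo capacities linked by condition-dependent linear
# calibrations, optionally offset by a metabolic penalty.

#' Configuration of the synthetic-data generator
#'
#' Defaults describe a realistic characterisation campaign: a construct
#' library spanning the observed range of synthesis costs (gamma 0.1-3
#' s^-1), standard RBS strengths (the monitor reference 1, a weak 0.5 and
#' the two bicistronic-design strengths 2.1 and 2.6), gene lengths from
#' short reporters to multi-domain enzymes, 5% multiplicative measurement
#' noise, triplicate measurements, and three growth conditions whose
#' calibration slope rises with growth rate (the standard condition uses
#' the reference relation y = 0.7x + 0.19).
#'
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @param n_constructs Library size.
#' @param gamma_range Log-uniform sampling bounds for gamma, s^-1.
#' @param rbs_choices RBS strengths sampled uniformly.
#' @param length_range Uniform sampling bounds for gene length, bp.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   measurement noise.
#' @param n_replicates Replicates per measurement (default 3).
#' @param conditions Data frame with columns `label`, `slope`, `intercept`:
#'   one linear in vitro to in vivo calibration per growth condition.
#' @param metabolic_penalty Additive in vivo capacity penalty applied to
#'   every construct (emulating an active metabolic pathway); default 0.
#' @return A list with class `ribocap_generator_config`.
#' @export
generator_config <- function(seed = 1L, n_constructs = 12,
                             gamma_range = c(0.1, 3),
                             rbs_choices = c(2.1, 2.6, 1.0, 0.5),
                             length_range = c(300, 3000),
                             noise_cv = 0.05, n_replicates = 3,
                             conditions = data.frame(
                               label = c("slow", "standard", "fast"),
                               slope = c(0.5, 0.7, 1.0),
                               intercept = c(0.30, 0.19, 0.0)),
                             metabolic_penalty = 0) {
  if (any(gamma_range <= 0) || any(length_range < 30) ||
      any(rbs_choices <= 0) || noise_cv < 0 || n_constructs < 1 ||
      n_replicates < 1) {
    stop_input("generator ranges must be positive (lengths >= 30 bp)")
  }
  if (!all(c("label", "slope", "intercept") %in% names(conditions))) {
    stop_input("conditions needs columns label, slope, intercept")
  }
  structure(
    list(seed = as.integer(seed), n_constructs = n_constructs,
         gamma_range = gamma_range, rbs_choices = rbs_choices,
         length_range = length_range, noise_cv = noise_cv,
         n_replicates = n_replicates, conditions = as_tibble(conditions),
         metabolic_penalty = metabolic_penalty),
    class = "ribocap_generator_config")
}

# unbiased multiplicative log-normal noise factors with the given CV
noise_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a construct library with known ground truth
#'
#' Samples constructs per the configuration, computes their true (noise-free)
#' in vitro capacities with the competitive translation model, derives true
#' in vivo capacities through each condition's linear calibration (minus any
#' metabolic penalty), and attaches noisy replicate observations of both.
#'
#' @param cfg A [generator_config()].
#' @param assay An [assay_config()] defining the model and assay doses.
#' @return A list of class `ribocap_library`: `constructs` (true parameters,
#'   a constructs tibble), `truth_in_vitro`, `truth_in_vivo`, `observed`
#'   (long tibble of noisy replicate capacities), and the `cfg` used.
#' @export
generate_library <- function(cfg = generator_config(),
                             assay = assay_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_constructs
  constructs <- as_constructs(tibble(
    name = sprintf("g%02d", seq_len(n)),
    rbs_strength = cfg$rbs_choices[sample.int(length(cfg$rbs_choices), n,
                                              replace = TRUE)],
    mrna_conc = assay_test_mrna(assay),
    length_bp = round(stats::runif(n, cfg$length_range[1],
                                   cfg$length_range[2])),
    gamma = exp(stats::runif(n, log(cfg$gamma_range[1]),
                             log(cfg$gamma_range[2])))
  ))

  truth_in_vitro <- constructs |>
    dplyr::mutate(capacity = map_dbl(seq_len(n), function(i) {
      normalized_capacity(constructs[i, ], assay$model_params)
    }))

  truth_in_vivo <- tidyr::expand_grid(
    name = constructs$name, condition = cfg$conditions$label) |>
    dplyr::left_join(cfg$conditions, by = c(condition = "label")) |>
    dplyr::left_join(truth_in_vitro[c("name", "capacity")], by = "name") |>
    dplyr::rename(capacity_in_vitro = "capacity") |>
    dplyr::mutate(
      metabolic_penalty = cfg$metabolic_penalty,
      capacity = pmin(pmax(.data$slope * .data$capacity_in_vitro +
                             .data$intercept - .data$metabolic_penalty,
                           0), 1))

  obs_vitro <- tidyr::expand_grid(
    name = constructs$name, replicate = seq_len(cfg$n_replicates)) |>
    dplyr::left_join(truth_in_vitro[c("name", "capacity")], by = "name") |>
    dplyr::mutate(mode = "lysate", condition = "lysate",
                  capacity = .data$capacity *
                    noise_factor(dplyr::n(), cfg$noise_cv))
  obs_vivo <- tidyr::expand_grid(
    name = constructs$name, condition = cfg$conditions$label,
    replicate = seq_len(cfg$n_replicates)) |>
    dplyr::left_join(truth_in_vivo[c("name", "condition", "capacity")],
                     by = c("name", "condition")) |>
    dplyr::mutate(mode = "in_vivo",
                  capacity = .data$capacity *
                    noise_factor(dplyr::n(), cfg$noise_cv))
  observed <- dplyr::bind_rows(obs_vitro, obs_vivo) |>
    dplyr::select("name", "mode", "condition", "replicate", "capacity")

  structure(
    list(constructs = constructs, truth_in_vitro = truth_in_vitro,
         truth_in_vivo = truth_in_vivo, observed = observed, cfg = cfg),
    class = "ribocap_library")
}

#' Synthetic lysate GFP kinetics
#'
#' A sigmoidal (interior-inflection) GFP accumulation whose maximal windowed
#' production rate is proportional to the supplied capacity truth, times one
#' multiplicative log-normal noise factor for the trace. Sampling every
#' 5 min over `span` hours. Because every trace shares the same shape,
#' normalizing an extracted maximal rate against a monitor-alone trace
#' recovers the truth exactly at zero noise.
#'
#' @param capacity_truth True normalized capacity (>= 0; 0 gives a flat
#'   trace).
#' @param cfg A [generator_config()] (supplies `noise_cv`; the RNG state is
#'   taken as-is — seed once per campaign).
#' @param span Trace duration in hours (default 6).
#' @param reference_rate Maximal GFP rate of a capacity-1 trace,
#'   fluorescence h^-1 (default 1e4).
#' @param well,sample Labels.
#' @return A [plate_time_series()] tibble.
#' @export
generate_lysate_trace <- function(capacity_truth, cfg = generator_config(),
                                  span = 6, reference_rate = 1e4,
                                  well = "A1", sample = "sample") {
  if (capacity_truth < 0) stop_input("capacity_truth must be >= 0")
  tt <- seq(0, span, by = 5 / 60)
  t0 <- span / 3
  tau <- 0.75
  sig <- function(z) 1 / (1 + exp(-z))
  # windowed rate at the inflection for a unit-amplitude sigmoid
  window_gain <- sig(0.5 / tau) - sig(-0.5 / tau)
  amplitude <- capacity_truth * reference_rate / window_gain
  gfp <- amplitude * (sig((tt - t0) / tau) - sig(-t0 / tau))
  gfp <- gfp * noise_factor(1, cfg$noise_cv)
  plate_time_series(time = tt, gfp = gfp, well = well, sample = sample,
                    condition = "lysate")
}

#' Synthetic in vivo growth and GFP kinetics
#'
#' OD grows sigmoidally on the log scale (symmetric about the mid-exponential
#' point, where the specific growth rate is maximal and equals
#' `growth_rate`); GFP accumulates at `capacity_truth * reference_rate *
#' OD(t)`, matching the per-OD production-rate statistic. Sampling every
#' 10 min.
#'
#' @param capacity_truth True normalized in vivo capacity.
#' @param growth_rate Maximal specific growth rate, h^-1.
#' @param cfg A [generator_config()].
#' @param span Duration in hours (default 10); the mid-exponential point
#'   sits at `span * 0.4`.
#' @param od_start,od_max Initial and saturating OD (defaults 0.05 and 1).
#' @param reference_rate Per-OD GFP rate of a capacity-1 strain,
#'   fluorescence h^-1 OD^-1 (default 1e3).
#' @param well,sample,condition Labels.
#' @return A [plate_time_series()] tibble with `gfp` and `od` channels.
#' @export
generate_invivo_trace <- function(capacity_truth, growth_rate,
                                  cfg = generator_config(), span = 10,
                                  od_start = 0.05, od_max = 1,
                                  reference_rate = 1e3,
                                  well = "A1", sample = "sample",
                                  condition = "standard") {
  if (growth_rate <= 0) stop_input("growth_rate must be positive")
  if (capacity_truth < 0) stop_input("capacity_truth must be >= 0")
  t0 <- span * 0.4
  amp <- log(od_max) - log(od_start)
  tau_g <- amp / (4 * growth_rate) # max d(log OD)/dt = growth_rate at t0
  sig <- function(z) 1 / (1 + exp(-z))
  od_at <- function(t) exp(log(od_start) + amp * sig((t - t0) / tau_g))
  # integrate GFP'(t) = truth * ref * OD(t) on a fine grid, then sample
  fine <- seq(0, span, by = 1 / 60)
  od_fine <- od_at(fine)
  gfp_fine <- c(0, cumsum((head(od_fine, -1) + tail(od_fine, -1)) / 2 *
                            diff(fine))) * capacity_truth * reference_rate
  tt <- seq(0, span, by = 10 / 60)
  idx <- round(tt * 60) + 1L
  gfp <- gfp_fine[idx] * noise_factor(1, cfg$noise_cv)
  plate_time_series(time = tt, gfp = gfp, od = od_at(tt), well = well,
                    sample = sample, condition = condition)
}

#' Write a complete synthetic demo dataset
#'
#' Generates a library, renders each construct (and monitor-alone reference
#' wells) as triplicate lysate kinetic traces, writes the plate CSV, the
#' construct annotation CSV, paired in vitro / in vivo capacities per
#' condition, and a ground-truth JSON — the same schemas the extraction and
#' pipeline readers consume.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [generator_config()].
#' @param assay An [assay_config()].
#' @return Invisibly, a named list of file paths plus the generated library.
#' @export
generate_demo_dataset <- function(dir, cfg = generator_config(),
                                  assay = assay_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lib <- generate_library(cfg, assay)

  # monitor-alone reference wells then one well per construct x replicate;
  # the RNG is already seeded by generate_library
  wells <- list()
  k <- 0
  for (r in seq_len(cfg$n_replicates)) {
    k <- k + 1
    wells[[k]] <- generate_lysate_trace(
      1, cfg, well = sprintf("REF%d", r), sample = "monitor_alone")
  }
  for (i in seq_len(nrow(lib$constructs))) {
    truth <- lib$truth_in_vitro$capacity[i]
    for (r in seq_len(cfg$n_replicates)) {
      k <- k + 1
      wells[[k]] <- generate_lysate_trace(
        truth, cfg, well = sprintf("W%02d_%d", i, r),
        sample = lib$constructs$name[i])
    }
  }
  plate <- dplyr::bind_rows(wells)

  paths <- list(
    plate = file.path(dir, "lysate_plate.csv"),
    constructs = file.path(dir, "constructs.csv"),
    pairs = file.path(dir, "capacity_pairs.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_plate_csv(plate, paths$plate)
  utils::write.csv(
    lib$constructs[c("name", "rbs_strength", "length_bp")],
    paths$constructs, row.names = FALSE)

  pairs <- lib$observed |>
    dplyr::group_by(.data$name, .data$mode, .data$condition) |>
    dplyr::summarise(capacity = mean(.data$capacity), .groups = "drop")
  vitro <- dplyr::filter(pairs, .data$mode == "lysate")
  vivo <- dplyr::filter(pairs, .data$mode == "in_vivo")
  paired <- dplyr::inner_join(
    dplyr::select(vitro, "name", in_vitro = "capacity"),
    dplyr::select(vivo, "name", "condition", in_vivo = "capacity"),
    by = "name")
  utils::write.csv(paired, paths$pairs, row.names = FALSE)

  truth <- list(
    seed = cfg$seed,
    constructs = as.data.frame(lib$truth_in_vitro),
    in_vivo = as.data.frame(lib$truth_in_vivo),
    metabolic_penalty = cfg$metabolic_penalty
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(c(paths, list(library = lib)))
}
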