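#' Lysate competition assay configuration
#'
#' Concentrations and model parameters describing the standard cell-free
#' competition assay: monitor plasmid plus test plasmid at a total DNA load
#' near expression saturation (50 nM).
#'
#' @param monitor_plasmid_conc Monitor plasmid, nM (default 30).
#' @param test_plasmid_conc Test construct plasmid, nM (default 20).
#' @param promoter_class Promoter class of the test construct, one of the
#'   labels known to [promoter_classes()] (default `"strong"`).
#' @param model_params A [model_params()] object.
#' @return A list with class `ribocap_assay`.
#' @export
assay_config <- function(monitor_plasmid_conc = 30, test_plasmid_conc = 20,
                         promoter_class = "strong",
                         model_params = ribocap::model_params()) {
  if (monitor_plasmid_conc <= 0 || test_plasmid_conc <= 0) {
    stop_input("plasmid concentrations must be positive")
  }
  structure(
    list(monitor_plasmid_conc = monitor_plasmid_conc,
         test_plasmid_conc = test_plasmid_conc,
         promoter_class = promoter_class,
         model_params = model_params),
    class = "ribocap_assay")
}

# mRNA concentration of the test construct implied by the assay
assay_test_mrna <- function(assay) {
  mrna_concentration(assay$promoter_class, assay$test_plasmid_conc)
}

#' Infer the lumped synthesis cost gamma from a measured capacity
#'
#' Inverts the competitive translation model: given the normalized in vitro
#' capacity measured with a test construct of known RBS strength and mRNA
#' length, finds the gamma at which the model reproduces that capacity.
#' Because capacity is strictly increasing in gamma, the inversion is a
#' bracketed monotone root-finding problem with a unique solution.
#'
#' @param measured_capacity Normalized capacity in (0, 1]. Replicates should
#'   be averaged beforehand (see [infer_gamma_batch()]).
#' @param rbs_strength RBS strength of the test construct.
#' @param length_bp mRNA length of the test construct, bp.
#' @param assay An [assay_config()].
#' @param tol Relative tolerance on the achieved capacity (default 1e-4).
#' @param bracket Search interval for gamma, s^-1 (default `c(1e-4, 1e2)`,
#'   enclosing all realistic per-gene costs with wide margin).
#' @param capacity_se Optional standard error of the measured capacity; when
#'   given, the gamma interval implied by +/- 1 s.e. is computed and the
#'   estimate flagged `wide_interval` if it spans more than 10-fold.
#' @return An object of class `ribocap_gamma_estimate` with fields `gamma`,
#'   `bracket`, `achieved_capacity`, `converged`, `wide_interval`.
#' @examples
#' \donttest{
#' cap <- normalized_capacity(
#'   construct("x", 2.6, 600, 720, gamma = 1.4))
#' infer_gamma(cap, rbs_strength = 2.6, length_bp = 720)
#' }
#' @export
infer_gamma <- function(measured_capacity, rbs_strength, length_bp,
                        assay = assay_config(), tol = 1e-4,
                        bracket = c(1e-4, 1e2), capacity_se = NULL) {
  if (!is.finite(measured_capacity) || measured_capacity <= 0 ||
      measured_capacity > 1) {
    stop_input(sprintf(
      "measured_capacity must lie in (0, 1], got %g", measured_capacity))
  }
  if (length(bracket) != 2 || any(bracket <= 0) || bracket[1] >= bracket[2]) {
    stop_input("bracket must be an increasing positive pair")
  }
  mrna <- assay_test_mrna(assay)
  cap_at <- function(g) {
    normalized_capacity(
      construct("test", rbs_strength = rbs_strength, mrna_conc = mrna,
                length_bp = length_bp, gamma = g),
      assay$model_params)
  }
  cap_lo <- cap_at(bracket[1])
  cap_hi <- cap_at(bracket[2])
  if (measured_capacity < cap_lo || measured_capacity > cap_hi) {
    stop_input(sprintf(
      paste0("measured capacity %.4g is outside the achievable interval ",
             "[%.4g, %.4g] for gamma in [%g, %g]"),
      measured_capacity, cap_lo, cap_hi, bracket[1], bracket[2]),
      class = "ribocap_range_error", achievable = c(cap_lo, cap_hi))
  }
  root <- uniroot(function(lg) cap_at(10^lg) - measured_capacity,
                  interval = log10(bracket),
                  f.lower = cap_lo - measured_capacity,
                  f.upper = cap_hi - measured_capacity,
                  tol = 1e-10)
  gamma <- 10^root$root
  achieved <- cap_at(gamma)
  converged <- abs(achieved - measured_capacity) <=
    tol * max(measured_capacity, .Machine$double.eps)

  wide_interval <- FALSE
  if (!is.null(capacity_se) && is.finite(capacity_se) && capacity_se > 0) {
    g_at <- function(cap) {
      cap <- min(max(cap, cap_lo), cap_hi)
      10^uniroot(function(lg) cap_at(10^lg) - cap,
                 interval = log10(bracket), tol = 1e-8)$root
    }
    g_lo <- g_at(measured_capacity - capacity_se)
    g_hi <- g_at(measured_capacity + capacity_se)
    wide_interval <- (g_hi / g_lo) > 10
  }
  structure(
    list(gamma = gamma, bracket = bracket, achieved_capacity = achieved,
         measured_capacity = measured_capacity, converged = converged,
         wide_interval = wide_interval, rbs_strength = rbs_strength,
         length_bp = length_bp),
    class = "ribocap_gamma_estimate")
}

#' @export
print.ribocap_gamma_estimate <- function(x, ...) {
  cat(sprintf(
    "gamma estimate: %.4g s^-1 (capacity %.4g achieved vs %.4g measured)%s\n",
    x$gamma, x$achieved_capacity, x$measured_capacity,
    if (x$wide_interval) " [wide interval]" else ""))
  invisible(x)
}

#' @rdname infer_gamma
#' @param x A `ribocap_gamma_estimate`.
#' @param ... Unused.
#' @export
tidy.ribocap_gamma_estimate <- function(x, ...) {
  tibble(
    gamma = x$gamma, bracket_low = x$bracket[1], bracket_high = x$bracket[2],
    achieved_capacity = x$achieved_capacity,
    measured_capacity = x$measured_capacity,
    converged = x$converged, wide_interval = x$wide_interval,
    rbs_strength = x$rbs_strength, length_bp = x$length_bp
  )
}

# one batch row: optionally clamp into (0, 1] and then into the model's
# achievable capacity interval; clamped rows are marked converged = FALSE
infer_gamma_one <- function(capacity, rbs_strength, length_bp, assay,
                            clamp, ...) {
  cap <- capacity
  clamped <- FALSE
  if (clamp && (cap > 1 || cap <= 0)) {
    cap <- min(max(cap, .Machine$double.eps), 1)
    clamped <- TRUE
  }
  out <- tryCatch(
    tidy(infer_gamma(cap, rbs_strength, length_bp, assay = assay, ...)),
    ribocap_range_error = function(e) {
      if (!clamp) abort(conditionMessage(e), class = class(e))
      cap2 <- min(max(cap, e$achievable[1]), e$achievable[2])
      clamped <<- TRUE
      tidy(infer_gamma(cap2, rbs_strength, length_bp, assay = assay, ...))
    })
  if (clamped) out$converged <- FALSE
  out
}

#' Batch gamma inference from a capacity table
#'
#' Data-frame-first wrapper around [infer_gamma()]: replicate capacities of
#' the same construct are averaged before inversion, mirroring how triplicate
#' lysate measurements are reported as a mean.
#'
#' Measurement noise can push an averaged capacity outside the interval the
#' model can reach (above the supremum for near-costless constructs, or
#' above 1 when a test well out-fluoresces the reference). With
#' `clamp = TRUE` (the default) such values are clamped to the nearest
#' achievable capacity, the estimate lands on the bracket boundary, and the
#' row is marked `converged = FALSE`; with `clamp = FALSE` the out-of-range
#' error propagates.
#'
#' @param data A data frame with columns `construct`, `capacity`,
#'   `rbs_strength`, `length_bp` (one row per replicate measurement).
#' @param assay An [assay_config()].
#' @param clamp Clamp out-of-range mean capacities to the achievable
#'   interval instead of failing (default TRUE).
#' @param ... Passed to [infer_gamma()].
#' @return A tibble with one row per construct: the averaged capacity, the
#'   number of replicates, and the gamma estimate columns.
#' @export
infer_gamma_batch <- function(data, assay = assay_config(), clamp = TRUE,
                              ...) {
  required <- c("construct", "capacity", "rbs_strength", "length_bp")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop_input(paste0("capacity table lacks column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  data |>
    dplyr::group_by(.data$construct, .data$rbs_strength, .data$length_bp) |>
    dplyr::summarise(capacity = mean(.data$capacity),
                     n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::mutate(fit = list(infer_gamma_one(
      .data$capacity, .data$rbs_strength, .data$length_bp,
      assay = assay, clamp = clamp, ...))) |>
    dplyr::ungroup() |>
    tidyr::unnest("fit", names_sep = "_") |>
    dplyr::select(-"fit_measured_capacity", -"fit_rbs_strength",
                  -"fit_length_bp") |>
    dplyr::rename(gamma = "fit_gamma", bracket_low = "fit_bracket_low",
                  bracket_high = "fit_bracket_high",
                  achieved_capacity = "fit_achieved_capacity",
                  converged = "fit_converged",
                  wide_interval = "fit_wide_interval")
}
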