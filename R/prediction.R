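# Forward prediction: construct/operon designs -> model species -> predicted
# in vitro capacity -> per-condition linear map to in vivo -> decomposition
# of measured burden into expression and metabolic components.

#' Promoter classes and their transcript yields
#'
#' Default per-plasmid mRNA yields: strong 30, medium 10 and weak 3
#' transcripts per DNA molecule.
#'
#' @param extra Optional named numeric vector of additional classes.
#' @return Named numeric vector of mRNA copies per plasmid copy.
#' @export
promoter_classes <- function(extra = NULL) {
  base <- c(strong = 30, medium = 10, weak = 3)
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(names(extra) == "") ||
        any(extra <= 0)) {
      stop_input("extra promoter classes must be a named positive vector")
    }
    base <- c(base[setdiff(names(base), names(extra))], extra)
  }
  base
}

#' Steady-state mRNA concentration from promoter class and plasmid dose
#'
#' `plasmid_conc * transcripts-per-DNA` for the promoter class.
#'
#' @param promoter Promoter class label (`"strong"`, `"medium"`, `"weak"`,
#'   or a class supplied via `classes`).
#' @param plasmid_conc Plasmid concentration, nM.
#' @param classes Named yield vector, see [promoter_classes()].
#' @return mRNA concentration in nM.
#' @examples
#' mrna_concentration("strong", 30) # 900, the monitor's mRNA level
#' mrna_concentration("strong", 20) # 600, a test construct
#' @export
mrna_concentration <- function(promoter, plasmid_conc,
                               classes = promoter_classes()) {
  if (any(plasmid_conc <= 0)) stop_input("plasmid_conc must be positive")
  if (!all(promoter %in% names(classes))) {
    stop_input(sprintf(
      "unknown promoter class '%s' (known: %s)",
      paste(setdiff(promoter, names(classes)), collapse = ", "),
      paste(names(classes), collapse = ", ")))
  }
  unname(plasmid_conc * classes[promoter])
}

#' Describe an operon design
#'
#' One promoter driving an ordered set of cistrons, each with its own RBS
#' and lumped synthesis cost.
#'
#' @param cistrons A data frame with columns `name`, `rbs_strength`,
#'   `length_bp`, `gamma` (one row per cistron, in operon order).
#' @param promoter Promoter class label.
#' @param plasmid_conc Plasmid concentration, nM (default 20).
#' @return A list with class `ribocap_operon`.
#' @export
operon_design <- function(cistrons, promoter = "strong", plasmid_conc = 20) {
  required <- c("name", "rbs_strength", "length_bp", "gamma")
  if (!is.data.frame(cistrons) || nrow(cistrons) < 1) {
    stop_input("cistrons must be a data frame with >= 1 row")
  }
  missing_cols <- setdiff(required, names(cistrons))
  if (length(missing_cols) > 0) {
    stop_input(paste0("cistrons table lacks column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (plasmid_conc <= 0) stop_input("plasmid_conc must be positive")
  structure(
    list(cistrons = as_tibble(cistrons), promoter = promoter,
         plasmid_conc = plasmid_conc),
    class = "ribocap_operon")
}

#' Expand an operon into competing mRNA species
#'
#' Each cistron becomes one species at the shared promoter-determined mRNA
#' concentration, with its own RBS strength, length and gamma. Cistrons are
#' modelled as independent entry points drawing on the same ribosome pool;
#' there is no inter-cistron ribosome coupling.
#'
#' @param op A [operon_design()] (a single [construct()] row also works and
#'   passes through unchanged).
#' @param classes Promoter yield table, see [promoter_classes()].
#' @return A constructs tibble, one row per cistron.
#' @export
operon_to_species <- function(op, classes = promoter_classes()) {
  if (inherits(op, "ribocap_constructs")) return(as_constructs(op))
  if (!inherits(op, "ribocap_operon")) {
    stop_input("op must be an operon_design() or a constructs tibble")
  }
  mrna <- mrna_concentration(op$promoter, op$plasmid_conc, classes)
  as_constructs(tibble(
    name = as.character(op$cistrons$name),
    rbs_strength = op$cistrons$rbs_strength,
    mrna_conc = mrna,
    length_bp = op$cistrons$length_bp,
    gamma = op$cistrons$gamma
  ))
}

#' Predict normalized in vitro capacity for a design
#'
#' Runs the competitive translation model with the design's species plus the
#' capacity monitor and returns the monitor's normalized output.
#'
#' @param op An [operon_design()] or a constructs tibble of species.
#' @param assay An [assay_config()] supplying the model parameters.
#' @return Normalized capacity in (0, 1].
#' @export
predict_in_vitro <- function(op, assay = assay_config()) {
  species <- operon_to_species(op)
  normalized_capacity(species, assay$model_params)
}

#' Fit the linear in vitro to in vivo calibration
#'
#' Ordinary least squares of normalized in vivo capacity on normalized in
#' vitro capacity for one growth condition. The slope is condition-dependent
#' (it increases with growth rate), so calibrations are fitted and stored
#' per condition.
#'
#' @param data A data frame with columns `in_vitro` and `in_vivo` (or a
#'   two-column numeric data frame in that order).
#' @param condition Condition label.
#' @return An object of class `ribocap_calibration` wrapping the `lm` fit,
#'   with `slope`, `intercept`, `r_squared`, `condition`, `n_points`.
#' @examples
#' d <- data.frame(in_vitro = c(0, 0.5, 1), in_vivo = 0.7 * c(0, 0.5, 1) + 0.19)
#' fit_calibration(d)
#' @export
fit_calibration <- function(data, condition = "default") {
  if (!is.data.frame(data)) stop_input("data must be a data frame")
  if (!all(c("in_vitro", "in_vivo") %in% names(data))) {
    if (ncol(data) == 2 && all(vapply(data, is.numeric, logical(1)))) {
      names(data) <- c("in_vitro", "in_vivo")
    } else {
      stop_input("data needs numeric columns in_vitro and in_vivo")
    }
  }
  data <- data[stats::complete.cases(data[c("in_vitro", "in_vivo")]), ]
  if (nrow(data) < 2 || length(unique(data$in_vitro)) < 2) {
    stop_input("calibration needs >= 2 points with distinct in_vitro values")
  }
  fit <- lm(in_vivo ~ in_vitro, data = data)
  # summary() warns on exact fits; an exact calibration is legitimate here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, condition = condition, n_points = nrow(data),
         model = fit, data = as_tibble(data)),
    class = "ribocap_calibration")
}

#' @export
print.ribocap_calibration <- function(x, ...) {
  cat(sprintf(
    "in vivo = %.3f x in vitro + %.3f  (R^2 = %.3f, n = %d, condition '%s')\n",
    x$slope, x$intercept, x$r_squared, x$n_points, x$condition))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `ribocap_calibration`.
#' @param ... Unused.
#' @export
tidy.ribocap_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         condition = x$condition)
}

#' @rdname fit_calibration
#' @export
glance.ribocap_calibration <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n_points = x$n_points,
         condition = x$condition)
}

#' @rdname fit_calibration
#' @param object A `ribocap_calibration`.
#' @export
autoplot.ribocap_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$in_vitro, y = .data$in_vivo)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(
      x = "normalized in vitro capacity",
      y = "normalized in vivo capacity",
      title = sprintf("y = %.2fx + %.2f (R² = %.2f, %s)",
                      object$slope, object$intercept, object$r_squared,
                      object$condition)) +
    ggplot2::theme_minimal()
}

#' Map a predicted in vitro capacity to in vivo
#'
#' Applies the condition's linear calibration `slope * x + intercept` and
#' clips the result to [0, 1] (with a warning when clipping occurs).
#'
#' @param in_vitro_capacity Normalized in vitro capacity value(s).
#' @param fit A [fit_calibration()] result.
#' @return Predicted normalized in vivo capacity in [0, 1].
#' @export
predict_in_vivo <- function(in_vitro_capacity, fit) {
  if (!inherits(fit, "ribocap_calibration")) {
    stop_input("fit must be a ribocap_calibration")
  }
  y <- fit$slope * in_vitro_capacity + fit$intercept
  clipped <- y < 0 | y > 1
  if (any(clipped)) {
    warn(sprintf("%d predicted in vivo value(s) clipped to [0, 1]",
                 sum(clipped)))
  }
  pmin(pmax(y, 0), 1)
}

#' Split measured in vivo burden into expression and metabolic parts
#'
#' The expression component is the capacity loss the translation model
#' accounts for (`1 - predicted`); the metabolic component is what the model
#' does not explain (`predicted - measured`), attributed to the encoded
#' enzymes draining host metabolism. A negative metabolic component
#' (over-prediction) is allowed and flagged.
#'
#' @param predicted_in_vivo,measured_in_vivo Normalized capacities in [0, 1]
#'   (vectors of equal length).
#' @param name Optional labels.
#' @return A tibble with columns `name`, `predicted_in_vivo`,
#'   `measured_in_vivo`, `metabolic_component`, `expression_component`,
#'   `over_predicted`.
#' @examples
#' decompose_burden(0.8, 0.6)
#' @export
decompose_burden <- function(predicted_in_vivo, measured_in_vivo,
                             name = NULL) {
  if (length(predicted_in_vivo) != length(measured_in_vivo)) {
    stop_input("predicted and measured must have equal length")
  }
  rng <- range(c(predicted_in_vivo, measured_in_vivo))
  if (rng[1] < 0 || rng[2] > 1) {
    stop_input("capacities must lie in [0, 1]")
  }
  out <- tibble(
    name = name %||% paste0("design_", seq_along(predicted_in_vivo)),
    predicted_in_vivo = predicted_in_vivo,
    measured_in_vivo = measured_in_vivo,
    metabolic_component = predicted_in_vivo - measured_in_vivo,
    expression_component = 1 - predicted_in_vivo,
    over_predicted = predicted_in_vivo - measured_in_vivo < 0
  )
  class(out) <- unique(c("ribocap_burden", class(out)))
  out
}

#' Stacked-bar view of a burden decomposition
#'
#' @param object A [decompose_burden()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ribocap_burden <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("name", "expression_component",
                        "metabolic_component")],
    -"name", names_to = "component", values_to = "capacity_loss")
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$name, .data$capacity_loss,
                       function(v) sum(v)),
    y = .data$capacity_loss, fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "capacity loss") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Per-condition calibration registry
#'
#' Calibrations are keyed by an explicit condition label (for example a
#' strain and medium combination); prediction requires naming the condition
#' — there is no silent default.
#'
#' @param ... [fit_calibration()] results to pre-register.
#' @return A named list with class `ribocap_registry`.
#' @export
calibration_registry <- function(...) {
  reg <- structure(list(), class = "ribocap_registry")
  for (fit in list(...)) reg <- register_calibration(reg, fit)
  reg
}

#' @rdname calibration_registry
#' @param registry A `ribocap_registry`.
#' @param fit A `ribocap_calibration`.
#' @export
register_calibration <- function(registry, fit) {
  if (!inherits(fit, "ribocap_calibration")) {
    stop_input("fit must be a ribocap_calibration")
  }
  registry[[fit$condition]] <- fit
  registry
}

#' @rdname calibration_registry
#' @param condition Condition label to look up.
#' @export
get_calibration <- function(registry, condition) {
  if (missing(condition) || is.null(condition)) {
    stop_input("a condition key is required (no default calibration)")
  }
  fit <- registry[[condition]]
  if (is.null(fit)) {
    stop_input(sprintf("no calibration registered for condition '%s'",
                       condition))
  }
  fit
}
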