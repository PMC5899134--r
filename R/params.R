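#' Describe one translated unit competing for ribosomes
#'
#' A construct is a single mRNA species in the competitive translation model:
#' an RBS of given strength (relative to the capacity monitor, whose strength
#' is 1 by definition), an mRNA concentration, a coding-sequence length, and a
#' lumped per-step synthesis cost `gamma`.
#'
#' @param name Label for the species.
#' @param rbs_strength Dimensionless translation-initiation strength relative
#'   to the monitor RBS (monitor = 1). Must be positive.
#' @param mrna_conc mRNA concentration in nM. Must be non-negative.
#' @param length_bp Coding-sequence length in base pairs (>= 30).
#' @param gamma Lumped synthesis rate in (10 codons) s^-1; low values mean
#'   costly translation. Must be positive.
#' @return A one-row tibble with class `ribocap_constructs`.
#' @examples
#' construct("mkate", rbs_strength = 2.6, mrna_conc = 600,
#'           length_bp = 711, gamma = 1.4)
#' @export
construct <- function(name, rbs_strength, mrna_conc, length_bp, gamma) {
  as_constructs(tibble(
    name = as.character(name),
    rbs_strength = as.numeric(rbs_strength),
    mrna_conc = as.numeric(mrna_conc),
    length_bp = as.numeric(length_bp),
    gamma = as.numeric(gamma)
  ))
}

#' Validate a table of constructs
#'
#' @param x A data frame with columns `name`, `rbs_strength`, `mrna_conc`,
#'   `length_bp`, `gamma` (one row per mRNA species).
#' @return `x` as a tibble with class `ribocap_constructs`.
#' @export
as_constructs <- function(x) {
  required <- c("name", "rbs_strength", "mrna_conc", "length_bp", "gamma")
  if (!is.data.frame(x)) {
    stop_input("constructs must be a data frame")
  }
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_input(paste0("constructs table lacks column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  x$name <- as.character(x$name)
  for (col in c("rbs_strength", "mrna_conc", "length_bp", "gamma")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  if (nrow(x) > 0) {
    if (any(!is.finite(x$rbs_strength)) || any(x$rbs_strength <= 0)) {
      stop_input("rbs_strength must be positive")
    }
    if (any(!is.finite(x$mrna_conc)) || any(x$mrna_conc < 0)) {
      stop_input("mrna_conc must be non-negative (nM)")
    }
    if (any(!is.finite(x$length_bp)) || any(x$length_bp < 30)) {
      stop_input("length_bp must be >= 30 (one ribosome footprint)")
    }
    if (any(!is.finite(x$gamma)) || any(x$gamma <= 0)) {
      stop_input("gamma must be positive ((10 codons) s^-1)")
    }
  }
  class(x) <- unique(c("ribocap_constructs", class(x)))
  x
}

#' The default capacity-monitor construct
#'
#' A constitutively expressed GFP cassette: RBS strength 1 (the reference),
#' 900 nM mRNA (30 nM plasmid under a strong promoter yielding 30 transcripts
#' per DNA), 720 bp, gamma = 1 s^-1.
#'
#' @return A one-row constructs tibble.
#' @export
monitor_construct <- function() {
  construct("monitor", rbs_strength = 1, mrna_conc = 900,
            length_bp = 720, gamma = 1)
}

#' Global parameters of the competitive translation model
#'
#' Reference kinetic rates of the capacity monitor RBS and the size of the
#' shared ribosome pool. Per-construct rates are scaled from the reference
#' by RBS strength (see [derived_rates()]).
#'
#' @param a_plus_M Reference ribosome binding rate, rib^-1 RBS^-1 s^-1.
#' @param a_minus_M Reference ribosome unbinding rate, s^-1.
#' @param b0_M Reference synthesis initiation rate, s^-1.
#' @param R_total Total ribosome pool, nM. A global lump for all translation
#'   resources being competed for.
#' @param monitor The capacity-monitor construct (one-row constructs tibble).
#' @return A list with class `ribocap_params`.
#' @examples
#' p <- model_params()
#' p$R_total
#' @export
model_params <- function(a_plus_M = 1e-4, a_minus_M = 200, b0_M = 1,
                         R_total = 2500, monitor = monitor_construct()) {
  rates <- c(a_plus_M = a_plus_M, a_minus_M = a_minus_M, b0_M = b0_M,
             R_total = R_total)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop_input("all model rates and R_total must be positive and finite")
  }
  monitor <- as_constructs(monitor)
  if (nrow(monitor) != 1) {
    stop_input("monitor must be a single construct")
  }
  structure(
    list(a_plus_M = a_plus_M, a_minus_M = a_minus_M, b0_M = b0_M,
         R_total = R_total, monitor = monitor),
    class = "ribocap_params"
  )
}

#' @export
print.ribocap_params <- function(x, ...) {
  cat("Competitive translation model parameters\n")
  cat(sprintf("  a_plus_M: %g rib^-1 RBS^-1 s^-1\n", x$a_plus_M))
  cat(sprintf("  a_minus_M: %g s^-1\n", x$a_minus_M))
  cat(sprintf("  b0_M: %g s^-1\n", x$b0_M))
  cat(sprintf("  R_total: %g nM\n", x$R_total))
  cat(sprintf("  monitor: %s (rbs %g, %g nM mRNA, %g bp, gamma %g)\n",
              x$monitor$name, x$monitor$rbs_strength, x$monitor$mrna_conc,
              x$monitor$length_bp, x$monitor$gamma))
  invisible(x)
}

#' Number of coarse synthesis steps for a coding sequence
#'
#' One step covers one ribosome footprint of 30 bases (10 codons); the number
#' of steps is the length divided by 30, rounded to the nearest integer with
#' ties rounded up, and never less than 1.
#'
#' @param length_bp Coding-sequence length(s) in base pairs.
#' @return Integer vector of step counts.
#' @examples
#' n_steps(720) # 24
#' @export
n_steps <- function(length_bp) {
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop_input("length_bp must be positive")
  }
  # round half up (base round() rounds half to even)
  pmax(1L, as.integer(floor(length_bp / 30 + 0.5)))
}

#' Per-construct kinetic rates scaled by RBS strength
#'
#' Binding scales up, unbinding scales down, and initiation scales up with
#' RBS strength: `a_plus = a_plus_M * s`, `a_minus = a_minus_M / s`,
#' `b0 = b0_M * s`.
#'
#' @param rbs_strength Dimensionless RBS strength(s), monitor = 1.
#' @param params A [model_params()] object.
#' @return A tibble with columns `rbs_strength`, `a_plus`, `a_minus`, `b0`.
#' @examples
#' derived_rates(2.6)
#' @export
derived_rates <- function(rbs_strength, params = model_params()) {
  if (any(!is.finite(rbs_strength)) || any(rbs_strength <= 0)) {
    stop_input("rbs_strength must be positive")
  }
  tibble(
    rbs_strength = as.numeric(rbs_strength),
    a_plus = params$a_plus_M * rbs_strength,
    a_minus = params$a_minus_M / rbs_strength,
    b0 = params$b0_M * rbs_strength
  )
}

#' Read and write model parameters as JSON
#'
#' The packaged default file `inst/extdata/default_params.json` reproduces
#' the reference parameter set bit-exactly.
#'
#' @param params A [model_params()] object.
#' @param path File path.
#' @return `read_model_params()` returns a `ribocap_params` object;
#'   `write_model_params()` returns `path` invisibly.
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "ribocap_params"))
  obj <- list(
    a_plus_M = params$a_plus_M, a_minus_M = params$a_minus_M,
    b0_M = params$b0_M, R_total = params$R_total,
    monitor = as.list(params$monitor)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_params(
    a_plus_M = as.numeric(obj$a_plus_M),
    a_minus_M = as.numeric(obj$a_minus_M),
    b0_M = as.numeric(obj$b0_M),
    R_total = as.numeric(obj$R_total),
    monitor = as_tibble(obj$monitor)
  )
}

#' Constructs table JSON round trip
#'
#' @param x A constructs tibble.
#' @param path File path.
#' @return `read_constructs()` returns a constructs tibble.
#' @export
write_constructs <- function(x, path) {
  jsonlite::write_json(as_constructs(x), path, auto_unbox = FALSE,
                       digits = NA, dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_constructs
#' @export
read_constructs <- function(path) {
  as_constructs(as_tibble(jsonlite::read_json(path, simplifyVector = TRUE)))
}
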