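#' Normalized capacity of the monitor under competition
#'
#' The capacity monitor's steady-state protein production rate with a set of
#' competitor species present, divided by its production rate alone. 1.0
#' means the competitors impose no expression burden.
#'
#' @param competitors Constructs tibble of competitor species (may have zero
#'   rows). Do not include the monitor; it is taken from `params`.
#' @param params A [model_params()] object defining the monitor and the
#'   shared ribosome pool.
#' @param tol Steady-state solver tolerance.
#' @return A single number in (0, 1].
#' @examples
#' normalized_capacity(as_constructs(monitor_construct()[0, ]))
#' @export
normalized_capacity <- function(competitors, params = model_params(),
                                tol = 1e-9) {
  competitors <- as_constructs(competitors)
  alone <- monitor_production_rate(params$monitor[0, ], params, tol)
  if (nrow(competitors) == 0) {
    return(1)
  }
  monitor_production_rate(competitors, params, tol) / alone
}

# monitor production rate with the given competitors added to the pool
monitor_production_rate <- function(competitors, params, tol = 1e-9) {
  species <- as_constructs(dplyr::bind_rows(params$monitor, competitors))
  ss <- solve_steady_state(species, params, tol = tol)
  tidy(ss)$production_rate[1L]
}

#' Simulated capacity over a grid of mRNA size and synthesis cost
#'
#' Recreates the heat-map procedure used to read off a construct's gamma:
#' for each (length, gamma) pair, one competitor at the assay's mRNA
#' concentration and the given RBS strength is simulated against the monitor
#' and the normalized capacity recorded. Capacity rises with gamma (cheaper
#' synthesis) and falls with length (more ribosomes sequestered per mRNA).
#'
#' @param lengths Coding-sequence lengths in bp.
#' @param gammas Synthesis rates in (10 codons) s^-1.
#' @param rbs_strength RBS strength of the competitor (single value).
#' @param assay An [assay_config()].
#' @return A tibble with columns `length_bp`, `gamma`, `capacity`, of class
#'   `ribocap_capacity_grid`.
#' @examples
#' \donttest{
#' capacity_grid(c(300, 720), c(0.5, 1), rbs_strength = 2.6)
#' }
#' @export
capacity_grid <- function(lengths, gammas, rbs_strength,
                          assay = assay_config()) {
  if (length(lengths) == 0 || length(gammas) == 0) {
    stop_input("lengths and gammas must be non-empty")
  }
  if (any(lengths < 30) || any(gammas <= 0) || length(rbs_strength) != 1 ||
      rbs_strength <= 0) {
    stop_input("lengths >= 30, gammas > 0 and a single positive rbs_strength required")
  }
  mrna <- assay_test_mrna(assay)
  grid <- tidyr::expand_grid(length_bp = as.numeric(lengths),
                             gamma = as.numeric(gammas))
  grid$capacity <- map_dbl(seq_len(nrow(grid)), function(i) {
    comp <- construct("test", rbs_strength = rbs_strength, mrna_conc = mrna,
                      length_bp = grid$length_bp[i], gamma = grid$gamma[i])
    normalized_capacity(comp, assay$model_params)
  })
  class(grid) <- unique(c("ribocap_capacity_grid", class(grid)))
  grid
}

#' Heat map of a simulated capacity grid
#'
#' @param object A `ribocap_capacity_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ribocap_capacity_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$gamma), y = factor(.data$length_bp),
    fill = .data$capacity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "normalized\ncapacity") +
    ggplot2::labs(x = expression(gamma ~ "((10 codons)" ~ s^-1 * ")"),
                  y = "mRNA size (bp)") +
    ggplot2::theme_minimal()
}

#' Capacity as a function of competitor mRNA concentration
#'
#' Sweeps the mRNA concentration of a single competitor, emulating titration
#' of construct DNA into the lysate. At weak RBS and high gamma the response
#' is linear in mRNA; at strong RBS and low gamma ribosome queuing makes the
#' monitor output fall faster than linearly.
#'
#' @param mrna_concs mRNA concentrations to sweep (nM).
#' @param rbs_strength,gamma,length_bp Competitor parameters.
#' @param params A [model_params()] object.
#' @return A tibble with `mrna_conc` and `capacity`.
#' @export
capacity_mrna_sweep <- function(mrna_concs, rbs_strength, gamma,
                                length_bp = 720, params = model_params()) {
  tibble(
    mrna_conc = as.numeric(mrna_concs),
    capacity = map_dbl(mrna_concs, function(m) {
      comp <- construct("test", rbs_strength = rbs_strength, mrna_conc = m,
                        length_bp = length_bp, gamma = gamma)
      normalized_capacity(comp, params)
    })
  )
}
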