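# Mean-field ribosome-flow dynamics over coarse 30-bp sites with hard
# exclusion. State per species: RBS occupancy p followed by one occupancy
# per synthesis step. Free ribosomes are never an independent state: they
# follow from conservation against R_total.

# flat-state layout: for species s with n_s steps the block is
# (p_s, x_{s,1}, ..., x_{s,n_s}); blocks concatenated in table order
state_layout <- function(constructs) {
  ns <- n_steps(constructs$length_bp)
  ends <- cumsum(ns + 1L)
  starts <- c(1L, head(ends, -1L) + 1L)
  list(n_sites = ns, start = starts, end = ends, total = sum(ns + 1L))
}

free_ribosomes_from_state <- function(y, constructs, layout, R_total) {
  bound <- 0
  for (s in seq_len(nrow(constructs))) {
    idx <- layout$start[s]:layout$end[s]
    bound <- bound + constructs$mrna_conc[s] * sum(y[idx])
  }
  R_total - bound
}

#' Time derivatives of the competitive translation model
#'
#' Evaluates the mean-field equations for all species sharing one ribosome
#' pool. For each species, the RBS site fills from the free pool at
#' `a_plus * R_free`, empties by unbinding at `a_minus` or by initiating onto
#' an empty first site at `b0`; interior sites exchange at rate `gamma`
#' subject to exclusion; the terminal site releases at `gamma`, returning the
#' ribosome to the pool. Free ribosomes are computed from conservation.
#'
#' @param y Flat state vector: per species, RBS occupancy then one occupancy
#'   per synthesis step, in the row order of `constructs`.
#' @param constructs Constructs tibble (one row per competing mRNA species).
#' @param params A [model_params()] object.
#' @return Numeric vector `dy/dt` matching `y`, with attributes
#'   `free_ribosomes` and `fluxes` (per-species list: initiation flux then
#'   one inter-site/release flux per step, all in occupancy s^-1).
#' @export
steady_state_rhs <- function(y, constructs, params) {
  constructs <- as_constructs(constructs)
  layout <- state_layout(constructs)
  if (length(y) != layout$total) {
    stop_input(sprintf("state has length %d, expected %d",
                       length(y), layout$total))
  }
  rates <- derived_rates(constructs$rbs_strength, params)
  R_free <- free_ribosomes_from_state(y, constructs, layout, params$R_total)
  dy <- numeric(length(y))
  fluxes <- vector("list", nrow(constructs))
  for (s in seq_len(nrow(constructs))) {
    i0 <- layout$start[s]
    n <- layout$n_sites[s]
    p <- y[i0]
    x <- y[(i0 + 1L):(i0 + n)]
    g <- constructs$gamma[s]
    occ_next <- c(x[-1L], 0) # terminal release sees an always-empty exit
    f_init <- rates$b0[s] * p * (1 - x[1L])
    f_sites <- g * x * (1 - occ_next)
    dy[i0] <- rates$a_plus[s] * R_free * (1 - p) - rates$a_minus[s] * p - f_init
    dy[(i0 + 1L):(i0 + n)] <- c(f_init, f_sites[-n]) - f_sites
    fluxes[[s]] <- c(f_init, f_sites)
  }
  attr(dy, "free_ribosomes") <- R_free
  attr(dy, "fluxes") <- fluxes
  dy
}

# Steady-state chain profile of one species given its flux J:
# terminal site x_n = J/gamma, then backwards x_i = (J/gamma)/(1 - x_{i+1}).
# Returns NULL when the profile leaves [0, 1) (flux infeasible).
chain_profile <- function(J, gamma, n) {
  u <- J / gamma
  if (u < 0 || u >= 1) return(NULL)
  x <- numeric(n)
  x[n] <- u
  if (n > 1) {
    for (i in (n - 1L):1L) {
      denom <- 1 - x[i + 1L]
      if (denom <= u) return(NULL) # next site too full to carry flux J
      x[i] <- u / denom
    }
  }
  x
}

# Given free ribosomes, solve one species' steady state by bisection on its
# flux J. The RBS balance fixes p(J) = (a_plus R_free - J)/(a_plus R_free +
# a_minus); the initiation residual b0 p (1 - x_1) - J is strictly
# decreasing in J, so the root is unique.
solve_species_given_free <- function(R_free, a_plus, a_minus, b0, gamma, n) {
  aR <- a_plus * R_free
  residual_at <- function(J) {
    p <- (aR - J) / (aR + a_minus)
    if (p <= 0) return(-1 - J)
    x <- chain_profile(J, gamma, n)
    if (is.null(x)) return(-1 - J)
    b0 * p * (1 - x[1L]) - J
  }
  lo <- 0
  hi <- min(aR, gamma * 0.999999)
  if (R_free <= 0 || residual_at(lo) <= 0) {
    return(list(p = max(0, aR / (aR + a_minus)), x = numeric(n) * 0, J = 0))
  }
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (residual_at(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-16 * max(1, hi)) break
  }
  J <- lo
  list(p = (aR - J) / (aR + a_minus), x = chain_profile(J, gamma, n), J = J)
}

#' Solve the competitive translation model to steady state
#'
#' Finds the stationary occupancy profile of every species and the free
#' ribosome concentration. The default algebraic method exploits the model's
#' structure: at steady state each species carries a single flux, so its
#' whole profile is a scalar root-finding problem, nested inside a monotone
#' outer solve on the free-ribosome concentration that enforces conservation
#' of the total pool. An ODE relaxation fallback (and alternative `method`)
#' integrates the same dynamics to long times.
#'
#' @param constructs Constructs tibble, one row per species (include the
#'   monitor explicitly if it competes).
#' @param params A [model_params()] object.
#' @param tol Absolute tolerance on the maximal time-derivative at the
#'   returned point (default 1e-9).
#' @param method `"algebraic"` (default) or `"ode"` relaxation.
#' @return An object of class `ribocap_steady_state`: the input table plus
#'   per-species `rbs_occupancy`, occupancy profiles, fluxes and
#'   `production_rate` (nM s^-1, `gamma * terminal occupancy * mrna_conc`),
#'   with `free_ribosomes`, `residual` and `R_total` attached.
#' @examples
#' ss <- solve_steady_state(monitor_construct())
#' tidy(ss)
#' @export
solve_steady_state <- function(constructs, params = model_params(),
                               tol = 1e-9, method = c("algebraic", "ode")) {
  method <- match.arg(method)
  constructs <- as_constructs(constructs)
  if (nrow(constructs) == 0) {
    stop_input("need at least one species")
  }
  if (!is.finite(tol) || tol <= 0) stop_input("tol must be positive")
  layout <- state_layout(constructs)
  rates <- derived_rates(constructs$rbs_strength, params)

  assemble <- function(y) {
    dy <- steady_state_rhs(y, constructs, params)
    res <- list(
      species = constructs,
      layout = layout,
      y = y,
      free_ribosomes = attr(dy, "free_ribosomes"),
      fluxes = attr(dy, "fluxes"),
      residual = max(abs(dy)),
      R_total = params$R_total
    )
    class(res) <- "ribocap_steady_state"
    res
  }

  if (method == "algebraic") {
    bound_at <- function(R_free) {
      total <- 0
      for (s in seq_len(nrow(constructs))) {
        sol <- solve_species_given_free(
          R_free, rates$a_plus[s], rates$a_minus[s], rates$b0[s],
          constructs$gamma[s], layout$n_sites[s])
        total <- total + constructs$mrna_conc[s] * (sol$p + sum(sol$x))
      }
      total
    }
    # conservation residual is strictly increasing in R_free
    lo <- 0
    hi <- params$R_total
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (mid + bound_at(mid) < params$R_total) lo <- mid else hi <- mid
      if ((hi - lo) < 1e-14 * params$R_total) break
    }
    R_free <- (lo + hi) / 2
    y <- numeric(layout$total)
    for (s in seq_len(nrow(constructs))) {
      sol <- solve_species_given_free(
        R_free, rates$a_plus[s], rates$a_minus[s], rates$b0[s],
        constructs$gamma[s], layout$n_sites[s])
      y[layout$start[s]:layout$end[s]] <- c(sol$p, sol$x)
    }
    res <- assemble(y)
    if (res$residual <= tol) return(res)
    # fall through to relaxation, polishing from the algebraic point
    start <- y
  } else {
    start <- numeric(layout$total)
  }

  deriv <- function(t, y, parms) {
    list(as.numeric(steady_state_rhs(y, constructs, params)))
  }
  t_end <- 5e4
  for (attempt in 1:3) {
    sol <- deSolve::ode(y = start, times = c(0, t_end), func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-12, atol = 1e-12)
    y <- pmin(pmax(as.numeric(sol[nrow(sol), -1]), 0), 1)
    res <- assemble(y)
    if (res$residual <= tol) return(res)
    start <- y
    t_end <- t_end * 10
  }
  stop_convergence(
    sprintf("steady-state solve did not reach tol = %g (residual %g)",
            tol, res$residual),
    residual = res$residual)
}

#' @export
print.ribocap_steady_state <- function(x, ...) {
  cat(sprintf(
    "Steady state: %d species, free ribosomes %.4g nM of %g, residual %.3g\n",
    nrow(x$species), x$free_ribosomes, x$R_total, x$residual))
  print(tidy(x))
  invisible(x)
}

#' Per-species summary of a steady state
#'
#' @param x A `ribocap_steady_state` object.
#' @param ... Unused.
#' @return A tibble with one row per species: occupancies, bound ribosomes
#'   per mRNA, steady flux (s^-1) and protein production rate (nM s^-1).
#' @export
tidy.ribocap_steady_state <- function(x, ...) {
  out <- x$species
  ns <- x$layout$n_sites
  out$n_steps <- ns
  out$rbs_occupancy <- map_dbl(seq_len(nrow(out)),
                               function(s) x$y[x$layout$start[s]])
  out$site_occupancies <- map(seq_len(nrow(out)), function(s) {
    x$y[(x$layout$start[s] + 1L):x$layout$end[s]]
  })
  out$bound_per_mrna <- out$rbs_occupancy +
    map_dbl(out$site_occupancies, sum)
  out$flux <- map_dbl(x$fluxes, function(f) f[length(f)])
  out$production_rate <- out$gamma *
    map_dbl(out$site_occupancies, function(v) v[length(v)]) * out$mrna_conc
  as_tibble(out)
}

#' One-row summary of a steady state
#'
#' @param x A `ribocap_steady_state` object.
#' @param ... Unused.
#' @return A tibble with `free_ribosomes`, `bound_ribosomes`, `residual`,
#'   `n_species`.
#' @export
glance.ribocap_steady_state <- function(x, ...) {
  td <- tidy(x)
  tibble(
    free_ribosomes = x$free_ribosomes,
    bound_ribosomes = sum(td$mrna_conc * td$bound_per_mrna),
    R_total = x$R_total,
    residual = x$residual,
    n_species = nrow(td)
  )
}
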