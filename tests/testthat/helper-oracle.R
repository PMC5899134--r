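# Independent oracle for the competitive translation model, written as
# plain per-species loops (no shared code with the package's solver):
# the same mean-field equations integrated to long times with deSolve.

oracle_rhs <- function(y, species, params) {
  # species: data.frame with rbs_strength, mrna_conc, length_bp, gamma
  n_sites <- pmax(1L, as.integer(floor(species$length_bp / 30 + 0.5)))
  dy <- numeric(length(y))
  # free pool from conservation
  bound <- 0
  pos <- 1L
  for (s in seq_len(nrow(species))) {
    blk <- y[pos:(pos + n_sites[s])]
    bound <- bound + species$mrna_conc[s] * sum(blk)
    pos <- pos + n_sites[s] + 1L
  }
  R_free <- params$R_total - bound
  pos <- 1L
  for (s in seq_len(nrow(species))) {
    w <- species$rbs_strength[s]
    a_plus <- params$a_plus_M * w
    a_minus <- params$a_minus_M / w
    b0 <- params$b0_M * w
    g <- species$gamma[s]
    n <- n_sites[s]
    p <- y[pos]
    x <- y[(pos + 1L):(pos + n)]
    f_init <- b0 * p * (1 - x[1])
    dy[pos] <- a_plus * R_free * (1 - p) - a_minus * p - f_init
    for (i in seq_len(n)) {
      inflow <- if (i == 1) f_init else g * x[i - 1] * (1 - x[i])
      outflow <- if (i == n) g * x[i] else g * x[i] * (1 - x[i + 1])
      dy[pos + i] <- inflow - outflow
    }
    pos <- pos + n + 1L
  }
  dy
}

# long-time relaxation from the empty state; returns per-species
# production rates gamma * x_terminal * mrna_conc
oracle_production_rates <- function(species, params, t_end = 2e5) {
  n_sites <- pmax(1L, as.integer(floor(species$length_bp / 30 + 0.5)))
  y0 <- numeric(sum(n_sites + 1L))
  sol <- deSolve::ode(
    y = y0, times = c(0, t_end),
    func = function(t, y, parms) list(oracle_rhs(y, species, params)),
    method = "lsoda", rtol = 1e-12, atol = 1e-12)
  y <- as.numeric(sol[nrow(sol), -1])
  pos <- 1L
  vapply(seq_len(nrow(species)), function(s) {
    out <- species$gamma[s] * y[pos + n_sites[s]] * species$mrna_conc[s]
    pos <<- pos + n_sites[s] + 1L
    out
  }, numeric(1))
}

# randomized small instances shared by the oracle-equivalence suites
random_instance <- function() {
  k <- sample(1:3, 1)
  data.frame(
    name = paste0("s", seq_len(k)),
    rbs_strength = round(stats::runif(k, 0.3, 3), 3),
    mrna_conc = round(stats::runif(k, 0, 900), 1),
    length_bp = sample(seq(30, 900, by = 30), k, replace = TRUE),
    gamma = round(exp(stats::runif(k, log(0.05), log(3))), 4)
  )
}
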