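make_series <- function(time, gfp = 0 * time, ...) {
  plate_time_series(time = time, gfp = gfp, ...)
}

test_that("growth rate reproduces closed forms", {
  tt <- seq(0, 8, by = 1 / 6)
  # doubling across a 1 h window
  ts1 <- make_series(tt, od = ifelse(tt < 3.5, 0.1, 0.2))
  expect_equal(growth_rate(ts1, t2 = 3.5), log(2), tolerance = 1e-12)
  # exponential series: exact rate at any interior point
  ts2 <- make_series(tt, od = 0.05 * exp(0.5 * tt))
  for (t2 in c(1, 4, 7)) {
    expect_equal(growth_rate(ts2, t2), 0.5, tolerance = 1e-10)
  }
  expect_error(growth_rate(ts2, t2 = 0.2), class = "ribocap_input_error")
  expect_error(growth_rate(make_series(tt), t2 = 4),
               class = "ribocap_input_error")
})

test_that("growth rate prefers OD700 when both channels are present", {
  tt <- seq(0, 4, by = 1 / 6)
  ts <- plate_time_series(time = tt, gfp = 0 * tt,
                          od600 = 0.05 * exp(1 * tt),
                          od700 = 0.05 * exp(0.6 * tt))
  expect_equal(growth_rate(ts, 2), 0.6, tolerance = 1e-10)
})

test_that("mid-exponential detection matches curve symmetry", {
  tt <- seq(0, 10, by = 1 / 6)
  # sigmoid in log-OD centred at 4 h: the centred log-slope peaks there
  lod <- log(0.05) + (log(1) - log(0.05)) / (1 + exp(-(tt - 4) / 1))
  ts <- make_series(tt, od = exp(lod))
  expect_equal(find_mid_exponential(ts), 4, tolerance = 1 / 6)
  # pure exponential: any interior point; implementation must return an
  # admissible window centre
  ts_exp <- make_series(tt, od = 0.05 * exp(0.3 * tt))
  t2 <- find_mid_exponential(ts_exp)
  expect_gte(t2, 0.5)
  expect_lte(t2, 9.5)
  # constant OD: no growth
  expect_error(find_mid_exponential(make_series(tt, od = rep(0.2, length(tt)))),
               class = "ribocap_no_growth_error")
})

test_that("production rates implement the windowed formulas", {
  tt <- seq(0, 4, by = 1 / 6)
  gfp <- 1000 * tt # rises 1000 units per hour
  ts <- plate_time_series(time = tt, gfp = gfp, od = rep(0.5, length(tt)))
  expect_equal(production_rate_in_vitro(ts, 2), 1000, tolerance = 1e-9)
  expect_equal(production_rate_in_vivo(ts, 2), 2000, tolerance = 1e-9)
  const <- plate_time_series(time = tt, gfp = rep(5, length(tt)),
                             od = rep(0.5, length(tt)))
  expect_equal(production_rate_in_vitro(const, 2), 0)
  expect_error(production_rate_in_vitro(ts, 2, channel = "rfp"),
               class = "ribocap_input_error")
})

test_that("windowed growth and production statistics share one convention", {
  tt <- seq(0, 6, by = 1 / 6)
  ts <- plate_time_series(time = tt, gfp = 200 * tt^2,
                          od = 0.05 * exp(0.4 * tt))
  t2 <- 3
  # same +/- 0.5 h samples feed all three statistics
  i1 <- which.min(abs(tt - 2.5)); i3 <- which.min(abs(tt - 3.5))
  expect_equal(growth_rate(ts, t2),
               (log(ts$od[i3]) - log(ts$od[i1])) / (tt[i3] - tt[i1]))
  expect_equal(production_rate_in_vitro(ts, t2),
               (ts$gfp[i3] - ts$gfp[i1]) / (tt[i3] - tt[i1]))
  expect_equal(production_rate_in_vivo(ts, t2),
               production_rate_in_vitro(ts, t2) /
                 ts$od[which.min(abs(tt - t2))])
})

test_that("capacity takes the maximal interior windowed rate", {
  tt <- seq(0, 6, by = 1 / 12)
  # sigmoid accumulation: peak rate at the inflection, before the plateau
  gfp <- 5000 / (1 + exp(-(tt - 2) / 0.5))
  ts <- make_series(tt, gfp = gfp)
  raw <- capacity(ts, mode = "lysate")
  rates <- vapply(tt[tt >= 0.5 & tt <= 5.5],
                  function(t2) production_rate_in_vitro(ts, t2), numeric(1))
  expect_equal(raw, max(rates), tolerance = 1e-9)
  # the peak window sits at the inflection, within one sampling interval
  t_peak <- tt[tt >= 0.5 & tt <= 5.5][which.max(rates)]
  expect_equal(t_peak, 2, tolerance = 1 / 12 + 1e-9)
  # all-zero signal
  expect_equal(capacity(make_series(tt), mode = "lysate"), 0)
  expect_error(capacity(make_series(seq(0, 0.5, 1 / 12))),
               class = "ribocap_input_error")
})

test_that("normalization divides by the reference and validates it", {
  out <- normalize_capacity(500, 1000, mode = "lysate", condition = "c1")
  expect_equal(out$value, 0.5)
  expect_identical(normalize_capacity(1000, 1000)$value, 1)
  expect_identical(normalize_capacity(0, 1000)$value, 0)
  expect_error(normalize_capacity(1, 0), class = "ribocap_input_error")
  expect_error(normalize_capacity(1, -2), class = "ribocap_input_error")
})

test_that("normalized capacities are invariant to instrument gain", {
  set.seed(3)
  cfg <- generator_config(noise_cv = 0)
  t_ref <- generate_lysate_trace(1, cfg)
  t_a <- generate_lysate_trace(0.6, cfg)
  scale_all <- function(ts, k) { ts$gfp <- ts$gfp * k; ts }
  v1 <- capacity(t_a) / capacity(t_ref)
  v2 <- capacity(scale_all(t_a, 37)) / capacity(scale_all(t_ref, 37))
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_equal(v1, 0.6, tolerance = 1e-6)
})

test_that("plate CSVs round-trip through both schemas", {
  tt <- seq(0, 2, by = 1 / 6)
  plate <- dplyr::bind_rows(
    plate_time_series(tt, gfp = 10 * tt, od = 0.1 * exp(tt),
                      well = "A1", sample = "s1"),
    plate_time_series(tt, gfp = 20 * tt, od = 0.1 * exp(0.5 * tt),
                      well = "A2", sample = "s2"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(plate, tmp)
  back <- read_plate_csv(tmp) # long schema, auto-detected
  expect_setequal(unique(back$well), c("A1", "A2"))
  a1 <- dplyr::filter(back, well == "A1")
  expect_equal(a1$gfp, 10 * tt)
  expect_equal(a1$od, 0.1 * exp(tt))
  # wide schema
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(plate, tmp2, row.names = FALSE)
  back2 <- read_plate_csv(tmp2)
  expect_equal(dplyr::filter(back2, well == "A2")$gfp, 20 * tt)
  expect_error(read_plate_csv(tempfile()), class = "ribocap_input_error")
})

test_that("well_statistics summarises every well", {
  set.seed(5)
  cfg <- generator_config(noise_cv = 0)
  plate <- dplyr::bind_rows(
    generate_lysate_trace(1, cfg, well = "R1", sample = "monitor_alone"),
    generate_lysate_trace(0.4, cfg, well = "W1", sample = "g1"))
  st <- well_statistics(plate, mode = "lysate")
  expect_equal(nrow(st), 2)
  ratio <- st$raw_max_rate[st$sample == "g1"] /
    st$raw_max_rate[st$sample == "monitor_alone"]
  expect_equal(ratio, 0.4, tolerance = 1e-6)
})
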