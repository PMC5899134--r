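test_that("promoter classes map plasmid dose to mRNA concentration", {
  expect_equal(mrna_concentration("strong", 30), 900)
  expect_equal(mrna_concentration("strong", 20), 600)
  expect_equal(mrna_concentration("medium", 20), 200)
  expect_equal(mrna_concentration("weak", 20), 60)
  expect_error(mrna_concentration("huge", 20), class = "ribocap_input_error")
  expect_error(mrna_concentration("strong", 0), class = "ribocap_input_error")
  classes <- promoter_classes(c(custom = 12))
  expect_equal(mrna_concentration("custom", 10, classes), 120)
})

test_that("operons expand to one species per cistron at shared mRNA level", {
  cis <- data.frame(name = c("lucA", "lucB"),
                    rbs_strength = c(2.6, 1.2),
                    length_bp = c(1650, 930), gamma = c(0.9, 1.3))
  op <- operon_design(cis, promoter = "strong", plasmid_conc = 20)
  sp <- operon_to_species(op)
  expect_equal(nrow(sp), 2)
  expect_equal(sp$mrna_conc, c(600, 600))
  expect_equal(sp$rbs_strength, cis$rbs_strength)
  # degenerate 1-cistron operon equals the single construct
  single <- operon_design(cis[1, ], promoter = "strong", plasmid_conc = 20)
  expect_equal(as.data.frame(operon_to_species(single)),
               as.data.frame(construct("lucA", 2.6, 600, 1650, 0.9)))
  expect_error(operon_design(cis[0, ]), class = "ribocap_input_error")
})

test_that("1-cistron prediction equals the single-gene path exactly", {
  cis <- data.frame(name = "g", rbs_strength = 2.1, length_bp = 720,
                    gamma = 0.7)
  op <- operon_design(cis, "strong", 20)
  expect_identical(predict_in_vitro(op),
                   predict_in_vitro(construct("g", 2.1, 600, 720, 0.7)))
})

test_that("weaker RBS on the same construct gives strictly higher capacity", {
  bcd2 <- construct("g", 2.6, 600, 1200, 0.8)
  bcd21 <- construct("g", 2.1, 600, 1200, 0.8)
  expect_gt(predict_in_vitro(bcd21), predict_in_vitro(bcd2))
})

test_that("adding cistrons never increases predicted capacity", {
  cis <- data.frame(
    name = c("crtE", "crtB", "crtI", "crtY"),
    rbs_strength = c(1.8, 2.2, 1.1, 0.9),
    length_bp = c(906, 930, 1479, 1152),
    gamma = c(0.8, 1.1, 0.5, 0.9))
  full <- predict_in_vitro(operon_design(cis, "strong", 20))
  for (i in seq_len(nrow(cis))) {
    single <- predict_in_vitro(operon_design(cis[i, ], "strong", 20))
    expect_lte(full, single + 1e-12)
  }
  for (k in 2:4) {
    partial <- predict_in_vitro(operon_design(cis[1:(k - 1), ], "strong", 20))
    more <- predict_in_vitro(operon_design(cis[1:k, ], "strong", 20))
    expect_lte(more, partial + 1e-12)
  }
})

test_that("calibration recovers an exact linear relation", {
  x <- c(0.1, 0.3, 0.55, 0.8, 1)
  fit <- fit_calibration(data.frame(in_vitro = x, in_vivo = 0.7 * x + 0.19),
                         condition = "standard")
  expect_equal(fit$slope, 0.7, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.19, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  ident <- fit_calibration(data.frame(in_vitro = x, in_vivo = x))
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  expect_error(fit_calibration(data.frame(in_vitro = rep(0.5, 3),
                                          in_vivo = 1:3)),
               class = "ribocap_input_error")
  # tidy/glance surface the coefficients
  expect_equal(tidy(fit)$estimate, c(0.19, 0.7), tolerance = 1e-12)
  expect_equal(glance(fit)$r_squared, 1, tolerance = 1e-12)
})

test_that("calibration recovers generator slopes under 5% noise", {
  set.seed(21)
  for (s in c(0.5, 0.7, 1.0)) {
    x <- seq(0.15, 1, length.out = 10)
    y <- (s * x + 0.1) * exp(stats::rnorm(10, 0, 0.05))
    fit <- fit_calibration(data.frame(in_vitro = x, in_vivo = y))
    expect_equal(fit$slope / s, 1, tolerance = 0.1,
                 label = sprintf("slope recovery at true slope %.1f", s))
  }
})

test_that("in vivo mapping applies the linear relation and clips", {
  fit <- fit_calibration(
    data.frame(in_vitro = c(0, 1), in_vivo = c(0.19, 0.89)))
  expect_equal(predict_in_vivo(1, fit), 0.89)
  expect_equal(predict_in_vivo(0, fit), 0.19)
  ident <- fit_calibration(data.frame(in_vitro = c(0, 1), in_vivo = c(0, 1)))
  expect_equal(predict_in_vivo(0.42, ident), 0.42)
  steep <- fit_calibration(
    data.frame(in_vitro = c(0, 1), in_vivo = c(0.5, 1.7)))
  expect_warning(out <- predict_in_vivo(c(0.2, 0.9), steep), "clipped")
  expect_equal(out, c(0.74, 1))
  expect_error(predict_in_vivo(0.5, "not a fit"),
               class = "ribocap_input_error")
})

test_that("burden decomposition identities hold exactly", {
  d <- decompose_burden(0.8, 0.6)
  expect_identical(d$metabolic_component, 0.8 - 0.6)
  expect_identical(d$expression_component, 1 - 0.8)
  expect_false(d$over_predicted)
  eq <- decompose_burden(0.7, 0.7)
  expect_identical(eq$metabolic_component, 0)
  over <- decompose_burden(0.5, 0.65)
  expect_true(over$over_predicted)
  expect_identical(over$metabolic_component, 0.5 - 0.65)
  # vectorized identities to machine precision
  set.seed(9)
  p <- stats::runif(20); m <- stats::runif(20)
  dd <- decompose_burden(p, m)
  expect_identical(dd$metabolic_component, p - m)
  expect_identical(dd$expression_component, 1 - p)
  expect_error(decompose_burden(1.2, 0.5), class = "ribocap_input_error")
  expect_error(decompose_burden(c(0.5, 0.6), 0.5),
               class = "ribocap_input_error")
})

test_that("the calibration registry requires an explicit condition", {
  f1 <- fit_calibration(data.frame(in_vitro = c(0, 1), in_vivo = c(0.19, 0.89)),
                        condition = "fructose_37C")
  f2 <- fit_calibration(data.frame(in_vitro = c(0, 1), in_vivo = c(0, 1)),
                        condition = "glucose_30C")
  reg <- calibration_registry(f1, f2)
  expect_equal(get_calibration(reg, "fructose_37C")$slope, 0.7)
  expect_equal(get_calibration(reg, "glucose_30C")$slope, 1)
  expect_error(get_calibration(reg, "unknown"),
               class = "ribocap_input_error")
  expect_error(get_calibration(reg), class = "ribocap_input_error")
})
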