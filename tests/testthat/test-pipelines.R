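test_that("config validation rejects unknown keys and missing files", {
  expect_error(pipeline_config(list(seed = 1, bogus = 2)),
               class = "ribocap_input_error")
  expect_error(pipeline_config("/nonexistent/config.json"),
               class = "ribocap_input_error")
  expect_error(run_simulate(list(seed = 1)), class = "ribocap_input_error")
  expect_error(run_simulate(list(simulate = list(lengths = 720))),
               class = "ribocap_input_error")
})

test_that("simulate stage writes a monotone capacity table", {
  out_dir <- withr::local_tempdir()
  res <- run_simulate(list(
    output_dir = out_dir, verbosity = "quiet",
    simulate = list(lengths = c(300, 900), gammas = c(0.2, 1, 5),
                    rbs_strength = 2.6)))
  expect_equal(nrow(res), 6)
  wide <- tidyr::pivot_wider(res, names_from = "gamma",
                             values_from = "capacity")
  m <- as.matrix(wide[-1])
  expect_true(all(apply(m, 1, function(r) all(diff(r) >= -1e-12))))
  expect_true(file.exists(file.path(out_dir, "capacities.csv")))
  expect_true(file.exists(file.path(out_dir, "provenance_simulate.json")))
  # no competitor: capacity 1 via a designs file of one null-load species
  designs <- file.path(out_dir, "designs.csv")
  utils::write.csv(data.frame(name = "null", rbs_strength = 1,
                              mrna_conc = 0, length_bp = 720, gamma = 1),
                   designs, row.names = FALSE)
  res2 <- run_simulate(list(output_dir = out_dir, verbosity = "quiet",
                            simulate = list(designs_file = designs)))
  expect_equal(res2$capacity, 1, tolerance = 1e-9)
})

test_that("generate -> characterise -> predict runs end to end", {
  out_dir <- withr::local_tempdir()
  config <- list(seed = 7, output_dir = out_dir, verbosity = "quiet",
                 generate = list(n_constructs = 3, noise_cv = 0.02,
                                 rbs_choices = 2.6))
  lib <- run_generate(config)
  demo <- file.path(out_dir, "demo")

  config$characterise <- list(
    plate_file = file.path(demo, "lysate_plate.csv"),
    constructs_file = file.path(demo, "constructs.csv"))
  gammas <- run_characterise(config)
  expect_equal(sort(gammas$construct), sort(lib$constructs$name))
  merged <- dplyr::inner_join(gammas,
                              lib$constructs[c("name", "gamma")],
                              by = c(construct = "name"),
                              suffix = c("_est", "_true"))
  expect_lt(stats::median(abs(merged$gamma_est / merged$gamma_true - 1)),
            0.15)

  # an operon per construct pair, predicted through the written gamma table
  designs <- file.path(out_dir, "designs.csv")
  utils::write.csv(data.frame(
    operon = c("op1", "op1", "op2"),
    name = lib$constructs$name[c(1, 2, 3)],
    rbs_strength = c(2.6, 1.0, 0.5),
    promoter = "strong", plasmid_conc = 20), designs, row.names = FALSE)
  measured <- file.path(out_dir, "measured.csv")
  utils::write.csv(data.frame(operon = c("op1", "op2"),
                              measured_in_vivo = c(0.45, 0.8)),
                   measured, row.names = FALSE)
  config$predict <- list(
    designs_file = designs,
    gamma_file = file.path(out_dir, "gamma_table.csv"),
    condition = "standard",
    calibration = list(slope = 0.7, intercept = 0.19),
    measured_file = measured)
  preds <- run_predict(config)
  expect_equal(nrow(preds), 2)
  expect_true(all(preds$predicted_in_vitro > 0 &
                    preds$predicted_in_vitro <= 1))
  expect_equal(preds$predicted_in_vivo,
               pmin(pmax(0.7 * preds$predicted_in_vitro + 0.19, 0), 1))
  # decomposition identities in the written table
  expect_equal(preds$metabolic_component,
               preds$predicted_in_vivo - preds$measured_in_vivo)
  expect_equal(preds$expression_component, 1 - preds$predicted_in_vivo)
  # a 1-cistron operon equals the single-gene path
  single <- dplyr::filter(preds, operon == "op2")
  g3 <- dplyr::filter(gammas, construct == lib$constructs$name[3])
  direct <- predict_in_vitro(construct("x", 0.5, 600, g3$length_bp, g3$gamma))
  expect_equal(single$predicted_in_vitro, direct, tolerance = 1e-9)
})

test_that("characterise fails clearly without monitor reference wells", {
  out_dir <- withr::local_tempdir()
  run_generate(list(seed = 8, output_dir = out_dir, verbosity = "quiet",
                    generate = list(n_constructs = 2)))
  demo <- file.path(out_dir, "demo")
  plate <- read_plate_csv(file.path(demo, "lysate_plate.csv"))
  no_ref <- dplyr::filter(plate, sample != "monitor_alone")
  bad <- file.path(out_dir, "no_ref.csv")
  write_plate_csv(no_ref, bad)
  expect_error(run_characterise(list(
    output_dir = out_dir, verbosity = "quiet",
    characterise = list(plate_file = bad,
                        constructs_file = file.path(demo, "constructs.csv")))),
    class = "ribocap_input_error")
})

test_that("predict names the gene when a gamma estimate is missing", {
  out_dir <- withr::local_tempdir()
  gamma_file <- file.path(out_dir, "gamma_table.csv")
  utils::write.csv(data.frame(construct = "known", gamma = 1,
                              length_bp = 720), gamma_file,
                   row.names = FALSE)
  designs <- file.path(out_dir, "designs.csv")
  utils::write.csv(data.frame(operon = "op", name = c("known", "mystery"),
                              rbs_strength = 1, promoter = "strong",
                              plasmid_conc = 20), designs, row.names = FALSE)
  err <- tryCatch(run_predict(list(
    output_dir = out_dir, verbosity = "quiet",
    predict = list(designs_file = designs, gamma_file = gamma_file,
                   condition = "std",
                   calibration = list(slope = 0.7, intercept = 0.19)))),
    ribocap_input_error = function(e) e)
  expect_match(conditionMessage(err), "mystery")
})
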