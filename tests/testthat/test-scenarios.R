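test_that("override application validates keys and values", {
  p <- with_overrides(builtin_parameters("propranolol"), list(k4 = 9.4))
  expect_equal(p$k4, 9.4)
  expect_equal(p$k3, 66)
  expect_error(with_overrides(p, list(kX = 1)), "kX")
  expect_error(with_overrides(p, list(k5 = -2)), "k5")
  # oral overrides require an oral PK component
  expect_error(with_overrides(builtin_parameters("imipramine"),
                              list(s = 100)), "oral")
  p2 <- with_overrides(builtin_parameters("propranolol"), list(s = 2300))
  expect_equal(attr(p2, "oral_pk")$s, 2300)
})

test_that("single scenarios reproduce published perturbation rows", {
  # propranolol with active efflux (tenfold k4): unchanged LF, 90% lower LM
  r7 <- run_scenario(scenario_spec("sim7", "propranolol", list(k4 = 9.4)))
  expect_equal(r7$solution$LF, 20.6, tolerance = 0.002)
  expect_equal(r7$solution$LM, 2.1, tolerance = 0.02)

  # imipramine with brain metabolism k9 = 6
  r18 <- run_scenario(scenario_spec("sim18", "imipramine", list(k9 = 6)))
  expect_equal(r18$solution$LF, 25.6, tolerance = 0.001)
  expect_equal(r18$solution$LM, 6.78, tolerance = 0.001)

  # self-referenced comparisons vanish
  base <- run_scenario(scenario_spec("basal", "propranolol", list()))
  expect_equal(pct_change(base$solution$LF, base$solution$LF), 0)
  expect_equal(fold_change(base$solution$LM, base$solution$LM), 1)
})

test_that("comparison conventions match the published prose percentages", {
  prop <- run_scenario(scenario_spec("sim1", "propranolol", list()))
  expect_equal(prop$pct_LF_vs_LF0, 102, tolerance = 2 / 102)
  expect_equal(prop$pct_LM_vs_LF0, 102, tolerance = 2 / 102)

  # the published 258% is itself the ratio of cells printed to 3
  # significant figures (14.7/4.1), so its own rounding uncertainty is
  # about +-5 points; the full-precision model value is ~256
  cancer <- run_scenario(scenario_spec("sim3", "propranolol",
                                       list(AF = 600000, GT0 = 70000)))
  expect_equal(cancer$pct_LF_vs_LF0, 258, tolerance = 2.5 / 258)
  expect_equal(100 * (round(cancer$solution$LF, 1) /
                        round(cancer$solution$arterial$LF0, 1) - 1),
               258, tolerance = 2 / 258)

  imi <- run_scenario(scenario_spec("sim11", "imipramine", list()))
  expect_equal(imi$fold_LF_LF0, 18, tolerance = 0.5 / 18)
  expect_equal(imi$fold_LM_LF0, 18, tolerance = 0.5 / 18)

  imi_cancer <- run_scenario(scenario_spec("sim13", "imipramine",
                                           list(AF = 600000,
                                                GT0 = 70000)))
  expect_equal(imi_cancer$fold_LF_LF0, 31, tolerance = 0.5 / 31)
  expect_warning(pct_change(1, 0), "zero")
})

test_that("batch tables reproduce both published simulation sets", {
  tab_p <- run_table(builtin_scenarios("propranolol"))
  expect_equal(nrow(tab_p), 10)
  expect_true(all(is.na(tab_p$error)))
  expect_table_match(tab_p, propranolol_table)

  tab_i <- run_table(builtin_scenarios("imipramine"))
  expect_equal(nrow(tab_i), 10)
  expect_table_match(tab_i, imipramine_table)

  # rows whose printed cells conflict with their own printed overrides:
  # the dissociation-limited runs must instead be internally consistent
  # with their no-enhancement counterparts (as the prose states)
  expect_equal(tab_p$LF[6], tab_p$LF[2], tolerance = 1e-12)
  expect_equal(tab_p$LM[6] / tab_p$LF[6], (66600 * 0.01) / (940 * 0.7),
               tolerance = 1e-12)
  expect_equal(unlist(tab_i[6, c("GL", "AL", "LF", "LM", "PL", "PF")]),
               unlist(tab_i[2, c("GL", "AL", "LF", "LM", "PL", "PF")]),
               tolerance = 1e-9)
  # garbled published cells of row 9: prose says 59% decrease of LF and
  # LM relative to the metabolism-only run (row 8)
  expect_equal(100 * (1 - tab_p$LF[9] / tab_p$LF[8]), 59, tolerance = 0.01)
  expect_equal(100 * (1 - tab_p$LM[9] / tab_p$LM[8]), 59, tolerance = 0.01)
})

test_that("packaged scenario files mirror the built-in sets", {
  dir <- system.file("extdata", "scenarios", package = "bbbpk")
  specs <- read_scenarios(dir)
  labels <- vapply(specs, `[[`, "", "label")
  expect_true(all(c("sim1", "sim10", "sim11", "sim20", "PT1000", "PT500",
                    "sim30") %in% labels))
  tab <- run_table(specs[labels %in% paste0("sim", 1:10)])
  expect_table_match(tab[match(paste0("sim", 1:10), tab$label), ],
                     propranolol_table)
  # supplementary variants
  sup <- run_table(specs[labels %in% c("PT1000", "PT500", "sim30")])
  expect_equal(sup$Kp_brain[sup$label == "PT1000"], 2.1, tolerance = 0.012)
  expect_equal(sup$Kp_brain[sup$label == "PT500"], 1.2, tolerance = 0.03)
  expect_equal(sup$LF[sup$label == "sim30"], 100, tolerance = 1e-9)
  expect_equal(sup$LF0[sup$label == "sim30"], 100, tolerance = 1e-9)
  expect_error(run_table(list()), "non-empty")
})

test_that("table runs isolate per-scenario failures", {
  specs <- list(scenario_spec("good", "propranolol", list()),
                scenario_spec("bad", "propranolol", list(k2 = -1)))
  tab <- run_table(specs)
  expect_equal(nrow(tab), 2)
  expect_true(is.na(tab$error[1]))
  expect_match(tab$error[2], "k2")
  expect_true(all(is.na(unlist(tab[2, c("LF", "LM", "Kp_brain")]))))
})

test_that("parameter sweeps expose the tissue-binding structure", {
  p <- builtin_parameters("propranolol")
  sw <- parameter_sweep(p, "PT", c(500, 1000, 5000))
  expect_equal(sw$Kp_brain, c(1.2, 2.1, 9.8), tolerance = 0.03)
  wide <- parameter_sweep(p, "PT", seq(100, 10000, length.out = 25))
  expect_equal(max(wide$LM) - min(wide$LM), 0)  # LM exactly constant
  expect_true(all(diff(wide$PL) > 0))
  # brain metabolism lowers free brain drug
  met <- parameter_sweep(p, "k9", c(0, 6))
  expect_lt(met$LM[2], met$LM[1])
  expect_error(parameter_sweep(p, "volume", 1:3), "param")
  expect_error(parameter_sweep(p, "PT", numeric(0)), "non-empty")
})

test_that("identical specs give bit-identical tables", {
  t1 <- run_table(builtin_scenarios("imipramine"))
  t2 <- run_table(builtin_scenarios("imipramine"))
  expect_identical(t1, t2)
})
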