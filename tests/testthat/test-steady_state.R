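test_that("closed form reproduces the published basal steady states", {
  # propranolol: modest PMU from the AGP pool only
  s <- solve_steady_state(builtin_parameters("propranolol"))
  expect_equal(s$GL, 23.6, tolerance = 0.002)
  expect_equal(s$AL, 55.8, tolerance = 0.001)
  expect_equal(s$LF, 20.6, tolerance = 0.002)
  expect_equal(s$LM, 20.6, tolerance = 0.002)
  expect_equal(s$PL, 959, tolerance = 1e-4)
  expect_equal(s$PF, 4040, tolerance = 3e-4)
  expect_equal(s$Kp_brain, 9.8, tolerance = 5e-4)
  expect_equal(s$fu_in_vitro, 0.102, tolerance = 5e-3)
  expect_equal(s$fu_in_vivo, 0.2057, tolerance = 1e-3)

  # imipramine: strong PMU from both albumin and AGP pools
  si <- solve_steady_state(builtin_parameters("imipramine"))
  expect_equal(si$LF, 49.2, tolerance = 2e-4)
  expect_equal(si$LM, 50.2, tolerance = 2e-4)
  expect_equal(si$PL, 1880, tolerance = 1e-4)
  expect_equal(si$Kp_brain, 19.3, tolerance = 1e-4)
})

test_that("mass conservation of tissue protein and nonnegativity hold", {
  set.seed(431)
  for (rep in 1:50) {
    p <- random_drug_params(with_metabolism = rep %% 3 == 0)
    s <- solve_steady_state(p)
    expect_equal(s$PL + s$PF, p$PT, tolerance = 1e-9)
    vals <- unlist(s[c("GL", "AL", "LF", "GF", "LM", "PL", "PF")])
    expect_true(all(vals >= -1e-12))
    # residual of the underlying quadratic in u = LM*VT/VP is zero
    it <- s$intermediates
    u <- s$LM * p$VT / p$VP
    resid <- it$a2 * it$b1 * u^2 + (it$a2 + it$a1 * it$b1) * u -
      (it$b2 - it$a1)
    expect_lt(abs(resid) / max(abs(it$b2), 1), 1e-10)
  }
})

test_that("no enhanced dissociation means no PMU (LF equals LF0 exactly)", {
  # in-vivo dissociation constants pinned at the in-vitro values
  s2 <- solve_steady_state(with_overrides(builtin_parameters("propranolol"),
                                          list(k1 = 198)))
  expect_equal(s2$LF, s2$arterial$LF0, tolerance = 1e-12)
  expect_equal(s2$LM / s2$LF, kp_uu(s2$params), tolerance = 1e-12)

  s12 <- solve_steady_state(with_overrides(builtin_parameters("imipramine"),
                                           list(k1 = 72, k7 = 252)))
  expect_equal(s12$LF, s12$arterial$LF0, tolerance = 1e-12)

  # dissociation-limited transport: a 1,000-fold permeability increase
  # still confers no PMU
  s6 <- solve_steady_state(with_overrides(builtin_parameters("propranolol"),
                                          list(k1 = 198, k3 = 66600,
                                               k4 = 940)))
  expect_equal(s6$LF, s6$arterial$LF0, tolerance = 1e-12)
  s16 <- solve_steady_state(with_overrides(builtin_parameters("imipramine"),
                                           list(k1 = 72, k7 = 252,
                                                k3 = 150000, k4 = 2100)))
  expect_equal(s16$LF, s16$arterial$LF0, tolerance = 1e-12)
})

test_that("without plasma binding all free pools equal total drug", {
  p <- with_overrides(builtin_parameters("propranolol"),
                      list(AF = 0, GT0 = 0, k4 = 66 * 0.01 / 0.7))
  s <- solve_steady_state(p)
  expect_equal(s$arterial$LF0, 100)
  expect_equal(s$LF, 100, tolerance = 1e-12)
  expect_equal(s$LM, 100, tolerance = 1e-12)
})

test_that("kpuu equals the PS-product ratio without brain metabolism", {
  p <- builtin_parameters("propranolol")
  expect_equal(kp_uu(p), (66 * 0.01) / (0.943 * 0.7))
  expect_equal(kp_uu(p), 1.000, tolerance = 2e-4)
  s <- solve_steady_state(p)
  expect_equal(s$kpuu, kp_uu(p), tolerance = 1e-12)

  i <- builtin_parameters("imipramine")
  expect_equal(kp_uu(i), 1.5 / 1.47)
  expect_equal(solve_steady_state(i)$kpuu, 1.5 / 1.47, tolerance = 1e-12)

  # active efflux (tenfold k4) drops the brain-to-plasma unbound ratio
  aet <- with_overrides(p, list(k4 = 9.4))
  s7 <- solve_steady_state(aet)
  expect_equal(s7$LM / s7$LF, 2.1 / 20.6, tolerance = 0.02)
  # with metabolism kpuu is the realized LM/LF, below the PS ratio
  met <- with_overrides(p, list(k9 = 6))
  expect_lt(kp_uu(met), kp_uu(p))
  expect_equal(kp_uu(met), solve_steady_state(met)$kpuu)
})

test_that("free brain drug is independent of tissue binding", {
  p <- builtin_parameters("propranolol")
  base <- solve_steady_state(p)
  for (PT in c(100, 500, 1000, 5000, 10000)) {
    for (fac in c(0.01, 1, 100)) {
      s <- solve_steady_state(with_overrides(p, list(PT = PT,
                                                     k5 = 0.006 * fac)))
      expect_equal(s$LM, base$LM, tolerance = 1e-9)
      expect_equal(s$LF, base$LF, tolerance = 1e-9)
    }
  }
  # while PL grows monotonically with PT
  pl <- vapply(c(100, 500, 1000, 5000, 10000), function(PT)
    solve_steady_state(with_overrides(p, list(PT = PT)))$PL, numeric(1))
  expect_true(all(diff(pl) > 0))
})

test_that("raising the in-vivo AGP dissociation rate never lowers LF", {
  p <- builtin_parameters("propranolol")
  k1_base <- 0.06 * 3300  # in-vitro-consistent dissociation rate
  lf <- vapply(k1_base * c(1, 2, 5, 10, 30, 100), function(k1)
    solve_steady_state(with_overrides(p, list(k1 = k1)))$LF, numeric(1))
  expect_true(all(diff(lf) >= -1e-12))
  expect_equal(lf[1], solve_steady_state(p)$arterial$LF0,
               tolerance = 1e-12)
})

test_that("closed form agrees with the stationary-point oracle", {
  for (drug in c("propranolol", "imipramine")) {
    p <- builtin_parameters(drug)
    cf <- solve_steady_state(p)
    or <- stationary_oracle(p)
    for (f in c("GL", "AL", "LF", "GF", "LM", "PL", "PF"))
      expect_equal(or[[f]], cf[[f]], tolerance = 1e-6)
  }
  set.seed(433)
  for (rep in 1:200) {
    p <- random_drug_params(with_metabolism = rep %% 4 == 0)
    cf <- solve_steady_state(p)
    or <- stationary_oracle(p)
    for (f in c("GL", "AL", "LF", "GF", "LM", "PL", "PF"))
      expect_equal(or[[f]], cf[[f]], tolerance = 1e-6,
                   label = paste0("draw ", rep, " ", f, " oracle"),
                   expected.label = "closed form")
  }
  # no-binding limit is exact
  free <- with_overrides(builtin_parameters("propranolol"),
                         list(AF = 0, GT0 = 0, k4 = 66 * 0.01 / 0.7))
  or <- stationary_oracle(free)
  expect_equal(or$LF, 100, tolerance = 1e-9)
  expect_equal(or$LM, 100, tolerance = 1e-9)
})
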