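# Closed-form event probabilities: frozen example values, analytic
# properties, and agreement between the plain-R reference forms and the
# compiled engine's internal evaluators over parameter lattices.

test_that("bond breaking uses the synergy exponent 3/2 on double chains", {
  p <- default_params()
  expect_equal(bond_break_probability(FALSE, p), 2e-6)
  expect_equal(bond_break_probability(TRUE, p), (2e-6)^1.5)
  expect_equal(bond_break_probability(TRUE, p), 2.8284271e-9,
               tolerance = 1e-7)
  p$P_BB <- 1
  expect_equal(bond_break_probability(TRUE, p), 1)
})

test_that("strand separation is P_SP^((r+1)/2), decreasing in r", {
  p <- default_params()
  expect_equal(separation_probability(1, p), 0.38)
  expect_equal(separation_probability(3, p), 0.38^2)
  expect_equal(separation_probability(3, p), 0.1444)
  v <- separation_probability(1:30, p)
  expect_true(all(diff(v) < 0))
  expect_error(separation_probability(0, p), ">= 1")
  # brute-force per-pair route: multiply sqrt(P_SP) once per pair, times
  # one extra half-power
  brute <- vapply(1:30, function(r) {
    acc <- sqrt(p$P_SP)
    for (i in seq_len(r)) acc <- acc * sqrt(p$P_SP)
    acc
  }, 0)
  expect_equal(v, brute, tolerance = 1e-12)
})

test_that("membrane formation switches on at the amphiphile lower limit", {
  p <- default_params()
  expect_equal(membrane_formation_probability(500, p), 0.01)
  expect_equal(membrane_formation_probability(499, p), 0)
  expect_equal(membrane_formation_probability(501, p), 1 - 0.99^2)
  expect_equal(membrane_formation_probability(501, p), 0.0199)
  expect_true(all(diff(membrane_formation_probability(400:900, p)) >= 0))
})

test_that("osmotic pressure retards amphiphile loss", {
  p <- default_params()
  expect_equal(amphiphile_leave_probability(1000, 0, p), p$P_ALM)
  expect_equal(amphiphile_leave_probability(1000, 500, p),
               2e-4 / (1 + 10 * 500 / (500^1.5)))
  expect_equal(amphiphile_leave_probability(1000, 500, p), 1.3819e-4,
               tolerance = 1e-4)
  v <- amphiphile_leave_probability(1000, seq(0, 5000, by = 100), p)
  expect_true(all(diff(v) < 0))
})

test_that("precursor influx scales with membrane size and is Donnan-suppressed", {
  p <- default_params()
  expect_equal(precursor_permeation_in_probability(500, 0, p), p$P_NPP)
  expect_equal(precursor_permeation_in_probability(1000, 0, p), 0.2)
  v <- precursor_permeation_in_probability(1000, seq(0, 5000, 100), p)
  expect_true(all(diff(v) < 0))
  p$P_NPP <- 1
  expect_equal(precursor_permeation_in_probability(1e6, 0, p), 1)  # clamped
})

test_that("division needs a membrane above twice the assembly limit", {
  p <- default_params()
  expect_equal(division_probability(1000, p), 0)
  expect_equal(division_probability(2000, p), 5e-5)
  v <- division_probability(seq(1000, 10000, by = 100), p)
  expect_true(all(diff(v) >= 0))
})

test_that("molecular movement scales with the inverse square root of mass", {
  p <- default_params()
  expect_equal(molecule_move_probability(1, p), 1e-4)
  expect_equal(molecule_move_probability(4, p), 5e-5)
  expect_equal(molecule_move_probability(100, p), 1e-5)
  expect_error(molecule_move_probability(0, p), ">= 1")
})

test_that("compiled engine formulas match the R reference on lattices", {
  p <- default_params()
  r <- 1:30
  expect_equal(protoworld:::cpp_formula_separation(r, p$P_SP),
               separation_probability(r, p))
  expect_equal(protoworld:::cpp_formula_bond_break(c(TRUE, FALSE), p$P_BB),
               bond_break_probability(c(TRUE, FALSE), p))
  a <- seq(350, 1200, by = 7)
  expect_equal(protoworld:::cpp_formula_membrane(a, p$P_MF, p$L_AM),
               membrane_formation_probability(a, p))
  grid <- expand.grid(b = seq(500, 4000, by = 350),
                      n = seq(0, 3000, by = 300))
  expect_equal(
    protoworld:::cpp_formula_leave(grid$b, grid$n, p$P_ALM, p$F_OP),
    amphiphile_leave_probability(grid$b, grid$n, p))
  expect_equal(
    protoworld:::cpp_formula_perm_in(grid$b, grid$n, p$P_NPP, p$L_AM,
                                     p$F_DE),
    precursor_permeation_in_probability(grid$b, grid$n, p))
  expect_equal(protoworld:::cpp_formula_division(grid$b, p$P_CD, p$L_AM),
               division_probability(grid$b, p))
  m <- c(1:50, 100, 400)
  expect_equal(protoworld:::cpp_formula_move(m, p$P_MV),
               molecule_move_probability(m, p))
})
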