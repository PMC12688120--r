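test_that("monomeric equilibrium reproduces Michaelis-Menten occupancy", {
  st <- solve_al(ligand_params(conc = 1, K_P = 1), receptor_config(1))
  expect_equal(st$species[["F"]], 0.5)          # EC50 point
  expect_equal(st$species[["A"]], 0.5)

  st0 <- solve_al(ligand_params(conc = 0, K_P = 1), receptor_config(1))
  expect_equal(st0$species[["F"]], 0)
  expect_equal(st0$species[["A"]], 1)

  st2 <- solve_al(ligand_params(conc = 3, K_P = 2), receptor_config(4))
  expect_equal(st2$species[["F"]], 4 * 6 / 7, tolerance = 1e-12)
  expect_lt(abs(st2$residuals[["A"]]), 1e-12)
})

test_that("homodimeric (ALA) equilibrium satisfies its relations and conservation", {
  lig <- ligand_params(conc = 1, K_P = 1, K_F = 0.01)
  st <- solve_ala(lig, receptor_config(1))
  # independent root of 0.02 A^2 + 2 A - 1 = 0
  A_ref <- (-2 + sqrt(4 + 4 * 0.02)) / (2 * 0.02)
  expect_equal(st$species[["A"]], A_ref, tolerance = 1e-12)
  expect_equal(st$species[["A"]], 0.49752, tolerance = 1e-4)
  expect_equal(st$species[["F"]], 2.4753e-3, tolerance = 1e-4)
  expect_lt(abs(st$residuals[["A"]]), 1e-12)
  expect_equal(st$species[["P"]], lig$K_P * lig$conc * st$species[["A"]])
  expect_equal(st$species[["F"]],
               lig$K_F * st$species[["A"]] * st$species[["P"]])

  # no ligand, no complexes
  st0 <- solve_ala(ligand_params(0, 1, 1), receptor_config(2))
  expect_equal(unname(st0$species), c(2, 0, 0))

  # high full-complex affinity at the partial EC50: all subunits pair up
  stH <- solve_ala(ligand_params(1, 1, 1e6), receptor_config(1))
  expect_equal(stH$species[["F"]], 0.5, tolerance = 2e-3)
  # and F -> A0/2 monotonically as K_F grows
  Fs <- vapply(c(1e2, 1e4, 1e6),
               function(k) solve_ala(ligand_params(1, 1, k),
                                     receptor_config(1))$species[["F"]],
               numeric(1))
  expect_true(all(diff(Fs) > 0) && all(Fs < 0.5))
})

test_that("two-ligand homodimer (LAAL) conserves subunits and saturates to A0/2", {
  # conservation identity on arbitrary parameters
  set.seed(11)
  for (i in 1:20) {
    lig <- random_ligand()
    A0 <- runif_log(1, 1e-2, 1e2)
    st <- solve_laal(lig, receptor_config(A0))
    expect_equal(st$species[["A"]] + st$species[["P"]] + 2 * st$species[["F"]],
                 A0, tolerance = 1e-12)
  }
  # K_F -> Inf at the partial EC50: free subunits vanish and re-equilibrate
  # into partials, so pairing consumes them all: F -> A0/2, 2F/A0 -> 1
  Fs <- vapply(c(1e4, 1e6, 1e8),
               function(k) solve_laal(ligand_params(1, 1, k),
                                      receptor_config(1))$species[["F"]],
               numeric(1))
  expect_true(all(diff(Fs) > 0))
  expect_equal(Fs[3], 0.5, tolerance = 2e-4)
  expect_equal(solve_laal(ligand_params(0, 1, 1),
                          receptor_config(1))$species[["F"]], 0)
})

test_that("sequential heterodimer (ALB) equilibrium is the feasible quadratic root", {
  st <- solve_alb_seq(ligand_params(1, 1, 1), receptor_config(1, 1))
  expect_equal(st$species[["F"]], 2 - sqrt(3), tolerance = 1e-12)
  expect_lt(max(abs(st$residuals)), 1e-12)

  st0 <- solve_alb_seq(ligand_params(0, 1, 1), receptor_config(1, 2))
  expect_equal(st0$species[["F"]], 0)
  expect_equal(st0$species[["B"]], 2)

  # saturating affinities: the limiting subunit caps the complex
  stS <- solve_alb_seq(ligand_params(1, 1e6, 1e6), receptor_config(1, 2))
  expect_equal(stS$species[["F"]], 1, tolerance = 1e-3)

  # degenerate totals give the all-zero complex state
  stz <- solve_alb_seq(ligand_params(1, 1, 1), receptor_config(0, 1))
  expect_equal(stz$species[["F"]], 0)
})

test_that("parameter-domain violations are rejected", {
  expect_error(ligand_params(-1, 1), "non-negative")
  expect_error(ligand_params(1, 0), "positive")
  expect_error(ligand_params(1, 1, activity = -2), "non-negative")
  expect_error(receptor_config(-1), "non-negative")
  expect_error(solve_alb_seq(ligand_params(1, 1), receptor_config(1)), "B0")
  expect_error(model_kind("XYZ"), "unknown model kind")
})

test_that("response is e * F^n and rejects non-positive exponents", {
  st <- solve_al(ligand_params(1, 1), receptor_config(1))  # F = 0.5
  expect_equal(response(st, ligand_params(1, 1, activity = 1)), 0.5)
  expect_equal(response(st, ligand_params(1, 1, activity = 2)), 1.0)
  expect_equal(response(st, ligand_params(1, 1, activity = 1), n = 2), 0.25)
  expect_error(response(st, ligand_params(1, 1), n = 0), "positive")
})

test_that("conservation laws hold to relative 1e-9 across random draws", {
  set.seed(42)
  nd <- 1e4
  kpc <- runif_log(nd); kf <- runif_log(nd)
  # vectorized kernels, A0 = 1 (dimensionless groups span [1e-4, 1e4])
  A_ala <- dimerscale:::homodimer_free_A(kpc, kf * kpc, 1)
  expect_lt(max(abs(A_ala * (1 + kpc) + 2 * kf * kpc * A_ala^2 - 1)), 1e-9)
  A_laal <- dimerscale:::homodimer_free_A(kpc, kf * kpc^2, 1)
  expect_lt(max(abs(A_laal * (1 + kpc) + 2 * kf * kpc^2 * A_laal^2 - 1)), 1e-9)
  B0 <- runif_log(nd, 1e-2, 1e2)
  alpha <- kf * kpc / (1 + kpc)
  Fab <- dimerscale:::alb_complex_kernel(alpha, 1, B0)
  A <- (1 - Fab) / (1 + kpc)
  expect_lt(max(abs(A + kpc * A + Fab - 1)), 1e-9)
  expect_lt(max(abs((B0 - Fab) + Fab - B0) / B0), 1e-9)
  expect_true(all(Fab >= 0 & Fab <= pmin(1, B0)))
})

test_that("ALA dose-response is non-monotonic in ligand concentration (hook effect)", {
  lig_at <- function(C) ligand_params(conc = C, K_P = 1, K_F = 1)
  F_at <- function(C) solve_ala(lig_at(C), receptor_config(1))$species[["F"]]
  Fs <- vapply(c(1e-3, 1, 1e3), F_at, numeric(1))
  expect_gt(Fs[2], Fs[1])
  expect_gt(Fs[2], Fs[3])
})

test_that("ALA behavior depends only on the dimensionless groups K_P*C and K_F*A0", {
  base <- list(C = 2, K_P = 0.5, K_F = 3, A0 = 0.7)
  f0 <- with(base, 2 * solve_ala(ligand_params(C, K_P, K_F),
                                 receptor_config(A0))$species[["F"]] / A0)
  for (lam in c(10, 0.037)) for (mu in c(5, 0.2)) {
    f1 <- with(base, 2 * solve_ala(
      ligand_params(C * lam, K_P / lam, K_F / mu),
      receptor_config(A0 * mu))$species[["F"]] / (base$A0 * mu))
    expect_equal(f1, f0, tolerance = 1e-12)
  }
})

test_that("solve_model dispatches to the matching architecture", {
  lig <- ligand_params(1, 1, 1)
  expect_identical(solve_model("AL", lig, receptor_config(1))$model, "AL")
  expect_identical(solve_model("ala", lig, receptor_config(1))$model, "ALA")
  expect_identical(solve_model("ALB", lig, receptor_config(1, 1))$model, "ALB_SEQ")
  expect_error(solve_model("ALB_NONSEQ", lig, receptor_config(1, 1)),
               "solve_alb_nonseq")
})
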