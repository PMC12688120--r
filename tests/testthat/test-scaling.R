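test_that("monomeric scaling is identically one across ligand parameters", {
  for (kp in c(1e-3, 1, 1e3)) for (C in c(0.01, 1, 100)) {
    s <- local_scaling("AL", ligand_params(C, kp), receptor_config(1))
    expect_equal(s$S, 1, tolerance = 1e-6)
  }
  expect_error(local_scaling("AL", ligand_params(0, 1), receptor_config(1)),
               "undefined")
})

test_that("homodimer scaling hits its regime extremes", {
  # sub-saturated full-complex step: quadratic dependence, S ~ 2
  s2 <- local_scaling("ALA", ligand_params(1, 1, 1e-6), receptor_config(1))
  expect_equal(s2$S, 2, tolerance = 1e-3)
  # saturated full-complex step: linear dependence, S ~ 1
  s1 <- local_scaling("ALA", ligand_params(1, 1, 1e6), receptor_config(1))
  expect_equal(s1$S, 1, tolerance = 1e-2)
})

test_that("ALA scaling collapses onto the bound fraction as 2/(1+f)", {
  expect_equal(scaling_from_bound_fraction_ala(0), 2)
  expect_equal(scaling_from_bound_fraction_ala(1), 1)
  expect_error(scaling_from_bound_fraction_ala(1.2), "\\[0, 1\\]")

  # numeric-derivative oracle at the regime endpoints
  for (kfa in c(1e-8, 1e8)) {
    s <- local_scaling("ALA", ligand_params(1, 1, kfa), receptor_config(1))
    expect_equal(s$S, scaling_from_bound_fraction_ala(s$bound_fraction),
                 tolerance = 1e-6)
  }
  # and across random draws
  set.seed(23)
  for (i in 1:100) {
    lig <- random_ligand()
    s <- local_scaling("ALA", lig, receptor_config(1))
    expect_equal(scaling_from_bound_fraction_ala(s$bound_fraction), s$S,
                 tolerance = 1e-4)
  }
})

test_that("single-ligand ALA scaling depends on parameters only through the bound fraction", {
  # engineer two very different parameter sets with the same bound fraction
  f_target <- 0.37
  kf_for <- function(kpc, A0 = 1) {
    # from A(1+kpc) + f*A0 = A0 with A = A0*(1-f)/(... ) under P = kpc*A:
    # A*(1+kpc) = A0*(1-f), F = f*A0/2  =>  K_F = F/(kpc*A^2)
    A <- (1 - f_target) / (1 + kpc)
    f_target / 2 / (kpc * A^2)
  }
  s1 <- local_scaling("ALA", ligand_params(1, 1, kf_for(1)), receptor_config(1))
  s2 <- local_scaling("ALA", ligand_params(50, 0.002, kf_for(0.1)),
                      receptor_config(1))
  expect_equal(s1$bound_fraction, f_target, tolerance = 1e-10)
  expect_equal(s2$bound_fraction, f_target, tolerance = 1e-10)
  expect_equal(s1$S, s2$S, tolerance = 1e-6)
})

test_that("a zero-activity inhibitor breaks the scaling-bound fraction collapse", {
  act <- ligand_params(1, 1, 1)
  rec <- receptor_config(1)
  no_inh <- ligand_params(0, 1, 1, activity = 0)
  inh <- ligand_params(1, 1, 1, activity = 0)
  # both settings tuned to the same activator-complex amount F_L = 0.05
  # (attainable with the inhibitor present: its competition caps the peak)
  FL <- 0.05
  C0 <- hold_complex_constant(act, no_inh, rec, FL, interval = c(-6, 6))
  act0 <- act; act0$conc <- C0
  s0 <- competition_scaling(act0, no_inh, rec)
  C1 <- hold_complex_constant(act, inh, rec, FL, interval = c(-6, 6))
  act1 <- act; act1$conc <- C1
  s1 <- competition_scaling(act1, inh, rec)
  expect_equal(s0$bound_fraction, 2 * FL / rec$A0, tolerance = 1e-6)
  expect_equal(s1$bound_fraction, s0$bound_fraction, tolerance = 1e-6)
  expect_gt(abs(s1$S - s0$S), 0.05)
  # an unattainable target is reported as such
  expect_error(hold_complex_constant(act, ligand_params(10, 1, 1, activity = 0),
                                     rec, 0.4, interval = c(-6, 6)),
               "not attainable")
})

test_that("heterodimer closed-form scaling matches the numeric derivative", {
  # unoccupied limit: both scalings -> 1
  sc0 <- scaling_alb_closed(receptor_config(1, 1), 1e-12)
  expect_equal(unname(sc0), c(1, 1), tolerance = 1e-10)
  # symmetric case
  sc <- scaling_alb_closed(receptor_config(1, 1), 2 - sqrt(3))
  expect_equal(unname(sc), rep(1 / (1 + 2 - sqrt(3)), 2), tolerance = 1e-12)
  expect_equal(unname(sc), rep(0.78868, 2), tolerance = 1e-4)
  # B limiting and nearly saturated: S_A -> 0
  expect_lt(scaling_alb_closed(receptor_config(1, 0.1), 0.1 * (1 - 1e-6))[["S_A"]],
            1e-4)
  expect_error(scaling_alb_closed(receptor_config(1, 0.5), 0.6), "below")

  set.seed(31)
  for (i in 1:100) {
    lig <- random_ligand()
    rec <- receptor_config(runif_log(1, 1e-2, 1e2), runif_log(1, 1e-2, 1e2))
    st <- solve_alb_seq(lig, rec)
    closed <- scaling_alb_closed(rec, st$species[["F"]])
    expect_equal(local_scaling("ALB_SEQ", lig, rec, "A")$S, closed[["S_A"]],
                 tolerance = 1e-4)
    expect_equal(local_scaling("ALB_SEQ", lig, rec, "B")$S, closed[["S_B"]],
                 tolerance = 1e-4)
  }
})

test_that("heterodimer scaling with the abundant subunit vanishes at saturation", {
  sB <- local_scaling("ALB_SEQ", ligand_params(1, 1e4, 1e4),
                      receptor_config(1, 100), "B")
  expect_lt(abs(sB$S), 1e-3)
  # joint scaling equals the per-subunit sum
  lig <- ligand_params(1, 2, 0.5)
  rec <- receptor_config(0.5, 3)
  s_both <- local_scaling("ALB_SEQ", lig, rec, "both")$S
  s_sum <- local_scaling("ALB_SEQ", lig, rec, "A")$S +
    local_scaling("ALB_SEQ", lig, rec, "B")$S
  expect_equal(s_both, s_sum, tolerance = 1e-6)
})

test_that("scaling is exactly independent of the activity rate", {
  for (model in c("AL", "ALA", "LAAL")) {
    lig1 <- ligand_params(1, 0.7, 2, activity = 1)
    lig2 <- ligand_params(1, 0.7, 2, activity = 7.3)
    s1 <- local_scaling(model, lig1, receptor_config(1))$S
    s2 <- local_scaling(model, lig2, receptor_config(1))$S
    expect_identical(s1, s2)
  }
})

test_that("a power-law readout multiplies the scaling by its exponent", {
  lig <- ligand_params(1, 1, 0.3)
  rec <- receptor_config(1)
  base <- local_scaling("ALA", lig, rec)$S
  for (n in c(0.5, 2, 3.7)) {
    expect_equal(local_scaling("ALA", lig, rec, n = n)$S, n * base,
                 tolerance = 1e-6)
    # still independent of e
    ligE <- lig; ligE$activity <- 7.3
    expect_identical(local_scaling("ALA", ligE, rec, n = n)$S,
                     local_scaling("ALA", lig, rec, n = n)$S)
  }
})

test_that("scan tables cover the documented ranges", {
  al <- scan_scaling("AL", kpc = log_space(1e-4, 1e4, 9),
                     kfx = log_space(1e-4, 1e4, 3))
  expect_true(all(abs(al$S - 1) < 1e-6))

  ala <- scan_scaling("ALA", kpc = log_space(1e-6, 1e6, 13),
                      kfx = log_space(1e-6, 1e6, 13))
  expect_true(all(ala$S >= 1 - 1e-6 & ala$S <= 2 + 1e-6))
  expect_lt(min(ala$S), 1.01)
  expect_gt(max(ala$S), 1.99)
  # monotone: scaling falls as the bound fraction rises
  ord <- order(ala$bound_fraction)
  expect_true(all(diff(ala$S[ord]) < 1e-6))

  alb <- scan_scaling("ALB_SEQ", kpc = log_space(1e-4, 1e4, 9),
                      kfx = log_space(1e-4, 1e4, 9), ratio = 0.25)
  expect_true(all(alb$S_A >= -1e-4 & alb$S_A <= 1 + 1e-4))
  expect_true(all(alb$S_B >= -1e-4 & alb$S_B <= 1 + 1e-4))
  expect_error(scan_scaling("ALA", kpc = numeric()), "empty")
  expect_error(scan_scaling("ALB_SEQ"), "ratio")
})
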