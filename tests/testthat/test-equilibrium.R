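test_that("solver agrees with an independent grid-scan oracle", {
  sys <- biphasic_system(volume_org = 0.5, volume_aq = 0.5,
                         P_neutral_0 = 1e3)
  st <- solve_equilibrium(naproxen, sys, n_total = 1e-2)
  oracle <- grid_scan_equilibrium(naproxen, sys, n_total = 1e-2)
  expect_equal(st$pH, oracle$pH, tolerance = 1e-6)
  expect_equal(st$logD, oracle$logD, tolerance = 1e-6)
  # and on the base branch with unequal volumes
  sysb <- biphasic_system(P_neutral_0 = 10^2.45)
  stb <- solve_equilibrium(lidocaine, sysb, n_total = 1e-3)
  orb <- grid_scan_equilibrium(lidocaine, sysb, n_total = 1e-3)
  expect_equal(stb$pH, orb$pH, tolerance = 1e-6)
  expect_equal(stb$logD, orb$logD, tolerance = 1e-6)
})

test_that("mass and charge balance close to 1e-9 relative across sweeps", {
  set.seed(42)
  for (i in 1:60) {
    cls <- sample(c("acid", "base"), 1)
    sol <- solute("x", cls, runif(1, 2.5, 11.5))
    sys <- biphasic_system(volume_org = runif(1, 0.1, 1),
                           volume_aq = runif(1, 0.1, 1),
                           P_neutral_0 = 10^runif(1, -1, 5),
                           conc_slope_s = runif(1, -2, 2),
                           P_ion = sample(c(0, 0.01), 1))
    st <- solve_equilibrium(sol, sys, n_total = 10^runif(1, -7, -1.5))
    res <- equilibrium_residuals(st)
    expect_lt(res[["mass_balance"]], 1e-9)
    expect_lt(res[["charge_balance"]], 1e-9)
    # the state also reproduces the solute pKa through the mass-action law
    expect_equal(dissociation_quotient(st$aqueous, cls), sol$pKa,
                 tolerance = 1e-9)
  }
})

test_that("infinite-dilution limits: pH -> 7 and logD -> closed form", {
  for (case in list(list(naproxen, 1e3), list(ibuprofen, 10^1.5),
                    list(lidocaine, 1e3))) {
    sol <- case[[1]]
    sys <- biphasic_system(P_neutral_0 = case[[2]])
    st <- solve_equilibrium(sol, sys, n_total = 1e-12)
    expect_equal(st$pH, 7, tolerance = 1e-3)
    expect_equal(st$logD, log10(closed_form_dow(sol, case[[2]])),
                 tolerance = 1e-3)
  }
  # approach direction: acids from below, bases from above
  expect_lt(solve_equilibrium(naproxen, biphasic_system(), 1e-12)$pH, 7)
  expect_gt(solve_equilibrium(lidocaine, biphasic_system(), 1e-12)$pH, 7)
})

test_that("closed-form D_OW evaluates the pH-7 ionization correction", {
  expect_equal(closed_form_dow(griseofulvin, 123.4), 123.4)
  expect_equal(closed_form_dow(naproxen, 1000), 1.5112738, tolerance = 1e-6)
  expect_equal(closed_form_dow(lidocaine, 1000), 107.32334, tolerance = 1e-5)
})

test_that("neutral solutes partition trivially at pH 7", {
  sys <- biphasic_system(P_neutral_0 = 10^2, conc_slope_s = 0)
  st <- solve_equilibrium(griseofulvin, sys, n_total = 5e-3)
  expect_identical(st$pH, 7)
  expect_equal(st$logD, 2)
  expect_equal(st$logP_apparent, 2)
  expect_identical(st$aqueous$c_charged_solute, 0)
})

test_that("species-resolved logP equals the logD conversion when P_ion = 0", {
  for (cls in c("acid", "base")) {
    for (pka in c(3, 4.18, 7.92, 10)) {
      sol <- solute("x", cls, pka)
      sys <- biphasic_system(P_neutral_0 = 10^2.5)
      for (ct in c(1e-6, 1e-4, 1e-2)) {
        st <- solve_equilibrium(sol, sys, n_total = ct)
        expect_equal(st$logP_apparent,
                     logp_from_logd(st$logD, st$pH, sol),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("logD rises and pH approaches neutrality with concentration", {
  grid <- 10^seq(-4, -2, length.out = 8)
  st <- species_table(naproxen, biphasic_system(P_neutral_0 = 1e3), grid)
  expect_true(all(diff(st$logD) > 0))
  expect_true(all(diff(st$pH) < 0))          # acid pH falls from near 7
  expect_true(all(st$pH < 7))
  stl <- species_table(lidocaine, biphasic_system(P_neutral_0 = 10^2.45),
                       grid)
  expect_true(all(diff(stl$logD) > 0))
  expect_true(all(diff(stl$pH) > 0))         # base pH rises away from 7
  expect_true(all(stl$pH > 7))
  # with s = 0 and P_ion = 0 the apparent logP is flat
  expect_equal(diff(range(st$logP_apparent)), 0, tolerance = 1e-9)
})

test_that("solver rejects invalid amounts and reports diagnostics", {
  expect_error(solve_equilibrium(naproxen, biphasic_system(), -1), ">= 0")
  # an absurd amount pushes the root outside the fixed bracket
  expect_error(solve_equilibrium(naproxen, biphasic_system(P_neutral_0 = 1),
                                 n_total = 1e6), "no sign change")
})

test_that("simulated series are deterministic under a seed and exact when noise-free", {
  sys <- biphasic_system(P_neutral_0 = 1e3)
  s1 <- simulate(sys, seed = 7, solute = naproxen)
  s2 <- simulate(sys, seed = 7, solute = naproxen)
  expect_identical(s1$measurements, s2$measurements)
  s3 <- simulate(sys, seed = 8, solute = naproxen)
  expect_false(identical(s1$measurements$c_org, s3$measurements$c_org))
  # noiseless output equals equilibrium values bit-exactly
  grid <- c(1e-4, 1e-3)
  sn <- simulate(sys, seed = 1, solute = naproxen, c_total_grid = grid,
                 noise = noise_model(0, 0))
  st <- solve_equilibrium(naproxen, sys, grid[1])
  expect_identical(sn$measurements$c_org[1], st$c_neutral_org)
  expect_identical(sn$measurements$pH[1], st$pH)
})

test_that("simulate restores the global RNG state when seeded", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate(biphasic_system(), seed = 99, solute = naproxen))
  expect_identical(.Random.seed, before)
})

test_that("designed concentration grids land in the method's pH window", {
  sys <- biphasic_system(P_neutral_0 = 1e3)
  for (sol in list(naproxen, ibuprofen, lidocaine)) {
    grid <- design_concentration_grid(sol, sys)
    expect_length(grid, 4L)
    expect_true(all(diff(grid) > 0))
    st <- species_table(sol, sys, grid)
    if (sol$ionization_class == "acid") {
      expect_true(all(st$pH > 5.9 & st$pH < 7))
    } else {
      expect_true(all(st$pH > 7 & st$pH < 7.6))
    }
  }
  expect_identical(design_concentration_grid(griseofulvin, sys),
                   10^seq(-4, -2, length.out = 4))
})
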