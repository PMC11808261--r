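test_that("mm_velocity follows the Michaelis-Menten form with unit conversion", {
  wt <- wt_params()
  expect_equal(mm_velocity(wt, Ea = 1.7, S = 0), 0)
  expect_equal(mm_velocity(wt, Ea = 0, S = 40), 0)
  # saturation limit kcat * E0 (uM -> mM)
  expect_equal(mm_velocity(wt, Ea = 1.7, S = 1e9), 4.25 * 0.0017,
               tolerance = 1e-6)
  expect_equal(mm_velocity(wt, Ea = 1.7, S = 40), 7.225e-3 * 40 / 43.69,
               tolerance = 1e-12)
  expect_error(mm_velocity(wt, Ea = -1, S = 5), "non-negative")
  expect_error(mm_velocity(wt, Ea = 1, S = -5), "non-negative")
})

test_that("parameter and condition constructors validate their domains", {
  expect_error(kinetic_params(Km = 0, kcat = 1), "Km")
  expect_error(kinetic_params(Km = 1, kcat = -1), "kcat")
  expect_error(kinetic_params(Km = 1, kcat = 1, kinact = -0.1), "kinact")
  expect_silent(kinetic_params(Km = 1, kcat = 1, kinact = 0))
  expect_error(reaction_conditions(E0 = 0, S0 = 40), "E0")
  expect_error(reaction_conditions(E0 = 1, S0 = 0), "S0")
})

test_that("simulate_progress validates the time grid", {
  wt <- wt_params()
  expect_error(simulate_progress(wt, wt_cond(), c(0, 10, 5)), "strictly increasing")
  expect_error(simulate_progress(wt, wt_cond(), c(5, 10, 20)), "start at 0")
})

test_that("without inactivation and saturating substrate, product grows linearly", {
  p <- kinetic_params(Km = 3.69, kcat = 4.25, kinact = 0)
  cond <- reaction_conditions(E0 = 1.7, S0 = 1000 * 3.69)
  # first ~1% of substrate: t such that kcat*E0*t <= 0.01*S0
  t_end <- 0.01 * cond$S0 / (4.25 * 0.0017) / 60 # minutes
  traj <- simulate_progress(p, cond, seq(0, t_end, length.out = 6))
  lin <- 4.25 * 0.0017 * traj$time_min * 60
  expect_lt(max(abs(traj$P_mM[-1] - lin[-1]) / lin[-1]), 0.002)
})

test_that("simulated trajectories satisfy both conservation invariants", {
  cases <- list(
    list(p = wt_params(0.0011), c = wt_cond()),
    list(p = kinetic_params(3.22, 8.29, 3e-4), c = wt_cond()),
    list(p = kinetic_params(0.5, 1.0, 5e-3), c = reaction_conditions(0.3, 5)),
    list(p = kinetic_params(10, 2, 1e-4), c = reaction_conditions(5, 100))
  )
  for (cs in cases) {
    traj <- simulate_progress(cs$p, cs$c, seq(0, 60, 5))
    expect_lt(max(abs(traj$S_mM + traj$P_mM - cs$c$S0)) / cs$c$S0, 1e-6)
    # Ea = E0 - (kinact/kcat) P, with P converted mM -> uM
    ea_pred <- cs$c$E0 - (cs$p$kinact / cs$p$kcat) * traj$P_mM * 1000
    expect_lt(max(abs(traj$Ea_uM - ea_pred)) / cs$c$E0, 1e-6)
    # monotonicity
    expect_true(all(diff(traj$P_mM) >= -1e-12))
    expect_true(all(diff(traj$S_mM) <= 1e-12))
    expect_true(all(diff(traj$Ea_uM) <= 1e-12))
  }
})

test_that("simulation matches the constant-substrate closed form", {
  # plateau = (kcat/kinact) E0 = 0.19 mM, i.e. S varies by ~0.5% of 40 mM
  p <- wt_params(0.0011)
  cond <- wt_cond(E0 = 0.05)
  tg <- seq(0, 120, 5)
  traj <- simulate_progress(p, cond, tg)
  expect_lt((cond$S0 - min(traj$S_mM)) / cond$S0, 0.01)
  exact <- closed_form_P(p, cond, tg)
  expect_lt(max(abs(traj$P_mM[-1] - exact[-1]) / exact[-1]), 1e-4)
})

test_that("product is bounded by the plateau and refining the grid leaves it unchanged", {
  p <- wt_params(0.0011)
  cond <- wt_cond()
  plateau <- as.numeric(final_product(p, cond))
  coarse <- simulate_progress(p, cond, seq(0, 60, 10))
  fine <- simulate_progress(p, cond, seq(0, 60, 1))
  expect_true(all(coarse$P_mM <= plateau * (1 + 1e-6)))
  p_end_coarse <- coarse$P_mM[nrow(coarse)]
  p_end_fine <- fine$P_mM[nrow(fine)]
  expect_lt(abs(p_end_coarse - p_end_fine) / p_end_fine, 1e-6)
})

test_that("first-order coupling decays the enzyme independently of saturation", {
  p <- kinetic_params(3.69, 4.25, 1e-3)
  cond <- reaction_conditions(E0 = 1, S0 = 2) # well below saturation
  tg <- seq(0, 30, 5)
  fo <- simulate_progress(p, cond, tg, coupling = "first_order")
  # active enzyme follows exp(-kinact t) regardless of S
  expect_equal(fo$Ea_uM, cond$E0 * exp(-1e-3 * tg * 60), tolerance = 1e-5)
  tc <- simulate_progress(p, cond, tg, coupling = "turnover")
  expect_true(all(tc$Ea_uM[-1] > fo$Ea_uM[-1])) # coupling slows decay off-saturation
})

test_that("partition ratio is kcat/kinact and demands inactivation", {
  expect_equal(partition_ratio(kinetic_params(3.69, 4.25, 0.0011)),
               4.25 / 0.0011)
  expect_equal(partition_ratio(kinetic_params(1, 1, 1)), 1)
  expect_equal(partition_ratio(kinetic_params(3.22, 8.29, 0.0003)),
               8.29 / 0.0003)
  expect_error(partition_ratio(kinetic_params(1, 1, 0)), "unbounded")
})

test_that("final_product takes the smaller of substrate and catalytic lifetime", {
  expect_equal(as.numeric(final_product(wt_params(0.0011), wt_cond())),
               (4.25 / 0.0011) * 0.0017)
  sub_lim <- final_product(kinetic_params(1, 1, 1e-6),
                           reaction_conditions(E0 = 1, S0 = 1))
  expect_equal(as.numeric(sub_lim), 1)
  expect_true(attr(sub_lim, "substrate_limited"))
  tiny <- final_product(wt_params(0.0011), reaction_conditions(1e-9, 40))
  expect_lt(as.numeric(tiny), 1e-8)
  expect_warning(out <- final_product(kinetic_params(1, 1, 0), wt_cond()),
                 "S0")
  expect_equal(as.numeric(out), 40)
})

test_that("increasing kinact strictly decreases the plateau", {
  ks <- c(2e-4, 5e-4, 1e-3, 2e-3)
  plateaus <- vapply(ks, function(k) {
    as.numeric(final_product(wt_params(k), wt_cond()))
  }, numeric(1))
  expect_true(all(diff(plateaus) < 0))
})
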