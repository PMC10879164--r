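test_that("cycle and rebound surfaces evaluate the printed coefficients", {
  expect_equal(fmd_cycle_change(45, 40), -3.5673, tolerance = 1e-10)
  # root of the cycle line gives zero change
  b0 <- (0.1017 + 0.1227 * 40) / 0.1906
  expect_equal(fmd_cycle_change(b0, 40), 0, tolerance = 1e-12)
  # linearity: finite differences match the coefficients
  expect_equal(fmd_cycle_change(46, 40) - fmd_cycle_change(45, 40), -0.1906,
               tolerance = 1e-12)
  expect_equal(fmd_cycle_change(45, 41) - fmd_cycle_change(45, 40), 0.1227,
               tolerance = 1e-12)

  expect_equal(rebound_change(45, 41.4327, 40), -3.148572, tolerance = 1e-6)
  # bioage_a = bioage_c collapses the two biological-age coefficients
  b <- 52.3
  expect_equal(rebound_change(b, b, 40),
               0.6687 - (0.5567 - 0.4008) * b + 0.1157 * 40,
               tolerance = 1e-12)
  expect_equal(rebound_change(45, 42, 40) - rebound_change(44, 42, 40),
               -0.5567, tolerance = 1e-12)
  expect_equal(rebound_change(45, 43, 40) - rebound_change(45, 42, 40),
               0.4008, tolerance = 1e-12)
})

test_that("one-year update chains cycle and rebound and advances the state", {
  st <- one_year_update(list(year = 0L, age = 40, bioage_a = 45))
  expect_equal(st$bioage_d, 45 - 3.5673 - 3.148572, tolerance = 1e-6)
  expect_equal(st$bioage_d, 38.284, tolerance = 1e-3)
  expect_equal(st$age, 41)
  expect_equal(st$year, 1L)
  expect_equal(st$bioage_a, st$bioage_d)
  # vanishing decay leaves biological age unchanged
  st0 <- one_year_update(list(year = 0L, age = 40, bioage_a = 45),
                         decay = 1e-12)
  expect_equal(st0$bioage_d, 45, tolerance = 1e-8)
  expect_error(one_year_update(list(year = 0L, age = 40, bioage_a = 45),
                               decay = 0), "\\(0, 1\\]")
})

test_that("iterated engine matches the composed affine recurrence exactly", {
  map <- fmd_affine_map()
  expect_equal(unname(map), c(0.57710752, 0.28757816, 0.81116136),
               tolerance = 1e-12)
  for (start in list(c(40, 45), c(25, 22), c(55, 70))) {
    traj <- simulate_person(start[1], start[2],
                            sim_config(horizon = start[1] + 30, draws = 1))
    b <- start[2]
    for (i in seq_len(nrow(traj))) {
      b_next <- map["a"] * b + map["b"] * (start[1] + i - 1) + map["c"]
      expect_lt(abs(traj$bioage_d[i] - b_next), 1e-10)
      b <- b_next
    }
  }
})

test_that("annual increments stabilize at the fixed-point slope from any start", {
  map <- fmd_affine_map()
  slope <- unname(map["b"] / (1 - map["a"]))
  expect_equal(slope, 0.6800, tolerance = 1e-4)
  for (start in list(c(30, 50), c(20, 20), c(45, 30))) {
    traj <- simulate_person(start[1], start[2],
                            sim_config(horizon = start[1] + 60, draws = 1))
    inc <- diff(traj$bioage_d)
    expect_lt(abs(inc[length(inc)] - slope), 1e-6)
  }
})

test_that("decay multipliers match the stated schedule and diverge at year 3", {
  expect_equal(decay_multiplier(0:2, "linear"), c(1, 1 / 2, 1 / 4))
  expect_equal(decay_multiplier(0:2, "doubling"), c(1, 1 / 2, 1 / 4))
  expect_equal(decay_multiplier(3, "linear"), 1 / 6)
  expect_equal(decay_multiplier(3, "doubling"), 1 / 8)
  expect_equal(decay_multiplier(0:5, "none"), rep(1, 6))
  expect_error(decay_multiplier(-1, "linear"), ">= 0")
})

test_that("deterministic simulation is draw- and seed-invariant", {
  cfg <- sim_config(horizon = 70, draws = 5, seed = 1)
  traj <- simulate_person(69, 72, cfg)
  expect_equal(nrow(traj), 5)            # 5 draws x 1 year
  expect_equal(unique(traj$year), 0)
  by_draw <- split(traj$bioage_d, traj$draw)
  expect_true(all(vapply(by_draw, identical, logical(1), by_draw[[1]])))
  traj2 <- simulate_person(69, 72, sim_config(horizon = 70, draws = 5,
                                              seed = 999))
  expect_equal(traj$bioage_d, traj2$bioage_d)
  expect_error(simulate_person(70, 60, sim_config(horizon = 70)),
               "exceed")
})

test_that("Monte-Carlo mean converges to the deterministic trajectory", {
  coeffs_se <- fmd_coefficients(
    cycle_se = c(intercept = 0.02, bioage = 0.002, age = 0.002),
    rebound_se = c(intercept = 0.02, bioage_a = 0.002, bioage_c = 0.002,
                   age = 0.002)
  )
  cfg <- sim_config(horizon = 50, draws = 10000, seed = 4)
  traj <- simulate_person(40, 45, cfg, coeffs_se)
  det <- simulate_person(40, 45, sim_config(horizon = 50, draws = 1))
  mc <- aggregate(traj$bioage_d, by = list(year = traj$year), FUN = mean)
  mc_se <- aggregate(traj$bioage_d, by = list(year = traj$year),
                     FUN = function(v) sd(v) / sqrt(length(v)))
  expect_true(all(abs(mc$x - det$bioage_d) < 3.5 * mc_se$x))
})

test_that("survey weights select the rounded number of draws", {
  cfg <- sim_config(horizon = 45, draws = 10, seed = 2)
  traj <- simulate_person(40, 45, cfg)
  agg <- weighted_aggregate(traj, sampling_weight = 3291, cfg)
  expect_equal(unique(agg$k), 6)  # 3291 / 548.5 = 6.0
  agg1 <- weighted_aggregate(traj, sampling_weight = 548.5, cfg)
  expect_equal(unique(agg1$k), 1)
  agg_min <- weighted_aggregate(traj, sampling_weight = 10, cfg)
  expect_equal(unique(agg_min$k), 1)  # clamped to at least one draw
  # zero-SE draws are identical, so any k reproduces the deterministic path
  det <- simulate_person(40, 45, sim_config(horizon = 45, draws = 1))
  expect_equal(agg$bioage_d, det$bioage_d, tolerance = 1e-12)
  expect_error(weighted_aggregate(traj, sampling_weight = 1e5, cfg),
               "available")
})

test_that("population simulation reduces to the single trajectory when homogeneous", {
  cohort <- data.frame(id = 1:4, age = rep(40, 4), bioage = rep(45, 4),
                       sample_weight = c(600, 3291, 100000, 548.5))
  cfg <- sim_config(horizon = 70, draws = 1)
  pop <- population_simulation(cohort, cfg)
  det <- simulate_person(40, 45, cfg)
  for (pid in 1:4) {
    sub <- pop$per_person[pop$per_person$id == pid, ]
    expect_equal(sub$bioage_d, det$bioage_d, tolerance = 1e-12)
  }
  map <- fmd_affine_map()
  expect_equal(pop$stabilized_increment, unname(map["b"] / (1 - map["a"])),
               tolerance = 1e-4)
  expect_error(population_simulation(data.frame(age = 40, bioage = NA,
                                                sample_weight = 10), cfg),
               "lacks biological age")
})

test_that("doubling decay freezes late-trajectory biological age", {
  traj <- simulate_person(30, 40, sim_config(horizon = 70, draws = 1,
                                             decay = "doubling"))
  late <- diff(traj$bioage_d)
  expect_lt(abs(late[length(late)]), 1e-6)
  # chronological age still advances
  expect_equal(diff(traj$age), rep(1, nrow(traj) - 1))
})
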