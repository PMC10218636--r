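test_that("Monod law reproduces the reference operating points", {
  kin <- rs_kinetics()
  # 0.86 mmol/L residual glucose -> 45% of capacity; minimum -> 21%
  expect_equal(round(100 * uptake_fraction(rs_point$S_res, kin)), 45)
  expect_equal(round(100 * uptake_fraction(rs_point$S_min, kin)), 21)
  expect_equal(monod_rate(0, kin), 0)
  expect_equal(monod_rate(kin$K_S, kin), kin$q_max / 2)
  expect_error(monod_rate(-1, kin), "negative")
})

test_that("Monod rate is monotone and bounded by q_max", {
  kin <- rs_kinetics()
  S <- sort(withr::with_seed(1, stats::runif(200, 0, 1e4)))
  q <- monod_rate(S, kin)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q <= kin$q_max))
  expect_lt(kin$q_max - monod_rate(1e12, kin), 1e-9)
})

test_that("maintenance margin stays five-fold above demand at the minimum", {
  kin <- rs_kinetics()
  expect_gte(maintenance_margin(rs_point$S_min, kin), 5)
})

test_that("dilution profiles reproduce the feed program arithmetic", {
  cfg <- reactor_config()
  cont <- dilution_profile(continuous_feed(2.83), cfg)
  expect_equal(cont$net_dilution, 2.83 * 0.06 / 1.7)
  expect_equal(round(cont$net_dilution, 2), 0.10)

  cyc <- dilution_profile(intermittent_feed(), cfg)
  expect_equal(cyc$net_flow, 3.64 * 7 / 9)
  expect_equal(cyc$net_dilution, cont$net_dilution, tolerance = 1e-3)

  zero <- dilution_profile(feed_schedule(c(2, 7), c(0, 0), cyclic = TRUE),
                           cfg, times = seq(0, 9, 0.5))
  expect_equal(zero$net_dilution, 0)
  expect_true(all(zero$profile$dilution == 0))

  expect_error(feed_schedule(numeric(0), numeric(0)), "empty")
  expect_error(feed_schedule(c(-1, 2), c(1, 1)), "> 0")
})

test_that("instantaneous dilution follows the cyclic segments", {
  cfg <- reactor_config()
  pr <- dilution_profile(intermittent_feed(), cfg,
                         times = c(0.5, 1.9, 2.5, 8.9, 9.5, 11.5))$profile
  on <- 3.64 * 0.06 / 1.7
  expect_equal(pr$dilution, c(0, 0, on, on, 0, on))
})

test_that("feed-off depletion matches the integrated-Monod oracle", {
  cfg <- reactor_config()
  kin <- rs_kinetics()
  traj <- simulate_sre(cfg, feed_schedule(c(2, 10), c(0, 2.83)), kin,
                       init = list(glucose = rs_point$S_res,
                                   biomass = rs_point$X),
                       horizon = 12)
  off <- as.data.frame(traj)[traj$time_min <= 2, ]
  oracle <- integrated_monod(off$time_min, kin$q_max, kin$K_S,
                             rs_point$S_res, rs_point$X)
  expect_lt(max(abs(off$glucose - oracle) / oracle), 0.005)
  # the 2-min pulse lands in the observed range (0.20-0.31 mmol glucose/L)
  S2 <- off$glucose[which.min(abs(off$time_min - 2))] / 6
  expect_gte(S2, 0.20)
  expect_lte(S2, 0.31)
})

test_that("zero-uptake limit follows the washout closed form", {
  cfg <- reactor_config()
  kin0 <- uptake_kinetics(q_max = 1e-9)
  traj <- simulate_sre(cfg, continuous_feed(2.83), kin0,
                       init = list(glucose = 100, biomass = 0.01),
                       horizon = 60, dt_out = 0.5)
  D <- dilution_profile(continuous_feed(2.83), cfg)$net_dilution
  Sfeed <- feed_mmol_c(cfg)
  expected <- Sfeed - (Sfeed - 100) * exp(-D * traj$time_min / 60)
  expect_lt(max(abs(traj$glucose - expected) / expected), 1e-6)
})

test_that("the analytic steady state is a fixed point of the simulator", {
  cfg <- reactor_config()
  kin <- rs_kinetics()
  D <- dilution_profile(continuous_feed(2.83), cfg)$net_dilution
  ss <- steady_state(cfg, kin, D)
  # consistency with the printed operating point
  expect_equal(ss$glucose / 6, 0.86, tolerance = 0.03)
  expect_equal(ss$biomass, 5.06, tolerance = 0.01)
  traj <- simulate_sre(cfg, continuous_feed(2.83), kin,
                       init = ss[c("glucose", "biomass", "products")],
                       horizon = 30)
  expect_lt(max(abs(traj$glucose - ss$glucose)) / ss$glucose, 1e-6)
  expect_lt(max(abs(traj$biomass - ss$biomass)) / ss$biomass, 1e-6)
})

test_that("carbon is conserved when yields sum to one", {
  cfg <- reactor_config()
  py <- c(ethanol = 0.52, co2 = 0.247, glycerol = 0.084, acetate = 0.0012,
          succinate = 0.0009, unknown = 0.0329)
  kin <- uptake_kinetics(biomass_yield = 0.114, product_yields = py)
  expect_equal(kin$biomass_yield + sum(py), 1, tolerance = 1e-12)
  traj <- simulate_sre(cfg, intermittent_feed(), kin, horizon = 27)
  cb <- carbon_balance(traj)
  expect_lt(abs(cb$residual_fraction), 0.001)
})

test_that("cyclic feeding converges to a periodic dynamic steady state", {
  cfg <- reactor_config()
  kin <- rs_kinetics()
  # switch the continuous reference steady state to intermittent feeding
  ss <- steady_state(cfg, kin, 0.0999)
  traj <- simulate_sre(cfg, intermittent_feed(), kin,
                       init = ss[c("glucose", "biomass", "products")],
                       horizon = 9 * 50, dt_out = 0.1)
  cyc <- floor(traj$time_min / 9 - 1e-9)
  avgS <- tapply(traj$glucose, cyc, mean)
  avgX <- tapply(traj$biomass, cyc, mean)
  expect_lt(abs(avgS[49] - avgS[48]) / avgS[49], 0.001)
  expect_lt(abs(avgX[49] - avgX[48]) / avgX[49], 0.001)
  # cycle-average dilution equals the net dilution rate
  avgD <- mean(tapply(traj$dilution, cyc, mean)[10:48])
  expect_equal(avgD, dilution_profile(intermittent_feed(), cfg)$net_dilution,
               tolerance = 1e-6)
})

test_that("recovery after feed resumption is fast and well defined", {
  cfg <- reactor_config()
  kin <- rs_kinetics()
  traj <- simulate_sre(cfg, continuous_feed(2.83), kin,
                       init = list(glucose = rs_point$S_min,
                                   biomass = rs_point$X),
                       horizon = 15)
  rt <- recovery_time(traj, rs_point$S_res, tol = 0.05)
  expect_lte(rt, 8)
  # already within tolerance -> 0
  ss <- steady_state(cfg, kin, 0.0999)
  flat <- simulate_sre(cfg, continuous_feed(2.83), kin,
                       init = ss[c("glucose", "biomass", "products")],
                       horizon = 5)
  expect_equal(recovery_time(flat, ss$glucose, tol = 0.05), 0)
  expect_error(recovery_time(traj, -1), "S_ref")
})

test_that("washout recovery matches its closed-form solution", {
  # with negligible uptake, S(t) = S_feed - (S_feed - S0) e^(-D t)
  cfg <- reactor_config()
  kin0 <- uptake_kinetics(q_max = 1e-9)
  S0 <- 100; tol <- 0.05
  traj <- simulate_sre(cfg, continuous_feed(2.83), kin0,
                       init = list(glucose = S0, biomass = 0.01),
                       horizon = 3000, dt_out = 0.5)
  D <- dilution_profile(continuous_feed(2.83), cfg)$net_dilution
  Sfeed <- feed_mmol_c(cfg)
  t_exact <- log((Sfeed - S0) / (tol * Sfeed)) / D * 60
  rt <- recovery_time(traj, Sfeed, tol = tol)
  expect_equal(rt, t_exact, tolerance = 0.01)
})

test_that("carbon unit conversions are consistent", {
  expect_equal(g_to_mmol_c(50, "glucose"), 50 / 180.156 * 6000)
  expect_equal(mmol_c_to_mmol(5.16, "glucose"), 0.86)
  x <- 12.3
  expect_equal(mmol_c_to_g(g_to_mmol_c(x, "ethanol"), "ethanol"), x)
  expect_error(g_to_mmol_c(1, "caffeine"), "unknown species")
  reg <- species_registry(carbon_species("caffeine", 8, 194.19))
  expect_equal(mmol_to_mmol_c(2, "caffeine", reg), 16)
})
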