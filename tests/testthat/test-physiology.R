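test_that("specific rates follow the chemostat balance", {
  q <- specific_rate(rs_point$D, rs_point$S_res, rs_point$X,
                     feed_conc = 1666.7)
  expect_equal(as.numeric(q), rs_point$q_glucose, tolerance = 0.01)
  expect_equal(attr(q, "direction"), "uptake")
  # residual equals feed -> zero uptake
  expect_equal(as.numeric(specific_rate(0.1, 100, 5, feed_conc = 100)), 0)
  # product balance inverted: q_ethanol 16.7 at X = 5.06, D = 0.098
  broth <- 16.7 * rs_point$X / rs_point$D
  expect_equal(as.numeric(specific_rate(rs_point$D, broth, rs_point$X,
                                        type = "product")), 16.7)
  expect_equal(broth, 862, tolerance = 0.001)
  expect_error(specific_rate(0.1, 5, 5), "feed concentration")
})

test_that("yields are unit-invariant C-mol ratios", {
  expect_equal(yield_coefficient(7.68, 32.1), 0.239, tolerance = 0.002)
  expect_equal(yield_coefficient(0, 10), 0)
  expect_error(yield_coefficient(1, 0), "> 0")
  # computing both rates in g-based or C-mmol-based units cancels out
  q_eth_c <- specific_rate(0.098, 862, 5.06, type = "product")
  q_glc_c <- specific_rate(0.098, 5.16, 5.06, feed_conc = 1665.2)
  y1 <- yield_coefficient(q_eth_c, q_glc_c)
  scale_e <- g_to_mmol_c(1, "ethanol")
  q_eth_g <- specific_rate(0.098, 862 / scale_e, 5.06, type = "product")
  y2 <- yield_coefficient(q_eth_g * scale_e, q_glc_c)
  expect_equal(y1, y2, tolerance = 1e-12)
})

test_that("biomass yield at f_C = 0.45 reproduces the printed value", {
  consumed <- 1665.2 - rs_point$S_res
  expect_equal(biomass_yield(rs_point$X, consumed), 0.114,
               tolerance = 0.005)
})

test_that("carbon recovery is an additive stream sum", {
  expect_equal(as.numeric(carbon_recovery(c(a = 1))), 1)
  y <- c(biomass = 0.114, ethanol = 0.488, co2 = 0.239, glycerol = 0.084,
         acetate = 0.0012, succinate = 0.0009, unknown = 0.033)
  r <- as.numeric(carbon_recovery(y))
  expect_equal(r, sum(y))
  # permutation invariance and exact additivity of dropping one stream
  expect_equal(as.numeric(carbon_recovery(rev(y))), r)
  expect_equal(r - as.numeric(carbon_recovery(y[names(y) != "unknown"])),
               unname(y["unknown"]))
})

test_that("unknown carbon subtracts knowns and antifoam carbon", {
  u <- unknown_carbon(150, 120, antifoam = 0.2)
  expect_equal(attr(u, "antifoam_mmol_c"), 0.2 * 0.61 / 12.011 * 1000,
               tolerance = 1e-12)
  expect_equal(as.numeric(u), 150 - 120 - 10.157, tolerance = 0.001)
  exact <- unknown_carbon(120 + 0.2 * 0.61 / 12.011 * 1000, 120,
                          antifoam = 0.2)
  expect_equal(as.numeric(exact), 0, tolerance = 1e-9)
  expect_warning(neg <- unknown_carbon(100, 120, antifoam = 0.2),
                 "negative")
  expect_lt(as.numeric(neg), 0)
  expect_equal(attr(neg, "flag"), "inconsistent")
})

test_that("percent change matches the printed comparison columns", {
  expect_equal(percent_change(7.68, 8.47), 10.3, tolerance = 0.01)
  expect_equal(percent_change(3, 3), 0)
  expect_equal(percent_change(2.87, 1.65), -42, tolerance = 0.51)
  expect_error(percent_change(0, 1), "zero reference")
  r <- withr::with_seed(2, stats::runif(20, -0.9, 3))
  x <- withr::with_seed(3, stats::runif(20, 0.1, 10))
  expect_equal(percent_change(x, x * (1 + r)), 100 * r)
})

test_that("Welch test matches the textbook computation", {
  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  w <- welch_test(a, b)
  v <- stats::var(a) / 3 + stats::var(b) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(v)
  df_hand <- v^2 / ((stats::var(a) / 3)^2 / 2 + (stats::var(b) / 5)^2 / 4)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$p, 2 * stats::pt(-abs(t_hand), df_hand),
               tolerance = 1e-12)
  expect_error(welch_test(1, c(1, 2)), ">= 2 replicates")
})

test_that("Welch rejection rate is calibrated under the null", {
  hits <- vapply(1:3000, function(i) {
    withr::with_seed(5000 + i,
                     welch_test(stats::rnorm(3), stats::rnorm(3))$p) < 0.05
  }, logical(1))
  expect_lte(abs(mean(hits) - 0.05), 0.015)
})

test_that("stripping model behaves physically", {
  prod_rate <- 16.7 * 5.06          # mmol_C/L/h
  broth <- 862                      # mmol_C/L
  base <- stripping_fraction(stripping_config(), prod_rate, broth)
  expect_gt(base, 0); expect_lt(base, 1)
  # zero gas flow strips nothing
  expect_equal(stripping_fraction(stripping_config(gas_flow = 0),
                                  prod_rate, broth), 0)
  # dilute-regime linearity in gas flow
  half <- stripping_fraction(stripping_config(gas_flow = 0.2125),
                             prod_rate, broth)
  expect_equal(half * 2, base, tolerance = 0.01)
  # monotone in gas flow and temperature
  expect_gt(stripping_fraction(stripping_config(gas_flow = 0.8),
                               prod_rate, broth), base)
  expect_gt(stripping_fraction(stripping_config(temperature = 35),
                               prod_rate, broth), base)
  expect_error(stripping_config(temperature = 70), "0-60")
  expect_error(ethanol_saturation_pressure(95), "Antoine")
})

test_that("physiology tables summarize replicate comparisons", {
  meas <- data.frame(
    state = rep(c("RS", "DS"), each = 6),
    replicate = rep(1:3, 4),
    variable = rep(rep(c("q_co2", "c_rna"), each = 3), 2),
    value = c(7.5, 7.7, 7.85, 64, 64.3, 64.6,
              8.3, 8.5, 8.61, 80.4, 80.7, 81.0))
  tab <- physiology_table(meas)
  expect_equal(nrow(tab), 2)
  co2 <- tab[tab$variable == "q_co2", ]
  expect_equal(co2$pct_change,
               round(percent_change(mean(c(7.5, 7.7, 7.85)),
                                    mean(c(8.3, 8.5, 8.61))), 1))
  expect_true(all(tab$p_value < 0.05))
  expect_false(any(tab$significance == "n.s."))
})
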