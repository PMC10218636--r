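#' Biomass-specific conversion rate from a chemostat balance
#'
#' At steady state the balance of a consumed species gives
#' q = D (c_feed - c_broth) / X and of a produced species q = D c_broth /
#' X. Both are reported positive; the direction is carried alongside.
#'
#' @param D dilution rate (1/h).
#' @param broth_conc broth concentration (mmol_C/L).
#' @param biomass dry biomass (g/L).
#' @param feed_conc feed concentration (mmol_C/L); required for
#'   `type = "uptake"`.
#' @param type `"uptake"` (consumed species) or `"product"`.
#' @return specific rate q (mmol_C / g_DMB / h), positive, with the
#'   direction in attribute `"direction"`.
#' @examples
#' specific_rate(0.098, 5.16, 5.06, feed_conc = 1666.7)  # ~32.2
#' @export
specific_rate <- function(D, broth_conc, biomass, feed_conc = NULL,
                          type = c("uptake", "product")) {
  type <- match.arg(type)
  stopifnot(D > 0, biomass > 0, broth_conc >= 0)
  if (type == "uptake") {
    if (is.null(feed_conc))
      stop("feed concentration required for a consumed species")
    q <- D * (feed_conc - broth_conc) / biomass
  } else {
    q <- D * broth_conc / biomass
  }
  structure(abs(q), direction = if (type == "uptake") "uptake" else
    "production")
}

#' Carbon yield coefficient
#'
#' Dimensionless C-mol/C-mol ratio of two biomass-specific rates (or any
#' two carbon fluxes in the same units).
#'
#' @param q_num numerator rate (mmol_C/g/h).
#' @param q_den denominator rate (mmol_C/g/h), > 0.
#' @return yield (C-mol/C-mol).
#' @export
yield_coefficient <- function(q_num, q_den) {
  if (any(q_den <= 0)) stop("denominator rate must be > 0")
  as.numeric(q_num) / as.numeric(q_den)
}

#' Biomass yield on consumed glucose
#'
#' Converts dry biomass to carbon moles with the carbon mass fraction f_C
#' and divides by the consumed glucose carbon.
#'
#' @param biomass dry biomass (g/L).
#' @param consumed_mmol_c consumed glucose (mmol_C/L).
#' @param carbon_fraction biomass carbon mass fraction (g_C/g_DMB).
#' @return Y_DMB/glucose (C-mol/C-mol).
#' @examples
#' biomass_yield(5.06, 1661.5)  # ~0.114 at f_C = 0.45
#' @export
biomass_yield <- function(biomass, consumed_mmol_c, carbon_fraction = 0.45) {
  stopifnot(consumed_mmol_c > 0)
  biomass * biomass_mmolc_per_g(carbon_fraction) / consumed_mmol_c
}

#' Carbon recovery
#'
#' Sum of all carbon-output yields on consumed substrate (biomass, ethanol
#' including its stripped fraction, CO2, glycerol, acetate, succinate,
#' unknown carbon). Additive and permutation-invariant; missing streams
#' simply lower the total.
#'
#' @param yields named numeric vector of C-mol/C-mol yields on glucose.
#' @return recovery (C-mol/C-mol) with per-stream contributions attached as
#'   attribute `"streams"`.
#' @export
carbon_recovery <- function(yields) {
  if (any(yields < 0)) stop("yields must be >= 0")
  structure(sum(yields), streams = yields)
}

#' Unknown carbon in the supernatant
#'
#' Total organic carbon minus the carbon of all quantified extracellular
#' metabolites and of the (non-consumed) antifoam agent, which carries a
#' carbon mass fraction of 61% (w/w). Negative results indicate a
#' measurement inconsistency and are flagged, not clamped.
#'
#' @param toc total organic carbon of the supernatant (mmol_C/L).
#' @param known_mmol_c vector of quantified metabolite carbon (mmol_C/L).
#' @param antifoam antifoam concentration (g/L).
#' @param antifoam_carbon_fraction antifoam carbon mass fraction (w/w).
#' @return unknown carbon (mmol_C/L); attribute `"flag"` is
#'   `"inconsistent"` when negative.
#' @examples
#' unknown_carbon(150, 120, antifoam = 0.2)  # ~19.84
#' @export
unknown_carbon <- function(toc, known_mmol_c, antifoam = 0.2,
                           antifoam_carbon_fraction = 0.61) {
  stopifnot(toc >= 0)
  af_c <- antifoam * antifoam_carbon_fraction / 12.011 * 1000
  val <- toc - sum(known_mmol_c) - af_c
  flag <- NULL
  if (val < 0) {
    warning("unknown carbon is negative: TOC below the quantified streams")
    flag <- "inconsistent"
  }
  structure(val, antifoam_mmol_c = af_c, flag = flag)
}

#' Percent change between reference and dynamic steady state
#'
#' @param rs reference steady-state value (non-zero).
#' @param ds dynamic steady-state value.
#' @return 100 * (ds - rs) / rs.
#' @export
percent_change <- function(rs, ds) {
  if (any(rs == 0)) stop("zero reference value")
  100 * (ds - rs) / rs
}

#' Welch's unequal-variance two-sample t test
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE`
#' (Welch-Satterthwaite degrees of freedom, two-sided p).
#'
#' @param a,b replicate values, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 replicates per sample")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Stripping configuration
#'
#' Operating conditions and vapor-liquid-equilibrium constants for the
#' ethanol stripping estimate. The partition model is a dilute-solution
#' activity coefficient times the ethanol saturation pressure (modified
#' Raoult's law); the default activity coefficient 4.68 is the classic
#' infinite-dilution measurement for ethanol in water (Butler et al.,
#' 1935), treated as temperature-insensitive between 25 and 35 degrees C.
#' All constants are explicit and overridable.
#'
#' @param gas_flow sparge rate (vvm, norm volume per liquid volume per
#'   minute).
#' @param volume liquid working volume (L).
#' @param temperature broth temperature (degrees C), within 0-60.
#' @param pressure total pressure (bar absolute).
#' @param activity_coeff dilute-solution activity coefficient of ethanol in
#'   water.
#' @param saturation approach-to-equilibrium of the leaving gas (1 = full
#'   vapor-liquid equilibrium, the model default).
#' @return object of class `stripping_config`.
#' @export
stripping_config <- function(gas_flow = 0.425, volume = 1.7,
                             temperature = 30, pressure = 1.3,
                             activity_coeff = 4.68, saturation = 1) {
  if (gas_flow < 0) stop("gas_flow must be >= 0")
  if (temperature < 0 || temperature > 60)
    stop("temperature outside the 0-60 degree C correlation range")
  stopifnot(volume > 0, pressure > 0, activity_coeff > 0,
            saturation >= 0, saturation <= 1)
  structure(list(gas_flow = gas_flow, volume = volume,
                 temperature = temperature, pressure = pressure,
                 activity_coeff = activity_coeff, saturation = saturation),
            class = "stripping_config")
}

#' Ethanol saturation pressure
#'
#' Antoine correlation (NIST constants, valid ~0-80 degrees C).
#'
#' @param temperature temperature (degrees C).
#' @return saturation pressure (kPa).
#' @export
ethanol_saturation_pressure <- function(temperature) {
  if (any(temperature < 0 | temperature > 80))
    stop("temperature outside the Antoine correlation range")
  Tk <- temperature + 273.15
  10^(5.24677 - 1598.673 / (Tk - 46.424)) * 100
}

#' Fraction of produced ethanol lost to the sparge gas
#'
#' Steady-state, well-mixed equilibrium stripping model: the gas leaves the
#' broth carrying an ethanol partial pressure equal to the activity
#' coefficient times the liquid mole fraction times the saturation pressure
#' (scaled by the approach-to-equilibrium factor). The molar gas flow
#' follows from the norm-metered sparge rate by the ideal gas law; the
#' stripped fraction is the gas-phase ethanol molar flow divided by the
#' production rate. Linear in broth concentration and gas flow in the
#' dilute regime, zero at zero gas flow.
#'
#' @param cfg a [stripping_config()].
#' @param ethanol_production volumetric ethanol production rate
#'   (mmol_C/L/h), e.g. q_ethanol * X.
#' @param broth_ethanol broth ethanol concentration (mmol_C/L).
#' @return fraction of produced ethanol leaving with the gas (0 to 1).
#' @examples
#' stripping_fraction(stripping_config(), 16.7 * 5.06, 862)
#' @export
stripping_fraction <- function(cfg, ethanol_production, broth_ethanol) {
  stopifnot(inherits(cfg, "stripping_config"),
            ethanol_production > 0, broth_ethanol >= 0)
  if (cfg$gas_flow == 0 || broth_ethanol == 0) return(0)
  R <- 8.314                      # J/mol/K = L kPa / mol / K
  # molar gas flow from the norm-metered volumetric rate (0 C, 1 atm)
  Q_norm <- cfg$gas_flow * cfg$volume * 60          # L/h
  n_gas <- 101.325 * Q_norm / (R * 273.15)          # mol/h
  # liquid mole fraction of ethanol (dilute aqueous broth)
  c_eth <- broth_ethanol / 2 / 1000                 # mol/L
  x <- c_eth / (c_eth + (1000 - c_eth * 46.068) / 18.015)
  p_eth <- cfg$saturation * cfg$activity_coeff * x *
    ethanol_saturation_pressure(cfg$temperature)    # kPa
  y <- p_eth / (cfg$pressure * 100)                 # gas mole fraction
  strip_mmol_c <- n_gas * y / (1 - y) * 2 * 1000    # mmol_C/h
  production <- ethanol_production * cfg$volume     # mmol_C/h
  min(strip_mmol_c / production, 1)
}

#' Summarize replicate steady-state measurements into a process table
#'
#' Builds the familiar two-state comparison table (parameter, RS mean and
#' sd, DS mean and sd, percent change, Welch p) from tidy replicate
#' measurements.
#'
#' @param measurements data.frame with columns `state` (factor with the
#'   reference level first), `replicate`, `variable`, `value` (and
#'   optionally `unit`).
#' @param digits_pct digits for the percent-change column.
#' @return data.frame with one row per variable: `variable`, `rs_mean`,
#'   `rs_sd`, `ds_mean`, `ds_sd`, `pct_change`, `p_value`, `significance`
#'   ("n.s." above 0.05, as in process-table convention).
#' @export
physiology_table <- function(measurements, digits_pct = 1) {
  stopifnot(all(c("state", "replicate", "variable", "value") %in%
                  names(measurements)))
  states <- unique(as.character(measurements$state))
  if (length(states) != 2) stop("need exactly two states (e.g. RS and DS)")
  rs <- states[1]; ds <- states[2]
  vars <- unique(measurements$variable)
  rows <- lapply(vars, function(v) {
    a <- measurements$value[measurements$variable == v &
                              measurements$state == rs]
    b <- measurements$value[measurements$variable == v &
                              measurements$state == ds]
    p <- if (length(a) >= 2 && length(b) >= 2) welch_test(a, b)$p else
      NA_real_
    data.frame(variable = v,
               rs_mean = mean(a), rs_sd = stats::sd(a),
               ds_mean = mean(b), ds_sd = stats::sd(b),
               pct_change = round(percent_change(mean(a), mean(b)),
                                  digits_pct),
               p_value = p,
               significance = if (is.na(p)) "n.a." else
                 if (p > 0.05) "n.s." else format(signif(p, 2)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
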