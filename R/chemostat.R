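#' Reactor configuration
#'
#' Physical description of the chemostat vessel and feed medium. Defaults
#' describe a 1.7 L anaerobic benchtop reactor sparged with nitrogen at
#' 0.425 vvm under 0.3 bar overpressure, fed with 50 g/L glucose.
#'
#' @param working_volume liquid working volume (L).
#' @param feed_glucose feed glucose concentration (g/L).
#' @param gas_flow sparge gas flow (vvm, gas volumes per liquid volume per
#'   minute, metered at norm conditions).
#' @param temperature broth temperature (degrees C).
#' @param overpressure head-space overpressure (bar gauge).
#' @return object of class `reactor_config`.
#' @examples
#' cfg <- reactor_config()
#' feed_mmol_c(cfg)  # feed glucose in mmol_C/L
#' @export
reactor_config <- function(working_volume = 1.7, feed_glucose = 50,
                           gas_flow = 0.425, temperature = 30,
                           overpressure = 0.3) {
  if (working_volume <= 0) stop("working_volume must be > 0")
  if (feed_glucose < 0) stop("feed_glucose must be >= 0")
  if (gas_flow < 0) stop("gas_flow must be >= 0")
  structure(list(working_volume = working_volume, feed_glucose = feed_glucose,
                 gas_flow = gas_flow, temperature = temperature,
                 overpressure = overpressure),
            class = "reactor_config")
}

#' @rdname reactor_config
#' @param config a `reactor_config`.
#' @export
feed_mmol_c <- function(config) {
  g_to_mmol_c(config$feed_glucose, "glucose")
}

#' Piecewise-constant feed schedule
#'
#' A feed program is an ordered list of segments, each with a duration in
#' minutes and a constant pump rate in mL/min. A cyclic schedule repeats the
#' segment list indefinitely (intermittent feeding); a non-cyclic schedule
#' holds the last rate after its end.
#'
#' @param minutes numeric vector of segment durations (min), all > 0.
#' @param ml_per_min numeric vector of pump rates (mL/min), all >= 0.
#' @param cyclic repeat the segments periodically?
#' @return object of class `feed_schedule`.
#' @examples
#' continuous_feed(2.83)
#' intermittent_feed()  # 2 min off / 7 min on at 3.64 mL/min
#' @export
feed_schedule <- function(minutes, ml_per_min, cyclic = FALSE) {
  if (length(minutes) == 0) stop("empty schedule")
  if (length(minutes) != length(ml_per_min))
    stop("minutes and ml_per_min must have the same length")
  if (any(minutes <= 0)) stop("all segment durations must be > 0")
  if (any(ml_per_min < 0)) stop("all feed rates must be >= 0")
  structure(list(minutes = as.numeric(minutes),
                 ml_per_min = as.numeric(ml_per_min),
                 cyclic = isTRUE(cyclic)),
            class = "feed_schedule")
}

#' @rdname feed_schedule
#' @param rate constant feed rate (mL/min).
#' @param duration nominal duration of the single segment (min).
#' @export
continuous_feed <- function(rate = 2.83, duration = 60) {
  feed_schedule(duration, rate, cyclic = TRUE)
}

#' @rdname feed_schedule
#' @param off_min feed-off duration (min).
#' @param on_min feed-on duration (min).
#' @param rate_on feed-on pump rate (mL/min).
#' @param off_first start the cycle with the feed-off segment?
#' @export
intermittent_feed <- function(off_min = 2, on_min = 7, rate_on = 3.64,
                              off_first = TRUE) {
  if (off_first) feed_schedule(c(off_min, on_min), c(0, rate_on), cyclic = TRUE)
  else feed_schedule(c(on_min, off_min), c(rate_on, 0), cyclic = TRUE)
}

#' Read a feed schedule from a YAML file
#'
#' Expected layout: `segments: [{minutes: 7, ml_per_min: 3.64}, ...]` plus an
#' optional top-level `cyclic: true`.
#'
#' @param path YAML file path.
#' @return a [feed_schedule()].
#' @export
read_feed_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- y$segments
  if (is.null(seg)) stop("YAML schedule needs a 'segments' list")
  feed_schedule(vapply(seg, function(s) s$minutes, numeric(1)),
                vapply(seg, function(s) s$ml_per_min, numeric(1)),
                cyclic = isTRUE(y$cyclic))
}

# pump rate (mL/min) at time t (min) from cycle start
feed_rate_at <- function(schedule, t) {
  cyc <- sum(schedule$minutes)
  ends <- cumsum(schedule$minutes)
  tt <- if (schedule$cyclic) t %% cyc else pmin(t, cyc - 1e-12)
  idx <- findInterval(tt, c(0, ends), rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[tt <= 0] <- 1L
  idx[idx > length(ends)] <- length(ends)
  schedule$ml_per_min[idx]
}

#' Dilution-rate profile of a feed schedule
#'
#' Converts a feed program into the instantaneous dilution rate
#' D(t) = F(t) * 0.06 / V (pump rate in mL/min, volume in L, D in 1/h) and
#' its time-weighted mean over one cycle (the net dilution rate that sets
#' the chemostat growth rate).
#'
#' @param schedule a [feed_schedule()].
#' @param config a [reactor_config()].
#' @param times optional time grid (min) at which to evaluate D(t).
#' @return list with `net_dilution` (1/h), `cycle_minutes`, `net_flow`
#'   (mL/min), and a data.frame `profile` (`time_min`, `dilution`) if
#'   `times` is given.
#' @examples
#' dilution_profile(continuous_feed(2.83), reactor_config())$net_dilution
#' dilution_profile(intermittent_feed(), reactor_config())$net_dilution
#' @export
dilution_profile <- function(schedule, config, times = NULL) {
  stopifnot(inherits(schedule, "feed_schedule"),
            inherits(config, "reactor_config"))
  net_flow <- sum(schedule$minutes * schedule$ml_per_min) /
    sum(schedule$minutes)
  out <- list(net_dilution = net_flow * 0.06 / config$working_volume,
              net_flow = net_flow,
              cycle_minutes = sum(schedule$minutes))
  if (!is.null(times)) {
    out$profile <- data.frame(
      time_min = times,
      dilution = feed_rate_at(schedule, times) * 0.06 / config$working_volume)
  }
  out
}

#' Monod glucose uptake kinetics
#'
#' Saturable uptake law q(S) = q_max * S / (K_S + S), parameterized in
#' carbon units, together with the yield structure used by the dynamic
#' model and a maintenance threshold used for diagnostics only (the
#' maintenance demand is a ratio check, not a term in the kinetic law).
#'
#' @param q_max maximal specific uptake rate (mmol_C / g_DMB / h).
#' @param K_S half-saturation constant (mmol_C / L).
#' @param maintenance maintenance requirement (mmol glucose / g_DMB / h).
#' @param biomass_yield Y_X/S on consumed glucose (C-mol/C-mol).
#' @param product_yields named numeric vector of per-product carbon yields on
#'   consumed glucose (C-mol/C-mol).
#' @param carbon_fraction biomass carbon mass fraction f_C (g_C/g_DMB).
#' @return object of class `uptake_kinetics`.
#' @examples
#' kin <- uptake_kinetics()      # reference steady-state parameters
#' monod_rate(5.16, kin)         # ~45% of q_max
#' @export
uptake_kinetics <- function(q_max = 71.50, K_S = 6.19, maintenance = 0.5,
                            biomass_yield = 0.114,
                            product_yields = c(ethanol = 0.520,
                                               co2 = 0.239,
                                               glycerol = 0.084,
                                               acetate = 0.0012,
                                               succinate = 0.0009,
                                               unknown = 0.033),
                            carbon_fraction = 0.45) {
  if (q_max <= 0) stop("q_max must be > 0")
  if (K_S <= 0) stop("K_S must be > 0")
  if (biomass_yield < 0 || any(product_yields < 0))
    stop("yields must be >= 0")
  if (biomass_yield + sum(product_yields) > 1 + 1e-9)
    stop("biomass_yield + sum(product_yields) must be <= 1")
  structure(list(q_max = q_max, K_S = K_S, maintenance = maintenance,
                 biomass_yield = biomass_yield,
                 product_yields = product_yields,
                 carbon_fraction = carbon_fraction),
            class = "uptake_kinetics")
}

#' Monod uptake rate
#'
#' @param S extracellular glucose (mmol_C/L), scalar or vector, >= 0.
#' @param kin an [uptake_kinetics()].
#' @return specific uptake rate(s) (mmol_C / g_DMB / h).
#' @export
monod_rate <- function(S, kin) {
  if (any(S < 0)) stop("negative substrate concentration")
  kin$q_max * S / (kin$K_S + S)
}

#' @rdname monod_rate
#' @return `uptake_fraction`: q(S)/q_max, the fractional saturation of the
#'   uptake system.
#' @export
uptake_fraction <- function(S, kin) monod_rate(S, kin) / kin$q_max

#' @rdname monod_rate
#' @return `maintenance_margin`: ratio of the glucose-unit uptake rate
#'   (q(S)/6) to the maintenance requirement; values > 1 mean the culture
#'   is above its maintenance demand.
#' @export
maintenance_margin <- function(S, kin) {
  (monod_rate(S, kin) / 6) / kin$maintenance
}

#' Analytic chemostat steady state
#'
#' For a constant dilution rate D, growth rate equals D, so the required
#' uptake is q* = D * c_X / Y_X/S with c_X the biomass carbon content
#' (mmol_C per g). Inverting the Monod law gives the residual substrate
#' S* = K_S q* / (q_max - q*); the biomass then follows from the substrate
#' balance and products from their yields.
#'
#' @param config a [reactor_config()].
#' @param kin an [uptake_kinetics()].
#' @param D dilution rate (1/h).
#' @return list with `glucose` (mmol_C/L), `biomass` (g/L), `products`
#'   (named, mmol_C/L) and `q` (mmol_C/g/h).
#' @export
steady_state <- function(config, kin, D) {
  cX <- biomass_mmolc_per_g(kin$carbon_fraction)
  q_req <- D * cX / kin$biomass_yield
  if (q_req >= kin$q_max)
    stop("washout: required uptake exceeds q_max at this dilution rate")
  S <- kin$K_S * q_req / (kin$q_max - q_req)
  X <- kin$biomass_yield * (feed_mmol_c(config) - S) / cX
  P <- kin$product_yields * q_req * X / D
  list(glucose = S, biomass = X, products = P, q = q_req)
}

#' Simulate a stimulus-response experiment
#'
#' Integrates the chemostat mass balances under a piecewise-constant feed
#' program:
#' \deqn{dS/dt = D(t) (S_{feed} - S) - q(S) X}
#' \deqn{dX/dt = (Y_{X/S} q(S) / c_X - D(t)) X}
#' \deqn{dP_i/dt = Y_i q(S) X - D(t) P_i}
#' with S and P_i in mmol_C/L, X in g/L and c_X the biomass carbon content
#' in mmol_C/g. During feed-off segments the harvest is also off, so all
#' dilution terms vanish and the volume stays constant. CO2 is carried as a
#' product stream so the carbon balance closes when yields sum to one.
#'
#' Integration uses a stiff-capable adaptive solver (lsoda) restarted at
#' every segment boundary, relative tolerance 1e-8, absolute tolerance
#' 1e-10.
#'
#' @param config a [reactor_config()].
#' @param schedule a [feed_schedule()].
#' @param kin an [uptake_kinetics()].
#' @param init initial state: list with `glucose` (mmol_C/L), `biomass`
#'   (g/L) and optional `products` (named mmol_C/L). Default: the analytic
#'   steady state at the schedule's net dilution rate.
#' @param horizon simulation horizon (min).
#' @param dt_out output grid spacing (min); default 1/60 (1 s) for horizons
#'   up to 30 min, 0.1 otherwise.
#' @return object of class `sre_trajectory`: a data.frame with columns
#'   `time_min`, `glucose`, `biomass`, one column per product and
#'   `dilution`, plus the configuration in attributes.
#' @examples
#' traj <- simulate_sre(horizon = 20)
#' recovery_time(traj, S_ref = steady_state(reactor_config(),
#'                                          uptake_kinetics(), 0.0999)$glucose)
#' @export
simulate_sre <- function(config = reactor_config(),
                         schedule = intermittent_feed(),
                         kin = uptake_kinetics(),
                         init = NULL, horizon = 60, dt_out = NULL) {
  stopifnot(horizon > 0)
  if (is.null(dt_out)) dt_out <- if (horizon <= 30) 1 / 60 else 0.1
  net_D <- dilution_profile(schedule, config)$net_dilution
  if (is.null(init)) {
    ss <- steady_state(config, kin, net_D)
    init <- list(glucose = ss$glucose, biomass = ss$biomass,
                 products = ss$products)
  }
  if (is.null(init$products))
    init$products <- setNames(rep(0, length(kin$product_yields)),
                              names(kin$product_yields))
  if (init$glucose < 0 || init$biomass < 0 || any(init$products < 0))
    stop("initial concentrations must be >= 0")

  cX <- biomass_mmolc_per_g(kin$carbon_fraction)
  Sfeed <- feed_mmol_c(config)
  n_prod <- length(init$products)
  y0 <- c(init$glucose, init$biomass, unname(init$products))

  deriv <- function(t, y, D) {
    S <- max(y[1], 0); X <- max(y[2], 0)
    q <- kin$q_max * S / (kin$K_S + S)
    dS <- D * (Sfeed - S) - q * X
    dX <- (kin$biomass_yield * q / cX - D) * X
    dP <- kin$product_yields * q * X - D * y[-(1:2)]
    list(c(dS, dX, dP) / 60)  # per-hour rates, time grid in minutes
  }

  # segment boundaries over the horizon
  seg_end <- cumsum(schedule$minutes)
  cyc <- sum(schedule$minutes)
  bounds <- 0
  if (schedule$cyclic) {
    reps <- ceiling(horizon / cyc)
    bounds <- c(0, rep(seq_len(reps) - 1, each = length(seg_end)) * cyc +
                  rep(seg_end, reps))
  } else bounds <- c(0, seg_end)
  bounds <- sort(unique(c(pmin(bounds, horizon), horizon)))

  rows <- list(); y <- y0
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    if (t1 - t0 < 1e-12) next
    D <- feed_rate_at(schedule, t0 + (t1 - t0) / 2) * 0.06 /
      config$working_volume
    times <- unique(c(seq(t0, t1, by = dt_out), t1))
    sol <- deSolve::lsoda(y, times, deriv, parms = D,
                          rtol = 1e-8, atol = 1e-10)
    if (any(!is.finite(sol)))
      stop(sprintf("solver failure (non-finite state) near t = %.3f min",
                   sol[which(!is.finite(rowSums(sol)))[1], 1]))
    sol <- as.data.frame(sol)
    sol$dilution <- D
    rows[[i]] <- if (i < length(bounds) - 1) sol[-nrow(sol), , drop = FALSE]
                 else sol
    y <- unlist(sol[nrow(sol), 1 + seq_len(2 + n_prod)])
  }
  traj <- do.call(rbind, rows)
  names(traj) <- c("time_min", "glucose", "biomass",
                   names(init$products), "dilution")
  rownames(traj) <- NULL
  structure(traj, class = c("sre_trajectory", "data.frame"),
            config = config, kinetics = kin, schedule = schedule)
}

#' Carbon balance of a simulated trajectory
#'
#' Integrates carbon inflow (feed) and outflow (efflux of substrate,
#' biomass carbon and products) over the trajectory and compares with the
#' change in accumulated broth carbon. When the kinetic yields sum to one
#' the residual is zero up to integration error.
#'
#' @param traj an `sre_trajectory`.
#' @return list with cumulative `carbon_in`, `carbon_out`, `accumulation`
#'   (all mmol_C/L over the run) and `residual_fraction` = (in - out -
#'   accumulation) / in.
#' @export
carbon_balance <- function(traj) {
  kin <- attr(traj, "kinetics")
  cfg <- attr(traj, "config")
  cX <- biomass_mmolc_per_g(kin$carbon_fraction)
  prod_cols <- setdiff(names(traj),
                       c("time_min", "glucose", "biomass", "dilution"))
  total <- traj$glucose + traj$biomass * cX +
    rowSums(as.data.frame(traj[, prod_cols, drop = FALSE]))
  dt_h <- diff(traj$time_min) / 60
  mid <- function(x) (x[-1] + x[-length(x)]) / 2
  inflow <- sum(mid(traj$dilution * feed_mmol_c(cfg)) * dt_h)
  # unconverted carbon fraction leaves the balance when yields sum below 1
  loss_y <- 1 - kin$biomass_yield - sum(kin$product_yields)
  q <- monod_rate(pmax(traj$glucose, 0), kin)
  outflow <- sum(mid(traj$dilution * total) * dt_h) +
    sum(mid(loss_y * q * traj$biomass) * dt_h)
  accum <- total[length(total)] - total[1]
  list(carbon_in = inflow, carbon_out = outflow, accumulation = accum,
       residual_fraction = if (inflow > 0)
         (inflow - outflow - accum) / inflow else NA_real_)
}

#' Time to recover a reference substrate level
#'
#' Returns the first time (minutes from trajectory start) at which the
#' glucose concentration is within a relative tolerance of `S_ref` and
#' stays there until the end of the trajectory; `NA` if never recovered.
#'
#' @param traj an `sre_trajectory` (or data.frame with `time_min`,
#'   `glucose`).
#' @param S_ref reference concentration (mmol_C/L), > 0.
#' @param tol relative tolerance (fraction of `S_ref`).
#' @return recovery time in minutes, or `NA_real_` if not recovered.
#' @export
recovery_time <- function(traj, S_ref, tol = 0.05) {
  if (S_ref <= 0) stop("S_ref must be > 0")
  ok <- abs(traj$glucose - S_ref) / S_ref <= tol
  # within tolerance from some index through the end
  stays <- rev(cumprod(rev(ok))) == 1
  idx <- which(ok & stays)[1]
  if (is.na(idx)) return(NA_real_)
  traj$time_min[idx] - traj$time_min[1]
}
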