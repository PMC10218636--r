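#' Temporal response templates
#'
#' Named trajectory shapes used by the count generator, each mapping time
#' in minutes to a relative log2 activation in [-1, 1]:
#' * `impulse_up` / `impulse_down`: transient response peaking at 15 min
#'   (inside the 10-20 min window) and relaxed to near zero by 60 min;
#' * `sustained_up` / `sustained_down`: monotone shift that saturates, the
#'   shape of a persistent steady-state change;
#' * `damped_oscillation`: decaying oscillation with a 9-min period
#'   matching the 2-min-off / 7-min-on feed cycle;
#' * `null`: identically zero.
#'
#' @return named list of vectorized functions of time (min).
#' @examples
#' tpl <- profile_templates()
#' tpl$impulse_up(c(0, 15, 60))
#' @export
profile_templates <- function() {
  impulse <- function(t) ((t / 15) * exp(1 - t / 15))^2
  list(
    null = function(t) rep(0, length(t)),
    impulse_up = function(t) impulse(t),
    impulse_down = function(t) -impulse(t),
    sustained_up = function(t) 1 - exp(-t / 8),
    sustained_down = function(t) -(1 - exp(-t / 8)),
    damped_oscillation = function(t) exp(-t / 30) * sin(2 * pi * t / 9)
  )
}

#' Ground truth for a synthetic expression experiment
#'
#' Parameters of the count generator. Defaults emulate the scale-down
#' study's single-pulse time course at desk scale: 2000 genes, baseline
#' count means log-normal (meanlog 5, sdlog 1.5), dispersion 0.05,
#' library sizes uniform in [0.8, 1.2] x 2e5 (the study's 2e7 read depth
#' scaled down 100-fold), five timepoints with three replicates, and a
#' responsive fraction of ~17.6% (1053 of ~6000 genes) split across the
#' impulse and sustained templates.
#'
#' @param n_genes number of genes.
#' @param class_proportions named proportions over
#'   [profile_templates()] names; must sum to 1.
#' @param amplitude absolute log2 fold-change amplitude of responsive
#'   genes.
#' @param dispersion NB dispersion (scalar, applied to all genes).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline mean distribution.
#' @param libsize_range range of library-size factors (reads per sample).
#' @param timepoints sampling times (min); must include 0.
#' @param replicates replicates per timepoint.
#' @return list of class `expression_truth`.
#' @export
expression_truth <- function(n_genes = 2000,
                             class_proportions = c(null = 0.8245,
                                                   impulse_up = 0.0600,
                                                   impulse_down = 0.0600,
                                                   sustained_up = 0.0300,
                                                   sustained_down = 0.0255),
                             amplitude = 2,
                             dispersion = 0.05,
                             baseline_meanlog = 5, baseline_sdlog = 1.5,
                             libsize_range = c(0.8, 1.2) * 2e5,
                             timepoints = c(0, 10, 20, 30, 60),
                             replicates = 3) {
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  if (!0 %in% timepoints) stop("timepoints must include 0")
  if (!all(names(class_proportions) %in% names(profile_templates())))
    stop("unknown template class in class_proportions")
  stopifnot(n_genes >= 1, replicates >= 1, dispersion >= 0,
            is.finite(amplitude))
  structure(as.list(environment()), class = "expression_truth")
}

#' Generate an NB count matrix with temporal structure
#'
#' Counts are drawn as NB(mean = libsize_j x share_g x
#' 2^(template_class(t_j) x amplitude_g), dispersion) where `share_g` is
#' the gene's relative baseline abundance. Returns the matrix together
#' with the sample design and the per-gene ground-truth labels, enabling
#' power and class-recovery analyses downstream. Fully deterministic per
#' seed.
#'
#' @param truth an [expression_truth()].
#' @param seed integer seed.
#' @return list with `counts` (integer matrix), `design` (data.frame:
#'   `sample`, `condition`, `time_min`, `replicate`) and `truth`
#'   (data.frame: `gene`, `class`, `amplitude`, `base_mean`).
#' @export
gen_count_matrix <- function(truth = expression_truth(), seed = 1) {
  tpl <- profile_templates()
  withr::with_seed(seed, {
    n <- truth$n_genes
    classes <- sample(rep(names(truth$class_proportions),
                          diff(round(cumsum(
                            c(0, truth$class_proportions)) * n))))
    if (length(classes) < n)
      classes <- c(classes, rep("null", n - length(classes)))
    base <- stats::rlnorm(n, truth$baseline_meanlog, truth$baseline_sdlog)
    amp <- ifelse(classes == "null", 0, truth$amplitude)

    times <- rep(truth$timepoints, each = truth$replicates)
    reps <- rep(seq_len(truth$replicates), length(truth$timepoints))
    libsize <- stats::runif(length(times), truth$libsize_range[1],
                            truth$libsize_range[2])
    # baselines are count means at nominal depth; library sizes act as
    # relative depth factors around their nominal mean
    depth <- libsize / mean(truth$libsize_range)
    genes <- sprintf("gene_%04d", seq_len(n))
    samples <- sprintf("t%03d_r%d", times, reps)

    lfc <- matrix(0, n, length(times))
    for (cl in setdiff(unique(classes), "null")) {
      i <- classes == cl
      lfc[i, ] <- outer(amp[i], tpl[[cl]](times))
    }
    mu <- (base %o% depth) * 2^lfc
    counts <- matrix(
      if (truth$dispersion <= 0) stats::rpois(length(mu), mu) else
        stats::rnbinom(length(mu), size = 1 / truth$dispersion, mu = mu),
      nrow = n, dimnames = list(genes, samples))

    list(counts = counts,
         design = data.frame(sample = samples,
                             condition = sprintf("t%03d", times),
                             time_min = times, replicate = reps,
                             stringsAsFactors = FALSE),
         truth = data.frame(gene = genes, class = classes,
                            amplitude = amp, base_mean = base,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a two-condition spike-in count matrix
#'
#' Simpler companion to [gen_count_matrix()] for calibration studies: two
#' conditions with `n_per_group` replicates each, a fraction of genes
#' spiked with a fixed absolute log2 fold change (balanced up/down), the
#' rest null. `spike_fraction = 0` gives a pure null dataset.
#'
#' @param n_genes number of genes.
#' @param spike_fraction fraction of genes with a true effect.
#' @param lfc absolute log2 fold change of spiked genes.
#' @param dispersion NB dispersion.
#' @param n_per_group replicates per condition.
#' @param baseline_meanlog,baseline_sdlog,libsize_range as in
#'   [expression_truth()].
#' @param seed integer seed.
#' @return list with `counts`, `design`, `truth` (gene, spiked, lfc).
#' @export
gen_two_group_counts <- function(n_genes = 2000, spike_fraction = 0.1,
                                 lfc = 2, dispersion = 0.05,
                                 n_per_group = 3,
                                 baseline_meanlog = 5, baseline_sdlog = 1.5,
                                 libsize_range = c(0.8, 1.2) * 2e5,
                                 seed = 1) {
  withr::with_seed(seed, {
    n_spike <- round(n_genes * spike_fraction)
    true_lfc <- rep(0, n_genes)
    if (n_spike > 0) {
      idx <- sample.int(n_genes, n_spike)
      true_lfc[idx] <- rep_len(c(lfc, -lfc), n_spike)
    }
    base <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    n_samp <- 2 * n_per_group
    libsize <- stats::runif(n_samp, libsize_range[1], libsize_range[2])
    depth <- libsize / mean(libsize_range)
    cond <- rep(c("RS", "DS"), each = n_per_group)
    lfc_mat <- outer(true_lfc, as.numeric(cond == "DS"))
    mu <- (base %o% depth) * 2^lfc_mat
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    samples <- sprintf("%s_r%d", cond, rep(seq_len(n_per_group), 2))
    counts <- matrix(
      if (dispersion <= 0) stats::rpois(length(mu), mu) else
        stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu),
      nrow = n_genes, dimnames = list(genes, samples))
    list(counts = counts,
         design = data.frame(sample = samples, condition = cond,
                             replicate = rep(seq_len(n_per_group), 2),
                             stringsAsFactors = FALSE),
         truth = data.frame(gene = genes, spiked = true_lfc != 0,
                            lfc = true_lfc, stringsAsFactors = FALSE))
  })
}

#' Ground truth for synthetic process measurements
#'
#' @param config a [reactor_config()].
#' @param schedule a [feed_schedule()].
#' @param kinetics an [uptake_kinetics()].
#' @param cv multiplicative noise coefficient of variation per observable.
#' @param replicates number of replicate measurement series.
#' @param horizon simulated horizon (min).
#' @param sample_every measurement spacing (min).
#' @return list of class `process_truth`.
#' @export
process_truth <- function(config = reactor_config(),
                          schedule = intermittent_feed(),
                          kinetics = uptake_kinetics(),
                          cv = 0.05, replicates = 3,
                          horizon = 18, sample_every = 0.5) {
  stopifnot(cv >= 0, replicates >= 1)
  structure(list(config = config, schedule = schedule, kinetics = kinetics,
                 cv = cv, replicates = replicates, horizon = horizon,
                 sample_every = sample_every),
            class = "process_truth")
}

#' Generate noisy replicate process measurements
#'
#' Simulates the noiseless trajectory with [simulate_sre()] and overlays
#' multiplicative Gaussian noise (the stated CV) independently per
#' observable, time point and replicate. Deterministic per seed.
#'
#' @param truth a [process_truth()].
#' @param seed integer seed.
#' @return list with `measurements` (tidy data.frame: `time_min`,
#'   `variable`, `value`, `unit`, `replicate`) and `trajectory` (the
#'   noiseless `sre_trajectory`).
#' @export
gen_process_measurements <- function(truth = process_truth(), seed = 1) {
  traj <- simulate_sre(truth$config, truth$schedule, truth$kinetics,
                       horizon = truth$horizon)
  grid <- seq(0, truth$horizon, by = truth$sample_every)
  keep <- vapply(traj$time_min,
                 function(t) any(abs(t - grid) < 1e-6), logical(1))
  sub <- as.data.frame(traj)[keep, , drop = FALSE]
  vars <- setdiff(names(sub), c("time_min", "dilution"))
  units <- ifelse(vars == "biomass", "g/L", "mmol_C/L")
  long <- do.call(rbind, lapply(seq_along(vars), function(i)
    data.frame(time_min = sub$time_min, variable = vars[i],
               value = sub[[vars[i]]], unit = units[i],
               stringsAsFactors = FALSE)))
  meas <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(truth$replicates), function(r) {
      out <- long
      out$value <- out$value *
        (1 + stats::rnorm(nrow(out), 0, truth$cv))
      out$replicate <- r
      out
    }))
  })
  rownames(meas) <- NULL
  list(measurements = meas, trajectory = traj)
}
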