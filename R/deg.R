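#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: each sample's counts are divided by
#' the geometric mean across samples (per gene, over genes expressed in
#' every sample), and the median of those ratios is the sample's factor.
#'
#' @param counts integer matrix, genes x samples.
#' @return positive numeric vector of per-sample factors.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers")
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) stop("no gene has nonzero counts in all samples")
  lg <- log(counts[use, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - ref)))
  unname(sf)
}

# ML normalized mean of one NB group with fixed dispersion.
# Solves sum_i (y_i - sf_i m) / (1 + alpha sf_i m) = 0 (Newton + bisection
# fallback); alpha = 0 reduces to the Poisson solution sum(y)/sum(sf).
nb_group_mean <- function(y, sf, alpha) {
  if (all(y == 0)) return(0)
  m <- sum(y) / sum(sf)
  if (alpha <= 0) return(m)
  h <- function(m) sum((y - sf * m) / (1 + alpha * sf * m))
  for (i in 1:50) {
    hm <- h(m)
    dm <- hm / sum(sf * (1 + alpha * y) / (1 + alpha * sf * m)^2)
    m_new <- m + dm
    if (m_new <= 0) m_new <- m / 2
    if (abs(m_new - m) < 1e-12 * (m + 1e-12)) { m <- m_new; break }
    m <- m_new
  }
  if (abs(h(m)) > 1e-6 * (1 + sum(y))) {
    up <- max(y / pmax(sf, 1e-12)) + 1
    m <- stats::uniroot(h, c(1e-12, up), extendInt = "downX",
                        tol = 1e-12)$root
  }
  m
}

nb_loglik <- function(y, mu, alpha) {
  if (alpha <= 1e-12) return(sum(stats::dpois(y, pmax(mu, 1e-300),
                                              log = TRUE)))
  sum(stats::dnbinom(y, size = 1 / alpha, mu = pmax(mu, 1e-300),
                     log = TRUE))
}

# fit per-level means; returns means, fitted mu, loglik and the Cox-Reid
# adjustment term 0.5 * log det(X' W X) for the one-hot design
nb_fit_groups <- function(y, sf, group, alpha) {
  levs <- levels(group)
  means <- vapply(levs, function(l) {
    i <- group == l
    nb_group_mean(y[i], sf[i], alpha)
  }, numeric(1))
  mu <- sf * means[as.integer(group)]
  w <- mu / (1 + alpha * mu)
  cr <- 0.5 * sum(log(pmax(vapply(levs, function(l)
    sum(w[group == l]), numeric(1)), 1e-300)))
  list(means = means, mu = mu, loglik = nb_loglik(y, mu, alpha), cr = cr)
}

#' Estimate per-gene NB dispersions with trend shrinkage
#'
#' Gene-wise dispersions are Cox-Reid-adjusted maximum-likelihood estimates
#' under the full (factor) model, then shrunk toward a fitted
#' mean-dispersion trend a0 + a1/mu by a weighted average in log space.
#' This is a deliberately simplified empirical-Bayes scheme (no posterior
#' variance machinery); genes with sub-Poisson variation land on the lower
#' dispersion bound, and all-zero genes are flagged and excluded from
#' testing.
#'
#' @param counts integer matrix, genes x samples.
#' @param group factor of sample conditions (the full model).
#' @param sf size factors, default [size_factors()].
#' @param shrink shrink gene-wise estimates toward the trend?
#' @param prior_var variance of the log-normal prior around the trend;
#'   `NULL` (default) estimates it from the robust spread of log
#'   gene-wise estimates about the trend minus the sampling variance
#'   trigamma((m - p)/2), floored at 0.25.
#' @param disp_range allowed dispersion range.
#' @return data.frame with `gene`, `base_mean`, `dispersion_gene`,
#'   `dispersion_trend`, `dispersion` (final), `all_zero`.
#' @export
estimate_dispersion <- function(counts, group, sf = size_factors(counts),
                                shrink = TRUE, prior_var = NULL,
                                disp_range = c(1e-8, 30)) {
  counts <- as.matrix(counts)
  group <- droplevels(as.factor(group))
  if (max(table(group)) < 2)
    stop("need >= 2 replicates in at least one condition")
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)
  all_zero <- rowSums(counts) == 0

  lo <- log(disp_range[1]); hi <- log(disp_range[2])
  d_gene <- rep(NA_real_, nrow(counts))
  for (g in which(!all_zero)) {
    y <- counts[g, ]
    obj <- function(la) {
      f <- nb_fit_groups(y, sf, group, exp(la))
      -(f$loglik - f$cr)
    }
    opt <- stats::optimize(obj, c(lo, hi), tol = 1e-4)
    d_gene[g] <- exp(opt$minimum)
    # accept the boundary when the likelihood is monotone
    if (obj(lo) < opt$objective) d_gene[g] <- disp_range[1]
  }

  # parametric trend: dispersion ~ a0 + a1 / mean (gamma-family fit)
  ok <- !all_zero & d_gene > disp_range[1] * 10 & base_mean > 0
  d_trend <- rep(NA_real_, nrow(counts))
  if (sum(ok) >= 10) {
    fit <- tryCatch(
      suppressWarnings(
        stats::glm(d_gene[ok] ~ I(1 / base_mean[ok]),
                   family = stats::Gamma(link = "identity"),
                   start = c(stats::median(d_gene[ok]), 1))),
      error = function(e) NULL)
    if (!is.null(fit) && all(stats::coef(fit) >= 0)) {
      cf <- stats::coef(fit)
      d_trend <- pmax(cf[1] + cf[2] / base_mean, disp_range[1])
    }
  }
  if (all(is.na(d_trend)))
    d_trend <- rep(max(stats::median(d_gene, na.rm = TRUE),
                       disp_range[1]), nrow(counts))

  d_final <- d_gene
  if (shrink) {
    if (is.null(prior_var)) {
      samp_var <- trigamma(max((ncol(counts) - nlevels(group)) / 2, 0.5))
      r <- log(d_gene[ok]) - log(d_trend[ok])
      prior_var <- max((1.4826 * stats::mad(r, na.rm = TRUE))^2 - samp_var,
                       0.25)
    }
    # maximum a posteriori: Cox-Reid likelihood + log-normal prior on the
    # trend; flat likelihoods (boundary genes) fall back to the trend
    for (g in which(!all_zero)) {
      y <- counts[g, ]
      lt <- log(d_trend[g])
      post <- function(la) {
        f <- nb_fit_groups(y, sf, group, exp(la))
        -(f$loglik - f$cr - (la - lt)^2 / (2 * prior_var))
      }
      opt <- stats::optimize(post, c(lo, hi), tol = 1e-4)
      d_final[g] <- exp(opt$minimum)
    }
    d_final <- pmin(pmax(d_final, disp_range[1]), disp_range[2])
  }
  data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
             base_mean = base_mean, dispersion_gene = d_gene,
             dispersion_trend = d_trend, dispersion = d_final,
             all_zero = all_zero, stringsAsFactors = FALSE)
}

#' Negative-binomial likelihood-ratio test per gene
#'
#' For each gene, NB log-likelihoods are maximized with fixed gene
#' dispersion and size-factor offsets under the full model (one mean per
#' condition level) and the reduced model (a single mean); the statistic
#' 2(l_full - l_reduced) is referred to a chi-squared distribution with
#' df = levels - 1. Per-level log2 fold changes are taken against the
#' reference (first) level. For two-level designs `method = "wald"` tests
#' the log fold change against its Fisher-information standard error
#' instead.
#'
#' @param counts integer matrix, genes x samples.
#' @param group factor of sample conditions; the first level is the
#'   reference.
#' @param sf size factors.
#' @param dispersions per-gene dispersions (vector or the data.frame from
#'   [estimate_dispersion()]).
#' @param method `"lrt"` (default) or `"wald"` (two-level designs only).
#' @return a `deg_table` data.frame: `gene`, `base_mean`, one `log2fc_*`
#'   column per non-reference level (plus `log2fc` alias for two-level
#'   designs), `stat`, `df`, `pvalue`, `padj` (Benjamini-Hochberg over
#'   tested genes), `status` (all `"ns"` until [call_degs()]), `flag`.
#' @export
nb_lrt <- function(counts, group, sf = size_factors(counts),
                   dispersions = estimate_dispersion(counts, group, sf),
                   method = c("lrt", "wald")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  group <- droplevels(as.factor(group))
  levs <- levels(group)
  if (length(levs) < 2) stop("need >= 2 condition levels")
  if (method == "wald" && length(levs) != 2)
    stop("Wald test supported for two-level designs only")
  disp <- if (is.data.frame(dispersions)) dispersions$dispersion else
    dispersions
  all_zero <- rowSums(counts) == 0

  n_gene <- nrow(counts)
  lfc <- matrix(NA_real_, n_gene, length(levs) - 1,
                dimnames = list(NULL, paste0("log2fc_", levs[-1])))
  stat <- pval <- rep(NA_real_, n_gene)
  flag <- rep("", n_gene)
  df <- length(levs) - 1

  for (g in seq_len(n_gene)) {
    if (all_zero[g]) { flag[g] <- "all_zero"; next }
    y <- counts[g, ]; a <- disp[g]
    full <- nb_fit_groups(y, sf, group, a)
    m <- full$means
    if (any(m == 0)) flag[g] <- "separation"
    lfc[g, ] <- log2(pmax(m[-1], 1e-8) / pmax(m[1], 1e-8))
    if (method == "lrt") {
      red <- nb_group_mean(y, sf, a)
      mu0 <- sf * red
      stat[g] <- max(2 * (full$loglik - nb_loglik(y, mu0, a)), 0)
      pval[g] <- stats::pchisq(stat[g], df = df, lower.tail = FALSE)
    } else {
      info <- vapply(levs, function(l) {
        i <- group == l
        sum(full$mu[i] / (1 + a * full$mu[i]))
      }, numeric(1))
      if (any(info == 0)) { flag[g] <- "separation"; next }
      se <- sqrt(sum(1 / info))
      z <- (log(pmax(m[2], 1e-8)) - log(pmax(m[1], 1e-8))) / se
      stat[g] <- z^2
      pval[g] <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    }
    if (flag[g] == "separation") pval[g] <- NA_real_
  }

  padj <- rep(NA_real_, n_gene)
  tested <- !is.na(pval)
  padj[tested] <- stats::p.adjust(pval[tested], method = "BH")
  out <- data.frame(gene = rownames(counts) %||% seq_len(n_gene),
                    base_mean = rowMeans(sweep(counts, 2, sf, "/")),
                    lfc, stat = stat, df = df, pvalue = pval, padj = padj,
                    status = "ns", flag = flag, stringsAsFactors = FALSE)
  if (length(levs) == 2) out$log2fc <- out[[paste0("log2fc_", levs[2])]]
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Call differentially expressed genes
#'
#' Applies the fold-change and FDR thresholds: status `"up"` iff
#' log2FC >= `lfc_threshold` and padj < `fdr_threshold`, `"down"`
#' symmetrically, `"ns"` otherwise. For multi-level designs the maximal
#' absolute per-level fold change decides the direction.
#'
#' @param table a `deg_table` from [nb_lrt()].
#' @param lfc_threshold absolute log2 fold-change threshold.
#' @param fdr_threshold BH FDR threshold.
#' @return the table with `status` filled in.
#' @export
call_degs <- function(table, lfc_threshold = 1.0, fdr_threshold = 1e-3) {
  lfc_cols <- grep("^log2fc_", names(table), value = TRUE)
  lfc_mat <- as.matrix(table[, lfc_cols, drop = FALSE])
  pick <- apply(abs(lfc_mat), 1, function(r)
    if (all(is.na(r))) NA_real_ else r[which.max(r)])
  sgn <- apply(lfc_mat, 1, function(r)
    if (all(is.na(r))) NA_real_ else r[which.max(abs(r))])
  sig <- !is.na(table$padj) & table$padj < fdr_threshold &
    !is.na(pick) & pick >= lfc_threshold
  table$status <- "ns"
  table$status[sig & sgn > 0] <- "up"
  table$status[sig & sgn < 0] <- "down"
  table
}

#' Full differential-expression stage
#'
#' Convenience wrapper: size factors, dispersion estimation, LRT (or Wald)
#' and DEG calling in one step.
#'
#' @param counts integer matrix, genes x samples.
#' @param design data.frame with columns `sample` and `condition` (rows
#'   match the columns of `counts`).
#' @param method `"lrt"` or `"wald"`.
#' @param lfc_threshold,fdr_threshold thresholds for [call_degs()].
#' @param ref_level reference condition level (default: first occurring).
#' @return a `deg_table` with metadata (`thresholds`, `method`, `sf`) in
#'   attributes.
#' @export
deg_test <- function(counts, design, method = c("lrt", "wald"),
                     lfc_threshold = 1.0, fdr_threshold = 1e-3,
                     ref_level = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("sample", "condition") %in% names(design)),
            nrow(design) == ncol(counts))
  design <- design[match(colnames(counts) %||% design$sample,
                         design$sample), ]
  group <- as.factor(design$condition)
  if (!is.null(ref_level)) group <- stats::relevel(group, ref_level)
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, group, sf)
  tab <- nb_lrt(counts, group, sf, disp, method = method)
  tab <- call_degs(tab, lfc_threshold, fdr_threshold)
  attr(tab, "thresholds") <- c(lfc = lfc_threshold, fdr = fdr_threshold)
  attr(tab, "method") <- method
  attr(tab, "sf") <- sf
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
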