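#' Read and write GMT gene-set files
#'
#' GMT is the tab-delimited gene-set format: set name, description, then
#' member gene ids. Reading is delegated to `fgsea::gmtPathways`.
#'
#' @param path file path.
#' @return `read_gmt`: named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Normalized log2 count matrix
#'
#' Divides counts by size factors and applies log2(x + pseudocount), the
#' input scale for the set-level t statistics.
#'
#' @param counts integer matrix, genes x samples.
#' @param sf size factors, default [size_factors()].
#' @param pseudocount added before the log (default 1).
#' @return numeric matrix of log2 normalized counts.
#' @export
normalize_log2 <- function(counts, sf = size_factors(counts),
                           pseudocount = 1) {
  log2(sweep(as.matrix(counts), 2, sf, "/") + pseudocount)
}

#' Per-gene mean log2 ratio for a contrast
#'
#' Mean over the test samples minus mean over the reference samples, per
#' gene, on the log2 normalized scale.
#'
#' @param log2_counts matrix from [normalize_log2()].
#' @param test,ref column names or indices of the two sample groups
#'   (both nonempty).
#' @return named numeric vector of per-gene log2 ratios.
#' @export
per_gene_log_ratio <- function(log2_counts, test, ref) {
  if (length(test) == 0 || length(ref) == 0) stop("empty sample group")
  rowMeans(log2_counts[, test, drop = FALSE]) -
    rowMeans(log2_counts[, ref, drop = FALSE])
}

#' Set-level t statistic
#'
#' Two-sample unequal-variance (Welch) t statistic comparing the log2
#' ratios of set members against all non-members, with a two-sided p from
#' the t distribution. The sign encodes the direction of the coordinated
#' change (positive = set up relative to the background).
#'
#' @param ratios named per-gene log2 ratios (see [per_gene_log_ratio()]).
#' @param set_genes gene ids of the set; at least 2 must resolve against
#'   `names(ratios)`, and the set must not cover the whole universe.
#' @return list with `t`, `df`, `p`, `n_set`.
#' @export
set_t_statistic <- function(ratios, set_genes) {
  inset <- names(ratios) %in% set_genes
  if (sum(inset) < 2)
    stop("set has fewer than 2 resolvable members")
  if (all(inset))
    stop("set covers the whole universe: complement is empty")
  ht <- stats::t.test(ratios[inset], ratios[!inset], var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), n_set = sum(inset))
}

#' Gene-set enrichment across contrasts
#'
#' Applies [set_t_statistic()] to every (set, contrast) pair and adjusts p
#' across sets within each contrast (BH). Sets with fewer than 2
#' resolvable members are skipped with a message. A display filter at
#' `fdr` keeps sets significant in at least one contrast (applied at
#' reporting, not computation).
#'
#' @param log2_counts matrix from [normalize_log2()].
#' @param sets named list of gene-id vectors.
#' @param contrasts named list; each element is `list(test = ..., ref =
#'   ...)` with column names/indices of `log2_counts`.
#' @param fdr display FDR threshold; `NULL` disables filtering.
#' @return `gsea_result` data.frame: `set`, `contrast`, `t`, `df`, `p`,
#'   `q`, `n_set`, `significant`.
#' @export
gsea_sets <- function(log2_counts, sets, contrasts, fdr = 1e-3) {
  rows <- list()
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    ratios <- per_gene_log_ratio(log2_counts, ct$test, ct$ref)
    for (sn in names(sets)) {
      res <- tryCatch(set_t_statistic(ratios, sets[[sn]]),
                      error = function(e) NULL)
      if (is.null(res)) {
        message("skipping set '", sn, "' in contrast '", cn, "'")
        next
      }
      rows[[length(rows) + 1]] <-
        data.frame(set = sn, contrast = cn, t = res$t, df = res$df,
                   p = res$p, n_set = res$n_set, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (cn in unique(out$contrast)) {
    i <- out$contrast == cn
    out$q[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  out$significant <- out$q < (fdr %||% Inf)
  if (!is.null(fdr)) {
    keep_sets <- unique(out$set[out$significant])
    out <- out[out$set %in% keep_sets, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Exact distribution of a multi-set intersection size
#'
#' Under the null that m subsets of fixed sizes n_1..n_m are drawn
#' independently and uniformly without replacement from a universe of N
#' elements, the size of their total intersection has an exact
#' distribution obtained by propagating conditional hypergeometrics: the
#' intersection after adding a new set of size n, given current size k, is
#' hypergeometric(N, k, n). For m = 2 this reduces exactly to the
#' hypergeometric overlap distribution.
#'
#' @param set_sizes integer vector of set sizes (m >= 2), all <= N.
#' @param N universe size.
#' @return numeric vector `p[j+1] = P(|intersection| = j)`,
#'   j = 0..min(set_sizes).
#' @export
multiset_intersection_distribution <- function(set_sizes, N) {
  m <- length(set_sizes)
  if (m < 2) stop("need at least two sets")
  if (any(set_sizes < 0) || any(set_sizes > N))
    stop("set sizes must lie in [0, N]")
  # start: intersection = first set, size n1 with probability 1
  pmf <- rep(0, set_sizes[1] + 1)
  pmf[set_sizes[1] + 1] <- 1
  for (j in 2:m) {
    n <- set_sizes[j]
    kmax_j <- min(set_sizes[1:j])  # support bound after j sets
    newp <- rep(0, kmax_j + 1)
    for (k in seq_along(pmf) - 1) {
      if (pmf[k + 1] == 0) next
      x <- 0:min(k, n)
      newp[x + 1] <- newp[x + 1] +
        pmf[k + 1] * stats::dhyper(x, k, N - k, n)
    }
    pmf <- newp
  }
  pmf / sum(pmf)
}

#' Exact multi-set intersection test
#'
#' Upper-tail exact p-value P(X >= observed) for the total intersection of
#' several gene lists under uniform sampling from a common universe, with
#' the closed-form expected size N * prod(n_i / N).
#'
#' @param set_sizes integer vector of set sizes (m >= 2).
#' @param observed observed intersection size, <= min(set_sizes).
#' @param N universe size.
#' @return object of class `intersection_result`: list with `set_sizes`,
#'   `N`, `observed`, `expected`, `p_value`, `distribution`.
#' @examples
#' multiset_intersection_pvalue(c(2, 2), 2, 4)$p_value      # 1/6
#' multiset_intersection_pvalue(c(2, 2, 2), 2, 4)$p_value   # 1/36
#' @export
multiset_intersection_pvalue <- function(set_sizes, observed, N) {
  if (observed < 0 || observed > min(set_sizes))
    stop("observed overlap must lie in [0, min(set sizes)]")
  pmf <- multiset_intersection_distribution(set_sizes, N)
  p <- sum(pmf[(observed + 1):length(pmf)])
  structure(list(set_sizes = set_sizes, N = N, observed = observed,
                 expected = N * prod(set_sizes / N),
                 p_value = min(max(p, 0), 1), distribution = pmf),
            class = "intersection_result")
}

#' @export
print.intersection_result <- function(x, ...) {
  cat(sprintf(
    "Intersection of %d sets (sizes %s) in universe N = %d\n",
    length(x$set_sizes), paste(x$set_sizes, collapse = ", "), x$N))
  cat(sprintf("  observed %d, expected %.3f, exact P(X >= obs) = %.4g\n",
              x$observed, x$expected, x$p_value))
  invisible(x)
}

#' Intersection test for explicit gene lists
#'
#' @param lists named list of gene-id vectors.
#' @param universe gene universe (character vector) or its size.
#' @return an `intersection_result` (see
#'   [multiset_intersection_pvalue()]).
#' @export
intersect_gene_lists <- function(lists, universe) {
  N <- if (is.numeric(universe)) as.integer(universe) else
    length(unique(universe))
  if (!is.numeric(universe))
    lists <- lapply(lists, intersect, y = universe)
  obs <- length(Reduce(intersect, lists))
  multiset_intersection_pvalue(lengths(lists), obs, N)
}
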