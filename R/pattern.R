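#' Standardize expression trajectories
#'
#' Per-gene z-scoring (mean 0, unit sample sd) of a genes x timepoints
#' matrix of expression summaries (typically per-timepoint log2 fold
#' changes versus time zero). Constant rows cannot be standardized; they
#' are excluded and reported in the `"excluded"` attribute.
#'
#' @param trajectories numeric matrix, genes x timepoints (>= 2 columns).
#' @return standardized matrix of class `profile_matrix` with attribute
#'   `"excluded"` (rownames of constant rows).
#' @export
standardize_profiles <- function(trajectories) {
  m <- as.matrix(trajectories)
  if (ncol(m) < 2) stop("need >= 2 timepoints")
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  sds <- apply(m, 1, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  z <- (m[!const, , drop = FALSE] -
          rowMeans(m[!const, , drop = FALSE])) / sds[!const]
  structure(z, class = c("profile_matrix", class(z)),
            excluded = rownames(m)[const])
}

#' Seeded k-means clustering of expression profiles
#'
#' Lloyd's algorithm with Euclidean distance, run as `n_init` seeded
#' restarts with centers drawn from the data rows; the restart with the
#' lowest within-cluster sum of squares wins. Restarts that hit an empty
#' cluster are redrawn. Rows are processed in sorted rowname order so the
#' result is invariant to input gene order, and bit-reproducible for a
#' fixed seed.
#'
#' @param profiles numeric matrix (ideally from [standardize_profiles()]).
#' @param k number of clusters (<= number of rows).
#' @param n_init number of seeded restarts.
#' @param seed integer seed.
#' @param iter_max Lloyd iterations per restart.
#' @return object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector, labels 1..k), `centers` (k x timepoints),
#'   `sizes`, `wcss` (total within-cluster sum of squares).
#' @export
kmeans_profiles <- function(profiles, k, n_init = 50, seed = 1,
                            iter_max = 200) {
  m <- as.matrix(profiles)
  if (k > nrow(m)) stop("k exceeds the number of profiles")
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  m <- m[order(rownames(m)), , drop = FALSE]
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_init)) {
      fit <- NULL
      for (try in 1:10) {
        centers <- m[sample.int(nrow(m), k), , drop = FALSE]
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(m, centers = centers,
                                         iter.max = iter_max,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit) && all(fit$size > 0)) break
        fit <- NULL
      }
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed in all restarts")
  structure(list(cluster = best$cluster, centers = best$centers,
                 sizes = as.integer(best$size),
                 wcss = best$tot.withinss),
            class = "cluster_assignment")
}

#' Agreement between cluster labels and ground-truth classes
#'
#' Adjusted Rand index between a clustering and reference labels
#' (via `mclust::adjustedRandIndex`).
#'
#' @param clusters named cluster labels (or a `cluster_assignment`).
#' @param truth reference labels, named or aligned with `clusters`.
#' @return adjusted Rand index in \[-1, 1\].
#' @export
class_recovery_ari <- function(clusters, truth) {
  if (inherits(clusters, "cluster_assignment")) clusters <- clusters$cluster
  if (!is.null(names(clusters)) && !is.null(names(truth)))
    truth <- truth[names(clusters)]
  mclust::adjustedRandIndex(clusters, truth)
}

#' Hypergeometric over-representation test for one gene list
#'
#' Upper-tail hypergeometric p-value P(X >= k) for the overlap k between a
#' gene list (e.g. one cluster) of size n and each annotation term of size
#' K inside a universe of size N; BH correction across terms.
#'
#' @param cluster_genes character vector of gene ids.
#' @param term_sets named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all eligible gene ids; the cluster
#'   must be contained in it and term sets are intersected with it.
#' @return an `enrichment_table` data.frame: `term`, `overlap`,
#'   `set_size`, `list_size`, `universe_size`, `pvalue`, `padj`, `tier`.
#'   Empty terms are skipped with a message.
#' @export
enrich_hypergeometric <- function(cluster_genes, term_sets, universe) {
  cluster_genes <- unique(cluster_genes)
  universe <- unique(universe)
  if (!all(cluster_genes %in% universe))
    stop("cluster genes must be contained in the universe")
  if (length(cluster_genes) == 0) stop("empty gene list")
  n <- length(cluster_genes); N <- length(universe)
  rows <- lapply(names(term_sets), function(tn) {
    set <- intersect(unique(term_sets[[tn]]), universe)
    if (length(set) == 0) return(NULL)
    k <- length(intersect(cluster_genes, set)); K <- length(set)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tn, overlap = k, set_size = K, list_size = n,
               universe_size = N, pvalue = p, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) stop("no term set overlaps the universe")
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  out$tier <- significance_tiers(out$padj)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Enrichment of every cluster in an assignment
#'
#' @param assignment a `cluster_assignment` from [kmeans_profiles()].
#' @param term_sets named list of gene-id vectors.
#' @param universe gene universe (default: all clustered genes).
#' @param global_bh apply BH across all clusters jointly instead of within
#'   each cluster (default: within cluster, matching per-panel displays).
#' @return combined `enrichment_table` with a `cluster` column.
#' @export
enrich_clusters <- function(assignment, term_sets,
                            universe = names(assignment$cluster),
                            global_bh = FALSE) {
  tabs <- lapply(sort(unique(assignment$cluster)), function(cl) {
    genes <- names(assignment$cluster)[assignment$cluster == cl]
    tab <- enrich_hypergeometric(genes, term_sets, universe)
    tab$cluster <- cl
    tab
  })
  out <- do.call(rbind, tabs)
  if (global_bh) {
    out$padj <- stats::p.adjust(out$pvalue, method = "BH")
    out$tier <- significance_tiers(out$padj)
  }
  out
}

#' FDR tier symbols
#'
#' Maps adjusted p-values to the display tiers
#' `"*"` for 1e-5 <= q < 5e-2, `"**"` for 1e-10 <= q < 1e-5,
#' `"***"` for q < 1e-10, and `""` otherwise — a total partition of
#' \[0, 1\].
#'
#' @param q adjusted p-value(s) in \[0, 1\].
#' @return character vector of tier symbols.
#' @export
significance_tiers <- function(q) {
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("q must lie in [0, 1]")
  out <- character(length(q))
  out[q < 5e-2] <- "*"
  out[q < 1e-5] <- "**"
  out[q < 1e-10] <- "***"
  out[is.na(q)] <- NA_character_
  out
}
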