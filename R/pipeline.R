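#' Pipeline configuration
#'
#' Validated parameter bundle for [run_sre_pipeline()]. Defaults run the
#' whole demonstration pipeline on synthetic data at desk scale.
#'
#' @param seed master seed; each stage derives its own sub-seed from it.
#' @param lfc_threshold,fdr_threshold DEG thresholds.
#' @param k_clusters number of k-means clusters for the time-course stage.
#' @param kmeans_restarts seeded k-means restarts.
#' @param expression an [expression_truth()].
#' @param process a [process_truth()].
#' @param gsea_fdr display FDR for the gene-set stage.
#' @param universe_size universe for the intersection stage (`NULL`: all
#'   simulated genes).
#' @return validated list of class `sre_config`.
#' @export
sre_config <- function(seed = 1,
                       lfc_threshold = 1.0, fdr_threshold = 1e-3,
                       k_clusters = 7, kmeans_restarts = 25,
                       expression = expression_truth(),
                       process = process_truth(),
                       gsea_fdr = 1e-3, universe_size = NULL) {
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    stop("fdr_threshold must lie in (0, 1]")
  if (gsea_fdr <= 0 || gsea_fdr > 1) stop("gsea_fdr must lie in (0, 1]")
  if (lfc_threshold < 0) stop("lfc_threshold must be >= 0")
  if (k_clusters < 1) stop("k_clusters must be >= 1")
  stopifnot(inherits(expression, "expression_truth"),
            inherits(process, "process_truth"))
  structure(as.list(environment()), class = "sre_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level YAML keys are passed to [sre_config()]; nested `expression:`
#' and `process:` blocks override the corresponding generator defaults.
#'
#' @param path YAML file.
#' @return an `sre_config`.
#' @export
read_sre_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("expression", "process"))]
  if (!is.null(y$expression))
    args$expression <- do.call(expression_truth, y$expression)
  if (!is.null(y$process))
    args$process <- do.call(process_truth, y$process)
  do.call(sre_config, args)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full scale-down analysis pipeline on synthetic data
#'
#' Executes the seven stages in dependency order — synthetic data
#' generation, kinetics estimation from the feed-off depletion, physiology
#' summary, differential expression, trajectory clustering with
#' enrichment, gene-set statistics and multi-set intersections — writing
#' each stage's tables under `out_dir` together with a JSON run manifest
#' (parameters, output checksums, seed). Stage outputs are deterministic
#' per seed; the manifest records enough to re-execute identically.
#'
#' @param config an [sre_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest (invisibly also written to
#'   `out_dir/manifest.json`).
#' @export
run_sre_pipeline <- function(config = sre_config(), out_dir) {
  stopifnot(inherits(config, "sre_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "sretools",
                   version = as.character(utils::packageVersion("sretools")),
                   seed = config$seed, stages = list())
  t_start <- Sys.time()
  add_stage <- function(name, params, files) {
    manifest$stages[[length(manifest$stages) + 1]] <<- list(
      stage = name, params = params,
      outputs = lapply(files, function(f)
        list(file = basename(f),
             md5 = unname(tools::md5sum(f)))))
  }

  # 1. synthetic data ------------------------------------------------------
  proc <- gen_process_measurements(config$process, seed = config$seed)
  expr <- gen_count_matrix(config$expression, seed = config$seed + 1)
  f_meas <- .write_tsv(proc$measurements, file.path(out_dir,
                                                    "measurements.tsv"))
  f_counts <- .write_tsv(data.frame(gene = rownames(expr$counts),
                                    expr$counts, check.names = FALSE),
                         file.path(out_dir, "counts.tsv"))
  f_design <- .write_tsv(expr$design, file.path(out_dir, "design.tsv"))
  f_truth <- .write_tsv(expr$truth, file.path(out_dir, "truth.tsv"))
  add_stage("synth", list(n_genes = config$expression$n_genes),
            list(f_meas, f_counts, f_design, f_truth))

  # 2. uptake kinetics from the feed-off depletion ------------------------
  dep <- proc$measurements[proc$measurements$variable == "glucose" &
                             proc$measurements$time_min <= 2, ]
  dep_w <- stats::reshape(dep[, c("time_min", "replicate", "value")],
                          direction = "wide", idvar = "time_min",
                          timevar = "replicate")
  X0 <- proc$trajectory$biomass[1]
  kin_fit <- fit_uptake_kinetics(dep_w$time_min,
                                 as.matrix(dep_w[, -1]), X = X0,
                                 seed = config$seed)
  f_kin <- file.path(out_dir, "kinetics.json")
  jsonlite::write_json(list(q_max = kin_fit$q_max, K_S = kin_fit$K_S,
                            S0 = kin_fit$S0, se = as.list(kin_fit$se),
                            rss = kin_fit$rss),
                       f_kin, auto_unbox = TRUE, digits = NA)
  add_stage("kinetics", list(biomass = X0), list(f_kin))

  # 3. physiology ----------------------------------------------------------
  kin <- config$process$kinetics
  cfg <- config$process$config
  D <- dilution_profile(config$process$schedule, cfg)$net_dilution
  ss <- steady_state(cfg, kin, D)
  q_glc <- as.numeric(specific_rate(D, ss$glucose, ss$biomass,
                                    feed_conc = feed_mmol_c(cfg)))
  q_prod <- D * ss$products / ss$biomass
  yields <- c(biomass = biomass_yield(ss$biomass,
                                      feed_mmol_c(cfg) - ss$glucose,
                                      kin$carbon_fraction),
              yield_coefficient(q_prod, q_glc))
  phys <- data.frame(parameter = c("D", "biomass", "q_glucose",
                                   paste0("q_", names(q_prod)),
                                   "c_recovery"),
                     value = c(D, ss$biomass, q_glc, unname(q_prod),
                               as.numeric(carbon_recovery(yields))),
                     stringsAsFactors = FALSE)
  f_phys <- .write_tsv(phys, file.path(out_dir, "physiology.tsv"))
  add_stage("physiology", list(f_C = kin$carbon_fraction), list(f_phys))

  # 4. differential expression --------------------------------------------
  degs <- deg_test(expr$counts, expr$design,
                   lfc_threshold = config$lfc_threshold,
                   fdr_threshold = config$fdr_threshold,
                   ref_level = expr$design$condition[
                     expr$design$time_min == 0][1])
  f_degs <- .write_tsv(as.data.frame(degs), file.path(out_dir, "degs.tsv"))
  add_stage("deg", list(lfc = config$lfc_threshold,
                        fdr = config$fdr_threshold,
                        method = attr(degs, "method")), list(f_degs))

  # 5. trajectory clustering + enrichment ---------------------------------
  lfc_cols <- grep("^log2fc_", names(degs), value = TRUE)
  deg_genes <- degs$gene[degs$status != "ns"]
  profiles <- cbind(0, as.matrix(
    degs[degs$gene %in% deg_genes, lfc_cols, drop = FALSE]))
  rownames(profiles) <- deg_genes
  std <- standardize_profiles(profiles)
  km <- kmeans_profiles(std, k = min(config$k_clusters, nrow(std)),
                        n_init = config$kmeans_restarts,
                        seed = config$seed)
  # annotation sets derived from the simulated truth classes
  term_sets <- split(expr$truth$gene, expr$truth$class)
  enr <- enrich_clusters(km, term_sets, universe = degs$gene)
  clus <- data.frame(gene = names(km$cluster), cluster = km$cluster)
  f_clus <- .write_tsv(clus, file.path(out_dir, "clusters.tsv"))
  f_enr <- .write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  add_stage("cluster", list(k = km$sizes |> length(),
                            n_init = config$kmeans_restarts),
            list(f_clus, f_enr))

  # 6. gene-set statistics -------------------------------------------------
  log2c <- normalize_log2(expr$counts)
  t0_samples <- expr$design$sample[expr$design$time_min == 0]
  other_t <- setdiff(unique(expr$design$time_min), 0)
  contrasts <- lapply(other_t, function(t)
    list(test = expr$design$sample[expr$design$time_min == t],
         ref = t0_samples))
  names(contrasts) <- sprintf("t%03d_vs_t000", other_t)
  gsea <- gsea_sets(log2c, term_sets, contrasts, fdr = config$gsea_fdr)
  f_gsea <- .write_tsv(gsea, file.path(out_dir, "gsea.tsv"))
  add_stage("gsea", list(fdr = config$gsea_fdr), list(f_gsea))

  # 7. multi-set intersections ---------------------------------------------
  up <- degs$gene[degs$status == "up"]
  down <- degs$gene[degs$status == "down"]
  responsive <- expr$truth$gene[expr$truth$class != "null"]
  N <- config$universe_size %||% nrow(expr$counts)
  isect <- lapply(list(up_vs_responsive = list(up, responsive),
                       down_vs_responsive = list(down, responsive),
                       up_down_responsive = list(up, down, responsive)),
                  function(ls) {
                    sizes <- lengths(ls)
                    if (any(sizes == 0)) return(NULL)
                    r <- intersect_gene_lists(ls, N)
                    data.frame(sets = paste(sizes, collapse = ","),
                               N = r$N, observed = r$observed,
                               expected = r$expected, p = r$p_value)
                  })
  isect <- do.call(rbind, Filter(Negate(is.null), isect))
  isect$comparison <- rownames(isect)
  f_isect <- .write_tsv(isect, file.path(out_dir, "intersections.tsv"))
  add_stage("intersect", list(universe = N), list(f_isect))

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start,
                                            units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
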