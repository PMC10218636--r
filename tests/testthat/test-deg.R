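test_that("size factors follow the median-of-ratios definition", {
  A <- c(10, 20, 40)
  m <- cbind(s1 = A, s2 = 2 * A)
  expect_equal(size_factors(m), c(1 / sqrt(2), sqrt(2)))
  ident <- cbind(A, A, A)
  expect_equal(size_factors(ident), c(1, 1, 1))
  # scaling one sample by c multiplies its factor by c^(2/3) relative shift:
  # with the geometric reference, c splits as c^(1-1/n) vs c^(-1/n)
  m2 <- cbind(s1 = A, s2 = A, s3 = 4 * A)
  sf <- size_factors(m2)
  expect_equal(sf[3] / sf[1], 4)
  expect_equal(prod(sf), 1, tolerance = 1e-12)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "no gene")
  expect_error(size_factors(matrix(c(-1, 2), 1)), "nonnegative")
})

test_that("NB group means reduce to arithmetic means at unit size factors", {
  fx <- tiny_counts()
  g <- factor(fx$design$condition)
  tab <- nb_lrt(fx$counts, g, sf = rep(1, 4),
                dispersions = rep(0.1, 4))
  for (i in 1:3) {
    mA <- mean(fx$counts[i, 1:2]); mB <- mean(fx$counts[i, 3:4])
    expect_equal(tab$log2fc[i], log2(mB / mA), tolerance = 1e-8)
  }
  expect_equal(tab$flag[4], "all_zero")
  expect_true(is.na(tab$pvalue[4]))
})

test_that("a gene with identical group behavior gives a null statistic", {
  m <- matrix(c(20, 20, 20, 20), 1,
              dimnames = list("g1", paste0("s", 1:4)))
  tab <- nb_lrt(m, factor(c("A", "A", "B", "B")), sf = rep(1, 4),
                dispersions = 0.05)
  expect_equal(tab$stat, 0, tolerance = 1e-8)
  expect_equal(tab$pvalue, 1, tolerance = 1e-8)
})

test_that("DEG status respects both thresholds", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc_B = c(0.9, 1.2, -1.5, 2),
                    padj = c(1e-5, 1e-4, 1e-4, 0.5))
  out <- call_degs(tab)
  expect_equal(out$status, c("ns", "up", "down", "ns"))
})

test_that("BH-adjusted q-values dominate p-values monotonically", {
  fx <- gen_two_group_counts(n_genes = 300, spike_fraction = 0.1,
                             seed = 21)
  tab <- deg_test(fx$counts, fx$design)
  ok <- !is.na(tab$pvalue)
  expect_true(all(tab$padj[ok] >= tab$pvalue[ok]))
  ord <- order(tab$pvalue[ok])
  expect_true(all(diff(tab$padj[ok][ord]) >= -1e-12))
})

test_that("the LRT is invariant to the reference level", {
  fx <- gen_two_group_counts(n_genes = 120, spike_fraction = 0.2,
                             seed = 8)
  g1 <- factor(fx$design$condition, levels = c("RS", "DS"))
  g2 <- factor(fx$design$condition, levels = c("DS", "RS"))
  sf <- size_factors(fx$counts)
  d <- estimate_dispersion(fx$counts, g1, sf)
  t1 <- nb_lrt(fx$counts, g1, sf, d$dispersion)
  t2 <- nb_lrt(fx$counts, g2, sf, d$dispersion)
  expect_equal(t1$stat, t2$stat, tolerance = 1e-6)
  expect_equal(t1$log2fc, -t2$log2fc, tolerance = 1e-6)
})

test_that("test statistics are stable under per-sample rescaling", {
  fx <- gen_two_group_counts(n_genes = 400, spike_fraction = 0.1,
                             seed = 13, baseline_meanlog = 6)
  scaled <- fx$counts
  scaled[, 1] <- scaled[, 1] * 2L   # integer doubling of one library
  t1 <- deg_test(fx$counts, fx$design)
  t2 <- deg_test(scaled, fx$design)
  ok <- !is.na(t1$pvalue) & !is.na(t2$pvalue) & t1$base_mean > 20
  expect_gt(stats::cor(t1$stat[ok], t2$stat[ok], method = "spearman"),
            0.98)
  expect_equal(stats::median(abs(t1$log2fc[ok] - t2$log2fc[ok])), 0,
               tolerance = 0.05)
})

test_that("dispersion estimation recovers the simulated regimes", {
  # Poisson data: gene-wise estimates collapse toward zero
  po <- gen_two_group_counts(400, 0, dispersion = 0, seed = 3)
  dp <- estimate_dispersion(po$counts, factor(po$design$condition))
  expect_lt(stats::median(dp$dispersion_gene, na.rm = TRUE), 0.01)
  # NB alpha = 0.1, n = 6: median within a factor two
  nb <- gen_two_group_counts(1000, 0, dispersion = 0.1, seed = 4)
  dn <- estimate_dispersion(nb$counts, factor(nb$design$condition))
  med <- stats::median(dn$dispersion_gene, na.rm = TRUE)
  expect_gte(med, 0.05); expect_lte(med, 0.2)
  # constant gene sits at the lower bound
  m <- rbind(g1 = rep(50L, 6), g2 = c(30L, 55L, 41L, 46L, 39L, 52L))
  dc <- estimate_dispersion(m, factor(rep(c("A", "B"), each = 3)),
                            sf = rep(1, 6), shrink = FALSE)
  expect_equal(dc$dispersion_gene[1], 1e-8)
})

test_that("Wald and LRT agree on strong two-level effects", {
  fx <- gen_two_group_counts(n_genes = 200, spike_fraction = 0.15,
                             seed = 17)
  lrt <- deg_test(fx$counts, fx$design, method = "lrt")
  wald <- deg_test(fx$counts, fx$design, method = "wald")
  both_called <- table(lrt$status != "ns", wald$status != "ns")
  agree <- sum(diag(both_called)) / sum(both_called)
  expect_gt(agree, 0.95)
  expect_equal(lrt$log2fc, wald$log2fc, tolerance = 1e-8)
})

test_that("fitted NB means match an independent reference implementation", {
  skip_if_not_installed("DESeq2")
  fx <- gen_two_group_counts(n_genes = 150, spike_fraction = 0.2,
                             seed = 31)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      fx$counts,
      data.frame(condition = factor(fx$design$condition,
                                    levels = c("RS", "DS"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, test = "LRT", reduced = ~1, quiet = TRUE)
  })
  res <- DESeq2::results(dds, independentFiltering = FALSE)
  mine <- deg_test(fx$counts, fx$design, ref_level = "RS")
  ok <- !is.na(res$pvalue) & !is.na(mine$pvalue) & mine$base_mean > 10
  # size factors agree exactly; fold changes and calls agree closely even
  # though the dispersion shrinkage schemes differ by design
  expect_equal(attr(mine, "sf"), unname(DESeq2::sizeFactors(dds)),
               tolerance = 1e-6)
  expect_gt(stats::cor(mine$log2fc[ok], res$log2FoldChange[ok]), 0.99)
  calls_mine <- mine$padj < 1e-3 & abs(mine$log2fc) >= 1
  calls_ref <- res$padj < 1e-3 & abs(res$log2FoldChange) >= 1
  expect_gt(mean(calls_mine[ok] == calls_ref[ok], na.rm = TRUE), 0.93)
})
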