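# Phage motif depletion and CDS / expression context analyses.

test_that("motif frequency per kb matches hand counts and a brute-force scan", {
  g <- reference_genome(c(c1 = paste0(strrep("C", 494), "GATC",
                                      strrep("C", 498), "GATC",
                                      strrep("C", 1000))))
  m <- iupac_motif("GATC")
  # 2 spans x 2 strands (palindrome) in 2000 bp = 2 per kb
  expect_equal(motif_freq_per_kb(g, m), 2)
  expect_equal(motif_freq_per_kb(g, iupac_motif("AAAAGG")), 0)
  expect_error(motif_freq_per_kb(g, m,
                                 interval = list(contig = "c1", start = 0, end = 3)),
               "shorter than the motif")

  g2 <- simulate_genome(77, 10000, gc = 0.45)
  ref <- nrow(brute_force_scan(g2$contigs[[1]], "GATC", 2))
  expect_equal(motif_freq_per_kb(g2, m), ref / 10)
})

test_that("depletion testing detects planted thinning and is antisymmetric", {
  set.seed(50)
  pairs <- data.frame(host_freq_per_kb = runif(10, 4, 8))
  pairs$phage_freq_per_kb <- pairs$host_freq_per_kb * runif(10, 0.1, 0.3)
  res <- depletion_test(pairs)
  expect_lte(res$t_test$p_value, 0.05)
  expect_lte(res$median_ratio, 0.5)

  swapped <- data.frame(host_freq_per_kb = pairs$phage_freq_per_kb,
                        phage_freq_per_kb = pairs$host_freq_per_kb)
  res_sw <- depletion_test(swapped)
  expect_equal(res_sw$t_test$t, -res$t_test$t, tolerance = 1e-12)

  equal_pairs <- data.frame(host_freq_per_kb = c(1, 2, 3),
                            phage_freq_per_kb = c(1, 2, 3))
  expect_error(depletion_test(equal_pairs), "zero variance")
  expect_error(depletion_test(pairs[1:2, ]), "at least 3")
})

test_that("CDS territory partitions the genome exactly and assigns every site once", {
  g <- reference_genome(c(c1 = strrep("ACGT", 2500))) # 10 kb
  ann <- annotation_set(data.frame(
    contig = "c1", start = c(1000L, 1500L, 4000L), end = c(2000L, 2500L, 6000L),
    strand = "+", type = "CDS",
    gene_id = c("g1", "g1b", "g2")), g)
  st <- random_site_records(200, seed = 9, contigs = "c1", max_pos = 10000L)
  res <- cds_vs_noncds_density(st, ann, g)
  # overlapping CDS merged: [1000,2500) + [4000,6000) = 3.5 kb
  expect_equal(res$cds_kb, 3.5)
  expect_equal(res$cds_kb + res$noncds_kb, 10)
  expect_identical(res$n_cds_sites + res$n_noncds_sites, nrow(st))

  inside <- site_records(data.table::data.table(
    contig = "c1", pos = c(1100L, 4100L, 5000L), strand = "+",
    n_total = 10L, n_meth = 10L))
  res2 <- cds_vs_noncds_density(inside, ann, g)
  expect_equal(res2$noncds_density, 0)

  full <- annotation_set(data.frame(contig = "c1", start = 0L, end = 10000L,
                                    strand = "+", type = "CDS", gene_id = "g"), g)
  expect_error(cds_vs_noncds_density(st, full, g), "whole genome")
})

test_that("uniformly placed sites show no CDS enrichment in most seeds", {
  g <- reference_genome(c(c1 = strrep("ACGT", 2500)))
  ann <- annotation_set(data.frame(
    contig = "c1", start = seq(0L, 9000L, by = 2000L),
    end = seq(800L, 9800L, by = 2000L), strand = "+", type = "CDS",
    gene_id = paste0("g", 1:5)), g)
  n_sig <- 0L
  for (s in 1:20) {
    dens <- lapply(1:4, function(gi) {
      st <- random_site_records(150, seed = s * 10 + gi, contigs = "c1",
                                max_pos = 10000L)
      cds_vs_noncds_density(st, ann, g)
    })
    p <- cds_enrichment_test(dens)$t_test$p_value
    if (p <= 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 4L) # about nominal over 20 seeds
})

test_that("3x denser CDS methylation is detected by the paired test", {
  g <- reference_genome(c(c1 = strrep("ACGT", 2500)))
  ann <- annotation_set(data.frame(
    contig = "c1", start = c(0L, 5000L), end = c(2500L, 7500L),
    strand = "+", type = "CDS", gene_id = c("g1", "g2")), g)
  union_pos <- c(0:2499, 5000:7499)
  noncds_pos <- setdiff(0:9999, union_pos)
  dens <- lapply(1:4, function(gi) {
    set.seed(gi + 400)
    pos <- c(sample(union_pos, 280 + 15 * gi), sample(noncds_pos, 90 + 8 * gi))
    st <- site_records(data.table::data.table(
      contig = "c1", pos = pos, strand = "+", n_total = 10L, n_meth = 10L))
    cds_vs_noncds_density(st, ann, g)
  })
  res <- cds_enrichment_test(dens)
  expect_lte(res$t_test$p_value, 0.05)
  expect_true(all(vapply(dens, `[[`, numeric(1), "cds_density") >
                    vapply(dens, `[[`, numeric(1), "noncds_density")))
})

test_that("per-gene methylation tables join expression and compute density per kb", {
  g <- reference_genome(c(c1 = strrep("ACGT", 2500)))
  ann <- annotation_set(data.frame(
    contig = "c1", start = c(0L, 2000L), end = c(1000L, 4000L),
    strand = "+", type = "CDS", gene_id = c("g1", "g2")), g)
  st <- site_records(data.table::data.table(
    contig = "c1", pos = c(10L, 500L, 2100L), strand = "+",
    n_total = 10L, n_meth = 10L))
  expr <- data.frame(gene_id = c("g1", "g2"), expression = c(5.0, 1.0))
  gm <- gene_methylation(st, ann, g, expr)
  g1 <- gm[gm$gene_id == "g1", ]
  expect_identical(g1$n_6mA_in_cds, 2L)
  expect_equal(g1$density, 2000 * 1 / 1000) # 2 sites / 1 kb
  expect_equal(g1$expression, 5.0)
})

test_that("expression correlation recovers planted signal and stays null when absent", {
  set.seed(91)
  density <- runif(40, 0, 20)
  # planted: expression follows density at signal-to-noise 3
  expr_signal <- density + rnorm(40, 0, sd(density) / 3)
  gm <- data.frame(gene_id = paste0("g", 1:40), density = density,
                   expression = expr_signal)
  res <- expression_correlation(gm)
  expect_gte(res$correlation$r, 0.6)
  expect_lte(res$correlation$p_value, 0.05)

  n_sig <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    gm0 <- data.frame(gene_id = paste0("g", 1:30), density = runif(30),
                      expression = runif(30))
    if (expression_correlation(gm0)$correlation$p_value <= 0.05) {
      n_sig <- n_sig + 1L
    }
  }
  expect_lte(n_sig, 4L)

  gm_small <- data.frame(gene_id = paste0("g", 1:5), density = runif(5),
                         expression = runif(5))
  expect_error(expression_correlation(gm_small), ">= 10 genes")
  # equal vectors correlate perfectly
  gm_eq <- data.frame(gene_id = paste0("g", 1:12), density = 1:12,
                      expression = 1:12)
  expect_equal(expression_correlation(gm_eq)$correlation$r, 1)
})
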