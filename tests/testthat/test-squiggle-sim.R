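# The synthetic-data generator: pore model, genome, methylation truth,
# per-read signal synthesis, dataset-level determinism and cohort mode.

test_that("pore model is seed-deterministic with full 6-mer coverage", {
  m1 <- build_pore_model(5)
  m2 <- build_pore_model(5)
  expect_identical(m1, m2)
  expect_length(m1$level, 4096L)
  expect_length(m1$kmers, 4096L)
  expect_true(all(m1$spread > 0))
  # shifts exist exactly where the offset base is A, with |shift| >= floor
  a_at <- sapply(1:6, function(j) substr(m1$kmers, j, j) == "A")
  expect_true(all(abs(m1$shift[a_at]) >= m1$shift_min))
  expect_true(all(m1$shift[!a_at] == 0))
  m3 <- build_pore_model(6)
  expect_gte(mean(m1$level != m3$level), 0.99)
  expect_error(build_pore_model(1, shift_min = 0), "shift_min")
})

test_that("simulated genomes hit the target GC within the binomial 99.9% band", {
  g <- simulate_genome(9, 10000, gc = 0.5)
  gc_count <- sum(strsplit(g$contigs[[1]], "")[[1]] %in% c("G", "C"))
  band <- qbinom(c(5e-4, 1 - 5e-4), 10000, 0.5)
  expect_gte(gc_count, band[1])
  expect_lte(gc_count, band[2])
  expect_identical(simulate_genome(9, 10000, gc = 0.5)$contigs,
                   g$contigs)
  expect_error(simulate_genome(1, 10), ">= 1000")
  expect_error(simulate_genome(1, 5000, gc = 1.2), "gc")
})

test_that("methylation truth respects boundary ratios and the binomial law", {
  g <- tiny_genome()
  occ <- scan_motif(g, iupac_motif("GATC"))

  full <- assign_methylation_states(g, gatc_scheme(ratio = 1, background = 0), 1)
  expect_identical(nrow(full), nrow(occ))
  expect_true(all(full$pos %in% occ$pos))

  none <- assign_methylation_states(g, gatc_scheme(ratio = 0, background = 0), 1)
  expect_identical(nrow(none), 0L)

  g10 <- simulate_genome(41, 10000, gc = 0.45)
  occ10 <- scan_motif(g10, iupac_motif("GATC"))
  tr <- assign_methylation_states(g10, gatc_scheme(ratio = 0.9, background = 0), 7)
  band <- qbinom(c(0.005, 0.995), nrow(occ10), 0.9)
  expect_gte(nrow(tr), band[1])
  expect_lte(nrow(tr), band[2])
})

test_that("overlapping motif occurrences use the maximum applicable ratio", {
  # two motifs sharing the same focal A: AGATC (focal offset 3) and GATC
  g <- reference_genome(c(c1 = paste0(strrep("C", 20), "AGATC", strrep("C", 20))))
  sch <- methylation_scheme(list(iupac_motif("GATC"), iupac_motif("AGATC", 3)),
                            c(0, 1), background_rate = 0)
  tr <- assign_methylation_states(g, sch, 3)
  # the shared focal A must be methylated with ratio max(0, 1) = 1
  expect_true(22L %in% tr$pos[tr$strand == "+"])
})

test_that("read simulation is conservative, deterministic and exact at zero noise", {
  g <- tiny_genome()
  pm <- small_pore_model()
  r <- simulate_read(g, NULL, pm, "sim_contig", 100, 300, "+",
                     noise_sd = 0, dwell_mean = 6, seed = 2)
  expect_identical(length(r$samples), sum(r$dwells))
  expect_identical(length(r$dwells), nchar(r$sequence))
  # zero noise, no methylation: every base's samples equal its model level
  ctx <- metameth:::molecule_context(g, "sim_contig", 100, 300, "+")
  lev <- pm$level[ctx$kidx]
  expect_equal(r$samples, rep(lev, r$dwells), tolerance = 1e-12)
  r2 <- simulate_read(g, NULL, pm, "sim_contig", 100, 300, "+",
                      noise_sd = 0, dwell_mean = 6, seed = 2)
  expect_identical(r2$samples, r$samples)
  expect_error(simulate_read(g, NULL, pm, "sim_contig", 4900, 5300, "+"),
               "outside contig")
})

test_that("methylated and unmethylated copies differ exactly at shifted contexts", {
  g <- tiny_genome()
  pm <- small_pore_model()
  truth <- assign_methylation_states(g, gatc_scheme(ratio = 1, background = 0), 1)
  r_meth <- simulate_read(g, truth, pm, "sim_contig", 500, 900, "+",
                          noise_sd = 0, dwell_mean = 5, seed = 9)
  r_unm <- simulate_read(g, NULL, pm, "sim_contig", 500, 900, "+",
                         noise_sd = 0, dwell_mean = 5, seed = 9)
  expect_identical(r_meth$dwells, r_unm$dwells) # same RNG stream
  per_base_m <- r_meth$samples[cumsum(r_meth$dwells)]
  per_base_u <- r_unm$samples[cumsum(r_unm$dwells)]
  differs <- which(abs(per_base_m - per_base_u) > 1e-9)
  # shifted bases are exactly those whose 6-mer window covers a methylated A;
  # the first/last 3 bases may also respond to methylation in the flanking
  # context outside the read, so the check is restricted to the interior
  meth_local <- r_meth$truth_local
  expect_gt(length(meth_local), 0L)
  affected <- sort(unique(unlist(lapply(meth_local, function(p) (p - 3):(p + 2)))))
  affected <- affected[affected >= 0 & affected < 400] + 1L
  interior <- 4:397
  expect_true(all(intersect(differs, interior) %in% affected))
  meth_interior <- intersect(meth_local + 1L, interior)
  expect_true(all(meth_interior %in% differs))
})

test_that("minus-strand reads carry the reverse-complement sequence and template truth", {
  g <- tiny_genome()
  pm <- small_pore_model()
  truth <- assign_methylation_states(g, gatc_scheme(ratio = 1, background = 0), 1)
  r <- simulate_read(g, truth, pm, "sim_contig", 1000, 1400, "-",
                     noise_sd = 0.5, dwell_mean = 9, seed = 4)
  expect_identical(r$sequence,
                   metameth:::revcomp(substr(g$contigs[[1]], 1001, 1400)))
  # read-local truth maps back to minus-strand genome truth
  gpos <- r$end - 1L - r$truth_local
  key <- paste(gpos, "-")
  truth_key <- paste(truth$pos, truth$strand)
  expect_true(all(key %in% truth_key))
  # and those genome positions carry T on the plus strand (A on minus)
  bases <- substring(g$contigs[[1]], gpos + 1L, gpos + 1L)
  expect_true(all(bases == "T"))
})

test_that("simulated datasets reach the target coverage and are byte-deterministic", {
  cfg <- sim_config(seed = 33, genome_length = 20000, coverage_mean = 10,
                    read_length_mean = 500, read_length_sd = 100)
  ds <- simulate_dataset(cfg, gatc_scheme())
  cov <- coverage_stats(ds$reads, ds$genome)
  expect_gte(cov$mean_depth, 8.5)
  expect_lte(cov$mean_depth, 11.5)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_signal_archive(ds$reads, d1, truth = ds$truth)
  ds2 <- simulate_dataset(cfg, gatc_scheme())
  write_signal_archive(ds2$reads, d2, truth = ds2$truth)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_error(sim_config(seed = 1, coverage_mean = 0), "coverage_mean")
})

test_that("prophage mode thins motif occurrences by the depletion factor", {
  cfg <- sim_config(seed = 55, genome_length = 30000, coverage_mean = 1,
                    read_length_mean = 500,
                    prophage = list(fraction = 0.3, depletion_factor = 5))
  ds <- simulate_dataset(cfg, gatc_scheme())
  m <- iupac_motif("GATC")
  ph <- ds$prophage_interval
  phage_kb <- motif_freq_per_kb(ds$genome, m, interval = ph)
  host_len <- genome_length(ds$genome) - (ph$end - ph$start)
  host_occ <- nrow(scan_motif(ds$genome, m)) -
    phage_kb * (ph$end - ph$start) / 1000
  host_kb <- host_occ / (host_len / 1000)
  expect_lt(phage_kb, host_kb / 3)
})

test_that("cohort mode fixes each individual's scheme across timepoints", {
  g <- tiny_genome()
  sch <- methylation_scheme(list(iupac_motif("GATC"), iupac_motif("CCATC"),
                                 iupac_motif("GAAGG")),
                            c(0.9, 0.7, 0.5), background_rate = 0)
  co <- simulate_cohort_usage(g, sch, n_individuals = 3, n_timepoints = 2,
                              seed = 12)
  expect_identical(dim(co$usage), c(6L, 1024L))
  expect_equal(unname(rowSums(co$usage)), rep(1, 6), tolerance = 1e-12)
  expect_identical(nrow(co$individual_weights), 3L)
  # within-individual usage distances smaller than between on average
  dm <- bray_curtis_matrix(co$usage)
  same <- outer(co$meta$individual, co$meta$individual, "==")
  ut <- upper.tri(dm$D)
  expect_lt(mean(dm$D[ut & same]), mean(dm$D[ut & !same]))
})
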