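# IUPAC motif scanning, modification ratios, 5-mer usage, enrichment scan.

test_that("IUPAC motifs validate their focal adenine", {
  m <- iupac_motif("GATC")
  expect_identical(m$focal, 2L)
  m2 <- iupac_motif("RAATTY", 2)
  expect_identical(m2$focal, 2L)
  expect_error(iupac_motif("GATC", 4), "does not admit A")
  expect_error(iupac_motif("GTC"), "at least 4")
  expect_error(iupac_motif("GXTC"), "invalid IUPAC")
})

test_that("degenerate motif matching honours IUPAC codes", {
  g <- reference_genome(c(c1 = paste0("TTTT", "GAATTC", "TTTT")))
  hits <- scan_motif(g, iupac_motif("RAATTY", 2))
  plus <- hits[hits$strand == "+", ]
  expect_identical(plus$pos, 5L) # focal A at offset 2 of the match at 4
  # GAATTC is an RAATTY palindample: minus strand hits too
  expect_identical(nrow(hits[hits$strand == "-", ]), 1L)
})

test_that("palindromic motif occurrences enumerate both strands correctly", {
  g <- reference_genome(c(c1 = "GATCGATC"))
  hits <- scan_motif(g, iupac_motif("GATC"))
  expect_identical(sort(hits[hits$strand == "+", ]$pos), c(1L, 5L))
  expect_identical(sort(hits[hits$strand == "-", ]$pos), c(2L, 6L))
})

test_that("scanning equals a brute-force position-by-position matcher", {
  set.seed(23)
  motifs <- list(iupac_motif("GATC"), iupac_motif("RAATTY", 2),
                 iupac_motif("CCWGG", 3), iupac_motif("GAAGG"))
  for (i in 1:5) {
    g <- simulate_genome(400 + i, 2000, gc = runif(1, 0.35, 0.6))
    for (m in motifs) {
      got <- scan_motif(g, m)
      ref <- brute_force_scan(g$contigs[[1]], m$pattern, m$focal)
      key <- function(d) sort(paste(d$pos, d$strand))
      expect_identical(key(got), key(ref))
    }
  }
})

test_that("N-containing windows are excluded from motif scans", {
  g <- reference_genome(c(c1 = "TTGANCTTGATCTT"))
  hits <- scan_motif(g, iupac_motif("GATC"))
  expect_identical(hits[hits$strand == "+", ]$pos, 9L) # only the intact copy
})

test_that("modification ratios follow the depth-qualified definition", {
  g <- reference_genome(c(c1 = paste0("TTTT", "GAAGG", "TTTT", "GAAGG", "TTTT")))
  occ <- scan_motif(g, iupac_motif("GAAGG"))
  plus <- occ[occ$strand == "+", ]
  expect_identical(nrow(plus), 2L)
  sites <- site_records(data.table::data.table(
    contig = "c1", pos = plus$pos, strand = "+",
    n_total = c(10L, 10L), n_meth = c(9L, 1L)))
  ms <- modification_ratio(sites, g, iupac_motif("GAAGG"))
  expect_identical(ms$n_occurrences, 2L)
  expect_identical(ms$n_modified, 1L)
  expect_equal(ms$modification_ratio, 0.5)

  shallow <- site_records(data.table::data.table(
    contig = "c1", pos = plus$pos, strand = "+",
    n_total = c(2L, 3L), n_meth = c(2L, 3L)))
  ms2 <- modification_ratio(shallow, g, iupac_motif("GAAGG"))
  expect_true(is.na(ms2$modification_ratio)) # missing, not zero
})

test_that("modification ratio is invariant to site row order", {
  g <- tiny_genome()
  st <- random_site_records(400, seed = 31, contigs = "sim_contig",
                            max_pos = 5000L)
  m <- iupac_motif("GATC")
  r1 <- modification_ratio(st, g, m)
  set.seed(1)
  r2 <- modification_ratio(st[sample(nrow(st)), ], g, m)
  expect_identical(r1$modification_ratio, r2$modification_ratio)
})

test_that("5-mer usage vectors normalise centred contexts, reverse-complementing minus sites", {
  g <- reference_genome(c(c1 = paste0("TT", "GGATC", "TT", "GGATC",
                                      "TT", "CCATC", "TT", "CCATC", "TT")))
  # centre each 5-mer on its adenine (offset 3 within the printed blocks)
  pos <- c(2L, 9L, 16L, 23L) + 2L
  st <- site_records(data.table::data.table(
    contig = "c1", pos = pos, strand = "+", n_total = 10L, n_meth = 10L))
  u <- kmer_usage_vector(st, g)
  expect_equal(unname(u["GGATC"]), 0.5)
  expect_equal(unname(u["CCATC"]), 0.5)
  expect_equal(sum(u), 1)

  one <- kmer_usage_vector(st[1], g)
  expect_identical(sum(one > 0), 1L) # one-hot

  # a minus-strand site reports its reverse-complement context
  stm <- site_records(data.table::data.table(
    contig = "c1", pos = 4L + 1L, strand = "-", n_total = 10L, n_meth = 10L))
  um <- kmer_usage_vector(stm, g)
  ctx_plus <- substr(g$contigs[[1]], 4, 8)
  expect_equal(unname(um[metameth:::revcomp(ctx_plus)]), 1)

  expect_warning(u0 <- kmer_usage_vector(st[0], g), "no usable")
  expect_equal(sum(u0), 0)
})

test_that("usage vectors sum to one across random site sets", {
  g <- tiny_genome()
  for (i in 1:20) {
    st <- random_site_records(50, seed = 100 + i, contigs = "sim_contig",
                              max_pos = 4990L)
    u <- suppressWarnings(kmer_usage_vector(st, g))
    if (sum(u) > 0) expect_equal(sum(u), 1, tolerance = 1e-12)
  }
})

test_that("enrichment scanning recovers a planted motif and refuses tiny inputs", {
  g <- simulate_genome(321, 20000, gc = 0.45)
  truth <- assign_methylation_states(g, gatc_scheme(ratio = 0.9, background = 1e-4), 5)
  st <- site_records(data.table::data.table(
    contig = truth$contig, pos = truth$pos, strand = truth$strand,
    n_total = 10L, n_meth = 10L))
  en <- discover_enriched_motifs(st, g)
  top5 <- en[en$k == 5, ][1:4, ]
  # the planted GATC contexts (NGATC with central A) dominate the ranking
  expect_true(all(substr(top5$kmer, 2, 5) == "GATC"))
  expect_true(all(top5$significant))
  expect_error(discover_enriched_motifs(st[1:10, ], g), "at least 50")
})

test_that("enrichment binomial p-values match explicit summation for small n", {
  for (n in c(5L, 12L, 20L)) {
    for (x in c(0L, 2L, n)) {
      p0 <- 0.13
      mine <- pbinom(x - 1L, n, p0, lower.tail = FALSE)
      exact <- sum(vapply(x:n, function(k) choose(n, k) * p0^k * (1 - p0)^(n - k),
                          numeric(1L)))
      expect_equal(mine, exact, tolerance = 1e-12)
    }
  }
})

test_that("uniform random methylation yields no significant enrichment in most seeds", {
  g <- cached("null_enrich_genome", simulate_genome(555, 8000, gc = 0.45))
  n_sig <- 0L
  for (s in 1:50) {
    set.seed(s)
    aa <- metameth:::all_adenine_sites(g)
    st <- aa[sample(nrow(aa), 120), ]
    en <- discover_enriched_motifs(st, g)
    if (any(en$q_value < 0.05)) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 0.05 * 50 + 2) # >= 95% of seeds clean
})
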