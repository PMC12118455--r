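# Shared fixtures. Expensive simulations are built lazily and cached for
# the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_genome <- function() cached("tiny_genome", simulate_genome(101, 5000, gc = 0.45))

small_pore_model <- function() cached("pore_model", build_pore_model(7))

gatc_scheme <- function(ratio = 0.9, background = 1e-4) {
  methylation_scheme(list(iupac_motif("GATC")), ratio, background_rate = background)
}

# small simulated dataset shared across resquiggle/caller/aggregation tests
small_dataset <- function() {
  cached("small_dataset", {
    cfg <- sim_config(seed = 311, genome_length = 20000, coverage_mean = 10,
                      read_length_mean = 600, read_length_sd = 100)
    simulate_dataset(cfg, gatc_scheme())
  })
}

# labelled windows from a small randomly methylated control
small_control_windows <- function() {
  cached("control_windows", {
    ds <- small_dataset()
    cfgT <- sim_config(seed = 955, genome_length = 30000, coverage_mean = 4,
                       read_length_mean = 600, read_length_sd = 100)
    dsT <- simulate_training_control(cfgT, ds$pore_model, meth_rate = 0.1)
    collect_feature_windows(dsT$reads, ds$pore_model, dsT$genome)
  })
}

random_site_records <- function(n, seed, contigs = "c1", max_pos = 1000L) {
  set.seed(seed)
  pos <- sample.int(max_pos, n, replace = TRUE) - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  dt <- unique(data.table::data.table(contig = sample(contigs, n, replace = TRUE),
                                      pos = pos, strand = strand))
  dt$n_total <- sample(1:50, nrow(dt), replace = TRUE)
  dt$n_meth <- vapply(dt$n_total, function(t) sample.int(t + 1L, 1L) - 1L, integer(1L))
  site_records(dt)
}

# brute-force monotone event-to-base alignment oracle (exhaustive)
brute_force_alignment <- function(event_means, expected, skip_cost) {
  ne <- length(event_means)
  nb <- length(expected)
  best <- Inf
  rec <- function(i, j_prev, acc) {
    if (acc >= best) return(invisible(NULL))
    if (i > ne) {
      total <- acc + skip_cost * (nb - j_prev)
      if (total < best) best <<- total
      return(invisible(NULL))
    }
    for (j in j_prev:nb) {
      # bases strictly between j_prev and j (or before the first) are skipped
      pen <- if (i == 1L) skip_cost * (j - 1L) else skip_cost * max(0L, j - j_prev - 1L)
      rec(i + 1L, j, acc + abs(event_means[i] - expected[j]) + pen)
    }
  }
  rec(1L, 1L, 0)
  best
}

# brute-force IUPAC matcher: position-by-position comparison, both strands
brute_force_scan <- function(seq, pattern, focal) {
  iupac <- metameth:::IUPAC_SETS
  pat <- strsplit(pattern, "")[[1]]
  match_at <- function(s, start0) {
    win <- substring(s, start0 + 1L, start0 + length(pat))
    if (grepl("N", win, fixed = TRUE)) return(FALSE)
    all(mapply(function(b, code) b %in% iupac[[code]],
               strsplit(win, "")[[1]], pat))
  }
  L <- nchar(seq)
  plus <- Filter(function(s) match_at(seq, s), 0:(L - length(pat)))
  rc <- metameth:::revcomp(seq)
  minus_rc <- Filter(function(s) match_at(rc, s), 0:(L - length(pat)))
  data.table::data.table(
    pos = c(unlist(plus) + focal - 1L,
            L - 1L - (unlist(minus_rc) + focal - 1L)),
    strand = rep(c("+", "-"), c(length(plus), length(minus_rc)))
  )
}

# exhaustive PERMANOVA oracle: enumerate all distinct label assignments
brute_force_permanova <- function(D, groups) {
  D2 <- D^2
  n <- nrow(D2)
  f_of <- function(g) {
    a <- length(unique(g))
    ss_t <- sum(D2[upper.tri(D2)]) / n
    ss_w <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      sub <- D2[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_of(groups)
  levs <- unique(groups)
  counts <- table(factor(groups, levels = levs))
  all_f <- c()
  # enumerate index subsets for the first group (two-group case only)
  stopifnot(length(levs) == 2L)
  combos <- utils::combn(n, counts[[1L]])
  for (ci in seq_len(ncol(combos))) {
    g <- rep(levs[2L], n)
    g[combos[, ci]] <- levs[1L]
    all_f <- c(all_f, f_of(g))
  }
  list(F = f_obs, p = mean(all_f >= f_obs - 1e-12))
}
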