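# Synthetic nanopore-style signal generator with motif-driven 6mA ground
# truth. The generator is first-class, tested code: its defaults define the
# study conditions every downstream contract is exercised under.

#' Build a random 6-mer pore model
#'
#' Expected current levels are drawn uniformly in \[60, 120\] pA-like units,
#' event spreads uniformly in \[1.5, 3.0\], and for every adenine offset of
#' every 6-mer a 6mA-induced level shift with magnitude in
#' \[`shift_min`, `shift_scale`\] and random sign. All draws come from one
#' seeded stream, so a seed fully determines the model.
#'
#' @param seed integer seed.
#' @param shift_scale maximum |shift| (default 8).
#' @param shift_min detectability floor for |shift| (default 2, must be > 0).
#' @return object of class `pore_model`: `k = 6`, `kmers` (4096 strings in
#'   index order), `level`, `spread` (numeric 4096), `shift` (4096 x 6
#'   matrix; zero where the offset base is not A).
#' @export
build_pore_model <- function(seed, shift_scale = 8, shift_min = 2) {
  if (shift_min <= 0) stop("shift_min must be > 0", call. = FALSE)
  if (shift_scale < shift_min) stop("shift_scale must be >= shift_min", call. = FALSE)
  kmers <- all_kmers(6L)
  n <- length(kmers)
  a_at <- sapply(1:6, function(j) substr(kmers, j, j) == "A")
  with_seed(seed, {
    level <- runif(n, 60, 120)
    spread <- runif(n, 1.5, 3.0)
    mag <- matrix(runif(n * 6L, shift_min, shift_scale), n, 6L)
    sgn <- matrix(sample(c(-1, 1), n * 6L, replace = TRUE), n, 6L)
    shift <- mag * sgn
    shift[!a_at] <- 0
    structure(list(k = 6L, kmers = kmers, level = level, spread = spread,
                   shift = shift, shift_min = shift_min,
                   shift_scale = shift_scale, seed = as.integer(seed)),
              class = "pore_model")
  })
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("pore_model: 6-mers, levels [%.1f, %.1f], |6mA shift| in [%g, %g]\n",
              min(x$level), max(x$level), x$shift_min, x$shift_scale))
  invisible(x)
}

#' Simulate an i.i.d. random genome
#'
#' @param seed integer seed.
#' @param length genome length in bp (>= 1000).
#' @param gc target GC content in (0, 1).
#' @param contig_id contig name.
#' @return a [reference_genome()] with a single contig.
#' @export
simulate_genome <- function(seed, length = 1e5, gc = 0.5, contig_id = "sim_contig") {
  if (length < 1000) stop("genome length must be >= 1000", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed, {
    bases <- sample(DNA_BASES, length, replace = TRUE, prob = p)
    reference_genome(stats::setNames(paste(bases, collapse = ""), contig_id))
  })
}

#' Define a methylation scheme
#'
#' Per-motif Bernoulli methylation of focal adenines at a target ratio plus
#' an off-motif background rate (both strands).
#'
#' @param motifs list of [iupac_motif()] objects.
#' @param ratios numeric vector of per-motif target modification ratios in
#'   \[0, 1\].
#' @param background_rate off-motif per-adenine 6mA probability.
#' @return object of class `methylation_scheme`.
#' @export
methylation_scheme <- function(motifs, ratios, background_rate = 0) {
  if (inherits(motifs, "iupac_motif")) motifs <- list(motifs)
  stopifnot(length(motifs) == length(ratios))
  for (m in motifs) stopifnot(inherits(m, "iupac_motif"))
  if (any(ratios < 0 | ratios > 1) || background_rate < 0 || background_rate > 1) {
    stop("methylation ratios must lie in [0, 1]", call. = FALSE)
  }
  structure(list(motifs = motifs, ratios = as.numeric(ratios),
                 background_rate = background_rate),
            class = "methylation_scheme")
}

#' Assign ground-truth methylation states
#'
#' Every strand-resolved motif occurrence has its focal adenine methylated
#' independently with the motif's target ratio; a focal adenine shared by
#' several motif occurrences uses the maximum applicable ratio. All
#' remaining adenines (both strands) are methylated at the background rate.
#'
#' @param genome a [reference_genome()].
#' @param scheme a [methylation_scheme()].
#' @param seed integer seed.
#' @return data.table of methylated template positions: `contig`, `pos`
#'   (0-based), `strand`.
#' @export
assign_methylation_states <- function(genome, scheme, seed) {
  stopifnot(inherits(scheme, "methylation_scheme"))
  occ <- rbindlist(lapply(seq_along(scheme$motifs), function(i) {
    o <- scan_motif(genome, scheme$motifs[[i]])
    o[, ratio := scheme$ratios[i]]
    o[, .(contig, pos, strand, ratio)]
  }))
  if (nrow(occ)) {
    occ <- occ[, .(ratio = max(ratio)), by = .(contig, pos, strand)]
  } else {
    occ <- data.table(contig = character(), pos = integer(),
                      strand = character(), ratio = numeric())
  }
  with_seed(seed, {
    meth_occ <- occ[rbinom(.N, 1L, ratio) == 1L, .(contig, pos, strand)]
    bg <- NULL
    if (scheme$background_rate > 0) {
      all_a <- all_adenine_sites(genome)[, .(contig, pos, strand)]
      if (nrow(occ)) {
        all_a <- all_a[!occ, on = c("contig", "pos", "strand")]
      }
      bg <- all_a[rbinom(.N, 1L, scheme$background_rate) == 1L]
    }
    truth <- rbindlist(list(meth_occ, bg))
    setorder(truth, contig, pos, strand)
    truth[]
  })
}

#' Construct a simulated read
#'
#' Low-level container; validated so that `length(samples) == sum(dwells)`
#' and `length(dwells) == nchar(sequence)`.
#'
#' @param read_id read identifier.
#' @param contig,start,end 0-based half-open reference placement.
#' @param strand `"+"` or `"-"`.
#' @param sequence molecule-strand sequence (reverse complement of the
#'   reference span for minus-strand reads).
#' @param dwells integer samples per base (all >= 1), molecule order.
#' @param samples numeric raw samples, molecule order.
#' @param truth_local 0-based molecule positions of methylated adenines.
#' @return object of class `simulated_read`.
#' @export
simulated_read <- function(read_id, contig, start, end, strand, sequence,
                           dwells, samples, truth_local = integer(0)) {
  if (length(dwells) != nchar(sequence)) {
    stop("need one dwell per base", call. = FALSE)
  }
  if (any(dwells < 1L)) stop("dwells must be >= 1 sample", call. = FALSE)
  if (length(samples) != sum(dwells)) {
    stop("sample count (", length(samples), ") != sum of dwells (",
         sum(dwells), ")", call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("read strand must be '+' or '-'", call. = FALSE)
  structure(list(read_id = read_id, contig = contig, start = as.integer(start),
                 end = as.integer(end), strand = strand, sequence = sequence,
                 dwells = as.integer(dwells), samples = as.numeric(samples),
                 truth_local = as.integer(truth_local)),
            class = "simulated_read")
}

#' @export
print.simulated_read <- function(x, ...) {
  cat(sprintf("simulated_read %s: %s:%d-%d(%s), %d bases, %d samples\n",
              x$read_id, x$contig, x$start, x$end, x$strand,
              nchar(x$sequence), length(x$samples)))
  invisible(x)
}

# Per-base 6-mer context of a placement, on the molecule strand. The 6-mer
# window places the current base at offset 3 (0-based window start = i - 2),
# clamped near the ends of the extended context. Returns the per-base k-mer
# index, the extended-sequence codes and bookkeeping offsets.
molecule_context <- function(genome, contig, start, end, strand, flank = 5L) {
  L <- genome$lengths[[contig]]
  if (start < 0L || end > L || end <= start) {
    stop("placement outside contig bounds: ", contig, ":", start, "-", end,
         call. = FALSE)
  }
  ext_start <- max(0L, start - flank)
  ext_end <- min(L, end + flank)
  ext <- substr(genome$contigs[[contig]], ext_start + 1L, ext_end)
  if (strand == "-") ext <- revcomp(ext)
  off <- if (strand == "+") start - ext_start else ext_end - end
  m <- end - start
  codes <- dna_codes(ext)
  kidx_all <- kmer_indices(codes, 6L) # index by window start (1-based)
  nw <- length(kidx_all)
  wstart <- pmin(pmax(off + seq_len(m) - 1L - 2L, 0L), nw - 1L) # 0-based window starts
  list(kidx = kidx_all[wstart + 1L], wstart = wstart, codes = codes,
       off = off, ext_start = ext_start, ext_end = ext_end, m = m, ext = ext)
}

# Methylation flags over the extended molecule coordinate system of
# molecule_context(), from genome-coordinate truth on the template strand.
ext_meth_flags <- function(ctx, truth, contig_id, read_strand) {
  flags <- logical(length(ctx$codes))
  if (is.null(truth) || nrow(truth) == 0L) return(flags)
  sel <- truth$contig == contig_id & truth$strand == read_strand &
    truth$pos >= ctx$ext_start & truth$pos < ctx$ext_end
  pos <- truth$pos[sel]
  if (length(pos) == 0L) return(flags)
  epos <- if (read_strand == "+") pos - ctx$ext_start else ctx$ext_end - 1L - pos
  flags[epos + 1L] <- TRUE
  flags
}

#' Simulate one nanopore-style read
#'
#' For each molecule base the 6-mer pore context determines the expected
#' level; every methylated adenine inside the context window adds its
#' 6mA shift (additively when several overlap). Dwell times are
#' `1 + Geometric(1 / dwell_mean)` samples and raw samples are Gaussian
#' around the (possibly shifted) level. Minus-strand reads emit the
#' reverse-complement sequence with signal in molecule order; truth labels
#' stay in template coordinates.
#'
#' @param genome a [reference_genome()].
#' @param truth methylated-position table from [assign_methylation_states()]
#'   (or `NULL` for a fully unmethylated molecule).
#' @param pore_model a [build_pore_model()] model.
#' @param contig,start,end,strand reference placement (0-based half-open).
#' @param noise_sd Gaussian sample noise (default 0.5).
#' @param dwell_mean mean samples per base (default 9).
#' @param seed integer seed.
#' @param read_id read identifier.
#' @return a [simulated_read()].
#' @export
simulate_read <- function(genome, truth, pore_model, contig, start, end,
                          strand = "+", noise_sd = 0.5, dwell_mean = 9,
                          seed = 1L, read_id = "read_1") {
  stopifnot(inherits(pore_model, "pore_model"))
  ctx <- molecule_context(genome, contig, start, end, strand)
  kidx <- ctx$kidx
  level <- pore_model$level[kidx]
  level[is.na(level)] <- mean(pore_model$level) # ambiguous context fallback
  flags <- ext_meth_flags(ctx, truth, contig, strand)
  shift <- numeric(ctx$m)
  for (d in 0:5) {
    f <- flags[ctx$wstart + d + 1L]
    f[is.na(f)] <- FALSE
    sh <- pore_model$shift[cbind(kidx, d + 1L)]
    sh[is.na(sh)] <- 0
    shift <- shift + ifelse(f, sh, 0)
  }
  mol_codes <- ctx$codes[ctx$off + seq_len(ctx$m)]
  mol_meth <- which(flags[ctx$off + seq_len(ctx$m)]) - 1L
  with_seed(seed, {
    dwells <- rgeom(ctx$m, prob = 1 / dwell_mean) + 1L
    mu <- rep(level + shift, dwells)
    samples <- rnorm(length(mu), mean = mu, sd = noise_sd)
    sequence <- paste(c(DNA_BASES, "N")[ifelse(is.na(mol_codes), 5L,
                                               mol_codes + 1L)], collapse = "")
    simulated_read(read_id = read_id, contig = contig, start = start, end = end,
                   strand = strand, sequence = sequence, dwells = dwells,
                   samples = samples, truth_local = mol_meth)
  })
}

#' Simulation configuration
#'
#' Bundles every tunable of [simulate_dataset()]. Defaults are the toolkit's
#' reference study conditions.
#'
#' @param seed mandatory integer seed.
#' @param genome optional [reference_genome()]; simulated when `NULL`.
#' @param genome_length,gc genome simulation parameters.
#' @param coverage_mean target mean read depth.
#' @param read_length_mean,read_length_sd read length distribution (bp).
#' @param noise_sd Gaussian sample noise.
#' @param dwell_mean mean samples per base.
#' @param shift_scale,shift_min pore-model 6mA shift range.
#' @param prophage optional `list(fraction=, depletion_factor=)`: rewrite a
#'   central sub-interval with motif occurrences thinned before state
#'   assignment (depletion_factor > 1).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed, genome = NULL, genome_length = 1e5, gc = 0.45,
                       coverage_mean = 20, read_length_mean = 1000,
                       read_length_sd = 200, noise_sd = 0.5, dwell_mean = 9,
                       shift_scale = 8, shift_min = 2, prophage = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (coverage_mean <= 0) stop("coverage_mean must be > 0", call. = FALSE)
  if (dwell_mean < 1) stop("dwell_mean must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(prophage)) {
    stopifnot(is.list(prophage), prophage$depletion_factor > 1,
              prophage$fraction > 0, prophage$fraction < 1)
  }
  structure(list(seed = as.integer(seed), genome = genome,
                 genome_length = genome_length, gc = gc,
                 coverage_mean = coverage_mean,
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd, noise_sd = noise_sd,
                 dwell_mean = dwell_mean, shift_scale = shift_scale,
                 shift_min = shift_min, prophage = prophage),
            class = "sim_config")
}

#' Thin motif occurrences inside an interval
#'
#' Rewrites a genomic interval so that each occurrence of the given motifs
#' survives with probability `1 / depletion_factor`; removed occurrences are
#' broken by mutating one non-focal motif position to a base the motif does
#' not admit. Used to emulate phage motif depletion.
#'
#' @param genome a [reference_genome()].
#' @param interval list/row with `contig`, `start`, `end` (0-based half-open).
#' @param motifs list of [iupac_motif()].
#' @param depletion_factor target occurrence thinning factor (> 1).
#' @param seed integer seed.
#' @return a new [reference_genome()] with the interval rewritten.
#' @export
thin_motif_occurrences <- function(genome, interval, motifs, depletion_factor,
                                   seed) {
  stopifnot(depletion_factor > 1)
  if (inherits(motifs, "iupac_motif")) motifs <- list(motifs)
  contigs <- genome$contigs
  seq_chars <- strsplit(contigs[[interval$contig]], "", fixed = TRUE)[[1L]]
  with_seed(seed, {
    for (m in motifs) {
      occ <- scan_motif(genome, m)
      occ <- occ[contig == interval$contig & match_start >= interval$start &
                   match_end <= interval$end]
      if (nrow(occ) == 0L) next
      # palindromic motifs occur on both strands over one span; thin spans,
      # not strand-resolved occurrences, so the realised thinning matches
      # depletion_factor
      occ <- unique(occ, by = c("contig", "match_start", "match_end"))
      kill <- occ[runif(.N) > 1 / depletion_factor]
      if (nrow(kill) == 0L) next
      pat <- strsplit(m$pattern, "", fixed = TRUE)[[1L]]
      # candidate non-focal offsets with a forbidden replacement available
      cand_off <- setdiff(seq_along(pat), m$focal)
      cand_off <- cand_off[vapply(cand_off, function(j) {
        length(setdiff(DNA_BASES, IUPAC_SETS[[pat[j]]])) > 0L
      }, logical(1L))]
      if (length(cand_off) == 0L) next # motif of all-N positions: cannot break
      for (r in seq_len(nrow(kill))) {
        j <- if (length(cand_off) == 1L) cand_off else sample(cand_off, 1L)
        gpos <- if (kill$strand[r] == "+") kill$match_start[r] + (j - 1L)
                else kill$match_end[r] - j
        admit <- IUPAC_SETS[[pat[j]]]
        if (kill$strand[r] == "-") {
          admit <- chartr("ACGT", "TGCA", admit)
        }
        repl <- setdiff(DNA_BASES, admit)
        seq_chars[gpos + 1L] <- if (length(repl) == 1L) repl else sample(repl, 1L)
      }
      # refresh the working genome so later motifs see the edits
      contigs[[interval$contig]] <- paste(seq_chars, collapse = "")
      genome <- reference_genome(contigs)
    }
    genome
  })
}

#' Simulate a full single-sample dataset
#'
#' Places reads uniformly over the genome on both strands, with the number
#' of reads chosen so mean depth approximates `coverage_mean`. In prophage
#' mode the configured sub-interval is motif-thinned before methylation
#' states are assigned.
#'
#' @param config a [sim_config()].
#' @param scheme a [methylation_scheme()].
#' @param out_dir optional directory: when given, the signal archive and
#'   `truth.bed` are written there.
#' @param pore_model optional existing [build_pore_model()] model, e.g. to
#'   share one pore chemistry between a training control and a study sample;
#'   built from the config seed when `NULL`.
#' @return list of class `sim_dataset`: `genome`, `pore_model`, `scheme`,
#'   `truth`, `reads` (list of [simulated_read()]), `prophage_interval`
#'   (or `NULL`), `config`.
#' @export
simulate_dataset <- function(config, scheme, out_dir = NULL, pore_model = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(scheme, "methylation_scheme"))
  if (is.null(pore_model)) {
    pore_model <- build_pore_model(derive_seed(config$seed, 101L),
                                   shift_scale = config$shift_scale,
                                   shift_min = config$shift_min)
  }
  stopifnot(inherits(pore_model, "pore_model"))
  genome <- config$genome
  if (is.null(genome)) {
    genome <- simulate_genome(derive_seed(config$seed, 202L),
                              length = config$genome_length, gc = config$gc)
  }
  prophage_interval <- NULL
  if (!is.null(config$prophage)) {
    id <- names(genome$contigs)[1L]
    L <- genome$lengths[[id]]
    span <- round(L * config$prophage$fraction)
    s <- as.integer((L - span) %/% 2L)
    prophage_interval <- list(contig = id, start = s, end = as.integer(s + span))
    genome <- thin_motif_occurrences(genome, prophage_interval, scheme$motifs,
                                     config$prophage$depletion_factor,
                                     derive_seed(config$seed, 303L))
  }
  truth <- assign_methylation_states(genome, scheme, derive_seed(config$seed, 404L))
  id <- names(genome$contigs)[1L]
  L <- genome$lengths[[id]]
  n_reads <- max(1L, as.integer(round(config$coverage_mean * L /
                                        config$read_length_mean)))
  placements <- with_seed(derive_seed(config$seed, 505L), {
    len <- pmax(50L, pmin(L, as.integer(round(
      rnorm(n_reads, config$read_length_mean, config$read_length_sd)))))
    start <- vapply(L - len, function(mx) as.integer(floor(runif(1, 0, mx + 1))),
                    integer(1L))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    data.table(start = start, end = start + len, strand = strand)
  })
  reads <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    reads[[i]] <- simulate_read(
      genome, truth, pore_model, contig = id,
      start = placements$start[i], end = placements$end[i],
      strand = placements$strand[i], noise_sd = config$noise_sd,
      dwell_mean = config$dwell_mean, seed = derive_seed(config$seed, 1000L + i),
      read_id = sprintf("read_%06d", i)
    )
  }
  out <- structure(list(genome = genome, pore_model = pore_model, scheme = scheme,
                        truth = truth, reads = reads,
                        prophage_interval = prophage_interval, config = config),
                   class = "sim_dataset")
  if (!is.null(out_dir)) {
    write_signal_archive(reads, out_dir, truth = truth)
    write_fasta(genome, file.path(out_dir, "reference.fasta"))
  }
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d bp genome, %d reads, %d methylated positions\n",
              genome_length(x$genome), length(x$reads), nrow(x$truth)))
  invisible(x)
}

#' Simulate a cohort of per-individual methylation-usage profiles
#'
#' Cohort mode of the generator: every individual receives one perturbation
#' of the methylation scheme — a Dirichlet jitter of the per-motif site
#' weights — that is held fixed across that individual's timepoints, so
#' between-individual differences dominate within-individual sampling noise.
#' Each (individual, timepoint) sample then draws its methylated sites from
#' the genome's motif occurrences according to the individual's weights.
#'
#' @param genome a [reference_genome()].
#' @param scheme a [methylation_scheme()] giving the cohort-average motif
#'   ratios.
#' @param n_individuals,n_timepoints cohort dimensions.
#' @param concentration Dirichlet concentration of the per-individual jitter
#'   (smaller = stronger individuality; default 50).
#' @param seed integer seed.
#' @return list: `usage` (samples x 1024 matrix of 5-mer usage), `meta`
#'   (data.table `sample_id`, `individual`, `timepoint`), `truth` (list of
#'   per-sample methylated-site tables), `individual_weights`.
#' @export
simulate_cohort_usage <- function(genome, scheme, n_individuals = 5L,
                                  n_timepoints = 3L, concentration = 50,
                                  seed = 1L) {
  stopifnot(n_individuals >= 2L, n_timepoints >= 1L)
  occ_by_motif <- lapply(scheme$motifs, function(m) scan_motif(genome, m))
  n_occ <- vapply(occ_by_motif, nrow, integer(1L))
  if (any(n_occ == 0L)) stop("a scheme motif has no occurrence in the genome",
                             call. = FALSE)
  base_w <- scheme$ratios * n_occ
  base_w <- base_w / sum(base_w)
  n_sites <- as.integer(round(sum(scheme$ratios * n_occ)))
  with_seed(seed, {
    weights <- t(vapply(seq_len(n_individuals), function(i) {
      g <- rgamma(length(base_w), shape = concentration * base_w, rate = 1)
      if (sum(g) == 0) g <- base_w
      g / sum(g)
    }, numeric(length(base_w))))
    meta <- data.table(
      sample_id = sprintf("ind%02d_t%02d", rep(seq_len(n_individuals),
                                               each = n_timepoints),
                          rep(seq_len(n_timepoints), n_individuals)),
      individual = sprintf("ind%02d", rep(seq_len(n_individuals),
                                          each = n_timepoints)),
      timepoint = rep(seq_len(n_timepoints), n_individuals)
    )
    truth_list <- vector("list", nrow(meta))
    usage <- matrix(0, nrow(meta), 4^5,
                    dimnames = list(meta$sample_id, all_kmers(5L)))
    for (s in seq_len(nrow(meta))) {
      ind <- rep(seq_len(n_individuals), each = n_timepoints)[s]
      counts <- as.integer(rmultinom(1L, n_sites, weights[ind, ]))
      picked <- rbindlist(lapply(seq_along(counts), function(mi) {
        o <- occ_by_motif[[mi]]
        take <- min(counts[mi], nrow(o))
        if (take == 0L) return(NULL)
        o[sample(.N, take), .(contig, pos, strand)]
      }))
      picked <- unique(picked)
      truth_list[[s]] <- picked
      st <- site_records(picked[, .(contig, pos, strand, n_total = 1L, n_meth = 1L)])
      usage[s, ] <- suppressWarnings(kmer_usage_vector(st, genome, k = 5L))
    }
    list(usage = usage, meta = meta, truth = truth_list,
         individual_weights = weights)
  })
}
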