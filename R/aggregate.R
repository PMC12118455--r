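# Collapse per-read calls to per-site frequencies, genome eligibility
# filters (depth/breadth), and methylome density summaries.

#' Aggregate per-read calls into per-site records
#'
#' One record per strand-resolved genomic position with at least one
#' covering call: `n_total` covering reads, `n_meth` positive binary calls,
#' `frequency = n_meth / n_total`.
#'
#' @param calls data.table from [predict_read_sites()] (columns `contig`,
#'   `pos`, `strand`, `call`).
#' @return a [site_records()] table.
#' @export
aggregate_site_calls <- function(calls) {
  ct <- as.data.table(calls)
  if (nrow(ct) == 0L) {
    return(site_records(data.table(contig = character(), pos = integer(),
                                   strand = character(), n_total = integer(),
                                   n_meth = integer())))
  }
  agg <- ct[, .(n_total = .N, n_meth = sum(call)), by = .(contig, pos, strand)]
  setorder(agg, contig, pos, strand)
  site_records(agg)
}

#' Depth and breadth of coverage from read placements
#'
#' Depth is computed per genome position from read reference spans (not
#' per-adenine calls); mean depth averages over every position of every
#' contig, and breadth is the fraction of positions covered by at least one
#' read.
#'
#' @param reads list of `simulated_read` objects, or a data.frame with
#'   `contig`, `start`, `end`.
#' @param genome a [reference_genome()].
#' @return list: `mean_depth`, `breadth`, `depth` (per-contig integer list).
#' @export
coverage_stats <- function(reads, genome) {
  if (is.list(reads) && length(reads) && inherits(reads[[1L]], "simulated_read")) {
    reads <- rbindlist(lapply(reads, function(r) {
      data.table(contig = r$contig, start = r$start, end = r$end)
    }))
  }
  rt <- as.data.table(reads)
  depth <- lapply(names(genome$contigs), function(id) {
    L <- genome$lengths[[id]]
    d <- numeric(L + 1L)
    sub <- rt[if (nrow(rt)) contig == id else FALSE]
    if (nrow(sub)) {
      starts <- tabulate(sub$start + 1L, nbins = L)
      ends <- tabulate(pmin(sub$end, L) + 1L, nbins = L + 1L)
      d <- cumsum(starts - ends[seq_len(L)])
    } else {
      d <- numeric(L)
    }
    d
  })
  names(depth) <- names(genome$contigs)
  all_d <- unlist(depth, use.names = FALSE)
  list(mean_depth = if (length(all_d)) mean(all_d) else 0,
       breadth = if (length(all_d)) mean(all_d >= 1) else 0,
       depth = depth)
}

#' Filter genomes by coverage eligibility
#'
#' A genome is eligible for 6mA profiling iff `mean_depth >= min_depth`
#' **and** `breadth >= min_breadth`; both thresholds are inclusive, reading
#' "10x depth" and "80% breadth" as minima. Exclusions are logged with both
#' values.
#'
#' @param methylomes data.frame with columns `genome_id`, `mean_depth`,
#'   `breadth` (e.g. rows of [methylome_density()] summaries).
#' @param min_depth minimum mean depth (default 10).
#' @param min_breadth minimum breadth (default 0.8).
#' @return the input with a logical `pass` column; attribute `"excluded"`
#'   holds the failing rows.
#' @export
filter_genomes <- function(methylomes, min_depth = 10, min_breadth = 0.8) {
  mt <- as.data.table(methylomes)
  mt[, pass := mean_depth >= min_depth & breadth >= min_breadth]
  excluded <- mt[pass == FALSE]
  for (i in seq_len(nrow(excluded))) {
    info_log("genome %s excluded: mean depth %.2f (need >= %g), breadth %.3f (need >= %g)",
             excluded$genome_id[i], excluded$mean_depth[i], min_depth,
             excluded$breadth[i], min_breadth)
  }
  data.table::setattr(mt, "excluded", excluded)
  mt[]
}

#' Per-genome methylome density summary
#'
#' A position is a called 6mA site iff `n_total >= site_min_depth` and
#' `frequency >= site_freq_min` (both tunable; the site rule is this
#' toolkit's operational definition). Densities are reported per genome and
#' per megabase.
#'
#' @param sites a [site_records()] table of aggregated calls.
#' @param genome a [reference_genome()].
#' @param genome_id identifier for the summary row.
#' @param reads optional read placements for depth/breadth (see
#'   [coverage_stats()]).
#' @param site_min_depth minimum covering reads per called site (default 5).
#' @param site_freq_min minimum methylated fraction per called site
#'   (default 0.5).
#' @return list of class `genome_methylome`: `genome_id`, `sites` (called
#'   subset), `n_sites_called`, `sites_per_mb`, `mean_depth`, `breadth`,
#'   `genome_bp`, `summary` (one-row data.table).
#' @export
methylome_density <- function(sites, genome, genome_id = "genome", reads = NULL,
                              site_min_depth = 5L, site_freq_min = 0.5) {
  L <- genome_length(genome)
  if (L == 0L) stop("zero-length genome", call. = FALSE)
  st <- as.data.table(sites)
  called <- st[n_total >= site_min_depth & frequency >= site_freq_min]
  info_log("%s: %d/%d aggregated positions pass the site rule (depth >= %d, freq >= %g)",
           genome_id, nrow(called), nrow(st), site_min_depth, site_freq_min)
  cov <- if (!is.null(reads)) coverage_stats(reads, genome) else
    list(mean_depth = NA_real_, breadth = NA_real_)
  n_called <- nrow(called)
  res <- list(genome_id = genome_id, sites = called,
              n_sites_called = n_called,
              sites_per_mb = n_called / (L / 1e6),
              mean_depth = cov$mean_depth, breadth = cov$breadth,
              genome_bp = L)
  res$summary <- data.table(genome_id = genome_id, genome_bp = L,
                            mean_depth = cov$mean_depth, breadth = cov$breadth,
                            n_sites = n_called,
                            sites_per_mb = res$sites_per_mb)
  structure(res, class = "genome_methylome")
}

#' @export
print.genome_methylome <- function(x, ...) {
  cat(sprintf("genome_methylome %s: %d called 6mA sites (%.0f per Mb) over %d bp\n",
              x$genome_id, x$n_sites_called, x$sites_per_mb, x$genome_bp))
  invisible(x)
}
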