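# Genomic-context analyses: prophage motif depletion, CDS vs non-CDS 6mA
# density, and methylation-expression coupling.

#' Motif frequency per kilobase
#'
#' Strand-pooled motif occurrence count divided by sequence length in kb.
#'
#' @param genome a [reference_genome()] (or a bare sequence string).
#' @param motif an [iupac_motif()].
#' @param interval optional list/row (`contig`, `start`, `end`) restricting
#'   the count to a sub-interval.
#' @return occurrences per kb.
#' @export
motif_freq_per_kb <- function(genome, motif, interval = NULL) {
  if (is.character(genome)) {
    genome <- reference_genome(c(seq1 = genome))
  }
  if (is.null(interval)) {
    len <- genome_length(genome)
    occ <- scan_motif(genome, motif)
    count <- nrow(occ)
  } else {
    len <- interval$end - interval$start
    if (len < nchar(motif$pattern)) {
      stop("interval shorter than the motif", call. = FALSE)
    }
    occ <- scan_motif(genome, motif)
    count <- nrow(occ[contig == interval$contig & match_start >= interval$start &
                        match_end <= interval$end])
  }
  if (len < nchar(motif$pattern)) stop("sequence shorter than the motif", call. = FALSE)
  count / (len / 1000)
}

#' Phage-versus-host motif depletion test
#'
#' One-sided paired t-test (phage < host) on per-pair motif frequencies per
#' kb, plus per-pair depletion ratios (phage/host). Pairs with zero host
#' frequency are excluded from the ratio summary (logged) but retained in
#' the t-test.
#'
#' @param pairs data.frame with columns `host_freq_per_kb`,
#'   `phage_freq_per_kb` (one row per phage-host pair; >= 3 rows).
#' @return list of class `depletion_result`: `t_test`
#'   (`paired_t_result`), `mean_host`, `mean_phage`, `ratios`,
#'   `median_ratio`, `n_pairs`.
#' @export
depletion_test <- function(pairs) {
  pt_ <- as.data.table(pairs)
  req <- c("host_freq_per_kb", "phage_freq_per_kb")
  if (!all(req %in% names(pt_))) {
    stop("pairs need columns host_freq_per_kb and phage_freq_per_kb", call. = FALSE)
  }
  pt_ <- pt_[complete.cases(pt_[, req, with = FALSE])]
  if (nrow(pt_) < 3L) stop("need at least 3 usable phage-host pairs", call. = FALSE)
  tt <- paired_t_test(pt_$phage_freq_per_kb, pt_$host_freq_per_kb,
                      alternative = "less")
  zero_host <- pt_$host_freq_per_kb == 0
  if (any(zero_host)) {
    info_log("%d pair(s) with zero host motif frequency excluded from ratios",
             sum(zero_host))
  }
  ratios <- pt_$phage_freq_per_kb[!zero_host] / pt_$host_freq_per_kb[!zero_host]
  structure(list(t_test = tt, mean_host = mean(pt_$host_freq_per_kb),
                 mean_phage = mean(pt_$phage_freq_per_kb), ratios = ratios,
                 median_ratio = if (length(ratios)) stats::median(ratios) else NA_real_,
                 n_pairs = nrow(pt_)),
            class = "depletion_result")
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(sprintf(paste0("depletion_result: %d pairs, host %.2f vs phage %.2f motifs/kb, ",
                     "median phage/host ratio %.3f, one-sided paired t p = %.4g\n"),
              x$n_pairs, x$mean_host, x$mean_phage, x$median_ratio,
              x$t_test$p_value))
  invisible(x)
}

# Merge possibly-overlapping intervals into a disjoint union; returns a
# data.table(contig, start, end) sorted by position.
merge_intervals <- function(intervals) {
  it <- as.data.table(intervals)[, .(contig, start, end)]
  setorder(it, contig, start, end)
  out <- list()
  for (id in unique(it$contig)) {
    sub <- it[contig == id]
    s <- sub$start[1L]; e <- sub$end[1L]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$start[i] <= e) {
        e <- max(e, sub$end[i])
      } else {
        out[[length(out) + 1L]] <- data.table(contig = id, start = s, end = e)
        s <- sub$start[i]; e <- sub$end[i]
      }
    }
    out[[length(out) + 1L]] <- data.table(contig = id, start = s, end = e)
  }
  rbindlist(out)
}

# TRUE for each site position falling inside the interval union.
sites_in_union <- function(sites, union_) {
  st <- as.data.table(sites)
  inside <- logical(nrow(st))
  for (i in seq_len(nrow(union_))) {
    inside <- inside | (st$contig == union_$contig[i] &
                          st$pos >= union_$start[i] & st$pos < union_$end[i])
  }
  inside
}

#' CDS versus non-CDS 6mA site density
#'
#' Overlapping CDS intervals are merged into a union before density
#' computation; every called site (either strand) is assigned to exactly one
#' of CDS / non-CDS by position. Densities are sites per kb of the
#' respective territory.
#'
#' @param sites called 6mA sites ([site_records()]).
#' @param annotations an [annotation_set()] with CDS features.
#' @param genome a [reference_genome()].
#' @return list of class `cds_density`: `cds_density`, `noncds_density`
#'   (sites per kb), `cds_kb`, `noncds_kb`, `n_cds_sites`, `n_noncds_sites`.
#' @export
cds_vs_noncds_density <- function(sites, annotations, genome) {
  cds <- as.data.table(annotations)[type == "CDS"]
  if (nrow(cds) == 0L) stop("no CDS annotations", call. = FALSE)
  union_ <- merge_intervals(cds)
  cds_bp <- sum(union_$end - union_$start)
  total_bp <- genome_length(genome)
  if (cds_bp >= total_bp) stop("CDS union covers the whole genome: no non-CDS territory",
                               call. = FALSE)
  st <- as.data.table(sites)
  inside <- sites_in_union(st, union_)
  n_cds <- sum(inside)
  n_non <- sum(!inside)
  structure(list(cds_density = n_cds / (cds_bp / 1000),
                 noncds_density = n_non / ((total_bp - cds_bp) / 1000),
                 cds_kb = cds_bp / 1000, noncds_kb = (total_bp - cds_bp) / 1000,
                 n_cds_sites = n_cds, n_noncds_sites = n_non),
            class = "cds_density")
}

#' Paired CDS-enrichment test across genomes
#'
#' One-sided paired t-test (CDS > non-CDS) over per-genome density pairs.
#'
#' @param densities list of `cds_density` objects (>= 3 genomes).
#' @return list: `t_test` (`paired_t_result`), `table` (per-genome
#'   densities).
#' @export
cds_enrichment_test <- function(densities) {
  if (length(densities) < 3L) stop("need >= 3 genomes for the paired test",
                                   call. = FALSE)
  tab <- data.table(
    cds_density = vapply(densities, `[[`, numeric(1L), "cds_density"),
    noncds_density = vapply(densities, `[[`, numeric(1L), "noncds_density")
  )
  tt <- paired_t_test(tab$cds_density, tab$noncds_density, alternative = "greater")
  list(t_test = tt, table = tab)
}

#' Per-gene CDS methylation table
#'
#' Counts called 6mA sites (either strand) inside each gene's CDS intervals
#' and converts to a density per kb; expression values are joined from an
#' input table taken as already normalized.
#'
#' @param sites called 6mA sites ([site_records()]).
#' @param annotations an [annotation_set()] with CDS features carrying
#'   `gene_id`.
#' @param genome a [reference_genome()].
#' @param expression optional data.frame (`gene_id`, `expression`).
#' @return data.table: `gene_id`, `cds_length`, `n_6mA_in_cds`, `density`
#'   (sites per kb), `expression` (NA when unavailable).
#' @export
gene_methylation <- function(sites, annotations, genome, expression = NULL) {
  cds <- as.data.table(annotations)[type == "CDS"]
  if (nrow(cds) == 0L) stop("no CDS annotations", call. = FALSE)
  if (!"gene_id" %in% names(cds) || anyNA(cds$gene_id)) {
    stop("CDS annotations need a gene_id", call. = FALSE)
  }
  st <- as.data.table(sites)
  rows <- cds[, {
    n_hit <- if (nrow(st)) sum(st$contig == contig[1L] & st$pos >= start[1L] &
                                 st$pos < end[1L]) else 0L
    .(cds_length = end[1L] - start[1L], n_6mA_in_cds = n_hit)
  }, by = .(gene_id, contig, start, end)]
  out <- rows[, .(cds_length = sum(cds_length), n_6mA_in_cds = sum(n_6mA_in_cds)),
              by = gene_id]
  out[, density := 1000 * n_6mA_in_cds / cds_length]
  if (!is.null(expression)) {
    ex <- as.data.table(expression)[, .(gene_id, expression)]
    out <- merge(out, ex, by = "gene_id", all.x = TRUE)
  } else {
    out[, expression := NA_real_]
  }
  out[]
}

#' Methylation-density versus expression correlation
#'
#' Correlates per-gene CDS 6mA density with normalized expression. Genes
#' with missing expression are dropped (logged); at least 10 usable genes
#' are required.
#'
#' @param gene_meth table from [gene_methylation()] with `density` and
#'   `expression` columns.
#' @param method `"pearson"` or `"spearman"`.
#' @return list of class `expression_correlation`: `correlation`
#'   (`correlation_result`), `n_genes`, `table`.
#' @export
expression_correlation <- function(gene_meth, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  gm <- as.data.table(gene_meth)
  usable <- gm[!is.na(expression) & !is.na(density)]
  dropped <- nrow(gm) - nrow(usable)
  if (dropped > 0L) info_log("%d gene(s) without expression dropped", dropped)
  if (nrow(usable) < 10L) {
    stop("need >= 10 genes with expression values; got ", nrow(usable),
         call. = FALSE)
  }
  ct <- correlation_test(usable$density, usable$expression, method = method)
  structure(list(correlation = ct, n_genes = nrow(usable), table = usable),
            class = "expression_correlation")
}

#' @export
print.expression_correlation <- function(x, ...) {
  cat(sprintf("expression_correlation: %s r = %.3f, p = %.4g over %d genes\n",
              x$correlation$method, x$correlation$r, x$correlation$p_value,
              x$n_genes))
  invisible(x)
}
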