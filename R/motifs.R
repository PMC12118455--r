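# IUPAC motif scanning, per-motif modification ratios, 5-mer methylation
# usage vectors, and an enumerative k-mer enrichment scan.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Define a degenerate (IUPAC) methylation motif
#'
#' @param pattern motif string over the 15 IUPAC nucleotide codes, length >= 4.
#' @param focal 1-based offset of the methylated adenine within the pattern.
#'   Defaults to the first literal `A`; degenerate motifs whose focal base is
#'   written as an ambiguity code (e.g. the leading `R` of `RAATTY`) must set
#'   it explicitly.
#' @return object of class `iupac_motif` with fields `pattern` and `focal`.
#' @examples
#' iupac_motif("GATC")          # focal A at offset 2
#' iupac_motif("RAATTY", 2)
#' @export
iupac_motif <- function(pattern, focal = NULL) {
  pattern <- toupper(pattern)
  letters_ <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (length(letters_) < 4L) stop("motif must be at least 4 bases long", call. = FALSE)
  if (!all(letters_ %in% names(IUPAC_SETS))) {
    stop("invalid IUPAC code in motif: ", pattern, call. = FALSE)
  }
  if (is.null(focal)) {
    focal <- which(letters_ == "A")[1L]
    if (is.na(focal)) {
      focal <- which(vapply(letters_, function(l) "A" %in% IUPAC_SETS[[l]], logical(1L)))[1L]
    }
    if (is.na(focal)) stop("motif has no position admitting A: ", pattern, call. = FALSE)
  }
  focal <- as.integer(focal)
  if (focal < 1L || focal > length(letters_)) {
    stop("focal offset outside motif", call. = FALSE)
  }
  if (!"A" %in% IUPAC_SETS[[letters_[focal]]]) {
    stop("focal position of ", pattern, " does not admit A", call. = FALSE)
  }
  structure(list(pattern = pattern, focal = focal), class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat("iupac_motif:", x$pattern, "(6mA at offset", x$focal, ")\n")
  invisible(x)
}

# Match an IUPAC pattern against one uppercase sequence string; returns
# 0-based match start positions. Matches whose genomic window contains N
# are dropped (degenerate contexts are uninformative).
match_iupac <- function(pattern, seq) {
  if (nchar(seq) < nchar(pattern)) return(integer(0))
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq), fixed = FALSE)
  starts <- Biostrings::start(hits) - 1L
  if (length(starts)) {
    win <- substring(seq, starts + 1L, starts + nchar(pattern))
    starts <- starts[!grepl("N", win, fixed = TRUE)]
  }
  starts
}

#' Scan a genome for a motif on both strands
#'
#' Plus-strand hits come from direct IUPAC matching; minus-strand hits from
#' matching the pattern on the reverse complement, with the focal adenine
#' mapped back to genome coordinates. Overlapping matches are all reported.
#'
#' @param genome a [reference_genome()].
#' @param motif an [iupac_motif()].
#' @return data.table with columns `contig`, `pos` (0-based genome position
#'   of the focal A), `strand`, `match_start`, `match_end` (0-based
#'   half-open span of the whole motif on the genome).
#' @export
scan_motif <- function(genome, motif) {
  stopifnot(inherits(genome, "reference_genome"), inherits(motif, "iupac_motif"))
  len <- nchar(motif$pattern)
  f0 <- motif$focal - 1L
  res <- vector("list", 2L * length(genome$contigs))
  k <- 0L
  for (id in names(genome$contigs)) {
    seq <- genome$contigs[[id]]
    L <- nchar(seq)
    plus <- match_iupac(motif$pattern, seq)
    k <- k + 1L
    res[[k]] <- data.table(contig = id, pos = plus + f0, strand = "+",
                           match_start = plus, match_end = plus + len)
    rc <- revcomp(seq)
    minus <- match_iupac(motif$pattern, rc)
    k <- k + 1L
    res[[k]] <- data.table(contig = id, pos = L - 1L - (minus + f0), strand = "-",
                           match_start = L - (minus + len), match_end = L - minus)
  }
  out <- rbindlist(res)
  setorder(out, contig, pos, strand)
  out[]
}

#' Per-motif modification ratio
#'
#' The denominator is the number of strand-resolved motif occurrences whose
#' focal adenine has read depth `>= site_min_depth`; the numerator counts
#' those whose focal adenine is a called 6mA site (depth and frequency
#' thresholds as in [methylome_density()]).
#'
#' @param sites a [site_records()] table of aggregated per-site calls.
#' @param genome a [reference_genome()].
#' @param motif an [iupac_motif()].
#' @param site_min_depth minimum reads at the focal A for it to count.
#' @param site_freq_min minimum methylated-read fraction for a called site.
#' @return list of class `motif_stats`: `motif`, `n_occurrences`,
#'   `n_modified`, `modification_ratio` (`NA` when no occurrence qualifies).
#' @export
modification_ratio <- function(sites, genome, motif, site_min_depth = 5L,
                               site_freq_min = 0.5) {
  occ <- scan_motif(genome, motif)
  st <- as.data.table(sites)
  hit <- merge(occ, st, by = c("contig", "pos", "strand"), all.x = TRUE)
  qual <- hit[!is.na(n_total) & n_total >= site_min_depth]
  n_occ <- nrow(qual)
  if (n_occ == 0L) {
    info_log("motif %s: no occurrence with depth >= %d; ratio undefined",
             motif$pattern, site_min_depth)
    ratio <- NA_real_
    n_mod <- 0L
  } else {
    n_mod <- qual[frequency >= site_freq_min, .N]
    ratio <- n_mod / n_occ
  }
  structure(list(motif = motif, n_occurrences = n_occ, n_modified = n_mod,
                 modification_ratio = ratio),
            class = "motif_stats")
}

#' @export
print.motif_stats <- function(x, ...) {
  cat(sprintf("motif %s: %d/%d occurrences modified (ratio %s)\n",
              x$motif$pattern, x$n_modified, x$n_occurrences,
              ifelse(is.na(x$modification_ratio), "NA",
                     sprintf("%.3f", x$modification_ratio))))
  invisible(x)
}

# Reference k-mer context centered on each site's focal A; minus-strand
# sites are reverse-complemented so the focal A is always central and read
# on its own strand. Contexts containing N, or truncated by contig edges,
# are NA.
site_contexts <- function(sites, genome, k = 5L) {
  st <- as.data.table(sites)
  if (nrow(st) == 0L) return(character(0))
  half <- (k - 1L) %/% 2L
  lens <- genome$lengths[st$contig]
  lo <- st$pos - half
  hi <- st$pos + (k - 1L - half)
  ok <- lo >= 0L & hi < lens
  ctx <- rep(NA_character_, nrow(st))
  if (any(ok)) {
    ctx[ok] <- substr(genome$contigs[st$contig[ok]], lo[ok] + 1L, hi[ok] + 1L)
  }
  minus <- ok & st$strand == "-"
  if (any(minus)) {
    ctx[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(ctx[minus]))
    )
  }
  ctx[grepl("N", ctx, fixed = TRUE)] <- NA_character_
  ctx
}

#' 5-mer methylation-usage vector
#'
#' The normalized distribution of reference k-mer contexts centered on
#' called 6mA sites. Minus-strand sites contribute their reverse-complement
#' context, so the focal adenine is always the central base. Contexts
#' containing `N` are excluded.
#'
#' @param sites called 6mA sites as [site_records()] (apply the site rule
#'   first, e.g. via [methylome_density()], or pass ground-truth sites).
#' @param genome a [reference_genome()].
#' @param k context width (odd; default 5, giving a 1024-long vector).
#' @return named numeric vector over all `4^k` k-mers summing to 1 (all-zero
#'   with a warning when no usable site exists).
#' @export
kmer_usage_vector <- function(sites, genome, k = 5L) {
  if (k %% 2L == 0L) stop("context width k must be odd", call. = FALSE)
  km <- all_kmers(k)
  out <- stats::setNames(numeric(length(km)), km)
  ctx <- site_contexts(sites, genome, k)
  ctx <- ctx[!is.na(ctx)]
  if (length(ctx) == 0L) {
    warning("no usable called sites; returning zero usage vector")
    return(out)
  }
  tab <- table(ctx)
  out[names(tab)] <- as.numeric(tab)
  out / sum(out)
}

#' Enumerative k-mer enrichment scan over called sites
#'
#' A deliberately simple stand-in for probabilistic motif discovery: for
#' every k-mer observed among site-centered contexts, a one-sided binomial
#' test compares its frequency among contexts against the genome-wide
#' background of adenine-centered k-mers, with Benjamini-Hochberg correction
#' across all tested k-mers.
#'
#' @param sites called 6mA sites as [site_records()].
#' @param genome a [reference_genome()].
#' @param k_range integer range of context widths to scan (odd values only;
#'   default `c(5, 7)`).
#' @param alpha q-value threshold used only to flag the `significant` column.
#' @return data.table ranked by q-value then enrichment: `kmer`, `k`,
#'   `count`, `n_sites`, `bg_prob`, `enrichment`, `p_value`, `q_value`,
#'   `significant`.
#' @export
discover_enriched_motifs <- function(sites, genome, k_range = c(5L, 7L),
                                     alpha = 0.05) {
  st <- as.data.table(sites)
  if (nrow(st) < 50L) {
    stop("need at least 50 called sites for enrichment scanning; got ",
         nrow(st), ". Lower the site thresholds or increase coverage.",
         call. = FALSE)
  }
  ks <- seq(k_range[1L], k_range[2L])
  ks <- ks[ks %% 2L == 1L]
  bg_sites <- all_adenine_sites(genome)
  rows <- list()
  for (k in ks) {
    ctx <- site_contexts(st, genome, k)
    ctx <- ctx[!is.na(ctx)]
    n <- length(ctx)
    if (n == 0L) next
    # background: contexts of every adenine on both strands
    bg <- site_contexts(bg_sites, genome, k)
    bg <- bg[!is.na(bg)]
    bg_tab <- table(bg)
    obs_tab <- table(ctx)
    kmers <- names(obs_tab)
    bg_p <- as.numeric(bg_tab[kmers]) / length(bg)
    bg_p[is.na(bg_p)] <- 0.5 / length(bg)
    x <- as.integer(obs_tab)
    p <- pbinom(x - 1L, n, bg_p, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.table(
      kmer = kmers, k = k, count = x, n_sites = n, bg_prob = bg_p,
      enrichment = (x / n) / bg_p, p_value = p
    )
  }
  out <- rbindlist(rows)
  out[, q_value := p.adjust(p_value, method = "BH")]
  out[, significant := q_value < alpha]
  setorder(out, q_value, -enrichment)
  out[]
}

# Every adenine position on both strands as a site table (used as the
# enrichment background and by the simulator).
all_adenine_sites <- function(genome) {
  res <- lapply(names(genome$contigs), function(id) {
    codes <- dna_codes(genome$contigs[[id]])
    plus <- which(codes == 0L) - 1L  # A on +
    minus <- which(codes == 3L) - 1L # T on +, i.e. A on -
    data.table(contig = id,
               pos = c(plus, minus),
               strand = rep(c("+", "-"), c(length(plus), length(minus))),
               n_total = 1L, n_meth = 1L)
  })
  site_records(rbindlist(res))
}
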