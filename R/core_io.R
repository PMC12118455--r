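# Readers and writers for every external format the toolkit touches:
# FASTA, GFF3 (CDS), BED3/BED6, 11-column bedMethyl, and the plain-text
# signal-archive layout used in place of FAST5/POD5.

#' Read a FASTA file into a reference genome
#'
#' Sequences are uppercased, `U` is mapped to `T` and any residual
#' non-`ACGTN` character is masked to `N`. Contig order is preserved.
#'
#' @param path FASTA file path.
#' @return a [reference_genome()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate contig id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  reference_genome(stats::setNames(as.character(set), ids))
}

#' Write a reference genome as FASTA
#' @param genome a [reference_genome()].
#' @param path output path.
#' @param width line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "reference_genome"))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(genome$contigs)) {
    writeLines(paste0(">", id), con)
    s <- genome$contigs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

parse_gff_attr <- function(attr, keys) {
  for (key in keys) {
    m <- regmatches(attr, regexpr(paste0("(^|;)\\s*", key, "=[^;]+"), attr))
    if (length(m) && nzchar(m)) return(sub(paste0("^.*", key, "="), "", m))
  }
  NA_character_
}

#' Read CDS features from a GFF3 file
#'
#' Keeps only `CDS` rows, converting GFF's 1-based closed coordinates to the
#' internal 0-based half-open convention. The gene identifier is taken from
#' the `ID` attribute, falling back to `Parent`.
#'
#' @param path GFF3 file path.
#' @param genome `reference_genome` the annotations must lie within.
#' @return an [annotation_set()] of CDS features with a `gene_id` column.
#' @export
read_gff_cds <- function(path, genome) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    warning("no features in GFF file: ", path)
    return(annotation_set(data.table(contig = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     type = character(), gene_id = character()),
                          genome))
  }
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(fields) < 9L) stop("malformed GFF3 (need 9 tab-separated columns): ",
                                path, call. = FALSE)
  gff <- data.table(
    contig = fields[[1L]], type = fields[[3L]],
    start1 = as.integer(fields[[4L]]), end1 = as.integer(fields[[5L]]),
    strand = fields[[7L]], attr = fields[[9L]]
  )
  cds <- gff[type == "CDS"]
  if (nrow(cds) == 0L) {
    warning("GFF file contains no CDS rows: ", path)
    return(annotation_set(data.table(contig = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     type = character(), gene_id = character()),
                          genome))
  }
  out <- data.table(
    contig = cds$contig,
    start = cds$start1 - 1L,   # GFF 1-based closed -> 0-based half-open
    end = cds$end1,
    strand = ifelse(cds$strand %in% c("+", "-"), cds$strand, "."),
    type = "CDS",
    gene_id = vapply(cds$attr, parse_gff_attr, character(1L),
                     keys = c("ID", "Parent"), USE.NAMES = FALSE)
  )
  bad <- !(out$contig %in% names(genome$lengths)) |
    out$end > genome$lengths[out$contig] | out$start < 0L
  if (any(bad)) {
    stop("CDS outside contig bounds at GFF row(s): ",
         paste(head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  annotation_set(out, genome)
}

#' Read a BED3+ file
#'
#' BED intervals are already 0-based half-open and are kept as such. A
#' fourth column, when present, is stored as the feature `name`; a sixth
#' column supplies the strand.
#'
#' @param path BED file path.
#' @param genome `reference_genome` for bounds validation.
#' @param feature_type label stored in the `type` column (e.g. `"prophage"`).
#' @return an [annotation_set()].
#' @export
read_bed <- function(path, genome, feature_type = "region") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bed <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(bed) == 0L) {
    return(annotation_set(data.table(contig = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     type = character(), name = character()),
                          genome))
  }
  if (ncol(bed) < 3L) stop("BED needs at least 3 columns: ", path, call. = FALSE)
  out <- data.table(
    contig = as.character(bed[[1L]]),
    start = as.integer(bed[[2L]]),
    end = as.integer(bed[[3L]]),
    strand = if (ncol(bed) >= 6L) as.character(bed[[6L]]) else ".",
    type = feature_type,
    name = if (ncol(bed) >= 4L) as.character(bed[[4L]]) else NA_character_
  )
  if (any(out$start >= out$end)) {
    stop("BED interval with start >= end at row(s): ",
         paste(head(which(out$start >= out$end), 5L), collapse = ", "), call. = FALSE)
  }
  out[!strand %in% c("+", "-"), strand := "."]
  annotation_set(out, genome)
}

#' Write per-site 6mA calls as 11-column bedMethyl
#'
#' Columns: chrom, start, end, name ("6mA"), score (`min(1000, n_total)`),
#' strand, thickStart, thickEnd, rgb, coverage (`n_total`), percent
#' (`100 * frequency`, 2 decimals). Rows are sorted by (chrom, start, strand).
#'
#' @param sites a [site_records()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(sites, path) {
  st <- site_records(sites)
  if (nrow(st) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  out <- data.table(
    chrom = st$contig, start = st$pos, end = st$pos + 1L,
    name = "6mA", score = pmin(1000L, st$n_total), strand = st$strand,
    thickStart = st$pos, thickEnd = st$pos + 1L, rgb = "0,0,0",
    coverage = st$n_total, percent = sprintf("%.2f", 100 * st$frequency)
  )
  setorder(out, chrom, start, strand)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an 11-column bedMethyl file
#' @param path bedMethyl path written by [write_bedmethyl()].
#' @return a [site_records()] table (frequency at 2-decimal percent precision).
#' @export
read_bedmethyl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(site_records(data.table(contig = character(), pos = integer(),
                                   strand = character(), n_total = integer(),
                                   n_meth = integer())))
  }
  bm <- fread(path, header = FALSE, sep = "\t")
  if (ncol(bm) != 11L) stop("expected 11 bedMethyl columns, got ", ncol(bm), call. = FALSE)
  n_total <- as.integer(bm[[10L]])
  n_meth <- as.integer(round(as.numeric(bm[[11L]]) / 100 * n_total))
  site_records(data.table(contig = as.character(bm[[1L]]), pos = as.integer(bm[[2L]]),
                          strand = as.character(bm[[6L]]),
                          n_total = n_total, n_meth = n_meth))
}

#' Write simulated reads as a signal archive
#'
#' The archive is a directory holding `index.tsv` (read_id, contig, start,
#' end, strand, sequence, comma-separated per-base dwells), one
#' little-endian float32 raw stream `<read_id>.sig` per read, and — when
#' ground truth is supplied — a `truth.bed` of methylated template positions.
#'
#' @param reads list of `simulated_read` objects.
#' @param path archive directory (created if absent).
#' @param truth optional data.frame (`contig`, `pos`, `strand`) of methylated
#'   template positions in genome coordinates.
#' @return `path`, invisibly.
#' @export
write_signal_archive <- function(reads, path, truth = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  idx <- rbindlist(lapply(reads, function(r) {
    stopifnot(inherits(r, "simulated_read"))
    data.table(read_id = r$read_id, contig = r$contig, start = r$start,
               end = r$end, strand = r$strand, sequence = r$sequence,
               dwells = paste(r$dwells, collapse = ","))
  }))
  fwrite(idx, file.path(path, "index.tsv"), sep = "\t")
  for (r in reads) {
    con <- file(file.path(path, paste0(r$read_id, ".sig")), "wb")
    writeBin(as.numeric(r$samples), con, size = 4L, endian = "little")
    close(con)
  }
  if (!is.null(truth)) {
    tr <- as.data.table(truth)
    bed <- data.table(tr$contig, tr$pos, tr$pos + 1L, "6mA", 0L, tr$strand)
    setorder(bed, V1, V2, V6)
    fwrite(bed, file.path(path, "truth.bed"), sep = "\t", col.names = FALSE)
  }
  invisible(path)
}

#' Read a signal archive
#'
#' Reconstructs `simulated_read` objects; when the archive carries a
#' `truth.bed`, read-local truth labels are re-attached from the genome-level
#' truth positions.
#'
#' @param path archive directory written by [write_signal_archive()].
#' @return list of `simulated_read` objects; the genome-level truth table (or
#'   `NULL`) is attached as attribute `"truth"`.
#' @export
read_signal_archive <- function(path) {
  idx_path <- file.path(path, "index.tsv")
  if (!file.exists(idx_path)) stop("not a signal archive (no index.tsv): ", path,
                                   call. = FALSE)
  idx <- fread(idx_path, sep = "\t",
               colClasses = list(character = c("read_id", "contig", "strand", "sequence",
                                               "dwells")))
  truth <- NULL
  truth_path <- file.path(path, "truth.bed")
  if (file.exists(truth_path) && file.size(truth_path) > 0L) {
    tb <- fread(truth_path, header = FALSE, sep = "\t")
    truth <- data.table(contig = as.character(tb[[1L]]), pos = as.integer(tb[[2L]]),
                        strand = as.character(tb[[6L]]))
  }
  reads <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    row <- idx[i]
    dwells <- as.integer(strsplit(row$dwells, ",", fixed = TRUE)[[1L]])
    sig_path <- file.path(path, paste0(row$read_id, ".sig"))
    if (!file.exists(sig_path)) stop("missing signal file for read ", row$read_id,
                                     call. = FALSE)
    n_expected <- sum(dwells)
    con <- file(sig_path, "rb")
    samples <- readBin(con, what = "numeric", n = n_expected + 1L, size = 4L,
                       endian = "little")
    close(con)
    if (length(samples) != n_expected) {
      stop("signal archive integrity error for read ", row$read_id, ": ",
           length(samples), " samples on disk, dwells sum to ", n_expected,
           call. = FALSE)
    }
    truth_local <- integer(0)
    if (!is.null(truth)) {
      hits <- truth[contig == row$contig & strand == row$strand &
                      pos >= row$start & pos < row$end]
      truth_local <- if (row$strand == "+") hits$pos - row$start
                     else row$end - 1L - hits$pos
      truth_local <- sort(truth_local)
    }
    reads[[i]] <- simulated_read(
      read_id = row$read_id, contig = row$contig, start = row$start, end = row$end,
      strand = row$strand, sequence = row$sequence, dwells = dwells,
      samples = samples, truth_local = truth_local
    )
  }
  attr(reads, "truth") <- truth
  reads
}
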