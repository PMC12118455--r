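# Core domain containers shared across the toolkit.
#
# All genomic coordinates are 0-based half-open internally; converters to
# and from GFF3 (1-based closed) live in the readers. Strand is one of
# "+", "-", or "." ("." only for unstranded features).

#' Construct a reference genome container
#'
#' Holds an ordered set of contigs as uppercase DNA strings over
#' `{A,C,G,T,N}`. `U` is mapped to `T` and every other IUPAC or stray
#' character is masked to `N` at construction.
#'
#' @param contigs named character vector or list of DNA sequences; names are
#'   contig identifiers.
#' @return an object of class `reference_genome` with elements `contigs`
#'   (named character) and `lengths` (named integer).
#' @export
reference_genome <- function(contigs) {
  contigs <- unlist(contigs)
  if (length(contigs) == 0L) stop("genome must contain at least one contig", call. = FALSE)
  ids <- names(contigs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every contig needs a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate contig id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(contigs)
  seqs <- chartr("U", "T", seqs)
  seqs <- gsub("[^ACGTN]", "N", seqs)
  if (any(!nzchar(seqs))) stop("empty sequence for contig(s)", call. = FALSE)
  structure(
    list(contigs = seqs, lengths = stats::setNames(nchar(seqs), ids)),
    class = "reference_genome"
  )
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("reference_genome:", length(x$contigs), "contig(s),",
      sum(x$lengths), "bp total\n")
  invisible(x)
}

#' Total genome length in bases
#' @param genome a `reference_genome`.
#' @return integer total length.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "reference_genome"))
  sum(genome$lengths)
}

#' Construct an annotation set
#'
#' A validated table of genomic features (CDS, prophage, gene, ...) bound to
#' a genome. Intervals are 0-based half-open.
#'
#' @param features data.frame with columns `contig`, `start`, `end`,
#'   `strand`, `type` and optionally `gene_id` / `name`.
#' @param genome optional `reference_genome` used to validate bounds.
#' @return a `data.table` with class `annotation_set` prepended.
#' @export
annotation_set <- function(features, genome = NULL) {
  ft <- as.data.table(features)
  req <- c("contig", "start", "end", "strand", "type")
  miss <- setdiff(req, names(ft))
  if (length(miss)) stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(ft)) {
    if (any(ft$start < 0L) || any(ft$end <= ft$start)) {
      stop("invalid interval(s): need 0 <= start < end", call. = FALSE)
    }
    if (!all(ft$strand %in% c("+", "-", "."))) {
      stop("strand must be one of '+', '-', '.'", call. = FALSE)
    }
    if (!is.null(genome)) {
      bad <- ft$contig %in% names(genome$lengths) == FALSE |
        ft$end > genome$lengths[ft$contig]
      if (any(bad)) {
        stop("feature(s) outside contig bounds at row(s): ",
             paste(head(which(bad), 5L), collapse = ", "), call. = FALSE)
      }
    }
  }
  data.table::setattr(ft, "class", c("annotation_set", class(ft)))
  ft[]
}

#' Construct per-site methylation records
#'
#' One row per strand-resolved genomic position with read support counts.
#' `frequency` is always `n_meth / n_total` (validated to 1e-9).
#'
#' @param df data.frame with columns `contig`, `pos` (0-based), `strand`
#'   (`+`/`-`), `n_total`, `n_meth`, and optionally `frequency`.
#' @return a `data.table` of class `site_records`.
#' @export
site_records <- function(df) {
  st <- as.data.table(df)
  req <- c("contig", "pos", "strand", "n_total", "n_meth")
  miss <- setdiff(req, names(st))
  if (length(miss)) stop("site table lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(st)) {
    if (!all(st$strand %in% c("+", "-"))) stop("site strand must be '+' or '-'", call. = FALSE)
    if (any(st$n_total < 0L) || any(st$n_meth < 0L) || any(st$n_meth > st$n_total)) {
      stop("need 0 <= n_meth <= n_total", call. = FALSE)
    }
    freq <- ifelse(st$n_total > 0L, st$n_meth / st$n_total, 0)
    if ("frequency" %in% names(st)) {
      ok <- st$n_total == 0L | abs(st$frequency - freq) <= 1e-9
      if (!all(ok)) stop("frequency inconsistent with n_meth/n_total", call. = FALSE)
    }
    st[, frequency := freq]
  } else if (!"frequency" %in% names(st)) {
    st[, frequency := numeric(0)]
  }
  data.table::setattr(st, "class", c("site_records", class(st)))
  st[]
}
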