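# Event segmentation of raw samples, banded alignment of events to the
# reference pore-model levels, and per-candidate-adenine feature windows.

#' Segment raw samples into events
#'
#' Changepoint segmentation in the style of signal-space resquiggling:
#' boundaries are local maxima of the two-sample Welch t-statistic between
#' adjacent windows of `w` samples exceeding `t`, selected greedily
#' left-to-right with a minimum event length.
#'
#' @param samples numeric raw signal.
#' @param w comparison window size in samples (default 2).
#' @param t t-statistic threshold (default 2.5).
#' @param min_event minimum event length in samples (default 2).
#' @return data.table of class `event_table` with columns `start`, `end`
#'   (0-based half-open sample spans), `mean`, `stdev`, `dwell`, and
#'   internal sufficient statistics `sum`, `sumsq`. Events tile
#'   `[0, length(samples))`.
#' @export
segment_events <- function(samples, w = 2L, t = 2.5, min_event = 2L) {
  n <- length(samples)
  if (n < 2L * w) stop("signal too short to segment: ", n, " samples", call. = FALSE)
  bounds <- .segment_boundaries_cpp(as.numeric(samples), as.integer(w),
                                    as.numeric(t), as.integer(min_event))
  starts <- c(0L, bounds)
  ends <- c(bounds, n)
  cs <- cumsum(c(0, samples))
  cs2 <- cumsum(c(0, samples^2))
  sums <- cs[ends + 1L] - cs[starts + 1L]
  sumsqs <- cs2[ends + 1L] - cs2[starts + 1L]
  dwell <- ends - starts
  mu <- sums / dwell
  v <- pmax(0, (sumsqs - sums * mu) / pmax(1L, dwell - 1L))
  ev <- data.table(start = starts, end = ends, mean = mu, stdev = sqrt(v),
                   dwell = dwell, sum = sums, sumsq = sumsqs)
  data.table::setattr(ev, "class", c("event_table", class(ev)))
  ev[]
}

#' Align events to expected reference levels
#'
#' Banded dynamic programming minimising the sum of |event mean − expected
#' level| over monotone many-to-one event-to-base assignments; bases that
#' receive no event are skipped at `skip_cost` each. The returned mapping is
#' collapsed so that every base maps to at least one event (skipped bases
#' inherit the nearest earlier event).
#'
#' @param events an `event_table` from [segment_events()] (or a numeric
#'   vector of event means).
#' @param expected_levels pore-model level per base of the read's placement.
#' @param band half-width of the alignment band, in events. The default
#'   (`NULL`) scales as `2 * sqrt(n_events)` (floor 16): dwell-count
#'   fluctuations drift off the straight diagonal like a random walk, so a
#'   fixed narrow band truncates the optimal path on long reads.
#' @param skip_cost penalty per skipped base (default 10, a few times the
#'   typical event spread: cheap enough that a base whose event was merged
#'   into a neighbour is skipped rather than force-fitted).
#' @return list of class `aligned_events`: `base_of_event` (1-based base per
#'   event), `events_of_base` (list), `cost`, `skip_cost`.
#' @export
align_events_to_reference <- function(events, expected_levels, band = NULL,
                                      skip_cost = 10) {
  means <- if (is.data.frame(events)) events$mean else as.numeric(events)
  nb <- length(expected_levels)
  ne <- length(means)
  if (ne == 0L || nb == 0L) stop("empty alignment input", call. = FALSE)
  if (is.null(band)) {
    band <- max(16L, as.integer(ceiling(2 * sqrt(ne))))
  }
  res <- .align_banded_cpp(means, as.numeric(expected_levels),
                           as.integer(band), as.numeric(skip_cost))
  boe <- res$base_of_event
  # collapsed base -> events mapping; skipped bases inherit the nearest
  # earlier event (or the first event at the leading edge)
  sp <- split(seq_along(boe), boe)
  eob <- vector("list", nb)
  eob[as.integer(names(sp))] <- sp
  last <- 1L
  for (j in seq_len(nb)) {
    if (is.null(eob[[j]])) eob[[j]] <- last else last <- eob[[j]][length(eob[[j]])]
  }
  structure(list(base_of_event = boe, events_of_base = eob, cost = res$cost,
                 skip_cost = skip_cost),
            class = "aligned_events")
}

# Per-base signal statistics pooled over each base's events; bases without
# an assigned event inherit their collapsed-mapping event.
base_signal_stats <- function(events, aligned, nb) {
  boe <- aligned$base_of_event
  agg <- rowsum(cbind(events$dwell, events$sum, events$sumsq), boe)
  present <- as.integer(rownames(agg))
  n <- numeric(nb); s <- numeric(nb); s2 <- numeric(nb)
  n[present] <- agg[, 1L]
  s[present] <- agg[, 2L]
  s2[present] <- agg[, 3L]
  miss <- which(n == 0)
  if (length(miss)) {
    einh <- vapply(aligned$events_of_base[miss],
                   function(x) x[length(x)], numeric(1L))
    n[miss] <- events$dwell[einh]
    s[miss] <- events$sum[einh]
    s2[miss] <- events$sumsq[einh]
  }
  mu <- s / n
  v <- pmax(0, (s2 - s * mu) / pmax(1, n - 1))
  list(mean = mu, stdev = sqrt(v), dwell = n)
}

#' Expected pore-model levels for a read placement
#'
#' @param read a `simulated_read` (placement fields are used).
#' @param pore_model a [build_pore_model()] model.
#' @param genome a [reference_genome()] providing flanking context.
#' @return list with `level`, `spread` per molecule base and the raw context.
#' @export
read_expected_levels <- function(read, pore_model, genome) {
  ctx <- molecule_context(genome, read$contig, read$start, read$end, read$strand)
  level <- pore_model$level[ctx$kidx]
  spread <- pore_model$spread[ctx$kidx]
  level[is.na(level)] <- mean(pore_model$level)
  spread[is.na(spread)] <- mean(pore_model$spread)
  list(level = level, spread = spread, ctx = ctx)
}

#' Extract per-candidate-adenine feature windows
#'
#' For every template-strand adenine in the read span, a window of `W`
#' consecutive bases centred on the adenine, with 7 features per base:
#' event-mean z-score against the unmethylated pore-model level, pooled
#' event stdev, log dwell, and a one-hot base encoding. Windows whose
#' centre lies within `W %/% 2` bases of a read or contig edge are skipped.
#'
#' @param read a `simulated_read`.
#' @param events `event_table` from [segment_events()].
#' @param aligned `aligned_events` from [align_events_to_reference()].
#' @param pore_model the pore model.
#' @param genome the reference genome.
#' @param W window width in bases (odd, >= 5; default 17).
#' @param attach_labels attach 0/1 truth labels from `read$truth_local`
#'   when available.
#' @return list of class `feature_windows`: `features` (matrix, one row per
#'   window, `7 * W` columns), `meta` (data.table: `read_id`, `contig`,
#'   `pos`, `strand`, `center_local`, `label`).
#' @export
extract_feature_windows <- function(read, events, aligned, pore_model, genome,
                                    W = 17L, attach_labels = TRUE) {
  if (W %% 2L == 0L) stop("window width W must be odd", call. = FALSE)
  if (W < 5L) stop("window width W must be >= 5", call. = FALSE)
  exp_lv <- read_expected_levels(read, pore_model, genome)
  m <- read$end - read$start
  stats_ <- base_signal_stats(events, aligned, m)
  z <- (stats_$mean - exp_lv$level) / exp_lv$spread
  feat <- cbind(z, stats_$stdev, log(stats_$dwell),
                one_hot_bases(read$sequence))
  half <- W %/% 2L
  codes <- dna_codes(read$sequence)
  centers <- which(codes == 0L) # molecule-strand adenines (1-based)
  centers <- centers[centers > half & centers <= m - half]
  if (length(centers)) {
    gpos <- if (read$strand == "+") read$start + centers - 1L
            else read$end - centers
    clen <- genome$lengths[[read$contig]]
    edge_ok <- gpos >= half & gpos < clen - half
    n_skip <- sum(!edge_ok)
    if (n_skip) info_log("skipped %d window(s) within %d bp of a contig edge",
                         n_skip, half)
    centers <- centers[edge_ok]
    gpos <- gpos[edge_ok]
  } else {
    gpos <- integer(0)
  }
  nwin <- length(centers)
  X <- matrix(0, nwin, 7L * W)
  if (nwin) {
    offs <- -half:half
    for (oi in seq_along(offs)) {
      X[, (oi - 1L) * 7L + 1:7] <- feat[centers + offs[oi], , drop = FALSE]
    }
  }
  label <- rep(NA_integer_, nwin)
  if (attach_labels && !is.null(read$truth_local)) {
    label <- as.integer((centers - 1L) %in% read$truth_local)
  }
  meta <- data.table(read_id = read$read_id, contig = read$contig,
                     pos = gpos, strand = read$strand,
                     center_local = centers - 1L, label = label)
  structure(list(features = X, meta = meta), class = "feature_windows")
}

one_hot_bases <- function(sequence) {
  codes <- dna_codes(sequence)
  oh <- matrix(0, length(codes), 4L)
  ok <- !is.na(codes)
  oh[cbind(which(ok), codes[ok] + 1L)] <- 1
  oh
}

#' Resquiggle one read end-to-end
#'
#' Convenience wrapper: [segment_events()], [align_events_to_reference()]
#' and [extract_feature_windows()] with shared defaults.
#'
#' @inheritParams extract_feature_windows
#' @param seg_w,seg_t,min_event segmentation parameters.
#' @param band,skip_cost alignment parameters.
#' @return a `feature_windows` object (with `events` and `aligned` attached
#'   as attributes).
#' @export
resquiggle_read <- function(read, pore_model, genome, W = 17L, seg_w = 2L,
                            seg_t = 2.5, min_event = 2L, band = NULL,
                            skip_cost = 10, attach_labels = TRUE) {
  events <- segment_events(read$samples, w = seg_w, t = seg_t,
                           min_event = min_event)
  exp_lv <- read_expected_levels(read, pore_model, genome)
  aligned <- align_events_to_reference(events, exp_lv$level, band = band,
                                       skip_cost = skip_cost)
  fw <- extract_feature_windows(read, events, aligned, pore_model, genome,
                                W = W, attach_labels = attach_labels)
  attr(fw, "events") <- events
  attr(fw, "aligned") <- aligned
  fw
}

#' Collect feature windows across many reads
#'
#' @param reads list of `simulated_read` objects.
#' @param pore_model,genome shared model and reference.
#' @param ... passed to [resquiggle_read()].
#' @return a `feature_windows` object pooling all reads.
#' @export
collect_feature_windows <- function(reads, pore_model, genome, ...) {
  parts <- lapply(reads, resquiggle_read, pore_model = pore_model,
                  genome = genome, ...)
  feats <- do.call(rbind, lapply(parts, `[[`, "features"))
  meta <- rbindlist(lapply(parts, `[[`, "meta"))
  structure(list(features = feats, meta = meta), class = "feature_windows")
}
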