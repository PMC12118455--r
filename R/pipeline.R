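# End-to-end orchestration: resquiggle a simulated dataset, train the
# caller on a read subset, predict per-read calls everywhere, aggregate to
# per-site frequencies and summarise the methylome. Reads are processed in
# batches so feature matrices never hold the whole dataset at once.

#' Run the 6mA calling pipeline on a simulated dataset
#'
#' Training windows come from a read-level subset (all positives plus
#' `neg_per_pos` sampled negatives per read); the caller's internal
#' validation split remains positional. Held-out performance is measured on
#' the per-read site calls of the remaining reads. All reads are then
#' called and aggregated into per-site records.
#'
#' @param dataset a `sim_dataset` from [simulate_dataset()].
#' @param seed pipeline seed (read split, negative subsampling, training).
#' @param train_dataset optional `sim_dataset` used as the training control
#'   (typically a randomly methylated sample sharing the study pore model,
#'   from [simulate_training_control()], so sequence context carries no
#'   label information). When `NULL`, training windows come from a subset
#'   of the study reads themselves.
#' @param train_read_fraction fraction of study reads whose windows feed
#'   training when no training control is given.
#' @param neg_per_pos negatives kept per positive window during training
#'   subsampling.
#' @param W feature window width.
#' @param site_min_depth,site_freq_min site rule for the methylome summary.
#' @param batch_size reads per prediction batch.
#' @param ... passed to [resquiggle_read()] (segmentation/alignment tuning).
#' @return list of class `pipeline_result`: `model`, `train_report`,
#'   `heldout_auroc`, `heldout_n`, `calls`, `sites` (aggregated
#'   [site_records()]), `methylome` (`genome_methylome`), `train_read_ids`.
#' @export
run_pipeline <- function(dataset, seed = 1L, train_dataset = NULL,
                         train_read_fraction = 0.5, neg_per_pos = 3L,
                         W = 17L, site_min_depth = 5L,
                         site_freq_min = 0.5, batch_size = 200L, ...) {
  stopifnot(inherits(dataset, "sim_dataset"))
  reads <- dataset$reads
  n_reads <- length(reads)
  read_ids <- vapply(reads, `[[`, character(1L), "read_id")
  if (is.null(train_dataset)) {
    train_ids <- with_seed(derive_seed(seed, 1L), {
      sample(read_ids, max(1L, round(train_read_fraction * n_reads)))
    })
    is_train <- read_ids %in% train_ids
    train_reads <- reads[is_train]
    train_genome <- dataset$genome
  } else {
    stopifnot(inherits(train_dataset, "sim_dataset"))
    train_ids <- character(0)
    is_train <- rep(FALSE, n_reads)
    train_reads <- train_dataset$reads
    train_genome <- train_dataset$genome
  }
  # pass 1: balanced training windows from the training reads
  feat_parts <- list()
  meta_parts <- list()
  for (i in seq_along(train_reads)) {
    fw <- resquiggle_read(train_reads[[i]], dataset$pore_model, train_genome,
                          W = W, ...)
    pos <- which(fw$meta$label == 1L)
    neg <- which(fw$meta$label == 0L)
    keep_neg <- with_seed(derive_seed(seed, 7000L + i), {
      sample(neg, min(length(neg), max(neg_per_pos * length(pos), 5L)))
    })
    keep <- sort(c(pos, keep_neg))
    if (length(keep) == 0L) next
    feat_parts[[length(feat_parts) + 1L]] <- fw$features[keep, , drop = FALSE]
    meta_parts[[length(meta_parts) + 1L]] <- fw$meta[keep]
  }
  train_windows <- list(features = do.call(rbind, feat_parts),
                        meta = rbindlist(meta_parts))
  fit <- train_caller(train_windows, seed = derive_seed(seed, 2L))
  # pass 2: call every read; keep per-window probabilities only
  call_parts <- list()
  heldout_scores <- list()
  for (bs in seq(1L, n_reads, by = batch_size)) {
    idx <- bs:min(bs + batch_size - 1L, n_reads)
    for (i in idx) {
      fw <- resquiggle_read(reads[[i]], dataset$pore_model, dataset$genome,
                            W = W, ...)
      calls <- predict_read_sites(fit$model, fw)
      call_parts[[length(call_parts) + 1L]] <- calls
      if (!is_train[i]) {
        heldout_scores[[length(heldout_scores) + 1L]] <-
          data.table(prob = calls$prob, label = fw$meta$label)
      }
    }
  }
  calls <- rbindlist(call_parts)
  ho <- rbindlist(heldout_scores)
  heldout_auroc <- if (nrow(ho)) auroc(ho$prob, ho$label) else NA_real_
  sites <- aggregate_site_calls(calls)
  methylome <- methylome_density(sites, dataset$genome,
                                 genome_id = names(dataset$genome$contigs)[1L],
                                 reads = reads, site_min_depth = site_min_depth,
                                 site_freq_min = site_freq_min)
  structure(list(model = fit$model, train_report = fit$report,
                 heldout_auroc = heldout_auroc, heldout_n = nrow(ho),
                 calls = calls, sites = sites, methylome = methylome,
                 train_read_ids = train_ids),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("pipeline_result: %d per-read calls, %d called sites, ",
                     "held-out per-read AUROC %.4f (n=%d)\n"),
              nrow(x$calls), x$methylome$n_sites_called, x$heldout_auroc,
              x$heldout_n))
  invisible(x)
}

#' Simulate a randomly methylated training control
#'
#' A control sample over its own random genome in which every adenine is
#' methylated independently with probability `meth_rate`, so sequence
#' context carries no information about the label and the caller must learn
#' the signal-level 6mA shift. Shares the study sample's pore model.
#'
#' @param config a [sim_config()] for the control (its own seed/genome).
#' @param pore_model the study pore model to share.
#' @param meth_rate per-adenine methylation probability (default 0.1: sparse
#'   enough that neighbouring methylation rarely confounds a window label).
#' @return a `sim_dataset`.
#' @export
simulate_training_control <- function(config, pore_model, meth_rate = 0.1) {
  scheme <- methylation_scheme(list(), numeric(0), background_rate = meth_rate)
  simulate_dataset(config, scheme, pore_model = pore_model)
}

#' Realised ground-truth modification ratio of a motif
#'
#' Fraction of the motif's strand-resolved occurrences whose focal adenine
#' is methylated in the simulation truth.
#'
#' @param truth methylated-position table (e.g. `dataset$truth`).
#' @param genome a [reference_genome()].
#' @param motif an [iupac_motif()].
#' @return realised fraction in \[0, 1\].
#' @export
true_modification_ratio <- function(truth, genome, motif) {
  occ <- scan_motif(genome, motif)
  if (nrow(occ) == 0L) return(NA_real_)
  tr <- as.data.table(truth)
  hit <- merge(occ, tr[, .(contig, pos, strand, meth = TRUE)],
               by = c("contig", "pos", "strand"), all.x = TRUE)
  mean(!is.na(hit$meth))
}
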