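# methDiff: compare per-sample 5-mer methylation-usage profiles with
# Bray-Curtis distances, a within- vs between-individual rank-sum test,
# principal coordinates, and PERMANOVA over individuals.

#' Run the methDiff framework
#'
#' Given per-sample methylation-usage vectors with individual/timepoint
#' metadata, computes (1) the full pairwise Bray-Curtis distance matrix,
#' (2) a one-sided Wilcoxon rank-sum test of within-individual versus
#' between-individual distances (within < between), (3) a principal
#' coordinates ordination, and (4) a PERMANOVA with individuals as groups.
#' Individuals represented by a single sample are excluded from the
#' within/between comparison (logged) and from PERMANOVA.
#'
#' @param usage samples x features non-negative matrix (rownames = sample
#'   ids), e.g. from [kmer_usage_vector()] per sample.
#' @param individuals character vector of individual ids, one per row.
#' @param timepoints optional timepoint labels (recorded in the report).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param seed permutation seed.
#' @return object of class `methdiff_report`: `distance` (`dist_matrix`),
#'   `within` / `between` distance vectors, `wilcoxon`
#'   (`rank_sum_result`), `ordination`, `permanova`, `excluded_individuals`,
#'   `seed`.
#' @export
methdiff <- function(usage, individuals, timepoints = NULL, n_perm = 999L,
                     seed = 1L) {
  usage <- as.matrix(usage)
  n <- nrow(usage)
  individuals <- as.character(individuals)
  if (length(individuals) != n) {
    stop("one individual label per usage row required", call. = FALSE)
  }
  dm <- bray_curtis_matrix(usage)
  sizes <- table(individuals)
  singletons <- names(sizes)[sizes < 2L]
  if (length(singletons)) {
    info_log("excluding %d individual(s) with a single sample from methDiff tests: %s",
             length(singletons), paste(singletons, collapse = ", "))
  }
  keep <- !(individuals %in% singletons)
  same <- outer(individuals, individuals, "==")
  ut <- upper.tri(dm$D)
  keep_pair <- outer(keep, keep, "&")
  within <- dm$D[ut & same & keep_pair]
  between <- dm$D[ut & !same & keep_pair]
  wil <- NULL
  if (length(within) && length(between)) {
    if (all(c(within, between) == 0)) {
      wil <- structure(list(U = length(within) * length(between) / 2, p_value = 1,
                            exact = FALSE, n_x = length(within),
                            n_y = length(between), alternative = "less"),
                       class = "rank_sum_result")
    } else {
      wil <- wilcoxon_rank_sum(within, between, alternative = "less")
    }
  }
  ord <- if (n >= 3L) pcoa_ordination(dm) else NULL
  perm <- NULL
  if (sum(keep) >= 4L && length(unique(individuals[keep])) >= 2L) {
    subD <- dm$D[keep, keep, drop = FALSE]
    perm <- permanova(subD, individuals[keep], n_perm = n_perm, seed = seed)
  }
  structure(list(distance = dm, within = within, between = between,
                 wilcoxon = wil, ordination = ord, permanova = perm,
                 individuals = individuals, timepoints = timepoints,
                 excluded_individuals = singletons, seed = as.integer(seed)),
            class = "methdiff_report")
}

#' @export
print.methdiff_report <- function(x, ...) {
  cat("methDiff report\n")
  cat(sprintf("  samples: %d; individuals: %d (%d excluded as singletons)\n",
              nrow(x$distance$D), length(unique(x$individuals)),
              length(x$excluded_individuals)))
  if (!is.null(x$wilcoxon)) {
    cat(sprintf("  within vs between (one-sided Wilcoxon, within < between): p = %.4g\n",
                x$wilcoxon$p_value))
    cat(sprintf("    median within %.4f (n=%d), median between %.4f (n=%d)\n",
                stats::median(x$within), length(x$within),
                stats::median(x$between), length(x$between)))
  }
  if (!is.null(x$permanova)) {
    cat(sprintf("  PERMANOVA over individuals: pseudo-F = %.3f, p = %.4g\n",
                x$permanova$pseudo_F, x$permanova$p_value))
  }
  if (!is.null(x$ordination) && length(x$ordination$eigenvalues)) {
    cat(sprintf("  PCoA axis 1-2 explain %.1f%% of positive inertia\n",
                100 * sum(head(x$ordination$proportion_explained, 2L))))
  }
  invisible(x)
}
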