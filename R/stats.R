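# The methDiff statistical layer, implemented from first principles:
# Bray-Curtis distances, principal coordinates, permutational MANOVA,
# rank-sum / paired-t / one-way ANOVA tests and correlation. Each statistic
# is cross-checked against an independent oracle in the test suite.

#' Bray-Curtis dissimilarity between two non-negative vectors
#'
#' `BC = sum(|x - y|) / sum(x + y)`; 0 for identical vectors, 1 for
#' disjoint supports.
#'
#' @param x,y equal-length non-negative numeric vectors, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("Bray-Curtis needs non-negative input",
                                     call. = FALSE)
  tot <- sum(x + y)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero vectors", call. = FALSE)
  sum(abs(x - y)) / tot
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param usage samples x features non-negative matrix (e.g. 5-mer usage),
#'   with sample ids as rownames.
#' @return object of class `dist_matrix`: `labels`, `D` (symmetric, zero
#'   diagonal).
#' @export
bray_curtis_matrix <- function(usage) {
  usage <- as.matrix(usage)
  n <- nrow(usage)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- bray_curtis(usage[i, ], usage[j, ])
    }
  }
  labels <- rownames(usage)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  dimnames(D) <- list(labels, labels)
  structure(list(labels = labels, D = D), class = "dist_matrix")
}

as_dist_matrix <- function(D) {
  if (inherits(D, "dist_matrix")) return(D)
  if (inherits(D, "dist")) D <- as.matrix(D)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0)) {
    stop("need a symmetric zero-diagonal distance matrix", call. = FALSE)
  }
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(D)))
  structure(list(labels = labels, D = D), class = "dist_matrix")
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower-centres the squared distance matrix (`B = -J D^2 J / 2` with
#' `J = I - 11'/n`), eigendecomposes it, and retains axes with eigenvalues
#' above `1e-10`, scaling eigenvectors by the square root of their
#' eigenvalue. Negative eigenvalues are dropped and their total magnitude
#' reported.
#'
#' @param D a `dist_matrix`, `dist`, or symmetric matrix (n >= 3).
#' @return object of class `ordination`: `coordinates` (samples x axes),
#'   `eigenvalues` (positive, decreasing), `proportion_explained`,
#'   `negative_magnitude`.
#' @export
pcoa_ordination <- function(D) {
  dm <- as_dist_matrix(D)
  n <- nrow(dm$D)
  if (n < 3L) stop("PCoA needs at least 3 samples", call. = FALSE)
  A <- -0.5 * dm$D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- eig$values > 1e-10
  negative_magnitude <- sum(abs(eig$values[eig$values < 0]))
  if (!any(keep)) {
    coords <- matrix(0, n, 0, dimnames = list(dm$labels, NULL))
    return(structure(list(coordinates = coords, eigenvalues = numeric(0),
                          proportion_explained = numeric(0),
                          negative_magnitude = negative_magnitude),
                     class = "ordination"))
  }
  vals <- eig$values[keep]
  vecs <- eig$vectors[, keep, drop = FALSE]
  coords <- sweep(vecs, 2L, sqrt(vals), "*")
  dimnames(coords) <- list(dm$labels, paste0("PCo", seq_along(vals)))
  structure(list(coordinates = coords, eigenvalues = vals,
                 proportion_explained = vals / sum(vals),
                 negative_magnitude = negative_magnitude),
            class = "ordination")
}

permanova_F <- function(D2, groups) {
  n <- nrow(D2)
  a <- length(unique(groups))
  ss_t <- sum(D2[upper.tri(D2)]) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- D2[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_a <- ss_t - ss_w
  if (ss_w <= 0) return(Inf * sign(ss_a))
  (ss_a / (a - 1)) / (ss_w / (n - a))
}

# all distinct permutations of a label vector (as index permutations of
# positions receiving each level) — used for the exact enumeration mode.
enumerate_group_assignments <- function(groups) {
  n <- length(groups)
  levs <- unique(groups)
  out <- list()
  assign_rec <- function(remaining_pos, remaining_counts, current) {
    if (length(remaining_pos) == 0L) {
      out[[length(out) + 1L]] <<- current
      return(invisible(NULL))
    }
    lev_idx <- which(remaining_counts > 0L)
    for (li in lev_idx) {
      cur <- current
      cur[remaining_pos[1L]] <- levs[li]
      cnt <- remaining_counts
      cnt[li] <- cnt[li] - 1L
      assign_rec(remaining_pos[-1L], cnt, cur)
    }
  }
  counts <- as.integer(table(factor(groups, levels = levs)))
  assign_rec(seq_len(n), counts, rep(levs[1L], n))
  out
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' Pseudo-F from the total / within-group sums of squared distances
#' (`SS_T = sum_{i<j} d_ij^2 / n`, `SS_W = sum_g sum_{i<j in g} d^2 / n_g`),
#' with a permutation p-value `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#' With `exact = TRUE` all distinct label assignments are enumerated instead
#' (feasible for small n) and `p = mean(F_all >= F_obs)`.
#'
#' @param D distance matrix (any form accepted by [pcoa_ordination()]).
#' @param groups group labels, length n, >= 2 groups of size >= 2.
#' @param n_perm number of label permutations (default 999).
#' @param seed permutation seed.
#' @param exact enumerate all distinct assignments instead of sampling.
#' @return object of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `group_sizes`, `seed`, `exact`.
#' @export
permanova <- function(D, groups, n_perm = 999L, seed = 1L, exact = FALSE) {
  dm <- as_dist_matrix(D)
  groups <- as.character(groups)
  n <- nrow(dm$D)
  if (length(groups) != n) stop("one group label per sample required", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("PERMANOVA needs >= 2 groups", call. = FALSE)
  if (any(sizes < 2L)) stop("every group needs >= 2 samples", call. = FALSE)
  D2 <- dm$D^2
  f_obs <- permanova_F(D2, groups)
  if (!is.finite(f_obs) && all(dm$D[upper.tri(dm$D)] == dm$D[1, 2])) {
    # all pairwise distances equal: no structure to test
    return(structure(list(pseudo_F = NA_real_, p_value = 1,
                          n_permutations = 0L, group_sizes = sizes,
                          seed = as.integer(seed), exact = FALSE),
                     class = "permanova_result"))
  }
  if (exact) {
    perms <- enumerate_group_assignments(groups)
    f_all <- vapply(perms, function(g) permanova_F(D2, g), numeric(1L))
    p <- mean(f_all >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) permanova_F(D2, sample(groups)),
             numeric(1L))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(pseudo_F = f_obs, p_value = p, n_permutations = n_used,
                 group_sizes = sizes, seed = as.integer(seed), exact = exact),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%d %s)\n",
              x$pseudo_F, x$p_value, x$n_permutations,
              if (x$exact) "exact assignments" else "permutations"))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p by enumeration of rank splits when `n_x + n_y <= 12` and the
#' pooled sample is tie-free; otherwise a normal approximation with tie and
#' continuity corrections. The U statistic counts (x, y) pairs with
#' `x > y` (+ half-ties).
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"less"` (x shifted below y), `"greater"`, or
#'   `"two.sided"`.
#' @return list of class `rank_sum_result`: `U`, `p_value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty",
                                               call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  wx <- sum(r[seq_len(nx)])
  U <- wx - nx * (nx + 1) / 2 # pairs with x > y (+0.5 per tie)
  has_ties <- anyDuplicated(pooled) > 0L
  if (n <= 12L && !has_ties) {
    splits <- utils::combn(n, nx)
    w_all <- colSums(matrix(sort(r)[splits], nrow = nx))
    p <- switch(alternative,
                less = mean(w_all <= wx + 1e-9),
                greater = mean(w_all >= wx - 1e-9),
                two.sided = min(1, 2 * min(mean(w_all <= wx + 1e-9),
                                           mean(w_all >= wx - 1e-9))))
    exact <- TRUE
  } else {
    p <- wilcoxon_normal_approx_p(x, y, alternative)
    exact <- FALSE
  }
  structure(list(U = U, p_value = p, exact = exact, n_x = nx, n_y = ny,
                 alternative = alternative),
            class = "rank_sum_result")
}

# normal approximation with tie and continuity corrections
wilcoxon_normal_approx_p <- function(x, y, alternative) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_corr))
  if (sigma == 0) return(1)
  switch(alternative,
         less = pnorm((U + 0.5 - mu) / sigma),
         greater = pnorm((U - 0.5 - mu) / sigma, lower.tail = FALSE),
         two.sided = {
           zc <- (abs(U - mu) - 0.5) / sigma
           min(1, 2 * pnorm(zc, lower.tail = FALSE))
         })
}

#' Paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences `a - b`,
#' with `df = n - 1`.
#'
#' @param a,b equal-length numeric vectors, n >= 3.
#' @param alternative `"two.sided"`, `"less"` (a < b), or `"greater"`.
#' @return list of class `paired_t_result`: `t`, `p_value`, `df`,
#'   `mean_diff`.
#' @export
paired_t_test <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("paired samples must have equal length",
                                   call. = FALSE)
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  s <- sd(d)
  if (s == 0) stop("zero variance of paired differences: t undefined", call. = FALSE)
  t_stat <- mean(d) / (s / sqrt(n))
  df <- n - 1
  p <- switch(alternative,
              two.sided = 2 * pt(abs(t_stat), df, lower.tail = FALSE),
              less = pt(t_stat, df),
              greater = pt(t_stat, df, lower.tail = FALSE))
  structure(list(t = t_stat, p_value = p, df = df, mean_diff = mean(d),
                 alternative = alternative),
            class = "paired_t_result")
}

#' One-way analysis of variance
#'
#' Standard between/within mean squares with an F-distribution p-value.
#' When the total variance is zero, `F = 0, p = 1`; when only the
#' within-group variance is zero (perfect separation) the p-value is
#' reported as 0 with a warning.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list of class `anova_result`: `F`, `p_value`, `df1`, `df2`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1L)) < 2L)) {
    stop("every group needs >= 2 values", call. = FALSE)
  }
  all_v <- unlist(groups)
  n <- length(all_v)
  a <- length(groups)
  grand <- mean(all_v)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                     numeric(1L)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  df1 <- a - 1L
  df2 <- n - a
  if (ss_b + ss_w == 0) {
    return(structure(list(F = 0, p_value = 1, df1 = df1, df2 = df2),
                     class = "anova_result"))
  }
  if (ss_w == 0) {
    warning("zero within-group variance: F unbounded, p reported as 0")
    return(structure(list(F = Inf, p_value = 0, df1 = df1, df2 = df2),
                     class = "anova_result"))
  }
  f_stat <- (ss_b / df1) / (ss_w / df2)
  structure(list(F = f_stat, p_value = pf(f_stat, df1, df2, lower.tail = FALSE),
                 df1 = df1, df2 = df2),
            class = "anova_result")
}

#' Pearson or Spearman correlation with a t-transform p-value
#'
#' Pearson by moments; Spearman as Pearson on midranks. The p-value uses
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `df = n - 2`.
#'
#' @param x,y numeric vectors, n >= 3, finite, non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @param alternative `"two.sided"`, `"less"`, or `"greater"`.
#' @return list of class `correlation_result`: `r`, `p_value`, `n`, `method`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman"),
                             alternative = c("two.sided", "less", "greater")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite",
                                                     call. = FALSE)
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined",
                                     call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  df <- n - 2
  if (abs(r) == 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt(df / (1 - r^2))
    p <- switch(alternative,
                two.sided = 2 * pt(abs(t_stat), df, lower.tail = FALSE),
                less = pt(t_stat, df),
                greater = pt(t_stat, df, lower.tail = FALSE))
  }
  structure(list(r = r, p_value = min(1, p), n = n, method = method,
                 alternative = alternative),
            class = "correlation_result")
}
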