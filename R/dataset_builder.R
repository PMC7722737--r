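#' Gini coefficient of fold balance
#'
#' Half the relative mean absolute difference of the counts:
#' `sum_ij |x_i - x_j| / (n^2 * mean(x)) / 2`. Used on the per-fold counts of
#' positive FRS peptides as a measure of how evenly the data is distributed
#' into folds (0 = perfectly even).
#'
#' @param counts Non-negative integer vector with positive mean.
#' @return Fraction in `[0, 1]`.
#' @examples
#' gini_coefficient(c(20, 10, 10, 10, 0))  # 0.32
#' @export
gini_coefficient <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  mu <- mean(counts)
  if (!is.finite(mu) || mu <= 0) stop("Gini coefficient undefined for zero mean", call. = FALSE)
  n <- length(counts)
  sum(abs(outer(counts, counts, "-"))) / (n^2 * mu) / 2
}

# union-find over n items
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1]); b <- find(edges[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Single-linkage identity clustering with Gini impurity report
#'
#' Connected components of the graph with an edge wherever pairwise identity
#' strictly exceeds `threshold`. Each cluster's Gini impurity
#' `1 - p^2 - (1-p)^2` (p = fraction of FRS positives) measures how
#' intermixed positives and negatives are; the report averages impurity over
#' clusters, size-weighted by default.
#'
#' @param peptides A `peptide_set` (FRS labels used for impurity; `NA`
#'   treated as negative).
#' @param threshold Identity threshold; peptides above it co-cluster.
#' @param params [alignment_params()].
#' @param weighting `"size"` (weighted mean over clusters) or `"unweighted"`.
#' @param idm Optional precomputed [identity_matrix()] to reuse.
#' @return List with `assignment` (cluster index per peptide) and `report`
#'   (`n_clusters`, `mean_gini_impurity`, `cluster_sizes`).
#' @export
cluster_by_identity <- function(peptides, threshold, params = alignment_params(),
                                weighting = c("size", "unweighted"), idm = NULL) {
  weighting <- match.arg(weighting)
  n <- nrow(peptides)
  if (n < 1L) stop("need at least one peptide", call. = FALSE)
  if (n == 1L) {
    assignment <- 1L
  } else {
    if (is.null(idm)) idm <- identity_matrix(peptides, params)
    adj <- idm > threshold
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    edges <- which(adj, arr.ind = TRUE)
    assignment <- uf_components(n, edges)
  }
  pos <- peptides$frs %in% 1L
  sizes <- as.integer(table(assignment))
  imp <- vapply(split(pos, assignment), function(v) {
    p <- mean(v)
    1 - p^2 - (1 - p)^2
  }, numeric(1))
  mean_imp <- if (weighting == "size") sum(imp * sizes) / sum(sizes) else mean(imp)
  list(assignment = assignment,
       report = list(n_clusters = length(sizes), mean_gini_impurity = mean_imp,
                     cluster_sizes = sizes))
}

#' Remove redundant peptides above an identity ceiling
#'
#' Greedy redundancy filter: while any pair within a label group exceeds
#' `max_identity`, drop the peptide with the most violating partners
#' (ties: shorter sequence first, then lexicographically smaller sequence).
#' Positives (FRS or chelator label 1) and negatives are filtered within
#' their own groups, mirroring a filter applied to "both the positive and
#' negative peptides" separately.
#'
#' @param peptides A `peptide_set`.
#' @param max_identity Ceiling (default 0.90: no surviving pair may exceed
#'   90% identity).
#' @param params [alignment_params()].
#' @param by_group Filter within positive/negative groups (`TRUE`) or over
#'   the pooled set.
#' @return The filtered `peptide_set` (input order preserved).
#' @export
deduplicate_by_identity <- function(peptides, max_identity = 0.90,
                                    params = alignment_params(), by_group = TRUE) {
  groups <- if (by_group) {
    pos <- peptides$frs %in% 1L | peptides$chel %in% 1L
    split(seq_len(nrow(peptides)), pos)
  } else {
    list(seq_len(nrow(peptides)))
  }
  keep <- logical(nrow(peptides))
  for (idx in groups) {
    if (length(idx) < 2L) { keep[idx] <- TRUE; next }
    sub <- peptides[idx, , drop = FALSE]
    adj <- identity_matrix(sub, params) > max_identity
    diag(adj) <- FALSE
    alive <- rep(TRUE, length(idx))
    repeat {
      deg <- rowSums(adj[alive, alive, drop = FALSE])
      if (!length(deg) || max(deg) == 0) break
      cand <- which(alive)[deg == max(deg)]
      ord <- order(nchar(sub$sequence[cand]), sub$sequence[cand])
      alive[cand[ord[1]]] <- FALSE
    }
    keep[idx[alive]] <- TRUE
  }
  out <- peptides[keep, , drop = FALSE]
  class(out) <- c("peptide_set", "data.frame")
  out
}

#' Sample random negative peptides from background proteins
#'
#' Draws `n` peptides by sampling a length from the positives' empirical
#' length distribution, a background protein (uniform among those long
#' enough), and a uniform start position. Exact-sequence collisions with the
#' positive set are rejected and redrawn. Labels are 0/0, stratum `RANDOM`.
#'
#' @param background data.frame of protein records (`id`, `sequence`).
#' @param n Number of negatives (500 in the benchmark recipe).
#' @param length_dist Integer vector of lengths to resample from (typically
#'   `nchar(positives$sequence)`).
#' @param positives A `peptide_set` whose exact sequences are excluded.
#' @param seed Integer RNG seed.
#' @param max_redraws Bound on rejected draws before erroring.
#' @return A `peptide_set` of `n` random-negative peptides.
#' @export
sample_random_negatives <- function(background, n = 500L, length_dist, positives = NULL,
                                    seed = 1L, max_redraws = 100L * max(n, 1L)) {
  if (n == 0L) return(peptide_set(character(0), frs = integer(0), chel = integer(0),
                                  stratum = character(0), id = character(0)))
  if (!length(length_dist)) stop("empty length distribution", call. = FALSE)
  set.seed(seed)
  prot_len <- nchar(background$sequence)
  if (max(prot_len) < min(length_dist)) {
    stop("background proteins shorter than every requested length", call. = FALSE)
  }
  forbidden <- if (is.null(positives)) character(0) else positives$sequence
  out <- character(n)
  draws <- 0L
  i <- 1L
  while (i <= n) {
    draws <- draws + 1L
    if (draws > n + max_redraws) {
      stop("could not sample ", n, " negatives within the redraw budget", call. = FALSE)
    }
    len <- length_dist[sample.int(length(length_dist), 1L)]
    ok <- which(prot_len >= len)
    if (!length(ok)) next
    p <- ok[sample.int(length(ok), 1L)]
    start <- sample.int(prot_len[p] - len + 1L, 1L)
    s <- substr(background$sequence[p], start, start + len - 1L)
    if (s %in% forbidden) next
    out[i] <- s
    i <- i + 1L
  }
  peptide_set(out, frs = 0L, chel = 0L, stratum = "RANDOM",
              id = paste0("rand", seq_len(n)), validate = FALSE)
}

#' Homology-aware balanced fivefold partition
#'
#' Clusters peptides by single-linkage identity at `threshold`, then assigns
#' whole clusters to folds (never splitting one), greedily balancing in
#' priority order chelator-positives, FRS-positives, then totals: clusters
#' are sorted descending by that key and each goes to the currently lightest
#' fold. By construction no cross-fold pair exceeds the identity threshold.
#'
#' @param peptides A labeled `peptide_set`.
#' @param threshold Between-fold identity ceiling (0.60/0.70/0.80/0.90 in
#'   the benchmark recipe).
#' @param params [alignment_params()].
#' @param n_folds Number of folds (5).
#' @param idm Optional precomputed [identity_matrix()].
#' @return A `benchmark_dataset`: list with `peptides` (the input plus a
#'   `fold` column, 0-based), `partition_threshold`, `n_folds`,
#'   `cluster_report`, and `fold_balance` (per-fold FRS counts and their
#'   [gini_coefficient()]).
#' @export
partition_fivefold <- function(peptides, threshold, params = alignment_params(),
                               n_folds = 5L, idm = NULL) {
  cl <- cluster_by_identity(peptides, threshold, params, idm = idm)
  sizes <- tabulate(cl$assignment)
  if (max(sizes) > 0.4 * nrow(peptides)) {
    warning(sprintf("largest cluster holds %.0f%% of the data; even %d-fold partitioning impossible",
                    100 * max(sizes) / nrow(peptides), n_folds), call. = FALSE)
  }
  chel_pos <- vapply(split(peptides$chel %in% 1L, cl$assignment), sum, numeric(1))
  frs_pos <- vapply(split(peptides$frs %in% 1L, cl$assignment), sum, numeric(1))
  ord <- order(-chel_pos, -frs_pos, -sizes, seq_along(sizes))
  fold_chel <- fold_frs <- fold_tot <- numeric(n_folds)
  cluster_fold <- integer(length(sizes))
  # greedy longest-processing-time assignment; the balancing key follows the
  # cluster's own content (a pure-FRS cluster must not be steered by chelator
  # balance, or the fold carrying the odd chelator would be starved of FRS)
  for (k in ord) {
    target <- if (chel_pos[k] > 0) {
      order(fold_chel, fold_frs, fold_tot, seq_len(n_folds))[1]
    } else if (frs_pos[k] > 0) {
      order(fold_frs, fold_tot, seq_len(n_folds))[1]
    } else {
      order(fold_tot, seq_len(n_folds))[1]
    }
    cluster_fold[k] <- target - 1L
    fold_chel[target] <- fold_chel[target] + chel_pos[k]
    fold_frs[target] <- fold_frs[target] + frs_pos[k]
    fold_tot[target] <- fold_tot[target] + sizes[k]
  }
  out <- peptides
  out$fold <- cluster_fold[cl$assignment]
  class(out) <- c("peptide_set", "data.frame")
  frs_counts <- vapply(0:(n_folds - 1L), function(f) sum(out$frs[out$fold == f] %in% 1L),
                       numeric(1))
  structure(list(peptides = out, partition_threshold = threshold, n_folds = n_folds,
                 cluster_report = cl$report,
                 fold_balance = list(per_fold_frs = frs_counts,
                                     gini_coefficient = gini_coefficient(frs_counts))),
            class = "benchmark_dataset")
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf("benchmark_dataset: %d peptides, %d folds at identity threshold %.2f\n",
              nrow(x$peptides), x$n_folds, x$partition_threshold))
  cat("  per-fold FRS positives:", x$fold_balance$per_fold_frs,
      sprintf("(Gini %.3f)\n", x$fold_balance$gini_coefficient))
  invisible(x)
}

#' Audit a partition's cross-fold identity ceiling
#'
#' Exhaustive pairwise check that no two peptides in different folds exceed
#' the partition threshold. Returns the maximum cross-fold identity.
#'
#' @param dataset A `benchmark_dataset`.
#' @param params [alignment_params()].
#' @param idm Optional precomputed identity matrix for `dataset$peptides`.
#' @return Maximum cross-fold pairwise identity (invisibly 0 if < 2 folds used).
#' @export
audit_partition <- function(dataset, params = alignment_params(), idm = NULL) {
  pep <- dataset$peptides
  if (is.null(idm)) idm <- identity_matrix(pep, params)
  cross <- outer(pep$fold, pep$fold, "!=")
  if (!any(cross)) return(invisible(0))
  max(idm[cross])
}
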