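# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration / direct formula), kept free of the package's
# own code paths.

# All global alignments of a and b by exhaustive path enumeration; end-gap
# columns (before the other sequence has started or after it has ended) are
# scored at end_gap. Returns the optimal score and the range of identity
# counts among co-optimal alignments. Only for tiny sequences.
brute_nw <- function(a, b, match = 1, mismatch = 0, gap = -10, end_gap = 0) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  best <- -Inf
  match_counts <- integer(0)
  rec <- function(i, j, score, matches) {
    if (i == n && j == m) {
      if (score > best) {
        best <<- score
        match_counts <<- matches
      } else if (score == best) {
        match_counts <<- c(match_counts, matches)
      }
      return(invisible())
    }
    if (i < n && j < m) {
      eq <- av[i + 1] == bv[j + 1]
      rec(i + 1, j + 1, score + if (eq) match else mismatch,
          matches + as.integer(eq))
    }
    if (i < n) {  # consume a against a gap in b
      g <- if (j == 0 || j == m) end_gap else gap
      rec(i + 1, j, score + g, matches)
    }
    if (j < m) {  # consume b against a gap in a
      g <- if (i == 0 || i == n) end_gap else gap
      rec(i, j + 1, score + g, matches)
    }
  }
  rec(0, 0, 0, 0L)
  list(score = best, matches_range = range(match_counts))
}

# pair-counting AUC
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# trapezoidal ROC integration
trapezoid_auc <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# connected components by boolean transitive closure
brute_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  match(apply(reach, 1, function(r) paste(which(r), collapse = ",")),
        unique(apply(reach, 1, function(r) paste(which(r), collapse = ","))))
}

mcc_from_counts <- function(tp, fp, tn, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
}

# deterministic random peptide generator for fixtures
random_peptides <- function(n, len_range = c(2, 12), seed = NULL,
                            alphabet = aa_alphabet()) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# a small linearly separable fixture: positives contain W, negatives do not
separable_fixture <- function(n_per_class = 40, seed = 42) {
  set.seed(seed)
  no_w <- setdiff(aa_alphabet(), "W")
  pos <- vapply(seq_len(n_per_class), function(i) {
    l <- sample(3:10, 1)
    s <- sample(no_w, l, replace = TRUE)
    s[sample(l, 1)] <- "W"
    paste(s, collapse = "")
  }, character(1))
  neg <- vapply(seq_len(n_per_class), function(i) {
    paste(sample(no_w, sample(3:10, 1), replace = TRUE), collapse = "")
  }, character(1))
  peptide_set(c(pos, neg), frs = rep(c(1L, 0L), each = n_per_class),
              chel = 0L,
              stratum = rep(c("FRS", "NON_AO"), each = n_per_class))
}
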