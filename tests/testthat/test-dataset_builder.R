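test_that("gini_coefficient matches direct enumeration", {
  expect_equal(gini_coefficient(c(7, 7, 7)), 0)
  expect_equal(gini_coefficient(c(1, 0)), 0.5)
  expect_equal(gini_coefficient(c(20, 10, 10, 10, 0)), 0.32)
  expect_error(gini_coefficient(c(0, 0)), "zero mean")
  expect_error(gini_coefficient(c(-1, 2)), "non-negative")
})

test_that("identity clustering matches a transitive-closure oracle", {
  # three planted families plus a singleton
  fam <- function(base, k) vapply(seq_len(k), function(i) {
    s <- strsplit(base, "")[[1]]
    s[i] <- if (s[i] == "A") "C" else "A"
    paste(s, collapse = "")
  }, character(1))
  seqs <- c(fam("AAAAAAAAAA", 3), fam("WWWWWWWWWW", 3), fam("HHHHHHHHHH", 2),
            "KLMNPQRS")
  ps <- peptide_set(seqs, frs = c(1, 1, 1, 0, 0, 0, 1, 0, 0), chel = 0L)
  cl <- cluster_by_identity(ps, threshold = 0.7)
  idm <- identity_matrix(ps)
  oracle <- brute_components(unname(idm) > 0.7)
  expect_equal(length(unique(cl$assignment)), length(unique(oracle)))
  expect_true(all(tapply(oracle, cl$assignment, function(v) length(unique(v))) == 1))
  expect_equal(cl$report$n_clusters, 4)

  # all-distinct peptides: n clusters, zero impurity
  d <- peptide_set(c("AAAA", "CCCC", "DDDD"), frs = c(1, 0, 0), chel = 0L)
  r <- cluster_by_identity(d, 0.9)$report
  expect_equal(r$n_clusters, 3)
  expect_equal(r$mean_gini_impurity, 0)

  # one mixed cluster: impurity 0.5
  m <- peptide_set(c("AAAA", "AAAA"), frs = c(1, 0), chel = 0L)
  expect_equal(cluster_by_identity(m, 0.9)$report$mean_gini_impurity, 0.5)
})

test_that("redundancy filter leaves no violating pair and follows its rule", {
  two <- peptide_set(c("HWYD", "HWYD"), frs = 1L, chel = 0L)
  expect_equal(nrow(deduplicate_by_identity(two)), 1)

  clean <- peptide_set(c("AAAA", "WWWW", "HHHH"), frs = 1L, chel = 0L)
  expect_equal(nrow(deduplicate_by_identity(clean)), 3)

  # planted near-duplicate triple among 10 peptides
  seqs <- c("AAAAAAAAAA", "AAAAAAAAAC", "AAAAAAAACC",
            random_peptides(7, c(4, 8), seed = 77, alphabet = c("D", "E", "F",
                                                                "G", "H", "I",
                                                                "K")))
  ps <- peptide_set(seqs, frs = 1L, chel = 0L)
  filt <- deduplicate_by_identity(ps, 0.90)
  idm <- identity_matrix(filt)
  expect_true(all(idm[upper.tri(idm)] <= 0.90))
  # independent simulation of the removal rule: drop max-degree, ties by
  # shorter then lexicographic sequence
  adj <- identity_matrix(ps) > 0.90
  diag(adj) <- FALSE
  alive <- rep(TRUE, nrow(ps))
  while (any(adj[alive, alive])) {
    deg <- rowSums(adj[alive, alive, drop = FALSE])
    cand <- which(alive)[deg == max(deg)]
    cand <- cand[order(nchar(ps$sequence[cand]), ps$sequence[cand])]
    alive[cand[1]] <- FALSE
  }
  expect_equal(filt$id, ps$id[alive])
})

test_that("random negatives respect the length law, exclusions and the seed", {
  expect_equal(nrow(sample_random_negatives(data.frame(id = "p", sequence = strrep("A", 50)),
                                            n = 0, length_dist = 4)), 0)
  bg <- make_background_proteins(20, c(60, 120), seed = 3)
  neg4 <- sample_random_negatives(bg, 50, length_dist = 4L, seed = 2)
  expect_true(all(nchar(neg4$sequence) == 4))
  expect_true(all(neg4$stratum == "RANDOM" & neg4$frs == 0 & neg4$chel == 0))

  a <- sample_random_negatives(bg, 100, length_dist = c(2, 3, 5, 8), seed = 9)
  b <- sample_random_negatives(bg, 100, length_dist = c(2, 3, 5, 8), seed = 9)
  expect_identical(a$sequence, b$sequence)

  # exact collisions with positives are redrawn: single-residue background
  # makes every length-2 draw "AA", which is forbidden
  homo <- data.frame(id = "h", sequence = strrep("A", 100))
  pos <- peptide_set("AA", frs = 1L, chel = 0L, stratum = "FRS")
  expect_error(sample_random_negatives(homo, 5, length_dist = 2L, positives = pos,
                                       seed = 1, max_redraws = 50), "redraw")

  # chi-squared goodness of fit of the sampled length histogram
  ld <- rep(c(2L, 3L, 4L, 7L, 12L), times = c(40, 30, 15, 10, 5))
  big <- sample_random_negatives(bg, 5000, length_dist = ld, seed = 123)
  obs <- table(factor(nchar(big$sequence), levels = c(2, 3, 4, 7, 12)))
  p <- chisq.test(obs, p = c(40, 30, 15, 10, 5) / 100)$p.value
  expect_gt(p, 0.01)
})

test_that("fivefold partition balances positives and respects the ceiling", {
  # 5 singleton positive clusters: one per fold, Gini 0
  ps <- peptide_set(c("AAAA", "CCCC", "DDDD", "EEEE", "FFFF"),
                    frs = 1L, chel = 0L)
  ds <- partition_fivefold(ps, 0.9)
  expect_setequal(ds$peptides$fold, 0:4)
  expect_equal(ds$fold_balance$per_fold_frs, rep(1, 5))
  expect_equal(ds$fold_balance$gini_coefficient, 0)

  # homology-structured fixture: audit the cross-fold ceiling exhaustively
  spec <- fixture_spec(n_positives = 60, n_negatives = 60, seed = 8)
  peps <- make_benchmark(spec)
  idm <- identity_matrix(peps)
  for (th in c(0.9, 0.7, 0.6)) {
    d <- suppressWarnings(partition_fivefold(peps, th, idm = idm))
    expect_lte(audit_partition(d, idm = idm), th)
    expect_equal(sort(unique(d$peptides$fold)), 0:4)
    expect_equal(nrow(d$peptides), nrow(peps))
  }

  # a dominating cluster triggers the pathology warning
  big <- peptide_set(c(rep("AAAAAAAA", 6), "WWWW", "HHHH"),
                     frs = c(rep(1L, 6), 0L, 0L), chel = 0L)
  expect_warning(partition_fivefold(big, 0.9), "impossible")
})
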