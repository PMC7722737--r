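test_that("validate_sequence normalizes and rejects precisely", {
  expect_identical(validate_sequence("hwyd"), "HWYD")
  expect_identical(validate_sequence("HW YD"), "HWYD")
  expect_error(validate_sequence("HXWD"), "'X' at position 2")
  expect_error(validate_sequence("A"), "length 1 outside")
  expect_error(validate_sequence(strrep("A", 31)), "outside")
  expect_error(validate_sequence("  "), "empty")
  # protein mode checks alphabet only
  expect_identical(validate_sequence(strrep("ay", 40), mode = "protein"),
                   strrep("AY", 40))
  expect_error(validate_sequence("AB", mode = "protein"), "position 2")
})

test_that("peptide_set enforces stratum/label invariants", {
  ps <- peptide_set(c("HWYD", "VWYA"), frs = c(1L, 0L), chel = c(1L, 0L),
                    stratum = c("FRS_CHEL", "RANDOM"))
  expect_s3_class(ps, "peptide_set")
  expect_error(peptide_set("HWYD", frs = 0L, chel = 1L, stratum = "FRS_CHEL"),
               "inconsistency")
  expect_error(peptide_set("HWYD", frs = 1L, chel = 0L, stratum = "NON_AO"),
               "inconsistency")
  expect_error(peptide_set("HWYD", frs = 2L), "binary")
  expect_error(peptide_set("HWYD", stratum = "WEIRD"), "stratum")
})

test_that("one-hot encoding is padded, invertible and length-preserving", {
  m <- one_hot_encode("A")
  expect_equal(sum(m), 1)
  expect_equal(unname(m[1, "A"]), 1)
  m2 <- one_hot_encode("HW")
  expect_equal(sum(m2), 2)
  expect_true(all(m2[3:30, ] == 0))
  full <- one_hot_encode(strrep("W", 30))
  expect_equal(sum(full), 30)
  expect_true(all(rowSums(full) == 1))
  expect_error(one_hot_encode(strrep("A", 31)), "exceeds")

  # property: decode(encode) round-trips; slab total equals peptide length
  seqs <- random_peptides(30, c(2, 30), seed = 11)
  for (s in seqs) {
    m <- one_hot_encode(s)
    expect_identical(decode_one_hot(m), s)
    expect_equal(sum(m), nchar(s))
    expect_true(all(rowSums(m)[seq_len(nchar(s))] == 1))
  }
  eb <- encode_batch(seqs)
  expect_equal(dim(eb$features), c(30, 30, 20))
  expect_equal(apply(eb$features, 1, sum), nchar(seqs))
})

test_that("peptide tables round-trip through CSV and load from TSV/FASTA", {
  ps <- peptide_set(c("HWYD", "VWYA", "KKLM"), frs = c(1L, 0L, 0L),
                    chel = c(0L, 0L, 0L), stratum = c("FRS", "NON_AO", "RANDOM"),
                    id = c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_peptide_table(ps, f)
  back <- read_peptide_table(f)
  expect_equal(as.data.frame(back), as.data.frame(ps)[, names(back)])

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tfrs\tchel", "HWYD\t1\t0", "VWYA\t0\t0"), tsv)
  tt <- read_peptide_table(tsv)
  expect_equal(tt$sequence, c("HWYD", "VWYA"))
  expect_equal(tt$frs, c(1L, 0L))

  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "VW", "YA", ">p2 description", "HWYD"), fa)
  fp <- read_peptide_table(fa)
  expect_equal(fp$sequence, c("VWYA", "HWYD"))  # wrapped lines joined
  expect_equal(fp$id, c("p1", "p2"))
  expect_true(all(is.na(fp$frs)))
})

test_that("malformed rows are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence,frs,chel", "HWYD,1,0", paste0(strrep("A", 31), ",0,0")), f)
  expect_error(read_peptide_table(f), "line 3")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence,frs,chel", "HWYD,1,0", "HWYD,1,0", "VWYA,0,0"), f2)
  expect_warning(d <- read_peptide_table(f2, dedupe = TRUE), "duplicate")
  expect_equal(nrow(d), 2)
})

test_that("write_predictions formats scores and optional calls", {
  rec <- data.frame(sequence = c("HWYD", "AAAA"), frs_score = c(0.59, 0),
                    chel_score = c(0.3, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_predictions(rec, f)
  lines <- readLines(f)
  expect_equal(lines[1], "sequence,frs_score,chel_score")
  expect_equal(lines[2], "HWYD,0.5900,0.3000")
  expect_equal(lines[3], "AAAA,0.0000,1.0000")

  write_predictions(rec, f, threshold = 0.59)
  lines <- readLines(f)
  expect_match(lines[1], "frs_call,chel_call")
  expect_equal(lines[2], "HWYD,0.5900,0.3000,1,0")  # score == threshold -> call 1

  write_predictions(rec[0, ], f)
  expect_equal(length(readLines(f)), 1L)  # header only
  expect_error(write_predictions(data.frame(sequence = "A", frs_score = 1.2,
                                            chel_score = 0.1), f), "0, 1")
})
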