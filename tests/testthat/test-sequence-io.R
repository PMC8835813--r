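write_tmp_fasta <- function(lines) {
  fa <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, fa)
  fa
}

test_that("read_fasta normalizes case and T->U, preserves order", {
  fa <- write_tmp_fasta(c(">a", "acgt", ">b", "UUGG", ">c desc text", "augc"))
  rec <- read_fasta(fa, role = "mature")
  expect_equal(rec$id, c("a", "b", "c"))
  expect_equal(rec$seq, c("ACGU", "UUGG", "AUGC"))
  expect_equal(rec$length, nchar(rec$seq))
  expect_true(all(rec$role == "mature"))
})

test_that("write_fasta / read_fasta round-trips cleaned records, wrapped or not", {
  set.seed(401)
  rec <- tibble::tibble(
    id = sprintf("r%02d", 1:8),
    seq = replicate(8, random_rna(sample(20:120, 1))),
    role = "mature", label = NA_character_
  )
  rec$length <- nchar(rec$seq)
  for (w in c(10L, 70L, Inf)) {
    fa <- withr::local_tempfile(fileext = ".fasta")
    write_fasta(rec, fa, width = w)
    back <- read_fasta(fa, role = "mature")
    expect_equal(back$id, rec$id)
    expect_equal(back$seq, rec$seq)
  }
})

test_that("read_fasta rejects duplicate IDs and missing/empty files", {
  fa <- write_tmp_fasta(c(">x", "ACGU", ">x", "GGCC"))
  expect_error(read_fasta(fa), "duplicate.*x")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("clean_dataset collapses duplicates, drops non-standard residues, reports counts", {
  rec <- tibble::tibble(
    id = paste0("s", 1:5),
    seq = c("ACGUACGU", "GGCCUUAA", "ACGUACGU", "ACGNACGU", "AUAUAUAU"),
    role = "mature", label = NA_character_, length = 8L
  )
  out <- clean_dataset(rec)
  expect_equal(out$id, c("s1", "s2", "s5"))
  rep <- provenance(out)
  expect_match(rep[grepl("non-standard", rep)], "1")
  expect_match(rep[grepl("duplicate", rep)], "1")
  # idempotent, and identity on already-clean input
  again <- clean_dataset(out)
  expect_equal(again$id, out$id)
  expect_error(clean_dataset(rec[4, ]), "no sequences survive")
})

test_that("dedup and residue filtering commute", {
  set.seed(402)
  for (rep_i in 1:10) {
    n <- 8
    seqs <- replicate(n, paste0(sample(c("A", "C", "G", "U", "N"), 6,
                                       replace = TRUE, prob = c(rep(0.22, 4), 0.12)),
                                collapse = ""))
    seqs[sample(n, 2)] <- seqs[sample(n, 1)]  # force duplicates
    rec <- tibble::tibble(id = paste0("q", 1:n), seq = seqs,
                          role = "mature", label = NA_character_,
                          length = nchar(seqs))
    # oracle: filter first, then dedup keeping first occurrence
    valid <- !grepl("[^ACGU]", seqs)
    expected <- rec[valid, ][!duplicated(seqs[valid]), ]$id
    got <- tryCatch(clean_dataset(rec)$id, error = function(e) character(0))
    expect_equal(got, expected)
  }
})

test_that("seq_identity matches the alignment oracle and obvious cases", {
  expect_equal(seq_identity("ACGU", "ACGU"), 1)
  expect_equal(seq_identity("AAAA", "CCCC"), 0)
  set.seed(403)
  for (i in 1:15) {
    a <- random_rna(sample(10:30, 1))
    b <- random_rna(sample(10:30, 1))
    expect_equal(seq_identity(a, b), oracle_identity(a, b), tolerance = 1e-12)
  }
})

test_that("reduce_redundancy matches the brute-force greedy oracle", {
  rec2 <- tibble::tibble(id = c("a", "b"), seq = c("ACGUACGU", "ACGUACGU"),
                         role = "mature", label = NA_character_, length = 8L)
  expect_equal(nrow(reduce_redundancy(rec2, 0.8)), 1L)
  rec_disjoint <- tibble::tibble(id = c("a", "b"), seq = c("AAAA", "CCCC"),
                                 role = "mature", label = NA_character_, length = 4L)
  expect_equal(nrow(reduce_redundancy(rec_disjoint, 0.8)), 2L)

  set.seed(404)
  seqs <- replicate(10, random_rna(24))
  seqs[4] <- seqs[1]  # plant one redundant pair
  rec <- tibble::tibble(id = paste0("r", 1:10), seq = seqs,
                        role = "mature", label = NA_character_, length = 24L)
  got <- reduce_redundancy(rec, 0.8)
  expect_equal(got$id, rec$id[oracle_reduce(seqs, 0.8)])
  expect_error(reduce_redundancy(rec, 1.2), "identity_threshold")
  expect_error(reduce_redundancy(rec, 0), "identity_threshold")
})

test_that("reduce_redundancy retains more sequences at higher thresholds", {
  set.seed(405)
  base <- random_rna(24)
  # family of mutated copies of one sequence, plus unrelated ones
  mutate_seq <- function(s, k) {
    pos <- sample(nchar(s), k)
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- sample(c("A", "C", "G", "U"), k, replace = TRUE)
    paste0(ch, collapse = "")
  }
  seqs <- c(base, sapply(c(2, 4, 6, 8), mutate_seq, s = base),
            replicate(5, random_rna(24)))
  rec <- tibble::tibble(id = paste0("m", seq_along(seqs)), seq = seqs,
                        role = "mature", label = NA_character_, length = 24L)
  sizes <- sapply(c(0.6, 0.75, 0.9, 1), function(th) nrow(reduce_redundancy(rec, th)))
  expect_true(all(diff(sizes) >= 0))
})

test_that("pair_combined joins by ID, drops unmatched with warning, checks labels", {
  mature <- tibble::tibble(id = c("x", "y", "z"), seq = c("ACGU", "GGCC", "AUAU"),
                           role = "mature", label = "positive", length = 4L)
  prec <- tibble::tibble(id = c("x", "y", "z"), seq = c("ACGUACGU", "GGCCGGCC", "AUAUAUAU"),
                         role = "precursor", label = "positive", length = 8L)
  pairs <- pair_combined(mature, prec)
  expect_equal(nrow(pairs), 3L)
  expect_equal(pairs$mature_seq, mature$seq)
  expect_equal(pairs$precursor_seq, prec$seq)

  expect_warning(p2 <- pair_combined(mature, prec[-1, ]), "x")
  expect_equal(p2$id, c("y", "z"))
  expect_error(pair_combined(mature, prec[-1, ], strict = TRUE), "x")

  prec_bad <- prec
  prec_bad$label[2] <- "negative"
  expect_error(pair_combined(mature, prec_bad), "disagreement.*y")
})

test_that("pairing 70 mature records with 70 matching precursors yields 70 pairs", {
  set.seed(406)
  ids <- sprintf("mir%03d", 1:70)
  mature <- tibble::tibble(id = ids, seq = replicate(70, random_rna(22)),
                           role = "mature", label = NA_character_, length = 22L)
  prec <- tibble::tibble(id = sample(ids), seq = replicate(70, random_rna(90)),
                         role = "precursor", label = NA_character_, length = 90L)
  pairs <- pair_combined(mature, prec)
  expect_equal(nrow(pairs), 70L)
  # bijection between retained mature and precursor IDs
  expect_setequal(pairs$id, ids)
  expect_equal(anyDuplicated(pairs$id), 0L)
})

test_that("read_labels accepts headerless and headered files, rejects bad labels", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tpositive", "b\tnegative"), tsv)
  lab <- read_labels(tsv)
  expect_equal(lab$label, c("positive", "negative"))
  writeLines(c("id\tlabel", "a\tpositive"), tsv)
  expect_equal(nrow(read_labels(tsv)), 1L)
  writeLines(c("a\tmaybe"), tsv)
  expect_error(read_labels(tsv), "maybe")
})
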