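test_that("default property tables are standardized at every K", {
  for (K in 2:5) {
    tb <- default_property_table(K)
    expect_equal(nrow(tb$values), 4^K)
    expect_equal(unname(colMeans(tb$values)), rep(0, tb$R), tolerance = 1e-10)
    expect_equal(unname(apply(tb$values, 2, var)), rep(1, tb$R), tolerance = 1e-10)
  }
})

test_that("property tables round-trip through the TSV format", {
  tb <- default_property_table(2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(
    tibble::as_tibble(tb$values, rownames = "tuple"), tsv)
  back <- read_property_table(tsv, 2)
  expect_equal(unname(back$values), unname(tb$values), tolerance = 1e-10)
})

test_that("property_table validates coverage of the tuple space", {
  vals <- matrix(rnorm(30), nrow = 15,
                 dimnames = list(mirstress:::all_ktuples(2)[-1], c("p1", "p2")))
  expect_error(property_table(vals, 2), "16 rows")
})

test_that("k-tuple frequencies match hand counts and the sliding-window oracle", {
  expect_equal(unname(ktuple_frequencies("AAAA", 2)["AA"]), 1)
  f <- ktuple_frequencies("AUGC", 2)
  expect_equal(unname(f[c("AU", "UG", "GC")]), rep(1 / 3, 3))
  expect_equal(sum(f), 1)

  set.seed(501)
  for (i in 1:5) {
    s <- random_rna(24)
    got <- ktuple_frequencies(s, 5)
    expect_equal(got, oracle_ktuple_freq(s, 5), tolerance = 1e-15)
    expect_equal(sum(got > 0 | got == 0), 1024L)  # full tuple space, 20 windows
  }
  expect_error(ktuple_frequencies("ACG", 4), "shorter")
})

test_that("tier correlation is zero for homopolymers and constant tables", {
  for (K in 2:3) {
    expect_equal(tier_correlation(strrep("A", 10), K, 1, default_property_table(K)), 0)
  }
  const <- property_table(
    matrix(5, nrow = 16, ncol = 2,
           dimnames = list(mirstress:::all_ktuples(2), c("p1", "p2"))),
    2, standardize = FALSE)
  expect_equal(tier_correlation("ACGUACGU", 2, 1, const), 0)
})

test_that("tier correlation equals the double-loop oracle on a toy table", {
  toy <- property_table(
    matrix(c(1:16, (16:1)^2), ncol = 2,
           dimnames = list(mirstress:::all_ktuples(2), c("p1", "p2"))),
    2, standardize = FALSE)
  expect_equal(tier_correlation("AUAU", 2, 1, toy),
               oracle_delta("AUAU", 2, 1, toy), tolerance = 1e-14)
  set.seed(502)
  for (i in 1:10) {
    s <- random_rna(sample(8:30, 1))
    j <- sample(1:3, 1)
    expect_equal(tier_correlation(s, 2, j, toy),
                 oracle_delta(s, 2, j, toy), tolerance = 1e-12)
  }
  expect_error(tier_correlation("ACGU", 2, 3, toy), "minimum length 5")
})

test_that("tier correlation scales quadratically with the property values", {
  base <- matrix(rnorm(32), ncol = 2,
                 dimnames = list(mirstress:::all_ktuples(2), c("p1", "p2")))
  t1 <- property_table(base, 2, standardize = FALSE)
  t3 <- property_table(3 * base, 2, standardize = FALSE)
  s <- "ACGGUACGUAUCG"
  for (j in 1:2) {
    expect_equal(tier_correlation(s, 2, j, t3),
                 9 * tier_correlation(s, 2, j, t1), tolerance = 1e-12)
  }
})

test_that("encode_block normalizes to 1 and collapses to frequencies for homopolymers", {
  cfg <- pseknc_config()
  s <- random_rna(24)
  for (K in 2:5) {
    b <- encode_block(s, K, cfg)
    expect_length(b, 4^K + 3)
    expect_equal(sum(b), 1, tolerance = 1e-9)
    expect_true(all(b >= 0))
  }
  hb <- encode_block(strrep("U", 20), 2, cfg)
  expect_equal(unname(hb["K2_UU"]), 1)
  expect_equal(sum(hb[names(hb) != "K2_UU"]), 0)
})

test_that("encoded blocks equal the brute-force formula oracle term by term", {
  cfg <- pseknc_config()
  b <- encode_block("AUGCAUGCAUGC", 2, cfg)
  expect_equal(unname(b),
               unname(oracle_block("AUGCAUGCAUGC", 2, 3, 0.2,
                                   cfg$property_tables[["2"]])),
               tolerance = 1e-14)
  set.seed(503)
  for (i in 1:10) {
    s <- random_rna(sample(8:40, 1))
    expect_equal(unname(encode_sequence(s, cfg)),
                 oracle_full_vector(s, cfg), tolerance = 1e-12)
  }
})

test_that("full encoding has the documented dimension, determinism, and invariances", {
  cfg <- pseknc_config()
  s <- random_rna(24)
  v <- encode_sequence(s, cfg)
  expect_length(v, 1372L)
  expect_equal(n_pseknc_features(cfg), 1372L)
  expect_identical(v, encode_sequence(s, cfg))
  expect_equal(sum(v), 4, tolerance = 1e-9)  # one unit per K block
  # T -> U normalization upstream leaves the encoding unchanged
  dna <- chartr("U", "T", s)
  expect_identical(encode_sequence(mirstress:::normalize_rna(dna), cfg), v)
  expect_error(encode_sequence("ACGUACG", cfg), "minimum encodable length 8")
  expect_error(encode_sequence("ACGNACGUA", cfg), "outside")
})

test_that("encode_dataset builds aligned matrices in both modes", {
  set.seed(504)
  rec <- tibble::tibble(id = sprintf("m%02d", 1:10),
                        seq = replicate(10, random_rna(22)),
                        role = "mature",
                        label = rep(c("positive", "negative"), 5),
                        length = 22L)
  mat <- encode_dataset(rec)
  expect_equal(dim(mat), c(10L, 1372L + 2L))
  expect_equal(mat$label, rec$label)

  # permuting records permutes rows but not values
  perm <- sample(10)
  mat_p <- encode_dataset(rec[perm, ])
  expect_equal(mat_p$id, rec$id[perm])
  expect_equal(dplyr::arrange(mat_p, id), dplyr::arrange(mat, id),
               ignore_attr = TRUE)

  pairs <- tibble::tibble(id = rec$id,
                          mature_seq = rec$seq,
                          precursor_seq = replicate(10, random_rna(90)),
                          label = rec$label)
  cmb <- encode_dataset(pairs)
  expect_equal(dim(cmb), c(10L, 2744L + 2L))
  expect_true(all(startsWith(feature_names(cmb), "mat_") |
                    startsWith(feature_names(cmb), "pre_")))
  expect_equal(sum(startsWith(feature_names(cmb), "mat_")), 1372L)

  bad <- rec
  bad$seq[3] <- "ACGU"  # too short to encode
  expect_error(encode_dataset(bad), "unencodable.*m03")
})
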