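# Independent oracles, coded straight from the defining formulas with plain
# double loops -- deliberately naive so they share no code path with the
# package implementations they check.

oracle_ktuple_freq <- function(seq, K) {
  tuples <- character(0)
  for (i in 1:(nchar(seq) - K + 1)) {
    tuples <- c(tuples, substr(seq, i, i + K - 1))
  }
  all_t <- mirstress:::all_ktuples(K)
  out <- setNames(numeric(length(all_t)), all_t)
  for (tp in tuples) out[tp] <- out[tp] + 1
  out / length(tuples)
}

oracle_delta <- function(seq, K, j, table) {
  L <- nchar(seq)
  n_pairs <- L - K - j + 1
  total <- 0
  for (i in seq_len(n_pairs)) {
    t1 <- substr(seq, i, i + K - 1)
    t2 <- substr(seq, i + j, i + j + K - 1)
    acc <- 0
    for (r in seq_len(table$R)) {
      acc <- acc + (table$values[t1, r] - table$values[t2, r])^2
    }
    total <- total + acc / table$R
  }
  total / n_pairs
}

oracle_block <- function(seq, K, lambda, omega, table) {
  g <- oracle_ktuple_freq(seq, K)
  delta <- sapply(seq_len(lambda), function(j) oracle_delta(seq, K, j, table))
  denom <- sum(g) + omega * sum(delta)
  c(g / denom, omega * delta / denom)
}

oracle_full_vector <- function(seq, config) {
  unlist(lapply(config$K_values, function(K) {
    oracle_block(seq, K, config$lambda, config$omega,
                 config$property_tables[[as.character(K)]])
  }), use.names = FALSE)
}

# auROC as the pairwise-concordance statistic: over all (positive, negative)
# pairs, the fraction where the positive outscores the negative, ties 1/2.
oracle_auroc_concordance <- function(truth, score) {
  pos <- score[truth == "positive"]
  neg <- score[truth == "negative"]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  100 * total / (length(pos) * length(neg))
}

# Global-alignment identity via Biostrings with the same scoring contract
# (match +1, mismatch/indel 0, free end gaps): the alignment score is the
# maximal match count.
oracle_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    gsub("U", "T", a), gsub("U", "T", b),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 0
  )
  m <- Biostrings::score(aln)
  m / (nchar(a) + nchar(b) - m)
}

# Greedy redundancy reduction recomputed with the oracle identity.
oracle_reduce <- function(seqs, threshold) {
  kept <- integer(0)
  for (i in seq_along(seqs)) {
    ok <- TRUE
    for (k in kept) {
      if (oracle_identity(seqs[i], seqs[k]) >= threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# SVM-RFE removal order recomputed by refitting a linear SVM and recomputing
# w^2 at every step (step = 1), straight from w = sum_i alpha_i y_i x_i on
# the standardized features.
oracle_rfe_order <- function(x, y, C = 1) {
  surviving <- colnames(x)
  removal <- character(0)
  while (length(surviving) > 0) {
    raw <- x[, surviving, drop = FALSE]
    sds <- apply(raw, 2, sd)
    sds[sds == 0] <- 1
    xs <- scale(raw, center = colMeans(raw), scale = sds)
    fit <- e1071::svm(x = xs, y = y, scale = FALSE, kernel = "linear",
                      cost = C, gamma = 1 / length(surviving))
    w <- numeric(length(surviving))
    for (s in seq_len(nrow(fit$SV))) {
      w <- w + fit$coefs[s] * fit$SV[s, ]
    }
    drop_i <- which.min(w^2)  # which.min is stable: first minimum wins
    removal <- c(removal, surviving[drop_i])
    surviving <- surviving[-drop_i]
  }
  removal
}

random_rna <- function(len) {
  paste0(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Small labeled gaussian feature tibble for classifier-level tests.
toy_feature_data <- function(n_per_class = 20, p = 4, shift = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p, mean = shift), ncol = p),
               matrix(rnorm(n_per_class * p, mean = 0), ncol = p))
    colnames(x) <- paste0("f", seq_len(p))
    dplyr::bind_cols(
      tibble::tibble(id = sprintf("s%03d", seq_len(2 * n_per_class)),
                     label = rep(c("positive", "negative"), each = n_per_class)),
      tibble::as_tibble(x)
    )
  })
}
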