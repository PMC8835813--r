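#' PseKNC encoder configuration
#'
#' Pseudo K-tuple nucleotide composition (PseKNC) represents an RNA sequence
#' by, for each tuple size K, the `4^K` normalized K-tuple frequencies
#' followed by `lambda` sequence-order correlation factors, jointly
#' normalized into a `4^K + lambda` block. With the defaults
#' `K = 2, 3, 4, 5` and `lambda = 3` the blocks have 19, 67, 259 and 1027
#' entries — 1372 features per sequence, or 2744 for a mature + precursor
#' pair.
#'
#' @param K_values Integer vector of tuple sizes (default `2:5`).
#' @param lambda Number of correlation tiers, shared across K blocks
#'   (default 3; mature miRNAs are only 20-24 nt, so higher tiers have few
#'   tuple pairs to average over).
#' @param omega Weight of the correlation factors relative to tuple
#'   frequencies (default 0.2).
#' @param property_tables Optional named list (names = K values) of
#'   [property_table()] objects; defaults from [default_property_table()].
#' @return An object of class `pseknc_config`.
#' @export
pseknc_config <- function(K_values = 2:5, lambda = 3L, omega = 0.2,
                          property_tables = NULL) {
  K_values <- sort(unique(as.integer(K_values)))
  lambda <- as.integer(lambda)
  if (lambda < 1L) abort("lambda must be >= 1")
  if (!is.numeric(omega) || omega <= 0) abort("omega must be > 0")
  tables <- lapply(K_values, function(K) {
    tb <- property_tables[[as.character(K)]]
    if (is.null(tb)) tb <- default_property_table(K)
    if (!inherits(tb, "property_table") || tb$K != K) {
      abort(sprintf("property_tables[['%d']] must be a property_table with K = %d", K, K))
    }
    tb
  })
  names(tables) <- as.character(K_values)
  structure(
    list(K_values = K_values, lambda = lambda, omega = omega,
         property_tables = tables),
    class = "pseknc_config"
  )
}

#' @export
print.pseknc_config <- function(x, ...) {
  cat(sprintf("<pseknc_config: K = {%s}, lambda = %d, omega = %g, %d features/sequence>\n",
              paste(x$K_values, collapse = ","), x$lambda, x$omega,
              n_pseknc_features(x)))
  invisible(x)
}

#' Total PseKNC feature count under a configuration
#' @param config A [pseknc_config()].
#' @return Integer: `sum(4^K + lambda)` over the configured K values.
#' @export
n_pseknc_features <- function(config) {
  sum(4L^config$K_values + config$lambda)
}

# Stable fingerprint of the encoder settings, stored in trained models so a
# model is never applied to features produced under different settings.
encoder_fingerprint <- function(config) {
  rlang::hash(list(config$K_values, config$lambda, config$omega,
                   lapply(config$property_tables, function(t) {
                     list(t$name, round(unname(t$values), 12))
                   })))
}

min_sequence_length <- function(config) max(config$K_values) + config$lambda

#' Normalized K-tuple frequencies of a sequence
#'
#' Counts overlapping windows of width K (step 1) and divides by the number
#' of windows, so the `4^K` frequencies sum to 1; tuples absent from the
#' sequence get 0.
#'
#' @param seq RNA sequence string over `{A, C, G, U}`.
#' @param K Tuple size.
#' @return Named numeric vector over all `4^K` tuples in lexicographic order.
#' @export
#' @examples
#' ktuple_frequencies("AUGC", 2)[c("AU", "UG", "GC")]
ktuple_frequencies <- function(seq, K) {
  wins <- sliding_tuples(seq, K)
  tuples <- all_ktuples(K)
  counts <- table(factor(wins, levels = tuples))
  out <- as.numeric(counts) / length(wins)
  names(out) <- tuples
  out
}

# Property rows for each window of the sequence: (L-K+1) x R matrix.
window_properties <- function(seq, K, table) {
  table$values[sliding_tuples(seq, K), , drop = FALSE]
}

#' Tier-j sequence-order correlation factor
#'
#' The j-th tier correlation factor is the average, over all positions i
#' with both a tuple at i and one j steps downstream, of the mean squared
#' difference of the R physicochemical properties of the two tuples:
#' `delta_j = mean_i mean_r (phi_r(tuple_i) - phi_r(tuple_{i+j}))^2`.
#' It is 0 when all tuples of the sequence are identical (homopolymers) or
#' when the property values are constant.
#'
#' @param seq RNA sequence string.
#' @param K Tuple size.
#' @param j Tier (1-based gap between tuple start positions).
#' @param table [property_table()] for this K.
#' @return Non-negative scalar.
#' @export
tier_correlation <- function(seq, K, j, table) {
  L <- nchar(seq)
  n_pairs <- L - K - j + 1L
  if (n_pairs < 1L) {
    abort(sprintf(
      "sequence of length %d is too short for tier j = %d at K = %d (minimum length %d)",
      L, j, K, K + j))
  }
  phi <- window_properties(seq, K, table)
  d <- phi[seq_len(n_pairs), , drop = FALSE] -
    phi[seq_len(n_pairs) + j, , drop = FALSE]
  mean(rowMeans(d^2))
}

#' Encode one K block of the PseKNC vector
#'
#' Computes the `4^K + lambda` block: tuple frequencies `g` and correlation
#' factors `delta_j` are jointly normalized as
#' `theta_m = g_m / (sum(g) + omega * sum(delta))` for the frequency part and
#' `theta_m = omega * delta_{m - 4^K} / (sum(g) + omega * sum(delta))` for
#' the correlation part, so every block sums to 1.
#'
#' @param seq RNA sequence string.
#' @param K Tuple size.
#' @param config [pseknc_config()] supplying `lambda`, `omega` and tables.
#' @return Named numeric vector of length `4^K + lambda`; names are
#'   `K{K}_{tuple}` then `K{K}_corr{j}`.
#' @export
encode_block <- function(seq, K, config = pseknc_config()) {
  g <- ktuple_frequencies(seq, K)
  table <- config$property_tables[[as.character(K)]] %||% default_property_table(K)
  delta <- vapply(seq_len(config$lambda), function(j) {
    tier_correlation(seq, K, j, table)
  }, numeric(1))
  denom <- sum(g) + config$omega * sum(delta)
  out <- c(g, config$omega * delta) / denom
  names(out) <- c(paste0("K", K, "_", names(g)),
                  paste0("K", K, "_corr", seq_len(config$lambda)))
  out
}

#' Encode a sequence into its full PseKNC feature vector
#'
#' Concatenates [encode_block()] over the configured tuple sizes in
#' ascending K. At the defaults this yields 19 + 67 + 259 + 1027 = 1372
#' features. The minimum sequence length is `max(K) + lambda` (8 at
#' defaults), enforced rather than silently dropping K blocks so that the
#' feature dimension is constant across a dataset.
#'
#' @param seq RNA sequence string over `{A, C, G, U}` (use [clean_dataset()]
#'   first for raw input).
#' @param config [pseknc_config()].
#' @return Named numeric vector of length [n_pseknc_features()].
#' @export
#' @examples
#' v <- encode_sequence("ACGUACGUACGUACGUACGUACGU")
#' length(v)  # 1372
encode_sequence <- function(seq, config = pseknc_config()) {
  min_len <- min_sequence_length(config)
  if (nchar(seq) < min_len) {
    abort(sprintf("sequence of length %d is below the minimum encodable length %d (max K + lambda)",
                  nchar(seq), min_len))
  }
  if (grepl(sprintf("[^%s]", paste(RNA_BASES, collapse = "")), seq)) {
    abort("sequence contains residues outside {A, C, G, U}; run clean_dataset() first")
  }
  unlist(lapply(config$K_values, encode_block, seq = seq, config = config))
}

#' Encode a dataset of sequence records into a feature matrix
#'
#' One row per record, or per mature/precursor pair for a combined-mode
#' tibble from [pair_combined()] (mature features prefixed `mat_`, precursor
#' features `pre_`, giving 2744 columns at defaults). The encoder
#' configuration is fingerprinted into the result so trained models can
#' refuse mismatched encodings.
#'
#' @param records Record tibble (`id`, `seq`, `label`) or pair tibble
#'   (`id`, `mature_seq`, `precursor_seq`, `label`).
#' @param config [pseknc_config()].
#' @return Tibble with `id`, `label` and one column per feature.
#' @export
encode_dataset <- function(records, config = pseknc_config()) {
  combined <- all(c("mature_seq", "precursor_seq") %in% names(records))
  if (!combined && !"seq" %in% names(records)) {
    abort("records must have a 'seq' column or 'mature_seq'/'precursor_seq' columns")
  }
  encode_all <- function(seqs) {
    bad <- character(0)
    rows <- lapply(seq_along(seqs), function(i) {
      tryCatch(encode_sequence(seqs[i], config), error = function(e) {
        bad <<- c(bad, records$id[i])
        NULL
      })
    })
    if (length(bad) > 0L) {
      abort(sprintf("unencodable sequence(s): %s", paste(bad, collapse = ", ")))
    }
    do.call(rbind, rows)
  }
  if (combined) {
    m <- encode_all(records$mature_seq)
    p <- encode_all(records$precursor_seq)
    colnames(m) <- paste0("mat_", colnames(m))
    colnames(p) <- paste0("pre_", colnames(p))
    feats <- cbind(m, p)
  } else {
    feats <- encode_all(records$seq)
  }
  out <- bind_cols(
    tibble(id = records$id,
           label = if ("label" %in% names(records)) records$label else NA_character_),
    as_tibble(feats)
  )
  attr(out, "encoder_fingerprint") <- encoder_fingerprint(config)
  attr(out, "pseknc_config") <- config
  out
}

#' Write an encoded feature matrix to a delimited file
#'
#' @param data Tibble from [encode_dataset()].
#' @param path Output path; `.csv` extension selects CSV, otherwise TSV.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(data, path) {
  if (grepl("\\.csv$", path)) {
    readr::write_csv(data, path, progress = FALSE)
  } else {
    readr::write_tsv(data, path, progress = FALSE)
  }
  invisible(path)
}
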