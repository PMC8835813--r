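#' Read RNA sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) FASTA file into a tibble of sequence
#' records, normalizing case and the DNA/RNA alphabet: sequences are
#' uppercased and `T` is rewritten to `U`, so DNA-alphabet FASTA files are
#' accepted without changing the feature space downstream.
#'
#' No residue filtering happens here: records containing residues outside
#' `{A, U, G, C}` are kept so that [clean_dataset()] can report them.
#'
#' @param path Path to a FASTA file.
#' @param role Either `"mature"` (~20-24 nt miRNA) or `"precursor"`
#'   (~80-120 nt pre-miRNA). Stored per record; encoding does not depend on
#'   it, but combined-mode pairing does.
#' @param label Optional label applied to every record in the file
#'   (`"positive"` or `"negative"`). Use this when positives and negatives
#'   arrive as separate FASTA files; per-record labels can instead be joined
#'   from [read_labels()].
#' @return A tibble with columns `id`, `seq`, `role`, `label`, `length`,
#'   one row per FASTA entry in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">mir1", "acguacgu", ">mir2", "UUGGCCAA"), fa)
#' read_fasta(fa, role = "mature")
read_fasta <- function(path, role = c("mature", "precursor"), label = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(sprintf("malformed FASTA in '%s': %s", path, conditionMessage(e)))
    }
  )
  if (length(set) == 0L) {
    abort(sprintf("no FASTA records in '%s'", path))
  }
  # FASTA headers may carry descriptions after the ID token
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate record IDs in '%s': %s", path,
                  paste(dup, collapse = ", ")))
  }
  seqs <- normalize_rna(as.character(set))
  if (!is.null(label)) check_labels(label)
  tibble(
    id = ids,
    seq = unname(seqs),
    role = role,
    label = if (is.null(label)) NA_character_ else label,
    length = nchar(unname(seqs))
  )
}

normalize_rna <- function(x) chartr("t", "U", chartr("T", "U", toupper(x)))

#' Write sequence records to a FASTA file
#'
#' @param records Tibble with `id` and `seq` columns.
#' @param path Output path.
#' @param width Line-wrap width; `Inf` writes one line per sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, filepath = path,
                              width = if (is.finite(width)) width else 20001L)
  invisible(path)
}

#' Read a two-column label file
#'
#' @param path TSV file with columns `id` and `label`
#'   (values `positive`/`negative`); a header line is optional.
#' @return Tibble with columns `id`, `label`.
#' @export
read_labels <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("id", "label"),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(tab) > 0L &&
      identical(unname(tolower(unlist(tab[1, ]))), c("id", "label"))) {
    tab <- tab[-1, ]
  }
  check_labels(tab$label)
  tab
}

#' Retrieve the provenance report of a filtered dataset
#'
#' [clean_dataset()] and [reduce_redundancy()] attach a plain-text log of the
#' filters applied, with counts; this accessor returns it.
#'
#' @param x A tibble returned by a filtering step.
#' @return Character vector of log lines (empty if none recorded).
#' @export
provenance <- function(x) attr(x, "provenance") %||% character(0)

add_provenance <- function(x, lines) {
  attr(x, "provenance") <- c(provenance(x), lines)
  x
}

#' Deduplicate and residue-filter a sequence dataset
#'
#' Applies the two standard cleaning rules for sequence classifier input:
#' exact-duplicate sequences are collapsed to their first occurrence, and
#' records containing any residue outside `{A, U, G, C}` are removed. The
#' counts removed under each rule are recorded in the [provenance()]
#' attribute. Cleaning is idempotent.
#'
#' @param records Tibble from [read_fasta()].
#' @return The retained records, with a provenance report attached.
#' @export
clean_dataset <- function(records) {
  n_in <- nrow(records)
  valid <- !grepl(sprintf("[^%s]", paste(RNA_BASES, collapse = "")), records$seq)
  n_bad <- sum(!valid)
  kept <- records[valid, , drop = FALSE]
  dup <- duplicated(kept$seq)
  n_dup <- sum(dup)
  kept <- kept[!dup, , drop = FALSE]
  if (nrow(kept) == 0L) {
    abort("no sequences survive filtering (all removed as duplicates or for non-standard residues)")
  }
  report <- c(
    sprintf("input records: %d", n_in),
    sprintf("removed (non-standard residues outside A/U/G/C): %d", n_bad),
    sprintf("removed (exact duplicate sequence, first kept): %d", n_dup),
    sprintf("retained: %d", nrow(kept))
  )
  add_provenance(as_tibble(kept), report)
}

# Maximum number of aligned matches between two sequences under global
# alignment with match +1, mismatch/indel 0 and free end gaps -- i.e. the
# length of the longest common subsequence.  Row-rolling DP.
lcs_length <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(y)
  prev <- integer(n + 1L)
  for (i in seq_along(x)) {
    cur <- integer(n + 1L)
    match_row <- c(0L, prev[-(n + 1L)] + as.integer(x[i] == y))
    for (j in seq_len(n) + 1L) {
      cur[j] <- max(match_row[j], cur[j - 1L], prev[j])
    }
    prev <- cur
  }
  prev[n + 1L]
}

#' Pairwise global-alignment identity of two short sequences
#'
#' Identity is matches / alignment-length under a global alignment scoring
#' match +1, mismatch and indel 0, with end gaps free. Under that scoring the
#' maximal number of matches is the longest common subsequence, and the
#' alignment length is `nchar(a) + nchar(b) - matches`.
#'
#' @param a,b Sequence strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  m <- lcs_length(a, b)
  m / (nchar(a) + nchar(b) - m)
}

#' Greedy redundancy reduction at a sequence-identity threshold
#'
#' Greedy clustering in input order, approximating the effect of CD-HIT-style
#' homology reduction on short RNAs: a record is retained iff its
#' [seq_identity()] to every already-retained record is below the threshold.
#' This is an exact all-pairs greedy clusterer, not a re-implementation of
#' CD-HIT's word-filter heuristics, so cluster membership can differ from
#' CD-HIT on borderline pairs.
#'
#' @param records Cleaned record tibble.
#' @param identity_threshold Fraction in `(0, 1]`; default 0.80.
#' @return Retained records, with provenance noting the count removed.
#' @export
reduce_redundancy <- function(records, identity_threshold = 0.8) {
  if (!is.numeric(identity_threshold) || length(identity_threshold) != 1L ||
      identity_threshold <= 0 || identity_threshold > 1) {
    abort("identity_threshold must be a single number in (0, 1]")
  }
  n <- nrow(records)
  keep <- logical(n)
  kept_seqs <- character(0)
  for (i in seq_len(n)) {
    s <- records$seq[i]
    redundant <- FALSE
    for (t in kept_seqs) {
      if (seq_identity(s, t) >= identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) {
      keep[i] <- TRUE
      kept_seqs <- c(kept_seqs, s)
    }
  }
  out <- records[keep, , drop = FALSE]
  add_provenance(
    out,
    sprintf("removed (>= %.0f%% identity to an earlier retained sequence): %d",
            100 * identity_threshold, n - nrow(out))
  )
}

#' Pair mature and precursor records by shared ID
#'
#' Builds the combined-mode dataset in which each observation is a mature
#' miRNA together with its precursor hairpin; downstream encoding
#' concatenates the two feature vectors (2744 columns at defaults). IDs
#' present in only one input are dropped with a warning (or are an error in
#' strict mode); paired records must agree on their label.
#'
#' @param mature,precursor Record tibbles (roles `mature` / `precursor`).
#' @param strict If `TRUE`, unmatched IDs are an error instead of a warning.
#' @return Tibble with one row per pair: `id`, `mature_seq`, `precursor_seq`,
#'   `label`.
#' @export
pair_combined <- function(mature, precursor, strict = FALSE) {
  only_m <- setdiff(mature$id, precursor$id)
  only_p <- setdiff(precursor$id, mature$id)
  unmatched <- c(only_m, only_p)
  if (length(unmatched) > 0L) {
    msg <- sprintf("%d ID(s) present in one input only, dropped: %s",
                   length(unmatched), paste(unmatched, collapse = ", "))
    if (strict) abort(msg) else warn(msg)
  }
  pairs <- inner_join(
    select(mature, id, mature_seq = "seq", mature_label = "label"),
    select(precursor, id, precursor_seq = "seq", precursor_label = "label"),
    by = "id"
  )
  disagree <- pairs$id[!is.na(pairs$mature_label) & !is.na(pairs$precursor_label) &
                         pairs$mature_label != pairs$precursor_label]
  if (length(disagree) > 0L) {
    abort(sprintf("label disagreement between paired records: %s",
                  paste(disagree, collapse = ", ")))
  }
  out <- tibble(
    id = pairs$id,
    mature_seq = pairs$mature_seq,
    precursor_seq = pairs$precursor_seq,
    label = ifelse(is.na(pairs$mature_label), pairs$precursor_label,
                   pairs$mature_label)
  )
  add_provenance(out, sprintf("paired records: %d (dropped unmatched: %d)",
                              nrow(out), length(unmatched)))
}
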