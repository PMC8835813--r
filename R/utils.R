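#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows bind_cols group_by
#'   ungroup summarise left_join inner_join anti_join distinct pull rename
#' @importFrom stats glm plogis predict quasibinomial runif sd setNames var
#' @importFrom utils head tail
NULL

RNA_BASES <- c("A", "C", "G", "U")

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream.  All stochastic steps in the package funnel through this so that a
# seed argument fully determines the result.
with_seed_ <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# All 4^K tuples over {A,C,G,U} in lexicographic order; leftmost position
# varies slowest so "AA..A" is first and "UU..U" last.
all_ktuples <- function(K) {
  stopifnot(K >= 1)
  grids <- rev(rep(list(RNA_BASES), K))
  mat <- as.matrix(rev(expand.grid(grids, stringsAsFactors = FALSE,
                                   KEEP.OUT.ATTRS = FALSE)))
  apply(mat, 1L, paste0, collapse = "")
}

# Overlapping windows of width K, step 1.
sliding_tuples <- function(seq, K) {
  L <- nchar(seq)
  if (L < K) {
    abort(sprintf("sequence of length %d is shorter than K = %d", L, K))
  }
  substring(seq, 1:(L - K + 1L), K:L)
}

is_feature_col <- function(nms) !nms %in% c("id", "label", "role", "seq", "length")

#' Names of the feature columns of an encoded dataset
#'
#' @param data A tibble as returned by [encode_dataset()].
#' @return Character vector of feature column names.
#' @export
feature_names <- function(data) {
  names(data)[is_feature_col(names(data))]
}

check_labels <- function(label) {
  bad <- !label %in% c("positive", "negative") & !is.na(label)
  if (any(bad)) {
    abort(sprintf("labels must be 'positive' or 'negative'; found: %s",
                  paste(unique(label[bad]), collapse = ", ")))
  }
  label
}

label_factor <- function(label) {
  factor(check_labels(label), levels = c("negative", "positive"))
}
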