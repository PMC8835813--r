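#' @include utils.R
NULL

# Six structural/thermodynamic properties of the 16 RNA dinucleotide steps
# (rise, roll, shift, slide, tilt, twist), as tabulated from A-form RNA
# crystallography and shipped with the common nucleotide-descriptor
# toolkits.  Raw (unstandardized) values; standardization happens at table
# construction.
rna_dinucleotide_raw <- function() {
  m <- matrix(c(
    # rise  roll  shift slide  tilt twist
    3.18,  7.0, -0.08, -1.27, -0.8, 31,   # AA
    3.24,  4.8,  0.23, -1.43,  0.8, 32,   # AC
    3.30,  8.5, -0.04, -1.50,  0.5, 30,   # AG
    3.24,  7.1, -0.06, -1.36,  1.1, 33,   # AU
    3.45,  9.9,  0.11, -1.46,  1.0, 31,   # CA
    3.22,  8.7, -0.01, -1.78,  0.3, 32,   # CC
    3.32, 12.1,  0.30, -1.89, -0.1, 27,   # CG
    3.30,  8.5,  0.04, -1.50, -0.5, 30,   # CU
    3.38,  9.4,  0.07, -1.70,  1.3, 32,   # GA
    3.22,  6.1,  0.07, -1.39,  0.0, 35,   # GC
    3.22,  8.7,  0.01, -1.78, -0.3, 32,   # GG
    3.24,  4.8, -0.23, -1.43, -0.8, 32,   # GU
    3.26, 10.7,  0.00, -1.45,  0.0, 32,   # UA
    3.38,  9.4, -0.07, -1.70, -1.3, 32,   # UC
    3.45,  9.9, -0.11, -1.46, -1.0, 31,   # UG
    3.18,  7.0,  0.08, -1.27,  0.8, 31    # UU
  ), nrow = 16, byrow = TRUE)
  dimnames(m) <- list(all_ktuples(2L),
                      c("rise", "roll", "shift", "slide", "tilt", "twist"))
  m
}

standardize_columns <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2L, sd)
  if (any(s == 0)) {
    abort("property with zero variance across tuples cannot be standardized")
  }
  scale(m, center = mu, scale = s)[, , drop = FALSE]
}

#' Construct a physicochemical property table for K-tuples
#'
#' A property table maps each of the `4^K` tuples over `{A, C, G, U}` to `R`
#' real-valued physicochemical properties. Values are z-score standardized
#' (mean 0, unit variance) across the `4^K` tuples at construction, so the
#' sequence-order correlation factors computed from them are scale-free.
#'
#' @param values Numeric matrix, `4^K` rows (rownames = tuples) by `R`
#'   property columns.
#' @param K Tuple size.
#' @param name Identifier for the property set.
#' @param standardize Standardize columns (default `TRUE`). Set `FALSE` only
#'   if `values` are already standardized.
#' @return An object of class `property_table`.
#' @export
property_table <- function(values, K, name = "custom", standardize = TRUE) {
  tuples <- all_ktuples(K)
  if (!is.matrix(values) || nrow(values) != length(tuples)) {
    abort(sprintf("property table for K = %d needs %d rows (one per tuple)",
                  K, length(tuples)))
  }
  if (is.null(rownames(values))) {
    abort("property values must have tuple rownames")
  }
  missing <- setdiff(tuples, rownames(values))
  if (length(missing) > 0L) {
    abort(sprintf("property table is missing tuples: %s%s",
                  paste(head(missing, 5L), collapse = ", "),
                  if (length(missing) > 5L) ", ..." else ""))
  }
  values <- values[tuples, , drop = FALSE]
  if (standardize) values <- standardize_columns(values)
  structure(
    list(K = K, R = ncol(values), values = values, name = name),
    class = "property_table"
  )
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table '%s': K = %d, %d tuples x %d properties>\n",
              x$name, x$K, nrow(x$values), x$R))
  invisible(x)
}

# cache: building the K = 5 table walks 1024 tuples
.property_cache <- new.env(parent = emptyenv())

#' Default property table for a given tuple size
#'
#' For `K = 2` this is the six standard RNA dinucleotide structural
#' properties (rise, roll, shift, slide, tilt, twist), standardized over the
#' 16 dinucleotides. For `K > 2` no canonical K-tuple property sets exist, so
#' each K-tuple is assigned the mean of its `K - 1` overlapping constituent
#' dinucleotides' standardized values, re-standardized over the `4^K` tuples.
#' Any table can be replaced via [read_property_table()].
#'
#' @param K Tuple size (>= 2).
#' @return A [property_table()].
#' @export
default_property_table <- function(K) {
  key <- as.character(K)
  if (!is.null(.property_cache[[key]])) {
    return(.property_cache[[key]])
  }
  if (K < 2) abort("default property tables are defined for K >= 2")
  dinuc <- standardize_columns(rna_dinucleotide_raw())
  if (K == 2) {
    out <- property_table(dinuc, 2L, name = "rna_dinucleotide_6",
                          standardize = FALSE)
  } else {
    tuples <- all_ktuples(K)
    vals <- t(vapply(tuples, function(tp) {
      steps <- substring(tp, 1:(K - 1L), 2:K)
      colMeans(dinuc[steps, , drop = FALSE])
    }, numeric(ncol(dinuc))))
    rownames(vals) <- tuples
    out <- property_table(vals, K,
                          name = sprintf("rna_dinucleotide_6_mean_K%d", K))
  }
  .property_cache[[key]] <- out
  out
}

#' Read a property table from a TSV file
#'
#' Expected format: header `tuple` followed by one column per property, one
#' row per K-tuple; all `4^K` tuples must be present. `T` is normalized to
#' `U` in the tuple column. Values are standardized on load.
#'
#' @param path TSV file path.
#' @param K Tuple size the table is for.
#' @param name Optional identifier; defaults to the file name.
#' @return A [property_table()].
#' @export
read_property_table <- function(path, K, name = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    tuple = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (!"tuple" %in% names(tab)) {
    abort("property table file must have a 'tuple' column")
  }
  vals <- as.matrix(tab[setdiff(names(tab), "tuple")])
  rownames(vals) <- normalize_rna(tab$tuple)
  property_table(vals, K, name = name %||% basename(path))
}
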