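#' Specification for a synthetic two-class miRNA dataset
#'
#' The simulator draws sequences from a "sticky" first-order Markov chain
#' over `{A, C, G, U}`: at each position the next base is drawn from a class
#' composition with probability `1 - rho` and repeats the current base with
#' probability `rho`. That chain has the class composition as its exact
#' stationary distribution (the initial base is drawn from it too) while the
#' self-persistence injects dinucleotide correlation, so the PseKNC
#' correlation tiers carry signal, not just the frequency blocks.
#'
#' Class separation is controlled by `effect` in `[0, 1]`: each class
#' generates from the composition
#' `(1 - effect) * midpoint + effect * class composition`, so `effect = 0`
#' makes the two classes identically distributed (a null dataset) and
#' `effect = 1` gives the full compositional contrast (default: GC-rich
#' positives vs AU-rich negatives).
#'
#' @param n_per_class Sequences per class.
#' @param length_mature Inclusive length range of mature sequences (nt).
#' @param length_precursor Inclusive length range of precursor sequences.
#' @param comp_positive,comp_negative Named base compositions
#'   (`A`, `C`, `G`, `U`), each summing to 1.
#' @param effect Separation knob in `[0, 1]`.
#' @param rho Self-persistence of the Markov chain in `[0, 1)`.
#' @param paired Also generate a precursor embedding each mature sequence.
#' @param seed Integer seed; output is reproducible byte-for-byte.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_per_class = 100L,
                     length_mature = c(20L, 24L),
                     length_precursor = c(80L, 120L),
                     comp_positive = c(A = 0.15, C = 0.35, G = 0.35, U = 0.15),
                     comp_negative = c(A = 0.35, C = 0.15, G = 0.15, U = 0.35),
                     effect = 1, rho = 0.25, paired = FALSE, seed = 1L) {
  check_comp <- function(p, what) {
    if (!all(RNA_BASES %in% names(p))) {
      abort(sprintf("%s must be named with A, C, G, U", what))
    }
    p <- p[RNA_BASES]
    if (any(p < 0)) abort(sprintf("%s has negative entries", what))
    if (abs(sum(p) - 1) > 1e-8) abort(sprintf("%s must sum to 1", what))
    p
  }
  if (effect < 0 || effect > 1) abort("effect must be in [0, 1]")
  if (rho < 0 || rho >= 1) abort("rho must be in [0, 1)")
  if (any(length_mature < 1) || any(length_precursor < 1)) {
    abort("length ranges must be positive")
  }
  structure(
    list(n_per_class = as.integer(n_per_class),
         length_mature = as.integer(length_mature),
         length_precursor = as.integer(length_precursor),
         comp_positive = check_comp(comp_positive, "comp_positive"),
         comp_negative = check_comp(comp_negative, "comp_negative"),
         effect = effect, rho = rho, paired = isTRUE(paired),
         seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# effective composition of a class after shrinking toward the midpoint
class_composition <- function(spec, class) {
  mid <- (spec$comp_positive + spec$comp_negative) / 2
  comp <- if (class == "positive") spec$comp_positive else spec$comp_negative
  (1 - spec$effect) * mid + spec$effect * comp
}

markov_seq <- function(len, comp, rho) {
  bases <- character(len)
  bases[1] <- sample(RNA_BASES, 1L, prob = comp)
  if (len > 1L) {
    for (i in 2:len) {
      bases[i] <- if (runif(1) < rho) bases[i - 1L] else sample(RNA_BASES, 1L, prob = comp)
    }
  }
  paste0(bases, collapse = "")
}

#' Generate a labeled synthetic dataset
#'
#' @param spec A [sim_spec()].
#' @return A list with `mature`: record tibble (`id`, `seq`, `role`,
#'   `label`, `length`), and, if `spec$paired`, `precursor`: records whose
#'   sequences contain the same-ID mature sequence verbatim at a random
#'   offset (flanks drawn from the same class chain).
#' @export
#' @examples
#' sim <- simulate_mirna_data(sim_spec(n_per_class = 5, seed = 42))
#' sim$mature
simulate_mirna_data <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed_(spec$seed, {
    mature <- list()
    precursor <- list()
    for (class in c("positive", "negative")) {
      comp <- class_composition(spec, class)
      tag <- if (class == "positive") "pos" else "neg"
      for (i in seq_len(spec$n_per_class)) {
        id <- sprintf("%s_%04d", tag, i)
        len_m <- sample(seq(spec$length_mature[1], spec$length_mature[2]), 1L)
        seq_m <- markov_seq(len_m, comp, spec$rho)
        mature[[id]] <- tibble(id = id, seq = seq_m, role = "mature",
                               label = class, length = len_m)
        if (spec$paired) {
          len_p <- sample(seq(spec$length_precursor[1], spec$length_precursor[2]), 1L)
          len_p <- max(len_p, len_m)
          n_flank <- len_p - len_m
          offset <- sample.int(n_flank + 1L, 1L) - 1L  # 5' flank length
          left <- if (offset > 0L) markov_seq(offset, comp, spec$rho) else ""
          right_len <- n_flank - offset
          right <- if (right_len > 0L) markov_seq(right_len, comp, spec$rho) else ""
          seq_p <- paste0(left, seq_m, right)
          precursor[[id]] <- tibble(id = id, seq = seq_p, role = "precursor",
                                    label = class, length = nchar(seq_p))
        }
      }
    }
    out <- list(mature = bind_rows(mature))
    if (spec$paired) out$precursor <- bind_rows(precursor)
    out
  })
}

#' Simulate and write a dataset to FASTA + truth files
#'
#' Writes `positive.fasta` / `negative.fasta` for mature sequences (plus
#' `positive_precursor.fasta` / `negative_precursor.fasta` in paired mode)
#' and a `truth.tsv` label file in the same two-column format consumed by
#' [read_labels()], so simulated fixtures flow through the command-line
#' pipeline unchanged.
#'
#' @param spec A [sim_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_mirna_data(spec)
  paths <- c()
  for (class in c("positive", "negative")) {
    sub <- filter(sim$mature, .data$label == class)
    p <- file.path(out_dir, paste0(class, ".fasta"))
    write_fasta(sub, p)
    paths[paste0(class, "_mature")] <- p
    if (!is.null(sim$precursor)) {
      subp <- filter(sim$precursor, .data$label == class)
      pp <- file.path(out_dir, paste0(class, "_precursor.fasta"))
      write_fasta(subp, pp)
      paths[paste0(class, "_precursor")] <- pp
    }
  }
  truth <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(sim$mature[c("id", "label")], truth, col_names = FALSE,
                   progress = FALSE)
  paths["truth"] <- truth
  invisible(paths)
}
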