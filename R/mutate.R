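#' Mutation spectra
#'
#' A mutation spectrum is a 4x4 row-stochastic table with zero diagonal: row b
#' gives the probability of each target base conditional on a mutation at a
#' source base b. Rows of bases declared immutable are all zero, and such
#' bases are silently never mutated.
#'
#' `spectrum_uniform()` mutates every base to each of the three others with
#' equal probability. `spectrum_transitions()` allows only A<->G and C<->T
#' swaps (purine-purine / pyrimidine-pyrimidine). `spectrum_ga_ct()` allows
#' only G->A and C->T, leaving A and T immutable — the strongly biased
#' spectrum characteristic of some editing-based mutagenesis methods.
#'
#' @param probs 4x4 numeric matrix, rows and columns ordered A, C, G, T.
#' @return An object of class `mutation_spectrum`.
#' @export
mutation_spectrum <- function(probs) {
  probs <- as.matrix(probs)
  if (!all(dim(probs) == c(4L, 4L))) abort("`probs` must be a 4x4 matrix.")
  dimnames(probs) <- list(DNA_BASES, DNA_BASES)
  if (any(diag(probs) != 0)) abort("Diagonal of a mutation spectrum must be zero.")
  if (any(probs < 0)) abort("Spectrum probabilities must be non-negative.")
  rs <- rowSums(probs)
  if (any(rs > 0 & abs(rs - 1) > 1e-8)) {
    abort("Each spectrum row must sum to 1 (or be all zero for an immutable base).")
  }
  structure(list(probs = probs), class = "mutation_spectrum")
}

#' @rdname mutation_spectrum
#' @export
spectrum_uniform <- function() {
  p <- matrix(1 / 3, 4, 4) - diag(1 / 3, 4)
  mutation_spectrum(p)
}

#' @rdname mutation_spectrum
#' @export
spectrum_transitions <- function() {
  p <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  p["A", "G"] <- 1; p["G", "A"] <- 1; p["C", "T"] <- 1; p["T", "C"] <- 1
  mutation_spectrum(p)
}

#' @rdname mutation_spectrum
#' @export
spectrum_ga_ct <- function() {
  p <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  p["G", "A"] <- 1; p["C", "T"] <- 1
  mutation_spectrum(p)
}

#' Construct a mutant library from explicit sequences
#'
#' Used for hand-built fixtures; [mutagenize()] is the random generator. The
#' per-position mutation mask is derived by direct comparison against the
#' wild type.
#'
#' @param sequences Character vector of variant sequences, all the same
#'   length as the wild type.
#' @param wild_type A [promoter()].
#' @return A `mutant_library`: a tibble with columns `variant` and `sequence`,
#'   carrying the wild type, TSS index and mutation mask as attributes.
#' @export
mutant_library <- function(sequences, wild_type) {
  stopifnot(inherits(wild_type, "promoter"))
  if (length(sequences) < 1L) abort("A library needs at least one variant.")
  if (any(nchar(sequences) != nchar(wild_type$bases))) {
    abort("All variants must have the same length as the wild type.")
  }
  bm <- seq_to_matrix(toupper(sequences))
  check_alphabet(bm)
  wt <- strsplit(wild_type$bases, "")[[1]]
  mask <- bm != matrix(wt, nrow(bm), ncol(bm), byrow = TRUE)
  out <- tibble::tibble(variant = seq_along(sequences), sequence = as.character(sequences))
  structure(out,
            class = c("mutant_library", class(out)),
            wild_type = wild_type,
            mask = mask * 1L)
}

#' Mutation mask of a library
#'
#' Returns the n x L binary matrix with entry 1 where variant i differs from
#' the wild type at position l. Recomputed from the sequences if the cached
#' attribute was stripped by data-frame operations.
#'
#' @param library A [mutant_library()].
#' @return Integer 0/1 matrix.
#' @export
library_mask <- function(library) {
  m <- attr(library, "mask")
  if (!is.null(m) && nrow(m) == nrow(library)) return(m)
  wt <- library_wild_type(library)
  bm <- seq_to_matrix(library$sequence)
  (bm != matrix(strsplit(wt$bases, "")[[1]], nrow(bm), ncol(bm), byrow = TRUE)) * 1L
}

#' @rdname library_mask
#' @export
library_wild_type <- function(library) {
  wt <- attr(library, "wild_type")
  if (is.null(wt)) abort("Library has lost its wild-type attribute; rebuild with mutant_library().")
  wt
}

#' Generate a random mutant promoter library
#'
#' Every position of every variant mutates independently with probability
#' `theta`; conditional on a mutation, the target base is drawn from the
#' spectrum row of the wild-type base. Bases whose spectrum row is all zero
#' are immutable and are silently skipped.
#'
#' @param wild_type A [promoter()].
#' @param n Library size (number of variants); default 5000, the size used
#'   throughout the package's reference simulations.
#' @param theta Per-base mutation rate in `[0, 1]`; default 0.1.
#' @param spectrum A [mutation_spectrum()]; default [spectrum_uniform()].
#' @param seed Integer seed; mutagenesis is fully reproducible under a fixed
#'   seed.
#' @param include_wild_type If `TRUE`, the unmutated wild type is prepended
#'   as variant 1 (default `FALSE`).
#' @return A [mutant_library()].
#' @export
#' @examples
#' lib <- mutagenize(default_promoter(), n = 10, theta = 0.1, seed = 7)
#' colMeans(library_mask(lib))[1:5]
mutagenize <- function(wild_type, n = 5000L, theta = 0.1,
                       spectrum = spectrum_uniform(), seed = 1L,
                       include_wild_type = FALSE) {
  stopifnot(inherits(wild_type, "promoter"), inherits(spectrum, "mutation_spectrum"))
  assert_scalar_number(theta, "theta", 0, 1)
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be >= 1.")
  wt <- strsplit(wild_type$bases, "")[[1]]
  L <- length(wt)
  mutable <- rowSums(spectrum$probs) > 0
  bm <- withr::with_seed(seed, {
    hit <- matrix(runif(n * L) < theta, n, L)
    hit[, !mutable[wt]] <- FALSE
    out <- matrix(wt, n, L, byrow = TRUE)
    for (b in DNA_BASES[mutable]) {
      cells <- which(hit & matrix(wt == b, n, L, byrow = TRUE))
      if (length(cells) > 0) {
        out[cells] <- sample(DNA_BASES, length(cells), replace = TRUE,
                             prob = spectrum$probs[b, ])
      }
    }
    out
  })
  seqs <- matrix_to_seq(bm)
  if (include_wild_type) seqs <- c(wild_type$bases, seqs)
  lib <- mutant_library(seqs, wild_type)
  attr(lib, "rate") <- theta
  attr(lib, "seed") <- seed
  lib
}

#' Design a promoter with engineered (possibly overlapping) binding sites
#'
#' Builds a promoter that maximizes binding strength given the energy
#' matrices of a polymerase and a repressor: at positions covered by a single
#' matrix the base minimizing that matrix's energy is chosen; at doubly
#' covered positions the base minimizing the sum of the two energies; all
#' other positions are filled with seeded random bases. Ties are broken
#' toward the alphabetically first base.
#'
#' @param rnap_matrix,repressor_matrix [energy_matrix()] objects; the
#'   polymerase site is placed at its own offset.
#' @param overlap_offset Display coordinate at which to place the repressor
#'   site (overriding the matrix's own offset), typically overlapping or
#'   abutting the polymerase site.
#' @param length,tss_index Promoter geometry (defaults 160 / 115).
#' @param seed Seed for the random background bases.
#' @return A [promoter()].
#' @export
design_overlap_promoter <- function(rnap_matrix, repressor_matrix,
                                    overlap_offset = repressor_matrix$offset,
                                    length = 160L, tss_index = 115L, seed = 1L) {
  stopifnot(inherits(rnap_matrix, "energy_matrix"),
            inherits(repressor_matrix, "energy_matrix"))
  bases <- withr::with_seed(seed, sample(DNA_BASES, length, replace = TRUE))
  score <- matrix(0, length, 4L, dimnames = list(NULL, DNA_BASES))
  covered <- logical(length)
  place <- function(em, offset) {
    idx <- display_to_index(offset, tss_index) + seq_len(em$site_length) - 1L
    if (idx[1] < 1L || idx[base::length(idx)] > length) {
      abort("Binding-site placement falls outside the promoter.")
    }
    score[idx, ] <<- score[idx, ] + em$energies
    covered[idx] <<- TRUE
  }
  place(rnap_matrix, rnap_matrix$offset)
  place(repressor_matrix, overlap_offset)
  pick <- apply(score[covered, , drop = FALSE], 1L, which.min)
  bases[covered] <- DNA_BASES[pick]
  promoter(paste0(bases, collapse = ""), tss_index)
}
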