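#' Create an energy matrix
#'
#' An energy matrix gives the additive per-position, per-base contribution (in
#' kBT) of a binding site to the total binding energy of one DNA-binding
#' factor. In the canonical wild-type-normalized form the entry for the
#' wild-type base at each position is 0 kBT, so the matrix reports the change
#' in binding energy of any mutation relative to the wild type.
#'
#' @param energies Numeric `l x 4` matrix with columns A, C, G, T (kBT).
#' @param offset Display (TSS-relative) coordinate of the site's first base.
#' @param factor_name Name of the binding factor (used to look up its copy
#'   number in [thermo_params()], e.g. "P", "R", "A").
#' @param factor_role One of "polymerase", "repressor", "activator".
#' @return An object of class `energy_matrix`.
#' @export
energy_matrix <- function(energies, offset, factor_name, factor_role) {
  energies <- as.matrix(energies)
  if (ncol(energies) != 4L) abort("`energies` must have 4 columns (A, C, G, T).")
  if (nrow(energies) < 1L) abort("`energies` must have at least one row.")
  if (any(!is.finite(energies))) abort("All energies must be finite.")
  colnames(energies) <- DNA_BASES
  factor_role <- match.arg(factor_role, c("polymerase", "repressor", "activator"))
  structure(
    list(energies = energies, offset = as.integer(offset),
         site_length = nrow(energies), factor_name = factor_name,
         factor_role = factor_role),
    class = "energy_matrix"
  )
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat(sprintf("<energy_matrix> %s (%s), %d bp at display %d..%d\n",
              x$factor_name, x$factor_role, x$site_length,
              x$offset, x$offset + x$site_length - 1L))
  print(utils::head(round(x$energies, 3), 10))
  if (x$site_length > 10) cat("...\n")
  invisible(x)
}

#' Display positions covered by an energy matrix
#'
#' @param x An [energy_matrix()].
#' @param informative_only If `TRUE` (default `FALSE`), return only positions
#'   with at least one nonzero entry, i.e. positions where mutations change
#'   the binding energy. Useful for averaging footprint signal over a site
#'   that contains zero-effect spacer (e.g. between the −35 and −10 elements).
#' @return Integer vector of display coordinates.
#' @export
site_positions <- function(x, informative_only = FALSE) {
  pos <- seq.int(x$offset, length.out = x$site_length)
  if (informative_only) pos <- pos[rowSums(abs(x$energies)) > 0]
  pos
}

#' Build a synthetic wild-type-normalized energy matrix
#'
#' Entries are 0 kBT at the wild-type base and `effect` kBT at each mutant
#' base, the convention used to construct energy matrices by hand when no
#' measured matrix is available. A subset of positions can be declared
#' informative; the remaining rows are all-zero spacer (mutations there have
#' no energetic effect).
#'
#' @param wild_type A [promoter()] supplying wild-type base identities.
#' @param offset Display coordinate of the site's first base.
#' @param length Site length in bp.
#' @param effect Energy penalty per mutant base (kBT, default 1).
#' @param informative 1-based positions within the site that carry the
#'   penalty; default all of them.
#' @inheritParams energy_matrix
#' @return An [energy_matrix()].
#' @export
synthetic_energy_matrix <- function(wild_type, offset, length, factor_name,
                                    factor_role, effect = 1,
                                    informative = seq_len(length)) {
  window <- strsplit(promoter_window(wild_type, offset, length), "")[[1]]
  e <- matrix(0, nrow = length, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  for (i in informative) {
    e[i, ] <- effect
    e[i, window[i]] <- 0
  }
  energy_matrix(e, offset, factor_name, factor_role)
}

#' Build an energy matrix anchored at a consensus sequence
#'
#' Entries are 0 kBT at the consensus base and `effect` kBT at the three
#' other bases; `N` in the consensus marks unconstrained (all-zero) spacer
#' positions. Unlike [synthetic_energy_matrix()], the matrix optimum is the
#' consensus rather than the wild type, so a promoter whose site differs
#' from consensus scores a positive energy — the situation of natural
#' promoters, whose elements are typically a few mismatches away from the
#' consensus motif. Used for non-specific-binding simulations where
#' near-consensus motifs elsewhere on the promoter can rival the canonical
#' site.
#'
#' @param consensus Character scalar over A/C/G/T/N.
#' @param effect Penalty per mutant base (kBT); scalar or one value per
#'   position.
#' @inheritParams energy_matrix
#' @return An [energy_matrix()].
#' @export
#' @examples
#' # sigma-70-like: weak -35 element, strong -10 element, 18-bp spacer
#' consensus_energy_matrix(paste0("TTGACA", strrep("N", 18), "TATAAT"),
#'                         offset = -36, factor_name = "P",
#'                         factor_role = "polymerase",
#'                         effect = c(rep(0.35, 6), rep(0, 18), rep(2, 6)))
consensus_energy_matrix <- function(consensus, offset, factor_name, factor_role,
                                    effect = 1) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(unique(chars), c(DNA_BASES, "N"))
  if (length(bad) > 0) abort("Consensus may contain only A, C, G, T or N.")
  l <- length(chars)
  effect <- rep_len(effect, l)
  e <- matrix(0, l, 4L, dimnames = list(NULL, DNA_BASES))
  for (i in seq_len(l)) {
    if (chars[i] != "N" && effect[i] != 0) {
      e[i, ] <- effect[i]
      e[i, chars[i]] <- 0
    }
  }
  energy_matrix(e, offset, factor_name, factor_role)
}

is_normalized <- function(x) {
  all(apply(x$energies, 1L, function(r) any(r == 0)))
}

#' Re-anchor an energy matrix to wild-type-normalized form
#'
#' Subtracts from each row the entry of the wild-type base over the site, so
#' the wild-type window scores 0 kBT.
#'
#' @param x An [energy_matrix()].
#' @param wild_type A [promoter()] giving the wild-type bases.
#' @return A normalized [energy_matrix()].
#' @export
normalize_matrix <- function(x, wild_type) {
  window <- strsplit(promoter_window(wild_type, x$offset, x$site_length), "")[[1]]
  wt_entries <- x$energies[cbind(seq_len(x$site_length), match(window, DNA_BASES))]
  x$energies <- sweep(x$energies, 1L, wt_entries, "-")
  x
}

#' Total binding energy of a sequence window
#'
#' Under the additivity assumption the total binding energy of a factor on a
#' window equals the sum of the matrix entries selected by the window's bases.
#'
#' @param window Character scalar; must have length equal to the matrix site
#'   length.
#' @param matrix An [energy_matrix()].
#' @return Energy in kBT.
#' @export
#' @examples
#' wt <- default_promoter()
#' em <- synthetic_energy_matrix(wt, 1, 20, "R", "repressor")
#' total_binding_energy(promoter_window(wt, 1, 20), em) # 0 by normalization
total_binding_energy <- function(window, matrix) {
  stopifnot(inherits(matrix, "energy_matrix"))
  chars <- strsplit(toupper(window), "")[[1]]
  if (length(chars) != matrix$site_length) {
    abort(sprintf("Window length %d does not match site length %d.",
                  length(chars), matrix$site_length))
  }
  check_alphabet(chars)
  sum(matrix$energies[cbind(seq_along(chars), match(chars, DNA_BASES))])
}

#' Average energetic effect of a mutation
#'
#' For a wild-type-normalized matrix, the mean change in binding energy per
#' mutated base, `(1/(3l)) * sum_i sum_{b != b_i} e[i, b]`: the sum of all
#' (mutant) entries divided by three mutant bases per position times the site
#' length.
#'
#' @param matrix A wild-type-normalized [energy_matrix()].
#' @return Mean mutation effect in kBT.
#' @export
average_mutation_effect <- function(matrix) {
  stopifnot(inherits(matrix, "energy_matrix"))
  if (!is_normalized(matrix)) {
    abort("Matrix is not wild-type-normalized (some row has no zero entry); see normalize_matrix().")
  }
  sum(matrix$energies) / (3 * matrix$site_length)
}

# per-variant total binding energies of one site over a base matrix
# (n x L character matrix from seq_to_matrix), in kBT
site_energies <- function(base_matrix, em, tss_index, offset = em$offset) {
  i0 <- display_to_index(offset, tss_index)
  idx <- seq.int(i0, length.out = em$site_length)
  if (idx[1] < 1L || idx[length(idx)] > ncol(base_matrix)) {
    abort("Binding site falls outside the promoter.")
  }
  n <- nrow(base_matrix)
  e <- numeric(n)
  for (k in seq_len(em$site_length)) {
    e <- e + unname(em$energies[k, ])[match(base_matrix[, idx[k]], DNA_BASES)]
  }
  e
}
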