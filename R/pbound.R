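#' Probability of RNA polymerase occupancy (states-and-weights engine)
#'
#' Evaluates the equilibrium probability that RNA polymerase occupies the
#' promoter for every variant in a library, by enumerating all occupancy
#' states allowed by the architecture's repression logic. The weight of a
#' state is the product over bound factors of `(copies/N_NS) *
#' exp(-beta * eps)` (with `eps` the sequence-dependent total binding energy
#' of the factor's site on that variant), times `exp(-beta * omega)` for each
#' interacting pair bound together. `p_bound` is the summed weight of
#' transcriptionally active states (any state with polymerase bound) over the
#' full partition function. Weights are accumulated in log space.
#'
#' @param library A [mutant_library()], a [promoter()], or a character vector
#'   of sequences (with `tss_index` supplied).
#' @param architecture An [mpra_architecture()].
#' @param params A [thermo_params()]; copy numbers may be per-variant
#'   vectors.
#' @param tss_index TSS index, only needed when `library` is a bare character
#'   vector.
#' @return Numeric vector of `p_bound` values in (0, 1), one per variant.
#' @export
#' @examples
#' arch <- architecture_preset("simple_repression")
#' pbound(default_promoter(), arch)
pbound <- function(library, architecture, params = thermo_params(),
                   tss_index = NULL) {
  stopifnot(inherits(architecture, "mpra_architecture"))
  lw <- site_log_weights(library, architecture, params, tss_index)
  states <- enumerate_states(architecture)
  state_lw <- vapply(seq_along(states$subsets), function(s) {
    idx <- states$subsets[[s]]
    if (length(idx) == 0) rep(0, nrow(lw))
    else rowSums(lw[, idx, drop = FALSE]) - states$omega[s]
  }, numeric(nrow(lw)))
  if (nrow(lw) == 1L) state_lw <- matrix(state_lw, nrow = 1L)
  active <- states$active
  if (!any(active)) abort("Architecture has no polymerase site; p_bound is undefined.")
  exp(logsumexp_rows(state_lw[, active, drop = FALSE]) - logsumexp_rows(state_lw))
}

# n x k matrix of per-site log Boltzmann weights
site_log_weights <- function(library, architecture, params, tss_index = NULL) {
  seqs_tss <- resolve_sequences(library, tss_index)
  bm <- seq_to_matrix(seqs_tss$sequences)
  check_alphabet(bm)
  k <- length(architecture$sites)
  lw <- matrix(0, nrow(bm), k)
  for (j in seq_len(k)) {
    site <- architecture$sites[[j]]
    copies <- params[[site$factor]]
    if (is.null(copies)) abort(sprintf("No copy number `%s` in params.", site$factor))
    e <- site$wt_energy + site_energies(bm, site$matrix, seqs_tss$tss_index)
    lw[, j] <- log(copies / params$N_NS) - e
  }
  lw
}

resolve_sequences <- function(library, tss_index = NULL) {
  if (inherits(library, "mutant_library")) {
    list(sequences = library$sequence,
         tss_index = library_wild_type(library)$tss_index)
  } else if (inherits(library, "promoter")) {
    list(sequences = library$bases, tss_index = library$tss_index)
  } else if (is.character(library)) {
    if (is.null(tss_index)) abort("Supply `tss_index` for bare character sequences.")
    list(sequences = library, tss_index = as.integer(tss_index))
  } else {
    abort("`library` must be a mutant_library, promoter, or character vector.")
  }
}

# all occupancy states allowed by the logic, with precomputed interaction
# energies and activity flags
enumerate_states <- function(architecture) {
  k <- length(architecture$sites)
  roles <- arch_roles(architecture)
  rep_idx <- which(roles == "repressor")
  pol_idx <- which(roles == "polymerase")
  subsets <- unlist(lapply(0:k, function(m) utils::combn(k, m, simplify = FALSE)),
                    recursive = FALSE)
  keep <- vapply(subsets, function(idx) {
    has_pol <- any(pol_idx %in% idx)
    if (!has_pol) return(TRUE)
    !represses(sum(rep_idx %in% idx), length(rep_idx), architecture$logic)
  }, logical(1))
  subsets <- subsets[keep]
  fac <- names(architecture$sites)
  omega <- vapply(subsets, function(idx) {
    bound <- fac[idx]
    sum(vapply(architecture$interactions, function(int) {
      if (all(int$pair %in% bound)) int$omega else 0
    }, numeric(1)))
  }, numeric(1))
  active <- vapply(subsets, function(idx) any(pol_idx %in% idx), logical(1))
  list(subsets = subsets, omega = omega, active = active)
}

represses <- function(n_bound, n_repressors, logic) {
  if (n_repressors == 0L || n_bound == 0L) return(FALSE)
  switch(logic,
         independent = ,
         OR = n_bound >= 1L,
         AND = n_bound == n_repressors,
         XOR = n_bound == 1L,
         abort(sprintf("Unknown logic '%s'.", logic)))
}
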