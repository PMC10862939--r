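#' Sigma-70-like consensus polymerase matrix
#'
#' A 30-bp consensus-anchored polymerase matrix (TTGACA −35 element, 18-bp
#' unconstrained spacer, TATAAT −10 element, spanning display −36..−7) for
#' non-specific-binding simulations. The −35 element carries a weak
#' per-base penalty and the −10 element a strong one, mirroring the relative
#' contributions of the two elements in measured polymerase matrices; with
#' a wild-type −10 element a couple of mismatches from consensus, a
#' near-consensus TATA-like motif inserted elsewhere on the promoter can
#' out-compete the canonical site and become a functional non-canonical
#' binding site.
#'
#' @param effect_35,effect_10 Per-base mutant penalties (kBT) of the −35 and
#'   −10 hexamers.
#' @return An [energy_matrix()].
#' @export
sigma70_consensus_matrix <- function(effect_35 = 0.35, effect_10 = 2) {
  consensus_energy_matrix(paste0("TTGACA", strrep("N", 18), "TATAAT"),
                          offset = -36L, factor_name = "P",
                          factor_role = "polymerase",
                          effect = c(rep(effect_35, 6), rep(0, 18),
                                     rep(effect_10, 6)))
}

#' Polymerase occupancy with genome-wide non-specific promoter binding
#'
#' Extends the simple-repression model so that polymerase may bind at every
#' possible start index along the promoter, one mutually exclusive state per
#' window: for window i the binding energy is the polymerase site's
#' wild-type energy plus the energy-matrix score of the window sequence, and
#' the state's weight is `(P/N_NS) * exp(-eps_i)`. The repressor excludes
#' polymerase binding (mutual exclusion, as in the single-site model), so the
#' states are empty, repressor-bound, and one polymerase-bound state per
#' window. By default every polymerase-bound state is transcriptionally
#' active; `active_windows` restricts activity to windows whose start display
#' coordinate falls in a declared start-site set.
#'
#' @inheritParams pbound
#' @param architecture A simple-repression (or constitutive)
#'   [mpra_architecture()]; default the simple-repression preset anchored on
#'   the library's wild type.
#' @param active_windows Optional integer vector of display coordinates; if
#'   given, only polymerase windows starting at these coordinates count as
#'   active (they all still contribute to the partition function).
#' @return Numeric vector of `p_bound` values, one per variant.
#' @export
pbound_nonspecific <- function(library, params = thermo_params(),
                               architecture = NULL, active_windows = NULL,
                               tss_index = NULL) {
  w <- nonspecific_window_weights(library, params, architecture, tss_index)
  lw_p <- w$log_weights            # n x n_windows
  lw_r <- w$log_weight_repressor   # n (or NULL)
  z_cols <- cbind(0, lw_p, lw_r)
  act <- lw_p
  if (!is.null(active_windows)) {
    keep <- w$window_start %in% active_windows
    if (!any(keep)) abort("No polymerase window starts at the declared start sites.")
    act <- lw_p[, keep, drop = FALSE]
  }
  exp(logsumexp_rows(act) - logsumexp_rows(z_cols))
}

#' @rdname pbound_nonspecific
#' @return `nonspecific_window_weights()` returns a list with `window_start`
#'   (display coordinate of each window), the `n x n_windows` matrix
#'   `log_weights` of polymerase window log-weights, and
#'   `log_weight_repressor` (per-variant, `NULL` for a constitutive
#'   architecture).
#' @export
nonspecific_window_weights <- function(library, params = thermo_params(),
                                       architecture = NULL, tss_index = NULL) {
  seqs_tss <- resolve_sequences(library, tss_index)
  if (is.null(architecture)) {
    wt <- if (inherits(library, "mutant_library")) library_wild_type(library)
          else promoter(seqs_tss$sequences[1], seqs_tss$tss_index)
    architecture <- architecture_preset("simple_repression", wild_type = wt)
  }
  roles <- arch_roles(architecture)
  pol <- architecture$sites[[which(roles == "polymerase")[1]]]
  bm <- seq_to_matrix(seqs_tss$sequences)
  L <- ncol(bm)
  lp <- pol$matrix$site_length
  if (L <= lp) abort("Promoter must be longer than the polymerase matrix.")
  starts_idx <- seq_len(L - lp + 1L)
  starts_disp <- starts_idx - 1L - seqs_tss$tss_index
  lw_p <- vapply(starts_disp, function(d) {
    e <- pol$wt_energy + site_energies(bm, pol$matrix, seqs_tss$tss_index, offset = d)
    log(params$P / params$N_NS) - e
  }, numeric(nrow(bm)))
  if (nrow(bm) == 1L) lw_p <- matrix(lw_p, nrow = 1L)
  lw_r <- NULL
  rep_i <- which(roles == "repressor")
  if (length(rep_i) > 0) {
    rep <- architecture$sites[[rep_i[1]]]
    e_r <- rep$wt_energy + site_energies(bm, rep$matrix, seqs_tss$tss_index)
    lw_r <- log(params[[rep$factor]] / params$N_NS) - e_r
  }
  list(window_start = starts_disp, log_weights = lw_p, log_weight_repressor = lw_r)
}
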