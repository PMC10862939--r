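#' Thermodynamic parameters
#'
#' Copy numbers and global constants of the states-and-weights models. Copy
#' numbers are looked up by the factor names used in the architecture's
#' binding sites ("P", "R", "R1", "R2", "A", "A1", "A2"). Any copy-number
#' field may also be a per-variant numeric vector (used for extrinsic-noise
#' simulations). `N_NS` is the non-specific genomic background (default the
#' E. coli genome size, 4e6 bp) and `alpha` the count scale r/gamma mapping
#' occupancy to expected mRNA counts (default 100). The inverse thermal
#' energy beta is fixed at 1 per kBT throughout the package.
#'
#' @param P,R,R1,R2,A,A1,A2 Factor copy numbers (non-negative).
#' @param N_NS Number of non-specific background sites (> 0).
#' @param alpha Count scale (> 0).
#' @return A list of class `thermo_params`.
#' @export
thermo_params <- function(P = 1000, R = 10, R1 = 10, R2 = 10,
                          A = 100, A1 = 100, A2 = 100,
                          N_NS = 4e6, alpha = 100) {
  pars <- list(P = P, R = R, R1 = R1, R2 = R2, A = A, A1 = A1, A2 = A2,
               N_NS = N_NS, alpha = alpha)
  for (nm in c("P", "R", "R1", "R2", "A", "A1", "A2")) {
    if (any(pars[[nm]] < 0)) abort(sprintf("Copy number `%s` must be >= 0.", nm))
  }
  assert_scalar_number(N_NS, "N_NS", min = 1e-12)
  assert_scalar_number(alpha, "alpha", min = 1e-12)
  structure(pars, class = "thermo_params")
}

#' MWC (Monod-Wyman-Changeux) induction parameters
#'
#' Two-state allosteric model of an inducible repressor with two inducer
#' binding sites. Defaults are the inferred values for LacI/IPTG:
#' KA = 139e-6 M, KI = 0.53e-6 M, structural gap 4.5 kBT.
#'
#' @param K_A Inducer dissociation constant of the active conformation (M).
#' @param K_I Inducer dissociation constant of the inactive conformation (M).
#' @param delta_eps_AI Active/inactive structural energy gap (kBT).
#' @param eps_rdA Binding energy of the active repressor at its operator
#'   (kBT, wild-type window).
#' @param eps_rdI Binding energy of the inactive repressor (weak-binding
#'   state, kBT).
#' @return A list of class `mwc_params`.
#' @export
mwc_params <- function(K_A = 139e-6, K_I = 0.53e-6, delta_eps_AI = 4.5,
                       eps_rdA = -15, eps_rdI = -2) {
  assert_scalar_number(K_A, "K_A", min = .Machine$double.xmin)
  assert_scalar_number(K_I, "K_I", min = .Machine$double.xmin)
  assert_scalar_number(delta_eps_AI, "delta_eps_AI")
  structure(list(K_A = K_A, K_I = K_I, delta_eps_AI = delta_eps_AI,
                 eps_rdA = eps_rdA, eps_rdI = eps_rdI, n_sites = 2L),
            class = "mwc_params")
}
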