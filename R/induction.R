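#' Probability that an allosteric repressor is in its active conformation
#'
#' Two-state MWC model with two inducer binding sites:
#' `p_active(c) = (1 + c/K_A)^2 / ((1 + c/K_A)^2 +
#' exp(-beta * delta_eps_AI) * (1 + c/K_I)^2)`.
#'
#' @param c Inducer concentration (M, >= 0); vectorized.
#' @param mwc An [mwc_params()].
#' @return Probability in (0, 1).
#' @export
#' @examples
#' pactive_mwc(0, mwc_params())  # 1 / (1 + exp(-delta_eps_AI))
pactive_mwc <- function(c, mwc = mwc_params()) {
  stopifnot(inherits(mwc, "mwc_params"))
  if (any(c < 0)) abort("Inducer concentration must be >= 0.")
  act <- (1 + c / mwc$K_A)^2
  inact <- exp(-mwc$delta_eps_AI) * (1 + c / mwc$K_I)^2
  act / (act + inact)
}

#' Polymerase occupancy under an inducible repressor
#'
#' Splits the repressor pool into `R_A = p_active * R` active and
#' `R_I = (1 - p_active) * R` inactive molecules and evaluates the four-state
#' occupancy
#' `p_bound = w_P / (1 + w_RA + w_RI + w_P)`,
#' where both repressor conformations read the same operator energy matrix
#' but from different wild-type binding energies (the inactive state binds
#' weakly, `eps_rdI`).
#'
#' @inheritParams pbound
#' @param c Inducer concentration (M).
#' @param mwc An [mwc_params()].
#' @param architecture A simple-repression [mpra_architecture()] (polymerase
#'   site + repressor site); default the preset anchored on the library's
#'   wild type. The repressor site's `wt_energy` is overridden by
#'   `mwc$eps_rdA` / `mwc$eps_rdI`.
#' @return Numeric vector of `p_bound` values, one per variant.
#' @export
pbound_induction <- function(library, c, mwc = mwc_params(),
                             params = thermo_params(), architecture = NULL,
                             tss_index = NULL) {
  seqs_tss <- resolve_sequences(library, tss_index)
  if (is.null(architecture)) {
    architecture <- architecture_preset(
      "simple_repression",
      wild_type = promoter(seqs_tss$sequences[1], seqs_tss$tss_index))
    if (inherits(library, "mutant_library")) {
      architecture <- architecture_preset("simple_repression",
                                          wild_type = library_wild_type(library))
    }
  }
  roles <- arch_roles(architecture)
  pol <- architecture$sites[[which(roles == "polymerase")[1]]]
  rep <- architecture$sites[[which(roles == "repressor")[1]]]
  bm <- seq_to_matrix(seqs_tss$sequences)
  e_p <- pol$wt_energy + site_energies(bm, pol$matrix, seqs_tss$tss_index)
  e_seq <- site_energies(bm, rep$matrix, seqs_tss$tss_index)
  p_act <- pactive_mwc(c, mwc)
  w_p <- (params$P / params$N_NS) * exp(-e_p)
  w_ra <- (p_act * params$R / params$N_NS) * exp(-(mwc$eps_rdA + e_seq))
  w_ri <- ((1 - p_act) * params$R / params$N_NS) * exp(-(mwc$eps_rdI + e_seq))
  w_p / (1 + w_ra + w_ri + w_p)
}
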