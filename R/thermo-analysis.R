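#' Rescaled Boltzmann weight of a bound factor
#'
#' The dimensionless statistical weight `(copies/N_NS) * exp(-beta * eps)` a
#' bound factor contributes to the promoter partition function.
#'
#' @param copies Factor copy number (> 0 for a nonzero weight).
#' @param delta_eps Binding energy relative to the non-specific background
#'   (kBT).
#' @param N_NS Number of non-specific sites (default 4e6).
#' @return Dimensionless weight.
#' @export
#' @examples
#' boltzmann_weight(1000, -5)  # polymerase weight, about 0.04
#' boltzmann_weight(10, -15)   # repressor weight, about 8
boltzmann_weight <- function(copies, delta_eps, N_NS = 4e6) {
  (copies / N_NS) * exp(-delta_eps)
}

#' Binding free energy of a transcription factor
#'
#' `F = delta_eps - kBT * ln(copies/N_NS)`: enthalpic binding energy plus the
#' entropic cost of localizing one of `copies` molecules out of the
#' non-specific reservoir. Under weak polymerase binding, simple-repression
#' occupancy is `exp(-F_P) / (1 + exp(-F_R))`.
#'
#' @inheritParams boltzmann_weight
#' @return Free energy in kBT.
#' @export
#' @examples
#' free_energy(10, -10)  # about 3 kBT
#' free_energy(10, -20)  # about -7 kBT
free_energy <- function(copies, delta_eps, N_NS = 4e6) {
  if (any(copies == 0)) {
    abort("`copies` = 0: the entropic term -ln(copies/N_NS) diverges; free energy is undefined.")
  }
  delta_eps - log(copies / N_NS)
}

#' Repressor/polymerase Boltzmann-weight ratio kappa
#'
#' `kappa = (R/P) * exp(-beta * (eps_r - eps_p + m_r * ddE_r - m_p * ddE_p))`,
#' the ratio of the repressor and polymerase statistical weights after `m_r`
#' and `m_p` mutations of mean effect `ddE_r` and `ddE_p` (kBT) in the
#' respective sites. `kappa_theta()` substitutes the expected mutation counts
#' `m = theta * l` for a library with per-base mutation rate `theta`.
#'
#' @param R,P Repressor and polymerase copy numbers (`P > 0`).
#' @param eps_r,eps_p Wild-type binding energies (kBT).
#' @param m_r,m_p Mutation counts in the repressor and polymerase sites.
#' @param ddE_r,ddE_p Mean per-mutation energy shifts (kBT), e.g. from
#'   [average_mutation_effect()].
#' @return Dimensionless ratio.
#' @export
kappa <- function(R, P, eps_r, eps_p, m_r = 0, m_p = 0, ddE_r = 0, ddE_p = 0) {
  if (any(P == 0)) abort("`P` = 0: the weight ratio kappa is undefined.")
  (R / P) * exp(-(eps_r - eps_p + m_r * ddE_r - m_p * ddE_p))
}

#' @rdname kappa
#' @param theta Per-base mutation rate.
#' @param l_r,l_p Repressor and polymerase binding-site lengths (bp).
#' @export
kappa_theta <- function(theta, R, P, eps_r, eps_p, l_r, l_p, ddE_r, ddE_p) {
  kappa(R, P, eps_r, eps_p, m_r = theta * l_r, m_p = theta * l_p,
        ddE_r = ddE_r, ddE_p = ddE_p)
}

#' Optimal library mutation rate
#'
#' The mutation rate at which the repressor and polymerase Boltzmann weights
#' are equal (`kappa(theta) = 1`), putting the two binding events on an equal
#' footing in the information footprint. Closed form:
#' `theta* = (ln(R/P) - (eps_r - eps_p)) / (l_r * ddE_r - l_p * ddE_p)`.
#' Values outside `[0, 1]` are clipped, with attribute `clipped = TRUE` and a
#' warning.
#'
#' @inheritParams kappa_theta
#' @return Optimal rate in `[0, 1]` (attribute `clipped` marks clipping).
#' @export
optimal_mutation_rate <- function(R, P, eps_r, eps_p, l_r, l_p, ddE_r, ddE_p) {
  denom <- l_r * ddE_r - l_p * ddE_p
  if (abs(denom) < 1e-300) {
    abort("l_r * ddE_r - l_p * ddE_p = 0: kappa does not depend on theta, no solution.")
  }
  theta <- (log(R / P) - (eps_r - eps_p)) / denom
  clipped <- theta < 0 | theta > 1
  if (any(clipped)) {
    warn("Optimal mutation rate outside [0, 1]; clipped.")
    theta <- pmin(pmax(theta, 0), 1)
  }
  structure(theta, clipped = clipped)
}

#' Repressor binding energy at a target weight ratio
#'
#' Inverts [kappa()] for the repressor binding energy: the `eps_r` at which
#' the weight ratio equals `kappa_target`, holding everything else fixed.
#' Used to locate the detection threshold below which the repressor-site
#' footprint signal vanishes (kappa of about 0.1).
#'
#' @param kappa_target Target weight ratio (> 0).
#' @inheritParams kappa
#' @return Binding energy in kBT.
#' @export
#' @examples
#' repressor_energy_for_kappa(0.1, R = 10, P = 1000, eps_p = -5,
#'                            m_r = 2, m_p = 2, ddE_r = 2.24, ddE_p = 0.36)
repressor_energy_for_kappa <- function(kappa_target, R, P, eps_p,
                                       m_r = 0, m_p = 0, ddE_r = 0, ddE_p = 0) {
  assert_scalar_number(kappa_target, "kappa_target", min = .Machine$double.xmin)
  eps_p - m_r * ddE_r + m_p * ddE_p - log(kappa_target * P / R)
}
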