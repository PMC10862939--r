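#' Solve the fugacity constraining average bound copy number
#'
#' Grand-canonical treatment of a factor partitioned between a set of
#' specific binding sites and a reservoir of `N_NS` non-specific sites at
#' zero energy: finds the fugacity `lambda >= 0` such that
#' `sum_j lambda * exp(-eps_j) / (1 + lambda * exp(-eps_j)) +
#'  N_NS * lambda / (1 + lambda) = copies`.
#' Because each site exchanges particles with the reservoir independently,
#' the partition function factorizes over sites and the occupancy of site j
#' is `lambda * exp(-eps_j) / (1 + lambda * exp(-eps_j))`. The root is found
#' by monotone bracketed bisection on the log-fugacity scale to relative
#' tolerance 1e-10.
#'
#' @param copies Average total number of bound molecules to enforce (>= 0).
#' @param site_energies Numeric vector of specific-site energies (kBT).
#' @param N_NS Reservoir size (number of zero-energy non-specific sites).
#' @param tol Relative tolerance of the root.
#' @return A list with `lambda`, per-site `occupancy`, and
#'   `reservoir_occupancy` (the average number bound in the reservoir).
#' @export
#' @examples
#' solve_fugacity(10, rep(-15, 50))$occupancy[1]
solve_fugacity <- function(copies, site_energies, N_NS = 4e6, tol = 1e-10) {
  assert_scalar_number(copies, "copies", min = 0)
  if (any(!is.finite(site_energies))) abort("Site energies must be finite.")
  n_sites <- length(site_energies)
  total_capacity <- n_sites + N_NS
  if (copies >= total_capacity) {
    abort(sprintf("copies = %g exceeds the total site count %g; constraint infeasible.",
                  copies, total_capacity))
  }
  if (copies == 0) {
    return(list(lambda = 0, occupancy = rep(0, n_sites), reservoir_occupancy = 0))
  }
  bound_total <- function(lambda) {
    x <- lambda * exp(-site_energies)
    sum(x / (1 + x)) + N_NS * lambda / (1 + lambda)
  }
  lam0 <- copies / (N_NS + sum(exp(-site_energies)))
  lo <- lam0
  while (bound_total(lo) > copies) lo <- lo / 2
  hi <- max(lam0, 1)
  while (bound_total(hi) < copies) hi <- hi * 2
  root <- uniroot(function(u) bound_total(exp(u)) - copies,
                  interval = c(log(lo) - 1e-9, log(hi) + 1e-9),
                  tol = tol * 1e-3, maxiter = 1000L)
  lambda <- exp(root$root)
  x <- lambda * exp(-site_energies)
  list(lambda = lambda, occupancy = x / (1 + x),
       reservoir_occupancy = N_NS * lambda / (1 + lambda))
}

#' Polymerase occupancy with multiple repressor binding-site copies
#'
#' Models a plasmid-borne reporter: the repressor's binding site exists in
#' `n_sites` identical copies (all carrying the variant's sequence) which
#' compete for a fixed repressor pool. The repressor's chemical potential is
#' solved per variant with [solve_fugacity()]; the reporter's repressor site
#' then contributes the grand-canonical weight `lambda * exp(-eps_r)` in
#' place of the canonical single-site Boltzmann weight, so
#' `p_bound = w_P / (1 + w_P + lambda * exp(-eps_r))`. As `n_sites` grows the
#' additional sites titrate the repressor away and `p_bound` approaches the
#' constitutive value. Polymerase is treated canonically (its own site is
#' present in one copy).
#'
#' @inheritParams pbound
#' @param n_sites Repressor binding-site copy number (>= 1).
#' @param architecture A simple-repression [mpra_architecture()]; default the
#'   preset anchored on the library's wild type.
#' @return Numeric vector of `p_bound` values, one per variant.
#' @export
pbound_multicopy <- function(library, params = thermo_params(), n_sites = 1L,
                             architecture = NULL, tss_index = NULL) {
  n_sites <- as.integer(n_sites)
  if (n_sites < 1L) abort("`n_sites` must be >= 1.")
  seqs_tss <- resolve_sequences(library, tss_index)
  if (is.null(architecture)) {
    wt <- if (inherits(library, "mutant_library")) library_wild_type(library)
          else promoter(seqs_tss$sequences[1], seqs_tss$tss_index)
    architecture <- architecture_preset("simple_repression", wild_type = wt)
  }
  roles <- arch_roles(architecture)
  pol <- architecture$sites[[which(roles == "polymerase")[1]]]
  rep <- architecture$sites[[which(roles == "repressor")[1]]]
  bm <- seq_to_matrix(seqs_tss$sequences)
  e_p <- pol$wt_energy + site_energies(bm, pol$matrix, seqs_tss$tss_index)
  e_r <- rep$wt_energy + site_energies(bm, rep$matrix, seqs_tss$tss_index)
  copies_r <- params[[rep$factor]]
  w_p <- (params$P / params$N_NS) * exp(-e_p)
  w_r_eff <- vapply(seq_along(e_r), function(i) {
    sol <- solve_fugacity(copies_r, rep(e_r[i], n_sites), N_NS = params$N_NS)
    sol$lambda * exp(-e_r[i])
  }, numeric(1))
  w_p / (1 + w_p + w_r_eff)
}
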