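#' Define a binding site for a states-and-weights model
#'
#' A binding site couples an [energy_matrix()] (the sequence-dependent change
#' in binding energy) with the wild-type binding energy of the factor at the
#' site, so the total energy of a variant window is
#' `wt_energy + total_binding_energy(window, matrix)`.
#'
#' @param matrix An [energy_matrix()].
#' @param wt_energy Wild-type binding energy relative to the non-specific
#'   background (kBT, typically negative).
#' @return A list of class `binding_site`.
#' @export
binding_site <- function(matrix, wt_energy) {
  stopifnot(inherits(matrix, "energy_matrix"))
  assert_scalar_number(wt_energy, "wt_energy")
  structure(list(matrix = matrix, wt_energy = wt_energy,
                 factor = matrix$factor_name, role = matrix$factor_role),
            class = "binding_site")
}

#' Regulatory architectures for the states-and-weights engine
#'
#' `mpra_architecture()` assembles binding sites, a repression logic and
#' factor-factor interaction energies into an architecture evaluated by
#' [pbound()]. `architecture_preset()` builds the six standard (A, R)
#' architecture classes with the package's default synthetic energy matrices
#' anchored on a wild-type promoter: constitutive (0,0), simple_repression
#' (0,1), simple_activation (1,0), repression_activation (1,1),
#' double_repression (0,2) and double_activation (2,0).
#'
#' Default geometry (display coordinates, conventions of this package): the
#' RNAP site is a 30-bp matrix at −36..−7 whose −35/−10 hexamers carry 1-kBT
#' mutant penalties with zero-effect spacer; the (first) repressor site is
#' 20 bp at +1..+20; the (first) activator / second repressor site is 20 bp
#' at −66..−47; the second activator site is 20 bp at −92..−73. Default
#' wild-type energies: polymerase −5 kBT, repressors −15 kBT (−12 each under
#' AND-logic double repression, where binding is weak but cooperative),
#' activators −13 kBT. Interactions: activator-polymerase −5 kBT;
#' repressor-repressor −5 kBT under AND logic only.
#'
#' Repression logic: a state with polymerase bound is disallowed when the
#' bound set of repressors "represses" — under `"OR"` (and `"independent"`)
#' any bound repressor represses; under `"AND"` only the full set of
#' repressors bound together represses (single-repressor-plus-polymerase
#' states are allowed); under `"XOR"` exactly one bound repressor represses
#' while the doubly bound state does not.
#'
#' @param sites List of [binding_site()] objects.
#' @param logic Repression logic: "independent", "AND", "OR" or "XOR".
#' @param interactions List of `list(pair = c(factor1, factor2), omega = kBT)`
#'   cooperative interaction energies applied when both factors are bound.
#' @param name Architecture label.
#' @return A list of class `mpra_architecture`.
#' @export
mpra_architecture <- function(sites, logic = "independent",
                              interactions = list(), name = "custom") {
  logic <- match.arg(logic, c("independent", "AND", "OR", "XOR"))
  stopifnot(all(vapply(sites, inherits, logical(1), "binding_site")))
  names(sites) <- vapply(sites, function(s) s$factor, character(1))
  if (anyDuplicated(names(sites))) abort("Each site must have a distinct factor name.")
  structure(list(name = name, sites = sites, logic = logic,
                 interactions = interactions),
            class = "mpra_architecture")
}

#' @export
print.mpra_architecture <- function(x, ...) {
  cat(sprintf("<mpra_architecture> %s (logic: %s)\n", x$name, x$logic))
  for (s in x$sites) {
    cat(sprintf("  %s [%s] %d bp at %d..%d, wt energy %.2f kBT\n",
                s$factor, s$role, s$matrix$site_length, s$matrix$offset,
                s$matrix$offset + s$matrix$site_length - 1L, s$wt_energy))
  }
  invisible(x)
}

# default site builders on a wild-type promoter -------------------------------

default_rnap_matrix <- function(wild_type, effect = 1) {
  # 30 bp spanning display -36..-7; informative rows are the -35 hexamer
  # (-36..-31, rows 1..6) and the -10 hexamer (-12..-7, rows 25..30)
  synthetic_energy_matrix(wild_type, offset = -36L, length = 30L,
                          factor_name = "P", factor_role = "polymerase",
                          effect = effect, informative = c(1:6, 25:30))
}

default_repressor_matrix <- function(wild_type, factor_name = "R", offset = 1L,
                                     effect = 1) {
  synthetic_energy_matrix(wild_type, offset = offset, length = 20L,
                          factor_name = factor_name, factor_role = "repressor",
                          effect = effect)
}

default_activator_matrix <- function(wild_type, factor_name = "A", offset = -66L,
                                     effect = 1) {
  synthetic_energy_matrix(wild_type, offset = offset, length = 20L,
                          factor_name = factor_name, factor_role = "activator",
                          effect = effect)
}

#' @rdname mpra_architecture
#' @param preset One of "constitutive", "simple_repression",
#'   "simple_activation", "repression_activation", "double_repression",
#'   "double_activation".
#' @param wild_type A [promoter()] the synthetic matrices are anchored on
#'   (default [default_promoter()]).
#' @param eps_p,eps_r,eps_a Wild-type binding energies (kBT) of polymerase,
#'   repressor(s) and activator(s).
#' @param omega_ap Activator-polymerase interaction energy (kBT).
#' @param omega_rr Repressor-repressor cooperativity under AND logic (kBT).
#' @export
architecture_preset <- function(preset = c("constitutive", "simple_repression",
                                           "simple_activation",
                                           "repression_activation",
                                           "double_repression",
                                           "double_activation"),
                                wild_type = default_promoter(),
                                logic = NULL,
                                eps_p = -5, eps_r = -15, eps_a = -13,
                                omega_ap = -5, omega_rr = -5) {
  preset <- match.arg(preset)
  pol <- binding_site(default_rnap_matrix(wild_type), eps_p)
  switch(
    preset,
    constitutive = mpra_architecture(list(pol), name = preset),
    simple_repression = mpra_architecture(
      list(pol, binding_site(default_repressor_matrix(wild_type), eps_r)),
      logic = logic %||% "independent", name = preset),
    simple_activation = mpra_architecture(
      list(pol, binding_site(default_activator_matrix(wild_type), eps_a)),
      interactions = list(list(pair = c("A", "P"), omega = omega_ap)),
      name = preset),
    repression_activation = mpra_architecture(
      list(pol,
           binding_site(default_repressor_matrix(wild_type, "R"), eps_r),
           binding_site(default_activator_matrix(wild_type, "A"), eps_a)),
      interactions = list(list(pair = c("A", "P"), omega = omega_ap)),
      logic = logic %||% "independent", name = preset),
    double_repression = {
      logic <- logic %||% "AND"
      # under AND logic the repressors bind weakly but cooperatively
      er <- if (logic == "AND") -12 else eps_r
      inter <- if (logic == "AND") list(list(pair = c("R1", "R2"), omega = omega_rr)) else list()
      mpra_architecture(
        list(pol,
             binding_site(default_repressor_matrix(wild_type, "R1", offset = 1L), er),
             binding_site(default_repressor_matrix(wild_type, "R2", offset = -66L), er)),
        logic = logic, interactions = inter, name = preset)
    },
    double_activation = mpra_architecture(
      list(pol,
           binding_site(default_activator_matrix(wild_type, "A1", offset = -66L), eps_a),
           binding_site(default_activator_matrix(wild_type, "A2", offset = -92L), eps_a)),
      interactions = list(list(pair = c("A1", "P"), omega = omega_ap),
                          list(pair = c("A2", "P"), omega = omega_ap)),
      name = preset)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

arch_roles <- function(architecture) {
  vapply(architecture$sites, function(s) s$role, character(1))
}
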