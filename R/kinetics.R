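#' Promoter kinetic graphs
#'
#' A kinetic graph describes the transitions between promoter occupancy
#' states as a strongly connected directed graph with positive rate
#' constants; its unique steady state is computed by [steady_state()].
#' `simple_activation_graph()` builds the four-vertex, eight-edge square
#' graph of a simple-activation promoter with states E (empty), P (RNAP
#' bound), A (activator bound) and AP (both bound), from binding energies,
#' concentrations and a shared diffusion-limited on-rate. A drive energy `U`
#' (kBT) multiplies the off-rate of the AP -> A edge (RNAP unbinding from
#' the doubly bound state) by `exp(U)`, breaking detailed balance on the
#' cycle; `U = 0` gives an equilibrium graph whose steady state reproduces
#' the Boltzmann weights.
#'
#' @param states Character vector of state labels.
#' @param edges Tibble/data frame with columns `from`, `to`, `rate`.
#' @param active Character vector of transcriptionally active states.
#' @return A list of class `kinetic_graph`.
#' @export
kinetic_graph <- function(states, edges, active) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "rate") %in% colnames(edges)))
  if (any(edges$rate <= 0)) abort("All rate constants must be > 0.")
  if (!all(c(edges$from, edges$to) %in% states)) {
    abort("Edge endpoints must be listed in `states`.")
  }
  if (!all(active %in% states)) abort("Active states must be listed in `states`.")
  if (length(active) == 0L) abort("The active-state set must not be empty.")
  structure(list(states = states, edges = edges, active = active),
            class = "kinetic_graph")
}

#' @rdname kinetic_graph
#' @param eps_p,eps_a Binding energies of RNAP and activator (kBT; dissociation
#'   constants `K_d = c0 * exp(eps)` with `c0 = 1 M`).
#' @param conc_p,conc_a Free concentrations of RNAP and activator (M).
#' @param k_on Shared diffusion-limited on-rate constant (1/(M s)).
#' @param omega Activator-RNAP interaction energy in the AP state (kBT).
#' @param U Drive energy invested on the AP -> A edge (kBT).
#' @param active Active-state set; the printed convention is `c("A", "AP")`,
#'   with `c("P", "AP")` (RNAP-bound states) selectable.
#' @export
simple_activation_graph <- function(eps_p, eps_a, conc_p, conc_a, k_on = 1,
                                    omega = 0, U = 0, active = c("A", "AP")) {
  r <- function(from, to, rate) tibble::tibble(from = from, to = to, rate = rate)
  edges <- dplyr::bind_rows(
    r("E", "P", k_on * conc_p),
    r("P", "E", k_on * exp(eps_p)),
    r("E", "A", k_on * conc_a),
    r("A", "E", k_on * exp(eps_a)),
    r("A", "AP", k_on * conc_p),
    r("AP", "A", k_on * exp(eps_p + omega) * exp(U)),
    r("P", "AP", k_on * conc_a),
    r("AP", "P", k_on * exp(eps_a + omega))
  )
  kinetic_graph(c("E", "P", "A", "AP"), edges, active)
}

#' Sequence-dependent rate constants from binding energies
#'
#' On-rates are diffusion-limited and sequence-independent; the
#' sequence-dependence enters through the dissociation constant
#' `K_d = c0 * exp(beta * delta_eps)` with reference concentration
#' `c0 = 1 M`, giving the equilibrium off-rate `k_off_eq = k_on * K_d`. A
#' drive energy `U` multiplies the off-rate by `exp(beta * U)`.
#'
#' @param delta_eps Binding energy (kBT).
#' @param k_on Diffusion-limited on-rate constant (> 0).
#' @param concentration Free concentration of the binding species (M, >= 0).
#' @param U Drive energy on the unbinding edge (kBT, default 0).
#' @return List with `k_bind` (= `k_on * concentration`), `k_off`, and `K_d`.
#' @export
rates_from_energies <- function(delta_eps, k_on = 1, concentration = 0, U = 0) {
  if (any(k_on <= 0)) abort("`k_on` must be > 0.")
  if (any(concentration < 0)) abort("`concentration` must be >= 0.")
  K_d <- exp(delta_eps)
  list(k_bind = k_on * concentration, k_off = k_on * K_d * exp(U), K_d = K_d)
}

#' Steady state of a kinetic graph via the Matrix Tree Theorem
#'
#' The steady-state probability of a state is proportional to the sum over
#' all spanning trees rooted at that state (edges directed toward the root)
#' of the product of edge rates. Trees are enumerated exactly for graphs of
#' up to `max_exact` states; larger graphs fall back to solving the
#' null space of the rate (Laplacian) matrix.
#'
#' @param graph A [kinetic_graph()].
#' @param max_exact Largest state count for exact tree enumeration
#'   (default 6).
#' @return Named numeric vector of steady-state probabilities (sums to 1).
#' @export
#' @examples
#' g <- kinetic_graph(c("a", "b"),
#'                    data.frame(from = c("a", "b"), to = c("b", "a"),
#'                               rate = c(1, 1)), active = "b")
#' steady_state(g)
steady_state <- function(graph, max_exact = 6L) {
  stopifnot(inherits(graph, "kinetic_graph"))
  n <- length(graph$states)
  if (!is_strongly_connected(graph)) {
    abort("Graph is not strongly connected: no unique steady state.")
  }
  if (n <= max_exact) {
    trees <- spanning_trees(graph)
    w <- vapply(graph$states, function(s) {
      sum(vapply(trees[[s]], function(idx) prod(graph$edges$rate[idx]), numeric(1)))
    }, numeric(1))
  } else {
    w <- laplacian_null(graph)
  }
  w / sum(w)
}

# all in-trees per root, as lists of edge-row indices; cached per topology
spanning_trees <- function(graph) {
  n <- length(graph$states)
  from <- match(graph$edges$from, graph$states)
  to <- match(graph$edges$to, graph$states)
  m <- nrow(graph$edges)
  combos <- utils::combn(m, n - 1L, simplify = FALSE)
  out <- setNames(vector("list", n), graph$states)
  for (root in seq_len(n)) {
    keep <- Filter(function(idx) {
      f <- from[idx]; t <- to[idx]
      # each non-root state has exactly one outgoing edge; root has none
      if (any(f == root)) return(FALSE)
      if (any(duplicated(f)) || !setequal(f, setdiff(seq_len(n), root))) return(FALSE)
      nxt <- integer(n); nxt[f] <- t
      for (s in setdiff(seq_len(n), root)) {  # every chain must reach the root
        cur <- s
        for (step in seq_len(n)) {
          cur <- nxt[cur]
          if (cur == root) break
        }
        if (cur != root) return(FALSE)
      }
      TRUE
    }, combos)
    out[[graph$states[root]]] <- keep
  }
  out
}

is_strongly_connected <- function(graph) {
  n <- length(graph$states)
  adj <- matrix(FALSE, n, n)
  adj[cbind(match(graph$edges$from, graph$states),
            match(graph$edges$to, graph$states))] <- TRUE
  reach <- function(a) {
    r <- diag(TRUE, n)
    for (i in seq_len(n)) r <- r | (r %*% a > 0)
    r
  }
  all(reach(adj))
}

laplacian_null <- function(graph) {
  n <- length(graph$states)
  K <- matrix(0, n, n)
  K[cbind(match(graph$edges$from, graph$states),
          match(graph$edges$to, graph$states))] <- graph$edges$rate
  A <- t(K) - diag(rowSums(K))
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- solve(A, b)
  setNames(pmax(p, 0), graph$states)
}

#' Total probability of transcriptionally active states
#'
#' @param graph A [kinetic_graph()] with a configured active-state set.
#' @return Probability (sum of steady-state probabilities over the active
#'   set).
#' @export
pactive_graph <- function(graph) {
  p <- steady_state(graph)
  sum(p[graph$active])
}

#' Simulate a library under the non-equilibrium kinetic model
#'
#' For each variant of a simple-activation promoter, derives sequence-
#' dependent off-rates from the architecture's energy matrices
#' ([rates_from_energies()]), assembles the square kinetic graph with drive
#' energy `U` on the AP -> A edge, computes its Matrix-Tree steady state and
#' reports counts `alpha * p_active`. Copy numbers are converted to
#' concentrations as `copies / N_NS` (in units of the reference
#' concentration), which makes the `U = 0` steady state match the
#' thermodynamic model's occupancies exactly.
#'
#' @inheritParams pbound
#' @param architecture A simple-activation [mpra_architecture()]; default the
#'   preset anchored on the library's wild type.
#' @param U Drive energy on the AP -> A edge (kBT).
#' @param k_on Shared on-rate constant.
#' @param conc_a Optional activator concentration override (M); default
#'   `A / N_NS`.
#' @param active Active-state set (default the printed `c("A", "AP")`).
#' @return An expression table (tibble: `variant`, `sequence`, `count`).
#' @export
simulate_noneq_library <- function(library, architecture = NULL,
                                   params = thermo_params(), U = 0, k_on = 1,
                                   conc_a = NULL, active = c("A", "AP")) {
  stopifnot(inherits(library, "mutant_library"))
  if (is.null(architecture)) {
    architecture <- architecture_preset("simple_activation",
                                        wild_type = library_wild_type(library))
  }
  roles <- arch_roles(architecture)
  pol <- architecture$sites[[which(roles == "polymerase")[1]]]
  act <- architecture$sites[[which(roles == "activator")[1]]]
  omega <- 0
  for (int in architecture$interactions) {
    if (setequal(int$pair, c(act$factor, pol$factor))) omega <- int$omega
  }
  tssi <- library_wild_type(library)$tss_index
  bm <- seq_to_matrix(library$sequence)
  e_p <- pol$wt_energy + site_energies(bm, pol$matrix, tssi)
  e_a <- act$wt_energy + site_energies(bm, act$matrix, tssi)
  conc_p <- params$P / params$N_NS
  if (is.null(conc_a)) conc_a <- params[[act$factor]] / params$N_NS
  # per-variant rates on the 8 edges of the square graph; tree structure is
  # shared, so tree weights vectorize across variants
  template <- simple_activation_graph(0, 0, 1, 1, active = active)
  trees <- spanning_trees(template)
  n <- nrow(bm)
  rates <- cbind(
    rep(k_on * conc_p, n),                 # E  -> P
    k_on * exp(e_p),                       # P  -> E
    rep(k_on * conc_a, n),                 # E  -> A
    k_on * exp(e_a),                       # A  -> E
    rep(k_on * conc_p, n),                 # A  -> AP
    k_on * exp(e_p + omega) * exp(U),      # AP -> A   (driven edge)
    rep(k_on * conc_a, n),                 # P  -> AP
    k_on * exp(e_a + omega)                # AP -> P
  )
  lograte <- log(rates)
  w <- vapply(template$states, function(s) {
    tw <- vapply(trees[[s]], function(idx) {
      if (length(idx) == 1L) lograte[, idx] else rowSums(lograte[, idx, drop = FALSE])
    }, numeric(n))
    if (n == 1L) tw <- matrix(tw, nrow = 1L)
    rowSums(exp(tw - apply(tw, 1L, max))) * exp(apply(tw, 1L, max))
  }, numeric(n))
  if (n == 1L) w <- matrix(w, nrow = 1L, dimnames = list(NULL, template$states))
  p_active <- rowSums(w[, active, drop = FALSE]) / rowSums(w)
  tibble::tibble(variant = library$variant, sequence = library$sequence,
                 count = params$alpha * p_active)
}
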