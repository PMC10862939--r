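# Shared fixtures and independent oracles used across the test files.

# a random wild-type-normalized matrix with heterogeneous mutant penalties
toy_matrix <- function(l = 8, offset = 0, factor_name = "R",
                       factor_role = "repressor", seed = 1) {
  withr::with_seed(seed, {
    wt <- sample(c("A", "C", "G", "T"), l, replace = TRUE)
    e <- matrix(round(runif(l * 4, 0, 3), 3), l, 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    for (i in seq_len(l)) e[i, wt[i]] <- 0
    energy_matrix(e, offset, factor_name, factor_role)
  })
}

random_window <- function(l, seed = 1) {
  withr::with_seed(seed, paste0(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                                collapse = ""))
}

# hand-written closed-form p_bound expressions for the six architecture
# classes, written independently of the generic state-enumeration engine
closed_form_pbound <- function(preset, logic, w, omega = list()) {
  O <- function(nm) exp(-(omega[[nm]] %||% 0))
  switch(
    preset,
    constitutive = w$P / (1 + w$P),
    simple_repression = w$P / (1 + w$P + w$R),
    simple_activation = {
      num <- w$P + w$A * w$P * O("AP")
      num / (1 + w$A + num)
    },
    repression_activation = {
      act <- w$P + w$A * w$P * O("AP")
      act / (1 + w$A + w$R + w$A * w$R + w$P + w$A * w$P * O("AP"))
    },
    double_repression = switch(
      logic,
      AND = {
        num <- w$P + w$R1 * w$P + w$R2 * w$P
        num / (1 + w$R1 + w$R2 + w$R1 * w$R2 * O("RR") + num)
      },
      OR = w$P / (1 + w$R1 + w$R2 + w$R1 * w$R2 + w$P),
      XOR = {
        num <- w$P + w$R1 * w$R2 * w$P
        num / (1 + w$R1 + w$R2 + w$R1 * w$R2 + num)
      }),
    double_activation = {
      num <- w$P * (1 + w$A1 * O("A1P")) * (1 + w$A2 * O("A2P"))
      num / ((1 + w$A1) * (1 + w$A2) + num)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# site Boltzmann weights of an architecture on a set of sequences, computed
# with scalar arithmetic (independent of the engine's vectorized path)
oracle_site_weights <- function(arch, sequences, tss_index, params) {
  lapply(seq_along(sequences), function(i) {
    w <- lapply(arch$sites, function(s) {
      win <- substr(sequences[i],
                    s$matrix$offset + tss_index + 1,
                    s$matrix$offset + tss_index + s$matrix$site_length)
      e <- s$wt_energy + total_binding_energy(win, s$matrix)
      (params[[s$factor]] / params$N_NS) * exp(-e)
    })
    names(w) <- names(arch$sites)
    w
  })
}

# steady state from the rate-matrix null space; independent linear-algebra
# oracle for the Matrix-Tree implementation
oracle_steady_state <- function(states, edges) {
  n <- length(states)
  K <- matrix(0, n, n, dimnames = list(states, states))
  for (r in seq_len(nrow(edges))) K[edges$from[r], edges$to[r]] <- edges$rate[r]
  A <- t(K) - diag(rowSums(K))
  A[n, ] <- 1
  p <- solve(A, c(rep(0, n - 1), 1))
  stats::setNames(p, states)
}

default_sites <- function(arch) {
  lapply(arch$sites, function(s) site_positions(s$matrix, informative_only = TRUE))
}
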