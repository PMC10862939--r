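test_that("two-state graphs and rate construction behave as expected", {
  g <- kinetic_graph(c("off", "on"),
                     data.frame(from = c("off", "on"), to = c("on", "off"),
                                rate = c(2, 2)), active = "on")
  expect_equal(unname(steady_state(g)), c(0.5, 0.5))

  r0 <- rates_from_energies(0, k_on = 1, concentration = 1)
  expect_equal(r0$K_d, 1)           # K_d = c0 at zero binding energy
  expect_equal(r0$k_off, 1)         # U = 0: equilibrium off-rate
  r2 <- rates_from_energies(-4, k_on = 3, concentration = 0.5, U = 2)
  expect_equal(r2$k_off, 3 * exp(-4) * exp(2))
  expect_equal(r2$k_bind, 1.5)
  expect_error(rates_from_energies(0, k_on = 0), "k_on")

  expect_error(kinetic_graph("a", data.frame(from = "a", to = "a", rate = 1),
                             active = character(0)), "active")
  # a disconnected graph has no unique steady state
  g_bad <- kinetic_graph(c("a", "b", "c"),
                         data.frame(from = c("a", "b"), to = c("b", "a"),
                                    rate = c(1, 1)), active = "a")
  expect_error(steady_state(g_bad), "strongly connected")
})

test_that("Matrix-Tree steady states match the Laplacian null space on random graphs", {
  for (n_states in 3:6) {
    for (rep in 1:3) {
      states <- paste0("s", seq_len(n_states))
      edges <- withr::with_seed(100 * n_states + rep, {
        # a ring (guaranteeing strong connectivity) plus random extra edges
        ring <- data.frame(from = states, to = states[c(2:n_states, 1)],
                           rate = rlnorm(n_states))
        extra <- expand.grid(from = states, to = states,
                             stringsAsFactors = FALSE)
        extra <- extra[extra$from != extra$to, ]
        extra <- extra[sample(nrow(extra), n_states), ]
        extra$rate <- rlnorm(nrow(extra))
        agg <- rbind(ring, extra)
        agg[!duplicated(agg[, c("from", "to")]), ]
      })
      g <- kinetic_graph(states, edges, active = states[1])
      p_mtt <- steady_state(g)
      p_lin <- oracle_steady_state(states, edges)
      expect_equal(p_mtt, p_lin / sum(p_lin), tolerance = 1e-12)
      expect_equal(sum(p_mtt), 1, tolerance = 1e-12)
      expect_true(all(p_mtt > 0))
    }
  }
})

test_that("detailed balance yields Boltzmann ratios; a drive multiplies the cycle product", {
  # equilibrium square graph: state ratios equal Boltzmann factors
  eps_p <- -2; eps_a <- -3; cp <- 0.05; ca <- 0.02; om <- -1
  g <- simple_activation_graph(eps_p, eps_a, cp, ca, omega = om, U = 0)
  p <- steady_state(g)
  expect_equal(p[["P"]] / p[["E"]], cp * exp(-eps_p), tolerance = 1e-12)
  expect_equal(p[["A"]] / p[["E"]], ca * exp(-eps_a), tolerance = 1e-12)
  expect_equal(p[["AP"]] / p[["E"]], cp * ca * exp(-(eps_p + eps_a + om)),
               tolerance = 1e-12)

  # cycle product of forward/backward rate ratios: 1 in equilibrium, e^U
  # under a single drive on the AP -> A edge
  cycle_product <- function(g) {
    rate <- function(f, t) g$edges$rate[g$edges$from == f & g$edges$to == t]
    (rate("E", "P") * rate("P", "AP") * rate("AP", "A") * rate("A", "E")) /
      (rate("P", "E") * rate("AP", "P") * rate("A", "AP") * rate("E", "A"))
  }
  expect_equal(cycle_product(g), 1, tolerance = 1e-12)
  g_u <- simple_activation_graph(eps_p, eps_a, cp, ca, omega = om, U = 3.5)
  expect_equal(cycle_product(g_u), exp(3.5), tolerance = 1e-12)

  # all states active: total probability 1
  g_all <- simple_activation_graph(eps_p, eps_a, cp, ca,
                                   active = c("E", "P", "A", "AP"))
  expect_equal(pactive_graph(g_all), 1, tolerance = 1e-12)
})

test_that("the equilibrium kinetic library matches the thermodynamic model per variant", {
  wt <- default_promoter()
  arch <- architecture_preset("simple_activation", wild_type = wt)
  lib <- mutagenize(wt, n = 300, seed = 61)

  # U = 0 with RNAP-bound active states reproduces thermodynamic counts
  kin <- simulate_noneq_library(lib, arch, U = 0, active = c("P", "AP"))
  thermo <- expected_counts(lib, arch)
  expect_lt(max(abs(kin$count - thermo$count) / thermo$count), 1e-6)

  # a wild-type-only library is flat
  wt_lib <- mutant_library(rep(wt$bases, 3), wt)
  flat <- simulate_noneq_library(wt_lib, arch)
  expect_equal(flat$count, rep(flat$count[1], 3))

  # doubling alpha doubles counts and leaves the footprint unchanged
  k1 <- simulate_noneq_library(lib, arch, params = thermo_params(alpha = 100))
  k2 <- simulate_noneq_library(lib, arch, params = thermo_params(alpha = 200))
  expect_equal(k2$count, 2 * k1$count, tolerance = 1e-12)
  expect_equal(information_footprint(lib, k1)$mi,
               information_footprint(lib, k2)$mi, tolerance = 1e-14)
})

test_that("positive drive at AP->A with a saturated activator flips its apparent role", {
  wt <- default_promoter()
  arch <- architecture_preset("simple_activation", wild_type = wt)
  lib <- mutagenize(wt, n = 1000, seed = 67)
  apos <- site_positions(arch$sites$A$matrix)

  # equilibrium: mutations in the activator site lower expression
  eq <- simulate_noneq_library(lib, arch, U = 0, active = c("P", "AP"))
  sh_eq <- expression_shift(lib, eq)
  expect_lt(mean(sh_eq$shift[sh_eq$position %in% apos]), 0)

  # strong positive drive ejecting RNAP from AP: the activator now
  # suppresses RNAP-bound states and its site turns repressor-like
  dr <- simulate_noneq_library(lib, arch, U = 10, active = c("P", "AP"))
  sh_dr <- expression_shift(lib, dr)
  expect_gt(mean(sh_dr$shift[sh_dr$position %in% apos]), 0)
})
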