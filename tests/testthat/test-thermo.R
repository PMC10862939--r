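pars <- thermo_params()

test_that("the state engine reproduces hand-written closed forms for all six architectures", {
  wt <- default_promoter()
  lib <- mutagenize(wt, n = 100, theta = 0.15, seed = 17)
  cases <- list(
    list(preset = "constitutive", logic = NULL, omega = list()),
    list(preset = "simple_repression", logic = NULL, omega = list()),
    list(preset = "simple_activation", logic = NULL, omega = list(AP = -5)),
    list(preset = "repression_activation", logic = NULL, omega = list(AP = -5)),
    list(preset = "double_repression", logic = "AND", omega = list(RR = -5)),
    list(preset = "double_repression", logic = "OR", omega = list()),
    list(preset = "double_repression", logic = "XOR", omega = list()),
    list(preset = "double_activation", logic = NULL, omega = list(A1P = -5, A2P = -5))
  )
  for (cs in cases) {
    arch <- architecture_preset(cs$preset, wild_type = wt, logic = cs$logic)
    engine <- pbound(lib, arch, pars)
    weights <- oracle_site_weights(arch, lib$sequence, wt$tss_index, pars)
    oracle <- vapply(weights, function(w) {
      closed_form_pbound(cs$preset, cs$logic, w, cs$omega)
    }, numeric(1))
    expect_equal(engine, oracle, tolerance = 1e-12,
                 label = paste(cs$preset, cs$logic %||% ""))
    expect_true(all(engine > 0 & engine < 1))
  }
})

test_that("printed simple-repression weights and the weak-polymerase limit hold", {
  w_p <- boltzmann_weight(1000, -5)
  w_r <- boltzmann_weight(10, -15)
  expect_equal(signif(w_p, 1), 0.04)
  expect_equal(signif(w_r, 1), 8)

  # with R = 0 the engine reduces exactly to the constitutive value
  wt <- default_promoter()
  arch <- architecture_preset("simple_repression", wild_type = wt)
  p0 <- thermo_params(R = 0)
  expect_equal(pbound(wt, arch, p0), w_p / (1 + w_p), tolerance = 1e-12)

  # dropping w_p from the denominator changes the result by < 4%
  full <- w_p / (1 + w_p + w_r)
  simplified <- w_p / (1 + w_r)
  expect_lt(abs(simplified - full) / full, 0.04)
})

test_that("pbound responds monotonically to regulator copy number", {
  wt <- default_promoter()
  rep_arch <- architecture_preset("simple_repression", wild_type = wt)
  act_arch <- architecture_preset("simple_activation", wild_type = wt)
  pb_r <- vapply(c(0, 1, 10, 100, 1000),
                 function(R) pbound(wt, rep_arch, thermo_params(R = R)), numeric(1))
  expect_true(all(diff(pb_r) < 0))
  pb_a <- vapply(c(0, 1, 10, 100, 1000),
                 function(A) pbound(wt, act_arch, thermo_params(A = A)), numeric(1))
  expect_true(all(diff(pb_a) > 0))
})

test_that("free energies match their definition and flag degenerate input", {
  expect_equal(round(free_energy(10, -10)), 3)
  expect_equal(round(free_energy(10, -20)), -7)
  expect_equal(free_energy(4e6, 0), 0)
  expect_error(free_energy(0, -10), "diverges")
})

test_that("kappa, its theta form and the optimal mutation rate are consistent", {
  # R = P, equal energies, no mutations: kappa = 1
  expect_equal(kappa(10, 10, -10, -10), 1)
  expect_error(kappa(10, 0, -10, -10), "undefined")

  # prefactor of the printed threshold analysis: kappa = C * exp(-eps_r)
  # with C close to the printed 1.5e-6
  C <- kappa(10, 1000, eps_r = 0, eps_p = -5, m_r = 2, m_p = 2,
             ddE_r = 2.24, ddE_p = 0.36)
  expect_lt(abs(C - 1.5e-6) / 1.5e-6, 0.05)

  # the site-length energy combination recovered from the theta-form
  comb <- -log(kappa_theta(1, 10, 1000, -15, -5, 20, 20, 2.24, 0.36) /
                 kappa_theta(0, 10, 1000, -15, -5, 20, 20, 2.24, 0.36))
  expect_equal(comb, 37.6, tolerance = 1e-12)

  # R = P with equal energies: theta* = 0
  expect_equal(as.numeric(optimal_mutation_rate(10, 10, -10, -10, 20, 20, 2.24, 0.36)), 0)

  # closed form vs a bisection root of kappa(theta) - 1
  th <- as.numeric(optimal_mutation_rate(10, 1000, -15, -5, 20, 20, 2.24, 0.36))
  root <- uniroot(function(t) kappa_theta(t, 10, 1000, -15, -5, 20, 20, 2.24, 0.36) - 1,
                  c(0, 1), tol = 1e-12)$root
  expect_equal(th, root, tolerance = 1e-10)
  expect_equal(kappa_theta(th, 10, 1000, -15, -5, 20, 20, 2.24, 0.36), 1,
               tolerance = 1e-9)

  # over a physiological parameter grid the optimum spans roughly 0.01-0.50
  grid <- expand.grid(R = c(1, 10, 100, 500), P = c(500, 1000, 5000),
                      eps_r = c(-20, -15, -12, -10), eps_p = c(-7, -5, -3))
  th_grid <- suppressWarnings(mapply(function(R, P, er, ep) {
    as.numeric(optimal_mutation_rate(R, P, er, ep, 20, 20, 2.24, 0.36))
  }, grid$R, grid$P, grid$eps_r, grid$eps_p))
  inside <- th_grid[th_grid > 0 & th_grid < 1]
  expect_lt(min(inside), 0.02)
  expect_gt(max(inside), 0.35)
  expect_true(all(inside <= 0.55))

  expect_error(optimal_mutation_rate(10, 1000, -15, -5, 20, 20, 0.36, 0.36),
               "no solution")

  # threshold energy for an observable repressor signal (kappa = 0.1)
  thr <- repressor_energy_for_kappa(0.1, R = 10, P = 1000, eps_p = -5,
                                    m_r = 2, m_p = 2, ddE_r = 2.24, ddE_p = 0.36)
  expect_equal(round(thr), -11)
  expect_equal(kappa(10, 1000, thr, -5, 2, 2, 2.24, 0.36), 0.1, tolerance = 1e-12)
})

test_that("MWC induction follows the two-site allosteric form", {
  mwc <- mwc_params()
  expect_equal(pactive_mwc(0, mwc), 1 / (1 + exp(-mwc$delta_eps_AI)))
  expect_gt(pactive_mwc(0, mwc_params(delta_eps_AI = 50)), 1 - 1e-12)

  # independent arithmetic oracle at c = K_A
  c0 <- mwc$K_A
  act <- (1 + c0 / mwc$K_A)^2
  inact <- exp(-mwc$delta_eps_AI) * (1 + c0 / mwc$K_I)^2
  expect_equal(pactive_mwc(c0, mwc), act / (act + inact), tolerance = 1e-15)
  expect_error(pactive_mwc(-1, mwc), ">= 0")

  wt <- default_promoter()
  lib <- mutagenize(wt, n = 50, seed = 23)
  arch <- architecture_preset("simple_repression", wild_type = wt)

  # a permanently active repressor reduces to simple repression at eps_rdA
  stiff <- mwc_params(delta_eps_AI = 60, eps_rdA = -15, eps_rdI = -2)
  pb <- pbound_induction(lib, c = 0, mwc = stiff)
  weights <- oracle_site_weights(arch, lib$sequence, wt$tss_index, pars)
  oracle <- vapply(weights, function(w) w$P / (1 + w$P + w$R), numeric(1))
  expect_equal(pb, oracle, tolerance = 1e-8)

  # saturating inducer with a non-binding inactive state: constitutive limit
  loose <- mwc_params(delta_eps_AI = -4.5, eps_rdA = -15, eps_rdI = 10)
  pb_sat <- pbound_induction(lib, c = 1, mwc = loose)
  const <- vapply(weights, function(w) w$P / (1 + w$P), numeric(1))
  expect_equal(pb_sat, const, tolerance = 1e-3)

  # monotone non-decreasing in inducer concentration when K_I < K_A
  cs <- 10^seq(-8, -2, length.out = 12)
  pb_c <- vapply(cs, function(cc) pbound_induction(lib, c = cc)[1], numeric(1))
  expect_true(all(diff(pb_c) >= -1e-15))
})

test_that("the fugacity solver conserves copies and matches canonical enumeration", {
  sol0 <- solve_fugacity(0, c(-5, -10))
  expect_identical(sol0$lambda, 0)
  expect_identical(sol0$occupancy, c(0, 0))

  # conservation at the solver tolerance
  sol <- solve_fugacity(10, rep(-15, 50), N_NS = 4e6)
  expect_equal(sum(sol$occupancy) + sol$reservoir_occupancy, 10, tolerance = 1e-8)
  expect_true(all(sol$occupancy < 10 / 50))

  # 2 specific sites + reservoir, 1 particle: canonical enumeration oracle.
  # The ensembles agree in the dilute large-reservoir regime (all
  # occupancies well below 1); saturation corrections are O(occupancy).
  eps <- c(-3, -4)
  n_res <- 1e4
  states_w <- c(exp(-eps), rep(1, n_res))   # particle on site 1, site 2, or a
  canonical <- exp(-eps) / sum(states_w)    # reservoir site
  gc <- solve_fugacity(1, eps, N_NS = n_res)
  expect_equal(gc$occupancy, canonical, tolerance = 0.01)

  expect_error(solve_fugacity(20, rep(-5, 10), N_NS = 5), "infeasible")
})

test_that("binding-site titration drives p_bound to the constitutive value", {
  wt <- default_promoter()
  lib <- mutagenize(wt, n = 30, seed = 29)
  arch <- architecture_preset("simple_repression", wild_type = wt)

  # weak binding regime: the grand-canonical single-copy value agrees with
  # the canonical two-state formula to within 1%
  weak <- thermo_params(R = 10)
  arch_w <- architecture_preset("simple_repression", wild_type = wt, eps_r = -10)
  pb_gc <- pbound_multicopy(lib, weak, n_sites = 1, architecture = arch_w)
  pb_can <- pbound(lib, arch_w, weak)
  expect_lt(max(abs(pb_gc - pb_can) / pb_can), 0.01)

  # strong binding (default) parameters: the ensembles differ by a known
  # sequestration correction of order 1 molecule out of R = 10, i.e. a few
  # percent, with the grand-canonical value always the larger
  pb_gc_s <- pbound_multicopy(lib, pars, n_sites = 1)
  pb_can_s <- pbound(lib, arch, pars)
  expect_true(all(pb_gc_s >= pb_can_s - 1e-15))
  expect_lt(max(abs(pb_gc_s - pb_can_s) / pb_can_s), 0.10)

  # monotone non-decreasing in the number of competing site copies, and
  # approaching the constitutive value as n_sites grows large
  wt_only <- mutant_library(wt$bases, wt)
  pb_n <- vapply(c(1, 2, 5, 10, 50, 200, 2000),
                 function(ns) pbound_multicopy(wt_only, pars, n_sites = ns), numeric(1))
  expect_true(all(diff(pb_n) >= -1e-15))
  w_p <- boltzmann_weight(1000, -5)
  expect_equal(pb_n[length(pb_n)], w_p / (1 + w_p), tolerance = 0.02)
})

test_that("non-specific polymerase binding reduces to the single-site model and sums to one", {
  wt <- default_promoter()
  lib <- mutagenize(wt, n = 40, seed = 31)
  arch <- architecture_preset("simple_repression", wild_type = wt)

  # degenerate limit: a huge mutant penalty pushes all non-canonical windows
  # to astronomically high energies, recovering the single-site p_bound
  steep <- architecture_preset("simple_repression", wild_type = wt, eps_r = -15)
  steep$sites$P <- binding_site(
    synthetic_energy_matrix(wt, -36, 30, "P", "polymerase", effect = 500,
                            informative = c(1:6, 25:30)), -5)
  pb_ns <- pbound_nonspecific(mutant_library(wt$bases, wt), pars, architecture = steep)
  pb_1 <- pbound(wt, arch, pars)
  expect_equal(pb_ns, pb_1, tolerance = 1e-12)

  # state probabilities match a direct partition-function evaluation
  w <- nonspecific_window_weights(lib, pars, architecture = arch)
  z <- 1 + exp(w$log_weight_repressor) + rowSums(exp(w$log_weights))
  direct <- rowSums(exp(w$log_weights)) / z
  expect_equal(pbound_nonspecific(lib, pars, architecture = arch), direct,
               tolerance = 1e-10)
  expect_true(all(direct > 0 & direct < 1))

  # restricting the active start sites can only lower p_bound
  pb_all <- pbound_nonspecific(lib, pars, architecture = arch)
  pb_canon <- pbound_nonspecific(lib, pars, architecture = arch,
                                 active_windows = -36L)
  expect_true(all(pb_canon <= pb_all + 1e-15))

  # inserting a near-consensus TATA-like motif at -80 strictly increases the
  # summed weight of windows overlapping -80 (consensus-anchored matrix,
  # wild-type -10 two mismatches from consensus)
  wt13 <- insert_motif(wt, "TATGGT", at = -12)
  arch13 <- mpra_architecture(
    list(binding_site(sigma70_consensus_matrix(), -5),
         binding_site(default_repressor_matrix(wt13), -15)),
    name = "nonspecific_demo")
  with_motif <- insert_motif(wt13, "TAGAAT", at = -80)
  wsum <- function(p) {
    ww <- nonspecific_window_weights(mutant_library(p$bases, p), pars,
                                     architecture = arch13)
    keep <- ww$window_start <= -80 & ww$window_start + 29 >= -80
    sum(exp(ww$log_weights[1, keep]))
  }
  expect_gt(wsum(with_motif), wsum(wt13))
})
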