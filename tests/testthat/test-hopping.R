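# Marcus rates, feasibility graph, master-equation dynamics and the
# adiabaticity diagnostic.

test_that("Marcus rate: activationless maximum, zero coupling, detailed
           balance", {
  lam <- 800; T_K <- 298
  kT <- kT_meV(T_K)
  # dG = -lambda: exponent vanishes
  k_max <- marcus_rate(10, -lam, lam, T_K)
  pref <- 2 * pi / quad_constants$hbar_meV_s * 100 /
    sqrt(4 * pi * lam * kT)
  expect_equal(k_max, pref, tolerance = 1e-12)
  # the activationless point maximizes the rate over dG
  expect_gt(k_max, marcus_rate(10, -lam + 100, lam, T_K))
  expect_gt(k_max, marcus_rate(10, -lam - 100, lam, T_K))
  # H_ab = 0 -> 0
  expect_equal(marcus_rate(0, -320, lam, T_K), 0)
  # forward/backward ratio for the published -320 meV step: detailed
  # balance at kT(298 K) = 25.68 meV (25.69 at 2-decimal rounding)
  ratio <- marcus_rate(31, -320, lam, T_K) / marcus_rate(31, 320, lam, T_K)
  expect_equal(ratio, exp(320 / kT_meV(298)), tolerance = 1e-9)
  expect_equal(ratio, exp(320 / 25.69), tolerance = 0.01)
  expect_error(marcus_rate(1, 0, lambda = -1), "lambda")
  expect_error(marcus_rate(1, 0, lambda = 800, T_K = 0), "temperature")
})

test_that("feasibility graph applies both strict thresholds to the
           reference tables", {
  net <- feasibility_graph(reference_dg_table(),
                           reference_coupling_table())
  e <- net$edges
  pick <- function(f, t) e[e$from == f & e$to == t, ]
  # the -320 meV / 31 meV interfacial edge is feasible on both counts
  expect_true(pick("124A", "122D")$feasible_thermo)
  expect_true(pick("124A", "122D")$feasible_kinetic)
  # the +172 meV / 0.2 meV long diagonal fails both (strict >)
  expect_false(pick("124A", "124D")$feasible_thermo)
  expect_false(pick("124A", "124D")$feasible_kinetic)
  # slightly uphill intramolecular step stays feasible (+67 < +70)
  expect_true(pick("124A", "122A")$feasible)
  # the 0.1 meV reverse diagonal coupling is kinetically blocked
  expect_false(pick("124D", "124A")$feasible_kinetic)
  # permissive thresholds open all 12 directed edges
  net_all <- feasibility_graph(reference_dg_table(),
                               reference_coupling_table(),
                               dG_max = Inf, H_min = 0)
  expect_true(all(net_all$edges$feasible))
  expect_equal(nrow(net_all$edges), 12L)
})

test_that("every feasible path terminates at the 122D hole state", {
  net <- feasibility_graph(reference_dg_table(),
                           reference_coupling_table())
  expect_equal(terminal_states(net), "122D")
  # and 122D has no feasible outgoing edges at all
  e <- net$edges
  expect_false(any(e$feasible[e$from == "122D"]))
})

test_that("master equation conserves population and obeys detailed
           balance on a two-state network", {
  dg <- matrix(NA_real_, 4, 4,
               dimnames = list(c("124A", "122A", "122D", "124D"),
                               c("124A", "122A", "122D", "124D")))
  dg["124A", "122A"] <- 67; dg["122A", "124A"] <- -67
  dg[is.na(dg)] <- 0; diag(dg) <- NA
  hab <- matrix(0, 4, 4, dimnames = dimnames(dg)); diag(hab) <- NA
  hab["124A", "122A"] <- hab["122A", "124A"] <- 5
  net <- feasibility_graph(dg, hab)
  me <- master_equation(net, c(`124A` = 1, `122A` = 0, `122D` = 0,
                               `124D` = 0), t_grid = 10^seq(-13, -7))
  expect_true(all(abs(rowSums(me$p) - 1) < 1e-9))
  # closed-form stationary ratio between the two coupled states
  sub <- me$stationary[c("124A", "122A")] / sum(me$stationary[c("124A",
                                                               "122A")])
  expect_equal(unname(sub["122A"] / sub["124A"]), exp(-67 / net$kT),
               tolerance = 1e-6)
})

test_that("all-zero rates leave the population unchanged", {
  dg <- matrix(0, 4, 4, dimnames = list(c("124A", "122A", "122D", "124D"),
                                        c("124A", "122A", "122D",
                                          "124D")))
  diag(dg) <- NA
  hab <- dg; hab[!is.na(hab)] <- 0
  net <- feasibility_graph(dg, hab)
  p0 <- c(`124A` = 0.4, `122A` = 0.3, `122D` = 0.2, `124D` = 0.1)
  me <- master_equation(net, p0, t_grid = c(1e-12, 1e-6))
  expect_equal(me$p[2, ], p0, tolerance = 1e-12)
  expect_error(master_equation(net, p0 * 2), "normalized")
})

test_that("propagator matches an independent matrix exponential", {
  skip_if_not_installed("Matrix")
  net <- feasibility_graph(reference_dg_table(),
                           reference_coupling_table())
  me <- master_equation(net, c(`124A` = 1, `122A` = 0, `122D` = 0,
                               `124D` = 0), t_grid = 1e-12)
  K <- me$K
  ref <- as.matrix(Matrix::expm(K * 1e-12)) %*% c(1, 0, 0, 0)
  expect_equal(as.numeric(me$p[1, ]), as.numeric(ref), tolerance = 1e-8)
})

test_that("detailed balance is exact in symmetric-coupling mode", {
  net <- feasibility_graph(reference_dg_table(),
                           reference_coupling_table(),
                           symmetric_coupling = TRUE)
  e <- net$edges
  for (k in seq_len(nrow(e))) {
    rev <- which(e$from == e$to[k] & e$to == e$from[k])
    expect_equal(log(e$rate[k] / e$rate[rev]), -e$dG[k] / net$kT,
                 tolerance = 1e-9)
  }
  # asymmetric mode reports a nonzero residual for these direction-
  # dependent couplings
  net_a <- feasibility_graph(reference_dg_table(),
                             reference_coupling_table(),
                             symmetric_coupling = FALSE)
  expect_gt(net_a$balance_residual, 0.1)
})

test_that("adiabaticity index matches an independent unit-checked
           re-derivation and its limits", {
  # independent evaluation in SI units
  H_J <- 31 * 1.602176634e-22       # meV -> J
  lam_J <- 800 * 1.602176634e-22
  kB_J <- 1.380649e-23
  hbar_J <- 1.054571817e-34
  nu <- 1 / (100e-15)
  kappa_ref <- 2 * pi * H_J^2 /
    (hbar_J * nu * sqrt(4 * pi * lam_J * kB_J * 298))
  ai <- adiabaticity_index(31, 800, 100, 298)
  expect_equal(ai$kappa, kappa_ref, tolerance = 1e-9)
  expect_equal(ai$classification, "adiabatic")
  # limits: vanishing coupling, proportionality to nu_eff^-1
  expect_equal(adiabaticity_index(1e-9, 800, 100, 298)$classification,
               "nonadiabatic")
  expect_equal(adiabaticity_index(5, 800, 200, 298)$kappa,
               2 * adiabaticity_index(5, 800, 100, 298)$kappa,
               tolerance = 1e-12)
})
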