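# Coulomb site potentials, potential differences, linear-response free
# energies and the step-table audit.

test_that("site potential reproduces the analytic Coulomb value", {
  site <- matrix(c(0, 0, 0), 1, 3)
  env <- charged_environment(matrix(c(1, 0, 0), 1, 3), 1, "solvent")
  rec <- site_potential(site, env)
  expect_equal(rec$phi_total, 14.3996, tolerance = 1e-12)
  # empty environment -> 0 V
  env0 <- charged_environment(matrix(numeric(0), 0, 3), numeric(0))
  expect_equal(site_potential(site, env0)$phi_total, 0)
  # overlapping particle is rejected
  env_bad <- charged_environment(matrix(c(0.1, 0, 0), 1, 3), 1, "solvent")
  expect_error(site_potential(site, env_bad), "0.5 A")
})

test_that("component potentials sum to the total and match brute force", {
  fr <- attr(fixture_quad(), "frame")
  site <- fr$sites[["122D"]]
  set.seed(51)
  n <- 100
  coords <- matrix(rnorm(3 * n, 0, 12), n, 3)
  ok <- apply(coords, 1, function(p)
    brute_min_distance(matrix(p, 1, 3), site$atoms) > 0.6)
  coords <- coords[ok, , drop = FALSE]
  q <- runif(nrow(coords), -1, 1)
  tags <- sample(c("protein", "solvent", "counterion"), nrow(coords),
                 replace = TRUE)
  env <- charged_environment(coords, q, tags)
  rec <- site_potential(site, env)
  expect_equal(sum(rec$phi_by_component), rec$phi_total,
               tolerance = 1e-12)
  expect_equal(rec$phi_total, brute_potential(site$atoms, coords, q),
               tolerance = 1e-9)
  # restricting components equals summing the matching tags
  rec_p <- site_potential(site, env, components = "protein")
  expect_equal(rec_p$phi_total, rec$phi_by_component[["protein"]],
               tolerance = 1e-12)
})

test_that("Coulomb evaluation is linear in charge and scales as 1/r", {
  site <- matrix(0, 1, 3)
  p <- matrix(c(2, 1, -1), 1, 3)
  phi1 <- site_potential(site, charged_environment(p, 0.5))$phi_total
  phi2 <- site_potential(site, charged_environment(p, 1.0))$phi_total
  expect_equal(phi2, 2 * phi1, tolerance = 1e-12)
  phi_half <- site_potential(site, charged_environment(2 * p, 1.0))$phi_total
  expect_equal(phi_half, phi2 / 2, tolerance = 1e-12)
})

test_that("delta_phi signs follow the environment by construction", {
  fr <- attr(fixture_quad(), "frame")
  ox <- fr$sites[["124A"]]; nu <- fr$sites[["122D"]]
  # single negative charge closer to the neutral indole than the oxidized:
  # phi(ox) - phi(neutral) > 0 (transfer toward the neutral site favored)
  p <- matrix(nu$nh + c(0, 0, 3), 1, 3)
  env <- charged_environment(p, -1, "solvent")
  d <- delta_phi(site_potential(ox, env)$phi_total,
                 site_potential(nu, env)$phi_total)
  expect_gt(d$summary[["mean"]], 0)
  # identical records -> identically zero
  v <- rnorm(10)
  expect_equal(delta_phi(v, v)$delta, rep(0, 10))
  expect_error(delta_phi(rnorm(5), rnorm(4)), "mismatch")
  # a positive charge planted near 124D lowers delta_phi toward 124D
  ox2 <- fr$sites[["124A"]]; tgt <- fr$sites[["124D"]]
  base_env <- charged_environment(matrix(c(30, 0, 0), 1, 3), -0.5,
                                  "solvent")
  red <- charged_environment(rbind(matrix(c(30, 0, 0), 1, 3),
                                   matrix(tgt$nh + c(0, 0, 3), 1, 3)),
                             c(-0.5, 1), c("solvent", "ReD"))
  d_base <- delta_phi(site_potential(ox2, base_env)$phi_total,
                      site_potential(tgt, base_env)$phi_total)
  d_red <- delta_phi(site_potential(ox2, red)$phi_total,
                     site_potential(tgt, red)$phi_total)
  expect_lt(d_red$summary[["mean"]], d_base$summary[["mean"]])
})

test_that("linear-response estimator: symmetric case, antisymmetry,
           recovery", {
  # exact symmetric means
  a <- c(800, 800); b <- c(-800, -800)
  fr <- linear_response_dG(a, b, n_boot = 10)
  expect_equal(fr$dG, 0)
  expect_equal(fr$lambda_est, 800)
  # swapping ensembles with negated gaps negates dG exactly
  g <- gen_energy_gaps(gap_spec(dG_true = 67, lambda_true = 800,
                                n_samples = 5000, seed = 12))
  f1 <- linear_response_dG(g$A, g$B, n_boot = 50)
  f2 <- linear_response_dG(-g$B$values, -g$A$values, n_boot = 50)
  expect_equal(f2$dG, -f1$dG, tolerance = 1e-12)
  # planted recovery at the published step value
  g3 <- gen_energy_gaps(gap_spec(dG_true = -320, lambda_true = 800,
                                 n_samples = 1e5, seed = 13))
  f3 <- linear_response_dG(g3$A, g3$B, n_boot = 50)
  expect_equal(f3$dG, -320, tolerance = 5)
  expect_equal(f3$lambda_est, 800, tolerance = 5)
  # inconsistent ensembles flag a non-positive lambda
  expect_warning(linear_response_dG(c(-10, -11), c(10, 11), n_boot = 5),
                 "non-positive")
})

test_that("node free energies recover a consistent potential exactly and
           rank the reference states thermodynamically", {
  # cycle-consistent table: G is recovered exactly
  G <- c(`124A` = 0, `122A` = 50, `122D` = -300, `124D` = 150)
  m <- outer(G, G, function(a, b) b - a)
  diag(m) <- NA
  expect_equal(node_free_energies(m), G)
  # the reference table: 122D most stable, 124D least stable
  g_ref <- node_free_energies(reference_dg_table())
  expect_equal(names(sort(g_ref)), c("122D", "124A", "122A", "124D"))
})

test_that("the reference step table is exactly antisymmetric and its
           cycle residuals are reported", {
  dg <- reference_dg_table()
  audit <- dg_table(dg)
  expect_true(audit$antisymmetric)
  expect_equal(max(abs(audit$antisym_residuals$residual)), 0)
  # the 124A -> 122A -> 122D -> 124A cycle closes to +91 meV
  r <- audit$cycles$residual[audit$cycles$cycle ==
                               "124A->122A->122D->124A"]
  expect_equal(r, 91)
  # missing off-diagonal entries are tolerated as NA markers
  m <- dg; m["124A", "122A"] <- NA; m["122A", "124A"] <- NA
  audit2 <- dg_table(m)
  expect_true(is.na(audit2$table["124A", "122A"]))
  # duplicate conflicting directed entries are rejected
  expect_error(dg_table(list(
    list(from = "124A", to = "122A", dG = 67),
    list(from = "124A", to = "122A", dG = 68))), "conflict")
})
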