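# Exclusive water assignment, coordination curves, density grids,
# difference maps and shift recovery.

test_that("exclusive assignment matches brute-force nearest-site search", {
  fr <- attr(fixture_quad(), "frame")
  set.seed(21)
  fr$waters <- matrix(rnorm(150, 0, 5), 50, 3)
  a <- assign_waters_exclusive(fr)
  sites <- c("124A", "122A", "122D", "124D")
  for (k in c(1, 10, 25, 50)) {
    d <- vapply(sites, function(lbl) brute_min_distance(
                  matrix(fr$waters[k, ], 1, 3), fr$sites[[lbl]]$atoms),
                numeric(1))
    expect_equal(a$nearest_site[k], names(d)[which.min(d)])
    expect_equal(a$distance[k], min(d), tolerance = 1e-12)
  }
})

test_that("assignment ties go to the earlier site in fixed order", {
  fr <- attr(fixture_quad(), "frame")
  # symmetric point: equidistant (NH metric) from 124A and 122A NE1
  mid <- (fr$sites[["124A"]]$nh + fr$sites[["122A"]]$nh) / 2
  fr$waters <- matrix(mid, 1, 3)
  a <- assign_waters_exclusive(fr, mode = "NH-only")
  expect_equal(a$nearest_site, "124A")
})

test_that("coordination curves are step-like, monotone, and partition
           waters", {
  fr <- attr(fixture_quad(), "frame")
  w <- fr$sites[["124A"]]$nh + c(2.5, 0, 0)
  # guard: make sure the planted water is indeed nearest to 124A
  fr$waters <- matrix(w, 1, 3)
  cc <- coordination_curve(list(fr), "124A", cutoffs = seq(1, 4, 0.25),
                           mode = "NH-only")
  d <- sqrt(sum((w - fr$sites[["124A"]]$nh)^2))
  expect_equal(cc$n_water, as.numeric(cc$cutoff >= d))
  expect_true(all(diff(cc$n_water) >= 0))
  expect_error(coordination_curve(list(fr), "124A", cutoffs = numeric(0)),
               "empty")

  # partition invariant on a real trajectory frame
  tr <- fixture_traj()
  f <- tr$frames[[5]]
  a <- assign_waters_exclusive(f)
  for (r in c(3, 4, 6)) {
    per_site <- vapply(c("124A", "122A", "122D", "124D"), function(s)
      sum(a$nearest_site == s & a$distance <= r), numeric(1))
    expect_equal(sum(per_site), sum(a$distance <= r))
  }
})

test_that("coordination changes upon forced transfer have the planted
           signs", {
  tr <- fixture_traj()
  n <- length(tr) / 2
  cuts <- seq(2.6, 3.4, by = 0.1)
  dcoord <- function(site) {
    c0 <- coordination_curve(tr$frames[1:n], site, cuts, mode = "NH-only")
    c1 <- coordination_curve(tr$frames[(n + 1):(2 * n)], site, cuts,
                             mode = "NH-only")
    c1$n_water - c0$n_water
  }
  expect_gt(max(dcoord("122D")), 0.5)   # acceptor gains its bridge water
  expect_lt(min(dcoord("124A")), -0.5)  # donor loses it
})

test_that("density maps conserve water counts and respect rho0 on uniform
           input", {
  fr <- attr(fixture_quad(), "frame")
  # all waters frozen at one point inside the grid
  p <- fr$sites[["122D"]]$nh + c(0, 0, 2)
  fr$waters <- matrix(p, 3, 3, byrow = TRUE)
  g <- density_map(rep(list(fr), 12), spacing = 0.2)
  expect_equal(grid_integral(g), 3, tolerance = 1e-9)

  # uniform random waters: mean masked density ~ rho0 (Monte Carlo)
  set.seed(31)
  ctr <- colMeans(fr$sites[["122A"]]$atoms)
  box <- 24
  n_w <- round(quad_constants$rho0_water * box^3)  # plant bulk density
  frames <- lapply(1:30, function(k) {
    f <- fr
    f$waters <- matrix(runif(n_w * 3, -box / 2, box / 2), n_w, 3) +
      matrix(ctr, n_w, 3, byrow = TRUE)
    f
  })
  g2 <- density_map(frames, spacing = 0.4, superpose = FALSE)
  expect_equal(mean(g2$values[g2$mask]), quad_constants$rho0_water,
               tolerance = 0.15)
})

test_that("density maps are invariant under global rigid motion", {
  tr <- fixture_traj()
  frames <- tr$frames[1:40]
  g0 <- density_map(frames, spacing = 0.2)
  set.seed(41)
  rig <- random_rigid()
  g1 <- density_map(lapply(frames, transform_frame, rig = rig),
                    spacing = 0.2)
  # canonical-pose grids: identical lattice and values
  expect_equal(g1$origin, g0$origin)
  expect_equal(g1$values, g0$values)
  expect_equal(grid_integral(g1, masked = TRUE),
               grid_integral(g0, masked = TRUE))
})

test_that("difference maps are antisymmetric, linear, and silent on
           identical input", {
  tr <- fixture_traj()
  n <- length(tr) / 2
  g0 <- density_map(tr$frames[1:n])
  g1 <- density_map(tr$frames[(n + 1):(2 * n)])
  d01 <- difference_map(g1, g0)
  d10 <- difference_map(g0, g1)
  expect_equal(d01$values, -d10$values)
  expect_equal(sum(d01$values) * d01$spacing^3,
               grid_integral(g1) - grid_integral(g0), tolerance = 1e-9)
  did <- difference_map(g0, g0)
  expect_equal(max(abs(did$values)), 0)
  expect_equal(nrow(attr(did, "regions")), 0L)
  g_bad <- g0; g_bad$origin <- g0$origin + 1
  expect_error(difference_map(g_bad, g0), "congruent")
})

test_that("planted shifts are recovered with antisymmetry", {
  tr <- fixture_traj()
  n <- length(tr) / 2
  first <- tr$frames[1:n]; second <- tr$frames[(n + 1):(2 * n)]
  s_fwd <- measure_shift(first, second, "122D")
  expect_equal(s_fwd, 0.15, tolerance = 0.02)
  # mirrored input: shift away from the site, equal magnitude
  s_rev <- measure_shift(second, first, "122D")
  expect_equal(s_rev, -s_fwd, tolerance = 0.02)
})

test_that("shift recovery works across the planted range on grids", {
  s <- fixture_quad()
  for (mag in c(0.05, 0.2)) {
    tr <- gen_trajectory(s, hydration_spec(shift_magnitude = mag,
                                           seed = 13),
                         n_frames_per_state = 150,
                         switch_state = "122D+")
    n <- length(tr) / 2
    est <- measure_shift(tr$frames[1:n], tr$frames[(n + 1):(2 * n)],
                         "122D")
    expect_equal(est, mag, tolerance = 0.02)
  }
})
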