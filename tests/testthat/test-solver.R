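# Static equilibrium: gradient correctness, convergence, balance, symmetry.

test_that("zero load leaves the model at the reference pose with zero energy", {
  res <- solve_static(canonical_model(), NULL)
  expect_true(res$converged)
  expect_identical(res$pose, rep(0, 12))
  expect_identical(res$springs$strain, rep(0, 64))
  expect_identical(res$elastic_energy, 0)
})

test_that("analytic gradient matches central differences at random poses", {
  model <- canonical_model()
  scen <- default_scenarios()[5, ]
  set.seed(314)
  worst <- 0
  for (rep_i in 1:20) {
    p <- rnorm(12, sd = 0.02)
    g <- potential_gradient(model, p, scen)
    gfd <- vapply(1:12, function(k) {
      h <- 1e-6 * (1 + abs(p[k]))
      ep <- p; em <- p; ep[k] <- ep[k] + h; em[k] <- em[k] - h
      (potential_energy(model, ep, scen) - potential_energy(model, em, scen)) / (2 * h)
    }, 1)
    scale <- max(abs(gfd), 1)
    worst <- max(worst, max(abs(g - gfd)) / scale)
  }
  expect_lt(worst, 1e-5)
})

test_that("every battery scenario converges and balances forces and moments", {
  recs <- canonical_battery()
  expect_true(all(recs$converged))
  results <- attr(recs, "results")
  expect_length(results, 8)
  for (res in results) {
    resid <- equilibrium_residual(canonical_model(), res)
    expect_lt(max(resid$force_residual), 1e-6)
    expect_lt(max(resid$moment_residual), 1e-6)
  }
})

test_that("no spring ever carries a negative (compressive) force", {
  recs <- canonical_battery()
  expect_true(all(recs$force >= 0))
})

test_that("symmetric load on the symmetric model gives equal left/right strains", {
  grid <- average_by_group(canonical_battery())
  g1 <- dplyr::filter(grid, scenario == 1)
  wide <- tidyr::pivot_wider(g1[, c("group", "side", "mean_strain")],
                             names_from = "side", values_from = "mean_strain")
  expect_equal(wide$L, wide$R, tolerance = 1e-8)
})

test_that("opposite lateral loads are reflection-equivalent", {
  grid <- average_by_group(canonical_battery())
  g3 <- dplyr::filter(grid, scenario == 3)
  g4 <- dplyr::filter(grid, scenario == 4)
  m <- dplyr::inner_join(g3, g4, by = "group", suffix = c("_3", "_4"),
                         relationship = "many-to-many")
  cross <- dplyr::filter(m, side_3 == "L" & side_4 == "R" |
                            side_3 == "R" & side_4 == "L")
  expect_equal(cross$mean_strain_3, cross$mean_strain_4, tolerance = 1e-8)
})

test_that("equilibrium elastic energy is monotone in the load scale", {
  model <- canonical_model()
  scen <- default_scenarios()[5, ]
  energies <- vapply(c(0.25, 0.5, 0.75, 1), function(a) {
    s <- scen; s$fx <- a * s$fx; s$fy <- a * s$fy
    solve_static(model, s)$elastic_energy
  }, 1)
  expect_true(all(diff(energies) > 0))
  expect_true(all(energies <= energies[4]))
})

test_that("repeated solves are bitwise identical", {
  model <- canonical_model()
  scen <- default_scenarios()[2, ]
  r1 <- solve_static(model, scen)
  r2 <- solve_static(model, scen)
  expect_identical(r1$pose, r2$pose)
  expect_identical(r1$springs$strain, r2$springs$strain)
})

test_that("recorded strains match independent point-distance arithmetic", {
  model <- canonical_model()
  res <- attr(canonical_battery(), "results")[[7]]
  X <- resolve_points(model, res$pose)
  for (k in c(1, 17, 33, 55, 64)) {
    a <- X[model$ia[k], ]; b <- X[model$ib[k], ]
    L <- sqrt(sum((a - b)^2))
    expect_equal(res$springs$strain[k],
                 (L - model$L0[k]) / model$L0[k], tolerance = 1e-12)
  }
})

test_that("axial displacement of an endpoint gives the defining strain", {
  model <- canonical_model()
  # translate the sacrum along +z by 1% of a dorsal parallel spring's length:
  # springs aligned with the motion change length accordingly
  pose <- rep(0, 12)
  pose[3] <- 0.5
  st <- element_strain(model, pose)
  # direct definition check on one spring
  X <- resolve_points(model, pose)
  L <- sqrt(sum((X[model$ia[1], ] - X[model$ib[1], ])^2))
  expect_equal(st$strain[1], (L - model$L0[1]) / model$L0[1], tolerance = 1e-14)
})

test_that("the rigid-motion guard flags mechanism-like drift", {
  model <- canonical_model()
  expect_error(
    solve_static(model, default_scenarios()[1, ],
                 opts = list(guard_translation = 1e-4)),
    class = "sijstrain_mechanism_error")
})
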