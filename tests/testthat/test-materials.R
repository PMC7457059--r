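# Constitutive laws: bone elasticity, ligament piecewise law, joint law,
# Mooney-Rivlin fit.

test_that("derived bulk and shear moduli follow the isotropic formulas", {
  iso <- derive_isotropic(1.7e10, 0.3)
  expect_equal(iso$K, 1.4167e10, tolerance = 1e-4)
  expect_equal(iso$G, 6.5385e9, tolerance = 1e-5)
  # exact formulas
  expect_identical(iso$K, 1.7e10 / (3 * (1 - 0.6)))
  expect_identical(iso$G, 1.7e10 / (2 * 1.3))
  # nu = 0 limit
  iso0 <- derive_isotropic(9e9, 0)
  expect_identical(iso0$K, 3e9)
  expect_identical(iso0$G, 4.5e9)
  expect_error(derive_isotropic(-1, 0.3), class = "sijstrain_invalid_parameter")
  expect_error(derive_isotropic(1e10, 0.5), class = "sijstrain_invalid_parameter")
})

test_that("ligament stiffness bands are half-open, closed on the left, and tension-only", {
  law <- ligament_law()
  strains <- c(-0.05, 0, 0.01, 0.0249, 0.025, 0.049, 0.05, 0.099, 0.10, 0.12, 0.5)
  expect_equal(ligament_stiffness(law, strains),
               c(0, 0, 39, 39, 55, 55, 103, 103, 100, 100, 100))
})

test_that("ligament force is the closed-form integral of the stiffness over elongation", {
  law <- ligament_law()
  expect_identical(ligament_force(law, 0, 10), 0)
  expect_identical(ligament_force(law, -0.1, 10), 0)
  expect_equal(ligament_force(law, 0.025, 10), 9.75)
  # band-edge values from an independently written cumulative sum
  edges <- c(0.025, 0.05, 0.10)
  ks <- c(39, 55, 103, 100)
  for (L0 in c(5, 10, 17.3)) {
    widths <- diff(c(0, edges)) * L0
    cum <- cumsum(ks[1:3] * widths)
    expect_equal(ligament_force(law, edges, L0), cum, tolerance = 1e-12)
    # quadrature oracle across the working strain range
    for (s in c(0.004, 0.03, 0.07, 0.15, 0.3)) {
      q <- integrate(function(d) ligament_stiffness(law, d / L0), 0, s * L0,
                     subdivisions = 500, rel.tol = 1e-11)$value
      expect_equal(ligament_force(law, s, L0), q, tolerance = 1e-8)
    }
  }
  expect_error(ligament_force(law, 0.1, -1), class = "sijstrain_invalid_parameter")
})

test_that("ligament energy is C1 with derivative equal to the force, and non-decreasing", {
  law <- ligament_law()
  L0 <- 12
  expect_identical(ligament_energy(law, 0, L0), 0)
  expect_identical(ligament_energy(law, -0.2, L0), 0)
  for (s in c(0.01, 0.025, 0.03, 0.05, 0.08, 0.1, 0.2)) {
    h <- 1e-7
    fd <- (ligament_energy(law, s + h / L0, L0) -
             ligament_energy(law, s - h / L0, L0)) / (2 * h)
    expect_equal(fd, ligament_force(law, s, L0), tolerance = 1e-6)
  }
  ss <- seq(0, 0.3, by = 0.002)
  expect_true(all(diff(ligament_energy(law, ss, L0)) >= 0))
})

test_that("joint tangent modulus is compression-only, monotone, with the printed coefficients", {
  law <- joint_law()
  expect_identical(joint_tangent_modulus(law, 0), 0)
  expect_identical(joint_tangent_modulus(law, -0.1), 0)
  expect_equal(joint_tangent_modulus(law, 0.1), 4.411)
  eps <- seq(0.01, 0.35, by = 0.01)
  expect_true(all(diff(joint_tangent_modulus(law, eps)) > 0))
})

test_that("joint stress is the exact antiderivative of the tangent modulus", {
  law <- joint_law()
  expect_identical(law$stress_coeff_quadratic, 20.71 / 2)
  expect_identical(law$stress_coeff_cubic, 234 / 3)
  expect_identical(joint_stress(law, 0), 0)
  for (e in c(0.05, 0.15, 0.3)) {
    q <- integrate(function(x) joint_tangent_modulus(law, x), 0, e,
                   rel.tol = 1e-12)$value
    expect_equal(joint_stress(law, e), q, tolerance = 1e-10)
    h <- 1e-7
    fd <- (joint_stress(law, e + h) - joint_stress(law, e - h)) / (2 * h)
    expect_equal(fd, joint_tangent_modulus(law, e), tolerance = 1e-6)
  }
})

test_that("Mooney-Rivlin uniaxial stress matches its strain-energy derivative", {
  p <- c(c10 = -1.7, c01 = 1.8, c11 = 1.6)
  expect_identical(mr_uniaxial_stress(p, 1), 0)
  # neo-Hookean limit
  nh <- c(c10 = 0.8, c01 = 0, c11 = 0)
  lam <- c(0.7, 0.9, 1.2)
  expect_equal(mr_uniaxial_stress(nh, lam), 2 * 0.8 * (lam - 1 / lam^2),
               tolerance = 1e-12)
  # energy-derivative oracle, written independently of the implementation
  W <- function(l) {
    I1 <- l^2 + 2 / l; I2 <- 2 * l + 1 / l^2
    pp <- unname(p)
    pp[1] * (I1 - 3) + pp[2] * (I2 - 3) + pp[3] * (I1 - 3) * (I2 - 3)
  }
  for (l in c(0.75, 0.9, 1.1, 1.3)) {
    h <- 1e-6
    fd <- (W(l + h) - W(l - h)) / (2 * h)
    expect_equal(mr_uniaxial_stress(p, l), fd, tolerance = 1e-8)
  }
  expect_error(mr_uniaxial_stress(p, -1), class = "sijstrain_invalid_parameter")
})

test_that("Mooney-Rivlin fit to the joint stress curve is tight, deterministic and bookkept", {
  law <- joint_law()
  fit <- fit_mooney_rivlin(law)
  expect_lt(fit$max_rel_error, 0.02)
  refit <- fit_mooney_rivlin(law)
  expect_identical(fit$coefficients, refit$coefficients)
  # recorded residual bound holds at every sample
  expect_true(all(abs(fit$samples$rel_residual) <= fit$max_rel_error + 1e-15))
  expect_equal(fit$samples$stress_target,
               joint_stress(law, fit$samples$eps_c))
  expect_error(fit_mooney_rivlin(law, fit_range = c(0, 0.3)),
               class = "sijstrain_invalid_parameter")
  expect_error(fit_mooney_rivlin(law, n_samples = 5),
               class = "sijstrain_invalid_parameter")
  td <- tidy(fit)
  expect_identical(td$term, c("c10", "c01", "c11"))
  expect_identical(glance(fit)$max_rel_error, fit$max_rel_error)
})
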