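# Constitutive laws: isotropic bone elasticity, piecewise tension-only
# ligament stiffness, compression-only hyperelastic sacrocaudal joint,
# and the 3-parameter Mooney-Rivlin fit to the joint stress curve.
#
# Internal units: N, mm, MPa (1 MPa * mm^2 = 1 N). Young's modulus and the
# derived bulk/shear moduli are kept in Pa as they enter no force balance
# (bones are rigid in this model) and are reported as loaded.

#' Isotropic elasticity with derived bulk and shear moduli
#'
#' Builds an isotropic linear-elastic parameter set from Young's modulus and
#' Poisson's ratio, deriving the bulk modulus `K = E / (3 (1 - 2 nu))` and
#' shear modulus `G = E / (2 (1 + nu))`. These are the bone properties of the
#' pelvis model; the rigid-body solver does not use them, but they are part
#' of the material contract and are exported with any serialized material set.
#'
#' @param E Young's modulus, Pa. Must be positive.
#' @param nu Poisson's ratio, dimensionless, in (0, 0.5) (0 is allowed for
#'   the degenerate no-lateral-coupling case).
#' @return A tibble with one row and columns `E`, `nu`, `K`, `G` (Pa),
#'   classed `sij_isotropic`.
#' @examples
#' derive_isotropic(1.7e10, 0.3)
#' @export
derive_isotropic <- function(E, nu) {
  check_pos_scalar(E, "E")
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) ||
      nu < 0 || nu >= 0.5) {
    abort("`nu` must be a single number in [0, 0.5).",
          class = "sijstrain_invalid_parameter")
  }
  out <- tibble(
    E = E, nu = nu,
    K = E / (3 * (1 - 2 * nu)),
    G = E / (2 * (1 + nu))
  )
  class(out) <- c("sij_isotropic", class(out))
  out
}

#' Piecewise tension-only ligament stiffness law
#'
#' The ligament tensile stiffness is a piecewise-constant function of tensile
#' strain: 39 N/mm below 2.5% strain, 55 N/mm from 2.5 to 5%, 103 N/mm from
#' 5 to 10%, and 100 N/mm above 10%. Bands are half-open, closed on the left,
#' so a strain of exactly 0.10 maps to 100 N/mm. The law carries no stiffness
#' in compression (strain <= 0 gives zero stiffness and zero force).
#'
#' Stiffness is force per unit elongation (N/mm) indexed by strain; force is
#' obtained by integrating the stiffness over elongation, which makes the
#' force-elongation curve continuous and piecewise linear.
#'
#' @param breakpoints Strain band edges (dimensionless), strictly increasing.
#' @param stiffness Stiffness per band, N/mm; length `length(breakpoints) + 1`.
#' @return A `sij_ligament_law` object.
#' @export
ligament_law <- function(breakpoints = c(0.025, 0.05, 0.10),
                         stiffness = c(39, 55, 103, 100)) {
  if (length(stiffness) != length(breakpoints) + 1L) {
    abort("`stiffness` must have one more element than `breakpoints`.",
          class = "sijstrain_invalid_parameter")
  }
  if (any(!is.finite(breakpoints)) || is.unsorted(breakpoints, strictly = TRUE) ||
      any(breakpoints <= 0)) {
    abort("`breakpoints` must be positive, finite and strictly increasing.",
          class = "sijstrain_invalid_parameter")
  }
  if (any(!is.finite(stiffness)) || any(stiffness < 0)) {
    abort("`stiffness` values must be finite and non-negative.",
          class = "sijstrain_invalid_parameter")
  }
  structure(
    list(edges = c(0, breakpoints), stiffness = stiffness, tension_only = TRUE),
    class = "sij_ligament_law"
  )
}

#' @export
print.sij_ligament_law <- function(x, ...) {
  bands <- paste0(
    "[", format(x$edges, trim = TRUE), ", ",
    c(format(x$edges[-1], trim = TRUE), "Inf"), ")"
  )
  cat("Tension-only piecewise ligament law (strain band -> N/mm):\n")
  cat(paste0("  ", bands, "  ", x$stiffness, collapse = "\n"), "\n")
  invisible(x)
}

#' Ligament stiffness at a given tensile strain
#'
#' @param law A [ligament_law()].
#' @param strain Tensile strain (dimensionless); vectorized. Values <= 0
#'   return 0 (no stiffness in compression).
#' @return Stiffness in N/mm.
#' @examples
#' law <- ligament_law()
#' ligament_stiffness(law, c(0.01, 0.12, -0.05))
#' @export
ligament_stiffness <- function(law, strain) {
  stopifnot(inherits(law, "sij_ligament_law"))
  idx <- findInterval(strain, law$edges)        # 0 for strain < 0
  k <- c(0, law$stiffness)[idx + 1L]
  k[strain <= 0] <- 0
  k
}

# Shared closed-form piecewise integration over elongation.
# delta: elongation (mm), L0: rest length (mm). Returns list(force, energy).
lig_force_energy <- function(law, delta, L0) {
  edges_e <- law$edges
  ks <- law$stiffness
  nb <- length(ks)
  force <- numeric(length(delta))
  energy <- numeric(length(delta))
  for (i in seq_len(nb)) {
    d_lo <- edges_e[i] * L0
    d_hi <- if (i < nb) edges_e[i + 1L] * L0 else Inf
    w <- d_hi - d_lo
    u <- pmin(pmax(delta - d_lo, 0), w)         # in-band elongation
    over <- pmax(delta - d_hi, 0)
    force <- force + ks[i] * u
    energy <- energy + ks[i] * (0.5 * u^2 + u * over)
  }
  list(force = force, energy = energy)
}

#' Tension-only ligament force
#'
#' Closed-form integral of [ligament_stiffness()] over elongation:
#' `F(delta) = int_0^delta k(delta'/L0) d delta'` with `delta = strain * L0`.
#' Zero for strain <= 0; continuous and piecewise linear in elongation.
#'
#' @inheritParams ligament_stiffness
#' @param rest_length Rest length `L0` in mm, positive. Recycled against
#'   `strain`.
#' @return Force in N (never negative).
#' @examples
#' ligament_force(ligament_law(), 0.025, 10)  # 39 * 0.25 mm = 9.75 N
#' @export
ligament_force <- function(law, strain, rest_length) {
  if (any(!is.finite(rest_length)) || any(rest_length <= 0)) {
    abort("`rest_length` must be positive and finite.",
          class = "sijstrain_invalid_parameter")
  }
  n <- max(length(strain), length(rest_length))
  strain <- rep_len(strain, n)
  rest_length <- rep_len(rest_length, n)
  lig_force_energy(law, strain * rest_length, rest_length)$force
}

#' Ligament elastic energy
#'
#' Piecewise-quadratic strain energy whose derivative with respect to
#' elongation is exactly [ligament_force()]; zero for strain <= 0.
#'
#' @inheritParams ligament_force
#' @return Energy in N mm.
#' @export
ligament_energy <- function(law, strain, rest_length) {
  if (any(!is.finite(rest_length)) || any(rest_length <= 0)) {
    abort("`rest_length` must be positive and finite.",
          class = "sijstrain_invalid_parameter")
  }
  n <- max(length(strain), length(rest_length))
  strain <- rep_len(strain, n)
  rest_length <- rep_len(rest_length, n)
  lig_force_energy(law, strain * rest_length, rest_length)$energy
}

#' Compression-only hyperelastic joint law
#'
#' Tangent modulus `E(eps) = a eps + b eps^2` (MPa) in compression, zero in
#' tension, with defaults `a = 20.71`, `b = 234` MPa. `eps` is the compressive
#' strain magnitude: positive values mean the joint is compressed. The
#' corresponding stress curve is the exact antiderivative,
#' `sigma(eps) = (a/2) eps^2 + (b/3) eps^3` (10.355 and 78 MPa at the
#' defaults).
#'
#' @param a Linear tangent-modulus coefficient, MPa.
#' @param b Quadratic tangent-modulus coefficient, MPa.
#' @return A `sij_joint_law` object with the derived stress coefficients.
#' @export
joint_law <- function(a = 20.71, b = 234) {
  check_pos_scalar(a, "a"); check_pos_scalar(b, "b")
  structure(
    list(a = a, b = b,
         stress_coeff_quadratic = a / 2,
         stress_coeff_cubic = b / 3,
         compression_only = TRUE),
    class = "sij_joint_law"
  )
}

#' @export
print.sij_joint_law <- function(x, ...) {
  cat(sprintf(
    "Compression-only joint law: E(eps) = %g eps + %g eps^2 MPa;\n  sigma(eps) = %g eps^2 + %g eps^3 MPa (eps = compressive strain magnitude)\n",
    x$a, x$b, x$stress_coeff_quadratic, x$stress_coeff_cubic))
  invisible(x)
}

#' Joint tangent modulus
#'
#' @param law A [joint_law()].
#' @param eps_c Compressive strain magnitude (dimensionless); vectorized.
#'   Values <= 0 (joint stretched or at rest) return 0.
#' @return Tangent modulus, MPa.
#' @export
joint_tangent_modulus <- function(law, eps_c) {
  stopifnot(inherits(law, "sij_joint_law"))
  ifelse(eps_c > 0, law$a * eps_c + law$b * eps_c^2, 0)
}

#' Joint compressive stress
#'
#' Exact antiderivative of [joint_tangent_modulus()]:
#' `(a/2) eps^2 + (b/3) eps^3` for `eps_c > 0`, zero otherwise.
#'
#' @inheritParams joint_tangent_modulus
#' @return Normal stress, MPa (compression positive).
#' @export
joint_stress <- function(law, eps_c) {
  stopifnot(inherits(law, "sij_joint_law"))
  ifelse(eps_c > 0,
         law$stress_coeff_quadratic * eps_c^2 + law$stress_coeff_cubic * eps_c^3,
         0)
}

# Strain-energy density (MPa = N mm / mm^3): antiderivative of joint_stress.
joint_energy_density <- function(law, eps_c) {
  ifelse(eps_c > 0,
         law$stress_coeff_quadratic * eps_c^3 / 3 +
           law$stress_coeff_cubic * eps_c^4 / 4,
         0)
}

# ---- Mooney-Rivlin -------------------------------------------------------

# Invariants and their stretch-derivatives under incompressible uniaxial
# kinematics: lambda1 = lambda, lambda2 = lambda3 = lambda^(-1/2).
mr_invariants <- function(stretch) {
  list(
    I1 = stretch^2 + 2 / stretch,
    I2 = 2 * stretch + 1 / stretch^2,
    dI1 = 2 * stretch - 2 / stretch^2,
    dI2 = 2 - 2 / stretch^3
  )
}

#' Uniaxial stress of an incompressible 3-parameter Mooney-Rivlin solid
#'
#' Strain-energy density `W = c10 (I1 - 3) + c01 (I2 - 3) +
#' c11 (I1 - 3)(I2 - 3)` under uniaxial incompressible kinematics. The
#' nominal (first Piola-Kirchhoff) stress is `P = dW/d lambda`; the true
#' (Cauchy) stress is `lambda * P`.
#'
#' @param p Either a `sij_mr_fit` from [fit_mooney_rivlin()] or a numeric
#'   vector/list with elements `c10`, `c01`, `c11` (MPa).
#' @param stretch Axial stretch ratio, positive; 1 is the undeformed state.
#' @param measure `"nominal"` (default) or `"true"`.
#' @return Stress in MPa (negative in compression).
#' @export
mr_uniaxial_stress <- function(p, stretch, measure = c("nominal", "true")) {
  measure <- match.arg(measure)
  if (any(!is.finite(stretch)) || any(stretch <= 0)) {
    abort("`stretch` must be positive and finite.",
          class = "sijstrain_invalid_parameter")
  }
  cf <- mr_coefs(p)
  iv <- mr_invariants(stretch)
  P <- cf[["c10"]] * iv$dI1 + cf[["c01"]] * iv$dI2 +
    cf[["c11"]] * ((iv$I1 - 3) * iv$dI2 + (iv$I2 - 3) * iv$dI1)
  if (measure == "true") P * stretch else P
}

mr_coefs <- function(p) {
  if (inherits(p, "sij_mr_fit")) p <- p$coefficients
  p <- unlist(p)
  if (!all(c("c10", "c01", "c11") %in% names(p))) {
    if (length(p) == 3L) names(p) <- c("c10", "c01", "c11")
    else abort("Mooney-Rivlin parameters must supply c10, c01, c11.",
               class = "sijstrain_invalid_parameter")
  }
  p[c("c10", "c01", "c11")]
}

#' Fit a 3-parameter Mooney-Rivlin model to the joint stress curve
#'
#' Samples the compression-only joint stress curve over a range of
#' compressive strain magnitudes and fits the three Mooney-Rivlin
#' coefficients by relative-error-weighted linear least squares (the model
#' is linear in `c10`, `c01`, `c11`, so the fit is closed-form and
#' deterministic). The compressive strain is interpreted as logarithmic
#' strain magnitude (`stretch = exp(-eps)`) and matched against the true
#' (Cauchy) uniaxial stress; see the methods vignette for why this
#' convention is used.
#'
#' @param law A [joint_law()].
#' @param fit_range Length-2 compressive-strain-magnitude interval within
#'   (0, 0.35].
#' @param n_samples Number of uniformly spaced samples, >= 10.
#' @return A `sij_mr_fit` with elements `coefficients` (c10, c01, c11, MPa),
#'   `fit_range`, `samples` (tibble of eps, target and fitted stress,
#'   relative residual) and `max_rel_error`.
#' @export
fit_mooney_rivlin <- function(law, fit_range = c(0.01, 0.30), n_samples = 60) {
  stopifnot(inherits(law, "sij_joint_law"))
  if (length(fit_range) != 2L || any(!is.finite(fit_range)) ||
      fit_range[1] <= 0 || fit_range[2] > 0.35 || fit_range[1] >= fit_range[2]) {
    abort("`fit_range` must be an increasing interval within (0, 0.35].",
          class = "sijstrain_invalid_parameter")
  }
  if (n_samples < 10) {
    abort("`n_samples` must be at least 10.",
          class = "sijstrain_invalid_parameter")
  }
  eps <- seq(fit_range[1], fit_range[2], length.out = n_samples)
  target <- joint_stress(law, eps)               # compressive magnitude, MPa
  stretch <- exp(-eps)
  iv <- mr_invariants(stretch)
  # Basis: compressive-magnitude true stress contributed by each coefficient.
  basis <- cbind(
    c10 = -iv$dI1 * stretch,
    c01 = -iv$dI2 * stretch,
    c11 = -((iv$I1 - 3) * iv$dI2 + (iv$I2 - 3) * iv$dI1) * stretch
  )
  w <- 1 / target                                # relative-error weighting
  co <- qr.solve(basis * w, target * w)
  fitted <- drop(basis %*% co)
  rel <- (fitted - target) / target
  if (any(!is.finite(co)) || any(!is.finite(rel))) {
    abort("Mooney-Rivlin fit failed to produce finite coefficients.",
          class = "sijstrain_fit_error")
  }
  structure(
    list(
      coefficients = setNames(as.numeric(co), colnames(basis)),
      fit_range = fit_range,
      n_samples = n_samples,
      samples = tibble(eps_c = eps, stress_target = target,
                       stress_fit = fitted, rel_residual = rel),
      max_rel_error = max(abs(rel))
    ),
    class = "sij_mr_fit"
  )
}

#' @export
print.sij_mr_fit <- function(x, ...) {
  cat("3-parameter Mooney-Rivlin fit (MPa):\n")
  print(round(x$coefficients, 5))
  cat(sprintf("fit range: [%g, %g] compressive strain, %d samples; max rel. error %.3g\n",
              x$fit_range[1], x$fit_range[2], x$n_samples, x$max_rel_error))
  invisible(x)
}

#' @rdname fit_mooney_rivlin
#' @param x A `sij_mr_fit`.
#' @param ... Unused.
#' @export
tidy.sij_mr_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = as.numeric(x$coefficients))
}

#' @rdname fit_mooney_rivlin
#' @export
glance.sij_mr_fit <- function(x, ...) {
  tibble(max_rel_error = x$max_rel_error,
         fit_lower = x$fit_range[1], fit_upper = x$fit_range[2],
         n_samples = x$n_samples)
}

#' @rdname fit_mooney_rivlin
#' @param object A `sij_mr_fit`.
#' @export
autoplot.sij_mr_fit <- function(object, ...) {
  dat <- object$samples %>%
    pivot_longer(c("stress_target", "stress_fit"),
                 names_to = "curve", values_to = "stress")
  ggplot(dat, aes(x = .data$eps_c, y = .data$stress, colour = .data$curve)) +
    geom_line() +
    labs(x = "compressive strain magnitude", y = "stress (MPa)",
         colour = NULL) +
    theme_minimal()
}

#' Default material set for the pelvis model
#'
#' Bundles the bone elasticity, ligament law and joint law defaults used
#' throughout the package.
#'
#' @return A list with elements `bone`, `ligament`, `joint`.
#' @export
default_materials <- function() {
  list(
    bone = derive_isotropic(1.7e10, 0.3),
    ligament = ligament_law(),
    joint = joint_law()
  )
}
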