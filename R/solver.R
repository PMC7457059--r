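# Static equilibrium of the two free rigid bodies (sacrum, C1) by
# minimization of total potential energy over a 12-dimensional pose
# (translation + rotation vector per body). Energy is C^1 (piecewise
# smooth forces), so a quasi-Newton search with an exact-gradient Newton
# polish is used rather than force Newton iteration.

skew <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

# Rodrigues rotation matrix for a rotation vector
rot_mat <- function(theta) {
  ang <- sqrt(sum(theta^2))
  if (ang < 1e-12) return(diag(3) + skew(theta))
  K <- skew(theta / ang)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# dR/dtheta_k, k = 1..3 (exact; Gallego & Yezzi form)
rot_grad <- function(theta) {
  ang2 <- sum(theta^2)
  R <- rot_mat(theta)
  if (ang2 < 1e-16) {
    return(lapply(1:3, function(k) skew(diag(3)[, k])))
  }
  lapply(1:3, function(k) {
    ek <- diag(3)[, k]
    v <- crossprod_vec(theta, drop((diag(3) - R) %*% ek))
    ((theta[k] * skew(theta) + skew(v)) / ang2) %*% R
  })
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

pose_split <- function(pose) {
  list(sacrum = list(t = pose[1:3], r = pose[4:6]),
       c1 = list(t = pose[7:9], r = pose[10:12]))
}

#' Resolve world coordinates of all model points under a pose
#'
#' Fixed points are unchanged; points on a free body `b` map to
#' `origin_b + t_b + R(r_b) (p - origin_b)`.
#'
#' @param model A `sij_model`.
#' @param pose Numeric vector of length 12: sacrum translation (mm),
#'   sacrum rotation vector (rad), then the same for C1.
#' @return An n x 3 matrix of world coordinates (mm).
#' @export
resolve_points <- function(model, pose) {
  stopifnot(inherits(model, "sij_model"), length(pose) == 12L)
  if (all(pose == 0)) return(model$P)   # reference configuration, exact
  X <- model$P
  ps <- pose_split(pose)
  for (b in model$bodies) {
    sel <- model$body == b
    o <- model$origins[[b]]
    R <- rot_mat(ps[[b]]$r)
    loc <- sweep(model$P[sel, , drop = FALSE], 2, o)
    X[sel, ] <- sweep(loc %*% t(R), 2, o + ps[[b]]$t, "+")
  }
  X
}

scenario_force <- function(scenario) {
  c(scenario$fx, scenario$fy, 0)
}

# spring geometry under a pose: lengths, unit vectors, strains
spring_state <- function(model, X) {
  d <- X[model$ib, , drop = FALSE] - X[model$ia, , drop = FALSE]
  L <- unname(sqrt(rowSums(d^2)))
  list(L = L, unit = d / L, strain = (L - model$L0) / model$L0)
}

# joint geometry: gap between interface points, compressive strain magnitude
joint_state <- function(model, X) {
  j <- model$joint
  d <- X[j$face_b, ] - X[j$face_a, ]
  gap <- sqrt(sum(d^2))
  list(gap = gap, unit = d / gap,
       eps_c = (j$rest_thickness - gap) / j$rest_thickness)
}

# dE/dL per spring: tension-only ligament force plus (for SIJ springs,
# when enabled) a linear compression-only penalty
spring_dEdL <- function(model, st) {
  f <- ligament_force(model$materials$ligament, st$strain, model$L0)
  if (isTRUE(model$config$sij_penalty)) {
    pen <- model$springs$group == "sij" & st$L < model$L0
    f[pen] <- f[pen] + model$config$sij_penalty_stiffness * (st$L[pen] - model$L0[pen])
  }
  f
}

#' Total potential energy of the model under a pose and load
#'
#' Sum of ligament spring energies, the SIJ compression penalty, the
#' sacrocaudal joint energy and the grounding regularization, minus the
#' work of the dead load at the load point. Exactly zero at the reference
#' pose with zero load.
#'
#' @inheritParams resolve_points
#' @param scenario A single-row scenario (list or tibble row with `fx`,
#'   `fy` in N); `NULL` means no load.
#' @return Energy in N mm.
#' @export
potential_energy <- function(model, pose, scenario = NULL) {
  X <- resolve_points(model, pose)
  st <- spring_state(model, X)
  E <- sum(ligament_energy(model$materials$ligament, st$strain, model$L0))
  if (isTRUE(model$config$sij_penalty)) {
    pen <- model$springs$group == "sij" & st$L < model$L0
    E <- E + 0.5 * model$config$sij_penalty_stiffness *
      sum((st$L[pen] - model$L0[pen])^2)
  }
  js <- joint_state(model, X)
  E <- E + model$joint$area * model$joint$rest_thickness *
    joint_energy_density(model$joint$law, js$eps_c)
  ps <- pose_split(pose)
  for (b in model$bodies) {
    E <- E + 0.5 * model$config$reg_translation * sum(ps[[b]]$t^2) +
      0.5 * model$config$reg_rotation * sum(ps[[b]]$r^2)
  }
  if (!is.null(scenario)) {
    u <- X[model$load_point, ] - model$P[model$load_point, ]
    E <- E - sum(scenario_force(scenario) * u)
  }
  E
}

#' Analytic gradient of the potential energy
#'
#' @inheritParams potential_energy
#' @return Numeric vector of length 12 (N for translations, N mm for
#'   rotation coordinates).
#' @export
potential_gradient <- function(model, pose, scenario = NULL) {
  X <- resolve_points(model, pose)
  st <- spring_state(model, X)
  dEdL <- spring_dEdL(model, st)

  n <- nrow(X)
  gpts <- matrix(0, n, 3)
  contrib <- rbind(-st$unit * dEdL, st$unit * dEdL)
  idx <- c(model$ia, model$ib)
  agg <- rowsum(contrib, idx)
  rows <- as.integer(rownames(agg))
  gpts[rows, ] <- gpts[rows, ] + agg

  js <- joint_state(model, X)
  dEdgap <- -model$joint$area * joint_stress(model$joint$law, js$eps_c)
  gpts[model$joint$face_a, ] <- gpts[model$joint$face_a, ] - dEdgap * js$unit
  gpts[model$joint$face_b, ] <- gpts[model$joint$face_b, ] + dEdgap * js$unit

  if (!is.null(scenario)) {
    gpts[model$load_point, ] <- gpts[model$load_point, ] - scenario_force(scenario)
  }

  ps <- pose_split(pose)
  g <- numeric(12)
  off <- c(sacrum = 0L, c1 = 6L)
  for (b in model$bodies) {
    sel <- model$body == b
    gb <- gpts[sel, , drop = FALSE]
    loc <- sweep(model$P[sel, , drop = FALSE], 2, model$origins[[b]])
    dR <- rot_grad(ps[[b]]$r)
    o <- off[[b]]
    g[o + 1:3] <- colSums(gb) + model$config$reg_translation * ps[[b]]$t
    for (k in 1:3) {
      g[o + 3 + k] <- sum(gb * (loc %*% t(dR[[k]]))) +
        model$config$reg_rotation * ps[[b]]$r[k]
    }
  }
  g
}

#' Solve static equilibrium under a load scenario
#'
#' Minimizes [potential_energy()] from the reference pose with BFGS
#' (analytic gradient), then polishes with damped Newton steps using a
#' finite-difference Hessian of the analytic gradient until the gradient
#' norm meets `tol`. Deterministic for fixed inputs.
#'
#' @param model A `sij_model`.
#' @param scenario Single-row load scenario (`fx`, `fy` in N) or `NULL`.
#' @param opts List: `tol` (gradient 2-norm, default 1e-6 N), `maxit`
#'   (BFGS iterations, default 500), `newton_maxit` (default 60),
#'   `guard_rotation` (rad, default 0.5), `guard_translation` (mm,
#'   default 50).
#' @return A `sij_equilibrium`: pose, convergence diagnostics, per-spring
#'   strain/force table and joint state.
#' @export
solve_static <- function(model, scenario = NULL, opts = list()) {
  stopifnot(inherits(model, "sij_model"))
  o <- modifyList(list(tol = 1e-6, maxit = 500, newton_maxit = 60,
                       guard_rotation = 0.5, guard_translation = 50), opts)
  fn <- function(p) potential_energy(model, p, scenario)
  gr <- function(p) potential_gradient(model, p, scenario)

  fit <- optim(rep(0, 12), fn, gr, method = "BFGS",
               control = list(maxit = o$maxit, reltol = 1e-14))
  p <- fit$par
  iter <- fit$counts[["function"]]

  # damped Newton polish on the analytic gradient
  g <- gr(p)
  lambda <- 1e-8
  for (it in seq_len(o$newton_maxit)) {
    ng <- sqrt(sum(g^2))
    if (ng <= o$tol) break
    H <- fd_hessian(gr, p)
    step <- tryCatch(solve(H + lambda * diag(12), -g),
                     error = function(e) NULL)
    if (is.null(step)) { lambda <- lambda * 100; next }
    p_new <- p + step
    g_new <- gr(p_new)
    if (sqrt(sum(g_new^2)) < ng || fn(p_new) < fn(p)) {
      p <- p_new; g <- g_new; lambda <- max(lambda / 10, 1e-12)
    } else {
      lambda <- lambda * 100
      if (lambda > 1e8) break
    }
    iter <- iter + 1L
  }
  ng <- sqrt(sum(g^2))

  ps <- pose_split(p)
  for (b in model$bodies) {
    if (sqrt(sum(ps[[b]]$t^2)) > o$guard_translation ||
        sqrt(sum(ps[[b]]$r^2)) > o$guard_rotation) {
      abort(sprintf("body '%s' drifted beyond the rigid-motion guard; the model is a mechanism under this load.", b),
            class = "sijstrain_mechanism_error")
    }
  }

  X <- resolve_points(model, p)
  st <- spring_state(model, X)
  js <- joint_state(model, X)
  force <- ligament_force(model$materials$ligament, st$strain, model$L0)
  elastic <- sum(ligament_energy(model$materials$ligament, st$strain, model$L0)) +
    model$joint$area * model$joint$rest_thickness *
    joint_energy_density(model$joint$law, js$eps_c)

  reg_energy <- 0.5 * model$config$reg_translation *
    (sum(ps$sacrum$t^2) + sum(ps$c1$t^2)) +
    0.5 * model$config$reg_rotation * (sum(ps$sacrum$r^2) + sum(ps$c1$r^2))
  if (elastic > 0 && reg_energy > 1e-6 * elastic) {
    warn("grounding regularization stores more than 1e-6 of the elastic energy; results may be regularization-dominated.")
  }

  structure(
    list(
      converged = ng <= o$tol,
      pose = p,
      gradient_norm = ng,
      energy = potential_energy(model, p, scenario),
      elastic_energy = elastic,
      reg_energy = reg_energy,
      iterations = iter,
      springs = model$springs %>%
        mutate(strain = st$strain, force = force),
      joint = tibble(gap = js$gap, gap_strain = (js$gap - model$joint$rest_thickness) /
                       model$joint$rest_thickness,
                     eps_c = js$eps_c,
                     force = model$joint$area * joint_stress(model$joint$law, js$eps_c)),
      scenario = if (is.null(scenario)) NULL else as_tibble(scenario)
    ),
    class = "sij_equilibrium"
  )
}

fd_hessian <- function(gr, p, h = 1e-6) {
  n <- length(p)
  H <- matrix(0, n, n)
  for (k in seq_len(n)) {
    hk <- h * (1 + abs(p[k]))
    ep <- p; ep[k] <- ep[k] + hk
    em <- p; em[k] <- em[k] - hk
    H[, k] <- (gr(ep) - gr(em)) / (2 * hk)
  }
  (H + t(H)) / 2
}

#' @export
print.sij_equilibrium <- function(x, ...) {
  cat(sprintf("sij_equilibrium: converged=%s, |grad|=%.3g, elastic energy %.4g N mm\n",
              x$converged, x$gradient_norm, x$elastic_energy))
  invisible(x)
}

#' Element strains under a pose
#'
#' Recomputes the strain of every spring (and the signed sacrocaudal gap
#' strain) by direct point-distance arithmetic.
#'
#' @inheritParams resolve_points
#' @return Tibble with spring id, group, side, length, strain; the joint
#'   gap strain is attached as attribute `joint_gap_strain`.
#' @export
element_strain <- function(model, pose) {
  X <- resolve_points(model, pose)
  st <- spring_state(model, X)
  js <- joint_state(model, X)
  out <- model$springs %>%
    mutate(length = st$L, strain = st$strain)
  attr(out, "joint_gap_strain") <-
    (js$gap - model$joint$rest_thickness) / model$joint$rest_thickness
  out
}

#' Independent force and moment balance check
#'
#' Recomputes, by direct force summation (not via the energy gradient),
#' the net force (N) and net moment (N mm, about each body's displaced
#' origin) on each free body at an equilibrium: spring tensions, SIJ
#' penalty, joint thrust, grounding regularization and the applied load.
#'
#' @param model A `sij_model`.
#' @param result A `sij_equilibrium` from [solve_static()].
#' @return Tibble with one row per free body: `body`, `force_residual`,
#'   `moment_residual` (vector norms).
#' @export
equilibrium_residual <- function(model, result) {
  stopifnot(inherits(result, "sij_equilibrium"))
  pose <- result$pose
  X <- resolve_points(model, pose)
  n <- nrow(X)

  # force on each point from each element, summed directly
  fpts <- matrix(0, n, 3)
  d <- X[model$ib, , drop = FALSE] - X[model$ia, , drop = FALSE]
  L <- unname(sqrt(rowSums(d^2)))
  unit <- d / L
  tension <- ligament_force(model$materials$ligament, (L - model$L0) / model$L0,
                            model$L0)
  if (isTRUE(model$config$sij_penalty)) {
    pen <- model$springs$group == "sij" & L < model$L0
    tension[pen] <- tension[pen] +
      model$config$sij_penalty_stiffness * (L[pen] - model$L0[pen])
  }
  # tension pulls endpoint a toward b and b toward a
  agg <- rowsum(rbind(unit * tension, -unit * tension),
                c(model$ia, model$ib))
  rows <- as.integer(rownames(agg))
  fpts[rows, ] <- fpts[rows, ] + agg

  j <- model$joint
  dj <- X[j$face_b, ] - X[j$face_a, ]
  gap <- sqrt(sum(dj^2)); uj <- dj / gap
  thrust <- j$area * joint_stress(j$law, (j$rest_thickness - gap) / j$rest_thickness)
  fpts[j$face_a, ] <- fpts[j$face_a, ] - thrust * uj   # pushed apart
  fpts[j$face_b, ] <- fpts[j$face_b, ] + thrust * uj

  if (!is.null(result$scenario)) {
    fpts[model$load_point, ] <- fpts[model$load_point, ] +
      scenario_force(result$scenario)
  }

  ps <- pose_split(pose)
  out <- lapply(model$bodies, function(b) {
    sel <- model$body == b
    centre <- model$origins[[b]] + ps[[b]]$t
    fb <- fpts[sel, , drop = FALSE]
    arm <- sweep(X[sel, , drop = FALSE], 2, centre)
    Fnet <- colSums(fb) - model$config$reg_translation * ps[[b]]$t
    Mnet <- colSums(cbind(
      arm[, 2] * fb[, 3] - arm[, 3] * fb[, 2],
      arm[, 3] * fb[, 1] - arm[, 1] * fb[, 3],
      arm[, 1] * fb[, 2] - arm[, 2] * fb[, 1]
    )) - model$config$reg_rotation * ps[[b]]$r
    tibble(body = b,
           force_residual = sqrt(sum(Fnet^2)),
           moment_residual = sqrt(sum(Mnet^2)))
  })
  bind_rows(out)
}
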