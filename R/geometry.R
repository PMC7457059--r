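# Synthetic pelvis geometry: a parametric, Labrador-scale landmark set.
#
# Coordinate convention (documented, not a measured convention): origin at
# the mid-sagittal point between the acetabula; x lateral (right positive),
# y dorsal positive, z cranial positive; right-handed; units mm. All
# canonical dimensions below are synthetic defaults loosely sized to a
# 25 kg Labrador retriever; they are not measured values.

# canonical right-side / midline coordinates at scale 1 (25 kg reference)
canonical_spec <- function() {
  zs4 <- c(45, 35, 25, 15)
  zs10 <- rep(c(45, 37.5, 30, 22.5, 15), times = 2)
  ys10 <- rep(c(22, 30), each = 5)
  list(
    acetabulum_center = cbind(x = 30, y = 0, z = 0),
    dorsal_sacrum  = cbind(x = rep(8, 4),  y = rep(35, 4), z = zs4),
    dorsal_ilium   = cbind(x = rep(22, 4), y = rep(38, 4), z = zs4),
    ventral_sacrum = cbind(x = rep(10, 4), y = rep(18, 4), z = zs4),
    ventral_ilium  = cbind(x = rep(24, 4), y = rep(16, 4), z = zs4),
    sij_sacrum     = cbind(x = rep(13, 10), y = ys10, z = zs10),
    sij_ilium      = cbind(x = rep(17, 10), y = ys10, z = zs10),
    st_origin_s3       = cbind(x = 9,  y = 25, z = 8),
    st_origin_c1       = cbind(x = 7,  y = 22, z = -6),
    st_insertion_tuber = cbind(x = 28, y = -5, z = -55),
    load_point         = cbind(x = 0, y = 30, z = 40),
    sacrocaudal_center = cbind(x = 0, y = 20, z = 2)
  )
}

# which rigid body carries each landmark class (hemipelves are fixed)
landmark_body <- c(
  acetabulum_center = "fixed",
  dorsal_sacrum = "sacrum", dorsal_ilium = "fixed",
  ventral_sacrum = "sacrum", ventral_ilium = "fixed",
  sij_sacrum = "sacrum", sij_ilium = "fixed",
  st_origin_s3 = "sacrum", st_origin_c1 = "c1",
  st_insertion_tuber = "fixed",
  load_point = "sacrum",
  sacrocaudal_center = "sacrum"   # split into joint faces at assembly time
)

# landmark classes that are spring attachment points (perturbation targets)
spring_attachment_classes <- function() {
  c("dorsal_sacrum", "dorsal_ilium", "ventral_sacrum", "ventral_ilium",
    "sij_sacrum", "sij_ilium", "st_origin_s3", "st_origin_c1",
    "st_insertion_tuber")
}

#' Canonical Labrador-scale pelvis landmarks
#'
#' Builds the mirror-symmetric synthetic landmark set that stands in for a
#' CT-derived pelvis: acetabular supports, 4 dorsal and 4 ventral sheet
#' ligament attachment points per bone per side, 10 sacroiliac joint points
#' per bone per side, the sacrotuberous "Y" attachment triplet per side, a
#' load point on the sacrum and the sacrocaudal joint interface. The left
#' side is the exact reflection of the right across the mid-sagittal plane
#' (x -> -x). All inter-point distances scale linearly with
#' `scale * (body_mass / 25)^(1/3)`.
#'
#' @param body_mass Body mass in kg (reference 25 kg).
#' @param scale Additional dimensionless geometric scale factor.
#' @return A `pelvis_landmarks` tibble with columns `landmark`, `class`,
#'   `side` ("L", "R" or NA for midline), `index`, `body`, `x`, `y`, `z`
#'   (mm), plus attributes `sacrocaudal_area` (mm^2), `sacrocaudal_thickness`
#'   (mm), `scale_factor`.
#' @examples
#' lm <- make_canonical_pelvis()
#' dplyr::count(lm, class, side)
#' @export
make_canonical_pelvis <- function(body_mass = 25, scale = 1) {
  check_pos_scalar(body_mass, "body_mass")
  check_pos_scalar(scale, "scale")
  s <- scale * (body_mass / 25)^(1 / 3)
  spec <- canonical_spec()
  rows <- list()
  for (cls in names(spec)) {
    pts <- unname(spec[[cls]]) * s
    colnames(pts) <- c("x", "y", "z")
    n <- nrow(pts)
    midline <- all(pts[, "x"] == 0)
    if (midline) {
      rows[[cls]] <- tibble(
        landmark = if (n == 1) cls else paste0(cls, "_", seq_len(n)),
        class = cls, side = NA_character_, index = seq_len(n),
        body = unname(landmark_body[cls]),
        x = unname(pts[, "x"]), y = unname(pts[, "y"]), z = unname(pts[, "z"])
      )
    } else {
      right <- tibble(
        landmark = paste0(cls, "_R", if (n > 1) paste0("_", seq_len(n)) else ""),
        class = cls, side = "R", index = seq_len(n),
        body = unname(landmark_body[cls]),
        x = unname(pts[, "x"]), y = unname(pts[, "y"]), z = unname(pts[, "z"])
      )
      left <- right %>%
        mutate(landmark = sub("_R", "_L", .data$landmark, fixed = TRUE),
               side = "L", x = -.data$x)
      rows[[cls]] <- bind_rows(right, left)
    }
  }
  out <- bind_rows(rows)
  attr(out, "sacrocaudal_area") <- 180 * s^2
  attr(out, "sacrocaudal_thickness") <- 3 * s
  attr(out, "scale_factor") <- s
  class(out) <- c("pelvis_landmarks", class(out))
  out
}

#' Operator placement noise model
#'
#' Isotropic Gaussian placement noise emulating the manual, repeated
#' placement of spring attachment points across trials.
#'
#' @param sd Standard deviation of the per-axis displacement, mm (>= 0).
#' @param seed Integer seed; the same seed reproduces the same perturbation.
#' @param targets Landmark classes to perturb; defaults to all spring
#'   attachment classes.
#' @return A `sij_noise_model` list.
#' @export
operator_noise <- function(sd = 0.25, seed = 1L,
                           targets = spring_attachment_classes()) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0) {
    abort("`sd` must be a single non-negative number (mm).",
          class = "sijstrain_invalid_parameter")
  }
  structure(list(sd = sd, seed = as.integer(seed), targets = targets),
            class = "sij_noise_model")
}

#' Perturb landmarks with operator placement noise
#'
#' Displaces each targeted landmark by i.i.d. zero-mean Gaussian offsets
#' with standard deviation `noise$sd` on each axis; non-targeted landmarks
#' are unchanged. Reproducible under the noise model's seed; `sd = 0` is the
#' identity.
#'
#' @param lm A [make_canonical_pelvis()] landmark set.
#' @param noise An [operator_noise()] model.
#' @return A perturbed `pelvis_landmarks` tibble (same shape and attributes).
#' @export
perturb_landmarks <- function(lm, noise) {
  stopifnot(inherits(lm, "pelvis_landmarks"), inherits(noise, "sij_noise_model"))
  if (noise$sd == 0) return(lm)
  hit <- lm$class %in% noise$targets
  nhit <- sum(hit)
  offs <- withr_seed(noise$seed, matrix(rnorm(3 * nhit, sd = noise$sd), ncol = 3))
  out <- lm
  out$x[hit] <- out$x[hit] + offs[, 1]
  out$y[hit] <- out$y[hit] + offs[, 2]
  out$z[hit] <- out$z[hit] + offs[, 3]
  out
}

# run expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read landmark sets as JSON
#'
#' Landmarks are serialized as a named list of `[x, y, z]` arrays in mm,
#' with the sacrocaudal area/thickness attributes carried alongside.
#'
#' @param lm A `pelvis_landmarks` tibble.
#' @param path File path.
#' @return `write_landmarks_json` returns `path` invisibly;
#'   `read_landmarks_json` returns a `pelvis_landmarks` tibble.
#' @export
write_landmarks_json <- function(lm, path) {
  stopifnot(inherits(lm, "pelvis_landmarks"))
  payload <- list(
    points = setNames(
      lapply(seq_len(nrow(lm)), function(i) c(lm$x[i], lm$y[i], lm$z[i])),
      lm$landmark
    ),
    meta = lm %>% select(!dplyr::any_of(c("x", "y", "z"))) %>% as.list(),
    sacrocaudal_area = attr(lm, "sacrocaudal_area"),
    sacrocaudal_thickness = attr(lm, "sacrocaudal_thickness"),
    scale_factor = attr(lm, "scale_factor")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- as_tibble(payload$meta)
  pts <- do.call(rbind, payload$points[meta$landmark])
  out <- meta %>% mutate(x = as.numeric(pts[, 1]), y = as.numeric(pts[, 2]),
                         z = as.numeric(pts[, 3]))
  attr(out, "sacrocaudal_area") <- payload$sacrocaudal_area
  attr(out, "sacrocaudal_thickness") <- payload$sacrocaudal_thickness
  attr(out, "scale_factor") <- payload$scale_factor
  class(out) <- c("pelvis_landmarks", class(out))
  out
}
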