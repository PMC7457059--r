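# Model assembly: crisscross sheet-ligament networks, "Y" sacrotuberous
# springs, parallel SIJ springs, the compression-only sacrocaudal joint
# element, fixed hemipelves and two free rigid bodies (sacrum, C1).

#' Crisscross spring topology for a sheet ligament
#'
#' Connects 4 points on the sacrum to 4 points on the ilium with 10 springs:
#' the 4 parallels `S_i - I_i` plus the 6 short diagonals `S_i - I_(i+1)` and
#' `S_(i+1) - I_i` (i = 1..3). This reproduces the sheet-like crisscross
#' pattern with the stated count of ten springs per side.
#'
#' @param sacrum_pts,ilium_pts Character vectors of 4 landmark names each
#'   (ordered along the cranio-caudal axis).
#' @return A tibble of 10 rows with columns `a`, `b`.
#' @export
crisscross_springs <- function(sacrum_pts, ilium_pts) {
  if (length(sacrum_pts) != 4L || length(ilium_pts) != 4L ||
      anyDuplicated(c(sacrum_pts, ilium_pts))) {
    abort("crisscross topology needs 4 + 4 distinct points.",
          class = "sijstrain_topology_error")
  }
  tibble(
    a = c(sacrum_pts,            sacrum_pts[1:3], sacrum_pts[2:4]),
    b = c(ilium_pts,             ilium_pts[2:4],  ilium_pts[1:3])
  )
}

#' Sacrotuberous "Y" spring topology
#'
#' Two springs sharing the ischiatic tuberosity insertion: one from the S3
#' transverse process (on the sacrum) and one from the first caudal
#' vertebra's transverse process (on C1).
#'
#' @param origin_s3,origin_c1,insertion_tuber Landmark names.
#' @return A tibble of 2 rows with columns `a`, `b`.
#' @export
sacrotuberous_springs <- function(origin_s3, origin_c1, insertion_tuber) {
  pts <- c(origin_s3, origin_c1, insertion_tuber)
  if (length(pts) != 3L || anyDuplicated(pts)) {
    abort("sacrotuberous topology needs three distinct points.",
          class = "sijstrain_topology_error")
  }
  tibble(a = c(origin_s3, origin_c1), b = rep(insertion_tuber, 2))
}

#' Assemble the pelvis mechanical model
#'
#' Builds the full spring network (per side: 10 dorsal, 10 ventral, 10 SIJ,
#' 2 sacrotuberous springs; 64 total), the compression-only sacrocaudal
#' joint element between sacrum and C1, the fixed hemipelvis environment and
#' the two free rigid bodies. Rest lengths are taken from the reference
#' geometry, so every spring is at exactly zero strain in the reference
#' configuration.
#'
#' @param lm A `pelvis_landmarks` set.
#' @param materials Material set from [default_materials()] (list with
#'   `ligament` and `joint` laws).
#' @param config Optional overrides: `sij_penalty` (logical, default TRUE),
#'   `sij_penalty_stiffness` (N/mm, default 1e3), `reg_translation` (N/mm,
#'   default 1e-6), `reg_rotation` (N mm/rad, default 1e-4).
#' @return A `sij_model` list with point matrix, spring table, joint
#'   element, body definitions and options.
#' @export
build_model <- function(lm, materials = default_materials(), config = list()) {
  stopifnot(inherits(lm, "pelvis_landmarks"))
  cfg <- modifyList(list(
    sij_penalty = TRUE,
    sij_penalty_stiffness = 1e3,
    reg_translation = 1e-6,
    reg_rotation = 1e-4
  ), config)

  need <- c("acetabulum_center", "dorsal_sacrum", "dorsal_ilium",
            "ventral_sacrum", "ventral_ilium", "sij_sacrum", "sij_ilium",
            "st_origin_s3", "st_origin_c1", "st_insertion_tuber",
            "load_point", "sacrocaudal_center")
  missing <- setdiff(need, unique(lm$class))
  if (length(missing)) {
    abort(paste0("landmark classes missing from the set: ",
                 paste(missing, collapse = ", ")),
          class = "sijstrain_assembly_error")
  }

  # split the sacrocaudal center into the two joint interface points
  thick <- attr(lm, "sacrocaudal_thickness")
  area <- attr(lm, "sacrocaudal_area")
  sc <- lm %>% filter(.data$class == "sacrocaudal_center")
  faces <- tibble(
    landmark = c("sacrocaudal_face_sacrum", "sacrocaudal_face_c1"),
    class = "sacrocaudal_face", side = NA_character_, index = 1:2,
    body = c("sacrum", "c1"),
    x = sc$x, y = sc$y, z = sc$z + c(thick / 2, -thick / 2)
  )
  pts <- lm %>%
    filter(.data$class != "sacrocaudal_center") %>%
    bind_rows(faces)

  name_of <- function(cls, side, idx = NULL) {
    sel <- pts$class == cls & (is.na(side) | pts$side %in% side)
    nm <- pts$landmark[sel][order(pts$index[sel])]
    if (!is.null(idx)) nm[idx] else nm
  }

  springs <- list()
  for (sd in c("R", "L")) {
    springs[[paste0("dorsal_", sd)]] <- crisscross_springs(
      name_of("dorsal_sacrum", sd), name_of("dorsal_ilium", sd)) %>%
      mutate(group = "dorsal_si", side = sd)
    springs[[paste0("ventral_", sd)]] <- crisscross_springs(
      name_of("ventral_sacrum", sd), name_of("ventral_ilium", sd)) %>%
      mutate(group = "ventral_si", side = sd)
    springs[[paste0("sij_", sd)]] <- tibble(
      a = name_of("sij_sacrum", sd), b = name_of("sij_ilium", sd),
      group = "sij", side = sd)
    springs[[paste0("st_", sd)]] <- sacrotuberous_springs(
      name_of("st_origin_s3", sd), name_of("st_origin_c1", sd),
      name_of("st_insertion_tuber", sd)) %>%
      mutate(group = "sacrotuberous", side = sd)
  }
  springs <- bind_rows(springs) %>%
    mutate(id = row_number(), .before = 1)

  P <- as.matrix(pts[, c("x", "y", "z")])
  rownames(P) <- pts$landmark
  ia <- match(springs$a, pts$landmark)
  ib <- match(springs$b, pts$landmark)
  d <- P[ib, , drop = FALSE] - P[ia, , drop = FALSE]
  L0 <- unname(sqrt(rowSums(d^2)))
  if (any(L0 <= 1e-9)) {
    bad <- paste(springs$a[L0 <= 1e-9], springs$b[L0 <= 1e-9], sep = "--")
    abort(paste0("zero rest length spring(s): ", paste(bad, collapse = ", ")),
          class = "sijstrain_zero_rest_length")
  }
  springs$rest_length <- L0

  body_names <- c("sacrum", "c1")
  origins <- lapply(body_names, function(b) colMeans(P[pts$body == b, , drop = FALSE]))
  names(origins) <- body_names

  jf_a <- match("sacrocaudal_face_sacrum", pts$landmark)
  jf_b <- match("sacrocaudal_face_c1", pts$landmark)

  structure(
    list(
      points = pts,
      P = P,
      body = pts$body,
      bodies = body_names,
      origins = origins,
      springs = springs,
      ia = ia, ib = ib, L0 = L0,
      joint = list(face_a = jf_a, face_b = jf_b,
                   area = area, rest_thickness = thick,
                   law = materials$joint),
      materials = materials,
      load_point = match(pts$landmark[pts$class == "load_point"], pts$landmark),
      config = cfg
    ),
    class = "sij_model"
  )
}

#' @export
print.sij_model <- function(x, ...) {
  census <- x$springs %>% count(.data$group, .data$side)
  cat(sprintf("sij_model: %d springs, %d points, 2 free bodies (sacrum, c1)\n",
              nrow(x$springs), nrow(x$points)))
  print(as.data.frame(census), row.names = FALSE)
  cat(sprintf("sacrocaudal joint: area %.1f mm^2, rest thickness %.2f mm\n",
              x$joint$area, x$joint$rest_thickness))
  invisible(x)
}

#' Spring census of a model
#'
#' @param model A `sij_model`.
#' @return Tibble of counts by ligament group and side.
#' @export
spring_census <- function(model) {
  stopifnot(inherits(model, "sij_model"))
  model$springs %>% count(.data$group, .data$side, name = "n_springs")
}

#' Serialize / load a model as JSON
#'
#' Round-trip stable serialization of points, spring topology, joint element
#' and options. Material laws are stored by their defining parameters.
#'
#' @param model A `sij_model`.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "sij_model"))
  payload <- list(
    points = model$points,
    springs = model$springs,
    joint = list(area = model$joint$area,
                 rest_thickness = model$joint$rest_thickness,
                 law = unclass(model$joint$law)),
    ligament_law = unclass(model$materials$ligament),
    bone = as.list(model$materials$bone),
    config = model$config
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
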