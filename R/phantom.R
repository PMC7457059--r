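# Synthetic CT phantom: simple box solids per bone (sacrum, left/right
# hemipelvis, first caudal vertebra) voxelized on a regular grid, with
# unique-intensity fiducial markers at every landmark, plus the
# threshold-segmentation round trip, landmark recovery, and NIfTI / STL
# export. Box faces are snapped outward to voxel boundaries so each
# solid's analytic volume is exactly representable on the grid.

bone_of_landmark <- function(lm) {
  dplyr::case_when(
    lm$body == "sacrum" ~ "sacrum",
    lm$body == "c1" ~ "c1",
    lm$side == "L" ~ "hemipelvis_L",
    TRUE ~ "hemipelvis_R"
  )
}

# padded, minimum-size bounding box per bone from its landmarks
bone_boxes <- function(lm, pad = 1.3, min_dim = 10) {
  lm2 <- lm %>% mutate(bone = bone_of_landmark(lm))
  boxes <- lm2 %>%
    group_by(.data$bone) %>%
    summarise(xmin = min(.data$x) - pad, xmax = max(.data$x) + pad,
              ymin = min(.data$y) - pad, ymax = max(.data$y) + pad,
              zmin = min(.data$z) - pad, zmax = max(.data$z) + pad,
              .groups = "drop")
  for (d in c("x", "y", "z")) {
    lo <- paste0(d, "min"); hi <- paste0(d, "max")
    w <- boxes[[hi]] - boxes[[lo]]
    grow <- pmax(0, (min_dim - w) / 2)
    boxes[[lo]] <- boxes[[lo]] - grow
    boxes[[hi]] <- boxes[[hi]] + grow
  }
  boxes
}

#' Render a CT-like phantom volume from a landmark set
#'
#' Builds a labeled, attenuation-like voxel volume: one simple box solid
#' per bone (sacrum, left and right hemipelvis, first caudal vertebra)
#' sized from that bone's landmarks, all above a nominal bone threshold,
#' plus a unique-intensity fiducial voxel at every landmark. Box faces are
#' snapped to voxel boundaries so the analytic box volume matches the
#' voxelized volume.
#'
#' @param lm A `pelvis_landmarks` set.
#' @param spacing Voxel spacing in mm, length 3 (x, y, z).
#' @param n_slices Number of transverse (z) slices (default 226).
#' @param bone_intensity Base intensity of bone voxels (distinct per bone:
#'   `bone_intensity + 10 * bone index`).
#' @param margin In-plane margin, voxels.
#' @return A `synthetic_ct`: `voxels` (3-D array), `spacing`, `origin`
#'   (world coordinate of the first voxel's corner), `n_slices`,
#'   `fiducials` tibble, `solids` tibble (snapped boxes with analytic
#'   volumes), `threshold` (suggested segmentation threshold).
#' @export
render_ct <- function(lm, spacing = c(0.8, 0.8, 0.625), n_slices = 226,
                      bone_intensity = 1000, margin = 2L) {
  stopifnot(inherits(lm, "pelvis_landmarks"))
  if (any(spacing <= 0)) {
    abort("`spacing` must be positive.", class = "sijstrain_invalid_parameter")
  }
  boxes <- bone_boxes(lm)

  zmin <- min(boxes$zmin); zmax <- max(boxes$zmax)
  z_extent <- n_slices * spacing[3]
  if (zmax - zmin > z_extent - 2 * spacing[3]) {
    abort("landmarks do not fit inside the field of view at this spacing / slice count.",
          class = "sijstrain_bounds_error")
  }
  origin <- c(min(boxes$xmin) - margin * spacing[1],
              min(boxes$ymin) - margin * spacing[2],
              (zmin + zmax) / 2 - z_extent / 2)
  nx <- ceiling((max(boxes$xmax) - origin[1]) / spacing[1]) + margin
  ny <- ceiling((max(boxes$ymax) - origin[2]) / spacing[2]) + margin
  nz <- as.integer(n_slices)

  # snap box faces inward to voxel boundaries so neighbouring bones keep a
  # background voxel between them and analytic volumes are grid-exact
  for (d in 1:3) {
    lo <- c("xmin", "ymin", "zmin")[d]; hi <- c("xmax", "ymax", "zmax")[d]
    boxes[[lo]] <- origin[d] + ceiling((boxes[[lo]] - origin[d]) / spacing[d]) * spacing[d]
    boxes[[hi]] <- origin[d] + floor((boxes[[hi]] - origin[d]) / spacing[d]) * spacing[d]
  }
  boxes$volume_mm3 <- (boxes$xmax - boxes$xmin) * (boxes$ymax - boxes$ymin) *
    (boxes$zmax - boxes$zmin)

  vox <- array(0, dim = c(nx, ny, nz))
  for (i in seq_len(nrow(boxes))) {
    ix <- which(origin[1] + (seq_len(nx) - 0.5) * spacing[1] > boxes$xmin[i] &
                  origin[1] + (seq_len(nx) - 0.5) * spacing[1] < boxes$xmax[i])
    iy <- which(origin[2] + (seq_len(ny) - 0.5) * spacing[2] > boxes$ymin[i] &
                  origin[2] + (seq_len(ny) - 0.5) * spacing[2] < boxes$ymax[i])
    iz <- which(origin[3] + (seq_len(nz) - 0.5) * spacing[3] > boxes$zmin[i] &
                  origin[3] + (seq_len(nz) - 0.5) * spacing[3] < boxes$zmax[i])
    vox[ix, iy, iz] <- bone_intensity + 10 * i
  }

  fid <- lm %>%
    mutate(bone = bone_of_landmark(lm),
           i = pmin(pmax(floor((.data$x - origin[1]) / spacing[1]) + 1L, 1L), nx),
           j = pmin(pmax(floor((.data$y - origin[2]) / spacing[2]) + 1L, 1L), ny),
           k = pmin(pmax(floor((.data$z - origin[3]) / spacing[3]) + 1L, 1L), nz),
           intensity = 2000 + row_number()) %>%
    select("landmark", "bone", "i", "j", "k", "intensity", "x", "y", "z")
  vox[cbind(fid$i, fid$j, fid$k)] <- fid$intensity

  structure(
    list(voxels = vox, spacing = spacing, origin = origin, n_slices = nz,
         fiducials = fid, solids = boxes, threshold = bone_intensity / 2),
    class = "synthetic_ct"
  )
}

#' @export
print.synthetic_ct <- function(x, ...) {
  cat(sprintf("synthetic_ct: %d x %d x %d voxels, spacing %s mm, %d fiducials\n",
              dim(x$voxels)[1], dim(x$voxels)[2], dim(x$voxels)[3],
              paste(x$spacing, collapse = " x "), nrow(x$fiducials)))
  invisible(x)
}

#' Threshold segmentation of the phantom
#'
#' Labels the supra-threshold voxels by 6-connected components and maps
#' each component to a bone name through the known solid centers. A
#' threshold low enough to merge bones raises an ambiguity error naming
#' the merged bones; a threshold above the maximum intensity raises an
#' empty-segmentation error.
#'
#' @param ct A [render_ct()] volume.
#' @param threshold Intensity threshold (default the volume's suggestion).
#' @return A `sij_segmentation`: `labels` (integer array, 0 background),
#'   `bones` tibble (`bone`, `label`, `n_voxels`, `volume_mm3`,
#'   `analytic_volume_mm3`).
#' @export
threshold_segment <- function(ct, threshold = ct$threshold) {
  stopifnot(inherits(ct, "synthetic_ct"))
  dims <- dim(ct$voxels)
  mask_idx <- which(ct$voxels > threshold)
  if (!length(mask_idx)) {
    abort("empty segmentation: threshold exceeds every intensity in the volume.",
          class = "sijstrain_empty_segmentation")
  }
  # rank of each mask voxel in the flat array
  rank <- integer(prod(dims)); rank[mask_idx] <- seq_along(mask_idx)
  ijk <- arrayInd(mask_idx, dims)
  edges <- list()
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (d in 1:3) {
    ok <- ijk[, d] < dims[d]
    nb <- mask_idx[ok] + strides[d]
    hit <- rank[nb] > 0L
    edges[[d]] <- cbind(rank[mask_idx[ok][hit]], rank[nb[hit]])
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(mask_idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership

  labels <- integer(prod(dims))
  labels[mask_idx] <- comp
  labels <- array(labels, dims)

  ctr <- ct$solids %>%
    mutate(i = floor(((.data$xmin + .data$xmax) / 2 - ct$origin[1]) / ct$spacing[1]) + 1L,
           j = floor(((.data$ymin + .data$ymax) / 2 - ct$origin[2]) / ct$spacing[2]) + 1L,
           k = floor(((.data$zmin + .data$zmax) / 2 - ct$origin[3]) / ct$spacing[3]) + 1L)
  bone_label <- labels[cbind(ctr$i, ctr$j, ctr$k)]
  if (any(bone_label == 0L)) {
    abort(paste0("no supra-threshold component found for bone(s): ",
                 paste(ctr$bone[bone_label == 0L], collapse = ", ")),
          class = "sijstrain_empty_segmentation")
  }
  if (anyDuplicated(bone_label)) {
    merged <- split(ctr$bone, bone_label)
    merged <- merged[vapply(merged, length, 1L) > 1L]
    abort(paste0("threshold merges bones: ",
                 paste(vapply(merged, paste, "", collapse = " + "),
                       collapse = "; ")),
          class = "sijstrain_ambiguous_segmentation")
  }
  voxvol <- prod(ct$spacing)
  nvox <- tabulate(comp)[bone_label]
  structure(
    list(labels = labels,
         bones = tibble(bone = ctr$bone, label = bone_label,
                        n_voxels = nvox, volume_mm3 = nvox * voxvol,
                        analytic_volume_mm3 = ct$solids$volume_mm3),
         spacing = ct$spacing, origin = ct$origin),
    class = "sij_segmentation"
  )
}

#' @export
print.sij_segmentation <- function(x, ...) {
  cat("threshold segmentation:\n")
  print(as.data.frame(x$bones), row.names = FALSE)
  invisible(x)
}

#' Recover landmark coordinates from phantom fiducials
#'
#' Locates each fiducial's unique intensity in the voxel volume and
#' returns the voxel-center world coordinates next to the ground-truth
#' landmark coordinates; the recovery error is bounded by one voxel.
#'
#' @param ct A [render_ct()] volume.
#' @return Tibble: `landmark`, recovered `x`, `y`, `z`, truth `x_true` ...
#'   and the per-landmark Euclidean `error_mm`.
#' @export
recover_landmarks <- function(ct) {
  stopifnot(inherits(ct, "synthetic_ct"))
  dims <- dim(ct$voxels)
  out <- ct$fiducials %>%
    mutate(found = map(.data$intensity, function(v) {
      idx <- which(ct$voxels == v)
      arrayInd(idx[1], dims)
    }))
  ijk <- do.call(rbind, out$found)
  rec <- sweep(sweep(ijk - 0.5, 2, ct$spacing, "*"), 2, ct$origin, "+")
  out %>%
    mutate(x_rec = rec[, 1], y_rec = rec[, 2], z_rec = rec[, 3],
           error_mm = sqrt((.data$x_rec - .data$x)^2 +
                             (.data$y_rec - .data$y)^2 +
                             (.data$z_rec - .data$z)^2)) %>%
    select("landmark", "bone", "x_rec", "y_rec", "z_rec",
           x_true = "x", y_true = "y", z_true = "z", "error_mm")
}

#' Write a phantom volume or segmentation as NIfTI
#'
#' @param x A `synthetic_ct` or `sij_segmentation`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  arr <- if (inherits(x, "synthetic_ct")) x$voxels
  else if (inherits(x, "sij_segmentation")) x$labels
  else abort("`x` must be a synthetic_ct or sij_segmentation.",
             class = "sijstrain_invalid_parameter")
  img <- RNifti::asNifti(arr, reference = list(pixdim = c(-1, x$spacing, rep(0, 4))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export one bone's surface as STL
#'
#' Extracts the iso-surface of the bone's voxel mask (boundary voxel faces,
#' two triangles per face, outward normals) and writes binary STL with
#' coordinates in mm.
#'
#' @param seg A [threshold_segment()] result.
#' @param bone Bone name from `seg$bones$bone`.
#' @param path Output `.stl` path.
#' @return Number of triangles written, invisibly.
#' @export
export_stl <- function(seg, bone, path) {
  stopifnot(inherits(seg, "sij_segmentation"))
  row <- match(bone, seg$bones$bone)
  if (is.na(row)) {
    abort(sprintf("unknown bone '%s'.", bone), class = "sijstrain_invalid_parameter")
  }
  dims <- dim(seg$labels)
  mask <- seg$labels == seg$bones$label[row]
  tris <- list()
  sp <- seg$spacing; o <- seg$origin
  # unit-square corner offsets for a face normal to axis d
  face_corners <- function(d) {
    others <- setdiff(1:3, d)
    corn <- matrix(0, 4, 3)
    corn[, others[1]] <- c(0, 1, 1, 0)
    corn[, others[2]] <- c(0, 0, 1, 1)
    corn
  }
  for (d in 1:3) {
    for (sgn in c(-1L, 1L)) {
      # neighbor occupancy along axis d, direction sgn
      perm <- seq_len(dims[d]) + sgn
      ok <- perm >= 1L & perm <= dims[d]
      nb <- array(FALSE, dims)
      sl <- function(a, idx) {
        switch(d,
               a[idx, , , drop = FALSE],
               a[, idx, , drop = FALSE],
               a[, , idx, drop = FALSE])
      }
      asg <- function(a, idx, val) {
        switch(d,
               {a[idx, , ] <- val; a},
               {a[, idx, ] <- val; a},
               {a[, , idx] <- val; a})
      }
      nb <- asg(nb, which(ok), sl(mask, perm[ok]))
      faces <- which(mask & !nb)
      if (!length(faces)) next
      ijk <- arrayInd(faces, dims)
      base <- sweep(ijk - 1L, 2, sp, "*")
      base <- sweep(base, 2, o, "+")
      if (sgn == 1L) base[, d] <- base[, d] + sp[d]
      corn <- face_corners(d)
      # wind so the normal points along sgn * e_d
      ordr <- if (sgn == 1L) c(1, 2, 3, 1, 3, 4) else c(1, 3, 2, 1, 4, 3)
      v <- lapply(ordr, function(ci) {
        sweep(base, 2, corn[ci, ] * sp, "+")
      })
      nrml <- rep(0, 3); nrml[d] <- sgn
      tris[[length(tris) + 1L]] <- list(
        v1 = rbind(v[[1]], v[[4]]), v2 = rbind(v[[2]], v[[5]]),
        v3 = rbind(v[[3]], v[[6]]),
        n = matrix(nrml, 2 * nrow(base), 3, byrow = TRUE))
    }
  }
  v1 <- do.call(rbind, lapply(tris, `[[`, "v1"))
  v2 <- do.call(rbind, lapply(tris, `[[`, "v2"))
  v3 <- do.call(rbind, lapply(tris, `[[`, "v3"))
  nm <- do.call(rbind, lapply(tris, `[[`, "n"))
  ntri <- nrow(v1)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("%-80s", "sijstrain voxel surface")), con)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  payload <- as.numeric(t(cbind(nm, v1, v2, v3)))  # 12 floats per triangle
  fl <- writeBin(payload, raw(), size = 4, endian = "little")
  rec <- matrix(as.raw(0), 50L, ntri)              # 48 float bytes + 2 pad
  rec[1:48, ] <- matrix(fl, 48L, ntri)
  writeBin(as.vector(rec), con)
  invisible(ntri)
}
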