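# --- minimal OBJ triangle-mesh output -------------------------------------
# Wavefront OBJ is plain text and has no installed R reader/writer, so a
# small writer (and a summary reader used for round-trip checks) lives here.
# All mesh coordinates are in cm, z-up; scene positions (m) are converted.

cylinder_mesh <- function(radius, z0, z1, cx = 0, cy = 0, sides = 8L) {
  a <- seq(0, 2 * pi, length.out = sides + 1)[-(sides + 1)]
  ring <- cbind(cx + radius * cos(a), cy + radius * sin(a))
  verts <- rbind(cbind(ring, z0), cbind(ring, z1))
  i <- seq_len(sides); j <- c(seq_len(sides - 1) + 1, 1)
  faces <- rbind(cbind(i, j, j + sides), cbind(i, j + sides, i + sides))
  list(v = verts, f = faces)
}

blade_mesh <- function(midrib, max_width) {
  n <- nrow(midrib)
  t <- seq(0, 1, length.out = n)
  half <- max_width / 2 * blade_width_profile(t)
  # lateral direction: horizontal, perpendicular to the local midrib heading
  head_xy <- diff(midrib[, 1:2, drop = FALSE])
  head_xy <- rbind(head_xy, head_xy[n - 1, , drop = FALSE])
  norm <- sqrt(rowSums(head_xy^2))
  lat <- cbind(-head_xy[, 2], head_xy[, 1]) / ifelse(norm > 1e-12, norm, 1)
  lat[norm <= 1e-12, ] <- rep(c(1, 0), each = sum(norm <= 1e-12))
  left <- midrib + cbind(lat * half, 0)
  right <- midrib - cbind(lat * half, 0)
  verts <- rbind(left, right)
  i <- seq_len(n - 1)
  faces <- rbind(cbind(i, i + 1, i + n), cbind(i + 1, i + n + 1, i + n))
  list(v = verts, f = faces)
}

plant_meshes <- function(plant, origin_cm = c(0, 0)) {
  org <- plant$organs
  out <- list()
  for (i in seq_len(nrow(org))) {
    r <- org$rank[i]
    cyl <- cylinder_mesh(org$internode_diameter_cm[i] / 2,
                         org$base_height_cm[i], org$base_height_cm[i] + org$internode_length_cm[i],
                         origin_cm[1], origin_cm[2])
    out[[paste0("internode_r", r)]] <- cyl
    sh_top <- org$lih_cm[i]
    sh <- cylinder_mesh(org$sheath_width_cm[i] / 2 + org$internode_diameter_cm[i] / 2,
                        max(0, sh_top - org$sheath_length_cm[i]), sh_top,
                        origin_cm[1], origin_cm[2])
    out[[paste0("sheath_r", r)]] <- sh
    m <- plant$midribs[[as.character(r)]]
    m2 <- m; m2[, 1] <- m2[, 1] + origin_cm[1]; m2[, 2] <- m2[, 2] + origin_cm[2]
    out[[paste0("leaf_r", r)]] <- blade_mesh(m2, org$lamina_width_cm[i])
  }
  out
}

#' Export a canopy scene as a Wavefront OBJ triangle mesh
#'
#' One named group per organ per plant (`plant<k>_internode_r<rank>`,
#' `plant<k>_sheath_r<rank>`, `plant<k>_leaf_r<rank>`), plus a vertical
#' 100 cm reference bar group for scale. Coordinates are centimeters,
#' z-up, soil at z = 0.
#'
#' @param scene A non-empty `canopy_scene` from [build_canopy()].
#' @param path Output `.obj` path.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(scene, path) {
  stopifnot(inherits(scene, "canopy_scene"))
  if (!length(scene$plants)) abort_domain("cannot export an empty scene")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# maizecanopy OBJ export (units: cm, z-up)", con)
  offset <- 0L
  emit <- function(name, mesh) {
    writeLines(paste0("g ", name), con)
    writeLines(sprintf("v %.4f %.4f %.4f", mesh$v[, 1], mesh$v[, 2], mesh$v[, 3]), con)
    f <- mesh$f + offset
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
    offset <<- offset + nrow(mesh$v)
  }
  for (k in seq_along(scene$plants)) {
    origin <- 100 * c(scene$positions$x_m[k], scene$positions$y_m[k])
    meshes <- plant_meshes(scene$plants[[k]], origin)
    for (name in names(meshes)) emit(paste0("plant", k, "_", name), meshes[[name]])
  }
  bar <- cylinder_mesh(1, 0, 100, cx = -50, cy = -50, sides = 6L)
  emit("reference_bar_100cm", bar)
  invisible(path)
}

#' Summarize an OBJ file
#'
#' Minimal reader used to verify exports: vertex and face counts, group
#' names, and the axis-aligned bounding box.
#'
#' @param path An `.obj` file.
#' @return List with `n_vertices`, `n_faces`, `groups`, `bbox` (2 x 3
#'   matrix, rows min/max).
#' @export
read_obj_summary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  verts <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(p) as.numeric(p[2:4])))
  groups <- sub("^g ", "", lines[startsWith(lines, "g ")])
  bbox <- rbind(min = apply(verts, 2, min), max = apply(verts, 2, max))
  colnames(bbox) <- c("x", "y", "z")
  list(n_vertices = nrow(verts),
       n_faces = sum(startsWith(lines, "f ")),
       groups = groups, bbox = bbox)
}
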