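#' Intra-row plant spacing implied by density and row spacing
#'
#' For plants on a regular grid, spacing x row_spacing x density = 1
#' exactly, so spacing = 1 / (row_spacing * density). Field reports round
#' to 2 decimals (see [plant_spacing_reported()]).
#'
#' @param density Plant density, plants m^-2.
#' @param row_spacing Row spacing in m (field default 0.6).
#' @return Intra-row spacing in m.
#' @examples
#' plant_spacing(6)    # 0.2778, reported 0.28
#' plant_spacing(15)   # 0.1111, reported 0.11
#' @export
plant_spacing <- function(density, row_spacing = 0.6) {
  if (any(density <= 0) || any(row_spacing <= 0)) {
    abort_domain("density and row_spacing must be positive")
  }
  1 / (row_spacing * density)
}

#' @rdname plant_spacing
#' @export
plant_spacing_reported <- function(density, row_spacing = 0.6) {
  round(plant_spacing(density, row_spacing), 2)
}

#' Leaf insertion heights
#'
#' The insertion height (LIH, cm) of the leaf at each modeled rank is the
#' cumulative sum of internode lengths from rank 6 upward, plus a
#' configurable basal offset standing in for the senesced ranks 1-5
#' (default 0 cm).
#'
#' @param profile A [base_profile].
#' @param basal_offset Height contributed by ranks 1-5, cm.
#' @return Numeric vector of LIH in cm, named by rank; nondecreasing.
#' @export
leaf_insertion_heights <- function(profile, basal_offset = 0) {
  il <- profile_sizes(profile, "IL")
  if (anyNA(il)) abort_missing_entry("profile lacks internode-length entries")
  basal_offset + cumsum(il)
}

#' Leaf blade area from length and width
#'
#' Maize blades are lanceolate, so area is a fixed fraction of the bounding
#' rectangle: LA = shape_factor * LL * LW. The default 0.75 is the standard
#' maize blade-area convention.
#'
#' @param ll Lamina length, cm.
#' @param lw Lamina maximum width, cm.
#' @param shape_factor Dimensionless, in (0, 1].
#' @return Blade area, cm^2.
#' @export
leaf_area <- function(ll, lw, shape_factor = 0.75) {
  if (any(shape_factor <= 0) || any(shape_factor > 1)) {
    abort_domain("shape_factor must lie in (0, 1]")
  }
  if (any(ll < 0) || any(lw < 0)) abort_domain("lamina dimensions must be >= 0")
  shape_factor * ll * lw
}

#' Default leaf insertion angles
#'
#' Insertion angle from the vertical stem, in degrees. Measured anchors
#' exist at the three ear-adjacent ranks (18 deg one below the ear, 22 deg
#' at the ear, 10 deg one above, at the reference density); angles at other
#' ranks are linearly interpolated in rank between anchors, held at the
#' nearest anchor outside the anchor span, and clamped to [5, 40] degrees.
#' Angles are held constant across densities (ear-adjacent angles are
#' approximately stable under increased density for this compact hybrid).
#'
#' @param ear_rank Ear-bearing rank (default 12).
#' @param anchors Named numeric vector of measured angles by rank.
#' @param ranks Ranks to resolve (default all modeled ranks).
#' @param overrides Optional named vector (by rank) replacing resolved
#'   values, e.g. for a density-specific reduction below the ear.
#' @return Named numeric vector of angles (degrees) by rank.
#' @export
default_leaf_angles <- function(ear_rank = 12L,
                                anchors = c(`11` = 18, `12` = 22, `13` = 10),
                                ranks = modeled_ranks(), overrides = NULL) {
  stopifnot(length(anchors) >= 1, !is.null(names(anchors)))
  ax <- as.numeric(names(anchors))
  ang <- if (length(anchors) == 1) rep(unname(anchors), length(ranks)) else
    stats::approx(ax, unname(anchors), xout = ranks, rule = 2)$y
  ang <- pmin(40, pmax(5, ang))
  out <- stats::setNames(ang, ranks)
  if (!is.null(overrides)) {
    idx <- intersect(names(overrides), names(out))
    out[idx] <- pmin(90, pmax(0, overrides[idx]))
  }
  out
}

# quadratic Bezier midrib, n sample points; cm coordinates relative to the
# insertion point; straight (exact length ll) when droop = 0
midrib_curve <- function(ll, angle_deg, azimuth_deg, droop = 0.3, n = 9L) {
  a <- angle_deg * pi / 180
  az <- azimuth_deg * pi / 180
  d <- c(sin(a) * cos(az), sin(a) * sin(az), cos(a))
  p0 <- c(0, 0, 0)
  p2 <- d * ll - c(0, 0, droop * ll)
  p1 <- d * (ll / 2)
  t <- seq(0, 1, length.out = n)
  pts <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  colnames(pts) <- c("x", "y", "z")
  pts
}

# relative blade half-width profile along the midrib; peaks mid-blade and
# tapers to tip and base
blade_width_profile <- function(t) sin(pi * t)^0.5

#' Build the 3D architecture of a single plant
#'
#' Stacks internode segments from the soil upward, attaches one sheath and
#' one leaf per modeled rank, and realizes leaf geometry: alternate
#' (distichous) azimuths flipping 180 degrees per rank plus seeded uniform
#' jitter, and a quadratic-Bezier midrib leaving the stem at the insertion
#' angle and drooping by a droop coefficient. Geometry is reproducible for
#' a fixed seed.
#'
#' @param profile A complete [base_profile].
#' @param angles Named numeric vector of insertion angles by rank (default
#'   [default_leaf_angles()]).
#' @param azimuth_seed Integer seed for azimuth jitter.
#' @param droop Midrib droop coefficient (fraction of blade length the tip
#'   falls below the straight-line tip); default 0.3.
#' @param jitter_deg Half-width of the uniform azimuth jitter, degrees.
#' @param basal_offset Stem height of senesced ranks 1-5, cm.
#' @param shape_factor Blade area shape factor, see [leaf_area()].
#' @return An object of class `plant_architecture`.
#' @export
build_plant <- function(profile, angles = default_leaf_angles(),
                        azimuth_seed = 1L, droop = 0.3, jitter_deg = 15,
                        basal_offset = 0, shape_factor = 0.75) {
  stopifnot(inherits(profile, "base_profile"))
  ranks <- modeled_ranks()
  if (!all(as.character(ranks) %in% names(angles))) {
    abort_missing_entry("angles must resolve every modeled rank")
  }
  lih <- leaf_insertion_heights(profile, basal_offset)
  il <- profile_sizes(profile, "IL"); id <- profile_sizes(profile, "ID")
  sl <- profile_sizes(profile, "SL"); sw <- profile_sizes(profile, "SW")
  ll <- profile_sizes(profile, "LL"); lw <- profile_sizes(profile, "LW")
  base_height <- lih - il  # internode base; leaf inserts at its top

  rng <- local({ set.seed(azimuth_seed); stats::runif(length(ranks), -1, 1) })
  azimuth <- (ranks %% 2) * 180 + rng * jitter_deg

  organs <- data.frame(
    rank = ranks,
    internode_length_cm = unname(il), internode_diameter_cm = unname(id),
    base_height_cm = unname(base_height),
    sheath_length_cm = unname(sl), sheath_width_cm = unname(sw),
    lih_cm = unname(lih),
    angle_deg = unname(angles[as.character(ranks)]),
    azimuth_deg = azimuth,
    lamina_length_cm = unname(ll), lamina_width_cm = unname(lw),
    leaf_area_cm2 = leaf_area(unname(ll), unname(lw), shape_factor)
  )
  midribs <- lapply(seq_along(ranks), function(i) {
    m <- midrib_curve(organs$lamina_length_cm[i], organs$angle_deg[i],
                      organs$azimuth_deg[i], droop)
    m[, "z"] <- m[, "z"] + organs$lih_cm[i]
    m
  })
  names(midribs) <- ranks
  structure(list(organs = organs, midribs = midribs,
                 height_cm = unname(lih[length(lih)]) ,
                 basal_offset_cm = basal_offset,
                 total_leaf_number = profile$total_leaf_number,
                 droop = droop, seed = azimuth_seed),
            class = "plant_architecture")
}

#' @export
print.plant_architecture <- function(x, ...) {
  cat(sprintf("Plant architecture: %d initiated leaves, %d modeled (ranks %d-%d), height %.1f cm\n",
              x$total_leaf_number, nrow(x$organs),
              min(x$organs$rank), max(x$organs$rank), x$height_cm))
  invisible(x)
}

#' Build a canopy scene for a plot
#'
#' Places plants on a row-major grid: rows 0.6 m apart (configurable) along
#' the plot width, plants [plant_spacing()] apart along the row. Each plant
#' receives its own azimuth seed drawn deterministically from the scene
#' seed.
#'
#' @param profile Organ-size profile used for every plant (apply the
#'   density response first for an elevated-density canopy).
#' @param density Plant density, plants m^-2 (drives intra-row spacing).
#' @param plot_length,plot_width Plot dimensions in m (rows run along the
#'   length). Defaults 9 x 5 m.
#' @param seed Scene seed.
#' @param row_spacing Row spacing, m.
#' @param ... Passed to [build_plant()].
#' @return An object of class `canopy_scene`.
#' @export
build_canopy <- function(profile, density, plot_length = 9, plot_width = 5,
                         seed = 1L, row_spacing = 0.6, ...) {
  if (plot_length <= 0 || plot_width <= 0) abort_domain("plot dimensions must be positive")
  spacing <- plant_spacing(density, row_spacing)
  n_rows <- max(0L, floor(plot_width / row_spacing + 1e-9))
  n_per_row <- max(0L, floor(plot_length / spacing + 1e-9))
  if (n_rows * n_per_row == 0) {
    warning("plot too small for a single plant; returning an empty scene", call. = FALSE)
  }
  grid <- expand.grid(col = seq_len(n_per_row), row = seq_len(n_rows))
  positions <- data.frame(
    row = grid$row, col = grid$col,
    x_m = (grid$col - 0.5) * spacing,
    y_m = (grid$row - 0.5) * row_spacing
  )
  plant_seeds <- if (nrow(positions)) {
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, nrow(positions), replace = TRUE)
  } else integer(0)
  plants <- lapply(plant_seeds, function(s) build_plant(profile, azimuth_seed = s, ...))
  structure(list(plot_length = plot_length, plot_width = plot_width,
                 row_spacing = row_spacing, plant_spacing = spacing,
                 density = density, positions = positions, plants = plants,
                 seed = seed),
            class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("Canopy scene: %.1f x %.1f m plot, %.3g plants/m2, %d plants (rows %.2f m, spacing %.4f m)\n",
              x$plot_length, x$plot_width, x$density, nrow(x$positions),
              x$row_spacing, x$plant_spacing))
  invisible(x)
}
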