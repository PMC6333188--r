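#' Beam-line geometry
#'
#' Axial layout of the modeled treatment head.  All axial coordinates are in
#' cm from the reference plane `Z = 0` at the nominal source position; the
#' isocenter plane sits at `Z = 100` cm (SAD 100 cm).  The primary virtual
#' source is placed at the distal side of the target (`Z = 1.1` cm), the
#' secondary source at the distal plane of the flattening filter
#' (`Z = 15.9` cm).
#'
#' @param z_reference Axial origin (cm).  Always 0 in practice.
#' @param z_target_distal Primary-source plane (cm).
#' @param z_filter_distal Secondary-source / scoring plane (cm).
#' @param z_mlc_top Upstream face of the MLC leaf bank (cm).  The vendor
#'   does not publish this distance; 30 cm is a typical value for this
#'   collimator class and is configurable.
#' @param z_isocenter Isocenter plane (cm).
#' @param sad Source-axis distance (cm).
#' @return An object of class `beam_geometry`.
#' @examples
#' geom <- beam_geometry()
#' geom$z_isocenter
#' @export
beam_geometry <- function(z_reference = 0, z_target_distal = 1.1,
                          z_filter_distal = 15.9, z_mlc_top = 30,
                          z_isocenter = 100, sad = 100) {
  g <- list(z_reference = z_reference, z_target_distal = z_target_distal,
            z_filter_distal = z_filter_distal, z_mlc_top = z_mlc_top,
            z_isocenter = z_isocenter, sad = sad)
  class(g) <- "beam_geometry"
  validate_beam_geometry(g)
  g
}

validate_beam_geometry <- function(g) {
  if (!(g$z_target_distal < g$z_filter_distal &&
        g$z_filter_distal < g$z_mlc_top &&
        g$z_mlc_top < g$z_isocenter))
    stop("invalid beam geometry: require z_target_distal < z_filter_distal ",
         "< z_mlc_top < z_isocenter", call. = FALSE)
  invisible(g)
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat("Beam geometry (axial cm from reference plane):\n")
  cat(sprintf("  target distal (primary source)  %6.2f\n", x$z_target_distal))
  cat(sprintf("  filter distal (secondary source)%6.2f\n", x$z_filter_distal))
  cat(sprintf("  MLC upstream face               %6.2f\n", x$z_mlc_top))
  cat(sprintf("  isocenter                       %6.2f  (SAD %.0f)\n",
              x$z_isocenter, x$sad))
  invisible(x)
}

#' MLC leaf specification
#'
#' Geometry and material of one leaf bank.  The physical leaf pitch at the
#' MLC plane is derived from the projected width so that one leaf projects
#' to exactly `projected_width` at the isocenter plane (projection from the
#' reference plane `Z = 0` through the MLC axial mid-plane).
#'
#' @param projected_width Leaf width projected at isocenter (mm).
#' @param height Leaf thickness along the beam axis (mm).
#' @param lbrot Leaf bank rotation angle (mrad).  The bank is "defocused"
#'   by tilting every leaf by this angle; see [mlc_shift()] for the
#'   resulting field-center translation.
#' @param air_gap Interleaf air gap (mm) between adjacent leaf flanks.
#' @param tg_enabled Model the tongue-and-groove step on the leaf sides?
#' @param tg_width Groove width (mm).
#' @param tg_depth Step depth along the beam axis (mm); defaults to half
#'   the leaf height.
#' @param density Leaf material density (g/cm^3).
#' @param composition Named numeric vector of element mass fractions;
#'   must sum to 1.
#' @param geom A [beam_geometry()] used to derive the physical pitch.
#' @return An object of class `leaf_spec` with derived fields
#'   `physical_pitch` (mm) and `z_mlc_mid` (cm).
#' @examples
#' spec <- leaf_spec()
#' spec$physical_pitch   # 5 mm * 34.5/100
#' @export
leaf_spec <- function(projected_width = 5, height = 90, lbrot = 9,
                      air_gap = 0.089, tg_enabled = FALSE, tg_width = 0.4,
                      tg_depth = height / 2, density = 18.5,
                      composition = c(W = 0.96, Ni = 0.03, Fe = 0.01),
                      geom = beam_geometry()) {
  if (projected_width <= 0) stop("projected_width must be > 0", call. = FALSE)
  if (height <= 0) stop("invalid geometry: leaf height must be > 0",
                        call. = FALSE)
  if (air_gap < 0) stop("air_gap must be >= 0", call. = FALSE)
  if (abs(sum(composition) - 1) > 1e-6)
    stop("composition mass fractions must sum to 1", call. = FALSE)
  z_mlc_mid <- geom$z_mlc_top + height / CM2MM / 2
  physical_pitch <- projected_width * z_mlc_mid / geom$z_isocenter
  if (tg_width < 0 || tg_width >= physical_pitch)
    stop("require 0 <= tg_width < physical_pitch", call. = FALSE)
  s <- list(projected_width = projected_width, physical_pitch = physical_pitch,
            height = height, lbrot = lbrot, air_gap = air_gap,
            tg_enabled = tg_enabled, tg_width = tg_width, tg_depth = tg_depth,
            density = density, composition = composition,
            z_mlc_mid = z_mlc_mid)
  class(s) <- "leaf_spec"
  s
}

#' @export
print.leaf_spec <- function(x, ...) {
  cat(sprintf(
    "MLC leaf spec: %.3g mm projected width (pitch %.4g mm at Z = %.3g cm),\n",
    x$projected_width, x$physical_pitch, x$z_mlc_mid))
  cat(sprintf("  height %.3g mm, bank rotation %.3g mrad, air gap %.3g mm\n",
              x$height, x$lbrot, x$air_gap))
  cat(sprintf("  tongue-and-groove: %s (width %.2g mm, depth %.3g mm)\n",
              if (x$tg_enabled) "on" else "off", x$tg_width, x$tg_depth))
  cat(sprintf("  material: %s, density %.3g g/cm^3\n",
              paste(sprintf("%s %.3g", names(x$composition), x$composition),
                    collapse = ", "), x$density))
  invisible(x)
}

#' Aperture state of the in-line leaf sequence
#'
#' A pattern of open/closed leaves along the in-line axis.  The pattern is
#' centered on the beam axis: with an odd number of leaves the middle leaf
#' cell straddles `y = 0`.
#'
#' @param leaf_open Logical vector, one entry per leaf, `TRUE` = open
#'   (leaf retracted), or a compact pattern string such as `"CCOCC"`
#'   (`O` = open, `C` = closed).
#' @return Object of class `aperture_state`.
#' @examples
#' aperture_state("CCCCCOCCCCC")   # single open leaf at the field center
#' @export
aperture_state <- function(leaf_open) {
  if (is.character(leaf_open)) {
    stopifnot(length(leaf_open) == 1)
    chars <- strsplit(toupper(leaf_open), "")[[1]]
    if (!all(chars %in% c("O", "C")))
      stop("aperture pattern string may only contain 'O' and 'C'",
           call. = FALSE)
    leaf_open <- chars == "O"
  }
  leaf_open <- as.logical(leaf_open)
  if (length(leaf_open) < 1 || anyNA(leaf_open))
    stop("leaf_open must be a non-empty logical vector", call. = FALSE)
  structure(list(leaf_open = leaf_open), class = "aperture_state")
}

#' @export
print.aperture_state <- function(x, ...) {
  cat("Aperture:", paste(ifelse(x$leaf_open, "O", "C"), collapse = ""),
      sprintf(" (%d leaves, %d open)\n", length(x$leaf_open),
              sum(x$leaf_open)))
  invisible(x)
}

#' Field-center translation caused by the leaf bank rotation
#'
#' Tilting every leaf of height `h` by the bank rotation angle translates
#' the center of the field opening by `h * sin(lbrot) / 2` at the MLC
#' plane.  The collimator model applies this shift to the whole bank so
#' that the opening stays centered by construction.
#'
#' @param height Leaf thickness along the beam axis (mm).
#' @param lbrot Leaf bank rotation angle (mrad).
#' @return Shift in mm.
#' @examples
#' mlc_shift(90, 9)    # ~0.41 mm
#' @export
mlc_shift <- function(height, lbrot) {
  if (height <= 0) stop("invalid geometry: height must be > 0", call. = FALSE)
  if (lbrot < 0) stop("lbrot must be >= 0", call. = FALSE)
  height * sin(lbrot / 1000) / 2
}

#' Divergent projection onto the isocenter plane
#'
#' Projects an in-line position at axial coordinate `z` onto the isocenter
#' plane along the straight line from the axial point at `origin_z`.
#'
#' @param position Length-2 numeric `c(y_mm, z_cm)` or a two-column matrix
#'   of such pairs.
#' @param origin_z Axial position of the projection origin (cm); must lie
#'   upstream of the projected point and of the isocenter.
#' @param geom A [beam_geometry()].
#' @return Projected in-line position(s) at the isocenter plane (mm).
#' @examples
#' project_to_isocenter(c(1, 50), 0)   # 2 mm by similar triangles
#' @export
project_to_isocenter <- function(position, origin_z = 0,
                                 geom = beam_geometry()) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 2)
  y <- position[, 1]; z <- position[, 2]
  if (origin_z >= geom$z_isocenter)
    stop("projection origin must be upstream of the isocenter", call. = FALSE)
  if (any(z <= origin_z))
    stop("position at or upstream of the projection origin", call. = FALSE)
  y * (geom$z_isocenter - origin_z) / (z - origin_z)
}

## ---------------------------------------------------------------------------
## Leaf polygons.
##
## Each closed leaf is represented by one or two convex quadrilaterals in the
## (y [mm], z [mm]) plane: a single parallelogram without tongue-and-groove,
## or an upper and a lower half with laterally stepped flanks when the
## tongue-and-groove step is enabled.  The bank rotation is applied as a
## small-angle shear about each leaf's own center at the MLC axial mid-plane
## (y(z) = y0 + (z - z_mid) tan(lbrot)), which preserves the leaf height and
## the interleaf air gaps; the whole bank is then translated by mlc_shift().
## A quad is stored as c(y_left, y_right, z_top, z_bot, slant) meaning the
## material occupies  y_left + (z - z_mid)*slant <= y <= y_right + (z -
## z_mid)*slant  for z_top <= z <= z_bot (z in mm, increasing downstream).
## Containment is half-open on the right/lower boundary; boundary points are
## assigned to material.

#' Build the closed-leaf polygon bank
#'
#' Constructs one cross-section polygon per closed leaf, with the bank
#' rotation (applied as a shear about each leaf's center at the MLC axial
#' mid-plane), the compensating bank translation from [mlc_shift()], the
#' interleaf air gaps, and optionally the tongue-and-groove step.
#'
#' @param spec A [leaf_spec()].
#' @param aperture An [aperture_state()].
#' @param geom A [beam_geometry()].
#' @return A list of `leaf_polygon` objects (empty if every leaf is open).
#'   Each has fields `vertices` (matrix of (y mm, z mm) corners) and
#'   `quads` (internal convex pieces used by the ray tracer).
#' @export
build_leaf_bank <- function(spec, aperture, geom = beam_geometry()) {
  n <- length(aperture$leaf_open)
  p <- spec$physical_pitch
  centers <- (seq_len(n) - (n + 1) / 2) * p
  shift <- mlc_shift(spec$height, spec$lbrot)
  slant <- tan(spec$lbrot / 1000)
  z_top <- geom$z_mlc_top * CM2MM
  z_bot <- z_top + spec$height
  z_mid <- (z_top + z_bot) / 2
  half_w <- (p - spec$air_gap) / 2

  polys <- list()
  for (i in seq_len(n)) {
    if (aperture$leaf_open[i]) next
    yl <- centers[i] - half_w + shift
    yr <- centers[i] + half_w + shift
    if (spec$tg_enabled) {
      ## symmetric step: the upper part is recessed by tg_width on the left
      ## flank, the lower part on the right flank, so the flank of every
      ## leaf carries a tongue that interlocks with the neighbour's groove
      z_step <- z_top + spec$tg_depth
      quads <- rbind(c(yl + spec$tg_width, yr, z_top, z_step, slant),
                     c(yl, yr - spec$tg_width, z_step, z_bot, slant))
    } else {
      quads <- rbind(c(yl, yr, z_top, z_bot, slant))
    }
    colnames(quads) <- c("y_left", "y_right", "z_top", "z_bot", "slant")
    polys[[length(polys) + 1]] <-
      structure(list(vertices = quads_to_vertices(quads, z_mid),
                     quads = quads, z_mid = z_mid, leaf_index = i),
                class = "leaf_polygon")
  }
  if (length(polys) >= 2) check_leaf_overlap(polys)
  polys
}

quads_to_vertices <- function(quads, z_mid) {
  vlist <- apply(quads, 1, function(q) {
    rbind(c(q[1] + (q[3] - z_mid) * q[5], q[3]),
          c(q[2] + (q[3] - z_mid) * q[5], q[3]),
          c(q[2] + (q[4] - z_mid) * q[5], q[4]),
          c(q[1] + (q[4] - z_mid) * q[5], q[4]))
  }, simplify = FALSE)
  v <- do.call(rbind, vlist)
  colnames(v) <- c("y_mm", "z_mm")
  v
}

check_leaf_overlap <- function(polys) {
  ## adjacent sheared leaves share the same slant, so overlap occurs iff
  ## their unsheared y-intervals overlap
  for (k in seq_len(length(polys) - 1)) {
    a <- polys[[k]]$quads; b <- polys[[k + 1]]$quads
    if (polys[[k + 1]]$leaf_index - polys[[k]]$leaf_index != 1) next
    if (max(a[, "y_right"]) > min(b[, "y_left"]) + 1e-9)
      stop("invalid geometry: leaf polygons overlap after rotation",
           call. = FALSE)
  }
  invisible(polys)
}

#' @export
print.leaf_polygon <- function(x, ...) {
  cat(sprintf("Leaf polygon (leaf %d): %d vertices, y in [%.3f, %.3f] mm\n",
              x$leaf_index, nrow(x$vertices), min(x$vertices[, 1]),
              max(x$vertices[, 1])))
  invisible(x)
}

#' Centroid of a leaf polygon cross-section
#'
#' Area-weighted centroid of the (possibly stepped) leaf cross-section,
#' useful for verifying the bank translation.
#'
#' @param poly A `leaf_polygon`.
#' @return Named numeric `c(y, z)` in mm.
#' @export
leaf_centroid <- function(poly) {
  q <- poly$quads
  areas <- (q[, "y_right"] - q[, "y_left"]) * (q[, "z_bot"] - q[, "z_top"])
  zc <- (q[, "z_top"] + q[, "z_bot"]) / 2
  yc <- (q[, "y_left"] + q[, "y_right"]) / 2 + (zc - poly$z_mid) * q[, "slant"]
  c(y = sum(yc * areas) / sum(areas), z = sum(zc * areas) / sum(areas))
}
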