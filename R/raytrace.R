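#' Ray-tracing options
#'
#' @param path_mode `"oblique"` traces the attenuation path along the true
#'   divergent ray; `"parallel"` uses the vertical traversal of the same
#'   leaf polygons at the ray's in-line coordinate at the MLC mid-plane
#'   (the approximation used by transmission-filter beam models).
#' @param quadrature Source-plane quadrature step (mm).  The number of
#'   nodes per source is capped at `max_nodes` (relevant only for the
#'   broad secondary source, which is smooth at the cm scale and fully
#'   converged at the capped step).
#' @param margin Margin added on either side of the source emission
#'   support when setting integration boundaries (mm).
#' @param max_nodes Upper bound on quadrature nodes per source.
#' @return Object of class `ray_trace_mode`.
#' @export
ray_trace_mode <- function(path_mode = c("oblique", "parallel"),
                           quadrature = 0.01, margin = 5, max_nodes = 6000) {
  path_mode <- match.arg(path_mode)
  stopifnot(quadrature > 0, margin >= 0, max_nodes >= 10)
  structure(list(path_mode = path_mode, quadrature = quadrature,
                 margin = margin, max_nodes = max_nodes),
            class = "ray_trace_mode")
}

#' Path length of a ray through the leaf bank
#'
#' Total chord length of the straight ray from `(y_source, z_source)` to
#' `(y_iso, z_isocenter)` inside leaf material.  Boundary-grazing rays are
#' assigned to material (half-open containment).
#'
#' @param y_source,z_source Ray origin: in-line mm, axial cm.
#' @param y_iso In-line position at the isocenter plane (mm).
#' @param polygons Leaf polygons from [build_leaf_bank()].
#' @param mode A [ray_trace_mode()].
#' @param geom A [beam_geometry()].
#' @return Path length in cm (0 if the ray misses all polygons).
#' @examples
#' geom <- beam_geometry()
#' bank <- build_leaf_bank(leaf_spec(lbrot = 0, air_gap = 0),
#'                         aperture_state("COC"), geom)
#' path_length(0, 1.1, 0, bank, geom = geom)     # open leaf: 0
#' @export
path_length <- function(y_source, z_source, y_iso, polygons,
                        mode = ray_trace_mode(), geom = beam_geometry()) {
  drop(path_matrix(y_iso, y_source, z_source, polygons, mode, geom))
}

## Path lengths (cm) for all combinations of isocenter points (rows) and
## source points (cols).  Rays run from (y_s, z_source) to (y_i, z_iso).
## Each convex leaf piece is a z-slab with sheared lateral faces, so the
## in-material interval in z follows from two linear inequalities.
path_matrix <- function(y_iso, y_source, z_source, polygons, mode, geom) {
  ni <- length(y_iso); ns <- length(y_source)
  z_s <- z_source * CM2MM
  z_i <- geom$z_isocenter * CM2MM
  m <- outer(y_iso, y_source, function(a, b) (a - b) / (z_i - z_s))
  y0 <- matrix(y_source, ni, ns, byrow = TRUE)   # y at z = z_s

  if (length(polygons) == 0) return(matrix(0, ni, ns))
  z_mid <- polygons[[1]]$z_mid

  if (mode$path_mode == "parallel") {
    ## vertical traversal at the ray's MLC-mid-plane coordinate
    y0 <- y0 + m * (z_mid - z_s)
    m <- matrix(0, ni, ns)
    z_s <- z_mid
  }
  sec <- sqrt(1 + m^2)

  total <- matrix(0, ni, ns)
  for (poly in polygons) {
    for (k in seq_len(nrow(poly$quads))) {
      q <- poly$quads[k, ]
      s <- q[["slant"]]
      b <- m - s
      ## left face:  y(z) - yl(z) = c1 + b z >= 0
      c1 <- y0 - m * z_s - q[["y_left"]] + s * z_mid
      ## right face: yr(z) - y(z) = c2 - b z >= 0
      c2 <- q[["y_right"]] - s * z_mid - y0 + m * z_s
      lo <- matrix(q[["z_top"]], ni, ns)
      hi <- matrix(q[["z_bot"]], ni, ns)
      eps <- 1e-12
      pos <- b > eps; neg <- b < -eps; zero <- !pos & !neg
      ## constraint c1 + b z >= 0
      lo[pos] <- pmax(lo[pos], -c1[pos] / b[pos])
      hi[neg] <- pmin(hi[neg], -c1[neg] / b[neg])
      hi[zero & c1 < 0] <- -Inf
      ## constraint c2 - b z >= 0
      hi[pos] <- pmin(hi[pos], c2[pos] / b[pos])
      lo[neg] <- pmax(lo[neg], c2[neg] / b[neg])
      hi[zero & c2 < 0] <- -Inf
      total <- total + pmax(0, hi - lo) * sec
    }
  }
  total / CM2MM
}

#' Source-plane integration boundaries
#'
#' Interval on the source plane containing all emission positions with
#' non-zero density reaching the profile window, widened by the
#' ray-tracing margin on each side.  Gaussian sources are cut at 5 sigma.
#'
#' @param source A [virtual_source()].
#' @param polygons Leaf polygons (accepted for interface symmetry; the
#'   emission support and margin alone set the bounds).
#' @param geom A [beam_geometry()].
#' @param margin Margin (mm).
#' @return Numeric `c(y_min, y_max)` in mm.
#' @export
source_boundaries <- function(source, polygons = list(),
                              geom = beam_geometry(), margin = 5) {
  half <- spatial_support(source) + margin
  c(-half, half)
}

#' Photon fluence at one isocenter point
#'
#' Quadrature over the source plane of the emission density times the
#' spectrum-weighted transmission along each ray through the leaf bank.
#'
#' @param y_iso Isocenter-plane position (mm).
#' @param source A [virtual_source()].
#' @param polygons Leaf polygons from [build_leaf_bank()].
#' @param geom A [beam_geometry()].
#' @param mode A [ray_trace_mode()].
#' @param table An [attenuation_table()].
#' @param mu_scale Scale factor on the attenuation coefficient.
#' @param attenuate Set `FALSE` to force transmission to 1 everywhere.
#' @return Fluence (per mm, unnormalized).
#' @export
fluence_at_point <- function(y_iso, source, polygons,
                             geom = beam_geometry(),
                             mode = ray_trace_mode(),
                             table = attenuation_table(),
                             mu_scale = 1, attenuate = TRUE) {
  drop(source_fluence(y_iso, source, polygons, geom, mode, table, mu_scale,
                      attenuate))
}

## fluence of one source on a vector of isocenter points
source_fluence <- function(y_grid, source, polygons, geom, mode, table,
                           mu_scale = 1, attenuate = TRUE) {
  if (source$spatial$type == "point") {
    nodes <- 0
    wts <- 1
    S <- 1   # Dirac mass collapsed analytically
  } else {
    bounds <- source_boundaries(source, polygons, geom, mode$margin)
    half <- bounds[2]
    step <- max(mode$quadrature, 2 * half / mode$max_nodes)
    fwhm <- switch(source$spatial$type, gaussian = source$spatial$fwhm,
                   disc = 2 * source$spatial$radius)
    if (fwhm / step < 10)
      warning("quadrature step too coarse: fewer than 10 nodes across ",
              "the source FWHM")
    ## nodes symmetric about the axis so symmetric configurations give
    ## exactly symmetric profiles
    k <- ceiling(half / step)
    nodes <- (-k:k) * (half / k)
    step <- half / k
    wts <- rep(step, length(nodes))
    wts[c(1, length(nodes))] <- step / 2     # trapezoid
    S <- spatial_density(source, nodes)
  }
  ## angular factor: mean intercept and window mass depend on nodes only
  a <- source$angular
  dz <- (geom$z_isocenter - source$z_source) * CM2MM
  if (a$type == "uniform") {
    A <- matrix(1 / (2 * a$window), length(y_grid), length(nodes))
  } else {
    sigma_y <- a$spread / 1000 * dz
    zf <- a$divergence_origin_z
    y0 <- if (is.null(zf)) nodes
          else nodes * (geom$z_isocenter - zf) / (source$z_source - zf)
    mass <- stats::pnorm((a$window - y0) / sigma_y) -
      stats::pnorm((-a$window - y0) / sigma_y)
    A <- outer(y_grid, y0, function(yi, mu) stats::dnorm(yi, mu, sigma_y)) /
      matrix(mass, length(y_grid), length(nodes), byrow = TRUE)
  }
  if (attenuate && length(polygons) > 0) {
    paths <- path_matrix(y_grid, nodes, source$z_source, polygons, mode, geom)
    Tm <- spectrum_transmission_mat(table, source$spectrum, paths, mu_scale)
  } else {
    Tm <- 1
  }
  drop((A * Tm) %*% (S * wts))
}

## memory-frugal matrix version of spectrum_transmission()
spectrum_transmission_mat <- function(table, spectrum, paths, mu_scale = 1) {
  mu <- mu_linear(table, spectrum$energies) * mu_scale
  if (spectrum$type == "mono") return(exp(-mu * paths))
  out <- 0
  for (i in seq_along(mu))
    out <- out + spectrum$probs[i] * exp(-mu[i] * paths)
  out
}

#' Compute an in-line fluence profile at the isocenter plane
#'
#' Weighted sum of the per-source ray-traced fluences on a regular in-line
#' grid, optionally normalized to unit trapezoidal integral.
#'
#' @param sources List of [virtual_source()] objects whose `rel_weight`s
#'   sum to 1 (a single source is accepted regardless of weight).
#' @param spec A [leaf_spec()].
#' @param aperture An [aperture_state()].
#' @param geom A [beam_geometry()].
#' @param grid In-line evaluation grid (mm), strictly increasing, uniform.
#' @param mode A [ray_trace_mode()].
#' @param table An [attenuation_table()]; defaults to the packaged table
#'   bound to the leaf material of `spec`.
#' @param normalize Normalize to unit integral?
#' @param mu_scale Attenuation-coefficient scale factor.
#' @param attenuate Set `FALSE` for 100% leaf transmission.
#' @return A `fluence_profile` with fields `y_grid`, `values`,
#'   `normalized`, `raw_integral` (unnormalized trapezoidal integral) and
#'   `meta`.
#' @examples
#' prof <- compute_profile(list(primary_source(rel_weight = 1)),
#'                         leaf_spec(), aperture_state("CCCCCOCCCCC"),
#'                         mode = ray_trace_mode(quadrature = 0.05),
#'                         grid = seq(-10, 10, 0.25))
#' profile_integral(prof)   # 1
#' @export
compute_profile <- function(sources, spec, aperture,
                            geom = beam_geometry(),
                            grid = seq(-15, 15, by = 0.1),
                            mode = ray_trace_mode(),
                            table = attenuation_table(
                              density = spec$density,
                              composition = spec$composition),
                            normalize = TRUE, mu_scale = 1,
                            attenuate = TRUE) {
  if (inherits(sources, "virtual_source")) sources <- list(sources)
  w <- vapply(sources, function(s) s$rel_weight, 0)
  if (length(sources) > 1 && abs(sum(w) - 1) > 1e-6)
    stop("source rel_weights must sum to 1", call. = FALSE)
  if (any(diff(grid) <= 0) ||
      max(abs(diff(diff(grid)))) > 1e-9 * mean(diff(grid)))
    stop("grid must be strictly increasing and uniform", call. = FALSE)
  polygons <- build_leaf_bank(spec, aperture, geom)
  vals <- 0
  for (s in sources)
    vals <- vals + s$rel_weight *
      source_fluence(grid, s, polygons, geom, mode, table, mu_scale,
                     attenuate)
  raw_integral <- trapz(grid, vals)
  if (all(vals == 0)) stop("all-zero fluence profile", call. = FALSE)
  if (normalize) vals <- vals / raw_integral
  structure(list(y_grid = grid, values = vals, normalized = normalize,
                 raw_integral = raw_integral,
                 meta = list(n_sources = length(sources),
                             path_mode = mode$path_mode,
                             lbrot = spec$lbrot,
                             aperture = paste(
                               ifelse(aperture$leaf_open, "O", "C"),
                               collapse = ""))),
            class = "fluence_profile")
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Construct a fluence profile from positions and values
#'
#' @param y_grid In-line positions (mm), strictly increasing.
#' @param values Fluence values (>= 0).
#' @param normalized Is the profile normalized to unit integral?
#' @param meta Optional provenance list.
#' @return A `fluence_profile`.
#' @export
fluence_profile <- function(y_grid, values, normalized = FALSE,
                            meta = list()) {
  stopifnot(length(y_grid) == length(values), all(diff(y_grid) > 0),
            all(values >= 0))
  if (normalized && abs(trapz(y_grid, values) - 1) > 1e-6)
    stop("profile flagged normalized but integral differs from 1",
         call. = FALSE)
  structure(list(y_grid = y_grid, values = values, normalized = normalized,
                 raw_integral = trapz(y_grid, values), meta = meta),
            class = "fluence_profile")
}

#' @export
print.fluence_profile <- function(x, ...) {
  cat(sprintf(
    "Fluence profile: %d points on [%.4g, %.4g] mm, max %.4g at %.3g mm%s\n",
    length(x$y_grid), min(x$y_grid), max(x$y_grid), max(x$values),
    x$y_grid[which.max(x$values)],
    if (x$normalized) " (unit integral)" else ""))
  invisible(x)
}

#' Trapezoidal integral and maximum of a fluence profile
#'
#' @param profile A `fluence_profile`.
#' @return A number.
#' @export
profile_integral <- function(profile) trapz(profile$y_grid, profile$values)

#' @rdname profile_integral
#' @export
profile_max <- function(profile) max(profile$values)

#' Rescale a profile to unit trapezoidal integral
#'
#' @param profile A `fluence_profile`.
#' @return The normalized `fluence_profile`.
#' @export
normalize_profile <- function(profile) {
  profile$values <- profile$values / profile_integral(profile)
  profile$normalized <- TRUE
  profile
}

#' Read/write fluence profiles as columnar text
#'
#' Two columns `y_mm fluence` preceded by `# key: value` metadata lines.
#'
#' @param profile A `fluence_profile`.
#' @param file Path.
#' @return `read_profile()` returns a `fluence_profile`.
#' @export
write_profile <- function(profile, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalized: %s", profile$normalized), con)
  for (k in names(profile$meta))
    writeLines(sprintf("# %s: %s", k, profile$meta[[k]]), con)
  writeLines("y_mm fluence", con)
  utils::write.table(data.frame(profile$y_grid, profile$values), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_profile
#' @export
read_profile <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  normalized <- any(grepl("^# normalized: TRUE", hdr))
  meta_lines <- grep("^# normalized:", hdr, value = TRUE, invert = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*: ", "", kv)
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  fluence_profile(df[[1]], df[[2]], normalized = normalized, meta = meta)
}
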