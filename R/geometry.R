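#' Geometry parameters for the idealised sphincter cross-section
#'
#' Defines the parametric two-dimensional domain used as a stand-in for the
#' histology-derived cross-section of the internal urethral sphincter: a
#' circular lumen, a dense-connective epithelium ring around it, and a spongy
#' stratum divided into four parts by thin open slits, with the upper and
#' lower halves connected by two 1-mm ligaments ("bounds") on the horizontal
#' axis.  The two lower spongy parts can be fibrotic.
#'
#' All lengths are in metres.  Internally the lumen centre is the origin with
#' the sane half up (positive y) and the fibrotic half down; angles are
#' measured counterclockwise from the positive x axis.
#'
#' @param lumen_radius radius of the undeformed lumen.
#' @param epithelium_thickness radial thickness of the dense-connective ring.
#' @param outer_radius mean radius of the outer boundary.
#' @param outer_waviness relative amplitude of a smooth `cos(2 theta)`
#'   modulation of the outer radius, mimicking the non-circular outline of the
#'   anatomical section; `0` gives a circle.
#' @param bound_length length of each of the two spongy-part connecting
#'   ligaments on the horizontal axis (default exactly 1 mm).
#' @param slit_width width of the open slits separating the four spongy
#'   parts.
#' @param fibrotic_half are the two lower spongy parts fibrotic?
#' @param lumen_center 2D position of the lumen centre.
#' @return Object of class `geometry_params`.
#' @export
geometry_params <- function(lumen_radius = 2.0e-3,
                            epithelium_thickness = 2.0e-3,
                            outer_radius = 6.8e-3,
                            outer_waviness = 0.04,
                            bound_length = 1.0e-3,
                            slit_width = 3.0e-4,
                            fibrotic_half = TRUE,
                            lumen_center = c(0, 0)) {
  p <- list(lumen_radius = lumen_radius,
            epithelium_thickness = epithelium_thickness,
            outer_radius = outer_radius,
            outer_waviness = outer_waviness,
            bound_length = bound_length,
            slit_width = slit_width,
            fibrotic_half = isTRUE(fibrotic_half),
            lumen_center = as.numeric(lumen_center))
  if (!(lumen_radius > 0))
    stop("parameter error: 0 < lumen_radius violated")
  if (!(epithelium_thickness > 0))
    stop("parameter error: lumen_radius < lumen_radius + epithelium_thickness violated")
  r_min_outer <- outer_radius * (1 - abs(outer_waviness))
  if (!(lumen_radius + epithelium_thickness < r_min_outer))
    stop("parameter error: lumen_radius + epithelium_thickness < min outer_radius violated")
  if (!(bound_length > 0))
    stop("parameter error: bound_length > 0 violated")
  if (!(slit_width > 0 && slit_width < lumen_radius))
    stop("parameter error: 0 < slit_width < lumen_radius violated")
  class(p) <- "geometry_params"
  p
}

# Outer-boundary radius profile at angle theta (centred coordinates).
outer_radius_at <- function(params, theta) {
  params$outer_radius * (1 + params$outer_waviness * cos(2 * theta))
}

# Derived radii: epithelium outer radius and bound outer x.
geom_radii <- function(params) {
  r_e <- params$lumen_radius + params$epithelium_thickness
  list(r_l = params$lumen_radius, r_e = r_e,
       x_b = r_e + params$bound_length)
}

#' Surgical hole specification
#'
#' Describes a set of laser-drilled circular holes placed on one arc
#' (`aligned`) or on two radially offset interleaved arcs (`staggered`)
#' inside the fibrotic spongy region.
#'
#' @param count number of holes, 0 to 7.
#' @param radius hole radius in metres (default 0.5 mm).
#' @param arrangement `"aligned"` or `"staggered"`.
#' @param arc_radius centre-line radius of the hole arc; default is the
#'   mid-thickness of the fibrotic region below the lumen.
#' @param arc_span angular extent of the hole arc in radians; default is the
#'   angular extent of the fibrotic sector minus one hole diameter of margin
#'   at each end.
#' @param stagger_offset radial separation of the two interleaved arcs
#'   (staggered arrangement only).
#' @param clearance minimum required gap between holes and between a hole and
#'   any region boundary.
#' @return Object of class `hole_spec`.
#' @export
hole_spec <- function(count,
                      radius = 0.5e-3,
                      arrangement = c("aligned", "staggered"),
                      arc_radius = NULL,
                      arc_span = NULL,
                      stagger_offset = 7e-4,
                      clearance = 5e-5) {
  arrangement <- match.arg(arrangement)
  stopifnot(count %in% 0:7, radius > 0, clearance >= 0)
  structure(list(count = as.integer(count), radius = radius,
                 arrangement = arrangement, arc_radius = arc_radius,
                 arc_span = arc_span, stagger_offset = stagger_offset,
                 clearance = clearance),
            class = "hole_spec")
}

## -- point classification ----------------------------------------------------

# Classify points (centred coordinates) into one of:
# "lumen", "epithelium", "spongy_sane", "spongy_fibrotic", "slit", "hole",
# "outside".  `holes` is a data.frame(x, y, r) or NULL.  `eps` shrinks void
# tests so that points exactly on a boundary count as material.
classify_points_xy <- function(params, x, y, holes = NULL, eps = 1e-9) {
  g <- geom_radii(params)
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  out <- rep("outside", length(x))
  hw <- params$slit_width / 2
  inside_outer <- r <= outer_radius_at(params, th) + eps
  out[inside_outer] <- "spongy_sane"
  out[r < g$r_l - eps] <- "lumen"
  band <- r >= g$r_l - eps & r <= g$r_e + eps & inside_outer
  out[band] <- "epithelium"
  sp <- inside_outer & r > g$r_e + eps
  # vertical slits (top and bottom): full depth of the spongy stratum
  vert <- sp & abs(x) < hw - eps
  out[vert] <- "slit"
  # horizontal slits (left and right): start one bound length out
  horiz <- sp & abs(y) < hw - eps & abs(x) > g$x_b + eps
  out[horiz] <- "slit"
  fib <- sp & !vert & !horiz & y < 0 & params$fibrotic_half
  out[fib] <- "spongy_fibrotic"
  if (!is.null(holes) && nrow(holes) > 0) {
    for (i in seq_len(nrow(holes))) {
      inh <- (x - holes$x[i])^2 + (y - holes$y[i])^2 < (holes$r[i] - eps)^2
      out[inh & out != "outside" & out != "lumen"] <- "hole"
    }
  }
  out
}

#' Classify points against a sphincter domain
#'
#' @param domain a [build_sphincter_domain()] result.
#' @param xy n x 2 matrix of coordinates (same frame as the domain).
#' @return Character vector with values among `"lumen"`, `"epithelium"`,
#'   `"spongy_sane"`, `"spongy_fibrotic"`, `"slit"`, `"hole"`, `"outside"`.
#' @export
classify_points <- function(domain, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  ctr <- domain$params$lumen_center
  classify_points_xy(domain$params, xy[, 1] - ctr[1], xy[, 2] - ctr[2],
                     domain$holes)
}

## -- polygon construction ----------------------------------------------------

# Points along the circle of radius r between angles a and b (increasing),
# using a shared global angular grid (plus shared break angles) so that
# different polygons tile exactly.
arc_points <- function(r, a, b, n_per_turn = 512L, breaks = numeric(0)) {
  th <- arc_angles(a, b, n_per_turn, breaks)
  cbind(r * cos(th), r * sin(th))
}

arc_angles <- function(a, b, n_per_turn = 512L, breaks = numeric(0)) {
  grid <- 2 * pi * seq(0L, n_per_turn) / n_per_turn
  grid <- sort(unique(c(grid, breaks %% (2 * pi))))
  grid <- grid + 2 * pi * floor((a - 2 * pi) / (2 * pi))
  th <- c(grid, grid + 2 * pi, grid + 4 * pi)
  th <- th[th > a + 1e-12 & th < b - 1e-12]
  c(a, th, b)
}

# Points along the outer boundary between angles a and b (increasing).
outer_arc_points <- function(params, a, b, n_per_turn = 512L,
                             breaks = numeric(0)) {
  th <- arc_angles(a, b, n_per_turn, breaks)
  r <- outer_radius_at(params, th)
  cbind(r * cos(th), r * sin(th))
}

# Shared break angles: slit-edge crossings on the inner (r_e) circle and on
# the outer boundary, mirrored to all four quadrants.
geom_breaks <- function(params) {
  g <- geom_radii(params)
  hw <- params$slit_width / 2
  ac <- acos(hw / g$r_e)
  f <- function(th) outer_radius_at(params, th) * sin(th) - hw
  th_a <- stats::uniroot(f, c(1e-8, pi / 4), tol = 1e-14)$root
  th_b <- outer_cross_x(params, hw, upper = TRUE)
  list(
    inner = sort(c(ac, pi - ac, pi + ac, 2 * pi - ac)),
    outer = sort(c(th_a, th_b, pi - th_b, pi - th_a,
                   pi + th_a, pi + th_b, 2 * pi - th_b, 2 * pi - th_a)),
    ac = ac, th_a = th_a, th_b = th_b)
}

# Angle at which the outer boundary crosses the vertical line x = x0 (near
# theta0) or the horizontal line y = y0.
outer_cross_x <- function(params, x0, upper = TRUE) {
  f <- function(th) outer_radius_at(params, th) * cos(th) - x0
  if (upper) stats::uniroot(f, c(1e-6, pi / 2 - 1e-6), tol = 1e-14)$root
  else stats::uniroot(f, c(-pi / 2 + 1e-6, -1e-6), tol = 1e-14)$root
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# Build the polygon of the upper-right spongy part in centred coordinates.
# The other three parts are mirror images.
spongy_part_polygon <- function(params, n_per_turn = 512L) {
  g <- geom_radii(params)
  hw <- params$slit_width / 2
  bk <- geom_breaks(params)
  th_a <- bk$th_a        # outer boundary crosses y = hw (right slit upper edge)
  th_b <- bk$th_b        # outer boundary crosses x = hw (top slit right edge)
  th_i_top <- bk$ac      # inner (r_e) circle crosses x = hw
  inner_arc <- arc_points(g$r_e, 0, th_i_top, n_per_turn, bk$inner)
  outer_arc <- outer_arc_points(params, th_a, th_b, n_per_turn, bk$outer)
  ia_rev <- inner_arc[rev(seq_len(nrow(inner_arc))), , drop = FALSE]
  ia_rev <- ia_rev[-nrow(ia_rev), , drop = FALSE]   # drop theta = 0 duplicate
  poly <- rbind(
    c(g$r_e, 0),
    c(g$x_b, 0),
    c(g$x_b, hw),
    outer_arc,                    # starts at (x_or, hw), ends at (hw, y_ob)
    ia_rev)
  # drop consecutive duplicates
  keep <- c(TRUE, rowSums((poly[-1, , drop = FALSE] -
                             poly[-nrow(poly), , drop = FALSE])^2) > 1e-24)
  poly[keep, , drop = FALSE]
}

mirror_poly <- function(poly, sx = 1, sy = 1) {
  out <- cbind(sx * poly[, 1], sy * poly[, 2])
  if (sx * sy < 0) out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  out
}

#' Build the parametric sphincter cross-section
#'
#' Constructs the tagged planar domain: one epithelium ring and four spongy
#' parts separated by thin open slits, with two 1-mm ligaments connecting the
#' upper and lower halves on the horizontal axis.  The two lower parts are
#' tagged `spongy_fibrotic` when `params$fibrotic_half` is set.  Pin points
#' (the two fully constrained points of the mechanical model) are placed on
#' the outer boundary immediately adjacent to the top and bottom slits.
#'
#' @param params a [geometry_params()] object.
#' @param n_per_turn angular resolution of polygonal arcs (vertices per full
#'   turn).
#' @return Object of class `planar_domain` with fields `params`, `regions`
#'   (list of `list(label, poly)`), `holes` (data.frame `x, y, r`),
#'   `lumen_boundary` (closed polygon), `pin_points` (2 x 2 matrix).
#' @export
build_sphincter_domain <- function(params, n_per_turn = 512L) {
  stopifnot(inherits(params, "geometry_params"))
  g <- geom_radii(params)
  hw <- params$slit_width / 2
  bk <- geom_breaks(params)
  lumen <- arc_points(g$r_l, 0, 2 * pi, n_per_turn)
  epi_outer <- arc_points(g$r_e, 0, 2 * pi, n_per_turn, bk$inner)
  # annulus polygon with a seam along theta = 0
  epi_poly <- rbind(epi_outer,
                    lumen[rev(seq_len(nrow(lumen))), , drop = FALSE])
  ur <- spongy_part_polygon(params, n_per_turn)
  parts <- list(ur,
                mirror_poly(ur, -1, 1),
                mirror_poly(ur, -1, -1),
                mirror_poly(ur, 1, -1))
  lower_label <- if (params$fibrotic_half) "spongy_fibrotic" else "spongy_sane"
  labels <- c("spongy_sane", "spongy_sane", lower_label, lower_label)
  regions <- c(list(list(label = "epithelium", poly = epi_poly)),
               Map(function(lab, p) list(label = lab, poly = p), labels, parts))
  names(regions) <- c("epithelium", "spongy_ur", "spongy_ul",
                      "spongy_ll", "spongy_lr")
  th_top <- outer_cross_x(params, hw, upper = TRUE)
  r_top <- outer_radius_at(params, th_top)
  pin <- rbind(c(r_top * cos(th_top), r_top * sin(th_top)),
               c(r_top * cos(th_top), -r_top * sin(th_top)))
  ctr <- params$lumen_center
  shift <- function(m) sweep(m, 2, ctr, "+")
  regions <- lapply(regions, function(rg) list(label = rg$label,
                                               poly = shift(rg$poly)))
  structure(list(params = params,
                 regions = regions,
                 holes = data.frame(x = numeric(0), y = numeric(0),
                                    r = numeric(0)),
                 lumen_boundary = shift(lumen),
                 pin_points = shift(pin),
                 n_per_turn = n_per_turn),
            class = "planar_domain")
}

#' @export
print.planar_domain <- function(x, ...) {
  labs <- vapply(x$regions, `[[`, "", "label")
  cat(sprintf("Planar sphincter domain: %d regions (%s), %d holes\n",
              length(labs), paste(table(labs)[unique(labs)], unique(labs),
                                  collapse = ", "),
              nrow(x$holes)))
  a <- domain_areas(x)
  cat(sprintf("  body area %.3f mm^2, lumen area %.3f mm^2\n",
              a$body * 1e6, a$lumen * 1e6))
  invisible(x)
}

#' Region, hole and body areas of a domain
#'
#' Areas are computed from the polygonal representation (shoelace formula);
#' the body area is the sum of the region polygon areas minus the hole areas,
#' and `outline` is an independently constructed outline check value: outer
#' boundary with slit notches minus the lumen disc.
#'
#' @param domain a [build_sphincter_domain()] result.
#' @return List with `regions` (named vector, m^2), `holes`, `lumen`, `body`,
#'   `outline`.
#' @export
domain_areas <- function(domain) {
  reg <- vapply(domain$regions, function(r) abs(polygon_area(r$poly)), 0)
  hole_area <- if (nrow(domain$holes)) {
    vapply(seq_len(nrow(domain$holes)), function(i) {
      abs(polygon_area(hole_polygon(domain$holes[i, ], 64L)))
    }, 0)
  } else numeric(0)
  lum <- abs(polygon_area(domain$lumen_boundary))
  body <- sum(reg) - sum(hole_area)
  # independent outline: outer-with-notches minus epithelium inner disc
  outline <- outline_area(domain$params, domain$n_per_turn) - lum
  list(regions = reg, holes = hole_area, lumen = lum, body = body,
       outline = outline)
}

hole_polygon <- function(hole, n = 64L) {
  th <- 2 * pi * seq(0, n - 1L) / n
  cbind(hole$x + hole$r * cos(th), hole$y + hole$r * sin(th))
}

# Area inside the outer boundary minus the four slit notches and the
# epithelium inner disc, computed from the same arc discretisations as the
# region polygons (centred coordinates).
outline_area <- function(params, n_per_turn = 512L) {
  g <- geom_radii(params)
  hw <- params$slit_width / 2
  bk <- geom_breaks(params)
  full <- abs(polygon_area(
    outer_arc_points(params, 0, 2 * pi, n_per_turn, bk$outer)))
  # top notch: region |x| < hw from the r_e circle to the outer curve
  oa_top <- outer_arc_points(params, bk$th_b, pi - bk$th_b, n_per_turn,
                             bk$outer)
  notch_tb <- rbind(
    arc_points(g$r_e, bk$ac, pi - bk$ac, n_per_turn, bk$inner),
    oa_top[rev(seq_len(nrow(oa_top))), , drop = FALSE])
  a_tb <- abs(polygon_area(notch_tb))
  # right notch: |y| < hw, x from the x_b cap to the outer curve
  oa <- outer_arc_points(params, -bk$th_a, bk$th_a, n_per_turn, bk$outer)
  notch_lr <- rbind(c(g$x_b, hw), c(g$x_b, -hw), oa)
  a_lr <- abs(polygon_area(notch_lr))
  full - 2 * a_tb - 2 * a_lr
}

## -- hole placement ----------------------------------------------------------

# Hole-centre angles for one fibrotic half-annulus: n holes distributed over
# the two lower quadrants, avoiding the bottom slit and the side slits.
hole_center_angles <- function(params, spec, arc_radius) {
  hw <- params$slit_width / 2
  # angular clearance to the slit edges, computed at the innermost arc radius
  # used (staggered patterns alternate between two radii) with a 20% safety
  # factor on the small-angle approximation
  r_eff <- arc_radius -
    if (spec$arrangement == "staggered") spec$stagger_offset / 2 else 0
  margin_mid <- 1.2 * (spec$radius + hw + spec$clearance) / r_eff
  margin_end <- margin_mid
  if (!is.null(spec$arc_span)) {
    span <- spec$arc_span
    lo <- 3 * pi / 2 - span / 2
    hi <- 3 * pi / 2 + span / 2
  } else {
    lo <- pi + margin_end
    hi <- 2 * pi - margin_end
  }
  # two sub-arcs excluding the bottom slit
  left <- c(lo, 3 * pi / 2 - margin_mid)
  right <- c(3 * pi / 2 + margin_mid, hi)
  n <- spec$count
  n_r <- ceiling(n / 2); n_l <- n - n_r
  spread <- function(intv, k) {
    if (k == 0) return(numeric(0))
    intv[1] + (intv[2] - intv[1]) * (seq_len(k) - 0.5) / k
  }
  sort(c(spread(left, n_l), spread(right, n_r)))
}

#' Place surgical holes in the fibrotic region
#'
#' Computes hole centres on one arc (`aligned`) or two interleaved arcs
#' (`staggered`) inside the fibrotic part of the domain, verifies the
#' placement geometrically (pairwise clearance and strict containment in the
#' fibrotic region), and returns the domain with the holes attached.  The
#' placement is fully deterministic.
#'
#' @param domain a [build_sphincter_domain()] result with a fibrotic region.
#' @param spec a [hole_spec()].
#' @return The domain with `spec$count` holes.
#' @export
place_holes <- function(domain, spec) {
  stopifnot(inherits(domain, "planar_domain"), inherits(spec, "hole_spec"))
  if (spec$count == 0L) return(domain)
  params <- domain$params
  labs <- vapply(domain$regions, `[[`, "", "label")
  if (!any(labs == "spongy_fibrotic"))
    stop("domain has no fibrotic region to place holes in")
  g <- geom_radii(params)
  r_out_bottom <- outer_radius_at(params, 3 * pi / 2)
  # default hole arc: 60% of the way through the fibrotic thickness, leaving
  # clearance for the staggered arrangement on both sides
  arc_radius <- if (is.null(spec$arc_radius))
    g$r_e + 0.6 * (r_out_bottom - g$r_e) else spec$arc_radius
  th <- hole_center_angles(params, spec, arc_radius)
  radii <- rep(arc_radius, spec$count)
  if (spec$arrangement == "staggered")
    radii <- arc_radius + spec$stagger_offset / 2 *
      ifelse(seq_len(spec$count) %% 2 == 1, 1, -1)
  holes <- data.frame(x = radii * cos(th) + params$lumen_center[1],
                      y = radii * sin(th) + params$lumen_center[2],
                      r = spec$radius)
  out <- domain
  out$holes <- holes
  out$hole_spec <- spec
  check_hole_placement(out, spec$clearance)
  out
}

# Geometric verification: pairwise clearance and strict containment of every
# hole (inflated by the clearance margin) in the fibrotic spongy region.
check_hole_placement <- function(domain, clearance, n_probe = 72L) {
  holes <- domain$holes
  n <- nrow(holes)
  if (n == 0) return(invisible(TRUE))
  bad <- integer(0)
  if (n > 1) {
    d <- as.matrix(stats::dist(holes[, c("x", "y")]))
    diag(d) <- Inf
    need <- outer(holes$r, holes$r, "+") + clearance
    ov <- which(d < need, arr.ind = TRUE)
    bad <- union(bad, unique(as.vector(ov)))
  }
  th <- 2 * pi * seq(0, n_probe - 1L) / n_probe
  for (i in seq_len(n)) {
    px <- holes$x[i] + (holes$r[i] + clearance) * cos(th)
    py <- holes$y[i] + (holes$r[i] + clearance) * sin(th)
    cls <- classify_points_xy(domain$params,
                              px - domain$params$lumen_center[1],
                              py - domain$params$lumen_center[2],
                              holes = NULL)
    if (!all(cls == "spongy_fibrotic")) bad <- union(bad, i)
  }
  if (length(bad))
    stop("placement error: holes ", paste(sort(bad), collapse = ", "),
         " overlap each other or a region boundary")
  invisible(TRUE)
}

## -- case registry -----------------------------------------------------------

#' Simulation case registry
#'
#' Returns the geometry parameters and hole specification for the named
#' simulation case: `P0` (sane tissue, no holes), `H0` (fibrotic lower half,
#' no holes), `H3`..`H7` (3 to 7 aligned holes), and `H6b` (6 staggered
#' holes).
#'
#' @param case_id one of `"P0"`, `"H0"`, `"H3"`, `"H4"`, `"H5"`, `"H6"`,
#'   `"H7"`, `"H6b"`.
#' @param params base [geometry_params()]; the registry only toggles
#'   `fibrotic_half`.
#' @return List with elements `params` and `holes` (a [hole_spec()]).
#' @export
#' @examples
#' case_registry("H6b")$holes$arrangement   # "staggered"
case_registry <- function(case_id, params = geometry_params()) {
  known <- c("P0", "H0", "H3", "H4", "H5", "H6", "H7", "H6b")
  if (!case_id %in% known)
    stop("unknown case id '", case_id, "'; known: ",
         paste(known, collapse = ", "))
  params$fibrotic_half <- case_id != "P0"
  n <- switch(case_id, P0 = 0L, H0 = 0L, H6b = 6L,
              as.integer(sub("^H", "", case_id)))
  arrangement <- if (case_id == "H6b") "staggered" else "aligned"
  list(params = params, holes = hole_spec(n, arrangement = arrangement))
}

#' Build the full domain for a registered case
#'
#' @inheritParams case_registry
#' @return A [build_sphincter_domain()] result with holes placed.
#' @export
build_case <- function(case_id, params = geometry_params()) {
  cs <- case_registry(case_id, params)
  dom <- build_sphincter_domain(cs$params)
  place_holes(dom, cs$holes)
}

## -- serialisation -----------------------------------------------------------

#' Write a domain description to a YAML file
#'
#' Serialises the geometry parameters, hole table and pin points to a plain
#' structured text file.
#'
#' @param domain a [build_sphincter_domain()] result.
#' @param path output file path.
#' @export
write_domain_yaml <- function(domain, path) {
  p <- domain$params
  obj <- list(
    geometry = list(
      lumen_radius = p$lumen_radius,
      epithelium_thickness = p$epithelium_thickness,
      outer_radius = p$outer_radius,
      outer_waviness = p$outer_waviness,
      bound_length = p$bound_length,
      slit_width = p$slit_width,
      fibrotic_half = p$fibrotic_half,
      lumen_center = p$lumen_center),
    holes = if (nrow(domain$holes)) lapply(seq_len(nrow(domain$holes)),
      function(i) as.list(domain$holes[i, ])) else list(),
    pin_points = list(as.numeric(domain$pin_points[1, ]),
                      as.numeric(domain$pin_points[2, ])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Write domain boundary polygons in a planar straight-line-graph text format
#'
#' Emits the region outlines and hole circles as a `.poly`-style plain-text
#' file (vertex list then segment list), usable by external triangulators.
#'
#' @inheritParams write_domain_yaml
#' @export
write_domain_poly <- function(domain, path) {
  polys <- c(lapply(domain$regions, `[[`, "poly"),
             if (nrow(domain$holes))
               lapply(seq_len(nrow(domain$holes)),
                      function(i) hole_polygon(domain$holes[i, ])))
  nv <- vapply(polys, nrow, 0L)
  off <- cumsum(c(0L, nv[-length(nv)]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d 2 0 0", sum(nv)), con)
  k <- 0L
  for (p in polys) for (i in seq_len(nrow(p))) {
    k <- k + 1L
    writeLines(sprintf("%d %.12e %.12e", k, p[i, 1], p[i, 2]), con)
  }
  writeLines(sprintf("%d 0", sum(nv)), con)
  s <- 0L
  for (j in seq_along(polys)) {
    n <- nv[j]
    idx <- off[j] + seq_len(n)
    nxt <- c(idx[-1], idx[1])
    for (i in seq_len(n)) {
      s <- s + 1L
      writeLines(sprintf("%d %d %d", s, idx[i], nxt[i]), con)
    }
  }
  writeLines("0", con)
  invisible(path)
}
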