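#' Delaunay triangulation of a planar point set
#'
#' Thin wrapper around the package's triangulation backend, returning
#' counterclockwise-oriented triangles.
#'
#' @param xy n x 2 matrix of point coordinates.
#' @return m x 3 integer matrix of node indices (counterclockwise).
#' @export
delaunay_triangulate <- function(xy, jitter = 0) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  xj <- xy
  if (jitter > 0) {
    # deterministic micro-perturbation to break co-circular degeneracies in
    # the triangulation backend; connectivity only, geometry keeps the exact
    # coordinates
    rs <- get0(".Random.seed", envir = globalenv())
    set.seed(nrow(xy) %% .Machine$integer.max)
    xj <- xy + matrix(stats::runif(2 * nrow(xy), -1, 1), ncol = 2) * jitter
    if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
  }
  tr <- interp::tri.mesh(xj[, 1], xj[, 2])
  tri <- interp::triangles(tr)[, 1:3, drop = FALSE]
  orient_ccw(tri, xy)
}

orient_ccw <- function(tri, xy) {
  a <- tri_signed_areas(tri, xy)
  flip <- a < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  tri
}

tri_signed_areas <- function(tri, xy) {
  x1 <- xy[tri[, 1], 1]; y1 <- xy[tri[, 1], 2]
  x2 <- xy[tri[, 2], 1]; y2 <- xy[tri[, 2], 2]
  x3 <- xy[tri[, 3], 1]; y3 <- xy[tri[, 3], 2]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

## -- size field and sampling -------------------------------------------------

# Target edge-length field: h_fine in the epithelium ring plus a band of one
# epithelium thickness around it and in a band around every hole, grading
# linearly up to h_coarse away from those features.
mesh_size_field <- function(domain, h_coarse, h_fine, x, y, grade = 0.3) {
  p <- domain$params
  g <- geom_radii(p)
  band_epi <- p$epithelium_thickness
  band_hole <- 3 * h_fine
  r <- sqrt(x^2 + y^2)
  d <- pmax(0, r - (g$r_e + band_epi))
  if (nrow(domain$holes)) {
    for (i in seq_len(nrow(domain$holes))) {
      hx <- domain$holes$x[i] - p$lumen_center[1]
      hy <- domain$holes$y[i] - p$lumen_center[2]
      dh <- pmax(0, abs(sqrt((x - hx)^2 + (y - hy)^2) - domain$holes$r[i]) -
                   band_hole)
      d <- pmin(d, dh)
    }
  }
  pmin(h_coarse, h_fine + grade * d)
}

# March along a parametric curve placing points at spacing `frac * h(x)`.
# `fun(t)` maps [0, 1] to coordinates; curve assumed close to arc-length
# parametrised via the supplied total length.
sample_curve <- function(fun, len, hfun, frac = 0.75) {
  t <- 0; ts <- 0
  while (t < 1) {
    p <- fun(t)
    step <- frac * hfun(p[1], p[2]) / len
    t <- min(1, t + step)
    ts <- c(ts, t)
  }
  # even out the last interval
  if (length(ts) > 2 && (ts[length(ts)] - ts[length(ts) - 1]) <
        0.4 * (ts[3] - ts[2]))
    ts <- ts[-(length(ts) - 1)]
  t(vapply(ts, fun, numeric(2)))
}

circle_points <- function(r, cx, cy, spacing) {
  n <- max(16L, ceiling(2 * pi * r / spacing))
  th <- 2 * pi * seq(0L, n - 1L) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# All boundary sample points of the domain (centred coordinates), with a
# curve id for edge-group classification later.
sample_boundaries <- function(domain, h_coarse, h_fine, grade = 0.3,
                              frac = 0.75, interface = NULL) {
  p <- domain$params
  g <- geom_radii(p)
  hw <- p$slit_width / 2
  bk <- geom_breaks(p)
  hfun <- function(x, y) mesh_size_field(domain, h_coarse, h_fine, x, y, grade)
  pts <- list()
  iface <- if (is.null(interface))
    circle_points(g$r_e, 0, 0, frac * h_fine) else interface
  # interface nodes under the top/bottom slits belong to the epithelium
  # surface only; excluding them from the spongy cloud keeps Delaunay edges
  # from crossing the slit mouths
  pts$interface <- iface[abs(iface[, 1]) >= hw, , drop = FALSE]
  # outer boundary, split at the slit corners
  brk <- c(bk$outer, bk$outer[1] + 2 * pi)
  segs <- list()
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]; b <- brk[i + 1]
    fun <- function(t) {
      th <- a + t * (b - a)
      R <- outer_radius_at(p, th)
      c(R * cos(th), R * sin(th))
    }
    len <- (b - a) * outer_radius_at(p, (a + b) / 2)
    segs[[i]] <- sample_curve(fun, len, hfun, frac)
  }
  pts$outer <- do.call(rbind, segs)
  # slit edges
  seg_line <- function(p0, p1) {
    len <- sqrt(sum((p1 - p0)^2))
    sample_curve(function(t) p0 + t * (p1 - p0), len, hfun, frac)
  }
  th_b <- bk$th_b; th_a <- bk$th_a
  y_ob <- outer_radius_at(p, th_b) * sin(th_b)
  x_oa <- outer_radius_at(p, th_a) * cos(th_a)
  # the inner ends of the top/bottom slit edges are snapped to the nearest
  # interface node on the material side (|x| >= hw), so the slit edges start
  # exactly at shared mesh nodes
  snap_inner <- function(target) {
    iface <- pts$interface
    okm <- abs(iface[, 1]) >= hw - 1e-12
    cand <- iface[okm, , drop = FALSE]
    d2 <- (cand[, 1] - target[1])^2 + (cand[, 2] - target[2])^2
    cand[which.min(d2), ]
  }
  y_i <- sqrt(g$r_e^2 - hw^2)
  tr_in <- snap_inner(c(hw, y_i))       # top right
  tl_in <- snap_inner(c(-hw, y_i))
  br_in <- snap_inner(c(hw, -y_i))
  bl_in <- snap_inner(c(-hw, -y_i))
  slit <- rbind(
    seg_line(tr_in, c(hw, y_ob)),             # top slit right edge
    seg_line(tl_in, c(-hw, y_ob)),            # top slit left edge
    seg_line(br_in, c(hw, -y_ob)),            # bottom slit edges
    seg_line(bl_in, c(-hw, -y_ob)),
    seg_line(c(g$x_b, -hw), c(g$x_b, hw)),    # right slit cap
    seg_line(c(g$x_b, hw), c(x_oa, hw)),      # right slit long edges
    seg_line(c(g$x_b, -hw), c(x_oa, -hw)),
    seg_line(c(-g$x_b, -hw), c(-g$x_b, hw)),  # left slit
    seg_line(c(-g$x_b, hw), c(-x_oa, hw)),
    seg_line(c(-g$x_b, -hw), c(-x_oa, -hw)))
  pts$slit <- slit
  if (nrow(domain$holes)) {
    ctr <- p$lumen_center
    pts$holes <- do.call(rbind, lapply(seq_len(nrow(domain$holes)), function(i)
      circle_points(domain$holes$r[i], domain$holes$x[i] - ctr[1],
                    domain$holes$y[i] - ctr[2], frac * h_fine)))
  }
  all <- do.call(rbind, pts)
  # deduplicate shared corners
  key <- paste(round(all[, 1], 12), round(all[, 2], 12))
  all[!duplicated(key), , drop = FALSE]
}

## -- mesh generation ---------------------------------------------------------

#' Generate a graded triangular mesh of the sphincter domain
#'
#' Distmesh-style generator: boundary curves are sampled at the local target
#' edge length, the interior is seeded with a hexagonal lattice thinned by
#' rejection sampling against the size field, the point cloud is Delaunay
#' triangulated, triangles outside the material are discarded, and a few
#' Laplacian smoothing sweeps (with re-triangulation) regularise element
#' shape.  The target edge length is `h_fine` in the epithelium ring, in a
#' band of one epithelium thickness around it and in a band around every
#' hole, grading linearly to `h_coarse` elsewhere.  Generation is
#' deterministic for identical inputs.
#'
#' @param domain a [build_sphincter_domain()] (optionally [place_holes()])
#'   result.
#' @param h_coarse,h_fine maximum element edge lengths (m) in the coarse and
#'   refined zones; `0 < h_fine <= h_coarse`.
#' @param quadratic must be `FALSE`; the model uses 3-node plane-stress
#'   triangles (two displacement components per node).
#' @param grade size-field gradation rate (dimensionless).
#' @param smooth_iters number of Laplacian smoothing sweeps.
#' @param seed integer seed for the (deterministic) interior point thinning.
#' @return Object of class `fe_mesh`: `nodes` (n x 2, m), `tri` (m x 3,
#'   counterclockwise), `region` (character per element), `edge_groups`
#'   (list with `lumen`, `holes`, `outer`; ordered edge matrices), `h_coarse`,
#'   `h_fine`, `pin_nodes` (two node indices), `domain`.
#' @export
generate_mesh <- function(domain, h_coarse = 2e-4, h_fine = 1e-4,
                          quadratic = FALSE, grade = 0.3,
                          smooth_iters = 3L, seed = 7L) {
  stopifnot(inherits(domain, "planar_domain"))
  if (quadratic)
    stop("quadratic elements are not supported: the model uses 3-node triangles")
  if (!(h_fine > 0 && h_fine <= h_coarse))
    stop("require 0 < h_fine <= h_coarse")
  p <- domain$params
  g <- geom_radii(p)
  ctr <- p$lumen_center
  frac <- 0.72
  # structured polar mesh of the epithelium annulus: exact thin-layer
  # refinement with well-shaped elements; its outer ring is shared with the
  # unstructured spongy mesh
  epi <- structured_annulus_mesh(g$r_l, g$r_e, h_fine)
  n_ring <- epi$n_theta
  interface_pts <- epi$nodes[epi$outer_ring, , drop = FALSE]
  bnd <- sample_boundaries(domain, h_coarse, h_fine, grade, frac,
                           interface = interface_pts)
  # hexagonal candidate lattice over the bounding box at the fine spacing
  rmax <- p$outer_radius * (1 + abs(p$outer_waviness)) + h_coarse
  s0 <- frac * h_fine
  xs <- seq(-rmax, rmax, by = s0)
  ys <- seq(-rmax, rmax, by = s0 * sqrt(3) / 2)
  lat <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  odd <- rep(seq_along(ys) %% 2 == 1, each = length(xs))
  lat[odd, 1] <- lat[odd, 1] + s0 / 2
  # thin by the size field: keep with probability (h_fine / h)^2
  hloc <- mesh_size_field(domain, h_coarse, h_fine, lat[, 1], lat[, 2], grade)
  rs <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(seed)
  keep <- stats::runif(nrow(lat)) < (h_fine / hloc)^2
  lat <- lat[keep, , drop = FALSE]
  hloc <- hloc[keep]
  # spongy material points only, away from the boundary samples
  cls <- classify_points_xy(p, lat[, 1], lat[, 2], domain_holes_centred(domain))
  ok <- cls %in% c("spongy_sane", "spongy_fibrotic")
  lat <- lat[ok, , drop = FALSE]; hloc <- hloc[ok]
  dmin <- min_dist_to(lat, bnd)
  ok <- dmin >= 0.55 * frac * hloc
  pts <- rbind(bnd, lat[ok, , drop = FALSE])
  is_bnd <- c(rep(TRUE, nrow(bnd)), rep(FALSE, sum(ok)))
  jit <- 1e-4 * h_fine
  hfield <- function(x, y) mesh_size_field(domain, h_coarse, h_fine, x, y, grade)
  material <- function(x, y)
    classify_points_xy(p, x, y, domain_holes_centred(domain)) %in%
      c("spongy_sane", "spongy_fibrotic")
  # refinement loop: split over-long edges, drop crowded interior nodes,
  # then Laplacian-smooth; re-triangulate each round
  for (it in seq_len(max(2L, smooth_iters + 1L))) {
    tri <- cull_triangles(delaunay_triangulate(pts, jit), pts, domain)
    ed <- unique_edges(tri)
    mx <- (pts[ed[, 1], 1] + pts[ed[, 2], 1]) / 2
    my <- (pts[ed[, 1], 2] + pts[ed[, 2], 2]) / 2
    len <- sqrt((pts[ed[, 1], 1] - pts[ed[, 2], 1])^2 +
                  (pts[ed[, 1], 2] - pts[ed[, 2], 2])^2)
    hmid <- hfield(mx, my)
    long <- len > 0.92 * hmid
    if (any(long)) {
      cand <- cbind(mx[long], my[long])
      cand <- cand[!duplicated(paste(round(cand[, 1], 12),
                                     round(cand[, 2], 12))), , drop = FALSE]
      okc <- material(cand[, 1], cand[, 2]) &
        min_dist_to(cand, bnd) >= 0.5 * frac * hfield(cand[, 1], cand[, 2]) &
        min_dist_to(cand, pts) >= 0.4 * frac * hfield(cand[, 1], cand[, 2])
      if (any(okc)) {
        pts <- rbind(pts, cand[okc, , drop = FALSE])
        is_bnd <- c(is_bnd, rep(FALSE, sum(okc)))
        tri <- cull_triangles(delaunay_triangulate(pts, jit), pts, domain)
        ed <- unique_edges(tri)
        len <- sqrt((pts[ed[, 1], 1] - pts[ed[, 2], 1])^2 +
                      (pts[ed[, 1], 2] - pts[ed[, 2], 2])^2)
      }
    }
    # remove interior nodes crowding a neighbour
    hmin <- hfield(pts[ed[, 1], 1], pts[ed[, 1], 2])
    short <- len < 0.45 * frac * hmin
    drop <- unique(ifelse(is_bnd[ed[short, 2]], ed[short, 1], ed[short, 2]))
    drop <- drop[!is_bnd[drop]]
    if (length(drop)) {
      keep_idx <- setdiff(seq_len(nrow(pts)), drop)
      pts <- pts[keep_idx, , drop = FALSE]
      is_bnd <- is_bnd[keep_idx]
      tri <- cull_triangles(delaunay_triangulate(pts, jit), pts, domain)
    }
    for (sw in seq_len(2L))
      pts <- smooth_interior(pts, tri, is_bnd, domain)
    # smoothing can park an interior node exactly on a boundary sample
    # (uniformly spaced curves make midpoints coincide); drop such copies
    dup <- duplicated(paste(round(pts[, 1], 12), round(pts[, 2], 12))) & !is_bnd
    if (any(dup)) {
      pts <- pts[!dup, , drop = FALSE]
      is_bnd <- is_bnd[!dup]
    }
  }
  tri <- cull_triangles(delaunay_triangulate(pts, jit), pts, domain)
  # sliver cleanup: local targeted smoothing of the interior nodes of badly
  # shaped elements; if a sliver has no interior node, drop an interior
  # neighbour-free fix is impossible and the element is left to the global
  # quality report
  for (it in seq_len(8L)) {
    ang <- tri_angles(tri, pts)
    bad <- which(apply(ang, 1, min) < 20)
    if (!length(bad)) break
    move <- unique(as.vector(tri[bad, ]))
    move <- move[!is_bnd[move]]
    if (!length(move)) break
    pts <- smooth_nodes(pts, tri, move, domain)
    tri <- cull_triangles(delaunay_triangulate(pts, jit), pts, domain)
  }
  # drop unreferenced nodes
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(pts)); remap[used] <- seq_along(used)
  nodes <- pts[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3)
  # merge the structured epithelium mesh: its outer-ring nodes coincide with
  # the first n_ring boundary-sample nodes of the spongy cloud
  key_sp <- paste(round(nodes[, 1], 12), round(nodes[, 2], 12))
  key_epi <- paste(round(epi$nodes[, 1], 12), round(epi$nodes[, 2], 12))
  map_epi <- match(key_epi, key_sp)              # NA where epithelium-only
  new_idx <- which(is.na(map_epi))
  map_epi[new_idx] <- nrow(nodes) + seq_along(new_idx)
  nodes <- rbind(nodes, epi$nodes[new_idx, , drop = FALSE])
  tri <- rbind(tri, matrix(map_epi[epi$tri], ncol = 3))
  cen <- tri_centroids(tri, nodes)
  region <- classify_points_xy(p, cen[, 1], cen[, 2],
                               domain_holes_centred(domain))
  edge_groups <- build_edge_groups(nodes, tri, domain)
  nodes_g <- sweep(nodes, 2, ctr, "+")
  pin <- vapply(1:2, function(i) {
    d2 <- (nodes_g[, 1] - domain$pin_points[i, 1])^2 +
      (nodes_g[, 2] - domain$pin_points[i, 2])^2
    which.min(d2)
  }, 0L)
  structure(list(nodes = nodes_g, tri = tri, region = region,
                 edge_groups = edge_groups, h_coarse = h_coarse,
                 h_fine = h_fine, pin_nodes = pin, domain = domain),
            class = "fe_mesh")
}

domain_holes_centred <- function(domain) {
  h <- domain$holes
  if (nrow(h)) {
    h$x <- h$x - domain$params$lumen_center[1]
    h$y <- h$y - domain$params$lumen_center[2]
  }
  h
}

min_dist_to <- function(a, b, chunk = 2000L) {
  out <- numeric(nrow(a))
  for (i0 in seq(1L, nrow(a), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(a))
    dx <- outer(a[i0:i1, 1], b[, 1], "-")
    dy <- outer(a[i0:i1, 2], b[, 2], "-")
    out[i0:i1] <- sqrt(apply(dx^2 + dy^2, 1, min))
  }
  out
}

tri_centroids <- function(tri, xy) {
  cbind((xy[tri[, 1], 1] + xy[tri[, 2], 1] + xy[tri[, 3], 1]) / 3,
        (xy[tri[, 1], 2] + xy[tri[, 2], 2] + xy[tri[, 3], 2]) / 3)
}

# Keep triangles that lie in the material.  The centroid decides strictly;
# edge midpoints additionally guard against triangles bridging a slit or
# leaving the outer boundary.  Midpoints are allowed to test "lumen"/"hole":
# chords of those concave boundary circles dip into the void by the sagitta,
# which is a discretisation artefact, not a bridging triangle.
cull_triangles <- function(tri, pts, domain,
                           material = c("spongy_sane", "spongy_fibrotic")) {
  p <- domain$params
  holes <- domain_holes_centred(domain)
  cen <- tri_centroids(tri, pts)
  ok <- classify_points_xy(p, cen[, 1], cen[, 2], holes) %in% material
  for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
    mx <- (pts[tri[, e[1]], 1] + pts[tri[, e[2]], 1]) / 2
    my <- (pts[tri[, e[1]], 2] + pts[tri[, e[2]], 2]) / 2
    cls <- classify_points_xy(p, mx, my, holes)
    ok <- ok & !(cls %in% c("slit", "outside"))
  }
  tri[ok, , drop = FALSE]
}

# Structured polar mesh of an annulus r0 <= r <= r1: nr uniform rings and a
# shared angular grid sized so that no element edge (including diagonals)
# exceeds h.
structured_annulus_mesh <- function(r0, r1, h, n_theta = NULL) {
  s <- h / sqrt(2)
  nr <- max(2L, ceiling((r1 - r0) / s))
  if (is.null(n_theta)) n_theta <- max(16L, ceiling(2 * pi * r1 / s))
  radii <- seq(r0, r1, length.out = nr + 1L)
  th <- 2 * pi * seq(0L, n_theta - 1L) / n_theta
  nodes <- cbind(rep(radii, each = n_theta) * cos(th),
                 rep(radii, each = n_theta) * sin(th))
  tris <- vector("list", nr)
  for (k in seq_len(nr)) {
    j <- seq_len(n_theta)
    j1 <- c(seq_len(n_theta)[-1], 1L)
    a <- (k - 1L) * n_theta + j
    b <- (k - 1L) * n_theta + j1
    cc <- k * n_theta + j1
    d <- k * n_theta + j
    even <- (j + k) %% 2L == 0L
    # alternate the quad diagonal for isotropy
    tris[[k]] <- rbind(
      cbind(a, b, ifelse(even, cc, d)),
      cbind(ifelse(even, a, b), cc, d))
  }
  tri <- orient_ccw(do.call(rbind, tris), nodes)
  list(nodes = nodes, tri = tri, n_theta = n_theta,
       inner_ring = seq_len(n_theta),
       outer_ring = nr * n_theta + seq_len(n_theta))
}

# Targeted Laplacian smoothing of selected nodes only.
smooth_nodes <- function(pts, tri, move, domain) {
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  i <- c(edges[, 1], edges[, 2])
  j <- c(edges[, 2], edges[, 1])
  sel <- i %in% move
  i <- i[sel]; j <- j[sel]
  sx <- rowsum(pts[j, 1], i)
  sy <- rowsum(pts[j, 2], i)
  cnt <- rowsum(rep(1, length(i)), i)
  idx <- as.integer(rownames(sx))
  newx <- sx / cnt; newy <- sy / cnt
  cls <- classify_points_xy(domain$params, newx, newy,
                            domain_holes_centred(domain))
  ok <- cls %in% c("spongy_sane", "spongy_fibrotic")
  pts[idx[ok], 1] <- newx[ok]
  pts[idx[ok], 2] <- newy[ok]
  pts
}

unique_edges <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

# One Laplacian sweep over interior nodes (is_bnd == FALSE), with a guard
# that rejects moves leaving the material.
smooth_interior <- function(pts, tri, is_bnd, domain) {
  n <- nrow(pts)
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  i <- c(edges[, 1], edges[, 2])
  j <- c(edges[, 2], edges[, 1])
  # edges appear once per adjacent triangle; interior edges are counted
  # twice, which only reweights the average slightly
  sx <- rowsum(pts[j, 1], i)
  sy <- rowsum(pts[j, 2], i)
  cnt <- rowsum(rep(1, length(i)), i)
  idx <- as.integer(rownames(sx))
  newx <- pts[, 1]; newy <- pts[, 2]
  newx[idx] <- sx / cnt; newy[idx] <- sy / cnt
  cls <- classify_points_xy(domain$params, newx, newy,
                            domain_holes_centred(domain))
  ok <- !is_bnd & cls %in% c("epithelium", "spongy_sane", "spongy_fibrotic")
  pts[ok, 1] <- newx[ok]
  pts[ok, 2] <- newy[ok]
  pts
}

# Boundary edges (appearing in exactly one triangle), oriented with the
# material on the left, classified into lumen / hole_i / outer groups and
# chained into ordered loops where closed.
build_edge_groups <- function(nodes, tri, domain) {
  p <- domain$params
  g <- geom_radii(p)
  holes <- domain_holes_centred(domain)
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  bnd <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  mx <- (nodes[bnd[, 1], 1] + nodes[bnd[, 2], 1]) / 2
  my <- (nodes[bnd[, 1], 2] + nodes[bnd[, 2], 2]) / 2
  r <- sqrt(mx^2 + my^2)
  # boundary nodes lie exactly on their curves, so chord midpoints are within
  # the sagitta (<< 1e-5 m) of the curve; 1e-5 m separates the groups safely
  tol <- 1e-5
  grp <- rep("outer", nrow(bnd))
  grp[abs(r - g$r_l) < tol] <- "lumen"
  if (nrow(holes)) {
    for (i in seq_len(nrow(holes))) {
      dh <- abs(sqrt((mx - holes$x[i])^2 + (my - holes$y[i])^2) - holes$r[i])
      grp[dh < tol] <- paste0("hole_", i)
    }
  }
  chain <- function(e) {
    # order edges head-to-tail into a loop
    if (nrow(e) == 0) return(e)
    nxt <- e[, 2][order(e[, 1])]
    from <- sort(e[, 1])
    lookup <- integer(max(e)); lookup[from] <- nxt
    out <- matrix(0L, nrow(e), 2)
    cur <- e[1, 1]
    for (k in seq_len(nrow(e))) {
      nx <- lookup[cur]
      out[k, ] <- c(cur, nx)
      cur <- nx
    }
    out
  }
  lumen <- chain(bnd[grp == "lumen", , drop = FALSE])
  hole_loops <- lapply(seq_len(nrow(holes)), function(i)
    chain(bnd[grp == paste0("hole_", i), , drop = FALSE]))
  list(lumen = lumen, holes = hole_loops,
       outer = bnd[grp == "outer", , drop = FALSE])
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("FE mesh: %d nodes, %d triangles (h_coarse %.3g m, h_fine %.3g m)\n",
              nrow(x$nodes), nrow(x$tri), x$h_coarse, x$h_fine))
  print(table(x$region))
  invisible(x)
}

## -- quality and distortion --------------------------------------------------

tri_angles <- function(tri, xy) {
  a2 <- (xy[tri[, 2], 1] - xy[tri[, 3], 1])^2 + (xy[tri[, 2], 2] - xy[tri[, 3], 2])^2
  b2 <- (xy[tri[, 1], 1] - xy[tri[, 3], 1])^2 + (xy[tri[, 1], 2] - xy[tri[, 3], 2])^2
  c2 <- (xy[tri[, 1], 1] - xy[tri[, 2], 1])^2 + (xy[tri[, 1], 2] - xy[tri[, 2], 2])^2
  clamp <- function(z) pmin(1, pmax(-1, z))
  A <- acos(clamp((b2 + c2 - a2) / (2 * sqrt(b2 * c2))))
  B <- acos(clamp((a2 + c2 - b2) / (2 * sqrt(a2 * c2))))
  C <- pi - A - B
  cbind(A, B, C) * 180 / pi
}

#' Mesh quality report
#'
#' Per-element angles and edge lengths aggregated into a quality summary.
#'
#' @param mesh an `fe_mesh`.
#' @return List with `min_angle`, `max_angle` (degrees), `max_edge`,
#'   `min_edge` (m), `max_aspect` (longest/shortest edge per element),
#'   `n_nodes`, `n_elements`, `n_by_region`.
#' @export
mesh_quality <- function(mesh) {
  ang <- tri_angles(mesh$tri, mesh$nodes)
  el <- element_edge_lengths(mesh$tri, mesh$nodes)
  list(min_angle = min(ang), max_angle = max(ang),
       max_edge = max(el), min_edge = min(el),
       max_aspect = max(apply(matrix(el, ncol = 3), 1, max) /
                          apply(matrix(el, ncol = 3), 1, min)),
       n_nodes = nrow(mesh$nodes), n_elements = nrow(mesh$tri),
       n_by_region = table(mesh$region))
}

element_edge_lengths <- function(tri, xy) {
  e1 <- sqrt((xy[tri[, 1], 1] - xy[tri[, 2], 1])^2 +
               (xy[tri[, 1], 2] - xy[tri[, 2], 2])^2)
  e2 <- sqrt((xy[tri[, 2], 1] - xy[tri[, 3], 1])^2 +
               (xy[tri[, 2], 2] - xy[tri[, 3], 2])^2)
  e3 <- sqrt((xy[tri[, 3], 1] - xy[tri[, 1], 1])^2 +
               (xy[tri[, 3], 2] - xy[tri[, 1], 2])^2)
  cbind(e1, e2, e3)
}

#' Detect excessively distorted elements in a displaced configuration
#'
#' Flags elements whose maximum internal angle in the displaced configuration
#' exceeds `angle_limit` (strict inequality) and elements that are inverted
#' (non-positive area), which are reported regardless of angle.
#'
#' @param mesh an `fe_mesh`.
#' @param displacement n x 2 nodal displacement matrix (m).
#' @param angle_limit distortion threshold in degrees.
#' @return Integer vector of distorted element indices (possibly empty).
#' @export
detect_distortion <- function(mesh, displacement, angle_limit = 160) {
  stopifnot(nrow(displacement) == nrow(mesh$nodes))
  xy <- mesh$nodes + displacement
  ang <- tri_angles(mesh$tri, xy)
  a <- tri_signed_areas(mesh$tri, xy)
  which(apply(ang, 1, max) > angle_limit | a <= 0)
}

# Area enclosed by the mesh boundary loops (Green's theorem over all
# boundary edges, material on the left), independent of the element sum.
mesh_boundary_area <- function(mesh) {
  eg <- mesh$edge_groups
  all_e <- rbind(eg$lumen, eg$outer, do.call(rbind, c(eg$holes, list(NULL))))
  x1 <- mesh$nodes[all_e[, 1], 1]; y1 <- mesh$nodes[all_e[, 1], 2]
  x2 <- mesh$nodes[all_e[, 2], 1]; y2 <- mesh$nodes[all_e[, 2], 2]
  sum(x1 * y2 - x2 * y1) / 2
}

## -- export ------------------------------------------------------------------

#' Write a mesh in Gmsh ASCII format (v2.2)
#'
#' Region tags are written as surface physical groups and edge groups
#' (lumen, holes, outer) as line physical groups.
#'
#' @param mesh an `fe_mesh`.
#' @param path output path.
#' @export
write_msh <- function(mesh, path) {
  regions <- sort(unique(mesh$region))
  reg_id <- stats::setNames(seq_along(regions) + 100L, regions)
  eg <- mesh$edge_groups
  lines <- list(lumen = eg$lumen, outer = eg$outer)
  if (length(eg$holes))
    for (i in seq_along(eg$holes)) lines[[paste0("hole_", i)]] <- eg$holes[[i]]
  line_id <- stats::setNames(seq_along(lines), names(lines))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  writeLines("$PhysicalNames", con)
  writeLines(sprintf("%d", length(regions) + length(lines)), con)
  for (nm in names(line_id))
    writeLines(sprintf("1 %d \"%s\"", line_id[[nm]], nm), con)
  for (nm in names(reg_id))
    writeLines(sprintf("2 %d \"%s\"", reg_id[[nm]], nm), con)
  writeLines("$EndPhysicalNames", con)
  writeLines("$Nodes", con)
  writeLines(sprintf("%d", nrow(mesh$nodes)), con)
  writeLines(sprintf("%d %.12e %.12e 0", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines("$EndNodes", con)
  nel <- sum(vapply(lines, nrow, 0L)) + nrow(mesh$tri)
  writeLines("$Elements", con)
  writeLines(sprintf("%d", nel), con)
  k <- 0L
  for (nm in names(lines)) {
    e <- lines[[nm]]
    if (nrow(e)) {
      writeLines(sprintf("%d 1 2 %d %d %d %d", k + seq_len(nrow(e)),
                         line_id[[nm]], line_id[[nm]], e[, 1], e[, 2]), con)
      k <- k + nrow(e)
    }
  }
  ids <- reg_id[mesh$region]
  writeLines(sprintf("%d 2 2 %d %d %d %d %d", k + seq_len(nrow(mesh$tri)),
                     ids, ids, mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3]),
             con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Write a mesh (optionally with fields) in legacy VTK ASCII format
#'
#' @param mesh an `fe_mesh`.
#' @param path output path.
#' @param point_data named list of per-node fields (vectors or n x k
#'   matrices).
#' @param cell_data named list of per-element fields.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "sphincterFE mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(sprintf("%.10e %.10e 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  write_fields <- function(fields, count) {
    for (nm in names(fields)) {
      f <- fields[[nm]]
      if (is.matrix(f) && ncol(f) >= 2) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.10e %.10e %.10e", f[, 1], f[, 2],
                           if (ncol(f) > 2) f[, 3] else rep(0, count)), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.10e", as.numeric(f)), con)
      }
    }
  }
  cd <- c(cell_data, list(region = as.numeric(factor(mesh$region))))
  writeLines(sprintf("CELL_DATA %d", m), con)
  write_fields(cd, m)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    write_fields(point_data, n)
  }
  invisible(path)
}
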