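#' Deformed lumen cross-sectional area
#'
#' Signed shoelace area of the deformed intraluminal boundary polygon,
#' reported in mm^2.  The boundary loop is checked for self-intersection.
#'
#' @param solution an `fe_solution` (or any list with `mesh` and `U`).
#' @param check verify that the deformed boundary is a simple polygon.
#' @return Area in mm^2.
#' @export
lumen_area <- function(solution, check = TRUE) {
  mesh <- solution$mesh
  loop <- mesh$edge_groups$lumen
  if (nrow(loop) == 0) stop("mesh has no lumen boundary loop")
  xy <- mesh$nodes + solution$U
  poly <- xy[loop[, 1], , drop = FALSE]
  if (check && polygon_self_intersects(poly))
    stop("deformed lumen boundary is self-intersecting")
  abs(polygon_area(poly)) * 1e6
}

# Naive O(n^2) segment-crossing test on a closed polyline.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1], 1L)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[nxt, 1]; y2 <- poly[nxt, 2]
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    j <- seq.int(i + 2L, n)
    j <- j[!(i == 1L & j == n)]          # skip shared-endpoint neighbours
    d1 <- cross(x2[i] - x1[i], y2[i] - y1[i], x1[j] - x1[i], y1[j] - y1[i])
    d2 <- cross(x2[i] - x1[i], y2[i] - y1[i], x2[j] - x1[i], y2[j] - y1[i])
    d3 <- cross(x2[j] - x1[j], y2[j] - y1[j], x1[i] - x1[j], y1[i] - y1[j])
    d4 <- cross(x2[j] - x1[j], y2[j] - y1[j], x2[i] - x1[j], y2[i] - y1[j])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Opening loss
#'
#' Relative loss of open cross-sectional area of a (possibly drilled)
#' fibrotic configuration against the sane configuration, normalised by the
#' fibrotic no-hole area: `100 * (A_i - A_P0) / A_H0` (percent; negative for
#' a loss).
#'
#' @param A_i deformed lumen area of the evaluated configuration (mm^2).
#' @param A_P0 deformed lumen area of the sane configuration (mm^2).
#' @param A_H0 deformed lumen area of the fibrotic no-hole configuration
#'   (mm^2).
#' @return Loss in percent.
#' @export
#' @examples
#' opening_loss(12.49, 18.09, 12.49)   # about -44.84
opening_loss <- function(A_i, A_P0, A_H0) {
  stopifnot(A_i > 0, A_P0 > 0)
  if (any(A_H0 == 0)) stop("zero denominator: A_H0 must be non-zero")
  100 * (A_i - A_P0) / A_H0
}

#' Opening deformation recovery
#'
#' Relative gain of open cross-sectional area of a drilled configuration
#' over the fibrotic no-hole configuration: `100 * (A_i - A_H0) / A_H0`
#' (percent).
#'
#' @inheritParams opening_loss
#' @return Recovery in percent.
#' @export
#' @examples
#' opening_recovery(14.44, 12.49)   # about 15.61
opening_recovery <- function(A_i, A_H0) {
  stopifnot(A_i > 0)
  if (any(A_H0 == 0)) stop("zero denominator: A_H0 must be non-zero")
  100 * (A_i - A_H0) / A_H0
}

## -- principal fields --------------------------------------------------------

eig2_sym <- function(xx, yy, xy) {
  ctr <- (xx + yy) / 2
  rad <- sqrt(((xx - yy) / 2)^2 + xy^2)
  list(max = ctr + rad, min = ctr - rad)
}

# Per-element in-plane Cauchy stress components from a solution state.
cauchy_components <- function(state) {
  F11 <- state$F$F11; F12 <- state$F$F12
  F21 <- state$F$F21; F22 <- state$F$F22
  J3 <- state$detF * sqrt(state$c3)
  P11 <- F11 * state$sxx + F12 * state$sxy
  P12 <- F11 * state$sxy + F12 * state$syy
  P21 <- F21 * state$sxx + F22 * state$sxy
  P22 <- F21 * state$sxy + F22 * state$syy
  list(sxx = (P11 * F11 + P12 * F12) / J3,
       syy = (P21 * F21 + P22 * F22) / J3,
       sxy = (P11 * F21 + P12 * F22) / J3)
}

#' Principal Cauchy stress and principal strain fields
#'
#' Eigen-decomposition of the per-element Cauchy stress and of the chosen
#' strain measure (logarithmic/Hencky by default, Green-Lagrange optionally),
#' with global extrema.
#'
#' @param solution an `fe_solution` with a stored `state`.
#' @param measure strain measure for reporting: `"hencky"` (ln of principal
#'   stretch) or `"green"`.
#' @return List with `elements` (data.frame of per-element principal values)
#'   and `extrema` (named list: `smax`, `smin` in Pa; `emax`, `emin`).
#' @export
principal_fields <- function(solution, measure = c("hencky", "green")) {
  measure <- match.arg(measure)
  state <- solution$state
  if (is.null(state)) stop("solution carries no stored state")
  sig <- cauchy_components(state)
  es <- eig2_sym(sig$sxx, sig$syy, sig$sxy)
  # principal squared stretches from in-plane C
  ec <- eig2_sym(state$cxx, state$cyy, state$cxy)
  strain_of <- function(l2)
    if (measure == "hencky") 0.5 * log(l2) else (l2 - 1) / 2
  e1 <- strain_of(ec$max); e2 <- strain_of(ec$min)
  elements <- data.frame(s1 = es$max, s2 = es$min, e1 = e1, e2 = e2)
  list(elements = elements,
       extrema = list(smax = max(es$max), smin = min(es$max),
                      emax = max(e1), emin = min(e1)),
       measure = measure)
}

## -- boundary profiles -------------------------------------------------------

#' Principal-field profile along the deformed intraluminal boundary
#'
#' Samples the per-element maximum principal strain and stress in the
#' elements adjacent to the lumen boundary, ordered clockwise by deformed arc
#' length and split into the physiological (upper, sane) and fibrotic
#' (lower) arcs at the horizontal axis of the reference configuration.
#'
#' @param solution an `fe_solution` with a stored `state`.
#' @param arc `"physiological"`, `"fibrotic"` or `"both"`.
#' @param measure strain measure, as in [principal_fields()].
#' @return data.frame with columns `s` (deformed arc length, m), `e1`,
#'   `s1_Pa`, `arc`.
#' @export
boundary_profile <- function(solution, arc = c("both", "physiological",
                                               "fibrotic"),
                             measure = "hencky") {
  arc <- match.arg(arc)
  mesh <- solution$mesh
  loop <- mesh$edge_groups$lumen
  pf <- principal_fields(solution, measure)$elements
  # adjacent element of each boundary edge
  tri <- mesh$tri
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  all_e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  owner <- rep(seq_len(nrow(tri)), 3L)
  map <- split(owner, ekey(all_e[, 1], all_e[, 2]))
  own <- vapply(ekey(loop[, 1], loop[, 2]),
                function(k) map[[k]][1], 0)
  xy <- mesh$nodes + solution$U
  ctr <- mesh$domain$params$lumen_center
  # reference angle of edge midpoints decides the arc; the loop is chained
  # with material on the left, i.e. clockwise around the lumen
  mid_ref <- (mesh$nodes[loop[, 1], , drop = FALSE] +
                mesh$nodes[loop[, 2], , drop = FALSE]) / 2
  upper <- (mid_ref[, 2] - ctr[2]) > 0
  seg_len <- sqrt(rowSums((xy[loop[, 2], , drop = FALSE] -
                             xy[loop[, 1], , drop = FALSE])^2))
  # start the abscissa at the right-hand interface crossing (reference
  # theta = 0), proceeding in loop order
  thmid <- atan2(mid_ref[, 2] - ctr[2], mid_ref[, 1] - ctr[1])
  start <- which.min(abs(thmid))
  ord <- c(seq(start, nrow(loop)), seq_len(start - 1L))
  s <- cumsum(seg_len[ord]) - seg_len[ord] / 2
  out <- data.frame(s = s, e1 = pf$e1[own[ord]], s1_Pa = pf$s1[own[ord]],
                    arc = ifelse(upper[ord], "physiological", "fibrotic"))
  if (arc != "both") out <- out[out$arc == arc, , drop = FALSE]
  out
}

## -- per-case report ---------------------------------------------------------

#' Metrics report for a set of solved cases
#'
#' Assembles the machine-readable analogue of the study's results table:
#' deformed lumen area per case, opening loss against the sane case,
#' opening recovery against the fibrotic no-hole case, and principal-field
#' extrema.  Loss and recovery are defined only when the bundle contains
#' `P0` and `H0`.
#'
#' @param solutions named list of `fe_solution` objects (names are case ids).
#' @param measure strain measure for the principal-field columns.
#' @return data.frame with one row per case: `case_id`, `A_mm2`,
#'   `delta_l_pct`, `delta_r_pct`, `smax_Pa`, `emax`.
#' @export
metrics_report <- function(solutions, measure = "hencky") {
  ids <- names(solutions)
  A <- vapply(solutions, lumen_area, 0)
  A_P0 <- if ("P0" %in% ids) A[["P0"]] else NA_real_
  A_H0 <- if ("H0" %in% ids) A[["H0"]] else NA_real_
  out <- data.frame(case_id = ids, A_mm2 = round(A, 2), delta_l_pct = NA_real_,
                    delta_r_pct = NA_real_, smax_Pa = NA_real_,
                    emax = NA_real_, row.names = NULL)
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (!is.na(A_P0) && !is.na(A_H0) && id != "P0")
      out$delta_l_pct[i] <- round(opening_loss(A[[id]], A_P0, A_H0), 2)
    if (!is.na(A_H0) && !id %in% c("P0", "H0"))
      out$delta_r_pct[i] <- round(opening_recovery(A[[id]], A_H0), 2)
    if (!is.null(solutions[[i]]$state)) {
      px <- principal_fields(solutions[[i]], measure)$extrema
      out$smax_Pa[i] <- px$smax
      out$emax[i] <- px$emax
    }
  }
  out
}
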