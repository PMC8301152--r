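# One shared default mesh per case id, built lazily (mesh generation is the
# slow step; several tests inspect the same object).
mesh_cache <- new.env()
get_mesh <- function(case_id = "H6", h_coarse = 2e-4, h_fine = 1e-4) {
  key <- paste(case_id, h_coarse, h_fine)
  if (is.null(mesh_cache[[key]])) {
    dom <- build_case(case_id)
    mesh_cache[[key]] <- suppressWarnings(
      generate_mesh(dom, h_coarse = h_coarse, h_fine = h_fine))
  }
  mesh_cache[[key]]
}

test_that("triangulating a unit square conserves area with >= 2 triangles", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  tri <- delaunay_triangulate(sq)
  expect_gte(nrow(tri), 2L)
  expect_equal(sum(sphincterFE:::tri_signed_areas(tri, sq)), 1)
})

test_that("generated mesh honours the size field and region tags", {
  msh <- get_mesh("H6")
  el <- sphincterFE:::element_edge_lengths(msh$tri, msh$nodes)
  expect_lte(max(el), msh$h_coarse)
  epi <- msh$region == "epithelium"
  expect_gt(sum(epi), 0)
  expect_lte(max(el[epi, ]), msh$h_fine)
  expect_true(all(msh$region %in% c("epithelium", "spongy_sane",
                                    "spongy_fibrotic")))
  expect_setequal(unique(msh$region),
                  c("epithelium", "spongy_sane", "spongy_fibrotic"))
})

test_that("element areas, boundary loops and domain area are consistent", {
  msh <- get_mesh("H6")
  sa <- sum(sphincterFE:::tri_signed_areas(msh$tri, msh$nodes))
  # element sum equals the area enclosed by the boundary loops exactly
  ba <- sphincterFE:::mesh_boundary_area(msh)
  expect_lt(abs(sa - ba) / sa, 1e-8)
  # and the analytic body area up to boundary-chord error
  body <- domain_areas(msh$domain)$body
  expect_lt(abs(sa - body) / body, 5e-3)
  # lumen loop is closed and single; one closed loop per hole
  lum <- msh$edge_groups$lumen
  expect_true(all(sort(lum[, 1]) == sort(lum[, 2])))
  expect_length(msh$edge_groups$holes, 6L)
  for (hl in msh$edge_groups$holes) {
    expect_gt(nrow(hl), 10)
    expect_true(all(sort(hl[, 1]) == sort(hl[, 2])))
  }
})

test_that("mesh generation is deterministic and meets its quality target", {
  m1 <- get_mesh("H3")
  m2 <- suppressWarnings(generate_mesh(build_case("H3")))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tri, m2$tri)
  q <- mesh_quality(m1)
  expect_gte(q$min_angle, 20)
  expect_lt(q$max_angle, 180)
})

test_that("quality report reproduces closed-form angles", {
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  ang <- sphincterFE:::tri_angles(matrix(1:3, 1), eq)
  expect_equal(as.numeric(ang), rep(60, 3), tolerance = 1e-10)
  ri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  ang <- sort(as.numeric(sphincterFE:::tri_angles(matrix(1:3, 1), ri)))
  expect_equal(ang, c(45, 45, 90), tolerance = 1e-10)
})

test_that("distortion detection flags collapsing elements, strictly", {
  msh <- get_mesh("H3")
  U0 <- matrix(0, nrow(msh$nodes), 2)
  expect_length(detect_distortion(msh, U0), 0L)
  # collapse one interior triangle towards a line
  el <- 1L
  vid <- msh$tri[el, ]
  v <- msh$nodes[vid, ]
  U <- U0
  # move vertex 3 close to the segment (v1, v2): max angle -> 180 degrees
  target <- (v[1, ] + v[2, ]) / 2 + (v[3, ] - (v[1, ] + v[2, ]) / 2) * 0.02
  U[vid[3], ] <- target - v[3, ]
  flagged <- detect_distortion(msh, U, angle_limit = 160)
  expect_true(el %in% flagged)
  # threshold exactly at the element's max angle: strict inequality
  ang <- sphincterFE:::tri_angles(msh$tri[el, , drop = FALSE],
                                 msh$nodes + U)
  expect_false(el %in% detect_distortion(msh, U, angle_limit = max(ang)))
  # inverted element is flagged regardless of angle
  U2 <- U0
  U2[vid[3], ] <- (v[1, ] + v[2, ]) - v[3, ] # reflect across the edge
  expect_true(el %in% detect_distortion(msh, U2, angle_limit = 179.9))
})

test_that("mesh export writes readable Gmsh and VTK files", {
  msh <- get_mesh("H3")
  f <- tempfile(fileext = ".msh")
  write_msh(msh, f)
  txt <- readLines(f)
  expect_identical(txt[1], "$MeshFormat")
  expect_true(any(grepl("spongy_fibrotic", txt)))
  expect_true(any(grepl("lumen", txt)))
  nn <- as.integer(txt[which(txt == "$Nodes") + 1L])
  expect_identical(nn, nrow(msh$nodes))
  v <- tempfile(fileext = ".vtk")
  write_vtk(msh, v, point_data = list(displacement = matrix(0, nrow(msh$nodes), 2)))
  vtxt <- readLines(v, n = 6)
  expect_identical(vtxt[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("UNSTRUCTURED_GRID", vtxt)))
})

test_that("quadratic elements are explicitly unsupported", {
  dom <- build_case("H0")
  expect_error(generate_mesh(dom, quadratic = TRUE), "3-node")
})
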