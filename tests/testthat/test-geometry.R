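test_that("parameter invariants are enforced with informative errors", {
  expect_error(geometry_params(lumen_radius = -1), "lumen_radius")
  expect_error(geometry_params(epithelium_thickness = 0),
               "epithelium_thickness")
  expect_error(geometry_params(lumen_radius = 5e-3, outer_radius = 5.2e-3),
               "outer_radius")
  expect_error(geometry_params(bound_length = 0), "bound_length")
  p <- geometry_params()
  expect_identical(p$bound_length, 1.0e-3)
})

test_that("the sane domain has five tagged regions and a circular lumen", {
  dom <- build_sphincter_domain(geometry_params(fibrotic_half = FALSE))
  labs <- vapply(dom$regions, `[[`, "", "label")
  expect_length(labs, 5L)
  expect_identical(sum(labs == "epithelium"), 1L)
  expect_identical(sum(labs == "spongy_sane"), 4L)
  expect_identical(nrow(dom$holes), 0L)
  # polygonal lumen area within 0.1% of pi r^2
  a <- domain_areas(dom)
  r <- dom$params$lumen_radius
  expect_lt(abs(a$lumen - pi * r^2) / (pi * r^2), 1e-3)
})

test_that("fibrotic tagging follows the lower half", {
  dom <- build_sphincter_domain(geometry_params(fibrotic_half = TRUE))
  labs <- vapply(dom$regions, `[[`, "", "label")
  expect_identical(sum(labs == "spongy_fibrotic"), 2L)
  # the fibrotic polygons lie in the lower half plane
  for (rg in dom$regions) {
    if (rg$label == "spongy_fibrotic") expect_true(all(rg$poly[, 2] <= 1e-12))
  }
  # classification agrees
  expect_identical(classify_points(dom, cbind(-3.5e-3, -3.5e-3)), "spongy_fibrotic")
  expect_identical(classify_points(dom, cbind(3.5e-3, 3.5e-3)), "spongy_sane")
  expect_identical(classify_points(dom, cbind(0, 0)), "lumen")
})

test_that("the two connecting bounds are exactly one bound_length long", {
  p <- geometry_params()
  dom <- build_sphincter_domain(p)
  g <- sphincterFE:::geom_radii(p)
  # the bound interface runs along y = 0 from the epithelium surface
  # outward; its ends are vertices of the upper-right part polygon
  ur <- dom$regions$spongy_ur$poly
  i0 <- which(abs(ur[, 1] - g$r_e) < 1e-12 & abs(ur[, 2]) < 1e-12)
  i1 <- which(abs(ur[, 1] - g$x_b) < 1e-12 & abs(ur[, 2]) < 1e-12)
  expect_length(i0, 1L); expect_length(i1, 1L)
  len <- abs(ur[i1, 1] - ur[i0, 1])
  expect_lt(abs(len - 1.0e-3), 1e-6)
  # a point inside the bound is material, a point past it is slit
  expect_identical(classify_points(dom, cbind(g$r_e + 5e-4, 0)),
                   "spongy_sane")
  expect_identical(classify_points(dom, cbind(g$x_b + 5e-4, 0)), "slit")
})

test_that("region polygons tile the body to machine precision", {
  for (fib in c(TRUE, FALSE)) {
    dom <- build_sphincter_domain(geometry_params(fibrotic_half = fib))
    a <- domain_areas(dom)
    expect_lt(abs(sum(a$regions) - a$outline) / a$outline, 1e-10)
  }
})

test_that("pin points sit on the outer boundary next to the vertical axis", {
  dom <- build_sphincter_domain(geometry_params())
  pp <- dom$pin_points
  expect_identical(dim(pp), c(2L, 2L))
  expect_gt(pp[1, 2], 0); expect_lt(pp[2, 2], 0)
  th <- atan2(pp[, 2], pp[, 1])
  r <- sqrt(rowSums(pp^2))
  expect_equal(r[1], sphincterFE:::outer_radius_at(dom$params, th[1]),
               tolerance = 1e-12)
  expect_lt(abs(abs(pp[1, 1]) - dom$params$slit_width / 2), 1e-9)
})

test_that("hole placement respects count, arcs and containment", {
  dom <- build_sphincter_domain(geometry_params())
  # count 0 leaves the domain unchanged
  expect_identical(place_holes(dom, hole_spec(0)), dom)
  # aligned holes all on one arc radius
  h6 <- place_holes(dom, hole_spec(6, arrangement = "aligned"))
  expect_identical(nrow(h6$holes), 6L)
  r <- sqrt(h6$holes$x^2 + h6$holes$y^2)
  expect_lt(diff(range(r)), 1e-12)
  expect_true(all(h6$holes$y < 0))
  # staggered holes alternate between two radii
  h6b <- place_holes(dom, hole_spec(6, arrangement = "staggered"))
  rb <- sqrt(h6b$holes$x^2 + h6b$holes$y^2)
  expect_identical(length(unique(round(rb, 9))), 2L)
  expect_true(all(abs(diff(rb)) > 1e-5))   # alternating
  # all hole probes strictly inside the fibrotic region, for all counts
  for (n in 3:7) {
    hn <- place_holes(dom, hole_spec(n))
    expect_identical(nrow(hn$holes), n)
    th <- seq(0, 2 * pi, length.out = 48)
    for (i in seq_len(n)) {
      px <- hn$holes$x[i] + hn$holes$r[i] * cos(th)
      py <- hn$holes$y[i] + hn$holes$r[i] * sin(th)
      expect_true(all(classify_points(hn, cbind(px, py)) ==
                        "spongy_fibrotic"))
    }
    # pairwise disjoint with positive clearance
    if (n > 1) {
      d <- as.matrix(dist(hn$holes[, c("x", "y")])); diag(d) <- Inf
      expect_gt(min(d), 2 * hn$holes$r[1])
    }
  }
  # an impossible request errors with the offending holes listed
  expect_error(place_holes(dom, hole_spec(7, radius = 1.4e-3)),
               "placement error")
})

test_that("hole placement is deterministic", {
  dom <- build_sphincter_domain(geometry_params())
  a <- place_holes(dom, hole_spec(6, arrangement = "staggered"))
  b <- place_holes(dom, hole_spec(6, arrangement = "staggered"))
  expect_identical(a, b)
})

test_that("the case registry maps ids to the study configurations", {
  p0 <- case_registry("P0")
  expect_false(p0$params$fibrotic_half)
  expect_identical(p0$holes$count, 0L)
  h0 <- case_registry("H0")
  expect_true(h0$params$fibrotic_half)
  expect_identical(h0$holes$count, 0L)
  h7 <- case_registry("H7")
  expect_true(h7$params$fibrotic_half)
  expect_identical(h7$holes$count, 7L)
  expect_identical(h7$holes$arrangement, "aligned")
  h6b <- case_registry("H6b")
  expect_identical(h6b$holes$count, 6L)
  expect_identical(h6b$holes$arrangement, "staggered")
  expect_error(case_registry("H9"), "unknown case")
})

test_that("domain serialisation round-trips through YAML and .poly text", {
  dom <- build_case("H3")
  yml <- tempfile(fileext = ".yaml")
  write_domain_yaml(dom, yml)
  obj <- yaml::read_yaml(yml)
  expect_equal(obj$geometry$lumen_radius, dom$params$lumen_radius)
  expect_length(obj$holes, 3L)
  poly <- tempfile(fileext = ".poly")
  write_domain_poly(dom, poly)
  first <- scan(poly, what = integer(), n = 4, quiet = TRUE)
  expect_identical(first[2], 2L)   # dimension marker
  expect_gt(first[1], 100L)        # vertex count
})
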