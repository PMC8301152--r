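# A fake "solution" with a prescribed boundary polygon, for area tests.
polygon_solution <- function(poly, U = NULL) {
  n <- nrow(poly)
  loop <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  mesh <- structure(list(nodes = poly, tri = matrix(c(1L, 2L, 3L), 1),
                         region = "epithelium",
                         edge_groups = list(lumen = loop, holes = list(),
                                            outer = NULL),
                         domain = list(params = list(lumen_center = c(0, 0)))),
                    class = "fe_mesh")
  list(mesh = mesh, U = if (is.null(U)) matrix(0, n, 2) else U)
}

test_that("lumen area reproduces closed forms and is rigid-motion safe", {
  th <- 2 * pi * seq(0, 255) / 256
  circ <- cbind(1e-3 * cos(th), 1e-3 * sin(th))
  expect_equal(lumen_area(polygon_solution(circ)), pi, tolerance = 1e-3)
  sq <- rbind(c(0, 0), c(1e-3, 0), c(1e-3, 1e-3), c(0, 1e-3))
  expect_identical(lumen_area(polygon_solution(sq)), 1)
  # rigid translation leaves the area unchanged to machine precision
  U <- matrix(rep(c(3e-3, -2e-3), each = 4), 4, 2)
  expect_equal(lumen_area(polygon_solution(sq, U)), 1, tolerance = 1e-12)
  # a self-intersecting deformed boundary is rejected
  bow <- rbind(c(0, 0), c(1e-3, 1e-3), c(1e-3, 0), c(0, 1e-3))
  expect_error(lumen_area(polygon_solution(bow)), "self-intersecting")
})

test_that("opening loss and recovery implement the area ratios exactly", {
  # identical areas give zero loss / recovery
  expect_equal(opening_loss(18.09, 18.09, 12.49), 0)
  expect_equal(opening_recovery(12.49, 12.49), 0)
  expect_error(opening_loss(1, 1, 0), "denominator")
  expect_error(opening_recovery(1, 0), "denominator")
  # published-area spot checks (loss normalised by the no-hole area)
  expect_equal(opening_loss(12.49, 18.09, 12.49), -44.84, tolerance = 0.005)
  expect_equal(opening_loss(13.97, 18.09, 12.49), -32.99, tolerance = 0.005)
  expect_equal(opening_recovery(14.44, 12.49), 15.61, tolerance = 0.005)
  expect_equal(opening_recovery(13.27, 12.49), 6.25, tolerance = 0.005)
})

# Synthetic per-element state for principal-field tests.
state_solution <- function(F11, F12, F21, F22, sxx, syy, sxy, c3 = 1) {
  list(state = list(
    F = list(F11 = F11, F12 = F12, F21 = F21, F22 = F22),
    c3 = c3, sxx = sxx, syy = syy, sxy = sxy,
    cxx = F11^2 + F21^2, cyy = F12^2 + F22^2,
    cxy = F11 * F12 + F21 * F22,
    detF = F11 * F22 - F12 * F21))
}

test_that("principal fields reproduce closed-form eigenstates", {
  # hydrostatic in-plane PK2 at F = I: both principal Cauchy stresses = a
  a <- 123.4
  sol <- state_solution(1, 0, 0, 1, a, a, 0)
  pf <- principal_fields(sol)
  expect_equal(pf$elements$s1, a)
  expect_equal(pf$elements$s2, a)
  # pure shear: principal stresses +tau and -tau
  tau <- 55
  sol <- state_solution(1, 0, 0, 1, 0, 0, tau)
  pf <- principal_fields(sol)
  expect_equal(pf$elements$s1, tau)
  expect_equal(pf$elements$s2, -tau)
  # uniaxial stretch with the Hencky measure: e1 = ln(lambda)
  lam <- 1.31
  sol <- state_solution(lam, 0, 0, 1, 0, 0, 0)
  expect_equal(principal_fields(sol, "hencky")$elements$e1, log(lam))
  expect_equal(principal_fields(sol, "green")$elements$e1, (lam^2 - 1) / 2)
})

test_that("boundary profile partitions the deformed lumen perimeter", {
  mesh <- annulus_mesh(1e-3, 2e-3, 4e-4)
  fixed <- annulus_symmetric_dofs(mesh)
  model <- sphincterFE:::fe_model(mesh, fixed_dofs = fixed)
  res <- sphincterFE:::solve_increments(model, 30,
                                        settings = solver_settings())
  out <- sphincterFE:::assemble(model, res$U, 30, res$c3)
  sol <- structure(list(mesh = mesh, U = res$U, state = out$state,
                        case_id = "annulus"), class = "fe_solution")
  prof <- boundary_profile(sol, "both")
  expect_true(all(diff(prof$s) > 0))
  # total abscissa span matches the deformed perimeter
  loop <- mesh$edge_groups$lumen
  xy <- mesh$nodes + res$U
  per <- sum(sqrt(rowSums((xy[loop[, 2], ] - xy[loop[, 1], ])^2)))
  expect_lt(abs(max(prof$s) + diff(prof$s)[1] / 2 - per) / per, 1e-2)
  expect_setequal(unique(prof$arc), c("physiological", "fibrotic"))
  # axisymmetric state: near-constant profile along the boundary
  expect_lt(diff(range(prof$s1_Pa)) / max(abs(prof$s1_Pa)), 0.05)
  expect_lt(diff(range(prof$e1)), 0.05 * max(abs(prof$e1)))
})

test_that("metrics report assembles the per-case table", {
  sq <- function(side) {
    s <- side * 1e-3
    rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  }
  sols <- list(P0 = polygon_solution(sq(sqrt(18.09))),
               H0 = polygon_solution(sq(sqrt(12.49))),
               H6b = polygon_solution(sq(sqrt(14.44))))
  rep <- metrics_report(sols)
  expect_identical(rep$case_id, c("P0", "H0", "H6b"))
  expect_equal(rep$A_mm2, c(18.09, 12.49, 14.44), tolerance = 1e-6)
  expect_true(is.na(rep$delta_l_pct[1]))
  expect_equal(rep$delta_l_pct[2], -44.83, tolerance = 0.02)
  expect_true(is.na(rep$delta_r_pct[2]))
  expect_equal(rep$delta_r_pct[3], 15.61, tolerance = 0.02)
})
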