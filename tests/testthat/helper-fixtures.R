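# Structured annulus fixture shared by solver and metrics tests: a spongy
# ring with its inner circle as the pressurised lumen loop and axis-aligned
# symmetry constraints available for axisymmetric benchmarks.
annulus_mesh <- function(r0 = 1e-3, r1 = 3e-3, h = 1.5e-4,
                         region = "spongy_sane") {
  sphincterFE:::annulus_fixture_mesh(r0, r1, h, region)
}

# Rigid-mode-free symmetric constraints for the annulus (ux = 0 on the
# y axis, uy = 0 on the x axis), compatible with an axisymmetric field.
annulus_symmetric_dofs <- function(mesh) {
  onx <- which(abs(mesh$nodes[, 2]) < 1e-9)
  ony <- which(abs(mesh$nodes[, 1]) < 1e-9)
  sort(c(2L * onx, 2L * ony - 1L))
}

# Single-element mesh with an imposed homogeneous deformation gradient.
single_element_mesh <- function() {
  X <- rbind(c(0, 0), c(2e-3, 0), c(0, 2e-3))
  structure(list(
    nodes = X, tri = matrix(c(1L, 2L, 3L), 1),
    region = "spongy_sane",
    edge_groups = list(lumen = cbind(c(1L, 2L, 3L), c(2L, 3L, 1L)),
                       holes = list(), outer = NULL),
    h_coarse = 2e-3, h_fine = 2e-3, pin_nodes = c(1L, 2L),
    domain = list(params = list(lumen_center = c(0, 0)))),
    class = "fe_mesh")
}

# Independent scalar evaluation of the isochoric 5-parameter energy,
# written directly from the invariant definitions (oracle path).
w_direct <- function(m, cxx, cyy, cxy, c3) {
  t2 <- cxx + cyy; d2 <- cxx * cyy - cxy^2
  J <- sqrt(d2 * c3)
  I1 <- (t2 + c3) * J^(-2 / 3); I2 <- (d2 + c3 * t2) * J^(-4 / 3)
  m$C10 * (I1 - 3) + m$C01 * (I2 - 3) + m$C20 * (I1 - 3)^2 +
    m$C02 * (I2 - 3)^2 + m$C11 * (I1 - 3) * (I2 - 3) + (1 / m$d1) * (J - 1)^2
}

# Richardson-extrapolated central difference (O(h^4)); the volumetric
# penalty makes plain central differences too coarse for 1e-8 checks.
fd_rich <- function(f, x, h = 1e-6) {
  d1 <- (f(x + h) - f(x - h)) / (2 * h)
  d2 <- (f(x + h / 2) - f(x - h / 2)) / h
  (4 * d2 - d1) / 3
}

# Independent plane-stress PK2 stress of the spongy material at in-plane C,
# via scalar energy minimisation over the thickness stretch plus
# extrapolated finite differences.
oracle_plane_stress_S <- function(mat, Cm) {
  c3 <- optimize(function(l3) w_direct(mat, Cm[1, 1], Cm[2, 2], Cm[1, 2],
                                       l3^2), c(0.3, 3), tol = 1e-12)$minimum^2
  g3 <- function(z) fd_rich(function(c3v) w_direct(mat, Cm[1, 1], Cm[2, 2],
                                                   Cm[1, 2], c3v), z)
  c3 <- uniroot(g3, c(0.9 * c3, 1.1 * c3), tol = 1e-14)$root
  dW <- function(k) {
    f <- function(z) {
      cc <- c(Cm[1, 1], Cm[2, 2], Cm[1, 2]); cc[k] <- z
      w_direct(mat, cc[1], cc[2], cc[3], c3)
    }
    fd_rich(f, c(Cm[1, 1], Cm[2, 2], Cm[1, 2])[k])
  }
  matrix(c(2 * dW(1), dW(3), dW(3), 2 * dW(2)), 2, 2)
}
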