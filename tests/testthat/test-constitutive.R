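tab <- material_table()

test_that("reference state has zero energy and zero stress for all presets", {
  st <- deformation_state(diag(2), 1)
  for (m in tab) {
    expect_equal(strain_energy(m, st), 0, tolerance = 1e-14)
    s <- pk2_stress(m, st)
    expect_lt(max(abs(s$S)), 1e-12)
    expect_lt(abs(s$S33), 1e-12)
    expect_lt(max(abs(s$cauchy)), 1e-12)
  }
})

test_that("invariants follow the plane-stress kinematics", {
  expect_equal(unname(invariants_of(diag(2), 1)), c(3, 3, 1))
  # isochoric in-plane stretch keeps J = 1 exactly
  lam <- 1.37
  inv <- invariants_of(diag(c(lam, 1 / lam)), 1)
  expect_equal(unname(inv[["J"]]), 1)
  # hand evaluation at F = diag(1.2, 1), lambda3 = 1: C = diag(1.44, 1)
  inv <- invariants_of(diag(c(1.2, 1)), 1)
  expect_equal(unname(inv[["I1"]]), 1.44 + 1 + 1)
  expect_equal(unname(inv[["I2"]]), 1.44 * 1 + 1.44 * 1 + 1 * 1)
  expect_equal(unname(inv[["J"]]), 1.2)
  expect_error(invariants_of(diag(c(-1, 1)), 1), "inverted")
})

test_that("energy matches direct substitution of the printed constants", {
  # spongy preset at I1 = I2 = 3.1, J = 1
  w <- strain_energy(tab$spongy, list(I1 = 3.1, I2 = 3.1, J = 1))
  expect_equal(w, 0.1 * 89.12 + 0.1 * 82.60 + 0.01 * 2064.50 +
                 0.01 * 2953.61 + 0.01 * (-4737.35), tolerance = 1e-12)
  expect_equal(w, 19.98, tolerance = 1e-3)
})

test_that("fibrotic preset is a tenfold deviatoric scaling of spongy", {
  for (f in c("C10", "C01", "C20", "C02", "C11")) {
    ratio <- tab$fibrotic[[f]] / tab$spongy[[f]]
    expect_equal(ratio, 10, tolerance = 5e-4)   # 4 significant digits
  }
  expect_identical(tab$fibrotic$d1, tab$spongy$d1)
  expect_identical(tab$dense_connective$d1, 8.00e-7)
  # at identical invariants and J = 1 the energies scale by the same factor
  st <- list(I1 = 3.2, I2 = 3.15, J = 1)
  expect_equal(strain_energy(tab$fibrotic, st) /
                 strain_energy(tab$spongy, st), 10, tolerance = 5e-4)
})

test_that("analytic stress matches a finite-difference energy oracle", {
  set.seed(42)
  for (rep in 1:5) {
    F <- diag(2) + matrix(rnorm(4, sd = 0.08), 2, 2)
    if (det(F) < 0.5) next
    l3 <- runif(1, 0.85, 1.15)
    st <- deformation_state(F, l3)
    S <- pk2_stress(tab$spongy, st)$S
    C <- st$C
    h <- 1e-7
    fd <- vapply(1:3, function(k) {
      dc <- c(0, 0, 0); dc[k] <- h
      (w_direct(tab$spongy, C[1, 1] + dc[1], C[2, 2] + dc[2],
                C[1, 2] + dc[3], l3^2) -
         w_direct(tab$spongy, C[1, 1] - dc[1], C[2, 2] - dc[2],
                  C[1, 2] - dc[3], l3^2)) / (2 * h)
    }, 0)
    err <- max(abs(c(2 * fd[1] - S[1, 1], 2 * fd[2] - S[2, 2],
                     fd[3] - S[1, 2]))) / max(abs(S))
    expect_lt(err, 1e-6)
    expect_equal(S[1, 2], S[2, 1])   # symmetry
  }
})

test_that("analytic tangent matches a finite-difference stress oracle", {
  set.seed(7)
  sc <- function(m, cv, c3) {
    ed <- sphincterFE:::mr_energy_derivs(m, cv[1], cv[2], cv[3], c3,
                                         hessian = FALSE)
    sv <- sphincterFE:::mr_stress_vec(ed)
    c(sv$sxx, sv$syy, sv$sxy)
  }
  for (m in tab) {
    F <- diag(2) + matrix(rnorm(4, sd = 0.05), 2, 2)
    l3 <- runif(1, 0.9, 1.1)
    st <- deformation_state(F, l3)
    D <- material_tangent(m, st, condensed = FALSE)
    expect_lt(max(abs(D - t(D))), 1e-12 * max(abs(D)))   # major symmetry
    C <- st$C
    cv0 <- c(C[1, 1], C[2, 2], C[1, 2])
    h <- 1e-8; dC <- c(2, 2, 1)
    Dfd <- matrix(0, 3, 3)
    for (j in 1:3) {
      e <- c(0, 0, 0); e[j] <- h
      Dfd[, j] <- (sc(m, cv0 + dC[j] * e, l3^2) -
                     sc(m, cv0 - dC[j] * e, l3^2)) / (2 * h)
    }
    expect_lt(max(abs(D - Dfd)) / max(abs(D)), 1e-5)
  }
})

test_that("small-strain in-plane stiffness is consistent with mu0", {
  # plane-stress condensed tangent at identity: D[3,3] (shear) equals mu0
  st <- deformation_state(diag(2), 1)
  for (m in tab) {
    D <- material_tangent(m, st, condensed = TRUE)
    expect_equal(D[3, 3], m$mu0, tolerance = 1e-9)
  }
  expect_equal(tab$spongy$mu0, 343.44, tolerance = 1e-12)
})

test_that("plane-stress stretch solves S33 = 0", {
  expect_equal(plane_stress_stretch(tab$spongy, diag(2)), 1, tolerance = 1e-9)
  # near-incompressibility: equibiaxial stretch gives lambda3 close to 1/lam^2
  lam <- 1.1
  l3 <- plane_stress_stretch(tab$spongy, diag(c(lam^2, lam^2)))
  expect_equal(l3, 1 / lam^2, tolerance = 1e-2)
  # uniaxial in-plane stretch against a brute-force 1D minimisation of W
  Cu <- diag(c(1.44, 1))
  l3 <- plane_stress_stretch(tab$spongy, Cu)
  opt <- optimize(function(z) w_direct(tab$spongy, 1.44, 1, 0, z^2),
                  c(0.3, 3), tol = 1e-12)$minimum
  expect_equal(l3, opt, tolerance = 1e-8)
  # the returned stretch satisfies |S33| <= 1e-8 mu0
  st <- deformation_state(diag(c(1.2, 1 / 1.1)), 1)
  C <- st$C
  l3b <- plane_stress_stretch(tab$spongy, C)
  s33 <- pk2_stress(tab$spongy, deformation_state(diag(c(1.2, 1 / 1.1)),
                                                  l3b))$S33
  expect_lt(abs(s33), 1e-8 * tab$spongy$mu0)
})

test_that("energy is objective and locally stable around the reference", {
  set.seed(5)
  for (rep in 1:5) {
    F <- diag(2) + matrix(rnorm(4, sd = 0.1), 2, 2)
    if (det(F) < 0.5) next
    th <- runif(1, 0, 2 * pi)
    Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    w1 <- strain_energy(tab$spongy, deformation_state(F, 1.02))
    w2 <- strain_energy(tab$spongy, deformation_state(Q %*% F, 1.02))
    expect_equal(w1, w2, tolerance = 1e-12)
  }
  # W >= 0 on a sampled neighbourhood of the identity for all presets
  lams <- seq(0.7, 1.4, by = 0.1)
  for (m in tab) {
    for (l1 in lams) for (l2 in lams) {
      C <- diag(c(l1^2, l2^2))
      l3 <- plane_stress_stretch(m, C)
      w <- strain_energy(m, deformation_state(diag(c(l1, l2)), l3))
      expect_gte(w, -1e-10 * m$mu0)
    }
  }
})

test_that("total-invariant variant differs only away from J = 1", {
  mt <- mooney_rivlin5(89.12, 82.60, 2064.50, 2953.61, -4737.35, 8e-7,
                       form = "total")
  st <- list(I1 = 3.1, I2 = 3.1, J = 1)
  expect_equal(strain_energy(mt, st), strain_energy(tab$spongy, st))
  # the literal total-invariant form carries residual stress at the identity
  s <- pk2_stress(mt, deformation_state(diag(2), 1))
  expect_gt(max(abs(s$S)), 1)
})
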