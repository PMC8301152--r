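#' Five-parameter Mooney-Rivlin material
#'
#' Constructs a hyperelastic material with strain-energy density
#' \deqn{W = C_{10}(\bar I_1-3) + C_{01}(\bar I_2-3) + C_{20}(\bar I_1-3)^2 +
#'       C_{02}(\bar I_2-3)^2 + C_{11}(\bar I_1-3)(\bar I_2-3) +
#'       \frac{1}{d_1}(J-1)^2,}
#' where \eqn{\bar I_1 = J^{-2/3} I_1} and \eqn{\bar I_2 = J^{-4/3} I_2} are
#' the isochoric invariants of the right Cauchy-Green tensor and \eqn{J} the
#' volume ratio.  The last term is a volumetric penalty with compliance
#' coefficient \eqn{d_1} (units 1/Pa), giving an initial bulk modulus
#' \eqn{2/d_1}.  The isochoric form (the default) is stress-free at the
#' reference state; `form = "total"` evaluates the deviatoric polynomial on
#' the total invariants \eqn{I_1, I_2} instead, which is the same expression
#' only at \eqn{J = 1} and carries a residual hydrostatic stress at the
#' reference state.  It is provided for sensitivity checks only.
#'
#' @param C10,C01,C20,C02,C11 polynomial coefficients in Pa.
#' @param d1 volumetric compliance in 1/Pa; must be positive.
#' @param form `"isochoric"` (default) or `"total"`; see Details.
#' @param name optional label carried into reports.
#' @return An object of class `mooney_rivlin5` with the coefficients and the
#'   derived initial shear modulus `mu0 = 2*(C10 + C01)` and bulk modulus
#'   `kappa0 = 2/d1`.
#' @export
#' @examples
#' mat <- mooney_rivlin5(89.12, 82.60, 2064.50, 2953.61, -4737.35, 8e-7)
#' mat$mu0   # 343.44 Pa
mooney_rivlin5 <- function(C10, C01, C20, C02, C11, d1,
                           form = c("isochoric", "total"), name = "custom") {
  form <- match.arg(form)
  stopifnot(is.numeric(d1), length(d1) == 1L)
  if (d1 <= 0) stop("d1 must be positive (volumetric compliance, 1/Pa)")
  mu0 <- 2 * (C10 + C01)
  if (mu0 <= 0) stop("initial shear modulus mu0 = 2*(C10 + C01) must be positive")
  structure(
    list(C10 = C10, C01 = C01, C20 = C20, C02 = C02, C11 = C11, d1 = d1,
         mu0 = mu0, kappa0 = 2 / d1, form = form, name = name),
    class = "mooney_rivlin5")
}

#' @export
print.mooney_rivlin5 <- function(x, ...) {
  cat(sprintf("Mooney-Rivlin (5 par., %s) '%s'\n", x$form, x$name))
  cat(sprintf("  C10 = %.6g Pa, C01 = %.6g Pa, C20 = %.6g Pa, C02 = %.6g Pa, C11 = %.6g Pa\n",
              x$C10, x$C01, x$C20, x$C02, x$C11))
  cat(sprintf("  d1 = %.3g 1/Pa  (mu0 = %.4g Pa, kappa0 = %.4g Pa)\n",
              x$d1, x$mu0, x$kappa0))
  invisible(x)
}

#' Tissue material presets
#'
#' The three constitutive presets used by the sphincter model: the dense
#' connective tissue of the transitional epithelium, the sane spongy stratum
#' (lamina propria), and its fibrotic counterpart.  Fibrosis is represented by
#' a tenfold scaling of the deviatoric coefficients of the spongy tissue at
#' identical volumetric compliance.
#'
#' @param form constitutive form passed to [mooney_rivlin5()].
#' @return Named list of [mooney_rivlin5()] objects with elements
#'   `dense_connective`, `spongy` and `fibrotic`.
#' @export
#' @examples
#' tab <- material_table()
#' tab$fibrotic$C10 / tab$spongy$C10   # 10
material_table <- function(form = c("isochoric", "total")) {
  form <- match.arg(form)
  list(
    dense_connective = mooney_rivlin5(
      C10 = 3030.83, C01 = 2142.94, C20 = 59059.00, C02 = 82911.00,
      C11 = -1.431e5, d1 = 8.00e-7, form = form, name = "dense_connective"),
    spongy = mooney_rivlin5(
      C10 = 89.12, C01 = 82.60, C20 = 2064.50, C02 = 2953.61,
      C11 = -4737.35, d1 = 8.00e-7, form = form, name = "spongy"),
    fibrotic = mooney_rivlin5(
      C10 = 891.18, C01 = 825.97, C20 = 20645.00, C02 = 29536.10,
      C11 = -47373.50, d1 = 8.00e-7, form = form, name = "fibrotic"))
}

#' Deformation state for plane-stress kinematics
#'
#' Bundles an in-plane deformation gradient with the through-thickness stretch
#' and caches the right Cauchy-Green tensor and its invariants.
#'
#' @param F 2x2 in-plane deformation gradient (dimensionless).
#' @param lambda3 through-thickness stretch, positive.
#' @return Object of class `deformation_state` with fields `F`, `lambda3`,
#'   `C` (2x2), `I1`, `I2`, `J`.
#' @export
deformation_state <- function(F, lambda3 = 1) {
  F <- matrix(as.numeric(F), 2, 2)
  if (det(F) * lambda3 <= 0)
    stop("inverted state: det(F) * lambda3 must be positive")
  C <- crossprod(F)            # F^T F
  inv <- invariants_of(F, lambda3)
  structure(list(F = F, lambda3 = lambda3, C = C,
                 I1 = inv[["I1"]], I2 = inv[["I2"]], J = inv[["J"]]),
            class = "deformation_state")
}

#' Invariants of the right Cauchy-Green tensor under plane-stress kinematics
#'
#' For a 2x2 in-plane deformation gradient `F` and out-of-plane stretch
#' `lambda3`, the three-dimensional deformation gradient is
#' `blockdiag(F, lambda3)`; the function returns the first and second
#' invariants of `C = F^T F` (3D) and the volume ratio `J`.
#'
#' @inheritParams deformation_state
#' @return Named numeric vector `c(I1, I2, J)`.
#' @export
#' @examples
#' invariants_of(diag(2), 1)          # (3, 3, 1)
invariants_of <- function(F, lambda3 = 1) {
  F <- matrix(as.numeric(F), 2, 2)
  detF <- F[1, 1] * F[2, 2] - F[1, 2] * F[2, 1]
  if (detF * lambda3 <= 0)
    stop("inverted state: det(F) * lambda3 must be positive")
  C <- crossprod(F)
  tr2 <- C[1, 1] + C[2, 2]
  det2 <- C[1, 1] * C[2, 2] - C[1, 2]^2
  c3 <- lambda3^2
  c(I1 = tr2 + c3, I2 = det2 + c3 * tr2, J = detF * lambda3)
}

#' Strain-energy density
#'
#' Evaluates the five-parameter Mooney-Rivlin energy at a deformation state.
#'
#' @param mat a [mooney_rivlin5()] material.
#' @param state a [deformation_state()], or any list with fields `I1`, `I2`,
#'   `J` (total invariants and volume ratio).
#' @return Energy density in Pa (J/m^3).
#' @export
strain_energy <- function(mat, state) {
  stopifnot(inherits(mat, "mooney_rivlin5"))
  J <- state$J
  if (identical(mat$form, "isochoric")) {
    m1 <- J^(-2 / 3) * state$I1
    m2 <- J^(-4 / 3) * state$I2
  } else {
    m1 <- state$I1
    m2 <- state$I2
  }
  i1 <- m1 - 3; i2 <- m2 - 3
  mat$C10 * i1 + mat$C01 * i2 + mat$C20 * i1^2 + mat$C02 * i2^2 +
    mat$C11 * i1 * i2 + (1 / mat$d1) * (J - 1)^2
}

## ---------------------------------------------------------------------------
## Vectorised kernel.
##
## All functions below operate on parallel vectors of the in-plane right
## Cauchy-Green components and the squared through-thickness stretch,
## q = (cxx, cyy, cxy, c3), one entry per quadrature point.  The energy is
## psi(q); the PK2 stress components are S = (2,2,1,2) * grad psi (the factor
## 1 on the shear slot because cxy parametrises both off-diagonal entries of
## C), and tangents follow from the Hessian of psi.  Gradients are lists of 4
## vectors, Hessians 4x4 lists of vectors.
## ---------------------------------------------------------------------------

# Gradients and Hessians of the invariant building blocks I1, I2, J wrt q.
mr_blocks <- function(cxx, cyy, cxy, c3) {
  t2 <- cxx + cyy
  d2 <- cxx * cyy - cxy^2
  if (any(d2 <= 0) || any(c3 <= 0)) stop("inverted state in constitutive update")
  J <- sqrt(d2 * c3)
  I1 <- t2 + c3
  I2 <- d2 + c3 * t2
  z <- rep(0, length(cxx))
  gI1 <- list(1, 1, 0, 1)
  gI2 <- list(cyy + c3, cxx + c3, -2 * cxy, t2)
  gP <- list(c3 * cyy, c3 * cxx, -2 * c3 * cxy, d2)     # P = d2 * c3 = J^2
  gJ <- lapply(gP, function(v) v / (2 * J))
  H0 <- function() lapply(1:4, function(i) lapply(1:4, function(j) 0))
  HI2 <- H0()
  HI2[[1]][[2]] <- HI2[[2]][[1]] <- 1
  HI2[[3]][[3]] <- -2
  HI2[[1]][[4]] <- HI2[[4]][[1]] <- 1
  HI2[[2]][[4]] <- HI2[[4]][[2]] <- 1
  HP <- H0()
  HP[[1]][[2]] <- HP[[2]][[1]] <- c3
  HP[[3]][[3]] <- -2 * c3
  HP[[1]][[4]] <- HP[[4]][[1]] <- cyy
  HP[[2]][[4]] <- HP[[4]][[2]] <- cxx
  HP[[3]][[4]] <- HP[[4]][[3]] <- -2 * cxy
  # H(J) = H(P)/(2J) - gP (x) gP / (4 J^3)
  HJ <- lapply(1:4, function(i) lapply(1:4, function(j)
    HP[[i]][[j]] / (2 * J) - gP[[i]] * gP[[j]] / (4 * J^3)))
  list(t2 = t2, d2 = d2, J = J, I1 = I1, I2 = I2,
       gI1 = gI1, gI2 = gI2, gJ = gJ, HI2 = HI2, HJ = HJ, zero = z)
}

# Energy derivatives of the deviatoric polynomial in its two arguments.
mr_poly_derivs <- function(mat, m1, m2) {
  i1 <- m1 - 3; i2 <- m2 - 3
  list(W1 = mat$C10 + 2 * mat$C20 * i1 + mat$C11 * i2,
       W2 = mat$C01 + 2 * mat$C02 * i2 + mat$C11 * i1,
       W11 = 2 * mat$C20, W22 = 2 * mat$C02, W12 = mat$C11)
}

# Full gradient (and optionally Hessian) of psi wrt q.
mr_energy_derivs <- function(mat, cxx, cyy, cxy, c3, hessian = TRUE) {
  b <- mr_blocks(cxx, cyy, cxy, c3)
  J <- b$J
  iso <- identical(mat$form, "isochoric")
  if (iso) {
    f1 <- J^(-2 / 3); f2 <- J^(-4 / 3)
    m1 <- f1 * b$I1; m2 <- f2 * b$I2
    gm1 <- lapply(1:4, function(i) f1 * b$gI1[[i]] - (2 / 3) * J^(-5 / 3) * b$I1 * b$gJ[[i]])
    gm2 <- lapply(1:4, function(i) f2 * b$gI2[[i]] - (4 / 3) * J^(-7 / 3) * b$I2 * b$gJ[[i]])
  } else {
    m1 <- b$I1; m2 <- b$I2
    gm1 <- b$gI1; gm2 <- b$gI2
  }
  pd <- mr_poly_derivs(mat, m1, m2)
  WJ <- (2 / mat$d1) * (J - 1)
  WJJ <- 2 / mat$d1
  g <- lapply(1:4, function(i)
    pd$W1 * gm1[[i]] + pd$W2 * gm2[[i]] + WJ * b$gJ[[i]])
  out <- list(g = g, blocks = b, m1 = m1, m2 = m2, pd = pd, WJ = WJ)
  if (!hessian) return(out)
  if (iso) {
    Hm1 <- lapply(1:4, function(i) lapply(1:4, function(j)
      -(2 / 3) * J^(-5 / 3) * (b$gI1[[i]] * b$gJ[[j]] + b$gJ[[i]] * b$gI1[[j]]) +
        (10 / 9) * J^(-8 / 3) * b$I1 * b$gJ[[i]] * b$gJ[[j]] -
        (2 / 3) * J^(-5 / 3) * b$I1 * b$HJ[[i]][[j]]))
    Hm2 <- lapply(1:4, function(i) lapply(1:4, function(j)
      f2 * b$HI2[[i]][[j]] -
        (4 / 3) * J^(-7 / 3) * (b$gI2[[i]] * b$gJ[[j]] + b$gJ[[i]] * b$gI2[[j]]) +
        (28 / 9) * J^(-10 / 3) * b$I2 * b$gJ[[i]] * b$gJ[[j]] -
        (4 / 3) * J^(-7 / 3) * b$I2 * b$HJ[[i]][[j]]))
  } else {
    Hm1 <- lapply(1:4, function(i) lapply(1:4, function(j) 0))
    Hm2 <- b$HI2
  }
  H <- lapply(1:4, function(i) lapply(1:4, function(j)
    pd$W11 * gm1[[i]] * gm1[[j]] + pd$W22 * gm2[[i]] * gm2[[j]] +
      pd$W12 * (gm1[[i]] * gm2[[j]] + gm2[[i]] * gm1[[j]]) +
      WJJ * b$gJ[[i]] * b$gJ[[j]] +
      pd$W1 * Hm1[[i]][[j]] + pd$W2 * Hm2[[i]][[j]] + WJ * b$HJ[[i]][[j]]))
  out$H <- H
  out
}

# PK2 stress components from the energy gradient: (sxx, syy, sxy, s33).
mr_stress_vec <- function(ed) {
  list(sxx = 2 * ed$g[[1]], syy = 2 * ed$g[[2]],
       sxy = ed$g[[3]], s33 = 2 * ed$g[[4]])
}

# S33 and dS33/dc3 only (cheap path for the through-thickness Newton;
# avoids building the full Hessian each iteration).
mr_s33_pair <- function(mat, cxx, cyy, cxy, c3) {
  t2 <- cxx + cyy
  d2 <- cxx * cyy - cxy^2
  if (any(d2 <= 0) || any(c3 <= 0)) stop("inverted state in constitutive update")
  J <- sqrt(d2 * c3)
  I1 <- t2 + c3; I2 <- d2 + c3 * t2
  gJ4 <- d2 / (2 * J)
  HJ44 <- -d2^2 / (4 * J^3)
  iso <- identical(mat$form, "isochoric")
  if (iso) {
    f1 <- J^(-2 / 3); f2 <- J^(-4 / 3)
    m1 <- f1 * I1; m2 <- f2 * I2
    gm1 <- f1 - (2 / 3) * J^(-5 / 3) * I1 * gJ4
    gm2 <- f2 * t2 - (4 / 3) * J^(-7 / 3) * I2 * gJ4
    Hm1 <- -(4 / 3) * J^(-5 / 3) * gJ4 +
      (10 / 9) * J^(-8 / 3) * I1 * gJ4^2 - (2 / 3) * J^(-5 / 3) * I1 * HJ44
    Hm2 <- -(8 / 3) * J^(-7 / 3) * t2 * gJ4 +
      (28 / 9) * J^(-10 / 3) * I2 * gJ4^2 - (4 / 3) * J^(-7 / 3) * I2 * HJ44
  } else {
    m1 <- I1; m2 <- I2
    gm1 <- 1; gm2 <- t2
    Hm1 <- 0; Hm2 <- 0
  }
  pd <- mr_poly_derivs(mat, m1, m2)
  WJ <- (2 / mat$d1) * (J - 1); WJJ <- 2 / mat$d1
  g <- 2 * (pd$W1 * gm1 + pd$W2 * gm2 + WJ * gJ4)
  dg <- 2 * (pd$W11 * gm1^2 + pd$W22 * gm2^2 + 2 * pd$W12 * gm1 * gm2 +
               WJJ * gJ4^2 + pd$W1 * Hm1 + pd$W2 * Hm2 + WJ * HJ44)
  list(g = g, dg = dg)
}

# Solve S33(c3) = 0 for c3 given in-plane C components (vectorised guarded
# Newton with bisection fallback).  Residual tolerance relative to mu0.
mr_solve_c3 <- function(mat, cxx, cyy, cxy, c3 = NULL,
                        tol = 1e-10, maxit = 80L) {
  n <- length(cxx)
  if (is.null(c3)) c3 <- rep(1, n)
  lo <- rep(0.05^2, n); hi <- rep(20^2, n)
  c3 <- pmin(pmax(c3, 1.01 * lo), 0.99 * hi)
  scale <- mat$mu0
  for (it in seq_len(maxit)) {
    pr <- mr_s33_pair(mat, cxx, cyy, cxy, c3)
    g <- pr$g
    if (all(abs(g) <= tol * scale)) break
    # S33 is increasing in c3 in the admissible range (volumetric penalty
    # dominates): g < 0 puts the root above c3, g > 0 below
    lo <- ifelse(g < 0, pmax(lo, c3), lo)
    hi <- ifelse(g > 0, pmin(hi, c3), hi)
    cand <- c3 - g / pr$dg
    bad <- !is.finite(cand) | cand <= lo | cand >= hi
    cand[bad] <- (lo[bad] + hi[bad]) / 2
    c3 <- cand
  }
  if (any(abs(mr_s33_pair(mat, cxx, cyy, cxy, c3)$g) > 1e-8 * scale))
    stop("plane-stress condition not satisfied: no through-thickness root for lambda3 in (0.05, 20)")
  c3
}

# In-plane stress and plane-stress condensed tangent for a batch of states
# with c3 already solved.  Returns stresses (sxx, syy, sxy), the 3x3
# condensed dS/dc entries M[[i]][[j]], and the energy per point.
mr_point_update <- function(mat, cxx, cyy, cxy, c3) {
  ed <- mr_energy_derivs(mat, cxx, cyy, cxy, c3, hessian = TRUE)
  sv <- mr_stress_vec(ed)
  fac <- c(2, 2, 1, 2)
  M <- lapply(1:3, function(i) lapply(1:3, function(j)
    fac[i] * (ed$H[[i]][[j]] - ed$H[[i]][[4]] * ed$H[[4]][[j]] / ed$H[[4]][[4]])))
  list(sxx = sv$sxx, syy = sv$syy, sxy = sv$sxy, s33 = sv$s33, M = M, ed = ed)
}

## ---------------------------------------------------------------------------
## Scalar (single-state) user API built on the kernel.
## ---------------------------------------------------------------------------

#' Second Piola-Kirchhoff stress
#'
#' Analytic PK2 stress `S = 2 dW/dC` of the five-parameter Mooney-Rivlin
#' material at a plane-stress deformation state, split into the in-plane 2x2
#' block and the out-of-plane normal component `S33`.
#'
#' @inheritParams strain_energy
#' @param state a [deformation_state()].
#' @return List with `S` (2x2 in-plane PK2, Pa), `S33` (Pa) and `cauchy`
#'   (2x2 in-plane Cauchy stress, Pa).
#' @export
pk2_stress <- function(mat, state) {
  stopifnot(inherits(mat, "mooney_rivlin5"), inherits(state, "deformation_state"))
  C <- state$C
  ed <- mr_energy_derivs(mat, C[1, 1], C[2, 2], C[1, 2], state$lambda3^2,
                         hessian = FALSE)
  sv <- mr_stress_vec(ed)
  S <- matrix(c(sv$sxx, sv$sxy, sv$sxy, sv$syy), 2, 2)
  cauchy <- state$F %*% S %*% t(state$F) / state$J
  list(S = S, S33 = sv$s33, cauchy = cauchy)
}

#' Material tangent in Voigt form
#'
#' Analytic tangent `dS/dE` of the in-plane PK2 stress with respect to the
#' in-plane Green-Lagrange strain, in Voigt ordering `(11, 22, 12)` with
#' engineering shear.  With `condensed = TRUE` (default) the through-thickness
#' stretch follows the plane-stress constraint `S33 = 0` and the tangent
#' includes the resulting `d lambda3 / dC` term; with `condensed = FALSE`
#' `lambda3` is held fixed at the state's value.
#'
#' @inheritParams pk2_stress
#' @param condensed include the plane-stress condensation term?
#' @return Symmetric 3x3 matrix (Pa).
#' @export
material_tangent <- function(mat, state, condensed = TRUE) {
  stopifnot(inherits(mat, "mooney_rivlin5"), inherits(state, "deformation_state"))
  C <- state$C
  ed <- mr_energy_derivs(mat, C[1, 1], C[2, 2], C[1, 2], state$lambda3^2)
  fac <- c(2, 2, 1)
  D <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    m <- ed$H[[i]][[j]]
    if (condensed) m <- m - ed$H[[i]][[4]] * ed$H[[4]][[j]] / ed$H[[4]][[4]]
    D[i, j] <- fac[i] * m
  }
  # chain rule from C-components to Voigt strain (E11, E22, gamma12):
  # dC11 = 2 dE11, dC22 = 2 dE22, dC12 = dgamma12
  D[, 1] <- 2 * D[, 1]; D[, 2] <- 2 * D[, 2]
  D
}

#' Through-thickness stretch from the plane-stress condition
#'
#' Solves `S33(lambda3) = 0` for the out-of-plane stretch given the in-plane
#' right Cauchy-Green tensor, by a guarded Newton iteration with bisection
#' fallback (residual tolerance `1e-10 * mu0`; root sought for
#' `lambda3` in (0.05, 20)).
#'
#' @inheritParams pk2_stress
#' @param C 2x2 in-plane right Cauchy-Green tensor (positive definite).
#' @return The through-thickness stretch `lambda3`.
#' @export
#' @examples
#' tab <- material_table()
#' plane_stress_stretch(tab$spongy, diag(2))   # 1
plane_stress_stretch <- function(mat, C) {
  stopifnot(inherits(mat, "mooney_rivlin5"))
  C <- matrix(as.numeric(C), 2, 2)
  d2 <- C[1, 1] * C[2, 2] - C[1, 2]^2
  if (d2 <= 0 || C[1, 1] <= 0) stop("in-plane C must be positive definite")
  sqrt(mr_solve_c3(mat, C[1, 1], C[2, 2], C[1, 2]))
}
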