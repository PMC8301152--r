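#' Solver settings
#'
#' @param tol relative residual tolerance (against the external load norm).
#' @param max_iter maximum Newton iterations per load increment.
#' @param line_search enable backtracking line search on the residual norm.
#' @param angle_limit element distortion threshold in degrees; exceeding it
#'   in a converged state triggers the remediation policy.
#' @param max_halvings maximum number of increment halvings before the mesh
#'   is regenerated at 0.75 x element size.
#' @return List of class `solver_settings`.
#' @export
solver_settings <- function(tol = 1e-8, max_iter = 30L, line_search = TRUE,
                            angle_limit = 160, max_halvings = 6L) {
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = max_iter, line_search = line_search,
                 angle_limit = angle_limit, max_halvings = max_halvings),
            class = "solver_settings")
}

#' Load program
#'
#' @param pressure target intraluminal pressure in Pa (default 1960 Pa).
#' @param n_increments number of equal load increments.
#' @param sweep optional strictly increasing vector of pressures (Pa) for a
#'   pressure sweep; overrides `pressure` when supplied to [sweep_pressure()].
#' @return List of class `load_program`.
#' @export
load_program <- function(pressure = 1960, n_increments = 20L, sweep = NULL) {
  stopifnot(pressure >= 0, n_increments >= 1)
  if (!is.null(sweep) && any(diff(sweep) <= 0))
    stop("sweep pressures must be strictly increasing")
  structure(list(pressure = pressure, n_increments = as.integer(n_increments),
                 sweep = sweep), class = "load_program")
}

# Per-region material map used by the mechanical model.
region_materials <- function(materials = material_table()) {
  list(epithelium = materials$dense_connective,
       spongy_sane = materials$spongy,
       spongy_fibrotic = materials$fibrotic)
}

## -- model precomputation ----------------------------------------------------

# Precompute element shape-function gradients, dof maps and boundary data.
fe_model <- function(mesh, materials = material_table(), fixed_dofs = NULL) {
  tri <- mesh$tri
  xy <- mesh$nodes
  x1 <- xy[tri[, 1], 1]; y1 <- xy[tri[, 1], 2]
  x2 <- xy[tri[, 2], 1]; y2 <- xy[tri[, 2], 2]
  x3 <- xy[tri[, 3], 1]; y3 <- xy[tri[, 3], 2]
  A0 <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  if (any(A0 <= 0)) stop("mesh contains inverted or degenerate elements")
  # dN_a/dx = b_a, dN_a/dy = c_a (constant per element)
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / (2 * A0)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / (2 * A0)
  # dof index of (node, component): 2*node - 1 (x), 2*node (y)
  idx <- cbind(2L * tri[, 1] - 1L, 2L * tri[, 1],
               2L * tri[, 2] - 1L, 2L * tri[, 2],
               2L * tri[, 3] - 1L, 2L * tri[, 3])
  matmap <- region_materials(materials)
  groups <- lapply(names(matmap), function(rg) which(mesh$region == rg))
  names(groups) <- names(matmap)
  fixed <- if (is.null(fixed_dofs))
    sort(c(2L * mesh$pin_nodes - 1L, 2L * mesh$pin_nodes)) else sort(fixed_dofs)
  ndof <- 2L * nrow(xy)
  isfix <- logical(ndof); isfix[fixed] <- TRUE
  list(mesh = mesh, mats = matmap, groups = groups,
       A0 = A0, b = b, cc = cc, idx = idx,
       lumen = mesh$edge_groups$lumen,
       fixed = fixed, isfix = isfix,
       free = setdiff(seq_len(ndof), fixed), ndof = ndof)
}

# Deformation gradient components for all elements at displacement U (n x 2).
element_F <- function(model, U) {
  tri <- model$mesh$tri
  b <- model$b; cc <- model$cc
  ux <- matrix(U[tri, 1], ncol = 3)
  uy <- matrix(U[tri, 2], ncol = 3)
  list(F11 = 1 + rowSums(ux * b), F12 = rowSums(ux * cc),
       F21 = rowSums(uy * b), F22 = 1 + rowSums(uy * cc))
}

## -- follower pressure -------------------------------------------------------

#' Follower pressure forces on a boundary edge group
#'
#' Computes the consistent nodal forces of a uniform pressure acting on the
#' deformed boundary (a follower load: the traction stays normal to the
#' deformed edge), together with the load-stiffness triplets needed for a
#' consistent Newton linearisation.  Edges must be oriented with the material
#' on the left; the pressure then pushes from the enclosed void into the
#' material.
#'
#' @param mesh an `fe_mesh`.
#' @param displacement n x 2 nodal displacements (m).
#' @param p pressure in Pa.
#' @param edge_group which closed loop to load (only `"lumen"` is meaningful
#'   for this model).
#' @return List with `forces` (n x 2 matrix) and `stiffness_triplets`
#'   (data.frame `i, j, x` of d f / d u entries).
#' @export
follower_pressure_forces <- function(mesh, displacement, p,
                                     edge_group = "lumen") {
  edges <- if (identical(edge_group, "lumen")) mesh$edge_groups$lumen
           else stop("unknown edge group: ", edge_group)
  if (nrow(edges) == 0) stop("edge group is empty")
  if (!all(sort(edges[, 1]) == sort(edges[, 2])))
    stop("edge group does not form (a set of) closed loops")
  xy <- mesh$nodes + displacement
  a <- edges[, 1]; bb <- edges[, 2]
  tx <- xy[bb, 1] - xy[a, 1]
  ty <- xy[bb, 2] - xy[a, 2]
  # half of p * rot90(t) to each end node; rot90 (x,y) -> (-y,x)
  fx <- -p * ty / 2; fy <- p * tx / 2
  forces <- matrix(0, nrow(xy), 2)
  node_ids <- c(a, bb)
  accx <- rowsum(c(fx, fx), node_ids)
  accy <- rowsum(c(fy, fy), node_ids)
  forces[as.integer(rownames(accx)), 1] <- accx
  forces[as.integer(rownames(accy)), 2] <- accy
  # load stiffness: d f / d u.  f_a = f_b = (p/2) R (x_b - x_a), R = rot90
  # df/dxb = (p/2) R, df/dxa = -(p/2) R, applied to both receiving nodes.
  n_e <- nrow(edges)
  di <- c(); dj <- c(); dx <- c()
  for (recv in list(a, bb)) {
    for (src in list(list(n = bb, s = +1), list(n = a, s = -1))) {
      # R = [[0,-1],[1,0]]: dfx/dy = -s*p/2, dfy/dx = +s*p/2
      di <- c(di, 2L * recv - 1L, 2L * recv)
      dj <- c(dj, 2L * src$n, 2L * src$n - 1L)
      dx <- c(dx, rep(-src$s * p / 2, n_e), rep(src$s * p / 2, n_e))
    }
  }
  list(forces = forces, stiffness_triplets = data.frame(i = di, j = dj, x = dx))
}

## -- assembly ----------------------------------------------------------------

# Assemble internal force vector, external (follower) force vector and the
# consistent tangent at displacement U (n x 2).  c3_warm carries the
# through-thickness stretch squared per element between calls.
#' Assemble residual and tangent of the pressurised model
#'
#' Total-Lagrangian assembly for constant-strain triangles with the
#' plane-stress Mooney-Rivlin material: returns the residual
#' `R = f_int - f_ext(p)`, the consistent tangent (including the follower
#' load stiffness), and the updated per-element through-thickness state.
#'
#' @param model internal model object (see `fe_model`).
#' @param U n x 2 nodal displacement matrix.
#' @param p intraluminal pressure (Pa).
#' @param c3_warm optional per-element warm start for the plane-stress
#'   through-thickness iteration.
#' @return List with `residual` (length-2n vector), `K` (2n x 2n sparse
#'   dgCMatrix), `fext` (length-2n), `c3` (per element), `state` (per-element
#'   stress/deformation scalars).
#' @keywords internal
assemble <- function(model, U, p, c3_warm = NULL) {
  m <- nrow(model$mesh$tri)
  Fel <- element_F(model, U)
  cxx <- Fel$F11^2 + Fel$F21^2
  cyy <- Fel$F12^2 + Fel$F22^2
  cxy <- Fel$F11 * Fel$F12 + Fel$F21 * Fel$F22
  detF <- Fel$F11 * Fel$F22 - Fel$F12 * Fel$F21
  if (any(detF <= 0)) stop("element inversion during assembly")
  c3 <- if (is.null(c3_warm)) rep(1, m) else c3_warm
  sxx <- syy <- sxy <- s33 <- numeric(m)
  Dv <- replicate(3, replicate(3, numeric(m), simplify = FALSE),
                  simplify = FALSE)
  for (rg in names(model$groups)) {
    ii <- model$groups[[rg]]
    if (!length(ii)) next
    mat <- model$mats[[rg]]
    c3[ii] <- mr_solve_c3(mat, cxx[ii], cyy[ii], cxy[ii], c3[ii])
    up <- mr_point_update(mat, cxx[ii], cyy[ii], cxy[ii], c3[ii])
    sxx[ii] <- up$sxx; syy[ii] <- up$syy; sxy[ii] <- up$sxy
    for (i in 1:3) for (j in 1:3) Dv[[i]][[j]][ii] <- up$M[[i]][[j]]
  }
  # Voigt tangent dS/dE with engineering shear: scale dc -> dE columns
  D <- list(list(2 * Dv[[1]][[1]], 2 * Dv[[1]][[2]], Dv[[1]][[3]]),
            list(2 * Dv[[2]][[1]], 2 * Dv[[2]][[2]], Dv[[2]][[3]]),
            list(2 * Dv[[3]][[1]], 2 * Dv[[3]][[2]], Dv[[3]][[3]]))
  # PK1 = F S
  P11 <- Fel$F11 * sxx + Fel$F12 * sxy
  P12 <- Fel$F11 * sxy + Fel$F12 * syy
  P21 <- Fel$F21 * sxx + Fel$F22 * sxy
  P22 <- Fel$F21 * sxy + Fel$F22 * syy
  A0 <- model$A0; b <- model$b; cc <- model$cc
  fint <- numeric(model$ndof)
  felem <- matrix(0, m, 6)
  for (a in 1:3) {
    felem[, 2 * a - 1] <- A0 * (P11 * b[, a] + P12 * cc[, a])
    felem[, 2 * a]     <- A0 * (P21 * b[, a] + P22 * cc[, a])
  }
  fint <- accumulate_vector(model$idx, felem, model$ndof)
  # B matrix rows (3 strain comps) x columns (6 dofs), per element
  B <- vector("list", 3L)
  for (r in 1:3) B[[r]] <- vector("list", 6L)
  for (a in 1:3) {
    B[[1]][[2 * a - 1]] <- Fel$F11 * b[, a]
    B[[1]][[2 * a]]     <- Fel$F21 * b[, a]
    B[[2]][[2 * a - 1]] <- Fel$F12 * cc[, a]
    B[[2]][[2 * a]]     <- Fel$F22 * cc[, a]
    B[[3]][[2 * a - 1]] <- Fel$F11 * cc[, a] + Fel$F12 * b[, a]
    B[[3]][[2 * a]]     <- Fel$F21 * cc[, a] + Fel$F22 * b[, a]
  }
  # K_e = A0 * (B' D B + geometric term)
  BD <- vector("list", 3L)
  for (q in 1:3) {
    BD[[q]] <- vector("list", 6L)
    for (col in 1:6) {
      acc <- 0
      for (pr in 1:3) acc <- acc + B[[pr]][[col]] * D[[pr]][[q]]
      BD[[q]][[col]] <- acc
    }
  }
  ntrip <- 36L * m
  ti <- integer(ntrip); tj <- integer(ntrip); tx <- numeric(ntrip)
  k <- 0L
  # geometric scalar g_ab = grad N_a . S . grad N_b
  for (arow in 1:6) {
    an <- (arow + 1L) %/% 2L; ai <- 2L - (arow %% 2L)  # node, component
    for (bcol in 1:6) {
      bn <- (bcol + 1L) %/% 2L; bi <- 2L - (bcol %% 2L)
      val <- 0
      for (q in 1:3) val <- val + BD[[q]][[arow]] * B[[q]][[bcol]]
      if (ai == bi) {
        val <- val + (b[, an] * sxx * b[, bn] + b[, an] * sxy * cc[, bn] +
                        cc[, an] * sxy * b[, bn] + cc[, an] * syy * cc[, bn])
      }
      rng <- k + seq_len(m)
      ti[rng] <- model$idx[, arow]
      tj[rng] <- model$idx[, bcol]
      tx[rng] <- A0 * val
      k <- k + m
    }
  }
  ext <- follower_pressure_forces(model$mesh, U, 1)   # unit pressure
  fn <- as.vector(t(ext$forces))
  fn[model$fixed] <- 0
  fext <- p * fn
  # residual R = fint - fext; tangent K = dR/du = K_int - p * K_unit_ext.
  # Dirichlet dofs are eliminated in the triplets (unit diagonal, zero
  # residual), so no submatrix extraction is needed at solve time.
  st <- ext$stiffness_triplets
  ti <- c(ti, st$i); tj <- c(tj, st$j); tx <- c(tx, -p * st$x)
  keep <- !model$isfix[ti] & !model$isfix[tj]
  K <- Matrix::sparseMatrix(i = c(ti[keep], model$fixed),
                            j = c(tj[keep], model$fixed),
                            x = c(tx[keep], rep(1, length(model$fixed))),
                            dims = c(model$ndof, model$ndof))
  residual <- fint - fext
  residual[model$fixed] <- 0
  list(residual = residual, K = K, fext = fext, fn = fn, c3 = c3,
       state = list(F = Fel, c3 = c3, sxx = sxx, syy = syy, sxy = sxy,
                    cxx = cxx, cyy = cyy, cxy = cxy, detF = detF))
}

accumulate_vector <- function(idx, vals, ndof) {
  out <- numeric(ndof)
  acc <- rowsum(as.vector(vals), as.vector(idx))
  out[as.integer(rownames(acc))] <- acc
  out
}

## -- Newton solve ------------------------------------------------------------

newton_increment <- function(model, U, p, c3, settings, fext_scale = NULL) {
  conv <- FALSE
  log <- data.frame(iter = integer(0), resid = numeric(0))
  out <- tryCatch(assemble(model, U, p, c3), error = function(e) NULL)
  if (is.null(out)) return(list(U = U, c3 = c3, converged = FALSE, log = log))
  for (it in seq_len(settings$max_iter)) {
    c3 <- out$c3
    scale <- max(sqrt(sum(out$fext^2)), fext_scale %||% 0, 1e-12)
    rn <- sqrt(sum(out$residual^2))
    log <- rbind(log, data.frame(iter = it, resid = rn / scale))
    if (rn <= settings$tol * scale) { conv <- TRUE; break }
    du <- tryCatch(as.numeric(Matrix::solve(out$K, -out$residual)),
                   error = function(e) NULL)
    if (is.null(du) || !all(is.finite(du))) break
    duM <- cbind(du[seq(1L, model$ndof, 2L)], du[seq(2L, model$ndof, 2L)])
    step <- 1; accepted <- FALSE
    for (ls in seq_len(6L)) {
      Utry <- U + step * duM
      ot <- tryCatch(assemble(model, Utry, p, c3), error = function(e) NULL)
      if (!is.null(ot)) {
        rt <- sqrt(sum(ot$residual^2))
        if (!settings$line_search || rt < max(1.2 * rn, rn + 1e-300) ||
              ls == 6L) {
          U <- Utry; out <- ot; accepted <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!accepted) break
  }
  list(U = U, c3 = c3, converged = conv, log = log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run the incremental loading to `pressure`, with adaptive halving on
# failure.  Returns displacements at each target level plus the state.
solve_increments <- function(model, levels, settings,
                             U = NULL, c3 = NULL, record = TRUE) {
  n <- nrow(model$mesh$nodes)
  if (is.null(U)) U <- matrix(0, n, 2)
  m <- nrow(model$mesh$tri)
  if (is.null(c3)) c3 <- rep(1, m)
  p_cur <- 0
  out_levels <- list()
  conv_log <- list()
  for (lev in seq_along(levels)) {
    p_target <- levels[lev]
    step <- p_target - p_cur
    halvings <- 0L
    while (p_cur < p_target - 1e-12) {
      p_next <- min(p_target, p_cur + step)
      res <- newton_increment(model, U, p_next, c3, settings)
      distorted <- if (res$converged)
        length(detect_distortion(model$mesh, res$U, settings$angle_limit)) > 0
        else FALSE
      if (res$converged && !distorted) {
        U <- res$U; c3 <- res$c3; p_cur <- p_next
        conv_log[[length(conv_log) + 1L]] <-
          cbind(pressure = p_next, res$log)
      } else {
        halvings <- halvings + 1L
        if (halvings > settings$max_halvings)
          return(list(U = U, c3 = c3, levels = out_levels, p_reached = p_cur,
                      failed = TRUE, log = conv_log,
                      reason = if (distorted) "distortion" else "no convergence"))
        step <- step / 2
      }
    }
    if (record) out_levels[[lev]] <- U
  }
  list(U = U, c3 = c3, levels = out_levels, p_reached = p_cur, failed = FALSE,
       log = conv_log)
}

## -- area-controlled continuation --------------------------------------------

# Deformed lumen area (m^2) and its gradient with respect to the nodal dofs.
lumen_area_and_grad <- function(model, U) {
  loop <- model$lumen
  nodes <- loop[, 1]                       # ordered cycle
  xy <- model$mesh$nodes[nodes, , drop = FALSE] + U[nodes, , drop = FALSE]
  n <- length(nodes)
  nxt <- c(seq_len(n)[-1], 1L)
  prv <- c(n, seq_len(n)[-n])
  Ssig <- sum(xy[, 1] * xy[nxt, 2] - xy[nxt, 1] * xy[, 2]) / 2
  sgn <- if (Ssig >= 0) 1 else -1
  g <- numeric(model$ndof)
  g[2L * nodes - 1L] <- sgn * (xy[nxt, 2] - xy[prv, 2]) / 2
  g[2L * nodes] <- sgn * (xy[prv, 1] - xy[nxt, 1]) / 2
  g[model$fixed] <- 0
  list(A = abs(Ssig), g = g)
}

# Bordered Newton at a prescribed lumen area: unknowns (U, p), equations
# R(U, p) = 0 and A(U) = A_t.  Traverses pressure limit points that defeat
# plain load control.
# `ks` adds pseudo-viscous stabilisation: a restoring force
# ks * dscale * (u - u_ref) regularising local wrinkling instabilities of
# compressed tissue strips; converged stabilised states are relaxed back to
# ks = 0 by the caller wherever possible.
newton_area <- function(model, U, p, A_t, c3, settings, u_ref = NULL,
                        ks = 0) {
  conv <- FALSE
  last_err <- NULL
  best <- Inf; best_it <- 0L
  uref_vec <- if (is.null(u_ref)) NULL else as.vector(t(u_ref))
  out <- tryCatch(assemble(model, U, p, c3), error = function(e) NULL)
  if (is.null(out)) return(list(converged = FALSE))
  dstab <- ks * mean(abs(Matrix::diag(out$K)))
  stab_resid <- function(resid, Uv) {
    if (dstab == 0) return(resid)
    r <- resid + dstab * (as.vector(t(Uv)) - uref_vec)
    r[model$fixed] <- 0
    r
  }
  for (it in seq_len(settings$max_iter)) {
    c3 <- out$c3
    ag <- lumen_area_and_grad(model, U)
    resid <- stab_resid(out$residual, U)
    rn <- sqrt(sum(resid^2))
    fscale <- max(abs(p), 1e-3) * sqrt(sum(out$fn^2))
    cA <- ag$A - A_t
    merit <- rn / fscale + abs(cA) / A_t
    if (rn <= settings$tol * fscale && abs(cA) <= 1e-8 * A_t) {
      conv <- TRUE; break
    }
    # near a bifurcation the tangent can become singular in a direction the
    # area constraint does not control; a small diagonal regularisation lets
    # the iteration follow the principal branch (converged states still
    # satisfy the unmodified equilibrium residual)
    sol2 <- NULL
    reg <- 0
    dscale <- mean(abs(Matrix::diag(out$K)))
    for (tryreg in 0:6) {
      shift <- dstab + reg * dscale
      Kr <- if (shift > 0)
        out$K + Matrix::Diagonal(model$ndof, shift) else out$K
      sol2 <- tryCatch(
        as.matrix(Matrix::solve(Kr, cbind(out$fn, -resid))),
        error = function(e) NULL)
      if (!is.null(sol2) && all(is.finite(sol2)) &&
            max(abs(sol2)) < 1e8) break
      reg <- if (reg == 0) 1e-8 else reg * 100
    }
    if (is.null(sol2) || !all(is.finite(sol2))) break
    x1 <- sol2[, 1]; x2 <- sol2[, 2]
    gx1 <- sum(ag$g * x1)
    if (abs(gx1) < 1e-300) break
    dp <- (-cA - sum(ag$g * x2)) / gx1
    du <- x2 + dp * x1
    duM <- cbind(du[seq(1L, model$ndof, 2L)], du[seq(2L, model$ndof, 2L)])
    step <- 1; accepted <- FALSE
    for (ls in seq_len(8L)) {
      Utry <- U + step * duM
      ptry <- p + step * dp
      ot <- tryCatch(assemble(model, Utry, ptry, c3),
                     error = function(e) { last_err <<- conditionMessage(e); NULL })
      if (!is.null(ot)) {
        # merit combines the force residual with the area-constraint error,
        # so a step from an equilibrated previous state (zero residual but
        # wrong area) is accepted on constraint progress
        agt <- lumen_area_and_grad(model, Utry)
        mt <- sqrt(sum(stab_resid(ot$residual, Utry)^2)) /
          (max(abs(ptry), 1e-3) * sqrt(sum(ot$fn^2))) +
          abs(agt$A - A_t) / A_t
        if (mt < max(0.99 * merit, merit - 1e-300) || ls == 8L) {
          U <- Utry; p <- ptry; out <- ot; accepted <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!accepted) break
    # stagnation bail-out: stop early when the merit has stopped improving
    if (merit < 0.8 * best) { best <- merit; best_it <- it }
    if (it - best_it >= 6L) break
  }
  list(U = U, p = p, c3 = c3, converged = conv, iters = it, err = last_err)
}

# Continuation in lumen area with states extracted at the requested target
# pressures (quasi-static pressure control: a target is taken the first time
# the path pressure rises past it).  Returns per-target states and the path.
area_continuation <- function(model, p_targets, settings,
                              dA0_frac = 0.05, A_cap_frac = 10,
                              verbose = FALSE) {
  n <- nrow(model$mesh$nodes)
  U <- matrix(0, n, 2)
  m <- nrow(model$mesh$tri)
  c3 <- rep(1, m)
  p <- 0
  A0 <- lumen_area_and_grad(model, U)$A
  A_cur <- A0
  dA <- dA0_frac * A0
  p_targets <- sort(p_targets)
  hit <- rep(FALSE, length(p_targets))
  states <- vector("list", length(p_targets))
  path <- list(data.frame(A = A0, p = 0))
  p_max <- 0
  prev <- list(U = U, p = p, c3 = c3, A = A0)
  fails <- 0L
  stab_used <- 0
  # states exactly at p = 0
  for (k in which(p_targets == 0)) {
    states[[k]] <- list(U = U, p = 0, c3 = c3); hit[k] <- TRUE
  }
  while (any(!hit) && A_cur < A_cap_frac * A0) {
    A_t <- A_cur + dA
    res <- newton_area(model, U, p, A_t, c3, settings)
    if (verbose)
      message(sprintf("  A/A0=%.3f p=%.1f conv=%s it=%d dA/A0=%.4f%s",
                      A_t / A0, if (is.null(res$p)) NA else res$p,
                      res$converged,
                      if (is.null(res$iters)) -1L else res$iters, dA / A0,
                      if (is.null(res$err)) "" else paste0(" [", res$err, "]")))
    if (!res$converged) {
      # local wrinkling instabilities: retry with pseudo-viscous
      # stabilisation, then relax the converged state back to ks = 0
      for (ks in c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1)) {
        r2 <- newton_area(model, U, p, A_t, c3, settings, u_ref = U, ks = ks)
        if (r2$converged) {
          r3 <- newton_area(model, r2$U, r2$p, A_t, r2$c3, settings)
          if (r3$converged) {
            res <- r3
          } else {
            res <- r2
            stab_used <- max(stab_used, ks)
          }
          if (verbose)
            message(sprintf("    stabilised step (ks=%g, relaxed=%s) at A/A0=%.3f",
                            ks, r3$converged, A_t / A0))
          break
        }
      }
    }
    if (!res$converged) {
      fails <- fails + 1L
      dA <- dA / 2
      if (dA < 1e-6 * A0 || fails > 25L)
        return(list(states = states, targets = p_targets, hit = hit,
                    path = do.call(rbind, path), failed = TRUE,
                    p_reached = p_max, last = prev, stabilised = stab_used))
      next
    }
    # distortion remediation signal
    if (length(detect_distortion(model$mesh, res$U,
                                 settings$angle_limit)) > 0)
      return(list(states = states, targets = p_targets, hit = hit,
                  path = do.call(rbind, path), failed = TRUE,
                  distorted = TRUE, p_reached = p_max,
                  last = list(U = res$U, p = res$p, c3 = res$c3, A = A_t)))
    newly <- which(!hit & p_targets > p_max & p_targets <= res$p)
    for (k in newly) {
      st <- refine_to_pressure(model, prev, res, A_t, p_targets[k], settings)
      if (is.null(st))
        return(list(states = states, targets = p_targets, hit = hit,
                    path = do.call(rbind, path), failed = TRUE,
                    p_reached = p_max, last = prev))
      states[[k]] <- st
      hit[k] <- TRUE
    }
    prev <- list(U = res$U, p = res$p, c3 = res$c3, A = A_t)
    U <- res$U; p <- res$p; c3 <- res$c3; A_cur <- A_t
    p_max <- max(p_max, res$p)
    path[[length(path) + 1L]] <- data.frame(A = A_t, p = res$p)
    dA <- min(dA * if (res$iters <= 5) 1.5 else 1.0, 0.1 * A0)
  }
  list(states = states, targets = p_targets, hit = hit,
       path = do.call(rbind, path), failed = any(!hit), p_reached = p_max,
       last = prev, stabilised = stab_used)
}

# Secant iteration in the area parameter to land on an exact target
# pressure between two accepted continuation states.
refine_to_pressure <- function(model, lo, hi, A_hi, p_t, settings,
                               tol_rel = 1e-5, maxit = 16L) {
  A_lo <- lo$A; p_lo <- lo$p
  A_hi2 <- A_hi; p_hi <- hi$p
  U <- hi$U; p <- hi$p; c3 <- hi$c3
  for (it in seq_len(maxit)) {
    w <- (p_t - p_lo) / (p_hi - p_lo)
    w <- min(0.99, max(0.01, w))
    A_try <- A_lo + w * (A_hi2 - A_lo)
    res <- newton_area(model, U, p, A_try, c3, settings)
    if (!res$converged) return(NULL)
    U <- res$U; p <- res$p; c3 <- res$c3
    if (abs(p - p_t) <= tol_rel * max(p_t, 1)) {
      return(list(U = U, p = p, c3 = c3))
    }
    if (p < p_t) { A_lo <- A_try; p_lo <- p } else { A_hi2 <- A_try; p_hi <- p }
  }
  if (abs(p - p_t) <= 1e-4 * max(p_t, 1)) list(U = U, p = p, c3 = c3)
  else NULL
}

## -- user-facing drivers -----------------------------------------------------

#' Solve a registered simulation case
#'
#' Builds (or reuses) the geometry and mesh for a case, applies the
#' intraluminal follower pressure in equal increments with Newton-Raphson
#' iteration, and returns the converged solution.  On element distortion
#' (displaced mesh angle above the limit) or non-convergence the load
#' increment is halved; if the minimum increment still fails, the mesh is
#' regenerated at 0.75 x element size and the load program restarted.
#'
#' @param case_id a [case_registry()] id, e.g. `"P0"`, `"H6"`, `"H6b"`.
#' @param params base [geometry_params()].
#' @param materials a [material_table()].
#' @param load a [load_program()].
#' @param settings a [solver_settings()].
#' @param mesh optional pre-built `fe_mesh` (overrides case geometry).
#' @param h_coarse,h_fine mesh sizes passed to [generate_mesh()].
#' @return Object of class `fe_solution`: `mesh`, `U` (displacement at the
#'   target pressure), `pressure`, `path` (the traversed area-pressure
#'   continuation path), `state` (per-element deformation and stress at the
#'   target), `case_id`.
#' @export
solve_case <- function(case_id, params = geometry_params(),
                       materials = material_table(),
                       load = load_program(),
                       settings = solver_settings(),
                       mesh = NULL, h_coarse = 4.5e-4, h_fine = 2.25e-4) {
  if (is.null(mesh)) {
    dom <- build_case(case_id, params)
    mesh <- generate_mesh(dom, h_coarse = h_coarse, h_fine = h_fine)
  }
  attempt <- function(mesh) {
    model <- fe_model(mesh, materials)
    res <- area_continuation(model, load$pressure, settings)
    list(model = model, res = res)
  }
  at <- attempt(mesh)
  if (at$res$failed) {
    # remediation: regenerate at 0.75x element size and restart from zero
    mesh <- generate_mesh(mesh$domain, h_coarse = 0.75 * mesh$h_coarse,
                          h_fine = 0.75 * mesh$h_fine)
    at <- attempt(mesh)
    if (at$res$failed)
      stop("solve_case(", case_id, ") failed: pressure reached ",
           signif(at$res$p_reached, 4), " Pa of ", load$pressure, " Pa")
  }
  st <- at$res$states[[length(at$res$states)]]
  final <- assemble(at$model, st$U, st$p, st$c3)
  structure(list(mesh = mesh, U = st$U,
                 pressure = st$p,
                 pressures = st$p,
                 path = at$res$path,
                 state = final$state, case_id = case_id,
                 load = load, settings = settings),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("FE solution '%s': %d nodes, p = %.4g Pa\n",
              x$case_id, nrow(x$mesh$nodes), x$pressure))
  cat(sprintf("  max |u| = %.3g m, lumen area = %.2f mm^2\n",
              max(abs(x$U)), lumen_area(x)))
  invisible(x)
}

#' Pressure sweep for a case
#'
#' Continuation over a strictly increasing pressure list with warm restart
#' from the previous level; per-pressure deformed lumen areas are recorded.
#'
#' @inheritParams solve_case
#' @param pressures strictly increasing pressures in Pa (default 196 to
#'   2584 Pa in steps of 196 Pa).
#' @param keep_state also store the per-element deformation/stress state in
#'   every returned solution (needed for [principal_fields()]).
#' @return List with `pressures`, `areas_mm2`, `solutions` (one
#'   `fe_solution` per pressure, sharing one mesh), `path`.
#' @export
sweep_pressure <- function(case_id, pressures = seq(196, 2584, by = 196),
                           params = geometry_params(),
                           materials = material_table(),
                           settings = solver_settings(),
                           mesh = NULL, h_coarse = 4.5e-4, h_fine = 2.25e-4,
                           keep_state = FALSE) {
  if (any(diff(pressures) <= 0)) stop("pressures must be strictly increasing")
  if (is.null(mesh)) {
    dom <- build_case(case_id, params)
    mesh <- generate_mesh(dom, h_coarse = h_coarse, h_fine = h_fine)
  }
  model <- fe_model(mesh, materials)
  res <- area_continuation(model, pressures, settings)
  if (res$failed) {
    mesh <- generate_mesh(mesh$domain, h_coarse = 0.75 * mesh$h_coarse,
                          h_fine = 0.75 * mesh$h_fine)
    model <- fe_model(mesh, materials)
    res <- area_continuation(model, pressures, settings)
    if (res$failed)
      stop("sweep failed for ", case_id, ": pressure reached ",
           signif(res$p_reached, 4), " Pa of ", max(pressures), " Pa")
  }
  # res$targets is sorted(pressures); map back to input order
  sols <- lapply(seq_along(pressures), function(i) {
    k <- which(res$targets == pressures[i])[1]
    st <- res$states[[k]]
    state <- if (keep_state)
      assemble(model, st$U, st$p, st$c3)$state else NULL
    structure(list(mesh = mesh, U = st$U, pressure = st$p, state = state,
                   case_id = case_id), class = "fe_solution")
  })
  areas <- vapply(sols, lumen_area, 0)
  list(pressures = pressures, areas_mm2 = areas, solutions = sols,
       case_id = case_id, path = res$path)
}
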