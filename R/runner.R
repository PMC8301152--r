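#' Run configuration
#'
#' Assembles a fully serialisable description of a simulation run: geometry
#' overrides, case list, load program, mesh sizes, solver settings and report
#' options.  Unspecified entries take the package defaults (the calibrated
#' study conditions).
#'
#' @param cases character vector of [case_registry()] ids.
#' @param geometry named list of [geometry_params()] overrides.
#' @param load named list of [load_program()] overrides.
#' @param mesh named list with `h_coarse`, `h_fine` (m).
#' @param settings named list of [solver_settings()] overrides.
#' @param sweep optional vector of sweep pressures (Pa); when set, `run()`
#'   performs the pressure sweep for each case instead of a single target
#'   pressure.
#' @param material_form constitutive form (see [mooney_rivlin5()]).
#' @param strain_measure `"hencky"` or `"green"` for reported strains.
#' @param output_dir directory for the result bundle, or `NULL` to skip
#'   writing files.
#' @return List of class `run_config`.
#' @export
run_config <- function(cases = c("P0", "H0", "H3", "H4", "H5", "H6", "H7",
                                 "H6b"),
                       geometry = list(), load = list(),
                       mesh = list(h_coarse = 4.5e-4, h_fine = 2.25e-4),
                       settings = list(), sweep = NULL,
                       material_form = "isochoric",
                       strain_measure = "hencky",
                       output_dir = NULL) {
  cfg <- list(cases = cases, geometry = geometry, load = load, mesh = mesh,
              settings = settings, sweep = sweep,
              material_form = material_form,
              strain_measure = strain_measure, output_dir = output_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @return [run_config()] object (for `read_run_config`).
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(run_config, obj)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

resolve_config <- function(config) {
  geo <- do.call(geometry_params, config$geometry)
  load <- do.call(load_program, config$load)
  settings <- do.call(solver_settings, config$settings)
  mats <- material_table(form = config$material_form)
  list(geometry = geo, load = load, settings = settings, materials = mats,
       h_coarse = config$mesh$h_coarse %||% 4.5e-4,
       h_fine = config$mesh$h_fine %||% 2.25e-4)
}

#' Run a configured case battery
#'
#' Solves every case in the configuration at the target pressure (or sweeps
#' the pressure list when `config$sweep` is set), computes the metrics table
#' (deformed lumen area, opening loss and recovery, principal-field extrema),
#' and optionally writes a result bundle: `metrics.csv`, per-case legacy VTK
#' field files and Gmsh meshes, a YAML manifest embedding the resolved
#' configuration, and the convergence log.  Identical configurations produce
#' byte-identical metrics files.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return List with `metrics` (data.frame), `solutions`, `sweeps`,
#'   `failures` (named character), `config`.
#' @export
run <- function(config = run_config(), quiet = FALSE) {
  rc <- resolve_config(config)
  say <- function(...) if (!quiet) message(...)
  solutions <- list(); failures <- character(0); sweeps <- list()
  meshes <- list()
  for (id in config$cases) {
    say("case ", id, " ...")
    dom <- build_case(id, rc$geometry)
    mesh <- suppressWarnings(
      generate_mesh(dom, h_coarse = rc$h_coarse, h_fine = rc$h_fine))
    meshes[[id]] <- mesh
    res <- tryCatch(
      suppressWarnings(solve_case(id, params = rc$geometry,
                                  materials = rc$materials, load = rc$load,
                                  settings = rc$settings, mesh = mesh)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
      say("  FAILED: ", failures[[id]])
    } else {
      solutions[[id]] <- res
      say(sprintf("  A = %.2f mm^2", lumen_area(res)))
    }
    if (!is.null(config$sweep) && !id %in% names(failures)) {
      sw <- tryCatch(
        suppressWarnings(sweep_pressure(id, pressures = config$sweep,
                                        params = rc$geometry,
                                        materials = rc$materials,
                                        settings = rc$settings, mesh = mesh)),
        error = function(e) e)
      if (inherits(sw, "error")) failures[[paste0(id, "_sweep")]] <-
          conditionMessage(sw)
      else sweeps[[id]] <- sw
    }
  }
  metrics <- metrics_report(solutions, measure = config$strain_measure)
  out <- list(metrics = metrics, solutions = solutions, sweeps = sweeps,
              failures = failures, config = config)
  if (!is.null(config$output_dir)) write_bundle(out, config$output_dir)
  invisible(out)
}

# Write the result bundle to disk.
write_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  if (length(result$sweeps)) {
    sw <- do.call(rbind, lapply(names(result$sweeps), function(id)
      data.frame(case_id = id, p_Pa = result$sweeps[[id]]$pressures,
                 A_mm2 = round(result$sweeps[[id]]$areas_mm2, 4))))
    utils::write.csv(sw, file.path(dir, "sweep.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  for (id in names(result$solutions)) {
    sol <- result$solutions[[id]]
    pf <- principal_fields(sol, result$config$strain_measure)
    write_vtk(sol$mesh, file.path(dir, paste0("fields_", id, ".vtk")),
              point_data = list(displacement = sol$U),
              cell_data = list(principal_stress_max = pf$elements$s1,
                               principal_strain_max = pf$elements$e1))
    write_msh(sol$mesh, file.path(dir, paste0("mesh_", id, ".msh")))
  }
  manifest <- list(
    package = "sphincterFE",
    config = unclass(result$config),
    materials = lapply(material_table(result$config$material_form),
                       function(m) m[c("C10", "C01", "C20", "C02", "C11",
                                       "d1", "form")]),
    failures = as.list(result$failures))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  logs <- lapply(names(result$solutions), function(id) {
    pth <- result$solutions[[id]]$path
    if (is.null(pth)) return(NULL)
    data.frame(case_id = id, A_m2 = pth$A, p_Pa = pth$p)
  })
  logs <- do.call(rbind, logs)
  if (!is.null(logs))
    utils::write.csv(logs, file.path(dir, "convergence.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

## -- verification suite ------------------------------------------------------

#' Run the built-in verification oracles
#'
#' `fast` checks the constitutive kernel against independent scalar oracles
#' (reference-state energy/stress, finite-difference stress and tangent,
#' plane-stress stretch by direct energy minimisation, single-element nodal
#' forces, follower-load resultants).  `full` adds the thick-walled-cylinder
#' (Lame) displacement benchmark and a mesh-refinement consistency gate on
#' the annulus.
#'
#' @param level `"fast"` or `"full"`.
#' @return data.frame with columns `check`, `value`, `tolerance`, `pass`.
#' @export
verify <- function(level = c("fast", "full")) {
  level <- match.arg(level)
  rows <- list()
  add <- function(check, value, tolerance)
    rows[[length(rows) + 1L]] <<- data.frame(check = check, value = value,
                                             tolerance = tolerance,
                                             pass = value <= tolerance)
  tab <- material_table()
  # reference state: energy and stress vanish for every preset
  refmax <- max(vapply(tab, function(m) {
    st <- deformation_state(diag(2), 1)
    s <- pk2_stress(m, st)
    max(abs(strain_energy(m, st)), max(abs(s$S)), abs(s$S33)) / m$mu0
  }, 0))
  add("reference_state_zero", refmax, 1e-12)
  # independent scalar energy (direct arithmetic on the invariants)
  w_scalar <- function(m, cxx, cyy, cxy, c3) {
    t2 <- cxx + cyy; d2 <- cxx * cyy - cxy^2
    J <- sqrt(d2 * c3)
    I1 <- (t2 + c3) * J^(-2 / 3); I2 <- (d2 + c3 * t2) * J^(-4 / 3)
    m$C10 * (I1 - 3) + m$C01 * (I2 - 3) + m$C20 * (I1 - 3)^2 +
      m$C02 * (I2 - 3)^2 + m$C11 * (I1 - 3) * (I2 - 3) +
      (1 / m$d1) * (J - 1)^2
  }
  # FD stress against the analytic kernel at a random state
  set.seed(11)
  F <- diag(2) + matrix(stats::rnorm(4, sd = 0.06), 2, 2)
  l3 <- 0.97
  st <- deformation_state(F, l3)
  C <- st$C
  S <- pk2_stress(tab$spongy, st)$S
  h <- 1e-7
  fd <- vapply(1:3, function(k) {
    dc <- c(0, 0, 0); dc[k] <- h
    (w_scalar(tab$spongy, C[1, 1] + dc[1], C[2, 2] + dc[2], C[1, 2] + dc[3],
              l3^2) -
       w_scalar(tab$spongy, C[1, 1] - dc[1], C[2, 2] - dc[2],
                C[1, 2] - dc[3], l3^2)) / (2 * h)
  }, 0)
  err_s <- max(abs(c(2 * fd[1] - S[1, 1], 2 * fd[2] - S[2, 2],
                     fd[3] - S[1, 2]))) / max(abs(S))
  add("pk2_stress_fd", err_s, 1e-6)
  # tangent against FD of the stress
  D <- material_tangent(tab$spongy, st, condensed = FALSE)
  hh <- 1e-8
  Dfd <- matrix(0, 3, 3)
  sc <- function(cv) {
    ed <- mr_energy_derivs(tab$spongy, cv[1], cv[2], cv[3], l3^2,
                           hessian = FALSE)
    sv <- mr_stress_vec(ed)
    c(sv$sxx, sv$syy, sv$sxy)
  }
  cv0 <- c(C[1, 1], C[2, 2], C[1, 2])
  dC <- c(2, 2, 1)
  for (j in 1:3) {
    e <- c(0, 0, 0); e[j] <- hh
    Dfd[, j] <- (sc(cv0 + dC[j] * e) - sc(cv0 - dC[j] * e)) / (2 * hh)
  }
  add("material_tangent_fd", max(abs(D - Dfd)) / max(abs(D)), 1e-5)
  # plane-stress stretch against direct 1D energy minimisation
  Cu <- diag(c(1.3, 0.9))
  l3k <- plane_stress_stretch(tab$spongy, Cu)
  opt <- stats::optimize(function(l3) w_scalar(tab$spongy, 1.3, 0.9, 0, l3^2),
                         c(0.3, 3), tol = 1e-12)$minimum
  add("plane_stress_minimisation", abs(l3k - opt), 1e-8)
  # single-element nodal forces against P * gradN * A0 with independent S
  el <- single_element_check()
  add("single_element_forces", el, 1e-8)
  # follower load on a circle: zero resultant and exact traction integral
  fl <- follower_circle_check()
  add("follower_resultant", fl$net, 1e-10)
  add("follower_traction_integral", fl$mag, 1e-3)
  if (level == "full") {
    lam <- lame_annulus_check()
    add("lame_annulus_displacement", lam, 0.02)
    conv <- annulus_refinement_check()
    add("annulus_refinement_gate", conv, 0.005)
  }
  do.call(rbind, rows)
}

# One CST under a homogeneous stretch: internal nodal forces must equal
# A0 * P * gradN with the plane-stress PK2 computed by an independent path
# (energy FD + scalar lambda3 minimisation).
single_element_check <- function() {
  tab <- material_table()
  mat <- tab$spongy
  X <- rbind(c(0, 0), c(2e-3, 0), c(0, 2e-3))
  Fh <- matrix(c(1.15, 0.03, -0.02, 0.92), 2, 2)
  U <- t(Fh %*% t(X)) - X
  mesh <- structure(list(
    nodes = X, tri = matrix(c(1L, 2L, 3L), 1),
    region = "spongy_sane",
    edge_groups = list(lumen = cbind(c(1L, 2L, 3L), c(2L, 3L, 1L)),
                       holes = list(), outer = NULL),
    h_coarse = 2e-3, h_fine = 2e-3, pin_nodes = c(1L, 2L),
    domain = list(params = list(lumen_center = c(0, 0)))), class = "fe_mesh")
  model <- fe_model(mesh)
  # package path: assemble internal forces only (p = 0), no constraints
  model$isfix[] <- FALSE; model$fixed <- integer(0)
  out <- assemble(model, U, 0)
  f_pkg <- out$residual
  # independent path
  w_scalar <- function(cxx, cyy, cxy, c3) {
    t2 <- cxx + cyy; d2 <- cxx * cyy - cxy^2; J <- sqrt(d2 * c3)
    I1 <- (t2 + c3) * J^(-2 / 3); I2 <- (d2 + c3 * t2) * J^(-4 / 3)
    mat$C10 * (I1 - 3) + mat$C01 * (I2 - 3) + mat$C20 * (I1 - 3)^2 +
      mat$C02 * (I2 - 3)^2 + mat$C11 * (I1 - 3) * (I2 - 3) +
      (1 / mat$d1) * (J - 1)^2
  }
  Cm <- crossprod(Fh)
  # Richardson-extrapolated central differences: O(h^4) truncation, needed
  # because the volumetric penalty makes the plain O(h^2) error ~1e-7
  rich <- function(f, x, h) {
    d1 <- (f(x + h) - f(x - h)) / (2 * h)
    d2 <- (f(x + h / 2) - f(x - h / 2)) / h
    (4 * d2 - d1) / 3
  }
  c3 <- stats::optimize(function(l3) w_scalar(Cm[1, 1], Cm[2, 2], Cm[1, 2],
                                              l3^2),
                        c(0.3, 3), tol = 1e-12)$minimum^2
  # polish: root of dW/dc3 = 0 with the extrapolated derivative
  g3 <- function(z) rich(function(c3v) w_scalar(Cm[1, 1], Cm[2, 2],
                                                Cm[1, 2], c3v), z, 1e-6)
  c3 <- stats::uniroot(g3, c(0.9 * c3, 1.1 * c3), tol = 1e-14)$root
  dS <- function(k) {
    f <- function(z) {
      cc <- c(Cm[1, 1], Cm[2, 2], Cm[1, 2]); cc[k] <- z
      w_scalar(cc[1], cc[2], cc[3], c3)
    }
    rich(f, c(Cm[1, 1], Cm[2, 2], Cm[1, 2])[k], 1e-6)
  }
  S <- matrix(c(2 * dS(1), dS(3), dS(3), 2 * dS(2)), 2, 2)
  P <- Fh %*% S
  A0 <- 2e-6
  grads <- rbind(c(-1, -1), c(1, 0), c(0, 1)) / 2e-3
  f_ref <- t(vapply(1:3, function(a) A0 * as.numeric(P %*% grads[a, ]),
                    numeric(2)))
  f_ref_v <- as.vector(t(f_ref))
  max(abs(f_pkg - f_ref_v)) / max(abs(f_ref_v))
}

follower_circle_check <- function() {
  em <- structured_annulus_mesh(1e-3, 1.5e-3, 1e-4)
  ring <- em$inner_ring
  loop <- cbind(c(ring[1], rev(ring[-1])), c(rev(ring[-1]), ring[1]))
  mesh <- structure(list(nodes = em$nodes, tri = em$tri,
                         region = rep("spongy_sane", nrow(em$tri)),
                         edge_groups = list(lumen = loop, holes = list(),
                                            outer = NULL),
                         h_coarse = 1e-4, h_fine = 1e-4,
                         pin_nodes = c(1L, 2L),
                         domain = list(params = list(lumen_center = c(0, 0)))),
                    class = "fe_mesh")
  p <- 7
  fp <- follower_pressure_forces(mesh, matrix(0, nrow(em$nodes), 2), p)
  net <- sqrt(sum(colSums(fp$forces)^2)) / (p * 1e-3)
  mag <- abs(sum(sqrt(rowSums(fp$forces^2))) - 2 * pi * 1e-3 * p) /
    (2 * pi * 1e-3 * p)
  list(net = net, mag = mag)
}

# Spongy annulus at p = 1 Pa against the plane-stress Lame solution.
lame_annulus_check <- function(h = 1.5e-4) {
  mesh <- annulus_fixture_mesh(1e-3, 3e-3, h)
  onx <- which(abs(mesh$nodes[, 2]) < 1e-9)
  ony <- which(abs(mesh$nodes[, 1]) < 1e-9)
  model <- fe_model(mesh, fixed_dofs = sort(c(2L * onx, 2L * ony - 1L)))
  res <- solve_increments(model, levels = 1, settings = solver_settings())
  if (res$failed) return(Inf)
  ring <- which(abs(sqrt(rowSums(mesh$nodes^2)) - 1e-3) < 1e-9)
  ur <- rowSums(res$U[ring, ] * mesh$nodes[ring, ]) / 1e-3
  mu <- material_table()$spongy$mu0
  K <- material_table()$spongy$kappa0
  nu <- (3 * K - 2 * mu) / (2 * (3 * K + mu))
  E <- 2 * mu * (1 + nu)
  a <- 1e-3; b <- 3e-3
  uref <- a^2 / (E * (b^2 - a^2)) * ((1 - nu) * a + (1 + nu) * b^2 / a)
  abs(mean(ur) - uref) / uref
}

annulus_fixture_mesh <- function(r0, r1, h, region = "spongy_sane") {
  nth <- 4L * ceiling(2 * pi * r1 / (h / sqrt(2)) / 4)
  em <- structured_annulus_mesh(r0, r1, h, n_theta = nth)
  ring <- em$inner_ring
  loop <- cbind(c(ring[1], rev(ring[-1])), c(rev(ring[-1]), ring[1]))
  outer <- em$outer_ring
  structure(list(nodes = em$nodes, tri = em$tri,
                 region = rep(region, nrow(em$tri)),
                 edge_groups = list(lumen = loop, holes = list(),
                                    outer = NULL),
                 h_coarse = h, h_fine = h,
                 pin_nodes = c(outer[which.max(em$nodes[outer, 2])],
                               outer[which.min(em$nodes[outer, 2])]),
                 domain = list(params = list(lumen_center = c(0, 0),
                                             lumen_radius = r0))),
            class = "fe_mesh")
}

# Refining the annulus mesh by 2x changes the inner-boundary area by < 0.5%.
annulus_refinement_check <- function() {
  area_at <- function(h) {
    mesh <- annulus_fixture_mesh(1e-3, 3e-3, h)
    onx <- which(abs(mesh$nodes[, 2]) < 1e-9)
    ony <- which(abs(mesh$nodes[, 1]) < 1e-9)
    model <- fe_model(mesh, fixed_dofs = sort(c(2L * onx, 2L * ony - 1L)))
    res <- solve_increments(model, levels = 50, settings = solver_settings())
    lumen_area(list(mesh = mesh, U = res$U))
  }
  a1 <- area_at(3e-4); a2 <- area_at(1.5e-4)
  abs(a2 - a1) / a2
}
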