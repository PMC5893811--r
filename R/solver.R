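#' Flow solver configuration
#'
#' Numerical parameters of the transient incompressible solver. The defaults
#' mirror the study protocol: time step 0.5 ms, four cardiac cycles of 0.8 s.
#' The scheme is a semi-implicit incremental pressure-projection method on P1
#' triangles: explicit SUPG-stabilized advection, implicit viscosity, a
#' pressure-increment Poisson solve gauged by the zero-pressure pulmonary-vein
#' boundary, followed by an exact face-flux projection so the transport step
#' sees discretely divergence-free volume fluxes.
#'
#' @param dt time step (s); must divide the period `T`.
#' @param n_cycles number of cardiac cycles (>= 1).
#' @param T cycle period (s).
#' @param advection_scheme `"supg"` (stabilized, default) or `"galerkin"`.
#' @param pressure_tol tolerance (1/s) on the post-projection divergence of
#'   the face fluxes.
#' @param cfl_limit advective CFL bound checked every step.
#' @param cfl_action `"error"`, `"warn"` or `"none"` on CFL violation.
#' @param scalar_order 1 (upwind) or 2 (MUSCL with Barth-Jespersen limiter)
#'   for the contrast transport.
#' @param backflow_stabilization damp incoming momentum flux at the open
#'   pulmonary-vein boundaries (directional do-nothing).
#' @param snapshot_phases cycle fractions at which velocity snapshots are
#'   recorded (used by the periodicity metric).
#' @param periodicity_threshold relative cycle-to-cycle velocity difference
#'   below which the flow is considered periodic.
#' @param pressure_increment use the incremental pressure-correction form
#'   (solve for a pressure increment). The default is the non-incremental
#'   form, which on equal-order P1/P1 elements damps spurious pressure modes
#'   that the incremental form lets accumulate through the SUPG term on
#'   domains with open boundaries.
#' @return an object of class `laa_solver_config`.
#' @export
flow_solver_config <- function(dt = 5e-4, n_cycles = 4L, T = 0.8,
                               advection_scheme = c("supg", "galerkin"),
                               pressure_tol = 1e-8,
                               cfl_limit = 0.9,
                               cfl_action = c("error", "warn", "none"),
                               scalar_order = 2L,
                               backflow_stabilization = TRUE,
                               snapshot_phases = c(seq(0.125, 0.875,
                                                       by = 0.125),
                                                   0.9375, 1),
                               periodicity_threshold = 0.1,
                               pressure_increment = FALSE) {
  advection_scheme <- match.arg(advection_scheme)
  cfl_action <- match.arg(cfl_action)
  if (!is.numeric(dt) || dt <= 0) stop("argument error: dt must be positive")
  if (n_cycles < 1L) stop("argument error: n_cycles must be >= 1")
  if (T <= 0) stop("argument error: T must be positive")
  steps <- T / dt
  if (abs(steps - round(steps)) > 1e-8 * steps)
    stop("argument error: dt must divide the cycle period T")
  if (!scalar_order %in% c(1L, 2L))
    stop("argument error: scalar_order must be 1 or 2")
  structure(list(dt = dt, n_cycles = as.integer(n_cycles), T = T,
                 advection_scheme = advection_scheme,
                 pressure_tol = pressure_tol, cfl_limit = cfl_limit,
                 cfl_action = cfl_action, scalar_order = as.integer(scalar_order),
                 backflow_stabilization = isTRUE(backflow_stabilization),
                 snapshot_phases = snapshot_phases,
                 periodicity_threshold = periodicity_threshold,
                 pressure_increment = isTRUE(pressure_increment)),
            class = "laa_solver_config")
}

#' Initialize the flow state
#'
#' Fluid at rest, pressure at the pulmonary-vein reference, and the virtual
#' contrast agent set to 1 uniformly over the whole fluid domain.
#'
#' @param mesh an `laa_mesh`.
#' @param config a [flow_solver_config()].
#' @return an object of class `laa_flow_state` holding `t`, nodal velocity
#'   (`u`, `v`), nodal pressure `p` and cell concentrations `c`.
#' @export
flow_initialize <- function(mesh, config = flow_solver_config()) {
  stopifnot(inherits(mesh, "laa_mesh"))
  n <- nrow(mesh$vertices); m <- nrow(mesh$triangles)
  structure(list(t = 0, u = numeric(n), v = numeric(n), p = numeric(n),
                 c = rep(1, m), mesh = mesh,
                 div_flux = 0, div_weak = 0, mass_out = 0, mass_in = 0,
                 ops = NULL),
            class = "laa_flow_state")
}

# prefactored operators for a (mesh, bcs, props, config) combination
.solver_ops <- function(mesh, bcs, props, config) {
  op <- mesh$operators
  n <- nrow(mesh$vertices); m <- nrow(mesh$triangles)
  dt <- config$dt; nu <- props$nu

  dir_nodes <- sort(unique(c(bcs$wall_nodes, bcs$mitral_nodes)))
  free <- setdiff(seq_len(n), dir_nodes)
  A <- Matrix::Diagonal(n, op$Mlump / dt) + nu * op$K
  chA <- Matrix::Cholesky(Matrix::forceSymmetric(A[free, free, drop = FALSE]),
                          LDL = FALSE, perm = TRUE)
  A_sub <- A[free, , drop = FALSE]

  pdir <- bcs$pv_nodes
  if (!length(pdir)) pdir <- 1L
  pfree <- setdiff(seq_len(n), pdir)
  chP <- Matrix::Cholesky(
    Matrix::forceSymmetric(op$K[pfree, pfree, drop = FALSE]),
    LDL = FALSE, perm = TRUE)

  f <- mesh$faces
  nf <- length(f$left)
  bnd <- f$right == 0L
  code <- integer(nf) # 0 interior, 1 wall, 2 pv, 3 mitral
  code[bnd & f$tag == "wall"] <- 1L
  code[bnd & grepl("^pv_", f$tag)] <- 2L
  code[bnd & f$tag == "mitral"] <- 3L

  # face-flux projection (two-point) Laplacian over cells: interior and
  # pulmonary-vein faces are correctable, walls and the prescribed mitral
  # flux are not.
  cx <- mesh$centroid[, 1L]; cy <- mesh$centroid[, 2L]
  tcoef <- numeric(nf)
  int <- which(code == 0L)
  dx <- cx[f$right[int]] - cx[f$left[int]]
  dy <- cy[f$right[int]] - cy[f$left[int]]
  tcoef[int] <- f$len[int] / pmax(sqrt(dx^2 + dy^2), 1e-14)
  pvb <- which(code == 2L)
  if (length(pvb)) {
    dpv <- sqrt((f$mx[pvb] - cx[f$left[pvb]])^2 +
                (f$my[pvb] - cy[f$left[pvb]])^2)
    tcoef[pvb] <- f$len[pvb] / pmax(dpv, 1e-14)
  }
  ii <- c(f$left[int], f$right[int], f$left[int], f$right[int])
  jj <- c(f$left[int], f$right[int], f$right[int], f$left[int])
  xx <- c(tcoef[int], tcoef[int], -tcoef[int], -tcoef[int])
  if (length(pvb)) {
    ii <- c(ii, f$left[pvb]); jj <- c(jj, f$left[pvb]); xx <- c(xx, tcoef[pvb])
  }
  Lc <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, m))
  cfree <- if (length(pvb)) seq_len(m) else 2:m # pure Neumann: pin one cell
  chC <- Matrix::Cholesky(
    Matrix::forceSymmetric(Lc[cfree, cfree, drop = FALSE]),
    LDL = FALSE, perm = TRUE)

  # lumped boundary lengths on pulmonary-vein nodes (backflow damping)
  pv_face_idx <- which(code == 2L)
  pv_bl <- numeric(n)
  for (fi in pv_face_idx) {
    pv_bl[f$n1[fi]] <- pv_bl[f$n1[fi]] + f$len[fi] / 2
    pv_bl[f$n2[fi]] <- pv_bl[f$n2[fi]] + f$len[fi] / 2
  }
  pv_all_nodes <- which(pv_bl > 0)
  # unit outward normal per pv node (length-weighted)
  pv_nx <- numeric(n); pv_ny <- numeric(n)
  for (fi in pv_face_idx) {
    for (nd in c(f$n1[fi], f$n2[fi])) {
      pv_nx[nd] <- pv_nx[nd] + f$nxl[fi] / 2
      pv_ny[nd] <- pv_ny[nd] + f$nyl[fi] / 2
    }
  }
  nrm <- sqrt(pv_nx^2 + pv_ny^2); nrm[nrm == 0] <- 1
  pv_nx <- pv_nx / nrm; pv_ny <- pv_ny / nrm

  list(n = n, m = m, K = op$K, Gx = op$Gx, Gy = op$Gy, Ml = op$Mlump,
       dir_nodes = dir_nodes, free = free, chA_ff = chA, A_sub = A_sub,
       pdir = pdir, pfree = pfree, chP = chP,
       code = code, tcoef = tcoef, cfree = cfree, chC = chC,
       face_xy = cbind(f$mx, f$my), face_nl = cbind(f$nxl, f$nyl),
       pv_bl = pv_bl, pv_nodes_all = pv_all_nodes, pv_nx = pv_nx,
       pv_ny = pv_ny, V_domain = sum(mesh$area),
       dt = dt, nu = nu, rho = props$rho)
}

# Dirichlet nodal velocities at time t (walls at rest, mitral plug)
.dirichlet_velocity <- function(bcs, ops, t) {
  uD <- numeric(ops$n); vD <- numeric(ops$n)
  if (length(bcs$mitral_nodes)) {
    vt <- mitral_velocity(t, bcs$waveform)
    uD[bcs$mitral_nodes] <- vt * bcs$plug_direction[1L]
    vD[bcs$mitral_nodes] <- vt * bcs$plug_direction[2L]
  }
  list(u = uD, v = vD)
}

#' Advance velocity and pressure by one projection step
#'
#' Semi-implicit fractional step: explicit (SUPG-stabilized) advection of the
#' current velocity, implicit viscous solve for the tentative velocity with
#' no-slip and mitral-plug Dirichlet conditions at the new time level, a
#' pressure-increment Poisson solve gauged at the pulmonary veins, and the
#' divergence-removing velocity correction.
#'
#' @param state an `laa_flow_state`.
#' @param bcs an [assemble_bcs()] result for the state's mesh.
#' @param props [fluid_properties()].
#' @param config [flow_solver_config()].
#' @param forcing optional body force `function(x, y, t)` returning
#'   `list(fx, fy)` at the mesh vertices (verification runs).
#' @return the advanced `laa_flow_state` (velocity, pressure, time; the
#'   contrast field is untouched — see [contrast_step()]).
#' @export
momentum_step <- function(state, bcs, props = fluid_properties(),
                          config = flow_solver_config(), forcing = NULL) {
  stopifnot(inherits(state, "laa_flow_state"))
  mesh <- state$mesh
  if (is.null(state$ops))
    state$ops <- .solver_ops(mesh, bcs, props, config)
  ops <- state$ops
  dt <- config$dt
  t_new <- state$t + dt

  # CFL check on the current velocity
  tri <- mesh$triangles
  umag <- sqrt(state$u^2 + state$v^2)
  ucell <- pmax(umag[tri[, 1L]], umag[tri[, 2L]], umag[tri[, 3L]])
  cfl <- dt * max(ucell / mesh$he)
  if (cfl > config$cfl_limit && config$cfl_action != "none") {
    msg <- sprintf("stability error: advective CFL %.2f exceeds limit %.2f",
                   cfl, config$cfl_limit)
    if (config$cfl_action == "error") stop(msg) else warning(msg)
  }

  fx <- numeric(0); fy <- numeric(0)
  if (!is.null(forcing)) {
    fv <- forcing(mesh$vertices[, 1L], mesh$vertices[, 2L], t_new)
    fx <- fv$fx; fy <- fv$fy
  }
  incr <- isTRUE(config$pressure_increment)
  pold <- if (incr) state$p else numeric(ops$n)
  adv <- .cpp_advection_rhs(tri, mesh$area, mesh$gx, mesh$gy, mesh$he,
                            state$u, state$v, pold, fx, fy,
                            ops$rho, ops$nu,
                            config$advection_scheme == "supg")

  rhs_u <- ops$Ml * state$u / dt - adv$Nx -
    as.vector(ops$Gx %*% pold) / ops$rho
  rhs_v <- ops$Ml * state$v / dt - adv$Ny -
    as.vector(ops$Gy %*% pold) / ops$rho
  if (length(fx)) {
    rhs_u <- rhs_u + ops$Ml * fx
    rhs_v <- rhs_v + ops$Ml * fy
  }
  if (config$backflow_stabilization && length(ops$pv_nodes_all)) {
    nd <- ops$pv_nodes_all
    un <- state$u[nd] * ops$pv_nx[nd] + state$v[nd] * ops$pv_ny[nd]
    w <- 0.5 * pmin(un, 0) * ops$pv_bl[nd]
    rhs_u[nd] <- rhs_u[nd] + w * state$u[nd]
    rhs_v[nd] <- rhs_v[nd] + w * state$v[nd]
  }

  bc <- .dirichlet_velocity(bcs, ops, t_new)
  ustar <- bc$u; vstar <- bc$v
  full_u <- numeric(ops$n); full_u[ops$dir_nodes] <- bc$u[ops$dir_nodes]
  full_v <- numeric(ops$n); full_v[ops$dir_nodes] <- bc$v[ops$dir_nodes]
  ru <- rhs_u[ops$free] - as.vector(ops$A_sub %*% full_u)
  rv <- rhs_v[ops$free] - as.vector(ops$A_sub %*% full_v)
  ustar[ops$free] <- as.vector(Matrix::solve(ops$chA_ff, ru))
  vstar[ops$free] <- as.vector(Matrix::solve(ops$chA_ff, rv))

  d <- as.vector(ops$Gx %*% ustar + ops$Gy %*% vstar)
  phi <- numeric(ops$n)
  phi[ops$pfree] <- as.vector(Matrix::solve(ops$chP,
                                            -(ops$rho / dt) * d[ops$pfree]))
  gpx <- as.vector(ops$Gx %*% phi) / ops$Ml
  gpy <- as.vector(ops$Gy %*% phi) / ops$Ml
  u <- ustar; v <- vstar
  u[ops$free] <- ustar[ops$free] - (dt / ops$rho) * gpx[ops$free]
  v[ops$free] <- vstar[ops$free] - (dt / ops$rho) * gpy[ops$free]

  dnew <- as.vector(ops$Gx %*% u + ops$Gy %*% v)
  div_weak <- sqrt(sum(dnew^2 / ops$Ml) / ops$V_domain)

  state$u <- u; state$v <- v
  state$p <- if (incr) state$p + phi else phi
  state$t <- t_new
  state$div_weak <- div_weak
  state$cfl <- cfl
  state
}

# volume fluxes across all faces from nodal velocities + Dirichlet values,
# then projected so every cell's net flux vanishes (machine precision).
.projected_fluxes <- function(state, ops, mesh) {
  f <- mesh$faces
  Fv <- 0.5 * ((state$u[f$n1] + state$u[f$n2]) * f$nxl +
               (state$v[f$n1] + state$v[f$n2]) * f$nyl)
  Fv[ops$code == 1L] <- 0 # rigid walls: exact

  m <- ops$m
  div <- numeric(m)
  agg <- rowsum(c(Fv, -Fv[ops$code == 0L]),
                c(f$left, f$right[ops$code == 0L]))
  div[as.integer(rownames(agg))] <- agg[, 1L]
  lam <- numeric(m)
  lam[ops$cfree] <- as.vector(Matrix::solve(ops$chC, div[ops$cfree]))
  corr <- numeric(length(Fv))
  int <- ops$code == 0L
  corr[int] <- ops$tcoef[int] * (lam[f$left[int]] - lam[f$right[int]])
  pvb <- ops$code == 2L
  corr[pvb] <- ops$tcoef[pvb] * lam[f$left[pvb]]
  Fp <- Fv - corr

  div2 <- numeric(m)
  agg2 <- rowsum(c(Fp, -Fp[int]), c(f$left, f$right[int]))
  div2[as.integer(rownames(agg2))] <- agg2[, 1L]
  list(flux = Fp, div_flux = max(abs(div2) / mesh$area))
}

#' Advance the virtual contrast agent by one step
#'
#' Pure advection of the cell-wise concentration by the projected
#' (divergence-free) face fluxes of the current velocity, using a monotone
#' MUSCL/upwind finite-volume scheme with the Barth-Jespersen limiter.
#' Inflowing fluid at the pulmonary veins carries zero concentration; outflow
#' through the mitral orifice removes contrast with the flow. The scheme is
#' conservative and keeps `0 <= c <= 1`; sub-steps are taken automatically
#' when the advective CFL of the transport would exceed 0.22.
#'
#' @inheritParams momentum_step
#' @return the state with the contrast field advanced to the state's time.
#' @export
contrast_step <- function(state, bcs, props = fluid_properties(),
                          config = flow_solver_config()) {
  stopifnot(inherits(state, "laa_flow_state"))
  mesh <- state$mesh
  if (is.null(state$ops))
    state$ops <- .solver_ops(mesh, bcs, props, config)
  ops <- state$ops
  pf <- .projected_fluxes(state, ops, mesh)
  if (pf$div_flux > config$pressure_tol)
    stop(sprintf("solver error: projected flux divergence %.3g above tolerance %.3g",
                 pf$div_flux, config$pressure_tol))
  f <- mesh$faces
  outflow <- numeric(ops$m)
  pos <- pf$flux > 0
  if (any(pos)) {
    agg <- rowsum(pf$flux[pos], f$left[pos])
    outflow[as.integer(rownames(agg))] <- agg[, 1L]
  }
  neg <- pf$flux < 0 & ops$code == 0L
  if (any(neg)) {
    agg <- rowsum(-pf$flux[neg], f$right[neg])
    outflow[as.integer(rownames(agg))] <-
      outflow[as.integer(rownames(agg))] + agg[, 1L]
  }
  rate <- max(outflow / mesh$area)
  nsub <- max(1L, ceiling(config$dt * rate / 0.22))
  dts <- config$dt / nsub
  cc <- state$c
  right0 <- ifelse(ops$code == 0L, f$right, 0L)
  for (k in seq_len(nsub)) {
    st <- .cpp_scalar_step(cc, f$left, right0, pf$flux,
                           mesh$centroid, ops$face_xy, ops$face_nl,
                           mesh$area, dts, 0, config$scalar_order)
    cc <- st$c
    state$mass_out <- state$mass_out + st$mass_out
    state$mass_in <- state$mass_in + st$mass_in
  }
  tol <- 1e-8
  if (min(cc) < -tol || max(cc) > 1 + tol)
    stop(sprintf("scheme error: contrast out of [0,1] (range %.3g .. %.3g)",
                 min(cc), max(cc)))
  state$c <- pmin(1, pmax(0, cc))
  state$div_flux <- pf$div_flux
  state
}

#' Run a transient washout simulation
#'
#' Time-marches the flow and the virtual contrast agent over `n_cycles`
#' cardiac cycles, recording velocity snapshots at fixed cycle phases, a
#' per-step diagnostics table (kinetic energy, divergence norms, total
#' contrast, CFL) and time averages of the velocity magnitude and shear
#' strain rate over the stationary window (cycles 2 and later; the first
#' cycle is spin-up), used by the stasis metrics.
#'
#' @param mesh an `laa_mesh`.
#' @param bcs an [assemble_bcs()] result.
#' @param props [fluid_properties()].
#' @param config [flow_solver_config()].
#' @param forcing optional body force (see [momentum_step()]).
#' @param transport advance the contrast agent (default `TRUE`).
#' @param verbose print one diagnostic line per cycle.
#' @return an object of class `laa_flow_run`.
#' @export
run_flow <- function(mesh, bcs, props = fluid_properties(),
                     config = flow_solver_config(), forcing = NULL,
                     transport = TRUE, verbose = FALSE) {
  stopifnot(inherits(mesh, "laa_mesh"), inherits(bcs, "laa_bcset"))
  state <- flow_initialize(mesh, config)
  state$ops <- .solver_ops(mesh, bcs, props, config)
  ops <- state$ops
  spc <- round(config$T / config$dt)
  nsteps <- config$n_cycles * spc
  phases <- config$snapshot_phases
  snap_steps <- pmax(1L, round(phases * spc))

  metrics <- data.frame(t = numeric(nsteps), ke = numeric(nsteps),
                        div_weak = numeric(nsteps),
                        div_flux = numeric(nsteps),
                        total_contrast = numeric(nsteps),
                        cfl = numeric(nsteps))
  snapshots <- vector("list", config$n_cycles)
  for (cy in seq_len(config$n_cycles))
    snapshots[[cy]] <- vector("list", length(phases))
  vmag_sum <- numeric(ops$n); ssr_sum <- numeric(ops$m); n_avg <- 0L
  V <- ops$V_domain

  for (step in seq_len(nsteps)) {
    state <- momentum_step(state, bcs, props, config, forcing)
    if (transport) state <- contrast_step(state, bcs, props, config)
    cy <- ((step - 1L) %/% spc) + 1L
    ph <- match(step - (cy - 1L) * spc, snap_steps)
    if (!is.na(ph))
      snapshots[[cy]][[ph]] <- list(u = state$u, v = state$v, t = state$t)
    if (cy >= 2L || config$n_cycles == 1L) {
      # stationary-window averages: the first cycle is spin-up
      vmag_sum <- vmag_sum + sqrt(state$u^2 + state$v^2)
      ssr_sum <- ssr_sum + .ssr_cells(mesh, state$u, state$v)
      n_avg <- n_avg + 1L
    }
    metrics$t[step] <- state$t
    metrics$ke[step] <- 0.5 * ops$rho * sum(ops$Ml * (state$u^2 + state$v^2))
    metrics$div_weak[step] <- state$div_weak
    metrics$div_flux[step] <- state$div_flux
    metrics$total_contrast[step] <- sum(state$c * mesh$area) / V
    metrics$cfl[step] <- state$cfl
    if (verbose && step %% spc == 0L)
      message(sprintf(
        "cycle %d/%d: KE=%.3e J/m, div_flux=%.2e 1/s, contrast=%.4f, CFL=%.2f",
        cy, config$n_cycles, metrics$ke[step], metrics$div_flux[step],
        metrics$total_contrast[step], metrics$cfl[step]))
  }

  structure(list(state = state, snapshots = snapshots, phases = phases,
                 metrics = metrics, mesh = mesh, bcs = bcs, props = props,
                 config = config, steps_per_cycle = spc,
                 time_avg = list(vmag = vmag_sum / max(1L, n_avg),
                                 ssr = ssr_sum / max(1L, n_avg))),
            class = "laa_flow_run")
}

#' @export
print.laa_flow_run <- function(x, ...) {
  nm <- nrow(x$metrics)
  cat(sprintf("laa_flow_run [%s]: %d cycles x %d steps (dt = %.2g ms)\n",
              x$bcs$condition, x$config$n_cycles, x$steps_per_cycle,
              1000 * x$config$dt))
  cat(sprintf("  final total contrast %.4f, max CFL %.2f, max flux divergence %.2e 1/s\n",
              x$metrics$total_contrast[nm], max(x$metrics$cfl),
              max(x$metrics$div_flux)))
  invisible(x)
}
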