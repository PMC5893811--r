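# shared fixtures, built once per test session and memoised

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# coarse chicken-wing anatomy + mesh (used by meshing/centerline/bcs tests)
cw_mesh <- function() fixture("cw_mesh", function() {
  an <- generate_anatomy(default_anatomy_specs(seed = 1)$chicken_wing)
  list(anatomy = an, mesh = generate_mesh(an, h = 1.4e-3))
})

# straight "appendage" on a structured rectangle: left strip is LA, rest LAA
rect_laa_mesh <- function(nx = 48, ny = 8, L = 0.06, H = 0.01) {
  structured_rect_mesh(nx, ny, L, H,
                       region = function(cx, cy) cx > L / 6)
}

# channel with open ends for transport tests
open_channel_mesh <- function(nx = 60, ny = 15, Lx = 4, Ly = 1) {
  tagf <- function(mx, my) {
    if (abs(mx) < 1e-9) "pv_1" else if (abs(mx - Lx) < 1e-9) "pv_2" else "wall"
  }
  structured_rect_mesh(nx, ny, Lx, Ly, facet_tags = tagf)
}

# force a prescribed nodal velocity into a state (transport-only tests)
with_velocity <- function(mesh, u, v, config, bcs) {
  st <- flow_initialize(mesh, config)
  st$ops <- laastasis:::.solver_ops(mesh, bcs, fluid_properties(), config)
  st$u <- u; st$v <- v
  st
}

# body-force-driven Poiseuille channel, returns state + exact profile error
poiseuille_error <- function(nx = 24, ny = 12, nsteps = 500, dt = 0.02,
                             nu = 0.1, scheme = "supg") {
  tagf <- function(mx, my) {
    if (abs(mx) < 1e-9) "pv_1" else if (abs(mx - 2) < 1e-9) "pv_2" else "wall"
  }
  msh <- structured_rect_mesh(nx, ny, 2, 1, facet_tags = tagf)
  props <- fluid_properties(rho = 1, mu = nu)
  cfg <- flow_solver_config(dt = dt, n_cycles = 1, T = nsteps * dt,
                            cfl_limit = 3, backflow_stabilization = FALSE,
                            advection_scheme = scheme)
  bcs <- assemble_bcs(msh, "healthy")
  st <- flow_initialize(msh, cfg)
  forcing <- function(x, y, t) list(fx = rep(8 * nu, length(x)),
                                    fy = rep(0, length(x)))
  div_flux <- numeric(nsteps)
  for (i in seq_len(nsteps)) {
    st <- momentum_step(st, bcs, props, cfg, forcing = forcing)
    pf <- laastasis:::.projected_fluxes(st, st$ops, msh)
    div_flux[i] <- pf$div_flux
  }
  uex <- 4 * msh$vertices[, 2] * (1 - msh$vertices[, 2])
  Ml <- msh$operators$Mlump
  err <- sqrt(sum(Ml * ((st$u - uex)^2 + st$v^2)) / sum(Ml * uex^2))
  list(err = err, state = st, mesh = msh, div_flux = div_flux)
}

# forced steady vortex (manufactured solution): relative L2 velocity error
mms_error <- function(n, nu = 0.2, dt = 0.002, t_end = 3) {
  msh <- structured_rect_mesh(n, n, 1, 1)
  props <- fluid_properties(rho = 1, mu = nu)
  cfg <- flow_solver_config(dt = dt, n_cycles = 1, T = t_end, cfl_limit = 3,
                            backflow_stabilization = FALSE)
  bcs <- assemble_bcs(msh, "healthy")
  forcing <- function(x, y, t) {
    sx <- sin(pi * x); sy <- sin(pi * y)
    cx <- cos(pi * x); cy <- cos(pi * y)
    list(fx = pi * (16 * pi^2 * nu * sx^2 * sy * cy - 4 * pi^2 * nu * sy * cy +
                      4 * pi^2 * sx^3 * sy^2 * cx - sx * cy),
         fy = pi * (-16 * pi^2 * nu * sx * sy^2 * cx + 4 * pi^2 * nu * sx * cx +
                      4 * pi^2 * sx^2 * sy^3 * cy - sy * cx))
  }
  st <- flow_initialize(msh, cfg)
  for (i in seq_len(round(t_end / dt)))
    st <- momentum_step(st, bcs, props, cfg, forcing = forcing)
  xx <- msh$vertices[, 1L]; yy <- msh$vertices[, 2L]
  uex <- 2 * pi * sin(pi * xx)^2 * sin(pi * yy) * cos(pi * yy)
  vex <- -2 * pi * sin(pi * xx) * sin(pi * yy)^2 * cos(pi * xx)
  Ml <- msh$operators$Mlump
  sqrt(sum(Ml * ((st$u - uex)^2 + (st$v - vex)^2)) /
         sum(Ml * (uex^2 + vex^2)))
}
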